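## Pseudo-spring mean-force estimation and PMF integration.
##
## The measurement model: two helices tethered by a harmonic spring of
## constant k (kJ/(mol nm^2)) and rest length x0; in equilibrium the mean
## force between the helices equals k * mean(x - x0), with the sign
## convention that a stretched spring (mean x > x0) means the underlying
## free-energy surface pushes the helices apart, i.e. positive = repulsive,
## and a compressed spring means attraction (negative).  The PMF is the
## inward integral of the mean force from an outer reference separation.

#' Block-averaged standard error of a (possibly correlated) series
#'
#' Computes the standard error of the mean by block averaging with doubling
#' block sizes.  The plateau is detected as the first doubling at which the
#' blocked SEM grows by less than 5 percent; the SEM after that doubling is
#' returned.  If the curve never flattens (strong long-range correlation for
#' the available length), the largest blocked SEM is returned — a
#' conservative choice.
#'
#' @param x Numeric series (>= 16 samples).
#' @param min_blocks Smallest number of blocks to allow (default 8).
#' @return The plateau SEM (same units as `x`).
#' @export
block_sem <- function(x, min_blocks = 8) {
  n <- length(x)
  if (n < 16) stop("block_sem needs >= 16 samples, got ", n)
  if (stats::sd(x) == 0) return(0)
  sems <- numeric(0)
  b <- 1
  while (n %/% b >= min_blocks) {
    nb <- n %/% b
    bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
    sems <- c(sems, stats::sd(bm) / sqrt(nb))
    b <- b * 2
  }
  if (length(sems) == 1) return(sems)
  ratio <- sems[-1] / sems[-length(sems)]
  flat <- which(ratio <= 1.05)
  if (length(flat)) sems[flat[1] + 1] else max(sems)
}

#' Mean force at one tether separation
#'
#' Applies the spring relation `F = k * mean(x - x0)` to the retained part of
#' a separation series, after discarding an initial equilibration segment.
#' The force is reported in kJ/(mol Angstrom) (positive = repulsive) and is
#' attributed to the mean retained separation, which removes the first-order
#' bias from the spring displacing the sampled window off its rest length.
#' The standard error comes from block averaging ([block_sem()]).
#'
#' @param series A `spring_series`.
#' @param equilibration Fraction of initial samples to discard (default 1/6,
#'   mirroring discarding ~10 of 60 ns in a typical production run).
#' @return Object of class `force_point`: list with `x` (mean retained
#'   separation, Angstrom), `x0`, `F` (kJ/(mol Angstrom)), `sem`,
#'   `n_effective`, `n_discarded`.
#' @examples
#' s <- spring_series(1000, 30, time = 1:100, x = rep(30, 100))
#' mean_force(s)$F   # 0: no spring deviation
#' @export
mean_force <- function(series, equilibration = 1 / 6) {
  stopifnot(inherits(series, "spring_series"))
  if (series$k <= 0) stop("spring constant must be > 0")
  if (equilibration < 0 || equilibration >= 1)
    stop("equilibration fraction must be in [0, 1)")
  n <- length(series$x)
  drop <- floor(n * equilibration)
  if (drop >= n) stop("all samples discarded as equilibration")
  xr <- series$x[(drop + 1):n]
  k_A <- series$k / 100                       # kJ/(mol nm^2) -> kJ/(mol A^2)
  Fm <- k_A * mean(xr - series$x0)
  sem <- if (length(xr) >= 16) k_A * block_sem(xr) else NA_real_
  naive <- stats::sd(xr) / sqrt(length(xr))
  n_eff <- if (!is.na(sem) && sem > 0 && naive > 0)
    max(1, length(xr) * (k_A * naive / sem)^2) else length(xr)
  structure(list(x = mean(xr), x0 = series$x0, F = Fm,
                 sem = sem, n_effective = n_eff, n_discarded = drop),
            class = "force_point")
}

#' @export
print.force_point <- function(x, ...) {
  cat(sprintf("<force_point> x=%.3f A  F=%+.4f kJ/(mol A) (sem %.4f), n_eff=%.0f\n",
              x$x, x$F, x$sem, x$n_effective))
  invisible(x)
}

#' Collect force points into a table
#' @param points List of `force_point` objects (or a data.frame with columns
#'   `x`, `F`, `sem`).
#' @return data.frame with columns `x`, `F`, `sem`.
#' @export
force_table <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "F") %in% names(points)))
    if (is.null(points$sem)) points$sem <- 0
    return(points[, c("x", "F", "sem")])
  }
  data.frame(x = vapply(points, `[[`, 0, "x"),
             F = vapply(points, `[[`, 0, "F"),
             sem = vapply(points, function(p)
               if (is.na(p$sem)) 0 else p$sem, 0))
}

#' Integrate mean forces into a potential of mean force
#'
#' Trapezoid integration of `F(x)` from each grid point inward-out to the
#' reference separation: `dG(x) = int_x^{x_ref} F dx'`, reported in units of
#' kT at 298 K with `dG(x_ref) = 0` exactly.  If `x_ref` lies beyond the
#' outermost sampled separation the outermost force is constant-extrapolated
#' over the gap (with a warning).  Point errors are propagated as independent
#' through the trapezoid weights.
#'
#' @param points List of `force_point`s or a data.frame (`x`, `F`, `sem`).
#' @param x_ref Reference separation, Angstrom (default 40).
#' @return Object of class `pmf_profile`: data.frame with columns `x`,
#'   `dG_kBT`, `sem_kBT`, and attributes `x_ref`, `method`.
#' @export
integrate_pmf <- function(points, x_ref = 40) {
  tab <- force_table(points)
  if (nrow(tab) < 2) stop("need at least 2 force points")
  tab <- tab[order(tab$x), ]
  if (any(diff(tab$x) == 0)) stop("duplicate separation values in force table")

  if (x_ref > max(tab$x)) {
    if (x_ref - max(tab$x) > 1e-9)
      warning(sprintf(
        "x_ref = %g A beyond outermost sampled separation %.3f A; ",
        x_ref, max(tab$x)),
        "constant-extrapolating the outermost force")
    tab <- rbind(tab, data.frame(x = x_ref, F = tab$F[nrow(tab)],
                                 sem = tab$sem[nrow(tab)]))
  } else if (x_ref < min(tab$x)) {
    stop("x_ref below the sampled range")
  } else if (!any(abs(tab$x - x_ref) < 1e-9)) {
    Fr <- stats::approx(tab$x, tab$F, xout = x_ref)$y
    sr <- stats::approx(tab$x, tab$sem, xout = x_ref)$y
    tab <- rbind(tab, data.frame(x = x_ref, F = Fr, sem = sr))
    tab <- tab[order(tab$x), ]
  }
  ## integrate only up to x_ref
  tab <- tab[tab$x <= x_ref + 1e-9, ]
  m <- nrow(tab)
  dx <- diff(tab$x)
  ## trapezoid weights: dG_i = sum_{j>=i} 0.5*(F_j + F_{j+1}) * dx_j
  seg <- 0.5 * (tab$F[-m] + tab$F[-1]) * dx
  dG <- rev(cumsum(rev(c(seg, 0))))           # kJ/mol, dG[m] = 0
  ## error propagation: weight of F_j in dG_i
  var <- numeric(m)
  for (i in seq_len(m)) {
    w <- numeric(m)
    if (i < m) {
      js <- i:(m - 1)
      w[js]     <- w[js]     + 0.5 * dx[js]
      w[js + 1] <- w[js + 1] + 0.5 * dx[js]
    }
    var[i] <- sum((w * tab$sem)^2)
  }
  out <- data.frame(x = tab$x, dG_kBT = dG / .kT, sem_kBT = sqrt(var) / .kT)
  attr(out, "x_ref") <- x_ref
  attr(out, "method") <- "spring_integration"
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' @export
print.pmf_profile <- function(x, ...) {
  imin <- which.min(x$dG_kBT)
  cat(sprintf("<pmf_profile> %s, %d points on [%.2f, %.2f] A, x_ref=%g A\n",
              attr(x, "method"), nrow(x), min(x$x), max(x$x),
              attr(x, "x_ref")))
  cat(sprintf("  minimum: %.3f kT at x = %.2f A\n",
              x$dG_kBT[imin], x$x[imin]))
  invisible(x)
}

#' Write / read a PMF profile as TSV
#' @param profile A `pmf_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmf_tsv <- function(profile, path) {
  write_tsv_table(data.frame(x_A = profile$x, dG_kBT = profile$dG_kBT,
                             sem_kBT = profile$sem_kBT), path,
                  meta = list(x_ref_A = attr(profile, "x_ref"),
                              method = attr(profile, "method")))
}

#' @rdname write_pmf_tsv
#' @export
read_pmf_tsv <- function(path) {
  df <- read_tsv_table(path)
  lines <- readLines(path)
  xr <- sub(".*x_ref_A:\\s*", "", grep("x_ref_A", lines, value = TRUE)[1])
  me <- sub(".*method:\\s*", "", grep("method", lines, value = TRUE)[1])
  out <- data.frame(x = df$x_A, dG_kBT = df$dG_kBT, sem_kBT = df$sem_kBT)
  attr(out, "x_ref") <- suppressWarnings(as.numeric(xr))
  attr(out, "method") <- me
  class(out) <- c("pmf_profile", "data.frame")
  out
}
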