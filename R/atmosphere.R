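## Ion-atmosphere analysis around one or two helices: cylindrical radial
## concentration profiles, internal/external binding taxonomy with groove
## splits, 3D charge-density grids, ion-bridge detection and water-dipole
## ordering around bridging ions.
##
## "Radial distance" is the perpendicular distance to a helix axis.  Profiles
## are restricted axially to the helix span plus a margin to limit end
## effects; shell normalization is the cylindrical-shell volume
## pi * (r2^2 - r1^2) * L_axial.

.perp_dist <- function(helix, pos) {
  dx <- pos[, 1] - helix$axis_origin[1]
  dy <- pos[, 2] - helix$axis_origin[2]
  sqrt(dx^2 + dy^2)
}

#' Cylindrical radial concentration profile of an ion species
#'
#' Bins each ion of `species` by its perpendicular distance to the helix
#' axis, restricted axially to the helix span plus `axial_margin`, and
#' converts mean counts per bin to mol/L through the cylindrical-shell
#' volume (1 ion/Angstrom^3 = 1660.539 mol/L).  Ions inside the axial slab
#' but beyond `r_max` are accumulated in an overflow bucket so that total
#' occupancy is conserved.
#'
#' @param traj An `ion_trajectory`.
#' @param helix A `helix_model`.
#' @param species Species name (default: first species in the trajectory).
#' @param bin_width Radial bin width, Angstrom (default 1).
#' @param r_max Outer profile radius, Angstrom (default 30).
#' @param axial_margin Axial allowance beyond the helix span, Angstrom
#'   (default 3; use `Inf` to include the whole box height).
#' @return Object of class `radial_profile`: data.frame with columns `r_lo`,
#'   `r_hi`, `count` (mean ions per frame per bin), `c_molL`; attributes
#'   `overflow` (mean ions beyond `r_max`), `L_axial`, `n_frames`, `species`.
#' @export
radial_profile <- function(traj, helix, species = NULL, bin_width = 1,
                           r_max = 30, axial_margin = 3) {
  if (bin_width <= 0) stop("bin width must be > 0")
  if (is.null(species)) species <- traj$species$name[1]
  rows <- species_rows(traj, species)
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1
  ext <- axial_extent(helix)
  zlo <- helix$axis_origin[3] - axial_margin
  zhi <- helix$axis_origin[3] + ext + axial_margin
  L <- if (is.finite(axial_margin)) ext + 2 * axial_margin else traj$box[3]
  if (!is.finite(axial_margin)) { zlo <- -Inf; zhi <- Inf }

  counts <- numeric(nb)
  overflow <- 0
  nf <- length(traj$frames)
  if (!length(rows)) {
    warning("species '", species, "' absent from trajectory; empty profile")
  } else {
    for (f in traj$frames) {
      p <- f[rows, , drop = FALSE]
      inz <- p[, 3] >= zlo & p[, 3] <= zhi
      r <- .perp_dist(helix, p[inz, , drop = FALSE])
      idx <- findInterval(r, edges, rightmost.closed = FALSE)
      inside <- idx >= 1 & idx <= nb & r < r_max
      counts <- counts + tabulate(idx[inside], nbins = nb)
      overflow <- overflow + sum(r >= r_max)
    }
    counts <- counts / nf
    overflow <- overflow / nf
  }
  shell_vol <- pi * (edges[-1]^2 - edges[-(nb + 1)]^2) * L
  out <- data.frame(r_lo = edges[-(nb + 1)], r_hi = edges[-1],
                    count = counts, c_molL = counts / shell_vol * .MOL)
  attr(out, "overflow") <- overflow
  attr(out, "L_axial") <- L
  attr(out, "n_frames") <- nf
  attr(out, "species") <- species
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Internal / external / bulk binding partition
#'
#' Classifies each ion of `species` by its perpendicular distance to the
#' nearest helix axis: internal for `r < r_int`, external for
#' `r_int <= r <= r_ext`, bulk beyond (defaults 11 and 15 Angstrom, the
#' conventional boundaries for the helix envelope and the outer-surface
#' shell).  Non-bulk ions are additionally split by groove sector via
#' [groove_of_point()] on their nearest helix.
#'
#' @param traj An `ion_trajectory`.
#' @param helices A `helix_model`, a list of them, or a `duplex_pair`.
#' @param r_int Internal/external boundary, Angstrom (default 11).
#' @param r_ext External/bulk boundary, Angstrom (default 15).
#' @param species Species name (default: first).
#' @return Object of class `binding_partition`: list with mean occupancies
#'   `internal`, `external`, `bulk`, `total`, and `groove` (data.frame of
#'   internal/external x major/minor mean occupancies).
#' @export
classify_binding <- function(traj, helices, r_int = 11, r_ext = 15,
                             species = NULL) {
  if (r_int >= r_ext) stop("r_int must be < r_ext")
  if (inherits(helices, "duplex_pair")) helices <- list(helices$helixA,
                                                        helices$helixB)
  if (inherits(helices, "helix_model")) helices <- list(helices)
  if (is.null(species)) species <- traj$species$name[1]
  rows <- species_rows(traj, species)
  nf <- length(traj$frames)

  acc <- c(internal = 0, external = 0, bulk = 0)
  gacc <- matrix(0, 2, 2, dimnames = list(c("internal", "external"),
                                          c("major", "minor")))
  for (f in traj$frames) {
    p <- f[rows, , drop = FALSE]
    if (!nrow(p)) next
    rmat <- vapply(helices, .perp_dist, numeric(nrow(p)), pos = p)
    rmat <- matrix(rmat, nrow = nrow(p))
    nearest <- max.col(-rmat)
    r <- rmat[cbind(seq_len(nrow(p)), nearest)]
    cls <- ifelse(r < r_int, "internal", ifelse(r <= r_ext, "external", "bulk"))
    acc <- acc + c(internal = sum(cls == "internal"),
                   external = sum(cls == "external"),
                   bulk = sum(cls == "bulk"))
    for (hi in unique(nearest)) {
      sel <- nearest == hi & cls != "bulk"
      if (!any(sel)) next
      g <- groove_of_point(helices[[hi]], p[sel, , drop = FALSE],
                           r_cutoff = Inf, axial_margin = Inf)
      for (cl in c("internal", "external"))
        for (gr in c("major", "minor"))
          gacc[cl, gr] <- gacc[cl, gr] + sum(g == gr & cls[sel] == cl)
    }
  }
  acc <- acc / nf
  gacc <- gacc / nf
  out <- list(internal = unname(acc["internal"]),
              external = unname(acc["external"]),
              bulk = unname(acc["bulk"]),
              total = sum(acc),
              groove = as.data.frame(gacc),
              r_int = r_int, r_ext = r_ext, species = species)
  class(out) <- "binding_partition"
  out
}

#' @export
print.binding_partition <- function(x, ...) {
  cat(sprintf("<binding_partition> %s: internal %.3f | external %.3f | bulk %.3f (per frame)\n",
              x$species, x$internal, x$external, x$bulk))
  cat(sprintf("  groove split (internal maj/min, external maj/min): %.3f/%.3f, %.3f/%.3f\n",
              x$groove["internal", "major"], x$groove["internal", "minor"],
              x$groove["external", "major"], x$groove["external", "minor"]))
  invisible(x)
}

#' Mean ion charge density on a 3D grid
#'
#' Nearest-voxel assignment of each ion's charge, averaged over frames and
#' divided by the voxel volume, giving e/Angstrom^3.  The grid covers the
#' whole box from the origin; conservation (sum density * voxel volume =
#' mean total gridded charge) holds by construction.
#'
#' @param traj An `ion_trajectory`.
#' @param species Character vector of species to include (default: all).
#' @param spacing Voxel edge, Angstrom (default 1; must be <= box/2).
#' @param threshold Display threshold stored with the grid, e/Angstrom^3
#'   (default 0.02).
#' @return Object of class `density_grid`: list with `origin`, `spacing`,
#'   `dim`, `density` (3D array, x-y-z order), `n_frames`, `species`,
#'   `threshold`.
#' @export
charge_density_grid <- function(traj, species = NULL, spacing = 1,
                                threshold = 0.02) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (spacing > min(traj$box) / 2)
    stop("spacing larger than half the smallest box dimension")
  if (is.null(species)) species <- traj$species$name
  rows <- unlist(lapply(species, species_rows, traj = traj))
  q <- ion_charges(traj)[rows]
  dims <- ceiling(traj$box / spacing)
  accv <- numeric(prod(dims))
  nf <- length(traj$frames)
  for (f in traj$frames) {
    p <- f[rows, , drop = FALSE]
    if (!nrow(p)) next
    ijk <- pmin(floor(p / spacing) + 1, matrix(dims, nrow(p), 3, byrow = TRUE))
    lin <- (ijk[, 3] - 1) * dims[1] * dims[2] + (ijk[, 2] - 1) * dims[1] +
      ijk[, 1]
    s <- rowsum(q, lin)
    at <- as.integer(rownames(s))
    accv[at] <- accv[at] + s[, 1]
  }
  density <- array(accv, dim = dims) / nf / spacing^3
  structure(list(origin = c(0, 0, 0), spacing = spacing, dim = dims,
                 density = density, n_frames = nf,
                 species = paste(species, collapse = ","),
                 threshold = threshold),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %dx%dx%d voxels, spacing %g A, species %s\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing, x$species))
  cat(sprintf("  total charge %.4f e; %d voxel(s) above %.3g e/A^3\n",
              sum(x$density) * x$spacing^3,
              sum(x$density > x$threshold), x$threshold))
  invisible(x)
}

#' Voxels above a charge-density threshold
#' @param grid A `density_grid`.
#' @param threshold e/Angstrom^3 (default: the grid's stored threshold,
#'   0.02 unless overridden).
#' @return List with `n` (voxel count) and `mask` (logical 3D array).
#' @export
threshold_density <- function(grid, threshold = NULL) {
  if (is.null(threshold)) threshold <- grid$threshold
  mask <- grid$density > threshold
  list(n = sum(mask), mask = mask)
}

#' Detect ion bridges between two helices
#'
#' An ion is bridging in a frame iff it lies within `cutoff` of at least one
#' phosphate site of helix A and at least one phosphate site of helix B —
#' the geometric signature of an ion shared by the two backbones.
#'
#' @param traj An `ion_trajectory`.
#' @param helixA,helixB `helix_model`s (must be distinct objects).
#' @param cutoff Ion-phosphate contact cutoff, Angstrom (default 6).
#' @param species Species name (default: first).
#' @return Object of class `bridge_report`: list with `per_frame` (integer
#'   counts), `mean` occupancy, `indices` (list of bridging ion row indices
#'   per frame), `cutoff`, `species`.
#' @export
detect_bridges <- function(traj, helixA, helixB, cutoff = 6, species = NULL) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (identical(helixA, helixB))
    stop("helixA and helixB are the same helix; bridges need two distinct helices")
  if (is.null(species)) species <- traj$species$name[1]
  rows <- species_rows(traj, species)
  PA <- phosphate_sites(helixA)
  PB <- phosphate_sites(helixB)
  mindist <- function(p, P) {
    ## n x m squared distances without forming huge intermediates (m is small)
    d2 <- outer(rowSums(p^2), rowSums(P^2), "+") - 2 * p %*% t(P)
    sqrt(pmax(apply(d2, 1, min), 0))
  }
  per_frame <- integer(length(traj$frames))
  indices <- vector("list", length(traj$frames))
  for (i in seq_along(traj$frames)) {
    p <- traj$frames[[i]][rows, , drop = FALSE]
    if (!nrow(p)) { indices[[i]] <- integer(0); next }
    bridging <- mindist(p, PA) <= cutoff & mindist(p, PB) <= cutoff
    per_frame[i] <- sum(bridging)
    indices[[i]] <- rows[which(bridging)]
  }
  structure(list(per_frame = per_frame, mean = mean(per_frame),
                 indices = indices, cutoff = cutoff, species = species),
            class = "bridge_report")
}

#' @export
print.bridge_report <- function(x, ...) {
  cat(sprintf("<bridge_report> %s: mean %.3f bridging ion(s)/frame over %d frame(s) (cutoff %g A)\n",
              x$species, x$mean, length(x$per_frame), x$cutoff))
  invisible(x)
}

#' Water-dipole ordering around bridging ions
#'
#' For every water whose oxygen lies within `shell` of a bridging ion,
#' accumulates `cos(theta)` between the water dipole (O to the H-midpoint)
#' and the O-to-nearest-bridging-ion vector.  A dipole anti-parallel to that
#' vector (`cos(theta) = -1`) means the oxygen points at the ion and the
#' hydrogens point away — the orientation a trivalent cation imposes on its
#' hydration shell.
#'
#' @param traj An `ion_trajectory` carrying water frames.
#' @param bridges A `bridge_report` for the same trajectory.
#' @param shell Shell cutoff around bridging ions, Angstrom (default 4.5).
#' @param n_bins Histogram bins over `[-1, 1]` (default 20).
#' @return Object of class `water_order_profile`: data.frame `cos_lo`,
#'   `cos_hi`, `density` (integrates to 1), attribute `n_waters`.
#' @export
water_ordering <- function(traj, bridges, shell = 4.5, n_bins = 20) {
  if (is.null(traj$water)) stop("trajectory carries no water coordinates")
  edges <- seq(-1, 1, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  nw_used <- 0
  any_bridge <- any(vapply(bridges$indices, length, 0L) > 0)
  if (!any_bridge) {
    warning("no bridging ions in any frame; empty water-order profile")
  } else {
    for (i in seq_along(traj$frames)) {
      idx <- bridges$indices[[i]]
      if (!length(idx)) next
      ions <- traj$frames[[i]][idx, , drop = FALSE]
      w <- traj$water[[i]]
      O <- w$O
      mid <- (w$H1 + w$H2) / 2
      dip <- mid - O
      ## nearest bridging ion per water
      d2 <- outer(rowSums(O^2), rowSums(ions^2), "+") - 2 * O %*% t(ions)
      nearest <- max.col(-d2)
      dmin <- sqrt(pmax(d2[cbind(seq_len(nrow(O)), nearest)], 0))
      sel <- which(dmin <= shell)
      if (!length(sel)) next
      v <- ions[nearest[sel], , drop = FALSE] - O[sel, , drop = FALSE]
      ct <- rowSums(dip[sel, , drop = FALSE] * v) /
        (sqrt(rowSums(dip[sel, , drop = FALSE]^2)) * sqrt(rowSums(v^2)))
      ct <- pmax(pmin(ct, 1), -1)
      bi <- pmin(findInterval(ct, edges, rightmost.closed = TRUE), n_bins)
      counts <- counts + tabulate(bi, nbins = n_bins)
      nw_used <- nw_used + length(sel)
    }
  }
  bw <- diff(edges)[1]
  dens <- if (sum(counts) > 0) counts / sum(counts) / bw else counts
  out <- data.frame(cos_lo = edges[-(n_bins + 1)], cos_hi = edges[-1],
                    density = dens)
  attr(out, "n_waters") <- nw_used
  attr(out, "shell") <- shell
  class(out) <- c("water_order_profile", "data.frame")
  out
}
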