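## Osmotic pressure of a hexagonal aggregate of parallel helices from a
## pairwise PMF under the additivity assumption: each helix has six nearest
## neighbours at the lattice spacing d, each pair counted once, so the
## lattice energy per helix is E(d) = 3 * dG_pair(d).  With the per-helix
## cell volume V(d) = (sqrt(3)/2) d^2 L the osmotic pressure is
## Pi = -dE/dV = -(dE/dd) / (sqrt(3) d L).

#' Lattice energy per helix of a hexagonal aggregate
#'
#' Nearest-neighbour additive sum: `E(d) = 3 * dG_pair(d)` (6 neighbours,
#' each pair shared by two helices).  Optionally adds the second shell of 6
#' neighbours at `sqrt(3) d` (off by default; the pair PMF is short-ranged).
#' Interpolation is linear on the PMF grid; requested spacings outside the
#' grid are an error (no extrapolation).
#'
#' @param pmf A `pmf_profile` (dG in kT).
#' @param spacings Lattice spacings d, Angstrom (default: the PMF grid).
#' @param second_shell Include the `sqrt(3) d` shell (default FALSE).
#' @return data.frame with columns `d` (Angstrom), `E_kBT`, `E_kJmol`.
#' @export
lattice_energy <- function(pmf, spacings = NULL, second_shell = FALSE) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (is.null(spacings)) spacings <- pmf$x
  if (min(spacings) < min(pmf$x) - 1e-9 || max(spacings) > max(pmf$x) + 1e-9)
    stop("requested spacing outside the PMF grid [",
         min(pmf$x), ", ", max(pmf$x), "] A; no extrapolation")
  g <- function(d) stats::approx(pmf$x, pmf$dG_kBT, xout = d)$y
  E <- 3 * g(spacings)
  if (second_shell) {
    d2 <- sqrt(3) * spacings
    inside <- d2 <= max(pmf$x) + 1e-9
    E[inside] <- E[inside] + 3 * g(d2[inside])
    ## beyond the grid the pair PMF is taken as its reference zero
  }
  data.frame(d = spacings, E_kBT = E, E_kJmol = E * .kT)
}

#' Osmotic pressure versus lattice spacing
#'
#' Central-difference derivative of the per-helix lattice energy, converted
#' through the hexagonal cell volume:
#' `Pi(d) = -(dE/dd) / (sqrt(3) d L)` in kJ/(mol Angstrom^3), also reported
#' in atm (1 kJ/(mol Angstrom^3) = 16388 atm).  One-sided stencils are used
#' at the grid ends and flagged.
#'
#' @param energy data.frame from [lattice_energy()] (columns `d`,
#'   `E_kJmol`), >= 3 rows on a strictly ascending grid.
#' @param L Helix contour length, Angstrom (e.g. `(N-1) * rise`).
#' @return Object of class `osmotic_curve`: data.frame with `d`,
#'   `E_kJmol`, `Pi_kJmolA3`, `Pi_atm`, `edge` (logical).
#' @export
osmotic_pressure <- function(energy, L) {
  stopifnot(is.data.frame(energy), all(c("d", "E_kJmol") %in% names(energy)))
  if (L <= 0) stop("helix length L must be > 0")
  d <- energy$d; E <- energy$E_kJmol
  m <- length(d)
  if (m < 3) stop("need at least 3 spacings")
  if (any(diff(d) <= 0)) stop("spacing grid must be strictly ascending")
  dEdd <- numeric(m)
  dEdd[1] <- (E[2] - E[1]) / (d[2] - d[1])
  dEdd[m] <- (E[m] - E[m - 1]) / (d[m] - d[m - 1])
  if (m > 2) {
    i <- 2:(m - 1)
    dEdd[i] <- (E[i + 1] - E[i - 1]) / (d[i + 1] - d[i - 1])
  }
  Pi <- -dEdd / (sqrt(3) * d * L)
  out <- data.frame(d = d, E_kJmol = E, Pi_kJmolA3 = Pi,
                    Pi_atm = Pi * hpmf_constants$atm_per_kJmolA3,
                    edge = c(TRUE, rep(FALSE, m - 2), TRUE))
  attr(out, "L") <- L
  class(out) <- c("osmotic_curve", "data.frame")
  out
}

#' Zero crossing of an osmotic curve
#'
#' Linearly interpolated spacing at which the pressure changes sign — the
#' equilibrium spacing of the aggregate, which coincides with the minimum of
#' the lattice energy within grid resolution.
#'
#' @param curve An `osmotic_curve`.
#' @return Spacing in Angstrom, or `NA` if the pressure never changes sign.
#' @export
osmotic_zero_crossing <- function(curve) {
  Pi <- curve$Pi_kJmolA3; d <- curve$d
  s <- which(Pi[-length(Pi)] * Pi[-1] < 0)
  if (!length(s)) {
    z <- which(Pi == 0)
    return(if (length(z)) d[z[1]] else NA_real_)
  }
  i <- s[1]
  d[i] + (d[i + 1] - d[i]) * Pi[i] / (Pi[i] - Pi[i + 1])
}
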