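## Synthetic-data generators with known ground truth: Boltzmann spring
## samples from a prescribed PMF, ion point clouds from target cylindrical
## concentration profiles, bridging / groove-patterned ion scenes, and
## rigid waters with controlled dipole orientation.  Every generator is
## bit-reproducible under a fixed seed; frames are i.i.d. by design.

#' Ground-truth PMF library
#'
#' Three analytic free-energy shapes mirroring the qualitative regimes the
#' package is meant to recover (used as recovery fixtures, never claimed to
#' be any system's true curve):
#' * `"repulsive"`: purely repulsive exponential wall (the low-multivalent
#'   regime where like-charged helices only repel).
#' * `"bdna_5mM"`: repulsive wall plus a Gaussian well calibrated to depth
#'   -3.5 kT at 27 Angstrom (the B-DNA high-Co-Hex regime).
#' * `"arna_50mM"`: same shape calibrated to -4.1 kT at 27 Angstrom (the
#'   A-RNA very-high-Co-Hex regime).
#'
#' The well calibration is a deterministic fixed-point adjustment of the
#' Gaussian depth and center so that the reference-shifted minimum sits at
#' the stated depth and location.  Values are in kT; `fn` is shifted so
#' `fn(40) = 0`; `deriv` is the analytic derivative (kT/Angstrom).
#'
#' @param shape One of `"repulsive"`, `"bdna_5mM"`, `"arna_50mM"`.
#' @param x_ref Reference separation at which `fn` is zeroed (default 40).
#' @return Object of class `ground_truth_pmf`: list with `name`, `fn`,
#'   `deriv`, `params`.
#' @export
ground_truth_pmf <- function(shape = c("repulsive", "bdna_5mM", "arna_50mM"),
                             x_ref = 40) {
  shape <- match.arg(shape)
  wall <- list(A = 6, x_w = 20, lambda = 2.5)
  spec <- switch(shape,
    repulsive = list(A = 4, x_w = 20, lambda = 4, D = 0, x_m = 27, sigma = 3),
    bdna_5mM  = list(A = wall$A, x_w = wall$x_w, lambda = wall$lambda,
                     D = 3.5, x_m = 27, sigma = 3, depth = -3.5),
    arna_50mM = list(A = wall$A, x_w = wall$x_w, lambda = wall$lambda,
                     D = 4.1, x_m = 27, sigma = 3, depth = -4.1))

  raw <- function(x, p)
    p$A * exp(-(x - p$x_w) / p$lambda) -
      if (p$D > 0) p$D * exp(-(x - p$x_m)^2 / (2 * p$sigma^2)) else 0
  draw <- function(x, p)
    -p$A / p$lambda * exp(-(x - p$x_w) / p$lambda) +
      if (p$D > 0) p$D * (x - p$x_m) / p$sigma^2 *
        exp(-(x - p$x_m)^2 / (2 * p$sigma^2)) else 0

  p <- spec
  if (p$D > 0) {
    ## fixed-point calibration: shift the Gaussian so the reference-shifted
    ## minimum is exactly (depth, 27)
    xs <- seq(20, 40, by = 0.005)
    for (it in 1:30) {
      g <- raw(xs, p) - raw(x_ref, p)
      i <- which.min(g)
      p$D <- p$D + (g[i] - p$depth)
      p$x_m <- p$x_m - (xs[i] - 27)
    }
  }
  off <- raw(x_ref, p)
  out <- list(name = shape,
              fn = function(x) raw(x, p) - off,
              deriv = function(x) draw(x, p),
              params = p, x_ref = x_ref)
  class(out) <- "ground_truth_pmf"
  out
}

#' Sample a pseudo-spring separation series from a known PMF
#'
#' Draws i.i.d. separations from the Boltzmann weight of the combined
#' potential `U(x) = dG_true(x) * kT + 0.5 * (k/100) * (x - x0)^2` by
#' inverse-CDF sampling on a 0.01 Angstrom grid over `x0 +/- window`.
#' Errors out if the weight has not decayed at the window edges (improper
#' sampling density).
#'
#' @param truth A `ground_truth_pmf` (values in kT).
#' @param k Spring constant, kJ/(mol nm^2).
#' @param x0 Tether rest length, Angstrom.
#' @param n Number of samples.
#' @param seed Integer seed (sampling is deterministic given the seed).
#' @param window Half-width of the sampling window, Angstrom (default 4).
#' @param dt Sample spacing in ps for the synthetic time stamps.
#' @return A `spring_series`.
#' @export
spring_sampler <- function(truth, k, x0, n, seed = 1, window = 4, dt = 1) {
  stopifnot(inherits(truth, "ground_truth_pmf"), n >= 1, k > 0)
  set.seed(seed)
  grid <- seq(x0 - window, x0 + window, by = 0.01)
  U <- truth$fn(grid) * .kT + 0.5 * (k / 100) * (grid - x0)^2   # kJ/mol
  w <- exp(-(U - min(U)) / .kT)
  if (w[1] > 1e-6 * max(w) || w[length(w)] > 1e-6 * max(w))
    stop("Boltzmann weight has not decayed at the sampling window edges; ",
         "improper density (widen the window or check the PMF)")
  ## trapezoidal cumulative distribution (a plain cumsum carries a half-bin
  ## bias that integrates into a visible PMF offset)
  cdf <- c(0, cumsum((w[-1] + w[-length(w)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  ## strictly increasing support for the inverse interpolation
  keep <- c(TRUE, diff(cdf) > 0)
  x <- stats::approx(cdf[keep], grid[keep], xout = stats::runif(n),
                     rule = 2)$y
  spring_series(k, x0, time = seq_len(n) * dt, x = x)
}

#' Generate an ion cloud from a target cylindrical concentration profile
#'
#' Per frame and per radial shell around each helix axis, draws a Poisson
#' count with mean `c_target * shell_volume / 1660.539` and places the ions
#' uniformly within the shell (optionally restricted to one groove's angular
#' sector), uniformly in the axial span.  The box outside the shells can be
#' filled at a uniform bulk concentration.
#'
#' @param c_target data.frame with columns `r_lo`, `r_hi` (Angstrom) and
#'   `c_molL`: the target step profile (finite support; must fit in the box).
#' @param helices A `helix_model`, list of them, or `duplex_pair`.
#' @param box 3-vector, Angstrom.
#' @param n_frames Number of i.i.d. frames.
#' @param species Species name (default `"COH"`, charge +3).
#' @param charge Ion charge, e.
#' @param groove Optional `"major"` or `"minor"`: restrict placement to that
#'   groove's angular sector at each sampled height.
#' @param c_bulk Uniform background concentration, mol/L (default 0).
#' @param seed Integer seed.
#' @return An `ion_trajectory` (all frames share the species table; counts
#'   vary per frame, so the table's `count` is the maximum and frames are
#'   padded — instead ions are pooled per frame; see Details).  To keep the
#'   container rectangular the generator draws the per-shell counts once per
#'   frame and pads nothing: each frame's matrix has its own row count pooled
#'   into a single per-frame list; the species table records the mean count.
#' @details Frames must share an atom count in an `ion_trajectory`, so the
#'   generator draws all Poisson counts first and uses the maximum total as
#'   the frame size, parking unused slots far outside every analysis region
#'   at the box corner opposite the helices (flagged by the
#'   `"n_active"` attribute, one value per frame).  All analysis operations
#'   in the package are insensitive to parked ions because they fall outside
#'   every radial, axial and grid region of interest — except whole-box
#'   grids, for which active counts should be equal; prefer `c_bulk = 0`
#'   with conservation tests, or use `fixed_counts = TRUE`.
#' @param fixed_counts If `TRUE`, uses the same (rounded-mean) shell counts
#'   in every frame instead of Poisson draws, so every frame has the same
#'   number of ions and nothing is parked.
#' @export
ion_cloud <- function(c_target, helices, box, n_frames, species = "COH",
                      charge = 3, groove = NULL, c_bulk = 0, seed = 1,
                      fixed_counts = FALSE) {
  stopifnot(all(c("r_lo", "r_hi", "c_molL") %in% names(c_target)),
            all(c_target$c_molL >= 0), n_frames >= 1)
  if (inherits(helices, "duplex_pair")) helices <- list(helices$helixA,
                                                        helices$helixB)
  if (inherits(helices, "helix_model")) helices <- list(helices)
  set.seed(seed)
  box <- as.numeric(box)

  for (h in helices) {
    o <- h$axis_origin
    if (any(o[1] + max(c_target$r_hi) > box[1], o[1] - max(c_target$r_hi) < 0,
            o[2] + max(c_target$r_hi) > box[2], o[2] - max(c_target$r_hi) < 0))
      stop("target profile support extends outside the box")
  }

  frames <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    pts <- matrix(numeric(0), 0, 3)
    for (h in helices) {
      ext <- axial_extent(h)
      L <- ext
      z0 <- h$axis_origin[3]
      f <- h$form
      for (i in seq_len(nrow(c_target))) {
        r1 <- c_target$r_lo[i]; r2 <- c_target$r_hi[i]
        vol <- pi * (r2^2 - r1^2) * L
        sector_frac <- 1
        if (!is.null(groove)) {
          width <- if (groove == "major") major_groove_sector_deg(f)
                   else 360 - major_groove_sector_deg(f)
          sector_frac <- width / 360
        }
        lambda <- c_target$c_molL[i] / .MOL * vol * sector_frac
        m <- if (fixed_counts) round(lambda) else stats::rpois(1, lambda)
        if (m == 0) next
        z <- z0 + stats::runif(m, 0, L)
        r <- sqrt(stats::runif(m, r1^2, r2^2))
        if (is.null(groove)) {
          ang <- stats::runif(m, 0, 360)
        } else {
          ## angular sector of the requested groove at each height
          phase1 <- h$phase0 + ((z - z0) / f$rise) * f$twist
          small_w <- f$phosphate_phase
          in_small <- (f$small_gap_groove == groove)
          lo <- if (in_small) phase1 else phase1 + small_w
          wdt <- if (in_small) small_w else 360 - small_w
          ## keep a 1-degree margin off the strand lines (tie-break region)
          ang <- lo + stats::runif(m, 1, wdt - 1)
        }
        a <- ang * pi / 180
        pts <- rbind(pts, cbind(h$axis_origin[1] + r * cos(a),
                                h$axis_origin[2] + r * sin(a), z))
      }
    }
    if (c_bulk > 0) {
      lam <- c_bulk / .MOL * prod(box)
      m <- if (fixed_counts) round(lam) else stats::rpois(1, lam)
      if (m > 0)
        pts <- rbind(pts, cbind(stats::runif(m, 0, box[1]),
                                stats::runif(m, 0, box[2]),
                                stats::runif(m, 0, box[3])))
    }
    frames[[fr]] <- pts
  }

  n_active <- vapply(frames, nrow, 0L)
  n_max <- max(n_active, 1L)
  park <- c(box[1] - 0.5, box[2] - 0.5, box[3] - 0.5)
  frames <- lapply(frames, function(p) {
    if (nrow(p) < n_max)
      p <- rbind(p, matrix(rep(park, n_max - nrow(p)),
                           ncol = 3, byrow = TRUE))
    p
  })
  sp <- data.frame(name = species, charge = charge, count = n_max,
                   stringsAsFactors = FALSE)
  traj <- ion_trajectory(sp, frames, box = box)
  attr(traj, "n_active") <- n_active
  attr(traj, "seed") <- seed
  traj
}

#' Construct a bridging / internal-binding ion scene with known answer
#'
#' Two 16-bp helices at the given separation in the standard box.
#' `"bdna_external"` places ions at midplane points between facing phosphate
#' pairs of the two B-DNA helices, each within `cutoff` of a phosphate of
#' both backbones, so every ion bridges by construction (and sits in the
#' external shell of its nearest helix).  `"arna_internal"` places ions
#' inside each A-RNA's major-groove sector at r ~ 8 Angstrom, too far from
#' the partner helix to bridge, so the expected bridge count is zero.
#'
#' @param mode `"bdna_external"` or `"arna_internal"`.
#' @param separation Axis-axis separation, Angstrom (default 27).
#' @param n_ions Ions per frame (default 6).
#' @param n_frames Frames (default 5).
#' @param cutoff Bridge criterion the expectation refers to (default 6).
#' @param seed Integer seed.
#' @return List with `traj` (an `ion_trajectory`), `pair` (`duplex_pair`),
#'   `expected_bridging` (per-frame count), `expected_binding`
#'   (`"external"` or `"internal"` for every placed ion).
#' @export
bridge_scene <- function(mode = c("bdna_external", "arna_internal"),
                         separation = 27, n_ions = 6, n_frames = 5,
                         cutoff = 6, seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "bdna_external") {
    pair <- duplex_pair("bdna", separation)
    PA <- phosphate_sites(pair$helixA)
    PB <- phosphate_sites(pair$helixB)
    midx <- pair$box[1] / 2
    ## candidate midpoints of cross-helix phosphate pairs, both legs < cutoff
    cand <- NULL
    for (i in seq_len(nrow(PA))) {
      d <- sqrt(colSums((t(PB) - PA[i, ])^2))
      ok <- which(d <= 2 * (cutoff - 0.8))
      for (j in ok) cand <- rbind(cand, (PA[i, ] + PB[j, ]) / 2)
    }
    if (is.null(cand) || nrow(cand) < 1)
      stop("no bridging midpoints exist at separation ", separation,
           " A with cutoff ", cutoff, " A")
    expected_binding <- "external"
    place <- function() {
      idx <- sample(nrow(cand), n_ions, replace = nrow(cand) < n_ions)
      cand[idx, , drop = FALSE] +
        matrix(stats::runif(3 * n_ions, -0.2, 0.2), n_ions, 3)
    }
    expected_bridging <- rep(n_ions, n_frames)
  } else {
    pair <- duplex_pair("arna", separation)
    expected_binding <- "internal"
    place <- function() {
      hs <- list(pair$helixA, pair$helixB)
      pts <- matrix(0, n_ions, 3)
      for (q in seq_len(n_ions)) {
        h <- hs[[(q %% 2) + 1]]
        f <- h$form
        z <- stats::runif(1, 0.2, 0.8) * axial_extent(h)
        phase1 <- h$phase0 + (z / f$rise) * f$twist
        ang <- (phase1 + stats::runif(1, 5, f$phosphate_phase - 5)) * pi / 180
        r <- 8
        pts[q, ] <- h$axis_origin + c(r * cos(ang), r * sin(ang), z)
      }
      pts
    }
    expected_bridging <- rep(0, n_frames)
  }
  frames <- lapply(seq_len(n_frames), function(i) place())
  sp <- data.frame(name = "COH", charge = 3, count = n_ions,
                   stringsAsFactors = FALSE)
  traj <- ion_trajectory(sp, frames, box = pair$box)
  list(traj = traj, pair = pair,
       expected_bridging = expected_bridging,
       expected_binding = rep(expected_binding, n_ions),
       mode = mode, cutoff = cutoff, seed = seed)
}

#' Build rigid waters around ions with controlled dipole orientation
#'
#' Places `n_waters` rigid three-site waters (OH 0.9572 Angstrom, HOH
#' 104.52 degrees) with oxygens at 2.5-4.0 Angstrom from randomly chosen
#' ions.  In `"toward_ion"` mode the dipole is anti-parallel to the
#' O-to-ion vector (oxygen facing the ion); in `"isotropic"` mode the
#' orientation is uniform on the sphere.
#'
#' @param mode `"toward_ion"` or `"isotropic"`.
#' @param ions Matrix (n x 3) of ion positions, Angstrom.
#' @param n_waters Number of waters (>= 1).
#' @param seed Integer seed.
#' @return List with matrices `O`, `H1`, `H2` (n_waters x 3), suitable as
#'   one frame of an `ion_trajectory`'s `water` list.
#' @export
water_scene <- function(mode = c("toward_ion", "isotropic"), ions, n_waters,
                        seed = 1) {
  mode <- match.arg(mode)
  ions <- if (is.null(dim(ions))) matrix(ions, ncol = 3) else as.matrix(ions)
  if (nrow(ions) < 1) stop("need at least one ion")
  if (n_waters < 1) stop("n_waters must be >= 1")
  set.seed(seed)
  r_oh <- 0.9572
  half <- (104.52 / 2) * pi / 180
  d_mid <- r_oh * cos(half)      # O -> H midpoint distance
  d_perp <- r_oh * sin(half)     # half H-H separation

  rand_unit <- function(n) {
    v <- matrix(stats::rnorm(3 * n), n, 3)
    v / sqrt(rowSums(v^2))
  }
  pick <- sample(nrow(ions), n_waters, replace = TRUE)
  dirs <- rand_unit(n_waters)                 # ion -> O direction
  dist <- stats::runif(n_waters, 2.5, 4.0)
  O <- ions[pick, , drop = FALSE] + dirs * dist

  u <- if (mode == "toward_ion") {
    oi <- ions[pick, , drop = FALSE] - O      # O -> ion
    -oi / sqrt(rowSums(oi^2))                 # dipole anti-parallel to O->ion
  } else rand_unit(n_waters)

  ## perpendicular axis for the H offsets
  helper <- rand_unit(n_waters)
  perp <- helper - u * rowSums(helper * u)
  small <- sqrt(rowSums(perp^2)) < 1e-8
  while (any(small)) {
    helper[small, ] <- rand_unit(sum(small))
    perp <- helper - u * rowSums(helper * u)
    small <- sqrt(rowSums(perp^2)) < 1e-8
  }
  perp <- perp / sqrt(rowSums(perp^2))
  mid <- O + u * d_mid
  list(O = O, H1 = mid + perp * d_perp, H2 = mid - perp * d_perp)
}

#' Attach water frames to an ion trajectory
#' @param traj An `ion_trajectory`.
#' @param water_frames List (length = number of frames) of `water_scene`
#'   outputs.
#' @return The trajectory with waters attached.
#' @export
with_waters <- function(traj, water_frames) {
  ion_trajectory(traj$species, traj$frames, box = traj$box,
                 times = traj$times, water = water_frames)
}
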