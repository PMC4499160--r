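## Simplified Metropolis Monte Carlo of a primitive-model electrolyte
## (charged hard spheres in a dielectric continuum) around fixed helix
## charge arrays.  Role: calibrating ion numbers to target bulk
## concentrations and reproducing qualitative binding-mode trends — not
## precise electrostatics (minimum-image truncation, no Ewald sum).

.DEFAULT_ION_PARAMS <- data.frame(
  name   = c("NA", "COH", "CL"),
  charge = c(1, 3, -1),
  radius = c(2.0, 4.0, 2.0),
  stringsAsFactors = FALSE
)

#' Assemble a Monte-Carlo system
#'
#' Fixed charges come from the phosphates of zero, one or two helix models;
#' mobile species are charged hard spheres.  The system must be electroneutral.
#'
#' @param species data.frame with columns `name`, `charge` (e), `radius`
#'   (Angstrom), `count`.
#' @param box 3-vector box lengths, Angstrom (periodic).
#' @param helices Optional `helix_model`, list of them, or `duplex_pair`.
#' @param eps Relative dielectric constant (default 78).
#' @param temperature Kelvin (default 298).
#' @param exclusions Optional matrix of cylindrical exclusion regions, one
#'   row per region: `(x0, y0, r_min, r_max, z_min, z_max)`; mobile ions
#'   inside get infinite energy (a stand-in for, e.g., a fixed water layer
#'   filling a deep groove).
#' @param fixed_radius Hard-sphere radius assigned to fixed phosphate sites,
#'   Angstrom (default 2).
#' @param enforce_neutrality Require total charge zero (default TRUE; can be
#'   relaxed for pair-energy checks and toy configurations).
#' @return Object of class `mc_system`.
#' @export
mc_system <- function(species, box, helices = NULL, eps = 78,
                      temperature = 298, exclusions = NULL,
                      fixed_radius = 2, enforce_neutrality = TRUE) {
  stopifnot(all(c("name", "charge", "radius", "count") %in% names(species)),
            all(species$count >= 0), all(species$radius > 0),
            length(box) == 3, all(box > 0), eps > 0, temperature > 0)
  if (inherits(helices, "duplex_pair")) helices <- list(helices$helixA,
                                                        helices$helixB)
  if (inherits(helices, "helix_model")) helices <- list(helices)
  fixed_pos <- matrix(numeric(0), 0, 3)
  fixed_q <- numeric(0)
  if (length(helices)) {
    fixed_pos <- do.call(rbind, lapply(helices, phosphate_sites))
    fixed_q <- unlist(lapply(helices, function(h)
      h$sites$charge[h$sites$role == "phosphate"]))
  }
  net <- sum(species$charge * species$count) + sum(fixed_q)
  if (enforce_neutrality && abs(net) > 1e-9)
    stop("system is not electroneutral (net charge ", net, " e)")
  if (!is.null(exclusions)) {
    exclusions <- matrix(as.numeric(exclusions), ncol = 6)
  }
  structure(list(species = species, box = as.numeric(box),
                 helices = helices, fixed_pos = fixed_pos, fixed_q = fixed_q,
                 fixed_radius = fixed_radius, eps = eps,
                 temperature = temperature,
                 kT = 8.314462618e-3 * temperature,
                 exclusions = exclusions),
            class = "mc_system")
}

.mobile_params <- function(system) {
  list(q = rep(system$species$charge, system$species$count),
       rad = rep(system$species$radius, system$species$count),
       n = sum(system$species$count))
}

.in_exclusion <- function(pos, exclusions) {
  if (is.null(exclusions) || !nrow(exclusions)) return(rep(FALSE, nrow(pos)))
  out <- rep(FALSE, nrow(pos))
  for (i in seq_len(nrow(exclusions))) {
    e <- exclusions[i, ]
    r <- sqrt((pos[, 1] - e[1])^2 + (pos[, 2] - e[2])^2)
    out <- out | (r >= e[3] & r <= e[4] & pos[, 3] >= e[5] & pos[, 3] <= e[6])
  }
  out
}

#' Configuration energy of the primitive-model system
#'
#' Pairwise Coulomb `1389.35 * q_i q_j / (eps * r_ij)` kJ/mol over
#' mobile-mobile and mobile-fixed pairs under the minimum-image convention,
#' with hard-sphere exclusion by the sum of radii and infinite energy inside
#' any exclusion region.  The fixed-fixed contribution is a constant and is
#' omitted.
#'
#' @param positions Matrix (n x 3) of mobile ion positions, Angstrom.
#' @param system An `mc_system`.
#' @return Energy in kJ/mol (`Inf` for configurations violating hard cores
#'   or exclusion regions).
#' @export
mc_energy <- function(positions, system) {
  p <- if (is.null(dim(positions))) matrix(positions, ncol = 3)
       else as.matrix(positions)
  mp <- .mobile_params(system)
  if (nrow(p) != mp$n)
    stop("positions rows (", nrow(p), ") != mobile ion count (", mp$n, ")")
  if (any(.in_exclusion(p, system$exclusions))) return(Inf)
  box <- system$box
  E <- 0
  n <- nrow(p)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      d <- t(p[(i + 1):n, , drop = FALSE]) - p[i, ]
      d <- d - box * round(d / box)
      r <- sqrt(colSums(d^2))
      if (any(r < mp$rad[i] + mp$rad[(i + 1):n])) return(Inf)
      E <- E + sum(.KC * mp$q[i] * mp$q[(i + 1):n] / (system$eps * r))
    }
  }
  if (nrow(system$fixed_pos)) {
    for (i in seq_len(n)) {
      d <- t(system$fixed_pos) - p[i, ]
      d <- d - box * round(d / box)
      r <- sqrt(colSums(d^2))
      if (any(r < mp$rad[i] + system$fixed_radius)) return(Inf)
      E <- E + sum(.KC * mp$q[i] * system$fixed_q / (system$eps * r))
    }
  }
  E
}

.random_start <- function(system, max_tries = 20000) {
  mp <- .mobile_params(system)
  box <- system$box
  pos <- matrix(NA_real_, mp$n, 3)
  placed <- 0
  tries <- 0
  while (placed < mp$n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not place ", mp$n, " non-overlapping ions in the box")
    cand <- stats::runif(3) * box
    cm <- matrix(cand, 1, 3)
    if (any(.in_exclusion(cm, system$exclusions))) next
    ok <- TRUE
    if (placed > 0) {
      d <- t(pos[seq_len(placed), , drop = FALSE]) - cand
      d <- d - box * round(d / box)
      if (any(sqrt(colSums(d^2)) <
              mp$rad[placed + 1] + mp$rad[seq_len(placed)])) ok <- FALSE
    }
    if (ok && nrow(system$fixed_pos)) {
      d <- t(system$fixed_pos) - cand
      d <- d - box * round(d / box)
      if (any(sqrt(colSums(d^2)) < mp$rad[placed + 1] + system$fixed_radius))
        ok <- FALSE
    }
    if (ok) {
      placed <- placed + 1
      pos[placed, ] <- cand
    }
  }
  pos
}

#' Run Metropolis Monte Carlo
#'
#' Single-ion displacement moves with periodic wrapping; the move size is
#' auto-tuned to 30-50 percent acceptance during a burn-in of 10 percent of
#' the sweeps (excluded from all averages).  Snapshots are taken every
#' `sample_every` sweeps after burn-in.  Fully reproducible given `seed`.
#'
#' @param system An `mc_system` with at least one mobile ion.
#' @param n_sweeps Number of sweeps (one attempted move per ion each).
#' @param seed Integer seed.
#' @param move Initial maximum displacement per coordinate, Angstrom.
#' @param sample_every Sweeps between snapshots (default 1).
#' @param tune Auto-tune the move size during burn-in (default TRUE).
#' @param r_ext Outer radius excluded around each helix axis when measuring
#'   bulk concentrations (default 15).
#' @return Object of class `mc_result`: list with `acceptance`,
#'   `mean_energy`, `energy_sem`, `bulk_molL` (named per species),
#'   `bulk_sem_molL`, `bulk_volume_A3`, `samples` (an `ion_trajectory` of
#'   snapshots), `move_final`, `n_sweeps`, `seed`.
#' @export
run_mc <- function(system, n_sweeps, seed = 1, move = 1.0, sample_every = 1,
                   tune = TRUE, r_ext = 15) {
  stopifnot(inherits(system, "mc_system"), n_sweeps >= 1)
  mp <- .mobile_params(system)
  if (mp$n == 0) stop("system has zero mobile ions")
  set.seed(seed)
  pos <- .random_start(system)
  burn <- min(floor(n_sweeps * 0.1), n_sweeps - 1)
  excl <- if (is.null(system$exclusions)) matrix(numeric(0), 0, 6)
          else system$exclusions
  res <- mc_run_cpp(pos, mp$q, mp$rad,
                    system$fixed_pos, system$fixed_q, system$fixed_radius,
                    system$box, system$eps, system$kT,
                    as.integer(n_sweeps), as.integer(burn),
                    move, tune, excl, as.integer(sample_every))
  ns <- dim(res$samples)[3]
  frames <- lapply(seq_len(ns), function(i) res$samples[, , i])
  sp <- system$species[system$species$count > 0, ]
  traj <- ion_trajectory(
    data.frame(name = sp$name, charge = sp$charge, count = sp$count,
               stringsAsFactors = FALSE),
    frames, box = system$box)

  bulk <- .bulk_concentration(traj, system, r_ext = r_ext)
  e_sem <- if (length(res$energies) >= 16) block_sem(res$energies)
           else NA_real_
  structure(list(acceptance = res$acceptance,
                 mean_energy = mean(res$energies), energy_sem = e_sem,
                 bulk_molL = bulk$c, bulk_sem_molL = bulk$sem,
                 bulk_volume_A3 = bulk$volume,
                 samples = traj, move_final = res$move_final,
                 n_sweeps = n_sweeps, seed = seed),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %d sweeps, acceptance %.2f, <E> = %.3f kJ/mol\n",
              x$n_sweeps, x$acceptance, x$mean_energy))
  cat("  bulk (mol/L):",
      paste(sprintf("%s=%.4g", names(x$bulk_molL), x$bulk_molL),
            collapse = "  "), "\n")
  invisible(x)
}

## bulk region: farther than r_ext from every helix axis (in xy) and inside
## the central 80% of the axial span; whole box when no helices are present.
.bulk_concentration <- function(traj, system, r_ext = 15) {
  box <- traj$box
  helices <- system$helices
  if (length(helices)) {
    ext <- axial_extent(helices[[1]])
    z0 <- helices[[1]]$axis_origin[3]
    zlo <- z0 + 0.1 * ext; zhi <- z0 + 0.9 * ext
    centers <- t(vapply(helices, function(h) h$axis_origin[1:2], numeric(2)))
    area <- box[1] * box[2] - .circle_union_area(centers, r_ext)
    volume <- area * (zhi - zlo)
  } else {
    zlo <- 0; zhi <- box[3]
    centers <- NULL
    volume <- prod(box)
  }
  names <- traj$species$name
  cvals <- numeric(length(names)); sems <- numeric(length(names))
  for (si in seq_along(names)) {
    rows <- species_rows(traj, names[si])
    per_frame <- vapply(traj$frames, function(f) {
      p <- f[rows, , drop = FALSE]
      inz <- p[, 3] >= zlo & p[, 3] <= zhi
      if (!is.null(centers)) {
        far <- rep(TRUE, nrow(p))
        for (ci in seq_len(nrow(centers)))
          far <- far & (sqrt((p[, 1] - centers[ci, 1])^2 +
                             (p[, 2] - centers[ci, 2])^2) > r_ext)
        sum(inz & far)
      } else sum(inz)
    }, 0)
    cvals[si] <- mean(per_frame) / volume * .MOL
    sems[si] <- if (length(per_frame) >= 16)
      block_sem(per_frame) / volume * .MOL else NA_real_
  }
  list(c = stats::setNames(cvals, names),
       sem = stats::setNames(sems, names), volume = volume)
}

## union area of up to two equal circles (analytic lens overlap)
.circle_union_area <- function(centers, r) {
  n <- nrow(centers)
  if (n == 0) return(0)
  if (n == 1) return(pi * r^2)
  if (n > 2) stop("bulk-region geometry supports at most two helices")
  d <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  if (d >= 2 * r) return(2 * pi * r^2)
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  2 * pi * r^2 - lens
}

#' Calibrate mobile ion counts to target bulk concentrations
#'
#' Iteratively adjusts species counts by the ratio of target to measured
#' bulk concentration (from [run_mc()]), re-imposing electroneutrality via
#' the Cl- count each round, until every targeted species is within
#' `tolerance` (relative) of its target.
#'
#' @param targets Named vector of target bulk concentrations, mol/L, e.g.
#'   `c(NA = 0.1, COH = 0.005)`.  Species with target 0 are dropped.
#' @param box 3-vector, Angstrom.
#' @param helices Optional helix model(s) providing fixed charges.
#' @param ion_params data.frame (`name`, `charge`, `radius`) for all species
#'   incl. the balancing anion `CL`; defaults to the package table.
#' @param tolerance Relative tolerance on measured bulks (default 0.1).
#' @param max_rounds Calibration rounds (default 6).
#' @param n_sweeps MC sweeps per round (default 2000).
#' @param seed Integer seed.
#' @return List with `counts` (named, incl. `CL`), `measured_molL`,
#'   `rounds`, `converged`, `system` (the final `mc_system`), `result`
#'   (final `mc_result`).
#' @export
calibrate_counts <- function(targets, box, helices = NULL,
                             ion_params = NULL, tolerance = 0.1,
                             max_rounds = 6, n_sweeps = 2000, seed = 1) {
  if (is.null(ion_params)) ion_params <- .DEFAULT_ION_PARAMS
  targets <- targets[targets > 0]
  if (!length(targets)) stop("at least one species needs a positive target")
  if (!all(names(targets) %in% ion_params$name))
    stop("unknown species in targets: ",
         paste(setdiff(names(targets), ion_params$name), collapse = ", "))
  if (inherits(helices, "duplex_pair")) helices <- list(helices$helixA,
                                                        helices$helixB)
  if (inherits(helices, "helix_model")) helices <- list(helices)
  q_fixed <- if (length(helices))
    sum(unlist(lapply(helices, function(h) sum(h$sites$charge)))) else 0

  V <- prod(box)
  counts <- pmax(round(targets / .MOL * V), 1)
  charge_of <- stats::setNames(ion_params$charge, ion_params$name)

  build <- function(counts) {
    n_cl <- sum(charge_of[names(counts)] * counts) + q_fixed
    if (n_cl < 0) {
      ## the fixed charge is not yet covered: top up the first targeted
      ## cation with neutralizing counterions (they condense near the helix
      ## and barely perturb the bulk the loop is calibrating)
      cat_i <- which(charge_of[names(counts)] > 0)[1]
      if (is.na(cat_i))
        stop("electroneutrality unsolvable: no cation species to cover ",
             "fixed charge ", q_fixed)
      counts[cat_i] <- counts[cat_i] +
        ceiling(-n_cl / charge_of[names(counts)[cat_i]])
      n_cl <- sum(charge_of[names(counts)] * counts) + q_fixed
    }
    all_counts <- c(counts, CL = unname(n_cl))
    sp <- ion_params[match(names(all_counts), ion_params$name), ]
    sp$count <- as.numeric(all_counts)
    list(system = mc_system(sp, box, helices = helices),
         counts = all_counts)
  }

  measured <- NULL; res <- NULL
  for (round in seq_len(max_rounds)) {
    built <- build(counts)
    counts <- built$counts[names(counts)]
    res <- run_mc(built$system, n_sweeps, seed = seed + round)
    measured <- res$bulk_molL[names(targets)]
    relerr <- abs(measured - targets) / targets
    if (all(relerr <= tolerance))
      return(list(counts = built$counts,
                  measured_molL = measured, rounds = round,
                  converged = TRUE, system = built$system, result = res))
    counts <- pmax(round(counts * targets / pmax(measured, 1e-12)), 1)
  }
  stop("calibration did not converge in ", max_rounds,
       " rounds; last measured bulks: ",
       paste(sprintf("%s=%.4g mol/L", names(measured), measured),
             collapse = ", "))
}
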