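box_std <- c(130, 80, 100)
helix_centered <- function(form = "bdna") {
  f <- helix_form(form)
  build_helix(seq16(if (form == "arna") "rna" else "dna"), form,
              axis_origin = c(box_std[1] / 2, box_std[2] / 2,
                              (box_std[3] - 15 * f$rise) / 2))
}

test_that("radial profiles place fixed ions in the right bin and conserve counts", {
  h <- helix_centered()
  # one ion fixed at perpendicular distance 13.0 A (the canonical
  # external-binding location) for all frames
  pos <- h$axis_origin + c(13, 0, 25)
  traj <- single_ion_traj(pos, box_std)
  prof <- radial_profile(traj, h)
  expect_equal(prof$count[prof$r_lo == 13], 1)
  expect_equal(sum(prof$count), 1)
  expect_equal(attr(prof, "overflow"), 0)
  # absent species: empty profile with warning
  expect_warning(p0 <- radial_profile(traj, h, species = "NA"), "absent")
  expect_true(all(p0$c_molL == 0))
  expect_error(radial_profile(traj, h, bin_width = 0), "> 0")
})

test_that("a homogeneous ion gas recovers a flat profile at the known density", {
  set.seed(91)
  h <- helix_centered()
  rho <- 600 / prod(box_std)                  # ions per A^3
  n_frames <- 60
  frames <- lapply(seq_len(n_frames), function(i) {
    n <- rpois(1, 600)
    cbind(runif(n, 0, box_std[1]), runif(n, 0, box_std[2]),
          runif(n, 0, box_std[3]))
  })
  nmax <- max(vapply(frames, nrow, 0L))
  # pad to rectangular container by drawing extra uniform ions (still ideal gas)
  frames <- lapply(frames, function(f) {
    extra <- nmax - nrow(f)
    if (extra > 0)
      f <- rbind(f, cbind(runif(extra, 0, box_std[1]),
                          runif(extra, 0, box_std[2]),
                          runif(extra, 0, box_std[3])))
    f
  })
  rho <- nmax / prod(box_std)
  sp <- data.frame(name = "COH", charge = 3, count = nmax,
                   stringsAsFactors = FALSE)
  traj <- ion_trajectory(sp, frames, box = box_std)
  prof <- radial_profile(traj, h, bin_width = 2, r_max = 20)
  c_expect <- rho * hpmf_constants$ions_per_A3_to_molar
  vol <- pi * (prof$r_hi^2 - prof$r_lo^2) * attr(prof, "L_axial")
  lambda <- rho * vol
  sig <- sqrt(lambda / n_frames) / vol * hpmf_constants$ions_per_A3_to_molar
  expect_true(all(abs(prof$c_molL - c_expect) <= 3 * sig))
})

test_that("profiles are invariant under rigid rotation of the whole system", {
  h <- helix_centered()
  set.seed(17)
  n <- 50
  pts <- cbind(runif(n, 40, 90), runif(n, 20, 60), runif(n, 20, 80))
  sp <- data.frame(name = "COH", charge = 3, count = n,
                   stringsAsFactors = FALSE)
  traj <- ion_trajectory(sp, list(pts), box = box_std)
  p0 <- radial_profile(traj, h)
  # rotate everything by 60 degrees about the helix axis
  th <- pi / 3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ctr <- c(h$axis_origin[1:2], 0)
  pts_rot <- t(t((pts - matrix(ctr, n, 3, byrow = TRUE)) %*% t(R)) + ctr)
  traj_rot <- ion_trajectory(sp, list(pts_rot), box = box_std)
  p1 <- radial_profile(traj_rot, rotate_helix(h, 60))
  expect_equal(p1$count, p0$count)
})

test_that("binding taxonomy uses the 11/15 A boundaries against the nearest axis", {
  h <- helix_centered()
  at_r <- function(r) single_ion_traj(h$axis_origin + c(r, 0, 25), box_std)
  # the canonical internal (deep major groove, ~8 A) and external (~13 A) ions
  p8 <- classify_binding(at_r(8), h)
  expect_equal(c(p8$internal, p8$external, p8$bulk), c(1, 0, 0))
  p13 <- classify_binding(at_r(13), h)
  expect_equal(c(p13$internal, p13$external, p13$bulk), c(0, 1, 0))
  p20 <- classify_binding(at_r(20), h)
  expect_equal(c(p20$internal, p20$external, p20$bulk), c(0, 0, 1))
  expect_equal(p8$total, 1)
  expect_error(classify_binding(at_r(8), h, r_int = 15, r_ext = 11), "r_int")
})

test_that("occupancy conservation links profiles, partitions and raw counts", {
  h <- helix_centered()
  target <- data.frame(r_lo = c(8, 13), r_hi = c(9, 14),
                       c_molL = c(0.4, 0.2))
  traj <- ion_cloud(target, h, box_std, 40, seed = 9, c_bulk = 0.01)
  raw <- mean(vapply(traj$frames, nrow, 0L))
  prof <- radial_profile(traj, h, axial_margin = Inf, r_max = 30)
  part <- classify_binding(traj, h)
  expect_lt(abs(sum(prof$count) + attr(prof, "overflow") - raw), 1e-9)
  expect_lt(abs(part$internal + part$external + part$bulk - raw), 1e-9)
})

test_that("charge density grids localize charge and conserve it exactly", {
  sp <- data.frame(name = "COH", charge = 3, count = 1,
                   stringsAsFactors = FALSE)
  traj <- ion_trajectory(sp, list(matrix(c(10.5, 10.5, 10.5), 1, 3)),
                         box = c(20, 20, 20))
  g <- charge_density_grid(traj, spacing = 1)
  expect_equal(max(g$density), 3.0)                 # one voxel at 3 e/A^3
  expect_equal(sum(g$density > 0), 1)
  expect_equal(threshold_density(g, 0.02)$n, 1)     # thresholding selects it
  expect_equal(sum(g$density) * g$spacing^3, 3.0)   # conservation
  expect_error(charge_density_grid(traj, spacing = 11), "half")
})

test_that("bridge detection needs contact with both backbones", {
  hA <- build_helix("AC", "bdna", axis_origin = c(20, 20, 20))
  hB <- translate_helix(hA, c(10, 0, 0))
  pA <- phosphate_sites(hA)[1, ]
  ion <- pA + c(5, 0, 0)       # midway between facing phosphates 10 A apart
  traj <- single_ion_traj(ion, c(60, 60, 60))
  expect_equal(detect_bridges(traj, hA, hB, cutoff = 6)$per_frame[1], 1L)
  expect_equal(detect_bridges(traj, hA, hB, cutoff = 4)$per_frame[1], 0L)
  expect_error(detect_bridges(traj, hA, hA, 6), "distinct")
  expect_error(detect_bridges(traj, hA, hB, 0), "> 0")
})

test_that("water ordering resolves constructed orientations", {
  sc <- bridge_scene("bdna_external", n_ions = 4, n_frames = 3, seed = 33)
  br <- detect_bridges(sc$traj, sc$pair$helixA, sc$pair$helixB, 6)
  # dipoles anti-parallel to the O->ion vector: all mass at cos(theta) = -1
  w_to <- lapply(seq_len(3), function(i)
    water_scene("toward_ion", sc$traj$frames[[i]], 60, seed = 100 + i))
  prof <- water_ordering(with_waters(sc$traj, w_to), br)
  bw <- prof$cos_hi[1] - prof$cos_lo[1]
  expect_equal(sum(prof$density) * bw, 1)           # normalized
  expect_equal(prof$density[1] * bw, 1)             # everything in [-1, -0.9)
  # isotropic orientations: flat histogram within sampling error
  w_iso <- lapply(seq_len(3), function(i)
    water_scene("isotropic", sc$traj$frames[[i]], 400, seed = 200 + i))
  prof_iso <- water_ordering(with_waters(sc$traj, w_iso), br)
  n <- attr(prof_iso, "n_waters")
  counts <- prof_iso$density * bw * n
  chi <- suppressWarnings(chisq.test(counts, p = rep(1 / 20, 20)))
  expect_gt(chi$p.value, 0.01)
  # waters outside the shell are excluded
  far <- lapply(seq_len(3), function(i) {
    w <- water_scene("toward_ion", sc$traj$frames[[i]], 10, seed = i)
    lapply(w, function(m) m + 50)
  })
  expect_equal(attr(water_ordering(with_waters(sc$traj, far), br),
                    "n_waters"), 0)
  expect_error(water_ordering(sc$traj, br), "no water")
})
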