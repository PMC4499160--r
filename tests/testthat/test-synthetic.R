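test_that("ground-truth PMFs are anchored, calibrated and self-consistent", {
  for (shape in c("repulsive", "bdna_5mM", "arna_50mM")) {
    gt <- ground_truth_pmf(shape)
    expect_equal(gt$fn(40), 0, tolerance = 1e-12)
    # analytic derivative agrees with central finite differences
    xs <- seq(20.5, 39.5, by = 0.5)
    h <- 1e-5
    fd <- (gt$fn(xs + h) - gt$fn(xs - h)) / (2 * h)
    expect_lt(max(abs(fd - gt$deriv(xs)) / pmax(abs(fd), 1)), 1e-6)
  }
  # calibrated well depths and locations
  xs <- seq(20, 40, by = 0.005)
  gb <- ground_truth_pmf("bdna_5mM")$fn(xs)
  expect_equal(min(gb), -3.5, tolerance = 1e-3)
  expect_equal(xs[which.min(gb)], 27, tolerance = 0.02)
  ga <- ground_truth_pmf("arna_50mM")$fn(xs)
  expect_equal(min(ga), -4.1, tolerance = 1e-3)
  expect_equal(xs[which.min(ga)], 27, tolerance = 0.02)
  gr <- ground_truth_pmf("repulsive")$fn(xs)
  expect_true(all(diff(gr) < 0))          # purely repulsive: monotone down
})

test_that("a flat landscape gives pure-spring Gaussian samples", {
  k <- 1000; x0 <- 30; n <- 2e4
  s <- spring_sampler(flat_truth(), k, x0, n, seed = 2)
  sigma <- sqrt(hpmf_constants$kT_kJmol / (k / 100))
  expect_lt(abs(mean(s$x) - x0), 3 * sigma / sqrt(n))
  expect_equal(sd(s$x), sigma, tolerance = 0.03)
  # determinism under the seed
  expect_identical(spring_sampler(flat_truth(), k, x0, 100, seed = 7)$x,
                   spring_sampler(flat_truth(), k, x0, 100, seed = 7)$x)
})

test_that("a linear landscape shifts the spring mean by -slope/k", {
  slope_kT <- 0.5                       # kT per Angstrom
  s <- spring_sampler(linear_truth(slope_kT), 1000, 30, 1e5, seed = 3)
  expected_shift <- -slope_kT * hpmf_constants$kT_kJmol / 10   # k_A = 10
  expect_lt(abs(mean(s$x) - 30 - expected_shift), 0.005)
})

test_that("a double-well landscape is recovered end to end", {
  # two Gaussian wells; the spring chain must find both minima
  truth <- structure(list(
    name = "double",
    fn = function(x) 5 * exp(-(x - 20) / 2.5) -
      2.5 * exp(-(x - 26)^2 / 3) - 2.0 * exp(-(x - 33)^2 / 3),
    deriv = function(x) -2 * exp(-(x - 20) / 2.5) +
      2.5 * (x - 26) * 2 / 3 * exp(-(x - 26)^2 / 3) +
      2.0 * (x - 33) * 2 / 3 * exp(-(x - 33)^2 / 3),
    params = list(), x_ref = 40), class = "ground_truth_pmf")
  pts <- lapply(seq(20, 40, 0.5), function(x0)
    mean_force(spring_sampler(truth, 1000, x0, 4000, seed = 700 + x0 * 2)))
  prof <- suppressWarnings(integrate_pmf(pts, 40))
  # local minima of the recovered profile
  g <- prof$dG_kBT
  loc <- which(diff(sign(diff(g))) > 0) + 1
  expect_gte(length(loc), 2)
  mins <- sort(prof$x[loc][order(g[loc])][1:2])
  expect_lt(abs(mins[1] - 26), 0.75)
  expect_lt(abs(mins[2] - 33), 0.75)
})

test_that("ion clouds round-trip their target profiles", {
  box <- c(130, 80, 100)
  h <- build_helix(seq16(), "bdna",
                   axis_origin = c(65, 40, (100 - 50.7) / 2))
  # delta-like spike in [8,9): a single occupied bin comes back
  spike <- data.frame(r_lo = 8, r_hi = 9, c_molL = 0.5)
  traj <- ion_cloud(spike, h, box, 30, seed = 21)
  prof <- radial_profile(traj, h, axial_margin = 0)
  expect_true(all(prof$count[prof$r_lo != 8] == 0))
  expect_gt(prof$count[prof$r_lo == 8], 0)
  # determinism
  t2 <- ion_cloud(spike, h, box, 3, seed = 5)
  t3 <- ion_cloud(spike, h, box, 3, seed = 5)
  expect_identical(t2$frames, t3$frames)
  # support must fit in the box
  expect_error(ion_cloud(data.frame(r_lo = 0, r_hi = 60, c_molL = 0.1),
                         h, box, 1), "outside the box")
})

test_that("groove-restricted clouds classify into the requested groove", {
  box <- c(130, 80, 100)
  h <- build_helix(seq16(), "bdna",
                   axis_origin = c(65, 40, (100 - 50.7) / 2))
  ring <- data.frame(r_lo = 7, r_hi = 9, c_molL = 1.5)
  traj <- ion_cloud(ring, h, box, 25, groove = "major", seed = 13)
  part <- classify_binding(traj, h)
  # padded spare ions are parked in the bulk, so normalize by bound ions only
  gm <- part$groove["internal", "major"] + part$groove["external", "major"]
  expect_equal(gm / (part$internal + part$external), 1, tolerance = 1e-9)
})

test_that("bridge scenes meet their constructed expectations exactly", {
  for (mode in c("bdna_external", "arna_internal")) {
    sc <- bridge_scene(mode, separation = 27, n_ions = 5, n_frames = 4,
                       seed = 3)
    rep <- detect_bridges(sc$traj, sc$pair$helixA, sc$pair$helixB,
                          cutoff = sc$cutoff)
    expect_equal(rep$per_frame, as.integer(sc$expected_bridging))
  }
  expect_error(bridge_scene("nope"), "arg")
})

test_that("water scenes have rigid geometry and controlled orientation", {
  ions <- rbind(c(10, 10, 10), c(20, 20, 20))
  w <- water_scene("toward_ion", ions, 40, seed = 6)
  oh1 <- sqrt(rowSums((w$H1 - w$O)^2))
  oh2 <- sqrt(rowSums((w$H2 - w$O)^2))
  expect_equal(oh1, rep(0.9572, 40), tolerance = 1e-9)
  expect_equal(oh2, rep(0.9572, 40), tolerance = 1e-9)
  v1 <- (w$H1 - w$O) / oh1; v2 <- (w$H2 - w$O) / oh2
  ang <- acos(rowSums(v1 * v2)) * 180 / pi
  expect_equal(ang, rep(104.52, 40), tolerance = 1e-6)
  expect_error(water_scene("toward_ion", ions, 0), ">= 1")
  expect_identical(water_scene("isotropic", ions, 5, seed = 9),
                   water_scene("isotropic", ions, 5, seed = 9))
})
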