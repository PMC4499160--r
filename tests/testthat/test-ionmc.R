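test_that("pair energies follow the primitive-model Coulomb form", {
  sys <- mc_system(data.frame(name = c("A", "B"), charge = c(1, 1),
                              radius = c(2, 2), count = c(1, 1)),
                   c(65, 40, 50), enforce_neutrality = FALSE)
  p <- rbind(c(10, 10, 10), c(20, 10, 10))
  # Coulomb-constant oracle: 1389.35 / (78 * 10)
  expect_equal(mc_energy(p, sys), 1389.35 / (78 * 10), tolerance = 1e-9)
  # hard-sphere overlap
  expect_identical(mc_energy(rbind(c(10, 10, 10), c(13, 10, 10)), sys), Inf)
  # a single ion alone has zero energy
  sys1 <- mc_system(data.frame(name = "A", charge = 1, radius = 2, count = 1),
                    c(65, 40, 50), enforce_neutrality = FALSE)
  expect_equal(mc_energy(c(5, 5, 5), sys1), 0)
})

test_that("energy is invariant under lattice translations (minimum image)", {
  set.seed(14)
  box <- c(65, 40, 50)
  sys <- mc_system(data.frame(name = c("NA", "CL"), charge = c(1, -1),
                              radius = c(2, 2), count = c(4, 4)),
                   box)
  p <- cbind(runif(8, 0, 65), runif(8, 0, 40), runif(8, 0, 50))
  E0 <- mc_energy(p, sys)
  shift <- matrix(rep(box * c(1, -2, 3), each = 8), 8, 3)
  expect_equal(mc_energy(p + shift, sys), E0, tolerance = 1e-9)
})

test_that("electroneutrality is enforced at construction", {
  expect_error(mc_system(data.frame(name = "NA", charge = 1, radius = 2,
                                    count = 3), c(65, 40, 50)),
               "electroneutral")
  pair <- duplex_pair("bdna", 27, box = c(65, 40, 60))
  # 20 trivalent cations neutralize the -60 e of two 16-bp duplexes
  sys <- mc_system(data.frame(name = "COH", charge = 3, radius = 4,
                              count = 20), c(65, 40, 60), helices = pair)
  expect_equal(sum(sys$fixed_q), -60)
})

test_that("Metropolis runs are seed-reproducible and measure the ideal gas", {
  box <- c(65, 40, 50)
  sysi <- mc_system(data.frame(name = "X", charge = 0, radius = 1, count = 20),
                    box)
  r1 <- run_mc(sysi, 300, seed = 9)
  r2 <- run_mc(sysi, 300, seed = 9)
  expect_identical(r1$samples$frames, r2$samples$frames)
  expect_equal(r1$mean_energy, 0)
  # whole-box bulk measurement of uncharged ions is exactly N/V
  expect_equal(unname(r1$bulk_molL),
               20 / prod(box) * hpmf_constants$ions_per_A3_to_molar)
  expect_error(run_mc(mc_system(
    data.frame(name = "X", charge = 0, radius = 1, count = 0), box), 10),
    "zero mobile ions")
})

test_that("counterions condense around the fixed helix charges", {
  box <- c(65, 40, 60)
  pair <- duplex_pair("bdna", 27, box = box)
  sys <- mc_system(data.frame(name = "COH", charge = 3, radius = 4,
                              count = 20), box, helices = pair)
  r <- run_mc(sys, 1500, seed = 7)
  prof <- radial_profile(r$samples, pair$helixA, bin_width = 1, r_max = 15,
                         axial_margin = 0)
  near <- sum(prof$count)
  uniform <- 20 * (pi * 15^2 * axial_extent(pair$helixA)) / prod(box)
  expect_gt(near, 1.3 * uniform)
})

test_that("groove exclusion regions suppress deep binding", {
  box <- c(65, 40, 50)
  h <- build_helix(seq16("rna"), "arna",
                   axis_origin = c(32.5, 20, (50 - 15 * 2.81) / 2))
  sp <- data.frame(name = "COH", charge = 3, radius = 4, count = 10)
  excl <- matrix(c(32.5, 20, 0, 7, 0, 50), 1)
  plain <- run_mc(mc_system(sp, box, helices = h,
                            enforce_neutrality = FALSE), 1200, seed = 3)
  blocked <- run_mc(mc_system(sp, box, helices = h, exclusions = excl,
                              enforce_neutrality = FALSE), 1200, seed = 3)
  deep_charge <- function(r) {
    pr <- radial_profile(r$samples, h, bin_width = 1, r_max = 7,
                         axial_margin = 0)
    sum(pr$count) * 3
  }
  expect_lt(deep_charge(blocked), deep_charge(plain))
  expect_equal(deep_charge(blocked), 0)
})

test_that("count calibration meets targets and keeps electroneutrality", {
  box <- c(65, 40, 50)
  cal <- calibrate_counts(c("NA" = 0.1), box, seed = 11)
  expect_true(cal$converged)
  expect_equal(unname(cal$measured_molL["NA"]), 0.1, tolerance = 0.1)
  expect_equal(unname(cal$counts["NA"] - cal$counts["CL"]), 0)
  # with two helices: N_Na + 3 N_CoHex - N_Cl = 60 whatever the counts.
  # (the desk-scale box holds a large neutralizing Na+ background, so only
  # the electroneutrality invariant is asserted here, not tight convergence)
  pair <- duplex_pair("bdna", 27, box = c(65, 40, 60))
  cal2 <- calibrate_counts(c("NA" = 0.15, "COH" = 0.01), c(65, 40, 60),
                           helices = pair, n_sweeps = 800, seed = 12,
                           tolerance = 2)
  expect_equal(unname(cal2$counts["NA"] + 3 * cal2$counts["COH"] -
                        cal2$counts["CL"]), 60)
  # a zero target drops the species and calibrates the rest
  cal3 <- calibrate_counts(c("NA" = 0.1, "COH" = 0), box, seed = 13)
  expect_false("COH" %in% names(cal3$counts))
  expect_true(cal3$converged)
})
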