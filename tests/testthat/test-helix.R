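test_that("fiber duplexes carry the right charge array and lattice geometry", {
  for (form in c("bdna", "arna", "adna")) {
    f <- helix_form(form)
    h <- build_helix(seq16(if (form == "arna") "rna" else "dna"), form)
    ph <- h$sites[h$sites$role == "phosphate", ]
    # no-5'-terminal-phosphate convention: 2*(N-1) phosphates at -1 e each
    expect_equal(nrow(ph), 2 * (16 - 1))
    expect_true(all(ph$charge == -1))
    expect_equal(sum(h$sites$charge), -2 * (16 - 1))
    # all phosphates exactly on the cylinder
    r <- sqrt(ph$x^2 + ph$y^2)
    expect_true(all(abs(r - f$phosphate_radius) < 1e-9))
    expect_equal(axial_extent(h), 15 * f$rise)
  }
  # frozen arithmetic: 16-bp B-DNA axial extent 15 * 3.38
  expect_frozen(axial_extent(build_helix(seq16(), "bdna")), 50.70)
})

test_that("A-form base pairs sit farther off-axis than B-form (deep major groove)", {
  ha <- build_helix(seq16("rna"), "arna")
  hb <- build_helix(seq16(), "bdna")
  rad <- function(h) {
    b <- h$sites[h$sites$role == "base", ]
    mean(sqrt(b$x^2 + b$y^2))
  }
  expect_gt(rad(ha), rad(hb))
})

test_that("A-DNA major-groove arc is ~2 A narrower than A-RNA's", {
  arc <- function(form) {
    f <- helix_form(form)
    major_groove_sector_deg(f) * pi / 180 * f$phosphate_radius
  }
  expect_equal(arc("arna") - arc("adna"), 2, tolerance = 0.15)
})

test_that("sequence validation rejects bad input by name", {
  expect_error(build_helix("ACGX", "bdna"), "X")
  expect_error(build_helix("A", "bdna"), "at least 2")
  # T/U interconversion is silent
  expect_equal(build_helix("ACGT", "arna")$sequence, "ACGU")
})

test_that("default_sequence covers all dinucleotides deterministically", {
  s17 <- default_sequence(17)
  expect_equal(length(dinucleotides_of(s17)), 16)   # exhaustive scan oracle
  expect_identical(default_sequence(17), s17)        # deterministic
  s24 <- default_sequence(24)
  expect_equal(length(dinucleotides_of(s24)), 16)
  expect_warning(s16 <- default_sequence(16), "15 dinucleotide")
  expect_gte(length(dinucleotides_of(s16)), 15)
  expect_error(default_sequence(15), ">= 16")
  expect_false(grepl("T", default_sequence(17, "rna")))
})

test_that("groove assignment follows the azimuthal sectors", {
  h <- build_helix(seq16(), "bdna")
  f <- h$form
  # point exactly on a phosphate site: documented tie-break -> minor
  p <- h$sites[h$sites$role == "phosphate", ][1, ]
  expect_equal(groove_of_point(h, c(p$x, p$y, p$z)), "minor")
  # midpoint of the minor (small-gap) sector at the height of bp 8
  z <- 7 * f$rise
  ang <- (h$phase0 + (z / f$rise) * f$twist + f$phosphate_phase / 2) * pi / 180
  pt <- c(9 * cos(ang), 9 * sin(ang), z)
  expect_equal(groove_of_point(h, pt), "minor")
  # beyond the radial cutoff -> bulk
  expect_equal(groove_of_point(h, c(30, 0, z)), "bulk")
})

test_that("groove sector fractions match the analytic angular fractions", {
  set.seed(71)
  for (form in c("bdna", "arna")) {
    h <- build_helix(seq16(if (form == "arna") "rna" else "dna"), form)
    n <- 4000
    z <- runif(n, 0, axial_extent(h))
    ang <- runif(n, 0, 2 * pi)
    pts <- cbind(8 * cos(ang), 8 * sin(ang), z)
    g <- groove_of_point(h, pts)
    frac_major <- mean(g == "major")
    expected <- major_groove_sector_deg(h$form) / 360
    expect_equal(frac_major, expected, tolerance = 4 / sqrt(n))
  }
})

test_that("groove assignment is covariant under axial rotation", {
  h <- build_helix(seq16(), "bdna")
  set.seed(5)
  n <- 300
  pts <- cbind(runif(n, -12, 12), runif(n, -12, 12),
               runif(n, 0, axial_extent(h)))
  g0 <- groove_of_point(h, pts)
  th <- 73.4 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_identical(groove_of_point(rotate_helix(h, 73.4), pts %*% t(R)), g0)
})

test_that("duplex pairs are placed on parallel z axes at the stated separation", {
  pair <- duplex_pair("bdna", 27)
  expect_equal(pair$helixA$axis_direction, c(0, 0, 1))
  expect_equal(pair$helixB$axis_origin[1] - pair$helixA$axis_origin[1], 27)
  expect_equal(pair$helixB$axis_origin[2:3], pair$helixA$axis_origin[2:3])
  expect_error(duplex_pair("bdna", 200), "fit inside")
})

test_that("helix PDB round-trips through bio3d with charges in occupancy", {
  h <- build_helix(seq16(), "bdna")
  path <- tempfile(fileext = ".pdb")
  write_helix_pdb(h, path)
  pdb <- bio3d::read.pdb(path)
  expect_equal(nrow(pdb$atom), nrow(h$sites))
  expect_equal(sum(pdb$atom$o), sum(h$sites$charge))
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$length_bp, 16)
})
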