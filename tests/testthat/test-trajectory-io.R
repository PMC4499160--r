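test_that("XYZ trajectories round-trip through topology + frames", {
  sp <- data.frame(name = "NA", charge = 1, count = 3,
                   stringsAsFactors = FALSE)
  frames <- list(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3, byrow = TRUE),
                 matrix(c(2, 3, 4, 5, 6, 7, 8, 9, 10), 3, 3, byrow = TRUE))
  traj <- ion_trajectory(sp, frames, box = c(20, 20, 20))
  top <- tempfile(fileext = ".pdb"); xyz <- tempfile(fileext = ".xyz")
  write_topology_pdb(traj, top)
  write_trajectory_xyz(traj, xyz)
  back <- read_trajectory(top, xyz)
  expect_equal(length(back$frames), 2)
  expect_equal(back$species$name, "NA")
  expect_equal(back$species$count, 3)
  expect_equal(back$species$charge, 1)
  expect_lt(max(abs(back$frames[[2]] - traj$frames[[2]])), 1e-6)
})

test_that("frame/topology mismatches are rejected with the frame index", {
  sp <- data.frame(name = "NA", charge = 1, count = 3,
                   stringsAsFactors = FALSE)
  traj <- ion_trajectory(sp, list(matrix(1, 3, 3)), box = c(20, 20, 20))
  top <- tempfile(fileext = ".pdb"); xyz <- tempfile(fileext = ".xyz")
  write_topology_pdb(traj, top)
  sp2 <- data.frame(name = "NA", charge = 1, count = 2,
                    stringsAsFactors = FALSE)
  write_trajectory_xyz(ion_trajectory(sp2, list(matrix(1, 2, 3)),
                                      box = c(20, 20, 20)), xyz)
  expect_error(read_trajectory(top, xyz), "frame 1")
  # unknown species without an override is rejected
  sp3 <- data.frame(name = "XX", charge = 2, count = 1,
                    stringsAsFactors = FALSE)
  t3 <- ion_trajectory(sp3, list(matrix(1, 1, 3)), box = c(20, 20, 20))
  top3 <- tempfile(fileext = ".pdb"); xyz3 <- tempfile(fileext = ".xyz")
  write_topology_pdb(t3, top3); write_trajectory_xyz(t3, xyz3)
  expect_error(read_trajectory(top3, xyz3), "XX")
  expect_equal(read_trajectory(top3, xyz3,
                               charges = c(XX = 2))$species$charge, 2)
})

test_that("positions are wrapped into the primary box on construction", {
  sp <- data.frame(name = "NA", charge = 1, count = 2,
                   stringsAsFactors = FALSE)
  raw <- matrix(c(25, -3, 41, 5, 19, 10), 2, 3, byrow = TRUE)
  box <- c(20, 20, 20)
  traj <- ion_trajectory(sp, list(raw), box = box)
  # modular-arithmetic oracle
  expect_equal(traj$frames[[1]], raw %% rep(box, each = 2))
  expect_true(all(traj$frames[[1]] >= 0 & traj$frames[[1]] < 20))
})

test_that("spring series reader validates shape, times and content", {
  f <- tempfile()
  writeLines(c("# comment", "0 30", "2 30.1", "4 29.9"), f)
  s <- read_spring_series(f, k = 1000, x0 = 30)
  expect_s3_class(s, "spring_series")
  expect_equal(length(s$x), 3)
  expect_equal(s$x[3], 29.9)

  writeLines(c("0 30", "0 30.1"), f)
  expect_error(read_spring_series(f, 1000, 30), "non-increasing time at line 2")
  writeLines(c("0 30", "oops"), f)
  expect_error(read_spring_series(f, 1000, 30), "line 2")
  writeLines(character(0), f)
  expect_error(read_spring_series(f, 1000, 30), "no samples")
  expect_error(spring_series(-5, 30, 1:3, rep(30, 3)), "k must be > 0")
  # write/read round trip
  s2 <- spring_series(1000, 30, time = c(1, 2, 3), x = c(30.05, 29.9, 30.2))
  f2 <- tempfile()
  write_spring_series(s2, f2)
  back <- read_spring_series(f2, 1000, 30)
  expect_equal(back$x, s2$x)
})

test_that("OpenDX grids round-trip and threshold as documented", {
  g <- structure(list(origin = c(0, 0, 0), spacing = 1, dim = c(2, 2, 2),
                      density = array(0, c(2, 2, 2)), n_frames = 1,
                      species = "COH", threshold = 0.02),
                 class = "density_grid")
  path <- tempfile(fileext = ".dx")
  write_density_dx(g, path)
  txt <- readLines(path)
  expect_true(any(grepl("gridpositions counts 2 2 2", txt)))
  vals <- suppressWarnings(as.numeric(unlist(strsplit(
    txt[(grep("data follows", txt) + 1):length(txt)], "\\s+"))))
  expect_equal(sum(is.finite(vals)), 8)

  g$density[1, 2, 1] <- 0.05
  g$density[2, 1, 2] <- 0.013
  write_density_dx(g, path)
  back <- read_density_dx(path)
  expect_equal(back$density, g$density, tolerance = 1e-9)
  expect_equal(threshold_density(back, 0.02)$n, 1)  # only the 0.05 voxel
  g$density[1, 1, 1] <- NaN
  expect_error(write_density_dx(g, path), "non-finite")
})

test_that("TSV tables keep column names through the '#' header", {
  df <- data.frame(x = c(1, 2.5), dG_kBT = c(-1.25, 0))
  f <- tempfile()
  write_tsv_table(df, f, meta = list(x_ref_A = 40))
  back <- read_tsv_table(f)
  expect_equal(names(back), names(df))
  expect_equal(back$dG_kBT, df$dG_kBT)
  expect_true(any(grepl("x_ref_A: 40", readLines(f))))
})
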