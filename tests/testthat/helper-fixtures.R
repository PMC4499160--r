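# Shared fixtures: everything is generated in code; no stored data.

seq16 <- function(alphabet = "dna")
  suppressWarnings(default_sequence(16, alphabet))

# a ground-truth PMF object that is identically zero (pure-spring sampling)
flat_truth <- function() {
  structure(list(name = "flat", fn = function(x) 0 * x,
                 deriv = function(x) 0 * x, params = list(), x_ref = 40),
            class = "ground_truth_pmf")
}

# a linear ground-truth PMF with slope s (kT per Angstrom)
linear_truth <- function(s) {
  structure(list(name = "linear", fn = function(x) s * (x - 40),
                 deriv = function(x) rep(s, length(x)),
                 params = list(slope = s), x_ref = 40),
            class = "ground_truth_pmf")
}

# trajectory holding one fixed ion (repeated over frames)
single_ion_traj <- function(pos, box, n_frames = 4, name = "COH", charge = 3) {
  sp <- data.frame(name = name, charge = charge, count = 1,
                   stringsAsFactors = FALSE)
  frames <- replicate(n_frames, matrix(pos, 1, 3), simplify = FALSE)
  ion_trajectory(sp, frames, box = box)
}

# exhaustive dinucleotide scan (oracle for sequence coverage)
dinucleotides_of <- function(s) {
  b <- strsplit(s, "")[[1]]
  unique(paste0(b[-length(b)], b[-1]))
}

expect_frozen <- function(value, frozen, tol = 1e-9)
  expect_equal(value, frozen, tolerance = tol)
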