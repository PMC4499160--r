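## Fiber-model duplex construction: reduced-representation A-RNA / B-DNA /
## A-DNA helices as charged pseudo-sites (phosphate / sugar / base) on a
## uniform helical lattice, plus groove geometry.

## One editable table of fiber parameters.  The duplex geometry downstream
## analyses see is entirely determined by these numbers:
##   rise, twist        : helical repeat per base pair
##   phosphate_radius   : radial distance of phosphate sites from the axis
##   phosphate_phase    : azimuthal gap (deg) from the strand-1 phosphate to
##                        the strand-2 phosphate at the same base-pair level,
##                        i.e. the angular width of the sector between the two
##                        backbone strands on the "short way" around
##   small_gap_groove   : which groove that short-way sector is.  B-form
##                        helices have a narrow minor groove; A-form helices
##                        have a narrow, deep major groove.
##   base_displacement  : radial distance of base sites from the axis.  A-form
##                        base pairs are displaced off-axis, which is what
##                        creates the deep major groove.
.FIBER_FORMS <- list(
  arna = list(name = "A-RNA", alphabet = c("A", "C", "G", "U"),
              rise = 2.81, twist = 32.7, phosphate_radius = 9.5,
              phosphate_phase = 80, small_gap_groove = "major",
              base_displacement = 4.4),
  bdna = list(name = "B-DNA", alphabet = c("A", "C", "G", "T"),
              rise = 3.38, twist = 36.0, phosphate_radius = 9.4,
              phosphate_phase = 144, small_gap_groove = "minor",
              base_displacement = 0.0),
  adna = list(name = "A-DNA", alphabet = c("A", "C", "G", "T"),
              rise = 2.56, twist = 32.7, phosphate_radius = 9.5,
              phosphate_phase = 68, small_gap_groove = "major",
              base_displacement = 4.4)
)

#' Fiber-form parameter set
#'
#' Returns the helical parameters of one of the three standard fiber forms
#' used by the package.  The values live in a single editable table; see the
#' methods vignette for their provenance and meaning.
#'
#' @param form `"arna"`, `"bdna"` or `"adna"` (case-insensitive; `"A-RNA"`
#'   style spellings also accepted).
#' @return An object of class `helix_form`: a named list with fields
#'   `name`, `alphabet`, `rise` (Angstrom/bp), `twist` (degrees/bp),
#'   `phosphate_radius` (Angstrom), `phosphate_phase` (degrees),
#'   `small_gap_groove` (`"major"` or `"minor"`), `base_displacement`
#'   (Angstrom).
#' @examples
#' helix_form("bdna")$rise
#' @export
helix_form <- function(form) {
  key <- tolower(gsub("[^a-z]", "", tolower(form)))
  if (!key %in% names(.FIBER_FORMS))
    stop("unknown helix form '", form, "'; expected one of: ",
         paste(names(.FIBER_FORMS), collapse = ", "))
  out <- .FIBER_FORMS[[key]]
  out$key <- key
  stopifnot(out$rise > 0, out$twist > 0, out$twist < 360,
            out$phosphate_radius > 0)
  class(out) <- "helix_form"
  out
}

#' Angular width of the major-groove sector of a form
#'
#' @param form A `helix_form` or a form name.
#' @return Width in degrees of the azimuthal sector assigned to the major
#'   groove.
#' @export
major_groove_sector_deg <- function(form) {
  f <- if (inherits(form, "helix_form")) form else helix_form(form)
  if (f$small_gap_groove == "major") f$phosphate_phase
  else 360 - f$phosphate_phase
}

.normalize_sequence <- function(sequence, form) {
  s <- toupper(sequence)
  bases <- strsplit(s, "")[[1]]
  ## RNA forms accept T-containing input by transcription, and vice versa;
  ## genuinely foreign characters are rejected by name.
  if ("U" %in% form$alphabet) bases[bases == "T"] <- "U"
  if ("T" %in% form$alphabet) bases[bases == "U"] <- "T"
  bad <- setdiff(unique(bases), form$alphabet)
  if (length(bad))
    stop("invalid character(s) in sequence for ", form$name, ": ",
         paste(bad, collapse = ", "))
  paste(bases, collapse = "")
}

#' Build a reduced-representation fiber-model duplex
#'
#' Lays phosphate, sugar and base pseudo-sites of both strands on the helical
#' lattice of the requested fiber form: residue `i` of strand 1 sits at
#' azimuth `phase0 + (i-1) * twist` and height `(i-1) * rise`; the strand-2
#' phosphate at the same level is offset by the form's `phosphate_phase`.
#' Phosphates carry -1 e each; under the no-5'-terminal-phosphate convention
#' an N-bp duplex has `2*(N-1)` phosphates and total charge `-2*(N-1)` e.
#' The helix axis is +z with the first base pair at the axis origin.
#'
#' @param sequence Base string (length >= 2) in the form's alphabet
#'   (`ACGU` for A-RNA, `ACGT` for the DNA forms; `T`/`U` are interconverted
#'   automatically).
#' @param form A `helix_form` or form name.
#' @param axis_origin 3-vector, position of the first base-pair level on the
#'   axis (Angstrom).
#' @param phase0 Azimuth (degrees) of the strand-1 phosphate at level 1.
#' @return An object of class `helix_model`: list with `form`, `sequence`,
#'   `sites` (data.frame: `x`,`y`,`z`,`charge`,`role`,`strand`,`residue`),
#'   `axis_origin`, `axis_direction` (unit +z), `phase0`, `length_bp`.
#' @examples
#' h <- build_helix(default_sequence(16), "bdna")
#' sum(h$sites$charge)      # -30 e for a 16-bp duplex
#' @export
build_helix <- function(sequence, form,
                        axis_origin = c(0, 0, 0), phase0 = 0) {
  f <- if (inherits(form, "helix_form")) form else helix_form(form)
  seq_norm <- .normalize_sequence(sequence, f)
  n <- nchar(seq_norm)
  if (n < 2) stop("sequence must have at least 2 base pairs, got ", n)
  stopifnot(length(axis_origin) == 3, is.finite(axis_origin))

  lev   <- seq_len(n)
  z     <- (lev - 1) * f$rise
  ang1  <- phase0 + (lev - 1) * f$twist          # strand-1 phase, degrees
  ang2  <- ang1 + f$phosphate_phase              # strand-2 phase

  polar <- function(ang_deg, radius, z, role, strand) {
    a <- ang_deg * pi / 180
    data.frame(x = axis_origin[1] + radius * cos(a),
               y = axis_origin[2] + radius * sin(a),
               z = axis_origin[3] + z,
               charge = if (role == "phosphate") -1 else 0,
               role = role, strand = strand, residue = lev,
               stringsAsFactors = FALSE)
  }

  ## no 5'-terminal phosphate: strand 1 runs 5'->3' with level, strand 2
  ## antiparallel, so the missing terminal phosphate is at level 1 on strand 1
  ## and level n on strand 2.
  p1 <- polar(ang1, f$phosphate_radius, z, "phosphate", 1L)[-1, ]
  p2 <- polar(ang2, f$phosphate_radius, z, "phosphate", 2L)[-n, ]
  s1 <- polar(ang1, f$phosphate_radius - 1.5, z, "sugar", 1L)
  s2 <- polar(ang2, f$phosphate_radius - 1.5, z, "sugar", 2L)
  ## base sites at the form's base displacement, in the middle of the
  ## inter-strand (short-way) sector
  b1 <- polar(ang1 + f$phosphate_phase / 2, f$base_displacement, z, "base", 1L)
  b2 <- polar(ang1 + f$phosphate_phase / 2, f$base_displacement, z, "base", 2L)

  sites <- rbind(p1, p2, s1, s2, b1, b2)
  rownames(sites) <- NULL

  out <- list(form = f, sequence = seq_norm, sites = sites,
              axis_origin = as.numeric(axis_origin),
              axis_direction = c(0, 0, 1),
              phase0 = phase0, length_bp = n)
  class(out) <- "helix_model"
  out
}

#' @export
print.helix_model <- function(x, ...) {
  cat(sprintf("<helix_model> %s, %d bp, axial extent %.2f A, total charge %+d e\n",
              x$form$name, x$length_bp,
              (x$length_bp - 1) * x$form$rise, sum(x$sites$charge)))
  invisible(x)
}

#' Axial extent of a helix model
#' @param helix A `helix_model`.
#' @return `(N-1) * rise` in Angstrom.
#' @export
axial_extent <- function(helix) (helix$length_bp - 1) * helix$form$rise

#' Phosphate site coordinates
#' @param helix A `helix_model`.
#' @return Matrix (n x 3) of phosphate positions, Angstrom.
#' @export
phosphate_sites <- function(helix) {
  p <- helix$sites[helix$sites$role == "phosphate", c("x", "y", "z")]
  as.matrix(p)
}

#' Deterministic all-dinucleotide cover sequence
#'
#' Returns a fixed sequence in which every one of the 16 ordered
#' dinucleotides occurs at least once, built from a de Bruijn cycle over
#' `{A,C,G,T}` (greedy prefer-last construction) closed by repeating the
#' first base, then truncated or periodically extended to the requested
#' length.  The full cover needs 17 bases; a 16-bp request is allowed with a
#' warning (one dinucleotide window short).
#'
#' @param length_bp Requested length (>= 16).
#' @param alphabet `"dna"` (default) or `"rna"` (T replaced by U).
#' @return A base string of `length_bp` characters; identical across calls.
#' @examples
#' default_sequence(17)
#' @export
default_sequence <- function(length_bp, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (length_bp < 16)
    stop("length_bp must be >= 16 to cover the 16 dinucleotides, got ",
         length_bp)
  if (length_bp == 16)
    warning("a 16-base sequence has only 15 dinucleotide windows; ",
            "one dinucleotide of 16 is necessarily missing")
  letters4 <- c("A", "C", "G", "T")
  ## greedy prefer-largest de Bruijn cycle of order 2: start from "AA",
  ## always append the largest base that does not recreate a used window.
  cyc <- c("A", "A")
  used <- new.env(parent = emptyenv())
  assign("AA", TRUE, envir = used)
  while (length(cyc) < 17) {           # 16-cycle + closing repeat of start
    lastc <- cyc[length(cyc)]
    placed <- FALSE
    for (b in rev(letters4)) {
      w <- paste0(lastc, b)
      if (!exists(w, envir = used)) {
        assign(w, TRUE, envir = used)
        cyc <- c(cyc, b)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("internal error: de Bruijn construction stalled")
  }
  cyc <- cyc[-1]                       # drop seed duplicate: 16-cycle
  full <- c(cyc, cyc[1])               # linearized cover, length 17
  reps <- ceiling(length_bp / 16)
  s <- c(rep(cyc, reps), cyc[1])[seq_len(length_bp)]
  out <- paste(s, collapse = "")
  if (alphabet == "rna") out <- gsub("T", "U", out)
  out
}

#' Rotate a helix about its own axis
#'
#' Rotates all sites and the stored strand phase by `angle_deg`, so groove
#' assignment remains frame-covariant.
#'
#' @param helix A `helix_model`.
#' @param angle_deg Rotation angle, degrees (right-handed about +z).
#' @return The rotated `helix_model`.
#' @export
rotate_helix <- function(helix, angle_deg) {
  a <- angle_deg * pi / 180
  o <- helix$axis_origin
  dx <- helix$sites$x - o[1]; dy <- helix$sites$y - o[2]
  helix$sites$x <- o[1] + cos(a) * dx - sin(a) * dy
  helix$sites$y <- o[2] + sin(a) * dx + cos(a) * dy
  helix$phase0 <- helix$phase0 + angle_deg
  helix
}

#' Translate a helix rigidly
#' @param helix A `helix_model`.
#' @param shift 3-vector, Angstrom.
#' @return Translated `helix_model`.
#' @export
translate_helix <- function(helix, shift) {
  stopifnot(length(shift) == 3)
  helix$sites$x <- helix$sites$x + shift[1]
  helix$sites$y <- helix$sites$y + shift[2]
  helix$sites$z <- helix$sites$z + shift[3]
  helix$axis_origin <- helix$axis_origin + as.numeric(shift)
  helix
}

## cylindrical coordinates of points relative to a helix axis (+z)
.cyl_coords <- function(helix, points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  dx <- p[, 1] - helix$axis_origin[1]
  dy <- p[, 2] - helix$axis_origin[2]
  list(r = sqrt(dx^2 + dy^2),
       azimuth_deg = atan2(dy, dx) * 180 / pi,
       z = p[, 3] - helix$axis_origin[3])
}

#' Assign points to the major or minor groove sector
#'
#' Groove membership is decided by the azimuthal sector of the point at its
#' axial height, relative to the two phosphate-strand phases there: the
#' strand-1 phase at height z is `phase0 + (z / rise) * twist` (continuous
#' interpolation of the helical lattice) and the strand-2 phase is offset by
#' the form's `phosphate_phase`.  Points in the short-way sector get the
#' form's `small_gap_groove` (minor for B-form, major for A-form); points in
#' the complementary sector get the other groove.  Points farther than
#' `r_cutoff` from the axis, or beyond the axial span plus `axial_margin`,
#' are labelled `"bulk"`.  Points exactly on a strand phase line are assigned
#' to the minor groove (documented tie-break).
#'
#' @param helix A `helix_model`.
#' @param points 3-vector or n x 3 matrix, Angstrom.
#' @param r_cutoff Radial assignment cutoff, Angstrom (default 15, the outer
#'   edge of the external-binding shell).
#' @param axial_margin Allowance beyond the helix span, Angstrom.
#' @return Character vector: `"major"`, `"minor"` or `"bulk"`.
#' @export
groove_of_point <- function(helix, points, r_cutoff = 15, axial_margin = 3) {
  cc <- .cyl_coords(helix, points)
  f <- helix$form
  phase1 <- helix$phase0 + (cc$z / f$rise) * f$twist
  delta <- (cc$azimuth_deg - phase1) %% 360
  small <- delta <= f$phosphate_phase
  out <- ifelse(small,
                f$small_gap_groove,
                if (f$small_gap_groove == "major") "minor" else "major")
  ## tie-break: exactly on a strand phase line -> minor
  tol <- 1e-9
  on_line <- pmin(delta, abs(delta - f$phosphate_phase), 360 - delta) < tol
  out[on_line] <- "minor"
  out[cc$r > r_cutoff] <- "bulk"
  ext <- axial_extent(helix)
  out[cc$z < -axial_margin | cc$z > ext + axial_margin] <- "bulk"
  out
}

#' Two parallel helices in a rectangular box
#'
#' Places two duplexes of the same form and sequence with axes parallel to +z,
#' separated along +x and centered in the box (the standard two-helix
#' simulation geometry; default box 130 x 80 x 100 Angstrom^3).
#'
#' @param form Form name or `helix_form`.
#' @param separation Axis-axis separation, Angstrom.
#' @param sequence Base string; default `default_sequence(16)`.
#' @param box 3-vector box lengths, Angstrom.
#' @param phase_b Additional axial-rotation phase of helix B, degrees.
#' @return Object of class `duplex_pair`: list with `helixA`, `helixB`,
#'   `box`, `separation_axis` (unit +x), `separation`.
#' @export
duplex_pair <- function(form, separation, sequence = NULL,
                        box = c(130, 80, 100), phase_b = 0) {
  f <- if (inherits(form, "helix_form")) form else helix_form(form)
  if (is.null(sequence))   # 16 bp is the standard duplex length here
    sequence <- suppressWarnings(
      default_sequence(16, if ("U" %in% f$alphabet) "rna" else "dna"))
  seq_norm <- sequence
  ext <- (nchar(seq_norm) - 1) * f$rise
  z0 <- (box[3] - ext) / 2
  cy <- box[2] / 2
  cx <- box[1] / 2
  hA <- build_helix(seq_norm, f, axis_origin = c(cx - separation / 2, cy, z0))
  hB <- build_helix(seq_norm, f, axis_origin = c(cx + separation / 2, cy, z0))
  if (phase_b != 0) hB <- rotate_helix(hB, phase_b)
  if (separation / 2 + f$phosphate_radius > cx ||
      f$phosphate_radius > cy || ext > box[3])
    stop("helices do not fit inside the box")
  out <- list(helixA = hA, helixB = hB, box = as.numeric(box),
              separation_axis = c(1, 0, 0), separation = separation)
  class(out) <- "duplex_pair"
  out
}

#' Write a helix model to PDB with a JSON sidecar
#'
#' Pseudo-atoms are written as P / S / B (phosphate, sugar, base), one chain
#' per strand, with the site charge in the occupancy column.  Form parameters
#' and axis frame go to `<path>.json`.
#'
#' @param helix A `helix_model`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_helix_pdb <- function(helix, path) {
  s <- helix$sites
  elety <- c(phosphate = "P", sugar = "S", base = "B")[s$role]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(s)),
                   resno = s$residue,
                   resid = rep("NUC", nrow(s)),
                   eleno = seq_len(nrow(s)),
                   elety = elety,
                   chain = c("A", "B")[s$strand],
                   o = s$charge,
                   b = rep(0, nrow(s)))
  meta <- list(form = unclass(helix$form), sequence = helix$sequence,
               axis_origin = helix$axis_origin,
               axis_direction = helix$axis_direction,
               phase0 = helix$phase0, length_bp = helix$length_bp)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
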