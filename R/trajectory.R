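## Coordinate, time-series, profile and density-grid I/O.
## Formats: PDB topology (via bio3d), XYZ-class multi-frame text and
## DCD-class binary frames (via bio3d), OpenDX scalar grids, TSV tables with
## '#'-prefixed headers, JSON sidecars.

.DEFAULT_CHARGES <- c(COH = 3, NA. = 1, CL = -1, K = 1, MG = 2)
.WATER_RESID <- c("HOH", "WAT", "SOL", "TIP3")

.species_charge <- function(name, charges = NULL) {
  tab <- .DEFAULT_CHARGES
  names(tab) <- sub("\\.$", "", names(tab))
  if (!is.null(charges)) tab[names(charges)] <- charges
  key <- toupper(name)
  if (!key %in% names(tab))
    stop("unknown ion species '", name,
         "'; supply its charge via the 'charges' argument")
  unname(tab[key])
}

#' Construct an ion trajectory container
#'
#' Holds per-frame ion coordinates (and optionally rigid three-site waters)
#' in a periodic rectangular box.  Ion rows are grouped by species in the
#' order of the species table; positions are wrapped into the primary box.
#'
#' @param species data.frame with columns `name`, `charge` (e), `count`.
#' @param frames List of matrices (`sum(count)` x 3), Angstrom.
#' @param box 3-vector box lengths, Angstrom.
#' @param times Frame times in ps (default `0, 1, 2, ...`); must be strictly
#'   increasing.
#' @param water Optional list (one element per frame) of lists with matrices
#'   `O`, `H1`, `H2` (n_water x 3).
#' @return Object of class `ion_trajectory`.
#' @export
ion_trajectory <- function(species, frames, box, times = NULL, water = NULL) {
  stopifnot(is.data.frame(species),
            all(c("name", "charge", "count") %in% names(species)),
            length(box) == 3, all(box > 0))
  ntot <- sum(species$count)
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames))
    stop("times and frames lengths differ")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  frames <- lapply(seq_along(frames), function(i) {
    f <- as.matrix(frames[[i]])
    if (nrow(f) != ntot || ncol(f) != 3)
      stop("frame ", i, " has wrong dimensions (", nrow(f), " x ", ncol(f),
           "), expected ", ntot, " x 3")
    f %% rep(box, each = nrow(f))      # wrap into primary box
  })
  if (!is.null(water) && length(water) != length(frames))
    stop("water frames length must match ion frames length")
  out <- list(species = species, frames = frames, times = as.numeric(times),
              box = as.numeric(box), water = water)
  class(out) <- "ion_trajectory"
  out
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf("<ion_trajectory> %d frame(s), box %.0fx%.0fx%.0f A, species: %s%s\n",
              length(x$frames), x$box[1], x$box[2], x$box[3],
              paste(sprintf("%s(%d, %+ge)", x$species$name, x$species$count,
                            x$species$charge), collapse = " "),
              if (is.null(x$water)) "" else ", with waters"))
  invisible(x)
}

#' Row indices of one species within a trajectory frame
#' @param traj An `ion_trajectory`.
#' @param name Species name.
#' @return Integer vector of row indices.
#' @export
species_rows <- function(traj, name) {
  idx <- match(name, traj$species$name)
  if (is.na(idx)) return(integer(0))
  offset <- if (idx == 1) 0 else sum(traj$species$count[seq_len(idx - 1)])
  seq_len(traj$species$count[idx]) + offset
}

#' Per-ion charges in frame row order
#' @param traj An `ion_trajectory`.
#' @return Numeric vector of length `sum(count)`.
#' @export
ion_charges <- function(traj) rep(traj$species$charge, traj$species$count)

#' Write trajectory topology as PDB
#'
#' One pseudo-atom per ion (residue name = species name) followed, if waters
#' are present, by OW/HW1/HW2 triplets with residue name HOH.
#'
#' @param traj An `ion_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_pdb <- function(traj, path) {
  name <- rep(traj$species$name, traj$species$count)
  elety <- toupper(substr(name, 1, 3))
  resid <- elety
  xyz <- traj$frames[[1]]
  if (!is.null(traj$water)) {
    w <- traj$water[[1]]
    nw <- nrow(w$O)
    xyz <- rbind(xyz, do.call(rbind, lapply(seq_len(nw), function(i)
      rbind(w$O[i, ], w$H1[i, ], w$H2[i, ]))))
    elety <- c(elety, rep(c("OW", "HW1", "HW2"), nw))
    resid <- c(resid, rep("HOH", 3 * nw))
  }
  n <- length(elety)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   type = rep("ATOM", n),
                   resno = seq_len(n), resid = resid,
                   eleno = seq_len(n), elety = elety,
                   chain = rep("I", n), o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Write trajectory frames as multi-frame XYZ text
#'
#' Standard XYZ blocks: atom count, a comment line carrying `time=<ps>` and
#' `box=<x> <y> <z>`, then `name x y z` rows (ions first, then water O/H1/H2
#' triplets).
#'
#' @param traj An `ion_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  name <- rep(traj$species$name, traj$species$count)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    xyz <- traj$frames[[i]]
    labels <- name
    if (!is.null(traj$water)) {
      w <- traj$water[[i]]
      nw <- nrow(w$O)
      xyz <- rbind(xyz, do.call(rbind, lapply(seq_len(nw), function(j)
        rbind(w$O[j, ], w$H1[j, ], w$H2[j, ]))))
      labels <- c(labels, rep(c("OW", "HW1", "HW2"), nw))
    }
    writeLines(c(sprintf("%d", nrow(xyz)),
                 sprintf("time=%.6f box=%.4f %.4f %.4f",
                         traj$times[i], traj$box[1], traj$box[2], traj$box[3]),
                 sprintf("%-4s %14.8f %14.8f %14.8f",
                         labels, xyz[, 1], xyz[, 2], xyz[, 3])),
               con)
  }
  invisible(path)
}

.read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0); boxes <- list()
  i <- 1; fi <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    fi <- fi + 1
    if (is.na(n) || n < 1)
      stop("malformed XYZ frame header at line ", i, " (frame ", fi, ")")
    if (i + 1 + n > length(lines))
      stop("truncated XYZ frame ", fi, " starting at line ", i)
    comment <- lines[i + 1]
    tm <- regmatches(comment, regexec("time=([-0-9.eE+]+)", comment))[[1]]
    bx <- regmatches(comment,
      regexec("box=([-0-9.eE+]+) ([-0-9.eE+]+) ([-0-9.eE+]+)", comment))[[1]]
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    if (any(lengths(parts) < 4))
      stop("malformed coordinate line in XYZ frame ", fi)
    lab <- vapply(parts, `[`, "", 1)
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                ncol = 3, byrow = TRUE)
    if (any(!is.finite(m)))
      stop("non-numeric coordinate in XYZ frame ", fi)
    frames[[fi]] <- m
    attr(frames[[fi]], "labels") <- lab
    times[fi] <- if (length(tm) == 2) as.numeric(tm[2]) else fi - 1
    boxes[[fi]] <- if (length(bx) == 4) as.numeric(bx[2:4]) else NULL
    i <- i + 2 + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  list(frames = frames, times = times, box = boxes[[1]])
}

#' Read an ion (and water) trajectory
#'
#' Topology is a PDB file (as written by [write_topology_pdb()]); frames are
#' either multi-frame XYZ text or a DCD-class binary stream (detected by the
#' `.dcd` extension and read with `bio3d::read.dcd`).  Species charges are
#' resolved from a name-to-charge table (Co-Hex `COH` +3, `NA` +1, `CL` -1 by
#' default) that can be overridden; waters are detected by residue name.
#'
#' @param topology Path to the PDB topology.
#' @param frames Path to the frame stream.
#' @param charges Optional named vector overriding/extending the species
#'   charge table.
#' @param box Box lengths (needed if the frame stream does not carry them).
#' @return An `ion_trajectory`.
#' @export
read_trajectory <- function(topology, frames, charges = NULL, box = NULL) {
  pdb <- bio3d::read.pdb(topology)
  at <- pdb$atom
  is_water <- toupper(at$resid) %in% .WATER_RESID
  ion_names <- at$resid[!is_water]
  nw <- sum(is_water) / 3
  if (nw != floor(nw))
    stop("water atom count is not a multiple of 3 in ", topology)

  if (grepl("\\.dcd$", frames, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(frames)
    flist <- lapply(seq_len(nrow(xyz)), function(i)
      matrix(xyz[i, ], ncol = 3, byrow = TRUE))
    times <- seq_len(nrow(xyz)) - 1
  } else {
    parsed <- .read_xyz_frames(frames)
    flist <- parsed$frames
    times <- parsed$times
    if (is.null(box)) box <- parsed$box
  }
  if (is.null(box)) stop("box lengths not found in frames; pass 'box='")

  natom_top <- nrow(at)
  for (i in seq_along(flist))
    if (nrow(flist[[i]]) != natom_top)
      stop("atom count mismatch between topology (", natom_top,
           ") and frame ", i, " (", nrow(flist[[i]]), ")")

  rle_sp <- rle(as.character(ion_names))
  species <- data.frame(name = rle_sp$values,
                        charge = vapply(rle_sp$values, .species_charge,
                                        0, charges = charges),
                        count = rle_sp$lengths, stringsAsFactors = FALSE)
  n_ion <- sum(species$count)
  ion_frames <- lapply(flist, function(f) f[which(!is_water), , drop = FALSE])
  water <- NULL
  if (nw > 0) {
    widx <- which(is_water)
    water <- lapply(flist, function(f) {
      w <- f[widx, , drop = FALSE]
      list(O  = w[seq(1, 3 * nw, 3), , drop = FALSE],
           H1 = w[seq(2, 3 * nw, 3), , drop = FALSE],
           H2 = w[seq(3, 3 * nw, 3), , drop = FALSE])
    })
  }
  ion_trajectory(species, ion_frames, box = box, times = times, water = water)
}

## ---- spring time series ----------------------------------------------------

#' Construct a pseudo-spring separation time series
#'
#' @param k Spring constant, kJ/(mol nm^2) (the conventional reporting unit;
#'   converted internally to kJ/(mol Angstrom^2)).
#' @param x0 Rest length of the tether, Angstrom.
#' @param time Sample times, ps (strictly increasing).
#' @param x Instantaneous center-of-mass separations, Angstrom.
#' @return Object of class `spring_series`.
#' @export
spring_series <- function(k, x0, time, x) {
  if (!is.finite(k) || k <= 0) stop("spring constant k must be > 0")
  if (length(time) != length(x)) stop("time and x lengths differ")
  if (!length(x)) stop("no samples")
  if (any(diff(time) <= 0)) stop("sample times must be strictly increasing")
  structure(list(k = k, x0 = x0, time = as.numeric(time), x = as.numeric(x)),
            class = "spring_series")
}

#' @export
print.spring_series <- function(x, ...) {
  cat(sprintf("<spring_series> k=%g kJ/(mol nm^2), x0=%g A, %d samples, mean x=%.3f A\n",
              x$k, x$x0, length(x$x), mean(x$x)))
  invisible(x)
}

#' Read a spring-extension series from two-column text
#'
#' Expects `time separation` numeric columns; `#`-prefixed comment lines and
#' blank lines are allowed.  Malformed lines and non-monotone times are
#' rejected with the offending line number.
#'
#' @param path Input path.
#' @param k Spring constant, kJ/(mol nm^2).
#' @param x0 Rest length, Angstrom.
#' @return A `spring_series`.
#' @export
read_spring_series <- function(path, k, x0) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep)) stop("no samples in ", path)
  parts <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  bad <- which(lengths(parts) < 2)
  if (length(bad))
    stop("malformed line ", keep[bad[1]], " in ", path)
  vals <- matrix(suppressWarnings(as.numeric(unlist(lapply(parts, `[`, 1:2)))),
                 ncol = 2, byrow = TRUE)
  nn <- which(!is.finite(vals[, 1]) | !is.finite(vals[, 2]))
  if (length(nn))
    stop("non-numeric value at line ", keep[nn[1]], " in ", path)
  if (any(diff(vals[, 1]) <= 0)) {
    j <- which(diff(vals[, 1]) <= 0)[1]
    stop("non-increasing time at line ", keep[j + 1], " in ", path)
  }
  spring_series(k, x0, vals[, 1], vals[, 2])
}

#' Write a spring series as two-column text
#' @param series A `spring_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spring_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# k_kJ_mol_nm2 %g", series$k),
               sprintf("# x0_A %g", series$x0),
               "# time_ps x_A",
               sprintf("%.6f %.8f", series$time, series$x)), con)
  invisible(path)
}

## ---- OpenDX scalar grids ---------------------------------------------------

#' Write a density grid as an OpenDX scalar field
#'
#' Header layout (fixed): `object 1 class gridpositions counts nx ny nz`,
#' `origin`, three `delta` rows, `object 2 class gridconnections`,
#' `object 3 class array ... data follows`, then values three per line with
#' the z index varying fastest (the OpenDX convention).
#'
#' @param grid A `density_grid` (see [charge_density_grid()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_dx <- function(grid, path) {
  d <- grid$density
  if (any(!is.finite(d))) stop("density grid contains non-finite values")
  n <- dim(d)
  ## stored as [x,y,z]; DX wants z varying fastest on output
  vals <- as.numeric(aperm(d, c(3, 2, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))), con)
  ## three values per line
  nv <- length(vals)
  full <- nv %/% 3
  if (full > 0)
    writeLines(sprintf("%.10g %.10g %.10g",
                       vals[seq(1, by = 3, length.out = full)],
                       vals[seq(2, by = 3, length.out = full)],
                       vals[seq(3, by = 3, length.out = full)]), con)
  rem <- nv - 3 * full
  if (rem > 0)
    writeLines(paste(sprintf("%.10g", vals[(3 * full + 1):nv]),
                     collapse = " "), con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"density\" class field"), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_density_dx()]
#' @param path Input path.
#' @return A `density_grid`.
#' @export
read_density_dx <- function(path) {
  lines <- readLines(path)
  g1 <- grep("class gridpositions counts", lines, value = TRUE)[1]
  counts <- as.integer(strsplit(trimws(sub(".*counts", "", g1)),
                                "[[:space:]]+")[[1]])
  org <- as.numeric(strsplit(trimws(sub("origin", "",
                    grep("^origin", lines, value = TRUE)[1])),
                    "[[:space:]]+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dvals <- lapply(deltas, function(l)
    as.numeric(strsplit(trimws(sub("delta", "", l)), "[[:space:]]+")[[1]]))
  spacing <- dvals[[1]][1]
  istart <- grep("data follows", lines)[1] + 1
  iend <- grep("^attribute", lines)[1] - 1
  if (is.na(iend)) iend <- length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[istart:iend]),
                                     "[[:space:]]+")))
  vals <- vals[is.finite(vals)]
  if (length(vals) != prod(counts))
    stop("DX data length ", length(vals), " != counts product ",
         prod(counts))
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))  # undo z-fastest
  structure(list(origin = org, spacing = spacing, dim = counts,
                 density = arr, n_frames = NA_integer_, species = NA_character_,
                 threshold = 0.02),
            class = "density_grid")
}

## ---- TSV tables with '#' headers -------------------------------------------

#' Write a data frame as TSV with a '#'-prefixed column header
#' @param df Data frame.
#' @param path Output path.
#' @param meta Optional named list written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = " "),
                              "")), con)
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv_table()]
#' @param path Input path.
#' @return Data frame with the stored column names.
#' @export
read_tsv_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (!length(hdr)) stop("no '#' header in ", path)
  cols <- strsplit(sub("^#\\s*", "", lines[max(hdr)]), "\t")[[1]]
  body <- lines[-hdr]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no rows in ", path)
  df <- utils::read.table(text = body, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- cols
  df
}
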