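#' Structure and trajectory containers
#'
#' A `pep_structure` holds an atom table (tibble) plus an `n_atoms x 3`
#' coordinate matrix in Angstrom. A `pep_trajectory` holds the same atom
#' table (the topology, shared by all frames) plus an `n_atoms x 3 x n_frames`
#' coordinate array and a frame interval in picoseconds (metadata only).
#'
#' The atom table columns are: `atom_name`, `element`, `resno` (1-based,
#' taken verbatim from input, never renumbered), `resname` (3-letter code),
#' `chain`, `charge` (e), `lj_sigma` (Angstrom), `lj_epsilon` (kJ/mol),
#' `mass` (Da). Charges and LJ parameters are zero placeholders until
#' [assign_params()] populates them.
#'
#' @param atoms Atom tibble as described above (missing parameter columns are
#'   filled with placeholders).
#' @param xyz Numeric `n x 3` matrix, Angstrom.
#' @return A `pep_structure`.
#' @export
pep_structure <- function(atoms, xyz) {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) < 1) {
    abort("a structure must contain at least one atom",
          class = "coag_validation_error")
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3) {
    abort("coordinate matrix must be n_atoms x 3",
          class = "coag_validation_error")
  }
  if (!all(is.finite(xyz))) {
    abort("all coordinates must be finite", class = "coag_validation_error")
  }
  for (col in c("charge", "lj_sigma", "lj_epsilon")) {
    if (!col %in% names(atoms)) atoms[[col]] <- 0
  }
  if (!"mass" %in% names(atoms)) {
    atoms$mass <- unname(ELEMENT_MASS[atoms$element])
    atoms$mass[is.na(atoms$mass)] <- 12.011
  }
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  structure(list(atoms = atoms, xyz = xyz), class = "pep_structure")
}

#' @rdname pep_structure
#' @param frames Either a list of `n x 3` matrices or an `n x 3 x F` array.
#' @param frame_interval Time between frames, ps (metadata only).
#' @export
pep_trajectory <- function(atoms, frames, frame_interval = NA_real_) {
  atoms <- as_tibble(atoms)
  if (is.list(frames)) {
    frames <- array(unlist(frames),
                    dim = c(nrow(frames[[1]]), 3, length(frames)))
  }
  if (length(dim(frames)) != 3 || dim(frames)[1] != nrow(atoms) ||
      dim(frames)[2] != 3 || dim(frames)[3] < 1) {
    abort("frames must be an n_atoms x 3 x n_frames array with >= 1 frame",
          class = "coag_validation_error")
  }
  if (!all(is.finite(frames))) {
    abort("all coordinates must be finite", class = "coag_validation_error")
  }
  for (col in c("charge", "lj_sigma", "lj_epsilon")) {
    if (!col %in% names(atoms)) atoms[[col]] <- 0
  }
  if (!"mass" %in% names(atoms)) {
    atoms$mass <- unname(ELEMENT_MASS[atoms$element])
    atoms$mass[is.na(atoms$mass)] <- 12.011
  }
  structure(list(atoms = atoms, frames = frames,
                 frame_interval = frame_interval),
            class = "pep_trajectory")
}

#' @export
print.pep_structure <- function(x, ...) {
  cat(sprintf("<pep_structure> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              nrow(distinct(x$atoms, .data$chain, .data$resno)),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' @export
print.pep_trajectory <- function(x, ...) {
  cat(sprintf("<pep_trajectory> %d atoms x %d frames (interval %s ps)\n",
              dim(x$frames)[1], dim(x$frames)[3],
              format(x$frame_interval)))
  invisible(x)
}

n_frames <- function(traj) dim(traj$frames)[3]

frame_xyz <- function(traj, i) matrix(traj$frames[, , i], ncol = 3)

#' Number of frames in a trajectory
#' @param traj A `pep_trajectory`.
#' @export
trajectory_length <- function(traj) n_frames(traj)

# unique residue table in atom order
residue_table <- function(atoms) {
  distinct(atoms, .data$chain, .data$resno, .data$resname)
}

# ---- PDB I/O (bio3d-backed, with contract validation) -----------------------

validate_pdb_lines <- function(lines, path) {
  atom_ln <- grep("^(ATOM  |HETATM)", lines)
  for (ln in atom_ln) {
    l <- lines[ln]
    if (nchar(l) < 54) {
      abort(sprintf("malformed ATOM record at line %d of %s (too short)",
                    ln, path), class = "coag_parse_error")
    }
    coords <- suppressWarnings(as.numeric(
      c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))))
    if (any(is.na(coords))) {
      abort(sprintf("malformed ATOM record at line %d of %s (bad coordinates)",
                    ln, path), class = "coag_parse_error")
    }
    if (substr(l, 17, 17) != " ") {
      abort(sprintf("alternate location indicator at line %d of %s not supported",
                    ln, path), class = "coag_parse_error")
    }
    if (substr(l, 27, 27) != " ") {
      abort(sprintf("insertion code at line %d of %s not supported",
                    ln, path), class = "coag_parse_error")
    }
  }
  # consistent atom counts across MODEL blocks
  model_ln <- grep("^MODEL", lines)
  if (length(model_ln) > 1) {
    endmdl_ln <- grep("^ENDMDL", lines)
    counts <- vapply(seq_along(model_ln), function(i) {
      sum(atom_ln > model_ln[i] & atom_ln < endmdl_ln[i])
    }, integer(1))
    if (length(unique(counts)) != 1) {
      abort(sprintf("inconsistent atom counts across MODEL blocks in %s: %s",
                    path, paste(counts, collapse = ", ")),
            class = "coag_structure_error")
    }
  }
  invisible(length(model_ln))
}

guess_element <- function(atom_name, pdb_elesy = NULL) {
  if (!is.null(pdb_elesy)) {
    e <- toupper(trimws(pdb_elesy))
    ok <- e %in% names(ELEMENT_MASS)
    if (all(ok)) return(e)
  }
  first <- toupper(substr(gsub("^[0-9]", "", trimws(atom_name)), 1, 1))
  first[!first %in% names(ELEMENT_MASS)] <- "C"
  first
}

#' Read a PDB file as a structure or trajectory
#'
#' Single-model files give a [pep_structure()]; with `multi_model = TRUE`,
#' MODEL/ENDMDL blocks (which must share atom ordering) give a
#' [pep_trajectory()]. Residue numbering is taken verbatim from the file.
#' Charges and LJ parameters are zero placeholders until [assign_params()].
#' Alternate locations and insertion codes are rejected.
#'
#' @param path PDB file path.
#' @param multi_model Read MODEL blocks as trajectory frames.
#' @param frame_interval Metadata stored on the trajectory, ps.
#' @return `pep_structure` or `pep_trajectory`.
#' @export
read_pdb <- function(path, multi_model = FALSE, frame_interval = NA_real_) {
  if (!file.exists(path)) {
    abort(sprintf("PDB file not found: %s", path), class = "coag_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  pdb <- bio3d::read.pdb(path, multi = multi_model, verbose = FALSE)
  at <- pdb$atom
  atoms <- tibble(
    atom_name = trimws(at$elety),
    element = guess_element(at$elety, at$elesy),
    resno = as.integer(at$resno),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    charge = 0, lj_sigma = 0, lj_epsilon = 0
  )
  atoms$mass <- unname(ELEMENT_MASS[atoms$element])
  nm <- nrow(pdb$xyz)
  if (multi_model && nm > 1) {
    frames <- array(0, dim = c(nrow(atoms), 3, nm))
    for (f in seq_len(nm)) {
      frames[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    }
    pep_trajectory(atoms, frames, frame_interval = frame_interval)
  } else {
    pep_structure(atoms, matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE))
  }
}

#' Write a structure or trajectory to PDB
#'
#' Round-trips with [read_pdb()]: atom names, residue indices and coordinates
#' (to the PDB's 3-decimal precision) are preserved. Trajectories are written
#' as MODEL/ENDMDL blocks.
#'
#' @param x `pep_structure` or `pep_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "pep_structure")) {
    atoms <- x$atoms
    xyz_mat <- matrix(as.vector(t(x$xyz)), nrow = 1)
  } else if (inherits(x, "pep_trajectory")) {
    atoms <- x$atoms
    xyz_mat <- t(apply(x$frames, 3, function(m) as.vector(t(m))))
    if (n_frames(x) == 1) xyz_mat <- matrix(xyz_mat, nrow = 1)
  } else {
    abort("x must be a pep_structure or pep_trajectory",
          class = "coag_validation_error")
  }
  if (nrow(atoms) < 1) {
    abort("refusing to write an empty atom list", class = "coag_validation_error")
  }
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz_mat,
                     resno = atoms$resno, resid = atoms$resname,
                     eleno = seq_len(nrow(atoms)), elety = atoms$atom_name,
                     chain = atoms$chain, elesy = atoms$element)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("cannot write PDB to %s: %s", path,
                  conditionMessage(ok)), class = "coag_io_error")
  }
  invisible(path)
}

# ---- parameter assignment ---------------------------------------------------

#' Minimal per-atom parameter table
#'
#' The bundled table gives per-atom partial charges for the backbone atoms of
#' all residues (wildcard residue `"*"`) and for the explicit terminal
#' side-chain atoms of the charged residues, such that residue net formal
#' charges are Asp/Glu -1 e, Lys/Arg +1 e and all others 0. LJ parameters use
#' a single type per element. This is deliberately minimal: the package
#' scores and compares interfaces, it does not simulate, so full force-field
#' fidelity is out of scope.
#'
#' @return Tibble with columns `resname`, `atom_name`, `charge`.
#' @export
default_param_table <- function() {
  bb <- tibble(
    resname = "*",
    atom_name = c("N", "H", "CA", "C", "O", "CB"),
    charge = c(-0.35, 0.25, 0.10, 0.55, -0.55, 0.00)
  )
  sc <- tibble(
    resname = c("ASP", "ASP", "GLU", "GLU", "LYS", "ARG", "ARG", "HIS"),
    atom_name = c("OD1", "OD2", "OE1", "OE2", "NZ", "NH1", "NH2", "NE2"),
    charge = c(-0.5, -0.5, -0.5, -0.5, 1.0, 0.5, 0.5, 0.0)
  )
  bind_rows(bb, sc)
}

#' Assign charges and LJ parameters to a structure
#'
#' Populates `charge` from a (residue, atom) lookup table (wildcard residue
#' rows `"*"` match any residue) and `lj_sigma`/`lj_epsilon` from the
#' per-element single-type table. Coordinates and atom ordering are never
#' modified.
#'
#' @param x A `pep_structure` or `pep_trajectory`.
#' @param table Parameter table (see [default_param_table()]).
#' @return `x` with parameters populated.
#' @export
assign_params <- function(x, table = default_param_table()) {
  atoms <- x$atoms
  key_specific <- paste(table$resname, table$atom_name)
  charge <- numeric(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    k1 <- paste(atoms$resname[i], atoms$atom_name[i])
    k2 <- paste("*", atoms$atom_name[i])
    hit <- match(k1, key_specific)
    if (is.na(hit)) hit <- match(k2, key_specific)
    if (is.na(hit)) {
      abort(sprintf("no parameters for atom '%s' of residue %s %d",
                    atoms$atom_name[i], atoms$resname[i], atoms$resno[i]),
            class = "coag_lookup_error")
    }
    charge[i] <- table$charge[hit]
  }
  atoms$charge <- charge
  atoms$lj_sigma <- unname(ELEMENT_LJ_SIGMA[atoms$element])
  atoms$lj_epsilon <- unname(ELEMENT_LJ_EPS[atoms$element])
  if (anyNA(atoms$lj_sigma)) {
    bad <- which(is.na(atoms$lj_sigma))[1]
    abort(sprintf("no LJ parameters for element '%s'", atoms$element[bad]),
          class = "coag_lookup_error")
  }
  x$atoms <- atoms
  x
}

# ---- receptor domain annotation --------------------------------------------

#' Receptor domain annotations
#'
#' `receptor_annotation()` validates a segment table (columns `start`, `end`,
#' `label`) into a `receptor_annotation` object; `read_annotation()` reads it
#' from a TSV file (`start<TAB>end<TAB>label`). Labels follow the class-B GPCR
#' region vocabulary: ECD, TM1-TM7, ECL1-ECL3, ICL1-ICL3, CTR, other.
#' `annotate_residues()` maps residue numbers to labels; residues outside all
#' ranges report `"other"` (the lookup is total).
#'
#' @param segments Data frame with columns `start`, `end`, `label`.
#' @return A `receptor_annotation` (a tibble subclass).
#' @export
receptor_annotation <- function(segments) {
  seg <- as_tibble(segments)
  if (!all(c("start", "end", "label") %in% names(seg))) {
    abort("annotation needs columns start, end, label",
          class = "coag_validation_error")
  }
  seg$start <- as.integer(seg$start)
  seg$end <- as.integer(seg$end)
  if (any(seg$start > seg$end)) {
    abort("annotation ranges must have start <= end",
          class = "coag_validation_error")
  }
  bad <- !seg$label %in% RECEPTOR_DOMAINS
  if (any(bad)) {
    abort(sprintf("unknown domain label(s): %s",
                  paste(unique(seg$label[bad]), collapse = ", ")),
          class = "coag_validation_error")
  }
  seg <- arrange(seg, .data$start)
  if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
    abort("annotation ranges overlap", class = "coag_validation_error")
  }
  class(seg) <- c("receptor_annotation", class(seg))
  seg
}

#' @rdname receptor_annotation
#' @param path TSV file path.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("annotation file not found: %s", path),
          class = "coag_io_error")
  }
  seg <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  receptor_annotation(seg)
}

#' @rdname receptor_annotation
#' @param annotation A `receptor_annotation`.
#' @param resno Integer vector of residue numbers.
#' @export
annotate_residues <- function(annotation, resno) {
  out <- rep("other", length(resno))
  for (i in seq_len(nrow(annotation))) {
    hit <- resno >= annotation$start[i] & resno <= annotation$end[i]
    out[hit] <- annotation$label[i]
  }
  out
}

# ---- small geometry helpers used across modules -----------------------------

pairwise_dist <- function(a, b) {
  # a: n x 3, b: m x 3 -> n x m Euclidean distances
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("zero-length vector", class = "coag_numeric_error")
  v / n
}
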