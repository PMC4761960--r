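# Structure and trajectory file I/O.
#
# PDB is fixed-width and stores Angstrom; GRO stores nm. All in-memory
# coordinates are nm, so the PDB boundary converts A <-> nm (factor 10).
# No topology perception is attempted: bonds, protonation and solvent are
# out of scope.

A_PER_NM <- 10

# Elements recognised during name-based inference. Two-letter symbols are
# matched only when the raw name is left-justified into column 13 (the
# standard PDB rule); nanotube carbons written by the builder carry an
# explicit element column and never rely on inference.
TWO_LETTER_ELEMENTS <- c("CL", "BR", "FE", "ZN", "MG", "NA", "CA", "MN",
                         "CU", "NI", "SE", "SI", "LI", "AL", "CO")

infer_element <- function(raw_name4) {
  # raw_name4: the 4-character atom-name field exactly as read (cols 13-16)
  letters_only <- gsub("[^A-Za-z]", "", raw_name4)
  if (!nzchar(letters_only)) return("")
  first_col_filled <- grepl("^[A-Za-z]", raw_name4)
  if (first_col_filled) {
    cand <- toupper(substr(letters_only, 1, 2))
    if (cand %in% TWO_LETTER_ELEMENTS) return(paste0(substr(cand, 1, 1),
                                                     tolower(substr(cand, 2, 2))))
  }
  toupper(substr(letters_only, 1, 1))
}

parse_pdb_atom_line <- function(line, lineno) {
  if (nchar(line) < 54) {
    stop("malformed PDB ATOM/HETATM record at line ", lineno,
         ": shorter than coordinate fields")
  }
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (any(is.na(xyz))) {
    stop("malformed PDB coordinate field at line ", lineno)
  }
  resid <- suppressWarnings(as.integer(trimws(substr(line, 23, 26))))
  if (is.na(resid)) {
    stop("malformed PDB residue number at line ", lineno)
  }
  raw_name <- substr(line, 13, 16)
  element <- trimws(substr(line, 77, 78))
  if (!nzchar(element)) element <- infer_element(raw_name)
  if (!nzchar(element)) {
    stop("cannot infer element for atom at line ", lineno)
  }
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 2)))
  list(name = trimws(raw_name),
       element = element,
       residue_name = trimws(substr(line, 18, 21)),
       residue_id = resid,
       chain_id = {ch <- substr(line, 22, 22); if (ch == " ") "A" else ch},
       xyz = xyz / A_PER_NM)
}

pdb_lines_to_atoms <- function(lines, linenos) {
  recs <- mapply(parse_pdb_atom_line, lines, linenos, SIMPLIFY = FALSE)
  data.frame(
    name = vapply(recs, `[[`, "", "name"),
    element = vapply(recs, `[[`, "", "element"),
    residue_name = vapply(recs, `[[`, "", "residue_name"),
    residue_id = vapply(recs, `[[`, 1L, "residue_id"),
    chain_id = vapply(recs, `[[`, "", "chain_id"),
    x = vapply(recs, function(r) r$xyz[1], 1.0),
    y = vapply(recs, function(r) r$xyz[2], 1.0),
    z = vapply(recs, function(r) r$xyz[3], 1.0),
    stringsAsFactors = FALSE)
}

read_pdb_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (!any(is_atom)) stop("zero atoms in PDB file '", path, "'")
  # only the first model of a multi-model file defines the structure
  endmdl <- which(grepl("^ENDMDL", lines))
  if (length(endmdl) > 0) is_atom[seq_along(lines) > endmdl[1]] <- FALSE
  atoms <- pdb_lines_to_atoms(lines[is_atom], which(is_atom))
  box <- NULL
  if (length(cryst) > 0) {
    abc <- suppressWarnings(as.numeric(c(substr(cryst[1], 7, 15),
                                         substr(cryst[1], 16, 24),
                                         substr(cryst[1], 25, 33))))
    if (all(is.finite(abc)) && all(abc > 1)) box <- abc / A_PER_NM
  }
  md_structure(atoms, box = box)
}

read_gro_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("zero atoms in GRO file '", path, "'")
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat) || nat < 1) stop("zero atoms in GRO file '", path, "'")
  if (length(lines) < 2 + nat + 1) stop("truncated GRO file '", path, "'")
  atom_lines <- lines[3:(2 + nat)]
  resid <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
  resname <- trimws(substr(atom_lines, 6, 10))
  aname <- trimws(substr(atom_lines, 11, 15))
  xyz <- suppressWarnings(cbind(as.numeric(substr(atom_lines, 21, 28)),
                                as.numeric(substr(atom_lines, 29, 36)),
                                as.numeric(substr(atom_lines, 37, 44))))
  bad <- which(is.na(resid) | is.na(xyz[, 1]) | is.na(xyz[, 2]) | is.na(xyz[, 3]))
  if (length(bad) > 0) stop("malformed GRO atom record at line ", bad[1] + 2L)
  # GRO has no element column; emulate the PDB left-justification rule
  # (short names indent to column 2 so e.g. "CA" reads as alpha-carbon)
  element <- vapply(aname, function(nm) {
    infer_element(if (nchar(nm) <= 3) sprintf(" %-3s", nm) else nm)
  }, "", USE.NAMES = FALSE)
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + nat]),
                                               "\\s+")[[1]]))
  box <- if (length(boxv) >= 3 && all(is.finite(boxv[1:3])) &&
             all(boxv[1:3] > 0)) boxv[1:3] else NULL
  # GRO has no chain column; segment into synthetic chains whenever a
  # residue number is reused with a different residue name
  chain <- character(nat)
  chain_letter <- 1L
  seen <- list()
  for (i in seq_len(nat)) {
    prev <- seen[[as.character(resid[i])]]
    if (!is.null(prev) && prev != resname[i]) {
      chain_letter <- chain_letter + 1L
      seen <- list()
    }
    seen[[as.character(resid[i])]] <- resname[i]
    chain[i] <- LETTERS[chain_letter]
  }
  md_structure(data.frame(name = aname, element = element,
                          residue_name = resname, residue_id = resid,
                          chain_id = chain, x = xyz[, 1], y = xyz[, 2],
                          z = xyz[, 3], stringsAsFactors = FALSE),
               box = box)
}

#' Read a molecular structure from file
#'
#' @param path path to the file.
#' @param format `"pdb"` or `"gro"`; default guesses from the extension.
#' @return an `md_structure` with coordinates in nm (PDB input is converted
#'   from Angstrom).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: '", path, "'")
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  switch(format, pdb = read_pdb_structure(path), gro = read_gro_structure(path))
}

format_pdb_serial <- function(i) {
  # serials beyond the 5-digit field fall back to uppercase hexadecimal
  # (the widespread VMD/hybrid convention); readers here never rely on them
  ifelse(i <= 99999, sprintf("%5d", i), sprintf("%5X", i))
}

pdb_atom_name_field <- function(name, element) {
  # 1-letter elements with short names are indented to column 14
  if (nchar(name) >= 4 || nchar(element) == 2) sprintf("%-4s", name)
  else sprintf(" %-3s", name)
}

structure_to_pdb_lines <- function(structure) {
  a <- structure$atoms
  if (any(nchar(a$residue_name) > 4)) {
    stop("residue name too long for PDB fixed-width columns: '",
         a$residue_name[which(nchar(a$residue_name) > 4)[1]], "'")
  }
  if (any(nchar(a$name) > 4)) {
    stop("atom name too long for PDB fixed-width columns: '",
         a$name[which(nchar(a$name) > 4)[1]], "'")
  }
  n <- nrow(a)
  name_field <- mapply(pdb_atom_name_field, a$name, a$element)
  lines <- sprintf("ATOM  %s %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   format_pdb_serial(seq_len(n)), name_field, a$residue_name,
                   substr(a$chain_id, 1, 1), a$residue_id %% 10000L,
                   a$x * A_PER_NM, a$y * A_PER_NM, a$z * A_PER_NM,
                   1.0, 0.0, toupper(a$element))
  header <- character(0)
  if (!is.null(structure$box)) {
    header <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                      structure$box[1] * A_PER_NM, structure$box[2] * A_PER_NM,
                      structure$box[3] * A_PER_NM, 90, 90, 90)
  }
  c(header, lines)
}

structure_to_gro_lines <- function(structure, title = "nanocyp structure") {
  a <- structure$atoms
  if (any(nchar(a$residue_name) > 5)) {
    stop("residue name too long for GRO fixed-width columns")
  }
  if (any(nchar(a$name) > 5)) stop("atom name too long for GRO fixed-width columns")
  n <- nrow(a)
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   a$residue_id %% 100000L, a$residue_name, a$name,
                   seq_len(n) %% 100000L, a$x, a$y, a$z)
  box <- if (is.null(structure$box)) c(0, 0, 0) else structure$box
  c(title, sprintf("%5d", n), lines,
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
}

#' Write a molecular structure to file
#'
#' Round-tripping through either format preserves coordinates within the
#' fixed-width precision of 1e-3 nm. Over-long atom or residue names are an
#' error, never a silent truncation.
#'
#' @param structure an `md_structure`.
#' @param path output path.
#' @param format `"pdb"` or `"gro"`; default guesses from the extension.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  lines <- switch(format,
                  pdb = c(structure_to_pdb_lines(structure), "END"),
                  gro = structure_to_gro_lines(structure))
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-frame trajectory
#'
#' Multi-model PDB is the supported on-disk trajectory format (frames are
#' MODEL/ENDMDL blocks). PDB carries no time field, so frame times are
#' synthesized as 0, 1, 2, ... ps and flagged via `times_synthesized`.
#' XTC/DCD are binary formats that would need an external reader library
#' and are rejected with an informative error.
#'
#' @param topology an `md_structure` whose atom count every frame must match.
#' @param path path to a multi-model PDB file.
#' @param format `"pdb"` (default), `"xtc"` or `"dcd"`.
#' @return an `md_trajectory`.
#' @export
read_trajectory <- function(topology, path, format = c("pdb", "xtc", "dcd")) {
  format <- match.arg(format)
  if (format %in% c("xtc", "dcd")) {
    stop("trajectory format '", format,
         "' requires an external binary reader library; ",
         "convert to multi-model PDB")
  }
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  model_starts <- which(grepl("^MODEL", lines))
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no frames in trajectory file '", path, "'")
  if (length(model_starts) == 0) {
    frame_of <- rep(1L, sum(is_atom))
    atom_idx <- which(is_atom)
  } else {
    atom_idx <- which(is_atom)
    frame_of <- findInterval(atom_idx, model_starts)
    keep <- frame_of >= 1L
    atom_idx <- atom_idx[keep]
    frame_of <- frame_of[keep]
  }
  na <- n_atoms(topology)
  frames <- vector("list", max(frame_of))
  for (k in seq_len(max(frame_of))) {
    sel <- atom_idx[frame_of == k]
    if (length(sel) != na) {
      stop("atom-count mismatch at frame ", k - 1L, ": topology has ", na,
           " atoms but frame has ", length(sel))
    }
    atoms <- pdb_lines_to_atoms(lines[sel], sel)
    frames[[k]] <- as.matrix(atoms[, c("x", "y", "z")])
  }
  md_trajectory(topology, frames)
}

#' Write a trajectory as multi-model PDB
#'
#' @param trajectory an `md_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  s <- trajectory$topology
  for (k in seq_len(n_frames(trajectory))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(structure_to_pdb_lines(set_coords(s, trajectory$frames[[k]])), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
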