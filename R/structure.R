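# Core domain types: md_structure (static topology + coordinates) and
# md_trajectory (ordered frames consistent with one topology).
#
# Unit conventions, fixed package-wide: coordinates nm, times ps,
# energies kJ/mol, charges in units of the elementary charge e.
# Atom indices are 1-based (R convention); residue_id is preserved as read.

HYDROGEN_ELEMENTS <- c("H", "D", "T")

#' Construct a molecular structure
#'
#' An `md_structure` holds an ordered atom table, an optional periodic box
#' and named atom groups. It is the single static container consumed by
#' every analysis function in the package.
#'
#' @param atoms data.frame with columns `name`, `element`, `residue_name`,
#'   `residue_id`, `chain_id`, `x`, `y`, `z` (nm). Optional column
#'   `formal_charge` (e); defaults to `NA` meaning "not annotated".
#' @param box optional numeric length-3 box vector in nm.
#' @param groups named list of integer atom-index vectors (1-based).
#' @return an object of class `md_structure`.
#' @export
md_structure <- function(atoms, box = NULL, groups = list()) {
  required <- c("name", "element", "residue_name", "residue_id",
                "chain_id", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) < 1) stop("structure must contain at least 1 atom (zero atoms)")
  if (any(!nzchar(atoms$element))) stop("element symbols must be non-empty")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(coords))) stop("atom positions must be finite")
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- NA_real_
  atoms$is_heavy <- !(toupper(atoms$element) %in% HYDROGEN_ELEMENTS)
  atoms$residue_id <- as.integer(atoms$residue_id)
  rownames(atoms) <- NULL
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be 3 positive finite lengths in nm")
    }
  }
  if (length(groups) > 0) {
    if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
      stop("groups must be a named list")
    }
    for (g in names(groups)) {
      idx <- groups[[g]]
      if (any(idx < 1L | idx > nrow(atoms))) {
        stop("group '", g, "' contains invalid atom indices")
      }
      groups[[g]] <- as.integer(idx)
    }
  }
  # residue identity must be consistent: one residue_name per (chain, id)
  key <- paste(atoms$chain_id, atoms$residue_id, sep = "\r")
  rn <- tapply(atoms$residue_name, key, function(v) length(unique(v)))
  if (any(rn > 1)) {
    bad <- names(rn)[rn > 1][1]
    stop("inconsistent residue_name within residue ", gsub("\r", ":", bad))
  }
  structure(list(atoms = atoms, box = box, groups = groups),
            class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat("md_structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain_id, x$atoms$residue_id))), "residues")
  if (!is.null(x$box)) cat(", box", paste(signif(x$box, 4), collapse = " x "), "nm")
  if (length(x$groups) > 0) {
    cat("\ngroups:", paste(sprintf("%s(%d)", names(x$groups),
                                   vapply(x$groups, length, 1L)), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure an `md_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinate matrix of a structure
#' @param structure an `md_structure`.
#' @return n x 3 numeric matrix in nm.
#' @export
coords <- function(structure) {
  unname(as.matrix(structure$atoms[, c("x", "y", "z")]))
}

#' Replace the coordinates of a structure
#' @param structure an `md_structure`.
#' @param xyz n x 3 matrix in nm.
#' @return the modified `md_structure`.
#' @export
set_coords <- function(structure, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atoms(structure) || ncol(xyz) != 3) {
    stop("coordinate matrix must be ", n_atoms(structure), " x 3")
  }
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Merge two structures into one
#'
#' Atom order is first structure then second; groups are re-indexed and a
#' prefix may be applied to disambiguate group names.
#'
#' @param a,b `md_structure` objects.
#' @return merged `md_structure`; groups of `b` are shifted by `n_atoms(a)`.
#' @export
merge_structures <- function(a, b) {
  atoms <- rbind(a$atoms[, union(names(a$atoms), names(b$atoms))],
                 b$atoms[, union(names(a$atoms), names(b$atoms))])
  offset <- n_atoms(a)
  groups <- a$groups
  for (g in names(b$groups)) {
    nm <- if (g %in% names(groups)) paste0(g, ".2") else g
    groups[[nm]] <- b$groups[[g]] + offset
  }
  md_structure(atoms, box = a$box, groups = groups)
}

#' Construct a trajectory
#'
#' An `md_trajectory` couples a static topology with an ordered list of
#' coordinate frames and strictly increasing timestamps in ps.
#'
#' @param topology an `md_structure`.
#' @param frames list of n_atoms x 3 coordinate matrices (nm).
#' @param times numeric vector of frame times in ps, strictly increasing.
#'   When `NULL`, times 0, 1, 2, ... ps are synthesized and flagged.
#' @return an object of class `md_trajectory` with fields `topology`,
#'   `times`, `frames` and `times_synthesized`.
#' @export
md_trajectory <- function(topology, frames, times = NULL) {
  if (!inherits(topology, "md_structure")) stop("topology must be an md_structure")
  if (length(frames) < 1) stop("trajectory must contain at least one frame")
  na <- n_atoms(topology)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!is.matrix(f) || nrow(f) != na || ncol(f) != 3) {
      stop("atom-count mismatch at frame ", k - 1L, ": expected ", na,
           " x 3 coordinates")
    }
  }
  synthesized <- is.null(times)
  if (synthesized) times <- seq_along(frames) - 1
  if (length(times) != length(frames)) stop("times and frames lengths differ")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  structure(list(topology = topology, times = as.numeric(times),
                 frames = lapply(frames, unname),
                 times_synthesized = synthesized),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", length(x$frames), "frames,",
      n_atoms(x$topology), "atoms, t =",
      signif(x$times[1], 4), "...", signif(x$times[length(x$times)], 4), "ps")
  if (x$times_synthesized) cat(" (times synthesized)")
  cat("\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

# internal: Euclidean distance matrix between two coordinate sets (rows)
cross_dist <- function(xa, xb) {
  a2 <- rowSums(xa * xa)
  b2 <- rowSums(xb * xb)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
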