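# Armchair (n,n) single-walled carbon nanotube builder.
#
# Geometry: a graphene sheet with the chiral vector C_h = n(a1+a2) along x
# is wrapped by arc length onto a cylinder. For an armchair tube the
# circumference is |C_h| = 3 n a_cc, the radius R = 3 n a_cc / (2 pi), and
# the diameter equals the closed form (sqrt(3) a_cc / pi) * sqrt(3 n^2).
# Atoms sit in circumferential rings of 2n atoms spaced sqrt(3)/2 a_cc
# apart along the axis; one translational period T = sqrt(3) a_cc holds
# two rings (4n atoms). Wrapping turns C-C bonds into chords, shortening
# them by <0.7% for n = 12; this is the standard builder convention and is
# not corrected.

#' Nanotube build recipe
#'
#' @param n armchair chiral index; the tube is (n, n). Must be >= 2.
#' @param target_length requested tube length in nm.
#' @param cc_bond carbon-carbon bond length in nm (graphene value 0.142).
#' @param carboxyl_count number of edge carboxylates to attach later.
#' @param seed integer seed controlling carboxylation site choice.
#' @return a `nanotube_spec` object.
#' @export
nanotube_spec <- function(n = 12L, target_length = 7.0, cc_bond = 0.142,
                          carboxyl_count = 11L, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("chiral index n must be >= 2")
  if (!is.finite(target_length) || target_length <= 0) {
    stop("target_length must be > 0")
  }
  if (cc_bond <= 0) stop("cc_bond must be > 0")
  if (carboxyl_count < 0) stop("carboxyl_count must be non-negative")
  if (carboxyl_count > 4L * n) {
    stop("carboxyl_count exceeds rim capacity (4n = ", 4L * n,
         " rim carbons on two open ends)")
  }
  structure(list(n = n, target_length = target_length, cc_bond = cc_bond,
                 carboxyl_count = as.integer(carboxyl_count),
                 seed = as.integer(seed)),
            class = "nanotube_spec")
}

#' Closed-form armchair tube diameter
#' @param n chiral index.
#' @param cc_bond C-C bond length in nm.
#' @return diameter in nm, `(sqrt(3) cc_bond / pi) * sqrt(3 n^2)`.
#' @export
armchair_diameter <- function(n, cc_bond = 0.142) {
  (sqrt(3) * cc_bond / pi) * sqrt(3 * n^2)
}

#' Build an armchair single-walled carbon nanotube
#'
#' Generates tube coordinates on a cylinder about the z axis, centered at
#' the origin. The realized length is the whole number of translational
#' periods (T = sqrt(3) cc_bond, 4n atoms each) nearest to
#' `target_length`, so the atom count is always ring-complete; the actual
#' length is reported rather than forced to the request. Deterministic: no
#' randomness is involved.
#'
#' @param spec a `nanotube_spec` (carboxylation is a separate step, see
#'   [carboxylate_edges()]).
#' @return a `built_tube` with fields `structure` (groups `cnt` registered),
#'   `spec`, `actual_length` (nm), `diameter` (nm, measured as twice the
#'   mean radial atom distance), `formal_charge` (e), `hexagons` (matrix of
#'   atom indices, 6 per lattice hexagon) and rim atom indices.
#' @export
build_armchair_swcnt <- function(spec) {
  if (!inherits(spec, "nanotube_spec")) spec <- do.call(nanotube_spec, spec)
  n <- spec$n
  acc <- spec$cc_bond
  period <- sqrt(3) * acc               # translational period T
  if (spec$target_length < period / 2) {
    stop("target_length shorter than one ring spacing (", signif(period / 2, 3),
         " nm)")
  }
  n_cells <- max(1L, as.integer(round(spec$target_length / period)))
  n_rings <- 2L * n_cells
  ring_dz <- period / 2
  circumference <- 3 * n * acc
  radius <- circumference / (2 * pi)

  # sheet coordinates: ring j at height j*ring_dz; within a ring, n motifs
  # of two atoms; even rings at arc offsets {0, acc}, odd at {1.5, 2.5}*acc
  ring <- rep(seq_len(n_rings) - 1L, each = 2L * n)
  k <- rep(rep(seq_len(n) - 1L, each = 2L), n_rings)
  pair <- rep(c(0L, 1L), n * n_rings)
  arc <- ifelse(ring %% 2L == 0L,
                3 * acc * k + acc * pair,
                3 * acc * k + 1.5 * acc + acc * pair)
  theta <- 2 * pi * arc / circumference
  z <- ring * ring_dz
  z <- z - mean(range(z))               # center on origin
  xyz <- cbind(radius * cos(theta), radius * sin(theta), z)

  atoms <- data.frame(
    name = "C", element = "C", residue_name = "CNT", residue_id = 1L,
    chain_id = "T", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    formal_charge = 0, stringsAsFactors = FALSE)
  st <- md_structure(atoms, groups = list(cnt = seq_len(nrow(atoms))))

  hexagons <- armchair_hexagons(n, n_rings, arc, ring, circumference, acc)
  measured_diameter <- 2 * mean(sqrt(xyz[, 1]^2 + xyz[, 2]^2))

  structure(list(
    structure = st, spec = spec,
    actual_length = n_cells * period,
    diameter = measured_diameter,
    formal_charge = 0,
    hexagons = hexagons,
    rim_bottom = which(ring == 0L),
    rim_top = which(ring == n_rings - 1L),
    n_rings = n_rings), class = "built_tube")
}

# Enumerate lattice hexagons in sheet space: centers lie at mid-row heights;
# the 6 vertices are the atoms within ~1 bond length of the center
# (arc coordinate wraps around the circumference).
armchair_hexagons <- function(n, n_rings, arc, ring, circumference, acc) {
  if (n_rings < 3L) return(matrix(integer(0), ncol = 6))
  centers <- list()
  for (m in 1:(n_rings - 2L)) {
    s_off <- if (m %% 2L == 1L) 0.5 * acc else 2.0 * acc
    centers[[m]] <- cbind(3 * acc * (seq_len(n) - 1L) + s_off, m)
  }
  centers <- do.call(rbind, centers)
  hex <- matrix(0L, nrow = nrow(centers), ncol = 6)
  h <- sqrt(3) / 2 * acc
  for (i in seq_len(nrow(centers))) {
    ds <- abs(arc - centers[i, 1])
    ds <- pmin(ds, circumference - ds)   # wraparound
    dz <- (ring - centers[i, 2]) * h
    d2 <- ds^2 + dz^2
    members <- which(d2 < (1.1 * acc)^2)
    if (length(members) != 6L) {
      stop("internal error: hexagon enumeration found ", length(members),
           " vertices")
    }
    hex[i, ] <- members
  }
  hex
}

#' @export
print.built_tube <- function(x, ...) {
  cat(sprintf("built_tube: (%d,%d) armchair, %d atoms, length %.3f nm, diameter %.3f nm, charge %+g e\n",
              x$spec$n, x$spec$n, n_atoms(x$structure), x$actual_length,
              x$diameter, x$formal_charge))
  invisible(x)
}

#' Attach edge carboxylates to a built tube
#'
#' Appends `count` deprotonated carboxyl groups (one sp2 carbon, two
#' equivalent oxygens carrying -0.5 e each) to rim carbons, split as evenly
#' as possible between the two open ends; the odd group (e.g. the 11th)
#' goes to the top rim. Site choice within a rim is a seeded draw, so the
#' result is deterministic given the seed. Carboxylate geometry is
#' idealized: C-C 0.142 nm axially outward, C-O 0.125 nm, O-C-O 124 deg in
#' the axial-radial plane.
#'
#' @param tube a `built_tube`.
#' @param count number of carboxylates; defaults to the spec's
#'   `carboxyl_count`.
#' @param seed integer; defaults to the spec's seed.
#' @return the tube with groups `carboxyl` and `carboxyl_oxygens`
#'   registered and `formal_charge = -count`.
#' @export
carboxylate_edges <- function(tube, count = tube$spec$carboxyl_count,
                              seed = tube$spec$seed) {
  if (!inherits(tube, "built_tube")) stop("tube must be a built_tube")
  if (count < 0) stop("carboxyl count must be non-negative")
  if (count == 0) {
    tube$formal_charge <- 0
    return(tube)
  }
  rim <- list(top = tube$rim_top, bottom = tube$rim_bottom)
  capacity <- length(rim$top) + length(rim$bottom)
  if (count > capacity) {
    stop("rim capacity exceeded: ", count, " carboxyls requested but only ",
         capacity, " rim carbons")
  }
  n_top <- ceiling(count / 2)
  n_bottom <- count - n_top
  rng <- local({set.seed(seed); list(top = sample(rim$top, n_top),
                                     bottom = sample(rim$bottom, n_bottom))})
  sites <- c(sort(rng$top), sort(rng$bottom))
  axial_sign <- c(rep(1, n_top), rep(-1, n_bottom))

  st <- tube$structure
  xyz <- coords(st)
  cc <- 0.142; co <- 0.125; half_oco <- (124 / 2) * pi / 180
  new_atoms <- list()
  next_res <- max(st$atoms$residue_id) + 1L
  for (g in seq_along(sites)) {
    p <- xyz[sites[g], ]
    u_ax <- c(0, 0, axial_sign[g])
    phi <- atan2(p[2], p[1])
    u_rad <- c(cos(phi), sin(phi), 0)
    cpos <- p + cc * u_ax
    o1 <- cpos + co * (cos(half_oco) * u_ax + sin(half_oco) * u_rad)
    o2 <- cpos + co * (cos(half_oco) * u_ax - sin(half_oco) * u_rad)
    new_atoms[[g]] <- data.frame(
      name = c("C", "O1", "O2"), element = c("C", "O", "O"),
      residue_name = "CXL", residue_id = next_res + g - 1L, chain_id = "T",
      x = c(cpos[1], o1[1], o2[1]), y = c(cpos[2], o1[2], o2[2]),
      z = c(cpos[3], o1[3], o2[3]),
      formal_charge = c(0, -0.5, -0.5), stringsAsFactors = FALSE)
  }
  added <- do.call(rbind, new_atoms)
  n0 <- n_atoms(st)
  atoms <- rbind(st$atoms[, names(added)], added)
  new_idx <- n0 + seq_len(nrow(added))
  groups <- st$groups
  groups$carboxyl <- new_idx
  groups$carboxyl_oxygens <- new_idx[added$element == "O"]
  tube$structure <- md_structure(atoms, box = st$box, groups = groups)
  tube$formal_charge <- -count
  tube$carboxyl_sites <- sites
  tube
}

#' Bundled nonbonded parameter table
#'
#' Tube sp2 carbons carry the uncharged Lennard-Jones parameters
#' epsilon = 0.36 kJ/mol, sigma = 0.34 nm. Carboxylate oxygens carry
#' -0.5 e each so every group sums to -1 e. Protein atoms fall back to a
#' deliberately simplified element-keyed row set (group `*`): these are
#' NOT a biomolecular force field, and energies computed with them are
#' comparable to published values in trend only.
#'
#' @return data.frame with columns `group`, `element`, `epsilon` (kJ/mol),
#'   `sigma` (nm), `charge` (e).
#' @export
default_parameter_table <- function() {
  rbind(
    data.frame(group = "cnt", element = "C",
               epsilon = 0.36, sigma = 0.34, charge = 0),
    data.frame(group = "carboxyl", element = c("C", "O"),
               epsilon = c(0.36, 0.50), sigma = c(0.34, 0.296),
               charge = c(0, -0.5)),
    data.frame(group = "*",
               element = c("C", "N", "O", "S", "H", "P"),
               epsilon = c(0.30, 0.70, 0.65, 1.00, 0.10, 0.80),
               sigma   = c(0.340, 0.325, 0.300, 0.355, 0.120, 0.370),
               charge  = c(0, -0.40, -0.40, -0.10, 0.10, 0.40)))
}

#' Assign per-atom nonbonded parameters
#'
#' Each atom is matched by (group, element): membership in the `carboxyl`
#' then `cnt` groups takes precedence; all remaining atoms use the
#' element-keyed fallback rows (group `*`).
#'
#' @param structure an `md_structure`.
#' @param parameter_table table in the format of
#'   [default_parameter_table()].
#' @return a `nonbonded_params` data.frame (one row per atom: `epsilon`
#'   kJ/mol, `sigma` nm, `charge` e).
#' @export
assign_nonbonded_params <- function(structure,
                                    parameter_table = default_parameter_table()) {
  a <- structure$atoms
  n <- nrow(a)
  glabel <- rep("*", n)
  for (g in c("cnt", "carboxyl")) {       # carboxyl applied last -> wins
    if (g %in% names(structure$groups)) glabel[structure$groups[[g]]] <- g
  }
  key <- paste(glabel, toupper(a$element))
  tkey <- paste(parameter_table$group, toupper(parameter_table$element))
  hit <- match(key, tkey)
  if (any(is.na(hit))) {
    bad <- which(is.na(hit))
    stop("no nonbonded parameters for atom(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         " with (group, element) ",
         paste(unique(key[bad]), collapse = "; "))
  }
  out <- data.frame(epsilon = parameter_table$epsilon[hit],
                    sigma = parameter_table$sigma[hit],
                    charge = parameter_table$charge[hit])
  stopifnot(all(out$epsilon >= 0), all(out$sigma > 0))
  class(out) <- c("nonbonded_params", "data.frame")
  out
}

# internal: rotation matrix taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- p - sum(p * a) * a; axis <- axis / sqrt(sum(axis^2))
    return(2 * outer(axis, axis) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Pose a tube against a protein channel mouth
#'
#' Rigidly places the built tube relative to a channel mouth of the
#' protein, then backs it away from the protein along the mouth outward
#' vector in 0.05 nm steps until no inter-body heavy-atom pair is closer
#' than `gap` (at most 100 trial placements). Placement is deterministic.
#'
#' Modes: `sidewall_facing` (tube axis perpendicular to the mouth outward
#' vector, sidewall toward the mouth), `end_on` (axis parallel to the
#' outward vector, rim toward the mouth), `sidewall_and_edge` (sidewall
#' pose translated half a tube length along the axis so one rim is also
#' proximal), `face_3_and_S` (sidewall pose aimed at the supplied channel,
#' intended for the 3/S channel pair).
#'
#' @param protein an `md_structure` with the channel lining resolvable.
#' @param tube a `built_tube`.
#' @param channel a `channel_spec` (see [channel_spec()]).
#' @param mode placement mode, see Details.
#' @param gap minimum inter-body heavy-atom distance in nm; must be > 0.
#' @return merged `md_structure` (protein atoms first); tube groups are
#'   preserved, and a `protein` group covering the protein atoms is added.
#' @export
pose_system <- function(protein, tube, channel,
                        mode = c("sidewall_facing", "end_on",
                                 "sidewall_and_edge", "face_3_and_S"),
                        gap = 1.0) {
  mode <- match.arg(mode)
  if (!is.finite(gap) || gap <= 0) stop("gap must be > 0")
  mouth <- mouth_geometry(coords(protein), protein, channel)
  outward <- mouth$outward

  txyz <- coords(tube$structure)
  if (mode == "end_on") {
    rot <- rotation_between(c(0, 0, 1), -outward)  # bottom rim leads
  } else {
    ref <- if (abs(outward[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    axis_target <- ref - sum(ref * outward) * outward
    axis_target <- axis_target / sqrt(sum(axis_target^2))
    rot <- rotation_between(c(0, 0, 1), axis_target)
  }
  txyz <- txyz %*% t(rot)
  if (mode == "sidewall_and_edge") {
    axis_target <- rot %*% c(0, 0, 1)
    txyz <- sweep(txyz, 2, as.numeric(axis_target) * tube$actual_length / 2,
                  "+")
  }

  pxyz <- coords(protein)
  p_heavy <- pxyz[protein$atoms$is_heavy, , drop = FALSE]
  t_heavy_mask <- tube$structure$atoms$is_heavy
  base <- if (mode == "end_on") tube$actual_length / 2 + gap else
    tube$diameter / 2 + gap
  placed <- NULL
  for (trial in 0:99) {
    shift <- mouth$centroid + outward * (base + 0.05 * trial)
    cand <- sweep(txyz, 2, shift, "+")
    dmin <- min(cross_dist(p_heavy, cand[t_heavy_mask, , drop = FALSE]))
    if (dmin >= gap) { placed <- cand; break }
  }
  if (is.null(placed)) {
    stop("steric clash unresolvable within 100 trial placements")
  }

  prot2 <- protein
  if (!("protein" %in% names(prot2$groups))) {
    prot2$groups$protein <- seq_len(n_atoms(prot2))
  }
  merge_structures(prot2, set_coords(tube$structure, placed))
}
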