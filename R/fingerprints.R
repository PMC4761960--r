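# Interaction fingerprints between a nanotube and a protein: heavy-atom
# contacts, hydrogen bonds, salt bridges and pi-pi stacking, per frame and
# aggregated over a trajectory.
#
# All criteria are geometric and config-exposed; the defaults follow common
# trajectory-analysis practice (0.5 nm heavy-atom contact, 0.35 nm / 150 deg
# hydrogen bond, 0.4 nm N+...O- salt bridge).

#' Contact criteria
#' @param cutoff pair distance cutoff in nm.
#' @param heavy_only count only non-hydrogen atoms.
#' @return a `contact_criteria` list.
#' @export
contact_criteria <- function(cutoff = 0.5, heavy_only = TRUE) {
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, heavy_only = isTRUE(heavy_only)),
            class = "contact_criteria")
}

#' Hydrogen-bond criteria
#' @param da_cutoff donor-acceptor heavy-atom distance cutoff in nm.
#' @param dha_angle_min minimum D-H...A angle in degrees.
#' @return an `hbond_criteria` list.
#' @export
hbond_criteria <- function(da_cutoff = 0.35, dha_angle_min = 150) {
  if (da_cutoff <= 0) stop("da_cutoff must be > 0")
  if (dha_angle_min <= 90 || dha_angle_min > 180) {
    stop("dha_angle_min must be in (90, 180]")
  }
  structure(list(da_cutoff = da_cutoff, dha_angle_min = dha_angle_min),
            class = "hbond_criteria")
}

#' Salt-bridge criteria
#' @param no_cutoff cationic nitrogen to anionic oxygen cutoff in nm.
#' @return a `salt_bridge_criteria` list.
#' @export
salt_bridge_criteria <- function(no_cutoff = 0.4) {
  if (no_cutoff <= 0) stop("no_cutoff must be > 0")
  structure(list(no_cutoff = no_cutoff), class = "salt_bridge_criteria")
}

#' Pi-pi stacking criteria
#'
#' Two mutually exclusive geometric classes relative to the local tube
#' surface: `parallel` (face-to-face: small interplanar angle, short
#' centroid distance, small lateral offset from a lattice hexagon centroid)
#' and `tshape` (edge-to-face: near-perpendicular angle at a slightly
#' longer centroid distance). Ties resolve toward `parallel`.
#'
#' @param parallel_centroid_max,parallel_angle_max,parallel_offset_max
#'   parallel-class gates (nm, degrees, nm).
#' @param tshape_centroid_max,tshape_angle_range T-shape gates (nm, degrees).
#' @return a `stacking_criteria` list.
#' @export
stacking_criteria <- function(parallel_centroid_max = 0.45,
                              parallel_angle_max = 30,
                              parallel_offset_max = 0.20,
                              tshape_centroid_max = 0.55,
                              tshape_angle_range = c(60, 90)) {
  stopifnot(parallel_centroid_max > 0, parallel_offset_max > 0,
            tshape_centroid_max > 0,
            parallel_angle_max >= 0, parallel_angle_max <= 90,
            length(tshape_angle_range) == 2,
            tshape_angle_range[1] >= 0, tshape_angle_range[2] <= 90)
  structure(list(parallel_centroid_max = parallel_centroid_max,
                 parallel_angle_max = parallel_angle_max,
                 parallel_offset_max = parallel_offset_max,
                 tshape_centroid_max = tshape_centroid_max,
                 tshape_angle_range = tshape_angle_range),
            class = "stacking_criteria")
}

# internal: coerce a frame argument (matrix or md_structure) to coordinates
frame_coords <- function(frame) {
  if (inherits(frame, "md_structure")) coords(frame) else as.matrix(frame)
}

#' Count heavy-atom contacts between two selections
#'
#' @param frame n x 3 coordinate matrix in nm (or an `md_structure`).
#' @param structure the `md_structure` providing atom metadata.
#' @param selA,selB disjoint, non-empty `md_selection`s (or index vectors).
#' @param criteria a [contact_criteria()].
#' @return integer number of cross pairs within the cutoff; symmetric in
#'   `selA`/`selB`.
#' @export
contact_count <- function(frame, structure, selA, selB,
                          criteria = contact_criteria()) {
  xyz <- frame_coords(frame)
  ia <- selection_indices(selA)
  ib <- selection_indices(selB)
  if (length(ia) == 0 || length(ib) == 0) stop("empty selection")
  if (length(intersect(ia, ib)) > 0) stop("selections must be disjoint")
  if (criteria$heavy_only) {
    ia <- ia[structure$atoms$is_heavy[ia]]
    ib <- ib[structure$atoms$is_heavy[ib]]
    if (length(ia) == 0 || length(ib) == 0) return(0L)
  }
  d <- cross_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  sum(d <= criteria$cutoff)
}

#' Per-residue contact-ratio table over a trajectory
#'
#' For each probe residue, the fraction of frames with at least one
#' qualifying contact to the partner selection. Rows with fraction > 0.5
#' are flagged persistent (the ">50% of the simulation time" benchmark).
#'
#' @param trajectory an `md_trajectory`.
#' @param probe_residues named list of per-residue `md_selection`s (see
#'   [split_by_residue()]), or one selection that is split by residue.
#' @param partner an `md_selection` (e.g. the carboxyl oxygens).
#' @param criteria a [contact_criteria()].
#' @return data.frame with columns `residue`, `n_frames`,
#'   `frames_in_contact`, `fraction`, `persistent`.
#' @export
contact_ratio_table <- function(trajectory, probe_residues, partner,
                                criteria = contact_criteria()) {
  if (n_frames(trajectory) < 1) stop("empty trajectory")
  st <- trajectory$topology
  if (length(selection_indices(partner)) == 0) stop("empty partner selection")
  if (!is.list(probe_residues) || inherits(probe_residues, "md_selection")) {
    probe_residues <- split_by_residue(st, probe_residues)
  }
  nf <- n_frames(trajectory)
  hits <- vapply(probe_residues, function(sel) {
    sum(vapply(trajectory$frames, function(f) {
      contact_count(f, st, sel, partner, criteria) > 0
    }, NA))
  }, 0L)
  out <- data.frame(residue = names(probe_residues), n_frames = nf,
                    frames_in_contact = as.integer(hits),
                    fraction = as.numeric(hits) / nf,
                    stringsAsFactors = FALSE)
  out$persistent <- out$fraction > 0.5
  rownames(out) <- NULL
  out
}

# internal: resolve the hydrogen attached to each donor heavy atom, by
# explicit map, by name convention (N -> H, NE2 -> HE2, NZ -> HZ*), or by
# proximity within the same residue (<= 0.115 nm)
resolve_donor_hydrogens <- function(frame_xyz, structure, donor_idx,
                                    hydrogen_map = NULL) {
  a <- structure$atoms
  out <- integer(length(donor_idx))
  for (i in seq_along(donor_idx)) {
    d <- donor_idx[i]
    if (!is.null(hydrogen_map) && as.character(d) %in% names(hydrogen_map)) {
      out[i] <- hydrogen_map[[as.character(d)]]
      next
    }
    same_res <- which(a$residue_id == a$residue_id[d] &
                        a$chain_id == a$chain_id[d] &
                        !a$is_heavy)
    if (length(same_res) > 0) {
      expected <- paste0("H", substring(a$name[d], 2))
      by_name <- same_res[a$name[same_res] == expected |
                            a$name[same_res] == paste0(expected, "1")]
      if (length(by_name) >= 1) { out[i] <- by_name[1]; next }
      dd <- cross_dist(frame_xyz[d, , drop = FALSE],
                       frame_xyz[same_res, , drop = FALSE])
      near <- same_res[dd[1, ] <= 0.115]
      if (length(near) >= 1) { out[i] <- near[1]; next }
    }
    stop("donor atom ", d, " (", a$name[d], " in ", a$residue_name[d],
         a$residue_id[d], ") has no resolvable attached hydrogen; ",
         "supply an explicit hydrogen_map")
  }
  out
}

#' Detect hydrogen bonds in one frame
#'
#' Geometric criterion: donor-acceptor distance <= `da_cutoff` and
#' D-H...A angle >= `dha_angle_min`.
#'
#' @param frame coordinate matrix (nm) or `md_structure`.
#' @param structure the topology `md_structure`.
#' @param donors selection of donor heavy atoms (each must have a
#'   resolvable attached hydrogen).
#' @param acceptors selection of acceptor atoms.
#' @param criteria an [hbond_criteria()].
#' @param hydrogen_map optional named vector mapping donor atom index
#'   (as character) to its hydrogen atom index, overriding name/proximity
#'   resolution.
#' @return data.frame with one row per bond: `donor`, `hydrogen`,
#'   `acceptor` atom indices, `distance` (nm), `angle` (degrees).
#' @export
detect_hbonds <- function(frame, structure, donors, acceptors,
                          criteria = hbond_criteria(), hydrogen_map = NULL) {
  xyz <- frame_coords(frame)
  di <- selection_indices(donors)
  ai <- selection_indices(acceptors)
  if (length(di) == 0 || length(ai) == 0) stop("empty selection")
  hi <- resolve_donor_hydrogens(xyz, structure, di, hydrogen_map)
  d <- cross_dist(xyz[di, , drop = FALSE], xyz[ai, , drop = FALSE])
  cand <- which(d <= criteria$da_cutoff, arr.ind = TRUE)
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    id <- di[cand[r, 1]]; ih <- hi[cand[r, 1]]; iacc <- ai[cand[r, 2]]
    if (iacc == id || iacc == ih) next
    v1 <- xyz[id, ] - xyz[ih, ]
    v2 <- xyz[iacc, ] - xyz[ih, ]
    ang <- angle_deg(v1, v2)
    if (ang >= criteria$dha_angle_min) {
      rows[[length(rows) + 1L]] <- data.frame(
        donor = id, hydrogen = ih, acceptor = iacc,
        distance = d[cand[r, 1], cand[r, 2]], angle = ang)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  }
  unique(do.call(rbind, rows))
}

# internal: angle between two vectors in degrees
angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect salt bridges in one frame
#'
#' A bridge is a cationic atom (formal charge > 0, e.g. Lys NZ) within
#' `no_cutoff` of an anionic atom (formal charge < 0, e.g. a carboxylate
#' oxygen). Bridges are reported once per (cation residue, anion residue)
#' pair at the minimum distance. Both selections must carry formal-charge
#' annotations (`formal_charge` column, set by the builders); unannotated
#' atoms are an error, not silently neutral.
#'
#' @param frame coordinate matrix (nm) or `md_structure`.
#' @param structure the topology `md_structure`.
#' @param cations,anions `md_selection`s of charged atoms.
#' @param criteria a [salt_bridge_criteria()].
#' @return data.frame: `cation_residue`, `anion_residue`, `cation_atom`,
#'   `anion_atom`, `distance` (nm).
#' @export
detect_salt_bridges <- function(frame, structure, cations, anions,
                                criteria = salt_bridge_criteria()) {
  xyz <- frame_coords(frame)
  ci <- selection_indices(cations)
  ai <- selection_indices(anions)
  if (length(ci) == 0 || length(ai) == 0) stop("empty selection")
  fc <- structure$atoms$formal_charge
  if (any(is.na(fc[c(ci, ai)]))) {
    stop("selection without charge annotations: set formal_charge on the ",
         "selected atoms")
  }
  ci <- ci[fc[ci] > 0]
  ai <- ai[fc[ai] < 0]
  empty <- data.frame(cation_residue = character(0),
                      anion_residue = character(0),
                      cation_atom = integer(0), anion_atom = integer(0),
                      distance = numeric(0))
  if (length(ci) == 0 || length(ai) == 0) return(empty)
  d <- cross_dist(xyz[ci, , drop = FALSE], xyz[ai, , drop = FALSE])
  hit <- which(d <= criteria$no_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  a <- structure$atoms
  res_label <- function(i) paste0(a$residue_name[i], a$residue_id[i], ":",
                                  a$chain_id[i])
  rows <- data.frame(cation_residue = res_label(ci[hit[, 1]]),
                     anion_residue = res_label(ai[hit[, 2]]),
                     cation_atom = ci[hit[, 1]], anion_atom = ai[hit[, 2]],
                     distance = d[hit], stringsAsFactors = FALSE)
  rows <- rows[order(rows$distance), ]
  rows <- rows[!duplicated(rows[, c("cation_residue", "anion_residue")]), ]
  rows <- rows[order(rows$cation_atom, rows$anion_atom), ]
  rownames(rows) <- NULL
  rows
}

#' Standard aromatic ring atom sets
#'
#' @param structure an `md_structure`.
#' @param selection optional selection restricting the residues considered.
#' @return named list (`"<res><id>:<chain>"`) of ring atom index vectors
#'   for PHE/TYR (6-ring), TRP (6-ring) and HIS (5-ring) residues.
#' @export
aromatic_rings <- function(structure, selection = NULL) {
  ring_names <- list(
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))
  a <- structure$atoms
  idx <- if (is.null(selection)) seq_len(nrow(a)) else
    selection_indices(selection)
  aromatic <- idx[a$residue_name[idx] %in% names(ring_names)]
  key <- paste0(a$residue_name[aromatic], a$residue_id[aromatic], ":",
                a$chain_id[aromatic])
  out <- list()
  for (k in unique(key)) {
    ii <- aromatic[key == k]
    want <- ring_names[[a$residue_name[ii[1]]]]
    ring <- ii[a$name[ii] %in% want]
    if (length(ring) >= 5) out[[k]] <- sort(ring)
  }
  out
}

# internal: best-fit plane normal of >=3 points; error when collinear
ring_plane <- function(pts) {
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  sv <- svd(centered)
  if (sv$d[2] < 1e-8) stop("degenerate (collinear) ring")
  list(centroid = ctr, normal = sv$v[, 3])
}

# internal: tube frame geometry -- axis direction (unit PC1), a point on
# the axis, and per-atom radial unit vectors
tube_frame_geometry <- function(tube_xyz) {
  ctr <- colMeans(tube_xyz)
  centered <- sweep(tube_xyz, 2, ctr)
  axis <- svd(centered)$v[, 1]
  axial <- centered %*% axis
  radial <- centered - axial %*% t(axis)
  rn <- sqrt(rowSums(radial^2))
  rn[rn < 1e-12] <- 1
  list(axis = axis, center = ctr, radial_unit = radial / rn)
}

#' Detect pi-pi stacking events in one frame
#'
#' The tube is treated locally: the reference point is the nearest lattice
#' hexagon centroid and the surface normal is the radial unit vector at the
#' nearest tube atom (a single tangent plane would be wrong on a curved
#' wall). A ring yields at most one event per frame; when both class gates
#' pass, `parallel` wins.
#'
#' @param frame coordinate matrix (nm) or `md_structure`.
#' @param structure topology `md_structure` containing a `cnt` group whose
#'   atom order matches `tube`.
#' @param rings named list of ring atom index vectors (>= 5 atoms each),
#'   e.g. from [aromatic_rings()].
#' @param tube the `built_tube` (provides lattice hexagon membership).
#' @param criteria a [stacking_criteria()].
#' @return data.frame of stack events: `residue`, `ring_centroid_distance`
#'   (nm), `interplanar_angle` (degrees), `lateral_offset` (nm), `class`.
#' @export
detect_pi_stacking <- function(frame, structure, rings, tube,
                               criteria = stacking_criteria()) {
  xyz <- frame_coords(frame)
  if (!("cnt" %in% names(structure$groups))) stop("structure has no cnt group")
  cnt_idx <- structure$groups$cnt
  tube_xyz <- xyz[cnt_idx, , drop = FALSE]
  geom <- tube_frame_geometry(tube_xyz)
  hex <- tube$hexagons
  hex_centroids <- t(vapply(seq_len(nrow(hex)), function(i) {
    colMeans(tube_xyz[hex[i, ], , drop = FALSE])
  }, numeric(3)))

  empty <- data.frame(residue = character(0), ring_centroid_distance = numeric(0),
                      interplanar_angle = numeric(0), lateral_offset = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
  rows <- list()
  for (rname in names(rings)) {
    ring_idx <- rings[[rname]]
    if (length(ring_idx) < 5) stop("ring '", rname, "' has fewer than 5 atoms")
    pl <- ring_plane(xyz[ring_idx, , drop = FALSE])
    dhex <- sqrt(rowSums(sweep(hex_centroids, 2, pl$centroid)^2))
    ih <- which.min(dhex)
    cdist <- dhex[ih]
    datom <- sqrt(rowSums(sweep(tube_xyz, 2, pl$centroid)^2))
    surf_normal <- geom$radial_unit[which.min(datom), ]
    ang <- angle_deg(pl$normal, surf_normal)
    if (ang > 90) ang <- 180 - ang
    sep <- pl$centroid - hex_centroids[ih, ]
    offset <- sqrt(max(0, sum(sep^2) - sum(sep * surf_normal)^2))
    cls <- NA_character_
    if (cdist <= criteria$parallel_centroid_max &&
        ang <= criteria$parallel_angle_max &&
        offset <= criteria$parallel_offset_max) {
      cls <- "parallel"
    } else if (cdist <= criteria$tshape_centroid_max &&
               ang >= criteria$tshape_angle_range[1] &&
               ang <= criteria$tshape_angle_range[2]) {
      cls <- "tshape"
    }
    if (!is.na(cls)) {
      rows[[length(rows) + 1L]] <- data.frame(
        residue = rname, ring_centroid_distance = cdist,
        interplanar_angle = ang, lateral_offset = offset, class = cls,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pi-pi stacking formation ratio of one residue over a trajectory
#'
#' @param trajectory an `md_trajectory` whose topology has a `cnt` group.
#' @param residue residue key as produced by [aromatic_rings()] (e.g.
#'   `"PHE228:A"`), or a residue_id matched among aromatic residues.
#' @param tube the `built_tube`.
#' @param criteria a [stacking_criteria()].
#' @return list with `ratio` (frames with any stack / total frames),
#'   `parallel_ratio`, `tshape_ratio` and the per-frame `events`
#'   data.frame (with a `frame` column, 1-based).
#' @export
stacking_formation_ratio <- function(trajectory, residue, tube,
                                     criteria = stacking_criteria()) {
  st <- trajectory$topology
  rings <- aromatic_rings(st)
  if (length(rings) == 0) stop("no aromatic residues in topology")
  key <- as.character(residue)
  if (!(key %in% names(rings))) {
    hit <- grep(paste0("^[A-Z]+", key, ":"), names(rings), value = TRUE)
    if (length(hit) == 0) {
      stop("residue '", residue, "' is not aromatic or has no ring atoms")
    }
    key <- hit[1]
  }
  rings <- rings[key]
  nf <- n_frames(trajectory)
  per_frame <- lapply(seq_len(nf), function(k) {
    ev <- detect_pi_stacking(trajectory$frames[[k]], st, rings, tube, criteria)
    if (nrow(ev) > 0) ev$frame <- k
    ev
  })
  events <- do.call(rbind, per_frame[vapply(per_frame, nrow, 1L) > 0])
  if (is.null(events)) {
    events <- data.frame(residue = character(0), class = character(0),
                         frame = integer(0))
  }
  list(ratio = length(unique(events$frame)) / nf,
       parallel_ratio = sum(events$class == "parallel") / nf,
       tshape_ratio = sum(events$class == "tshape") / nf,
       events = events)
}
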