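# Seeded synthetic trajectories with exact ground truth.
#
# Events are scripted kinematically: at each frame the relevant rigid piece
# (the tube for channel blocking, one named residue otherwise) is placed
# either in an "on" pose that satisfies the corresponding detector's
# default criteria with a margin of at least 20% of each threshold, or in
# an "off" pose that violates them by far more. Nothing is simulated; the
# ground truth is therefore exact by construction. Seeded Gaussian jitter
# is added afterward. A single seed controls all randomness.

#' Toy protein-like host
#'
#' A rigid pseudo-residue scaffold with named sites mirroring the key
#' residue chemistry of a P450-nanotube encounter: an aromatic residue
#' (PHE 228: full 6-ring), a cationic lysine (LYS 35: NZ, formal charge
#' +1 e), a polar amide donor (GLN 78: NE2-HE2), a backbone donor (GLY 31:
#' N-H) and three channel-mouth lining residues (ids 10-12) whose C-alpha
#' triangle centers the mouth at (1, 0, 0) nm with outward vector +x.
#' A compact 8-atom body around the origin supplies the center of geometry.
#' This is a synthetic stand-in, not any crystal structure.
#'
#' @return an `md_structure` with group `protein` registered.
#' @export
toy_host <- function() {
  rows <- list()
  add <- function(name, element, rname, rid, x, y, z, q = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, residue_name = rname, residue_id = rid,
      chain_id = "A", x = x, y = y, z = z, formal_charge = q,
      stringsAsFactors = FALSE)
  }
  # body: cube of alanine C-alphas around the origin
  corners <- expand.grid(x = c(-0.3, 0.3), y = c(-0.3, 0.3), z = c(-0.3, 0.3))
  for (i in seq_len(nrow(corners))) {
    add("CA", "C", "ALA", i, corners$x[i], corners$y[i], corners$z[i], 0)
  }
  # channel mouth lining (centroid (1,0,0), outward +x)
  add("CA", "C", "LEU", 10L, 1.0, 0.30, 0.00, 0)
  add("CA", "C", "ILE", 11L, 1.0, -0.15, 0.26, 0)
  add("CA", "C", "VAL", 12L, 1.0, -0.15, -0.26, 0)
  # PHE 228: ideal aromatic ring (radius 0.14 nm) + CA, parked far away
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  phi <- (seq_len(6) - 1) * pi / 3
  for (j in seq_len(6)) {
    add(ring_names[j], "C", "PHE", 228L,
        -2.5 + 0.14 * cos(phi[j]), 2.5 + 0.14 * sin(phi[j]), 0, 0)
  }
  add("CA", "C", "PHE", 228L, -2.5, 2.5, 0.25, 0)
  # LYS 35: cationic amine
  add("CA", "C", "LYS", 35L, -2.5, -2.5, 0.15, 0)
  add("NZ", "N", "LYS", 35L, -2.5, -2.5, 0.00, 1)
  # GLN 78: amide donor with explicit hydrogen
  add("CA", "C", "GLN", 78L, 2.5, -2.5, 0.15, 0)
  add("NE2", "N", "GLN", 78L, 2.5, -2.5, 0.00, 0)
  add("HE2", "H", "GLN", 78L, 2.5, -2.5, -0.101, 0)
  # GLY 31: backbone donor
  add("CA", "C", "GLY", 31L, 2.5, 2.5, 0.15, 0)
  add("N", "N", "GLY", 31L, 2.5, 2.5, 0.00, 0)
  add("H", "H", "GLY", 31L, 2.5, 2.5, -0.101, 0)
  atoms <- do.call(rbind, rows)
  md_structure(atoms, groups = list(protein = seq_len(nrow(atoms))))
}

#' Scripted event inside a synthetic scenario
#'
#' @param type one of `stack_parallel`, `stack_tshape`, `salt_bridge`,
#'   `hbond`, `channel_block`.
#' @param start_frame,end_frame half-open 0-based frame range
#'   `[start, end)`; `0 <= start < end <= n_frames`.
#' @param residue target residue_id in the host (ignored for
#'   `channel_block`); defaults per type to PHE 228, LYS 35 and GLN 78.
#' @return a `scenario_event`.
#' @export
scenario_event <- function(type = c("stack_parallel", "stack_tshape",
                                    "salt_bridge", "hbond", "channel_block"),
                           start_frame, end_frame, residue = NULL) {
  type <- match.arg(type)
  if (is.null(residue)) {
    residue <- switch(type, stack_parallel = 228L, stack_tshape = 228L,
                      salt_bridge = 35L, hbond = 78L, channel_block = NA_integer_)
  }
  if (start_frame < 0 || start_frame >= end_frame) {
    stop("event frame range must satisfy 0 <= start < end")
  }
  structure(list(type = type, start_frame = as.integer(start_frame),
                 end_frame = as.integer(end_frame),
                 residue = as.integer(residue)),
            class = "scenario_event")
}

#' Synthetic scenario recipe
#'
#' @param n_frames number of frames.
#' @param frame_spacing ps between frames.
#' @param tube_spec `nanotube_spec` for the small probe tube.
#' @param events list of [scenario_event()]s.
#' @param jitter_sigma per-coordinate Gaussian jitter sd in nm.
#' @param seed integer seed controlling all randomness.
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(n_frames = 100L, frame_spacing = 1000,
                          tube_spec = nanotube_spec(n = 5L, target_length = 2.0,
                                                    carboxyl_count = 2L),
                          events = list(), jitter_sigma = 0, seed = 1L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  for (ev in events) {
    if (!inherits(ev, "scenario_event")) stop("events must be scenario_event objects")
    if (ev$end_frame > n_frames) {
      stop("event range [", ev$start_frame, ", ", ev$end_frame,
           ") exceeds n_frames = ", n_frames)
    }
  }
  # one pose per residue per frame: overlapping events on the same residue
  # are geometrically incompatible
  per_res <- split(events, vapply(events, function(e) {
    if (is.na(e$residue)) "tube" else as.character(e$residue)
  }, ""))
  for (tgt in names(per_res)) {
    evs <- per_res[[tgt]]
    if (length(evs) < 2) next
    occupied <- integer(0)
    for (e in evs) {
      rng <- e$start_frame:(e$end_frame - 1L)
      if (length(intersect(occupied, rng)) > 0) {
        stop("events geometrically incompatible: target '", tgt,
             "' is scripted into two poses simultaneously")
      }
      occupied <- c(occupied, rng)
    }
  }
  structure(list(n_frames = n_frames, frame_spacing = frame_spacing,
                 tube_spec = tube_spec, events = events,
                 jitter_sigma = jitter_sigma, seed = as.integer(seed)),
            class = "scenario_spec")
}

# internal: pose a residue's atoms rigidly so that a chosen local frame
# lands on a target frame. ref/target: list(origin, ex, ey) orthonormal.
place_rigid <- function(xyz, origin_from, rot, origin_to) {
  sweep(sweep(xyz, 2, origin_from) %*% t(rot), 2, origin_to, "+")
}

# internal: on-pose builders; each returns replacement coordinates for the
# residue's atoms given the current full-system coordinates. All group
# indices are in merged-system space; hexagon rows index the cnt group.
synthetic_on_pose <- function(type, res_atoms, system, tube, sys_xyz) {
  a <- system$atoms[res_atoms, , drop = FALSE]
  xyz0 <- as.matrix(a[, c("x", "y", "z")])
  cnt_idx <- system$groups$cnt
  cnt_xyz <- sys_xyz[cnt_idx, , drop = FALSE]
  geom <- tube_frame_geometry(cnt_xyz)
  if (type %in% c("stack_parallel", "stack_tshape")) {
    # reference hexagon: the one whose centroid is most +y and mid-height
    hex_c <- t(vapply(seq_len(nrow(tube$hexagons)), function(i) {
      colMeans(cnt_xyz[tube$hexagons[i, ], , drop = FALSE])
    }, numeric(3)))
    rel <- sweep(hex_c, 2, geom$center)
    ax <- rel %*% geom$axis
    score <- hex_c[, 2] - 2 * abs(ax)
    ih <- which.max(score)
    hc <- hex_c[ih, ]
    datom <- sqrt(rowSums(sweep(cnt_xyz, 2, hc)^2))
    # surface normal: radial unit vector near the hexagon
    nrm <- geom$radial_unit[which.min(datom), ]
    ring_rows <- which(a$name %in% c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))
    ring0 <- xyz0[ring_rows, , drop = FALSE]
    c0 <- colMeans(ring0)
    n0 <- ring_plane(ring0)$normal
    if (type == "stack_parallel") {
      target_c <- hc + 0.35 * nrm          # <= 0.8 * 0.45 centroid gate
      target_n <- nrm                      # angle 0, offset 0
    } else {
      target_c <- hc + 0.40 * nrm          # inside the 0.55 tshape gate
      tang <- geom$axis - sum(geom$axis * nrm) * nrm
      tang <- tang / sqrt(sum(tang^2))
      ang <- 80 * pi / 180                 # >= 1.2 * 60 deg angle gate
      target_n <- cos(ang) * nrm + sin(ang) * tang
    }
    rot <- rotation_between(n0, target_n)
    return(place_rigid(xyz0, c0, rot, target_c))
  }
  oxy <- system$groups$carboxyl_oxygens
  car <- system$groups$carboxyl
  if (length(oxy) < 2) stop("scenario tube needs at least one carboxylate")
  if (type == "salt_bridge") {
    o <- sys_xyz[oxy[1], ]
    cpar <- sys_xyz[car[1], ]              # carboxyl carbon of group 1
    dir <- o - cpar; dir <- dir / sqrt(sum(dir^2))
    nz <- which(a$name == "NZ")
    target <- o + 0.28 * dir               # <= 0.8 * 0.4 nm N+...O- gate
    return(place_rigid(xyz0, xyz0[nz, ], diag(3), target))
  }
  if (type == "hbond") {
    o <- sys_xyz[oxy[length(oxy)], ]       # a different oxygen than the bridge
    cpar <- sys_xyz[car[length(car) - 2L], ]
    dir <- o - cpar; dir <- dir / sqrt(sum(dir^2))
    dn <- which(a$element == "N")
    hn <- which(a$element == "H")
    if (length(dn) != 1 || length(hn) != 1) {
      stop("hbond event residue must have exactly one N-H donor")
    }
    # linear D-H...A: N at 0.28 nm (<= 0.8 * 0.35), H on the N-O axis
    d0 <- xyz0[dn, ]; h0 <- xyz0[hn, ]
    rot <- rotation_between(h0 - d0, -dir)
    placed <- place_rigid(xyz0, d0, rot, o + 0.28 * dir)
    return(placed)
  }
  stop("unknown event type ", type)
}

#' Generate a synthetic trajectory with ground truth
#'
#' Builds the toy host and a small carboxylated tube, merges them, scripts
#' the requested events and applies seeded Gaussian jitter. The same seed
#' always yields bit-identical coordinates.
#'
#' @param spec a [scenario_spec()].
#' @return list with `trajectory` (`md_trajectory`), `truth`
#'   (`ground_truth`), `system` (merged `md_structure`), `tube`
#'   (`built_tube` whose group indices refer to the merged system),
#'   `channel` (the scripted mouth as a [channel_spec()]) and `params`
#'   (nonbonded table for the merged system).
#' @export
generate_scenario <- function(spec) {
  if (!inherits(spec, "scenario_spec")) stop("spec must be a scenario_spec")
  host <- toy_host()
  tube <- build_armchair_swcnt(spec$tube_spec)
  tube <- carboxylate_edges(tube, spec$tube_spec$carboxyl_count,
                            seed = spec$seed)
  n_host <- n_atoms(host)
  system <- merge_structures(host, tube$structure)
  # re-point tube group indices at the merged system
  tube$structure <- system
  for (g in c("rim_top", "rim_bottom")) tube[[g]] <- tube[[g]] + n_host
  tube$hexagons <- tube$hexagons   # local to cnt order, unchanged

  channel <- channel_spec("2e",
                          "residue_id == 10 or residue_id == 11 or residue_id == 12",
                          block_distance = 0.7)
  mouth_centroid <- c(1, 0, 0)
  tube_radius <- tube$diameter / 2

  cnt_rel <- seq(n_host + 1L, n_atoms(system))  # all tube atoms in system
  base_xyz <- coords(system)
  tube_xyz0 <- base_xyz[cnt_rel, , drop = FALSE]
  # far pose: tube axis along z, center at (4, 0, 0)
  far_shift <- c(4, 0, 0)
  # blocked pose: nearest wall atom 0.42 nm (= 0.6 * block_distance) from
  # the mouth centroid
  near_shift <- mouth_centroid + c(tube_radius + 0.42, 0, 0)

  events <- spec$events
  ev_frames <- function(e) (e$start_frame + 1L):e$end_frame  # 1-based
  block_flags <- rep(FALSE, spec$n_frames)
  for (e in events) {
    if (e$type == "channel_block") block_flags[ev_frames(e)] <- TRUE
  }
  res_events <- Filter(function(e) e$type != "channel_block", events)

  res_atom_idx <- function(rid) which(system$atoms$residue_id == rid &
                                        system$atoms$chain_id == "A")

  set.seed(spec$seed)
  frames <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    xyz <- base_xyz
    shift <- if (block_flags[k]) near_shift else far_shift
    tube_now <- sweep(tube_xyz0, 2, shift, "+")
    xyz[cnt_rel, ] <- tube_now
    for (e in res_events) {
      if (k >= e$start_frame + 1L && k <= e$end_frame) {
        ridx <- res_atom_idx(e$residue)
        xyz[ridx, ] <- synthetic_on_pose(e$type, ridx, system, tube, xyz)
      }
    }
    if (spec$jitter_sigma > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$jitter_sigma),
                          ncol = 3)
    }
    frames[[k]] <- xyz
  }
  trajectory <- md_trajectory(system, frames,
                              times = (seq_len(spec$n_frames) - 1) *
                                spec$frame_spacing)

  onset_frame <- NA_integer_
  if (any(block_flags) && block_flags[spec$n_frames]) {
    runs <- rle(block_flags)
    onset_frame <- spec$n_frames - runs$lengths[length(runs$lengths)]  # 0-based
  }
  ratios <- list()
  for (e in res_events) {
    key <- as.character(e$residue)
    ratios[[key]] <- (ratios[[key]] %||% 0) +
      (e$end_frame - e$start_frame) / spec$n_frames
  }
  truth <- structure(list(
    spec = spec,
    events = lapply(events, unclass),
    block_flags = block_flags,
    blocking_onset_frame = onset_frame,
    blocking_onset_ns = if (is.na(onset_frame)) NA_real_ else
      onset_frame * spec$frame_spacing / 1000,
    blocked_fraction = mean(block_flags),
    formation_ratios = ratios), class = "ground_truth")

  list(trajectory = trajectory, truth = truth, system = system, tube = tube,
       channel = channel,
       params = assign_nonbonded_params(system))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run all detectors against a generated scenario
#'
#' Convenience wrapper producing the quantities that [recovery_report()]
#' compares against ground truth.
#'
#' @param scenario output of [generate_scenario()].
#' @param persistence persistence for [blocking_onset()].
#' @return list with `blocking` (a `blocking_profile`),
#'   `blocking_onset_frame` (0-based or `NA`), `formation_ratios` (named by
#'   residue_id), and per-frame `salt_bridge_frames` / `hbond_frames`.
#' @export
analyze_scenario <- function(scenario, persistence = 1.0) {
  traj <- scenario$trajectory
  st <- traj$topology
  cnt_sel <- resolve_selection(st, "group == cnt")
  prof <- blocking_onset(traj, scenario$channel, cnt_sel,
                         persistence = persistence, run_id = "synthetic")
  dt_ns <- scenario$truth$spec$frame_spacing / 1000
  onset_frame <- if (is.na(prof$onset)) NA_integer_ else
    as.integer(round(prof$onset / dt_ns))

  ratios <- list()
  res_events <- Filter(function(e) e$type != "channel_block",
                       scenario$truth$spec$events)
  for (rid in unique(vapply(res_events, `[[`, 1L, "residue"))) {
    rname <- st$atoms$residue_name[which(st$atoms$residue_id == rid &
                                           st$atoms$chain_id == "A")][1]
    if (rname %in% c("PHE", "TYR", "TRP", "HIS")) {
      sfr <- stacking_formation_ratio(traj, rid, scenario$tube)
      ratios[[as.character(rid)]] <- sfr$ratio
    } else if (rname == "LYS") {
      cat_sel <- selection_from_indices(st, which(st$atoms$residue_id == rid &
                                                    st$atoms$element == "N"))
      ani_sel <- resolve_selection(st, "group == carboxyl_oxygens")
      hits <- vapply(traj$frames, function(f) {
        nrow(detect_salt_bridges(f, st, cat_sel, ani_sel)) > 0
      }, NA)
      ratios[[as.character(rid)]] <- mean(hits)
    } else {
      don_sel <- selection_from_indices(st, which(st$atoms$residue_id == rid &
                                                    st$atoms$element == "N"))
      acc_sel <- resolve_selection(st, "group == carboxyl_oxygens")
      hits <- vapply(traj$frames, function(f) {
        nrow(detect_hbonds(f, st, don_sel, acc_sel)) > 0
      }, NA)
      ratios[[as.character(rid)]] <- mean(hits)
    }
  }
  list(blocking = prof, blocking_onset_frame = onset_frame,
       blocked_fraction = prof$blocked_fraction,
       formation_ratios = ratios)
}

#' Compare detector output against scenario ground truth
#'
#' @param truth `ground_truth` from [generate_scenario()].
#' @param detected output of [analyze_scenario()].
#' @param onset_tolerance_frames allowed absolute onset error in frames.
#' @param ratio_tolerance allowed absolute error on formation ratios.
#' @return data.frame `(quantity, true, detected, abs_error, pass)`; the
#'   attribute `exit_status` is 0 when every row passes, 1 otherwise.
#' @export
recovery_report <- function(truth, detected, onset_tolerance_frames = 0,
                            ratio_tolerance = 0) {
  rows <- list()
  t_on <- truth$blocking_onset_frame
  d_on <- detected$blocking_onset_frame
  onset_err <- if (is.na(t_on) && is.na(d_on)) 0 else
    if (is.na(t_on) || is.na(d_on)) Inf else abs(t_on - d_on)
  rows[[1]] <- data.frame(quantity = "blocking_onset_frame",
                          true = as.numeric(t_on), detected = as.numeric(d_on),
                          abs_error = onset_err,
                          pass = onset_err <= onset_tolerance_frames)
  rows[[2]] <- data.frame(quantity = "blocked_fraction",
                          true = truth$blocked_fraction,
                          detected = detected$blocked_fraction,
                          abs_error = abs(truth$blocked_fraction -
                                            detected$blocked_fraction),
                          pass = abs(truth$blocked_fraction -
                                       detected$blocked_fraction) <=
                            ratio_tolerance + 1e-12)
  for (key in names(truth$formation_ratios)) {
    tv <- truth$formation_ratios[[key]]
    dv <- detected$formation_ratios[[key]] %||% NA_real_
    err <- abs(tv - dv)
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = paste0("formation_ratio_", key), true = tv, detected = dv,
      abs_error = err, pass = !is.na(err) && err <= ratio_tolerance + 1e-12)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exit_status") <- if (all(out$pass)) 0L else 1L
  out
}
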