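# Substrate-channel occlusion: channel mouth geometry, per-frame blocked
# status, persistent blocking onset per run, and the pooled blocked-time
# fraction across runs.
#
# "Blocked" is operationalized as a minimum-distance criterion: the channel
# mouth (mean C-alpha of the lining residues) is occluded when any tube
# heavy atom comes within `block_distance` of it. Lining residue sets are
# configuration, not hard-coded truth.

#' Channel mouth definition
#'
#' @param id channel name, conventionally one of `2a, 2b, 2c, 2e, 3, S`.
#' @param lining_residues selection expression resolving the residues that
#'   line the mouth (at least 3 residues must resolve).
#' @param mouth_radius nominal mouth radius in nm (bookkeeping for the
#'   probe-disc criterion stub; the default min-distance criterion does not
#'   use it).
#' @param block_distance tube-heavy-atom-to-centroid distance (nm) at or
#'   under which the mouth counts as blocked.
#' @return a `channel_spec`.
#' @export
channel_spec <- function(id, lining_residues, mouth_radius = 0.35,
                         block_distance = 0.7) {
  if (mouth_radius <= 0 || block_distance <= 0) stop("radii must be > 0")
  structure(list(id = as.character(id), lining_residues = lining_residues,
                 mouth_radius = mouth_radius, block_distance = block_distance),
            class = "channel_spec")
}

#' Channel mouth centroid and outward vector
#'
#' @param frame coordinate matrix (nm) or `md_structure`.
#' @param protein `md_structure` against which lining residues resolve.
#' @param channel a [channel_spec()].
#' @return list with `centroid` (mean lining C-alpha position, nm) and
#'   `outward` (unit vector from the protein center of geometry through the
#'   centroid).
#' @export
mouth_geometry <- function(frame, protein, channel) {
  xyz <- frame_coords(frame)
  sel <- resolve_selection(protein, channel$lining_residues)
  idx <- sel$resolved
  if (length(idx) == 0) stop("channel '", channel$id,
                             "' lining selection resolves to no atoms")
  a <- protein$atoms
  ca <- idx[a$name[idx] == "CA"]
  if (length(ca) == 0) ca <- idx   # fall back to all lining atoms
  nres <- length(unique(paste(a$chain_id[ca], a$residue_id[ca])))
  if (nres < 3) {
    stop("channel '", channel$id, "' needs >= 3 lining residues, got ", nres)
  }
  centroid <- colMeans(xyz[ca, , drop = FALSE])
  prot_idx <- if ("protein" %in% names(protein$groups)) {
    protein$groups$protein
  } else seq_len(n_atoms(protein))
  cog <- colMeans(xyz[prot_idx, , drop = FALSE])
  v <- centroid - cog
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("mouth centroid coincides with protein center; ",
                      "outward vector undefined")
  list(centroid = centroid, outward = v / nv)
}

#' Per-frame blocked status of a channel mouth
#'
#' @param frame coordinate matrix (nm) or `md_structure`.
#' @param structure topology `md_structure` (protein + tube).
#' @param channel a [channel_spec()].
#' @param tube_atoms selection of tube atoms.
#' @return `TRUE` iff the minimum distance from any tube heavy atom to the
#'   mouth centroid is <= `channel$block_distance`.
#' @export
is_blocked <- function(frame, structure, channel, tube_atoms) {
  xyz <- frame_coords(frame)
  ti <- selection_indices(tube_atoms)
  if (length(ti) == 0) stop("empty tube selection")
  ti <- ti[structure$atoms$is_heavy[ti]]
  mouth <- mouth_geometry(xyz, structure, channel)
  dmin <- min(sqrt(rowSums(sweep(xyz[ti, , drop = FALSE], 2,
                                 mouth$centroid)^2)))
  dmin <= channel$block_distance
}

#' Construct a blocking profile directly from onset and duration
#'
#' Used when per-run onsets and durations are known (e.g. quoted run
#' summaries) rather than recomputed from frames; blocking is assumed to
#' persist from onset to the end of the run.
#'
#' @param run_id run label.
#' @param duration run length in ns.
#' @param onset blocking onset in ns, or `NA` for never blocked.
#' @return a `blocking_profile`.
#' @export
blocking_profile <- function(run_id, duration, onset = NA_real_) {
  if (duration <= 0) stop("duration must be > 0")
  if (!is.na(onset) && (onset < 0 || onset > duration)) {
    stop("onset must lie within [0, duration]")
  }
  blocked_fraction <- if (is.na(onset)) 0 else (duration - onset) / duration
  structure(list(run_id = as.character(run_id), duration = duration,
                 onset = onset, blocked_fraction = blocked_fraction,
                 per_frame_flags = NULL, times_ns = NULL),
            class = "blocking_profile")
}

#' @export
print.blocking_profile <- function(x, ...) {
  cat(sprintf("blocking_profile '%s': duration %.4g ns, onset %s, blocked %.1f%%\n",
              x$run_id, x$duration,
              if (is.na(x$onset)) "none" else sprintf("%.4g ns", x$onset),
              100 * x$blocked_fraction))
  invisible(x)
}

#' Persistent blocking onset of a run
#'
#' The onset is the earliest frame time `t` such that the fraction of
#' blocked frames in `[t, end]` is at least `persistence`; `NA` when no
#' such time exists. With the default `persistence = 1` this is the start
#' of the final uninterrupted blocked stretch reaching the end of the run
#' ("remained unchanged until the end").
#'
#' @param trajectory an `md_trajectory` (times in ps).
#' @param channel a [channel_spec()].
#' @param tube_atoms selection of tube atoms.
#' @param persistence required blocked fraction in `[t, end]`, in (0, 1].
#' @param run_id label stored in the profile.
#' @return a `blocking_profile` with `onset` and `duration` in ns,
#'   `blocked_fraction` = blocked frames / total frames, and the per-frame
#'   flag series.
#' @export
blocking_onset <- function(trajectory, channel, tube_atoms, persistence = 1.0,
                           run_id = "run") {
  if (persistence <= 0 || persistence > 1) stop("persistence must be in (0, 1]")
  if (n_frames(trajectory) < 1) stop("empty trajectory")
  st <- trajectory$topology
  flags <- vapply(trajectory$frames, function(f) {
    is_blocked(f, st, channel, tube_atoms)
  }, NA)
  nf <- length(flags)
  # earliest index whose suffix satisfies the persistence requirement
  suffix_blocked <- rev(cumsum(rev(flags)))
  suffix_n <- nf - seq_len(nf) + 1
  ok <- which(flags & (suffix_blocked / suffix_n >= persistence))
  times_ns <- trajectory$times / 1000
  dt <- if (nf > 1) stats::median(diff(times_ns)) else 1
  onset <- if (length(ok) > 0) times_ns[ok[1]] - times_ns[1] else NA_real_
  profile <- blocking_profile(run_id,
                              duration = times_ns[nf] - times_ns[1] + dt,
                              onset = onset)
  profile$blocked_fraction <- mean(flags)
  profile$per_frame_flags <- flags
  profile$times_ns <- times_ns
  profile
}

#' Pool blocked-time fractions across runs
#'
#' @param profiles list of `blocking_profile`s.
#' @return a `pooled_blocking` with `pooled_fraction` = total blocked time /
#'   total duration and `pooled_percent`.
#' @export
pool_blocked_fraction <- function(profiles) {
  if (length(profiles) == 0) stop("no blocking profiles to pool")
  if (inherits(profiles, "blocking_profile")) profiles <- list(profiles)
  durations <- vapply(profiles, `[[`, 1.0, "duration")
  if (any(durations <= 0)) stop("durations must be > 0")
  blocked <- vapply(profiles, function(p) p$blocked_fraction * p$duration, 1.0)
  frac <- sum(blocked) / sum(durations)
  structure(list(profiles = profiles, pooled_fraction = frac,
                 pooled_percent = 100 * frac),
            class = "pooled_blocking")
}

#' @export
print.pooled_blocking <- function(x, ...) {
  cat(sprintf("pooled_blocking: %d run(s), blocked %.2f%% of total time\n",
              length(x$profiles), x$pooled_percent))
  invisible(x)
}
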