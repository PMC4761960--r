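# Config-driven orchestration: read a topology and one or more trajectory
# runs, resolve selections, run every fingerprint/occlusion/energetics
# analysis, pool channel statistics across runs, and emit a deterministic
# machine-readable report (JSON) plus tabular series (TSV).
#
# The config is a single JSON document; every criteria block is optional
# and defaulted, and the effective (defaulted) values are echoed in the
# report so any figure is regenerable from the report alone.

default_analysis_config <- function() {
  list(
    topology = NULL, topology_format = "auto",
    runs = list(),                      # list of {id, trajectory}
    selections = list(protein = "group == protein",
                      tube = "group == cnt",
                      carboxyl = "group == carboxyl_oxygens"),
    channels = list(),                  # list of {id, lining_residues, ...}
    criteria = list(contact = list(cutoff = 0.5, heavy_only = TRUE),
                    hbond = list(da_cutoff = 0.35, dha_angle_min = 150),
                    salt_bridge = list(no_cutoff = 0.4),
                    stacking = list(parallel_centroid_max = 0.45,
                                    parallel_angle_max = 30,
                                    parallel_offset_max = 0.20,
                                    tshape_centroid_max = 0.55,
                                    tshape_angle_range = c(60, 90))),
    energy = list(cutoff = 1.0),
    frame_spacing_ps = NULL,            # overrides synthesized frame times
    rmsd = list(selection = "name == CA", reference = 1),
    persistence = 1.0,
    tube = NULL,                        # optional nanotube_spec fields
    output_dir = NULL,
    seed = 1)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load an analysis config
#'
#' @param path JSON config file, or a list already in config shape.
#' @return full config with defaults filled in.
#' @export
load_analysis_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: '", path, "'")
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else path
  merge_config(default_analysis_config(), user)
}

# internal: register config selections as groups on a bare topology
register_config_groups <- function(topology, config) {
  for (g in c("protein", "cnt", "carboxyl")) {
    expr <- switch(g, protein = config$selections$protein,
                   cnt = config$selections$tube,
                   carboxyl = config$selections$carboxyl)
    if (g %in% names(topology$groups) || is.null(expr)) next
    # expressions may reference groups that do not exist yet; fall back to
    # structural predicates
    idx <- tryCatch(resolve_selection(topology, expr)$resolved,
                    error = function(e) integer(0))
    if (length(idx) > 0) topology$groups[[g]] <- idx
  }
  if (!("cnt" %in% names(topology$groups))) {
    idx <- resolve_selection(topology, "residue_name == CNT")$resolved
    if (length(idx) > 0) topology$groups$cnt <- idx
  }
  if (!("carboxyl" %in% names(topology$groups))) {
    idx <- resolve_selection(topology, "residue_name == CXL")$resolved
    if (length(idx) > 0) {
      topology$groups$carboxyl <- idx
      topology$groups$carboxyl_oxygens <-
        idx[topology$atoms$element[idx] == "O"]
    }
  }
  if (!("protein" %in% names(topology$groups))) {
    idx <- setdiff(seq_len(n_atoms(topology)),
                   c(topology$groups$cnt, topology$groups$carboxyl))
    if (length(idx) > 0) topology$groups$protein <- idx
  }
  topology
}

analyze_one_run <- function(run, topology, config, tube, crit) {
  traj <- if (inherits(run$trajectory, "md_trajectory")) run$trajectory else {
    if (!file.exists(run$trajectory)) {
      stop("run '", run$id, "': trajectory file not found: '",
           run$trajectory, "'")
    }
    read_trajectory(topology, run$trajectory)
  }
  traj$topology <- topology
  if (traj$times_synthesized && !is.null(config$frame_spacing_ps)) {
    traj$times <- (seq_len(n_frames(traj)) - 1) * config$frame_spacing_ps
  }
  st <- topology
  prot <- selection_from_indices(st, st$groups$protein, "group == protein")
  cnt <- selection_from_indices(st, st$groups$cnt, "group == cnt")
  oxy_idx <- st$groups$carboxyl_oxygens %||% st$groups$carboxyl
  params <- assign_nonbonded_params(st)

  nf <- n_frames(traj)
  contacts <- integer(nf); hbonds <- integer(nf); bridges <- integer(nf)
  stacks <- integer(nf)
  rings <- aromatic_rings(st, prot)
  a <- st$atoms
  don_idx <- which(seq_len(nrow(a)) %in% prot$resolved & a$element == "N" &
                     vapply(seq_len(nrow(a)), function(i) {
                       any(a$residue_id == a$residue_id[i] &
                             a$chain_id == a$chain_id[i] & !a$is_heavy)
                     }, NA))
  cat_idx <- which(seq_len(nrow(a)) %in% prot$resolved &
                     !is.na(a$formal_charge) & a$formal_charge > 0)
  for (k in seq_len(nf)) {
    f <- traj$frames[[k]]
    contacts[k] <- contact_count(f, st, prot, cnt, crit$contact)
    if (length(don_idx) > 0 && length(oxy_idx) > 0) {
      hbonds[k] <- nrow(detect_hbonds(f, st,
                                      selection_from_indices(st, don_idx),
                                      selection_from_indices(st, oxy_idx),
                                      crit$hbond))
    }
    if (length(cat_idx) > 0 && length(oxy_idx) > 0) {
      bridges[k] <- nrow(detect_salt_bridges(f, st,
                                             selection_from_indices(st, cat_idx),
                                             selection_from_indices(st, oxy_idx),
                                             crit$salt_bridge))
    }
    if (!is.null(tube) && length(rings) > 0) {
      stacks[k] <- nrow(detect_pi_stacking(f, st, rings, tube, crit$stacking))
    }
  }
  series <- data.frame(frame = seq_len(nf) - 1L, time_ps = traj$times,
                       contacts = contacts, hbonds = hbonds,
                       salt_bridges = bridges, stacks = stacks)

  ratio_tab <- if (length(oxy_idx) > 0) {
    basic_polar <- which(seq_len(nrow(a)) %in% prot$resolved &
                           a$residue_name %in% c("LYS", "ARG", "HIS", "GLN",
                                                 "SER", "ASN", "GLY"))
    if (length(basic_polar) > 0) {
      contact_ratio_table(traj, selection_from_indices(st, basic_polar),
                          selection_from_indices(st, oxy_idx), crit$contact)
    } else NULL
  } else NULL

  stacking_ratios <- list()
  if (!is.null(tube)) {
    for (key in names(rings)) {
      sfr <- stacking_formation_ratio(traj,
                                      sub(":.*$", "", sub("^[A-Z]+", "", key)),
                                      tube, crit$stacking)
      stacking_ratios[[key]] <- list(ratio = sfr$ratio,
                                     parallel = sfr$parallel_ratio,
                                     tshape = sfr$tshape_ratio)
    }
  }

  energy <- interaction_energy_series(traj, prot, cnt, params,
                                      cutoff = config$energy$cutoff)
  rmsd <- tryCatch(rmsd_series(traj, reference = config$rmsd$reference,
                               selection = resolve_selection(
                                 st, config$rmsd$selection)),
                   error = function(e) NULL)

  blocking <- list()
  for (ch in config$channels) {
    cspec <- channel_spec(ch$id, ch$lining_residues,
                          mouth_radius = ch$mouth_radius %||% 0.35,
                          block_distance = ch$block_distance %||% 0.7)
    blocking[[cspec$id]] <- blocking_onset(traj, cspec, cnt,
                                           persistence = config$persistence,
                                           run_id = run$id)
  }

  list(id = run$id, series = series, contact_ratio_table = ratio_tab,
       stacking_ratios = stacking_ratios, energy = energy, rmsd = rmsd,
       blocking = blocking)
}

#' Run the full analysis pipeline
#'
#' @param config path to a JSON config, or an equivalent list. Recognised
#'   fields: `topology`, `runs` (list of `{id, trajectory}`), `selections`,
#'   `channels`, `criteria` blocks, `energy$cutoff`, `rmsd`, `persistence`,
#'   optional `tube` (nanotube spec fields enabling stacking analysis),
#'   `output_dir`, `seed`. In-memory `md_trajectory` objects may be passed
#'   in place of trajectory paths.
#' @param topology optional pre-built `md_structure` overriding
#'   `config$topology`.
#' @return a `nanocyp_report` list: per-run series and tables, per-channel
#'   blocking profiles, pooled blocking per channel, and a config echo with
#'   all defaults filled. When `config$output_dir` is set the report is
#'   also written to disk via [write_report()].
#' @export
run_analysis <- function(config, topology = NULL) {
  config <- load_analysis_config(config)
  if (is.null(topology)) {
    if (is.null(config$topology)) stop("config must name a topology file")
    topology <- read_structure(config$topology, config$topology_format)
  }
  if (length(config$runs) == 0) stop("config lists no trajectory runs")
  topology <- register_config_groups(topology, config)
  crit <- list(
    contact = do.call(contact_criteria, config$criteria$contact),
    hbond = do.call(hbond_criteria, config$criteria$hbond),
    salt_bridge = do.call(salt_bridge_criteria, config$criteria$salt_bridge),
    stacking = do.call(stacking_criteria,
                       lapply(config$criteria$stacking, unlist)))
  tube <- NULL
  if (!is.null(config$tube)) {
    tube <- build_armchair_swcnt(do.call(nanotube_spec, config$tube))
    if (n_atoms(tube$structure) != length(topology$groups$cnt)) {
      stop("config tube spec produces ", n_atoms(tube$structure),
           " carbons but the cnt selection has ",
           length(topology$groups$cnt), " atoms")
    }
  }
  runs <- lapply(config$runs, analyze_one_run, topology = topology,
                 config = config, tube = tube, crit = crit)
  names(runs) <- vapply(config$runs, function(r) as.character(r$id), "")

  pooled <- list()
  for (ch in config$channels) {
    profs <- lapply(runs, function(r) r$blocking[[as.character(ch$id)]])
    profs <- profs[!vapply(profs, is.null, NA)]
    if (length(profs) > 0) {
      pooled[[as.character(ch$id)]] <- pool_blocked_fraction(unname(profs))
    }
  }

  report <- list(package = "nanocyp",
                 version = tryCatch(
                   as.character(utils::packageVersion("nanocyp")),
                   error = function(e) "dev"),
                 seed = config$seed, config = config, runs = runs,
                 pooled_blocking = pooled)
  class(report) <- "nanocyp_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# internal: strip non-serializable pieces down to plain lists for JSON
report_to_serializable <- function(report) {
  runs <- lapply(report$runs, function(r) {
    list(id = r$id,
         series = r$series,
         contact_ratio_table = r$contact_ratio_table,
         stacking_ratios = r$stacking_ratios,
         energy = r$energy,
         rmsd = r$rmsd,
         blocking = lapply(r$blocking, function(p) {
           list(run_id = p$run_id, duration_ns = p$duration,
                onset_ns = p$onset, blocked_fraction = p$blocked_fraction,
                per_frame_flags = p$per_frame_flags)
         }))
  })
  cfg <- report$config
  cfg$output_dir <- NULL   # environment detail, kept out of the echo so
                           # identical analyses give byte-identical reports
  cfg$runs <- lapply(cfg$runs, function(r) {
    list(id = r$id,
         trajectory = if (is.character(r$trajectory)) r$trajectory
         else "<in-memory trajectory>")
  })
  list(package = report$package, version = report$version,
       seed = report$seed, config = cfg, runs = runs,
       pooled_blocking = lapply(report$pooled_blocking, function(p) {
         list(pooled_fraction = p$pooled_fraction,
              pooled_percent = p$pooled_percent)
       }))
}

#' Write a report to disk
#'
#' Writes `report.json` (deterministic: no timestamps; identical inputs
#' give byte-identical output), per-run TSV series, and a `meta.txt`
#' sidecar holding the wall-clock timestamp.
#'
#' @param report a `nanocyp_report`.
#' @param output_dir directory (created if needed).
#' @return invisibly, the path to `report.json`.
#' @export
write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(output_dir, "report.json")
  jsonlite::write_json(report_to_serializable(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  for (r in report$runs) {
    utils::write.table(r$series,
                       file.path(output_dir, paste0(r$id, "_series.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(r$energy,
                       file.path(output_dir, paste0(r$id, "_energy.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(r$rmsd)) {
      utils::write.table(r$rmsd,
                         file.path(output_dir, paste0(r$id, "_rmsd.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(r$contact_ratio_table)) {
      utils::write.table(r$contact_ratio_table,
                         file.path(output_dir,
                                   paste0(r$id, "_contact_ratios.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  writeLines(paste("generated:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
             file.path(output_dir, "meta.txt"))
  invisible(json_path)
}

#' @export
print.nanocyp_report <- function(x, ...) {
  cat("nanocyp_report:", length(x$runs), "run(s)\n")
  for (id in names(x$pooled_blocking)) {
    cat(sprintf("  channel %s pooled blocked: %.2f%%\n", id,
                x$pooled_blocking[[id]]$pooled_percent))
  }
  invisible(x)
}
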