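# One-command orchestration: simulate or ingest tracks, regularize,
# decompose, gate, run the neighborhood and lead-lag analyses, and emit a
# structured report plus persisted intermediate tables.
#
# A single global seed drives every stochastic stage through fixed
# offsets: simulation +0, gate sampling +1, permutation null +2.

#' Assemble and validate a pipeline run configuration
#'
#' Exactly one input source must be given: a simulation preset name or a
#' track file. Stage configurations default to the package defaults.
#'
#' @param preset Simulation preset name (see [sim_preset()]).
#' @param input_file Path to a delimited track export.
#' @param dialect A [track_dialect()] for `input_file`.
#' @param group,group_map,dt_frame Passed to [read_tracks()] for file
#'   input (`dt_frame` is its `dt`).
#' @param dt_target If non-`NULL`, tracks are regularized to this
#'   interval (s).
#' @param tracklet A [tracklet_config()].
#' @param gate A [gate_config()]; its seed is overridden by
#'   `seed + 1`.
#' @param neighborhood A [neighborhood_config()].
#' @param sim Named list of [sim_config()] overrides for preset input.
#' @param leader_group,follower_group Group labels used by the
#'   neighborhood stage.
#' @param out_dir Output directory for persisted tables (`NULL` = keep
#'   everything in memory).
#' @param format `"csv"` or `"tsv"` for persisted tables.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = NULL, input_file = NULL,
                       dialect = track_dialect("canonical"),
                       group = NULL, group_map = NULL, dt_frame = NULL,
                       dt_target = NULL,
                       tracklet = tracklet_config(),
                       gate = gate_config(),
                       neighborhood = neighborhood_config(),
                       sim = list(),
                       leader_group = "wt", follower_group = "ko",
                       out_dir = NULL, format = c("csv", "tsv"),
                       seed = 1L) {
  format <- match.arg(format)
  errors <- character(0)
  if (is.null(preset) && is.null(input_file)) {
    errors <- c(errors, "input: one of preset or input_file is required")
  }
  if (!is.null(preset) && !is.null(input_file)) {
    errors <- c(errors, "input: preset and input_file are mutually exclusive")
  }
  if (!is.null(dt_target) && (!is_number(dt_target) || dt_target <= 0)) {
    errors <- c(errors, "dt_target: must be a positive number of seconds")
  }
  if (!is_number(seed)) errors <- c(errors, "seed: must be a single integer")
  for (nm in c("tracklet", "gate", "neighborhood")) {
    cls <- paste0(switch(nm, tracklet = "tracklet", gate = "gate",
                         neighborhood = "neighborhood"), "_config")
    if (!inherits(get(nm), cls)) {
      errors <- c(errors, paste0(nm, ": must be a ", cls, " object"))
    }
  }
  if (length(errors) > 0) {
    stop_config(paste0("invalid run configuration:\n  ",
                       paste(errors, collapse = "\n  ")))
  }
  structure(list(preset = preset, input_file = input_file, dialect = dialect,
                 group = group, group_map = group_map, dt_frame = dt_frame,
                 dt_target = dt_target, tracklet = tracklet, gate = gate,
                 neighborhood = neighborhood, sim = sim,
                 leader_group = leader_group, follower_group = follower_group,
                 out_dir = out_dir, format = format, seed = as.integer(seed)),
            class = "run_config")
}

#' Parse and validate a pipeline configuration file
#'
#' Reads a key-value (YAML) configuration, fills defaults and returns a
#' fully resolved [run_config()]. All violations found are reported
#' together, not just the first. Recognized top-level keys: `preset`,
#' `input_file`, `group`, `dt_frame`, `dt_target`, `seed`, `out_dir`,
#' `format`, and nested `tracklet`, `gate`, `neighborhood`, `sim`
#' sections whose entries override the corresponding config defaults.
#'
#' @param path Path to a YAML config file, or a YAML string.
#' @return A `run_config`.
#' @export
validate_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    yaml::yaml.load(path)
  raw <- raw %||% list()
  errors <- character(0)
  known <- c("preset", "input_file", "group", "dt_frame", "dt_target",
             "seed", "out_dir", "format", "tracklet", "gate",
             "neighborhood", "sim")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  build_sub <- function(fun, section, label) {
    args <- raw[[section]] %||% list()
    tryCatch(do.call(fun, args), error = function(e) {
      errors <<- c(errors, paste0(label, ": ", conditionMessage(e)))
      fun()
    })
  }
  tracklet <- build_sub(tracklet_config, "tracklet", "tracklet")
  gate <- build_sub(gate_config, "gate", "gate")
  neighborhood <- build_sub(neighborhood_config, "neighborhood",
                            "neighborhood")
  cfg <- tryCatch(
    run_config(preset = raw$preset, input_file = raw$input_file,
               group = raw$group, dt_frame = raw$dt_frame,
               dt_target = raw$dt_target, tracklet = tracklet, gate = gate,
               neighborhood = neighborhood, sim = raw$sim %||% list(),
               out_dir = raw$out_dir, format = raw$format %||% "csv",
               seed = raw$seed %||% 1L),
    migratrack_config_error = function(e) {
      errors <<- c(errors, conditionMessage(e))
      NULL
    })
  if (length(errors) > 0) {
    stop_config(paste0("configuration errors:\n  ",
                       paste(errors, collapse = "\n  ")))
  }
  cfg
}

write_table_file <- function(x, dir, name, format) {
  delim <- if (format == "tsv") "\t" else ","
  readr::write_delim(as_tibble(x), file.path(dir, paste0(name, ".", format)),
                     delim = delim)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input (simulation or ingest), regularization,
#' tracklet decomposition and metrics, per-group track summaries, gate
#' counting, conditional-velocity analysis, and (when both leader and
#' follower groups are present) the lead-lag analysis. Every intermediate
#' table is persisted when `out_dir` is set; identical configurations
#' (including the seed) give identical reports.
#'
#' @param cfg A [run_config()].
#' @return A `run_report` list: `config`, `seeds`, `track_summaries`,
#'   `gate` (counts, sample metadata), `conditional_velocity`,
#'   `lead_lag`, `n_cells`, `n_tracklets`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- list(simulation = cfg$seed, gate_sampling = cfg$seed + 1L,
                permutation = cfg$seed + 2L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "migratrack_pipeline_error", parent = e)
    })
  }
  sim <- NULL
  tracks <- stage("ingest", {
    if (!is.null(cfg$preset)) {
      sim_cfg <- do.call(sim_preset,
                         c(list(name = cfg$preset, seed = seeds$simulation),
                           cfg$sim))
      sim <- simulate_tracks(sim_cfg)
      message("[ingest] simulated preset '", cfg$preset, "' (",
              sim_cfg$n_leaders, " leaders, ", sim_cfg$n_followers,
              " followers, seed ", seeds$simulation, ")")
      sim$tracks
    } else {
      tt <- read_tracks(cfg$input_file, dialect = cfg$dialect,
                        group = cfg$group, group_map = cfg$group_map,
                        dt = cfg$dt_frame)
      message("[ingest] read ", length(unique(tt$cell_id)), " tracks from ",
              cfg$input_file)
      tt
    }
  })
  tracks <- stage("regularize", {
    if (!is.null(cfg$dt_target)) {
      tt <- regularize(tracks, cfg$dt_target)
      message("[regularize] resampled to dt = ", cfg$dt_target, " s")
      tt
    } else {
      validate_tracks(tracks, require_uniform_dt = TRUE)
      tracks
    }
  })
  tracklets <- stage("decompose", decompose_tracklets(tracks, cfg$tracklet))
  metrics <- stage("metrics", tracklet_metrics(tracklets, cfg$tracklet))
  message("[tracklets] ", nrow(metrics), " tracklets from ",
          length(unique(tracks$cell_id)), " cells")
  track_summaries <- stage("track_summaries", {
    dt <- track_dt(tracks)
    per_cell <- bind_rows(lapply(split(as_tibble(tracks), tracks$cell_id),
                                 function(cc) {
      pos <- as.matrix(cc[, intersect(c("x", "y", "z"), names(cc))])
      cbind(tibble(cell_id = cc$cell_id[1], group = cc$group[1]),
            summarize_track(pos, dt))
    }))
    dist_stats <- function(x) {
      tibble(n = length(x), mean = mean(x), median = median(x),
             q25 = quantile(x, 0.25), q75 = quantile(x, 0.75))
    }
    per_group <- per_cell |>
      group_by(.data$group) |>
      summarise(across(all_of(c("D", "L", "v")),
                       list(mean = mean, median = median)),
                n = n(), .groups = "drop")
    list(per_cell = per_cell, per_group = per_group,
         velocity = lapply(split(per_cell$v, per_cell$group), dist_stats))
  })
  gate_cfg <- cfg$gate
  gate_cfg$seed <- seeds$gate_sampling
  gates <- stage("gating", gate_counts(metrics, gate_cfg))
  gated_metrics <- stage("gating", classify_tracklets(metrics, gate_cfg))
  cond_vel <- stage("neighborhood",
                    conditional_velocity(tracks, gated_metrics,
                                         cfg$neighborhood,
                                         leader_group = cfg$leader_group))
  groups_present <- unique(tracks$group)
  lead_lag <- NULL
  if (all(c(cfg$leader_group, cfg$follower_group) %in% groups_present)) {
    lead_lag <- stage("lead_lag",
                      lead_lag_analysis(tracks, cfg$neighborhood,
                                        leader_group = cfg$leader_group,
                                        follower_group = cfg$follower_group,
                                        window = cfg$tracklet$W,
                                        seed = seeds$permutation))
  } else {
    message("[lead_lag] skipped: needs both leader and follower groups")
  }
  report <- structure(list(
    config = cfg, seeds = seeds,
    n_cells = length(unique(tracks$cell_id)),
    n_tracklets = nrow(metrics),
    track_summaries = track_summaries,
    gate = list(counts = gates$counts,
                count_matrix = gate_count_matrix(gates),
                config = gate_cfg),
    conditional_velocity = list(summary = cond_vel$summary,
                                tests = cond_vel$tests),
    lead_lag = if (!is.null(lead_lag)) {
      list(overall = lead_lag$overall, per_follower = lead_lag$per_follower)
    }
  ), class = "run_report")
  if (!is.null(cfg$out_dir)) {
    stage("persist", {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_tracks(tracks, file.path(cfg$out_dir,
                                     paste0("tracks.", cfg$format)),
                   sep = if (cfg$format == "tsv") "\t" else ",")
      write_table_file(metrics, cfg$out_dir, "tracklet_metrics", cfg$format)
      write_table_file(gates$counts, cfg$out_dir, "gate_counts", cfg$format)
      write_table_file(gate_scatter_export(gates), cfg$out_dir,
                       "gate_scatter", cfg$format)
      write_table_file(cond_vel$records, cfg$out_dir,
                       "neighborhood_records", cfg$format)
      write_table_file(track_summaries$per_cell, cfg$out_dir,
                       "track_summaries", cfg$format)
      # gate definitions echoed into a JSON sidecar
      jsonlite::write_json(
        list(a_star = gate_cfg$a_star, d_star = gate_cfg$d_star,
             sample_N = gate_cfg$sample_N, seed = gate_cfg$seed),
        file.path(cfg$out_dir, "gate_config.json"), auto_unbox = TRUE)
      jsonlite::write_json(report_to_list(report),
                           file.path(cfg$out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    })
  }
  report
}

# Plain-list view of a report for JSON serialization.
report_to_list <- function(report) {
  cv_tests <- report$conditional_velocity$tests
  list(
    seeds = report$seeds,
    n_cells = report$n_cells,
    n_tracklets = report$n_tracklets,
    gate_counts = as.data.frame(report$gate$counts),
    gate_config = report$gate$config[c("a_star", "d_star", "sample_N",
                                       "seed")],
    track_summary_per_group = as.data.frame(
      report$track_summaries$per_group),
    conditional_velocity = list(
      summary = as.data.frame(report$conditional_velocity$summary),
      tests = if (!is.null(cv_tests)) as.data.frame(cv_tests)),
    lead_lag = if (!is.null(report$lead_lag)) {
      list(overall = report$lead_lag$overall,
           per_follower = as.data.frame(report$lead_lag$per_follower))
    }
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("migratrack run report\n")
  cat("  cells:", x$n_cells, " tracklets:", x$n_tracklets, "\n")
  cat("  gate counts (N =", x$gate$config$sample_N, "per group):\n")
  print(x$gate$count_matrix)
  if (!is.null(x$lead_lag)) {
    cat("  lead-lag: fraction =",
        signif(x$lead_lag$overall$fraction, 3),
        " p =", signif(x$lead_lag$overall$p_value, 3), "\n")
  }
  invisible(x)
}
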