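# Pipeline orchestration: a single YAML-serialisable configuration drives
# synth -> preprocess -> eyetrack/filter -> cluster -> stats -> model, with a
# JSON manifest recording checksums, timings and warnings for reproducibility.

#' Default run configuration
#'
#' Nested list with one section per stage; serialisable to/from YAML with a
#' lossless round trip. Unknown keys are rejected at validation.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = list(synth = TRUE, preprocess = TRUE, eyetrack = TRUE,
                  cluster = TRUE, stats = TRUE, model = TRUE),
    synth = list(n_neurons = 300L, n_reps = 20L, contexts = "dark",
                 frame_rate = 31.5, trial_gain_cv = 0.3, context_mod_hz = 0,
                 noise_sd = 0.02, drift_sd = 0.01, tau_decay = 2,
                 tau_rise = 0.18, amp = 0.05, neuropil_weight = 0.7,
                 saccade_rate = 0.1, saccade_amp_um = 100),
    preprocess = list(tau = 2, smooth_window = 0.19, neuropil_weight = 0.7,
                      gaussian_sigma = 1),
    eyetrack = list(acuity_deg = 2, eye_radius_mm = 1.65),
    cluster = list(n_over = 25L, hom_threshold = 0.4, reagg_threshold = 0.4,
                   exclude = integer(0)),
    stats = list(alpha = 0.01, mask_pct = 1, n_partitions = 2000L,
                 n_shuffles = 2000L, response_window = c(0.2, 1.0)),
    model = list(spec = "default")
  )
}

#' Validate a run configuration
#'
#' Recursively checks that every key exists in the default schema; unknown
#' keys raise a config error.
#'
#' @param config candidate configuration list.
#' @return the config, invisibly, on success.
#' @export
validate_config <- function(config) {
  check <- function(cfg, ref, path) {
    unknown <- setdiff(names(cfg), names(ref))
    if (length(unknown) > 0) {
      xmv1_stop(paste0("unknown config key(s) at ", path, ": ",
                       paste(unknown, collapse = ", ")), "xmv1_config_error")
    }
    for (k in names(cfg)) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
        if (!is.list(cfg[[k]])) {
          xmv1_stop(paste0("config key ", path, k, " must be a section"),
                    "xmv1_config_error")
        }
        check(cfg[[k]], ref[[k]], paste0(path, k, "."))
      }
    }
  }
  check(config, default_config(), "")
  invisible(config)
}

#' Load / save a run configuration (YAML)
#'
#' Values present in the file override the defaults; missing keys keep their
#' default values; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return full configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(user)
  merge_cfg <- function(ref, usr) {
    for (k in names(usr)) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(usr[[k]])) {
        ref[[k]] <- merge_cfg(ref[[k]], usr[[k]])
      } else {
        ref[[k]] <- usr[[k]]
      }
    }
    ref
  }
  cfg <- merge_cfg(default_config(), user)
  # YAML has no empty-integer-vector literal: [] reads back as list()
  cfg$cluster$exclude <- as.integer(unlist(cfg$cluster$exclude))
  cfg
}

#' @rdname load_config
#' @param config configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

stage_output <- function(out_dir, name) file.path(out_dir, name)

require_stage_file <- function(path, stage) {
  if (!file.exists(path)) {
    xmv1_stop(sprintf("missing output %s: run stage '%s' first",
                      basename(path), stage), "xmv1_stage_error")
  }
  path
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order against `out_dir`, failing fast with
#' stage-named errors, and writes `manifest.json` with the config hash,
#' per-file md5 checksums, timings and captured warnings. Deterministic
#' stages reproduce identical checksums for the same config + seed.
#'
#' @param config configuration list ([default_config()]) or path to a YAML
#'   file.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- load_config(config)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- stage_output(out_dir, "config.yaml")
  save_config(config, cfg_path)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("xmv1")),
                   stages = list())
  warnings_log <- character(0)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    files <- withCallingHandlers(
      fun(),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = as.list(tools::md5sum(unlist(files))))
    invisible(NULL)
  }

  run_stage("synth", function() {
    ds <- do.call(make_synthetic_dataset, c(config$synth, seed = config$seed))
    state$dataset <- ds
    h5 <- stage_output(out_dir, "dataset.h5")
    write_dataset_h5(ds, h5)
    c(h5, stage_output(out_dir, "dataset_trials.csv"),
      stage_output(out_dir, "dataset_pupil.csv"))
  })

  get_dataset <- function(stage) {
    if (is.null(state$dataset)) {
      h5 <- require_stage_file(stage_output(out_dir, "dataset.h5"), "synth")
      state$dataset <- read_dataset_h5(h5)
    }
    state$dataset
  }

  run_stage("preprocess", function() {
    ds <- get_dataset("preprocess")
    pp <- do.call(preprocess_traces, c(list(traces = ds$traces),
                                       config$preprocess))
    state$pp <- pp
    f <- stage_output(out_dir, "preprocess_exclusions.csv")
    utils::write.csv(data.frame(excluded_roi = pp$excluded), f,
                     row.names = FALSE)
    f
  })

  run_stage("eyetrack", function() {
    ds <- get_dataset("eyetrack")
    tf <- filter_trials(ds$trials, ds$pupil,
                        threshold_deg = config$eyetrack$acuity_deg,
                        eye_radius_mm = config$eyetrack$eye_radius_mm)
    state$trials <- tf
    f1 <- stage_output(out_dir, "trials_filtered.csv")
    utils::write.csv(as.data.frame(tf), f1, row.names = FALSE)
    f2 <- stage_output(out_dir, "trial_filter_summary.json")
    jsonlite::write_json(attr(tf, "summary"), f2, auto_unbox = TRUE,
                         digits = NA)
    c(f1, f2)
  })

  run_stage("cluster", function() {
    ds <- get_dataset("cluster")
    if (is.null(state$pp)) xmv1_stop(
      "cluster stage needs preprocess outputs: run stage 'preprocess' first",
      "xmv1_stage_error")
    trials <- if (!is.null(state$trials)) state$trials else ds$trials
    rp <- epoch_and_average(state$pp$r, trials,
                            frame_rate = state$pp$frame_rate)
    X <- profiles_matrix(rp)
    m <- cluster_pipeline(X, n_over = config$cluster$n_over,
                          hom_threshold = config$cluster$hom_threshold,
                          reagg_threshold = config$cluster$reagg_threshold,
                          exclude = config$cluster$exclude)
    templates <- make_rate_templates(frame_rate = attr(trials, "frame_rate"))
    type_map <- label_clusters(m, templates, attr(X, "stimuli"),
                               smooth_window = config$preprocess$smooth_window)
    state$model_clusters <- m
    state$type_map <- type_map
    state$profiles <- X
    f1 <- stage_output(out_dir, "cluster_labels.csv")
    utils::write.csv(data.frame(neuron = seq_along(m$labels),
                                cluster = m$labels,
                                functional_type = ifelse(
                                  m$labels == 0, "nonresponsive",
                                  type_map[as.character(m$labels)])),
                     f1, row.names = FALSE)
    fr <- type_fractions(m$labels, type_map)
    f2 <- stage_output(out_dir, "type_fractions.csv")
    utils::write.csv(data.frame(type = names(fr), fraction = as.numeric(fr)),
                     f2, row.names = FALSE)
    f3 <- stage_output(out_dir, "cluster_report.json")
    jsonlite::write_json(list(
      n_over = m$n_over, n_kept = nrow(m$centroids),
      n_clustered = sum(m$labels > 0), n_pool = sum(m$labels == 0),
      n_reaggregated = m$n_reaggregated,
      homogeneity = as.list(m$homogeneity),
      explained_variance_pct = m$explained_variance_pct$total),
      f3, auto_unbox = TRUE, digits = NA)
    c(f1, f2, f3)
  })

  run_stage("stats", function() {
    ds <- get_dataset("stats")
    if (is.null(state$pp)) xmv1_stop(
      "stats stage needs preprocess outputs: run stage 'preprocess' first",
      "xmv1_stage_error")
    trials <- if (!is.null(state$trials)) state$trials else ds$trials
    fr <- state$pp$frame_rate
    win <- config$stats$response_window
    onset <- attr(trials, "stim_onset")
    files <- character(0)
    res <- list()
    for (ctx in unique(trials$context)) {
      sel <- trials$context == ctx & trials$valid
      scalars <- function(stim_set) {
        rows <- which(sel & trials$stimulus %in% stim_set)
        sapply(rows, function(j) {
          on <- trials$onset_sample[j]
          cols <- (on + round(win[1] * fr)):(on + round(win[2] * fr))
          pre <- (on - round(0.5 * fr)):(on - 1)
          rowMeans(state$pp$r[, cols, drop = FALSE]) -
            rowMeans(state$pp$r[, pre, drop = FALSE])
        })
      }
      stim <- scalars(c("up_ramp", "down_ramp"))
      blank <- scalars("blank")
      calls <- detect_responders(stim, blank, alpha = config$stats$alpha)
      fr_tab <- masked_fraction(calls, config$stats$mask_pct)
      f <- stage_output(out_dir, paste0("responders_", ctx, ".csv"))
      utils::write.csv(calls, f, row.names = FALSE)
      files <- c(files, f)
      res[[ctx]] <- fr_tab
    }
    # distribution bootstrap: functional-label distribution, two half-splits
    if (!is.null(state$model_clusters)) {
      lab <- state$model_clusters$labels
      set.seed(config$seed)
      half <- sample(length(lab), floor(length(lab) / 2))
      db <- distribution_bootstrap(lab[half], lab[-half],
                                   n_partitions = config$stats$n_partitions,
                                   seed = config$seed)
      f <- stage_output(out_dir, "distribution_bootstrap.csv")
      utils::write.csv(as.data.frame(db), f, row.names = FALSE)
      files <- c(files, f)
    }
    f <- stage_output(out_dir, "responder_fractions.json")
    jsonlite::write_json(res, f, auto_unbox = TRUE, digits = NA)
    c(files, f)
  })

  run_stage("model", function() {
    spec <- if (identical(config$model$spec, "default")) {
      default_rate_model_spec()
    } else {
      default_rate_model_spec(config$model$spec)
    }
    ctx <- context_experiment(spec)
    bim <- bimodal_experiment(spec)
    f1 <- stage_output(out_dir, "model_context.json")
    jsonlite::write_json(as.list(ctx), f1, auto_unbox = TRUE, digits = NA)
    f2 <- stage_output(out_dir, "model_bimodal.csv")
    utils::write.csv(bim, f2, row.names = FALSE)
    c(f1, f2)
  })

  manifest$warnings <- warnings_log
  mpath <- stage_output(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Human-readable run report
#'
#' Summarises a completed run directory (type fractions, responder fractions
#' per context after masking, bootstrap p-values, rate-model signs) as
#' Markdown. Sections whose outputs are absent are marked "skipped".
#' Regeneration is idempotent.
#'
#' @param out_dir run directory written by [run_pipeline()].
#' @param path output file (default `report.md` inside `out_dir`).
#' @return the report text, invisibly.
#' @export
pipeline_report <- function(out_dir, path = file.path(out_dir, "report.md")) {
  lines <- c("# xmv1 run report", "")
  section <- function(title, file, fmt) {
    f <- stage_output(out_dir, file)
    if (!file.exists(f)) return(c(paste0("## ", title), "", "_skipped_", ""))
    c(paste0("## ", title), "", fmt(f), "")
  }
  lines <- c(lines, section("Functional type fractions", "type_fractions.csv",
    function(f) {
      df <- utils::read.csv(f)
      sprintf("- %s: %.1f%%", df$type, 100 * df$fraction)
    }))
  lines <- c(lines, section("Responder fractions (masked)",
                            "responder_fractions.json", function(f) {
    res <- jsonlite::read_json(f, simplifyVector = TRUE)
    unlist(lapply(names(res), function(ctx) {
      df <- res[[ctx]]
      sprintf("- %s / %s: raw %.2f%%, displayed %.2f%%", ctx, df$direction,
              df$raw_pct, df$displayed_pct)
    }))
  }))
  lines <- c(lines, section("Distribution bootstrap",
                            "distribution_bootstrap.csv", function(f) {
    df <- utils::read.csv(f)
    sprintf("- cluster %s: diff %+.3f, p = %.4f", df$cluster, df$observed,
            df$p_value)
  }))
  lines <- c(lines, section("Supra-linearity bootstrap",
                            "supralinearity.json", function(f) {
    res <- jsonlite::read_json(f, simplifyVector = TRUE)
    sprintf("- observed %.4g, p = %.4g", res$observed_stat, res$p_value)
  }))
  lines <- c(lines, section("Rate model", "model_context.json", function(f) {
    ctx <- jsonlite::read_json(f, simplifyVector = TRUE)
    verdict <- if (ctx$dark < 0 && ctx$light > 0) {
      "dark-negative / light-positive (context-dependent sign switch)"
    } else "no sign switch with these parameters"
    out <- c(sprintf("- sound response dark: %+.4f, light: %+.4f",
                     ctx$dark, ctx$light),
             paste0("- verdict: ", verdict))
    bf <- stage_output(out_dir, "model_bimodal.csv")
    if (file.exists(bf)) {
      bim <- utils::read.csv(bf)
      out <- c(out, sprintf("- boost(%s): %+.4f", bim$level, bim$boost))
    }
    out
  }))
  writeLines(lines, path)
  invisible(paste(lines, collapse = "\n"))
}
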