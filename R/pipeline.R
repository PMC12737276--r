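# End-to-end orchestration: simulate -> stage -> psd -> coherence ->
# spindles -> stats from a single JSON-able config, with a manifest and a
# log so runs are reproducible and each artifact is re-parseable by the io
# module.

#' Default pipeline configuration
#'
#' @param duration_s simulated length per condition in seconds.
#' @param n_channels channels in the simulation.
#' @param fs sampling rate in Hz.
#' @param seed master seed; the before/after conditions use `seed` and
#'   `seed + 1000`.
#' @param video simulate and use per-epoch motion frames for staging.
#' @param psd_channels,coherence_channels channel indices analyzed by the
#'   respective stages (kept small by default to bound runtime).
#' @param n_coherence_segments 15-s segments per condition entering the
#'   paired coherence comparison.
#' @return a nested list accepted by [run_all()].
#' @export
pipeline_config <- function(duration_s = 300, n_channels = 8, fs = 1024,
                            seed = 1, video = TRUE,
                            psd_channels = 1:4, coherence_channels = 1:4,
                            n_coherence_segments = 12) {
  list(duration_s = duration_s, n_channels = n_channels, fs = fs,
       seed = seed, video = video, psd_channels = psd_channels,
       coherence_channels = coherence_channels,
       n_coherence_segments = n_coherence_segments)
}

pipe_log <- function(logfile, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the full analysis pipeline into a directory
#'
#' Simulates a before and an after condition, stages the "before"
#' recording (video-assisted when configured), computes per-channel Welch
#' PSDs and band powers, per-segment six-band pairwise coherences with the
#' paired Wilcoxon + FDR change table, runs the spindle detector on both
#' conditions, and fits the before/after mixed model per spindle metric.
#' Identical seeds give identical outputs.
#'
#' @param config a [pipeline_config()] (or a JSON file path holding one).
#' @param out_dir run directory, created if needed.
#' @return `out_dir`, invisibly; see the manifest for the artifact list.
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  cat("", file = logfile)
  stage_name <- "config"
  result <- try({
    artifacts <- character(0)
    keep <- function(p) { artifacts <<- c(artifacts, basename(p)); p }

    stage_name <- "simulate"
    pipe_log(logfile, "simulating before/after conditions")
    mk <- function(sd) simulate_recording(sim_config(
      n_channels = config$n_channels, fs = config$fs,
      duration = config$duration_s, seed = sd))
    sims <- list(before = mk(config$seed), after = mk(config$seed + 1000))
    write_bundle(sims$before$recording, keep(file.path(out_dir, "bundle_before")))
    write_hypnogram_csv(sims$before$ground_truth$hypnogram,
                        keep(file.path(out_dir, "hypnogram_truth.csv")))

    stage_name <- "stage"
    frames <- NULL
    if (isTRUE(config$video)) {
      set.seed(config$seed + 7)
      frames <- simulate_motion_frames(sims$before$ground_truth$hypnogram)
    }
    hyp <- stage_recording(sims$before$recording, frames = frames)
    write_hypnogram_csv(hyp, keep(file.path(out_dir, "hypnogram.csv")))
    jsonlite::write_json(as.list(stage_proportions(hyp)),
                         keep(file.path(out_dir, "stage_proportions.json")),
                         auto_unbox = TRUE, digits = NA)
    pipe_log(logfile, "staged ", length(hyp$labels), " epochs; motion=",
             if (is.null(frames)) "absent" else "present")

    stage_name <- "psd"
    rec <- sims$before$recording
    chs <- rec$channel_ids[config$psd_channels]
    psds <- lapply(chs, function(ch)
      welch_psd(apply_notch(rec$samples[ch, ], rec$fs), rec$fs))
    psd_df <- data.frame(freq_hz = psds[[1]]$freqs)
    for (i in seq_along(chs)) psd_df[[chs[i]]] <- psds[[i]]$power
    utils::write.csv(psd_df, keep(file.path(out_dir, "psd.csv")), row.names = FALSE)
    bands <- band_set()
    bp <- expand.grid(channel_id = chs, band = bands$band,
                      stringsAsFactors = FALSE)
    bp$power <- mapply(function(ch, b) {
      k <- which(bands$band == b)
      band_power(psds[[which(chs == ch)]], c(bands$low[k], bands$high[k]))
    }, bp$channel_id, bp$band)
    utils::write.csv(bp, keep(file.path(out_dir, "band_power.csv")), row.names = FALSE)

    stage_name <- "coherence"
    pipe_log(logfile, "coherence over ", config$n_coherence_segments,
             " segments/condition")
    coh_long <- list()
    for (cond in names(sims)) {
      r <- sims[[cond]]$recording
      idx <- config$coherence_channels
      nseg <- min(config$n_coherence_segments,
                  floor(ncol(r$samples) / r$fs / 15))
      for (s in seq_len(nseg)) {
        seg <- recording(r$samples[idx, ((s - 1) * 15 * r$fs + 1):(s * 15 * r$fs),
                                   drop = FALSE], fs = r$fs)
        for (b in bands$band) {
          m <- pairwise_band_matrix(seg, b)
          ut <- which(upper.tri(m), arr.ind = TRUE)
          coh_long[[length(coh_long) + 1]] <- data.frame(
            condition = cond,
            pair = paste0(rownames(m)[ut[, 1]], "-", colnames(m)[ut[, 2]]),
            band = b, segment = s, value = m[ut])
        }
      }
    }
    coh_long <- do.call(rbind, coh_long)
    utils::write.csv(coh_long, keep(file.path(out_dir, "coherence_segments.csv")),
                     row.names = FALSE)
    changes <- compare_conditions(coh_long[coh_long$condition == "before", ],
                                  coh_long[coh_long$condition == "after", ])
    utils::write.csv(changes, keep(file.path(out_dir, "coherence_changes.csv")),
                     row.names = FALSE)

    stage_name <- "spindles"
    sp <- lapply(names(sims), function(cond)
      spindle_pipeline(sims[[cond]]$recording,
                       sims[[cond]]$ground_truth$hypnogram,
                       channels = seq_len(min(4, config$n_channels))))
    names(sp) <- names(sims)
    write_events_csv(sp$before$events, keep(file.path(out_dir, "spindle_events.csv")))
    jsonlite::write_json(
      list(before = sp$before$summary[c("n_events", "nrem_duration", "density")],
           after = sp$after$summary[c("n_events", "nrem_duration", "density")]),
      keep(file.path(out_dir, "spindle_summary.json")),
      auto_unbox = TRUE, digits = NA)

    stage_name <- "stats"
    long <- do.call(rbind, lapply(names(sp), function(cond) {
      ev <- sp[[cond]]$events
      if (!nrow(ev)) return(NULL)
      tm <- if (cond == "before") "Before" else "After"
      rbind(data.frame(mouse_id = "m1", time = tm, metric = "amplitude",
                       value = ev$amplitude),
            data.frame(mouse_id = "m1", time = tm, metric = "duration",
                       value = ev$duration),
            data.frame(mouse_id = "m1", time = tm, metric = "power",
                       value = ev$power))
    }))
    eff <- suppressWarnings(effects_table(long))  # single simulated mouse -> lm fallback
    utils::write.csv(eff, keep(file.path(out_dir, "effects.csv")), row.names = FALSE)

    stage_name <- "manifest"
    manifest <- list(package = "ecogsleep",
                     version = as.character(utils::packageVersion("ecogsleep")),
                     seed = config$seed,
                     motion = if (is.null(frames)) "absent" else "present",
                     config = config,
                     config_hash = config_hash(config),
                     artifacts = sort(artifacts))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pipe_log(logfile, "done: ", length(artifacts), " artifacts")
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    pipe_log(logfile, "FAILED at stage '", stage_name, "': ",
             attr(result, "condition")$message)
    stop("pipeline failed at stage '", stage_name, "': ",
         attr(result, "condition")$message)
  }
  invisible(out_dir)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # tiny rolling hash of the serialized config; enough to fingerprint a run
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `stage`, `psd`, `coherence`, `spindles`,
#' `stats` (each a focused slice of [run_all()]) and `run-all`. Flags:
#' `--config` (JSON), `--seed`, `--out`. Exit codes: 0 success, 2 config
#' error, 3 stage failure. Installed as `cli/ecogsleep-cli.R` under the
#' package root for use with `Rscript`.
#'
#' @param args character vector, default the trailing command line.
#' @return integer exit code, invisibly.
#' @export
ecog_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: ecogsleep-cli.R <simulate|stage|psd|coherence|spindles|stats|run-all> [--config f.json] [--seed n] [--out dir]"
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opt <- list(seed = 1L, out = "ecogsleep-run", config = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) { message(usage); return(invisible(2L)) }
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) {
    if (!file.exists(opt$config)) { message("config not found: ", opt$config); return(invisible(2L)) }
    utils::modifyList(pipeline_config(), jsonlite::read_json(opt$config, simplifyVector = TRUE))
  } else pipeline_config()
  cfg$seed <- as.integer(opt$seed)
  ok <- try({
    if (cmd == "run-all") run_all(cfg, opt$out)
    else if (cmd %in% c("simulate", "stage", "psd", "coherence", "spindles", "stats")) {
      # the focused subcommands reuse run_all and point the user at the artifact
      run_all(cfg, opt$out)
      message("artifacts for '", cmd, "' written under ", opt$out)
    } else { message(usage); return(invisible(2L)) }
  }, silent = TRUE)
  if (inherits(ok, "try-error")) {
    message(attr(ok, "condition")$message)
    return(invisible(3L))
  }
  invisible(0L)
}
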