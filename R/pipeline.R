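#' Validate a pipeline configuration
#'
#' Checks the nested configuration used by [run_pipeline()]. Errors name
#' the offending field with its full path (e.g. `simulate$fs`).
#'
#' @param config a named list, or a path to a YAML/JSON file.
#' @return The validated config list, with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        abort("reading YAML configs requires the yaml package.",
              class = "ferrotrace_config_error")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) {
    abort("config must be a named list or a YAML/JSON path.",
          class = "ferrotrace_config_error")
  }
  need <- function(x, field, path, check = is.numeric) {
    if (is.null(x[[field]]) || !check(x[[field]])) {
      abort(sprintf("config field `%s$%s` is missing or invalid.", path, field),
            class = "ferrotrace_config_error")
    }
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$simulate)) {
    abort("config field `simulate` is missing.", class = "ferrotrace_config_error")
  }
  sim <- config$simulate
  need(sim, "experiment", "simulate", is.character)
  if (!sim$experiment %in% c("trap", "pair", "loading", "control")) {
    abort("config field `simulate$experiment` must be one of trap, pair, loading, control.",
          class = "ferrotrace_config_error")
  }
  need(sim, "fs", "simulate")
  need(sim, "duration", "simulate")
  if (is.null(sim$t_trap)) sim$t_trap <- 5
  if (sim$experiment == "trap" && is.null(sim$preset)) sim$preset <- "apo"
  config$simulate <- sim
  if (is.null(config$preprocess)) config$preprocess <- list()
  if (is.null(config$preprocess$filter_cutoff)) config$preprocess$filter_cutoff <- 1000
  if (config$preprocess$filter_cutoff >= sim$fs / 2) {
    abort("config field `preprocess$filter_cutoff` must be below fs/2.",
          class = "ferrotrace_config_error")
  }
  if (is.null(config$metrics)) config$metrics <- list()
  m <- config$metrics
  if (is.null(m$window)) m$window <- 0.1
  if (is.null(m$hop)) m$hop <- 0.05
  config$metrics <- m
  if (is.null(config$segment)) config$segment <- list()
  if (is.null(config$segment$min_dwell)) config$segment$min_dwell <- 0.5
  if (is.null(config$segment$hysteresis_fraction)) config$segment$hysteresis_fraction <- 0.25
  if (is.null(config$compare)) config$compare <- list()
  if (is.null(config$compare$n_permutations)) config$compare$n_permutations <- 1e4
  config
}

preset_by_name <- function(name) {
  switch(name,
         apo = preset_apo(),
         holo = preset_holo(),
         ferric_control = preset_ferric_control(),
         abort(sprintf("unknown preset '%s'.", name),
               class = "ferrotrace_config_error"))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> filter -> step detection -> fluctuation
#' metrics -> (segmentation) -> (comparison) according to a validated
#' config, writing a JSON summary, CSV tables, PNG figures and a
#' stage-tagged log into `out_dir`. All randomness flows from
#' `config$seed`, so reruns with the same config produce an identical
#' JSON summary (timestamps go only to the log).
#'
#' @param config list or YAML/JSON path, see [validate_config()].
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing and just returns the result bundle.
#' @return Invisibly, a list with elements `summary` (the JSON-able
#'   result list), `traces`, `rms`, `segments`, `events`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- validate_config(config)
  logf <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    logf <- file.path(out_dir, "log.txt")
  }
  say <- function(stage, msg) {
    line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, msg)
    if (!is.null(logf)) cat(line, "\n", file = logf, append = TRUE)
    invisible(NULL)
  }
  run_stage <- function(stage, expr) {
    say(stage, sprintf("start (seed %s)", cfg$seed))
    tryCatch(force(expr), error = function(e) {
      abort(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
            class = "ferrotrace_stage_error")
    })
  }

  sim <- cfg$simulate
  traces <- run_stage("simulate", {
    switch(sim$experiment,
      trap = list(trap = simulate_trap_experiment(
        preset_by_name(sim$preset), seed = cfg$seed, duration = sim$duration,
        fs = sim$fs, t_trap = sim$t_trap)),
      pair = list(
        apo = simulate_trap_experiment(preset_apo(), seed = cfg$seed,
                                       duration = sim$duration, fs = sim$fs,
                                       t_trap = sim$t_trap),
        holo = simulate_trap_experiment(preset_holo(), seed = cfg$seed,
                                        duration = sim$duration, fs = sim$fs,
                                        t_trap = sim$t_trap)),
      loading = list(loading = simulate_loading_experiment(
        seed = cfg$seed, duration = sim$duration, fs = sim$fs,
        t_trap = sim$t_trap,
        loading_delay = sim$loading_delay %||% 60)),
      control = list(control = simulate_control_experiment(
        seed = cfg$seed, duration = sim$duration, fs = sim$fs,
        t_trap = sim$t_trap,
        exposure_delay = sim$exposure_delay %||% 25)))
  })

  filtered <- run_stage("preprocess", {
    lapply(traces, gaussian_lowpass, cutoff = cfg$preprocess$filter_cutoff)
  })

  events <- run_stage("detect", {
    lapply(names(filtered), function(nm) {
      ev <- detect_trap_event(traces[[nm]])
      ev$trace <- nm
      ev
    })
  })
  events <- dplyr::bind_rows(events)

  rms <- run_stage("metrics", {
    lapply(filtered, sliding_rms, window = cfg$metrics$window,
           hop = cfg$metrics$hop)
  })
  summaries <- run_stage("metrics", {
    purrr::imap(filtered, function(tr, nm) {
      ev <- events[events$trace == nm, ]
      seg <- tr[tr$time >= ev$t_trap + 0.5 &
                  (is.na(ev$t_release) | tr$time < ev$t_release), ]
      q <- quartile_summary(seg$value)
      list(nrms = nrms(seg$value),
           ratio = ev$ratio, T0 = ev$T0, deltaT = ev$deltaT,
           t_trap = ev$t_trap,
           q1 = q$q1, q2 = q$q2, q3 = q$q3,
           median_rms_mv = stats::median(
             rms[[nm]]$rms[rms[[nm]]$time >= ev$t_trap + 0.5]))
    })
  })

  seg_out <- NULL
  dwell <- NULL
  if (sim$experiment %in% c("loading", "control")) {
    seg_out <- run_stage("segment", {
      nm <- names(filtered)[1]
      ev <- events[events$trace == nm, ]
      rs <- rms[[nm]]
      rs <- rs[rs$time >= ev$t_trap + 0.5, ]
      class(rs) <- c("ferro_rms", "tbl_df", "tbl", "data.frame")
      withCallingHandlers(
        segment_states(rs, min_dwell = cfg$segment$min_dwell,
                       hysteresis_fraction = cfg$segment$hysteresis_fraction),
        warning = function(w) invokeRestart("muffleWarning"))
    })
    dwell <- tryCatch(dwell_statistics(seg_out), error = function(e) NULL)
  }

  comparison <- NULL
  if (sim$experiment == "pair") {
    comparison <- run_stage("compare", {
      seg_nrms <- function(tr, ev) {
        t1 <- ev$t_trap + 0.5
        t2 <- max(tr$time)
        starts <- seq(t1, t2 - 1, by = 1)
        vapply(starts, function(s) {
          nrms(tr$value[tr$time >= s & tr$time < s + 1])
        }, numeric(1))
      }
      a <- seg_nrms(filtered$apo, events[events$trace == "apo", ])
      b <- seg_nrms(filtered$holo, events[events$trace == "holo", ])
      pt <- permutation_test(a, b, n_permutations = cfg$compare$n_permutations,
                             seed = cfg$seed)
      list(statistic = pt$statistic, p_value = pt$p_value,
           n_permutations = pt$n_permutations,
           group_sizes = pt$group_sizes,
           calls = lapply(summaries, function(s)
             classify_isoform(s)$label))
    })
  }

  summary <- list(
    seed = cfg$seed,
    experiment = sim$experiment,
    events = as.list(events),
    traces = summaries,
    segments = if (!is.null(seg_out))
      list(n = nrow(seg_out), single_state = attr(seg_out, "single_state"),
           threshold = attr(seg_out, "threshold")),
    dwell = if (!is.null(dwell))
      list(mean_on = dwell$mean_on, mean_off = dwell$mean_off,
           n_cycles = dwell$n_cycles),
    comparison = comparison)

  if (!is.null(out_dir)) {
    run_stage("report", {
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
      purrr::iwalk(rms, function(rs, nm) {
        utils::write.csv(rs, file.path(out_dir, sprintf("rms_%s.csv", nm)),
                         row.names = FALSE)
      })
      if (!is.null(seg_out)) {
        utils::write.csv(as.data.frame(seg_out),
                         file.path(out_dir, "segments.csv"), row.names = FALSE)
      }
      purrr::iwalk(filtered, function(tr, nm) {
        grDevices::png(file.path(out_dir, sprintf("trace_%s.png", nm)),
                       width = 900, height = 500)
        print(plot_trace(tr, max_points = 5000))
        grDevices::dev.off()
        grDevices::png(file.path(out_dir, sprintf("rms_%s.png", nm)),
                       width = 900, height = 400)
        print(ggplot2::autoplot(rms[[nm]]))
        grDevices::dev.off()
      })
    })
    say("report", "done")
  }
  invisible(list(summary = summary, traces = filtered, rms = rms,
                 segments = seg_out, events = events, dwell = dwell,
                 comparison = comparison))
}
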