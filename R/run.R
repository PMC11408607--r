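#' Reproduction run configuration
#'
#' Bundles everything needed to reproduce one of the three experimental
#' designs end to end, or a custom protocol set. The presets encode the
#' published designs: `"fig2"` — background-plus-pulse at one concentration
#' level (8 flies at low, 6 at high, 3 trials each); `"fig3"` — the
#' 15-stimulus onset-asynchrony set at low concentration, 8 flies, 10
#' trials; `"fig4"` — the five 10-s fluctuating-mixture stimuli, 8 flies
#' (high) or 6 (low), 5 trials.
#'
#' @param experiment `"fig2"`, `"fig3"`, `"fig4"`, or `"custom"`.
#' @param seed Master seed.
#' @param level Concentration level of the run.
#' @param n_flies,n_trials Design size; `NULL` takes the preset default.
#' @param params A [sensillum_params()].
#' @param sigma Alpha-kernel time constant, seconds.
#' @param q Victor-Purpura cost factor, 1/s.
#' @param sort Sort synthesized voltage traces instead of using ground-truth
#'   trains (slower; requires trace synthesis).
#' @param protocols Protocol list for `experiment = "custom"`.
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @return An object of class `run_config`.
#' @export
run_config <- function(experiment = c("fig3", "fig2", "fig4", "custom"),
                       seed = 1, level = NULL, n_flies = NULL,
                       n_trials = NULL, params = sensillum_params(),
                       sigma = 0.050, q = 20, sort = FALSE,
                       protocols = NULL, out_dir = NULL) {
  experiment <- match.arg(experiment)
  defaults <- switch(experiment,
                     fig2 = list(level = "high", n_flies = 6, n_trials = 3),
                     fig3 = list(level = "low", n_flies = 8, n_trials = 10),
                     fig4 = list(level = "high", n_flies = 8, n_trials = 5),
                     custom = list(level = "low", n_flies = 8, n_trials = 5))
  level <- level %||% defaults$level
  if (experiment == "fig2" && is.null(n_flies)) {
    n_flies <- if (level == "low") 8 else 6
  }
  if (experiment == "fig4" && is.null(n_flies)) {
    n_flies <- if (level == "low") 6 else 8
  }
  n_flies <- n_flies %||% defaults$n_flies
  n_trials <- n_trials %||% defaults$n_trials
  stopifnot(n_flies >= 1, n_trials >= 1, sigma > 0, q >= 0,
            level %in% c("low", "high"),
            inherits(params, "sensillum_params"))
  if (experiment == "custom" && is.null(protocols)) {
    stop("custom runs need a protocol list")
  }
  structure(list(experiment = experiment, seed = seed, level = level,
                 n_flies = n_flies, n_trials = n_trials, params = params,
                 sigma = sigma, q = q, sort = sort, protocols = protocols,
                 out_dir = out_dir),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s: %d flies x %d trials, %s concentration\n",
              x$experiment, x$n_flies, x$n_trials, x$level))
  cat(sprintf("  seed %d, sigma %g s, q %g /s, sort = %s\n",
              x$seed, x$sigma, x$q, x$sort))
  cat(sprintf("  coupling g_AB = %.3g, g_BA = %.3g, fly jitter CV %.2g\n",
              x$params$g_AB, x$params$g_BA, x$params$fly_jitter_cv))
  invisible(x)
}

#' Run a full simulated experiment and its analysis
#'
#' Executes the pipeline stages in order — stimulus construction, sensillum
#' simulation, optional spike sorting, response metrics, statistics — for the
#' configured design. Identical configuration and seed give identical
#' results. When `out_dir` is set, all tables are written as CSV together
#' with a JSON manifest recording the configuration and file hashes.
#'
#' @param config A [run_config()].
#' @return List of class `run_result` with elements `config`, `trials`
#'   (the [trial_table()]), `responses`, experiment-specific analysis tables
#'   (`battery`, `window_width_ms`, `regression` for fig3; `paired_tests`
#'   for fig2; `dvp`, `utests` for fig4), and `manifest` when files were
#'   written.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  protocols <- switch(config$experiment,
                      fig2 = protocols_background_pulse(config$level),
                      fig3 = protocols_asynchrony(config$level),
                      fig4 = protocols_fluctuating(config$level,
                                                   seedA = derive_seed(config$seed, 9001),
                                                   seedB = derive_seed(config$seed, 9002)),
                      custom = config$protocols)
  tt <- simulate_experiment(protocols, config$params,
                            n_flies = config$n_flies,
                            n_trials = config$n_trials,
                            seed = config$seed,
                            synthesize = config$sort)
  analysis_tt <- if (config$sort) sort_trial_table(tt) else tt

  out <- list(config = config, trials = tt)
  if (config$experiment == "fig2") {
    resp <- compute_response_table(analysis_tt, "window_mean_rate")
    out$responses <- resp
    out$paired_tests <- fig2_paired_tests(resp)
  } else if (config$experiment %in% c("fig3", "custom")) {
    resp <- compute_response_table(analysis_tt, "peak_rate",
                                   sigma = config$sigma)
    out$responses <- resp
    if (config$experiment == "fig3") {
      norm <- normalize_to_cognate(resp)
      out$normalized <- norm
      out$battery <- asynchrony_test_battery(norm)
      out$window_width_ms <- synchrony_window_width(out$battery, unit = "B")
      out$regression <- pooled_synchrony_regression(norm, unit = "B")
    }
  } else if (config$experiment == "fig4") {
    out$responses <- compute_response_table(analysis_tt, "peak_rate",
                                            sigma = config$sigma,
                                            window = c(0, 10))
    out$dvp <- do.call(rbind, lapply(c("A", "B"), function(u) {
      pairs <- if (u == "A") {
        list(c("A", "A"), c("AB_i", "AB_i"), c("AB_i", "A"), c("AB_A", "A"))
      } else {
        list(c("B", "B"), c("AB_i", "AB_i"), c("AB_i", "B"), c("AB_B", "B"))
      }
      dvp_comparison_groups(analysis_tt, q = config$q, pairs = pairs,
                            unit = u)
    }))
    out$utests <- do.call(rbind, lapply(c("A", "B"), function(u) {
      du <- out$dvp[out$dvp$unit == u, ]
      groups <- split(du$d_vp, du$pair)
      cmp <- if (u == "A") {
        list(c("(A, A)", "(AB_i, A)"), c("(AB_i, A)", "(AB_A, A)"))
      } else {
        list(c("(B, B)", "(AB_i, B)"), c("(AB_i, B)", "(AB_B, B)"))
      }
      res <- utest_bonferroni(groups, cmp)
      res$unit <- u
      res
    }))
  }
  if (!is.null(config$out_dir)) {
    out$manifest <- write_run_outputs(out, config$out_dir)
  }
  class(out) <- "run_result"
  out
}

# Fig 2-style paired tests: cognate-alone vs with-incognate window rates,
# per unit, on per-fly means
fig2_paired_tests <- function(resp) {
  cmps <- list(
    list(unit = "B", alone = "B", mixed = "A on B"),
    list(unit = "A", alone = "A", mixed = "B on A")
  )
  do.call(rbind, lapply(cmps, function(cm) {
    ru <- resp[resp$unit == cm$unit, ]
    alone <- tapply(ru$value[ru$stimulus_id == cm$alone],
                    ru$fly_id[ru$stimulus_id == cm$alone], mean)
    mixed <- tapply(ru$value[ru$stimulus_id == cm$mixed],
                    ru$fly_id[ru$stimulus_id == cm$mixed], mean)
    flies <- intersect(names(alone), names(mixed))
    res <- paired_t_test(alone[flies], mixed[flies],
                         comparison = paste0(cm$unit, ": ", cm$alone,
                                             " vs ", cm$mixed))
    res$mean_alone <- mean(alone[flies])
    res$mean_mixed <- mean(mixed[flies])
    res
  }))
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %s (seed %d)\n", x$config$experiment,
              x$config$seed))
  print(x$trials)
  if (!is.null(x$window_width_ms)) {
    cat(sprintf("  synchrony window width: %g ms\n", x$window_width_ms))
  }
  if (!is.null(x$paired_tests)) print(x$paired_tests)
  if (!is.null(x$utests)) print(x$utests)
  invisible(x)
}

# write all tables + JSON manifest; returns the manifest
write_run_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  p <- function(name) file.path(dir, name)
  write_spike_csv(out$trials, p("spikes.csv"))
  files <- c(files, p("spikes.csv"))
  for (nm in c("responses", "normalized", "battery", "dvp", "utests",
               "paired_tests")) {
    if (!is.null(out[[nm]])) {
      utils::write.csv(out[[nm]], p(paste0(nm, ".csv")), row.names = FALSE)
      files <- c(files, p(paste0(nm, ".csv")))
    }
  }
  cfg <- out$config
  manifest <- list(
    experiment = cfg$experiment, seed = cfg$seed, level = cfg$level,
    n_flies = cfg$n_flies, n_trials = cfg$n_trials, sigma = cfg$sigma,
    q = cfg$q, sort = cfg$sort,
    g_AB = cfg$params$g_AB, g_BA = cfg$params$g_BA,
    fly_jitter_cv = cfg$params$fly_jitter_cv,
    package_version = as.character(utils::packageVersion("sensillum")),
    window_width_ms = if (!is.null(out$window_width_ms))
      as.numeric(out$window_width_ms) else NULL,
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- p("manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}

#' Write / read spike trains as long-format CSV
#'
#' Columns: `fly_id`, `stimulus_id`, `mixture_mode`, `onset_asynchrony_ms`,
#' `level`, `trial`, `unit`, `spike_time_s`. Spike times are written with
#' microsecond precision and round-trip losslessly at that precision; trains
#' without any spike have no rows in the long format and are therefore
#' absent after a round trip. On read, unsorted spike times within a train
#' are sorted with a warning, and missing required columns raise an error
#' naming the column.
#'
#' @param tt A [trial_table()].
#' @param path CSV file path.
#' @return `write_spike_csv()` returns `path` invisibly; `read_spike_csv()`
#'   returns a [trial_table()] (without protocols or traces).
#' @export
write_spike_csv <- function(tt, path) {
  stopifnot(inherits(tt, "trial_table"))
  tr <- tt$trains
  n <- lengths(tr$times)
  long <- data.frame(
    fly_id = rep(tr$fly_id, n),
    stimulus_id = rep(tr$stimulus_id, n),
    mixture_mode = rep(tr$mixture_mode, n),
    onset_asynchrony_ms = rep(tr$onset_asynchrony_ms, n),
    level = rep(tr$level, n),
    trial = rep(tr$trial, n),
    unit = rep(tr$unit, n),
    spike_time_s = sprintf("%.6f", unlist(tr$times))
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  required <- c("fly_id", "stimulus_id", "mixture_mode",
                "onset_asynchrony_ms", "level", "trial", "unit",
                "spike_time_s")
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(long))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  key <- interaction(long$fly_id, long$stimulus_id, long$trial, long$unit,
                     drop = TRUE)
  idx <- !duplicated(key)
  trains <- data.frame(
    fly_id = long$fly_id[idx], stimulus_id = long$stimulus_id[idx],
    onset_asynchrony_ms = long$onset_asynchrony_ms[idx],
    mixture_mode = long$mixture_mode[idx], level = long$level[idx],
    trial = long$trial[idx], unit = long$unit[idx]
  )
  times <- split(as.numeric(long$spike_time_s), key)[as.character(unique(key))]
  n_unsorted <- sum(vapply(times, is.unsorted, logical(1)))
  if (n_unsorted > 0) {
    warning("unsorted spike times in ", n_unsorted, " train(s); sorting")
  }
  sorted <- lapply(times, function(x) if (is.unsorted(x)) sort(x) else x)
  trains$times <- unname(sorted)
  trial_table(trains, protocols = NULL, params = NULL)
}
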