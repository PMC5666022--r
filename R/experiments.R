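#' Preset experiment specifications
#'
#' The standard experiments of the droplet-model study, each a named recipe
#' of parameters, trial counts and requested analyses:
#'
#' \describe{
#'   \item{`"fig2"`}{interdrop-interval distribution P(DT), TM variant at
#'     default parameters, 100 trials.}
#'   \item{`"fig3"`}{fluctuation function and scaling exponent, TM defaults.}
#'   \item{`"fig4a"`/`"fig4b"`}{increment-magnitude model selection for the
#'     TM and NTM variants at defaults, 5 trials pooled.}
#'   \item{`"fig4c"`/`"fig4d"`}{as `fig4a` with the initial threshold set to
#'     3 and 7.}
#'   \item{`"fig5"`}{broad-movement parameter set (threshold 3, descent
#'     probability 0.5, lateral 0.25/0.25): P(DT) and aspect ratios.}
#'   \item{`"s3"`}{entry position drawn uniformly from three heights at and
#'     below the rod; increment model selection.}
#' }
#'
#' @param name Preset name.
#' @param seed Master seed stored in the returned parameters.
#' @return An `experiment_spec`: list with `name`, `params`, `n_trials`, and
#'   the set of requested `outputs`.
#' @examples
#' experiment_preset("fig4a", seed = 1)$params$variant
#' @export
experiment_preset <- function(name = c("fig2", "fig3", "fig4a", "fig4b",
                                       "fig4c", "fig4d", "fig5", "s3"),
                              seed = 1L) {
  name <- match.arg(name)
  three_heights <- list(c(500L, 500L), c(500L, 499L), c(500L, 498L))
  spec <- switch(name,
    fig2 = list(params = sim_params(seed = seed),
                n_trials = 100L, outputs = c("events", "histogram", "summary")),
    fig3 = list(params = sim_params(seed = seed),
                n_trials = 100L, outputs = c("events", "fluctuation", "summary")),
    fig4a = list(params = sim_params(n_trials = 5L, seed = seed),
                 n_trials = 5L, outputs = c("events", "fits", "summary")),
    fig4b = list(params = sim_params(variant = "NTM", n_trials = 5L, seed = seed),
                 n_trials = 5L, outputs = c("events", "fits", "summary")),
    fig4c = list(params = sim_params(threshold0 = 3, n_trials = 5L, seed = seed),
                 n_trials = 5L, outputs = c("events", "fits", "summary")),
    fig4d = list(params = sim_params(threshold0 = 7, n_trials = 5L, seed = seed),
                 n_trials = 5L, outputs = c("events", "fits", "summary")),
    fig5 = list(params = sim_params(threshold0 = 3, prob_y_minus = 0.5,
                                    prob_x_plus = 0.25, prob_x_minus = 0.25,
                                    seed = seed),
                n_trials = 100L,
                outputs = c("events", "histogram", "aspect", "summary")),
    s3 = list(params = sim_params(entry_positions = three_heights,
                                  n_trials = 5L, seed = seed),
              n_trials = 5L, outputs = c("events", "fits", "summary")))
  spec$name <- name
  class(spec) <- "experiment_spec"
  spec
}

#' Run an experiment end to end
#'
#' Runs the trials of an [experiment_preset()] (or a hand-built spec of the
#' same shape), computes the requested observables and statistics, and —
#' when `out_dir` is given — writes the artefacts: the event-log CSV, the
#' per-step metrics CSV, any histogram/fluctuation CSVs and a summary JSON.
#' Re-running with the same seed regenerates identical artefacts.
#'
#' @param spec An `experiment_spec`.
#' @param out_dir Output directory (created if missing); `NULL` for no files.
#' @param quiet Suppress the per-trial progress line on stderr?
#' @return A list with the batch, the computed `summary` (droplet tempo,
#'   sizes, and the requested statistics) and the artefact paths written.
#' @export
run_experiment <- function(spec, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(spec, "experiment_spec") ||
            all(c("name", "params", "n_trials", "outputs") %in% names(spec)))
  keep_metrics <- "aspect" %in% spec$outputs
  if (!quiet)
    message(sprintf("[%s] running %d trial(s) of %s (seed %d)", spec$name,
                    spec$n_trials, spec$params$variant, spec$params$seed))
  batch <- run_trials(spec$params, n_trials = spec$n_trials,
                      keep_metrics = keep_metrics)
  series <- intervals_from_events(batch$events)
  summary <- list(
    name = spec$name, variant = spec$params$variant,
    n_trials = spec$n_trials, seed = spec$params$seed,
    droplets_per_trial = mean(batch$summary$n_droplets),
    mean_droplet_size = if (nrow(batch$events)) mean(batch$events$size) else NA,
    sd_droplet_size = if (nrow(batch$events) > 1) sd(batch$events$size) else NA)
  hist_df <- NULL
  if ("histogram" %in% spec$outputs)
    hist_df <- interval_histogram(series)
  if ("fluctuation" %in% spec$outputs) {
    al <- vapply(series$dt_by_trial, function(d) {
      if (length(d) >= 20) fluctuation_function(d)$alpha else NA_real_
    }, numeric(1))
    summary$alpha <- mean(al, na.rm = TRUE)
  }
  if ("fits" %in% spec$outputs) {
    mc <- compare_increment_models(series)
    summary <- c(summary, list(
      n_increments = mc$n_obs,
      mu = mc$power_law$parameter,
      lambda = mc$exponential$parameter,
      akaike_weight_power_law = unname(mc$akaike_weights["power_law"]),
      preferred_model = mc$preferred,
      g_statistic = mc$g_statistic, df = mc$df, p_value = mc$p_value))
  }
  if ("aspect" %in% spec$outputs) {
    ar <- aspect_ratio_track(batch$metrics)
    summary$mean_max_width <- ar$mean_max_width
    summary$mean_max_height <- ar$mean_max_height
  }
  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pre <- file.path(out_dir, spec$name)
    paths["events"] <- write_event_log(batch, paste0(pre, "_events.csv"))
    if (keep_metrics) {
      write.csv(batch$metrics, paste0(pre, "_metrics.csv"), row.names = FALSE)
      paths["metrics"] <- paste0(pre, "_metrics.csv")
    }
    if (!is.null(hist_df)) {
      write.csv(hist_df, paste0(pre, "_pdt.csv"), row.names = FALSE)
      paths["histogram"] <- paste0(pre, "_pdt.csv")
    }
    jsonlite::write_json(summary, paste0(pre, "_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths["summary"] <- paste0(pre, "_summary.json")
  }
  list(batch = batch, summary = summary, paths = paths)
}
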