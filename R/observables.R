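#' Interdrop intervals and increments from an event log
#'
#' Computes, per trial, the interdrop intervals `DT(n) = t[n+1] - t[n]`
#' between consecutive droplet events and the interdrop increments
#' `I(n) = DT(n+1) - DT(n)`.  Intervals are never formed across trial
#' boundaries; a trial with fewer than two events contributes no intervals.
#'
#' @param events Droplet-event data frame with columns `t` and `size`, and
#'   optionally `trial` (assumed a single trial when absent).  Events must
#'   be time-ordered within each trial.
#' @return An object of class `interval_series`: a list with `dt` and
#'   `increments` data frames (`trial`, `n`, value), the event `sizes`, and
#'   `dt_by_trial` (a list of per-trial interval vectors).
#' @examples
#' ev <- data.frame(t = c(10, 25, 27, 60), size = c(3, 1, 5, 2))
#' s <- intervals_from_events(ev)
#' s$dt$dt           # 15 2 33
#' s$increments$i    # -13 31
#' @export
intervals_from_events <- function(events) {
  events <- as.data.frame(events)
  if (is.null(events$trial)) events$trial <- rep(1L, nrow(events))
  trials <- if (nrow(events)) unique(events$trial) else integer()
  dt_by_trial <- list()
  dt <- list(); inc <- list()
  for (tr in trials) {
    e <- events[events$trial == tr, , drop = FALSE]
    e <- e[order(e$t), , drop = FALSE]
    if (anyDuplicated(e$t))
      stop("event times must be strictly ordered within a trial")
    d <- diff(e$t)
    dt_by_trial[[as.character(tr)]] <- d
    if (length(d)) {
      dt[[as.character(tr)]] <- data.frame(trial = tr, n = seq_along(d), dt = d)
      i <- diff(d)
      if (length(i))
        inc[[as.character(tr)]] <- data.frame(trial = tr, n = seq_along(i), i = i)
    }
  }
  out <- list(
    dt = if (length(dt)) do.call(rbind, dt) else
      data.frame(trial = integer(), n = integer(), dt = numeric()),
    increments = if (length(inc)) do.call(rbind, inc) else
      data.frame(trial = integer(), n = integer(), i = numeric()),
    sizes = events$size,
    dt_by_trial = dt_by_trial)
  rownames(out$dt) <- NULL
  rownames(out$increments) <- NULL
  class(out) <- "interval_series"
  out
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("<interval_series> %d interval(s) over %d trial(s)",
              nrow(x$dt), length(x$dt_by_trial)))
  if (nrow(x$dt))
    cat(sprintf("; mean DT %.2f, %d increment(s)", mean(x$dt$dt),
                nrow(x$increments)))
  cat("\n")
  invisible(x)
}

#' Normalised interdrop-interval histogram P(DT)
#'
#' @param dt Vector of pooled interdrop intervals (or an `interval_series`,
#'   whose pooled `dt` column is used).
#' @param bin_width Histogram bin width in time steps (>= 1).
#' @return Data frame with bin lower edge `dt`, count, and probability `p`
#'   (summing to 1).  Empty input gives an empty data frame.
#' @examples
#' interval_histogram(c(2, 2, 4))
#' @export
interval_histogram <- function(dt, bin_width = 1) {
  if (inherits(dt, "interval_series")) dt <- dt$dt$dt
  stopifnot(bin_width >= 1)
  if (!length(dt))
    return(data.frame(dt = numeric(), count = integer(), p = numeric()))
  lo <- floor(min(dt) / bin_width) * bin_width
  edges <- seq(lo, max(dt) + bin_width, by = bin_width)
  cnt <- tabulate(findInterval(dt, edges), nbins = length(edges) - 1)
  keep <- cnt > 0
  data.frame(dt = edges[-length(edges)][keep], count = cnt[keep],
             p = cnt[keep] / sum(cnt))
}

#' Structure extent at the step of maximum height
#'
#' From per-step metrics, records each trial's `(width, height)` at the step
#' where the hanging structure is deepest, and averages the two components
#' across trials.  Width is the horizontal extent of the inactive agents
#' (`max x - min x + 1`), height the vertical extent below the rod row.
#' Trials that never hold an inactive agent are excluded.
#'
#' @param metrics Per-step metrics data frame with columns `trial`, `t`,
#'   `width`, `height` (as produced by [run_trials()]).
#' @return List with `mean_max_width`, `mean_max_height` and the per-trial
#'   data frame `per_trial`.
#' @export
aspect_ratio_track <- function(metrics) {
  metrics <- as.data.frame(metrics)
  if (is.null(metrics$trial)) metrics$trial <- rep(1L, nrow(metrics))
  per <- lapply(split(metrics, metrics$trial), function(d) {
    if (all(d$height == 0)) return(NULL)
    j <- which.max(d$height)
    data.frame(trial = d$trial[1], t = d$t[j], width = d$width[j],
               height = d$height[j])
  })
  per <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  if (is.null(per) || !nrow(per))
    return(list(mean_max_width = NA_real_, mean_max_height = NA_real_,
                per_trial = per))
  list(mean_max_width = mean(per$width), mean_max_height = mean(per$height),
       per_trial = per)
}
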