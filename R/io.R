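#' Write and read event logs
#'
#' The event-log CSV pools droplet events and unsupported-agent removals in
#' one table with columns `trial`, `t`, `event_type` (`"droplet"` or
#' `"eq4_removal"`), `size` and `trigger_id` (removal rows carry size 1 and
#' the removed agent's id).
#'
#' @param batch A `sim_batch` from [run_trials()] (or a `sim_trial`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(batch, path) {
  ev <- batch$events
  eq <- batch$eq4_removals
  if (is.null(ev$trial)) ev$trial <- rep(1L, nrow(ev))
  if (is.null(eq$trial)) eq$trial <- rep(1L, nrow(eq))
  drop <- data.frame(trial = ev$trial, t = ev$t, event_type = "droplet",
                     size = ev$size, trigger_id = ev$trigger_id)
  rmv <- data.frame(trial = eq$trial, t = eq$t, event_type = "eq4_removal",
                    size = rep(1L, nrow(eq)), trigger_id = eq$id)
  log <- rbind(drop, rmv)
  log <- log[order(log$trial, log$t), ]
  write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @param droplets_only Drop the `eq4_removal` rows on read?
#' @export
read_event_log <- function(path, droplets_only = TRUE) {
  log <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "t", "event_type", "size", "trigger_id")
  if (!all(need %in% names(log)))
    stop("event log must have columns ", paste(need, collapse = ", "))
  if (droplets_only) log <- log[log$event_type == "droplet", , drop = FALSE]
  log
}

#' Read an interval or increment series from a single-column CSV
#'
#' For standalone use of the statistics layer on externally produced
#' event-interval series.
#'
#' @param path CSV path; the first column is used.
#' @return Numeric vector.
#' @export
read_series_csv <- function(path) {
  as.numeric(read.csv(path, stringsAsFactors = FALSE)[[1]])
}
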