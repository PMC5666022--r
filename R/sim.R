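#' Sub-model step functions
#'
#' Each function applies one sub-model of the droplet-growth model to a
#' world, exactly as [run_trial()] applies it inside its per-step loop (both
#' call the same compiled routines).  They exist so the individual rules can
#' be exercised and tested on hand-built configurations.
#'
#' \describe{
#'   \item{`spawn_agents()`}{`phi` new active agents enter, each at an entry
#'     position drawn uniformly from `params$entry_positions`.}
#'   \item{`move_down_step()`}{every active agent takes one synchronous move
#'     (down with `prob_y_minus`, right/left with `prob_x_plus` /
#'     `prob_x_minus`); an agent that moves onto a site holding no inactive
#'     agent (and not the rod) settles there and becomes inactive with
#'     threshold `threshold0`.  When two agents would settle on one site a
#'     uniform-random winner settles and the other stays active.}
#'   \item{`remove_unsupported()`}{one synchronous pass removing every
#'     inactive agent with no inactive agent (nor the rod) within
#'     `|dx| <= 1` in the row directly above; such removals are logged but
#'     are not droplets.}
#'   \item{`warning_signal_step()`}{inactive agents whose weight has reached
#'     `threshold - 1` signal; the active agent directly beneath a
#'     signalling agent climbs one site, uniformly among the up/diagonal-up
#'     sites that hold an inactive agent (the rod counts as climbable), and
#'     is flagged `moved_up` for this step.}
#'   \item{`threshold_coordination_step()`}{inactive agents with a `moved_up`
#'     active agent within Chebyshev distance 1 adapt their threshold using
#'     the local pattern estimated on the previous step: unstable pattern
#'     collapses the threshold to the current weight, stable pattern raises
#'     it by one.  The `TM_STABLE` / `TM_UNSTABLE` variants apply only one
#'     of the two rules; `NTM` skips the step.}
#'   \item{`local_pattern_step()`}{each inactive agent records its pattern:
#'     stable iff another inactive agent occupies the same row at
#'     `|dx| = 1` (the rod does not count).}
#'   \item{`fall_step()`}{inactive agents whose weight has reached their
#'     threshold shed their whole supporting area; all removals in the step
#'     merge into one droplet event and the triggering agent survives with
#'     weight 0.}
#' }
#'
#' @param world An `ant_world` object.
#' @param params A [sim_params()] object.
#' @name sub_models
#' @return The updated world; `remove_unsupported()` returns
#'   `list(world, removed_ids)`, `compute_weights()` returns
#'   `list(world, sites)` and `fall_step()` returns
#'   `list(world, event)` where `event` is a one-row droplet-event data
#'   frame or `NULL` when nothing fell.
NULL

#' @rdname sub_models
#' @export
spawn_agents <- function(world, params) {
  validate_sim_params(params)
  restore_world(cpp_spawn(world, params$phi, entry_matrix(params)))
}

#' @rdname sub_models
#' @export
move_down_step <- function(world, params) {
  restore_world(cpp_move_down(world, params$prob_y_minus, params$prob_x_plus,
                              params$prob_x_minus, params$threshold0))
}

#' @rdname sub_models
#' @export
remove_unsupported <- function(world) {
  res <- cpp_remove_unsupported(world)
  list(world = restore_world(res$world), removed_ids = res$removed_ids)
}

#' Weight-sharing supporting-area computation
#'
#' Computes the weight borne by every inactive agent.  The supporting area
#' of an inactive agent at `(x, y)` is the 3-wide column strictly below it,
#' `{|dx| <= 1, y' < y}`.  Every occupant (active or inactive) of an
#' occupied site `s` inside the area contributes `1/m(s)` to the supporter's
#' weight, where the multiplicity `m(s)` is the number of inactive agents
#' whose supporting area contains `s` — so each agent's unit mass is split
#' exactly among its supporters and total weight is conserved.
#'
#' @param world An `ant_world` object.
#' @return `list(world, sites)`: the world with the `weight` column updated
#'   (active agents always 0), and a data frame of occupied sites with their
#'   occupant count `n_agents` and multiplicity `m`.
#' @examples
#' w <- make_world(agents = data.frame(
#'   x = c(500, 500), y = c(499, 498), state = c("inactive", "active")))
#' compute_weights(w)$world$agents$weight
#' @export
compute_weights <- function(world) {
  res <- cpp_compute_weights(world)
  list(world = restore_world(res$world), sites = res$sites)
}

#' @rdname sub_models
#' @export
warning_signal_step <- function(world) {
  restore_world(cpp_warning_signal(world))
}

#' @rdname sub_models
#' @export
threshold_coordination_step <- function(world, params) {
  restore_world(cpp_threshold_coordination(world, variant_code(params$variant)))
}

#' @rdname sub_models
#' @export
local_pattern_step <- function(world) {
  restore_world(cpp_local_pattern(world))
}

#' @rdname sub_models
#' @export
fall_step <- function(world) {
  res <- cpp_fall(world)
  event <- NULL
  if (res$size > 0) {
    event <- data.frame(t = res$world$t, size = res$size,
                        trigger_id = res$trigger_id)
  }
  list(world = restore_world(res$world), event = event)
}

#' Run one simulation trial
#'
#' Executes `params$time_length` update steps of the chosen model variant.
#' Each step runs: spawn, move down, removal of unsupported agents, weight
#' calculation, warning signals, then — for the threshold-modified variants
#' — threshold coordination followed by local pattern calculation, and
#' finally the fall check (the `NTM` variant goes straight from warning
#' signals to the fall check).  The trajectory is fully determined by
#' `seed`.
#'
#' @param params A [sim_params()] object.
#' @param seed RNG seed; defaults to `params$seed`.
#' @param keep_metrics Record per-step structure metrics (`n_inactive`,
#'   `n_active`, `width`, `height`)?
#'
#' @return A list of class `sim_trial`: `events` (droplet events: `t`,
#'   `size`, `trigger_id`), `eq4_removals` (unsupported-agent removals:
#'   `t`, `id`), `metrics` (if requested), and the final `world`.
#' @examples
#' tr <- run_trial(sim_params(time_length = 300, seed = 7))
#' nrow(tr$events)
#' @export
run_trial <- function(params, seed = params$seed, keep_metrics = TRUE) {
  validate_sim_params(params)
  set.seed(as.integer(seed))
  res <- cpp_run_trial(params$phi, params$prob_y_minus, params$prob_x_plus,
                       params$prob_x_minus, params$threshold0,
                       params$time_length, variant_code(params$variant),
                       entry_matrix(params), params$rod[1], params$rod[2],
                       keep_metrics)
  res$world <- restore_world(res$world)
  res$params <- params
  res$seed <- as.integer(seed)
  class(res) <- "sim_trial"
  res
}

#' Run a batch of independent trials
#'
#' Runs `n_trials` trials with per-trial seeds derived from the master seed
#' by a fixed splitting rule (`seed + trial index`), so extending the trial
#' count never reshuffles earlier trials.
#'
#' @param params A [sim_params()] object.
#' @param n_trials Number of trials; defaults to `params$n_trials`.
#' @param seed Master seed; defaults to `params$seed`.
#' @param keep_metrics Record per-step structure metrics?
#'
#' @return A list of class `sim_batch`: `events` and `eq4_removals` (with a
#'   leading `trial` column), `metrics` (if requested) and `summary`
#'   (per-trial droplet counts and entered/removed tallies).
#' @examples
#' b <- run_trials(sim_params(time_length = 200, n_trials = 3, seed = 1))
#' b$summary
#' @export
run_trials <- function(params, n_trials = params$n_trials,
                       seed = params$seed, keep_metrics = TRUE) {
  validate_sim_params(params)
  ev <- vector("list", n_trials)
  eq <- vector("list", n_trials)
  mt <- if (keep_metrics) vector("list", n_trials) else NULL
  smry <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tr <- run_trial(params, seed = (as.numeric(seed) + i) %% 2147483647,
                    keep_metrics = keep_metrics)
    ev[[i]] <- cbind(trial = rep(i, nrow(tr$events)), tr$events)
    eq[[i]] <- cbind(trial = rep(i, nrow(tr$eq4_removals)), tr$eq4_removals)
    if (keep_metrics) mt[[i]] <- cbind(trial = rep(i, nrow(tr$metrics)), tr$metrics)
    smry[[i]] <- data.frame(
      trial = i, n_droplets = nrow(tr$events),
      agents_fallen = tr$world$n_removed_droplet,
      agents_entered = tr$world$n_entered,
      eq4_removed = tr$world$n_removed_eq4)
  }
  out <- list(
    events = do.call(rbind, ev),
    eq4_removals = do.call(rbind, eq),
    metrics = if (keep_metrics) do.call(rbind, mt) else NULL,
    summary = do.call(rbind, smry),
    params = params, seed = as.integer(seed))
  class(out) <- "sim_batch"
  out
}

#' @export
print.sim_trial <- function(x, ...) {
  cat(sprintf("<sim_trial> %s variant, %d steps, seed %d\n",
              x$params$variant, x$params$time_length, x$seed))
  cat(sprintf("  %d droplet events (total %g agents), %g unsupported removals\n",
              nrow(x$events), x$world$n_removed_droplet, x$world$n_removed_eq4))
  invisible(x)
}

#' @export
print.sim_batch <- function(x, ...) {
  cat(sprintf("<sim_batch> %s variant, %d trial(s) x %d steps, master seed %d\n",
              x$params$variant, nrow(x$summary), x$params$time_length, x$seed))
  cat(sprintf("  droplets/trial: mean %.1f (range %d-%d); mean size %.2f\n",
              mean(x$summary$n_droplets), min(x$summary$n_droplets),
              max(x$summary$n_droplets),
              if (nrow(x$events)) mean(x$events$size) else NA_real_))
  invisible(x)
}
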