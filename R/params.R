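#' Simulation parameters
#'
#' Bundles every run-level parameter of the droplet-growth model: the inflow
#' rate, the three movement probabilities of active agents, the initial
#' weight threshold assigned to an agent when it settles, the trial length,
#' the trial count, the model variant and the entry position(s) on or just
#' below the rod.  Defaults are the model's standard operating point: one
#' agent enters per time step at the rod, descends with probability 0.9 and
#' steps sideways with probability 0.05 each way, settles with threshold 5,
#' and a trial lasts 1000 steps.
#'
#' @param phi Integer inflow rate, agents entering per time step (>= 1).
#' @param prob_y_minus Probability an active agent steps down (-y).
#' @param prob_x_plus Probability an active agent steps right (+x).
#' @param prob_x_minus Probability an active agent steps left (-x).
#'   The three probabilities must sum to 1.
#' @param threshold0 Initial weight threshold given to an agent when it
#'   settles into the structure (> 0).
#' @param time_length Steps per trial (>= 1).
#' @param n_trials Number of trials for batch runs (>= 1).
#' @param variant Model variant: `"TM"` (full threshold coordination),
#'   `"NTM"` (fixed thresholds), `"TM_STABLE"` (raise-only rule) or
#'   `"TM_UNSTABLE"` (collapse-only rule).
#' @param entry_positions List of `c(x, y)` integer lattice coordinates from
#'   which each entering agent's position is drawn uniformly.  Every entry
#'   position must sit on the rod row or at most two rows below it.
#' @param rod `c(x, y)` coordinates of the rod, the single lattice site that
#'   feeds the structure.  Agents never occupy sites above the rod row.
#' @param seed Integer RNG seed for [run_trial()] / [run_trials()].
#'
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params(time_length = 200, n_trials = 5)
#' p
#' @export
sim_params <- function(phi = 1L,
                       prob_y_minus = 0.9,
                       prob_x_plus = 0.05,
                       prob_x_minus = 0.05,
                       threshold0 = 5,
                       time_length = 1000L,
                       n_trials = 100L,
                       variant = c("TM", "NTM", "TM_STABLE", "TM_UNSTABLE"),
                       entry_positions = list(c(500L, 500L)),
                       rod = c(500L, 500L),
                       seed = 1L) {
  variant <- match.arg(variant)
  p <- list(
    phi = as.integer(phi),
    prob_y_minus = as.numeric(prob_y_minus),
    prob_x_plus = as.numeric(prob_x_plus),
    prob_x_minus = as.numeric(prob_x_minus),
    threshold0 = as.numeric(threshold0),
    time_length = as.integer(time_length),
    n_trials = as.integer(n_trials),
    variant = variant,
    entry_positions = lapply(entry_positions, function(e) as.integer(e[1:2])),
    rod = as.integer(rod[1:2]),
    seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  probs <- c(p$prob_y_minus, p$prob_x_plus, p$prob_x_minus)
  errs <- character()
  if (is.na(p$phi) || p$phi < 1L)
    errs <- c(errs, "phi: inflow rate must be an integer >= 1")
  if (any(is.na(probs)) || any(probs < 0))
    errs <- c(errs, "prob_y_minus/prob_x_plus/prob_x_minus: probabilities must be >= 0")
  else if (abs(sum(probs) - 1) > 1e-8)
    errs <- c(errs, sprintf(
      "prob_y_minus/prob_x_plus/prob_x_minus: must sum to 1 (got %.6g)", sum(probs)))
  if (is.na(p$threshold0) || p$threshold0 <= 0)
    errs <- c(errs, "threshold0: weight threshold must be > 0")
  if (is.na(p$time_length) || p$time_length < 1L)
    errs <- c(errs, "time_length: must be >= 1")
  if (is.na(p$n_trials) || p$n_trials < 1L)
    errs <- c(errs, "n_trials: must be >= 1")
  if (length(p$entry_positions) < 1L)
    errs <- c(errs, "entry_positions: at least one entry position required")
  for (e in p$entry_positions) {
    if (length(e) != 2L || anyNA(e)) {
      errs <- c(errs, "entry_positions: each position must be c(x, y)")
      next
    }
    if (e[2] > p$rod[2])
      errs <- c(errs, sprintf(
        "entry_positions: (%d, %d) lies above the rod row y = %d", e[1], e[2], p$rod[2]))
    if (e[2] < p$rod[2] - 2L)
      errs <- c(errs, sprintf(
        "entry_positions: (%d, %d) lies more than 2 rows below the rod", e[1], e[2]))
  }
  if (length(errs))
    stop("invalid simulation parameters:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Droplet-model simulation parameters (", x$variant, " variant)\n", sep = "")
  cat(sprintf("  inflow phi            : %d agent(s)/step\n", x$phi))
  cat(sprintf("  move probs (-y,+x,-x) : %.3g / %.3g / %.3g\n",
              x$prob_y_minus, x$prob_x_plus, x$prob_x_minus))
  cat(sprintf("  initial threshold     : %g\n", x$threshold0))
  cat(sprintf("  trial length / count  : %d steps x %d trials\n",
              x$time_length, x$n_trials))
  cat(sprintf("  rod at (%d, %d); %d entry position(s); seed %d\n",
              x$rod[1], x$rod[2], length(x$entry_positions), x$seed))
  invisible(x)
}

variant_code <- function(variant) {
  match(variant, c("TM", "NTM", "TM_STABLE", "TM_UNSTABLE")) - 1L
}

entry_matrix <- function(p) {
  do.call(rbind, p$entry_positions)
}

#' Validate a raw configuration list
#'
#' Fills omitted keys with the standard defaults and validates the result.
#' Accepts the flat key set used by [read_config()]: `phi`, `prob_y_minus`,
#' `prob_x_plus`, `prob_x_minus`, `threshold` (alias of `threshold0`),
#' `time_length`, `n_trials`, `variant`, `entry_positions`, `rod`, `seed`.
#'
#' @param raw Named list of configuration values (possibly empty).
#' @return A validated [sim_params()] object.
#' @examples
#' validate_config(list(threshold = 3, variant = "NTM"))
#' @export
validate_config <- function(raw = list()) {
  if (!is.list(raw)) stop("config must be a named list", call. = FALSE)
  if (!is.null(raw$threshold) && is.null(raw$threshold0)) {
    raw$threshold0 <- raw$threshold
    raw$threshold <- NULL
  }
  known <- names(formals(sim_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(raw$entry_positions) && !is.list(raw$entry_positions))
    raw$entry_positions <- list(raw$entry_positions)
  do.call(sim_params, raw)
}

#' Read a simulation configuration file
#'
#' Reads a flat YAML key-value file (see [validate_config()] for the key
#' set) and returns validated parameters; keys not present fall back to the
#' defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated [sim_params()] object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}
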