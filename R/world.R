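#' Construct a lattice world
#'
#' Builds the simulation state: the rod site, the agent table and the
#' running removal counters.  Mostly useful for constructing fixtures and
#' for stepping the sub-models one at a time; [run_trial()] builds its own
#' world internally.
#'
#' @param rod `c(x, y)` rod coordinates.
#' @param agents Data frame with columns `id`, `x`, `y`, `state`
#'   (`"active"`/`"inactive"`), and optionally `threshold`, `weight`,
#'   `moved_up`, `last_pattern` (`"undefined"`/`"stable"`/`"unstable"`).
#'   Missing optional columns are filled with defaults.
#' @param t Current time step.
#'
#' @return An object of class `ant_world`.
#' @examples
#' w <- make_world(agents = data.frame(x = 500, y = 499, state = "inactive"))
#' w
#' @export
make_world <- function(rod = c(500L, 500L), agents = NULL, t = 0L) {
  if (is.null(agents)) {
    agents <- data.frame(id = integer(), x = integer(), y = integer(),
                         state = character(), threshold = numeric(),
                         weight = numeric(), moved_up = logical(),
                         last_pattern = character(),
                         stringsAsFactors = FALSE)
  } else {
    agents <- as.data.frame(agents, stringsAsFactors = FALSE)
    n <- nrow(agents)
    if (is.null(agents$id)) agents$id <- seq_len(n)
    if (is.null(agents$state)) agents$state <- rep("inactive", n)
    if (is.null(agents$threshold)) agents$threshold <- rep(0, n)
    if (is.null(agents$weight)) agents$weight <- rep(0, n)
    if (is.null(agents$moved_up)) agents$moved_up <- rep(FALSE, n)
    if (is.null(agents$last_pattern)) agents$last_pattern <- rep("undefined", n)
    agents <- agents[, c("id", "x", "y", "state", "threshold", "weight",
                         "moved_up", "last_pattern")]
    agents$id <- as.integer(agents$id)
    agents$x <- as.integer(agents$x)
    agents$y <- as.integer(agents$y)
    agents$threshold <- as.numeric(agents$threshold)
    agents$weight <- as.numeric(agents$weight)
  }
  w <- list(
    rod = as.integer(rod[1:2]),
    t = as.integer(t),
    next_id = if (nrow(agents)) max(agents$id) + 1L else 1L,
    n_entered = as.numeric(nrow(agents)),
    n_removed_droplet = 0,
    n_removed_eq4 = 0,
    agents = agents
  )
  class(w) <- "ant_world"
  validate_world(w)
  w
}

validate_world <- function(w) {
  a <- w$agents
  if (any(a$y > w$rod[2]))
    stop("world invariant violated: agent above the rod row", call. = FALSE)
  ina <- a[a$state == "inactive", , drop = FALSE]
  if (nrow(ina)) {
    key <- paste(ina$x, ina$y)
    if (anyDuplicated(key))
      stop("world invariant violated: two inactive agents on one site",
           call. = FALSE)
    if (any(ina$x == w$rod[1] & ina$y == w$rod[2]))
      stop("world invariant violated: inactive agent on the rod site",
           call. = FALSE)
  }
  invisible(w)
}

#' @export
print.ant_world <- function(x, ...) {
  a <- x$agents
  cat(sprintf(
    "<ant_world> t = %d, rod (%d, %d): %d inactive + %d active agent(s)\n",
    x$t, x$rod[1], x$rod[2],
    sum(a$state == "inactive"), sum(a$state == "active")))
  cat(sprintf("  entered %g | fallen in droplets %g | unsupported removals %g\n",
              x$n_entered, x$n_removed_droplet, x$n_removed_eq4))
  invisible(x)
}

restore_world <- function(w) {
  class(w) <- "ant_world"
  w
}
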