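# World builders and independent oracles shared across the suite.

# Weight-sharing worked example: supporter k with lateral neighbours L and R,
# three agents stacked in k's own column, two in the column below-left and
# one below-right.  Expected weights (k, L, R) = (2.5, 2.0, 1.5).
fig1b_world <- function(load_state = "inactive") {
  sup <- data.frame(id = 1:3, x = c(500L, 499L, 501L), y = 495L,
                    state = "inactive", threshold = 5)
  loads <- data.frame(
    id = 4:9,
    x = c(500L, 500L, 500L, 499L, 499L, 501L),
    y = c(494L, 493L, 492L, 494L, 493L, 494L),
    state = load_state, threshold = 5)
  make_world(agents = rbind(sup, loads))
}

# Brute-force row-sharing weight computation straight from the definition:
# every occupant of an occupied site s strictly below supporter k (|dx| <= 1)
# contributes n(s) / m, m = number of inactive agents in k's row whose
# supporting area also contains s.
brute_force_weights <- function(world) {
  a <- world$agents
  occ <- aggregate(list(n = rep(1L, nrow(a))), by = list(x = a$x, y = a$y),
                   FUN = sum)
  ina <- a[a$state == "inactive", , drop = FALSE]
  w <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (a$state[i] != "inactive") next
    tot <- 0
    for (s in seq_len(nrow(occ))) {
      if (abs(occ$x[s] - a$x[i]) > 1 || occ$y[s] >= a$y[i]) next
      m <- sum(ina$y == a$y[i] & abs(ina$x - occ$x[s]) <= 1)
      tot <- tot + occ$n[s] / m
    }
    w[i] <- tot
  }
  w
}

# Random structure below the rod: one inactive agent per site, optional
# stacked active agents.
random_world <- function(n_inactive = 20, n_active = 6, seed = 1) {
  set.seed(seed)
  sites <- expand.grid(x = 495:505, y = 490:499)
  pick <- sites[sample(nrow(sites), n_inactive), ]
  ina <- data.frame(id = seq_len(n_inactive), x = pick$x, y = pick$y,
                    state = "inactive", threshold = 5,
                    last_pattern = sample(c("stable", "unstable"), n_inactive,
                                          replace = TRUE))
  act <- data.frame(id = n_inactive + seq_len(n_active),
                    x = sample(495:505, n_active, replace = TRUE),
                    y = sample(490:499, n_active, replace = TRUE),
                    state = "active", threshold = 0,
                    last_pattern = "undefined")
  make_world(agents = rbind(ina, act))
}

default_params <- function(...) sim_params(...)

# Per-trial interdrop intervals from a batch, pooled alpha and model fits
batch_alpha <- function(batch, min_len = 20) {
  s <- intervals_from_events(batch$events)
  al <- vapply(s$dt_by_trial, function(d) {
    if (length(d) >= min_len) fluctuation_function(d)$alpha else NA_real_
  }, numeric(1))
  mean(al, na.rm = TRUE)
}
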