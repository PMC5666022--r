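test_that("the rod supports agents directly and diagonally beneath it", {
  w <- make_world(agents = data.frame(x = c(500L, 501L), y = 499L,
                                      state = "inactive", threshold = 5))
  res <- remove_unsupported(w)
  expect_identical(nrow(res$world$agents), 2L)
  expect_length(res$removed_ids, 0)
})

test_that("an agent with no support in the row above is removed", {
  w <- make_world(agents = data.frame(id = 1L, x = 505L, y = 499L,
                                      state = "inactive", threshold = 5))
  res <- remove_unsupported(w)
  expect_identical(res$removed_ids, 1L)
  expect_identical(nrow(res$world$agents), 0L)
  expect_equal(res$world$n_removed_eq4, 1)
})

test_that("a dangling horizontal pair is removed in one synchronous pass", {
  # each member is judged against start-of-pass occupancy: neither has a
  # supporter in the row above, so both go even though they flank each other
  w <- make_world(agents = data.frame(id = 1:2, x = c(505L, 506L), y = 499L,
                                      state = "inactive", threshold = 5))
  res <- remove_unsupported(w)
  expect_setequal(res$removed_ids, 1:2)
})

test_that("support from one row above retains a hanging chain", {
  chain <- data.frame(id = 1:4, x = 500L, y = 499:496, state = "inactive",
                      threshold = 5)
  res <- remove_unsupported(make_world(agents = chain))
  expect_length(res$removed_ids, 0)
})

test_that("lateral contact in the same row marks the pattern stable", {
  w <- make_world(agents = data.frame(id = 1:2, x = c(500L, 501L), y = 497L,
                                      state = "inactive", threshold = 5))
  w <- local_pattern_step(w)
  expect_identical(w$agents$last_pattern, c("stable", "stable"))
})

test_that("a vertical chain and diagonal contacts are unstable", {
  chain <- make_world(agents = data.frame(x = 500L, y = 499:495,
                                          state = "inactive", threshold = 5))
  chain <- local_pattern_step(chain)
  expect_true(all(chain$agents$last_pattern == "unstable"))

  diag <- make_world(agents = data.frame(x = c(500L, 501L), y = c(497L, 496L),
                                         state = "inactive", threshold = 5))
  diag <- local_pattern_step(diag)
  expect_true(all(diag$agents$last_pattern == "unstable"))
})

test_that("the rod is not a lateral neighbour for pattern recognition", {
  w <- make_world(agents = data.frame(x = 501L, y = 500L, state = "inactive",
                                      threshold = 5))
  w <- local_pattern_step(w)
  expect_identical(w$agents$last_pattern, "unstable")
})

signalling_world <- function(weight, threshold = 5, side_sites = FALSE) {
  k <- data.frame(id = 1L, x = 500L, y = 498L, state = "inactive",
                  threshold = threshold, weight = weight)
  below <- data.frame(id = 2L, x = 500L, y = 497L, state = "active",
                      threshold = 0, weight = 0)
  agents <- rbind(k, below)
  if (side_sites)
    agents <- rbind(agents,
                    data.frame(id = 3:4, x = c(499L, 501L), y = 498L,
                               state = "inactive", threshold = threshold,
                               weight = 0))
  make_world(agents = agents)
}

test_that("a loaded agent signals at one below threshold and the agent beneath climbs", {
  w <- signalling_world(weight = 4.0)
  set.seed(1)
  w <- warning_signal_step(w)
  a <- w$agents[w$agents$id == 2L, ]
  expect_identical(c(a$x, a$y), c(500L, 498L))  # forced to the only occupied up-site
  expect_true(a$moved_up)
})

test_that("below the signalling band no active agent climbs", {
  w <- signalling_world(weight = 3.9)
  set.seed(1)
  w <- warning_signal_step(w)
  a <- w$agents[w$agents$id == 2L, ]
  expect_identical(c(a$x, a$y), c(500L, 497L))
  expect_false(a$moved_up)
})

test_that("with all three up-sites occupied the climb target is uniform", {
  tallies <- c(`499` = 0, `500` = 0, `501` = 0)
  set.seed(99)
  for (i in 1:3000) {
    w <- warning_signal_step(signalling_world(4.5, side_sites = TRUE))
    a <- w$agents[w$agents$id == 2L, ]
    expect_true(a$moved_up)
    tallies[as.character(a$x)] <- tallies[as.character(a$x)] + 1
  }
  sd3 <- 3 * sqrt(3000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(tallies - 1000) < sd3))
})

coord_world <- function(pattern, threshold = 5, weight = 4.2) {
  make_world(agents = data.frame(
    id = 1:2, x = c(500L, 500L), y = c(498L, 497L),
    state = c("inactive", "active"), threshold = c(threshold, 0),
    weight = c(weight, 0), moved_up = c(FALSE, TRUE),
    last_pattern = c(pattern, "undefined")))
}

test_that("an unstable agent near a climber collapses its threshold to its weight", {
  w <- threshold_coordination_step(coord_world("unstable"), sim_params())
  expect_equal(w$agents$threshold[1], 4.2)
})

test_that("a stable agent near a climber raises its threshold by one", {
  w <- threshold_coordination_step(coord_world("stable"), sim_params())
  expect_equal(w$agents$threshold[1], 6)
})

test_that("agents without a pattern estimate skip coordination", {
  w <- threshold_coordination_step(coord_world("undefined"), sim_params())
  expect_equal(w$agents$threshold[1], 5)
})

test_that("coordination requires a climber within Chebyshev distance one", {
  w <- coord_world("stable")
  w$agents$y[2] <- 495L  # too far away
  w <- threshold_coordination_step(w, sim_params())
  expect_equal(w$agents$threshold[1], 5)
})

test_that("variant gating applies only its own coordination rule", {
  ntm <- sim_params(variant = "NTM")
  st <- sim_params(variant = "TM_STABLE")
  un <- sim_params(variant = "TM_UNSTABLE")
  expect_equal(threshold_coordination_step(coord_world("unstable"), ntm)$agents$threshold[1], 5)
  expect_equal(threshold_coordination_step(coord_world("stable"), ntm)$agents$threshold[1], 5)
  expect_equal(threshold_coordination_step(coord_world("unstable"), st)$agents$threshold[1], 5)
  expect_equal(threshold_coordination_step(coord_world("stable"), st)$agents$threshold[1], 6)
  expect_equal(threshold_coordination_step(coord_world("unstable"), un)$agents$threshold[1], 4.2)
  expect_equal(threshold_coordination_step(coord_world("stable"), un)$agents$threshold[1], 5)
})
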