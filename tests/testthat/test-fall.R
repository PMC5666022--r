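breached_chain <- function(threshold = 5, weight = 5, extra_active = FALSE) {
  # trigger at the top of a 7-agent column; 6 descendants hang beneath it
  k <- data.frame(id = 1L, x = 500L, y = 499L, state = "inactive",
                  threshold = threshold, weight = weight)
  below <- data.frame(id = 2:7, x = 500L, y = 498:493, state = "inactive",
                      threshold = 5, weight = 0)
  agents <- rbind(k, below)
  if (extra_active)
    agents <- rbind(agents, data.frame(id = 8L, x = 500L, y = 495L,
                                       state = "active", threshold = 0,
                                       weight = 0))
  make_world(agents = agents)
}

test_that("a breached supporter sheds its whole supported set and survives", {
  set.seed(1)
  res <- fall_step(breached_chain())
  expect_identical(res$event$size, 6L)
  a <- res$world$agents
  expect_identical(a$id, 1L)            # only the trigger remains
  expect_equal(a$weight, 0)             # with its weight reset
  expect_identical(res$event$trigger_id, 1L)
  expect_equal(res$world$n_removed_droplet, 6)
})

test_that("the fall condition is threshold <= weight, strictly", {
  set.seed(1)
  res <- fall_step(breached_chain(threshold = 5, weight = 4.99))
  expect_null(res$event)
  expect_identical(nrow(res$world$agents), 7L)
  set.seed(1)
  res_eq <- fall_step(breached_chain(threshold = 5, weight = 5))
  expect_identical(res_eq$event$size, 6L)
})

test_that("active riders standing on the supported set fall with it", {
  set.seed(1)
  res <- fall_step(breached_chain(extra_active = TRUE))
  expect_identical(res$event$size, 7L)
  expect_identical(nrow(res$world$agents), 1L)
})

test_that("the supported set follows support links, not bare column occupancy", {
  # a second, laterally separated column is out of the trigger's set even
  # though partially inside its 3-wide supporting area
  k <- data.frame(id = 1L, x = 500L, y = 499L, state = "inactive",
                  threshold = 5, weight = 5)
  mine <- data.frame(id = 2:3, x = 500L, y = 498:497, state = "inactive",
                     threshold = 5, weight = 0)
  other <- data.frame(id = 4:5, x = 502L, y = 499:498, state = "inactive",
                      threshold = 5, weight = 0)
  set.seed(1)
  res <- fall_step(make_world(agents = rbind(k, mine, other)))
  expect_identical(res$event$size, 2L)
  expect_setequal(res$world$agents$id, c(1L, 4L, 5L))
})

test_that("all removals within a step merge into one ordered event", {
  # two simultaneous breaches, one droplet event with the pooled size
  a <- data.frame(id = 1:2, x = c(500L, 505L), y = 499L, state = "inactive",
                  threshold = c(5, 5), weight = c(5, 6))
  b <- data.frame(id = 3:6, x = c(500L, 500L, 505L, 505L), y = c(498L, 497L, 498L, 497L),
                  state = "inactive", threshold = 5, weight = 0)
  set.seed(1)
  res <- fall_step(make_world(agents = rbind(a, b)))
  expect_identical(res$event$size, 4L)
  expect_identical(nrow(res$world$agents), 2L)
})

test_that("a relieved breach does not fire after its load is already gone", {
  # the deeper agent is breached only through the set the upper breach sheds;
  # once that set is removed its weight is reset and it must not trigger
  top <- data.frame(id = 1L, x = 500L, y = 499L, state = "inactive",
                    threshold = 4, weight = 5)
  mid <- data.frame(id = 2L, x = 500L, y = 498L, state = "inactive",
                    threshold = 4, weight = 4)
  low <- data.frame(id = 3:4, x = 500L, y = 497:496, state = "inactive",
                    threshold = 5, weight = 0)
  seen <- integer()
  for (seed in 1:10) {
    set.seed(seed)
    res <- fall_step(make_world(agents = rbind(top, mid, low)))
    # top first: sheds mid + both low agents (size 3).  mid first: sheds the
    # two low agents, which empties top's area, resets its weight and
    # relieves its breach (size 2) — top must then not fire as well.
    expect_true(res$event$size %in% c(2L, 3L))
    expect_identical(res$event$size + nrow(res$world$agents), 4L)
    if (res$event$size == 2L)
      expect_setequal(res$world$agents$id, 1:2)
    seen <- union(seen, res$event$size)
  }
  expect_setequal(seen, c(2L, 3L))
})

test_that("after the fall pass no inactive agent is left in breach", {
  # every breach is either processed or relieved (weight reset to zero when
  # its supported load is removed by an earlier trigger)
  for (seed in 1:6) {
    w <- random_world(n_inactive = 22, n_active = 6, seed = seed)
    w <- compute_weights(w)$world
    w$agents$threshold[w$agents$state == "inactive"] <-
      pmax(w$agents$weight[w$agents$state == "inactive"] - 0.5, 0.5)
    set.seed(seed)
    res <- fall_step(w)
    a <- res$world$agents[res$world$agents$state == "inactive", ]
    expect_true(all(a$threshold > a$weight))
  }
})
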