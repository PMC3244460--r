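test_that("waiting-time draw is the exponential inverse transform", {
  expect_equal(draw_waiting_time(1, exp(-1)), 1)
  expect_equal(draw_waiting_time(2, exp(-1)), 0.5)
  expect_error(draw_waiting_time(0, 0.5), "positive")
  set.seed(21)
  taus <- vapply(runif(1e5), function(u) draw_waiting_time(4, u), numeric(1))
  expect_equal(mean(taus), 0.25, tolerance = 0.02)
})

test_that("reaction selection is proportional to the rates", {
  expect_equal(select_reaction(c(5, 0, 0), 0.3), 1L)
  # cumulative fractions 0.4, 0.4, 1.0: u = 0.5 falls in the third interval
  expect_equal(select_reaction(c(2, 0, 3), 0.5), 3L)
  expect_equal(select_reaction(c(1, 1), 0.25), 1L)
  expect_error(select_reaction(c(0, 0), 0.5), "zero")
  expect_error(select_reaction(c(-1, 2), 0.5), "negative")
})

test_that("a synchronized step overshoots to the sync and discards the draw", {
  sys <- two_process_system(1e-9, 0)  # nearly silent system
  set.seed(22)
  st <- step_synchronized(c(0, 0), 0, 1, sys)
  expect_identical(st$event, "synced")
  expect_identical(st$state, c(0, 0))
  expect_equal(st$t, 1)
  # zero total propensity syncs without consuming randomness
  sys0 <- two_process_system(0, 0)
  before <- .Random.seed
  st0 <- step_synchronized(c(0, 0), 0, 2.5, sys0)
  expect_identical(st0$event, "synced")
  expect_identical(before, .Random.seed)
  # a busy system fires
  sysb <- two_process_system(1e6, 0)
  stb <- step_synchronized(c(0, 0), 0, 1, sysb)
  expect_identical(stb$event, "fired")
  expect_identical(stb$state, c(1, 0))
})

test_that("no-op syncs leave SSA statistics invariant (memorylessness)", {
  r1 <- 1; r2 <- 3
  mean_wait <- 1 / (r1 + r2)
  horizon <- 4e4 * mean_wait
  set.seed(23)
  classic <- run_sync_ssa(two_process_system(r1, r2), c(0, 0),
                          sync_schedule(horizon * 10, horizon),
                          record = "times")
  iv_classic <- inter_event_times(classic)
  for (mult in c(0.1, 1, 10)) {
    synced <- run_sync_ssa(two_process_system(r1, r2), c(0, 0),
                           sync_schedule(mult * mean_wait, horizon),
                           record = "times")
    iv_sync <- inter_event_times(synced)
    expect_equal(mean(iv_sync), mean_wait, tolerance = 0.01)
    ks <- suppressWarnings(stats::ks.test(iv_classic, iv_sync))
    expect_gt(ks$p.value, 0.01)
    # per-process event shares follow the rates
    types <- synced$types[synced$types > 0]
    # binomial sd of the share is ~0.0022 at this event count
    expect_lt(abs(mean(types == 1) - r1 / (r1 + r2)), 0.012)
  }
})

test_that("sync hooks update the state exactly at multiples of dt_sync", {
  sys <- two_process_system(5, 0)
  seen <- numeric(0)
  hook <- function(state, t) { seen <<- c(seen, t); state }
  set.seed(24)
  run_sync_ssa(sys, c(0, 0), sync_schedule(0.5, 2.3), hook, record = "none")
  expect_equal(seen, c(0.5, 1.0, 1.5, 2.0))
  # a hook that zeroes the rates stops all events
  sysx <- reaction_system("X", matrix(1, 1, 1), function(s) if (s >= 1) 0 else 2)
  set.seed(25)
  tr <- run_sync_ssa(sysx, 0, sync_schedule(10, 100),
                     external_update = function(s, t) s + 1,
                     record = "times")
  ev <- tr$times[tr$types > 0]
  expect_true(all(ev < 10))
  # hooks may not return negative counts
  expect_error(
    run_sync_ssa(sys, c(0, 0), sync_schedule(0.5, 1),
                 external_update = function(s, t) s - 5, record = "none"),
    "negative")
})

test_that("pure-death process matches its closed-form mean decay", {
  d <- 0.1; X0 <- 30
  sys <- reaction_system("X", matrix(-1, 1, 1), function(s) d * s)
  set.seed(26)
  n_runs <- 1500
  fin <- replicate(n_runs,
    run_sync_ssa(sys, X0, sync_schedule(3, 10), record = "none")$final_state)
  expected <- X0 * exp(-d * 10)
  se <- sqrt(X0 * exp(-d * 10) * (1 - exp(-d * 10)) / n_runs)
  expect_lt(abs(mean(fin) - expected), 4 * se)
})

test_that("stationary distribution of a capped birth-death chain matches the master equation", {
  b <- 4; d <- 1; cap <- 20
  sys <- reaction_system("X", matrix(c(1, -1), 1, 2),
                         function(s) c(if (s < cap) b else 0, d * s))
  set.seed(27)
  tr <- run_sync_ssa(sys, 4, sync_schedule(1e9, 12000), record = "events")
  # time-weighted occupancy over the trajectory, after burn-in
  ev <- tr$types > 0
  times <- tr$times[ev]; states <- tr$states[ev, 1]
  keep <- times > 100
  times <- times[keep]; states <- states[keep]
  hold <- diff(c(times, tr$t_end))
  occ <- vapply(0:cap, function(k) sum(hold[states == k]), numeric(1))
  pi_hat <- occ / sum(occ)
  pi_exact <- birth_death_stationary(b, d, cap)
  expect_lt(max(abs(pi_hat - pi_exact)), 0.01)
})

test_that("trajectory recording is consistent and the horizon is respected", {
  sys <- two_process_system(2, 1)
  set.seed(28)
  tr <- run_sync_ssa(sys, c(0, 0), sync_schedule(0.5, 3), record = "events")
  expect_true(all(diff(tr$times) >= 0))
  expect_lte(max(tr$times), 3)
  expect_identical(unname(tr$final_state),
                   unname(tr$states[nrow(tr$states), ]))
  # event counts add up in the states
  n1 <- sum(tr$types == 1)
  expect_equal(tr$final_state[1], n1)
  # t_end = 0 yields only the initial state
  tr0 <- run_sync_ssa(sys, c(5, 5), sync_schedule(1, 0), record = "events")
  expect_identical(tr0$final_state, c(5, 5))
  expect_length(tr0$times, 0)
})
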