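truth_a <- make_ground_truth(1, "attractor")
arena_a <- make_arena_model()
cfg_small <- agent_config(n_flies = 3, duration = 120, light_on = 60,
                          entry_percentile = 100)

test_that("simulation is deterministic and conserves time and space", {
  f1 <- simulate_fly(cfg_small, arena_a, truth_a$encoder,
                     policy_from_truth(truth_a), seed = 51)
  f2 <- simulate_fly(cfg_small, arena_a, truth_a$encoder,
                     policy_from_truth(truth_a), seed = 51)
  expect_identical(f1$track, f2$track)
  expect_identical(f1$log, f2$log)
  # containment: no position beyond the wall
  expect_lte(max(sqrt(f1$track$x^2 + f1$track$y^2)), 1)
  # conservation: executed state durations tile the simulated time
  expect_equal(sum(f1$log$duration), cfg_small$duration,
               tolerance = 0.05 * cfg_small$duration)
  # every frame carries a state label
  expect_false(any(f1$track$state == ""))
  # starts at the center in a curved walk heading +x
  expect_equal(unlist(f1$track[1, c("x", "y")]), c(x = 0, y = 0))
  expect_equal(f1$log$state[1], "curved_walk")
})

test_that("pre-light behavior matches the generating distributions", {
  # light never turns on within the simulated window
  cfg <- agent_config(n_flies = 6, duration = 150, light_on = 1e6,
                      entry_percentile = 100)
  ts <- simulate_cohort(cfg, arena_a, truth_a$encoder,
                        policy_from_truth(truth_a), seed = 52)
  logs <- do.call(rbind, lapply(ts$flies, `[[`, "log"))
  cw <- logs[logs$state == "curved_walk" & is.finite(logs$speed), ]
  # sampled speeds follow the baseline lognormal (f ~ baseline, df ~ 0)
  s <- truth_surface(truth_a, "curved_walk", "avg_speed", 4.7, 0)
  se <- s$sdlog / sqrt(nrow(cw))
  expect_lt(abs(mean(log(cw$speed)) - s$meanlog), 4 * se)
  # no fly ever enters (no light): all first entries NA
  expect_true(all(is.na(ts$all_first_entries)))
})

test_that("the first-entry percentile filter works as specified", {
  cfg <- agent_config(n_flies = 20, duration = 240, light_on = 120,
                      entry_percentile = 100)
  ts <- simulate_cohort(cfg, arena_a, truth_a$encoder,
                        policy_from_truth(truth_a), seed = 53)
  expect_length(ts$flies, 20)             # percentile 100 keeps every fly
  cfg85 <- agent_config(n_flies = 20, duration = 240, light_on = 120,
                        entry_percentile = 85)
  ts85 <- simulate_cohort(cfg85, arena_a, truth_a$encoder,
                          policy_from_truth(truth_a), seed = 53)
  n_entered <- sum(is.finite(ts$all_first_entries))
  expect_lte(length(ts85$flies), n_entered)
  expect_gte(length(ts85$flies), floor(0.85 * n_entered) - 1)
  # identical master seed reproduces the cohort
  ts85b <- simulate_cohort(cfg85, arena_a, truth_a$encoder,
                           policy_from_truth(truth_a), seed = 53)
  expect_identical(ts85$first_entries, ts85b$first_entries)
})

test_that("null border-choice settings reduce to the plain model", {
  cfg_none <- agent_config(n_flies = 1, duration = 90, light_on = 30,
                           entry_percentile = 100)
  cfg_h0 <- agent_config(n_flies = 1, duration = 90, light_on = 30,
                         entry_percentile = 100,
                         border_choice_mode = "exponential",
                         border_hazard = 0)
  f_none <- simulate_fly(cfg_none, arena_a, truth_a$encoder,
                         policy_from_truth(truth_a), seed = 54)
  f_h0 <- simulate_fly(cfg_h0, arena_a, truth_a$encoder,
                       policy_from_truth(truth_a), seed = 54)
  expect_identical(f_none$track, f_h0$track)
  # filter mode with zero filters is also a no-op
  pol <- policy_from_truth(truth_a)
  pol$border_filters <- list(speed = rep(0, 200), curvature = rep(0, 200))
  cfg_f <- agent_config(n_flies = 1, duration = 90, light_on = 30,
                        entry_percentile = 100,
                        border_choice_mode = "filter")
  f_f <- simulate_fly(cfg_f, arena_a, truth_a$encoder, pol, seed = 54)
  expect_identical(f_none$track, f_f$track)
})

test_that("an active exponential border hazard adds turns near crossings", {
  cfg_on <- agent_config(n_flies = 4, duration = 240, light_on = 60,
                         entry_percentile = 100,
                         border_choice_mode = "exponential",
                         border_hazard = 4, border_tau = 0.5)
  cfg_off <- agent_config(n_flies = 4, duration = 240, light_on = 60,
                          entry_percentile = 100)
  n_turns <- function(cfg) {
    ts <- simulate_cohort(cfg, arena_a, truth_a$encoder,
                          policy_from_truth(truth_a), seed = 55)
    logs <- do.call(rbind, lapply(ts$flies, `[[`, "log"))
    sum(logs$state == "sharp_turn" & logs$start_t > cfg$light_on)
  }
  expect_gt(n_turns(cfg_on), n_turns(cfg_off))
})
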