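test_that("ridge solution equals the dense normal-equations oracle", {
  set.seed(7)
  n <- 400; d <- 25
  x <- stats::rnorm(n)
  r <- stats::rnorm(n)
  S <- hankel_design(x, d)
  for (lam in c(0.01, 1, 30)) {
    fit <- fit_filter(x, r, d = d, lambda_grid = lam)
    oracle <- solve(crossprod(S) + lam^2 * diag(d), crossprod(S, r))
    expect_equal(fit$taps, drop(oracle), tolerance = 1e-8)
  }
})

test_that("identity system and ridge shrinkage behave canonically", {
  set.seed(8)
  x <- stats::rnorm(600)
  fit <- fit_filter(x, x, d = 15, lambda_grid = 1e-6)
  expect_equal(fit$taps[1], 1, tolerance = 1e-4)
  expect_lt(max(abs(fit$taps[-1])), 1e-4)
  # ||taps|| decreases monotonically in lambda
  fit2 <- fit_filter(x, x, d = 15)
  expect_true(all(diff(fit2$solution_norms) <= 1e-12))
})

test_that("a known biphasic filter is recovered from noisy data", {
  set.seed(9)
  fs <- 100
  tt <- (0:29) / fs
  truth <- (tt / 0.05) * exp(1 - tt / 0.05) -
    0.5 * (tt / 0.12) * exp(1 - tt / 0.12)
  x <- stats::rnorm(6000)                      # 60 s white noise
  clean <- conv_causal(x, truth)
  r <- clean + stats::rnorm(6000, 0, stats::sd(clean) / sqrt(10))  # SNR 10
  fit <- fit_filter(x, r, d = 60)
  expect_lt(nrmse_taps(fit$taps, truth), 0.1)
  # selected solution matches the closed-form ridge at lambda*
  S <- hankel_design(x, 60)
  oracle <- solve(crossprod(S) + fit$lambda_star^2 * diag(60),
                  crossprod(S, r))
  expect_equal(fit$taps, drop(oracle), tolerance = 1e-6)
})

test_that("L-curve selection is scale-consistent", {
  set.seed(10)
  x <- stats::rnorm(2000)
  truth <- c(0.5, 1, -0.3, rep(0, 17))
  r <- conv_causal(x, truth) + stats::rnorm(2000, 0, 0.2)
  f1 <- fit_filter(x, r, d = 20)
  f2 <- fit_filter(x, 5 * r, d = 20, lambda_grid = f1$lambda_grid)
  expect_equal(f2$lambda_index, f1$lambda_index)
  expect_equal(f2$taps, 5 * f1$taps, tolerance = 1e-8)
})

test_that("cascade fits recover a generating cascade and predict cleanly", {
  truth <- make_ground_truth(1)
  # linear regime: an unrectified copy of the truth cascade, so the
  # noiseless generation oracle is exactly within the model class
  # (rectified responses are exercised by the SNR-10 recovery check)
  lin <- new_cascade(truth$encoder$filter1, truth$encoder$filter2,
                     baseline = 4.7, rectify = FALSE)
  set.seed(12)
  pats <- replicate(4, crossing_stimulus(6000), simplify = FALSE)
  resp <- lapply(pats, predict_response, cascade = lin)
  casc <- fit_cascade(pats, lapply(resp, `[[`, "lfp"),
                      lapply(resp, `[[`, "rate"),
                      d1 = 150, d2 = 150, baseline = 4.7)
  expect_lt(nrmse_taps(casc$filter1, truth$encoder$filter1), 0.05)
  expect_lt(nrmse_taps(casc$filter2, truth$encoder$filter2), 0.05)
  # held-out noiseless prediction R^2 ~ 1
  hold_s <- crossing_stimulus(3000)
  hold <- predict_response(lin, hold_s)
  casc$rectify <- FALSE
  pred <- predict_response(casc, hold_s)
  r2 <- 1 - sum((pred$rate - hold$rate)^2) /
    sum((hold$rate - mean(hold$rate))^2)
  expect_gt(r2, 0.999)
  # rate at baseline with arbitrary stimulus -> stage-2 taps ~ 0
  set.seed(13)
  s0 <- stats::rnorm(2000)
  l0 <- conv_causal(s0, truth$encoder$filter1)
  c0 <- fit_cascade(s0, l0, rep(4.7, 2000), d1 = 50, d2 = 50,
                    baseline = 4.7)
  expect_lt(max(abs(c0$filter2)), 1e-6)
})

test_that("prediction is linear in the LFP stage and baselined at rest", {
  truth <- make_ground_truth(1)
  casc <- truth$encoder
  expect_equal(predict_response(casc, rep(0, 300))$rate, rep(4.7, 300))
  set.seed(14)
  s1 <- stats::rnorm(500); s2 <- stats::rnorm(500)
  pa <- predict_response(casc, 2 * s1 + 3 * s2)$lfp
  pb <- 2 * predict_response(casc, s1)$lfp + 3 * predict_response(casc, s2)$lfp
  expect_equal(pa, pb, tolerance = 1e-10)
})

test_that("trial registration recovers affine distortions", {
  set.seed(15)
  tmpl <- stats::rnorm(500)
  # trial = 2 * template + 1 maps back onto the template exactly
  reg <- register_trials(cbind(tmpl, 2 * tmpl + 1))
  expect_equal(reg$gains[2], 0.5, tolerance = 1e-12)
  expect_equal(reg$offsets[2], -0.5, tolerance = 1e-12)
  expect_equal(reg$registered[, 2], tmpl, tolerance = 1e-12)
  # identical trials: identity registration
  reg2 <- register_trials(cbind(tmpl, tmpl, tmpl))
  expect_equal(reg2$mean, tmpl)
  # averaging noisy copies reduces residual to the template
  noisy <- sapply(1:3, function(i) tmpl + stats::rnorm(500, 0, 0.5))
  reg3 <- register_trials(cbind(tmpl, noisy), template = 1)
  res_mean <- mean((rowMeans(reg3$registered[, -1]) - tmpl)^2)
  res_single <- mean((reg3$registered[, 2] - tmpl)^2)
  expect_lt(res_mean, res_single)
  expect_error(register_trials(cbind(rep(1, 10), stats::rnorm(10))),
               "degenerate")
})

test_that("recording preprocessing separates LFP, spikes, and rate", {
  fs <- 10000
  # zero trace
  z <- preprocess_recording(rep(0, fs), fs = fs)
  expect_equal(z$lfp, rep(0, length(z$lfp)))
  expect_length(z$spike_times, 0)
  expect_equal(z$rate, rep(0, length(z$rate)))
  # single -1 mV spike in 10 s: rate integrates to ~1 spike
  v <- rep(0, 10 * fs)
  v[5 * fs + (0:10)] <- -1
  p <- preprocess_recording(v, fs = fs)
  expect_length(p$spike_times, 1)
  expect_equal(sum(p$rate) / 100, 1, tolerance = 0.01)
  # two valleys 3 ms apart below threshold: one spike retained
  v2 <- rep(0, fs)
  v2[3000 + (0:5)] <- -1
  v2[3030 + (0:5)] <- -0.9
  p2 <- preprocess_recording(v2, fs = fs)
  expect_length(p2$spike_times, 1)
  expect_error(preprocess_recording(rep(0, 100), fs = fs), "shorter")
})

test_that("voltage-to-intensity calibration fits a shifted ReLU", {
  v <- seq(0, 5, by = 0.5)
  I <- pmax(0, 3 * (v - 1))
  fit <- fit_voltage_to_intensity(v, I)
  expect_equal(fit$v0, 1, tolerance = 1e-3)
  expect_equal(fit$m, 3, tolerance = 1e-3)
  expect_equal(fit$map(0.5), 0)
  expect_error(fit_voltage_to_intensity(v, rep(0, 11)), "zero")
})

test_that("stimulus reconstruction evaluates the profile along the path", {
  arena <- make_arena_model()
  n <- 300
  tt <- (seq_len(n) - 1) / 30
  # fly crossing the border at constant speed
  x <- seq(0.9, 0, length.out = n)
  tr <- make_track(tt, x, rep(0, n))
  st <- reconstruct_stimulus(tr, arena, light_on_time = 0)
  r_at <- stats::approx(tt, x, xout = st$t)$y
  expect_equal(st$stimulus, arena$intensity(abs(r_at)), tolerance = 0.05)
  # parked at center: plateau after light-on, zero before
  trc <- make_track(tt, rep(0, n), rep(0, n))
  stc <- reconstruct_stimulus(trc, arena, light_on_time = 5)
  expect_equal(stc$stimulus[stc$t < 5], rep(0, sum(stc$t < 5)))
  expect_equal(stc$stimulus[stc$t >= 5.1],
               rep(arena$plateau_intensity, sum(stc$t >= 5.1)))
  # parked at the wall: always dark
  trw <- make_track(tt, rep(0.999, n), rep(0, n))
  expect_lt(max(reconstruct_stimulus(trw, arena, 0)$stimulus), 1e-8)
})
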