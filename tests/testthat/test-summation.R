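# simulate the three activation arms plus baselines for known parameters
sim_arms <- function(n = 500, mu_o = log(10), sigma_o = 0.3,
                     mu_a = 0.3, mu_b = 0.3, alpha = 0.5,
                     sigma_a = 0.15, sigma_b = 0.15, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(mu, s2) stats::rlnorm(n, mu, sqrt(s2))
    list(baseline_A = mk(mu_o, sigma_o^2),
         baseline_B = mk(mu_o, sigma_o^2),
         baseline_AB = mk(mu_o, sigma_o^2),
         A = mk(mu_o + mu_a, sigma_o^2 + sigma_a^2),
         B = mk(mu_o + mu_b, sigma_o^2 + sigma_b^2),
         AB = mk(mu_o + mu_a + mu_b + alpha * mu_a * mu_b,
                 sigma_o^2 + sigma_a^2 + sigma_b^2))
  })
}

test_that("known interaction parameters are recovered within 2 SE", {
  d <- sim_arms(n = 500, alpha = 0.5, seed = 41)
  fit <- fit_interaction_model(d$A, d$B, d$AB, d$baseline_A, d$baseline_B,
                               d$baseline_AB)
  expect_lt(abs(fit$mu_a - 0.3), 2 * 0.3 / sqrt(500) * 2)
  expect_lt(abs(fit$mu_b - 0.3), 2 * 0.3 / sqrt(500) * 2)
  expect_true(fit$identifiable)
  expect_lt(abs(fit$alpha - 0.5), 2 * fit$se_alpha)
  # null interaction: alpha within 2 SE of zero
  d0 <- sim_arms(n = 500, alpha = 0, seed = 42)
  f0 <- fit_interaction_model(d0$A, d0$B, d0$AB, d0$baseline_A,
                              d0$baseline_B, d0$baseline_AB)
  expect_lt(abs(f0$alpha), 2 * f0$se_alpha)
})

test_that("the closed-form MLE matches a grid-search oracle", {
  d <- sim_arms(n = 300, alpha = 0.8, seed = 43)
  fit <- fit_interaction_model(d$A, d$B, d$AB, d$baseline_A, d$baseline_B,
                               d$baseline_AB, sigma_ab_mode = "zero")
  # oracle: maximize the AB-arm normal likelihood over alpha by grid search
  lab <- log(d$AB)
  mu_base <- fit$mu_o["AB"] + fit$mu_a + fit$mu_b
  s2 <- fit$sigma2_AB
  grid <- seq(-3, 3, by = 1e-4)
  nll <- vapply(grid, function(a)
    -sum(stats::dnorm(lab, mu_base + a * fit$mu_a * fit$mu_b, sqrt(s2),
                      log = TRUE)), numeric(1))
  expect_equal(fit$alpha, grid[which.min(nll)], tolerance = 2e-4)
})

test_that("no-effect arms give unit gains and the factorization is exact", {
  d <- sim_arms(n = 400, mu_a = 0, mu_b = 0.3, alpha = 0, seed = 44)
  # A identical in law to its baseline
  fit <- fit_interaction_model(d$A, d$B, d$AB, d$baseline_A, d$baseline_B,
                               d$baseline_AB)
  g <- compute_gains(fit)
  expect_equal(unname(g["gain_a"]), 1, tolerance = 0.1)
  # exact multiplicative factorization of the joint mean
  expect_equal(exp(fit$mu_AB),
               exp(fit$mu_o["AB"]) * g["gain_a"] * g["gain_b"] *
                 g["gain_ab"],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("gains convert to percent changes as printed", {
  expect_equal(gain_to_percent(1.46), 46)
  expect_equal(gain_to_percent(1), 0)
  d <- sim_arms(n = 400, seed = 45)
  fit <- fit_interaction_model(d$A, d$B, d$AB, d$baseline_A, d$baseline_B,
                               d$baseline_AB)
  fit$mu_a <- 0.2; fit$mu_b <- 0.3; fit$alpha <- 1
  g <- compute_gains(fit)
  expect_equal(unname(g["gain_ab"]), exp(0.06), tolerance = 1e-12)
  fit$mu_a <- 0
  expect_equal(unname(compute_gains(fit)["gain_a"]), 1)
})

test_that("interaction labels cover synergy, antagonism, dominance, linear", {
  base <- fit_interaction_model(sim_arms(seed = 46)$A,
                                sim_arms(seed = 46)$B,
                                sim_arms(seed = 46)$AB,
                                sim_arms(seed = 46)$baseline_A,
                                sim_arms(seed = 46)$baseline_B,
                                sim_arms(seed = 46)$baseline_AB)
  stub <- function(mu_a, mu_b, alpha) {
    f <- base
    f$mu_a <- mu_a; f$mu_b <- mu_b; f$alpha <- alpha
    f$identifiable <- TRUE
    f
  }
  # concordant increases enhanced by the interaction: synergistic
  expect_equal(classify_interaction(stub(log(1.3), log(1.2),
                                         0.25 / (log(1.3) * log(1.2))))$label,
               "synergistic")
  # interaction cutting back concordant increases: antagonistic
  expect_equal(classify_interaction(stub(log(1.3), log(1.2),
                                         -0.2 / (log(1.3) * log(1.2))))$label,
               "antagonistic")
  # small interaction gain: linear
  expect_equal(classify_interaction(stub(log(1.3), log(1.2),
                                         log(1.05) / (log(1.3) * log(1.2))))$label,
               "linear")
  # opposing effects, joint follows A: dominant_A
  expect_equal(classify_interaction(stub(log(1.5), log(0.8),
                                         log(1.2) / (log(1.5) * log(0.8))))$label,
               "dominant_A")
  # no individual effects but a notable interaction: other
  expect_equal(classify_interaction(stub(log(1.02), log(1.02),
                                         log(1.3) / (log(1.02) * log(1.02))))$label,
               "other_interaction")
})

test_that("small samples and degenerate effects are rejected or flagged", {
  d <- sim_arms(n = 10, seed = 47)
  expect_error(fit_interaction_model(d$A, d$B, d$AB, d$baseline_A,
                                     d$baseline_B, d$baseline_AB),
               "at least")
  # mu_a * mu_b ~ 0: alpha unidentifiable
  d2 <- sim_arms(n = 500, mu_a = 0, mu_b = 0, alpha = 1, seed = 48)
  f2 <- fit_interaction_model(d2$A, d2$B, d2$AB, d2$baseline_A,
                              d2$baseline_B, d2$baseline_AB)
  expect_false(f2$identifiable)
  expect_true(is.na(f2$alpha))
})
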