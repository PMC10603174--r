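# Lognormal summation model for ORN-class integration: per-region effects
# of single and paired class activation on log kinematics, multiplicative
# gains, and the synergy / antagonism / dominance classification.

#' Fit the pairwise lognormal interaction model for one region
#'
#' Within a region of the (f, df) space, the log of a kinematic parameter
#' is modeled as normal with mean mu_o + mu_a (class A alone), mu_o + mu_b
#' (class B alone), and mu_o + mu_a + mu_b + alpha * mu_a * mu_b for joint
#' activation; variances add (sigma_o^2 + sigma_a^2 [+ sigma_b^2 +
#' 2 sigma_ab]).  Baseline terms (mu_o, sigma_o^2) are fixed per genotype
#' from its before-first-entry values; single-class effects come from the
#' single-activation arms; the interaction coefficient alpha (and, in
#' `"joint"` mode, the covariance sigma_ab) is then the maximum-likelihood
#' fit to the joint arm.  For the normal likelihood these MLEs are
#' available in closed form from the joint arm's log moments; sigma_ab is
#' constrained so the joint variance stays positive.
#'
#' @param values_A,values_B,values_AB positive kinematic values in the
#'   region for the three activation arms
#' @param baseline_A,baseline_B,baseline_AB before-first-entry values for
#'   each genotype
#' @param sigma_ab_mode `"joint"` (estimate the covariance term) or
#'   `"zero"` (fix sigma_ab = 0)
#' @param min_n minimum sample size per arm (default 20)
#' @return object of class `summation_fit`
#' @export
fit_interaction_model <- function(values_A, values_B, values_AB,
                                  baseline_A, baseline_B, baseline_AB,
                                  sigma_ab_mode = c("joint", "zero"),
                                  min_n = 20) {
  sigma_ab_mode <- match.arg(sigma_ab_mode)
  arms <- list(values_A, values_B, values_AB,
               baseline_A, baseline_B, baseline_AB)
  if (any(vapply(arms, function(v) sum(is.finite(v) & v > 0), 0L) < min_n))
    stop("each arm needs at least ", min_n, " positive values")

  bA <- log_moments(baseline_A); bB <- log_moments(baseline_B)
  bAB <- log_moments(baseline_AB)
  mA <- log_moments(values_A); mB <- log_moments(values_B)
  mAB <- log_moments(values_AB)

  mu_a <- mA$meanlog - bA$meanlog
  mu_b <- mB$meanlog - bB$meanlog
  sigma2_a <- max(0, mA$sdlog^2 - bA$sdlog^2)
  sigma2_b <- max(0, mB$sdlog^2 - bB$sdlog^2)
  boundary_a <- mA$sdlog^2 < bA$sdlog^2
  boundary_b <- mB$sdlog^2 < bB$sdlog^2

  prod_ab <- mu_a * mu_b
  identifiable <- abs(prod_ab) >= 0.01
  resid <- mAB$meanlog - bAB$meanlog - mu_a - mu_b
  alpha <- if (identifiable) resid / prod_ab else NA_real_

  base_var <- bAB$sdlog^2 + sigma2_a + sigma2_b
  if (sigma_ab_mode == "joint") {
    sigma_ab <- (mAB$sdlog^2 - base_var) / 2
    # keep sigma2_AB strictly positive
    lower <- (-base_var + 1e-8) / 2
    boundary_ab <- sigma_ab < lower
    sigma_ab <- max(sigma_ab, lower)
  } else {
    sigma_ab <- 0
    boundary_ab <- FALSE
  }
  sigma2_AB <- base_var + 2 * sigma_ab

  mu_AB_hat <- bAB$meanlog + mu_a + mu_b +
    (if (identifiable) alpha * prod_ab else resid)
  loglik <- sum(stats::dnorm(log(values_AB[values_AB > 0]), mu_AB_hat,
                             sqrt(sigma2_AB), log = TRUE))

  # standard error of alpha: propagate the mean errors of the four arms
  var_num <- mAB$sdlog^2 / mAB$n + bAB$sdlog^2 / bAB$n +
    mA$sdlog^2 / mA$n + bA$sdlog^2 / bA$n +
    mB$sdlog^2 / mB$n + bB$sdlog^2 / bB$n
  se_alpha <- if (identifiable) sqrt(var_num) / abs(prod_ab) else NA_real_
  se_resid <- sqrt(var_num)

  structure(list(
    mu_o = c(A = bA$meanlog, B = bB$meanlog, AB = bAB$meanlog),
    sigma2_o = c(A = bA$sdlog^2, B = bB$sdlog^2, AB = bAB$sdlog^2),
    mu_a = mu_a, mu_b = mu_b, sigma2_a = sigma2_a, sigma2_b = sigma2_b,
    alpha = alpha, sigma_ab = sigma_ab, sigma2_AB = sigma2_AB,
    mu_A = bA$meanlog + mu_a, mu_B = bB$meanlog + mu_b, mu_AB = mu_AB_hat,
    interaction_log = resid, se_alpha = se_alpha, se_resid = se_resid,
    identifiable = identifiable,
    boundary = c(a = boundary_a, b = boundary_b, ab = boundary_ab),
    sigma_ab_mode = sigma_ab_mode, loglik = loglik,
    n = c(A = mA$n, B = mB$n, AB = mAB$n)),
    class = "summation_fit")
}

#' Multiplicative gains from a summation fit
#'
#' gain_a = exp(mu_a), gain_b = exp(mu_b), and the interaction gain
#' gain_ab = exp(alpha * mu_a * mu_b).  A gain of 1 is no effect; 1.46 is
#' a 46% increase of the real-world kinematic parameter.  When alpha is
#' unidentifiable the interaction gain falls back to exp of the raw joint
#' residual (which equals alpha * mu_a * mu_b when identifiable).
#'
#' @param fit a [fit_interaction_model()] result
#' @return named numeric vector `(gain_a, gain_b, gain_ab)`
#' @export
compute_gains <- function(fit) {
  inter <- if (fit$identifiable) fit$alpha * fit$mu_a * fit$mu_b
           else fit$interaction_log
  c(gain_a = exp(fit$mu_a), gain_b = exp(fit$mu_b), gain_ab = exp(inter))
}

#' Percent change implied by a gain
#'
#' @param gain multiplicative gain
#' @return percent change of the kinematic parameter (gain 1.46 -> 46)
#' @export
gain_to_percent <- function(gain) 100 * (gain - 1)

#' Classify the interaction between two ORN classes
#'
#' Effect directions use the 10% band around 1: increase when gain > 1.1,
#' decrease when gain < 0.9, no change otherwise.  The interaction is
#' `linear` when the interaction gain is inside the band.  Otherwise:
#' `synergistic` when it pushes in the same direction as concordant
#' individual effects, `antagonistic` when it cuts back against them,
#' `dominant_A`/`dominant_B` when the individual effects oppose each other
#' and the joint effect follows one class, and `other_interaction` when
#' neither class has an individual effect (or the opposing effects
#' cancel) yet the interaction is notable.  When alpha was unidentifiable,
#' the interaction is judged notable only if the CI of the joint residual
#' excludes the band.
#'
#' @param fit a [fit_interaction_model()] result
#' @param band half-width of the no-effect band on the gain scale (0.1)
#' @return object of class `interaction_call` with `gains`, per-arm
#'   `directions`, and `label`
#' @export
classify_interaction <- function(fit, band = 0.1) {
  gains <- compute_gains(fit)
  dir_of <- function(g) if (g > 1 + band) "increase"
                        else if (g < 1 - band) "decrease" else "no_change"
  da <- dir_of(gains["gain_a"]); db <- dir_of(gains["gain_b"])
  g_ab <- gains["gain_ab"]
  notable <- g_ab > 1 + band || g_ab < 1 - band
  if (notable && !fit$identifiable) {
    ci <- exp(fit$interaction_log + c(-1.96, 1.96) * fit$se_resid)
    notable <- ci[1] > 1 + band || ci[2] < 1 - band
  }
  if (!notable) {
    label <- "linear"
  } else if (da == "no_change" && db == "no_change") {
    label <- "other_interaction"
  } else if (da != db && da != "no_change" && db != "no_change") {
    # opposing individual effects: which class does the joint follow?
    total <- gains["gain_a"] * gains["gain_b"] * g_ab
    dt <- dir_of(total)
    label <- if (dt == da) "dominant_A"
             else if (dt == db) "dominant_B"
             else "other_interaction"
  } else {
    # concordant (or single-sided) individual effects
    dir_ind <- if (da != "no_change") da else db
    enhances <- (dir_ind == "increase" && g_ab > 1) ||
      (dir_ind == "decrease" && g_ab < 1)
    label <- if (enhances) "synergistic" else "antagonistic"
  }
  structure(list(gains = gains,
                 directions = c(A = da, B = db),
                 interaction_gain = unname(g_ab),
                 label = label),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("<interaction_call> %s | gains: a %.3f, b %.3f, ab %.3f\n",
              x$label, x$gains["gain_a"], x$gains["gain_b"],
              x$gains["gain_ab"]))
  invisible(x)
}
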