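# Ground-truth generative settings for the synthetic-data module: a known
# encoder cascade, smooth kinematic mapping surfaces over (f, df),
# transition rules, and turn-direction bias, so that every estimator in
# the pipeline can be tested by parameter recovery.

# Truth filters for the two-stage cascade: a monophasic negative stimulus
# -> LFP kernel (LFP deflects downward with light) and a mildly biphasic
# LFP -> rate kernel (inverted, with a small undershoot giving transient
# overshoot at onset and a shallow dip at offset).
make_truth_cascade <- function(fs = 100, baseline = 4.7,
                               lfp_per_intensity = -0.2,
                               rate_gain = 30, plateau = 20,
                               undershoot = 0.1, d = 120) {
  tt <- (seq_len(d) - 1) / fs
  k1 <- (tt / 0.06) * exp(1 - tt / 0.06)
  k1 <- k1 * lfp_per_intensity / sum(k1)      # mV per (uW/mm^2)
  k2 <- (tt / 0.05) * exp(1 - tt / 0.05) -
    undershoot * (tt / 0.25) * exp(1 - tt / 0.25)
  lfp_ss <- lfp_per_intensity * plateau       # steady LFP at the plateau
  k2 <- k2 * rate_gain / (sum(k2) * lfp_ss)   # spikes/s per mV, inverted
  new_cascade(k1, k2, baseline = baseline, fs = fs)
}

#' Ground truth for synthetic cohorts
#'
#' Bundles everything the generative model needs with known parameters:
#' the encoder cascade (baseline 4.7 spikes/s), smooth lognormal-parameter
#' surfaces over (f, df) for each state's kinematics (sums of planar and
#' Gaussian-bump terms, so KNN recovery has an analytic target),
#' state-transition rules, turn-direction optimality bias, the boundary
#' (arc angle, duration) bivariate lognormal, and trial noise levels.
#'
#' Presets: `"null"` has constant surfaces at the baseline values, an
#' unbiased turn direction, and constant transitions — no stimulus effect
#' on behavior.  `"attractor"` slows walking at high firing rates,
#' increases sharp-turn curvature when the rate is falling (df < 0), and
#' biases turns toward the arena center in region III, producing
#' attraction to the light zone.
#'
#' @param seed stored with the object and used to derive simulation
#'   sub-seeds
#' @param profile `"attractor"` or `"null"`
#' @return object of class `ground_truth`
#' @export
make_ground_truth <- function(seed = 1, profile = c("attractor", "null")) {
  profile <- match.arg(profile)
  null <- profile == "null"

  base <- list(
    curved_walk = list(avg_speed = c(log(12), 0.35),
                       curvature = c(log(0.6), 0.5),   # rad/s magnitude
                       duration = c(log(0.8), 0.5)),
    sharp_turn = list(avg_speed = c(log(6), 0.3),
                      curvature = c(log(1.5), 0.5),    # total rad magnitude
                      duration = c(log(0.35), 0.3)),
    stop = list(curvature = c(log(0.3), 0.5),          # total rad magnitude
                duration = c(log(1.0), 0.6)))

  # effect surfaces: delta-meanlog as a function of (f, df)
  eff <- function(state, param) {
    if (null) return(function(f, df) 0)
    if (state == "curved_walk" && param == "avg_speed")
      return(function(f, df) -0.012 * f)
    if (state == "sharp_turn" && param == "curvature")
      return(function(f, df)
        0.002 * f + 0.3 * exp(-((df + 60)^2) / (2 * 40^2)))
    if (state == "curved_walk" && param == "duration")
      return(function(f, df) -0.004 * f)
    function(f, df) 0
  }
  surfaces <- lapply(names(base), function(s) {
    pars <- base[[s]]
    out <- lapply(names(pars), function(p) {
      e <- eff(s, p)
      m0 <- pars[[p]][1]; s0 <- pars[[p]][2]
      function(f, df) list(meanlog = m0 + e(f, df), sdlog = s0)
    })
    names(out) <- names(pars)
    out
  })
  names(surfaces) <- names(base)

  transition <- function(state, f, df) {
    if (state == "sharp_turn")
      return(c(curved_walk = 1, stop = 0, sharp_turn = 0))
    if (state == "stop")
      return(c(curved_walk = 0.75, stop = 0, sharp_turn = 0.25))
    # curved walk: mostly sharp turns; more stops at low firing rates
    p_stop <- if (null) 0.25 else min(0.6, 0.25 + 0.3 * exp(-f / 5))
    c(curved_walk = 0, stop = p_stop, sharp_turn = 1 - p_stop)
  }

  optimality <- function(f, df) {
    if (null) return(rep(0.5, length(f)))
    ifelse(df < -20, 0.7, 0.5)
  }

  structure(list(
    profile = profile, seed = seed,
    encoder = make_truth_cascade(),
    surfaces = surfaces,
    transition = transition,
    optimality = optimality,
    boundary = list(mean = c(log(1.0), log(2.0)),
                    cov = matrix(c(0.25, 0.1, 0.1, 0.16), 2)),
    noise = list(lfp_sd = 0.4, rate_sd = 2)),
    class = "ground_truth")
}

#' Evaluate a ground-truth mapping surface
#'
#' @param truth a [make_ground_truth()] object
#' @param state,parameter which surface
#' @param f,df coordinates (vectorized)
#' @return list of vectors `meanlog`, `sdlog`
#' @export
truth_surface <- function(truth, state, parameter, f, df) {
  fn <- truth$surfaces[[state]][[parameter]]
  n <- max(length(f), length(df))
  f <- rep_len(f, n); df <- rep_len(df, n)
  ml <- sl <- numeric(n)
  for (i in seq_len(n)) {
    v <- fn(f[i], df[i])
    ml[i] <- v$meanlog; sl[i] <- v$sdlog
  }
  list(meanlog = ml, sdlog = sl)
}
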