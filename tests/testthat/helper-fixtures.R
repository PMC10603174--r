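# Shared fixtures: geometric tracks with known kinematics, small ground
# truths, and independent brute-force oracles.

fps_default <- 30

# circular track at constant radius and angular velocity (rad/s);
# CCW for omega > 0
circle_track <- function(n = 120, radius = 0.5, omega = 2, fps = 30,
                         phase = 0, t0 = 0) {
  tt <- t0 + (seq_len(n) - 1) / fps
  ang <- phase + omega * (tt - t0)
  make_track(tt, radius * cos(ang), radius * sin(ang))
}

# straight track with constant velocity (normalized units per s)
straight_track <- function(n = 120, vx = 0.05, vy = 0, x0 = -0.8, y0 = 0,
                           fps = 30, t0 = 0) {
  tt <- t0 + (seq_len(n) - 1) / fps
  make_track(tt, x0 + vx * (tt - t0), y0 + vy * (tt - t0))
}

# independent brute-force KNN oracle: plain order() over all points
brute_knn <- function(f, df, y, x, a, b, K, T_bound) {
  d2 <- ((f - y) / a)^2 + ((df - x) / b)^2
  ord <- order(d2)
  ord <- ord[d2[ord] <= T_bound^2]
  sort(utils::head(ord, K))
}

# range-normalized RMSE between an estimated and a true filter
nrmse_taps <- function(est, truth) {
  L <- max(length(est), length(truth))
  e <- c(est, rep(0, L - length(est)))
  tt <- c(truth, rep(0, L - length(truth)))
  sqrt(mean((e - tt)^2)) / diff(range(tt))
}

# smooth band-limited stimulus pattern resembling zone crossings
crossing_stimulus <- function(n = 6000, plateau = 20) {
  x <- as.numeric(stats::filter(stats::runif(n), rep(1 / 300, 300),
                                sides = 1))
  x[is.na(x)] <- x[which(!is.na(x))[1]]
  z <- (x - mean(x)) / stats::sd(x)
  plateau * pmin(pmax(z * 0.7 + 0.5, 0), 1)
}

# random state points over the response space with values drawn from a
# ground-truth surface
surface_points <- function(truth, n, state = "curved_walk",
                           parameter = "avg_speed", seed = 1) {
  withr::with_seed(seed, {
    f <- stats::runif(n, 0, 55)
    df <- stats::runif(n, -150, 150)
    s <- truth_surface(truth, state, parameter, f, df)
    out <- data.frame(state = state, f = f, df = df,
                      t_entry = stats::runif(n, 0, 180))
    out[[parameter]] <- stats::rlnorm(n, s$meanlog, s$sdlog)
    out
  })
}
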