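test_that("region classification matches an exhaustive truth-table oracle", {
  oracle <- function(f, df) {
    if (df > 20) return("I")
    if (df < -20) return("III")
    if (f < 4.7) return("IV")
    if (f > 15) return("II")
    "V"
  }
  grid <- expand.grid(f = seq(0, 55, by = 0.5),
                      df = seq(-150, 150, by = 2.5))
  expect_equal(classify_region(grid$f, grid$df),
               mapply(oracle, grid$f, grid$df))
  # worked examples at the stated thresholds
  expect_equal(classify_region(30, 50), "I")
  expect_equal(classify_region(2, 0), "IV")
  expect_equal(classify_region(10, 0), "V")
  expect_equal(classify_region(20, 0), "II")
  expect_equal(classify_region(2, -30), "III")
})

test_that("state-point embedding computes f and df over the 200 ms window", {
  rate_t <- seq(0, 10, by = 0.01)
  seg <- data.frame(state = "curved_walk", start_t = 5,
                    avg_speed = 10, total_curvature = 1,
                    avg_curvature = 0.1, avg_abs_curvature = 0.1,
                    duration = 1)
  # constant rate 20
  p1 <- embed_state_points(seg, rep(20, length(rate_t)), rate_t,
                           first_entry_time = 0)
  expect_equal(p1$f, 20)
  expect_equal(p1$df, 0)
  # ramp 0 -> 20 spikes/s over the window: df = 100 spikes/s^2
  ramp <- pmin(pmax((rate_t - 4.8) / 0.2, 0), 1) * 20
  p2 <- embed_state_points(seg, ramp, rate_t, first_entry_time = 0)
  expect_equal(p2$df, 100, tolerance = 1)
  seg_far <- seg
  seg_far$start_t <- 99
  expect_error(embed_state_points(seg_far, rep(1, length(rate_t)),
                                  rate_t, 0), "coverage")
})

test_that("KNN neighborhoods equal the brute-force oracle", {
  set.seed(21)
  n <- 2000
  f <- stats::runif(n, 0, 55); df <- stats::runif(n, -150, 150)
  g <- make_map_grid()
  for (node in list(c(5, -60), c(30, 0), c(55, 150), c(0, -150))) {
    got <- sort(odorwalk:::knn_neighbors(f, df, node[1], node[2],
                                         g$a, g$b, g$K, g$T_bound))
    want <- brute_knn(f, df, node[1], node[2], g$a, g$b, g$K, g$T_bound)
    expect_equal(got, want)
  }
})

test_that("weight-scale invariance: (a, b, T) scale out of the map", {
  truth <- make_ground_truth(2)
  pts <- surface_points(truth, 3000, seed = 5)
  # the neighbor ordering depends only on the a:b ratio; the ellipse
  # semi-axes are a*T and b*T, so (a, b) / 10 with T * 10 is the identity
  g1 <- make_map_grid(a = 10, b = 30, T_bound = 1.5)
  g2 <- make_map_grid(a = 1, b = 3, T_bound = 15)
  m1 <- fit_knn_map(pts, "avg_speed", g1)
  m2 <- fit_knn_map(pts, "avg_speed", g2)
  expect_equal(m1$mu, m2$mu)
  expect_equal(m1$sigma, m2$sigma)
  expect_equal(m1$n, m2$n)
})

test_that("degenerate maps and non-positive values are handled", {
  set.seed(22)
  pts <- data.frame(f = stats::runif(500, 0, 10),
                    df = stats::runif(500, -30, 30),
                    val = 7)
  g <- make_map_grid(f_axis = 0:10, df_axis = seq(-30, 30, 15))
  m <- fit_knn_map(pts, "val", g)
  expect_equal(unique(m$mu[m$mask]), log(7))
  expect_equal(unique(m$sigma[m$mask]), 0)
  pts$val[1:100] <- -1
  m2 <- fit_knn_map(pts, "val", g)
  expect_gt(m2$excluded, 0)
})

test_that("map queries interpolate bilinearly and respect the mask", {
  g <- make_map_grid(f_axis = 0:3, df_axis = seq(-30, 30, 15))
  mu <- outer(0:3, seq(-30, 30, 15), function(a, b) a + 0.01 * b)
  map <- structure(list(grid = g, mu = mu, sigma = mu * 0 + 0.5,
                        n = mu * 0 + 100, mask = is.finite(mu),
                        defined = which(is.finite(mu), arr.ind = TRUE)),
                   class = "kinematic_map")
  # exact node
  expect_equal(query_map(map, 2, 15)$mu, 2 + 0.15)
  # midpoint of two nodes: arithmetic mean
  expect_equal(query_map(map, 1.5, 0)$mu, mean(c(1, 2)))
  # random queries against an independent bilinear oracle
  set.seed(23)
  fq <- stats::runif(20, 0, 3); dq <- stats::runif(20, -30, 30)
  oracle <- vapply(seq_along(fq), function(i) {
    i0 <- findInterval(fq[i], 0:3, rightmost.closed = TRUE)
    j0 <- findInterval(dq[i], seq(-30, 30, 15), rightmost.closed = TRUE)
    fx <- 0:3; dx <- seq(-30, 30, 15)
    wx <- (fq[i] - fx[i0]) / diff(fx)[1]
    wy <- (dq[i] - dx[j0]) / diff(dx)[1]
    (1 - wx) * (1 - wy) * mu[i0, j0] + wx * (1 - wy) * mu[i0 + 1, j0] +
      (1 - wx) * wy * mu[i0, j0 + 1] + wx * wy * mu[i0 + 1, j0 + 1]
  }, numeric(1))
  expect_equal(query_map(map, fq, dq)$mu, oracle, tolerance = 1e-12)
  # masked region: undefined unless fallback
  map$mask[2, 2] <- FALSE
  map$defined <- which(map$mask, arr.ind = TRUE)
  q <- query_map(map, 1.5, -20)
  expect_true(is.na(q$mu))
  qf <- query_map(map, 1.5, -20, fallback = TRUE)
  expect_true(qf$fallback_used)
  expect_true(is.finite(qf$mu))
})

test_that("K/T grid search: SEM falls with K and the defaults are stated", {
  truth <- make_ground_truth(2, "null")
  pts <- surface_points(truth, 4000, seed = 6)
  g <- make_map_grid(f_axis = seq(0, 55, 5))
  sel <- select_knn_params(pts, "avg_speed", K_grid = c(16, 32, 64, 128),
                           T_grid = 1.5, grid = g)
  expect_true(all(diff(sel$sem[, 1]) < 0))
  kd <- knn_defaults()
  expect_equal(kd$kinematics, list(K = 64, T = 1.5))
  expect_equal(kd$stops, list(K = 64, T = 1))
  expect_equal(kd$transitions$K, 128)
})

test_that("time-resolved maps are stationary when the truth is", {
  truth <- make_ground_truth(2)
  pts <- surface_points(truth, 6000, seed = 7)
  g <- make_map_grid(f_axis = seq(0, 55, 5))
  m3 <- fit_time_resolved_map(pts, "avg_speed", g,
                              t_axis = c(30, 90, 150))
  # slices agree within 3 SE wherever defined
  se <- m3$sigma / sqrt(m3$n)
  for (k in 2:3) {
    both <- m3$mask[, , 1] & m3$mask[, , k]
    dd <- abs(m3$mu[, , 1] - m3$mu[, , k])[both]
    ss <- 3 * sqrt(se[, , 1]^2 + se[, , k]^2)[both]
    expect_gt(mean(dd <= ss), 0.95)
  }
  # ellipsoid neighborhoods equal a brute-force oracle
  sub <- pts[1:800, ]
  got <- odorwalk:::knn_neighbors(sub$f, sub$df, 20, 0, g$a, g$b, g$K,
                                  g$T_bound, t = sub$t_entry, z = 90,
                                  cweight = g$c)
  d2 <- ((sub$f - 20) / g$a)^2 + ((sub$df - 0) / g$b)^2 +
    ((sub$t_entry - 90) / g$c)^2
  ord <- order(d2); ord <- ord[d2[ord] <= g$T_bound^2]
  expect_equal(sort(got), sort(utils::head(ord, g$K)))
})

test_that("adaptation permutation test flags a constructed step change", {
  truth <- make_ground_truth(2, "null")
  set.seed(24)
  n <- 4000
  pts <- surface_points(truth, n, seed = 8)
  # step change at t = 60 s: speeds double afterwards
  pts$avg_speed[pts$t_entry > 60] <- pts$avg_speed[pts$t_entry > 60] * 2
  g <- make_map_grid(f_axis = seq(0, 55, 10))
  res <- permutation_adaptation_test(pts, "avg_speed", g,
                                     t_axis = c(20, 120), n_perm = 30,
                                     seed = 99)
  # early slice below the pooled mean, late slice above
  early <- res$flags[, , 1]; late <- res$flags[, , 2]
  expect_gt(mean(early == "below", na.rm = TRUE), 0.8)
  expect_gt(mean(late == "above", na.rm = TRUE), 0.8)
  # seed-reproducible
  res2 <- permutation_adaptation_test(pts, "avg_speed", g,
                                      t_axis = c(20, 120), n_perm = 30,
                                      seed = 99)
  expect_identical(res$flags, res2$flags)
})

test_that("map comparison: likelihood family and shift detection", {
  truth <- make_ground_truth(2, "null")
  ptsA <- surface_points(truth, 3000, seed = 9)
  ptsB <- surface_points(truth, 3000, seed = 10)
  g <- make_map_grid(f_axis = seq(0, 55, 10))
  same <- compare_maps(ptsA, ptsB, "avg_speed", g, adjust = TRUE)
  # identical generators: few significant cells after BH
  expect_lt(mean(same$significant[is.finite(same$p)]), 0.05)
  # lognormal data: lognormal NLL beats normal NLL
  expect_lt(same$nll_lognormal, same$nll_normal)
  # location-shifted B: detected
  ptsB2 <- ptsB
  ptsB2$avg_speed <- ptsB2$avg_speed * 1.5
  shift <- compare_maps(ptsA, ptsB2, "avg_speed", g, adjust = TRUE)
  expect_gt(mean(shift$significant[is.finite(shift$p)]), 0.8)
})

test_that("transition maps recover known probabilities and normalize", {
  set.seed(25)
  n <- 6000
  pts <- data.frame(f = stats::runif(n, 0, 55),
                    df = stats::runif(n, -150, 150),
                    state = "stop",
                    next_state = sample(c("sharp_turn", "curved_walk"), n,
                                        replace = TRUE, prob = c(.25, .75)))
  tm <- fit_transition_map(pts, states = "stop")
  pr <- tm$maps$stop
  def <- is.finite(pr[, , 1])
  # per-cell normalization preserved by smoothing
  tot <- apply(pr, c(1, 2), sum)
  expect_equal(tot[def], rep(1, sum(def)), tolerance = 1e-9)
  # ~25% of stops transition to sharp turns
  expect_equal(mean(pr[, , "sharp_turn"][def]), 0.25, tolerance = 0.03)
  expect_equal(unname(query_transition(tm, "stop", 10, 0)["sharp_turn"]),
               0.25, tolerance = 0.05)
})

test_that("state distribution fits use the stated estimators", {
  set.seed(26)
  n <- 400
  segs <- data.frame(
    state = "curved_walk", phase = "before",
    avg_speed = stats::rlnorm(n, log(10), 0.4),
    avg_abs_curvature = stats::rlnorm(n, log(0.5), 0.5),
    total_curvature = NA, duration = stats::rexp(n, 2),
    arc_angle = NA, t_inhibition = NA)
  fits <- fit_state_distributions(segs)
  lv <- log(segs$avg_speed)
  # lognormal MLE identity: mean and ML SD of logs
  expect_equal(fits$before$curved_walk$avg_speed$meanlog, mean(lv))
  expect_equal(fits$before$curved_walk$avg_speed$sdlog,
               sqrt(mean((lv - mean(lv))^2)))
  # inhibition-period time-dependent fits: constant truth -> flat splines,
  # exponential rate recovered within 2 SE
  lam0 <- 2
  ni <- 600
  inh <- data.frame(
    state = "curved_walk", phase = "inhibition",
    avg_speed = stats::rlnorm(ni, log(8), 0.3),
    avg_abs_curvature = stats::rbeta(ni, 2, 3),
    total_curvature = NA, duration = stats::rexp(ni, lam0),
    arc_angle = NA, t_inhibition = stats::runif(ni, 0, 4))
  fi <- fit_state_distributions(rbind(segs, inh))
  ip <- fi$inhibition$curved_walk
  tq <- seq(min(ip$centers), max(ip$centers), length.out = 9)
  mls <- ip$interpolate$meanlog(tq)
  expect_lt(max(mls) - min(mls), 0.25)
  rate_hat <- mean(ip$interpolate$rate(tq))
  expect_lt(abs(rate_hat - lam0), 2 * lam0 / sqrt(ni / length(ip$centers)))
})
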