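test_that("speed follows displacement arithmetic", {
  # 1 mm per frame at 30 Hz in the 4 cm arena -> 30 mm/s
  tr <- straight_track(n = 60, vx = norm_from_mm(1) * 30)
  kin <- compute_kinematics(tr)
  expect_equal(kin$speed, rep(30, length(kin$speed)), tolerance = 1e-9)
  expect_equal(kin$curvature, rep(0, length(kin$curvature)))
})

test_that("circular motion gives the analytic constant curvature", {
  omega <- 1.5
  fps <- 30
  tr <- circle_track(n = 150, radius = 0.5, omega = omega, fps = fps)
  kin <- compute_kinematics(tr)
  # turning angle per frame; |dN| = 2 sin(delta/2) from circle geometry
  delta <- omega / fps
  expected <- 2 * sin(delta / 2)
  mid <- kin$curvature[kin$valid]
  expect_equal(mid, rep(expected, length(mid)), tolerance = 1e-9)
  expect_true(all(mid > 0))   # CCW = leftward = positive
  # CW circle: negative
  kin2 <- compute_kinematics(circle_track(n = 150, omega = -omega))
  expect_true(all(kin2$curvature[kin2$valid] < 0))
})

test_that("mirror symmetry negates curvature and preserves speed", {
  set.seed(11)
  n <- 200
  steps <- complex(modulus = 0.004 + 0.003 * stats::runif(n),
                   argument = cumsum(stats::rnorm(n, 0, 0.3)))
  z <- cumsum(steps) * 0.5
  tt <- (seq_len(n) - 1) / 30
  tr <- make_track(tt, Re(z), Im(z))
  trm <- make_track(tt, Re(z), -Im(z))
  k1 <- compute_kinematics(tr)
  k2 <- compute_kinematics(trm)
  expect_equal(k1$speed, k2$speed, tolerance = 1e-9)
  expect_equal(k1$curvature, -k2$curvature, tolerance = 1e-9)
})

test_that("state segmentation matches definitions and tiles the track", {
  # slow drift away from the wall -> single stop
  tr <- straight_track(n = 90, vx = norm_from_mm(0.2 / 30))  # 0.2 mm/s
  kin <- compute_kinematics(tr)
  seg <- segment_states(kin, tr)
  expect_equal(seg$state, "stop")
  # circle hugging the wall -> single boundary segment
  trb <- circle_track(n = 90, radius = 0.98, omega = 0.5)
  segb <- segment_states(compute_kinematics(trb), trb)
  expect_equal(segb$state, "boundary")
  # partition invariant on a mixed synthetic track
  set.seed(3)
  n <- 400
  ang <- cumsum(c(0, stats::rnorm(n - 2, 0, 0.1)))
  step <- 0.004
  x <- cumsum(c(0, step * cos(ang))) - 0.3
  y <- cumsum(c(0, step * sin(ang)))
  trc <- make_track((seq_len(n) - 1) / 30, x, y)
  segc <- segment_states(compute_kinematics(trc), trc)
  expect_equal(segc$start[1], 0)
  expect_equal(segc$end[nrow(segc)], n)
  expect_equal(segc$start[-1], segc$end[-nrow(segc)])
})

test_that("an isolated curvature spike becomes exactly one sharp turn", {
  n <- 240
  fps <- 30
  # straight, one sharp kink, straight again
  ang <- rep(0, n - 1)
  kink <- 120
  ang[kink:(n - 1)] <- 1.2          # 1.2 rad heading change at one frame
  x <- cumsum(c(0, 0.004 * cos(ang))) - 0.4
  y <- cumsum(c(0, 0.004 * sin(ang)))
  tr <- make_track((seq_len(n) - 1) / fps, x, y)
  kin <- compute_kinematics(tr)
  seg <- segment_states(kin, tr)
  expect_equal(seg$state, c("curved_walk", "sharp_turn", "curved_walk"))
  # brute-force scan oracle: frames above the offset threshold around the
  # single peak
  ac <- abs(c(kin$curvature, 0))
  pk <- which.max(ac)
  thr <- 0.5 * ac[pk]
  lo <- pk; while (lo > 1 && ac[lo - 1] > thr) lo <- lo - 1
  hi <- pk; while (hi < n && ac[hi + 1] > thr) hi <- hi + 1
  turn <- seg[seg$state == "sharp_turn", ]
  expect_equal(turn$start, lo - 1L)
  expect_equal(turn$end, hi)
})

test_that("segment summaries report the defining kinematics", {
  fps <- 30
  # stop of 15 frames
  tr <- straight_track(n = 15, vx = 0)
  tr$x <- tr$x + 1e-9 * seq_len(15)   # avoid strictly zero displacement
  kin <- compute_kinematics(tr)
  seg <- summarize_segments(segment_states(kin, tr), kin, tr)
  expect_equal(seg$duration, 0.5)
  # boundary quarter circle: arc angle pi/2
  nq <- 91
  trq <- circle_track(n = nq, radius = 0.99,
                      omega = (pi / 2) / ((nq - 1) / fps))
  kinq <- compute_kinematics(trq)
  segq <- summarize_segments(segment_states(kinq, trq), kinq, trq)
  expect_equal(segq$state, "boundary")
  expect_equal(segq$arc_angle, pi / 2, tolerance = 0.02)
  # curved walk at constant speed v
  v <- 12
  trw <- circle_track(n = 80, radius = 0.5,
                      omega = v / (10 * 4) / 0.5)  # v mm/s along the circle
  kinw <- compute_kinematics(trw)
  segw <- summarize_segments(segment_states(kinw, trw), kinw, trw)
  walk <- segw[segw$state == "curved_walk", ]
  expect_equal(walk$avg_speed[1], v, tolerance = 0.05)
})

test_that("first entry follows the head and the light clock", {
  # never inside
  tr <- circle_track(n = 90, radius = 0.8, t0 = 0)
  expect_true(is.na(detect_first_entry(tr, 1)))
  # crossing before light-on only
  n <- 240
  tt <- (seq_len(n) - 1) / 30
  x <- seq(-0.9, 0.9, length.out = n)     # passes through the center early
  tr2 <- make_track(tt, x, rep(0, n))
  expect_true(is.na(detect_first_entry(tr2, light_on_time = 100)))
  # head crosses the 0.3125 border after light-on
  fe <- detect_first_entry(tr2, light_on_time = 0)
  expect_equal(fe, tt[which(abs(x) <= 0.3125)[1]])
})
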