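# ORN encoder: stimulus reconstruction, recording preprocessing, and the
# two-stage linear filter cascade (stimulus -> LFP -> firing rate) fit by
# Tikhonov-regularized least squares with L-curve selection of lambda.

#' Build the lagged (Hankel) design matrix for a causal FIR fit
#'
#' Row t holds the input from time t back to t - d + 1, with (d - 1) zeros
#' padded before the first sample, so the matrix has one row per time point.
#'
#' @param x input series
#' @param d filter length in samples
#' @return a `length(x)` by `d` matrix; column 1 is lag 0
#' @export
hankel_design <- function(x, d) {
  stopifnot(d >= 1, d < length(x) + d)
  emb <- stats::embed(c(rep(0, d - 1), x), d)
  emb
}

#' Fit a causal linear filter by ridge (Tikhonov) regression
#'
#' Solves min ||S k - r||^2 + ||lambda I k||^2 over a grid of lambda using a
#' single SVD of the design matrix, then picks lambda at the elbow of the
#' log-log L-curve of solution norm against residual norm (the point
#' farthest from the chord joining the curve's ends).
#'
#' Multiple trials can be fit jointly by passing lists of series: each
#' trial gets its own zero-padded design block, so no spurious coupling is
#' introduced across trial boundaries.
#'
#' @param input input series (e.g. stimulus), uniformly sampled, or a list
#'   of trials
#' @param response response series of the same length (or matching list)
#' @param d filter length in samples (default 200, i.e. 2 s at 100 Hz)
#' @param lambda_grid regularization values; default 30 values log-spaced
#'   over 6 decades scaled to the largest singular value of the design
#' @param lambda_fixed optional single lambda to use, skipping selection
#' @return an object of class `filter_fit` with elements `taps`, `d`,
#'   `lambda_grid`, `lambda_star`, `solution_norms`, `residual_norms`
#' @export
fit_filter <- function(input, response, d = 200, lambda_grid = NULL,
                       lambda_fixed = NULL) {
  if (!is.list(input)) input <- list(input)
  if (!is.list(response)) response <- list(response)
  stopifnot(length(input) == length(response),
            all(lengths(input) == lengths(response)), d >= 1,
            d < sum(lengths(input)))
  S <- do.call(rbind, lapply(input, hankel_design, d = d))
  response <- unlist(response, use.names = FALSE)
  sv <- svd(S)
  if (is.null(lambda_grid)) {
    smax <- max(sv$d)
    lambda_grid <- smax * 10^seq(-6, 0, length.out = 30)
  }
  if (!is.null(lambda_fixed)) lambda_grid <- sort(unique(c(lambda_grid,
                                                           lambda_fixed)))
  if (any(lambda_grid < 0)) stop("lambda must be >= 0")
  if (any(lambda_grid == 0) && min(sv$d) < max(sv$d) * 1e-10)
    stop("design matrix is numerically singular; lambda > 0 is required")
  utr <- crossprod(sv$u, response)           # d x 1
  norms_at <- function(lams) {
    sol <- res <- numeric(length(lams))
    rss0 <- max(0, sum(response^2) - sum(utr^2))  # out-of-span residual
    for (i in seq_along(lams)) {
      lam <- lams[i]
      filt <- sv$d^2 / (sv$d^2 + lam^2)
      sol[i] <- sqrt(sum((filt * utr / sv$d)^2))
      res[i] <- sqrt(rss0 + sum(((1 - filt) * utr)^2))
    }
    list(sol = sol, res = res)
  }
  taps_all <- vapply(lambda_grid, function(lam) {
    shrink <- sv$d / (sv$d^2 + lam^2)
    drop(sv$v %*% (shrink * utr))
  }, numeric(d))
  nm <- norms_at(lambda_grid)
  sol_norms <- nm$sol
  res_norms <- nm$res
  if (!is.null(lambda_fixed)) {
    star <- which.min(abs(lambda_grid - lambda_fixed))
  } else {
    # elbow: maximum curvature of the log-log L-curve, evaluated on a
    # dense lambda grid (the norms are smooth functions of lambda given
    # the SVD), then snapped to the requested grid
    dense <- exp(seq(log(min(lambda_grid)), log(max(lambda_grid)),
                     length.out = 400))
    dn <- norms_at(dense)
    lam_dense <- dense[lcurve_corner(dn$res, dn$sol)]
    star <- which.min(abs(log(lambda_grid) - log(lam_dense)))
  }
  structure(
    list(taps = taps_all[, star], d = d, lambda_grid = lambda_grid,
         lambda_star = lambda_grid[star], lambda_index = star,
         solution_norms = sol_norms, residual_norms = res_norms),
    class = "filter_fit")
}

#' Two-stage linear-linear encoder cascade
#'
#' Stage 1 maps stimulus intensity to LFP; stage 2 maps LFP to firing rate.
#' The rate is baseline-subtracted before the stage-2 fit; prediction adds
#' the baseline back and rectifies at zero (firing rates are non-negative).
#'
#' @param stimulus,lfp,rate aligned series at 100 Hz (or lists of trials)
#' @param d1,d2 filter lengths (samples) for the two stages
#' @param baseline resting firing rate in spikes/s; if `NULL`, estimated as
#'   the mean rate where the stimulus is at its minimum 5% of values
#' @param lambda_grids optional list of two lambda grids
#' @return an object of class `orn_cascade`
#' @export
fit_cascade <- function(stimulus, lfp, rate, d1 = 200, d2 = 200,
                        baseline = NULL, lambda_grids = NULL) {
  if (!is.list(stimulus)) stimulus <- list(stimulus)
  if (!is.list(lfp)) lfp <- list(lfp)
  if (!is.list(rate)) rate <- list(rate)
  stopifnot(all(lengths(stimulus) == lengths(lfp)),
            all(lengths(lfp) == lengths(rate)))
  if (is.null(baseline)) {
    sflat <- unlist(stimulus); rflat <- unlist(rate)
    lo <- sflat <= stats::quantile(sflat, 0.05)
    baseline <- mean(rflat[lo])
  }
  g1 <- if (is.null(lambda_grids)) NULL else lambda_grids[[1]]
  g2 <- if (is.null(lambda_grids)) NULL else lambda_grids[[2]]
  f1 <- fit_filter(stimulus, lfp, d = d1, lambda_grid = g1)
  f2 <- fit_filter(lfp, lapply(rate, function(r) r - baseline), d = d2,
                   lambda_grid = g2)
  new_cascade(f1$taps, f2$taps, baseline = baseline, fs = 100,
              fits = list(stage1 = f1, stage2 = f2))
}

#' Construct an encoder cascade from explicit filter taps
#'
#' @param filter1,filter2 FIR taps (lag 0 first) for the two stages
#' @param baseline resting firing rate, spikes/s
#' @param fs sampling rate, Hz
#' @param rectify rectify the predicted rate at zero
#' @param fits optional `filter_fit` diagnostics
#' @return an object of class `orn_cascade`
#' @export
new_cascade <- function(filter1, filter2, baseline = 4.7, fs = 100,
                        rectify = TRUE, fits = NULL) {
  stopifnot(baseline >= 0)
  structure(list(filter1 = as.numeric(filter1),
                 filter2 = as.numeric(filter2),
                 baseline = baseline, fs = fs, rectify = rectify,
                 fits = fits),
            class = "orn_cascade")
}

#' Predict LFP and firing rate from a stimulus
#'
#' @param cascade an `orn_cascade`
#' @param stimulus intensity series at the cascade sampling rate
#' @return list with `lfp` and `rate` series
#' @export
predict_response <- function(cascade, stimulus) {
  lfp <- conv_causal(stimulus, cascade$filter1)
  rate <- conv_causal(lfp, cascade$filter2) + cascade$baseline
  if (isTRUE(cascade$rectify)) rate <- pmax(rate, 0)
  list(lfp = lfp, rate = rate)
}

#' @export
print.orn_cascade <- function(x, ...) {
  cat(sprintf(
    "<orn_cascade> d1 = %d, d2 = %d taps at %g Hz; baseline %.2f spikes/s\n",
    length(x$filter1), length(x$filter2), x$fs, x$baseline))
  invisible(x)
}

#' Reconstruct the light stimulus a fly experienced from its trajectory
#'
#' Evaluates the arena intensity profile at the head's radial distance,
#' zero before light onset, and linearly upsamples from the tracking frame
#' rate to the electrophysiology rate.
#'
#' @param track a track (see [make_track()])
#' @param arena an [make_arena_model()] object
#' @param light_on_time light onset time, s (default 180)
#' @param out_fs output sampling rate, Hz (default 100)
#' @return data.frame with `t` and `stimulus`
#' @export
reconstruct_stimulus <- function(track, arena, light_on_time = 180,
                                 out_fs = 100) {
  r <- sqrt(track$head_x^2 + track$head_y^2)
  s <- arena$intensity(r)
  s[track$t < light_on_time] <- 0
  t_out <- seq(track$t[1], track$t[length(track$t)], by = 1 / out_fs)
  s_out <- stats::approx(track$t, s, xout = t_out, rule = 2)$y
  s_out[t_out < light_on_time] <- 0
  data.frame(t = t_out, stimulus = s_out)
}

#' Preprocess a raw single-sensillum voltage recording
#'
#' The LFP is the 300-ms running median of the raw trace; spikes are valleys
#' of the median-subtracted trace below -0.8 mV with at least 5 ms between
#' spikes (deeper valleys win); the firing rate is the Gaussian-kernel
#' smoothed spike train (150 ms bandwidth).  All outputs are returned at
#' `out_fs` (LFP by block averaging).
#'
#' @param raw_voltage raw trace, mV
#' @param fs input sampling rate, Hz (default 10000)
#' @param out_fs output rate, Hz (default 100)
#' @param lfp_window median-filter window, s
#' @param spike_threshold valley threshold, mV
#' @param min_isi minimum inter-spike interval, s
#' @param rate_bw rate kernel bandwidth (Gaussian SD), s
#' @return list with `t`, `lfp`, `rate`, `spike_times`
#' @export
preprocess_recording <- function(raw_voltage, fs = 10000, out_fs = 100,
                                 lfp_window = 0.3, spike_threshold = -0.8,
                                 min_isi = 0.005, rate_bw = 0.15) {
  n <- length(raw_voltage)
  k <- as.integer(round(lfp_window * fs))
  if (k %% 2 == 0) k <- k + 1L
  if (n < k) stop("trace shorter than the median-filter window")
  lfp <- stats::runmed(raw_voltage, k, endrule = "median")
  band <- raw_voltage - lfp
  # candidate valleys: local minima below threshold
  i <- 2:(n - 1)
  is_valley <- band[i] < band[i - 1] & band[i] <= band[i + 1] &
    band[i] < spike_threshold
  cand <- i[is_valley]
  # enforce minimum separation, deeper valleys first
  spikes <- integer(0)
  if (length(cand)) {
    cand <- cand[order(band[cand])]
    keep_t <- numeric(0)
    gap <- min_isi * fs
    for (ci in cand) {
      if (!length(keep_t) || min(abs(keep_t - ci)) >= gap) {
        spikes <- c(spikes, ci)
        keep_t <- c(keep_t, ci)
      }
    }
    spikes <- sort(spikes)
  }
  spike_times <- (spikes - 1) / fs
  dec <- as.integer(round(fs / out_fs))
  n_out <- n %/% dec
  t_out <- (seq_len(n_out) - 1) / out_fs
  lfp_out <- colMeans(matrix(lfp[seq_len(n_out * dec)], nrow = dec))
  rate_out <- rate_from_spikes(spike_times, t_out, bw = rate_bw)
  list(t = t_out, lfp = lfp_out, rate = rate_out, spike_times = spike_times)
}

#' Kernel-smoothed firing rate from spike times
#'
#' @param spike_times spike times, s
#' @param t_grid evaluation times, s
#' @param bw Gaussian kernel SD, s (default 0.15)
#' @return firing rate in spikes/s at `t_grid`
#' @export
rate_from_spikes <- function(spike_times, t_grid, bw = 0.15) {
  if (!length(spike_times)) return(rep(0, length(t_grid)))
  rowSums(vapply(spike_times,
                 function(ts) stats::dnorm(t_grid - ts, sd = bw),
                 numeric(length(t_grid))))
}

#' Register trials onto a template by gain and offset
#'
#' Each trial is mapped onto the template by the least-squares affine map
#' (gain, offset) minimizing ||gain * trial + offset - template||^2, i.e. a
#' one-dimensional linear registration; the mean over registered trials is
#' returned.  Trials whose |gain| falls below `gain_flag` are flagged as
#' outliers (but still included).
#'
#' @param trials matrix with one trial per column, or a list of equal-length
#'   numeric vectors
#' @param template column index of the template trial (default 1)
#' @param gain_flag |gain| below which a trial is flagged
#' @return list with `registered` (matrix), `mean`, `gains`, `offsets`,
#'   `outliers` (logical)
#' @export
register_trials <- function(trials, template = 1, gain_flag = 0.1) {
  if (is.list(trials) && !is.matrix(trials)) trials <- do.call(cbind, trials)
  stopifnot(is.matrix(trials), ncol(trials) >= 2)
  tmpl <- trials[, template]
  if (stats::sd(tmpl) == 0) stop("degenerate (constant) template")
  reg <- trials
  gains <- offsets <- numeric(ncol(trials))
  for (j in seq_len(ncol(trials))) {
    x <- trials[, j]
    vx <- stats::var(x)
    g <- if (vx > 0) stats::cov(x, tmpl) / vx else 0
    o <- mean(tmpl) - g * mean(x)
    gains[j] <- g
    offsets[j] <- o
    reg[, j] <- g * x + o
  }
  list(registered = reg, mean = rowMeans(reg), gains = gains,
       offsets = offsets, outliers = abs(gains) < gain_flag)
}

#' Fit the LED calibration: shifted rectified-linear voltage-to-intensity map
#'
#' Fits intensity = max(0, m * (v - v0)) to calibration pairs by least
#' squares (nonlinear in v0, which is profiled out: for fixed v0 the slope
#' has a closed form, and the remaining one-dimensional problem is solved
#' by golden-section search over the voltage range).
#'
#' @param voltage driver control voltages, V
#' @param intensity measured intensities, uW/mm^2
#' @return list with `m`, `v0`, and a vectorized `map(v)` function
#' @export
fit_voltage_to_intensity <- function(voltage, intensity) {
  stopifnot(length(voltage) == length(intensity), length(voltage) >= 3)
  if (all(intensity == 0)) stop("all intensities are zero; map unidentifiable")
  # profile out the slope: for fixed v0 the least-squares m is closed form
  slope_for <- function(v0) {
    z <- pmax(0, voltage - v0)
    s2 <- sum(z^2)
    if (s2 == 0) 0 else sum(z * intensity) / s2
  }
  sse_v0 <- function(v0) {
    pred <- slope_for(v0) * pmax(0, voltage - v0)
    sum((pred - intensity)^2)
  }
  opt <- stats::optimize(sse_v0, range(voltage))
  v0 <- opt$minimum
  m <- slope_for(v0)
  list(m = m, v0 = v0, map = function(v) pmax(0, m * (v - v0)),
       sse = opt$objective)
}
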