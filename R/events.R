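# Entry/exit-aligned analyses: crossing detection from rate dynamics,
# aligned kinematic averages with half-resampled errors, turn-triggered
# rate averages, the logistic GLM for turn probability, and event-aligned
# behavioral filters.

#' Detect light-border crossings from a firing-rate series
#'
#' Entries and exits appear as positive and negative peaks of the rate
#' derivative beyond +/-15 spikes/s^2.  The derivative is the 200-ms mean
#' finite difference of the rate.
#'
#' @param rate firing-rate series, spikes/s
#' @param fs sampling rate, Hz (default 100)
#' @param threshold derivative threshold, spikes/s^2 (default 15)
#' @param smooth_s derivative smoothing window, s
#' @return data.frame with `kind` ("entry"/"exit"), `time` (s), `peak_df`
#' @export
detect_crossings <- function(rate, fs = 100, threshold = 15,
                             smooth_s = 0.2) {
  n <- length(rate)
  if (n < 3) return(data.frame(kind = character(), time = numeric(),
                               peak_df = numeric()))
  d <- running_mean(diff(rate) * fs, round(smooth_s * fs))
  m <- length(d)
  i <- 2:(m - 1)
  peak_up <- i[d[i] > threshold & d[i] >= d[i - 1] & d[i] > d[i + 1]]
  peak_dn <- i[d[i] < -threshold & d[i] <= d[i - 1] & d[i] < d[i + 1]]
  out <- rbind(
    data.frame(kind = rep("entry", length(peak_up)),
               time = (peak_up - 1) / fs, peak_df = d[peak_up]),
    data.frame(kind = rep("exit", length(peak_dn)),
               time = (peak_dn - 1) / fs, peak_df = d[peak_dn]))
  out[order(out$time), , drop = FALSE]
}

#' Entry/exit-aligned kinematic and state statistics
#'
#' Aligns per-fly speed, curvature, and sharp-turn state/transition
#' indicators to crossing events over a +/-`window` lag range, averages
#' across crossings, and estimates errors as the SD over 100 resamples of
#' 50% of the crossings.  Transition probability traces are smoothed with
#' a 200 ms mean filter and state-probability traces with a 1 s mean
#' filter.
#'
#' @param flies list of per-fly data.frames with columns `t`, `speed`,
#'   `curvature`, `state`
#' @param events data.frame with `fly` (index into `flies`) and `time`
#' @param window half-window, s (default 10)
#' @param fs lag-grid rate, Hz (default 30)
#' @param n_resample,resample_frac resampling settings (100 x 50%)
#' @param seed RNG seed for the resamples
#' @return list with `lag`, mean traces (`speed`, `curvature`, `p_turn`,
#'   `p_transition`) and matching `sd_*` traces, and `n_events`
#' @export
aligned_event_statistics <- function(flies, events, window = 10, fs = 30,
                                     n_resample = 100, resample_frac = 0.5,
                                     seed = NULL) {
  if (nrow(events) < 1) stop("no crossing events")
  lag <- seq(-window, window, by = 1 / fs)
  grab <- function(fly, t0, col) {
    stats::approx(fly$t, fly[[col]], xout = t0 + lag, rule = 1)$y
  }
  ne <- nrow(events)
  sp <- cv <- tn <- tr <- matrix(NA_real_, length(lag), ne)
  for (e in seq_len(ne)) {
    fly <- flies[[events$fly[e]]]
    t0 <- events$time[e]
    sp[, e] <- grab(fly, t0, "speed")
    cv[, e] <- grab(fly, t0, "curvature")
    is_turn <- as.numeric(fly$state == "sharp_turn")
    trans <- c(0, diff(is_turn) > 0)
    tn[, e] <- stats::approx(fly$t, is_turn, xout = t0 + lag,
                             method = "constant", rule = 1)$y
    tr[, e] <- stats::approx(fly$t, trans, xout = t0 + lag,
                             method = "constant", rule = 1)$y
  }
  mean_trace <- function(m) rowMeans(m, na.rm = TRUE)
  p_turn <- running_mean(mean_trace(tn), round(1 * fs))
  p_trans <- running_mean(mean_trace(tr), round(0.2 * fs))
  resamp <- with_seed(seed, {
    k <- max(1L, round(ne * resample_frac))
    arr <- replicate(n_resample, {
      pick <- sample.int(ne, k)
      c(speed = list(mean_trace(sp[, pick, drop = FALSE])),
        curvature = list(mean_trace(cv[, pick, drop = FALSE])),
        p_turn = list(running_mean(mean_trace(tn[, pick, drop = FALSE]),
                                   round(1 * fs))),
        p_transition = list(running_mean(
          mean_trace(tr[, pick, drop = FALSE]), round(0.2 * fs))))
    }, simplify = FALSE)
    arr
  })
  sd_of <- function(name) {
    m <- vapply(resamp, function(r) r[[name]], numeric(length(lag)))
    apply(m, 1, stats::sd, na.rm = TRUE)
  }
  list(lag = lag, speed = mean_trace(sp), curvature = mean_trace(cv),
       p_turn = p_turn, p_transition = p_trans,
       sd_speed = sd_of("speed"), sd_curvature = sd_of("curvature"),
       sd_p_turn = sd_of("p_turn"), sd_p_transition = sd_of("p_transition"),
       n_events = ne)
}

#' Turn-triggered average firing-rate history
#'
#' Averages the 10-s rate history preceding each qualifying sharp turn
#' (indexed at its curvature peak).  Only turns at a non-baseline rate
#' qualify; histories of turns within 10 s of the previous entry are
#' truncated to that entry time.
#'
#' @param rate firing-rate series
#' @param rate_t time stamps of `rate`
#' @param turn_times sharp-turn (curvature-peak) times, s
#' @param entry_times entry times, s (used for truncation)
#' @param baseline baseline rate, spikes/s (default 4.7)
#' @param window history length, s (default 10)
#' @return list with `lag` (-window..0), `tta`, `n_per_lag`, `n_turns`
#' @export
turn_triggered_average <- function(rate, rate_t, turn_times, entry_times,
                                   baseline = 4.7, window = 10) {
  fs <- 1 / stats::median(diff(rate_t))
  lag <- seq(-window, 0, by = 1 / fs)
  rate_at <- function(tt) stats::approx(rate_t, rate, xout = tt,
                                        rule = 1)$y
  qual <- turn_times[!is.na(rate_at(turn_times)) &
                       rate_at(turn_times) > baseline]
  if (!length(qual)) stop("no qualifying turns")
  hist_m <- vapply(qual, function(t0) {
    h <- rate_at(t0 + lag)
    prev_entry <- suppressWarnings(max(entry_times[entry_times <= t0]))
    if (is.finite(prev_entry)) h[t0 + lag < prev_entry] <- NA_real_
    h
  }, numeric(length(lag)))
  list(lag = lag, tta = rowMeans(hist_m, na.rm = TRUE),
       n_per_lag = rowSums(!is.na(hist_m)), n_turns = length(qual))
}

#' Logistic GLM for turn-transition probability
#'
#' Fits logit(P(turn transition at t)) = b0 + b_f * f(t) + b_df * df(t)
#' by maximum likelihood.
#'
#' @param turn_indicator 0/1 series of turn-transition steps
#' @param f,df firing rate and rate change series, aligned
#' @return list of class `turn_glm`: `coef` (b0, b_f, b_df), `se`,
#'   `deviance`, `separation` flag, and the `glm` fit
#' @export
fit_turn_glm <- function(turn_indicator, f, df) {
  stopifnot(length(turn_indicator) == length(f), length(f) == length(df),
            length(f) >= 100)
  dat <- data.frame(y = turn_indicator, f = f, df = df)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ f + df, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(coef = c(b0 = unname(cf[1]), b_f = unname(cf[2]),
                          b_df = unname(cf[3])),
                 se = c(b0 = unname(se[1]), b_f = unname(se[2]),
                        b_df = unname(se[3])),
                 deviance = stats::deviance(fit), separation = sep,
                 fit = fit),
            class = "turn_glm")
}

#' Event-aligned behavioral filter
#'
#' Fits a 2-s linear filter predicting a kinematic series from the firing
#' rate, using the same ridge machinery as the encoder filters.
#'
#' @param rate firing-rate series at 100 Hz
#' @param kinematic aligned kinematic series
#' @param d filter length, samples (default 200 = 2 s)
#' @param ... passed to [fit_filter()]
#' @return a `filter_fit`
#' @export
fit_event_filter <- function(rate, kinematic, d = 200, ...) {
  fit_filter(rate, kinematic, d = d, ...)
}
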