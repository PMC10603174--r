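# State-space mapping: embedding of locomotor-state starts at (f, df),
# region classification, KNN lognormal kinematic maps with elliptical
# distance bounds, time-resolved (adaptation) maps and permutation test,
# map comparison, transition-probability maps, and the auxiliary state
# distribution fits used by the agent model.

#' Grid over the neural response space (f, df)
#'
#' Defaults follow the standard analysis grid: firing rate f from 0 to 55
#' spikes/s in 1 spikes/s steps; rate change df from -150 to 150 spikes/s^2
#' in 15 spikes/s^2 steps.  Distances are measured after dividing f and df
#' by weights a = 10 and b = 30 (only the ratio matters); the time axis of
#' the 3-D (adaptation) variant uses weight c = 20 and 5-s increments.
#'
#' @param f_axis grid values for f
#' @param df_axis grid values for df
#' @param a,b,c distance weights for f, df, and time
#' @param K neighbor count
#' @param T_bound elliptical distance bound (unitless)
#' @param min_n cells with <= `min_n` in-bound points are masked
#' @return object of class `map_grid`
#' @export
make_map_grid <- function(f_axis = 0:55, df_axis = seq(-150, 150, by = 15),
                          a = 10, b = 30, c = 20, K = 64, T_bound = 1.5,
                          min_n = 15) {
  stopifnot(all(diff(f_axis) > 0), all(diff(df_axis) > 0),
            a > 0, b > 0, c > 0, T_bound > 0, K >= 1)
  structure(list(f_axis = f_axis, df_axis = df_axis, a = a, b = b, c = c,
                 K = K, T_bound = T_bound, min_n = min_n),
            class = "map_grid")
}

#' Recommended K and T per mapped quantity
#'
#' Sharp-turn and curved-walk kinematics use K = 64, T = 1.5; stop
#' kinematics use K = 64, T = 1; transition probabilities use K = 128,
#' T = 1.5.
#'
#' @return named list of `list(K, T)` settings
#' @export
knn_defaults <- function() {
  list(kinematics = list(K = 64, T = 1.5),
       stops = list(K = 64, T = 1),
       transitions = list(K = 128, T = 1.5))
}

#' Classify a point of the neural response space into regions I-V
#'
#' Region I: strongly rising rate (df > 20 spikes/s^2), the fly entering
#' the stimulus zone.  Region III: strongly falling rate (df < -20),
#' leaving.  Otherwise region IV when the rate is below the 4.7 spikes/s
#' baseline (inhibition), region II when above 15 spikes/s (fully inside),
#' and region V between baseline and 15 spikes/s (border exploration).
#' Rate-of-change regions take precedence where definitions overlap.
#'
#' @param f firing rate, spikes/s (vectorized)
#' @param df rate change, spikes/s^2 (vectorized)
#' @param baseline baseline rate, spikes/s
#' @return character vector of "I".."V"
#' @export
classify_region <- function(f, df, baseline = 4.7) {
  stopifnot(length(f) == length(df))
  out <- rep("V", length(f))
  out[f > 15] <- "II"
  out[f < baseline] <- "IV"
  out[df > 20] <- "I"
  out[df < -20] <- "III"
  out
}

#' Embed locomotor-state starts in the neural response space
#'
#' For every state segment starting after first entry, computes the mean
#' firing rate f and the mean rate derivative df over the 200 ms window
#' preceding the state start, and attaches the segment's kinematic
#' summaries.  Points are also labeled by firing-rate context: `inhibition`
#' when f is near zero, `baseline` when f sits in a band around the
#' baseline rate with small |df|, else `non_baseline`.
#'
#' @param segments summarized segments (see [summarize_segments()]) with a
#'   `start_t` column
#' @param rate firing-rate series, spikes/s
#' @param rate_t time stamps of `rate`, s (100 Hz)
#' @param first_entry_time first entry, s; segments starting earlier are
#'   dropped (pass `-Inf` to keep all)
#' @param window look-back window, s (default 0.2)
#' @param baseline baseline rate, spikes/s
#' @param baseline_band half-width of the baseline band, spikes/s
#' @param inhibition_rate f below this is labeled inhibition
#' @return data.frame of class `state_points`: `state`, `f`, `df`,
#'   `t_entry`, `context`, kinematic columns, `next_state`
#' @export
embed_state_points <- function(segments, rate, rate_t, first_entry_time,
                               window = 0.2, baseline = 4.7,
                               baseline_band = 3, inhibition_rate = 1) {
  dt <- stats::median(diff(rate_t))
  if (is.null(segments$avg_abs_curvature))
    segments$avg_abs_curvature <- NA_real_
  keep <- which(segments$start_t >= first_entry_time &
                  segments$start_t - window >= rate_t[1])
  if (length(keep) && any(segments$start_t[keep] > max(rate_t) + dt))
    stop("segment start beyond rate coverage")
  rows <- lapply(keep, function(i) {
    t0 <- segments$start_t[i]
    in_win <- rate_t >= t0 - window & rate_t < t0
    rw <- rate[in_win]
    if (length(rw) < 2) return(NULL)
    f <- mean(rw)
    df <- mean(diff(rw) / dt)
    data.frame(state = segments$state[i], f = f, df = df,
               t_entry = t0 - first_entry_time,
               avg_speed = segments$avg_speed[i],
               total_curvature = segments$total_curvature[i],
               avg_curvature = segments$avg_curvature[i],
               avg_abs_curvature = segments$avg_abs_curvature[i],
               duration = segments$duration[i],
               next_state = if (i < nrow(segments)) segments$state[i + 1]
                            else NA_character_,
               stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, rows)
  if (is.null(pts)) pts <- data.frame(state = character(), f = numeric(),
                                      df = numeric(), t_entry = numeric(),
                                      avg_speed = numeric(),
                                      total_curvature = numeric(),
                                      avg_curvature = numeric(),
                                      avg_abs_curvature = numeric(),
                                      duration = numeric(),
                                      next_state = character())
  pts$context <- ifelse(pts$f < inhibition_rate, "inhibition",
                 ifelse(abs(pts$f - baseline) <= baseline_band &
                          abs(pts$df) <= 10, "baseline", "non_baseline"))
  class(pts) <- c("state_points", "data.frame")
  pts
}

# Indices of the K nearest points to node (y, x) under the weighted
# elliptical metric, restricted to the T bound.  Internal workhorse.
knn_neighbors <- function(f, df, y, x, a, b, K, T_bound,
                          t = NULL, z = NULL, cweight = NULL) {
  d2 <- ((f - y) / a)^2 + ((df - x) / b)^2
  if (!is.null(t)) d2 <- d2 + ((t - z) / cweight)^2
  within <- which(d2 <= T_bound^2)
  if (length(within) > K) within[order(d2[within])[seq_len(K)]] else within
}

#' Fit a KNN lognormal kinematic map
#'
#' For each grid node, gathers the K nearest embedded points under the
#' weighted elliptical metric within distance bound T, and fits a lognormal
#' distribution (mean and ML standard deviation of the log values) to the
#' chosen kinematic parameter.  Nodes with at most `min_n` in-bound points
#' are masked.  Values that are not strictly positive cannot be
#' log-transformed and are excluded, with the exclusion count recorded.
#'
#' @param points a `state_points` data.frame (already filtered to one state
#'   if appropriate)
#' @param parameter column of `points` to map (e.g. `"avg_speed"`); values
#'   are used as |value| when `use_magnitude` is `TRUE`
#' @param grid a [make_map_grid()]; its `K`, `T_bound`, `min_n` are used
#' @param use_magnitude map |value| instead of the signed value
#' @param value_floor values below this are clamped to it before the log
#'   transform; tracking has a finite spatial resolution, and clamping at
#'   the measurement floor keeps a handful of numerically-zero magnitudes
#'   (e.g. curvature on a perfectly straight path) from dominating the
#'   log-scale variance
#' @return object of class `kinematic_map` with matrices `mu`, `sigma`,
#'   `n` (f along rows, df along columns) and a logical `mask` of defined
#'   cells
#' @export
fit_knn_map <- function(points, parameter, grid = make_map_grid(),
                        use_magnitude = FALSE, value_floor = 0) {
  vals <- points[[parameter]]
  if (use_magnitude) vals <- abs(vals)
  if (value_floor > 0) vals <- pmax(vals, value_floor)
  nf <- length(grid$f_axis); ndf <- length(grid$df_axis)
  mu <- sigma <- matrix(NA_real_, nf, ndf)
  nmat <- matrix(0L, nf, ndf)
  excluded <- 0L
  for (i in seq_len(nf)) {
    for (j in seq_len(ndf)) {
      nb <- knn_neighbors(points$f, points$df, grid$f_axis[i],
                          grid$df_axis[j], grid$a, grid$b, grid$K,
                          grid$T_bound)
      nmat[i, j] <- length(nb)
      if (length(nb) > grid$min_n) {
        v <- vals[nb]
        bad <- !(is.finite(v) & v > 0)
        excluded <- excluded + sum(bad)
        lm_ <- log_moments(v[!bad])
        if (lm_$n > grid$min_n) {
          mu[i, j] <- lm_$meanlog
          sigma[i, j] <- lm_$sdlog
        }
      }
    }
  }
  mask <- is.finite(mu)
  structure(list(grid = grid, parameter = parameter, mu = mu, sigma = sigma,
                 n = nmat, mask = mask, excluded = excluded,
                 defined = which(mask, arr.ind = TRUE)),
            class = "kinematic_map")
}

#' Query a kinematic map by bilinear interpolation
#'
#' Interpolates mu and sigma linearly over the grid.  Queries whose
#' surrounding cell has any masked corner are undefined (`NA`) unless
#' `fallback = TRUE`, in which case the nearest defined node is used and
#' flagged.
#'
#' @param map a [fit_knn_map()] result
#' @param f,df query coordinates (vectorized)
#' @param fallback use nearest defined node outside the defined hull
#' @return data.frame with `mu`, `sigma`, `fallback_used`
#' @export
query_map <- function(map, f, df, fallback = FALSE) {
  g <- map$grid
  n <- max(length(f), length(df))
  f <- rep_len(f, n); df <- rep_len(df, n)
  mu <- sig <- rep(NA_real_, n)
  fb <- rep(FALSE, n)
  fi <- findInterval(f, g$f_axis, rightmost.closed = TRUE)
  dj <- findInterval(df, g$df_axis, rightmost.closed = TRUE)
  nf <- length(g$f_axis); ndf <- length(g$df_axis)
  for (q in seq_len(n)) {
    i <- fi[q]; j <- dj[q]
    ok <- i >= 1 && i < nf && j >= 1 && j < ndf
    if (ok) {
      ii <- c(i, i + 1L); jj <- c(j, j + 1L)
      if (all(map$mask[ii, jj])) {
        wx <- (f[q] - g$f_axis[i]) / (g$f_axis[i + 1] - g$f_axis[i])
        wy <- (df[q] - g$df_axis[j]) / (g$df_axis[j + 1] - g$df_axis[j])
        w <- outer(c(1 - wx, wx), c(1 - wy, wy))
        mu[q] <- sum(w * map$mu[ii, jj])
        sig[q] <- sum(w * map$sigma[ii, jj])
        next
      }
    }
    # exactly on a defined node?
    hit_i <- which(g$f_axis == f[q]); hit_j <- which(g$df_axis == df[q])
    if (length(hit_i) && length(hit_j) && map$mask[hit_i, hit_j]) {
      mu[q] <- map$mu[hit_i, hit_j]; sig[q] <- map$sigma[hit_i, hit_j]
      next
    }
    if (fallback && any(map$mask)) {
      def <- map$defined %||% which(map$mask, arr.ind = TRUE)
      d2 <- ((g$f_axis[def[, 1]] - f[q]) / g$a)^2 +
        ((g$df_axis[def[, 2]] - df[q]) / g$b)^2
      k <- which.min(d2)
      mu[q] <- map$mu[def[k, 1], def[k, 2]]
      sig[q] <- map$sigma[def[k, 1], def[k, 2]]
      fb[q] <- TRUE
    }
  }
  data.frame(mu = mu, sigma = sig, fallback_used = fb)
}

#' Grid search of K and T with elbow selection
#'
#' Computes the mean standard error of the per-cell lognormal mean
#' (sigma / sqrt(n)) over all defined cells for every (K, T) combination,
#' and locates the elbow (maximum-curvature point) of the SEM-versus-K
#' curve at each T.
#'
#' @param points state points
#' @param parameter mapped column
#' @param K_grid,T_grid search grids
#' @param grid base grid geometry
#' @param use_magnitude see [fit_knn_map()]
#' @return list: `sem` matrix (K by T), `elbow_K` per T, and `selected`
#'   (K at the elbow for the largest T, with that T)
#' @export
select_knn_params <- function(points, parameter,
                              K_grid = c(16, 32, 64, 128, 256),
                              T_grid = c(1, 1.5), grid = make_map_grid(),
                              use_magnitude = FALSE) {
  sem <- matrix(NA_real_, length(K_grid), length(T_grid),
                dimnames = list(K_grid, T_grid))
  for (tj in seq_along(T_grid)) {
    for (ki in seq_along(K_grid)) {
      g <- grid; g$K <- K_grid[ki]; g$T_bound <- T_grid[tj]
      m <- fit_knn_map(points, parameter, g, use_magnitude = use_magnitude)
      if (any(m$mask))
        sem[ki, tj] <- mean((m$sigma / sqrt(m$n))[m$mask])
    }
  }
  elbow_K <- vapply(seq_along(T_grid), function(tj) {
    s <- sem[, tj]
    if (sum(is.finite(s)) < 3) return(NA_real_)
    K_grid[elbow_index(log(K_grid), s)]
  }, numeric(1))
  sel_t <- length(T_grid)
  list(sem = sem, elbow_K = elbow_K,
       selected = list(K = elbow_K[sel_t], T = T_grid[sel_t]))
}

#' Time-resolved (adaptation) KNN map
#'
#' Extends the neighborhood metric with time since first entry as a third
#' dimension (weight `grid$c`, default 20; 5-s increments along the time
#' axis), giving per-(cell, time-slice) lognormal fits.
#'
#' @param points state points with a `t_entry` column
#' @param parameter mapped column
#' @param grid a [make_map_grid()]
#' @param t_axis time-slice centers, s (default 5-s increments spanning the
#'   observed `t_entry` range)
#' @param use_magnitude see [fit_knn_map()]
#' @return object of class `kinematic_map3`: arrays `mu`, `sigma`, `n` of
#'   dim (f, df, t), `mask`, plus `t_axis`
#' @export
fit_time_resolved_map <- function(points, parameter, grid = make_map_grid(),
                                  t_axis = NULL, use_magnitude = FALSE) {
  if (is.null(t_axis))
    t_axis <- seq(0, max(points$t_entry), by = 5)
  vals <- points[[parameter]]
  if (use_magnitude) vals <- abs(vals)
  nf <- length(grid$f_axis); ndf <- length(grid$df_axis)
  nt <- length(t_axis)
  mu <- sigma <- array(NA_real_, c(nf, ndf, nt))
  nn <- array(0L, c(nf, ndf, nt))
  for (i in seq_len(nf)) {
    for (j in seq_len(ndf)) {
      d2fd <- ((points$f - grid$f_axis[i]) / grid$a)^2 +
        ((points$df - grid$df_axis[j]) / grid$b)^2
      for (k in seq_len(nt)) {
        d2 <- d2fd + ((points$t_entry - t_axis[k]) / grid$c)^2
        within <- which(d2 <= grid$T_bound^2)
        if (length(within) > grid$K)
          within <- within[order(d2[within])[seq_len(grid$K)]]
        nn[i, j, k] <- length(within)
        if (length(within) > grid$min_n) {
          lm_ <- log_moments(vals[within])
          if (lm_$n > grid$min_n) {
            mu[i, j, k] <- lm_$meanlog
            sigma[i, j, k] <- lm_$sdlog
          }
        }
      }
    }
  }
  structure(list(grid = grid, parameter = parameter, t_axis = t_axis,
                 mu = mu, sigma = sigma, n = nn, mask = is.finite(mu)),
            class = "kinematic_map3")
}

#' Permutation test for adaptation of the kinematic mapping
#'
#' Shuffles time-since-first-entry across points, recomputes the
#' time-resolved map for each shuffle, and flags each (cell, slice) whose
#' empirical lognormal mean lies above, below, or within the central 95%
#' band of the shuffled means.
#'
#' @param points state points with `t_entry`
#' @param parameter mapped column
#' @param grid a [make_map_grid()]
#' @param t_axis time-slice centers, s
#' @param n_perm number of shuffles (default 100)
#' @param seed RNG seed
#' @param use_magnitude see [fit_knn_map()]
#' @return list with the empirical map, `flags` array ("above" / "below" /
#'   "within" / NA), and the permutation band arrays `lo`, `hi`
#' @export
permutation_adaptation_test <- function(points, parameter,
                                        grid = make_map_grid(),
                                        t_axis = NULL, n_perm = 100,
                                        seed = NULL, use_magnitude = FALSE) {
  stopifnot(n_perm >= 2)
  if (is.null(t_axis)) t_axis <- seq(0, max(points$t_entry), by = 5)
  emp <- fit_time_resolved_map(points, parameter, grid, t_axis,
                               use_magnitude = use_magnitude)
  dims <- dim(emp$mu)
  perm_mu <- array(NA_real_, c(dims, n_perm))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      shuffled <- points
      shuffled$t_entry <- sample(points$t_entry)
      pm <- fit_time_resolved_map(shuffled, parameter, grid, t_axis,
                                  use_magnitude = use_magnitude)
      perm_mu[, , , p] <- pm$mu
    }
  })
  lo <- apply(perm_mu, 1:3, stats::quantile, probs = 0.025, na.rm = TRUE)
  hi <- apply(perm_mu, 1:3, stats::quantile, probs = 0.975, na.rm = TRUE)
  flags <- array(NA_character_, dims)
  def <- emp$mask & is.finite(lo) & is.finite(hi)
  flags[def] <- "within"
  flags[def & emp$mu > hi] <- "above"
  flags[def & emp$mu < lo] <- "below"
  list(map = emp, flags = flags, lo = lo, hi = hi)
}

#' Compare two embedded point sets over the map grid
#'
#' Per cell, runs a two-sample Kolmogorov-Smirnov test between the raw
#' kinematic values of the two sets' neighborhoods, and accumulates total
#' negative log-likelihoods of lognormal versus normal fits (on set A).
#' Cells with too few points on either side are skipped.  Benjamini-
#' Hochberg correction across cells is applied when flagging significance
#' (configurable off).
#'
#' @param points_A,points_B state-point sets on the same grid
#' @param parameter compared column
#' @param grid a [make_map_grid()]
#' @param adjust apply BH correction for the significance flags
#' @param alpha significance level
#' @param use_magnitude see [fit_knn_map()]
#' @return list: `p` matrix of KS p-values, `significant` logical matrix,
#'   `nll_lognormal`, `nll_normal` totals
#' @export
compare_maps <- function(points_A, points_B, parameter,
                         grid = make_map_grid(), adjust = TRUE,
                         alpha = 0.05, use_magnitude = FALSE) {
  va <- points_A[[parameter]]; vb <- points_B[[parameter]]
  if (use_magnitude) { va <- abs(va); vb <- abs(vb) }
  nf <- length(grid$f_axis); ndf <- length(grid$df_axis)
  p <- matrix(NA_real_, nf, ndf)
  nll_ln <- nll_n <- 0
  for (i in seq_len(nf)) {
    for (j in seq_len(ndf)) {
      na_ <- knn_neighbors(points_A$f, points_A$df, grid$f_axis[i],
                           grid$df_axis[j], grid$a, grid$b, grid$K,
                           grid$T_bound)
      nb_ <- knn_neighbors(points_B$f, points_B$df, grid$f_axis[i],
                           grid$df_axis[j], grid$a, grid$b, grid$K,
                           grid$T_bound)
      if (length(na_) <= grid$min_n || length(nb_) <= grid$min_n) next
      xa <- va[na_]; xb <- vb[nb_]
      xa <- xa[is.finite(xa) & xa > 0]; xb <- xb[is.finite(xb) & xb > 0]
      if (length(xa) <= grid$min_n || length(xb) <= grid$min_n) next
      p[i, j] <- suppressWarnings(stats::ks.test(xa, xb)$p.value)
      lm_ <- log_moments(xa)
      nll_ln <- nll_ln - sum(stats::dlnorm(xa, lm_$meanlog,
                                           max(lm_$sdlog, 1e-12),
                                           log = TRUE))
      mu_n <- mean(xa); sd_n <- sqrt(mean((xa - mu_n)^2))
      nll_n <- nll_n - sum(stats::dnorm(xa, mu_n, max(sd_n, 1e-12),
                                        log = TRUE))
    }
  }
  pv <- p[is.finite(p)]
  sig <- matrix(FALSE, nf, ndf)
  if (length(pv)) {
    padj <- if (adjust) stats::p.adjust(pv, "BH") else pv
    sig[is.finite(p)] <- padj < alpha
  }
  list(p = p, significant = sig, nll_lognormal = nll_ln, nll_normal = nll_n)
}

#' Transition-probability map over the neural response space
#'
#' For each source state and grid cell, estimates the categorical
#' distribution of the next state from the K = 128, T = 1.5 neighborhood
#' of points of that source state (non-self transitions), smooths each
#' next-state plane with a 5 x 5 uniform kernel over defined cells, and
#' renormalizes.
#'
#' @param points state points with `state` and `next_state`
#' @param grid a [make_map_grid()]; the transition defaults K = 128 are
#'   applied unless the grid was built with other values on purpose
#' @param states source states to map
#' @return object of class `transition_map`: per source state an array
#'   (f, df, next_state) of probabilities plus a `mask`
#' @export
fit_transition_map <- function(points, grid = NULL,
                               states = c("curved_walk", "stop",
                                          "sharp_turn")) {
  if (is.null(grid)) {
    d <- knn_defaults()$transitions
    grid <- make_map_grid(K = d$K, T_bound = d$T)
  }
  nf <- length(grid$f_axis); ndf <- length(grid$df_axis)
  all_states <- c("sharp_turn", "curved_walk", "stop", "boundary")
  maps <- list()
  for (s in states) {
    sub <- points[points$state == s & !is.na(points$next_state) &
                    points$next_state != s, , drop = FALSE]
    pr <- array(NA_real_, c(nf, ndf, length(all_states)),
                dimnames = list(NULL, NULL, all_states))
    for (i in seq_len(nf)) {
      for (j in seq_len(ndf)) {
        nb <- knn_neighbors(sub$f, sub$df, grid$f_axis[i], grid$df_axis[j],
                            grid$a, grid$b, grid$K, grid$T_bound)
        if (length(nb) > grid$min_n) {
          tab <- table(factor(sub$next_state[nb], levels = all_states))
          pr[i, j, ] <- as.numeric(tab) / sum(tab)
        }
      }
    }
    # 5x5 uniform smoothing over defined cells, then renormalize
    mask <- is.finite(pr[, , 1])
    for (k in seq_along(all_states)) {
      pr[, , k] <- smooth_defined(pr[, , k], 5)
    }
    tot <- apply(pr, c(1, 2), sum)
    for (k in seq_along(all_states)) pr[, , k] <- pr[, , k] / tot
    maps[[s]] <- pr
  }
  defined <- lapply(maps, function(pr) which(is.finite(pr[, , 1]),
                                             arr.ind = TRUE))
  structure(list(grid = grid, maps = maps, states = states,
                 all_states = all_states, defined = defined),
            class = "transition_map")
}

# Uniform k x k smoothing of a matrix with NA cells: each output cell is
# the mean of the defined cells in its window; NA where none are defined.
smooth_defined <- function(m, k = 5) {
  nf <- nrow(m); ndf <- ncol(m)
  half <- k %/% 2
  out <- m
  for (i in seq_len(nf)) {
    ii <- max(1, i - half):min(nf, i + half)
    for (j in seq_len(ndf)) {
      jj <- max(1, j - half):min(ndf, j + half)
      v <- m[ii, jj]
      if (any(is.finite(v))) out[i, j] <- mean(v, na.rm = TRUE)
      else out[i, j] <- NA_real_
    }
  }
  out
}

#' Query a transition map
#'
#' Nearest-defined-cell lookup of the next-state distribution for a source
#' state at (f, df).
#'
#' @param tmap a [fit_transition_map()] result
#' @param state source state
#' @param f,df query coordinates (scalars)
#' @return named probability vector over next states
#' @export
query_transition <- function(tmap, state, f, df) {
  g <- tmap$grid
  pr <- tmap$maps[[state]]
  if (is.null(pr)) stop("no transition map for state ", state)
  def <- tmap$defined[[state]] %||% which(is.finite(pr[, , 1]),
                                          arr.ind = TRUE)
  if (!nrow(def)) stop("transition map for ", state, " is empty")
  d2 <- ((g$f_axis[def[, 1]] - f) / g$a)^2 +
    ((g$df_axis[def[, 2]] - df) / g$b)^2
  k <- which.min(d2)
  stats::setNames(pr[def[k, 1], def[k, 2], ], tmap$all_states)
}

#' Fit the auxiliary state distributions used by the agent model
#'
#' Covers the firing-rate contexts that the KNN maps do not: per-state
#' lognormal fits of each kinematic parameter before first entry; a
#' bivariate lognormal over (arc angle, duration) for the boundary state;
#' time-dependent fits during inhibition periods (lognormal speed, beta
#' curvature rescaled to [0, 1] by the empirical range, exponential
#' duration) over a 0.5-s sliding window with 0.3-s overlap, with the
#' window-center parameters interpolated by a spline; and post-entry
#' baseline fits split into the first two trajectories after reaching
#' baseline versus trajectory three onward.
#'
#' @param curvature_floor curvature magnitudes are clamped from below at
#'   this value before log fits (measurement resolution floor)
#' @param segments summarized segments with columns `state`, `avg_speed`,
#'   `total_curvature`, `avg_curvature`, `duration`, `arc_angle`, plus
#'   `phase` in `{"before", "baseline_12", "baseline_3plus", "inhibition"}`
#'   and, for inhibition rows, `t_inhibition` (s since inhibition onset)
#' @param min_window_n windows with fewer segments are skipped (default 5)
#' @return object of class `state_distributions`
#' @export
fit_state_distributions <- function(segments, min_window_n = 5,
                                    curvature_floor = 1e-3) {
  for (cc in c("avg_abs_curvature", "total_curvature")) {
    if (cc %in% names(segments)) {
      v <- segments[[cc]]
      segments[[cc]] <- sign(v) * pmax(abs(v), curvature_floor)
    }
  }
  param_for <- function(state) switch(
    state,
    curved_walk = c("avg_speed", "avg_abs_curvature", "duration"),
    sharp_turn = c("avg_speed", "total_curvature", "duration"),
    stop = c("total_curvature", "duration"),
    boundary = c("arc_angle", "duration"))
  states <- c("curved_walk", "sharp_turn", "stop")
  fit_block <- function(sub) {
    out <- list()
    for (s in states) {
      ss <- sub[sub$state == s, , drop = FALSE]
      fits <- list()
      for (p in param_for(s)) {
        lm_ <- log_moments(abs(ss[[p]]))
        pos <- mean(ss[[p]] > 0, na.rm = TRUE)
        fits[[p]] <- list(meanlog = lm_$meanlog, sdlog = lm_$sdlog,
                          n = lm_$n, p_positive = pos)
      }
      out[[s]] <- fits
    }
    out
  }
  before <- segments[segments$phase == "before", , drop = FALSE]
  res <- list(before = fit_block(before))
  # boundary: bivariate lognormal on (arc angle, duration), before/after
  for (ph in c("before", "after")) {
    b <- segments[segments$state == "boundary" &
                    (if (ph == "before") segments$phase == "before"
                     else segments$phase != "before"), , drop = FALSE]
    b <- b[is.finite(b$arc_angle) & b$arc_angle > 0 & b$duration > 0, ,
           drop = FALSE]
    if (nrow(b) >= 3) {
      lg <- cbind(log(b$arc_angle), log(b$duration))
      res$boundary[[ph]] <- list(mean = colMeans(lg), cov = stats::cov(lg),
                                 n = nrow(b))
    }
  }
  # baseline splits
  res$baseline_12 <- fit_block(
    segments[segments$phase == "baseline_12", , drop = FALSE])
  res$baseline_3plus <- fit_block(
    segments[segments$phase == "baseline_3plus", , drop = FALSE])
  # inhibition: time-dependent fits
  inh <- segments[segments$phase == "inhibition" &
                    is.finite(segments$t_inhibition), , drop = FALSE]
  res$inhibition <- list()
  if (nrow(inh)) {
    step <- 0.2    # 0.5-s window, 0.3-s overlap
    tmax <- max(inh$t_inhibition)
    centers <- seq(0.25, max(0.25, tmax), by = step)
    for (s in states) {
      ss <- inh[inh$state == s, , drop = FALSE]
      if (!nrow(ss)) next
      speed_p <- curv_p <- dur_p <- NULL
      cv <- abs(if (s == "curved_walk") ss$avg_abs_curvature
                else ss$total_curvature)
      rng <- range(cv[is.finite(cv)], na.rm = TRUE)
      used <- numeric(0)
      pars <- list()
      for (ct in centers) {
        w <- ss[ss$t_inhibition >= ct - 0.25 & ss$t_inhibition < ct + 0.25, ,
                drop = FALSE]
        if (nrow(w) < min_window_n) next
        lm_ <- log_moments(w$avg_speed)
        cvw <- abs(if (s == "curved_walk") w$avg_abs_curvature
                   else w$total_curvature)
        sc <- (cvw - rng[1]) / max(diff(rng), 1e-12)
        sc <- pmin(pmax(sc, 1e-4), 1 - 1e-4)
        mb <- mean(sc); vb <- stats::var(sc)
        k0 <- max(mb * (1 - mb) / max(vb, 1e-8) - 1, 0.1)
        start_mm <- list(shape1 = max(mb * k0, 0.05),
                         shape2 = max((1 - mb) * k0, 0.05))
        bfit <- tryCatch(
          suppressWarnings(
            fitdistrplus::fitdist(sc, "beta", start = start_mm)$estimate),
          error = function(e) unlist(start_mm))
        used <- c(used, ct)
        pars[[length(pars) + 1]] <- c(
          meanlog = lm_$meanlog, sdlog = lm_$sdlog,
          shape1 = unname(bfit[1]), shape2 = unname(bfit[2]),
          rate = 1 / mean(w$duration))
      }
      if (length(used) >= 1) {
        pm <- do.call(rbind, pars)
        # spline through the finite window estimates; constant (or NA)
        # interpolants where fewer than two windows are usable
        splines <- lapply(colnames(pm), function(cn) {
          v <- pm[, cn]
          ok <- is.finite(v)
          if (sum(ok) >= 2)
            stats::splinefun(used[ok], v[ok], method = "natural")
          else if (sum(ok) == 1) {
            v0 <- v[ok]
            function(t) rep(v0, length(t))
          } else function(t) rep(NA_real_, length(t))
        })
        names(splines) <- colnames(pm)
        res$inhibition[[s]] <- list(centers = used, params = pm,
                                    interpolate = splines,
                                    curvature_range = rng)
      }
    }
  }
  class(res) <- "state_distributions"
  res
}
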