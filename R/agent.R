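# Generative agent-based model: virtual flies walk the arena through the
# four locomotor states; at every state transition the next state, the
# state kinematics, and the turn direction are sampled conditionally on
# the fly's own reconstructed ORN activity (f, df over the preceding
# 200 ms), closing the loop through the encoder cascade.

#' Agent simulation configuration
#'
#' @param n_flies cohort size (default 150)
#' @param duration total simulated time, s (default 360)
#' @param light_on light onset, s (default 180)
#' @param dt simulation step, s (default 0.01, i.e. 100 Hz)
#' @param first_entry_rate_threshold firing rate defining first entry,
#'   spikes/s (default 10)
#' @param boundary_threshold distance from the wall entering the boundary
#'   state, normalized (default 0.0375 = 1.5 mm in the 4 cm arena)
#' @param inhibition_rate firing rate below which the fly is in an
#'   inhibition period, spikes/s
#' @param border_choice_mode `"none"`, `"exponential"` (extra exponentially
#'   decaying turn hazard after |df| crossings) or `"filter"` (kinematics
#'   corrected by linear filters of recent rate history for 2 s after each
#'   crossing)
#' @param df_crossing_threshold |df| threshold defining border crossings,
#'   spikes/s^2 (default 15)
#' @param border_hazard,border_tau exponential border-choice hazard scale
#'   (1/s) and decay constant (s)
#' @param exit_turn_prob probability of exiting the boundary state into a
#'   sharp turn rather than a curved walk (default 0.5)
#' @param entry_percentile cohort filter: keep flies whose first entry is
#'   within this percentile of the reference first-entry distribution
#' @param seed master seed
#' @return object of class `agent_config`
#' @export
agent_config <- function(n_flies = 150, duration = 360, light_on = 180,
                         dt = 0.01, first_entry_rate_threshold = 10,
                         boundary_threshold = 0.0375, inhibition_rate = 1,
                         border_choice_mode = c("none", "exponential",
                                                "filter"),
                         df_crossing_threshold = 15, border_hazard = 2,
                         border_tau = 0.5, exit_turn_prob = 0.5,
                         entry_percentile = 85, seed = NULL) {
  border_choice_mode <- match.arg(border_choice_mode)
  stopifnot(dt > 0, duration > 0, boundary_threshold > 0,
            first_entry_rate_threshold > 0, df_crossing_threshold > 0,
            border_tau > 0, border_hazard >= 0)
  structure(as.list(environment()), class = "agent_config")
}

#' Sampling policy backed by a ground truth
#'
#' Wraps a [make_ground_truth()] object into the policy interface the
#' simulator consumes (kinematic sampling, transition probabilities, turn
#' optimality, boundary-state parameters).
#'
#' @param truth a `ground_truth`
#' @return object of class `agent_policy`
#' @export
policy_from_truth <- function(truth) {
  structure(list(
    sample_kin = function(state, f, df, phase, t_inh) {
      pars <- truth$surfaces[[state]]
      draw <- function(p) {
        v <- pars[[p]](f, df)
        stats::rlnorm(1, v$meanlog, v$sdlog)
      }
      list(speed = if (state == "stop") 0 else draw("avg_speed"),
           curv = draw("curvature"),
           duration = draw("duration"))
    },
    trans_probs = function(state, f, df, phase) truth$transition(state, f, df),
    opt_prob = function(f, df) truth$optimality(f, df),
    boundary_sample = function(phase) {
      z <- drop(stats::rnorm(2) %*% chol(truth$boundary$cov)) +
        truth$boundary$mean
      list(arc_angle = exp(z[1]), duration = exp(z[2]))
    },
    border_filters = NULL),
    class = "agent_policy")
}

#' Sampling policy backed by fitted maps and distributions
#'
#' Builds the simulator policy from estimated KNN kinematic maps, a
#' transition map, an optimality map, and the auxiliary state
#' distributions (before-entry, baseline splits, inhibition-period,
#' boundary).  Map queries use nearest-defined-cell fallback so the policy
#' covers the whole response space.  Fitted curvature values are in
#' analysis units (change of the path normal per tracking frame); the
#' policy converts curved-walk curvature to an angular velocity with
#' `fps_track`.
#'
#' @param kin_maps nested list: `kin_maps[[state]][[parameter]]` is a
#'   [fit_knn_map()] result keyed by the summary column (`avg_speed`,
#'   `avg_abs_curvature` or `total_curvature` fitted on magnitudes,
#'   `duration`)
#' @param trans_map a [fit_transition_map()] result
#' @param opt_map a [fit_optimality_map()] result (or `NULL` for unbiased)
#' @param dists a [fit_state_distributions()] result
#' @param fps_track tracking frame rate the maps were estimated at
#' @param border_filters optional list of FIR taps (`speed`, `curvature`,
#'   `optimality`) for the filter border-choice mode
#' @return object of class `agent_policy`
#' @export
policy_from_fits <- function(kin_maps, trans_map, opt_map, dists,
                             fps_track = 30, border_filters = NULL) {
  draw_lognormal <- function(fit) {
    if (is.null(fit) || !is.finite(fit$meanlog) || fit$n < 2)
      return(NA_real_)
    stats::rlnorm(1, fit$meanlog, max(fit$sdlog, 1e-6))
  }
  sample_block <- function(block, state, param)
    draw_lognormal(block[[state]][[param]])
  structure(list(
    sample_kin = function(state, f, df, phase, t_inh) {
      curv_col <- if (state == "curved_walk") "avg_abs_curvature"
                  else "total_curvature"
      is_curv <- function(param) param == curv_col
      get_val <- function(param) {
        if (phase == "non_baseline") {
          m <- kin_maps[[state]][[param]]
          if (!is.null(m)) {
            q <- query_map(m, f, df, fallback = TRUE)
            if (is.finite(q$mu))
              return(stats::rlnorm(1, q$mu, max(q$sigma, 1e-6)))
          }
        }
        if (phase == "inhibition" && !is.null(dists$inhibition[[state]])) {
          ip <- dists$inhibition[[state]]
          tq <- min(max(t_inh, min(ip$centers)), max(ip$centers))
          v <- if (param == "avg_speed") {
            ml <- ip$interpolate$meanlog(tq)
            if (is.finite(ml))
              stats::rlnorm(1, ml, max(ip$interpolate$sdlog(tq), 1e-6,
                                       na.rm = TRUE))
            else NA_real_
          } else if (is_curv(param)) {
            sh1 <- ip$interpolate$shape1(tq)
            sh2 <- ip$interpolate$shape2(tq)
            if (is.finite(sh1) && is.finite(sh2)) {
              u <- stats::rbeta(1, max(sh1, 0.05), max(sh2, 0.05))
              ip$curvature_range[1] + u * diff(ip$curvature_range)
            } else NA_real_
          } else if (param == "duration") {
            rt <- ip$interpolate$rate(tq)
            if (is.finite(rt)) stats::rexp(1, max(rt, 1e-6)) else NA_real_
          } else NA_real_
          if (is.finite(v)) return(v)
        }
        block <- switch(phase,
                        baseline_12 = dists$baseline_12,
                        baseline_3plus = dists$baseline_3plus,
                        dists$before)
        v <- sample_block(block, state, param)
        if (!is.finite(v)) v <- sample_block(dists$before, state, param)
        if (!is.finite(v)) v <- switch(param, avg_speed = 5, duration = 0.5,
                                       0.5)
        v
      }
      speed <- if (state == "stop") 0 else get_val("avg_speed")
      curv <- get_val(curv_col)
      if (state == "curved_walk") curv <- curv * fps_track  # rad/frame -> rad/s
      dur <- get_val("duration")
      list(speed = speed, curv = curv, duration = dur)
    },
    trans_probs = function(state, f, df, phase) {
      pr <- tryCatch(query_transition(trans_map, state, f, df),
                     error = function(e) NULL)
      if (is.null(pr))
        return(switch(state,
                      sharp_turn = c(curved_walk = 1, stop = 0,
                                     sharp_turn = 0),
                      stop = c(curved_walk = 0.75, stop = 0,
                               sharp_turn = 0.25),
                      c(curved_walk = 0, stop = 0.25, sharp_turn = 0.75)))
      pr <- pr[c("curved_walk", "stop", "sharp_turn")]
      pr[!is.finite(pr)] <- 0
      pr[state] <- 0                     # non-self transitions
      if (sum(pr) <= 0) pr[setdiff(names(pr), state)[1]] <- 1
      pr / sum(pr)
    },
    opt_prob = function(f, df) {
      if (is.null(opt_map)) 0.5 else query_optimality(opt_map, f, df)
    },
    boundary_sample = function(phase) {
      b <- if (phase == "before") dists$boundary$before
           else dists$boundary$after %||% dists$boundary$before
      if (is.null(b)) return(list(arc_angle = 1, duration = 2))
      z <- drop(stats::rnorm(2) %*% chol(b$cov)) + b$mean
      list(arc_angle = exp(z[1]), duration = exp(z[2]))
    },
    border_filters = border_filters),
    class = "agent_policy")
}

# mean f and df of the rate over the preceding 200 ms window ending at
# step i (inclusive)
window_f_df <- function(rate, i, dt, window = 0.2) {
  w <- max(1L, i - as.integer(round(window / dt)) + 1L):i
  rw <- rate[w]
  f <- mean(rw)
  df <- if (length(rw) >= 2) mean(diff(rw)) / dt else 0
  c(f = f, df = df)
}

#' Simulate one virtual fly
#'
#' The fly starts at the arena center heading along +x in a curved walk.
#' At every state end the next state is drawn from the transition
#' probabilities at the current (f, df), state kinematics are drawn from
#' the policy's conditional distributions, and the turn direction is drawn
#' toward the optimal side with the mapped optimality probability.  Sharp
#' turns move straight for half the duration, rotate by the sampled total
#' curvature in a single step, then move straight; stops do the same with
#' zero speed; curved walks move at constant sampled speed and angular
#' velocity.  Hitting the wall band switches to the boundary state (arc at
#' constant angular speed, then reorientation toward the center).  The
#' stimulus follows from the agent's own positions through the arena
#' profile and the encoder cascade, online.
#'
#' @param config an [agent_config()]
#' @param arena an [make_arena_model()]
#' @param cascade an `orn_cascade` used for the online rate
#' @param policy an `agent_policy`
#' @param seed RNG seed for this fly
#' @return list of class `agent_track`: `track` (data.frame at the
#'   tracking rate: `t`, `x`, `y`, `state`), `log` (per-state data.frame
#'   with latent `f`, `df` and sampled kinematics), `first_entry` (s or
#'   NA), `rate` (100 Hz), `dt`
#' @export
simulate_fly <- function(config, arena, cascade, policy, seed = NULL) {
  with_seed(seed, {
    dt <- config$dt
    n <- as.integer(round(config$duration / dt))
    fs <- 1 / dt
    d_warm <- length(cascade$filter1) + length(cascade$filter2)
    px <- py <- numeric(n)
    stim <- rate <- rep(NA_real_, n)
    state_id <- character(n)
    r_wall <- 1 - config$boundary_threshold

    heading <- 0
    i <- 1L                      # last completed step
    px[1] <- 0; py[1] <- 0
    stim[1] <- 0
    rate[1] <- cascade$baseline
    first_entry <- NA_real_
    last_above <- 1L             # last step with rate above inhibition
    baseline_visits <- 0L
    in_baseline_run <- FALSE
    crossings <- numeric(0)      # times of |df| threshold crossings
    log_rows <- list()

    # compute stimulus and rate for newly added steps (i0..i1)
    fill_rate <- function(i0, i1) {
      w <- max(1L, i0 - d_warm)
      seg <- w:i1
      rr <- sqrt(px[seg]^2 + py[seg]^2)
      ss <- arena$intensity(rr)
      ss[(seg - 1) * dt < config$light_on] <- 0
      stim[seg] <<- ss
      lfp <- conv_causal(ss, cascade$filter1)
      rt <- conv_causal(lfp, cascade$filter2) + cascade$baseline
      if (isTRUE(cascade$rectify)) rt <- pmax(rt, 0)
      keep <- seg >= i0
      rate[seg[keep]] <<- rt[keep]
    }

    # update first-entry / inhibition / crossing bookkeeping over i0..i1
    update_events <- function(i0, i1) {
      seg <- i0:i1
      if (is.na(first_entry)) {
        hit <- seg[rate[seg] > config$first_entry_rate_threshold &
                     (seg - 1) * dt >= config$light_on]
        if (length(hit)) first_entry <<- (hit[1] - 1) * dt
      }
      above <- seg[rate[seg] >= config$inhibition_rate]
      if (length(above)) last_above <<- max(last_above, max(above))
      if (i1 - i0 >= 1) {
        w <- as.integer(round(0.2 / dt))
        lo <- max(1L, i0 - w)
        dfs <- diff(rate[lo:i1]) / dt
        dfs <- running_mean(dfs, w)
        idx <- which(abs(dfs) >= config$df_crossing_threshold)
        if (length(idx)) {
          tt <- (lo + idx - 1) * dt
          # keep one crossing per contiguous run
          newc <- tt[c(TRUE, diff(idx) > 1)]
          newc <- newc[!(newc %in% crossings)]
          last <- if (length(crossings)) max(crossings) else -Inf
          newc <- newc[newc > last + 0.2]
          crossings <<- c(crossings, newc)
        }
      }
    }

    advance <- function(xs, ys, label) {
      m <- length(xs)
      if (m == 0L) return(invisible(NULL))
      take <- min(m, n - i)
      if (take <= 0L) return(invisible(NULL))
      seg <- (i + 1L):(i + take)
      px[seg] <<- xs[seq_len(take)]
      py[seg] <<- ys[seq_len(take)]
      state_id[seg] <<- label
      fill_rate(seg[1], seg[take])
      update_events(seg[1], seg[take])
      i <<- i + take
      invisible(NULL)
    }

    state_id[1] <- "curved_walk"
    state <- "curved_walk"
    # pre-sampled kinematics for the very first state
    repeat {
      if (i >= n) break
      t_now <- (i - 1) * dt
      fd <- window_f_df(rate, i, dt)
      phase <- if (is.na(first_entry)) "before"
      else if (rate[i] < config$inhibition_rate) "inhibition"
      else if (abs(fd["f"] - cascade$baseline) <= 3 &&
                 abs(fd["df"]) <= 10) {
        if (!in_baseline_run) {
          baseline_visits <- baseline_visits + 1L
          in_baseline_run <- TRUE
        }
        if (baseline_visits <= 2L) "baseline_12" else "baseline_3plus"
      } else "non_baseline"
      if (phase != "baseline_12" && phase != "baseline_3plus")
        in_baseline_run <- FALSE
      t_inh <- (i - last_above) * dt

      if (state == "boundary") {
        bs <- policy$boundary_sample(phase)
        m <- max(1L, as.integer(round(bs$duration / dt)))
        phi0 <- atan2(py[i], px[i])
        # continue in the current angular direction
        vsign <- sign(px[i] * (py[i] - py[max(1, i - 1)]) -
                        py[i] * (px[i] - px[max(1, i - 1)]))
        if (vsign == 0) vsign <- sample(c(-1, 1), 1)
        omega <- vsign * bs$arc_angle / bs$duration
        phis <- phi0 + omega * dt * seq_len(m)
        advance(r_wall * cos(phis), r_wall * sin(phis), "boundary")
        heading <- atan2(-py[i], -px[i])   # reorient toward the center
        state <- if (stats::runif(1) < config$exit_turn_prob) "sharp_turn"
                 else "curved_walk"
        log_rows[[length(log_rows) + 1]] <- data.frame(
          state = "boundary", start_t = t_now, f = unname(fd["f"]),
          df = unname(fd["df"]),
          phase = phase, speed = NA, curv = bs$arc_angle,
          duration = bs$duration, theta = NA, optimal = NA)
        next
      }

      kin <- policy$sample_kin(state, fd["f"], fd["df"], phase, t_inh)
      # filter border-choice: additive corrections within 2 s of a crossing
      if (config$border_choice_mode == "filter" &&
          !is.null(policy$border_filters) && length(crossings) &&
          t_now - max(crossings) <= 2) {
        bf <- policy$border_filters
        hist_len <- max(vapply(bf, length, 0L))
        w <- max(1L, i - hist_len + 1L):i
        rh <- rev(rate[w]); rh[!is.finite(rh)] <- 0
        corr_of <- function(taps) {
          h <- c(rh, rep(0, max(0, length(taps) - length(rh))))
          sum(taps * h[seq_along(taps)])
        }
        kin$speed <- max(0, kin$speed + corr_of(bf$speed))
        kin$curv <- kin$curv + corr_of(bf$curvature)
      }

      # turn direction: optimal side with mapped probability
      look <- max(1L, i - as.integer(round(0.2 / dt)))
      theta <- directed_angle(c(px[look], py[look]), c(px[i], py[i]))
      p_opt <- policy$opt_prob(fd["f"], fd["df"])
      sgn <- if (is.finite(theta) && theta != 0) {
        if (stats::runif(1) < p_opt) sign(theta) else -sign(theta)
      } else sample(c(-1, 1), 1)

      m <- max(1L, as.integer(round(kin$duration / dt)))
      v_norm <- kin$speed / (10 * arena$arena_radius_cm)   # mm/s -> norm/s

      if (state == "curved_walk") {
        omega <- sgn * kin$curv                    # rad/s
        heads <- heading + omega * dt * seq_len(m)
        xs <- px[i] + cumsum(v_norm * dt * cos(heads))
        ys <- py[i] + cumsum(v_norm * dt * sin(heads))
        # exponential border-choice: extra turn hazard after crossings
        if (config$border_choice_mode == "exponential" &&
            length(crossings) && config$border_hazard > 0) {
          tau <- (t_now + dt * seq_len(m)) - max(crossings)
          h <- ifelse(tau >= 0, config$border_hazard *
                        exp(-tau / config$border_tau), 0)
          u <- stats::runif(m)
          cut <- which(u < h * dt)
          if (length(cut) && cut[1] < m) {
            m <- cut[1]
            xs <- xs[seq_len(m)]; ys <- ys[seq_len(m)]
            heads <- heads[seq_len(m)]
          }
        }
        hit <- which(xs^2 + ys^2 >= r_wall^2)
        if (length(hit)) {
          m <- hit[1]
          xs <- xs[seq_len(m)]; ys <- ys[seq_len(m)]
          heads <- heads[seq_len(m)]
          next_state <- "boundary"
        } else next_state <- NA
        heading <- heads[m]
        advance(xs, ys, "curved_walk")
      } else {
        # sharp turn / stop: straight, single-step rotation, straight
        sp <- if (state == "stop") 0 else v_norm
        half <- m %/% 2
        heads <- c(rep(heading, max(half, 0)),
                   rep(heading + sgn * kin$curv, m - half))
        xs <- px[i] + cumsum(sp * dt * cos(heads))
        ys <- py[i] + cumsum(sp * dt * sin(heads))
        hit <- which(xs^2 + ys^2 >= r_wall^2)
        if (length(hit)) {
          m <- hit[1]
          xs <- xs[seq_len(m)]; ys <- ys[seq_len(m)]
          heads <- heads[seq_len(m)]
          next_state <- "boundary"
        } else next_state <- NA
        heading <- heads[m]
        advance(xs, ys, state)
      }

      log_rows[[length(log_rows) + 1]] <- data.frame(
        state = state, start_t = t_now, f = unname(fd["f"]),
        df = unname(fd["df"]),
        phase = phase, speed = kin$speed, curv = sgn * kin$curv,
        duration = m * dt, theta = theta,
        optimal = if (is.finite(theta) && theta != 0)
          sign(theta) == sgn else NA)

      if (!is.na(next_state)) {
        state <- next_state
      } else {
        pr <- policy$trans_probs(state, fd["f"], fd["df"], phase)
        state <- sample(names(pr), 1, prob = pr)
      }
    }

    # downsample to a uniform tracking grid (30 Hz); positions are
    # piecewise linear in the step grid, so linear interpolation is exact
    fps_track <- 30
    t_steps <- (seq_len(n) - 1) * dt
    t30 <- seq(0, t_steps[n], by = 1 / fps_track)
    x30 <- stats::approx(t_steps, px, xout = t30)$y
    y30 <- stats::approx(t_steps, py, xout = t30)$y
    nearest <- pmin(pmax(round(t30 / dt) + 1, 1), n)
    track <- make_track(t = t30, x = x30, y = y30, fly_id = 1L,
                        arena_radius_cm = arena$arena_radius_cm)
    track$state <- state_id[nearest]
    log_df <- do.call(rbind, log_rows)
    rownames(log_df) <- NULL
    structure(list(track = track, log = log_df, first_entry = first_entry,
                   rate = rate, dt = dt, seed = seed),
              class = "agent_track")
  })
}

#' Simulate a cohort of virtual flies
#'
#' Runs `n_flies` independent simulations with sub-seeds derived from the
#' master seed, then applies the first-entry percentile filter: only flies
#' whose first entry time (after light onset) is within the
#' `entry_percentile`-th percentile of the reference distribution (the
#' supplied empirical one, or the cohort's own) are kept.  A percentile of
#' 100 keeps every fly.
#'
#' @param config an [agent_config()]
#' @param arena,cascade,policy as in [simulate_fly()]
#' @param seed master seed (overrides `config$seed`)
#' @param empirical_first_entries optional reference first-entry times
#'   (s after light onset)
#' @return object of class `trackset`: `flies` (list of `agent_track`),
#'   `first_entries`, `kept` (logical), `config`
#' @export
simulate_cohort <- function(config, arena, cascade, policy, seed = NULL,
                            empirical_first_entries = NULL) {
  if (is.null(seed)) seed <- config$seed
  seeds <- derive_seeds(seed, config$n_flies)
  flies <- lapply(seq_len(config$n_flies), function(k)
    simulate_fly(config, arena, cascade, policy, seed = seeds[k]))
  fe <- vapply(flies, function(f) f$first_entry %||% NA_real_, numeric(1))
  fe_rel <- fe - config$light_on
  kept <- rep(TRUE, length(flies))
  if (config$entry_percentile < 100) {
    ref <- if (!is.null(empirical_first_entries)) empirical_first_entries
           else fe_rel[is.finite(fe_rel)]
    if (length(ref)) {
      cutoff <- stats::quantile(ref, config$entry_percentile / 100,
                                na.rm = TRUE)
      kept <- is.finite(fe_rel) & fe_rel <= cutoff
    }
  }
  structure(list(flies = flies[kept], first_entries = fe[kept],
                 kept = kept, all_first_entries = fe, config = config,
                 seed = seed),
            class = "trackset")
}

#' @export
print.trackset <- function(x, ...) {
  cat(sprintf("<trackset> %d flies (%d simulated), %g s at light-on %g s\n",
              length(x$flies), length(x$kept), x$config$duration,
              x$config$light_on))
  invisible(x)
}
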