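# End-to-end cohort analysis: from raw tracks to fitted kinematic maps,
# transition and optimality maps, and auxiliary distributions — the full
# estimation loop that can feed the agent simulator back.

#' Label segments with their firing-rate context
#'
#' Adds `phase` (`before`, `baseline_12`, `baseline_3plus`, `inhibition`,
#' `non_baseline`) and, for inhibition rows, `t_inhibition` (time since
#' the rate fell below the inhibition threshold), using the 200-ms f/df
#' window preceding each segment start.
#'
#' @param segments summarized segments with `start_t`
#' @param rate,rate_t firing-rate series and time stamps
#' @param first_entry_time first entry, s (`NA` = never)
#' @param baseline baseline rate, spikes/s
#' @param baseline_band half-width of the baseline f band
#' @param inhibition_rate inhibition threshold, spikes/s
#' @return segments with `phase` and `t_inhibition` columns
#' @export
label_segment_phases <- function(segments, rate, rate_t, first_entry_time,
                                 baseline = 4.7, baseline_band = 3,
                                 inhibition_rate = 1) {
  dt <- stats::median(diff(rate_t))
  segments$phase <- "before"
  segments$t_inhibition <- NA_real_
  if (!is.finite(first_entry_time)) return(segments)
  baseline_visits <- 0L
  in_run <- FALSE
  below <- rate < inhibition_rate
  for (i in seq_len(nrow(segments))) {
    t0 <- segments$start_t[i]
    if (t0 < first_entry_time) next
    win <- rate_t >= t0 - 0.2 & rate_t < t0
    rw <- rate[win]
    if (length(rw) < 2) next
    f <- mean(rw)
    df <- mean(diff(rw)) / dt
    if (f < inhibition_rate) {
      segments$phase[i] <- "inhibition"
      # time since the rate last fell below threshold (continuously)
      ii <- max(which(rate_t < t0))
      j <- ii
      while (j > 1 && below[j - 1]) j <- j - 1
      segments$t_inhibition[i] <- t0 - rate_t[j]
      in_run <- FALSE
    } else if (abs(f - baseline) <= baseline_band && abs(df) <= 10) {
      if (!in_run) {
        baseline_visits <- baseline_visits + 1L
        in_run <- TRUE
      }
      segments$phase[i] <- if (baseline_visits <= 2L) "baseline_12"
                           else "baseline_3plus"
    } else {
      segments$phase[i] <- "non_baseline"
      in_run <- FALSE
    }
  }
  segments
}

#' Analyze a cohort of tracks through the full pipeline
#'
#' For each fly: reconstruct the stimulus from the head trajectory,
#' predict the firing rate with the encoder cascade, compute kinematics,
#' segment into the four states, detect first entry (rate crossing the
#' 10 spikes/s threshold after light onset), and embed post-entry state
#' starts at (f, df).  Across flies: fit the KNN kinematic maps (K = 64
#' with T = 1.5 for sharp turns and curved walks, T = 1 for stops), the
#' transition map (K = 128, T = 1.5), the turn-optimality map, and the
#' auxiliary state distributions, and wrap everything into an agent
#' policy.
#'
#' @param tracks list of `fly_track` objects (30 Hz)
#' @param arena an [make_arena_model()]
#' @param cascade an `orn_cascade` used to predict rates
#' @param light_on light onset, s
#' @param entry_rate_threshold first-entry rate threshold, spikes/s
#' @param grid base map grid (K/T overridden per map kind)
#' @return list of class `cohort_analysis`: `points`, `segments`,
#'   `first_entries`, `kin_maps`, `trans_map`, `opt_map`, `dists`,
#'   `policy`
#' @export
analyze_cohort <- function(tracks, arena, cascade, light_on = 180,
                           entry_rate_threshold = 10,
                           grid = make_map_grid()) {
  all_points <- list()
  all_segments <- list()
  first_entries <- numeric(length(tracks))
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    stim <- reconstruct_stimulus(tr, arena, light_on_time = light_on)
    resp <- predict_response(cascade, stim$stimulus)
    rate <- resp$rate
    fe_idx <- which(rate > entry_rate_threshold & stim$t >= light_on)
    fe <- if (length(fe_idx)) stim$t[fe_idx[1]] else NA_real_
    first_entries[k] <- fe
    kin <- compute_kinematics(tr)
    seg <- segment_states(kin, tr, light_on_time = light_on)
    seg <- summarize_segments(seg, kin, tr)
    seg <- label_segment_phases(seg, rate, stim$t, fe)
    seg$fly <- k
    all_segments[[k]] <- seg
    if (is.finite(fe)) {
      pts <- embed_state_points(seg, rate, stim$t, fe)
      if (nrow(pts)) {
        pts$fly <- k
        # turn geometry at each state start
        frame0 <- findInterval(pts$t_entry + fe, tr$t)
        back <- pmax(frame0 - round(0.2 * kin$fps), 1)
        th <- directed_angle(cbind(tr$x[back], tr$y[back]),
                             cbind(tr$x[frame0], tr$y[frame0]))
        pts$theta <- th
        pts$optimal <- classify_turn_optimality(th, pts$total_curvature)
        all_points[[length(all_points) + 1]] <- pts
      }
    }
  }
  points <- do.call(rbind, all_points)
  segments <- do.call(rbind, all_segments)

  kd <- knn_defaults()
  g_kin <- grid; g_kin$K <- kd$kinematics$K; g_kin$T_bound <- kd$kinematics$T
  g_stop <- grid; g_stop$K <- kd$stops$K; g_stop$T_bound <- kd$stops$T
  fit_for <- function(state, param, g) {
    sub <- points[points$state == state & points$context == "non_baseline", ,
                  drop = FALSE]
    if (is.null(points) || nrow(sub) <= g$K) return(NULL)
    is_curv <- param != "avg_speed" && param != "duration"
    fit_knn_map(sub, param, g, use_magnitude = is_curv,
                value_floor = if (is_curv) 1e-3 else 0)
  }
  kin_maps <- list(
    curved_walk = list(
      avg_speed = fit_for("curved_walk", "avg_speed", g_kin),
      avg_abs_curvature = fit_for("curved_walk", "avg_abs_curvature",
                                  g_kin),
      duration = fit_for("curved_walk", "duration", g_kin)),
    sharp_turn = list(
      avg_speed = fit_for("sharp_turn", "avg_speed", g_kin),
      total_curvature = fit_for("sharp_turn", "total_curvature", g_kin),
      duration = fit_for("sharp_turn", "duration", g_kin)),
    stop = list(
      total_curvature = fit_for("stop", "total_curvature", g_stop),
      duration = fit_for("stop", "duration", g_stop)))
  kin_maps <- lapply(kin_maps, function(x) Filter(Negate(is.null), x))

  trans_map <- if (!is.null(points) && nrow(points) > 128)
    fit_transition_map(points) else NULL
  turnish <- points[!is.na(points$optimal) &
                      points$state %in% c("sharp_turn", "stop"), ,
                    drop = FALSE]
  opt_map <- if (!is.null(points) && nrow(turnish) > 64) {
    g_opt <- grid; g_opt$K <- kd$kinematics$K
    g_opt$T_bound <- kd$kinematics$T
    fit_optimality_map(turnish, g_opt)
  } else NULL
  dists <- fit_state_distributions(segments)
  policy <- policy_from_fits(kin_maps, trans_map, opt_map, dists)
  structure(list(points = points, segments = segments,
                 first_entries = first_entries, kin_maps = kin_maps,
                 trans_map = trans_map, opt_map = opt_map, dists = dists,
                 policy = policy),
            class = "cohort_analysis")
}
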