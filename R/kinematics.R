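# Track container, per-frame kinematics (speed, signed curvature), the
# four-state segmentation, per-segment summaries, and first-entry detection.

#' Construct a track
#'
#' Positions are in normalized arena coordinates (origin at the arena
#' center, wall at radius 1).  If head positions are not tracked the
#' centroid is reused.
#'
#' @param t time stamps, s, strictly increasing (nominally 30 Hz)
#' @param x,y centroid position, normalized units
#' @param head_x,head_y head position (defaults to the centroid)
#' @param fly_id identifier
#' @param arena_radius_cm arena radius for unit conversion (default 4)
#' @return a data.frame of class `fly_track`
#' @export
make_track <- function(t, x, y, head_x = x, head_y = y, fly_id = 1L,
                       arena_radius_cm = 4) {
  stopifnot(length(t) >= 3, all(diff(t) > 0),
            length(x) == length(t), length(y) == length(t))
  if (any(sqrt(x^2 + y^2) > 1 + 1e-6))
    warning("positions outside the unit arena")
  tr <- data.frame(t = t, x = x, y = y, head_x = head_x, head_y = head_y)
  attr(tr, "fly_id") <- fly_id
  attr(tr, "arena_radius_cm") <- arena_radius_cm
  class(tr) <- c("fly_track", "data.frame")
  tr
}

#' Per-frame speed and signed curvature of a track
#'
#' Speed at frame t is the centroid displacement between consecutive frames
#' divided by the frame interval, converted to mm/s.  Curvature is the
#' magnitude of the change in the unit normal to the movement path, where
#' the normal at frame t is the normalized sum of the normals of the two
#' displacements meeting at t; its sign is taken from the z-component of
#' the cross product of the mean headings on either side of the change
#' (positive = leftward turn).  Frames with zero displacement have
#' undefined normals; their curvature is reported as 0 and flagged, and
#' flagged frames never seed sharp-turn peaks.
#'
#' @param track a [make_track()] object
#' @return list of class `kinematic_series`: `speed` (mm/s, per displacement,
#'   length n-1), `curvature` (signed, per frame, length n-1 with the last
#'   two entries invalid), `heading` (rad, per displacement), `valid`
#'   (logical, curvature defined), `fps`, `arena_radius_cm`
#' @export
compute_kinematics <- function(track) {
  n <- nrow(track)
  arena_cm <- attr(track, "arena_radius_cm") %||% 4
  dt <- diff(track$t)
  dx <- diff(track$x)
  dy <- diff(track$y)
  s <- sqrt(dx^2 + dy^2)                      # normalized units per frame
  speed <- s / dt * arena_cm * 10             # mm/s
  fps <- 1 / stats::median(dt)
  heading <- atan2(dy, dx)

  nd <- n - 1                                 # number of displacements
  curvature <- rep(0, nd)
  valid <- rep(FALSE, nd)
  if (nd >= 3) {
    # unit normals of each displacement (rotate tangent +90 degrees)
    ok <- s > 0
    nx <- ifelse(ok, -dy / s, NA_real_)
    ny <- ifelse(ok, dx / s, NA_real_)
    # path normal at frame t combines displacements t and t+1
    ax <- nx[1:(nd - 1)] + nx[2:nd]
    ay <- ny[1:(nd - 1)] + ny[2:nd]
    al <- sqrt(ax^2 + ay^2)
    Nx <- ax / al
    Ny <- ay / al
    # change in the normal between successive frames
    m <- nd - 1                               # number of normals
    dNx <- Nx[2:m] - Nx[1:(m - 1)]
    dNy <- Ny[2:m] - Ny[1:(m - 1)]
    mag <- sqrt(dNx^2 + dNy^2)
    # sign from the cross product of the mean headings on either side
    hx1 <- dx[1:(m - 1)] + dx[2:m]
    hy1 <- dy[1:(m - 1)] + dy[2:m]
    hx2 <- dx[2:m] + dx[3:(m + 1)]
    hy2 <- dy[2:m] + dy[3:(m + 1)]
    sgn <- sign(hx1 * hy2 - hy1 * hx2)
    k <- sgn * mag
    defined <- is.finite(k)
    curvature[1 + which(defined)] <- k[defined]   # aligned to frame t+1
    valid[1 + which(defined)] <- TRUE
  }
  structure(list(speed = speed, curvature = curvature, heading = heading,
                 valid = valid, fps = fps, arena_radius_cm = arena_cm),
            class = "kinematic_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment a track into the four locomotor states
#'
#' Frame-by-frame classification with precedence: boundary (centroid within
#' 1.5 mm of the wall), then stop (speed < 0.5 mm/s), then sharp turn
#' (frames around curvature peaks exceeding a per-track threshold, expanded
#' outward while |curvature| stays above a fraction of the peak), remainder
#' curved walk.  Adjacent same-state frames are merged into half-open
#' segments `[start, end)` (0-based frame indices).
#'
#' The sharp-turn peak threshold defaults to the 95th percentile of
#' pre-light |curvature| (whole-track when `light_on_time` is `NULL`),
#' which operationalizes "large peaks in curvature" and self-calibrates per
#' fly.
#'
#' @param kin a [compute_kinematics()] result
#' @param track the matching track
#' @param boundary_mm boundary band, mm from the wall (default 1.5)
#' @param stop_speed stop threshold, mm/s (default 0.5)
#' @param peak_quantile quantile of |curvature| defining the peak threshold
#' @param expand_frac expansion stops when |curvature| falls below this
#'   fraction of the peak value
#' @param min_peak absolute floor on the peak threshold, rad/frame; guards
#'   against spurious peaks from numerical noise on nearly straight paths
#'   (0.05 rad/frame is ~3 degrees, far below any real sharp turn)
#' @param min_walk_frag curved-walk fragments up to this duration (s)
#'   adjacent to a sharp turn are absorbed into the turn episode; set 0 to
#'   disable
#' @param light_on_time optional light onset, s, for threshold calibration
#' @return data.frame of class `state_segments` with columns `state`,
#'   `start`, `end` (half-open, 0-based)
#' @export
segment_states <- function(kin, track, boundary_mm = 1.5, stop_speed = 0.5,
                           peak_quantile = 0.95, expand_frac = 0.5,
                           min_peak = 0.05, min_walk_frag = 0.25,
                           light_on_time = NULL) {
  n <- nrow(track)
  if (n < 3) stop("track too short to segment")
  arena_cm <- kin$arena_radius_cm
  fps <- kin$fps
  r <- sqrt(track$x^2 + track$y^2)
  # per-frame speed/curvature: assign displacement values to their first
  # frame; last frame inherits the final displacement
  spd <- c(kin$speed, kin$speed[length(kin$speed)])
  curv <- c(kin$curvature, 0)
  valid <- c(kin$valid, FALSE)

  boundary_norm <- norm_from_mm(boundary_mm, arena_cm)
  lab <- rep("curved_walk", n)
  # sub-resolution tolerance (0.04 mm in the 4 cm arena) so wall-following
  # arcs sampled mid-chord are not fragmented; real tracking quantization
  # is coarser than this
  is_boundary <- r >= 1 - boundary_norm - 1e-3
  is_stop <- spd < stop_speed

  free <- !(is_boundary | is_stop)
  # sharp-turn detection on free frames
  ac <- abs(curv)
  pre <- if (is.null(light_on_time)) rep(TRUE, n) else track$t < light_on_time
  calib <- ac[pre & free & valid]
  if (length(calib) < 10) calib <- ac[free & valid]
  thresh <- if (length(calib))
    max(stats::quantile(calib, peak_quantile), min_peak) else Inf
  is_turn <- rep(FALSE, n)
  if (is.finite(thresh) && thresh > 0) {
    # peaks: local maxima of |curvature| above threshold on valid frames
    cand <- which(valid & free & ac > thresh)
    cand <- cand[cand > 1 & cand < n]
    cand <- cand[ac[cand] >= ac[cand - 1] & ac[cand] >= ac[cand + 1]]
    for (p in cand) {
      lo <- p
      while (lo > 1 && free[lo - 1] && ac[lo - 1] > expand_frac * ac[p])
        lo <- lo - 1
      hi <- p
      while (hi < n && free[hi + 1] && ac[hi + 1] > expand_frac * ac[p])
        hi <- hi + 1
      is_turn[lo:hi] <- TRUE
    }
  }
  lab[is_turn] <- "sharp_turn"
  lab[is_stop] <- "stop"
  lab[is_boundary] <- "boundary"

  # cleanup: brief curved-walk fragments flanking a sharp turn belong to
  # the turn episode (slowed straight approach/recovery around the
  # reorientation peak); genuine curved walks of that length are rare
  if (min_walk_frag > 0) {
    runs0 <- rle(lab)
    ends0 <- cumsum(runs0$lengths)
    starts0 <- ends0 - runs0$lengths + 1L
    frag_frames <- ceiling(min_walk_frag * fps)
    for (k in seq_along(runs0$values)) {
      if (runs0$values[k] != "curved_walk") next
      if (runs0$lengths[k] > frag_frames) next
      nb_turn <- (k > 1 && runs0$values[k - 1] == "sharp_turn") ||
        (k < length(runs0$values) && runs0$values[k + 1] == "sharp_turn")
      if (nb_turn) lab[starts0[k]:ends0[k]] <- "sharp_turn"
    }
  }

  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- c(0L, ends[-length(ends)])
  seg <- data.frame(state = runs$values, start = starts, end = ends,
                    stringsAsFactors = FALSE)
  attr(seg, "frame_labels") <- lab
  class(seg) <- c("state_segments", "data.frame")
  seg
}

#' Per-segment kinematic summaries
#'
#' Stops: total (signed) curvature and duration.  Boundary: total arc angle
#' swept around the arena center and duration.  Sharp turns: total
#' curvature, average speed, duration.  Curved walks: average curvature,
#' average speed, duration.  All segments also carry `midpoint_radius`
#' and `avg_abs_curvature`, the mean per-frame |curvature| — the signed
#' average cancels on nearly straight paths, so the unsigned version is
#' the one fitted by the lognormal curvature models.
#'
#' Curved-walk speed and curvature averages are taken over the segment's
#' interior frames (`edge_trim` seconds clipped from each end of segments
#' at least three trims long): the frames bordering a transition carry the
#' tail of the neighboring episode's kinematics, and the interior average
#' is the cleaner estimate of the walk's own speed.
#'
#' @param segments a [segment_states()] result
#' @param kin the matching kinematics
#' @param track the matching track
#' @param edge_trim transition-contamination guard, s (default 0.2)
#' @return the segments data.frame with summary columns appended
#' @export
summarize_segments <- function(segments, kin, track, edge_trim = 0.2) {
  n <- nrow(track)
  spd <- c(kin$speed, kin$speed[length(kin$speed)])
  curv <- c(kin$curvature, 0)
  fps <- kin$fps
  ang <- atan2(track$y, track$x)
  r <- sqrt(track$x^2 + track$y^2)
  out <- segments
  m <- nrow(segments)
  out$avg_speed <- out$total_curvature <- out$avg_curvature <-
    out$avg_abs_curvature <- out$duration <- out$arc_angle <-
    out$midpoint_radius <- out$start_t <- rep(NA_real_, m)
  n_tr <- nrow(track)
  for (i in seq_len(m)) {
    idx <- (segments$start[i] + 1):segments$end[i]   # 1-based frames
    # duration from time stamps: frame intervals need not be uniform
    t_end <- if (segments$end[i] < n_tr) track$t[segments$end[i] + 1]
             else track$t[n_tr] + 1 / fps
    out$duration[i] <- t_end - track$t[idx[1]]
    core <- idx
    if (segments$state[i] == "curved_walk") {
      trim <- round(edge_trim * fps)
      if (length(idx) >= 3 * trim && trim > 0)
        core <- idx[(trim + 1):(length(idx) - trim)]
    }
    out$avg_speed[i] <- mean(spd[core])
    out$total_curvature[i] <- sum(curv[idx])
    out$avg_curvature[i] <- mean(curv[core])
    out$avg_abs_curvature[i] <- mean(abs(curv[core]))
    out$midpoint_radius[i] <- r[idx[ceiling(length(idx) / 2)]]
    out$start_t[i] <- track$t[idx[1]]
    if (segments$state[i] == "boundary") {
      da <- diff(ang[idx])
      da <- (da + pi) %% (2 * pi) - pi      # unwrap
      out$arc_angle[i] <- sum(abs(da))
    }
  }
  out
}

#' First entry of the head into the light zone after light onset
#'
#' @param track a track
#' @param light_on_time light onset, s
#' @param light_zone_radius_norm zone radius, normalized (default 0.3125 =
#'   1.25 cm / 4 cm)
#' @return entry time in s, or `NA` if the fly never enters
#' @export
detect_first_entry <- function(track, light_on_time,
                               light_zone_radius_norm = 0.3125) {
  r <- sqrt(track$head_x^2 + track$head_y^2)
  hit <- which(track$t >= light_on_time & r <= light_zone_radius_norm)
  if (!length(hit)) return(NA_real_)
  track$t[hit[1]]
}
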