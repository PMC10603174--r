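# Spatial-distribution summaries and empirical-vs-synthetic comparison:
# radial occupancy, sharp-turn density, probability of being inside the
# light zone, a spatiotemporal kernel density estimate, the half-L1
# discrepancy, and a BCa bootstrap.

#' Radial occupancy distribution after first entry
#'
#' Per-fly probability mass functions of the head's radial position over
#' frames after that fly's first entry, binned at 0.05 normalized units
#' (2 mm in the 4 cm arena), combined as a weighted mean with weights
#' proportional to each fly's post-entry duration; the SEM per bin is the
#' weighted standard error across flies.
#'
#' @param tracks list of tracks (with `head_x`, `head_y`)
#' @param first_entries per-fly first-entry times, s (`NA` flies are
#'   skipped)
#' @param bin_width bin width, normalized units (default 0.05)
#' @return object of class `radial_pmf`: `breaks`, `mass`, `sem`,
#'   `weights`, `per_fly` matrix
#' @export
radial_occupancy <- function(tracks, first_entries, bin_width = 0.05) {
  stopifnot(length(tracks) == length(first_entries))
  breaks <- seq(0, 1, by = bin_width)
  use <- which(is.finite(first_entries))
  if (!length(use)) stop("no fly with a first entry")
  per <- matrix(0, length(breaks) - 1, length(use))
  w <- numeric(length(use))
  for (k in seq_along(use)) {
    tr <- tracks[[use[k]]]
    sel <- tr$t >= first_entries[use[k]]
    r <- pmin(sqrt(tr$head_x[sel]^2 + tr$head_y[sel]^2), 1 - 1e-12)
    h <- graphics::hist(r, breaks = breaks, plot = FALSE)
    per[, k] <- h$counts / max(sum(h$counts), 1)
    w[k] <- sum(sel)
  }
  w <- w / sum(w)
  mass <- drop(per %*% w)
  sem <- sqrt(drop(((per - mass)^2) %*% (w^2)))
  structure(list(breaks = breaks, mass = mass, sem = sem, weights = w,
                 per_fly = per),
            class = "radial_pmf")
}

#' Radial density of sharp turns
#'
#' Probability mass function of head radial positions at the midpoints of
#' sharp-turn segments, using the same 0.05 binning as the occupancy.
#'
#' @param midpoint_radii radii of sharp-turn midpoints (normalized); e.g.
#'   the `midpoint_radius` column of summarized segments restricted to
#'   sharp turns
#' @param bin_width bin width, normalized units
#' @return a `radial_pmf` (no per-fly weighting); flagged empty when there
#'   are no turns
#' @export
turn_density <- function(midpoint_radii, bin_width = 0.05) {
  breaks <- seq(0, 1, by = bin_width)
  r <- midpoint_radii[is.finite(midpoint_radii)]
  if (!length(r)) {
    return(structure(list(breaks = breaks,
                          mass = rep(0, length(breaks) - 1),
                          sem = rep(NA_real_, length(breaks) - 1),
                          empty = TRUE),
                     class = "radial_pmf"))
  }
  h <- graphics::hist(pmin(r, 1 - 1e-12), breaks = breaks, plot = FALSE)
  structure(list(breaks = breaks, mass = h$counts / sum(h$counts),
                 sem = rep(NA_real_, length(breaks) - 1), empty = FALSE),
            class = "radial_pmf")
}

#' Proportion of flies inside the light zone over time
#'
#' @param tracks list of tracks on a shared time base
#' @param zone_radius_norm zone radius, normalized (default 0.3125)
#' @param smooth_s boxcar width, s (default 0.2); edge windows are
#'   truncated
#' @return data.frame with `t` and `p_inside`
#' @export
probability_inside <- function(tracks, zone_radius_norm = 0.3125,
                               smooth_s = 0.2) {
  t0 <- tracks[[1]]$t
  inside <- vapply(tracks, function(tr) {
    r <- sqrt(tr$head_x^2 + tr$head_y^2)
    as.numeric(r <= zone_radius_norm)[seq_along(t0)]
  }, numeric(length(t0)))
  p <- rowMeans(inside)
  fps <- 1 / stats::median(diff(t0))
  data.frame(t = t0, p_inside = running_mean(p, round(smooth_s * fps)))
}

#' Spatiotemporal density of radial position after first entry
#'
#' Gaussian-kernel density over radial distance, estimated separately in
#' each time-since-entry slice and normalized to integrate to 1 per slice.
#' Bandwidth defaults to Silverman's rule per slice.
#'
#' @param tracks list of tracks
#' @param first_entries per-fly first-entry times
#' @param t_breaks slice edges for time since entry, s
#' @param r_grid radial evaluation grid
#' @param bw kernel SD; `NULL` for Silverman's rule per slice
#' @return list: `r_grid`, `t_centers`, `density` (length(r_grid) x
#'   slices)
#' @export
kde_spatiotemporal <- function(tracks, first_entries,
                               t_breaks = seq(0, 180, by = 20),
                               r_grid = seq(0, 1, by = 0.01), bw = NULL) {
  use <- which(is.finite(first_entries))
  if (!length(use)) stop("no fly with a first entry")
  rr <- tt <- numeric(0)
  for (k in use) {
    tr <- tracks[[k]]
    sel <- tr$t >= first_entries[k]
    rr <- c(rr, sqrt(tr$head_x[sel]^2 + tr$head_y[sel]^2))
    tt <- c(tt, tr$t[sel] - first_entries[k])
  }
  ns <- length(t_breaks) - 1
  dens <- matrix(NA_real_, length(r_grid), ns)
  for (s in seq_len(ns)) {
    x <- rr[tt >= t_breaks[s] & tt < t_breaks[s + 1]]
    if (length(x) < 2) next
    h <- if (is.null(bw)) stats::bw.nrd0(x) else bw
    d <- rowMeans(outer(r_grid, x, function(a, b)
      stats::dnorm(a - b, sd = h)))
    area <- sum((d[-1] + d[-length(d)]) / 2 * diff(r_grid))
    dens[, s] <- d / area
  }
  list(r_grid = r_grid,
       t_centers = (t_breaks[-1] + t_breaks[-length(t_breaks)]) / 2,
       density = dens)
}

#' Total positive difference between two radial PMFs
#'
#' Sum over bins of max(0, empirical - synthetic); because both PMFs sum
#' to 1 this equals half the L1 distance and lies in [0, 1].
#'
#' @param empirical,synthetic `radial_pmf` objects (or plain mass vectors)
#'   on identical bins
#' @return scalar discrepancy
#' @export
occupancy_discrepancy <- function(empirical, synthetic) {
  pe <- if (inherits(empirical, "radial_pmf")) empirical$mass else empirical
  ps <- if (inherits(synthetic, "radial_pmf")) synthetic$mass else synthetic
  if (length(pe) != length(ps)) stop("mismatched bins")
  if (inherits(empirical, "radial_pmf") &&
      inherits(synthetic, "radial_pmf") &&
      !isTRUE(all.equal(empirical$breaks, synthetic$breaks)))
    stop("mismatched bins")
  sum(pmax(pe - ps, 0))
}

#' Correlation of per-genotype discrepancies
#'
#' Pearson correlation between radial-occupancy discrepancies and
#' turn-density discrepancies across genotypes.
#'
#' @param occupancy_disc,turn_disc numeric vectors, one value per genotype
#' @return correlation coefficient
#' @export
discrepancy_correlation <- function(occupancy_disc, turn_disc) {
  stopifnot(length(occupancy_disc) == length(turn_disc))
  if (length(occupancy_disc) < 3) stop("need at least 3 genotypes")
  if (stats::sd(occupancy_disc) == 0 || stats::sd(turn_disc) == 0)
    stop("zero variance")
  stats::cor(occupancy_disc, turn_disc)
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Resamples the data `n_boot` times (default 10,000), with the bias
#' correction taken from the fraction of bootstrap statistics below the
#' point estimate and the acceleration from the jackknife skewness.
#'
#' @param values sample
#' @param statistic function of a numeric vector (default `mean`)
#' @param n_boot bootstrap resamples
#' @param conf confidence level
#' @param seed RNG seed
#' @return numeric `c(lower, upper)` with attributes `point`, `z0`, `a`
#' @export
bootstrap_bca <- function(values, statistic = mean, n_boot = 10000,
                          conf = 0.95, seed = NULL) {
  n <- length(values)
  stopifnot(n >= 5)
  if (stats::sd(values) == 0) stop("degenerate constant sample")
  theta <- statistic(values)
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    if (identical(statistic, mean)) colMeans(matrix(values[idx], nrow = n))
    else apply(idx, 2, function(ii) statistic(values[ii]))
  })
  z0 <- stats::qnorm(pmin(pmax(mean(boots < theta), 1e-12), 1 - 1e-12))
  jack <- vapply(seq_len(n), function(i) statistic(values[-i]), numeric(1))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den > 0) num / den else 0
  alpha <- (1 - conf) / 2
  zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
  p_lo <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  p_hi <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  # adjusted-percentile endpoints via interpolation of order statistics on
  # the normal-quantile scale (the canonical construction; plain empirical
  # quantiles run slightly narrow in the far tails)
  sorted <- sort(boots)
  R <- length(sorted)
  norm_inter <- function(p) {
    k <- (R + 1) * p
    k1 <- min(max(floor(k), 1L), R - 1L)
    q1 <- stats::qnorm(k1 / (R + 1))
    q2 <- stats::qnorm((k1 + 1) / (R + 1))
    w <- (stats::qnorm(p) - q1) / (q2 - q1)
    w <- min(max(w, 0), 1)
    sorted[k1] + w * (sorted[k1 + 1] - sorted[k1])
  }
  ci <- c(norm_inter(p_lo), norm_inter(p_hi))
  structure(ci, point = theta, z0 = z0, a = a, conf = conf)
}
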