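# Shared numerical helpers: unit conversions, causal convolution, L-curve
# elbow location, log-moment estimators, seeded RNG scoping.

#' Convert a length in millimetres to normalized arena units
#'
#' Arena coordinates are normalized so that the wall sits at radius 1.
#' With the standard 4 cm arena, the half-fly-length boundary band of
#' 1.5 mm becomes 0.0375 and the 2 mm radial histogram bin becomes 0.05.
#'
#' @param mm length in millimetres
#' @param arena_radius_cm arena radius in centimetres (default 4)
#' @return length in normalized units
#' @export
norm_from_mm <- function(mm, arena_radius_cm = 4) {
  stopifnot(arena_radius_cm > 0)
  mm / (10 * arena_radius_cm)
}

#' @rdname norm_from_mm
#' @param x length in normalized units
#' @export
mm_from_norm <- function(x, arena_radius_cm = 4) {
  x * 10 * arena_radius_cm
}

#' Causal finite-impulse-response convolution
#'
#' y[t] = sum_i k[i] * x[t - i + 1], with implicit zero padding before the
#' first sample, so the output has the same length as the input.
#'
#' @param x input series
#' @param taps filter coefficients, lag 0 first
#' @return filtered series, same length as `x`
#' @export
conv_causal <- function(x, taps) {
  n <- length(x)
  d <- length(taps)
  if (n == 0L) return(numeric(0))
  y <- stats::convolve(c(x, rep(0, d)), rev(taps), type = "open")
  # "open" convolution of length n+d with d gives n+2d-1; causal part is 1..n
  y[seq_len(n)]
}

# Index of the elbow of a discrete curve: the point farthest from the
# chord joining the curve's endpoints, after normalizing both axes to
# [0, 1].  More robust than pointwise discrete curvature, which explodes
# where consecutive points nearly coincide (the flat ends of an L-curve).
elbow_index <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_integer_)
  rx <- range(x[ok]); ry <- range(y[ok])
  if (diff(rx) == 0 || diff(ry) == 0) return(NA_integer_)
  xn <- (x - rx[1]) / diff(rx)
  yn <- (y - ry[1]) / diff(ry)
  i1 <- which(ok)[1]; i2 <- rev(which(ok))[1]
  vx <- xn[i2] - xn[i1]; vy <- yn[i2] - yn[i1]
  d <- abs(vx * (yn - yn[i1]) - vy * (xn - xn[i1])) / sqrt(vx^2 + vy^2)
  d[!ok] <- -Inf
  which.max(d)
}

# Corner of an L-curve sampled on a dense grid, traversed with lambda
# increasing (log residual norm on x, log solution norm on y).  The
# genuine elbow — noise suppression giving way to signal loss — is a
# counterclockwise bend in this orientation, so the maximum of the
# *signed* discrete curvature is used, and the search is restricted to
# the part of the curve where the residual is still within a factor 2 of
# its floor — the elbow is by definition where the residual leaves the
# noise floor, and bends further up the over-regularized branch are
# spurious.  When no counterclockwise corner exists there (noise-free
# data has no vertical branch), the smallest lambda whose residual is
# within 0.1% of the minimum is returned.  Segments where the curve
# barely moves are excluded (finite differences there are numerical
# noise).
lcurve_corner <- function(res, sol) {
  n <- length(res)
  fallback <- which(res <= min(res) * 1.001)[1]
  if (n < 5) return(fallback)
  x <- log(pmax(res, .Machine$double.xmin))
  y <- log(pmax(sol, .Machine$double.xmin))
  i <- 2:(n - 1)
  x1 <- (x[i + 1] - x[i - 1]) / 2
  y1 <- (y[i + 1] - y[i - 1]) / 2
  x2 <- x[i + 1] - 2 * x[i] + x[i - 1]
  y2 <- y[i + 1] - 2 * y[i] + y[i - 1]
  speed2 <- x1^2 + y1^2
  k <- (x1 * y2 - y1 * x2) / speed2^1.5
  k[speed2 < max(speed2) * 1e-4] <- -Inf
  k[res[i] > 2 * min(res) + 1e-12 * max(res)] <- -Inf
  if (!any(is.finite(k)) || max(k, na.rm = TRUE) < 1e-2) return(fallback)
  which.max(k) + 1L
}

# Maximum-likelihood moments of log-transformed positive values.
# Returns meanlog, sdlog (ML, i.e. 1/n variance), and n.
log_moments <- function(values) {
  v <- values[is.finite(values) & values > 0]
  n <- length(v)
  if (n == 0L) return(list(meanlog = NA_real_, sdlog = NA_real_, n = 0L))
  lv <- log(v)
  m <- mean(lv)
  s <- sqrt(mean((lv - m)^2))
  list(meanlog = m, sdlog = s, n = n)
}

# Evaluate a function with a locally seeded RNG; the caller's RNG stream is
# left untouched.  `seed = NULL` uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive n reproducible sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Centered running mean with edge-truncated windows (width in samples).
running_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  n <- length(x)
  if (n == 0L || width == 1L) return(x)
  cs <- cumsum(c(0, x))
  half <- width %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - half - 1L), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
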