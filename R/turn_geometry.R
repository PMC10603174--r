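# Turn-optimality geometry: directed angle of the movement direction
# relative to the inward (toward arena center) vector, optimal-turn
# classification, and the KNN optimality-ratio map.

#' Directed angle between movement direction and the inward vector
#'
#' The movement direction is v = p2 - p1 (from the position 200 ms before a
#' state transition to the position at the transition); the inward vector
#' is u = -p2.  The directed angle is atan2((v x u) . n, v . u) with n the
#' +z normal of the plane: positive theta means the arena center lies to
#' the fly's left, so a leftward (positive-curvature) turn is the smaller
#' reorientation toward the center.
#'
#' @param p1 matrix (n x 2) or length-2 vector: position 200 ms before the
#'   transition
#' @param p2 position at the transition
#' @return directed angle(s) in (-pi, pi]; `NA` for degenerate geometry
#'   (p1 == p2 or p2 at the origin)
#' @export
directed_angle <- function(p1, p2) {
  if (is.null(dim(p1))) p1 <- matrix(p1, ncol = 2)
  if (is.null(dim(p2))) p2 <- matrix(p2, ncol = 2)
  vx <- p2[, 1] - p1[, 1]; vy <- p2[, 2] - p1[, 2]
  ux <- -p2[, 1]; uy <- -p2[, 2]
  bad <- (vx == 0 & vy == 0) | (ux == 0 & uy == 0)
  theta <- atan2(vx * uy - vy * ux, vx * ux + vy * uy)
  theta[bad] <- NA_real_
  theta
}

#' Classify whether a turn was optimal
#'
#' A turn is optimal when the sign of the total curvature of the next
#' state instance matches the sign of the directed angle.  Ties — zero net
#' curvature, zero angle, or |theta| = pi (the center is directly behind,
#' both directions equivalent) — are excluded (`NA`).
#'
#' @param theta directed angle(s), rad
#' @param next_total_curvature signed total curvature of the following
#'   sharp-turn or stop instance
#' @param tie_tol tolerance around |theta| = pi treated as a tie
#' @return logical vector (`NA` for ties/degenerate cases)
#' @export
classify_turn_optimality <- function(theta, next_total_curvature,
                                     tie_tol = 1e-9) {
  st <- sign(theta)
  sc <- sign(next_total_curvature)
  out <- st == sc
  out[!is.finite(theta) | !is.finite(next_total_curvature) |
        st == 0 | sc == 0 | abs(abs(theta) - pi) < tie_tol] <- NA
  out
}

#' KNN map of the turn-optimality ratio
#'
#' Per grid cell, the fraction of optimal turns among the K-neighborhood
#' of state points (ties excluded); masked below `min_n`.
#'
#' @param points state points with columns `f`, `df`, and logical `optimal`
#' @param grid a [make_map_grid()] (K = 64, T = 1.5 by default)
#' @return object of class `optimality_map` with `ratio`, `n`, `mask`
#'   matrices; query with [query_optimality()]
#' @export
fit_optimality_map <- function(points, grid = make_map_grid()) {
  pts <- points[!is.na(points$optimal), , drop = FALSE]
  nf <- length(grid$f_axis); ndf <- length(grid$df_axis)
  ratio <- matrix(NA_real_, nf, ndf)
  nmat <- matrix(0L, nf, ndf)
  for (i in seq_len(nf)) {
    for (j in seq_len(ndf)) {
      nb <- knn_neighbors(pts$f, pts$df, grid$f_axis[i], grid$df_axis[j],
                          grid$a, grid$b, grid$K, grid$T_bound)
      nmat[i, j] <- length(nb)
      if (length(nb) > grid$min_n)
        ratio[i, j] <- mean(pts$optimal[nb])
    }
  }
  mask <- is.finite(ratio)
  structure(list(grid = grid, ratio = ratio, n = nmat, mask = mask,
                 defined = which(mask, arr.ind = TRUE)),
            class = "optimality_map")
}

#' Query an optimality map (nearest defined cell)
#'
#' @param omap a [fit_optimality_map()] result
#' @param f,df query coordinates (scalars)
#' @return optimality ratio at the nearest defined cell, or 0.5 when the
#'   map is empty
#' @export
query_optimality <- function(omap, f, df) {
  if (!any(omap$mask)) return(0.5)
  g <- omap$grid
  def <- omap$defined %||% which(omap$mask, arr.ind = TRUE)
  d2 <- ((g$f_axis[def[, 1]] - f) / g$a)^2 +
    ((g$df_axis[def[, 2]] - df) / g$b)^2
  k <- which.min(d2)
  omap$ratio[def[k, 1], def[k, 2]]
}
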