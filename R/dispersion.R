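# Central tendency, variability, and palette-density statistics.

# Resolve inputs to a (u, v) point matrix: either raw points (matrix / data
# frame with u, v) or match records plus a palette and booth.
.points_uv <- function(x, palette = NULL, booth = NULL) {
  if (is.matrix(x)) return(x[, 1:2, drop = FALSE])
  if (is.data.frame(x) && is.null(palette)) {
    stopifnot(all(c("u", "v") %in% names(x)))
    return(cbind(u = x$u, v = x$v))
  }
  match_chromaticities(x, palette, booth)
}

#' Mean chromaticity of a set of matches
#'
#' Arithmetic mean of the matched chips' u and v coordinates in the given
#' booth; luminance is discarded.
#'
#' @param matches Match records, or a two-column matrix / data frame of (u, v)
#'   points (in which case `palette` is ignored).
#' @param palette Palette table (when `matches` are records).
#' @param booth Booth of measurement (when `matches` are records).
#' @return Named vector `c(u, v)`.
#' @export
mean_chromaticity <- function(matches, palette = NULL, booth = NULL) {
  uv <- .points_uv(matches, palette, booth)
  if (nrow(uv) == 0L) stop("no valid matches to average")
  c(u = mean(uv[, 1]), v = mean(uv[, 2]))
}

#' Match variability
#'
#' The average u'v' distance between each match and the mean match — the
#' dispersion measure used to compare conditions. Translation invariant and
#' scale equivariant.
#'
#' @inheritParams mean_chromaticity
#' @return Non-negative scalar.
#' @export
variability <- function(matches, palette = NULL, booth = NULL) {
  uv <- .points_uv(matches, palette, booth)
  if (nrow(uv) == 0L) stop("no valid matches")
  ctr <- colMeans(uv)
  mean(sqrt((uv[, 1] - ctr[1])^2 + (uv[, 2] - ctr[2])^2))
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic minimising algebraic distance subject to the ellipse
#' constraint 4ac - b^2 = 1, using the numerically stabilised formulation
#' (data are centred and scaled before the fit; the constrained eigenproblem
#' is solved on a reduced 3x3 system). At chromaticity scale (~1e-1) the raw
#' normal equations are badly conditioned, hence the normalisation.
#'
#' @param points Two-column matrix or data frame of (u, v) coordinates; at
#'   least 5 points in general position, 6 recommended.
#' @return An object of class `"ellipse_fit"`: list with `center` (u, v),
#'   `semi_axes` (a >= b), `orientation` (radians, angle of the major axis in
#'   (-pi/2, pi/2]), `algebraic_residual`, and the conic `coefficients`
#'   (a, b, c, d, e, f) in the original coordinates' normalised frame.
#' @export
fit_ellipse <- function(points) {
  uv <- .points_uv(points)
  uv <- uv[stats::complete.cases(uv), , drop = FALSE]
  n <- nrow(uv)
  if (n < 5L) stop("ellipse fit needs at least 5 points")
  ctr <- colMeans(uv)
  x0 <- uv[, 1] - ctr[1]; y0 <- uv[, 2] - ctr[2]
  s <- mean(sqrt(x0^2 + y0^2))
  if (s == 0) stop("degenerate point configuration: all points coincide")
  # collinearity check on the centred data
  if (min(svd(cbind(x0, y0))$d) < 1e-10 * max(svd(cbind(x0, y0))$d))
    stop("degenerate point configuration: points are collinear")
  x <- x0 / s; y <- y0 / s
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, rep(1, n))
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point configuration: cannot fit an ellipse"))
  M <- S1 + S2 %*% T
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  evec <- Re(eg$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  i <- which(cond > 0)
  if (length(i) == 0L)
    stop("no elliptical solution for these points")
  a1 <- evec[, i[1]]
  coef <- c(a1, as.numeric(T %*% a1))
  names(coef) <- c("a", "b", "c", "d", "e", "f")
  # geometry in normalised frame
  Q <- matrix(c(coef["a"], coef["b"] / 2, coef["b"] / 2, coef["c"]), 2, 2)
  L <- c(coef["d"], coef["e"])
  z0 <- -solve(Q, L) / 2
  c0 <- sum(L * z0) / 2 + coef["f"]
  eQ <- eigen(Q, symmetric = TRUE)
  ax2 <- -c0 / eQ$values
  if (any(ax2 <= 0)) stop("no elliptical solution for these points")
  semi <- sqrt(ax2)            # eigen() sorts values decreasing -> semi incr.
  ord <- order(semi, decreasing = TRUE)
  major_vec <- eQ$vectors[, ord[1]]
  orientation <- atan2(major_vec[2], major_vec[1])
  if (orientation <= -pi / 2) orientation <- orientation + pi
  if (orientation > pi / 2) orientation <- orientation - pi
  resid <- mean((cbind(D1, D2) %*% (coef / sqrt(sum(coef^2))))^2)
  structure(list(center = c(u = ctr[1] + s * z0[1], v = ctr[2] + s * z0[2]),
                 semi_axes = c(a = s * semi[ord[1]], b = s * semi[ord[2]]),
                 orientation = orientation,
                 algebraic_residual = resid,
                 coefficients = coef),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("Ellipse fit: center (%.4f, %.4f), semi-axes %.4f / %.4f, ",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2]))
  cat(sprintf("orientation %.1f deg\n", x$orientation * 180 / pi))
  invisible(x)
}

#' Palette density around a chromaticity
#'
#' Number of palette chips, measured in one booth, lying within a disc of the
#' given radius around a center chromaticity. Chips exactly on the boundary
#' count as inside. Used as a proxy for response-option granularity: the
#' center is typically a cube's average baseline match and the radius the
#' average baseline variability.
#'
#' @param palette Palette table.
#' @param booth Booth of measurement.
#' @param center Chromaticity (vector with u, v).
#' @param radius Positive disc radius in u'v' units.
#' @return Integer chip count.
#' @export
palette_density <- function(palette, booth, center, radius) {
  stopifnot(radius > 0)
  sub <- palette[palette$booth == booth, , drop = FALSE]
  ctr <- .uv(center)
  d <- sqrt((sub$u - ctr[1])^2 + (sub$v - ctr[2])^2)
  sum(d <= radius)
}

#' Palette density over a range of radii
#'
#' Evaluates [palette_density()] at `radius * multipliers`, to check that a
#' density-based conclusion is not an artifact of one radius choice.
#'
#' @inheritParams palette_density
#' @param multipliers Positive radius multipliers.
#' @return Data frame with columns `multiplier`, `radius`, `count`.
#' @export
density_sensitivity <- function(palette, booth, center, radius,
                                multipliers = c(0.5, 0.75, 1, 1.5, 2)) {
  stopifnot(all(multipliers > 0))
  counts <- vapply(multipliers, function(m)
    palette_density(palette, booth, center, radius * m), numeric(1))
  data.frame(multiplier = multipliers, radius = radius * multipliers,
             count = as.integer(counts))
}
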