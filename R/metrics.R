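# Core constancy statistics.
#
# The estimator frames each cube's matches relative to the baseline
# condition: the reference is the average baseline match, the physical shift
# (phys) is what that average would become if observers simply re-picked
# their baseline chips under the matching booth's illuminant, and the
# perceptual shift (perc) is what the matches actually became. The modified
# Brunswick ratio is the scalar projection of perc onto phys, normalised by
# the length of phys: 1 = perfect constancy, 0 = no compensation, > 1 =
# overcompensation.

#' Chromaticities of matched chips
#'
#' Looks up, for each record with a recorded chip, that chip's measured
#' chromaticity in the requested booth.
#'
#' @param matches Match record data frame.
#' @param palette Palette table.
#' @param booth Booth in which to take the measurement (defaults to each
#'   record's own matching booth; a single booth id applies to all records).
#' @return Two-column matrix of (u, v), one row per record with a chip.
#' @export
match_chromaticities <- function(matches, palette, booth = NULL) {
  m <- matches[!is.na(matches$chip_id), , drop = FALSE]
  if (nrow(m) == 0L) return(cbind(u = numeric(0), v = numeric(0)))
  b <- if (is.null(booth)) m$match_booth else rep(booth, nrow(m))
  out <- matrix(NA_real_, nrow(m), 2, dimnames = list(NULL, c("u", "v")))
  for (bb in unique(b)) {
    i <- b == bb
    out[i, ] <- .chip_uv(palette, m$chip_id[i], bb)
  }
  out
}

#' Constancy prediction for one cube
#'
#' The chromaticity a perfectly constant observer's matches would average to:
#' the chips chosen in the baseline condition, re-measured in the matching
#' booth, averaged with trial weights (a chip chosen by k observers
#' contributes k times).
#'
#' @param cube Cube name.
#' @param baseline_records Baseline-condition match records (any extra
#'   conditions/cubes present are filtered out).
#' @param palette Palette table; every baseline chip must be measured in
#'   `match_booth`.
#' @param match_booth Booth whose illuminant the prediction is expressed
#'   under.
#' @return Named numeric vector `c(u, v)`.
#' @export
constancy_prediction <- function(cube, baseline_records, palette,
                                 match_booth) {
  b <- baseline_records[baseline_records$cube_name == cube &
                          baseline_records$condition == "baseline" &
                          !is.na(baseline_records$chip_id), , drop = FALSE]
  if (nrow(b) == 0L)
    stop("no baseline records for cube '", cube, "'")
  uv <- .chip_uv(palette, b$chip_id, match_booth)
  c(u = mean(uv[, 1]), v = mean(uv[, 2]))
}

#' Modified Brunswick ratio
#'
#' `dot(perc, phys) / ||phys||^2`: the scalar projection of the perceptual
#' shift onto the physical (illuminant) shift, divided by the length of the
#' physical shift. Linear in `perc`, and blind to the component of `perc`
#' orthogonal to `phys`.
#'
#' @param perc Perceptual shift, 2-vector in u'v'.
#' @param phys Physical shift, 2-vector in u'v', non-zero.
#' @return Dimensionless scalar.
#' @examples
#' modified_brunswick_ratio(c(0.05, 0.03), c(0.05, 0.03))  # 1
#' modified_brunswick_ratio(c(0.05, 0), c(0.05, 0.03))     # ~0.735
#' @export
modified_brunswick_ratio <- function(perc, phys) {
  perc <- as.numeric(perc); phys <- as.numeric(phys)
  stopifnot(length(perc) == 2L, length(phys) == 2L)
  n2 <- sum(phys^2)
  if (n2 == 0)
    stop("undefined index: physical shift has zero length")
  sum(perc * phys) / n2
}

#' Per-cube constancy index
#'
#' For a cross-booth condition (illumination or joint), computes the
#' reference (average baseline match in the cube's home booth), the physical
#' shift (constancy prediction minus reference), and a per-observer modified
#' Brunswick ratio from each observer's own match. Reports the
#' across-observer mean and s.e.m. Alternatively, `estimator = "average"`
#' computes a single ratio from the condition's average match; by linearity
#' of the index the two estimators have the same mean.
#'
#' @param cube Cube name.
#' @param matches Cleaned match records (must include baseline and the
#'   requested condition for this cube).
#' @param palette Palette table.
#' @param condition `"illumination"` or `"joint"`.
#' @param estimator `"per_observer"` (default) or `"average"`.
#' @return List with `cube`, `condition`, `n_observers`, `mbr_mean`,
#'   `mbr_sem` (NA when fewer than 2 observers), `ei`, `reference`, `phys`,
#'   `prediction`, `avg_match`.
#' @export
mbr_per_cube <- function(cube, matches, palette,
                         condition = c("illumination", "joint"),
                         estimator = c("per_observer", "average")) {
  condition <- match.arg(condition)
  estimator <- match.arg(estimator)
  cond <- matches[matches$cube_name == cube &
                    matches$condition == condition &
                    !is.na(matches$chip_id), , drop = FALSE]
  if (nrow(cond) == 0L)
    stop("no '", condition, "' records for cube '", cube, "'")
  match_booth <- unique(cond$match_booth)
  view_booth <- unique(cond$view_booth)
  stopifnot(length(match_booth) == 1L, length(view_booth) == 1L)
  base <- matches[matches$cube_name == cube &
                    matches$condition == "baseline", , drop = FALSE]
  reference <- .baseline_mean(cube, base, palette, view_booth)
  prediction <- constancy_prediction(cube, base, palette, match_booth)
  phys <- prediction - reference
  uv <- .chip_uv(palette, cond$chip_id, match_booth)
  avg_match <- c(u = mean(uv[, 1]), v = mean(uv[, 2]))
  if (estimator == "per_observer") {
    ratios <- apply(uv, 1, function(p)
      modified_brunswick_ratio(p - reference, phys))
    mbr_mean <- mean(ratios)
    mbr_sem <- if (length(ratios) >= 2L)
      stats::sd(ratios) / sqrt(length(ratios)) else NA_real_
  } else {
    mbr_mean <- modified_brunswick_ratio(avg_match - reference, phys)
    mbr_sem <- NA_real_
  }
  list(cube = cube, condition = condition, n_observers = nrow(cond),
       mbr_mean = mbr_mean, mbr_sem = mbr_sem,
       ei = error_index(avg_match, prediction),
       reference = reference, phys = phys, prediction = prediction,
       avg_match = avg_match)
}

.baseline_mean <- function(cube, baseline_records, palette, booth) {
  b <- baseline_records[baseline_records$cube_name == cube &
                          baseline_records$condition == "baseline" &
                          !is.na(baseline_records$chip_id), , drop = FALSE]
  if (nrow(b) == 0L) stop("no baseline records for cube '", cube, "'")
  uv <- .chip_uv(palette, b$chip_id, booth)
  c(u = mean(uv[, 1]), v = mean(uv[, 2]))
}

#' Error index
#'
#' Distance in the u'v' plane between a condition's average match and the
#' constancy prediction; an atheoretic effect-size measure that is agnostic
#' about the direction or cause of the shift.
#'
#' @param avg_match,prediction Chromaticities (vectors with u, v).
#' @return Non-negative scalar.
#' @export
error_index <- function(avg_match, prediction) {
  uv_distance(avg_match, prediction)
}

#' Split-half error of a set of matches
#'
#' The noise-floor analogue of the error index for the baseline condition:
#' the data are randomly divided into two equal-as-possible halves and the
#' distance between the two half means is computed. A single split is a noisy
#' estimator, so the default averages many seeded random splits; `n_splits =
#' 1` reproduces the single-split procedure.
#'
#' @param uv Two-column matrix or data frame of match chromaticities
#'   (at least 2 rows).
#' @param n_splits Number of random partitions to average, default 1000.
#' @param seed RNG seed for the partition draws.
#' @return Mean split-half distance across partitions.
#' @export
split_half_ei <- function(uv, n_splits = 1000, seed = 1L) {
  uv <- as.matrix(uv)[, 1:2, drop = FALSE]
  n <- nrow(uv)
  if (n < 2L) stop("split-half error needs at least 2 records")
  h <- n %/% 2L
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  d <- vapply(seq_len(n_splits), function(i) {
    g1 <- sample.int(n, h)
    m1 <- colMeans(uv[g1, , drop = FALSE])
    m2 <- colMeans(uv[-g1, , drop = FALSE])
    sqrt(sum((m1 - m2)^2))
  }, numeric(1))
  mean(d)
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
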