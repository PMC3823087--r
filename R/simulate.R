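# Synthetic experiment generator.
#
# Observers are modelled with three parameters: alpha, the degree of
# illuminant adaptation (0 = match the raw baseline chromaticity, 1 = match
# the chip a perfectly constant observer would pick); beta, a gain on a
# background-contrast term (0 = background has no effect, the study's
# headline finding); and sigma, the per-axis sd of bivariate perceptual
# noise in u'v'. Cross-booth matching carries extra uncertainty
# (sigma_cross), reflecting that the illumination conditions force the
# observer to represent two illuminants at once. Responses are snapped to
# the nearest palette chip in the matching booth.

# Hunt-Pointer-Estevez cone-like primaries (normalised to D65); the fixed
# linear transform in which diagonal von-Kries scaling is applied.
.hpe <- matrix(c(0.38971, 0.68898, -0.07868,
                 -0.22981, 1.18340, 0.04641,
                 0, 0, 1), 3, 3, byrow = TRUE)
.hpe_inv <- solve(.hpe)

# u'v' at unit luminance -> XYZ
.uv_to_xyz <- function(uv) {
  uv <- .uv(uv)
  den <- 6 * uv[1] - 16 * uv[2] + 12
  x <- 9 * uv[1] / den
  y <- 4 * uv[2] / den
  c(X = x / y, Y = 1, Z = (1 - x - y) / y)
}

#' Map a chromaticity from one illuminant to another
#'
#' Diagonal von-Kries-style adaptation: the chromaticity is lifted to
#' tristimulus values at unit luminance, expressed in a fixed cone-like
#' space, scaled componentwise by the ratio of the two booth illuminants in
#' that space, and projected back to u'v'. By construction the source
#' illuminant maps exactly onto the destination illuminant. This serves as a
#' surrogate for physically re-measuring a surface under the second booth's
#' light.
#'
#' @param uv Chromaticity to map (vector with u, v).
#' @param illum_from,illum_to Illuminant white points (vectors with u, v).
#' @return Named vector `c(u, v)`.
#' @export
illuminant_map <- function(uv, illum_from, illum_to) {
  lms_from <- as.numeric(.hpe %*% .uv_to_xyz(illum_from))
  lms_to <- as.numeric(.hpe %*% .uv_to_xyz(illum_to))
  lms <- as.numeric(.hpe %*% .uv_to_xyz(uv)) * lms_to / lms_from
  ch <- tristimulus_to_chromaticity(as.numeric(.hpe_inv %*% lms))
  ch[c("u", "v")]
}

#' Simulation configuration
#'
#' Bundles and validates the generator's parameters. Defaults emulate the
#' study's conditions: a 1022-chip palette in strips of 7 or 8 with
#' non-uniform chromatic density, booth white points at (0.27, 0.53) and
#' (0.22, 0.50), 16 cubes with paired backgrounds, high-but-imperfect
#' adaptation, no background effect, and a retained-sample-sized observer
#' pool (112, fourteen full counterbalance cycles).
#'
#' @param alpha Degree of illuminant adaptation, in \[0, 1.2\].
#' @param beta Background modulation gain (0 disables background effects).
#' @param sigma Per-axis sd of bivariate perceptual noise in u'v'.
#' @param sigma_cross Additional per-axis noise sd (combined in quadrature
#'   with `sigma`) when the viewing and matching booths differ; models the
#'   extra uncertainty of representing two illuminants.
#' @param n_observers Number of simulated observers.
#' @param n_chips Palette size; must be expressible as 7a + 8b.
#' @param n_clusters,cluster_sd,cluster_weights Palette mixture: number of
#'   Gaussian clusters, their per-axis sd, and their weight profile (default
#'   a geometric profile, giving markedly non-uniform density).
#' @param illuminants Data frame of booth white points, as
#'   [booth_illuminants()].
#' @param seed Root RNG seed; per-observer streams are derived from it by
#'   counter-based splitting so earlier observers are unchanged when
#'   `n_observers` grows.
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(alpha = 0.9, beta = 0, sigma = 0.005,
                              sigma_cross = 0.004, n_observers = 112L,
                              n_chips = 1022L, n_clusters = 8L,
                              cluster_sd = 0.03, cluster_weights = NULL,
                              illuminants = booth_illuminants(),
                              seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1.2, sigma >= 0, sigma_cross >= 0,
            n_observers >= 1, n_chips >= 7, n_clusters >= 1, cluster_sd > 0)
  strips <- .strip_partition(n_chips)
  if (is.null(cluster_weights))
    cluster_weights <- 0.75^seq_len(n_clusters)
  stopifnot(length(cluster_weights) == n_clusters, all(cluster_weights > 0))
  structure(list(alpha = alpha, beta = beta, sigma = sigma,
                 sigma_cross = sigma_cross,
                 n_observers = as.integer(n_observers),
                 n_chips = as.integer(n_chips), strip_sizes = strips,
                 n_clusters = as.integer(n_clusters),
                 cluster_sd = cluster_sd,
                 cluster_weights = cluster_weights / sum(cluster_weights),
                 illuminants = illuminants, seed = as.integer(seed)),
            class = "simulation_config")
}

# partition n into strip sizes from {7, 8}, preferring 8s as the physical
# palette book does; errors when impossible (n < 42 not of the form 7a+8b)
.strip_partition <- function(n) {
  a <- (8L - (n %% 8L)) %% 8L       # number of 7-strips
  if (7L * a > n)
    stop("n_chips = ", n, " cannot be partitioned into strips of 7 and 8")
  b <- (n - 7L * a) %/% 8L
  rep(c(8L, 7L), c(b, a))
}

#' Generate a synthetic matching palette
#'
#' Chip chromaticities under booth A are drawn from a mixture of Gaussian
#' clusters (commercial palettes sample color space very unevenly), clipped
#' to a plausible paint gamut, sorted by hue and partitioned into strips of
#' 7 or 8 chips. Booth-B chromaticities are derived with [illuminant_map()],
#' standing in for re-measuring each chip under the second illuminant.
#'
#' @param config A [simulation_config()].
#' @return Palette data frame (`chip_id`, `strip_id`, `booth`, `u`, `v`,
#'   `Y`), one row per chip per booth.
#' @export
gen_palette <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  n <- config$n_chips
  box <- list(u = c(0.14, 0.45), v = c(0.44, 0.57))
  centers <- cbind(stats::runif(config$n_clusters, box$u[1] + 0.02,
                                box$u[2] - 0.02),
                   stats::runif(config$n_clusters, box$v[1] + 0.01,
                                box$v[2] - 0.01))
  k <- sample.int(config$n_clusters, n, replace = TRUE,
                  prob = config$cluster_weights)
  u <- stats::rnorm(n, centers[k, 1], config$cluster_sd)
  v <- stats::rnorm(n, centers[k, 2], config$cluster_sd)
  u <- pmin(pmax(u, box$u[1]), box$u[2])
  v <- pmin(pmax(v, box$v[1]), box$v[2])
  illA <- .illum_uv("A"); illB <- .illum_uv("B")
  ord <- order(atan2(v - mean(v), u - mean(u)), u, v)
  u <- u[ord]; v <- v[ord]
  chip_id <- sprintf("SW%05d", seq_len(n))
  strip_id <- sprintf("strip%03d", rep(seq_along(config$strip_sizes),
                                       config$strip_sizes))
  uvB <- t(vapply(seq_len(n), function(i)
    illuminant_map(c(u[i], v[i]), illA, illB), numeric(2)))
  rbind(
    data.frame(chip_id = chip_id, strip_id = strip_id, booth = "A",
               u = u, v = v, Y = NA_real_),
    data.frame(chip_id = chip_id, strip_id = strip_id, booth = "B",
               u = uvB[, 1], v = uvB[, 2], Y = NA_real_))
}

# Noise-free internal match target for one cube in one condition.
.match_target <- function(cube_row, condition, config) {
  b <- cube_row$booth
  other <- setdiff(c("A", "B"), b)
  illA <- config$illuminants
  ill_view <- c(u = illA$u[illA$booth == b], v = illA$v[illA$booth == b])
  target <- c(cube_row$u, cube_row$v)
  cross <- condition %in% c("illumination", "joint")
  if (cross) {
    ill_match <- c(u = illA$u[illA$booth == other],
                   v = illA$v[illA$booth == other])
    mapped <- illuminant_map(target, ill_view, ill_match)
    target <- (1 - config$alpha) * target + config$alpha * mapped
  }
  if (condition %in% c("background", "joint") && config$beta != 0) {
    contrast <- c(cube_row$bg_u, cube_row$bg_v) - ill_view
    target <- target + config$beta * contrast
  }
  c(u = unname(target[1]), v = unname(target[2]))
}

#' Simulate one observer's match
#'
#' Builds the noise-free internal target for the cube/condition (baseline
#' chromaticity, shifted fraction `alpha` of the way to its von-Kries image
#' when matching across booths, plus `beta` times the background-contrast
#' term when a background is present), perturbs it with bivariate normal
#' noise, and snaps to the nearest palette chip measured in the matching
#' booth (ties broken by lowest chip id). Draws from the current RNG stream.
#'
#' @param cube_row One row of the cube stimulus table.
#' @param condition One of baseline, background, illumination, joint.
#' @param palette Palette table.
#' @param config A [simulation_config()].
#' @return The chosen `chip_id`.
#' @export
simulate_observer_match <- function(cube_row, condition, palette, config) {
  sub <- palette[palette$booth ==
                   (if (condition %in% c("illumination", "joint"))
                     setdiff(c("A", "B"), cube_row$booth) else cube_row$booth),
                 , drop = FALSE]
  if (nrow(sub) == 0L) stop("palette has no chips in the matching booth")
  target <- .match_target(cube_row, condition, config)
  sd_tot <- if (condition %in% c("illumination", "joint"))
    sqrt(config$sigma^2 + config$sigma_cross^2) else config$sigma
  target <- target + stats::rnorm(2, 0, sd_tot)
  sub <- sub[order(sub$chip_id), , drop = FALSE]
  d2 <- (sub$u - target[1])^2 + (sub$v - target[2])^2
  sub$chip_id[which.min(d2)]
}

#' Generate a complete synthetic experiment
#'
#' Builds the counterbalanced design for every observer, simulates every
#' match, and returns the experiment in the study-data formats together with
#' the generator's ground truth. Each observer draws from an RNG stream
#' derived from the root seed and the observer counter, so growing
#' `n_observers` never reshuffles earlier observers.
#'
#' @param config A [simulation_config()].
#' @param palette Optional palette table to match against; default is the
#'   config's own [gen_palette()]. Supplying e.g. a fine grid palette gives a
#'   near-continuous response scale for parameter-recovery studies.
#' @return List of class `"constancy_sim"` with `matches`, `palette`,
#'   `cubes`, `truth` (per cube x condition noise-free expected match
#'   chromaticity plus the generating parameters) and `config`.
#' @export
gen_experiment <- function(config = simulation_config(), palette = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(palette)) palette <- gen_palette(config)
  cubes <- builtin_table2()
  old <- .save_rng(); on.exit(.restore_rng(old))
  rows <- vector("list", config$n_observers)
  for (i in seq_len(config$n_observers)) {
    des <- design_assignment(i)
    set.seed((config$seed %% 100000L) * 20011L + i * 7919L)
    chips <- character(nrow(des))
    for (j in seq_len(nrow(des))) {
      cr <- cubes[cubes$cube == des$cube[j], , drop = FALSE]
      chips[j] <- simulate_observer_match(cr, des$condition[j], palette,
                                          config)
    }
    rows[[i]] <- data.frame(observer_id = sprintf("obs%04d", i),
                            trial_index = des$trial_index,
                            cube_name = des$cube,
                            condition = des$condition,
                            view_booth = des$view_booth,
                            match_booth = des$match_booth,
                            chip_id = chips)
  }
  matches <- do.call(rbind, rows)
  for (f in .flag_cols) matches[[f]] <- FALSE
  truth <- do.call(rbind, lapply(.conditions, function(cond) {
    uv <- t(vapply(seq_len(nrow(cubes)), function(k)
      .match_target(cubes[k, ], cond, config), numeric(2)))
    data.frame(cube = cubes$cube, condition = cond, u = uv[, 1], v = uv[, 2])
  }))
  structure(list(matches = matches, palette = palette, cubes = cubes,
                 truth = list(alpha = config$alpha, beta = config$beta,
                              sigma = config$sigma,
                              sigma_cross = config$sigma_cross,
                              expected = truth),
                 config = config),
            class = "constancy_sim")
}

#' @export
print.constancy_sim <- function(x, ...) {
  cat(sprintf(paste0("Synthetic matching experiment: %d observers, %d chips,",
                     " alpha = %.2f, beta = %.2f, sigma = %.3f\n"),
              x$config$n_observers, x$config$n_chips, x$config$alpha,
              x$config$beta, x$config$sigma))
  invisible(x)
}

#' Write a synthetic experiment to a directory
#'
#' Emits `matches.csv`, `palette.csv`, `cubes.csv`, `truth.json` and
#' `config.json` in the study-data formats, so the experiment round-trips
#' through [load_matches()], [read_palette()] and [read_cubes()].
#'
#' @param sim A `"constancy_sim"` object from [gen_experiment()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "constancy_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matches(sim$matches, file.path(dir, "matches.csv"))
  write_palette(sim$palette, file.path(dir, "palette.csv"))
  write_cubes(sim$cubes, file.path(dir, "cubes.csv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  cfg <- unclass(sim$config)
  cfg$illuminants <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
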