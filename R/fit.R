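# The central estimator: runs cleaning, per-cube constancy / error /
# dispersion statistics, palette density, and the inferential layer, and
# returns everything as one classed object.

#' Fit the constancy analysis to a matching experiment
#'
#' Runs the full pipeline on a set of match records: observer- and
#' trial-level cleaning; per cube and condition the average match, the
#' modified Brunswick ratio (cross-booth conditions), the error index
#' (split-half in baseline), variability, and the best-fit ellipse center;
#' palette density around each cube's baseline match; and the inferential
#' layer (three-way ANOVA on error indices, paired t-tests across cubes,
#' Pearson correlations).
#'
#' @param matches Match records (see [load_matches()]).
#' @param palette Palette table (see [read_palette()]).
#' @param cubes Cube stimulus table, default [builtin_table2()].
#' @param estimator `"per_observer"` (constancy index averaged over
#'   per-observer ratios, with s.e.m. across observers) or `"average"`
#'   (single ratio from the condition's average match); the two agree in the
#'   mean by linearity of the index.
#' @param n_splits Random partitions averaged for the baseline split-half
#'   error; 1 reproduces the single-split procedure.
#' @param split_seed Seed for the split-half partitions.
#' @param density_radius Radius for palette density; default is the grand
#'   mean of per-cube baseline variability.
#' @param radius_multipliers Multipliers for the density sensitivity table.
#' @param bonferroni If TRUE, Bonferroni-adjusted p-values are added to the
#'   t-test and correlation tables (uncorrected p-values are always
#'   reported).
#' @param clean If FALSE, the records are assumed already cleaned.
#' @return Object of class `"constancy_fit"`; see [summary.constancy_fit()].
#' @export
constancy_fit <- function(matches, palette, cubes = builtin_table2(),
                          estimator = c("per_observer", "average"),
                          n_splits = 1000, split_seed = 1L,
                          density_radius = NULL,
                          radius_multipliers = c(0.5, 0.75, 1, 1.5, 2),
                          bonferroni = FALSE, clean = TRUE) {
  estimator <- match.arg(estimator)
  cl <- match.call()
  if (clean) {
    cleaned <- clean_matches(matches, palette)
    matches <- cleaned$matches
    report <- cleaned$report
  } else report <- NULL

  res <- list()
  for (cube in cubes$cube) {
    home <- cubes$booth[cubes$cube == cube]
    for (cond in .conditions) {
      m <- matches[matches$cube_name == cube & matches$condition == cond &
                     !is.na(matches$chip_id), , drop = FALSE]
      row <- list(cube = cube, condition = cond, n = nrow(m),
                  mbr_mean = NA_real_, mbr_sem = NA_real_, ei = NA_real_,
                  mean_u = NA_real_, mean_v = NA_real_,
                  ellipse_u = NA_real_, ellipse_v = NA_real_,
                  variability = NA_real_)
      if (nrow(m) >= 1L) {
        uv <- match_chromaticities(m, palette)
        ctr <- colMeans(uv)
        row$mean_u <- ctr[1]; row$mean_v <- ctr[2]
        row$variability <- variability(uv)
        ell <- tryCatch(fit_ellipse(uv), error = function(e) NULL)
        if (!is.null(ell)) {
          row$ellipse_u <- unname(ell$center[1])
          row$ellipse_v <- unname(ell$center[2])
        }
        if (cond == "baseline") {
          if (nrow(uv) >= 2L)
            row$ei <- split_half_ei(uv, n_splits = n_splits,
                                    seed = split_seed)
        } else if (cond == "background") {
          pred <- tryCatch(constancy_prediction(cube, matches, palette,
                                                unique(m$match_booth)),
                           error = function(e) NULL)
          if (!is.null(pred)) row$ei <- error_index(ctr, pred)
        } else {
          r <- tryCatch(mbr_per_cube(cube, matches, palette, cond,
                                     estimator = estimator),
                        error = function(e) NULL)
          if (!is.null(r)) {
            row$mbr_mean <- r$mbr_mean; row$mbr_sem <- r$mbr_sem
            row$ei <- r$ei
          }
        }
      }
      res[[length(res) + 1L]] <- row
    }
  }
  results <- do.call(rbind, lapply(res, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(results) <- NULL

  # palette density around each cube's baseline match, one shared radius
  base <- results[results$condition == "baseline", ]
  if (is.null(density_radius))
    density_radius <- mean(base$variability, na.rm = TRUE)
  results$density <- NA_integer_
  dens_sens <- NULL
  if (is.finite(density_radius) && density_radius > 0) {
    for (cube in cubes$cube) {
      b <- base[base$cube == cube, ]
      if (!is.finite(b$mean_u)) next
      home <- cubes$booth[cubes$cube == cube]
      results$density[results$cube == cube] <-
        palette_density(palette, home, c(b$mean_u, b$mean_v), density_radius)
    }
    ref <- base[which(is.finite(base$mean_u))[1], ]
    dens_sens <- density_sensitivity(
      palette, cubes$booth[cubes$cube == ref$cube],
      c(ref$mean_u, ref$mean_v), density_radius, radius_multipliers)
  }

  anova_tab <- t_tab <- cor_tab <- NULL
  wide <- function(cond, col) {
    v <- results[[col]][results$condition == cond]
    v[match(cubes$cube, results$cube[results$condition == cond])]
  }
  ei <- sapply(.conditions, wide, col = "ei")
  if (all(is.finite(ei))) {
    cells <- expand.grid(cube = cubes$cube,
                         illumination = c(FALSE, TRUE),
                         background = c(FALSE, TRUE),
                         KEEP.OUT.ATTRS = FALSE)
    cond_of <- function(ill, bg)
      .conditions[1 + bg + 2 * ill]  # baseline, background, illumination, joint
    cells$ei <- mapply(function(cu, il, bg)
      ei[match(cu, cubes$cube), cond_of(il, bg)],
      cells$cube, cells$illumination, cells$background)
    anova_tab <- three_way_anova(cells)

    vb <- sapply(.conditions, wide, col = "variability")
    mbr <- sapply(c("illumination", "joint"), wide, col = "mbr_mean")
    tt <- list(
      `ei: illumination vs background` = paired_t(ei[, "illumination"],
                                                  ei[, "background"]),
      `ei: illumination vs baseline` = paired_t(ei[, "illumination"],
                                                ei[, "baseline"]),
      `ei: background vs baseline` = paired_t(ei[, "background"],
                                              ei[, "baseline"]),
      `ei: joint vs illumination` = paired_t(ei[, "joint"],
                                             ei[, "illumination"]),
      `mbr: joint vs illumination` = paired_t(mbr[, "joint"],
                                              mbr[, "illumination"]),
      `variability: illumination vs baseline` =
        paired_t(vb[, "illumination"], vb[, "baseline"]),
      `variability: background vs baseline` =
        paired_t(vb[, "background"], vb[, "baseline"]))
    t_tab <- data.frame(comparison = names(tt),
                        t = sapply(tt, `[[`, "statistic"),
                        df = sapply(tt, `[[`, "df"),
                        p = sapply(tt, `[[`, "p_two_tailed"),
                        mean_diff = sapply(tt, `[[`, "mean_diff"))
    rownames(t_tab) <- NULL
    dens <- wide("baseline", "density")
    cc <- list(
      `variability: baseline vs illumination` =
        pearson_r(vb[, "baseline"], vb[, "illumination"]),
      `variability: baseline vs background` =
        pearson_r(vb[, "baseline"], vb[, "background"]),
      `mbr: illumination vs joint` = pearson_r(mbr[, "illumination"],
                                               mbr[, "joint"]),
      `density vs mbr (illumination)` = pearson_r(dens,
                                                  mbr[, "illumination"]),
      `density vs mbr (joint)` = pearson_r(dens, mbr[, "joint"]),
      `density vs variability (illumination)` =
        pearson_r(dens, vb[, "illumination"]),
      `density vs variability (joint)` = pearson_r(dens, vb[, "joint"]))
    cor_tab <- data.frame(comparison = names(cc),
                          r = sapply(cc, `[[`, "statistic"),
                          df = sapply(cc, `[[`, "df"),
                          p = sapply(cc, `[[`, "p_two_tailed"))
    rownames(cor_tab) <- NULL
    if (bonferroni) {
      t_tab$p_bonferroni <- stats::p.adjust(t_tab$p, "bonferroni")
      cor_tab$p_bonferroni <- stats::p.adjust(cor_tab$p, "bonferroni")
    }
  }

  structure(list(results = results, anova = anova_tab, t_tests = t_tab,
                 correlations = cor_tab, cleaning = report,
                 density_radius = density_radius,
                 density_sensitivity = dens_sens,
                 estimator = estimator, n_splits = n_splits,
                 call = cl),
            class = "constancy_fit")
}

#' @export
print.constancy_fit <- function(x, ...) {
  cat("Color-constancy analysis (modified Brunswick ratios)\n")
  ill <- x$results[x$results$condition == "illumination", ]
  ok <- is.finite(ill$mbr_mean)
  if (any(ok)) {
    m <- mean(ill$mbr_mean[ok])
    sem <- stats::sd(ill$mbr_mean[ok]) / sqrt(sum(ok))
    cat(sprintf("  mean constancy index (illumination): %.2f +/- %.2f (n = %d cubes, range %.2f-%.2f)\n",
                m, sem, sum(ok), min(ill$mbr_mean[ok]), max(ill$mbr_mean[ok])))
  }
  if (!is.null(x$cleaning))
    cat(sprintf("  trials: %d analysed (of %d after observer screening)\n",
                x$cleaning$n_trials_out, x$cleaning$n_trials_in))
  cat("  use summary() for per-cube indices, ANOVA and tests\n")
  invisible(x)
}

#' Summarise a constancy fit
#'
#' @param object A `"constancy_fit"`.
#' @param ... Unused.
#' @return The object, invisibly, after printing the per-cube table, the
#'   ANOVA, the paired t-tests and the correlations.
#' @export
summary.constancy_fit <- function(object, ...) {
  print(object)
  cat("\nPer-cube results:\n")
  r <- object$results
  num <- vapply(r, is.numeric, logical(1))
  r[num] <- lapply(r[num], function(z) round(z, 4))
  print(r, row.names = FALSE)
  if (!is.null(object$anova)) { cat("\n"); print(object$anova) }
  if (!is.null(object$t_tests)) {
    cat("\nPaired two-tailed t-tests (across cubes):\n")
    print(object$t_tests, row.names = FALSE, digits = 4)
  }
  if (!is.null(object$correlations)) {
    cat("\nPearson correlations (across cubes):\n")
    print(object$correlations, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' Per-cube constancy indices
#'
#' @param object A `"constancy_fit"`.
#' @param ... Unused.
#' @return Matrix of modified Brunswick ratios, cubes by cross-booth
#'   condition.
#' @export
coef.constancy_fit <- function(object, ...) {
  r <- object$results
  cubes <- unique(r$cube)
  out <- sapply(c("illumination", "joint"), function(cond)
    r$mbr_mean[r$condition == cond][match(cubes,
                                          r$cube[r$condition == cond])])
  rownames(out) <- cubes
  out
}

#' Plot a constancy fit
#'
#' Two base-graphics panels: per-cube constancy indices in the illumination
#' condition (with s.e.m. bars and the perfect-constancy line), and the mean
#' error index per condition (with s.e.m. across cubes).
#'
#' @param x A `"constancy_fit"`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.constancy_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  ill <- x$results[x$results$condition == "illumination", ]
  bp <- graphics::barplot(ill$mbr_mean, names.arg = ill$cube, las = 2,
                          ylab = "constancy index (mBR)",
                          main = "Illumination condition", ...)
  ok <- is.finite(ill$mbr_sem)
  graphics::arrows(bp[ok], ill$mbr_mean[ok] - ill$mbr_sem[ok],
                   bp[ok], ill$mbr_mean[ok] + ill$mbr_sem[ok],
                   angle = 90, code = 3, length = 0.02)
  graphics::abline(h = 1, col = "red")
  agg <- vapply(.conditions, function(cond) {
    v <- x$results$ei[x$results$condition == cond]
    c(mean(v, na.rm = TRUE),
      stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v))))
  }, numeric(2))
  bp <- graphics::barplot(agg[1, ], names.arg = .conditions, las = 2,
                          ylab = "error index (u'v' distance)",
                          main = "Error by condition")
  graphics::arrows(bp, agg[1, ] - agg[2, ], bp, agg[1, ] + agg[2, ],
                   angle = 90, code = 3, length = 0.02)
  invisible(x)
}

#' Write the report tables of a fit
#'
#' Emits `results.csv` (per cube x condition), `anova.csv`, `t_tests.csv`,
#' `correlations.csv`, `density_sensitivity.csv` and `cleaning.json` under a
#' directory.
#'
#' @param fit A `"constancy_fit"`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(fit, dir) {
  stopifnot(inherits(fit, "constancy_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$results, file.path(dir, "results.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(fit$anova))
    write_anova_table(fit$anova, file.path(dir, "anova.csv"))
  if (!is.null(fit$t_tests))
    utils::write.table(fit$t_tests, file.path(dir, "t_tests.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(fit$correlations))
    utils::write.table(fit$correlations, file.path(dir, "correlations.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(fit$density_sensitivity))
    utils::write.table(fit$density_sensitivity,
                       file.path(dir, "density_sensitivity.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(fit$cleaning))
    write_cleaning_report(fit$cleaning, file.path(dir, "cleaning.json"))
  invisible(dir)
}
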