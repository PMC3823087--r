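# Inferential layer: paired t-tests across cubes, the three-way
# fixed-effects ANOVA on error indices, and Pearson correlations. These are
# thin, validated wrappers over the standard stats machinery; p-values are
# reported uncorrected by default, with an optional Bonferroni adjustment at
# the reporting level.

#' Paired two-tailed t-test
#'
#' Standard paired t on the differences, `df = n - 1`. Values are paired by
#' position (here: by cube). Zero-variance differences are an error rather
#' than an infinite statistic.
#'
#' @param x,y Equal-length numeric vectors, length >= 2.
#' @return List with `statistic`, `df`, `p_two_tailed`, `n`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  # constant differences (up to float rounding) have no usable variance
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1e-300))
    stop("degenerate variance: all paired differences are equal")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_two_tailed = tt$p.value, n = length(x), mean_diff = mean(d))
}

#' Pearson correlation with two-tailed p
#'
#' Sample correlation; the p-value comes from the t transform with
#' `df = n - 2`.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return List with `statistic` (r), `t`, `df`, `p_two_tailed`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(statistic = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p_two_tailed = ct$p.value, n = length(x))
}

#' Three-way fixed-effects ANOVA on error indices
#'
#' The model has main effects for cube, illumination shift, and background
#' presence, plus the illumination x background interaction; cube x factor
#' interactions are pooled into the error term. On the full design (16 cubes
#' x 2 illumination levels x 2 background levels, one error-index value per
#' cell) the degrees of freedom are 15, 1, 1, 1 with 45 residual and 63
#' total.
#'
#' @param ei_cells Data frame with columns `cube`, `illumination` (two
#'   levels, e.g. FALSE/TRUE for same-/cross-booth), `background` (two
#'   levels), and `ei` (one value per cell). The design must be complete.
#' @return Data frame of class `"anova_table"` with rows Cube, Illumination,
#'   Background, Interaction (ill-back), Error, Total and columns `source`,
#'   `df`, `ss`, `F`, `p`.
#' @export
three_way_anova <- function(ei_cells) {
  need <- c("cube", "illumination", "background", "ei")
  stopifnot(all(need %in% names(ei_cells)))
  d <- data.frame(cube = factor(ei_cells$cube),
                  illumination = factor(ei_cells$illumination),
                  background = factor(ei_cells$background),
                  ei = ei_cells$ei)
  if (nlevels(d$illumination) != 2L || nlevels(d$background) != 2L)
    stop("illumination and background must each have exactly 2 levels")
  counts <- table(d$cube, d$illumination, d$background)
  if (any(counts != 1L))
    stop("design must be complete: exactly one ei value per ",
         "cube x illumination x background cell")
  fit <- stats::aov(ei ~ cube + illumination * background, data = d)
  s <- summary(fit)[[1]]
  rn <- trimws(rownames(s))
  pick <- function(nm) which(rn == nm)
  rows <- c(pick("cube"), pick("illumination"), pick("background"),
            pick("illumination:background"), pick("Residuals"))
  out <- data.frame(
    source = c("Cube", "Illumination", "Background",
               "Interaction (ill-back)", "Error", "Total"),
    df = c(s$Df[rows], sum(s$Df)),
    ss = c(s$`Sum Sq`[rows], sum(s$`Sum Sq`)),
    F = c(s$`F value`[rows], NA),
    p = c(s$`Pr(>F)`[rows], NA))
  out$F[out$source == "Error"] <- NA
  out$p[out$source == "Error"] <- NA
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("ANOVA for errors in color matches\n")
  y <- x
  y$ss <- signif(y$ss, 4)
  y$F <- ifelse(is.na(y$F), "", sprintf("%.2f", y$F))
  y$p <- ifelse(is.na(y$p), "", sprintf("%.3g", y$p))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @rdname three_way_anova
#' @param x An `anova_table`.
#' @param path Output path; the table is written as delimited text.
#' @param sep Field separator.
#' @export
write_anova_table <- function(x, path, sep = ",") {
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
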