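test_that("constancy prediction is the trial-weighted chip mean", {
  # c1 chosen twice at (0.30, 0.50), c2 once at (0.36, 0.53) in the match
  # booth: weighted mean (0.32, 0.51)
  pal <- tiny_palette(data.frame(chip_id = c("c1", "c2", "c1", "c2"),
                                 booth = c("A", "A", "B", "B"),
                                 u = c(0.28, 0.33, 0.30, 0.36),
                                 v = c(0.52, 0.54, 0.50, 0.53)))
  recs <- baseline_records(c("c1", "c1", "c2"))
  pred <- constancy_prediction("Ice blue", recs, pal, "B")
  expect_equal(unname(pred), c(0.32, 0.51), tolerance = 1e-12)
  # in the baseline booth itself: the baseline average match
  predA <- constancy_prediction("Ice blue", recs, pal, "A")
  expect_equal(unname(predA), c(mean(c(0.28, 0.28, 0.33)),
                                mean(c(0.52, 0.52, 0.54))), tolerance = 1e-12)
  # single chip: the prediction is that chip's chromaticity
  pred1 <- constancy_prediction("Ice blue", baseline_records(c("c1", "c1")),
                                pal, "B")
  expect_equal(unname(pred1), c(0.30, 0.50))
  expect_error(constancy_prediction("Plum", recs, pal, "B"), "no baseline")
  # chip without a measurement in the match booth is named
  pal_a <- pal[pal$booth == "A" | pal$chip_id != "c2", ]
  expect_error(constancy_prediction("Ice blue", recs, pal_a, "B"), "c2")
})

test_that("modified Brunswick ratio honours its contract", {
  expect_equal(modified_brunswick_ratio(c(0.05, 0.03), c(0.05, 0.03)), 1)
  expect_equal(modified_brunswick_ratio(c(0, 0), c(0.05, 0.03)), 0)
  # hand oracle: dot = 0.0025, ||phys||^2 = 0.0034
  expect_equal(modified_brunswick_ratio(c(0.05, 0), c(0.05, 0.03)),
               0.0025 / 0.0034, tolerance = 1e-12)
  expect_equal(modified_brunswick_ratio(c(0.05, 0), c(0.05, 0.03)),
               0.7353, tolerance = 1e-4)
  expect_error(modified_brunswick_ratio(c(0.01, 0.01), c(0, 0)), "zero")
})

test_that("the ratio is linear in perc and blind to orthogonal components", {
  set.seed(21)
  for (i in 1:20) {
    phys <- runif(2, -0.05, 0.05)
    if (sum(phys^2) < 1e-6) next
    perc <- runif(2, -0.05, 0.05)
    a <- runif(1, -2, 2)
    expect_equal(modified_brunswick_ratio(a * perc, phys),
                 a * modified_brunswick_ratio(perc, phys), tolerance = 1e-10)
    orth <- c(-phys[2], phys[1])
    expect_equal(modified_brunswick_ratio(perc + 0.3 * orth, phys),
                 modified_brunswick_ratio(perc, phys), tolerance = 1e-10)
  }
})

# A hand-built cross-booth scenario: baseline chips and illumination matches
# with known geometry. Baseline chips b1, b2 both at (0.30, 0.52) in A; their
# booth-B measurements at (0.25, 0.49). Illumination matches use chips at
# chosen offsets from the reference along phys.
cross_booth_fixture <- function(ill_chips) {
  pal <- tiny_palette(data.frame(
    chip_id = c("b1", "b1", "full", "full", "half", "half", "none", "none"),
    booth = rep(c("A", "B"), 4),
    u = c(0.30, 0.25, 0.31, 0.25, 0.31, 0.275, 0.32, 0.30),
    v = c(0.52, 0.49, 0.53, 0.49, 0.52, 0.505, 0.53, 0.52)))
  base <- baseline_records(c("b1", "b1", "b1"))
  ill <- match_df(observer_id = sprintf("i%02d", seq_along(ill_chips)),
                  cube_name = "Ice blue", condition = "illumination",
                  view_booth = "A", match_booth = "B", chip_id = ill_chips)
  list(matches = rbind(base, ill), palette = pal)
}

test_that("per-cube index recovers the designed constancy level", {
  # reference = (0.30, 0.52); prediction = b1 in B = (0.25, 0.49);
  # phys = (-0.05, -0.03). Chip "full" sits at the prediction (mBR 1),
  # "none" at the reference (mBR 0), "half" midway (mBR 0.5).
  fx <- cross_booth_fixture(c("full", "full"))
  r <- mbr_per_cube("Ice blue", fx$matches, fx$palette, "illumination")
  expect_equal(r$mbr_mean, 1, tolerance = 1e-10)
  expect_equal(r$mbr_sem, 0, tolerance = 1e-10)
  expect_equal(r$ei, 0, tolerance = 1e-10)

  fx <- cross_booth_fixture(c("none", "none"))
  r <- mbr_per_cube("Ice blue", fx$matches, fx$palette, "illumination")
  expect_equal(r$mbr_mean, 0, tolerance = 1e-10)

  # one observer at the prediction, one at the reference
  fx <- cross_booth_fixture(c("full", "none"))
  r <- mbr_per_cube("Ice blue", fx$matches, fx$palette, "illumination")
  expect_equal(r$mbr_mean, 0.5, tolerance = 1e-10)
  expect_equal(r$mbr_sem, sd(c(1, 0)) / sqrt(2), tolerance = 1e-10)
  expect_equal(r$n_observers, 2L)

  # the average-match estimator agrees in the mean (linearity)
  r2 <- mbr_per_cube("Ice blue", fx$matches, fx$palette, "illumination",
                     estimator = "average")
  expect_equal(r2$mbr_mean, r$mbr_mean, tolerance = 1e-10)
})

test_that("per-observer index is invariant to common translation", {
  fx <- cross_booth_fixture(c("full", "none", "half"))
  r0 <- mbr_per_cube("Ice blue", fx$matches, fx$palette, "illumination")
  shifted <- fx$palette
  shifted$u <- shifted$u + 0.01
  shifted$v <- shifted$v - 0.02
  r1 <- mbr_per_cube("Ice blue", fx$matches, shifted, "illumination")
  expect_equal(r1$mbr_mean, r0$mbr_mean, tolerance = 1e-10)
  expect_equal(r1$mbr_sem, r0$mbr_sem, tolerance = 1e-10)
})

test_that("error index is a translated distance", {
  expect_equal(error_index(c(0.30, 0.54), c(0.33, 0.50)), 0.05)
  expect_equal(error_index(c(0.3, 0.5), c(0.3, 0.5)), 0)
  set.seed(22)
  for (i in 1:10) {
    a <- runif(2); b <- runif(2); off <- runif(2, -0.1, 0.1)
    expect_equal(error_index(a + off, b + off), error_index(a, b),
                 tolerance = 1e-12)
  }
})

test_that("split-half error: degenerate cases", {
  uv <- matrix(c(0.3, 0.3, 0.3, 0.5, 0.5, 0.5), ncol = 2)
  expect_equal(split_half_ei(uv, n_splits = 50), 0)
  two <- matrix(c(0.3, 0.4, 0.5, 0.5), ncol = 2)
  expect_equal(split_half_ei(two, n_splits = 50), 0.1, tolerance = 1e-12)
  expect_error(split_half_ei(two[1, , drop = FALSE]), "at least 2")
})

test_that("split-half error matches a large Monte-Carlo partition oracle", {
  set.seed(23)
  n <- 12
  uv <- cbind(rnorm(n, 0.30, 0.004), rnorm(n, 0.52, 0.004))
  # independent oracle: direct Monte Carlo over random equal partitions
  oracle <- local({
    set.seed(24)
    mean(vapply(seq_len(1e5), function(i) {
      g <- sample.int(n, n / 2)
      sqrt(sum((colMeans(uv[g, ]) - colMeans(uv[-g, ]))^2))
    }, numeric(1)))
  })
  est <- split_half_ei(uv, n_splits = 2e4, seed = 99)
  expect_equal(est, oracle, tolerance = 0.02)
})

test_that("split-half estimates are reproducible for a given seed", {
  uv <- cbind(runif(10, 0.2, 0.4), runif(10, 0.45, 0.55))
  expect_identical(split_half_ei(uv, 100, seed = 5),
                   split_half_ei(uv, 100, seed = 5))
})
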