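test_that("default synthetic palette replicates the physical book's layout", {
  pal <- gen_palette(simulation_config())
  chips <- unique(pal$chip_id)
  expect_length(chips, 1022L)
  expect_setequal(unique(pal$booth), c("A", "B"))
  sizes <- table(unique(pal[c("chip_id", "strip_id")])$strip_id)
  expect_true(all(sizes %in% c(7, 8)))
  expect_equal(sum(sizes), 1022)
  # every chip measured in both booths
  expect_true(all(table(pal$chip_id) == 2L))
})

test_that("palette generation is deterministic given the seed", {
  cfg <- simulation_config(seed = 17)
  expect_identical(gen_palette(cfg), gen_palette(cfg))
  cfg2 <- simulation_config(seed = 18)
  expect_false(identical(gen_palette(cfg), gen_palette(cfg2)))
})

test_that("impossible strip partitions are rejected", {
  expect_error(simulation_config(n_chips = 13), "partition")
  expect_error(simulation_config(n_chips = 9), "partition")
  # boundary: 42 is the smallest awkward-free region; 41 is not representable
  expect_error(simulation_config(n_chips = 41), "partition")
  expect_silent(simulation_config(n_chips = 42))
})

test_that("one large flat cluster approaches uniform disc counting", {
  cfg <- simulation_config(n_chips = 4088, n_clusters = 1, cluster_sd = 0.2,
                           seed = 3)
  pal <- gen_palette(cfg)
  sub <- pal[pal$booth == "A", ]
  # with sd >> box size the mixture is near-uniform over the clipped box
  # (minus boundary pile-up): disc counts scale with disc area
  ctr <- c(0.29, 0.50)
  n1 <- palette_density(pal, "A", ctr, 0.02)
  n2 <- palette_density(pal, "A", ctr, 0.04)
  brute <- sum(sqrt((sub$u - ctr[1])^2 + (sub$v - ctr[2])^2) <= 0.02)
  expect_equal(n1, brute)
  expect_gt(n2 / n1, 2.5)   # area ratio 4, attenuated by box clipping
})

test_that("the illuminant map fixes the white points and matches a matrix oracle", {
  illA <- c(u = 0.27, v = 0.53); illB <- c(u = 0.22, v = 0.50)
  expect_equal(unname(illuminant_map(illA, illA, illB)), unname(illB),
               tolerance = 1e-12)
  expect_equal(unname(illuminant_map(c(0.3, 0.52), illA, illA)),
               c(0.3, 0.52), tolerance = 1e-12)

  # independent oracle: hand-composed lift/scale/project matrices
  M <- matrix(c(0.38971, 0.68898, -0.07868,
                -0.22981, 1.18340, 0.04641,
                0, 0, 1), 3, 3, byrow = TRUE)
  lift <- function(uv) {
    den <- 6 * uv[1] - 16 * uv[2] + 12
    x <- 9 * uv[1] / den; y <- 4 * uv[2] / den
    c(x / y, 1, (1 - x - y) / y)
  }
  gains <- as.numeric(M %*% lift(illB)) / as.numeric(M %*% lift(illA))
  xyz <- solve(M) %*% (gains * as.numeric(M %*% lift(c(0.30, 0.52))))
  den <- xyz[1] + 15 * xyz[2] + 3 * xyz[3]
  oracle <- c(4 * xyz[1] / den, 9 * xyz[2] / den)
  expect_equal(unname(illuminant_map(c(0.30, 0.52), illA, illB)), oracle,
               tolerance = 1e-12)
})

test_that("noiseless observers at the adaptation limits pick the expected chips", {
  pal <- grid_palette(u = seq(0.14, 0.50, 0.004), v = seq(0.43, 0.59, 0.004))
  cube <- builtin_table2()[1, ]            # Ice blue, home booth A
  illA <- c(u = 0.27, v = 0.53); illB <- c(u = 0.22, v = 0.50)

  cfg1 <- simulation_config(alpha = 1, sigma = 0, sigma_cross = 0, seed = 5)
  set.seed(1)
  chip <- simulate_observer_match(cube, "illumination", pal, cfg1)
  uv <- pal[pal$chip_id == chip & pal$booth == "B", c("u", "v")]
  target <- illuminant_map(c(cube$u, cube$v), illA, illB)
  expect_lt(uv_distance(c(uv$u, uv$v), target), 0.006)  # ~one grid step

  cfg0 <- simulation_config(alpha = 0, sigma = 0, sigma_cross = 0, seed = 5)
  set.seed(1)
  chip <- simulate_observer_match(cube, "illumination", pal, cfg0)
  uv <- pal[pal$chip_id == chip & pal$booth == "B", c("u", "v")]
  expect_lt(uv_distance(c(uv$u, uv$v), c(cube$u, cube$v)), 0.004)
})

test_that("noiseless dense-palette pipeline recovers alpha exactly per cube", {
  # quantization is the only residual: with a fine grid palette and sigma = 0
  # every per-cube index equals alpha up to the grid step / shift ratio; the
  # grid extends past the stimulus range so its booth-B image still covers
  # every cube
  pal <- grid_palette(u = seq(0.14, 0.50, 0.002), v = seq(0.43, 0.59, 0.002))
  for (alpha in c(0, 0.5, 1)) {
    cfg <- simulation_config(alpha = alpha, sigma = 0, sigma_cross = 0,
                             n_observers = 8, seed = 2)
    sim <- gen_experiment(cfg, palette = pal)
    fit <- constancy_fit(sim$matches, pal, n_splits = 20, clean = FALSE)
    mbr <- fit$results$mbr_mean[fit$results$condition == "illumination"]
    expect_true(all(abs(mbr - alpha) < 0.08),
                info = sprintf("alpha = %.2f", alpha))
  }
})

test_that("experiments are deterministic and extend without reshuffling", {
  cfg <- simulation_config(n_observers = 10, seed = 9)
  s1 <- gen_experiment(cfg)
  s2 <- gen_experiment(cfg)
  expect_identical(s1$matches, s2$matches)
  bigger <- gen_experiment(simulation_config(n_observers = 12, seed = 9))
  expect_identical(s1$matches,
                   bigger$matches[bigger$matches$observer_id %in%
                                    unique(s1$matches$observer_id), ])
})

test_that("a generated experiment round-trips through the file formats", {
  dir <- withr::local_tempdir()
  sim <- gen_experiment(simulation_config(n_observers = 8, seed = 13))
  write_experiment(sim, dir)
  m <- load_matches(file.path(dir, "matches.csv"),
                    palette = read_palette(file.path(dir, "palette.csv")))
  expect_equal(nrow(m), 64L)
  cubes <- read_cubes(file.path(dir, "cubes.csv"))
  expect_equal(nrow(cubes), 16L)
  # one full counterbalance cycle: every cube once in each condition
  tab <- table(m$cube_name, m$condition)
  expect_true(all(tab == 1L))
})

test_that("match variability grows with sigma and is floored by quantization", {
  coarse <- grid_palette(u = seq(0.16, 0.44, 0.02), v = seq(0.44, 0.58, 0.02))
  fine <- grid_palette(u = seq(0.16, 0.44, 0.002),
                       v = seq(0.44, 0.58, 0.002))
  draw_var <- function(pal, sigma, cube) {
    cfg <- simulation_config(alpha = 0.9, sigma = sigma, sigma_cross = 0,
                             seed = 21)
    chips <- replicate(40, simulate_observer_match(cube, "baseline", pal,
                                                   cfg))
    sub <- pal[pal$booth == cube$booth, ]
    uv <- cbind(sub$u[match(chips, sub$chip_id)],
                sub$v[match(chips, sub$chip_id)])
    variability(uv)
  }
  cube <- builtin_table2()[2, ]
  set.seed(77)
  v_fine <- vapply(c(0.002, 0.006, 0.012),
                   function(s) draw_var(fine, s, cube), numeric(1))
  expect_true(all(diff(v_fine) > 0))
  # snapping to a coarser response scale adds quantization variance: summed
  # over cubes (averaging over grid phase), coarse > fine at fixed sigma
  t2 <- builtin_table2()
  set.seed(78)
  v_coarse_sum <- sum(vapply(1:8, function(k)
    draw_var(coarse, 0.015, t2[k, ]), numeric(1)))
  set.seed(78)
  v_fine_sum <- sum(vapply(1:8, function(k)
    draw_var(fine, 0.015, t2[k, ]), numeric(1)))
  expect_gt(v_coarse_sum, v_fine_sum)
})
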