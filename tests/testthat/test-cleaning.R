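# One observer's 8 assigned records with a controllable number of missing
# chips (grid_palette chip ids are valid in both booths).
one_observer <- function(id, n_missing = 0, wrong_location = FALSE) {
  d <- design_assignment(1)
  chips <- sprintf("g%04d", 1:8)
  if (n_missing > 0) chips[seq_len(n_missing)] <- NA
  match_df(observer_id = id, cube_name = d$cube, condition = d$condition,
           view_booth = d$view_booth, match_booth = d$match_booth,
           chip_id = chips, wrong_location = wrong_location)
}

test_that("observers missing strictly more than half their cubes are dropped", {
  m <- rbind(one_observer("a", n_missing = 5),
             one_observer("b", n_missing = 4),
             one_observer("c", n_missing = 0))
  out <- discard_observers(m)
  expect_equal(sort(unique(out$matches$observer_id)), c("b", "c"))
  expect_equal(unname(out$report["n_observers_in"]), 3)
  expect_equal(unname(out$report["n_observers_discarded"]), 1)
})

test_that("the wrong-location study flag discards the whole observer", {
  m <- rbind(one_observer("a", wrong_location = TRUE), one_observer("b"))
  out <- discard_observers(m)
  expect_equal(unique(out$matches$observer_id), "b")
})

test_that("wrong-category discards require both raters to agree", {
  pal <- grid_palette()
  m <- one_observer("a")
  m$rater1_wrong_category[1] <- TRUE                 # one rater: retained
  m$rater1_wrong_category[2] <- TRUE                 # both raters: discarded
  m$rater2_wrong_category[2] <- TRUE
  out <- discard_trials(m, pal)
  expect_true(m$cube_name[1] %in% out$matches$cube_name)
  expect_false(m$cube_name[2] %in% out$matches$cube_name)
  expect_equal(unname(out$report["wrong_category"]), 1)
})

test_that("chips without radiometry in the match booth are discarded", {
  pal <- grid_palette()
  m <- one_observer("a")
  # chip measured only in booth A, chosen in a booth-B match
  brow <- which(m$match_booth == "B")[1]
  pal2 <- rbind(pal, data.frame(chip_id = "onlyA", strip_id = "s001",
                                booth = "A", u = 0.3, v = 0.5, Y = NA))
  m$chip_id[brow] <- "onlyA"
  out <- discard_trials(m, pal2)
  expect_equal(unname(out$report["missing_radiometry"]), 1)
  expect_false("onlyA" %in% out$matches$chip_id)
})

test_that("cleaning conserves counts and is idempotent", {
  pal <- grid_palette()
  m <- rbind(one_observer("a", n_missing = 5), one_observer("b"),
             one_observer("c", n_missing = 2))
  m$rater1_wrong_category[9] <- m$rater2_wrong_category[9] <- TRUE
  out1 <- clean_matches(m, pal)
  rep <- out1$report
  expect_equal(rep$n_trials_out,
               rep$n_trials_in - sum(rep$n_trials_discarded_by_reason))
  out2 <- clean_matches(out1$matches, pal)
  expect_equal(out2$matches, out1$matches)
  expect_equal(out2$report$n_trials_out, out2$report$n_trials_in)
})

test_that("surrogate rater flags only hue differences beyond adjacent sectors", {
  illA <- c(u = 0.27, v = 0.53)
  r <- 0.05
  mk_chip <- function(id, ang_deg) {
    a <- ang_deg * pi / 180
    data.frame(chip_id = id, booth = "A",
               u = illA[1] + r * cos(a), v = illA[2] + r * sin(a))
  }
  # cube displaced from the white point at 0 degrees
  cube <- builtin_table2()[1, ]
  cube$u <- illA[1] + r; cube$v <- illA[2]
  pal <- tiny_palette(rbind(mk_chip("same", 0), mk_chip("opp", 180),
                            mk_chip("near", 30), mk_chip("edge", 89),
                            mk_chip("far", 91)))
  m <- match_df(observer_id = "o1", cube_name = cube$cube,
                condition = "baseline", view_booth = "A", match_booth = "A",
                chip_id = c("same", "opp", "near", "edge", "far"))
  m$observer_id <- sprintf("o%d", 1:5)   # avoid duplicate (observer, cube)
  flags <- surrogate_category_rater(m, pal, cubes = cube, sector_width = 45)
  expect_identical(flags, c(FALSE, TRUE, FALSE, FALSE, TRUE))
})

test_that("a chip at the white point is never flagged", {
  illA <- c(u = 0.27, v = 0.53)
  cube <- builtin_table2()[1, ]
  cube$u <- illA[1] + 0.05; cube$v <- illA[2]
  pal <- tiny_palette(data.frame(chip_id = "white", booth = "A",
                                 u = illA[1], v = illA[2]))
  m <- match_df(observer_id = "o1", cube_name = cube$cube,
                condition = "baseline", view_booth = "A", match_booth = "A",
                chip_id = "white")
  expect_false(surrogate_category_rater(m, pal, cubes = cube))
})
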