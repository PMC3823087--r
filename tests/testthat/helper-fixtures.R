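# Fixtures are built in code: small palettes, hand-rolled match records, and
# design-complete experiments at reduced observer counts.

# A palette laid out on a regular grid in booth A, with booth B coordinates
# produced by the same von-Kries map the generator uses. Strip ids are
# assigned in runs of 7 so the strip-size invariant holds.
grid_palette <- function(u = seq(0.18, 0.42, by = 0.01),
                         v = seq(0.46, 0.58, by = 0.01)) {
  g <- expand.grid(u = u, v = v, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(g)
  pad <- (7 - n %% 7) %% 7
  strip <- sprintf("s%03d", rep(seq_len(ceiling(n / 7)), each = 7))[seq_len(n)]
  chip <- sprintf("g%04d", seq_len(n))
  illA <- c(0.27, 0.53); illB <- c(0.22, 0.50)
  uvB <- t(vapply(seq_len(n), function(i)
    illuminant_map(c(g$u[i], g$v[i]), illA, illB), numeric(2)))
  rbind(data.frame(chip_id = chip, strip_id = strip, booth = "A",
                   u = g$u, v = g$v, Y = NA_real_),
        data.frame(chip_id = chip, strip_id = strip, booth = "B",
                   u = uvB[, 1], v = uvB[, 2], Y = NA_real_))
}

# Minimal match-record constructor with all flag columns defaulting FALSE.
match_df <- function(observer_id, cube_name, condition, view_booth,
                     match_booth, chip_id,
                     indecipherable = FALSE, missing_radiometry = FALSE,
                     rater1_wrong_category = FALSE,
                     rater2_wrong_category = FALSE, wrong_location = FALSE) {
  data.frame(observer_id = observer_id,
             trial_index = ifelse(condition %in% c("baseline", "background"),
                                  1L, 2L),
             cube_name = cube_name, condition = condition,
             view_booth = view_booth, match_booth = match_booth,
             chip_id = chip_id, indecipherable = indecipherable,
             missing_radiometry = missing_radiometry,
             rater1_wrong_category = rater1_wrong_category,
             rater2_wrong_category = rater2_wrong_category,
             wrong_location = wrong_location,
             stringsAsFactors = FALSE)
}

# Baseline-style records for one cube: each observer chose the given chip.
baseline_records <- function(chips, cube = "Ice blue", booth = "A") {
  match_df(observer_id = sprintf("o%03d", seq_along(chips)),
           cube_name = cube, condition = "baseline",
           view_booth = booth, match_booth = booth, chip_id = chips)
}

# A two-chip palette with explicit coordinates per booth, for hand-arithmetic
# oracles (strip sizes intentionally valid: one strip of 7 padded chips).
tiny_palette <- function(coords) {
  # coords: data.frame(chip_id, booth, u, v)
  ids <- unique(coords$chip_id)
  pad_n <- max(0L, 7L - length(ids))
  pad <- if (pad_n > 0) {
    pid <- sprintf("pad%02d", seq_len(pad_n))
    do.call(rbind, lapply(c("A", "B"), function(b)
      data.frame(chip_id = pid, booth = b, u = 0.60, v = 0.58)))
  } else NULL
  out <- rbind(coords[c("chip_id", "booth", "u", "v")], pad)
  out$strip_id <- "s001"
  out$Y <- NA_real_
  out[c("chip_id", "strip_id", "booth", "u", "v", "Y")]
}
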