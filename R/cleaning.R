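# Observer- and trial-level discard rules with a conservation-checked audit
# trail. Rules mirror the study protocol: observers are dropped wholesale for
# task failure; single trials are dropped for unusable notation, missing
# radiometry, or a wrong-category judgment by both independent raters.

#' Apply observer-level discard rules
#'
#' Removes every record of observers who failed the task: either no chip
#' recorded for strictly more than half of their assigned cubes, or a
#' study-supplied flag for systematically recording cube color in the wrong
#' location. Exactly half missing is retained.
#'
#' @param matches Match record data frame (see [load_matches()]).
#' @return List with `matches` (retained records) and `report` (named counts:
#'   `n_observers_in`, `n_observers_discarded`).
#' @export
discard_observers <- function(matches) {
  obs <- split(matches, matches$observer_id)
  drop <- vapply(obs, function(d) {
    sum(is.na(d$chip_id)) * 2L > nrow(d) || any(d$wrong_location)
  }, logical(1))
  keep_ids <- names(obs)[!drop]
  list(matches = matches[matches$observer_id %in% keep_ids, , drop = FALSE],
       report = c(n_observers_in = length(obs),
                  n_observers_discarded = sum(drop)))
}

#' Apply trial-level discard rules
#'
#' Assumes observer-level cleaning has already run. Each surviving trial is
#' tested against three reasons, in order, and counted under the first that
#' applies: (1) indecipherable or missing chip notation; (2) no radiometric
#' measurement for the chosen chip in the matching booth (flagged in the data
#' or absent from the palette); (3) judged a clearly-different, non-adjacent
#' color category by \emph{both} raters — a single rater's flag never
#' discards a match.
#'
#' @param matches Match record data frame.
#' @param palette Palette table used to check chip radiometry per booth.
#' @return List with `matches` (retained records) and `report` (named counts
#'   per reason plus totals).
#' @export
discard_trials <- function(matches, palette) {
  n_in <- nrow(matches)
  indec <- matches$indecipherable | is.na(matches$chip_id)
  in_pal <- !is.na(matches$chip_id) &
    paste(matches$chip_id, matches$match_booth) %in%
      paste(palette$chip_id, palette$booth)
  norad <- !indec & (matches$missing_radiometry | !in_pal)
  wrong <- !indec & !norad &
    matches$rater1_wrong_category & matches$rater2_wrong_category
  keep <- !(indec | norad | wrong)
  list(matches = matches[keep, , drop = FALSE],
       report = c(n_trials_in = n_in,
                  indecipherable_or_missing = sum(indec),
                  missing_radiometry = sum(norad),
                  wrong_category = sum(wrong),
                  n_trials_out = sum(keep)))
}

#' Run the full cleaning stage
#'
#' Observer-level rules first, then trial-level rules, with an audit report
#' that conserves counts at each level.
#'
#' @param matches Match record data frame.
#' @param palette Palette table.
#' @return List with `matches` and a `cleaning_report` object.
#' @export
clean_matches <- function(matches, palette) {
  o <- discard_observers(matches)
  t <- discard_trials(o$matches, palette)
  rep <- structure(list(
    n_observers_in = unname(o$report["n_observers_in"]),
    n_observers_discarded = unname(o$report["n_observers_discarded"]),
    n_trials_in = unname(t$report["n_trials_in"]),
    n_trials_discarded_by_reason = c(
      indecipherable_or_missing = unname(t$report["indecipherable_or_missing"]),
      missing_radiometry = unname(t$report["missing_radiometry"]),
      wrong_category = unname(t$report["wrong_category"])),
    n_trials_out = unname(t$report["n_trials_out"])),
    class = "cleaning_report")
  stopifnot(rep$n_trials_out ==
              rep$n_trials_in - sum(rep$n_trials_discarded_by_reason))
  list(matches = t$matches, report = rep)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report\n")
  cat(sprintf("  observers: %d in, %d discarded, %d retained\n",
              x$n_observers_in, x$n_observers_discarded,
              x$n_observers_in - x$n_observers_discarded))
  cat(sprintf("  trials:    %d in, %d retained\n",
              x$n_trials_in, x$n_trials_out))
  r <- x$n_trials_discarded_by_reason
  for (nm in names(r))
    cat(sprintf("    - %-26s %4d (%.0f%%)\n", nm, r[nm],
                100 * r[nm] / max(x$n_trials_in, 1L)))
  invisible(x)
}

#' @rdname clean_matches
#' @param report A `cleaning_report` object.
#' @param path Output path for a JSON serialisation of the report.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Automated stand-in for the human category raters
#'
#' In real-data mode the two wrong-category judgments are inputs recorded by
#' human raters and are never computed. This surrogate exists so synthetic
#' pipelines can exercise the discard path: a match is flagged when the hue
#' angle of (chip - illuminant white point) differs from the hue angle of
#' (cube - illuminant white point) by more than one full hue sector beyond
#' adjacency, i.e. by more than twice `sector_width`. A chip lying exactly at
#' the white point has no hue and is never flagged.
#'
#' @param matches Match record data frame.
#' @param palette Palette table (chips must be measured in each match booth).
#' @param cubes Cube stimulus table, defaults to [builtin_table2()].
#' @param sector_width Hue sector width in degrees, default 45.
#' @return Logical vector, one flag per record.
#' @export
surrogate_category_rater <- function(matches, palette,
                                     cubes = builtin_table2(),
                                     sector_width = 45) {
  stopifnot(sector_width > 0)
  ci <- match(matches$cube_name, cubes$cube)
  if (anyNA(ci)) stop("unknown cube in matches")
  n <- nrow(matches)
  flag <- logical(n)
  for (k in seq_len(n)) {
    if (is.na(matches$chip_id[k])) next
    booth <- matches$match_booth[k]
    wp <- .illum_uv(booth)
    cube_uv <- c(cubes$u[ci[k]], cubes$v[ci[k]])
    if (cubes$booth[ci[k]] != booth)
      cube_uv <- illuminant_map(cube_uv, .illum_uv(cubes$booth[ci[k]]), wp)
    chip_uv <- .chip_uv(palette, matches$chip_id[k], booth)[1, ]
    dc <- chip_uv - wp
    dq <- cube_uv - wp
    if (sum(dc^2) == 0 || sum(dq^2) == 0) next
    ang <- abs(atan2(dc[2], dc[1]) - atan2(dq[2], dq[1])) * 180 / pi
    ang <- min(ang, 360 - ang)
    flag[k] <- ang > 2 * sector_width
  }
  flag
}
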