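# Experimental design and data model: booths, palette, cube stimuli, match
# records, and the delimited-text readers/writers for each.

.conditions <- c("baseline", "background", "illumination", "joint")
.flag_cols <- c("indecipherable", "missing_radiometry",
                "rater1_wrong_category", "rater2_wrong_category",
                "wrong_location")

#' Booth illuminant chromaticities
#'
#' The two viewing booths are lit by incandescent-like sources of different
#' correlated color temperature: booth A around 2600 K, booth B around
#' 4000 K, with the u'v' white points measured off a reflectance standard.
#'
#' @return Data frame with columns `booth`, `u`, `v`.
#' @export
booth_illuminants <- function() {
  data.frame(booth = c("A", "B"), u = c(0.27, 0.22), v = c(0.53, 0.50))
}

.illum_uv <- function(booth) {
  b <- booth_illuminants()
  i <- match(booth, b$booth)
  if (anyNA(i)) stop("unknown booth: ", booth)
  c(u = b$u[i], v = b$v[i])
}

#' The 16 cube stimuli and their paired backgrounds
#'
#' The built-in stimulus table: sixteen painted cubes spanning color space,
#' each measured (u', v', luminance in cd/m^2) in the booth where it was
#' presented, and each paired with one of eight 3D backgrounds chosen to be
#' approximately color-opponent. Every background serves exactly two cubes.
#'
#' @return Data frame with columns `cube`, `booth`, `u`, `v`, `Y`,
#'   `background`, `bg_u`, `bg_v`, `bg_Y`.
#' @export
builtin_table2 <- function() {
  d <- data.frame(
    cube = c("Ice blue", "Dull green", "Orange", "Dark brown", "Dark green",
             "Plum", "Peach", "Purple", "Gold", "Aqua", "Gray", "Red",
             "Yellow", "Doeskin", "Secure blue", "Pink"),
    booth = c("A", "A", "B", "B", "A", "A", "B", "B",
              "A", "A", "B", "B", "A", "A", "B", "B"),
    u = c(0.27, 0.25, 0.36, 0.32, 0.23, 0.30, 0.31, 0.30,
          0.30, 0.24, 0.28, 0.42, 0.30, 0.29, 0.24, 0.38),
    v = c(0.53, 0.54, 0.54, 0.54, 0.54, 0.53, 0.54, 0.52,
          0.54, 0.53, 0.54, 0.53, 0.55, 0.53, 0.52, 0.53),
    Y = c(62.54, 21.77, 45.06, 16.61, 13.74, 13.48, 59.50, 28.01,
          41.82, 67.15, 48.80, 19.93, 71.38, 48.75, 19.69, 36.15),
    background = c("Red", "Dull blue", "Surf green", "Yellow", "Red",
                   "Dull blue", "Surf green", "Yellow", "Purple",
                   "Hyper blue", "Peach", "Green", "Purple", "Hyper blue",
                   "Peach", "Green"),
    bg_u = c(0.43, 0.23, 0.22, 0.30, 0.43, 0.23, 0.22, 0.30,
             0.29, 0.17, 0.35, 0.14, 0.29, 0.17, 0.35, 0.14),
    bg_v = c(0.53, 0.51, 0.53, 0.55, 0.53, 0.51, 0.53, 0.55,
             0.51, 0.46, 0.54, 0.55, 0.51, 0.46, 0.54, 0.55),
    bg_Y = c(14.27, 7.19, 12.01, 58.64, 14.27, 7.19, 12.01, 58.64,
             18.47, 3.62, 32.38, 5.62, 18.47, 3.62, 32.38, 5.62))
  d
}

#' Counterbalanced trial design for one observer
#'
#' Each observer contributes eight matches: two trials of four cubes each
#' (two per booth), one cube per booth embedded in its background per trial.
#' Trial 1 is matched within-booth (baseline and background conditions);
#' trial 2 across booths (illumination and joint). The counterbalance cycles
#' over 8 observers so that every cube is seen in every condition once per
#' cycle, and no observer ever sees the same cube in two conditions.
#'
#' @param observer_index Positive integer; positions `1..8` form one full
#'   counterbalance cycle, after which the scheme repeats.
#' @param scheme Counterbalance scheme as produced by
#'   [default_counterbalance()]; a list with an integer vector `half` (which
#'   half of each booth's cube group an observer draws from) and a character
#'   matrix `cond` (the condition permutation applied to the four drawn cubes).
#' @param cubes Stimulus table, defaults to [builtin_table2()].
#' @return Data frame with one row per match: `cube`, `condition`,
#'   `trial_index`, `view_booth`, `match_booth`.
#' @export
design_assignment <- function(observer_index,
                              scheme = default_counterbalance(),
                              cubes = builtin_table2()) {
  stopifnot(length(observer_index) == 1L, observer_index >= 1)
  .validate_scheme(scheme)
  pos <- ((observer_index - 1L) %% nrow(scheme$cond)) + 1L
  half <- scheme$half[pos]
  conds <- scheme$cond[pos, ]
  out <- lapply(c("A", "B"), function(b) {
    grp <- cubes$cube[cubes$booth == b]
    if (length(grp) != 8L) stop("each booth must have 8 home cubes")
    sel <- grp[(half - 1L) * 4L + 1:4]
    data.frame(cube = sel, condition = conds, view_booth = b,
               match_booth = ifelse(conds %in% c("baseline", "background"),
                                    b, setdiff(c("A", "B"), b)))
  })
  out <- do.call(rbind, out)
  out$trial_index <- ifelse(out$condition %in% c("baseline", "background"),
                            1L, 2L)
  if (anyDuplicated(out$cube))
    stop("invalid scheme: a cube is shown twice to one observer")
  out[order(out$trial_index, out$view_booth), c("cube", "condition",
      "trial_index", "view_booth", "match_booth")]
}

#' @rdname design_assignment
#' @export
default_counterbalance <- function() {
  half <- rep(c(1L, 2L), 4)
  rot <- rep(0:3, each = 2)
  cond <- t(vapply(rot, function(r) .conditions[((seq_len(4) - 1 + r) %% 4) + 1],
                   character(4)))
  list(half = half, cond = cond)
}

.validate_scheme <- function(scheme) {
  if (!is.list(scheme) || !all(c("half", "cond") %in% names(scheme)))
    stop("scheme must be a list with elements 'half' and 'cond'")
  if (!all(scheme$half %in% c(1L, 2L)))
    stop("scheme$half entries must be 1 or 2")
  ok <- apply(scheme$cond, 1, function(r) setequal(r, .conditions))
  if (!all(ok))
    stop("invalid scheme: each row of scheme$cond must be a permutation of ",
         "the four conditions (a repeat would show one cube twice or ",
         "unbalance conditions)")
  invisible(TRUE)
}

#' Read and validate match records
#'
#' Parses a delimited text file of observer match records and enforces the
#' design invariants row by row: known condition tokens, within-booth viewing
#' and matching for baseline/background, cross-booth for illumination/joint,
#' no duplicated (observer, cube) pair, and (when a palette is supplied)
#' known chip ids. Rater/validity flag columns are optional and default to
#' `FALSE`; a missing `chip_id` is legal and handled by the cleaning stage.
#'
#' @param path Path to a delimited text file with header columns
#'   `observer_id`, `trial_index`, `cube_name`, `condition`, `view_booth`,
#'   `match_booth`, `chip_id`, and optionally the logical flag columns
#'   `indecipherable`, `missing_radiometry`, `rater1_wrong_category`,
#'   `rater2_wrong_category`, `wrong_location`.
#' @param palette Optional palette table (see [read_palette()]); if given,
#'   non-missing chip ids must appear in it.
#' @param sep Field separator, default comma.
#' @return Data frame of match records with all flag columns present.
#' @export
load_matches <- function(path, palette = NULL, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = NA, stringsAsFactors = FALSE)
  need <- c("observer_id", "trial_index", "cube_name", "condition",
            "view_booth", "match_booth", "chip_id")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("matches file lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) {
    warning("matches file contains a header but no records")
    for (f in .flag_cols) d[[f]] <- logical(0)
    return(d)
  }
  d$observer_id <- as.character(d$observer_id)
  d$cube_name <- as.character(d$cube_name)
  d$chip_id <- as.character(d$chip_id)
  d$chip_id[d$chip_id %in% c("", "NA")] <- NA_character_
  for (f in .flag_cols)
    d[[f]] <- if (f %in% names(d)) as.logical(d[[f]]) else FALSE
  bad <- which(!d$condition %in% .conditions)
  if (length(bad))
    stop("row ", bad[1], ": unknown condition '", d$condition[bad[1]], "'")
  same <- d$view_booth == d$match_booth
  want_same <- d$condition %in% c("baseline", "background")
  bad <- which(same != want_same)
  if (length(bad))
    stop("row ", bad[1], ": condition '", d$condition[bad[1]],
         "' is inconsistent with view/match booths ",
         d$view_booth[bad[1]], "/", d$match_booth[bad[1]])
  key <- paste(d$observer_id, d$cube_name)
  bad <- which(duplicated(key))
  if (length(bad))
    stop("row ", bad[1], ": duplicate (observer, cube) pair ", key[bad[1]])
  if (!is.null(palette)) {
    known <- unique(palette$chip_id)
    bad <- which(!is.na(d$chip_id) & !d$chip_id %in% known)
    if (length(bad))
      stop("row ", bad[1], ": unknown chip_id '", d$chip_id[bad[1]], "'")
  }
  d
}

#' @rdname load_matches
#' @param matches Match record data frame.
#' @export
write_matches <- function(matches, path, sep = ",") {
  utils::write.table(matches, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read or write a palette table
#'
#' A palette row gives one chip's chromaticity measured in one booth:
#' `chip_id,strip_id,booth,u,v,Y`. The same physical chip appears once per
#' booth because its reflected light differs under the two illuminants.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator, default comma.
#' @return Data frame with the columns above.
#' @export
read_palette <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("chip_id", "strip_id", "booth", "u", "v")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("palette file lacks columns: ", paste(miss, collapse = ", "))
  d$chip_id <- as.character(d$chip_id)
  d$strip_id <- as.character(d$strip_id)
  if (!"Y" %in% names(d)) d$Y <- NA_real_
  .validate_palette(d)
  d
}

#' @rdname read_palette
#' @param palette Palette data frame.
#' @export
write_palette <- function(palette, path, sep = ",") {
  utils::write.table(palette, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.validate_palette <- function(palette) {
  key <- paste(palette$chip_id, palette$booth)
  if (anyDuplicated(key))
    stop("palette has duplicated (chip_id, booth) rows")
  sizes <- table(unique(palette[c("chip_id", "strip_id")])$strip_id)
  if (length(sizes) && !all(sizes %in% c(7L, 8L)))
    stop("palette strips must contain 7 or 8 chips")
  invisible(TRUE)
}

#' Read or write a cube stimulus table
#'
#' Mirrors the built-in stimulus table layout (see [builtin_table2()]).
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator, default comma.
#' @return Data frame of cube stimuli.
#' @export
read_cubes <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("cube", "booth", "u", "v", "background", "bg_u", "bg_v")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cube file lacks columns: ", paste(miss, collapse = ", "))
  d
}

#' @rdname read_cubes
#' @param cubes Cube stimulus data frame.
#' @export
write_cubes <- function(cubes, path, sep = ",") {
  utils::write.table(cubes, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Chromaticity lookup: (u, v) matrix for chip ids measured in one booth.
# Errors name the first chip that lacks a measurement in that booth.
.chip_uv <- function(palette, chip_ids, booth) {
  sub <- palette[palette$booth == booth, ]
  i <- match(chip_ids, sub$chip_id)
  if (anyNA(i)) {
    missing_chip <- chip_ids[which(is.na(i))[1]]
    stop("chip '", missing_chip, "' has no measurement in booth ", booth)
  }
  cbind(u = sub$u[i], v = sub$v[i])
}
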