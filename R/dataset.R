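#' Fixation dataset
#'
#' A `gc_dataset` bundles a fixation table with the face layouts the
#' fixations refer to. The fixation table has one row per fixation with
#' columns `participant_id`, `phase` (`"study"`/`"test"`), `trial_index`,
#' `face_id`, `race`, `start_position`, `was_studied` (test phase only),
#' `ordinal` (1 = first fixation after stimulus onset), `x_deg`, `y_deg`,
#' `duration_ms`, and — on test-phase rows — the trial response `judgment`
#' (`"old"`/`"new"`) and `rt_ms`. Construction validates the full data
#' model: ordinals within a trial must be consecutive starting at 1,
#' responses must be present exactly on test trials, and every `face_id`
#' must have a layout of the matching race. Fixations landing outside the
#' face frame are kept and flagged in the derived `in_frame` column.
#'
#' @param fixations Data frame of fixation rows (see Details).
#' @param layouts Named list of [face_layout()] objects.
#' @return A `gc_dataset` with elements `fixations`, `trials` (one row per
#'   trial, with the response), and `layouts`.
#' @export
gc_dataset <- function(fixations, layouts) {
  fixations <- validate_fixation_table(fixations, layouts)
  trials <- derive_trials(fixations)
  structure(list(fixations = fixations, trials = trials, layouts = layouts),
            class = "gc_dataset")
}

#' @export
print.gc_dataset <- function(x, ...) {
  cat(sprintf(paste0("<gc_dataset> %d fixations, %d trials, %d participants, ",
                     "%d face layouts\n"),
              nrow(x$fixations), nrow(x$trials),
              length(unique(x$fixations$participant_id)), length(x$layouts)))
  invisible(x)
}

FIX_COLS <- c("participant_id", "phase", "trial_index", "face_id", "race",
              "start_position", "was_studied", "ordinal", "x_deg", "y_deg",
              "duration_ms", "judgment", "rt_ms")

validate_fixation_table <- function(fix, layouts) {
  miss <- setdiff(setdiff(FIX_COLS, c("judgment", "rt_ms", "was_studied")),
                  names(fix))
  if (length(miss))
    stop("fixation table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(fix$judgment)) fix$judgment <- NA_character_
  if (is.null(fix$rt_ms)) fix$rt_ms <- NA_real_
  if (is.null(fix$was_studied)) fix$was_studied <- NA

  fix$participant_id <- as.character(fix$participant_id)
  fix$face_id <- as.character(fix$face_id)
  fix$judgment <- as.character(fix$judgment)
  fix$was_studied <- as.logical(fix$was_studied)
  fix$trial_index <- as.integer(fix$trial_index)
  fix$ordinal <- as.integer(fix$ordinal)

  if (!all(fix$phase %in% c("study", "test")))
    stop("invalid phase label; must be 'study' or 'test'")
  if (!all(fix$race %in% RACES))
    stop("invalid race label; must be one of: ", paste(RACES, collapse = ", "))
  if (!all(fix$start_position %in% START_POSITIONS))
    stop("invalid start_position label")
  if (any(!is.finite(fix$x_deg)) || any(!is.finite(fix$y_deg)))
    stop("non-finite fixation coordinates")
  if (any(!is.finite(fix$duration_ms)) || any(fix$duration_ms <= 0))
    stop("fixation durations must be positive")
  if (any(!is.finite(fix$trial_index)) || any(fix$trial_index < 1L))
    stop("trial_index must be a positive integer")

  unknown <- setdiff(unique(fix$face_id), names(layouts))
  if (length(unknown))
    stop("unknown face_id (no layout): ", paste(unknown, collapse = ", "))
  lay_race <- vapply(layouts, `[[`, "", "race")
  if (!all(fix$race == lay_race[fix$face_id]))
    stop("fixation race label disagrees with the face layout's race")

  key <- interaction(fix$participant_id, fix$phase, fix$trial_index, drop = TRUE)
  ord_ok <- tapply(fix$ordinal, key, function(o) {
    identical(sort(o), seq_along(o)) && !anyDuplicated(o)
  })
  if (!all(ord_ok))
    stop("ordinal gap: ordinals within each trial must be consecutive from 1")

  # trial-level fields must be constant within a trial
  for (cc in c("face_id", "race", "start_position", "was_studied",
               "judgment", "rt_ms")) {
    n_distinct <- tapply(fix[[cc]], key, function(v) length(unique(v)))
    if (any(n_distinct > 1L))
      stop(sprintf("column '%s' varies within a trial", cc))
  }

  is_test <- fix$phase == "test"
  if (any(is.na(fix$judgment[is_test])) || any(is.na(fix$rt_ms[is_test])))
    stop("test-phase trials must carry a response (judgment and rt_ms)")
  if (any(is.na(fix$was_studied[is_test])))
    stop("test-phase trials must record was_studied")
  if (any(!is.na(fix$judgment[!is_test])) || any(!is.na(fix$rt_ms[!is_test])))
    stop("study-phase trials must not carry a response")
  if (!all(fix$judgment[is_test] %in% c("old", "new")))
    stop("judgment must be 'old' or 'new'")
  if (any(fix$rt_ms[is_test] <= 0))
    stop("response rt_ms must be positive")

  frames <- do.call(rbind, lapply(layouts, `[[`, "frame"))
  fr <- frames[fix$face_id, , drop = FALSE]
  fix$in_frame <- fix$x_deg >= fr[, "x0"] & fix$x_deg < fr[, "x1"] &
    fix$y_deg >= fr[, "y0"] & fix$y_deg < fr[, "y1"]

  o <- order(fix$participant_id, fix$phase, fix$trial_index, fix$ordinal)
  fix <- fix[o, c(FIX_COLS, "in_frame")]
  rownames(fix) <- NULL
  fix
}

derive_trials <- function(fix) {
  first <- !duplicated(fix[c("participant_id", "phase", "trial_index")])
  tr <- fix[first, c("participant_id", "phase", "trial_index", "face_id",
                     "race", "start_position", "was_studied", "judgment",
                     "rt_ms")]
  key <- interaction(fix$participant_id, fix$phase, fix$trial_index, drop = TRUE)
  tr$n_fix <- as.integer(stats::ave(fix$ordinal, key, FUN = length))[first]
  rownames(tr) <- NULL
  tr
}

#' Read and write fixation report tables
#'
#' `read_fixations()` parses a UTF-8 tab-separated fixation report (columns
#' as described in [gc_dataset()]; `was_studied`, `judgment` and `rt_ms`
#' empty on study-phase rows) and validates it against the given layouts.
#' `write_fixations()` writes the inverse dialect with rows sorted by
#' participant, phase, trial and ordinal; `read_fixations()` on its output
#' reproduces the dataset field-for-field.
#'
#' @param path File path of the tab-separated fixation report.
#' @param layouts Named list of [face_layout()] objects (e.g. from
#'   [read_aois()]).
#' @return `read_fixations()` returns a validated `gc_dataset`.
#' @export
read_fixations <- function(path, layouts) {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    stringsAsFactors = FALSE, na.strings = NULL)
  miss <- setdiff(FIX_COLS, names(tab))
  if (length(miss))
    stop("fixation report is missing column(s): ", paste(miss, collapse = ", "))
  num_cols <- c("trial_index", "ordinal", "x_deg", "y_deg", "duration_ms", "rt_ms")
  for (cc in num_cols) {
    raw <- tab[[cc]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & nzchar(raw))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s' at line %d",
                   raw[bad[1]], cc, bad[1] + 1L))
    tab[[cc]] <- v
  }
  tab$judgment[!nzchar(tab$judgment)] <- NA_character_
  tab$was_studied <- ifelse(nzchar(tab$was_studied),
                            tab$was_studied == "TRUE", NA)
  gc_dataset(tab, layouts)
}

#' @rdname read_fixations
#' @param ds A `gc_dataset`.
#' @export
write_fixations <- function(ds, path) {
  fix <- ds$fixations[, FIX_COLS]
  fix$was_studied <- ifelse(is.na(fix$was_studied), "",
                            ifelse(fix$was_studied, "TRUE", "FALSE"))
  fix$judgment[is.na(fix$judgment)] <- ""
  out <- format_num_df(fix)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Select the analyzed fixation window of each trial
#'
#' Applies the per-phase analysis window. The default study-phase rule keeps
#' ordinal fixations 2 through 5: trials are truncated at the fifth fixation
#' so every trial contributes the same amount of data, and the first fixation
#' is excluded because it is systematically shorter and tied to the
#' pre-stimulus start position rather than to face encoding. The
#' `"study_1_5"` variant keeps fixations 1-5. The test-phase rule keeps every
#' fixation whose onset falls within the 1-second stimulus presentation,
#' where a fixation's onset is the summed duration of the preceding
#' fixations of its trial.
#'
#' @param fixations A fixation table (`ds$fixations`) or a `gc_dataset`.
#' @param rule One of `"study_2_5"` (default), `"study_1_5"`, `"test_1s"`.
#' @param display_ms Test-phase display duration in ms (default 1000).
#' @return The windowed fixation table.
#' @export
window_fixations <- function(fixations, rule = c("study_2_5", "study_1_5", "test_1s"),
                             display_ms = 1000) {
  rule <- match.arg(rule)
  fix <- if (inherits(fixations, "gc_dataset")) fixations$fixations else fixations
  if (rule == "study_2_5") {
    fix[fix$phase == "study" & fix$ordinal >= 2L & fix$ordinal <= 5L, , drop = FALSE]
  } else if (rule == "study_1_5") {
    fix[fix$phase == "study" & fix$ordinal <= 5L, , drop = FALSE]
  } else {
    fix <- fix[fix$phase == "test", , drop = FALSE]
    key <- interaction(fix$participant_id, fix$trial_index, drop = TRUE)
    onset <- stats::ave(fix$duration_ms, key,
                        FUN = function(d) c(0, cumsum(d)[-length(d)]))
    fix[onset < display_ms, , drop = FALSE]
  }
}
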