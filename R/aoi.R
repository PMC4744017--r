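#' Assign fixations to AOI groups
#'
#' Classifies each fixation into one of the six analysis groups
#' `left_eye`, `bridge`, `right_eye`, `nose` (both halves), `mouth` (both
#' halves) or `other`. Membership uses the half-open rectangle convention,
#' so a fixation exactly on a nose or mouth bisection edge belongs to
#' exactly one half (and hence unambiguously to the combined group).
#' Fixations outside every AOI — including outside the image frame — are
#' `other`; they are never dropped.
#'
#' @param fixations Fixation table (or `gc_dataset`).
#' @param layouts Named list of `gc_layout` objects; taken from the dataset
#'   when `fixations` is a `gc_dataset`.
#' @return Character vector of AOI group labels, one per fixation row.
#' @export
assign_fixations <- function(fixations, layouts = NULL) {
  if (inherits(fixations, "gc_dataset")) {
    layouts <- fixations$layouts
    fixations <- fixations$fixations
  }
  if (is.null(layouts)) stop("`layouts` is required")
  out <- rep("other", nrow(fixations))
  for (fid in unique(fixations$face_id)) {
    lay <- layouts[[fid]]
    if (is.null(lay)) stop("no layout for face '", fid, "'")
    ix <- which(fixations$face_id == fid)
    x <- fixations$x_deg[ix]; y <- fixations$y_deg[ix]
    for (nm in AOI_NAMES) {
      hit <- rect_contains(lay$aois[[nm]], x, y)
      if (any(hit)) {
        grp <- switch(nm, nose_left = , nose_right = "nose",
                      mouth_left = , mouth_right = "mouth", nm)
        out[ix[hit]] <- grp
      }
    }
  }
  out
}

#' AOI relative fixation frequencies
#'
#' For every participant x race (x start position unless `pool_start`) cell
#' of one phase, computes the relative frequency of fixations in each AOI
#' group as the number of actual fixations in the group divided by the
#' total number of *possible* fixations of the cell. In the study phase the
#' possible count is design-determined: trials in the cell times the window
#' size (4 under the default fixation-2-5 window, 5 under `"study_1_5"`) —
#' trials with fewer fixations than the window still count fully toward the
#' denominator, so frequencies across groups sum to at most 1. In the test
#' phase the possible count is realized: the summed number of in-window
#' fixations over the cell's trials (the 1-second cap makes the possible
#' count data-dependent); the fixed-window alternative is available via
#' `test_denominator = "fixed"` with `window_size` per trial.
#'
#' @param ds A [gc_dataset()].
#' @param phase `"study"` or `"test"`.
#' @param pool_start Pool across start positions (default) or keep them as
#'   a cell factor.
#' @param window Study-phase window rule, see [window_fixations()].
#' @param test_denominator `"realized"` (default) or `"fixed"`.
#' @param window_size Per-trial possible count under the fixed test rule.
#' @return Long data frame: cell keys, `aoi_group`, `n_fix`, `n_possible`,
#'   `rel_freq` (`NA` with `flag = "zero_denominator"` for empty cells).
#' @export
relative_frequencies <- function(ds, phase = c("study", "test"),
                                 pool_start = TRUE,
                                 window = c("study_2_5", "study_1_5"),
                                 test_denominator = c("realized", "fixed"),
                                 window_size = 5) {
  phase <- match.arg(phase)
  window <- match.arg(window)
  test_denominator <- match.arg(test_denominator)

  tr <- ds$trials[ds$trials$phase == phase, , drop = FALSE]
  rule <- if (phase == "study") window else "test_1s"
  fix <- window_fixations(ds$fixations, rule)
  fix <- fix[fix$phase == phase, , drop = FALSE]
  fix$aoi_group <- assign_fixations(fix, ds$layouts)

  keycols <- c("participant_id", "race", if (!pool_start) "start_position")
  wsize <- if (window == "study_2_5") 4L else 5L

  cell_key <- function(d) interaction(d[keycols], drop = TRUE, sep = "\r")
  # denominators from the trial table (design-determined for study)
  tr_key <- cell_key(tr)
  if (phase == "study") {
    denom <- tapply(rep(wsize, nrow(tr)), tr_key, sum)
  } else if (test_denominator == "fixed") {
    denom <- tapply(rep(as.integer(window_size), nrow(tr)), tr_key, sum)
  } else {
    fix_key <- cell_key(fix)
    denom <- tapply(rep(1L, nrow(fix)), fix_key, sum)
    # cells with trials but no in-window fixations
    all_cells <- unique(as.character(tr_key))
    denom <- denom[all_cells]
    denom[is.na(denom)] <- 0L
    names(denom) <- all_cells
  }

  cells <- strsplit(names(denom), "\r", fixed = TRUE)
  base <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(base) <- keycols

  fix_key_chr <- as.character(cell_key(fix))
  counts <- table(factor(fix_key_chr, levels = names(denom)),
                  factor(fix$aoi_group, levels = AOI_GROUPS))

  rows <- lapply(seq_along(denom), function(i) {
    nd <- as.integer(denom[i])
    data.frame(base[i, , drop = FALSE], aoi_group = AOI_GROUPS,
               n_fix = as.integer(counts[i, AOI_GROUPS]),
               n_possible = nd,
               rel_freq = if (nd > 0) as.numeric(counts[i, AOI_GROUPS]) / nd
                          else NA_real_,
               flag = if (nd > 0) "" else "zero_denominator",
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$phase <- phase
  out <- out[order(out$participant_id, out$race), ]
  rownames(out) <- NULL
  out
}

#' Planned paired AOI contrasts
#'
#' Runs the planned within-participant comparisons on AOI relative
#' frequencies: for each declared contrast, a paired t-test between two
#' condition levels on one AOI group, with the declared tail, plus the
#' bias-corrected paired effect size [hedges_g_paired()]. Conditions are
#' matched within participant; the table should be pooled across start
#' positions (pooling is justified once the start-position and race
#' effects show no interaction).
#'
#' @param tbl Output of [relative_frequencies()].
#' @param contrasts Data frame with columns `aoi_group`, `cond_a`, `cond_b`
#'   (race levels; the test is `a` vs `b`) and `alternative`
#'   (`"greater"`, `"less"`, `"two.sided"`). Defaults to the planned
#'   own-race-eyes / other-race-nose-mouth set of [default_contrasts()].
#' @return Data frame with one row per contrast: `label`, `t`, `df`, `p`,
#'   `g`, `direction` (sign of the mean difference).
#' @export
planned_contrasts <- function(tbl, contrasts = default_contrasts()) {
  need <- c("aoi_group", "cond_a", "cond_b", "alternative")
  if (!all(need %in% names(contrasts)))
    stop("contrast declarations need columns: ", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(contrasts)), function(i) {
    cs <- contrasts[i, ]
    sub <- tbl[tbl$aoi_group == cs$aoi_group, ]
    a <- sub[sub$race == cs$cond_a, ]
    b <- sub[sub$race == cs$cond_b, ]
    a <- a[order(a$participant_id), ]
    b <- b[order(b$participant_id), ]
    common <- intersect(a$participant_id, b$participant_id)
    if (length(common) < 2)
      stop("contrast ", i, ": fewer than 2 participants with both conditions")
    av <- a$rel_freq[match(common, a$participant_id)]
    bv <- b$rel_freq[match(common, b$participant_id)]
    diffs <- av - bv
    n <- length(common)
    if (sd(diffs) == 0) {
      # degenerate cases t.test() refuses: identical conditions give t = 0
      # (one-tailed p = 0.5); a constant nonzero shift gives t = +/- Inf
      tstat <- if (all(diffs == 0)) 0 else sign(mean(diffs)) * Inf
      pval <- if (cs$alternative == "two.sided") {
        if (tstat == 0) 1 else 0
      } else {
        up <- cs$alternative == "greater"
        if (tstat == 0) 0.5 else if ((tstat > 0) == up) 0 else 1
      }
      ht <- list(statistic = c(t = tstat), parameter = c(df = n - 1),
                 p.value = pval)
    } else {
      ht <- t.test(av, bv, paired = TRUE, alternative = cs$alternative)
    }
    data.frame(
      label = sprintf("%s: %s vs %s (%s)", cs$aoi_group, cs$cond_a,
                      cs$cond_b, cs$alternative),
      aoi_group = cs$aoi_group, cond_a = cs$cond_a, cond_b = cs$cond_b,
      alternative = cs$alternative,
      t = unname(ht$statistic), df = unname(ht$parameter),
      p = unname(ht$p.value), g = hedges_g_paired(av, bv),
      direction = sign(mean(diffs)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname planned_contrasts
#' @param own Own-race level; `others` the other-race levels.
#' @export
default_contrasts <- function(own = "caucasian",
                              others = c("african", "chinese")) {
  eye <- expand.grid(aoi_group = c("left_eye", "right_eye"), cond_a = own,
                     cond_b = others, stringsAsFactors = FALSE)
  eye$alternative <- "greater"
  nm <- expand.grid(aoi_group = c("nose", "mouth"), cond_a = others,
                    cond_b = own, stringsAsFactors = FALSE)
  nm$alternative <- "greater"
  rbind(eye, nm)
}
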