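#' Correct extreme hit / false-alarm proportions
#'
#' Signal-detection indices are undefined at proportions of exactly 0 or 1.
#' The default `"clamp"` rule replaces `k/n = 0` by `1/(2n)` and `k/n = 1`
#' by `1 - 1/(2n)`, leaving other proportions untouched; the `"loglinear"`
#' rule returns `(k + 0.5) / (n + 1)` for every count.
#'
#' @param k_yes Number of "old" responses, `0 <= k_yes <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param rule `"clamp"` (default) or `"loglinear"`.
#' @return Corrected proportion strictly in (0, 1).
#' @export
#' @examples
#' correct_rates(16, 16)               # 31/32
#' correct_rates(0, 16, "loglinear")   # 0.5/17
correct_rates <- function(k_yes, n, rule = c("clamp", "loglinear")) {
  rule <- match.arg(rule)
  if (any(n < 1)) stop("n must be at least 1")
  if (any(k_yes < 0) || any(k_yes > n)) stop("need 0 <= k_yes <= n")
  if (rule == "loglinear") return((k_yes + 0.5) / (n + 1))
  ifelse(k_yes == 0, 1 / (2 * n),
         ifelse(k_yes == n, 1 - 1 / (2 * n), k_yes / n))
}

#' Signal-detection discrimination and bias
#'
#' `dprime()` returns `z(hit_rate) - z(fa_rate)` and `criterion()` returns
#' `-(z(hit_rate) + z(fa_rate)) / 2`, with `z` the standard-normal quantile
#' function. Higher criterion means a stricter (more "new"-prone) observer.
#' Rates must lie strictly in (0, 1); see [correct_rates()].
#'
#' @param hit_rate,fa_rate Proportions strictly in (0, 1); vectorised.
#' @return Numeric vector.
#' @export
#' @examples
#' dprime(0.8413, 0.1587)   # ~ 2
#' criterion(0.7, 0.3)      # 0
dprime <- function(hit_rate, fa_rate) {
  check_rates(hit_rate, fa_rate)
  qnorm(hit_rate) - qnorm(fa_rate)
}

#' @rdname dprime
#' @export
criterion <- function(hit_rate, fa_rate) {
  check_rates(hit_rate, fa_rate)
  -(qnorm(hit_rate) + qnorm(fa_rate)) / 2
}

check_rates <- function(hit_rate, fa_rate) {
  if (any(hit_rate <= 0 | hit_rate >= 1) || any(fa_rate <= 0 | fa_rate >= 1))
    stop("rates must lie strictly in (0, 1); apply correct_rates() first")
  invisible(NULL)
}

#' Reaction-time outlier filter
#'
#' Keeps a reaction time iff it lies within 2.5 sample standard deviations
#' of the *median* of the unfiltered list (the SD is the ordinary mean-based
#' sample standard deviation; the center is the median). Lists with fewer
#' than two elements or zero variance are kept whole. Intended to be applied
#' within one participant x condition cell of correct trials.
#'
#' @param rts Numeric vector of reaction times (ms).
#' @param n_sd Width of the acceptance band in standard deviations.
#' @return List with elements `kept` and `excluded`.
#' @export
#' @examples
#' filter_rts(c(500, 510, 490, 505, 5000))$excluded   # 5000
filter_rts <- function(rts, n_sd = 2.5) {
  if (length(rts) == 0) return(list(kept = numeric(0), excluded = numeric(0)))
  if (length(rts) == 1) return(list(kept = rts, excluded = numeric(0)))
  s <- sd(rts)
  if (!is.finite(s) || s == 0) return(list(kept = rts, excluded = numeric(0)))
  keep <- abs(rts - median(rts)) <= n_sd * s
  list(kept = rts[keep], excluded = rts[!keep])
}

#' Paired Hedges' g (d_av standardizer)
#'
#' Bias-corrected standardized mean difference for paired samples:
#' `g = J * mean(a - b) / s_av`, where `s_av` is the mean of the two
#' condition standard deviations (the d_av convention, which does not
#' inflate the effect when the pairs are correlated) and
#' `J = 1 - 3 / (4 * df - 1)` with `df = n - 1` is the small-sample bias
#' correction.
#'
#' @param a,b Paired per-participant values of equal length `n >= 2`.
#' @return The effect size; signed `Inf` (with a warning) when both
#'   standard deviations are zero but the mean difference is not.
#' @export
hedges_g_paired <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must be paired (equal length)")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  md <- mean(a - b)
  s_av <- (sd(a) + sd(b)) / 2
  j <- 1 - 3 / (4 * (n - 1) - 1)
  if (s_av == 0) {
    if (md == 0) return(0)
    warning("zero variance in both conditions with a nonzero mean difference")
    return(sign(md) * Inf)
  }
  j * md / s_av
}

#' Per-participant behavioural summary of the test phase
#'
#' Tabulates hits, misses, false alarms and correct rejections per
#' participant x race (optionally also split by start position), applies
#' the extreme-rate correction, and computes d-prime, criterion, and the
#' median reaction time of correct trials after [filter_rts()] outlier
#' removal (applied within each participant x condition cell).
#'
#' @param ds A [gc_dataset()] containing test-phase trials.
#' @param by_start Split by start position in addition to race.
#' @param rate_rule Extreme-rate correction rule, see [correct_rates()].
#' @return Data frame with one row per cell: counts, corrected rates,
#'   `dprime`, `criterion`, `median_rt`, `n_rt_excluded`.
#' @export
behavior_summary <- function(ds, by_start = FALSE, rate_rule = "clamp") {
  tr <- ds$trials[ds$trials$phase == "test", , drop = FALSE]
  if (nrow(tr) == 0) stop("dataset has no test-phase trials")
  keys <- list(participant_id = tr$participant_id, race = tr$race)
  if (by_start) keys$start_position <- tr$start_position
  split_key <- interaction(keys, drop = TRUE, sep = "\r")
  cells <- split(tr, split_key)
  rows <- lapply(cells, function(d) {
    old <- d$was_studied
    said_old <- d$judgment == "old"
    hits <- sum(old & said_old); misses <- sum(old & !said_old)
    fas <- sum(!old & said_old); crs <- sum(!old & !said_old)
    hr <- correct_rates(hits, hits + misses, rate_rule)
    fr <- correct_rates(fas, fas + crs, rate_rule)
    correct <- (old & said_old) | (!old & !said_old)
    f <- filter_rts(d$rt_ms[correct])
    out <- data.frame(participant_id = d$participant_id[1], race = d$race[1],
                      stringsAsFactors = FALSE)
    if (by_start) out$start_position <- d$start_position[1]
    cbind(out, data.frame(
      hits = hits, misses = misses, false_alarms = fas,
      correct_rejections = crs, hit_rate = hr, fa_rate = fr,
      dprime = dprime(hr, fr), criterion = criterion(hr, fr),
      median_rt = if (length(f$kept)) median(f$kept) else NA_real_,
      n_rt_excluded = length(f$excluded)))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$participant_id, res$race), ]
  rownames(res) <- NULL
  res
}
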