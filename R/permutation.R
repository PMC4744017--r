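#' Monte Carlo permutation configuration
#'
#' @param n_iter Number of resampling iterations (the full-scale analysis
#'   uses 104,000; simulation studies and tests typically use 1,000-2,000).
#' @param seed Master seed. Each iteration's random reassignment is drawn
#'   from a stream seeded by a documented affine counter scheme on the
#'   master seed, so results do not depend on the order in which
#'   iterations are evaluated.
#' @param chunk_size Iterations per matrix-multiply chunk (memory control).
#' @return A `gc_permconfig` list.
#' @export
perm_config <- function(n_iter = 2000, seed = 1, chunk_size = 500) {
  stopifnot(n_iter >= 1)
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 chunk_size = as.integer(chunk_size)),
            class = "gc_permconfig")
}

# ---- token machinery --------------------------------------------------------
#
# A token is one windowed fixation of the contrast, carrying its aligned
# location and its precomputed single-fixation density column. The
# permutation null exchanges tokens between the two contrasted conditions
# only within cells of (participant x ordinal fixation index), preserving
# each condition's token count per cell. Because the token keeps its face's
# alignment offset baked into its location, every resampled map lives in
# the same aligned reference frame as the observed maps.

build_tokens <- function(ds, cond_a, cond_b, grid = coarse_grid(), sigma = 0.3,
                         window = "study_2_5", condition_var = "race") {
  fix <- window_fixations(ds$fixations, window)
  fix <- fix[fix[[condition_var]] %in% c(cond_a, cond_b), , drop = FALSE]
  if (nrow(fix) == 0) stop("no fixations in the contrasted conditions")
  offs <- alignment_offsets(ds$layouts)
  fix$ax <- fix$x_deg + offs[fix$face_id, "dx"]
  fix$ay <- fix$y_deg + offs[fix$face_id, "dy"]
  fix$cond <- ifelse(fix[[condition_var]] == cond_a, "a", "b")

  phase <- unique(fix$phase)
  tr <- ds$trials[ds$trials$phase %in% phase, , drop = FALSE]
  tr <- tr[tr[[condition_var]] %in% c(cond_a, cond_b), , drop = FALSE]
  participants <- sort(unique(tr$participant_id))
  tr$cond <- ifelse(tr[[condition_var]] == cond_a, "a", "b")
  n_trials <- table(factor(tr$participant_id, levels = participants),
                    factor(tr$cond, levels = c("a", "b")))
  missing <- participants[n_trials[, "a"] == 0 | n_trials[, "b"] == 0]
  if (length(missing))
    stop("participant(s) missing a contrasted condition: ",
         paste(missing, collapse = ", "))

  o <- order(fix$participant_id, fix$ordinal, fix$cond, fix$trial_index)
  fix <- fix[o, , drop = FALSE]
  npx <- grid$height * grid$width
  G <- matrix(0, npx, nrow(fix))
  for (i in seq_len(nrow(fix)))
    G[, i] <- fixation_cell_mass(fix$ax[i], fix$ay[i], grid, sigma)

  P <- length(participants)
  na_p <- n_trials[fix$participant_id, "a"]
  nb_p <- n_trials[fix$participant_id, "b"]
  pos_w <- 1 / (na_p * P)
  neg_w <- -1 / (nb_p * P)
  w_obs <- ifelse(fix$cond == "a", pos_w, neg_w)

  cell_f <- interaction(fix$participant_id, fix$ordinal, drop = TRUE)
  cells <- split(seq_len(nrow(fix)), cell_f)
  cells_nA <- vapply(cells, function(ix) sum(fix$cond[ix] == "a"), 0L)

  list(G = G, fix = fix, grid = grid, sigma = sigma,
       participants = participants, n_trials = n_trials,
       pos_w = pos_w, neg_w = neg_w, w_obs = w_obs,
       cells = cells, cells_nA = cells_nA,
       cond_a = cond_a, cond_b = cond_b, condition_var = condition_var)
}

# logical vector (one per token): assigned to condition a in iteration
# `iter`. Deterministic given (seed, iter).
perm_assignment <- function(tok, iter, seed) {
  with_seed(derive_seed(seed, iter), {
    toA <- logical(nrow(tok$fix))
    for (ci in seq_along(tok$cells)) {
      ix <- tok$cells[[ci]]
      nA <- tok$cells_nA[ci]
      if (nA > 0) toA[ix[sample.int(length(ix), nA)]] <- TRUE
    }
    toA
  })
}

perm_weight_matrix <- function(tok, iters, seed) {
  W <- matrix(0, nrow(tok$fix), length(iters))
  for (j in seq_along(iters)) {
    toA <- perm_assignment(tok, iters[j], seed)
    w <- tok$neg_w
    w[toA] <- tok$pos_w[toA]
    W[, j] <- w
  }
  W
}

# collapse the token-map matrix to profile rows: Gy (height x ntok) sums
# over columns of each token map, Gx (width x ntok) over rows
collapse_G <- function(G, grid) {
  H <- grid$height; W <- grid$width
  Gy <- matrix(0, H, ncol(G))
  Gx <- matrix(0, W, ncol(G))
  for (w in seq_len(W)) {
    block <- G[(w - 1L) * H + seq_len(H), , drop = FALSE]
    Gy <- Gy + block
    Gx[w, ] <- colSums(block)
  }
  list(y = Gy, x = Gx)
}

#' Stream of resampled group difference maps
#'
#' Draws `n_iter` random within-(participant x ordinal) reassignments of
#' fixation tokens between the contrasted conditions, and returns the
#' resulting group-average difference maps. The `"fast"` method multiplies
#' precomputed per-fixation density columns by signed weight vectors, so
#' the cost per iteration is additive in tokens; `"naive"` re-renders
#' every participant's condition maps from scratch with [render_density()]
#' and averages them, and exists as the correctness oracle for the fast
#' path (both consume identical reassignments).
#'
#' @param ds A [gc_dataset()].
#' @param cond_a,cond_b Contrasted levels of `condition_var`
#'   (condition 1 and 2; positive differences mean more density in
#'   `cond_a`).
#' @param grid,sigma Density configuration, see [render_density()].
#' @param cfg A [perm_config()].
#' @param window Analysis window rule, see [window_fixations()].
#' @param condition_var Condition column (default `"race"`).
#' @param method `"fast"` or `"naive"`.
#' @return List of signed `gc_density` maps, one per iteration.
#' @export
resample_null_maps <- function(ds, cond_a, cond_b, grid = coarse_grid(),
                               sigma = 0.3, cfg = perm_config(),
                               window = "study_2_5", condition_var = "race",
                               method = c("fast", "naive")) {
  method <- match.arg(method)
  tok <- build_tokens(ds, cond_a, cond_b, grid, sigma, window, condition_var)
  iters <- seq_len(cfg$n_iter)
  if (method == "fast") {
    W <- perm_weight_matrix(tok, iters, cfg$seed)
    D <- tok$G %*% W
    lapply(seq_along(iters), function(j) density_map(D[, j], grid))
  } else {
    lapply(iters, function(it) {
      toA <- perm_assignment(tok, it, cfg$seed)
      per_part <- lapply(tok$participants, function(p) {
        pp <- tok$fix$participant_id == p
        ra <- render_density(tok$fix[pp & toA, ], NULL, grid, sigma)
        rb <- render_density(tok$fix[pp & !toA, ], NULL, grid, sigma)
        density_map(ra$values / tok$n_trials[p, "a"] -
                      rb$values / tok$n_trials[p, "b"], grid)
      })
      average_maps(per_part)
    })
  }
}

#' Pixel-wise permutation p-values
#'
#' For a pixel with positive observed difference, the p-value is the
#' fraction of resampled difference maps whose value at that pixel is at
#' least as large; for a negative pixel, at least as small (sign-dependent
#' single tails). Monte Carlo p-values are smoothed as
#' `(count + 1) / (n_iter + 1)` so they are strictly positive and valid;
#' pixels with an observed difference of exactly zero get p = 1 and tail
#' sign 0.
#'
#' @param observed Signed `gc_density` group difference map.
#' @param resamples List of resampled maps from [resample_null_maps()].
#' @return A `gc_pmap` with matrices `p` and `tail_sign`, plus `n_iter`.
#' @export
pixel_pvalues <- function(observed, resamples) {
  o <- as.vector(observed$values)
  n <- length(resamples)
  cnt_ge <- numeric(length(o)); cnt_le <- numeric(length(o))
  for (r in resamples) {
    rv <- as.vector(r$values)
    cnt_ge <- cnt_ge + (rv >= o)
    cnt_le <- cnt_le + (rv <= o)
  }
  pmap_from_counts(o, cnt_ge, cnt_le, n, observed$grid, smoothing = "add_one")
}

pmap_from_counts <- function(o, cnt_ge, cnt_le, n_iter, grid,
                             smoothing = c("add_one", "none"), axis = NULL) {
  smoothing <- match.arg(smoothing)
  raw_ge <- if (smoothing == "add_one") (cnt_ge + 1) / (n_iter + 1) else cnt_ge / n_iter
  raw_le <- if (smoothing == "add_one") (cnt_le + 1) / (n_iter + 1) else cnt_le / n_iter
  p <- ifelse(o > 0, raw_ge, ifelse(o < 0, raw_le, 1))
  p <- pmin(p, 1)
  sign_o <- sign(o)
  if (is.null(axis)) {
    p <- matrix(p, grid$height, grid$width)
    sign_o <- matrix(sign_o, grid$height, grid$width)
  }
  structure(list(p = p, tail_sign = sign_o, n_iter = n_iter, grid = grid,
                 smoothing = smoothing, axis = axis), class = "gc_pmap")
}

#' @export
print.gc_pmap <- function(x, ...) {
  kind <- if (is.null(x$axis)) "2-D" else paste0(x$axis, "-profile")
  cat(sprintf("<gc_pmap> %s, %d iterations (%s smoothing), min p = %.4g\n",
              kind, x$n_iter, x$smoothing, min(x$p)))
  invisible(x)
}

#' Full Monte Carlo permutation test on density contrasts
#'
#' Runs the observed contrast and the complete resampling stream in
#' memory-bounded chunks, producing the pixel-wise p-value map and — from
#' the *same* resampled iterations, collapsed by summation — the x- and
#' y-profile p-value curves. This is the main entry point for statistical
#' maps; [resample_null_maps()] exposes the raw stream for small-scale
#' inspection.
#'
#' @inheritParams resample_null_maps
#' @return A `gc_permtest` with elements `observed` (signed group
#'   difference map), `observed_profiles`, `pmap` (2-D `gc_pmap`),
#'   `pmap_x`, `pmap_y` (profile `gc_pmap`s), and `config`.
#' @export
permutation_test <- function(ds, cond_a, cond_b, grid = coarse_grid(),
                             sigma = 0.3, cfg = perm_config(),
                             window = "study_2_5", condition_var = "race") {
  tok <- build_tokens(ds, cond_a, cond_b, grid, sigma, window, condition_var)
  Gc <- collapse_G(tok$G, grid)

  o <- as.vector(tok$G %*% tok$w_obs)
  oy <- as.vector(Gc$y %*% tok$w_obs)
  ox <- as.vector(Gc$x %*% tok$w_obs)

  npx <- length(o)
  cnt <- list(ge = numeric(npx), le = numeric(npx),
              ge_y = numeric(grid$height), le_y = numeric(grid$height),
              ge_x = numeric(grid$width), le_x = numeric(grid$width))
  it0 <- 1L
  while (it0 <= cfg$n_iter) {
    iters <- seq.int(it0, min(it0 + cfg$chunk_size - 1L, cfg$n_iter))
    W <- perm_weight_matrix(tok, iters, cfg$seed)
    D <- tok$G %*% W
    cnt$ge <- cnt$ge + rowSums(D >= o)
    cnt$le <- cnt$le + rowSums(D <= o)
    Dy <- Gc$y %*% W
    cnt$ge_y <- cnt$ge_y + rowSums(Dy >= oy)
    cnt$le_y <- cnt$le_y + rowSums(Dy <= oy)
    Dx <- Gc$x %*% W
    cnt$ge_x <- cnt$ge_x + rowSums(Dx >= ox)
    cnt$le_x <- cnt$le_x + rowSums(Dx <= ox)
    it0 <- it0 + cfg$chunk_size
  }
  observed <- density_map(o, grid)
  structure(list(
    observed = observed,
    observed_profiles = list(
      y = structure(list(axis = "y", values = oy, grid = grid,
                         n_fixations = NA), class = "gc_profile"),
      x = structure(list(axis = "x", values = ox, grid = grid,
                         n_fixations = NA), class = "gc_profile")),
    pmap = pmap_from_counts(o, cnt$ge, cnt$le, cfg$n_iter, grid),
    pmap_y = pmap_from_counts(oy, cnt$ge_y, cnt$le_y, cfg$n_iter, grid,
                              axis = "y"),
    pmap_x = pmap_from_counts(ox, cnt$ge_x, cnt$le_x, cfg$n_iter, grid,
                              axis = "x"),
    config = list(cond_a = cond_a, cond_b = cond_b, sigma = sigma,
                  window = window, condition_var = condition_var,
                  n_iter = cfg$n_iter, seed = cfg$seed),
    n_tokens = ncol(tok$G), participants = tok$participants),
    class = "gc_permtest")
}

#' @export
print.gc_permtest <- function(x, ...) {
  cat(sprintf(paste0("<gc_permtest> %s vs %s, %d tokens, %d participants, ",
                     "%d iterations\n"),
              x$config$cond_a, x$config$cond_b, x$n_tokens,
              length(x$participants), x$config$n_iter))
  invisible(x)
}

#' Profile p-values of a permutation test
#'
#' Accessor for the profile p-value curves of a [permutation_test()]. The
#' profiles reuse the identical resampled iterations of the 2-D test
#' (each resampled map is collapsed by summation before counting), rather
#' than drawing a new permutation run.
#'
#' @param pt A `gc_permtest`.
#' @param axis `"y"` or `"x"`.
#' @return A 1-D `gc_pmap`.
#' @export
profile_pvalues <- function(pt, axis = c("y", "x")) {
  axis <- match.arg(axis)
  if (axis == "y") pt$pmap_y else pt$pmap_x
}

#' Threshold a p-value map (uncorrected)
#'
#' Marks pixels significant at the given per-tail alpha. Because each
#' pixel's p-value is computed in the single tail matching its observed
#' sign, a per-tail threshold alpha corresponds to a two-tailed level of
#' `2 * alpha` (e.g. per-tail p < 0.01 is equivalent to two-tailed
#' p < 0.02; for profile maps the conventional per-tail 0.025 is
#' equivalent to two-tailed 0.05), which is recorded in the metadata.
#'
#' @param pm A `gc_pmap`.
#' @param per_tail_alpha Per-tail significance level in (0, 0.5).
#' @return A `gc_sigmap` with `mask`, `tail_sign`, and threshold metadata.
#' @export
threshold_pmap <- function(pm, per_tail_alpha = 0.01) {
  stopifnot_scalar_number(per_tail_alpha, "per_tail_alpha", 1e-12, 0.5 - 1e-12)
  structure(list(mask = pm$p < per_tail_alpha, tail_sign = pm$tail_sign,
                 grid = pm$grid, axis = pm$axis, method = "uncorrected",
                 per_tail_alpha = per_tail_alpha,
                 two_tailed_alpha = 2 * per_tail_alpha,
                 analysis_mask = NULL), class = "gc_sigmap")
}

#' FDR-corrected significance map
#'
#' Benjamini-Hochberg step-up control of the false discovery rate over the
#' pixel p-values inside the analysis mask (for spatial maps, the face
#' region — non-face pixels are ignored entirely and can never be
#' significant; for profile maps, all pixels are conventionally used, i.e.
#' `analysis_mask = NULL`).
#'
#' @param pm A `gc_pmap`.
#' @param analysis_mask Logical matrix/vector of pixels to include, or
#'   `NULL` for all.
#' @param q FDR threshold (expected false-positive fraction among
#'   survivors).
#' @return A `gc_sigmap`.
#' @export
fdr_correct <- function(pm, analysis_mask = NULL, q = 0.05) {
  stopifnot_scalar_number(q, "q", 1e-12, 1 - 1e-12)
  p <- pm$p
  if (is.null(analysis_mask)) analysis_mask <- array(TRUE, dim = dim(p) %||% length(p))
  if (!any(analysis_mask)) stop("analysis mask is empty")
  mask <- array(FALSE, dim = dim(p) %||% length(p))
  padj <- p.adjust(p[analysis_mask], method = "BH")
  mask[analysis_mask] <- padj <= q
  structure(list(mask = mask, tail_sign = pm$tail_sign, grid = pm$grid,
                 axis = pm$axis, method = "fdr", q = q,
                 analysis_mask = analysis_mask), class = "gc_sigmap")
}

#' @export
print.gc_sigmap <- function(x, ...) {
  thr <- if (x$method == "fdr") sprintf("q <= %g", x$q)
         else sprintf("p < %g per tail (two-tailed %g)", x$per_tail_alpha,
                      x$two_tailed_alpha)
  cat(sprintf("<gc_sigmap> %s, %d significant of %d pixels\n", thr,
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Exact permutation enumeration (small-instance oracle)
#'
#' Enumerates *every* within-(participant x ordinal) reassignment of the
#' contrast's tokens, computing exact sign-dependent tail proportions with
#' the same counting convention as the Monte Carlo test but without the
#' `+1` smoothing (the enumeration includes the observed assignment, so
#' exact p-values are already strictly positive). Only feasible on tiny
#' instances; the total number of distinct reassignments must not exceed
#' `limit`.
#'
#' @inheritParams resample_null_maps
#' @param limit Maximum number of reassignments to enumerate.
#' @return A `gc_pmap` (raw proportions, `smoothing = "none"`,
#'   `n_iter` = number of enumerated reassignments).
#' @export
exact_enumeration <- function(ds, cond_a, cond_b, grid = coarse_grid(),
                              sigma = 0.3, window = "study_2_5",
                              condition_var = "race", limit = 1e6) {
  tok <- build_tokens(ds, cond_a, cond_b, grid, sigma, window, condition_var)
  combos <- lapply(seq_along(tok$cells), function(ci) {
    ix <- tok$cells[[ci]]
    utils::combn(length(ix), tok$cells_nA[ci], simplify = FALSE)
  })
  counts <- vapply(combos, length, 0)
  total <- prod(counts)
  if (total > limit)
    stop(sprintf("instance too large: %.3g distinct reassignments (limit %g)",
                 total, limit))
  grid_idx <- expand.grid(lapply(counts, seq_len))
  W <- matrix(0, nrow(tok$fix), nrow(grid_idx))
  for (k in seq_len(nrow(grid_idx))) {
    toA <- logical(nrow(tok$fix))
    for (ci in seq_along(tok$cells)) {
      ix <- tok$cells[[ci]]
      toA[ix[combos[[ci]][[grid_idx[k, ci]]]]] <- TRUE
    }
    W[, k] <- ifelse(toA, tok$pos_w, tok$neg_w)
  }
  o <- as.vector(tok$G %*% tok$w_obs)
  D <- tok$G %*% W
  cnt_ge <- rowSums(D >= o)
  cnt_le <- rowSums(D <= o)
  pmap_from_counts(o, cnt_ge, cnt_le, nrow(grid_idx), grid, smoothing = "none")
}
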