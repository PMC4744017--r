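# deterministic 3-fixation trial locations (ordinal 1 is outside the window)
locs_a <- rbind(c(8.0, 8.0), c(6.0, 6.0), c(7.2, 9.8), c(9.5, 6.1), c(8.1, 7.3))
locs_b <- rbind(c(8.0, 8.0), c(9.9, 6.2), c(8.3, 9.9), c(6.4, 7.7), c(7.7, 8.8))

test_that("resampling is deterministic and chunk-order independent", {
  ds <- two_condition_dataset(locs_a, locs_b, jitter = 0.15)
  cfg <- perm_config(40, seed = 7)
  r1 <- resample_null_maps(ds, "caucasian", "chinese", tiny_grid(), 0.3, cfg)
  r2 <- resample_null_maps(ds, "caucasian", "chinese", tiny_grid(), 0.3, cfg)
  expect_identical(lapply(r1, `[[`, "values"), lapply(r2, `[[`, "values"))

  pt1 <- permutation_test(ds, "caucasian", "chinese", tiny_grid(), 0.3,
                          perm_config(40, 7, chunk_size = 7))
  pt2 <- permutation_test(ds, "caucasian", "chinese", tiny_grid(), 0.3,
                          perm_config(40, 7, chunk_size = 1000))
  expect_identical(pt1$pmap$p, pt2$pmap$p)
  expect_identical(pt1$pmap_y$p, pt2$pmap_y$p)
})

test_that("the fast token path agrees with naive re-rendering", {
  ds <- two_condition_dataset(locs_a, locs_b, jitter = 0.15)
  cfg <- perm_config(25, seed = 13)
  fast <- resample_null_maps(ds, "caucasian", "chinese", tiny_grid(), 0.3,
                             cfg, method = "fast")
  naive <- resample_null_maps(ds, "caucasian", "chinese", tiny_grid(), 0.3,
                              cfg, method = "naive")
  for (i in seq_along(fast)) {
    expect_equal(fast[[i]]$values, naive[[i]]$values, tolerance = 1e-12)
  }
})

test_that("exchanging identical condition multisets gives all-zero resamples", {
  ds <- two_condition_dataset(locs_a, locs_a)
  pt <- permutation_test(ds, "caucasian", "chinese", tiny_grid(), 0.3,
                         perm_config(30, 3))
  expect_true(all(abs(pt$observed$values) < 1e-15))
  expect_true(all(pt$pmap$p == 1))
  expect_true(all(pt$pmap$tail_sign == 0))
  expect_true(all(pt$pmap_y$p == 1))
})

test_that("resampled null differences are centered and sign-symmetric", {
  ds <- two_condition_dataset(locs_a, locs_b, jitter = 0.15)
  r <- resample_null_maps(ds, "caucasian", "chinese", tiny_grid(), 0.3,
                          perm_config(400, 21))
  vals <- vapply(r, function(m) m$values[15, 16], 0)
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
  sk <- mean((vals - mean(vals))^3) / sd(vals)^3
  expect_lt(abs(sk), 0.5)
})

test_that("pixel p-values follow the sign-dependent counting convention", {
  g <- grid_spec(2, 2, 1)
  obs <- gazecontrast:::density_map(matrix(c(0.5, -0.5, 0, 0.2), 2, 2), g)
  # 99 resamples strictly below the positive pixels, above the negative one
  res <- lapply(1:99, function(i)
    gazecontrast:::density_map(matrix(c(0.4, -0.4, 0.1, 0.21), 2, 2), g))
  pm <- pixel_pvalues(obs, res)
  expect_equal(pm$p[1, 1], 1 / 100)    # exceeds all 99 resamples
  expect_equal(pm$p[2, 1], 1 / 100)    # negative tail, below all 99
  expect_equal(pm$p[1, 2], 1)          # observed 0 -> p = 1 by convention
  expect_equal(pm$p[2, 2], 1)          # all resamples >= observed
  expect_equal(pm$tail_sign, matrix(c(1, -1, 0, 1), 2, 2))
})

test_that("thresholding records the two-tailed equivalent and nests", {
  g <- grid_spec(2, 2, 1)
  pm <- structure(list(p = matrix(c(0.005, 0.02, 0.5, 1), 2, 2),
                       tail_sign = matrix(c(1, -1, 1, 0), 2, 2),
                       n_iter = 1000, grid = g, smoothing = "add_one",
                       axis = NULL), class = "gc_pmap")
  sm <- threshold_pmap(pm, 0.01)
  expect_equal(sm$two_tailed_alpha, 0.02)
  expect_equal(sum(sm$mask), 1)
  sm25 <- threshold_pmap(pm, 0.025)
  expect_equal(sm25$two_tailed_alpha, 0.05)
  expect_true(all(sm$mask <= sm25$mask))      # nested masks
  pm1 <- pm; pm1$p[] <- 1
  expect_equal(sum(threshold_pmap(pm1, 0.01)$mask), 0)
})

test_that("FDR correction is BH step-up restricted to the analysis mask", {
  g <- grid_spec(1, 5, 1)
  pvec <- c(0.01, 0.02, 0.03, 0.04, 0.2)
  pm <- structure(list(p = matrix(pvec, 1, 5),
                       tail_sign = matrix(1, 1, 5), n_iter = 1000, grid = g,
                       smoothing = "add_one", axis = NULL), class = "gc_pmap")
  sm <- fdr_correct(pm, NULL, q = 0.05)
  # brute-force BH step-up on the vector
  m <- length(pvec); srt <- sort(pvec)
  k <- max(c(0, which(srt <= 0.05 * seq_len(m) / m)))
  reject <- pvec <= (if (k > 0) srt[k] else -1)
  expect_equal(as.vector(sm$mask), reject)
  expect_equal(sum(sm$mask), 4)

  # all p = 1: nothing survives
  pm1 <- pm; pm1$p[] <- 1
  expect_equal(sum(fdr_correct(pm1, NULL, 0.05)$mask), 0)

  # single in-mask pixel with p < q is rejected; out-of-mask pixels never
  msk <- matrix(c(TRUE, FALSE, FALSE, FALSE, FALSE), 1, 5)
  sm1 <- fdr_correct(pm, msk, 0.05)
  expect_equal(as.vector(sm1$mask), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_error(fdr_correct(pm, matrix(FALSE, 1, 5), 0.05), "empty")
})

test_that("exact enumeration matches hand counts on the minimal instance", {
  # 1 participant, 1 exchange cell ({a, b} at ordinal 2): 2 reassignments
  lays <- tiny_layouts()
  rows <- rbind(
    fix_trial(rbind(c(8, 8), c(6, 6)), trial_index = 1L,
              face_id = "cau_01", race = "caucasian"),
    fix_trial(rbind(c(8, 8), c(10, 10)), trial_index = 2L,
              face_id = "chi_01", race = "chinese"))
  ds <- gc_dataset(rows, lays)
  pm <- exact_enumeration(ds, "caucasian", "chinese", tiny_grid(), 0.3)
  expect_equal(pm$n_iter, 2)
  expect_true(all(pm$p %in% c(0.5, 1)))
  # nonzero pixels flip tails symmetrically under condition swap
  pm_swap <- exact_enumeration(ds, "chinese", "caucasian", tiny_grid(), 0.3)
  expect_equal(pm_swap$p, pm$p)
  expect_equal(pm_swap$tail_sign, -pm$tail_sign)

  # instance-size guard
  big <- small_dataset(seed = 3)
  expect_error(exact_enumeration(big, "caucasian", "chinese", tiny_grid(),
                                 0.3, limit = 10), "too large")
})

test_that("Monte Carlo p-values converge to the exact enumeration", {
  ds <- two_condition_dataset(locs_a[1:3, ], locs_b[1:3, ], jitter = 0.137)
  g <- grid_spec(16, 16, 1)
  exact <- exact_enumeration(ds, "caucasian", "chinese", g, 0.4)
  n_mc <- 4000
  pt <- permutation_test(ds, "caucasian", "chinese", g, 0.4,
                         perm_config(n_mc, 33))
  raw_mc <- (pt$pmap$p * (n_mc + 1) - 1) / n_mc   # undo the +1 smoothing
  nz <- exact$tail_sign != 0
  se <- sqrt(exact$p * (1 - exact$p) / n_mc)
  expect_true(all(abs(raw_mc[nz] - exact$p[nz]) <= 3 * se[nz] + 1e-9))
})

test_that("profile p-values reuse the 2-D resamples consistently", {
  ds <- two_condition_dataset(locs_a, locs_b, jitter = 0.137)
  g <- tiny_grid()
  n <- 500
  pt <- permutation_test(ds, "caucasian", "chinese", g, 0.3, perm_config(n, 41))

  # oracle: collapse the actual resampled maps and count by the convention
  maps <- resample_null_maps(ds, "caucasian", "chinese", g, 0.3,
                             perm_config(n, 41))
  oy <- pt$observed_profiles$y$values
  cnt_ge <- numeric(g$height); cnt_le <- numeric(g$height)
  for (m in maps) {
    ry <- rowSums(m$values)
    cnt_ge <- cnt_ge + (ry >= oy)
    cnt_le <- cnt_le + (ry <= oy)
  }
  p_oracle <- ifelse(oy > 0, (cnt_ge + 1) / (n + 1),
                     ifelse(oy < 0, (cnt_le + 1) / (n + 1), 1))
  # compare only where the observed profile carries real mass; in the far
  # Gaussian tails tie-breaking between near-zero values is float noise.
  # Iterations that redraw the observed assignment (prob (1/2)^8 per iter
  # here) tie with the observed value exactly, and the two float paths may
  # break those ties differently, so allow a few counts of slack.
  keep <- abs(oy) > 0.01 * max(abs(oy))
  expect_gt(sum(keep), 10)
  expect_lt(max(abs(as.vector(pt$pmap_y$p)[keep] - p_oracle[keep])), 10 / n)

  # an independent permutation run (different seed) agrees in distribution
  pt2 <- permutation_test(ds, "caucasian", "chinese", g, 0.3, perm_config(n, 99))
  se <- sqrt(pt$pmap_y$p * (1 - pt$pmap_y$p) / n)
  expect_true(all(abs(pt2$pmap_y$p - pt$pmap_y$p)[keep] <=
                    (4 * se + 2 / n)[keep]))
})

test_that("a participant missing one condition is reported by name", {
  lays <- tiny_layouts()
  rows <- rbind(
    fix_trial(locs_a, participant_id = "p01", trial_index = 1L),
    fix_trial(locs_b, participant_id = "p01", trial_index = 2L,
              face_id = "chi_01", race = "chinese"),
    fix_trial(locs_a, participant_id = "p02", trial_index = 1L))
  ds <- gc_dataset(rows, lays)
  expect_error(permutation_test(ds, "caucasian", "chinese", tiny_grid(), 0.3,
                                perm_config(5, 1)), "p02")
})
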