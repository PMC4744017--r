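test_that("generation is deterministic given the seed", {
  a <- small_dataset(seed = 5)
  b <- small_dataset(seed = 5)
  expect_identical(a$fixations, b$fixations)
  expect_identical(a$trials, b$trials)
  c <- small_dataset(seed = 6)
  expect_false(identical(a$fixations$x_deg, c$fixations$x_deg))

  # byte-identical TSV export
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fixations(a, f1); write_fixations(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the generated design is balanced as specified", {
  ds <- small_dataset(seed = 12)   # 2 participants, 4 study trials/race
  tr <- ds$trials
  study <- tr[tr$phase == "study", ]
  # every race x start cell has the same trial count within each participant
  tab <- table(study$participant_id, study$race, study$start_position)
  expect_true(all(tab == 1))
  test <- tr[tr$phase == "test", ]
  tab2 <- table(test$participant_id, test$race, test$start_position)
  expect_true(all(tab2 == 2))
  # half the test faces were studied
  expect_equal(mean(test$was_studied), 0.5)

  # studied faces reappear half with the same, half with the opposite start
  opp <- c(left = "right", right = "left", up = "down", down = "up")
  for (p in unique(tr$participant_id)) {
    s <- study[study$participant_id == p, ]
    t2 <- test[test$participant_id == p & test$was_studied, ]
    m <- match(t2$face_id, s$face_id)
    same <- t2$start_position == s$start_position[m]
    flipped <- t2$start_position == opp[s$start_position[m]]
    expect_true(all(same | flipped))
    expect_equal(sum(same), sum(flipped))
  }

  # full default design: 48 study and 96 test trials per participant
  p <- generator_params(seed = 1)
  expect_equal(p$n_participants * (p$trials_per_race_study * 3), 30 * 48)
  big <- generate_dataset(generator_params(n_participants = 1, seed = 9))
  expect_equal(sum(big$trials$phase == "study"), 48)
  expect_equal(sum(big$trials$phase == "test"), 96)
  expect_true(all(table(big$trials$race[big$trials$phase == "study"]) == 16))
})

test_that("layout generation reduces to the template without jitter", {
  p <- generator_params(layout_jitter_sd = 0, mirror_faces = FALSE,
                        faces_per_race = 2, phases = "study", seed = 3)
  lays <- generate_face_layouts(p)
  tmpl <- template_face_layout()
  for (l in lays) expect_equal(l$aois, tmpl$aois)
  # determinism
  expect_equal(generate_face_layouts(generator_params(seed = 8)),
               generate_face_layouts(generator_params(seed = 8)))
})

test_that("jittered AOI centers average to the template centers", {
  p <- generator_params(faces_per_race = 200, layout_jitter_sd = 0.1,
                        mirror_faces = FALSE, phases = "study", seed = 17)
  lays <- generate_face_layouts(p)
  cen <- Reduce(`+`, lapply(lays, aoi_centers)) / length(lays)
  tmpl <- aoi_centers(template_face_layout())
  se <- 0.1 / sqrt(length(lays))
  expect_true(all(abs(cen - tmpl) < 3 * se + 0.005))
})

test_that("start points satisfy their defining equidistance properties", {
  lay <- template_face_layout()
  sp <- compute_start_points(lay)
  cen <- aoi_centers(lay)
  d <- function(p, a) sqrt((p$x - cen[a, "x"])^2 + (p$y - cen[a, "y"])^2)

  left <- sp[sp$position == "left", ]
  dl <- c(d(left, "left_eye"), d(left, "nose_left"), d(left, "mouth_left"))
  expect_lt(max(dl) - min(dl), 1e-9)
  right <- sp[sp$position == "right", ]
  dr <- c(d(right, "right_eye"), d(right, "nose_right"), d(right, "mouth_right"))
  expect_lt(max(dr) - min(dr), 1e-9)

  up <- sp[sp$position == "up", ]
  expect_lt(abs(d(up, "left_eye") - d(up, "right_eye")), 1e-9)
  expect_lt(up$y, cen["left_eye", "y"])          # above the eyes
  down <- sp[sp$position == "down", ]
  expect_lt(abs(d(down, "mouth_left") - d(down, "mouth_right")), 1e-9)
  expect_gt(down$y, cen["mouth_left", "y"])      # below the mouth

  # up/down distances equal the mean of the lateral equidistances
  expect_equal(d(up, "left_eye"), mean(c(dl[1], dr[1])), tolerance = 1e-9)
  expect_equal(d(down, "mouth_left"), mean(c(dl[1], dr[1])), tolerance = 1e-9)

  # mirror-symmetric template: left/right points mirror about the midline
  expect_equal(left$x + right$x, 16, tolerance = 1e-9)
  expect_equal(left$y, right$y, tolerance = 1e-9)
})

test_that("lateral start points match a brute-force equidistance search", {
  lays <- generate_face_layouts(generator_params(faces_per_race = 3,
                                                 phases = "study", seed = 23))
  for (lay in lays[1:3]) {
    sp <- compute_start_points(lay)
    cen <- aoi_centers(lay)
    pts <- cen[c("left_eye", "nose_left", "mouth_left"), , drop = FALSE]
    # grid search minimizing the variance of the three distances
    gx <- seq(0, 16, by = 0.02); gy <- seq(0, 16, by = 0.02)
    gg <- expand.grid(x = gx, y = gy)
    dv <- sapply(seq_len(nrow(pts)), function(i)
      sqrt((gg$x - pts[i, "x"])^2 + (gg$y - pts[i, "y"])^2))
    best <- gg[which.min(apply(dv, 1, stats::var)), ]
    left <- sp[sp$position == "left", ]
    expect_lt(abs(best$x - left$x), 0.021)
    expect_lt(abs(best$y - left$y), 0.021)
  }
})

test_that("degenerate mixtures and determinism of trial generation", {
  lay <- template_face_layout()
  sp <- compute_start_points(lay)
  start <- sp[sp$position == "left", ]
  w <- matrix(c(1, 0, 0, 0, 0, 0), 1, dimnames = list("caucasian", aoi_groups6))
  p <- generator_params(feature_weights = w, races = "caucasian",
                        behavior = default_behavior("caucasian"),
                        scatter_sd = 1e-9, start_pull = 0, phases = "study",
                        seed = 1)
  fx <- withr::with_seed(4, generate_trial_fixations(lay, start, "caucasian", 8, p))
  ctr <- colMeans(rbind(lay$aois$left_eye[c("x0", "x1")]))
  expect_true(all(abs(fx$x_deg[-1] - mean(lay$aois$left_eye[c("x0", "x1")])) < 1e-6))
  expect_true(all(abs(fx$y_deg[-1] - mean(lay$aois$left_eye[c("y0", "y1")])) < 1e-6))

  f1 <- withr::with_seed(9, generate_trial_fixations(lay, start, "caucasian", 6, p))
  f2 <- withr::with_seed(9, generate_trial_fixations(lay, start, "caucasian", 6, p))
  expect_identical(f1, f2)
})

test_that("empirical AOI label frequencies recover the mixture weights", {
  lay <- template_face_layout()
  sp <- compute_start_points(lay)
  start <- sp[sp$position == "up", ]
  p <- generator_params(start_pull = 0, phases = "study", seed = 1)
  n_per <- 2000; trials <- 5
  labs <- withr::with_seed(31, unlist(lapply(seq_len(trials), function(i) {
    fx <- generate_trial_fixations(lay, start, "chinese", n_per + 1, p)
    fx$label[-1]
  })))
  n <- length(labs)
  w <- p$feature_weights["chinese", ]
  for (g in aoi_groups6) {
    se <- sqrt(w[g] * (1 - w[g]) / n)
    expect_lt(abs(mean(labs == g) - w[g]), 3 * se + 1e-9)
  }
})

test_that("race and start-position effects are independent by construction", {
  ds <- generate_dataset(generator_params(n_participants = 16,
                                          races = c("caucasian", "chinese"),
                                          phases = "study", seed = 27))
  rf <- relative_frequencies(ds, "study", pool_start = FALSE)
  le <- rf[rf$aoi_group == "left_eye", ]
  wide <- reshape(le[c("participant_id", "race", "start_position", "rel_freq")],
                  direction = "wide", idvar = c("participant_id", "start_position"),
                  timevar = "race")
  wide$diff <- wide$rel_freq.caucasian - wide$rel_freq.chinese
  fit <- stats::aov(diff ~ start_position + participant_id, data = wide)
  pval <- summary(fit)[[1]]["start_position", "Pr(>F)"]
  # no injected interaction: the race contrast must not vary by start
  expect_gt(pval, 0.01)
})

test_that("a strong injected eye bias is recovered as a significant contrast", {
  w <- default_feature_weights(c("caucasian", "chinese"))
  w["caucasian", "left_eye"] <- w["caucasian", "left_eye"] + 0.14
  w["caucasian", "other"] <- w["caucasian", "other"] - 0.14
  hits <- 0; reps <- 30
  for (i in seq_len(reps)) {
    ds <- generate_dataset(generator_params(
      n_participants = 8, trials_per_race_study = 8, faces_per_race = 8,
      races = c("caucasian", "chinese"), feature_weights = w,
      phases = "study", seed = 1000 + i))
    rf <- relative_frequencies(ds, "study")
    ct <- planned_contrasts(rf, data.frame(
      aoi_group = "left_eye", cond_a = "caucasian", cond_b = "chinese",
      alternative = "greater", stringsAsFactors = FALSE))
    if (ct$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("null feature weights give a nominal AOI false-positive rate", {
  w0 <- default_feature_weights(c("caucasian", "chinese"))
  w0["caucasian", ] <- w0["chinese", ]
  hits <- 0; reps <- 100
  for (i in seq_len(reps)) {
    ds <- generate_dataset(generator_params(
      n_participants = 8, trials_per_race_study = 8, faces_per_race = 8,
      races = c("caucasian", "chinese"), feature_weights = w0,
      phases = "study", seed = 2000 + i))
    rf <- relative_frequencies(ds, "study")
    ct <- planned_contrasts(rf, data.frame(
      aoi_group = "left_eye", cond_a = "caucasian", cond_b = "chinese",
      alternative = "greater", stringsAsFactors = FALSE))
    if (ct$p < 0.05) hits <- hits + 1
  }
  # 99% binomial band around 0.05 with 100 replicates
  expect_lte(hits / reps, 0.11)
})

test_that("default feature weights are calibrated to paired g around 0.2", {
  gs <- c()
  for (i in 1:25) {
    ds <- generate_dataset(generator_params(phases = "study", seed = 3000 + i))
    rf <- relative_frequencies(ds, "study")
    cts <- planned_contrasts(rf, data.frame(
      aoi_group = c("left_eye", "right_eye", "left_eye", "right_eye"),
      cond_a = "caucasian",
      cond_b = c("chinese", "chinese", "african", "african"),
      alternative = "greater", stringsAsFactors = FALSE))
    gs <- c(gs, cts$g)
  }
  expect_gt(mean(gs), 0.12)
  expect_lt(mean(gs), 0.33)
})
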