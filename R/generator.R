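#' Parameters of the synthetic face-viewing experiment generator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate a three-race (Caucasian observer) old/new face
#' recognition design: 30 participants, 16 study trials per race
#' (4 per start position), a test phase with the 48 studied plus 48 new
#' faces under 1-second viewing, feature-biased fixation mixtures giving the
#' own-race eye bias and other-race nose/mouth bias at paired effect sizes
#' around g = 0.2, a larger start-position effect on early fixations, and
#' race-ordered recognition rates (d-prime deficit for Chinese faces,
#' criterion strictest for Caucasian faces).
#'
#' @param n_participants Number of participants.
#' @param races Character vector of face races in the design.
#' @param trials_per_race_study Study trials per race per participant; must
#'   be divisible by the number of start positions (4).
#' @param faces_per_race Size of the face pool per race; at least
#'   `2 * trials_per_race_study` so the test phase can show as many new as
#'   studied faces.
#' @param feature_weights Numeric matrix (`races` x AOI groups
#'   `left_eye, bridge, right_eye, nose, mouth, other`); each row is the
#'   fixation-target mixture for that race and must sum to 1.
#' @param scatter_sd Within-AOI Gaussian scatter SD in degrees.
#' @param start_pull Mixing weight in `[0, 1]` of the start-position-biased
#'   label distribution for the second fixation; decays by `start_decay`
#'   per subsequent fixation. Also scales the displacement of the first
#'   fixation toward the start side.
#' @param start_decay Geometric decay of the start-side bias over ordinals.
#' @param layout_jitter_sd SD in degrees of the per-face jitter applied to
#'   the template AOI centers.
#' @param behavior Named list per race with elements `hit_rate`, `fa_rate`
#'   in (0, 1).
#' @param behavior_sd SD of the per-participant normal jitter applied to
#'   the z-transformed hit and false-alarm rates.
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters (ms).
#' @param rt_outlier_rate,rt_outlier_scale Rate of injected slow-response
#'   outliers and their multiplicative factor (exercises the RT filter).
#' @param fix_dur_meanlog,fix_dur_sdlog Log-normal fixation-duration
#'   parameters (ms).
#' @param n_fix_study Integer range `c(min, max)` of fixations per study
#'   trial (uniform).
#' @param phases Phases to generate (`"study"`, `"test"`).
#' @param mirror_faces Mirror the layouts of a random half of the faces of
#'   each race, emulating left-right flipped stimuli.
#' @param seed Master seed; every random choice derives from it.
#' @return A validated list of class `gc_params`.
#' @export
generator_params <- function(n_participants = 30,
                             races = RACES,
                             trials_per_race_study = 16,
                             faces_per_race = 32,
                             feature_weights = default_feature_weights(races),
                             scatter_sd = 0.4,
                             start_pull = 0.3,
                             start_decay = 0.5,
                             layout_jitter_sd = 0.3,
                             behavior = default_behavior(races),
                             behavior_sd = 0.35,
                             rt_meanlog = log(750),
                             rt_sdlog = 0.25,
                             rt_outlier_rate = 0.02,
                             rt_outlier_scale = 4,
                             fix_dur_meanlog = log(260),
                             fix_dur_sdlog = 0.3,
                             n_fix_study = c(5, 9),
                             phases = c("study", "test"),
                             mirror_faces = TRUE,
                             seed = 1) {
  races <- match.arg(races, RACES, several.ok = TRUE)
  p <- list(n_participants = as.integer(n_participants), races = races,
            trials_per_race_study = as.integer(trials_per_race_study),
            faces_per_race = as.integer(faces_per_race),
            feature_weights = feature_weights, scatter_sd = scatter_sd,
            start_pull = start_pull, start_decay = start_decay,
            layout_jitter_sd = layout_jitter_sd, behavior = behavior,
            behavior_sd = behavior_sd, rt_meanlog = rt_meanlog,
            rt_sdlog = rt_sdlog, rt_outlier_rate = rt_outlier_rate,
            rt_outlier_scale = rt_outlier_scale,
            fix_dur_meanlog = fix_dur_meanlog, fix_dur_sdlog = fix_dur_sdlog,
            n_fix_study = as.integer(n_fix_study), phases = phases,
            mirror_faces = isTRUE(mirror_faces), seed = as.integer(seed))
  validate_params(p)
  structure(p, class = "gc_params")
}

validate_params <- function(p) {
  if (p$n_participants < 1L) stop("need at least one participant")
  if (p$trials_per_race_study %% length(START_POSITIONS) != 0L)
    stop("trials_per_race_study must be divisible by the 4 start positions")
  if ("test" %in% p$phases && p$faces_per_race < 2L * p$trials_per_race_study)
    stop("faces_per_race must be at least 2 * trials_per_race_study ",
         "so the test phase has as many new as studied faces")
  w <- p$feature_weights
  if (!is.matrix(w) || !setequal(rownames(w), p$races) ||
      !identical(colnames(w), AOI_GROUPS))
    stop("feature_weights must be a races x AOI-group matrix with columns ",
         paste(AOI_GROUPS, collapse = ", "))
  if (any(w < 0) || any(abs(rowSums(w) - 1) > 1e-12))
    stop("each feature_weights row must be a probability vector summing to 1")
  if (!setequal(names(p$behavior), p$races))
    stop("behavior must be a named list with one entry per race")
  for (r in p$races) {
    b <- p$behavior[[r]]
    if (!all(c("hit_rate", "fa_rate") %in% names(b)) ||
        any(unlist(b[c("hit_rate", "fa_rate")]) <= 0) ||
        any(unlist(b[c("hit_rate", "fa_rate")]) >= 1))
      stop("behavior rates must lie strictly in (0, 1)")
  }
  stopifnot_scalar_number(p$start_pull, "start_pull", 0, 1)
  stopifnot_scalar_number(p$start_decay, "start_decay", 0, 1)
  stopifnot_scalar_number(p$scatter_sd, "scatter_sd", 1e-12, Inf)
  stopifnot_scalar_number(p$layout_jitter_sd, "layout_jitter_sd", 0, Inf)
  if (length(p$n_fix_study) != 2L || p$n_fix_study[1] < 1L ||
      p$n_fix_study[2] < p$n_fix_study[1])
    stop("n_fix_study must be c(min, max) with 1 <= min <= max")
  invisible(p)
}

#' @rdname generator_params
#' @export
default_feature_weights <- function(races = RACES) {
  w <- rbind(
    caucasian = c(0.240, 0.140, 0.200, 0.160, 0.105, 0.155),
    african   = c(0.230, 0.140, 0.190, 0.170, 0.117, 0.153),
    chinese   = c(0.228, 0.140, 0.187, 0.172, 0.115, 0.158)
  )
  colnames(w) <- AOI_GROUPS
  w[races, , drop = FALSE]
}

#' @rdname generator_params
#' @export
default_behavior <- function(races = RACES) {
  b <- list(
    caucasian = list(hit_rate = 0.70, fa_rate = 0.15),
    african   = list(hit_rate = 0.71, fa_rate = 0.17),
    chinese   = list(hit_rate = 0.64, fa_rate = 0.29)
  )
  b[races]
}

# start-side-biased label distributions (race-independent, so the race and
# start-position effects act on disjoint parameters of the label mixture)
start_side_weights <- function() {
  m <- rbind(
    left  = c(0.50, 0.10, 0.02, 0.14, 0.09, 0.15),
    right = c(0.02, 0.10, 0.50, 0.14, 0.09, 0.15),
    up    = c(0.30, 0.25, 0.30, 0.05, 0.02, 0.08),
    down  = c(0.04, 0.04, 0.04, 0.25, 0.48, 0.15)
  )
  colnames(m) <- AOI_GROUPS
  m
}

#' Generate jittered face layouts
#'
#' Draws one layout per face by jittering the centers of the five feature
#' blocks (left eye, bridge, right eye, whole nose, whole mouth) of the
#' [template_face_layout()] with independent N(0, `layout_jitter_sd`^2)
#' offsets in x and y, keeping each block's size; nose and mouth halves are
#' re-split by x bisection. Draws violating the layout invariants
#' (overlap or leaving the frame) are rejected and redrawn (up to 100
#' attempts per face). If `mirror_faces` is set, a random half of each
#' race's faces is mirrored about the frame midline. Deterministic given
#' `params$seed`.
#'
#' @param params A [generator_params()] object.
#' @return Named list of `gc_layout` objects.
#' @export
generate_face_layouts <- function(params) {
  with_seed(derive_seed(params$seed, 1), {
    layouts <- list()
    for (race in params$races) {
      ids <- sprintf("%s_%02d", substr(race, 1, 3), seq_len(params$faces_per_race))
      mirrored <- rep(FALSE, params$faces_per_race)
      if (params$mirror_faces)
        mirrored[sample.int(params$faces_per_race, params$faces_per_race %/% 2)] <- TRUE
      for (i in seq_along(ids)) {
        lay <- jitter_layout(ids[i], race, params$layout_jitter_sd)
        if (mirrored[i]) lay <- mirror_layout(lay)
        layouts[[ids[i]]] <- lay
      }
    }
    layouts
  })
}

jitter_layout <- function(face_id, race, sd) {
  tmpl <- template_face_layout(face_id, race)
  if (sd == 0) return(tmpl)
  blocks <- list(
    left_eye = "left_eye", bridge = "bridge", right_eye = "right_eye",
    nose = c("nose_left", "nose_right"), mouth = c("mouth_left", "mouth_right")
  )
  for (attempt in seq_len(100)) {
    aois <- tmpl$aois
    ok <- TRUE
    for (b in names(blocks)) {
      d <- rnorm(2, 0, sd)
      for (nm in blocks[[b]]) aois[[nm]] <- shift_rect(aois[[nm]], d[1], d[2])
    }
    # a draw is only usable if the layout invariants hold AND the four
    # equidistant start positions exist for the resulting geometry
    lay <- tryCatch({
      l <- face_layout(face_id, race, tmpl$frame[c("x0", "y0", "x1", "y1")], aois)
      compute_start_points(l)
      l
    }, error = function(e) NULL)
    if (!is.null(lay)) return(lay)
  }
  stop("could not draw a valid jittered layout for face '", face_id,
       "' in 100 attempts; reduce layout_jitter_sd")
}

#' Pre-stimulus start positions of a face
#'
#' Computes the four enforced pre-stimulus gaze locations relative to a
#' face's internal features. The left (right) start position is the unique
#' point equidistant from the centers of the nearest eye, nearest half-nose
#' and nearest half-mouth AOI — the circumcenter of those three centers.
#' The upper start position lies on the perpendicular bisector of the two
#' eye centers, above them; the lower one below the two half-mouth centers;
#' both at a distance from their defining centers equal to the mean of the
#' left and right equidistances.
#'
#' @param layout A `gc_layout`.
#' @return Data frame with columns `position`, `x`, `y`.
#' @export
compute_start_points <- function(layout) {
  cen <- aoi_centers(layout)
  left <- circumcenter(cen["left_eye", ], cen["nose_left", ], cen["mouth_left", ])
  right <- circumcenter(cen["right_eye", ], cen["nose_right", ], cen["mouth_right", ])
  d <- mean(c(left$radius, right$radius))

  up <- equidistant_point(cen["left_eye", ], cen["right_eye", ], d, upward = TRUE)
  down <- equidistant_point(cen["mouth_left", ], cen["mouth_right", ], d,
                            upward = FALSE)
  pts <- data.frame(
    position = c("left", "right", "up", "down"),
    x = c(left$center[1], right$center[1], up[1], down[1]),
    y = c(left$center[2], right$center[2], up[2], down[2]),
    stringsAsFactors = FALSE
  )
  inside <- vapply(seq_len(4), function(i) {
    any(vapply(layout$aois, rect_contains, TRUE, pts$x[i], pts$y[i]))
  }, TRUE)
  if (any(inside))
    stop("start position(s) ", paste(pts$position[inside], collapse = ", "),
         " fall inside an internal-feature AOI of face '", layout$face_id, "'")
  pts
}

# circumcenter of three points; errors when (nearly) collinear
circumcenter <- function(a, b, c) {
  ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
  dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(dd) < 1e-9)
    stop("feature centers are collinear; no equidistant point exists")
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / dd
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / dd
  list(center = c(x = unname(ux), y = unname(uy)),
       radius = sqrt((ux - ax)^2 + (uy - ay)^2))
}

# point on the perpendicular bisector of p1--p2 at distance d from both,
# on the upward (-y) or downward (+y) side
equidistant_point <- function(p1, p2, d, upward) {
  m <- (p1 + p2) / 2
  half <- sqrt(sum((p2 - p1)^2)) / 2
  if (d <= half)
    stop("required equidistance ", format(d),
         " is smaller than half the separation of the defining centers")
  u <- (p2 - p1) / (2 * half)
  n <- c(-u[2], u[1])
  if ((n[2] > 0) == upward) n <- -n
  unname(m + sqrt(d^2 - half^2) * n)
}

#' Generate the fixation sequence of one trial
#'
#' The generative scanning model is a mixture over AOI targets: the first
#' fixation lands near the face center, displaced toward the start side by
#' `start_pull`; each subsequent fixation first draws an AOI-group label —
#' from a start-side-biased distribution with probability
#' `start_pull * start_decay^(ordinal - 2)`, otherwise from
#' `feature_weights[race, ]` — and then a location from an isotropic
#' N(AOI center, `scatter_sd`^2) truncated to the AOI rectangle (for the
#' `other` label: uniform over the frame outside all AOIs). Truncation makes
#' the realized AOI of each fixation equal its sampled label, so the
#' injected mixture weights are directly recoverable from AOI frequencies.
#' Durations are log-normal. Uses the current RNG state.
#'
#' @param layout A `gc_layout`.
#' @param start One row of [compute_start_points()] (list or 1-row data
#'   frame with `position`, `x`, `y`).
#' @param race Face race (indexes `feature_weights` rows).
#' @param n_fix Number of fixations to generate.
#' @param params A [generator_params()] object.
#' @return Data frame with columns `ordinal`, `x_deg`, `y_deg`,
#'   `duration_ms`, `label`.
#' @export
generate_trial_fixations <- function(layout, start, race, n_fix, params) {
  fx <- trial_fixations_core(layout, start, race, n_fix, params)
  data.frame(ordinal = seq_len(n_fix), x_deg = fx$x, y_deg = fx$y,
             duration_ms = fx$dur, label = fx$label, stringsAsFactors = FALSE)
}

# plain-vector core, avoids data.frame overhead in bulk generation
trial_fixations_core <- function(layout, start, race, n_fix, params) {
  stopifnot(n_fix >= 1)
  ctr <- rect_center(layout$frame)
  p1 <- unname(ctr) +
    0.5 * params$start_pull * (c(start$x, start$y) - unname(ctr)) +
    rnorm(2, 0, params$scatter_sd)
  x <- numeric(n_fix); y <- numeric(n_fix)
  lab <- character(n_fix)
  x[1] <- p1[1]; y[1] <- p1[2]; lab[1] <- "first"
  if (n_fix > 1) {
    k <- seq.int(2, n_fix)
    q <- params$start_pull * params$start_decay^(k - 2)
    use_side <- runif(length(k)) < q
    sw <- start_side_weights()[start$position, ]
    rw <- params$feature_weights[race, ]
    labs <- character(length(k))
    if (any(use_side))
      labs[use_side] <- sample(AOI_GROUPS, sum(use_side), TRUE, prob = sw)
    if (any(!use_side))
      labs[!use_side] <- sample(AOI_GROUPS, sum(!use_side), TRUE, prob = rw)
    for (i in seq_along(k)) {
      pos <- sample_in_group(layout, labs[i], params$scatter_sd)
      x[k[i]] <- pos[1]; y[k[i]] <- pos[2]
    }
    lab[k] <- labs
  }
  list(x = x, y = y,
       dur = rlnorm(n_fix, params$fix_dur_meanlog, params$fix_dur_sdlog),
       label = lab)
}

group_rect <- function(layout, group) {
  a <- layout$aois
  switch(group,
         left_eye = a$left_eye, bridge = a$bridge, right_eye = a$right_eye,
         nose = rect(a$nose_left["x0"], a$nose_left["y0"],
                     a$nose_right["x1"], a$nose_right["y1"]),
         mouth = rect(a$mouth_left["x0"], a$mouth_left["y0"],
                      a$mouth_right["x1"], a$mouth_right["y1"]),
         stop("no rectangle for group '", group, "'"))
}

sample_in_group <- function(layout, group, scatter_sd) {
  if (group == "other") {
    fr <- layout$frame
    repeat {
      p <- c(runif(1, fr["x0"], fr["x1"]), runif(1, fr["y0"], fr["y1"]))
      hit <- any(vapply(layout$aois, rect_contains, TRUE, p[1], p[2]))
      if (!hit) return(p)
    }
  }
  r <- group_rect(layout, group)
  ctr <- rect_center(r)
  repeat {
    p <- ctr + rnorm(2, 0, scatter_sd)
    if (rect_contains(r, p[1], p[2])) return(unname(p))
  }
}

#' Generate one old/new response
#'
#' A studied face is judged `"old"` with the participant-adjusted hit
#' probability, a new face with the false-alarm probability; probabilities
#' are the race's configured rates shifted on the z scale by the
#' participant's bias. Reaction times are log-normal with occasional
#' injected slow outliers (rate `rt_outlier_rate`, factor
#' `rt_outlier_scale`) to exercise the RT filter. Uses the current RNG
#' state.
#'
#' @param race Face race.
#' @param was_studied Logical.
#' @param params A [generator_params()] object.
#' @param z_shift Numeric `c(hit, fa)` participant shift on the z scale.
#' @return List with `judgment` and `rt_ms`.
#' @export
generate_responses <- function(race, was_studied, params, z_shift = c(0, 0)) {
  b <- params$behavior[[race]]
  p_old <- if (was_studied) pnorm(qnorm(b$hit_rate) + z_shift[1])
           else pnorm(qnorm(b$fa_rate) + z_shift[2])
  judgment <- if (runif(1) < p_old) "old" else "new"
  rt <- rlnorm(1, params$rt_meanlog, params$rt_sdlog)
  if (runif(1) < params$rt_outlier_rate) rt <- rt * params$rt_outlier_scale
  list(judgment = judgment, rt_ms = rt)
}

#' Generate a full synthetic dataset
#'
#' Builds the complete balanced design and simulates every trial. Per
#' participant: `trials_per_race_study` study faces per race, start
#' positions balanced within race; at test (if generated) the studied faces
#' reappear — half with the same start position as at study, half with the
#' opposite one (left/right, up/down) — together with an equal number of
#' new faces with balanced start positions, and an old/new response with
#' reaction time is simulated for every test trial. Deterministic given
#' `params$seed`.
#'
#' @param params A [generator_params()] object.
#' @return A validated [gc_dataset()].
#' @export
generate_dataset <- function(params) {
  if (!inherits(params, "gc_params")) params <- do.call(generator_params, params)
  layouts <- generate_face_layouts(params)
  starts <- lapply(layouts, compute_start_points)
  races <- params$races
  tpr <- params$trials_per_race_study
  per_start <- tpr %/% 4L
  opposite <- c(left = "right", right = "left", up = "down", down = "up")

  rows <- with_seed(derive_seed(params$seed, 2), {
    out <- vector("list", params$n_participants)
    for (pi in seq_len(params$n_participants)) {
      pid <- sprintf("p%02d", pi)
      z_shift <- rnorm(2, 0, params$behavior_sd)
      plan <- list()
      for (race in races) {
        pool <- grep(paste0("^", substr(race, 1, 3), "_"), names(layouts),
                     value = TRUE)
        studied <- sample(pool, tpr)
        st <- sample(rep(START_POSITIONS, per_start))
        plan[[race]] <- list(studied = studied, study_start = st)
        if ("test" %in% params$phases) {
          # half of studied faces keep their start position at test, half
          # flip to the opposite side; counts are kept equal within each
          # opposite-position pair so test-phase starts stay balanced
          n_same <- c(left = 0L, right = 0L, up = 0L, down = 0L)
          odd <- per_start %% 2L == 1L
          lr <- per_start %/% 2L + (odd && runif(1) < 0.5)
          n_same[c("left", "right")] <- lr
          n_same[c("up", "down")] <- per_start - lr
          same <- unlist(lapply(split(seq_len(tpr), st), function(ix) {
            k <- n_same[[st[ix[1]]]]
            if (k > 0) ix[sample.int(length(ix), k)] else integer(0)
          }))
          plan[[race]]$test_start <-
            ifelse(seq_len(tpr) %in% same, st, opposite[st])
          plan[[race]]$new_faces <- sample(setdiff(pool, studied), tpr)
          plan[[race]]$new_start <- sample(rep(START_POSITIONS, per_start))
        }
      }
      trials <- list()
      if ("study" %in% params$phases) {
        for (race in races) {
          pl <- plan[[race]]
          for (i in seq_len(tpr)) {
            trials[[length(trials) + 1L]] <- list(
              phase = "study", face_id = pl$studied[i], race = race,
              start = pl$study_start[i], was_studied = NA)
          }
        }
      }
      if ("test" %in% params$phases) {
        for (race in races) {
          pl <- plan[[race]]
          for (i in seq_len(tpr)) {
            trials[[length(trials) + 1L]] <- list(
              phase = "test", face_id = pl$studied[i], race = race,
              start = pl$test_start[i], was_studied = TRUE)
            trials[[length(trials) + 1L]] <- list(
              phase = "test", face_id = pl$new_faces[i], race = race,
              start = pl$new_start[i], was_studied = FALSE)
          }
        }
      }
      # randomize presentation order within phase
      phase_of <- vapply(trials, `[[`, "", "phase")
      ord <- c(sample(which(phase_of == "study")),
               sample(which(phase_of == "test")))
      trials <- trials[ord]
      idx <- c(study = 0L, test = 0L)
      nt <- length(trials)
      m <- list(phase = character(nt), trial_index = integer(nt),
                face_id = character(nt), race = character(nt),
                start = character(nt), was_studied = logical(nt),
                judgment = rep(NA_character_, nt), rt = rep(NA_real_, nt),
                n_fix = integer(nt))
      fxs <- vector("list", nt)
      for (ti in seq_along(trials)) {
        tr <- trials[[ti]]
        idx[tr$phase] <- idx[tr$phase] + 1L
        lay <- layouts[[tr$face_id]]
        sp <- starts[[tr$face_id]]
        sp <- sp[sp$position == tr$start, ]
        if (tr$phase == "study") {
          n_fix <- sample(seq.int(params$n_fix_study[1], params$n_fix_study[2]), 1)
        } else {
          n_fix <- 6L
          resp <- generate_responses(tr$race, tr$was_studied, params, z_shift)
          m$judgment[ti] <- resp$judgment; m$rt[ti] <- resp$rt_ms
        }
        m$phase[ti] <- tr$phase; m$trial_index[ti] <- idx[[tr$phase]]
        m$face_id[ti] <- tr$face_id; m$race[ti] <- tr$race
        m$start[ti] <- tr$start; m$was_studied[ti] <- tr$was_studied
        m$n_fix[ti] <- n_fix
        fxs[[ti]] <- trial_fixations_core(lay, sp, tr$race, n_fix, params)
      }
      rep_tr <- rep.int(seq_len(nt), m$n_fix)
      out[[pi]] <- data.frame(
        participant_id = pid, phase = m$phase[rep_tr],
        trial_index = m$trial_index[rep_tr], face_id = m$face_id[rep_tr],
        race = m$race[rep_tr], start_position = m$start[rep_tr],
        was_studied = m$was_studied[rep_tr],
        ordinal = unlist(lapply(m$n_fix, seq_len)),
        x_deg = unlist(lapply(fxs, `[[`, "x")),
        y_deg = unlist(lapply(fxs, `[[`, "y")),
        duration_ms = unlist(lapply(fxs, `[[`, "dur")),
        judgment = m$judgment[rep_tr], rt_ms = m$rt[rep_tr],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  gc_dataset(rows, layouts)
}
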