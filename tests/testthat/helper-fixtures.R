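# Shared fixtures: everything is built in code at test time.

races3 <- c("caucasian", "african", "chinese")
aoi_groups6 <- c("left_eye", "bridge", "right_eye", "nose", "mouth", "other")

# two undistorted template layouts of different races
tiny_layouts <- function() {
  list(cau_01 = template_face_layout("cau_01", "caucasian"),
       chi_01 = template_face_layout("chi_01", "chinese"))
}

# one well-formed fixation row (study phase by default)
fix_row <- function(participant_id = "p01", phase = "study", trial_index = 1L,
                    face_id = "cau_01", race = "caucasian",
                    start_position = "left", ordinal = 1L,
                    x_deg = 8, y_deg = 6, duration_ms = 250,
                    was_studied = NA, judgment = NA_character_,
                    rt_ms = NA_real_) {
  data.frame(participant_id = participant_id, phase = phase,
             trial_index = trial_index, face_id = face_id, race = race,
             start_position = start_position, was_studied = was_studied,
             ordinal = ordinal, x_deg = x_deg, y_deg = y_deg,
             duration_ms = duration_ms, judgment = judgment, rt_ms = rt_ms,
             stringsAsFactors = FALSE)
}

# a study trial of n fixations at given locations
fix_trial <- function(xy, participant_id = "p01", trial_index = 1L,
                      face_id = "cau_01", race = "caucasian",
                      start_position = "left", phase = "study", ...) {
  do.call(rbind, lapply(seq_len(nrow(xy)), function(i)
    fix_row(participant_id = participant_id, phase = phase,
            trial_index = trial_index, face_id = face_id, race = race,
            start_position = start_position, ordinal = i,
            x_deg = xy[i, 1], y_deg = xy[i, 2], ...)))
}

# small but complete generated dataset (both phases)
small_dataset <- function(seed = 11, ...) {
  generate_dataset(generator_params(n_participants = 2,
                                    trials_per_race_study = 4,
                                    faces_per_race = 8, seed = seed, ...))
}

# minimal two-participant, two-condition dataset for permutation tests:
# per participant, one study trial per race, each with `n_fix` fixations at
# given deterministic locations (list race -> n x 2 matrix)
two_condition_dataset <- function(locs_a, locs_b, participants = c("p01", "p02"),
                                  jitter = 0) {
  lays <- tiny_layouts()
  rows <- list()
  for (pi in seq_along(participants)) {
    off <- (pi - 1) * jitter
    rows[[length(rows) + 1L]] <- fix_trial(
      locs_a + off, participant_id = participants[pi], trial_index = 1L,
      face_id = "cau_01", race = "caucasian")
    rows[[length(rows) + 1L]] <- fix_trial(
      locs_b + off, participant_id = participants[pi], trial_index = 2L,
      face_id = "chi_01", race = "chinese")
  }
  gc_dataset(do.call(rbind, rows), lays)
}

# small grid for fast density tests
tiny_grid <- function() grid_spec(32, 32, 0.5)
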