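#' @title Synthetic gaze, video and cohort generator
#' @description
#' Generates stimulus videos with known salient patches and areas of
#' interest, binocular gaze/pupil streams with planted fixations, blinks and
#' stimulus-locked pupil responses, and cohort tables with planted
#' group-level effects, so that every downstream stage of the pipeline can
#' be validated against ground truth. All generators are deterministic given
#' their seed, and planted values are returned alongside the artifacts.
#' @name synthgen
NULL

#' Specify a synthetic scene
#'
#' @param duration_ms Scene duration (> 0).
#' @param category `"human"` or `"non-human"`.
#' @param fps Frame rate (default 25).
#' @param static_patch Logical; render one static high-contrast patch.
#' @param moving_patch Logical; render one moving patch.
#' @param moving_speed_px Patch speed in frame pixels per frame (default 2).
#' @param background Background grey level in `[0, 1]` (default 0.5).
#' @param age_restricted Logical flag carried through the manifest.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(duration_ms = 4000, category = c("human", "non-human"),
                       fps = 25, static_patch = TRUE, moving_patch = TRUE,
                       moving_speed_px = 2, background = 0.5,
                       age_restricted = FALSE) {
  category <- match.arg(category)
  if (duration_ms <= 0) stop("duration_ms must be > 0")
  if (fps <= 0) stop("fps must be > 0")
  structure(list(duration_ms = duration_ms, category = category, fps = fps,
                 static_patch = static_patch, moving_patch = moving_patch,
                 moving_speed_px = moving_speed_px, background = background,
                 age_restricted = age_restricted),
            class = "scene_spec")
}

#' Generate a synthetic video for one scene
#'
#' Renders RGB frames on a uniform background with (optionally) one static
#' high-contrast patch and one moving patch, plus nested binary
#' area-of-interest masks (eyes and mouth inside face, face inside body) for
#' human scenes. Frames are rendered at a reduced grid that is aligned to the
#' screen (`frame_width` pixels across the full display width), which keeps
#' feature-map computation tractable; the mapping back to screen pixels is
#' recorded in the result.
#'
#' @param spec A [scene_spec()].
#' @param geometry A [screen_geometry()].
#' @param seed Integer seed; identical (spec, seed) gives identical frames.
#' @param frame_width Frame grid width in pixels (default 96).
#' @return A list of class `synthetic_video`: `frames` (list of
#'   height x width x 3 arrays in `[0,1]`), `fps`, `duration_ms`,
#'   `category`, `width`, `height`, `px_per_screen_px`, `aoi` (per-label
#'   list of per-frame logical masks, human scenes only), and `truth` with
#'   the static-patch box and the moving-patch per-frame track.
#' @export
generate_video <- function(spec, geometry, seed = 1, frame_width = 96) {
  stopifnot(inherits(spec, "scene_spec"))
  n_frames <- max(round(spec$duration_ms / 1000 * spec$fps), 0)
  if (n_frames == 0) stop("scene too short: zero frames requested")
  set.seed(seed)
  w <- frame_width
  h <- max(round(w * geometry$height_px / geometry$width_px), 8)
  bg <- spec$background

  # static patch: high-contrast checker block in one quadrant
  sp_size <- max(round(w / 8), 4)
  sp_x <- round(w * 0.70); sp_y <- round(h * 0.25)
  static_box <- c(x0 = sp_x, y0 = sp_y, x1 = sp_x + sp_size - 1,
                  y1 = sp_y + sp_size - 1)

  # moving patch: starts lower-left, translates rightward, wraps
  mp_size <- max(round(w / 12), 3)
  mp_y <- round(h * 0.75)
  mp_x0 <- round(w * 0.10)
  track <- data.frame(frame = seq_len(n_frames))
  track$x0 <- ((mp_x0 - 1 + (track$frame - 1) * spec$moving_speed_px) %%
                 (w - mp_size)) + 1
  track$y0 <- mp_y
  track$x1 <- track$x0 + mp_size - 1
  track$y1 <- track$y0 + mp_size - 1

  checker <- outer(seq_len(sp_size), seq_len(sp_size),
                   function(i, j) (i + j) %% 2)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    fr <- array(bg, dim = c(h, w, 3))
    if (spec$static_patch) {
      blk <- ifelse(checker == 1, 1, 0)
      for (ch in 1:3) fr[sp_y:(sp_y + sp_size - 1),
                         sp_x:(sp_x + sp_size - 1), ch] <- blk
    }
    if (spec$moving_patch) {
      # dark blue patch: strong grayscale contrast against the background
      mp_col <- c(0.05, 0.05, 0.45)
      for (ch in 1:3) {
        fr[track$y0[f]:track$y1[f], track$x0[f]:track$x1[f], ch] <- mp_col[ch]
      }
    }
    frames[[f]] <- fr
  }

  aoi <- NULL
  aoi_boxes <- NULL
  if (spec$category == "human") {
    # nested rectangular person: body > face > {eyes, mouth}
    body <- c(x0 = round(w * 0.30), y0 = round(h * 0.20),
              x1 = round(w * 0.55), y1 = round(h * 0.90))
    face <- c(x0 = round(w * 0.34), y0 = round(h * 0.22),
              x1 = round(w * 0.51), y1 = round(h * 0.42))
    eyes <- c(x0 = round(w * 0.36), y0 = round(h * 0.25),
              x1 = round(w * 0.49), y1 = round(h * 0.30))
    mouth <- c(x0 = round(w * 0.37), y0 = round(h * 0.36),
               x1 = round(w * 0.48), y1 = round(h * 0.40))
    aoi_boxes <- list(body = body, face = face, eyes = eyes, mouth = mouth)
    mask_of <- function(b) {
      m <- matrix(FALSE, h, w)
      m[b["y0"]:b["y1"], b["x0"]:b["x1"]] <- TRUE
      m
    }
    aoi <- lapply(aoi_boxes, function(b) {
      rep(list(mask_of(b)), n_frames)      # static person; frame-aligned
    })
    # draw the person as a darker region so AOIs have visual support
    for (f in seq_len(n_frames)) {
      frames[[f]][body["y0"]:body["y1"], body["x0"]:body["x1"], ] <- 0.35
      frames[[f]][face["y0"]:face["y1"], face["x0"]:face["x1"], ] <- 0.75
    }
  }

  structure(list(
    frames = frames, fps = spec$fps, duration_ms = spec$duration_ms,
    category = spec$category, width = w, height = h,
    px_per_screen_px = w / geometry$width_px,
    age_restricted = spec$age_restricted,
    aoi = aoi,
    truth = list(static_patch = if (spec$static_patch) static_box,
                 moving_track = if (spec$moving_patch) track,
                 aoi_boxes = aoi_boxes, seed = seed)
  ), class = "synthetic_video")
}

#' Default participant parameters for the gaze generator
#'
#' @param jitter_sd_px Within-fixation gaze jitter SD in screen pixels. The
#'   within-fixation noise of real trackers is not characterised here; this
#'   is a free parameter (default 2 px, about 0.05 degrees).
#' @param pupil_baseline_mm Baseline pupil diameter (default 3.6 mm).
#' @param pupil_amplitude_mm Amplitude of the stimulus-locked pupil response
#'   (default 0.15 mm).
#' @param pupil_latency_ms Stimulus-to-pupil latency (default 300 ms).
#' @param pupil_noise_sd_mm Additive pupil measurement noise (default 0.01).
#' @param blink_rate Expected fraction of time lost to blinks (default 0.05).
#' @param blink_duration_ms Mean blink duration (default 150 ms).
#' @param pupil_shape `"gamma"` for a gamma-function impulse response (the
#'   standard pupillometry convention) or `"step"` for a sustained step.
#' @return A list of class `participant_params`.
#' @export
participant_params <- function(jitter_sd_px = 2, pupil_baseline_mm = 3.6,
                               pupil_amplitude_mm = 0.15,
                               pupil_latency_ms = 300,
                               pupil_noise_sd_mm = 0.01,
                               blink_rate = 0.05, blink_duration_ms = 150,
                               pupil_shape = c("gamma", "step")) {
  structure(list(jitter_sd_px = jitter_sd_px,
                 pupil_baseline_mm = pupil_baseline_mm,
                 pupil_amplitude_mm = pupil_amplitude_mm,
                 pupil_latency_ms = pupil_latency_ms,
                 pupil_noise_sd_mm = pupil_noise_sd_mm,
                 blink_rate = blink_rate,
                 blink_duration_ms = blink_duration_ms,
                 pupil_shape = match.arg(pupil_shape)),
            class = "participant_params")
}

#' Plant a fixation plan over a sequence of scenes
#'
#' Plants non-overlapping fixations separated by short saccade gaps. Each
#' fixation lands either on a salient patch, on the face area (human
#' scenes), or at a random screen location, with configurable probabilities.
#'
#' @param scenes List of [scene_spec()]s (in presentation order).
#' @param geometry A [screen_geometry()].
#' @param seed Integer seed.
#' @param fix_duration_ms Range of planted fixation durations (default
#'   `c(200, 600)`).
#' @param saccade_ms Range of inter-fixation saccade durations, default
#'   `c(20, 40)`.
#' @param p_on_face Probability a fixation lands on the face (human scenes).
#' @param p_on_patch Probability a fixation lands on the static patch.
#' @param min_separation_deg Minimum angular separation between consecutive
#'   planted centroids (default 1.5 degrees, comfortably above the 0.5
#'   degree merge rule so planted fixations stay recoverable as distinct
#'   events).
#' @return Data frame: scene number, global/in-scene onset and offset (ms),
#'   planted centroid in screen px, and the landing target
#'   (`"face"`, `"patch"`, `"random"`).
#' @export
plant_fixations <- function(scenes, geometry, seed = 1,
                            fix_duration_ms = c(200, 600),
                            saccade_ms = c(20, 40),
                            p_on_face = 0.4, p_on_patch = 0.2,
                            min_separation_deg = 1.5) {
  set.seed(seed)
  rows <- list()
  t0 <- 0
  margin <- 0.05
  prev_cx <- NA_real_; prev_cy <- NA_real_
  for (s in seq_along(scenes)) {
    sc <- scenes[[s]]
    t <- t0 + stats::runif(1, 30, 80)       # scene-onset latency
    end <- t0 + sc$duration_ms
    while (TRUE) {
      dur <- stats::runif(1, fix_duration_ms[1], fix_duration_ms[2])
      if (t + dur > end) break
      for (try in 1:50) {
        u <- stats::runif(1)
        if (sc$category == "human" && u < p_on_face) {
          target <- "face"
          cx <- stats::runif(1, 0.36, 0.49) * geometry$width_px
          cy <- stats::runif(1, 0.24, 0.40) * geometry$height_px
        } else if (u < p_on_face + p_on_patch) {
          target <- "patch"
          cx <- stats::runif(1, 0.71, 0.78) * geometry$width_px
          cy <- stats::runif(1, 0.26, 0.33) * geometry$height_px
        } else {
          target <- "random"
          cx <- stats::runif(1, margin, 1 - margin) * geometry$width_px
          cy <- stats::runif(1, margin, 1 - margin) * geometry$height_px
        }
        if (is.na(prev_cx) ||
              angular_distance(prev_cx, prev_cy, cx, cy, geometry) >=
                min_separation_deg) break
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scene = s, onset_ms = t, offset_ms = t + dur,
        onset_in_scene_ms = t - t0, cx_px = cx, cy_px = cy, target = target)
      prev_cx <- cx; prev_cy <- cy
      t <- t + dur + stats::runif(1, saccade_ms[1], saccade_ms[2])
    }
    t0 <- end
  }
  if (!length(rows)) stop("no fixation fits the requested scenes")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# gamma-function pupil impulse response (Hoeks-Levelt form), unit peak
pupil_impulse <- function(t_ms, n = 10.1, t_max_ms = 930) {
  h <- (t_ms / t_max_ms)^n * exp(n * (1 - t_ms / t_max_ms))
  h[t_ms < 0] <- 0
  h
}

#' Generate a raw binocular gaze stream from a fixation plan
#'
#' Renders a planted fixation plan into Tobii-like raw samples: within
#' fixations gaze jitters around the planted centroid, between fixations it
#' moves linearly (a saccade), blinks produce contiguous invalid runs in
#' both eyes, and the pupil trace is the participant baseline plus
#' stimulus-locked responses (one per fixation onset, delayed by the
#' configured latency) plus noise.
#'
#' @param plan Fixation plan from [plant_fixations()].
#' @param params A [participant_params()].
#' @param geometry A [screen_geometry()] (supplies the sampling rate, which
#'   must be 120 or 300 Hz).
#' @param seed Integer seed.
#' @param total_ms Stream length; defaults to the plan's last offset.
#' @param pupil_gain Multiplier on the per-event response amplitude, one
#'   value recycled over fixations (lets cohort effects scale responses per
#'   scene category).
#' @return Raw binocular sample data frame (see [binocular_combine()]).
#' @export
generate_gaze_stream <- function(plan, params, geometry, seed = 1,
                                 total_ms = NULL, pupil_gain = 1) {
  if (!geometry$sampling_rate_hz %in% c(120, 300)) {
    stop("sampling rate must be 120 or 300 Hz")
  }
  if (any(plan$cx_px < 0 | plan$cx_px > geometry$width_px |
            plan$cy_px < 0 | plan$cy_px > geometry$height_px)) {
    stop("planted fixations must lie on-screen")
  }
  set.seed(seed)
  dt <- 1000 / geometry$sampling_rate_hz
  if (is.null(total_ms)) total_ms <- max(plan$offset_ms) + 100
  ts <- seq(0, total_ms, by = dt)
  n <- length(ts)
  gain <- rep_len(pupil_gain, nrow(plan))

  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  for (i in seq_len(nrow(plan))) {
    infix <- ts >= plan$onset_ms[i] & ts < plan$offset_ms[i]
    x[infix] <- plan$cx_px[i]
    y[infix] <- plan$cy_px[i]
    if (i < nrow(plan)) {
      # hold the old position through the gap, then a short ballistic
      # saccade (linear, <= 30 ms) completing one sample before the next
      # onset so the first on-target sample already has fixation velocity
      gap <- ts >= plan$offset_ms[i] & ts < plan$onset_ms[i + 1L]
      if (any(gap)) {
        t_land <- plan$onset_ms[i + 1L] - dt
        t_s <- max(plan$offset_ms[i], t_land - 30)
        f <- if (t_land > t_s) {
          pmin(pmax((ts[gap] - t_s) / (t_land - t_s), 0), 1)
        } else {
          rep(1, sum(gap))
        }
        x[gap] <- plan$cx_px[i] + f * (plan$cx_px[i + 1L] - plan$cx_px[i])
        y[gap] <- plan$cy_px[i] + f * (plan$cy_px[i + 1L] - plan$cy_px[i])
      }
    }
  }
  # leading/trailing samples hold the nearest planted position
  first_def <- which(is.finite(x))[1]
  if (is.na(first_def)) stop("empty fixation plan")
  x[seq_len(first_def)] <- x[first_def]; y[seq_len(first_def)] <- y[first_def]
  last_def <- max(which(is.finite(x)))
  if (last_def < n) {
    x[(last_def + 1L):n] <- x[last_def]; y[(last_def + 1L):n] <- y[last_def]
  }
  jx <- x + stats::rnorm(n, 0, params$jitter_sd_px)
  jy <- y + stats::rnorm(n, 0, params$jitter_sd_px)

  # pupil: baseline + delayed per-fixation response + noise
  pup <- rep(params$pupil_baseline_mm, n)
  for (i in seq_len(nrow(plan))) {
    t_rel <- ts - (plan$onset_ms[i] + params$pupil_latency_ms)
    shape <- if (params$pupil_shape == "gamma") {
      pupil_impulse(t_rel)
    } else {
      as.numeric(t_rel >= 0)
    }
    pup <- pup + params$pupil_amplitude_mm * gain[i] * shape
  }
  pup <- pup + stats::rnorm(n, 0, params$pupil_noise_sd_mm)

  # blinks: Poisson process of invalid runs covering ~blink_rate of time;
  # pre-roll samples before the first planted fixation are invalid (the
  # tracker has not locked on yet), so detection starts at the first onset
  valid <- ts >= plan$onset_ms[1]
  if (params$blink_rate > 0) {
    if (params$blink_rate >= 1) {
      valid[] <- FALSE
    } else {
      n_blinks <- stats::rpois(1, params$blink_rate * total_ms /
                                 params$blink_duration_ms)
      if (n_blinks > 0) {
        starts <- sort(stats::runif(n_blinks, 0, total_ms))
        for (b in starts) {
          len <- stats::rexp(1, 1 / params$blink_duration_ms)
          valid[ts >= b & ts < b + len] <- FALSE
        }
      }
    }
  }

  data.frame(
    timestamp_ms = ts,
    gx_left_px = jx, gy_left_px = jy,
    gx_right_px = jx + stats::rnorm(n, 0, params$jitter_sd_px / 2),
    gy_right_px = jy + stats::rnorm(n, 0, params$jitter_sd_px / 2),
    pupil_left_mm = pup, pupil_right_mm = pup,
    valid_left = valid, valid_right = valid
  )
}

#' Specify a synthetic cohort design
#'
#' Planted effects are on the standardized scale of the downstream mixed
#' models: `face_gaze_group` shifts the probability that an autistic
#' participant's fixation lands on the face, and `pupil_interaction` scales
#' the pupil-response amplitude by group x scene category (positive values
#' give the ASD group larger responses for non-human and smaller for human
#' scenes).
#'
#' @param n_per_group Participants per group (>= 2).
#' @param n_scenes Number of scenes (half human, half non-human).
#' @param scene_duration_ms Scene duration (default 4000).
#' @param face_gaze_group Group shift in on-face landing probability for the
#'   ASD group (default -0.12).
#' @param pupil_interaction Group x category amplitude modulation (default
#'   0.3).
#' @param missing_covariate_rate Fraction of symptom-score cells set missing
#'   completely at random (default 0.05).
#' @param sampling_rate_hz 120 or 300.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 4, n_scenes = 4,
                          scene_duration_ms = 4000,
                          face_gaze_group = -0.12,
                          pupil_interaction = 0.3,
                          missing_covariate_rate = 0.05,
                          sampling_rate_hz = 120) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (n_scenes < 1) stop("n_scenes must be >= 1")
  structure(list(n_per_group = n_per_group, n_scenes = n_scenes,
                 scene_duration_ms = scene_duration_ms,
                 face_gaze_group = face_gaze_group,
                 pupil_interaction = pupil_interaction,
                 missing_covariate_rate = missing_covariate_rate,
                 sampling_rate_hz = sampling_rate_hz),
            class = "cohort_design")
}

#' Generate a synthetic cohort: participants, streams, truth
#'
#' Draws a participant table (group, sex, age 6-30 y, perceptual IQ, symptom
#' scores with planted group differences, data-quality metrics, missing
#' covariate cells), builds the scene list (alternating human / non-human),
#' and renders one raw gaze stream per participant with the planted
#' group-level effects routed through the stream generator.
#'
#' @param design A [cohort_design()].
#' @param geometry A [screen_geometry()]; its sampling rate is overridden by
#'   the design.
#' @param seed Integer seed.
#' @return List of class `synthetic_cohort`: `participants` (table),
#'   `scenes` (list of [scene_spec()]s), `streams` (named list of raw sample
#'   frames), `plans` (planted fixation plans), and `truth` (the planted
#'   effect sizes and the seed).
#' @export
generate_cohort <- function(design, geometry = screen_geometry(), seed = 1) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed)
  geometry <- screen_geometry(
    display_width_mm = geometry$display_width_mm,
    display_height_mm = geometry$display_height_mm,
    width_px = geometry$width_px, height_px = geometry$height_px,
    viewing_distance_mm = geometry$viewing_distance_mm,
    sampling_rate_hz = design$sampling_rate_hz)

  n <- 2 * design$n_per_group
  group <- rep(c("ASD", "TD"), each = design$n_per_group)
  part <- data.frame(
    participant = sprintf("p%03d", seq_len(n)),
    group = group,
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.28, 0.72)),
    age = round(stats::runif(n, 6, 30), 1),
    perceptual_iq = round(stats::rnorm(n, 103, 17)),
    srs_score = round(stats::rnorm(n, ifelse(group == "ASD", 97, 28), 22)),
    adhd_inattention = round(pmax(stats::rnorm(
      n, ifelse(group == "ASD", 4.4, 1.2), 2.5), 0), 1),
    anxiety_score = round(pmax(stats::rnorm(
      n, ifelse(group == "ASD", 15, 7), 8), 0), 1),
    accuracy_z = round(stats::rnorm(n), 2),
    precision_z = round(stats::rnorm(n), 2)
  )
  part$perceptual_iq <- pmin(pmax(part$perceptual_iq, 61), 138)
  for (v in c("adhd_inattention", "anxiety_score")) {
    miss <- stats::runif(n) < design$missing_covariate_rate
    part[[v]][miss] <- NA
  }

  scenes <- lapply(seq_len(design$n_scenes), function(s) {
    scene_spec(duration_ms = design$scene_duration_ms,
               category = if (s %% 2 == 1) "human" else "non-human")
  })
  categories <- vapply(scenes, `[[`, "", "category")

  streams <- vector("list", n); names(streams) <- part$participant
  plans <- vector("list", n); names(plans) <- part$participant
  for (i in seq_len(n)) {
    p_face <- 0.40 + if (group[i] == "ASD") design$face_gaze_group else 0
    plan <- plant_fixations(scenes, geometry, seed = seed * 1000 + i,
                            p_on_face = p_face)
    # group x category pupil gain: deviation-coded planted interaction
    g <- if (group[i] == "ASD") 0.5 else -0.5
    ccat <- ifelse(categories[plan$scene] == "human", 0.5, -0.5)
    gain <- 1 - design$pupil_interaction * 2 * g * ccat
    params <- participant_params(
      pupil_baseline_mm = stats::rnorm(1, 3.65, 0.5))
    streams[[i]] <- generate_gaze_stream(
      plan, params, geometry, seed = seed * 1000 + 500 + i,
      total_ms = design$n_scenes * design$scene_duration_ms,
      pupil_gain = gain)
    plans[[i]] <- plan
  }

  structure(list(
    participants = part, scenes = scenes, streams = streams, plans = plans,
    geometry = geometry,
    truth = list(face_gaze_group = design$face_gaze_group,
                 pupil_interaction = design$pupil_interaction,
                 base_face_prob = 0.40, seed = seed)
  ), class = "synthetic_cohort")
}

#' Simulate a long-format fixation-record table with planted model structure
#'
#' Draws analysis records directly from the linear mixed model the inference
#' stage assumes, without rendering videos or streams: crossed random
#' intercepts for participant and scene, deviation-coded group (ASD +0.5,
#' TD -0.5) and category (human +0.5, non-human -0.5) effects, a planted
#' group x category interaction on the pupillary response, a cubic time
#' trend over the 0-5000 ms scene window, and a planted group effect on the
#' on-face indicator. Residual plus random-intercept variance is scaled to
#' about 1 so planted coefficients are on the standardized-beta scale.
#'
#' @param n_per_group Participants per group.
#' @param n_scenes Number of scenes (alternating human / non-human).
#' @param fixations_per_scene Records per participant x scene.
#' @param effects Named list of planted effects: `pupil_group`,
#'   `pupil_category`, `pupil_interaction`, `face_group` (probability
#'   shift), plus variance components `sd_participant`, `sd_scene`,
#'   `sd_resid`.
#' @param seed Integer seed.
#' @return A data frame of fixation records (one row per fixation) with the
#'   covariates the model stage expects, and the planted values in
#'   `attr(,"truth")`.
#' @export
simulate_fixation_records <- function(n_per_group = 20, n_scenes = 10,
                                      fixations_per_scene = 5,
                                      effects = list(), seed = 1) {
  ef <- utils::modifyList(list(
    pupil_group = 0, pupil_category = 0.2, pupil_interaction = 0,
    face_group = 0, sd_participant = 0.4, sd_scene = 0.3, sd_resid = 0.85,
    time_poly = c(0.1, -0.05, 0.02)), effects)
  set.seed(seed)
  n <- 2 * n_per_group
  group <- rep(c("ASD", "TD"), each = n_per_group)
  g <- ifelse(group == "ASD", 0.5, -0.5)
  cat_lab <- ifelse(seq_len(n_scenes) %% 2 == 1, "human", "non-human")
  cc <- ifelse(cat_lab == "human", 0.5, -0.5)
  u_p <- stats::rnorm(n, 0, ef$sd_participant)
  u_s <- stats::rnorm(n_scenes, 0, ef$sd_scene)
  age <- stats::runif(n, 6, 30)
  iq <- stats::rnorm(n, 103, 17)

  idx <- expand.grid(fix = seq_len(fixations_per_scene),
                     scene = seq_len(n_scenes), part = seq_len(n))
  m <- nrow(idx)
  time_ms <- stats::runif(m, 0, 5000)
  tt <- time_ms / 5000
  time_trend <- ef$time_poly[1] * tt + ef$time_poly[2] * tt^2 +
    ef$time_poly[3] * tt^3
  pupil <- ef$pupil_group * g[idx$part] +
    ef$pupil_category * cc[idx$scene] +
    ef$pupil_interaction * g[idx$part] * cc[idx$scene] +
    time_trend + u_p[idx$part] + u_s[idx$scene] +
    stats::rnorm(m, 0, ef$sd_resid)

  p_face <- 0.40 + ef$face_group * (g[idx$part] + 0.5)   # shift for ASD only
  on_face <- stats::runif(m) < p_face
  on_face[cat_lab[idx$scene] == "non-human"] <- NA

  out <- data.frame(
    participant = sprintf("p%03d", idx$part),
    group = factor(group[idx$part], levels = c("ASD", "TD")),
    scene = sprintf("s%02d", idx$scene),
    category = factor(cat_lab[idx$scene], levels = c("human", "non-human")),
    time_in_scene_ms = time_ms,
    pupil_response = 1 + 0.1 * pupil,   # relative scale around 1
    gaze_physical_salience = stats::runif(m),
    gaze_motion_salience = stats::runif(m),
    luminance = stats::runif(m),
    on_face = on_face,
    sex = sample(c("female", "male"), n, TRUE)[idx$part],
    age = age[idx$part],
    perceptual_iq = iq[idx$part]
  )
  attr(out, "truth") <- ef
  out
}
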