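geom <- screen_geometry()
dt <- 1000 / geom$sampling_rate_hz

test_that("binocular combination averages valid eyes and flags missing", {
  raw <- data.frame(timestamp_ms = c(0, dt, 2 * dt),
                    gx_left_px = c(100, 100, NA),
                    gy_left_px = c(100, 100, NA),
                    gx_right_px = c(110, NA, NA),
                    gy_right_px = c(100, NA, NA),
                    pupil_left_mm = c(3.5, 3.5, NA),
                    pupil_right_mm = c(3.7, NA, NA),
                    valid_left = c(TRUE, TRUE, FALSE),
                    valid_right = c(TRUE, FALSE, FALSE))
  cyc <- binocular_combine(raw)
  expect_equal(cyc$x, c(105, 100, NA))           # mean, then left fallback
  expect_equal(cyc$pupil_mm, c(3.6, 3.5, NA))
  expect_equal(cyc$valid, c(TRUE, TRUE, FALSE))
  expect_error(binocular_combine(raw[0, ]), "empty")
})

test_that("smoothing is a fixed point on constant traces and attenuates
           sub-scale excursions", {
  n <- 60
  cyc <- binocular_combine(make_raw((seq_len(n) - 1) * dt, 400, 300))
  sm <- smooth_gaze(cyc, geom)
  expect_equal(sm$x, cyc$x)
  expect_equal(sm$y, cyc$y)

  # single 2 mm excursion is pulled back toward its neighbours
  exc <- cyc
  exc$x[30] <- 400 + mm_to_px(2, geom)
  sme <- smooth_gaze(exc, geom)
  expect_lt(abs(sme$x[30] - 400), abs(exc$x[30] - 400))

  # an all-missing trace stays all-missing
  mis <- cyc
  mis$x <- NA_real_; mis$y <- NA_real_; mis$valid <- FALSE
  smm <- smooth_gaze(mis, geom)
  expect_true(all(is.na(smm$x)))
})

test_that("gap interpolation follows the 100 ms / 1 degree rule", {
  n <- 60
  base_x <- rep(400, n)
  mk_gap <- function(gap_samples, disp_deg) {
    x <- base_x
    x[41:n] <- 400 + deg_to_px(disp_deg, geom)
    v <- rep(TRUE, n)
    v[(41 - gap_samples):40] <- FALSE
    cyc <- binocular_combine(make_raw((seq_len(n) - 1) * dt, x, 300,
                                      valid = v))
    interpolate_gaps(cyc, geom)
  }
  # 80 ms gap (~9 samples at 120 Hz), flanks 0.5 degrees apart: filled
  filled <- mk_gap(9, 0.5)
  expect_true(all(filled$valid))
  expect_true(any(filled$interpolated))
  # interpolation is linear in time across the gap
  idx <- which(filled$interpolated)
  expect_equal(diff(filled$x[c(min(idx) - 1, idx, max(idx) + 1)]),
               rep(diff(filled$x[min(idx) - 1 + 0:1]), length(idx) + 1),
               tolerance = 1e-9)

  # 150 ms gap: untouched
  expect_false(any(mk_gap(18, 0.5)$interpolated))
  # flanks 2 degrees apart: untouched
  expect_false(any(mk_gap(9, 2)$interpolated))
  # boundary gap (one flank missing): never filled
  v <- rep(TRUE, n); v[1:5] <- FALSE
  cyc <- binocular_combine(make_raw((seq_len(n) - 1) * dt, base_x, 300,
                                    valid = v))
  expect_false(any(interpolate_gaps(cyc, geom)$interpolated))
})

test_that("angular velocity matches hand trigonometry", {
  # stationary trace: zero everywhere (velocity defined from sample 2)
  cyc <- binocular_combine(make_raw((0:19) * dt, 500, 400))
  v <- angular_velocity(cyc, geom)
  expect_true(is.na(v[1]))
  expect_equal(v[-1], rep(0, 19))

  # one 1-degree step between consecutive samples at 120 Hz -> 120 deg/s
  x <- rep(500, 20); x[11:20] <- 500 + deg_to_px(1, geom)
  cyc <- binocular_combine(make_raw((0:19) * dt, x, 400))
  v <- angular_velocity(cyc, geom)
  expect_equal(v[11], 120, tolerance = 1e-9)
  expect_equal(v[12], 0)

  # undefined across missing samples
  val <- rep(TRUE, 20); val[10] <- FALSE
  cyc <- binocular_combine(make_raw((0:19) * dt, 500, 400, valid = val))
  v <- angular_velocity(cyc, geom)
  expect_true(is.na(v[10]) && is.na(v[11]))
})

test_that("velocity thresholding separates stations from sweeps", {
  # 500 ms stationary trace -> exactly one fixation of ~500 ms
  n <- 60
  cyc <- binocular_combine(make_raw((seq_len(n) - 1) * dt, 400, 300))
  ev <- detect_events(cyc, geom)
  expect_equal(nrow(ev$fixations), 1L)
  expect_equal(ev$fixations$duration_ms, (n - 1) * dt, tolerance = 1e-6)

  # two stations joined by a 30 deg/s sweep -> 2 fixations, 1 saccade
  sweep_step <- deg_to_px(30 * dt / 1000, geom)
  x <- c(rep(300, 30), 300 + cumsum(rep(sweep_step, 20)),
         rep(300 + 20 * sweep_step, 30))
  cyc <- binocular_combine(make_raw((seq_along(x) - 1) * dt, x, 300))
  ev <- detect_events(cyc, geom)
  expect_equal(nrow(ev$fixations), 2L)
  expect_equal(sum(ev$samples$label == "saccade"), 20L)

  # constant 25 deg/s drift -> no fixations
  ev <- detect_events(binocular_combine(constant_velocity_trace(25, geom)),
                      geom)
  expect_equal(nrow(ev$fixations), 0L)

  # all samples missing -> empty sequence, not an error
  mis <- binocular_combine(make_raw((0:9) * dt, 400, 300, valid = FALSE))
  expect_equal(nrow(detect_events(mis, geom)$fixations), 0L)
})

test_that("classification flips from fixation to saccade at 20 deg/s", {
  classify <- function(v) {
    ev <- detect_events(binocular_combine(constant_velocity_trace(v, geom)),
                        geom)
    nrow(ev$fixations) > 0
  }
  vs <- c(seq(2, 18, by = 4), 19, 19.9, 20.1, 21, seq(24, 40, by = 4))
  for (v in vs) expect_identical(classify(v), v < 20)
})

test_that("nearby fixations merge with duration-weighted centroids", {
  sep_px <- function(d) deg_to_px(d, geom)
  fx <- function(onset, dur, x) {
    out <- data.frame(onset_ms = onset, offset_ms = onset + dur,
                      duration_ms = dur, cx_px = x, cy_px = 300,
                      rms_deg = 0, n_samples = round(dur / dt))
    out$sample_idx <- list(integer(0))
    out
  }
  # 0.3 degrees apart: merged; 0.8 degrees: kept apart
  near <- rbind(fx(0, 200, 400), fx(230, 200, 400 + sep_px(0.3)))
  far <- rbind(fx(0, 200, 400), fx(230, 200, 400 + sep_px(0.8)))
  expect_equal(nrow(merge_fixations(near, geom, samples = NULL)), 1L)
  expect_equal(nrow(merge_fixations(far, geom, samples = NULL)), 2L)

  # 100 ms at 0 deg and 300 ms at 0.4 deg -> centroid at 0.3 deg
  pair <- rbind(fx(0, 100, 400), fx(120, 300, 400 + sep_px(0.4)))
  m <- merge_fixations(pair, geom, samples = NULL)
  expect_equal(nrow(m), 1L)
  expect_equal(px_to_deg(m$cx_px - 400, geom), 0.3, tolerance = 1e-5)

  # merging is idempotent
  m2 <- merge_fixations(m, geom, samples = NULL)
  expect_equal(m$cx_px, m2$cx_px)
  expect_equal(nrow(m2), 1L)
})

test_that("validity filter enforces duration and dispersion rules", {
  fx <- data.frame(onset_ms = c(0, 200, 500, 800),
                   offset_ms = c(90, 320, 700, 900),
                   duration_ms = c(90, 120, 200, 100),
                   cx_px = 400, cy_px = 300,
                   rms_deg = c(0.2, 0.2, 1.5, 0.2),
                   n_samples = 10)
  fx$sample_idx <- replicate(4, integer(0), simplify = FALSE)
  kept <- filter_fixations(fx)
  # 90 ms dropped; 120 ms / 0.2 deg kept; 200 ms / 1.5 deg dropped;
  # exactly 100 ms dropped (strictly longer than 100 required)
  expect_equal(kept$duration_ms, 120)

  # monotone: raising min_duration never increases the retained count
  counts <- vapply(c(50, 100, 150, 250),
                   function(d) nrow(filter_fixations(fx, min_duration_ms = d)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("full pipeline recovers planted fixations on noise-free streams", {
  for (hz in c(120, 300)) {
    g <- screen_geometry(sampling_rate_hz = hz)
    scenes <- list(scene_spec(3000, "human"), scene_spec(3000, "non-human"))
    plan <- plant_fixations(scenes, g, seed = 5)
    pp <- participant_params(jitter_sd_px = 0, blink_rate = 0,
                             pupil_noise_sd_mm = 0)
    raw <- generate_gaze_stream(plan, pp, g, seed = 5, total_ms = 6000)
    ev <- detect_fixations(raw, g, smooth = FALSE)
    expect_equal(nrow(ev$fixations), nrow(plan))
    expect_lt(max(abs(ev$fixations$onset_ms - plan$onset_ms)), 1000 / hz)
    expect_lt(max(abs(ev$fixations$cx_px - plan$cx_px)), 0.1)
  }
})

test_that("jittered, blink-interrupted streams still yield plausible events", {
  g <- screen_geometry()
  scenes <- list(scene_spec(3000, "human"))
  plan <- plant_fixations(scenes, g, seed = 9)
  pp <- participant_params(jitter_sd_px = 2, blink_rate = 0.05)
  raw <- generate_gaze_stream(plan, pp, g, seed = 9, total_ms = 3000)
  ev <- detect_fixations(raw, g)
  expect_gt(nrow(ev$fixations), 0)
  expect_true(all(ev$fixations$duration_ms > 100))
  expect_true(all(ev$fixations$rms_deg < 1))
})
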