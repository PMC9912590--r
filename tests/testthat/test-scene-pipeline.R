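geom <- screen_geometry()

test_that("scene segmentation applies the 5000 ms analysis window", {
  man <- data.frame(video = "v1", scene = 1:3,
                    category = c("human", "non-human", "human"),
                    onset_ms = c(0, 8000, 11000),
                    offset_ms = c(8000, 11000, 17000))
  segs <- segment_scenes(man)
  expect_equal(segs$analysis_window_ms, c(5000, 3000, 5000))
  expect_equal(segs$duration_ms, c(8000, 3000, 6000))

  bad <- man; bad$onset_ms[2] <- 7000
  expect_error(segment_scenes(bad), "overlap")

  # manifest with k cuts covers k+1 scenes back-to-back
  scenes <- replicate(4, scene_spec(2000, "human"), simplify = FALSE)
  s4 <- segment_scenes(scenes)
  expect_equal(nrow(s4), 4)
  expect_equal(s4$onset_ms, c(0, 2000, 4000, 6000))
})

test_that("fixations are assigned by onset, truncated at cuts, chopped at
           the window", {
  segs <- segment_scenes(data.frame(
    video = "v1", scene = 1:2, category = c("human", "non-human"),
    onset_ms = c(0, 6000), offset_ms = c(6000, 10000)))
  fx <- data.frame(onset_ms = c(100, 4900, 5500, 6100),
                   offset_ms = c(400, 6300, 5800, 6400),
                   duration_ms = 300, cx_px = 400, cy_px = 300,
                   rms_deg = 0.1, n_samples = 30)
  out <- assign_scenes(fx, segs)
  # onset 5500 is beyond the 5000 ms window of scene 1: dropped
  expect_equal(out$onset_ms, c(100, 4900, 6100))
  expect_true(all(out$time_in_scene_ms <= 5000))
  # fixation straddling the cut at 6000 is truncated there
  expect_equal(out$offset_ms[out$onset_ms == 4900], 6000)
  expect_equal(out$scene, c(1, 1, 2))
})

test_that("map sampling reads the centroid pixel of the nearest frame", {
  grid <- matrix(0, 10, 12)
  grid[3, 5] <- 0.7
  grids <- list(grid, grid * 0)
  # centroid mapping: screen px scaled onto the grid
  cx <- (5 - 0.5) / 12 * geom$width_px
  cy <- (3 - 0.5) / 10 * geom$height_px
  expect_equal(sample_map_at_gaze(cx, cy, 0, grids, 25, geom), 0.7)
  # nearest frame switches with time (frame 2 at 40 ms for 25 fps)
  expect_equal(sample_map_at_gaze(cx, cy, 45, grids, 25, geom), 0)
  # off-screen centroid is missing, flagged by NA
  expect_true(is.na(sample_map_at_gaze(-5, cy, 0, grids, 25, geom)))
  expect_true(is.na(sample_map_at_gaze(geom$width_px + 1, cy, 0, grids,
                                       25, geom)))
  expect_error(sample_map_at_gaze(cx, cy, 0, list(), 25, geom), "no frames")
})

test_that("AOI hits test centroid membership per label", {
  vid <- generate_video(scene_spec(1000, "human"), geom, seed = 5)
  fb <- vid$truth$aoi_boxes$face
  # a screen point in the centre of the face box
  cx <- (fb["x0"] + fb["x1"]) / 2 / vid$width * geom$width_px
  cy <- (fb["y0"] + fb["y1"]) / 2 / vid$height * geom$height_px
  hits <- aoi_hit(cx, cy, 100, vid$aoi, vid$fps, geom)
  expect_true(hits[["face"]])
  expect_true(hits[["body"]])
  # a point far outside the person
  h2 <- aoi_hit(geom$width_px * 0.95, geom$height_px * 0.95, 100, vid$aoi,
                vid$fps, geom)
  expect_true(!any(h2))
  # non-human scene (no masks): missing, not an error
  h3 <- aoi_hit(cx, cy, 100, NULL, 25, geom)
  expect_true(all(is.na(h3)))
})

test_that("AOI proportions recover planted on-face counts", {
  vid <- generate_video(scene_spec(1000, "human"), geom, seed = 6)
  fb <- vid$truth$aoi_boxes$face
  face_x <- (fb["x0"] + fb["x1"]) / 2 / vid$width * geom$width_px
  face_y <- (fb["y0"] + fb["y1"]) / 2 / vid$height * geom$height_px
  n_on <- 3; n_off <- 7
  xs <- c(rep(face_x, n_on), rep(geom$width_px * 0.95, n_off))
  ys <- c(rep(face_y, n_on), rep(geom$height_px * 0.95, n_off))
  hits <- vapply(seq_along(xs), function(i)
    aoi_hit(xs[i], ys[i], 100, vid$aoi, vid$fps, geom)[["face"]], TRUE)
  expect_equal(mean(hits), 0.30)
})

test_that("record assembly joins losslessly and computes data quality", {
  coh <- generate_cohort(cohort_design(n_per_group = 2, n_scenes = 2),
                         geom, seed = 11)
  segs <- segment_scenes(coh$scenes)
  fixl <- lapply(coh$streams, function(s) {
    assign_scenes(detect_fixations(s, coh$geometry)$fixations, segs)
  })
  recs <- assemble_records(fixl, coh$participants, segs,
                           geometry = coh$geometry)
  # lossless: one row per retained fixation
  expect_equal(nrow(recs), sum(vapply(fixl, nrow, 1L)))
  expect_true(all(recs$time_in_scene_ms <= 5000))
  expect_true(all(c("group", "age", "perceptual_iq",
                    "available_data_pct") %in% names(recs)))
  # available data = retained fixation time / investigated scene time
  pid <- names(fixl)[1]
  expect_equal(unique(recs$available_data_pct[recs$participant == pid]),
               sum(fixl[[pid]]$duration_ms) /
                 sum(segs$analysis_window_ms) * 100)
  # unmatched participants are an error naming the offender
  expect_error(assemble_records(stats::setNames(fixl[1], "ghost"),
                                coh$participants, segs),
               "ghost")
  # zero fixations: empty table with full schema
  empty <- lapply(fixl, function(f) f[0, , drop = FALSE])
  e <- assemble_records(empty, coh$participants, segs)
  expect_equal(nrow(e), 0)
  expect_true(all(c("gaze_physical_salience", "on_face", "pupil_response")
                  %in% names(e)))
})

test_that("AOI masks round-trip through PNG and polygon JSON readers", {
  vid <- generate_video(scene_spec(400, "human"), geom, seed = 8)
  d <- tempfile()
  write_aoi_masks_png(vid$aoi, d)
  back <- read_aoi_masks_png(d)
  expect_setequal(names(back), names(vid$aoi))
  expect_identical(back$face[[1]], vid$aoi$face[[1]])
  unlink(d, recursive = TRUE)

  # polygon JSON rasterization of the same face rectangle
  fb <- vid$truth$aoi_boxes$face
  poly <- list(face = list(list(
    frame = 1,
    x = c(fb["x0"] - 1, fb["x1"], fb["x1"], fb["x0"] - 1),
    y = c(fb["y0"] - 1, fb["y0"] - 1, fb["y1"], fb["y1"]))))
  pf <- tempfile(fileext = ".json")
  jsonlite::write_json(poly, pf, auto_unbox = TRUE, digits = NA)
  masks <- read_aoi_polygons(pf, vid$height, vid$width,
                             length(vid$frames))
  expect_identical(masks$face[[1]], vid$aoi$face[[1]])
  unlink(pf)
})

test_that("frame sequences round-trip through numbered PNGs", {
  vid <- generate_video(scene_spec(200, "non-human"), geom, seed = 9)
  d <- tempfile()
  write_frames_png(vid$frames, d, fps = vid$fps)
  back <- read_frames_png(d)
  expect_equal(back$fps, vid$fps)
  expect_equal(length(back$frames), length(vid$frames))
  expect_lt(max(abs(back$frames[[1]] - vid$frames[[1]])), 1 / 255)
  unlink(d, recursive = TRUE)
})
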