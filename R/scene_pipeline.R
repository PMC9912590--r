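#' @title Scene segmentation and analysis-table assembly
#' @description
#' Segments videos at camera cuts into scenes, restricts each scene to its
#' first 5000 ms analysis window, assigns fixations to scenes, samples
#' feature maps and area-of-interest masks at fixation centroids, and
#' assembles the long-format fixation-record table consumed by the
#' mixed-model stage.
#' @name scene_pipeline
NULL

#' Build the scene-segment table from a manifest
#'
#' A manifest is a data frame with columns `video`, `scene`, `category`
#' (`"human"`/`"non-human"`), `onset_ms`, `offset_ms` and optionally
#' `age_restricted`. Each scene's analyzable window is
#' `[0, min(duration, window_ms)]` ms; fixations beyond it are excluded
#' downstream.
#'
#' @param manifest Manifest data frame (or a list of [scene_spec()]s, which
#'   are laid out back-to-back as one video).
#' @param window_ms Analysis chop (default 5000 ms).
#' @return The manifest with `duration_ms` and `analysis_window_ms` columns,
#'   ordered by onset; overlapping scenes within a video are an error.
#' @export
segment_scenes <- function(manifest, window_ms = 5000) {
  if (is.list(manifest) && !is.data.frame(manifest) &&
        all(vapply(manifest, inherits, TRUE, "scene_spec"))) {
    durs <- vapply(manifest, `[[`, 0, "duration_ms")
    offs <- cumsum(durs)
    manifest <- data.frame(
      video = "v1", scene = seq_along(manifest),
      category = vapply(manifest, `[[`, "", "category"),
      onset_ms = c(0, offs[-length(offs)]), offset_ms = offs,
      age_restricted = vapply(manifest, `[[`, TRUE, "age_restricted"))
  }
  stopifnot(all(c("video", "scene", "category", "onset_ms", "offset_ms")
                %in% names(manifest)))
  if (!"age_restricted" %in% names(manifest)) manifest$age_restricted <- FALSE
  manifest <- manifest[order(manifest$video, manifest$onset_ms), ]
  for (v in unique(manifest$video)) {
    m <- manifest[manifest$video == v, ]
    if (any(m$offset_ms <= m$onset_ms)) stop("scene with non-positive duration")
    if (nrow(m) > 1 && any(m$onset_ms[-1] < m$offset_ms[-nrow(m)])) {
      stop("overlapping scene cuts in video ", v)
    }
  }
  manifest$duration_ms <- manifest$offset_ms - manifest$onset_ms
  manifest$analysis_window_ms <- pmin(manifest$duration_ms, window_ms)
  rownames(manifest) <- NULL
  manifest
}

#' Assign fixations to scenes and apply the analysis window
#'
#' Scene membership is by fixation onset; fixations straddling a cut are
#' truncated at the cut. Fixations whose in-scene onset falls beyond the
#' scene's analysis window are dropped.
#'
#' @param fixations Fixation table with global `onset_ms`/`offset_ms`
#'   (stream time aligned to video time).
#' @param segments Output of [segment_scenes()] (a single video's rows).
#' @return Fixation table with `scene`, `category`, `age_restricted` and
#'   `time_in_scene_ms` columns; out-of-window rows removed.
#' @export
assign_scenes <- function(fixations, segments) {
  if (nrow(fixations) == 0) {
    fixations$scene <- integer(0); fixations$category <- character(0)
    fixations$time_in_scene_ms <- numeric(0)
    fixations$age_restricted <- logical(0)
    return(fixations)
  }
  idx <- findInterval(fixations$onset_ms, segments$onset_ms)
  keep <- idx >= 1 & fixations$onset_ms < segments$offset_ms[pmax(idx, 1)]
  fx <- fixations[keep, , drop = FALSE]
  idx <- idx[keep]
  fx$scene <- segments$scene[idx]
  fx$category <- segments$category[idx]
  fx$age_restricted <- segments$age_restricted[idx]
  fx$time_in_scene_ms <- fx$onset_ms - segments$onset_ms[idx]
  # truncate at the scene cut
  over <- fx$offset_ms > segments$offset_ms[idx]
  fx$offset_ms[over] <- segments$offset_ms[idx][over]
  fx$duration_ms <- fx$offset_ms - fx$onset_ms
  fx <- fx[fx$time_in_scene_ms <= segments$analysis_window_ms[idx], ,
           drop = FALSE]
  rownames(fx) <- NULL
  fx
}

#' Sample a feature grid at a fixation centroid
#'
#' Returns the grid value at the fixation centroid pixel of the temporally
#' nearest frame. Off-screen centroids give `NA`.
#'
#' @param cx_px,cy_px Fixation centroid in screen pixels.
#' @param time_in_scene_ms Fixation time in scene.
#' @param grids List of per-frame grids for the scene.
#' @param fps Frame rate of the grids.
#' @param geometry A [screen_geometry()] (maps screen pixels onto the grid).
#' @return Scalar grid value, or `NA` if the centroid is off-screen.
#' @export
sample_map_at_gaze <- function(cx_px, cy_px, time_in_scene_ms, grids, fps,
                               geometry) {
  if (length(grids) == 0) stop("no frames available for scene")
  f <- round(time_in_scene_ms / 1000 * fps) + 1L
  f <- min(max(f, 1L), length(grids))
  g <- grids[[f]]
  if (!is.finite(cx_px) || !is.finite(cy_px)) return(NA_real_)
  col <- floor(cx_px / geometry$width_px * ncol(g)) + 1L
  row <- floor(cy_px / geometry$height_px * nrow(g)) + 1L
  if (col < 1 || col > ncol(g) || row < 1 || row > nrow(g)) return(NA_real_)
  g[row, col]
}

#' Area-of-interest hit flags for a fixation
#'
#' Flags whether the centroid pixel falls inside each labelled mask of the
#' temporally nearest frame. For scenes without masks (non-human scenes)
#' all flags are `NA` (missing, not an error).
#'
#' @param cx_px,cy_px Fixation centroid in screen pixels.
#' @param time_in_scene_ms Fixation time in scene.
#' @param aoi Per-label list of per-frame logical masks (or NULL).
#' @param fps Frame rate.
#' @param geometry A [screen_geometry()].
#' @return Named logical vector over `eyes`, `mouth`, `face`, `body`.
#' @export
aoi_hit <- function(cx_px, cy_px, time_in_scene_ms, aoi, fps, geometry) {
  labs <- c("eyes", "mouth", "face", "body")
  out <- stats::setNames(rep(NA, 4), labs)
  if (is.null(aoi)) return(out)
  for (lab in labs) {
    masks <- aoi[[lab]]
    if (is.null(masks)) next
    f <- round(time_in_scene_ms / 1000 * fps) + 1L
    f <- min(max(f, 1L), length(masks))
    m <- masks[[f]]
    col <- floor(cx_px / geometry$width_px * ncol(m)) + 1L
    row <- floor(cy_px / geometry$height_px * nrow(m)) + 1L
    out[lab] <- if (col < 1 || col > ncol(m) || row < 1 || row > nrow(m)) {
      FALSE
    } else {
      m[row, col]
    }
  }
  out
}

#' Assemble the long-format fixation-record table
#'
#' Joins per-participant fixations (already scene-assigned) with feature
#' maps, AOI masks, standardized pupil traces and the participant table into
#' one row per valid fixation within the analysis window. Per-participant
#' data-quality covariates (available-data %: retained fixation time over
#' total investigated scene time) are computed and carried in.
#'
#' @param fixations Named list (by participant) of scene-assigned fixation
#'   tables (see [assign_scenes()]).
#' @param cohort Participant table with a `participant` column.
#' @param segments Output of [segment_scenes()].
#' @param features Optional named-by-scene list with elements
#'   `physical`, `motion`, `luminance` (per-frame grid lists) and `fps`.
#' @param aoi Optional named-by-scene list of AOI mask sets.
#' @param pupil Optional named-by-participant list of standardized
#'   `pupil_trace` objects.
#' @param geometry A [screen_geometry()].
#' @param shift_window Pupil latency window (default `c(200, 400)` ms).
#' @return `fixation_record` data frame; unmatched participants are an
#'   error naming the offenders.
#' @export
assemble_records <- function(fixations, cohort, segments, features = NULL,
                             aoi = NULL, pupil = NULL,
                             geometry = screen_geometry(),
                             shift_window = c(200, 400)) {
  unknown <- setdiff(names(fixations), cohort$participant)
  if (length(unknown)) {
    stop("fixations for unknown participants: ",
         paste(unknown, collapse = ", "))
  }
  total_window <- sum(segments$analysis_window_ms)
  rows <- list()
  for (pid in names(fixations)) {
    fx <- fixations[[pid]]
    cov <- cohort[cohort$participant == pid, , drop = FALSE]
    avail <- if (nrow(fx)) sum(fx$duration_ms) / total_window * 100 else 0
    if (nrow(fx) == 0) next
    for (i in seq_len(nrow(fx))) {
      sc <- as.character(fx$scene[i])
      phys <- mot <- lum <- NA_real_
      if (!is.null(features) && !is.null(features[[sc]])) {
        ft <- features[[sc]]
        phys <- sample_map_at_gaze(fx$cx_px[i], fx$cy_px[i],
                                   fx$time_in_scene_ms[i], ft$physical,
                                   ft$fps, geometry)
        mot <- sample_map_at_gaze(fx$cx_px[i], fx$cy_px[i],
                                  fx$time_in_scene_ms[i], ft$motion,
                                  ft$fps, geometry)
        lum <- sample_map_at_gaze(fx$cx_px[i], fx$cy_px[i],
                                  fx$time_in_scene_ms[i], ft$luminance,
                                  ft$fps, geometry)
      }
      hits <- aoi_hit(fx$cx_px[i], fx$cy_px[i], fx$time_in_scene_ms[i],
                      if (is.null(aoi)) NULL else aoi[[sc]],
                      if (!is.null(features) && !is.null(features[[sc]]))
                        features[[sc]]$fps else 25,
                      geometry)
      resp <- NA_real_
      if (!is.null(pupil) && !is.null(pupil[[pid]])) {
        resp <- fixation_pupil_response(pupil[[pid]], fx$onset_ms[i],
                                        fx$offset_ms[i], shift_window)
      }
      tt <- fx$time_in_scene_ms[i] / 5000
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(participant = pid, scene = fx$scene[i],
                   category = fx$category[i],
                   age_restricted = fx$age_restricted[i],
                   time_in_scene_ms = fx$time_in_scene_ms[i],
                   time1 = tt, time2 = tt^2, time3 = tt^3,
                   onset_ms = fx$onset_ms[i], duration_ms = fx$duration_ms[i],
                   cx_px = fx$cx_px[i], cy_px = fx$cy_px[i],
                   gaze_physical_salience = phys,
                   gaze_motion_salience = mot, luminance = lum,
                   on_eyes = hits[["eyes"]], on_mouth = hits[["mouth"]],
                   on_face = hits[["face"]], on_body = hits[["body"]],
                   pupil_response = resp, available_data_pct = avail),
        cov[, setdiff(names(cov), "participant"), drop = FALSE])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    empty_record_frame(cohort)
  rownames(out) <- NULL
  class(out) <- c("fixation_record", "data.frame")
  out
}

empty_record_frame <- function(cohort) {
  base <- data.frame(participant = character(0), scene = integer(0),
                     category = character(0), age_restricted = logical(0),
                     time_in_scene_ms = numeric(0), time1 = numeric(0),
                     time2 = numeric(0), time3 = numeric(0),
                     onset_ms = numeric(0), duration_ms = numeric(0),
                     cx_px = numeric(0), cy_px = numeric(0),
                     gaze_physical_salience = numeric(0),
                     gaze_motion_salience = numeric(0),
                     luminance = numeric(0), on_eyes = logical(0),
                     on_mouth = logical(0), on_face = logical(0),
                     on_body = logical(0), pupil_response = numeric(0),
                     available_data_pct = numeric(0))
  cov <- cohort[0, setdiff(names(cohort), "participant"), drop = FALSE]
  cbind(base, cov)
}
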