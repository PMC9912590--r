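#' @title Fixation and saccade detection from raw gaze samples
#' @description
#' Velocity-threshold (I-VT) event detection on raw binocular gaze streams:
#' binocular combination, temporal/spatial smoothing, gap interpolation,
#' angular-velocity computation, thresholding into fixations and saccades,
#' merging of nearby fixations, and validity filtering. All thresholds
#' default to the conventions used for remote-eye-tracker video viewing:
#' a 20 deg/s velocity threshold, fixations kept only when longer than
#' 100 ms with an RMS dispersion below 1 degree, consecutive fixations
#' closer than 0.5 degrees merged, and gaps up to 100 ms interpolated when
#' the flanking positions differ by at most 1 degree.
#' @name gaze_events
NULL

#' Combine binocular samples into a cyclopean stream
#'
#' Gaze position and pupil diameter are averaged over the valid eyes; samples
#' with neither eye valid are marked missing. A raw stream is a data frame
#' with columns `timestamp_ms`, `gx_left_px`, `gy_left_px`, `gx_right_px`,
#' `gy_right_px`, `pupil_left_mm`, `pupil_right_mm`, `valid_left`,
#' `valid_right` (a Tobii-like layout).
#'
#' @param samples Raw binocular sample data frame (see Details).
#' @return A data frame with columns `timestamp_ms`, `x`, `y`, `pupil_mm`,
#'   `valid`. Missing samples carry `NA` coordinates and `valid = FALSE`.
#' @export
binocular_combine <- function(samples) {
  if (nrow(samples) == 0) stop("empty gaze stream")
  if (is.unsorted(samples$timestamp_ms, strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  vl <- as.logical(samples$valid_left) & is.finite(samples$gx_left_px)
  vr <- as.logical(samples$valid_right) & is.finite(samples$gx_right_px)
  w <- cbind(vl, vr)
  avg2 <- function(a, b) {
    num <- ifelse(vl, a, 0) + ifelse(vr, b, 0)
    n <- rowSums(w)
    out <- num / n
    out[n == 0] <- NA_real_
    out
  }
  data.frame(
    timestamp_ms = samples$timestamp_ms,
    x = avg2(samples$gx_left_px, samples$gx_right_px),
    y = avg2(samples$gy_left_px, samples$gy_right_px),
    pupil_mm = avg2(samples$pupil_left_mm, samples$pupil_right_mm),
    valid = vl | vr
  )
}

#' Smooth a cyclopean gaze stream
#'
#' Joint temporal/spatial smoothing: each sample is replaced by the mean of
#' the valid samples inside a centred window of `temporal_window` samples
#' that lie within `spatial_scale_mm` of it on the screen. Sub-scale jitter
#' is averaged away while true gaze shifts (saccade end points, which exceed
#' the spatial scale) are excluded from the window, so event boundaries are
#' not blurred. Missing samples are excluded from windows and stay missing;
#' edge windows shrink to the available samples.
#'
#' @param samples Cyclopean stream from [binocular_combine()].
#' @param geometry A [screen_geometry()] (converts mm to px).
#' @param temporal_window Window length in samples (default 20).
#' @param spatial_scale_mm Spatial smoothing scale in mm (default 8).
#' @return The stream with smoothed `x`, `y`.
#' @export
smooth_gaze <- function(samples, geometry, temporal_window = 20,
                        spatial_scale_mm = 8) {
  if (temporal_window < 1) stop("temporal_window must be >= 1")
  n <- nrow(samples)
  if (n == 0) return(samples)
  half <- max(temporal_window %/% 2, 1L)
  scale_px <- mm_to_px(spatial_scale_mm, geometry)
  xs <- samples$x
  ys <- samples$y
  ok <- is.finite(xs) & is.finite(ys)
  out <- samples
  for (i in seq_len(n)) {
    if (!ok[i]) next
    j <- max(1L, i - half):min(n, i + half)
    j <- j[ok[j]]
    near <- (xs[j] - xs[i])^2 + (ys[j] - ys[i])^2 < scale_px^2
    j <- j[near]
    out$x[i] <- mean(xs[j])
    out$y[i] <- mean(ys[j])
  }
  out
}

#' Linearly interpolate short gaps in a gaze stream
#'
#' Runs of missing samples lasting at most `max_gap_ms` are filled linearly
#' (gaze and pupil) when the flanking valid positions are at most
#' `max_displacement_deg` apart; longer gaps, larger displacements, and gaps
#' at the stream boundary are left untouched. Gap duration is the number of
#' missing samples times the nominal inter-sample interval.
#'
#' @param samples Cyclopean stream.
#' @param geometry A [screen_geometry()].
#' @param max_gap_ms Longest fillable gap, default 100 ms.
#' @param max_displacement_deg Largest fillable flank separation, default 1.
#' @return The stream with fillable gaps interpolated (`valid` set TRUE and
#'   `interpolated` flagged).
#' @export
interpolate_gaps <- function(samples, geometry, max_gap_ms = 100,
                             max_displacement_deg = 1) {
  n <- nrow(samples)
  out <- samples
  out$interpolated <- rep(FALSE, n)
  if (n < 3) return(out)
  dt <- stats::median(diff(samples$timestamp_ms))
  miss <- !samples$valid | !is.finite(samples$x)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1L || i1 == n) next            # boundary gap: one flank missing
    if (r$lengths[k] * dt > max_gap_ms * (1 + 1e-9)) next
    a <- i0 - 1L; b <- i1 + 1L
    sep <- angular_distance(samples$x[a], samples$y[a],
                            samples$x[b], samples$y[b], geometry)
    if (!is.finite(sep) || sep > max_displacement_deg) next
    f <- (samples$timestamp_ms[i0:i1] - samples$timestamp_ms[a]) /
      (samples$timestamp_ms[b] - samples$timestamp_ms[a])
    out$x[i0:i1] <- samples$x[a] + f * (samples$x[b] - samples$x[a])
    out$y[i0:i1] <- samples$y[a] + f * (samples$y[b] - samples$y[a])
    if (is.finite(samples$pupil_mm[a]) && is.finite(samples$pupil_mm[b])) {
      out$pupil_mm[i0:i1] <-
        samples$pupil_mm[a] + f * (samples$pupil_mm[b] - samples$pupil_mm[a])
    }
    out$valid[i0:i1] <- TRUE
    out$interpolated[i0:i1] <- TRUE
  }
  out
}

#' Per-sample angular velocity
#'
#' Velocity at sample i is the angular displacement from sample i-1 divided
#' by the inter-sample interval; the angle is the arctangent subtense of the
#' metric on-screen displacement at the viewing distance. Undefined across
#' missing samples and at the first sample.
#'
#' @param samples Cyclopean stream.
#' @param geometry A [screen_geometry()].
#' @return Numeric vector of velocities in deg/s, `NA` where undefined.
#' @export
angular_velocity <- function(samples, geometry) {
  n <- nrow(samples)
  v <- rep(NA_real_, n)
  if (n < 2) return(v)
  dx <- diff(samples$x); dy <- diff(samples$y)
  dt <- diff(samples$timestamp_ms)
  ang <- mm_to_deg(sqrt(dx^2 + dy^2) * geometry$mm_per_px, geometry)
  v[-1] <- ang / (dt / 1000)
  v[-1][!samples$valid[-1] | !samples$valid[-n]] <- NA_real_
  v
}

#' Detect fixations and saccades by velocity threshold
#'
#' Maximal runs of samples with velocity strictly below the threshold become
#' fixation candidates; runs at or above it become saccades. Runs are broken
#' by missing samples. The first sample of the stream (undefined velocity)
#' joins the event of the sample that follows it.
#'
#' @param samples Cyclopean stream (after smoothing/interpolation).
#' @param geometry A [screen_geometry()].
#' @param velocity_threshold Fixation/saccade boundary in deg/s (default 20).
#' @return A list of class `event_sequence` with elements `samples` (the
#'   input plus `velocity_deg_s` and a per-sample `label` in
#'   fixation/saccade/missing), and `fixations`, a data frame of candidates
#'   with onset/offset/duration (ms), pixel centroid, member-sample indices
#'   and RMS dispersion (deg).
#' @export
detect_events <- function(samples, geometry, velocity_threshold = 20) {
  n <- nrow(samples)
  vel <- angular_velocity(samples, geometry)
  lab <- rep("missing", n)
  defined <- samples$valid & is.finite(samples$x)
  isfix <- defined & !is.na(vel) & vel < velocity_threshold
  issac <- defined & !is.na(vel) & vel >= velocity_threshold
  lab[isfix] <- "fixation"
  lab[issac] <- "saccade"
  # samples with undefined velocity but valid position (stream/gap starts)
  # inherit the label of the following defined sample
  pend <- which(defined & is.na(vel))
  for (i in pend) {
    if (i < n && lab[i + 1L] != "missing") lab[i] <- lab[i + 1L]
  }
  sm <- samples
  sm$velocity_deg_s <- vel
  sm$label <- lab
  fix <- fixation_table(sm, geometry)
  structure(list(samples = sm, fixations = fix), class = "event_sequence")
}

# build the candidate fixation table from labelled samples
fixation_table <- function(sm, geometry) {
  n <- nrow(sm)
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), cx_px = numeric(0),
                      cy_px = numeric(0), rms_deg = numeric(0),
                      n_samples = integer(0))
  empty$sample_idx <- list()
  if (n == 0) return(empty)
  r <- rle(sm$label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values == "fixation")
  if (!length(keep)) return(empty)
  rows <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    fixation_from_samples(sm, idx, geometry)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fixation_from_samples <- function(sm, idx, geometry) {
  cx <- mean(sm$x[idx]); cy <- mean(sm$y[idx])
  rms <- sqrt(mean(angular_distance(sm$x[idx], sm$y[idx], cx, cy, geometry)^2))
  out <- data.frame(
    onset_ms = sm$timestamp_ms[idx[1]],
    offset_ms = sm$timestamp_ms[idx[length(idx)]],
    duration_ms = sm$timestamp_ms[idx[length(idx)]] - sm$timestamp_ms[idx[1]],
    cx_px = cx, cy_px = cy, rms_deg = rms, n_samples = length(idx)
  )
  out$sample_idx <- list(idx)
  out
}

#' Merge consecutive nearby fixations
#'
#' Consecutive fixations whose centroids are strictly less than
#' `merge_threshold_deg` apart are merged; the merged centroid is the
#' duration-weighted mean and dispersion is recomputed over the union of
#' member samples. Applied left-to-right and iterated until stable, so the
#' operation is idempotent.
#'
#' @param events An `event_sequence` from [detect_events()], or its
#'   `fixations` data frame (then `samples` must be passed too).
#' @param geometry A [screen_geometry()].
#' @param merge_threshold_deg Merge radius in degrees (default 0.5).
#' @param samples Labelled sample frame when `events` is a bare table.
#' @return Same shape as the input (`event_sequence` or fixation table).
#' @export
merge_fixations <- function(events, geometry, merge_threshold_deg = 0.5,
                            samples = NULL) {
  if (inherits(events, "event_sequence")) {
    fx <- events$fixations; sm <- events$samples
  } else {
    fx <- events; sm <- samples
  }
  repeat {
    changed <- FALSE
    i <- 1L
    while (i < nrow(fx)) {
      sep <- angular_distance(fx$cx_px[i], fx$cy_px[i],
                              fx$cx_px[i + 1L], fx$cy_px[i + 1L], geometry)
      if (sep < merge_threshold_deg) {
        fx[i, ] <- merge_pair(fx[i, ], fx[i + 1L, ], sm, geometry)
        fx <- fx[-(i + 1L), , drop = FALSE]
        changed <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!changed) break
  }
  rownames(fx) <- NULL
  if (inherits(events, "event_sequence")) {
    events$fixations <- fx
    events
  } else {
    fx
  }
}

merge_pair <- function(a, b, sm, geometry) {
  w <- c(a$duration_ms, b$duration_ms)
  if (sum(w) <= 0) w <- c(a$n_samples, b$n_samples)
  cx <- sum(w * c(a$cx_px, b$cx_px)) / sum(w)
  cy <- sum(w * c(a$cy_px, b$cy_px)) / sum(w)
  idx <- c(a$sample_idx[[1]], b$sample_idx[[1]])
  rms <- if (!is.null(sm)) {
    sqrt(mean(angular_distance(sm$x[idx], sm$y[idx], cx, cy, geometry)^2))
  } else {
    max(a$rms_deg, b$rms_deg)
  }
  out <- data.frame(
    onset_ms = a$onset_ms, offset_ms = b$offset_ms,
    duration_ms = b$offset_ms - a$onset_ms,
    cx_px = cx, cy_px = cy, rms_deg = rms,
    n_samples = a$n_samples + b$n_samples
  )
  out$sample_idx <- list(idx)
  out
}

#' Filter fixations by duration and dispersion
#'
#' Retains fixations strictly longer than `min_duration_ms` with an RMS
#' dispersion strictly below `max_rms_deg`.
#'
#' @param fixations Fixation table (or `event_sequence`).
#' @param min_duration_ms Minimum duration, exclusive (default 100 ms).
#' @param max_rms_deg Maximum RMS dispersion, exclusive (default 1 degree).
#' @return The retained rows, same shape as the input.
#' @export
filter_fixations <- function(fixations, min_duration_ms = 100,
                             max_rms_deg = 1) {
  fx <- if (inherits(fixations, "event_sequence")) fixations$fixations else fixations
  keep <- fx$duration_ms > min_duration_ms & fx$rms_deg < max_rms_deg
  fx <- fx[keep, , drop = FALSE]
  rownames(fx) <- NULL
  if (inherits(fixations, "event_sequence")) {
    fixations$fixations <- fx
    fixations
  } else {
    fx
  }
}

#' Full fixation-detection pipeline
#'
#' Chains [binocular_combine()], [smooth_gaze()], [interpolate_gaps()],
#' [detect_events()], [merge_fixations()] and [filter_fixations()] with the
#' standard thresholds.
#'
#' @param raw Raw binocular sample data frame.
#' @param geometry A [screen_geometry()].
#' @param velocity_threshold,merge_threshold_deg,min_duration_ms,max_rms_deg
#'   Event thresholds, see the individual steps.
#' @param temporal_window,spatial_scale_mm Smoothing parameters.
#' @param max_gap_ms,max_displacement_deg Interpolation parameters.
#' @param smooth Logical; apply the smoothing stage (default TRUE; disable
#'   for already-clean traces).
#' @return An `event_sequence` whose `fixations` are the valid fixations.
#' @export
detect_fixations <- function(raw, geometry,
                             velocity_threshold = 20,
                             merge_threshold_deg = 0.5,
                             min_duration_ms = 100,
                             max_rms_deg = 1,
                             temporal_window = 20,
                             spatial_scale_mm = 8,
                             max_gap_ms = 100,
                             max_displacement_deg = 1,
                             smooth = TRUE) {
  cyc <- binocular_combine(raw)
  if (smooth) cyc <- smooth_gaze(cyc, geometry, temporal_window, spatial_scale_mm)
  cyc <- interpolate_gaps(cyc, geometry, max_gap_ms, max_displacement_deg)
  ev <- detect_events(cyc, geometry, velocity_threshold)
  ev <- merge_fixations(ev, geometry, merge_threshold_deg)
  filter_fixations(ev, min_duration_ms, max_rms_deg)
}
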