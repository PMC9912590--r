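#' @title Pupillary response extraction and temporal decomposition
#' @description
#' Cleans raw pupil-diameter traces (plausible-range and dilation-speed
#' filtering, short-gap interpolation, light smoothing), standardizes each
#' trace by the participant's mean diameter, extracts a latency-shifted
#' per-fixation response, and decomposes responses over scene time into an
#' early (PR1) and a late (PR2) component by principal components with
#' varimax rotation.
#' @name pupil
NULL

#' Preprocess a raw pupil trace
#'
#' Removes implausible diameters (outside `[1, 9]` mm), removes
#' dilation-speed outliers by a median-absolute-deviation rule on
#' sample-to-sample speed, linearly interpolates gaps up to
#' `max_interp_ms`, and applies a light 3-sample median smooth.
#'
#' @param timestamp_ms,pupil_mm Numeric vectors (one trace; `NA` = missing).
#' @param plausible_mm Plausible diameter range (default `c(1, 9)`).
#' @param mad_multiplier Dilation-speed rejection threshold in MADs above
#'   the median speed (default 16).
#' @param max_interp_ms Longest interpolated gap (default 250 ms).
#' @param smooth_k Median-smooth window in samples, odd (default 3).
#' @return A list of class `pupil_trace`: `timestamp_ms`, `pupil_mm`
#'   (cleaned, `NA` where unrecoverable), `valid`, `usable` (FALSE when more
#'   than 90% of samples were removed), and `mean_mm` (the participant mean
#'   over valid cleaned samples).
#' @export
preprocess_pupil <- function(timestamp_ms, pupil_mm,
                             plausible_mm = c(1, 9), mad_multiplier = 16,
                             max_interp_ms = 250, smooth_k = 3) {
  n <- length(pupil_mm)
  stopifnot(length(timestamp_ms) == n)
  p <- as.numeric(pupil_mm)
  p[!is.finite(p) | p < plausible_mm[1] | p > plausible_mm[2]] <- NA

  # dilation-speed filter: max of backward/forward absolute speed per sample
  if (sum(is.finite(p)) > 2) {
    d <- abs(diff(p)) / diff(timestamp_ms)
    speed <- pmax(c(d[1], d), c(d, d[length(d)]), na.rm = TRUE)
    speed[!is.finite(speed)] <- NA
    med <- stats::median(speed, na.rm = TRUE)
    mad <- stats::median(abs(speed - med), na.rm = TRUE)
    thr <- med + mad_multiplier * mad
    if (is.finite(thr) && mad > 0) p[!is.na(speed) & speed > thr] <- NA
  }

  # linear interpolation of short gaps (interior only)
  dt <- if (n > 1) stats::median(diff(timestamp_ms)) else Inf
  miss <- !is.finite(p)
  if (any(miss) && any(!miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      if (i0 == 1L || i1 == n) next
      if (r$lengths[k] * dt > max_interp_ms * (1 + 1e-9)) next
      a <- i0 - 1L; b <- i1 + 1L
      f <- (timestamp_ms[i0:i1] - timestamp_ms[a]) /
        (timestamp_ms[b] - timestamp_ms[a])
      p[i0:i1] <- p[a] + f * (p[b] - p[a])
    }
  }

  if (smooth_k > 1 && sum(is.finite(p)) >= smooth_k) {
    sm <- stats::runmed(ifelse(is.finite(p), p, stats::median(p, na.rm = TRUE)),
                        k = smooth_k, endrule = "keep")
    p <- ifelse(is.finite(p), sm, NA)
  }

  usable <- mean(!is.finite(p)) <= 0.9
  structure(list(timestamp_ms = timestamp_ms, pupil_mm = p,
                 valid = is.finite(p), usable = usable,
                 mean_mm = if (any(is.finite(p))) mean(p, na.rm = TRUE) else NA_real_),
            class = "pupil_trace")
}

#' Standardize a pupil trace by the participant mean
#'
#' Divides the cleaned trace by the participant's absolute mean pupil size,
#' giving a dimensionless relative trace whose mean is 1.
#'
#' @param trace A `pupil_trace` from [preprocess_pupil()].
#' @return The trace with an added `relative` vector (mean 1).
#' @export
standardize_pupil <- function(trace) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (!is.finite(trace$mean_mm) || trace$mean_mm == 0) {
    stop("participant mean pupil size is zero or undefined")
  }
  trace$relative <- trace$pupil_mm / trace$mean_mm
  trace
}

#' Per-fixation pupillary response
#'
#' The response to a fixation is the mean of the standardized pupil trace
#' over the fixation's span shifted forward for pupillary latency: samples
#' in `[onset + shift_window[1], offset + shift_window[2]]` ms. With
#' `fixed_lag`, a single-lag alternative is used instead:
#' `[onset + lag, offset + lag]`.
#'
#' @param trace A standardized `pupil_trace` (see [standardize_pupil()]).
#' @param onset_ms,offset_ms Fixation bounds.
#' @param shift_window Latency window, default `c(200, 400)` ms.
#' @param fixed_lag Optional single lag in ms replacing the window.
#' @return Mean relative pupil size in the shifted span (about 1; larger
#'   values = dilation), or `NA` when no valid samples fall in the window.
#' @export
fixation_pupil_response <- function(trace, onset_ms, offset_ms,
                                    shift_window = c(200, 400),
                                    fixed_lag = NULL) {
  stopifnot(!is.null(trace$relative))
  if (!is.null(fixed_lag)) {
    lo <- onset_ms + fixed_lag; hi <- offset_ms + fixed_lag
  } else {
    lo <- onset_ms + shift_window[1]; hi <- offset_ms + shift_window[2]
  }
  sel <- trace$timestamp_ms >= lo & trace$timestamp_ms <= hi &
    is.finite(trace$relative)
  if (!any(sel)) return(NA_real_)
  mean(trace$relative[sel])
}

#' Fit early/late temporal pupil components
#'
#' Bins per-fixation responses by time-in-scene over `[0, 5000]` ms,
#' averages within participant x scene x bin, runs a principal component
#' analysis on the observation x bin matrix (missing bins mean-imputed for
#' the decomposition only), varimax-rotates the first two components, and
#' labels the component whose absolute-loading centroid lies earlier in
#' scene time PR1 (early) and the other PR2 (late).
#'
#' @param records Data frame with columns `participant`, `scene`,
#'   `time_in_scene_ms`, `pupil_response`.
#' @param n_bins Number of time bins (default 20, i.e. 250 ms bins).
#' @param window_ms Scene window (default `c(0, 5000)`).
#' @return A list of class `pupil_component_model`: `bins` (bin centres,
#'   ms), `loadings` (n_bins x 2 matrix, columns PR1/PR2),
#'   `explained_variance` (share per rotated component), `centroids_ms`.
#' @export
fit_time_components <- function(records, n_bins = 20,
                                window_ms = c(0, 5000)) {
  if (n_bins < 3) stop("n_bins must be >= 3")
  brks <- seq(window_ms[1], window_ms[2], length.out = n_bins + 1)
  bin <- cut(records$time_in_scene_ms, brks, include.lowest = TRUE,
             labels = FALSE)
  ok <- !is.na(bin) & is.finite(records$pupil_response)
  df <- data.frame(obs = interaction(records$participant[ok],
                                     records$scene[ok], drop = TRUE),
                   bin = bin[ok], y = records$pupil_response[ok])
  m <- tapply(df$y, list(df$obs, df$bin), mean)
  full <- matrix(NA_real_, nrow(m), n_bins,
                 dimnames = list(rownames(m), seq_len(n_bins)))
  full[, as.integer(colnames(m))] <- m
  if (nrow(full) < 3) stop("too few participant x scene observations")
  # mean-impute missing bins (decomposition only)
  bm <- colMeans(full, na.rm = TRUE)
  bm[!is.finite(bm)] <- mean(full, na.rm = TRUE)
  for (j in seq_len(n_bins)) full[!is.finite(full[, j]), j] <- bm[j]

  pc <- stats::prcomp(full, center = TRUE, scale. = FALSE)
  V <- pc$rotation[, 1:2, drop = FALSE]
  # varimax criterion evaluated on variance-scaled loadings; the resulting
  # orthogonal rotation is applied to the orthonormal basis so the returned
  # loading vectors stay mutually orthogonal
  L <- V %*% diag(pc$sdev[1:2], 2)
  rot <- stats::varimax(L, normalize = FALSE)
  Lr <- V %*% rot$rotmat
  # sign convention: dominant loading positive
  for (j in 1:2) if (sum(Lr[, j]) < 0) Lr[, j] <- -Lr[, j]
  centres <- (brks[-1] + brks[-length(brks)]) / 2
  centroid <- apply(abs(Lr), 2, function(l) sum(centres * l) / sum(l))
  ordr <- order(centroid)
  Lr <- Lr[, ordr, drop = FALSE]
  centroid <- centroid[ordr]
  colnames(Lr) <- c("PR1", "PR2")
  tot_var <- sum(pc$sdev^2)
  rot_var <- diag(t(rot$rotmat) %*% diag(pc$sdev[1:2]^2, 2) %*% rot$rotmat)
  expl <- rot_var[ordr] / tot_var
  names(expl) <- c("PR1", "PR2")
  structure(list(bins = centres, loadings = Lr,
                 explained_variance = expl, centroids_ms = centroid,
                 n_bins = n_bins, window_ms = window_ms),
            class = "pupil_component_model")
}

#' Component-weighted pupillary responses (PR1, PR2)
#'
#' Multiplies a fixation's pupillary response by the loading of each rotated
#' component at the fixation's time bin.
#'
#' @param response Per-fixation pupillary response (vector).
#' @param time_in_scene_ms Fixation time in scene (vector, within the
#'   model's window).
#' @param model A `pupil_component_model`.
#' @return Data frame with columns `PR1`, `PR2`.
#' @export
weight_response <- function(response, time_in_scene_ms, model) {
  stopifnot(inherits(model, "pupil_component_model"))
  w <- model$window_ms
  if (any(time_in_scene_ms < w[1] | time_in_scene_ms > w[2], na.rm = TRUE)) {
    stop("time_in_scene_ms outside the model window; pre-filter records")
  }
  brks <- seq(w[1], w[2], length.out = model$n_bins + 1)
  bin <- cut(time_in_scene_ms, brks, include.lowest = TRUE, labels = FALSE)
  data.frame(PR1 = response * model$loadings[bin, "PR1"],
             PR2 = response * model$loadings[bin, "PR2"])
}
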