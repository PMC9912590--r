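#' @title Per-frame salience and luminance maps
#' @description
#' Computes the three per-frame feature grids the analysis samples at gaze
#' locations: physical salience by spectral-residual analysis of the
#' log-amplitude spectrum, motion salience by per-pixel Gaussian-mixture
#' background subtraction (learning rate 0.002), and relative luminance from
#' gamma-corrected RGB with Rec.709 coefficients. All maps are normalized to
#' `[0, 1]` and spatially aligned with the source frame.
#' @name frame_features
NULL

# ---- small image utilities ------------------------------------------------

# symmetric (edge-inclusive) reflection padding of a matrix by r rows/cols
pad_reflect <- function(m, r) {
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- c(rev(seq_len(min(r, n1))), seq_len(n1),
          n1 + 1 - seq_len(min(r, n1)))
  ci <- c(rev(seq_len(min(r, n2))), seq_len(n2),
          n2 + 1 - seq_len(min(r, n2)))
  m[ri, ci, drop = FALSE]
}

# circular padding of a matrix by r rows/cols
pad_circular <- function(m, r) {
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- ((seq_len(n1 + 2 * r) - r - 1) %% n1) + 1
  ci <- ((seq_len(n2 + 2 * r) - r - 1) %% n2) + 1
  m[ri, ci, drop = FALSE]
}

# separable convolution with a 1-D kernel (odd length)
conv_sep <- function(m, kern, pad = c("reflect", "circular")) {
  pad <- match.arg(pad)
  r <- (length(kern) - 1L) %/% 2L
  if (r == 0) return(m * kern)
  p <- if (pad == "reflect") pad_reflect(m, r) else pad_circular(m, r)
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2 + 2 * r)
  for (o in seq_along(kern)) {          # rows
    out <- out + kern[o] * p[(o - 1L) + seq_len(n1), , drop = FALSE]
  }
  res <- matrix(0, n1, n2)
  for (o in seq_along(kern)) {          # cols
    res <- res + kern[o] * out[, (o - 1L) + seq_len(n2), drop = FALSE]
  }
  res
}

gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur of a matrix with reflective padding
#'
#' Separable Gaussian convolution; the normalized kernel plus symmetric
#' reflection padding conserves the spatial mean.
#'
#' @param m Numeric matrix.
#' @param sigma Kernel standard deviation in pixels.
#' @param radius Kernel half-width in pixels (default `ceiling(3 * sigma)`).
#' @param pad `"reflect"` (default) or `"circular"` boundary handling.
#' @return Blurred matrix, same shape.
#' @export
gaussian_blur <- function(m, sigma, radius = ceiling(3 * sigma),
                          pad = "reflect") {
  conv_sep(m, gaussian_kernel(sigma, radius), pad = pad)
}

# 3x3 box mean with circular padding: used on the log-amplitude spectrum,
# whose domain (DFT frequencies) is periodic
box_mean3 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  for (di in -1:1) {
    for (dj in -1:1) {
      out <- out + m[((seq_len(n1) - 1 + di) %% n1) + 1,
                     ((seq_len(n2) - 1 + dj) %% n2) + 1] / 9
    }
  }
  out
}

#' Bilinear resize of a matrix
#'
#' @param m Numeric matrix.
#' @param new_h,new_w Target dimensions.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(m, new_h, new_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == new_h && w == new_w) return(m)
  # map target pixel centres onto source pixel centres
  ry <- (seq_len(new_h) - 0.5) * h / new_h + 0.5
  rx <- (seq_len(new_w) - 0.5) * w / new_w + 0.5
  y0 <- pmin(pmax(floor(ry), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(rx), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  top <- a * outer(rep(1, new_h), 1 - fx) + b * outer(rep(1, new_h), fx)
  bot <- c_ * outer(rep(1, new_h), 1 - fx) + d * outer(rep(1, new_h), fx)
  top * outer(1 - fy, rep(1, new_w)) + bot * outer(fy, rep(1, new_w))
}

# min-max normalize to [0,1]; constant input maps to zero by convention
minmax01 <- function(m) {
  rng <- range(m)
  if (!all(is.finite(rng)) || rng[2] - rng[1] < .Machine$double.eps * 100) {
    return(matrix(0, nrow(m), ncol(m)))
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

frame_to_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) == 3) {
    return((frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3)
  }
  stop("frame must be a matrix or an HxWx3 array")
}

# ---- physical salience: spectral residual ---------------------------------

#' Spectral-residual physical salience
#'
#' The spectral-residual method: the frame is converted to grayscale and
#' downscaled to `downscale_width` pixels wide, Fourier transformed, and the
#' log-amplitude spectrum is compared with its local (3x3 box) mean — the
#' difference, the spectral residual, captures the statistically
#' non-redundant part of the image. The residual is recombined with the
#' original phase, inverse transformed, squared, Gaussian smoothed,
#' upscaled to the frame size and min-max normalized. A constant frame maps
#' to an all-zero grid by convention.
#'
#' @param frame Grayscale matrix or HxWx3 RGB array, values in `[0, 1]`.
#' @param downscale_width Working width in pixels (default 64, the method's
#'   canonical scale).
#' @param smooth_sigma Post-smoothing Gaussian sigma on the working grid
#'   (default 2.5).
#' @return Salience grid in `[0, 1]`, same shape as the input frame.
#' @export
spectral_residual_salience <- function(frame, downscale_width = 64,
                                       smooth_sigma = 2.5) {
  g <- frame_to_gray(frame)
  h <- nrow(g); w <- ncol(g)
  if (diff(range(g)) < .Machine$double.eps * 100) {
    return(matrix(0, h, w))            # constant frame: nothing non-redundant
  }
  wh <- max(round(h * downscale_width / w), 8)
  small <- resize_bilinear(g, wh, downscale_width)
  f <- stats::fft(small)
  amp <- Mod(f)
  logamp <- log1p(amp)                 # log amplitude, safe at spectrum zeros
  residual <- logamp - box_mean3(logamp)
  # unit phasor, zero where no spectral energy exists (keeps the operator
  # exactly equivariant under shifts and right-angle rotations)
  nz <- amp > max(amp) * 1e-12
  phasor <- matrix(0i, nrow(f), ncol(f))
  phasor[nz] <- f[nz] / amp[nz]
  rec <- stats::fft(exp(residual) * phasor, inverse = TRUE) / length(small)
  sal <- Mod(rec)^2
  # circular smoothing: the reconstruction lives on the periodic DFT grid
  sal <- gaussian_blur(sal, smooth_sigma, pad = "circular")
  sal <- resize_bilinear(sal, h, w)
  minmax01(sal)
}

# ---- motion salience: Gaussian-mixture background subtraction -------------

#' Initialize a per-pixel Gaussian-mixture background model
#'
#' Adaptive background mixture model: each pixel's intensity history is
#' modelled by `k` weighted Gaussians updated online with learning rate
#' `alpha`; components are ranked by weight/sd and the top-ranked mass
#' `background_fraction` is taken as background.
#'
#' @param frame First grayscale frame (matrix or RGB array, `[0, 1]`).
#' @param k Number of mixture components (default 5).
#' @param alpha Learning rate (default 0.002).
#' @param match_sd Match threshold in component SDs (default 2.5).
#' @param background_fraction Cumulative weight taken as background
#'   (default 0.9).
#' @param init_sd Initial component SD on the `[0, 255]` intensity scale
#'   (default 15), stored on the `[0, 1]` scale.
#' @return A list of class `motion_model_state`.
#' @export
motion_model_init <- function(frame, k = 5, alpha = 0.002, match_sd = 2.5,
                              background_fraction = 0.9, init_sd = 15) {
  g <- frame_to_gray(frame)
  h <- nrow(g); w <- ncol(g)
  mu <- array(0, c(h, w, k)); va <- array((init_sd / 255)^2, c(h, w, k))
  wt <- array(0, c(h, w, k))
  mu[, , 1] <- g
  wt[, , 1] <- 1
  structure(list(mu = mu, var = va, w = wt, k = k, alpha = alpha,
                 match_sd = match_sd,
                 background_fraction = background_fraction,
                 init_var = (init_sd / 255)^2, n_frames = 1L,
                 dim = c(h, w)),
            class = "motion_model_state")
}

#' Update the background model with one frame and emit motion salience
#'
#' Online mixture update: the best-matching component within `match_sd`
#' standard deviations absorbs the pixel (weights move by `alpha`, mean and
#' variance by `alpha` toward the observation); an unmatched pixel replaces
#' the lowest-weight component. A pixel is foreground when it matches no
#' component of the background set (top-ranked components holding
#' `background_fraction` of the weight). Weights are renormalized to a
#' simplex after every update.
#'
#' @param state A `motion_model_state`.
#' @param frame Next frame (matrix or RGB array, same shape).
#' @return List with updated `state` and `salience`, the foreground map in
#'   `[0, 1]`.
#' @export
motion_salience_update <- function(state, frame) {
  g <- frame_to_gray(frame)
  if (!all(dim(g) == state$dim)) stop("frame shape mismatch with model state")
  h <- state$dim[1]; w <- state$dim[2]; k <- state$k
  a <- state$alpha
  mu <- state$mu; va <- state$var; wt <- state$w

  dev <- abs(sweep(mu, c(1, 2), g, "-"))
  match <- dev < state$match_sd * sqrt(va)
  # best match = matching component with the largest weight
  scored <- ifelse(match, wt, -Inf)
  best <- apply(scored, c(1, 2), which.max)
  any_match <- apply(match, c(1, 2), any)

  onehot <- array(0, c(h, w, k))
  for (j in seq_len(k)) onehot[, , j] <- (best == j) & any_match

  # weight update; unmatched pixels keep weights (their lowest component is
  # replaced below)
  wt <- (1 - a) * wt + a * onehot
  # mean/variance update for the matched component
  if (a > 0) {
    gj <- array(g, c(h, w, k))
    mu_new <- mu + a * (gj - mu)
    va_new <- va + a * ((gj - mu)^2 - va)
    mu <- ifelse(onehot == 1, mu_new, mu)
    va <- ifelse(onehot == 1, pmax(va_new, 1e-6), va)
  }
  # replacement of the weakest component where nothing matched
  if (any(!any_match)) {
    wmin <- apply(wt, c(1, 2), which.min)
    for (j in seq_len(k)) {
      repl <- (!any_match) & (wmin == j)
      if (any(repl)) {
        muj <- mu[, , j]; vaj <- va[, , j]; wtj <- wt[, , j]
        muj[repl] <- g[repl]
        vaj[repl] <- state$init_var
        wtj[repl] <- 0.05
        mu[, , j] <- muj; va[, , j] <- vaj; wt[, , j] <- wtj
      }
    }
  }
  wsum <- apply(wt, c(1, 2), sum)
  wt <- sweep(wt, c(1, 2), wsum, "/")

  # background set: top components by w/sd holding background_fraction mass
  rankscore <- wt / sqrt(va)
  ord <- apply(rankscore, c(1, 2), order, decreasing = TRUE)  # k x h x w
  fg <- matrix(TRUE, h, w)
  cum <- matrix(0, h, w)
  for (r in seq_len(k)) {
    comp <- matrix(ord[r, , ], h, w)
    in_bg <- cum < state$background_fraction
    sel_match <- matrix(FALSE, h, w)
    sel_w <- matrix(0, h, w)
    for (j in seq_len(k)) {
      pick <- comp == j
      if (any(pick)) {
        mj <- match[, , j]; wj <- wt[, , j]
        sel_match[pick] <- mj[pick]
        sel_w[pick] <- wj[pick]
      }
    }
    fg[in_bg & sel_match] <- FALSE
    cum <- cum + ifelse(in_bg, sel_w, 0)
  }

  state$mu <- mu; state$var <- va; state$w <- wt
  state$n_frames <- state$n_frames + 1L
  list(state = state, salience = ifelse(fg, 1, 0))
}

#' Motion salience over a frame sequence
#'
#' Runs [motion_salience_update()] over an ordered frame list, resetting the
#' model at scene cuts so foreground evidence never leaks across scenes.
#'
#' @param frames List of frames.
#' @param cuts Integer indices of frames that start a new scene (model is
#'   re-initialized there); frame 1 is always a reset.
#' @param ... Passed to [motion_model_init()].
#' @return List of salience grids, one per frame (resets give all-zero maps).
#' @export
motion_salience_sequence <- function(frames, cuts = integer(0), ...) {
  out <- vector("list", length(frames))
  state <- NULL
  for (i in seq_along(frames)) {
    if (i == 1L || i %in% cuts) {
      state <- motion_model_init(frames[[i]], ...)
      out[[i]] <- matrix(0, state$dim[1], state$dim[2])
    } else {
      up <- motion_salience_update(state, frames[[i]])
      state <- up$state
      out[[i]] <- up$salience
    }
  }
  out
}

# ---- luminance ------------------------------------------------------------

#' sRGB gamma linearization
#'
#' Piecewise sRGB transfer function (linear segment below 0.04045, power
#' 2.4 above), mapping gamma-encoded values in `[0, 1]` to linear light.
#'
#' @param v Numeric vector/array of gamma-encoded values in `[0, 1]`.
#' @return Linearized values in `[0, 1]`.
#' @export
srgb_linearize <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

#' Relative-luminance map of an RGB frame
#'
#' Channels are gamma-linearized and combined with the Rec.709 luminance
#' coefficients, `L = 0.2126 R + 0.7152 G + 0.0722 B`. The local map is a
#' Gaussian blur (sigma `blur_sigma`, kernel extent `kernel_frac` of the
#' frame width/height) of the per-pixel luminance; the global value is the
#' unblurred spatial mean.
#'
#' @param frame HxWx3 RGB array, values in `[0, 1]` or `[0, 255]`.
#' @param blur_sigma Gaussian sigma in frame pixels (default 10).
#' @param kernel_frac Kernel half-extent as a fraction of frame size
#'   (default 0.10).
#' @param gamma_corrected Logical; if TRUE (default) the input is assumed
#'   gamma-encoded (sRGB) and linearized first.
#' @return List with `map` (local luminance grid in `[0, 1]`) and `global`
#'   (scalar mean luminance).
#' @export
luminance_map <- function(frame, blur_sigma = 10, kernel_frac = 0.10,
                          gamma_corrected = TRUE) {
  if (length(dim(frame)) != 3 || dim(frame)[3] != 3) {
    stop("luminance requires an RGB (HxWx3) frame")
  }
  if (max(frame) > 1) frame <- frame / 255
  lin <- if (gamma_corrected) srgb_linearize(frame) else frame
  L <- 0.2126 * lin[, , 1] + 0.7152 * lin[, , 2] + 0.0722 * lin[, , 3]
  radius <- max(1L, round(kernel_frac * min(dim(L))))
  map <- gaussian_blur(L, blur_sigma, radius)
  list(map = map, global = mean(L))
}

#' Per-frame percent-of-maximum salience summary
#'
#' Expresses each normalized map as its spatial mean in percent of the
#' frame's total possible salience (an all-ones map is 100%).
#'
#' @param maps List of normalized grids (or a single grid).
#' @return Numeric vector of percentages.
#' @export
scene_salience_summary <- function(maps) {
  if (is.matrix(maps)) maps <- list(maps)
  vapply(maps, function(m) 100 * mean(m), numeric(1))
}

#' All feature maps for one frame
#'
#' Convenience wrapper returning the three aligned grids for a frame within
#' a sequence (motion salience requires the running model state).
#'
#' @param frame RGB frame.
#' @param motion_state Optional `motion_model_state` (updated in place of
#'   the return value); NULL gives an all-zero motion map.
#' @param frame_index Index within the scene.
#' @return List of class `frame_feature_maps`: `physical_salience`,
#'   `motion_salience`, `luminance`, `global_luminance`, `frame_index`,
#'   and the updated `motion_state`.
#' @export
frame_feature_maps <- function(frame, motion_state = NULL, frame_index = 1L) {
  phys <- spectral_residual_salience(frame)
  lum <- luminance_map(frame)
  if (is.null(motion_state)) {
    motion <- matrix(0, nrow(phys), ncol(phys))
  } else {
    up <- motion_salience_update(motion_state, frame)
    motion <- up$salience
    motion_state <- up$state
  }
  structure(list(physical_salience = phys, motion_salience = motion,
                 luminance = lum$map, global_luminance = lum$global,
                 frame_index = frame_index, motion_state = motion_state),
            class = "frame_feature_maps")
}
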