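# Independent straight-line implementations used as oracles. These are kept
# deliberately naive (explicit loops, dense convolutions) and share no code
# with the package internals they check.

# dense 2-D convolution with symmetric (edge-inclusive) reflection padding
oracle_conv2 <- function(m, kern) {
  kr <- (nrow(kern) - 1L) %/% 2L
  kc <- (ncol(kern) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  reflect <- function(i, n) {
    # mirror index into 1..n (edge-inclusive reflection)
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      acc <- 0
      for (dr in -kr:kr) {
        for (dc in -kc:kc) {
          acc <- acc + kern[dr + kr + 1L, dc + kc + 1L] *
            m[reflect(r + dr, h), reflect(cc + dc, w)]
        }
      }
      out[r, cc] <- acc
    }
  }
  out
}

oracle_gaussian_kernel2 <- function(sigma, radius) {
  x <- seq(-radius, radius)
  k1 <- exp(-x^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  outer(k1, k1)
}

# straight-line spectral-residual salience for a square grayscale frame at
# its native resolution (no resizing involved)
oracle_spectral_residual <- function(g, smooth_sigma = 2.5) {
  f <- stats::fft(g)
  amp <- Mod(f)
  logamp <- log(1 + amp)
  # local mean over the periodic frequency grid (explicit wrap-around)
  h <- nrow(g); w <- ncol(g)
  local_mean <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      acc <- 0
      for (dr in -1:1) {
        for (dc in -1:1) {
          acc <- acc + logamp[(r + dr - 1) %% h + 1, (cc + dc - 1) %% w + 1]
        }
      }
      local_mean[r, cc] <- acc / 9
    }
  }
  residual <- logamp - local_mean
  phasor <- ifelse(amp > max(amp) * 1e-12, f / pmax(amp, 1e-300), 0i)
  spec <- exp(residual) * phasor
  rec <- stats::fft(spec, inverse = TRUE) / length(g)
  sal <- Mod(rec)^2
  radius <- ceiling(3 * smooth_sigma)
  # dense Gaussian smoothing on the periodic grid (explicit wrap-around)
  kern <- oracle_gaussian_kernel2(smooth_sigma, radius)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      acc <- 0
      for (dr in -radius:radius) {
        for (dc in -radius:radius) {
          acc <- acc + kern[dr + radius + 1L, dc + radius + 1L] *
            sal[(r + dr - 1) %% h + 1, (cc + dc - 1) %% w + 1]
        }
      }
      out[r, cc] <- acc
    }
  }
  sal <- out
  rng <- range(sal)
  if (rng[2] - rng[1] < 1e-12) return(matrix(0, nrow(g), ncol(g)))
  (sal - rng[1]) / (rng[2] - rng[1])
}

# raw sample frame with both eyes identical and fully valid
make_raw <- function(t, x, y, pupil = 3.6, valid = TRUE) {
  data.frame(timestamp_ms = t,
             gx_left_px = x, gy_left_px = y,
             gx_right_px = x, gy_right_px = y,
             pupil_left_mm = pupil, pupil_right_mm = pupil,
             valid_left = valid, valid_right = valid)
}

# trace moving at a constant angular velocity (deg/s) along x
constant_velocity_trace <- function(v_deg_s, geometry, n = 120,
                                    y_px = 480) {
  dt <- 1000 / geometry$sampling_rate_hz
  step_px <- deg_to_px(v_deg_s * dt / 1000, geometry)
  x <- 100 + step_px * (seq_len(n) - 1)
  make_raw(t = (seq_len(n) - 1) * dt, x = x, y = y_px)
}

# synthetic per-fixation pupil responses mixing an early and a late
# temporal bump with independent observation-level amplitudes
make_two_bump_records <- function(n_obs = 60, n_per_obs = 30, seed = 1,
                                  noise_sd = 0.02) {
  set.seed(seed)
  early <- function(t) exp(-(t - 1000)^2 / (2 * 500^2))
  late <- function(t) exp(-(t - 4000)^2 / (2 * 500^2))
  rows <- list()
  for (o in seq_len(n_obs)) {
    a <- stats::rnorm(1, 1, 0.5)
    b <- stats::rnorm(1, 1, 0.5)
    t <- stats::runif(n_per_obs, 0, 5000)
    rows[[o]] <- data.frame(
      participant = sprintf("p%02d", (o - 1) %/% 4 + 1),
      scene = sprintf("s%02d", (o - 1) %% 4 + 1),
      obs = o,
      time_in_scene_ms = t,
      pupil_response = 1 + 0.05 * (a * early(t) + b * late(t)) +
        stats::rnorm(n_per_obs, 0, noise_sd))
  }
  out <- do.call(rbind, rows)
  # distinct participant x scene cell per obs
  out$scene <- sprintf("s%03d", out$obs)
  out
}
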