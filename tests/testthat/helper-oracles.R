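# Independent reference implementations used to cross-check package code.

# Itoh's 1-D unwrapping: cumulative sum of wrapped phase differences.
itoh_unwrap_1d <- function(wrapped) {
  d <- diff(wrapped)
  d <- (d + pi) %% (2 * pi) - pi
  cumsum(c(wrapped[1L], d))
}

# External field of a uniformly susceptible sphere (radius a, susceptibility
# chi) for the 1/3 - kz^2/|k|^2 kernel convention: zero inside,
# chi * a^3 * (3 cos^2 theta - 1) / (3 r^3) outside, theta from the z axis.
sphere_field_analytic <- function(shape, voxel_size, center, a, chi) {
  cx <- (seq_len(shape[1]) - center[1]) * voxel_size[1]
  cy <- (seq_len(shape[2]) - center[2]) * voxel_size[2]
  cz <- (seq_len(shape[3]) - center[3]) * voxel_size[3]
  X <- array(rep(cx, times = shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(cy, each = shape[1]), times = shape[3]), dim = shape)
  Z <- array(rep(cz, each = shape[1] * shape[2]), dim = shape)
  r2 <- X^2 + Y^2 + Z^2
  out <- array(0, dim = shape)
  ext <- r2 > a^2
  out[ext] <- chi * a^3 * (3 * Z[ext]^2 / r2[ext] - 1) / (3 * r2[ext]^1.5)
  out
}

# First-order propagation of additive magnitude noise (SD sigma) through the
# unweighted log-linear mono-exponential fit: SD of the T2* estimate.
loglinear_t2star_sd <- function(te, t2star, amplitude, sigma) {
  m <- amplitude * exp(-te / t2star)
  tc <- te - mean(te)
  cc <- tc / sum(tc^2)                # slope = sum(cc * log m)
  var_slope <- sum(cc^2 * (sigma / m)^2)
  t2star^2 * sqrt(var_slope)
}

# Direct fixed-point iteration of the one-period longitudinal map, reading
# mz just before the inversion pulse (no closed-form algebra).
iterate_period_mz <- function(p, T1, M0 = 1, n_periods = 400L) {
  g <- derive_gaps(p)
  a1 <- p$alpha_1 * p$flip_accuracy * pi / 180
  a2 <- p$alpha_2 * p$flip_accuracy * pi / 180
  relax <- function(mz, dt) M0 + (mz - M0) * exp(-dt / T1)
  mz <- M0
  for (i in seq_len(n_periods)) {
    mz <- (1 - 2 * p$inv_efficiency) * mz
    mz <- relax(mz, g[["T_A"]])
    for (k in seq_len(p$n_lines)) mz <- relax(mz * cos(a1), p$T_R_gre)
    mz <- relax(mz, g[["T_B"]])
    for (k in seq_len(p$n_lines)) mz <- relax(mz * cos(a2), p$T_R_gre)
    mz <- relax(mz, g[["T_C"]])
  }
  mz
}

# Gaussian low-pass filter via FFT (periodic), used to build smooth test maps.
fft_smooth <- function(x, sigma_vox) {
  d <- dim(x)
  g <- lapply(1:3, function(i) {
    f <- c(0:(d[i] - 1))
    f[f >= ceiling(d[i] / 2)] <- f[f >= ceiling(d[i] / 2)] - d[i]
    exp(-2 * (pi * f / d[i] * sigma_vox)^2)
  })
  G <- outer(outer(g[[1]], g[[2]]), g[[3]])
  Re(stats::fft(stats::fft(x) * G, inverse = TRUE)) / length(x)
}

rel_err <- function(a, b) max(abs(a - b) / pmax(abs(b), .Machine$double.eps))
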