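#' Monte-Carlo simulation configuration
#'
#' Describes one precision/accuracy experiment: noisy signals are
#' synthesized for a range of true relaxation times, the chosen estimator
#' is applied to every noisy replicate, and the per-value SD of the
#' estimates, `sigma_T`, summarizes the precision.
#'
#' The SNR is defined as (maximum noise-free signal over the scanned
#' range) / (noise SD), applied identically to both inversion images, so
#' that SNR levels are comparable across protocols.
#'
#' @param estimator `"t1_magnitude_fit"` (two-parameter scale + T1 fit to
#'   the two magnitudes), `"t1_rho_lookup"` (uniform-image combination plus
#'   lookup inversion), or `"t2star_loglinear"`.
#' @param protocol an [`protocol()`] supplying timings/angles (echo times
#'   for the T2* case).
#' @param snr signal-to-noise ratio (conventionally 25, 50 or 100).
#' @param n_reps replicates per true value (N; 2000 is a practical default,
#'   configurable up to 20000).
#' @param n_values number of true relaxation-time values probed (n_T).
#' @param value_range `(lo, hi)` of the true values, seconds.
#' @param seed integer seed; fixed seed implies bitwise-reproducible
#'   results.
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(estimator = c("t1_magnitude_fit", "t1_rho_lookup",
                                    "t2star_loglinear"),
                      protocol, snr = 50, n_reps = 2000L, n_values = 100L,
                      value_range = NULL, seed = 1L) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(protocol, "mri_protocol"), snr > 0, n_reps >= 2L,
            n_values >= 1L)
  if (is.null(value_range))
    value_range <- if (estimator == "t2star_loglinear") c(2e-3, 60e-3)
                   else c(0.5, 3.5)
  stopifnot(length(value_range) == 2L, value_range[1] < value_range[2],
            value_range[1] > 0)
  if (startsWith(estimator, "t1") && protocol$sequence_kind == "me_flash")
    stop("T1 estimators require an (ME-)MP2RAGE protocol")
  structure(list(estimator = estimator, protocol = protocol, snr = snr,
                 n_reps = as.integer(n_reps), n_values = as.integer(n_values),
                 value_range = value_range, seed = as.integer(seed)),
            class = "mc_config")
}

mc_result <- function(true_values, mean_est, sigma_T, n_dropped = 0L) {
  structure(list(true_values = true_values, mean_est = mean_est,
                 sigma_T = sigma_T, n_dropped = n_dropped),
            class = "mc_result")
}

#' Monte-Carlo precision of T1 estimation
#'
#' For each true T1, the noise-free signals of the two inversion volumes
#' (first echo, k-space centre) are synthesized from the closed-form model;
#' `n_reps` noisy replicates receive independent Gaussian noise of SD
#' `max |signal| / snr`, and T1 is re-estimated per replicate:
#'
#' * `t1_magnitude_fit` - noise is added to the magnitude images; the
#'   estimate minimizes the two-point residual over a T1 grid with the
#'   non-negative scale profiled out analytically (the magnitude-only route,
#'   which loses the sign of the first-inversion signal and is therefore a
#'   lower bound on the accuracy of the complex route);
#' * `t1_rho_lookup` - noise is added to the signed (real) signals, the
#'   uniform image is formed, and T1 comes from the lookup inversion.
#'
#' @param cfg an [`mc_config()`] with a T1 estimator.
#' @return An `mc_result` with `true_values`, `mean_est`, `sigma_T`.
#' @export
run_t1_mc <- function(cfg) {
  stopifnot(inherits(cfg, "mc_config"),
            cfg$estimator %in% c("t1_magnitude_fit", "t1_rho_lookup"))
  p <- cfg$protocol
  lo <- cfg$value_range[1]; hi <- cfg$value_range[2]
  tv <- seq(lo, hi, length.out = cfg$n_values)
  bs <- block_signals(p, tissue_params(T1 = tv))
  s1 <- bs$s1[, 1L]; s2 <- bs$s2[, 1L]
  sdn <- max(abs(c(s1, s2))) / cfg$snr

  pad <- 0.25 * (hi - lo)
  grid <- seq(max(lo - pad, 0.05), hi + pad, length.out = 1201L)
  bg <- block_signals(p, tissue_params(T1 = grid))
  g1 <- bg$s1[, 1L]; g2 <- bg$s2[, 1L]
  lut <- if (cfg$estimator == "t1_rho_lookup")
    build_rho_lookup(p, t1_min = max(lo - pad, 0.05), t1_max = hi + pad,
                     step = 1e-3)
  else NULL

  set.seed(cfg$seed)
  mean_est <- sigma_T <- numeric(cfg$n_values)
  for (i in seq_len(cfg$n_values)) {
    e1 <- stats::rnorm(cfg$n_reps, 0, sdn)
    e2 <- stats::rnorm(cfg$n_reps, 0, sdn)
    if (cfg$estimator == "t1_magnitude_fit") {
      m1 <- abs(s1[i]) + e1
      m2 <- abs(s2[i]) + e2
      a1 <- abs(g1); a2 <- abs(g2)
      # profile the non-negative scale per grid point, take the best grid T1
      k <- (outer(m1, a1) + outer(m2, a2)) /
        rep(a1^2 + a2^2, each = cfg$n_reps)
      k[k < 0] <- 0
      cost <- (m1 - k * rep(a1, each = cfg$n_reps))^2 +
        (m2 - k * rep(a2, each = cfg$n_reps))^2
      est <- grid[max.col(-cost, ties.method = "first")]
    } else {
      rho <- rho_combine(s1[i] + e1, s2[i] + e2)
      est <- invert_rho(as.numeric(rho), lut)$t1
    }
    mean_est[i] <- mean(est)
    sigma_T[i] <- stats::sd(est)
  }
  mc_result(tv, mean_est, sigma_T)
}

#' Monte-Carlo precision of log-linear T2* estimation
#'
#' Mono-exponential magnitudes (`unit amplitude`) are synthesized at the
#' protocol's echo times for each true T2*, Gaussian noise of SD
#' `max signal / snr` is added, and [fit_t2star()] is applied. Replicates
#' in which fewer than two echoes stay positive (or no decay is seen) are
#' dropped and counted.
#'
#' @param cfg an [`mc_config()`] with `estimator = "t2star_loglinear"`.
#' @return An `mc_result`; `n_dropped` counts discarded replicates.
#' @export
run_t2star_mc <- function(cfg) {
  stopifnot(inherits(cfg, "mc_config"),
            cfg$estimator == "t2star_loglinear")
  te <- echo_times(cfg$protocol)
  tv <- seq(cfg$value_range[1], cfg$value_range[2],
            length.out = cfg$n_values)
  # max noise-free signal over the scanned range: first echo, longest T2*
  sdn <- exp(-te[1L] / max(tv)) / cfg$snr
  set.seed(cfg$seed)
  mean_est <- sigma_T <- numeric(cfg$n_values)
  dropped <- 0L
  for (i in seq_len(cfg$n_values)) {
    clean <- exp(-te / tv[i])
    mag <- matrix(clean, nrow = cfg$n_reps, ncol = length(te),
                  byrow = TRUE) +
      matrix(stats::rnorm(cfg$n_reps * length(te), 0, sdn),
             nrow = cfg$n_reps)
    f <- fit_t2star(te, mag)
    est <- f$T2star[f$valid]
    dropped <- dropped + sum(!f$valid)
    mean_est[i] <- mean(est)
    sigma_T[i] <- stats::sd(est)
  }
  mc_result(tv, mean_est, sigma_T, n_dropped = dropped)
}

#' Summarize a Monte-Carlo result
#'
#' The mean and SD of the per-value precision `sigma_T` over the scanned
#' range (`mu_sigma`, `sigma_sigma`); the SD is the population form.
#'
#' @param result an `mc_result`.
#' @return Named numeric vector `c(mu_sigma, sigma_sigma)` in seconds.
#' @export
mc_summary <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  s <- result$sigma_T
  mu <- mean(s)
  c(mu_sigma = mu, sigma_sigma = sqrt(mean((s - mu)^2)))
}

#' @export
print.mc_result <- function(x, ...) {
  s <- mc_summary(x)
  cat(sprintf(
    "<mc_result: %d values in [%.3g, %.3g] s, mu_sigma = %.3g s, sigma_sigma = %.3g s%s>\n",
    length(x$true_values), min(x$true_values), max(x$true_values),
    s[1], s[2],
    if (x$n_dropped > 0) sprintf(", %d replicates dropped", x$n_dropped)
    else ""))
  invisible(x)
}
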