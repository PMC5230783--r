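# Small replicate counts keep these checks fast; the calibrated comparison
# against the closed-form regression variance runs at N = 2000 in the
# acceptance suite.

test_that("near-infinite SNR recovers the true values with vanishing spread", {
  p <- me_mp2rage_protocol()
  cfg <- mc_config("t1_rho_lookup", p, snr = 1e9, n_reps = 10L,
                   n_values = 5L, value_range = c(0.8, 2.5), seed = 1L)
  res <- run_t1_mc(cfg)
  expect_lt(max(abs(res$mean_est - res$true_values)), 2e-3)
  expect_lt(max(res$sigma_T), 2e-3)

  cfgT2 <- mc_config("t2star_loglinear", me_flash_protocol(), snr = 1e9,
                     n_reps = 10L, n_values = 5L, seed = 1L)
  resT2 <- run_t2star_mc(cfgT2)
  expect_lt(rel_err(resT2$mean_est, resT2$true_values), 1e-5)
})

test_that("a fixed seed makes results bitwise reproducible", {
  cfg <- mc_config("t2star_loglinear", me_flash_protocol(), snr = 50,
                   n_reps = 200L, n_values = 4L, seed = 99L)
  a <- run_t2star_mc(cfg)
  b <- run_t2star_mc(cfg)
  expect_identical(a, b)
  cfg1 <- mc_config("t1_magnitude_fit", mp2rage_protocol(), snr = 50,
                    n_reps = 100L, n_values = 3L, seed = 7L)
  expect_identical(run_t1_mc(cfg1), run_t1_mc(cfg1))
})

test_that("precision summaries use the population spread of sigma_T", {
  r <- memp2rage:::mc_result(c(1, 2), c(1, 2), c(0.5, 0.5))
  expect_equal(unname(mc_summary(r)), c(0.5, 0))
  r2 <- memp2rage:::mc_result(c(1, 2), c(1, 2), c(0, 2))
  expect_equal(unname(mc_summary(r2)), c(1, 1))
  # matches an independent recomputation
  set.seed(5)
  s <- runif(11)
  r3 <- memp2rage:::mc_result(seq_len(11), seq_len(11), s)
  expect_equal(unname(mc_summary(r3)),
               c(mean(s), sqrt(mean((s - mean(s))^2))))
})

test_that("T1 precision scales inversely with SNR in the linear regime", {
  p <- mp2rage_protocol()
  sig <- function(snr) {
    cfg <- mc_config("t1_rho_lookup", p, snr = snr, n_reps = 600L,
                     n_values = 3L, value_range = c(1.2, 2.0), seed = 11L)
    run_t1_mc(cfg)$sigma_T
  }
  s25 <- sig(25); s100 <- sig(100)
  # first-order propagation predicts a ratio of 25/100, +/-20% plus MC error
  expect_true(all(abs(s100 / s25 - 0.25) < 0.07))
})

test_that("sigma_T is non-increasing in SNR at every probed value", {
  cfgs <- lapply(c(25, 50, 100), function(snr)
    mc_config("t2star_loglinear", me_flash_protocol(), snr = snr,
              n_reps = 500L, n_values = 6L, value_range = c(10e-3, 50e-3),
              seed = 4L))
  s <- lapply(cfgs, function(c) run_t2star_mc(c)$sigma_T)
  se <- function(x) x / sqrt(2 * 500)
  expect_true(all(s[[2]] <= s[[1]] + 3 * se(s[[1]])))
  expect_true(all(s[[3]] <= s[[2]] + 3 * se(s[[2]])))
})

test_that("estimator bias at high SNR is small over the middle of the range", {
  cfg <- mc_config("t2star_loglinear", me_flash_protocol(), snr = 100,
                   n_reps = 800L, n_values = 9L, seed = 2L)
  res <- run_t2star_mc(cfg)
  mid <- res$true_values >= 16e-3 & res$true_values <= 45e-3
  expect_lt(max(abs(res$mean_est[mid] - res$true_values[mid]) /
                  res$true_values[mid]), 0.02)
})

test_that("echo trains reaching beyond T2* estimate long T2* more precisely", {
  # TE,1 < T2* < TE,max rule: at T2* = 50 ms the train ending at 14.77 ms
  # is worse than the one ending at 27 ms
  short_train <- protocol("me_flash", alpha_1 = 11, T_R_gre = 31e-3,
                          n_echoes = 4L, T_E_first = 2.35e-3,
                          delta_T_E = 4.14e-3)
  long_train <- me_flash_protocol()
  sig <- function(p) {
    cfg <- mc_config("t2star_loglinear", p, snr = 50, n_reps = 2000L,
                     n_values = 1L, value_range = c(49.9e-3, 50e-3),
                     seed = 3L)
    run_t2star_mc(cfg)$sigma_T[1]
  }
  expect_gt(sig(short_train), sig(long_train))
})

test_that("estimator/protocol mismatches are rejected", {
  expect_error(mc_config("t1_rho_lookup", me_flash_protocol()),
               "MP2RAGE")
  cfg <- mc_config("t1_magnitude_fit", mp2rage_protocol())
  expect_error(run_t2star_mc(cfg), "t2star_loglinear")
})
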