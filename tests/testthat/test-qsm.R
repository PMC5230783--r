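kg32 <- kgrid(c(32, 32, 32), 1)

test_that("dipole kernel takes its closed-form values", {
  kg <- kgrid(c(8, 8, 8), 1)
  D <- dipole_kernel(kg)
  expect_equal(D[1, 1, 1], 0)            # zero frequency, by convention
  expect_equal(D[1, 1, 2], -2 / 3)       # k along z
  expect_equal(D[2, 1, 1], 1 / 3)        # k transverse
  expect_equal(D[3, 2, 1], 1 / 3)
  expect_true(all(D >= -2 / 3 - 1e-12 & D <= 1 / 3 + 1e-12))
  # magic angle: kz^2/|k|^2 = 1/3
  kz <- 1; kt <- sqrt(2)   # (kt, 0, kz) has kz^2/k^2 = 1/3
  expect_equal(1 / 3 - kz^2 / (kt^2 + kz^2), 0)
})

test_that("anisotropic voxels enter the kernel through physical frequencies", {
  kg <- kgrid(c(16, 16, 16), c(1, 1, 2))
  D <- dipole_kernel(kg)
  # one step along z now means half the physical frequency
  f <- 1 / (16 * 2)
  g <- 1 / 16
  expect_equal(D[2, 1, 2], 1 / 3 - f^2 / (g^2 + f^2))
})

test_that("uniform susceptibility induces no field", {
  chi <- array(42, dim = c(16, 16, 16))
  f <- forward_field(chi, kgrid(c(16, 16, 16), 1))
  expect_lt(max(abs(f)), 1e-10)
})

test_that("an impulse produces the kernel's point spread", {
  kg <- kgrid(c(16, 16, 16), 1)
  chi <- array(0, dim = kg$shape); chi[1, 1, 1] <- 1
  f <- forward_field(chi, kg)
  psf <- Re(stats::fft(dipole_kernel(kg), inverse = TRUE)) / prod(kg$shape)
  expect_equal(f, psf, tolerance = 1e-12)
})

test_that("a susceptible sphere reproduces the analytic dipole field", {
  shape <- c(48, 48, 48)
  kg <- kgrid(shape, 1)
  co <- (shape + 1) / 2
  a <- 6; chi0 <- 100
  chi <- array(0, dim = shape)
  x <- slice.index(chi, 1) - co[1]
  y <- slice.index(chi, 2) - co[2]
  z <- slice.index(chi, 3) - co[3]
  r2 <- x^2 + y^2 + z^2
  chi[r2 <= a^2] <- chi0
  f <- forward_field(chi, kg)
  ana <- sphere_field_analytic(shape, c(1, 1, 1), co, a, chi0)
  outside <- r2 > (a + 2)^2 & r2 < (min(shape) / 2 - 4)^2
  err <- sqrt(mean((f[outside] - ana[outside])^2)) /
    sqrt(mean(ana[outside]^2))
  expect_lt(err, 0.05)
})

test_that("constant phase unwraps to a constant", {
  ph <- array(1.2, dim = kg32$shape)
  u <- laplacian_unwrap(ph, kg32)
  expect_lt(max(abs(u - mean(u))), 1e-8)
})

test_that("a wrapped linear ramp is recovered up to harmonics", {
  shape <- c(64, 16, 16)
  kg <- kgrid(shape, 1)
  # smooth periodic ramp 0 -> 6*pi -> 0 (periodic so the spectral Poisson
  # solve is consistent), wrapped into (-pi, pi]
  x <- seq(0, 2 * pi, length.out = shape[1] + 1)[seq_len(shape[1])]
  truth1d <- 3 * pi * (1 - cos(x)) / 2 * 2 - 3 * pi   # 0..6pi-ish, periodic
  truth <- array(rep(truth1d, times = prod(shape[2:3])), dim = shape)
  wrapped <- memp2rage:::wrap_phase(truth)
  u <- laplacian_unwrap(wrapped, kg)
  u <- u - mean(u) + mean(truth)
  expect_lt(sqrt(mean((u - truth)^2)) / sqrt(mean((truth - mean(truth))^2)),
            0.01)
  # 1-D oracle along the varying axis agrees
  oracle <- itoh_unwrap_1d(wrapped[, 1, 1])
  oracle <- oracle - mean(oracle) + mean(truth1d)
  expect_lt(max(abs(oracle - truth1d)), 1e-9)
  expect_lt(sqrt(mean((u[, 1, 1] - oracle)^2)) /
              sqrt(mean((truth1d - mean(truth1d))^2)), 0.01)
})

test_that("a smooth 4-pi phase blob is recovered after wrapping", {
  shape <- c(48, 48, 48)
  kg <- kgrid(shape, 1)
  co <- (shape + 1) / 2
  x <- slice.index(array(0, shape), 1) - co[1]
  y <- slice.index(array(0, shape), 2) - co[2]
  z <- slice.index(array(0, shape), 3) - co[3]
  truth <- 4 * pi * exp(-(x^2 + y^2 + z^2) / (2 * 6^2))
  u <- laplacian_unwrap(memp2rage:::wrap_phase(truth), kg)
  u <- u - mean(u) + mean(truth)
  expect_lt(sqrt(mean((u - truth)^2)) / sqrt(mean(truth^2)), 0.01)
})

test_that("SHARP removes harmonic fields and keeps internal sources", {
  shape <- c(48, 48, 48)
  kg <- kgrid(shape, 1)
  co <- (shape + 1) / 2
  x <- slice.index(array(0, shape), 1) - co[1]
  y <- slice.index(array(0, shape), 2) - co[2]
  z <- slice.index(array(0, shape), 3) - co[3]
  r2 <- x^2 + y^2 + z^2
  mask <- r2 <= 16^2
  # external point dipole: analytic field of a small sphere far outside
  ext <- sphere_field_analytic(shape, c(1, 1, 1), co + c(0, 0, 21), 2, 5000)
  sh <- sharp_filter(ext, mask, kg, radius = 4, threshold = 0.05)
  expect_true(any(sh$mask))
  expect_lt(sqrt(mean(sh$field[sh$mask]^2)) / sqrt(mean(ext[mask]^2)), 0.05)
  # constants are harmonic: removed to numerical precision
  cst <- array(3.3, dim = shape)
  shc <- sharp_filter(cst, mask, kg, radius = 4, threshold = 0.05)
  expect_lt(max(abs(shc$field)), 1e-6)
  # zero in, zero out
  sh0 <- sharp_filter(array(0, dim = shape), mask, kg)
  expect_equal(max(abs(sh0$field)), 0)
  # eroded mask is strictly inside the original
  expect_true(all(mask[sh$mask]))
  expect_lt(sum(sh$mask), sum(mask))
})

test_that("phase converts to ppb by the reciprocal of gamma TE B0", {
  fc <- field_constants(TE_qsm = 14.77e-3, B0 = 7, gamma = 2.675e8)
  expect_equal(phase_to_ppb(array(0, c(2, 2, 2)), fc),
               array(0, c(2, 2, 2)))
  one_ppb_phase <- 1e-9 * 2.675e8 * 14.77e-3 * 7
  expect_equal(one_ppb_phase, 0.0276568, tolerance = 1e-5)
  x <- array(one_ppb_phase, c(2, 2, 2))
  expect_equal(phase_to_ppb(x, fc), array(1, c(2, 2, 2)), tolerance = 1e-12)
  expect_equal(phase_to_ppb(2 * x, fc), 2 * phase_to_ppb(x, fc))
})

test_that("thresholded dipole inversion round-trips smooth susceptibility", {
  shape <- c(64, 64, 64)
  kg <- kgrid(shape, 1)
  co <- (shape + 1) / 2
  x <- slice.index(array(0, shape), 1) - co[1]
  y <- slice.index(array(0, shape), 2) - co[2]
  z <- slice.index(array(0, shape), 3) - co[3]
  mask <- (x^2 + y^2 + z^2) <= 27^2
  blob <- function(cx, cy, cz, s, amp)
    amp * exp(-((x - cx)^2 + (y - cy)^2 + (z - cz)^2) / (2 * s^2))
  chi <- blob(5, 0, -4, 5, 60) + blob(-8, 6, 5, 4, -40) + blob(0, -8, 0, 4, 30)
  f <- forward_field(chi, kg)
  rec <- sdi_invert(f, mask, kg, kthresh = 0.2)
  ref <- chi - mean(chi[mask])
  fit <- stats::lm(rec[mask] ~ ref[mask])
  expect_gt(stats::cor(rec[mask], ref[mask])^2, 0.9)
  expect_gt(unname(stats::coef(fit)[2]), 0.75)
  expect_lt(unname(stats::coef(fit)[2]), 1.05)
  # reference invariance and the zero-mean convention
  rec2 <- sdi_invert(forward_field(chi + 11, kg), mask, kg, kthresh = 0.2)
  expect_equal(rec2, rec, tolerance = 1e-9)
  expect_lt(abs(mean(rec[mask])), 1e-10)
  expect_equal(sdi_invert(array(0, shape), mask, kg),
               array(0, shape))
  expect_error(sdi_invert(f, mask, kg, kthresh = 0), "positive")
})

test_that("the mask-free spectral chain is exactly linear", {
  shape <- c(16, 16, 16)
  kg <- kgrid(shape, 1)
  set.seed(3)
  x <- array(rnorm(prod(shape)), dim = shape)
  lin <- function(v) forward_field(v, kg)
  expect_equal(lin(3.7 * x), 3.7 * lin(x), tolerance = 1e-10)
  m <- array(TRUE, dim = shape)
  expect_equal(sdi_invert(3.7 * x, m, kg), 3.7 * sdi_invert(x, m, kg),
               tolerance = 1e-9)
})
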