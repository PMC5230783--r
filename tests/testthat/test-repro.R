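test_that("difference statistics reproduce their closed forms", {
  x <- array(c(1, 2, 3, 4), dim = c(4, 1, 1))
  # identical maps
  st <- diff_stats(x, x)
  expect_equal(st$mu_D, 0); expect_equal(st$sigma_D, 0)
  expect_equal(st$mu_absD, 0); expect_equal(st$sigma_absD, 0)
  expect_equal(st$r2, 1)
  expect_equal(st$n_voxels, 4L)
  # constant offset
  st2 <- diff_stats(x, x + 10)
  expect_equal(st2$mu_D, 10); expect_equal(st2$sigma_D, 0)
  expect_equal(st2$mu_absD, 10); expect_equal(st2$r2, 1)
  # the centring question: x = (0, 0), y = (1, -1)
  a <- array(c(0, 0), dim = c(2, 1, 1))
  b <- array(c(1, -1), dim = c(2, 1, 1))
  st3 <- diff_stats(a, b)
  expect_equal(st3$mu_D, 0)
  expect_equal(st3$sigma_D, 1)
  expect_equal(st3$mu_absD, 1)
  expect_equal(st3$sigma_absD, 1)            # |D| centred on mu_D
  expect_equal(st3$sigma_absD_centered, 0)   # |D| centred on mu_|D|
  expect_true(is.na(st3$r2))                 # x has zero variance: flagged
})

test_that("mu_D is antisymmetric and sigma_D, mu_|D|, r2 symmetric under swap", {
  set.seed(1)
  x <- array(rnorm(200), dim = c(10, 5, 4))
  y <- x + array(rnorm(200, 0.3, 0.2), dim = dim(x))
  ab <- diff_stats(x, y); ba <- diff_stats(y, x)
  expect_equal(ab$mu_D, -ba$mu_D)
  expect_equal(ab$sigma_D, ba$sigma_D)
  expect_equal(ab$mu_absD, ba$mu_absD)
  expect_equal(ab$r2, ba$r2)
})

test_that("r2 is invariant under affine rescaling of either map", {
  set.seed(2)
  x <- array(rnorm(500), dim = c(10, 10, 5))
  y <- 0.8 * x + array(rnorm(500, 0, 0.5), dim = dim(x))
  base <- diff_stats(x, y)$r2
  expect_equal(diff_stats(x, 3.2 * y - 7)$r2, base, tolerance = 1e-12)
  expect_equal(diff_stats(-0.5 * x + 2, y)$r2, base, tolerance = 1e-12)
})

test_that("estimated r2 converges to the squared true correlation", {
  set.seed(3)
  n <- 1e5
  rho_true <- 0.8
  u <- rnorm(n)
  x <- array(u, dim = c(100, 100, 10))
  y <- array(rho_true * u + sqrt(1 - rho_true^2) * rnorm(n), dim = dim(x))
  expect_equal(diff_stats(x, y)$r2, rho_true^2, tolerance = 0.01)
})

test_that("2-D histograms conserve mass and concentrate on the diagonal for equal maps", {
  set.seed(4)
  x <- array(runif(1000), dim = c(10, 10, 10))
  h <- hist2d(x, x, bins = 32, range = list(x = c(0, 1), y = c(0, 1)))
  expect_equal(sum(h$counts), 1000)
  expect_equal(h$n_in_range, 1000)
  expect_equal(sum(diag(h$counts)), 1000)
  # uncorrelated maps spread off the diagonal
  y <- array(runif(1000), dim = dim(x))
  h2 <- hist2d(x, y, bins = 32, range = list(x = c(0, 1), y = c(0, 1)))
  expect_lt(sum(diag(h2$counts)), 150)
  expect_equal(sum(h2$counts), 1000)
  expect_lt(diff_stats(x, y)$r2, 0.05)
})

test_that("rigid transforms behave at the identity and at integer shifts", {
  set.seed(5)
  a <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  id <- apply_rigid(a, 0, 0)
  expect_equal(id, a, ignore_attr = TRUE)
  expect_true(all(attr(id, "valid")))
  sh <- apply_rigid(a, 0, 1, interp = "nearest")
  expect_equal(sh[, , 2:8], a[, , 1:7])
  expect_true(all(is.na(sh[, , 1])))
  # trilinear at integer offset equals the exact shift too
  sh2 <- apply_rigid(a, 0, 1, interp = "trilinear")
  expect_equal(sh2[, , 2:8], a[, , 1:7], tolerance = 1e-12)
})

test_that("sub-voxel mis-registration degrades correlation monotonically", {
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 32)))
  m <- ph$truth$T2star
  m[is.na(m)] <- 0
  tr <- data.frame(rotation_deg = 0, translation_px = c(0, 0.25, 0.5, 1.0))
  sw <- misregistration_sweep(m, tr, mask = ph$mask)
  expect_equal(sw$r2[1], 1)
  expect_equal(sw$mu_D[1], 0)
  expect_true(all(diff(sw$r2) <= 1e-9))
})

test_that("textured maps lose more correlation than smooth maps for the same offset", {
  set.seed(6)
  shape <- c(32, 32, 32)
  base <- array(rnorm(prod(shape)), dim = shape)
  smooth <- fft_smooth(base, 3)               # T1-like: large-scale structure
  textured <- smooth + 0.5 * sd(smooth) *
    array(rnorm(prod(shape)), dim = shape)    # T2*-like: fine texture
  r2_of <- function(m) {
    tr <- apply_rigid(m, 0, 0.5)
    diff_stats(m, tr, mask = attr(tr, "valid"))$r2
  }
  expect_lt(r2_of(textured), r2_of(smooth))
})

test_that("ROI summaries are exact on toy volumes and the noiseless phantom", {
  lab <- array(1L, dim = c(4, 2, 2))
  lab[3:4, , ] <- 2L
  attr(lab, "levels") <- c("a", "b")
  m <- array(0, dim = dim(lab))
  m[lab == 1L] <- 2
  m[lab == 2L] <- c(1, 3)                     # mean 2, sd 1 (population)
  rs <- roi_stats(m, lab)
  expect_equal(rs$mean[rs$label == "a"], 2)
  expect_equal(rs$sd[rs$label == "a"], 0)
  expect_equal(rs$mean[rs$label == "b"], 2)
  expect_equal(rs$sd[rs$label == "b"], 1)
  expect_warning(roi_stats(m, lab, which_labels = c("a", "zz")), "absent")

  ph <- make_phantom(phantom_spec(shape = c(32, 32, 32)))
  t1map <- ph$truth$T1; t1map[is.na(t1map)] <- NA
  rph <- roi_stats(t1map, ph$labels, which_labels = "wm")
  expect_equal(rph$mean, 1.219)
  expect_equal(rph$sd, 0)
})

test_that("QSM noise sweep keeps near-zero bias while correlation decays", {
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 32)))
  acq <- simulate_acquisition(ph, me_mp2rage_protocol(), noise_sd = 0)
  # rescale the complex data so the magnitude peak is ~1000 arbitrary units
  k <- 1000 / max(Mod(acq$inv2))
  acq$inv1 <- acq$inv1 * k
  acq$inv2 <- acq$inv2 * k
  sw <- noise_sweep(acq, noise_sds = c(0, 10, 30), radius = 3, seed = 2L)
  expect_equal(sw$r2[1], 1)
  expect_equal(sw$mu_D[1], 0)
  expect_true(all(diff(sw$r2) <= 0.01))
  expect_lt(sw$r2[3], sw$r2[1])
  expect_true(all(abs(sw$mu_D) <= 2))
})
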