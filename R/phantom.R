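#' Default tissue table of the digital brain phantom
#'
#' Per-class ground truth used by [make_phantom()]. T1, T2* and
#' susceptibility of the brain classes follow published 7 T ROI values
#' (white matter, frontal-lobe cortical gray matter, putamen, caudate,
#' thalamus); the caudate stands out with a strongly paramagnetic
#' susceptibility (26.3 ppb vs 7.0 ppb in WM). CSF is not covered by those
#' ROI tables: its long T1 (4.3 s) is chosen deliberately to exercise the
#' out-of-range clamping of short-window T1 lookups, and its T2* and the
#' per-class proton densities (M0) are field-typical synthetic values.
#' The per-class `sd_*` columns carry the published group SDs (used only
#' when jittering is requested).
#'
#' @return A data.frame with one row per tissue class.
#' @export
default_tissue_table <- function() {
  data.frame(
    label = c("background", "wm", "gm", "csf", "putamen", "caudate",
              "thalamus"),
    M0 = c(0, 0.75, 0.85, 1.0, 0.85, 0.85, 0.85),
    T1 = c(NA, 1.219, 1.802, 4.3, 1.659, 1.441, 1.696),
    T2star = c(NA, 25.85e-3, 33.1e-3, 100e-3, 33.2e-3, 27.4e-3, 30.7e-3),
    chi = c(0, 7.0, -0.3, 0, -0.4, 26.3, -1.5),
    sd_T1 = c(0, 0.030, 0.051, 0, 0.036, 0.034, 0.044),
    sd_T2star = c(0, 0.80e-3, 1.7e-3, 0, 1.9e-3, 1.1e-3, 1.9e-3),
    sd_chi = c(0, 2.3, 1.0, 0, 1.4, 3.4, 1.6)
  )
}

#' Specification of the synthetic brain phantom
#'
#' @param shape voxels per axis (default 64^3, small enough that every
#'   pipeline stage runs in seconds on one CPU; configurable up to
#'   scanner-matrix sizes).
#' @param voxel_size mm per axis (0.6 mm isotropic default, the
#'   high-resolution protocol's voxel).
#' @param tissue_table per-class parameters, see [default_tissue_table()].
#' @param b1_amplitude peak deviation of a smooth (Gaussian-profile)
#'   multiplicative B1+ field; 0 gives a uniform field of 1.
#' @param jitter if `TRUE`, per-class values are jittered voxelwise with
#'   the tabulated group SDs.
#' @param seed integer seed from which all phantom randomness flows.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), voxel_size = 0.6,
                         tissue_table = default_tissue_table(),
                         b1_amplitude = 0, jitter = FALSE, seed = 1L) {
  shape <- as.integer(rep_len(shape, 3L))
  stopifnot(all(shape >= 8L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  stopifnot(all(voxel_size > 0))
  structure(list(shape = shape, voxel_size = voxel_size,
                 tissue_table = tissue_table,
                 b1_amplitude = b1_amplitude, jitter = isTRUE(jitter),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# normalized coordinate grids in [-1, 1] per axis
phantom_coords <- function(shape) {
  cc <- lapply(1:3, function(i) {
    x <- seq_len(shape[i])
    2 * (x - (shape[i] + 1) / 2) / shape[i]
  })
  n <- shape
  list(
    x = array(rep(cc[[1L]], times = n[2] * n[3]), dim = n),
    y = array(rep(rep(cc[[2L]], each = n[1]), times = n[3]), dim = n),
    z = array(rep(cc[[3L]], each = n[1] * n[2]), dim = n)
  )
}

inside_ellipsoid <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

#' Build the digital brain phantom
#'
#' Deterministic nested-ellipsoid geometry: a cortical gray-matter shell
#' enclosing white matter, a central CSF (ventricle) core, and embedded
#' deep-gray nuclei (bilateral putamen, caudate, thalamus). Per-voxel truth
#' maps (M0, T1, T2*, chi) are drawn from the tissue table, optionally
#' jittered with the per-class SDs.
#'
#' @param spec a [`phantom_spec()`].
#' @return A list of class `brain_phantom`: `labels` (integer array with a
#'   `levels` attribute of class names), `truth` (list of M0/T1/T2star/chi
#'   arrays), `mask` (brain mask), `b1` (flip-angle multiplier array), and
#'   `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- phantom_coords(spec$shape)
  tab <- spec$tissue_table
  lev <- tab$label
  lab <- array(match("background", lev), dim = spec$shape)
  assign_class <- function(region, name) lab[region] <<- match(name, lev)
  assign_class(inside_ellipsoid(co, c(0, 0, 0), c(0.90, 0.86, 0.80)), "gm")
  assign_class(inside_ellipsoid(co, c(0, 0, 0), c(0.72, 0.68, 0.62)), "wm")
  for (s in c(-1, 1)) {
    assign_class(inside_ellipsoid(co, c(0.38 * s, 0.05, 0.00),
                                  c(0.10, 0.14, 0.12)), "putamen")
    assign_class(inside_ellipsoid(co, c(0.17 * s, 0.24, 0.10),
                                  c(0.08, 0.12, 0.09)), "caudate")
    assign_class(inside_ellipsoid(co, c(0.16 * s, -0.18, -0.02),
                                  c(0.10, 0.13, 0.10)), "thalamus")
  }
  assign_class(inside_ellipsoid(co, c(0, 0.03, 0.05),
                                c(0.065, 0.16, 0.10)), "csf")
  attr(lab, "levels") <- lev

  pick <- function(col) {
    v <- tab[[col]][lab]
    dim(v) <- spec$shape
    v
  }
  truth <- list(M0 = pick("M0"), T1 = pick("T1"), T2star = pick("T2star"),
                chi = pick("chi"))
  if (spec$jitter) {
    set.seed(spec$seed)
    nv <- prod(spec$shape)
    for (fld in c("T1", "T2star", "chi")) {
      sdv <- tab[[paste0("sd_", fld)]][lab]
      truth[[fld]] <- truth[[fld]] + array(stats::rnorm(nv, 0, sdv),
                                           dim = spec$shape)
    }
    truth$T1 <- pmax(truth$T1, 0.05)
    truth$T2star <- pmax(truth$T2star, 1e-3)
  }
  mask <- lab != match("background", lev)
  b1 <- array(1, dim = spec$shape)
  if (spec$b1_amplitude != 0) {
    r2 <- co$x^2 + co$y^2 + co$z^2
    b1 <- 1 + spec$b1_amplitude * exp(-r2 / 0.45)
  }
  structure(list(labels = lab, truth = truth, mask = mask, b1 = b1,
                 spec = spec),
            class = "brain_phantom")
}

#' Simulate a full two-inversion multi-echo acquisition of a phantom
#'
#' Composes the closed-form block-signal model with the forward dipole
#' field: per voxel and echo, the magnitude comes from [block_signals()]
#' (with the phantom's B1+ multiplier applied to the flip angles), the phase
#' is the susceptibility-induced field shift accrued at that echo time
#' (plus an optional smooth background field), wrapped into `(-pi, pi]`,
#' and independent complex Gaussian noise (SD `noise_sd` on the real and
#' imaginary parts) is added to every volume. All randomness flows from
#' `seed`.
#'
#' @param ph a [`make_phantom()`] result.
#' @param p an (ME-)MP2RAGE [`protocol()`].
#' @param noise_sd complex-noise SD in the units of the simulated signal
#'   (the signal scale is of order `M0 * sin(alpha)`).
#' @param fc [`field_constants()`]; defaults to 7 T with `TE_qsm` at the
#'   protocol's longest echo.
#' @param background_field optional array (ppb) added to the dipole field,
#'   emulating an external (harmonic-inside-the-brain) background; pass
#'   e.g. a low-order polynomial in the coordinates.
#' @param seed integer seed.
#' @return A list of class `synthetic_acquisition`: complex 4-D arrays
#'   `inv1`, `inv2` (x, y, z, echo), `truth`, `labels`, `mask`, `b1`,
#'   `protocol`, `kgrid`, `fc`, `te`, `noise_sd`, and `field_ppb` (the
#'   noiseless total field used for the phase).
#' @export
simulate_acquisition <- function(ph, p, noise_sd = 0, fc = NULL,
                                 background_field = NULL, seed = 1L) {
  stopifnot(inherits(ph, "brain_phantom"), inherits(p, "mri_protocol"))
  derive_gaps(p)   # fail early on infeasible protocols
  shape <- ph$spec$shape
  te <- echo_times(p)
  if (is.null(fc)) fc <- field_constants(TE_qsm = max(te))
  kg <- kgrid(shape, ph$spec$voxel_size)

  idx <- which(ph$mask)
  tp <- tissue_params(T1 = ph$truth$T1[idx], M0 = ph$truth$M0[idx],
                      T2star = ph$truth$T2star[idx])
  bs <- block_signals(p, tp, b1_scale = ph$b1[idx])

  field <- forward_field(ph$truth$chi, kg)
  if (!is.null(background_field)) field <- field + background_field
  nE <- p$n_echoes
  nv <- prod(shape)
  inv1 <- array(0i, dim = c(shape, nE))
  inv2 <- array(0i, dim = c(shape, nE))
  set.seed(seed)
  for (e in seq_len(nE)) {
    phase <- wrap_phase(1e-9 * fc$gamma * fc$B0 * te[e] * field)
    carrier <- exp(1i * phase)
    m1 <- m2 <- array(0, dim = shape)
    m1[idx] <- bs$s1[, e]
    m2[idx] <- bs$s2[, e]
    off <- (e - 1L) * nv
    inv1[off + seq_len(nv)] <- m1 * carrier +
      complex(real = stats::rnorm(nv, 0, noise_sd),
              imaginary = stats::rnorm(nv, 0, noise_sd))
    inv2[off + seq_len(nv)] <- m2 * carrier +
      complex(real = stats::rnorm(nv, 0, noise_sd),
              imaginary = stats::rnorm(nv, 0, noise_sd))
  }
  structure(list(inv1 = inv1, inv2 = inv2, truth = ph$truth,
                 labels = ph$labels, mask = ph$mask, b1 = ph$b1,
                 protocol = p, kgrid = kg, fc = fc, te = te,
                 noise_sd = noise_sd, field_ppb = field,
                 protocol_fingerprint = protocol_fingerprint(p)),
            class = "synthetic_acquisition")
}

#' Recover T1, T2* and susceptibility maps from a synthetic acquisition
#'
#' Convenience wrapper running the three estimation chains exactly as on
#' scanner data: first-echo complex uniform image -> lookup T1; magnitudes
#' of the second-inversion echoes -> log-linear T2*; phase of the longest
#' second-inversion echo -> QSM chain.
#'
#' @param acq a [`simulate_acquisition()`] result.
#' @param lut optional [`build_rho_lookup()`] table (built from the
#'   acquisition's protocol when omitted).
#' @param radius,threshold,kthresh QSM parameters.
#' @return A list with `t1` (array, s), `t1_clamped`, `t2star` (array, s),
#'   `t2star_valid`, `chi` (ppb), `qsm_mask`, and `rho`.
#' @export
recover_maps <- function(acq, lut = NULL, radius = 3, threshold = 0.02,
                         kthresh = 0.2) {
  stopifnot(inherits(acq, "synthetic_acquisition"))
  p <- acq$protocol
  if (is.null(lut)) lut <- build_rho_lookup(p)
  shape <- acq$kgrid$shape
  nv <- prod(shape)
  s1 <- array(acq$inv1[seq_len(nv)], dim = shape)        # first echo
  s2 <- array(acq$inv2[seq_len(nv)], dim = shape)
  rho <- rho_combine(s1, s2)
  attr(rho, "protocol_fingerprint") <- acq$protocol_fingerprint
  inv <- invert_rho(rho, lut)

  mags <- Mod(acq$inv2)
  t2fit <- fit_t2star_volume(mags, acq$te)

  eL <- p$n_echoes
  sL <- array(acq$inv2[(eL - 1L) * nv + seq_len(nv)], dim = shape)
  qsm <- map_qsm(Arg(sL), acq$mask, acq$kgrid, acq$fc, radius = radius,
                 threshold = threshold, kthresh = kthresh)
  list(t1 = inv$t1, t1_clamped = inv$clamped,
       t2star = t2fit$data, t2star_valid = t2fit$mask,
       chi = qsm$chi, qsm_mask = qsm$mask, rho = rho)
}
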