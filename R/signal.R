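#' Tissue parameter set
#'
#' Per-voxel (or per-class) ground-truth parameters for signal simulation.
#' All fields are recycled to a common length, so a single call can describe
#' one tissue or a whole volume.
#'
#' @param M0 equilibrium magnetization (arbitrary units), `>= 0`.
#' @param T1 longitudinal relaxation time (s), `> 0`.
#' @param T2star effective transverse relaxation time (s), `> 0`
#'   (`Inf` = no echo decay).
#' @param chi magnetic susceptibility (ppb); used by the phantom and QSM
#'   modules only, never by the relaxation signal model.
#' @param scanner_scale lumped scanner gain converting magnetization to
#'   signal units.
#' @return An object of class `tissue_params` (a list of parallel vectors).
#' @export
tissue_params <- function(T1, M0 = 1, T2star = Inf, chi = 0,
                          scanner_scale = 1) {
  n <- max(length(T1), length(M0), length(T2star), length(chi),
           length(scanner_scale))
  t <- structure(list(
    M0 = rep_len(as.numeric(M0), n),
    T1 = rep_len(as.numeric(T1), n),
    T2star = rep_len(as.numeric(T2star), n),
    chi = rep_len(as.numeric(chi), n),
    scanner_scale = rep_len(as.numeric(scanner_scale), n)
  ), class = "tissue_params")
  stopifnot(all(t$M0 >= 0), all(t$T1 > 0), all(t$T2star > 0))
  t
}

# sum_{j=0..k-1} c^j, stable at c ~ 1
geom_sum <- function(c, k) ifelse(abs(1 - c) < 1e-12, k, (1 - c^k) / (1 - c))

deg2rad <- function(x) x * pi / 180

# effective flip angles in radians, after the B1+ accuracy scale and an
# optional extra per-voxel/offset multiplier
effective_angles <- function(p, b1_scale = 1) {
  list(a1 = deg2rad(p$alpha_1 * p$flip_accuracy * b1_scale),
       a2 = deg2rad(p$alpha_2 * p$flip_accuracy * b1_scale))
}

#' Steady-state longitudinal magnetization of an (ME-)MP2RAGE period
#'
#' One sequence period is the composition, in order, of: the inversion pulse
#' (`mz -> (1 - 2 * eta) * mz`), free relaxation over `T_A`, `n_lines`
#' excitation/relaxation steps with `alpha_1`
#' (`mz -> mz * cos(a) * E1 + M0 * (1 - E1)`), relaxation over `T_B`,
#' `n_lines` steps with `alpha_2`, and relaxation over `T_C`. Each step is
#' affine in `mz`, so the period map is `mz -> a * mz + b` and the steady
#' state is its fixed point `b / (1 - a)`, reported at the instant just
#' before the inversion pulse.
#'
#' @param p an (ME-)MP2RAGE [`protocol()`].
#' @param t a [`tissue_params()`] set (vectorized over voxels/tissues).
#' @param b1_scale optional extra flip-angle multiplier (per voxel), e.g. a
#'   B1+ offset; applied on top of the protocol's `flip_accuracy`.
#' @return Numeric vector of steady-state `Mz` (same units as `M0`).
#' @export
steady_state_mz <- function(p, t, b1_scale = 1) {
  period_map_mz(p, t, b1_scale)$mz_ss
}

# affine period map coefficients and steady state (vectorized over tissues)
period_map_mz <- function(p, t, b1_scale = 1) {
  stopifnot(inherits(p, "mri_protocol"), inherits(t, "tissue_params"))
  g <- derive_gaps(p)
  an <- effective_angles(p, b1_scale)
  T1 <- t$T1; M0 <- t$M0
  E1 <- exp(-p$T_R_gre / T1)
  EA <- exp(-g[["T_A"]] / T1)
  EB <- exp(-g[["T_B"]] / T1)
  EC <- exp(-g[["T_C"]] / T1)
  c1 <- cos(an$a1) * E1
  c2 <- cos(an$a2) * E1
  n <- p$n_lines
  a <- 1; b <- 0
  compose <- function(as, bs) { b <<- as * b + bs; a <<- as * a }
  compose(1 - 2 * p$inv_efficiency, 0)            # inversion
  compose(EA, M0 * (1 - EA))                      # T_A
  compose(c1^n, M0 * (1 - E1) * geom_sum(c1, n))  # first GRE block
  compose(EB, M0 * (1 - EB))                      # T_B
  compose(c2^n, M0 * (1 - E1) * geom_sum(c2, n))  # second GRE block
  compose(EC, M0 * (1 - EC))                      # T_C
  if (any(abs(a) >= 1))
    stop("non-contractive period map (|a| >= 1); unphysical parameters")
  list(mz_ss = b / (1 - a), E1 = E1, EA = EA, EB = EB, EC = EC,
       c1 = c1, c2 = c2, angles = an)
}

#' Closed-form (ME-)MP2RAGE block signals
#'
#' Evaluates the analytic signal of both GRE blocks at every echo time.
#' Starting from the steady state, the longitudinal magnetization is
#' propagated through the inversion, the `T_A` gap, and
#' `round(center_fraction * n_lines)` line periods to the k-space centre of
#' the first block (and analogously, through the rest of the first block and
#' the `T_B` gap, to the centre of the second block) using the matrix powers
#' and geometric sums of the per-line affine map rather than explicit
#' iteration. Each echo carries the common factor
#' `scanner_scale * exp(-T_E_i / T2star) * sin(alpha)`.
#' Signals are returned real-valued; phase (from the susceptibility-induced
#' field) is added by the phantom simulator.
#'
#' @inheritParams steady_state_mz
#' @return A list of class `block_signals` with elements `s1`, `s2`
#'   (numeric matrices, tissues x echoes), `mz_ss`, and `te`.
#' @seealso [bloch_signals()] for the brute-force time-stepped equivalent,
#'   [rho_combine()] for the uniform-image combination.
#' @export
block_signals <- function(p, t, b1_scale = 1) {
  if (p$sequence_kind == "me_flash")
    stop("block_signals is defined only for (ME-)MP2RAGE protocols")
  pm <- period_map_mz(p, t, b1_scale)
  M0 <- t$M0; E1 <- pm$E1
  nb <- n_before_center(p)
  n <- p$n_lines
  mz0 <- (1 - 2 * p$inv_efficiency) * pm$mz_ss
  mzA <- pm$EA * mz0 + M0 * (1 - pm$EA)
  mz1c <- pm$c1^nb * mzA + M0 * (1 - E1) * geom_sum(pm$c1, nb)
  mz1e <- pm$c1^n * mzA + M0 * (1 - E1) * geom_sum(pm$c1, n)
  mzB <- pm$EB * mz1e + M0 * (1 - pm$EB)
  mz2c <- pm$c2^nb * mzB + M0 * (1 - E1) * geom_sum(pm$c2, nb)
  te <- echo_times(p)
  decay <- exp(-outer(1 / t$T2star, te))    # tissues x echoes
  s1 <- (t$scanner_scale * sin(pm$angles$a1) * mz1c) * decay
  s2 <- (t$scanner_scale * sin(pm$angles$a2) * mz2c) * decay
  structure(list(s1 = s1, s2 = s2, mz_ss = pm$mz_ss, te = te),
            class = "block_signals")
}

#' Brute-force time-stepped Bloch simulation of an (ME-)MP2RAGE period
#'
#' Steps the longitudinal magnetization line by line through repeated
#' sequence periods until steady state, reading the signal at the k-space
#' centre excitation of each block. This is the independent reference for
#' [block_signals()] and [steady_state_mz()]: it encodes the sequence as a
#' literal event loop with no closed-form algebra.
#'
#' @inheritParams steady_state_mz
#' @param n_periods number of periods to simulate (relaxation enforces
#'   convergence well before the default).
#' @return Same structure as [block_signals()].
#' @export
bloch_signals <- function(p, t, b1_scale = 1, n_periods = 80L) {
  if (p$sequence_kind == "me_flash")
    stop("bloch_signals is defined only for (ME-)MP2RAGE protocols")
  stopifnot(inherits(t, "tissue_params"), n_periods >= 1L)
  g <- derive_gaps(p)
  an <- effective_angles(p, b1_scale)
  M0 <- t$M0; T1 <- t$T1
  relax <- function(mz, dt) M0 + (mz - M0) * exp(-dt / T1)
  nb <- n_before_center(p)
  mz <- M0
  mz1c <- mz2c <- NA_real_
  for (per in seq_len(n_periods)) {
    mz_pre <- mz
    mz <- (1 - 2 * p$inv_efficiency) * mz
    mz <- relax(mz, g[["T_A"]])
    for (k in seq_len(p$n_lines)) {
      if (k == nb + 1L) mz1c <- mz
      mz <- relax(mz * cos(an$a1), p$T_R_gre)
    }
    mz <- relax(mz, g[["T_B"]])
    for (k in seq_len(p$n_lines)) {
      if (k == nb + 1L) mz2c <- mz
      mz <- relax(mz * cos(an$a2), p$T_R_gre)
    }
    mz <- relax(mz, g[["T_C"]])
  }
  te <- echo_times(p)
  decay <- exp(-outer(1 / t$T2star, te))
  structure(list(
    s1 = (t$scanner_scale * sin(an$a1) * mz1c) * decay,
    s2 = (t$scanner_scale * sin(an$a2) * mz2c) * decay,
    mz_ss = mz, te = te
  ), class = "block_signals")
}

#' Combine the two inversion signals into the uniform image
#'
#' The MP2RAGE "uniform" (bias-cancelled) image is
#' `rho = Re(Conj(s1) * s2) / (|s1|^2 + |s2|^2)`, bounded in
#' `[-0.5, 0.5]`. Scanner gain, `M0`, and the echo's `T2star` decay are
#' common factors of `s1` and `s2` and cancel exactly.
#'
#' @param s1,s2 signals of the first and second inversion volume (numeric or
#'   complex, any congruent shape).
#' @return `rho`, same shape as the inputs. Voxels where both signals are
#'   zero get `rho = 0`; if any occur, their positions are attached as a
#'   logical `undefined` attribute.
#' @export
rho_combine <- function(s1, s2) {
  stopifnot(length(s1) == length(s2))
  den <- Mod(s1)^2 + Mod(s2)^2
  rho <- Re(Conj(s1) * s2)
  zero <- den == 0
  rho[!zero] <- rho[!zero] / den[!zero]
  rho[zero] <- 0
  if (is.array(s1)) dim(rho) <- dim(s1)
  if (any(zero)) attr(rho, "undefined") <- zero
  rho
}

#' The rho(T1) curve of a protocol
#'
#' Evaluates the first-echo uniform-image value as a function of T1 (the
#' quantity tabulated by [build_rho_lookup()]).
#'
#' @param p an (ME-)MP2RAGE [`protocol()`].
#' @param t1 vector of T1 values (s).
#' @param b1_offset fractional flip-angle offset (e.g. `0.2` for +20% B1+).
#' @return Numeric vector of `rho` values in `[-0.5, 0.5]`.
#' @export
rho_t1_curve <- function(p, t1, b1_offset = 0) {
  bs <- block_signals(p, tissue_params(T1 = t1), b1_scale = 1 + b1_offset)
  as.numeric(rho_combine(bs$s1[, 1L], bs$s2[, 1L]))
}
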