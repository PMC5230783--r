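#' Define an acquisition protocol
#'
#' Constructs a validated `mri_protocol` object describing one acquisition:
#' an ME-MP2RAGE or MP2RAGE sequence (two gradient-echo blocks per inversion
#' pulse) or a multi-echo FLASH sequence (a plain spoiled GRE train).
#'
#' All timings are in seconds and flip angles in degrees. For the
#' (ME-)MP2RAGE kinds, `T_I_1` and `T_I_2` are the times (after the
#' inversion pulse) at which the k-space centre line of the first and the
#' second GRE block is acquired; `T_R_seq` is the time between successive
#' inversion pulses. `center_fraction` places the k-space centre within each
#' block: a fraction `f` means `round(f * n_lines)` lines are acquired before
#' the centre line (0.5 for linear symmetric encoding, 1/3 is typical for
#' 6/8 partial Fourier along the block direction).
#'
#' Nominal flip angles are scaled internally by `flip_accuracy` (the B1+
#' accuracy factor, effective/nominal) before any signal computation;
#' `inv_efficiency` is the adiabatic inversion efficiency (1 = perfect).
#' `bandwidth` (Hz/pixel) is carried as metadata only.
#'
#' @param sequence_kind one of `"me_mp2rage"`, `"mp2rage"`, `"me_flash"`.
#' @param T_R_seq sequence repetition time (s); unused for `me_flash`.
#' @param T_I_1,T_I_2 k-space-centre times of the two GRE blocks (s);
#'   unused for `me_flash`.
#' @param alpha_1,alpha_2 nominal excitation flip angles (degrees);
#'   `me_flash` uses only `alpha_1`.
#' @param T_R_gre line repetition time within a block (s); this is the TR
#'   for `me_flash`.
#' @param n_lines number of k-space lines per GRE block.
#' @param n_echoes number of gradient echoes per line.
#' @param T_E_first first echo time (s).
#' @param delta_T_E uniform echo spacing (s); may be `NA`/0 when
#'   `n_echoes == 1`.
#' @param bandwidth readout bandwidth (Hz/pixel), metadata only.
#' @param inv_efficiency inversion efficiency in `[0, 1]`.
#' @param flip_accuracy B1+ scale factor applied to the nominal angles.
#' @param center_fraction fraction of each block acquired before the
#'   k-space centre, in `(0, 1)`.
#'
#' @return An object of class `mri_protocol`.
#' @seealso [echo_times()], [derive_gaps()], [me_mp2rage_protocol()]
#' @export
protocol <- function(sequence_kind = c("me_mp2rage", "mp2rage", "me_flash"),
                     T_R_seq = NA_real_, T_I_1 = NA_real_, T_I_2 = NA_real_,
                     alpha_1, alpha_2 = NA_real_,
                     T_R_gre, n_lines = NA_integer_, n_echoes = 1L,
                     T_E_first, delta_T_E = 0,
                     bandwidth = NA_real_,
                     inv_efficiency = 1, flip_accuracy = 1,
                     center_fraction = 0.5) {
  sequence_kind <- match.arg(sequence_kind)
  if (is.na(delta_T_E)) delta_T_E <- 0
  p <- structure(list(
    sequence_kind = sequence_kind,
    T_R_seq = as.numeric(T_R_seq),
    T_I_1 = as.numeric(T_I_1), T_I_2 = as.numeric(T_I_2),
    alpha_1 = as.numeric(alpha_1), alpha_2 = as.numeric(alpha_2),
    T_R_gre = as.numeric(T_R_gre),
    n_lines = as.integer(n_lines), n_echoes = as.integer(n_echoes),
    T_E_first = as.numeric(T_E_first), delta_T_E = as.numeric(delta_T_E),
    bandwidth = as.numeric(bandwidth),
    inv_efficiency = as.numeric(inv_efficiency),
    flip_accuracy = as.numeric(flip_accuracy),
    center_fraction = as.numeric(center_fraction)
  ), class = "mri_protocol")
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  stopifnot(p$T_R_gre > 0, p$T_E_first > 0, p$n_echoes >= 1L,
            p$delta_T_E >= 0,
            p$inv_efficiency >= 0, p$inv_efficiency <= 1,
            p$flip_accuracy > 0,
            p$center_fraction > 0, p$center_fraction < 1)
  if (p$n_echoes > 1L && p$delta_T_E <= 0)
    stop("delta_T_E must be positive when n_echoes > 1")
  if (p$T_E_first + (p$n_echoes - 1L) * p$delta_T_E >= p$T_R_gre)
    stop("echo train does not fit in one line period: ",
         "T_E_first + (n_echoes - 1) * delta_T_E must be < T_R_gre")
  if (p$sequence_kind != "me_flash") {
    stopifnot(is.finite(p$T_R_seq), is.finite(p$T_I_1), is.finite(p$T_I_2),
              p$n_lines >= 0L, is.finite(p$alpha_2))
    if (!(p$T_R_seq > 0 && p$T_I_1 > 0 && p$T_I_1 < p$T_I_2 &&
          p$T_I_2 < p$T_R_seq))
      stop("invalid timing: need 0 < T_I_1 < T_I_2 < T_R_seq")
  }
  invisible(p)
}

#' Echo times of a protocol
#'
#' @param p an [`protocol()`] object.
#' @return Numeric vector of echo times (s), strictly increasing, of length
#'   `n_echoes`.
#' @export
echo_times <- function(p) {
  stopifnot(inherits(p, "mri_protocol"))
  p$T_E_first + (seq_len(p$n_echoes) - 1L) * p$delta_T_E
}

#' Inter-block gap durations of an (ME-)MP2RAGE protocol
#'
#' Derives the three idle intervals of one sequence period: `T_A` from the
#' inversion pulse to the start of the first GRE block, `T_B` between the two
#' blocks, and `T_C` from the end of the second block to the next inversion.
#' With `n_before = round(center_fraction * n_lines)` lines acquired before
#' the k-space centre, `T_A = T_I_1 - n_before * T_R_gre`,
#' `T_B = T_I_2 - T_I_1 - n_lines * T_R_gre`, and
#' `T_C = T_R_seq - T_I_2 - (n_lines - n_before) * T_R_gre`.
#'
#' @param p an (ME-)MP2RAGE [`protocol()`].
#' @return Named numeric vector `c(T_A, T_B, T_C)` (s), all non-negative.
#'   A negative gap means the requested inversion times are infeasible for
#'   the block length and raises an error naming the offending gap.
#' @export
derive_gaps <- function(p) {
  stopifnot(inherits(p, "mri_protocol"))
  if (p$sequence_kind == "me_flash")
    stop("derive_gaps is defined only for (ME-)MP2RAGE protocols")
  nb <- round(p$center_fraction * p$n_lines)
  g <- c(T_A = p$T_I_1 - nb * p$T_R_gre,
         T_B = p$T_I_2 - p$T_I_1 - p$n_lines * p$T_R_gre,
         T_C = p$T_R_seq - p$T_I_2 - (p$n_lines - nb) * p$T_R_gre)
  bad <- names(g)[g < -1e-12]
  if (length(bad))
    stop("infeasible timing: gap ", paste(bad, collapse = ", "),
         " is negative for this protocol")
  pmax(g, 0)
}

n_before_center <- function(p) round(p$center_fraction * p$n_lines)

#' Total acquisition time
#'
#' @param p an (ME-)MP2RAGE [`protocol()`].
#' @param n_outer number of outer-loop (second phase-encoding) steps.
#' @return `T_R_seq * n_outer` in seconds.
#' @export
total_time <- function(p, n_outer) {
  stopifnot(inherits(p, "mri_protocol"), n_outer >= 1)
  p$T_R_seq * n_outer
}

#' @rdname reference_protocols
#' @param flip_accuracy,center_fraction overrides passed to [protocol()].
#' @export
me_mp2rage_protocol <- function(flip_accuracy = 1, center_fraction = 1 / 3) {
  protocol("me_mp2rage", T_R_seq = 6.0, T_I_1 = 0.75, T_I_2 = 2.90,
           alpha_1 = 4, alpha_2 = 6, T_R_gre = 18.1e-3, n_lines = 114L,
           n_echoes = 4L, T_E_first = 2.35e-3, delta_T_E = 4.14e-3,
           bandwidth = 280, flip_accuracy = flip_accuracy,
           center_fraction = center_fraction)
}

#' @rdname reference_protocols
#' @export
mp2rage_protocol <- function(flip_accuracy = 1, center_fraction = 0.5) {
  protocol("mp2rage", T_R_seq = 5.0, T_I_1 = 0.80, T_I_2 = 2.40,
           alpha_1 = 4, alpha_2 = 4, T_R_gre = 5.9e-3, n_lines = 105L,
           n_echoes = 1L, T_E_first = 2.35e-3, delta_T_E = 0,
           bandwidth = 280, flip_accuracy = flip_accuracy,
           center_fraction = center_fraction)
}

#' Reference 7 T protocols
#'
#' Ready-made `mri_protocol` objects for the three 0.6 mm isotropic 7 T
#' protocols used throughout the package examples and tests: the ME-MP2RAGE
#' sequence (4 echoes), the single-echo MP2RAGE reference, and the ME-FLASH
#' reference (5 echoes). The ME-MP2RAGE block timing is only feasible with
#' the k-space centre at the partial-Fourier position, hence its default
#' `center_fraction = 1/3`.
#'
#' @return A single `mri_protocol`, or for `reference_protocols()` a named list
#'   of all three.
#' @export
me_flash_protocol <- function() {
  protocol("me_flash", alpha_1 = 11, T_R_gre = 31e-3, n_echoes = 5L,
           T_E_first = 3.0e-3, delta_T_E = 6.0e-3, bandwidth = 200)
}

#' @rdname reference_protocols
#' @export
reference_protocols <- function() {
  list(me_mp2rage = me_mp2rage_protocol(),
       mp2rage = mp2rage_protocol(),
       me_flash = me_flash_protocol())
}

#' Serialize protocols as flat YAML config files
#'
#' Protocols are written as a flat key/value mapping with fixed units
#' (seconds, degrees, Hz/pixel). Rounding of flip angles to integer degrees
#' (a scanner-console constraint) is applied only here, never internally.
#'
#' @param p an `mri_protocol`.
#' @param path file path.
#' @param round_angles round exported nominal flip angles to whole degrees.
#' @return `read_protocol` returns an `mri_protocol`; `write_protocol`
#'   returns `path` invisibly.
#' @export
write_protocol <- function(p, path, round_angles = FALSE) {
  stopifnot(inherits(p, "mri_protocol"))
  x <- unclass(p)
  if (round_angles) {
    x$alpha_1 <- round(x$alpha_1)
    if (!is.na(x$alpha_2)) x$alpha_2 <- round(x$alpha_2)
  }
  yaml::write_yaml(x[!vapply(x, function(v) all(is.na(v)), logical(1))],
                   path, precision = 15L)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(protocol, x)
}

#' Read a file holding several named protocols
#'
#' The bundled fixture `system.file("extdata", "reference_protocols.yaml",
#' package = "memp2rage")` holds the three reference protocols in this
#' format.
#'
#' @param path YAML file mapping protocol names to flat key/value configs.
#' @return Named list of `mri_protocol` objects.
#' @export
read_protocol_set <- function(path) {
  lapply(yaml::read_yaml(path), function(x) do.call(protocol, x))
}

#' @export
print.mri_protocol <- function(x, ...) {
  cat(sprintf("<mri_protocol: %s>\n", x$sequence_kind))
  if (x$sequence_kind != "me_flash")
    cat(sprintf("  T_R_seq %.3g s | T_I %.3g/%.3g s | alpha %.3g/%.3g deg | n %d\n",
                x$T_R_seq, x$T_I_1, x$T_I_2, x$alpha_1, x$alpha_2, x$n_lines))
  else
    cat(sprintf("  TR %.3g s | alpha %.3g deg\n", x$T_R_gre, x$alpha_1))
  cat(sprintf("  T_R_gre %.4g s | %d echo(es): %s ms\n", x$T_R_gre, x$n_echoes,
              paste(format(echo_times(x) * 1e3, digits = 4), collapse = ", ")))
  if (x$flip_accuracy != 1)
    cat(sprintf("  flip accuracy %.3g (effective angles %.3g/%.3g deg)\n",
                x$flip_accuracy, x$alpha_1 * x$flip_accuracy,
                x$alpha_2 * x$flip_accuracy))
  invisible(x)
}

# opaque identifier tying lookup tables to the generating protocol
protocol_fingerprint <- function(p) {
  u <- unclass(p)
  paste(names(u), vapply(u, function(v) paste(format(v, digits = 15),
                                              collapse = ","), ""),
        sep = "=", collapse = ";")
}
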