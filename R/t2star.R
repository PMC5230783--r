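#' Log-linear mono-exponential T2* fit
#'
#' Ordinary least squares of `log(magnitude)` against echo time: the slope
#' is `-1/T2star` and the intercept `log(S0)`. The fit is unweighted (the
#' plain polynomial-fit reading of multi-echo relaxometry); magnitude noise
#' is treated as Gaussian, so a small positive bias of log-domain fitting at
#' low SNR is accepted rather than corrected.
#'
#' Degenerate voxels are masked, never raised as errors: echoes with
#' non-positive magnitude are excluded voxelwise, voxels with fewer than two
#' positive echoes are invalid, and a non-negative slope (no decay) yields
#' `T2star = Inf` with the voxel marked invalid.
#'
#' @param te echo times (s), strictly increasing, length >= 2.
#' @param mag magnitudes: a vector of length `length(te)` (one voxel) or a
#'   matrix with one row per voxel and one column per echo.
#' @param weighted if `TRUE`, weight each echo by its squared magnitude
#'   (the first-order variance of `log(mag)` under additive noise);
#'   off by default.
#' @return A list with numeric vectors `S0`, `T2star` (s), and logical
#'   `valid`.
#' @export
fit_t2star <- function(te, mag, weighted = FALSE) {
  stopifnot(length(te) >= 2L, all(diff(te) > 0))
  if (is.null(dim(mag))) mag <- matrix(mag, nrow = 1L)
  stopifnot(ncol(mag) == length(te))
  nv <- nrow(mag)
  pos <- is.finite(mag) & mag > 0
  npos <- rowSums(pos)
  S0 <- rep(NA_real_, nv)
  T2s <- rep(NA_real_, nv)
  valid <- npos >= 2L

  full <- valid & npos == length(te)
  if (any(full)) {
    y <- log(mag[full, , drop = FALSE])
    if (!weighted) {
      tc <- te - mean(te)
      sxx <- sum(tc^2)
      slope <- as.numeric(y %*% tc) / sxx
      inter <- rowMeans(y) - slope * mean(te)
    } else {
      w <- mag[full, , drop = FALSE]^2
      sw <- rowSums(w)
      mt <- as.numeric(w %*% te) / sw
      my <- rowSums(w * y) / sw
      tcw <- sweep(matrix(te, nrow = sum(full), ncol = length(te),
                          byrow = TRUE), 1L, mt)
      slope <- rowSums(w * tcw * y) / rowSums(w * tcw^2)
      inter <- my - slope * mt
    }
    S0[full] <- exp(inter)
    T2s[full] <- -1 / slope
  }
  part <- which(valid & npos < length(te))
  for (i in part) {
    k <- pos[i, ]
    f <- stats::lsfit(te[k], log(mag[i, k]))$coefficients
    S0[i] <- exp(f[1L]); T2s[i] <- -1 / f[2L]
  }
  # non-negative slope (within float noise of a flat fit) means no decay
  nodecay <- valid & !is.na(T2s) & (T2s <= 0 | T2s > 1e9)
  T2s[nodecay] <- Inf
  valid <- valid & is.finite(T2s)
  list(S0 = S0, T2star = T2s, valid = valid)
}

#' Voxelwise T2* map from multi-echo magnitude volumes
#'
#' Applies [fit_t2star()] to every voxel of a stack of congruent echo
#' volumes. For ME-MP2RAGE data, use the magnitudes of the
#' second-inversion volume (acquired later on the recovery curve, hence at
#' higher signal).
#'
#' @param echo_volumes a list of 3-D arrays / [`volume_map()`]s (one per
#'   echo) or a single 4-D array with echoes on the last dimension.
#' @param te echo times (s), one per echo.
#' @param weighted see [fit_t2star()].
#' @return A [`volume_map()`] of T2* in seconds whose `mask` combines any
#'   input mask with the fit validity; invalid voxels are `NA`. The `S0`
#'   map is attached as attribute `S0`.
#' @export
fit_t2star_volume <- function(echo_volumes, te, weighted = FALSE) {
  vs <- c(1, 1, 1); msk <- NULL
  if (is.list(echo_volumes)) {
    arrs <- lapply(echo_volumes, function(v) {
      if (inherits(v, "volume_map")) v$data else v
    })
    if (inherits(echo_volumes[[1L]], "volume_map")) {
      vs <- echo_volumes[[1L]]$voxel_size
      msk <- echo_volumes[[1L]]$mask
    }
    d1 <- dim(arrs[[1L]])
    if (!all(vapply(arrs, function(a) identical(dim(a), d1), logical(1))))
      stop("echo volumes have mismatching shapes")
    x <- vapply(arrs, as.numeric, numeric(prod(d1)))
    shp <- d1
  } else {
    d <- dim(echo_volumes)
    stopifnot(length(d) == 4L)
    shp <- d[1:3]
    x <- matrix(echo_volumes, nrow = prod(shp))
  }
  if (ncol(x) != length(te))
    stop("number of echo volumes (", ncol(x),
         ") does not match length(te) (", length(te), ")")
  f <- fit_t2star(te, x, weighted = weighted)
  t2 <- f$T2star
  t2[!f$valid] <- NA_real_
  dim(t2) <- shp
  valid <- f$valid
  dim(valid) <- shp
  if (!is.null(msk)) valid <- valid & msk
  out <- volume_map(t2, voxel_size = vs, units = "s", mask = valid,
                    provenance = list("fit_t2star_volume"))
  s0 <- f$S0; dim(s0) <- shp
  attr(out, "S0") <- s0
  out
}
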