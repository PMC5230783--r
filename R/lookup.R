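#' Build the rho -> T1 lookup table for a protocol
#'
#' Tabulates the uniform-image value `rho(T1)` on a regular T1 grid and
#' identifies the largest contiguous strictly monotonic branch containing
#' the white/gray-matter anchor (1.6 s by default, the midpoint of the
#' expected WM/GM range). T1 maps can only be estimated on that branch;
#' outside it the `rho -> T1` relation is ambiguous.
#'
#' @param p an (ME-)MP2RAGE [`protocol()`]. Flip-angle accuracy
#'   (`flip_accuracy`) must already be set on the protocol if effective
#'   angles are wanted.
#' @param t1_min,t1_max grid limits (s). The defaults cover brain tissue
#'   and CSF with margin.
#' @param step grid step (s); 1 ms is much finer than any effect reported
#'   for these protocols.
#' @param anchor T1 (s) that the selected monotonic branch must contain.
#' @return An object of class `rho_lookup`: `t1_grid`, `rho_grid`,
#'   `valid_range` (c(lo, hi) in s), `branch` (grid index range),
#'   `direction` (+1/-1 sign of d rho/d T1 on the branch), and
#'   `protocol_fingerprint`.
#' @export
build_rho_lookup <- function(p, t1_min = 0.1, t1_max = 5.0, step = 1e-3,
                             anchor = 1.6) {
  stopifnot(0 < t1_min, t1_min < t1_max, step > 0)
  t1 <- seq(t1_min, t1_max, by = step)
  rho <- rho_t1_curve(p, t1)
  br <- monotonic_branch(t1, rho, anchor)
  structure(list(
    t1_grid = t1, rho_grid = rho,
    valid_range = c(t1[br$start], t1[br$end]),
    branch = c(br$start, br$end),
    direction = br$direction,
    anchor = anchor,
    protocol_fingerprint = protocol_fingerprint(p)
  ), class = "rho_lookup")
}

# largest maximal strictly-monotone run of rho containing `anchor`
monotonic_branch <- function(t1, rho, anchor) {
  s <- sign(diff(rho))
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # run k covers grid points starts[k] .. ends[k] + 1
  cover <- r$values != 0 & t1[starts] <= anchor & t1[pmin(ends + 1L,
                                                          length(t1))] >= anchor
  if (!any(cover))
    stop("no strictly monotonic branch of rho(T1) contains the anchor ",
         anchor, " s")
  k <- which(cover)[which.max(r$lengths[cover])]
  list(start = starts[k], end = ends[k] + 1L, direction = r$values[k])
}

#' @export
print.rho_lookup <- function(x, ...) {
  cat(sprintf(
    "<rho_lookup: %d points, invertible T1 range [%.3f, %.3f] s, %s>\n",
    length(x$t1_grid), x$valid_range[1], x$valid_range[2],
    if (x$direction < 0) "rho decreasing" else "rho increasing"))
  invisible(x)
}

#' Invert a rho map to a T1 map through a lookup table
#'
#' Per voxel, linear interpolation of the inverse of the tabulated monotonic
#' branch. `rho` values outside the branch's range are clamped to the
#' nearest branch endpoint and flagged: clamping (rather than dropping)
#' mirrors how out-of-range tissue such as CSF appears in protocols whose
#' invertible window ends below the CSF T1 - the voxels survive with an
#' underestimated value.
#'
#' For (ME-)MP2RAGE data the `rho` map must come from the first echo; the
#' uniform image is echo-independent in the noiseless model but the first
#' echo maximizes SNR.
#'
#' @param rho a numeric vector/array of uniform-image values, or a
#'   [`volume_map()`].
#' @param lut a [`build_rho_lookup()`] table. If `rho` carries a
#'   `protocol_fingerprint` attribute (set by the simulator), it must match
#'   the table's.
#' @return A list with `t1` (same container type as `rho`, units s) and
#'   `clamped` (logical, same shape) marking out-of-branch voxels.
#' @export
invert_rho <- function(rho, lut) {
  stopifnot(inherits(lut, "rho_lookup"))
  fp <- if (inherits(rho, "volume_map")) attr(rho$data, "protocol_fingerprint",
                                              exact = TRUE) %||%
          attr(rho, "protocol_fingerprint", exact = TRUE)
        else attr(rho, "protocol_fingerprint", exact = TRUE)
  if (!is.null(fp) && !identical(fp, lut$protocol_fingerprint))
    stop("rho map and lookup table come from different protocols")
  vals <- if (inherits(rho, "volume_map")) rho$data else rho
  stopifnot(all(is.finite(vals[!is.na(vals)])))
  idx <- lut$branch[1]:lut$branch[2]
  rb <- lut$rho_grid[idx]
  tb <- lut$t1_grid[idx]
  if (lut$direction < 0) {          # approx() needs increasing abscissae
    rb <- rev(rb); tb <- rev(tb)
  }
  lo <- rb[1L]; hi <- rb[length(rb)]
  clamped <- !is.na(vals) & (vals < lo | vals > hi)
  x <- pmin(pmax(vals, lo), hi)
  t1 <- stats::approx(x = rb, y = tb, xout = as.numeric(x),
                      ties = "ordered")$y
  if (is.array(vals)) {
    dim(t1) <- dim(vals)
    dim(clamped) <- dim(vals)
  }
  if (inherits(rho, "volume_map")) {
    out <- volume_map(t1, voxel_size = rho$voxel_size, units = "s",
                      mask = rho$mask,
                      provenance = c(rho$provenance, list("invert_rho")))
    return(list(t1 = out, clamped = clamped))
  }
  list(t1 = t1, clamped = clamped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' B1+ sensitivity curves of the T1 estimation
#'
#' Evaluates the `rho(T1)` curve for a family of fractional flip-angle
#' offsets (both excitation angles scaled by `1 + offset`), reproducing the
#' classic +/-20% / +/-40% B1+ sensitivity overlay. Offset 0 reproduces the
#' nominal curve exactly. Tight convergence of the offset curves onto the
#' nominal one over the tissue T1 range indicates B1+ insensitivity of the
#' protocol; the steady-state magnetization level is the main driver, so
#' longer `T_R_seq` (lower Mzss) protocols converge better.
#'
#' @param p an (ME-)MP2RAGE [`protocol()`].
#' @param offsets fractional offsets, each `> -1`.
#' @param t1 T1 grid (s).
#' @return A data.frame with columns `offset`, `T1`, `rho`.
#' @export
b1_sensitivity_curves <- function(p, offsets = c(-0.4, -0.2, 0, 0.2, 0.4),
                                  t1 = seq(0.5, 4.5, by = 0.01)) {
  stopifnot(all(offsets > -1))
  out <- lapply(offsets, function(off)
    data.frame(offset = off, T1 = t1, rho = rho_t1_curve(p, t1, off)))
  do.call(rbind, out)
}

#' Apparent T1 error induced by a B1+ offset
#'
#' For each true T1, computes the rho value under a flip-angle offset and
#' converts it back through the nominal lookup table: the difference to the
#' true T1 is the mapping error a B1+ deviation of that size would cause.
#'
#' @inheritParams b1_sensitivity_curves
#' @param offset single fractional flip-angle offset.
#' @param lut optional pre-built nominal lookup for `p`.
#' @return Data.frame with `T1`, `t1_est`, `error` (s).
#' @export
b1_t1_error <- function(p, offset, t1 = seq(1.2, 2.0, by = 0.01),
                        lut = NULL) {
  if (is.null(lut)) lut <- build_rho_lookup(p)
  rho_off <- rho_t1_curve(p, t1, offset)
  est <- invert_rho(rho_off, lut)$t1
  data.frame(T1 = t1, t1_est = est, error = est - t1)
}

#' Export a lookup table as a two-column CSV
#'
#' @param lut a `rho_lookup`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lookup_csv <- function(lut, path) {
  utils::write.csv(data.frame(T1 = lut$t1_grid, rho = lut$rho_grid),
                   path, row.names = FALSE)
  invisible(path)
}
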