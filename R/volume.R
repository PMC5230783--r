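#' 3-D scalar or complex volume with geometry and provenance
#'
#' The package's lightweight in-memory container: a 3-D (or 4-D,
#' echo-stacked) array plus voxel size in mm, a units tag, an optional
#' congruent validity mask, and an ordered provenance list of the
#' operations applied so far.
#'
#' @param data numeric or complex array.
#' @param voxel_size voxel edge lengths in mm (length 3).
#' @param units free-text units tag (`"s"`, `"ms"`, `"ppb"`, `"rad"`,
#'   `"a.u."`, ...). Required on written outputs.
#' @param mask optional logical array congruent with `data` (first three
#'   dimensions).
#' @param provenance ordered list of character descriptions.
#' @return An object of class `volume_map`.
#' @export
volume_map <- function(data, voxel_size = c(1, 1, 1), units = "a.u.",
                       mask = NULL, provenance = list()) {
  stopifnot(is.array(data), length(voxel_size) == 3L, all(voxel_size > 0),
            nzchar(units))
  if (!is.null(mask)) {
    stopifnot(is.logical(mask),
              identical(dim(mask), dim(data)[seq_along(dim(mask))]))
  }
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 units = units, mask = mask,
                 provenance = as.list(provenance)),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat(sprintf("<volume_map %s, %s mm, units '%s'%s>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size, digits = 3), collapse = "x"),
              x$units,
              if (is.null(x$mask)) ""
              else sprintf(", %d masked-in voxels", sum(x$mask))))
  if (length(x$provenance))
    cat("  provenance:", paste(unlist(x$provenance), collapse = " -> "), "\n")
  invisible(x)
}

#' @export
as.array.volume_map <- function(x, ...) x$data

vm_data <- function(x) if (inherits(x, "volume_map")) x$data else x
vm_mask <- function(x) if (inherits(x, "volume_map")) x$mask else NULL

#' Write a volume to a NIfTI-1 file
#'
#' Writes the data with voxel geometry honoured in the header, the units tag
#' in the header description field, and the full units/voxel-size/provenance
#' record in a small JSON sidecar (`<path>.json`), since the NIfTI-1
#' description is limited to 80 bytes. Complex volumes must be split into
#' magnitude and phase before writing (the scanner convention); writing a
#' complex array is an error.
#'
#' @param v a [`volume_map()`] with non-empty `units`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_map"), nzchar(v$units))
  if (is.complex(v$data))
    stop("complex volumes must be written as magnitude/phase pairs")
  img <- RNifti::asNifti(v$data, reference = list(
    pixdim = c(-1, v$voxel_size, rep(1, 4)),
    descrip = substr(paste0("units=", v$units), 1L, 79L)))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(units = v$units, voxel_size = v$voxel_size,
         provenance = v$provenance),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}

#' Read a volume from a NIfTI-1 file
#'
#' Reads data and voxel geometry; units and provenance are restored from
#' the JSON sidecar written by [write_volume()] when present (falling back
#' to the header description). If `phase` is given, the two files are
#' reassembled into one complex volume (`magnitude * exp(1i * phase)`).
#'
#' @param path magnitude (or plain scalar) NIfTI file.
#' @param phase optional phase NIfTI file (radians) to combine with.
#' @return A [`volume_map()`].
#' @export
read_volume <- function(path, phase = NULL) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  vs <- RNifti::pixdim(img)[seq_len(3L)]
  hdr <- RNifti::niftiHeader(img)
  units <- sub("^units=", "", hdr$descrip)
  if (!nzchar(units)) units <- "a.u."
  prov <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$units) && nzchar(meta$units)) units <- meta$units
    prov <- as.list(meta$provenance)
    # the NIfTI header stores pixdim in float32; the sidecar keeps full
    # precision
    if (!is.null(meta$voxel_size)) vs <- as.numeric(meta$voxel_size)
  }
  if (!is.null(phase)) {
    ph <- read_volume(phase)
    if (!identical(dim(ph$data), dim(data)))
      stop("magnitude and phase volumes have mismatching shapes: ",
           path, " vs ", phase)
    data <- data * exp(1i * ph$data)
    units <- "a.u."
  }
  volume_map(data, voxel_size = vs, units = units, provenance = prov)
}
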