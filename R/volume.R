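# volume_io: CT volume containers, NIfTI/DICOM reading, NIfTI writing and
# the world <-> voxel coordinate conventions every other module relies on.

#' CT volume in Hounsfield units
#'
#' A 3-D scalar grid of Hounsfield units with physical spacing and origin.
#' The array axes are ordered slice z (first), row y, column x, so that
#' `voxels[i, , ]` is one axial slice. Voxel centres carry the HU sample:
#' the centre of 0-based voxel `(i, j, k)` sits at world position
#' `origin + c(i, j, k) * spacing` (all in mm, `(z, y, x)` order).
#'
#' @param voxels numeric 3-D array of HU values, dimension order (z, y, x).
#' @param spacing numeric length-3, `(dz, dy, dx)` in mm, all positive.
#' @param origin numeric length-3, world position of voxel `(0, 0, 0)` in mm.
#' @return an object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(0, c(4, 5, 6)), spacing = c(0.5, 0.7, 0.7))
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (length(voxels) == 0L) stop("empty volume")
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  stopifnot(length(spacing) == 3L, length(origin) == 3L)
  if (any(spacing <= 0)) stop("all spacing components must be > 0")
  rng <- range(voxels, finite = TRUE)
  if (rng[1] < -1024 || rng[2] > 3071) {
    stop("HU values outside [-1024, 3071]")
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels (z, y, x), spacing %.3g/%.3g/%.3g mm, HU [%d, %d]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    round(min(x$voxels)), round(max(x$voxels))
  ))
  invisible(x)
}

#' Label volume aligned with a CT volume
#'
#' Integer labels on the same grid as a [ct_volume()]. Codes:
#' 0 background/fat, 1 parenchyma, 2 PCS lumen, 3 stone.
#'
#' @param labels integer 3-D array, dimension order (z, y, x).
#' @inheritParams ct_volume
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:3)) stop("label codes restricted to {0, 1, 2, 3}")
  spacing <- as.double(spacing)
  if (any(spacing <= 0)) stop("all spacing components must be > 0")
  structure(list(labels = labels, spacing = spacing,
                 origin = as.double(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, codes %s\n",
              d[1], d[2], d[3],
              paste(sort(unique(as.vector(x$labels))), collapse = ",")))
  invisible(x)
}

#' Read a CT volume from disk
#'
#' Reads either a NIfTI-1 file or a directory holding a single-frame DICOM
#' series. DICOM stored values are rescaled to HU with the slope/intercept
#' tags and slices are sorted by physical z ascending. Only axis-aligned
#' volumes are supported; oblique direction cosines are rejected.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom_series"`; guessed from `path` when
#'   omitted (directory implies a DICOM series).
#' @return a [ct_volume()] (or a [label_volume()] if `as_labels = TRUE`).
#' @param as_labels logical, return the integer array as a [label_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series"),
                        as_labels = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  }
  if (format == "dicom_series") {
    vol <- read_dicom_series(path)
  } else {
    vol <- read_nifti_volume(path)
  }
  if (as_labels) {
    label_volume(array(as.integer(round(vol$voxels)), dim(vol$voxels)),
                 spacing = vol$spacing, origin = vol$origin)
  } else {
    vol
  }
}

read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("bad dimensionality: expected 3-D volume")
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  scl <- sqrt(colSums(rot^2))
  dirs <- sweep(rot, 2, scl, "/")
  if (max(abs(dirs - diag(3))) > 1e-4) {
    stop("direction cosines other than identity are rejected")
  }
  # NIfTI order is (x, y, z); internal order is (z, y, x)
  arr <- aperm(unclass(img)[, , , drop = FALSE], c(3, 2, 1))
  spacing <- rev(scl)                 # (dz, dy, dx)
  origin <- rev(xf[1:3, 4])           # (z, y, x)
  ct_volume(arr, spacing = spacing, origin = origin)
}

#' Write a volume to NIfTI-1
#'
#' Writes a [ct_volume()] or [label_volume()] so that [read_volume()]
#' round-trips voxels, spacing and origin. Label volumes keep integer
#' storage.
#'
#' @param vol a [ct_volume()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param format only `"nifti"` is supported.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = "nifti") {
  stopifnot(format == "nifti")
  is_label <- inherits(vol, "label_volume")
  arr <- if (is_label) vol$labels else vol$voxels
  out <- aperm(arr, c(3, 2, 1))       # back to NIfTI (x, y, z)
  if (is_label) storage.mode(out) <- "integer"
  img <- RNifti::asNifti(out)
  aff <- diag(4)
  diag(aff)[1:3] <- rev(vol$spacing)  # (dx, dy, dz)
  aff[1:3, 4] <- rev(vol$origin)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = if (is_label) "int16" else "auto")
  invisible(path)
}

#' Convert between world (mm) and voxel coordinates
#'
#' Coordinates are `(z, y, x)` mm world positions and 0-based continuous
#' voxel indices `(i, j, k)`. Voxel `(0, 0, 0)` maps to the volume origin;
#' the transforms are exact inverses. Points outside the grid are allowed
#' (an `inside` attribute flags them).
#'
#' @param vol a [ct_volume()] or [label_volume()].
#' @param point_mm numeric length-3 `(z, y, x)` world point, mm.
#' @return continuous 0-based indices `(i, j, k)` with attribute `inside`.
#' @examples
#' vol <- ct_volume(array(0, c(8, 8, 8)))
#' world_to_voxel(vol, c(3, 4, 5))
#' @export
world_to_voxel <- function(vol, point_mm) {
  idx <- (as.double(point_mm) - vol$origin) / vol$spacing
  d <- dim(vol$voxels %||% vol$labels)
  attr(idx, "inside") <- all(idx > -0.5 & idx < d - 0.5)
  idx
}

#' @param index continuous 0-based voxel indices `(i, j, k)`.
#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(vol, index) {
  as.double(index) * vol$spacing + vol$origin
}

# dim accessor working for both carriers
vol_dim <- function(vol) dim(vol$voxels %||% vol$labels)
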