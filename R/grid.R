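#' Image grid: shape, affine, and voxel size
#'
#' An `image_grid` ties a 3D array shape to a 4x4 voxel-to-mm affine
#' (NIfTI convention: the affine maps 0-based voxel indices to mm
#' coordinates, typically MNI space). All images entering one analysis
#' must share a grid; see [same_grid()].
#'
#' @param shape integer vector of length 3, voxels per axis (all > 0).
#' @param affine numeric 4x4 voxel-to-mm transform; must be invertible.
#' @return An object of class `image_grid` with fields `shape`, `affine`
#'   and `voxel_size` (mm per axis, derived from the affine columns).
#' @export
image_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  d <- det(affine)
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("'affine' is not invertible")
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(voxel_size <= 0))
    stop("voxel sizes derived from the affine must be positive")
  structure(list(shape = shape, affine = affine, voxel_size = voxel_size),
            class = "image_grid")
}

#' Default centered grid
#'
#' Builds an axis-aligned grid with isotropic voxels whose mm origin is at
#' the array center (so coordinate (0,0,0) mm falls mid-volume), the
#' convention used by the synthetic cohort.
#'
#' @param shape 3 positive integers.
#' @param voxel_mm isotropic voxel edge length in mm.
#' @return An `image_grid`.
#' @export
centered_grid <- function(shape, voxel_mm) {
  shape <- as.integer(shape)
  off <- -(shape - 1) / 2 * voxel_mm
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- off
  image_grid(shape, affine)
}

#' Test whether two grids are compatible
#'
#' Grids match when shapes are identical and affines agree within `tol`
#' mm elementwise. The relation is symmetric and transitive up to the
#' stated tolerance.
#'
#' @param g1,g2 `image_grid` objects.
#' @param tol absolute tolerance on affine entries, in mm.
#' @export
same_grid <- function(g1, g2, tol = 1e-4) {
  identical(g1$shape, g2$shape) &&
    max(abs(g1$affine - g2$affine)) <= tol
}

stop_unless_same_grid <- function(g1, g2, what = "images") {
  if (!same_grid(g1, g2))
    stop("grid mismatch: ", what, " do not share shape/affine")
  invisible(TRUE)
}

#' Convert 1-based voxel indices to mm coordinates
#'
#' @param grid an `image_grid`.
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based array indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk - 1, 1)   # affine acts on 0-based indices
  out <- h %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

#' @export
print.image_grid <- function(x, ...) {
  cat("image_grid:", paste(x$shape, collapse = " x "),
      "voxels,", paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' 3D scalar map on an image grid
#'
#' @param grid an `image_grid`.
#' @param data 3D numeric array matching `grid$shape`.
#' @param kind one of `"int_seconds"`, `"int_z"`, `"gmv"`, `"tstat"`,
#'   `"other"`. Raw timescale maps (`int_seconds`) must be non-negative
#'   wherever finite.
#' @param units free-text unit label; defaulted from `kind`.
#' @return A `voxel_map`.
#' @export
voxel_map <- function(grid, data,
                      kind = c("other", "int_seconds", "int_z", "gmv", "tstat"),
                      units = NULL) {
  kind <- match.arg(kind)
  data <- as.array(data)
  if (!identical(dim(data), as.integer(grid$shape)))
    stop("data dimensions do not match grid shape")
  if (kind == "int_seconds") {
    fin <- data[is.finite(data)]
    if (length(fin) && any(fin < -1e-9))
      stop("int_seconds maps must be non-negative")
  }
  if (is.null(units))
    units <- switch(kind, int_seconds = "seconds", gmv = "volume-fraction",
                    "dimensionless")
  structure(list(grid = grid, data = data, kind = kind, units = units),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  fin <- x$data[is.finite(x$data)]
  cat("voxel_map (", x$kind, ", ", x$units, "): ",
      paste(x$grid$shape, collapse = " x "),
      "; finite voxels ", length(fin), sep = "")
  if (length(fin))
    cat(sprintf("; range [%.4g, %.4g]", min(fin), max(fin)))
  cat("\n")
  invisible(x)
}

#' Boolean brain mask on an image grid
#'
#' @param grid an `image_grid`.
#' @param data logical 3D array; at least one voxel must be TRUE.
#' @return A `brain_mask`.
#' @export
brain_mask <- function(grid, data) {
  data <- array(as.logical(data), dim = dim(as.array(data)))
  if (!identical(dim(data), as.integer(grid$shape)))
    stop("mask dimensions do not match grid shape")
  if (!any(data, na.rm = TRUE))
    stop("mask contains no in-mask voxel")
  data[is.na(data)] <- FALSE
  structure(list(grid = grid, data = data), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("brain_mask:", sum(x$data), "of", prod(x$grid$shape), "voxels\n")
  invisible(x)
}

#' 4D BOLD image
#'
#' @param grid an `image_grid` describing the spatial axes.
#' @param data 4D numeric array (x, y, z, time).
#' @param tr repetition time in seconds (> 0).
#' @return A `bold_image` with `n_volumes` time points.
#' @export
bold_image <- function(grid, data, tr) {
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    stop("BOLD data must be 4D")
  if (!identical(dim(data)[1:3], as.integer(grid$shape)))
    stop("BOLD spatial dimensions do not match grid shape")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("TR must be a positive scalar (seconds)")
  structure(list(grid = grid, data = data, tr = tr,
                 n_volumes = dim(data)[4]),
            class = "bold_image")
}

#' @export
print.bold_image <- function(x, ...) {
  cat("bold_image:", paste(x$grid$shape, collapse = " x "), "voxels x",
      x$n_volumes, "volumes, TR", x$tr, "s\n")
  invisible(x)
}

#' Integer-labelled atlas
#'
#' @param grid an `image_grid`.
#' @param data non-negative integer 3D array; 0 is background.
#' @param names data.frame with columns `label` and `name` covering every
#'   nonzero label present in `data`.
#' @return An `atlas_labels` object.
#' @export
atlas_labels <- function(grid, data, names) {
  data <- array(as.integer(data), dim = dim(as.array(data)))
  if (!identical(dim(data), as.integer(grid$shape)))
    stop("atlas dimensions do not match grid shape")
  if (any(data < 0L, na.rm = TRUE))
    stop("atlas labels must be non-negative (0 = background)")
  names <- as.data.frame(names)
  if (!all(c("label", "name") %in% colnames(names)))
    stop("'names' needs columns 'label' and 'name'")
  present <- setdiff(unique(as.vector(data)), 0L)
  missing <- setdiff(present, names$label)
  if (length(missing))
    stop("unnamed atlas labels: ", paste(missing, collapse = ", "))
  structure(list(grid = grid, data = data, names = names),
            class = "atlas_labels")
}
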