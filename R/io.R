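#' Read a 3D NIfTI volume
#'
#' Loads a NIfTI-1/2 file (optionally gzipped) into a [voxel_map()],
#' taking the grid from the header (sform/qform affine). Fails loudly on
#' 4D input; use [read_bold()] for time series.
#'
#' @param path path to a 3D NIfTI file.
#' @param expected_kind map kind recorded on the result (see [voxel_map()]).
#' @return A `voxel_map`.
#' @export
read_volume <- function(path, expected_kind = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) == 4L && d[4] == 1L) {
    im <- array(im, dim = d[1:3])
    d <- d[1:3]
  } else if (length(d) != 3L) {
    stop("expected a 3D volume, got ", length(d), "D: ", path)
  }
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = c(4L, 4L))
  grid <- image_grid(d, aff)
  voxel_map(grid, array(as.numeric(im), dim = d), kind = expected_kind)
}

#' Write a 3D map (or mask) as NIfTI
#'
#' @param x a `voxel_map` or `brain_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "brain_mask")) {
    dat <- array(as.numeric(x$data), dim = x$grid$shape)
  } else if (inherits(x, "voxel_map")) {
    dat <- x$data
  } else stop("x must be a voxel_map or brain_mask")
  .write_nifti(dat, x$grid, path)
  invisible(path)
}

.write_nifti <- function(dat, grid, path, time_step = 1) {
  im <- RNifti::asNifti(dat)
  nd <- length(dim(dat))
  RNifti::pixdim(im) <- c(grid$voxel_size, if (nd == 4L) time_step)[seq_len(nd)]
  aff <- structure(grid$affine, code = 2L)
  RNifti::sform(im) <- aff
  RNifti::qform(im) <- aff
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a 4D BOLD NIfTI file
#'
#' @param path path to a 4D NIfTI file.
#' @param tr_seconds repetition time in seconds; if `NULL`, taken from the
#'   header's 4th pixdim. Must end up positive.
#' @param min_volumes minimum number of time points required to estimate
#'   an autocorrelation function downstream.
#' @return A `bold_image`.
#' @export
read_bold <- function(path, tr_seconds = NULL, min_volumes = 20L) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4L)
    stop("expected a 4D BOLD series, got ", length(d), "D: ", path)
  if (d[4] < min_volumes)
    stop("too few volumes (", d[4], ") to estimate an ACF")
  if (is.null(tr_seconds)) {
    hdr <- RNifti::niftiHeader(im)
    tr_seconds <- hdr$pixdim[5]
  }
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("TR must be positive; supply tr_seconds explicitly")
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = c(4L, 4L))
  grid <- image_grid(d[1:3], aff)
  bold_image(grid, array(as.numeric(im), dim = d), tr = tr_seconds)
}

#' Write a 4D BOLD image as NIfTI
#'
#' The repetition time is recorded in the header's 4th pixdim, so
#' [read_bold()] recovers it without an explicit argument.
#'
#' @param bold a `bold_image`.
#' @param path output path.
#' @export
write_bold <- function(bold, path) {
  .write_nifti(bold$data, bold$grid, path, time_step = bold$tr)
  invisible(path)
}

#' Read realignment (motion) parameters
#'
#' Six-column whitespace-delimited text, one row per volume: three
#' translations (mm) then three rotations (degrees).
#'
#' @param path text file path.
#' @return A `motion_params` object (see [motion_params()]).
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  motion_params(m)
}

#' Read the subject covariate/cognition table
#'
#' Delimited text with a header row. The delimiter is inferred (tab if
#' the header contains tabs, otherwise comma). Required columns:
#' `subject_id, group, age_years, education_years, steroid_months,
#' mean_fd_mm, tiv_ml`; the five WISC-IV indices (`fsiq, vci, pri, wmi,
#' psi`) and tissue volumes (`gm_ml, wm_ml, csf_ml`) are optional.
#'
#' @param path TSV/CSV file path.
#' @return A data.frame with `group` as a factor (levels control, patient).
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "age_years", "education_years",
           "steroid_months", "mean_fd_mm", "tiv_ml")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("covariate table is missing column(s): ", paste(miss, collapse = ", "))
  df$group <- factor(df$group, levels = c("control", "patient"))
  if (anyNA(df$group))
    stop("'group' must be 'patient' or 'control'")
  df
}

#' Read atlas label names
#'
#' Two-column tab-separated file: integer label, network name.
#' @param path TSV path.
#' @return data.frame with columns `label`, `name`.
#' @export
read_atlas_names <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("label", "name"),
                          stringsAsFactors = FALSE)
  df$label <- as.integer(df$label)
  df
}

#' Assign a cluster to an atlas network
#'
#' Finds the atlas label with majority voxel overlap (background voxels
#' excluded from the denominator). Ties are broken toward the smallest
#' label id and flagged. A cluster lying entirely in background is
#' labelled `"unassigned"`.
#'
#' @param cluster_mask logical 3D array on the atlas grid.
#' @param atlas an `atlas_labels` object.
#' @return list with `label`, `name`, `fraction` (of non-background
#'   cluster voxels), and `tied`.
#' @export
label_cluster_network <- function(cluster_mask, atlas) {
  cluster_mask <- as.array(cluster_mask)
  if (!identical(dim(cluster_mask), as.integer(atlas$grid$shape)))
    stop("cluster mask and atlas are on different grids")
  labs <- atlas$data[cluster_mask]
  labs <- labs[labs != 0L]
  if (!length(labs))
    return(list(label = NA_integer_, name = "unassigned",
                fraction = NA_real_, tied = FALSE))
  tab <- table(labs)
  best <- max(tab)
  winners <- sort(as.integer(names(tab)[tab == best]))
  lab <- winners[1]
  list(label = lab,
       name = atlas$names$name[match(lab, atlas$names$label)],
       fraction = as.numeric(best) / length(labs),
       tied = length(winners) > 1L)
}
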