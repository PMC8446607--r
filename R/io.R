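# NIfTI I/O. The package's internal dialect: plain axis-aligned grids, spacing
# carried in pixdim, origin in the sform translation column. Displacement
# fields are written as 4D NIfTI with the three components along the 4th
# dimension; the header description records the intent.

nifti_with_geometry <- function(arr, grid, description = "") {
  im <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(im) <- c(grid$spacing, rep(1, nd - 3))
  m <- rbind(cbind(diag(grid$spacing), grid$origin), c(0, 0, 0, 1))
  RNifti::`sform<-`(im, structure(m, code = 2L))
}

grid_from_nifti <- function(im) {
  d <- dim(im)
  sp <- RNifti::pixdim(im)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) stop("non-positive voxel spacing in header")
  xf <- try(RNifti::xform(im), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else abs(as.numeric(xf[1:3, 4])) * 0 +
    as.numeric(xf[1:3, 4])
  volume_grid(d[1:3], sp, org)
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a .nii/.nii.gz file containing a 3D image (or a 4D
#'   image together with `frame`).
#' @param frame for a 4D file, which frame (1-based) to extract.
#' @return A [cs_volume()] with grid metadata taken from the header.
#' @export
read_volume <- function(path, frame = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) == 4 && !is.null(frame)) {
    grid <- grid_from_nifti(im)
    return(cs_volume(array(im[, , , frame], dim = d[1:3]), grid))
  }
  if (length(d) != 3) stop("expected a 3D NIfTI payload, got ", length(d), "D")
  cs_volume(array(as.numeric(im), dim = d), grid_from_nifti(im))
}

#' Write a volume, mask or displacement field as NIfTI
#' @param x a `cs_volume`, `cs_mask` or `cs_field`.
#' @param path output path (.nii or .nii.gz).
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "cs_volume")) {
    im <- nifti_with_geometry(x$values, x$grid)
  } else if (inherits(x, "cs_mask")) {
    im <- nifti_with_geometry(x$labels + 0, x$grid)
  } else if (inherits(x, "cs_field")) {
    im <- nifti_with_geometry(x$u, x$grid, "displacement xyz voxel units")
  } else stop("unsupported object")
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a segmentation mask from NIfTI
#' @param path path to a 3D label image with values in 0..3.
#' @return A [seg_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  seg_mask(array(as.integer(round(v$values)), dim = v$grid$shape), v$grid)
}

#' Read a displacement field from 4D NIfTI (3 volumes on the 4th axis)
#' @param path path to the field file.
#' @return A [disp_field()] in voxel units.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4 || d[4] != 3) stop("field file must be 4D with 3 volumes")
  disp_field(array(as.numeric(im), dim = d), grid_from_nifti(im))
}

#' Read a 4D cine NIfTI into a cine sequence
#' @param path 4D NIfTI, one cardiac phase per 4th-dim index.
#' @param frame_times optional ms per frame; default uniform over `cycle_ms`.
#' @param cycle_ms cycle duration used when no times are given.
#' @return A [cine_sequence()].
#' @export
read_cine <- function(path, frame_times = NULL, cycle_ms = 1000) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4) stop("cine file must be a 4D NIfTI")
  grid <- grid_from_nifti(im)
  frames <- lapply(seq_len(d[4]), function(t)
    cs_volume(array(im[, , , t], dim = d[1:3]), grid))
  if (is.null(frame_times))
    frame_times <- (seq_len(d[4]) - 1) * (cycle_ms / d[4])
  if (length(frame_times) != d[4]) stop("frame time count mismatch")
  cine_sequence(frames, frame_times)
}

#' Load per-frame acquisition times
#'
#' Reads one time (ms) per line from a plain-text sidecar, or synthesises a
#' uniform grid from a cycle duration when no sidecar exists.
#' @param source path to a sidecar file, or `NULL`.
#' @param n_frames expected number of frames.
#' @param cycle_ms cycle duration (ms) for the uniform fallback.
#' @return Numeric vector of strictly increasing times, length `n_frames`.
#' @export
load_frame_times <- function(source = NULL, n_frames, cycle_ms = 1000) {
  if (is.null(source)) return((seq_len(n_frames) - 1) * (cycle_ms / n_frames))
  if (!file.exists(source)) stop("sidecar not found: ", source)
  txt <- readLines(source, warn = FALSE)
  tms <- as.numeric(unlist(strsplit(paste(txt, collapse = ","), "[,;[:space:]]+")))
  tms <- tms[!is.na(tms)]
  if (length(tms) != n_frames)
    stop("sidecar has ", length(tms), " times for ", n_frames, " frames")
  if (any(diff(tms) <= 0)) stop("frame times must be strictly increasing")
  tms
}

#' Write a cine sequence as 4D NIfTI (plus a frame-time sidecar)
#' @param seq a `cine_sequence`.
#' @param path output .nii/.nii.gz path; sidecar written as `<path>.times.txt`.
#' @export
write_cine <- function(seq, path) {
  d <- seq$grid$shape
  arr <- array(0, dim = c(d, length(seq$frames)))
  for (t in seq_along(seq$frames)) arr[, , , t] <- seq$frames[[t]]$values
  RNifti::writeNifti(nifti_with_geometry(arr, seq$grid), path)
  writeLines(format(seq$frame_times, trim = TRUE), paste0(path, ".times.txt"))
  invisible(path)
}
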