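#' @useDynLib cinestrain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rnorm runif sd qf quantile
#' @importFrom utils read.csv write.csv
NULL

# Arrays are indexed (x, y, z), 0-based in all voxel-coordinate arithmetic,
# with x/y in-plane and z through-plane. Displacement channels follow the same
# order. Internally tensors are reshaped to (nx*ny*nz, channels) matrices.

#' Spatial grid of a short-axis volume
#'
#' @param shape integer triple (nx, ny, nz).
#' @param spacing mm triple (in-plane x, in-plane y, slice thickness).
#' @param origin mm triple of the voxel (0,0,0) centre.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  if (shape[3] < 1L) stop("grid needs at least one slice")
  structure(list(shape = shape, spacing = spacing, origin = as.numeric(origin),
                 axes = "xyz"),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %dx%dx%d, spacing %.3gx%.3gx%.3g mm>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) && all(abs(a$spacing - b$spacing) < tol)
}

#' Default workspace grid (resampling target preceding the networks)
#'
#' All inputs are resampled onto a common 256 x 256 x 16 grid with 1.25 mm
#' in-plane resolution before centering; the slice spacing is inherited from
#' the source field of view.
#' @param nz number of slices, default 16.
#' @param slice_spacing slice thickness in mm.
#' @param shape_xy in-plane extent, default 256.
#' @return A `volume_grid`.
#' @export
workspace_grid <- function(nz = 16L, slice_spacing = 10, shape_xy = 256L) {
  volume_grid(c(shape_xy, shape_xy, nz), c(1.25, 1.25, slice_spacing))
}

#' Intensity volume on a grid
#' @param values numeric array with dim (nx, ny, nz).
#' @param grid a `volume_grid` matching `dim(values)`.
#' @return An object of class `cs_volume`.
#' @export
cs_volume <- function(values, grid) {
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("volume values must be a 3D array")
  if (!all(dim(values) == grid$shape)) stop("values do not match grid shape")
  if (any(!is.finite(values))) stop("volume contains non-finite values")
  structure(list(values = values, grid = grid), class = "cs_volume")
}

#' Four-class segmentation mask (0 background, 1 RV, 2 LVM, 3 LV cavity)
#' @param labels integer array with dim (nx, ny, nz), values in 0..3.
#' @param grid a `volume_grid`.
#' @return An object of class `cs_mask`.
#' @export
seg_mask <- function(labels, grid) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3) stop("mask labels must be a 3D array")
  if (!all(dim(labels) == grid$shape)) stop("labels do not match grid shape")
  lv <- unique(as.integer(labels))
  if (!all(lv %in% 0:3)) stop("mask labels must lie in {0,1,2,3}")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, grid = grid), class = "cs_mask")
}

#' Dense displacement field in voxel units of its grid
#'
#' Component i in voxel units; physical displacement (mm) is component times
#' the corresponding spacing entry. The identity motion is the all-zero field.
#' @param u numeric array with dim (nx, ny, nz, 3); channels are x, y, z.
#' @param grid a `volume_grid`.
#' @return An object of class `cs_field`.
#' @export
disp_field <- function(u, grid) {
  u <- as.array(u)
  if (length(dim(u)) != 4 || dim(u)[4] != 3) stop("field must be (nx,ny,nz,3)")
  if (!all(dim(u)[1:3] == grid$shape)) stop("field does not match grid shape")
  if (any(!is.finite(u))) stop("field contains non-finite values")
  structure(list(u = u, grid = grid), class = "cs_field")
}

#' Ordered cine frames on a common grid
#' @param frames list of `cs_volume`, all on one grid; frame 1 is end-diastole.
#' @param frame_times acquisition times in ms, strictly increasing.
#' @param es_index 1-based index of the end-systolic frame, or `NA`.
#' @return An object of class `cine_sequence`.
#' @export
cine_sequence <- function(frames, frame_times, es_index = NA_integer_) {
  stopifnot(length(frames) >= 1, length(frame_times) == length(frames))
  if (any(diff(frame_times) <= 0)) stop("frame times must be strictly increasing")
  g <- frames[[1]]$grid
  for (f in frames) if (!grids_equal(f$grid, g)) stop("frames must share one grid")
  structure(list(frames = frames, frame_times = as.numeric(frame_times),
                 ed_index = 1L, es_index = as.integer(es_index), grid = g),
            class = "cine_sequence")
}

#' @export
print.cine_sequence <- function(x, ...) {
  cat(sprintf("<cine_sequence: %d frames, %.0f-%.0f ms, ES frame %s>\n",
              length(x$frames), x$frame_times[1], max(x$frame_times),
              ifelse(is.na(x$es_index), "?", x$es_index)))
  invisible(x)
}

# ---- tensor reshaping helpers ------------------------------------------------

# (nx,ny,nz[,C]) array -> (N, C) matrix; layout is shared so this is cheap.
as_mat <- function(a) {
  d <- dim(a)
  if (length(d) == 3) matrix(a, nrow = prod(d), ncol = 1L)
  else matrix(a, nrow = prod(d[1:3]), ncol = d[4])
}

mat_to_arr <- function(m, shape) {
  C <- ncol(m)
  if (C == 1L) array(m, dim = shape) else array(m, dim = c(shape, C))
}

#' One-hot expansion of a segmentation mask
#' @param mask a `cs_mask` or integer label array.
#' @return (nx, ny, nz, 4) array of 0/1 channels (background, RV, LVM, cavity).
#' @export
one_hot_mask <- function(mask) {
  lab <- if (inherits(mask, "cs_mask")) mask$labels else mask
  d <- dim(lab)
  oh <- array(0, dim = c(d, 4L))
  for (k in 0:3) oh[, , , k + 1L] <- (lab == k) * 1
  oh
}

hard_labels <- function(prob) {
  # per-voxel argmax over the 4th dim; ties -> lowest class index
  m <- as_mat(prob)
  array(max.col(m, ties.method = "first") - 1L, dim = dim(prob)[1:3])
}

#' Min-max normalization of an intensity volume to [0, 1]
#' @param vol a `cs_volume` or numeric array.
#' @return Same type, values scaled to [0, 1] (all-constant input maps to 0).
#' @export
normalize_volume <- function(vol) {
  v <- if (inherits(vol, "cs_volume")) vol$values else vol
  rng <- range(v)
  out <- if (diff(rng) == 0) array(0, dim = dim(v)) else (v - rng[1]) / diff(rng)
  if (inherits(vol, "cs_volume")) cs_volume(out, vol$grid) else out
}
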