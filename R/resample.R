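# Workspace resampling and centre-cropping. Resampling aligns the physical
# centres of the source and target fields of view; intensities are
# interpolated trilinearly, labels by nearest neighbour (which can never
# invent a label absent from the input).

target_to_source_coords <- function(src_grid, tgt_grid) {
  ns <- src_grid$shape; ss <- src_grid$spacing
  nt <- tgt_grid$shape; st <- tgt_grid$spacing
  ax <- function(i) {
    idx <- seq_len(nt[i]) - 1
    (idx - (nt[i] - 1) / 2) * st[i] / ss[i] + (ns[i] - 1) / 2
  }
  cx <- ax(1); cy <- ax(2); cz <- ax(3)
  cbind(rep(cx, times = nt[2] * nt[3]),
        rep(rep(cy, each = nt[1]), times = nt[3]),
        rep(cz, each = nt[1] * nt[2]))
}

#' Resample a volume or mask onto the workspace grid
#'
#' Resamples onto a common analysis grid (by default 256 x 256 x 16 at
#' 1.25 mm in-plane) with the field of view centred on the source field of
#' view. The slice spacing of the target defaults to covering the source
#' z-extent with the target slice count.
#' @param x a `cs_volume` or `cs_mask`.
#' @param target_grid optional `volume_grid`; defaults to [workspace_grid()]
#'   with an inherited z field of view.
#' @return The resampled object on `target_grid`.
#' @export
resample_to_workspace <- function(x, target_grid = NULL) {
  grid <- x$grid
  if (any(grid$shape[1:2] < 2)) stop("degenerate input grid")
  if (is.null(target_grid)) {
    dz <- grid$spacing[3] * grid$shape[3] / 16
    target_grid <- workspace_grid(nz = 16L, slice_spacing = dz)
  }
  pts <- target_to_source_coords(grid, target_grid)
  if (inherits(x, "cs_volume")) {
    vals <- cpp_sample_points(as_mat(x$values), grid$shape, pts, 0L)
    cs_volume(array(vals, dim = target_grid$shape), target_grid)
  } else if (inherits(x, "cs_mask")) {
    vals <- cpp_sample_points(as_mat(x$labels + 0), grid$shape, pts, 1L)
    seg_mask(array(as.integer(vals), dim = target_grid$shape), target_grid)
  } else stop("resample_to_workspace expects a volume or mask")
}

#' Crop a workspace object around a centre voxel
#'
#' Produces a (size x size x nz) block in which the requested centre voxel
#' lands at in-plane index (size/2, size/2) (0-based). Out-of-window regions
#' are zero-padded (intensity) or background-padded (labels). The inverse
#' mapping is recorded in attribute `crop_info` so outputs can be placed back
#' with [paste_back()].
#' @param x a `cs_volume`, `cs_mask` or `cs_field`.
#' @param center_voxel 0-based in-plane voxel pair (x, y) (a third entry, if
#'   given, is ignored: all slices are kept).
#' @param size in-plane output extent, default 128.
#' @return Cropped object of the same class.
#' @export
crop_around_center <- function(x, center_voxel, size = 128L) {
  grid <- x$grid
  cx <- as.integer(round(center_voxel[1])); cy <- as.integer(round(center_voxel[2]))
  if (cx < 0 || cy < 0 || cx >= grid$shape[1] || cy >= grid$shape[2])
    stop("crop centre outside grid")
  half <- as.integer(size) %/% 2L
  off <- c(cx - half, cy - half)        # 0-based source index of output (0,0)
  src_x <- (off[1]):(off[1] + size - 1L)
  src_y <- (off[2]):(off[2] + size - 1L)
  ok_x <- src_x >= 0 & src_x < grid$shape[1]
  ok_y <- src_y >= 0 & src_y < grid$shape[2]
  new_grid <- volume_grid(c(size, size, grid$shape[3]), grid$spacing,
                          grid$origin + c(off * grid$spacing[1:2], 0))
  fill_block <- function(arr, pad = 0) {
    d4 <- length(dim(arr)) == 4
    outdim <- c(size, size, grid$shape[3], if (d4) dim(arr)[4])
    out <- array(pad, dim = outdim)
    if (any(ok_x) && any(ok_y)) {
      if (d4) out[which(ok_x), which(ok_y), , ] <-
          arr[src_x[ok_x] + 1L, src_y[ok_y] + 1L, , , drop = FALSE]
      else out[which(ok_x), which(ok_y), ] <-
          arr[src_x[ok_x] + 1L, src_y[ok_y] + 1L, , drop = FALSE]
    }
    out
  }
  out <- if (inherits(x, "cs_volume")) {
    cs_volume(fill_block(x$values), new_grid)
  } else if (inherits(x, "cs_mask")) {
    m <- fill_block(x$labels + 0L); storage.mode(m) <- "integer"
    seg_mask(m, new_grid)
  } else if (inherits(x, "cs_field")) {
    disp_field(fill_block(x$u), new_grid)
  } else stop("unsupported object")
  attr(out, "crop_info") <- list(offset = off, source_shape = grid$shape,
                                 source_grid = grid)
  out
}

#' Place a cropped object back into its source geometry
#' @param cropped object returned by [crop_around_center()] (or one of the
#'   same shape carrying the same `crop_info`).
#' @param background value for voxels outside the crop window (0 for
#'   intensities and labels).
#' @param crop_info optional crop record; defaults to `attr(cropped, "crop_info")`.
#' @return Object of the same class on the original workspace grid.
#' @export
paste_back <- function(cropped, background = 0, crop_info = NULL) {
  info <- if (is.null(crop_info)) attr(cropped, "crop_info") else crop_info
  if (is.null(info)) stop("no crop_info available")
  ns <- info$source_shape
  size <- cropped$grid$shape[1]
  src_x <- (info$offset[1]):(info$offset[1] + size - 1L)
  src_y <- (info$offset[2]):(info$offset[2] + size - 1L)
  ok_x <- src_x >= 0 & src_x < ns[1]
  ok_y <- src_y >= 0 & src_y < ns[2]
  restore <- function(arr) {
    d4 <- length(dim(arr)) == 4
    out <- array(background, dim = c(ns, if (d4) dim(arr)[4]))
    if (d4) out[src_x[ok_x] + 1L, src_y[ok_y] + 1L, , ] <-
        arr[which(ok_x), which(ok_y), , , drop = FALSE]
    else out[src_x[ok_x] + 1L, src_y[ok_y] + 1L, ] <-
        arr[which(ok_x), which(ok_y), , drop = FALSE]
    out
  }
  g <- info$source_grid
  if (inherits(cropped, "cs_volume")) cs_volume(restore(cropped$values), g)
  else if (inherits(cropped, "cs_mask")) {
    m <- restore(cropped$labels + 0L); storage.mode(m) <- "integer"
    seg_mask(m, g)
  } else if (inherits(cropped, "cs_field")) disp_field(restore(cropped$u), g)
  else stop("unsupported object")
}
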