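# Green-Lagrange strain engine: displacement gradients, tensor assembly,
# cylindrical projection about the LV long axis, global and AHA-segment
# averages, millisecond interpolation and strain-rate parameter extraction.

#' Gradient of the physical displacement with respect to physical coordinates
#'
#' The field is stored in voxel units; component i is scaled by spacing
#' entry i and differentiated by central differences (one-sided at borders),
#' each directional derivative divided by the spacing of its axis.
#' @param field a [disp_field()].
#' @return Array (nx, ny, nz, 3, 3); `[ , , , i, j]` is d u_i / d x_j (mm/mm).
#' @export
displacement_gradient <- function(field) {
  g <- field$grid
  if (any(g$shape[1:2] < 3)) stop("grid too small for central differences")
  d <- g$shape
  G <- array(0, dim = c(d, 3, 3))
  um <- as_mat(field$u)
  for (j in 1:3) {
    dj <- cpp_fd(um, d, j - 1L) / g$spacing[j]
    for (i in 1:3) G[, , , i, j] <- array(dj[, i] * g$spacing[i], dim = d)
  }
  G
}

#' Green-Lagrange strain tensor from a displacement gradient
#'
#' `E = (G + G^T + G^T G) / 2`, evaluated per voxel; exactly zero for rigid
#' motion (including finite rotations).
#' @param grad_u array (nx, ny, nz, 3, 3) from [displacement_gradient()].
#' @return Array of the same shape holding the symmetric tensor E.
#' @export
green_lagrange <- function(grad_u) {
  d <- dim(grad_u)[1:3]
  E <- array(0, dim = dim(grad_u))
  for (i in 1:3) for (j in i:3) {
    quad <- 0
    for (k in 1:3) quad <- quad + grad_u[, , , k, i] * grad_u[, , , k, j]
    Eij <- (grad_u[, , , i, j] + grad_u[, , , j, i] + quad) / 2
    E[, , , i, j] <- Eij
    if (j != i) E[, , , j, i] <- Eij
  }
  E
}

#' Cardiac cylindrical coordinate system from a segmentation
#'
#' Per-slice LV centre (centroid of LVM plus cavity), per-voxel in-plane
#' radial/circumferential unit vectors, and the septal direction (angle of
#' the RV centroid seen from the LV centre) used to orient polar maps.
#' @param mask a [seg_mask()] containing LVM (label 2); RV (label 1) is
#'   required only for polar-map orientation.
#' @return Object of class `cardiac_cs`.
#' @export
define_cardiac_cs <- function(mask) {
  g <- mask$grid; d <- g$shape
  lab <- mask$labels
  if (!any(lab == 2L)) stop("mask contains no LV myocardium")
  centers <- matrix(NA_real_, d[3], 2)
  septal <- rep(NA_real_, d[3])
  xs <- seq_len(d[1]) - 1; ys <- seq_len(d[2]) - 1
  X <- matrix(rep(xs, times = d[2]), d[1]); Y <- matrix(rep(ys, each = d[1]), d[1])
  rx <- array(NA_real_, d); ry <- array(NA_real_, d)
  for (z in seq_len(d[3])) {
    lv <- lab[, , z] >= 2L
    if (!any(lv)) next
    cx <- mean(X[lv]); cy <- mean(Y[lv])
    centers[z, ] <- c(cx, cy)
    dx <- (X - cx) * g$spacing[1]; dy <- (Y - cy) * g$spacing[2]
    nrm <- sqrt(dx^2 + dy^2); nrm[nrm == 0] <- NA_real_
    rx[, , z] <- dx / nrm; ry[, , z] <- dy / nrm
    rv <- lab[, , z] == 1L
    if (any(rv))
      septal[z] <- atan2((mean(Y[rv]) - cy) * g$spacing[2],
                         (mean(X[rv]) - cx) * g$spacing[1])
  }
  structure(list(grid = g, centers = centers, septal_angle = septal,
                 rx = rx, ry = ry),
            class = "cardiac_cs")
}

#' Project a strain tensor field onto cylindrical components
#'
#' Radial and circumferential strain are the diagonal entries of E in the
#' local cylindrical frame; the three shear projections are also returned.
#' @param E array (nx, ny, nz, 3, 3) of Green-Lagrange tensors.
#' @param cs a `cardiac_cs` on the same grid.
#' @return List of arrays `E_rr`, `E_cc`, `E_zz`, `E_rc`, `E_rz`, `E_cz`
#'   (NA where the coordinate system is undefined).
#' @export
cylindrical_project <- function(E, cs) {
  rx <- cs$rx; ry <- cs$ry
  cx <- -ry; cy <- rx
  E11 <- E[, , , 1, 1]; E22 <- E[, , , 2, 2]; E33 <- E[, , , 3, 3]
  E12 <- E[, , , 1, 2]; E13 <- E[, , , 1, 3]; E23 <- E[, , , 2, 3]
  list(E_rr = rx^2 * E11 + 2 * rx * ry * E12 + ry^2 * E22,
       E_cc = cx^2 * E11 + 2 * cx * cy * E12 + cy^2 * E22,
       E_zz = E33,
       E_rc = rx * cx * E11 + (rx * cy + ry * cx) * E12 + ry * cy * E22,
       E_rz = rx * E13 + ry * E23,
       E_cz = cx * E13 + cy * E23)
}

#' Interior of the myocardial wall (mask eroded by one voxel in-plane/through-plane)
#'
#' LVM voxels whose six face neighbours are all LVM; finite differences at
#' wall-boundary voxels straddle the tissue interface, so oracle comparisons
#' are made on this set.
#' @param mask a [seg_mask()].
#' @return Logical array marking interior LVM voxels.
#' @export
wall_interior <- function(mask) {
  lab <- mask$labels == 2L
  d <- dim(lab)
  out <- lab
  shift_l <- function(a, ax, by) {
    r <- array(FALSE, dim = d)
    i <- seq_len(d[ax])
    src <- i - by
    ok <- src >= 1 & src <= d[ax]
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    sidx <- idx; sidx[[ax]] <- src[ok]
    didx <- idx; didx[[ax]] <- i[ok]
    r[didx[[1]], didx[[2]], didx[[3]]] <- a[sidx[[1]], sidx[[2]], sidx[[3]]]
    r
  }
  for (ax in 1:3) for (by in c(-1, 1)) {
    if (d[ax] == 1) next
    out <- out & shift_l(lab, ax, by)
  }
  out
}

#' Global (whole-LVM) strain in percent
#' @param component array of a cylindrical strain component.
#' @param mask a [seg_mask()] (or a logical array selecting the voxels).
#' @return Mean over LVM voxels, in percent.
#' @export
global_strain <- function(component, mask) {
  sel <- if (inherits(mask, "cs_mask")) mask$labels == 2L else mask
  if (!any(sel)) stop("empty myocardium mask")
  mean(component[sel], na.rm = TRUE) * 100
}

#' Millisecond interpolation and strain rate
#'
#' Linearly interpolates per-frame strain values onto a 1 ms grid and
#' differentiates by central differences (one-sided at the ends), reported
#' per second.
#' @param values per-frame strain values (unitless).
#' @param frame_times acquisition times (ms), strictly increasing, length >= 3.
#' @return data.frame with `time_ms`, `strain` (unitless) and `sr` (1/s).
#' @export
interpolate_and_rate <- function(values, frame_times) {
  if (length(values) < 3) stop("need at least 3 frames")
  if (any(diff(frame_times) <= 0)) stop("frame times must be strictly increasing")
  tg <- seq(frame_times[1], frame_times[length(frame_times)], by = 1)
  st <- approx(frame_times, values, xout = tg)$y
  n <- length(st)
  sr <- numeric(n)
  sr[2:(n - 1)] <- (st[3:n] - st[1:(n - 2)]) / 2
  sr[1] <- st[2] - st[1]
  sr[n] <- st[n] - st[n - 1]
  data.frame(time_ms = tg, strain = st, sr = sr * 1000)
}

#' Scalar strain parameters: ESS, SRs, SRe
#'
#' End-systolic strain is the curve value at `es_time` (percent); systolic
#' and early-diastolic strain rates are the peak absolute global strain rate
#' on [0, es_time] and (es_time, end], signed by the value at the peak.
#' @param curves data.frame from [interpolate_and_rate()].
#' @param es_time end-systolic time (ms).
#' @return List with `ESS` (percent), `SRs` and `SRe` (1/s).
#' @export
extract_params <- function(curves, es_time) {
  if (es_time < min(curves$time_ms) || es_time > max(curves$time_ms))
    stop("es_time outside the curve range")
  ei <- which.min(abs(curves$time_ms - es_time))
  sys <- curves$sr[curves$time_ms <= es_time]
  dia <- curves$sr[curves$time_ms > es_time]
  srs <- if (length(sys)) sys[which.max(abs(sys))] else NA_real_
  sre <- if (length(dia)) dia[which.max(abs(dia))] else NA_real_
  list(ESS = curves$strain[ei] * 100, SRs = srs, SRe = sre)
}

#' End-systole detection from cavity volumes
#' @param masks list of [seg_mask()] over the cycle.
#' @return 1-based frame index of minimum LV-cavity volume (earliest on ties).
#' @export
detect_es <- function(masks) {
  vols <- vapply(masks, function(m) sum(m$labels == 3L), 0L)
  if (all(vols == 0L)) stop("no LV cavity labels present")
  if (length(unique(vols)) == 1L) {
    warning("cavity volume is constant; returning frame 1")
    return(1L)
  }
  which.min(vols)
}

#' AHA 16-segment polar map of a strain component
#'
#' Slices containing LVM are split along z into basal/mid/apical thirds
#' (equal counts, remainder assigned to basal then mid; slice 1 is basal).
#' Basal and mid rings use six 60-degree sectors starting at the anterior RV
#' insertion (septal angle + 90 degrees); the apical ring uses four
#' 90-degree sectors offset by 45 degrees, per the standard bullseye.
#' @param component cylindrical strain component array.
#' @param mask a [seg_mask()] with LVM and RV labels.
#' @param cs a `cardiac_cs` from [define_cardiac_cs()].
#' @return data.frame with `segment` (1-16), `ring`, `value` (percent) and
#'   `n_voxels`.
#' @export
polar_map <- function(component, mask, cs) {
  if (all(is.na(cs$septal_angle))) stop("RV labels required to orient the polar map")
  d <- mask$grid$shape
  lvm_slices <- which(vapply(seq_len(d[3]), function(z)
    any(mask$labels[, , z] == 2L), TRUE))
  ns <- length(lvm_slices)
  base_n <- ns %/% 3L + (ns %% 3L >= 1L)
  mid_n <- ns %/% 3L + (ns %% 3L >= 2L)
  ring_of <- rep(c(1L, 2L, 3L), c(base_n, mid_n, ns - base_n - mid_n))
  vals <- rep(NA_real_, 16); cnt <- integer(16)
  acc <- vector("list", 16)
  xs <- seq_len(d[1]) - 1; ys <- seq_len(d[2]) - 1
  X <- matrix(rep(xs, times = d[2]), d[1]); Y <- matrix(rep(ys, each = d[1]), d[1])
  septal <- cs$septal_angle
  septal[is.na(septal)] <- mean(septal, na.rm = TRUE)
  for (si in seq_along(lvm_slices)) {
    z <- lvm_slices[si]; ring <- ring_of[si]
    sel <- mask$labels[, , z] == 2L
    th <- atan2((Y - cs$centers[z, 2]) * mask$grid$spacing[2],
                (X - cs$centers[z, 1]) * mask$grid$spacing[1])
    insertion <- septal[z] + pi / 2
    alpha <- (th - insertion) %% (2 * pi)
    if (ring < 3L) {
      sec <- floor(alpha / (pi / 3)) + 1L         # 1..6
      seg <- sec + (ring - 1L) * 6L
    } else {
      sec <- floor(((alpha + pi / 4) %% (2 * pi)) / (pi / 2)) + 1L  # 1..4
      seg <- 12L + sec
    }
    comp_z <- component[, , z]
    for (s in unique(seg[sel])) {
      pick <- sel & seg == s
      acc[[s]] <- c(acc[[s]], comp_z[pick])
    }
  }
  for (s in 1:16) {
    v <- acc[[s]]
    cnt[s] <- length(v)
    vals[s] <- if (length(v)) mean(v, na.rm = TRUE) * 100 else NA_real_
  }
  ring_names <- c(rep("basal", 6), rep("mid", 6), rep("apical", 4))
  data.frame(segment = 1:16, ring = ring_names, value = vals, n_voxels = cnt)
}

#' Strain analysis of a displacement-field sequence
#'
#' Runs the full deterministic chain: per-frame gradients, Green-Lagrange
#' tensors, cylindrical projection, global averaging over the end-diastolic
#' LVM mask, millisecond interpolation, and scalar parameter extraction.
#' The first frame's field is taken as the zero reference.
#' @param fields list of [disp_field()] per frame (frame 1 = ED).
#' @param mask_ed end-diastolic [seg_mask()].
#' @param frame_times ms per frame.
#' @param es_index 1-based end-systolic frame; if `NA`, supply `es_time`.
#' @param es_time end-systolic time in ms (overrides `es_index`).
#' @return Object of class `strain_result`: per-component curves, scalar
#'   parameters, per-frame global values, and the ES-frame polar maps (when
#'   RV labels allow orientation).
#' @export
strain_from_fields <- function(fields, mask_ed, frame_times,
                               es_index = NA_integer_, es_time = NULL) {
  stopifnot(length(fields) == length(frame_times))
  cs <- define_cardiac_cs(mask_ed)
  lvm <- mask_ed$labels == 2L
  nT <- length(fields)
  gr <- matrix(0, nT, 2, dimnames = list(NULL, c("E_rr", "E_cc")))
  cyl_es <- NULL
  if (is.null(es_time)) {
    if (is.na(es_index)) stop("need es_index or es_time")
    es_time <- frame_times[es_index]
  } else es_index <- which.min(abs(frame_times - es_time))
  for (t in seq_len(nT)) {
    if (t == 1L) next  # strain reference: u_0 := 0
    u <- fields[[t]]
    E <- green_lagrange(displacement_gradient(u))
    cyl <- cylindrical_project(E, cs)
    gr[t, "E_rr"] <- mean(cyl$E_rr[lvm], na.rm = TRUE)
    gr[t, "E_cc"] <- mean(cyl$E_cc[lvm], na.rm = TRUE)
    if (t == es_index) cyl_es <- cyl
  }
  curves <- list(E_rr = interpolate_and_rate(gr[, "E_rr"], frame_times),
                 E_cc = interpolate_and_rate(gr[, "E_cc"], frame_times))
  params <- lapply(curves, extract_params, es_time = es_time)
  polar <- NULL
  if (!is.null(cyl_es) && !all(is.na(cs$septal_angle))) {
    polar <- list(E_rr = polar_map(cyl_es$E_rr, mask_ed, cs),
                  E_cc = polar_map(cyl_es$E_cc, mask_ed, cs))
  }
  structure(list(curves = curves, params = params, global_by_frame = gr,
                 frame_times = frame_times, es_index = es_index,
                 es_time = es_time, polar = polar, cs = cs),
            class = "strain_result")
}

#' @export
print.strain_result <- function(x, ...) {
  cat("<strain_result>\n")
  cat(sprintf("  ES at %.0f ms (frame %d)\n", x$es_time, x$es_index))
  cat(sprintf("  ESS: radial %+.1f%%, circumferential %+.1f%%\n",
              x$params$E_rr$ESS, x$params$E_cc$ESS))
  cat(sprintf("  SRs: %+.2f / %+.2f 1/s   SRe: %+.2f / %+.2f 1/s (rad/circ)\n",
              x$params$E_rr$SRs, x$params$E_cc$SRs,
              x$params$E_rr$SRe, x$params$E_cc$SRe))
  invisible(x)
}

#' Write strain curves and parameters to files
#' @param result a `strain_result`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_strain_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cv <- data.frame(time_ms = result$curves$E_rr$time_ms,
                   E_rr = result$curves$E_rr$strain,
                   E_cc = result$curves$E_cc$strain,
                   SR_rr = result$curves$E_rr$sr,
                   SR_cc = result$curves$E_cc$sr)
  p1 <- file.path(dir, "strain_curves.csv")
  write.csv(cv, p1, row.names = FALSE)
  p2 <- file.path(dir, "strain_params.json")
  jsonlite::write_json(result$params, p2, auto_unbox = TRUE, digits = NA)
  paths <- c(p1, p2)
  if (!is.null(result$polar)) {
    p3 <- file.path(dir, "polar_map_Err.csv")
    p4 <- file.path(dir, "polar_map_Ecc.csv")
    write.csv(result$polar$E_rr, p3, row.names = FALSE)
    write.csv(result$polar$E_cc, p4, row.names = FALSE)
    paths <- c(paths, p3, p4)
  }
  invisible(paths)
}

#' Write a cylindrical strain field as multi-channel NIfTI
#'
#' Channels (4th dimension) are E_rr, E_cc, E_zz, E_rc, E_rz, E_cz; voxels
#' without a defined coordinate system are written as 0.
#' @param cyl list from [cylindrical_project()].
#' @param grid the `volume_grid` of the field.
#' @param path output .nii/.nii.gz path.
#' @export
write_strain_field <- function(cyl, grid, path) {
  comps <- c("E_rr", "E_cc", "E_zz", "E_rc", "E_rz", "E_cz")
  arr <- array(0, dim = c(grid$shape, length(comps)))
  for (i in seq_along(comps)) {
    v <- cyl[[comps[i]]]
    v[is.na(v)] <- 0
    arr[, , , i] <- v
  }
  RNifti::writeNifti(nifti_with_geometry(arr, grid), path)
  invisible(path)
}
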