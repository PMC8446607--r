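# Evaluation statistics: segmentation overlap and boundary distance,
# volumetric indices, landmark end-point error, Bland-Altman agreement,
# single-rating absolute-agreement ICC and test-retest relative changes.

#' Dice similarity coefficient for one label
#' @param mask_a,mask_b [seg_mask()] objects on a shared grid.
#' @param label label to compare (default 2, the LV myocardium).
#' @return Scalar in [0, 1]; both sets empty returns 1 by convention.
#' @export
dice <- function(mask_a, mask_b, label = 2L) {
  if (!grids_equal(mask_a$grid, mask_b$grid)) stop("grid mismatch")
  a <- mask_a$labels == label; b <- mask_b$labels == label
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# voxels of a label set with at least one 6-neighbour outside the set
boundary_voxels <- function(lab, label) {
  sel <- lab == label
  d <- dim(sel)
  interior <- sel
  pad_shift <- function(a, ax, by) {
    out <- array(FALSE, dim = d)
    n <- d[ax]
    if (n == 1) return(out)
    idx <- vector("list", 3)
    for (k in 1:3) idx[[k]] <- seq_len(d[k])
    src <- idx; dst <- idx
    if (by == 1) { src[[ax]] <- 1:(n - 1); dst[[ax]] <- 2:n }
    else { src[[ax]] <- 2:n; dst[[ax]] <- 1:(n - 1) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1, 1)) interior <- interior & pad_shift(sel, ax, by)
  which(sel & !interior, arr.ind = TRUE)
}

#' Hausdorff distance between two label sets (mm)
#'
#' Exact symmetric Hausdorff distance between boundary voxel centres, using
#' the grid spacing.
#' @param mask_a,mask_b [seg_mask()] objects on a shared grid.
#' @param label label to compare.
#' @return Distance in mm.
#' @export
hausdorff <- function(mask_a, mask_b, label = 2L) {
  if (!grids_equal(mask_a$grid, mask_b$grid)) stop("grid mismatch")
  sp <- mask_a$grid$spacing
  A <- boundary_voxels(mask_a$labels, label)
  B <- boundary_voxels(mask_b$labels, label)
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty label set")
  Am <- sweep(A, 2, sp, "*"); Bm <- sweep(B, 2, sp, "*")
  d2 <- outer(rowSums(Am^2), rowSums(Bm^2), "+") - 2 * Am %*% t(Bm)
  d2[d2 < 0] <- 0
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

#' Volumetric indices from ED and ES segmentations
#'
#' Cavity volumes from voxel counts, ejection fraction, and LV mass from the
#' ED myocardial volume at a density of 1.05 g/mL.
#' @param mask_ed,mask_es [seg_mask()] at end-diastole and end-systole.
#' @return List with `EDV_ml`, `ESV_ml`, `EF_pct`, `LVM_g`.
#' @export
volumetrics <- function(mask_ed, mask_es) {
  if (!grids_equal(mask_ed$grid, mask_es$grid)) stop("grid mismatch")
  vv <- prod(mask_ed$grid$spacing) / 1000  # mm^3 -> mL
  edv <- sum(mask_ed$labels == 3L) * vv
  esv <- sum(mask_es$labels == 3L) * vv
  if (edv == 0) stop("empty ED cavity")
  lvm <- sum(mask_ed$labels == 2L) * vv
  list(EDV_ml = edv, ESV_ml = esv, EF_pct = (edv - esv) / edv * 100,
       LVM_g = lvm * 1.05)
}

#' In-plane end-point error between two landmark positions (mm)
#' @param p,p_prime length-2 (or longer; only x, y used) positions in mm.
#' @return Euclidean in-plane distance.
#' @export
epe <- function(p, p_prime) {
  sqrt((p[1] - p_prime[1])^2 + (p[2] - p_prime[2])^2)
}

#' Deform landmarks with a displacement field
#'
#' Samples the field trilinearly at each landmark (voxel coordinates derived
#' from the mm positions), converts to mm via the spacing, and adds it to
#' the reference positions. The field is sampled at the landmark's slice;
#' errors are reported in-plane only.
#' @param landmarks data.frame with `x_mm`, `y_mm` (grid frame: mm from the
#'   voxel (0,0) centre) and `z_slice`.
#' @param field a [disp_field()].
#' @return data.frame of deformed positions (mm) with `z_slice` retained.
#' @export
deform_landmarks <- function(landmarks, field) {
  g <- field$grid
  vx <- landmarks$x_mm / g$spacing[1]
  vy <- landmarks$y_mm / g$spacing[2]
  vz <- landmarks$z_slice
  if (any(vx < 0 | vx > g$shape[1] - 1 | vy < 0 | vy > g$shape[2] - 1))
    stop("landmark outside grid")
  u <- cpp_sample_points(as_mat(field$u), g$shape, cbind(vx, vy, vz), 0L)
  data.frame(x_mm = landmarks$x_mm + u[, 1] * g$spacing[1],
             y_mm = landmarks$y_mm + u[, 2] * g$spacing[2],
             z_slice = landmarks$z_slice)
}

#' Average end-point error over subjects and observers at end-systole (mm)
#'
#' `(1/2n) * sum_i sum_j EPE(p_ij(t_ES), deform(p_0, u_i(t_ES)))`, evaluated
#' at ES only.
#' @param tracks list over subjects; each subject is a list of two observer
#'   data.frames of manually tracked ES positions (`x_mm`, `y_mm`,
#'   `z_slice`), plus `p0`, the shared ED reference positions.
#' @param fields_es list of ES-frame [disp_field()] per subject.
#' @return Mean EPE in mm (per-landmark errors in attribute `"per_point"`).
#' @export
aepe <- function(tracks, fields_es) {
  n <- length(tracks)
  if (n == 0 || length(fields_es) != n) stop("subject count mismatch")
  errs <- c()
  per_subject <- numeric(0)
  for (i in seq_len(n)) {
    p0 <- tracks[[i]]$p0
    def <- deform_landmarks(p0, fields_es[[i]])
    for (j in 1:2) {
      obs <- tracks[[i]]$observers[[j]]
      if (is.null(obs)) stop("missing observer track")
      e <- sqrt((obs$x_mm - def$x_mm)^2 + (obs$y_mm - def$y_mm)^2)
      errs <- c(errs, e)
      per_subject <- c(per_subject, mean(e))
    }
  }
  out <- mean(per_subject)
  attr(out, "per_point") <- errs
  out
}

#' Bland-Altman bias and precision
#'
#' Bias is the mean paired difference; precision is the sample standard
#' deviation of the differences (n - 1 denominator).
#' @param x,y paired measurements.
#' @return List with `bias`, `precision` and the 95% limits of agreement.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop("need paired samples, n >= 2")
  d <- x - y
  b <- mean(d); s <- sd(d)
  list(bias = b, precision = s, loa = c(lower = b - 1.96 * s,
                                        upper = b + 1.96 * s))
}

#' Intraclass correlation ICC(A,1) with 95% confidence interval
#'
#' Single-rating, absolute-agreement, two-way model, from the two-way ANOVA
#' mean squares: `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with
#' the standard F-based confidence interval.
#' @param table n x k matrix (subjects x repeated acquisitions).
#' @param conf confidence level, default 0.95.
#' @return List with `icc`, `ci` (length 2) and the ANOVA mean squares.
#' @export
icc_a1 <- function(table, conf = 0.95) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 acquisitions")
  gm <- mean(table)
  rm_ <- rowMeans(table); cm <- colMeans(table)
  MSR <- k * sum((rm_ - gm)^2) / (n - 1)
  MSC <- n * sum((cm - gm)^2) / (k - 1)
  resid <- table - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (denom <= 0 || (MSR == 0 && MSC == 0 && MSE == 0)) {
    warning("degenerate table; ICC undefined")
    return(list(icc = NA_real_, ci = c(NA_real_, NA_real_),
                MSR = MSR, MSC = MSC, MSE = MSE))
  }
  icc <- (MSR - MSE) / denom
  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  F1 <- qf(1 - alpha / 2, n - 1, v)
  F2 <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - F1 * MSE) /
    (F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (F2 * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * F2 * MSR)
  list(icc = icc, ci = c(lower = lower, upper = upper),
       MSR = MSR, MSC = MSC, MSE = MSE)
}

#' Relative change and absolute relative change between two acquisitions
#'
#' The first acquisition is the reference: `RC = (x2 - x1)/x1 * 100`,
#' `aRC = |RC|`.
#' @param x1,x2 per-subject measurements from acquisitions 1 and 2.
#' @return List with per-subject `RC`, `aRC` and their mean (sd) summaries.
#' @export
rc_arc <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("length mismatch")
  if (any(x1 == 0)) stop("zero reference value")
  rc <- (x2 - x1) / x1 * 100
  arc <- abs(rc)
  list(RC = rc, aRC = arc,
       RC_mean = mean(rc), RC_sd = sd(rc),
       aRC_mean = mean(arc), aRC_sd = sd(arc))
}

#' Read a landmark table from CSV
#'
#' Expected columns: `subject`, `observer`, `frame`, `x_mm`, `y_mm`, `z_slice`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  need <- c("subject", "observer", "frame", "x_mm", "y_mm", "z_slice")
  if (!all(need %in% names(df)))
    stop("landmark table must have columns: ", paste(need, collapse = ", "))
  df
}
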