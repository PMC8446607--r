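# Training losses: MSE heatmap regression, multi-class Dice and categorical
# cross-entropy for segmentation, and the unsupervised motion objective
# (absolute intensity difference after warping + anatomical overlap of warped
# labels + diffusion smoothness of the field), combined with weights
# (lambda_i, lambda_a, lambda_s). Gradients are hand-derived and returned by
# the *_grad companions used by the optimizer.

#' Loss weights for the motion-estimation objective
#' @param lambda_i intensity weight (default 0.01).
#' @param lambda_a anatomical weight (default 0.5).
#' @param lambda_s smoothness weight (default 0.1).
#' @return List of class `loss_weights`.
#' @export
loss_weights <- function(lambda_i = 0.01, lambda_a = 0.5, lambda_s = 0.1) {
  stopifnot(lambda_i >= 0, lambda_a >= 0, lambda_s >= 0)
  structure(list(lambda_i = lambda_i, lambda_a = lambda_a, lambda_s = lambda_s),
            class = "loss_weights")
}

#' Mean squared error
#' @param target,pred numeric arrays of equal shape.
#' @return Scalar mean of squared differences.
#' @export
mse_loss <- function(target, pred) {
  if (length(target) != length(pred)) stop("shape mismatch")
  mean((target - pred)^2)
}

mse_grad <- function(target, pred) 2 * (pred - target) / length(pred)

#' Multi-class Dice loss
#'
#' Negative mean of the per-class Dice terms over the four classes
#' (background, RV, LVM, cavity); identical one-hot masks score -1. Soft
#' (warped/probabilistic) masks use the standard differentiable relaxation:
#' sum-of-products overlap, sum-of-values sizes. A class absent from both
#' masks contributes a term of 1 (perfect agreement on absence).
#' @param m_a,m_b arrays (..., 4) of nonnegative channel weights.
#' @return Scalar in [-1, 0].
#' @export
mdc_loss <- function(m_a, m_b) {
  da <- dim(m_a); db <- dim(m_b)
  if (da[length(da)] != 4 || db[length(db)] != 4) stop("masks must have 4 channels")
  if (!all(da == db)) stop("shape mismatch")
  A <- matrix(m_a, ncol = 4); B <- matrix(m_b, ncol = 4)
  terms <- vapply(1:4, function(k) {
    den <- sum(A[, k]) + sum(B[, k])
    if (den == 0) 1 else 2 * sum(A[, k] * B[, k]) / den
  }, 0)
  -mean(terms)
}

# gradient of mdc_loss with respect to m_b
mdc_grad <- function(m_a, m_b) {
  da <- dim(m_a)
  A <- matrix(m_a, ncol = 4); B <- matrix(m_b, ncol = 4)
  G <- matrix(0, nrow(B), 4)
  for (k in 1:4) {
    den <- sum(A[, k]) + sum(B[, k])
    if (den == 0) next
    num <- 2 * sum(A[, k] * B[, k])
    G[, k] <- -(2 * A[, k] / den - num / den^2) / 4
  }
  array(G, dim = da)
}

#' Pixel-wise categorical cross-entropy
#' @param m_true one-hot array (..., 4).
#' @param m_prob predicted class probabilities (..., 4), clipped at 1e-7.
#' @return Scalar: mean over pixels of -log p(true class).
#' @export
cce_loss <- function(m_true, m_prob) {
  if (!all(dim(m_true) == dim(m_prob))) stop("shape mismatch")
  A <- matrix(m_true, ncol = 4); P <- pmax(matrix(m_prob, ncol = 4), 1e-7)
  -sum(A * log(P)) / nrow(A)
}

cce_grad <- function(m_true, m_prob) {
  da <- dim(m_true)
  A <- matrix(m_true, ncol = 4); P <- pmax(matrix(m_prob, ncol = 4), 1e-7)
  G <- -(A / P) / nrow(A)
  G[matrix(m_prob, ncol = 4) < 1e-7] <- 0
  array(G, dim = da)
}

#' Intensity (image-matching) loss of a motion estimate
#'
#' Mean absolute difference between the reference frame and the moving frame
#' warped by the field: `mean |V0(v) - Vt(v + u(v))|`.
#' @param v0,vt intensity arrays (nx, ny, nz) on a shared grid.
#' @param u displacement array (nx, ny, nz, 3), voxel units.
#' @return Scalar loss.
#' @export
intensity_loss <- function(v0, vt, u) {
  d <- dim(v0)
  if (!all(dim(vt) == d) || !all(dim(u)[1:3] == d)) stop("grid mismatch")
  w <- cpp_warp_fwd(as_mat(vt), d, as_mat(u))
  mean(abs(as.vector(v0) - w))
}

intensity_grad <- function(v0, vt, u) {
  d <- dim(v0)
  vm <- as_mat(vt); um <- as_mat(u)
  w <- cpp_warp_fwd(vm, d, um)
  r <- w - as.vector(v0)
  gy <- matrix(sign(r) / length(r), ncol = 1)
  bw <- cpp_warp_bwd(vm, d, um, gy)
  list(loss = mean(abs(r)), gu = array(bw$gu, dim = c(d, 3)))
}

#' Anatomical (label-overlap) loss of a motion estimate
#'
#' Warps each one-hot channel of the moving mask independently with trilinear
#' interpolation (giving a soft mask) and scores it against the reference
#' mask with the multi-class Dice loss (default) or cross-entropy.
#' @param m0,mt one-hot arrays (nx, ny, nz, 4) on a shared grid.
#' @param u displacement array (nx, ny, nz, 3), voxel units.
#' @param mode `"MDC"` (default) or `"CCE"`.
#' @return Scalar loss.
#' @export
anatomical_loss <- function(m0, mt, u, mode = c("MDC", "CCE")) {
  mode <- match.arg(mode)
  d <- dim(m0)[1:3]
  if (!all(dim(mt) == dim(m0)) || !all(dim(u)[1:3] == d)) stop("grid mismatch")
  w <- cpp_warp_fwd(as_mat(mt), d, as_mat(u))
  wm <- array(w, dim = dim(m0))
  if (mode == "MDC") mdc_loss(m0, wm) else cce_loss(m0, wm)
}

anatomical_grad <- function(m0, mt, u, mode = "MDC") {
  d <- dim(m0)[1:3]
  mm <- as_mat(mt); um <- as_mat(u)
  w <- cpp_warp_fwd(mm, d, um)
  wm <- array(w, dim = dim(m0))
  if (mode == "MDC") {
    loss <- mdc_loss(m0, wm); gw <- mdc_grad(m0, wm)
  } else {
    loss <- cce_loss(m0, wm); gw <- cce_grad(m0, wm)
  }
  bw <- cpp_warp_bwd(mm, d, um, as_mat(gw))
  list(loss = loss, gu = array(bw$gu, dim = c(d, 3)))
}

#' Diffusion (smoothness) regularizer of a displacement field
#'
#' Squared norm of the spatial gradient of the field, each directional
#' derivative (central differences, one-sided at borders, voxel units)
#' scaled by the spacing of its axis to account for anisotropic resolution.
#' Reduced by the mean over voxels by default (a `"sum"` switch is provided);
#' the mean keeps the weight interpretable across grid sizes.
#' @param u displacement array (nx, ny, nz, 3), voxel units.
#' @param dr spacing triple (mm).
#' @param reduce `"mean"` (default) or `"sum"`.
#' @return Scalar loss.
#' @export
smoothness_loss <- function(u, dr, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  d <- dim(u)[1:3]
  um <- as_mat(u)
  tot <- 0
  for (j in 1:3) {
    dj <- cpp_fd(um, d, j - 1L) * dr[j]
    tot <- tot + sum(dj^2)
  }
  if (reduce == "mean") tot / prod(d) else tot
}

smoothness_grad <- function(u, dr, reduce = "mean") {
  d <- dim(u)[1:3]
  um <- as_mat(u)
  gu <- matrix(0, nrow(um), 3)
  tot <- 0
  for (j in 1:3) {
    dj <- cpp_fd(um, d, j - 1L)
    tot <- tot + sum((dj * dr[j])^2)
    gu <- gu + 2 * dr[j]^2 * cpp_fd_adjoint(dj, d, j - 1L)
  }
  scale <- if (reduce == "mean") 1 / prod(d) else 1
  list(loss = tot * scale, gu = array(gu * scale, dim = c(d, 3)))
}

#' Combined motion-estimation loss
#'
#' `lambda_i * intensity + lambda_a * anatomical + lambda_s * smoothness`.
#' @param v0,vt intensity arrays; `m0`, `mt` one-hot masks; `u` the field.
#' @param m0,mt one-hot (nx, ny, nz, 4) arrays.
#' @param u displacement array (nx, ny, nz, 3).
#' @param weights a [loss_weights()].
#' @param dr spacing triple (mm).
#' @param mode anatomical mode, `"MDC"` or `"CCE"`.
#' @param reduce smoothness reduction.
#' @return Scalar total loss (components in attribute `"components"`).
#' @export
carmen_total_loss <- function(v0, vt, m0, mt, u, weights = loss_weights(),
                              dr = c(1.25, 1.25, 10), mode = "MDC",
                              reduce = "mean") {
  li <- if (weights$lambda_i > 0) intensity_loss(v0, vt, u) else 0
  la <- if (weights$lambda_a > 0) anatomical_loss(m0, mt, u, mode) else 0
  ls <- if (weights$lambda_s > 0) smoothness_loss(u, dr, reduce) else 0
  tot <- weights$lambda_i * li + weights$lambda_a * la + weights$lambda_s * ls
  attr(tot, "components") <- c(intensity = li, anatomical = la, smoothness = ls)
  tot
}

carmen_total_grad <- function(v0, vt, m0, mt, u, weights, dr, mode = "MDC",
                              reduce = "mean") {
  d <- dim(u)[1:3]
  gu <- array(0, dim = c(d, 3))
  li <- la <- ls <- 0
  if (weights$lambda_i > 0) {
    gi <- intensity_grad(v0, vt, u)
    li <- gi$loss; gu <- gu + weights$lambda_i * gi$gu
  }
  if (weights$lambda_a > 0) {
    ga <- anatomical_grad(m0, mt, u, mode)
    la <- ga$loss; gu <- gu + weights$lambda_a * ga$gu
  }
  if (weights$lambda_s > 0) {
    gs <- smoothness_grad(u, dr, reduce)
    ls <- gs$loss; gu <- gu + weights$lambda_s * gs$gu
  }
  list(loss = weights$lambda_i * li + weights$lambda_a * la +
         weights$lambda_s * ls,
       components = c(intensity = li, anatomical = la, smoothness = ls),
       gu = gu)
}
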