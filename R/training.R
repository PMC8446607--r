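# Training: Adam optimizer, in-plane augmentation, ED-ED/ED-ES pairing,
# Gaussian heatmap targets and the per-network loops. One master seed fans
# out to weight initialization, data order and augmentation draws. Batches
# are stacked along z, which is exact for kz = 1 networks (no through-plane
# mixing); batch normalization then runs over batch plus space.

#' Training configuration
#' @param learning_rate Adam step size (full-scale default 1e-4).
#' @param adam_betas Adam (beta1, beta2).
#' @param batch_size samples per step (80 for centering/segmentation, 5 for
#'   motion estimation).
#' @param epochs training epochs.
#' @param seed master RNG seed.
#' @param augment apply random in-plane augmentation each epoch.
#' @param rotation_deg,translation_vox,gamma_range augmentation ranges.
#' @param heatmap_sigma Gaussian width (mm) of the centre-heatmap target.
#' @param weights a [loss_weights()] (motion network only).
#' @param anatomical_mode `"MDC"` or `"CCE"` anatomical term.
#' @param seg_loss segmentation loss, `"MDC"` or `"CCE"`.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, adam_betas = c(0.9, 0.999),
                         batch_size = 80L, epochs = 50L, seed = 1L,
                         augment = FALSE, rotation_deg = 15,
                         translation_vox = 10, gamma_range = c(0.7, 1.4),
                         heatmap_sigma = 10, weights = loss_weights(),
                         anatomical_mode = "MDC", seg_loss = "MDC") {
  stopifnot(learning_rate > 0, batch_size >= 1, all(gamma_range > 0))
  structure(list(learning_rate = learning_rate, adam_betas = adam_betas,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seed = as.integer(seed), augment = augment,
                 rotation_deg = rotation_deg, translation_vox = translation_vox,
                 gamma_range = gamma_range, heatmap_sigma = heatmap_sigma,
                 weights = weights, anatomical_mode = anatomical_mode,
                 seg_loss = seg_loss),
            class = "train_config")
}

#' Gaussian centre-heatmap target from a segmentation
#'
#' Isotropic (in mm) Gaussian with peak 1 centred on the LVM centre of mass.
#' @param mask a [seg_mask()] containing LVM voxels.
#' @param sigma_mm Gaussian standard deviation in mm.
#' @return A [cs_volume()] heatmap on the mask's grid.
#' @export
gaussian_target <- function(mask, sigma_mm = 10) {
  g <- mask$grid; d <- g$shape
  lvm <- which(mask$labels == 2L, arr.ind = TRUE)
  if (nrow(lvm) == 0) stop("mask contains no LVM voxels")
  ctr <- colMeans(lvm) - 1  # 0-based centroid
  dx2 <- (((seq_len(d[1]) - 1) - ctr[1]) * g$spacing[1])^2
  dy2 <- (((seq_len(d[2]) - 1) - ctr[2]) * g$spacing[2])^2
  dz2 <- (((seq_len(d[3]) - 1) - ctr[3]) * g$spacing[3])^2
  hm <- exp(-(outer(outer(dx2, dy2, "+"), dz2, "+")) / (2 * sigma_mm^2))
  cs_volume(array(hm, dim = d), g)
}

# Draw one set of in-plane augmentation parameters from the active RNG.
draw_augment <- function(config) {
  list(angle = runif(1, -config$rotation_deg, config$rotation_deg) * pi / 180,
       shift = runif(2, -config$translation_vox, config$translation_vox),
       mirror_x = runif(1) < 0.5, mirror_y = runif(1) < 0.5,
       gamma = runif(1, config$gamma_range[1], config$gamma_range[2]))
}

identity_augment <- function() {
  list(angle = 0, shift = c(0, 0), mirror_x = FALSE, mirror_y = FALSE, gamma = 1)
}

# In-plane linear part (rotation composed with mirroring) of an augmentation.
augment_matrix <- function(par) {
  R <- matrix(c(cos(par$angle), sin(par$angle),
                -sin(par$angle), cos(par$angle)), 2)
  M <- diag(c(if (par$mirror_x) -1 else 1, if (par$mirror_y) -1 else 1))
  R %*% M
}

#' Apply one consistent in-plane augmentation to a sample
#'
#' The same rotation/translation/mirroring is applied to every volume and
#' mask of the sample (bilinear vs nearest-neighbour sampling); gamma
#' contrast applies to intensities only; an accompanying displacement field
#' has its in-plane components rotated/mirrored consistently. The z axis is
#' never touched.
#' @param sample list with `volumes` (list of 3D arrays in [0,1]), `masks`
#'   (list of integer label arrays) and optionally `field`
#'   ((nx, ny, nz, 3) array, voxel units).
#' @param par augmentation parameters from the active RNG (internal draw when
#'   omitted); pass the result of a previous call's `attr(, "par")` to reuse.
#' @param config a [train_config()] supplying ranges for the internal draw.
#' @return Augmented sample (same structure), with the parameter draw in
#'   attribute `"par"`.
#' @export
augment <- function(sample, par = NULL, config = train_config()) {
  if (is.null(par)) par <- draw_augment(config)
  d <- dim(sample$volumes[[1]])
  A <- augment_matrix(par)
  Ainv <- solve(A)
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
  idx <- seq_len(d[1] * d[2]) - 1
  gx <- idx %% d[1]; gy <- idx %/% d[1]
  # source coords: invert translation then the linear part, about the centre
  px <- gx - cx - par$shift[1]; py <- gy - cy - par$shift[2]
  sx <- Ainv[1, 1] * px + Ainv[1, 2] * py + cx
  sy <- Ainv[2, 1] * px + Ainv[2, 2] * py + cy
  pts <- do.call(rbind, lapply(seq_len(d[3]) - 1, function(z)
    cbind(sx, sy, rep(z, length(sx)))))
  warp_arr <- function(a, mode) {
    C <- if (length(dim(a)) == 4) dim(a)[4] else 1L
    out <- cpp_sample_points(as_mat(a), d, pts, mode)
    array(out, dim = c(d, if (length(dim(a)) == 4) C))
  }
  out <- sample
  out$volumes <- lapply(sample$volumes, function(v)
    pmin(pmax(warp_arr(v, 0L), 0), 1)^par$gamma)
  if (!is.null(sample$masks))
    out$masks <- lapply(sample$masks, function(m) {
      r <- warp_arr(m + 0, 1L); storage.mode(r) <- "integer"; r
    })
  if (!is.null(sample$field)) {
    f <- warp_arr(sample$field, 0L)
    fx <- A[1, 1] * f[, , , 1] + A[1, 2] * f[, , , 2]
    fy <- A[2, 1] * f[, , , 1] + A[2, 2] * f[, , , 2]
    f[, , , 1] <- fx; f[, , , 2] <- fy
    out$field <- f
  }
  attr(out, "par") <- par
  out
}

#' Training pairs from a cine sequence (ED-ED and ED-ES)
#'
#' Only the identity pair (teaching the zero transform) and the ED-ES pair
#' are used for motion-estimation training.
#' @param sequence a [cine_sequence()] with a known ES index.
#' @param masks list of [seg_mask()] matching the frames.
#' @return List of two pairs, each `list(v0, vt, m0, mt, type)`.
#' @export
make_pairs <- function(sequence, masks) {
  es <- sequence$es_index
  if (is.na(es)) stop("sequence has no ES index; run detect_es() first")
  if (es == 1L) {
    warning("ES frame equals ED; pairs are degenerate")
  }
  v0 <- sequence$frames[[1]]; m0 <- masks[[1]]
  list(list(v0 = v0, vt = v0, m0 = m0, mt = m0, type = "ED-ED"),
       list(v0 = v0, vt = sequence$frames[[es]], m0 = m0, mt = masks[[es]],
            type = "ED-ES"))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, betas) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * grads[[i]]
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / corr1) / (sqrt(state$v[[i]] / corr2) + 1e-8)
  }
  list(params = params, state = state)
}

# stack (N, C) sample tensors along z: rbind is exact for kz = 1 networks
stack_batch <- function(mats) do.call(rbind, mats)

check_finite_loss <- function(loss, epoch) {
  if (!is.finite(loss))
    stop("non-finite loss at epoch ", epoch, "; aborting training")
}

#' Train one of the three networks
#'
#' @param kind `"vcn"` (centre-heatmap regression), `"carson"` (per-slice
#'   segmentation) or `"carmen"` (unsupervised motion estimation).
#' @param dataset for `"vcn"`: list of `list(volume, mask)` on a common grid;
#'   for `"carson"`: list of `list(image, labels)` 2D slices;
#'   for `"carmen"`: list of pairs from [make_pairs()].
#' @param config a [train_config()].
#' @param net_config a [network_config()].
#' @param verbose print per-epoch losses.
#' @return Object of class `cs_model`: the network, configs and per-epoch
#'   loss history.
#' @export
train_network <- function(kind = c("vcn", "carson", "carmen"), dataset, config,
                          net_config = network_config(), verbose = FALSE) {
  kind <- match.arg(kind)
  if (length(dataset) == 0) stop("empty training dataset")
  trainer <- switch(kind, vcn = train_vcn, carson = train_carson,
                    carmen = train_carmen)
  with_seed(config$seed, trainer(dataset, config, net_config, verbose))
}

#' @export
print.cs_model <- function(x, ...) {
  cat(sprintf("<cs_model %s: %d epochs, final loss %.5g>\n", x$kind,
              length(x$history), x$history[length(x$history)]))
  invisible(x)
}

model_object <- function(kind, net, config, net_config, history) {
  structure(list(kind = kind, net = net, config = config,
                 net_config = net_config, history = history),
            class = "cs_model")
}

epoch_batches <- function(n, batch_size, kz = 1L) {
  # z-stacked batching is exact only for in-plane-only (kz = 1) networks;
  # kz = 3 networks step one sample at a time
  if (kz == 3L) batch_size <- 1L
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / min(batch_size, n)))
}

maybe_augment <- function(sample, config) {
  if (!config$augment) return(sample)
  augment(sample, config = config)
}

train_vcn <- function(dataset, config, net_config, verbose) {
  d <- dim(dataset[[1]]$volume$values)
  net <- build_backbone(net_config, 1L, 1L, seed = sample.int(1e6, 1))
  opt <- adam_init(net$params)
  history <- numeric(config$epochs)
  targets <- lapply(dataset, function(s)
    gaussian_target(s$mask, config$heatmap_sigma)$values)
  for (ep in seq_len(config$epochs)) {
    ep_loss <- 0; nb <- 0
    for (batch in epoch_batches(length(dataset), config$batch_size,
                                net_config$kz)) {
      xs <- list(); ys <- list()
      for (i in batch) {
        sm <- maybe_augment(list(volumes = list(
          normalize_volume(dataset[[i]]$volume$values), targets[[i]])), config)
        xs[[length(xs) + 1]] <- as_mat(sm$volumes[[1]])
        ys[[length(ys) + 1]] <- as_mat(sm$volumes[[2]])
      }
      x <- stack_batch(xs); y <- stack_batch(ys)
      bd <- c(d[1], d[2], d[3] * length(batch))
      fw <- net_forward(net, x, bd, training = TRUE)
      net <- fw$net
      loss <- mse_loss(y, fw$out)
      check_finite_loss(loss, ep)
      bw <- net_backward(fw, mse_grad(y, fw$out))
      st <- adam_step(net$params, bw$gparams, opt, config$learning_rate,
                      config$adam_betas)
      net$params <- st$params; opt <- st$state
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    history[ep] <- ep_loss / nb
    if (verbose) message(sprintf("vcn epoch %d loss %.6f", ep, history[ep]))
  }
  model_object("vcn", net, config, net_config, history)
}

train_carson <- function(dataset, config, net_config, verbose) {
  d2 <- dim(dataset[[1]]$image)
  d <- c(d2[1], d2[2], 1L)
  net <- build_backbone(net_config, 1L, 4L, seed = sample.int(1e6, 1),
                        head_sd = 1e-2)
  opt <- adam_init(net$params)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ep_loss <- 0; nb <- 0
    for (batch in epoch_batches(length(dataset), config$batch_size,
                                net_config$kz)) {
      xs <- list(); ms <- list()
      for (i in batch) {
        img <- array(dataset[[i]]$image, dim = d)
        lab <- array(dataset[[i]]$labels, dim = d)
        sm <- maybe_augment(list(volumes = list(normalize_volume(img)),
                                 masks = list(lab)), config)
        xs[[length(xs) + 1]] <- as_mat(sm$volumes[[1]])
        ms[[length(ms) + 1]] <- matrix(one_hot_mask(sm$masks[[1]]), ncol = 4)
      }
      x <- stack_batch(xs); mtrue <- stack_batch(ms)
      bd <- c(d[1], d[2], length(batch))
      fw <- net_forward(net, x, bd, training = TRUE)
      net <- fw$net
      prob <- softmax_channels(fw$out)
      oh <- array(mtrue, dim = c(bd, 4))
      pr <- array(prob, dim = c(bd, 4))
      if (config$seg_loss == "MDC") {
        loss <- mdc_loss(oh, pr)
        gprob <- matrix(mdc_grad(oh, pr), ncol = 4)
      } else {
        loss <- cce_loss(oh, pr)
        gprob <- matrix(cce_grad(oh, pr), ncol = 4)
      }
      check_finite_loss(loss, ep)
      # softmax jacobian: dL/dlogit = p * (g - sum_k g_k p_k)
      glogit <- prob * (gprob - rowSums(gprob * prob))
      bw <- net_backward(fw, glogit)
      st <- adam_step(net$params, bw$gparams, opt, config$learning_rate,
                      config$adam_betas)
      net$params <- st$params; opt <- st$state
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    history[ep] <- ep_loss / nb
    if (verbose) message(sprintf("carson epoch %d loss %.6f", ep, history[ep]))
  }
  model_object("carson", net, config, net_config, history)
}

train_carmen <- function(dataset, config, net_config, verbose) {
  g <- dataset[[1]]$v0$grid
  d <- g$shape
  net <- build_backbone(net_config, 2L, 3L, seed = sample.int(1e6, 1),
                        head_sd = 1e-3)
  opt <- adam_init(net$params)
  history <- numeric(config$epochs)
  N <- prod(d)
  prep <- lapply(dataset, function(p)
    list(v0 = normalize_volume(p$v0$values), vt = normalize_volume(p$vt$values),
         m0 = one_hot_mask(p$m0), mt = one_hot_mask(p$mt)))
  for (ep in seq_len(config$epochs)) {
    ep_loss <- 0; nb <- 0
    for (batch in epoch_batches(length(dataset), config$batch_size,
                                net_config$kz)) {
      sm <- lapply(batch, function(i) {
        s <- prep[[i]]
        if (!config$augment) return(s)
        a <- augment(list(volumes = list(s$v0, s$vt),
                          masks = list(hard_labels(s$m0), hard_labels(s$mt))),
                     config = config)
        list(v0 = a$volumes[[1]], vt = a$volumes[[2]],
             m0 = one_hot_mask(a$masks[[1]]), mt = one_hot_mask(a$masks[[2]]))
      })
      x <- stack_batch(lapply(sm, function(s)
        cbind(as_mat(s$v0), as_mat(s$vt))))
      bd <- c(d[1], d[2], d[3] * length(batch))
      fw <- net_forward(net, x, bd, training = TRUE)
      net <- fw$net
      gy <- matrix(0, nrow(fw$out), 3)
      loss <- 0
      for (bi in seq_along(sm)) {
        rows <- ((bi - 1) * N + 1):(bi * N)
        u <- array(fw$out[rows, ], dim = c(d, 3))
        gr <- carmen_total_grad(sm[[bi]]$v0, sm[[bi]]$vt, sm[[bi]]$m0,
                                sm[[bi]]$mt, u, config$weights, g$spacing,
                                mode = config$anatomical_mode)
        gy[rows, ] <- as_mat(gr$gu) / length(sm)
        loss <- loss + gr$loss / length(sm)
      }
      check_finite_loss(loss, ep)
      bw <- net_backward(fw, gy)
      st <- adam_step(net$params, bw$gparams, opt, config$learning_rate,
                      config$adam_betas)
      net$params <- st$params; opt <- st$state
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    history[ep] <- ep_loss / nb
    if (verbose) message(sprintf("carmen epoch %d loss %.6f", ep, history[ep]))
  }
  model_object("carmen", net, config, net_config, history)
}

#' Estimate motion for a whole cine sequence
#'
#' Pairs the reference (ED) frame with every frame sequentially; the first
#' field is the model's ED-ED output (no forced zeroing).
#' @param model a trained `"carmen"` [train_network()] model.
#' @param sequence a centred/cropped [cine_sequence()].
#' @return List of [disp_field()], one per frame.
#' @export
infer_sequence <- function(model, sequence) {
  v0 <- sequence$frames[[1]]
  lapply(sequence$frames, function(vt) carmen_forward(model, v0, vt))
}

#' Save / load a trained model
#'
#' Weights are serialized in R's native format next to a JSON sidecar
#' recording the architecture and training configuration.
#' @param model a `cs_model`.
#' @param path checkpoint path (`.rds`).
#' @return `save_model`: the path, invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(kind = model$kind, net_config = unclass(model$net_config),
               seed = model$config$seed, epochs = model$config$epochs,
               final_loss = model$history[length(model$history)])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
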