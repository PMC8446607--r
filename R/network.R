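# Compact convolutional encoder-decoder shared by the three networks
# (centering, segmentation, motion). Convolutions are 3 x 3 x kz with
# kz in {1, 3}; for kz = 1 all operators act in-plane only, so stacks with
# any slice count are valid inputs and batches can be stacked along z.
# Forward passes record a tape of intermediates; backward walks it in
# reverse with hand-derived layer gradients.

#' Network architecture configuration
#' @param kz through-plane kernel extent, 1 (in-plane-only operators) or 3.
#' @param base_filters channel width at full resolution.
#' @param depth number of resolution levels (>= 2); in-plane size must be
#'   divisible by `2^(depth-1)`.
#' @param residual include a residual conv block per level.
#' @param normalization include batch normalization after convolutions.
#' @return List of class `network_config`.
#' @export
network_config <- function(kz = 1L, base_filters = 16L, depth = 3L,
                           residual = TRUE, normalization = TRUE) {
  stopifnot(kz %in% c(1L, 3L), depth >= 2, base_filters >= 4)
  structure(list(kz = as.integer(kz), base_filters = as.integer(base_filters),
                 depth = as.integer(depth), residual = residual,
                 normalization = normalization, activation = "prelu"),
            class = "network_config")
}

conv_init <- function(cin, cout, kz, sd = NULL) {
  fan_in <- 9 * kz * cin
  if (is.null(sd)) sd <- sqrt(2 / fan_in)
  list(w = array(rnorm(9 * kz * cin * cout, sd = sd),
                 dim = c(3, 3, kz, cin, cout)),
       b = rep(0, cout))
}

#' Build an encoder-decoder network
#'
#' Levels double the channel width while halving the in-plane resolution
#' (average pooling); the decoder mirrors with nearest-neighbour upsampling
#' and additive skip connections; a linear 3 x 3 x kz head produces the
#' output channels. The head is initialized with small weights so untrained
#' motion/heatmap outputs start near zero.
#' @param config a [network_config()].
#' @param in_channels,out_channels channel counts.
#' @param seed RNG seed for weight initialization.
#' @param head_sd standard deviation of the head initialization.
#' @return Object of class `cs_network`.
#' @export
build_backbone <- function(config, in_channels, out_channels, seed = 1L,
                           head_sd = 1e-3) {
  F <- config$base_filters * 2^(0:(config$depth - 1))
  ops <- list(); params <- list()
  add_param <- function(p) { params[[length(params) + 1]] <<- p; length(params) }
  add_conv <- function(cin, cout, sd = NULL) {
    ini <- conv_init(cin, cout, config$kz, sd)
    ops[[length(ops) + 1]] <<- list(type = "conv", w = add_param(ini$w),
                                    b = add_param(ini$b), cin = cin, cout = cout)
  }
  add_bn <- function(c) {
    if (!config$normalization) return(invisible())
    ops[[length(ops) + 1]] <<- list(type = "bn", gamma = add_param(rep(1, c)),
                                    beta = add_param(rep(0, c)), c = c)
  }
  add_prelu <- function() {
    ops[[length(ops) + 1]] <<- list(type = "prelu", alpha = add_param(0.25))
  }
  add_op <- function(type, ...) ops[[length(ops) + 1]] <<- list(type = type, ...)
  block <- function(cw) {
    if (!config$residual) return(invisible())
    add_op("res_begin")
    add_conv(cw, cw); add_bn(cw); add_prelu()
    add_op("res_add")
  }
  with_seed(seed, {
    add_conv(in_channels, F[1]); add_bn(F[1]); add_prelu()
    block(F[1])
    add_op("save_skip", slot = 1L)
    for (l in 2:config$depth) {
      add_op("pool")
      add_conv(F[l - 1], F[l]); add_bn(F[l]); add_prelu()
      block(F[l])
      if (l < config$depth) add_op("save_skip", slot = l)
    }
    for (l in (config$depth - 1):1) {
      add_op("upsample")
      add_conv(F[l + 1], F[l]); add_bn(F[l]); add_prelu()
      add_op("add_skip", slot = l)
    }
    add_conv(F[1], out_channels, sd = head_sd)
  })
  bn_state <- lapply(ops, function(o)
    if (o$type == "bn") list(mean = rep(0, o$c), var = rep(1, o$c)) else NULL)
  structure(list(config = config, in_channels = in_channels,
                 out_channels = out_channels, ops = ops, params = params,
                 bn_state = bn_state, seed = seed),
            class = "cs_network")
}

#' @export
print.cs_network <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<cs_network: %d -> %d channels, depth %d, base %d, kz %d, %d parameters>\n",
              x$in_channels, x$out_channels, x$config$depth,
              x$config$base_filters, x$config$kz, np))
  invisible(x)
}

n_params <- function(net) sum(vapply(net$params, length, 0L))

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# x: (N, Cin) matrix; dims: c(nx, ny, nz). Returns list(out, tape).
net_forward <- function(net, x, dims, training = FALSE) {
  if (any(dims[1:2] %% 2^(net$config$depth - 1) != 0))
    stop("in-plane size must be divisible by 2^(depth-1)")
  P <- net$params
  tape <- vector("list", length(net$ops))
  skips <- list(); res_stack <- list()
  cur <- x; cd <- dims
  for (i in seq_along(net$ops)) {
    op <- net$ops[[i]]
    if (op$type == "conv") {
      tape[[i]] <- list(x = cur, dims = cd)
      cur <- cpp_conv3d_fwd(cur, cd, as.numeric(P[[op$w]]), P[[op$b]],
                            net$config$kz)
    } else if (op$type == "bn") {
      if (training) {
        fwd <- cpp_bn_fwd_train(cur, P[[op$gamma]], P[[op$beta]], BN_EPS)
        st <- net$bn_state[[i]]
        st$mean <- BN_MOMENTUM * st$mean + (1 - BN_MOMENTUM) * as.numeric(fwd$mu)
        st$var <- BN_MOMENTUM * st$var + (1 - BN_MOMENTUM) * as.numeric(fwd$var)
        net$bn_state[[i]] <- st
        tape[[i]] <- list(xhat = fwd$xhat, sdv = fwd$sdv, dims = cd)
        cur <- fwd$y
      } else {
        st <- net$bn_state[[i]]
        cur <- cpp_bn_fwd_infer(cur, st$mean, st$var, P[[op$gamma]],
                                P[[op$beta]], BN_EPS)
        tape[[i]] <- list(dims = cd)
      }
    } else if (op$type == "prelu") {
      tape[[i]] <- list(x = cur)
      cur <- cpp_prelu_fwd(cur, P[[op$alpha]])
    } else if (op$type == "pool") {
      tape[[i]] <- list(dims = cd)
      cur <- cpp_avgpool_fwd(cur, cd)
      cd <- c(cd[1] %/% 2L, cd[2] %/% 2L, cd[3])
    } else if (op$type == "upsample") {
      tape[[i]] <- list(dims = cd)
      cur <- cpp_upsample_fwd(cur, cd)
      cd <- c(cd[1] * 2L, cd[2] * 2L, cd[3])
    } else if (op$type == "save_skip") {
      skips[[op$slot]] <- cur
    } else if (op$type == "add_skip") {
      cur <- cur + skips[[op$slot]]
    } else if (op$type == "res_begin") {
      res_stack[[length(res_stack) + 1]] <- cur
    } else if (op$type == "res_add") {
      cur <- cur + res_stack[[length(res_stack)]]
      res_stack[[length(res_stack)]] <- NULL
    }
  }
  list(out = cur, dims = cd, tape = tape, net = net)
}

# gy: gradient wrt network output. Returns list(gparams, gx).
net_backward <- function(fw, gy) {
  net <- fw$net; P <- net$params
  gP <- vector("list", length(P))
  skip_g <- list(); res_g <- list()
  g <- gy
  for (i in rev(seq_along(net$ops))) {
    op <- net$ops[[i]]; tp <- fw$tape[[i]]
    if (op$type == "conv") {
      bw <- cpp_conv3d_bwd(tp$x, tp$dims, as.numeric(P[[op$w]]), g,
                           net$config$kz)
      gP[[op$w]] <- array(bw$gw, dim = dim(P[[op$w]]))
      gP[[op$b]] <- as.numeric(bw$gb)
      g <- bw$gx
    } else if (op$type == "bn") {
      bw <- cpp_bn_bwd(tp$xhat, tp$sdv, P[[op$gamma]], g)
      gP[[op$gamma]] <- as.numeric(bw$ggamma)
      gP[[op$beta]] <- as.numeric(bw$gbeta)
      g <- bw$gx
    } else if (op$type == "prelu") {
      bw <- cpp_prelu_bwd(tp$x, P[[op$alpha]], g)
      gP[[op$alpha]] <- bw$galpha
      g <- bw$gx
    } else if (op$type == "pool") {
      g <- cpp_avgpool_bwd(g, tp$dims)
    } else if (op$type == "upsample") {
      g <- cpp_upsample_bwd(g, tp$dims)
    } else if (op$type == "save_skip") {
      sg <- skip_g[[as.character(op$slot)]]
      if (!is.null(sg)) g <- g + sg
    } else if (op$type == "add_skip") {
      skip_g[[as.character(op$slot)]] <- g
    } else if (op$type == "res_begin") {
      g <- g + res_g[[length(res_g)]]
      res_g[[length(res_g)]] <- NULL
    } else if (op$type == "res_add") {
      res_g[[length(res_g) + 1]] <- g
    }
  }
  for (j in seq_along(gP)) if (is.null(gP[[j]])) gP[[j]] <- P[[j]] * 0
  list(gparams = gP, gx = g)
}

softmax_channels <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Ventricular-centering forward pass
#'
#' Produces the centre heatmap for a workspace volume; the crop centre is the
#' argmax voxel (lowest linear index on ties). When the model records an
#' inference grid (`input_grid`), the volume is first resampled onto it and
#' the detected centre is mapped back to the voxel coordinates of the input.
#' @param model a trained model from [train_network()] (kind `"vcn"`), or a
#'   raw `cs_network`.
#' @param volume a [cs_volume()] on the workspace grid, intensity-normalized.
#' @return List with `heatmap` ([cs_volume()] on the inference grid) and
#'   `center` (0-based voxel triple in the input volume's grid).
#' @export
vcn_forward <- function(model, volume) {
  net <- if (inherits(model, "cs_network")) model else model$net
  work <- volume
  igrid <- if (inherits(model, "cs_network")) NULL else model$input_grid
  if (!is.null(igrid) && !grids_equal(volume$grid, igrid))
    work <- resample_to_workspace(volume, igrid)
  d <- work$grid$shape
  v <- normalize_volume(work)
  out <- net_forward(net, as_mat(v$values), d)$out
  hm <- array(out[, 1], dim = d)
  idx <- which.max(hm)  # lowest linear index on ties
  ctr <- c((idx - 1) %% d[1],
           ((idx - 1) %/% d[1]) %% d[2],
           (idx - 1) %/% (d[1] * d[2]))
  if (!identical(work, volume)) {
    # map back through the centre-aligned resampling
    ns <- volume$grid$shape; ss <- volume$grid$spacing
    nt <- work$grid$shape; st <- work$grid$spacing
    ctr <- round((ctr - (nt - 1) / 2) * st / ss + (ns - 1) / 2)
  }
  list(heatmap = cs_volume(hm, work$grid), center = as.integer(ctr))
}

#' Cardiac segmentation forward pass (per-slice 2D)
#'
#' Runs every slice of a cropped volume through the 2D segmentation network
#' and returns per-voxel class probabilities and the hard label mask.
#' @param model a trained model (kind `"carson"`) or raw `cs_network`.
#' @param volume a cropped, normalized [cs_volume()].
#' @return List with `prob` ((nx, ny, nz, 4) array) and `mask` ([seg_mask()]).
#' @export
carson_forward <- function(model, volume) {
  net <- if (inherits(model, "cs_network")) model else model$net
  d <- volume$grid$shape
  v <- normalize_volume(volume)
  # slices are independent for a 2D net: stack them along z as a batch
  out <- net_forward(net, as_mat(v$values), d)$out
  prob <- softmax_channels(out)
  prob_arr <- array(prob, dim = c(d, 4))
  list(prob = prob_arr,
       mask = seg_mask(hard_labels(prob_arr), volume$grid))
}

#' Motion-estimation forward pass
#'
#' Concatenates the reference and moving frames as a 2-channel input and
#' predicts the 3-component displacement field (voxel units) on the same grid.
#' @param model a trained model (kind `"carmen"`) or raw `cs_network`.
#' @param v0,vt reference and moving [cs_volume()] on a shared grid,
#'   normalized.
#' @return A [disp_field()].
#' @export
carmen_forward <- function(model, v0, vt) {
  net <- if (inherits(model, "cs_network")) model else model$net
  if (!grids_equal(v0$grid, vt$grid)) stop("frames must share a grid")
  d <- v0$grid$shape
  x <- cbind(as_mat(normalize_volume(v0)$values),
             as_mat(normalize_volume(vt)$values))
  out <- net_forward(net, x, d)$out
  disp_field(array(out, dim = c(d, 3)), v0$grid)
}

#' Differentiable spatial transform (trilinear warp)
#'
#' `output(v) = input(v + u(v))` with trilinear interpolation and
#' clamp-to-edge border handling.
#' @param x a [cs_volume()], [seg_mask()] (warped as one-hot channels and
#'   re-argmaxed) or plain array (3D or 4D channels-last).
#' @param u a [disp_field()] or (nx, ny, nz, 3) array in voxel units.
#' @return Warped object of the same type.
#' @export
spatial_transform <- function(x, u) {
  um <- if (inherits(u, "cs_field")) as_mat(u$u) else as_mat(u)
  if (inherits(x, "cs_volume")) {
    d <- x$grid$shape
    cs_volume(array(cpp_warp_fwd(as_mat(x$values), d, um), dim = d), x$grid)
  } else if (inherits(x, "cs_mask")) {
    d <- x$grid$shape
    oh <- one_hot_mask(x)
    w <- array(cpp_warp_fwd(as_mat(oh), d, um), dim = dim(oh))
    seg_mask(hard_labels(w), x$grid)
  } else {
    d <- dim(x)[1:3]
    out <- cpp_warp_fwd(as_mat(x), d, um)
    if (length(dim(x)) == 3) array(out, dim = d) else array(out, dim = dim(x))
  }
}
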