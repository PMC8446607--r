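test_that("backbone shape contract and construction determinism", {
  nc <- network_config(kz = 1L, base_filters = 4L, depth = 2L)
  net <- build_backbone(nc, 2L, 3L, seed = 9L)
  d <- c(16L, 16L, 3L)
  out <- cinestrain:::net_forward(net, matrix(rnorm(prod(d) * 2), ncol = 2), d)
  expect_equal(ncol(out$out), 3L)
  expect_equal(nrow(out$out), prod(d))
  expect_true(all(is.finite(out$out)))
  net2 <- build_backbone(nc, 2L, 3L, seed = 9L)
  expect_identical(cinestrain:::n_params(net), cinestrain:::n_params(net2))
  expect_identical(net$params, net2$params)
  # odd in-plane size cannot be pooled
  expect_error(cinestrain:::net_forward(net, matrix(0, 15 * 15 * 2, 2),
                                        c(15L, 15L, 2L)), "divisible")
})

test_that("kz = 1 networks never mix slices: z-permutation equivariance", {
  nc <- network_config(kz = 1L, base_filters = 4L, depth = 2L)
  net <- build_backbone(nc, 1L, 2L, seed = 2L)
  d <- c(8L, 8L, 4L)
  x <- array(rnorm(prod(d)), dim = d)
  perm <- c(3L, 1L, 4L, 2L)
  y1 <- cinestrain:::net_forward(net, cinestrain:::as_mat(x), d)$out
  y1a <- array(y1, dim = c(d, 2))
  y2 <- cinestrain:::net_forward(net,
                                 cinestrain:::as_mat(x[, , perm]), d)$out
  y2a <- array(y2, dim = c(d, 2))
  expect_equal(y2a, y1a[, , perm, ], tolerance = 1e-12)
  # and a different slice count is a valid input (no z pooling)
  d8 <- c(8L, 8L, 8L)
  y3 <- cinestrain:::net_forward(net, matrix(rnorm(prod(d8)), ncol = 1), d8)
  expect_equal(nrow(y3$out), prod(d8))
})

test_that("forward passes are deterministic with fixed weights (inference)", {
  nc <- network_config(base_filters = 4L, depth = 2L)
  net <- build_backbone(nc, 1L, 1L, seed = 4L)
  d <- c(8L, 8L, 2L)
  x <- matrix(rnorm(prod(d)), ncol = 1)
  expect_identical(cinestrain:::net_forward(net, x, d)$out,
                   cinestrain:::net_forward(net, x, d)$out)
})

test_that("centering forward: shape, finiteness and argmax tie-breaking", {
  nc <- network_config(base_filters = 4L, depth = 2L)
  net <- build_backbone(nc, 1L, 1L, seed = 5L)
  g <- volume_grid(c(32, 32, 4), c(1.25, 1.25, 8))
  v <- cs_volume(array(runif(prod(g$shape)), dim = g$shape), g)
  out <- vcn_forward(net, v)
  expect_equal(dim(out$heatmap$values), g$shape)
  expect_true(all(is.finite(out$heatmap$values)))
  expect_true(all(out$center >= 0 & out$center < g$shape))
  # tie in the maxima: the lowest linear index wins
  hm <- out$heatmap$values * 0
  hm[5, 7, 2] <- 1; hm[9, 3, 3] <- 1
  idx <- which.max(hm)
  expect_equal(idx, which(hm == 1)[1])
})

test_that("segmentation forward: probabilities sum to one, argmax contract", {
  nc <- network_config(base_filters = 4L, depth = 2L)
  net <- build_backbone(nc, 1L, 4L, seed = 6L, head_sd = 0.5)
  g <- volume_grid(c(16, 16, 3), c(2, 2, 8))
  v <- cs_volume(array(runif(prod(g$shape)), dim = g$shape), g)
  out <- carson_forward(net, v)
  sums <- apply(out$prob, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_identical(out$mask$labels,
                   cinestrain:::hard_labels(out$prob))
})

test_that("motion forward: untrained output is finite, near zero, right shape", {
  nc <- network_config(base_filters = 4L, depth = 2L)
  net <- build_backbone(nc, 2L, 3L, seed = 7L)
  g <- volume_grid(c(16, 16, 4), c(2.5, 2.5, 10))
  v0 <- cs_volume(array(runif(prod(g$shape)), dim = g$shape), g)
  vt <- cs_volume(array(runif(prod(g$shape)), dim = g$shape), g)
  u <- carmen_forward(net, v0, vt)
  expect_equal(dim(u$u), c(g$shape, 3))
  expect_true(all(is.finite(u$u)))
  g2 <- volume_grid(c(8, 8, 4), c(2.5, 2.5, 10))
  v2 <- cs_volume(array(0, dim = g2$shape), g2)
  expect_error(carmen_forward(net, v0, v2), "grid")
})

test_that("spatial transform: identity, unit shift on a ramp, gather oracle", {
  g <- volume_grid(c(10, 10, 4), c(1, 1, 1))
  set.seed(21)
  v <- cs_volume(array(runif(prod(g$shape)), dim = g$shape), g)
  u0 <- disp_field(array(0, dim = c(g$shape, 3)), g)
  expect_identical(spatial_transform(v, u0)$values, v$values)
  # ramp f(x) = x under u = (1,0,0): output f(x) = x + 1 in the interior
  ramp <- cs_volume(array(rep(0:9, 10 * 4), dim = g$shape), g)
  u1 <- array(0, dim = c(g$shape, 3)); u1[, , , 1] <- 1
  w <- spatial_transform(ramp, disp_field(u1, g))
  expect_equal(w$values[1:9, , ], ramp$values[1:9, , ] + 1, tolerance = 1e-12)
  # random integer field equals a direct integer gather on interior voxels
  set.seed(22)
  ui <- array(sample(-2:2, prod(g$shape) * 3, TRUE), dim = c(g$shape, 3))
  wi <- spatial_transform(v, disp_field(ui, g))
  for (k in 1:50) {
    p <- c(sample(3:8, 2), sample(2:3, 1))
    q <- p + ui[p[1], p[2], p[3], ]
    q <- pmin(pmax(q, 1), g$shape)  # border clamp
    expect_equal(wi$values[p[1], p[2], p[3]],
                 v$values[q[1], q[2], q[3]], tolerance = 1e-12)
  }
})

test_that("trilinear warping is exact on affine images for any field", {
  g <- volume_grid(c(12, 12, 4), c(1, 1, 1))
  co <- expand.grid(x = 0:11, y = 0:11, z = 0:3)
  aff <- array(2 + 0.3 * co$x - 0.2 * co$y + 0.5 * co$z, dim = g$shape)
  set.seed(23)
  u <- array(runif(prod(g$shape) * 3, -1.5, 1.5), dim = c(g$shape, 3))
  w <- spatial_transform(cs_volume(aff, g), disp_field(u, g))
  # interior voxels whose sample point stays inside the grid
  ok <- TRUE
  for (k in 1:100) {
    p <- c(sample(3:10, 2), sample(2:3, 1))
    q <- p - 1 + u[p[1], p[2], p[3], ]
    if (any(q < 0 | q > c(11, 11, 3))) next
    want <- 2 + 0.3 * q[1] - 0.2 * q[2] + 0.5 * q[3]
    expect_equal(w$values[p[1], p[2], p[3]], want, tolerance = 1e-10)
  }
})

test_that("mask warping transports labels without inventing classes", {
  m <- toy_heart_mask()
  u <- array(0, dim = c(m$grid$shape, 3)); u[, , , 1] <- 1.2
  wm <- spatial_transform(m, u)
  expect_true(all(wm$labels %in% unique(as.vector(m$labels))))
})
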