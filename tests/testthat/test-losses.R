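test_that("mean-squared-error identities and brute-force oracle", {
  a <- array(runif(60), dim = c(5, 4, 3))
  expect_equal(mse_loss(a, a), 0)
  expect_equal(mse_loss(a, a + 0.5), 0.25, tolerance = 1e-12)
  set.seed(1)
  b <- array(runif(60), dim = c(5, 4, 3))
  loop <- 0
  for (i in seq_along(a)) loop <- loop + (a[i] - b[i])^2
  expect_equal(mse_loss(a, b), loop / length(a), tolerance = 1e-10)
})

test_that("multi-class Dice loss: identities, empty classes, toy-grid count", {
  m <- one_hot_mask(toy_heart_mask())
  expect_equal(mdc_loss(m, m), -1)
  # all-background mask against itself: three empty classes still score 1
  d <- c(4, 4, 1)
  bg <- array(0, dim = c(d, 4)); bg[, , , 1] <- 1
  expect_equal(mdc_loss(bg, bg), -1)
  # hand-countable 4x4 toy grid: masks agree on 8 background pixels only;
  # class 1 (RV) is disjoint between the two masks, classes 2/3 absent
  la <- array(0L, dim = d); lb <- array(0L, dim = d)
  la[1:2, , 1] <- 0L; la[3, , 1] <- 1L; la[4, , 1] <- 0L
  lb[1:2, , 1] <- 0L; lb[3, , 1] <- 0L; lb[4, , 1] <- 1L
  ga <- volume_grid(d, c(1, 1, 1))
  A <- one_hot_mask(seg_mask(la, ga)); B <- one_hot_mask(seg_mask(lb, ga))
  # background: |A|=12, |B|=12, overlap 8 -> 16/24; RV: overlap 0 -> 0;
  # LVM and cavity empty in both -> 1 each
  expect_equal(mdc_loss(A, B), -(16 / 24 + 0 + 1 + 1) / 4, tolerance = 1e-12)
})

test_that("Dice loss is bounded, minimal only at perfect overlap, monotone", {
  set.seed(7)
  d <- c(6, 6, 2)
  vals <- replicate(20, {
    la <- array(sample(0:3, prod(d), replace = TRUE), dim = d)
    lb <- array(sample(0:3, prod(d), replace = TRUE), dim = d)
    g <- volume_grid(d, c(1, 1, 1))
    mdc_loss(one_hot_mask(seg_mask(la, g)), one_hot_mask(seg_mask(lb, g)))
  })
  expect_true(all(vals >= -1 & vals <= 0))
  # nested masks: growing the overlap never increases the loss
  g <- volume_grid(d, c(1, 1, 1))
  base <- array(0L, dim = d); base[2:5, 2:5, ] <- 2L
  ref <- one_hot_mask(seg_mask(base, g))
  prev <- 0
  for (k in 2:5) {
    cand <- array(0L, dim = d); cand[2:k, 2:5, ] <- 2L
    v <- mdc_loss(ref, one_hot_mask(seg_mask(cand, g)))
    expect_lte(v, prev + 1e-12)
    prev <- v
  }
})

test_that("cross-entropy: perfect, uniform and random-case loop oracle", {
  d <- c(4, 4, 1)
  oh <- one_hot_mask(seg_mask(array(sample(0:3, 16, TRUE), dim = d),
                              volume_grid(d, c(1, 1, 1))))
  expect_lte(cce_loss(oh, oh * (1 - 1e-9) + 1e-9 / 4), 1e-6)
  unif <- array(0.25, dim = c(d, 4))
  expect_equal(cce_loss(oh, unif), log(4), tolerance = 1e-12)
  set.seed(3)
  pr <- array(runif(64, 0.05, 1), dim = c(d, 4))
  pr <- pr / array(rep(apply(pr, 1:3, sum), 4), dim = dim(pr))
  loop <- 0
  ohm <- matrix(oh, ncol = 4); prm <- matrix(pr, ncol = 4)
  for (i in 1:16) loop <- loop - log(prm[i, which(ohm[i, ] == 1)])
  expect_equal(cce_loss(oh, pr), loop / 16, tolerance = 1e-8)
})

test_that("intensity loss: identity, constant offset, ground truth beats zero", {
  ph <- cached_phantom()
  v0 <- ph$sequence$frames[[1]]$values
  u0 <- array(0, dim = c(dim(v0), 3))
  expect_equal(intensity_loss(v0, v0, u0), 0)
  expect_equal(intensity_loss(v0, v0 + 0.2, u0), 0.2, tolerance = 1e-12)
  es <- ph$truth$es_index
  ves <- ph$sequence$frames[[es]]$values
  expect_lt(intensity_loss(v0, ves, ph$truth$fields[[es]]$u),
            intensity_loss(v0, ves, u0))
})

test_that("anatomical loss: identity masks, ground-truth ordering, CCE limit", {
  ph <- cached_phantom()
  m0 <- one_hot_mask(ph$masks[[1]])
  d <- dim(m0)[1:3]
  u0 <- array(0, dim = c(d, 3))
  expect_equal(anatomical_loss(m0, m0, u0, "MDC"), -1)
  es <- ph$truth$es_index
  mes <- one_hot_mask(ph$masks[[es]])
  expect_lt(anatomical_loss(m0, mes, ph$truth$fields[[es]]$u, "MDC"),
            anatomical_loss(m0, mes, u0, "MDC"))
  expect_lt(anatomical_loss(m0, m0, u0, "CCE"), 1e-6)
  expect_error(anatomical_loss(m0, m0, u0, "XX"))
})

test_that("smoothness loss: constants, linear-field oracle, homogeneity", {
  d <- c(8, 8, 4)
  dr <- c(1.25, 1.25, 7)
  u <- array(2.5, dim = c(d, 3))
  expect_equal(smoothness_loss(u, dr), 0)
  # u_x = g * x (voxel units): interior derivative g along x, scaled by dr_x
  gslope <- 0.3
  ul <- array(0, dim = c(d, 3))
  ul[, , , 1] <- array(rep((seq_len(d[1]) - 1) * gslope, d[2] * d[3]), dim = d)
  got <- smoothness_loss(ul, dr, reduce = "sum")
  # loop oracle over voxels and derivative directions
  oracle <- 0
  um <- matrix(ul, ncol = 3)
  for (j in 1:3) {
    dj <- cinestrain:::cpp_fd(um, d, j - 1L) * dr[j]
    oracle <- oracle + sum(dj^2)
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  # every interior voxel contributes (g * dr_x)^2
  expect_equal(smoothness_loss(ul, dr, reduce = "sum"),
               prod(d) * (gslope * dr[1])^2, tolerance = 1e-12)
  expect_equal(smoothness_loss(2 * ul, dr), 4 * smoothness_loss(ul, dr),
               tolerance = 1e-12)
})

test_that("combined motion loss decomposes and matches manual assembly", {
  ph <- cached_phantom()
  es <- ph$truth$es_index
  v0 <- ph$sequence$frames[[1]]$values
  vt <- ph$sequence$frames[[es]]$values
  m0 <- one_hot_mask(ph$masks[[1]]); mt <- one_hot_mask(ph$masks[[es]])
  u <- ph$truth$fields[[es]]$u
  dr <- ph$params$grid$spacing
  expect_equal(as.numeric(carmen_total_loss(v0, vt, m0, mt, u,
                                            loss_weights(0, 0, 0), dr)), 0)
  w100 <- carmen_total_loss(v0, vt, m0, mt, u, loss_weights(1, 0, 0), dr)
  expect_equal(as.numeric(w100), intensity_loss(v0, vt, u), tolerance = 1e-12)
  wdef <- carmen_total_loss(v0, vt, m0, mt, u, loss_weights(), dr)
  manual <- 0.01 * intensity_loss(v0, vt, u) +
    0.5 * anatomical_loss(m0, mt, u, "MDC") +
    0.1 * smoothness_loss(u, dr)
  expect_equal(as.numeric(wdef), manual, tolerance = 1e-10)
})

test_that("loss gradients with respect to the field match finite differences", {
  set.seed(10)
  d <- c(6, 6, 3)
  v0 <- array(runif(prod(d)), dim = d)
  vt <- array(runif(prod(d)), dim = d)
  lab0 <- array(sample(0:3, prod(d), TRUE), dim = d)
  labt <- array(sample(0:3, prod(d), TRUE), dim = d)
  g <- volume_grid(d, c(1.25, 1.25, 7))
  m0 <- one_hot_mask(seg_mask(lab0, g)); mt <- one_hot_mask(seg_mask(labt, g))
  u <- array(rnorm(prod(d) * 3, sd = 0.3), dim = c(d, 3))
  w <- loss_weights(0.3, 0.5, 0.2)
  gr <- cinestrain:::carmen_total_grad(v0, vt, m0, mt, u, w, g$spacing)
  idx <- sample(length(u), 25)
  for (i in idx) {
    up <- u; up[i] <- up[i] + 1e-6
    um <- u; um[i] <- um[i] - 1e-6
    fp <- as.numeric(carmen_total_loss(v0, vt, m0, mt, up, w, g$spacing))
    fm <- as.numeric(carmen_total_loss(v0, vt, m0, mt, um, w, g$spacing))
    fd <- (fp - fm) / 2e-6
    expect_lt(abs(gr$gu[i] - fd), 1e-6 + 1e-3 * abs(fd))
  }
})
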