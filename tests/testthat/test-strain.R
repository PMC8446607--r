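test_that("displacement gradient: constants, exact linear fields, loop oracle", {
  g <- volume_grid(c(8, 8, 4), c(1.25, 1.25, 7))
  u <- disp_field(array(1.7, dim = c(g$shape, 3)), g)
  expect_true(all(displacement_gradient(u) == 0))
  # physical displacement u_phys = A x for a constant matrix A
  A <- matrix(c(0.1, 0.02, 0, -0.03, 0.05, 0.01, 0, 0.04, -0.02), 3, 3,
              byrow = TRUE)
  co <- list(x = (seq_len(8) - 1) * 1.25, y = (seq_len(8) - 1) * 1.25,
             z = (seq_len(4) - 1) * 7)
  ua <- array(0, dim = c(g$shape, 3))
  for (i in 1:3) {
    phys <- outer(outer(A[i, 1] * co$x, A[i, 2] * co$y, "+"),
                  A[i, 3] * co$z, "+")
    ua[, , , i] <- phys / g$spacing[i]  # back to voxel units
  }
  G <- displacement_gradient(disp_field(ua, g))
  for (i in 1:3) for (j in 1:3)
    expect_equal(max(abs(G[, , , i, j] - A[i, j])), 0, tolerance = 1e-12)
  # random smooth field vs a dense finite-difference loop oracle (one entry)
  set.seed(6)
  ur <- array(rnorm(prod(g$shape) * 3), dim = c(g$shape, 3))
  Gr <- displacement_gradient(disp_field(ur, g))
  # loop-oracle check at a strictly interior voxel: d(u_x)/dy
  fd <- (ur[4, 6, 2, 1] - ur[4, 4, 2, 1]) * g$spacing[1] / (2 * g$spacing[2])
  expect_equal(Gr[4, 5, 2, 1, 2], fd, tolerance = 1e-12)
  expect_error(displacement_gradient(
    disp_field(array(0, dim = c(2, 2, 2, 3)), volume_grid(c(2, 2, 2), c(1, 1, 1)))),
    "central")
})

test_that("Green-Lagrange tensor: zero, finite-rotation invariance, scaling", {
  g <- volume_grid(c(10, 10, 4), c(1, 1, 2))
  zero <- array(0, dim = c(g$shape, 3, 3))
  expect_true(all(green_lagrange(zero) == 0))
  # rigid rotation by 30 degrees about z: u_phys = R x - x
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  co <- expand.grid(x = (0:9), y = (0:9) , z = (0:3) * 2)
  u <- array(0, dim = c(g$shape, 3))
  for (i in 1:3) {
    phys <- as.matrix(co) %*% (R[i, ] - diag(3)[i, ])
    u[, , , i] <- array(phys, dim = g$shape) / g$spacing[i]
  }
  E <- green_lagrange(displacement_gradient(disp_field(u, g)))
  interior <- E[2:9, 2:9, 2:3, , ]
  expect_lt(max(abs(interior)), 1e-8)
  # isotropic scaling s = 1.2: E = (s^2-1)/2 I = 0.22 I
  s <- 1.2
  us <- array(0, dim = c(g$shape, 3))
  for (i in 1:3) {
    phys <- (s - 1) * as.matrix(co)[, i]
    us[, , , i] <- array(phys, dim = g$shape) / g$spacing[i]
  }
  Es <- green_lagrange(displacement_gradient(disp_field(us, g)))
  for (i in 1:3) for (j in 1:3) {
    want <- if (i == j) (s^2 - 1) / 2 else 0
    expect_equal(max(abs(Es[2:9, 2:9, 2:3, i, j] - want)), 0,
                 tolerance = 1e-10)
  }
})

test_that("cardiac coordinate system: centre, septal angle, orthogonality", {
  m <- toy_heart_mask()
  cs <- define_cardiac_cs(m)
  expect_equal(cs$centers[1, ], c(15.5, 15.5), tolerance = 1e-9)
  # RV blob sits at -x from the centre: septal angle pi (180 degrees)
  expect_equal(abs(cs$septal_angle[1]), pi, tolerance = 0.05)
  sel <- !is.na(cs$rx)
  cx <- -cs$ry; cy <- cs$rx
  dots <- cs$rx[sel] * cx[sel] + cs$ry[sel] * cy[sel]
  expect_lt(max(abs(dots)), 1e-12)
  norms <- cs$rx[sel]^2 + cs$ry[sel]^2
  expect_equal(max(abs(norms - 1)), 0, tolerance = 1e-12)
  expect_error(define_cardiac_cs(seg_mask(array(0L, dim = c(4, 4, 2)),
                                          volume_grid(c(4, 4, 2), c(1, 1, 1)))),
               "myocardium")
})

test_that("cylindrical projection: isotropy, phantom oracle, single-voxel shear", {
  m <- toy_heart_mask()
  g <- m$grid
  cs <- define_cardiac_cs(m)
  # isotropic in-plane tensor: E_rr == E_cc everywhere
  E <- array(0, dim = c(g$shape, 3, 3))
  E[, , , 1, 1] <- 0.07; E[, , , 2, 2] <- 0.07
  cyl <- cylindrical_project(E, cs)
  sel <- !is.na(cyl$E_rr)
  expect_equal(cyl$E_rr[sel], cyl$E_cc[sel], tolerance = 1e-12)
  # pure z-shear u_x = alpha * z: no in-plane shear, E_rz/E_cz split by angle
  alpha <- 0.2
  Ez <- array(0, dim = c(g$shape, 3, 3))
  Ez[, , , 1, 3] <- alpha / 2; Ez[, , , 3, 1] <- alpha / 2
  Ez[, , , 3, 3] <- alpha^2 / 2
  cz <- cylindrical_project(Ez, cs)
  expect_lt(max(abs(cz$E_rc[sel])), 1e-12)
  # hand computation at a voxel straight out along +x from the centre of an
  # odd-sized grid: r = (1,0), c = (0,1) -> E_rz = alpha/2, E_cz = 0
  m33 <- toy_heart_mask(shape = c(33, 33, 4))
  cs33 <- define_cardiac_cs(m33)
  E33 <- array(0, dim = c(m33$grid$shape, 3, 3))
  E33[, , , 1, 3] <- alpha / 2; E33[, , , 3, 1] <- alpha / 2
  E33[, , , 3, 3] <- alpha^2 / 2
  c33 <- cylindrical_project(E33, cs33)
  expect_equal(c33$E_rz[27, 17, 1], alpha / 2, tolerance = 1e-9)
  expect_equal(c33$E_cz[27, 17, 1], 0, tolerance = 1e-9)
})

test_that("global strain averages the masked field in percent", {
  m <- toy_heart_mask()
  comp <- array(0.1, dim = m$grid$shape)
  expect_equal(global_strain(comp, m), 10)
  lvm <- which(m$labels == 2L)
  half <- comp
  half[lvm[seq(1, length(lvm), by = 2)]] <- 0.2
  half[lvm[seq(2, length(lvm), by = 2)]] <- 0.0
  # equal halves at 0.2 and 0.0 average to 10%
  expect_equal(global_strain(half, m),
               mean(half[m$labels == 2L]) * 100, tolerance = 1e-12)
  set.seed(8)
  rnd <- array(rnorm(prod(m$grid$shape)), dim = m$grid$shape)
  loop <- mean(rnd[m$labels == 2L])
  expect_equal(global_strain(rnd, m), loop * 100, tolerance = 1e-12)
  expect_error(global_strain(comp, seg_mask(array(0L, dim = m$grid$shape),
                                            m$grid)), "empty")
})

test_that("millisecond interpolation and strain rate contracts", {
  # linear ramp 0 -> 0.2 over 200 ms: SR = 1.0 1/s on the interior
  cv <- interpolate_and_rate(c(0, 0.1, 0.2), c(0, 100, 200))
  expect_equal(nrow(cv), 201L)
  expect_true(all(abs(cv$sr[2:200] - 1.0) < 1e-9))
  cc <- interpolate_and_rate(c(0.3, 0.3, 0.3, 0.3), c(0, 50, 100, 150))
  expect_true(all(cc$sr == 0))
  # sinusoid A sin(2 pi t / T): peak |SR| = 2 pi A / T within 1%
  A <- 0.15; Tp <- 800
  tt <- seq(0, Tp, by = 10)
  cs_ <- interpolate_and_rate(A * sin(2 * pi * tt / Tp), tt)
  expect_equal(max(abs(cs_$sr)), 2 * pi * A / Tp * 1000, tolerance = 0.01)
  expect_error(interpolate_and_rate(c(0, 1), c(0, 10)), "3 frames")
})

test_that("scalar parameters: ESS at ES, symmetric triangle rates, signs", {
  tt <- seq(0, 800, by = 40)
  tri <- ifelse(tt <= 400, -0.18 * tt / 400, -0.18 * (800 - tt) / 400)
  cv <- interpolate_and_rate(tri, tt)
  pr <- extract_params(cv, es_time = 400)
  expect_equal(pr$ESS, -18, tolerance = 1e-6)
  expect_equal(abs(pr$SRs), abs(pr$SRe), tolerance = 1e-6)
  expect_lt(pr$SRs, 0)  # falling limb during systole
  expect_gt(pr$SRe, 0)
  expect_error(extract_params(cv, 900), "range")
})

test_that("end-systole detection finds the minimum cavity volume", {
  ph <- cached_phantom()
  expect_equal(detect_es(ph$masks), ph$truth$es_index)
  m <- toy_heart_mask()
  expect_warning(es0 <- detect_es(list(m, m, m)), "constant")
  expect_equal(es0, 1L)
  empty <- seg_mask(array(0L, dim = m$grid$shape), m$grid)
  expect_error(detect_es(list(empty, empty)), "cavity")
})

test_that("polar map: uniform field, exact partition, per-sector oracle", {
  m <- toy_heart_mask(shape = c(32, 32, 6))
  cs <- define_cardiac_cs(m)
  unif <- array(0.05, dim = m$grid$shape)
  pm <- polar_map(unif, m, cs)
  expect_equal(nrow(pm), 16L)
  expect_true(all(abs(pm$value - 5) < 1e-9))
  expect_equal(sum(pm$n_voxels), sum(m$labels == 2L))
  expect_equal(unname(table(pm$ring)[c("basal", "mid", "apical")]),
               c(6L, 6L, 4L), ignore_attr = TRUE)
  # field depending only on the angle from the septum: sector means match a
  # direct masked average over the same sector definition
  d <- m$grid$shape
  X <- matrix(rep(seq_len(d[1]) - 1, times = d[2]), d[1])
  Y <- matrix(rep(seq_len(d[2]) - 1, each = d[1]), d[1])
  fld <- array(0, dim = d)
  for (z in seq_len(d[3])) {
    th <- atan2(Y - cs$centers[z, 2], X - cs$centers[z, 1])
    fld[, , z] <- cos(th - cs$septal_angle[z])
  }
  pm2 <- polar_map(fld, m, cs)
  # oracle for basal segment 1 on the basal slices (ring rule: slices 1-2)
  insertion <- cs$septal_angle[1] + pi / 2
  acc <- c()
  for (z in 1:2) {
    th <- atan2((Y - cs$centers[z, 2]) * m$grid$spacing[2],
                (X - cs$centers[z, 1]) * m$grid$spacing[1])
    alpha <- (th - insertion) %% (2 * pi)
    sel <- m$labels[, , z] == 2L & alpha < pi / 3
    acc <- c(acc, fld[, , z][sel])
  }
  expect_equal(pm2$value[1], mean(acc) * 100, tolerance = 1e-9)
  mnorv <- toy_heart_mask(rv = FALSE)
  expect_error(polar_map(unif, mnorv, define_cardiac_cs(mnorv)), "RV")
})

test_that("strain engine reproduces the phantom's closed-form wall strain", {
  ph <- cached_phantom_full()   # 128 x 128 x 16 at 1.25 mm
  es <- ph$truth$es_index
  u <- ph$truth$fields[[es]]
  m0 <- ph$masks[[1]]
  E <- green_lagrange(displacement_gradient(u))
  cyl <- cylindrical_project(E, define_cardiac_cs(m0))
  lvm <- m0$labels == 2L
  co <- cinestrain:::phantom_coords(ph$params)
  Rarr <- array(rep(co$R, ph$params$grid$shape[3]), dim = ph$params$grid$shape)
  rads <- pmin(pmax(Rarr[lvm], ph$params$endo_radius_ed),
               ph$params$epi_radius_ed)
  an <- analytic_strain(ph$params, ph$truth$times[es], rads)
  expect_lt(abs(mean(cyl$E_rr[lvm], na.rm = TRUE) - mean(an$E_rr)), 0.01)
  expect_lt(abs(mean(cyl$E_cc[lvm], na.rm = TRUE) - mean(an$E_cc)), 0.01)
  # incompressibility of the engine output, wall-averaged
  wi <- wall_interior(m0)
  inc <- (1 + 2 * cyl$E_rr[wi]) * (1 + 2 * cyl$E_cc[wi])
  expect_lt(abs(mean(inc, na.rm = TRUE) - 1), 0.02)
})
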