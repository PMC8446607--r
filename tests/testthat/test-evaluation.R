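test_that("Dice: identity, closed form, set-arithmetic oracle", {
  m <- toy_heart_mask()
  expect_equal(dice(m, m, 2L), 1)
  g <- volume_grid(c(20, 20, 1), c(1, 1, 1))
  a <- array(0L, dim = g$shape); a[1:10, 1:10, 1] <- 2L      # 100 voxels
  b <- array(0L, dim = g$shape); b[6:15, 1:10, 1] <- 2L      # overlap 50
  expect_equal(dice(seg_mask(a, g), seg_mask(b, g), 2L), 0.5)
  set.seed(12)
  ra <- seg_mask(array(sample(0:3, 400, TRUE), dim = g$shape), g)
  rb <- seg_mask(array(sample(0:3, 400, TRUE), dim = g$shape), g)
  A <- which(ra$labels == 1L); B <- which(rb$labels == 1L)
  expect_equal(dice(ra, rb, 1L),
               2 * length(intersect(A, B)) / (length(A) + length(B)))
  expect_equal(dice(ra, rb, 1L), dice(rb, ra, 1L))
})

test_that("Hausdorff: identity, two points, all-pairs loop oracle, symmetry", {
  m <- toy_heart_mask()
  expect_equal(hausdorff(m, m, 2L), 0)
  g <- volume_grid(c(16, 16, 1), c(1.25, 1.25, 1))
  a <- array(0L, dim = g$shape); a[4, 8, 1] <- 2L
  b <- array(0L, dim = g$shape); b[7, 8, 1] <- 2L
  expect_equal(hausdorff(seg_mask(a, g), seg_mask(b, g), 2L), 3.75)
  set.seed(13)
  ra <- array(0L, dim = g$shape); ra[3:6, 3:7, 1] <- 2L
  rb <- array(0L, dim = g$shape); rb[8:11, 9:12, 1] <- 2L
  ma <- seg_mask(ra, g); mb <- seg_mask(rb, g)
  # brute force over all label voxels (boundary and interior agree here)
  pa <- which(ra == 2L, arr.ind = TRUE)[, 1:2] * 1.25
  pb <- which(rb == 2L, arr.ind = TRUE)[, 1:2] * 1.25
  dmat <- as.matrix(dist(rbind(pa, pb)))[seq_len(nrow(pa)),
                                         nrow(pa) + seq_len(nrow(pb))]
  oracle <- max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
  expect_equal(hausdorff(ma, mb, 2L), oracle)
  expect_equal(hausdorff(ma, mb, 2L), hausdorff(mb, ma, 2L))
  empty <- seg_mask(array(0L, dim = g$shape), g)
  expect_error(hausdorff(ma, empty, 2L), "empty")
})

test_that("volumetrics: EF closed form, density convention, phantom geometry", {
  g <- volume_grid(c(20, 20, 10), c(5, 5, 10))  # 0.25 mL voxels
  ed <- array(0L, dim = g$shape); ed[1:10, 1:10, 1:6] <- 3L  # 600 vox = 150 mL
  es <- array(0L, dim = g$shape); es[1:10, 1:10, 1:6] <- 0L
  es[1:8, 1:10, 1:3] <- 3L                                   # 240 vox = 60 mL
  ed[11:14, 1:10, 1:10] <- 2L                                # 400 vox = 100 mL
  vv <- volumetrics(seg_mask(ed, g), seg_mask(es, g))
  expect_equal(vv$EDV_ml, 150)
  expect_equal(vv$ESV_ml, 60)
  expect_equal(vv$EF_pct, 60)
  expect_equal(vv$LVM_g, 105)
  # phantom: EF from voxel counts close to the analytic annulus geometry
  ph <- cached_phantom()
  es_i <- ph$truth$es_index
  v <- volumetrics(ph$masks[[1]], ph$masks[[es_i]])
  s <- ph$truth$activation[es_i]
  ef_true <- (1 - (1 - ph$params$contraction_fraction * s)^2) * 100
  expect_lt(abs(v$EF_pct - ef_true), 2)
})

test_that("end-point error and landmark deformation", {
  expect_equal(epe(c(0, 0), c(3, 4)), 5)
  expect_equal(epe(c(1.2, -3), c(1.2, -3)), 0)
  set.seed(14)
  for (i in 1:5) {
    p <- rnorm(2); q <- rnorm(2)
    expect_equal(epe(p, q), sqrt(sum((p - q)^2)))
  }
  g <- volume_grid(c(16, 16, 4), c(1.25, 1.25, 8))
  u0 <- disp_field(array(0, dim = c(g$shape, 3)), g)
  lm <- data.frame(x_mm = c(5, 10), y_mm = c(6, 3), z_slice = c(1, 2))
  expect_equal(deform_landmarks(lm, u0)[, 1:2], lm[, 1:2])
  uc <- array(0, dim = c(g$shape, 3)); uc[, , , 1] <- 2
  d2 <- deform_landmarks(lm, disp_field(uc, g))
  expect_equal(d2$x_mm, lm$x_mm + 2.5)
  expect_equal(d2$y_mm, lm$y_mm)
  out <- data.frame(x_mm = 100, y_mm = 0, z_slice = 1)
  expect_error(deform_landmarks(out, u0), "outside")
})

test_that("average end-point error equals the flat-loop mean over observers", {
  g <- volume_grid(c(16, 16, 4), c(1, 1, 8))
  u0 <- disp_field(array(0, dim = c(g$shape, 3)), g)
  p0 <- data.frame(x_mm = c(5, 7), y_mm = c(5, 9), z_slice = c(1, 1))
  mk <- function(dx) data.frame(x_mm = p0$x_mm + dx, y_mm = p0$y_mm,
                                z_slice = p0$z_slice)
  # observers displaced by 2 and 4 mm: AEPE = 3
  tracks <- list(list(p0 = p0, observers = list(mk(2), mk(4))))
  expect_equal(as.numeric(aepe(tracks, list(u0))), 3)
  # identity: deformed equals manual for all
  tracks0 <- list(list(p0 = p0, observers = list(mk(0), mk(0))),
                  list(p0 = p0, observers = list(mk(0), mk(0))))
  expect_equal(as.numeric(aepe(tracks0, list(u0, u0))), 0)
  set.seed(15)
  tr <- list(); flat <- c()
  for (i in 1:3) {
    o1 <- mk(rnorm(1)); o2 <- mk(rnorm(1))
    tr[[i]] <- list(p0 = p0, observers = list(o1, o2))
    flat <- c(flat, mean(sqrt((o1$x_mm - p0$x_mm)^2 + (o1$y_mm - p0$y_mm)^2)),
              mean(sqrt((o2$x_mm - p0$x_mm)^2 + (o2$y_mm - p0$y_mm)^2)))
  }
  expect_equal(as.numeric(aepe(tr, list(u0, u0, u0))), mean(flat))
})

test_that("Bland-Altman bias and precision", {
  x <- c(1, 2, 3, 4)
  expect_equal(bland_altman(x, x)$bias, 0)
  expect_equal(bland_altman(x, x)$precision, 0)
  ba <- bland_altman(c(2, 4), c(1, 1))  # differences (1, 3)
  expect_equal(ba$bias, 2)
  expect_equal(ba$precision, sqrt(2))
  set.seed(16)
  a <- rnorm(20); b <- rnorm(20)
  ba2 <- bland_altman(a, b)
  expect_equal(ba2$bias, mean(a - b))
  expect_equal(ba2$precision, sd(a - b))
  # adding a constant to x shifts the bias by exactly that constant
  ba3 <- bland_altman(a + 1.7, b)
  expect_equal(ba3$bias, ba2$bias + 1.7)
  expect_equal(ba3$precision, ba2$precision)
})

test_that("ICC(A,1): worked-table oracle, agreement extremes, shift invariance", {
  tab <- matrix(c(10.0, 12.5, 9.2, 14.1, 11.3,
                  10.8, 12.1, 9.9, 13.5, 11.9), ncol = 2)
  r <- icc_a1(tab)
  # hand-computed two-way ANOVA mean squares for this table
  df <- data.frame(y = c(tab), subj = factor(rep(1:5, 2)),
                   rater = factor(rep(1:2, each = 5)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  want <- (ms[1] - ms[3]) / (ms[1] + ms[3] + (2 / 5) * (ms[2] - ms[3]))
  expect_equal(r$icc, want, tolerance = 1e-10)
  # independent reference value for this table (single-rating absolute
  # agreement, two-way model): 0.928912, CI [0.55, 0.99]
  expect_equal(r$icc, 0.928912, tolerance = 1e-6)
  expect_equal(unname(r$ci), c(0.5475, 0.9922), tolerance = 1e-3)
  # perfect repeat with between-subject variance
  expect_equal(icc_a1(cbind(1:5, 1:5))$icc, 1)
  # no agreement signal: |ICC| stays small across seeds
  set.seed(17)
  vals <- replicate(20, icc_a1(cbind(rnorm(10), rnorm(10)))$icc)
  expect_lt(median(abs(vals)), 0.3)
  # invariance to a common additive constant
  expect_equal(icc_a1(tab + 100)$icc, r$icc, tolerance = 1e-10)
  expect_warning(icc_a1(matrix(1, 4, 2)), "degenerate")
})

test_that("relative change takes the first acquisition as reference", {
  r <- rc_arc(c(10, 10), c(10, 10))
  expect_equal(r$RC, c(0, 0)); expect_equal(r$aRC, c(0, 0))
  r2 <- rc_arc(10, 11)
  expect_equal(r2$RC, 10); expect_equal(r2$aRC, 10)
  # mixed signs: mean RC ~ 0 while mean aRC is large
  r3 <- rc_arc(c(10, 10), c(11, 9))
  expect_equal(r3$RC_mean, 0)
  expect_equal(r3$aRC_mean, 10)
  expect_error(rc_arc(c(0, 1), c(1, 1)), "zero")
})
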