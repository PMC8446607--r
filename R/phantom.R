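# Analytic left-ventricle phantom: an annular myocardium that contracts
# incompressibly (per-slice area preserving) and twists about the long axis,
# with closed-form displacement and strain. It serves both as a training
# substrate and as ground truth for the motion/strain pipeline.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the analytic LV phantom
#'
#' @param endo_radius_ed,epi_radius_ed endo/epicardial radii at end-diastole (mm).
#' @param rv_offset in-plane offset (mm) of the RV blood-pool blob centre from
#'   the LV axis; its direction defines the septum.
#' @param rv_radius radius of the RV blob (mm).
#' @param contraction_fraction peak fractional reduction of the endocardial
#'   radius (unitless, in [0, 0.4)).
#' @param twist_per_slice peak rotation per slice (degrees).
#' @param n_frames frames over one cycle.
#' @param cycle_ms cycle duration (ms).
#' @param es_fraction fraction of the cycle at which activation peaks.
#' @param noise_sd additive Gaussian image noise (intensity units in [0,1]).
#' @param texture_amp amplitude of the smooth material texture.
#' @param center_mm in-plane LV-axis position (mm) relative to the grid centre.
#' @param grid a `volume_grid` (default 128 x 128 x 16 at 1.25 mm in-plane).
#' @param seed RNG seed controlling texture and noise.
#' @param banding if `TRUE`, overlay a dark horizontal stripe (artifact test).
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(endo_radius_ed = 25, epi_radius_ed = 35,
                           rv_offset = c(-42, 0), rv_radius = 14,
                           contraction_fraction = 0.2, twist_per_slice = 1.5,
                           n_frames = 25L, cycle_ms = 1000, es_fraction = 0.4,
                           noise_sd = 0.02, texture_amp = 0.15,
                           center_mm = c(0, 0),
                           grid = volume_grid(c(128, 128, 16), c(1.25, 1.25, 8)),
                           seed = 1L, banding = FALSE) {
  stopifnot(endo_radius_ed > 0, epi_radius_ed > endo_radius_ed,
            contraction_fraction >= 0, contraction_fraction < 1,
            n_frames >= 2, es_fraction > 0, es_fraction < 1)
  structure(list(endo_radius_ed = endo_radius_ed, epi_radius_ed = epi_radius_ed,
                 rv_offset = rv_offset, rv_radius = rv_radius,
                 contraction_fraction = contraction_fraction,
                 twist_per_slice = twist_per_slice, n_frames = as.integer(n_frames),
                 cycle_ms = cycle_ms, es_fraction = es_fraction,
                 noise_sd = noise_sd, texture_amp = texture_amp,
                 center_mm = center_mm, grid = grid, seed = as.integer(seed),
                 banding = banding),
            class = "phantom_params")
}

#' Activation waveform of the phantom
#'
#' Smooth sin^2 pulse with a piecewise time-warp so the single peak (s = 1)
#' lands at `es_fraction * cycle_ms`; s(0) = s(cycle) = 0.
#' @param t time in ms (vectorised).
#' @param params a `phantom_params`.
#' @return Activation values in [0, 1].
#' @export
activation <- function(t, params) {
  Tc <- params$cycle_ms; tes <- params$es_fraction * Tc
  if (any(t < 0 | t > Tc)) stop("time outside the cardiac cycle")
  ts <- ifelse(t <= tes, t / (2 * tes), 0.5 + (t - tes) / (2 * (Tc - tes)))
  sin(pi * ts)^2
}

# forward radial map r -> r'(r) at activation s; all radii in mm
radial_map <- function(r, s, p, decay = 8) {
  re0 <- p$endo_radius_ed; rp0 <- p$epi_radius_ed
  ret <- re0 * (1 - p$contraction_fraction * s)
  inner <- r <= re0
  wall <- r > re0 & r <= rp0
  outer <- r > rp0
  out <- numeric(length(r))
  out[inner] <- r[inner] * ret / re0
  if (any(wall)) {
    sq <- r[wall]^2 - re0^2 + ret^2
    if (any(sq < 0)) stop("parameters yield a negative squared radius")
    out[wall] <- sqrt(sq)
  }
  if (any(outer)) {
    rpt <- sqrt(rp0^2 - re0^2 + ret^2)
    out[outer] <- r[outer] + (rpt - rp0) * exp(-(r[outer] - rp0) / decay)
  }
  out
}

# twist angle (radians) applied at material radius r, slice z (0-based), time t
twist_angle <- function(r, z_slice, s, p, decay = 8) {
  beta <- p$twist_per_slice * pi / 180 * z_slice * s
  taper <- ifelse(r <= p$epi_radius_ed, 1, exp(-(r - p$epi_radius_ed) / decay))
  beta * taper
}

# numeric inverse of the radial map via a dense monotone table
radial_inverse_fun <- function(s, p, r_max) {
  rg <- seq(0, r_max, by = 0.05)
  rp <- radial_map(rg, s, p)
  function(q) approx(rp, rg, xout = pmin(pmax(q, min(rp)), max(rp)))$y
}

# in-plane mm coordinates of every voxel centre relative to the LV axis
phantom_coords <- function(p) {
  g <- p$grid
  cx <- (g$shape[1] - 1) / 2 + p$center_mm[1] / g$spacing[1]
  cy <- (g$shape[2] - 1) / 2 + p$center_mm[2] / g$spacing[2]
  xs <- ((seq_len(g$shape[1]) - 1) - cx) * g$spacing[1]
  ys <- ((seq_len(g$shape[2]) - 1) - cy) * g$spacing[2]
  n_xy <- g$shape[1] * g$shape[2]
  X <- matrix(rep(xs, times = g$shape[2]), nrow = g$shape[1])
  Y <- matrix(rep(ys, each = g$shape[1]), nrow = g$shape[1])
  list(X = X, Y = Y, R = sqrt(X^2 + Y^2), TH = atan2(Y, X),
       center_vox = c(cx, cy), n_xy = n_xy)
}

#' Analytic phantom motion at a time point
#'
#' Evaluates the forward map phi_t on every end-diastolic voxel centre and
#' returns the ground-truth displacement field (voxel units).
#' @param params a `phantom_params`.
#' @param t time in ms.
#' @return A [disp_field()] (`u_gt`), with the activation value in
#'   attribute `s`.
#' @export
analytic_motion <- function(params, t) {
  s <- activation(t, params)
  g <- params$grid
  co <- phantom_coords(params)
  ug <- array(0, dim = c(g$shape, 3))
  for (z in seq_len(g$shape[3])) {
    rp <- radial_map(as.vector(co$R), s, params)
    beta <- twist_angle(as.vector(co$R), z - 1, s, params)
    thp <- as.vector(co$TH) + beta
    newx <- rp * cos(thp); newy <- rp * sin(thp)
    ug[, , z, 1] <- matrix((newx - as.vector(co$X)) / g$spacing[1], g$shape[1])
    ug[, , z, 2] <- matrix((newy - as.vector(co$Y)) / g$spacing[2], g$shape[1])
  }
  out <- disp_field(ug, g)
  attr(out, "s") <- s
  out
}

#' Closed-form radial/circumferential strain of the phantom
#'
#' For the incompressible (per-slice area-preserving) wall map,
#' `E_cc = ((r'/r)^2 - 1)/2` and `E_rr = ((r/r')^2 - 1)/2`; twist contributes
#' only shear in the aligned cylindrical frame, leaving these diagonals
#' unchanged.
#' @param params a `phantom_params`.
#' @param t time in ms.
#' @param r end-diastolic radius (mm), inside the wall (vectorised).
#' @return List with `E_rr` and `E_cc` at `r`.
#' @export
analytic_strain <- function(params, t, r) {
  if (any(r < params$endo_radius_ed | r > params$epi_radius_ed))
    stop("radius outside the end-diastolic wall")
  s <- activation(t, params)
  rp <- radial_map(r, s, params)
  list(E_rr = ((r / rp)^2 - 1) / 2, E_cc = ((rp / r)^2 - 1) / 2)
}

# analytic wall-averaged strain: area-weighted integral over the ED annulus
analytic_global_strain <- function(params, t) {
  rs <- seq(params$endo_radius_ed, params$epi_radius_ed, length.out = 400)
  st <- analytic_strain(params, t, rs)
  w <- rs / sum(rs)  # annulus area element ~ r dr
  list(E_rr = sum(st$E_rr * w), E_cc = sum(st$E_cc * w))
}

phantom_ed_labels <- function(params) {
  g <- params$grid; co <- phantom_coords(params)
  lab2d <- matrix(0L, g$shape[1], g$shape[2])
  lab2d[co$R <= params$epi_radius_ed] <- 2L
  lab2d[co$R <= params$endo_radius_ed] <- 3L
  rvd <- sqrt((co$X - params$rv_offset[1])^2 + (co$Y - params$rv_offset[2])^2)
  lab2d[rvd <= params$rv_radius & lab2d == 0L] <- 1L
  array(rep(lab2d, g$shape[3]), dim = g$shape)
}

# continuous ED image model evaluated at material points (mm, LV-axis frame)
phantom_v0_fun <- function(params, texture) {
  p <- params
  function(x, y, z_slice) {
    r <- sqrt(x^2 + y^2)
    v <- rep(0.10, length(x))
    v[r <= p$epi_radius_ed] <- 0.40
    v[r <= p$endo_radius_ed] <- 0.85
    rvd <- sqrt((x - p$rv_offset[1])^2 + (y - p$rv_offset[2])^2)
    v[rvd <= p$rv_radius & r > p$epi_radius_ed] <- 0.70
    # smooth material texture sampled trilinearly from a coarse seeded field
    g <- p$grid
    cx <- (g$shape[1] - 1) / 2 + p$center_mm[1] / g$spacing[1]
    cy <- (g$shape[2] - 1) / 2 + p$center_mm[2] / g$spacing[2]
    tx <- (x / g$spacing[1] + cx) / (g$shape[1] - 1) * (dim(texture)[1] - 1)
    ty <- (y / g$spacing[2] + cy) / (g$shape[2] - 1) * (dim(texture)[2] - 1)
    tz <- z_slice / max(g$shape[3] - 1, 1) * (dim(texture)[3] - 1)
    tv <- cpp_sample_points(as_mat(texture), dim(texture),
                            cbind(tx, ty, tz), 0L)
    v + p$texture_amp * as.vector(tv)
  }
}

#' Render a phantom cine sequence with ground truth
#'
#' Frame t is rendered as `V_t(x) = V_0(phi_t^{-1}(x))` (plus per-frame noise)
#' so that the motion-estimation convention `V_0(v) = V_t(v + u_gt(v))` holds;
#' masks are advected the same way with nearest-neighbour label transport.
#' @param params a `phantom_params`.
#' @return List with `sequence` (a [cine_sequence()]), `masks` (list of
#'   [seg_mask()]), `truth` (displacement fields, analytic wall-averaged
#'   strain curves, landmarks, activation), and `params`.
#' @export
render_sequence <- function(params) {
  p <- params; g <- p$grid
  with_seed(p$seed, {
    texture <- array(rnorm(12 * 12 * 4), dim = c(12, 12, 4))
    noise <- lapply(seq_len(p$n_frames), function(i)
      if (p$noise_sd > 0) array(rnorm(prod(g$shape), sd = p$noise_sd), dim = g$shape)
      else array(0, dim = g$shape))
  })
  v0f <- phantom_v0_fun(p, texture)
  co <- phantom_coords(p)
  ed_labels <- phantom_ed_labels(p)
  times <- (seq_len(p$n_frames) - 1) * (p$cycle_ms / p$n_frames)
  r_max <- max(co$R) + 5
  frames <- vector("list", p$n_frames)
  masks <- vector("list", p$n_frames)
  fields <- vector("list", p$n_frames)
  svals <- activation(times, p)
  for (ti in seq_len(p$n_frames)) {
    s <- svals[ti]
    rinv <- radial_inverse_fun(s, p, r_max)
    vol <- array(0, dim = g$shape)
    lab <- array(0L, dim = g$shape)
    for (z in seq_len(g$shape[3])) {
      rq <- as.vector(co$R); thq <- as.vector(co$TH)
      rm <- rinv(rq)
      thm <- thq - twist_angle(rm, z - 1, s, p)
      mx <- rm * cos(thm); my <- rm * sin(thm)
      vol[, , z] <- matrix(v0f(mx, my, z - 1), g$shape[1])
      rmat <- matrix(rm, g$shape[1])
      l2 <- matrix(0L, g$shape[1], g$shape[2])
      l2[rmat <= p$epi_radius_ed] <- 2L
      l2[rmat <= p$endo_radius_ed] <- 3L
      rvd <- matrix(sqrt((mx - p$rv_offset[1])^2 + (my - p$rv_offset[2])^2),
                    g$shape[1])
      l2[rvd <= p$rv_radius & l2 == 0L] <- 1L
      lab[, , z] <- l2
    }
    vol <- vol + noise[[ti]]
    if (p$banding) {
      yb <- round(g$shape[2] * c(0.45, 0.55))
      vol[, yb[1]:yb[2], ] <- vol[, yb[1]:yb[2], ] * 0.6
    }
    frames[[ti]] <- cs_volume(pmin(pmax(vol, 0), 1), g)
    masks[[ti]] <- seg_mask(lab, g)
    fields[[ti]] <- analytic_motion(p, times[ti])
  }
  es_index <- which.min(abs(times - p$es_fraction * p$cycle_ms))
  seq <- cine_sequence(frames, times, es_index = es_index)
  # mid-wall landmark ring at ED (12 angles x 3 levels), LV-axis mm frame
  rmid <- (p$endo_radius_ed + p$epi_radius_ed) / 2
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  zl <- round(seq(2, g$shape[3] - 1, length.out = 3))
  lm <- do.call(rbind, lapply(zl, function(z)
    cbind(x_mm = rmid * cos(ang), y_mm = rmid * sin(ang), z_slice = z)))
  gl <- lapply(seq_len(p$n_frames), function(ti) {
    gsl <- analytic_global_strain(p, times[ti])
    c(E_rr = gsl$E_rr, E_cc = gsl$E_cc)
  })
  truth <- list(fields = fields, masks = masks,
                E_rr = vapply(gl, `[[`, 0, "E_rr"),
                E_cc = vapply(gl, `[[`, 0, "E_cc"),
                activation = svals, times = times,
                landmarks_ed = as.data.frame(lm), es_index = es_index)
  list(sequence = seq, masks = masks, truth = truth, params = p)
}

#' Advect phantom landmarks with the analytic map
#' @param params a `phantom_params`.
#' @param landmarks data.frame with `x_mm`, `y_mm`, `z_slice` (ED, LV-axis frame).
#' @param t time in ms.
#' @return data.frame of deformed in-plane positions (mm).
#' @export
advect_landmarks <- function(params, landmarks, t) {
  s <- activation(t, params)
  r <- sqrt(landmarks$x_mm^2 + landmarks$y_mm^2)
  th <- atan2(landmarks$y_mm, landmarks$x_mm)
  rp <- radial_map(r, s, params)
  thp <- th + twist_angle(r, landmarks$z_slice, s, params)
  data.frame(x_mm = rp * cos(thp), y_mm = rp * sin(thp),
             z_slice = landmarks$z_slice)
}
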