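# Desk-scale phantom study: a reduced-resolution training and evaluation
# protocol that exercises the whole workflow (centering, segmentation,
# motion, strain) on the analytic phantom with closed-form ground truth.
# Working grid 64 x 64 x 8 at 2.5 mm in-plane / 10 mm slices (half the
# resolution of the full 128 x 128 x 16 crop), 10 training + 5 held-out
# phantoms, 20 motion-training pairs (ED-ED and ED-ES per phantom).

#' Generate a corpus of varied phantoms
#'
#' Geometry, contraction, twist and position are drawn per phantom from
#' physiological ranges (endo radius 22-28 mm, wall to 33-38 mm, peak
#' endocardial contraction 15-25%, twist 1-2 degrees/slice) so trained
#' networks must generalize across anatomy.
#' @param n number of phantoms.
#' @param seed base seed; phantom i derives its own stream from it.
#' @param grid rendering grid (desk default 64 x 64 x 8 at 2.5/10 mm).
#' @param n_frames frames per cycle (5 places a frame exactly at peak
#'   activation for `es_fraction` 0.4).
#' @param center_jitter_mm in-plane LV-position jitter range.
#' @return List of rendered phantoms (see [render_sequence()]).
#' @export
phantom_corpus <- function(n, seed = 1L,
                           grid = volume_grid(c(64, 64, 8), c(2.5, 2.5, 10)),
                           n_frames = 5L, center_jitter_mm = 3) {
  lapply(seq_len(n), function(i) {
    s <- (seed %% 100000L) * 1000L + i
    pp <- with_seed(s, phantom_params(
      endo_radius_ed = runif(1, 22, 28),
      epi_radius_ed = runif(1, 33, 38),
      contraction_fraction = runif(1, 0.15, 0.25),
      twist_per_slice = runif(1, 1, 2),
      rv_offset = c(-runif(1, 40, 46), runif(1, -5, 5)),
      center_mm = runif(2, -center_jitter_mm, center_jitter_mm),
      n_frames = n_frames, grid = grid, seed = s))
    render_sequence(pp)
  })
}

carson_slices <- function(phantoms) {
  out <- list()
  for (ph in phantoms) {
    nz <- ph$params$grid$shape[3]
    zs <- unique(round(seq(1, nz, length.out = min(6, nz))))
    for (t in c(1L, ph$truth$es_index)) {
      for (z in zs) {
        out[[length(out) + 1]] <- list(
          image = ph$sequence$frames[[t]]$values[, , z],
          labels = ph$masks[[t]]$labels[, , z])
      }
    }
  }
  out
}

#' Train the desk-scale model stack on a phantom corpus
#'
#' Trains the motion network on the ED-ED/ED-ES pairs of the corpus and the
#' centering/segmentation networks on matching phantom renderings. Batch
#' sizes (5 motion, 80 otherwise) and Adam moments follow the full-scale
#' protocol; the desk-scale default step size is 2e-3 (see the methods
#' vignette for the rationale at this small step budget).
#' @param corpus list from [phantom_corpus()] (motion/segmentation substrate).
#' @param vcn_corpus corpus rendered on the workspace-analog grid for the
#'   centering network (built internally when `NULL`).
#' @param seed master training seed.
#' @param weights motion-loss weights ([loss_weights()]).
#' @param epochs named integer vector (carmen, carson, vcn).
#' @param learning_rate Adam step size for the motion network.
#' @param seg_learning_rate Adam step size for the segmentation and
#'   centering networks (fewer, larger batches: a larger step).
#' @param base_filters network width at full resolution.
#' @param verbose print per-epoch losses.
#' @return List with trained `carmen`, `carson`, `vcn` models and the
#'   `vcn_corpus` used.
#' @export
desk_study_train <- function(corpus, vcn_corpus = NULL, seed = 1L,
                             weights = loss_weights(),
                             epochs = c(carmen = 200L, carson = 50L, vcn = 80L),
                             learning_rate = 2e-3, seg_learning_rate = 5e-3,
                             base_filters = 6L, verbose = FALSE) {
  pairs <- unlist(lapply(corpus, function(ph)
    make_pairs(ph$sequence, ph$masks)), recursive = FALSE)
  nc <- network_config(kz = 1L, base_filters = base_filters, depth = 2L)
  cfg_carmen <- train_config(learning_rate = learning_rate, batch_size = 5L,
                             epochs = epochs[["carmen"]], seed = seed,
                             weights = weights)
  carmen <- train_network("carmen", pairs, cfg_carmen, nc, verbose = verbose)

  cfg_carson <- train_config(learning_rate = seg_learning_rate, batch_size = 80L,
                             epochs = epochs[["carson"]], seed = seed + 1L)
  carson <- train_network("carson", carson_slices(corpus), cfg_carson, nc,
                          verbose = verbose)

  # centering trains and infers on a half-resolution workspace (5 mm
  # in-plane): localization is a low-frequency task and the coarser grid
  # gives the small network whole-heart context
  vcn_grid <- volume_grid(c(64, 64, 8), c(5, 5, 10))
  if (is.null(vcn_corpus))
    vcn_corpus <- phantom_corpus(length(corpus), seed = seed + 500L,
                                 grid = vcn_grid, n_frames = 2L,
                                 center_jitter_mm = 12)
  vcn_data <- lapply(vcn_corpus, function(ph)
    list(volume = ph$sequence$frames[[1]], mask = ph$masks[[1]]))
  nc_vcn <- network_config(kz = 1L, base_filters = base_filters, depth = 3L)
  cfg_vcn <- train_config(learning_rate = seg_learning_rate, batch_size = 80L,
                          epochs = epochs[["vcn"]], seed = seed + 2L)
  vcn <- train_network("vcn", vcn_data, cfg_vcn, nc_vcn, verbose = verbose)
  vcn$input_grid <- vcn_grid
  list(carmen = carmen, carson = carson, vcn = vcn, vcn_corpus = vcn_corpus)
}

#' Evaluate a trained motion model against phantom ground truth
#'
#' For each held-out phantom: median in-wall end-point error of the ED-ES
#' motion estimate (voxel units), the identity-pair (ED-ED) median
#' displacement, and the end-systolic global strain bias (estimated minus
#' closed-form, strain points) for both components.
#' @param model trained `"carmen"` model.
#' @param phantoms held-out corpus.
#' @return data.frame, one row per phantom.
#' @export
desk_study_motion_eval <- function(model, phantoms) {
  rows <- lapply(phantoms, function(ph) {
    es <- ph$truth$es_index
    lvm <- ph$masks[[1]]$labels == 2L
    u <- carmen_forward(model, ph$sequence$frames[[1]],
                        ph$sequence$frames[[es]])
    du <- u$u - ph$truth$fields[[es]]$u
    epe_vox <- median(sqrt(du[, , , 1]^2 + du[, , , 2]^2 + du[, , , 3]^2)[lvm])
    u0 <- carmen_forward(model, ph$sequence$frames[[1]],
                         ph$sequence$frames[[1]])
    id_vox <- median(sqrt(u0$u[, , , 1]^2 + u0$u[, , , 2]^2 +
                            u0$u[, , , 3]^2)[lvm])
    E <- green_lagrange(displacement_gradient(u))
    cyl <- cylindrical_project(E, define_cardiac_cs(ph$masks[[1]]))
    co <- phantom_coords(ph$params)
    Rarr <- array(rep(co$R, ph$params$grid$shape[3]),
                  dim = ph$params$grid$shape)
    rads <- pmin(pmax(Rarr[lvm], ph$params$endo_radius_ed),
                 ph$params$epi_radius_ed)
    an <- analytic_strain(ph$params, ph$truth$times[es], rads)
    data.frame(
      epe_vox = epe_vox, id_vox = id_vox,
      ess_cc_bias = mean(cyl$E_cc[lvm], na.rm = TRUE) * 100 -
        mean(an$E_cc) * 100,
      ess_rr_bias = mean(cyl$E_rr[lvm], na.rm = TRUE) * 100 -
        mean(an$E_rr) * 100)
  })
  do.call(rbind, rows)
}

#' Evaluate segmentation and centering models on held-out phantoms
#' @param carson trained segmentation model.
#' @param vcn trained centering model.
#' @param phantoms held-out corpus on the segmentation grid.
#' @param vcn_phantoms held-out corpus on the workspace-analog grid.
#' @return List with per-phantom LVM Dice and centroid errors, the latter
#'   in voxels of the centering model's working grid.
#' @export
desk_study_seg_eval <- function(carson, vcn, phantoms, vcn_phantoms) {
  dices <- vapply(phantoms, function(ph) {
    pred <- carson_forward(carson, ph$sequence$frames[[1]])$mask
    dice(pred, ph$masks[[1]], 2L)
  }, 0)
  centroid_err <- vapply(vcn_phantoms, function(ph) {
    ctr <- vcn_forward(vcn, ph$sequence$frames[[1]])$center
    lvm <- which(ph$masks[[1]]$labels == 2L, arr.ind = TRUE)
    true_ctr <- colMeans(lvm) - 1
    sqrt(sum((ctr[1:2] - true_ctr[1:2])^2))
  }, 0)
  list(lvm_dice = dices, centroid_err_vox = centroid_err)
}
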