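# Trained desk-scale model stack, built once per test session and shared by
# the acceptance and pipeline tests. Seeds are fixed; training is the
# package's reduced-scale study protocol (see desk_study_train).

get_desk_stack <- function() {
  if (!is.null(.fixture_cache$stack)) return(.fixture_cache$stack)
  corpus <- phantom_corpus(10, seed = 42L)
  heldout <- phantom_corpus(5, seed = 973L)
  models <- desk_study_train(corpus, seed = 7L)
  heldout_vcn <- phantom_corpus(3, seed = 555L,
                                grid = volume_grid(c(64, 64, 8), c(5, 5, 10)),
                                n_frames = 2L, center_jitter_mm = 12)
  .fixture_cache$stack <- list(corpus = corpus, heldout = heldout,
                               models = models, heldout_vcn = heldout_vcn)
  .fixture_cache$stack
}

# motion model trained identically but without the anatomical term
get_ablation_model <- function() {
  if (!is.null(.fixture_cache$ablation)) return(.fixture_cache$ablation)
  stack <- get_desk_stack()
  pairs <- unlist(lapply(stack$corpus, function(ph)
    make_pairs(ph$sequence, ph$masks)), recursive = FALSE)
  nc <- network_config(kz = 1L, base_filters = 6L, depth = 2L)
  cfg <- train_config(learning_rate = 2e-3, batch_size = 5L, epochs = 200L,
                      seed = 7L, weights = loss_weights(lambda_a = 0))
  .fixture_cache$ablation <- train_network("carmen", pairs, cfg, nc)
  .fixture_cache$ablation
}

pooled_epe <- function(model, phantoms) {
  errs <- unlist(lapply(phantoms, function(ph) {
    es <- ph$truth$es_index
    u <- carmen_forward(model, ph$sequence$frames[[1]],
                        ph$sequence$frames[[es]])
    du <- u$u - ph$truth$fields[[es]]$u
    mag <- sqrt(du[, , , 1]^2 + du[, , , 2]^2 + du[, , , 3]^2)
    mag[ph$masks[[1]]$labels == 2L]
  }))
  median(errs)
}
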