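# Shared fixtures: all built in code at test time.

tiny_grid <- function(shape = c(8, 8, 4), spacing = c(1.25, 1.25, 7)) {
  volume_grid(shape, spacing)
}

random_volume <- function(shape = c(8, 8, 4), spacing = c(1.25, 1.25, 7),
                          seed = 1) {
  set.seed(seed)
  cs_volume(array(runif(prod(shape)), dim = shape),
            volume_grid(shape, spacing))
}

# annulus mask (LVM=2 around cavity=3, RV blob=1) on a small grid
toy_heart_mask <- function(shape = c(32, 32, 4), spacing = c(2, 2, 8),
                           r_endo = 6, r_epi = 10, rv = TRUE) {
  g <- volume_grid(shape, spacing)
  cx <- (shape[1] - 1) / 2; cy <- (shape[2] - 1) / 2
  X <- matrix(rep(seq_len(shape[1]) - 1, times = shape[2]), shape[1])
  Y <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1])
  R <- sqrt((X - cx)^2 + (Y - cy)^2)
  sl <- matrix(0L, shape[1], shape[2])
  sl[R <= r_epi] <- 2L
  sl[R <= r_endo] <- 3L
  if (rv) sl[R > r_epi & sqrt((X - cx + 14)^2 + (Y - cy)^2) <= 4] <- 1L
  seg_mask(array(rep(sl, shape[3]), dim = shape), g)
}

# a single shared mid-size phantom rendering, memoised across test files
.fixture_cache <- new.env(parent = emptyenv())

cached_phantom <- function() {
  if (is.null(.fixture_cache$phantom)) {
    .fixture_cache$phantom <- render_sequence(phantom_params(
      n_frames = 5L, grid = volume_grid(c(64, 64, 8), c(2.5, 2.5, 10)),
      seed = 11L))
  }
  .fixture_cache$phantom
}

# full-resolution phantom (128 x 128 x 16) used by the strain-engine oracle
cached_phantom_full <- function() {
  if (is.null(.fixture_cache$phantom_full)) {
    .fixture_cache$phantom_full <- render_sequence(phantom_params(
      n_frames = 3L, seed = 5L))
  }
  .fixture_cache$phantom_full
}
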