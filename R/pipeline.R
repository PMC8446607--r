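# End-to-end orchestration: centre -> crop -> segment -> detect ES ->
# estimate motion -> strain analysis, with a reproducible run manifest.

cs_log <- function(level, ..., verbosity = getOption("cinestrain.log", "info")) {
  lv <- c(debug = 1, info = 2, warn = 3)
  if (lv[[level]] >= lv[[verbosity]])
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    toupper(level), paste0(...)))
  invisible(NULL)
}

file_hashes <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(as.character(h), basename(paths))
}

#' Run the full strain-quantification pipeline on a cine sequence
#'
#' Centres the end-diastolic frame with the centering network, crops every
#' frame around the detected centre, segments all frames, detects end-systole
#' from the cavity volumes (unless given), estimates motion from the ED frame
#' to every frame, and runs the strain engine. All outputs plus a manifest
#' (inputs, checkpoint hashes, seed, timings, output hashes) are written to
#' `out_dir`.
#' @param sequence a [cine_sequence()] (or path to a 4D cine NIfTI).
#' @param models list with elements `vcn`, `carson`, `carmen` ([train_network()]
#'   models or checkpoint paths).
#' @param out_dir output directory.
#' @param crop_size in-plane crop extent fed to segmentation/motion networks.
#' @param es_index optional 1-based ES frame (user flag wins over detection).
#' @param seed recorded in the manifest (the pipeline itself is deterministic).
#' @return List with `masks`, `fields`, `strain` (a `strain_result`),
#'   `volumetrics`, `center`, and `manifest`.
#' @export
run_pipeline <- function(sequence, models, out_dir, crop_size = 128L,
                         es_index = NULL, seed = NA_integer_) {
  t0 <- Sys.time()
  input_path <- NULL
  if (is.character(sequence)) {
    input_path <- sequence
    sequence <- read_cine(sequence)
  }
  for (nm in c("vcn", "carson", "carmen")) {
    if (is.null(models[[nm]])) stop("missing checkpoint: ", nm)
    if (is.character(models[[nm]])) models[[nm]] <- load_model(models[[nm]])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t, stage) timings[stage] <<- as.numeric(Sys.time() - t, units = "secs")

  t <- tic()
  ctr <- vcn_forward(models$vcn, sequence$frames[[1]])$center
  cs_log("info", sprintf("LV centre at voxel (%d, %d)", ctr[1], ctr[2]))
  toc(t, "centering")

  t <- tic()
  cropped <- lapply(sequence$frames, crop_around_center,
                    center_voxel = ctr, size = crop_size)
  crop_info <- attr(cropped[[1]], "crop_info")
  toc(t, "cropping")

  t <- tic()
  segs <- lapply(cropped, function(v) carson_forward(models$carson, v)$mask)
  toc(t, "segmentation")

  if (is.null(es_index)) es_index <- detect_es(segs)
  cs_log("info", "ES frame: ", es_index)

  t <- tic()
  crop_seq <- cine_sequence(cropped, sequence$frame_times, es_index = es_index)
  fields <- infer_sequence(models$carmen, crop_seq)
  toc(t, "motion")

  t <- tic()
  strain <- strain_from_fields(fields, segs[[1]], sequence$frame_times,
                               es_index = es_index)
  vol <- volumetrics(segs[[1]], segs[[es_index]])
  toc(t, "strain")

  # outputs in original geometry (crop inverted) plus curves and parameters
  paths <- write_strain_report(strain, out_dir)
  mask_path <- file.path(out_dir, "mask_ed.nii.gz")
  write_nifti(paste_back(segs[[1]], crop_info = crop_info), mask_path)
  field_path <- file.path(out_dir, "field_es.nii.gz")
  write_nifti(fields[[es_index]], field_path)
  paths <- c(paths, mask_path, field_path)

  manifest <- list(
    input = input_path %||% "<in-memory sequence>",
    checkpoints = lapply(models, function(m)
      list(kind = m$kind, epochs = m$config$epochs, seed = m$config$seed)),
    seed = seed, crop_center = ctr, crop_size = crop_size,
    es_index = es_index, n_frames = length(sequence$frames),
    version = as.character(utils::packageVersion("cinestrain")),
    timings_s = as.list(round(timings, 3)),
    outputs = as.list(file_hashes(paths)),
    total_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  list(masks = segs, fields = fields, strain = strain, volumetrics = vol,
       center = ctr, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment a cine sequence and report volumetric indices
#'
#' Runs centering and segmentation only; masks are returned in the original
#' workspace geometry (crop inverted).
#' @param sequence a [cine_sequence()] or path to a 4D cine NIfTI.
#' @param vcn,carson models or checkpoint paths.
#' @param crop_size in-plane crop extent.
#' @param es_index optional ES frame override.
#' @return List with `masks` (original geometry), `es_index`, `volumetrics`.
#' @export
segment_only <- function(sequence, vcn, carson, crop_size = 128L,
                         es_index = NULL) {
  if (is.character(sequence)) sequence <- read_cine(sequence)
  if (is.character(vcn)) vcn <- load_model(vcn)
  if (is.character(carson)) carson <- load_model(carson)
  ctr <- vcn_forward(vcn, sequence$frames[[1]])$center
  cropped <- lapply(sequence$frames, crop_around_center,
                    center_voxel = ctr, size = crop_size)
  segs <- lapply(cropped, function(v) carson_forward(carson, v)$mask)
  # plausibility gate: a real heart yields a spatially coherent label field
  # with a non-trivial LV; fragmented predictions mean there is no heart
  coherence <- vapply(segs, function(m) {
    d <- dim(m$labels)
    mean(m$labels[-1, , ] == m$labels[-d[1], , ])
  }, 0)
  lv_vox <- vapply(segs, function(m) sum(m$labels >= 2L), 0L)
  if (max(lv_vox) < 50L || mean(coherence) < 0.9)
    stop("no LV found in the input sequence")
  if (is.null(es_index)) es_index <- detect_es(segs)
  full <- lapply(seq_along(segs), function(i)
    paste_back(segs[[i]], crop_info = attr(cropped[[i]], "crop_info")))
  list(masks = full, es_index = es_index,
       volumetrics = volumetrics(segs[[1]], segs[[es_index]]))
}

#' Structured run log
#'
#' Emits timestamped, levelled log lines (respecting the
#' `cinestrain.log` option: `"debug"`, `"info"` or `"warn"`) echoing the
#' package version, seed and configuration, and returns the same record.
#' @param seed seed in use.
#' @param config named list echoed into the log.
#' @return List with `version`, `r_version`, `seed`, `config`, `timestamp`.
#' @export
version_and_log <- function(seed = NA_integer_, config = list()) {
  rec <- list(version = as.character(utils::packageVersion("cinestrain")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seed = seed, config = config,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  cs_log("info", "cinestrain ", rec$version, " (R ", rec$r_version, ")")
  cs_log("info", "seed: ", seed)
  for (nm in names(config))
    cs_log("debug", "config ", nm, " = ", paste(format(config[[nm]]),
                                                collapse = " "))
  invisible(rec)
}
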