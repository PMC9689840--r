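# Trained models are expensive; train once per session and cache on disk in
# the session tempdir so every test file reuses them.

.model_cache <- new.env(parent = emptyenv())

cached_models <- function() {
  if (!is.null(.model_cache$models)) return(.model_cache$models)
  path <- file.path(tempdir(), "limbalign_test_models.rds")
  if (file.exists(path)) {
    .model_cache$models <- readRDS(path)
    return(.model_cache$models)
  }
  tr <- phantom_training_images(30, seed = 100)
  models <- list(segmenter = train_segmenter(tr$images, tr$masks,
                                             seg_config(epochs = 30, seed = 0)))
  for (region in c("proximal_femur", "knee_native", "talus")) {
    ts <- phantom_training_crops(region, 40, seed = 500)
    models[[region]] <- train_landmark_model(region, ts$crops, ts$landmarks,
                                             lm_config(epochs = 30, seed = 0))
  }
  saveRDS(models, path)
  .model_cache$models <- models
  models
}

# small deterministic phantom set reused across tests
neutral_phantom <- function(seed = 3) generate_phantom(phantom_spec(seed = seed))

oracle_angles <- function(ph, ...) {
  rep <- measure_image(ph, ...)[[1]]
  vapply(rep$angles, function(a) if (inherits(a, "unavailable")) NA_real_ else a,
         numeric(1))
}

flip_h_matrix <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
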