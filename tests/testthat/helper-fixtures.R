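# Shared fixtures. Phantoms and trained smoke models are built once per
# test run and memoized, so the expensive pieces (network training) are
# paid for exactly once.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

desk_config <- function(seed = 11) {
  phantom_config(width = 128, height = 128, seed = seed)
}

# 128 x 128 phantoms used across suites (generated lazily, cached).
desk_phantom <- function(index, seed = 11) {
  memo(sprintf("ph_%d_%d", seed, index),
       function() generate_phantom(desk_config(seed), index))
}

# Smoke-recipe segmentation models: a depth-3 ELU fracture-line U-Net
# trained on 40 phantom pairs at 128 x 128 for 30 epochs, plus a
# tooth-region U-Net trained for 10 epochs (the tooth band is a far easier
# target). Training is deterministic (fixed seeds).
smoke_models <- function() {
  memo("smoke_models", function() {
    cfg <- desk_config()
    pairs_frac <- lapply(1:40, function(i) {
      ph <- desk_phantom(i)
      list(image = ph$image, mask = ph$gt$line_mask)
    })
    pairs_tooth <- lapply(1:40, function(i) {
      ph <- desk_phantom(i)
      list(image = ph$image, mask = ph$gt$tooth_mask)
    })
    spec <- unet_spec(input_size = 128, depth = 3, base_channels = 8,
                      activation = "elu")
    frac <- train_segmenter(pairs_frac,
                            train_config(batch_size = 6, learning_rate = 0.003,
                                         epochs = 30, seed = 5), spec)
    # the tooth band is a large contiguous target: a narrower net suffices
    tooth <- train_segmenter(pairs_tooth,
                             train_config(batch_size = 6, learning_rate = 0.003,
                                          epochs = 20, seed = 6),
                             unet_spec(input_size = 128, depth = 3,
                                       base_channels = 4, activation = "elu"))
    list(fracture = frac, tooth = tooth, spec = spec)
  })
}

held_out_phantoms <- function(indices = 41:50) {
  lapply(indices, desk_phantom)
}

# Independent brute-force maximum-TP matcher over an eligibility matrix
# (rows = predictions, cols = ground truths): recursive enumeration of all
# injective assignments.
brute_force_max_tp <- function(elig) {
  n_pred <- nrow(elig); n_gt <- ncol(elig)
  if (n_pred == 0 || n_gt == 0) return(0L)
  best <- 0L
  recurse <- function(p, used, count) {
    if (count + (n_pred - p + 1) <= best) return()
    if (p > n_pred) { best <<- max(best, count); return() }
    recurse(p + 1L, used, count)  # leave prediction p unmatched
    for (g in seq_len(n_gt)) {
      if (elig[p, g] && !used[g]) {
        used[g] <- TRUE
        recurse(p + 1L, used, count + 1L)
        used[g] <- FALSE
      }
    }
  }
  recurse(1L, logical(n_gt), 0L)
  best
}

# Pipeline configuration for the 128 x 128 desk profile: the tooth-fill
# structuring element scales with resolution (the 512-scale default would
# dilate the tooth region by a quarter of the bone width).
desk_pipeline_config <- function() {
  pipeline_config(se_radius = 2, fill_iterations = 1, min_component_size = 20)
}
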