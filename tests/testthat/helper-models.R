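# Desk-scale model and data settings shared across tests.

tiny_csat_config <- function(num_classes = 2L) {
  csat_config(stem_channels = 8L, stage_depths = c(1L, 1L, 1L, 1L),
              stage_transformers = c(0L, 0L, 1L, 1L),
              stage_channels = c(8L, 12L, 16L, 24L), pooled_size = 4L,
              conv_expansion = 2L, transformer_mlp_ratio = 2L,
              sat_qk_dim = 3L, num_classes = num_classes, heads = 2L)
}

tiny_slide_params <- function(...) {
  slide_params(width = 64L, height = 64L, n_blobs = 8, radius_range = c(3, 6),
               ...)
}

desk_distill_config <- function(epochs = 40L, seed = 5L) {
  distill_config(input_size = 64L, batch_size = 8L, epochs = epochs,
                 warmup_epochs = 5L, peak_lr = 1, trust_coefficient = 0.01,
                 seed = seed)
}

desk_finetune_config <- function(n_folds = 3L, max_epochs = 35L, seed = 2L,
                                 ...) {
  finetune_config(input_resolution = 64L, learning_rate = 0.003,
                  momentum = 0.9, head_lr_multiplier = 600, batch_size = 4L,
                  max_epochs = max_epochs, patience = max_epochs,
                  n_folds = n_folds, seed = seed, ...)
}
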