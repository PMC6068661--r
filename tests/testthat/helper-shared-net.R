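# A classifier trained once per test session at the study scale and shared
# by the tests that need a realistic trained network: 32 sprites per class
# -> 1152 augmented tiles -> 20 balanced momentum-SGD epochs (lr 0.02, batch 64).
.shared_env <- new.env(parent = emptyenv())

shared_trained_net <- function() {
  if (is.null(.shared_env$net)) {
    bank <- render_sprite_bank(32, seed = 101)
    tiles <- build_tile_dataset(bank, n_deform = 2, seed = 102)
    split <- split_dataset(tiles, ratio = 0.8, seed = 103)
    net <- tile_cnn(split$train,
                    config = training_config(learning_rate = 0.02, epochs = 20,
                                             batch_size = 64, seed = 104,
                                             balance_classes = TRUE),
                    seed = 105)
    .shared_env$bank <- bank
    .shared_env$split <- split
    .shared_env$net <- net
    .shared_env$eval <- evaluate_cnn(net, split$test)
  }
  .shared_env
}
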