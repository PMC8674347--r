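# Shared fixtures built once per test run (training a forest is the most
# expensive step; several files reuse the same small model).

.fixtures <- new.env(parent = emptyenv())

# compact 11-class library and model: 20 spectra/class, 300 trees, high SNR
get_small_library <- function() {
  if (is.null(.fixtures$lib)) {
    .fixtures$lib <- generate_training_library(n_per_class = 20,
                                               snr_range = c(15, 40),
                                               seed = 421L)
  }
  .fixtures$lib
}

get_small_library_pp <- function() {
  if (is.null(.fixtures$lib_pp)) {
    .fixtures$lib_pp <- preprocess_library(get_small_library())
  }
  .fixtures$lib_pp
}

get_small_model <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- train_classifier(get_small_library_pp(),
                                        n_trees = 300, seed = 422L)
  }
  .fixtures$model
}
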