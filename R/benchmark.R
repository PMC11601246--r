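#' Canonical desk-scale benchmark configuration
#'
#' The reduced model and training settings used with
#' [default_benchmark_spec()] throughout the package's tests and
#' reproduction script: a 5-layer CNN (widths 8-64, stride-2 cascade on a
#' 2x average-pooled input), transformer dimension 64 with 2 layers and 4
#' heads, 256-dimensional provider embeddings, and 20 epochs of RAdam at
#' learning rate 1e-2 with 2-channel dropout on the 7-12 marker panels
#' (a ~40k-parameter model trained for a few hundred steps needs a much
#' hotter rate than the full-scale reference). The full-scale reference
#' settings remain the defaults of [model_config()] and [train_config()].
#'
#' @param seed seed for initialization (`model`) / the training run
#'   (`train`).
#' @return a [model_config()] / [train_config()].
#' @export
benchmark_model_config <- function(seed = 1L) {
  model_config(d_model = 64L, n_layers = 2L, ff_dim = 128L, n_heads = 4L,
               cnn_widths = c(8L, 16L, 32L, 64L, 64L),
               cnn_strides = c(2L, 2L, 2L, 2L, 1L), pool_in = 2L,
               C_max = 16L, d_raw = 256L, n_modalities = 2L,
               mlp_hidden = 64L, seed = seed)
}

#' @rdname benchmark_model_config
#' @param w_adv_base adversarial ramp base weight (0 ablates the
#'   adversary).
#' @export
benchmark_train_config <- function(seed = 1L, w_adv_base = 0.1) {
  train_config(lr = 1e-2, epochs = 20L, batch_size = 64L,
               channel_dropout_k = 2L, w_adv_base = w_adv_base,
               seed = seed)
}

#' Split a corpus by dataset (leave-one-dataset-out)
#'
#' Restricts a corpus to the given dataset ids, e.g. to hold one panel out
#' of training entirely for zero-shot evaluation.
#'
#' @param corpus a `phenoclip_corpus`.
#' @param datasets dataset ids to keep.
#' @return the restricted corpus.
#' @export
subset_corpus <- function(corpus, datasets) {
  stopifnot(all(datasets %in% names(corpus$panels)))
  keep <- corpus$cells$dataset_id %in% datasets
  corpus$cells <- corpus$cells[keep, , drop = FALSE]
  corpus$positivity <- corpus$positivity[keep, , drop = FALSE]
  corpus$panels <- corpus$panels[datasets]
  corpus$modalities <- sort(unique(corpus$cells$modality_id))
  corpus$types <- sort(unique(corpus$cells$type[!is.na(corpus$cells$type)]))
  corpus
}
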