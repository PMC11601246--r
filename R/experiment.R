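#' Run the synthetic benchmark study at one seed
#'
#' The package's end-to-end simulation experiment on
#' [default_benchmark_spec()]: train the reduced model
#' ([benchmark_model_config()]) on the two larger-panel datasets, then
#' measure
#' \itemize{
#'   \item held-out validation macro F1 within the training datasets,
#'   \item zero-shot macro F1 on the held-out dataset, whose 7-marker
#'     panel never occurs in training,
#'   \item the same zero-shot task for the mean-intensity XGBoost
#'     baseline (absent markers as missing values),
#'   \item marker-positivity AUC of the attention scores on the held-out
#'     dataset (per marker, averaged),
#'   \item linear-probe accuracy for imaging modality on the [CLS]
#'     embeddings, for the adversarially trained model and (optionally) an
#'     ablated model trained without the adversary.
#' }
#' The corpus and baseline features depend only on the spec seed; `seed`
#' drives model initialization and the training run, so repeated calls
#' with different seeds give independent replicates on identical data.
#'
#' @param seed model/training seed for this replicate.
#' @param corpus optional precomputed corpus from [make_corpus()].
#' @param features optional precomputed table from
#'   [extract_feature_table()] on the spec's normalized FOVs.
#' @param include_ablated also train the no-adversary model?
#' @param include_baseline fit the tree baseline?
#' @param spec the generating spec.
#' @param provider embedding provider.
#' @param holdout dataset id held out for zero-shot evaluation.
#' @return list with the metrics above, the trained `model` (and
#'   `model_ablated`), and the per-epoch `history`.
#' @export
benchmark_experiment <- function(seed = 1L, corpus = NULL, features = NULL,
                                 include_ablated = TRUE,
                                 include_baseline = TRUE,
                                 spec = default_benchmark_spec(),
                                 provider = offline_provider(256L),
                                 holdout = "ds3") {
  if (is.null(corpus)) corpus <- make_corpus(spec)
  train_ds <- setdiff(names(corpus$panels), holdout)
  train_sub <- subset_corpus(corpus, train_ds)

  model <- init_phenotype_model(benchmark_model_config(seed = seed))
  fit <- fit_phenotype_model(model, train_sub,
                             benchmark_train_config(seed = seed), provider)

  cand <- candidate_set(fit$types, provider)
  zs <- which(corpus$cells$dataset_id == holdout)
  pred <- predict_cell_types(fit, corpus, cand, provider, idx = zs)
  zero_f1 <- evaluate_classification(pred$predicted_type,
                                     corpus$cells$type[zs])$macro_f1

  # attention positivity vs truth bits on the held-out dataset
  C_h <- length(corpus$panels[[holdout]])
  posm <- attr(pred, "positivity")[, seq_len(C_h), drop = FALSE]
  truthp <- corpus$positivity[zs, seq_len(C_h), drop = FALSE]
  aucs <- vapply(seq_len(C_h), function(m) {
    t <- truthp[, m]
    if (length(unique(t[!is.na(t)])) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(t, posm[, m], quiet = TRUE,
                                   direction = "<")))
  }, 0)

  # linear modality probe on training-dataset embeddings
  emb <- export_embeddings(fit, train_sub, provider)
  ecols <- grepl("^e[0-9]+$", names(emb))
  probe_adv <- modality_probe(emb[, ecols], train_sub$cells$modality_id,
                              seed = seed)

  out <- list(seed = seed,
              heldout_macro_f1 = max(fit$history$val_macro_f1),
              zeroshot_macro_f1 = zero_f1,
              positivity_auc = mean(aucs, na.rm = TRUE),
              positivity_auc_per_marker = aucs,
              probe_adversarial = probe_adv$accuracy,
              probe_chance = probe_adv$chance,
              model = fit, history = fit$history)

  if (include_baseline) {
    if (is.null(features)) {
      fovs <- render_corpus_fovs(spec)
      fovs <- lapply(fovs, function(f) {
        f$image <- normalize_fov(f$image)
        f
      })
      features <- extract_feature_table(fovs)
    }
    tr <- features$dataset_id %in% train_ds
    bl <- fit_intensity_baseline(features[tr, , drop = FALSE])
    bp <- predict(bl, features[!tr, , drop = FALSE])
    out$baseline_zeroshot_macro_f1 <-
      evaluate_classification(bp, features$label[!tr])$macro_f1
    out$features <- features
  }

  if (include_ablated) {
    model0 <- init_phenotype_model(benchmark_model_config(seed = seed))
    fit0 <- fit_phenotype_model(
      model0, train_sub,
      benchmark_train_config(seed = seed, w_adv_base = 0), provider)
    emb0 <- export_embeddings(fit0, train_sub, provider)
    out$probe_ablated <- modality_probe(emb0[, ecols],
                                        train_sub$cells$modality_id,
                                        seed = seed)$accuracy
    out$model_ablated <- fit0
  }
  out
}
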