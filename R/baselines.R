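#' Mean-intensity feature tables (classical baseline input)
#'
#' Builds the per-cell feature representation used by tabular baselines:
#' the mean normalized intensity of every available marker over the cell's
#' own pixels, aligned across datasets to the union of all markers, plus a
#' cell-size column (pixel count). Markers absent from a dataset's panel
#' receive a placeholder (`NA` for tree models with native missing-value
#' handling, or 0). Cells with zero pixels are excluded with a warning.
#'
#' @param fovs list of lists, each with `image` ([fov_image]), `mask`
#'   ([segmentation_mask]) and optional `truth` (data.frame with `cell_id`
#'   and `cell_type`).
#' @param all_markers character vector defining the column universe
#'   (default: union over the supplied FOVs).
#' @param placeholder value for absent markers (`NA` or 0).
#' @return data.frame: metadata columns (`dataset_id`, `modality_id`,
#'   `fov`, `cell_id`, optional `label`), one column per marker, and
#'   `cell_size`.
#' @export
extract_feature_table <- function(fovs, all_markers = NULL,
                                  placeholder = NA_real_) {
  if (is.null(all_markers))
    all_markers <- unique(unlist(lapply(fovs, function(f)
      f$image$panel$canonical_names)))
  rows <- list()
  for (fi in seq_along(fovs)) {
    f <- fovs[[fi]]
    panel <- f$image$panel$canonical_names
    labs <- f$mask$labels
    ids <- sort(unique(labs[labs > 0]))
    sizes <- tabulate(labs[labs > 0])
    feat <- matrix(placeholder, length(ids), length(all_markers),
                   dimnames = list(NULL, all_markers))
    for (m in seq_along(panel)) {
      ch <- f$image$pixels[, , m]
      sums <- vapply(ids, function(k) sum(ch[labs == k]), 0)
      feat[, panel[m]] <- sums / sizes[ids]
    }
    keep <- sizes[ids] > 0
    if (!all(keep))
      warning("excluding ", sum(!keep), " zero-pixel cell(s)",
              call. = FALSE)
    df <- data.frame(dataset_id = f$image$dataset_id,
                     modality_id = f$image$modality_id, fov = fi,
                     cell_id = ids, stringsAsFactors = FALSE)
    if (!is.null(f$truth))
      df$label <- f$truth$cell_type[match(ids, f$truth$cell_id)]
    df <- cbind(df, as.data.frame(feat), cell_size = sizes[ids])
    rows[[fi]] <- df[keep, , drop = FALSE]
  }
  do.call(rbind, rows)
}

#' Classification metrics with a support filter
#'
#' Per-class F1, retained-class macro F1 and the confusion matrix.
#' Classes with truth support below `min_support` are excluded from the
#' macro average (rare categories carry no statistical weight).
#'
#' @param predictions,truth character vectors of equal length.
#' @param min_support smallest truth count for a class to be retained.
#' @return list: `per_class` (data.frame class/precision/recall/f1/support),
#'   `macro_f1`, `confusion`.
#' @export
evaluate_classification <- function(predictions, truth, min_support = 0L) {
  stopifnot(length(predictions) == length(truth))
  classes <- sort(unique(c(predictions, truth)))
  conf <- table(factor(truth, classes), factor(predictions, classes))
  support <- rowSums(conf)
  keep <- names(support)[support >= min_support & support > 0]
  if (length(keep) == 0L)
    stop("no class meets min_support = ", min_support, call. = FALSE)
  per <- lapply(keep, function(cl) {
    tp <- conf[cl, cl]
    prec <- if (sum(conf[, cl]) > 0) tp / sum(conf[, cl]) else 0
    rec <- tp / sum(conf[cl, ])
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = sum(conf[cl, ]), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_class = per, macro_f1 = mean(per$f1), confusion = conf)
}

#' Linear probe for residual modality information
#'
#' Measures how much imaging-platform identity is linearly decodable from
#' frozen cell embeddings: a multinomial logistic probe is cross-validated
#' (stratified folds) and its accuracy reported next to the chance level
#' (majority-class share). Adversarially trained embeddings should score
#' closer to chance than an ablated model's.
#'
#' @param embeddings numeric matrix (cells x dimensions).
#' @param modality_labels character/factor vector, at least two levels.
#' @param folds cross-validation folds.
#' @param seed fold-assignment seed.
#' @return list `accuracy`, `chance`, `n`.
#' @export
modality_probe <- function(embeddings, modality_labels, folds = 5L,
                           seed = 1L) {
  y <- factor(modality_labels)
  if (nlevels(y) < 2L)
    stop("modality probe needs at least two modalities", call. = FALSE)
  X <- as.matrix(embeddings)
  stopifnot(nrow(X) == length(y))
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    ids <- which(y == lv)
    fold[ids] <- sample(rep_len(seq_len(folds), length(ids)))
  }
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    dtrain <- data.frame(y = y[tr], X[tr, , drop = FALSE])
    dtest <- data.frame(X[!tr, , drop = FALSE])
    fit <- nnet::multinom(y ~ ., dtrain, trace = FALSE, MaxNWts = 100000)
    pred <- predict(fit, dtest)
    correct <- correct + sum(pred == y[!tr])
  }
  list(accuracy = correct / length(y),
       chance = max(table(y)) / length(y), n = length(y))
}

#' Gradient-boosted tree baseline on mean-intensity features
#'
#' The classical comparator: XGBoost on the aligned mean-intensity table,
#' with absent markers flagged as missing values through the native sparse
#' interface. Trained with default parameters for 160 rounds.
#'
#' @param features data.frame from [extract_feature_table()] with a
#'   `label` column.
#' @param feature_cols columns to use (default: all markers + cell_size).
#' @param nrounds boosting rounds.
#' @param seed RNG seed.
#' @return a `phenoclip_xgb` (model + class levels + feature columns).
#' @export
fit_intensity_baseline <- function(features, feature_cols = NULL,
                                   nrounds = 160L, seed = 1L) {
  stopifnot("label" %in% names(features))
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(features),
                            c("dataset_id", "modality_id", "fov",
                              "cell_id", "label"))
  y <- factor(features$label)
  X <- as.matrix(features[, feature_cols, drop = FALSE])
  set.seed(seed)
  booster <- xgboost::xgboost(
    x = X, y = y, nrounds = nrounds, objective = "multi:softprob",
    verbosity = 0, nthreads = 1L, seed = seed)
  structure(list(booster = booster, levels = levels(y),
                 feature_cols = feature_cols),
            class = "phenoclip_xgb")
}

#' @rdname fit_intensity_baseline
#' @param object a `phenoclip_xgb`.
#' @param newdata feature data.frame aligned to the same marker universe.
#' @param ... unused.
#' @export
predict.phenoclip_xgb <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  p <- predict(object$booster, X)
  if (is.null(dim(p)))
    p <- matrix(p, ncol = length(object$levels), byrow = TRUE)
  object$levels[max.col(p, ties.method = "first")]
}
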