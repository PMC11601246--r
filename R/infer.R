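#' Candidate cell-type sets for prediction-set binding
#'
#' Because classification is similarity-based, the set of candidate cell
#' types is chosen at inference time, independently of the training label
#' set. `candidate_set()` embeds an explicit list of names;
#' `bind_by_tissue()` derives the list from a tissue -> cell-types map,
#' falling back to the full set with a warning for unknown tissues.
#'
#' @param cell_types non-empty character vector of unique canonical names.
#' @param provider embedding provider (must match the training provider).
#' @return a `candidate_set` (names + raw embedding matrix).
#' @export
candidate_set <- function(cell_types, provider) {
  stopifnot(length(cell_types) >= 1L, !anyDuplicated(cell_types))
  structure(list(cell_types = cell_types,
                 embeddings = term_embedding_matrix(cell_types, "cell_type",
                                                    provider),
                 provider_id = provider$id),
            class = "candidate_set")
}

#' @rdname candidate_set
#' @param tissue_id tissue name to bind to.
#' @param tissue_map named list: tissue -> character vector of cell types.
#' @param full_set character vector used when the tissue is unknown.
#' @export
bind_by_tissue <- function(tissue_id, tissue_map, full_set, provider) {
  if (!tissue_id %in% names(tissue_map)) {
    warning("tissue '", tissue_id,
            "' not in tissue map; using the full label set", call. = FALSE)
    return(candidate_set(full_set, provider))
  }
  candidate_set(tissue_map[[tissue_id]], provider)
}

#' Zero-shot cell-type prediction
#'
#' Computes each cell's [CLS] embedding (evaluation mode), its cosine
#' similarity to every candidate cell-type name embedding (projected with
#' the trained map), and the attention-derived marker positivity scores.
#' The predicted type is the argmax similarity with lowest-index
#' tie-breaking; similarities are raw cosines in `[-1, 1]`, with no
#' confidence calibration applied.
#'
#' @param model a trained `phenotype_model`.
#' @param corpus a `phenoclip_corpus` (all cells are scored) — or use
#'   `batch` with a `padded_batch`.
#' @param candidates a [candidate_set()].
#' @param provider embedding provider; must be the one used in training
#'   (checked via the recorded provider id).
#' @param idx optional row indices of `corpus$cells` to score.
#' @param batch alternative input to `corpus`.
#' @return a `data.frame` with `cell_id`, `dataset_id`, `predicted_type`
#'   and one `sim_<type>` column per candidate; attribute `"positivity"`
#'   holds the per-cell marker positivity matrix (columns = channel slots),
#'   attribute `"similarity"` the plain similarity matrix.
#' @export
predict_cell_types <- function(model, corpus = NULL, candidates, provider,
                               idx = NULL, batch = NULL) {
  stopifnot(inherits(model, "phenotype_model"), isTRUE(model$trained),
            inherits(candidates, "candidate_set"))
  if (!is.null(model$provider_id) &&
      !identical(candidates$provider_id, model$provider_id))
    stop("candidate set embedded with provider '", candidates$provider_id,
         "' but model was trained with '", model$provider_id, "'",
         call. = FALSE)
  if (is.null(corpus) + is.null(batch) != 1L)
    stop("supply exactly one of corpus or batch", call. = FALSE)
  if (!is.null(batch)) {
    fw <- model_forward(model, batch, provider)
    cell_id <- batch$cell_id
    dataset_id <- batch$dataset_id
  } else {
    if (is.null(idx)) idx <- seq_len(nrow(corpus$cells))
    marker_embs <- lapply(corpus$panels, function(p)
      term_embedding_matrix(p, "marker", provider))
    fw <- forward_cells(model, corpus, idx, marker_embs,
                        max(lengths(corpus$panels)))
    cell_id <- corpus$cells$cell_id[idx]
    dataset_id <- corpus$cells$dataset_id[idx]
  }
  cl <- classify_cls(fw$cls, model$params, candidates$embeddings,
                     candidates$cell_types)
  out <- data.frame(cell_id = cell_id, dataset_id = dataset_id,
                    predicted_type = cl$predicted,
                    stringsAsFactors = FALSE)
  sims <- cl$similarity
  colnames(sims) <- paste0("sim_", candidates$cell_types)
  out <- cbind(out, as.data.frame(sims))
  attr(out, "similarity") <- cl$similarity
  attr(out, "positivity") <- fw$positivity
  out
}

#' Export cell embeddings for external analysis
#'
#' Writes each cell's [CLS] embedding with its metadata, e.g. for
#' dimensionality-reduction visualization in other tools.
#'
#' @inheritParams predict_cell_types
#' @param file optional CSV path.
#' @return data.frame of metadata plus `e1..ed` columns.
#' @export
export_embeddings <- function(model, corpus, provider, idx = NULL,
                              file = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(corpus$cells))
  marker_embs <- lapply(corpus$panels, function(p)
    term_embedding_matrix(p, "marker", provider))
  fw <- forward_cells(model, corpus, idx, marker_embs,
                      max(lengths(corpus$panels)))
  emb <- t(fw$cls)
  colnames(emb) <- paste0("e", seq_len(ncol(emb)))
  out <- cbind(corpus$cells[idx, c("cell_id", "dataset_id", "modality_id",
                                   "tissue_id")],
               as.data.frame(emb))
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
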