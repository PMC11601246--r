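#' Embedding providers for marker and cell-type names
#'
#' The model consumes fixed-length "language" embeddings of marker and
#' cell-type names. Providers are pluggable: each one can describe a term
#' (an expert-explainer step) and embed the resulting text. The default
#' offline provider is fully deterministic: it writes a templated
#' description and maps it through a cryptographic hash to a seeded
#' pseudo-random unit vector, so distinct terms receive near-orthogonal
#' embeddings at moderate dimension and the whole pipeline runs without
#' network access. An HTTP provider can be slotted in by supplying custom
#' `describe`/`embed` closures; swapping providers changes vectors but no
#' tensor shapes.
#'
#' @param d_raw embedding dimension produced by the provider (the reference
#'   setting uses 8192; 256 is the default desk-scale configuration).
#' @param id provider identifier recorded for provenance and caching.
#' @return a `phenoclip_provider`.
#' @export
offline_provider <- function(d_raw = 256L, id = "offline-hash-v1") {
  stopifnot(d_raw >= 1L)
  pr <- list(
    id = id,
    d_raw = as.integer(d_raw),
    describe = function(term, role) paste0(term, ": ", role),
    embed = function(text) {
      if (!nzchar(text)) stop("empty description", call. = FALSE)
      with_seed(hash_seed(paste(id, d_raw, text, sep = "")), {
        v <- rnorm(d_raw)
        v / sqrt(sum(v^2))
      })
    },
    cache = new.env(parent = emptyenv())
  )
  structure(pr, class = "phenoclip_provider")
}

#' @rdname offline_provider
#' @param term canonical marker or cell-type name.
#' @param role `"marker"` or `"cell_type"`.
#' @param provider a `phenoclip_provider`.
#' @return `describe_term()`: a `term_description` (term, role, description,
#'   provider_id). `embed_description()`: numeric vector of length `d_raw`.
#' @export
describe_term <- function(term, role = c("marker", "cell_type"), provider) {
  role <- match.arg(role)
  stopifnot(is.character(term), length(term) == 1L, nzchar(term))
  txt <- provider$describe(term, role)
  if (!nzchar(txt))
    stop("provider returned an empty description for '", term, "'",
         call. = FALSE)
  structure(list(term = term, role = role, description = txt,
                 provider_id = provider$id),
            class = "term_description")
}

#' @rdname offline_provider
#' @param desc a `term_description`.
#' @export
embed_description <- function(desc, provider) {
  stopifnot(inherits(desc, "term_description"))
  v <- provider$embed(desc$description)
  if (length(v) != provider$d_raw)
    stop("provider returned length ", length(v), ", configured d_raw is ",
         provider$d_raw, call. = FALSE)
  v
}

#' Cached raw embeddings for a set of terms
#'
#' Computes (or retrieves from the provider's cache) the raw embedding of
#' every term, so a corpus run never queries the provider twice for the same
#' (term, role, provider) triple.
#'
#' @inheritParams describe_term
#' @param terms character vector of canonical names.
#' @return numeric matrix `(d_raw, length(terms))` with terms as column
#'   names.
#' @export
term_embedding_matrix <- function(terms, role = c("marker", "cell_type"),
                                  provider) {
  role <- match.arg(role)
  out <- matrix(0, provider$d_raw, length(terms))
  colnames(out) <- terms
  for (i in seq_along(terms)) {
    key <- paste(role, terms[i], sep = "")
    hitv <- provider$cache[[key]]
    if (is.null(hitv)) {
      hitv <- embed_description(describe_term(terms[i], role, provider),
                                provider)
      assign(key, hitv, envir = provider$cache)
    }
    out[, i] <- hitv
  }
  out
}

#' Gaussian perturbation of embeddings (training-time regularization)
#'
#' Adds elementwise N(0, sigma^2) noise; applied to marker-name and
#' cell-type embeddings on every batch draw during training and never at
#' inference.
#'
#' @param x numeric vector, matrix or array.
#' @param sigma noise standard deviation (default 0.005).
#' @return object of the same shape.
#' @export
perturb_embedding <- function(x, sigma = 0.005) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(x)
  x + rnorm(length(x), 0, sigma)
}

#' Write or read an embedding cache as JSON-lines
#'
#' Each line holds `{term, role, provider_id, vector}`; loading a cache file
#' pre-populates a provider so no computation is repeated across sessions.
#'
#' @param provider a `phenoclip_provider`.
#' @param path JSONL file path.
#' @export
save_embedding_cache <- function(provider, path) {
  keys <- ls(provider$cache)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in keys) {
    parts <- strsplit(k, "", fixed = TRUE)[[1]]
    writeLines(jsonlite::toJSON(
      list(term = parts[2], role = parts[1], provider_id = provider$id,
           vector = provider$cache[[k]]),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname save_embedding_cache
#' @export
load_embedding_cache <- function(provider, path) {
  for (ln in readLines(path)) {
    rec <- jsonlite::fromJSON(ln)
    if (!identical(rec$provider_id, provider$id)) next
    assign(paste(rec$role, rec$term, sep = ""), rec$vector,
           envir = provider$cache)
  }
  invisible(provider)
}
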