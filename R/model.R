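#' Model configuration
#'
#' Architecture hyperparameters for the phenotyping network. The defaults
#' follow the reference design: an 11-layer CNN (kernel 3, padding 1,
#' interleaved strides 1 and 2, SiLU then batch normalization per layer)
#' shared across channel slots, a 5-layer channel-wise transformer with
#' hidden dimension 256 and feed-forward dimension 512, and a 3-layer MLP
#' modality head behind a gradient-reversal layer. Channel widths double
#' from a configurable base; heads default to 8 of dimension 32.
#'
#' `pool_in` optionally average-pools the 64x64 input by an integer factor
#' before the first convolution; it is 1 (off) in the reference
#' configuration and used by reduced desk-scale configurations.
#'
#' @param d_model embedding dimension shared by image and text tokens.
#' @param n_layers transformer encoder layers.
#' @param ff_dim transformer feed-forward dimension.
#' @param n_heads attention heads (`d_model` must be divisible).
#' @param cnn_widths integer vector of per-layer output channels.
#' @param cnn_strides matching vector of strides (1 or 2).
#' @param pool_in average-pool factor applied to the 64x64 input (1 = none).
#' @param C_max channel capacity of the padded batch.
#' @param d_raw raw language-embedding dimension (provider-dependent).
#' @param n_modalities number of imaging platforms for the adversary head.
#' @param mlp_hidden hidden width of the modality head.
#' @param temperature_init initial contrastive temperature tau.
#' @param pos_mode attention-to-positivity normalization: `"max"` rescales
#'   the head-averaged [CLS] attention by the per-cell maximum (top marker
#'   scores 1); `"sum"` normalizes to sum 1 over real channels.
#' @param seed initialization seed.
#' @return a `phenoclip_config`.
#' @export
model_config <- function(d_model = 256L, n_layers = 5L, ff_dim = 512L,
                         n_heads = 8L,
                         cnn_widths = c(16L, 32L, 32L, 64L, 64L, 128L, 128L,
                                        256L, 256L, 256L, 256L),
                         cnn_strides = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L,
                                         2L, 1L),
                         pool_in = 1L, C_max = 75L, d_raw = 256L,
                         n_modalities = 2L, mlp_hidden = d_model,
                         temperature_init = 0.07,
                         pos_mode = c("max", "sum"), seed = 1L) {
  pos_mode <- match.arg(pos_mode)
  if (length(cnn_widths) != length(cnn_strides))
    stop("cnn_widths and cnn_strides lengths differ", call. = FALSE)
  if (d_model %% n_heads != 0L)
    stop("d_model must be divisible by n_heads", call. = FALSE)
  if (n_modalities < 2L)
    stop("n_modalities must be at least 2", call. = FALSE)
  if (!(64L %% pool_in == 0L))
    stop("pool_in must divide 64", call. = FALSE)
  stopifnot(all(c(d_model, n_layers, ff_dim, n_heads, cnn_widths, C_max,
                  d_raw, mlp_hidden) >= 1),
            all(cnn_strides %in% c(1L, 2L)), temperature_init > 0)
  # the spatial grid must survive the stride schedule
  h <- 64L %/% pool_in
  for (s in cnn_strides) {
    h <- (h + 2L - 3L) %/% s + 1L
    if (h < 1L) stop("stride schedule collapses the spatial grid",
                     call. = FALSE)
  }
  structure(list(d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers),
                 ff_dim = as.integer(ff_dim), n_heads = as.integer(n_heads),
                 cnn_widths = as.integer(cnn_widths),
                 cnn_strides = as.integer(cnn_strides),
                 pool_in = as.integer(pool_in), C_max = as.integer(C_max),
                 d_raw = as.integer(d_raw),
                 n_modalities = as.integer(n_modalities),
                 mlp_hidden = as.integer(mlp_hidden),
                 temperature_init = temperature_init,
                 pos_mode = pos_mode, seed = as.integer(seed)),
            class = "phenoclip_config")
}

# integer pos_mode for the C++ core
pos_mode_int <- function(config) match(config$pos_mode, c("max", "sum")) - 1L

cfg_for_cpp <- function(config) {
  list(cnn_widths = config$cnn_widths, cnn_strides = config$cnn_strides,
       d_model = config$d_model, n_layers = config$n_layers,
       n_heads = config$n_heads, ff_dim = config$ff_dim,
       n_modalities = config$n_modalities, pos_mode = pos_mode_int(config),
       pool_in = config$pool_in)
}

#' Initialize a phenotyping model
#'
#' Creates all parameter arrays (He-normal convolutions, Glorot linear
#' maps, unit batch-norm/layer-norm scales, `log(tau)` at the configured
#' temperature) from the configuration seed; the same seed and
#' configuration always give bit-identical parameters.
#'
#' @param config a [model_config()].
#' @return a `phenotype_model` (config + named parameter list).
#' @export
init_phenotype_model <- function(config) {
  stopifnot(inherits(config, "phenoclip_config"))
  with_seed(config$seed, {
    d <- config$d_model
    p <- list()
    cin <- 3L
    for (l in seq_along(config$cnn_widths)) {
      co <- config$cnn_widths[l]
      p[[paste0("cnn_W", l)]] <-
        matrix(rnorm(co * 9 * cin, 0, sqrt(2 / (9 * cin))), co, 9 * cin)
      p[[paste0("cnn_b", l)]] <- rep(0, co)
      p[[paste0("bn_g", l)]] <- rep(1, co)
      p[[paste0("bn_b", l)]] <- rep(0, co)
      p[[paste0("bn_m", l)]] <- rep(0, co)
      p[[paste0("bn_v", l)]] <- rep(1, co)
      cin <- co
    }
    p$img_W <- glorot(d, cin)
    p$img_b <- rep(0, d)
    p$txt_W <- glorot(d, config$d_raw)
    p$txt_b <- rep(0, d)
    p$cls_tok <- rnorm(d, 0, 0.02)
    for (l in seq_len(config$n_layers)) {
      pre <- paste0("tf", l, "_")
      for (nm in c("Wq", "Wk", "Wv", "Wo"))
        p[[paste0(pre, nm)]] <- glorot(d, d)
      for (nm in c("bq", "bk", "bv", "bo"))
        p[[paste0(pre, nm)]] <- rep(0, d)
      p[[paste0(pre, "ff1_W")]] <- glorot(config$ff_dim, d)
      p[[paste0(pre, "ff1_b")]] <- rep(0, config$ff_dim)
      p[[paste0(pre, "ff2_W")]] <- glorot(d, config$ff_dim)
      p[[paste0(pre, "ff2_b")]] <- rep(0, d)
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- rep(0, d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- rep(0, d)
    }
    p$lnf_g <- rep(1, d)
    p$lnf_b <- rep(0, d)
    h <- config$mlp_hidden
    p$mod_W1 <- glorot(h, d)
    p$mod_b1 <- rep(0, h)
    p$mod_W2 <- glorot(h, h)
    p$mod_b2 <- rep(0, h)
    p$mod_W3 <- glorot(config$n_modalities, h)
    p$mod_b3 <- rep(0, config$n_modalities)
    p$log_tau <- log(config$temperature_init)
    structure(list(config = config, params = p, provider_id = NULL,
                   types = NULL, history = NULL, trained = FALSE),
              class = "phenotype_model")
  })
}

#' @export
print.phenotype_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "<phenotype_model> d=%d, %d conv + %d transformer layers, %s params%s\n",
    x$config$d_model, length(x$config$cnn_widths), x$config$n_layers,
    format(np, big.mark = ","),
    if (isTRUE(x$trained)) " (trained)" else ""))
  invisible(x)
}

# Marshal a padded batch (or corpus rows) into the flat-image form consumed
# by the C++ core. Returns img_* index vectors (0-based).
batch_index <- function(padding_mask, slot_offsets) {
  B <- nrow(padding_mask)
  item <- integer(0); slot <- integer(0); off <- integer(0)
  for (b in seq_len(B)) {
    sl <- which(padding_mask[b, ] > 0)
    item <- c(item, rep.int(b - 1L, length(sl)))
    slot <- c(slot, sl - 1L)
    off <- c(off, slot_offsets[[b]][sl])
  }
  list(item = item, slot = as.integer(slot), off = as.integer(off))
}

#' Run the network forward on a padded batch
#'
#' @param model a `phenotype_model`.
#' @param batch a `padded_batch` from [pad_batch()].
#' @param provider embedding provider used for the marker names (must match
#'   the one used in training).
#' @param training use batch statistics and expose the training path
#'   (default `FALSE`: running statistics, deterministic).
#' @return list with `cls` (`d x B` [CLS] embeddings), `channel_emb`
#'   (`d x C_max x B`), `positivity` (`B x C_max`, `NA` on padded slots),
#'   `attn_raw` (head-averaged [CLS] attention), `mod_logits` and `tau`.
#' @export
model_forward <- function(model, batch, provider, training = FALSE) {
  stopifnot(inherits(batch, "padded_batch"))
  C_max <- ncol(batch$padding_mask)
  B <- nrow(batch$padding_mask)
  d_raw <- model$config$d_raw
  Tm <- array(0, c(d_raw, C_max, B))
  for (b in seq_len(B)) {
    nms <- batch$channel_names[[b]]
    sl <- which(batch$padding_mask[b, ] > 0)   # names align to real slots
    if (length(nms) != length(sl))
      stop("channel_names and padding mask disagree for item ", b,
           call. = FALSE)
    if (length(nms))
      Tm[, sl, b] <- term_embedding_matrix(nms, "marker", provider)
  }
  slot_offsets <- lapply(seq_len(B) - 1L, function(b0)
    (b0 * C_max + (seq_len(C_max) - 1L)) * 12288L)
  ix <- batch_index(batch$padding_mask, slot_offsets)
  run_core(model, as.numeric(batch$tensor), ix, B, Tm,
           training = training)
}

# shared low-level call
run_core <- function(model, patch_data, ix, B, Tm, Ty = matrix(0, 0, 0),
                     pos_t = matrix(0, 0, 0), pos_lab = matrix(0, 0, 0),
                     mod_y = integer(0),
                     loss_cfg = list(w_cls = 0, w_pos = 0, lambda = 0,
                                     gamma = 2, smooth_pos = 0.2,
                                     smooth_mod = 0.01, eps_clip = 1e-6),
                     training = FALSE, want_grads = FALSE,
                     bn_momentum = 0.1) {
  out <- cpp_model_run(model$params, cfg_for_cpp(model$config), patch_data,
                       ix$off, ix$item, ix$slot,
                       ix$aug %||% rep.int(0L, length(ix$off)),
                       B, as.numeric(Tm), dim(Tm), Ty, pos_t, pos_lab,
                       mod_y, loss_cfg, training, want_grads, bn_momentum)
  out$positivity[is.nan(out$positivity)] <- NA_real_
  out$attn_raw[is.nan(out$attn_raw)] <- NA_real_
  out
}

#' Save or load a model checkpoint
#'
#' A checkpoint is a single-file archive of the parameter arrays, the full
#' configuration, the embedding-provider id and the training history.
#' Loading verifies a hash of the configuration so silently mismatched
#' architectures are rejected.
#'
#' @param model a trained `phenotype_model`.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  cfg_hash <- hash_seed(paste(deparse(unclass(model$config)),
                              collapse = "\n"))
  saveRDS(list(params = model$params, config = model$config,
               provider_id = model$provider_id, types = model$types,
               history = model$history, trained = model$trained,
               config_hash = cfg_hash, format_version = 1L),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  expect <- hash_seed(paste(deparse(unclass(x$config)), collapse = "\n"))
  if (!identical(expect, x$config_hash))
    stop("checkpoint configuration hash mismatch", call. = FALSE)
  structure(list(config = x$config, params = x$params,
                 provider_id = x$provider_id, types = x$types,
                 history = x$history, trained = x$trained),
            class = "phenotype_model")
}
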