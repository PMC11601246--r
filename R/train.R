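#' Training configuration
#'
#' Optimization and regularization settings. Reference values: RAdam with
#' learning rate 1e-4 for 20 epochs; focal gamma 2; positivity label
#' smoothing 0.2; modality label smoothing 0.01; 8 marker channels dropped
#' per cell per draw (clipped so at least one channel always remains);
#' Gaussian noise with sd 0.005 added to marker and cell-type embeddings on
#' every batch draw. Loss weights for the phenotype and positivity terms
#' are constant; the adversarial term ramps with the quartic root of the
#' epoch index (see [adversarial_weight()]).
#'
#' @param lr learning rate.
#' @param epochs training epochs.
#' @param batch_size cells per minibatch.
#' @param channel_dropout_k channels dropped per cell per draw.
#' @param embed_noise_sigma sd of embedding noise.
#' @param label_smoothing_pos,label_smoothing_mod smoothing constants.
#' @param gamma focal-loss focusing parameter.
#' @param w_cls,w_pos,w_adv_base loss weights.
#' @param val_fraction held-out fraction per cell type for epoch-level
#'   validation (stratified, seeded).
#' @param augment apply random flips/rotations?
#' @param bn_momentum batch-norm running-statistics momentum.
#' @param seed RNG seed for the whole run (split, shuffling, augmentation,
#'   dropout, noise).
#' @param log_dir optional directory; when set, the run writes a resolved
#'   configuration copy (`config.yaml`) and appends one JSON line per
#'   epoch to `metrics.jsonl`.
#' @return a `phenoclip_train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 20L, batch_size = 64L,
                         channel_dropout_k = 8L, embed_noise_sigma = 0.005,
                         label_smoothing_pos = 0.2,
                         label_smoothing_mod = 0.01, gamma = 2,
                         w_cls = 1, w_pos = 1, w_adv_base = 0.1,
                         val_fraction = 0.1, augment = TRUE,
                         bn_momentum = 0.1, seed = 1L, log_dir = NULL) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1, channel_dropout_k >= 0,
            embed_noise_sigma >= 0, gamma >= 0, w_cls >= 0, w_pos >= 0,
            w_adv_base >= 0, val_fraction > 0, val_fraction < 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 channel_dropout_k = as.integer(channel_dropout_k),
                 embed_noise_sigma = embed_noise_sigma,
                 label_smoothing_pos = label_smoothing_pos,
                 label_smoothing_mod = label_smoothing_mod,
                 gamma = gamma, w_cls = w_cls, w_pos = w_pos,
                 w_adv_base = w_adv_base, val_fraction = val_fraction,
                 augment = isTRUE(augment), bn_momentum = bn_momentum,
                 seed = as.integer(seed), log_dir = log_dir),
            class = "phenoclip_train_config")
}

# ---- RAdam ---------------------------------------------------------------

radam_init <- function() new.env(parent = emptyenv())

radam_step <- function(params, grads, state, t, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  rho_inf <- 2 / (1 - beta2) - 1
  b1t <- beta1^t
  b2t <- beta2^t
  rho <- rho_inf - 2 * t * b2t / (1 - b2t)
  rect <- rho > 5
  if (rect)
    r <- sqrt(((rho - 4) * (rho - 2) * rho_inf) /
              ((rho_inf - 4) * (rho_inf - 2) * rho))
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- state[[paste0("m.", nm)]]
    v <- state[[paste0("v.", nm)]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state[[paste0("m.", nm)]] <- m
    state[[paste0("v.", nm)]] <- v
    mhat <- m / (1 - b1t)
    upd <- if (rect) lr * r * mhat / (sqrt(v / (1 - b2t)) + eps)
           else lr * mhat
    params[[nm]] <- params[[nm]] - upd
  }
  params
}

# ---- augmentation --------------------------------------------------------

# source linear indices (1-based) of the dihedral transform for one 64x64
# plane; code = r + 4*f as in the compute core
aug_index <- function(code, n = 64L) {
  g <- expand.grid(i = 0:(n - 1L), j = 0:(n - 1L))
  si <- g$i; sj <- g$j
  r <- code %% 4L
  for (t in seq_len(r)) {
    ti <- si
    si <- sj
    sj <- n - 1L - ti
  }
  if (code >= 4L) si <- n - 1L - si
  si + n * sj + 1L
}

#' Augment a padded batch
#'
#' Training-time augmentation: a random spatial transform from the dihedral
#' group (flips and 90-degree rotations), applied identically to all three
#' planes of every channel of a cell, plus channel dropout that zeroes `k`
#' randomly chosen real channels and clears their padding-mask bits. At
#' least one channel is always retained. `dropout_k = 0` with `codes = 0`
#' is the identity.
#'
#' @param batch a `padded_batch`.
#' @param codes integer vector (one per cell) of dihedral codes 0..7, or
#'   `NULL` to sample them.
#' @param dropout_k number of channels to drop per cell (clipped per cell).
#' @return the augmented `padded_batch`.
#' @export
augment_batch <- function(batch, codes = NULL, dropout_k = 0L) {
  B <- nrow(batch$padding_mask)
  if (is.null(codes)) codes <- sample(0:7, B, replace = TRUE)
  stopifnot(length(codes) == B, all(codes %in% 0:7))
  n <- dim(batch$tensor)[1]
  for (b in seq_len(B)) {
    if (codes[b] != 0L) {
      idx <- aug_index(codes[b], n)
      sub <- batch$tensor[, , , , b, drop = FALSE]
      dim(sub) <- c(n * n, prod(dim(batch$tensor)[3:4]))
      batch$tensor[, , , , b] <- array(sub[idx, ], c(n, n,
                                                     dim(batch$tensor)[3:4]))
    }
    real <- which(batch$padding_mask[b, ] > 0)
    k_eff <- min(dropout_k, length(real) - 1L)
    if (k_eff > 0) {
      drop <- sample(real, k_eff)
      batch$tensor[, , , drop, b] <- 0
      batch$padding_mask[b, drop] <- 0L
      # dropped channels' text embeddings disappear with their names
      batch$channel_names[[b]] <- batch$channel_names[[b]][-drop]
    }
  }
  batch
}

# ---- training loop -------------------------------------------------------

#' Train a phenotyping model on a processed corpus
#'
#' Runs the full objective: focal CLIP phenotype loss on [CLS]/type-name
#' embedding pairs, smoothed BCE between [CLS]-attention positivity scores
#' and gating labels, and the ramping gradient-reversed modality loss.
#' Cells are split 90/10 (stratified by type, seeded) for epoch-level
#' validation; the parameters with the best validation macro F1 are
#' retained. The run is fully seeded: the same corpus, configs and seed
#' reproduce the history bit-exactly. Inference never uses positivity or
#' modality labels; they enter only through the training losses.
#'
#' @param model a `phenotype_model` from [init_phenotype_model()].
#' @param corpus a `phenoclip_corpus` with cell-type labels (positivity
#'   labels optional).
#' @param config a [train_config()].
#' @param provider embedding provider (its `d_raw` must match the model).
#' @param verbose print per-epoch progress?
#' @return the trained model, with `$history` (per-epoch losses, ramp
#'   weight and validation macro F1), `$types`, `$best_epoch`.
#' @export
fit_phenotype_model <- function(model, corpus, config = train_config(),
                                provider = offline_provider(
                                  model$config$d_raw),
                                verbose = FALSE) {
  tc <- config
  cfg <- model$config
  stopifnot(inherits(corpus, "phenoclip_corpus"),
            inherits(tc, "phenoclip_train_config"))
  if (provider$d_raw != cfg$d_raw)
    stop("provider d_raw (", provider$d_raw, ") != model d_raw (",
         cfg$d_raw, ")", call. = FALSE)
  cells <- corpus$cells
  labeled <- which(!is.na(cells$type))
  if (length(labeled) == 0L)
    stop("corpus has no cell-type labels", call. = FALSE)
  types <- sort(unique(cells$type[labeled]))
  mods <- corpus$modalities
  if (length(mods) > cfg$n_modalities)
    stop("corpus has ", length(mods), " modalities; model allows ",
         cfg$n_modalities, call. = FALSE)
  C_b <- max(lengths(corpus$panels))
  if (C_b > cfg$C_max)
    stop("panel size ", C_b, " exceeds model C_max ", cfg$C_max,
         call. = FALSE)
  if (length(corpus$patch_data) > .Machine$integer.max)
    stop("corpus too large for in-memory training", call. = FALSE)

  marker_embs <- lapply(corpus$panels, function(p)
    term_embedding_matrix(p, "marker", provider))
  type_embs <- term_embedding_matrix(types, "cell_type", provider)

  set.seed(tc$seed)
  val_idx <- integer(0)
  for (ty in types) {
    ids <- labeled[cells$type[labeled] == ty]
    n_val <- max(1L, floor(length(ids) * tc$val_fraction))
    val_idx <- c(val_idx, sample(ids, n_val))
  }
  train_idx <- setdiff(labeled, val_idx)

  type_i <- match(cells$type, types)
  mod_i <- match(cells$modality_id, mods) - 1L
  nC <- cells$n_channels
  offs <- cells$offset
  ds_of <- cells$dataset_id
  sigma <- tc$embed_noise_sigma

  state <- radam_init()
  best <- list(f1 = -Inf, params = model$params, epoch = 0L)
  hist <- NULL
  step <- 0L

  log_con <- NULL
  if (!is.null(tc$log_dir)) {
    dir.create(tc$log_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(yaml::as.yaml(list(
      model = unclass(cfg), train = unclass(tc),
      provider = provider$id,
      data = list(datasets = names(corpus$panels),
                  n_cells = nrow(cells)))),
      file.path(tc$log_dir, "config.yaml"))
    log_con <- file(file.path(tc$log_dir, "metrics.jsonl"), "w")
    on.exit(close(log_con), add = TRUE)
  }

  for (epoch in seq_len(tc$epochs)) {
    lam <- adversarial_weight(epoch, tc$w_adv_base)
    ord <- sample(train_idx)
    nb <- ceiling(length(ord) / tc$batch_size)
    ep <- c(cls = 0, pos = 0, adv = 0, total = 0)
    for (s in seq_len(nb)) {
      idx <- ord[((s - 1L) * tc$batch_size + 1L):
                 min(s * tc$batch_size, length(ord))]
      B <- length(idx)
      aug_codes <- if (tc$augment) sample(0:7, B, replace = TRUE)
                   else rep.int(0L, B)
      Tm <- array(0, c(cfg$d_raw, C_b, B))
      Ty <- matrix(0, B, cfg$d_raw)
      pos_t <- matrix(0, B, C_b)
      pos_lab <- matrix(0, B, C_b)
      parts <- vector("list", B)
      for (b in seq_len(B)) {
        i <- idx[b]
        C <- nC[i]
        keep <- seq_len(C)
        k_eff <- min(tc$channel_dropout_k, C - 1L)
        if (k_eff > 0L) keep <- sort(sample.int(C, C - k_eff))
        parts[[b]] <- list(item = rep.int(b - 1L, length(keep)),
                           slot = keep - 1L,
                           off = as.integer(offs[i] + (keep - 1L) * 12288),
                           aug = rep.int(aug_codes[b], length(keep)))
        ME <- marker_embs[[ds_of[i]]][, keep, drop = FALSE]
        if (sigma > 0) ME <- ME + rnorm(length(ME), 0, sigma)
        Tm[, keep, b] <- ME
        Ty[b, ] <- type_embs[, type_i[i]] +
                   if (sigma > 0) rnorm(cfg$d_raw, 0, sigma) else 0
        pv <- corpus$positivity[i, seq_len(C)]
        lab <- intersect(which(!is.na(pv)), keep)
        if (length(lab)) {
          pos_t[b, lab] <- pv[lab]
          pos_lab[b, lab] <- 1
        }
      }
      ix <- list(off = unlist(lapply(parts, `[[`, "off")),
                 item = unlist(lapply(parts, `[[`, "item")),
                 slot = unlist(lapply(parts, `[[`, "slot")),
                 aug = unlist(lapply(parts, `[[`, "aug")))
      out <- run_core(model, corpus$patch_data, ix, B, Tm, Ty, pos_t,
                      pos_lab, mod_y = mod_i[idx],
                      loss_cfg = list(w_cls = tc$w_cls, w_pos = tc$w_pos,
                                      lambda = lam, gamma = tc$gamma,
                                      smooth_pos = tc$label_smoothing_pos,
                                      smooth_mod = tc$label_smoothing_mod,
                                      eps_clip = 1e-6),
                      training = TRUE, want_grads = TRUE,
                      bn_momentum = tc$bn_momentum)
      if (!is.finite(out$loss_total)) {
        terms <- c(cls = out$loss_cls, pos = out$loss_pos,
                   adv = out$loss_adv)
        stop("non-finite loss term: ",
             paste(names(terms)[!is.finite(terms)], collapse = ", "),
             call. = FALSE)
      }
      step <- step + 1L
      model$params <- radam_step(model$params, out$grads, state, step,
                                 tc$lr)
      for (nm in names(out$bn_updates))
        model$params[[nm]] <- out$bn_updates[[nm]]
      ep <- ep + B * c(out$loss_cls, out$loss_pos, out$loss_adv,
                       out$loss_total)
    }
    ep <- ep / length(ord)

    val <- forward_cells(model, corpus, val_idx, marker_embs, C_b)
    pred <- classify_cls(val$cls, model$params, type_embs, types)
    f1 <- evaluate_classification(pred$predicted, cells$type[val_idx],
                                  min_support = 0)$macro_f1
    hist <- rbind(hist, data.frame(
      epoch = epoch, loss_cls = ep[["cls"]], loss_pos = ep[["pos"]],
      loss_adv = ep[["adv"]], loss_total = ep[["total"]], lambda = lam,
      val_macro_f1 = f1))
    if (!is.null(log_con))
      writeLines(jsonlite::toJSON(as.list(hist[nrow(hist), ]),
                                  auto_unbox = TRUE, digits = NA,
                                  dataframe = "rows"), log_con)
    if (verbose)
      message(sprintf(
        "epoch %2d  loss %.4f (cls %.4f pos %.4f adv %.4f)  val F1 %.3f",
        epoch, ep[["total"]], ep[["cls"]], ep[["pos"]], ep[["adv"]], f1))
    if (f1 >= best$f1)
      best <- list(f1 = f1, params = model$params, epoch = epoch)
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  model$history <- hist
  model$types <- types
  model$provider_id <- provider$id
  model$trained <- TRUE
  model
}

# Eval-mode forward over corpus rows (no augmentation, dropout or noise).
# Returns cls (d x n), positivity and raw attention (n x C_b), modality
# logits (K x n).
forward_cells <- function(model, corpus, idx, marker_embs, C_b,
                          chunk = 256L) {
  cfg <- model$config
  cells <- corpus$cells
  d <- cfg$d_model
  n <- length(idx)
  cls <- matrix(0, d, n)
  posit <- matrix(NA_real_, n, C_b)
  attn <- matrix(NA_real_, n, C_b)
  mlog <- matrix(0, cfg$n_modalities, n)
  for (s in seq_len(ceiling(n / chunk))) {
    rows <- ((s - 1L) * chunk + 1L):min(s * chunk, n)
    sub <- idx[rows]
    B <- length(sub)
    Tm <- array(0, c(cfg$d_raw, C_b, B))
    parts <- vector("list", B)
    for (b in seq_len(B)) {
      i <- sub[b]
      C <- cells$n_channels[i]
      parts[[b]] <- list(item = rep.int(b - 1L, C), slot = 0:(C - 1L),
                         off = as.integer(cells$offset[i] +
                                          (0:(C - 1L)) * 12288))
      Tm[, seq_len(C), b] <- marker_embs[[cells$dataset_id[i]]]
    }
    ix <- list(off = unlist(lapply(parts, `[[`, "off")),
               item = unlist(lapply(parts, `[[`, "item")),
               slot = unlist(lapply(parts, `[[`, "slot")))
    out <- run_core(model, corpus$patch_data, ix, B, Tm, training = FALSE)
    cls[, rows] <- out$cls
    posit[rows, ] <- out$positivity[, seq_len(C_b), drop = FALSE]
    attn[rows, ] <- out$attn_raw[, seq_len(C_b), drop = FALSE]
    mlog[, rows] <- out$mod_logits
  }
  list(cls = cls, positivity = posit, attn_raw = attn, mod_logits = mlog)
}

# Cosine-similarity classification of [CLS] embeddings against projected
# cell-type name embeddings; ties break to the lowest candidate index.
classify_cls <- function(cls, params, type_embs, types) {
  Tt <- params$txt_W %*% type_embs + params$txt_b
  Tt <- sweep(Tt, 2, pmax(sqrt(colSums(Tt^2)), 1e-12), "/")
  Zn <- sweep(cls, 2, pmax(sqrt(colSums(cls^2)), 1e-12), "/")
  sims <- crossprod(Zn, Tt)          # n x K
  colnames(sims) <- types
  k <- apply(sims, 1L, which.max)
  list(predicted = types[k], similarity = sims)
}
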