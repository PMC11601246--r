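# Shared fixtures and independent oracles. Oracles are written as direct
# elementwise computations (explicit loops, no code shared with the
# implementation under test).

# ---- oracles --------------------------------------------------------------

# brute-force symmetric focal CLIP loss, elementwise
oracle_focal_clip <- function(I, T, gamma, tau) {
  N <- nrow(I)
  In <- I
  Tn <- T
  for (i in seq_len(N)) {
    In[i, ] <- I[i, ] / sqrt(sum(I[i, ]^2))
    Tn[i, ] <- T[i, ] / sqrt(sum(T[i, ]^2))
  }
  S <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    S[i, j] <- sum(In[i, ] * Tn[j, ]) / tau
  side <- function(M) {
    tot <- 0
    for (i in seq_len(N)) {
      e <- exp(M[i, ] - max(M[i, ]))
      p <- e[i] / sum(e)
      tot <- tot + (1 - p)^gamma * (-log(p))
    }
    tot / N
  }
  (side(S) + side(t(S))) / 2
}

# plain symmetric CLIP cross-entropy (no focal weighting), coded separately
oracle_plain_clip <- function(I, T, tau) {
  N <- nrow(I)
  In <- t(apply(I, 1, function(r) r / sqrt(sum(r^2))))
  Tn <- t(apply(T, 1, function(r) r / sqrt(sum(r^2))))
  S <- In %*% t(Tn) / tau
  ce_rows <- function(M) {
    out <- 0
    for (i in seq_len(N)) {
      out <- out - log(exp(M[i, i]) / sum(exp(M[i, ])))
    }
    out / N
  }
  (ce_rows(S) + ce_rows(t(S))) / 2
}

# per-element smoothed BCE oracle
oracle_bce <- function(scores, targets, mask, smoothing, eps = 1e-6) {
  tot <- 0
  n <- 0
  for (i in seq_len(nrow(scores))) for (j in seq_len(ncol(scores))) {
    if (mask[i, j] != 1) next
    n <- n + 1
    tp <- targets[i, j] * (1 - smoothing) + smoothing / 2
    s <- min(max(scores[i, j], eps), 1 - eps)
    tot <- tot - (tp * log(s) + (1 - tp) * log(1 - s))
  }
  tot / n
}

# nearest-source-center index map for nearest-neighbor resampling; exact
# half-distance ties resolve to the upper neighbor (the documented rule)
oracle_resample_index <- function(n, s) {
  n_out <- max(1L, floor(n * s + 0.5))
  vapply(seq_len(n_out) - 1L, function(i) {
    dst_center <- (i + 0.5) / s          # in source pixel units
    d <- abs((seq_len(n) - 0.5) - dst_center)
    max(which(d <= min(d) + 1e-9))
  }, 0L)
}

# brute-force 99th-percentile clip + min-max rescale
oracle_normalize <- function(ch, probs = 0.99) {
  nz <- sort(ch[ch > 0])
  if (length(nz) == 0) return(ch)
  # linear-interpolation (type 7) percentile, computed directly
  h <- (length(nz) - 1) * probs
  lo <- floor(h)
  q <- nz[lo + 1] + (h - lo) * (nz[min(lo + 2, length(nz))] - nz[lo + 1])
  x <- pmin(ch, q)
  if (max(x) <= min(x)) {
    x[] <- 0
    return(x)
  }
  (x - min(x)) / (max(x) - min(x))
}

# conv output-size arithmetic, independent of the compute core: enumerate
# the 3-wide windows that fit inside the zero-padded axis [-1, H]
oracle_conv_out <- function(H, stride) {
  count <- 0L
  for (o in 0:(H + 2)) {
    lo <- o * stride - 1L
    hi <- lo + 2L
    if (lo >= -1L && hi <= H) count <- count + 1L
  }
  count
}

# ---- small model / batch builders ----------------------------------------

tiny_config <- function(seed = 1L, C_max = 6L, n_modalities = 2L,
                        d_model = 16L, n_layers = 2L) {
  big <- d_model >= 32L
  model_config(d_model = d_model, n_layers = n_layers,
               ff_dim = if (big) 48L else 24L,
               n_heads = if (big) 4L else 2L,
               cnn_widths = if (big) c(8L, 16L) else c(4L, 8L),
               cnn_strides = c(2L, 2L), pool_in = 2L, C_max = C_max,
               d_raw = 32L, n_modalities = n_modalities, mlp_hidden = 16L,
               seed = seed)
}

# a padded batch of random patches with the given per-item channel counts
random_batch <- function(channel_counts, C_max = max(channel_counts),
                         seed = 99L, markers = NULL) {
  set.seed(seed)
  if (is.null(markers))
    markers <- paste0("M", seq_len(max(channel_counts)))
  patches <- lapply(seq_along(channel_counts), function(b) {
    C <- channel_counts[b]
    structure(list(
      tensor = array(runif(64 * 64 * 3 * C), c(64, 64, 3, C)),
      channel_names = markers[seq_len(C)], cell_id = b,
      centroid = c(row = 32, col = 32), dataset_id = "dsA",
      modality_id = "m1", tissue_id = "t1", label = NULL,
      positivity = NULL), class = "cell_patch")
  })
  pad_batch(patches, C_max = C_max)
}

# ---- shared mini synthetic spec (fast module tests) -----------------------

mini_spec <- function(seed = 5L, noise = TRUE) {
  markers <- c("CD45", "CD3", "CD20", "Pan-Keratin")
  types <- c("B cell", "Epithelial", "T cell")
  prof <- matrix(log(0.02), 3, 4, dimnames = list(types, markers))
  prof["T cell", c("CD45", "CD3")] <- log(0.7)
  prof["B cell", c("CD45", "CD20")] <- log(0.7)
  prof["Epithelial", "Pan-Keratin"] <- log(0.7)
  synthetic_spec(
    master_panel = markers, cell_types = types, profile = prof,
    panels = list(dsA = markers, dsB = markers[c(1, 2, 4)]),
    modalities = list(
      m1 = list(gain = 1, offset = if (noise) 0.005 else 0, blur = 0),
      m2 = list(gain = 1.5, offset = if (noise) 0.02 else 0, blur = 0.7)),
    dataset_modality = c(dsA = "m1", dsB = "m2"),
    dataset_tissue = c(dsA = "tonsil", dsB = "lung"),
    dataset_mpp = c(dsA = 0.5, dsB = 0.5),
    cells_per_fov = 25L, fovs_per_dataset = 2L, fov_size = 128L,
    jitter_sd = if (noise) 0.2 else 0,
    noise_sigma = if (noise) 0.01 else 0,
    spillover = list(), seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())

# memoised mini corpus shared across test files
mini_corpus <- function() {
  if (is.null(.fixture_env$mini_corpus))
    .fixture_env$mini_corpus <- make_corpus(mini_spec())
  .fixture_env$mini_corpus
}

# a small trained model shared by the inference and CLI tests
trained_mini <- function() {
  if (is.null(.fixture_env$trained_mini)) {
    corpus <- mini_corpus()
    prov <- offline_provider(32L)
    model <- init_phenotype_model(tiny_config(seed = 2L, C_max = 4L))
    fit <- fit_phenotype_model(
      model, corpus,
      train_config(lr = 1e-2, epochs = 6L, batch_size = 50L,
                   channel_dropout_k = 1L, seed = 5L), prov)
    .fixture_env$trained_mini <- list(fit = fit, corpus = corpus,
                                      prov = prov)
  }
  .fixture_env$trained_mini
}

# 200 labeled cells of 3 well-separated types in a single dataset, for
# optimization smoke tests
smoke_corpus <- function() {
  if (is.null(.fixture_env$smoke_corpus)) {
    spec <- mini_spec()
    spec$panels <- spec$panels["dsA"]
    spec$dataset_modality <- spec$dataset_modality["dsA"]
    spec$dataset_tissue <- spec$dataset_tissue["dsA"]
    spec$dataset_mpp <- spec$dataset_mpp["dsA"]
    spec$cells_per_fov <- 50L
    spec$fovs_per_dataset <- 4L
    spec$fov_size <- 160L
    .fixture_env$smoke_corpus <- make_corpus(spec)
  }
  .fixture_env$smoke_corpus
}
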