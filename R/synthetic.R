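#' Synthetic multiplexed-image corpora with known ground truth
#'
#' `synthetic_spec()` describes a generative benchmark: a master marker
#' panel, cell types with log-intensity expression profiles, per-dataset
#' panel subsets, imaging-platform effects (gain, offset, blur), staining
#' noise, channel spillover and cell geometry. Cells are strictly positive
#' log-normal emitters (heavy-tailed like real staining), rendered as
#' non-overlapping random ellipses, some adjacent to the image boundary so
#' patch padding is exercised. The generator exists so that every pipeline
#' stage — preprocessing, training, zero-shot inference, positivity — can
#' be tested against exact truth without downloads.
#'
#' @param master_panel character vector of M marker names.
#' @param cell_types character vector of K type names.
#' @param profile K x M matrix of mean log-intensities (dimnames required).
#' @param panels named list (dataset id -> subset of `master_panel`).
#' @param modalities named list (modality id -> list(gain, offset, blur)).
#' @param dataset_modality,dataset_tissue,dataset_mpp named character /
#'   numeric vectors keyed by dataset id.
#' @param cells_per_fov,fovs_per_dataset,fov_size scene geometry.
#' @param cell_radius_range major-axis radius range in pixels.
#' @param jitter_sd per-cell log-intensity jitter.
#' @param noise_sigma additive Gaussian background noise sd.
#' @param spillover list of `list(src, dst, frac)` channel-leakage entries.
#' @param spillover_sigma Gaussian blur sd of the leaked signal.
#' @param type_props sampling proportions over cell types.
#' @param pos_threshold log-intensity above which a marker counts positive
#'   in the truth table.
#' @param seed corpus seed.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(master_panel, cell_types, profile, panels,
                           modalities, dataset_modality, dataset_tissue,
                           dataset_mpp, cells_per_fov = 50L,
                           fovs_per_dataset = 10L, fov_size = 256L,
                           cell_radius_range = c(4, 8), jitter_sd = 0.25,
                           noise_sigma = 0.01, spillover = list(),
                           spillover_sigma = 1, type_props = NULL,
                           pos_threshold = log(0.1), seed = 42L) {
  stopifnot(is.matrix(profile),
            nrow(profile) == length(cell_types),
            ncol(profile) == length(master_panel))
  dimnames(profile) <- list(cell_types, master_panel)
  for (p in panels)
    if (!all(p %in% master_panel))
      stop("every panel must be a subset of the master panel",
           call. = FALSE)
  bits <- profile > pos_threshold
  if (any(duplicated(bits)))
    stop("thresholded profiles must be pairwise distinct", call. = FALSE)
  stopifnot(jitter_sd >= 0, noise_sigma >= 0, spillover_sigma >= 0,
            all(names(dataset_modality) == names(panels)),
            all(unlist(dataset_modality) %in% names(modalities)))
  if (is.null(type_props))
    type_props <- rep(1 / length(cell_types), length(cell_types))
  structure(list(master_panel = master_panel, cell_types = cell_types,
                 profile = profile, panels = panels,
                 modalities = modalities,
                 dataset_modality = dataset_modality,
                 dataset_tissue = dataset_tissue,
                 dataset_mpp = dataset_mpp,
                 cells_per_fov = as.integer(cells_per_fov),
                 fovs_per_dataset = as.integer(fovs_per_dataset),
                 fov_size = as.integer(fov_size),
                 cell_radius_range = cell_radius_range,
                 jitter_sd = jitter_sd, noise_sigma = noise_sigma,
                 spillover = spillover,
                 spillover_sigma = spillover_sigma,
                 type_props = type_props, pos_threshold = pos_threshold,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' The canonical desk-scale benchmark spec
#'
#' Twelve immune/stromal/epithelial markers, four well-separated cell
#' types (T cell, B cell, macrophage, epithelial), three datasets with
#' panels of 12, 9 and 7 markers, two imaging modalities with different
#' gain/offset/blur, ~500 cells per dataset. The 7-marker dataset shares
#' its modality with the first dataset and is conventionally held out for
#' zero-shot evaluation: its exact panel never occurs in training.
#'
#' @param seed corpus seed.
#' @return a `synthetic_spec`.
#' @export
default_benchmark_spec <- function(seed = 42L) {
  markers <- c("CD45", "CD3", "CD4", "CD8", "CD20", "CD68", "CD11c",
               "Pan-Keratin", "E-cadherin", "Vimentin", "CD31", "aSMA")
  types <- c("B cell", "Epithelial", "Macrophage", "T cell")
  on <- log(0.7)
  off <- log(0.02)
  prof <- matrix(off, length(types), length(markers),
                 dimnames = list(types, markers))
  prof["T cell", c("CD45", "CD3", "CD4", "CD8")] <- on
  prof["B cell", c("CD45", "CD20")] <- on
  prof["Macrophage", c("CD45", "CD68", "CD11c")] <- on
  prof["Epithelial", c("Pan-Keratin", "E-cadherin")] <- on
  synthetic_spec(
    master_panel = markers, cell_types = types, profile = prof,
    panels = list(
      ds1 = markers,
      ds2 = c("CD45", "CD3", "CD4", "CD8", "CD20", "CD68", "CD11c",
              "Pan-Keratin", "E-cadherin"),
      ds3 = c("CD45", "CD3", "CD4", "CD20", "CD68", "Pan-Keratin",
              "E-cadherin")),
    modalities = list(
      codex = list(gain = 1.0, offset = 0.005, blur = 0.5),
      mibi = list(gain = 1.7, offset = 0.03, blur = 1.0)),
    dataset_modality = c(ds1 = "codex", ds2 = "mibi", ds3 = "codex"),
    dataset_tissue = c(ds1 = "tonsil", ds2 = "lung", ds3 = "intestine"),
    dataset_mpp = c(ds1 = 0.5, ds2 = 0.5, ds3 = 0.5),
    cells_per_fov = 50L, fovs_per_dataset = 10L, fov_size = 256L,
    spillover = list(list(src = "CD4", dst = "CD8", frac = 0.05),
                     list(src = "Pan-Keratin", dst = "E-cadherin",
                          frac = 0.05)),
    seed = seed)
}

#' Render one synthetic field of view
#'
#' Places non-overlapping random ellipses by rejection sampling, fills each
#' cell's panel markers with `exp(profile + jitter)`, leaks designated
#' channel pairs (Gaussian-blurred spillover), applies the dataset's
#' modality transform (blur, then gain and offset) and additive background
#' noise. Uses the current RNG stream unless `seed` is given.
#'
#' @param spec a `synthetic_spec`.
#' @param dataset dataset id (name in `spec$panels`).
#' @param seed optional seed for this FOV.
#' @return list with `image` ([fov_image]), `mask`
#'   ([segmentation_mask]) and `truth` (data.frame: cell_id, cell_type,
#'   centroid and one `pos_<marker>` column per panel marker).
#' @export
render_fov <- function(spec, dataset, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!dataset %in% names(spec$panels))
    stop("unknown dataset '", dataset, "'", call. = FALSE)
  panel <- spec$panels[[dataset]]
  modal <- spec$modalities[[spec$dataset_modality[[dataset]]]]
  H <- spec$fov_size
  n <- spec$cells_per_fov
  rr <- spec$cell_radius_range

  # Poisson-disk style rejection placement (bounded retries)
  ctr <- matrix(0, n, 2)
  a <- numeric(n)
  b <- numeric(n)
  th <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 300L * n
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    ai <- runif(1, rr[1], rr[2])
    ci <- runif(2, 3, H - 4)
    if (placed > 0L) {
      dmin <- sqrt((ctr[seq_len(placed), 1] - ci[1])^2 +
                   (ctr[seq_len(placed), 2] - ci[2])^2)
      if (any(dmin < a[seq_len(placed)] + ai + 1)) next
    }
    placed <- placed + 1L
    ctr[placed, ] <- ci
    a[placed] <- ai
    b[placed] <- ai * runif(1, 0.6, 1)
    th[placed] <- runif(1, 0, pi)
  }
  if (placed < n)
    stop("infeasible packing: placed ", placed, " of ", n,
         " cells after ", max_tries, " tries", call. = FALSE)

  labels <- matrix(0L, H, H)
  for (k in seq_len(n)) {
    i0 <- max(0, floor(ctr[k, 1] - a[k]))
    i1 <- min(H - 1, ceiling(ctr[k, 1] + a[k]))
    j0 <- max(0, floor(ctr[k, 2] - a[k]))
    j1 <- min(H - 1, ceiling(ctr[k, 2] + a[k]))
    ii <- i0:i1
    jj <- j0:j1
    dx <- outer(ii - ctr[k, 1], rep(1, length(jj)))
    dy <- outer(rep(1, length(ii)), jj - ctr[k, 2])
    u <- dx * cos(th[k]) + dy * sin(th[k])
    v <- -dx * sin(th[k]) + dy * cos(th[k])
    inside <- (u / a[k])^2 + (v / b[k])^2 <= 1
    sub <- labels[ii + 1L, jj + 1L]
    sub[inside & sub == 0L] <- k
    labels[ii + 1L, jj + 1L] <- sub
  }

  type_k <- sample(spec$cell_types, n, replace = TRUE,
                   prob = spec$type_props)
  # per-cell per-marker intensities (log-normal around the profile)
  inten <- exp(spec$profile[type_k, panel, drop = FALSE] +
               matrix(rnorm(n * length(panel), 0, spec$jitter_sd), n))

  fg <- which(labels > 0L)
  lab_fg <- labels[fg]
  px <- array(0, c(H, H, length(panel)))
  for (m in seq_along(panel)) {
    img <- matrix(0, H, H)
    img[fg] <- inten[lab_fg, m]
    px[, , m] <- img
  }
  # channel spillover: blurred leakage between designated pairs
  for (sp in spec$spillover) {
    si <- match(sp$src, panel)
    di <- match(sp$dst, panel)
    if (is.na(si) || is.na(di)) next
    leak <- px[, , si]
    if (spec$spillover_sigma > 0)
      leak <- as.matrix(EBImage::gblur(leak, spec$spillover_sigma))
    px[, , di] <- px[, , di] + sp$frac * leak
  }
  # modality transform and background noise
  for (m in seq_along(panel)) {
    img <- px[, , m]
    if (modal$blur > 0) img <- as.matrix(EBImage::gblur(img, modal$blur))
    img <- modal$gain * img + modal$offset
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(H * H, 0, spec$noise_sigma), H, H)
    px[, , m] <- pmax(img, 0)
  }

  pos <- spec$profile[type_k, panel, drop = FALSE] > spec$pos_threshold
  truth <- data.frame(cell_id = seq_len(n), cell_type = type_k,
                      centroid_row = ctr[, 1], centroid_col = ctr[, 2],
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(pos * 1,
                                      col.names = paste0("pos_", panel)))
  names(truth)[-(1:4)] <- paste0("pos_", panel)

  image <- fov_image(px, mpp = spec$dataset_mpp[[dataset]],
                     panel = marker_panel(panel),
                     modality_id = spec$dataset_modality[[dataset]],
                     tissue_id = spec$dataset_tissue[[dataset]],
                     dataset_id = dataset)
  list(image = image, mask = segmentation_mask(labels), truth = truth)
}

#' Render every field of view of a spec
#'
#' Reproduces the exact FOV sequence underlying [make_corpus()] (same seed,
#' same order), returning raw images, masks and truth tables. Useful when a
#' second representation of the same cells is needed, e.g. mean-intensity
#' feature tables for baseline classifiers.
#'
#' @param spec a `synthetic_spec`.
#' @return list of `list(image, mask, truth)` in dataset/FOV order.
#' @export
render_corpus_fovs <- function(spec) {
  set.seed(spec$seed)
  out <- list()
  for (d in names(spec$panels))
    for (f in seq_len(spec$fovs_per_dataset)) {
      rf <- render_fov(spec, d)
      rf$fov <- f
      out[[length(out) + 1L]] <- rf
    }
  out
}

#' Build a processed corpus from a synthetic spec
#'
#' Runs the real preprocessing path end to end on freshly rendered FOVs:
#' resampling to 0.5 microns per pixel where needed, percentile min-max
#' normalization per channel per FOV, and 64x64 patch extraction with
#' self/neighbor masks. The resulting corpus holds the flat patch store,
#' per-cell metadata, truth labels and positivity bits, and records the
#' generating spec for provenance. Fully determined by `spec$seed`.
#'
#' @param spec a `synthetic_spec`.
#' @param store_path optional directory; when given the corpus is also
#'   written as a chunked store ([write_corpus_store()]).
#' @return a `phenoclip_corpus`.
#' @export
make_corpus <- function(spec, store_path = NULL) {
  ds_ids <- names(spec$panels)
  n_per_fov <- spec$cells_per_fov
  total <- sum(vapply(ds_ids, function(d)
    spec$fovs_per_dataset * n_per_fov * length(spec$panels[[d]]), 0))
  patch_data <- numeric(total * 12288)
  cell_rows <- list()
  pos_list <- list()
  cur <- 0
  gid <- 0L
  max_C <- max(lengths(spec$panels))
  fovs <- render_corpus_fovs(spec)
  for (rf in fovs) {
    {
      d <- rf$image$dataset_id
      f <- rf$fov
      C <- length(spec$panels[[d]])
      img <- rf$image
      msk <- rf$mask
      if (img$mpp != 0.5) {
        msk <- resample_to_mpp(msk, 0.5, mpp = img$mpp)
        img <- resample_to_mpp(img, 0.5)
      }
      img <- normalize_fov(img)
      posm <- as.matrix(rf$truth[, paste0("pos_", spec$panels[[d]])])
      for (k in rf$truth$cell_id) {
        p <- extract_patch(img, msk, k)
        gid <- gid + 1L
        n_el <- C * 12288
        patch_data[(cur + 1):(cur + n_el)] <- as.numeric(p$tensor)
        cell_rows[[gid]] <- data.frame(
          cell_id = gid, dataset_id = d, fov = f, fov_cell = k,
          modality_id = img$modality_id, tissue_id = img$tissue_id,
          type = rf$truth$cell_type[k], offset = cur, n_channels = C,
          stringsAsFactors = FALSE)
        row <- rep(NA_real_, max_C)
        row[seq_len(C)] <- posm[k, ]
        pos_list[[gid]] <- row
        cur <- cur + n_el
      }
    }
  }
  cells <- do.call(rbind, cell_rows)
  corpus <- structure(list(
    patch_data = patch_data, cells = cells,
    panels = spec$panels,
    positivity = do.call(rbind, pos_list),
    types = sort(unique(cells$type)),
    modalities = sort(unique(cells$modality_id)),
    spec = spec), class = "phenoclip_corpus")
  if (!is.null(store_path)) write_corpus_store(corpus, store_path)
  corpus
}

#' @export
print.phenoclip_corpus <- function(x, ...) {
  cat(sprintf(
    "<phenoclip_corpus> %d cells, %d datasets (panels %s), %d modalities\n",
    nrow(x$cells), length(x$panels),
    paste(lengths(x$panels), collapse = "/"), length(x$modalities)))
  invisible(x)
}

# patch tensor of corpus cell i, dim (64, 64, 3, C)
corpus_patch <- function(corpus, i) {
  C <- corpus$cells$n_channels[i]
  off <- corpus$cells$offset[i]
  array(corpus$patch_data[(off + 1):(off + C * 12288)], c(64, 64, 3, C))
}

#' Write a synthetic corpus as on-disk images
#'
#' Renders every FOV of the spec and writes OME-style multi-channel TIFFs,
#' channel-name sidecar CSVs, integer mask TIFFs, truth CSVs and the
#' resolved spec, mirroring the layout of a real acquisition.
#'
#' @param spec a `synthetic_spec`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
simulate_to_dir <- function(spec, out_dir) {
  set.seed(spec$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(spec$panels)) {
    dd <- file.path(out_dir, d)
    dir.create(dd, showWarnings = FALSE)
    for (f in seq_len(spec$fovs_per_dataset)) {
      rf <- render_fov(spec, d)
      base <- file.path(dd, sprintf("fov%02d", f))
      write_fov_tiff(rf$image, paste0(base, ".tiff"),
                     paste0(base, "_channels.csv"))
      write_mask_tiff(rf$mask, paste0(base, "_mask.tiff"))
      write.csv(rf$truth, paste0(base, "_truth.csv"), row.names = FALSE)
    }
  }
  writeLines(yaml::as.yaml(list(
    master_panel = spec$master_panel, cell_types = spec$cell_types,
    panels = spec$panels, seed = spec$seed,
    cells_per_fov = spec$cells_per_fov,
    fovs_per_dataset = spec$fovs_per_dataset)),
    file.path(out_dir, "spec.yaml"))
  invisible(out_dir)
}
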