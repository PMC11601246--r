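#' Multi-channel field-of-view images and segmentation masks
#'
#' `fov_image()` bundles a (C, H, W) stack of marker images with its
#' resolution, panel and provenance; `segmentation_mask()` wraps an integer
#' whole-cell label image (0 = background, k > 0 = cell k). Masks are
#' consumed, not produced: segmentation is an upstream tool's job.
#'
#' @param pixels numeric array, dim `(H, W, C)`, non-negative.
#' @param mpp microns per pixel (positive scalar).
#' @param panel a [marker_panel] with one canonical name per channel.
#' @param modality_id,tissue_id,dataset_id provenance strings.
#' @return `fov_image` / `segmentation_mask` objects.
#' @export
fov_image <- function(pixels, mpp, panel, modality_id = "unknown",
                      tissue_id = "unknown", dataset_id = "unknown") {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  stop_if_not_scalar_pos(mpp, "mpp")
  if (!inherits(panel, "marker_panel")) panel <- marker_panel(panel)
  if (dim(pixels)[3] != length(panel$canonical_names))
    stop("channel count does not match panel length", call. = FALSE)
  if (any(pixels < 0) || any(!is.finite(pixels)))
    stop("pixel values must be finite and non-negative", call. = FALSE)
  structure(list(pixels = pixels, mpp = mpp, panel = panel,
                 modality_id = modality_id, tissue_id = tissue_id,
                 dataset_id = dataset_id),
            class = "fov_image")
}

#' @rdname fov_image
#' @param labels integer matrix `(H, W)` of cell labels.
#' @export
segmentation_mask <- function(labels) {
  stopifnot(is.matrix(labels))
  if (any(labels < 0) || any(labels != round(labels)))
    stop("mask labels must be non-negative integers", call. = FALSE)
  structure(list(labels = labels), class = "segmentation_mask")
}

#' @export
print.fov_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fov_image> %dx%d px, %d channels, %.3g mpp (%s / %s / %s)\n",
              d[1], d[2], d[3], x$mpp, x$dataset_id, x$modality_id,
              x$tissue_id))
  invisible(x)
}

#' Read and write multi-channel TIFF images with a channel-name sidecar
#'
#' Channel names come from a sidecar CSV with columns `channel_index`
#' (1-based) and `raw_name`; names are standardized through `alias_map` when
#' one is given.
#'
#' @param path TIFF file (one directory/plane per channel).
#' @param channels_csv sidecar CSV path.
#' @param mpp resolution of the stored image, microns per pixel.
#' @param alias_map optional raw -> canonical map applied to channel names.
#' @param ... provenance fields passed to [fov_image()].
#' @return an [fov_image].
#' @export
read_fov_tiff <- function(path, channels_csv, mpp, alias_map = NULL, ...) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(planes)) planes <- list(planes)
  ch <- read.csv(channels_csv, stringsAsFactors = FALSE)
  if (!all(c("channel_index", "raw_name") %in% names(ch)))
    stop("channels CSV needs columns channel_index, raw_name", call. = FALSE)
  ch <- ch[order(ch$channel_index), ]
  if (nrow(ch) != length(planes))
    stop("channel table rows != TIFF planes", call. = FALSE)
  nms <- ch$raw_name
  if (!is.null(alias_map)) nms <- standardize_names(nms, alias_map)
  px <- array(0, c(dim(planes[[1]])[1:2], length(planes)))
  for (i in seq_along(planes)) {
    p <- planes[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    px[, , i] <- p
  }
  fov_image(px, mpp = mpp, panel = marker_panel(nms), ...)
}

#' @rdname read_fov_tiff
#' @param image an [fov_image] to write.
#' @param bits_per_sample TIFF bit depth (values are scaled to `[0, 1]` by
#'   the channel max before writing when they exceed 1).
#' @export
write_fov_tiff <- function(image, path, channels_csv = NULL,
                           bits_per_sample = 32) {
  px <- image$pixels
  mx <- max(px, 1)
  planes <- lapply(seq_len(dim(px)[3]), function(c) px[, , c] / mx)
  tiff::writeTIFF(planes, path, bits.per.sample = bits_per_sample)
  if (!is.null(channels_csv))
    write.csv(data.frame(channel_index = seq_along(planes),
                         raw_name = image$panel$canonical_names),
              channels_csv, row.names = FALSE)
  invisible(path)
}

#' @rdname read_fov_tiff
#' @export
read_mask_tiff <- function(path, max_label = 65535) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  segmentation_mask(matrix(as.integer(round(m)), nrow(m), ncol(m)))
}

#' @rdname read_fov_tiff
#' @param mask a [segmentation_mask] to write (stored as 16-bit integers).
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a per-cell label table
#'
#' Expected columns: `cell_id`, `cell_type`, plus optional per-marker
#' positivity columns named `pos_<marker>` with values in \{0, 1\}.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cell_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cell_type") %in% names(df)))
    stop("label CSV needs columns cell_id, cell_type", call. = FALSE)
  df
}
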