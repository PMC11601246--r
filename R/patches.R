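#' Extract a single-cell patch from a field of view
#'
#' Returns the cell's 64x64 neighborhood in every channel together with two
#' binary context planes: a self-mask (1 inside the focal cell) and a
#' neighbor-mask (1 inside any other cell). The patch is centered on the
#' integer-rounded mask centroid; coordinates are 0-based and the window is
#' the half-open block `[r - 32, r + 32) x [c - 32, c + 32)`. Regions
#' falling outside the image are zero in all three planes, so boundary
#' cells still yield complete 64x64 patches.
#'
#' @param image an [fov_image] (normally already resampled and normalized).
#' @param mask its [segmentation_mask] (same height/width).
#' @param cell_id positive integer label present in the mask.
#' @param size patch side length in pixels.
#' @return a `cell_patch`: list with `tensor` (array, dim
#'   `(size, size, 3, C)`; plane 1 = marker image, 2 = self-mask,
#'   3 = neighbor-mask), `channel_names`, `cell_id`, `centroid` (0-based
#'   `(row, col)`), and provenance fields.
#' @export
extract_patch <- function(image, mask, cell_id, size = 64L) {
  d <- dim(image$pixels)
  if (!all(dim(mask$labels) == d[1:2]))
    stop("image and mask dimensions differ", call. = FALSE)
  hit <- which(mask$labels == cell_id)
  if (length(hit) == 0L)
    stop("cell_id ", cell_id, " not found in mask", call. = FALSE)
  rows <- (hit - 1L) %% d[1]          # 0-based
  cols <- (hit - 1L) %/% d[1]
  r0 <- as.integer(floor(mean(rows) + 0.5))
  c0 <- as.integer(floor(mean(cols) + 0.5))
  half <- size %/% 2L

  # half-open window in 0-based coordinates, clipped to the image
  rr <- (r0 - half):(r0 + half - 1L)
  cc <- (c0 - half):(c0 + half - 1L)
  rin <- rr >= 0L & rr < d[1]
  cin <- cc >= 0L & cc < d[2]

  C <- d[3]
  tensor <- array(0, c(size, size, 3L, C))
  sub_m <- mask$labels[rr[rin] + 1L, cc[cin] + 1L, drop = FALSE]
  self_w <- matrix(0, size, size)
  neigh_w <- matrix(0, size, size)
  self_w[rin, cin] <- (sub_m == cell_id) * 1
  neigh_w[rin, cin] <- (sub_m > 0 & sub_m != cell_id) * 1
  for (ch in seq_len(C)) {
    plane <- matrix(0, size, size)
    plane[rin, cin] <- image$pixels[rr[rin] + 1L, cc[cin] + 1L, ch]
    tensor[, , 1L, ch] <- plane
    tensor[, , 2L, ch] <- self_w
    tensor[, , 3L, ch] <- neigh_w
  }
  structure(list(tensor = tensor,
                 channel_names = image$panel$canonical_names,
                 cell_id = cell_id,
                 centroid = c(row = r0, col = c0),
                 dataset_id = image$dataset_id,
                 modality_id = image$modality_id,
                 tissue_id = image$tissue_id,
                 label = NULL, positivity = NULL),
            class = "cell_patch")
}

#' Pad a set of cell patches to a fixed channel capacity
#'
#' Stacks patches into a dense batch tensor with `C_max` channel slots.
#' Each patch's real channels occupy the leading slots in panel order; the
#' remaining slots are all-zero and flagged 0 in the padding mask, so the
#' transformer can ignore them.
#'
#' @param patches list of `cell_patch` objects (panels may differ).
#' @param C_max channel capacity (75 by default, comfortably above the
#'   largest panel in common use).
#' @return a `padded_batch`: list with `tensor`
#'   (dim `(64, 64, 3, C_max, B)`), `padding_mask` (`B x C_max`, 1 = real),
#'   `channel_names` (list), and aligned metadata vectors.
#' @export
pad_batch <- function(patches, C_max = 75L) {
  stopifnot(length(patches) >= 1L)
  B <- length(patches)
  size <- dim(patches[[1]]$tensor)[1]
  tensor <- array(0, c(size, size, 3L, C_max, B))
  mask <- matrix(0L, B, C_max)
  nms <- vector("list", B)
  for (b in seq_len(B)) {
    p <- patches[[b]]
    C <- dim(p$tensor)[4]
    if (C > C_max)
      stop("dataset '", p$dataset_id, "' has ", C,
           " channels, exceeding C_max = ", C_max, call. = FALSE)
    tensor[, , , seq_len(C), b] <- p$tensor
    mask[b, seq_len(C)] <- 1L
    nms[[b]] <- p$channel_names
  }
  structure(list(tensor = tensor, padding_mask = mask, channel_names = nms,
                 cell_id = vapply(patches, `[[`, 0, "cell_id"),
                 dataset_id = vapply(patches, `[[`, "", "dataset_id"),
                 modality_id = vapply(patches, `[[`, "", "modality_id"),
                 tissue_id = vapply(patches, `[[`, "", "tissue_id")),
            class = "padded_batch")
}
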