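#' Resample an image or mask to a target resolution
#'
#' All datasets are brought to a standard resolution (0.5 microns per pixel
#' by default) with nearest-neighbor interpolation and no anti-aliasing, so
#' no new intensity values are created and label masks stay label-valued.
#'
#' The grid rule is fixed so results are exactly reproducible: with scale
#' `s = mpp / target_mpp`, the output has `floor(n * s + 0.5)` pixels per
#' axis and output pixel `i` (0-based) reads source pixel
#' `clamp(floor((i + 0.5) / s), 0, n - 1)`. Images and masks use the same
#' index map, keeping them registered.
#'
#' @param x an [fov_image] or [segmentation_mask].
#' @param target_mpp target resolution, microns per pixel.
#' @param mpp for masks (which carry no resolution), the source resolution.
#' @return object of the same class on the new grid.
#' @export
resample_to_mpp <- function(x, target_mpp = 0.5, mpp = NULL) {
  stop_if_not_scalar_pos(target_mpp, "target_mpp")
  if (inherits(x, "fov_image")) {
    s <- x$mpp / target_mpp
    d <- dim(x$pixels)
    ri <- resample_index(d[1], s)
    ci <- resample_index(d[2], s)
    px <- x$pixels[ri, ci, , drop = FALSE]
    out <- x
    out$pixels <- px
    out$mpp <- target_mpp
    return(out)
  }
  if (inherits(x, "segmentation_mask")) {
    stop_if_not_scalar_pos(mpp, "mpp")
    s <- mpp / target_mpp
    ri <- resample_index(nrow(x$labels), s)
    ci <- resample_index(ncol(x$labels), s)
    return(segmentation_mask(x$labels[ri, ci, drop = FALSE]))
  }
  stop("resample_to_mpp expects an fov_image or segmentation_mask",
       call. = FALSE)
}

# 1-based source indices implementing the documented nearest-neighbor rule
resample_index <- function(n, s) {
  n_out <- max(1L, as.integer(floor(n * s + 0.5)))
  i <- seq_len(n_out) - 1L
  src <- floor((i + 0.5) / s)
  pmin(pmax(src, 0), n - 1) + 1L
}

#' Percentile-clipped min-max normalization of one channel
#'
#' Values are clipped at the 99th percentile of the channel's non-zero
#' pixels (linear-interpolation percentile), then min-max scaled to
#' `[0, 1]`. An all-zero channel passes through unchanged; a constant
#' non-zero channel maps to all zeros (the min == max convention), which
#' preserves "no contrast means no signal".
#'
#' @param channel numeric matrix of non-negative finite intensities.
#' @param probs clip percentile (default 0.99).
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_channel <- function(channel, probs = 0.99) {
  nz <- channel[channel > 0]
  if (length(nz) == 0L) return(channel)
  q <- unname(quantile(nz, probs, type = 7))
  x <- pmin(channel, q)
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) {
    x[] <- 0
    return(x)
  }
  (x - lo) / (hi - lo)
}

#' @rdname normalize_channel
#' @param image an [fov_image]; every channel is normalized independently
#'   (per channel per FOV).
#' @export
normalize_fov <- function(image, probs = 0.99) {
  for (c in seq_len(dim(image$pixels)[3]))
    image$pixels[, , c] <- normalize_channel(image$pixels[, , c], probs)
  image
}
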