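#' Focal CLIP contrastive loss
#'
#' Symmetric contrastive loss on N matched (image, text) embedding pairs
#' with a focal weight that down-weights easy pairs. Rows of `I` and `T`
#' are L2-normalized, the similarity matrix `S = I T' / tau` is softmaxed
#' along rows (image side) and columns (text side), and the negative
#' log-likelihood of the diagonal targets is weighted by `(1 - p_t)^gamma`;
#' the two sides are averaged. `gamma = 0` recovers the plain symmetric
#' CLIP cross-entropy; a single pair (`N = 1`) gives exactly zero loss.
#'
#' @param I numeric matrix `(N, d)` of image embeddings.
#' @param T numeric matrix `(N, d)` of matching text embeddings.
#' @param gamma focusing parameter (2 in the reference setting).
#' @param tau temperature (positive).
#' @param want_grads also return analytic gradients?
#' @return loss (scalar), or with `want_grads` a list
#'   `loss, grad_I, grad_T, grad_tau`.
#' @export
focal_clip_loss <- function(I, T, gamma = 2, tau = 0.07,
                            want_grads = FALSE) {
  stopifnot(is.matrix(I), is.matrix(T), all(dim(I) == dim(T)), nrow(I) >= 1)
  stop_if_not_scalar_pos(tau, "tau")
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  out <- cpp_focal_clip(I, T, gamma, tau, want_grads)
  if (out$n_guarded > 0)
    warning(out$n_guarded,
            " zero-norm embedding row(s) guarded with epsilon",
            call. = FALSE)
  if (!want_grads) return(out$loss)
  out[c("loss", "grad_I", "grad_T", "grad_tau")]
}

#' Marker-positivity loss (smoothed binary cross-entropy)
#'
#' Mean binary cross-entropy between attention-derived positivity scores
#' and expert gating labels, restricted to real channels that carry a
#' label. Binary targets t are smoothed to `t (1 - s) + s / 2`; scores are
#' clamped away from 0/1 by `eps` so the loss stays finite when the
#' max-rescaled top channel sits exactly at 1.
#'
#' @param scores numeric matrix `(B, C)` in `[0, 1]` (`NA` allowed on
#'   unlabeled/padded entries).
#' @param targets binary matrix `(B, C)`.
#' @param mask 0/1 matrix flagging entries that are real, labeled channels.
#' @param smoothing label-smoothing s (0.2 in the reference setting).
#' @param eps clamping width.
#' @inheritParams focal_clip_loss
#' @return loss scalar (0 with a warning if no entry is labeled), or a list
#'   with `grad_scores`.
#' @export
positivity_loss <- function(scores, targets, mask, smoothing = 0.2,
                            eps = 1e-6, want_grads = FALSE) {
  stopifnot(all(dim(scores) == dim(targets)), all(dim(scores) == dim(mask)))
  if (sum(mask, na.rm = TRUE) == 0) {
    warning("no labeled channels in batch; positivity loss is 0",
            call. = FALSE)
    if (want_grads)
      return(list(loss = 0, grad_scores = matrix(0, nrow(scores),
                                                 ncol(scores))))
    return(0)
  }
  s <- scores; s[is.na(s)] <- 0
  t <- targets; t[is.na(t)] <- 0
  m <- mask; m[is.na(m)] <- 0
  out <- cpp_bce_smoothed(s, t, m, smoothing, eps, want_grads)
  if (!want_grads) return(out$loss)
  out
}

#' Modality classification loss (smoothed cross-entropy)
#'
#' Cross-entropy of the adversary head's logits against imaging-modality
#' labels, with uniform label smoothing. Used behind the gradient-reversal
#' layer: the head minimizes it while the trunk receives the negated,
#' ramp-scaled gradient.
#'
#' @param logits numeric matrix `(B, K)`.
#' @param targets integer vector of 1-based modality indices.
#' @param smoothing label-smoothing mass (0.01 in the reference setting).
#' @inheritParams focal_clip_loss
#' @export
modality_loss <- function(logits, targets, smoothing = 0.01,
                          want_grads = FALSE) {
  stopifnot(is.matrix(logits), length(targets) == nrow(logits))
  out <- cpp_ce_smoothed(logits, as.integer(targets) - 1L, smoothing,
                         want_grads)
  if (!want_grads) return(out$loss)
  out
}

#' Ramp schedule for the adversarial weight
#'
#' The adversarial term enters with weight `w_adv_base * epoch^(1/4)`
#' (quartic root of the current 1-based epoch index), so early training
#' focuses on phenotyping before modality invariance is enforced. Epoch 0
#' gives weight 0, epoch 1 gives `w_adv_base`, epoch 16 gives
#' `2 w_adv_base`.
#'
#' @param epoch integer epoch index (>= 0).
#' @param w_adv_base base weight.
#' @export
adversarial_weight <- function(epoch, w_adv_base = 0.1) {
  if (any(epoch < 0) || any(epoch != round(epoch)))
    stop("epoch must be a non-negative integer", call. = FALSE)
  w_adv_base * epoch^0.25
}

#' Weighted total training loss
#'
#' `w_cls * L_cls + w_pos * L_pos + adversarial_weight(epoch) * L_adv`,
#' with the per-term breakdown returned alongside. Any non-finite term
#' aborts with the offending term named.
#'
#' @param loss_cls,loss_pos,loss_adv per-term scalar losses.
#' @param weights list with `w_cls`, `w_pos`, `w_adv_base` (all >= 0).
#' @param epoch current 1-based epoch (0 allowed, disabling the adversary).
#' @return list `total`, `breakdown` (named vector of weighted terms).
#' @export
total_loss <- function(loss_cls, loss_pos, loss_adv,
                       weights = list(w_cls = 1, w_pos = 1,
                                      w_adv_base = 0.1),
                       epoch = 1) {
  terms <- c(cls = loss_cls, pos = loss_pos, adv = loss_adv)
  bad <- names(terms)[!is.finite(terms)]
  if (length(bad))
    stop("non-finite loss term: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(unlist(weights) < 0))
    stop("loss weights must be non-negative", call. = FALSE)
  w <- c(cls = weights$w_cls, pos = weights$w_pos,
         adv = adversarial_weight(epoch, weights$w_adv_base))
  list(total = sum(w * terms), breakdown = w * terms)
}
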