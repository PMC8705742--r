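#' Supervised contrastive loss over a multiviewed batch
#'
#' For a batch of `2N` unit-norm embeddings `z_i` (two augmented views per
#' source) with labels `y_i`, let `A(i)` be all indices except `i` and
#' `P(i)` the same-label indices except `i`. The loss is the mean over
#' anchors of
#' \deqn{-\frac{1}{|P(i)|}\sum_{p \in P(i)}
#'   \log\frac{\exp(z_i \cdot z_p/\tau)}{\sum_{a \in A(i)}\exp(z_i \cdot z_a/\tau)}}
#' computed with a numerically stable log-sum-exp (essential at the small
#' default temperature, where `exp(1/tau)` overflows naively). Allows an
#' arbitrary number of positives per anchor and needs no classification
#' head, so model size is independent of the number of identities.
#'
#' @param Z Numeric matrix of embeddings, one unit-norm row each.
#' @param labels Vector of batch labels, one per row of `Z`; every anchor
#'   must have at least one positive.
#' @param tau Positive temperature (default 0.01; smaller temperatures
#'   sharpen the contrast).
#' @param grad If `TRUE`, also return the gradient with respect to `Z`.
#' @return The scalar loss, or (with `grad = TRUE`) a list with `loss`
#'   and `grad` (same shape as `Z`).
#' @export
supcon_loss <- function(Z, labels, tau = 0.01, grad = FALSE) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (length(labels) != n) stop("one label per embedding required")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a positive scalar")
  nrm <- sqrt(rowSums(Z^2))
  if (any(abs(nrm - 1) > 1e-4))
    stop("embeddings must be unit-norm")
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  n_pos <- rowSums(same)
  if (any(n_pos == 0))
    stop("anchor without a positive in the batch (batch construction bug)")
  S <- tcrossprod(Z) / tau
  diag(S) <- -Inf                      # exclude i from A(i)
  mx <- apply(S, 1L, max)
  lse <- mx + log(rowSums(exp(S - mx)))
  log_prob <- S - lse                  # log softmax over A(i)
  lp <- log_prob
  diag(lp) <- 0                        # avoid 0 * -Inf on the diagonal
  loss <- -mean(rowSums(lp * same) / n_pos)
  if (!grad) return(loss)
  P <- exp(log_prob)                   # row-stochastic, zero diagonal
  dS <- (P - same / n_pos) / n         # d loss / d S[i, a]
  dZ <- (dS + t(dS)) %*% Z / tau
  list(loss = loss, grad = dZ)
}
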