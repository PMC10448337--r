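# Task heads on top of the encoder: masked-LM, per-residue classifier,
# [CLS] classifier, and the external-score fusion head, plus their
# training losses with explicit backward passes.

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Masked-language-model head
#'
#' Dense + GELU + layer-norm, then a decoder tied to the token embeddings
#' with a free output bias; rows are softmax-normalized probability
#' distributions over the vocabulary.
#'
#' @param model An `mf_model`.
#' @param hidden_states `n x H` matrix of final-layer hidden vectors.
#' @return `n x vocab_size` matrix of per-position token probabilities
#'   (each row sums to 1).
#' @export
mf_mlm_head <- function(model, hidden_states) {
  p <- model$params
  d <- .dense_fwd(hidden_states, p$mlm.W, p$mlm.b)
  gl <- .gelu_fwd(d$y)
  ln <- .ln_fwd(gl$y, p$mlm_ln.g, p$mlm_ln.b)
  logits <- tcrossprod(ln$y, p$tok_emb)
  logits <- sweep(logits, 2L, p$mlm.bias, "+")
  .softmax_rows(logits)
}

#' Per-residue benign/deleterious probabilities
#'
#' @param model An `mf_model`.
#' @param hidden_states `n x H` matrix of hidden vectors.
#' @return Numeric vector of P(deleterious) per position, in `[0, 1]`.
#' @export
mf_token_head <- function(model, hidden_states) {
  p <- model$params
  as.numeric(.sigmoid(hidden_states %*% p$token.w + p$token.b))
}

#' Whole-sequence deleteriousness probability from the pooled [CLS] vector
#'
#' @param model An `mf_model`.
#' @param pooled `B x H` matrix (or length-H vector) of pooled vectors.
#' @return Numeric vector of P(deleterious) in `[0, 1]`.
#' @export
mf_cls_head <- function(model, pooled) {
  if (is.null(dim(pooled))) pooled <- matrix(pooled, nrow = 1L)
  p <- model$params
  as.numeric(.sigmoid(pooled %*% p$cls.w + p$cls.b))
}

#' Fusion head combining sequence analysis with external predictor scores
#'
#' The standardized external-score vector (values in `{0} U [1, 2]`, 0 =
#' missing) passes through a dense layer whose output width equals the
#' hidden size H, is concatenated with the pooled sequence vector (width
#' H + H, capping the sequence-vs-external capacity at about 1:1), and a
#' final dense layer produces the output probability.
#'
#' @param model An `mf_model` built with `n_external > 0`.
#' @param pooled `B x H` matrix (or length-H vector).
#' @param external `B x n_external` matrix (or vector) of standardized
#'   scores.
#' @return Numeric vector of P(deleterious).
#' @export
mf_fusion_head <- function(model, pooled, external) {
  p <- model$params
  if (is.null(p$fusion.ext_W)) stop("model has no fusion head")
  if (is.null(dim(pooled))) pooled <- matrix(pooled, nrow = 1L)
  if (is.null(dim(external))) external <- matrix(external, nrow = 1L)
  if (ncol(external) != nrow(p$fusion.ext_W)) {
    stop("external score vector length must be ", nrow(p$fusion.ext_W))
  }
  z <- .gelu_fwd(sweep(external %*% p$fusion.ext_W, 2L, p$fusion.ext_b, "+"))$y
  cc <- cbind(pooled, z)
  as.numeric(.sigmoid(cc %*% p$fusion.out_w + p$fusion.out_b))
}

#' Sequence-vs-external weighting of a fusion model
#'
#' Splits the output layer's weight vector at the concatenation boundary
#' and reports the normalized sums of absolute weight magnitudes of the
#' two halves (the sequence-analysis path and the external-prediction
#' path).  An external half whose combining dense layer is entirely zero
#' transmits nothing and contributes zero regardless of its output-layer
#' weights.
#'
#' @param model An `mf_model` with a trained fusion head.
#' @return Named numeric vector `c(w_sequence, w_external)` summing to 1.
#' @export
weighting_analysis <- function(model) {
  p <- model$params
  if (is.null(p$fusion.out_w)) stop("model has no fusion head")
  H <- model$config$hidden_size
  s_seq <- sum(abs(p$fusion.out_w[seq_len(H)]))
  s_ext <- sum(abs(p$fusion.out_w[H + seq_len(H)]))
  if (sum(abs(p$fusion.ext_W)) == 0) s_ext <- 0
  tot <- s_seq + s_ext
  if (tot == 0) stop("fusion layers carry no weight (untrained head?)")
  c(w_sequence = s_seq / tot, w_external = s_ext / tot)
}

# ---- training losses (forward + backward) ---------------------------------

# Masked-LM cross-entropy at selected flat rows of the hidden matrix.
# Returns loss, n correct, d_hidden (full matrix), grads accumulated in g.
.mlm_loss_bwd <- function(model, fw, sel_rows, target_ids, g) {
  p <- model$params
  h <- fw$hidden[sel_rows, , drop = FALSE]
  d <- .dense_fwd(h, p$mlm.W, p$mlm.b)
  gl <- .gelu_fwd(d$y)
  ln <- .ln_fwd(gl$y, p$mlm_ln.g, p$mlm_ln.b)
  logits <- tcrossprod(ln$y, p$tok_emb)
  logits <- sweep(logits, 2L, p$mlm.bias, "+")
  n <- length(sel_rows)
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  tgt1 <- target_ids + 1L
  picked <- logits[cbind(seq_len(n), tgt1)]
  loss <- mean(lse - picked)
  acc <- mean(max.col(logits, ties.method = "first") == tgt1)
  prob <- exp(logits - lse)
  dlogits <- prob
  dlogits[cbind(seq_len(n), tgt1)] <- dlogits[cbind(seq_len(n), tgt1)] - 1
  dlogits <- dlogits / n
  .acc(g, "mlm.bias", colSums(dlogits))
  .acc(g, "tok_emb", crossprod(dlogits, ln$y))   # tied decoder
  dln <- dlogits %*% p$tok_emb
  lb <- .ln_bwd(dln, ln, p$mlm_ln.g)
  .acc(g, "mlm_ln.g", lb$dg); .acc(g, "mlm_ln.b", lb$db)
  dgl <- .gelu_bwd(lb$dx, gl)
  db <- .dense_bwd(dgl, d, p$mlm.W)
  .acc(g, "mlm.W", db$dW); .acc(g, "mlm.b", db$db)
  d_hidden <- matrix(0, nrow(fw$hidden), ncol(fw$hidden))
  d_hidden[sel_rows, ] <- db$dx
  list(loss = loss, accuracy = acc, d_hidden = d_hidden)
}

# Binary cross-entropy on sigmoid(logit); returns loss, probs, dlogit.
.bce <- function(logit, y) {
  p <- .sigmoid(logit)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  list(loss = loss, prob = p, dlogit = (p - y) / length(y))
}

# [CLS]-head (optionally fusion) loss; labels in {0,1} per example.
.cls_loss_bwd <- function(model, fw, labels, g, external = NULL) {
  p <- model$params
  pooled <- fw$pooled
  use_fusion <- !is.null(external)
  if (use_fusion) {
    pre <- sweep(external %*% p$fusion.ext_W, 2L, p$fusion.ext_b, "+")
    gl <- .gelu_fwd(pre)
    cc <- cbind(pooled, gl$y)
    logit <- as.numeric(cc %*% p$fusion.out_w + p$fusion.out_b)
    b <- .bce(logit, labels)
    dcc <- outer(b$dlogit, p$fusion.out_w)
    .acc(g, "fusion.out_w", as.numeric(crossprod(cc, b$dlogit)))
    .acc(g, "fusion.out_b", sum(b$dlogit))
    H <- model$config$hidden_size
    d_pooled <- dcc[, seq_len(H), drop = FALSE]
    dz <- dcc[, H + seq_len(H), drop = FALSE]
    dpre <- .gelu_bwd(dz, gl)
    .acc(g, "fusion.ext_W", crossprod(external, dpre))
    .acc(g, "fusion.ext_b", colSums(dpre))
  } else {
    logit <- as.numeric(pooled %*% p$cls.w + p$cls.b)
    b <- .bce(logit, labels)
    .acc(g, "cls.w", as.numeric(crossprod(pooled, b$dlogit)))
    .acc(g, "cls.b", sum(b$dlogit))
    d_pooled <- outer(b$dlogit, p$cls.w)
  }
  list(loss = b$loss, prob = b$prob, d_pooled = d_pooled)
}

# Per-residue head loss, computed only at the mutation-site rows.
.token_loss_bwd <- function(model, fw, site_rows, labels, g) {
  p <- model$params
  h <- fw$hidden[site_rows, , drop = FALSE]
  logit <- as.numeric(h %*% p$token.w + p$token.b)
  b <- .bce(logit, labels)
  .acc(g, "token.w", as.numeric(crossprod(h, b$dlogit)))
  .acc(g, "token.b", sum(b$dlogit))
  d_hidden <- matrix(0, nrow(fw$hidden), ncol(fw$hidden))
  d_hidden[site_rows, ] <- outer(b$dlogit, p$token.w)
  list(loss = b$loss, prob = b$prob, d_hidden = d_hidden)
}
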