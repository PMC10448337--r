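# Decoupled weight-decay Adam with a linear learning-rate schedule and
# optional global-norm gradient clipping (clipping is used in pre-training
# but not in fine-tuning).

.adam_init <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

# Linear decay from initial_lr to end_lr over total steps.
.lr_at <- function(step, total, initial_lr, end_lr) {
  if (total <= 1L) return(initial_lr)
  frac <- (step - 1) / (total - 1)
  initial_lr + (end_lr - initial_lr) * frac
}

.grad_global_norm <- function(g, names) {
  s <- 0
  for (nm in names) {
    gr <- g[[nm]]
    if (!is.null(gr)) s <- s + sum(gr * gr)
  }
  sqrt(s)
}

# One optimizer step, in place on `model$params`.  `g` is the gradient
# environment from the backward pass.  Frozen parameters and parameters
# without gradients are untouched.  Weight decay applies to matrices only
# (biases and layer-norm vectors are exempt, the BERT convention).
.adam_step <- function(model, g, opt, lr, weight_decay = 0,
                       clip = NULL, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  names <- setdiff(ls(g), model$frozen)
  if (!is.null(clip) && clip > 0) {
    gn <- .grad_global_norm(g, names)
    if (is.finite(gn) && gn > clip) {
      sc <- clip / gn
      for (nm in names) g[[nm]] <- g[[nm]] * sc
    }
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names) {
    gr <- g[[nm]]
    if (is.null(gr)) next
    if (any(!is.finite(gr))) stop("non-finite gradient in ", nm)
    m <- opt$m[[nm]]; v <- opt$v[[nm]]
    if (is.null(m)) { m <- gr * 0; v <- gr * 0 }
    m <- beta1 * m + (1 - beta1) * gr
    v <- beta2 * v + (1 - beta2) * gr * gr
    opt$m[[nm]] <- m; opt$v[[nm]] <- v
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    th <- model$params[[nm]]
    if (weight_decay > 0 && !is.null(dim(th))) upd <- upd + weight_decay * th
    model$params[[nm]] <- th - lr * upd
  }
  model
}
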