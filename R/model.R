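#' Model configuration
#'
#' Architecture hyperparameters fully determining the trainable parameter
#' count.  `conv_mode = "none"` is the plain BERT-style encoder (the
#' "MutBERT" family); `"sequential"` feeds the transformer body from the
#' convolution outputs only; `"integrated"` adds skip connections so the
#' transformer receives the sum of the embedding output and both
#' convolution-operation outputs.
#'
#' @param num_layers Number of transformer encoder layers (published-scale
#'   models use 8/10/12).
#' @param hidden_size Hidden width H (published scale: 768); must be divisible
#'   by `num_heads`.
#' @param intermediate_size Feed-forward inner width (published scale: 3072).
#' @param num_heads Attention heads (default 12, the BERT-Base convention;
#'   unstated for the published models).
#' @param max_positions Maximum aggregate input length S (published scale:
#'   1024).
#' @param vocab_size Token vocabulary size (defaults to the built-in
#'   27-token amino-acid vocabulary).
#' @param conv_mode One of `"none"`, `"sequential"`, `"integrated"`.
#' @param conv_layers Number of convolution layers, grouped into two
#'   operations of `conv_layers / 2` (published models: 4).
#' @param kernel_size Convolution kernel width; must be 3 (odd, as in the
#'   reference architecture).
#' @param dropout Dropout rate used during training (BERT default 0.1).
#' @param n_external Number of external predictor methods wired into the
#'   fusion head (0 = no fusion head).
#' @return An `mf_config` list.
#' @export
mf_config <- function(num_layers, hidden_size, intermediate_size = 4L * hidden_size,
                      num_heads = 12L, max_positions = 1024L,
                      vocab_size = mf_vocab()$size,
                      conv_mode = c("none", "sequential", "integrated"),
                      conv_layers = 4L, kernel_size = 3L,
                      dropout = 0.1, n_external = 0L) {
  conv_mode <- match.arg(conv_mode)
  if (hidden_size %% num_heads != 0L) {
    stop("hidden_size must be divisible by num_heads")
  }
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd")
  if (kernel_size != 3L) stop("only kernel_size = 3 is implemented")
  if (conv_mode != "none" && conv_layers %% 2L != 0L) {
    stop("conv_layers must be even (two stacked operations)")
  }
  structure(list(
    num_layers = as.integer(num_layers),
    hidden_size = as.integer(hidden_size),
    intermediate_size = as.integer(intermediate_size),
    num_heads = as.integer(num_heads),
    max_positions = as.integer(max_positions),
    vocab_size = as.integer(vocab_size),
    conv_mode = conv_mode,
    conv_layers = if (conv_mode == "none") 0L else as.integer(conv_layers),
    kernel_size = as.integer(kernel_size),
    dropout = dropout,
    n_external = as.integer(n_external)
  ), class = "mf_config")
}

#' Read/write a model configuration as JSON
#' @param path File path.
#' @export
mf_read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(mf_config, x[setdiff(names(x), character(0))])
}

#' @rdname mf_read_config
#' @param config An `mf_config`.
#' @export
mf_write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE)
  invisible(path)
}

#' Count trainable parameters
#'
#' Exact closed-form count of the trainable scalars of the pre-training
#' model: embeddings (token, position, segment, embedding layer-norm), the
#' convolution stack if any, the transformer encoder, and the masked-
#' language-model head (dense + layer-norm + decoder bias; decoder weights
#' are tied to the token embeddings and therefore not double-counted).
#' Task heads used only in fine-tuning (pooler, classifiers, fusion) are
#' excluded.
#'
#' @param config An `mf_config`.
#' @return Integer (double) parameter count.
#' @export
#' @examples
#' cfg <- mf_config(num_layers = 8, hidden_size = 768,
#'                  intermediate_size = 3072, max_positions = 1024)
#' round(count_parameters(cfg) / 1e6)  # 58
count_parameters <- function(config) {
  H <- config$hidden_size
  I <- config$intermediate_size
  V <- config$vocab_size
  S <- config$max_positions
  emb <- V * H + S * H + 2 * H + 2 * H
  conv <- if (config$conv_mode == "none") 0 else
    config$conv_layers * (config$kernel_size * H * H + H)
  layer <- 4 * (H * H + H) + 2 * H +   # attention QKV+output, LN
    (H * I + I) + (I * H + H) + 2 * H  # feed-forward, LN
  mlm <- H * H + H + 2 * H + V
  emb + conv + config$num_layers * layer + mlm
}

.n_conv_ops <- function(config) {
  if (config$conv_mode == "none") 0L else 2L
}

.convs_per_op <- function(config) {
  config$conv_layers %/% 2L
}

#' Initialize a model
#'
#' Weights use truncated-normal(sd = 0.02) initialization clipped at two
#' standard deviations; biases zero; layer-norm gains one.  Uses R's RNG:
#' call `set.seed()` first for reproducible initialization.
#'
#' @param config An `mf_config`.
#' @return An `mf_model`: list with `config`, flat named `params` list,
#'   and `frozen` (character vector of non-trainable parameter names).
#' @export
mf_init_model <- function(config) {
  H <- config$hidden_size
  I <- config$intermediate_size
  V <- config$vocab_size
  S <- config$max_positions
  tn <- function(r, c) matrix(.trunc_normal(r * c), r, c)
  p <- list(
    tok_emb = tn(V, H),
    pos_emb = tn(S, H),
    seg_emb = tn(2L, H),
    emb_ln.g = rep(1, H),
    emb_ln.b = rep(0, H)
  )
  if (config$conv_mode != "none") {
    for (k in seq_len(config$conv_layers)) {
      p[[paste0("conv", k, ".Wp")]] <- tn(H, H)
      p[[paste0("conv", k, ".Wc")]] <- tn(H, H)
      p[[paste0("conv", k, ".Wn")]] <- tn(H, H)
      p[[paste0("conv", k, ".b")]] <- rep(0, H)
    }
  }
  for (i in seq_len(config$num_layers)) {
    pre <- paste0("layer", i, ".")
    p[[paste0(pre, "Wq")]] <- tn(H, H); p[[paste0(pre, "bq")]] <- rep(0, H)
    p[[paste0(pre, "Wk")]] <- tn(H, H); p[[paste0(pre, "bk")]] <- rep(0, H)
    p[[paste0(pre, "Wv")]] <- tn(H, H); p[[paste0(pre, "bv")]] <- rep(0, H)
    p[[paste0(pre, "Wo")]] <- tn(H, H); p[[paste0(pre, "bo")]] <- rep(0, H)
    p[[paste0(pre, "ln1.g")]] <- rep(1, H); p[[paste0(pre, "ln1.b")]] <- rep(0, H)
    p[[paste0(pre, "Wi")]] <- tn(H, I); p[[paste0(pre, "bi")]] <- rep(0, I)
    p[[paste0(pre, "Wf")]] <- tn(I, H); p[[paste0(pre, "bf")]] <- rep(0, H)
    p[[paste0(pre, "ln2.g")]] <- rep(1, H); p[[paste0(pre, "ln2.b")]] <- rep(0, H)
  }
  # masked-LM head: dense + GELU + LN, decoder tied to tok_emb, free bias
  p$mlm.W <- tn(H, H); p$mlm.b <- rep(0, H)
  p$mlm_ln.g <- rep(1, H); p$mlm_ln.b <- rep(0, H)
  p$mlm.bias <- rep(0, V)
  # fine-tuning heads (not counted in count_parameters)
  p$pooler.W <- tn(H, H); p$pooler.b <- rep(0, H)
  p$cls.w <- .trunc_normal(H); p$cls.b <- 0
  p$token.w <- .trunc_normal(H); p$token.b <- 0
  if (config$n_external > 0L) {
    p$fusion.ext_W <- tn(config$n_external, H)
    p$fusion.ext_b <- rep(0, H)
    p$fusion.out_w <- .trunc_normal(2L * H)
    p$fusion.out_b <- 0
  }
  structure(list(config = config, params = p, frozen = character(0)),
            class = "mf_model")
}

#' @export
print.mf_model <- function(x, ...) {
  cat("<mf_model> layers=", x$config$num_layers,
      " H=", x$config$hidden_size,
      " conv=", x$config$conv_mode,
      " params(pretrain)=", format(count_parameters(x$config), big.mark = ","),
      if (length(x$frozen)) paste0(" frozen=", length(x$frozen)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Freeze the first n encoder layers (plus embeddings and convolutions)
#'
#' Freezing-layer counts follow the convention that `n` is the number of
#' transformer body layers frozen starting from the first; any `n > 0`
#' also freezes the embedding layers and the convolution stack.  Task
#' heads stay trainable.
#'
#' @param model An `mf_model`.
#' @param n Number of encoder layers to freeze, `0 <= n <= num_layers`.
#' @return The model with its `frozen` name set updated.
#' @export
freeze_layers <- function(model, n) {
  if (n < 0L || n > model$config$num_layers) {
    stop("n must be between 0 and num_layers")
  }
  if (n == 0L) {
    model$frozen <- character(0)
    return(model)
  }
  frozen <- c("tok_emb", "pos_emb", "seg_emb", "emb_ln.g", "emb_ln.b")
  if (model$config$conv_mode != "none") {
    frozen <- c(frozen, grep("^conv", names(model$params), value = TRUE))
  }
  for (i in seq_len(n)) {
    frozen <- c(frozen, grep(paste0("^layer", i, "\\."), names(model$params),
                             value = TRUE))
  }
  model$frozen <- intersect(frozen, names(model$params))
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding the configuration, all
#' weights, and the frozen set.
#'
#' @param model An `mf_model`.
#' @param path Checkpoint file path.
#' @export
mf_save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname mf_save_checkpoint
#' @export
mf_load_checkpoint <- function(path) {
  x <- readRDS(path)
  x$config <- structure(x$config, class = "mf_config")
  structure(x, class = "mf_model")
}

# ---- forward / backward ----------------------------------------------------

.batch_arrays <- function(batch) {
  S <- length(batch[[1]]$token_ids)
  B <- length(batch)
  ids <- matrix(0L, B, S)
  seg <- matrix(0L, B, S)
  msk <- matrix(0L, B, S)
  for (b in seq_len(B)) {
    ex <- batch[[b]]
    if (length(ex$token_ids) != S) stop("batch examples differ in length")
    ids[b, ] <- ex$token_ids
    seg[b, ] <- ex$segment_ids
    msk[b, ] <- ex$attention_mask
  }
  list(ids = ids, seg = seg, msk = msk, S = S, B = B,
       format = batch[[1]]$format)
}

#' Embed a batch of tokenized examples
#'
#' Output is LayerNorm(token + position + label embeddings).  Position 0
#' is always assigned to the first token of the (possibly cropped) input,
#' so positions are relative to the crop, not the full protein.  The label
#' (segment) term is used only for paired input and is identically zero
#' for single-sequence input.
#'
#' @param model An `mf_model`.
#' @param batch List of `mf_example`s of a common length and format.
#' @return `(B*S) x H` matrix of embedded representations (rows grouped by
#'   example).
#' @export
mf_embed <- function(model, batch) {
  fw <- .embed_fwd(model$params, model$config, .batch_arrays(batch),
                   training = FALSE)
  fw$out
}

.embed_fwd <- function(p, config, ba, training) {
  S <- ba$S; B <- ba$B
  if (S > config$max_positions) {
    stop("input length ", S, " exceeds max_positions ", config$max_positions)
  }
  if (any(ba$ids >= config$vocab_size)) stop("token id out of vocabulary")
  idvec <- as.integer(t(ba$ids))            # row-major: example-by-example
  E <- p$tok_emb[idvec + 1L, , drop = FALSE]
  posrows <- rep(seq_len(S), times = B)
  E <- E + p$pos_emb[posrows, , drop = FALSE]
  segvec <- as.integer(t(ba$seg))
  use_seg <- identical(ba$format, "paired")
  if (use_seg) E <- E + p$seg_emb[segvec + 1L, , drop = FALSE]
  ln <- .ln_fwd(E, p$emb_ln.g, p$emb_ln.b)
  dp <- .dropout_fwd(ln$y, config$dropout, training)
  list(out = dp$y, ln = ln, dp = dp, idvec = idvec, posrows = posrows,
       segvec = segvec, use_seg = use_seg)
}

.embed_bwd <- function(dy, cache, p, g) {
  dy <- .dropout_bwd(dy, cache$dp)
  lb <- .ln_bwd(dy, cache$ln, p$emb_ln.g)
  .acc(g, "emb_ln.g", lb$dg); .acc(g, "emb_ln.b", lb$db)
  dE <- lb$dx
  dtok <- rowsum(dE, group = cache$idvec, reorder = FALSE)
  ids_seen <- as.integer(rownames(dtok))
  dT <- matrix(0, nrow(p$tok_emb), ncol(p$tok_emb))
  dT[ids_seen + 1L, ] <- dtok
  .acc(g, "tok_emb", dT)
  dposg <- rowsum(dE, group = cache$posrows, reorder = FALSE)
  dP <- matrix(0, nrow(p$pos_emb), ncol(p$pos_emb))
  dP[as.integer(rownames(dposg)), ] <- dposg
  .acc(g, "pos_emb", dP)
  if (cache$use_seg) {
    dsegg <- rowsum(dE, group = cache$segvec, reorder = FALSE)
    dS <- matrix(0, 2L, ncol(p$seg_emb))
    dS[as.integer(rownames(dsegg)) + 1L, ] <- dsegg
    .acc(g, "seg_emb", dS)
  }
  invisible(NULL)
}

# grad accumulation into an environment keyed by parameter name
.acc <- function(g, name, val) {
  if (is.null(g[[name]])) g[[name]] <- val else g[[name]] <- g[[name]] + val
  invisible(NULL)
}

.mask_rows <- function(x, maskvec) x * maskvec

# One convolution operation = convs_per_op stacked kernel-3 convolutions
# with GELU between (none after the last).  Applied per example to avoid
# cross-example leakage in the row-concatenated batch.
.conv_op_fwd <- function(p, config, x, ba, op_index, maskvec) {
  n_in_op <- .convs_per_op(config)
  first <- (op_index - 1L) * n_in_op + 1L
  S <- ba$S; B <- ba$B
  x <- .mask_rows(x, maskvec)
  caches <- vector("list", n_in_op)
  for (j in seq_len(n_in_op)) {
    k <- first + j - 1L
    Wp <- p[[paste0("conv", k, ".Wp")]]
    Wc <- p[[paste0("conv", k, ".Wc")]]
    Wn <- p[[paste0("conv", k, ".Wn")]]
    bb <- p[[paste0("conv", k, ".b")]]
    y <- matrix(0, nrow(x), ncol(x))
    excache <- vector("list", B)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * S + 1L):(b * S)
      cf <- .conv3_fwd(x[rows, , drop = FALSE], Wp, Wc, Wn, bb)
      y[rows, ] <- cf$y
      excache[[b]] <- cf
    }
    gl <- NULL
    if (j < n_in_op) {
      gl <- .gelu_fwd(y)
      xnext <- gl$y
    } else {
      xnext <- y
    }
    caches[[j]] <- list(conv = excache, gelu = gl, k = k)
    x <- xnext
  }
  x <- .mask_rows(x, maskvec)
  list(out = x, caches = caches)
}

.conv_op_bwd <- function(dy, opcache, p, config, ba, maskvec, g) {
  S <- ba$S; B <- ba$B
  dy <- .mask_rows(dy, maskvec)
  n_in_op <- length(opcache$caches)
  for (j in rev(seq_len(n_in_op))) {
    cc <- opcache$caches[[j]]
    if (!is.null(cc$gelu)) dy <- .gelu_bwd(dy, cc$gelu)
    k <- cc$k
    Wp <- p[[paste0("conv", k, ".Wp")]]
    Wc <- p[[paste0("conv", k, ".Wc")]]
    Wn <- p[[paste0("conv", k, ".Wn")]]
    dx <- matrix(0, nrow(dy), ncol(dy))
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * S + 1L):(b * S)
      cb <- .conv3_bwd(dy[rows, , drop = FALSE], cc$conv[[b]], Wp, Wc, Wn)
      dx[rows, ] <- cb$dx
      .acc(g, paste0("conv", k, ".Wp"), cb$dWp)
      .acc(g, paste0("conv", k, ".Wc"), cb$dWc)
      .acc(g, paste0("conv", k, ".Wn"), cb$dWn)
      .acc(g, paste0("conv", k, ".b"), cb$db)
    }
    dy <- dx
  }
  .mask_rows(dy, maskvec)
}

#' Apply the convolutional "learned vocabulary" block
#'
#' Two convolution operations (each `conv_layers/2` stacked kernel-3,
#' stride-1, same-padding convolutions with GELU between).  In
#' `sequential` mode the output of the stacked operations replaces the
#' embedding output; in `integrated` mode skip connections are added
#' before both operations, so the result is
#' `embedded + op1(embedded) + op2(embedded + op1(embedded))`.
#'
#' @param model An `mf_model` with `conv_mode != "none"`.
#' @param embedded `(B*S) x H` matrix from [mf_embed()].
#' @param batch The same batch of examples (for masks/shapes).
#' @return Shape-preserving `(B*S) x H` matrix.
#' @export
mf_conv_stack <- function(model, embedded, batch) {
  ba <- .batch_arrays(batch)
  maskvec <- as.numeric(t(ba$msk))
  .conv_stack_fwd(model$params, model$config, embedded, ba, maskvec)$out
}

.conv_stack_fwd <- function(p, config, x0, ba, maskvec) {
  if (config$conv_mode == "none") {
    return(list(out = x0, mode = "none"))
  }
  op1 <- .conv_op_fwd(p, config, x0, ba, 1L, maskvec)
  if (config$conv_mode == "sequential") {
    op2 <- .conv_op_fwd(p, config, op1$out, ba, 2L, maskvec)
    return(list(out = op2$out, op1 = op1, op2 = op2, mode = "sequential"))
  }
  x1 <- x0 + op1$out                # skip before operation 1
  op2 <- .conv_op_fwd(p, config, x1, ba, 2L, maskvec)
  x2 <- x1 + op2$out                # skip before operation 2
  list(out = x2, op1 = op1, op2 = op2, mode = "integrated")
}

.conv_stack_bwd <- function(dy, cache, p, config, ba, maskvec, g) {
  if (cache$mode == "none") return(dy)
  if (cache$mode == "sequential") {
    d1 <- .conv_op_bwd(dy, cache$op2, p, config, ba, maskvec, g)
    return(.conv_op_bwd(d1, cache$op1, p, config, ba, maskvec, g))
  }
  # integrated: x2 = x1 + op2(x1); x1 = x0 + op1(x0)
  dx1 <- dy + .conv_op_bwd(dy, cache$op2, p, config, ba, maskvec, g)
  dx0 <- dx1 + .conv_op_bwd(dx1, cache$op1, p, config, ba, maskvec, g)
  dx0
}

.layer_fwd <- function(p, config, X, ba, pre, training) {
  H <- config$hidden_size
  nh <- config$num_heads
  dh <- H %/% nh
  S <- ba$S; B <- ba$B
  q <- .dense_fwd(X, p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]])
  k <- .dense_fwd(X, p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]])
  v <- .dense_fwd(X, p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
  ctx <- matrix(0, nrow(X), H)
  attn <- vector("list", B)
  scale <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * S + 1L):(b * S)
    bias <- (ba$msk[b, ] - 1) * 1e9
    hc <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- q$y[rows, cols, drop = FALSE]
      Kh <- k$y[rows, cols, drop = FALSE]
      Vh <- v$y[rows, cols, drop = FALSE]
      sc <- tcrossprod(Qh, Kh) * scale
      sc <- sweep(sc, 2L, bias, "+")
      P <- .softmax_rows(sc)
      dp <- .dropout_fwd(P, config$dropout, training)
      ctx[rows, cols] <- dp$y %*% Vh
      hc[[h]] <- list(P = P, dp = dp)
    }
    attn[[b]] <- hc
  }
  ao <- .dense_fwd(ctx, p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
  ad <- .dropout_fwd(ao$y, config$dropout, training)
  ln1 <- .ln_fwd(X + ad$y, p[[paste0(pre, "ln1.g")]], p[[paste0(pre, "ln1.b")]])
  ff1 <- .dense_fwd(ln1$y, p[[paste0(pre, "Wi")]], p[[paste0(pre, "bi")]])
  gl <- .gelu_fwd(ff1$y)
  ff2 <- .dense_fwd(gl$y, p[[paste0(pre, "Wf")]], p[[paste0(pre, "bf")]])
  fd <- .dropout_fwd(ff2$y, config$dropout, training)
  ln2 <- .ln_fwd(ln1$y + fd$y, p[[paste0(pre, "ln2.g")]], p[[paste0(pre, "ln2.b")]])
  list(out = ln2$y, q = q, k = k, v = v, attn = attn, ao = ao, ad = ad,
       ln1 = ln1, ff1 = ff1, gl = gl, ff2 = ff2, fd = fd, ln2 = ln2)
}

.layer_bwd <- function(dy, cache, p, config, ba, pre, g) {
  H <- config$hidden_size
  nh <- config$num_heads
  dh <- H %/% nh
  S <- ba$S; B <- ba$B
  scale <- 1 / sqrt(dh)
  l2 <- .ln_bwd(dy, cache$ln2, p[[paste0(pre, "ln2.g")]])
  .acc(g, paste0(pre, "ln2.g"), l2$dg); .acc(g, paste0(pre, "ln2.b"), l2$db)
  dres2 <- l2$dx                               # into ln1$y + fd$y
  dfd <- .dropout_bwd(dres2, cache$fd)
  f2 <- .dense_bwd(dfd, cache$ff2, p[[paste0(pre, "Wf")]])
  .acc(g, paste0(pre, "Wf"), f2$dW); .acc(g, paste0(pre, "bf"), f2$db)
  dgl <- .gelu_bwd(f2$dx, cache$gl)
  f1 <- .dense_bwd(dgl, cache$ff1, p[[paste0(pre, "Wi")]])
  .acc(g, paste0(pre, "Wi"), f1$dW); .acc(g, paste0(pre, "bi"), f1$db)
  dln1y <- dres2 + f1$dx
  l1 <- .ln_bwd(dln1y, cache$ln1, p[[paste0(pre, "ln1.g")]])
  .acc(g, paste0(pre, "ln1.g"), l1$dg); .acc(g, paste0(pre, "ln1.b"), l1$db)
  dres1 <- l1$dx                               # into X + ad$y
  dad <- .dropout_bwd(dres1, cache$ad)
  ab <- .dense_bwd(dad, cache$ao, p[[paste0(pre, "Wo")]])
  .acc(g, paste0(pre, "Wo"), ab$dW); .acc(g, paste0(pre, "bo"), ab$db)
  dctx <- ab$dx
  dQ <- matrix(0, nrow(dctx), H)
  dK <- matrix(0, nrow(dctx), H)
  dV <- matrix(0, nrow(dctx), H)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * S + 1L):(b * S)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      ac <- cache$attn[[b]][[h]]
      Vh <- cache$v$y[rows, cols, drop = FALSE]
      dctx_h <- dctx[rows, cols, drop = FALSE]
      dPd <- tcrossprod(dctx_h, Vh)
      dV[rows, cols] <- crossprod(ac$dp$y, dctx_h)
      dP <- .dropout_bwd(dPd, ac$dp)
      dS_ <- ac$P * (dP - rowSums(dP * ac$P))
      dQ[rows, cols] <- (dS_ %*% cache$k$y[rows, cols, drop = FALSE]) * scale
      dK[rows, cols] <- (crossprod(dS_, cache$q$y[rows, cols, drop = FALSE])) * scale
    }
  }
  qb <- .dense_bwd(dQ, cache$q, p[[paste0(pre, "Wq")]])
  .acc(g, paste0(pre, "Wq"), qb$dW); .acc(g, paste0(pre, "bq"), qb$db)
  kb <- .dense_bwd(dK, cache$k, p[[paste0(pre, "Wk")]])
  .acc(g, paste0(pre, "Wk"), kb$dW); .acc(g, paste0(pre, "bk"), kb$db)
  vb <- .dense_bwd(dV, cache$v, p[[paste0(pre, "Wv")]])
  .acc(g, paste0(pre, "Wv"), vb$dW); .acc(g, paste0(pre, "bv"), vb$db)
  dres1 + qb$dx + kb$dx + vb$dx
}

# Full forward pass: embedding -> conv stack -> encoder -> pooler.
.model_fwd <- function(model, batch, training = FALSE) {
  p <- model$params
  config <- model$config
  ba <- .batch_arrays(batch)
  maskvec <- as.numeric(t(ba$msk))
  emb <- .embed_fwd(p, config, ba, training)
  conv <- .conv_stack_fwd(p, config, emb$out, ba, maskvec)
  X <- conv$out
  layers <- vector("list", config$num_layers)
  for (i in seq_len(config$num_layers)) {
    pre <- paste0("layer", i, ".")
    layers[[i]] <- .layer_fwd(p, config, X, ba, pre, training)
    X <- layers[[i]]$out
  }
  cls_rows <- (seq_len(ba$B) - 1L) * ba$S + 1L
  pool_in <- X[cls_rows, , drop = FALSE]
  pl <- .dense_fwd(pool_in, p$pooler.W, p$pooler.b)
  pooled <- tanh(pl$y)
  list(hidden = X, pooled = pooled, ba = ba, maskvec = maskvec,
       emb = emb, conv = conv, layers = layers, pl = pl,
       cls_rows = cls_rows)
}

# Backward pass; d_hidden may be NULL (zero), d_pooled likewise.
# Returns an environment of accumulated gradients keyed by parameter name.
.model_bwd <- function(model, fw, d_hidden = NULL, d_pooled = NULL,
                       g = new.env(parent = emptyenv())) {
  p <- model$params
  config <- model$config
  ba <- fw$ba
  dX <- if (is.null(d_hidden)) matrix(0, nrow(fw$hidden), ncol(fw$hidden))
        else d_hidden
  if (!is.null(d_pooled)) {
    dpre <- d_pooled * (1 - fw$pooled^2)
    pb <- .dense_bwd(dpre, fw$pl, p$pooler.W)
    .acc(g, "pooler.W", pb$dW); .acc(g, "pooler.b", pb$db)
    dX[fw$cls_rows, ] <- dX[fw$cls_rows, , drop = FALSE] + pb$dx
  }
  for (i in rev(seq_len(config$num_layers))) {
    pre <- paste0("layer", i, ".")
    dX <- .layer_bwd(dX, fw$layers[[i]], p, config, ba, pre, g)
  }
  dX <- .conv_stack_bwd(dX, fw$conv, p, config, ba, fw$maskvec, g)
  .embed_bwd(dX, fw$emb, p, g)
  g
}

#' Run the transformer encoder over a batch
#'
#' @param model An `mf_model`.
#' @param batch List of `mf_example`s of one length/format.
#' @return List with `hidden_states` (list of `S x H` matrices, one per
#'   example) and `pooled` (`B x H` matrix: tanh-pooled final-layer `[CLS]`
#'   vectors).
#' @export
mf_encode_batch <- function(model, batch) {
  fw <- .model_fwd(model, batch, training = FALSE)
  S <- fw$ba$S
  hs <- lapply(seq_len(fw$ba$B), function(b) {
    fw$hidden[((b - 1L) * S + 1L):(b * S), , drop = FALSE]
  })
  list(hidden_states = hs, pooled = fw$pooled)
}
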