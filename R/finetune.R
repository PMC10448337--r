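#' Remove variants whose wild-type sequence occurs in other sets
#'
#' Bias control between training and evaluation: an entry is removed when
#' its reference (wild-type) protein sequence is identical to the
#' reference sequence of any entry in the other sets.  Apply in both
#' directions (train vs. tests, tests vs. pre-training data) as needed.
#'
#' @param variants An `mf_variants` table to filter.
#' @param proteome `mf_proteome` resolving `variants`.
#' @param others One `mf_variants` table or a list of them.
#' @param others_proteome Proteome resolving the other sets (defaults to
#'   `proteome`).
#' @return List with `variants` (filtered) and `removed` (count).
#' @export
filter_overlap <- function(variants, proteome, others,
                           others_proteome = proteome) {
  if (inherits(others, "mf_variants") || is.data.frame(others)) {
    others <- list(others)
  }
  other_refs <- unique(unlist(lapply(others, function(tb) {
    vapply(tb$protein_id, function(id) .lookup_protein(others_proteome, id),
           character(1))
  })))
  refs <- vapply(variants$protein_id,
                 function(id) .lookup_protein(proteome, id), character(1))
  keep <- !(refs %in% other_refs)
  out <- variants[keep, , drop = FALSE]
  class(out) <- class(variants)
  list(variants = out, removed = sum(!keep))
}

#' Build a supervised fine-tuning dataset
#'
#' Materializes one model-ready example per labeled variant in one of the
#' three task formats: `per_residue` (single mutated sequence; only the
#' mutation site carries the example's class, all other residues are
#' benign), `single` (whole-sequence classification of the mutated
#' sequence), or `paired` (reference + mutated pair, mutation
#' center-cropped).
#'
#' @param variants Labeled `mf_variants`.
#' @param proteome `mf_proteome` with the reference sequences.
#' @param format `"per_residue"`, `"single"`, or `"paired"`.
#' @param capacity Token capacity: total capacity for the single-sequence
#'   formats, per-sequence capacity for the paired format.
#' @return An `mf_dataset`: list with `entries` (each holding `ref_seq`,
#'   `mut_seq`, `variant`, `example`, `label01`), `format`, `capacity`.
#' @export
build_task_dataset <- function(variants, proteome,
                               format = c("paired", "single", "per_residue"),
                               capacity = 64L) {
  format <- match.arg(format)
  if (any(is.na(variants$label))) stop("all variants must be labeled")
  entries <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    ref <- .lookup_protein(proteome, v$protein_id)
    mut <- apply_variant(ref, v)
    ex <- if (format == "paired") {
      build_paired_example(ref, mut, v, per_seq_capacity = capacity)
    } else {
      build_single_example(mut, v, capacity = capacity)
    }
    entries[[i]] <- list(ref_seq = ref, mut_seq = mut, variant = v,
                         example = ex,
                         label01 = as.integer(v$label == "deleterious"))
  }
  structure(list(entries = entries, format = format, capacity = capacity),
            class = "mf_dataset")
}

#' Per-residue label vector of a dataset entry
#'
#' Every residue identical to the reference is benign; the mutated residue
#' carries the example's class.
#'
#' @param dataset An `mf_dataset` with `format = "per_residue"`.
#' @param i Entry index.
#' @return Character vector (one per residue token of the example crop)
#'   of `"benign"` / `"deleterious"`.
#' @export
per_residue_labels <- function(dataset, i) {
  en <- dataset$entries[[i]]
  ex <- en$example
  v <- mf_vocab()
  ids <- ex$token_ids[ex$attention_mask == 1L]
  res <- which(!(ids %in% c(v$cls_id, v$sep_id, v$b_id, v$j_id)))
  labs <- rep("benign", length(res))
  labs[match(ex$mutation_index, res)] <- en$variant$label
  labs
}

# Relative-position-preserving crop: choose start so the site keeps its
# original relative position inside the trimmed window (clamped to the
# sequence); used by augmentation.
.relpos_crop_start <- function(L, site0, t) {
  if (t >= L) return(0L)
  rel <- if (L > 1L) site0 / (L - 1) else 0
  start <- as.integer(round(site0 - rel * (t - 1)))
  max(0L, min(start, L - t))
}

#' Training-time trimming augmentation
#'
#' With probability 0.5 the example is left unchanged; otherwise the
#' retained residue count is drawn uniformly from
#' `[ceiling(0.5 * L), L]` and the window is placed so the mutation site
#' keeps its original relative position (hence on average it stays in the
#' same location and is never dropped).  Boundary sentinels are recomputed
#' from the crop, and the example is re-padded to the original capacity.
#'
#' @param entry A dataset entry (see [build_task_dataset()]).
#' @param format Task format of the dataset.
#' @param capacity Dataset token capacity.
#' @param p_alter Probability of altering the example (default 0.5).
#' @return An `mf_example` (the original one when unaltered).
#' @export
augment_example <- function(entry, format, capacity, p_alter = 0.5) {
  if (stats::runif(1) >= p_alter) return(entry$example)
  L <- nchar(entry$mut_seq)
  lo <- as.integer(ceiling(0.5 * L))
  t <- if (lo >= L) L else sample(seq.int(lo, L), 1L)
  site0 <- entry$variant$position - 1L
  start <- .relpos_crop_start(L, site0, t)
  sub_mut <- substr(entry$mut_seq, start + 1L, start + t)
  # treat the trimmed window as a crop of the full protein: B/J follow the
  # boundary rule, and the variant is re-addressed inside the window
  v2 <- entry$variant
  v2$position <- site0 - start + 1L
  if (format == "paired") {
    sub_ref <- substr(entry$ref_seq, start + 1L, start + t)
    ex <- build_paired_example(sub_ref, sub_mut, v2,
                               per_seq_capacity = capacity)
  } else {
    ex <- build_single_example(sub_mut, v2, capacity = capacity)
  }
  # boundary sentinels must reflect the full protein, not the window
  ex <- .fix_boundary_sentinels(ex, start > 0L, start + t < L)
  ex$position_offset <- ex$position_offset + start
  ex
}

# Replace B/J that mark window edges which are not true protein edges.
# Dropping a sentinel would change the token count, so instead the
# sentinel is replaced by [PAD]-free removal: rebuild without it.
.fix_boundary_sentinels <- function(ex, strip_b, strip_j) {
  if (!strip_b && !strip_j) return(ex)
  v <- mf_vocab()
  ids <- ex$token_ids[ex$attention_mask == 1L]
  keep <- rep(TRUE, length(ids))
  if (strip_b) keep[ids == v$b_id] <- FALSE
  if (strip_j) keep[ids == v$j_id] <- FALSE
  removed_before_mut <- sum(!keep[seq_len(ex$mutation_index - 1L)])
  ids <- ids[keep]
  seg <- ex$segment_ids[ex$attention_mask == 1L][keep]
  total <- length(ex$token_ids)
  n <- length(ids)
  .new_example(
    token_ids = c(ids, rep(v$pad_id, total - n)),
    segment_ids = c(seg, rep(seg[n], total - n)),
    attention_mask = c(rep(1L, n), rep(0L, total - n)),
    position_offset = ex$position_offset,
    mutation_index = ex$mutation_index - removed_before_mut,
    format = ex$format)
}

# Scores for all entries of a dataset (forward only, batched).
.predict_dataset <- function(model, dataset, external = NULL,
                             batch_size = 16L) {
  n <- length(dataset$entries)
  probs <- numeric(n)
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + batch_size - 1L, n)
    batch <- lapply(dataset$entries[idx], `[[`, "example")
    fw <- .model_fwd(model, batch, training = FALSE)
    if (dataset$format == "per_residue") {
      S <- fw$ba$S
      rows <- vapply(seq_along(idx), function(b) {
        (b - 1L) * S + batch[[b]]$mutation_index
      }, integer(1))
      probs[idx] <- mf_token_head(model, fw$hidden[rows, , drop = FALSE])
    } else if (!is.null(external)) {
      probs[idx] <- mf_fusion_head(model, fw$pooled,
                                   external[idx, , drop = FALSE])
    } else {
      probs[idx] <- mf_cls_head(model, fw$pooled)
    }
    i <- i + batch_size
  }
  probs
}

#' Supervised fine-tuning
#'
#' Cross-entropy on the format's target (the mutation-site logit for
#' `per_residue`, the pooled `[CLS]` logit otherwise, through the fusion
#' head when external scores are supplied).  The learning rate decays
#' linearly between the given endpoints; no gradient clipping is applied
#' (clipping is a pre-training-only device).  Epochs are shuffled
#' independently.  When evaluation checkpoints and a validation set are
#' given, the returned model is the checkpoint with the best validation
#' ROC AUC.
#'
#' @param model An `mf_model` (typically pre-trained).
#' @param dataset Training `mf_dataset`.
#' @param schedule List: `steps`, `batch_size` (default 16), `initial_lr`,
#'   `end_lr`, `weight_decay` (default 0.01), `freeze_n` (default 0),
#'   `eval_checkpoints` (integer step vector, default: final step),
#'   `augment` (default FALSE).
#' @param val_dataset Optional held-out `mf_dataset` for checkpoint
#'   selection.
#' @param external,val_external Optional standardized external-score
#'   matrices (rows aligned with the dataset entries) for fusion training.
#' @param seed Integer seed.
#' @return List with `model` (best checkpoint), `history` (per-checkpoint
#'   metrics), `final_model`.
#' @export
finetune <- function(model, dataset, schedule, val_dataset = NULL,
                     external = NULL, val_external = NULL, seed = 0L) {
  sc <- utils::modifyList(list(batch_size = 16L, weight_decay = 0.01,
                               freeze_n = 0L, eval_checkpoints = NULL,
                               augment = FALSE),
                          schedule)
  if (is.null(sc$steps) || is.null(sc$initial_lr) || is.null(sc$end_lr)) {
    stop("schedule needs steps, initial_lr and end_lr")
  }
  if (is.null(sc$eval_checkpoints)) sc$eval_checkpoints <- sc$steps
  if (any(sc$eval_checkpoints > sc$steps)) {
    stop("eval checkpoints must not exceed steps")
  }
  if (sc$end_lr > sc$initial_lr) stop("end_lr must be <= initial_lr")
  if (!is.null(external) && model$config$n_external != ncol(external)) {
    stop("external score matrix width must match config n_external")
  }
  if (dataset$format == "per_residue" && !is.null(external)) {
    stop("fusion head requires a [CLS]-pooled format (single or paired)")
  }
  set.seed(seed)
  model <- freeze_layers(model, sc$freeze_n)
  opt <- .adam_init()
  n <- length(dataset$entries)
  order <- integer(0); cursor <- 1L
  history <- list()
  best <- NULL
  eval_now <- function(step) {
    if (is.null(val_dataset)) return(NULL)
    pr <- .predict_dataset(model, val_dataset, external = val_external)
    yv <- vapply(val_dataset$entries, `[[`, integer(1), "label01")
    auc <- roc_auc(pr, yv)$auc
    history[[length(history) + 1L]] <<-
      data.frame(step = step, val_auc = auc)
    if (is.null(best) || auc > best$auc) best <<- list(auc = auc,
                                                       model = model,
                                                       step = step)
    invisible(auc)
  }
  if (sc$steps >= 1L) for (step in seq_len(sc$steps)) {
    take <- integer(0)
    while (length(take) < sc$batch_size) {
      if (cursor > n || length(order) == 0L) {
        order <- sample.int(n)      # independent epoch shuffling
        cursor <- 1L
      }
      take <- c(take, order[cursor])
      cursor <- cursor + 1L
    }
    batch <- lapply(dataset$entries[take], function(en) {
      if (sc$augment) augment_example(en, dataset$format, dataset$capacity)
      else en$example
    })
    labels <- vapply(dataset$entries[take], `[[`, integer(1), "label01")
    fw <- .model_fwd(model, batch, training = TRUE)
    g <- new.env(parent = emptyenv())
    if (dataset$format == "per_residue") {
      S <- fw$ba$S
      rows <- vapply(seq_along(take), function(b) {
        (b - 1L) * S + batch[[b]]$mutation_index
      }, integer(1))
      tl <- .token_loss_bwd(model, fw, rows, labels, g)
      if (!is.finite(tl$loss)) stop("fine-tuning diverged at step ", step)
      .model_bwd(model, fw, d_hidden = tl$d_hidden, g = g)
    } else {
      ext_b <- if (!is.null(external)) external[take, , drop = FALSE]
      cl <- .cls_loss_bwd(model, fw, labels, g, external = ext_b)
      if (!is.finite(cl$loss)) stop("fine-tuning diverged at step ", step)
      .model_bwd(model, fw, d_pooled = cl$d_pooled, g = g)
    }
    lr <- .lr_at(step, sc$steps, sc$initial_lr, sc$end_lr)
    model <- .adam_step(model, g, opt, lr, sc$weight_decay, clip = NULL)
    if (step %in% sc$eval_checkpoints) eval_now(step)
  }
  if (is.null(best)) best <- list(model = model, step = sc$steps, auc = NA)
  list(model = best$model, final_model = model,
       history = if (length(history)) do.call(rbind, history) else NULL,
       best_step = best$step)
}
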