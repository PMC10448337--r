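#' Number of residues to corrupt in a sequence of length L
#'
#' The masking count is the lower of 15% of the residue count (floored)
#' and a hard cap of 20 residues per sequence, with a minimum of one so
#' every sequence contributes to the objective.
#'
#' @param L Residue count.
#' @return Integer number of positions to corrupt.
#' @export
masking_count <- function(L) {
  if (any(L < 1L)) stop("L must be >= 1")
  pmax(1L, pmin(as.integer(floor(0.15 * L)), 20L))
}

#' Plan the corruption of one sequence
#'
#' Selects `masking_count(L)` residue positions uniformly without
#' replacement and assigns each a corruption mode: replacement by the
#' `[MASK]` token (probability `mask_prob`) or by a different random amino
#' acid.  Uses R's RNG.
#'
#' @param L Residue count of the sequence.
#' @param mask_prob Probability of the `[MASK]` mode (default 0.8; the
#'   remainder uses the random-amino-acid mode).
#' @return An `mf_masking_plan`: list with sorted 1-based `positions` and
#'   per-position `modes` (`"mask_token"` / `"random_aa"`).
#' @export
plan_masking <- function(L, mask_prob = 0.8) {
  n <- masking_count(L)
  positions <- sort(sample.int(L, n))
  modes <- ifelse(stats::runif(n) < mask_prob, "mask_token", "random_aa")
  structure(list(positions = positions, modes = modes, originals = NULL),
            class = "mf_masking_plan")
}

#' Corrupt residue tokens according to a masking plan
#'
#' Only the planned residue positions are touched; a `random_aa`
#' replacement is drawn from the 20 standard amino acids and never equals
#' the original residue.  The plan is returned with the original token ids
#' recorded, so the clean sequence is exactly recoverable.
#'
#' @param residue_ids Integer vector of residue token ids (no special
#'   tokens).
#' @param plan An `mf_masking_plan` valid for this length.
#' @return List with `tokens` (corrupted ids) and `plan` (with
#'   `originals` filled in).
#' @export
apply_masking <- function(residue_ids, plan) {
  v <- mf_vocab()
  if (length(plan$positions) &&
      (max(plan$positions) > length(residue_ids) || min(plan$positions) < 1L)) {
    stop("masking plan does not fit the token sequence")
  }
  if (any(residue_ids %in% c(v$pad_id, v$cls_id, v$sep_id, v$mask_id,
                             v$b_id, v$j_id))) {
    stop("residue_ids must not contain special tokens")
  }
  originals <- residue_ids[plan$positions]
  out <- residue_ids
  for (i in seq_along(plan$positions)) {
    pos <- plan$positions[i]
    if (plan$modes[i] == "mask_token") {
      out[pos] <- v$mask_id
    } else {
      choices <- setdiff(v$aa_ids, residue_ids[pos])
      out[pos] <- choices[sample.int(length(choices), 1L)]
    }
  }
  plan$originals <- originals
  list(tokens = out, plan = plan)
}

#' Assemble the self-supervised pre-training corpus
#'
#' The corpus combines all reference isoforms with one mutated sequence
#' per common (population-frequent, hence presumed benign) variant; exact
#' duplicate sequences are removed and sequences longer than `window`
#' residues are tiled into overlapping segments (overlap `window / 2`,
#' right-aligned final tile).
#'
#' @param references An `mf_proteome` of reference isoforms.
#' @param common_variants An `mf_variants` table of common variants.
#' @param window Residue capacity of one training sequence.
#' @return An `mf_corpus` data frame with columns `id`, `sequence` (tile),
#'   `source` (`reference` / `common_variant`), `b_flag`, `j_flag`
#'   (whether the tile carries the true start/end).
#' @export
build_pretrain_corpus <- function(references, common_variants = NULL,
                                  window = 1020L) {
  seqs <- references$sequence
  ids <- references$id
  src <- rep("reference", length(seqs))
  if (!is.null(common_variants) && nrow(common_variants)) {
    for (i in seq_len(nrow(common_variants))) {
      v <- common_variants[i, ]
      ref <- .lookup_protein(references, v$protein_id)
      mut <- tryCatch(apply_variant(ref, v), error = function(e) {
        stop("invalid common variant ", v$protein_id, ":", v$ref_aa,
             v$position, v$alt_aa, ": ", conditionMessage(e), call. = FALSE)
      })
      seqs <- c(seqs, mut)
      ids <- c(ids, paste0(v$protein_id, ":", v$ref_aa, v$position, v$alt_aa))
      src <- c(src, "common_variant")
    }
  }
  keep <- !duplicated(seqs)
  seqs <- seqs[keep]; ids <- ids[keep]; src <- src[keep]
  out <- list()
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    tiles <- segment_protein(seqs[i], window)
    for (tl in tiles) {
      out[[length(out) + 1L]] <- data.frame(
        id = ids[i], sequence = tl$subsequence, source = src[i],
        b_flag = tl$offset == 0L,
        j_flag = tl$offset + nchar(tl$subsequence) == L,
        stringsAsFactors = FALSE)
    }
  }
  corpus <- do.call(rbind, out)
  rownames(corpus) <- NULL
  class(corpus) <- c("mf_corpus", "data.frame")
  corpus
}

#' Draw one epoch's masking plans (dynamic masking)
#'
#' Plans are re-drawn independently for every epoch, seeded by
#' `(seed, epoch_index)` so the same epoch always reproduces identical
#' plans while different epochs corrupt different positions.
#'
#' @param corpus An `mf_corpus`.
#' @param epoch_index 0-based epoch number.
#' @param seed Global integer seed.
#' @param mask_prob `[MASK]`-mode probability, see [plan_masking()].
#' @return List of `mf_masking_plan`s, one per corpus sequence.
#' @export
dynamic_remask <- function(corpus, epoch_index, seed = 0L, mask_prob = 0.8) {
  # derive the epoch seed in double precision to avoid integer overflow
  epoch_seed <- (as.numeric(seed) * 48271 + as.numeric(epoch_index) * 16807) %%
    2147483647
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(epoch_seed))
  lapply(nchar(corpus$sequence), plan_masking, mask_prob = mask_prob)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Build the padded token example for one corpus row after masking.
# Returns token ids, attention mask, the flat token indices of corrupted
# positions (1-based within the example), and their original ids.
.pretrain_example <- function(row, plan, capacity) {
  v <- mf_vocab()
  res_ids <- mf_encode(strsplit(row$sequence, "", fixed = TRUE)[[1]])
  msk <- apply_masking(res_ids, plan)
  body <- c(v$cls_id,
            if (row$b_flag) v$b_id,
            msk$tokens,
            if (row$j_flag) v$j_id,
            v$sep_id)
  n <- length(body)
  if (n > capacity) stop("corpus sequence exceeds example capacity")
  offset <- 1L + as.integer(row$b_flag)     # tokens before residue 1
  ex <- .new_example(
    token_ids = c(body, rep(v$pad_id, capacity - n)),
    segment_ids = rep(0L, capacity),
    attention_mask = c(rep(1L, n), rep(0L, capacity - n)),
    position_offset = 0L, mutation_index = NA_integer_, format = "single")
  list(example = ex,
       sel = offset + msk$plan$positions,
       targets = msk$plan$originals)
}

# forward-only masked-position loss/accuracy
.mlm_eval <- function(model, batch, sels, targets) {
  fw <- .model_fwd(model, batch, training = FALSE)
  S <- fw$ba$S
  rows <- unlist(lapply(seq_along(batch), function(b) (b - 1L) * S + sels[[b]]))
  tgt <- unlist(targets)
  probs <- mf_mlm_head(model, fw$hidden[rows, , drop = FALSE])
  eps <- 1e-12
  picked <- probs[cbind(seq_along(tgt), tgt + 1L)]
  list(loss = mean(-log(picked + eps)),
       accuracy = mean(max.col(probs, ties.method = "first") == tgt + 1L))
}

#' Masked-residue pre-training
#'
#' Optimizes cross-entropy over the corrupted positions only (there is no
#' next-sentence objective).  Dynamic masking re-draws the corrupted
#' positions each epoch.  The optimizer is decoupled-weight-decay Adam
#' with linear learning-rate decay and global-norm gradient clipping.
#' A held-out split (by hash of sequence id) provides masked-position
#' loss/accuracy; its masking is fixed across evaluations.
#'
#' @param corpus An `mf_corpus` from [build_pretrain_corpus()].
#' @param model An `mf_model` (freshly initialized or resumed).
#' @param schedule List: `steps`, `batch_size`, `initial_lr`, `end_lr`,
#'   `weight_decay` (default 0.01), `clip` (default 1.0), `mask_prob`
#'   (default 0.8), `capacity` (example token capacity), `eval_every`
#'   (default: steps, i.e., once at the end), `holdout_frac` (default
#'   0.05).
#' @param seed Integer seed controlling shuffling and masking.
#' @return List with `model` (trained) and `history` (data frame of step,
#'   split, loss, accuracy, lr).
#' @export
run_pretraining <- function(corpus, model, schedule, seed = 0L) {
  sc <- utils::modifyList(list(batch_size = 8L, weight_decay = 0.01,
                               clip = 1.0, mask_prob = 0.8,
                               eval_every = NULL, holdout_frac = 0.05),
                          schedule)
  if (is.null(sc$steps) || is.null(sc$initial_lr) || is.null(sc$end_lr) ||
      is.null(sc$capacity)) {
    stop("schedule needs steps, initial_lr, end_lr and capacity")
  }
  if (is.null(sc$eval_every)) sc$eval_every <- sc$steps
  set.seed(seed)
  # held-out split by id hash so all tiles of one protein land together
  idhash <- vapply(corpus$id, function(s) sum(utf8ToInt(s)) %% 100L, integer(1))
  hold <- idhash < round(100 * sc$holdout_frac)
  if (all(hold) || !any(hold)) {  # degenerate tiny corpora: random holdout
    hold <- rep(FALSE, nrow(corpus))
    n_hold <- max(1L, as.integer(round(nrow(corpus) * sc$holdout_frac)))
    hold[sample.int(nrow(corpus), n_hold)] <- TRUE
  }
  train <- corpus[!hold, , drop = FALSE]
  val <- corpus[hold, , drop = FALSE]
  # fixed evaluation masking
  val_plans <- dynamic_remask(val, epoch_index = -1L, seed = seed,
                              mask_prob = sc$mask_prob)
  val_built <- lapply(seq_len(nrow(val)), function(i) {
    .pretrain_example(val[i, ], val_plans[[i]], sc$capacity)
  })
  eval_val <- function() {
    .mlm_eval(model,
              batch = lapply(val_built, `[[`, "example"),
              sels = lapply(val_built, `[[`, "sel"),
              targets = lapply(val_built, `[[`, "targets"))
  }
  opt <- .adam_init()
  history <- list()
  n_train <- nrow(train)
  epoch <- -1L
  order <- integer(0)
  cursor <- 1L
  plans <- NULL
  ev0 <- eval_val()
  history[[1]] <- data.frame(step = 0L, split = "val", loss = ev0$loss,
                             accuracy = ev0$accuracy, lr = NA_real_)
  if (sc$steps >= 1L) for (step in seq_len(sc$steps)) {
    take <- integer(0)
    while (length(take) < sc$batch_size) {
      if (cursor > n_train || epoch < 0L) {
        epoch <- epoch + 1L
        plans <- dynamic_remask(train, epoch, seed = seed,
                                mask_prob = sc$mask_prob)
        order <- sample.int(n_train)
        cursor <- 1L
      }
      take <- c(take, order[cursor])
      cursor <- cursor + 1L
    }
    built <- lapply(take, function(i) {
      .pretrain_example(train[i, ], plans[[i]], sc$capacity)
    })
    batch <- lapply(built, `[[`, "example")
    fw <- .model_fwd(model, batch, training = TRUE)
    S <- fw$ba$S
    rows <- unlist(lapply(seq_along(built), function(b) {
      (b - 1L) * S + built[[b]]$sel
    }))
    targets <- unlist(lapply(built, `[[`, "targets"))
    g <- new.env(parent = emptyenv())
    ml <- .mlm_loss_bwd(model, fw, rows, targets, g)
    if (!is.finite(ml$loss)) {
      stop("pre-training diverged at step ", step, " (loss = ", ml$loss, ")")
    }
    .model_bwd(model, fw, d_hidden = ml$d_hidden, g = g)
    lr <- .lr_at(step, sc$steps, sc$initial_lr, sc$end_lr)
    model <- .adam_step(model, g, opt, lr, sc$weight_decay, clip = sc$clip)
    if (step %% sc$eval_every == 0L || step == sc$steps) {
      ev <- eval_val()
      history[[length(history) + 1L]] <-
        data.frame(step = step, split = "val", loss = ev$loss,
                   accuracy = ev$accuracy, lr = lr)
    }
  }
  list(model = model, history = do.call(rbind, history))
}
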