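#' Configuration of the synthetic proteome generator
#'
#' The generator emulates the statistical structure the method assumes:
#' background residue composition, one conserved functional motif planted
#' per protein (the sequence-local determinant of deleteriousness),
#' common benign variation outside motifs, and external predictor scores
#' correlated with the labels.
#'
#' @param n_proteins Number of proteins.
#' @param min_len,max_len Protein length range (residues).
#' @param motif Conserved k-mer planted once per protein; substitutions
#'   inside it are deleterious, outside it benign.
#' @param background Residue sampling weights (default uniform over the
#'   20 amino acids); named by residue or in [AA_LETTERS] order.
#' @param n_external Number of simulated external predictor methods.
#' @param signal Per-method Gaussian class separation of external scores
#'   (two-class d'; AUC = pnorm(signal / sqrt(2))).
#' @param missing_rate Fraction of external predictions missing.
#' @return An `mf_sim_config` list.
#' @export
mf_sim_config <- function(n_proteins = 40L, min_len = 60L, max_len = 100L,
                          motif = "WDWDW", background = NULL,
                          n_external = 4L, signal = 2, missing_rate = 0.1) {
  if (nchar(motif) >= min_len) stop("motif must be shorter than min_len")
  if (is.null(background)) background <- rep(1 / 20, 20L)
  if (length(background) != 20L) stop("background needs 20 weights")
  background <- background / sum(background)
  structure(list(n_proteins = as.integer(n_proteins),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 motif = motif, background = background,
                 n_external = as.integer(n_external), signal = signal,
                 missing_rate = missing_rate),
            class = "mf_sim_config")
}

#' Generate a synthetic proteome with planted motifs
#'
#' Sequences are drawn i.i.d. from the background residue distribution;
#' one copy of the motif is planted per protein at a recorded position.
#' Deterministic given the RNG state (call `set.seed()` first).
#'
#' @param config An `mf_sim_config`.
#' @return An `mf_proteome` with attribute `motif_sites`: data frame of
#'   `id`, `start`, `end` (1-based, inclusive) of the planted motif.
#' @export
generate_proteome <- function(config) {
  k <- nchar(config$motif)
  ids <- sprintf("sprot%03d", seq_len(config$n_proteins))
  seqs <- character(config$n_proteins)
  starts <- integer(config$n_proteins)
  for (i in seq_len(config$n_proteins)) {
    L <- sample(seq.int(config$min_len, config$max_len), 1L)
    chars <- sample(AA_LETTERS, L, replace = TRUE, prob = config$background)
    s <- sample.int(L - k + 1L, 1L)
    chars[s:(s + k - 1L)] <- strsplit(config$motif, "")[[1]]
    seqs[i] <- paste(chars, collapse = "")
    starts[i] <- s
  }
  pr <- mf_proteome(ids, seqs)
  attr(pr, "motif_sites") <- data.frame(id = ids, start = starts,
                                        end = starts + k - 1L,
                                        stringsAsFactors = FALSE)
  pr
}

.motif_positions <- function(proteome, id) {
  ms <- attr(proteome, "motif_sites")
  r <- ms[ms$id == id, ]
  seq.int(r$start, r$end)
}

#' Generate common (benign-by-construction) variants
#'
#' Models population-frequent missense variation: every residue outside
#' the planted motif mutates independently with probability `rate` to a
#' random different amino acid.  Motif positions are never touched, so no
#' common variant disrupts a functional site.
#'
#' @param proteome Output of [generate_proteome()].
#' @param rate Per-residue substitution probability.
#' @return An `mf_variants` table with all labels `"benign"`.
#' @export
generate_common_variants <- function(proteome, rate = 0.01) {
  out <- list()
  for (i in seq_len(nrow(proteome))) {
    id <- proteome$id[i]; s <- proteome$sequence[i]
    motif <- .motif_positions(proteome, id)
    eligible <- setdiff(seq_len(nchar(s)), motif)
    hit <- eligible[stats::runif(length(eligible)) < rate]
    for (pos in hit) {
      ref <- substr(s, pos, pos)
      alt <- sample(setdiff(AA_LETTERS, ref), 1L)
      out[[length(out) + 1L]] <- data.frame(protein_id = id, position = pos,
                                            ref_aa = ref, alt_aa = alt,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(mf_variants(character(0), integer(0), character(0), character(0)))
  }
  df <- do.call(rbind, out)
  mf_variants(df$protein_id, df$position, df$ref_aa, df$alt_aa,
              rep("benign", nrow(df)))
}

#' Generate labeled variants under the planted deleteriousness rule
#'
#' The rule is deterministic and sequence-local: a substitution is
#' deleterious iff it falls on a planted motif position (destroying the
#' conserved site), benign otherwise -- so a position-aware oracle
#' achieves AUC 1 and the task has Bayes error 0.  Classes are balanced
#' by default and the output is disjoint from `exclude` (e.g., the common
#' variants used for pre-training).
#'
#' @param proteome Output of [generate_proteome()].
#' @param n Total number of variants.
#' @param balanced Balanced classes (n/2 each)?
#' @param exclude Optional `mf_variants` to avoid duplicating.
#' @return A labeled `mf_variants` table.
#' @export
generate_labeled_variants <- function(proteome, n, balanced = TRUE,
                                      exclude = NULL) {
  key <- function(p, pos, a) paste(p, pos, a)
  used <- new.env(parent = emptyenv())
  if (!is.null(exclude) && nrow(exclude)) {
    for (kk in key(exclude$protein_id, exclude$position, exclude$alt_aa)) {
      used[[kk]] <- TRUE
    }
  }
  n_del <- if (balanced) n %/% 2L else stats::rbinom(1L, n, 0.5)
  n_ben <- n - n_del
  ms <- attr(proteome, "motif_sites")
  n_motif_sites <- sum(ms$end - ms$start + 1L)
  n_total_sites <- sum(nchar(proteome$sequence))
  if (n_del > 19L * n_motif_sites ||
      n_ben > 19L * (n_total_sites - n_motif_sites)) {
    stop("n exceeds available variant sites")
  }
  draw <- function(n_want, in_motif) {
    rows <- list()
    space <- 19L * (if (in_motif) n_motif_sites else
                    n_total_sites - n_motif_sites)
    guard <- 0L
    while (length(rows) < n_want) {
      guard <- guard + 1L
      if (guard > 50L * space) stop("n exceeds available variant sites")
      i <- sample.int(nrow(proteome), 1L)
      id <- proteome$id[i]; s <- proteome$sequence[i]
      motif <- .motif_positions(proteome, id)
      cand <- if (in_motif) motif else setdiff(seq_len(nchar(s)), motif)
      pos <- cand[sample.int(length(cand), 1L)]
      ref <- substr(s, pos, pos)
      alt <- sample(setdiff(AA_LETTERS, ref), 1L)
      kk <- key(id, pos, alt)
      if (!is.null(used[[kk]])) next
      used[[kk]] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, position = pos, ref_aa = ref, alt_aa = alt,
        label = if (in_motif) "deleterious" else "benign",
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  df <- rbind(draw(n_del, TRUE), draw(n_ben, FALSE))
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  mf_variants(df$protein_id, df$position, df$ref_aa, df$alt_aa, df$label)
}

#' Simulate external predictor scores correlated with the labels
#'
#' Per method, the raw score is `scale * (signal * y + N(0,1)) + offset`
#' on a method-specific raw scale, with entries missing completely at
#' random at the configured rate.  The per-method ROC AUC is controlled
#' by `signal` through the Gaussian two-class closed form
#' `AUC = pnorm(signal / sqrt(2))`.
#'
#' @param variants Labeled `mf_variants`.
#' @param config An `mf_sim_config` (uses `n_external`, `signal`,
#'   `missing_rate`).
#' @return An `mf_external_table` of raw scores.
#' @export
generate_external_scores <- function(variants, config) {
  y <- as.integer(variants$label == "deleterious")
  n <- length(y)
  m <- config$n_external
  scores <- matrix(NA_real_, n, m)
  colnames(scores) <- sprintf("method_%02d", seq_len(m))
  for (j in seq_len(m)) {
    scale <- stats::runif(1, 0.5, 10)
    offset <- stats::runif(1, -5, 5)
    raw <- scale * (config$signal * y + stats::rnorm(n)) + offset
    raw[stats::runif(n) < config$missing_rate] <- NA_real_
    scores[, j] <- raw
  }
  mf_external_table(variants, scores)
}
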