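#' Boundary-delimited token list for a (possibly cropped) sequence
#'
#' A `B` sentinel is prepended iff the crop starts at the true first
#' residue, and a `J` sentinel is appended iff the crop ends at the true
#' last residue, so a cropped start/end is distinguishable from a real one.
#'
#' @param sequence Full amino-acid sequence.
#' @param crop_start 0-based start of the crop (inclusive).
#' @param crop_end 0-based end of the crop (exclusive).
#' @return Character vector of tokens (residue letters, possibly flanked by
#'   `B` / `J`).
#' @export
#' @examples
#' delimit_boundaries("MKV", 0, 3)   # B M K V J
#' delimit_boundaries("MKVL", 1, 3)  # K V
delimit_boundaries <- function(sequence, crop_start, crop_end) {
  L <- nchar(sequence)
  if (crop_start < 0L || crop_end > L || crop_start >= crop_end) {
    stop("invalid crop [", crop_start, ", ", crop_end, ") for length ", L)
  }
  tokens <- strsplit(substr(sequence, crop_start + 1L, crop_end), "",
                     fixed = TRUE)[[1]]
  if (crop_start == 0L) tokens <- c(BOUNDARY_START, tokens)
  if (crop_end == L) tokens <- c(tokens, BOUNDARY_END)
  tokens
}

#' Center-crop a sequence around a site
#'
#' Used for fine-tuning and inference input: the crop is centered on the
#' mutation site up to truncation at the protein boundaries, so the site is
#' always retained.
#'
#' @param sequence Amino-acid sequence.
#' @param site 0-based residue index that must be retained.
#' @param window Maximum number of residues to retain.
#' @return List with `subsequence` and `position_offset` (0-based index of
#'   the first retained residue).
#' @export
crop_around_site <- function(sequence, site, window) {
  L <- nchar(sequence)
  if (site < 0L || site >= L) stop("site out of range")
  if (window < 1L) stop("window must be >= 1")
  if (L <= window) {
    return(list(subsequence = sequence, position_offset = 0L))
  }
  start <- site - window %/% 2L
  start <- max(0L, min(start, L - window))
  list(subsequence = substr(sequence, start + 1L, start + window),
       position_offset = as.integer(start))
}

#' Tile a sequence into overlapping segments
#'
#' Pre-training path for proteins longer than the model capacity: fixed
#' stride `window - overlap`, with the final segment right-aligned so every
#' residue is covered at least once.
#'
#' @param sequence Amino-acid sequence.
#' @param window Segment length (residues).
#' @param overlap Residues shared by consecutive segments; must be smaller
#'   than `window`.
#' @return List of lists with `subsequence` and `offset` (0-based).
#' @export
segment_protein <- function(sequence, window, overlap = window %/% 2L) {
  if (overlap < 0L || overlap >= window) stop("need window > overlap >= 0")
  L <- nchar(sequence)
  if (L <= window) {
    return(list(list(subsequence = sequence, offset = 0L)))
  }
  stride <- window - overlap
  offsets <- seq(0L, by = stride, length.out = (L - window) %/% stride + 1L)
  if (offsets[length(offsets)] < L - window) {
    offsets <- c(offsets, L - window)  # right-aligned final tile
  }
  lapply(as.integer(offsets), function(o) {
    list(subsequence = substr(sequence, o + 1L, o + window), offset = o)
  })
}

.new_example <- function(token_ids, segment_ids, attention_mask,
                         position_offset, mutation_index, format) {
  structure(
    list(token_ids = as.integer(token_ids),
         segment_ids = as.integer(segment_ids),
         attention_mask = as.integer(attention_mask),
         position_offset = as.integer(position_offset),
         mutation_index = as.integer(mutation_index),
         format = format),
    class = "mf_example"
  )
}

# Crop `sequence` around `site0` so that residues plus any B/J sentinels fit
# within `budget` tokens.  Boundary sentinels are charged to the budget, so
# shrinking the residue window can itself re-trigger a sentinel; iterate to
# a fixed point (at most a few steps).
.crop_with_sentinels <- function(sequence, site0, budget) {
  L <- nchar(sequence)
  w <- budget
  repeat {
    if (w < 1L) stop("capacity too small to retain the mutation site")
    cr <- crop_around_site(sequence, site0, w)
    n_res <- nchar(cr$subsequence)
    start <- cr$position_offset
    nb <- (start == 0L) + (start + n_res == L)
    if (n_res + nb <= budget) {
      tokens <- delimit_boundaries(sequence, start, start + n_res)
      return(list(tokens = tokens, offset = start, n_res = n_res))
    }
    w <- budget - nb
  }
}

#' Build a single-sequence model input
#'
#' Layout: `[CLS] (B?) residues (J?) [SEP] [PAD]*`, right-padded to exactly
#' `capacity` tokens.  The residue window (plus boundary sentinels) is
#' charged `capacity - 2` tokens; `[CLS]`/`[SEP]` are charged to the
#' aggregate budget.  The crop is centered on the mutation site.
#'
#' @param mutated_sequence The mutated protein sequence.
#' @param variant One-row `mf_variants` data frame locating the mutation
#'   (1-based `position`; `alt_aa` must match the mutated sequence).
#' @param capacity Total token capacity (>= 5).
#' @return An `mf_example`: `token_ids` (0-based ids), `segment_ids` (all
#'   0), `attention_mask`, `position_offset`, `mutation_index` (1-based
#'   index into `token_ids` of the mutated residue), `format = "single"`.
#' @export
build_single_example <- function(mutated_sequence, variant, capacity) {
  if (capacity < 5L) stop("capacity must be at least 5")
  site0 <- variant$position - 1L
  L <- nchar(mutated_sequence)
  if (site0 < 0L || site0 >= L) stop("variant position out of range")
  if (substr(mutated_sequence, site0 + 1L, site0 + 1L) != variant$alt_aa) {
    stop("mutated sequence does not carry alt_aa at the variant position")
  }
  cr <- .crop_with_sentinels(mutated_sequence, site0, capacity - 2L)
  if (site0 < cr$offset || site0 >= cr$offset + cr$n_res) {
    stop("internal error: crop lost the mutation site")  # nocov
  }
  body <- c("[CLS]", cr$tokens, "[SEP]")
  ids <- mf_encode(body)
  n <- length(ids)
  pad <- capacity - n
  v <- mf_vocab()
  has_b <- cr$offset == 0L
  mut_idx <- 1L + as.integer(has_b) + (site0 - cr$offset) + 1L
  .new_example(
    token_ids = c(ids, rep(v$pad_id, pad)),
    segment_ids = rep(0L, capacity),
    attention_mask = c(rep(1L, n), rep(0L, pad)),
    position_offset = cr$offset,
    mutation_index = mut_idx,
    format = "single"
  )
}

#' Build a paired (reference, mutated) model input
#'
#' Layout: `[CLS] ref-tokens [SEP] mut-tokens [SEP] [PAD]*`, right-padded
#' to exactly `2 * per_seq_capacity` tokens.  Each side's residue window
#' plus its boundary sentinels is charged `per_seq_capacity - 2` tokens and
#' both sides are cropped identically, centered on the mutation site, so a
#' per-sequence capacity of 512 yields an aggregate input of 1,024 tokens.
#' Segment ids are 0 over `[CLS]` + reference + first `[SEP]` and 1
#' thereafter.
#'
#' @param ref_sequence Reference protein sequence.
#' @param mut_sequence Mutated protein sequence (same length, differing
#'   from the reference only at the variant position).
#' @param variant One-row `mf_variants` data frame.
#' @param per_seq_capacity Per-sequence token capacity (<= 512 at published
#'   scale; any value >= 3 is accepted for small models).
#' @return An `mf_example` with `format = "paired"`; `mutation_index`
#'   points at the alternate residue inside the mutated segment.
#' @export
build_paired_example <- function(ref_sequence, mut_sequence, variant,
                                 per_seq_capacity) {
  if (per_seq_capacity < 3L) stop("per_seq_capacity must be at least 3")
  if (nchar(ref_sequence) != nchar(mut_sequence)) {
    stop("reference and mutated sequences differ in length")
  }
  .check_variant(ref_sequence, variant)
  site0 <- variant$position - 1L
  diffs <- which(strsplit(ref_sequence, "")[[1]] !=
                 strsplit(mut_sequence, "")[[1]])
  if (!identical(diffs, as.integer(site0 + 1L))) {
    stop("sequences must differ at exactly the variant position")
  }
  budget <- per_seq_capacity - 2L
  cr_ref <- .crop_with_sentinels(ref_sequence, site0, budget)
  # identical crop window on the mutated side
  mut_tokens <- delimit_boundaries(mut_sequence, cr_ref$offset,
                                   cr_ref$offset + cr_ref$n_res)
  body <- c("[CLS]", cr_ref$tokens, "[SEP]", mut_tokens, "[SEP]")
  ids <- mf_encode(body)
  n <- length(ids)
  total <- 2L * per_seq_capacity
  if (n > total) stop("internal error: paired layout exceeds capacity")  # nocov
  v <- mf_vocab()
  n_seg0 <- 1L + length(cr_ref$tokens) + 1L
  has_b <- cr_ref$offset == 0L
  mut_idx <- n_seg0 + as.integer(has_b) + (site0 - cr_ref$offset) + 1L
  .new_example(
    token_ids = c(ids, rep(v$pad_id, total - n)),
    segment_ids = c(rep(0L, n_seg0), rep(1L, total - n_seg0)),
    attention_mask = c(rep(1L, n), rep(0L, total - n)),
    position_offset = cr_ref$offset,
    mutation_index = mut_idx,
    format = "paired"
  )
}

#' @export
print.mf_example <- function(x, ...) {
  cat("<mf_example> format=", x$format,
      " length=", length(x$token_ids),
      " non-pad=", sum(x$attention_mask),
      " mutation_index=", x$mutation_index,
      " offset=", x$position_offset, "\n", sep = "")
  cat(paste(mf_decode(x$token_ids[x$attention_mask == 1L]), collapse = " "),
      "\n")
  invisible(x)
}
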