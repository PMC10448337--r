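#' Protein records and missense variants
#'
#' A proteome is represented as a data frame with columns `id` and
#' `sequence` (class `mf_proteome`).  Sequences contain only the 20
#' standard amino-acid letters plus `X`; nonstandard residues are mapped to
#' `X` on construction so the reserved boundary letters `B`/`J` never occur
#' inside a stored sequence.
#'
#' @param id Character vector of protein identifiers.
#' @param sequence Character vector of amino-acid sequences (same length).
#' @return A data frame of class `mf_proteome`.
#' @export
mf_proteome <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  if (any(!nzchar(sequence))) stop("empty protein sequence")
  sequence <- vapply(sequence, mf_sanitize_sequence, character(1),
                     USE.NAMES = FALSE)
  out <- data.frame(id = as.character(id), sequence = sequence,
                    stringsAsFactors = FALSE)
  class(out) <- c("mf_proteome", "data.frame")
  out
}

#' Missense variant table
#'
#' Variants use 1-based residue coordinates as in standard protein variant
#' nomenclature (p.K2R is `position = 2, ref_aa = "K", alt_aa = "R"`).
#'
#' @param protein_id Character vector of protein identifiers.
#' @param position Integer vector of 1-based residue positions.
#' @param ref_aa,alt_aa Single-letter reference and alternate residues.
#' @param label Optional factor/character vector with values `"benign"` /
#'   `"deleterious"` (or `NA` for unlabeled variants).
#' @return A data frame of class `mf_variants`.
#' @export
mf_variants <- function(protein_id, position, ref_aa, alt_aa, label = NULL) {
  n <- length(protein_id)
  if (is.null(label)) label <- rep(NA_character_, n)
  stopifnot(length(position) == n, length(ref_aa) == n,
            length(alt_aa) == n, length(label) == n)
  if (any(nchar(ref_aa) != 1L) || any(nchar(alt_aa) != 1L)) {
    stop("ref_aa and alt_aa must be single letters")
  }
  if (any(ref_aa == alt_aa)) stop("ref_aa must differ from alt_aa")
  bad <- !(is.na(label) | label %in% c("benign", "deleterious"))
  if (any(bad)) stop("labels must be 'benign' or 'deleterious'")
  out <- data.frame(protein_id = as.character(protein_id),
                    position = as.integer(position),
                    ref_aa = as.character(ref_aa),
                    alt_aa = as.character(alt_aa),
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  class(out) <- c("mf_variants", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' Nonstandard residues (U, O, ambiguity codes, `*`) are stored as `X`;
#' entry order is preserved.
#'
#' @param path Path to a FASTA file (plain or line-wrapped).
#' @return An `mf_proteome` data frame (possibly with zero rows).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(mf_proteome(character(0), character(0))[0, ])
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(set))
  mf_proteome(ids, as.character(set))
}

#' Write a proteome to FASTA
#'
#' @param proteome An `mf_proteome` data frame.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteome))) {
    writeLines(paste0(">", proteome$id[i]), con)
    s <- proteome$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read / write a missense-variant TSV
#'
#' The file is tab-delimited with a header and columns `protein_id`,
#' `position`, `ref_aa`, `alt_aa` and optionally `label`.
#'
#' @param path Path to the TSV file.
#' @return An `mf_variants` data frame.
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("protein_id", "position", "ref_aa", "alt_aa")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "))
  lab <- if ("label" %in% names(df)) df$label else NULL
  if (!is.null(lab)) lab[!nzchar(lab)] <- NA_character_
  mf_variants(df$protein_id, as.integer(df$position), df$ref_aa, df$alt_aa, lab)
}

#' @rdname read_variants
#' @param variants An `mf_variants` data frame.
#' @export
write_variants <- function(variants, path) {
  out <- as.data.frame(variants)
  out$label[is.na(out$label)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.lookup_protein <- function(proteome, protein_id) {
  i <- match(protein_id, proteome$id)
  if (is.na(i)) stop("unknown protein: ", protein_id)
  proteome$sequence[i]
}

#' Validate a variant against its reference protein
#'
#' Checks that the position is in range and that `ref_aa` matches the
#' reference sequence at that position.
#'
#' @param sequence Reference amino-acid sequence.
#' @param variant One-row `mf_variants` data frame (or list with the same
#'   fields).
#' @keywords internal
.check_variant <- function(sequence, variant) {
  pos <- variant$position
  if (pos < 1L || pos > nchar(sequence)) {
    stop("variant position ", pos, " out of range for protein ",
         variant$protein_id, " (length ", nchar(sequence), ")")
  }
  have <- substr(sequence, pos, pos)
  if (have != variant$ref_aa) {
    stop("reference inconsistency for ", variant$protein_id, " position ",
         pos, ": sequence has '", have, "', variant expects '",
         variant$ref_aa, "'")
  }
  invisible(TRUE)
}

#' Apply a missense substitution to a protein sequence
#'
#' @param sequence Reference amino-acid sequence (character scalar).
#' @param variant One-row `mf_variants` data frame.
#' @return The mutated sequence: identical to the input except the single
#'   substituted residue; length unchanged.
#' @export
#' @examples
#' v <- mf_variants("p1", 2L, "K", "R")
#' apply_variant("MKV", v)  # "MRV"
apply_variant <- function(sequence, variant) {
  .check_variant(sequence, variant)
  substr(sequence, variant$position, variant$position) <- variant$alt_aa
  sequence
}
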