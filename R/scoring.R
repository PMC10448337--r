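#' External predictor score table
#'
#' A variant-by-method matrix of raw scores from external deleteriousness
#' predictors, with missingness explicit as `NA` (never a sentinel raw
#' value).
#'
#' @param variants An `mf_variants` table (keys; one row per scored
#'   variant).
#' @param scores Numeric matrix, one column per method, `NA` = missing;
#'   column names are the method names.
#' @return An `mf_external_table`.
#' @export
mf_external_table <- function(variants, scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(variants)) stop("row mismatch")
  if (is.null(colnames(scores))) stop("score columns must be named")
  structure(list(variants = variants, scores = scores,
                 methods = colnames(scores)),
            class = "mf_external_table")
}

#' Read / write an external-score TSV
#'
#' Tab-delimited with variant key columns (`protein_id`, `position`,
#' `ref_aa`, `alt_aa`) followed by one numeric column per method; an empty
#' cell means missing.
#'
#' @param path File path.
#' @export
read_external_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  keys <- c("protein_id", "position", "ref_aa", "alt_aa")
  if (!all(keys %in% names(df))) stop("missing variant key columns")
  methods <- setdiff(names(df), c(keys, "label"))
  v <- mf_variants(df$protein_id, df$position, df$ref_aa, df$alt_aa)
  mf_external_table(v, as.matrix(df[methods]))
}

#' @rdname read_external_table
#' @param table An `mf_external_table`.
#' @export
write_external_table <- function(table, path) {
  df <- cbind(as.data.frame(table$variants)[
    c("protein_id", "position", "ref_aa", "alt_aa")],
    as.data.frame(table$scores))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

.standardize <- function(table, lo, hi, missing_value, reference) {
  out <- table$scores
  for (j in seq_len(ncol(out))) {
    refcol <- if (is.null(reference)) table$scores[, j] else reference[, j]
    rng <- suppressWarnings(range(refcol, na.rm = TRUE))
    x <- table$scores[, j]
    if (!all(is.finite(rng))) {
      warning("method '", table$methods[j], "' has no observed scores; ",
              "column emitted as all-missing")
      out[, j] <- missing_value
      next
    }
    if (rng[1] == rng[2]) {
      y <- rep((lo + hi) / 2, length(x))       # uninformative constant
    } else {
      y <- lo + (x - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
      y <- pmin(pmax(y, lo), hi)               # clamp outside reference range
    }
    y[is.na(x)] <- missing_value
    out[, j] <- y
  }
  table$scores <- out
  table
}

#' Standardize external scores for fusion input
#'
#' Each method's observed (or reference) raw range is mapped affinely onto
#' `[1, 2]`; missing predictions become exactly 0, so the model can
#' distinguish "missing" from any real score.  A constant-score method
#' maps to the midpoint 1.5.
#'
#' @param table An `mf_external_table` of raw scores.
#' @param reference Optional matrix of reference score distributions
#'   (same columns) standing in for the database-wide score population;
#'   defaults to the table itself.
#' @return The table with scores in `{0} U [1, 2]`.
#' @export
standardize_for_fusion <- function(table, reference = NULL) {
  .standardize(table, 1, 2, 0, reference)
}

#' Standardize external scores for method comparison
#'
#' Affine map of each method onto `[0, 1]` based on a reference score
#' population; missing predictions are assigned 0.
#'
#' @inheritParams standardize_for_fusion
#' @return The table with scores in `[0, 1]`.
#' @export
standardize_for_comparison <- function(table, reference = NULL) {
  .standardize(table, 0, 1, 0, reference)
}

#' Orient a method's scores so higher means more deleterious
#'
#' Both orientations are evaluated by ROC AUC on labeled training data and
#' the better one kept (ties keep the non-inverted orientation).
#' Inversion maps `x` to `min + max - x`, preserving the score range.
#'
#' @param scores Numeric scores (`NA` allowed; ignored in the AUC).
#' @param labels Training labels (both classes required).
#' @return List with `scores` (possibly inverted) and `inverted` flag.
#' @export
orient_scores <- function(scores, labels) {
  y <- .as01(labels)
  ok <- !is.na(scores)
  if (length(unique(y[ok])) < 2L) {
    stop("training labels must contain both classes with observed scores")
  }
  auc <- roc_auc(scores[ok], y[ok])$auc
  if (auc >= 0.5) {
    list(scores = scores, inverted = FALSE)
  } else {
    rng <- range(scores, na.rm = TRUE)
    list(scores = rng[1] + rng[2] - scores, inverted = TRUE)
  }
}

#' Score variants with a model
#'
#' Builds a model input for each variant (paired or single format as the
#' model was fine-tuned), runs the encoder, and converts the pooled (or
#' mutation-site) representation into a deleteriousness probability.
#' Unresolvable variants are skipped with a warning.
#'
#' @param model A fine-tuned `mf_model`.
#' @param variants An `mf_variants` table (labels not required).
#' @param proteome An `mf_proteome` with the reference sequences.
#' @param format Task format used in fine-tuning.
#' @param capacity Token capacity (per sequence for `paired`).
#' @param external_table Optional `mf_external_table` of raw external
#'   scores; required iff the model carries a fusion head.  Scores are
#'   standardized for fusion internally (rows matched by variant key).
#' @param model_tag Tag stored with each prediction.
#' @return Data frame of prediction records: variant keys, `score` in
#'   `[0, 1]`, `model_tag`.
#' @export
mf_predict <- function(model, variants, proteome,
                       format = c("paired", "single", "per_residue"),
                       capacity = 64L, external_table = NULL,
                       model_tag = "mutformer") {
  format <- match.arg(format)
  has_fusion <- !is.null(model$params$fusion.ext_W)
  if (has_fusion && is.null(external_table)) {
    stop("model has a fusion head: external_table is required")
  }
  ok <- rep(TRUE, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    res <- tryCatch({
      ref <- .lookup_protein(proteome, variants$protein_id[i])
      .check_variant(ref, variants[i, ])
      TRUE
    }, error = function(e) {
      warning("skipping variant ", i, ": ", conditionMessage(e))
      FALSE
    })
    ok[i] <- res
  }
  vkeep <- variants[ok, , drop = FALSE]
  class(vkeep) <- class(variants)
  if (!nrow(vkeep)) {
    return(data.frame(protein_id = character(0), position = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      score = numeric(0), model_tag = character(0)))
  }
  vkeep$label <- "benign"   # placeholder; build_task_dataset requires labels
  ds <- build_task_dataset(vkeep, proteome, format = format,
                           capacity = capacity)
  ext <- NULL
  if (has_fusion) {
    std <- standardize_for_fusion(external_table)
    key <- function(v) paste(v$protein_id, v$position, v$ref_aa, v$alt_aa)
    idx <- match(key(vkeep), key(std$variants))
    ext <- matrix(0, nrow(vkeep), ncol(std$scores))
    hit <- !is.na(idx)
    ext[hit, ] <- std$scores[idx[hit], , drop = FALSE]
  }
  probs <- .predict_dataset(model, ds, external = ext)
  data.frame(protein_id = vkeep$protein_id, position = vkeep$position,
             ref_aa = vkeep$ref_aa, alt_aa = vkeep$alt_aa,
             score = probs, model_tag = model_tag,
             stringsAsFactors = FALSE)
}

#' Write / read a flat prediction score table
#'
#' Tab-delimited with header `protein_id position ref_aa alt_aa score
#' model_tag`, sorted by (protein_id, position, alt_aa), scores with six
#' decimal places -- a flat-file layout usable by downstream annotation
#' tools.
#'
#' @param records Prediction data frame from [mf_predict()].
#' @param path Output path.
#' @export
write_score_table <- function(records, path) {
  o <- order(records$protein_id, records$position, records$alt_aa)
  records <- records[o, , drop = FALSE]
  records$score <- sprintf("%.6f", records$score)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$score <- as.numeric(df$score)
  df
}
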