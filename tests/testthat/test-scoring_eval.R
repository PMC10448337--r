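# independent O(n^2) pairwise AUC oracle
auc_oracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (xp in pos) for (xn in neg) {
    tot <- tot + (xp > xn) + 0.5 * (xp == xn)
  }
  tot / (length(pos) * length(neg))
}

# independent PRG oracle: recompute vertices from scratch, dedupe recall-gain
# (keeping the best precision-gain, i.e. the earliest cut), interpolate the
# rg = 0 crossing, and integrate over the union of all vertex abscissae.
prg_oracle <- function(scores, y) {
  pi0 <- mean(y)
  cuts <- sort(unique(scores), decreasing = TRUE)
  pts <- NULL
  for (t in cuts) {
    pred <- scores >= t
    tp <- sum(pred & y == 1)
    if (tp == 0) next
    rec <- tp / sum(y == 1)
    prec <- tp / sum(pred)
    pts <- rbind(pts, c(rg = (rec - pi0) / ((1 - pi0) * rec),
                        pg = (prec - pi0) / ((1 - pi0) * prec)))
  }
  if (is.null(pts)) return(0)
  keep <- !duplicated(pts[, "rg"])
  f <- stats::approxfun(pts[keep, "rg"], pts[keep, "pg"], rule = 1)
  xs <- sort(unique(c(0, 1, pts[keep, "rg"])))
  xs <- xs[xs >= max(0, min(pts[, "rg"])) & xs <= min(1, max(pts[, "rg"]))]
  if (length(xs) < 2) return(0)
  ys <- f(xs)
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

test_that("ROC AUC equals the pairwise Mann-Whitney statistic", {
  expect_equal(roc_auc(c(.9, .8, .3, .2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(.9, .8, .3, .2), c(0, 0, 1, 1))$auc, 0)
  set.seed(71)
  for (i in 1:5) {
    s <- round(runif(50), 2)          # rounded: exercises tie handling
    y <- rbinom(50, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y)$auc, auc_oracle(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  # complement identity for tie-free scores
  set.seed(72)
  s <- runif(40); y <- c(rep(1, 15), rep(0, 25))
  expect_equal(roc_auc(s, y)$auc + roc_auc(-s, y)$auc, 1)
  # curve endpoints
  r <- roc_auc(s, y)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))
})

test_that("PRG area matches brute-force integration, with display clipping", {
  # perfect ranking -> area 1 (closed form)
  y <- c(rep(1, 10), rep(0, 30))
  expect_equal(prg_auc(seq(40, 1), y)$auc_raw, 1, tolerance = 1e-12)
  # anti-perfect ranking -> negative raw, clipped display 0
  anti <- prg_auc(seq(1, 40), y)
  expect_lt(anti$auc_raw, 0)
  expect_equal(anti$auc, 0)
  expect_equal(prg_auc(seq(1, 40), y)$auc_raw,
               prg_oracle(seq(1, 40), y), tolerance = 1e-9)
  set.seed(73)
  for (i in 1:8) {
    s <- round(runif(30), 1)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- prg_auc(s, y)
    expect_equal(p$auc_raw, prg_oracle(s, y), tolerance = 1e-9)
    expect_lte(p$auc_raw, 1 + 1e-12)
    expect_equal(p$auc, max(p$auc_raw, 0))
  }
})

test_that("DeLong test matches permutation and bootstrap oracles", {
  set.seed(74)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  sep <- y + rnorm(n, sd = 0.1)       # near-perfectly separating
  rnd <- rnorm(n)
  d <- delong_test(sep, rnd, y)
  expect_lt(d$p_value, 0.01)
  expect_gt(d$auc_a, 0.95)
  # permutation oracle: swap the two methods' scores per example
  obs <- abs(roc_auc(sep, y)$auc - roc_auc(rnd, y)$auc)
  perm <- replicate(200, {
    swap <- runif(n) < 0.5
    a <- ifelse(swap, rnd, sep); b <- ifelse(swap, sep, rnd)
    abs(roc_auc(a, y)$auc - roc_auc(b, y)$auc)
  })
  expect_lt(mean(perm >= obs), 0.01)
  # identical scores: difference 0, p = 1
  same <- delong_test(rnd, rnd, y)
  expect_equal(same$p_value, 1)
  expect_equal(same$auc_a, same$auc_b)
  # variance vs bootstrap on correlated random scores, n = 500
  set.seed(75)
  n <- 500
  y <- rbinom(n, 1, 0.5)
  base <- rnorm(n)
  s_a <- base + rnorm(n)
  s_b <- base + rnorm(n)
  dl <- delong_test(s_a, s_b, y)
  boots <- replicate(1000, {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    roc_auc(s_a[idx], y[idx])$auc - roc_auc(s_b[idx], y[idx])$auc
  })
  expect_lt(abs(stats::var(boots, na.rm = TRUE) - dl$var_diff) / dl$var_diff,
            0.2)
})

test_that("corner-threshold specificity matches an exhaustive scan", {
  # perfectly separable training data
  tr_s <- c(.9, .8, .7, .2, .1)
  tr_y <- c(1, 1, 1, 0, 0)
  r <- specificity_at_corner(tr_s, tr_y, c(.05, .1, .15))
  expect_gt(r$threshold, 0.2); expect_lte(r$threshold, 0.7)
  expect_equal(r$specificity, 1)
  expect_equal(specificity_at_corner(tr_s, tr_y, c(.95, .99))$specificity, 0)
  set.seed(76)
  for (i in 1:5) {
    s <- round(runif(60), 2)
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    test_s <- runif(30)
    got <- specificity_at_corner(s, y, test_s)
    # exhaustive oracle
    cand <- sort(unique(s)); best <- Inf; bd <- 1
    for (t in cand) {
      fpr <- mean(s[y == 0] >= t); tpr <- mean(s[y == 1] >= t)
      dd <- sqrt(fpr^2 + (1 - tpr)^2)
      if (dd < bd - 1e-15) { bd <- dd; best <- t }
    }
    expect_equal(got$threshold, best)
    expect_equal(got$specificity, mean(test_s < best))
  }
  expect_error(specificity_at_corner(c(1, 2), c(1, 1), 0.5), "both classes")
})

test_that("fusion standardization maps ranges onto [1,2] with explicit missing", {
  v <- mf_variants(c("p1", "p1", "p2"), c(1L, 2L, 3L), c("M", "K", "V"),
                   c("V", "R", "L"))
  tab <- mf_external_table(v, cbind(m1 = c(0.2, 0.7, NA),
                                    m2 = c(3, 3, 3),
                                    m3 = c(-5, 0, 10)))
  std <- standardize_for_fusion(tab)
  expect_equal(std$scores[, "m1"], c(1, 2, 0))
  expect_equal(std$scores[, "m2"], rep(1.5, 3))       # constant -> midpoint
  expect_equal(std$scores[, "m3"], 1 + c(0, 5, 15) / 15)
  expect_true(all(std$scores == 0 | (std$scores >= 1 & std$scores <= 2)))
  # all-missing column warns and stays missing-coded
  tab2 <- mf_external_table(v, cbind(m1 = c(1, 2, 3), dead = rep(NA_real_, 3)))
  expect_warning(std2 <- standardize_for_fusion(tab2), "no observed")
  expect_equal(std2$scores[, "dead"], rep(0, 3))
})

test_that("comparison standardization uses the reference distribution", {
  v <- mf_variants(c("p1", "p1"), 1:2, c("M", "K"), c("V", "R"))
  tab <- mf_external_table(v, cbind(m = c(3, 5)))
  std <- standardize_for_comparison(tab)
  expect_equal(std$scores[, "m"], c(0, 1))
  # reference median maps to the affine midpoint
  ref <- cbind(m = c(0, 2, 4, 6, 8))
  std2 <- standardize_for_comparison(tab, reference = ref)
  expect_equal(std2$scores[, "m"], c(3 / 8, 5 / 8))
  tab3 <- mf_external_table(v, cbind(m = c(NA, 5)))
  expect_equal(standardize_for_comparison(tab3)$scores[, "m"][1], 0)
})

test_that("score orientation maximizes training AUC, ties keep non-inverted", {
  y <- c(1, 1, 0, 0)
  flipped <- orient_scores(c(.1, .2, .8, .9), y)   # AUC 0 -> invert
  expect_true(flipped$inverted)
  expect_equal(roc_auc(flipped$scores, y)$auc, 1)
  kept <- orient_scores(c(.9, .8, .2, .1), y)
  expect_false(kept$inverted)
  tie <- orient_scores(c(.9, .1, .8, .2), y)       # AUC exactly 0.5
  expect_false(tie$inverted)
  expect_error(orient_scores(1:3, c(1, 1, 1)), "both classes")
  # property: oriented training AUC always >= 0.5
  set.seed(77)
  for (i in 1:10) {
    s <- runif(30); y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    o <- orient_scores(s, y)
    expect_gte(roc_auc(o$scores, y)$auc, 0.5)
  }
})

test_that("prediction records and the flat score file round trip", {
  w <- tiny_world()
  set.seed(78)
  model <- mf_init_model(tiny_config(H = 16L, layers = 1L, S = 32L))
  v <- subset_variants(w$labeled, 1:5)
  rec <- mf_predict(model, v, w$proteome, format = "paired", capacity = 12L)
  expect_equal(nrow(rec), 5L)
  expect_true(all(rec$score >= 0 & rec$score <= 1))
  # determinism: same variant scores identically
  rec2 <- mf_predict(model, v, w$proteome, format = "paired", capacity = 12L)
  expect_identical(rec$score, rec2$score)
  # unresolvable variants are skipped with a warning
  bad <- mf_variants(c(v$protein_id[1], "nosuch"), c(v$position[1], 3L),
                     c(v$ref_aa[1], "A"), c(v$alt_aa[1], "G"))
  expect_warning(rec3 <- mf_predict(model, bad, w$proteome,
                                    format = "paired", capacity = 12L),
                 "skipping")
  expect_equal(nrow(rec3), 1L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(rec, path)
  lines <- readLines(path)
  expect_length(lines, 6L)  # header + 5 records
  back <- read_score_table(path)
  o <- order(rec$protein_id, rec$position, rec$alt_aa)
  expect_equal(back$score, round(rec$score[o], 6))
  expect_equal(back$protein_id, rec$protein_id[o])
})

test_that("fusion models require and use external tables in prediction", {
  w <- tiny_world()
  set.seed(79)
  model <- mf_init_model(tiny_config(H = 16L, layers = 1L, S = 32L,
                                     n_external = 3L))
  v <- subset_variants(w$labeled, 1:4)
  expect_error(mf_predict(model, v, w$proteome, capacity = 12L),
               "external_table")
  ext <- mf_external_table(v, matrix(rnorm(12), 4, 3,
                                     dimnames = list(NULL, c("a", "b", "c"))))
  rec <- mf_predict(model, v, w$proteome, format = "paired", capacity = 12L,
                    external_table = ext)
  expect_equal(nrow(rec), 4L)
  expect_true(all(rec$score >= 0 & rec$score <= 1))
})

test_that("external tables round trip through TSV with empty-cell missing", {
  v <- mf_variants(c("p1", "p2"), c(1L, 5L), c("M", "G"), c("T", "C"))
  tab <- mf_external_table(v, cbind(sift = c(0.2, NA), cadd = c(12, 25)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_external_table(tab, path)
  expect_false(grepl("NA", paste(readLines(path), collapse = "")))
  back <- read_external_table(path)
  expect_equal(back$scores, tab$scores)
  expect_equal(back$methods, c("sift", "cadd"))
})
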