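make_batch <- function(n = 2L, capacity = 12L, format = "paired") {
  w <- tiny_world()
  v <- subset_variants(w$labeled, seq_len(n))
  ds <- build_task_dataset(v, w$proteome, format = format,
                           capacity = capacity)
  lapply(ds$entries, `[[`, "example")
}

test_that("embedding sums token/position/label terms with layer norm", {
  set.seed(1)
  model <- mf_init_model(tiny_config())
  b_single <- make_batch(2, 16, "single")
  b_paired <- make_batch(2, 8, "paired")
  E <- mf_embed(model, b_single)
  expect_equal(dim(E), c(2L * 16L, 16L))
  # single-sequence input must not receive any label-embedding term:
  # perturbing seg_emb leaves it unchanged (asymmetric perturbation, since
  # a constant shift would be absorbed by the layer norm)
  m2 <- model
  m2$params$seg_emb[, 1] <- m2$params$seg_emb[, 1] + 5
  expect_equal(mf_embed(m2, b_single), E)
  expect_false(isTRUE(all.equal(mf_embed(m2, b_paired),
                                mf_embed(model, b_paired))))
  # identical tokens at different positions embed differently
  v <- mf_variants("pp", 2L, "K", "R")
  ex <- build_single_example("ARAAAA", mf_variants("pp", 2L, "K", "R"), 10L)
  Ee <- mf_embed(model, list(ex))
  expect_false(isTRUE(all.equal(Ee[3, ], Ee[5, ])))  # two 'A' residues
  expect_error(mf_embed(model, make_batch(1, 80, "single")),
               "exceeds max_positions")
})

test_that("position 0 is assigned to the first retained token after cropping", {
  set.seed(2)
  model <- mf_init_model(tiny_config())
  d <- demo_entry()
  ex_crop <- build_single_example(d$mut, d$variant, 12L)  # interior crop
  expect_gt(ex_crop$position_offset, 0L)
  ex_full <- build_single_example(d$mut, d$variant, 40L)
  E1 <- mf_embed(model, list(ex_crop))
  # first row always uses position row 1 regardless of crop offset:
  # rebuild by hand with pos row 1 and compare
  E2 <- mf_embed(model, list(ex_full))
  expect_equal(E1[1, ], E2[1, ])  # both [CLS] at position 0
})

test_that("conv stack is shape preserving with the documented degeneracies", {
  set.seed(3)
  batch <- make_batch(2, 10, "paired")
  for (mode in c("sequential", "integrated")) {
    model <- mf_init_model(tiny_config(conv_mode = mode))
    E <- mf_embed(model, batch)
    out <- mf_conv_stack(model, E, batch)
    expect_equal(dim(out), dim(E))
    zeroed <- model
    for (nm in grep("^conv", names(zeroed$params), value = TRUE)) {
      zeroed$params[[nm]] <- zeroed$params[[nm]] * 0
    }
    z <- mf_conv_stack(zeroed, E, batch)
    if (mode == "integrated") expect_equal(z, E) else expect_true(all(z == 0))
  }
})

test_that("integrated convs with zero weights reproduce the conv-free model exactly", {
  set.seed(4)
  cfg_conv <- tiny_config(conv_mode = "integrated")
  model_conv <- mf_init_model(cfg_conv)
  model_none <- mf_init_model(tiny_config(conv_mode = "none"))
  # share every non-conv parameter, zero the convs
  for (nm in names(model_none$params)) {
    model_conv$params[[nm]] <- model_none$params[[nm]]
  }
  for (nm in grep("^conv", names(model_conv$params), value = TRUE)) {
    model_conv$params[[nm]] <- model_conv$params[[nm]] * 0
  }
  batch <- make_batch(2, 10, "paired")
  a <- mf_encode_batch(model_conv, batch)
  b <- mf_encode_batch(model_none, batch)
  expect_identical(a$hidden_states, b$hidden_states)
  expect_identical(a$pooled, b$pooled)
})

test_that("encoder outputs are padding invariant and deterministic", {
  set.seed(5)
  model <- mf_init_model(tiny_config(conv_mode = "integrated"))
  d <- demo_entry()
  ex_short <- build_single_example(d$mut, d$variant, 36L)
  ex_long <- build_single_example(d$mut, d$variant, 50L)
  n <- sum(ex_short$attention_mask)
  expect_equal(sum(ex_long$attention_mask), n)  # same content, more pad
  h1 <- mf_encode_batch(model, list(ex_short))$hidden_states[[1]]
  h2 <- mf_encode_batch(model, list(ex_long))$hidden_states[[1]]
  expect_equal(h1[seq_len(n), ], h2[seq_len(n), ], tolerance = 1e-5)
  # bit-stable repeat
  h3 <- mf_encode_batch(model, list(ex_short))$hidden_states[[1]]
  expect_identical(h1, h3)
})

test_that("zero-layer config degenerates to a passthrough of the embedding", {
  set.seed(6)
  cfg <- mf_config(num_layers = 0, hidden_size = 16, intermediate_size = 32,
                   num_heads = 4, max_positions = 32, dropout = 0)
  model <- mf_init_model(cfg)
  batch <- make_batch(1, 12, "single")
  out <- mf_encode_batch(model, batch)
  expect_equal(out$hidden_states[[1]], mf_embed(model, batch))
})

test_that("parameter accounting matches allocation and the conv closed form", {
  cfg <- tiny_config(conv_mode = "none", H = 16L, layers = 2L, S = 48L)
  m <- mf_init_model(cfg)
  heads <- c("pooler.W", "pooler.b", "cls.w", "cls.b", "token.w", "token.b")
  actual <- sum(vapply(m$params[setdiff(names(m$params), heads)], length, 1L))
  expect_equal(count_parameters(cfg), actual)
  # hand arithmetic for a degenerate 0-layer config
  cfg0 <- mf_config(0, 16, 32, num_heads = 4, max_positions = 48)
  V <- 27; H <- 16; S <- 48
  expect_equal(count_parameters(cfg0),
               V * H + S * H + 2 * H + 2 * H +       # embeddings + LN
               H * H + H + 2 * H + V)                # MLM head, tied decoder
  # conv increment closed form
  cfg_seq <- tiny_config(conv_mode = "sequential", H = 16L, layers = 2L, S = 48L)
  expect_equal(count_parameters(cfg_seq) - count_parameters(cfg),
               4 * (3 * 16 * 16 + 16))
})

test_that("mlm/token/cls heads satisfy their output contracts", {
  set.seed(7)
  model <- mf_init_model(tiny_config())
  batch <- make_batch(2, 10, "paired")
  out <- mf_encode_batch(model, batch)
  h <- out$hidden_states[[1]]
  probs <- mf_mlm_head(model, h)
  expect_equal(dim(probs), c(nrow(h), 27L))
  expect_equal(rowSums(probs), rep(1, nrow(h)), tolerance = 1e-6)
  tp <- mf_token_head(model, h)
  expect_true(all(tp >= 0 & tp <= 1))
  cp <- mf_cls_head(model, out$pooled)
  expect_true(all(cp >= 0 & cp <= 1))
  expect_identical(cp, mf_cls_head(model, out$pooled))
})

test_that("fusion head width and degeneracies follow the 1:1 capacity design", {
  set.seed(8)
  model <- mf_init_model(tiny_config(n_external = 3L))
  H <- model$config$hidden_size
  expect_length(model$params$fusion.out_w, 2L * H)  # concat width H + H
  pooled <- matrix(rnorm(2 * H), 2, H)
  ext <- matrix(c(0, 1.5, 2, 0, 1.1, 1.9), 2, 3)
  p <- mf_fusion_head(model, pooled, ext)
  expect_true(all(p >= 0 & p <= 1))
  # all-missing externals still yield a valid sequence-driven probability
  p0 <- mf_fusion_head(model, pooled, matrix(0, 2, 3))
  expect_true(all(p0 >= 0 & p0 <= 1))
  # zeroing the external dense cuts the external path entirely
  m2 <- model
  m2$params$fusion.ext_W <- m2$params$fusion.ext_W * 0
  m2$params$fusion.ext_b <- m2$params$fusion.ext_b * 0
  expect_equal(mf_fusion_head(m2, pooled, ext),
               mf_fusion_head(m2, pooled, matrix(0, 2, 3)))
  expect_error(mf_fusion_head(model, pooled, matrix(0, 2, 2)), "length")
})

test_that("weighting analysis splits the output layer at the concatenation", {
  set.seed(9)
  model <- mf_init_model(tiny_config(H = 8L, heads = 2L, n_external = 2L))
  H <- 8L
  m <- model
  m$params$fusion.out_w <- c(rep(0.5, H), rep(0.5, H))
  expect_equal(unname(weighting_analysis(m)), c(0.5, 0.5))
  m$params$fusion.out_w <- c(rep(1, H), rep(0, H))
  m$params$fusion.ext_W <- m$params$fusion.ext_W * 0
  expect_equal(unname(weighting_analysis(m)), c(1, 0))
  # asymmetric case against direct arithmetic
  m2 <- model
  m2$params$fusion.out_w <- c(rep(-1, H), rep(3, H))
  w <- weighting_analysis(m2)
  expect_equal(unname(w), c(H * 1, H * 3) / (H * 1 + H * 3))
  expect_equal(sum(w), 1)
  expect_error(weighting_analysis(mf_init_model(tiny_config())), "fusion")
})

test_that("freezing marks embeddings, convs and the first n layers", {
  set.seed(10)
  model <- mf_init_model(tiny_config(conv_mode = "integrated"))
  expect_length(freeze_layers(model, 0)$frozen, 0L)
  m2 <- freeze_layers(model, 2)
  expect_true(all(c("tok_emb", "pos_emb", "emb_ln.g") %in% m2$frozen))
  expect_true("conv1.Wc" %in% m2$frozen)
  expect_true(all(grepl("^(layer[12]\\.|conv|tok|pos|seg|emb)", m2$frozen)))
  expect_false(any(grepl("^(cls|token|pooler|mlm)", m2$frozen)))
  m1 <- freeze_layers(model, 1)
  expect_true(any(grepl("^layer1\\.", m1$frozen)))
  expect_false(any(grepl("^layer2\\.", m1$frozen)))
  expect_error(freeze_layers(model, 3), "between 0 and")
})

test_that("checkpoints and configs round trip", {
  set.seed(11)
  model <- mf_init_model(tiny_config(conv_mode = "sequential"))
  path <- withr::local_tempfile(fileext = ".rds")
  mf_save_checkpoint(model, path)
  m2 <- mf_load_checkpoint(path)
  expect_equal(m2$params, model$params)
  expect_equal(unclass(m2$config), unclass(model$config))
  cpath <- withr::local_tempfile(fileext = ".json")
  mf_write_config(model$config, cpath)
  expect_equal(unclass(mf_read_config(cpath)), unclass(model$config))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(mf_config(2, 30, num_heads = 4), "divisible")
  expect_error(mf_config(2, 32, num_heads = 4, kernel_size = 4), "odd")
  expect_error(mf_config(2, 32, num_heads = 4, kernel_size = 5), "kernel_size = 3")
})
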