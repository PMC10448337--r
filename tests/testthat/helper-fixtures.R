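# Shared fixtures: tiny configs, a small synthetic world, and cached
# trained models so expensive training runs happen once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_config <- function(conv_mode = "none", H = 16L, layers = 2L,
                        heads = 4L, S = 64L, n_external = 0L) {
  mf_config(num_layers = layers, hidden_size = H,
            intermediate_size = 2L * H, num_heads = heads,
            max_positions = S, conv_mode = conv_mode,
            conv_layers = 4L, dropout = 0, n_external = n_external)
}

# deterministic small synthetic world shared across tests
tiny_world <- function() {
  cached("world", {
    set.seed(101)
    cfg <- mf_sim_config(n_proteins = 30, min_len = 50, max_len = 80,
                         motif = "WDWDW")
    pr <- generate_proteome(cfg)
    common <- generate_common_variants(pr, rate = 0.02)
    labeled <- generate_labeled_variants(pr, 200, exclude = common)
    list(sim = cfg, proteome = pr, common = common, labeled = labeled)
  })
}

subset_variants <- function(v, idx) {
  out <- v[idx, , drop = FALSE]
  class(out) <- class(v)
  out
}

# one fixed protein + variant for layout tests
demo_entry <- function() {
  ref <- "MKVLWAAYDDLQEFGHIKNNPQRSTVWYAC"
  v <- mf_variants("demo", 12L, "Q", "H", "deleterious")
  list(ref = ref, mut = apply_variant(ref, v), variant = v)
}
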