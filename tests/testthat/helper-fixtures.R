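# Shared fixtures, built once per test session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small clean benchmark (5 identity types, no activity) carried through the
# decomposition and network stages; used by network/pruning/annotation tests
small_pipeline <- function() {
  memo("small_pipeline", function() {
    cfg <- synthetic_config(n_identity_programs = 5, n_activity_programs = 0,
                            cells_per_type = 40, n_genes = 200,
                            noise_level = "low", seed = 42)
    bm <- generate_benchmark(cfg)
    Z <- kernel_transform(bm$expr)
    red <- reduce_profile(Z, dim = 20, seed = 1)
    ml <- run_multilevel(red, 2, 12)
    net <- build_network(ml)
    list(cfg = cfg, bm = bm, Z = Z, red = red, ml = ml, net = net)
  })
}

# noisy hull fixture whose rank supports decompositions past the planted k
noisy_hull <- function() {
  memo("noisy_hull", function() {
    hf <- hull_fixture(D = 10, k = 6, n_cells = 120, seed = 11)
    S <- hf$S_r + statescape:::with_seed(99, matrix(rnorm(10 * 120, sd = 0.05), 10, 120))
    out <- as_reduced_profile(S, cell_names = hf$cell_names)
    attr(out, "planted") <- attr(hf, "planted")
    out
  })
}
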