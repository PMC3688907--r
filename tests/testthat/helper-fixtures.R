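# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from disk except through the package's own writers.

# a small hand-written universe used by the trivial-example tests
tiny_mapping <- function() {
  mapping_table(data.frame(
    protein_id    = c("P1", "P2", "P2", "P3", "P4", ""),
    transcript_id = c("T1", "T2", "T3", "T4", "T5", "T6"),
    gene_id       = c("G1", "G2", "G2", "G3", "G4", "G2"),
    stringsAsFactors = FALSE))
}

tiny_complexes <- function() {
  complex_set(data.frame(
    complex_id = c("C1", "C2", "C3"),
    name = c("alpha", "beta", "gamma"),
    subunits = c("P1;P2", "P1;P9", "P2;P4"),
    stringsAsFactors = FALSE))
}

# an expr_set built directly from matrices
make_expr <- function(est, sd, level = "transcript") {
  expr_set(est, sd, level = level)
}

# detection_call with everything detected (for tests that only exercise the
# set logic); build through the public API so the class stays consistent
all_detected_call <- function(features, samples) {
  est <- matrix(1, length(features), length(samples),
                dimnames = list(features, samples))
  call_detection(expr_set(est, est * 0, level = "transcript"), sd_max = 1.5)
}

# small fast synthetic configuration for randomized-fixture loops
small_cfg <- function(seed, ...) {
  args <- utils::modifyList(list(seed = seed, n_complexes = 30, n_samples = 3,
                                 de = list(n_tx = 300)), list(...))
  do.call(synth_config, args)
}

# noise-free configuration: everything detected, no missing files, planted
# structure exactly recoverable
noise_free_cfg <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, absent_rate = 0, tx_detect = 1, extra_detect = 1,
         missing_rate = 0, boundary_frac = 0,
         p_multi_gene = 0, p_shared_gene = 0), list(...))
  do.call(synth_config, args)
}

# complete small synthetic study: universe + expression + calls
make_study <- function(seed, cfg = small_cfg(seed)) {
  u <- simulate_universe(cfg)
  se <- simulate_expression(cfg, u)
  resolved <- resolve_complexes(u$complexes, u$mapping)
  call <- call_detection(se$expr)
  list(cfg = cfg, universe = u, synth = se, resolved = resolved,
       expr = se$expr, call = call, mapping = u$mapping)
}
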