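test_that("the major isoform is the highest-expressed detected transcript, ties to smallest id", {
  tx2gene <- c(T1 = "G1", T2 = "G1", T3 = "G2", T4 = "G2")
  est <- matrix(c(5, 3, 4, 4), 4, 1, dimnames = list(names(tx2gene), "S1"))
  sd <- est * 0
  ex <- expr_set(est, sd)
  a <- assign_major_isoforms(ex, call_detection(ex), tx2gene)
  expect_equal(a["G1", "S1"], "T1")     # plain argmax
  expect_equal(a["G2", "S1"], "T3")     # 4.0 vs 4.0: lexicographic tie-break

  # undetected transcripts cannot be major; genes with nothing detected are NA
  sd2 <- matrix(c(2, 0.5, 2, 2), 4, 1, dimnames = dimnames(est))
  ex2 <- expr_set(est, sd2)
  a2 <- assign_major_isoforms(ex2, call_detection(ex2), tx2gene)
  expect_equal(a2["G1", "S1"], "T2")
  expect_true(is.na(a2["G2", "S1"]))
})

test_that("assignment on a random 200-gene matrix equals the per-gene argmax oracle", {
  set.seed(701)
  n_tx <- 520
  tx <- sprintf("T%04d", seq_len(n_tx))
  tx2gene <- setNames(sprintf("G%03d", sample(200, n_tx, replace = TRUE)), tx)
  est <- matrix(rnorm(n_tx * 4, 3), n_tx, 4,
                dimnames = list(tx, paste0("S", 1:4)))
  sd <- matrix(runif(n_tx * 4, 0, 3), n_tx, 4, dimnames = dimnames(est))
  ex <- expr_set(est, sd)
  call <- call_detection(ex)
  a <- assign_major_isoforms(ex, call, tx2gene)
  o <- oracle_major(ex, call$detected, tx2gene)
  expect_identical(a[rownames(o), ], o)
})

test_that("assignment is invariant under a monotone rescaling of one sample", {
  st <- make_study(702)
  a0 <- assign_major_isoforms(st$expr, st$call, st$mapping)
  ex2 <- st$expr
  ex2$estimate[, 2] <- 2 * ex2$estimate[, 2] + 7    # monotone map on sample 2
  a1 <- assign_major_isoforms(ex2, st$call, st$mapping)
  expect_identical(a0, a1)
})

test_that("major-isoform assignment recovers the generator's planted dominants", {
  for (seed in c(703, 704)) {
    st <- make_study(seed)
    a <- assign_major_isoforms(st$expr, st$call, st$mapping)
    truth <- st$synth$truth$dominant
    expect_identical(a[rownames(truth), colnames(truth)], truth)
  }
})

test_that("involvement fractions match the generator's ground-truth ledger", {
  st <- make_study(705, small_cfg(705, n_samples = 4))
  p <- call_pfpc(st$resolved, st$call, st$mapping)
  a <- assign_major_isoforms(st$expr, st$call, st$mapping)
  inv <- major_involvement(a, p, st$resolved, st$mapping)
  truth <- st$synth$truth$involvement
  expect_equal(inv$frac_subunits_major, truth$frac_subunits_major)
  expect_equal(inv$frac_pfpc_major, truth$frac_pfpc_major)
})

test_that("a sole detected isoform is trivially major; all-extra genes are not involved", {
  m <- mapping_table(data.frame(
    protein_id    = c("P1", "P2", ""),
    transcript_id = c("T1", "T2", "T3"),
    gene_id       = c("G1", "G2", "G2"), stringsAsFactors = FALSE))
  cs <- complex_set(data.frame(complex_id = c("C1", "C2"),
                               name = c("a", "b"),
                               subunits = c("P1", "P2"),
                               stringsAsFactors = FALSE))
  res <- resolve_complexes(cs, m)
  est <- matrix(c(1, 1, 5), 3, 1, dimnames = list(c("T1", "T2", "T3"), "S1"))
  ex <- expr_set(est, est * 0)
  call <- call_detection(ex)
  p <- call_pfpc(res, call, m)
  a <- assign_major_isoforms(ex, call, m)
  inv <- major_involvement(a, p, res, m)
  # P1: sole isoform of G1 is major -> involved; P2: G2's major is the
  # non-coding T3 -> not involved
  expect_equal(inv$frac_subunits_major, 0.5)
  expect_equal(inv$frac_pfpc_major, 0.5)
})

test_that("eligibility needs >= 2 transcripts from a single gene", {
  m <- mapping_table(data.frame(
    protein_id    = c("P1", "P1", "P2", "P2", "P3"),
    transcript_id = c("T1", "T2", "T3", "T4", "T5"),
    gene_id       = c("G1", "G1", "G2", "G3", "G4"),
    stringsAsFactors = FALSE))
  e <- eligible_components(c("P1", "P2", "P3"), m)
  expect_equal(e$protein, "P1")   # P2 has 2 transcripts but from 2 genes
  expect_equal(e$gene, "G1")
})

test_that("switch matrices are symmetric, zero-diagonal and bounded", {
  st <- make_study(706, small_cfg(706, n_samples = 5))
  a <- assign_major_isoforms(st$expr, st$call, st$mapping)
  proteins <- sort(unique(unlist(st$resolved$kept$subunits)))
  sw <- switch_matrix(a, proteins, st$mapping)
  f <- sw$fraction
  expect_identical(f, t(f))
  expect_equal(unname(diag(f)), rep(0, ncol(f)))
  off <- f[upper.tri(f)]
  expect_true(all(is.na(off) | (off >= 0 & off <= 1)))
  expect_identical(sw$n_informative, t(sw$n_informative))
})

test_that("identical samples produce an all-zero switch matrix", {
  st <- make_study(707)
  ex <- st$expr
  ex$estimate <- ex$estimate[, c(1, 1, 1)]
  ex$sd <- ex$sd[, c(1, 1, 1)]
  colnames(ex$estimate) <- colnames(ex$sd) <- paste0("S", 1:3)
  call <- call_detection(ex)
  a <- assign_major_isoforms(ex, call, st$mapping)
  proteins <- sort(unique(unlist(st$resolved$kept$subunits)))
  sw <- switch_matrix(a, proteins, st$mapping)
  off <- sw$fraction[upper.tri(sw$fraction)]
  expect_true(all(off[!is.na(off)] == 0))
  expect_equal(sw$overall_switch_fraction, 0)
})

test_that("an empty pair denominator is reported as missing, not zero", {
  a <- matrix(c("T1", NA, NA, "T2"), 2, 2,
              dimnames = list(c("G1", "G2"), c("S1", "S2")))
  m <- mapping_table(data.frame(
    protein_id    = c("P1", "P1", "P2", "P2"),
    transcript_id = c("T1", "T1b", "T2", "T2b"),
    gene_id       = c("G1", "G1", "G2", "G2"), stringsAsFactors = FALSE))
  sw <- switch_matrix(a, c("P1", "P2"), m)
  expect_true(is.na(sw$fraction["S1", "S2"]))
  expect_equal(sw$n_informative["S1", "S2"], 0L)
})

test_that("a noise-free planted switch rate is recovered exactly", {
  # enough single-gene two-isoform components that rounding is exact
  cfg <- noise_free_cfg(708, n_complexes = 120, n_samples = 3,
                        switch_rate = 0.12, p_gene_extra_tx = 0)
  u <- simulate_universe(cfg)
  se <- simulate_expression(cfg, u)
  res <- resolve_complexes(u$complexes, u$mapping)
  call <- call_detection(se$expr)
  a <- assign_major_isoforms(se$expr, call, u$mapping)
  proteins <- sort(unique(unlist(res$kept$subunits)))
  sw <- switch_matrix(a, proteins, u$mapping)
  for (s in names(se$truth$switch)) {
    planted <- se$truth$switch[[s]]
    expect_equal(sw$fraction["S01", s], planted$planted_fraction)
    expect_equal(sw$n_informative["S01", s], planted$n_eligible_defined)
  }
})
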