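test_that("median-deviation normalization has its closed-form properties", {
  set.seed(801)
  x <- matrix(rpois(300, 50) + 1, 100, 3,
              dimnames = list(sprintf("T%03d", 1:100), c("A", "B", "C")))

  # single sample: offset zero, matrix unchanged
  one <- normalize_median_deviation(x[, 1, drop = FALSE])
  expect_equal(unname(attr(one, "offsets")), 0)
  expect_equal(one[, 1], x[, 1])

  # doubling a sample shifts its offset by log(2) relative to the original
  y <- cbind(A = x[, 1], B = 2 * x[, 1])
  ny <- normalize_median_deviation(y)
  off <- attr(ny, "offsets")
  expect_equal(unname(off["B"] - off["A"]), log(2))
  expect_equal(median(log(ny[ny[, 1] > 0, 1])),
               median(log(ny[ny[, 2] > 0, 2])))

  # definitional: per-sample medians of log nonzero values all equal
  nx <- normalize_median_deviation(x)
  meds <- apply(nx, 2, function(v) median(log(v[v > 0])))
  expect_equal(max(meds) - min(meds), 0, tolerance = 1e-12)
  expect_equal(sum(attr(nx, "offsets")), 0)

  # a sample with no nonzero values is an error
  bad <- x; bad[, 2] <- 0
  expect_error(normalize_median_deviation(bad), "nonzero")
})

test_that("a transcript with identical group means gets M = 0, D = 0, q = 0", {
  set.seed(802)
  counts <- matrix(rpois(400, 100), 100, 4,
                   dimnames = list(sprintf("T%03d", 1:100),
                                   c("c1", "c2", "k1", "k2")))
  counts[1, ] <- 100                     # flat transcript
  groups <- c("case", "case", "control", "control")
  res <- noiseq_probability(counts, groups)
  expect_equal(res$M[1], 0)
  expect_equal(res$D[1], 0)
  expect_equal(res$q[1], 0)              # strict domination: no pair beaten
  expect_true(all(res$q >= 0 & res$q <= 1))
})

test_that("q equals a recomputation from the explicit noise pool and the loop oracle", {
  set.seed(803)
  counts <- matrix(rnbinom(200 * 6, mu = 80, size = 20), 200, 6,
                   dimnames = list(sprintf("T%03d", 1:200),
                                   sprintf("s%d", 1:6)))
  counts[1, 1:3] <- counts[1, 1:3] * 8   # strong planted signal
  groups <- rep(c("case", "control"), each = 3)
  res <- noiseq_probability(counts, groups)
  noise <- attr(res, "noise")
  expect_equal(res$q, oracle_q(res$M, res$D, noise$M, noise$D))
  # and against the full independent implementation of the statistic
  o <- oracle_noiseq(counts, groups)
  expect_equal(res$M, o$M)
  expect_equal(res$D, o$D)
  expect_equal(res$q, o$q)
  expect_gt(res$q[1], 0.9)               # eight-fold at high abundance
})

test_that("q is invariant to within-group sample order and label swaps negate M only", {
  set.seed(804)
  counts <- matrix(rnbinom(150 * 8, mu = 60, size = 20), 150, 8,
                   dimnames = list(sprintf("T%03d", 1:150),
                                   sprintf("s%d", 1:8)))
  groups <- rep(c("case", "control"), each = 4)
  res <- noiseq_probability(counts, groups)
  perm <- c(3, 1, 4, 2, 7, 8, 5, 6)      # shuffle within each group
  res_p <- noiseq_probability(counts[, perm], groups[perm])
  expect_equal(res$q, res_p$q)
  expect_equal(res$M, res_p$M)

  swapped <- ifelse(groups == "case", "control", "case")
  res_s <- noiseq_probability(counts, swapped, case = "case")
  expect_equal(res_s$M, -res$M)
  expect_equal(res_s$D, res$D)
  expect_equal(res_s$q, res$q)
})

test_that("singleton groups require simulated technical replicates", {
  counts <- matrix(rpois(100 * 2, 50), 100, 2,
                   dimnames = list(sprintf("T%03d", 1:100), c("a", "b")))
  groups <- c("case", "control")
  expect_error(noiseq_probability(counts, groups, simulate_replicates = FALSE),
               "replicate")
  set.seed(805)
  res <- noiseq_probability(counts, groups)   # auto-enables simulation
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_gt(length(attr(res, "noise")$M), 0)
})

test_that("thresholding is strict, monotone and validated", {
  res <- structure(data.frame(transcript = c("T1", "T2"),
                              M = c(1, 0.1), D = c(10, 1),
                              q = c(0.95, 0.5), stringsAsFactors = FALSE),
                   class = c("de_result", "data.frame"))
  expect_equal(de_call(res, 0.9), "T1")
  expect_length(de_call(res, 0.99), 0)
  expect_length(de_call(res, 0.95), 0)          # strict inequality
  expect_error(de_call(res, 1.2), "q_min")
  expect_error(de_call(res, 0), "q_min")
  expect_error(de_call(res), "q_min")
  # conventional per-dataset defaults
  expect_equal(de_call(res, dataset = "prostate"), "T1")   # 0.8
  expect_length(de_call(res, dataset = "lung"), 0)         # 0.99
})

test_that("raising q_min never grows the DE set under the global null", {
  set.seed(806)
  counts <- matrix(rnbinom(500 * 8, mu = 100, size = 20), 500, 8,
                   dimnames = list(sprintf("T%03d", 1:500), sprintf("s%d", 1:8)))
  groups <- rep(c("case", "control"), each = 4)
  res <- noiseq_probability(normalize_median_deviation(counts), groups)
  prev <- de_call(res, 0.5)
  for (qm in c(0.8, 0.9, 0.99)) {
    cur <- de_call(res, qm)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # under the null, high-q calls are rare
  expect_lte(length(de_call(res, 0.9)) / nrow(counts), 0.1)
})

test_that("planted DE recovery matches the independent oracle on a small study", {
  cfg <- synth_config(seed = 807, de = list(n_tx = 400))
  dd <- simulate_de_counts(cfg, dataset = "small")
  norm <- normalize_median_deviation(dd$counts)
  res <- noiseq_probability(norm, dd$groups)
  o <- oracle_noiseq(norm, dd$groups)
  expect_equal(res$q, o$q)
  de <- de_call(res, 0.9)
  o_de <- o$transcript[o$q > 0.9]
  expect_setequal(de, o_de)
  expect_gte(mean(dd$truth$de %in% de), 0.8)
})
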