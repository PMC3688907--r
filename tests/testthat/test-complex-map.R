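test_that("duplicate subunit sets collapse to the first record", {
  cs <- complex_set(data.frame(
    complex_id = c("A", "B", "C"),
    name = c("one", "two", "three"),
    subunits = c("P1;P2", "P2;P1", "P3"),
    stringsAsFactors = FALSE))
  expect_equal(cs$complexes$complex_id, c("A", "C"))
  expect_equal(cs$rejects$complex_id, "B")
  expect_match(cs$rejects$reason, "duplicate of A")
})

test_that("complexes with uncertain subunit tokens are dropped and logged", {
  cs <- complex_set(data.frame(
    complex_id = c("A", "B"),
    name = c("ok", "ambiguous"),
    subunits = c("P1;P2", "P1;(P2|P3)"),
    stringsAsFactors = FALSE))
  expect_equal(cs$complexes$complex_id, "A")
  expect_equal(cs$rejects$reason, "uncertain subunits")
})

test_that("empty subunit lists are rejected, not fatal", {
  cs <- complex_set(data.frame(
    complex_id = c("A", "B"),
    name = c("ok", "empty"),
    subunits = c("P1", ""),
    stringsAsFactors = FALSE))
  expect_equal(nrow(cs$complexes), 1)
  expect_equal(cs$rejects$reason, "empty subunit list")
})

test_that("a missing required column is reported by name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("complex_id\tname", path)
  expect_error(read_complex_table(path), "subunits")
})

test_that("a planted 50-row table with 7 duplicates and 3 uncertain rows leaves 40", {
  set.seed(401)
  base_sets <- lapply(1:40, function(i) {
    sort(sample(sprintf("P%02d", 1:60), sample(2:4, 1)))
  })
  # regenerate until the 40 base sets are distinct as sets
  while (anyDuplicated(vapply(base_sets, paste, character(1), collapse = ";"))) {
    base_sets <- lapply(1:40, function(i) {
      sort(sample(sprintf("P%02d", 1:60), sample(2:4, 1)))
    })
  }
  dup_sets <- lapply(base_sets[sample(40, 7)], rev)   # same sets, new order
  unc_sets <- list(c("P01", "(P02|P03)"), c("(P9|P8)"), c("P04;(P05|P06)"))
  subunits <- c(vapply(base_sets, paste, character(1), collapse = ";"),
                vapply(dup_sets, paste, character(1), collapse = ";"),
                vapply(unc_sets, paste, character(1), collapse = ";"))
  ord <- sample(length(subunits))
  df <- data.frame(complex_id = sprintf("CPX%02d", seq_along(subunits)),
                   name = "x", subunits = subunits,
                   stringsAsFactors = FALSE)[ord, ]

  # independent brute-force recount: distinct subunit sets among certain rows
  certain <- !grepl("[(|]", df$subunits)
  keys <- vapply(strsplit(df$subunits[certain], ";"),
                 function(s) paste(sort(s), collapse = ";"), character(1))
  expect_equal(length(unique(keys)), 40)

  cs <- complex_set(df)
  expect_equal(nrow(cs$complexes), 40)
  expect_equal(sum(grepl("duplicate", cs$rejects$reason)), 7)
  expect_equal(sum(cs$rejects$reason == "uncertain subunits"), 3)
})

test_that("cleaning is idempotent through its own serialization", {
  set.seed(402)
  u <- simulate_universe(small_cfg(402))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_complex_table(u$complexes, path)
  again <- read_complex_table(path)
  expect_equal(again$complexes$complex_id, u$complexes$complexes$complex_id)
  expect_equal(again$complexes$subunits, u$complexes$complexes$subunits)
  expect_equal(nrow(again$rejects), 0)
})

test_that("resolution keeps fully mappable complexes and names the first unmapped subunit", {
  res <- resolve_complexes(tiny_complexes(), tiny_mapping())
  expect_equal(res$kept$complex_id, c("C1", "C3"))
  expect_equal(res$kept$resolved_transcripts[[1]], c("T1", "T2", "T3"))
  expect_equal(res$kept$resolved_genes[[1]], c("G1", "G2"))
  expect_equal(res$dropped$complex_id, "C2")
  expect_equal(res$dropped$unmapped_subunit, "P9")
})

test_that("keep/drop on a mutilated mapping matches a brute-force recount", {
  cfg <- synth_config(seed = 403, n_complexes = 200, n_samples = 2)
  u <- simulate_universe(cfg)
  tab <- u$mapping$table
  victims <- sample(unique(tab$protein_id[nzchar(tab$protein_id)]), 12)
  tab2 <- tab[!(tab$protein_id %in% victims), , drop = FALSE]
  mapping2 <- mapping_table(tab2)

  res <- resolve_complexes(u$complexes, mapping2)
  keep_oracle <- vapply(u$complexes$complexes$subunits, function(su) {
    all(vapply(su, function(p) p %in% names(mapping2$protein2tx), logical(1)))
  }, logical(1))
  expect_equal(nrow(res$kept), sum(keep_oracle))
  expect_equal(res$kept$complex_id,
               u$complexes$complexes$complex_id[keep_oracle])
  # partition invariant
  expect_equal(nrow(res$kept) + nrow(res$dropped),
               nrow(u$complexes$complexes))
})

test_that("resolved transcript sets are the union over subunits", {
  st <- make_study(404)
  for (i in seq_len(nrow(st$resolved$kept))) {
    su <- st$resolved$kept$subunits[[i]]
    expected <- sort(unique(unlist(st$mapping$protein2tx[su])))
    expect_identical(st$resolved$kept$resolved_transcripts[[i]], expected)
  }
})

test_that("sharing and per-protein statistics follow the definitions", {
  m <- mapping_table(data.frame(
    protein_id = c("P1", "P2", "P3"),
    transcript_id = c("T1", "T2", "T3"),
    gene_id = c("G1", "G2", "G3"),
    stringsAsFactors = FALSE))
  cs <- complex_set(data.frame(complex_id = c("C1", "C2"),
                               name = c("a", "b"),
                               subunits = c("P1;P2", "P1;P3"),
                               stringsAsFactors = FALSE))
  st <- complex_stats(resolve_complexes(cs, m), m)
  expect_equal(st$sharing_fraction, 1 / 3)
  expect_equal(st$max_complexes_per_protein, 2)
  expect_equal(st$most_shared_protein, "P1")

  m1 <- mapping_table(data.frame(
    protein_id = rep("P1", 4),
    transcript_id = paste0("T", 1:4),
    gene_id = rep("G1", 4), stringsAsFactors = FALSE))
  cs1 <- complex_set(data.frame(complex_id = "C1", name = "solo",
                                subunits = "P1", stringsAsFactors = FALSE))
  st1 <- complex_stats(resolve_complexes(cs1, m1), m1)
  expect_equal(st1$mean_tx_per_subunit, 4.0)

  expect_warning(st0 <- complex_stats(resolve_complexes(
    complex_set(data.frame(complex_id = character(0), name = character(0),
                           subunits = character(0), stringsAsFactors = FALSE)),
    m), m), "empty")
  expect_equal(st0$n_complexes, 0)
})

test_that("the generator's planted sharing rate is recovered exactly from its output", {
  # around 300 proteins: 200 complexes of mean size ~3.4 at sharing 0.5
  cfg <- synth_config(seed = 405, n_complexes = 200, n_samples = 2,
                      sharing = 0.5)
  u <- simulate_universe(cfg)
  st <- complex_stats(resolve_complexes(u$complexes, u$mapping), u$mapping)
  expect_gte(st$n_proteins, 250)
  expect_identical(st$sharing_fraction, u$truth$sharing_fraction)
})
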