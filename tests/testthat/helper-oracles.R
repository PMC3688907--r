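# Brute-force reference implementations, written as plain loops over the
# definitions, independent of the package's vectorised code paths.

oracle_detection <- function(expr, sd_max = 1.5) {
  out <- matrix(FALSE, nrow(expr$sd), ncol(expr$sd), dimnames = dimnames(expr$sd))
  for (i in seq_len(nrow(expr$sd))) {
    for (j in seq_len(ncol(expr$sd))) {
      s <- expr$sd[i, j]
      out[i, j] <- !is.na(s) && s <= sd_max
    }
  }
  out
}

oracle_rollup <- function(detected, tx2gene) {
  genes <- unique(unname(tx2gene[rownames(detected)]))
  out <- matrix(FALSE, length(genes), ncol(detected),
                dimnames = list(genes, colnames(detected)))
  for (g in genes) {
    txs <- rownames(detected)[tx2gene[rownames(detected)] == g]
    for (j in seq_len(ncol(detected))) {
      out[g, j] <- any(detected[txs, j])
    }
  }
  out
}

oracle_protein_expressed <- function(proteins, detected, assoc) {
  out <- matrix(FALSE, length(proteins), ncol(detected),
                dimnames = list(proteins, colnames(detected)))
  for (p in proteins) {
    feats <- assoc[[p]]
    feats <- feats[feats %in% rownames(detected)]
    for (j in seq_len(ncol(detected))) {
      out[p, j] <- length(feats) > 0 && any(detected[feats, j])
    }
  }
  out
}

# exhaustive PFPC enumeration: complex formable iff every subunit has >= 1
# detected associated feature in the sample
oracle_pfpc <- function(kept, detected, assoc) {
  out <- matrix(FALSE, nrow(kept), ncol(detected),
                dimnames = list(kept$complex_id, colnames(detected)))
  for (i in seq_len(nrow(kept))) {
    for (j in seq_len(ncol(detected))) {
      ok <- TRUE
      for (p in kept$subunits[[i]]) {
        feats <- assoc[[p]]
        feats <- feats[feats %in% rownames(detected)]
        if (length(feats) == 0 || !any(detected[feats, j])) {
          ok <- FALSE
          break
        }
      }
      out[i, j] <- ok
    }
  }
  out
}

# per-gene argmax over detected transcripts, ties to smallest transcript id
oracle_major <- function(expr, detected, tx2gene) {
  feats <- rownames(expr$estimate)
  genes <- unique(unname(tx2gene[feats]))
  out <- matrix(NA_character_, length(genes), ncol(expr$estimate),
                dimnames = list(genes, colnames(expr$estimate)))
  for (g in genes) {
    txs <- feats[tx2gene[feats] == g]
    for (j in seq_len(ncol(expr$estimate))) {
      det <- txs[detected[txs, j] & !is.na(expr$estimate[txs, j])]
      if (length(det) == 0) next
      e <- expr$estimate[det, j]
      best <- det[e == max(e)]
      out[g, j] <- sort(best)[1]
    }
  }
  out
}

# bipartite reachability: DE transcript -> subunit -> complex
oracle_impact <- function(de_set, kept, assoc) {
  affected <- character(0)
  de_in <- character(0)
  for (i in seq_len(nrow(kept))) {
    hit <- character(0)
    for (p in kept$subunits[[i]]) {
      hit <- c(hit, intersect(de_set, assoc[[p]]))
    }
    if (length(hit) > 0) {
      affected <- c(affected, kept$complex_id[i])
      de_in <- c(de_in, hit)
    }
  }
  list(affected = affected, de_in_complex = sort(unique(de_in)))
}

oracle_overlap <- function(sets) {
  k <- length(sets)
  m <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  m
}

# q recomputed from an explicit noise pool, one signal at a time
oracle_q <- function(M, D, noise_M, noise_D) {
  vapply(seq_along(M), function(i) {
    mean(abs(noise_M) < abs(M[i]) & noise_D < D[i])
  }, numeric(1))
}

# full independent implementation of the (M, D) statistic for replicated
# groups: plain loops over the definition (pseudo-count on zeros, group
# means, within-group pair pool)
oracle_noiseq <- function(counts, groups, case = "case", pseudo = 0.5) {
  x <- counts
  x[x == 0] <- pseudo
  ctrl <- setdiff(unique(groups), case)
  mc <- rowMeans(x[, groups == case, drop = FALSE])
  mk <- rowMeans(x[, groups == ctrl, drop = FALSE])
  M <- log2(mc) - log2(mk)
  D <- abs(mc - mk)
  nM <- numeric(0); nD <- numeric(0)
  for (g in c(case, ctrl)) {
    cols <- which(groups == g)
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a < b) {
          nM <- c(nM, log2(x[, cols[a]]) - log2(x[, cols[b]]))
          nD <- c(nD, abs(x[, cols[a]] - x[, cols[b]]))
        }
      }
    }
  }
  data.frame(transcript = rownames(counts), M = M, D = D,
             q = oracle_q(M, D, nM, nD), stringsAsFactors = FALSE)
}
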