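#' Assign the major (dominant) isoform of each gene per sample
#'
#' The major isoform of a gene in a sample is its highest-expressed detected
#' transcript; genes with no detected transcript in a sample have no major
#' isoform there (`NA`). Ties on the expression estimate are broken
#' deterministically by the lexicographically smallest transcript id. The
#' assignment is invariant under any monotone rescaling applied uniformly to
#' one sample's estimates, since only the within-sample ranking matters.
#'
#' @param expr a transcript-level [expr_set()].
#' @param call the matching [call_detection()] result.
#' @param mapping a [mapping_table()] or named character vector transcript →
#'   gene, covering every feature in `expr`.
#' @return Character matrix of class `major_isoforms` (genes x samples),
#'   entries transcript ids or `NA`.
#' @export
assign_major_isoforms <- function(expr, call, mapping) {
  stopifnot(inherits(expr, "expr_set"), inherits(call, "detection_call"))
  if (expr$level != "transcript" || call$level != "transcript") {
    .stopf("major-isoform assignment works on transcript-level data")
  }
  tx2gene <- if (inherits(mapping, "mapping_table")) mapping$tx2gene else mapping
  feats <- rownames(expr$estimate)
  genes_of <- tx2gene[feats]
  offenders <- feats[is.na(genes_of)]
  if (length(offenders) > 0) {
    .stopf("transcript(s) without a gene mapping: %s",
           paste(utils::head(offenders, 5), collapse = ", "))
  }
  genes <- unique(genes_of)
  samples <- colnames(expr$estimate)
  out <- matrix(NA_character_, length(genes), length(samples),
                dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    det <- call$detected[, j] & !is.na(expr$estimate[, j])
    if (!any(det)) next
    idx <- which(det)
    g <- genes_of[idx]
    e <- expr$estimate[idx, j]
    tid <- feats[idx]
    o <- order(g, -e, tid, method = "radix")
    top <- o[!duplicated(g[o])]
    out[g[top], j] <- tid[top]
  }
  structure(out, class = c("major_isoforms", "matrix"))
}

#' Major-isoform involvement of complexes and subunits
#'
#' For each sample, computes (a) the fraction of formable complexes (PFPCs)
#' having at least one subunit whose associated transcript set contains the
#' major isoform of one of that subunit's genes, and (b) the fraction of
#' expressed subunit proteins whose associated transcript set contains the
#' major isoform of one of their genes. A subunit whose sole detected isoform
#' is its gene's only isoform is trivially "involved" (the sole isoform is
#' major by definition).
#'
#' @param assignment a [assign_major_isoforms()] matrix.
#' @param pfpc a transcript-level [call_pfpc()] result on the same samples.
#' @param resolved the [resolve_complexes()] result used for the PFPC calls.
#' @param mapping the [mapping_table()].
#' @return Data frame, one row per sample: `sample`, `n_pfpc`,
#'   `frac_pfpc_major` (a), `n_expressed_subunits`, `frac_subunits_major` (b).
#' @export
major_involvement <- function(assignment, pfpc, resolved, mapping) {
  stopifnot(inherits(pfpc, "pfpc_result"), inherits(mapping, "mapping_table"))
  kept <- if (inherits(resolved, "resolved_complexes")) resolved$kept else resolved
  samples <- colnames(pfpc$formable)
  if (!all(samples %in% colnames(assignment))) {
    .stopf("assignment and PFPC result cover different samples")
  }
  proteins <- rownames(pfpc$expressed)

  res <- lapply(samples, function(s) {
    maj <- assignment[, s]
    involved <- vapply(proteins, function(p) {
      gs <- mapping$protein2gene[[p]]
      m <- maj[gs[gs %in% names(maj)]]
      m <- m[!is.na(m)]
      length(m) > 0 && any(m %in% mapping$protein2tx[[p]])
    }, logical(1))
    expr_p <- pfpc$expressed[, s]
    frac_b <- if (any(expr_p)) mean(involved[expr_p]) else NA_real_
    fm <- pfpc$formable[, s]
    cplx_inv <- vapply(kept$subunits, function(su) any(involved[su]), logical(1))
    frac_a <- if (any(fm)) mean(cplx_inv[fm]) else NA_real_
    data.frame(sample = s,
               n_pfpc = sum(fm),
               frac_pfpc_major = frac_a,
               n_expressed_subunits = sum(expr_p),
               frac_subunits_major = frac_b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Eligible components for major-isoform switching
#'
#' A complex component (protein) is eligible when at least one gene
#' contributes two or more of its associated transcripts; switching is
#' evaluated on that gene's major isoform. For proteins with several
#' qualifying genes the gene contributing the most transcripts is used,
#' ties broken by the lexicographically smallest gene id.
#'
#' @param proteins character vector of component accessions.
#' @param mapping a [mapping_table()].
#' @param min_tx minimum number of same-gene transcripts (default 2).
#' @return Data frame `protein`, `gene` (one row per eligible component).
#' @export
eligible_components <- function(proteins, mapping, min_tx = 2) {
  stopifnot(inherits(mapping, "mapping_table"))
  rows <- lapply(proteins, function(p) {
    txs <- mapping$protein2tx[[p]]
    if (is.null(txs)) return(NULL)
    cnt <- table(mapping$tx2gene[txs])
    cnt <- cnt[cnt >= min_tx]
    if (length(cnt) == 0) return(NULL)
    g <- names(cnt)[order(-as.integer(cnt), names(cnt))][1]
    data.frame(protein = p, gene = g, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein = character(0), gene = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Pairwise major-isoform switch matrix
#'
#' For every pair of samples, the fraction of eligible components whose
#' gene's major isoform differs between the two samples, among components
#' whose gene has a defined major isoform in both (pair-specific
#' denominators). Pairs with an empty denominator are reported as `NA`, not
#' zero. Also reports the overall fraction of eligible components (with a
#' defined major isoform in at least two samples) that switch in at least one
#' sample pair.
#'
#' @param assignment a [assign_major_isoforms()] matrix.
#' @param proteins component accessions to consider (typically all subunit
#'   proteins of the resolved universe).
#' @param mapping a [mapping_table()].
#' @param min_tx minimum same-gene transcript count for eligibility.
#' @return A list of class `switch_matrix` with
#'   * `fraction`: samples x samples symmetric matrix, zero diagonal,
#'     entries in `[0, 1]` or `NA`;
#'   * `n_informative`: pair-specific denominator counts;
#'   * `eligible`: the [eligible_components()] table;
#'   * `overall_switch_fraction`: scalar.
#' @export
switch_matrix <- function(assignment, proteins, mapping, min_tx = 2) {
  elig <- eligible_components(proteins, mapping, min_tx = min_tx)
  samples <- colnames(assignment)
  n <- length(samples)
  if (n < 2) .stopf("switch matrix needs >= 2 samples")
  frac <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  denom <- matrix(0L, n, n, dimnames = list(samples, samples))
  diag(frac) <- 0
  # components whose gene never appears in the expression set are undefined
  # in every sample (all-NA rows), so they never enter a pair denominator
  a <- matrix(NA_character_, nrow(elig), n, dimnames = list(elig$gene, samples))
  present <- elig$gene %in% rownames(assignment)
  a[present, ] <- assignment[elig$gene[present], , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      def <- !is.na(a[, i]) & !is.na(a[, j])
      denom[i, j] <- denom[j, i] <- sum(def)
      if (any(def)) {
        f <- mean(a[def, i] != a[def, j])
        frac[i, j] <- frac[j, i] <- f
      }
    }
  }
  diag(denom) <- as.integer(colSums(!is.na(a)))
  defined_n <- rowSums(!is.na(a))
  switched_any <- vapply(seq_len(nrow(a)), function(k) {
    v <- a[k, !is.na(a[k, ])]
    length(v) >= 2 && length(unique(v)) > 1
  }, logical(1))
  informative <- defined_n >= 2
  overall <- if (any(informative)) mean(switched_any[informative]) else NA_real_
  structure(list(fraction = frac, n_informative = denom,
                 eligible = elig, overall_switch_fraction = overall),
            class = "switch_matrix")
}

#' @export
print.switch_matrix <- function(x, ...) {
  off <- x$fraction[upper.tri(x$fraction)]
  cat(sprintf("switch_matrix: %d eligible components, pairwise switching %.3f-%.3f, overall %.3f\n",
              nrow(x$eligible),
              suppressWarnings(min(off, na.rm = TRUE)),
              suppressWarnings(max(off, na.rm = TRUE)),
              x$overall_switch_fraction))
  invisible(x)
}

#' Write a major-isoform assignment as a long TSV
#'
#' Columns `sample`, `gene`, `major_transcript`; genes without a defined
#' major isoform in a sample are omitted.
#'
#' @param assignment a [assign_major_isoforms()] matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_major_isoforms <- function(assignment, path) {
  idx <- which(!is.na(assignment), arr.ind = TRUE)
  df <- data.frame(sample = colnames(assignment)[idx[, 2]],
                   gene = rownames(assignment)[idx[, 1]],
                   major_transcript = assignment[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(df$sample, df$gene), , drop = FALSE]
  .write_tsv(df, path)
}
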