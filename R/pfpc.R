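#' Per-sample expression status of proteins
#'
#' A protein is considered expressed in a sample when at least one of its
#' associated features is detected there: at transcript level, >= 1 of its
#' associated transcripts; at gene level, >= 1 of its associated genes.
#' Existential (not universal) detection is used throughout: a multi-isoform
#' protein counts as expressed as soon as any isoform that encodes it is
#' reliably detected.
#'
#' @param proteins character vector of protein accessions.
#' @param call a [call_detection()] result (its `level` selects which
#'   association map is used).
#' @param mapping a [mapping_table()]; every protein must be present in it.
#' @return Logical matrix, proteins x samples.
#' @export
protein_expressed <- function(proteins, call, mapping) {
  stopifnot(inherits(call, "detection_call"), inherits(mapping, "mapping_table"))
  assoc <- switch(call$level,
                  transcript = mapping$protein2tx,
                  gene = mapping$protein2gene)
  absent <- proteins[!(proteins %in% names(assoc))]
  if (length(absent) > 0) {
    .stopf("protein(s) absent from the mapping: %s",
           paste(utils::head(absent, 5), collapse = ", "))
  }
  det <- call$detected
  out <- matrix(FALSE, length(proteins), ncol(det),
                dimnames = list(proteins, colnames(det)))
  for (i in seq_along(proteins)) {
    feats <- intersect(assoc[[proteins[i]]], rownames(det))
    if (length(feats) > 0) {
      out[i, ] <- colSums(det[feats, , drop = FALSE]) > 0
    }
  }
  out
}

#' Call possible formable protein complexes (PFPCs) per sample
#'
#' A complex is judged formable in a sample when every one of its subunit
#' proteins is expressed there (existential transcript detection per subunit,
#' see [protein_expressed()]). This is a transcript-presence proxy for
#' assemblability, not evidence of physical assembly. Besides the formable
#' calls the function returns, per sample, the fraction of complexes that are
#' formable, the fraction of subunit proteins expressed, the gap between the
#' two, and the number of complexes missing formability by exactly one
#' unexpressed subunit (the dominant failure mode in tissue panels).
#'
#' @param resolved a [resolve_complexes()] result (or its `kept` data frame).
#' @param call a [call_detection()] result (transcript or gene level).
#' @param mapping a [mapping_table()].
#' @return An object of class `pfpc_result`: list with
#'   * `level`: detection level used;
#'   * `formable`: logical complexes x samples matrix;
#'   * `expressed`: logical subunit-proteins x samples matrix;
#'   * `unexpressed_counts`: integer complexes x samples matrix (number of
#'     unexpressed subunits);
#'   * `summary`: per-sample data frame (`sample`, `n_pfpc`, `pfpc_fraction`,
#'     `n_expressed_subunits`, `expressed_subunit_fraction`, `gap`,
#'     `n_missing_one`).
#' @export
call_pfpc <- function(resolved, call, mapping) {
  kept <- if (inherits(resolved, "resolved_complexes")) resolved$kept else resolved
  proteins <- sort(unique(unlist(kept$subunits, use.names = FALSE)))
  expressed <- protein_expressed(proteins, call, mapping)
  n_s <- ncol(expressed)

  unexpr <- matrix(0L, nrow(kept), n_s,
                   dimnames = list(kept$complex_id, colnames(expressed)))
  for (i in seq_len(nrow(kept))) {
    su <- kept$subunits[[i]]
    unexpr[i, ] <- as.integer(colSums(!expressed[su, , drop = FALSE]))
  }
  formable <- unexpr == 0L

  n_pfpc <- colSums(formable)
  n_expr <- colSums(expressed)
  summary <- data.frame(
    sample = colnames(expressed),
    n_pfpc = as.integer(n_pfpc),
    pfpc_fraction = n_pfpc / nrow(kept),
    n_expressed_subunits = as.integer(n_expr),
    expressed_subunit_fraction = n_expr / nrow(expressed),
    gap = n_expr / nrow(expressed) - n_pfpc / nrow(kept),
    n_missing_one = as.integer(colSums(unexpr == 1L)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(level = call$level, formable = formable,
                 expressed = expressed, unexpressed_counts = unexpr,
                 summary = summary),
            class = "pfpc_result")
}

#' @export
print.pfpc_result <- function(x, ...) {
  cat(sprintf("pfpc_result (%s level): %d complexes x %d samples, mean PFPC fraction %.3f\n",
              x$level, nrow(x$formable), ncol(x$formable),
              mean(x$summary$pfpc_fraction)))
  invisible(x)
}

#' Cross-sample PFPC summaries
#'
#' Summarizes a PFPC result across samples: per-sample counts, the samples
#' with the most and fewest formable complexes, and the common PFPC set
#' (complexes formable in every sample). When `groups` assigns each sample to
#' one of two groups (for example case/control), the two group PFPC sets —
#' each the intersection over the group's samples — are decomposed into
#' shared and group-specific complexes.
#'
#' @param result a [call_pfpc()] result spanning at least two samples.
#' @param groups optional named character vector (names = sample ids) with
#'   exactly two distinct values.
#' @return A list of class `pfpc_cross` with `per_sample` (named counts),
#'   `common` (character vector), `common_fraction`, `max_sample`,
#'   `min_sample`, and — when `groups` is given — `group_sets` and
#'   `decomposition` (`shared`, `only_<group1>`, `only_<group2>`).
#' @export
pfpc_cross_sample <- function(result, groups = NULL) {
  stopifnot(inherits(result, "pfpc_result"))
  fm <- result$formable
  if (ncol(fm) < 2) .stopf("cross-sample summary needs >= 2 samples")
  counts <- colSums(fm)
  common <- rownames(fm)[rowSums(fm) == ncol(fm)]
  out <- list(per_sample = counts,
              common = common,
              common_fraction = length(common) / nrow(fm),
              max_sample = colnames(fm)[which.max(counts)],
              min_sample = colnames(fm)[which.min(counts)])
  if (!is.null(groups)) {
    groups <- groups[colnames(fm)]
    if (anyNA(groups)) .stopf("groups must cover every sample")
    gl <- unique(groups)
    if (length(gl) != 2) .stopf("groups must have exactly two distinct values")
    sets <- lapply(gl, function(g) {
      cols <- which(groups == g)
      rownames(fm)[rowSums(fm[, cols, drop = FALSE]) == length(cols)]
    })
    names(sets) <- gl
    out$group_sets <- sets
    dec <- list(shared = intersect(sets[[1]], sets[[2]]),
                setdiff(sets[[1]], sets[[2]]),
                setdiff(sets[[2]], sets[[1]]))
    names(dec) <- c("shared", paste0("only_", gl[1]), paste0("only_", gl[2]))
    out$decomposition <- dec
  }
  structure(out, class = "pfpc_cross")
}

#' Write a PFPC 0/1 matrix to TSV
#'
#' Rows are complexes, columns samples, cells 0/1.
#'
#' @param result a [call_pfpc()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pfpc_matrix <- function(result, path) {
  stopifnot(inherits(result, "pfpc_result"))
  df <- data.frame(complex_id = rownames(result$formable),
                   result$formable + 0L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}
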