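#' Propagate differentially expressed transcripts to affected complexes
#'
#' A transcript impacts a complex when some subunit of the complex has that
#' transcript in its associated transcript set; a complex is affected when at
#' least one of its subunits has at least one associated DE transcript. DE
#' transcripts outside the complex universe simply do not propagate. The
#' direction of change is not used for membership.
#'
#' @param de_set character vector of DE transcript ids.
#' @param resolved a [resolve_complexes()] result (or its `kept` data frame).
#' @param mapping a [mapping_table()].
#' @param dataset optional dataset label carried through to overlap reports.
#' @return An object of class `complex_impact`: list with `dataset`,
#'   `de_set` (the input), `de_in_complex` (DE transcripts associated with
#'   >= 1 subunit), `affected` (complex ids), `per_complex` (named list of
#'   impacting transcripts per affected complex) and `universe` (all complex
#'   ids, used to validate overlap comparisons).
#' @export
map_de_to_complexes <- function(de_set, resolved, mapping, dataset = NULL) {
  kept <- if (inherits(resolved, "resolved_complexes")) resolved$kept else resolved
  stopifnot(inherits(mapping, "mapping_table"))
  de_set <- unique(as.character(de_set))

  per_complex <- lapply(kept$resolved_transcripts, function(txs) {
    intersect(de_set, txs)
  })
  names(per_complex) <- kept$complex_id
  hit <- lengths(per_complex) > 0
  structure(list(dataset = dataset,
                 de_set = de_set,
                 de_in_complex = sort(unique(unlist(per_complex[hit],
                                                    use.names = FALSE))),
                 affected = kept$complex_id[hit],
                 per_complex = per_complex[hit],
                 universe = sort(kept$complex_id)),
            class = "complex_impact")
}

#' @export
print.complex_impact <- function(x, ...) {
  cat(sprintf("complex_impact%s: %d DE transcripts, %d in complexes, %d affected complexes\n",
              if (is.null(x$dataset)) "" else paste0(" [", x$dataset, "]"),
              length(x$de_set), length(x$de_in_complex), length(x$affected)))
  invisible(x)
}

#' Pairwise and global overlaps of complex impacts across datasets
#'
#' For each dataset pair, counts the shared complex-associated DE transcripts
#' and the shared affected complexes, plus their ratio (how many times more
#' complexes than transcripts are shared; undefined when the transcript
#' overlap is zero). Because complexes pool many transcripts through shared
#' multi-subunit membership, disjoint DE transcript sets can still hit the
#' same complexes, so the complex overlap is bounded below by the complex
#' image of the transcript overlap. Global intersections across all datasets
#' are returned as well.
#'
#' @param impacts list of >= 2 [map_de_to_complexes()] results over the same
#'   complex universe; names (or their `dataset` fields) label the matrices.
#' @return A list of class `impact_overlap` with `tx_overlap` and
#'   `complex_overlap` (count matrices, diagonals = own set sizes),
#'   `amplification` (complex/transcript overlap ratio, `NA` where
#'   undefined), `combined` (upper triangle complex counts, lower triangle
#'   transcript counts, as overlap figures are conventionally laid out),
#'   `common_tx` and `common_complexes` (global intersections).
#' @export
cross_dataset_overlap <- function(impacts) {
  stopifnot(is.list(impacts), length(impacts) >= 2)
  if (!all(vapply(impacts, inherits, logical(1), "complex_impact"))) {
    .stopf("impacts must be a list of complex_impact objects")
  }
  universes <- lapply(impacts, `[[`, "universe")
  if (!all(vapply(universes, identical, logical(1), universes[[1]]))) {
    .stopf("impacts were computed over different complex universes")
  }
  labels <- names(impacts)
  if (is.null(labels)) {
    labels <- vapply(seq_along(impacts), function(i) {
      d <- impacts[[i]]$dataset
      if (is.null(d)) paste0("dataset", i) else d
    }, character(1))
  }
  k <- length(impacts)
  txm <- matrix(0L, k, k, dimnames = list(labels, labels))
  cxm <- txm
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      txm[i, j] <- length(intersect(impacts[[i]]$de_in_complex,
                                    impacts[[j]]$de_in_complex))
      cxm[i, j] <- length(intersect(impacts[[i]]$affected,
                                    impacts[[j]]$affected))
    }
  }
  amp <- cxm / txm
  amp[txm == 0] <- NA_real_
  diag(amp) <- NA_real_
  combined <- txm
  combined[upper.tri(combined)] <- cxm[upper.tri(cxm)]
  structure(list(tx_overlap = txm,
                 complex_overlap = cxm,
                 amplification = amp,
                 combined = combined,
                 common_tx = Reduce(intersect,
                                    lapply(impacts, `[[`, "de_in_complex")),
                 common_complexes = Reduce(intersect,
                                           lapply(impacts, `[[`, "affected"))),
            class = "impact_overlap")
}

#' @export
print.impact_overlap <- function(x, ...) {
  cat(sprintf("impact_overlap across %d datasets: %d common complexes, %d common transcripts\n",
              nrow(x$tx_overlap), length(x$common_complexes),
              length(x$common_tx)))
  invisible(x)
}

#' Write overlap matrices to TSV
#'
#' Writes the combined matrix (upper triangle = shared affected complexes,
#' lower triangle = shared complex-associated DE transcripts) plus the two
#' clean count matrices next to it (`<stem>_complexes.tsv`,
#' `<stem>_transcripts.tsv`).
#'
#' @param overlap a [cross_dataset_overlap()] result.
#' @param stem output path stem (files get `.tsv` suffixes).
#' @return Character vector of the files written, invisibly.
#' @export
write_overlap_matrices <- function(overlap, stem) {
  stopifnot(inherits(overlap, "impact_overlap"))
  wr <- function(m, path) {
    df <- data.frame(dataset = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .write_tsv(df, path)
  }
  files <- c(paste0(stem, "_combined.tsv"),
             paste0(stem, "_complexes.tsv"),
             paste0(stem, "_transcripts.tsv"))
  wr(overlap$combined, files[1])
  wr(overlap$complex_overlap, files[2])
  wr(overlap$tx_overlap, files[3])
  invisible(files)
}
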