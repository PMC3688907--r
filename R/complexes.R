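#' Build a complex set from a parsed table
#'
#' Takes a data frame describing curated protein complexes (one row per
#' complex, subunits as a single semicolon-separated string of protein
#' accessions) and returns the cleaned analysis set: rows whose subunit field
#' contains the uncertainty marker are dropped, rows with an empty subunit
#' list are rejected, and complexes with identical subunit sets are collapsed
#' to the first occurrence. Survivors keep their input order.
#'
#' Curated complex resources encode ambiguous subunits with parenthesised
#' alternatives (for example `P1;(P2|P3)`); any subunit token matching
#' `uncertainty_pattern` flags the whole complex as uncertain and removes it
#' from the analysis universe.
#'
#' @param df data frame with character columns `complex_id`, `name`,
#'   `subunits` (semicolon-separated accessions).
#' @param uncertainty_pattern regular expression; a subunit token matching it
#'   marks the complex as uncertain. Default matches `(` or `|`.
#' @return An object of class `complex_set`: a list with
#'   * `complexes`: data frame with `complex_id`, `name` and a list column
#'     `subunits` of character vectors;
#'   * `rejects`: data frame `complex_id`, `reason` recording uncertain,
#'     empty and duplicate rows.
#' @seealso [read_complex_table()] to build one from a TSV file.
#' @export
complex_set <- function(df, uncertainty_pattern = "[(|]") {
  stopifnot(is.data.frame(df))
  need <- c("complex_id", "name", "subunits")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    .stopf("complex table is missing required column(s): %s",
           paste(missing, collapse = ", "))
  }
  n <- nrow(df)
  subunits <- lapply(strsplit(as.character(df$subunits), ";", fixed = TRUE),
                     function(tok) {
                       tok <- .trim(tok)
                       unique(tok[nzchar(tok)])
                     })
  reason <- character(n)
  uncertain <- vapply(subunits, function(tok) any(grepl(uncertainty_pattern, tok)),
                      logical(1))
  empty <- lengths(subunits) == 0
  reason[empty] <- "empty subunit list"
  reason[uncertain & !empty] <- "uncertain subunits"

  keep <- !empty & !uncertain
  key <- vapply(subunits, .subunit_key, character(1))
  first_id <- character(0)
  if (any(keep)) {
    kept_keys <- key[keep]
    dup_within <- duplicated(kept_keys)
    first_of_key <- df$complex_id[keep][match(kept_keys, kept_keys)]
    idx_keep <- which(keep)
    reason[idx_keep[dup_within]] <-
      paste0("duplicate of ", first_of_key[dup_within])
    keep[idx_keep[dup_within]] <- FALSE
  }

  complexes <- data.frame(complex_id = as.character(df$complex_id)[keep],
                          name = as.character(df$name)[keep],
                          stringsAsFactors = FALSE)
  complexes$subunits <- subunits[keep]
  rejects <- data.frame(complex_id = as.character(df$complex_id)[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  structure(list(complexes = complexes, rejects = rejects),
            class = "complex_set")
}

#' Read a protein-complex table from a TSV file
#'
#' The file must be tab-separated with header
#' `complex_id<TAB>name<TAB>subunits`; the `subunits` field holds
#' semicolon-separated protein accessions. Lines starting with `#` are
#' comments. Cleaning (uncertainty marker, empty rows, duplicate collapse)
#' is performed by [complex_set()].
#'
#' @inheritParams complex_set
#' @param path path to the TSV file.
#' @return A `complex_set` object.
#' @export
read_complex_table <- function(path, uncertainty_pattern = "[(|]") {
  df <- .read_tsv(path, c("complex_id", "name", "subunits"), "complex table")
  complex_set(df, uncertainty_pattern = uncertainty_pattern)
}

#' Write a complex set back to its TSV serialization
#'
#' @param x a `complex_set`, or the `kept` data frame of
#'   [resolve_complexes()] (anything with `complex_id`, `name` and a
#'   `subunits` list column).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_complex_table <- function(x, path) {
  df <- if (inherits(x, "complex_set")) x$complexes else x
  out <- data.frame(complex_id = df$complex_id,
                    name = df$name,
                    subunits = vapply(df$subunits, paste, character(1),
                                      collapse = ";"),
                    stringsAsFactors = FALSE)
  .write_tsv(out, path)
}

#' Write the rejects report of a complex set
#'
#' @param x a `complex_set`.
#' @param path output TSV (`complex_id<TAB>reason`).
#' @return `path`, invisibly.
#' @export
write_rejects_report <- function(x, path) {
  stopifnot(inherits(x, "complex_set"))
  .write_tsv(x$rejects, path)
}

#' @export
print.complex_set <- function(x, ...) {
  cat(sprintf("complex_set: %d complexes (%d rejected rows)\n",
              nrow(x$complexes), nrow(x$rejects)))
  invisible(x)
}

#' Resolve complexes against an identifier mapping
#'
#' A complex is kept if and only if every subunit has at least one associated
#' transcript (and hence gene) in the mapping; otherwise it is dropped and
#' its first unmapped subunit recorded. Kept complexes gain resolved gene and
#' transcript sets, the unions over their subunits.
#'
#' @param x a `complex_set` (or its `complexes` data frame).
#' @param mapping a [mapping_table()].
#' @return A list of class `resolved_complexes` with
#'   * `kept`: data frame `complex_id`, `name`, list columns `subunits`,
#'     `resolved_genes`, `resolved_transcripts`;
#'   * `dropped`: data frame `complex_id`, `unmapped_subunit`.
#' @export
resolve_complexes <- function(x, mapping) {
  df <- if (inherits(x, "complex_set")) x$complexes else x
  stopifnot(inherits(mapping, "mapping_table"))
  mappable <- names(mapping$protein2tx)

  first_unmapped <- vapply(df$subunits, function(su) {
    bad <- su[!(su %in% mappable)]
    if (length(bad) == 0) NA_character_ else bad[[1]]
  }, character(1))
  keep <- is.na(first_unmapped)

  kept <- df[keep, c("complex_id", "name"), drop = FALSE]
  kept$subunits <- df$subunits[keep]
  kept$resolved_transcripts <- lapply(df$subunits[keep], function(su) {
    sort(unique(unlist(mapping$protein2tx[su], use.names = FALSE)))
  })
  kept$resolved_genes <- lapply(df$subunits[keep], function(su) {
    sort(unique(unlist(mapping$protein2gene[su], use.names = FALSE)))
  })
  rownames(kept) <- NULL
  dropped <- data.frame(complex_id = df$complex_id[!keep],
                        unmapped_subunit = first_unmapped[!keep],
                        stringsAsFactors = FALSE)
  structure(list(kept = kept, dropped = dropped),
            class = "resolved_complexes")
}

#' @export
print.resolved_complexes <- function(x, ...) {
  cat(sprintf("resolved_complexes: %d kept, %d dropped\n",
              nrow(x$kept), nrow(x$dropped)))
  invisible(x)
}

#' Summary statistics of a resolved complex universe
#'
#' Computes the descriptive statistics used to characterize a complex
#' universe: per-protein transcript/gene/complex counts, the mean number of
#' transcripts and genes per subunit, the fraction of subunits with two or
#' more transcripts, the fraction of proteins shared across two or more
#' complexes (with the maximally shared protein), and the complex-size and
#' transcripts-per-subunit histograms.
#'
#' @param resolved a `resolved_complexes` object (or its `kept` data frame).
#' @param mapping the [mapping_table()] used for resolution.
#' @return A list of class `complex_stats` with elements `protein_table`
#'   (one row per distinct subunit protein), scalar summaries, and the two
#'   histograms (`size_hist`, `tx_per_subunit_hist`) as named integer vectors.
#' @export
complex_stats <- function(resolved, mapping) {
  kept <- if (inherits(resolved, "resolved_complexes")) resolved$kept else resolved
  stopifnot(inherits(mapping, "mapping_table"))

  if (nrow(kept) == 0) {
    warning("no resolved complexes: returning empty summary")
    empty <- data.frame(protein = character(0), n_transcripts = integer(0),
                        n_genes = integer(0), n_complexes = integer(0),
                        stringsAsFactors = FALSE)
    return(structure(list(protein_table = empty,
                          n_complexes = 0L, n_proteins = 0L,
                          n_genes = 0L, n_transcripts = 0L,
                          mean_tx_per_subunit = NA_real_,
                          mean_genes_per_subunit = NA_real_,
                          frac_subunits_multi_tx = NA_real_,
                          sharing_fraction = NA_real_,
                          max_complexes_per_protein = 0L,
                          most_shared_protein = NA_character_,
                          size_hist = integer(0),
                          tx_per_subunit_hist = integer(0)),
                     class = "complex_stats"))
  }

  membership <- data.frame(
    protein = unlist(kept$subunits, use.names = FALSE),
    complex_id = rep(kept$complex_id, lengths(kept$subunits)),
    stringsAsFactors = FALSE)
  proteins <- sort(unique(membership$protein))
  n_cplx <- as.integer(table(factor(membership$protein, levels = proteins)))
  n_tx <- vapply(mapping$protein2tx[proteins], length, integer(1))
  n_genes <- vapply(mapping$protein2gene[proteins], length, integer(1))
  protein_table <- data.frame(protein = proteins,
                              n_transcripts = n_tx,
                              n_genes = n_genes,
                              n_complexes = n_cplx,
                              stringsAsFactors = FALSE)
  rownames(protein_table) <- NULL

  sizes <- lengths(kept$subunits)
  all_tx <- unique(unlist(kept$resolved_transcripts, use.names = FALSE))
  all_genes <- unique(unlist(kept$resolved_genes, use.names = FALSE))
  imax <- which.max(n_cplx)

  structure(list(
    protein_table = protein_table,
    n_complexes = nrow(kept),
    n_proteins = length(proteins),
    n_genes = length(all_genes),
    n_transcripts = length(all_tx),
    mean_tx_per_subunit = mean(n_tx),
    mean_genes_per_subunit = mean(n_genes),
    frac_subunits_multi_tx = mean(n_tx >= 2),
    sharing_fraction = mean(n_cplx >= 2),
    max_complexes_per_protein = max(n_cplx),
    most_shared_protein = proteins[imax],
    size_hist = table(sizes),
    tx_per_subunit_hist = table(n_tx)
  ), class = "complex_stats")
}

#' @export
print.complex_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "complex_stats: %d complexes, %d proteins, %d genes, %d transcripts\n",
    "  transcripts/subunit %.2f (%.1f%% with >=2), genes/subunit %.2f\n",
    "  %.1f%% of proteins shared across >=2 complexes (max %d, %s)\n"),
    x$n_complexes, x$n_proteins, x$n_genes, x$n_transcripts,
    x$mean_tx_per_subunit, 100 * x$frac_subunits_multi_tx,
    x$mean_genes_per_subunit,
    100 * x$sharing_fraction, x$max_complexes_per_protein,
    x$most_shared_protein))
  invisible(x)
}
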