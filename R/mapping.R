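#' Build a protein/transcript/gene identifier mapping
#'
#' The mapping is many-to-many between proteins and transcripts (a protein can
#' be encoded by several distinct transcripts, and occasionally by transcripts
#' of different genes) and many-to-one between transcripts and genes. Rows
#' whose `protein_id` is empty or `"-"` carry a transcript–gene association
#' only; such rows are how transcripts that encode no complex protein (for
#' example non-coding isoforms of a subunit gene) enter the transcript→gene
#' map used for gene roll-up and major-isoform assignment.
#'
#' @param df data frame with character columns `protein_id`, `transcript_id`,
#'   `gene_id`, one association per row.
#' @return An object of class `mapping_table`: a list with
#'   * `protein2tx`: named list, protein accession → character vector of
#'     transcript ids;
#'   * `protein2gene`: named list, protein accession → character vector of
#'     gene ids (the image of its transcripts under the transcript→gene map);
#'   * `tx2gene`: named character vector, transcript id → gene id;
#'   * `table`: the input associations.
#' @export
mapping_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("protein_id", "transcript_id", "gene_id")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    .stopf("mapping table is missing required column(s): %s",
           paste(missing, collapse = ", "))
  }
  df <- data.frame(protein_id = .trim(as.character(df$protein_id)),
                   transcript_id = .trim(as.character(df$transcript_id)),
                   gene_id = .trim(as.character(df$gene_id)),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$transcript_id) | !nzchar(df$transcript_id) |
                 is.na(df$gene_id) | !nzchar(df$gene_id))
  if (length(bad) > 0) {
    .stopf("mapping table: missing transcript_id/gene_id in row(s) %s",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  df$protein_id[is.na(df$protein_id) | df$protein_id == "-"] <- ""

  tx_first <- !duplicated(df$transcript_id)
  tx2gene <- stats::setNames(df$gene_id[tx_first], df$transcript_id[tx_first])
  conflict <- df$gene_id != tx2gene[df$transcript_id]
  if (any(conflict)) {
    .stopf("mapping table: transcript(s) mapped to more than one gene: %s",
           paste(utils::head(unique(df$transcript_id[conflict]), 5),
                 collapse = ", "))
  }

  assoc <- df[nzchar(df$protein_id), , drop = FALSE]
  protein2tx <- lapply(split(assoc$transcript_id, assoc$protein_id), unique)
  protein2gene <- lapply(split(assoc$gene_id, assoc$protein_id),
                         function(g) unique(g))
  structure(list(protein2tx = protein2tx,
                 protein2gene = protein2gene,
                 tx2gene = tx2gene,
                 table = df),
            class = "mapping_table")
}

#' Read an identifier-mapping table from a TSV file
#'
#' Expects header `protein_id<TAB>transcript_id<TAB>gene_id`, one association
#' per row; `#`-prefixed comment lines are skipped. Rows with a missing
#' transcript or gene id raise an error naming the offending row.
#'
#' @param path path to the TSV file.
#' @return A [mapping_table()].
#' @export
read_mapping_table <- function(path) {
  df <- .read_tsv(path, c("protein_id", "transcript_id", "gene_id"),
                  "mapping table")
  mapping_table(df)
}

#' Write a mapping table to TSV
#'
#' @param mapping a [mapping_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mapping_table <- function(mapping, path) {
  stopifnot(inherits(mapping, "mapping_table"))
  .write_tsv(mapping$table, path)
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("mapping_table: %d proteins, %d transcripts, %d genes\n",
              length(x$protein2tx), length(x$tx2gene),
              length(unique(x$tx2gene))))
  invisible(x)
}
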