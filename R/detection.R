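#' Call detected features by the posterior-SD filter
#'
#' A feature is detected in a sample when its estimate is present in that
#' sample's file and its posterior standard deviation does not exceed
#' `sd_max`. The boundary is inclusive: an SD of exactly `sd_max` is kept;
#' only SDs strictly greater are excluded (a posterior SD above 1.5 is the
#' conventional mark of a feature with no uniquely mapping reads). The
#' expression estimate itself is not thresholded unless an optional floor is
#' supplied.
#'
#' @param expr an [expr_set()].
#' @param sd_max maximum posterior SD for a detected call; default 1.5.
#' @param min_estimate optional minimum log-expression estimate (default
#'   `NULL`, off).
#' @return An object of class `detection_call`: list with `level`,
#'   `detected` (logical features x samples matrix) and `missing` (logical
#'   matrix marking cells absent from the input files, so that "not measured"
#'   stays distinguishable from "measured but SD-filtered").
#' @export
call_detection <- function(expr, sd_max = 1.5, min_estimate = NULL) {
  stopifnot(inherits(expr, "expr_set"))
  if (!is.numeric(sd_max) || length(sd_max) != 1 || sd_max <= 0) {
    .stopf("sd_max must be a single positive number")
  }
  missing <- is.na(expr$sd)
  detected <- !missing & expr$sd <= sd_max
  if (!is.null(min_estimate)) {
    detected <- detected & !is.na(expr$estimate) & expr$estimate >= min_estimate
  }
  detected[is.na(detected)] <- FALSE
  structure(list(level = expr$level, detected = detected, missing = missing),
            class = "detection_call")
}

#' Roll transcript-level detection up to gene level
#'
#' A gene is detected in a sample when at least one of its transcripts is
#' detected there. Compared with loading a native gene-level matrix, the
#' roll-up makes the gene-level calls a deterministic function of the
#' transcript-level calls, so transcript-level results are contained in
#' gene-level results by construction.
#'
#' @param call a transcript-level `detection_call`.
#' @param mapping a [mapping_table()] or a named character vector
#'   transcript id → gene id covering every called feature.
#' @return A gene-level `detection_call` (its `missing` matrix marks genes
#'   whose every transcript cell was missing).
#' @export
rollup_gene_detection <- function(call, mapping) {
  stopifnot(inherits(call, "detection_call"))
  if (call$level != "transcript") .stopf("roll-up needs a transcript-level call")
  tx2gene <- if (inherits(mapping, "mapping_table")) mapping$tx2gene else mapping
  feats <- rownames(call$detected)
  genes_of <- tx2gene[feats]
  offenders <- feats[is.na(genes_of)]
  if (length(offenders) > 0) {
    .stopf("transcript(s) without a gene mapping: %s%s",
           paste(utils::head(offenders, 5), collapse = ", "),
           if (length(offenders) > 5) sprintf(" (and %d more)",
                                              length(offenders) - 5) else "")
  }
  genes <- unique(genes_of)
  gf <- factor(genes_of, levels = genes)
  detected <- rowsum(call$detected + 0L, gf) > 0
  missing <- rowsum(call$missing + 0L, gf) == as.integer(table(gf))
  colnames(detected) <- colnames(call$detected)
  colnames(missing) <- colnames(call$detected)
  structure(list(level = "gene", detected = detected, missing = missing),
            class = "detection_call")
}

#' @export
print.detection_call <- function(x, ...) {
  cat(sprintf("detection_call (%s level): %d x %d, %.1f%% detected\n",
              x$level, nrow(x$detected), ncol(x$detected),
              100 * mean(x$detected)))
  invisible(x)
}
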