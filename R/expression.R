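#' Construct an expression set from estimate and SD matrices
#'
#' Container for feature-by-sample log-scale expression estimates with a
#' per-cell posterior standard deviation, as produced by Bayesian isoform
#' quantification pipelines (one table per sample: feature id, log-expression
#' estimate, posterior SD). Cells may be `NA` when a feature was absent from a
#' sample's file; such cells are treated as "not detected" downstream, kept
#' distinct from SD-filtered cells.
#'
#' @param estimate numeric matrix (features x samples) of log-scale estimates,
#'   with rownames (feature ids) and colnames (sample ids).
#' @param sd numeric matrix of posterior standard deviations, same shape and
#'   dimnames; non-missing values must be >= 0.
#' @param level `"transcript"` or `"gene"`.
#' @return An object of class `expr_set`: list with `level`, `estimate`, `sd`.
#' @export
expr_set <- function(estimate, sd, level = c("transcript", "gene")) {
  level <- match.arg(level)
  stopifnot(is.matrix(estimate), is.matrix(sd))
  if (!identical(dim(estimate), dim(sd))) {
    .stopf("estimate and sd matrices have different shapes")
  }
  if (is.null(rownames(estimate)) || is.null(colnames(estimate))) {
    .stopf("expression matrices need feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(estimate)) || anyDuplicated(colnames(estimate))) {
    .stopf("duplicate feature or sample ids in expression matrix")
  }
  if (any(sd < 0, na.rm = TRUE)) .stopf("posterior SDs must be >= 0")
  dimnames(sd) <- dimnames(estimate)
  structure(list(level = level, estimate = estimate, sd = sd),
            class = "expr_set")
}

#' Read per-sample expression tables into an expression set
#'
#' Each file is a TSV with columns `feature_id`, `estimate`, `sd`
#' (`#`-comments allowed), one file per sample. The feature universe is the
#' union across samples in order of first appearance; a feature absent from a
#' sample's file gets `NA` cells there (not detected downstream). Column
#' order follows the order of `paths`.
#'
#' @param paths character vector of file paths, one per sample.
#' @param level `"transcript"` or `"gene"`.
#' @param sample_ids sample names; defaults to file base names without
#'   extension. Must be unique.
#' @return An [expr_set()].
#' @export
read_expression_set <- function(paths, level = c("transcript", "gene"),
                                sample_ids = NULL) {
  level <- match.arg(level)
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  if (anyDuplicated(sample_ids)) .stopf("duplicate sample ids")
  stopifnot(length(sample_ids) == length(paths))

  tabs <- lapply(paths, function(p) {
    df <- .read_tsv(p, c("feature_id", "estimate", "sd"), "expression table")
    if (anyDuplicated(df$feature_id)) {
      .stopf("duplicate feature id(s) in '%s': %s", p,
             paste(utils::head(unique(df$feature_id[duplicated(df$feature_id)]), 3),
                   collapse = ", "))
    }
    df$estimate <- as.numeric(df$estimate)
    df$sd <- as.numeric(df$sd)
    df
  })
  features <- unique(unlist(lapply(tabs, `[[`, "feature_id"), use.names = FALSE))
  est <- matrix(NA_real_, length(features), length(paths),
                dimnames = list(features, sample_ids))
  sdm <- est
  for (j in seq_along(tabs)) {
    idx <- match(tabs[[j]]$feature_id, features)
    est[idx, j] <- tabs[[j]]$estimate
    sdm[idx, j] <- tabs[[j]]$sd
  }
  expr_set(est, sdm, level = level)
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set (%s level): %d features x %d samples, %d missing cells\n",
              x$level, nrow(x$estimate), ncol(x$estimate),
              sum(is.na(x$sd))))
  invisible(x)
}
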