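#' Normalize count columns by their median deviation from the mean
#'
#' Per sample, the offset is the median log-abundance over that sample's
#' expressed (non-zero) transcripts minus the mean of those medians across
#' samples; each sample's abundances are rescaled so its log-abundances shift
#' by minus that offset. After normalization the per-sample medians of the
#' log non-zero abundances are all equal and the offsets sum to zero, which
#' removes library-depth differences without touching relative abundances
#' within a sample. A single-sample matrix is returned unchanged.
#'
#' @param counts non-negative numeric matrix, transcripts x samples, with
#'   dimnames.
#' @return The normalized matrix, with the per-sample offsets (natural-log
#'   scale) in attribute `"offsets"`.
#' @export
normalize_median_deviation <- function(counts) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (any(counts < 0)) .stopf("abundances must be >= 0")
  meds <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    x <- x[x > 0]
    if (length(x) == 0) .stopf("sample '%s' has no nonzero abundances",
                               colnames(counts)[j])
    stats::median(log(x))
  }, numeric(1))
  offsets <- meds - mean(meds)
  out <- sweep(counts, 2, exp(-offsets), `*`)
  attr(out, "offsets") <- stats::setNames(offsets, colnames(counts))
  out
}

#' Nonparametric (M, D) differential-expression probability
#'
#' For each transcript the signal is the pair `M = log2(mean_case /
#' mean_control)` and `D = |mean_case - mean_control|` of (normalized) group
#' mean abundances; zeros are replaced by a small pseudo-count first. The
#' noise distribution is the pool of `(M*, D*)` pairs from all within-group
#' sample-pair comparisons across both groups (replicate mode). The
#' probability of differential expression is
#' `q = mean(|M*| < |M| & D* < D)` — the fraction of noise pairs strictly
#' dominated by the signal (boundary ties do not count).
#'
#' When a group has a single sample (no biological replicates), technical
#' replicates are simulated instead: each observed sample is resampled
#' `n_sim` times from a multinomial at its observed total depth, and noise
#' pairs are taken among resamples of the same original sample. Because
#' technical noise understates biological noise, a stricter probability
#' cutoff is conventionally used downstream in this mode (see [de_call()]).
#'
#' @param counts non-negative matrix, transcripts x samples, with dimnames;
#'   normalize with [normalize_median_deviation()] first.
#' @param groups character vector (length = samples, or named by sample)
#'   with exactly two distinct values.
#' @param case which group value is the numerator of M; defaults to
#'   `"case"` when present, else the first distinct value.
#' @param pseudo_count replacement for zero abundances before logs
#'   (default 0.5).
#' @param simulate_replicates `NULL` (auto: simulate iff some group has one
#'   sample), `TRUE` or `FALSE`. With `FALSE` and a singleton group, an error
#'   explains the replicate requirement.
#' @param n_sim simulated technical replicates per sample (default 5).
#' @return Data frame of class `de_result` with columns `transcript`, `M`,
#'   `D`, `q`; the pooled noise pairs are kept in attribute `"noise"` (a list
#'   with numeric vectors `M` and `D`).
#' @export
noiseq_probability <- function(counts, groups, case = NULL,
                               pseudo_count = 0.5,
                               simulate_replicates = NULL, n_sim = 5) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (any(counts < 0)) .stopf("abundances must be >= 0")
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  groups <- as.character(groups)
  if (length(groups) != ncol(counts) || anyNA(groups)) {
    .stopf("groups must label every sample column")
  }
  lev <- unique(groups)
  if (length(lev) != 2) .stopf("exactly two groups are required")
  if (is.null(case)) case <- if ("case" %in% lev) "case" else lev[1]
  if (!case %in% lev) .stopf("case level '%s' not found in groups", case)
  ctrl <- setdiff(lev, case)

  # canonical column order: q is then exactly invariant to how the caller
  # happened to order the samples (tie comparisons are knife-edge otherwise)
  ord <- order(colnames(counts))
  counts <- counts[, ord, drop = FALSE]
  groups <- groups[ord]

  sizes <- table(groups)
  if (is.null(simulate_replicates)) simulate_replicates <- any(sizes < 2)
  if (!simulate_replicates && any(sizes < 2)) {
    .stopf(paste("a group has a single sample: within-group noise pairs need",
                 "replicates; enable simulate_replicates to resample",
                 "technical replicates instead"))
  }

  x <- counts
  x[x == 0] <- pseudo_count

  mu_case <- rowMeans(x[, groups == case, drop = FALSE])
  mu_ctrl <- rowMeans(x[, groups == ctrl, drop = FALSE])
  # difference-of-logs form: exactly antisymmetric under a label swap
  M <- log2(mu_case) - log2(mu_ctrl)
  D <- abs(mu_case - mu_ctrl)

  noise_cols <- function(mat) {
    # all unordered column pairs of mat -> list(M*, D*) pooled over transcripts
    k <- ncol(mat)
    if (k < 2) return(list(M = numeric(0), D = numeric(0)))
    pairs <- utils::combn(k, 2)
    Ms <- vector("list", ncol(pairs))
    Ds <- vector("list", ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      a <- mat[, pairs[1, p]]
      b <- mat[, pairs[2, p]]
      Ms[[p]] <- log2(a) - log2(b)
      Ds[[p]] <- abs(a - b)
    }
    list(M = unlist(Ms, use.names = FALSE), D = unlist(Ds, use.names = FALSE))
  }

  if (simulate_replicates) {
    noise_M <- list(); noise_D <- list()
    for (j in seq_len(ncol(counts))) {
      tot <- sum(counts[, j])
      prob <- counts[, j] / tot
      sims <- stats::rmultinom(n_sim, size = round(tot), prob = prob)
      sims[sims == 0] <- pseudo_count
      np <- noise_cols(sims)
      noise_M[[j]] <- np$M
      noise_D[[j]] <- np$D
    }
    noise <- list(M = unlist(noise_M, use.names = FALSE),
                  D = unlist(noise_D, use.names = FALSE))
  } else {
    np1 <- noise_cols(x[, groups == case, drop = FALSE])
    np2 <- noise_cols(x[, groups == ctrl, drop = FALSE])
    noise <- list(M = c(np1$M, np2$M), D = c(np1$D, np2$D))
  }

  q <- .dominance_fraction(abs(M), D, abs(noise$M), noise$D)
  out <- data.frame(transcript = rownames(counts), M = M, D = D, q = q,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "noise") <- noise
  class(out) <- c("de_result", "data.frame")
  out
}

# Fraction of noise pairs strictly dominated by each signal:
# q_i = mean(noise_absM < absM_i & noise_D < D_i). Chunked to bound memory.
.dominance_fraction <- function(absM, D, noise_absM, noise_D,
                                chunk = 256L) {
  n_noise <- length(noise_absM)
  q <- numeric(length(absM))
  if (n_noise == 0) return(q)
  idx <- seq_along(absM)
  for (start in seq(1L, length(idx), by = chunk)) {
    sel <- idx[start:min(start + chunk - 1L, length(idx))]
    dom <- outer(absM[sel], noise_absM, `>`) & outer(D[sel], noise_D, `>`)
    q[sel] <- rowSums(dom) / n_noise
  }
  q
}

#' Threshold a DE result into the differentially expressed set
#'
#' Returns the transcripts with `q` strictly above the cutoff. Conventional
#' per-dataset cutoffs are supplied for the four cancer datasets this kind of
#' analysis is typically run on — breast 0.9, colon 0.9, lung 0.99 (no
#' biological replicates, hence stricter) and prostate 0.8; for any other
#' dataset name `q_min` must be given explicitly.
#'
#' @param result a [noiseq_probability()] result.
#' @param q_min probability cutoff in (0, 1).
#' @param dataset optional dataset name used to look up a default cutoff
#'   when `q_min` is missing.
#' @return Character vector of transcript ids.
#' @export
de_call <- function(result, q_min = NULL, dataset = NULL) {
  defaults <- c(breast = 0.9, colon = 0.9, lung = 0.99, prostate = 0.8)
  if (is.null(q_min)) {
    if (is.null(dataset) || !(tolower(dataset) %in% names(defaults))) {
      .stopf("q_min required (no default cutoff for dataset '%s')",
             if (is.null(dataset)) "" else dataset)
    }
    q_min <- defaults[[tolower(dataset)]]
  }
  if (!is.numeric(q_min) || length(q_min) != 1 || q_min <= 0 || q_min >= 1) {
    .stopf("q_min must be a single number in (0, 1)")
  }
  result$transcript[result$q > q_min]
}

#' Write a DE result table to TSV
#'
#' Columns `transcript`, `M`, `D`, `q`, `de_flag` (0/1 at `q_min`).
#'
#' @inheritParams de_call
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(result, path, q_min = NULL, dataset = NULL) {
  de <- de_call(result, q_min = q_min, dataset = dataset)
  df <- as.data.frame(result)
  df$de_flag <- as.integer(df$transcript %in% de)
  .write_tsv(df, path)
}
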