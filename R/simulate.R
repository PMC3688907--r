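#' Configuration for the synthetic complex-expression generator
#'
#' Builds a validated configuration for [simulate_universe()],
#' [simulate_expression()] and [simulate_de_counts()]. Defaults emulate the
#' statistical structure of curated human complex catalogues profiled across
#' a 16-tissue RNA-seq panel: complex sizes concentrated on 2–4 subunits,
#' about 2.26 transcripts per subunit (geometric-like), roughly half of the
#' subunit proteins shared across two or more complexes, occasional
#' same-gene subunit pairs and multi-gene proteins, strongly co-detected
#' complex members, a ~78% dominant-isoform involvement rate, ~11% pairwise
#' major-isoform switching, and negative-binomial case/control count
#' matrices with planted fold changes for the differential-expression path.
#'
#' @param seed integer RNG seed; the same configuration (seed included)
#'   yields byte-identical output files.
#' @param n_samples number of tissue samples (default 16).
#' @param n_complexes number of complexes (default 500).
#' @param complex_size_probs named numeric vector of size probabilities
#'   (names = subunit counts).
#' @param sharing target fraction of subunit proteins appearing in >= 2
#'   complexes (default 0.49); realized exactly up to rounding by
#'   construction.
#' @param share_multiplicity mean number of extra complex memberships per
#'   shared protein (default 1.3; > 1 gives a heavy tail with a maximally
#'   shared protein).
#' @param tx_per_subunit_mean mean transcripts per protein–gene link,
#'   geometric-like (default 2.26).
#' @param p_multi_gene probability a protein is encoded by a second gene
#'   (default 0.01).
#' @param p_shared_gene probability a protein reuses another protein's gene
#'   with a disjoint transcript subset (default 0.005).
#' @param p_gene_extra_tx probability a gene carries isoforms that encode no
#'   complex subunit (default 0.5).
#' @param extra_tx_mean mean count of such extra isoforms when present
#'   (default 1.7).
#' @param absent_rate per-(subunit, sample) probability the subunit is silent
#'   (all its transcripts undetected) (default 0.06, so ~84% of size-3
#'   complexes are formable per sample).
#' @param tx_detect detection probability of each member transcript of an
#'   expressed subunit beyond the first, which is always detected
#'   (default 0.94, the co-expression strength).
#' @param extra_detect detection probability of non-subunit isoforms
#'   (default 0.8).
#' @param involvement_rate probability the planted dominant isoform of a gene
#'   encodes the subunit rather than an extra isoform, when both are
#'   available (default 0.78).
#' @param switch_rate planted fraction of eligible components whose gene's
#'   major isoform differs between sample 1 and each other sample
#'   (default 0.11).
#' @param dominant_margin log-expression margin of the dominant isoform above
#'   its gene's other detected isoforms; must be > 0 (default 1).
#' @param est_noise SD of Gaussian noise on log-expression estimates
#'   (default 0.3).
#' @param sd_detected range of posterior SDs for detected cells
#'   (default c(0.05, 1.45)).
#' @param boundary_frac fraction of detected cells given a posterior SD of
#'   exactly 1.5, exercising the inclusive filter boundary (default 0.02).
#' @param sd_undetected range of posterior SDs for undetected cells, all
#'   above 1.5 (default c(1.6, 3.5)).
#' @param missing_rate probability an undetected cell is omitted from the
#'   sample's file entirely (default 0.02).
#' @param de list of case/control count settings: `n_tx` (total transcripts,
#'   default 2000, padded with background transcripts beyond the complex
#'   universe), `n_case`/`n_control` (default 5/5), `de_fraction`
#'   (default 0.05), `fold` (default 4), `dispersion` (negative-binomial,
#'   default 0.05), `mean_log_mu`/`sd_log_mu` (log-normal abundance,
#'   defaults log(50)/1.2), `depth_factor_sd` (default 0.1).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_samples = 16L,
                         n_complexes = 500L,
                         complex_size_probs = c("1" = 0.04, "2" = 0.38,
                                                "3" = 0.22, "4" = 0.14,
                                                "5" = 0.08, "6" = 0.05,
                                                "7" = 0.04, "8" = 0.03,
                                                "9" = 0.01, "10" = 0.01),
                         sharing = 0.49,
                         share_multiplicity = 1.3,
                         tx_per_subunit_mean = 2.26,
                         p_multi_gene = 0.01,
                         p_shared_gene = 0.005,
                         p_gene_extra_tx = 0.5,
                         extra_tx_mean = 1.7,
                         absent_rate = 0.06,
                         tx_detect = 0.94,
                         extra_detect = 0.8,
                         involvement_rate = 0.78,
                         switch_rate = 0.11,
                         dominant_margin = 1,
                         est_noise = 0.3,
                         sd_detected = c(0.05, 1.45),
                         boundary_frac = 0.02,
                         sd_undetected = c(1.6, 3.5),
                         missing_rate = 0.02,
                         de = list()) {
  de_defaults <- list(n_tx = 2000L, n_case = 5L, n_control = 5L,
                      de_fraction = 0.05, fold = 4, dispersion = 0.05,
                      mean_log_mu = log(100), sd_log_mu = 0.6,
                      depth_factor_sd = 0.1)
  de <- utils::modifyList(de_defaults, de)

  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_complexes = as.integer(n_complexes),
              complex_size_probs = complex_size_probs,
              sharing = sharing, share_multiplicity = share_multiplicity,
              tx_per_subunit_mean = tx_per_subunit_mean,
              p_multi_gene = p_multi_gene, p_shared_gene = p_shared_gene,
              p_gene_extra_tx = p_gene_extra_tx, extra_tx_mean = extra_tx_mean,
              absent_rate = absent_rate, tx_detect = tx_detect,
              extra_detect = extra_detect,
              involvement_rate = involvement_rate, switch_rate = switch_rate,
              dominant_margin = dominant_margin, est_noise = est_noise,
              sd_detected = sd_detected, boundary_frac = boundary_frac,
              sd_undetected = sd_undetected, missing_rate = missing_rate,
              de = de)

  rates <- c(sharing = sharing, p_multi_gene = p_multi_gene,
             p_shared_gene = p_shared_gene, p_gene_extra_tx = p_gene_extra_tx,
             absent_rate = absent_rate, tx_detect = tx_detect,
             extra_detect = extra_detect, involvement_rate = involvement_rate,
             switch_rate = switch_rate, boundary_frac = boundary_frac,
             missing_rate = missing_rate, de_fraction = de$de_fraction)
  bad <- rates < 0 | rates > 1
  if (any(bad)) .stopf("rate(s) outside [0, 1]: %s",
                       paste(names(rates)[bad], collapse = ", "))
  if (abs(sum(complex_size_probs) - 1) > 1e-8 || any(complex_size_probs < 0)) {
    .stopf("complex_size_probs must be a probability distribution")
  }
  if (dominant_margin <= 0) .stopf("dominant_margin must be > 0")
  if (tx_per_subunit_mean < 1) .stopf("tx_per_subunit_mean must be >= 1")
  if (share_multiplicity < 1) .stopf("share_multiplicity must be >= 1")
  if (sharing > 0 && n_complexes < 2) {
    .stopf("a shared protein needs >= 2 complexes: sharing %.2f is infeasible with %d complex(es)",
           sharing, n_complexes)
  }
  if (de$n_case < 1 || de$n_control < 1) .stopf("each DE group needs >= 1 sample")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic complex/mapping universe with ground truth
#'
#' Draws complex sizes from the configured distribution, then constructs
#' subunit sharing exactly: `round(sharing * n_proteins)` proteins receive
#' one or more extra complex memberships (mean `share_multiplicity`), so the
#' realized sharing fraction equals the target up to rounding. Each protein
#' is linked to one gene (occasionally two, or a gene shared with another
#' protein via a disjoint transcript subset) and a geometric-like number of
#' coding transcripts; genes may carry additional isoforms that encode no
#' subunit.
#'
#' @param config a [synth_config()].
#' @return An object of class `synth_universe`: list with `complexes` (a
#'   [complex_set()]), `mapping` (a [mapping_table()]), `truth` (realized
#'   sharing fraction, shared proteins, membership table, per-protein
#'   transcript counts) and `config`.
#' @export
simulate_universe <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  C <- config$n_complexes

  if (C == 0) {
    complexes <- complex_set(data.frame(complex_id = character(0),
                                        name = character(0),
                                        subunits = character(0),
                                        stringsAsFactors = FALSE))
    mapping <- mapping_table(data.frame(protein_id = character(0),
                                        transcript_id = character(0),
                                        gene_id = character(0),
                                        stringsAsFactors = FALSE))
    truth <- list(sharing_fraction = NA_real_, shared_proteins = character(0),
                  membership = data.frame(protein = character(0),
                                          complex_id = character(0)),
                  mean_tx_per_subunit = NA_real_)
    return(structure(list(complexes = complexes, mapping = mapping,
                          truth = truth, config = config),
                     class = "synth_universe"))
  }

  size_vals <- as.integer(names(config$complex_size_probs))
  sizes <- sample(size_vals, C, replace = TRUE, prob = config$complex_size_probs)
  S <- sum(sizes)

  # exact-sharing construction: P proteins, E = S - P extra memberships
  # distributed over n_sh = round(sharing * P) shared proteins
  f <- config$sharing
  m <- config$share_multiplicity
  P <- max(1L, as.integer(round(S / (1 + f * m))))
  E <- S - P
  if (E > S - C) {        # every complex keeps at least one "home" slot
    E <- S - C
    P <- S - E
  }
  n_sh <- min(as.integer(round(f * P)), E)
  if (f > 0 && E > 0 && n_sh == 0) n_sh <- 1L

  complex_ids <- sprintf("CPX%04d", seq_len(C))
  protein_ids <- sprintf("P%05d", seq_len(P))
  complex_of_slot <- rep(seq_len(C), sizes)
  non_home <- which(duplicated(complex_of_slot))
  reuse_slots <- if (E > 0) sort(sample(non_home, E)) else integer(0)
  home_slots <- setdiff(seq_len(S), reuse_slots)

  protein_of_slot <- integer(S)
  protein_of_slot[home_slots] <- seq_len(P)

  members <- split(protein_of_slot[home_slots], complex_of_slot[home_slots])
  members <- lapply(seq_len(C), function(c) {
    v <- members[[as.character(c)]]
    if (is.null(v)) integer(0) else v
  })

  if (n_sh > 0) {
    shared_idx <- sort(sample.int(P, n_sh))
    counts <- rep(1L, n_sh)
    if (E > n_sh) {
      extra <- sample.int(n_sh, E - n_sh, replace = TRUE)
      counts <- counts + tabulate(extra, nbins = n_sh)
    }
    occ <- sample(rep(shared_idx, counts))
    for (k in seq_along(reuse_slots)) {
      cx <- complex_of_slot[reuse_slots[k]]
      if (occ[k] %in% members[[cx]]) {
        later <- which(seq_along(occ) > k & !(occ %in% members[[cx]]))
        swapped <- FALSE
        for (j in later) {
          cj <- complex_of_slot[reuse_slots[j]]
          if (!(occ[k] %in% members[[cj]])) {
            tmp <- occ[k]; occ[k] <- occ[j]; occ[j] <- tmp
            swapped <- TRUE
            break
          }
        }
        if (!swapped) {
          cand <- setdiff(shared_idx, members[[cx]])
          if (length(cand) == 0) cand <- setdiff(seq_len(P), members[[cx]])
          occ[k] <- cand[sample.int(length(cand), 1)]
        }
      }
      protein_of_slot[reuse_slots[k]] <- occ[k]
      members[[cx]] <- c(members[[cx]], occ[k])
    }
  }

  membership <- data.frame(
    protein = protein_ids[protein_of_slot],
    complex_id = complex_ids[complex_of_slot],
    stringsAsFactors = FALSE)

  # gene and transcript layer
  gene_of_protein <- character(P)
  extra_gene <- rep(NA_character_, P)     # second gene of multi-gene proteins
  gene_counter <- 0L
  new_gene <- function() {
    gene_counter <<- gene_counter + 1L
    sprintf("G%05d", gene_counter)
  }
  for (i in seq_len(P)) {
    if (gene_counter > 0 && stats::runif(1) < config$p_shared_gene) {
      gene_of_protein[i] <- sprintf("G%05d", sample.int(gene_counter, 1))
    } else {
      gene_of_protein[i] <- new_gene()
    }
    if (stats::runif(1) < config$p_multi_gene) extra_gene[i] <- new_gene()
  }

  p_geom <- 1 / config$tx_per_subunit_mean
  tx_counter <- 0L
  map_rows <- vector("list", 2L * P)
  ri <- 0L
  for (i in seq_len(P)) {
    for (g in c(gene_of_protein[i], extra_gene[i])) {
      if (is.na(g)) next
      n_tx <- 1L + stats::rgeom(1, p_geom)
      txs <- sprintf("T%06d", tx_counter + seq_len(n_tx))
      tx_counter <- tx_counter + n_tx
      ri <- ri + 1L
      map_rows[[ri]] <- data.frame(protein_id = protein_ids[i],
                                   transcript_id = txs, gene_id = g,
                                   stringsAsFactors = FALSE)
    }
  }
  genes_used <- unique(c(gene_of_protein, extra_gene[!is.na(extra_gene)]))
  for (g in genes_used) {
    if (stats::runif(1) < config$p_gene_extra_tx) {
      n_tx <- 1L + stats::rgeom(1, 1 / config$extra_tx_mean)
      txs <- sprintf("T%06d", tx_counter + seq_len(n_tx))
      tx_counter <- tx_counter + n_tx
      ri <- ri + 1L
      map_rows[[ri]] <- data.frame(protein_id = "",
                                   transcript_id = txs, gene_id = g,
                                   stringsAsFactors = FALSE)
    }
  }
  mapping <- mapping_table(do.call(rbind, map_rows[seq_len(ri)]))

  subunit_strings <- vapply(members, function(v)
    paste(protein_ids[v], collapse = ";"), character(1))
  complexes <- complex_set(data.frame(
    complex_id = complex_ids,
    name = sprintf("synthetic complex %d", seq_len(C)),
    subunits = subunit_strings,
    stringsAsFactors = FALSE))

  n_cplx_per_protein <- table(factor(membership$protein, levels = protein_ids))
  shared_proteins <- protein_ids[n_cplx_per_protein >= 2]
  truth <- list(
    sharing_fraction = mean(n_cplx_per_protein >= 2),
    shared_proteins = shared_proteins,
    membership = membership,
    mean_tx_per_subunit = mean(lengths(mapping$protein2tx[protein_ids])),
    n_proteins = P,
    complex_sizes = stats::setNames(sizes, complex_ids))
  structure(list(complexes = complexes, mapping = mapping,
                 truth = truth, config = config),
            class = "synth_universe")
}

#' Generate synthetic per-sample expression with planted structure
#'
#' Produces a transcript-level [expr_set()] (log-scale Gaussian estimates
#' with bimodal posterior SDs) over the universe's transcripts, planting:
#' per-sample silent subunits (all their transcripts' SDs above 1.5), a
#' dominant isoform per (gene, sample) with a fixed expression margin,
#' dominant-isoform involvement at the configured rate, and an exact count of
#' major-isoform switches between sample 1 and every other sample. All
#' planted structure is recorded in the returned ground-truth ledger, which
#' is consistent with the emitted data by construction.
#'
#' @param config a [synth_config()].
#' @param universe a [simulate_universe()] result.
#' @return An object of class `synth_expression`: list with `expr` (the
#'   [expr_set()]), and `truth` containing `formable` (logical complexes x
#'   samples), `expressed` (subunits x samples), `detected` (transcripts x
#'   samples), `dominant` (genes x samples transcript ids), `switch` (per
#'   non-reference sample: planted genes, planted fraction, eligible-defined
#'   count), `involvement` (per-sample realized involvement fractions for
#'   subunits and for formable complexes) and `eligible_genes`.
#' @export
simulate_expression <- function(config, universe) {
  stopifnot(inherits(config, "synth_config"),
            inherits(universe, "synth_universe"))
  set.seed(config$seed + 1L)
  mapping <- universe$mapping
  kept <- resolve_complexes(universe$complexes, mapping)$kept

  samples <- sprintf("S%02d", seq_len(config$n_samples))
  txs <- names(mapping$tx2gene)
  genes <- unique(unname(mapping$tx2gene))
  proteins <- sort(unique(unlist(kept$subunits, use.names = FALSE)))
  n_s <- length(samples)

  # transcript ownership: in this generator each transcript codes at most one
  # protein; the remainder are gene-only extra isoforms
  assoc <- mapping$table[nzchar(mapping$table$protein_id), , drop = FALSE]
  owner <- stats::setNames(rep(NA_character_, length(txs)), txs)
  owner[assoc$transcript_id] <- assoc$protein_id
  coding_by_gene <- split(assoc$transcript_id, assoc$gene_id)
  extra_tx <- txs[is.na(owner)]
  extra_by_gene <- split(extra_tx, mapping$tx2gene[extra_tx])
  tx_by_gene <- split(txs, mapping$tx2gene[txs])
  gene_txs <- function(g, lst) {
    v <- lst[[g]]
    if (is.null(v)) character(0) else v
  }

  absent <- matrix(stats::runif(length(proteins) * n_s) < config$absent_rate,
                   length(proteins), n_s, dimnames = list(proteins, samples))

  det <- matrix(FALSE, length(txs), n_s, dimnames = list(txs, samples))
  for (p in proteins) {
    ptx <- mapping$protein2tx[[p]]
    d <- matrix(stats::runif(length(ptx) * n_s) < config$tx_detect,
                length(ptx), n_s)
    d[1, ] <- TRUE                       # an expressed subunit has >= 1 isoform
    d[, absent[p, ]] <- FALSE
    det[ptx, ] <- det[ptx, ] | d
  }
  if (length(extra_tx) > 0) {
    det[extra_tx, ] <- stats::runif(length(extra_tx) * n_s) < config$extra_detect
  }

  base <- matrix(stats::rnorm(length(genes) * n_s, mean = 3, sd = 1),
                 length(genes), n_s, dimnames = list(genes, samples))
  est <- base[mapping$tx2gene[txs], , drop = FALSE] +
    matrix(stats::rnorm(length(txs) * n_s, sd = config$est_noise),
           length(txs), n_s)
  dimnames(est) <- list(txs, samples)

  # qualifying genes: a component contributes >= 2 transcripts of one gene
  link_tab <- table(assoc$protein_id, assoc$gene_id)
  qual <- colnames(link_tab)[colSums(link_tab >= 2) > 0]

  dominant <- matrix(NA_character_, length(genes), n_s,
                     dimnames = list(genes, samples))
  pick_fresh <- function(g, s) {
    cod <- gene_txs(g, coding_by_gene)
    cod <- cod[det[cod, s]]
    ext <- gene_txs(g, extra_by_gene)
    ext <- ext[det[ext, s]]
    if (length(cod) > 0 && length(ext) > 0) {
      side <- if (stats::runif(1) < config$involvement_rate) cod else ext
    } else if (length(cod) > 0) side <- cod else side <- ext
    if (length(side) == 0) return(NA_character_)
    side[sample.int(length(side), 1)]
  }

  switch_truth <- list()
  for (s in seq_len(n_s)) {
    det_s <- det[, s]
    active_genes <- unique(mapping$tx2gene[txs[det_s]])
    if (s == 1) {
      for (g in active_genes) dominant[g, 1] <- pick_fresh(g, 1)
    } else {
      elig <- qual[!is.na(dominant[qual, 1])]
      elig <- elig[vapply(elig, function(g) {
        any(det_s[gene_txs(g, tx_by_gene)])
      }, logical(1))]
      k <- as.integer(round(config$switch_rate * length(elig)))
      cand <- elig[vapply(elig, function(g) {
        gtx <- gene_txs(g, tx_by_gene)
        any(det_s[gtx] & gtx != dominant[g, 1])
      }, logical(1))]
      sw <- if (k > 0 && length(cand) > 0)
        sample(cand, min(k, length(cand))) else character(0)
      for (g in active_genes) {
        if (g %in% sw) {
          d1 <- dominant[g, 1]
          cod <- gene_txs(g, coding_by_gene)
          ext <- gene_txs(g, extra_by_gene)
          same_side <- if (d1 %in% cod) cod else ext
          other_side <- if (d1 %in% cod) ext else cod
          pool <- setdiff(same_side[det_s[same_side]], d1)
          if (length(pool) == 0 && length(other_side) > 0) {
            pool <- setdiff(other_side[det_s[other_side]], d1)
          }
          dominant[g, s] <- if (length(pool) > 0)
            pool[sample.int(length(pool), 1)] else pick_fresh(g, s)
        } else if (g %in% elig) {
          d1 <- dominant[g, 1]
          dominant[g, s] <- if (!is.na(d1) && det_s[d1]) d1 else pick_fresh(g, s)
        } else {
          dominant[g, s] <- pick_fresh(g, s)
        }
      }
      switch_truth[[samples[s]]] <- list(
        genes = sort(sw),
        planted_fraction = if (length(elig) > 0)
          length(sw) / length(elig) else NA_real_,
        n_eligible_defined = length(elig))
    }
  }

  # enforce the dominant margin so the argmax over detected isoforms is the
  # planted dominant, whatever the Gaussian noise did
  for (s in seq_len(n_s)) {
    ds <- dominant[, s]
    def <- which(!is.na(ds))
    for (gi in def) {
      gtx <- gene_txs(genes[gi], tx_by_gene)
      gdet <- gtx[det[gtx, s]]
      est[ds[gi], s] <- max(est[gdet, s]) + config$dominant_margin
    }
  }

  sd_mat <- matrix(NA_real_, length(txs), n_s, dimnames = list(txs, samples))
  nd <- sum(det)
  sd_det <- stats::runif(nd, config$sd_detected[1], config$sd_detected[2])
  sd_det[stats::runif(nd) < config$boundary_frac] <- 1.5
  sd_mat[det] <- sd_det
  sd_mat[!det] <- stats::runif(sum(!det), config$sd_undetected[1],
                               config$sd_undetected[2])

  missing <- matrix(FALSE, length(txs), n_s, dimnames = list(txs, samples))
  if (config$missing_rate > 0) {
    missing[!det] <- stats::runif(sum(!det)) < config$missing_rate
    est[missing] <- NA_real_
    sd_mat[missing] <- NA_real_
  }

  expr <- expr_set(est, sd_mat, level = "transcript")

  expressed <- !absent
  formable <- matrix(FALSE, nrow(kept), n_s,
                     dimnames = list(kept$complex_id, samples))
  for (i in seq_len(nrow(kept))) {
    su <- kept$subunits[[i]]
    formable[i, ] <- colSums(!expressed[su, , drop = FALSE]) == 0
  }

  involvement <- do.call(rbind, lapply(seq_len(n_s), function(s) {
    inv <- vapply(proteins, function(p) {
      gs <- unique(mapping$tx2gene[mapping$protein2tx[[p]]])
      d <- dominant[gs, s]
      d <- d[!is.na(d)]
      length(d) > 0 && any(d %in% mapping$protein2tx[[p]])
    }, logical(1))
    expr_p <- expressed[, s]
    fm <- formable[, s]
    cplx_inv <- vapply(kept$subunits, function(su) any(inv[su]), logical(1))
    data.frame(sample = samples[s],
               frac_subunits_major = if (any(expr_p)) mean(inv[expr_p]) else NA_real_,
               frac_pfpc_major = if (any(fm)) mean(cplx_inv[fm]) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  truth <- list(formable = formable, expressed = expressed, detected = det,
                dominant = dominant, switch = switch_truth,
                involvement = involvement, eligible_genes = qual,
                absent = absent)
  structure(list(expr = expr, truth = truth, config = config),
            class = "synth_expression")
}

#' Generate a synthetic case/control count matrix with planted DE
#'
#' Draws log-normal baseline abundances over the universe's transcripts
#' (padded with background transcripts up to `config$de$n_tx`), plants a
#' fraction of transcripts as differentially expressed at the configured fold
#' change (alternating up/down, each group shifted symmetrically by
#' `sqrt(fold)` about the baseline), and emits negative-binomial counts with
#' per-sample depth factors.
#'
#' @param config a [synth_config()].
#' @param universe optional [simulate_universe()] result supplying transcript
#'   ids; without it all transcripts are background.
#' @param dataset optional label (also selects the RNG substream, so
#'   different datasets from one config are independent).
#' @param seed_offset integer added to `config$seed` (default 2; dataset
#'   labels add their own offset).
#' @return List with `counts` (matrix transcripts x samples), `groups`
#'   (character vector `"case"`/`"control"`), `dataset` and `truth`
#'   (`de` transcript ids, `direction` +1/-1).
#' @export
simulate_de_counts <- function(config, universe = NULL, dataset = NULL,
                               seed_offset = 2L) {
  stopifnot(inherits(config, "synth_config"))
  off <- seed_offset
  if (!is.null(dataset)) {
    off <- off + sum(utf8ToInt(dataset)) %% 1000L
  }
  set.seed(config$seed + off)
  dc <- config$de

  txs <- if (!is.null(universe)) names(universe$mapping$tx2gene) else character(0)
  if (length(txs) < dc$n_tx) {
    txs <- c(txs, sprintf("BGTX%05d", seq_len(dc$n_tx - length(txs))))
  }
  n <- length(txs)

  mu <- stats::rlnorm(n, meanlog = dc$mean_log_mu, sdlog = dc$sd_log_mu)
  n_de <- as.integer(round(dc$de_fraction * n))
  de_idx <- sort(sample.int(n, n_de))
  direction <- rep_len(c(1, -1), n_de)
  # symmetric fold planting: the two groups deviate from a common baseline
  # by sqrt(fold) each, so up- and down-regulation are equally strong signals
  mu_case <- mu
  mu_ctrl <- mu
  mu_case[de_idx] <- mu[de_idx] * dc$fold^(direction / 2)
  mu_ctrl[de_idx] <- mu[de_idx] * dc$fold^(-direction / 2)

  n_samp <- dc$n_case + dc$n_control
  groups <- c(rep("case", dc$n_case), rep("control", dc$n_control))
  sample_ids <- c(sprintf("case%02d", seq_len(dc$n_case)),
                  sprintf("ctrl%02d", seq_len(dc$n_control)))
  depth <- exp(stats::rnorm(n_samp, sd = dc$depth_factor_sd))
  size <- 1 / dc$dispersion
  counts <- matrix(0, n, n_samp, dimnames = list(txs, sample_ids))
  for (j in seq_len(n_samp)) {
    mu_j <- (if (groups[j] == "case") mu_case else mu_ctrl) * depth[j]
    counts[, j] <- stats::rnbinom(n, mu = mu_j, size = size)
  }
  list(counts = counts, groups = stats::setNames(groups, sample_ids),
       dataset = dataset,
       truth = list(de = txs[de_idx],
                    direction = stats::setNames(direction, txs[de_idx])))
}

#' Write a synthetic universe to disk
#'
#' Emits `complexes.tsv` and `mapping.tsv` in the formats read by
#' [read_complex_table()] and [read_mapping_table()], plus `truth.json` with
#' the ground-truth ledger (realized sharing, shared proteins, membership).
#'
#' @param universe a [simulate_universe()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_universe <- function(universe, dir) {
  stopifnot(inherits(universe, "synth_universe"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(complexes = file.path(dir, "complexes.tsv"),
             mapping = file.path(dir, "mapping.tsv"),
             truth = file.path(dir, "truth.json"))
  write_complex_table(universe$complexes, files[["complexes"]])
  write_mapping_table(universe$mapping, files[["mapping"]])
  truth <- universe$truth
  jsonlite::write_json(list(sharing_fraction = truth$sharing_fraction,
                            n_proteins = truth$n_proteins,
                            mean_tx_per_subunit = truth$mean_tx_per_subunit,
                            shared_proteins = truth$shared_proteins),
                       files[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Write an expression set as per-sample TSV files
#'
#' One file per sample (`<sample>.tsv`) with columns `feature_id`,
#' `estimate`, `sd`; cells missing from the matrix are omitted from the file,
#' matching how per-sample quantification output behaves.
#'
#' @param expr an [expr_set()].
#' @param dir output directory (created if needed).
#' @return Character vector of file paths (in sample order), invisibly.
#' @export
write_expression_set <- function(expr, dir) {
  stopifnot(inherits(expr, "expr_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- colnames(expr$estimate)
  paths <- file.path(dir, paste0(samples, ".tsv"))
  for (j in seq_along(samples)) {
    present <- !is.na(expr$sd[, j])
    df <- data.frame(feature_id = rownames(expr$estimate)[present],
                     estimate = sprintf("%.6f", expr$estimate[present, j]),
                     sd = sprintf("%.6f", expr$sd[present, j]),
                     stringsAsFactors = FALSE)
    .write_tsv(df, paths[j])
  }
  invisible(paths)
}
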