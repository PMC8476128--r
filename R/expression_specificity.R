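#' Tau tissue-specificity index
#'
#' For each gene with expression vector `x` over `n` tissues,
#' `tau = sum(1 - x_i / max(x)) / (n - 1)`: 0 for uniformly expressed
#' genes, 1 for single-tissue expression. Genes whose maximal cross-tissue
#' TPM is below `min_max_tpm` (lowly expressed) receive `NA`.
#'
#' @param tpm genes x tissues numeric matrix of median TPM (>= 0).
#' @param min_max_tpm low-expression filter on the per-gene maximum
#'   (default 1; strict `<` removes).
#' @return named numeric vector of tau values (NA where filtered).
#' @export
compute_tau <- function(tpm, min_max_tpm = 1) {
  stopifnot(is.matrix(tpm), ncol(tpm) >= 2)
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  mx <- apply(tpm, 1, max)
  tau <- rowSums(1 - tpm / ifelse(mx > 0, mx, 1)) / (ncol(tpm) - 1)
  tau[mx < min_max_tpm | mx == 0] <- NA_real_
  names(tau) <- rownames(tpm)
  tau
}

#' Locate the central nadir of a bimodal tau distribution
#'
#' Histograms the tau values (default 50 bins over [0,1]), smooths the
#' counts with a centered moving average, finds the two largest local
#' modes, and returns the midpoint of the minimum-density bin strictly
#' between them. The nadir must be genuine: its smoothed count must fall
#' below `min_prominence` times the smaller of the two mode counts,
#' otherwise the distribution is treated as unimodal. When no interior
#' minimum exists (unimodal or degenerate input) the supplied fallback
#' threshold is returned with a warning.
#'
#' @param tau numeric vector of tau values (NAs dropped); at least 100
#'   required.
#' @param bins number of histogram bins (default 50).
#' @param window moving-average window, odd (default 3).
#' @param fallback threshold returned when no nadir is found
#'   (default 0.76).
#' @param min_prominence maximum nadir-to-smaller-mode count ratio for the
#'   bimodal call (default 0.5).
#' @return numeric threshold.
#' @export
find_tau_threshold <- function(tau, bins = 50, window = 3,
                               fallback = 0.76, min_prominence = 0.5) {
  tau <- tau[!is.na(tau)]
  if (length(tau) < 100) stop("need at least 100 tau values")
  h <- graphics::hist(tau, breaks = seq(0, 1, length.out = bins + 1),
                      plot = FALSE)
  counts <- as.numeric(stats::filter(h$counts, rep(1 / window, window),
                                     sides = 2))
  counts[is.na(counts)] <- h$counts[is.na(counts)]
  # local maxima of the smoothed histogram; runs of equal counts form a
  # plateau and count as a single candidate peak at their midpoint
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vals <- c(-Inf, r$values, -Inf)
  is_peak <- r$values > vals[seq_along(r$values)] &
    r$values > vals[seq_along(r$values) + 2L]
  peaks <- as.integer(floor((starts[is_peak] + ends[is_peak]) / 2))
  if (length(peaks) < 2) {
    warning("tau distribution not bimodal; using fallback threshold ",
            fallback)
    return(fallback)
  }
  top2 <- sort(peaks[order(counts[peaks], decreasing = TRUE)][1:2])
  between <- (top2[1] + 1):(top2[2] - 1)
  if (length(between) == 0 || top2[2] - top2[1] < 2) {
    warning("no interior minimum between modes; using fallback threshold ",
            fallback)
    return(fallback)
  }
  nadir <- between[which.min(counts[between])]
  if (counts[nadir] > min_prominence * min(counts[top2])) {
    warning("no pronounced nadir between modes; using fallback threshold ",
            fallback)
    return(fallback)
  }
  h$mids[nadir]
}

#' Select one representative tissue per correlated tissue class
#'
#' Tissue resources often sample several correlated subtypes of a broader
#' tissue class (e.g. many brain sub-regions), which biases tau and
#' tissue-count statistics upward. This keeps exactly one tissue per
#' class: the `chosen` tissue for multi-tissue classes, the sole tissue
#' otherwise.
#'
#' @param class_map `data.frame` with columns `tissue`, `class`.
#' @param chosen named character vector mapping class to its
#'   representative tissue (required for every class with > 1 tissue).
#' @return character vector of retained tissues.
#' @export
select_representative_tissues <- function(class_map, chosen = character()) {
  stopifnot(all(c("tissue", "class") %in% names(class_map)))
  out <- character()
  for (cls in unique(class_map$class)) {
    members <- class_map$tissue[class_map$class == cls]
    if (length(members) == 1) {
      out <- c(out, members)
    } else {
      if (!cls %in% names(chosen))
        stop("class ", cls, " has ", length(members),
             " tissues but no chosen representative")
      if (!chosen[[cls]] %in% members)
        stop("chosen tissue ", chosen[[cls]], " is not in class ", cls)
      out <- c(out, chosen[[cls]])
    }
  }
  out
}

#' Top-fraction tissue-expressed gene-sets
#'
#' Per tissue, selects the `ceiling(top_fraction * n_genes)` genes with the
#' highest tissue-specific expression statistic; ties at the cutoff are
#' broken by gene identifier.
#'
#' @param tstats genes x tissues numeric matrix of t-statistics for
#'   tissue-specific expression.
#' @param top_fraction fraction of genes per set, in (0,1] (default 0.1).
#' @return named list of per-tissue gene-sets.
#' @export
tissue_expressed_sets <- function(tstats, top_fraction = 0.1) {
  stopifnot(is.matrix(tstats), !is.null(rownames(tstats)))
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0,1]")
  k <- ceiling(top_fraction * nrow(tstats))
  genes <- rownames(tstats)
  sets <- lapply(seq_len(ncol(tstats)), function(j) {
    ord <- order(-tstats[, j], genes)
    sort(genes[ord[seq_len(k)]])
  })
  names(sets) <- colnames(tstats)
  sets
}

#' Build the per-gene cis-eQTL landscape
#'
#' Counts, over representative tissues only, the tissues where a gene has
#' a significant cis-eQTL (`q < q_threshold`, strict) and where it is
#' expressed (`TPM > tpm_threshold`, strict), and attaches tau computed on
#' the same tissue subset.
#'
#' @param qvals genes x tissues matrix of cis-eGene q-values.
#' @param tpm genes x tissues matrix of median TPM.
#' @param tissues character vector of (representative) tissues to count
#'   over; defaults to all shared columns.
#' @param q_threshold eQTL significance cutoff (default 0.05).
#' @param tpm_threshold expression cutoff (default 5).
#' @param min_max_tpm tau low-expression filter (default 1).
#' @return `data.frame` with columns `gene`, `n_eqtl`, `n_express`, `tau`.
#' @export
count_landscape <- function(qvals, tpm, tissues = NULL, q_threshold = 0.05,
                            tpm_threshold = 5, min_max_tpm = 1) {
  if (is.null(tissues)) tissues <- intersect(colnames(qvals), colnames(tpm))
  stopifnot(length(tissues) >= 2,
            all(tissues %in% colnames(qvals)),
            all(tissues %in% colnames(tpm)))
  genes <- intersect(rownames(qvals), rownames(tpm))
  qv <- qvals[genes, tissues, drop = FALSE]
  xp <- tpm[genes, tissues, drop = FALSE]
  data.frame(gene = genes,
             n_eqtl = rowSums(qv < q_threshold),
             n_express = rowSums(xp > tpm_threshold),
             tau = unname(compute_tau(xp, min_max_tpm)),
             stringsAsFactors = FALSE)
}

#' Cross-tissue eQTL-landscape regression
#'
#' Fits, by ordinary least squares, the number of tissues with a detected
#' cis-eQTL on an organelle-membership indicator, controlling for the
#' number of expressed tissues, tau, log gene length, and gene length:
#' `n_eqtl ~ I_organelle + n_express + tau + log(length) + length`.
#' Genes without tau (low expression) must be excluded upstream.
#'
#' @param landscape output of [count_landscape()] (tau present for all
#'   rows).
#' @param organelle character vector, the organellar proteome gene-set.
#' @param gene_length named numeric vector of gene lengths (bp).
#' @return one-row `data.frame`: `beta`, `se`, `t`, `p` (two-sided) for
#'   the organelle indicator, plus `n_genes`, `n_set`.
#' @export
eqtl_regression <- function(landscape, organelle, gene_length) {
  stopifnot(all(c("gene", "n_eqtl", "n_express", "tau") %in%
                  names(landscape)))
  dat <- landscape[!is.na(landscape$tau), , drop = FALSE]
  len <- gene_length[dat$gene]
  if (anyNA(len)) stop("gene_length missing for some genes")
  member <- as.numeric(dat$gene %in% organelle)
  if (sum(member) == 0) stop("organelle set empty after filtering")
  X <- cbind(intercept = 1, organelle = member, n_express = dat$n_express,
             tau = dat$tau, log_length = log(len), length = len)
  fit <- ols_fit(X, dat$n_eqtl)
  p <- 2 * stats::pt(abs(fit$t["organelle"]), df = fit$df,
                     lower.tail = FALSE)
  data.frame(beta = unname(fit$coef["organelle"]),
             se = unname(fit$se["organelle"]),
             t = unname(fit$t["organelle"]), p = unname(p),
             n_genes = nrow(dat), n_set = sum(member))
}
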