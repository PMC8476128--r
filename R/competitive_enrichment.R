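covariate_design <- function(covariates, genes) {
  idx <- match(genes, covariates$gene)
  if (anyNA(idx)) stop("covariates missing for some analyzed genes")
  cv <- covariates[idx, , drop = FALSE]
  X <- cbind(length_bp = cv$length_bp, snp_density = cv$snp_density,
             inv_mac = cv$inv_mac, log_length = log(cv$length_bp),
             log_density = log(cv$snp_density), log_inv_mac = log(cv$inv_mac))
  if (any(!is.finite(X))) stop("covariates must be positive and finite")
  X
}

#' Competitive gene-set enrichment regression
#'
#' Regresses gene-level association Z statistics on a set-membership
#' indicator plus six technical covariates — gene length, SNP density,
#' inverse minor allele count, and their logs — by ordinary least squares.
#' The test is one-sided (enrichment only): the p-value is the upper-tail
#' t probability of the membership coefficient. When a control superset is
#' supplied the analysis is restricted to its genes, so membership is
#' tested competitively against that background (e.g. all protein-coding
#' genes with data).
#'
#' @param stats `data.frame` with columns `gene`, `z` (a single trait).
#' @param set character vector, the gene-set tested.
#' @param covariates `data.frame` with columns `gene`, `length_bp`,
#'   `snp_density`, `inv_mac`.
#' @param control_superset optional character vector restricting the
#'   analyzed genes (competitive background).
#' @return one-row `data.frame`: `set_size`, `n_genes`, `beta`, `se`,
#'   `t`, `p_one_sided`.
#' @export
geneset_regression <- function(stats, set, covariates,
                               control_superset = NULL) {
  stopifnot(all(c("gene", "z") %in% names(stats)))
  dat <- stats
  if (!is.null(control_superset))
    dat <- dat[dat$gene %in% control_superset, , drop = FALSE]
  member <- as.numeric(dat$gene %in% set)
  if (length(unique(member)) < 2)
    stop("degenerate design: membership indicator is constant")
  if (sum(member) < 2 || sum(1 - member) < 2)
    stop("need at least 2 members and 2 non-members")
  X <- cbind(intercept = 1, member = member,
             covariate_design(covariates, dat$gene))
  fit <- ols_fit(X, dat$z)
  p1 <- stats::pt(fit$t["member"], df = fit$df, lower.tail = FALSE)
  data.frame(set_size = sum(member), n_genes = nrow(dat),
             beta = unname(fit$coef["member"]), se = unname(fit$se["member"]),
             t = unname(fit$t["member"]), p_one_sided = unname(p1))
}

#' Enrichment regression conditioning on constraint
#'
#' Tests whether a set's enrichment survives conditioning on gene
#' constraint: LOEUF and log LOEUF are residualized out of the membership
#' indicator (membership replaced by its OLS residual on
#' `[1, LOEUF, log LOEUF]`) before the competitive regression, which still
#' retains the six default technical covariates. Genes with missing or
#' non-positive LOEUF are dropped and counted.
#'
#' @inheritParams geneset_regression
#' @param loeuf named numeric vector of per-gene LOEUF values.
#' @return one-row `data.frame` as in [geneset_regression()], plus
#'   `n_dropped` (genes without usable LOEUF).
#' @export
condition_on_constraint <- function(stats, set, covariates, loeuf,
                                    control_superset = NULL) {
  dat <- stats
  if (!is.null(control_superset))
    dat <- dat[dat$gene %in% control_superset, , drop = FALSE]
  lo <- loeuf[dat$gene]
  usable <- !is.na(lo) & lo > 0
  n_dropped <- sum(!usable)
  if (n_dropped > 0)
    message("dropping ", n_dropped, " gene(s) without positive LOEUF")
  dat <- dat[usable, , drop = FALSE]
  lo <- lo[usable]
  member <- as.numeric(dat$gene %in% set)
  if (length(unique(member)) < 2)
    stop("degenerate design: membership indicator is constant")
  # projection residual; robust to collinearity between LOEUF and its log
  # (e.g. LOEUF taking few distinct values)
  Z <- cbind(1, lo, log(lo))
  m_res <- drop(member - qr.fitted(qr(Z), member))
  X <- cbind(intercept = 1, member = m_res,
             covariate_design(covariates, dat$gene))
  fit <- ols_fit(X, dat$z)
  p1 <- stats::pt(fit$t["member"], df = fit$df, lower.tail = FALSE)
  data.frame(set_size = sum(member), n_genes = nrow(dat),
             beta = unname(fit$coef["member"]), se = unname(fit$se["member"]),
             t = unname(fit$t["member"]), p_one_sided = unname(p1),
             n_dropped = n_dropped)
}

#' Benjamini-Hochberg q-values and significance verdicts
#'
#' Standard step-up BH across a batch of p-values; a test is declared
#' significant when its q-value is below `fdr`.
#'
#' @param pvals numeric vector of p-values in (0,1].
#' @param fdr false-discovery-rate threshold (default 0.1).
#' @return `data.frame` with columns `p`, `q`, `significant`.
#' @export
bh_threshold <- function(pvals, fdr = 0.1) {
  if (length(pvals) == 0)
    return(data.frame(p = numeric(), q = numeric(), significant = logical()))
  stopifnot(all(pvals > 0 & pvals <= 1))
  q <- stats::p.adjust(pvals, method = "BH")
  data.frame(p = pvals, q = q, significant = q < fdr)
}

#' Subsampling power analysis for competitive enrichment
#'
#' Draws `n_trials` uniform subsamples of `source_set` at each requested
#' size, tests each with [geneset_regression()], and reports the fraction
#' significant (power) per size with a Wilson 95% interval. Significance is
#' decided either by BH at `fdr` across the full batch of tests in the run
#' (`rule = "bh"`, the default) or by comparing each one-sided p to `fdr`
#' directly (`rule = "nominal"`).
#'
#' @inheritParams geneset_regression
#' @param source_set the gene-set subsampled from.
#' @param sizes integer vector of subsample sizes.
#' @param n_trials subsamples per size.
#' @param fdr threshold for the significance rule (default 0.1).
#' @param rule `"bh"` or `"nominal"`.
#' @param seed RNG seed for the subsampling.
#' @return `data.frame` with columns `size`, `n_trials`, `power`, `lower`,
#'   `upper`.
#' @export
subsample_power <- function(stats, covariates, source_set, sizes,
                            n_trials = 100, fdr = 0.1,
                            rule = c("bh", "nominal"), seed = 1,
                            control_superset = NULL) {
  rule <- match.arg(rule)
  stopifnot(n_trials >= 1)
  if (any(sizes > length(source_set)))
    stop("subsample size exceeds the source set size")
  pmat <- withr::with_seed(as.integer(seed) %% 2000000000L, {
    sapply(sizes, function(sz) {
      vapply(seq_len(n_trials), function(i) {
        sub <- sample(source_set, sz)
        geneset_regression(stats, sub, covariates,
                           control_superset)$p_one_sided
      }, numeric(1))
    })
  })
  pmat <- matrix(pmat, nrow = n_trials)
  sig <- if (rule == "bh") {
    matrix(bh_threshold(as.numeric(pmat), fdr)$significant,
           nrow = n_trials)
  } else pmat < fdr
  out <- do.call(rbind, lapply(seq_along(sizes), function(j) {
    ci <- wilson_ci(sum(sig[, j]), n_trials)
    data.frame(size = sizes[j], n_trials = n_trials,
               power = unname(ci["estimate"]), lower = unname(ci["lower"]),
               upper = unname(ci["upper"]))
  }))
  rownames(out) <- NULL
  out
}
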