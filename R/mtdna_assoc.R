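#' mtDNA variant quality control
#'
#' Drops variants that (i) appear on the exclusion list (e.g. cluster-plot
#' review failures), (ii) carry any heterozygous call (anything other than
#' 0, 1 or missing in a haploid matrix), (iii) have a within-array-type
#' call rate below `call_rate_min` in any array batch where the variant is
#' assessed, or (iv) have fewer than `min_carriers` alternate-genotype
#' individuals. The result is independent of row/column order.
#'
#' @param geno samples x variants numeric matrix with values 0/1/NA
#'   (heterozygous calls encoded as any other value).
#' @param batch character vector of array-batch labels per sample.
#' @param exclusion_list variant names to drop a priori.
#' @param call_rate_min within-batch call-rate threshold (default 0.95;
#'   strict `<` removes).
#' @param min_carriers minimum alternate-carrier count (default 20;
#'   "less than 20" removes). Set to 0 to skip this rule.
#' @return list with `kept` (variant names) and `log`
#'   (`data.frame(variant, reason)` for dropped variants).
#' @export
variant_qc <- function(geno, batch, exclusion_list = character(),
                       call_rate_min = 0.95, min_carriers = 20) {
  stopifnot(is.matrix(geno), length(batch) == nrow(geno))
  variants <- colnames(geno)
  unknown <- setdiff(exclusion_list, variants)
  if (length(unknown))
    warning("exclusion list names unknown variant(s): ",
            paste(utils::head(unknown, 3), collapse = ", "))
  reasons <- stats::setNames(rep(NA_character_, length(variants)), variants)
  for (v in variants) {
    calls <- geno[, v]
    if (v %in% exclusion_list) {
      reasons[v] <- "exclusion_list"
    } else if (any(!is.na(calls) & !calls %in% c(0, 1))) {
      reasons[v] <- "heterozygous_calls"
    } else {
      low <- FALSE
      for (b in unique(batch)) {
        bc <- calls[batch == b]
        if (all(is.na(bc))) next  # variant not assessed on this array
        if (mean(!is.na(bc)) < call_rate_min) low <- TRUE
      }
      if (low) {
        reasons[v] <- "low_call_rate"
      } else if (min_carriers > 0 &&
                 sum(calls == 1, na.rm = TRUE) < min_carriers) {
        reasons[v] <- "too_few_carriers"
      }
    }
  }
  dropped <- !is.na(reasons)
  list(kept = variants[!dropped],
       log = data.frame(variant = variants[dropped],
                        reason = unname(reasons[dropped]),
                        stringsAsFactors = FALSE))
}

#' mtDNA sample quality control
#'
#' Removes samples whose call rate — over the variants assessed on the
#' sample's own array batch — is below `call_rate_min`.
#'
#' @inheritParams variant_qc
#' @return character vector of kept sample names.
#' @export
sample_qc <- function(geno, batch, call_rate_min = 0.95) {
  stopifnot(is.matrix(geno), length(batch) == nrow(geno))
  keep <- logical(nrow(geno))
  for (b in unique(batch)) {
    rows <- which(batch == b)
    assessed <- colSums(!is.na(geno[rows, , drop = FALSE])) > 0
    if (!any(assessed)) next
    cr <- rowMeans(!is.na(geno[rows, assessed, drop = FALSE]))
    keep[rows] <- cr >= call_rate_min
  }
  rownames(geno)[keep]
}

#' Full mtDNA QC pipeline
#'
#' Applies exclusion-list / heterozygosity / call-rate variant QC, then
#' sample QC, then the minimum-carrier variant filter on the retained
#' samples (carriers are counted after sample removal).
#'
#' @inheritParams variant_qc
#' @return list with `geno` (filtered matrix), `batch`, `samples`,
#'   `variants`, and the combined QC `log`.
#' @export
mt_qc <- function(geno, batch, exclusion_list = character(),
                  call_rate_min = 0.95, min_carriers = 20) {
  v1 <- variant_qc(geno, batch, exclusion_list, call_rate_min,
                   min_carriers = 0)
  g <- geno[, v1$kept, drop = FALSE]
  samples <- sample_qc(g, batch, call_rate_min)
  rows <- match(samples, rownames(geno))
  g <- g[rows, , drop = FALSE]
  b <- batch[rows]
  carriers <- colSums(g == 1, na.rm = TRUE)
  few <- carriers < min_carriers
  log2 <- data.frame(variant = colnames(g)[few],
                     reason = rep("too_few_carriers", sum(few)),
                     stringsAsFactors = FALSE)
  g <- g[, !few, drop = FALSE]
  list(geno = g, batch = b, samples = samples, variants = colnames(g),
       log = rbind(v1$log, log2))
}

#' Build the standard mtDNA association covariate set
#'
#' The 20 nuclear principal components, sex, age, and the derived terms
#' age^2, sex*age and sex*age^2; optionally an array-batch indicator.
#'
#' @param pheno `data.frame` containing `sex`, `age` and `PC1..PC20`.
#' @param batch optional batch labels; when given, a 0/1 indicator for the
#'   second batch level is appended.
#' @return numeric covariate matrix (no intercept).
#' @export
build_covariates <- function(pheno, batch = NULL) {
  pcs <- as.matrix(pheno[, sprintf("PC%d", 1:20)])
  X <- cbind(pcs, sex = pheno$sex, age = pheno$age, age2 = pheno$age^2,
             sex_age = pheno$sex * pheno$age,
             sex_age2 = pheno$sex * pheno$age^2)
  if (!is.null(batch)) {
    lev <- sort(unique(batch))
    if (length(lev) > 1)
      X <- cbind(X, array_batch = as.numeric(batch == lev[2]))
  }
  X
}

#' Phenotype-variant pair quality control for binary traits
#'
#' A binary phenotype-variant pair is tested only when the expected number
#' of alternate-genotype cases, `n_carriers * n_cases / n_total`, reaches
#' `min_expected_cases`. Continuous traits are unaffected.
#'
#' @param n_carriers alternate-carrier count(s) for the variant(s).
#' @param n_cases number of cases for the trait.
#' @param n_total cohort size.
#' @param min_expected_cases threshold (default 20; kept iff expected
#'   `>=` threshold).
#' @return logical vector: keep the pair?
#' @export
pair_qc <- function(n_carriers, n_cases, n_total, min_expected_cases = 20) {
  expected <- n_carriers * (n_cases / n_total)
  expected >= min_expected_cases
}

#' Linear mtDNA association for a continuous trait
#'
#' Ordinary least squares of the phenotype on genotype plus the covariate
#' set (with intercept); samples with a missing call are dropped for that
#' variant only. Two-sided t-test on the genotype coefficient.
#'
#' @param y continuous phenotype vector.
#' @param g genotype vector (0/1/NA).
#' @param covar covariate matrix from [build_covariates()].
#' @param variant,trait labels for the output record.
#' @return one-row `data.frame(variant, trait, beta, se, p, model,
#'   n_used, converged)` or `NULL` when the genotype is constant after
#'   missingness.
#' @export
linear_assoc <- function(y, g, covar, variant = "v", trait = "y") {
  ok <- !is.na(g) & !is.na(y) & stats::complete.cases(covar)
  gv <- g[ok]
  if (length(unique(gv)) < 2) return(NULL)
  X <- cbind(intercept = 1, geno = gv, covar[ok, , drop = FALSE])
  if (nrow(X) <= ncol(X) + 1) stop("too few observations for the design")
  fit <- ols_fit(X, y[ok])
  p <- 2 * stats::pt(abs(fit$t["geno"]), df = fit$df, lower.tail = FALSE)
  data.frame(variant = variant, trait = trait,
             beta = unname(fit$coef["geno"]), se = unname(fit$se["geno"]),
             p = unname(p), model = "linear", n_used = nrow(X),
             converged = TRUE, stringsAsFactors = FALSE)
}

# Firth-penalized logistic log-likelihood: l(beta) + 0.5 * log det I(beta)
firth_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  W <- p * (1 - p)
  info <- crossprod(X * W, X)
  ld <- determinant(info, logarithm = TRUE)
  # numerically stable log(1 + exp(eta))
  lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
  sum(y * eta - lse) + 0.5 * as.numeric(ld$modulus)
}

#' Firth-penalized logistic regression for a binary trait
#'
#' Maximizes the Jeffreys-prior-penalized logistic log-likelihood
#' `l(beta) + 0.5 log det I(beta)` by Newton iteration with step-halving,
#' converging when the largest modified-score component falls below `tol`
#' (default 1e-6) or after `max_iter` iterations. Estimates remain finite
#' even under complete separation. Standard errors are Wald, from the
#' penalized information at the optimum.
#'
#' @param y binary 0/1 phenotype.
#' @param g genotype vector (0/1/NA), or `NULL` to fit covariates only.
#' @param covar covariate matrix (no intercept; may be `NULL`).
#' @param variant,trait labels for the output record.
#' @param tol score convergence tolerance.
#' @param max_iter maximum Newton iterations (default 100).
#' @return one-row `data.frame` as in [linear_assoc()] with
#'   `model = "firth"`; `converged = FALSE` flags non-convergence.
#' @export
firth_logistic <- function(y, g = NULL, covar = NULL, variant = "v",
                           trait = "y", tol = 1e-6, max_iter = 100) {
  X <- cbind(intercept = rep(1, length(y)))
  if (!is.null(g)) X <- cbind(X, geno = g)
  if (!is.null(covar)) X <- cbind(X, covar)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  yy <- y[ok]
  if (length(unique(yy)) < 2)
    stop("both case and control classes must be present")
  if (!is.null(g) && length(unique(X[, "geno"])) < 2) return(NULL)
  beta <- numeric(ncol(X))
  ll <- firth_loglik(X, yy, beta)
  converged <- FALSE
  info <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    pr <- stats::plogis(eta)
    W <- pr * (1 - pr)
    info <- crossprod(X * W, X)
    Vinv <- solve(info)
    # hat values of the weighted design give the Firth score modification
    h <- rowSums((X %*% Vinv) * X) * W
    score <- drop(crossprod(X, yy - pr + h * (0.5 - pr)))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    step <- drop(Vinv %*% score)
    # step-halving on the penalized likelihood
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- firth_loglik(X, yy, cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    beta <- beta + lam * step
    ll <- firth_loglik(X, yy, beta)
  }
  se <- sqrt(diag(solve(info)))
  names(se) <- colnames(X)
  j <- if (is.null(g)) 1L else which(colnames(X) == "geno")
  z <- beta[j] / se[j]
  rec <- data.frame(variant = variant, trait = trait, beta = beta[j],
                    se = unname(se[j]), p = 2 * stats::pnorm(-abs(z)),
                    model = "firth", n_used = nrow(X),
                    converged = converged, stringsAsFactors = FALSE)
  attr(rec, "coef") <- stats::setNames(beta, colnames(X))
  rec
}

#' Per-allele effect size for a target power in the mtDNA scan
#'
#' Inverts the two-sided Wald power calculation for a biallelic haploid
#' variant: the effect (in phenotype SD units) whose non-centrality
#' `beta * sqrt(n p (1-p)) / sigma` reaches `qnorm(1-alpha/2) +
#' qnorm(power)`.
#'
#' @param n cohort size.
#' @param n_carriers alternate-allele carrier count.
#' @param alpha significance threshold (default the mtDNA-wide
#'   Bonferroni threshold over 4337 pairs).
#' @param power target power (default 0.9).
#' @param sigma residual phenotype SD (default 1).
#' @return numeric per-allele effect size.
#' @export
mt_power_effect <- function(n, n_carriers, alpha = 0.05 / 4337,
                            power = 0.9, sigma = 1) {
  p <- n_carriers / n
  stopifnot(p > 0, p < 1)
  ncp <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  ncp * sigma / sqrt(n * p * (1 - p))
}

#' mtDNA-wide significance threshold
#'
#' Bonferroni correction over the tested phenotype-variant pairs:
#' `0.05 / n_pairs` at the default alpha.
#'
#' @param n_pairs number of tested pairs (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return numeric threshold.
#' @export
mtdna_threshold <- function(n_pairs, alpha = 0.05) {
  if (n_pairs < 1) stop("n_pairs must be at least 1")
  alpha / n_pairs
}

#' Run an mtDNA-wide association scan
#'
#' QCs the genotype matrix with [mt_qc()], applies [pair_qc()] for binary
#' traits, and tests every remaining variant by linear regression
#' (continuous traits) or Firth logistic regression (binary traits) with
#' the standard covariate formula.
#'
#' @param geno samples x variants 0/1/NA matrix.
#' @param batch array-batch labels per sample.
#' @param pheno phenotype/covariate `data.frame` (see
#'   [build_covariates()]); rows aligned with `geno`.
#' @param trait name of the phenotype column to test.
#' @param binary is the trait binary? (selects the Firth model.)
#' @param exclusion_list,call_rate_min,min_carriers passed to [mt_qc()].
#' @param min_expected_cases passed to [pair_qc()] for binary traits.
#' @param array_covariate include the batch indicator (linear model only
#'   by default; Firth models omit it unless forced).
#' @return `data.frame` of association records, one row per tested pair.
#' @export
mt_gwas <- function(geno, batch, pheno, trait, binary = FALSE,
                    exclusion_list = character(), call_rate_min = 0.95,
                    min_carriers = 20, min_expected_cases = 20,
                    array_covariate = FALSE) {
  qc <- mt_qc(geno, batch, exclusion_list, call_rate_min, min_carriers)
  rows <- match(qc$samples, pheno$sample)
  ph <- pheno[rows, , drop = FALSE]
  covar <- build_covariates(ph, batch = if (array_covariate) qc$batch)
  y <- ph[[trait]]
  out <- list()
  for (v in qc$variants) {
    g <- qc$geno[, v]
    if (binary) {
      n_carriers <- sum(g == 1, na.rm = TRUE)
      if (!pair_qc(n_carriers, sum(y == 1, na.rm = TRUE),
                   sum(!is.na(y)), min_expected_cases)) next
      out[[v]] <- firth_logistic(y, g, covar, variant = v, trait = trait)
    } else {
      out[[v]] <- linear_assoc(y, g, covar, variant = v, trait = trait)
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(res)) rownames(res) <- NULL
  res
}
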