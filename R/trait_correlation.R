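# Bivariate standard-normal rectangle probability P(X <= h, Y <= k | rho),
# evaluated by one-dimensional quadrature over the conditional CDF.
pbinorm <- function(h, k, rho) {
  if (abs(rho) >= 1) rho <- sign(rho) * 0.999999
  if (!is.finite(h) && h > 0) return(stats::pnorm(k))
  if (!is.finite(k) && k > 0) return(stats::pnorm(h))
  if (!is.finite(h) || !is.finite(k)) return(0)
  s <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((k - rho * x) / s)
  stats::integrate(f, -8.5, h, rel.tol = 1e-10,
                   stop.on.error = FALSE)$value
}

# Two-step tetrachoric estimate from a 2x2 table. Thresholds are fixed
# from the margins; rho maximizes the bivariate-normal cell likelihood.
tetrachoric_fit <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  p1 <- (n11 + n10) / n   # P(A = 1)
  p2 <- (n11 + n01) / n   # P(B = 1)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1))
    stop("binary trait with a single observed class")
  h <- stats::qnorm(1 - p1)
  k <- stats::qnorm(1 - p2)
  cellp <- function(rho) {
    p_hk <- pbinorm(h, k, rho)          # P(A=0, B=0) on latent scale
    q00 <- p_hk
    q01 <- stats::pnorm(h) - p_hk
    q10 <- stats::pnorm(k) - p_hk
    q11 <- 1 - q00 - q01 - q10
    pmax(c(q11, q10, q01, q00), 1e-12)
  }
  negll <- function(rho) {
    q <- cellp(rho)
    -(n11 * log(q[1]) + n10 * log(q[2]) + n01 * log(q[3]) + n00 * log(q[4]))
  }
  opt <- stats::optimize(negll, c(-0.999, 0.999), tol = 1e-6)
  rho <- opt$minimum
  # observed information by central finite difference of the negative
  # log-likelihood; SE supports the normal-approximation p-value
  eps <- 1e-4
  hess <- (negll(min(rho + eps, 0.999)) - 2 * negll(rho) +
             negll(max(rho - eps, -0.999))) / eps^2
  se <- if (is.finite(hess) && hess > 0) 1 / sqrt(hess) else NA_real_
  list(estimate = rho, se = se)
}

# Biserial correlation: point-biserial corrected by the latent-normal
# density factor at the dichotomization threshold.
biserial_fit <- function(x_cont, x_bin) {
  p1 <- mean(x_bin)
  if (p1 %in% c(0, 1)) stop("binary trait with a single observed class")
  n <- length(x_cont)
  r_pb <- stats::cor(x_cont, x_bin)
  z <- stats::qnorm(p1)
  factor <- sqrt(p1 * (1 - p1)) / stats::dnorm(z)
  est <- max(-1, min(1, r_pb * factor))
  se <- factor * (1 - r_pb^2) / sqrt(n - 3)
  list(estimate = est, se = se)
}

#' Pairwise trait correlations under a latent-normal model
#'
#' For every trait pair the estimator follows the type combination:
#' Pearson for two continuous traits, tetrachoric (two-step: thresholds
#' from the marginal prevalences, then likelihood maximization over the
#' latent correlation) for two binary traits, and biserial (point-biserial
#' corrected by the normal-density factor at the threshold) for mixed
#' pairs. Observations are pairwise-complete; p-values come from
#' `estimate / se` against a standard normal.
#'
#' @param data `data.frame` of sample rows and trait columns (a `sample`
#'   column, if present, is ignored).
#' @param types named character vector `"continuous"`/`"binary"` per
#'   trait; defaults to the `"types"` attribute of `data` (as set by
#'   [gen_phenotypes()]).
#' @param min_obs minimum complete observations per pair (default 10).
#' @return `data.frame` with columns `trait_a`, `trait_b`, `estimator`,
#'   `estimate`, `se`, `p`, `n`.
#' @export
pairwise_correlation <- function(data, types = attr(data, "types"),
                                 min_obs = 10) {
  if (is.null(types)) stop("trait types must be supplied")
  traits <- names(types)
  stopifnot(all(traits %in% names(data)))
  out <- list()
  for (i in seq_along(traits)) for (j in seq_len(i - 1L)) {
    ta <- traits[j]; tb <- traits[i]
    xa <- data[[ta]]; xb <- data[[tb]]
    ok <- !is.na(xa) & !is.na(xb)
    if (sum(ok) < min_obs)
      stop("pair ", ta, "/", tb, " has fewer than ", min_obs,
           " complete observations")
    xa <- xa[ok]; xb <- xb[ok]
    n <- length(xa)
    both_bin <- types[ta] == "binary" && types[tb] == "binary"
    both_cont <- types[ta] == "continuous" && types[tb] == "continuous"
    res <- tryCatch({
      if (both_cont) {
        r <- stats::cor(xa, xb)
        list(estimator = "pearson", estimate = r,
             se = (1 - r^2) / sqrt(n - 3))
      } else if (both_bin) {
        n11 <- sum(xa == 1 & xb == 1); n10 <- sum(xa == 1 & xb == 0)
        n01 <- sum(xa == 0 & xb == 1); n00 <- sum(xa == 0 & xb == 0)
        c(list(estimator = "tetrachoric"), tetrachoric_fit(n11, n10, n01, n00))
      } else {
        cont <- if (types[ta] == "continuous") xa else xb
        bin <- if (types[ta] == "continuous") xb else xa
        c(list(estimator = "biserial"), biserial_fit(cont, bin))
      }
    }, error = function(e) {
      warning("pair ", ta, "/", tb, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    p <- 2 * stats::pnorm(-abs(res$estimate / res$se))
    out[[paste(ta, tb)]] <- data.frame(trait_a = ta, trait_b = tb,
                                       estimator = res$estimator,
                                       estimate = res$estimate, se = res$se,
                                       p = p, n = n,
                                       stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble a symmetric correlation matrix from pairwise entries
#'
#' @param entries output of [pairwise_correlation()].
#' @return symmetric numeric matrix with unit diagonal.
#' @export
correlation_matrix <- function(entries) {
  traits <- unique(c(entries$trait_a, entries$trait_b))
  m <- diag(length(traits))
  dimnames(m) <- list(traits, traits)
  for (r in seq_len(nrow(entries))) {
    m[entries$trait_a[r], entries$trait_b[r]] <- entries$estimate[r]
    m[entries$trait_b[r], entries$trait_a[r]] <- entries$estimate[r]
  }
  m
}

#' Order traits by the first eigenvector of |correlation|
#'
#' Takes the element-wise absolute value of a symmetric correlation
#' matrix, extracts the eigenvector of the largest-magnitude eigenvalue,
#' flips its sign so the largest-magnitude loading is positive, and
#' returns the traits sorted by descending loading (ties broken by trait
#' label).
#'
#' @param corr symmetric correlation matrix with dimnames.
#' @return character vector of ordered trait names.
#' @export
order_by_first_eigenvector <- function(corr) {
  if (!is.matrix(corr) || max(abs(corr - t(corr))) > 1e-8)
    stop("correlation matrix must be symmetric")
  a <- abs(corr)
  ev <- eigen(a, symmetric = TRUE)
  lam <- ev$values
  # all eigenvalues tied (within tolerance) with the largest magnitude span
  # the leading eigenspace; projecting a uniform start vector onto it gives
  # a deterministic representative (equal loadings for an identity matrix)
  top <- abs(abs(lam) - max(abs(lam))) <= 1e-8 * max(abs(lam))
  V <- ev$vectors[, top, drop = FALSE]
  start <- rep(1 / sqrt(nrow(a)), nrow(a))
  v <- drop(V %*% crossprod(V, start))
  if (sqrt(sum(v^2)) < 1e-8) v <- V[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  # round so exchangeable traits tie exactly and fall back to the label
  v <- round(v / max(abs(v)), 9)
  traits <- rownames(corr)
  traits[order(-v, traits)]
}

#' Bonferroni cutoff across genetic and phenotypic correlation tests
#'
#' `alpha / (C(n_g, 2) + C(n_p, 2))`, counting every pairwise hypothesis
#' in both the genetic and the phenotypic correlation analyses. An absent
#' arm may be given as 0 traits.
#'
#' @param n_traits_genetic number of traits in the genetic arm.
#' @param n_traits_phenotypic number of traits in the phenotypic arm.
#' @param alpha family-wise error rate (default 0.05).
#' @return numeric p-value threshold.
#' @export
bonferroni_cutoff <- function(n_traits_genetic, n_traits_phenotypic = 0,
                              alpha = 0.05) {
  n_tests <- choose(n_traits_genetic, 2) + choose(n_traits_phenotypic, 2)
  if (n_tests < 1) stop("fewer than one pairwise test; need >= 2 traits")
  alpha / n_tests
}
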