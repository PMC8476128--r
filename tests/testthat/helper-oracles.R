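# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, normal equations, grid search, closed form)
# kept separate from the package's own code paths.

# Two-sided Fisher exact p by enumerating every 2x2 table with the observed
# margins and summing hypergeometric point probabilities <= the observed
# table's (with a small relative tolerance for floating-point ties).
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b          # target-set size
  n <- c + d          # non-members
  k <- a + c          # trait-associated genes
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# OLS coefficient table straight from the normal equations.
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(XtX)))
  t <- drop(beta) / se
  list(beta = drop(beta), se = se, t = t, df = df,
       p_two = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
       p_upper = stats::pt(t, df, lower.tail = FALSE))
}

# Firth-penalized logistic log-likelihood, written independently of the
# package internals.
firth_ll_oracle <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  info <- t(X * (p * (1 - p))) %*% X
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) +
    0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
}

# Maximize the penalized likelihood for a 2-column design by nested grid
# refinement; returns the argmax to ~1e-4.
firth_grid_oracle <- function(X, y, lo = -10, hi = 10) {
  centre <- c(0, 0)
  width <- hi - lo
  for (round in 1:5) {
    g1 <- seq(centre[1] - width / 2, centre[1] + width / 2, length.out = 41)
    g2 <- seq(centre[2] - width / 2, centre[2] + width / 2, length.out = 41)
    best <- -Inf
    for (b1 in g1) for (b2 in g2) {
      ll <- firth_ll_oracle(X, y, c(b1, b2))
      if (ll > best) { best <- ll; centre <- c(b1, b2) }
    }
    width <- width / 10
  }
  centre
}

# Exhaustive enrichment-count null for a tiny universe: every size-m
# subset is a sample; returns Pr(N_null <= n_obs) exactly.
enrich_count_exhaustive <- function(trait_sets, target, universe) {
  m <- length(target)
  count_for <- function(member_genes) {
    sum(vapply(trait_sets, function(tg) {
      a <- length(intersect(tg, member_genes))
      b <- m - a
      c_ <- length(tg) - a
      d <- length(universe) - m - c_
      (a * d) > (b * c_)
    }, logical(1)))
  }
  obs <- count_for(target)
  combos <- utils::combn(universe, m, simplify = FALSE)
  nulls <- vapply(combos, count_for, numeric(1))
  list(n_obs = obs, exact_p = mean(nulls <= obs), null_counts = nulls)
}

# a small, well-conditioned competitive-regression design together with the
# explicit model matrix its oracle uses
small_acc_design <- function(seed, n = 14) {
  withr::with_seed(seed, {
    cov <- data.frame(gene = sprintf("g%02d", 1:n),
                      length_bp = rlnorm(n, 1.5, 0.5),
                      snp_density = rgamma(n, 4, 1),
                      inv_mac = runif(n, 0.05, 0.9))
    member <- rep(c(1, 0), length.out = n)
    stats <- data.frame(gene = cov$gene, z = rnorm(n) + 0.6 * member)
    X <- cbind(1, member, cov$length_bp, cov$snp_density, cov$inv_mac,
               log(cov$length_bp), log(cov$snp_density), log(cov$inv_mac))
    list(stats = stats, cov = cov, set = cov$gene[member == 1], X = X)
  })
}

# small default config used by many tests
tiny_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 200, n_traits = 5, n_tissues = 6,
             n_samples = 500, planted_set_size = 20, ...)
}
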