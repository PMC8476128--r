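small_design <- function(seed = 21, n = 12) {
  withr::with_seed(seed, {
    # modest covariate scales keep the normal equations well conditioned,
    # so implementation and oracle agree to full precision
    cov <- data.frame(gene = sprintf("g%02d", 1:n),
                      length_bp = rlnorm(n, 1.5, 0.5),
                      snp_density = rgamma(n, 4, 1),
                      inv_mac = runif(n, 0.05, 0.9))
    member <- rep(c(1, 0), length.out = n)
    z <- rnorm(n) + 0.8 * member
    list(stats = data.frame(gene = cov$gene, z = z),
         cov = cov, set = cov$gene[member == 1])
  })
}

test_that("regression layer matches the normal-equations oracle to 1e-10", {
  d <- small_design()
  got <- geneset_regression(d$stats, d$set, d$cov)
  X <- cbind(1, as.numeric(d$stats$gene %in% d$set), d$cov$length_bp,
             d$cov$snp_density, d$cov$inv_mac, log(d$cov$length_bp),
             log(d$cov$snp_density), log(d$cov$inv_mac))
  oracle <- ols_oracle(X, d$stats$z)
  expect_equal(got$beta, oracle$beta[2], tolerance = 1e-10)
  expect_equal(got$se, unname(oracle$se[2]), tolerance = 1e-10)
  expect_equal(got$p_one_sided, unname(oracle$p_upper[2]), tolerance = 1e-10)
})

test_that("regression equals the oracle on 100 random small designs", {
  for (s in 1:100) {
    d <- small_design(seed = 400 + s, n = sample(10:25, 1))
    got <- geneset_regression(d$stats, d$set, d$cov)
    X <- cbind(1, as.numeric(d$stats$gene %in% d$set), d$cov$length_bp,
               d$cov$snp_density, d$cov$inv_mac, log(d$cov$length_bp),
               log(d$cov$snp_density), log(d$cov$inv_mac))
    oracle <- ols_oracle(X, d$stats$z)
    expect_equal(got$beta, oracle$beta[2], tolerance = 1e-10)
    expect_equal(got$p_one_sided, unname(oracle$p_upper[2]),
                 tolerance = 1e-10)
  }
})

test_that("degenerate and rank-deficient designs raise clear errors", {
  d <- small_design()
  expect_error(geneset_regression(d$stats, d$stats$gene, d$cov),
               "membership indicator is constant")
  expect_error(geneset_regression(d$stats, character(), d$cov),
               "membership indicator is constant")
  collinear <- d$cov
  collinear$snp_density <- collinear$length_bp * 2
  expect_error(geneset_regression(d$stats, d$set, collinear),
               "collinear")
})

test_that("one-sided type-I error is calibrated under a null set", {
  cfg0 <- sim_config(seed = 2, n_genes = 2000, enrichment_delta = 0)
  gt <- gen_gene_table(cfg0)
  target <- gt$gene[1:200]
  hits <- 0
  for (r in 1:500) {
    cfr <- sim_config(seed = 1000 + r, n_genes = 2000, enrichment_delta = 0)
    st <- gen_gene_stats(cfr, gt$gene, target)
    hits <- hits + (geneset_regression(st, target, gt)$p_one_sided <= 0.05)
  }
  expect_gte(hits / 500, 0.03)
  expect_lte(hits / 500, 0.07)
})

test_that("control superset restricts the competitive background", {
  cfg <- sim_config(seed = 31, n_genes = 1000, enrichment_delta = 0.5)
  gt <- gen_gene_table(cfg)
  target <- gt$gene[1:100]
  st <- gen_gene_stats(cfg, gt$gene, target)
  superset <- gt$gene[1:500]
  got <- geneset_regression(st, target, gt, control_superset = superset)
  expect_equal(got$n_genes, 500)
  full <- geneset_regression(st, target, gt)
  expect_equal(full$n_genes, 1000)
})

test_that("conditioning is an exact no-op under constructed orthogonality", {
  # members and non-members share the same LOEUF multiset, so the sample
  # covariance of membership with (LOEUF, log LOEUF) is exactly zero and
  # residualization only recentres the indicator
  d <- small_design(seed = 61, n = 16)
  lo_vals <- rep(c(0.3, 0.3, 0.9, 0.9), 4)  # pairs straddle the alternation
  loeuf <- setNames(lo_vals, d$stats$gene)  # same values in both groups
  plain <- geneset_regression(d$stats, d$set, d$cov)
  cond <- condition_on_constraint(d$stats, d$set, d$cov, loeuf)
  expect_equal(cond$beta, plain$beta, tolerance = 1e-8)
  expect_equal(cond$p_one_sided, plain$p_one_sided, tolerance = 1e-8)
})

test_that("constraint conditioning is a no-op when membership is independent of LOEUF", {
  cfg <- sim_config(seed = 32, n_genes = 1500, enrichment_delta = 0.4)
  gt <- gen_gene_table(cfg)
  target <- gt$gene[1:150]   # LOEUF independent of membership by design
  st <- gen_gene_stats(cfg, gt$gene, target)
  loeuf <- setNames(gt$loeuf, gt$gene)
  plain <- geneset_regression(st, target, gt)
  cond <- condition_on_constraint(st, target, gt, loeuf)
  # residualization changes the indicator only through its LOEUF projection;
  # with (near) orthogonality the estimates coincide closely
  expect_equal(cond$beta, plain$beta, tolerance = 0.02)
  # zero/missing LOEUF genes are dropped and counted
  loeuf2 <- loeuf
  loeuf2[1:10] <- 0
  expect_message(cond2 <- condition_on_constraint(st, target, gt, loeuf2),
                 "10 gene")
  expect_equal(cond2$n_dropped, 10)
  expect_equal(cond2$n_genes, 1490)
})

test_that("conditioning attenuates enrichment carried purely by constraint", {
  # z depends on LOEUF; the set is enriched for low LOEUF; no direct effect
  atten <- 0
  for (r in 1:60) {
    cfg <- sim_config(seed = 7000 + r, n_genes = 1200, enrichment_delta = 0)
    gt <- gen_gene_table(cfg)
    ord <- order(gt$loeuf)
    target <- gt$gene[ord[1:150]]          # most-constrained genes
    st <- gen_gene_stats(cfg, gt$gene, character())
    st$z <- st$z - 1.2 * scale(gt$loeuf)[, 1]   # LOEUF -> z pathway only
    loeuf <- setNames(gt$loeuf, gt$gene)
    p_plain <- geneset_regression(st, target, gt)$p_one_sided
    p_cond <- condition_on_constraint(st, target, gt, loeuf)$p_one_sided
    atten <- atten + (p_cond > p_plain)
  }
  expect_gt(atten / 60, 0.5)   # conditioned p attenuated in the median rep
})

test_that("BH step-up matches the hand-computed rule", {
  res <- bh_threshold(c(0.01, 0.02, 0.04, 0.9), fdr = 0.1)
  expect_equal(sum(res$significant), 3)   # 0.04 <= 3/4 * 0.1
  expect_equal(res$q, p.adjust(c(0.01, 0.02, 0.04, 0.9), "BH"))
  expect_equal(sum(bh_threshold(rep(1, 5), 0.1)$significant), 0)
  expect_true(bh_threshold(0.05, 0.1)$significant)
  expect_equal(nrow(bh_threshold(numeric(), 0.1)), 0)
})

test_that("subsample power shows a real gradient at a weak planted effect", {
  cfg <- sim_config(seed = 33, n_genes = 6000, enrichment_delta = 0.08,
                    planted_set_size = 1523)
  gt <- gen_gene_table(cfg)
  target <- gt$gene[1:1523]
  st <- gen_gene_stats(cfg, gt$gene, target)
  pw <- subsample_power(st, gt, target, sizes = c(350, 1523), n_trials = 80,
                        fdr = 0.05, rule = "nominal", seed = 4)
  expect_gt(pw$power[pw$size == 1523], pw$power[pw$size == 350] + 0.15)
  # degenerate: subsample size equal to the source set -> identical trials
  pw_full <- subsample_power(st, gt, target, sizes = 1523, n_trials = 5,
                             rule = "nominal", seed = 5)
  expect_true(pw_full$power %in% c(0, 1))
  expect_error(subsample_power(st, gt, target, sizes = 2000, n_trials = 2),
               "exceeds")
})

test_that("null subsample power stays near the nominal level", {
  cfg <- sim_config(seed = 34, n_genes = 4000, enrichment_delta = 0)
  gt <- gen_gene_table(cfg)
  source_set <- gt$gene[1:1000]
  st <- gen_gene_stats(cfg, gt$gene, character())
  pw <- subsample_power(st, gt, source_set, sizes = c(200, 500),
                        n_trials = 100, fdr = 0.05, rule = "nominal",
                        seed = 6)
  # power ~ alpha: the Wilson interval must cover 0.05 at each size
  expect_true(all(pw$lower <= 0.05 & pw$upper >= 0.05))
})
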