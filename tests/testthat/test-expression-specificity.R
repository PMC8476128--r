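test_that("tau matches its formula on uniform, one-hot and hand-computed vectors", {
  x <- matrix(c(5, 5, 5,
                0, 9, 0,
                8, 2, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("uniform", "onehot", "hand"), NULL))
  tau <- compute_tau(x, min_max_tpm = 1)
  expect_equal(unname(tau["uniform"]), 0)
  expect_equal(unname(tau["onehot"]), 1)
  expect_equal(unname(tau["hand"]), 0.875)  # (0 + 0.75 + 1) / 2
  # low-expression and all-zero genes are filtered
  low <- matrix(c(0.4, 0.2, 0.1, 0, 0, 0), 2, 3, byrow = TRUE,
                dimnames = list(c("low", "zero"), NULL))
  expect_true(all(is.na(compute_tau(low, min_max_tpm = 1))))
})

test_that("tau is scale-invariant and monotone in concentration", {
  withr::with_seed(41, {
    for (i in 1:50) {
      x <- matrix(runif(8, 0.5, 30), 1, 8)
      expect_equal(compute_tau(x)[1], compute_tau(x * runif(1, 0.1, 10))[1],
                   tolerance = 1e-12)
      # move mass from a minor tissue into the maximal tissue
      xm <- x
      j <- which.max(xm[1, ]); k <- which.min(xm[1, ])
      shift <- xm[1, k] / 2
      xm[1, k] <- xm[1, k] - shift; xm[1, j] <- xm[1, j] + shift
      expect_gte(compute_tau(xm)[1], compute_tau(x)[1] - 1e-12)
    }
  })
})

test_that("nadir detection finds the valley of a bimodal mixture and falls back", {
  withr::with_seed(42, {
    mix <- c(rbeta(600, 3, 12), rbeta(400, 22, 3))  # modes near 0.2 and 0.9
    thr <- find_tau_threshold(mix)
    expect_gt(thr, 0.3)
    expect_lt(thr, 0.8)
    expect_warning(u <- find_tau_threshold(rbeta(500, 5, 5)), "fallback")
    expect_equal(u, 0.76)
    expect_warning(cst <- find_tau_threshold(rep(0.4, 200)), "fallback")
    expect_equal(cst, 0.76)
    expect_error(find_tau_threshold(runif(50)), "at least 100")
  })
})

test_that("synthetic expression yields a detectable bimodal tau nadir", {
  cfg <- sim_config(seed = 5, n_genes = 3000, n_tissues = 30)
  gt <- gen_gene_table(cfg)
  ex <- gen_expression(cfg, gt$gene, specific_fraction = 0.4)
  tau <- compute_tau(ex$tpm)
  thr <- find_tau_threshold(tau)
  spec <- rownames(ex$tpm) %in% ex$specific_genes
  expect_gt(thr, quantile(tau[!spec], 0.95, na.rm = TRUE))
  expect_lt(thr, quantile(tau[spec], 0.05, na.rm = TRUE))
})

test_that("representative-tissue selection keeps one tissue per class", {
  cm <- data.frame(tissue = c("cortex", "cerebellum", "hippocampus",
                              "liver", "lv", "atrium"),
                   class = c("brain", "brain", "brain", "liver",
                             "heart", "heart"))
  kept <- select_representative_tissues(cm, c(brain = "cortex", heart = "lv"))
  expect_setequal(kept, c("cortex", "liver", "lv"))
  expect_error(select_representative_tissues(cm, c(brain = "liver",
                                                   heart = "lv")),
               "not in class")
  expect_error(select_representative_tissues(cm, c(brain = "cortex")),
               "no chosen representative")
})

test_that("deduplicating correlated subtypes lowers tau on a constructed example", {
  # a broadly expressed gene that is weak in one tissue class: oversampling
  # that class as three correlated subtypes inflates tau, dedup removes it
  dup <- matrix(c(10, 9, 1, 1, 1), 1, 5,
                dimnames = list("g", c("x", "y", "b1", "b2", "b3")))
  dedup <- dup[, c("x", "y", "b1"), drop = FALSE]
  expect_lte(compute_tau(dedup)[1], compute_tau(dup)[1])
})

test_that("tissue-expressed sets take the ceiling top fraction with tie-break", {
  tst <- matrix(c(5, 4, 3, 2, 1, 0, -1, -2, -3, -4), 10, 1,
                dimnames = list(sprintf("g%02d", 1:10), "t1"))
  expect_identical(tissue_expressed_sets(tst, 0.1)$t1, "g01")
  expect_length(tissue_expressed_sets(tst, 1)$t1, 10)
  expect_length(tissue_expressed_sets(tst, 0.25)$t1, 3)  # ceiling(2.5)
  # ties at the cutoff resolved by gene identifier
  tie <- matrix(c(5, 3, 3, 1), 4, 1,
                dimnames = list(c("gd", "gb", "ga", "gc"), "t1"))
  expect_identical(tissue_expressed_sets(tie, 0.5)$t1, c("ga", "gd"))
  expect_error(tissue_expressed_sets(tst, 0), "top_fraction")
  # planted tissue-specific genes are recovered in their tissue's set
  cfg <- sim_config(seed = 44, n_genes = 500, n_tissues = 12)
  gt <- gen_gene_table(cfg)
  ex <- gen_expression(cfg, gt$gene, specific_fraction = 0.1)
  tstat <- t(scale(t(log1p(ex$tpm))))  # per-gene standardized expression
  sets <- tissue_expressed_sets(tstat, 0.1)
  rec <- mean(vapply(ex$specific_genes, function(g) {
    any(vapply(sets, function(s) g %in% s, logical(1)))
  }, logical(1)))
  expect_gt(rec, 0.9)
})

test_that("landscape counts use strict thresholds over representative tissues", {
  q <- matrix(c(0.01, 0.04, 0.2, 0.5,
                0.05, 0.05, 0.05, 0.05), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), sprintf("t%d", 1:4)))
  tpm <- matrix(c(10, 6, 2, 1,
                  5, 5, 5, 5), 2, 4, byrow = TRUE,
                dimnames = dimnames(q))
  ls <- count_landscape(q, tpm)
  expect_equal(ls$n_eqtl[ls$gene == "g1"], 2)
  expect_equal(ls$n_eqtl[ls$gene == "g2"], 0)   # q = 0.05 not < 0.05
  expect_equal(ls$n_express[ls$gene == "g2"], 0) # tpm = 5 not > 5
  expect_equal(ls$n_express[ls$gene == "g1"], 2)
  sub <- count_landscape(q, tpm, tissues = c("t1", "t2"))
  expect_equal(sub$n_eqtl[sub$gene == "g1"], 2)
})

test_that("eQTL regression matches the oracle and recovers a planted effect", {
  withr::with_seed(45, {
    n <- 400
    genes <- sprintf("g%03d", 1:n)
    organelle <- genes[1:80]
    len <- setNames(rlnorm(n, 9.5, 0.8), genes)
    landscape <- data.frame(
      gene = genes,
      n_express = rbinom(n, 40, 0.6),
      tau = runif(n, 0.05, 0.95))
    beta_true <- 3
    landscape$n_eqtl <- pmax(0, round(
      2 + beta_true * (genes %in% organelle) + 0.3 * landscape$n_express -
        2 * landscape$tau + rnorm(n, 0, 2)))
    got <- eqtl_regression(landscape, organelle, len)
    X <- cbind(1, as.numeric(genes %in% organelle), landscape$n_express,
               landscape$tau, log(len), len)
    oracle <- ols_oracle(X, landscape$n_eqtl)
    expect_equal(got$beta, unname(oracle$beta[2]), tolerance = 1e-10)
    expect_equal(got$p, unname(oracle$p_two[2]), tolerance = 1e-10)
    expect_lt(abs(got$beta - beta_true), 2 * got$se + 0.5)
    # constant outcome -> zero coefficient
    landscape$n_eqtl <- 7
    flat <- eqtl_regression(landscape, organelle, len)
    expect_equal(flat$beta, 0, tolerance = 1e-8)
    expect_error(eqtl_regression(landscape, "absent", len), "empty")
  })
})

test_that("eQTL regression type-I error is controlled under a null organelle", {
  hits <- 0
  withr::with_seed(46, {
    for (r in 1:500) {
      n <- 150
      genes <- sprintf("g%03d", 1:n)
      organelle <- sample(genes, 30)
      len <- setNames(rlnorm(n, 9.5, 0.8), genes)
      landscape <- data.frame(gene = genes, n_express = rbinom(n, 30, 0.6),
                              tau = runif(n, 0.05, 0.95))
      landscape$n_eqtl <- rpois(n, 5 + 0.2 * landscape$n_express)
      hits <- hits + (eqtl_regression(landscape, organelle, len)$p < 0.05)
    }
  })
  expect_lte(hits / 500, 0.07)
})
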