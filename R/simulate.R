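#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data module. All generators are pure
#' functions of a `sim_config` (plus their explicit arguments): calling a
#' generator twice with the same configuration yields byte-identical output,
#' and the global RNG stream is left untouched.
#'
#' @param seed integer seed driving every generator.
#' @param n_genes number of genes in the universe (default 18000, the order
#'   of the protein-coding genome).
#' @param n_traits number of traits.
#' @param n_tissues number of tissues in the expression matrix.
#' @param n_samples number of individuals for genotype/phenotype tables.
#' @param planted_set_size size of the planted gene-set.
#' @param enrichment_delta standardized mean shift of gene Z inside the
#'   planted set.
#' @param mt_effect per-allele effect of the planted mtDNA variant, in
#'   phenotype standard-deviation units.
#' @param latent_corr target trait correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite). Defaults to a 2-trait identity.
#' @param case_fraction case proportion used when dichotomizing liabilities.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 18000L, n_traits = 20L,
                       n_tissues = 40L, n_samples = 5000L,
                       planted_set_size = 1523L, enrichment_delta = 0.3,
                       mt_effect = 0.3, latent_corr = NULL,
                       case_fraction = 0.25) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1)
    stop("invalid config: n_genes must be a positive count")
  if (n_traits < 1 || n_tissues < 1 || n_samples < 1)
    stop("invalid config: counts must be positive")
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("invalid config: case_fraction must lie in (0,1)")
  if (is.null(latent_corr)) latent_corr <- diag(2)
  check_corr_matrix(latent_corr)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_traits = as.integer(n_traits),
                 n_tissues = as.integer(n_tissues),
                 n_samples = as.integer(n_samples),
                 planted_set_size = as.integer(planted_set_size),
                 enrichment_delta = enrichment_delta, mt_effect = mt_effect,
                 latent_corr = latent_corr, case_fraction = case_fraction),
            class = "sim_config")
}

check_corr_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("invalid config: latent_corr must be square")
  if (max(abs(m - t(m))) > 1e-8)
    stop("invalid config: latent_corr must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8)
    stop("invalid config: latent_corr must have unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("invalid config: latent_corr must be positive semi-definite")
  invisible(m)
}

# Every generator mixes the config seed with a fixed per-generator offset so
# tables are independent of one another but jointly reproducible.
sim_seed <- function(cfg, offset) (cfg$seed %% 2000000000L) + offset

#' Generate the synthetic gene universe
#'
#' Gene identifiers plus the per-gene technical covariates used by the
#' competitive enrichment layer: gene length (log-normal, bp), SNP density
#' (SNPs per kb), inverse minor allele count in (0,1], LOEUF constraint in
#' (0,2], and an ordered age phylostratum in 1..19.
#'
#' @param cfg a [sim_config()].
#' @return `data.frame` with columns `gene`, `length_bp`, `snp_density`,
#'   `inv_mac`, `loeuf`, `phylostratum`.
#' @export
gen_gene_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 10) stop("invalid config: n_genes must be >= 10")
  n <- cfg$n_genes
  withr::with_seed(sim_seed(cfg, 101L), {
    # LOEUF sampled from a log-normal truncated to (0, 2] by inverse CDF
    lo_cap <- stats::plnorm(2, meanlog = log(0.9), sdlog = 0.45)
    data.frame(
      gene = sprintf("G%05d", seq_len(n)),
      length_bp = stats::rlnorm(n, meanlog = log(20000), sdlog = 1.0),
      snp_density = stats::rgamma(n, shape = 4, rate = 0.8),
      inv_mac = stats::rbeta(n, 0.8, 4) * 0.999 + 0.001,
      loeuf = stats::qlnorm(stats::runif(n, 0, lo_cap),
                            meanlog = log(0.9), sdlog = 0.45),
      phylostratum = sample.int(19L, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate localization confidence scores with planted memberships
#'
#' Emulates an integrated localization-evidence resource: each (gene,
#' compartment) pair carries an integer confidence score from 0 (no
#' evidence) to 5 (strongest). Planted members of a compartment receive
#' scores in \{3,4,5\}; all other pairs score in \{0,1,2\}, so a downstream
#' `score > 2` filter recovers the planted sets exactly.
#'
#' @param cfg a [sim_config()].
#' @param genes character vector, the gene universe.
#' @param compartments character vector of compartment names.
#' @param planted named list mapping compartment name to its planted member
#'   genes (subsets of `genes`).
#' @return long `data.frame` with columns `gene`, `compartment`, `score`.
#' @export
gen_localization <- function(cfg, genes, compartments, planted = list()) {
  stopifnot(inherits(cfg, "sim_config"))
  for (cmp in names(planted)) {
    if (!cmp %in% compartments) stop("unknown compartment in planted map: ", cmp)
    missing <- setdiff(planted[[cmp]], genes)
    if (length(missing))
      stop("unknown gene(s) planted in ", cmp, ": ",
           paste(utils::head(missing, 3), collapse = ", "))
  }
  withr::with_seed(sim_seed(cfg, 102L), {
    df <- expand.grid(gene = genes, compartment = compartments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$score <- sample(0:2, nrow(df), replace = TRUE)
    # one high score per planted gene, shared across all its planted
    # compartments, so the downstream max-score rule recovers every
    # planted membership exactly (ties assign to all)
    planted_genes <- unique(unlist(planted))
    high <- stats::setNames(sample(3:5, length(planted_genes),
                                   replace = TRUE), planted_genes)
    for (cmp in names(planted)) {
      idx <- df$compartment == cmp & df$gene %in% planted[[cmp]]
      df$score[idx] <- high[df$gene[idx]]
    }
    df
  })
}

#' Generate gene-level association Z statistics with a planted enrichment
#'
#' Genes outside `target_set` draw Z from a standard normal; genes inside
#' draw from N(`enrichment_delta`, 1). An optional linear leakage of Z onto
#' standardized log gene length models confounding by gene size. The p-value
#' is the upper-tail normal probability of Z.
#'
#' @param cfg a [sim_config()]; `cfg$enrichment_delta` is the planted shift.
#' @param genes gene universe.
#' @param target_set genes carrying the planted shift (subset of `genes`).
#' @param trait trait label attached to the output.
#' @param length_slope slope of Z on standardized log length (default 0).
#' @param length_bp gene lengths, required when `length_slope != 0`.
#' @return `data.frame` with columns `gene`, `trait`, `z`, `p`.
#' @export
gen_gene_stats <- function(cfg, genes, target_set = character(),
                           trait = "trait1", length_slope = 0,
                           length_bp = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  missing <- setdiff(target_set, genes)
  if (length(missing)) stop("target_set contains genes outside the universe")
  withr::with_seed(sim_seed(cfg, 103L), {
    z <- stats::rnorm(length(genes))
    z[genes %in% target_set] <- z[genes %in% target_set] + cfg$enrichment_delta
    if (length_slope != 0) {
      if (is.null(length_bp)) stop("length_bp required when length_slope != 0")
      z <- z + length_slope * as.numeric(scale(log(length_bp)))
    }
    data.frame(gene = genes, trait = trait, z = z,
               p = stats::pnorm(z, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
}

#' Generate a trait-to-gene association catalog with planted enrichment odds
#'
#' Each trait's associated genes are sampled gene-by-gene; genes in
#' `target_set` have their inclusion odds multiplied by that trait's
#' `odds_multiplier`. Every emitted association carries a genome-wide
#' significant p-value (p < 5e-8), matching a lead-SNP-mapped catalog.
#'
#' @param cfg a [sim_config()].
#' @param genes gene universe.
#' @param target_set planted gene-set.
#' @param odds_multiplier positive numeric, one per trait (recycled).
#' @param n_assoc expected number of associated genes per trait (recycled).
#' @return `data.frame` with columns `trait`, `gene`, `assoc_p`.
#' @export
gen_trait_catalog <- function(cfg, genes, target_set = character(),
                              odds_multiplier = 1, n_assoc = 100) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(odds_multiplier <= 0)) stop("odds_multiplier must be > 0")
  n_traits <- cfg$n_traits
  odds_multiplier <- rep_len(odds_multiplier, n_traits)
  n_assoc <- rep_len(n_assoc, n_traits)
  in_set <- genes %in% target_set
  withr::with_seed(sim_seed(cfg, 104L), {
    out <- vector("list", n_traits)
    for (t in seq_len(n_traits)) {
      p0 <- min(n_assoc[t] / length(genes), 0.99)
      odds <- p0 / (1 - p0)
      p_in <- (odds * odds_multiplier[t]) / (1 + odds * odds_multiplier[t])
      prob <- ifelse(in_set, p_in, p0)
      hit <- stats::runif(length(genes)) < prob
      g <- genes[hit]
      if (length(g))
        out[[t]] <- data.frame(trait = sprintf("trait%02d", t), gene = g,
                               assoc_p = stats::runif(length(g), 0, 5e-8),
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Generate a gene-by-tissue median TPM matrix with tissue classes
#'
#' A `specific_fraction` of genes concentrate expression in one randomly
#' chosen tissue class (tau near 1); the rest are broadly expressed with
#' mild log-normal noise (tau near 0), so the tau histogram is bimodal.
#' Tissues are grouped into classes; tissues within a class share the
#' class-level signal (correlated subtypes), the feature that motivates
#' representative-tissue deduplication.
#'
#' @param cfg a [sim_config()].
#' @param genes gene universe (or any identifier vector).
#' @param specific_fraction fraction of genes made tissue-specific, in [0,1].
#' @param n_classes number of tissue classes; classes are assigned
#'   round-robin so some classes contain several correlated subtypes.
#' @return list with `tpm` (genes x tissues matrix), `class_map`
#'   (`data.frame(tissue, class)`), and `specific_genes`.
#' @export
gen_expression <- function(cfg, genes, specific_fraction = 0.3,
                           n_classes = max(2L, cfg$n_tissues %/% 3L)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (specific_fraction < 0 || specific_fraction > 1)
    stop("invalid config: specific_fraction must lie in [0,1]")
  n_t <- cfg$n_tissues
  tissues <- sprintf("tissue%02d", seq_len(n_t))
  classes <- sprintf("class%02d", rep_len(seq_len(n_classes), n_t))
  withr::with_seed(sim_seed(cfg, 105L), {
    n_g <- length(genes)
    n_spec <- round(specific_fraction * n_g)
    spec_idx <- if (n_spec > 0) sample.int(n_g, n_spec) else integer()
    base <- stats::rlnorm(n_g, meanlog = log(20), sdlog = 0.8)
    class_of <- match(classes, unique(classes))
    # class-level noise is shared by subtype tissues, making subtypes of a
    # class more correlated with one another than with other tissues
    class_noise <- matrix(stats::rlnorm(n_g * n_classes, 0, 0.15),
                          n_g, n_classes)
    tpm <- base * class_noise[, class_of, drop = FALSE] *
      matrix(stats::rlnorm(n_g * n_t, 0, 0.08), n_g, n_t)
    dimnames(tpm) <- list(genes, tissues)
    home_class <- sample.int(n_classes, n_spec, replace = TRUE)
    for (k in seq_along(spec_idx)) {
      g <- spec_idx[k]
      off <- class_of != home_class[k]
      tpm[g, off] <- tpm[g, off] * 0.005
    }
    list(tpm = tpm,
         class_map = data.frame(tissue = tissues, class = classes,
                                stringsAsFactors = FALSE),
         specific_genes = genes[sort(spec_idx)])
  })
}

#' Generate haploid mtDNA genotypes with covariates and phenotypes
#'
#' Haploid calls in \{0,1,NA\}; per-variant alternate-carrier counts follow a
#' log-uniform spectrum between `min_carriers_sim` and 10% of the cohort.
#' Samples split into two array batches with batch-specific
#' missing-completely-at-random call rates. The continuous phenotype is a
#' linear predictor over the covariates plus `mt_effect` times the planted
#' variant's genotype plus unit-variance noise; the binary phenotype
#' dichotomizes the same liability at the configured case fraction.
#' Covariates: 20 synthetic nuclear PCs, sex, age.
#'
#' @param cfg a [sim_config()]; `cfg$mt_effect` is the planted effect.
#' @param n_variants number of mtDNA variants.
#' @param planted_variant name of the effect-carrying variant, or `NULL`
#'   for a fully null dataset.
#' @param missing_rate length-2 missing-call rate for the two batches.
#' @param min_carriers_sim lower end of the simulated carrier-count spectrum.
#' @return list with `geno` (samples x variants 0/1/NA matrix), `batch`,
#'   `pheno` (`data.frame` incl. `y_cont`, `y_bin`, covariates), and
#'   `variants` (`data.frame(variant, position, carriers)`).
#' @export
gen_mt_data <- function(cfg, n_variants = 100L, planted_variant = "MT0001",
                        missing_rate = c(0.01, 0.02),
                        min_carriers_sim = 20L) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples
  variants <- sprintf("MT%04d", seq_len(n_variants))
  if (!is.null(planted_variant) && !planted_variant %in% variants)
    stop("unknown variant: ", planted_variant)
  withr::with_seed(sim_seed(cfg, 106L), {
    positions <- sort(sample.int(16569L, n_variants))
    carriers <- round(exp(stats::runif(n_variants, log(min_carriers_sim),
                                       log(max(min_carriers_sim + 1, 0.1 * n)))))
    geno <- matrix(0L, n, n_variants,
                   dimnames = list(sprintf("S%05d", seq_len(n)), variants))
    for (v in seq_len(n_variants))
      geno[sample.int(n, carriers[v]), v] <- 1L
    batch <- rep(c("axiom", "bileve"), length.out = n)
    pcs <- matrix(stats::rnorm(n * 20), n, 20,
                  dimnames = list(NULL, sprintf("PC%d", 1:20)))
    sex <- stats::rbinom(n, 1, 0.5)
    age <- stats::runif(n, 40, 70)
    lin <- pcs %*% stats::rnorm(20, 0, 0.05) + 0.1 * sex +
      0.01 * (age - 55)
    g_eff <- if (is.null(planted_variant)) 0 else
      cfg$mt_effect * geno[, planted_variant]
    liab <- drop(lin) + g_eff + stats::rnorm(n)
    y_bin <- as.integer(liab > stats::quantile(liab, 1 - cfg$case_fraction))
    # mask calls after phenotypes so the planted effect is on true genotype
    for (b in 1:2) {
      rows <- which(batch == c("axiom", "bileve")[b])
      mask <- matrix(stats::runif(length(rows) * n_variants) < missing_rate[b],
                     length(rows), n_variants)
      geno[rows, ][mask] <- NA_integer_
    }
    list(geno = geno, batch = batch,
         pheno = data.frame(sample = rownames(geno), y_cont = liab,
                            y_bin = y_bin, sex = sex, age = age, pcs,
                            stringsAsFactors = FALSE),
         variants = data.frame(variant = variants, position = positions,
                               carriers = carriers,
                               stringsAsFactors = FALSE))
  })
}

#' Generate correlated phenotypes under a latent-normal model
#'
#' Traits are drawn from a multivariate normal with correlation
#' `cfg$latent_corr`; traits named in `binary_traits` are dichotomized at
#' the matching latent `thresholds` (liability-threshold model), yielding
#' the data-generating process assumed by tetrachoric/biserial estimators.
#'
#' @param cfg a [sim_config()] whose `latent_corr` sets the trait count.
#' @param binary_traits indices (or names `trait<k>`) of traits to
#'   dichotomize.
#' @param thresholds latent threshold per binary trait (recycled).
#' @return `data.frame` with `sample` plus one column per trait; attribute
#'   `"types"` maps trait name to `"continuous"`/`"binary"`.
#' @export
gen_phenotypes <- function(cfg, binary_traits = integer(), thresholds = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  R <- cfg$latent_corr
  check_corr_matrix(R)
  k <- nrow(R)
  n <- cfg$n_samples
  if (is.character(binary_traits))
    binary_traits <- match(binary_traits, sprintf("trait%d", seq_len(k)))
  thresholds <- rep_len(thresholds, length(binary_traits))
  withr::with_seed(sim_seed(cfg, 107L), {
    ev <- eigen(R, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
    lat <- matrix(stats::rnorm(n * k), n, k) %*% t(L)
    colnames(lat) <- sprintf("trait%d", seq_len(k))
    out <- as.data.frame(lat)
    types <- rep("continuous", k)
    names(types) <- colnames(lat)
    for (j in seq_along(binary_traits)) {
      tr <- binary_traits[j]
      out[[tr]] <- as.numeric(lat[, tr] > thresholds[j])
      types[tr] <- "binary"
    }
    out <- cbind(sample = sprintf("S%05d", seq_len(n)), out)
    attr(out, "types") <- types
    out
  })
}

#' Overwrite LOEUF with compartment-shifted distributions
#'
#' Applies multiplicative (log-scale) shifts to the LOEUF of each
#' compartment's member genes, so planted differences in constraint are
#' recoverable by the decile summaries while values stay positive.
#'
#' @param cfg a [sim_config()].
#' @param gene_table output of [gen_gene_table()].
#' @param compartment_sets named list of gene-sets.
#' @param shifts named numeric, log-scale shift per compartment (negative =
#'   more constrained).
#' @return `gene_table` with an updated `loeuf` column.
#' @export
gen_loeuf <- function(cfg, gene_table, compartment_sets, shifts) {
  stopifnot(inherits(cfg, "sim_config"))
  stopifnot(all(names(shifts) %in% names(compartment_sets)))
  lo <- gene_table$loeuf
  for (cmp in names(shifts)) {
    idx <- gene_table$gene %in% compartment_sets[[cmp]]
    lo[idx] <- lo[idx] * exp(shifts[[cmp]])
  }
  gene_table$loeuf <- lo
  gene_table
}
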