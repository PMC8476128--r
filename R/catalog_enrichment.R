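#' Per-trait associated gene-sets from an association catalog
#'
#' For each trait, collects the unique genes with at least one association
#' below `p_threshold`, then drops traits that do not exceed `min_genes`
#' associated genes (strict `>`), the filter used to admit catalog traits
#' into the enrichment screen.
#'
#' @param catalog `data.frame` with columns `trait`, `gene`, `assoc_p`.
#' @param p_threshold genome-wide significance cutoff (default 5e-8,
#'   strict `<`).
#' @param min_genes minimum associated-gene count, strict `>` (default 30).
#' @return named list mapping trait to its associated gene vector.
#' @export
trait_gene_sets <- function(catalog, p_threshold = 5e-8, min_genes = 30) {
  stopifnot(all(c("trait", "gene", "assoc_p") %in% names(catalog)))
  hit <- catalog[catalog$assoc_p < p_threshold, , drop = FALSE]
  sets <- lapply(split(hit$gene, hit$trait), function(g) sort(unique(g)))
  sets[vapply(sets, length, integer(1)) > min_genes]
}

#' Fisher enrichment/depletion screen of a target set across traits
#'
#' For each trait, a 2x2 table crossing target-set membership with
#' trait-association over the gene universe is tested by a two-sided
#' Fisher's exact test (p = sum of hypergeometric point probabilities no
#' larger than the observed table's). The sample odds ratio `ad/bc` gives
#' the direction; Benjamini-Hochberg correction is applied across the
#' tested traits and the verdict is `enriched`/`depleted` when `q < fdr`,
#' else `null`.
#'
#' @param trait_sets named list of per-trait gene vectors (see
#'   [trait_gene_sets()]).
#' @param target character vector, the gene-set screened for enrichment.
#' @param universe character vector, the protein-coding background.
#' @param fdr BH false-discovery-rate threshold (default 0.1).
#' @param or `"sample"` (default, `ad/bc`) or `"cmle"` (conditional MLE as
#'   returned by [stats::fisher.test()]).
#' @return `data.frame` with columns `trait`, `a`, `b`, `c`, `d`, `or`,
#'   `p`, `q`, `verdict`.
#' @export
fisher_screen <- function(trait_sets, target, universe, fdr = 0.1,
                          or = c("sample", "cmle")) {
  or <- match.arg(or)
  target <- unique(target)
  if (length(setdiff(target, universe)))
    stop("target contains genes outside the universe")
  n_univ <- length(universe)
  n_target <- length(target)
  rows <- list()
  for (tr in names(trait_sets)) {
    genes <- intersect(unique(trait_sets[[tr]]), universe)
    if (length(genes) == 0) {
      warning("trait ", tr, " has an empty gene set after filtering; skipped")
      next
    }
    a <- length(intersect(genes, target))
    b <- n_target - a
    c_ <- length(genes) - a
    d <- n_univ - a - b - c_
    if (b == 0 && d == 0) {
      # target == universe: membership margin degenerate
      rows[[tr]] <- data.frame(trait = tr, a = a, b = b, c = c_, d = d,
                               or = NA_real_, p = 1, stringsAsFactors = FALSE)
      next
    }
    tab <- matrix(c(a, b, c_, d), 2, 2)
    ft <- stats::fisher.test(tab)
    this_or <- if (or == "sample") (a * d) / (b * c_) else
      unname(ft$estimate)
    rows[[tr]] <- data.frame(trait = tr, a = a, b = b, c = c_, d = d,
                             or = this_or, p = ft$p.value,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(trait = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), or = numeric(),
                      p = numeric(), q = numeric(), verdict = character()))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$verdict <- ifelse(is.na(out$or) | out$q >= fdr, "null",
                        ifelse(out$or > 1, "enriched", "depleted"))
  rownames(out) <- NULL
  out
}

# number of traits whose 2x2 sample odds ratio exceeds 1 (strictly) for a
# membership indicator over the universe; `p05` additionally requires the
# two-sided Fisher p < 0.05
count_nominal_enrich <- function(trait_mat, trait_sizes, member,
                                 nominal = "or") {
  a <- as.integer(crossprod(trait_mat, member))
  m <- sum(member)
  n <- nrow(trait_mat)
  b <- m - a
  c_ <- trait_sizes - a
  d <- n - m - c_
  orv <- (a * d) / (b * c_)
  enr <- !is.na(orv) & orv > 1
  if (nominal == "p05") {
    for (j in which(enr)) {
      p <- stats::fisher.test(matrix(c(a[j], b[j], c_[j], d[j]), 2, 2))$p.value
      if (p >= 0.05) enr[j] <- FALSE
    }
  }
  sum(enr)
}

#' Empirical null for the enrichment count statistic
#'
#' The test statistic is the number of traits showing a nominal (not
#' necessarily significant) enrichment of the target set — odds ratio
#' strictly above 1. Its null distribution is built by drawing `n_samples`
#' uniform same-size gene samples from the universe without replacement and
#' recomputing the count for each. The one-sided empirical p-value asks
#' whether the target is nominally enriched in *fewer* traits than random
#' sets, `Pr(N_null <= N_obs)`, estimated with an add-one pseudo-count.
#'
#' @param trait_sets named list of per-trait gene vectors.
#' @param target target gene-set.
#' @param universe background gene universe.
#' @param n_samples number of null samples (default 1000).
#' @param seed RNG seed for the null draws.
#' @param nominal `"or"` (default, odds ratio > 1) or `"p05"` (odds ratio
#'   > 1 and Fisher p < 0.05).
#' @param add_one use the add-one estimator `(1 + #{null <= obs})/(1 + S)`
#'   (default); `FALSE` gives the plain proportion.
#' @return list with `n_enrich`, integer vector `null_counts`, and `emp_p`.
#' @export
enrichment_count_null <- function(trait_sets, target, universe,
                                  n_samples = 1000, seed = 1,
                                  nominal = c("or", "p05"),
                                  add_one = TRUE) {
  nominal <- match.arg(nominal)
  if (n_samples < 1) stop("invalid n_samples")
  target <- unique(target)
  if (length(target) > length(universe))
    stop("target larger than universe")
  trait_mat <- vapply(trait_sets,
                      function(g) universe %in% g, logical(length(universe)))
  trait_mat <- matrix(as.numeric(trait_mat), nrow = length(universe))
  trait_sizes <- colSums(trait_mat)
  member <- as.numeric(universe %in% target)
  n_obs <- count_nominal_enrich(trait_mat, trait_sizes, member, nominal)
  m <- sum(member)
  null_counts <- withr::with_seed(as.integer(seed) %% 2000000000L, {
    if (nominal == "or") {
      # all null samples at once: one indicator matrix, one crossproduct
      S <- vapply(seq_len(n_samples), function(i) {
        s <- numeric(length(universe))
        s[sample.int(length(universe), m)] <- 1
        s
      }, numeric(length(universe)))
      A <- crossprod(trait_mat, S)            # traits x samples overlap
      B <- m - A
      C <- trait_sizes - A
      D <- length(universe) - m - C
      colSums(A * D > B * C, na.rm = TRUE)
    } else {
      vapply(seq_len(n_samples), function(i) {
        s <- numeric(length(universe))
        s[sample.int(length(universe), m)] <- 1
        count_nominal_enrich(trait_mat, trait_sizes, s, nominal)
      }, numeric(1))
    }
  })
  emp_p <- if (add_one) (1 + sum(null_counts <= n_obs)) / (1 + n_samples)
           else mean(null_counts <= n_obs)
  list(n_enrich = n_obs, null_counts = as.integer(null_counts),
       emp_p = emp_p)
}
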