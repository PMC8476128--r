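#' Lowest-LOEUF-decile proportion of a gene-set
#'
#' Decile boundaries are the 10%..90% empirical quantiles (type-1, lower)
#' of LOEUF over the *full* gene table; the statistic is the proportion of
#' set members at or below the first-decile boundary, with a Wilson 95%
#' interval. Higher values mean the set contains more highly constrained
#' genes.
#'
#' @param set character vector of member genes.
#' @param table `data.frame` with columns `gene`, `loeuf` (one row per
#'   gene, LOEUF > 0).
#' @return list with `proportion`, `lower`, `upper`, `n_set`, `boundary`.
#' @export
decile_proportion <- function(set, table) {
  stopifnot(all(c("gene", "loeuf") %in% names(table)))
  if (any(table$loeuf <= 0)) stop("LOEUF values must be positive")
  lo <- table$loeuf[table$gene %in% set]
  if (length(lo) == 0) stop("gene-set does not intersect the table")
  boundary <- stats::quantile(table$loeuf, 0.1, type = 1, names = FALSE)
  k <- sum(lo <= boundary)
  ci <- wilson_ci(k, length(lo))
  list(proportion = unname(ci["estimate"]), lower = unname(ci["lower"]),
       upper = unname(ci["upper"]), n_set = length(lo),
       boundary = boundary)
}

#' Decile boundaries of the constraint distribution
#'
#' @param table constraint `data.frame` (`gene`, `loeuf`).
#' @return numeric vector of the 9 interior decile boundaries.
#' @export
loeuf_decile_boundaries <- function(table) {
  stats::quantile(table$loeuf, seq(0.1, 0.9, by = 0.1), type = 1,
                  names = FALSE)
}

#' Mean LOEUF of a gene-set with a bootstrap interval
#'
#' Set-restricted mean with a seeded percentile bootstrap 95% CI
#' (default 2000 resamples). Sets with fewer than 2 members return the
#' point estimate only.
#'
#' @inheritParams decile_proportion
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return list with `mean`, `lower`, `upper` (NA when `|set| < 2`),
#'   `n_set`.
#' @export
distribution_summary <- function(set, table, n_boot = 2000, seed = 1) {
  stopifnot(all(c("gene", "loeuf") %in% names(table)))
  lo <- table$loeuf[table$gene %in% set]
  if (length(lo) == 0) stop("gene-set does not intersect the table")
  m <- mean(lo)
  if (length(lo) < 2)
    return(list(mean = m, lower = NA_real_, upper = NA_real_,
                n_set = length(lo)))
  boots <- withr::with_seed(as.integer(seed) %% 2000000000L, {
    vapply(seq_len(n_boot),
           function(i) mean(lo[sample.int(length(lo), replace = TRUE)]),
           numeric(1))
  })
  qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  list(mean = m, lower = qs[1], upper = qs[2], n_set = length(lo))
}
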