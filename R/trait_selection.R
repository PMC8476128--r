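#' Rank age-related diseases by late-life period prevalence
#'
#' Diseases with median onset above `onset_min` are scored by the sum of
#' their period prevalence over age bands whose lower bound is at least
#' `age_min`, and ranked in descending score order. Ties are broken
#' lexicographically by disease identifier for determinism.
#'
#' @param tbl long `data.frame` with columns `disease`, `median_onset`,
#'   `band_lower` (lower bound of the age band, years) and `prevalence`
#'   (proportion in [0,1]).
#' @param onset_min minimum median onset, years; strict `>` (default 50).
#' @param age_min minimum age-band lower bound included in the score
#'   (default 50, inclusive `>=`).
#' @param top_k number of diseases to return (default all).
#' @return `data.frame` with columns `disease`, `score`, ordered.
#' @export
rank_age_related <- function(tbl, onset_min = 50, age_min = 50,
                             top_k = Inf) {
  need <- c("disease", "median_onset", "band_lower", "prevalence")
  stopifnot(all(need %in% names(tbl)))
  if (nrow(tbl) == 0)
    return(data.frame(disease = character(), score = numeric()))
  if (any(tbl$prevalence < 0 | tbl$prevalence > 1))
    stop("prevalence values must lie in [0,1]")
  keep_band <- tbl$band_lower >= age_min
  score <- tapply(tbl$prevalence * keep_band, tbl$disease, sum)
  onset <- tapply(tbl$median_onset, tbl$disease, function(x) x[1])
  dis <- names(score)
  ok <- onset > onset_min
  out <- data.frame(disease = dis[ok], score = as.numeric(score[ok]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$disease), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Filter traits by SNP-heritability Z-score
#'
#' Retains records whose heritability Z-score, `h2 / se`, strictly exceeds
#' `z_min` — the evidence filter used to admit traits into the genetic
#' correlation and enrichment analyses.
#'
#' @param records `data.frame` with columns `trait`, `h2`, `se` (and
#'   optionally `cohort`).
#' @param z_min Z threshold, strict `>` (default 4).
#' @return the retained rows, with a `z` column appended.
#' @export
heritability_filter <- function(records, z_min = 4) {
  stopifnot(all(c("trait", "h2", "se") %in% names(records)))
  if (any(!is.finite(records$se) | records$se <= 0))
    stop("invalid record: se must be positive")
  records$z <- records$h2 / records$se
  out <- records[records$z > z_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}
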