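#' Build organellar gene-sets from localization confidence scores
#'
#' Per gene, localization assignments with score strictly greater than
#' `min_score` (on the integer 0--5 evidence scale) are kept; among those,
#' the gene is assigned to every compartment achieving its maximal score
#' (ties give multiple assignments). Compartments with no more than
#' `min_size` members are dropped. When `mitocarta` is supplied, the
#' mitochondrion set is replaced by that curated list before the size
#' filter is applied.
#'
#' @param scores long `data.frame` with columns `gene`, `compartment`,
#'   `score` (integers in 0--5, one row per pair).
#' @param min_score keep assignments with score strictly above this
#'   (default 2).
#' @param min_size drop compartments with `<=` this many members
#'   (default 240; i.e. "over 240" is strict).
#' @param mitocarta optional character vector overriding the mitochondrion
#'   set; `mito_name` names the compartment it replaces.
#' @param mito_name compartment name the override applies to.
#' @return named list of character vectors (one gene-set per compartment).
#' @export
assign_compartments <- function(scores, min_score = 2, min_size = 240,
                                mitocarta = NULL,
                                mito_name = "mitochondrion") {
  stopifnot(all(c("gene", "compartment", "score") %in% names(scores)))
  if (any(scores$score != round(scores$score)) ||
      any(scores$score < 0 | scores$score > 5))
    stop("scores must be integers in [0,5]")
  if (anyDuplicated(paste(scores$gene, scores$compartment, sep = "\r")))
    stop("duplicate (gene, compartment) score rows")
  kept <- scores[scores$score > min_score, , drop = FALSE]
  sets <- list()
  if (nrow(kept)) {
    top <- stats::ave(kept$score, kept$gene, FUN = max)
    kept <- kept[kept$score == top, , drop = FALSE]
    sets <- lapply(split(kept$gene, kept$compartment),
                   function(g) sort(unique(g)))
  }
  if (!is.null(mitocarta)) sets <- mito_override(sets, mitocarta, mito_name)
  sets <- sets[vapply(sets, length, integer(1)) > min_size]
  if (length(sets)) sets <- sets[order(names(sets))]
  sets
}

#' Replace the mitochondrion set with a curated inventory
#'
#' The score-derived mitochondrion set is replaced exactly by the supplied
#' curated list (e.g. a MitoCarta-style inventory of nuclear-encoded
#' mitochondrial genes).
#'
#' @param sets named list of gene-sets.
#' @param mitocarta character vector of curated member genes.
#' @param mito_name name of the compartment to replace.
#' @return updated list of gene-sets.
#' @export
mito_override <- function(sets, mitocarta, mito_name = "mitochondrion") {
  sets[[mito_name]] <- sort(unique(as.character(mitocarta)))
  sets
}

#' Build nuclear sub-compartment gene-sets
#'
#' From sub-compartment localization scores restricted to nucleus-localizing
#' genes, emits: `nucleoplasm` (with genes also assigned to any other
#' nuclear subset removed), `chromosome_tf` (the union of chromosome-assigned
#' genes and a curated transcription-factor list), `nucleolus`,
#' `nuclear_envelope`, and `other_nucleus` (nucleus members assigned to none
#' of the four).
#'
#' @param nuclear_scores long score `data.frame` over the sub-compartments
#'   `nucleoplasm`, `chromosome`, `nucleolus`, `nuclear_envelope`.
#' @param nucleus_members genes localizing to the nucleus.
#' @param tf_list curated transcription-factor genes, merged into the
#'   chromosome category.
#' @param universe the gene universe; TFs outside it are skipped with a
#'   warning.
#' @param min_score score filter passed through (default 2).
#' @return named list of gene-sets.
#' @export
build_nuclear_subsets <- function(nuclear_scores, nucleus_members, tf_list,
                                  universe = nucleus_members,
                                  min_score = 2) {
  sub <- assign_compartments(nuclear_scores, min_score = min_score,
                             min_size = 0)
  get <- function(nm) if (is.null(sub[[nm]])) character() else sub[[nm]]
  bad_tf <- setdiff(tf_list, universe)
  if (length(bad_tf)) {
    warning("skipping ", length(bad_tf), " TF gene(s) absent from universe")
    tf_list <- intersect(tf_list, universe)
  }
  chromosome_tf <- sort(unique(c(get("chromosome"), tf_list)))
  nucleolus <- get("nucleolus")
  envelope <- get("nuclear_envelope")
  nucleoplasm <- setdiff(get("nucleoplasm"),
                         c(chromosome_tf, nucleolus, envelope))
  assigned <- unique(c(nucleoplasm, chromosome_tf, nucleolus, envelope))
  other <- sort(setdiff(nucleus_members, assigned))
  list(nucleoplasm = sort(nucleoplasm), chromosome_tf = chromosome_tf,
       nucleolus = sort(nucleolus), nuclear_envelope = sort(envelope),
       other_nucleus = other)
}

#' Partition transcription factors into functional subsets
#'
#' Emits three partitions of a TF list: (i) tissue-specific
#' (`tau >= tau_threshold`) versus broadly expressed, TFs without a tau
#' value (filtered for low expression) excluded from this partition only;
#' (ii) age terciles by phylostratum rank (stable rank, sizes differing by
#' at most one, tercile 1 = evolutionarily oldest); (iii) DNA-binding-domain
#' groups: KRAB zinc fingers, non-KRAB zinc fingers, and all other domains.
#'
#' @param tf_list character vector of TF genes.
#' @param tau named numeric of tissue-specificity values; may be `NA` or
#'   missing for low-expression TFs.
#' @param tau_threshold tissue-specific cutoff, inclusive (default 0.76).
#' @param age_stratum named integer phylostratum (1--19, 1 = oldest).
#' @param dbd named character DNA-binding-domain label; values containing
#'   `"KRAB"` form the KRAB zinc-finger group, other values containing
#'   `"ZF"` or `"zinc"` the non-KRAB zinc-finger group.
#' @return named list of gene-sets: `tf_tissue_specific`, `tf_broad`,
#'   `tf_age_tercile1..3`, `tf_krab_zf`, `tf_other_zf`, `tf_non_zf`.
#' @export
partition_tfs <- function(tf_list, tau, tau_threshold = 0.76,
                          age_stratum, dbd) {
  tf_list <- unique(as.character(tf_list))
  tv <- tau[tf_list]
  has_tau <- !is.na(tv)
  spec <- tf_list[has_tau & tv >= tau_threshold]
  broad <- tf_list[has_tau & tv < tau_threshold]

  st <- age_stratum[tf_list]
  ord <- order(st, seq_along(tf_list))  # stable: ties keep input order
  n <- length(tf_list)
  sizes <- rep(n %/% 3L, 3L)
  extra <- n %% 3L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  tercile <- rep(1:3, times = sizes)
  terc_sets <- split(tf_list[ord], tercile)

  db <- dbd[tf_list]
  is_krab <- grepl("KRAB", db, ignore.case = TRUE)
  is_zf <- !is_krab & grepl("ZF|zinc", db, ignore.case = TRUE)
  list(tf_tissue_specific = sort(spec), tf_broad = sort(broad),
       tf_age_tercile1 = sort(terc_sets[["1"]]),
       tf_age_tercile2 = sort(terc_sets[["2"]]),
       tf_age_tercile3 = sort(terc_sets[["3"]]),
       tf_krab_zf = sort(tf_list[is_krab]),
       tf_other_zf = sort(tf_list[is_zf]),
       tf_non_zf = sort(tf_list[!is_krab & !is_zf]))
}
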