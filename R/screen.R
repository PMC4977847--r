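# Screening cascade, per-miRNA target ranking and the three-level
# validation harness.

#' Screening threshold profile
#'
#' Bundles the filter cascade thresholds. The `"plant"` profile adds the
#' structural caps used for plant-genome screening (internal loops at most
#' 5 nt per side, bulges at most 9 nt); the `"human"` profile leaves the
#' structure uncapped.
#'
#' @param species `"plant"` or `"human"`; sets default caps.
#' @param mfe_max Maximum (least negative) accepted MFE in kcal/mol; hits
#'   must satisfy `mfe <= mfe_max`. Default -25.
#' @param p_max Maximum accepted p-value (default 0.05).
#' @param require_seed Require a perfect Watson-Crick seed (positions 2-8)?
#' @param max_loop,max_bulge Structural caps in nt; `NULL` = uncapped.
#'   Defaults depend on `species`.
#' @param top_k_rank Rank cutoff used by downstream selection (default 50).
#' @return An object of class `filter_profile`.
#' @export
#' @examples
#' filter_profile("plant")
filter_profile <- function(species = c("plant", "human"),
                           mfe_max = -25, p_max = 0.05, require_seed = TRUE,
                           max_loop = if (species == "plant") 5 else NULL,
                           max_bulge = if (species == "plant") 9 else NULL,
                           top_k_rank = 50) {
  species <- match.arg(species)
  force(max_loop); force(max_bulge)
  stopifnot(mfe_max < 0, p_max > 0, p_max <= 1)
  structure(
    list(species = species, mfe_max = mfe_max, p_max = p_max,
         require_seed = require_seed, max_loop = max_loop,
         max_bulge = max_bulge, top_k_rank = top_k_rank),
    class = "filter_profile"
  )
}

#' @export
print.filter_profile <- function(x, ...) {
  cat("<filter_profile>", x$species,
      sprintf("| mfe <= %g, p <= %g, seed %s, loop <= %s, bulge <= %s\n",
              x$mfe_max, x$p_max, if (x$require_seed) "required" else "free",
              if (is.null(x$max_loop)) "Inf" else x$max_loop,
              if (is.null(x$max_bulge)) "Inf" else x$max_bulge))
  invisible(x)
}

#' Apply the screening filter cascade to predicted hits
#'
#' Retains exactly the hits with `mfe <= mfe_max`, `pvalue <= p_max` (when
#' p-values are present), an intact Watson-Crick seed (if required), and all
#' bulges/internal loops within the profile caps. Input order is preserved.
#'
#' @param hits Hit tibble from [predict_targets()] / [add_pvalues()].
#' @param profile A [filter_profile()].
#' @return The retained subset of `hits`.
#' @export
apply_filters <- function(hits, profile) {
  stopifnot(inherits(profile, "filter_profile"))
  if (nrow(hits) == 0) return(hits)
  keep <- hits$mfe <= profile$mfe_max
  if (!all(is.na(hits$pvalue))) {
    keep <- keep & (is.na(hits$pvalue) | hits$pvalue <= profile$p_max)
  }
  if (profile$require_seed) keep <- keep & seed_match(hits)
  sm <- structure_measures(hits$pairs)
  if (!is.null(profile$max_bulge)) keep <- keep & sm$max_bulge_len <= profile$max_bulge
  if (!is.null(profile$max_loop)) keep <- keep & sm$max_loop_side <= profile$max_loop
  hits[keep, , drop = FALSE]
}

#' Rank targets within each miRNA
#'
#' Orders each miRNA's hits by p-value ascending, then MFE ascending, then
#' gene id (a deterministic tie-break), and assigns dense 1-based ranks.
#'
#' @param hits Hit tibble (may span several miRNAs; ranks are per miRNA).
#' @return `hits` with a `rank` column, sorted by miRNA then rank.
#' @export
rank_targets <- function(hits) {
  if (nrow(hits) == 0) return(dplyr::mutate(hits, rank = integer()))
  hits |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::arrange(.data$pvalue, .data$mfe, .data$gene_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Three-level validation of known targets against the prediction pipeline
#'
#' For each validated (miRNA, gene, region) triple, checks (1) whether the
#' gene's region is present in the input mRNA set, (2) whether a primary
#' (pre-screening) hit exists for that miRNA/gene/region, and (3) whether
#' the hit survived screening; survivors get the per-miRNA rank of the
#' refined hit.
#'
#' @param validated Tibble with `mirna_id`, `gene_id`, `region`.
#' @param mrna_set Tibble of input transcript regions (`gene_id`,
#'   `accession`, `region`).
#' @param primary_hits Hit tibble before screening.
#' @param refined_hits Hit tibble after screening (subset of primary).
#' @return One record per validated triple: `mirna_id`, `gene_id`,
#'   `accession`, `region_validated`, `in_mrna_set`, `in_primary`,
#'   `in_refined`, `rank` (`NA` unless refined).
#' @export
validate_three_level <- function(validated, mrna_set, primary_hits,
                                 refined_hits) {
  ranked <- rank_targets(refined_hits)
  purrr::map_dfr(seq_len(nrow(validated)), function(i) {
    v <- validated[i, ]
    mr <- mrna_set[mrna_set$gene_id == v$gene_id &
                     mrna_set$region == v$region, , drop = FALSE]
    in_mrna <- nrow(mr) > 0
    acc <- if (in_mrna) mr$accession[[1]] else NA_character_
    in_prim <- in_mrna && any(
      primary_hits$mirna_id == v$mirna_id &
        primary_hits$gene_id == v$gene_id &
        primary_hits$region == v$region)
    rr <- ranked[ranked$mirna_id == v$mirna_id &
                   ranked$gene_id == v$gene_id &
                   ranked$region == v$region, , drop = FALSE]
    in_ref <- in_prim && nrow(rr) > 0
    tibble(mirna_id = v$mirna_id, gene_id = v$gene_id, accession = acc,
           region_validated = v$region,
           in_mrna_set = in_mrna, in_primary = in_prim, in_refined = in_ref,
           rank = if (in_ref) min(rr$rank) else NA_integer_)
  })
}

#' Summarize a validation report
#'
#' @param records Tibble from [validate_three_level()].
#' @return One-row tibble: `n_validated`, `n_in_top10`, `n_in_top50`,
#'   `frac_top50` (`NA` with a warning when nothing was validated).
#' @export
validation_summary <- function(records) {
  n <- nrow(records)
  if (n == 0) {
    warning("no validated targets; fraction undefined", call. = FALSE)
    return(tibble(n_validated = 0L, n_in_top10 = 0L, n_in_top50 = 0L,
                  frac_top50 = NA_real_))
  }
  rk <- records$rank[!is.na(records$rank)]
  tibble(n_validated = n,
         n_in_top10 = sum(rk <= 10),
         n_in_top50 = sum(rk <= 50),
         frac_top50 = sum(rk <= 50) / n)
}
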