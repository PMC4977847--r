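# Per-module GO enrichment against the whole-network background, BH
# adjustment, slim-category grouping, cross-species functional similarity
# and three-tier tissue-expression classification.

#' GO annotation container
#'
#' Bundles a term table and gene-to-term assignments, validating that every
#' annotated term exists and that the `is_a` graph is acyclic.
#'
#' @param terms Tibble with `term_id`, `name`, `namespace` and `parents`
#'   (list-column of `is_a` parent term ids).
#' @param mapping Tibble with `gene_id`, `term_id`.
#' @return An object of class `go_annotation`.
#' @export
go_annotation <- function(terms, mapping) {
  stopifnot(all(c("term_id", "name", "parents") %in% names(terms)),
            all(c("gene_id", "term_id") %in% names(mapping)))
  if (!"namespace" %in% names(terms)) terms$namespace <- "biological_process"
  unknown <- setdiff(mapping$term_id, terms$term_id)
  if (length(unknown) > 0) {
    stop("annotations reference unknown terms: ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  check_acyclic(terms)
  structure(list(terms = terms, mapping = dplyr::distinct(mapping)),
            class = "go_annotation")
}

# topological-sort cycle check on the is_a graph
check_acyclic <- function(terms) {
  parents <- setNames(terms$parents, terms$term_id)
  state <- setNames(rep(0L, nrow(terms)), terms$term_id)  # 0 new, 1 open, 2 done
  visit <- function(t) {
    stack <- list(c(t, "enter"))
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      id <- top[1]
      if (top[2] == "exit") { state[[id]] <<- 2L; next }
      if (state[[id]] == 2L) next
      if (state[[id]] == 1L) stop("cycle in is_a graph at ", id, call. = FALSE)
      state[[id]] <<- 1L
      stack[[length(stack) + 1]] <- c(id, "exit")
      for (p in parents[[id]]) {
        if (!p %in% names(state)) next
        if (state[[p]] == 1L) stop("cycle in is_a graph at ", p, call. = FALSE)
        if (state[[p]] == 0L) stack[[length(stack) + 1]] <- c(p, "enter")
      }
    }
  }
  for (t in terms$term_id) if (state[[t]] == 0L) visit(t)
  invisible(TRUE)
}

#' @export
print.go_annotation <- function(x, ...) {
  cat("<go_annotation>", nrow(x$terms), "terms,",
      length(unique(x$mapping$gene_id)), "annotated genes,",
      nrow(x$mapping), "assignments\n")
  invisible(x)
}

# all is_a ancestors (including the term itself) for each term id
term_ancestors <- function(annotation) {
  parents <- setNames(annotation$terms$parents, annotation$terms$term_id)
  memo <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- parents[[t]]
    out <- t
    for (p in ps) if (p %in% names(parents)) out <- c(out, anc(p))
    out <- unique(out)
    memo[[t]] <- out
    out
  }
  setNames(lapply(annotation$terms$term_id, anc), annotation$terms$term_id)
}

#' Propagate annotations up the is_a hierarchy (true-path rule)
#'
#' @param annotation A [go_annotation()].
#' @return A `go_annotation` whose mapping includes every ancestor of each
#'   annotated term.
#' @export
propagate_annotations <- function(annotation) {
  anc <- term_ancestors(annotation)
  mapping <- annotation$mapping |>
    dplyr::mutate(term_id = lapply(.data$term_id, function(t) anc[[t]])) |>
    tidyr::unnest("term_id") |>
    dplyr::distinct()
  go_annotation(annotation$terms, mapping)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` where `X` is the number of annotated genes in a random draw
#' of `n` genes from a background of `N_bg` genes of which `K` carry the
#' term.
#'
#' @param k Annotated genes in the module.
#' @param n Module size.
#' @param K Annotated genes in the background.
#' @param N_bg Background size.
#' @return P-value in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_enrich(5, 10, 10, 100)
hypergeom_enrich <- function(k, n, K, N_bg) {
  stopifnot(k >= 0, k <= min(n, K) || K == 0, n <= N_bg)
  if (K == 0) {
    if (k > 0) stop("k > 0 with no background carriers", call. = FALSE)
    return(1)
  }
  phyper(k - 1, K, N_bg - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, order-preserving wrapper over [stats::p.adjust()] with
#' `method = "BH"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' GO enrichment of one module against the network background
#'
#' Tests every term carried by at least one background gene with the
#' upper-tail hypergeometric test, BH-adjusts across the tested terms, and
#' returns the terms significant at `alpha`, sorted by adjusted p.
#'
#' @param module_genes Character vector of module gene ids (subset of
#'   `background_genes`).
#' @param annotation A [go_annotation()].
#' @param background_genes Character vector, the complete network.
#' @param alpha Adjusted-p cutoff (default 0.1).
#' @param propagate Propagate annotations up is_a before testing?
#' @param keep_all Return all tested terms instead of only significant ones.
#' @return Tibble with `term_id`, `name`, `k`, `n`, `K`, `N_bg`, `p_raw`,
#'   `p_adj`.
#' @export
enrich_module <- function(module_genes, annotation, background_genes,
                          alpha = 0.1, propagate = TRUE, keep_all = FALSE) {
  stopifnot(all(module_genes %in% background_genes))
  if (length(module_genes) == 0) {
    return(tibble(term_id = character(), name = character(),
                  k = integer(), n = integer(), K = integer(),
                  N_bg = integer(), p_raw = double(), p_adj = double()))
  }
  ann <- if (propagate) propagate_annotations(annotation) else annotation
  mp <- ann$mapping[ann$mapping$gene_id %in% background_genes, ]
  bg_counts <- table(mp$term_id)
  mod_counts <- table(mp$term_id[mp$gene_id %in% module_genes])
  terms <- names(bg_counts)
  if (length(terms) == 0) {
    return(enrich_module(character(0), annotation, background_genes))
  }
  n <- length(module_genes)
  N_bg <- length(background_genes)
  res <- tibble(
    term_id = terms,
    k = as.integer(ifelse(is.na(mod_counts[terms]), 0L, mod_counts[terms])),
    n = n,
    K = as.integer(bg_counts[terms]),
    N_bg = N_bg
  )
  res$p_raw <- vapply(seq_len(nrow(res)), function(i) {
    hypergeom_enrich(res$k[i], n, res$K[i], N_bg)
  }, double(1))
  res$p_adj <- bh_adjust(res$p_raw)
  res <- dplyr::left_join(res,
                          dplyr::select(ann$terms, "term_id", "name"),
                          by = "term_id") |>
    dplyr::select("term_id", "name", "k", "n", "K", "N_bg", "p_raw", "p_adj") |>
    dplyr::arrange(.data$p_adj, .data$p_raw, .data$term_id)
  if (keep_all) res else res[res$p_adj < alpha, , drop = FALSE]
}

#' Enrichment across all modules of a decomposition
#'
#' @param modules A `module_set` from [decompose_modules()].
#' @param annotation A [go_annotation()].
#' @param background_genes The complete network's genes.
#' @inheritParams enrich_module
#' @return Tibble of per-module enrichment results with a `module_id`
#'   column.
#' @export
enrich_modules <- function(modules, annotation, background_genes,
                           alpha = 0.1, propagate = TRUE) {
  purrr::map_dfr(seq_len(nrow(modules)), function(i) {
    genes <- intersect(modules$genes[[i]], background_genes)
    res <- enrich_module(genes, annotation, background_genes,
                         alpha = alpha, propagate = propagate)
    if (nrow(res) == 0) return(res)
    dplyr::bind_cols(tibble(module_id = modules$module_id[i]), res)
  })
}

#' Map GO terms to generic (slim) categories
#'
#' Each term maps to every slim category among its transitive `is_a`
#' ancestors (a slim term maps to itself); terms reaching no slim category
#' fall into an explicit `"unclassified"` bucket.
#'
#' @param terms Character vector of term ids to map.
#' @param slim_list Character vector of slim category term ids (must be in
#'   the ontology).
#' @param annotation A [go_annotation()] supplying the ontology.
#' @return Tibble `(term_id, slim_id)`.
#' @export
map_to_slim <- function(terms, slim_list, annotation) {
  stopifnot(all(slim_list %in% annotation$terms$term_id))
  anc <- term_ancestors(annotation)
  purrr::map_dfr(terms, function(t) {
    a <- if (t %in% names(anc)) anc[[t]] else t
    hit <- intersect(a, slim_list)
    if (length(hit) == 0) hit <- "unclassified"
    tibble(term_id = t, slim_id = sort(hit))
  })
}

#' Functional similarity between two category profiles
#'
#' Compares two collections of generic GO categories (e.g. the slim
#' categories of enriched functions in two species) by set overlap.
#'
#' @param cats1,cats2 Character vectors of slim category ids (duplicates
#'   collapse to the support set).
#' @return One-row tibble with `jaccard` (`|A&B| / |A|B|`), `overlap_coef`
#'   (`|A&B| / min(|A|, |B|)`) and `shared` (list-column of common
#'   categories).
#' @export
#' @examples
#' functional_similarity(c("ion transport", "growth"),
#'                       c("ion transport", "photosynthesis"))
functional_similarity <- function(cats1, cats2) {
  a <- unique(cats1); b <- unique(cats2)
  if (length(a) == 0 && length(b) == 0) {
    warning("both category sets empty; similarity 0", call. = FALSE)
    return(tibble(jaccard = 0, overlap_coef = 0, shared = list(character(0))))
  }
  inter <- intersect(a, b)
  tibble(
    jaccard = length(inter) / length(union(a, b)),
    overlap_coef = if (min(length(a), length(b)) == 0) 0 else
      length(inter) / min(length(a), length(b)),
    shared = list(sort(inter))
  )
}

#' Three-tier tissue-expression classification
#'
#' A gene counts as expressed in a tissue when its value exceeds
#' `detect_thresh`. Genes expressed in at least `n_tissues - 1` tissues are
#' `ubiquitous` (housekeeping-like); in exactly one, `tissue_specific`
#' (assigned to that tissue); in an intermediate number with a clear peak
#' (max z-score across tissues above `z_thresh`), `highly_expressed`; genes
#' expressed nowhere are `not_expressed`, everything else `other`.
#'
#' @param expr Data frame: `gene_id` column plus one numeric column per
#'   tissue (at least two tissues), non-negative values.
#' @param detect_thresh Expression-detection threshold (default 1).
#' @param z_thresh Peak z-score threshold for the highly-expressed tier.
#' @return Tibble `(gene_id, level, n_expressed, max_z, tissue)`; `tissue`
#'   is set for tissue-specific genes only.
#' @export
classify_tissue_levels <- function(expr, detect_thresh = 1, z_thresh = 1) {
  tissues <- setdiff(names(expr), "gene_id")
  stopifnot(length(tissues) >= 2)
  mat <- as.matrix(expr[, tissues])
  stopifnot(all(is.finite(mat)), all(mat >= 0))
  det <- mat > detect_thresh
  n_exp <- rowSums(det)
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  max_z <- ifelse(s > 0, (apply(mat, 1, max) - mu) / s, 0)
  level <- dplyr::case_when(
    n_exp == 0 ~ "not_expressed",
    n_exp >= length(tissues) - 1 ~ "ubiquitous",
    n_exp == 1 ~ "tissue_specific",
    max_z > z_thresh ~ "highly_expressed",
    TRUE ~ "other"
  )
  tissue <- ifelse(n_exp == 1, tissues[apply(det, 1, which.max)],
                   NA_character_)
  tibble(gene_id = expr$gene_id, level = level,
         n_expressed = as.integer(n_exp), max_z = max_z, tissue = tissue)
}
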