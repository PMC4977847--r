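# Gene interaction network: adjacency-iteration node weighting (the
# iterated-matrix PageRank variant), bridge-gene selection and module
# decomposition by bridge deletion.

#' Build an undirected gene interaction graph from an edge table
#'
#' Duplicate edges (in either orientation) are collapsed and self-loops
#' dropped.
#'
#' @param edges Two-column data frame (`from`, `to`) of gene ids, or a path
#'   to a TSV edge list.
#' @return An [igraph::igraph] object.
#' @export
build_graph <- function(edges) {
  if (is.character(edges) && length(edges) == 1) {
    edges <- read_edges(edges)
  }
  edges <- as.data.frame(edges[, 1:2])
  names(edges) <- c("from", "to")
  if (nrow(edges) == 0) stop("empty edge list", call. = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Node weights by iterated adjacency multiplication (PageRank variants)
#'
#' `mode = "paper"` starts every node at weight one and repeatedly
#' multiplies the weight vector by the 0/1 adjacency matrix, renormalizing
#' the total weight to N each step (power iteration toward the principal
#' eigenvector of A); `mode = "damped"` is standard PageRank on the
#' degree-normalized matrix with damping 0.85, scaled to total N. Iteration
#' stops when the largest per-node change drops below `tol`.
#'
#' @param graph An [igraph::igraph] from [build_graph()].
#' @param mode `"paper"` (adjacency power iteration) or `"damped"`.
#' @param tol Convergence tolerance on the max per-node weight change.
#' @param max_iter Iteration cap; exceeding it flags `converged = FALSE`
#'   (with a warning) rather than failing.
#' @param damping Damping factor for `mode = "damped"`.
#' @return An object of class `weight_vector`: tibble `(gene, weight)` with
#'   attributes `iteration_count`, `final_perturbation`, `converged`, `mode`.
#' @export
pagerank_weights <- function(graph, mode = c("paper", "damped"),
                             tol = 0.005, max_iter = 1000, damping = 0.85) {
  mode <- match.arg(mode)
  n <- igraph::vcount(graph)
  genes <- igraph::V(graph)$name
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  b <- rep(1, n)
  iters <- 0L
  pert <- 0
  converged <- TRUE
  deg <- igraph::degree(graph)

  if (igraph::ecount(graph) > 0) {
    repeat {
      if (mode == "paper") {
        nb <- as.numeric(A %*% b)
        s <- sum(nb)
        nb <- if (s > 0) nb * n / s else nb
      } else {
        contrib <- ifelse(deg > 0, b / deg, 0)
        nb <- damping * as.numeric(A %*% contrib) +
          (1 - damping) * sum(b) / n +
          damping * sum(b[deg == 0]) / n  # dangling mass spread uniformly
      }
      iters <- iters + 1L
      pert <- max(abs(nb - b))
      b <- nb
      if (pert < tol) break
      if (iters >= max_iter) {
        converged <- FALSE
        warning("weight iteration did not converge within ", max_iter,
                " iterations (last perturbation ", signif(pert, 3), ")",
                call. = FALSE)
        break
      }
    }
  }

  structure(
    tibble(gene = genes, weight = b),
    class = c("weight_vector", class(tibble())),
    iteration_count = iters,
    final_perturbation = pert,
    converged = converged,
    mode = mode
  )
}

#' Select the top-weight bridge genes
#'
#' @param weights A `weight_vector` from [pagerank_weights()].
#' @param graph The graph the weights were computed on (degrees break ties).
#' @param k Number of bridges (default 15).
#' @return Character vector of `k` gene ids, ordered by decreasing weight;
#'   ties broken by degree descending, then gene id.
#' @export
select_bridges <- function(weights, graph, k = 15) {
  if (k > nrow(weights)) stop("k exceeds the number of nodes", call. = FALSE)
  deg <- igraph::degree(graph)[weights$gene]
  ord <- order(-weights$weight, -deg, weights$gene)
  weights$gene[ord][seq_len(k)]
}

#' Decompose the network into modules by bridge deletion
#'
#' Deletes the bridge nodes (and incident edges) and takes the connected
#' components of the residual graph; components with at least `min_size`
#' members become modules, smaller ones are reported as residue. Each
#' module's central bridges are the bridges adjacent, in the original graph,
#' to any module member.
#'
#' @param graph An [igraph::igraph].
#' @param bridges Character vector of bridge gene ids (subset of nodes).
#' @param min_size Minimum component size to count as a module.
#' @return An object of class `module_set`: tibble with one row per module
#'   (`module_id`, `size`, `genes` list-column, `central_bridges`
#'   list-column), with attributes `bridges` and `residue` (genes in
#'   sub-threshold components).
#' @export
decompose_modules <- function(graph, bridges, min_size = 3) {
  stopifnot(all(bridges %in% igraph::V(graph)$name))
  residual <- igraph::delete_vertices(graph, bridges)
  comp <- igraph::components(residual)
  membership <- split(names(comp$membership), comp$membership)
  modules <- membership[lengths(membership) >= min_size]
  residue <- unlist(membership[lengths(membership) < min_size],
                    use.names = FALSE)
  # stable ordering: by size descending then first gene
  ord <- order(-lengths(modules),
               vapply(modules, function(g) sort(g)[1], character(1)))
  modules <- unname(modules[ord])
  el <- igraph::as_data_frame(graph, what = "edges")
  central <- lapply(modules, function(genes) {
    nb <- unique(c(el$to[el$from %in% genes], el$from[el$to %in% genes]))
    sort(intersect(nb, bridges))
  })
  out <- tibble(
    module_id = seq_along(modules),
    size = unname(lengths(modules)),
    genes = lapply(modules, function(g) sort(unname(g))),
    central_bridges = unname(central)
  )
  structure(out,
            class = c("module_set", class(tibble())),
            bridges = bridges,
            residue = if (is.null(residue)) character(0) else residue)
}

#' Long-format module membership
#'
#' @param modules A `module_set`.
#' @return Tibble `(module_id, gene, is_central_bridge)`, central bridges
#'   listed once per module they border.
#' @export
module_membership <- function(modules) {
  dplyr::bind_rows(
    tidyr::unnest(dplyr::select(modules, "module_id", gene = "genes"),
                  "gene") |>
      dplyr::mutate(is_central_bridge = FALSE),
    tidyr::unnest(dplyr::select(modules, "module_id",
                                gene = "central_bridges"), "gene") |>
      dplyr::mutate(is_central_bridge = TRUE)
  ) |>
    dplyr::arrange(.data$module_id, .data$is_central_bridge, .data$gene)
}

#' @export
tidy.weight_vector <- function(x, ...) {
  tibble(gene = x$gene, weight = x$weight,
         rank = rank(-x$weight, ties.method = "min"))
}

#' @export
glance.weight_vector <- function(x, ...) {
  tibble(n_nodes = nrow(x),
         iteration_count = attr(x, "iteration_count"),
         final_perturbation = attr(x, "final_perturbation"),
         converged = attr(x, "converged"),
         mode = attr(x, "mode"))
}

#' @export
glance.module_set <- function(x, ...) {
  tibble(n_modules = nrow(x),
         n_module_genes = sum(x$size),
         n_bridges = length(attr(x, "bridges")),
         n_residue = length(attr(x, "residue")))
}
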