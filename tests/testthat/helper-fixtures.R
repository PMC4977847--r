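# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_model <- function() fix_get("model", energy_model)

# energy model whose every stack step costs the same, for hand-computable
# expectations
uniform_model <- function(dg = -3.3) {
  m <- energy_model()
  m$stacks[, ] <- dg
  m
}

rand_rna <- function(n) paste(sample(RNA_BASES_T, n, TRUE), collapse = "")
RNA_BASES_T <- c("A", "C", "G", "U")

# raw C++ entry points, convenient for oracle comparisons
dp_mfe <- function(mseq, wseq, model, max_bulge = -1L, max_loop = -1L) {
  crossmir:::duplex_mfe_cpp(
    crossmir:::seq_to_int(mseq), crossmir:::seq_to_int(wseq), model$stacks,
    model$bulge_open, model$bulge_ext, model$loop_open, model$loop_ext,
    model$end_penalty, max_bulge, max_loop)$mfe
}

enum_mfe <- function(mseq, wseq, model, max_bulge = -1L, max_loop = -1L) {
  crossmir:::duplex_mfe_enum_cpp(
    crossmir:::seq_to_int(mseq), crossmir:::seq_to_int(wseq), model$stacks,
    model$bulge_open, model$bulge_ext, model$loop_open, model$loop_ext,
    model$end_penalty, max_bulge, max_loop)
}

# screening benchmark: 10 miRNAs, each with a clean planted site, plus
# seed-mismatch / wobble / 10-nt-bulge sites on dedicated transcripts;
# primary hits with calibrated p-values included
screen_fixture <- function() fix_get("screen_fix", function() {
  cfg <- synth_config(seed = 42, n_mirnas = 10, n_transcripts = 15,
                      region_len = 150)
  mirnas <- gen_mirnas(cfg)
  tr <- gen_transcripts_with_sites(cfg, mirnas)
  hits <- predict_targets(mirnas, tr$regions)
  calibs <- calibrate_nulls(mirnas, tr$regions, n_shuffles = 100, seed = 420,
                            windows_per_shuffle = 10)
  list(cfg = cfg, mirnas = mirnas, regions = tr$regions, truth = tr$truth,
       hits = add_pvalues(hits, calibs), calibs = calibs)
})

# planted paper-scale network (11 modules, 15 bridges)
network_fixture <- function() fix_get("net_fix", function() {
  cfg <- synth_config(seed = 42)
  net <- gen_network(cfg)
  g <- build_graph(net$edges)
  list(cfg = cfg, net = net, graph = g)
})

# truth lookup: does any hit match a planted site (by miRNA and gene)?
truth_hit_present <- function(hits, truth_row) {
  any(hits$mirna_id == truth_row$mirna_id &
        hits$gene_id == truth_row$gene_id)
}

# independent BFS component counter (oracle for igraph-based decomposition)
bfs_component_count <- function(nodes, edge_from, edge_to) {
  adj <- split(c(edge_to, edge_from), c(edge_from, edge_to))
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  ncomp <- 0L
  for (v in nodes) {
    if (seen[[v]]) next
    ncomp <- ncomp + 1L
    queue <- v; seen[[v]] <- TRUE
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (wn in adj[[u]]) {
        if (!is.null(seen[[wn]]) && !seen[[wn]]) {
          seen[[wn]] <- TRUE
          queue <- c(queue, wn)
        }
      }
    }
  }
  ncomp
}

# exact hypergeometric upper tail by direct combinatorial summation
hyper_tail_oracle <- function(k, n, K, N) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# five-node star (hub 1) with a chord 2-3: fixed graph for eigenvector checks
star_chord_graph <- function() {
  build_graph(tibble::tibble(from = c("n1", "n1", "n1", "n1", "n2"),
                             to = c("n2", "n3", "n4", "n5", "n3")))
}
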