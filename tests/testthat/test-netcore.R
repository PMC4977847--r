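test_that("graph construction deduplicates edges and drops self-loops", {
  e <- tibble::tibble(from = c("a", "b", "c"), to = c("b", "a", "c"))
  g <- build_graph(e)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)

  gp <- build_graph(tibble::tibble(from = c("a", "b"), to = c("b", "c")))
  expect_equal(unname(igraph::degree(gp)["b"]), 2)

  # round trip through the edge-list writer/reader preserves the edge set
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_dot(igraph::as_data_frame(gp, "edges")[, 1:2], tmp)
  g2 <- build_graph(tmp)
  key <- function(g) {
    el <- igraph::as_data_frame(g, "edges")
    sort(paste(pmin(el$from, el$to), pmax(el$from, el$to)))
  }
  expect_identical(key(g2), key(gp))

  expect_error(build_graph(tibble::tibble(from = character(),
                                          to = character())), "empty")
})

test_that("adjacency power iteration matches the eigenvector oracle", {
  # K3: all weights equal by symmetry
  k3 <- build_graph(tibble::tibble(from = c("a", "b", "c"),
                                   to = c("b", "c", "a")))
  w3 <- pagerank_weights(k3, "paper", tol = 1e-10)
  expect_equal(w3$weight, rep(1, 3))

  # single isolated node: weight one, nothing to iterate
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "solo"
  w1 <- pagerank_weights(g1, "paper")
  expect_equal(w1$weight, 1)
  expect_equal(attr(w1, "iteration_count"), 0L)

  # fixed 5-node star + chord: dense eigen-solver oracle
  g5 <- star_chord_graph()
  w5 <- pagerank_weights(g5, "paper", tol = 1e-10, max_iter = 10000)
  A <- as.matrix(igraph::as_adjacency_matrix(g5))
  ev <- eigen(A, symmetric = TRUE)
  v <- abs(ev$vectors[, which.max(ev$values)])
  oracle <- v / sum(v) * 5
  expect_lt(max(abs(w5$weight - oracle[match(w5$gene, rownames(A))])), 1e-6)

  # total weight is conserved at N after any number of iterations
  for (it in 1:4) {
    wi <- suppressWarnings(pagerank_weights(g5, "paper", tol = 1e-15,
                                            max_iter = it))
    expect_equal(sum(wi$weight), 5)
    expect_equal(attr(wi, "iteration_count"), it)
  }

  # the default tolerance stops at a perturbation below 0.005
  wd <- pagerank_weights(g5, "paper", tol = 0.005)
  expect_lt(attr(wd, "final_perturbation"), 0.005)
  expect_true(attr(wd, "converged"))
})

test_that("damped PageRank conserves mass and favors the hub", {
  g5 <- star_chord_graph()
  wd <- pagerank_weights(g5, "damped", tol = 1e-10, max_iter = 10000)
  expect_equal(sum(wd$weight), 5, tolerance = 1e-8)
  expect_identical(wd$gene[which.max(wd$weight)], "n1")
  # agrees with igraph's implementation up to the sum-N scaling
  pr <- igraph::page_rank(g5, damping = 0.85)$vector
  expect_lt(max(abs(wd$weight - pr[wd$gene] * 5)), 1e-6)
})

test_that("bridge selection is top-k by weight with degree tie-breaks", {
  w <- structure(tibble::tibble(gene = paste0("g", 1:5),
                                weight = c(5, 4, 3, 2, 1)),
                 class = c("weight_vector", class(tibble::tibble())))
  g <- build_graph(tibble::tibble(from = paste0("g", 1:4),
                                  to = paste0("g", 2:5)))
  expect_identical(select_bridges(w, g, 2), c("g1", "g2"))
  expect_identical(select_bridges(w, g, 5), paste0("g", 1:5))
  expect_error(select_bridges(w, g, 6), "exceeds")

  # tie on weight: higher degree first, then lexicographic id
  wt <- structure(tibble::tibble(gene = c("a", "b", "c"),
                                 weight = c(1, 1, 1)),
                  class = c("weight_vector", class(tibble::tibble())))
  gt <- build_graph(tibble::tibble(from = c("a", "b", "c"),
                                   to = c("b", "c", "a")))
  expect_identical(select_bridges(wt, gt, 2), c("a", "b"))
})

test_that("bridge deletion decomposes a barbell into its two cliques", {
  clique_edges <- function(genes) {
    idx <- t(utils::combn(genes, 2))
    tibble::tibble(from = idx[, 1], to = idx[, 2])
  }
  left <- paste0("L", 1:5); right <- paste0("R", 1:5)
  e <- dplyr::bind_rows(clique_edges(left), clique_edges(right),
                        tibble::tibble(from = "hub", to = c("L1", "R1")))
  g <- build_graph(e)
  mods <- decompose_modules(g, "hub")
  expect_equal(nrow(mods), 2)
  expect_equal(sort(mods$size), c(5L, 5L))
  expect_identical(sort(unlist(mods$genes)), sort(c(left, right)))
  expect_identical(unique(unlist(mods$central_bridges)), "hub")

  # no bridges on a connected graph: one module
  expect_equal(nrow(decompose_modules(g, character(0))), 1)

  # modules plus residue partition the non-bridge nodes
  mm <- module_membership(mods)
  expect_false(any(duplicated(mm$gene[!mm$is_central_bridge])))
})

test_that("component counts agree with an independent BFS oracle", {
  withr::with_seed(808, {
    for (i in 1:30) {
      n <- sample(10:40, 1)
      g <- igraph::sample_gnp(n, runif(1, 0.02, 0.2))
      igraph::V(g)$name <- paste0("v", seq_len(n))
      el <- igraph::as_data_frame(g, "edges")
      oracle <- bfs_component_count(igraph::V(g)$name, el$from, el$to)
      expect_equal(igraph::components(g)$no, oracle)
      # and through decompose_modules with no bridges and min_size 1
      mods <- decompose_modules(g, character(0), min_size = 1)
      expect_equal(nrow(mods), oracle)
    }
  })
})

test_that("planted bridges and modules are recovered at study scale", {
  fx <- network_fixture()
  w <- pagerank_weights(fx$graph, "paper", tol = 1e-9, max_iter = 5000)
  br <- select_bridges(w, fx$graph, 15)
  expect_setequal(br, fx$net$bridges)

  mods <- decompose_modules(fx$graph, br)
  expect_equal(nrow(mods), 11)
  expect_equal(length(attr(mods, "residue")), 0)
  truth_split <- split(fx$net$truth$gene, fx$net$truth$module)
  recovered <- lapply(mods$genes, sort)
  expect_true(all(vapply(truth_split, function(tg) {
    any(vapply(recovered, identical, logical(1), y = sort(tg)))
  }, logical(1))))
})
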