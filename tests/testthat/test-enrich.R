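# tiny hand-built ontology: two roots (slim), a chain underneath
toy_ontology <- function() {
  tibble::tibble(
    term_id = c("S1", "S2", "t1", "t2", "t3"),
    name = paste("term", c("S1", "S2", "t1", "t2", "t3")),
    namespace = "biological_process",
    parents = list(character(0), character(0), "S1", "t1", c("t1", "S2"))
  )
}

test_that("hypergeometric tail equals the combinatorial oracle", {
  expect_equal(hypergeom_enrich(5, 10, 10, 100),
               hyper_tail_oracle(5, 10, 10, 100), tolerance = 1e-12)
  # a term annotating the whole background is never enriched
  expect_equal(hypergeom_enrich(10, 10, 100, 100), 1)
  expect_equal(hypergeom_enrich(0, 10, 10, 100), 1)
  expect_error(hypergeom_enrich(1, 10, 0, 100), "no background")
  expect_equal(hypergeom_enrich(0, 10, 0, 100), 1)

  withr::with_seed(909, {
    for (i in 1:60) {
      N <- sample(20:200, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      k <- sample(0:min(n, K), 1)
      expect_lt(abs(hypergeom_enrich(k, n, K, N) -
                      hyper_tail_oracle(k, n, K, N)), 1e-10)
    }
  })
})

test_that("Benjamini-Hochberg step-up matches hand evaluation", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  withr::with_seed(910, {
    p <- runif(50)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # permutation invariance
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm])[order(perm)], adj)
  })
})

test_that("module enrichment finds planted terms and respects empty input", {
  fx <- network_fixture()
  ann <- gen_annotations(fx$cfg, fx$net)
  bg <- igraph::V(fx$graph)$name
  mods <- decompose_modules(fx$graph, fx$net$bridges)
  res <- enrich_modules(mods, ann$annotation, bg)

  planted_mod_genes <- fx$net$truth$gene[fx$net$truth$module ==
                                           ann$truth$module[1]]
  mid <- mods$module_id[vapply(mods$genes, function(g)
    any(g %in% planted_mod_genes), logical(1))][1]
  found <- res[res$module_id == mid & res$term_id == ann$truth$term_id[1], ]
  expect_equal(nrow(found), 1)
  expect_lt(found$p_adj, 0.1)

  # counts are internally consistent
  expect_true(all(res$k <= pmin(res$n, res$K)))
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))

  # no annotations -> empty result
  empty_ann <- go_annotation(toy_ontology(),
                             tibble::tibble(gene_id = character(),
                                            term_id = character()))
  expect_equal(nrow(enrich_module(bg[1:5], empty_ann, bg)), 0)
  expect_equal(nrow(enrich_module(character(0), ann$annotation, bg)), 0)
})

test_that("type-I error stays controlled on null modules", {
  cfg <- synth_config(seed = 7, annotation = list(planted = NULL))
  net <- gen_network(cfg)
  ann <- gen_annotations(cfg, net)
  genes <- c(net$truth$gene, net$bridges)
  pre <- propagate_annotations(ann$annotation)
  withr::with_seed(911, {
    hits <- vapply(1:60, function(i) {
      mod <- sample(genes, 40)
      nrow(enrich_module(mod, pre, genes, alpha = 0.1, propagate = FALSE)) > 0
    }, logical(1))
  })
  expect_lte(mean(hits), 0.1 + 3 * sqrt(0.1 * 0.9 / 60))
})

test_that("slim mapping is transitive-closure reachability and idempotent", {
  ann <- go_annotation(toy_ontology(),
                       tibble::tibble(gene_id = "g", term_id = "t2"))
  # a slim term maps to itself
  expect_identical(map_to_slim("S1", c("S1", "S2"), ann)$slim_id, "S1")
  # chain t2 -> t1 -> S1
  expect_identical(map_to_slim("t2", "S1", ann)$slim_id, "S1")
  # multi-parent: t3 reaches both roots
  expect_setequal(map_to_slim("t3", c("S1", "S2"), ann)$slim_id,
                  c("S1", "S2"))
  # no slim ancestor -> explicit unclassified bucket
  expect_identical(map_to_slim("t1", "S2", ann)$slim_id, "unclassified")
  # idempotence: mapping the mapped categories returns themselves
  m1 <- map_to_slim(c("t2", "t3"), c("S1", "S2"), ann)
  m2 <- map_to_slim(unique(m1$slim_id), c("S1", "S2"), ann)
  expect_true(all(m2$term_id == m2$slim_id))

  # random DAG against a DFS reachability oracle
  withr::with_seed(912, {
    n <- 50
    ids <- sprintf("r%02d", 1:n)
    parents <- lapply(1:n, function(i) {
      if (i <= 5) character(0) else sample(ids[1:(i - 1)], sample(1:2, 1))
    })
    terms <- tibble::tibble(term_id = ids, name = ids,
                            namespace = "bp", parents = parents)
    rann <- go_annotation(terms, tibble::tibble(gene_id = "g",
                                                term_id = ids[n]))
    slim <- ids[1:5]
    reach <- function(t) {  # plain recursive DFS
      out <- t
      for (p in parents[[match(t, ids)]]) out <- union(out, reach(p))
      out
    }
    for (t in sample(ids, 10)) {
      expected <- intersect(reach(t), slim)
      if (length(expected) == 0) expected <- "unclassified"
      expect_setequal(map_to_slim(t, slim, rann)$slim_id, expected)
    }
  })
})

test_that("cyclic ontologies are rejected", {
  cyc <- tibble::tibble(term_id = c("a", "b"), name = c("a", "b"),
                        namespace = "bp", parents = list("b", "a"))
  expect_error(go_annotation(cyc, tibble::tibble(gene_id = "g",
                                                 term_id = "a")),
               "cycle")
  expect_error(go_annotation(toy_ontology(),
                             tibble::tibble(gene_id = "g", term_id = "nope")),
               "unknown")
})

test_that("functional similarity is set overlap on slim categories", {
  same <- functional_similarity(c("x", "y"), c("y", "x"))
  expect_equal(same$jaccard, 1)
  disj <- functional_similarity(c("x"), c("y"))
  expect_equal(disj$jaccard, 0)

  s <- functional_similarity(
    c("ion transport", "stress response", "growth"),
    c("ion transport", "stress response", "photosynthesis"))
  expect_equal(s$jaccard, 0.5)
  expect_equal(s$overlap_coef, 2 / 3)
  expect_setequal(s$shared[[1]], c("ion transport", "stress response"))

  expect_warning(z <- functional_similarity(character(0), character(0)),
                 "empty")
  expect_equal(z$jaccard, 0)
})

test_that("tissue tiers follow detection counts and peak z-scores", {
  tis <- c("brain", "heart", "kidney", "liver", "lung", "spleen",
           "stomach", "small_intestine")
  expr <- tibble::tibble(gene_id = c("ubi", "spec", "high", "off"))
  vals <- rbind(rep(20, 8),
                c(rep(0, 7), 30),
                c(40, 5, 5, rep(0, 5)),
                rep(0, 8))
  colnames(vals) <- tis
  expr <- dplyr::bind_cols(expr, tibble::as_tibble(vals))
  cl <- classify_tissue_levels(expr)
  expect_identical(cl$level,
                   c("ubiquitous", "tissue_specific", "highly_expressed",
                     "not_expressed"))
  expect_identical(cl$tissue[2], "small_intestine")
  expect_true(is.na(cl$tissue[1]))
})
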