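# Synthetic-data generators with planted, recoverable structure. Every
# generator is a pure function of its configuration (all randomness flows
# from cfg$seed), and every planted feature is emitted in a truth table so
# downstream stages can be scored without re-reading generator internals.

#' Synthetic-benchmark configuration
#'
#' Collects every knob of the synthetic generators. The defaults mirror the
#' shape of the study the pipeline was built around: 25 miRNAs of 21 nt,
#' an interaction network of 11 dense modules totalling ~528 genes plus 15
#' high-degree bridge hubs (~2450 edges), 8 tissues, and planted
#' hybridization sites covering every corruption class the screening stage
#' distinguishes.
#'
#' @param seed Integer master seed.
#' @param n_mirnas,mirna_len miRNA count and length.
#' @param n_transcripts,region_len Transcript count and length (nt). Needs
#'   `n_transcripts >= n_mirnas + 5` for the default planting layout.
#' @param planted_sites Tibble (`mirna`, `gene`, `region`, `offset`,
#'   `corruption`, `bulge_len`) or `NULL` for the default layout: one clean
#'   site per miRNA on its own transcript, plus seed-mismatch, wobble and
#'   10-nt-bulge sites on dedicated transcripts.
#' @param network List: `n_modules`, `module_size`, `n_bridges`, `intra_p`
#'   (within-module edge probability), `bridge_degree`.
#' @param annotation List: `n_terms`, `n_slim`, `background_rate`, `planted`
#'   (tibble `module`, `frac`).
#' @param expression List: `tissues`, `tier_probs`, `noise_sd`, `on_level`,
#'   `peak_level`, `base_level`.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 42L,
                         n_mirnas = 25, mirna_len = 21,
                         n_transcripts = n_mirnas + 5, region_len = 200,
                         planted_sites = NULL,
                         network = list(),
                         annotation = list(),
                         expression = list()) {
  net <- utils::modifyList(
    list(n_modules = 11, module_size = 48, n_bridges = 15,
         intra_p = 0.155, bridge_degree = 36), network)
  ann <- utils::modifyList(
    list(n_terms = 120, n_slim = 8, background_rate = 0.04,
         planted = tibble(module = 1L, frac = 0.8)), annotation)
  expr <- utils::modifyList(
    list(tissues = c("brain", "heart", "kidney", "liver", "lung", "spleen",
                     "stomach", "small_intestine"),
         tier_probs = c(ubiquitous = 0.3, highly_expressed = 0.3,
                        tissue_specific = 0.3, not_expressed = 0.1),
         noise_sd = 0.3, on_level = 20, peak_level = 40, base_level = 5),
    expression)
  stopifnot(net$n_modules >= 2, net$intra_p > 0, net$intra_p <= 1,
            ann$background_rate >= 0, ann$background_rate <= 1)
  structure(
    list(seed = as.integer(seed), n_mirnas = n_mirnas, mirna_len = mirna_len,
         n_transcripts = n_transcripts, region_len = region_len,
         planted_sites = planted_sites, network = net, annotation = ann,
         expression = expr),
    class = "synth_config"
  )
}

#' Generate random miRNA sequences
#'
#' Uniform random RNA of `mirna_len`, ids `mir001`...
#'
#' @param cfg A [synth_config()].
#' @return Tibble `(id, seq)`.
#' @export
gen_mirnas <- function(cfg) {
  withr::with_seed(cfg$seed + 101L, {
    tibble(
      id = sprintf("mir%03d", seq_len(cfg$n_mirnas)),
      seq = vapply(seq_len(cfg$n_mirnas), function(i) {
        paste(sample(RNA_BASES, cfg$mirna_len, replace = TRUE), collapse = "")
      }, character(1))
    )
  })
}

pair_partners <- function(b) {
  switch(b, A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))
}

default_planted_sites <- function(cfg) {
  nm <- cfg$n_mirnas
  stopifnot(cfg$n_transcripts >= nm + 5)
  clean <- tibble(mirna = seq_len(nm), gene = seq_len(nm),
                  corruption = "none", bulge_len = 0L)
  extra <- tibble(
    mirna = (0:4) %% nm + 1L,
    gene = nm + 1:5,
    corruption = c("seed_mismatch", "seed_mismatch", "seed_mismatch",
                   "wobble", "bulge"),
    bulge_len = c(0L, 0L, 0L, 0L, 10L)
  )
  dplyr::bind_rows(clean, extra) |>
    dplyr::mutate(offset = 60L,
                  region = ifelse(.data$gene %% 2 == 1, "CDS", "UTR3"))
}

apply_corruption <- function(site, mirna_seq, corruption, bulge_len) {
  sb <- strsplit(site, "")[[1]]
  mb <- strsplit(mirna_seq, "")[[1]]
  L <- length(mb)
  if (corruption == "seed_mismatch") {
    p <- 5L                       # miRNA seed position
    q <- L - p + 1L               # its partner within the site
    repl <- setdiff(RNA_BASES, pair_partners(mb[p]))[1]
    sb[q] <- repl
  } else if (corruption == "wobble") {
    cand <- which(mb %in% c("G", "U"))
    cand <- cand[cand >= 10 & cand <= L - 1]
    if (length(cand) == 0) return(site)  # no wobble-able position; leave clean
    p <- cand[1]
    sb[L - p + 1L] <- if (mb[p] == "G") "U" else "G"
  } else if (corruption == "bulge") {
    cut <- L - 12L                # between the partners of miRNA pos 12/13
    ins <- sample(RNA_BASES, bulge_len, replace = TRUE)
    sb <- c(sb[seq_len(cut)], ins, sb[(cut + 1):L])
  }
  paste(sb, collapse = "")
}

#' Generate transcript regions with planted hybridization sites
#'
#' Background sequence is uniform random RNA; each planted site is the
#' reverse complement of its miRNA with the configured corruption applied
#' (`seed_mismatch` toggles one seed partner to a non-pairing base, `wobble`
#' converts one Watson-Crick pair outside the seed to G:U, `bulge` inserts
#' `bulge_len` nucleotides mid-site on the target strand).
#'
#' @param cfg A [synth_config()].
#' @param mirnas Tibble from [gen_mirnas()].
#' @return List with `regions` (tibble `gene_id`, `accession`, `region`,
#'   `seq`) and `truth` (tibble `mirna_id`, `gene_id`, `region`, `offset`,
#'   `site_len`, `corruption`, `bulge_len`).
#' @export
gen_transcripts_with_sites <- function(cfg, mirnas) {
  sites <- cfg$planted_sites
  if (is.null(sites)) sites <- default_planted_sites(cfg)
  stopifnot(all(sites$mirna <= nrow(mirnas)),
            all(sites$gene <= cfg$n_transcripts))
  if (anyDuplicated(sites$gene) > 0) {
    stop("overlapping planted sites: one site per transcript", call. = FALSE)
  }
  withr::with_seed(cfg$seed + 202L, {
    regions <- tibble(
      gene_id = sprintf("G%03d", seq_len(cfg$n_transcripts)),
      accession = sprintf("ACC%05d", seq_len(cfg$n_transcripts)),
      region = ifelse(seq_len(cfg$n_transcripts) %% 2 == 1, "CDS", "UTR3"),
      seq = vapply(seq_len(cfg$n_transcripts), function(i) {
        paste(sample(RNA_BASES, cfg$region_len, replace = TRUE), collapse = "")
      }, character(1))
    )
    truth <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
      s <- sites[i, ]
      mseq <- mirnas$seq[s$mirna]
      site <- apply_corruption(revcomp_rna(mseq), mseq, s$corruption,
                               s$bulge_len)
      g <- s$gene
      old <- regions$seq[g]
      stopifnot(s$offset + nchar(site) <= nchar(old))
      regions$seq[g] <<- paste0(
        substr(old, 1, s$offset),
        site,
        substr(old, s$offset + nchar(site) + 1, nchar(old))
      )
      tibble(mirna_id = mirnas$id[s$mirna], gene_id = regions$gene_id[g],
             region = if (!is.null(s$region)) s$region else regions$region[g],
             offset = s$offset, site_len = nchar(site),
             corruption = s$corruption, bulge_len = s$bulge_len)
    })
    regions$region[match(truth$gene_id, regions$gene_id)] <- truth$region
    list(regions = regions, truth = truth)
  })
}

#' Generate an interaction network with planted modules and bridge hubs
#'
#' Each module is a dense Erdos-Renyi block (repaired to be connected);
#' there are no direct inter-module edges. Bridge hubs connect to
#' `bridge_degree` module genes spread across at least two modules, giving
#' them the highest degrees in the graph.
#'
#' @param cfg A [synth_config()].
#' @return List with `edges` (tibble `from`, `to`), `truth` (tibble `gene`,
#'   `module`) and `bridges` (character vector).
#' @export
gen_network <- function(cfg) {
  net <- cfg$network
  withr::with_seed(cfg$seed + 303L, {
    modules <- lapply(seq_len(net$n_modules), function(m) {
      sprintf("M%02d_G%03d", m, seq_len(net$module_size))
    })
    bridges <- sprintf("BRG%02d", seq_len(net$n_bridges))
    edges <- purrr::map_dfr(seq_len(net$n_modules), function(m) {
      genes <- modules[[m]]
      k <- length(genes)
      idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
      pick <- runif(nrow(idx)) < net$intra_p
      e <- tibble(from = genes[idx[pick, 1]], to = genes[idx[pick, 2]])
      # repair: connect any stray components so bridge deletion leaves one
      # component per module
      g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                         vertices = genes)
      comp <- igraph::components(g)
      while (comp$no > 1) {
        c1 <- names(comp$membership)[comp$membership == 1]
        c2 <- names(comp$membership)[comp$membership == 2]
        e <- dplyr::bind_rows(e, tibble(from = sample(c1, 1),
                                        to = sample(c2, 1)))
        g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                           vertices = genes)
        comp <- igraph::components(g)
      }
      e
    })
    all_module_genes <- unlist(modules)
    module_of <- rep(seq_len(net$n_modules),
                     each = net$module_size)
    # stratified wiring: every bridge touches every module with nearly equal
    # multiplicity, so each hub's weight reflects the whole network rather
    # than whichever module it happened to sample
    bridge_edges <- purrr::map_dfr(bridges, function(b) {
      base <- net$bridge_degree %/% net$n_modules
      extra <- sample(net$n_modules, net$bridge_degree %% net$n_modules)
      nb <- unlist(lapply(seq_len(net$n_modules), function(m) {
        sample(modules[[m]], base + (m %in% extra))
      }))
      tibble(from = b, to = nb)
    })
    list(
      edges = dplyr::bind_rows(edges, bridge_edges),
      truth = tibble(gene = all_module_genes,
                     module = module_of),
      bridges = bridges
    )
  })
}

#' Generate a random GO-like ontology and gene annotations
#'
#' Builds an acyclic `is_a` DAG whose roots are the slim categories, draws
#' background annotations at `background_rate`, and plants one enriched
#' term per configured module: a dedicated term assigned to `frac` of that
#' module's genes.
#'
#' @param cfg A [synth_config()].
#' @param network_truth The `truth`/`bridges` list from [gen_network()]
#'   (annotated genes are the network's genes).
#' @return List with `annotation` (a [go_annotation()]), `slim`
#'   (character vector) and `truth` (tibble `module`, `term_id`, `frac`).
#' @export
gen_annotations <- function(cfg, network_truth) {
  ann <- cfg$annotation
  genes <- c(network_truth$truth$gene, network_truth$bridges)
  withr::with_seed(cfg$seed + 404L, {
    slim <- sprintf("S%02d", seq_len(ann$n_slim))
    spec_terms <- sprintf("T%03d", seq_len(ann$n_terms))
    all_terms <- c(slim, spec_terms)
    parents <- c(
      replicate(ann$n_slim, character(0), simplify = FALSE),
      lapply(seq_len(ann$n_terms), function(i) {
        pool <- all_terms[seq_len(ann$n_slim + i - 1)]
        sample(pool, min(length(pool), sample(1:2, 1)))
      })
    )
    terms <- tibble(term_id = all_terms,
                    name = paste("synthetic process", all_terms),
                    namespace = "biological_process",
                    parents = parents)
    bg <- tibble(
      gene_id = rep(genes, each = ann$n_terms),
      term_id = rep(spec_terms, times = length(genes))
    )
    bg <- bg[runif(nrow(bg)) < ann$background_rate, ]
    planted <- ann$planted
    truth <- NULL
    planted_map <- NULL
    if (!is.null(planted) && nrow(planted) > 0) {
      truth <- purrr::map_dfr(seq_len(nrow(planted)), function(i) {
        m <- planted$module[i]
        term <- sprintf("T%03d", ann$n_terms - i + 1L)  # reserve tail terms
        mod_genes <- network_truth$truth$gene[network_truth$truth$module == m]
        chosen <- sample(mod_genes, round(planted$frac[i] * length(mod_genes)))
        planted_map <<- dplyr::bind_rows(
          planted_map, tibble(gene_id = chosen, term_id = term))
        tibble(module = m, term_id = term, frac = planted$frac[i])
      })
      bg <- dplyr::bind_rows(bg, planted_map)
    }
    list(annotation = go_annotation(terms, dplyr::distinct(bg)),
         slim = slim,
         truth = if (is.null(truth)) tibble(module = integer(),
                                            term_id = character(),
                                            frac = double()) else truth)
  })
}

#' Generate a tissue expression matrix with planted tiers
#'
#' Ubiquitous genes are expressed in all tissues, tissue-specific genes in
#' exactly one, highly-expressed genes in 2 to `n_tissues - 2` tissues with
#' one strong peak; truncated Gaussian noise (`noise_sd`) is added
#' everywhere.
#'
#' @param cfg A [synth_config()].
#' @param genes Character vector of gene ids.
#' @return List with `expr` (tibble `gene_id` + one column per tissue) and
#'   `truth` (tibble `gene_id`, `tier`, `tissue`).
#' @export
gen_expression <- function(cfg, genes) {
  ex <- cfg$expression
  tis <- ex$tissues
  nt <- length(tis)
  withr::with_seed(cfg$seed + 505L, {
    tier <- sample(names(ex$tier_probs), length(genes), replace = TRUE,
                   prob = ex$tier_probs)
    mat <- matrix(0, nrow = length(genes), ncol = nt,
                  dimnames = list(NULL, tis))
    spec_tissue <- rep(NA_character_, length(genes))
    for (i in seq_along(genes)) {
      if (tier[i] == "ubiquitous") {
        mat[i, ] <- ex$on_level
      } else if (tier[i] == "tissue_specific") {
        j <- sample.int(nt, 1)
        mat[i, j] <- ex$peak_level
        spec_tissue[i] <- tis[j]
      } else if (tier[i] == "highly_expressed") {
        k <- sample(2:(nt - 2), 1)
        js <- sample.int(nt, k)
        mat[i, js] <- ex$base_level
        mat[i, js[1]] <- ex$peak_level
      }
    }
    if (ex$noise_sd > 0) {
      mat <- pmax(mat + matrix(rnorm(length(mat), 0, ex$noise_sd),
                               nrow = nrow(mat)), 0)
    }
    list(
      expr = dplyr::bind_cols(tibble(gene_id = genes), as_tibble(mat)),
      truth = tibble(gene_id = genes, tier = tier, tissue = spec_tissue)
    )
  })
}
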