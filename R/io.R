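# Readers and writers for the package's plain-text interchange formats:
# FASTA with region tags, TSV tables ('.' for missing), the flat ontology
# format and YAML pipeline configuration. All TSVs have headers, stable
# column order, UTF-8, LF endings.

#' Read a FASTA file of RNA sequences with optional region tags
#'
#' Sequences are normalized to uppercase RNA (`T` -> `U`). A description
#' tag ` region=CDS` or ` region=3UTR` is parsed into the `region` column
#' (`3UTR` is stored as `UTR3`); records without a tag get `region = NA`.
#'
#' @param path FASTA file path.
#' @param default_region Region label for untagged records (e.g. `"UTR3"`),
#'   or `NULL` to leave `NA`.
#' @return Tibble `(id, region, seq)` in file order.
#' @export
read_fasta <- function(path, default_region = NULL) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("empty FASTA: ", path, call. = FALSE)
  full <- names(x)
  id <- sub("\\s.*$", "", full)
  if (anyDuplicated(id) > 0) {
    stop("duplicate FASTA id: ", id[duplicated(id)][1], call. = FALSE)
  }
  seqs <- as.character(x)
  if (any(!nzchar(seqs))) stop("empty FASTA record in ", path, call. = FALSE)
  region <- ifelse(grepl("region=", full),
                   sub(".*region=([^ ]+).*", "\\1", full), NA_character_)
  region[region %in% "3UTR"] <- "UTR3"
  if (!is.null(default_region)) region[is.na(region)] <- default_region
  tibble(id = id, region = region, seq = normalize_rna(unname(seqs)))
}

#' Write sequences to FASTA
#'
#' @param df Tibble with `id`, `seq`, and optionally `region` (emitted as a
#'   ` region=` tag, `UTR3` written as `3UTR`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(df, path) {
  hdr <- df$id
  if ("region" %in% names(df)) {
    tag <- ifelse(is.na(df$region), "",
                  paste0(" region=", sub("^UTR3$", "3UTR", df$region)))
    hdr <- paste0(hdr, tag)
  }
  writeLines(paste0(">", hdr, "\n", df$seq), path)
  invisible(path)
}

#' Read a two-column gene interaction edge list
#'
#' @param path TSV with columns `from`, `to` (header required).
#' @return Tibble `(from, to)`.
#' @export
read_edges <- function(path) {
  e <- readr::read_tsv(path, show_col_types = FALSE)
  if (nrow(e) == 0) stop("empty edge list: ", path, call. = FALSE)
  names(e)[1:2] <- c("from", "to")
  e[, 1:2]
}

#' Write a TSV with the package dialect
#'
#' Tab-separated, header, `.` for missing values, LF endings. List-columns
#' are collapsed with `|`.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_dot <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.list),
    ~ vapply(.x, function(v) paste(v, collapse = "|"), character(1))))
  readr::write_tsv(df, path, na = ".")
  invisible(path)
}

#' Read a package-dialect TSV
#'
#' @param path TSV path (`.` read as missing).
#' @return Tibble.
#' @export
read_tsv_dot <- function(path) {
  readr::read_tsv(path, na = c(".", ""), show_col_types = FALSE)
}

#' Read the flat ontology format
#'
#' A TSV with columns `term_id`, `name`, `namespace`, `is_a` (pipe-separated
#' parent ids, `.` for roots).
#'
#' @param path Ontology TSV path.
#' @return Tibble suitable as the `terms` argument of [go_annotation()].
#' @export
read_ontology <- function(path) {
  tab <- read_tsv_dot(path)
  stopifnot(all(c("term_id", "name", "is_a") %in% names(tab)))
  if (!"namespace" %in% names(tab)) tab$namespace <- "biological_process"
  tibble(term_id = tab$term_id, name = tab$name, namespace = tab$namespace,
         parents = lapply(tab$is_a, function(p) {
           if (is.na(p) || !nzchar(p)) character(0)
           else strsplit(p, "|", fixed = TRUE)[[1]]
         }))
}

#' Write the flat ontology format
#'
#' @param terms Term tibble (`term_id`, `name`, `namespace`, `parents`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(terms, path) {
  out <- tibble(
    term_id = terms$term_id, name = terms$name,
    namespace = terms$namespace,
    is_a = vapply(terms$parents, function(p) {
      if (length(p) == 0) NA_character_ else paste(p, collapse = "|")
    }, character(1))
  )
  write_tsv_dot(out, path)
}

#' Read gene-to-term annotations
#'
#' @param path Two-column TSV (`gene_id`, `term_id`).
#' @return Tibble `(gene_id, term_id)`.
#' @export
read_annotations <- function(path) {
  a <- readr::read_tsv(path, show_col_types = FALSE)
  names(a)[1:2] <- c("gene_id", "term_id")
  a[, 1:2]
}

#' Pipeline configuration
#'
#' Validates and assembles the configuration consumed by [run_pipeline()].
#' Unknown fields are rejected.
#'
#' @param mirnas,targets,edges,ontology,annotations,slim,expression,validated
#'   Input file paths (`validated`, `expression`, `slim` optional).
#' @param profile `"plant"` or `"human"` screening profile.
#' @param mfe_max,p_max Screening thresholds (see [filter_profile()]).
#' @param k_bridges,mode,tol Network stage parameters.
#' @param alpha,propagate Enrichment parameters.
#' @param n_shuffles,windows_per_shuffle Null-calibration parameters.
#' @param width,stride Scan parameters.
#' @param seed Master seed for every stochastic step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mirnas, targets, edges, ontology, annotations,
                            slim = NULL, expression = NULL, validated = NULL,
                            profile = "plant", mfe_max = -25, p_max = 0.05,
                            k_bridges = 15, mode = "paper", tol = 0.005,
                            alpha = 0.1, propagate = TRUE,
                            n_shuffles = 100, windows_per_shuffle = 30,
                            width = 40, stride = 1, seed = 42L) {
  cfg <- list(mirnas = mirnas, targets = targets, edges = edges,
              ontology = ontology, annotations = annotations, slim = slim,
              expression = expression, validated = validated,
              profile = profile, mfe_max = mfe_max, p_max = p_max,
              k_bridges = k_bridges, mode = mode, tol = tol, alpha = alpha,
              propagate = propagate, n_shuffles = n_shuffles,
              windows_per_shuffle = windows_per_shuffle, width = width,
              stride = stride, seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; unknown keys are an error.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, y)
}
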