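# RNA alphabet helpers shared across the package. All sequences are handled
# as uppercase RNA strings 5'->3'; the integer encoding A=0, C=1, G=2, U=3 is
# what the compiled duplex routines consume.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to uppercase RNA
#'
#' Accepts DNA or RNA in either case; `T` is rewritten to `U`. Any other
#' character is an error.
#'
#' @param x Character vector of sequences.
#' @return Character vector of uppercase RNA sequences.
#' @export
#' @examples
#' normalize_rna("acgt")
normalize_rna <- function(x) {
  out <- chartr("tT", "uU", x)
  out <- toupper(out)
  bad <- vapply(out, function(s) {
    any(!strsplit(s, "")[[1]] %in% RNA_BASES)
  }, logical(1))
  if (any(bad)) {
    stop("non-RNA characters in sequence(s): ",
         paste(utils::head(names(which(bad)), 3), collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

seq_to_int <- function(s) {
  match(strsplit(s, "")[[1]], RNA_BASES) - 1L
}

int_to_seq <- function(v) {
  paste(RNA_BASES[v + 1L], collapse = "")
}

#' Reverse complement of an RNA sequence
#'
#' @param x Character vector of RNA sequences (`A`, `C`, `G`, `U`).
#' @return Character vector of reverse complements, 5'->3'.
#' @export
#' @examples
#' revcomp_rna("ACGU")
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGU", "UGCA", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# TRUE iff (a, b) is an allowed pair; wc = TRUE restricts to Watson-Crick.
is_pair <- function(a, b, wc = FALSE) {
  p <- paste0(a, b)
  allowed <- if (wc) c("AU", "UA", "CG", "GC") else
    c("AU", "UA", "CG", "GC", "GU", "UG")
  p %in% allowed
}

# Dinucleotide-preserving shuffle (Altschul-Erikson): build the dinucleotide
# multigraph, shuffle each vertex's outgoing edge list while keeping a
# spanning arborescence into the final base, and walk the Eulerian path.
shuffle_dinuc <- function(s) {
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  if (n <= 3) return(s)
  first <- b[1]; last <- b[n]
  edges <- split(b[-1], factor(b[-n], levels = RNA_BASES))

  repeat {
    sh <- lapply(edges, function(e) if (length(e)) sample(e) else e)
    # connectivity check: from every vertex with outgoing edges, the last
    # outgoing edge must lead (transitively) to `last`
    lastout <- vapply(RNA_BASES, function(v) {
      e <- sh[[v]]
      if (length(e) == 0 || v == last) NA_character_ else e[length(e)]
    }, character(1))
    ok <- TRUE
    for (v in RNA_BASES) {
      if (is.na(lastout[v])) next
      seen <- character(0); cur <- v
      while (!is.na(lastout[cur]) && !(cur %in% seen)) {
        seen <- c(seen, cur); cur <- lastout[cur]
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }

  ptr <- setNames(rep(1L, 4), RNA_BASES)
  out <- character(n); out[1] <- first; cur <- first
  for (i in 2:n) {
    nxt <- sh[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
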