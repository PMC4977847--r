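PAIR_CODES <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Nearest-neighbor duplex energy model
#'
#' Builds the energy model used by [duplex_mfe()] and [scan_transcript()]:
#' a 6x6 stack free-energy table over the allowed pair types (`AU`, `UA`,
#' `CG`, `GC`, `GU`, `UG`), linear bulge and internal-loop penalties, and a
#' helix-end penalty. The default stack values are Turner-style
#' nearest-neighbor free energies (kcal/mol at 37 degrees C) read from the
#' versioned parameter file shipped with the package, with G:U wobble steps
#' weaker than Watson-Crick ones.
#'
#' Energies are additive over consecutive base-pair steps of a single
#' contiguous intermolecular duplex:
#' stacked steps cost `stacks[pair1, pair2]`; a bulge of `L` unpaired
#' nucleotides on one side costs `bulge_open + bulge_ext * L`; an internal
#' loop with `l1`/`l2` unpaired nucleotides costs
#' `loop_open + loop_ext * (l1 + l2)`; each helix end adds `end_penalty`.
#'
#' @param stack_file Path to a stack-parameter TSV (`pair1`, `pair2`, `dg`).
#'   Defaults to the packaged table.
#' @param bulge_open,bulge_ext Bulge penalty intercept and per-nucleotide
#'   slope (kcal/mol, non-negative).
#' @param loop_open,loop_ext Internal-loop penalty intercept and
#'   per-nucleotide slope (kcal/mol, non-negative).
#' @param end_penalty Penalty per helix end (kcal/mol, non-negative).
#' @return An object of class `energy_model`.
#' @export
#' @examples
#' m <- energy_model()
#' m$stacks["GC", "CG"]
energy_model <- function(stack_file = NULL,
                         bulge_open = 3.8, bulge_ext = 0.5,
                         loop_open = 4.0, loop_ext = 0.3,
                         end_penalty = 0.45) {
  if (is.null(stack_file)) {
    stack_file <- system.file("extdata", "stack_energies.tsv",
                              package = "crossmir", mustWork = TRUE)
  }
  tab <- readr::read_tsv(stack_file, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("pair1", "pair2", "dg") %in% names(tab)))
  stacks <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_CODES, PAIR_CODES))
  for (i in seq_len(nrow(tab))) {
    stacks[tab$pair1[i], tab$pair2[i]] <- tab$dg[i]
  }
  if (anyNA(stacks)) stop("incomplete stack table", call. = FALSE)
  wc <- c("AU", "UA", "CG", "GC")
  if (any(stacks[wc, wc] >= 0)) {
    stop("Watson-Crick stack energies must be strictly negative", call. = FALSE)
  }
  pen <- c(bulge_open, bulge_ext, loop_open, loop_ext, end_penalty)
  if (any(pen < 0)) stop("penalties must be non-negative", call. = FALSE)
  structure(
    list(stacks = stacks,
         bulge_open = bulge_open, bulge_ext = bulge_ext,
         loop_open = loop_open, loop_ext = loop_ext,
         end_penalty = end_penalty),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model>\n")
  cat("  stacks: 6x6 table, WC range [",
      min(x$stacks[1:4, 1:4]), ",", max(x$stacks[1:4, 1:4]), "] kcal/mol\n")
  cat("  bulge:", x$bulge_open, "+", x$bulge_ext, "* L\n")
  cat("  internal loop:", x$loop_open, "+", x$loop_ext, "* (l1+l2)\n")
  cat("  helix end:", x$end_penalty, "per end\n")
  invisible(x)
}
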