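# Seed-anchored miRNA:transcript hybridization. The heavy lifting (the
# intermolecular MFE dynamic program and the window scan) is compiled; this
# file owns the user-facing surface, pairing-string construction and the
# empirical extreme-value p-value calibration.

EULER_GAMMA <- 0.5772156649015329

resolve_caps <- function(max_bulge, max_loop) {
  c(bulge = if (is.null(max_bulge)) -1L else as.integer(max_bulge),
    loop  = if (is.null(max_loop))  -1L else as.integer(max_loop))
}

#' Minimum-free-energy intermolecular duplex between a miRNA and a window
#'
#' Computes the lowest-energy purely intermolecular, non-crossing pairing of
#' a miRNA (5'->3') against a target window read antiparallel, as a single
#' contiguous duplex with bulges and internal loops subject to optional
#' length caps. This is the primitive behind [scan_transcript()].
#'
#' @param mirna_seq,window_seq Uppercase RNA strings.
#' @param model An [energy_model()].
#' @param max_bulge,max_loop Maximum bulge length / internal-loop side length
#'   in nucleotides, or `NULL` for uncapped.
#' @return A list with `mfe` (kcal/mol; `Inf` when no admissible pairing
#'   exists), `pairs` (tibble of `mirna_pos`, `window_pos` 1-based, and pair
#'   `type` `"W"`/`"G"` for Watson-Crick vs G:U), and `pairing` (a printable
#'   three-line structure string).
#' @export
#' @examples
#' m <- energy_model()
#' duplex_mfe("GGGGGG", "CCCCCC", m)$mfe
duplex_mfe <- function(mirna_seq, window_seq, model = energy_model(),
                       max_bulge = NULL, max_loop = NULL) {
  if (!nzchar(mirna_seq) || !nzchar(window_seq)) {
    stop("empty sequence", call. = FALSE)
  }
  caps <- resolve_caps(max_bulge, max_loop)
  r <- duplex_mfe_cpp(seq_to_int(mirna_seq), seq_to_int(window_seq),
                      model$stacks, model$bulge_open, model$bulge_ext,
                      model$loop_open, model$loop_ext, model$end_penalty,
                      caps[["bulge"]], caps[["loop"]])
  if (!is.finite(r$mfe)) {
    return(list(mfe = Inf,
                pairs = tibble(mirna_pos = integer(), window_pos = integer(),
                               type = character()),
                pairing = ""))
  }
  pairs <- pair_table(r$mirna_pos, r$window_pos, mirna_seq, window_seq)
  list(mfe = r$mfe, pairs = as_tibble(pairs),
       pairing = pairing_string(pairs, mirna_seq, window_seq))
}

# lightweight (plain-list) pair table; hot path, so no tibble here
pair_table <- function(mirna_pos, window_pos, mirna_seq, window_seq) {
  mb <- strsplit(mirna_seq, "")[[1]][mirna_pos]
  wb <- strsplit(window_seq, "")[[1]][window_pos]
  list(mirna_pos = as.integer(mirna_pos),
       window_pos = as.integer(window_pos),
       type = ifelse(paste0(mb, wb) %in% c("GU", "UG"), "G", "W"))
}

# Three-line alignment: miRNA 5'->3' / match line ('|' WC, ':' G:U) /
# target 3'->5', columns padded with '-' across bulges and loops; lines
# joined by '&' so the whole structure fits one TSV field.
pairing_string <- function(pairs, mirna_seq, window_seq) {
  np <- length(pairs$mirna_pos)
  if (np == 0) return("")
  mch <- strsplit(mirna_seq, "")[[1]]
  wch <- strsplit(window_seq, "")[[1]]
  top <- character(0); mid <- character(0); bot <- character(0)
  for (t in seq_len(np)) {
    if (t > 1) {
      gm <- pairs$mirna_pos[t] - pairs$mirna_pos[t - 1] - 1L
      gj <- pairs$window_pos[t - 1] - pairs$window_pos[t] - 1L
      mun <- if (gm > 0) mch[(pairs$mirna_pos[t - 1] + 1):(pairs$mirna_pos[t] - 1)] else character(0)
      wun <- if (gj > 0) wch[(pairs$window_pos[t - 1] - 1):(pairs$window_pos[t] + 1)] else character(0)
      k <- max(gm, gj)
      if (k > 0) {
        top <- c(top, mun, rep("-", k - gm))
        bot <- c(bot, wun, rep("-", k - gj))
        mid <- c(mid, rep(" ", k))
      }
    }
    top <- c(top, mch[pairs$mirna_pos[t]])
    bot <- c(bot, wch[pairs$window_pos[t]])
    mid <- c(mid, if (pairs$type[t] == "W") "|" else ":")
  }
  paste(paste(top, collapse = ""), paste(mid, collapse = ""),
        paste(bot, collapse = ""), sep = "&")
}

encode_pairs <- function(pairs, offset = 0L) {
  # "mirnaPos:regionPos0:type" triplets; regionPos0 is 0-based on the region
  paste(sprintf("%d:%d:%s", pairs$mirna_pos,
                pairs$window_pos - 1L + offset, pairs$type),
        collapse = ";")
}

#' Parse the compact pair encoding of a hit
#'
#' @param pairs_chr Character vector of `pairs` fields from a hit table.
#' @return A list of tibbles with `mirna_pos` (1-based), `region_pos`
#'   (0-based) and `type`.
#' @export
parse_pairs <- function(pairs_chr) {
  lapply(pairs_chr, function(p) {
    if (is.na(p) || !nzchar(p)) {
      return(tibble(mirna_pos = integer(), region_pos = integer(),
                    type = character()))
    }
    parts <- strsplit(strsplit(p, ";")[[1]], ":")
    tibble(mirna_pos = as.integer(vapply(parts, `[`, "", 1)),
           region_pos = as.integer(vapply(parts, `[`, "", 2)),
           type = vapply(parts, `[`, "", 3))
  })
}

#' Scan a transcript region for miRNA hybridization sites
#'
#' Slides a window along the region, computes the duplex MFE in each window,
#' and reduces overlapping windows to local-minimum sites: a hit is retained
#' iff no overlapping hit has a lower MFE (ties broken leftmost). Only
#' stabilizing duplexes (MFE < 0) are reported.
#'
#' @param mirna One-row data frame (or list) with `id` and `seq`.
#' @param region One-row data frame (or list) with `gene_id`, `accession`,
#'   `region` and `seq`.
#' @param model An [energy_model()].
#' @param max_bulge,max_loop Structural caps passed to the dynamic program
#'   (`NULL` = uncapped).
#' @param width Scan window width in nucleotides.
#' @param stride Window step in nucleotides (>= 1).
#' @return A tibble of hits sorted by MFE ascending with columns `mirna_id`,
#'   `gene_id`, `accession`, `region`, `target_start`/`target_end` (0-based,
#'   half-open on the region), `mfe`, `pvalue` (`NA` until calibrated),
#'   `pairing` and `pairs`.
#' @export
scan_transcript <- function(mirna, region, model = energy_model(),
                            max_bulge = NULL, max_loop = NULL,
                            width = 40, stride = 1) {
  stopifnot(stride >= 1)
  mseq <- mirna$seq[[1]]
  rseq <- region$seq[[1]]
  empty <- tibble(mirna_id = character(), gene_id = character(),
                  accession = character(), region = character(),
                  target_start = integer(), target_end = integer(),
                  mfe = double(), pvalue = double(),
                  pairing = character(), pairs = character())
  if (nchar(rseq) < nchar(mseq)) return(empty)
  raw <- scan_region_cpp(seq_to_int(mseq), seq_to_int(rseq), model$stacks,
                         model$bulge_open, model$bulge_ext,
                         model$loop_open, model$loop_ext, model$end_penalty,
                         resolve_caps(max_bulge, max_loop)[["bulge"]],
                         resolve_caps(max_bulge, max_loop)[["loop"]],
                         as.integer(width), as.integer(stride))
  if (length(raw) == 0) return(empty)
  wlen <- min(width, nchar(rseq))
  ptabs <- lapply(raw, function(h) {
    wseq <- substr(rseq, h$offset + 1, h$offset + wlen)
    pair_table(h$mirna_pos, h$window_pos, mseq, wseq)
  })
  offs <- vapply(raw, function(h) as.integer(h$offset), integer(1))
  hits <- tibble(
    mirna_id = mirna$id[[1]], gene_id = region$gene_id[[1]],
    accession = region$accession[[1]], region = region$region[[1]],
    target_start = offs +
      vapply(ptabs, function(p) min(p$window_pos), integer(1)) - 1L,
    target_end = offs +
      vapply(ptabs, function(p) max(p$window_pos), integer(1)),
    mfe = vapply(raw, function(h) h$mfe, double(1)),
    pvalue = NA_real_,
    pairing = vapply(seq_along(raw), function(i) {
      wseq <- substr(rseq, offs[i] + 1, offs[i] + wlen)
      pairing_string(ptabs[[i]], mseq, wseq)
    }, character(1)),
    pairs = vapply(seq_along(raw), function(i) {
      encode_pairs(ptabs[[i]], offset = offs[i])
    }, character(1))
  )
  hits <- dplyr::distinct(hits, .data$target_start, .data$target_end,
                          .data$mfe, .keep_all = TRUE)
  keep <- local_minimum_sites(hits$target_start, hits$target_end, hits$mfe)
  hits <- hits[keep, , drop = FALSE]
  dplyr::arrange(hits, .data$mfe, .data$target_start)
}

# retained iff no overlapping hit has lower mfe, or equal mfe and an earlier
# start (leftmost wins among ties)
local_minimum_sites <- function(start, end, mfe) {
  n <- length(start)
  keep <- logical(n)
  for (i in seq_len(n)) {
    ov <- start < end[i] & end > start[i]
    ov[i] <- FALSE
    better <- mfe[ov] < mfe[i] |
      (mfe[ov] == mfe[i] & start[ov] < start[i])
    keep[i] <- !any(better)
  }
  keep
}

#' Predict hybridization sites for every miRNA x transcript pair
#'
#' Tidy umbrella over [scan_transcript()].
#'
#' @param mirnas Tibble with `id`, `seq`.
#' @param regions Tibble with `gene_id`, `accession`, `region`, `seq`.
#' @inheritParams scan_transcript
#' @return One hit tibble, sorted by miRNA then MFE.
#' @export
predict_targets <- function(mirnas, regions, model = energy_model(),
                            max_bulge = NULL, max_loop = NULL,
                            width = 40, stride = 1) {
  purrr::map_dfr(seq_len(nrow(mirnas)), function(i) {
    purrr::map_dfr(seq_len(nrow(regions)), function(j) {
      scan_transcript(mirnas[i, ], regions[j, ], model,
                      max_bulge = max_bulge, max_loop = max_loop,
                      width = width, stride = stride)
    })
  }) |>
    dplyr::arrange(.data$mirna_id, .data$mfe, .data$gene_id)
}

#' Seed-rule check on predicted hits
#'
#' TRUE iff miRNA positions 2-8 (1-based, seven nucleotides) are each paired
#' Watson-Crick (G:U excluded) with contiguous target nucleotides.
#'
#' @param hits Hit tibble (rows from [scan_transcript()]).
#' @param seed_from,seed_to Seed span in 1-based miRNA coordinates.
#' @return Logical vector, one element per hit.
#' @export
seed_match <- function(hits, seed_from = 2L, seed_to = 8L) {
  vapply(parse_pairs(hits$pairs), function(pt) {
    sp <- pt[pt$mirna_pos >= seed_from & pt$mirna_pos <= seed_to, ]
    if (nrow(sp) != seed_to - seed_from + 1L) return(FALSE)
    if (any(sp$type != "W")) return(FALSE)
    all(diff(sp$mirna_pos) == 1L) && all(diff(sp$region_pos) == -1L)
  }, logical(1))
}

# Structure measures used by the screening filters: the longest single bulge
# and the longest internal-loop side, read off the traceback pairing.
structure_measures <- function(pairs_chr) {
  res <- vapply(parse_pairs(pairs_chr), function(pt) {
    if (nrow(pt) < 2) return(c(0, 0))
    gm <- diff(pt$mirna_pos) - 1L
    gj <- -diff(pt$region_pos) - 1L
    bulge <- ifelse(xor(gm > 0, gj > 0), gm + gj, 0L)
    loop <- ifelse(gm > 0 & gj > 0, pmax(gm, gj), 0L)
    c(max(bulge, 0L), max(loop, 0L))
  }, double(2))
  tibble(max_bulge_len = res[1, ], max_loop_side = res[2, ])
}

#' Calibrate a per-miRNA null distribution of duplex energies
#'
#' Generates null best-hit scores by dinucleotide-preserving shuffling of
#' windows sampled from the scanned regions, then fits a minimum
#' extreme-value (Gumbel) distribution by the method of moments. Each
#' shuffle replicate draws `windows_per_shuffle` windows, shuffles each, and
#' records the best (lowest) MFE across them.
#'
#' @param mirna One-row data frame (or list) with `id` and `seq`.
#' @param regions Tibble of transcript regions to draw windows from.
#' @param model An [energy_model()].
#' @param n_shuffles Number of null replicates (>= 100 recommended).
#' @param seed Integer seed making the calibration reproducible.
#' @param max_bulge,max_loop,width Scan parameters (match the real scan).
#' @param windows_per_shuffle Windows drawn per replicate.
#' @return An object of class `null_calibration` with fields `mirna_id`,
#'   `mu` (Gumbel location on the MFE scale), `beta` (scale, floored at
#'   1e-6), `n_shuffles`, `shuffle_seed`, and the null `scores`.
#' @export
calibrate_null <- function(mirna, regions, model = energy_model(),
                           n_shuffles = 100, seed = 1L,
                           max_bulge = NULL, max_loop = NULL,
                           width = 40, windows_per_shuffle = 30) {
  mseq <- mirna$seq[[1]]
  caps <- resolve_caps(max_bulge, max_loop)
  wins <- unlist(lapply(regions$seq, function(s) {
    L <- nchar(s)
    w <- min(width, L)
    if (L < nchar(mseq)) return(character(0))
    starts <- seq(1, L - w + 1, by = w)  # non-overlapping window tiling
    vapply(starts, function(st) substr(s, st, st + w - 1), character(1))
  }))
  if (length(wins) == 0) stop("no scannable windows for calibration", call. = FALSE)
  mint <- seq_to_int(mseq)
  scores <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      pick <- sample(wins, min(windows_per_shuffle, length(wins)),
                     replace = length(wins) < windows_per_shuffle)
      best <- Inf
      for (w in pick) {
        sh <- shuffle_dinuc(w)
        r <- duplex_mfe_cpp(mint, seq_to_int(sh), model$stacks,
                            model$bulge_open, model$bulge_ext,
                            model$loop_open, model$loop_ext,
                            model$end_penalty, caps[["bulge"]], caps[["loop"]])
        if (r$mfe < best) best <- r$mfe
      }
      best
    }, double(1))
  })
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0) {
    stop("null calibration failed: no admissible pairing in any shuffle",
         call. = FALSE)
  }
  beta <- max(sd(scores) * sqrt(6) / pi, 1e-6)
  if (!is.finite(beta)) beta <- 1e-6
  mu <- mean(scores) + EULER_GAMMA * beta
  structure(
    list(mirna_id = mirna$id[[1]], mu = mu, beta = beta,
         n_shuffles = as.integer(n_shuffles), shuffle_seed = as.integer(seed),
         scores = scores),
    class = "null_calibration"
  )
}

#' @export
print.null_calibration <- function(x, ...) {
  cat("<null_calibration>", x$mirna_id,
      sprintf(" Gumbel(min) mu = %.3f, beta = %.3f, n = %d\n",
              x$mu, x$beta, x$n_shuffles))
  invisible(x)
}

#' Calibrate nulls for a set of miRNAs
#'
#' @param mirnas Tibble with `id`, `seq`.
#' @param seed Base seed; miRNA `i` uses `seed + i`.
#' @inheritParams calibrate_null
#' @return Named list of `null_calibration` objects keyed by miRNA id.
#' @export
calibrate_nulls <- function(mirnas, regions, model = energy_model(),
                            n_shuffles = 100, seed = 1L, ...) {
  calibs <- lapply(seq_len(nrow(mirnas)), function(i) {
    calibrate_null(mirnas[i, ], regions, model, n_shuffles = n_shuffles,
                   seed = seed + i, ...)
  })
  setNames(calibs, mirnas$id)
}

#' Extreme-value p-value of a hit energy
#'
#' Probability that the calibrated null best-hit MFE is at least as low as
#' the observed one, under the fitted minimum-Gumbel distribution.
#'
#' @param mfe Numeric vector of hit energies (kcal/mol).
#' @param calib A `null_calibration`.
#' @return P-values in `[0, 1]`, monotone non-increasing as MFE decreases.
#' @export
hit_pvalue <- function(mfe, calib) {
  p <- 1 - exp(-exp((mfe - calib$mu) / calib$beta))
  pmin(pmax(p, 0), 1)
}

#' Attach calibrated p-values to a hit table
#'
#' @param hits Hit tibble.
#' @param calibs Named list from [calibrate_nulls()].
#' @return `hits` with the `pvalue` column filled.
#' @export
add_pvalues <- function(hits, calibs) {
  if (nrow(hits) == 0) return(hits)
  hits$pvalue <- vapply(seq_len(nrow(hits)), function(i) {
    cal <- calibs[[hits$mirna_id[i]]]
    if (is.null(cal)) return(NA_real_)
    hit_pvalue(hits$mfe[i], cal)
  }, double(1))
  hits
}

#' @export
glance.null_calibration <- function(x, ...) {
  tibble(mirna_id = x$mirna_id, mu = x$mu, beta = x$beta,
         n_shuffles = x$n_shuffles, shuffle_seed = x$shuffle_seed)
}
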