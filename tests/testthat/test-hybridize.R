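test_that("dynamic program equals exhaustive enumeration on small duplexes", {
  m <- default_model()
  u <- uniform_model(-3.3)

  # fully complementary G/C hexamer: five identical stacks plus two ends
  r <- duplex_mfe("GGGGGG", "CCCCCC", u)
  expect_equal(r$mfe, 5 * (-3.3) + 2 * u$end_penalty)
  expect_equal(r$mfe, enum_mfe("GGGGGG", "CCCCCC", u))

  # no admissible pairing -> infinite-energy sentinel, not an error
  r0 <- duplex_mfe("AAAA", "AAAA", m)
  expect_identical(r0$mfe, Inf)
  expect_equal(nrow(r0$pairs), 0)

  expect_error(duplex_mfe("", "ACGU", m), "empty")

  withr::with_seed(101, {
    caps_sets <- list(c(-1L, -1L), c(9L, 5L), c(3L, 2L), c(-1L, 5L))
    for (i in 1:120) {
      ms <- rand_rna(sample(4:10, 1))
      ws <- rand_rna(sample(4:12, 1))
      caps <- caps_sets[[sample(4, 1)]]
      dp <- dp_mfe(ms, ws, m, caps[1], caps[2])
      en <- enum_mfe(ms, ws, m, caps[1], caps[2])
      expect_identical(is.finite(dp), is.finite(en))
      if (is.finite(en)) expect_lt(abs(dp - en), 1e-9)
    }
  })
})

test_that("tightening bulge or loop caps never improves the MFE", {
  m <- default_model()
  withr::with_seed(202, {
    for (i in 1:40) {
      ms <- rand_rna(15)
      ws <- rand_rna(30)
      free <- dp_mfe(ms, ws, m, -1L, -1L)
      for (caps in list(c(9L, 5L), c(4L, 2L), c(1L, 1L), c(0L, 0L))) {
        capped <- dp_mfe(ms, ws, m, caps[1], caps[2])
        expect_gte(capped, free - 1e-12)
      }
      # nested caps are monotone among themselves too
      expect_gte(dp_mfe(ms, ws, m, 2L, 1L), dp_mfe(ms, ws, m, 9L, 5L) - 1e-12)
    }
  })
})

test_that("traceback pairing reproduces the reported energy and never crosses", {
  m <- default_model()
  withr::with_seed(303, {
    for (i in 1:25) {
      ms <- rand_rna(21)
      ws <- rand_rna(40)
      r <- duplex_mfe(ms, ws, m)
      if (!is.finite(r$mfe)) next
      pt <- r$pairs
      expect_true(all(diff(pt$mirna_pos) > 0))
      expect_true(all(diff(pt$window_pos) < 0))  # antiparallel, non-crossing
      e <- 2 * m$end_penalty
      for (t in seq_len(nrow(pt))[-1]) {
        gi <- pt$mirna_pos[t] - pt$mirna_pos[t - 1] - 1
        gk <- pt$window_pos[t - 1] - pt$window_pos[t] - 1
        p1 <- paste0(substr(ms, pt$mirna_pos[t - 1], pt$mirna_pos[t - 1]),
                     substr(ws, pt$window_pos[t - 1], pt$window_pos[t - 1]))
        p2 <- paste0(substr(ms, pt$mirna_pos[t], pt$mirna_pos[t]),
                     substr(ws, pt$window_pos[t], pt$window_pos[t]))
        e <- e + if (gi == 0 && gk == 0) m$stacks[p1, p2]
        else if (gi == 0 || gk == 0) m$bulge_open + m$bulge_ext * (gi + gk)
        else m$loop_open + m$loop_ext * (gi + gk)
      }
      expect_equal(e, r$mfe, tolerance = 1e-9)
    }
  })
})

test_that("planted sites are recovered as unique local-minimum hits", {
  m <- default_model()
  withr::with_seed(404, {
    mseq <- rand_rna(21)
    site <- revcomp_rna(mseq)
    mk_region <- function(seq) {
      list(gene_id = "g1", accession = "a1", region = "CDS", seq = seq)
    }
    mirna <- list(id = "m1", seq = mseq)

    reg <- mk_region(paste0(rand_rna(17), site, rand_rna(80)))
    h <- scan_transcript(mirna, reg, m)
    top <- h[h$mfe == min(h$mfe), ]
    expect_equal(nrow(top), 1)
    expect_equal(top$target_start, 17L)
    expect_equal(top$target_end, 17L + 21L)

    # a full reverse complement of a 21-nt miRNA is strongly stabilizing
    expect_lt(top$mfe, -25)

    # two identical planted sites, far apart -> both survive the reduction
    reg2 <- mk_region(paste0(rand_rna(10), site, rand_rna(60), site,
                             rand_rna(30)))
    h2 <- scan_transcript(mirna, reg2, m)
    strong <- h2[h2$mfe < -25, ]
    expect_equal(sort(strong$target_start), c(10L, 91L))

    # determinism at stride 1
    h3 <- scan_transcript(mirna, reg, m)
    expect_identical(h, h3)

    # region shorter than the miRNA -> empty
    expect_equal(nrow(scan_transcript(mirna, mk_region("ACGUACGU"), m)), 0)
  })
})

test_that("seed rule demands contiguous Watson-Crick pairing at positions 2-8", {
  m <- default_model()
  withr::with_seed(505, {
    mseq <- rand_rna(21)
    mirna <- list(id = "m1", seq = mseq)
    scan1 <- function(site) {
      reg <- list(gene_id = "g", accession = "a", region = "CDS",
                  seq = paste0(rand_rna(30), site, rand_rna(30)))
      h <- scan_transcript(mirna, reg, m)
      h[which.min(h$mfe), ]
    }
    clean <- scan1(revcomp_rna(mseq))
    expect_true(seed_match(clean))

    # corrupt the partner of miRNA position 5 (inside the seed)
    mis5 <- scan1(crossmir:::apply_corruption(revcomp_rna(mseq), mseq,
                                              "seed_mismatch", 0L))
    expect_false(seed_match(mis5))

    # mismatch at position 12 only: seed untouched
    sb <- strsplit(revcomp_rna(mseq), "")[[1]]
    mb <- strsplit(mseq, "")[[1]]
    q <- 21 - 12 + 1
    sb[q] <- setdiff(c("A", "C", "G", "U"),
                     crossmir:::pair_partners(mb[12]))[1]
    mis12 <- scan1(paste(sb, collapse = ""))
    expect_true(seed_match(mis12))
  })
})

test_that("null calibration is reproducible and behaves like a minimum Gumbel", {
  m <- default_model()
  withr::with_seed(606, {
    mirna <- list(id = "m1", seq = rand_rna(21))
    regs <- tibble::tibble(gene_id = "g1", accession = "a", region = "CDS",
                           seq = rand_rna(240))
    c1 <- calibrate_null(mirna, regs, m, n_shuffles = 100, seed = 7,
                         windows_per_shuffle = 5)
    c2 <- calibrate_null(mirna, regs, m, n_shuffles = 100, seed = 7,
                         windows_per_shuffle = 5)
    expect_identical(c(c1$mu, c1$beta), c(c2$mu, c2$beta))
    expect_gt(c1$beta, 0)

    # Gumbel identity at the location parameter
    expect_equal(hit_pvalue(c1$mu, c1), 1 - exp(-1), tolerance = 1e-12)
    # limits and monotonicity
    expect_equal(hit_pvalue(-1e6, c1), 0)
    mfes <- seq(-40, 0, by = 0.5)
    expect_true(all(diff(hit_pvalue(mfes, c1)) >= 0))
    expect_true(all(hit_pvalue(mfes, c1) >= 0 & hit_pvalue(mfes, c1) <= 1))
  })
})

test_that("degenerate nulls fall back to a floored scale", {
  cal <- structure(list(mirna_id = "m", mu = -10, beta = 1e-6,
                        n_shuffles = 100L, shuffle_seed = 1L,
                        scores = rep(-10, 100)),
                   class = "null_calibration")
  # effectively a step function around mu
  expect_lt(hit_pvalue(-10.001, cal), 1e-12)
  expect_equal(hit_pvalue(-9.999, cal), 1)
})

test_that("dinucleotide shuffling preserves dinucleotide composition", {
  dinucs <- function(s) {
    b <- strsplit(s, "")[[1]]
    table(paste0(b[-length(b)], b[-1]))
  }
  withr::with_seed(707, {
    for (i in 1:20) {
      s <- rand_rna(40)
      sh <- crossmir:::shuffle_dinuc(s)
      expect_equal(nchar(sh), nchar(s))
      expect_identical(dinucs(sh), dinucs(s))
    }
  })
})
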