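test_that("discover_candidate_loci recovers planted loci", {
  pl <- make_planted(n = 5, seed = 31, divergence = 0.05,
                     classes = c("full_length", "truncated", "solo"))
  # query library: the planted elements' own (element-oriented) sequences
  lib <- setNames(pl$truth$sequence, pl$truth$element_id)
  hits <- discover_candidate_loci(pl$genome, lib, k = 12, min_chain_hits = 3,
                                  max_gap = 500)
  tr <- pl$truth
  expect_equal(nrow(hits), nrow(tr))
  for (i in seq_len(nrow(tr))) {
    h <- hits[hits$chromosome == tr$chromosome[i] &
                hits$end > tr$start[i] & hits$start < tr$end[i], ]
    expect_equal(nrow(h), 1L)
    ov <- min(h$end, tr$end[i]) - max(h$start, tr$start[i])
    expect_gte(ov / (tr$end[i] - tr$start[i]), 0.9)  # reciprocal overlap
    expect_gte(ov / (h$end - h$start), 0.9)
    expect_identical(h$strand, tr$strand[i])
  }

  # background-only genome: no hits at min_chain_hits >= 3
  bg <- list(chrB = generate_background(50000, 0.42, 5))
  expect_equal(nrow(discover_candidate_loci(bg, lib, min_chain_hits = 3)), 0)
})

test_that("discovery recall is 1.0 on diverged copies at k = 12", {
  # plant copies diverged from a single consensus by d <= 0.08
  cons <- random_seq(3000, seed = 8)
  gs <- genome_spec(c(chr1 = 100000L), seed = 8)
  bg <- generate_background(100000, 0.42, 88)
  pos <- c(10000, 40000, 70000)
  genome <- bg
  copies <- lapply(seq_along(pos), function(i)
    perturb_seq(cons, 0.08, seed = 100 + i))
  for (i in rev(seq_along(pos)))
    genome <- paste0(substr(genome, 1, pos[i]), copies[[i]],
                     substr(genome, pos[i] + 1, nchar(genome)))
  hits <- discover_candidate_loci(list(chr1 = genome), c(cons = cons),
                                  k = 12)
  found <- vapply(seq_along(pos), function(i) {
    s <- pos[i] + 3000 * (i - 1)  # earlier insertions shift later copies
    any(hits$start < s + 3000 & hits$end > s)
  }, logical(1))
  expect_true(all(found))
})

test_that("find_ltr_pair locates planted pairs and rejects solos", {
  sp0 <- element_spec("full_length", ltr_length = 500, ltr_divergence = 0,
                      internal_length = 2000)
  b0 <- build_element(sp0, seed = 17)
  pair <- find_ltr_pair(b0$sequence)
  expect_false(is.null(pair))
  expect_equal(pair$identity, 1.0)
  f <- b0$features
  expect_equal(pair$ltr5_interval,
               c(f$start[f$feature == "ltr5"], f$end[f$feature == "ltr5"]))
  expect_equal(pair$ltr3_interval,
               c(f$start[f$feature == "ltr3"], f$end[f$feature == "ltr3"]))

  solo <- build_element(element_spec("solo", ltr_length = 600,
                                     pbs_trna = "none",
                                     psf_motif_count = 0,
                                     internal_length = 0), seed = 18)
  expect_null(find_ltr_pair(solo$sequence))

  # divergence 0.05: identity within the 99% binomial CI of 0.95
  sp5 <- element_spec("full_length", ltr_length = 600, ltr_divergence = 0.05,
                      internal_length = 2000)
  b5 <- build_element(sp5, seed = 19)
  p5 <- find_ltr_pair(b5$sequence, min_identity = 0.8)
  expect_false(is.null(p5))
  expect_lte(abs(p5$identity - 0.95), 2.576 * sqrt(0.05 * 0.95 / 600) + 0.01)
})

test_that("detect_tsd finds the longest terminal duplication", {
  expect_equal(detect_tsd(paste0(random_seq(20, 1), "ACGT"),
                          paste0("ACGT", random_seq(20, 2)))$length, 4)
  left <- paste0(random_seq(20, 3), "AACGT")
  right <- paste0("AACGT", random_seq(20, 4))
  call <- detect_tsd(left, right)
  expect_equal(call$length, 5)     # longest wins over the embedded 4-mer
  expect_identical(call$motif, "AACGT")
  expect_null(detect_tsd("CCCCCCCCCCCC", "GGGGGGGGGGGG"))
  expect_error(detect_tsd("ACGT", "ACGTACGTACGT"), "max_len")

  # brute-force oracle over all L on random flank pairs
  ltrscape:::with_seed(55, {
    for (rep in 1:20) {
      L <- sample(0:10, 1)
      core <- if (L > 0) random_seq(L) else ""
      left <- paste0(random_seq(15), core)
      right <- paste0(core, random_seq(15))
      brute <- NA
      nl <- nchar(left)
      for (k in 10:2)
        if (substr(left, nl - k + 1, nl) == substr(right, 1, k)) {
          brute <- k; break
        }
      got <- detect_tsd(left, right)
      if (is.na(brute)) expect_null(got) else expect_equal(got$length, brute)
    }
  })
})

test_that("classify_element applies the intactness criteria", {
  pair <- list(); pbs <- list(); ppt <- list() # presence is what matters
  expect_identical(classify_element("x", pair, pbs, ppt), "full_length")
  # missing PBS disqualifies an otherwise intact element
  expect_identical(classify_element(random_seq(5000, 6), pair, NULL, ppt),
                   "truncated")
  expect_identical(classify_element(random_seq(600, 7), NULL, NULL, NULL),
                   "solo")
  expect_identical(classify_element(random_seq(3000, 8), NULL, NULL, NULL),
                   "truncated")
  expect_identical(classify_element(random_seq(3000, 9), NULL, NULL, NULL,
                                    internal_hit = FALSE), "solo")
})

test_that("insilico_pcr amplifies planted primer sites", {
  bg <- generate_background(20000, 0.42, 61)
  fwd <- random_seq(20, seed = 62)
  rev <- random_seq(20, seed = 63)
  insert_at <- 5000
  # product: fwd ... 360 bp ... revcomp(rev)  => product length 400
  product <- paste0(fwd, random_seq(360, seed = 64), revcomp(rev))
  genome <- list(chr1 = paste0(substr(bg, 1, insert_at), product,
                               substr(bg, insert_at + 1, nchar(bg))))
  amp <- insilico_pcr(genome, fwd, rev, max_mismatch = 0,
                      max_product = 1000)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, insert_at)
  expect_equal(amp$length, 400)
  expect_identical(amp$strand, "+")

  # both primers on the same strand: no amplicon
  same <- paste0(fwd, random_seq(360, seed = 65), rev)
  genome2 <- list(chr1 = paste0(substr(bg, 1, insert_at), same,
                                substr(bg, insert_at + 1, nchar(bg))))
  expect_equal(nrow(insilico_pcr(genome2, fwd, rev, max_product = 1000)), 0)

  expect_error(insilico_pcr(genome, substr(fwd, 1, 10), rev), "15")
})

test_that("insilico_pcr mismatch tolerance matches an exhaustive scan", {
  bg <- generate_background(20000, 0.42, 71)
  fwd <- random_seq(20, seed = 72)
  rev <- random_seq(20, seed = 73)
  # plant a forward site with 1 internal mismatch
  fwd_mut <- fwd
  substr(fwd_mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(fwd, 10, 10))[1]
  product <- paste0(fwd_mut, random_seq(100, seed = 74), revcomp(rev))
  genome <- list(chr1 = paste0(substr(bg, 1, 3000), product,
                               substr(bg, 3001, nchar(bg))))
  expect_equal(nrow(insilico_pcr(genome, fwd, rev, max_mismatch = 0,
                                 max_product = 500)), 0)
  amp <- insilico_pcr(genome, fwd, rev, max_mismatch = 1, max_product = 500)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$fwd_mismatches, 1L)

  # exhaustive oracle: scan every offset for both primers
  oracle_sites <- function(g, primer, mm) {
    hits <- naive_scan(g, primer, mm)
    # 3'-terminal base must match exactly
    keep <- vapply(hits$offset, function(o)
      substr(g, o + nchar(primer), o + nchar(primer)) ==
        substr(primer, nchar(primer), nchar(primer)), logical(1))
    hits[keep, , drop = FALSE]
  }
  g <- genome$chr1
  fs <- oracle_sites(g, fwd, 1)
  rs <- naive_scan(g, revcomp(rev), 1)
  rs <- rs[vapply(rs$offset, function(o)
    substr(g, o + 1, o + 1) == substr(revcomp(rev), 1, 1), logical(1)), ]
  n_expected <- 0L
  for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs)))
    if (rs$offset[j] >= fs$offset[i] &&
        rs$offset[j] + 20 - fs$offset[i] <= 500) n_expected <- n_expected + 1L
  expect_equal(sum(amp$strand == "+"), n_expected)
})

test_that("end-to-end census is exact and strand-invariant", {
  pl <- make_planted(n = 20, seed = 301, divergence = 0.05,
                     lens = c(chr1 = 400000L, chr2 = 300000L))
  ann <- annotate_loci(pl$genome, pl$truth)
  # class confusion matrix is diagonal
  expect_identical(ann$element_class, pl$truth$element_class)

  # reverse-complementing the genome permutes but preserves class counts
  rc_genome <- lapply(pl$genome, revcomp)
  tr_rc <- pl$truth
  for (i in seq_len(nrow(tr_rc))) {
    len <- nchar(pl$genome[[tr_rc$chromosome[i]]])
    s <- tr_rc$start[i]; e <- tr_rc$end[i]
    tr_rc$start[i] <- len - e
    tr_rc$end[i] <- len - s
    tr_rc$strand[i] <- if (tr_rc$strand[i] == "+") "-" else "+"
  }
  ann_rc <- annotate_loci(rc_genome, tr_rc)
  expect_equal(table(ann_rc$element_class), table(ann$element_class))
})
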