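test_that("expected_counts allocates proportionally", {
  em <- expected_counts(c(c1 = 100, c2 = 100), 10)
  expect_equal(em$expected, c(5, 5))
  em2 <- expected_counts(c(c1 = 300, c2 = 100), 8)
  expect_equal(em2$expected, c(6, 2))
  expect_error(expected_counts(numeric(0), 5), "empty")

  # sum property on a 21-chromosome size table
  lens <- setNames(seq(50e6, 150e6, length.out = 21), paste0("chr", 1:21))
  em3 <- expected_counts(lens, 372)
  expect_equal(sum(em3$expected), 372)
})

test_that("chisq_gof statistic, df and p-value", {
  g <- chisq_gof(c(5, 5, 5), c(5, 5, 5))
  expect_equal(g$statistic, 0)
  expect_equal(g$df, 2L)
  expect_equal(g$p_value, 1)
  expect_error(chisq_gof(c(1, 2), c(0, 3)), "positive")

  obs <- c(10, 20, 30); exp <- c(15, 25, 20)
  g2 <- chisq_gof(obs, exp)
  expect_equal(g2$statistic, sum((obs - exp)^2 / exp))
  expect_equal(g2$p_value, pchisq(g2$statistic, 2, lower.tail = FALSE))
})

test_that("flank_gc measures the flanking windows", {
  genome <- list(chr1 = paste0(strrep("A", 400), strrep("G", 100),
                               strrep("T", 400)))
  rec <- data.frame(element_id = "e1", chromosome = "chr1",
                    start = 400L, end = 500L, stringsAsFactors = FALSE)
  expect_equal(flank_gc(genome, rec, 400)$mean_gc, 0)

  genome2 <- list(chr1 = paste0(strrep("C", 400), strrep("A", 100),
                                strrep("G", 400)))
  expect_equal(flank_gc(genome2, rec, 400)$mean_gc, 1)

  # clipping is flagged at chromosome edges
  rec_edge <- data.frame(element_id = "e2", chromosome = "chr1",
                         start = 100L, end = 500L, stringsAsFactors = FALSE)
  expect_true(flank_gc(genome, rec_edge, 400)$per_record$clipped)

  # planted genome: flank GC near the 0.42 background
  pl <- make_planted(n = 6, seed = 401)
  fg <- flank_gc(pl$genome, pl$truth, 400)
  expect_lt(abs(fg$mean_gc - 0.42), 0.02)
})

test_that("nearest_tss_binning: signed distances, bins, exhaustiveness", {
  genes <- data.frame(gene_id = c("g1", "g2"), chromosome = "chr1",
                      strand = c("+", "-"), start = c(100000L, 500000L),
                      end = c(110000L, 510000L),
                      tss = c(100000L, 510000L), stringsAsFactors = FALSE)
  genes$exons <- list(cbind(100000L, 110000L), cbind(500000L, 510000L))
  class(genes) <- c("gene_models", "data.frame")

  rec <- function(s, e) data.frame(element_id = "e", chromosome = "chr1",
                                   start = s, end = e,
                                   stringsAsFactors = FALSE)
  # element with midpoint 3 kb upstream of the + strand gene
  b <- nearest_tss_binning(rec(96500L, 97500L), genes)
  expect_identical(b$bin, "0-5")
  expect_identical(b$side, "upstream")
  expect_equal(b$distance, -3000)

  # 865 bp upstream
  b2 <- nearest_tss_binning(rec(98635L, 99635L), genes)
  expect_equal(b2$distance, -865)

  # TSS inside the element
  b3 <- nearest_tss_binning(rec(99500L, 100500L), genes)
  expect_identical(b3$side, "within")
  expect_equal(b3$distance, 0)

  # minus-strand gene: element left of the TSS is downstream
  b4 <- nearest_tss_binning(rec(449500L, 450500L), genes)
  expect_identical(b4$side, "downstream")
  expect_equal(b4$distance, 60000)
  expect_identical(b4$bin, "50-500")

  # beyond 1 Mb: not associated
  b5 <- nearest_tss_binning(rec(1700000L, 1701000L), genes,
                            max_distance = 1e6)
  expect_identical(b5$bin, "not_associated")

  # exhaustive & exclusive binning over random records
  pl <- make_planted(n = 10, seed = 402)
  lens <- setNames(nchar(pl$genome), names(pl$genome))
  gm <- generate_gene_models(pl$gspec, 15, seed = 402,
                             chromosome_lengths = lens)
  bins <- nearest_tss_binning(pl$truth, gm)
  expect_equal(nrow(bins), nrow(pl$truth))
  expect_true(all(bins$bin %in% c("0-5", "5-50", "50-500", "500-1000",
                                  "not_associated")))
  expect_true(all(is.na(bins$side) == (bins$bin == "not_associated")))
})

test_that("classify_gene_context follows the category precedence", {
  exons <- cbind(c(100000L, 120000L, 140000L), c(105000L, 125000L, 150000L))
  genes <- data.frame(gene_id = "g1", chromosome = "chr1", strand = "+",
                      start = 100000L, end = 150000L, tss = 100000L,
                      stringsAsFactors = FALSE)
  genes$exons <- list(exons)
  class(genes) <- c("gene_models", "data.frame")
  rec <- function(s, e, strand = "+")
    data.frame(element_id = "e", chromosome = "chr1", start = s, end = e,
               strand = strand, stringsAsFactors = FALSE)

  expect_identical(classify_gene_context(rec(99000L, 101000L),
                                         genes)$category,
                   "TSS_within_element")
  # wholly inside intron 2 (125000-140000)
  ctx <- classify_gene_context(rec(130000L, 131000L), genes)
  expect_identical(ctx$category, "intronic")
  expect_gt(ctx$distance, 0) # inside the gene, past its TSS
  # overlapping the final exon
  expect_identical(classify_gene_context(rec(149000L, 151000L),
                                         genes)$category, "end_of_gene")
  # 10 kb upstream: adjacent to TSS
  adj <- classify_gene_context(rec(89500L, 90500L), genes,
                               adjacency_threshold = 20000L)
  expect_identical(adj$category, "adjacent_to_TSS")
  expect_lt(adj$distance, 0)
  # 10 kb upstream but on the minus strand: orientation is opposite
  expect_identical(classify_gene_context(rec(89500L, 90500L, "-"),
                                         genes)$orientation, "opposite")
  # far away: intergenic
  expect_identical(classify_gene_context(rec(900000L, 901000L),
                                         genes)$category, "intergenic")
})

test_that("find_clusters: planted cluster, sparse case, brute-force oracle", {
  # 8 truncated elements within a 1.5 Mb domain
  starts <- sort(c(100000, 300000, 450000, 700000, 900000, 1100000,
                   1300000, 1500000))
  rec <- data.frame(element_id = sprintf("t%d", 1:8), chromosome = "chrX",
                    start = as.integer(starts),
                    end = as.integer(starts + 2000),
                    stringsAsFactors = FALSE)
  cl <- find_clusters(rec, window = 1.5e6, min_count = 8)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n, 8L)

  sparse <- data.frame(element_id = sprintf("s%d", 1:5), chromosome = "chr1",
                       start = as.integer(seq(0, 4e6, by = 1e6)),
                       end = as.integer(seq(0, 4e6, by = 1e6) + 1000),
                       stringsAsFactors = FALSE)
  expect_equal(nrow(find_clusters(sparse, window = 5e5, min_count = 2)), 0)

  # oracle: all maximal qualifying contiguous runs over sorted starts
  brute_clusters <- function(r, window, min_count) {
    r <- r[order(r$start, r$end), ]
    n <- nrow(r)
    sets <- list()
    for (i in 1:n) for (j in i:n) {
      if (j - i + 1 < min_count) next
      if (max(r$end[i:j]) - min(r$start[i:j]) <= window)
        sets[[length(sets) + 1L]] <- i:j
    }
    keep <- vapply(seq_along(sets), function(a)
      !any(vapply(seq_along(sets), function(b)
        a != b && all(sets[[a]] %in% sets[[b]]), logical(1))), logical(1))
    sets[keep]
  }
  ltrscape:::with_seed(403, {
    for (rep in 1:10) {
      n <- sample(5:15, 1)
      st <- sort(sample.int(2e6, n))
      r <- data.frame(element_id = sprintf("r%d", 1:n), chromosome = "c",
                      start = st, end = st + sample.int(5000, n),
                      stringsAsFactors = FALSE)
      for (window in c(1e5, 5e5)) {
        got <- find_clusters(r, window, 3)
        want <- brute_clusters(r, window, 3)
        expect_equal(nrow(got), length(want))
        if (length(want))
          expect_equal(got$n, lengths(want))
      }
    }
  })
})

test_that("great_association: closed forms and enumeration oracle", {
  lens <- c(chr1 = 1e6)
  genes <- data.frame(gene_id = c("g1", "g2"), chromosome = "chr1",
                      strand = "+", start = c(100000L, 600000L),
                      end = c(110000L, 610000L),
                      tss = c(100000L, 600000L), stringsAsFactors = FALSE)
  genes$exons <- list(cbind(100000L, 110000L), cbind(600000L, 610000L))
  class(genes) <- c("gene_models", "data.frame")
  recs <- data.frame(element_id = sprintf("e%d", 1:10), chromosome = "chr1",
                     start = as.integer(seq(50000, 950000, length.out = 10)),
                     end = as.integer(seq(50000, 950000, length.out = 10)) +
                       100L, stringsAsFactors = FALSE)

  # domains covering the whole genome -> binomial p = 1
  res_all <- great_association(recs, c("g1", "g2"), genes, lens,
                               basal_upstream = 5e5, basal_downstream = 5e5,
                               max_extension = 1e6)
  expect_equal(res_all$genome_fraction, 1)
  expect_equal(res_all$binomial_p, 1)

  # closed form: all 10 records inside domains covering 10% of the genome
  genes10 <- genes[1, , drop = FALSE]
  genes10$exons <- list(cbind(100000L, 110000L))
  class(genes10) <- c("gene_models", "data.frame")
  recs10 <- data.frame(element_id = sprintf("e%d", 1:10),
                       chromosome = "chr1",
                       start = as.integer(seq(55000, 145000,
                                              length.out = 10)),
                       end = as.integer(seq(55000, 145000,
                                            length.out = 10)) + 10L,
                       stringsAsFactors = FALSE)
  res10 <- great_association(recs10, "g1", genes10, lens,
                             basal_upstream = 50000,
                             basal_downstream = 50000,
                             max_extension = 50000)
  expect_equal(res10$genome_fraction, 0.1)
  expect_equal(res10$k_hits, 10L)
  expect_equal(res10$binomial_p, 1e-10)

  # enumeration oracle at n <= 12: upper tail as an explicit binomial sum
  res <- great_association(recs, "g1", genes, lens)
  k <- res$k_hits; n <- res$n_regions; p <- res$genome_fraction
  enum <- sum(vapply(k:n, function(j)
    choose(n, j) * p^j * (1 - p)^(n - j), numeric(1)))
  expect_equal(res$binomial_p, enum, tolerance = 1e-12)

  # monotone decreasing in k at fixed (n, p)
  pv <- vapply(0:10, function(k) {
    if (k == 0) 1 else pbinom(k - 1, 10, 0.2, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(pv) <= 0))

  expect_error(great_association(recs, "g1", genes[0, ], lens), "empty")
})
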