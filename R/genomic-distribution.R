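# Genomic-distribution statistics: proportional-insertion expected counts
# and chi-square goodness of fit per chromosome, flank GC, signed
# TSS-distance binning, gene-context classification, cluster detection, and
# GREAT-style binomial/hypergeometric association of regions with gene sets.

#' Expected element counts under a proportional (random) insertion model
#'
#' Each chromosome's expected count is the total element count multiplied by
#' the chromosome's fraction of the genome length.
#'
#' @param chromosome_lengths named positive lengths (bp).
#' @param total total number of elements (>= 0).
#' @return data.frame: chromosome, length, expected (sums to `total`).
#' @export
expected_counts <- function(chromosome_lengths, total) {
  if (length(chromosome_lengths) == 0L) stop("empty chromosome set")
  stopifnot(all(chromosome_lengths > 0), total >= 0)
  data.frame(chromosome = names(chromosome_lengths),
             length = as.numeric(chromosome_lengths),
             expected = total * chromosome_lengths /
               sum(chromosome_lengths),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Observed vs expected chromosome model for a catalogue
#'
#' @param records an element catalogue (data.frame with a `chromosome`
#'   column).
#' @param chromosome_lengths named lengths covering every chromosome in use.
#' @return data.frame: chromosome, length, observed, expected.
#' @export
chromosome_model <- function(records, chromosome_lengths) {
  missing <- setdiff(unique(records$chromosome), names(chromosome_lengths))
  if (length(missing))
    stop("no length for chromosome(s): ", paste(missing, collapse = ", "))
  em <- expected_counts(chromosome_lengths, nrow(records))
  obs <- table(factor(records$chromosome, levels = em$chromosome))
  em$observed <- as.integer(obs)
  em[, c("chromosome", "length", "observed", "expected")]
}

#' Chi-square goodness-of-fit test
#'
#' `statistic = sum((O - E)^2 / E)`, `df = k - 1`, upper-tail p-value from
#' the chi-square distribution.
#'
#' @param observed,expected equal-length numeric vectors; every expected
#'   count must be positive.
#' @return list: statistic, df, p_value.
#' @export
chisq_gof <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  if (any(expected <= 0)) stop("all expected counts must be positive")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' GC content of the windows flanking each element
#'
#' GC fraction over the `window` bp on each side of every record (both
#' windows pooled per record); windows are clipped at chromosome edges and
#' clipping is flagged.
#'
#' @param genome named character vector of chromosome sequences.
#' @param records catalogue data.frame (chromosome, start, end).
#' @param window flank width in bp (>= 1).
#' @return list: `per_record` (data.frame element_id, gc, clipped) and
#'   `mean_gc`.
#' @export
flank_gc <- function(genome, records, window = 400L) {
  stopifnot(window >= 1)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    chrom <- records$chromosome[i]
    len <- nchar(genome[[chrom]])
    ls <- max(0L, records$start[i] - window)
    rs <- records$end[i]
    re <- min(len, records$end[i] + window)
    flank <- paste0(substr(genome[[chrom]], ls + 1L, records$start[i]),
                    substr(genome[[chrom]], rs + 1L, re))
    data.frame(element_id = records$element_id[i],
               gc = gc_fraction_of(flank),
               clipped = (records$start[i] - ls < window) ||
                 (re - rs < window),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_record = per, mean_gc = mean(per$gc, na.rm = TRUE))
}

TSS_BINS <- c("0-5", "5-50", "50-500", "500-1000", "not_associated")

#' Bin elements by signed distance to the nearest TSS
#'
#' Distances are measured from the element midpoint to the nearest TSS
#' within `max_distance`, signed in the gene's orientation (upstream of the
#' TSS negative, downstream positive). Elements containing a TSS are
#' `within` at distance 0. Bins: 0-5, 5-50, 50-500, 500-1000 kb by absolute
#' distance, else `not_associated`.
#'
#' @param records catalogue data.frame.
#' @param genes `gene_models` data.frame.
#' @param max_distance association ceiling in bp (default 1 Mb).
#' @return data.frame: element_id, nearest_gene, distance, bin, side.
#' @export
nearest_tss_binning <- function(records, genes, max_distance = 1e6) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    chrom <- records$chromosome[i]
    mid <- (records$start[i] + records$end[i]) %/% 2
    g <- genes[genes$chromosome == chrom, , drop = FALSE]
    na_row <- data.frame(element_id = records$element_id[i],
                         nearest_gene = NA_character_,
                         distance = NA_real_, bin = "not_associated",
                         side = NA_character_, stringsAsFactors = FALSE)
    if (nrow(g) == 0L) return(na_row)
    inside <- g$tss >= records$start[i] & g$tss < records$end[i]
    if (any(inside)) {
      j <- which(inside)[1]
      return(data.frame(element_id = records$element_id[i],
                        nearest_gene = g$gene_id[j], distance = 0,
                        bin = "0-5", side = "within",
                        stringsAsFactors = FALSE))
    }
    dsign <- ifelse(g$strand == "+", mid - g$tss, g$tss - mid)
    j <- which.min(abs(dsign))
    if (abs(dsign[j]) > max_distance) return(na_row)
    bin <- cut(abs(dsign[j]), c(-1, 5e3, 5e4, 5e5, 1e6),
               labels = TSS_BINS[1:4])
    data.frame(element_id = records$element_id[i],
               nearest_gene = g$gene_id[j], distance = dsign[j],
               bin = as.character(bin),
               side = if (dsign[j] < 0) "upstream" else "downstream",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify the gene context of each element
#'
#' Per element, the first matching category: `TSS_within_element` (a TSS
#' falls inside the element), `intronic` (element fully inside an intron),
#' `end_of_gene` (element overlaps the strand-aware final exon or 3' gene
#' boundary), `adjacent_to_TSS` (nearest TSS upstream within
#' `adjacency_threshold`), else `intergenic`. Orientation reports strand
#' agreement between element and gene.
#'
#' @param records catalogue data.frame.
#' @param gene_models `gene_models` data.frame.
#' @param adjacency_threshold upstream adjacency ceiling (default 20 kb).
#' @return data.frame: element_id, category, gene_id, distance, orientation.
#' @export
classify_gene_context <- function(records, gene_models,
                                  adjacency_threshold = 20000L) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    chrom <- records$chromosome[i]
    s <- records$start[i]; e <- records$end[i]
    mid <- (s + e) %/% 2
    g <- gene_models[gene_models$chromosome == chrom, , drop = FALSE]
    res <- function(category, gene_id = NA_character_,
                    distance = NA_real_, orientation = NA_character_)
      data.frame(element_id = records$element_id[i], category = category,
                 gene_id = gene_id, distance = distance,
                 orientation = orientation, stringsAsFactors = FALSE)
    orient <- function(j) if (records$strand[i] == g$strand[j]) "same"
                          else "opposite"
    signed <- function(j) if (g$strand[j] == "+") mid - g$tss[j]
                          else g$tss[j] - mid
    if (nrow(g) == 0L) return(res("intergenic"))
    inside <- which(g$tss >= s & g$tss < e)
    if (length(inside))
      return(res("TSS_within_element", g$gene_id[inside[1]], 0,
                 orient(inside[1])))
    for (j in seq_len(nrow(g))) {
      ex <- g$exons[[j]]
      if (is.null(ex) || nrow(ex) < 2L) next
      ord <- order(ex[, 1])
      introns <- cbind(ex[ord[-nrow(ex)], 2], ex[ord[-1], 1])
      if (any(s >= introns[, 1] & e <= introns[, 2]))
        return(res("intronic", g$gene_id[j], signed(j), orient(j)))
    }
    for (j in seq_len(nrow(g))) {
      ex <- g$exons[[j]]
      if (is.null(ex) || nrow(ex) == 0L) next
      last <- if (g$strand[j] == "+") ex[which.max(ex[, 2]), , drop = FALSE]
              else ex[which.min(ex[, 1]), , drop = FALSE]
      end3 <- if (g$strand[j] == "+") g$end[j] else g$start[j]
      if ((s < last[1, 2] && e > last[1, 1]) ||
          (s <= end3 && e >= end3))
        return(res("end_of_gene", g$gene_id[j], signed(j), orient(j)))
    }
    dsign <- vapply(seq_len(nrow(g)), signed, numeric(1))
    j <- which.min(abs(dsign))
    if (dsign[j] < 0 && abs(dsign[j]) <= adjacency_threshold)
      return(res("adjacent_to_TSS", g$gene_id[j], dsign[j], orient(j)))
    res("intergenic", g$gene_id[j], dsign[j], orient(j))
  })
  do.call(rbind, rows)
}

#' Find same-chromosome element clusters
#'
#' Maximal sets of same-chromosome elements whose genomic span does not
#' exceed `window` and whose size is at least `min_count` (sliding-window
#' sweep over start-sorted elements).
#'
#' @param records catalogue data.frame.
#' @param window maximum cluster span in bp (> 0).
#' @param min_count minimum cluster size (>= 2).
#' @return data.frame: chromosome, start, end, n, element_ids
#'   (comma-separated).
#' @export
find_clusters <- function(records, window, min_count = 2L) {
  stopifnot(window > 0, min_count >= 2L)
  out <- list()
  for (chrom in unique(records$chromosome)) {
    r <- records[records$chromosome == chrom, , drop = FALSE]
    r <- r[order(r$start, r$end), , drop = FALSE]
    n <- nrow(r)
    prev_j <- 0L
    for (i in seq_len(n)) {
      j <- i
      max_end <- r$end[i]
      while (j + 1L <= n &&
             max(max_end, r$end[j + 1L]) - r$start[i] <= window) {
        j <- j + 1L
        max_end <- max(max_end, r$end[j])
      }
      if (j - i + 1L >= min_count && j > prev_j) {
        out[[length(out) + 1L]] <- data.frame(
          chromosome = chrom, start = r$start[i], end = max_end,
          n = j - i + 1L,
          element_ids = paste(r$element_id[i:j], collapse = ","),
          stringsAsFactors = FALSE)
        prev_j <- j
      }
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), n = integer(0),
                      element_ids = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' GREAT-style region/gene-set association
#'
#' Builds per-gene regulatory domains (basal window around the TSS extended
#' toward the neighboring genes' basal domains, capped at `max_extension`),
#' then tests the input regions against the `gene_set` domains with (a) a
#' binomial test over regions — a region "hits" when its midpoint falls in
#' the merged gene-set domains, the null probability is the fraction of the
#' genome they cover — and (b) a hypergeometric test over genes, drawing the
#' genes with at least one region in their domain from the gene universe.
#'
#' @param records catalogue data.frame.
#' @param gene_set character vector of gene ids (subset of the universe).
#' @param all_genes `gene_models` data.frame (the gene universe).
#' @param chromosome_lengths named lengths of the genome analysed.
#' @param basal_upstream,basal_downstream basal domain around the TSS in bp
#'   (defaults 5000/1000, strand-aware).
#' @param max_extension extension cap in bp (default 1 Mb).
#' @return list: binomial_p, hypergeometric_p, n_regions, k_hits,
#'   genome_fraction, n_genes_hit, n_set_genes_hit.
#' @export
great_association <- function(records, gene_set, all_genes,
                              chromosome_lengths,
                              basal_upstream = 5000L,
                              basal_downstream = 1000L,
                              max_extension = 1e6) {
  if (nrow(all_genes) == 0L) stop("empty gene universe")
  stopifnot(all(gene_set %in% all_genes$gene_id))
  dom <- regulatory_domains(all_genes, chromosome_lengths, basal_upstream,
                            basal_downstream, max_extension)
  set_dom <- dom[dom$gene_id %in% gene_set, , drop = FALSE]
  merged <- merge_intervals(set_dom)
  covered <- sum(merged$end - merged$start)
  p <- covered / sum(chromosome_lengths)
  mids <- data.frame(chromosome = records$chromosome,
                     pos = (records$start + records$end) %/% 2)
  in_iv <- function(ivs, chrom, pos)
    any(ivs$chromosome == chrom & ivs$start <= pos & pos < ivs$end)
  k <- sum(vapply(seq_len(nrow(mids)), function(i)
    in_iv(merged, mids$chromosome[i], mids$pos[i]), logical(1)))
  n <- nrow(records)
  binom_p <- if (p >= 1) 1 else pbinom(k - 1, n, p, lower.tail = FALSE)
  hit_gene <- vapply(seq_len(nrow(dom)), function(j)
    any(mids$chromosome == dom$chromosome[j] & mids$pos >= dom$start[j] &
          mids$pos < dom$end[j]), logical(1))
  hit_ids <- dom$gene_id[hit_gene]
  q <- sum(hit_ids %in% gene_set)
  hyper_p <- phyper(q - 1, length(gene_set),
                    nrow(all_genes) - length(gene_set), length(hit_ids),
                    lower.tail = FALSE)
  list(binomial_p = unname(binom_p), hypergeometric_p = unname(hyper_p),
       n_regions = n, k_hits = k, genome_fraction = p,
       n_genes_hit = length(hit_ids), n_set_genes_hit = q)
}

# Basal-plus-extension regulatory domains (GREAT-like): basal window around
# each TSS (strand-aware), extended on both sides up to `max_extension` from
# the TSS but never into a neighboring gene's basal domain, clamped to the
# chromosome.
regulatory_domains <- function(genes, chromosome_lengths, basal_upstream,
                               basal_downstream, max_extension) {
  rows <- list()
  for (chrom in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chrom, , drop = FALSE]
    clen <- chromosome_lengths[[chrom]]
    if (is.null(clen) || is.na(clen))
      stop("no length for chromosome ", chrom)
    basal_start <- ifelse(g$strand == "+", g$tss - basal_upstream,
                          g$tss - basal_downstream)
    basal_end <- ifelse(g$strand == "+", g$tss + basal_downstream,
                        g$tss + basal_upstream)
    basal_start <- pmax(0, basal_start)
    basal_end <- pmin(clen, basal_end)
    ord <- order(g$tss)
    for (idx in seq_along(ord)) {
      j <- ord[idx]
      prev_end <- if (idx > 1) max(basal_end[ord[seq_len(idx - 1)]]) else 0
      next_start <- if (idx < length(ord))
        min(basal_start[ord[(idx + 1):length(ord)]]) else clen
      ext_start <- min(basal_start[j],
                       max(g$tss[j] - max_extension, prev_end, 0))
      ext_end <- max(basal_end[j],
                     min(g$tss[j] + max_extension, next_start, clen))
      ext_start <- min(ext_start, basal_start[j])
      ext_end <- max(ext_end, basal_end[j])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id[j], chromosome = chrom,
        start = ext_start, end = ext_end, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

merge_intervals <- function(ivs) {
  if (nrow(ivs) == 0L)
    return(data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  out <- list()
  for (chrom in unique(ivs$chromosome)) {
    v <- ivs[ivs$chromosome == chrom, , drop = FALSE]
    v <- v[order(v$start), , drop = FALSE]
    s <- v$start[1]; e <- v$end[1]
    for (i in seq_len(nrow(v))[-1]) {
      if (v$start[i] <= e) e <- max(e, v$end[i])
      else {
        out[[length(out) + 1L]] <- data.frame(chromosome = chrom,
                                              start = s, end = e)
        s <- v$start[i]; e <- v$end[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chromosome = chrom, start = s,
                                          end = e)
  }
  do.call(rbind, out)
}
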