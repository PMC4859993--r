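# Discovery and structural classification of candidate LTR-retroelement
# loci: k-mer seed-and-chain discovery against a consensus library, LTR-pair
# detection by terminal-window local alignment, TSD detection, the
# full-length/truncated/solo classification rule, and in-silico PCR.

# 2-bit rolling hashes of all k-mers of a sequence (exact in doubles for
# k <= 15). Positions with non-ACGT characters yield NA.
kmer_hashes <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(numeric(0))
  code <- match(strsplit(seq, "")[[1]], BASES) - 1
  h <- numeric(n - k + 1)
  for (j in 0:(k - 1))
    h <- h + code[(1 + j):(n - k + 1 + j)] * 4^(k - 1 - j)
  h
}

empty_loci <- function() {
  data.frame(chromosome = character(0), start = integer(0),
             end = integer(0), strand = character(0),
             n_hits = integer(0), stringsAsFactors = FALSE)
}

#' Discover candidate loci by k-mer seeding against a consensus library
#'
#' Indexes all k-mers of the query library (both strands) with their
#' positions, finds their exact occurrences in the genome, and chains
#' colinear hits: same library sequence, same strand, consistent alignment
#' diagonal (within `diag_tolerance`) and genomic gap at most `max_gap`.
#' Chains with at least `min_chain_hits` seeds become candidate intervals;
#' same-strand intervals closer than `max_gap` are merged. With `k = 12`
#' this recovers planted elements diverged up to ~8 percent from the
#' library with full sensitivity, while diagonal consistency suppresses
#' chance background chains.
#'
#' @param genome named character vector of chromosome sequences.
#' @param library named character vector of LTR/internal consensus sequences.
#' @param k seed length (8-15).
#' @param min_chain_hits minimum seed hits per chain.
#' @param max_gap maximum genomic gap between chained seeds (bp).
#' @param diag_tolerance allowed drift of the alignment diagonal within a
#'   chain (bp); 0 for substitution-only divergence, larger to bridge
#'   indels.
#' @return data.frame: chromosome, start, end (0-based half-open), strand,
#'   n_hits.
#' @export
discover_candidate_loci <- function(genome, library, k = 12L,
                                    min_chain_hits = 3L, max_gap = 500L,
                                    diag_tolerance = 25L) {
  stopifnot(k >= 8L, k <= 15L, length(library) >= 1L)
  if (length(genome) == 0L || all(!nzchar(genome))) return(empty_loci())
  # index: hash -> (library sequence, offset), one table per strand sense
  index_lib <- function(seqs) {
    hs <- lapply(seqs, kmer_hashes, k = k)
    data.frame(hash = unlist(hs, use.names = FALSE),
               lib = rep(seq_along(hs), lengths(hs)),
               off = unlist(lapply(lengths(hs), seq_len),
                            use.names = FALSE) - 1L)
  }
  idx <- list("+" = index_lib(library), "-" = index_lib(revcomp(library)))
  rows <- list()
  for (chrom in names(genome)) {
    h <- kmer_hashes(genome[[chrom]], k)
    if (!length(h)) next
    for (strand in c("+", "-")) {
      tab <- idx[[strand]]
      gpos <- which(h %in% tab$hash) - 1L # 0-based genome offsets
      if (!length(gpos)) next
      # expand every (genome position, library occurrence) pairing
      by_hash <- split(seq_len(nrow(tab)), tab$hash)
      entry <- by_hash[as.character(h[gpos + 1L])]
      nrep <- lengths(entry)
      rid <- unlist(entry, use.names = FALSE)
      hit <- data.frame(gpos = rep(gpos, nrep), lib = tab$lib[rid],
                        diag = rep(gpos, nrep) - tab$off[rid])
      hit <- hit[order(hit$lib, hit$diag, hit$gpos), , drop = FALSE]
      newchain <- c(TRUE, diff(hit$lib) != 0 |
                      abs(diff(hit$diag)) > diag_tolerance |
                      diff(hit$gpos) < 0 | diff(hit$gpos) > max_gap)
      cid <- cumsum(newchain)
      for (cc in split(seq_len(nrow(hit)), cid)) {
        pos <- unique(hit$gpos[cc])
        # chance matches yield runs of overlapping seeds from one short
        # shared substring; demand min_chain_hits non-overlapping seeds
        spaced <- 1L
        last <- pos[1]
        for (p in pos[-1]) if (p >= last + k) { spaced <- spaced + 1L
                                                last <- p }
        if (spaced < min_chain_hits) next
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chrom, start = min(pos), end = max(pos) + k,
          strand = strand, n_hits = spaced, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_loci())
  out <- do.call(rbind, rows)
  out <- merge_nearby(out, max_gap)
  out <- merge_strand_overlaps(out)
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Merge same-chromosome, same-strand intervals that overlap or lie within
# `gap` of each other (e.g. the 5' LTR, internal and 3' LTR chains of one
# locus).
merge_nearby <- function(df, gap) {
  out <- list()
  for (key in unique(paste(df$chromosome, df$strand))) {
    v <- df[paste(df$chromosome, df$strand) == key, , drop = FALSE]
    v <- v[order(v$start), , drop = FALSE]
    cur <- v[1, ]
    for (i in seq_len(nrow(v))[-1]) {
      if (v$start[i] <= cur$end + gap) {
        cur$end <- max(cur$end, v$end[i])
        cur$n_hits <- cur$n_hits + v$n_hits[i]
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- v[i, ]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

# If + and - chains overlap (e.g. palindromic seeds), keep the chain with
# more hits for that locus.
merge_strand_overlaps <- function(df) {
  keep <- rep(TRUE, nrow(df))
  for (chrom in unique(df$chromosome)) {
    idx <- which(df$chromosome == chrom)
    for (i in idx) for (j in idx) {
      if (i >= j || !keep[i] || !keep[j]) next
      ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j])
      if (ov > 0.5 * min(df$end[i] - df$start[i], df$end[j] - df$start[j])) {
        drop <- if (df$n_hits[i] >= df$n_hits[j]) j else i
        keep[drop] <- FALSE
      }
    }
  }
  df[keep, , drop = FALSE]
}

#' Locate a 5'/3' LTR pair within a locus sequence
#'
#' Aligns a 5'-terminal window against a 3'-terminal window (window size
#' `min(40%` of the locus, `1200)` bp per end) with a local alignment
#' (match +1, mismatch -1, gap -2) and reports the pair when the alignment
#' reaches `min_ltr` aligned bp at identity >= `min_identity`. "Near
#' identical" defaults to 0.80 identity over >= 100 bp.
#'
#' @param locus_sequence element-oriented sequence (character scalar).
#' @param min_ltr minimum aligned LTR length (bp).
#' @param min_identity minimum fraction of identical alignment columns.
#' @return `NULL` when no qualifying pair exists, else a list with
#'   `ltr5_interval` and `ltr3_interval` (element-oriented 0-based half-open
#'   2-vectors), `identity` and `aligned_length`.
#' @export
find_ltr_pair <- function(locus_sequence, min_ltr = 100L,
                          min_identity = 0.8) {
  len <- nchar(locus_sequence)
  if (len < 2L * min_ltr) return(NULL)
  w <- min(floor(0.4 * len), 1200L)
  if (w < min_ltr) return(NULL)
  head_w <- substr(locus_sequence, 1L, w)
  tail_w <- substr(locus_sequence, len - w + 1L, len)
  al <- .sw_align_cpp(head_w, tail_w, 1, -1, -2)
  cols <- nchar(al$aligned_a)
  if (cols < min_ltr) return(NULL)
  av <- strsplit(al$aligned_a, "")[[1]]
  bv <- strsplit(al$aligned_b, "")[[1]]
  ident <- sum(av == bv & av != "-") / cols
  if (ident < min_identity) return(NULL)
  list(ltr5_interval = c(al$a_start, al$a_end),
       ltr3_interval = c(len - w + al$b_start, len - w + al$b_end),
       identity = ident, aligned_length = cols)
}

#' Detect a target-site duplication between element flanks
#'
#' Finds the longest L in `[min_len, max_len]` such that the terminal L-mer
#' of the left flank equals the initial L-mer of the right flank — the
#' duplication of host sequence created at integration.
#'
#' @param left_flank,right_flank flanking sequences, each >= `max_len` bp.
#' @param min_len,max_len length bounds (defaults 2 and 10 bp).
#' @return `NULL`, or a list with `motif` and `length`.
#' @export
detect_tsd <- function(left_flank, right_flank, min_len = 2L, max_len = 10L) {
  if (nchar(left_flank) < max_len || nchar(right_flank) < max_len)
    stop("flanks must each be at least max_len bp")
  nl <- nchar(left_flank)
  for (L in seq(max_len, min_len)) {
    a <- substr(left_flank, nl - L + 1L, nl)
    if (a == substr(right_flank, 1L, L))
      return(list(motif = a, length = L))
  }
  NULL
}

#' Classify a locus as full-length, truncated or solo LTR
#'
#' An intact (full-length) element must carry near-identical paired LTRs, an
#' intact PBS and a PPT; a solo LTR carries nothing but LTR sequence; every
#' other locus with internal sequence is truncated.
#'
#' @param locus_sequence element-oriented sequence.
#' @param ltr_pair result of [find_ltr_pair()] (or `NULL`).
#' @param pbs_call result of [detect_pbs()] (or `NULL`).
#' @param ppt_call result of [detect_ppt()] (or `NULL`).
#' @param internal_hit optional logical: independent evidence that the locus
#'   matches internal (non-LTR) consensus sequence. When `NULL`, a locus no
#'   longer than `max_ltr_length` without any replication signal is taken to
#'   be a bare LTR.
#' @param max_ltr_length length ceiling for the solo-LTR heuristic (default
#'   1000 bp; observed LTRs range 436-681 bp).
#' @return one of `"full_length"`, `"truncated"`, `"solo"`.
#' @export
classify_element <- function(locus_sequence, ltr_pair, pbs_call, ppt_call,
                             internal_hit = NULL, max_ltr_length = 1000L) {
  if (!is.null(ltr_pair) && !is.null(pbs_call) && !is.null(ppt_call))
    return("full_length")
  solo <- if (!is.null(internal_hit)) !isTRUE(internal_hit)
          else (is.null(ltr_pair) && is.null(pbs_call) && is.null(ppt_call) &&
                nchar(locus_sequence) <= max_ltr_length)
  if (solo) "solo" else "truncated"
}

#' In-silico PCR
#'
#' Finds amplicons where the forward primer matches one strand and the
#' reverse complement of the reverse primer matches the same strand
#' downstream, with at most `max_mismatch` mismatches per primer, no indels,
#' and an exactly matching 3'-terminal base (primer-extension chemistry).
#' Both genomic orientations are scanned.
#'
#' @param genome named character vector of chromosome sequences.
#' @param forward_primer,reverse_primer primer sequences (>= 15 nt).
#' @param max_mismatch maximum mismatches per primer (default 0).
#' @param max_product maximum product length in bp.
#' @return data.frame: chromosome, start, end (0-based half-open, spanning
#'   both primer sites), length, strand, fwd_mismatches, rev_mismatches.
#' @export
insilico_pcr <- function(genome, forward_primer, reverse_primer,
                         max_mismatch = 0L, max_product = 5000L) {
  if (nchar(forward_primer) < 15L || nchar(reverse_primer) < 15L)
    stop("primers must be at least 15 nt")
  out <- rbind(
    pcr_plus(genome, forward_primer, reverse_primer, max_mismatch,
             max_product, "+"),
    pcr_plus(genome, reverse_primer, forward_primer, max_mismatch,
             max_product, "-"))
  out <- unique(out)
  out[order(out$chromosome, out$start), , drop = FALSE]
}

# One orientation: `fwd` literal on the plus strand (3'-exact at its last
# base), revcomp(`rev`) downstream on the plus strand (3'-exact at its first
# base, which is the reverse primer's 3' end).
pcr_plus <- function(genome, fwd, rev, max_mismatch, max_product, strand) {
  rows <- list()
  rev_rc <- revcomp(rev)
  for (chrom in names(genome)) {
    subject <- Biostrings::DNAString(genome[[chrom]])
    fh <- mismatch_hits(fwd, subject, max_mismatch, anchor = "last")
    rh <- mismatch_hits(rev_rc, subject, max_mismatch, anchor = "first")
    if (!nrow(fh) || !nrow(rh)) next
    for (i in seq_len(nrow(fh))) {
      ok <- rh$start >= fh$start[i] &
        (rh$end - fh$start[i]) <= max_product
      for (j in which(ok)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chromosome = chrom, start = fh$start[i], end = rh$end[j],
          length = rh$end[j] - fh$start[i], strand = strand,
          fwd_mismatches = fh$mismatches[i],
          rev_mismatches = rh$mismatches[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      strand = character(0), fwd_mismatches = integer(0),
                      rev_mismatches = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Ungapped occurrences of `pattern` with <= max_mismatch mismatches, with
# the anchored end required to match exactly. 0-based half-open starts/ends.
mismatch_hits <- function(pattern, subject, max_mismatch,
                          anchor = c("last", "first")) {
  anchor <- match.arg(anchor)
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                max.mismatch = max_mismatch,
                                with.indels = FALSE)
  if (length(m) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  pv <- strsplit(pattern, "")[[1]]
  starts <- Biostrings::start(m) - 1L
  seqs <- as.character(m)
  mm <- vapply(seqs, function(s)
    sum(strsplit(s, "")[[1]] != pv), integer(1), USE.NAMES = FALSE)
  exact_pos <- if (anchor == "last") length(pv) else 1L
  ok <- substr(seqs, exact_pos, exact_pos) == pv[exact_pos] &
    mm <= max_mismatch
  data.frame(start = starts[ok], end = starts[ok] + length(pv),
             mismatches = mm[ok])
}
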