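# Replication-signal scanning on element-oriented sequences: PBS (tRNA
# assignment), PPT, generic mismatch-tolerant motif scanning (covers the PSF
# motifs and the psi packaging-signal query), ORF audit, and text
# position-profile consensus building.

#' Detect the primer binding site and assign its tRNA class
#'
#' Scans the `window` bp immediately downstream of the 5' LTR for the best
#' match to the reverse complement of the 3'-terminal 15-18 nt of each tRNA
#' class. The best call minimises mismatches, then maximises matched length,
#' then follows the fixed class order Gly < Pro < Gln < Met < Thr, then the
#' smallest offset.
#'
#' @param element_sequence element-oriented sequence.
#' @param ltr5_end 0-based offset of the first base after the 5' LTR.
#' @param trna_library named vector of tRNA 3'-terminal 18-mers.
#' @param window search window in bp downstream of `ltr5_end`.
#' @param max_mismatch maximum mismatches tolerated.
#' @return `NULL`, or a list with `trna`, `pbs_length` (15-18), `mismatches`
#'   and `offset` (0-based, element-oriented).
#' @export
detect_pbs <- function(element_sequence, ltr5_end,
                       trna_library = trna_3prime_library(),
                       window = 30L, max_mismatch = 2L) {
  if (length(trna_library) == 0L) stop("empty tRNA library")
  stopifnot(ltr5_end >= 0, ltr5_end < nchar(element_sequence))
  len <- nchar(element_sequence)
  region_end <- min(len, ltr5_end + window + 18L)
  region <- substr(element_sequence, ltr5_end + 1L, region_end)
  classes <- intersect(TRNA_CLASSES, names(trna_library))
  best <- NULL
  for (ci in seq_along(classes)) {
    t3 <- trna_library[[classes[ci]]]
    t3 <- substr(t3, nchar(t3) - 17L, nchar(t3))
    q18 <- revcomp(t3)
    for (L in 18:15) {
      q <- substr(q18, 1L, L) # revcomp of the tRNA's 3'-terminal L nt
      qv <- strsplit(q, "")[[1]]
      for (s in 0:(window - 1L)) {
        if (s + L > nchar(region)) break
        mm <- sum(strsplit(substr(region, s + 1L, s + L), "")[[1]] != qv)
        if (mm > max_mismatch) next
        cand <- list(trna = classes[ci], pbs_length = L, mismatches = mm,
                     offset = ltr5_end + s, .rank = ci, .s = s)
        if (is.null(best) ||
            mm < best$mismatches ||
            (mm == best$mismatches && L > best$pbs_length) ||
            (mm == best$mismatches && L == best$pbs_length &&
             ci < best$.rank) ||
            (mm == best$mismatches && L == best$pbs_length &&
             ci == best$.rank && s < best$.s))
          best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$.rank <- NULL; best$.s <- NULL
  best
}

#' Detect the polypurine tract upstream of the 3' LTR
#'
#' Compares every 15-mer in the `window` bp upstream of the 3' LTR to the
#' consensus `AGAAGAAGTGGGGAA`. A call is reported only when the best 15-mer
#' has at most 2 mismatches and every mismatching position carries an A or a
#' T. Ties on mismatch count go to the candidate closest to the 3' LTR.
#'
#' @param element_sequence element-oriented sequence.
#' @param ltr3_start 0-based offset where the 3' LTR begins.
#' @param window search window in bp upstream of `ltr3_start`.
#' @return `NULL`, or a list with `sequence`, `substitutions` and `offset`.
#' @export
detect_ppt <- function(element_sequence, ltr3_start, window = 30L) {
  stopifnot(ltr3_start >= window)
  cons <- strsplit(PPT_CONSENSUS, "")[[1]]
  k <- length(cons)
  region <- substr(element_sequence, ltr3_start - window + 1L, ltr3_start)
  best <- NULL
  for (s in 0:(window - k)) {
    cand <- substr(region, s + 1L, s + k)
    cv <- strsplit(cand, "")[[1]]
    diffpos <- which(cv != cons)
    if (length(diffpos) > 2L) next
    if (!all(cv[diffpos] %in% c("A", "T"))) next
    # larger s = closer to the 3' LTR; >= keeps the closest among ties
    if (is.null(best) || length(diffpos) < best$substitutions ||
        (length(diffpos) == best$substitutions && s > best$.s))
      best <- list(sequence = cand, substitutions = length(diffpos),
                   offset = ltr3_start - window + s, .s = s)
  }
  if (is.null(best)) return(NULL)
  best$.s <- NULL
  best
}

#' Scan a sequence for ungapped motif hits
#'
#' Reports every occurrence of `motif` with at most `max_mismatch`
#' mismatches (no indels); overlapping hits are allowed and hits are sorted
#' by offset.
#'
#' @param sequence subject sequence.
#' @param motif query motif (>= 8 nt).
#' @param max_mismatch maximum mismatches.
#' @param motif_id optional identifier echoed into the result.
#' @return data.frame: offset (0-based), matched, mismatches, motif_id.
#' @export
scan_motif <- function(sequence, motif, max_mismatch = 0L,
                       motif_id = NA_character_) {
  if (nchar(motif) < 8L) stop("motif must be at least 8 nt")
  empty <- data.frame(offset = integer(0), matched = character(0),
                      mismatches = integer(0), motif_id = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(sequence) < nchar(motif)) return(empty)
  m <- Biostrings::matchPattern(Biostrings::DNAString(motif),
                                Biostrings::DNAString(sequence),
                                max.mismatch = max_mismatch,
                                with.indels = FALSE)
  if (length(m) == 0L) return(empty)
  qv <- strsplit(motif, "")[[1]]
  matched <- as.character(m)
  mm <- vapply(matched, function(s) sum(strsplit(s, "")[[1]] != qv),
               integer(1), USE.NAMES = FALSE)
  out <- data.frame(offset = Biostrings::start(m) - 1L, matched = matched,
                    mismatches = mm, motif_id = motif_id,
                    stringsAsFactors = FALSE)
  out[order(out$offset), , drop = FALSE]
}

#' Count PSF-binding motifs present in an element
#'
#' Scans for the two known PSF-binding motifs (a 22-mer and a 30-mer) and
#' returns how many of the two are present at least once (0, 1 or 2).
#'
#' @param element_sequence element-oriented sequence.
#' @param max_mismatch mismatch tolerance per motif (default 2).
#' @return integer in 0..2.
#' @export
count_psf_motifs <- function(element_sequence, max_mismatch = 2L) {
  if (!nzchar(element_sequence)) stop("sequence must be non-empty")
  sum(vapply(PSF_MOTIFS, function(m)
    nrow(scan_motif(element_sequence, m, max_mismatch)) > 0L, logical(1)))
}

#' Find open reading frames in all six frames
#'
#' Reports ATG-initiated, stop-terminated ORFs of at least `min_length_aa`
#' codons (stop excluded from the length) in the three plus and three minus
#' frames, together with the per-frame stop-codon counts. Per frame and stop
#' codon, the ORF from the first ATG after the previous stop is reported.
#'
#' @param sequence input sequence.
#' @param min_length_aa minimum ORF length in amino acids (>= 1).
#' @return list with `orfs` (data.frame: frame, start, end, length_aa; frame
#'   in +1,+2,+3,-1,-2,-3; coordinates 0-based half-open on the input
#'   sequence, stop codon included) and `stop_counts` (named per frame).
#' @export
find_orfs <- function(sequence, min_length_aa = 1L) {
  stopifnot(min_length_aa >= 1L)
  stops <- c("TAA", "TAG", "TGA")
  len <- nchar(sequence)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  rows <- list()
  stop_counts <- setNames(integer(6), frames)
  for (f in 1:6) {
    minus <- f > 3
    off <- (f - 1L) %% 3L # 0-based frame offset
    s <- if (minus) revcomp(sequence) else sequence
    ncod <- (nchar(s) - off) %/% 3L
    if (ncod < 1L) next
    codons <- substring(s, off + 1L + 3L * (0:(ncod - 1L)),
                        off + 3L * (1:ncod))
    is_stop <- codons %in% stops
    stop_counts[f] <- sum(is_stop)
    prev_stop <- 0L
    for (si in which(is_stop)) {
      atg <- if (si - 1L >= prev_stop + 1L)
        which(codons[(prev_stop + 1L):(si - 1L)] == "ATG") else integer(0)
      if (length(atg)) {
        a <- prev_stop + atg[1]
        aa <- si - a # codons from ATG up to (excluding) the stop
        if (aa >= min_length_aa) {
          # 0-based half-open on the frame's strand, stop included
          s0 <- off + 3L * (a - 1L)
          e0 <- off + 3L * si
          if (minus) { tmp <- s0; s0 <- len - e0; e0 <- len - tmp }
          rows[[length(rows) + 1L]] <- data.frame(
            frame = frames[f], start = s0, end = e0, length_aa = aa,
            stringsAsFactors = FALSE)
        }
      }
      prev_stop <- si
    }
  }
  orfs <- if (length(rows)) do.call(rbind, rows)
          else data.frame(frame = character(0), start = integer(0),
                          end = integer(0), length_aa = integer(0),
                          stringsAsFactors = FALSE)
  list(orfs = orfs, stop_counts = stop_counts)
}

#' Build a position profile (text consensus) from equal-length sequences
#'
#' Per-column base counts, modal-base consensus (ties become IUPAC ambiguity
#' codes) and per-column information content, `2 - H` bits where `H` is the
#' Shannon entropy of the column's base frequencies.
#'
#' @param sequences character vector (>= 2, identical lengths).
#' @return list with `counts` (4 x L matrix), `consensus` (string) and
#'   `information_content` (numeric vector, bits).
#' @export
build_consensus <- function(sequences) {
  stopifnot(length(sequences) >= 2L)
  if (length(unique(nchar(sequences))) != 1L)
    stop("sequences must have identical lengths")
  m <- do.call(rbind, strsplit(toupper(sequences), ""))
  L <- ncol(m)
  counts <- vapply(seq_len(L), function(j)
    tabulate(match(m[, j], BASES), nbins = 4L), integer(4))
  rownames(counts) <- BASES
  iupac <- c(A = "A", C = "C", G = "G", T = "T", AC = "M", AG = "R",
             AT = "W", CG = "S", CT = "Y", GT = "K", ACG = "V", ACT = "H",
             AGT = "D", CGT = "B", ACGT = "N")
  consensus <- vapply(seq_len(L), function(j) {
    mx <- max(counts[, j])
    iupac[[paste(BASES[counts[, j] == mx], collapse = "")]]
  }, character(1))
  ic <- vapply(seq_len(L), function(j) {
    p <- counts[, j] / sum(counts[, j])
    p <- p[p > 0]
    2 + sum(p * log2(p))
  }, numeric(1))
  list(counts = counts, consensus = paste(consensus, collapse = ""),
       information_content = ic)
}
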