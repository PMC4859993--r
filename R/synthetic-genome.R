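# Synthetic genomes with planted VL30-like elements and a machine-readable
# truth table, so every downstream stage can be tested against known ground
# truth without downloading an assembly.

#' Specification of one planted LTR-retroelement
#'
#' Describes a full-length, truncated or solo-LTR element to plant in a
#' synthetic genome. Defaults mirror the structure of full-length mouse VL30
#' elements: LTRs in the 436-681 bp range (default 600 bp), a 4-bp target-site
#' duplication, a PBS complementary to the 3' end of a Gly/Pro/Gln/Met/Thr
#' tRNA, a 15-bp polypurine tract, and up to two PSF-binding motifs in the
#' internal sequence.
#'
#' @param element_class one of `"full_length"`, `"truncated"`, `"solo"`.
#' @param ltr_length LTR length in bp (>= 100 for full-length elements).
#' @param ltr_divergence per-site substitution probability applied to derive
#'   the 3' LTR from the 5' LTR; in `[0, 1)`. `0` plants identical LTRs.
#' @param pbs_trna tRNA class priming reverse transcription, or `"none"`.
#' @param ppt_substitutions number of A/T substitutions (0-3) applied to the
#'   PPT consensus `AGAAGAAGTGGGGAA`.
#' @param psf_motif_count how many of the two PSF-binding motifs to plant
#'   (0, 1 or 2; 1 plants the 22-mer).
#' @param tsd_length target-site duplication length in bp (default 4).
#' @param internal_length length of the internal region in bp (0 for solo).
#' @param strand `"+"` or `"-"`; minus-strand elements are planted as the
#'   reverse complement of the built element.
#' @return an object of class `element_spec`.
#' @export
element_spec <- function(element_class = c("full_length", "truncated", "solo"),
                         ltr_length = 600L,
                         ltr_divergence = 0,
                         pbs_trna = "Gly",
                         ppt_substitutions = 0L,
                         psf_motif_count = 2L,
                         tsd_length = 4L,
                         internal_length = 4400L,
                         strand = "+") {
  element_class <- match.arg(element_class)
  stopifnot(ltr_length >= 1, ltr_divergence >= 0, ltr_divergence < 1,
            tsd_length >= 0, internal_length >= 0,
            ppt_substitutions %in% 0:3, psf_motif_count %in% 0:2,
            strand %in% c("+", "-"),
            pbs_trna %in% c(TRNA_CLASSES, "none"))
  if (element_class == "full_length") {
    if (ltr_length < 100L)
      stop("full-length elements require ltr_length >= 100")
    if (internal_length < 1L)
      stop("full-length elements require internal_length >= 1")
  }
  if (element_class == "solo") {
    if (internal_length != 0L)
      stop("solo LTRs have no internal sequence (internal_length must be 0)")
    if (psf_motif_count > 0L)
      stop("contradictory spec: solo LTR cannot carry PSF motifs")
    if (pbs_trna != "none")
      stop("contradictory spec: solo LTR cannot carry a PBS")
  }
  structure(list(element_class = element_class,
                 ltr_length = as.integer(ltr_length),
                 ltr_divergence = ltr_divergence,
                 pbs_trna = pbs_trna,
                 ppt_substitutions = as.integer(ppt_substitutions),
                 psf_motif_count = as.integer(psf_motif_count),
                 tsd_length = as.integer(tsd_length),
                 internal_length = as.integer(internal_length),
                 strand = strand),
            class = "element_spec")
}

#' Specification of a synthetic genome
#'
#' @param chromosome_lengths named integer vector of chromosome lengths (bp).
#' @param gc_fraction background GC content in `[0, 1]`; the default 0.42
#'   matches the average GC of the mouse genome at VL30 integration sites.
#' @param seed integer seed controlling all randomness.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(chromosome_lengths, gc_fraction = 0.42, seed = 1L) {
  stopifnot(is.numeric(chromosome_lengths), length(chromosome_lengths) >= 1,
            all(chromosome_lengths > 0),
            !is.null(names(chromosome_lengths)),
            gc_fraction >= 0, gc_fraction <= 1)
  structure(list(chromosome_lengths = round(chromosome_lengths),
                 gc_fraction = gc_fraction, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate random background sequence
#'
#' I.i.d. bases with P(G) = P(C) = gc/2, P(A) = P(T) = (1 - gc)/2. The same
#' seed always yields the same sequence.
#'
#' @param length sequence length in bp (>= 0).
#' @param gc_fraction target GC fraction.
#' @param seed integer seed.
#' @return a character scalar over A/C/G/T of exactly `length` bases.
#' @export
generate_background <- function(length, gc_fraction = 0.42, seed = 1L) {
  if (length < 0) stop("length must be non-negative")
  with_seed(seed, random_dna(as.integer(length), gc_fraction))
}

#' Load the packaged tRNA 3'-end reference set
#'
#' Returns 18-mers representing the 3' termini of the five tRNA classes that
#' prime VL30 reverse transcription (Gly, Pro, Gln, Met, Thr). These are
#' synthetic stand-in sequences (see file name): distinct, CCA-terminated
#' 18-mers, sufficient for planting and recovering PBS assignments.
#'
#' @param path optional path to an alternative FASTA of 3'-terminal 18-mers
#'   named by tRNA class.
#' @return named character vector of 18-mers.
#' @export
trna_3prime_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "trna_3prime_18mers.synthetic.fasta",
                        package = "ltrscape", mustWork = TRUE)
  lib <- read_fasta(path)
  stopifnot(all(nchar(lib) >= 15))
  lib
}

#' Build one element sequence from its specification
#'
#' Full-length layout, 5' to 3': 5'LTR, PBS (reverse complement of the
#' 3'-terminal 18 nt of the chosen tRNA, immediately after the LTR), internal
#' sequence carrying the requested PSF motifs, PPT (consensus with the
#' requested number of A/T substitutions) immediately before the 3'LTR, and a
#' 3'LTR derived from the 5'LTR by per-site random substitution at rate
#' `ltr_divergence`. Truncated elements lack the PPT and 3'LTR; solo elements
#' are a bare LTR.
#'
#' @param spec an [element_spec()].
#' @param seed integer seed.
#' @param gc_fraction base composition of the random portions.
#' @param trna_library named 18-mer vector, see [trna_3prime_library()].
#' @return list with `sequence` (character scalar) and `features`, a
#'   data.frame of element-oriented 0-based half-open intervals
#'   (`feature`, `start`, `end`, `detail`).
#' @export
build_element <- function(spec, seed = 1L, gc_fraction = 0.42,
                          trna_library = trna_3prime_library()) {
  stopifnot(inherits(spec, "element_spec"))
  with_seed(seed, {
    feats <- list()
    add_feat <- function(name, start, len, detail = NA_character_) {
      feats[[length(feats) + 1L]] <<- data.frame(
        feature = name, start = start, end = start + len,
        detail = detail, stringsAsFactors = FALSE)
    }
    ltr5 <- random_dna(spec$ltr_length, gc_fraction)
    parts <- character(0)
    pos <- 0L
    push <- function(s) { parts <<- c(parts, s); pos <<- pos + nchar(s) }
    if (spec$element_class == "solo") {
      add_feat("ltr", 0L, spec$ltr_length)
      return(list(sequence = ltr5, features = do.call(rbind, feats)))
    }
    add_feat("ltr5", 0L, spec$ltr_length)
    push(ltr5)
    if (spec$pbs_trna != "none") {
      t3 <- trna_library[[spec$pbs_trna]]
      t3 <- substr(t3, nchar(t3) - 17L, nchar(t3))
      pbs <- revcomp(t3)
      add_feat("pbs", pos, nchar(pbs), spec$pbs_trna)
      push(pbs)
    }
    # internal region with planted PSF motifs at random non-overlapping slots
    motifs <- if (spec$psf_motif_count == 0L) character(0)
              else unname(PSF_MOTIFS[seq_len(spec$psf_motif_count)])
    need <- sum(nchar(motifs)) + 20L * length(motifs)
    if (spec$internal_length < need)
      stop("internal_length too short to hold the requested PSF motifs")
    internal <- random_dna(spec$internal_length, gc_fraction)
    if (length(motifs)) {
      # carve the internal background into chunks and interleave the motifs
      free <- spec$internal_length - sum(nchar(motifs))
      cuts <- sort(sample.int(free - length(motifs) + 1L, length(motifs)))
      out <- character(0)
      prev <- 0L
      at <- pos
      for (i in seq_along(motifs)) {
        seg <- substr(internal, prev + 1L, cuts[i])
        out <- c(out, seg)
        at <- at + nchar(seg)
        add_feat(paste0("psf", i), at, nchar(motifs[i]),
                 names(PSF_MOTIFS)[i])
        out <- c(out, motifs[i])
        at <- at + nchar(motifs[i])
        prev <- cuts[i]
      }
      out <- c(out, substr(internal, prev + 1L, free))
      internal <- paste(out, collapse = "")
      stopifnot(nchar(internal) == spec$internal_length)
    }
    add_feat("internal", pos, spec$internal_length)
    push(internal)
    if (spec$element_class == "full_length") {
      ppt <- mutate_ppt(PPT_CONSENSUS, spec$ppt_substitutions)
      add_feat("ppt", pos, nchar(ppt), ppt)
      push(ppt)
      ltr3 <- mutate_per_site(ltr5, spec$ltr_divergence)
      add_feat("ltr3", pos, nchar(ltr3))
      push(ltr3)
    }
    list(sequence = paste(parts, collapse = ""),
         features = do.call(rbind, feats))
  })
}

# Apply `n` substitutions to the PPT consensus; every substitution writes an
# A or a T (the variants observed in real elements), never the original base.
mutate_ppt <- function(consensus, n) {
  if (n == 0L) return(consensus)
  v <- strsplit(consensus, "")[[1]]
  pos <- sample(length(v), n)
  for (p in pos) {
    cand <- setdiff(c("A", "T"), v[p])
    v[p] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  paste(v, collapse = "")
}

#' Plant elements into a synthetic genome
#'
#' Builds each element, picks non-overlapping insertion sites, and inserts
#' each element flanked by an exact duplication of the `tsd_length`-bp target
#' site (the TSD), mimicking retroviral integration. Minus-strand elements
#' are inserted as the reverse complement of the built sequence.
#'
#' @param gspec a [genome_spec()].
#' @param specs list of [element_spec()] objects.
#' @param seed integer seed; defaults to the genome spec's seed.
#' @param min_gap minimum distance in bp kept between planted elements
#'   (leaves flanks clean for TSD/GC analyses).
#' @param max_tries placement retries before giving up.
#' @return list with `genome` (named character vector of chromosome
#'   sequences) and `truth`, a data.frame with one row per planted element:
#'   element_id, chromosome, start, end, strand, element_class, genomic LTR
#'   intervals, tsd, pbs_trna, ppt_substitutions, psf_count plus the planted
#'   sequences (`sequence`, element-oriented).
#' @export
plant_elements <- function(gspec, specs, seed = NULL, min_gap = 1000L,
                           max_tries = 200L) {
  stopifnot(inherits(gspec, "genome_spec"))
  seed <- seed %||% gspec$seed
  lens <- gspec$chromosome_lengths
  genome <- setNames(vapply(seq_along(lens), function(i)
    generate_background(lens[[i]], gspec$gc_fraction,
                        derive_seed(seed, paste0("bg:", names(lens)[i]))),
    character(1)), names(lens))
  if (length(specs) == 0L)
    return(list(genome = genome, truth = empty_truth()))
  built <- lapply(seq_along(specs), function(i)
    build_element(specs[[i]], derive_seed(seed, paste0("elem:", i)),
                  gspec$gc_fraction))
  with_seed(derive_seed(seed, "placement"), {
    total <- sum(vapply(built, function(b) nchar(b$sequence), numeric(1)))
    if (any(total >= lens))
      stop("placement error: total planted length exceeds a chromosome")
    # choose (chromosome, position-in-background) per element, no overlap
    occupied <- lapply(lens, function(...) matrix(numeric(0), ncol = 2))
    placement <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      elen <- nchar(built[[i]]$sequence)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        ci <- sample(seq_along(lens), 1L, prob = lens)
        pmax_ <- lens[[ci]] - elen - 2L * specs[[i]]$tsd_length - min_gap
        if (pmax_ <= min_gap) next
        p <- sample(seq.int(min_gap, pmax_), 1L)
        occ <- occupied[[ci]]
        if (nrow(occ) == 0 ||
            all(p + elen + min_gap < occ[, 1] | p > occ[, 2] + min_gap)) {
          occupied[[ci]] <- rbind(occ, c(p, p + elen))
          placement[[i]] <- list(chrom = ci, p = p)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("placement error: could not place element ", i,
                    " without overlap after ", max_tries, " tries")
    }
    rows <- list()
    for (ci in seq_along(lens)) {
      idx <- which(vapply(placement, function(pl) pl$chrom == ci, logical(1)))
      if (!length(idx)) next
      idx <- idx[order(vapply(placement[idx], `[[`, numeric(1), "p"))]
      bg <- genome[[ci]]
      pieces <- character(0)
      out_len <- 0L
      prev <- 0L # background consumed so far (0-based)
      for (i in idx) {
        sp <- specs[[i]]
        p <- placement[[i]]$p
        tl <- sp$tsd_length
        tsd <- substr(bg, p + 1L, p + tl)
        eseq <- built[[i]]$sequence
        planted <- if (sp$strand == "+") eseq else revcomp(eseq)
        left <- substr(bg, prev + 1L, p + tl)
        pieces <- c(pieces, left, planted)
        start <- out_len + nchar(left)
        end <- start + nchar(planted)
        out_len <- end
        prev <- p # right copy of the TSD starts the remaining background
        rows[[length(rows) + 1L]] <- truth_row(
          i, names(lens)[ci], start, end, sp, built[[i]], tsd)
      }
      pieces <- c(pieces, substr(bg, prev + 1L, nchar(bg)))
      genome[[ci]] <- paste(pieces, collapse = "")
    }
    truth <- do.call(rbind, rows)
    truth <- truth[order(truth$chromosome, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(genome = genome, truth = truth)
  })
}

empty_truth <- function() {
  data.frame(element_id = character(0), chromosome = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             element_class = character(0),
             ltr5_start = integer(0), ltr5_end = integer(0),
             ltr3_start = integer(0), ltr3_end = integer(0),
             tsd = character(0), pbs_trna = character(0),
             ppt_substitutions = integer(0), psf_count = integer(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

truth_row <- function(i, chrom, start, end, sp, built, tsd) {
  f <- built$features
  ltr5 <- f[f$feature %in% c("ltr5", "ltr"), , drop = FALSE]
  ltr3 <- f[f$feature == "ltr3", , drop = FALSE]
  elen <- end - start
  # map element-oriented offsets to genomic coordinates
  g <- function(iv) {
    if (nrow(iv) == 0) return(c(NA_integer_, NA_integer_))
    if (sp$strand == "+") c(start + iv$start, start + iv$end)
    else c(end - iv$end, end - iv$start)
  }
  l5 <- g(ltr5); l3 <- g(ltr3)
  data.frame(element_id = sprintf("elem_%03d", i), chromosome = chrom,
             start = start, end = end, strand = sp$strand,
             element_class = sp$element_class,
             ltr5_start = l5[1], ltr5_end = l5[2],
             ltr3_start = l3[1], ltr3_end = l3[2],
             tsd = tsd,
             pbs_trna = sp$pbs_trna,
             ppt_substitutions = if (sp$element_class == "full_length")
               sp$ppt_substitutions else NA_integer_,
             psf_count = sp$psf_motif_count,
             sequence = built$sequence, stringsAsFactors = FALSE)
}

#' Generate random non-overlapping gene models
#'
#' Plants `n_genes` multi-exon gene models (2-5 exons, 2-10 kb span) on both
#' strands, non-overlapping, for use by the TSS-distance and gene-context
#' analyses. Deterministic given the seed.
#'
#' @param gspec a [genome_spec()] (or any object with `chromosome_lengths`).
#' @param n_genes number of genes (>= 0).
#' @param seed integer seed.
#' @param chromosome_lengths optional named lengths overriding the spec (use
#'   the post-planting lengths when annotating a planted genome).
#' @return a `gene_models` data.frame: gene_id, chromosome, strand, start,
#'   end, tss (0-based), and `exons`, a list-column of 2-column matrices of
#'   0-based half-open exon intervals.
#' @export
generate_gene_models <- function(gspec, n_genes, seed = 1L,
                                 chromosome_lengths = NULL) {
  lens <- chromosome_lengths %||% gspec$chromosome_lengths
  stopifnot(n_genes >= 0)
  if (n_genes == 0L) return(empty_gene_models())
  with_seed(seed, {
    occupied <- lapply(lens, function(...) matrix(numeric(0), ncol = 2))
    rows <- list()
    for (i in seq_len(n_genes)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        ci <- sample(seq_along(lens), 1L, prob = lens)
        span <- sample(2000:10000, 1L)
        if (lens[[ci]] <= span + 2000L) next
        start <- sample.int(lens[[ci]] - span - 1000L, 1L)
        occ <- occupied[[ci]]
        if (nrow(occ) && any(start <= occ[, 2] + 500 &
                             start + span >= occ[, 1] - 500)) next
        occupied[[ci]] <- rbind(occ, c(start, start + span))
        strand <- sample(c("+", "-"), 1L)
        n_ex <- sample(2:5, 1L)
        # exon/intron layout: cut the span into 2*n_ex - 1 ordered blocks
        cuts <- sort(sample.int(span - 1L, 2L * n_ex - 2L))
        bounds <- c(0L, cuts, span)
        ex <- cbind(start + bounds[seq(1, 2 * n_ex - 1, by = 2)],
                    start + bounds[seq(2, 2 * n_ex, by = 2)])
        ex <- ex[ex[, 2] > ex[, 1], , drop = FALSE]
        if (nrow(ex) < 2L) next
        tss <- if (strand == "+") start else start + span
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sprintf("gene_%03d", i), chromosome = names(lens)[ci],
          strand = strand, start = start, end = start + span, tss = tss,
          stringsAsFactors = FALSE)
        attr(rows[[length(rows)]], "exons") <- ex
        placed <- TRUE
        break
      }
      if (!placed) stop("placement error: genes cannot fit")
    }
    exons <- lapply(rows, attr, "exons")
    gm <- do.call(rbind, rows)
    gm$exons <- exons
    ord <- order(gm$chromosome, gm$start)
    gm <- gm[ord, , drop = FALSE]
    rownames(gm) <- NULL
    class(gm) <- c("gene_models", "data.frame")
    gm
  })
}

empty_gene_models <- function() {
  gm <- data.frame(gene_id = character(0), chromosome = character(0),
                   strand = character(0), start = integer(0),
                   end = integer(0), tss = integer(0),
                   stringsAsFactors = FALSE)
  gm$exons <- list()
  class(gm) <- c("gene_models", "data.frame")
  gm
}
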