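# Pipeline orchestration: annotate a catalogue of loci on a genome, then run
# the census end-to-end (signals, dating, phylogeny, distribution) and write
# a report bundle. A flat YAML config drives the CLI (`exec/ltrscape`).

#' Extract the element-oriented sequence of a record
#'
#' Minus-strand loci are reverse-complemented so that all signal scanning
#' happens on the plus-sense (element-oriented) sequence.
#'
#' @param genome named character vector of chromosome sequences.
#' @param record one catalogue row (list or single-row data.frame).
#' @return character scalar.
#' @export
element_sequence <- function(genome, record) {
  s <- substr(genome[[record$chromosome]], record$start + 1L, record$end)
  if (record$strand == "-") revcomp(s) else s
}

#' Annotate loci: LTR pairs, TSD, PBS, PPT, PSF and classification
#'
#' For every locus interval, extracts the element-oriented sequence, finds
#' the LTR pair, scans the replication signals, detects the flanking TSD,
#' and applies the full-length/truncated/solo classification rule.
#'
#' @param genome named character vector of chromosome sequences.
#' @param loci data.frame with chromosome, start, end, strand (and
#'   optionally element_id).
#' @param trna_library named tRNA 3'-end 18-mers.
#' @param min_ltr,min_identity LTR-pair thresholds (see [find_ltr_pair()]).
#' @param max_ltr_length solo-LTR length ceiling (see [classify_element()]).
#' @param flank flank width used for TSD detection (bp).
#' @return an `element_catalogue` data.frame with classification and signal
#'   columns filled in.
#' @export
annotate_loci <- function(genome, loci, trna_library = trna_3prime_library(),
                          min_ltr = 100L, min_identity = 0.8,
                          max_ltr_length = 1000L, flank = 20L) {
  n <- nrow(loci)
  ids <- if ("element_id" %in% names(loci)) loci$element_id
         else sprintf("locus_%03d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    rec <- loci[i, ]
    seq <- element_sequence(genome, rec)
    pair <- find_ltr_pair(seq, min_ltr, min_identity)
    pbs <- ppt <- NULL
    if (!is.null(pair)) {
      pbs <- detect_pbs(seq, pair$ltr5_interval[2], trna_library)
      ppt <- detect_ppt(seq, pair$ltr3_interval[1])
    } else {
      # truncated elements keep a 5' LTR: probe right after the best
      # LTR-sized prefix by scanning the first 1 kb for a PBS
      pbs <- tryCatch(detect_pbs(seq, 0L, trna_library,
                                 window = min(1000L, nchar(seq))),
                      error = function(e) NULL)
    }
    cls <- classify_element(seq, pair, pbs, ppt,
                            max_ltr_length = max_ltr_length)
    # TSD from genomic flanks (genome-oriented; duplication is symmetric)
    chromseq <- genome[[rec$chromosome]]
    tsd <- NULL
    if (rec$start >= flank && nchar(chromseq) - rec$end >= flank) {
      left <- substr(chromseq, rec$start - flank + 1L, rec$start)
      right <- substr(chromseq, rec$end + 1L, rec$end + flank)
      tsd <- detect_tsd(left, right)
    }
    g5 <- g3 <- c(NA_integer_, NA_integer_)
    if (!is.null(pair)) {
      tog <- function(iv) {
        if (rec$strand == "+") c(rec$start + iv[1], rec$start + iv[2])
        else c(rec$end - iv[2], rec$end - iv[1])
      }
      g5 <- tog(pair$ltr5_interval); g3 <- tog(pair$ltr3_interval)
    }
    data.frame(element_id = ids[i], chromosome = rec$chromosome,
               start = rec$start, end = rec$end, strand = rec$strand,
               element_class = cls,
               ltr5_start = g5[1], ltr5_end = g5[2],
               ltr3_start = g3[1], ltr3_end = g3[2],
               tsd = if (is.null(tsd)) NA_character_ else tsd$motif,
               pbs_trna = if (is.null(pbs)) NA_character_ else pbs$trna,
               ppt_substitutions = if (is.null(ppt)) NA_integer_
                 else ppt$substitutions,
               psf_count = if (cls == "solo") NA_integer_
                 else count_psf_motifs(seq),
               stringsAsFactors = FALSE)
  })
  as_catalogue(do.call(rbind, rows))
}

#' Read a flat YAML pipeline configuration
#'
#' @param path YAML file with the pipeline fields (paths, thresholds, seed).
#' @return named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::yaml.load_file(path)
  if (is.null(cfg$seed)) stop("config error: seed is mandatory")
  cfg
}

#' Run the full census pipeline
#'
#' Stages: (optional) simulate a genome with planted elements, discover
#' candidate loci against a consensus library (or load a catalogue),
#' annotate and classify, tally replication signals, date full-length LTR
#' pairs, build the 5'-LTR phylogeny, and test the genomic distribution.
#' Writes catalogue TSV/BED, an ages TSV, a newick tree, a JSON summary and
#' a run log into `out_dir`.
#'
#' @param config named list (see [read_config()]); recognised fields:
#'   `seed` (mandatory), `out_dir`, `genome_fasta`, `catalogue`,
#'   `library_fasta`, `gene_models_gff3`, and the `simulate` block
#'   (`chromosome_lengths`, `gc_fraction`, `n_elements`, `n_genes`).
#' @return invisible list with the stage results.
#' @export
run_census <- function(config) {
  seed <- as.integer(config$seed %||% stop("config error: seed is mandatory"))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(package = "ltrscape",
              version = as.character(packageVersion("ltrscape")),
              seed = seed, config = config)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  genes <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    lens <- unlist(sim$chromosome_lengths)
    gs <- genome_spec(lens, sim$gc_fraction %||% 0.42, seed)
    specs <- with_seed(derive_seed(seed, "specs"), lapply(
      seq_len(sim$n_elements %||% 10L), function(i)
        random_element_spec()))
    planted <- stage("simulate", plant_elements(gs, specs, seed))
    genome <- planted$genome
    truth <- planted$truth
    lens_final <- setNames(nchar(genome), names(genome))
    genes <- stage("simulate",
                   generate_gene_models(gs, sim$n_genes %||% 20L,
                                        derive_seed(seed, "genes"),
                                        chromosome_lengths = lens_final))
    write_fasta(genome, file.path(out_dir, "genome.fasta"))
    write_catalogue(truth[, setdiff(names(truth), "sequence")],
                    file.path(out_dir, "truth.tsv"))
    write_gff3(genes, file.path(out_dir, "genes.gff3"))
  } else {
    genome <- stage("input", read_fasta(
      config$genome_fasta %||% stop("config error: genome_fasta required")))
    if (!is.null(config$gene_models_gff3))
      genes <- stage("input", read_gff3(config$gene_models_gff3))
  }
  loci <- if (!is.null(config$catalogue)) {
    stage("catalogue", read_catalogue(config$catalogue))
  } else if (!is.null(truth)) {
    truth
  } else if (!is.null(config$library_fasta)) {
    lib <- read_fasta(config$library_fasta)
    stage("discover", discover_candidate_loci(genome, lib))
  } else stop("config error: need a catalogue, truth table or library")
  cat_out <- stage("annotate", annotate_loci(genome, loci))
  write_catalogue(cat_out, file.path(out_dir, "catalogue.tsv"),
                  file.path(out_dir, "catalogue.bed"))
  # signal summary
  summary <- list(
    total_loci = nrow(cat_out),
    class_counts = as.list(table(cat_out$element_class)),
    pbs_tally = as.list(table(cat_out$pbs_trna[!is.na(cat_out$pbs_trna)])),
    ppt_exact = sum(cat_out$ppt_substitutions == 0, na.rm = TRUE),
    ppt_substituted = sum(cat_out$ppt_substitutions > 0, na.rm = TRUE),
    psf_tally = as.list(table(cat_out$psf_count[!is.na(cat_out$psf_count)])))
  # dating of full-length LTR pairs
  fl <- cat_out[cat_out$element_class == "full_length" &
                  !is.na(cat_out$ltr5_start), , drop = FALSE]
  ages <- NULL
  if (nrow(fl)) {
    ages <- stage("date", do.call(rbind, lapply(seq_len(nrow(fl)),
      function(i) {
        r <- fl[i, ]
        seq <- element_sequence(genome, r)
        pair <- find_ltr_pair(seq)
        est <- date_ltr_pair(
          substr(seq, pair$ltr5_interval[1] + 1L, pair$ltr5_interval[2]),
          substr(seq, pair$ltr3_interval[1] + 1L, pair$ltr3_interval[2]))
        data.frame(element_id = r$element_id,
                   divergence = est$divergence,
                   age_years = est$age_years,
                   identical_ltrs = est$identical_ltrs,
                   formula_variant = est$formula_variant,
                   stringsAsFactors = FALSE)
      })))
    write.table(ages, file.path(out_dir, "ages.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$identical_ltr_pairs <- sum(ages$identical_ltrs)
  }
  # phylogeny of 5' LTRs
  if (nrow(fl) >= 3L) {
    ltr5 <- setNames(vapply(seq_len(nrow(fl)), function(i) {
      r <- fl[i, ]
      seq <- element_sequence(genome, r)
      pair <- find_ltr_pair(seq)
      substr(seq, pair$ltr5_interval[1] + 1L, pair$ltr5_interval[2])
    }, character(1)), fl$element_id)
    tree <- stage("phylo", {
      msa <- center_star_msa(ltr5)
      bootstrap_support(msa, n_replicates = config$bootstrap %||% 100L,
                        seed = derive_seed(seed, "bootstrap"))
    })
    ape::write.tree(tree, file.path(out_dir, "ltr_phylogeny.nwk"))
  }
  # genomic distribution
  lens_final <- setNames(nchar(genome), names(genome))
  model <- stage("dist", chromosome_model(cat_out, lens_final))
  gof <- chisq_gof(model$observed, model$expected)
  dist_report <- list(chromosome_model = model, chisq = gof,
                      flank_gc = flank_gc(genome, cat_out)$mean_gc,
                      clusters = find_clusters(
                        cat_out, config$cluster_window %||% 1.5e6,
                        config$cluster_min %||% 8L))
  if (!is.null(genes) && nrow(genes)) {
    dist_report$tss_bins <- as.list(table(
      nearest_tss_binning(cat_out, genes)$bin))
    dist_report$gene_context <- as.list(table(
      classify_gene_context(cat_out, genes)$category))
  }
  summary$distribution <- dist_report[c("chisq", "flank_gc")]
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log$config_hash <- digest_config(config)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(catalogue = cat_out, summary = summary, ages = ages,
                 distribution = dist_report, truth = truth,
                 genes = genes, genome = genome))
}

# Stable content hash of the config (md5 of its canonical JSON).
digest_config <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE)
  tf <- tempfile()
  writeLines(json, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' Draw a random element specification
#'
#' Samples a class (proportions 86:49:237 full-length:truncated:solo, the
#' observed VL30 census composition), an LTR length uniform in 436-681 bp,
#' a tRNA class, 0-2 PPT substitutions and 0-2 PSF motifs.
#'
#' @param element_class optional fixed class.
#' @param ltr_divergence per-site LTR divergence (default 0.02).
#' @return an [element_spec()].
#' @export
random_element_spec <- function(element_class = NULL,
                                ltr_divergence = 0.02) {
  cls <- element_class %||%
    sample(c("full_length", "truncated", "solo"), 1L,
           prob = c(86, 49, 237) / 372)
  ltr_len <- sample(436:681, 1L)
  if (cls == "solo")
    return(element_spec("solo", ltr_length = ltr_len, pbs_trna = "none",
                        psf_motif_count = 0L, internal_length = 0L,
                        strand = sample(c("+", "-"), 1L)))
  element_spec(cls, ltr_length = ltr_len, ltr_divergence = ltr_divergence,
               pbs_trna = sample(TRNA_CLASSES, 1L,
                                 prob = c(57, 17, 10, 1, 1) / 86),
               ppt_substitutions = sample(0:2, 1L, prob = c(68, 12, 6) / 86),
               psf_motif_count = sample(0:2, 1L, prob = c(3, 5, 78) / 86),
               internal_length = sample(3000:5000, 1L),
               strand = sample(c("+", "-"), 1L))
}
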