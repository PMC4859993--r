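# Readers/writers for the formats shared by all stages: FASTA genomes,
# element catalogues (TSV + BED6), and gene models (GFF3). The catalogue TSV
# schema is frozen: the columns of an ElementRecord, in order; unknown extra
# columns are preserved opaquely and round-trip unchanged.

CATALOGUE_COLUMNS <- c("element_id", "chromosome", "start", "end", "strand",
                       "element_class", "ltr5_start", "ltr5_end",
                       "ltr3_start", "ltr3_end", "tsd", "pbs_trna",
                       "ppt_substitutions", "psf_count")
ELEMENT_CLASSES <- c("full_length", "truncated", "solo")

#' Read a FASTA file
#'
#' Sequences are upper-cased on ingest; CRLF line endings and mixed case are
#' tolerated.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences as FASTA (60-column wrapped)
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read an element catalogue (TSV or BED)
#'
#' The TSV schema is the frozen ElementRecord column set (see
#' [write_catalogue()]); extra columns are preserved. BED6 input yields
#' minimal records (no class or signal columns). Malformed rows are rejected
#' with their line numbers.
#'
#' @param path path to a `.tsv`/`.txt` catalogue or a `.bed` file.
#' @return a data.frame of class `element_catalogue`, 0-based half-open
#'   coordinates.
#' @export
read_catalogue <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE))
    return(read_catalogue_bed(path))
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  missing <- setdiff(c("element_id", "chromosome", "start", "end",
                       "strand", "element_class"), names(df))
  if (length(missing))
    stop("catalogue header lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(as_catalogue(df))
  # header is line 1; data row i sits on file line i + 1
  line <- seq_len(nrow(df)) + 1L
  bad <- function(cond, what) {
    if (any(cond))
      stop("format error in ", path, ": ", what, " at line(s) ",
           paste(line[cond], collapse = ", "))
  }
  bad(!df$strand %in% c("+", "-"), "unknown strand")
  bad(!df$element_class %in% ELEMENT_CLASSES, "unknown element_class")
  bad(!is.finite(df$start) | !is.finite(df$end) | df$end <= df$start,
      "end <= start")
  as_catalogue(df)
}

read_catalogue_bed <- function(path) {
  df <- read.delim(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("BED catalogue needs >= 6 columns")
  out <- data.frame(element_id = as.character(df[[4]]),
                    chromosome = as.character(df[[1]]),
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                    strand = as.character(df[[6]]),
                    element_class = NA_character_, stringsAsFactors = FALSE)
  # drop LTR sub-interval rows emitted by write_catalogue
  out <- out[!grepl("/LTR[35]$", out$element_id), , drop = FALSE]
  bad <- which(out$end <= out$start | !out$strand %in% c("+", "-"))
  if (length(bad))
    stop("format error in ", path, " at line(s) ",
         paste(bad, collapse = ", "))
  as_catalogue(out)
}

CATALOGUE_INT_COLUMNS <- c("start", "end", "ltr5_start", "ltr5_end",
                           "ltr3_start", "ltr3_end", "ppt_substitutions",
                           "psf_count")

as_catalogue <- function(df) {
  n <- nrow(df)
  for (col in CATALOGUE_COLUMNS) {
    if (!col %in% names(df))
      df[[col]] <- rep(if (col %in% CATALOGUE_INT_COLUMNS) NA_integer_
                       else NA_character_, n)
    # columns that are entirely NA come back typeless from read.delim
    df[[col]] <- if (col %in% CATALOGUE_INT_COLUMNS)
      as.integer(df[[col]]) else as.character(df[[col]])
  }
  extra <- setdiff(names(df), CATALOGUE_COLUMNS)
  df <- df[, c(CATALOGUE_COLUMNS, extra), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("element_catalogue", "data.frame")
  df
}

#' Write an element catalogue as TSV (and optionally BED6)
#'
#' The TSV is the authoritative representation and round-trips exactly
#' through [read_catalogue()]. The BED6 export writes one row per element
#' (name = element_id, score = 0) plus extra rows for LTR sub-intervals
#' suffixed `/LTR5` and `/LTR3` when present.
#'
#' @param records an `element_catalogue` data.frame.
#' @param path output TSV path.
#' @param bed_path optional output BED6 path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(records, path, bed_path = NULL) {
  stopifnot(is.data.frame(records))
  records <- as_catalogue(as.data.frame(records))
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  if (!is.null(bed_path)) {
    bed <- data.frame(records$chromosome, records$start, records$end,
                      records$element_id, 0L, records$strand)
    sub <- function(s, e, suffix) {
      keep <- !is.na(s)
      data.frame(records$chromosome[keep], s[keep], e[keep],
                 paste0(records$element_id[keep], suffix), 0L,
                 records$strand[keep])
    }
    rows <- list(bed)
    if (any(!is.na(records$ltr5_start)))
      rows <- c(rows, list(setNames(sub(records$ltr5_start,
                                        records$ltr5_end, "/LTR5"),
                                    names(bed))))
    if (any(!is.na(records$ltr3_start)))
      rows <- c(rows, list(setNames(sub(records$ltr3_start,
                                        records$ltr3_end, "/LTR3"),
                                    names(bed))))
    bed <- do.call(rbind, rows)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits `gene` and `exon` features with ID/Parent attributes. Output is
#' deterministic (byte-identical for identical input).
#'
#' @param gene_models a `gene_models` data.frame (see
#'   [generate_gene_models()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gene_models, path) {
  con <- file(path, "wb") # binary mode: stable \n endings on all platforms
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  for (i in seq_len(nrow(gene_models))) {
    g <- gene_models[i, ]
    # GFF3 is 1-based closed
    writeLines(paste(g$chromosome, "ltrscape", "gene", g$start + 1L, g$end,
                     ".", g$strand, ".", paste0("ID=", g$gene_id),
                     sep = "\t"), con, sep = "\n")
    ex <- gene_models$exons[[i]]
    for (j in seq_len(nrow(ex)))
      writeLines(paste(g$chromosome, "ltrscape", "exon", ex[j, 1] + 1L,
                       ex[j, 2], ".", g$strand, ".",
                       paste0("ID=", g$gene_id, ".exon", j, ";Parent=",
                              g$gene_id),
                       sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `exon` features (ID/Parent attributes); exons are
#' attached to their parent gene and sorted. TSS is the strand-aware 5' end
#' of the gene.
#'
#' @param path GFF3 path.
#' @return a `gene_models` data.frame (0-based half-open coordinates).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(empty_gene_models())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 9L)
  if (length(bad)) stop("malformed GFF3 line(s): ", paste(bad, collapse = ", "))
  m <- do.call(rbind, f)
  type <- m[, 3]
  attr_field <- function(x, key) {
    parts <- strsplit(x, ";", fixed = TRUE)[[1]]
    hit <- grep(paste0("^", key, "="), parts, value = TRUE)
    if (!length(hit)) NA_character_
    else sub(paste0("^", key, "="), "", hit[1])
  }
  genes <- which(type == "gene")
  if (!length(genes)) return(empty_gene_models())
  ids <- vapply(m[genes, 9], function(a) attr_field(a, "ID"), character(1))
  gm <- data.frame(gene_id = unname(ids), chromosome = m[genes, 1],
                   strand = m[genes, 7],
                   start = as.integer(m[genes, 4]) - 1L,
                   end = as.integer(m[genes, 5]), stringsAsFactors = FALSE)
  gm$tss <- ifelse(gm$strand == "+", gm$start, gm$end)
  exons <- which(type == "exon")
  parent <- vapply(m[exons, 9], function(a) attr_field(a, "Parent"),
                   character(1))
  gm$exons <- lapply(gm$gene_id, function(g) {
    rows <- exons[parent == g]
    ex <- cbind(as.integer(m[rows, 4]) - 1L, as.integer(m[rows, 5]))
    ex[order(ex[, 1]), , drop = FALSE]
  })
  class(gm) <- c("gene_models", "data.frame")
  gm
}
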