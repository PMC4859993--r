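# Internal helpers shared across modules. All sequences are plain uppercase
# character scalars over {A,C,G,T} unless stated otherwise; coordinates are
# 0-based half-open internally, converted only at BED/GFF boundaries.

BASES <- c("A", "C", "G", "T")

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stable 31-bit sub-seed for a named stage from one master seed.
derive_seed <- function(seed, stage) {
  bytes <- utf8ToInt(paste0(stage, ":", as.integer(seed)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings (A/C/G/T plus
#' IUPAC ambiguity codes are accepted).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

random_dna <- function(n, gc_fraction = 0.42) {
  if (n == 0L) return("")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

gc_fraction_of <- function(x) {
  if (!nzchar(x)) return(NA_real_)
  n <- nchar(x)
  gc <- n - nchar(gsub("[GCgc]", "", x))
  gc / n
}

# Count mismatches between two equal-length ungapped strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Substitute `n_sub` uniformly chosen positions of `x` with a uniformly
# chosen alternative base (never the original).
mutate_positions <- function(x, n_sub) {
  if (n_sub == 0L) return(x)
  v <- strsplit(x, "")[[1]]
  pos <- sample(length(v), n_sub)
  for (p in pos) v[p] <- sample(setdiff(BASES, v[p]), 1L)
  paste(v, collapse = "")
}

# Per-site Bernoulli(d) substitution (uniform over the 3 alternatives).
mutate_per_site <- function(x, d) {
  if (d <= 0) return(x)
  v <- strsplit(x, "")[[1]]
  hit <- runif(length(v)) < d
  for (p in which(hit)) v[p] <- sample(setdiff(BASES, v[p]), 1L)
  paste(v, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
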