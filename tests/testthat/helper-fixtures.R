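# Shared fixtures and independent oracles, all generated in code.

# A small genome with planted elements of every class.
make_planted <- function(n = 8L, seed = 42L, divergence = 0.02,
                         lens = c(chr1 = 200000L, chr2 = 150000L),
                         classes = NULL) {
  gs <- genome_spec(lens, seed = seed)
  specs <- ltrscape:::with_seed(seed + 1L, lapply(seq_len(n), function(i) {
    cls <- if (is.null(classes)) NULL else classes[(i - 1L) %% length(classes) + 1L]
    random_element_spec(cls, ltr_divergence = divergence)
  }))
  c(plant_elements(gs, specs), list(gspec = gs, specs = specs))
}

# Naive O(n*m) motif scan oracle.
naive_scan <- function(sequence, motif, max_mismatch) {
  sv <- strsplit(sequence, "")[[1]]
  mv <- strsplit(motif, "")[[1]]
  n <- length(sv); m <- length(mv)
  hits <- list()
  if (n >= m) for (s in 0:(n - m)) {
    mm <- sum(sv[(s + 1):(s + m)] != mv)
    if (mm <= max_mismatch)
      hits[[length(hits) + 1L]] <- data.frame(offset = s, mismatches = mm)
  }
  if (!length(hits)) return(data.frame(offset = integer(0),
                                       mismatches = integer(0)))
  do.call(rbind, hits)
}

# Random additive (tree-metric) distance matrix from a random topology with
# positive branch lengths; returns the matrix and the generating tree.
random_tree_metric <- function(n, seed) {
  ltrscape:::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(tr)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    list(tree = tr, d = d)
  })
}

# Unrooted Robinson-Foulds distance.
rf_dist <- function(t1, t2) as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)))

random_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else ltrscape:::with_seed(seed, draw())
}

# Evolve each base of `x` with the given per-site substitution probability
# (uniform over alternatives) - used for planting diverged copies.
perturb_seq <- function(x, d, seed) {
  ltrscape:::with_seed(seed, ltrscape:::mutate_per_site(x, d))
}
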