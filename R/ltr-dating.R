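# LTR-pair dating: global alignment of paired LTRs, substitution accounting
# under the Tamura-Nei (1993) model, and conversion of divergence to an
# integration age under a neutral molecular clock. At integration the two
# LTRs of an element are identical; each subsequently accumulates mutations
# independently, so divergence d at rate mu per site per year corresponds to
# an age of T = d / (2 mu) (the default `half` variant; `full` = d / mu is
# also provided because published analyses do not always state which was
# used).

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment under a linear gap scheme (defaults match +1,
#' mismatch -1, gap -2) with deterministic traceback (diagonal > up > left).
#'
#' @param a,b sequences (non-empty character scalars).
#' @param match,mismatch,gap scoring parameters.
#' @return list of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  al <- .nw_align_cpp(toupper(a), toupper(b), match, mismatch, gap)
  structure(al, class = "pairwise_alignment")
}

#' Substitution statistics and Tamura-Nei distance of an alignment
#'
#' Gap columns are excluded. Transitions are split into A<->G and C<->T; all
#' other differences are transversions. Base frequencies are the empirical
#' frequencies over both sequences at gap-free columns. The TN93 distance is
#' the closed form
#' \deqn{d = -k_1 \log w_1 - k_2 \log w_2 - k_3 \log w_3}
#' with \eqn{k_1 = 2\pi_A\pi_G/\pi_R}, \eqn{k_2 = 2\pi_T\pi_C/\pi_Y},
#' \eqn{k_3 = 2(\pi_R\pi_Y - \pi_A\pi_G\pi_Y/\pi_R - \pi_T\pi_C\pi_R/\pi_Y)}
#' and \eqn{w_1 = 1 - P_1/k_1 - Q/(2\pi_R)}, \eqn{w_2 = 1 - P_2/k_2 -
#' Q/(2\pi_Y)}, \eqn{w_3 = 1 - Q/(2\pi_R\pi_Y)}, where \eqn{P_1, P_2, Q} are
#' the two transition proportions and the transversion proportion. When any
#' logarithm argument is non-positive the distance is saturated and reported
#' as `NaN` with `saturated = TRUE`.
#'
#' @param alignment a `pairwise_alignment` from [global_align()] (or any
#'   list with equal-length `aligned_a`/`aligned_b`).
#' @return list of class `divergence_stats`: aligned_sites, transitions_AG,
#'   transitions_CT, transversions, gap_columns, base_frequencies (named
#'   A/C/G/T), p_distance, tn93_distance, saturated.
#' @export
divergence <- function(alignment) {
  av <- strsplit(alignment$aligned_a, "")[[1]]
  bv <- strsplit(alignment$aligned_b, "")[[1]]
  stopifnot(length(av) == length(bv))
  gap <- av == "-" | bv == "-"
  a <- av[!gap]; b <- bv[!gap]
  n <- length(a)
  if (n == 0L) stop("undefined distance: zero gap-free columns")
  diff <- a != b
  ts_ag <- sum((a == "A" & b == "G") | (a == "G" & b == "A"))
  ts_ct <- sum((a == "C" & b == "T") | (a == "T" & b == "C"))
  tv <- sum(diff) - ts_ag - ts_ct
  freq <- (tabulate(match(a, BASES), 4L) + tabulate(match(b, BASES), 4L)) /
    (2 * n)
  names(freq) <- BASES
  P1 <- ts_ag / n; P2 <- ts_ct / n; Q <- tv / n
  pA <- freq["A"]; pC <- freq["C"]; pG <- freq["G"]; pT <- freq["T"]
  pR <- pA + pG; pY <- pC + pT
  k1 <- if (pR > 0) 2 * pA * pG / pR else 0
  k2 <- if (pY > 0) 2 * pT * pC / pY else 0
  k3 <- 2 * (pR * pY -
               (if (pR > 0) pA * pG * pY / pR else 0) -
               (if (pY > 0) pT * pC * pR / pY else 0))
  term <- function(k, P, denom) {
    if (k == 0) { if (P > 0) return(NaN) else return(0) }
    w <- 1 - P / k - Q / denom
    if (w <= 0) return(NaN)
    -k * log(w)
  }
  t1 <- term(k1, P1, 2 * pR)
  t2 <- term(k2, P2, 2 * pY)
  t3 <- if (pR * pY == 0) { if (Q > 0) NaN else 0 } else {
    w3 <- 1 - Q / (2 * pR * pY)
    if (w3 <= 0) NaN else -k3 * log(w3)
  }
  d <- unname(t1 + t2 + t3)
  structure(list(aligned_sites = n, transitions_AG = ts_ag,
                 transitions_CT = ts_ct, transversions = tv,
                 gap_columns = sum(gap), base_frequencies = freq,
                 p_distance = unname(sum(diff) / n),
                 tn93_distance = d, saturated = is.nan(d)),
            class = "divergence_stats")
}

#' Convert LTR-pair divergence to an integration age
#'
#' Under the default `half` variant, `age = d / (2 * rate)`: each LTR of a
#' pair accumulates substitutions independently after integration, so the
#' observed divergence is twice the per-lineage distance. The `full` variant
#' (`age = d / rate`) is provided for comparison with analyses whose
#' arithmetic is not stated. Dating uses the raw substitution proportion
#' (p-distance) by default; gap columns never count as substitutions.
#'
#' @param stats a `divergence_stats` object.
#' @param rate substitutions per site per year (> 0); the default is the
#'   mean mouse genomic rate, 4.6e-9.
#' @param formula_variant `"half"` (default) or `"full"`.
#' @param distance `"p"` (default) or `"tn93"`.
#' @return list of class `age_estimate`: divergence, rate, formula_variant,
#'   age_years, identical_ltrs.
#' @export
estimate_age <- function(stats, rate = MOUSE_SUBSTITUTION_RATE,
                         formula_variant = c("half", "full"),
                         distance = c("p", "tn93")) {
  formula_variant <- match.arg(formula_variant)
  distance <- match.arg(distance)
  stopifnot(rate > 0)
  d <- if (distance == "p") stats$p_distance else stats$tn93_distance
  if (is.nan(d))
    stop("saturated distance: no finite TN93 estimate; ",
         "use distance = \"p\" (raw substitution proportion) instead")
  nsub <- stats$transitions_AG + stats$transitions_CT + stats$transversions
  age <- if (formula_variant == "half") d / (2 * rate) else d / rate
  structure(list(divergence = d, rate = rate,
                 formula_variant = formula_variant, age_years = age,
                 identical_ltrs = (nsub == 0L && stats$gap_columns == 0L)),
            class = "age_estimate")
}

#' Date one LTR pair from sequences
#'
#' Convenience wrapper: global alignment, divergence statistics, and age.
#'
#' @param ltr5,ltr3 the paired LTR sequences.
#' @inheritParams estimate_age
#' @return an `age_estimate` with the `divergence_stats` attached as
#'   attribute `stats`.
#' @export
date_ltr_pair <- function(ltr5, ltr3, rate = MOUSE_SUBSTITUTION_RATE,
                          formula_variant = c("half", "full"),
                          distance = c("p", "tn93")) {
  st <- divergence(global_align(ltr5, ltr3))
  est <- estimate_age(st, rate, formula_variant, distance)
  attr(est, "stats") <- st
  est
}
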