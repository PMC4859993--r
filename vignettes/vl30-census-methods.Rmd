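---
title: "Methods: an LTR-retroelement census on synthetic and real genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an LTR-retroelement census on synthetic and real genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ltrscape` implements a census of LTR retrotransposon loci of the VL30
type: discovery, structural classification, replication-signal scanning,
LTR-pair dating, a distance phylogeny, and distribution statistics. This
vignette is the package's own account of the underlying models, the
parameters that matter, the numerical choices, and what a green test does
and does not establish. Coordinates are 0-based half-open everywhere
internally; 1-based conventions appear only at the BED/GFF boundaries, as
those formats require.

## The element model

A full-length element is laid out 5′→3′ as: 5′LTR — PBS — internal
sequence — PPT — 3′LTR, flanked on both sides by a short duplication of
the integration site (TSD). The biological anchors:

* **LTRs** are identical at integration and diverge afterwards by
  independent mutation; observed lengths span 436–681 bp.
* **PBS** is complementary to the 3′ terminus of a host tRNA (Gly, Pro,
  Gln, Met or Thr for this family) and sits immediately downstream of the
  5′LTR; matches of 15–20 bp are biologically meaningful.
* **PPT** is a purine-rich 15-mer (`AGAAGAAGTGGGGAA`) immediately upstream
  of the 3′LTR; naturally occurring variants carry one or two A/T
  substitutions, so the caller accepts at most 2 mismatches and only if
  the mismatching base is A or T.
* **PSF motifs** are two specific RNA motifs (a 22-mer and a 30-mer)
  through which the element RNA binds the splicing factor PSF; an element
  carries 0, 1 or 2 of them.
* **TSD** is a duplication (here 4 bp by default) of host sequence created
  on both sides at integration.

Classification follows the intactness rule: *full-length* requires paired
near-identical LTRs **and** a PBS **and** a PPT; *solo* is a bare LTR (the
product of inter-LTR recombination); everything else with internal
sequence is *truncated*.

### Design choice: solo vs truncated without internal evidence

The classification operation receives only the locus sequence and the
three signal calls. Distinguishing a bare LTR from a short truncated
fragment strictly requires evidence of internal (non-LTR) sequence, which
the discovery stage has but the classifier signature does not. We expose
an optional `internal_hit` argument for callers that have such evidence;
the default heuristic calls *solo* when no LTR pair, PBS or PPT is present
and the locus is ≤ 1000 bp — comfortably above the observed LTR range
(436–681 bp) and far below real truncated elements, which retain kilobases
of internal sequence. On planted data this heuristic is exact.

## The synthetic world

The simulator's defaults are the observed conditions of the real census,
and they are deliberately not tunable by the tests:

* background GC 0.42 (the genomic average at integration sites);
* LTR length uniform in 436–681 bp; internal length 3–5 kb (full-length
  elements end up 4–6 kb, matching the family's size range);
* class proportions 86:49:237 (full-length : truncated : solo);
* PBS tRNA class proportions 57:17:10:1:1 (Gly:Pro:Gln:Met:Thr);
* PPT substitution counts 68:12:6 for 0:1:2 (the observed
  exact-vs-substituted split); PSF motif counts 3:5:78 for 0:1:2;
* TSD generated by duplicating the insertion-site 4-mer, matching
  retroviral integration mechanics;
* LTR divergence: each 3′LTR site substituted independently with
  probability *d* (uniform over the three alternative bases). No
  substitution spectrum is imposed because none is stated for the family;
  the same uniformity applies to PPT mutation, restricted to A/T
  replacements.

What the generator does **not** emulate: nested or fragmented insertions,
inter-element recombination, indel mutation of LTR pairs, CpG
hypermutability, and real internal coding-derived sequence (the internal
region is random background plus the planted motifs, since no internal
consensus composition is published). A green planted-census test therefore
establishes that the *operations* are correct on the stated element
anatomy — not that discovery parameters are adequate for a repeat-rich
mammalian assembly, where nested elements and old diverged copies make
recall a library-quality question.

The tRNA 3′-end reference shipped in `inst/extdata/` is a synthetic
stand-in (flagged in the filename): the family's tRNA classes are named in
the literature but the 18-mer termini are not printed, so the fixture
provides five distinct CCA-terminated 18-mers sufficient for planting and
recovering PBS assignments. Users analysing real data should supply real
tRNA 3′ termini via `trna_3prime_library(path)`.

## Discovery: k-mer seeding with diagonal chaining

Discovery replaces library-based repeat masking with a transparent
seed-and-chain search: all k-mers (default k = 12) of the query library
are indexed with their positions on both strands; genome hits are chained
when they come from the same library sequence, the same strand, a
consistent alignment diagonal (±25 bp by default) and genomic gaps ≤ 500
bp. Two numerical details matter:

* **Non-overlapping seed count.** A single chance shared substring of
  ~14–15 bp produces several *overlapping* 12-mer seeds on one diagonal;
  chains therefore qualify only if they contain `min_chain_hits` seeds
  spaced ≥ k apart, which suppresses background chains (a spurious chain
  would need a ≥ 36 bp chance match — vanishingly rare).
* **Diagonal consistency.** Without it, the background hit rate of a
  multi-kilobase library is high enough that independent chance hits chain
  into long pseudo-loci.

At k = 12 a copy diverged 8 % from the library still matches an exact
12-mer every ~30 bp in expectation, so planted recall is 1.0 at the
divergences the tests exercise (≤ 0.08).

## Dating: divergence and the molecular clock

Paired LTRs are aligned globally (match +1, mismatch −1, gap −2;
traceback tie-break diagonal > up > left, so results are reproducible to
the byte). Gap columns are excluded from substitution accounting. Dating
uses the raw substitution proportion by default — "number of nucleotide
substitutions" is the quantity the clock argument is about — while the
TN93 distance (distinct A↔G and C↔T transition rates, empirical base
frequencies) serves the phylogeny, where correction for multiple hits
matters more. TN93 saturation (non-positive logarithm argument) is
reported as `NaN` with a flag, and `estimate_age()` refuses it with advice
to fall back to the p-distance.

**Which clock formula?** At integration the LTRs are identical; afterwards
each accumulates substitutions independently, so observed divergence *d*
corresponds to `T = d / (2μ)`. Published element-dating analyses do not
always state whether they divided by μ or 2μ, so both variants are
implemented; `half` is the default on the independent-accumulation
argument, every `age_estimate` records its variant, and the run log echoes
it. "Identical LTRs" (the retrotransposition-competence marker) requires
zero substitutions *and* zero gaps over the full alignment.

μ defaults to 4.6 × 10⁻⁹ substitutions/site/year, the mean mouse genomic
rate. No CpG-aware or deamination-corrected clock is provided; such biases
inflate apparent age and are a known limitation.

## Phylogeny: a declared method substitution

The reference analysis for this family used maximum-likelihood tree search
over a ClustalW alignment. `ltrscape` deliberately substitutes: pairwise
TN93 distances → center-star multiple alignment ("once a gap, always a
gap", center chosen to maximise total pairwise score) → Saitou–Nei
neighbor joining (ties in the Q criterion resolved toward the first pair
in label order; negative branch lengths clamped to zero with the deficit
recorded) → column bootstrap, with supports as the percentage of
replicates containing each bipartition of the point tree. The grouping
claims this supports are clade-level claims, which NJ tests faithfully —
NJ is exact on additive distances, and the test suite verifies exact
recovery of random tree metrics up to 12 taxa and agreement with an
independent NJ implementation. It is documented as a substitution, not a
reproduction: borderline leaves may shuffle between ML and NJ, so only
monophyly and supports are asserted, never leaf-by-leaf composition.
Because per-node labels are ambiguous for the clade spanning the stored
root, `clade_support()` evaluates a named clade's bipartition directly
against the stored replicates.

## Distribution statistics

* **Chromosomal randomness**: expected counts are proportional to
  chromosome length; the χ² statistic uses df = k − 1 (21 chromosomes ⇒
  df = 20 for the mouse karyotype including X and Y). Calibration is
  tested: under multinomial placement the test rejects at α = 0.05 in
  5 % ± 1.5 % of 1000 seeded trials.
* **TSS binning**: distances are measured from the element midpoint to the
  nearest TSS within 1 Mb, signed in gene orientation (upstream negative),
  binned 0–5/5–50/50–500/500–1000 kb; an element containing a TSS is
  `within` at distance 0. Binning is exhaustive and exclusive.
* **Gene context** precedence: TSS-within-element → intronic (fully inside
  an intron) → end-of-gene (overlapping the strand-aware final exon or 3′
  boundary) → adjacent-to-TSS (≤ 20 kb upstream, the distance at which
  *cis*-regulatory effects on neighbours are documented) → intergenic.
* **Clusters**: maximal same-chromosome sets with span ≤ window and size ≥
  `min_count` (the "8 truncated elements in 1.5 Mb" pattern), verified
  against brute-force enumeration.
* **GREAT-style association**: per-gene regulatory domains are basal −5
  kb/+1 kb around the TSS (strand-aware), extended toward the neighbours'
  basal domains up to 1 Mb — the published defaults, since "default
  settings" is all the reference analysis states. A region hits a domain
  when its **midpoint** falls inside (the binomial null is a uniform
  random point; genome fraction covered = null hit probability). The
  binomial tail is over regions; the hypergeometric test draws
  genes-with-hits from the gene universe. Raw p-values only; no ontology
  propagation or multiple-testing correction.

## Determinism and tolerances

Every stochastic stage derives a named 31-bit substream from one master
seed, and library code saves/restores the caller's RNG state. Statistical
tests use 99 % binomial/Poisson intervals around planted parameters rather
than ad-hoc tolerances; exact-arithmetic claims (profile information
content, alignment scores, binomial tails vs explicit enumeration) are
asserted to 1e-12 or to machine precision. TN93 is cross-checked against
an independent implementation (`ape::dist.dna`) and against a simulation
oracle that evolves 10⁴ sites through the eigendecomposed rate matrix.

## Known limitations

* Discovery has no indel-aware extension; intervals end at the outermost
  exact seeds (diagonal tolerance bridges small indels only).
* In-silico PCR forbids indels and demands an exact 3′-terminal base —
  deliberate, mimicking primer-extension chemistry, but stricter than
  thermodynamic models.
* The ORF audit uses the standard code and ATG initiation only.
* Headline counts of the real mouse census (372 loci; PBS/PSF tallies)
  derive from assembly-scale screening plus manual curation and are not
  recomputable here without the assembly; the package asserts the
  recomputable arithmetic and reproduces the per-element behaviours on
  planted data instead.
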