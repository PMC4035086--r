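---
title: "Methods: models, parameters and design choices in orthodiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in orthodiverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

orthodiverge compares two closely related transcript sets — the motivating
case is the gut transcriptomes of two invasive cryptic species of the
*Bemisia tabaci* whitefly complex — through five stages: ortholog pairing,
region-wise divergence, Ka/Ks selection scanning, pathway enrichment, and
count-based differential expression. A sixth component, the synthetic
cohort generator, exists so that each stage can be validated against known
ground truth. This vignette records the models, the tunable parameters and
the design decisions behind each stage.

## The synthetic cohort: what it emulates

The generator draws an ancestral transcriptome (each gene a
5'UTR + CDS + 3'UTR; the CDS starts with ATG, ends with a stop codon and
contains no internal in-frame stop), keeps it as species A, and derives
species B by a per-site proposal/acceptance process:

* UTR sites receive a Poisson(`t_utr`) number of substitutions each,
  with transition/transversion bias κ.
* CDS sites receive Poisson(`t_cds`) *proposed* substitutions each
  (the terminal stop codon is frozen). A proposal is accepted with
  probability 1 if synonymous, ω if nonsynonymous, and never if it would
  create a stop codon — mirroring the filter that removes coding regions
  with unexpected stop codons.

This is a proposal-plus-selection scheme rather than a full codon rate
matrix: it is simpler, it makes ω the exact nonsynonymous/synonymous
acceptance ratio that the Ka/Ks estimators should recover, and it keeps
the truth bookkeeping exact. No indels are simulated, because the
divergence arithmetic downstream is defined purely on substitutions per
compared base pair; indel handling would add a dimension that nothing in
the analysis measures. The ground-truth table records end-state differing
sites per region and per ancestral degeneracy class (so realized counts
can never exceed region lengths), plus raw event tallies.

**Default parameters.** The defaults are fixed to emulate a pair of
recently diverged cryptic species as characterised in the whitefly gut
comparison, and are not tuned afterwards:

| parameter | default | rationale |
|---|---|---|
| `t_cds` | 0.0248 /site | neutral (4d-site) CDS divergence near 2.5% |
| `omega` | 0.07 | suppresses nd-site divergence ~14-fold below 4d |
| `t_utr` | 0.0166 /site | UTR divergence near 1.65% (between the two UTRs' reported levels) |
| `kappa` | 2 | typical transition bias for animal nuclear genes |
| `gc` | 0.42 | between the reported CDS (~43%) and UTR (~33–39%) GC |
| CDS length | mean ~675 bp | matches the reported average orthologous CDS (~678 bp) |
| library sizes | 4×10⁵ reads / 500 genes | ~800 reads per transcript, the depth-per-transcript of ~27M reads over ~33k transcripts |
| DE fractions | 7.8% up, 1.6% down | the reported 304 up / 64 down among 3,910 ortholog pairs |
| planted &#124;log2 fold&#124; | 1 + Exp(rate 2), capped at 6.6 | reproduces the reported shape: most DE pairs between 1 and 2, ~13.5% above 2, extremes near ±5–6.6 |
| enrichment planting | odds ratio 3 for one pathway | a clearly detectable but not degenerate signal |

What the generator does **not** emulate: assembly artifacts (chimeras,
fragmented transcripts, redundant isoforms), sequencing error, read-level
data, indels and alignment ambiguity, paralogous gene families, and
correlated expression between genes. Passing tests therefore demonstrate
the *inference machinery* — not robustness to assembly noise, which on
real data is handled upstream of this package.

## Ortholog pairing

A database search at desk scale is replaced by exact alignment:
candidates are pre-screened by cosine similarity of 6-mer count profiles
(top 5 per gene, both directions; `candidates = Inf` forces an exhaustive
all-vs-all search), then scored with affine-gap global Needleman–Wunsch
(match 1, mismatch −1; a gap of length L costs 2 + L). A pair is retained
when each member is the other's unique best score, identity is at least
0.9, and the aligned overlap exceeds 200 bp. The identity/score
thresholds stand in for the E-value cut-off of a database search, which
has no meaning without a database size.

Tie-breaking is deterministic: equal scores are broken by higher
identity; a tie surviving both keys marks the gene ambiguous and
disqualifies it — an ambiguous best hit is not an ortholog call.

Retained pairs pass a same-reference-protein filter (both genes carry
exactly one protein label and the labels agree; missing or multi-valued
labels are ambiguous and drop the pair), then a region partition: species
A's annotated CDS interval is projected through the alignment, columns
falling in gaps inherit the label of the nearest 5'-ward column, and the
pair is rejected when its gap-free aligned CDS is shorter than 75 bp or
contains an internal in-frame stop codon in either species. The internal
stop check deliberately ignores the terminal codon. The CDS frame comes
from the annotation table; for unannotated inputs the synthetic
annotation dialect must be produced first (the generator's truth plays
the role that a protein-database frame assignment plays on real data).

Coordinates are 1-based and inclusive everywhere, the native convention
of R and Bioconductor ranges; every TSV the pipeline writes states this
in a header comment.

Orthogroups between a tissue set and a whole-body set use the same
reciprocal-best machinery; tissue genes with no reciprocal partner are
reported as tissue-specific, with their proportion of the tissue set.
This replaces a Markov-clustering orthogroup construction: the analysis
uses group membership only as a presence/absence criterion, which
reciprocal pairing reproduces.

## Divergence and site classes

Divergence of an aligned region is substitutions divided by compared
base pairs; columns with a gap or N in either sequence are never
compared. GC is computed over both sequences' compared bases.

Codon-position degeneracy is classified from the standard genetic code:
*nondegenerate* if every single-nucleotide change (changes producing stop
codons excluded from the enumeration) alters the amino acid, *fourfold*
if none does, two-/threefold between. Two conventions needed a decision
the source analysis does not state:

* **Stop-producing changes are excluded** from the enumeration (the
  NG86-style convention), so e.g. the third position of TAT is classified
  by its one non-stop variant.
* **Discordant positions are excluded from both classes**: a position
  counts for nd (or 4d) divergence only when *both* species' codons give
  it that class. The alternative — classifying by one reference species —
  would make the table depend on which species is listed first.

The five-row summary (5'UTR, CDS, nd, 4d, 3'UTR) reports both the
per-locus mean divergence with its standard error (sd/√loci; a single
locus reports SE 0 with a flag) and the pooled substitutions-over-bases
ratio, because a per-locus mean and a pooled ratio answer subtly
different questions and the source table does not say which it prints.
Pooled divergence equals the compared-bp-weighted mean of per-pair
divergences; this conservation identity is asserted in the tests.

Note one measurable bias of the concordance rule: under strong purifying
selection a nonsynonymous substitution often changes the codon's class
map, removing exactly the substituted site from the nd tally. Measured
nd divergence therefore sits slightly below the generator's truth, and
the measured 4d/nd fold slightly above it; the recovery test bounds this
at ±30%.

## Ka/Ks estimation

**NG86.** Synonymous sites per codon are the per-position fractions of
non-stop single-nucleotide changes that are synonymous (weight
redistributed when a stop variant is excluded), averaged over both
sequences. Multi-step codon differences are averaged over all minimal
mutational pathways; pathways through stop codons are dropped and their
weight redistributed over the remainder (if every pathway is blocked,
all are used). Jukes–Cantor correction d = −(3/4)·ln(1 − 4p/3) is applied
to both proportions; p ≥ 3/4 flags the result `saturated`. The whole
estimator is cross-checked in the tests against a literal
pathway-enumeration oracle on short pairs.

**YN00-style.** Codon frequencies are estimated from the pair by F3x4
(position-specific nucleotide frequencies). κ is estimated from K80
distances at concordant fourfold (synonymous) and nondegenerate
(nonsynonymous) sites — for each class the transitional and
transversional distance components A and B give κ = 2A/B, and the two
estimates are averaged weighted by site counts (classes with fewer than
10 sites, or saturated distances, are dropped; if nothing informs κ it
falls back to 1). Site counting weights each possible change by
π(target codon) · κ^(transition); pathway weights additionally carry
ω^(nonsynonymous steps) and are averaged over both directions of the
pair, which enforces exact symmetry. Multiple-hit correction is applied
K80-style *within* the synonymous and nonsynonymous classes separately.
ω enters the pathway weights, so it is solved by fixed-point iteration
from ω = 1 with tolerance 1e-8 and at most 100 iterations (conservative;
convergence typically takes a handful of steps). Non-convergence returns
the last iterate flagged `not_converged`; alignments under 100 codons are
flagged `short_alignment`.

Exact numerical agreement with any external Ka/Ks tool is not claimed;
the validation standard is parameter recovery on simulations (the
acceptance suite requires the mean estimated ratio over 50 seeded
3,000-codon pairs evolved at ω = 0.2, κ = 2 to fall in [0.16, 0.24]) and
agreement with NG86 when κ = 1 and codon usage is flat, where the two
weightings coincide.

A pair with Ks = 0 (or a saturated correction) has an undefined ratio:
it is labelled `undefined`, never "infinite", and excluded from summary
denominators — matching the restriction of the published selection scan
to pairs that generated both rates. Ka = 0 with Ks > 0 is a defined
ratio of zero.

## Enrichment

For background and subset annotated-gene totals N and n, and pathway
membership counts M and m, the enrichment p-value is the upper tail
P(X ≥ m) of Hypergeometric(N, M, n), evaluated through R's `phyper`
(computed internally in log space). Genes without any pathway annotation
do not count towards N or n. The enriched flag uses the raw threshold
p < 5.0e-3 with no multiple-testing correction — the convention of the
emulated analysis — but a BH column is emitted for reference. An
exclusion list (in the original analysis, human-disease pathways) is
applied before testing. Only enrichment is tested, not depletion.

## Differential expression

RPKM is count · 10⁹ / (length · total mapped reads); the log2 ratio is
taken A over B with no pseudocount by default, so a zero RPKM on one side
yields a signed infinity that is flagged and excluded from ranged
summaries and the fold-change histogram.

The Audic–Claverie test conditions on the count x in library 1:
Y | x is negative binomial with size x + 1 and success probability
N1/(N1+N2). The two-sided p-value doubles the smaller of P(Y ≤ y) and
its complement P(Y > y), capped at 1. This tail-partition convention was
chosen over doubling two point-inclusive tails because it is *exactly*
invariant under exchanging the two libraries (the identity
P(Y > y | x; N1, N2) = P(X ≤ x | y; N2, N1) pairs the two orientations'
tails), a property the analysis should not silently lack. At low counts
the test is mildly conservative — discreteness plus tail doubling — which
the calibration tests tolerate explicitly.

BH adjustment is R's `p.adjust` step-up; calls require |log2| > 1 *and*
FDR < 1.0e-3, with direction taken from the sign ("log2 > 1" in the
emulated analysis is read as a threshold on the absolute value, since
both up- and down-regulated genes are reported).

One honest artefact worth knowing about: with a single library per
species, normalising by total mapped reads makes every gene's ratio
depend on the cohort's composition. Asymmetrically planted fold changes
shift null genes' log2 ratios by roughly −0.1 under the defaults, which
can graze the call threshold for a handful of genes. This is a property
of RPKM-on-totals itself, not of the simulator; replicate-aware
normalisation is out of scope because the emulated design has one
library per species.

## Pipeline, determinism and problem sizes

`run_stage()` chains simulate → pair → diverge → kaks → enrich → de.
All randomness flows from the named seeds in the configuration (the
master seed derives fixed offsets per stage), so a rerun with the same
configuration is byte-identical; the run manifest records package
version, seeds and artifact checksums, deliberately omitting timestamps.
Exit codes of the shell wrapper are 0/1/2 for ok / input error / config
error, and a stage missing its upstream artifact names the absent file.

Default problem sizes were chosen so the whole chain stays comfortable
on a single CPU: the demo cohort is 500 genes (the full chain in a few
minutes), parameter-recovery simulations use 50 replicates of 3,000
codons, and calibration suites use 2,000-gene count tables. The test
suite's smaller cohorts (40–120 genes) exercise identical code paths.

## Known limitations

* The aligner is exact but quadratic; the k-mer pre-screen makes pairing
  linear-ish in practice but assumes orthologs share bulk k-mer content,
  which very high divergence (or heavy assembly fragmentation) would
  break.
* Degeneracy-class divergence and both Ka/Ks estimators require the
  codon-aligned, gap-free CDS; codons touching gaps or Ns are dropped
  whole, so heavily gapped CDS alignments lose sites.
* YN00 here is a faithful re-derivation of the counting approach, not a
  line-for-line port of any particular tool; third-party tools differ in
  their own corrections and will not match to the last digit.
* The enrichment test treats genes as exchangeable units; transcript
  redundancy (isoforms counted as genes) would inflate counts on real
  assemblies.
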