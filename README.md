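# orthodiverge

Comparative divergence and expression analysis for paired transcriptomes of
closely related species, motivated by gut-transcriptome comparisons between
cryptic species of the *Bemisia tabaci* whitefly complex (MEAM1 vs MED).
When two *de novo* assembled transcript sets are this closely related
(~99% nucleotide identity), the interesting biology sits in a few
percent of sites: which codon positions diverge, which genes escape
purifying selection, which pathways a tissue over-uses, and which orthologs
shift expression between species.

The package implements the full analysis chain as tested, reusable R
functions:

1. **Ortholog pairing** — reciprocal best hits under exact affine-gap
   global alignment (candidates pre-screened by shared k-mer content), a
   same-reference-protein filter against paralogs, and partition of each
   pair into aligned 5'UTR / CDS / 3'UTR regions with the cascade's
   published cut-offs (overlap > 200 bp, CDS ≥ 75 bp, no internal stop).
2. **Divergence** — per-region substitution fractions and divergence
   restricted to nondegenerate (nd) sites, where every single-nucleotide
   change alters the amino acid, and fourfold-degenerate (4d) sites, where
   none does.
3. **Selection** — Ka/Ks per ortholog pair by two counting methods:
   Nei–Gojobori (NG86; equal-weight pathways, Jukes–Cantor correction) and
   a Yang–Nielsen style estimator (YN00; F3x4 codon frequencies, κ from
   K80 distances at 4d vs nd sites, κ/frequency-weighted counting).
   Ka/Ks < 1 indicates purifying, > 1 positive selection.
4. **Enrichment** — upper-tail hypergeometric test of a tissue gene set
   against a whole-body background: for pathway membership counts
   (N, M, n, m), p = P(X ≥ m), X ~ Hypergeom(N, M, n); enriched at
   p < 5.0e-3.
5. **Differential expression** — RPKM normalisation
   (count · 10⁹ / (length · library size)), log2 ratio, the
   Audic–Claverie exact test on the two counts, Benjamini–Hochberg FDR,
   and calls at |log2| > 1, FDR < 1.0e-3.
6. **Synthetic data** — a codon-model simulator (per-site proposals with
   transition bias κ, accepted with probability 1 if synonymous, ω if
   nonsynonymous, never when creating a stop codon) that generates
   two-species transcriptomes, annotations, pathway catalogs and read
   counts with known ground truth, so every stage above is testable
   without any external download.

## Worked example

```r
library(orthodiverge)

cfg <- pipeline_config(outdir = "demo", n_genes = 60, seed = 5)
run_stage("all", cfg)

div <- read.delim("demo/divergence.tsv", comment.char = "#")
div[, c("region", "loci", "mean_divergence", "se", "compared_kb")]
#>     region loci mean_divergence           se compared_kb
#> 1     utr5   60     0.015570646 0.0018648847       5.253
#> 2      cds   60     0.007160946 0.0004271727      42.381
#> 3       nd   60     0.001309272 0.0002221776      26.709
#> 4 fourfold   60     0.022772519 0.0018407093       6.226
#> 5     utr3   60     0.019469192 0.0014804468      11.180
```

Divergence is lowest at nd sites (0.13%), ~17-fold higher at 4d sites
(2.3%), with UTRs in between — the signature of strong purifying selection
on coding positions while silent sites drift.

```r
sel <- classify_selection(read.delim("demo/kaks.tsv", comment.char = "#"))
sel$summary
#>   n_defined n_purifying n_positive pct_purifying     mean_ka    mean_ks mean_ratio
#> 1        60          60          0           100 0.001436184 0.02740295  0.0647775
```

Every pair in this small cohort has Ka/Ks < 1, as expected for orthologs
simulated under ω = 0.07.

The same stages can be driven from a shell through the thin wrapper in
`inst/scripts/pipeline.R`:

```sh
Rscript inst/scripts/pipeline.R all --outdir demo --seed 5
```

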