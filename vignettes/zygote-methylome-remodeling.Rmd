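---
title: "Allele-specific methylome analysis of hybrid zygotes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific methylome analysis of hybrid zygotes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zygoteMeth)
library(data.table)
```

## The scientific problem

When a plant zygote forms, the two parental genomes arrive with different
DNA methylation landscapes: the egg and the sperm methylomes differ at
many loci in all three plant cytosine contexts (CG, CHG, CHH). In a
hybrid zygote, each parental allele can be followed separately because
the parental genomes differ at SNPs. The question this package is built
around is *what happens to the paternal allele's methylation after
fertilization*: does it persist at sperm levels, revert to vegetative
levels, or get remodeled toward the maternal (egg) pattern? And is
whatever state the zygote establishes maintained through early
embryogenesis, or are parental allele-specific patterns reestablished
later?

`zygoteMeth` implements the complete analysis chain needed to answer
this from whole-genome bisulfite data of gametes and hybrid zygotes:
per-cytosine methylation calling, SNP-based partitioning of reads into
parental alleles, windowed DMR detection between egg and sperm, tracking
of those DMRs into the hybrid stages, an explicit estimator of the
degree of paternal remodeling, and — on the expression side —
classification of imprinted genes from reciprocal-cross allelic RNA
counts. A seeded synthetic-data generator produces all inputs with known
truth, so every stage is testable end to end.

## Methylation calling

A cytosine's context is a pure function of the reference trinucleotide
on its own strand: `CG` when the next base is G, `CHG` for C-H-G, `CHH`
for C-H-H (H is A, C or T); minus-strand cytosines are read on the
reverse complement. Cytosines within two bases of a sequence end, or
whose trinucleotide contains a non-ACGT base (notably an N-masked SNP),
carry no context and are excluded from all analyses.

Reads are represented as simplified aligned fragments: an interval, a
strand, a converted/unconverted call at every covered cytosine of the
read's strand, and the observed base at every covered SNP. Alignment
itself is out of scope — the package starts where a bisulfite aligner
and methylation extractor leave off — which keeps the in-scope
computations (allele splitting, DMR calling, remodeling estimation)
exercisable without any external aligner. `extract_cytosine_counts()`
tallies unconverted observations as `n_meth` and converted ones as
`n_unmeth` per site; CG sites are kept per strand (a merge across the
symmetric pair is deliberately not the default, so strand-specific
artifacts remain visible). Individual cytosines need at least 3 reads to
enter level calculations. The coverage wording in the field is
inconsistent between "more than three" and "at least three"; we take the
inclusive reading (depth ≥ 3), and the flag `min_depth` exposes the
choice. Replicates are pooled by summing counts; a `mean_level` mode
averages per-replicate levels instead, which is the quantity usually
shown in figure-style summaries.

## Allele splitting

SNP positions are N-masked in the reference (`build_nmasked_reference()`),
mirroring how hybrid data are aligned without reference bias. Each
read's observed bases at overlapped SNPs then vote:

* a SNP is *unusable* for a plus-strand read when its allele pair is
  C/T, and for a minus-strand read when it is G/A — bisulfite conversion
  makes the two alleles indistinguishable on that strand;
* all usable bases matching one parent assigns the read to that parent;
* no usable SNP leaves the read `unassigned`;
* support for both parents, or a base matching neither, makes the read
  `conflicting`, and conflicting reads are discarded rather than
  majority-voted — the conservative behavior of standard SNP-sorting
  tools. A flag could relax this, but discarding is the default because
  a single sequencing or conversion artifact should not flip a read's
  parental assignment.

Allele-specific methylation uses only maternal- or paternal-assigned
reads, and a cytosine needs at least 3 allele-specific reads (pooled
over replicates) per allele to be reported. The simulator reproduces the
conversion mechanics at SNP bases (a C allele on the converted strand
reads as T when unmethylated), which is exactly why the strand-specific
skip rule exists; with it in place, assignment purity on error-free
simulated reads is 100%.

## DMR calling

The genome is tiled with fixed, non-overlapping 50-bp bins (0-based
grid: 0, 50, 100, ...). Per context, a bin is testable when it contains
at least 5 context cytosines and every one of them has at least 3-fold
coverage, in both samples. The two-sample comparison is a Fisher exact
test on the 2×2 table of pooled methylated/unmethylated counts in the
bin — pooling over replicates and over the bin's cytosines is the only
construction that yields a single 2×2 table per bin — followed by
Benjamini–Hochberg adjustment across all tested bins of the context. A
DMR additionally requires a methylation difference above the
context-specific cutoff: 0.5 (CG), 0.3 (CHG), 0.1 (CHH). The FDR
threshold (0.05) is applied to the adjusted value; a `use_raw_p` flag
reproduces the laxer raw-p variant that sometimes appears in summary
descriptions, but the adjusted criterion is authoritative here. Bins
are never merged by default (counts are reported per 50-bp bin);
`merge_adjacent_dmrs()` exists for display purposes. The trailing
sub-50-bp chromosome remainder is kept as a short window.

Two deliberately distinct bin-level summaries are used. For DMR testing
the bin level is the pooled count ratio (consistent with the Fisher
table). For density-plot differences (`density_difference()`) the bin
level is the unweighted mean of per-cytosine levels — the "average
cytosine methylation level" — and a bin is retained only with at least
20 informative sequenced cytosines in both samples and a level of at
least 0.5/0.3/0.1 (CG/CHG/CHH) in at least one sample.
"Informative sequenced cytosines" is read as the summed per-cytosine
sequencing depth in the bin; the alternative grammatical reading (depth
multiplied by cytosine count) is exposed as
`informative = "depth_by_sites"`. Whether the 5-cytosine/3× bin filter
applies to both samples or either is equally unstated in common usage;
both-samples is implemented because an untestable bin in either sample
makes the 2×2 table meaningless.

DMR feature annotation is by any-overlap (≥ 1 bp) with precedence
TE-gene (overlaps both a TE and a gene) > TE > gene body > intergenic.

## Remodeling coefficient

Egg-versus-sperm DMRs (hyper = egg > sperm) are tracked into the hybrid
stages. For each DMR, the maternal- and paternal-allele levels are
pooled over the DMR's filtered allelic cytosines; a DMR needs at least 3
testable cytosines per allele, otherwise it is `untestable`. The degree
of paternal remodeling is formalized as the coefficient $\rho$ in

$$ m_{pat} = \rho \, m_{egg} + (1 - \rho)\, m_{sperm}, $$

so $\rho = 1$ is full remodeling to the maternal level and $\rho = 0$ is
none. It is estimated by depth-weighted least squares over testable DMRs
with an egg-sperm gap of at least 0.2:

$$ \hat\rho = \frac{\sum_i w_i (m_{pat,i} - m_{sperm,i})(m_{egg,i} - m_{sperm,i})}
                   {\sum_i w_i (m_{egg,i} - m_{sperm,i})^2}, $$

with $w_i$ the paternal allelic depth (the paternal allele is the
quantity being measured; weighting by its depth downweights noisy DMRs),
clipped to $[0, 1]$. The estimator is symmetric in DMR direction —
hyper and hypo subsets estimate the same $\rho$ — and requires at least
20 informative DMRs; fewer raises an explicit error rather than
returning an unstable number. Uncertainty comes from a 1000-resample
percentile bootstrap over DMRs with a fixed seed; the interval is
widened, if necessary, to contain the point estimate (clipping at the
boundary can otherwise exclude it in degenerate cases).

Because $m_{egg}$ and $m_{sperm}$ enter as regressors measured with
binomial noise, $\hat\rho$ is mildly attenuated at low gamete depth;
with the ≥ 0.2 gap filter and pooled bin counts the attenuation is
negligible at the depths used here (simulation recovery is within
±0.05 at allelic depth 30 over 500 DMRs, verified in the test suite).

Per-DMR classification uses proximity thresholds: `maternal_match` when
the paternal allele is within 0.1 of the egg level and at least 0.2 from
the sperm level, `paternal_match` mirrored, otherwise `intermediate`.
The thresholds are display conveniences (boxplot-style proximity made
explicit) and are configurable; $\hat\rho$ does not depend on them.

CHH behaves differently from CG/CHG in the zygote: rather than matching
the maternal allele, zygotic CHH methylation parallels the *lower*
parental level. The package therefore does not estimate $\rho$ for CHH
by default; it reports the lower-parent statistic
$\mathrm{mean}(m_{sample} - \min(m_{egg}, m_{sperm}))$ over CHH DMRs,
which is near 0 when the lower-parent rule holds.
`compare_stages()` contrasts stages: on data where the zygote is fully
remodeled ($\rho = 1$) and the globular embryo has reverted to
gamete-of-origin levels, it recovers $\hat\rho \ge 0.9$ and
$\hat\rho \le 0.1$ respectively — the remodeling-then-reestablishment
pattern.

## Imprinting classification

From reciprocal-cross allelic RNA counts, each gene is tested per cross
with an exact two-sided binomial test of the maternal count against 0.5,
BH-adjusted across testable genes (total count ≥ 10 in both crosses).
The published decision thresholds are kept verbatim — |log2 allelic
ratio| > 1 and adjusted p < 0.01 — but the original count-model test is
replaced by the exact binomial: with two alleles of one gene in one
sample there is no dispersion to model, and the exact test is
self-contained and oracle-checkable. The log2 ratio adds a pseudocount
of 1 to both alleles for display stability; the test never sees the
pseudocount. A gene paternal-biased in both crosses is a PEG,
maternal-biased in both a MEG; a gene whose bias follows the *genotype*
(favoring the same genomic parent as mother in one cross and as father
in the other) is `sequence_specific` — the reciprocal design exists
precisely to separate these. The null proportion is fixed at 0.5 even
though zygote transcriptomes are strongly maternal-biased; an optional
`prob` argument allows testing against an estimated global maternal
fraction, off by default because the published cutoffs imply 0.5, and
because planted imprinted genes at ≥ 95% allelic purity remain
recoverable even under a 90% maternal background (verified in the
suite).

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
at desk scale, with fixed seeds (identical configurations give
byte-identical outputs):

* **Haplotypes and SNPs.** A random maternal genome; SNPs placed
  per-base Bernoulli at rate 0.0035 (a few variants per kilobase, the
  density typical of an indica intervarietal rice cross), two thirds
  of them transitions — the C/T and G/A pairs that bisulfite conversion
  renders strand-specifically uninformative. Gene blocks (2 kb,
  covering ~30% of the genome) are non-overlapping; TE insertions
  (400 bp, ~35%) are placed uniformly and may fall inside genes,
  producing all four feature classes.
* **Methylomes.** Per-cytosine true levels are Beta-distributed around
  compartment/context baselines chosen to be rice-like (e.g. CG: 0.90
  TE / 0.55 gene / 0.40 intergenic; CHH low everywhere), *shared*
  between egg and sperm outside planted DMRs, so every non-planted
  window is a true null. Planted egg-sperm DMRs occupy distinct
  compartment-pure 50-bp grid windows with ≥ 5 context cytosines and a
  configurable effect (default 0.8, symmetric around 0.5, alternating
  hyper/hypo).
* **Remodeling rule.** Zygote: maternal allele keeps egg levels;
  paternal CG/CHG at `rho * m_egg + (1 - rho) * m_sperm` (default
  `rho = 1`, the full-maternal-match scenario); CHH at
  `min(m_egg, m_sperm)` on both alleles under the default
  `lower_parent` rule. Globular embryo: both alleles revert to
  gamete-of-origin levels (reestablishment).
* **Reads.** Poisson read counts at the configured depth (default 30×
  per replicate, two replicates — matching a two-biological-replicate
  design), uniform starts, random strand; per-cytosine calls Bernoulli
  at the true level with unmethylated cytosines escaping conversion at
  rate 0.005 (a typical lambda-control failure rate); sequencing
  base-call errors are off by default. Zygote and embryo reads draw
  their allele of origin fairly; the truth is recorded but hidden from
  the pipeline.
* **Expression.** Negative-binomial gene totals (mean 200, size 5)
  split binomially at the global maternal fraction; planted PEGs draw
  97% paternal reads in both crosses, MEGs the mirror, and
  genotype-biased genes favor one genotype regardless of role.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: alignment and mapping bias, PCR
duplicates, non-uniform coverage, context-dependent conversion
efficiency, partially methylated domains and chromatin-scale
autocorrelation of methylation, linked SNP haplotype blocks, and
allele-specific expression dispersion beyond binomial. Results on real
libraries depend on those factors; the suite validates the *computation*,
not the sequencing.

## Numerical choices and degenerate inputs

* Fisher p-values sum hypergeometric probabilities ≤ the observed one
  with the customary 1e-7 relative tolerance; an all-zero margin gives
  p = 1. The implementation is enumerated directly over the support
  (the window counts are small) and is validated to 1e-9 against an
  independent binomial-coefficient oracle for all tables with margins
  ≤ 30, and against `stats::fisher.test` on random larger tables.
* BH adjustment delegates to `stats::p.adjust`.
* Coordinates: 1-based inclusive for cytosines and SNPs (the
  caller/VCF convention), 0-based half-open for windows, BED intervals
  and DMRs.
* Zero-depth sites are omitted (an option keeps them as zero rows);
  empty read sets, empty SNP tables and empty DMR sets flow through and
  return typed empty tables.
* Bootstrap and all simulations are seeded; seeds derived from a user
  seed stay below 2^31.

## Problem sizes used in validation

The validation suite and the reproducibility script
(`scripts/acceptance.R`) use: a 1-Mb genome with 200 planted CG DMRs
(effect 0.8, depth 30, 2 replicates) for detection scoring; a matched
null of ~1000 windows over 20 seeded runs; five 100-kb simulations at
true rho of 0, 0.25, 0.5, 0.75 and 1 (500 planted CG DMRs, SNP rate
0.02, depth 100, giving ~30 allele-assigned reads per allele per site)
for recovery; one stage-contrast simulation (zygote at rho 1 versus
reverted globular embryo, with 150 CHH DMRs for the lower-parent
statistic); and imprinting scenarios of 500 genes with 20 PEGs and 50
MEGs, including a 90% maternal-fraction stress test and a 20-seed null.
These sizes give stable statistics (binomial standard errors well below
the tested tolerances) while each block runs in minutes.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- sim_config(genome_length = 50000L, snp_rate = 0.02, depth = 60,
                  n_planted_dmrs = c(CG = 20L, CHG = 0L, CHH = 0L),
                  rho = 0.5, seed = 7L)
sim <- simulate_cross(cfg, samples = c("egg", "sperm", "zygote"))
res <- run_hybrid_pipeline(sim, stages = "zygote", contexts = "CG",
                           rho_contexts = "CG", min_dmrs = 5)
res$rho
#>     stage context       rho     ci_lo    ci_hi     n
#> 1: zygote      CG 0.4932453 0.4747266 0.510837    17
```

The simulation planted half remodeling (`rho = 0.5`); the pipeline —
running blind through DMR calling, read assignment and allelic pooling —
estimates 0.49 with a CI covering the truth.

## Known limitations

* Single-end fragments only; paired reads are not modeled.
* One reference backbone (the maternal genome); paternal-only cytosines
  (where only the paternal allele carries a C) are invisible, exactly as
  they are on a real single-backbone N-masked alignment.
* No smoothing or HMM segmentation of DMRs, and no replicate dispersion
  model in the window test — the design follows the fixed-bin
  pooled-count construction it validates, not BSmooth/methylKit-style
  approaches.
* $\hat\rho$ summarizes a linear interpolation between gamete levels;
  loci that overshoot the egg level or move orthogonally are absorbed
  into the residual, visible in the per-DMR classes rather than in
  $\hat\rho$.
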