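---
title: "Allelic multi-omics of the maternal-to-zygotic transition: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allelic multi-omics of the maternal-to-zygotic transition: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mztallele)
```

## The scientific question and the study design

The maternal-to-zygotic transition (MZT) couples two processes: the embryo
begins transcribing its own genome (zygotic genome activation, ZGA — the
major wave at the 8-cell stage in human embryos) and clears the transcripts
the oocyte deposited (maternal RNA degradation, MRD). Whether both parental
genomes drive these processes equally cannot be read off ordinary embryos,
where the two genomes are mixed in every cell. Uniparental embryos separate
them: parthenogenetic (PG) embryos carry only maternal genomes,
androgenetic (AG) embryos only paternal ones. If ZGA fires at the 8-cell
stage in AG embryos but not until the morula in PG embryos, initiation is a
paternal-genome property; if MRD tracks ZGA, it should show the same delay.

`mztallele` implements the analysis layer of that comparison — expression,
DNA methylation and chromatin accessibility — as reusable, tested functions,
and pairs it with a synthetic data generator that encodes the delayed-PG
program as ground truth. Every statistical claim the package makes is
exercised against that truth in the test suite.

## Allele-specific expression

For a gene with $x_p$ paternal and $x_m$ maternal informative reads, the
biallelic null model says each read is paternal with probability $p_0=1/2$.
We use the exact two-sided binomial p-value under the minimum-likelihood
rule: all outcomes whose point mass does not exceed the observed one
contribute. At $p_0 = 1/2$ this equals doubling the smaller tail (capped at
1), by symmetry. A gene is called parentally biased when the raw p-value is
below 0.001, the Benjamini–Hochberg adjusted value below 0.05, and the
parental read fold change exceeds 2. The tested family is all genes with at
least `min_reads` (default 10) informative reads; the floor is configurable
because a per-gene depth requirement is a practical choice, not part of the
model.

Three numerical details:

* **Fold change with zero counts.** The cutoff comparison uses
  $(x+0.5)/(y+0.5)$, which preserves ordering while avoiding infinities;
  raw counts are reported unchanged.
* **Tie handling.** Point masses are compared with a relative tolerance of
  $10^{-7}$ (the convention `stats::binom.test` also uses), so
  floating-point noise cannot split exactly tied outcomes.
* **Degenerate input.** Genes with zero informative reads carry no
  information and are excluded before testing.

Traceable-locus discovery turns paired exome/RNA pileups into these counts
when phased variants are unavailable. A site qualifies when it is
homozygous in the exome — implemented as the majority base carrying at
least 98 % of exome reads, a tolerance for sequencing error since strict
100 % homozygosity would discard most deep sites — with more than 10 reads
(≥ 11) in both assays, and the RNA shows exactly one alternative base at
≥ 5 % of reads and ≥ 3 reads. Sites with two qualifying alternative bases
are ambiguous (possible mapping artefacts) and are excluded and counted.
The alternative-base rule is evaluated per sample pair; pooling across
samples is a caller-level choice the interface leaves open.

## Differential expression and MZT classes

FPKM is recomputed from raw counts as $10^9 x / (L N)$ with $L$ the union
length of the gene's exons (strand-agnostic, from BED12 models) and $N$ the
sample's assigned reads. Group-level FPKM merges replicates by summing
counts and libraries first — a ratio of sums, not a mean of ratios — so
deep replicates carry their proper weight.

The differential test pools replicates per group and asks whether the
gene's share of reads matches the groups' library-size split: with pooled
counts $x_A, x_B$ and libraries $N_A, N_B$, the p-value is the exact
two-sided binomial test of $x_A$ in $x_A + x_B$ trials at
$p_0 = N_A/(N_A+N_B)$. This is a deliberately simple exact engine: the
thresholds, not the engine, define the DEG set, and the interface keeps the
testing backend pluggable (a negative-binomial model could substitute
without touching the callers). Pooling ignores biological
replicate-to-replicate variance, so raw p-values are anticonservative under
overdispersion; the conjunction with the fold-change and FPKM filters is
what keeps the empirical null DEG rate low (about 1 % at the default three
replicates per group — measured by the test suite's null simulation). The
log2 fold change rescales pooled counts to the geometric-mean library
before adding a 0.5 pseudocount, so equal normalized rates give exactly 0.
The fold cutoff is applied to this normalized pooled ratio (the alternative
— a shrunken engine-specific estimate — would tie the thresholds to an
engine; this choice keeps them elementary and reproducible).

DEGs require adjusted p < 0.05 (BH over all genes with nonzero pooled
counts), fold > 2 (strict), and merged FPKM ≥ 1 in at least one group.
Comparisons involving AG morulae drop chromosome-X genes: AG morulae carry
no X chromosome, so X-linked "differences" there are karyotype, not
regulation.

MZT classes come from the 4-cell vs 8-cell contrast within one genotype:
maternally degraded genes are 4-cell-biased DEGs with 4-cell FPKM ≥ 2;
newly transcribed genes are 8-cell-biased DEGs with 8-cell FPKM ≥ 2. The
ZGA gene set is an externally supplied list (the package ships none;
the simulator writes its truth list as the input) intersected with genes
expressed at the 8-cell stage (FPKM ≥ 1). A listed ZGA gene that is also an
8-cell-biased DEG is reported as newly transcribed in the single `class`
column, with list membership kept in `is_zga` — the two notions genuinely
overlap and flattening them any other way would hide the DEG evidence.

Retrotransposon subfamilies are classified on subfamily-level FPKM alone:
parent-specific means FPKM > 20 in the high genotype and at least twice the
other genotype's value.

## Differential methylation

Methylation level at a CpG is $m/(m+u)$ over strand-merged counts; sites
need depth ≥ 3 to be quantified and depth ≥ 5 in *both* samples to be
tested. Each tested site's $2\times2$ table is evaluated with a two-tailed
Fisher exact test (minimum-likelihood enumeration of the conditional
hypergeometric distribution, same tie tolerance as above). The BH family is
all tested sites — not only large-difference sites — so the adjustment is
honest about how many hypotheses were examined. DMSs require adjusted
p < 0.1 and |difference| > 0.2.

Region merging chains same-direction DMSs whose gaps are under 500 bp
(strict: a gap of exactly 500 breaks the chain), separately for
maternal-hyper and paternal-hyper sites; mixed-direction regions cannot
arise under this rule. A pre-DMR spans its first to last member DMS
(1-based inclusive; size = end − start + 1). Region-level significance is
under-determined by a site-level recipe, so the package makes a choice and
names it: a Fisher exact test on the counts pooled over every *tested* site
in the region, BH-adjusted across pre-DMRs (`region_test = "pooled"`, the
default). The stricter alternative — requiring every member DMS to pass the
site-level adjusted cutoff — is available as
`region_test = "all_members"` without any claim that one or the other is
canonical. Final DMRs need ≥ 3 member DMSs, region padj < 0.1, pooled
|difference| > 0.2 and size > 50 bp. DMR output is invariant to input row
order (sites are sorted internally), and every reported region satisfies
all four filters by construction — both properties are asserted in tests.

Element-level methylation pools counts over the covered CpGs inside an
interval; promoters (TSS ± 1 kb) report no value below 5 covered CpGs,
since a promoter mean from 2–3 CpGs is mostly noise.

## Allelic chromatin accessibility

Per-sample peak calls are concatenated and overlapping intervals merged
(transitively) into a master list; a master peak is "detected" in a sample
if it overlaps any of that sample's original peaks. Signal is FPKM over the
master interval. Because uniparental DNase-seq libraries differ in
signal-to-noise ratio, depth normalization alone is not comparable across
samples; the package assumes the brightest peaks carry equal true signal
and computes a scale factor as the ratio of median FPKM in each sample's
own top 10 % of master peaks (`n_top = ceiling(0.1 n)`, ties broken by
position order so the factor is deterministic; the alternative of a joint
ranking is available via the `top_frac`/ordering machinery but the
per-sample ranking is the default because each sample's own brightest peaks
are the ones its noise floor is calibrated against). Degenerate inputs — a
zero median in the denominator sample, or fewer than 10 peaks — are errors,
not silent values.

After multiplying sample B's FPKM by the factor, a peak is allele-specific
only when *both* rules hold: detected in exactly one sample, and scaled
fold change above 2 computed as $(f_A + 0.5)/(f_B^{scaled} + 0.5)$. The 0.5
FPKM pseudocount handles undetected peaks with near-zero signal without
manufacturing infinite fold changes. The calls are invariant to a global
rescaling of either sample — the normalization exists precisely to remove
that factor — and the suite exercises this with signal-to-noise ratios
0.5–4.

## What the generator emulates, and what it does not

The generator is the package's study design, not a tuning knob; its
defaults are fixed and the tests run against them.

* **Expression** (`n_genes = 2000`, three stages × AG/PG × 3 replicates,
  library 10⁶): negative-binomial counts, $\mathrm{Var} = \mu + \phi\mu^2$
  with $\phi = 0.1$ (a typical bulk-RNA overdispersion), per-sample means
  rescaled to the library size. 15 % ZGA genes (pre-activation mean 1,
  ×16 at activation: 8-cell in AG/biparental, morula in PG; α-amanitin
  pins them at pre-activation), 15 % maternal-decay genes (mean 100 at
  4-cell, ÷16 once ZGA has fired — decay is ZGA-dependent, so PG retains
  them at the 8-cell stage), the rest stable log-normal. Three replicates
  match the study design this emulates and keep the pooled test's null DEG
  rate (~1–2 %) inside its nominal 5 %. About 5 % of genes sit on
  chromosome X to exercise the AG-morula exclusion.
* **Allelic counts** (`n = 2000`): depth $30 + \mathrm{Pois}(30)$,
  paternal reads binomial with $\pi = 0.95$ for the 5 % paternally biased
  genes, $1-\pi$ for the 5 % maternally biased, 0.5 otherwise.
* **Methylomes** (`n_cpgs = 2400`, spacing ~55 bp, depth
  $\mathrm{Pois}(10)$, zero-depth sites omitted as in real coverage files):
  100 injected DMRs of 8 CpGs, baseline 0.5 shifted +0.5 in the
  hypermethylated sample, separated by > 500 bp margins so truth regions
  cannot chain together. A third of CpGs lie inside parent-specific DMRs —
  a deliberately differential landscape, appropriate for a PG-vs-AG
  contrast where the gamete-derived methylomes differ pervasively.
  `ml_shift_b` adds global paternal hypomethylation when the analysis under
  test is the genome-wide level difference.
* **Accessibility** (`n_peaks = 2000`): log-normal true signal with a
  detectability floor of 2 FPKM (a peak caller cannot call a peak at the
  ~0.3 FPKM background, so truly undetectable "peaks" would be generator
  artefacts); 10 % allele-specific peaks absent from the other sample's
  call list; sample B's in-peak signal divided by the signal-to-noise
  factor β before Poisson read sampling, so the top-decile scale factor
  should recover β.

Not emulated: read-level artefacts (mappability, GC, bisulfite conversion
failure), linked SNP phasing, imprinting clusters, X inactivation,
transcript isoforms, peak-boundary jitter between samples. Passing tests
therefore demonstrate the statistical machinery — calibration, recovery,
normalization, rule conjunctions — on data whose error structure is
idealized; they do not certify performance on alignment-level artefacts,
which the pipeline's inputs (counts, coverage files, peak lists) assume
were handled upstream.

A note on power, recorded rather than hidden: at the simulated depth
(λ = 10) a single CpG with a 0.5 methylation difference yields a Fisher
p-value around 0.02–0.07, so under the BH family of all ~2300 tested sites
only ~45 % of true member sites reach the site-level DMS threshold. Eight-CpG
regions then clear the 3-DMS floor in roughly 55–75 % of cases depending on
seed, and recovered regions span their first-to-last DMS — a subset of the
truth interval. Region-level recovery (overlap-matched Jaccard, reported by
`dmr_recovery()` alongside the stricter base-pair Jaccard) is the primary
recovery metric for exactly this reason: it measures whether regions are
found, while the bp metric additionally penalizes the deliberate
first-to-last-DMS boundary convention.

## Reproducibility and problem sizes

All randomness flows from one seed: each generator runs under
`seed + offset` (101 expression, 202 allelic, 303 methylome, 404
accessibility), so the four data types are independent but jointly
reproducible, and repeated simulation with one seed is byte-identical on
disk. The test suite and `scripts/acceptance.R` use 2000 genes, 2000
allelic genes, ~2400 CpGs and 2000 peaks per run — sizes chosen so the full
statistical battery (exhaustive exact-test oracles up to table totals of
60, null calibrations on ≥ 2000 entities, recovery runs at three
signal-to-noise ratios) completes in a few minutes on one core while
keeping every empirical rate estimate's Monte-Carlo error well below the
margins being tested.

## Known limitations

* The pooled exact DE test trades replicate-variance modelling for
  exactness and zero fitted parameters; with strong overdispersion and many
  replicates a negative-binomial engine should be plugged in instead.
* Region-level DMR significance is a design choice between two defensible
  definitions (pooled re-test vs all-members); both are implemented, and
  results near the padj boundary can differ between them.
* The scale-factor normalization assumes the top-decile signal is truly
  shared; a genome where the brightest peaks are themselves allele-specific
  would bias it.
* `classify_mzt()` classifies per contrast; combining genotypes (e.g. a
  gene degraded in AG but ZGA-listed in PG) is left to the caller's
  downstream logic.
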