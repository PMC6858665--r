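---
title: "Discovering TE-derived lncRNAs and their stress co-expression hubs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering TE-derived lncRNAs and their stress co-expression hubs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncstress)
```

## The problem this package addresses

Long non-coding RNAs (lncRNAs) are transcripts longer than 200 nt that
carry no open reading frame of 100 amino acids or more. In large plant
genomes — maize being the canonical example, with the great majority of
its DNA derived from transposable elements (TEs) — a substantial share
of lncRNAs is itself TE-derived, and a subset responds to abiotic
stresses such as heat, cold, drought and salt. Deciding which of
thousands of candidate transcripts are credible lncRNAs, which derive
from which TE superfamilies, which respond to stress, and which sit at
the centre of stress-responsive co-expression modules is a pipeline
problem: a cascade of sequence filters, interval arithmetic against
genome annotations, count-based differential-expression tests, and a
weighted network analysis.

`lncstress` implements that pipeline as composable, tested functions
with tidyverse interfaces, together with a fully deterministic synthetic
data generator that plants known truth at every stage, so the whole
cascade can be exercised and validated at desk scale without any
external download.

## The discovery cascade

A transcript from the unified assembly passes the filter cascade — and
is recorded as a high-confidence lncRNA — if and only if:

1. **Length**: spliced length $\geq$ 200 nt (`min_length_nt`).
2. **Coding potential**: called non-coding by *both* external
   predictors when their tables are supplied — a CPC2 score below $-1$
   (`cpc2_noncoding_max_score`) *and* a non-coding CNCI label. When
   external evidence is absent and strict mode is off, an internal
   ORF-based stand-in is used instead: non-coding iff the longest ORF
   is under 100 aa *and* covers less than 35% of the transcript. The
   stand-in is deliberately conservative about ORF coverage: a short
   transcript dominated by one ORF is plausibly a small-peptide gene,
   not a lncRNA.
3. **Protein-domain exclusion**: no Pfam hit with e-value $\leq 10^{-5}$
   (`pfam_evalue_max`). The boundary case (an e-value exactly at the
   threshold) rejects: with a filter meant to exclude anything
   resembling a protein family, the conservative reading puts ties on
   the reject side.
4. **ORF rule**: longest ORF strictly under 100 aa (`max_orf_aa`). ORFs
   are scanned on the annotated strand only, in all three frames; an
   ORF is an ATG followed by an in-frame stop wholly inside the
   transcript, and nested starts sharing a stop collapse to the longest
   (earliest start after the previous stop). The classical definition
   also says "no more than one short ORF"; counting literally every
   ATG–stop pair would make that unsatisfiable for most random 200-nt
   sequences, so `orf_count` counts only ORFs of at least
   `min_orf_aa_to_count` (30 aa) and is reported, not enforced.
5. **Genomic context**: class code `u` (intergenic: the transcript span
   overlaps no gene span) or `i` (every base inside introns of a single
   gene, no exon overlap). Any exon overlap — or straddling a gene
   boundary without being intron-contained — excludes the transcript;
   sense/antisense exonic lncRNAs are deliberately out of scope, at the
   cost of under-representing gene-derived lncRNAs. Candidates falling
   within or overlapping known lncRNA loci are relabelled instead of
   double-counted.
6. **Expression**: FPKM strictly above 1 (`min_fpkm`) in at least one
   sample, with FPKM $= c \,/\, \big((L/10^3)(N/10^6)\big)$ for count
   $c$, transcript length $L$ and mapped-fragment total $N$.

Filters are applied in the order length → coding potential → Pfam →
class code → FPKM. The order affects only which rejection reasons are
recorded — membership in the final set is order-invariant, and every
record carries its full reason trail.

A transcript is assigned **polyA$^-$ origin** when it exceeds the FPKM
floor in at least one total-RNA library and in none of the polyA$^+$
libraries; otherwise polyA$^+$. Transcripts expressed nowhere (already
rejected by the FPKM filter) default to polyA$^+$ and are flagged.

All genomic coordinates are 0-based half-open internally; GTF,
GFF3 and RepeatMasker coordinates are converted exactly once, at the
I/O boundary. Overlap computations ignore strand, matching
orientation-free repeat masking.

## TE overlap and superfamily attribution

Real pipelines mask lncRNA sequences against a species-specific repeat
library by alignment. Here masking is positional: the fraction of a
transcript's exonic bases covered by annotated TE intervals. For
synthetic data the two notions coincide by construction (TE-derived
lncRNAs are literal copies of TE interval sequence); for real data a
precomputed RepeatMasker `.out` on the lncRNA set can be ingested
through the same reader.

Bases covered by several superfamilies count once toward `masked_bp`
(so the masked fraction never exceeds 1) and are attributed to the
family with the larger local overlap, ties broken lexicographically;
the assigned superfamily is the argmax of per-family bases. Any overlap
($>0$ bases) calls a TE-lncRNA — that matches the "overlapped with
known TEs" reading of the source analyses — but the threshold is
configurable because single-base calls are fragile in noisy
annotations.

The enrichment table compares each superfamily's share of TE-lncRNA
masked bases with its share of genomic TE bases; the fold ratio of the
two shares is the enrichment statistic, computed per family and per
grouped class (retroelements, DNA transposons, helitrons,
unclassified). Percentage columns sum to 100 by construction.
Pearson's $\chi^2$ (no continuity correction, df = 1) serves for 2×2
contrasts such as polyA$^-$ vs polyA$^+$ TE proportions.

## Differential expression

Counts are normalized with median-of-ratios size factors (median over
all-nonzero transcripts of the count over its geometric mean across
samples, rescaled to geometric mean 1; library-size ratios as a warned
fallback). The test stage is implemented in-package rather than
delegated, as a deliberately transparent negative-binomial Wald test:

* per-transcript dispersion $\alpha$ by method of moments on normalized
  counts, pooled across the two arms (within-arm residual variance;
  $\alpha = \max\{(v - \bar\mu)/\bar\mu^2,\ 10^{-8}\}$),
* $\log_2$ fold change from arm means with pseudo-count 0.5 (so zeros
  are finite),
* a delta-method standard error with per-sample variance
  $\mu/s_j + \alpha\mu^2$,
* and the Wald statistic referred two-sided to a **t distribution with
  $n_1+n_0-2$ degrees of freedom**. With 2–3 replicates per arm — the
  regime these stress designs live in — the variance estimate has very
  few degrees of freedom, and a normal reference rejects roughly 12%
  of true nulls at a nominal 5%; the t reference restores calibration
  (measured 0.048–0.052 across simulation seeds in the test suite).

No dispersion shrinkage, outlier filtering or independent filtering is
applied; these are documented simplifications, and numerical agreement
with any particular DE package is not a contract — agreement with the
planted truth of the simulation (type-I error, effect recovery, power)
is what the tests assert.

A transcript is called `up` when $\log_2\mathrm{FC} > 1$ and BH-adjusted
$p < 0.05$, `down` symmetrically; the absolute-value reading for
down-regulation is adopted since down-regulated calls plainly exist in
the source tables. Benjamini–Hochberg is the adjustment for DE calls;
Bonferroni is reserved for term enrichment, where the source analysis
names it.

## The co-expression network

Counts are transformed as $\log_2(c/s + 1)$ — a simple
variance-stabilizing surrogate; module recovery at these scales is
insensitive to the difference from a parametric VST, which is why the
exact transform was not reimplemented. The unsigned adjacency is
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^{\beta}$ with soft threshold
$\beta = 12$, and the topological overlap similarity is

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \neq i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \neq i} a_{iu}.$$

Modules come from average-linkage hierarchical clustering on
$1-\mathrm{TOM}$ with a flat cut, replacing the dynamic tree cut for
determinism and simplicity. The default `cut_height` is **0.99**, and
the choice deserves a note: on the $1-\mathrm{TOM}$ scale, unrelated
transcripts sit essentially at 1 (their $|r|^{12}$ adjacency is
numerically zero), while genuinely co-expressed blocks — even tightly
correlated ones, $|r| \approx 0.9$ — merge at heights around 0.7–0.9,
because $0.9^{12} \approx 0.28$ keeps topological overlap well below 1.
A cut far below that (say at 0.25, which is the familiar *eigengene
merge* threshold from the WGCNA tradition, a threshold on a different
dissimilarity) would shatter every real module into singletons. Cutting
just under 1 separates signal from the noise floor; clusters below
`min_module_size` (20) are relabelled `grey`, which is also what keeps
pure-noise data module-free. Labels are assigned by decreasing size
with deterministic tie-breaking, so module names are invariant to input
order.

Each module's eigengene is the first principal component of the
row-standardized member expression, unit-normalized, with its sign
fixed so it correlates non-negatively with the members' mean profile.
Module–trait correlations use per-sample one-hot indicators for each
(condition, stage) combination, with $p$ from the t transform at
$n-2$ df; the same machinery applied to transcript rows gives
gene-significance (GS). Both $r$ and $r^2$ are reported explicitly,
since correlation heat maps in this literature label the two
inconsistently.

Membership is $\mathrm{kME}(t, M) = \mathrm{cor}(x_t, E_M)$ and
intramodular connectivity $\mathrm{kIM}(t)$ is the adjacency sum to the
transcript's own module. A **hub** is a module member with kIM rank
within the top 10% of the module, own-module kME $> 0.9$, and GS
$p < 0.01$ against the module's best-correlated trait. The GS reading
of "high significance in the module" (rather than a kME p-value) is a
design choice: it ties hub status to the stress trait the module
tracks, which is the scientific claim a hub is meant to support.

The "$R^2 \geq 0.8$ pairwise correlation" step described in the source
methods is ambiguous — it could be a node prefilter, an edge filter for
visualization, or a restatement of defaults — so it is implemented as
an optional node-retention filter (`prefilter_min_r2`, keep transcripts
with at least one partner at $r^2 \geq 0.8$) and is **off** by default.

## Downstream analyses

* **Nearest gene**: gap distance between genomic spans (0 when
  overlapping or book-ended), minimized over genes; span distance
  rather than TSS distance because the source does not specify, and
  span distance is the convention interval toolkits default to.
  Equidistant flanks resolve to the upstream gene and are flagged.
* **Cis correlation**: Pearson correlation of pooled
  ($\log_2$FC lncRNA, $\log_2$FC nearest gene) pairs across contrasts
  — fold-change space, not raw expression, matching how the
  relationship is displayed in this literature.
* **Expression summaries**: per-transcript maximum FPKM across samples,
  averaged per class, with coding-over-class fold ratios.
* **Expression entropy**: with group means $m_g$ over (condition ×
  stage) groups, $p_g = m_g/\sum m_g$ and $H = -\sum p_g \log_2 p_g$.
  The grouping is configurable because the source does not define its
  own; condition × stage is the finest design-level grouping available
  here.
* **Term enrichment**: one-sided Fisher exact p per term from the
  hypergeometric upper tail, Bonferroni-adjusted across tested terms at
  an experiment-wide 0.05. No GO-DAG propagation — the term map is a
  flat term → gene table.
* **qPCR utility**: the comparative $2^{-\Delta\Delta C_t}$ fold change
  with its standard error propagated from replicate variances.

## The synthetic data generator

`sim_config()` defines the study the package simulates; its defaults
*are* the desk-scale study conditions, chosen once:

* **Genome**: one 2 Mb chromosome. Genes (200, three exons each,
  planted ORFs of 150–260 aa written into the genome) sit in islands of
  about five genes separated by wide intergenic seas — the gene-island
  architecture of large TE-rich plant genomes, and the only layout in
  which 10 kb retrotransposons have contiguous room. TEs cover 45% of
  the genome (a desk-scale stand-in for a TE-dominated genome that
  still leaves room for genes and TE-free lncRNAs), packed
  non-overlapping, widest first, with superfamily base shares matching
  a maize-like composition (Gypsy 0.596, Copia 0.324, DNA transposons
  0.060 in total, helitron/LINE/SINE the remainder) exactly up to
  element-length rounding.
* **lncRNAs**: 150 single-exon loci with log-normal lengths around
  380 nt (the average candidate length reported for maize), clipped to
  [200, 1500]. 65% are TE-derived (copied from a TE interval over at
  least 90% of their length, occasionally with a small overhang), 5%
  intronic — large enough that the intronic code path is genuinely
  exercised at n = 150, while keeping intronic lncRNAs the rare class
  they are in real annotations — and the rest intergenic and TE-free.
  Every lncRNA locus is rejection-sampled until the *full* non-coding
  rule holds (longest ORF < 100 aa *and* ORF coverage < 35%): the
  generator plants transcripts that are non-coding by the declared
  definition, not merely by its ORF-length half, so discovery failures
  on synthetic data can only come from the expression filter.
* **Samples**: 36 in total — polyA$^+$ libraries for control plus four
  stresses (heat, cold, drought, salt) across stages V3/V4/V6 with two
  replicates each, and two total-RNA control libraries per stage. 40%
  of lncRNAs are total-RNA-only (zero counts in every polyA$^+$
  library), mirroring the polyA$^-$ share of the motivating dataset.
* **Counts**: negative binomial with variance $\mu + \alpha\mu^2$,
  $\alpha = 0.1$ — standard bulk RNA-seq overdispersion. Base
  expression is log-normal on the FPKM scale (sdlog 0.6) with class
  medians 8 (coding), 2 (lncRNA) and 4/3 (TE-lncRNA): coding
  transcripts severalfold above lncRNAs, TE-lncRNAs lowest, as in the
  expression summaries this package reproduces.
* **Differential expression**: 15% of transcripts receive a ±2 log2FC
  shift in one randomly chosen (stress, stage) contrast, shared with a
  second contrast with probability 0.3. For each DE lncRNA, its nearest
  gene (if otherwise untouched) receives a correlated effect calibrated
  so the population correlation of the planted fold-change pairs equals
  0.5. Recovery of that correlation from *estimated* fold changes is
  checked in a dedicated study with six replicates per arm — the same
  precision regime as the effect-recovery checks — because at two or
  three replicates the estimation noise on low-abundance lncRNAs
  attenuates the pooled correlation well below its population value,
  a measurement fact, not a pipeline defect.
* **Modules**: three planted modules of 30 members drawn from expressed
  polyA$^+$ transcripts. Each module follows a latent factor that is
  partly its assigned (stress, stage) indicator (correlation 0.7) and
  partly free variation; members load on the latent factor so pairwise
  correlations target 0.9, with a log2-scale signal standard deviation
  of 2.5 — large enough that biological covariation dominates NB
  measurement noise even for low-abundance lncRNA members, which is
  what "correlation 0.9" has to mean after counting noise. The first
  member of each module follows the latent factor with loading one and
  minimal extra noise: the planted hub.
* **Determinism**: one seed fixes everything; identical configurations
  produce byte-identical FASTA/GFF3/BED/GTF/TSV/JSON outputs, which the
  tests verify by file comparison.

What the generator does **not** emulate — and hence what passing tests
cannot certify about real data: multi-isoform loci and splice
complexity, batch and library-preparation effects, read-level error
(there is no FASTQ stage), sequence-homology TE masking (positional
overlap stands in for it), GC and mappability biases, and any genome
larger than desk scale. The recovery results on synthetic data are
statements about the pipeline's correctness under its own model, not
about biology.

## Numerical choices and degenerate inputs

Pseudo-count 0.5 on normalized means keeps fold changes finite at
zeros; all-zero transcripts test at $p = 1$. The dispersion floor is
$10^{-8}$. Zero-variance expression rows are flagged and excluded from
correlation. Constant traits yield absent (NA) correlations rather than
errors. Ties break lexicographically (superfamily attribution) or by
smallest member index (module labels), never by input order. Empty
interval sets are legal everywhere and yield zeros. The simulation and
every pipeline stage run single-threaded in a few seconds to a few tens
of seconds at default sizes; the test suite's heaviest block (20-seed
module/hub recovery) reuses one simulated genome and varies only the
count layer.

## Known limitations

The class-code vocabulary covers only the intergenic/intronic discovery
scope, so gene-overlapping lncRNA classes are reported as `excluded`
rather than subclassified. The internal coding-potential stand-in is a
rule of thumb, not a trained model — for real data, supply CPC2/CNCI
tables. The flat tree cut trades the adaptivity of dynamic
tree-cutting for determinism; strongly nested module structure would
need a more elaborate cut. Module merging by eigengene similarity and
scale-free-fit–based $\beta$ selection are out of scope.
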