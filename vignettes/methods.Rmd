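---
title: "Methods: allele-fraction lattices, copy-number inference and RNA-DNA imbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-fraction lattices, copy-number inference and RNA-DNA imbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelecho)
```

## The question and the model

A heterozygous somatic mutation matters only to the extent that the
mutation-bearing allele is transcribed. `allelecho` quantifies this by
comparing, mutation by mutation, the DNA allele fraction with the RNA allele
fraction, after first solving the prerequisite problem: what fraction *should*
we expect in DNA?

Because chromosomes come in whole copies, the DNA mutant allele fraction is
constrained to a discrete lattice. With locus copy number $CN$, mutant
multiplicity $m \in \{1,\dots,CN\}$ and tumor purity $\rho$,

$$\mathrm{AF}(m, CN; \rho) = \frac{m\rho}{CN\rho + 2(1-\rho)},$$

the $2(1-\rho)$ term being the two wild-type copies contributed by
contaminating normal cells. For a pure cell line ($\rho = 1$) this is $m/CN$.
Mutations at $m = CN$ are homozygous and appear at 100% regardless of $CN$.

Two independent observations pin an SNV to a lattice point:

1. its pooled tumor DNA counts $k/n$, scored with a binomial likelihood at
   each lattice fraction (fractions are clamped to $[10^{-6}, 1-10^{-6}]$ so
   homozygous points remain comparable if a stray error read appears);
2. its tumor:germline coverage ratio $r$, scored with a Gaussian likelihood
   on the log scale around $\log\{(\rho\,CN + 2(1-\rho))/c\}$, with
   delta-method standard error $\sqrt{1/n_t + 1/n_g}$ for a ratio of Poisson
   read totals. The sample-wide scale $c$ absorbs the mean DNA content per
   cell; at $\rho = 1$, $c$ estimates the mean ploidy $\psi$.

`fit_sample_model()` grid-searches $\rho \in \{0.10, 0.15, \dots, 1.00\}$
(the granularity at which purity is scientifically meaningful here) and $c$
(coarse log-grid then local refinement), assigning each SNV its best lattice
point at each candidate and keeping the $(\rho, c)$ with the highest total
log-likelihood. $\psi$ is reported as the mean fitted $CN$ over loci. When
several purities fit equally well — an all-diploid genome is the canonical
case, where every heterozygous SNV sits at 50% under many $(\rho, CN, m)$
combinations — the model is flagged `rho_identifiable = FALSE` with a
warning rather than silently picking one.

### Tie-breaking and evidence weighting

Lattice fractions coincide across copy numbers ($1/2 = 2/4$, $1 = m/m$).
The coverage-ratio term usually separates them; exact ties are broken toward
the smaller copy number, then the smaller multiplicity — a deterministic
parsimony rule. The two likelihood terms get equal weight by default
(`ratio_weight = 1`), exposed as a tunable scalar since there is no
principled universal choice.

### Segment pooling

Copy number is a property of a genomic segment, not of one base. A single
SNV position sequenced at depth ~100 in duplicate gives a log-ratio standard
error of ~0.1, while adjacent copy numbers at $CN \ge 3$ differ by only
0.2–0.3 in log ratio — so for homozygous mutations, whose allele fraction
carries no copy-number information, per-SNV ratios leave a few percent of
assignments ambiguous. `pool_segment_ratios()` therefore sums tumor and
germline totals over all SNVs sharing a segment (membership from the BED
segment table via `snv_segment_index()`) before forming the ratio, shrinking
its uncertainty by roughly $\sqrt{\text{loci per segment}}$. The pipeline
uses pooled ratios; the per-SNV path remains available (`assign_cn()` with
per-SNV ratios) and is what the single-locus worked example uses.
Discovering segment boundaries from coverage is out of scope — segments are
an input.

## Allele fractions and filters

The allele fraction estimate is $\hat p = k/n$ with a binomial standard
error stabilized by a +2/+4 pseudocount, $\tilde p = (k+2)/(n+4)$,
$se = \sqrt{\tilde p(1-\tilde p)/(n+4)}$, so that boundary replicates
($k = 0$ or $k = n$) keep a finite, positive uncertainty and therefore a
finite inverse-variance weight. Replicates are combined with weights
$w_i = 1/se_i^2$; more reads, more weight. On duplicates at depth ≥ 50 the
weighted and pooled estimates agree within one percentage point for >99% of
loci; the exceptions are loci whose replicates disagree beyond sampling
noise, where estimate-dependent variance weights deliberately differ from
pure count weights.

Two filters precede any comparison:

* **Coverage floor** (`min_read_filter`): at least 10 DNA and 10 RNA reads
  must overlap the position, pooled over replicates, cutoff inclusive. The
  pooled reading (rather than per-replicate) was chosen because the decision
  is about the information available at the position. 10 reads trades
  allele-fraction accuracy against the number of usable SNVs.
* **Germline binomial filter** (`germline_binomial_filter`, $\alpha = 0.05$,
  error rate $\varepsilon = 10^{-3}$ by default): a somatic call is kept only
  if the germline is deep enough that a heterozygous germline variant would
  almost surely have shown up ($0.5^{n_g} < \alpha$, i.e. $n_g \ge 5$ at
  $\alpha = 0.05$) *and* observed germline mutant reads are consistent with
  sequencing error (one-sided exact binomial test). Both thresholds are
  configurable; the defaults are conventional rather than derived.

## Imbalance statistics

The imbalance score is $I = 100(p_{RNA} - p_{DNA})$ percentage points —
negative when the mutant allele is under-represented in RNA. Groups are
compared with the classic pooled-variance two-sample t-test (Welch available
via `welch = TRUE`); agreement is measured as squared Pearson correlation.
SNVs are stratified by RNA coverage (≥ 65 vs < 15 reads — chosen to give
similarly sized strata in data at these depths) and by consequence:
`no_PTC` vs `PTC_not_last_exon` vs `PTC_last_exon`, and orthogonally silent
vs non-synonymous. $|I| > 25$ flags extreme imbalance. No multiple-testing
correction is applied; the handful of p-values are reported raw.

## Consequence annotation

`classify_consequence()` maps each SNV into its transcript's spliced CDS —
strand-aware, with codons allowed to span exon junctions — translates
reference and mutant codons with the standard genetic code, and labels the
change silent, non-synonymous, or stop-gained. A premature termination codon
is split by whether its exon is the transcript's last: PTCs before the last
exon trigger NMD; PTCs in the last exon escape it. Exon membership alone
decides the split by default. The classical refinement — PTCs within 50 nt
upstream of the final exon–exon junction also escape — is available behind
`nmd_50nt_rule = TRUE` but off by default, keeping the simpler
last-exon-only rule as the canonical behavior. SNVs hitting the reference
start or stop codon are classified non-synonymous with a warning flag
(`start_codon` / `ref_stop`): they disrupt the protein but are not
stop-*gains*. Frame inconsistencies and non-ACGT bases raise errors naming
the transcript.

## What the simulator emulates — and what it does not

`simulate_genome()` + `simulate_counts()` generate the study conditions the
analysis assumes:

* a genome of segments with integer copy numbers 1–5 (weights default to a
  hyperdiploid profile, mass on CN 2–4; CN is capped at 5, matching the
  highest ploidy the analysis targets), one 3-exon gene per SNV, exon
  lengths 299/301/300 nt so codons genuinely span junctions;
* multiplicity $m$ uniform on $1..CN$; consequence labels drawn per
  configured fractions (defaults ~2% PTC-not-last, ~0.6% PTC-last, 29%
  silent, reflecting the approximate proportions seen in exome studies of
  this kind) and *realized in the reference sequence*, so annotation can be
  validated against generator truth;
* Poisson sequencing depths (the simplest model consistent with binomial
  read sampling; no over-dispersion by default) around 100 reads per
  replicate, two replicates — cell lines sequenced in duplicate; the tumor
  depth scaled by $(\rho CN + 2(1-\rho))/(\rho\psi + 2(1-\rho))$, i.e.
  equal-size libraries spread over genomes of different DNA content;
* a diploid germline everywhere with zero somatic mutant reads (inbred-strain
  germline; a configurable error rate exists for filter testing);
* log-normal per-gene expression (sdlog 1) driving RNA depth; RNA mutant
  fraction equal to the DNA fraction except for PTC-not-last SNVs, where the
  mutant transcript pool is multiplied by $(1-e)$, giving expected RNA
  fraction $(1-e)p/((1-e)p + (1-p))$ and a correspondingly shrunken total
  RNA depth. NMD efficiency defaults to $e = 0.8$ — strong but incomplete
  decay, the regime in which the PTC contrast is clearly visible at
  realistic depths.

Real data differ in ways the simulator deliberately omits: alignment bias
against mismatch-bearing reads, GC and capture biases, over-dispersed depths,
subclonal mutations off the lattice, multiple isoforms per gene, splice and
regulatory effects, X-inactivation and imprinting. Passing tests therefore
demonstrate that the estimators are correct *under the stated model*, not
that real libraries satisfy the model.

## Problem sizes, determinism and numerical choices

The validation fixtures use 500 SNVs at depth 100 (the scale at which
recovery properties stabilize while a full run stays in seconds), a
950-SNV fixture with ~20 PTC-not-last and ~6 PTC-last SNVs for the NMD
contrast, and depth $10^4$ for law-of-large-numbers checks. All generators
are seeded; identical configurations reproduce byte-identical fixture files
and pipeline manifests (MD5-hashed in `manifest.json`). The purity grid step
(0.05) bounds purity resolution; the coverage-scale grid is refined locally
to ~0.4% relative resolution. Copy-number recovery on pooled segments is
effectively exact at these depths; per-SNV assignment accuracy is ~94–97%
with the residual errors concentrated in homozygous mutations at adjacent
high copy numbers, as expected from the ratio information available at a
single position.

## Known limitations

* Purity enters as a single global parameter: no subclonality.
* One transcript per gene; isoform-aware annotation is out of scope.
* The germline filter assumes independent reads and a known error rate.
* Segment pooling assumes the provided segments are correct; a wrong
  breakpoint contaminates every SNV in the segment.
* At very low purity (ρ ≤ 0.2) lattice fractions crowd together and both
  purity and multiplicity become weakly identified; the profile-likelihood
  flag reports but does not fix this.
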