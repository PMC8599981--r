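---
title: "CNV harmonization and burden analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV harmonization and burden analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvburden)
```

# Scope

`cnvburden` post-processes copy-number-variant (CNV) callsets from
whole-genome sequencing (WGS) cohorts into a case/control burden analysis.
It does **not** call CNVs from reads: it assumes per-sample callsets from one
or more callers (or an already joint-genotyped multi-sample VCF) and covers
everything downstream — alignment-coverage quality control, harmonization
into non-overlapping per-sample segments, rare-variant filtering, burden
testing with permutation p-values, and cross-callset concordance. A
synthetic-data generator produces every input the pipeline consumes, so the
whole workflow is exercised end to end by the test suite.

The data model is deliberately plain: one `data.frame` row per CNV event per
sample, 0-based half-open coordinates (the BED convention), and a
copy-number alphabet of {0, 1, 3, 4}. Deletions carry 0 or 1 copies,
duplications 3 or 4, with 4 standing for "four or more"; the diploid state 2
is not a CNV and is rejected on input. Genotypes from a CNV VCF map onto
this alphabet by zygosity: a heterozygous deletion is copy number 1, a
homozygous deletion 0, a heterozygous duplication 3, a homozygous
duplication 4. Copy numbers outside the alphabet are clamped into it on
ingest.

# Coverage quality control

CNV calling from read depth is sensitive to uneven coverage across
chromosomes, so samples are screened before any calling is trusted. The
screen estimates per-chromosome fold coverage over *repetitive-free
regions*: windows (default 20 kb) in which every fully contained k-mer
(default 25-mer) occurs exactly once in the entire reference. Read depth
averaged over such windows estimates true fold coverage without mapping
ambiguity. Two deliberate conventions:

* **Strandedness.** A k-mer and its reverse complement are treated as the
  same object (sequencing is strand-agnostic), so "unique" means the
  canonical form occurs once genome-wide across both strands. k-mers
  containing ambiguous bases disqualify their window.
* **Placement.** Up to 20 regions per chromosome are chosen
  deterministically: the chromosome is partitioned into 20 equal bins and
  the leftmost qualifying window in each bin is taken; unfilled slots are
  completed by a greedy left-to-right scan over non-overlapping qualifying
  windows. When a chromosome has fewer qualifying windows than requested the
  search is best-effort, and a chromosome shorter than the window length
  simply contributes no regions. Identical inputs always give identical
  regions.

From the per-chromosome coverages, a chromosome is flagged as an **outlier**
when it deviates from the median by more than 25% of the median. The 25% is
chosen midway between the euploid expectation (0% deviation) and the ~50%
deviation of a whole-chromosome trisomy (1.5x) or monosomy (0.5x), so
aneuploidies are flagged crisply while ordinary noise is not. The overall
mean and standard deviation are then computed over non-outlier chromosomes
only (outliers are excluded *before* the verdict, so an aneuploid sample
with otherwise even coverage still passes), and a sample **fails** QC when
the standard deviation exceeds 15% of the mean. The standard deviation is
the population form (divide by *n*): the autosomes are the entire population
of interest, not a sample from one. The comparison is strict — a sample
sitting exactly at 15% passes. The verdict is scale-invariant: multiplying
all coverages by a constant changes nothing. Sex chromosomes can be excluded
by simply not supplying regions for them, since X/Y coverage depends on sex.

# Harmonization

Two distinct merging steps, with different semantics:

**Across callers (one sample).** Callers report the same event with slightly
different breakpoints. `merge_caller_callsets()` clusters same-type calls by
single linkage: a call joins a cluster when some member has *both*
breakpoints within `max_breakpoint_distance` (default 100 bp). Each cluster
collapses to the span from earliest start to latest end, with provenance
recording the contributing callers. This is a stated positional-clustering
stand-in for dedicated SV merging tools; the threshold is configurable and
no claim is made of replicating any specific tool's clustering. Calls of
different types never merge.

**Within a sample (consolidation).** Downstream association tools refuse
overlapping CNVs within one sample. `consolidate_sample_cnvs()` first merges
same-type segments that overlap or are book-ended (gap 0, the interval-merge
default) into their union; the merged copy number is the *minimum* for
deletions and the *maximum* (capped at 4) for duplications, preserving the
most extreme reported state. Then any merged deletion and merged duplication
that still overlap are **both removed entirely**. Whole-segment removal —
rather than trimming to the intersection — is deliberate: the conflicting
region carries irreconcilable copy-number evidence, and trimming would
fabricate breakpoints no caller reported. (Intersection-only removal is a
documented alternative a user can implement from the merged pieces; the
package takes the conservative route.) Consolidation is idempotent, never
increases the event count, and always yields non-overlapping sorted
segments — properties the test suite asserts on randomized inputs.

# Rare-CNV identification

Rarity is defined by overlap-based cohort frequency, mirroring the
frequency-exclusion semantics of the standard CNV association toolkit:

1. A count threshold is derived as `floor(frequency x n_samples)` — a 1%
   cutoff gives 38 on a 3,800-sample cohort and 9/12/15 on subgroups of
   978/1,247/1,566.
2. For every base, the number of cohort events covering it is counted —
   type-agnostic, any sample, *including the event under test*. An event is
   excluded when **more than** 50% of its length lies on bases whose count
   **exceeds** the threshold. Both comparisons are strict, so a threshold of
   38 tolerates exactly 38 carriers, and an event with exactly half its
   length in a common region is retained.
3. Rare events must additionally *reside entirely* in accessible genome: a
   CNV is kept only when 100% of its span is covered by the union of
   P-labeled intervals of the accessibility mask (classes P/N/L/H/Z:
   passed / reference-N / low coverage / high coverage / zero mapping
   quality). "Reside" is read as containment, not majority overlap.

The mask is applied before the frequency filter by default; the order is
configurable because either reading of the workflow is defensible, and the
two orders differ only for events whose commonness depends on
mask-excluded neighbors.

# Burden analysis

Four burden features per sample and event class (DelDup, Del, Dup): event
count, an indicator for "has at least one event" (whose group mean is the
proportion-of-samples feature), total event length in kb, and average event
length in kb. A sample with no events has count 0, total 0, and an
*undefined* average — it is excluded from the average-length statistic
rather than counted as 0, since undefined per-sample averages cannot be
averaged.

Each cell of the analysis grid — 2 CNV sets (all, rare) x 4 features x 3
event classes x 4 groups (ALL plus three ancestry groups) = 96 analyses —
is tested by label permutation: the observed statistic is the case mean
minus the control mean, labels are permuted uniformly, and the one-sided
p-value is estimated as `(1 + #{permuted >= observed}) / (1 + B)` with
B = 500,000 by default. Choices worth stating:

* **One-sided, case > control.** This matches the burden-test convention of
  the toolkit the grid mirrors, and explains p-values of exactly 1 in cells
  where controls exceed cases; a two-sided mode is available.
* **The +1/(B+1) estimator** never returns 0 and is valid (slightly
  conservative) at any B.
* **Exhaustive enumeration** replaces Monte Carlo automatically whenever the
  number of distinct label assignments `choose(n, n_cases)` is at most B;
  the p-value is then exact.
* **Undefined permuted statistics** (a permuted group containing no
  event-carrying sample, possible for the average-length feature) count as
  not exceeding the observed value — a conservative tie-break that matters
  only in near-degenerate cohorts.
* **No covariates.** The permutation test examines marginal case/control
  differences only; covariate-adjusted association is out of scope.
* The family-wise threshold is Bonferroni: 0.05/96 = 0.000521 (3
  significant figures). The grid applies it over the cells actually
  evaluated, so absent groups shrink the correction accordingly.

With a fixed seed the whole grid is bit-reproducible; cells are processed in
a fixed order and results are invariant to input row order and sample
relabeling.

# Concordance

`pairwise_concordance()` measures the fraction of a *primary* callset's
events recalled by a *secondary* callset, under either a 1-bp criterion (any
overlap) or a fractional criterion (the union of secondary overlap covers at
least `f` of the primary event, default 0.5). Coverage of the primary by the
union of the secondary makes the comparison directional — swapping roles
changes the answer, which is why the all-pairs matrix evaluates both
orders — and makes the result invariant to splitting a secondary call into
book-ended pieces. The union reading was chosen over per-single-call overlap
precisely for that splitting invariance. Matching is type-agnostic by
default (callsets compared as plain intervals); a type-aware flag restricts
matching to equal SV types. 1-bp recall always dominates fractional recall,
and stricter fractions are nested — properties asserted on random callsets.

# The synthetic-data generator

The generator emulates, under one seeded configuration object:

* **Reference sequences** of i.i.d. random bases, optionally with implanted
  duplicated blocks (known repetitive regions for the QC scanner to avoid).
  At the default scale, random 25-mers are essentially always unique, so
  duplication-free chromosomes yield abundant repetitive-free windows.
* **A population CNV pool** with log-normal lengths (median ~3 kb, a
  realistic WGS CNV scale), ~85% deletions (the deletion:duplication ratio
  typical of WGS callsets), and Beta(0.5, 5) allele frequencies skewed
  toward rarity. Pool events overlapping an existing event of the other
  type are re-drawn, so truth is conflict-free by construction.
* **Genotypes** binomial in the allele frequency, mapped to copy number by
  zygosity; **phenotypes** with configurable case count and ancestry-group
  weights (defaults proportioned like a large multi-ethnic WGS cohort).
* **An injectable burden effect**: each case receives Poisson-distributed
  extra private duplications (default mean 0, i.e. the null; the
  worked-example effect size used in the acceptance checks is 16, on the
  duplication-count channel). Effect events are placed clear of pool events
  so consolidation cannot silently erase them.
* **Caller observations**: per-caller Bernoulli missed calls, Gaussian
  breakpoint jitter, and event splitting into book-ended pieces — the three
  failure modes that the harmonization stage exists to undo.
* **Depth tracks**: per-base Poisson depth at 37x by default (a realistic
  cohort average), with per-chromosome multipliers (1.5 trisomy, 0.5
  monosomy) to exercise outlier detection.
* **Accessibility masks** partitioned into ~10-kb segments with class
  proportions defaulting to P/N/L/H/Z = 89/5.3/1.4/0.6/3.7%; labels are
  assigned by remaining base budget in shuffled order, so the realized
  composition tracks the target to within a segment length.

What the generator does **not** emulate: read-level data (no FASTQ/BAM), GC
bias, linkage disequilibrium between CNVs, population structure beyond group
labels, caller-specific size-range sensitivities, and genotyping error in
the joint-genotyped VCF. Passing tests therefore demonstrate the
correctness of the post-processing arithmetic and the statistical behavior
of the tests under a clean generative model — not robustness to every
artifact of real cohort data.

# Numerical choices and problem sizes

* Coordinates are integers throughout; interval arithmetic is delegated to
  IRanges/GenomicRanges. Fractional-coverage comparisons use a 1e-9 slack to
  absorb floating-point division; permutation-statistic comparisons use
  1e-12.
* The brute-force k-mer census oracle in the test suite (hash-table counts,
  full window scan) validates the region scanner on simulated references of
  150–200 kb — large enough that both unique and repetitive windows occur,
  small enough to enumerate exhaustively. The suite's statistical checks
  use 1,000 null replicates (type-I error and p-value uniformity at 10v10,
  400 permutations), 25 power replicates (200 cases v 200 controls, 2,999
  permutations, detecting the 16-event duplication excess below 0.000521),
  and per-base brute-force comparison on cohorts of up to 500 events. These
  sizes are the package's own choices for a thorough desk-scale validation.
* Degenerate inputs are defined, not special-cased: empty callsets
  consolidate to empty, a constant statistic yields p = 1, an empty primary
  callset makes recall undefined (an error), and an all-outlier coverage
  profile is an error since no baseline remains.

# Known limitations

* The caller-merge step is a positional-clustering approximation; callsets
  merged by dedicated SV tools may cluster differently near the threshold.
* Frequency filtering is O(events x event length) per chromosome via
  run-length coverage; genome-scale cohorts are fine, but the per-event
  loop is not optimized for tens of millions of events.
* The permutation engine permutes labels only; stratified or
  covariate-adjusted permutation is out of scope.
* The QC scanner holds per-chromosome k-mer tables in memory; it is sized
  for desk-scale references and chromosome-at-a-time use, not for running a
  3-Gb genome in one call on small machines.
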