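---
title: "Methods: panel discovery, depth-based genotyping and fingerprint analysis"
author: "snppanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel discovery, depth-based genotyping and fingerprint analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snppanel)
```

`snppanel` implements the computational side of targeted-amplicon SNP
fingerprinting of crop varieties: selecting a panel of "perfect" SNPs from
population variant data, calling genotypes from per-allele read depths,
summarising diversity and differentiation, selecting a minimal
discriminating marker set, and identifying core (backbone) varieties.
This vignette documents the models, the thresholds and their semantics,
the numerical conventions, and the choices made where the design was
genuinely open.

## Perfect-SNP discovery

A candidate site passes the panel filter iff all of the following hold
(`filter_thresholds()` collects the knobs):

1. **Biallelic SNP** — exactly one ALT allele, REF and ALT both single
   bases. Multi-allelic records and indels are retained by the VCF reader
   (`read_vcf()`) and rejected here, so the audit can report how many fall
   at this step; enforcing biallelism at read time is available as a flag
   (`require_biallelic`) with an excluded-record count.
2. **Unique flanks** — the (2·`flank_bp` + 1)-mer centred on the site
   (default 61-mer, `flank_bp = 30` bp) occurs exactly once in the genome,
   counting both strands (forward plus reverse complement). Uniqueness is
   *exact string matching*: no aligner or mismatch tolerance is involved,
   which makes the criterion fully reproducible. The site's window is read
   as one 61-mer rather than two independent 30-mers; the centred k-mer is
   the stricter and simpler reading, and is what a multiplex-PCR probe
   actually spans. Sites closer than `flank_bp` to a chromosome end fail
   with reason `edge`; windows containing `N` fail as `ambiguous base`.
3. **Clean neighbourhood** — no other SNP or indel in the variant table
   within ±`flank_bp`, and no SSR in the flanking window. The SSR
   definition follows the MISA convention by default (perfect tandem
   repeats, motif lengths 1–6, minimum copies 10/6/5/5/5/5), fully
   configurable via `ssr_min_copies`. Only *primitive* motifs are
   reported — an `(AT)x14` run is a di-nucleotide SSR, not a
   tetra-nucleotide one.
4. **Heterozygosity ≤ `het_max`** (default 0.2) — the fraction of
   heterozygous accessions among non-missing ones at the site. The bound
   is inclusive ("no more than").
5. **Missing rate < `miss_max`** (default 0.2) — fraction of missing
   accessions among all accessions. The bound is exclusive ("less than").
6. **MAF > `maf_min`** (default 0.4, exclusive: "above") — frequency of
   the second most common allele over non-missing accessions — **or** the
   subgroup-differential rescue: some allele has frequency
   ≥ `subgroup_hi` (0.95) in *exactly one* subgroup and ≤ `subgroup_lo`
   (0.05) in *every* other subgroup. "Other subgroups" is read as all of
   them; a site high in two subgroups does not qualify.

Boundary semantics are deliberate and tested: a site with heterozygosity
exactly 0.2 passes criterion 4, a site with missing rate exactly 0.2
fails criterion 5, and MAF exactly 0.4 fails criterion 6.

`select_perfect_snps()` emits one audit row per site (per-criterion
verdicts, computed values, failure reasons) plus a funnel of
per-criterion counts. Verdicts are independent of site and accession
order. A convenience subsampler (`thin_panel()`) reduces a panel to
near-uniform genomic spacing; even spacing alone does not determine a
unique subset, so no claim is made that it reproduces any particular
published panel reduction.

## Genotype calling from allele depths

`call_genotype()`/`call_genotypes()` implement a deliberately simple,
threshold-based rule set (`call_thresholds()`), not a likelihood model —
at amplicon depths of hundreds to thousands of reads the binomial
uncertainty is negligible and transparency wins:

* The allele with the most reads is the **major** allele, the runner-up
  the **minor**; further alleles at the locus are ignored for the call but
  reported as contamination depth.
* Major depth < `min_major_depth` (default 20 reads) ⇒ missing
  (`low_depth`).
* Otherwise, with ratio r = major/(major + minor) ∈ [0.5, 1]:
  r < `het_ratio_max` (0.7) ⇒ heterozygote; r ≥ `hom_ratio_min` (0.8) ⇒
  homozygote for the major allele; the band between ⇒ missing
  (`ambiguous_ratio`).

The ratio is major/(major+minor), not major:minor — the latter is ≥ 1 by
construction and could never be "under 0.7"; the chosen reading also
gives the ratio its natural support [0.5, 1]. Treating the 0.7–0.8 gap as
an explicit ambiguous band is what makes a "confident-call rate" (het
band plus hom band) a meaningful lower bound on accuracy. A depth tie is
called heterozygous — a tie is maximal evidence of heterozygosity — with
the lexically smaller allele named major for determinism. The 20-read
floor applies to the major allele's depth, per the rule's formulation; a
total-depth variant can be had by raising `min_major_depth`.

`qc_summaries()` reports the depth-band distribution (default bands
<100×, 100–5000×, >5000×), the ratio-band distribution with the
confident fraction, per-locus call rates, and flags loci for exclusion
when PIC < 0.1 or missing rate > 0.1.

## Diversity statistics

For allele frequencies $p_i$ over non-missing calls (two copies per
variety):

$$\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2,
\qquad D = 1 - \sum_i p_i^2, \qquad F = 1 - H_o/H_e.$$

$H_e$ is Nei's gene diversity $1-\sum p_i^2$ with no small-sample
correction, which makes $H_e$ and $D$ coincide per locus — consistent
with the two formulas being used side by side in this literature; the
$2n/(2n-1)$ bias-corrected variant is available via
`locus_stats(corrected = TRUE)`. MAF is the frequency of the second most
common allele (never above 0.5, also for multi-allelic sites). For a
biallelic locus PIC is maximised at $p = 0.5$ with value 0.375 and $D$
with value 0.5; PIC ≤ D always. Note that published "PIC" columns
sometimes reach 0.5 for biallelic SNPs, which exceeds the PIC formula's
biallelic maximum and matches $D$ instead — both statistics are therefore
always emitted and never conflated. $F$ is computed per locus and
averaged for subpopulation summaries (`subpop_summary()`); the
ratio-of-means alternative is a different estimator, and neither is
canonical — the per-locus average is used because it weights loci
equally. $F$ is undefined (NA) where $H_e = 0$.

## AMOVA and pairwise Fst

`amova()` performs the classic three-level hierarchical decomposition —
among populations, among individuals within populations, within
individuals — on allele copies (2N copies for N individuals; total df
2N−1). The squared distance between two copies is the number of loci at
which their alleles differ, evaluated over pairwise-complete loci; for
biallelic SNPs this is the standard squared-Euclidean allele-mismatch
convention up to a constant factor, which cancels in percentages and
Φ-statistics. Sums of squares come from the copy-level distance matrix;
variance components follow from the expected mean squares of the
unbalanced nested design (with the usual n_c coefficient). Negative
components are reported as computed, not truncated. Percentages are
components over their sum; Φ-statistics (F_ST, F_IS, F_IT) use the
standard ratios. Subpopulations of size 1 are rejected (zero
within-population df). No permutation test is run by default.

`pairwise_fst()` re-implements the Weir–Cockerham estimator rather than
delegating: per locus and allele the components a (among populations),
b (among individuals) and c (within individuals) are computed from sample
sizes, allele frequencies and heterozygote frequencies, and the
multi-locus estimate is the ratio of sums θ = Σa/Σ(a+b+c). The h̄ terms
make the estimator valid for inbred material. θ is symmetric, invariant
to allele relabelling, and NA (with a message) when every locus is
monomorphic across the pair.

## Core markers and core varieties

`differential_matrix()` counts, for each variety pair, loci where both
calls are non-missing and the unordered genotypes differ. A missing
genotype is treated as **null**: it never distinguishes a pair. The same
conservative rule is used in marker selection and kinship, for internal
consistency; the number of comparable loci per pair is reported
alongside.

`select_core_snps()` is a set-cover heuristic over variety pairs: greedy
mode adds the locus resolving the most currently unresolved pairs, with
ties broken by higher PIC then input (genome) order, so the output is
deterministic. Exhaustive mode finds a provably smallest subset matching
the full panel's discrimination by size-increasing search, and is bounded
to ≤ 25 loci and ≤ 50 varieties (set cover is NP-hard; beyond that the
search space explodes and the function directs you to greedy mode). The
saturation curve records distinguished pairs after each added locus and
is non-decreasing by construction. The discrimination denominator is the
fraction of variety *pairs* distinguished; the alternative reading — the
number of varieties whose profile is unique against all others — is
computed alongside in the curve (`unique_varieties`).

`select_core_varieties()` ranks varieties within each subpopulation by
mean differential count against the other members (ascending — most
central first, ties broken by matrix order) and takes the top
`ceil(fraction · n)` (default decile). Ceiling is used so that every
subpopulation, however small, contributes at least one core variety; with
subpopulation sizes 78/105/58/20 this yields 8+11+6+2. No floor/ceiling
convention reproduces every published core-variety count exactly, so the
rule is explicit rather than fitted.

`matrix_correlation()` correlates two pairwise matrices over their
strictly-lower triangles (Pearson), dropping pairs with missing entries
and returning NA for constant matrices. The companion matrices are
allele-sharing distance — mean over comparable loci of (2 − shared
alleles)/2, where "shared" is the multiset intersection of the two
unordered genotypes — and its complement as similarity.

## The simulator

`simulate_population()`/`simulate_depths()` emulate the statistical shape
of a targeted-amplicon study panel; defaults (`sim_config()`) describe
the study conditions the package is aimed at: 261 inbred varieties in
four subpopulations of 78/105/58/20, 163 SNP loci on 7 chromosomes,
strong differentiation, kilobase-scale amplicon depths.

* **Structure.** Ancestral minor-allele frequencies are uniform on
  `maf_range` (default 0.1–0.5, assigned to REF or ALT at random);
  subpopulation frequencies follow the Balding–Nichols model
  Beta(p(1−F)/F, (1−p)(1−F)/F) with F = `fst_target` (default 0.4), so
  the across-subpopulation frequency variance is F·p(1−p) and F = 0
  collapses to panmixia.
* **Inbred genotypes.** A literal "heterozygous with fixed probability h"
  rule cannot preserve allele frequencies near fixation (the homozygote
  frequency would have to be clipped), and in testing it measurably
  deflated realized differentiation. Instead an **autozygosity model** is
  used: with probability 1 − 2·`residual_het` a locus is autozygous (one
  allele draw, doubled), otherwise Hardy–Weinberg (two draws). This
  preserves subpopulation frequencies exactly and gives heterozygosity
  4·`residual_het`·p(1−p), i.e. `residual_het` (default 0.15) is the het
  probability at a p = 0.5 locus. Residual heterozygosity is i.i.d.
  across loci; no linkage is simulated, because no downstream stage uses
  linkage.
* **Depths.** Total depth per variety × locus is negative-binomial with
  mean `mean_depth` (default 2000×) and size `depth_dispersion` (default
  1.5). The overdispersion is essential: a Poisson law cannot produce the
  ~50-fold depth spread seen in multiplex amplicon data, while size 1.5
  at mean 2000 places roughly 90% of records in the 100–5000× band.
  Reads split binomially between the two true alleles: p = 0.5 for
  heterozygotes, p = 1 − `error_rate` toward the true allele for
  homozygotes. The per-read error default 0.002 is a convention for
  Illumina-class data, recorded in the config, not an empirical claim.
  With probability `missing_rate` (default 0.02) a record's total depth
  is resampled uniformly below `min_major_depth`, forcing a missing call.
* **Reproducibility.** One seed fixes the whole stream
  (`simulate_depths` derives its own substream as seed + 1 so it is
  deterministic whether or not it follows a fresh
  `simulate_population`).

What the simulator does *not* emulate: read-level sequences and quality
scores, PCR duplicates, primer bias and amplicon-specific efficiency,
linkage disequilibrium, and population admixture. Passing recovery tests
therefore validates the calling/statistics machinery under the stated
model, not the wet-lab properties of any particular assay.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based internally and in VCF; BED export is 0-based
  half-open, tested both ways at positions 1 and chromosome length.
* Genotypes are unordered allele pairs everywhere (phase is never used);
  the canonical token sorts alleles lexically ("A/G", never "G/A"), and
  missing is `./.` on disk, NA in memory.
* Frequency vectors must sum to 1 within 1e-6; AMOVA percentage sums are
  exact to 1e-9 in tests.
* All-missing sites and loci raise errors naming the offender; empty
  depth maps yield missing calls with reason `no_data`; monomorphic
  panels make θ NA with a message rather than 0/0.
* Order invariance: permuting accessions, varieties or sites never
  changes verdicts, statistics, or (up to tie-broken ordering) selected
  marker sets.

## Scale of the validation suites

The test and acceptance suites size their simulations to exercise the
statistics at meaningful precision while staying quick on one CPU:
parameter-recovery runs use 4 subpopulations × 50 varieties × 500 loci
(θ recovery, ±0.05), 100 varieties × 200 loci at 1000× depth
(concordance ≥ 99.5%), and 50,000 records for missingness calibration
(±0.01); oracle-equivalence suites run the panel filter against a naive
per-site re-check on 1,000 synthetic sites with planted violations, and
the discrimination machinery against brute-force recounts on 30 × 50
matrices and exhaustive search on 12 × 15 instances.

## Known limitations

* Flank uniqueness is exact-match only; a near-match (one-mismatch)
  tolerance would be a stricter primer-specificity screen and is not
  implemented.
* The exhaustive core-set search guarantees minimality only within its
  feasibility bound; at realistic panel sizes the greedy set is an upper
  bound on the minimum.
* AMOVA missing-data handling is pairwise-complete without rescaling to
  the full locus count; with very uneven missingness patterns the SS
  contributions of sparse pairs are attenuated.
* The depth model draws records independently; real amplicon panels show
  correlated per-locus and per-sample effects, so simulated QC
  distributions are cleaner than real ones.
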