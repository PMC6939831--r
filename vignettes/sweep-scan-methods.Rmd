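---
title: "Methods: window-based sweep scans and life-history phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based sweep scans and life-history phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
library(dplyr)
```

sweepscan implements the population-genomic workflow used to separate
migratory from freshwater-resident individuals of a partially migratory
fish and to localize candidate genes under selection in the resident
group. This vignette is the package's own account of the models, the
tunable parameters, the numerical conventions, and what the synthetic
validation does and does not demonstrate.

## The statistical model

### Nucleotide diversity

For a variant site with $r$ observed reference alleles and $a$ observed
alternate alleles ($c = r + a$), the per-site diversity is the unbiased
probability that two alleles sampled without replacement differ:

$$\hat\pi_{\text{site}} = \frac{2ra}{c(c-1)}.$$

Window diversity is the sum of site values over the window's variant
sites divided by the **window length in base pairs**. Monomorphic and
unsequenced positions therefore contribute zero, and "per site" means
per base pair of the scanned genome, not per variant. This choice
matters: dividing by the number of variants instead changes the scale of
$\pi$ (and hence ROD) by orders of magnitude, and the per-bp convention
is what makes windows of equal physical size comparable. Sites where a
group has fewer than two observed alleles are skipped for that group.

### Fst

Window differentiation uses the Weir–Cockerham (1984) two-population
estimator. Per usable site, variance components $a$ (between
populations), $b$ (between individuals within populations) and $c$
(within individuals) are computed from each group's sample size, allele
frequency and observed heterozygosity; the window estimate is the ratio
of averages $\sum a / \sum (a + b + c)$. Ratio-of-averages is preferred
to averaging per-site ratios because single sites have wildly unstable
denominators. Window values can be slightly negative for
undifferentiated windows; they are reported unclamped (capped above at
1) so that empirical quantiles are well defined. A Hudson-style
estimator is available through `estimator = "hudson"` behind the same
interface. A site enters the Fst sums only when both groups have at
least one called genotype and the mean sample size exceeds one; skipped
sites are counted per window (`n_skipped_fst`).

### ROD

Reduction of diversity is
$$\mathrm{ROD} = 1 - \frac{\pi_{\text{freshwater}}}{\pi_{\text{migratory}}},$$
positive when the freshwater group has lost diversity relative to the
migratory group — the footprint expected of a selective sweep restricted
to the resident population. ROD is undefined
($\pi_{\text{migratory}} = 0$) in windows with no migratory variation;
such windows are reported as `NA` and can never be selected.

### Joint top-5% selection

Thresholds for Fst and ROD are the empirical 0.95 quantiles (linear
interpolation between order statistics, the "type 7" rule) computed over
*eligible* windows only — windows with at least `min_sites` variants —
and both thresholds come from the same window set. Selection is strict
(`fst > thr_fst` **and** `rod > thr_rod`), so with $n$ eligible windows
at most $\lceil 0.05 n \rceil + 1$ windows can exceed either threshold.
Adjacent selected windows merge into regions (`max_gap = 0` by default:
regions are exactly the union of selected windows), and genes overlap a
region with at least `min_overlap_bp = 1` base.

## Population grouping

Pairwise genetic distances are 1 − IBS: per pair, the mean over jointly
called sites of half the dosage difference, each pair normalized by its
own shared-site count (the "flat-missing" convention, matching PLINK).
The neighbor-joining tree is built by the classic Saitou–Nei
agglomeration with deterministic tie-breaking (lowest index pair on
exact $Q$ ties) and negative branch lengths clamped to zero with the
clamped deficit recorded. The two-group call removes the longest
internal edge and reads off the leaf bipartition, smaller side first;
the minority side is labelled freshwater because the resident fraction
of a partially migratory cohort is the minority. This operationalizes
what is usually a visual reading of the tree; a user-supplied grouping
always overrides the tree-derived one downstream.

## Candidate characterization

*Allele association.* Per site, a 2×2 table of group × allele counts is
tested with a two-sided Fisher exact test implemented by
point-probability ordering (all tables with the observed margins whose
probability is at most the observed table's, with $10^{-12}$ relative
slack for floating-point ties). Raw $p < 0.01$ drives the default flag;
Benjamini–Hochberg q-values are always reported alongside.

*Effect classification.* Variants are classified into
coding (synonymous / non-synonymous), intronic, upstream, downstream and
intergenic. Codons are reconstructed from the spliced CDS in transcript
orientation (reverse-complemented on the minus strand, phase from
cumulative CDS length) and translated with the standard nuclear code.
The upstream/downstream flank is 5,000 bp by default — a conventional
promoter-proximal window, configurable via `flank`. When several genes
apply, the most severe class wins (coding > intronic >
upstream/downstream > intergenic), ties resolved by the nearest gene.
Genes whose CDS length is not a multiple of 3 are excluded with a
warning; codons containing ambiguity bases exclude the variant.

*Enrichment.* Per term, the 2×2 candidate × term-membership table is
tested with a 1-df chi-square without continuity correction when all
expected counts are at least 5, and with the exact Fisher test
otherwise — the classic GOstat-style branch rule. Whether the original
analyses applied a continuity correction is not recoverable; the
uncorrected statistic is the GOstat default and is what the package
uses.

## Phenotype calls

*Otolith microchemistry.* Sr:Ca (×1000) thresholds follow the standard
reading: freshwater ≤ 3.0 < brackish ≤ 7.0 < seawater, with boundary
values falling to the lower class per the interval notation. A transect
is called migratory when, after 3-point median smoothing, it contains a
run of at least `min_run = 3` consecutive non-freshwater points.
"Constant" versus "alternating" coloring is thereby operationalized as a
run-length rule; the minimum run rejects isolated instrument spikes
while a genuine marine phase (many consecutive points) always passes.

*qPCR.* Relative expression follows 2^−ΔΔCt: per-sample
ΔCt = Ct(target) − Ct(reference), centered on the arithmetic mean ΔCt of
the calibrator group (equivalently, the geometric mean RQ of the
calibrator is exactly 1 — the standard convention). Group differences
use a pooled-variance Student t-test by default, with Welch available;
distributional pre-tests are out of scope. DEG flagging requires both
$p < 0.05$ and fold > 2, with the fold taken as the larger group mean
over the smaller and the t-test applied to $\log_2(x+1)$ values.

## The synthetic-data generator

The generator emulates the *structure* the analysis assumes, not the
demographic history that produced it:

- 85 migratory and 11 freshwater diploid samples (the study design's
  cohort split), two 500-kb chromosomes, one SNP per 200 bp in
  expectation, 3% missing genotypes;
- background differentiation via the Balding–Nichols model: each
  population's allele frequency is a Beta draw around the ancestral
  frequency ($p \sim U(0.05, 0.95)$) with drift parameter $F = 0.02$,
  giving $E[(p_1-p_2)^2] = 2Fp(1-p)$ — a closed form the tests check;
- one planted 25-kb sweep per chromosome in which the freshwater group
  gets strong drift ($F = 0.6$) and its minor-allele frequency is
  multiplied by 0.1, jointly producing the low-$\pi$/high-Fst/high-ROD
  signature the scan is designed to detect.

What it does **not** emulate: linkage disequilibrium and recombination
(sites are independent), hitchhiking dynamics, allele-frequency spectra
shaped by real demography, sequencing error, or call-rate structure
correlated with genotype. Passing the recovery tests therefore shows the
estimators and the thresholding logic are correct on data satisfying
their assumptions — it does not certify power on real resequencing
data, where LD makes neighboring windows dependent and background
selection can mimic sweeps.

Generator defaults are study conditions, not tuning knobs: the 85/11
split and the sweep geometry are fixed by the design being emulated, and
the drift values were chosen once as a realistic weak background
divergence versus a strong local sweep. The qPCR generator's baseline
ΔCt of 8 cycles is a typical offset between a moderately expressed
target and the 18S reference; the planted effect of 2 cycles corresponds
to a four-fold expression increase.

## Numerical choices and edge cases

- Window tiling starts at position 1 and steps by `step` (default:
  `step = window_size`, i.e. non-overlapping 5-kb windows — the
  configuration under which the scan's results are interpreted; a
  sliding step is available). The final short window of each chromosome
  is kept and flagged `partial`.
- `min_sites = 3` suppresses single-SNP windows whose ratio statistics
  are noise; ineligible windows are reported but excluded from
  thresholding.
- Variant filters follow the stated rules exactly: missing fraction
  strictly above 0.10 removes a site; minor-allele frequency at least
  0.10 (computed from called genotypes) keeps it.
- Half-called genotypes (`./1`) are treated as missing: the estimators
  need an unambiguous diploid dosage.
- Coordinates are 1-based inclusive everywhere inside the package; BED
  I/O converts to 0-based half-open at the boundary, and chromosome
  names are matched by exact string equality.
- Newick output is deterministic (children ordered by smallest contained
  leaf label) with 6-decimal branch lengths by default; a `digits`
  argument serves applications needing higher precision round-trips.
- Fisher ties are absorbed with $10^{-12}$ relative slack; degenerate
  margins return $p = 1$ by convention.
- Degenerate t-tests (zero variance in both groups) return $p = 1$ on
  equal means and $p = 0$ on unequal means, flagged `degenerate`.

## Validation scale

The test suite validates the estimators against independent oracles
(allele-pair enumeration for $\pi$, a scalar textbook implementation for
Weir–Cockerham Fst, full fixed-margin enumeration for Fisher, path
distances and the ape reference for neighbor joining) and the full
pipeline on the default synthetic study: 20 replicate seeds of the
85+11 × two-500-kb-chromosome design for sweep recovery and grouping
recovery, 50 seeds per pattern for otolith calls. These sizes were
chosen as the smallest replication at which the Monte-Carlo acceptance
bounds are stable.

## Worked example

```{r example}
cfg <- sim_config(seed = 20)
sim <- simulate_dataset(cfg)
filtered <- filter_variants(sim$dataset)
windows <- scan_windows(filtered, sim$grouping,
                        chrom_lengths = cfg$chrom_lengths)
sweeps <- call_sweeps(windows, ann = simulate_annotation(cfg))
glance(sweeps)
tidy(sweeps)

tree <- neighbor_joining(ibs_distance(filtered))
table(tree_grouping(tree)$group)
```

Both planted sweeps are recovered as merged regions containing the truth
intervals, and the tree splits the cohort into the true 11/85 groups.

## Known limitations

- Independent-site simulation overstates the independence of window
  statistics; empirical thresholds on real data should be interpreted
  with LD-aware caution.
- The NJ two-group split assumes the deepest divergence is the
  migratory/resident one; admixed or multi-population cohorts need a
  user-supplied grouping.
- The effect classifier handles SNVs against single-transcript gene
  models; splice-site, UTR and multi-isoform annotation are out of
  scope.
- Term maps are taken as given (no ontology graph propagation).
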