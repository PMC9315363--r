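---
title: "Methods: diversity, structure, and EigenGWAS selection scans in selfing crop panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, structure, and EigenGWAS selection scans in selfing crop panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigensel)
library(dplyr)
```

`eigensel` implements the population-genomic workflow commonly applied to
selfing crop diversity panels genotyped with sparse genome-wide SNPs
(e.g. genotyping-by-sequencing in hexaploid wheat): marker QC, diversity
statistics, windowed nucleotide diversity and Tajima's D, relatedness and
structure, F~ST~ and AMOVA differentiation, linkage-disequilibrium decay,
and an EigenGWAS scan for selection signatures. This vignette documents
the statistical models, the defaults and why they were chosen, the
numerical decisions, and what the bundled simulator does and does not
emulate.

## The genotype model

All statistics operate on a samples x variants dosage matrix with values
0/1/2 (copies of the ALT allele) or missing. Markers are named
`chrom_pos` (e.g. `1A_555961328`) and kept sorted by chromosome and
position. Subpopulation labels ride along with the samples; samples
without a label are `UNASSIGNED`.

Marker QC retains variants passing, in order: missing-call fraction at
most 0.50; mapped to one of the 21 wheat chromosomes `1A`..`7D`; minor
allele frequency strictly above 0.05; observed heterozygosity strictly
below 0.20 — the filter settings routinely used for inbred wheat GBS
panels. Attribution to the *first* failing rule makes the QC report
additive: removed + retained equals the input count. MAF and
heterozygosity are computed on non-missing calls only; imputation is
deliberately out of scope (panels of this type are usually imputed
upstream), so each statistic states its own missing-data rule instead.

## Diversity statistics

For ALT frequency $p$ and $q = 1 - p$:

* gene diversity (expected heterozygosity): $GD = 1 - p^2 - q^2$,
  maximal 0.5;
* polymorphism information content (biallelic Botstein form):
  $PIC = 1 - p^2 - q^2 - 2p^2q^2$, maximal 0.375 at $p = 0.5$ and
  $\approx 0.09$ at the 0.05 MAF floor — which is why MAF-filtered
  panels report PIC ranges of exactly [0.09, 0.375];
* observed heterozygosity: heterozygote fraction among non-missing
  calls.

Substitutions are tabulated in the six unordered classes A/G, C/T
(transitions) and A/T, A/C, G/T, C/G (transversions), deliberately *not*
collapsing strand complements (A/C and G/T stay distinct), matching how
GBS SNP tables are conventionally reported.

Chromosome summary tables report marker density as markers per Mb of the
chromosome length, where length is the maximum observed SNP position
(such tables sometimes carry an inverted "Mb/marker" column label; the
value here is always markers per Mb). Genome-level and whole-genome
density is the *unweighted mean* of the member chromosomes' densities —
this is the convention that reproduces reported genome-row values
exactly, rather than total count over total length.

## Windowed nucleotide diversity and Tajima's D

Per biallelic site with $n$ called haplotypes and $j$ ALT copies, the
mean pairwise difference is $\pi_{site} = 2j(n-j)/(n(n-1))$. Windows of
1,000 kb advanced by 100 kb tile each chromosome from position 1 (the
final partial window is kept; every reported window spans the nominal
size). Window $\pi$ is the sum of site $\pi$ divided by the window
length in bp — the VCFtools `--window-pi` convention, which at ~1 SNP/Mb
marker density produces the $10^{-7}$-order values typical of GBS
panels. Empty windows report $\pi = 0$ and an undefined Tajima's D.

Tajima's D uses the standard 1989 constants
($a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$) with
$D = (\pi_{sum} - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}$, where $S$ is the
number of SNPs in the window and $n$ is twice the rounded mean
non-missing sample count over those SNPs. $S = 0$ or a non-positive
variance term yields an undefined value (`NA`, never 0).

## Relatedness, PCA, distance, trees

* **VanRaden kinship** (method 1):
  $K = (X - 2P)(X - 2P)^\top / (2\sum_k p_k(1-p_k))$ with missing
  dosages at their expectation $2p_k$. Negative entries are clamped to
  zero *in the reported kinship only* — the usual convention for
  relative-kinship heatmaps — never in the GRM used downstream.
* **Standardized GRM**:
  $A_{ij} = \frac1M \sum_k \frac{(x_{ik}-2p_k)(x_{jk}-2p_k)}{2p_k(1-p_k)}$,
  unclamped. With sample-estimated frequencies every column of the
  standardized matrix sums to zero, so $\sum_{ij} A_{ij} = 0$ exactly
  and the mean off-diagonal is $-\overline{\mathrm{diag}}/(n-1)$. In a
  selfing panel the diagonal sits near $1 + F_{IS} \approx 2$, which is
  why effective sample sizes computed from $-1/\bar g$ come out near
  $n/2$ rather than $n$.
* **PCA** is the eigendecomposition of the standardized GRM (not a raw
  covariance), so the eigenvectors are identical to the EigenGWAS
  responses and one decomposition serves both the structure plots and
  the scan. Signs are fixed by making each vector's largest-magnitude
  loading positive — reproducible across BLAS implementations.
* **Rogers' distance** between individuals averages
  $\sqrt{\tfrac12\sum_a (p_a - q_a)^2}$ over loci called in both
  individuals (complete-case per pair); for biallelic dosages this is
  $|x_i - x_j|/2$. Identical genotypes give 0, opposite homozygotes 1.
* **Neighbor joining** uses the Saitou–Nei algorithm via `ape::nj`;
  negative branch lengths (possible on non-additive inputs) are clamped
  to zero with a message. On additive matrices the tree reproduces the
  input path lengths to numerical precision.

Panel-level diagnostics from the GRM: mean off-diagonal relatedness
$\bar g$, effective sample size $n_e = -1/\bar g$, and effective number
of genome segments $m_e = 1/\mathrm{var}(g_{ij})$.

## Differentiation

Per-SNP F~ST~ uses the Weir–Cockerham (1984) moment estimator with the
observed-heterozygosity term: variance components $a$ (among
populations), $b$ (among individuals within), $c$ (within individuals),
and $\theta = a/(a+b+c)$, complete-case per SNP. Per-SNP estimates are
reported raw (negative values kept) for Miami-plot tracks; multi-locus
and pairwise values use the ratio of sums $\sum a / \sum(a+b+c)$ — the
standard choice, more stable than averaging per-locus ratios — with
permutation p-values from shuffling group labels.

AMOVA decomposes allele-level squared differences (each diploid
contributes two allele values per locus; the squared molecular distance
is the number of allele differences, Arlequin's default for SNPs) into
among-subpopulation, among-individual, and within-individual components
with df $(G-1, N-G, N)$. Unphased heterozygotes contribute 1/2 to the
within-individual sum of squares per locus. Variance components follow
the standard mean-square equations with
$n_c = (N - \sum n_g^2/N)/(G-1)$; permutation p-values shuffle whole
individuals across subpopulations.

## LD decay

Pairwise LD is the squared Pearson correlation of dosage vectors over
shared non-missing samples (the genotype-composite $r^2$; no haplotype
phasing). The scan enumerates intra-chromosomal pairs up to 50 Mb by
default — decay distances in wheat panels are of order 5–10 Mb, so 50 Mb
spans the curve tail while bounding pair counts.

The decay curve is the Hill–Weir drift-plus-sampling expectation in
Remington's parameterisation with $C = \beta d$:
$$E[r^2] = \frac{10+C}{(2+C)(11+C)}
\left[1 + \frac{(3+C)(12+12C+C^2)}{n(2+C)(11+C)}\right],$$
fitted by Levenberg–Marquardt least squares on the raw $(d, r^2)$ pairs,
with the starting $\beta$ set so $C = 1$ at the median distance (the fit
is deterministic; no seed involved). The decay distance is the root of
fitted $E[r^2] = 0.1$ found by bisection on the monotone curve, flagged
"not reached" if the curve stays on one side of the threshold over ten
times the observed range. On noiseless curve data the fit recovers
$\beta$ to well under 1%.

## EigenGWAS selection scan

For each of the top eigenvectors EV1..EV10 of the standardized GRM, each
SNP is tested with the ordinary least-squares regression
$EV_i = \mu + \beta x_i + \varepsilon$ over its non-missing calls, and
the Wald statistic $\chi^2 = (\beta/se)^2$ referred to $\chi^2_1$ (at
panel sizes of hundreds the difference from the $t$ reference is
negligible, and the $\chi^2$ form is what the genomic-control machinery
expects). Eigenvectors are used at unit norm, so $\beta$'s scale is
arbitrary but the p-values are scale-invariant.

Drift inflates these statistics genome-wide, so genomic control divides
every statistic by $\lambda_{GC} = \mathrm{median}(\chi^2)/0.4549364$
(per eigenvector) before recomputing upper-tail p-values ($P_{GC}$).
Two calibration facts are worth knowing:

* Even with *no* population structure, $\lambda_{GC}$ for an
  eigenvector estimated from the same genotypes sits near the
  Marchenko–Pastur bound $(1+\sqrt{n/m})^2$ (about 1.4 at $n = 200$,
  $m = 5000$) — the eigenvector partially overfits the very SNPs being
  tested. $\lambda_{GC} \approx 1$ holds for the *permutation* null
  (eigenvector shuffled across samples), which is exactly the null the
  permutation threshold simulates.
* The permutation threshold reshuffles the chosen EV, reruns the whole
  scan per permutation, applies a *within-permutation* $\lambda_{GC}$,
  records the minimum $P_{GC}$, and reports $-\log_{10}$ of the 5th
  percentile of those minima — so by construction ~5% of null scans beat
  it. A fixed cutoff of $-\log_{10}(P_{GC}) \ge 5.0$ is the default
  declaration rule; both are available.

Significant SNPs within ±5 Mb of each other (per EV and chromosome) are
merged transitively into candidate selection regions spanning
[min − 5 Mb (floored at 0), max + 5 Mb], reported in Mb to two decimals.
The representative SNP is the region's largest $-\log_{10}(P_{GC})$
(ties break to the smaller position) and carries its per-SNP F~ST~.
Regions are kept separate per EV; a cross-EV unique-region count
collapses overlapping intervals per chromosome.

## The simulator: what it emulates, and what it does not

`sim_genotypes()` generates panels with the statistical structure this
analysis assumes, so the full pipeline is testable without external
data. Defaults emulate a three-subpopulation selfing wheat panel:
145/128/149 accessions; 10,000 biallelic SNPs on the 21 wheat
chromosomes with subgenome shares A/B/D = 40/49/11% (split within a
subgenome by chromosome length, positions sorted-uniform); ancestral
frequencies Uniform(0.05, 0.95), matching a MAF-filtered panel's
support; transition-heavy REF/ALT pairs; drift F = 0.06 (the middle of
the weak 0.05–0.075 pairwise F~ST~ range typical of such panels); 20
selected loci with an extra frequency shift of 0.5; heterozygote
retention 0.05 (mean observed heterozygosity ~0.02, as in inbred
wheat); 2% missing calls, completely at random.

Model details and the reasoning behind the genuinely open choices:

* **Subpopulation frequencies** are Balding–Nichols:
  $p_k \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, mean $p$ and
  variance $Fp(1-p)$, so pairwise Weir–Cockerham F~ST~ recovers $F$
  to within ±0.01 at moderate panel sizes.
* **Selfing**: genotype classes follow the partial-inbreeding law
  $P(\mathrm{het}) = s\,2pq$,
  $P(\mathrm{hom}) = p^2 + (1-s)pq$ per side (i.e. $F_{IS} = 1-s$).
  This deflates the heterozygote class by the single factor $s$ while
  conserving the allele frequency — a redistribution proportional to
  $p^2$/$q^2$ would not conserve it.
* **Selected loci** shift subpopulation 1's frequency by `selected_delta`
  *across* 0.5 (upward when below, downward otherwise, clipped to
  [0.01, 0.99]). Crossing guarantees the realised extra divergence is
  close to `delta` at every selected locus; shifting toward the nearer
  boundary would clip low- and high-frequency loci to a negligible
  shift and make "selected" loci undetectable by construction.
* **Missingness** is MCAR — no informative-missingness model is
  warranted for imputed GBS panels.
* The generator is a pure function of its config (including the seed):
  identical configs give byte-identical VCF output.

What it does **not** emulate: linkage — variants are independent given
the subpopulation frequencies, so LD hovers at the $1/n$ sampling floor
and LD-decay fits on simulated data do not produce megabase decay
curves (the decay fitter is validated on noiseless Hill–Weir curves
instead). It also has no admixture, no kinship families within
subpopulations, and no site-frequency-spectrum realism beyond the
uniform ancestral draw; windowed $\pi$/Tajima's D on simulated data
validate bookkeeping against brute-force oracles, not coalescent
expectations. Passing tests therefore demonstrate correct statistical
machinery on data with known truth, not realism of any particular wheat
panel.

A note on detection power: with $n = 200$, $m = 5000$, drift F = 0.05
and a 0.5 frequency shift, a selected locus' dosage $r^2$ with EV1 is
capped near 0.25 by the within-subpopulation variance, giving Wald
statistics around 60; after genomic control ($\lambda \approx 6.5$ under
that structure) this sits near $-\log_{10}(P_{GC}) \approx 3$, below the
5.0 declaration cutoff. Recovering most such loci at that cutoff
requires either larger panels, stronger shifts (near-fixation apart), or
a relaxed cutoff — a real limitation of fixed-threshold selection scans
in small structured panels, reproduced faithfully here.

## Problem sizes used in the test suite

Simulation-based tests run at a few hundred samples by a few thousand
SNPs (up to 200 x 5,000 for the calibration and recovery suites, 10
seeds for calibration checks, 3 for recovery), sizes at which the
Balding–Nichols recovery tolerances (±0.01 on F~ST~), the ±3-SE
frequency/heterozygosity bands, and the permutation binomial bands are
comfortably informative while the whole suite stays fast. Exact-value
checks (OLS oracle equivalence at $10^{-12}$, NJ additivity at
$10^{-9}$, window oracles) use small fixtures built in code.
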