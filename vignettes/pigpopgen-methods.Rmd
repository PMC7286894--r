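---
title: "Methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigpopgen)
```

`pigpopgen` reimplements the downstream population-genomic analyses used in
whole-genome resequencing studies of divergent domestic pig populations:
windowed diversity and differentiation, LD structure and haplotype blocks,
X-chromosome haplotype classification, a haplotype-sharing introgression
scan, population-structure inference, and group-contrast variant scans.
Because such studies' raw data are typically not depositable, the package
ships a seeded generator that produces datasets with planted, recoverable
ground truth; every analysis here is exercised against that truth.

## The synthetic-data generator

**Allele-frequency model.** Each site has an ancestral frequency $p$ and a
per-group frequency drawn from the Balding–Nichols distribution
$q_g \sim \mathrm{Beta}\!\big(p\,\tfrac{1-F_g}{F_g},\,(1-p)\tfrac{1-F_g}{F_g}\big)$,
so that $E[q_g]=p$ and $\mathrm{Var}[q_g]=F_g\,p(1-p)$. Haplotypes are
drawn independently per site given $q_g$; diploids are phased by
construction. Under this model the expected Hudson $F_{ST}$ between groups
$A$ and $B$ is approximately $(F_A+F_B)/2$, which is how the default drift
coefficients were fixed once, up front: $F=0.06$ for the two Chinese
domestic subpopulations and the wild group and $F=0.10$ for the European
group, so that the simulated CnSouth–CnNorth differentiation sits near
0.06 and Europe–wild near 0.08 — the scale reported for these populations.
The default design is 31 animals (CnSouth 11, CnNorth 9, Europe 5,
wild 6), mirroring a realistic panel of this kind.

**Frequency spectrum.** The default draws $p$ uniformly on $(0,1)$, which
is convenient for planting contrasts but is not the neutral standing
spectrum; with `spectrum = "neutral"` the generator instead draws $p$ with
density $\propto 1/p$ truncated below at `spectrum_min` (default 0.0025).
Only under the neutral spectrum do $\theta_\pi$ and $\theta_w$ agree in
expectation, and the package's neutrality checks use that mode.

**Linkage.** Sites are unlinked except where structure is explicitly
planted. Linked haplotypes for LD analyses come from a separate
copy-with-mutation process (`simulate_ld_haplotypes`): two complementary
founder haplotypes segregate at frequency 1/2 and each simulated haplotype
follows a hidden template chain that switches founders between adjacent
sites with probability $(1-(1-2s)^d)/2$ for inter-site distance $d$. Then
$r^2$ decays as $(1-2s)^{2d}$, halving near $\ln 2/(4s)$ — an
interpretable single-knob decay model.

**Introgression tracts.** A planted tract emulates introgression of a
haplotype that segregates widely in the donor group — the regime in which
haplotype-sharing scans have power. Inside the tract the donor group is
made to carry a shared haplotype (`donor_ibd`, default 1: effectively
fixed in the donor group, as after a strong sweep or breed formation), and
the recipient's diploid genotype is replaced by a copy of a randomly
chosen donor individual's genotype, so recipient-vs-donor sharing is
exactly 1 at every tract site. With unlinked Balding–Nichols sites alone
(no donor homogenization, `donor_ibd = 0`), cross-group sharing in a tract
plateaus near $(1 + (n_D-1)\bar S_D)/n_D \approx 0.86$ at $F = 0.2$ and
the 0.8 ratio threshold is rarely crossed; the IBD-region emulation is
what makes tract windows behave like the real phenomenon.

**X chromosome.** Males carry one X haplotype, coded homozygous. The
planted X LD block holds two background allele vectors: N (the reference
pattern) and S (opposite at a fraction `informative_frac`, default 0.9, of
block markers). Samples are assigned pure-N, pure-S or a mosaic switching
at specified breakpoints; the block is written homozygous for the assigned
haplotype, reflecting a low-recombination region where haplotypes travel
intact. An optional per-marker flip probability adds genotyping noise.

**What the generator does not emulate:** coalescent genealogies and
realistic site-frequency correlations, recombination maps,
sequencing-error and depth models, and genuine multi-breed substructure
within groups. Passing recovery tests on these data therefore shows the
estimators are implemented correctly and have power in the planted regime,
not that they would behave identically on real resequencing data.

## Estimators

**Diversity.** $\theta_\pi = \sum_\text{sites} 2\hat p(1-\hat p)\,n/(n-1)$
(equal to the mean over all haplotype pairs of per-site differences, the
identity the tests assert), and $\theta_w = \sum 1/a_{n}$ over segregating
sites with $a_n=\sum_{i<n} 1/i$; both are reported per Kb of window
length, with per-site $n$ reduced at missing data. Windows are fixed,
non-overlapping, anchored at position 1; the width is a parameter
(default 100 Kb).

**Differentiation.** Hudson's ratio-of-averages estimator
$F_{ST} = 1 - \pi_\text{within}/\pi_\text{between}$, with the unbiased
within-group estimator and sums taken over sites before the ratio. The
ratio-of-averages form is stable for windows with few sites and small,
unbalanced groups; this choice (over Weir–Cockerham) is deliberate and
documented here because the downstream comparisons (0.06 vs 0.08 scale)
are between estimates computed the same way.

**p-distance.** Diploid allele-sharing distance
$d_{ij} = \mathrm{mean}(|g_i-g_j|)/2$ over pairwise-complete sites —
equivalently $1-\mathrm{IBS}/2$ with het–het identical genotypes counting
as full sharing. The neighbor-joining implementation is the standard
Saitou–Nei agglomeration; negative branch lengths are clamped to zero
with the excess moved to the sister branch so path lengths are preserved.
Topology recovery is verified against path-length matrices of random
trees and cross-checked against an independent NJ implementation.

**PCA.** Dosages are imputed to the column mean, monomorphic columns
dropped, columns centered and scaled by $\sqrt{p(1-p)}$, and the sample
covariance eigendecomposed. Coordinates are eigenvectors; signs are
arbitrary, and tests treat them as such.

**Admixture.** The unsupervised binomial mixture
$g_{il} \sim \mathrm{Binom}(2, \sum_k q_{ik} f_{kl})$ fitted by classical
EM with 5 seeded random restarts (the reference implementations do not
publish an exact update schedule, so plain EM was chosen); the
log-likelihood is non-decreasing by construction and asserted in tests.
Missing genotypes contribute nothing. Component frequencies are kept in
$[10^{-6}, 1-10^{-6}]$ to keep the likelihood finite; a degenerate (empty)
component triggers a re-jittered restart.

## LD and haplotype blocks

Pairwise LD is computed from phased haplotypes: $D$, $r^2$ (identical to
the squared Pearson correlation of the two indicator vectors, asserted
exactly), and $|D'|$ with a likelihood-based confidence interval: the
multinomial likelihood of the four haplotype counts is profiled over
$|D'|$ on a grid of step 0.001 with allele frequencies held at their MLEs,
normalized, and read off at the 2.5% and 97.5% quantiles. Block calling
follows the confidence-interval rules: a pair is *strong LD* when
$CI_{low} \ge 0.70$ and $CI_{high} \ge 0.98$, *strong recombination* when
$CI_{high} < 0.90$; a candidate block is a marker run whose outermost pair
is strong LD with at least 95% of informative pairs strong LD, and
candidates are accepted greedily longest-first without overlap. The caller
is verified against an exhaustive span enumeration on small instances.
Marker thinning (default 3 Kb) is a greedy scan; whether blocks are called
on thinned or all markers is the caller's choice — both are supported, and
the bundled workflow thins first.

LD decay bins all intra-contig pairs within 500 Kb into 5 Kb distance
bins and reports the first distance, interpolated linearly between bin
midpoints, where mean $r^2$ falls to half its maximum; when the half
maximum is never reached the distance is `NA` by design.

EM phasing enumerates haplotypes compatible with each genotype (windows
capped at 12 markers), splits multi-heterozygotes across compatible
ordered pairs in proportion to current frequency products, and
renormalizes; with no ambiguous genotypes this reduces to direct counting,
and a lone double-heterozygote ties at posterior 0.5.

## X-haplotype classification

Block haplotypes are recoded 0/1 against the reference alleles. Consensus
backgrounds N and S are per-marker majorities over declared anchor sets
(southern samples anchor S; European plus wild samples anchor N).
Classification uses only informative markers (where the consensuses
differ): a haplotype is N or S when its match fraction reaches the purity
threshold (default 0.95 — the separation between real mosaics and noise is
not standardized anywhere, so this is the package's choice, exposed as a
parameter), recombinant when a dynamic-programming segmentation into N/S
runs fits with every segment at the purity threshold, and unclassified
otherwise.

The segmentation DP charges one unit per mismatch and `switch_penalty`
(default 3) per background switch, so up to two isolated genotyping flips
cannot create a spurious breakpoint; cost ties prefer the switch, so an
exactly balanced mosaic is still segmented, and the final state ties break
toward the background matching the last marker. Each breakpoint is
reported as the open interval between the last informative marker of the
left segment and the first informative marker of the right segment;
under 2% genotype noise at ~120 markers this interval contains the true
breakpoint in about 95% of simulations, with misses dominated by flips
immediately adjacent to the true switch. Per-haplotype intervals are
clustered by overlap; each cluster's maximal range is its union, and the
conserved core is the segment between the first cluster's right edge and
the second cluster's left edge, measured as a plain coordinate difference.

## Introgression scan

Sharing between two animals at a SNP is genotype-level IBS/2 (identical
genotypes 1, one shared allele 0.5, none 0) — the source analyses do not
define the score numerically, so this is the package's documented choice.
For each focal pig and 100 Kb window with at least 10 SNPs and at least 3
genotyped partners in each group, $R = S_\text{own}/S_\text{cross}$ and
windows with $R < 0.8$ are flagged; the orientation (own over cross, flag
low) is a config switch and is logged. Ineligible windows are skipped, not
emitted. Flagged windows merge into segments under strict adjacency
(gap tolerance configurable). High-sharing regions report, per window, the
maximum over other-group pigs of the fraction of *identically shared*
SNPs: counting single shared alleles saturates near 1 between unrelated
animals and would flag most of the genome under the null, so the
shared-SNP definition defaults to full genotype identity
(`share_score_min = 1`), with the looser reading available as a parameter.
The window likelihood-ratio statistic is a plain binomial composite
likelihood, $\Lambda = 2(\ln L_A - \ln L_B)$ with group frequencies
clamped to $[1/(2n+2), 1-1/(2n+2)]$; the exact construction of the
original method is not published, so this form is a documented stand-in
whose sign behaviour (favoring the true source in ≥95% of diverged
windows) is what the tests pin down.

## Differential scans

Near-fixation contrasts use strict inequalities (>0.80 in one group,
<0.20 in the other, either orientation), on alternate-allele frequencies
with missing genotypes excluded from denominators. Group tests are
classical Pearson $\chi^2$ (no continuity correction) on 2×2
allele-count tables — allele counts rather than carrier counts, consistent
with an expected-count coverage filter of at least 5 genotyped samples per
group. Multiplicity is handled by Benjamini–Hochberg or Bonferroni;
structural variants are scored as per-sample presence/absence, tested per
SV, BH-adjusted, kept at adjusted $P<0.01$ and ranked, truncating to the
top K (default 100).

## Numerical conventions

Coordinates are 1-based inclusive internally (BED converts on read/write);
segment lengths are plain coordinate differences $|b-a|$, because that is
how printed spans of this kind (40.09 Mb, 10.40 Mb, 382 bp, 487 bp) are
derived; percentages and Mb figures round half-away-from-zero to two
decimals, which reproduces every printed proportion exactly. Multi-allelic
VCF records split into tagged biallelic records with a warning. All
randomness flows from explicit seeds through one generator wrapper; no
global RNG state leaks, and equal seeds give byte-identical VCFs and
pipeline summaries.

## Problem sizes

The bundled workflow and test suite run at desk scale by choice: 31
samples, 4,000–10,000 sites over two contigs (5 Mb + 3 Mb), 2 Mb and 1 Mb
planted tracts, ~120-marker breakpoint simulations, 100 random trees for
topology recovery, and ≤15-marker instances for the exhaustive block
oracle. These sizes keep every recovery property measurable with tight
Monte-Carlo error while the whole suite completes in a couple of minutes.

## Known limitations

Star-shaped group divergence (no hierarchical population history), no
linkage outside planted structure, haplotype-level phasing assumed correct
in the X and LD analyses, the binomial LRT stand-in above, and a
presence/absence SV model without dosage. The genome-wide values reported
for the real populations (e.g. $\theta_w$/Kb of 2.01–2.80, the 8 observed
X haplotypes) are properties of the non-deposited data and are out of
reach by design; the package reproduces the *arithmetic* of the printed
derived quantities and the *behaviour* of the estimators under known
truth.
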