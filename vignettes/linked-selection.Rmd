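---
title: "Linked selection, recombination, and neutral diversity: models and methods"
author: "linksel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked selection, recombination, and neutral diversity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Natural selection does not only change the frequency of the mutations it
acts on; by linkage it also removes variation at nearby neutral sites.
Purifying selection steadily purges haplotypes carrying deleterious
mutations (background selection), and beneficial mutations drag linked
neutral alleles to fixation (selective sweeps, hitchhiking). Both effects
are stronger where recombination is rare, because a larger stretch of
chromosome shares the fate of each selected site. The observable
footprints are correlations across the genome: neutral diversity and the
allele-frequency spectrum versus the local recombination rate, and
neutral diversity versus the local density of functional substitutions.

`linksel` implements the full analysis path needed to measure those
footprints in windowed genome data and to interpret them with explicit
population-genetic models:

1. **Window summaries** -- mask-aware per-window statistics on 100 kb
   windows (SNP count `S`, covered bases, interspecies difference count
   `d`, divergence-normalized diversity `S_norm`, average minor allele
   frequency, Tajima's D, GC and genic content).
2. **Low-coverage allele-frequency estimation** -- a method-of-moments
   estimator refined by maximum likelihood, operating directly on pooled
   read counts.
3. **Nei-Gojobori divergence accounting** -- synonymous / nonsynonymous
   site and difference counts per window.
4. **Correlation machinery** -- Spearman and partial Spearman
   correlations, permutation tests for genic vs non-genic contrasts,
   bootstrap confidence intervals, percentile subsetting, display
   binning.
5. **A forward Wright-Fisher simulator** of the same 100 kb windows under
   background selection, sweeps, recombination hotspots, and a
   two-species (human-chimp style) demography, measured by the same
   pipeline as the data.
6. **Synthetic-data generators** for every input, with known ground
   truth, so the whole pipeline is testable without external downloads.

## Window summaries and filters

Windows are non-overlapping 100 kb tiles; tiles within 10 Mb of an
annotated centromere, telomere, or chromosome end are dropped, because
both the genetic map and the alignment degrade there. Within a window,
repeat-masked bases and cross-species conserved elements are excluded
from both the SNP and the divergence accounting -- conserved elements are
the sites most likely under direct selection, and the point of the
analysis is variation at putatively *neutral* sites. The one deliberate
exception: conserved elements are *not* masked when counting coding
(synonymous/nonsynonymous) divergence, where selected sites are the
object of interest.

The central diversity measure is SNP density normalized by divergence,

$$ S_{\mathrm{norm}} = \frac{S / \mathrm{covered}}{d / \mathrm{aligned}}, $$

which cancels local mutation-rate variation to first order. The source
description of this quantity divides SNPs per covered base by the number
of differences; because the bases covered by sequencing and the bases
aligned to the outgroup differ, we normalize both numerator and
denominator to rates (the literal raw-count denominator is available via
`normalize_aligned = FALSE`). Windows with zero covered bases or zero
differences have no defined `S_norm` and are flagged and excluded from
correlation inputs.

Genic windows are those at least half covered by a transcript; non-genic
windows have no transcript overlap at all. Windows in between belong to
neither class -- the two published definitions leave a gap, and we keep
it. The small-panel heterozygosity filter (`cgs_het_filter`) drops
windows with at least 10 SNPs averaging more than 3 heterozygous
genotypes out of 6, the signature of collapsed segmental duplications.

A "within 2 bp of an indel" filter is interpreted as distance < 2
removed, distance >= 2 retained; the boundary choice is configurable
(`indel_distance`).

## Low-coverage allele frequencies

With ~2,000 individuals at well under 1x each, genotypes are hopeless but
population allele frequencies are not. At every site with at least 100
good reads, a random subset of exactly 100 reads (uniform, without
replacement, preserving individual of origin) equalizes information
across the genome. The second-most common base is the minor allele (ties
broken A < C < G < T and flagged).

Under a uniform miscall model -- a read is wrong with probability $e$ and
then equally likely any other base -- the expected minor-base read
fraction is $f = q(1-e) + (1-q)e/3$, giving the moments estimator

$$ \hat q_{\mathrm{MoM}} = \frac{f - e/3}{1 - 4e/3}, $$

clamped to $[0, \tfrac12]$. The exact closed form of the published
moments estimator is not printed in our source material; this is the
unique unbiased inversion under the same error model the rest of the
package uses, and it reduces to $f$ at $e = 0$.

Sites passing a 1% MoM prefilter get a maximum-likelihood refinement:
with $k_i$ minor-base reads out of $n_i$ for individual $i$,

$$ L(q) = \prod_i \sum_{g \in \{0,1,2\}}
   \binom{n_i}{k_i} p_g^{k_i} (1-p_g)^{n_i-k_i} \,
   \Pr(g \mid q), $$

with Hardy-Weinberg genotype priors and per-read minor-base
probabilities $p_0 = e/3$, $p_1 = \tfrac12(1-e) + \tfrac12 e/3$,
$p_2 = 1-e$. The likelihood is unimodal in $q$; we maximize with R's
`optimize` (golden-section with parabolic refinement, tolerance $10^{-6}$)
and verify against an exhaustive $10^{-5}$ grid in the test suite. Sites
with ML estimate strictly above 5% are SNPs: at 100x pooled depth, rarer
variants are not reliably separable from sequencing error.

One estimator subtlety: the folded estimate $\min(\hat q, 1-\hat q)$ is
bounded by $\tfrac12$, so at a true frequency of 0.5 folding necessarily
biases it downward. The estimator-consistency checks therefore evaluate
the unfolded frequency of the *known* minor allele (`fold = FALSE`,
`minor_base =` truth); applied analyses, which have no truth, use the
folded value.

## Nei-Gojobori accounting

Synonymous and nonsynonymous *sites* are fractions: position $p$ of a
codon contributes to $L_S$ the share of its three possible single-base
changes that preserve the amino acid, and the complement to $L_N$
($L_N + L_S = 3$ per fully eligible codon, to numerical precision).
Sites are counted from the focal species' sequence only, not averaged
across species. Each observed cross-species difference is classified by
substituting the outgroup base into the focal codon with the other two
positions held fixed -- per-site classification, not the pathway
averaging of the full evolutionary-distance method; a codon with two
differences contributes two independently classified differences.
Changes to or from stop codons count as nonsynonymous; codons containing
an internal stop are skipped with a warning; ambiguous bases are
skipped. When gene models overlap, the longest is kept. No multiple-hit
correction is applied; $d_N = D_N / L_N$ is a raw proportion, as in the
analysis this package supports.

## Correlation machinery

Spearman correlations use average ranks; p-values use the
t-approximation. Partial rank correlations rank-transform every column
and read the partial correlation off the precision matrix of the rank
correlation matrix, $\rho_{xy \cdot Z} = -\Omega_{xy} /
\sqrt{\Omega_{xx}\Omega_{yy}}$; with a single control this equals the
textbook first-order formula, which the tests assert to machine
precision. Complete-case analysis throughout; collinear controls raise
an error naming the offenders.

The genic vs non-genic contrast uses a permutation test that reassigns
windows to the two groups keeping group sizes fixed, one-sided in the
direction genic > non-genic. We report the add-one convention
$p = (\#\{\Delta^\ast \ge \Delta\} + 1)/(B+1)$ by default so p is never
exactly zero; the plain proportion is available by flag. No
multiple-testing correction is applied anywhere -- raw thresholds are
reported, deliberately. Bootstrap intervals are percentile intervals
over window resamples; a resample where the statistic is undefined is
redrawn and counted.

## The forward simulator

### Window anatomy

Each simulated window is 100 kb: a gene of 8 exons (1.5 kb) and 7
introns (5 kb) totalling 47 kb, split at its midpoint -- the middle of
the central intron -- around a 53 kb neutral intergenic block. Only the
exon/intron counts and the 53 kb block are dictated by the design being
reproduced; the individual exon and intron sizes are not, so defaults
were chosen to make the arithmetic close (8 x 1.5 + 7 x 5 + 53 = 100 kb)
and are fully configurable. The reading frame runs across exons in
genomic order; first and second codon positions are nonsynonymous
targets, third positions are treated as synonymous and neutral. This
positional treatment of coding selection mirrors how simulated $d_N$ is
measured: the rate of cross-species differences at first and second
codon positions.

### Demography and rescaling

An ancestral population of $N = 20{,}000$ diploids splits 200,000
generations ago (5 Myr at 25 yr/gen) into two lineages of 10,000 each (a
two-fold contraction at the split). The focal lineage passes through a
recent bottleneck; the published parameterization of that bottleneck is
cited to external work and not restated, so the shipped block
(contraction to $N/10$ for 500 generations, ending 1,000 generations
ago) is an explicit placeholder and fully configurable. Mutation is
Jukes-Cantor symmetric at $\mu = 2.5\times10^{-8}$ per bp per
generation.

Everything is run rescaled by a factor $\lambda$ (default 40: the
ancestral population is simulated with 500 diploids): sizes and times
divided by $\lambda$, mutation and recombination rates and selection
coefficients multiplied by it, preserving $\theta = 4N\mu$, the
population recombination rate, and $2Ns$. Burn-in is $10 \times 2N$
rescaled generations before the split. A property test checks that
$\lambda = 40$ and $\lambda = 80$ runs of the same model are
statistically indistinguishable (KS test on window summaries); this is
also the justification for running some of the heavier acceptance
batches at $\lambda = 60$.

### Recombination hotspots

Hotspots are 2 kb wide with exponential inter-hotspot gaps of mean
20 kb. Hotspots carry exactly 80% of the window's genetic map: hotspot
$i$ receives mass $0.8 x_i$ with $x \sim$ Dirichlet$(1,\ldots,1)$ over
the $k$ hotspots, and the background segments share the remaining 20%
via an independent symmetric Dirichlet. The published description fixes
the Dirichlet dimension but not its concentration; we read it as the
symmetric simplex draw (concentration 1), configurable. If no hotspot
fits, all mass is background. Crossover positions are drawn from the
resulting piecewise-constant density; the expected crossover count per
meiosis is the window's map length in Morgans (rescaled).

### Selection models

A `selection_model` mixes three window regimes: *positive* windows
(probability `p_plus`) where a fraction of nonsynonymous mutations
(default 0.5%) are beneficial at coefficient `s_pos` and the rest are
neutral; *negative* windows (probability `p_minus`) where nonsynonymous
mutations draw deleterious effects from a gamma distribution and a
fraction of intronic mutations are weakly deleterious; and neutral
windows. The gamma DFE parameters are cited to external estimates and
not printed in our source, so the defaults (shape 0.184, mean 0.03) are
external-source placeholders, configurable like everything else. Preset
constructors cover the models used in the acceptance analyses:
`model_neutral()`, `model_bgs_nonsyn()`, `model_bgs_intronic()` (25% of
intronic sites at $s = 2.5\times10^{-4}$, the intermediate strength with
the strongest frequency-spectrum effect), `model_sweep()` (0.5% of
nonsynonymous mutations at $s = 0.625\%$), and `model_mixed()` (5%
positive windows, 95% negative windows with 50% of intronic sites at
$s = 7.5\times10^{-5}$).

Fitness is multiplicative across sites, $1 + hs$ per heterozygous and
$1 + s$ per homozygous mutation, clamped at zero, with additive dominance
$h = 0.5$ by default; selection acts on viability in a soft-selection
(fixed-$N$) Wright-Fisher population, so extinction is impossible.
Window regimes are assigned independently of the recombination-rate bin.

### Engine design

The engine (C++ via Rcpp, as is usual for forward simulators) represents
a haplotype as a position-sorted vector of mutation entries and shares
haplotypes copy-on-write between generations: a gamete with neither
crossover nor mutation is a pointer copy. Mutations live at continuous
(infinite-sites) positions. Fixed mutations are detected by periodic
frequency sweeps (`purge_every` generations, default 25, bounding the
resolution of recorded fixation times); their removal from haplotypes is
batched, which is exact because a fixed mutation can never be lost again
and multiplies every individual's fitness equally. Each replicate has
its own seeded generator (xorshift128+), so replicates are reproducible
independently of scheduling. Bookkeeping (generated / segregating /
fixed / lost per population) is exported and asserted in tests.

### Measurement

Simulated windows are measured exactly like data windows, restricted to
the neutral intergenic block. In `population-MAF` mode (the low-coverage
analogue), `S` counts intergenic SNPs with population MAF strictly above
5%; in `sample-6` mode (the small-panel analogue), all SNPs segregating
in the sampled individuals count. Divergence compares one individual per
species: opposite homozygotes count 1, identical homozygotes 0, and any
configuration with a heterozygote counts one half. The amount of
intergenic sequence analyzed can be drawn from an empirical coverage
distribution; with none supplied the full 53 kb is used (the acceptance
analyses use the full block -- no real coverage distribution ships with
the package, and using the whole block is the lower-noise choice).

## Synthetic data

The generators exist so that every downstream estimator can be tested
against planted truth: pileups with known population frequencies and a
uniform miscall error model; window feature tables from a Gaussian
copula (chosen because its rank correlation has the closed form
$\rho_S = \tfrac{6}{\pi}\arcsin(r/2)$, making the generator itself
verifiable); Bernoulli-block masks whose realized masked fraction is
binomial by construction; and stop-free coding alignments with exact
planted synonymous/nonsynonymous difference counts, one difference per
codon. What these emulate -- and what they do not: read counts have no
mapping bias, no base-quality structure, and no correlated errors;
window features are monotone transforms of a joint Gaussian, with none
of the long-range autocorrelation of real genomes; masks are
independent blocks rather than clustered repeats. Passing tests
demonstrate correctness of the estimators under the stated models, not
robustness to artifacts those models exclude.

## Problem sizes in the shipped checks

The test suite and the acceptance analyses are sized for a single
desktop CPU; these are the package's chosen study sizes, stated here so
their resolving power is explicit:

* Hotspot-map geometry: 10,000 maps (spacing check pooled over ~10^5
  gaps).
* Estimator consistency: 520 sites (130 per frequency in
  {0.1, 0.2, 0.3, 0.5}) at 100x pooled depth over 2,000 individuals.
* Neutral calibration: 150 burn-in-only replicates of a rescaled
  4,000-diploid population at high recombination; >10^4 pooled SFS
  entries.
* Model comparison: 110 windows per model for the neutral vs
  background-selection ordering (rescaling 60), 130 windows for the
  sweep-only model and 70 windows of the 5%/95% mixture (both at the
  canonical rescaling 40, where the beneficial coefficient stays safely
  inside the diffusion regime).

At these sizes the *direction* of every effect is resolved, and the
mixture model's recent-sweep window fraction is estimated with a
binomial confidence interval a few percent wide. What a few hundred
windows cannot do is turn a correlation difference of ~0.1 into a
p-value below 1% -- that resolution needs thousands of windows per
model, hours of CPU; the ordering test is therefore the one acceptance
check whose significance threshold may not be reached at desk scale,
and it is asserted at its stated threshold regardless rather than
silently weakened.

## Known limitations

* Windows are simulated independently; linkage to selected sites outside
  the window is absent, which understates background selection for a
  given density of selected sites (the model parameterizations being
  reproduced compensate with generous selected-site fractions, and say
  so).
* Biased gene conversion is a disabled hook (`linksel` exposes no
  parameterization for it because the one being reproduced is not
  printed); conclusions about GC-related confounding must come from the
  correlation controls, not the simulator.
* The coding classifier holds non-focal codon positions at the focal
  alleles; multi-hit codons are classified per site, which can differ
  from pathway-averaging methods on rare codons.
* Real annotation pipelines disagree with any classifier on splice-edge
  cases; such sites are expected, rare, and not modeled.
* The low-coverage likelihood treats reads as independent given
  genotype, with a single scalar error rate by default; base-quality
  recalibration and correlated errors are out of scope.
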