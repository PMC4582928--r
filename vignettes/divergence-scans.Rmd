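---
title: "Divergence scans across a hybrid-zone continuum: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence scans across a hybrid-zone continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

# The problem

Pairs of *Heliconius erato* races and incipient species meet and hybridize
across narrow contact zones while remaining phenotypically distinct, most
visibly at the red wing-pattern locus whose 65-kb regulatory interval near
*optix* controls the postman/rayed switch. A divergence scan asks where in
the genome such taxa differ: relative divergence (F_ST-type statistics)
localizes allele-frequency differentiation; absolute divergence (d_xy)
measures expected sequence difference between the taxa; and contrasting the
selected interval against unlinked "background" intervals, and against
comparisons at increasing reproductive isolation, separates locus-specific
selection (divergence hitchhiking) from genome-wide buildup (genomic
hitchhiking). This package implements that entire analysis as composable,
tested operations, plus a generator of synthetic datasets with known
divergence structure so the whole chain can be validated end to end.

# Estimators

## Weir–Cockerham variance components

`site_components()` implements the Weir & Cockerham (1984) random-effects
model for diploids with r = 2 populations. For each allele at a site, with
per-population sample sizes $n_i$ (genotyped diploids only), allele
frequencies $p_i$, observed heterozygote frequencies $h_i$,
$\bar n = \tfrac{1}{2}(n_1+n_2)$, $n_c = 2n_1n_2/(n_1+n_2)$, weighted mean
frequency $\bar p$, frequency variance $s^2$ and mean heterozygosity
$\bar h$:

$$a = \frac{\bar n}{n_c}\Big(s^2 - \frac{1}{\bar n - 1}\big(\bar p(1-\bar p)
  - \tfrac12 s^2 - \tfrac14 \bar h\big)\Big)$$
$$b = \frac{\bar n}{\bar n - 1}\Big(\bar p(1-\bar p) - \tfrac12 s^2
  - \frac{2\bar n - 1}{4\bar n}\,\bar h\Big), \qquad c = \tfrac12 \bar h.$$

Components are summed over the site's alleles, so multiallelic records are
handled without splitting (splitting would change allele frequencies).
Key numerical choices:

- **Negative components are kept.** $a$ and $b$ are unbiased component
  estimators and can be negative site by site; truncating them at zero
  would bias the ratio of sums upward.
- **Ratio of sums, never mean of ratios.** The multi-site estimate is
  $\hat\theta = \sum_s a_s / \sum_s (a+b+c)_s$ (`multilocus_theta()`), and
  groups of comparisons pool all sites of all member pairs into one ratio
  (`combine_group()`). Monomorphic sites contribute 0/0 and leave
  $\hat\theta$ unchanged; a mean of per-site ratios would weight sites
  equally regardless of information and does not agree with the pooled
  estimator (the package tests assert the distinction numerically).
- **Definedness.** A site needs ≥1 genotyped diploid in each population
  *and* more than two in total: with exactly one per population the
  within-population mean square ($\bar n - 1$ in the denominator) does not
  exist. This is marginally narrower than "≥1 per population" and is
  unreachable anyway behind the 75% filter at the study's sample sizes.

## Absolute divergence

`site_dxy()` computes $d_{xy} = 1 - \sum_i x_i y_i$ from sample allele
frequencies of the two populations — the per-site probability that one
allele drawn from each population differs. It is combined as an arithmetic
mean over positions (`mean_dxy()`), and for groups as the mean across
comparisons of per-comparison means. Unlike $\hat\theta$, the mean *is*
diluted by monomorphic positions; whether the average runs over all
filtered positions or only variant ones therefore matters. The default is
all filtered positions (d_xy is a per-genomic-position quantity and
monomorphic positions legitimately contribute 0); callers can subset to
variant sites with `remove_invariant_sites()` if they need the other
convention.

# Filters and conventions

- **Missingness** (`filter_pair_missingness()`): a site is kept iff the
  genotyped fraction is ≥ 0.75 in *each* population, computed per diploid
  individual — a genotype is either called or not; half-calls (`./0`) and
  haploid calls are collapsed to missing at read time. The boundary is
  inclusive: 3 of 4 genotyped passes.
- **Coordinates**: 1-based inclusive everywhere in the package, matching
  VCF and the R/Bioconductor convention. (An all-0-based-internal design
  was considered and rejected: every user-visible structure in this
  ecosystem is 1-based, and a single convention end to end removes the
  boundary translations that cause off-by-ones. BED-like output writes
  `start0 = start − 1`.)
- **SNP-only**: indels, spanning deletions and symbolic alleles are dropped
  at read time; QUAL/FILTER are not re-examined (variant quality control is
  upstream of this analysis).

# Windows, baseline, decay

`make_windows()` emits 15-kb windows every 5 kb, anchored at position 1 of
the contig and never truncated — a contig shorter than one window yields
none, so the count is exactly `floor((L − size)/step) + 1`. Per window,
$\hat\theta$ is the ratio of sums over contained sites and coverage is the
fraction of window positions carrying estimates; windows under 20% coverage
are emitted with `NA` estimates so the scan grid stays regular.

The **coverage denominator** deserves a note. Against resequencing-dense
input — where nearly every genomic position, invariant ones included, is
genotyped and filtered — "positions in the window" naturally means window
size in bp, and that is the default. The synthetic generator, however,
emits variant sites only, at a realistic SNP density (~0.05/bp); no
SNP-only input can reach 20% of window bp. `window_estimates(...,
denominator = "records")` measures coverage against the positions present
in the input instead, which is the appropriate reading for SNP-only data
and what the synthetic recovery checks use. The 20% bp boundary itself is
tested exactly (3,000 of 15,000 passes; 2,999 fails).

The **baseline** is the pooled ratio-of-sums over ~350 kb of intervals
unlinked to the color-pattern locus, with a percentile bootstrap over sites
(1000 replicates, 95% level, deterministic under a seed). Resampling
individual positions pooled across the unlinked intervals is the minimal
reading of "bootstrap replicates" and treats sites as exchangeable; linked
sites are positively correlated, so these CIs are, if anything, slightly
narrow. Degenerate input (all sites identical) collapses the CI to the
point estimate rather than erroring.

**Decay**: physical distance from the centre of the functional interval
(midpoint, floored to an integer bp) is converted at the genome-average
rate 1430 cM / 400 Mb = 3.575 × 10⁻⁶ cM/bp and binned in half-open 0.01-cM
bins (a site exactly at an edge joins the upper bin); per-bin $\hat\theta$
again pools components, so the bins sum back to the region estimate
exactly. Upstream and downstream sites pool by unsigned distance — the
symmetric-hitchhiking reading. Loess smoothing (span 0.3, degree 2, tricube
weights, direct surface so polynomial inputs reproduce exactly) is applied
for presentation only and never feeds any estimate; the smoothing
parameters are package choices, since none are prescribed for this
analysis.

# The synthetic generator

`simulate_pair()` draws, per site: an ancestral frequency
$p \sim U(0.05, 0.95)$; population frequencies from the Balding–Nichols
Beta distribution $\mathrm{Beta}\!\big(p\tfrac{1-F}{F},
(1-p)\tfrac{1-F}{F}\big)$ (Dirichlet for the optional triallelic mode),
with $F(x) = F_{bg} + (F_{pk} - F_{bg})e^{-d(x)/\lambda}$ a peak decaying
with recombination distance from a causative site; Hardy–Weinberg
genotypes within populations; and independent per-genotype missingness.
The generating truth (ancestral and realized frequencies, per-site target
F) is returned alongside, and `expected_theta()` converts it into the
estimand the ratio-of-sums estimator converges to: the
$p(1-p)$-weighted average of $F(x)$ — which, because ancestral frequency is
drawn independently of position, equals the plain average of the profile
(computed by quadrature when no truth is supplied).

Defaults state the emulated world once: 10 diploids per population (the
study sampled 4–14 per taxon), 50,000 sites on a 1-Mb contig (≈0.05/bp;
the empirical 65-kb functional interval held 5,399 SNPs ≈ 0.08/bp),
baseline $F_{bg} = 0.02$ against a $F_{pk} = 0.9$ peak with
$\lambda = 0.5$ cM — a sharp peak over a near-zero background, the
situation the within-species scans show — and 10% missingness.

What the generator does *not* emulate, and green tests therefore do not
establish: linkage disequilibrium between sites (sites are independent, so
bootstrap CIs face no autocorrelation), realistic site-frequency spectra
(every simulated site is ancestrally polymorphic; real data are mostly
invariant), selection dynamics, migration, or more than two populations.
It validates estimator correctness, combining rules, bookkeeping and
recovery of a known divergence landscape — not demographic realism.

# Reproducibility

One top-level seed drives everything; stochastic stages derive child seeds
through a fixed multiplicative map (`child_seed()`), so a pipeline rerun
reproduces every analysis table byte for byte, and the full configuration
is echoed into the output directory (`config_echo.json`) for provenance.

# Known limitations

- $d_{xy}$ is frequency-based per site; haplotype/sequence-based absolute
  divergence from phased data is out of scope, as are within-population
  diversity ($\pi$) and other summary statistics.
- The recombination model is a single genome-wide constant; real maps vary
  along chromosomes, so cM distances near the locus are approximate.
- The site bootstrap ignores linkage (see above); a block bootstrap would
  widen CIs on strongly autocorrelated data.
- Window anchoring at the contig start is a convention; anchoring at
  interval starts would shift window boundaries by up to one step.
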