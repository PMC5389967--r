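---
title: "Population genomics of LINE insertion polymorphisms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population genomics of LINE insertion polymorphisms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`linepopgen` analyses presence/absence polymorphism of LINE (long
interspersed nuclear element) insertions alongside SNPs in two populations
of the green anole, *Anolis carolinensis*: the East Florida population and
the roughly ten-fold smaller Gulf-Atlantic population, sampled as 7 and 6
diploid genomes respectively. The scientific question is whether insertion
frequencies are shaped by purifying selection, which the package addresses
by (i) summarising the frequency spectra of SNPs and of each LINE
clade/family, (ii) fitting a neutral demographic model to the SNP joint
site frequency spectrum, and (iii) asking whether the insertion statistics
could have arisen under that neutral demography.

This vignette documents the models, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Data model and filtering

Variants live in a `genotype_table`: biallelic sites by diploid samples,
with 0/1/2 dosage of the alternate (for SNPs) or insertion (for MEIs)
allele, 1-based VCF point positions throughout, and a two-population
sample map. MEI records additionally carry the family and clade labels and
the predicted insertion length (taken from the `SVLEN` INFO key, falling
back to a `MEILEN` key; the writer emits both).

`filter_snps()` applies the quality recipe used to build the SNP set:
per-genotype depth >= 6 and genotype quality >= 20, site quality >= 20,
indels and multi-allelic records removed, and no missing genotypes
tolerated (exposed as `min_fraction_called = 1` rather than a double
negative). Filters are site-wise: one failing genotype removes the whole
site. `thin_snps()` then keeps every 1,000th SNP (genome-wide in sorted
order by default; per-chromosome restarting is available, since either
reading of "every 1,000 SNPs" is defensible) to limit linkage
disequilibrium between retained markers.

Per-family MEI callsets are unioned by `merge_mei_callsets()`, which drops
loci lacking coverage in any sample or flagged low quality. Calls of
*different* families within 50 bp are treated as one physical insertion:
`dedup_nearby()` clusters records by single linkage (chained windows) and
keeps the longest record, breaking ties by lowest position. Single linkage
is the conservative reading of "within 50 bp of each other"; with a
window this small the distinction rarely matters in practice.

## Descriptive statistics

For MEIs the insertion allele is treated as derived -- the reference
genome lacks the insertion -- so derived-allele spectra are available
without an outgroup. SNP spectra are offered folded (minor allele), the
convention used for the SNP panels of the published figures, as well as
unfolded for simulation comparisons.

* **Mean pairwise difference** is the per-locus average of
  2k(n-k)/(n(n-1)), averaged over loci. The printed per-group values
  (~0.1--0.4) identify this as a per-locus quantity, not a per-genome sum.
* **Tajima's D** uses the standard constants derived from the sample size;
  all components (a1 ... e2, S, pi) are returned for audit. D is an error,
  not zero, when no site segregates in the focal population.
* **Weir--Cockerham F_ST** is computed per site from the variance
  components (a, b, c) with observed heterozygosity. The headline value is
  the arithmetic mean of defined per-site estimates (matching a "mean
  F_ST" column); the ratio-of-sums (weighted) estimate is also reported.
  Negative per-site values are retained by default (`clamp = TRUE`
  floors them), matching common tool behaviour.
* **Allele sharing** partitions variant loci into private to either
  population, fixed differences, and shared.
* The **exact signed-rank test** drops zero differences, uses midranks for
  ties, and computes the exact two-sided p over all 2^n sign assignments
  for n <= 25 tie-free pairs (via the `signrank` distribution, which is
  that enumeration), with a tie-corrected normal approximation otherwise.

An element is **complete** when its predicted length is at least 90% of
its family's maximum length (boundary inclusive), otherwise truncated.
The source of "maximum size for its family" is not recoverable, so the
package ships per-clade maxima derived from the published full-length
ranges (L1 6.8 kb, L2 6.3 kb, CR1 5.8 kb, R4 3.8 kb, RTE 3.9 kb) and
falls back to the observed per-family maximum for unconfigured families.

## The demographic model

The two populations are modelled by an isolation-with-migration (IM)
coalescent: an ancestral population (diploid size ~1.17M) splits
`T_split` generations ago into Florida and Gulf-Atlantic; each daughter
has one instantaneous size change (Florida expanded from ~751k to ~3.32M
around 802k generations ago; Gulf contracted from ~1.42M to ~236k around
274k generations ago); migration is constant between split and present.
The split is fixed at 1.34 million generations, converting the published
divergence time of 1.34 Mya at one generation per year -- the generation
time is an explicit assumption surfaced here, not an estimate.

Three conventions deserve emphasis because silent transposition is easy:

* all sizes are **diploid individuals** (the source table is labelled
  "diploid population size"), and pairwise coalescence happens at rate
  1/(2N);
* migration rates are **backward** per-lineage probabilities: `m21`, the
  rate at which a Gulf lineage traces into Florida, encodes the
  forward-labelled "Gulf from Florida" rate (3.94e-7), and `m12` the
  "Florida from Gulf" rate (3.38e-7);
* time is generations before present.

`anole_im_model()` returns this fitted model; `anole_model_ci()` the 95%
confidence ranges per parameter. Encoding ambiguities (haploid vs diploid
size units, rate direction) were resolved by checking that the model
reproduces the published SNP summary statistics: simulating 20,000
unlinked SNPs for 7 + 6 diploids gives multi-locus Tajima's D near -0.6
in Florida and +0.4 in Gulf-Atlantic and a mean per-site F_ST near 0.12,
the values reported for the real SNP set. A haploid reading or a
transposed migration matrix does not reproduce these signs and
magnitudes, so no unit switch is exposed.

## Simulation machinery and its numerics

The structured coalescent is simulated backward in time per site
(unlinked sites are independent genealogies; there is no recombination
machinery). Two mutation modes serve different purposes:

* `fixed_sites`: exactly one mutation placed uniformly on the realised
  total branch length. Every site is polymorphic in the pooled sample,
  matching the ascertainment of called SNPs and MEIs. Note a subtlety:
  the marginal class probabilities are E[L_k / L_tot], which differs
  slightly from the unconditional E[L_k]/E[L_tot] = (1/k)/a1 -- the
  ratio weighting slightly favours rare classes (for n = 14 the induced
  multi-locus D is about -0.1). This is a property of conditioning on
  single-mutation sites, shared by the data being emulated, not a
  simulator defect.
* `theta_poisson`: Poisson(theta/(4 N_ref) x branch length) mutations per
  site. In this unconditioned mode the class expectations are exactly
  theta/k, which is what the calibration tests check (Watterson's E[S],
  chi-square on the spectrum at low theta where sites are effectively
  independent, Tajima's D centred at zero).

All randomness flows through R's RNG, so `set.seed()` makes every
simulation, fit and report reproducible bit for bit.

## Demographic fitting

`fit_demography()` maximises the multinomial composite log-likelihood of
the observed joint SFS (polymorphic entries only; the two monomorphic
corners are excluded). Expected entry probabilities are themselves
estimated by simulation, so the optimiser is built for noisy objectives:

* parameters are searched on the log scale (sizes, times and rates are
  positive and span decades) by coordinate-wise multiplicative proposals
  with a step that shrinks from 2x to 1.15x over cycles;
* the per-evaluation simulation budget grows linearly over cycles
  (2,000 to 10,000 sites in the desk preset; the published protocol of 40
  cycles, 50,000 to 250,000 simulations and 100 replicates is available
  as `fit_schedule("published")`);
* within a cycle every candidate is evaluated with **common random
  numbers** (one shared substream), so candidate comparisons are not
  swamped by simulation noise;
* expected probabilities of zero at occupied entries are floored at
  1/(10 x simulated sites) -- a standard composite-likelihood
  stabilisation -- and the flooring is counted and reported;
* the split time is held fixed by default, as in the original estimation;
  it can be freed for reduced models.

Replicates restart from random points in the bounds; the best final
composite likelihood wins, and estimates pinned at a bound are flagged
rather than hidden. Search bounds are not stated in the source material;
sensible defaults are the published confidence ranges widened ten-fold.

Confidence intervals come from a parametric bootstrap: pseudo-observed
joint spectra are simulated under the fitted model with the observed
number of SNPs, refitted, and the 2.5/97.5 percentiles taken per
parameter (150 pseudo-datasets at full scale). The PCA goodness-of-fit
check simulates spectra with parameters drawn uniformly from the CI
ranges, summarises them by principal components, and projects the
observed spectrum; "inside the cloud" is judged by the 95% Mahalanobis
ellipse on PC1--PC2, a deterministic, convex stand-in for a hull-based
95% region.

## Neutrality tests

`family_null()` builds the null distribution of a statistic (multi-locus
Tajima's D, mean per-site F_ST, or pi) by repeated simulation: each of
the 5,000 full-scale simulations draws one parameter vector uniformly
from the 95% CI ranges (the sampling distribution is not stated in the
source; uniform is the least-informative reading), then simulates exactly
the observed number of unlinked polymorphic loci for the family under
test. Conditioning on the family's locus count makes the null
family-specific. p-values use the add-one rule (r + 1)/(N + 1), which
cannot return zero from a finite simulation. Tajima's D and F_ST are
tested in the lower tail by default -- purifying selection predicts an
excess of rare variants and reduced differentiation -- with a two-sided
option. A non-parametric alternative, `snp_bootstrap_null()`, draws
contiguous runs of 100--500 SNPs along chromosomes and recomputes D.

## The synthetic-data generator

`generate_snp_dataset()` and `generate_mei_dataset()` produce complete
input bundles (VCF, per-family MEI VCFs, population map) so the entire
pipeline runs and is tested without any external download. They emulate:

* neutral SNP joint spectra under the fitted IM demography (7 + 6
  diploids by default);
* purifying selection on insertions, via rejection sampling against the
  Wright--Fisher diffusion sojourn density for scaled coefficient gamma
  -- acceptance weight (1 - exp(-gamma(1-q))) / ((1-q)(1 - exp(-gamma)))
  relative to the neutral 1/q, so gamma = 0 reproduces the coalescent
  frequencies exactly and negative gamma down-weights common variants.
  Selection enters only through this frequency distortion, not through
  genealogy shape -- adequate for frequency-based statistics, and
  explicitly a modelling choice;
* clade-specific truncation: uniform-plus-full-length for R4 and RTE-1
  (truncation anywhere along the element), linearly decreasing length
  density for CR1 and L2 (truncation probability falling with distance
  from the 3' end), and a bimodal early-or-complete shape for L1, with
  complete-element fractions calibrated to the observed 41%, 62%, 9%, 7%
  and 43%;
* filter-clean quality fields, with a "dirty" mode that injects
  sub-threshold records to exercise the filters, and an option to place
  loci in 50 bp pairs to exercise deduplication.

They do **not** emulate read-level evidence (split/discordant reads),
genotyping error, reference bias, linkage between sites, or transposition
bursts. Passing tests therefore validate the statistical machinery under
the stated model, not the upstream calling pipeline on real sequence
data.

## Problem sizes and known limitations

The package's default problem sizes are chosen for interactive, single-
workstation use: 20,000 unlinked SNPs reproduce the simulated SNP summary
statistics to well within their Monte-Carlo spread; neutrality-test
calibration uses hundreds of trials against nulls of 99--999 simulations;
the desk fit preset (10 cycles, 2,000--10,000 simulated sites, a few
replicates) recovers a reduced four-parameter model from a 50,000-site
spectrum within tens of percent. The full published schedules remain
available as presets where a cluster-scale rerun is wanted.

Limitations worth keeping in mind: the published per-group tables are not
reproducible from synthetic data (they summarise the real resequencing
data, which is not shipped); composite likelihood treats sites as
independent, so likelihood differences are not chi-square calibrated;
migration rates are weakly identified from spectra of this size, and the
bootstrap intervals for them are wide; and the R4 complete/truncated
locus counts printed in two source tables disagree (712 vs 1,017 complete
elements) -- the fixtures carry both tables as printed and the package
takes no side.
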