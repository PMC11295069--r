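---
title: "Droplet-microfluidic screening analytics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Droplet-microfluidic screening analytics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropevo)
```

## The screening problem

Directed evolution of a whole microorganism toward a material-production
phenotype — here, a cellulose-overproducing *Komagataeibacter* — runs in four
stages: UV mutagenesis of a cell suspension, single-cell encapsulation in
monodisperse water-in-oil droplets, incubation so each cell's cellulose
deposit builds up a dye-bound fluorescence signal, and fluorescence-activated
droplet sorting (FADS) that pulls the brightest droplets for colony recovery.
`dropevo` implements the desk-side analytics of every stage, plus a stochastic
simulator that replaces the wet-lab steps so that the full campaign can be run
and studied in silico.

## Poisson encapsulation design

Cell loading into droplets is Poisson: the probability of `k` cells in a
droplet at loading density $\lambda$ (mean cells per droplet) is
$p(k,\lambda) = \lambda^k e^{-\lambda}/k!$. Screens operate at low
$\lambda$ so that cell-laden droplets almost surely hold a single genome,
which is what couples genotype to phenotype. At the standard operating point
$\lambda = 0.1$:

```{r}
occupancy_fractions(0.1)
```

`concentration_to_lambda()` converts a feedstock concentration to $\lambda$
through the spherical droplet volume; 49 µm droplets need about 1.6 million
CFU/mL for $\lambda \approx 0.1$. The droplet is treated as an undeformed
sphere; deformation in channels is ignored. Both the single-cell fraction
(9.0% at $\lambda = 0.1$) and the overall occupancy (9.5%) are reported,
since design targets are quoted both ways. Reported percentages round half-up
to one decimal.

## The detector signal model

Every droplet carries fluorescein adjusted to a baseline voltage on the
detector (0.1 V in screening runs, 0.05 V in sorting runs). The cellulose
channel of an occupied droplet reads

$$V = V_\mathrm{base} + s \cdot t \sum_i r_i + \epsilon,$$

with $r_i$ the occupants' production rates (fluorescence-units per hour),
$t$ the incubation time (hours), and $\epsilon$ Gaussian noise. The scale
$s$ (`volts_per_rate_hour`, default 0.012 V per unit-hour) is the one free
calibration constant: absolute detector units are arbitrary, so it is fixed
such that a native cell (rate 1 by convention, 24 h incubation) sits at
0.388 V over the 0.1 V screening baseline — the native strain's normalized
middle-component mean, used as the calibration anchor throughout.

Defaults the data do not pin down, chosen once:

* `signal_sd = 0.05` V — within-strain spread of occupied-droplet signals.
  Published histograms show clearly separated baseline and cellulose peaks
  but no component SDs; 0.05 V keeps the peaks separated by >3 SD at the
  anchor geometry, consistent with those histograms.
* `baseline_sd = 0.01` V — detector noise on the fluorescein floor.
* neutral-mutant production rates are log-normal around the native rate
  (relative SD `neutral_sd = 0.1`): non-negative and right-skewed, the shape
  one sees in droplet fluorescence histograms. The log-normal is
  mean-preserving, so a neutral library averages the native rate exactly.

## Mutant libraries and the dose–survival curve

`generate_library()` draws each mutagenized cell's fate independently:
survival with the probability given by the dose–survival curve (default
tabulated at the quantified doses: 98% at 0.5 mJ/cm², 17% at 10 mJ/cm², 0 at
100 mJ/cm², log-linear interpolation in between, linear into the zero
endpoint), then a `beneficial_fraction` (default 1%) of survivors receive a
multiplicative production boost (`beneficial_effect`, default 1.6 — the scale
of the improvement seen in evolved overproducers). Genotypes follow a minimal
descriptive model tied to the deletion arithmetic: lethal variants carry a
frameshift deletion, beneficial ones a 12-bp in-frame deletion (removing 4
codons, as `apply_inframe_deletion()` computes), neutral mutants a single
substitution.

The UV dose acts only through the survival curve and the (dose-independent)
beneficial fraction; photoproduct chemistry and dose-dependent mutation
spectra are out of scope.

## Synthetic micrographs and quantification

`generate_droplet_image()` renders a sum-projected confocal-like frame:
non-overlapping disks (rejection-sampled placement with a bounded retry
budget, mirroring a monolayer in the incubation vial) of near-uniform
brightness `background_level`, with occupied droplets adding a total
deposited dye intensity proportional to occupancy, spread uniformly over the
disk, plus additive Gaussian pixel noise. Diameters are Gaussian with CV
0.02 by default — droplet generation is highly monodisperse, but the exact
polydispersity-index convention varies, so the CV is an explicit parameter.
The renderer is deliberately idealized: no point-spread function, no
z-structure, no intra-droplet texture. Passing detection tests on these
images therefore demonstrates the correctness of the measurement chain, not
robustness to real optics.

`detect_droplets()` offers two detectors. The default thresholds the frame
(Otsu) and labels connected components, which is exact on monolayer images
where droplets do not touch; a gradient-voting circular Hough transform with
non-maximum suppression is provided for frames with touching or partially
merged rims. Coordinates are 0-based `(x = column, y = row)`; a pixel belongs
to a disk when its center lies within the radius (inclusive). Droplets
touching the frame edge (optionally grown by `edge_margin`) are flagged and
excluded from measurement.

Occupancy is called against the Day-0 maximum: a droplet is occupied when its
measured fluorescence strictly exceeds the brightest value seen before any
cellulose could form. Both the integrated total and the area-normalized mean
are available as the comparison statistic. The total is the default, but the
mean is preferable when droplet sizes vary: an empty droplet's *total*
scales with its area, so with nonzero diameter CV the Day-0 maximum on totals
is set by droplet size rather than dye, while the mean is size-invariant.
The package's own end-to-end occupancy checks use the mean statistic for this
reason.

## Gating and sort statistics

Gating is a strict inequality: a droplet is sorted when its signal is
*higher than* the threshold, so ties stay in the waste stream.
`threshold_for_top_fraction()` inverts the gate prospectively using the lower
empirical (type-1) quantile of occupied-droplet signals — the conservative
choice whose sorted count never exceeds the target count — and re-gating at
the derived threshold reproduces the target within one droplet.
`sort_statistics()` is the retrospective direction: exact ratio arithmetic
for a recorded sort (e.g. 500 sorted of 430,000 droplets / 40,000 cell-laden
is 0.12% of all and 1.25% of occupied droplets). Both directions are exposed
because screen reports quote both.

## Mixture analysis and the middle mean

Screening signals are summarized by a three-component Gaussian mixture:
fluorescein baseline (empty droplets), the majority cellulose peak, and a
high-signal component (multi-occupancy and outlier producers). Components are
identified by ascending mean with ties broken by weight; the strain statistic
is the middle mean, and strains are compared after rescaling signals so the
fluorescein peak sits at 0.1 V (`normalize_baseline()`; the mixture MLE is
equivariant under this linear map, so `normalize_fit()` rescales a fit
directly).

The EM fitter is written for this mixture shape. Droplet screens produce
strongly unbalanced mixtures — a ~90% narrow baseline next to minority
peaks — on which generic single-start EM reliably finds a local optimum that
splits the baseline and merges the signal peaks (we observed a log-likelihood
gap of ~270 nats on a 15,000-event draw). The fitter therefore uses k-means++
seeding, scores 10 short restarts, and polishes the best by likelihood; a
variance floor of $10^{-3}$ sample SDs prevents collapse onto single points.
Values are sorted internally so the RNG-driven seeding is invariant to input
order, and the fit is deterministic given its seed. At the screening scale of
15,000 events with components separated by at least 3 SD, all three fitted
means land within 0.02 V of truth in well over 95% of seeded replicates.

Published tail fractions above a 3 V cut (0.07%, 0.84%, 2.46% for
native/control/evolved) cannot be reproduced numerically because the
generating component SDs are unpublished; the package asserts only the strain
*ordering* on calibrated synthetic streams, and provides `fraction_above()`
for the statistic itself.

## CFU assay math

`cfu_from_dilution()` back-calculates a stock concentration from replicate
drop counts (`mean(counts) / (drop_volume × dilution)`, 5 µL drops and 6
replicates by default). When several dilutions are plated,
`select_countable()` picks the most concentrated dilution whose mean count
lies in 3–30 colonies per drop — dense plates are uncountable, sparse ones
Poisson-noisy; the bounds are an explicit package choice since counting
practice rarely states one. All-zero plates return 0 flagged below-detection
rather than an imputed value. Survival is the exposed/control concentration
ratio in percent (control ≡ 100% by construction), and `survival_curve()`
summarizes a dose series by the least-squares slope of log survival — a
single exponential-decay rate, fitted only because it is a useful summary;
no mechanistic claim is attached.

## The campaign simulator

`run_campaign()` chains rounds of: deterministic recovery growth (each
viable variant's abundance weight is $2^{g t}$ for growth rate $g$ and
recovery time $t$, default 50 h — the step that enriches fast growers roughly
eightfold before encapsulation), Poisson encapsulation, incubation signal,
gating, and colony picking. Multi-occupancy droplets contribute their summed
signal and, when sorted, all their occupants to the picked pool: plating a
sorted droplet grows every occupant into a separate colony, restoring
clonality at the pick. Picks are uniform without replacement (default 5
colonies; the acceptance analyses plate the whole sorted pool instead, so the
beneficial share is measured on ~250 colonies rather than 5 and its sampling
noise stays well below the 1% enrichment bar). Picked variants, clonally
expanded, seed the next round. Per-round seeds derive from the master seed,
making a campaign bit-reproducible.

A known confounder is modeled faithfully rather than hidden: co-encapsulated
pairs of neutral cells sum to a brighter signal than a single beneficial
cell (at effect 1.6), so the very top of the gate is dominated by
multi-occupancy droplets and the realized beneficial share among picks (a few
percent from a 1% class) is far below what single-cell gating would give.
This mirrors the real motivation for operating at low $\lambda$. An optional
additive stress modifier on production rates can represent non-genetic
production boosts, but ships disabled: no mechanism is available to calibrate
it, so it defaults to zero and is left to the user.

## Problem sizes and numerical choices

The packaged analyses use 15,000-event streams for mixture fits, 100,000 to
430,000-droplet streams for gate statistics, 50 images of 200 droplets for
detection fidelity, and 40–100 seeded replicates for stochastic properties —
the scales at which the corresponding statistics are quoted, and comfortable
for a laptop session. Percent reports round half-up (one decimal for
occupancy profiles, two for sort fractions, integers for strain increases
and fold changes); internal values are never rounded. Degenerate inputs fail
loudly: all-equal data for the mixture, empty streams for the gate, fields
too small for the requested droplet count, doses outside the tabulated
survival curve.

## Limitations

The simulator captures the statistical structure of a droplet screen, not
its physics: no droplet coalescence or false sorts, no PMT pulse dynamics,
no optics in the image model, no sequence-level mutagenesis, and no
mechanistic link from genotype to production rate beyond the
lethal/neutral/beneficial classes. Conclusions drawn from it are about the
analytics — gate arithmetic, estimator behavior, selection statistics —
and transfer to real data only insofar as those data match the stated
generative assumptions.
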