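---
title: "Modelling bee-perceived flower colour and testing its link to nectar reward"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bee-perceived flower colour and testing its link to nectar reward}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexflora)
```

## The question

Flower-constant pollinators such as bees learn and revisit colour signals,
so a community could in principle evolve an honest mapping between colour
and nectar reward. `hexflora` provides the machinery to test this at the
community level: a colour-vision model that places each species where a
bee sees it, contingency and rank-correlation tests of the colour/reward
association over ecologically motivated species subsets, and a
phylogenetic-signal analysis that asks how much of the variation in reward
is simply inherited.

## The colour-vision model

A hymenopteran trichromat is modelled by three photoreceptor sensitivities
$S_i(\lambda)$ ($i \in \{UV, B, G\}$) built from the Govardovskii A1
pigment template with peaks at 350, 440 and 540 nm. Given a stimulus
reflectance $I(\lambda)$, a background reflectance $I_B(\lambda)$ and an
illuminant photon flux $D(\lambda)$, the relative photon capture of
receptor $i$ is

$$P_i = R_i \int_{300}^{650} S_i(\lambda)\, I(\lambda)\, D(\lambda)\,
  d\lambda, \qquad
  R_i = 1 \Big/ \int_{300}^{650} S_i(\lambda)\, I_B(\lambda)\, D(\lambda)\,
  d\lambda .$$

The von Kries coefficient $R_i$ normalises each receptor to the adapting
background, so the background itself always has $P_i = 1$. Excitation
saturates as $E = P/(P+1)$, and the locus in the colour hexagon is

$$x = \sin 60^\circ\,(E_G - E_{UV}), \qquad
  y = E_B - \tfrac12 (E_G + E_{UV}).$$

Note the $+$ sign inside $y$: a typographic variant with
$E_G - E_{UV}$ circulates in print, but it would displace the adapting
background to $y = 0.5$, contradicting the defining property of the model
that the background sits at the centre. The background-neutrality property
(`spectrum_to_locus(background) == (0, 0)` for *any* background) is tested
to machine precision.

Hue is the polar angle of the locus, measured counter-clockwise with the
blue vertex $(0, 1)$ at $90^\circ$; chromatic contrast is the distance
from the centre. The six colour categories are $60^\circ$ sectors centred
on the receptor and receptor-pair axes: BG $[0^\circ, 60^\circ)$, B
$[60^\circ, 120^\circ)$, UB, U, UG, G continuing counter-clockwise. Two
conventions here are declared rather than forced by the model, and both
are configurable at the relevant call sites:

* a boundary hue belongs to the counter-clockwise sector (so $60^\circ$ is
  B, not BG);
* a locus with contrast below $10^{-9}$ has *undefined* hue (reported as
  `NA`, never silently $0^\circ$), since polar angle is meaningless at the
  centre.

### Numerical choices

All spectral functions are tabulated on the 300–650 nm grid in 10 nm
steps (36 points) and integrated by a plain Riemann sum; finer measurement
grids are linearly interpolated onto the model grid and wavelengths beyond
650 nm are truncated. The absolute scale of the illuminant, and the step
width itself, cancel between $P_i$ and $R_i$, which the scale-invariance
test exercises directly. The quadrature choice matters only at the level
of the end points; a trapezoid-rule cross-check in the test suite agrees
to about a percent, and identically once both rules see the same grid
convention.

The default illuminant is the CIE D65 relative power table converted to
photon flux (multiplied by $\lambda$); the default background is a
parametric green-leaf curve — low UV and blue reflectance, chlorophyll
bump near 550 nm, mild red-edge rise — standing in for a field-averaged
foliage spectrum. Both are replaceable by measured spectra, and because
published hexagon coordinates can be consumed directly (`read_records()`),
reproducing a published analysis does not depend on recovering its exact
background.

When a species is measured on two colour patches, `read_spectra_csv()`
averages the patch spectra into one species spectrum. Reducing a
multi-coloured flower to one locus is genuinely under-determined — using
the larger patch, the more contrasting patch, or the average are all
defensible — and the average was chosen as the least-informative default;
classification from dominant-patch data is available simply by supplying
only that patch, or by providing published coordinates directly.

## Reward statistics

Per-flower soluble sugar (µg sucrose-equivalent) is dichotomised at the
sample median: *high* means strictly above the threshold, so with an odd
sample the median species itself is *low*. The MAD is reported alongside
with the usual 1.4826 normal-consistency constant (configurable to 1);
only the median enters the analysis, so this convention has no downstream
effect.

Four exclusion rules generate nested subsets, each re-dichotomised at its
own median: SS1 drops the (typically single) UV-sector species, SS2
additionally drops Asteraceae — their "flower" is a compound head, so
per-flower sugar is not comparable — and SS3 additionally drops
Orchidaceae, where food deception is common; the orchids are also analysed
on their own. The reward-by-sector contingency table (empty sectors
dropped) is tested with the Pearson χ² statistic referred to a Monte-Carlo
null: tables are drawn uniformly with both margins fixed (Patefield's
algorithm via `stats::r2dtable`, the same engine behind R's
`chisq.test(simulate.p.value = TRUE)`), and
$p = (1 + \#\{\chi^2_{sim} \ge \chi^2_{obs}\}) / (n_{sim} + 1)$, which is
never exactly zero. Conditioning on both margins is the standard choice
when the column totals (species per colour) are design-like rather than
sampled.

The sugar–contrast association uses Kendall's τ-b, tie-corrected, with an
exact permutation null for $n \le 10$ without ties and the tie-adjusted
normal approximation otherwise. The implementation is checked against a
brute-force pair-counting oracle on a thousand random small instances and
against `stats::cor.test` on larger tied ones. No multiplicity correction
is applied across subsets: the subsets are nested reformulations of one
question, not independent hypotheses, and the per-test p-values are
reported as such.

## Phylogenetic signal

Pagel's λ rescales the off-diagonal of the Brownian-motion covariance
$C$ implied by the tree ($C_{ij}$ = shared root-to-MRCA path length).
Under the model the trait is multivariate normal,
$y \sim N(a\mathbf{1}, \sigma^2 C_\lambda)$; the root state $a$ is
profiled by GLS, $\sigma^2$ by its ML value, and λ is found by bounded 1-D
maximisation of the profile log-likelihood on $[0, 1]$ (tolerance
$10^{-8}$, ties to the smaller λ; the cap at 1 reflects the Brownian
benchmark, and a tree-derived upper bound can be supplied instead).
Polytomies pose no difficulty because only $C$ is needed. Tips without
trait values are pruned with a logged count. Significance against
$\lambda = 0$ uses the likelihood-ratio test by default (matching the
practice of the standard tools in this area) with an explicit tip-shuffle
permutation test available, because the χ²₁ reference is approximate at
boundary hypotheses.

One behaviour worth knowing about: the likelihood is Gaussian, while
per-flower sugar is strongly right-skewed. A single extreme species on a
tree whose splits are concentrated near the tips can pull
$\hat\lambda$ to the boundary with a dramatic likelihood gain — the fit is
answering "which covariance best absorbs this outlier", not "is reward
heritable". The estimator itself is sound (parameter-recovery simulations
give mean $\hat\lambda \approx 1$ under Brownian motion and
$\approx 0.05$ under independent noise on 64-tip trees), but on raw sugar
values the λ test should be read with the trait distribution in mind, or
applied to log-transformed values.

## The synthetic-data generator

The generator exists so that every stage is testable without any
download, and its defaults are fixed once to describe the study system
the package targets: a 59-species bee-pollinated community from temperate
Australian woodland. Specifically:

* **Sector mix** 12 B / 20 BG / 12 G / 10 UG / 1 UV / 4 UB —
  blue-green and blue dominate and the UV sector is nearly empty, the
  shape repeatedly found in bee-pollinated floras worldwide.
* **Families** 28 Orchidaceae and 3 Asteraceae among the non-UV species,
  so the exclusion cascade produces subset sizes 59/58/55/27 with 28
  orchids, matching the structure the analysis is designed around.
* **Sugar** log-normal with `meanlog = log(392)` and `sdlog = 1`: a
  median of ~392 µg per flower with MAD of the same order, i.e.
  right-skewed amounts on the hundreds-of-µg scale typical of
  field-measured per-flower soluble sugar. Colour/reward effects are
  injected as multiplicative sector offsets of the location parameter;
  all-ones is the null community.
* **Spectra** are drawn from six parametric archetypes (sigmoid plateau +
  optional Gaussian peak + optional UV bump) whose zero-jitter curves
  land in the six sectors under the default visual system; each species'
  jittered spectrum is rejection-sampled until the realised sector —
  computed through the *full* colour model, never assigned — matches its
  target.
* **Trees and traits** come from a pure-birth process with traits drawn
  from $N(0, \sigma^2 C_\lambda)$, giving the λ-recovery tests a ground
  truth.

What the generator deliberately does not emulate: real petal optics
(multi-layer scattering, iridescence), correlated measurement noise from a
spectrophotometer, within-species colour variation across sites, and any
realistic mapping of families onto colour sectors. Passing tests on
synthetic communities therefore validate the statistical machinery and its
calibration, not ecological conclusions about any real flora; analyses of
real communities should feed measured spectra or published loci through
the same entry points.

## Problem sizes and calibration checks

The test suite validates the Monte-Carlo χ² against exact enumeration on
a 2×2 table with margins (2,2)/(2,2) at 20,000 simulations, estimates the
type-I error of the full reward test at $\alpha = 0.05$ over 500 null
communities at 2,000 simulations each (accepted in $[0.02, 0.08]$ — the
conditional test is slightly conservative on discrete tables), and runs
λ-recovery over 100 replicates of 64-tip trees. The acceptance script
uses 100,000 simulations for the contingency tests (the analysis-grade
setting), 50 λ-recovery replicates and 200 calibration communities; these
sizes give Monte-Carlo standard errors comfortably below the effects of
interest while keeping a full run around a minute.

## Known limitations

* The hexagon model is the standard choice for comparative flower-colour
  work, but it ignores receptor noise; no colour-discrimination distance
  (ΔS) or detectability modelling is attempted.
* Sector boundaries are a declared convention. Species whose hue falls
  within measurement error of a 60° boundary can switch categories under
  a different convention, which is why the contingency χ² is only
  expected to be stable to within a few hundredths against analyses that
  used a different boundary rule.
* The λ likelihood assumes a Gaussian trait, as discussed above.
* Families are matched by exact name; no taxonomic normalisation is
  attempted beyond whitespace/underscore handling of species labels.
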