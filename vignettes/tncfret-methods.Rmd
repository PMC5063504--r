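---
title: "Models and methods behind tncfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tncfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tncfret)
```

This vignette is the package's own account of its science: the models it
fits, the assumptions they rest on, the defaults it ships, and the
numerical choices a maintainer would otherwise have to reverse-engineer
from the code.

## The measurement model

A donor--TnC--acceptor fusion (CFP/Cerulean donor, YFP/Venus acceptor)
reports divalent-cation binding through FRET. The package models every
emission scan as a **linear mix of two known unit-peak shapes**:

$$I(\lambda) \approx F_{Don}\, D(\lambda) + F_{Acc}\, A(\lambda),$$

with the acceptor channel split into a FRET-driven and a directly excited
part,

$$F_{Acc} = F_{AccFRET} + F_{AccDirect}, \qquad
  F_R = \frac{F_{AccFRET}}{F_{Don}}.$$

Everything downstream assumes only this linearity -- no lifetime,
anisotropy, bleaching or inner-filter physics. $(F_{Don}, F_{Acc})$ is the
global least-squares solution; the direct-excitation term is estimated from
an acceptor-only control as a per-excitation fraction
$r(\lambda_{ex}) =$ (control acceptor amplitude at $\lambda_{ex}$) /
(control acceptor amplitude at 515 nm), and subtracted as
$F_{AccDirect} = r \cdot F_{Acc}^{515}$, where $F_{Acc}^{515}$ is the
sample's own amplitude under 515 nm excitation, recorded per condition.

Why a ratio? Both $F_{AccFRET}$ and $F_{Don}$ scale with the same donor
excitation efficiency, so $F_R$ cancels lamp intensity and excitation
wavelength. The end-point analysis exploits this by averaging $F_R$ over
nine excitation wavelengths (433, 424, 420, 418, 414, 410, 408, 404,
400 nm) and reporting mean $\pm$ SE (sample SD / $\sqrt{n}$, $n$ = number
of excitations), mirroring the error bars conventional for this assay.

Two deliberate choices:

* **Unconstrained least squares.** Amplitudes may come out slightly
  negative under noise; truncating at zero would bias estimates near zero
  upward, so negative amplitudes are reported with a warning flag instead.
* **Grid harmonization by linear interpolation** of the references onto the
  scan's grid, with extrapolation refused outright.

`peak_read()` implements the simpler convention used for full-range
titration series -- raw intensities at 475 nm and 515 nm. The donor shape
is nonzero at 515 nm, so peak reads carry donor bleed-through; on a fixed
instrument this is a constant construct-specific factor, which is why the
two statistics track each other but unmixing is the default for end-point
work. Nearest-grid-point ties resolve to the lower wavelength,
deterministically. The acceptor *emits* maximally near 525 nm but is *read*
at 515 nm; both wavelengths are configuration, not constants, since the
conventions differ between instruments.

## End-point statistic and reversibility

The 3-condition protocol (chelate, saturate with 400 µM Ca²⁺, re-chelate)
gives

$$\Delta F_R = \left\langle F_R^{sat} - \tfrac12\left(F_R^{init} +
F_R^{final}\right) \right\rangle_{\lambda_{ex}},$$

and the two cation-free conditions provide a reversibility diagnostic: the
dataset is flagged non-reversible when $|F_R^{init} - F_R^{final}|$
exceeds 3 combined standard errors.

## Titration models

All binding curves are parameterized in $pX = -\log_{10}[X^{2+}]_{free}$.

* **Force--pCa** (skinned-fiber mechanics):
  $F = 100 / (1 + 10^{n_H (pCa - pCa_{50})})$. The numerator is *fixed* at
  100 because force is normalized to the same fiber's post-reconstitution
  maximum at pCa 4 -- the plateau is 100 by construction, and the printed
  form of the relation has no free amplitude. Letting it float is the main
  alternative; we follow the printed form.
* **Single Hill** (Mg²⁺ titrations):
  $f = F_{min} + F_{max} / (1 + 10^{n (pMg - pMg_{50})})$, fit to
  non-normalized $F_R$ directly (no pre-scaling).
* **Double Hill** (biphasic Ca²⁺ titrations):
  $f = F_{min} + F_{max1}/(1 + 10^{n_1 (pCa - pCa_{501})}) +
  F_{max2}/(1 + 10^{n_2 (pCa - pCa_{502})})$. The high-affinity C-domain
  component rises; the low-affinity N-domain component has *negative*
  amplitude. Components are relabelled after convergence so that
  component 1 has the larger midpoint (ties broken by amplitude
  magnitude); midpoints closer than 0.3 pX units trigger a
  weak-identification flag rather than a rejection, because a
  near-degenerate second component (amplitude indistinguishable from zero)
  is a real outcome for Ca²⁺-in-Mg²⁺ titrations.
* **Affinities**: $K_a = 10^{pX_{50}}$ L/mol, reported at full precision
  and rounded to 2 significant figures for display, the convention used
  for every printed affinity in this literature.
* **Sedimentation peaks**:
  $f(x) = A_0 \exp\!\left(-\tfrac12 ((x - s)/\delta)^2\right)$ per peak,
  fit inside a window required to contain one interior maximum.

The equation typography in the extracted source text is garbled (division
and exponent marks lost); the forms above are the standard Hill-in-pX
readings and are validated by their limits -- force $\to$ 100 at saturating
Ca²⁺, and a biphasic $F_R$ response with a negative second amplitude.

**Fitting machinery.** All nonlinear fits use Levenberg--Marquardt
(`minpack.lm::nlsLM`) with box bounds $0.2 \le n \le 6$ on Hill slopes.
Initialization: offsets/amplitudes from response extrema; midpoint starts
on the 25/50/75% quantiles of the observed pX range (all ordered pairs for
the double Hill); slopes start at 1. The best-RSS start wins; on noiseless
data every start converges to the same optimum, and the test suite asserts
recovery of generating parameters to $10^{-4}$ or better.

## Buffer speciation

Free-ion control in fiber and titration experiments uses chelator
mixtures. The solver treats **1:1 complexes only** with **apparent
(pH-conditional) association constants**: adequate for EGTA, EDTA, NTA and
ATP with Ca²⁺/Mg²⁺ at fixed pH 7.0 and fixed ionic strength, which is how
the recipes are defined. No proton balance, ionic-strength or temperature
corrections are computed; the constants are configuration, and the shipped
table (`default_binding_constants()`) is labelled representative and
user-overridable. Only one check depends on the shipped values -- the
recipe "~4.4 mM total Mg²⁺ in 2 mM EGTA + 5 mM NTA gives 2 mM free
Mg²⁺" -- and it is asserted at 25% tolerance for exactly this reason.

Numerics: a damped (geometric-mean) fixed point on the free-ligand vector,
then a Newton polish in log space with analytic Jacobian and step halving.
Log variables keep concentrations positive; the stall guard stops at
numerical precision. Every converged result carries its worst relative
mass-balance residual (contract: $< 10^{-10}$; typically $10^{-14}$ or
better). The inverse problem (total needed for a target free
concentration) exploits strict monotonicity of the forward map and uses
safeguarded root bracketing on $[x_{target},\ x_{target} + \sum L_{tot}]$.

## EF-hand decomposition

Under the independence assumption a construct's signal is the sum of its
active sites' contributions plus a construct-independent baseline (the
signal of the triple mutant, interpreted neutrally -- for Mg²⁺ it may
reflect non-EF-hand binding). Stacking the panel gives a design matrix of
active-site indicators plus a column of ones; the solve is weighted least
squares ($w = 1/\mathrm{SE}^2$ when SEs are given), which reduces to the
exact solve for a square panel -- so the choice of solver is immaterial
for the standard five-construct Ca²⁺ panel and four-construct Mg²⁺ panel.
Mg²⁺ panels carry no site-II column: site II binds Mg²⁺ at most very
weakly, so no Mg²⁺ contrast can inform it. Contribution SEs come from the
weighted normal equations (pure linear propagation of the input SEs).
`predict()` sums contributions over active sites;
`compare_to_wt()` reports the additivity discrepancy against the directly
measured wild-type signal and flags violations beyond 3 combined SEs.

## The synthetic fluorometer

The generator exists so that every stage of the pipeline can be exercised
against known truth. What it emulates, and what it deliberately does not:

* **Emission shapes**: skewed Gaussians (Gaussian core, long-wavelength
  exponential tail) -- real fluorescent-protein spectra are right-skewed,
  but since the analysis assumes only linear mixing of known shapes, the
  exact form is not load-bearing.
* **Direct excitation**: log-normal in excitation wavelength, peaking at
  515 nm, with profile(433)/profile(515) = 0.10 (within the plausible
  0.05--0.15 range for Venus); monotonically decreasing toward 400 nm. The
  profile is configuration; the analysis never hard-codes it.
* **Donor excitation efficiency**: a smooth bump centred at 433 nm that is
  exactly zero at and beyond 490 nm. It scales brightness only (and so
  cancels from $F_R$, which is the excitation-invariance property); the
  hard zero means a 515 nm sample scan contains no FRET emission, making
  the noiseless round trip (pipeline $F_R$ = generator $f_r$ to
  $10^{-9}$) exact, and reflecting the negligible CFP absorption at
  515 nm.
* **Noise**: additive i.i.d. Gaussian per wavelength -- the simplest model
  consistent with PMT readout at fixed voltage. Poisson (shot-noise)
  behaviour, bleaching, scatter and baseline drift are *not* modelled, so
  green tests demonstrate correctness of the estimators under the stated
  model, not robustness to instrument pathologies.
* **End-point truths** follow the additive site model with the shipped
  per-site defaults, anchored at an apo-state ratio `f_r_apo = 0.25` (the
  wild-type sensor's observed cation-free scale). The anchor is needed
  because contributions are signal-change quantities: the site-II-only
  construct has a net negative change, and only an absolute-ratio offset
  keeps every simulated condition physically emittable. The offset cancels
  from all end-point differences. Conditions 1 and 3 share one truth, so
  reversibility holds by construction; non-reversible datasets used in
  tests are constructed by corrupting condition 3 explicitly.
* **Determinism**: every stochastic call takes a seed, uses it locally,
  and restores the caller's RNG state; identical config + seed is
  bit-identical.

## Study-scale simulation designs

The recovery simulations use the designs of the original experiments:
Ca²⁺ titrations with 25 pCa points from 9.5 to 4.0 and 4 replicates at
noise SD 0.005 (the $F_R$ scale); Mg²⁺ titrations with 15 pMg points from
5.5 to 1.5; force--pCa with 12 points from pCa 8 to 4, 6 replicates, 2%
noise; sedimentation grids on [3.0, 5.5] S at 0.01 S. Recovery statistics
average 20 seeded runs, which bounds the Monte-Carlo error of the mean
midpoint well below the 0.03--0.05 pX acceptance tolerances while keeping
the whole suite interactive.

## Degenerate inputs and edge behaviour

* Identical (or near-collinear) donor/acceptor shapes are rejected at
  construction (Gram condition number $\ge 10^6$) and again at unmixing
  ($> 10^8$).
* A control with nonpositive acceptor amplitude at 515 nm is an unusable
  normalization and is an error; a missing control at a working
  wavelength only excludes that wavelength, with a warning.
* Flat titrations ("no transition": range below 5$\times$ the replicate
  noise), monotone-increasing force--pCa data, windows without an interior
  maximum, and rank-deficient mutant panels are all errors naming the
  offending structure.
* Normalized force is sanity-checked against gross violations
  ([-15, 125]%) rather than the idealized [-5, 110] band, so that
  legitimate noise excursions at the curve's extremes do not abort a fit.

## Known limitations

* Two-component unmixing only; no third species, scatter or baseline term.
* Apparent-constant speciation: results are only as good as the constants
  supplied for the actual pH/ionic strength/temperature.
* The decomposition assumes site independence; cooperativity shows up only
  as an additivity discrepancy, not as a model term.
* The double-Hill likelihood surface is genuinely flat when one amplitude
  is near zero; the weak-identification flag is the honest output there,
  and downstream affinity estimates for such components should not be
  trusted (their SEs say as much).
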