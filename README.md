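# tncfret

Analysis of a cardiac troponin C (cTnC) FRET sensor: from raw fluorescence
emission spectra to a FRET-ratio statistic, divalent-cation binding
affinities, and per-EF-hand structural contributions.

## The problem

Cardiac TnC is the Ca²⁺ sensor of the contractile apparatus. Flanking it
with a donor fluorescent protein (Cerulean, emission peak 475 nm) and an
acceptor (Venus, emission peak ~525 nm) turns the protein's global
conformational changes upon Ca²⁺/Mg²⁺ binding into a FRET readout. This
package implements the full analysis chain for such a sensor, for
spectroscopists and muscle biophysicists who want the pipeline reusable and
testable rather than trapped in one-off instrument scripts:

* **Spectral unmixing.** Each emission scan (445–610 nm) is decomposed by
  least squares into donor and acceptor amplitudes,
  `intensity ≈ F_Don · donor_shape + F_Acc · acceptor_shape`. The acceptor
  channel splits as `F_Acc = F_AccFRET + F_AccDirect`; the direct-excitation
  part is measured with an acceptor-only control, normalized to the
  acceptor's direct-excitation maximum (515 nm), and subtracted. The
  statistic is the FRET ratio `F_R = F_AccFRET / F_Don`, which is
  independent of excitation intensity and wavelength.
* **End-point titrations.** The 3-condition protocol (chelated → 400 µM
  Ca²⁺ → re-chelated) yields
  `ΔF_R = F_R(Ca²⁺) − ½·[F_R(initial) + F_R(final)]`, averaged over nine
  excitation wavelengths (433–400 nm), with a built-in reversibility check.
* **Titration fitting.** Force–pCa data: `F = 100 / (1 + 10^{n_H (pCa −
  pCa₅₀)})`. Biphasic Ca²⁺ titrations of the sensor: a double Hill with a
  rising high-affinity (C-domain, sites III/IV) and a falling low-affinity
  (N-domain, site II) component. Mg²⁺ titrations: a single 4-parameter
  Hill. Affinities via `K_a = 10^{pX₅₀}`. Sedimentation-coefficient
  distributions from analytical ultracentrifugation: a 3-parameter Gaussian
  peak.
* **Buffer speciation.** Free Ca²⁺/Mg²⁺ in multi-chelator buffers
  (EGTA/EDTA/NTA/ATP) under simultaneous 1:1 equilibria with apparent
  pH-conditional constants, forward (totals → free) and inverse (target
  free → required total).
* **EF-hand decomposition.** From a panel of site-inactivation mutants
  (D104A, D140A, D104-140A, 3XEF), per-site contributions to `F_R` are
  solved as a linear system under the independence assumption, and summed
  predictions are compared against the wild-type signal.

A seeded synthetic fluorometer generates every input — reference shapes,
mixed scans, acceptor-only controls, complete end-point datasets, titration
series, sedimentation distributions — with ground truth attached, so every
stage is exercisable and testable without instrument data.

## Worked example

Simulate a wild-type end-point experiment at realistic noise and analyze it:

```r
library(tncfret)
ds <- simulate_endpoint_experiment(
  ctv_constructs()[1, ],               # CTV-TnC WT: sites II, III, IV
  ctv_site_contributions("Ca"),        # shipped per-site defaults
  "Ca-in-EDTA",
  simulation_config(seed = 42, noise_sd = 0.3))
analyze_endpoint(ds)
#> End-point analysis: CTV-TnC WT, protocol Ca-in-EDTA
#>   condition  mean_f_r       se_f_r n
#>    chelated 0.2601135 0.0004090034 9
#>   saturated 0.4636385 0.0004136474 9
#>  rechelated 0.2597857 0.0003062082 9
#>   delta F_R = 0.2037 (SE 0.00033)
#>   reversibility gap |F_R(1) - F_R(3)| = 0.000328 (reversible)
```

The recovered `ΔF_R = 0.2037` matches the generating truth (0.204, the sum
of the three per-site contributions −0.120 + 0.224 + 0.100), and the two
cation-free conditions agree to within noise — the signal is reversible.

Fit a biphasic Ca²⁺ titration and convert midpoints to affinities:

```r
cfg <- simulation_config(seed = 42, noise_sd = 0.005, mode = "hill",
  model_params = list(f_min = 0.040, f_max1 = 0.133, n1 = 2.70,
                      p50_1 = 7.17, f_max2 = -0.082, n2 = 0.94,
                      p50_2 = 5.47))
s <- simulate_titration(cfg, seq(9.5, 4.0, length.out = 25), replicates = 4)
summary(fit_double_hill(s))
#> Double (biphasic) Hill fit
#>         estimate       se
#> f_min   0.040963 0.000909
#> f_max1  0.125613 0.003430
#> n1      2.968262 0.221340
#> p50_1   7.177263 0.012900
#> f_max2 -0.071337 0.004589
#> n2      1.277480 0.178883
#> p50_2   5.457256 0.047353
#>   residual SS 0.002517; converged
#>   association constant(s) K_a = 10^p50 (2 s.f.):
#> component1 component2
#>    1.5e+07    2.9e+05
```

The high-affinity midpoint pCa₅₀₁ ≈ 7.18 (K_a = 1.5 × 10⁷ M⁻¹) and the
negative second amplitude (N-domain site II lowering `F_R`) are both
recovered. Compose a titration buffer:

```r
solve_free(buffer_system(c(Mg = 4.4e-3), c(EGTA = 2e-3, NTA = 5e-3)))
#> Buffer speciation (apparent 1:1 constants, pH 7 )
#>   free Mg: 0.00185551 M (pMg = 2.732)
#>   free EGTA: 0.00186182 M
#>   free NTA: 0.00259369 M
#>   max relative mass-balance residual: 4.3e-16
```

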