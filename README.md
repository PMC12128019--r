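# spinfep

Alchemical free energy perturbation (FEP) for converting one electronic state
into another — the singlet-to-triplet transformation in particular.

## The problem

The adiabatic triplet energy of a nucleobase embedded in a macromolecular
environment (a nucleotide in water, a base stacked inside a DNA helix) is the
free-energy difference between the equilibrated triplet excited state and the
equilibrated singlet ground state. The conventional estimate averages each
state's energy over its own molecular-dynamics ensemble and takes the
difference,

    ΔU = ⟨E_T⟩_T − ⟨E_S⟩_S ,

but in a QM/MM setting the raw energies carry the full fluctuation of the
classical environment — tens of kJ/mol of standard deviation — which is as
large as the physical effects one wants to resolve.

`spinfep` implements the alternative: treat the spin conversion as an
*alchemical* transformation through mixed Hamiltonians

    H(λ) = (1 − λ) H_S + λ H_T ,      λ ∈ [0, 1]

and accumulate the free energy over a ladder of λ windows with the Zwanzig
estimator,

    ΔG = Σᵢ ΔG_{i,i+1} = −k_B T Σᵢ ln ⟨ exp(−(H_{i+1} − H_i)/k_B T) ⟩ᵢ .

Because every sample of the gap `H_{i+1} − H_i` is evaluated at a single
configuration, every energy term common to both electronic states — the whole
classical environment — cancels exactly inside the exponent. The statistical
error collapses by orders of magnitude relative to ΔU.

Each window's error bar is the first-order propagation of the Monte-Carlo
error of the exponential average, corrected for serial correlation:

    ε = k_B T δε / ⟨X⟩ ,   δε² = (1 + 2τ)/N · (⟨X²⟩ − ⟨X⟩²) ,
    1 + 2τ = (1 + r₁)/(1 − r₁) ,

with `X = exp(−ΔH/k_B T)` and `r₁` the lag-1 autocorrelation of the sampled
`X` series. Window errors combine in quadrature.

The package is aimed at method developers and modellers who want to test,
calibrate or teach this estimator chain: it ships analytic two-state systems
(harmonic, quartic, and a "noisy environment" model with an exactly
common-mode bath), a BAOAB Langevin sampler and an exact canonical sampler
for them, the full estimator with its error model, the ΔU baseline, and a
Mulliken spin-population localization classifier for triplet character. No
electronic-structure engine is wrapped; the `external_stub` backend documents
the adapter contract a QM/MM engine must satisfy.

## Worked example

A 1D harmonic two-state pair with a 10 kJ/mol triplet offset and an `e²`
force-constant ratio has the closed-form free energy
ΔF = 10 + k_B·300/2 · ln e² = 12.494 kJ/mol. Sample the default 6-window
schedule exactly and estimate:

```r
library(spinfep)

hp <- make_harmonic_pair(delta_e0 = 10, k_ratio = exp(2), n_coords = 1)
hp$delta_f
#> [1] 12.49434

series <- lapply(c(0, 0.2, 0.4, 0.6, 0.8, 1), function(l)
  direct_canonical_sample(hp$system, l, temperature = 300, n = 5000,
                          seed = 42 + round(100 * l)))
fep <- fep_estimate(series)
fep
#> <fep_result>
#>   schedule: {0, 0.2, 0.4, 0.6, 0.8, 1}
#>   total dG = 12.4929 +/- 0.0213 kJ/mol (5 windows)

tidy(fep)
#> # A tibble: 5 × 7
#>   lambda_from lambda_to    dg     eps      r1 sampling_ratio     n
#> 1         0         0.2  3.03 0.0162  0.00543           1.01  5000
#> 2         0.2       0.4  2.56 0.00970 0.0193            1.04  5000
#> 3         0.4       0.6  2.38 0.00681 0.0206            1.04  5000
#> 4         0.6       0.8  2.29 0.00523 0.0102            1.02  5000
#> 5         0.8       1    2.24 0.00446 0.0192            1.04  5000
```

The total, 12.493 ± 0.021 kJ/mol, covers the analytic 12.494 within one
error bar. The ΔU baseline from the two endpoint ensembles of the same run
is `delta_u(series[[1]], series[[6]])` → 9.98 ± 2.50 kJ/mol: unbiased only
up to the neglected entropic term, and two orders of magnitude noisier.

Spin localization from fragment-summed Mulliken populations:

```r
classify_localization(c(T1 = 1.96, T2 = 0.04))
#> <spin_localization> localized (index 0.980, threshold 0.75) on 'T1'
```

`autoplot()` methods exist for `fep_result`, `energy_series` and
`spin_localization`; `tidy()`/`glance()` return tibbles throughout. A thin
command-line shim over these functions is installed at `inst/cli/spinfep.R`
(subcommands `simulate`, `estimate`, `deltau`, `spin`, `fixtures`).

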