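---
title: "Alchemical spin-state free energies: model, error chain and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alchemical spin-state free energies: model, error chain and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinfep)
```

## The model

`spinfep` estimates the free-energy difference between two electronic states
that share one set of nuclei — prototypically a singlet ground state and a
triplet excited state of a nucleobase. The transformation is alchemical: a
ladder of unphysical intermediate states

$$H(\lambda) = (1-\lambda)\,H_S + \lambda\,H_T, \qquad \lambda \in [0,1],$$

connects the two physical endpoints, and the total free energy accumulates
over adjacent windows by exponential averaging (the Zwanzig relation),

$$\Delta G = \sum_i \Delta G_{i,i+1}
  = -k_B T \sum_i \ln\left\langle
      e^{-(H_{i+1}-H_i)/k_B T}\right\rangle_i .$$

Only differences are ever computed; no absolute free energy appears anywhere
in the package. The mixture acts on potential energies alone: both spin
states share nuclear masses, so the kinetic term is state-independent and
cancels identically in every gap.

Two structural facts drive the whole design:

* **Every frame carries both endpoint energies.** Each evaluation of
  $H(\lambda)$ returns $E_S$, $E_T$ and the mixture, so the gap between
  *any* two windows of the same schedule is available from a single
  trajectory pass: for an affine mixture,
  $H_j - H_i = (\lambda_j - \lambda_i)(E_T - E_S)$ frame by frame. Window
  records are built from stored series without re-evaluating a backend.
* **Common-mode terms cancel exactly.** Any energy contribution that is
  identical in both electronic states — in a QM/MM setting, the whole
  classical environment — drops out of $E_T - E_S$ by construction. This is
  the mechanism behind the package's headline demonstration (below).

## The error chain

The estimator of each window average is a mean of
$X_i = e^{-\Delta H_i / k_B T}$ over $N$ serially correlated samples. The
implemented first-order error model is

$$\delta\varepsilon^2 = \frac{1+2\tau}{N}
  \left(\langle X^2\rangle - \langle X\rangle^2\right),
  \qquad 1+2\tau = \frac{1+r_1}{1-r_1},
  \qquad \varepsilon = \frac{k_B T\,\delta\varepsilon}{\langle X\rangle},$$

with $r_1$ the lag-1 autocorrelation. Three points here were genuinely open
and are fixed as follows, each isolated in `chipot_error()` with a toggle so
the alternative can be compared:

* **Which series feeds $r_1$.** The error being estimated is that of
  $\langle X\rangle$, so the autocorrelation is computed on the Boltzmann
  factors $X_i$, not on $\Delta H_i$. (`lag1_autocorrelation()` itself is
  generic over any ordered series.)
* **The variance form.** The population variance
  $\langle X^2\rangle - \langle X\rangle^2$ is used. The degenerate
  alternative $\langle X\rangle - \langle X\rangle^2$ (not a variance, and
  not invariant under the natural rescaling of $X$) is available as
  `variance_form = "printed"`.
* **The position of $\langle X\rangle$.** Dividing by $\langle X\rangle$ is
  the standard delta-method propagation through $-k_B T\ln m$; the
  multiplicative variant is available as `mean_position = "multiply"`.

Cross-window errors combine in quadrature, since each window is sampled from
its own independent trajectory (independent seeds by construction). The
replicate-calibration tests verify that on IID Gaussian gaps the predicted
$\varepsilon$ tracks the empirical spread of $\Delta G$ across replicates
within a factor of 1.5, and that with AR(1) correlation $\rho = 0.8$ the
sampling-ratio correction recovers the roughly threefold inflated spread.

Numerical policy: every exponential average and every error term is computed
on max-shifted exponents (log-sum-exp), so a constant gap of $\pm 10^4$
kJ/mol passes through exactly and no overflow can occur. A constant series
returns its constant exactly, with zero error and $r_1 = 0$ by convention
(a zero-variance series carries no correlation information). $r_1$ is
clamped to $\pm(1 - 10^{-12})$ before forming the sampling ratio.

## The baseline it outperforms

`delta_u()` implements the conventional estimate: sample the two endpoint
ensembles independently, average each state's own energy, take the
difference. Its quoted uncertainty is the standard deviation of the raw
per-frame data (not the standard error of the mean), combined across the two
ensembles as $\sqrt{SD_S^2 + SD_T^2}$ — the convention used when endpoint
averages over a fixed number of conformations are reported. This SD carries
the full environment fluctuation, which is precisely what never enters the
FEP gap. Note also that $\Delta U$ estimates an internal-energy difference:
even noise-free it differs from $\Delta G$ by the entropic term (visible on
harmonic fixtures with unequal widths, where
$\langle E \rangle$ is width-independent but $\Delta F$ is not).

## Sampling

Two samplers share one output contract (`energy_series`, a tibble of
per-frame $E_S$, $E_T$, $E_{mix}$ with $\lambda$, temperature and seed
attached):

* `run_window()` — Langevin dynamics with the BAOAB splitting. BAOAB is
  chosen for its superior configurational sampling accuracy at moderate
  timesteps; with `friction = 0` the O-step reduces to the identity and the
  scheme becomes velocity Verlet, which the NVE drift diagnostic exploits
  (relative drift below $10^{-4}$ over $10^5$ steps on harmonic systems).
  Defaults: `dt` = 1 fs, friction 1 ps⁻¹, 300 K, 10 % of steps discarded as
  equilibration. Frozen particles are held with zero velocity and zero
  displacement — not merely unforced — which keeps the kinetic temperature
  well-defined on the mobile subset and mirrors the frozen-shell protocol of
  large-system simulations.
* `direct_canonical_sample()` — exact, independent canonical draws for
  harmonic-family backends, exploiting that an affine mix of quadratics is
  quadratic with $k_{\rm eff} = (1-\lambda)k_S + \lambda k_T$. This is the
  reference sampler for estimator tests: it removes integrator and
  autocorrelation error from the comparison entirely.

Units are fixed globally: kJ/mol, Å, amu, K, fs, with
$k_B = 0.00831446$ kJ mol⁻¹ K⁻¹. In this system the natural time unit is
exactly 100 fs, which the integrator uses internally. Per-window seeds are
derived deterministically from the master seed and window index, so windows
are independently reproducible (and bit-identical on rerun).

## Synthetic systems and what they do (not) show

All test inputs are generated in code:

* **Harmonic pairs** (`make_harmonic_pair()`) carry their closed-form
  oracle $\Delta F = \Delta E_0 + \tfrac{k_B T}{2}\sum_i \ln(k_{T,i}/k_{S,i})$.
  A brute-force partition-function quadrature (`quadrature_delta_f()`, up to
  two coordinates, grid covering ≥ 8 thermal SDs with a boundary-decay
  check) independently confirms the closed form to $10^{-6}$ kJ/mol and
  extends the oracle to anharmonic (quartic) pairs.
* **The noisy-environment system** (`make_noisy_environment()`) adds $n$
  harmonic bath modes whose energy enters both states identically. The
  instantaneous potential energy of $n$ modes fluctuates with
  $SD = \sqrt{n/2}\,k_B T$ (chi-squared statistics), so $n$ is chosen to
  realize a requested SD — the default 40 kJ/mol at 300 K needs 514 modes,
  placing the endpoint ΔU error in the tens-of-kJ/mol regime reported for
  QM/MM spin-state simulations, against a solute with a 300 kJ/mol
  singlet–triplet offset (the scale of thymine triplet energies) and a
  mild 1.2 width ratio. Targets unreachable within 5 % by an integer mode
  count (or needing more than $10^5$ modes) are rejected.
* **Calibrated random series** (`generate_ar1()`, `generate_gaussian_dh()`)
  provide known-$\rho$ and known-$(\mu,\sigma)$ inputs; for Gaussian gaps
  the Zwanzig limit is the lognormal closed form
  $\mu - \sigma^2/(2 k_B T)$.

What passing on these fixtures shows: the estimator chain, its error
calibration, the sampler correctness, and the common-mode cancellation
mechanism are right. What it does not show: anything about real
electronic-structure surfaces — anharmonic coupling between solute and
environment, slow conformational degrees of freedom, state-dependent
polarization of the environment, or the quality of any QM method. The
`external_stub` backend documents the adapter contract (energy and gradient
for *both* spin states at every configuration) that connecting a real engine
would require.

## Spin localization

`spin_populations()` takes a plain per-atom table of Mulliken spin
populations (summing to 2 for a triplet, tolerance 0.05) with fragment
labels; `fragment_spins()` repartitions them exactly; and
`classify_localization()` reports the localization index — the dominant
fragment's share of the total spin. The threshold between "localized" and
"delocalized" is pictorial in origin, not a physical constant: the default
0.75 sits midway between a fully localized dimer triplet (index → 1) and a
symmetric excimer-like split (index 0.5), and is configurable within
(0.5, 1]. No wavefunction parsing is attempted; converting QM output to the
table is the caller's concern.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use desk-scale problem sizes
chosen so the full suite runs in minutes on one CPU: 5000 exact samples per
window for oracle-recovery runs (total $\varepsilon \approx 0.02$ kJ/mol on
the harmonic fixtures, two orders below the effect sizes probed), $10^5$-step
MD runs for integrator diagnostics, 200 replicates for error calibration,
and — mirroring endpoint-average conventions — 100 frames per endpoint for
ΔU against 6 × 2000 FEP samples in the noise-cancellation demonstration,
where the median error reduction over 10 seeds is close to four orders of
magnitude, comfortably beyond the two-orders threshold the demonstration is
designed around. Every random quantity in the package flows from an explicit
seed argument; no function touches the global RNG state without restoring
it.

## Known limitations

* Forward-only estimation is the default; backward series exist solely for
  the `window_overlap()` diagnostic (histogram intersection plus
  forward/backward closure). No BAR/MBAR reweighting, no thermodynamic
  integration, no bootstrap errors.
* The lag-1 model of the sampling ratio assumes roughly AR(1)-like decay;
  strongly multi-timescale correlation will be underestimated (the
  `sampling_ratio > 10` warning flags poorly decorrelated input).
* The Zwanzig estimator is biased at finite $N$ when window overlap is poor;
  the schedule-refinement invariance test bounds this on harmonic systems
  but arbitrary backends should be checked with `window_overlap()`.
* No constraints, barostats, periodic boundaries or replica exchange; the
  dynamics module is a sampler for the estimator, not a general MD engine.
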