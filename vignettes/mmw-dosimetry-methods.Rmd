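---
title: "Methods: millimeter-wave dosimetry in layered skin models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: millimeter-wave dosimetry in layered skin models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmwdosim)
```

## Overview

`mmwdosim` computes the steady-state temperature elevation produced in a
one-dimensional stack of tissue slabs by a normally incident plane wave in
the 6–100 GHz band. The computation is a one-way coupling of two exactly
solvable problems:

1. an **electromagnetic problem** — reflection, transmission and absorption
   of a plane wave in a lossy multilayer, which yields the absorbed power
   density (APD) at the surface and the specific absorption rate SAR(z) at
   depth; and
2. a **thermal problem** — the steady one-dimensional Pennes bioheat
   equation driven by that absorption profile, solved in closed form layer
   by layer.

The front door is `solve_dosimetry()`, which returns an `mmw_dosimetry`
object with `print()`, `summary()`, `plot()` and `as.data.frame()` methods.
The individual stages (`solve_stack_em()`, `delta_T()`, `metrics_at()`,
sweeps) are exported for direct use.

## Tissue dielectrics

Tissue permittivity is represented by a multi-term Cole-Cole dispersion

$$\hat\varepsilon(\omega) = \varepsilon_\infty +
\sum_n \frac{\Delta\varepsilon_n}{1 + (j\omega\tau_n)^{1-\alpha_n}} -
j\frac{\sigma_s}{\omega\varepsilon_0},$$

under the $e^{+j\omega t}$ time convention, so passive media satisfy
$\hat\varepsilon = \varepsilon' - j\varepsilon''$ with
$\varepsilon'' \ge 0$. The packaged database
(`default_dielectrics()`) carries literature parametric-model values for
dry skin, infiltrated fat, muscle, cortical bone and grey matter; rodent
dermal white adipose tissue (dWAT) resolves to the fat record and the
panniculus carnosus to the muscle record. Measured values can be
substituted per tissue with `dielectric_table()` and
`merge_dielectrics()` — an important option, because the absolute
transmittance and heating-factor levels of skin models are sensitive to
the skin dielectric source (parametric dry-skin values differ appreciably
from in-vivo measurements at these frequencies), while conservation- and
symmetry-type results are not.

Propagation constants follow from
$\gamma = j\omega\sqrt{\mu_0\varepsilon_0\hat\varepsilon}$ with the branch
fixed by $\mathrm{Re}(\gamma) = \alpha \ge 0$, and the intrinsic impedance
$\eta = \sqrt{\mu_0/(\varepsilon_0\hat\varepsilon)}$ with
$\mathrm{Re}(\eta) > 0$.

## Electromagnetic solve

In layer $i$ (local depth $\zeta$ from its top) the field is
$E_i(\zeta) = \tau_i e^{-\gamma_i\zeta} + \upsilon_i e^{+\gamma_i\zeta}$.
Instead of multiplying raw transfer matrices — which overflows once
$\alpha_i d_i$ is large — `solve_stack_em()` uses the impedance
transformation: from the bottom up, the reflection coefficient at the
bottom of layer $i$ and the input impedance at its top are

$$g_i = \frac{Z_{i+1} - \eta_i}{Z_{i+1} + \eta_i},\qquad
Z_i = \eta_i\,\frac{1 + g_i e^{-2\gamma_i d_i}}{1 - g_i e^{-2\gamma_i d_i}},$$

so only decaying exponentials appear. The deepest layer is treated as
semi-infinite (no returning wave); for the packaged stacks the terminal
layer is many penetration depths thick above 6 GHz, and the sensitivity of
surface quantities to this choice is small. Amplitudes are normalised to a
unit incident field; the incident-power scaling $|E_{inc}|^2 = 2p\eta_0$
enters only in SAR and APD. The solver is verified in the test suite
against a brute-force dense linear system of all interface continuity
conditions (agreement at the $10^{-10}$ level) and against closed-form
Fresnel cases, and satisfies power conservation
(`APD = sum of per-layer absorbed power`) to better than $10^{-9}$
relative.

Outputs: overall reflection coefficient, APD $= p(1-|\Gamma_0|^2)$,
transmittance APD/IPD, `sar_at()` (SAR $= \sigma|E|^2/2\rho$ with peak
phasors) and `poynting_at()` (net flux versus depth).

## Thermal solve

Each layer obeys the steady Pennes equation

$$\kappa_i T_i'' + \rho_i\,\mathrm{SAR}_i(z) + A_i - B_i\,(T_i - T_{blood}) = 0,$$

with metabolic heat $A_i$ and perfusion coefficient $B_i$. Boundary
conditions: a convective (Robin) balance
$h\,(T(0) - T_{air}) = \kappa_1 T'(0)$ at the exposed surface and a core
clamp $T(L) = T_{body}$ at the bottom of the stack. Within a layer the
solution is written as

$$T_i(\zeta) = a(\zeta)\,T_i(0) + b(\zeta)\,T_i'(0) + c(\zeta),$$

where $(a, b)$ are the homogeneous propagators — $(1, \zeta)$ for
$B_i = 0$, $(\cosh m\zeta, \sinh(m\zeta)/m)$ with $m = \sqrt{B_i/\kappa_i}$
otherwise — and $c$ collects the metabolic/perfusion offset plus the
electromagnetic particular term $S_i(\zeta)$, defined by
$\kappa S'' - B S = -\rho\,\mathrm{SAR}$ with $S(0) = S'(0) = 0$.
Because the absorption profile is a sum of exponentials
$e^{\pm 2\alpha\zeta}$ and a standing-wave oscillation $e^{2j\beta\zeta}$,
$S_i$ is available in closed form from the unit response to $e^{k\zeta}$;
the removable singularity at $k^2 = m^2$ (physically,
$4\alpha^2\kappa \approx B$) switches to a limit expression when the
denominator is within $10^{-6}$ relative, and small $|k\zeta|$ uses a
series to avoid cancellation.

The $2N$ unknowns (top temperature and gradient of each layer) then solve
a small dense linear system assembled from the surface balance, the
$2(N-1)$ interface continuity conditions for $T$ and $\kappa T'$, and the
core clamp. The reported elevation is
$\Delta T(z) = T_{exposed}(z) - T_{baseline}(z)$, both solved with the
identical assembly, which cancels the metabolic background exactly and
forces $\Delta T(L) = 0$.

### Verification

An independent conservative finite-difference solver (`solve_fd()`,
interfaces on shared nodes, per-interval conductivity, half-cell-weighted
sources, micron-scale cells in the skin block) reproduces the analytic
elevation to well under 0.5 % of the peak on the packaged stacks and on
randomly generated stacks; `validate` in the command-line interface runs
this cross-check on any configuration. The test suite additionally checks
the bioheat ODE residual pointwise, the boundary/interface residuals, the
maximum principle for source-free problems, and second-order convergence
of the finite-difference scheme itself.

## Packaged stacks and the thickness sampler

Three fixtures ship with the package (`fixture_stack()`): a six-layer rat
head model and a six-layer rat dorsal model — epidermis, dermis, dWAT and
panniculus carnosus resolved at micron precision over deep bone/brain or
muscle/bone blocks — and a four-layer human forearm model. Boundary
defaults are $h = 0.5$ W/(m² °C), $T_{air} = 23$ °C,
$T_{blood} = T_{body} = 37$ °C. The human forearm stack reuses the rat
thermal parameter set for the shared tissue types (with the lower muscle
perfusion of deep muscle), since its role is cross-species geometric
comparison rather than human-specific prediction.

`sample_stack()` draws the four skin-layer thicknesses from per-layer
normal distributions (`thickness_distributions()`), truncated below at
$\mu - 3\sigma$ and floored at 1 µm so no draw can produce a vanishing or
negative slab; deep layers stay at their fixture values. Draws are
deterministic in the seed and do not disturb the caller's RNG stream.

## Metrics

* `thermal_resistance()`: $R_i = d_i/\kappa_i$ (°C m²/W).
* `metrics_at()`: transmittance APD/IPD and the heating factor
  $\Delta T(0)/\mathrm{APD}$ (°C m²/W), both independent of the incident
  power by linearity; surface $\Delta T$ at the requested IPD.
* `sweep_frequency()`, `sweep_perfusion()`: band and perfusion
  sensitivities; the perfusion default is 13 log-spaced points over
  300–36300 W/(m³ °C), a rodent physiological range.
* `model_dispersion()`: population relative standard deviation of APD and
  surface $\Delta T$ across a set of stacks.
* `layer_report()`: thickness, $\Delta T$ and APD at each layer top, and
  $R_i$ — a per-layer dosimetry table for any stack and frequency.

## Worked example

```{r example, eval = FALSE}
fit <- solve_dosimetry("rat_head", frequency = c(6, 30, 60, 100) * 1e9,
                       ipd = 1000)
print(fit)
plot(fit, which = "depth")
layer_report(fixture_stack("rat_head"), f = 30e9)
```

## Limitations

* One-dimensional normal incidence only; no oblique incidence,
  polarisation effects, curvature or lateral diffusion.
* Steady state only; no transient heating or thermoregulation dynamics.
* The packaged parametric dielectrics are a documented substitute for
  measured skin values; absolute transmittance and heating-factor levels
  shift with the dielectric source while conservation properties and
  relative/depth-resolved behaviour are robust.
* The frequency band is validated for 6–100 GHz (accepted 1–300 GHz).
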