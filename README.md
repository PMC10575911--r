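# mmwdosim

Analytical millimeter-wave (6–100 GHz) dosimetry for layered skin models:
plane-wave power absorption in a stack of lossy tissue slabs coupled to a
closed-form steady-state solution of the one-dimensional Pennes bioheat
equation.

## What it computes

A normally incident plane wave of incident power density (IPD) `p` hits a
one-dimensional stack of tissue layers (exposure side first). The package:

1. **Electromagnetics** — solves the multilayer reflection/transmission
   problem with a numerically stable impedance-transformation recursion
   (semi-infinite terminal layer, only decaying exponentials, no
   transfer-matrix overflow). Tissue permittivity comes from a packaged
   multi-term Cole-Cole database (dry skin, infiltrated fat, muscle,
   cortical bone, grey matter) or from user-supplied measured tables.
   Outputs: overall reflection, absorbed power density
   `APD = p(1 − |Γ|²)`, transmittance APD/IPD, the SAR depth profile
   `σ|E|²/2ρ`, and the net power flux at any depth.
2. **Bioheat** — solves the steady Pennes equation
   `κT″ + ρ·SAR + A − B(T − T_blood) = 0` per layer, with a convective
   (Robin) balance `h(T(0) − T_air) = κT′(0)` at the surface and a core
   clamp `T(L) = T_body`, **in closed form**: the electromagnetic source is
   a sum of exponentials and a standing-wave oscillation, so the particular
   solution of each layer is analytic and the whole problem reduces to a
   small linear system for the layer-top temperatures and gradients. The
   reported elevation is `ΔT(z) = T_exposed(z) − T_baseline(z)`.
3. **Metrics** — transmittance, heating factor `ΔT(0)/APD` (°C·m²/W),
   per-layer thermal resistance `d/κ`, layer-by-layer report tables,
   frequency sweeps, blood-perfusion sensitivity sweeps, cross-model
   dispersion, and a stochastic sampler for the histologically measured
   skin-layer thickness distributions.

An independent conservative finite-difference solver verifies the analytic
temperature solution (agreement ~0.001 % of peak on the packaged models);
the electromagnetic recursion is verified against a brute-force interface
linear system, Fresnel closed forms, and power conservation at the 1e−9
level.

Three fixtures ship with the package: a six-layer **rat head** model, a
six-layer **rat dorsal** model (epidermis / dermis / dermal white adipose
tissue / panniculus carnosus over deep blocks, micron-resolved), and a
four-layer **human forearm** model for cross-species comparison.

## Worked example

```r
library(mmwdosim)

fit <- solve_dosimetry("rat_head", frequency = c(6, 30, 60, 100) * 1e9,
                       ipd = 1000)
print(fit)
```

```
mmw dosimetry: 6 layers, IPD 1000 W/m^2, 4 frequency point(s)
 frequency      apd transmittance surface_delta_t heating_factor
     6e+09 643.3010     0.6433010        5.694153    0.008851461
     3e+10 554.9050     0.5549050        7.666154    0.013815255
     6e+10 605.8388     0.6058388        8.690711    0.014344922
     1e+11 708.8116     0.7088116       10.287834    0.014514201
```

A per-layer dosimetry table at 30 GHz:

```r
layer_report(fixture_stack("rat_head"), f = 30e9)
```

```
              tissue thickness_um delta_t_top apd_top thermal_resistance
           epidermis         22.8       7.666  554.90          5.429e-05
              dermis        563.4       7.666  524.73          1.341e-03
                dWAT        191.5       7.314  142.74          7.660e-04
 panniculus_carnosus        230.1       7.004  133.37          4.602e-04
                bone       1000.0       6.802   48.21          2.703e-03
               brain       9500.0       5.571   18.17          1.667e-02
```

Cross-checking the closed-form temperature solution against the
finite-difference oracle:

```r
s  <- fixture_stack("rat_head")
em <- solve_stack_em(s, 30e9, 1000)
fd <- delta_T_fd(s, em)
ana <- delta_T(s, 30e9, 1000)
max(abs(delta_t_at(ana, fd$z) - fd$delta_t))   # 5.9e-05 degC on a 7.67 degC peak
```

Other entry points: `sample_stack()` (stochastic thickness draws),
`sweep_frequency()`, `sweep_perfusion()`, `model_dispersion()`,
`read_stack()`/`write_stack()` (YAML stack configs), and a command-line
interface (`mmw_cli()`, launcher in `inst/exec/mmwdosim`) with `run`,
`table3`, `sweep-frequency`, `sweep-perfusion`, `sample-stacks` and
`validate` subcommands, deterministic outputs and a JSON run manifest.

## A note on dielectric provenance

Absolute transmittance and heating-factor levels of skin stacks are
sensitive to the skin permittivity source. The packaged database uses
literature parametric (Cole-Cole) values for dry skin; in-vivo measured
skin dielectrics — which are not part of this package — give noticeably
different absolute levels at these frequencies. Measured values can be
substituted per tissue via `dielectric_table()` + `merge_dielectrics()`.
Conservation properties, depth-resolved structure and sensitivity trends
are robust to this choice; absolute levels are not.

## License

MIT (see `LICENSE`).
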