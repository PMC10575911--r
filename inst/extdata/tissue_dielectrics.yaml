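# Four-term Cole-Cole dispersion parameters for the tissues of the packaged
# layer stacks (parametric tissue-dielectric literature values; valid well
# beyond the 6-100 GHz band used here). sigma_static in S/m, tau in seconds.
# Rodent dWAT resolves to fat_infiltrated, panniculus carnosus to muscle.
skin_dry:
  model: cole_cole
  eps_inf: 4.0
  sigma_static: 0.0002
  terms:
    - {delta_eps: 32.0, tau: 7.234e-12, alpha: 0.00}
    - {delta_eps: 1100.0, tau: 3.2481e-8, alpha: 0.20}
    - {delta_eps: 0.0, tau: 1.59155e-4, alpha: 0.20}
    - {delta_eps: 0.0, tau: 1.5915e-2, alpha: 0.20}
fat_infiltrated:
  model: cole_cole
  eps_inf: 2.5
  sigma_static: 0.035
  terms:
    - {delta_eps: 9.0, tau: 7.958e-12, alpha: 0.20}
    - {delta_eps: 35.0, tau: 1.5915e-8, alpha: 0.10}
    - {delta_eps: 3.3e+4, tau: 1.59155e-4, alpha: 0.05}
    - {delta_eps: 1.0e+7, tau: 1.5915e-2, alpha: 0.01}
muscle:
  model: cole_cole
  eps_inf: 4.0
  sigma_static: 0.2
  terms:
    - {delta_eps: 50.0, tau: 7.234e-12, alpha: 0.10}
    - {delta_eps: 7000.0, tau: 3.53678e-7, alpha: 0.10}
    - {delta_eps: 1.2e+6, tau: 3.1831e-4, alpha: 0.10}
    - {delta_eps: 2.5e+7, tau: 2.2736e-3, alpha: 0.00}
bone_cortical:
  model: cole_cole
  eps_inf: 2.5
  sigma_static: 0.02
  terms:
    - {delta_eps: 10.0, tau: 1.3263e-11, alpha: 0.20}
    - {delta_eps: 180.0, tau: 7.9577e-8, alpha: 0.20}
    - {delta_eps: 5.0e+3, tau: 1.59155e-4, alpha: 0.20}
    - {delta_eps: 1.0e+5, tau: 1.5915e-2, alpha: 0.00}
brain_grey_matter:
  model: cole_cole
  eps_inf: 4.0
  sigma_static: 0.02
  terms:
    - {delta_eps: 45.0, tau: 7.958e-12, alpha: 0.10}
    - {delta_eps: 400.0, tau: 1.5915e-8, alpha: 0.15}
    - {delta_eps: 2.0e+5, tau: 1.06103e-4, alpha: 0.22}
    - {delta_eps: 4.5e+7, tau: 5.3052e-3, alpha: 0.00}
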