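# viabsim

Continuum modelling and parameter estimation of in vitro cancer-cell
viability under chemotherapeutic treatment.

Adherent cultures monitored by impedance-based real-time cell analysis
(RTCA) report a normalized cell index (NCI) proportional to the attached,
viable cell mass; Annexin V/PI flow cytometry snapshots the same culture
as four fractions (viable, early apoptotic, late apoptotic, necrotic).
viabsim ties the two modalities to a two-phase avascular growth model so
that treatments can be compared through fitted model parameters rather
than raw curves. It is aimed at modellers and quantitative biologists who
want a tested, reproducible pipeline from culture image + viability data
to parameter estimates and sensitivity statements.

## Model

The cell concentration α ∈ [0,1] at each grid node evolves as

    dα/dt = (1+s₁) α (1−α) C / (1+s₁C)  −  (s₂+s₃C) α / (1+s₄C)

(growth − death; cell motion neglected, as for a stably attached
monolayer), coupled to a quasi-steady oxygen field C solved from

    ∇²C = Q α C / (1+Q₁C),   C = 1 on medium nodes,  ∂C/∂n = 0 on walls.

Percent viability is the α-mass of the field relative to the t = 0
(treatment-time) field — the model-side analogue of NCI × 100. Parameters
are estimated by minimizing the sum of squared viability errors
SE = Σᵢ (Vᵢᵉ − Vᵢˢ)² over five RTCA points (24–72 h) and optionally two
pooled flow points (24, 72 h; early apoptotic counted as viable), using
seeded Latin-hypercube multistart L-BFGS-B followed by Nelder–Mead
refinement. Q, Q₁ are fitted only for control cultures and frozen for
treatments; one-at-a-time ±75 % sensitivity analysis quantifies each
parameter's influence on the 72-h viability.

## Worked example

```r
library(viabsim)

# synthetic culture image -> initial state on a 15x15 grid
img    <- generate_blob_image(64, 64, 6, seed = 1)
state0 <- image_to_alpha0(img, sim_grid(15, 15))

# generate treated-culture data with known truth (declining viability)
truth <- model_params(s1 = 1, s2 = 0.4, s3 = 0.35, s4 = 0)
sc    <- synth_config(truth, noise_sigma = 0, dirichlet_conc = Inf, seed = 11)
rtca  <- generate_rtca(state0, sim_config(), sc)
flow  <- generate_flow(state0, sim_config(), sc)
round(rtca$fit$viability_pct, 2)
#> [1] 50.06 50.00 50.00 50.00 50.00

# refit s1..s4 with oxygen parameters frozen at the control values (0 here)
fit <- estimate_treatment(list(rtca$fit, flow$series), state0, sim_config(),
                          frozen_q = c(0, 0),
                          opt = optimizer_config(n_starts = 8, seed = 3))
fit$se
#> [1] 3.294111e-21
```

The five fit-point viabilities start at ~50 % of the treatment-time mass
(the truth's death terms outweigh growth, steady state α = 0.25 from
α₀ = 0.5) and the refit reproduces the generating curve to machine-level
SE — the parameters themselves are only weakly identifiable from seven
points, so the package's recovery claims are about the predicted curve.

Sensitivity around the aerobic control:

```r
sens <- oat_sensitivity(example_params("control"), state0, sim_config())
round(sens$spans, 2)
#>    s1    s2    s3    s4     Q    Q1
#>  0.10 30.10 59.97 52.28  0.12  0.16
```

The death parameters (s₂–s₄) dominate; growth saturation and oxygen
consumption barely move the 72-h viability under aerobic conditions.

A command-line interface wraps the same functions
(`inst/cli/viabsim.R`): subcommands `simulate`, `fit`, `sensitivity`,
`synth` over a YAML config, every output embedding the resolved config
and seed, byte-reproducible per seed.

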