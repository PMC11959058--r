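# sweatkin

Mechanistic estimation of **blood urea from sweat urea** for non-invasive
hemodialysis monitoring.

Patients with end-stage renal disease have dialysis adequacy judged by the
fall in blood urea across a session, which normally requires repeated blood
draws. Sweat carries urea too — but at concentrations typically *above*
plasma, so it cannot be read off directly: on top of passive
convection–diffusion there is an active secretion component. `sweatkin`
implements a three-compartment kinetic transport model (blood capillary →
interstitial fluid → sweat gland) and inverts it, estimating the blood urea
concentration that produced a measured sweat urea concentration. It is
aimed at researchers developing sweat-sensing assays and at modellers
studying biomarker partitioning between blood and sweat.

## The model

Water flows by Starling filtration into the interstitium,
`Q = L_pc · A_c · (P_c − P_ISF)`, and through the gland duct by
Darcy/Poiseuille flow, `Q_sg = ΔP/R` with `R = 128 μ L/(π d⁴)`, scaled by
the measured normalized sweat velocity `u_sweat,n`. Urea obeys coupled 1-D
convection–diffusion equations: the interstitial compartment is fed by
plasma at rate `k_DE (C_p − C_ISF) V_p`; the secretory coil equilibrates
passively with the interstitium across the gland wall (Fick,
`D_sg,wall ΔC / h_sg`); the coil content is diluted by co-transported water
by the factor `1 + K_w/u / u_sg,n`; and urea transporters inject urea along
the duct at volumetric rate `S` (mmol L⁻¹ s⁻¹). The readout is the diluted
concentration at the duct exit.

With `S = 0` sweat always sits *below* blood (dilution); physiological
`S ≈ 0.2–0.5` lifts it above at post-dialysis plasma levels — which is why
a passive-only inverse model systematically overestimates blood urea, and
an estimate of `S` is carried along with the blood-urea estimate.

The inverse uses a **double-loop optimization**: loop 1 inverts the
monotone forward model for blood urea; loop 2 refines a sensitivity-ranked
subset of transport parameters (`S`, `D_sw`, `K_w/u`) under a
sensitivity-scaled ridge prior that resolves the single-observation
identifiability ambiguity. Convergence requires the squared sweat error
below 0.01 mmol²/L² plus stationarity; final estimates are independent of
the loop-1 starting value.

## Worked example

```r
library(sweatkin)

# forward: what sweat concentration does a post-dialysis patient produce?
sim <- simulate_sweat(6.4, default_parameters(S = 0.36))
sim
#> <sweat_simulation>
#>   C_blood  6.4 mmol/L  ->  C_sweat  6.62 mmol/L
#>   u_sg 0.0003 m/s (u_sg_n 1), dilution x3.5
#>   modes: pressure fixed, S buffered; converged TRUE in 2 steps; ...

# inverse: recover blood urea from the sweat measurement
estimate_blood_urea(sim$C_sweat)
#> <sweat_estimate>
#>   measured sweat 6.62 mmol/L -> blood estimate 6.4 mmol/L
#>   mode full; S = 0.36; error 7.89e-31 after 29 outer iterations (converged)

# a passive-only comparator must inflate blood urea to explain sweat > blood
estimate_blood_urea(sim$C_sweat, mode = "passive")
#> <sweat_estimate>
#>   measured sweat 6.62 mmol/L -> blood estimate 23.27 mmol/L
#>   mode passive; S = 0; error 3.82e-28 after 4 outer iterations (converged)
```

The forward readout is 6.62 mmol/L — slightly *above* the 6.4 mmol/L blood
level, the signature of active transport. The full inverse recovers the
blood value essentially exactly; the passive comparator lands at 23.3
mmol/L, a ~3.6-fold overestimate set by the water-dilution factor.

End-to-end on a synthetic dialysis cohort (paired pre/post samples, 5%
sweat measurement noise, active transport rate known per sample):

```r
co  <- generate_cohort(cohort_spec(n_patients = 6, seed = 7,
                                   missing_sweat_fraction = 0))
est <- estimate_cohort(co$samples, truth = co$truth)
glance(evaluate_estimates(est))
#> # A tibble: 1 × 9
#>       n  rmse rmspe     r ci_lo ci_hi   bias loa_lo loa_hi
#>   <int> <dbl> <dbl> <dbl> <dbl> <dbl>  <dbl>  <dbl>  <dbl>
#> 1    12 0.537  5.86 0.999 0.995 1.000 -0.112  -1.19  0.965
```

RMSE 0.54 mmol/L and RMSPE 5.9% against the generating blood values, with
a near-unit correlation and a clinically irrelevant bias — the noise-driven
floor of the inversion. `plot_estimates()`, `plot_bland_altman()` and
`plot_sensitivity()` render the standard figures; `tidy()`/`glance()`
methods expose every result as a tibble.

A thin command-line interface (`exec/sweatkin`) wraps the same functions:
`sweatkin synth`, `simulate`, `estimate`, `evaluate`, `sensitivity`,
`robustness`, `params`.

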