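# dpaintsim

Treatment-simulation pipeline for hypofractionated prostate radiotherapy,
comparing **dose painting by numbers (DPBN)** against homogeneous
prescriptions under **conventional** (plan once, deliver with rigid
marker-based alignment) and **adaptive** (re-plan daily on the
anatomy-of-the-day) workflows. It is aimed at medical-physics researchers
who want to study workflow mechanisms — target misses, rectum dose-volume
bookkeeping under organ deformation, robust-optimization trade-offs — on a
fully synthetic, seeded phantom where the geometric ground truth is known.

## The model

Tumor control probability is a voxel product over the prostate CTV and
seminal vesicles,

    TCP = prod_i [ sum_g P(g | ADC_i) * S_g(E_i) ] ^ (v_i / v_ref),

where `E_i` is the accumulated EQD2 of voxel `i`
(`E = D (d + α/β) / (2 + α/β)`, `d = D/N`, `α/β = 1.93 Gy`),
`P(g | ADC)` an ordinal-logistic posterior over Gleason categories GS6–GS9
(low ADC ⇒ high grade), and `S_g` logistic control curves in EQD2 calibrated
at `v_ref = 1 cm³`. DPBN plans maximize the worst-case TCP over a setup-error
scenario set ("minimax", only the TCP objective is robust) under hard rectum
constraints `V33Gy < 30%`, `V38Gy < 15%`, `V41Gy < 10%` — the
*treat-to-tolerance* aim, with no upper bound on prostate voxel dose.
Homogeneous plans cover a PTV built with the van Herk margin
`M = 2.5 Σ_eff + 0.7 σ_eff`, with effective components for `N = 7` fractions
(`Σ_eff² = Σ² + σ²/N`, `σ_eff² = σ² (1 − 1/N)`); the shipped uncertainty
budgets give 3 mm (adaptive) and 6 mm (conventional) margins. Courses are
simulated per fraction with sampled execution errors, fraction doses are
mapped to the reference frame along ground-truth deformation fields, and
EQD2/physical dose is accumulated for TCP and DVH endpoints.

See `vignettes/methods.Rmd` for the full model description, parameter
tables and design rationale.

## Worked example

```r
library(dpaintsim)

case <- generate_fractions(generate_case(seed = 1))   # anatomy + ADC + 7 fractions
case
#> Case case-1: prostate 37.2 cm^3, SV 9.7, rectum 45.4, bladder 83.2; ADC mean 1073

margin_from_budget(build_budget("adaptive"))
#> adaptive margin: Sigma_eff 0.655 mm, sigma_eff 1.604 mm, raw 2.759 mm -> 3 mm
margin_from_budget(build_budget("conventional"))
#> conventional margin: Sigma_eff 1.813 mm, sigma_eff 1.309 mm, raw 5.448 mm -> 6 mm

eqd2_convert(43.89, 7, alpha_beta = 1.93)   # prescription level in EQD2
#> [1] 91.5771

engine <- case_engine(case)
conv <- simulate_course(case, "DPBN-conv", engine)
adap <- simulate_course(case, "DPBN-adap", engine)
rbind(course_endpoints(conv, case), course_endpoints(adap, case))
#>     case       arm       tcp rectum_V33 rectum_V38 rectum_V41 prostate_Dmean ...
#> 1 case-1 DPBN-conv 0.9997918       8.63       3.99       2.14       55.88
#> 2 case-1 DPBN-adap 0.9997351       2.68       0.54       0.00       55.65
```

Both workflows reach TCP above 99.9% on this case; the adaptive course
spares the rectum more (accumulated `V33Gy` 2.7% vs 8.6%) because each
daily plan conforms to that day's rectum. The per-fraction breakdown
(`per_fraction_endpoints()`) and the volume-change analysis
(`vad_volume_change()`) expose the mechanisms behind differences between
planned and delivered rectum metrics. An engineered over-margin fraction
shows the target-miss mechanism:

```r
miss <- target_miss_experiment(generate_case(seed = 3))
c(conv = miss$tcp_conventional, adap = miss$tcp_adaptive)
#>         conv         adap
#> 0.0002155015 0.9998706354
```

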