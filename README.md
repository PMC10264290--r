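# dissectflow

Calibration of grouped three-element Windkessel (WK3) outlet boundary
conditions for patient-specific aortic flow models, and the haemodynamic
metric suite used to analyse the results — built for studies of type-B
aortic dissection (TBAD), where the descending aorta is split into a true
lumen (TL) and a false lumen (FL) and where dozens of minor branches
(intercostal/subcostal/lumbar segmentals, the inferior mesenteric artery)
together drain a clinically significant fraction of stroke volume.

It is aimed at cardiovascular-modelling groups who need the
*around-the-solver* machinery to be reproducible and testable: target
derivation from 4D-flow measurements, 0D surrogate simulation, automatic
outlet tuning, moving-plane registration, and the standard metric suite
(forward/reverse flow, FLEF, transmural pressure, TAWSS/OSI/ECAP,
Bland–Altman agreement), with deterministic synthetic generators so every
stage can be verified offline with closed-form ground truth.

## The model in brief

Each outlet group is a WK3 — proximal resistance `R_p = ρ·R_tot` in
series with parallel distal resistance `R_d = (1−ρ)·R_tot` and compliance
`C` — and all outlets share one inlet node driven by a periodic inflow
`Q_in(t)`:

    C_i dPc_i/dt = (P − Pc_i)/R_p,i − (Pc_i − P_ven)/R_d,i
    P = (Q_in + Σ Pc_i/R_p,i) / Σ (1/R_p,i)

integrated with BDF2 at 1 ms to cyclic periodicity (systolic and
diastolic inlet pressure changing < 1 % between cycles). At periodic
steady state each outlet's mean flow is `(P̄ − P_ven)/R_tot,i`, so the
mean split depends only on the resistances; the tuner exploits this by
fixing `R_tot,i ∝ 1/Q̄_i` (flow split exact by construction), spreading
compliance at equal `R·C` time constants, and alternating two global
scale factors until the systolic/diastolic targets from the brachial
back-transform `P_s = 0.83·P′_s + 0.15·P′_d`, `P_d = P′_d` are met.

Flow targets: grouped branch fractions `φ_B = Q̄′_B / Σ_Γ Q̄′` re-based on
the inter-plane flow loss, `Q̄_B = φ_B·Q̄′_Γ`; minor-branch groups use
literature Doppler flows. Metrics: `Q = Σ (v·n)A`, `Q = Q_F − Q_R`,
`R/F = Q_R/Q_F` (FLEF = cycle-averaged R/F at the primary entry tear),
`TMP = P_TL − P_FL`, `TAWSS = (1/T)∫|τ|dt`,
`OSI = ½(1 − |∫τdt|/∫|τ|dt)`, `ECAP = OSI/TAWSS` (1.4 Pa⁻¹ threshold),
Carreau–Yasuda viscosity, and a Womersley-number power law for the
pulsatile critical Reynolds number.

## Worked example

Calibrate the packaged 16-outlet study case (major branches plus grouped
minor branches) against its printed flow targets and the brachial
measurement 138/81 mmHg:

```r
library(dissectflow)
library(dplyr)

# brachial cuff -> aortic inlet targets
pt <- aortic_pressure_targets(138, 81) |> format_pressure_targets()
pt
#> # A tibble: 1 × 5
#>   brachial_systolic_mmHg brachial_diastolic_mmHg systolic_mmHg diastolic_mmHg
#> 1                    138                      81           127             81
#> # pulse_mmHg: 46

# tune WK3 parameters for the 16 grouped outlets
tab <- study_wk3_table("D_min")
targets <- tibble(outlet = tab$outlet,
                  target_flow_mL_s = tab$target_flow_mL_s, rho = tab$rho)
wf <- gen_inflow(synth_spec(heart_rate = 94,
                            stroke_volume_mL = sum(targets$target_flow_mL_s) * 60 / 94))
fit <- tune_wk3(targets, pt, wf)
glance(fit)
#> # A tibble: 1 × 7
#>   p_sys_mmHg p_dia_mmHg p_sys_target_mmHg p_dia_target_mmHg max_flow_deviation
#> 1       128.       81.0               127                81            0.00344
#> # iterations: 5-ish, converged: TRUE

tidy(fit) |> select(outlet, r_total_mmHg_per_mL_s, c_mL_per_mmHg,
                    target_flow_mL_s, mean_flow_mL_s) |> head(3)
#> # A tibble: 3 × 5
#>   outlet r_total_mmHg_per_mL_s c_mL_per_mmHg target_flow_mL_s mean_flow_mL_s
#> 1 BT                      5.83        0.271             17.1           17.1
#> 2 LCC                    26.0         0.0608             3.84           3.84
#> 3 LSA                    14.9         0.106              6.69           6.69
```

The achieved inlet pressures sit within 1 mmHg of the 127/81 mmHg
targets and every outlet's cycle-mean flow within 0.4 % of its target;
the recovered resistances land within ~1 % of the study's published
calibration (e.g. BT 5.83 vs 5.77 mmHg·s/mL), with compliances differing
more because the pulse response also depends on the waveform shape,
which is synthetic here.

Synthetic data with known truth exercises the metric suite end to end:

```r
gen <- gen_plane_series(synth_spec(seed = 1))        # moving two-lumen plane
reg <- register_series(gen$series, reference = gen$reference)
flef(flow_decomposition(reg))                        # FL ejection fraction, %
wss <- gen_wss_history(synth_spec(seed = 1))
wss_metrics(wss$history) |> ecap_exceeds()           # TAWSS / OSI / ECAP maps
```

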