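# spirped

Model-informed design tools for a pediatric pharmacokinetic trial of a
spironolactone oral suspension.

## What this is for

Spironolactone (SPIR) has been dosed off-label in children for decades
without pediatric PK data or an approved liquid formulation. Planning a
first pediatric trial of the oral suspension (children 2 to <17 years with
edema from heart failure or liver cirrhosis) requires choosing doses and
blood-sampling times before any pediatric concentrations exist. `spirped`
provides the simulation machinery for that problem, aimed at
pharmacometricians and trial designers:

* a deterministic parent–metabolite model for SPIR and its active
  metabolite canrenone (CAN): first-order absorption with lag into
  two-compartment SPIR disposition, a fixed fraction metabolized
  `Fm = 0.7` feeding two-compartment CAN disposition, with total parent
  clearance `CLtot = CL·(1−Fm) + CLM1·Fm = 629·0.3 + 217·0.7 = 340.6 L/h`
  at the adult typical values;
* log-normal between-subject variability with a CL–V2 covariance and
  proportional residual error per analyte, carried unchanged from adults to
  children;
* allometric bridging `P_ped = P_adult (WT/70)^b` with `b = 0.75` for
  clearances and `b = 1` for volumes, plus the shipped median weights for
  the eight reference age/sex cells;
* what-if scenario modifiers for cirrhosis (CL −84.44%, CLM1 −37.76%,
  CLM −71.55%) and food (ka −93.5%, Fm −60%, bioavailability ×2);
* Monte Carlo dose selection: noncompartmental AUC of simulated pediatric
  cohorts compared against adult 25 mg and 100 mg reference exposure bands;
* a windowed sparse sampling design (6 samples/subject in adolescents, 5 in
  younger groups) evaluated by first-order population Fisher information
  and by simulation/re-estimation.

## Worked example

```r
library(spirped)
p <- adult_params()
total_clearance(p)
#> [1] 340.6

scenario_halflife_report(p, scenario_spec(cirrhotic = TRUE))
#>   analyte         scenario disposition_slope disposition_halflife
#> 1    SPIR cirrhotic_fasted       0.058961835             11.75586
#> 2     CAN cirrhotic_fasted       0.007296906             94.99192
```

Reduced cirrhotic clearances stretch the SPIR disposition half-life from
7.8 h (healthy) to 11.8 h and CAN from 30 h to 95 h — the qualitative
pattern reported in cirrhotic adults.

Dose selection: simulate 200 children per reference age at 0.5 and
1.5 mg/kg and compare mean AUC (mg·h/L) against adult reference bands:

```r
set.seed(1)
sw <- dose_sweep(doses_mg_per_kg = c(0.5, 1.5), n_per_sex = 100)
subset(sw, dose_mg_per_kg == 0.5 & ref_dose_mg == 25 & analyte == "SPIR")
#>  age   n   mean     sd ref_p5 ref_p95 inside_pi
#>    2 200 0.0694 0.0210 0.0429   0.122      TRUE
#>    6 200 0.0775 0.0240 0.0429   0.122      TRUE
#>   12 200 0.0945 0.0283 0.0429   0.122      TRUE
#>   17 200 0.0981 0.0294 0.0429   0.122      TRUE
```

At 0.5 mg/kg every age's mean SPIR AUC lies inside the adult 25 mg 5th–95th
prediction band (`inside_pi`), i.e. the low pediatric dose reproduces the
adult 25 mg exposure — the same holds for CAN and for 1.5 mg/kg against
100 mg.

Design precision: expected %RSE of the structural parameters under the
sparse windowed scheme (18 subjects, 0.5 mg/kg):

```r
set.seed(2)
fim <- expected_rse_fim(design_from_schemes(design_cohort(6), 0.5))
round(fim$rse, 1)
#>   cl clm1   v2  clm   v4   ka
#> 11.7 12.2 11.7  9.6 12.1 29.4
```

All below 35%, with the absorption rate constant (largest between-subject
variance) dominating.

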