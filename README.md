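# RubiscoTherm

Tools for two questions about Rubisco, the CO₂-fixing enzyme of the
Calvin–Benson–Bassham cycle, in organisms that carry several enzyme forms
(II, carboxysomal IAc, cytosolic IAq):

1. **Under which CO₂ / O₂ / temperature conditions does each Rubisco form
   fix carbon fastest — and where does autotrophy become impossible?**
   The package models gross carboxylation with competitive O₂ inhibition,

   *R_C = k_cat,C · [CO₂] / ([CO₂] + K_C + K_C·[O₂]/K_O)*,

   derives the oxygenation rate from the specificity factor
   *S_C/O = (k_cat,C·K_O)/(k_cat,O·K_C)*, subtracts the carbon cost of
   phosphoglycolate salvage (0.5 CO₂ per oxygenation for the C2 cycle),

   *f = R_C − 0.5·R_O = R_C·(1 − [O₂]/(2·S_C/O·[CO₂]))*,

   and scales every kinetic parameter with its own calibrated Arrhenius law
   *x(T) = exp(c − ΔH/(R·T))*. Two forms are then compared cell-by-cell
   over CO₂ × O₂ grids at chosen temperatures, including the "gray" region
   where both forms lose carbon (f ≤ 0).

2. **Does a Rubisco protein sequence carry a signal of cold or hot
   adaptation?** Ten amino-acid indices (Gly/Pro/Ser counts, acidic,
   charged and polar-uncharged residue counts, Ikai aliphatic index,
   aromaticity, Kyte–Doolittle GRAVY, isoelectric point) are tested per
   sequence against a per-form mesophilic reference (one-sample t-test;
   any deviation counts when the reference SE is 0). Each significant
   index scores ±1 by direction; totals ≥ +3 are cold-inferred, ≤ −3
   hot-inferred, otherwise neutral.

A seed-deterministic synthetic-data module (multinomial sequence generator
with controlled composition shifts; random valid kinetic parameter sets)
makes the whole pipeline testable offline, and a small CLI
(`inst/scripts/rubiscotherm`) exposes the stages
(`simulate`, `build-reference`, `score`, `grid`).

The package is for microbial ecologists and enzymologists comparing Rubisco
forms across environments (e.g. cold brines vs hydrothermal vents) and for
anyone screening protein cohorts for composition-level thermal signatures.

## Worked example

```r
library(RubiscoTherm)

# Arrhenius calibration: turnover 2.98 1/s at 303.15 K, ΔH = 47.2 kJ/mol
calibrateArrhenius(2.98, temp_ref_k = 303.15, delta_h = 47.2)
#> ArrheniusLaw: x(T) = exp(19.8192 - 47.20/(R*T)), R = 0.008314 kJ/mol/K

# Compare form II against form IAc on the default CO2 x O2 grid
models <- readKineticTable(system.file("extdata", "example_kinetics.tsv",
                                       package = "RubiscoTherm"))
compareForms(models$II$model, models$IAc$model, defaultGridSpec(), temp_c = 25)
#> ComparisonGrid II - IAc (net rates) at 25.0 degC: 64 x 64 cells
#>   diff range [-0.7906, 10.63] C/s; both non-viable in 1096 cells
compareForms(models$II$model, models$IAc$model, defaultGridSpec(), temp_c = 0)
#> ComparisonGrid II - IAc (net rates) at 0.0 degC: 64 x 64 cells
#>   diff range [-0.1515, 0.7028] C/s; both non-viable in 978 cells
```

At 25 °C form II fixes up to ~10.6 C/s more per active site than form IAc
(at high CO₂), while IAc wins by up to ~0.8 C/s in the low-CO₂/high-O₂
corner; at 0 °C the spread collapses below 1 C/s. 1096 of 4096 cells at
25 °C are non-viable for both forms (net carbon loss). The bundled
parameter file holds clearly labeled synthetic example values, not
published measurements — swap in your own TSV for real enzymes.

```r
# Score a synthetic cohort: 5 reference + 10 baseline + 10 cold-shifted
cohort  <- generateCohort(seed = 1)
records <- assembleRecords(cohort$fasta, cohort$metadata)
res <- scoreCohort(records, buildReferencesFromRecords(records))
str(res$summary)
#> List of 4
#>  $ n_scored         : int 20
#>  $ counts           :List of 3
#>   ..$ cold   : int 11
#>   ..$ hot    : int 1
#>   ..$ neutral: int 8
#>  $ n_skipped        : int 0
#>  $ median_cold_total: int 8
```

All 10 cold-shifted sequences (plus one baseline false positive) classify
cold with a median total of +8; 8 of the 10 baseline sequences stay
neutral. See the methods vignette
(`vignettes/rubisco-tradeoffs-and-thermal-scoring.Rmd`) for the model,
assumptions, parameter choices and what the synthetic cohort does and does
not demonstrate.

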