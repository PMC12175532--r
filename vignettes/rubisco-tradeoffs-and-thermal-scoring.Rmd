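---
title: "Modeling Rubisco form trade-offs and scoring thermal adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Rubisco form trade-offs and scoring thermal adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RubiscoTherm)
```

# The scientific problem

Rubisco (ribulose 1,5-bisphosphate carboxylase/oxygenase) fixes CO~2~ in the
Calvin–Benson–Bassham cycle, but the same active site also reacts with O~2~.
Chemoautotrophic bacteria such as *Thiomicrorhabdus* often carry several
Rubisco forms (II, carboxysomal IAc, cytosolic IAq) whose kinetics trade
speed against CO~2~/O~2~ specificity. Which form fixes carbon fastest
therefore depends on the ambient CO~2~ and O~2~ concentrations and on
temperature. This package provides two analysis tracks around that question:

1. a **kinetic trade-off model** that computes net carboxylation per active
   site for any enzyme form across CO~2~ × O~2~ × temperature conditions and
   compares forms cell by cell, and
2. a **thermal-adaptation scoring pipeline** that tests ten amino-acid
   composition and physicochemical indices of a Rubisco protein against a
   mesophilic reference and classifies the sequence as cold-inferred,
   hot-inferred or neutral.

# The kinetic model

## Rate laws

Carboxylation is Michaelis–Menten with O~2~ as a competitive inhibitor:

$$R_C = \frac{k_{cat,C}\,[\mathrm{CO_2}]}
{[\mathrm{CO_2}] + K_C + K_C\,[\mathrm{O_2}]/K_O}$$

and symmetrically for oxygenation,

$$R_O = \frac{k_{cat,O}\,[\mathrm{O_2}]}
{[\mathrm{O_2}] + K_O + K_O\,[\mathrm{CO_2}]/K_C}.$$

$k_{cat,O}$ is rarely measured; it is recovered from the routinely measured
specificity factor $S_{C/O} = (k_{cat,C} K_O)/(k_{cat,O} K_C)$. A useful
consequence, which the package verifies as a property test over random
parameter draws, is the identity

$$\frac{R_C}{R_O} = S_{C/O}\,\frac{[\mathrm{CO_2}]}{[\mathrm{O_2}]},$$

valid at *any* concentrations, not only in the low-substrate limit: the
inhibition cross-terms make the two denominators proportional.

## Phosphoglycolate salvage and net fixation

Each oxygenation produces 2-phosphoglycolate that must be salvaged. In the
C2 cycle one CO~2~ is lost per two 2-PG molecules, i.e. 0.5 CO~2~ per
oxygenation, so the net fixation rate is

$$f = R_C - 0.5\,R_O
    = R_C\left(1 - \frac{[\mathrm{O_2}]}{2\,S_{C/O}\,[\mathrm{CO_2}]}\right).$$

The difference form is used internally so `[CO2] = 0` stays well defined.
$f$ changes sign exactly on the line
$[\mathrm{CO_2}]/[\mathrm{O_2}] = 0.5/S_{C/O}$; $f \le 0$ is classified
non-viable (autotrophy impossible), including the exact break-even point.
The loss ratio is configurable (`pgsModel()`): 0 disables salvage
accounting, and other salvage pathways with different stoichiometries can be
expressed through the same parameter.

## Temperature scaling

Each kinetic parameter ($k_{cat,C}$, $K_C$, $K_O$, $k_{cat,O}$) gets its own
Arrhenius law $x(T) = e^{\,c - \Delta H/(RT)}$ with
$R = 0.008314$ kJ/mol/K. The constant $c$ is calibrated by anchoring the
law to a reported value at its reference temperature:
$c = \ln x_{ref} + \Delta H/(R\,T_{ref})$, which reproduces $x_{ref}$
exactly on round trip. Design choices worth stating:

* Each reported value carries its **own** reference temperature, because
  published kinetics of one enzyme are commonly assayed at different
  temperatures (e.g. a turnover at 30 °C with affinities at 25 °C).
* $k_{cat,O}$ is never a user input. Its reference value comes from the
  specificity identity applied to the reported values and is anchored at
  the $k_{cat,C}$ reference temperature; its $\Delta H$ must be given
  explicitly (there is no sensible default).
* $S_{C/O}$ is not scaled directly: at any temperature it is re-derived
  from the four scaled parameters, so its effective enthalpy is
  $\Delta H_{kcat,C} + \Delta H_{K_O} - \Delta H_{kcat,O} - \Delta H_{K_C}$.
* Enthalpies for carboxysomal and cytosolic form IA enzymes are usually
  reported only at the form-IA level; the parameter-file loader lets `IAc`
  and `IAq` fall back to shared `IA` rows.

Units: concentrations and half-saturations are micromolar throughout (the
loader converts mM), temperatures are Celsius at the interface and kelvin
internally.

## Grids and the bundled example parameters

`compareForms()` evaluates two forms on a CO~2~ × O~2~ grid at one
temperature and returns per-cell differences plus viability masks;
`maxAbsDifference()` and `nonviableRegion()` summarise the result. The
default grid is CO~2~ log-spaced 0.1–10 000 µM and O~2~ linear 0–500 µM
(64 × 64), spanning reported habitat ranges (O~2~ up to ~0.6 mM, CO~2~ into
the millimolar range) plus the low-CO~2~ region where net fixation turns
negative.

`inst/extdata/example_kinetics.tsv` is a **synthetic, clearly labeled
example**, not a set of published measurements: full kinetic constants for
all three forms of the relevant organisms are only available in
supplementary material we do not redistribute. The example values were
chosen once from field-typical ranges with the qualitative structure the
literature reports — form II fast (13.1 s⁻¹ at 25 °C) with low specificity
(S~C/O~ ≈ 10) and weak O~2~ affinity; form IAc slow (2.98 s⁻¹ at 30 °C)
with high specificity (≈ 47); form IAq slower still with intermediate
specificity; form II's turnover more temperature-sensitive (67.4 vs
47.2 kJ/mol) and its specificity declining less steeply with warming. With
these inputs the model reproduces the expected pattern: form II leads nearly
everywhere in gross rate; with C2-cycle salvage included, form IAc overtakes
form II only at low CO~2~ under oxygenation at 25 °C; the form II lead
collapses from ~11 C/s at 25 °C to under 1 C/s at 0 °C; and form IAq is
never the fastest viable form.

# Thermal-adaptation scoring

## The ten indices

For each protein the package computes: counts of glycine, proline, serine,
acidic (D,E), charged (D,E,H,K,R) and polar uncharged (C,N,Q,S,T,Y)
residues; the Ikai aliphatic index
$X_{Ala} + 2.9 X_{Val} + 3.9 (X_{Ile}+X_{Leu})$ in mole percent;
aromaticity (fraction F,W,Y); GRAVY (mean Kyte–Doolittle hydropathy); and
the isoelectric point. Counts are raw residue counts, not length-normalized
— comparisons are within one enzyme form, where lengths are similar, and
the synthetic generator emits fixed-length cohorts. Form I analyses
concatenate the large and small subunits (large first); form II uses the
large subunit alone. Sequences are sanitized first: gaps and terminal stops
are stripped, and ambiguity codes (B, Z, X, U, O) are dropped from counts
and from every length denominator.

The pI is found by bisection of the net-charge function on pH ∈ [0, 14] to
|charge| < 10⁻⁴, using the Bjellqvist (ProtParam) pKa constants with
residue-specific terminal overrides; the scale is swappable
(`bjellqvistScale()` documents the structure). Unlike some implementations
that bracket the search to a fixed pH window, the bisection covers the full
range, so extreme compositions get the true root of the charge function.

## References, tests and classification

A mesophilic reference per form holds each index's mean, standard error
(sample SD/√n) and n over designated reference sequences. A one-sample
t-test (df = n − 1, two-sided) compares a test sequence's index value
against the reference; when the reference SE is 0 a p-value cannot be
computed and **any** deviation counts as significant (a rule that actually
occurs in practice with small reference sets). A reference built from one
sequence is allowed but warned about, since every index then falls under
the SE = 0 rule.

Each significant index scores +1 if it deviates in its cold direction and
−1 in its hot direction (direction table overridable by YAML config; the
defaults encode the conventional psychrophile signatures — more Gly, Ser,
acidic and polar residues, fewer Pro, charged and aromatic residues, lower
aliphatic index, GRAVY and pI). The summed score over the ten indices
classifies the sequence: ≥ +3 cold-inferred, ≤ −3 hot-inferred, −2…2
neutral; the boundary values belong to the inferred classes. α defaults to
0.05 and is exposed everywhere.

Two statistical caveats are inherent to the method and worth knowing. The
t-test treats the test sequence's index value as a fixed quantity, ignoring
its own sampling variability, which inflates the per-index false-positive
rate beyond α for short sequences. And because the ten indices share
residues (charged ⊃ acidic, aromaticity overlaps GRAVY, pI depends on the
charged groups), per-index scores are correlated — the total is a robust
composite signal, not a count of independent tests.

# The synthetic-data generator

The generator exists so every pipeline stage is testable offline with known
ground truth. Sequences are drawn residue-by-residue (i.i.d. multinomial)
from a 20-letter composition profile; the default baseline composition
comes from a bundled, fixed synthetic 460-residue sequence with a typical
bacterial Rubisco-like composition (`synthetic_form2_baseline.faa`,
editable by pointing `baselineComposition()` at any FASTA). Cold-shifted
sequences move a configurable amount of composition mass
(`effect_size`, default 0.03 — about 3% of residues per index group at the
default length of 460) into or out of each index's defining residue group
(e.g. V/I/L down for the aliphatic index, K/R down for pI), split
proportionally within the group and renormalized. The default cohort is 10
cold-shifted and 10 baseline test sequences against a 5-sequence reference,
mirroring a small-genus survey with a 5-genome mesophilic reference.

What the generator deliberately does **not** emulate: positional structure,
indels and alignment gaps, phylogenetic covariance among sequences, and
subunit architecture (it emits large-subunit-only form II records). Passing
recovery tests therefore demonstrates that the scoring statistics detect
composition-level shifts of realistic size above multinomial noise — not
that real cold-adapted Rubiscos will always carry such shifts, nor that the
method is robust to lineage effects, which the i.i.d. reference assumption
ignores.

All generators are seed-deterministic, derive per-sequence streams from the
master seed, and restore the caller's RNG state.

# Numerical and design choices

* Difference form of the net rate everywhere (ratio form only as a test
  oracle), so zero CO~2~ is handled without special cases.
* `f = 0` is non-viable, making the viability boundary consistent with the
  analytic break-even line; grid masks are therefore per-O~2~-row prefixes
  in increasing CO~2~.
* Grid serialization is plain long-format TSV (`%.10g`) plus a JSON
  metadata sidecar; writing is deterministic and write∘read round-trips.
* Tie-breaks in `maxAbsDifference()` go to the lowest CO~2~, then lowest
  O~2~.
* Arrhenius calibration is exact by construction; the round trip is tested
  to 10⁻¹² relative.
* Shrinking α can only drop per-index scores to zero, never flip them (the
  significant set is nested in α); note the summed total's magnitude is not
  monotone in α when significant indices disagree in sign.
* Problem sizes in the test-suite and acceptance runs: 64 × 64 default
  grids, 1000-draw identity sweeps, 20-sequence cohorts at length 460 —
  small enough to run in seconds while keeping the multinomial noise floor
  realistic.

# Known limitations

* The kinetic model is per active site and ignores carboxysome
  CO~2~-concentration, pH/ionic effects and enzyme abundance; it compares
  intrinsic kinetics, not cellular carbon budgets.
* Arrhenius extrapolation far below the calibration temperatures inherits
  the sparseness of published enthalpy data; the bundled example enthalpies
  are placeholders with realistic structure, and conclusions about real
  enzymes require the user's own parameter table.
* Form labels are inputs; the package does no alignment or phylogenetic
  placement.
* The scoring thresholds (±3) are the conventional cutoffs, inherited, not
  derived; they are exposed only through the classification rule, which is
  deliberately kept fixed to stay comparable with prior studies.

# A worked example

```{r example, eval = FALSE}
models <- readKineticTable(system.file("extdata", "example_kinetics.tsv",
                                       package = "RubiscoTherm"))
g25 <- compareForms(models$II$model, models$IAc$model,
                    defaultGridSpec(), temp_c = 25)
maxAbsDifference(g25)

cohort <- generateCohort(seed = 1)
records <- assembleRecords(cohort$fasta, cohort$metadata)
refs <- buildReferencesFromRecords(records)
res <- scoreCohort(records, refs)
res$summary
```
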