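# coopbind

Quantitative analysis of cooperative protein binding to repeat nucleic-acid
lattices, built around the biology of TDP-43: its tandem RNA recognition
motifs (RRM1–2) bind GU/GT-repeat tracts in a cooperative manner, several
monomers packing onto one long repeat, and that cooperativity shapes where
the protein ends up in the cell. The package is for biophysicists and cell
biologists who want to go from titration heats, line-scan fluorescence
profiles or per-object intensity tables to defensible numbers: a
cooperativity statistic with a confidence interval, a demixing compartment
count with a significance test, a classification of condensates, a
nucleo-cytoplasmic slope.

## What it computes

**Lattice stoichiometry.** A bound monomer covers a 9-nt footprint with a
1-nt spacer; `max_stoichiometry()` and `place_registers()` give the monomer
count and the 1-based binding registers (on 24 nt: G1–G9 and G11–G19; 48 nt
takes four monomers, 12 nt takes one).

**Sequential binding thermodynamics.** `binding_model(kd, dh)` holds
macroscopic step constants; the binding polynomial is

    Z(p) = 1 + Σ_j β_j p^j,   β_j = Π_{i≤j} 1/Kd_i

with species fractions `β_j p^j / Z` and mass balance
`P_tot = p + R_tot · Σ_j j β_j p^j / Z`, solved by bracketed bisection to
1e-12 relative. Cooperativity is summarized by the macroscopic ratio
`Kd1/Kd2` and the statistical-factor-corrected `ω = 4·Kd1/Kd2` (two
identical independent sites give `Kd1/Kd2 = 1/4`, ω = 1).

**ITC simulation and fitting.** `simulate_itc()` generates per-injection
heats under the standard displacement model (36 × 1 µL of 120 µM
oligonucleotide into 200 µL of 15 µM protein by default); `itc_fit()` is a
classed model object (print/summary/coef/predict/plot/simulate/residuals/
confint methods) fitting one- or two-site sequential models by variable
projection over log-Kd with a deterministic multi-start grid, AIC model
comparison (`compare_models()`) and residual-resampling bootstrap CIs.

**Microtubule-bench demixing.** `call_profile()` detects compartments on
two-channel profiles by the 20%/720 nm rule (oriented ratio ≥ 1.2 over ≥ 6
pixels at 120 nm/pixel) after robust flat-fielding; `summarize_condition()`
aggregates counts per 0.5 mm analyzed, and `ks_two_sample()` compares
enrichment distributions (exact permutation p-values for small samples).

**Condensate classification.** `classify_objects()` gates objects into
TDP43-rich stress granules, TDP43-poor stress granules and mRNA-poor
TDP-43 condensates; `nucleocytoplasmic_slope()` fits the through-origin
slope of cytoplasmic vs nuclear intensity (lower slope = nuclear
retention).

**Synthetic data.** `gen_itc()`, `gen_profiles()`, `gen_objects()`,
`gen_cells()` generate every input with known ground truth, deterministic
given a seed.

## Worked example

```r
library(coopbind)

# a synthetic cooperative titration (Kd1/Kd2 = 128, total dH = -80 kcal/mol)
tg  <- gen_itc("cooperative", seed = 1)$thermogram
fit <- itc_fit(tg, n_sites = 2)
print(fit)
#> <itc_fit> 2-site sequential model, 36 injections
#>   Kd1 = 2.364e-06 M, dH1 = -35.82 kcal/mol
#>   Kd2 = 5.362e-08 M, dH2 = -44.14 kcal/mol
#>   dilution offset = -0.02739 ucal/injection
#>   Kd1/Kd2 = 44.08 (omega = 176.3)
#>   RSS = 0.2409 ucal^2, AIC = -66.09

compare_models(itc_fit(tg, n_sites = 1), fit)$selected
#> [1] "2-site"
```

The fitted `Kd1/Kd2` of ~44 against a planted 128 is typical single-curve
scatter at 1% heat noise (the ratio is heavy-tailed; medians across seeds
recover the truth within a few percent). `omega` is the intrinsic
cooperativity after removing the 4× statistical factor, and model selection
confirms the two-site (two-plateau) interpretation.

```r
reg <- place_registers(repeat_lattice(24, sequence_label = "(GU)12"))
reg
#>   register start_nt end_nt
#> 1        1        1      9
#> 2        2       11     19
```

Two monomers pack on 12 GU repeats: the first on G1–G9 (position 10 free),
the second starting at G11 — the register geometry behind the footprint
model.

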