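# redoxpH

Tools for turning quantum-chemical free energies into pH-dependent
one-electron oxidation potentials of nucleobases and their epigenetic
derivatives (5-methyl-, 5-hydroxymethyl-, 5-formyl-, 5-carboxy-cytosine
and the corresponding uracils).

Oxidation potentials of DNA bases control where oxidative damage starts
and how electron holes migrate along the helix. In aprotic media the
thermodynamic-cycle potential

E° = ΔG_IE^sol / nF − E_ref

is enough (ΔG_IE^sol = ΔG_IE^gas + ΔG^solv(RH⁺•) − ΔG^solv(RH)). In
water, coupled deprotonation equilibria (RH ⇌ R⁻ + H⁺ and
RH⁺• ⇌ R• + H⁺) dominate the observable, so the package implements a
hierarchy of four models:

- **M1** — the raw cycle potential above;
- **M2** — Henderson–Hasselbalch mixing of the neutral and deprotonated
  oxidation pathways, E = x_RH·E°(RH⁺•|RH) + x_R⁻·E°(R•|R⁻);
- **M3** — the Nernst prototropic correction of one pathway,
  E = E° + (RT/F)·ln[(10⁻ᵖᴴ + K_a(0)r)/(10⁻ᵖᴴ + K_a(+1)o)];
- **M4** — both pathways in the Nernst quotient,
  E = E° + (RT/F)·ln(K_a(+1)o/K_a(0)r) + 2(RT/F)·ln[(10⁻ᵖᴴ + K_a(0)r)/(10⁻ᵖᴴ + K_a(+1)o)].

Around the models sit the supporting machinery a practitioner needs:
solution free-energy assembly (including the +7.91 kJ/mol 1 atm → 1 M
standard-state term), two-point CBS extrapolation, Boltzmann-weighted
conformer/tautomer ensembles with deduplication and a 2% contribution
filter, theory-vs-experiment calibration (OLS slope/intercept/R², MSE,
MUE, RMSE, censored-value policies), a slope-and-anchor linear
adjustment, packaged transcriptions of the benchmark tables, and a
synthetic-system generator with known ground truth.

## Worked example

Xanthine has a neutral-molecule pKa of 7.5, so at pH 7 about a quarter
of it is deprotonated and the two oxidation pathways must be mixed:

```r
library(redoxpH)

mole_fractions(pH = 7, pKa = 7.5)$x_RH
#> [1] 0.7597469

# pathway potentials 1.89 V (neutral) and 0.92 V (deprotonated) vs SHE
cp <- redox_couple(1.89 + 4.281, 0.92 + 4.281,
                   acid_base_spec(pKa_oxidized = 3, pKa_reduced = 7.5))
m2_potential(cp, pH = 7)$E
#> [1] 1.656955
```

i.e. 76% neutral character pulls the observable to 1.66 V, well below
the neutral pathway's 1.89 V. The Nernst correction of M3 in the
limiting literal-Ka case (non-acidic reduced form, Ka(+1)o = 1) is

```r
prototropic_correction(Ka_reduced = 0, Ka_oxidized = 1, pH = 7)
#> [1] -0.4141155
```

and the linear adjustment scales a computed series by a benchmark slope
and anchors it on an experimental reference (cytosine, 1.44 V):

```r
adj <- linear_adjust(c(C = 2.18, U = 1.94), adjustment_rule(0.6, "C", 1.44))
adj$derived_intercept
#> [1] 0.132
adj$adjusted
#>     C     U 
#> 1.440 1.296
```

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the published
analyses end to end on the packaged tables and write their outputs under
`results/`:

1. `01_benchmark_regressions.R` — gas-phase and acetonitrile benchmark
   calibrations;
2. `02_aqueous_models.R` — mixed-pathway recomposition and the aqueous
   M1 → M3 → M4 correlation progression;
3. `03_linear_adjustment.R` — slope-and-anchor adjustment and the
   substituent trend of the cytosine marks;
4. `04_speciation_curves.R` — E versus pH curves under M2/M3/M4;
5. `05_synthetic_validation.R` — ground-truth recovery on synthetic
   systems.

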