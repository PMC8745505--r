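# bindspec

Spectroscopic analysis of drug–drug interference in serum albumin binding.

When two drugs are co-administered, one can displace the other from its
binding site on serum albumin, raising the free (pharmacologically active)
fraction of the displaced drug. `bindspec` quantifies this from three
standard desk experiments on a ternary system (albumin pre-incubated with an
interfering drug, then titrated with the probe ligand):

1. **Fluorescence quenching.** The intrinsic tryptophan/tyrosine emission of
   albumin (λ_ex = 280 nm) decreases as the quencher binds. After inner
   filter correction

   F_cor = F_obs · e^((A_ex + A_em)/2),

   the modified Stern–Volmer model

   F₀/(F₀ − F) = 1/(f_a·K_SV·Q) + 1/f_a

   yields the quenching constant K_SV and accessible fraction f_a, and the
   double-logarithm model

   log₁₀((F₀ − F)/F) = log₁₀ K_a + n·log₁₀ Q

   yields the binding constant K_a and site count n. The temperature trend
   of K_SV classifies the mechanism: decreasing → static (ground-state
   complex), increasing → dynamic (collisional).

2. **Thermodynamics.** Binding constants at two or more temperatures are
   decomposed by van't Hoff analysis, ln K_a = −ΔH/(R·T) + ΔS/R, giving the
   enthalpy and entropy of binding; ΔG = ΔH − T·ΔS (equivalently
   −R·T·ln K_a) tests spontaneity, and the signs of (ΔH, ΔS) classify the
   dominant forces (both positive → hydrophobic; both negative → hydrogen
   bonding / van der Waals; ΔH < 0, ΔS > 0 → electrostatic).

3. **Circular dichroism.** Far-UV CD ellipticity is converted to mean
   residue ellipticity, MRE = Θ_obs/(c_p·n·l·10), and the α-helix content is
   read from the 208 nm band:
   α% = 100·(|MRE₂₀₈| − 4000)/(33000 − 4000).

A synthetic-data generator with known ground truth (titration design:
2 µM albumin + 8 µM interfering drug, 0→14 µM quencher at 298/303/310 K)
makes every stage testable without instrument data.

## Worked example

```r
library(bindspec)

# published constants for the atenolol ternary system (units of 1e4 M^-1)
k <- reference_ternary_constants()
ka <- 1e4 * k$k_a_1e4[k$system == "ATN"]          # 5800 (298 K), 8700 (310 K)

th <- vant_hoff_fit(c(298, 310), ka)
th
#> <thermo_result> dH = 25.95 kJ/mol, dS = 159.13 J/(mol K) [two_point, hydrophobic]
#>   dG(298 K) = -21.47 kJ/mol (spontaneous)
#>   dG(310 K) = -23.38 kJ/mol (spontaneous)
```

Binding is spontaneous (ΔG < 0) at both temperatures; the positive ΔH and
ΔS indicate hydrophobic interactions dominate for this system, and the
magnitudes reproduce the published decomposition (25.94 kJ/mol,
159.06 J mol⁻¹ K⁻¹) within the rounding of the printed inputs.

End-to-end on synthetic data:

```r
truth <- quenching_preset("static", seed = 7)
report <- run_full_analysis(experiment_config(),
                            list(SYN = simulate_multitemperature(truth,
                                                                 model = "stern_volmer")))
report
#> <analysis_report> 1 system(s)
#>   SYN: 3 temperature(s), mechanism static, dH = -72.91 kJ/mol (hbond_vdw)
render_constants_table(report)
#>   system temperature_K K_SV_1e4  R2_SV K_a_1e4    n  R2_dl flags
#> 1    SYN           298     2.80 1.0000    2.80 1.00 1.0000
#> 2    SYN           303     1.80 1.0000    1.80 1.00 1.0000
#> 3    SYN           310     0.90 1.0000    0.90 1.00 1.0000
```

The static preset's quenching constant falls with temperature, so the
mechanism call is `static`; with the fractional-accessibility model at
f_a = 1 the apparent binding constant coincides with K_SV and likewise
falls, giving a negative apparent enthalpy (hydrogen-bond / van der Waals
signature).

## Command line

```sh
Rscript inst/exec/bindspec simulate --out simdir --seed 3 --noise 0.01
Rscript inst/exec/bindspec all --titrations simdir/titrations.csv \
    --out report.json --tables tables/
```

(after installation the launcher lives at
`system.file("exec", "bindspec", package = "bindspec")`.)

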