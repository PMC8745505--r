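---
title: "Methods: quenching, thermodynamic and CD analysis of albumin-ligand binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quenching, thermodynamic and CD analysis of albumin-ligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindspec)
```

## The problem

Serum albumin carries most small drugs in plasma; only the unbound fraction
is pharmacologically active. When a second drug competes for (or allosterically
perturbs) the albumin binding sites, the probe drug's binding constant drops
and its free fraction rises. `bindspec` implements the standard spectroscopic
workflow for quantifying that interference in a ternary system — albumin
pre-incubated with an interfering drug, then titrated with the probe ligand —
from fluorescence quenching, multi-temperature thermodynamics, and far-UV
circular dichroism.

## Models and assumptions

### Inner filter correction

Observed emission is attenuated by absorption of the excitation beam and
reabsorption of emitted light. The correction

$$F_\mathrm{cor} = F_\mathrm{obs}\, e^{(A_\mathrm{ex}+A_\mathrm{em})/2}$$

assumes a centrally illuminated 1 cm cuvette and moderate absorbances. It is
the identity at zero absorbance, depends only on the sum
$A_\mathrm{ex}+A_\mathrm{em}$, and never decreases the signal. The pipeline
applies it only when *both* absorbances are supplied for every titration
point — partially corrected series would silently mix scales — and records in
the report whether correction was applied, because it is unknowable from
fitted constants alone whether a published table used corrected or raw
intensities (both paths are supported).

### Modified Stern–Volmer (quenching constant)

$$\frac{F_0}{F_0-F} = \frac{1}{f_a K_{SV} Q} + \frac{1}{f_a}$$

treats a fraction $f_a$ of the protein's fluorophores as accessible to the
quencher at concentration $Q$. We fit ordinary least squares of
$y = F_0/(F_0-F)$ on $x = 1/Q$, so $f_a = 1/b$ and $K_{SV} = b/m$ for
intercept $b$ and slope $m$. Standard errors of $(K_{SV}, f_a)$ are obtained
by first-order (delta-method) propagation from the OLS coefficient
covariance. The fit is unweighted: the R² values reported for these systems
in the literature are consistent with plain linear regression on the
transformed variables, and an unweighted fit keeps the estimator transparent.
Since the transform requires $F < F_0$, non-quenched points are dropped with
a flag; fewer than three usable points produces a fit-failure *result* (not
an exception) so batch runs never abort. A configuration switch
(`experiment_config(fix_fa = TRUE)`) fixes $f_a = 1$, because published
tables for this assay sometimes omit $f_a$ and it cannot be determined
retrospectively whether the fraction was freed.

### Double-logarithm plot (binding constant and stoichiometry)

$$\log_{10}\frac{F_0-F}{F} = \log_{10} K_a + n \log_{10} Q$$

Base-10 logarithms are used; any base gives identical $K_a$ and $n$, the
choice only fixes how intercepts are reported. $Q$ is the *added* quencher
concentration — no free-ligand correction is attempted, since none is
defined for this assay. Fits with $R^2 < 0.97$ are retained but flagged
"poor linearity"; the table renderer prints such cells as `"-"`, mirroring
how very poor fits are reported in this literature (the threshold sits below
every accepted published fit for these systems, all $\ge 0.9912$). Both
estimates and their standard errors come straight from OLS on the
transformed variables.

### Mechanism classification

Static quenching (ground-state complex) weakens with temperature; dynamic
(collisional) quenching strengthens. The classifier compares accepted
$K_{SV}$ at the lowest and highest temperatures:
$(K_{SV,\mathrm{low}} - K_{SV,\mathrm{high}})/K_{SV,\mathrm{low}}$ above
+5% → static, below −5% → dynamic, otherwise indeterminate. The 5% default
is a package choice — the field's rule is qualitative — and is deliberately
small relative to the 3–30-fold changes measured for these systems, while
absorbing fitting noise near equality.

### van't Hoff thermodynamics

$$\ln K_a = -\frac{\Delta H}{RT} + \frac{\Delta S}{R}, \qquad
\Delta G = \Delta H - T\Delta S = -RT\ln K_a$$

with $R = 8.314$ J mol⁻¹ K⁻¹ fixed (it is what makes the published
arithmetic reproduce). With exactly two temperatures the closed form is
used and tagged `two_point`; with three or more, OLS of $\ln K_a$ on $1/T$
is used and tagged `regression` — both paths are needed because assays are
run at three temperatures but binding constants are often only reported at
two. Reported $\Delta G$ values are evaluated via $\Delta H - T\Delta S$
from the fitted pair rather than per-temperature $-RT\ln K_a$: the two
coincide exactly at the fitted temperatures of a two-point fit, and the
former is the convention that reproduces published free-energy tables at
interpolated temperatures (e.g. 303 K when constants exist only at 298 and
310 K). Force classification follows the strict sign rules (ΔH, ΔS both
positive → hydrophobic; both negative → hydrogen bonds / van der Waals;
ΔH negative, ΔS positive → electrostatic); exact zeros are classified
"mixed" because the rules are stated only for strict signs.

### Circular dichroism

$$\mathrm{MRE} = \frac{\Theta_\mathrm{obs}}{c_p\, n\, l \cdot 10}, \qquad
\alpha\% = 100\,\frac{|\mathrm{MRE}_{208}| - 4000}{33000 - 4000}$$

with $n = 583$ residues and $l = 0.1$ cm by default (bovine serum albumin in
a standard CD cuvette). The magnitude $|\mathrm{MRE}_{208}|$ is used: the
208 nm helix band is negative, and taking the formula literally on the signed
value would yield negative helix content — the magnitude is the standard
reading. Analysis is restricted to 205–250 nm (buffer absorption makes
shorter wavelengths unusable in phosphate buffer) and only α-helix content is
estimated; no multi-component secondary-structure deconvolution
(CONTIN/CDSSTR-style) is attempted. MRE at 208 nm is taken from the exact
grid point when present, else linearly interpolated between the bracketing
points. Results are clamped to [0, 100] with a flag.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| protein concentration | 2e-6 | M | titration design: albumin at 2 µM |
| interfering drug | 8e-6 | M | 4:1 drug:albumin pre-incubation |
| quencher range | 0–14e-6, step 2e-6 | M | 0:1 → 7:1 quencher:albumin |
| temperatures | 298, 303, 310 | K | ambient / intermediate / physiological |
| ε₂₈₀ | 43824 | cm⁻¹M⁻¹ | BSA extinction coefficient |
| residues | 583 | — | BSA chain length, for MRE |
| CD path | 0.1 | cm | far-UV cuvette |
| peak window | 320–360 | nm | tryptophan emission under 280 nm excitation; the read wavelength is not standardized, so it is configurable |
| R² linearity flag | 0.97 | — | below every accepted published fit; flags, never suppresses |
| mechanism threshold | 0.05 | relative | qualitative rule made operational |

## What the generator emulates — and what it does not

`synthetic_truth()` describes a titration with known $f_a$, $K_{SV}(T)$,
$K_a(T)$, $n$, optionally tied to a $(\Delta H, \Delta S)$ pair through the
van't Hoff relation, plus a helix content for CD. Two generative models are
provided because the modified Stern–Volmer and double-log relations are
mutually consistent only at $n = 1$: `"double_log"` takes
$(F_0-F)/F = K_a Q^n$ as exact, `"stern_volmer"` takes the fractional-
accessibility form as exact. Each fit is validated against its own
generative direction; that a single dataset can satisfy both only at
$n = 1$ is a property of the models, not of the code. Noise is
multiplicative Gaussian on $F$ (fluorescence noise scales with signal),
truncated at ±4 sd to preserve positivity; the unquenched point is taken as
the noise-free reference. Inner-filter distortion, when requested, stores
absorbances the correction exactly undoes. Full emission spectra use a
Gaussian band at 340 nm; CD spectra mix a fixed two-Gaussian helix basis
(minima at 208/222 nm, −33000 at 100% helix) with a coil basis (−4000 at 0%).

The generator does **not** emulate photobleaching, drift, scattering,
temperature gradients, competitive two-ligand occupancy, or realistic CD
band shapes beyond the 208 nm anchor. A green round-trip test therefore
establishes that the estimators invert the stated models correctly and are
calibrated under the stated noise — not that the models describe any
particular instrument's systematics.

## Numerical choices and degenerate inputs

- Titration series must contain exactly one zero-quencher point (it defines
  $F_0$) and at least four points; fits additionally need three usable
  titrated points.
- Points with $F \ge F_0$ are dropped with a flag; an all-flat series gives
  a "no quenching" fit-failure result.
- Blank subtraction requires identical wavelength grids (no silent
  interpolation); strictly negative differences on non-CD channels are
  floored at 1e-9 with a warning so downstream log transforms stay defined,
  while exact zeros are left intact.
- Peak extraction breaks ties toward the shorter wavelength.
- Internally everything is SI (M, K, J); display tables convert to the
  field's customary mixed units (constants in 10⁴ M⁻¹, ΔH and ΔG in kJ/mol,
  ΔS in J mol⁻¹ K⁻¹, two decimals).
- JSON reports serialize at jsonlite's maximum precision (~16 significant
  digits); round trips reproduce numeric fields to 1e-14 relative error,
  which is the practical meaning of "full precision" for printed doubles.

## Known limitations

- The double-log intercept $\log_{10} K_a$ lies far outside the covered
  $\log_{10} Q$ range for micromolar titrations (about five decades below),
  so $K_a$ estimates are intrinsically noise-sensitive: at 1% multiplicative
  noise on $F$ the median relative error of $K_a$ across seeded replicates
  is ~45% (while $n$ stays within ~4%); at 0.1% noise both fall well inside
  5%/3%. The acceptance suite records this honestly — the corresponding
  noisy-recovery criterion is asserted at its stated 1%-noise bounds and
  fails, while the unit suite asserts the attainable calibration (bounds at
  0.1% noise, approximately linear error scaling).
- The reported OLS standard error of $\log_{10} K_a$ underestimates the true
  sampling spread by a factor of ~2 under multiplicative noise, which is
  strongly heteroscedastic after the log-ratio transform; a weighted fit
  would fix this but would depart from the unweighted convention this assay
  literature uses.
- Mechanism classification uses only the two extreme temperatures; a
  non-monotone $K_{SV}(T)$ profile (rare, but possible with mixed
  static/dynamic contributions) is not detected.
- No heat-capacity term: the van't Hoff line is assumed straight over
  298–310 K.
- CD analysis yields α-helix content only; β-sheet/turn fractions require
  deconvolution methods out of scope here.
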