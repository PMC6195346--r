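---
title: "Barrier-model analysis of ligand-gated anion permeation"
author: "ionbarrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barrier-model analysis of ligand-gated anion permeation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionbarrier)
```

## The permeation model and its assumptions

`ionbarrier` analyzes ion conduction through ligand-gated anion channels of
the TMEM16A type with a minimal Eyring rate model: the open pore is a
sequence of `n = 3` energy barriers, equally spaced in a linear
transmembrane field — two large desolvation barriers at the pore entrances
flanking a smaller central barrier at the narrow neck. The model assumes no
deep wells along the permeation path and no saturation of the pore, which
is appropriate for channels whose Cl⁻ K_M is far above the working
concentration (here symmetric 150 mM). Under these assumptions the current
is fully determined by an amplitude factor `A` (absorbing channel count,
open probability and the absolute outer-barrier rate) and two shape
parameters: `sigma_h` and `sigma_beta`, the zero-voltage rates of crossing
the middle and innermost barrier relative to the outermost one. Because the
field drops linearly, both ratios are intrinsically voltage independent;
any apparent voltage dependence of `sigma_beta` in concentration series
enters through the voltage dependence of ligand binding (below).

Three closed-form properties serve as the model's verification contract,
and the test suite asserts all of them: the current reverses exactly at the
Nernst potential `(RT/zF) ln(c_o/c_i)`; it is ohmic through 0 mV; and for
symmetric barriers in symmetric solutions it collapses to
`2zFAc·sinh(zFV/6RT)`. The middle-barrier term of the denominator has a
removable singularity at 0 mV whose analytic limit (`n − 2`) is evaluated
explicitly, so `I(0)` is never NaN. Outward current is positive; `z = −1`
for Cl⁻; `c_i` is the bath side of an inside-out patch. Voltages are mV at
every public interface, energies kJ/mol, with R = 8.314 J mol⁻¹ K⁻¹,
F = 96485 C mol⁻¹ and T = 293.15 K by default (recordings at 20 °C).

Barrier profiles are reported relative to the outermost barrier,
`−RT ln sigma` in kJ/mol, at electrical distances (1/6, 1/2, 5/6). Those
positions follow from three equally spaced barriers in a linear field,
consistent with the `e^{zFV/2nRT}` voltage factors of the model; they are a
model-consistent convention, not an independently measured geometry. The
Gaussian rendering width (0.08 electrical-distance units) is purely
cosmetic.

## The data-reduction chain

The pipeline reproduces the reduction an experimenter applies to
instantaneous I-V families, in order:

1. **Pre-pulse normalization.** Excised patches run down irreversibly;
   within a voltage-step train (−100 to +120 mV in 20-mV steps, low to
   high, so that the small inward currents are least affected) the current
   scale decays by ~10–15%. Each sweep's currents are rescaled by the ratio
   of the recording-median pre-pulse amplitude to that sweep's own
   pre-pulse amplitude. The median reference is a robustness choice; with
   noiseless data the correction restores the I-V *shape* exactly while the
   amplitude continues to track the recording's overall rundown level.
2. **Quality control.** Every session must bracket its test concentrations
   with zero-ligand recordings. A patch is discarded as *leaky* when the
   mean zero-ligand current magnitude at −100 mV exceeds a bound (default
   120 pA, sized for ~1-nA saturating currents), and as *deteriorated* when
   the bracket amplitude drifts by more than 20% across the session. The
   drift statistic divides each bracket's reference-voltage current by the
   train's median pre-pulse — multiplicative rundown then cancels — and
   discounts the fitted drift by twice its standard error, so that
   measurement noise on small late-session currents is not mistaken for
   deterioration. With only two brackets and no pre-pulse information the
   statistic degenerates to the plain amplitude-ratio test. The published
   protocols leave the quantitative rule unspecified ("judicious" use);
   these thresholds are explicit, configurable stand-ins and every decision
   is logged with its reason.
3. **Background subtraction** (optional, for constructs without basal
   activity) subtracts a zero-ligand I-V point-wise on a shared grid.
4. **Model fit.** With `n` fixed at 3, `sigma_h`, `sigma_beta` and `A` are
   the only free parameters. They are fitted by Levenberg-Marquardt on the
   log scale (positivity by construction) from at least five starting
   points on a log-spaced sigma grid, keeping the best residual sum of
   squares. Residuals are unweighted by default; per-point weights can be
   supplied. Confidence intervals are asymptotic: t-based on the log scale
   from the linearized covariance, then exponentiated (asymmetric,
   positivity-respecting); symmetric delta-method half-widths are also
   reported. Profile-likelihood intervals are not implemented; the
   calibration test below is the evidence that the asymptotic intervals
   are adequate at the noise levels considered.
5. **Aggregation.** Following standard practice, the pipeline averages
   *normalized I-V curves* across patches at each concentration and fits
   the mean curve, rather than averaging per-patch parameters. This matters
   in practice: `sigma_h` is weakly determined by a single noisy recording
   (occasional fits run away to absurd values), while the mean-curve fit is
   stable. `sigma_beta` is generally the better-defined parameter and the
   one emphasized downstream; per-recording fits are returned for
   inspection.

## Ligand modulation

Dose-response data and sigma-concentration series are fitted to the Hill
equation in log₁₀-concentration space, `y = floor + (ceiling − floor)/(1 +
10^{(log EC₅₀ − log c) h})`, with EC₅₀ and `h` on the log scale. Zero
concentrations are handled exactly (they pin the floor). For single-site
ligands (Mg²⁺, and binding-site mutants that retain one functional site)
`h` is fixed at 1, in which case the curve is algebraically the rectangular
hyperbola `c/(c + EC₅₀)`. A series whose responses span less than 10% of
their range is flagged unidentifiable rather than fitted. Inner- and
central-barrier series are fitted independently; no parameters are shared
across voltages or barriers.

Some binding-site mutants show a secondary low-affinity *decay* of
`sigma_beta` at high Ca²⁺, attributed to processes extrinsic to the
transmembrane site; only the high-affinity phase is analyzed. The exclusion
rule keeps the longest non-decreasing prefix through the series maximum and
masks points beyond the maximum that fall more than 5% (configurable) below
it. The rule is idempotent and never masks the maximum. Because points
within the tolerance band are retained, a fitted EC₅₀ can still be biased
by up to roughly the tolerance-to-slope ratio (~10% here); the tests
measure exactly that.

The voltage dependence of EC₅₀ is fitted as `log EC₅₀(V) = log EC₅₀(0) −
z_Ca f_V V F/(2.303 RT)` — pure linear-model algebra whose slope yields the
product of ligand valence and electrical distance `f_V` of the binding site
within the field. Rundown-corrected concentration-response construction
divides each steady-state test response by the linear interpolation (in
epoch index) of its bracketing saturating-reference responses; bracketed
linear interpolation is this package's stand-in for the cited protocol,
and unbracketed points are dropped with a warning.

## Electrostatics and energetics

`delta_Ea()` converts the innermost-barrier rate to an activation-energy
difference, `−RT ln sigma_beta`. Energy-versus-valence relations are
interpreted through a bare Coulomb potential at fixed distance:
`fit_valence_energy()` fits `ΔE_a = −K z_bs/(ε_r r) + const` against the
assumed net charge of the binding site (five acidic residues, Glu/Asp −1,
Gln/Ser 0, Arg +1, plus +2 per bound divalent and +3 per Gd³⁺;
`site_valence()` does this bookkeeping), and `fit_pore_charge_energy()`
fits `ΔΔG_obs = K Δz_pore z_Ca/(ε_r r) + const` for charge changes at the
intracellular pore entrance, with `ΔΔG_obs = RT ln(EC₅₀/EC₅₀,bg)`. The
prefactor `K = N_A q²/4πε₀` is computed from CODATA constants at run time,
never hard-coded. Distances come from structure (13.6 Å site-to-barrier;
11.9/10.6 Å for the two pore-entrance lysines). The CI on `ε_r` is
propagated from the slope CI by the delta method. Fits with the
non-physical slope sign are flagged rather than silently returned. The
fitted `ε_r` values are reported with their intervals and no further
physical interpretation — they are effective constants of a deliberately
coarse model.

Double-mutant-cycle coupling is `(E_AB − E_p) − (E_A − E_p) − (E_B − E_p)`;
for purely Coulombic (superposable) energies every cycle couples to zero
exactly, which is the machine-precision additivity property the tests
assert.

`axial_potential()` is an explicitly simplified stand-in for a full
membrane-embedded Poisson-Boltzmann calculation: point charges on the pore
axis in a uniform dielectric with Debye-Hückel screening (λ_D ≈ 7.8 Å at
150 mM, 20 °C). It is linear in the charges and reproduces ordering and
monotonicity trends — removing a bound Ca²⁺ lowers the potential
everywhere; stepwise neutralization of acidic residues orders the profiles
monotonically — but its absolute values are not comparable to a structure-
based solver with protein/membrane/solvent dielectric boundaries, and no
such comparison is made anywhere in the package.

## Occupancy decomposition

Ensemble I-V curves are decomposed as `I = i·I_0Ca + j·I_1Ca + k·I_2Ca`
over basis curves for the zero-, one- and two-Ca²⁺-occupied open states,
with basis parameters supplied externally (in practice from constitutively
active constructs measured at zero and saturating ligand) and never
refitted during decomposition. Weights are estimated by non-negative least
squares using an in-package Lawson-Hanson active-set solver (the fitted
weights satisfy the KKT conditions of the constrained problem exactly;
nonnegativity is enforced, never clipped). There is no sum-to-one
constraint — weights absorb open probability and channel count — and
normalized fractions are a separate view. For constructs without
measurable basal activity the apo term can be fixed at zero. Decompositions
are per curve (per concentration) with no smoothness coupling across
concentrations.

## The synthetic-patch generator

`generator_config()`/`generate_patch()` emulate the statistical structure
the chain assumes: three-barrier currents whose sigma parameters follow
Hill isotherms of the intracellular ligand, EC₅₀ shifted by the pre-pulse
voltage through the electrical-distance relation, geometric per-step
irreversible rundown (12% per train by default, within the 10–15% seen
experimentally), ohmic leak, additive Gaussian current noise (2% of the
saturating current by default; pre-pulse amplitudes, being time-averages,
carry one fifth of that), zero-ligand brackets around every test
concentration, and a configurable fraction of injected leaky patches.
Reference-construct dose-response anchors are EC₅₀ 60 nM / h 2.1 (inner
barrier) and 170 nM / h 1.7 (central barrier) at a +80 mV pre-pulse.
Defaults that the printed record does not fix are invented and labelled as
such: sigma floors/ceilings (0.05→1 inner, 0.2→1 central, chosen to give
strong outward rectification at zero ligand and a pseudo-linear curve at
saturation), `z_Ca·f_V = 0.5`, amplitude `A = 4×10⁻⁵` (≈1 nA at +120 mV),
the single-site mutants' EC₅₀s, and the biphasic decay (30% of the sigma
range, centered three decades above the primary EC₅₀). Pore-entrance
mutant EC₅₀s are derived from the pore-charge Coulombic truths, so
forward-generated datasets are exactly linear in valence. Every dataset
carries a truth record keyed to its rows; the pipeline under test never
reads it. Identical configuration and seed give bit-identical output, and
patch indices use distinct substreams.

The generator does **not** emulate capacitive transients, series-resistance
error, single-channel gating noise, liquid-junction offsets, Gd³⁺'s
irreversible binding phase, or genuine conformational gating — so passing
recovery tests demonstrates that the chain is correct and calibrated for
data matching its own assumptions, not that those assumptions hold for any
particular real recording.

## Numerical choices and problem sizes

Fits run Levenberg-Marquardt (`minpack.lm`) in log-parameter space with
multi-start; linear fits use `lm`; NNLS is the active-set solver above with
an SVD-based rank-safe subproblem. Ties in the exclusion rule resolve to
the first maximum. Degenerate inputs error early with named messages
(missing columns, non-spanning responses, collinear bases, coincident
charge positions).

The shipped tests use cohorts of 2–10 patches, 3–8 concentrations, 12
voltage steps, and 200-replicate Monte-Carlo calibration runs, which keep
the whole suite under ~10 s while leaving the coverage checks (93–97%
acceptance band for 95% intervals on `sigma_beta` and EC₅₀) adequately
powered. Larger cohorts only tighten the same checks.

## Known limitations

- `sigma_h` is weakly identified from single noisy recordings; use the
  mean-curve fits (the pipeline default) and treat per-recording `sigma_h`
  with caution.
- The Coulombic layer assumes a uniform effective dielectric and a single
  fixed distance per fit; the returned `ε_r` is an effective parameter.
- The QC thresholds are calibrated to the generator's current scale
  (~1 nA); recordings on a very different scale need a rescaled
  `qc_policy()`.
- Hill fits with free floor/ceiling need data spanning the transition;
  series confined near one bound are flagged, not fitted.
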