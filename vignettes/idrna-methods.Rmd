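---
title: "Models and methods behind idrna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind idrna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrna)
```

`idrna` implements the quantitative machinery used to characterise a small,
highly charged intrinsically disordered protein (SERF, 68 residues, +12 at
pH 7.5), a folded RNA (the 29-nt apical stem-loop of HIV-1 TAR, −29), and
their 1:1 complex. This vignette explains each model, the parameters that
matter, the numerical choices, and what the synthetic-data generators do and
do not emulate.

## Sequence charge analytics

Charges follow the coarse-grained convention of the simulation model the
analyses are built around: Arg/Lys +1, Asp/Glu −1, His/Cys/Tyr neutral,
termini neutral (the simulated construct carries acetyl/amide caps), and −1
per ribonucleotide. Only pH 7.5 semantics are defined; the `ph` argument is
validated but no Henderson–Hasselbalch titration is attempted (that is a
non-goal — the rule exists to reproduce the integer formal charges the
stoichiometry argument rests on). `ncpr_profile()` uses truncated windows at
the chain ends so the profile covers every residue; the default window of 5
matches the standard presentation for disordered sequences.
`charge_match_ratio()` returns |q_RNA|/q_protein, the protein:RNA molar
ratio at which total charges balance — 29/12 ≈ 2.42 for this pair, close to
the ~2.5:1 ratio at which turbidity of the mixture peaks.

## Ensemble geometry and the two null models

`radius_of_gyration()` and `mean_distance_map()` are the standard
mass-weighted definitions, computed per frame and averaged. All coordinates
are in ångströms; masses default to 1 because the inputs are one-bead-per
residue coarse-grained ensembles (mass-weighting is available).

Two distinct random-coil references coexist, and they are deliberately not
the same chain:

* **Freely rotating chain (FRC)** — fixed bond length l = 3.8 Å, fixed
  cosine α = 0.8 of the bond-angle supplement, uniform dihedrals. Its mean
  squared inter-monomer distance has the closed form
  r²(n) = n·l²·[(1+α)/(1−α) − 2α(1−αⁿ)/(n(1−α)²)]. This is the null used
  for PRE profiles. With α = 0.8 its long-chain Kuhn ratio is
  (1+α)/(1−α) = 9, i.e. a rather expanded chain.
* **Analytical Flory random coil (AFRC)** — a sequence-length-only
  ideal-chain (ν = 1/2) reference for typical disordered proteins, used to
  normalise distance maps and as the Rg yardstick. The defining
  implementation is an external numerical package; `idrna` parameterises
  the ideal-chain closed form with a per-residue segment scale
  b = 6.179 Å chosen so that the 68-residue reference reproduces the
  published AFRC mean Rg of 20.8 Å. Distances at separation k follow
  ⟨r²⟩ = b²k with the Gaussian-chain mean ⟨r⟩ = √(8/3π)·b·√k, and
  mean Rg = b·√((N²−1)/(6N)). Distance-map normalisation is indexed by
  sequence separation |i−j| only, which is exactly the information the
  AFRC carries.

## Scattering: Debye forward model, Guinier, Kratky

`debye_scattering()` evaluates the orientationally averaged Debye sum with
unit form factors, so I(q→0) → N². It is plumbing: enough forward model to
test Guinier/Kratky logic against ensembles, with no solvent or atomic form
factors (experimental-curve fitting is out of scope).

`guinier_fit()` fits ln I against q² and shrinks the window from the high-q
end until q_max·Rg ≤ `qrg_limit` (default 1.1; the classical 1.3 is also
accepted). One caveat matters for flexible chains: the Guinier
approximation has a systematic truncation bias that grows as (qRg)⁴, and
for an ideal-chain (Debye) profile a window out to qRg = 1.1 underestimates
Rg by ≈5 %. Accuracy-critical checks in the package therefore use a
conservative window (qRg ≤ 0.65, bias < 2 %); the default remains 1.1
because experimental signal-to-noise rarely supports tighter windows. A
non-negative slope (unphysical rising profile) or a window with fewer than
4 points returns a failure object rather than throwing.

`dimensionless_kratky()` returns (qRg, (qRg)²I/I₀). For an ideal chain the
ordinate plateaus at 2; compact globules peak near qRg = √3 and decay;
chains stiffer than Gaussian (such as the α = 0.8 FRC) plateau above 2.

## PRE back-calculation

The observable is the paramagnetic/diamagnetic intensity ratio
I_P/I_D = R₂·exp(−R₂sp·t)/(R₂+R₂sp), with
R₂sp = (K/r⁶)·(4τ_c + 3τ_c/(1+ω²τ_c²)). Defaults: R₂ = 8.1 s⁻¹,
t = 50 ms, τ_c = 1 ns (a ~8 kDa disordered protein), proton constants
(ω = 2π·600 MHz), matching the proton-start acquisition scheme the
profiles correspond to.

**The constant K needs care.** The protocol that defines these equations
prints K_H = 1.23×10⁻²³ and K_C = 7.78×10⁻³⁴ cm⁶ s⁻², but these two
numbers are not mutually consistent with the defining formula
K = (1/15)S(S+1)γ²g²β² — their ratio is not (γ_C/γ_H)², and the ¹H value
is nine orders of magnitude from the conventional 1.23×10⁻³². Evaluating
the formula in CGS units with the tabulated constants gives
1.2338×10⁻³² cm⁶ s⁻² for ¹H. `pre_settings()` exposes both: `K_mode =
"computed"` (the default) evaluates the formula, `K_mode = "paper"`
returns the printed values verbatim, and the mode used is recorded. The
computed value is the default because the printed ¹H constant would bleach
every residue of a 68-residue chain to I_P/I_D ≈ 0, which contradicts the
localized bleaching the same protocol reports; the two modes are never
silently reconciled.

Two distance-averaging conventions are provided. `"mean_distance"`
(default) takes ⟨r⟩ over frames and then the sixth power — the convention
the protocol text states. `"mean_inverse_sixth"` takes ⟨r⁻⁶⟩, the usual
PRE average; by Jensen's inequality it always bleaches at least as much.
The closed-form null (`pre_null_profile()`) plugs the *rms* distance
√r²(n) from the FRC formula into the same transfer function; at the label
site itself (n = 0) the formula is degenerate, so that residue is emitted
as ratio 0 and flagged. Oracle-equivalence tests compare the sampled rms
distance against the closed form, since those are the matched quantities;
the ⟨r⟩-based user profile tracks the null to within ~0.005 in ratio units
for 20 000-frame ensembles.

## NMR scalar observables

Relaxation decays are fitted to I = I₀·exp(−t/T) by bounded
Levenberg–Marquardt with a log-linear initialisation; duplicate delays are
averaged first (the acquisition scheme collects duplicates), and flat or
rising series return failure objects. Combined CSPs use
√(Δδ_H² + (γ_X/γ_H·Δδ_X)²) with ratios 0.10137 (¹⁵N) and 0.2516 (¹³C).
Secondary shifts are (Cα_obs−Cα_coil) − (Cβ_obs−Cβ_coil) against a
user-supplied coil reference table (coil-shift prediction is out of
scope); glycine rows without Cβ fall back to the Cα deviation and are
flagged; the statistic is exactly linear in the observed shifts. Whether
to smooth is left to the user (default none — the unsmoothed statistic is
assumed in the tests).

## 1:1 binding models and fits

`fraction_bound()` solves 1:1 mass action exactly:
F_B = (b − √(b² − 4LM))/(2M), b = K_D+L+M. The negative root is the
physical one (the positive root exceeds 1); F_B is read as the fraction of
the *fluorescent macromolecule* bound, which is what the anisotropy of a
labelled RNA reports. M = 0 degrades gracefully to the hyperbolic limit,
flagged. The anisotropy observable is
r = (Q·F·r_B + r_F(1−F))/(1 − F(1−Q)); Q = 1 reduces exactly to linear
mixing. Concentrations are µM throughout.

Fits run bounded Levenberg–Marquardt with multi-start over K_D (and Q when
it floats): initialisation is r_F from the first point, r_B from the last,
Q = 1, K_D at the half-range ligand concentration. An important empirical
fact, quantified during development and visible in `kd_profile_interval()`:
with all four parameters floating, a single 14-point titration at 0.002
anisotropy noise constrains K_D only weakly, because K_D and Q trade off
along a shallow valley (Wald standard errors of order the estimate
itself). Interval statements therefore use profile likelihood (an F-test
threshold on the profiled SSR), which restores ~95 % coverage. Point
comparisons of recovered constants condition on the known generator Q via
the `fix` argument — for synthetic data Q is known, and this is the
apples-to-apples recovery question; with real data, where Q must float,
the profile interval is the honest summary.

`titration_refit_study()` packages the study-conditions comparison: truths
0.67 and 1.9 µM (the two experimentally fitted constants), 200 nM
labelled RNA, noise 0.002, and three technical replicates averaged
point-wise (the experimental design also used three). The ligand grid —
28 log-spaced points from 0.03 to 40 µM — is a design choice: a variance
analysis across seeds showed that sparser grids leave the fitted-constant
ratio with ≈5 % standard deviation and occasional >10 % excursions,
whereas this density conditions it to ≈4 % with rare excursions. The
recovered ratio lands at the experimental ~2.8-fold affinity difference.

CSP titrations fit Δδ = Δδ_max·F_B. The regime mimicking the RNA-observed
experiment (M = 0.5 mM at K_D ≈ 100 µM, i.e. M/K_D ≈ 5) is close to
stoichiometric, where K_D is intrinsically poorly determined; single-seed
recoveries scatter with a median error near 8 % at 2 % noise, and the
tests assert the median across seeds rather than pretending each
realisation is accurate.

## Trajectory → K_D pipeline

The pipeline reproduces, step by step, the published analysis of
coarse-grained two-molecule trajectories:

1. **COM trajectory** (`com_distance_trajectory()`): per-frame
   centre-of-mass separation under the minimum-image convention in the
   cubic periodic box (edges accepted in nm, coordinates in Å).
2. **Two-Gaussian decomposition** (`fit_two_gaussian_rdf()`): the pooled
   distance histogram (plain distances, no r² shell normalisation — the
   published fit is over the distances themselves) is fitted with
   A₁N(µ₁,σ₁)+A₂N(µ₂,σ₂). Binning is Freedman–Diaconis by default;
   initialisation is a 2-means split. Components count as resolved only if
   µ₂−µ₁ > 2·max(σ₁,σ₂); a unimodal distribution is reported as
   unbound-only (the failure mode that matters for replicate omission is
   missing unbound sampling — an all-bound trajectory is caught downstream
   by the f = 1 guard). Failures return diagnostic objects, not errors,
   so replicates can be omitted from aggregation as in the original
   analysis.
3. **Threshold** (`bound_threshold()`): the intersection of the two
   weighted component densities inside (µ₁, µ₂), found by root-finding
   with a dense-grid fallback; for symmetric components this is exactly
   the midpoint. The published reference threshold (53.5 Å) can be passed
   directly to the classifier instead.
4. **Lifetime filter** (`classify_bound_frames()`): below-threshold runs
   of ≥ 5 consecutive frames are bound; shorter encounters are stochastic
   collisions, not complexes.
5. **Mass action** (`apparent_kd()`): K_D = c_box·(1−f)²/f, with c_box
   the concentration of one pair in the box (25.95 µM at 40 nm). The
   literature applies a finite-size/virial correction whose formula is
   not printed; it is surfaced as an explicit multiplicative factor
   defaulting to 1 rather than silently applied.

Contact maps count, over bound frames only, pairs within 15 Å; because it
is unstated whether published per-residue footprints aggregate by maximum
or mean over partners, both marginals are emitted.

## Synthetic data: what it emulates, what it does not

* `sample_frc_ensemble()` builds chains bond by bond with the exact
  length/angle constraints and uniform dihedrals — the generative twin of
  the FRC closed form (the sampled mean squared separations converge to
  it; this is tested at 3·SEM). It does not emulate excluded volume,
  sequence-specific interactions, or secondary structure.
* `simulate_binding_trajectory()` is a two-state Markov chain: bound
  frames emit N(µ_b = 30 Å, σ_b = 6 Å) truncated positive; unbound frames
  emit r²-weighted distances up to the box half-diagonal — a tractable
  stand-in for two uniformly placed molecules that affects only the
  unbound mode's shape, not the occupancies. Defaults (40 nm box,
  p_off = 0.02, i.e. 50-frame mean bound dwells) give a few hundred
  association events per 10⁵ frames, the sampling regime the published
  trajectories were in. It has no interaction energies, no diffusive
  dynamics, and no intermediate states — so passing recovery tests shows
  the *pipeline* is unbiased, not that any force field is right.
* Titration and decay generators add i.i.d. Gaussian noise to the exact
  forward models.

All generators take an explicit integer seed, derive any sub-streams from
it, restore the caller's RNG state, and are bit-reproducible.

## Problem sizes and numerical choices

Desk-scale defaults keep every analysis deterministic-feeling and fast:
20 000-frame FRC ensembles for PRE oracle comparisons; 3×10⁵-frame
trajectories for K_D recovery at occupancies 0.2/0.5/0.8 (the statistical
error of the bound fraction at 50-frame dwell times is ≈0.006, giving
≲5 % K_D error at the least favourable occupancy); 50-seed batteries for
coverage statements. Root-finding uses `uniroot` at 10⁻¹⁰ tolerance;
optimisations are bounded Levenberg–Marquardt (`minpack.lm`) with
multi-start where valleys are known to be shallow.

## Known limitations

* The AFRC parameterisation is calibrated to the published 20.8 Å
  reference dimension for a 68-residue chain rather than re-derived from
  the defining numerical package; other chain lengths inherit ideal-chain
  scaling from that single anchor.
* The charge rule is formal and pH-blind by design; His-rich or
  terminal-charged systems need a different rule.
* The Debye forward model ignores form factors and solvent; it supports
  method tests, not beamline-data fitting.
* The unbound-distance emission is an approximation to the true
  periodic-box pair-separation density; only the unbound Gaussian's
  fitted shape parameters are affected.
* Workflow orchestration (`validate_config()`/`run_workflow()`) covers the
  package's own stage registry, not arbitrary user stages.
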