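---
title: "Quantitative binding analysis for SH2 domain–phosphopeptide recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative binding analysis for SH2 domain–phosphopeptide recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindfit)
```

## The scientific problem

SH2 domains recognize short phosphotyrosine (pY)–containing epitopes. For a
substrate-recognition module such as the SOCS2 SH2 domain, the questions a
binding study must answer quantitatively are: how tightly does each candidate
peptide bind, which peptide positions carry the binding energy (hotspots),
and do orthogonal assays agree? `bindfit` implements the complete analysis
chain for the three assay modalities such studies use — a ligand-observed
¹⁹F NMR displacement assay, steady-state surface plasmon resonance (SPR),
and isothermal titration calorimetry (ITC) — plus the panel-level analytics
(fold-changes, hotspot calling, cross-assay concordance) and structural
interface metrics (solvent-accessible and buried surface area, distances,
contacts).

Because raw instrument data for such studies are rarely deposited, every
modality has a seeded synthetic generator that emulates the statistical
structure of the real experiment; all parameter-recovery claims in the test
suite are made against these generators with known ground truth.

## Competitive binding equilibria

All concentrations are in μM everywhere; the computational core performs no
unit conversion.

**Two components.** For protein P (total $P_0$) and a reporter ("spy")
ligand L (total $L_0$, dissociation constant $K_D$), the complex
concentration is the smaller root of the binding quadratic:

$$[PL_0] = \tfrac{1}{2}\left(P_0 + L_0 + K_D - \sqrt{(P_0+L_0+K_D)^2 - 4P_0L_0}\right),$$

computed in the numerically stable form $2P_0L_0/(b+\sqrt{b^2-4P_0L_0})$,
$b = P_0+L_0+K_D$ (`solve_two_component()`).

**Three components.** Adding a competitor I (total $I_0$, constant $K_i$)
couples two mass-action equations. Free protein $P_f$ is the unique root of
the strictly increasing function

$$f(P_f) = P_f\left(1 + \frac{L_0}{K_D+P_f} + \frac{I_0}{K_i+P_f}\right) - P_0$$

on $[0, P_0]$. `solve_competition()` brackets it by 100 bisection steps and
polishes with Newton iterations (the derivative is bounded below by 1, so
the polish is safe). The equivalent closed-form cubic is implemented only as
an independent oracle in the tests: for extreme parameter ratios the cubic's
coefficients lose precision long before the monotone bracketing does.

**Inference direction.** The displacement assay observes $[PL]$ and needs
$[PI]$ and then $K_i$:

$$[PI] = \frac{P_0L_0 - (P_0+L_0+K_D)[PL] + [PL]^2}{L_0 - [PL]}, \qquad
K_i = \frac{(P_0-[PI]-[PL])(I_0-[PI])}{[PI]}.$$

A note on numerical domain: when $[PI]$ is below about $10^{-6}$ μM the
inversion's numerator is a cancellation of terms of order $P_0L_0$, leaving
an absolute error floor near $10^{-13}$ μM. The forward→inverse→$K_i$
round-trip is therefore verified to better than $10^{-8}$ relative wherever
$[PI] > 10^{-4}$ μM (0.1 nM — far below anything measurable by
displacement); outside that domain no double-precision implementation can do
better.

**Clamping policy.** Measurement noise routinely produces slight
infeasibility (e.g. inferred $[PI]$ a hair below 0). Values within
$10^{-6}$ μM of the feasible interval are clamped and flagged `"clamped"`;
larger violations raise errors, since gross infeasibility signals bad input
rather than noise. An observed $[PL]$ exceeding the competitor-free $[PL_0]$
is flagged `"no_displacement"` instead of producing a negative $[PI]$.

## The ¹⁹F CPMG displacement assay

The spy molecule is a fluorinated pY-pocket binder ($K_D$ = 50 μM) observed
at 100 μM with 5 μM protein. A CPMG filter attenuates fast-relaxing
(protein-bound) signal; the spy's transverse relaxation time is obtained by
fitting

$$I(t) = I(0)\,e^{-t/T_2}$$

to integrals at delays $t \in \{0.05, 0.1, 0.2, 0.4, 0.8\}$ s
(`fit_t2()`). Fitting happens in intensity space — noise on peak integrals
is closer to additive than log-additive — with starting values from the
log-linear regression, which is already exact on noiseless data; the
optimizer is Levenberg–Marquardt on $(\log I_0, \log R_2)$, making
positivity structural. `R2` is stored as the fitted parameter and `T2` as
its exact reciprocal.

A displacement measurement is the integral triplet $(I_F, I_P, I_I)$ —
spy free, with protein, with protein + competitor — at the fixed 0.133 s
delay. The remaining bound-spy fraction is

$$f = \frac{I_F - I_I}{I_F - I_P} = \frac{[PL]}{[PL_0]},$$

and `ki_from_displacement()` chains quadratic → $f$ → inversion → $K_i$.
Guard rails:

* **assay window**: triplets with $(I_F-I_P)/I_F$ below 10% carry no usable
  information and are rejected;
* **clamping**: $f$ within 0.05 outside $[0,1]$ is clamped and flagged;
* **censoring**: $f = 1$ (no displacement) bounds $K_i$ only from below and
  $f = 0$ (complete displacement) only from above. Rather than reporting
  infinities, the quantitation bounds are evaluated at $f = 0.98$ and
  $f = 0.02$ and returned in `ki_bound` with the corresponding flag.

Replicates are analyzed individually and the per-replicate $K_i$ values
averaged (mean ± s.e.m., `aggregate_replicates()`); integrals are never
averaged before inference. The four-replicate convention follows standard
panel reporting; with $n = 1$ the s.e.m. is flagged undefined rather than
silently zero.

## SPR steady-state fitting and triage

Steady-state responses on the seven-point series 0.08–60 μM are fit to the
1:1 Langmuir isotherm $R_{eq}(C) = R_{max}C/(K_D+C)$ in
$(\log K_D, \log R_{max})$ (`fit_spr_steady_state()`). Every fit is triaged
(`classify_spr_signal()`) the way mutant-panel tables report it:

* `"n.d."` — maximal response below 3× the response noise (signal not
  detected);
* `"weak"` — signal present but the fitted $K_D$ exceeds the highest tested
  concentration, or the fit failed (saturation not achieved);
* `"quantified"` otherwise.

## ITC one-set-of-sites fitting

`itc_expected_heats()` implements the standard single-cell instrument
model. With cumulative injected volume $dV$, the displacement-corrected
totals are $M_t = C_{cell}(1 - dV/2V_0)$ and
$X_t = C_{syr}(dV/V_0)(1 - dV/2V_0)$; the cumulative heat after injection
$i$ is

$$Q_i = \frac{N M_t \Delta H V_0}{2}\left[A - \sqrt{A^2 - \frac{4X_t}{NM_t}}\right],
\quad A = 1 + \frac{X_t}{NM_t} + \frac{K_D}{NM_t},$$

and the per-injection heat adds the displaced-volume correction
$\Delta Q_i = Q_i - Q_{i-1} + (dV_i/V_0)(Q_i+Q_{i-1})/2$ plus a constant
per-injection offset standing in for the heat of dilution (the
peptide-into-buffer control is modeled this way because raw control data
are not available). Units: μM × μl × kcal/mol → μcal via a factor
$10^{-3}$.

Defaults mirror the standard protocol: a 0.4 μl initial injection
(discarded from fitting but still displacing volume) followed by 19 × 2 μl;
cell volume 200 μl — the instrument-class value, configurable, since it is
not usually printed in papers.

`fit_itc()` runs Levenberg–Marquardt over $(\log N, \log K_D, \Delta H,
\text{offset})$ from several $K_D$ starting points. Two deliberate
robustness choices: (i) a fit that stalls at the iteration cap but has the
best finite residual is accepted — with a shallow isotherm the
$N\!\cdot\!\Delta H$ ridge is flat and the optimizer wanders along it
without improving; (ii) the Wiseman parameter $c = N C_{cell}/K_D$ is
always reported and `low_confidence_N` is set when $c < 1$, where
stoichiometry is structurally unidentifiable even though $K_D$ and
$N\Delta H$ remain usable.

## Panel analytics

`load_panel()` validates a mutant-peptide table (exactly one wild-type per
panel, unique ids, exactly one `pY` per sequence, position labels of the
form `pY(±n)` or `X(±n)Y` parsing to integer offsets). The packaged
23-peptide fixture (`reference_panel()`) holds the GHR-derived and
EpoR-derived panels: wild-types, two valine point mutants, and complete
alanine scans with both assays' means ± s.e.m.

* **Concordance** (`assay_concordance()`): Pearson correlation of SPR $K_D$
  against NMR $K_i$ on log₁₀-transformed values pooled across panels.
  Affinities are log-normally distributed, so agreement between orthogonal
  assays is assessed on the log scale; on the packaged fixture this yields
  $R^2 = 0.74$ (n = 23), and the same value is obtained at any log base.
* **Fold-changes** (`fold_changes()`): mutant/wild-type ratio per assay
  within each panel; > 1 means weakened binding. Scale-invariant by
  construction.
* **Hotspots** (`call_hotspots()`): a scanned position is a hotspot when
  the *geometric mean* of the two assays' fold-changes is ≥ 2. The verbal
  rule "at least two-fold weakened" is ambiguous when assays disagree (the
  GHR pY(−2) position shows ~2.7-fold by NMR but ~0.9 by SPR); requiring
  joint support via the geometric mean resolves the ambiguity and
  reproduces both published hotspot sets on the fixture. `"either"` and
  `"both"` rules are available for sensitivity analysis. Only alanine-scan
  rows are scanned; non-alanine point mutants probe chemistry, not
  positional energetics.

## Structural interface metrics

`read_structure()` parses PDB and mmCIF through bio3d, keeping the first
model, reducing altlocs to the highest-occupancy conformer, flagging waters
and heteroatoms, and treating phosphotyrosine (PTR) as a peptide residue.

`compute_sasa()` is a Shrake–Rupley implementation with a deterministic
golden-spiral point set (default 960 points, probe 1.4 Å), a fixed
published heavy-atom radius set (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å),
hydrogens ignored, unknown elements falling back to a configurable default
with a warning. Buried surface area (`buried_surface_area()`) reports the
peptide-side ΔSASA as the headline number together with the receptor side
and their mean, because deposition services differ in convention; the
identity $\mathrm{bsa}_A + \mathrm{bsa}_B = SASA(A)+SASA(B)-SASA(A\cup B)$
holds by construction. Contacts (`list_contacts()`) use heavy-atom geometry
only: hydrogen bonds are N/O pairs within 3.5 Å passing an
antecedent–donor–acceptor angle ≥ 120° where an antecedent exists
(distance-only otherwise, flagged); hydrophobic contacts are apolar-carbon
pairs (no covalent N/O neighbour) within 4.5 Å.

Checks against deposited SH2-domain complexes (peptide-side buried areas of
roughly 595/641 Å², pY–pY Cα distances of ~23 Å) require downloading the
entries and are convention-sensitive; the same functions run unchanged on
any local PDB/mmCIF path, and the test suite exercises the machinery on
deterministic toy complexes instead.

## What the generators emulate — and what they do not

* `gen_cpmg_series()` uses the two-state fast-exchange observable model:
  bound fraction $f_b = [PL]/L_0$ from the equilibrium solver,
  $R_{2,obs} = (1-f_b)R_{2,free} + f_b R_{2,bound}$, mono-exponential decay
  with multiplicative Gaussian noise. Defaults $R_{2,free} = 3\,s^{-1}$ and
  $R_{2,bound} = 245.7\,s^{-1}$ are calibrated once so that the observed
  with-protein rate under the standard assay conditions
  ($f_b \approx 0.033$) equals the experimentally observed
  $11\,s^{-1}$.
* `gen_displacement_panel()` computes the $I_F$ and $I_P$ endpoints from
  that relaxation model at the 0.133 s delay and places $I_I$ *linearly in
  the remaining bound-spy fraction* between them. This is a deliberate
  modeling decision: the analysis equation for $f$ assumes the integral
  responds linearly to $[PL]$, and a generator violating that assumption
  (e.g. exponentiating a mixed rate, where $t\,\Delta R_2 \approx 32$)
  would make even noiseless data unrecoverable and would conflate model
  error with estimator error in the recovery tests. The consequence: the
  recovery tests validate the inference chain, not the linear-response
  approximation itself.
* `gen_spr_titration()` / `gen_itc_titration()` add additive Gaussian
  noise to the exact model curves (1 RU; 2% of the largest heat). True
  instrument noise magnitudes are not published for this assay family;
  these defaults are stated assumptions, chosen as typical of the
  instrument classes.
* None of the generators simulate raw FIDs, kinetic sensorgrams, baseline
  drift, or correlated (systematic) errors — so passing recovery tests
  demonstrate estimator correctness under the stated noise model, not
  robustness to every real-world artifact.

Every generator is a pure function of (parameters, seed): the RNG is seeded
locally and the caller's random state restored.

## Numerical choices and problem sizes

Tolerances: root-finding to relative $10^{-12}$; LM fitters run with
`ftol = ptol = 1e-15` so that noiseless round-trips reproduce generating
parameters to near machine precision. Degenerate inputs ($P_0 = 0$ or
$L_0 = 0$) return analytic zero states without invoking the solver.

The test suite checks mass-action invariants on 10,000 random systems,
solver-vs-oracle agreement on a 50×50 log-spaced $(K_D, K_i)$ grid, the
noise-magnitude contract over 400 seeds, and end-to-end hotspot recovery
(generate both assays → fit → call) over 60 seeds with a planted 4-fold
effect, recovered in ≥ 95% of seeds. These sizes were chosen to give the
invariants real coverage while keeping the default suite fast to run
locally.

Recovery statements for noisy data are made on 4-replicate means — the
same convention the assay tables use ("means ± s.e.m. from four independent
experiments") — because a single 7-point titration at 2% noise determines
$K_D$ only to roughly ±17% at the 90th percentile, which is a property of
the experiment design, not the fitter.

## Known limitations

* Single-site, non-cooperative models only; no kinetic (time-resolved)
  analysis of either NMR or SPR data.
* The displacement analysis inherits the linear-response assumption of the
  integral-ratio equation; strongly saturating CPMG filters violate it.
* ITC dilution control is a constant offset, not a fitted injection-wise
  baseline.
* The SASA kernel is O(n²) in atoms and intended for peptide–domain
  complexes, not megadalton assemblies.
* Hotspot calling requires both assays at every scanned position; it does
  not impute missing values.
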