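---
title: "Trajectory interaction analysis and stability quantitation with serpdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory interaction analysis and stability quantitation with serpdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpdyn)
```

`serpdyn` quantifies how a point mutation changes a serpin's structural
dynamics and conformational stability. The package has two halves: a
trajectory half that turns molecular-dynamics coordinate ensembles into
interaction occupancies, fluctuation profiles, correlated-motion rankings
and surface areas, and a spectroscopy half that turns denaturation curves,
emission spectra and gel densitometry into midpoints, moments and
fractions. This vignette is the package's own account of each method: the
model, its assumptions, the tunable parameters and their defaults, the
numerical choices, and what validation on synthetic data does — and does
not — establish about real simulation data.

## Data model

A `serp_topology` holds per-atom identity (name, element, residue, chain),
mass, and a van der Waals radius from an element-keyed table in the style
of classic accessibility programs (C 1.87 Å, N 1.65 Å, O 1.40 Å, S 1.85 Å,
H 1.00 Å; overridable per call). A `serp_trajectory` binds a T×N×3
coordinate array (Å) to its topology with strictly increasing frame times
(ns). PDB parsing is delegated to `bio3d`; multi-model PDB and a plain
`xyz-frames` text format are the trajectory carriers, with times assigned
as frame index × `dt` because neither format stores physical time
(`dt` defaults to 0.1 ns, a typical snapshot interval).

Chemistry needed by the detectors is derived, not trusted from input:
every hydrogen is paired with its nearest heavy atom within 1.2 Å in the
reference coordinates — the covalent-bond criterion — rather than from
CONECT records, which MD-derived PDB files rarely carry. Acceptors are all
N and O atoms; acidic oxygens follow residue templates (Asp OD1/OD2, Glu
OE1/OE2, C-terminal carboxylate); basic hydrogens are those bonded to Arg
NE/NH1/NH2, Lys NZ, or — only when the residue is marked protonated — His
ND1/NE2. Histidine protonation is genuinely ambiguous in most inputs
(force-field preparation tools decide it per residue), so the package
takes an explicit `his_protonation` map and defaults to neutral rather
than claiming fidelity to any particular preparation.

## Interaction detection and occupancy

A hydrogen bond requires d(D,A) ≤ 3.0 Å **and** an angle ≤ 30° between
the D→H and D→A vectors; a salt bridge requires an acidic oxygen within
3.0 Å of a basic hydrogen. Two conventions were open:

- *Angle.* The 30° cutoff is applied to the D→H/D→A angle, the convention
  of the standard MD hydrogen-bond tools this definition descends from.
  The alternative reading — the deviation of the D–H–A angle from
  linearity — is available via `angle_convention = "DHA-deviation"`.
- *Boundaries.* Distance and angle comparisons are inclusive (a pair at
  exactly 3.0 Å counts), while the persistence threshold is strict: "more
  than 50 % occupancy" means occupancy > 0.5, so a pair at exactly 0.5 is
  persistent in neither variant and never appears in a difference set.

Occupancy is the fraction of frames a pair is detected. At residue level a
frame counts once if *any* constituent atom pair is in contact, matching
how persistent bonds are reported residue-by-residue (e.g. Glu289–Arg362).
Occupancy-zero rows are suppressed. `occupancy_diff(a, b, threshold)`
partitions pairs into unique-to-a, unique-to-b and shared at the
threshold; `compare_variants()` mirrors exactly under argument swap.

Periodic boundary images are **not** considered: the analysis assumes a
whole, wrapped solute, which is the normal state of protein-only
coordinates exported for analysis. Inputs without hydrogens are refused by
the detectors unless a documented heavy-atom proxy mode is enabled
(distance-only H-bond test; basic nitrogens with the cutoff extended by
one N–H bond length for salt bridges); the proxy trades geometric
specificity for applicability and is flagged with a warning wherever it
engages.

## Superposition and fluctuations

Global motion is removed by Kabsch superposition: the SVD solution of the
weighted least-squares rotation, with reflections excluded by sign
correction, so the returned matrix is always a proper rotation.
`fit_trajectory()` defaults to the *iterated-mean* reference — fit to
frame 1, then re-fit to the running mean structure until it moves by less
than 1e-6 Å — because a mean reference removes the arbitrary choice of
frame; a `first-frame` option is kept since the canonical reference for
any given study is unknowable from the data.

RMSF is computed per residue on Cα atoms by default (the convention of
Cα-based covariance analysis; any selection can be substituted), about the
trajectory-mean position, with **population** (1/T) time averages
throughout. That convention is load-bearing: it makes
trace(C) = Σ RMSF² an exact algebraic identity between the covariance and
fluctuation modules, which the test suite asserts to 1e-10.

The radius of gyration is mass-weighted over all atoms by default.
"Stationary" summaries are trailing-window time averages over
(t_max − window, t_max], with a 20 ns default window; a window equal to
the full span averages every frame. No plateau detection is attempted —
the window is an explicit, reported parameter, not an inference.

## Correlated motions

The covariance C = ⟨δr δrᵀ⟩ of the fitted Cα coordinates feeds the linear
mutual information

I_ij = ½ ( ln det C_i + ln det C_j − ln det C_ij ),

with C_i the atom's 3×3 marginal block and C_ij the 6×6 joint block. This
is the Gaussian (linear) mutual information: it is exact for a
multivariate-normal ensemble and a lower bound otherwise. A ridge of
1e-10 Å² keeps near-static atoms' blocks nonsingular. Reporting uses the
generalized correlation coefficient gcc = √(1 − e^{−2I/3}), a Pearson-like
[0,1] magnitude (the diagonal is the sentinel Inf / 1).

"Correlated but structurally distant" pairs are selected purely
geometrically: trajectory-mean Cα–Cα distance > 20 Å (2 nm) plus a
sequence-separation guard of 4 residues, with no secondary-structure
assignment dependency — the distance filter *is* the operational
definition of "not in the same structural element". The mean distance was
chosen over min/max (both available) as the least frame-sensitive
statistic. The default of 10 reported pairs is a plotting convention, not
a statistical claim; ties in I are broken by residue order for
determinism.

Estimator behaviour verified on synthetic Gaussian ensembles: the sampled
LMI converges to the closed form −½ Σ ln(1−ρ_k²) as T grows, added
isotropic noise never increases it beyond sampling error, and T = 10⁵
frames puts the estimate within a few thousandths of a nat (standard
errors assessed by disjoint-block resampling).

## Solvent-accessible surface area

SASA uses Shrake–Rupley point sampling: each heavy atom's sphere of radius
r_vdw + 1.4 Å carries a deterministic Fibonacci (golden-angle) lattice of
960 points; a point is accessible when outside every neighbour's expanded
sphere. Point sampling was chosen over analytical slice methods because it
exposes a single convergence knob (`n_points`) that is directly testable:
isolated spheres are exact by construction, overlapping-sphere errors
shrink as the lattice refines and sit well under 1 % of the spherical-cap
closed form at the default. The deterministic lattice makes results
bit-reproducible and translation-invariant; rotation invariance holds to
lattice tolerance (≤ 1 %). Absolute areas are reported (Å²); no
normalisation against extended-tripeptide references is attempted.

## Denaturation fitting and spectroscopic summaries

Sigmoidal transitions use the Boltzmann logistic

y = b₀ + Σ_k A_k / (1 + exp((m_k − x) / w_k)),

with a shared baseline and one or two transitions; "sigmoidal" fixes no
particular family, and the Boltzmann form is the standard choice when no
thermodynamic linear-extrapolation model is intended (m-value analysis is
deliberately out of scope). Fitting is Levenberg–Marquardt
(`minpack.lm`), with midpoints bounded to the x range and widths to
[10⁻³, 1] × span. Initialisation places midpoints at the steepest points
of the numerical derivative; because the width is the least identifiable
parameter, the optimiser is started from several width scales
(span/30 … span/4) and the lowest-RSS solution is kept — single-start
fits occasionally strand in a collapsed-width local minimum on noisy
25-point curves. Standard errors come from the fit covariance
σ²(JᵀJ)⁻¹. A fit is flagged low-confidence when an amplitude is not
resolved above the residual noise (|A| < 3σ) or a midpoint standard error
exceeds a quarter of the x span, so flat or drifting curves yield a
warning rather than a spuriously confident midpoint.

The emission first moment λ₁ = ∫λL(λ)dλ / ∫L(λ)dλ uses trapezoid
integration on the native wavelength grid (no resampling; resampling
would smuggle in an interpolation model). It is invariant under intensity
scaling, equivariant under wavelength shifts, and biased towards the
retained side when the grid truncates the band — the generator warns in
that case. The CD conversion Δε_res = θ / (32980 · c · l · n_res) adopts
the standard millidegree conversion constant, exposed as an argument.
Lane densitometry divides each band by its lane total (so fractions sum
to 1 exactly); the ×5 display scaling of minor oligomer bands affects a
separate display column only, never analysis values.

## Synthetic data: what it emulates and what it does not

The generators define the validation conditions and return machine-readable
ground truth:

- `gen_gaussian_trajectory()` draws i.i.d. frames from a prescribed 3N×3N
  covariance (isotropic per-atom marginals plus planted per-axis
  cross-correlations, positive-definiteness checked at build). It gives
  closed-form targets for covariance, RMSF (σ√3 for isotropic jitter) and
  LMI, but has no time correlation — real MD frames are autocorrelated,
  so real-data standard errors are larger than the i.i.d. ones tested.
- `gen_interaction_rig()` builds a minimal Glu/Arg (or donor/acceptor)
  geometry that satisfies the contact criteria in exactly
  ⌈fraction·T⌉ frames — the on-frames are a seeded draw of that exact
  count, not Bernoulli — and violates the cutoff by ≥ 0.5 Å otherwise, so
  occupancy checks are exact equalities.
- `gen_rigid_tumble()` applies random proper rotations (quaternion draw)
  and translations to a fixed structure: any post-fit fluctuation is pure
  numerical error.
- `gen_denaturation_curve()` / `gen_spectrum()` produce Boltzmann curves
  and Gaussian bands with additive Gaussian noise scaled as a percentage
  of the dynamic range. The midpoint-recovery checks use a two-step
  unfolding curve with transitions at 0.8 M and 2.6 M denaturant, 1 %
  noise and 25 points over 0–5 M — deliberately sparse, matching
  realistic titration practice.

Passing these checks establishes that the estimators are *correct
implementations of their definitions* and well-behaved at realistic noise
and sampling. It does not establish that 50–100 ns all-atom trajectories
of a real ~400-residue serpin are converged enough for their headline
numbers to be stable — that is a property of the simulation, not of the
analysis, and no synthetic test can stand in for it. Problem sizes used in
the shipped tests (ensembles up to 10⁵ frames of small atom groups,
25-point titration curves, 100 randomized detector rigs) were chosen so
every closed-form comparison has comfortable statistical resolution.

## Degenerate inputs and edge policies

Collinear or < 3-point sets are refused by the superposition (the rotation
is underdetermined); single-frame trajectories pass through fitting
unchanged up to one rigid transform; trajectories without Cα fall back to
heavy atoms in the pipeline report; empty and self-identical selections,
zero-area spectra, zero-density lanes, non-increasing x grids, frame-shape
mismatches (reported with the frame number) and windows longer than the
series span all raise immediate, specific errors rather than propagating
NaN.

## Known limitations

- No periodic-image handling; no binary trajectory formats (text PDB and
  xyz-frames only — convert upstream).
- LMI is the linear (Gaussian) information; genuinely nonlinear coupling
  is underestimated. Nonlinear estimators are used nowhere except as
  conceptual contrast.
- The long-range pair list depends on the 2 nm / sequence-separation
  filter; it is a reporting device, not a hypothesis test — no p-values
  are attached.
- Heavy-atom proxy detection is a documented approximation for
  hydrogen-free inputs, not an equivalent of the full geometric
  definition.
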