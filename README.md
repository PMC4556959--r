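# serpdyn

Comparative molecular-dynamics trajectory analysis and stability
quantitation for serpin variants.

Serpins (SERine Protease INhibitors) such as human neuroserpin inhibit
their target protease through a mousetrap-like mechanism centred on the
reactive centre loop (RCL). Point mutations that remove an RCL-anchoring
salt bridge can subtly change a serpin's stability, dynamics and activity.
Deciding whether such a change is real requires a reproducible analysis
chain on both the simulation side (is an interaction persistently present
in one variant and absent in the other? do distant regions move together?)
and the spectroscopy side (do denaturation midpoints shift?). `serpdyn`
implements that chain as a tested R package for structural-bioinformatics
users who have trajectories and spectra in hand and need defensible
numbers out.

## What it computes

**Trajectory side** (coordinates in Å, times in ns):

- *Interactions.* A hydrogen bond is scored when the donor–acceptor
  distance satisfies d(D,A) ≤ 3 Å and the D→H / D→A angle is ≤ 30°; a salt
  bridge when an acidic-residue oxygen (Asp/Glu carboxylate) lies within
  3 Å of a basic-residue hydrogen (Arg, Lys, protonated His). Per-pair
  *occupancy* is the fraction of frames the interaction is present;
  `occupancy_diff()` splits pairs into those persistent (occupancy > 50 %)
  in only one variant.
- *Fluctuations.* Kabsch least-squares superposition removes global
  translation/rotation; then RMSD series, per-residue RMSF
  √⟨|r<sub>i</sub> − ⟨r<sub>i</sub>⟩|²⟩, mass-weighted radius of gyration,
  and trailing-window ("last 20 ns") stationary averages.
- *Correlated motions.* The 3N×3N covariance of coordinate fluctuations
  C = ⟨δr δrᵀ⟩ feeds the linear mutual information between residues i, j:
  I<sub>ij</sub> = ½(ln det C<sub>i</sub> + ln det C<sub>j</sub> −
  ln det C<sub>ij</sub>), reported alongside the generalized correlation
  coefficient gcc = √(1 − e<sup>−2I/3</sup>) ∈ [0,1], with ranking of
  strongly correlated residue pairs more than 2 nm apart.
- *Surface.* Shrake–Rupley SASA: a 1.4 Å probe rolled over the van der
  Waals surface of the heavy atoms, sampled on a deterministic Fibonacci
  sphere lattice.

**Spectroscopy side** (two-column text curves):

- Boltzmann sigmoid fits, y = b₀ + Σ<sub>k</sub> A<sub>k</sub>/(1 +
  e<sup>(m<sub>k</sub>−x)/w<sub>k</sub></sup>), for thermal (T½) and one-
  or two-transition chemical denaturation midpoints with standard errors;
- the first moment λ₁ = ∫λL(λ)dλ of a normalised emission spectrum
  (tryptophan exposure red-shift);
- CD mdeg → per-residue Δε conversion (θ / (32980·c·l·n<sub>res</sub>));
- gel-lane densitometry normalisation with replicate summaries.

A synthetic-data module (`gen_gaussian_trajectory`, `gen_interaction_rig`,
`gen_rigid_tumble`, `gen_denaturation_curve`, `gen_spectrum`) generates
every input with known ground truth, so each estimator is validated against
closed forms and brute-force oracles.

## Worked example

Plant a salt bridge between residues 289 (Glu) and 362 (Arg) in 90 % of
frames of one synthetic trajectory and 10 % of another, then compare:

```r
library(serpdyn)

wt  <- gen_interaction_rig("saltbridge", fraction = 0.9, n_frames = 10, seed = 5)
mut <- gen_interaction_rig("saltbridge", fraction = 0.1, n_frames = 10, seed = 5)

tp <- track_pair(wt$traj, 289, 362)
tp$fraction_below
#> [1] 0.9

rep <- compare_variants(wt$traj, mut$traj, labels = c("WT", "MUT"),
                        window = 0.9, fit_selection = "all", run_lmi = FALSE)
rep
#> <comparison_report>
#>   WT: RMSD* 0.059 A, Rg* 2.864 A, SASA* 260 A^2, HB>thr 0, SB>thr 1
#>   MUT: RMSD* 0.059 A, Rg* 3.316 A, SASA* 278 A^2, HB>thr 0, SB>thr 0
#>   unique persistent H-bonds: 0 vs 0; salt bridges: 1 vs 0
#>   (* trailing-window time averages)

rep$saltbridge_diff$unique_to_a[, c("resid_a", "resname_a", "resid_b", "resname_b", "occupancy")]
#>   resid_a resname_a resid_b resname_b occupancy
#> 1     289       GLU     362       ARG       0.9
```

The charged-group distance stays below the 3 Å cutoff in 90 % of wild-type
frames, the Glu289–Arg362 bridge is the single interaction persistent
(occupancy > 0.5) in only one variant, and the summary rows mirror the
per-variant structural table (stationary RMSD, Rg, SASA and persistent-bond
counts).

On the spectroscopy side:

```r
g <- gen_denaturation_curve(midpoints = c(0.8, 2.6), widths = 0.15,
                            amplitudes = c(10, 10), baseline = 330,
                            noise_pct = 1, n_points = 25, seed = 42)
fit <- fit_denaturation(g$curve, n_transitions = 2)
fit
#> <sigmoid_fit> 2 transition(s), RSS 1.355
#>   midpoint 0.8066 +/- 0.023, width 0.1554, amplitude 10.18
#>   midpoint 2.612 +/- 0.02, width 0.1484, amplitude 9.706
```

Both planted midpoints of the two-step unfolding transition (0.8 M and
2.6 M denaturant) are recovered well within their standard errors.

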