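---
title: "Models and methods behind serpinfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind serpinfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpinfold)
```

`serpinfold` implements the computational workflow for designing a
consensus serpin from a family alignment and characterising its
folding: equilibrium chemical denaturation, chevron kinetics with a
folding-intermediate model, thermal melts, inhibition stoichiometry,
and comparative structure metrics. This vignette documents the models,
their assumptions, the tunable parameters, and the numerical choices —
including the places where the package had to make a decision that the
field's conventions leave open.

## Consensus design from an alignment

The consensus method takes, at every alignment column, the most
frequently observed residue. Around that one-line idea sit three
conventions the package makes explicit:

* **Incomplete-sequence filter.** Sequences whose non-gap coverage is
  below `min_coverage` (default 0.9) are removed first, because
  fragments bias column counts toward whatever region they happen to
  cover. The default is a common choice, not a claim about how any
  particular published alignment was filtered; it is exposed as an
  argument.
* **Redundancy reduction.** Near-duplicate sequences would let one
  well-sequenced genus dominate the vote. `reduce_redundancy` performs
  greedy representative selection in input order at a gap-excluded
  identity threshold (default 0.9): a sequence is kept iff it is below
  the threshold against every previously kept sequence. Greedy
  selection is deterministic, cheap, and idempotent; it is not a
  globally optimal clustering, which the task does not need.
* **Gaps and ties.** A column where the gap symbol is the *strict*
  plurality is dropped from the consensus — this is precisely how a
  consensus design ends up shorter than family members. `X` counts as
  ambiguity and can never win. Ties between residues break
  alphabetically by default (deterministic and auditable; every tie is
  reported in the result), with a seeded random rule available.

Comparison to a reference (`compare_to_reference`) uses global
Needleman–Wunsch alignment with BLOSUM62, gap open 10 and extension
0.5 — the de-facto defaults of classical global aligners. Percent
identity is reported with two denominators (full alignment length, and
the shorter sequence) because published identity figures rarely say
which was used; residue differences count mismatched aligned pairs
plus inserted/deleted residues. The numbering map renders every
aligned pair as `<refAA><refPos><tgtAA>_<tgtPos>` (e.g. `Q105R_79`),
the dual-numbering convention used when two homologous serpins are
discussed together.

## Two-state equilibrium unfolding

`fit_two_state` fits the six-parameter Santoro–Bolen form — a
two-state transition with linear native and denatured baselines:

$$y([D]) = \frac{(a_N + b_N[D]) + (a_D + b_D[D])\,
  e^{m([D]-[D]_{50})/RT}}{1 + e^{m([D]-[D]_{50})/RT}}$$

with $R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and a default
temperature of 298.15 K (the interface takes a `temperature` argument;
25 °C is the standard assumption when an experiment temperature is not
stated). Stability follows by linear extrapolation,
$\Delta G_{D\text{-}N} = -m\cdot[D]_{50}$, reported negative for a
stable fold, with first-order error propagation that includes the
$m$–$[D]_{50}$ covariance. The identity
$\Delta G = -m\cdot[D]_{50}$ holds to machine precision for every
returned fit because it is computed, not re-fitted.

Initial guesses come from the data: terminal linear fits for the
baselines, the half-span crossing for $[D]_{50}$, and the 25–75%
transition width for $m$. Fits are performed with
Levenberg–Marquardt (`minpack.lm`); a curve whose span is
indistinguishable from its noise raises a structured
`no_transition_error` rather than a misleading fit.

**Reversibility.** `reversibility` fits unfolding and refolding curves
independently and requires (i) $[D]_{50}$ and $m$ to agree within
`se_tol` joint standard errors and (ii) the implied fraction-folded
curves to overlay within `frac_tol` (default 0.05). The default
`se_tol` is 2.5: with two compared parameters, a 2-SE conjunction
would mislabel roughly 9% of genuinely reversible pairs
($1 - 0.954^2$), while 2.5 SE keeps that below ~3%. Note that for a
transition as steep as a stable serpin's ($m \approx 8$), the 5%
fraction-folded bound is itself a demanding criterion — it corresponds
to midpoint agreement of roughly 0.015 M — so a small fraction of
truly reversible replicate pairs will still be called hysteretic at
realistic noise; both thresholds are exposed.

**bis-ANS peaks.** The dye reports exposed hydrophobic surface, so a
peak at intermediate denaturant marks a molten/intermediate ensemble.
`detect_ans_peak` interpolates a baseline between the native-end and
denatured-end medians and calls a peak where the excursion exceeds
`k_mad` (default 5) times the MAD of the flanks for at least two
consecutive points — a conservative rule chosen because published
profiles describe peaks qualitatively, without a detection algorithm.

## Folding kinetics and the ground-state switch

`fit_exponentials` fits sums of 1–3 exponentials plus an offset, with
rates parameterised on a log scale for positivity, and selects the
*smallest* number of phases such that no larger model improves the
corrected AIC by more than 10 — a deliberately strict threshold, since
exponential sums overfit notoriously. Rates within a ratio of 1.05 are
treated as degenerate and the simpler model wins. The first 2 ms of
each trace are excluded by default (stopped-flow mixing dead time);
fitted amplitudes are therefore referenced to the start of the
post-dead-time window.

`build_chevron` assigns phase labels (`refold-fast`, `refold-slow`,
`unfolding`) by continuity: each limb's trajectory is extrapolated
from its previous two points and observed rates are matched to the
nearest prediction. This matters because the two refolding limbs can
genuinely *cross*; labelling by rank at each concentration would swap
identities at the crossing. Points that cannot be assigned confidently
— a single observed phase lying close to both limb predictions, or an
amplitude consistent with an unresolved blend of two nearly degenerate
phases — are flagged, and flagged points are excluded from model fits
and the diagnostics (they remain in the dataset for inspection).

The fast refolding limb is modelled as folding from a rapid
pre-equilibrium between the denatured state D and an intermediate I1:

$$k_{obs} = \frac{k_f\,e^{-m_{kf}[D]}}{1 + K_{DI}([D])}
  + k_u\,e^{+m_{ku}[D]},\qquad
  K_{DI} = e^{-(\Delta G_{DI} + m_{DI}[D])/RT}$$

When I1 is more stable than D (low denaturant, $K_{DI} > 1$) the
observed rate is suppressed by the pre-equilibrium, and because
$m_{DI}/RT > m_{kf}$ the refolding limb's slope is *positive* — the
kinetic signature that the starting state is structured. The ground
state switches from I1 to D where the two species are equally stable,
$K_{DI} = 1$, i.e. at $[D] = -\Delta G_{DI}/m_{DI}$, reported as
`crossover_conc`. The slower limb (I2) is fitted in parallel with its
own stability and, by default, the same kinetic folding m-value
(`share_m_kf = TRUE`), reflecting the assumption that both
intermediates fold over the same major transition state; the option
exists because that is an assumption, not an observation. The
`kinetic_midpoint` is the concentration where the observed fast
refolding rate equals the unfolding rate, found numerically above the
crossover (below it, the extrapolated unfolding rate can intersect the
I1-suppressed refolding rate a second, physically irrelevant time).
For a clean two-state folder this midpoint must agree with the
equilibrium $[D]_{50}$, and the two-state consistency
$m_{D\text{-}N} = RT(m_{kf}+m_{ku})$ links the kinetic and equilibrium
m-values; both identities are exercised in the test suite.

`diagnose_phase_origin` implements three mechanism tests on a chevron
with two refolding limbs:

1. **Do the rates cross?** Directly, as a sign change of
   $\ln k_{fast} - \ln k_{slow}$ on the shared grid; or, when the
   crossing region itself is unresolved, as the intersection of the
   two limbs' local linear trajectories.
2. **Does the fast phase survive the crossing?** If folding were
   sequential (fast to intermediate, then slow to native), the fast
   phase should become kinetically invisible once the rates cross.
   The package tests this label-independently: a gap between the last
   concentration with observable refolding and the first with
   observable unfolding marks a vanished phase.
3. **Is the amplitude ratio constant?** Two fluorophores reporting
   independent folding events would keep a fixed amplitude ratio. The
   package regresses the log amplitude ratio on denaturant with a
   Theil–Sen slope (robust to single unstable amplitude estimates,
   which occur where the rates are barely resolved; only
   concentrations with a rate separation above 3-fold enter) and calls
   the ratio constant when the implied systematic fold change across
   the range is below 1.5.

The verdict is `parallel-ground-states` iff the rates cross, the fast
phase persists, and the ratio is not constant; `sequential` when the
fast phase vanishes past the crossing; `independent-probes` when the
ratio is constant; otherwise `inconclusive`.

## Thermal melts

`fit_melt` uses van't Hoff transitions with linear baselines:
$K(T) = \exp[(\Delta H/R)(1/T_m - 1/T)]$, two-state or two sequential
transitions sharing the middle (intermediate) baseline. Interfaces are
in °C, internals in Kelvin. Because serpin thermal unfolding is
usually irreversible (the unfolded material aggregates), the fitted
$\Delta H$ and $T_m$ are *apparent* quantities and are documented as
such — the package fits the curve shape without claiming equilibrium
validity.

A transition whose fitted $T_m$ lies within 5 °C of, or beyond, the
scan maximum is reported with an `incomplete` flag rather than
rejected; its post-transition baseline slope is fixed at zero, since
it is not identifiable from data that never reach the plateau.
`detect_transition` compares a straight line against the two-state
sigmoid by corrected AIC with the same Δ > 10 rule used for
exponential counting. Initial $T_m$ guesses come from the extremum of
the smoothed signal derivative, with scan-edge points excluded (the
smoothing window is incomplete there and raw noise leaks through);
the weakly determined second transition of an incomplete three-state
fit is retried from alternative starting values when the first attempt
fails to converge.

`spectral_change` interpolates two far-UV spectra onto a shared grid
(required overlap ≥ 50 nm) and calls them unchanged when the maximum
absolute difference, normalised by the first spectrum's maximum, is
below 5%.

## Inhibition stoichiometry

Serpins are suicide substrates: each encounter partitions between
covalent inhibition and cleavage-and-release, so SI moles of serpin
are consumed per mole of protease inhibited. `stoichiometry` fits
ordinary least squares to the linear descending region of the
titration — points with residual activity above 0.1, which excludes
the post-equivalence plateau — and reports the x-intercept with a
delta-method standard error. The relation `k_ass = SI × k_ass_app`
follows from the same partitioning: only 1 in SI association events
registers as inhibition, so the apparent rate underestimates the true
one by that factor. An SI below 1 is unphysical and draws a warning
rather than an error, since noisy estimates can dip below 1 for a
perfect inhibitor.

## Structure metrics

All metrics use heavy atoms only, because deposited X-ray structures
lack hydrogens:

* **Hydrogen bonds**: donor N/O (with proton-bearing chemistry per the
  standard residue table; proline backbone N excluded) to acceptor N/O
  at ≤ 3.5 Å with an antecedent–donor–acceptor angle ≥ 120°. Both
  cutoffs are conventional and configurable.
* **Salt bridges**: Lys NZ, Arg NE/NH1/NH2 or His ND1/NE2 within
  4.0 Å of Asp OD1/OD2 or Glu OE1/OE2; multiple atom pairs between one
  residue pair count once, at the minimum distance.
* **ASA**: Shrake–Rupley with 960 golden-spiral sample points per atom
  by default, probe 1.4 Å, van der Waals radii C 1.70, N 1.55, O 1.52,
  S 1.80 Å. An isolated atom reproduces $4\pi(r+1.4)^2$ essentially
  exactly; note that because the sample points have a fixed
  laboratory-frame orientation, ASA is rotation-invariant only to the
  sampling resolution (~0.1% at the default density).
* **Cavities**: the padded bounding box is voxelised (default 0.7 Å;
  the spacing must not exceed the probe radius), voxels within
  vdW + probe of any atom are occupied, free voxels 6-connected to the
  boundary are bulk solvent, and the remaining free voxels form the
  solvent-inaccessible cavities, reported per connected component as
  voxel count × spacing³. Cavity volumes are inherently
  method-dependent (grid spacing, radii, probe), so cross-software
  comparisons should be treated as approximate.
* **RMSD**: atoms are paired by chain, residue number, insertion code
  and atom name over the CA or backbone selection; residues whose
  identities disagree are excluded and flagged rather than silently
  aligned. The optimal rigid transform is the closed-form Kabsch
  solution (SVD of the covariance of the centred sets, with the
  reflection guard).

PDB reading is delegated to `bio3d`'s parser behind `read_structure`,
which adds the package's conventions: highest-occupancy altloc wins
(ties to `A`), waters excluded by default, malformed coordinate lines
reported with their line number.

## The synthetic-data generators

Every generator is deterministic under `(seed, parameters)` and
returns a machine-readable `truth` record; changing only the seed
changes only the noise realisation. Noise is Gaussian on the signal,
expressed as a fraction of the signal span for curves and melts and as
1/SNR for kinetic traces; MSA generation uses i.i.d. substitutions
with a uniform replacement residue. These are the simplest models
consistent with the data types; they deliberately do *not* emulate
correlated instrument drift, photobleaching, phylogenetic covariation
between sequences, or mixing artefacts beyond a constant dead time —
so parameter-recovery results here bound what is achievable on real
data rather than guaranteeing it.

Choices worth knowing about:

* **Equilibrium grid.** The default titration design is 25 points
  spanning 0–6 M: 12 coarse points for the baselines plus 13 fine
  points across the transition (midpoint ± 0.9 M). For a steep serpin
  transition (m ≈ 8.45, width ≈ 0.5 M) a uniform 25-point grid would
  put essentially one point inside the transition, leaving the m-value
  unidentifiable — the least-squares objective becomes flat in m — and
  no real titration of a steep unfolder is designed that way.
* **Chevron preset.** No numeric rate constants were available to
  encode, so the preset plants the qualitative topology with realistic
  stopped-flow magnitudes and the two stated landmarks exactly:
  ln k_f = ln 2000, m_kf = 1.5 M⁻¹, ΔG_DI = −4.0 kcal/mol, m_DI = 2.0
  kcal/mol/M (crossover exactly 2.0 M); slow limb ln k_f2 = ln 2.9e5,
  ΔG_DI2 = −12.375, m_DI2 = 4.5 (ground-state switch at the 2.75 M
  midpoint, and a limb crossing just above 2 M); m_ku = 0.9 M⁻¹ with
  ln k_u solved so the observed fast refolding rate equals the
  unfolding rate at exactly 2.75 M. Phases outside the instrument
  window (default 10⁻³–600 s⁻¹: slower than the acquisition time or
  faster than the dead time) are omitted from traces, as they would be
  in a real experiment. The three mechanistic variants differ only in
  their amplitude patterns: constant amplitudes for `two-probe`, a
  drifting ratio for the parallel preset, and a fast-phase amplitude
  that collapses at the crossing for `sequential`.
* **Toy structures.** The hollow-sphere fixture places carbon atoms on
  a shell of radius (void + vdW + probe) at ~0.8 Å spacing, so the
  interior cavity boundary is analytically the requested sphere and
  the flood-fill volume can be checked against (4/3)πr³. Salt-bridge
  and H-bond fixtures plant their geometry (distances and the 150°
  donor angle) exactly.

## Problem sizes and runtime

The shipped tests and the acceptance script use the study-scale
replicate counts — 100 synthetic curves per equilibrium preset, 100
melts per melt preset, 50 full trace-to-chevron pipeline runs (24
concentrations each), 200 seeds for the exponential model-selection
property — which together run in a few minutes on a single core.
Structure metrics are exercised on fixtures of tens to hundreds of
atoms; ASA and cavity computation scale to full protein chains but are
pure-R implementations, so expect seconds to minutes, not
milliseconds, for thousands of atoms.

## Known limitations

* Three-state *equilibrium chemical* denaturation is out of scope by
  design: the intermediates modelled here are kinetically, not
  thermodynamically, populated, and the equilibrium module is strictly
  two-state.
* The chevron module fits limb parameters and landmarks; it does not
  model polymerization kinetics, proline-isomerisation phases beyond a
  generic slow contaminant, or Phi-value analysis.
* The SI regression assumes a linear titration with a sharp
  equivalence point; progress-curve analysis of raw fluorogenic
  substrate data is not implemented.
* Thermal-melt parameters for aggregating proteins are apparent
  quantities; no scan-rate-dependent irreversibility model is fitted.
* The structure module reads PDB format only (no mmCIF), and cavity
  volumes should be compared across programs only qualitatively.
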