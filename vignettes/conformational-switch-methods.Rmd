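---
title: "Methods: characterizing a monomer-to-tetramer conformational switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing a monomer-to-tetramer conformational switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraconf)
```

# The scientific problem

MLKL, the terminal effector of necroptosis, is a two-domain protein: an
N-terminal four-helix bundle (4HB, residues 2–154) that permeabilizes
membranes, a two-helix brace (≈155–189), and a pseudokinase domain (PsKD,
190–471) that acts as a conformational switch. Activation converts a
closed monomer — the 4HB packed against the PsKD αC helix — into an open
conformer that assembles into a C4-symmetric tetramer. No single
technique resolves this switch: the evidence is integrative, combining
normal-mode modelling of the domain closure, chemical crosslinking
distance restraints, hydrogen–deuterium exchange (HDX) protection
patterns, small-angle X-ray scattering (SAXS) of the assembly, native
mass spectrometry of intact complexes, thermal-shift ATP titrations, and
sedimentation velocity. `tetraconf` re-implements each of those analysis
stages as tested, reusable code, with seeded synthetic-data generators
standing in for raw instrument data.

# Models and procedures

## Elastic-network modes and domain-closure tracking

The monomer is coarse-grained to one bead per Cα. An anisotropic network
model (ANM) places a harmonic spring of uniform stiffness γ (default 1,
arbitrary energy/Å²) between every Cα pair closer than a cutoff (default
15 Å, the conventional choice for Cα ANMs). The 3N×3N Hessian assembled
from the standard super-elements is diagonalized exactly; a connected
network has exactly six zero-frequency rigid-body modes, which are
discarded after verification.

*Rigid-mode tolerance.* Numerical zeros from the symmetric
eigendecomposition sit below 1e-14 of the largest eigenvalue, while the
softest genuine mode of a thin-linker model can sit near 1e-8. The
default threshold of 1e-12 separates these two populations; at 1e-8 a
connected dumbbell can be misclassified as disconnected mid-trajectory.

*Closure tracking.* The transition search displaces the structure along a
low-frequency eigenvector and relaxes the geometry, iterating until the
two domains touch:

- iteration 1 picks the lowest-frequency non-rigid mode whose
  displacement (signed so the domain centroids approach) reduces the
  minimum inter-domain Cα–Cα distance; that eigenvector becomes the
  *reference*;
- later iterations recompute the modes on the relaxed geometry and try
  candidates in descending order of overlap (absolute cosine) with the
  reference, accepting the first that does not increase the minimum
  inter-domain distance. Trying both displacement signs and falling back
  past the single best-overlap mode is a deliberate extension: with one
  candidate only, mode mixing stalls the dumbbell trajectory around
  13 Å. Monotone non-increase of the distance is still enforced; if no
  candidate advances, the run reports `converged = FALSE` rather than
  erroring.
- the step amplitude scales each mode so the largest per-residue
  displacement is `step` Å (default 0.5; the conservative default keeps
  the harmonic approximation valid but needs a higher iteration cap for
  large closures — the test fixture uses 1.0 with `max_iter = 800`);
- relaxation minimizes a Cα-level pseudo-energy — harmonic restraints on
  the sequential bond lengths of the starting topology plus a quadratic
  soft-sphere repulsion below 4 Å — with L-BFGS (≤200 iterations). This
  replaces all-atom minimization; its role is purely to preserve chain
  connectivity and prevent overlaps.
- contact is declared at a minimum inter-domain Cα–Cα distance of 8 Å
  (configurable), a standard proxy for side-chain contact at Cα
  resolution.

## Crosslink restraints

Identified crosslinks are residue pairs with a linker chemistry. DMTMM
(zero-length amide coupling of K with D/E) implies a Cα–Cα upper bound
of 30 Å; the ~11 Å-spacer amine-reactive reagents DSS and BS³ (K/S/T/Y)
allow 35 Å. Distances are measured Cα–Cα with the bound compared
inclusively (≤): the knife-edge difference from a strict inequality is
immaterial at reported precision. On an oligomer, each link takes the
minimum over all chain assignments (the standard optimistic convention);
homotypic links (same residue on both sides) exclude the self-assignment
and are the only links that unambiguously demonstrate inter-subunit
contact in a homo-oligomer. The tetramer refinement restraints that a
rigid-body tool would place on lysine Nζ atoms act here on Cα with the
target distance unchanged — a documented ±1–2 Å approximation.

## HDX per-residue profiles

Peptide-level deuteration (percent of theoretical maximum) is converted
to per-residue profiles: each peptide contributes its value to residues
`start + exclude_prefix … end`, and residues average the contributions
of covering peptides without weighting. `exclude_prefix` defaults to 2
(rapid back exchange of the first residues); 3 is available because the
stricter variant is also in common use — the choice is logged in the
profile's attributes. Replicates are averaged per peptide *before*
pooling across peptides; the SEM is computed *across replicates* (each
replicate is pooled to a per-residue value first). No further
back-exchange correction is applied. The theoretical maximum for a
peptide is `length − 1 − #(prolines after position 1)` exchangeable
backbone amides.

A subtlety worth stating: with overlapping peptides, per-residue
re-aggregation of a *step-like* truth cannot be exact even at zero noise
— peptides straddling the step carry intermediate values (peptide-level
smearing is inherent to HDX). Zero-noise closure of the synthetic
generator is therefore exact only for locally constant profiles; for a
step the differential localizes the transition to within roughly one
peptide length, which is what the tests assert.

## SAXS

*Guinier.* The fit maximizes the low-q window subject to the
self-consistency condition `q_max·Rg ≤ 1.3`. Within the window, ln I is
regressed on q² *and q⁴* (weighted by `(I/σ)²`): the quartic term
absorbs the leading deviation from the Gaussian law, vanishes identically
for an exactly Gaussian curve, and removes the +1.7–2% Rg bias a plain
linear fit picks up on a sphere at `q·Rg ≈ 1.3`. The textbook linear fit
remains available (`correct_curvature = FALSE`).

*P(r).* The indirect Fourier transform solves
`min ‖(I − K·P)/σ‖² + α‖D²P‖²` subject to `P ≥ 0`,
`P(0) = P(Dmax) = 0`, with `K` the `sin(qr)/(qr)` kernel and `D²` the
second-difference operator, by Lawson–Hanson non-negative least squares
on the stacked system. α is dimensionless (the smoothness operator is
rescaled to the data term internally); 0.01 is a good default across the
fixtures. `estimate_dmax` scans candidate sizes and accepts the smallest
whose P(r) decays to ≤1% of peak at the last interior bin while the
back-fit χ stays within 5% of the scan minimum *and* below an absolute
bar of 1.5 — the absolute bar is what rejects featureless noise-only
input, for which the relative criteria are vacuous.

*Model scattering and fitting.* Model curves use the Debye formula with
unit form factors on Cα beads; there is no excluded-volume or hydration
shell term, so χ values are comparable in form, not in absolute value,
to full-atom solvent-corrected fits. χ uses the closed-form optimal
scale factor.

*C4 rigid-body modelling.* "P4 symmetry" is interpreted as point-group
C4 about z. One protomer pose — three z-y-z Euler angles plus a radial
offset ρ — generates the tetramer; azimuth and axial translation are
gauge freedoms of the scattering problem and are pinned to zero.
Simulated annealing (geometric cooling, proposals ≤5° per angle and
≤2 Å in ρ, mandatory seed, hence bit-for-bit reproducible) minimizes
`χ² + w·Σ max(0, d − 35)² + w_clash·overlaps` over the pose, with `d`
the homotypic inter-protomer distances of the restraint residues
(defaults 157, 173, 305). Restrained refinement then applies harmonic
wells `k(d − 30)²` (default k = 10 energy/Å²; the published constant is
unit-ambiguous, so k is exposed as configuration) plus the clash term,
by local Nelder–Mead, keeping the incoming pose unless strictly
improved.

## Native MS

Peaks of an intact-protein electrospray envelope obey
`m/z = (M + z·1.00728)/z`. For every adjacent peak pair the candidate
charge is `z = round((x₂ − m_p)/(x₁ − x₂))`; per-peak masses
`M = z(x − m_p)` are clustered (width 2×10⁻⁴ of the median estimate by
default) and consensus solutions are ranked by supporting-peak count,
then mass spread. Only peak lists are consumed — peak picking from
profile spectra and adduct modelling are out of scope. Intensities do
not enter the mass estimate, so solutions are invariant to uniform
intensity rescaling.

## Thermal-shift titrations

Melting temperatures are the maxima of the smoothed first derivative
dF/dT (quadratic Savitzky–Golay, default window 11 — a 5-point window
passes derivative noise spikes at realistic signal-to-noise — applied to
the trace and its derivative), filtered by both height and topographic
prominence at 5% of the maximum derivative and refined by parabolic
interpolation. When two transitions appear, the first is the canonical
Tm. The titration fit is the minimal single-site saturation model
`ΔTm(L) = ΔTm_max·L/(Kd + L)` by (optionally weighted) nonlinear least
squares; a thermodynamic ligand-linkage model is deliberately out of
scope. Fits whose Kd standard error exceeds the estimate are flagged
unreliable but returned. Fitting the raw replicate points is preferred
over fitting replicate means weighted by n = 3 sample SDs: over 200
simulations at the experimental design (0–400 µM, σ = 0.2 °C, 3
replicates) the median |error| is ~7.5% versus ~10.5%. The titration
range treats the published "0–400 mM" as a µM typo — the measured
affinities are tens of µM, at which 400 mM would be 4 orders of
magnitude past saturation.

## Sedimentation velocity

The forward model solves the Lamm equation
`∂c/∂t = (1/r)∂/∂r[rD∂c/∂r − sω²r²c]` in sector geometry by a
conservative finite-volume scheme with Scharfetter–Gummel exponential
flux weighting (accurate for cell Péclet numbers of order 1–10, where a
central scheme oscillates and plain upwinding adds diffusion comparable
to D itself) and Crank–Nicolson time stepping (Δt ≤ 20 s); no-flux
walls conserve the sector-weighted integral to machine precision. The
default cell: meniscus 6.0 cm, base 7.2 cm, 200 radial points, 30 scans
over 3 h at 50,000 rpm.

c(s) fitting projects the scan matrix onto unit-signal single-species
solutions on an s grid, with `D(s)` tied to s through a single
frictional ratio (default f/f₀ = 1.2, SEDFIT's convention; the study
does not state its value) via
`D(s) = √2/(18π)·kT·(η·f/f₀)^(−3/2)·((1 − v̄ρ)/(v̄s))^(1/2)`,
non-negative least squares with second-difference Tikhonov
regularization (dimensionless α, default 0.01). Peaks are local maxima
above 2% of the distribution maximum, parabolic-refined. s20,w
standardization applies the usual viscosity/buoyancy correction with
water-at-20 °C reference values (ρ = 0.99823 g/mL, η = 1.002 cP).

# The synthetic-data generators: what they emulate, what they do not

Every pipeline input has a seeded generator with recorded ground truth
(serialized as a key=value sidecar next to each written artifact; tests
compare against sidecars, never against re-derived values). All
randomness derives from one master seed through a documented affine
splitting scheme; identical seeds give byte-identical artifacts.

- **Two-domain dumbbell** (closure fixture): idealized helices (1.5 Å
  rise, 100°/residue, 2.3 Å radius), two 30-residue lobes on a common
  axis joined by a 5-residue linker with a small helical wiggle (a
  perfectly collinear strand would hand the network model spurious
  zero-energy modes) and 0.01 Å coordinate jitter. A 5-residue linker
  spans at most ~23 Å at 3.8 Å per bond, so the requested 25 Å lobe
  separation is capped at the chain-compatible 23.1 Å — inside the
  ±2 Å acceptance band of the stated scenario. This fixture tests
  closure mechanics; it does not mimic the real protein's fold.
- **Crosslink tables**: chemistry-valid residue pairs sampled to hit a
  requested satisfied fraction exactly, with a 1 Å margin from the
  bound; errors honestly when the geometry cannot supply enough
  violating pairs (e.g. compact models shorter than the bound).
- **HDX tables**: overlapping peptide tilings (mean length 10, overlap
  5, tunable), peptide values = truth means over the aggregated span,
  Gaussian noise per replicate. Real data's sequence-dependent intrinsic
  exchange rates and EX1 signatures are *not* emulated — a green test
  establishes correct aggregation arithmetic, not kinetics.
- **SAXS curves**: Debye scattering of the coordinates with a mixed
  error model σ = rel·I + 0.05·rel·max(I) (a purely relative σ gives
  high-q points unphysically extreme weights); no inter-particle
  structure factor, no solvent effects.
- **ESI envelopes**: exact charge-state peak positions, Gaussian m/z
  jitter and a Gaussian intensity profile over z; no adducts, no
  baseline.
- **Titrations / melt curves**: the single-site model plus Gaussian
  noise (σ = 0.2 °C on ΔTm at the published design; melt-curve noise
  0.005 of unit amplitude, a realistic DSF signal-to-noise).
- **SV scans**: the package's own Lamm solver plus Gaussian noise;
  time- and radially-invariant systematic offsets of real detectors are
  not modelled. c(s) recovery tests therefore validate the
  fit machinery against the forward model, not detector artifacts.

# Numerical choices and degenerate inputs

- Eigendecompositions are full symmetric `eigen()` calls — exact and
  affordable at N ≤ ~500 residues.
- The Lawson–Hanson NNLS falls back to a ridge-stabilized solve if an
  active-set subproblem is singular; callers regularize by row stacking.
- `fit_kd` on all-zero shifts reports the flat model with the
  `unreliable` flag instead of erroring; `rigid_body_fit` warns (not
  errors) on an annealing stall and returns the best-so-far;
  `track_closure` reports non-convergence as a state.
- Bound comparisons (crosslinks) are inclusive; Guinier windows need ≥5
  points; melt curves need ≥10 points and a genuinely rising region
  (relative derivative threshold 1e-10 guards against constant traces).
- Altlocs resolve to the highest-occupancy conformer; author/PDB residue
  numbering is never rewritten.

# Known limitations

- χ values from Cα-bead Debye scattering are not comparable in absolute
  value to solvent-corrected all-atom fits.
- The closure tracker's contact criterion and step size are heuristic
  knobs; the published procedure left both unstated.
- The c(s) implementation has no time-invariant/radial-invariant noise
  terms and no meniscus fitting; it is aimed at synthetic data.
- The deposited-structure superposition check (PsKD phosphomimetic vs
  wild type, RMSD ≈ 0.78 Å) requires downloading two PDB entries and is
  the one acceptance item that cannot run in an offline environment; the
  residue subset used for the published value is also unstated, so the
  default common-numbered Cα pairing may differ from the original
  selection.
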