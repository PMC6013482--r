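# tetraconf

Integrative analysis of a two-domain protein's monomer-to-tetramer
conformational switch, at desk scale and fully seeded.

MLKL — the pore-forming executioner of necroptosis — interconverts between
a closed monomer, in which the N-terminal four-helix bundle (4HB, residues
2–154) is restrained against the pseudokinase domain (PsKD, 190–471), and
an open conformer that assembles into a C4-symmetric tetramer. No single
measurement proves that switch; the case is built from orthogonal
biophysics. `tetraconf` implements each analysis stage as tested R code,
for structural biologists who want to rerun, stress or adapt the pipeline
without access to the original instrument data:

| stage | core method | entry points |
|---|---|---|
| structure I/O | PDB/mmCIF parsing, Kabsch superposition (SVD, det +1) | `read_structure`, `extract_calpha`, `kabsch_superpose` |
| domain closure | Cα anisotropic network model, eigenvector tracking of the lowest closure mode | `build_enm`, `normal_modes`, `track_closure` |
| crosslinking MS | Cα–Cα restraint mapping; DMTMM ≤ 30 Å, DSS/BS³ ≤ 35 Å | `parse_crosslinks`, `map_distances`, `satisfaction_score` |
| HDX-MS | per-residue aggregation of overlapping peptides, differential maps | `per_residue_profile`, `differential`, `write_residue_map` |
| SAXS | Guinier (q·Rg ≤ 1.3), regularized P(r)/Dmax, Debye scattering, C4 rigid-body fit + restrained refinement | `guinier_fit`, `pofr_transform`, `rigid_body_fit`, `refine_restrained` |
| native MS | charge-envelope deconvolution, m/z = (M + z·1.00728)/z | `simulate_envelope`, `deconvolve`, `species_report` |
| thermal shift | ΔTm(L) = ΔTm_max·L/(Kd + L) titration fitting | `extract_tm`, `fit_kd` |
| AUC | Lamm-equation forward model, regularized non-negative c(s), s20,w | `simulate_sv`, `fit_cs`, `standardize_s` |
| synthetic data | seeded generators with ground-truth sidecars for every input above | `make_*`, `scenario_tetramer_recovery` |
| pipeline | JSON config, subcommand CLI (`exec/tetraconf`) | `run_pipeline`, `pipeline_main` |

The methods vignette
(`vignettes/conformational-switch-methods.Rmd`) documents every model,
default and numerical choice, and what the synthetic generators do and do
not emulate.

## Worked example

Recover an oligomer mass from a simulated native-MS envelope, an ATP
affinity from a simulated thermal-shift titration, and the two
sedimenting species from a simulated velocity run:

```r
library(tetraconf)

## native MS: 9-peak envelope of a 216,190 Da tetramer, 0.3 Th m/z noise
env <- simulate_envelope(216190, 20:28, seed = 1, mz_noise_sd = 0.3)
deconvolve(env, 10:40)[[1]]
#> MassSolution: 216191.6 Da (z 20-28, 9 peaks, sd 5.70 Da)
```

The deconvolved mass lands 1.6 Da from the simulated truth; nine charge
states support it. `species_report(..., monomer_mass = 55350)` labels it
a tetramer (n = 4).

```r
## thermal shift: ATP titration generated at Kd = 36 uM, fitted back
tt <- make_titration(36, seed = 1)                 # 0-400 uM, 3 replicates
full <- attr(tt, "replicates")
fit_kd(full$conc, full$dTm)
#> KdFit: Kd 31.0 +/- 3.1, dTm_max 3.88 +/- 0.11 C
```

The fitted Kd of 31 ± 3 µM brackets the generating 36 µM within two
standard errors — representative of the σ = 0.2 °C, 3-replicate design.

```r
## AUC: two species at 3.5 S and 8.2 S, c(s) analysis on 0.5-15 S
species <- data.frame(s = c(3.5, 8.2),
                      D = diffusion_from_s(c(3.5, 8.2)),
                      signal = c(0.5, 0.5))
sv <- simulate_sv(species, sv_design(), noise_sd = 0.005, seed = 1)
fit_cs(sv, seq(0.5, 15, length.out = 100))
#> CsDistribution: 2 peaks (3.51, 8.20 S), total signal 1.002
```

Both sedimentation coefficients are recovered to within 0.01 S and the
loading signal is conserved.

## Command line

```sh
exec/tetraconf run config.json        # staged pipeline from a JSON config
exec/tetraconf saxs-guinier curve=curve.dat outdir=out
exec/tetraconf simulate scenario=tetramer-recovery outdir=out
```

Each stage writes its numeric results into `report.json` plus
stage-specific artifacts (trace tables, PDB models, distributions); a
resolved-config snapshot and the seed are stored for provenance. Unknown
configuration keys are rejected before anything runs.
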