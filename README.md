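# allodyn

Detecting direct and allosteric perturbation of protein internal dynamics
upon small-molecule binding, from paired apo/holo molecular-dynamics
trajectories and NMR data.

## The problem

A ligand can inhibit a protein without changing its structure: by clamping
its binding site and redistributing the protein's internal motions, it can
alter recognition at surfaces far from where it binds. Demonstrating such a
direct-plus-allosteric mechanism requires comparing the *dynamics* of the
apo and holo states residue by residue, across independent observables, and
asking where they agree. `allodyn` implements that comparison as a tested,
reusable pipeline for anyone analyzing a ligand-bound vs free protein pair —
the motivating system being an FGF2-class growth factor whose heparin-binding
site is engaged by a naphthalene-sulfonate inhibitor while its receptor-
binding surfaces change dynamics at a distance.

## What it computes

**From MD trajectories** (multi-model PDB, plain coordinate tables, or DCD;
one representative atom per residue, default Cα; no superposition needed —
every observable is built from internal distances):

- the distance-fluctuation matrix
  `DF(i,j) = ⟨(d_ij − ⟨d_ij⟩)²⟩` (population variance over frames, Å²),
  the holo − apo difference matrix, and algorithmic calls of
  quenched/enhanced residue segments;
- time-resolved geometric strain
  `s_i(t) = |N(i)|⁻¹ Σ_{j∈N(i)} (d_ij(t) − ⟨d_ij⟩)²` over a neighbor map
  fixed from the time-averaged structure (default 8 Å), its per-residue
  average profile, and apo/holo strain-hotspot calls.

**From NMR tables** (TSV peak lists and relaxation tables):

- combined chemical shift perturbation
  `Δδ = sqrt(ΔδH² + (α·ΔδN)²)` (α = 0.154) with separate ¹H/¹⁵N analysis
  and iterative mean + 3 SD significance;
- per-spectrum-normalized HSQC intensity changes with
  increased/decreased/appeared/disappeared classes;
- R2/R1ρ conformational-exchange flags (mean + 1 SD threshold, error-aware);
- ePHOGSY NOE/ROE hydration classification with the ±50 % change rule;
- Lipari–Szabo model-free analysis: the five standard models
  (M1: S²; M2: S², τe; M3: S², Rex; M4: S², τe, Rex; M5: Sf², Ss², τe)
  fitted per residue by weighted least squares from deterministic
  multi-starts, AIC or F-test selection, global τm from rigid-limit R2/R1
  inversion, and the S² summary with the mean − 2 SD flexibility threshold.

**Synthetic ground truth** for every stage: Gaussian-network trajectories
sampled from the pseudo-inverse of a spring-weighted contact Laplacian with
implanted binding-site stiffening and distal softening; relaxation datasets
forward-modelled from known per-residue (S², τe, Rex) under a global τm;
apo/holo peak tables with implanted shifts and intensity changes.

**A pipeline orchestrator** (`runPipeline()`, or the `allodyn run` CLI in
`inst/exec/`) that runs whichever stages have inputs and reports, per
residue, every stage's classification plus the cross-technique consensus
(residues flagged by ≥ 2 independent stages).

## Worked example

Generate a paired apo/holo trajectory with a stiffened 5-residue "binding
site" (ids 128–132) and a softened 4-residue distal region (ids 109–112),
then locate both from the data alone:

```r
library(allodyn)

specs <- demoGNMSpecs(seed = 3, nFrames = 2000)   # 131 residues, ids 25-155
apo  <- gnmTrajectory(specs$apo)
holo <- gnmTrajectory(specs$holo)

d <- differenceMatrix(distanceFluctuation(holo, c(25, 155)),
                      distanceFluctuation(apo,  c(25, 155)))
callPerturbedRegions(d, k = 1, minLen = 3)
#>   first last direction     score
#> 1   109  112  enhanced 0.6045123
#> 2   128  134  quenched 0.4914211
```

The stiffened site shows up as a quenched block (distance fluctuations lost
upon binding, in Å²), the softened distal region as an enhanced one. The
strain side of the analysis finds the same regions from single-residue
deformation:

```r
nmA <- neighborMap(apo,  8, c(25, 155)); nmH <- neighborMap(holo, 8, c(25, 155))
strainHotspots(averageStrainProfile(strainSeries(apo,  nmA, window = 50)),
               averageStrainProfile(strainSeries(holo, nmH, window = 50)))
#>     first last direction     score
#> 108   108  112  enhanced 0.5838814
#> 128   128  138  quenched 0.4475774
```

On the NMR side, a relaxation dataset forward-generated at τm = 8 ns with a
flexible tail and five exchange-bearing residues is analyzed back:

```r
ds  <- generateRelaxation(demoRelaxSpec(seed = 1))
fit <- fitDataset(ds, c(30, 153))
fit
#> ModelFreeFit: 124 residues, tm = 8.00 ns (isotropic diffusion)
#>   S2 = 0.80 +/- 0.15 over ids 30-153; flexibility threshold 0.51 (8 residues below)
ef <- exchangeFlags(ds, k = 1)
ef$residue[ef$flagged]
#> [1]  85  95 105 115 125
```

The recovered τm, S² means, flexibility threshold (mean − 2 SD) and the
exchange-flag set all match the generating truth. `runPipeline()` combines
all stages and returns the consensus residues — for the packaged synthetic
configuration these are exactly the implanted binding-site and distal
residues (plus the implanted CSP/intensity probes 129/144).

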