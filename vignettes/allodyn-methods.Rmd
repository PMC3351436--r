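---
title: "Methods: apo/holo dynamics perturbation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: apo/holo dynamics perturbation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`allodyn` asks one question of a protein–ligand pair: *where does binding
change the protein's internal dynamics?* It answers it twice, from
molecular-dynamics trajectories and from NMR observables, and reports the
residues on which the independent answers agree. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic ground truth does and does not establish.

## MD observables

### Distance-fluctuation matrix

For residues $i,j$ with representative-atom distance $d_{ij}(t)$,

$$\mathrm{DF}(i,j) \;=\; \big\langle\, (d_{ij} - \langle d_{ij}\rangle)^2 \,\big\rangle$$

with $\langle\cdot\rangle$ the mean over frames. Small values mean the pair
moves as a rigid unit; the holo $-$ apo difference matrix localizes pairs
whose coordination is quenched (negative) or enhanced (positive) by the
ligand.

Choices and assumptions:

* **Representative atom.** One point per residue, Cα by default
  (configurable). Whether a per-residue centroid would behave differently is
  untested here; Cα is the standard residue-level choice and the matrices
  are residue-level objects.
* **Population variance.** The $1/N$ ("mean squared fluctuation") form, not
  the $1/(N-1)$ sample variance. At trajectory scale the difference is
  negligible and it cancels in apo $-$ holo differences; the choice is
  stated so round-trip tests are exact.
* **Two-pass accumulation.** The mean distance is computed first, then
  squared deviations, keeping the matrix accurate to the $10^{-10}$
  relative tolerance the oracle tests demand.
* **No superposition.** Every observable is a function of internal distances
  only, hence exactly invariant under per-frame rigid-body motion (tested to
  $10^{-9}$ Å²). Trajectories must *not* be RMSD-fitted first — fitting is
  unnecessary and harmless, but never required.
* **Analysis window.** `range` is a required argument with no default. The
  caller must decide where disordered termini end (for the motivating
  FGF2-sized system: ids 25–155); silently analyzing a flailing tail would
  dominate every statistic.

### Region calling on the difference matrix

The underlying analysis reads perturbed regions off the matrix by eye; the
package makes the reading algorithmic with a two-level rule:

1. *Entry level.* An off-diagonal entry is significant when
   $|\Delta| > \text{mean} + k\,\mathrm{SD}$ of all off-diagonal
   $|\Delta|$.
2. *Residue level.* Each residue's score is the sum of its significant row
   entries divided by the row length; residues with
   $|\text{score}| > \text{mean} + k\,\mathrm{SD}$ of all scores are
   called.

The second level exists because a strongly perturbed *block* contaminates
the corresponding columns of every other residue's row: with a single
entry-level threshold, every residue ends up carrying a few significant
entries and the whole chain fuses into one call. Normalizing by row length
separates residues whose entire row moved (the perturbed block) from
residues that merely face the block in a few columns. A residue whose
significant entries are mixed in sign takes the sign of the sign-group with
the larger mean magnitude (documented tie-break). Contiguous same-direction
runs of at least `minLen` residues become calls.

Defaults $k = 1$, `minLen = 3`: one standard deviation matches the
visual-threshold convention of the exchange analysis below, and three
residues is the shortest segment the motivating analysis names. Both are
exposed; calls are monotone in $k$ (an all-zero matrix yields no calls, by
strict inequality).

### Geometric strain

$$s_i(t) \;=\; \frac{1}{|N(i)|} \sum_{j \in N(i)} \big(d_{ij}(t) - \langle d_{ij}\rangle\big)^2$$

* **Neighborhood** $N(i)$: residues within `cutoff` of $i$ in the
  *time-averaged* distance matrix, fixed for the whole trajectory, so strain
  measures deformation of one fixed local contact network rather than a
  changing one. Default 8 Å Cα–Cα, the standard residue-contact scale; the
  defining method leaves squared-vs-absolute differences, the cutoff, and
  normalization open, so the squared, cutoff-based, neighbor-normalized form
  is **this implementation's definition**, not an imported one.
* **Normalization** by $|N(i)|$ makes surface and core residues comparable;
  `normalized = FALSE` gives the raw sum.
* **Windows.** The series averages consecutive non-overlapping windows
  (default 50 frames) for time-resolved maps; the average profile uses all
  frames. Leftover frames beyond the last full window are dropped.
* **Isolated residues** (no neighbor at the cutoff) propagate as `NA`,
  never 0 — a zero would read as "perfectly rigid".

With a complete neighbor graph and window 1, the mean over residues of
time-averaged strain equals the mean over pairs of DF — both are averages of
the same squared deviations. This identity links the two engines and is
asserted to $10^{-10}$.

Hotspots are called on the per-residue profile difference
$\Delta s = s^{\text{holo}} - s^{\text{apo}}$ with the same
mean $+ k\,$SD / contiguity rule (one level: profiles have no column
contamination).

## NMR observables

### Chemical shift perturbation

$\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}$ with
$\alpha = 0.154$, the common ¹⁵N down-weighting; $\alpha$ is configurable
because published variants range from 0.10 to 0.25 and the motivating
analysis shows its formula only as an image. Separate ¹H and ¹⁵N deltas are
reported alongside. Significance: iterative exclusion above
mean $+ 3\,$SD, recomputed until stable — standard CSP practice that keeps
a handful of genuinely shifted residues from inflating their own threshold.
A fixed-cutoff mode is provided. The combined shift is invariant under a
uniform referencing offset applied to both spectra (tested), but no
referencing correction is attempted (out of scope).

### Intensity changes

Each spectrum is normalized by the mean (or median) of its own non-missing
intensities, backbone and side-chain peaks within their own groups —
normalization schemes differ between labs, and the per-spectrum mean makes
the classification exactly invariant under a global rescale of either
spectrum (tested). Ratio thresholds 1.5 / 0.67 define
increased/decreased. Peaks present in one spectrum only are a *distinct*
class (`appeared`/`disappeared`), never ratio 0 or $\infty$: an
exchange-broadened peak that reappears on binding is a strong, qualitatively
different signal.

### Conformational exchange

$R_2$ carries the µs–ms exchange term $R_{ex}$; the rotating-frame rate
$R_{1\rho}$ does not, so $R_2/R_{1\rho}$ ratios above one flag exchange.
Threshold: mean $+ k\,$SD over the dataset with $k = 1$ (the convention the
motivating figures plot as a line), **and** the ratio must clear the
threshold by more than its own uncertainty, propagated in quadrature from
the input errors. The error clause exists because at realistic 2 % rate
noise a bare threshold produces one marginal false positive in roughly one
dataset in seven, each within its own error bar — exactly the ratios the
field annotates as "affected by significant errors" and sets aside.

### Hydration (ePHOGSY NOE/ROE)

Water-selective NOE and ROE intensities are normalized per spectrum and
binned into high/medium/low by two thresholds; the thresholds are
**implementation defaults (apo-NOE tertiles)** because the source analysis
draws them as unlabelled lines. Changes beyond ±50 % of the apo value are
flagged. Residues with an ROE correlation are retained but excluded from
water-proximity claims: their water peak may be chemical exchange, not a
resident water molecule.

### Lipari–Szabo model-free analysis

Spectral density (simple form; extended form adds $S_f^2$):

$$J(\omega) = \tfrac{2}{5}\left[\frac{S^2\tau_m}{1+(\omega\tau_m)^2}
 + \frac{(S_f^2 - S^2)\,\tau'}{1+(\omega\tau')^2}\right],
 \qquad \tau'^{-1} = \tau_m^{-1} + \tau_e^{-1}$$

$R_1$, $R_2$, NOE are the standard dipolar + CSA combinations of $J$ at
$\{0, \omega_N, \omega_H\pm\omega_N, \omega_H\}$, with $R_{ex}$ additive in
$R_2$ only. Constants $r_{NH} = 1.02$ Å and $\Delta\sigma = -172$ ppm follow
the conventions of the classic fitting programs and are configurable — the
motivating study does not state its values, which is one reason its absolute
$S^2$ values are not reproduction targets (only its printed summary
arithmetic is: mean $0.79$, SD $0.13$, threshold $0.79 - 2\times0.13 =
0.53$).

Fitting choices:

* **Five models** M1 ($S^2$), M2 ($S^2,\tau_e$), M3 ($S^2,R_{ex}$),
  M4 ($S^2,\tau_e,R_{ex}$), M5 ($S_f^2,S_s^2,\tau_e$; $S^2 = S_f^2 S_s^2$),
  each by bounded weighted least squares over three observables.
* **Deterministic multi-start.** A fixed grid
  ($S^2 \in \{0.3,\dots,0.95\}$, $\tau_e \in \{0,20,100,500\}$ ps,
  $R_{ex} \in \{0,2,5\}$ s⁻¹) seeds L-BFGS-B; richer models are additionally
  warm-started from the best nested solution, which *guarantees* the nesting
  property $\chi^2(M4) \le \chi^2(M2) \le \chi^2(M1)$, $\chi^2(M4) \le
  \chi^2(M3)$ (tested on 20 noisy records). No randomness anywhere: fits are
  bitwise reproducible.
* **Convergence.** L-BFGS-B occasionally reports a line-search failure at a
  point that is already optimal (flat finite-difference gradient); a fit is
  accepted when a restart from the returned point cannot improve it.
  Residues whose best model still fails are flagged unfit and excluded from
  summaries.
* **Selection.** AIC ($\chi^2 + 2p$) by default — deterministic and
  well-defined with zero residual degrees of freedom, which the 3-parameter
  models have against three observables. The classic nested F-test protocol
  is available (`criterion = "ftest"`); with zero degrees of freedom it
  falls back to a goodness-of-fit test on the simpler model.
* **Global τm** from the trimmed mean (10 %) of $R_2/R_1$ over residues with
  NOE ≥ 0.65, inverted through the rigid isotropic relation by 1-D root
  finding. With $\tau_e = 0$ the rigid ratio is independent of $S^2$, so
  noise-free data are recovered exactly; the NOE cutoff excludes flexible
  residues and the trim discards exchange-inflated ratios.
* **Diffusion.** Isotropic is the tested default. An axially symmetric
  tensor (three-Lorentzian $J$ weighted by the N–H angle) is implemented and
  reduces exactly to isotropic at $D_\parallel/D_\perp = 1$ (tested); full
  tensor optimization from structure is out of scope.
* **Error floors** 2 %/2 %/3 % for $R_1/R_2/$NOE when uncertainties are
  absent, with an absolute floor of 0.02 on the NOE error.

## Synthetic ground truth

The generator exists to give every analysis a fixture with *known* answers.

* **Trajectories: Gaussian network.** Residues sit on a compact
  self-avoiding lattice chain (3.8 Å virtual bonds, 0.3 Å jitter, seeded and
  platform-independent); contacts within 7.5 Å become unit springs; frames
  are *independent* draws with per-axis covariance
  $a\,L^+$ ($L$ the spring-weighted Laplacian, $a$ an amplitude giving
  ~0.8 Å RMSF). The sampled covariance converges to the analytic target
  (tested at 5000 frames, <10 % Frobenius error), so fluctuation analyses
  have exact ground truth. The default perturbation pair — a 5-residue
  "binding site" (ids 128–132) with all incident springs ×5, a 4-residue
  distal region (ids 109–112) with incident springs ×0.2 — was fixed once as
  the study condition: five-fold stiffening is the stated perturbation
  scale, 0.2 is its symmetric counterpart, and the ids echo the motivating
  system's binding loop and distal turn so region reports read naturally.
  What the GNM does **not** emulate: anharmonicity, frame-to-frame
  correlation, solvent, side chains, actual binding chemistry. Passing the
  recovery tests therefore shows the *estimators and callers* work at
  realistic signal-to-noise; it does not validate any force field.
* **Relaxation.** Rates are forward-modelled from per-residue
  $(S^2, \tau_e, R_{ex})$ under a global $\tau_m$ with the package's own
  rate equations (themselves pinned to an independently coded reference to
  $10^{-9}$), plus fractional Gaussian noise; $R_{1\rho}$ is $R_2$ minus the
  exchange term, which is precisely what makes $R_2/R_{1\rho}$ an exchange
  probe. The demo dataset (124 residues, ids 30–153, $\tau_m = 8$ ns at
  500 MHz) carries a flexible tail ($S^2 = 0.30$), a rigid core
  ($S^2 = 0.80$–$0.85$), and five exchange residues at 3–5 s⁻¹ — the
  magnitudes typical of measured conformational exchange.
* **Peak tables.** Baselines are drawn once, the holo table adds implanted
  shifts/intensity ratios, and independent measurement noise is added to
  both spectra. The demo implants the motivating pattern: large shifts at
  residues 129/144 and exchange-suppressed apo intensities (×0.2) at
  129/144/145 recovering to baseline upon binding.

All generators are pure functions of their spec, seed included.

## Pipeline and consensus

`runPipeline()` runs whichever stages have inputs, classifies each residue
per stage (CSP flag; intensity class; exchange changed between states;
$|\Delta S^2| > 0.1$, a change large relative to typical fit uncertainty;
membership in a DF region or strain hotspot; hydration change) and reports
the consensus: residues flagged by at least 2 independent stages. The ≥2
rule operationalizes the cross-technique argument — a perturbation believed
when two unrelated measurements see it — and is configurable. Reports
contain input hashes, parameters and package version but no timestamps, so
identical inputs give byte-identical files (tested). The CLI wrapper exits
0 on success, 2 on configuration errors, 3 on stage failures.

## Problem sizes and limitations

The packaged test and acceptance runs use 131-residue, 2000-frame GNM pairs
(20 seeds) for region recovery, 124-residue relaxation datasets (20 seeds)
for model-free bias, and 400-frame pairs for the end-to-end determinism
check — sizes at which all statistics are comfortably converged while the
full suite completes in a few minutes.

Known limitations: XTC input is not supported (PDB/table/DCD are); no
Cartesian-covariance/PCA or network-community analysis of coordination; no
peak picking, assignment or titration $K_d$ fitting; no full anisotropic
diffusion-tensor optimization; Monte-Carlo model-free errors are replaced by
covariance-based uncertainties; the hydration class thresholds are
implementation defaults, not field constants. The region callers' exactness
has been demonstrated on GNM fixtures; on real trajectories with slow,
correlated modes the effective number of independent frames is smaller and
thresholds should be read accordingly.
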