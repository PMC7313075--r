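---
title: "Correlated segmental dynamics from PRE and PRI NMR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated segmental dynamics from PRE and PRI NMR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prePRI)
```

## Scope

`prePRI` implements the full analysis chain for probing correlated
conformational dynamics of an intrinsically disordered protein (IDP) by
paramagnetic relaxation enhancement (PRE) and paramagnetic relaxation
interference (PRI):

1. peak-intensity decay series to relaxation rates (R1, R2, amide-proton
   R2, heteronuclear NOE) with Monte-Carlo uncertainties;
2. reduced spectral density mapping;
3. PRE rates (Γ2) from paramagnetic/diamagnetic pairs and PRI rates
   (ΔΓ2) from dual-labelled samples;
4. inter-residue correlation maps across spin-label datasets, detection
   of locally correlated segments, wild-type vs mutant comparison;
5. secondary chemical-shift (Δδ) β-propensity profiles.

Because raw spectrometer data for such a study are not reproducible at a
desk, the package ships a first-class synthetic data generator: a
coarse-grained, spin-labelled conformational ensemble of a 100-residue
tau fragment (residues 225–324) with planted segmental correlated
motions and a sparsely populated compact state.  All validation runs
end-to-end against this generator.

## The measurement models

### Exponential decay fitting

Peak intensities follow $I(t) = I_0 e^{-Rt}$ with both parameters free
and no baseline term.  $I_0$ is profiled out analytically
($\hat I_0(R) = \sum I_i e^{-Rt_i} / \sum e^{-2Rt_i}$), leaving a 1-D
least-squares problem solved by a bracketing grid plus Brent refinement;
Monte-Carlo replicas (default `nMc = 500`, the count is the package's
choice) perturb every intensity by the spectral noise RMSD and are
refitted by a vectorised golden-section search.  Duplicated delays enter
as independent observations.  Residues whose intensities are all
non-positive, or whose fitted rate runs into the search bound (signals
broadened beyond observability, e.g. amides within a few residues of a
nitroxide), are masked.  The fit is exactly scale invariant.

### Heteronuclear NOE and R2/R1

hNOE is the ratio of saturated to reference intensities, with
first-order error propagation from the noise RMSD on both intensities
and a reliability mask at $|I_{ref}| < 3\,\mathrm{RMSD}$ (the handling
of weak peaks is the package's choice).  R2/R1 ratios carry a flag for
residues above the profile mean, the usual indicator of additional
ms-timescale exchange broadening.

### Reduced spectral density mapping

The three-point mapping inverts (R1, R2, NOE) into
$J_{\mathrm{eff}}(0)$, $J(\omega_N)$ and $J(0.87\,\omega_H)$ using the
dipolar constant from $r_{NH} = 1.02$ Å and a $^{15}$N CSA of
$-172$ ppm (community defaults; configurable).  The forward and inverse
forms are exact linear inverses of each other, which the tests verify to
$10^{-10}$; a full five-frequency Lorentzian forward model is provided
as an independent oracle, and the 0.87 ωH approximation reproduces
$J(0) = (2/5)\tau_c$ for a 4 ns Lorentzian within 10%.  Exchange
contributions inflate only $J_{\mathrm{eff}}(0)$; negative values are
flagged, never clipped.

### PRE and PRI

The PRE forward model is the Solomon–Bloembergen transverse form
$$\Gamma_2 = K\,\langle r^{-6}\rangle\left(4\tau_c +
\frac{3\tau_c}{1+\omega_H^2\tau_c^2}\right),$$
with $K = 1.23\times10^{-32}\ \mathrm{cm^6\,s^{-2}}$ and a configurable
$\tau_c$ (default 4 ns), which puts back-calculated rates in the
tens-of-s$^{-1}$ regime of MTSL-labelled IDPs.  Measured Γ2 is the
paramagnetic minus diamagnetic amide-proton R2, uncertainties in
quadrature, negative values retained and flagged.

PRI is the interference between the two electron–proton dipolar
couplings of a dual-labelled sample,
$$\Delta\Gamma_2 = \Gamma_2[X_1{+}X_2] - \Gamma_2[X_1] - \Gamma_2[X_2],$$
back-calculated as
$K'\langle(3\cos^2\theta - 1)\,r_A^{-3} r_B^{-3}\rangle$ over conformers
whose labels lie within 50 Å.  Only the sign structure (positive for
$\theta \to 0/180^\circ$, negative near $90^\circ$, zero at the magic
angle 54.7°) and the proximity cutoff are treated as normative; the
prefactor is a configurable scale (default $10K$), chosen once so the
forward-model PRI rates of the default compact state land in the
±tens-of-s$^{-1}$ regime.

### Correlation maps and segments

With rates $R_{ik}$ for residue $i$ in dataset $k = 1..N$,
$$\mathrm{cov}_{ij} = \frac1N \sum_k (R_{ik}-R_{i0})(R_{jk}-R_{j0}),
\qquad \mathrm{corr}_{ij} = \mathrm{cov}_{ij}/(\sigma_i\sigma_j)$$
with population (1/N) normalisation.  Residues missing from some
datasets are handled pairwise-complete; pairs sharing fewer than two
datasets, and zero-variance residues, are masked.  The observability
threshold for entering the matrix is configurable: the strict choice
keeps residues observable in every dataset, the map convention keeps
those observable in at least two (the pipeline default).

Segments are maximal runs of consecutive residues whose mean pairwise
correlation stays at or above 0.5 with at least 4 observed residues.  A
candidate residue joins a run when its mean correlation to the run
members reaches the threshold and it is not anti-correlated with any of
them — a deliberately sharper boundary criterion than testing the
diluted whole-run mean, which systematically absorbs the neighbouring
segment's edge.  Unobservable positions (prolines, label sites) are
bridged up to 2 consecutive residues: the tau proline-rich region
contains adjacent prolines (232/233) that a single-residue bridge would
turn into artificial segment boundaries.

Map comparisons report the element-wise difference on commonly valid
pairs and per-segment-pair block means with sign-flip flags (both means
at magnitude ≥ 0.2 and opposite sign).

### Secondary chemical shifts

$\Delta\delta = \delta_{obs} - \delta_{rc}$ against a packaged
Wishart-style random-coil table (the reference set is configurable and
shipped as plain text; no sequence-context corrections by default).
The combined index is $\Delta\delta_{av} = [3\Delta\delta C_\alpha +
4\Delta\delta C']/7$.  β-strand propensity is a run of ≥ `minRunBeta`
residues with both $\Delta\delta_{av} < 0$ and
$\Delta\delta C_\alpha < 0$ (default 4, "more than three"; the run
length is per-call configurable because a meaningful 3-residue region
exists in this system), turn propensity a run of ≥ 3 residues with
$\Delta\delta_{av} > 0$.

## The synthetic ensemble generator

The generator is the package's stand-in for all experimental inputs and
defines the study conditions: a 100-residue chain (residues 225–324,
real tau sequence, so prolines carry no amide), eight semi-rigid
segments C1–C8, single-label sites 262/291/305/322 and dual pairs
(262, 305) and (291, 322), 5% compact population, a 3.8 Å virtual
Cα–Cα bond (exact in every conformer) and an 8 Å nitroxide pseudo-atom
offset.

**Major state.**  Segments are rigid rods; linker beads get Gaussian
bends/torsions (0.35 rad); each hinge draws one signed bend by mapping
correlated latent normals (the hinge-coupling matrix) through a probit
onto $(-\mathrm{bendMax}, \mathrm{bendMax})$.  Hinge torsions stay at
the linker scale, i.e. hinges bend in a preferred plane — without this
the coupling could never reach a geometric observable.

**Compact state.**  Transient compaction is a library of docking-fold
templates, one per segment: fold $s$ places segment $s$ against an
assigned label site while keeping every other segment–label contact
weak.  Assignments make the fingerprint sets of sequence-adjacent
segments disjoint; the fold geometries are found by a deterministic
random search plus hill climbing (seeded once, cached).  Gap "openings"
(probability 0.15 per gap, correlated through the same hinge-coupling
latent) release the docking turns, so which segments engage together is
governed by the coupling; off-path linkers stay floppy even when
docked.  Within a docked rod the $r^{-6}$ contact contribution is
registry-averaged — a transient docking contact has no preferred
register along a semi-rigid segment, so all its residues share the
segment's contact statistics.  This registry averaging is the geometric
embodiment of concerted segmental motion and is what makes the planted
architecture recoverable from ensemble-mean rates at all: without it,
ensemble-mean PRE profiles of a chain are spatially smooth (sequence
neighbours are always spatial neighbours) and cannot carry sharp
segment boundaries.

The P301L variant differs in three documented ways: residue 301 becomes
observable (L for P), the sign of the C-terminal hinge loading flips
(the C7/C8 arm moves against the N-terminal segment), and the docking
turn at the PGGG-motif gap is relaxed, swinging the PHF6-bearing arm
into a different docking geometry.

**Calibrations to printed regimes.**  Two generator constants were set
once against the study's printed values: the PRI prefactor (ten times
the PRE prefactor) puts forward-model ΔΓ2 in the ±tens-of-s$^{-1}$
range, and the 15N motional truth uses a 0.7 ns baseline correlation
time so the mean hNOE is ≈ 0.25 at 700.3 MHz, with slightly longer τ
over the more
ordered β3/β5-corresponding regions, shorter over the amyloid motifs,
and a 2 s$^{-1}$ exchange term at the 292–294 hinge.

**Problem sizes.**  Default runs draw 2000 conformers (pipeline) or
8000 (recovery studies); tests use 40–6000 depending on the property.
These sizes are the package's accuracy/runtime compromise: the
compact-state bumps average over `0.05 × nConformers / 8` conformers
per fold, so recovery statistics stabilise from a few thousand
conformers upwards.

## What passing tests do and do not show

The generator emulates: exponential decays with Gaussian spectral
noise and duplicate delays; observability loss near labels; segmental
co-variation of PRE across label datasets; interference confined to a
compact minor state; secondary-shift sign runs.  It does not emulate:
peak overlap and assignment errors, field inhomogeneity, label rotamer
distributions beyond a fixed offset, chemical exchange outside one
planted hinge, or real tau's full conformational statistics.  Passing
tests therefore validate the analysis chain and the planted-recovery
behaviour of the model, not the biology of tau.

### Known limitations

* With four label datasets, the inter-residue correlations are
  estimated from four numbers per residue; the maps are intrinsically
  noisy, exactly as in the underlying experiment.
* Planted-architecture recovery has a measured ceiling: at the frozen
  defaults the detector returns 7–8 segments with typically 5–7 of 8
  boundaries exact to ±1 (exact recovery at some seeds).  The
  two-segment architecture is read out by only two labels, whose
  two-point Pearson map is ±1-degenerate, so its boundaries are loose
  even though the segment count is usually correct.
* Hinge-coupling causality reaches the map as a graded change of
  inter-segment correlation (≈ −0.6 under anti-coupling vs ≈ −0.3
  under positive coupling for the three-rod probe); block means do not
  cross zero because each rod's own-label signal dominates, so the
  sign-flip flag of `compareMaps` responds to fold-geometry
  perturbations (as in the P301L model) rather than to pure coupling
  flips.
* The chain is a phantom (no excluded volume); a contact floor of 5 Å
  stands in for the hard core, and label-proximal unobservability
  emerges from the fit bound rather than an explicit cutoff.

## Numerical choices

* Rate search interval $[-50, 2000]$ s$^{-1}$; fits at ≥ 98% of the
  upper bound are masked as broadened out.
* Correlations are clamped to $[-1, 1]$ against rounding; the diagonal
  is set exactly to 1 where defined.
* The hinge-coupling matrix must be symmetric positive semi-definite
  with unit diagonal; the default is a one-factor model, which
  guarantees this by construction.
* Stage seeds derive from the root seed by a fixed affine map modulo
  $2^{31} - 19$, so every artifact is reproducible from one integer.

## Reproducing the study figures' logic

`runPipeline()` executes the whole chain for wild-type and P301L
variants and writes plain-text artifacts (rate tables, spectral
densities, correlation matrices as CSV, segment tables, difference
tables, a summary JSON).  `scripts/acceptance.R` recomputes the
headline numbers from scratch for a given seed.
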