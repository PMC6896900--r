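---
title: "Trajectory analysis of partially disassembled nucleosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory analysis of partially disassembled nucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucdyn)
```

## The system and the analyses

A nucleosome is ~147 bp of DNA wrapped in ~1.65 left-handed superhelical
turns around a histone octamer (two H2A/H2B and two H3/H4 dimers). During
chromatin remodeling, nucleosomes transiently lose a dimer: removing an
H2A/H2B dimer yields the experimentally observed hexasome, and H3/H4-deleted
models are a useful hypothetical comparison. `nucdyn` post-processes
molecular-dynamics trajectories of such complexes — the canonical particle
plus the four single-dimer-deletion variants ΔH3/H4, ΔH2A/H2B, ΔH3'/H4',
ΔH2A'/H2B' (chains A–H in the 1KX5 convention; DNA strands I and J numbered
−73..73 around the dyad) — and quantifies how DNA and histone dynamics change
when a dimer is missing.

The pipeline computes, per variant:

1. **Superposition** under two conventions. Frames are rigid-body fitted
   (unweighted Kabsch/orthogonal Procrustes, proper rotations enforced) to a
   reference using (i) all heavy atoms except the disordered histone tails,
   or (ii) histone-core heavy atoms only. Convention (ii) deliberately
   leaves DNA deformation in the aligned coordinates, so DNA descriptors
   measure internal deformation rather than whole-particle tumbling.
2. **RMSD time series**, `rmsd(t) = sqrt(mean_i |x_i(t) − x_i(0)|²)` over a
   group mask (per histone chain, or all DNA), per trial, against the first
   saved frame.
3. **RMSF per nucleotide**, `rmsf_i = sqrt(<|x_i − <x_i>|²>)` of the C1'
   atom after convention-(ii) alignment, pooled over the analysis window of
   all trials (a per-trial profile is available behind a flag; with equal
   frame counts the pooled ratio and the mean of per-trial ratios coincide).
4. **Essential dynamics**: PCA of the 3N-dimensional stacked C1' coordinate
   vector over the pooled window; projections
   `S(τ, j) = (X(τ) − <X>) · v_j` for every frame; a Gaussian-kernel density
   landscape over (S₁, S₂) with the initial conformation marked.
5. **Contact frequency**: a nucleotide and an amino acid are in contact in a
   frame when their C1'–Cα distance is *strictly less than* 10 Å; the
   frequency is the fraction of pooled window frames in contact. Raw
   (unaligned) coordinates are used — distances are rigid-invariant.
6. **α-helix occupancy** per histone residue, from backbone hydrogen bonds
   scored with the classical Kabsch–Sander dipole–dipole energy
   `E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol, bond when
   `E < −0.5`; a residue is helical when it lies in a run of overlapping
   minimal helices (two consecutive i→i+4 turns). Only the α class is
   assigned; 3₁₀/π helices and strands are out of scope.

## Conventions and parameters that matter

* **Core/tail region table** (residues, file numbering): H3 core 45–135,
  tail 1–44; H4 core 25–102, tail 1–24; H2A core 18–98, tails 1–17 and
  99–128; H2B core 35–122, tail 1–34; primed copies identical. Tails are
  excluded from every alignment and from RMSD/RMSF/PCA masks, but retained
  in contact analysis — tail–DNA contacts are a finding, not noise.
* **Analysis window**: frames with time strictly greater than half the trial
  length. The first saved frame is at `t = sampling_interval` (default
  10 ps), so for a 100 ns trial the window is exactly the last 5,000 of
  10,000 frames (50.01–100 ns).
* **Contact cutoff**: 10 Å, strict inequality; a pair at exactly 10 Å is
  not a contact. Enlarging the cutoff can only increase frequencies.
* **KDE bandwidth**: Scott's rule per axis (`sd · n^(−1/6)`), recorded in
  the landscape object; the grid covers the samples with a ≥3-bandwidth
  margin and the density integrates to 1 over the grid to within 2%.
  The landscape is reported as a probability density, with −ln(density)
  attached for free-energy-style plots (no kT scaling).
* **Residue numbering** is never rewritten: deletion variants keep the
  canonical numbering, and DNA keeps the −73..73 dyad-centered convention.
  All 147 bp × 2 strands enter the DNA masks (no terminal-nucleotide
  exclusion), and the two strands are kept separate in contact matrices.
* **Hydrogens** in input files are retained in the topology but excluded
  from every analysis mask; amide hydrogens for hydrogen-bond scoring are
  always reconstructed from backbone geometry (N–H of 1.0 Å along the
  bisector opposite C(i−1) and Cα), which makes the assignment independent
  of force-field hydrogen placement and usable on H-free structures.

## Numerical choices

* The Procrustes reflection case (det = −1) is resolved by sign-flipping the
  smallest singular vector; degenerate inputs (<3 atoms, collinear sets)
  raise errors rather than returning an improper fit.
* Eigenvector signs are fixed so the largest-magnitude component is
  positive; within numerically degenerate eigenvalues the ordering is by
  eigenvalue then first differing component, and is documented as arbitrary.
* The covariance uses `1/n` normalization (population form), so the
  eigenvalue sum equals the total positional variance of the pooled frames.
* The spatial-partition contact engine (cubic cells of edge = cutoff, 27
  neighbor cells) evaluates the same squared-distance expression as the
  all-pairs loop on the candidate pairs, so the two engines return identical
  matrices, not merely close ones.
* No periodic-boundary unwrapping is performed; the package assumes each
  frame contains a whole complex and documents this as a pre-processing
  requirement, since imaging conventions differ between MD engines.

## The synthetic-trajectory generator

Real all-atom runs of these systems (10 trials × 100 ns per variant) are far
beyond a test suite, so the package ships a deterministic coarse-grained
emulator with one bead per residue (C1' for nucleotides, Cα for amino
acids) that produces the statistical structure the analyses assume:

* DNA beads on a left-handed superhelix (radius 41.9 Å, pitch 25.9 Å,
  1.65 turns — literature constants for the canonical particle, configurable,
  and not claims of this package); strand J is paired antiparallel with
  strand I (residue j of J sits by residue −j of I). Histone chains are
  compact bead clusters at their dimer positions with explicit tail beads;
  bead counts follow the region table (e.g. H2A has 128 beads).
* **Breathing**: a sinusoidal displacement of the DNA arm adjacent to the
  deleted dimer along the outward superhelix normal. With the default
  `"bead"` normalization each arm bead has peak amplitude `amplitude` (Å);
  with `"collective"` normalization the stacked 3N mode vector is unit-norm
  and `amplitude` is the peak collective displacement, which gives the
  closed forms `λ₁ = A²/2 + σ²` and mode direction `u` used by the PCA
  tests. Defaults: 10 bp per strand (20 beads), 6 Å per bead, period 100
  frames.
* **Drift** (H2A/H2B deletions only): the freed arm's center ramps outward
  by `drift` Å per bead over the first half of each trial, so the latter
  half fluctuates about a displaced center. This reproduces the landscape
  signature of hexasome-like runs — the initial conformation sits in a
  low-density region — while H3/H4-deleted runs stay centered on it.
* **Tail invasion** (H3/H4 deletions, on by default): the C-terminal tail
  of the H2A adjacent to the vacated site interpolates into the patch and
  parks within 6 Å of the patch C1' beads, and the arm amplitude is damped
  (×0.25). This reproduces both the enhanced H2A C-tail contact frequency
  and the mitigated DNA fluctuation of those models.
* Isotropic Gaussian noise (σ = 0.5 Å per coordinate) on every bead, an
  optional slow rigid wobble to exercise the alignment, and per-(seed,
  trial) RNG seeding for bitwise reproducibility.

What the generator does **not** emulate: all-atom packing, force-field
energetics, solvent, sequence effects, anharmonic or Langevin dynamics
(breathing is sinusoidal so mode shapes and variances have closed forms —
testability over realism), and backbone geometry for the bead chains. A
separate ideal-geometry peptide builder (`build_peptide`, standard bond
lengths/angles from φ/ψ dihedrals) provides all-atom backbones for the
hydrogen-bond and helix tests. Passing tests therefore demonstrate that the
analysis operators are correct on data with known structure, not that any
biological conclusion transfers to real trajectories.

Default problem sizes in the shipped tests are scaled to desk hardware
(hundreds to a few thousand frames, 1–3 trials); the generator's structural
and noise defaults are held fixed across all tests, and the qualitative
variant signatures are asserted at those sizes.

## Design points that were genuinely open

* *Reference frame for alignment*: each trial's first saved frame (the
  post-minimization structure), because the RMSD series is defined against
  `x(0)`; time-mean structures are used only inside RMSF/PCA after
  alignment.
* *DNA RMSD convention*: both conventions are supported; the report bundle
  carries the per-chain series under convention (i) and a DNA series under
  convention (ii), since whole-complex fits absorb part of the DNA
  deformation.
* *Published hexasome comparison*: `structure_rmsd` exposes independent fit
  and measure masks, so any atom-subset interpretation of a published
  crystal-structure comparison can be tried; the corresponding check needs
  the two full deposited structures and stays inactive without them.
* *Config format*: plain-text YAML key–value with compiled-in defaults equal
  to the analysis conventions above; the region table round-trips through
  TSV bit-exactly (apostrophes in primed role names are handled by disabling
  quote interpretation).

## Known limitations

* Atom correspondence between two structures is positional; there is no
  sequence alignment.
* The DCD reader follows the common fixed-header single-precision dialect
  via `bio3d::read.dcd`; exotic dialects should be converted to the
  documented plain-text frame format.
* Contact analysis is residue-representative (C1'/Cα) by construction;
  atom-level hydrogen bonds or salt bridges between DNA and histones are
  out of scope.
* The emulator's histone clusters are not meant to have realistic internal
  dynamics; histone-side descriptors (helix occupancy) are exercised on the
  peptide fixtures instead.
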