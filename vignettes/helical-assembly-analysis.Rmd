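---
title: "Methods: helical CARD assembly analysis with helicard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: helical CARD assembly analysis with helicard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helicard)
```

# The system

CARD9/CARD11-family adaptors are autoinhibited dimers: the N-terminal CARD
packs against a linker and the first coiled-coil segment, and activation
(point mutations in the interface, or ubiquitination of a coiled-coil lysine)
displaces the CARD. Freed CARDs assemble into a helical filament with the
canonical death-domain architecture, and that filament is the template that
nucleates Bcl10 polymerization. Three distinct structural/biophysical
measurements bear on this model, and the package implements the quantitative
side of each:

1. **geometry of the filament lattice** (rise/twist, interface typing,
   contact shells) and of the autoinhibited dimer ensemble (RMSD statistics,
   backbone dihedrals, sub-domain contacts, buried surface area);
2. **solution-state perturbation mapping** (NMR line broadening and chemical
   shift perturbation; HDX protection factors) that localizes which surfaces
   are engaged or released;
3. **assembly kinetics** (nucleation-limited polymerization,
   unidirectional growth, capping by interface-dead monomers, seeding).

# Geometry conventions

All rigid transforms use the row-vector convention `y = x R + t`. A screw
decomposition reports `twist` (degrees, in (−180, 180]) and `rise` (Å) about
a unit axis; the axis sign is fixed by requiring `rise ≥ 0` (for a pure
rotation, the largest-magnitude axis component is made positive). A
left-handed helix therefore has negative twist about its growth axis, and a
filament built at `twist = −101.6°` prints as "101.6 deg (left-handed)".
Rotation angles below 1e−7 rad are treated as pure translations: the screw
axis of an exact identity is undefined and raises an error rather than
returning noise.

Filaments are always built about +z with subunit 0 at the −z end, so the +z
tip is the growing, "b"-face-exposed end; this orientation is what the
capping assay semantics refer to. `fit_helical_params()` averages the screw
decompositions of consecutive-pair superpositions rather than performing a
global optimization: for an ideal lattice the per-pair spread is zero, and
for a real (noisy) filament the spread is itself a useful regularity
diagnostic, which is why it is reported alongside the means.

Ensemble spread is reported in two conventions because deposited statistics
rarely state which was used: `to_mean` (iterative superposition onto the mean
structure, convergence when the mean moves < 1e−6 Å, at most 100 iterations —
far below coordinate precision) and `mean_pairwise` (average over all
pairwise superpositions). `to_mean` is the default, matching common
NMR-ensemble reporting, and is never larger than `mean_pairwise` for the
same selection.

Backbone dihedrals follow the IUPAC sign convention (cross-checked against
bio3d in the test suite). Residues missing backbone atoms, or adjacent to a
numbering gap, get `NA` angles rather than an error, since deposited files
routinely have disordered termini.

# Interface analysis

Contacts are residue pairs whose minimum heavy-atom distance is at or below
a cutoff. Two cutoffs matter and they are deliberately different:

* **2.5 Å** (default for dimer sub-domain analysis) — the strict
  contact criterion used to define which CARD/linker/coiled-coil residues
  engage each other within a dimer ensemble, evaluated with an "any model"
  rule: a pair counts if it touches in at least one ensemble member.
* **4.5 Å** (default for filament neighbour enumeration) — a typical van
  der Waals contact distance. No published criterion pins the filament
  contact shell, so this knob is explicit, configurable, and echoed in
  output headers.

The cell-list contact search is validated against an O(n²) brute-force path
that recomputes candidate distances with the same arithmetic, so the two
methods agree exactly, not just approximately.

SASA is Shrake–Rupley with a fixed element radius table (C 1.70, N 1.55,
O 1.52, S 1.80, H 1.20, P 1.80 Å; override hook for anything else), probe
1.4 Å, and a deterministic golden-spiral point set (default 960 points,
~1% accuracy on a single sphere; the two-body closed-form checks use 3840
points because a shallow lens boundary is quantized at the single-point
level). Hydrogens are excluded by default: NMR models carry them, EM models
do not, and a heavy-atom convention keeps the two comparable. Exactly
coincident spheres are counted once via an index-asymmetric tie-break.
Buried area is defined per component — SASA(isolated) − SASA(in complex) —
not as half a pairwise interface area, because per-protomer accounting is
what "X Å² buried per subunit" statements refer to.

# Perturbation mapping

Line-broadening classification is plain ratio thresholding: ratio =
perturbed/apo intensity, `selective` below 0.25 (a >75% intensity
reduction), `minimal` above 0.50, `intermediate` between. For a small,
fast-tumbling partner such as ubiquitin the matching defaults are
0.05/0.10. Optional global normalization against designated reference
residues exists but is off by default, since published intensity-ratio maps
do not state a normalization; classification is invariant to a common
rescaling of both columns either way. Overlapped/unassigned peaks and peaks
with zero apo intensity are excluded, never silently classified. No
multiple-testing machinery is applied: this is descriptive thresholding.

The HDX protection factor is estimated as a **time-dilation factor**: the α
minimizing Σ[test(t) − reference(t/α)]² over a log grid spanning 1e−3 to
1e3, refined by golden-section search between the best grid point's
neighbours (final resolution ≪ 1%). The reference curve is forced monotone
(running maximum) and interpolated linearly in log-time with clamped ends.
α = 1 means no change; α < 1 means faster exchange (de-protection). This
estimator is an explicit, documented choice: it reproduces the defining
behaviours (identical curves give exactly 1; `test(t) = reference(2t)`
gives 0.5) and is symmetric, PF(A,B) ≈ 1/PF(B,A). Curves with no
resolvable exchange amplitude (< 1e−6) are flagged undefined rather than
fitted. Identifiability is physical, not numerical: a peptide whose curve
is fully saturated (or barely started) inside the labeling window carries
little information about α, and its PF estimate is correspondingly noisy.

Residue-level consensus assigns each residue the plurality vote of its
covering peptides (deprotected below PF 0.7, protected above 1/0.7 —
a conservative margin around 1, configurable), with ties broken toward the
perturbed call. Consensus output covers exactly the union of peptide spans;
uncovered residues are labelled `no_coverage`. **Edge resolution:** with an
offset-3 tiling of 8–15-residue peptides, the two-stage vote recovers a
designed de-protected segment's edges to within one residue but not
exactly — peptide-level data cannot localize a boundary more finely than
the tiling, and the tests assert exactly that (±1 residue on a 15-residue
segment). Segments shorter than a peptide length are not reliably
recoverable at all.

# The polymerization model

No kinetic equations are published for this system; the simulator implements
the **minimal scheme consistent with the qualitative observations**:
nucleation-limited assembly, strictly unidirectional b-end growth, permanent
capping by b-face-dead monomers, and seeding that bypasses nucleation.

States: free monomer counts per species (each species has an `a` and `b`
face flag), plus per-filament subunit sequences with a capped flag.
Reactions, simulated exactly (Gillespie SSA; no tau-leaping, particle counts
stay ≤ 1e5 at desk scale):

* **Nucleation**: rate `k_nuc · C(m, n*)` where m counts free monomers
  functional on both faces; consumes n* of them drawn uniformly without
  replacement.
* **Elongation**: each uncapped filament gains one monomer at rate
  `k_on · (free monomers with a functional a face)`; the joining species is
  drawn proportionally to those counts. A monomer with a dead b face caps
  the filament irreversibly (the depolymerization rate, default 0, never
  removes a capper).
* **Depolymerization** (optional, `k_off`): removes the terminal subunit of
  an uncapped filament.

Invariants guaranteed by construction and asserted in tests: total monomers
conserved at every event; capped filaments never change; nothing ever adds
to an a-end; identical (parameters, species, seed) give identical event
sequences. Observables: total polymer mass fraction (turbidity proxy) and
polymerized fraction of a designated labelled species
(fluorescence-polarization proxy) — readout proxies without optics
modelling.

**Default study conditions** (chosen once, at desk scale): 500 monomers,
nucleus size n\* = 4, `k_nuc = 2e−11` per combination per time unit (so the
initial nucleation propensity is ≈ 0.05 events per time unit),
`k_on = 5e−4` per monomer per end, `k_off = 0`, horizon 200 time units with
201 samples. These make the unseeded lag clearly resolvable (median ≈ 70–110
time units across seeds) while ten pre-formed tetramer seeds collapse it
about tenfold, and a 1:1 b-dead capper reduces wild-type polymer mass to
roughly a quarter of the matched-seed control. The capping assay pairs
control and treatment on the same per-replicate seed (variance reduction)
and tests the one-sided reduction with a paired Wilcoxon at α = 0.01.
An a-face-dead mutant contributes zero propensity everywhere, so it cannot
slow growth in this scheme; a transient end-blocking mode ("minimally
impacted" need not mean exactly zero) is a known omission, left out because
the minimal model has no data to calibrate such a rate against.

# Synthetic data: what it does and does not emulate

`make_toy_protomer()` places a jittered pseudo-atom core (carbon radii) on a
ring of radius 15 Å about the helix axis plus one a/b patch-atom pair per
enabled start number, at fraction 0.42 of the way toward the ∓k/±k
neighbour centres. Under the lattice (5.1 Å, −101.6°) the b patch of
subunit j and the a patch of subunit j+k then sit
(1 − 2·0.42)·|Δcentre| ≈ 3.3–3.8 Å apart — inside the 4.5 Å contact
cutoff — while all other inter-subunit distances stay well outside it. The
generator *verifies* this post hoc by building a 10-mer and enumerating
neighbours, erroring with diagnostics if the requested geometry does not
realize the intended contact shell. This is geometry emulation only: no
side chains, no chemistry, one atom per pseudo-residue.

`perturb_ensemble()` adds isotropic Gaussian coordinate noise (model 1 is
kept unchanged as the reference conformer). Real NMR ensembles have
correlated, anisotropic variation concentrated in loops and termini, so
passing spread statistics on this fixture validates the estimator
arithmetic, not realism of the disorder model. The default noise levels
across the generators (0.3 Å coordinates, 2% intensities, 0.02 fractional
uptake) are sized so recovery tests pass with margin but are not vacuous.

`make_perturbation_dataset()` emulates the *shapes* of the perturbation
data: log-normal peak intensities with designated broadened residues at
ratio 0.1 (others 0.9); single-exponential uptake curves
`1 − exp(−kt)` with per-peptide rates log-uniform in [2e−5, 2e−4] s⁻¹ over
eight log-spaced labeling times from 30 s to 1 day, time-dilated by the
de-protection factor (default 0.3) for peptides whose residue majority lies
in a designated segment. Real peptides exchange multi-exponentially
(per-residue rates spanning orders of magnitude), so recovered PFs on real
data are effective, amplitude-weighted quantities; the single-exponential
fixture tests the estimator under its own model.

# Problem sizes and numerical choices

The test suite and acceptance script run entirely on generated data:
10-subunit filaments of ~26-atom protomers, 500-atom contact fixtures,
20-model × 1000-atom ensembles for the spread closed form, 100 build–fit
round-trip draws across the 4.8–5.4 Å / −104° to −100° box (recovery to
1e−6), 100 paired capping replicates and 15 paired seeding replicates.
PDB coordinates are written at 3 decimals, so file round-trips are exact to
1e−3 Å and helical parameters re-fitted from written files are good to about
that scale. All generators and the simulator take explicit integer seeds;
there is no hidden global-RNG dependence between stages (each stage calls
`set.seed` itself, which also means a stage reseeds the session RNG — by
design, so pipelines are reproducible from the manifest alone).

# Known limitations

* No mmCIF or density-map input; PDB only, and >9999 residues per chain
  would require renumbering (error, not silent wraparound). Construct vs
  deposited residue numbering offsets are the caller's responsibility.
* SASA radii/probe differ in detail from any specific published server, so
  absolute buried-area numbers carry an implementation tolerance of a few
  percent even when the algorithm is exact on closed-form cases.
* The PF estimator returns a single multiplicative factor per peptide; it
  cannot represent mixed protection within one peptide, and consensus edges
  are only peptide-resolution (±1 residue at the default tiling).
* The kinetic model omits fragmentation, secondary nucleation,
  heterotypic (CARD9→Bcl10) hand-off, and zinc-binding equilibria; rates
  are in arbitrary time units and are not fitted to data.
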