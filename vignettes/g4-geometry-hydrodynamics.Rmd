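---
title: "Geometry and hydrodynamics of G-quadruplexes: models and conventions"
author: "g4hydro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and hydrodynamics of G-quadruplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4hydro)
```

This vignette documents the models behind `g4hydro`, the conventions it
fixes where the field leaves choices open, and what its synthetic
generators do and do not emulate.

## The system

A G-quadruplex (G4) is a four-stranded nucleic-acid fold in which four
guanines, usually from different G-tracts, associate into a planar tetrad
through Hoogsteen hydrogen bonds: the Watson–Crick edge of each guanine
(N1-H and N2-H) donates to the Hoogsteen face (O6 and N7) of its neighbour
around a closed 4-cycle. Tetrads stack with a characteristic helical twist,
and monovalent cations (typically K⁺) occupy the central channel between
stacked tetrads, coordinated by the inward-pointing O6 carbonyls.
Interruptions of a G-tract — bulged nucleotides that loop out of the core —
leave a torsional signature on the backbone of the flanking guanylates.
Connecting such structures to solution data means computing hydrodynamic
and scattering descriptors (R~g~, D~max~, P(r), R~h~, s, f/f₀, mass) from
atomic or bead models, and reducing concentration series from
sedimentation-velocity (SV) experiments to standardized infinite-dilution
values.

## Torsion angles

Dihedrals use the IUPAC sign convention — `dihedral()` is the atan2 of the
binormal triple product over the normal dot product — reported in
(−180°, 180°]. The signed convention (rather than [0°, 360°)) is used
because backbone-angle plots in the G4 literature quote γ values as
negative numbers. `torsionProfile()` computes α–ζ and χ per residue;
residues at chain termini, or with disordered atoms, yield `NA` silently
(terminal phosphates are absent by construction, and partially disordered
bases are common in crystal structures).

Two range flags are provided by `flagSpecialRanges()`:

* `gamma_bulge_range`: γ ∈ [−75°, −45°], a region essentially unpopulated
  in idealized loop-free quadruplexes and preferentially occupied by core
  guanylates adjacent to bulges;
* `zeta_loop_range`: ζ ∈ [75°, 180°], populated only when loops are
  present.

The boundaries are fixed package constants (configurable per call); the
package does not re-derive them from reference-ensemble statistics, which
would require a curated set of external structures.

The syn/anti boundary for χ is not standardized anywhere in the field's
nomenclature; `classifyGlycosidic()` uses syn ⇔ χ ∈ (−90°, +90°], which
matches common usage, makes the classification total, and places the
canonical anti region (χ ≈ −120°) unambiguously.

## Base frames and simple pair parameters

`baseFrame()` fits the 9 (purine) or 6 (pyrimidine) ring atoms onto a
planar standard base template by least-squares superposition (Kabsch with a
determinant correction). Because the template is planar, the out-of-plane
axis of the fit is fixed by requiring a proper rotation, which ties the
base normal's sign to the template's atom-order chirality and keeps it
consistent across a structure. The template coordinates follow the
published standard nucleic-acid reference frames; only their internal
geometry matters here, and the tests lock the frame behaviour through
equivariance properties rather than absolute coordinates.

For non-canonical pairs the classic base-pair parameters are hard to
interpret, so the package reports "simple" parameters built directly from
the two base normals and the C1′–C1′ direction as pair long axis:
the rotation taking one normal onto the other is resolved into its
component about the long axis (**propeller**) and about the in-plane axis
perpendicular to it (**buckle**); because the rotation axis is exactly
perpendicular to the mean normal, buckle² + propeller² reproduces the total
inter-normal bend. **Stagger** is the inter-origin displacement along the
mean normal, reported as an unsigned magnitude.

One convention needed fixing: if both the pair axes and the bend direction
follow the argument order, the two sign flips cancel and the parameters
become symmetric under argument exchange. `simplePairParams()` therefore
ties the in-plane axes to the canonical (residue-key-ordered) pair while
measuring the bend from the first argument to the second, which yields the
clean antisymmetry "swap negates buckle and propeller, stagger invariant".
Inside a tetrad the cycle replaces the canonical order: pair parameters are
computed around the Hoogsteen donor→acceptor cycle with the tetrad normal
as common orientation reference, so buckle signs are comparable among the
four pairs — which is what the shape rules need.

## Tetrad detection and shape

`detectTetrads()` builds a directed graph with an edge g → h when both
heavy-atom distances N1(g)–O6(h) and N2(g)–N7(h) are ≤ 3.5 Å (default,
configurable). No hydrogen positions or angle terms are used because
crystal structures typically lack hydrogens. Tetrads are directed 4-cycles;
each guanine joins at most one tetrad (deterministic greedy resolution),
and cycle order is normalized to start at the lowest residue key. Tetrad
normals are oriented along the strands' 5′→3′ direction, inferred from
covalently consecutive guanines in different tetrads; with that
orientation, positive buckle means bending toward the channel direction.

Shape rules (evaluated in order, first match wins; threshold 5°):

1. **planar** — all |buckle| < 5° and all |propeller| < 5°;
2. **convex** — all four buckles positive;
3. **concave** — all four buckles negative (added as the complement of
   convex so the classification is total);
4. **saddle** — buckle signs alternating (+,−,+,−) or (−,+,−,+);
5. **other** — everything else.

`stackingTwist()` averages, over the four strands, the rotation about the
mean tetrad normal between corresponding C1′→N9 in-plane axes. Positive
twist is counter-clockwise when viewed from the 5′ side looking along the
5′→3′ channel direction. A "counter-clockwise" offset in words depends on
the viewing direction, so this sign convention is the package's own,
shared by the ideal builder and the measurement — the two are tested
against each other for both signs.

## Synthetic generators

`buildIdealG4()` places a planar guanine template (base ring + C1′, plus an
O4′ added at the requested glycosidic torsion, default anti at −120°) with
an in-plane rigid placement solved at build time so that the Hoogsteen
contacts of 4-fold-rotated neighbours are 2.90 Å and C1′ sits at
`c1Radius` from the axis. The default `c1Radius` of 8.26 Å puts the O6
ring at ≈ 2.4 Å from the axis, consistent with channel-cation
coordination. Tetrad *k* is rotated by *k*·twist and raised by *k*·rise;
defaults (twist 30°, rise 3.4 Å, K⁺ midway between tetrads) reproduce the
canonical parallel-G4 stacking geometry with an ion grid spacing equal to
the rise. Because base planes are exactly perpendicular to the axis, the
pristine output has zero buckle, propeller and stagger: its classification
as "planar" is provable, and every downstream detector must recover the
construction parameters exactly.

The builder intentionally omits the sugar-phosphate backbone (no sugar
pucker optimization, no loop or bulge conformers): it is a geometric
oracle, not a chemically complete model builder. Backbone torsion
round-trips are instead covered by `buildChainFromInternalCoords()`, a
natural-extension (NeRF) constructor that reproduces any requested torsion
list exactly (verified to ≤ 10⁻⁶ degrees) and can emit backbone-named
chains whose `torsionProfile()` recovers the inputs.

`simulateSVSeries()` draws s_app(c) = s₀(1 − k_s·c) + ε with homoscedastic
Gaussian ε — symmetric confidence intervals in species analyses justify the
homoscedastic choice — behind a single integer seed, restoring the global
RNG state afterwards. What it does *not* emulate: radially dependent
optical noise, Lamm-equation model error, concentration-dependent
monomer–dimer re-equilibration, or correlated uncertainties between s, M
and the fractions. Passing tests therefore certify the extrapolation and
coverage machinery, not the upstream fitting of sedimentation profiles.

## Hydrodynamics

Bead models carry centers (Å), radii and weights. Atomic structures become
bead models with one bead per heavy atom (weight = atomic mass) and a
uniform atomic element radius, default **2.54 Å**, the value calibrated in
the literature for quadruplex DNA atomic-level hydrodynamic calculations.
For ab initio SAXS models the bead radius comes from the header volume via
AER = (3·V_DA/4π)^(1/3).

* **R~g~** includes the bead self-term:
  R~g~² = Σw|r−r̄|²/Σw + (3/5)⟨σ²⟩~w~. For an atomic model this self-term
  inflates R~g~ slightly relative to shell-model conventions; a residual
  difference of a few percent against shell-model programs is expected.
* **P(r)** is the weighted histogram of center distances with a triangular
  smearing kernel of half-width σᵢ+σⱼ per pair; D~max~ = max distance + one
  bead diameter; normalization is to unit integral (instrument-scaled
  P(r) is out of scope). The default bin width is
  max(bead diameter, D~max~/200).
* **R~h~ (Kirkwood)**: 1/R~h~ = (1/N²)(Σ1/σᵢ + Σ_{i≠j}1/r~ij~). This
  orientationally averaged double sum is exact in spirit for *surface*
  distributions: for a spherical shell the mean inverse distance is exactly
  1/R. For a volume-filled ball it converges to 5R/6 — interior beads
  contribute friction they cannot physically exert — which is precisely why
  shell-model programs build surface shells. `makeSphereBeadModel(shell =
  TRUE)` provides such shells (outermost lattice layer projected onto the
  sphere), and the convergence tests run on them.
* **R~h~ (RPY)**: rigid-body friction from solving the 3N×3N
  Rotne–Prager–Yamakawa mobility system for uniform translation and taking
  the trace of the resistance tensor over 3. The volume-corrected RPY
  overlap form is used for overlapping beads (exact for equal radii; the
  mean radius with a warning otherwise). RPY is the accuracy path and
  handles filled models correctly (interior screening emerges from the
  matrix inversion).
* **Svedberg relation**: s = M(1 − v̄ρ)/(N_A·6πη·R~h~), reported in
  Svedberg (10⁻¹³ s). Buffer standardization multiplies by
  (η_T,b/η₂₀,w)·(1 − v̄ρ₂₀,w)/(1 − v̄ρ_T,b) with standard-water constants
  η₂₀,w = 0.010016 P and ρ₂₀,w = 0.998206 g/cm³ (documented package
  constants, exposed through `waterAt20C()`), and v̄ treated as buffer- and
  temperature-independent. The default v̄ = 0.541 cm³/g is the literature
  value for a potassium-folded DNA quadruplex.
* **Mass from composition** uses average atomic masses, 5′-OH/3′-OH
  termini (a 5′-phosphate flag exists) and n−1 phosphodiester linkages;
  bound cations add their bare atomic mass.

## SV extrapolation

`extrapolateToZeroConc()` fits value ~ concentration by least squares,
inverse-variance weighted by default whenever per-point uncertainties are
available (zero uncertainties fall back to unweighted with a warning,
rather than producing infinite weights). 95% confidence intervals come from
the t distribution with n−2 degrees of freedom. Because the buffer factor
is concentration-independent, standardizing before or after extrapolation
gives identical intercepts; the package standardizes per point first, and
the commutation is a tested property. Exclusion of high-concentration
points (non-ideal sedimentation) is the caller's explicit decision via
`excludeAbove` — nothing is dropped silently. Dissociation-constant
estimation is deliberately absent: with species fractions flat in
concentration, the data only bound K_d from above.

## Numerical choices and degenerate inputs

* Alternate locations: highest occupancy wins, ties to the first
  encountered — the analyses need exactly one conformer per atom.
* Hydrogens are dropped on read (crystal structures lack them; the
  Hoogsteen criterion and bead models are heavy-atom-based); `hydrogens =
  TRUE` retains them.
* Collinear point triples make dihedrals undefined and raise errors, as do
  degenerate NeRF requests (bond angle 0°/180°, collinear seed frame).
* Structures beyond 99999 atoms are refused by the writer (fixed-width PDB
  serials; hybrid numbering schemes are out of scope).
* The in-plane tetrad placement is solved by deterministic quasi-Newton
  minimization from a fixed start near the physical solution; an
  unattainable `c1Radius` raises an error rather than returning a distorted
  tetrad.
* Problem sizes in the test suite were chosen to certify convergence at
  desk scale: filled spheres to bead radius 2 (≈ 500 beads) for R~g~ and
  RPY, projected shells to bead radius 1.25 (≈ 700 beads, Kirkwood and RPY
  within 3% of the Stokes limit), and 1000 seeded replicates for the 95%
  CI coverage check (observed coverage must fall in [93%, 97%]).

## Known limitations

* Tetrad detection is guanine-only; mixed tetrads (U-tetrads, C-quartets)
  are not detected.
* Only standard PDB-format input is supported (no mmCIF writing, no
  crystallographic symmetry expansion, no anisotropic B-factors).
* The RPY path is single-resolution; no shell extrapolation over bead sizes
  is attempted, so small systematic differences from shell-extrapolating
  programs remain within the tolerance band stated above.
* Absolute-scale SAXS intensities, I(0)-based masses and ab initio shape
  reconstruction are out of scope; the package starts from coordinates or
  bead models and from species-analysis outputs, not from raw scattering
  curves or sedimentation profiles.
* Bulge "type" labels (looped-out type I vs type II) are descriptive
  metadata in the literature without an operational definition; the package
  reports them only if supplied by the user, never computes them.
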