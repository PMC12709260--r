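---
title: "Ensemble observables for disordered peptides: models and numerical choices"
author: "idplens"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Ensemble observables for disordered peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idplens)
```

# What the package computes

`idplens` analyses conformer ensembles of intrinsically disordered
peptides — the motivating system is a 35-residue fragment of the amyloid
precursor protein intracellular domain (AICD) carrying the YENPTY
phosphotyrosine-binding motif at residues 22–27. The workflow decomposes an
ensemble by radius of gyration (Rg) and computes, per Rg group and globally:
forward small-angle X-ray scattering (SAXS), Guinier and dimensionless
Kratky analyses, the pair-distance distribution P(r), solvent-accessible
surface area (SASA), minimal Cα–Cα contact and hydrogen-bond occupancy
maps, secondary structure, Ramachandran region fractions, Karplus scalar
J-couplings, a predicted circular-dichroism (CD) spectrum, tICA landscapes,
and GROMOS-style conformational clusters.

Because curated molecular-dynamics trajectories are large and external, the
package ships a seeded generator that produces ensembles with the
statistical features the analyses rely on, so every stage runs and is
tested end to end from code alone.

# The synthetic conformer generator

Each replica is a Markov chain over backbone dihedrals. A proposal redraws
one residue's (φ, ψ) from a Gaussian mixture of four Ramachandran basins —
αR (−63°, −43°), β (−120°, 130°), PPII (−75°, 150°) and αL (60°, 45°), with
default weights 0.30 / 0.35 / 0.25 / 0.10 and spread σ = 15°. Chains are
rebuilt with ideal geometry (N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å,
ω = 180°; amide H and carbonyl O in the peptide plane, Cβ at the
tetrahedral L-position). A proposal is rejected when any two heavy atoms
from residues at least two apart come closer than the clash cutoff
(default 2.8 Å), and, when a compaction target is set, by a Metropolis
step on U = k (Rg − Rg⁎)² with k in kBT/Å² (default 2.0). States are
recorded every 10 accepted moves, so consecutive frames are autocorrelated
— a prerequisite for meaningful time-lagged analysis, not a claim about
physical kinetics. Replica r runs on R's RNG seeded with `seed + r`:
replicas are independent and the whole ensemble is a deterministic
function of the seed.

Five replicas of 2,000 frames each, with a pseudo-time of 100 ps per frame
and the first 30 ns of each replica discarded, form the default
"desk-scale" study (8,500 analysed frames). These sizes were chosen so the
whole pipeline, including the O(n²) stages, completes comfortably on one
CPU; all of them are configuration fields.

Two deliberate departures from real data: side chains beyond Cβ are not
modelled (the missing mass is lumped onto Cβ, and the missing electrons are
absorbed into the Cβ form factor, so Rg and scattering still track whole
residues), and the hard-sphere/bias energetics are not a force field.
Consequently, passing tests demonstrate that the *observables* are computed
correctly on ensembles with realistic compaction, autocorrelation and
dihedral statistics; they do not validate any force field.

One visible consequence of the excluded-volume model is worth stating:
under the default 2.8 Å clash cutoff, the sampled dihedral marginals are
*not* the proposal mixture. Helical stretches place the O(i)…N(i+4) pair
near 2.9 Å, so basin-weight recovery tests run with a minimal cutoff
(1.0 Å) that isolates dihedral sampling from steric depletion; the recovery
regions partition the Ramachandran torus at basin midpoints so each
rectangle owns one basin's full Gaussian mass.

# Rg decomposition

Rg is mass-weighted over all atoms (a Cα-only selection is available).
Frames join the nearest integer-Å bin (configurable width) with a half-up
rule at ties: 10.4 Å → group 10, 10.5 Å → group 11. Group index lists are
written as GROMACS-convention NDX files (1-based on disk, 0-based in
memory; the shift lives exclusively in the reader/writer pair). Frames with
pseudo-time strictly below the discard horizon are dropped; a frame exactly
at the horizon is kept. RMSD uses the Kabsch least-squares superposition
and is reported in nm; the default reference is the first post-trim frame,
a choice that matters for absolute RMSD levels and is therefore explicit in
the API.

# SAXS forward model

Scattering is the Debye sum
I(q) = Σᵢⱼ fᵢ(q) fⱼ(q) sin(q rᵢⱼ)/(q rᵢⱼ) with Cromer–Mann atomic form
factors and the Gaussian dummy-atom excluded-solvent term
f_eff = f(q) − ρ V exp(−q² V^{2/3}/4π) at ρ = 0.334 e/Å³; the hydration
shell contributes nothing (zero contrast) and no hydration model exists in
the package. The default q grid is 100 log-spaced points over
0.0078–0.495 Å⁻¹. For reduced topologies the electrons of unmodelled
side-chain atoms scale the Cβ carbon form factor (Cα for Gly), and the
terminal H/OH are added to the first N and last C; the per-element
coefficients and volumes ship in `inst/extdata/cromer_mann.tsv`.

Ensemble and group averages accumulate per-type-pair distance histograms
(bin width 0.1 Å) and apply the Debye kernel once per bin — identical to
the frame-by-frame sum to about 10⁻⁴ relative and orders of magnitude
faster; `method = "exact"` forces the full sum, and the unit tests hold
the vectorised sum to a brute-force double loop at 10⁻¹⁰.

The Guinier fit iterates: fit ln I vs q², restrict to q·Rg < 1.3, refit
until stable. The dimensionless Kratky plot is (qRg)² I(q)/I(0) with I(0)
from the Guinier extrapolation. χ² between curves is
Σ (Eᵢ − Sᵢ)²/Sᵢ² — the simulated-intensity-weighted form, implemented
literally; the conventional σ-weighted reduced χ² is a separate function
(`chiSquareSigma`), and an optional least-squares scale factor on S is
fitted and reported because published comparisons often leave the scaling
convention unstated.

P(r) is computed two ways. The indirect transform expands P(r) in sines
vanishing at 0 and Dmax and fits I(q) by Tikhonov-regularised least squares
(penalty α‖k² aₖ‖², so α → ∞ drives P → 0) plus a fittable flat offset
that absorbs the point-atom self-scattering term the sine basis cannot
represent. The direct route histograms all interatomic distances weighted
by f(0) products. With data truncated at q_max, the indirect curve is
band-limited to a real-space resolution of roughly π/q_max ≈ 6 Å; for the
broad, skewed P(r) of a disordered chain this smoothing shifts the
apparent mode by 1–2 Å, so the cross-validation between the two routes
compares modes at that resolution, not at arbitrary fine binning.

# Structural observables

SASA is Shrake–Rupley with a 1.4 Å probe, 960 golden-spiral points per
atom and Bondi radii over heavy atoms (hydrogens optional). The fixed
sphere grid makes single-atom areas exact to ≪0.5% but leaves a small
orientation dependence (≈ a few percent on per-residue variances), shared
with other deterministic implementations. Group summaries subtract the
unweighted mean over group means — the "grand mean" — from group totals
and per-residue values; a frame-weighted alternative sits behind a flag.

Hydrogen bonds use the geometric criterion N…O ≤ 3.5 Å and H–N–O ≤ 30°
(the common trajectory-tool defaults; both configurable), reported as the
fraction of group frames with at least one bond per residue pair.
Secondary structure uses the Kabsch–Sander electrostatic energy
E = 27.888 (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with a bond below
−0.5: helix from two consecutive i→i+4 bonds, strand from
parallel/antiparallel bridge patterns, turn from isolated i→i+3/i+4
bonds, bend from a >70° Cα direction change, priority helix > strand >
turn > bend > coil. Richer DSSP classes are collapsed into these five
(3₁₀/π into helix, isolated bridges into strand); on ideal helix and
hairpin fixtures the collapsed labels agree exactly with a full DSSP
implementation, which the tests freeze as an oracle.

J-couplings evaluate ³J(φ) = A cos²φ + B cosφ + C (A 6.4, B −1.4, C 1.9
Hz) and ²J(ψ) = A′cos²ψ + B′cosψ + C′ (A′ 2.0, B′ −0.5, C′ 0.5 Hz)
literally, with means and SDs per residue per group. A configurable angle
offset exists because many ³J(HN–Hα) parameterisations use θ = φ − 60°;
the default is 0 so the equations are applied exactly as written, and
users comparing to experiment should set the offset their coefficients
assume.

Ramachandran fractions integrate a 5°-binned 2D histogram over named
rectangles. No universal region definition exists, so reported fractions
always carry their rectangles; the defaults cover the four generator
basins.

# CD

Measured millidegrees convert to molar CD via
Δε = CD·MRW / (32980 · l · c), with MRW = MW/(L−1) from average residue
masses; the constant 32980 is used exactly and the inverse conversion
makes the round trip an identity. The predicted ensemble spectrum is the
secondary-structure fractions applied to per-class basis spectra; by
linearity, frame-wise and fraction-wise averaging coincide, which is
asserted rather than assumed. The packaged basis curves are *synthetic*
parametric Gaussian-band approximations at the canonical band positions
(helix +192/−208/−222 nm, strand +196/−217 nm, coil −197 nm, weak turn
bands) — adequate for testing the linear-mixing machinery and for
qualitative shapes, not a digitised reference set; substitute a
literature basis via the `basis` argument for quantitative work. The
decomposition back onto the basis is exact non-negative least squares
with the fractions constrained to the simplex (active sets enumerated,
so no iterative-solver failure modes).

# tICA, landscapes, clustering

Features default to sin/cos of every defined backbone dihedral — φ for
residues 2..L and ψ for 1..L−1, hence 4(L−1) dimensions; Cα distance
features are available. Lagged pairs never straddle replica boundaries.
The estimator uses the symmetrised lagged covariance
C_τ = (C(τ)+C(τ)ᵀ)/2 and solves C_τ v = λ (C₀ + εI) v through a Cholesky
whitening, so eigenvalues are real and bounded by 1 up to sampling noise
and eigenvectors return C₀-orthonormal. The default lag is 100 frames and
is echoed into every output. Free-energy surfaces are −ln(ρ/ρ_max) in kBT
with empty bins undefined (NA), never infinite; observable-coloured
landscapes average a per-frame quantity per bin.

Clustering is the GROMOS/Daura neighbour-count algorithm under a pairwise
Cα RMSD cutoff of 0.9 nm: the frame with the most neighbours seeds a
cluster, members are removed, iterate; ties go to the lowest frame index.
The O(n²) cost is capped by stride subsampling above a configurable frame
budget (default 20,000 in the function, 2,000 in the pipeline), and the
stride is recorded in the result.

# Pipeline and provenance

`runPipeline()` executes generate/ingest → pseudo-time → trim+concatenate
→ decompose → per-group SAXS, P(r), optional χ² against an experimental
curve → SASA/contacts/H-bonds/secondary structure/Ramachandran/J-couplings
→ CD → tICA and landscapes → clustering, writing every table under one
run directory with a manifest (config serialised verbatim with its MD5,
seed, package version, per-stage frame counts). Quantity names carry
units (trim_ns, cutoff_nm) because the field mixes Å (Rg, SAXS) and nm
(RMSD, SASA, cluster cutoff). A failed stage halts with its name and
preserves earlier artifacts; `pipelineReport()` is a pure function of the
run directory.

# Known limitations

- No hydration-shell scattering model; comparisons to shell-sensitive
  reference curves will differ at mid-q.
- The reduced topology cannot resolve side-chain-specific SASA or
  side-chain hydrogen bonds; full-atom input is accepted for scattering
  and SASA but the generator never produces it.
- CD basis spectra are parametric stand-ins (above).
- The Markov-chain kinetics are a sampling device; tICA on generated
  ensembles tests the estimator, not molecular timescales.
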