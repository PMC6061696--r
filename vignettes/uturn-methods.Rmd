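---
title: "Methods: ensemble analysis of an RNA U-turn"
author: "uturn package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble analysis of an RNA U-turn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uturn)
```

# The system and the questions

The neomycin-sensing riboswitch (NSR) is a 27-nucleotide RNA hairpin whose
apex folds into a U-turn, a backbone-reversal submotif with a 5'-UNR-3'
consensus. The motif is held together by a small set of named interactions:
the signature hydrogen bond from the conserved uridine's imino nitrogen
(U14 N3-H3) to a downstream non-bridging phosphate oxygen (A17 OP2), two
cis Watson-Crick (cWW) U/U base pairs (U13/U18 closing the loop and
U10/U21 in the upper helix), an anion-pi contact of a phosphate oxygen
(A16 OP2) over the base-14 plane, a lone-pair-pi contact of an ether
oxygen (U18 O4') over the A16 base, and a monovalent-cation site keyed to
U14 O4. This package turns the analyses used to characterize these
features in multi-model coordinate ensembles — NMR model series or
trajectory frame series — into tested, reusable functions, together with
the nonlinear fits for the associated NMR observables (chemical-shift
titrations and trans-hydrogen-bond scalar couplings).

Every quantity below is computed by exported functions; this document
explains the conventions and the reasoning behind the defaults. It states
no result that the test suite or `scripts/acceptance.R` does not itself
compute.

# Containers and units

Coordinates are Angstrom, times picoseconds, concentrations mM, couplings
Hz, shifts ppm — enforced once, in the classes. An `Ensemble` stores an
ordered frame series over one atom table (`natoms x 3 x nframes` array);
`getFrame()` views one frame. Atoms are addressed by author residue number
plus PDB atom name (`"14:N3"`), never re-indexed, because every interaction
in this motif is conventionally named that way. Sugar-name dialects
(`O2'`/`O2′`/`O2*`, `O2P`/`OP2`) are normalized on input; waters and
cations are recognized under their common residue-name dialects
(`HOH`/`WAT`, `K`/`K+`, `NA`/`NA+`, `MG`). PDB reading and writing is
delegated to `bio3d`; the package adds a pre-scan so a deposition with
inconsistent per-model atom counts fails naming the first offending model.
A plain frame-series TSV is provided as the trajectory carrier for
synthetic data; atom order within a frame block is canonicalized on
reading, so file row order is never significant.

# Hydrogen bonds and water bridges

A hydrogen bond is counted when the donor-acceptor heavy-atom distance is
strictly below 3.5 Angstrom and the donor-hydrogen-acceptor angle strictly
above 120 degrees. Both inequalities are strict exactly as printed, so
counts at boundary geometries are reproducible. Hydrogens are required: the
angle is part of the criterion, and structures lacking hydrogens are
rejected rather than approximated with a silently different criterion. A
hydrogen more than 1.2 Angstrom from its donor triggers a warning
(implausible covalent labelling) but the geometry is still reported.

A water bridge between a donor triple and an acceptor is the first water
whose oxygen accepts from the donor under the same criteria and donates to
the acceptor through either of its hydrogens. When several waters qualify
in one frame, the smallest water residue number wins — an arbitrary but
documented tie-break that makes traces reproducible.

# U/U base-pair conformer states

The two cWW U/U pairs are classified per frame against small state
schemes. For U13/U18 there are two states: `2a`, with direct
U13(N3)->U18(O4) and U18(N3)->U13(O2) bonds, and `1a`, in which the
U18(N3)/U13(O2) interaction is water-mediated. For U10/U21 the
symmetry-related `2b`/`1b` variants (O2 and O4 roles swapped) exist as
well; in both single-bond variants the water-mediated bond is the one
involving O2. Classification priority follows the reporting convention:
states with more direct bonds are tested first (a frame satisfying a
two-bond state keeps that label even if a bridging water is also present),
then scheme list order (`2a` before `2b`).

One subtlety the test suite documents: relabeling O2<->O4 in both residues
maps `2a` and `2b` onto each other exactly, but not `1a` onto `1b` — the
relabeled single-bond frames have their direct bond on O2 and their bridge
on O4, which matches no defined arrangement and is reported `unassigned`.
This is a consequence of fixing the water-mediated bond to the O2
interaction and is intentional.

Populations are reported twice: fractions over all frames with the
unassigned fraction listed separately, and percentages renormalized over
assigned frames only (the table-row convention). Whether published
population tables renormalize over assigned frames is generally unstated,
so both are always emitted. Ensembles without explicit waters cannot
exhibit water-mediated states; those states are reported as unavailable
(`NA`), never as zero.

# Base planes and pi-contact distances

Base planes are fitted by the singular-value solution of the centered ring
coordinates — the plane minimizing the sum of squared perpendicular
distances. Ring-only atoms are the default (six atoms for pyrimidines,
nine for purines); whether published plane definitions include exocyclic
atoms is typically unstated, so exocyclic inclusion is available via the
`ringAtoms` argument. The normal's sign is fixed toward the glycosidic
N->C1' direction purely for reproducibility; pi-contact distances are
unsigned. Summaries are the median across frames (midpoint of the two
central values for even counts) plus/minus the standard deviation: a
published "median ± x" rarely defines x, so the pair median/sd is declared
here as the single testable convention.

# Superposition and per-residue RMSD

`superposeAndRMSD()` implements the average-structure reference: frames
are superposed on frame 1 (Kabsch rotation over the fit subset), averaged,
re-superposed on the average and re-averaged until the average moves less
than 1e-4 Angstrom. Per-residue RMSD is computed over heavy atoms against
the final average. A finite-size caveat the tests exercise: superposition
absorbs 6 rigid degrees of freedom, so for N fitted atoms the expected
atom RMSD under isotropic coordinate noise sigma is
`sigma * sqrt(3) * sqrt(1 - 6/(3N))`, which is within 5% of
`sigma * sqrt(3)` only for N of about 40 and above.

# NOE ensemble averaging

The effective distance of a restraint over an ensemble is
`d = [ mean_frames ( sum_pairs r^-6 ) ]^(-1/6)`: within each frame all
proton pairs between the two groups contribute their `r^-6` sum (so
equivalent protons are combined without pseudoatoms or corrections), the
sums are averaged over frames, and the result inverted. The exponent 6 is
the NOE-intensity-consistent convention for "weighted average" ensemble
distances; `exponent = 3` is available and recorded in report metadata
when used. No pseudoatom correction is applied to upper bounds by default.
A restraint is violated when the effective distance exceeds its bound by
strictly more than 0.3 Angstrom ("larger than 0.3"); restraints whose
atoms do not resolve are listed separately and excluded from the
applicable denominator, giving the familiar "V of N" totals.

The power-mean inequality pins the estimate for single pairs:
min over frames <= effective distance <= arithmetic mean. The suite
asserts this on 1000 random ensembles.

# Cation atmosphere

`computeRDF()` normalizes the pair count in each shell by the count
expected for ions uniformly distributed at the ensemble's mean ion density
over the analysis sphere, so g(r) converges to 1 on an ideal-gas fixture.
Site occupancy is keyed to the primary coordinating atom only — a frame is
occupied when any ion of the species is within the inner cutoff of that
atom — because the characterized site is defined by its near-permanent
direct contact there; auxiliary atoms are descriptive, their contacts
classified inner / outer / none by distance shells. The inner cutoff
default of 3.4 Angstrom is the first minimum of the K+/Na+-oxygen RDF on
the package's fixtures; published cutoffs are usually not printed, and the
documented workflow is to re-derive them with `computeRDF()`. The
outer-shell label is a distance band (3.4-6.0 Angstrom); verifying an
intervening water would be a possible extension.

Residence episodes are maximal runs of occupied frames; unoccupied gaps up
to a tolerance (default 0, i.e. strict) are absorbed, and the tolerance is
part of the output metadata because published residence accounting is
rarely specified. Durations are frames times dt. Density maxima bin ion
positions on a 0.5-Angstrom grid and greedily merge cells within 2
Angstrom into ranked regions; the operation refuses ensembles that have
not been superposed first, since densities in an unaligned frame mix
internal and overall motion. Periodic boundaries are not modelled —
inputs are assumed imaged, as processed ensembles are.

# NMR observable fits

The trans-hydrogen-bond coupling is fitted globally to
`I_cross/I_ref = cos(pi * J * tau_m)` with one J pooled across replicates
(replicates therefore weigh by their point count; the alternative
equal-replicate weighting is not used, and duplicating identical
replicates demonstrably leaves the solution unchanged). The cosine is
periodic, so the fit is initialized by a 0-20 Hz grid at 0.05 Hz and takes
the smallest-J minimum before local refinement; uncertainty comes from a
seeded residual bootstrap. Fewer than three distinct delays are refused by
default; the `minDelays` argument exists for deliberate degenerate checks
such as reading J off a single zero crossing (`J = 1/(2 tau)`).

Binding isotherms use `dd = ddmax * c / (KD + c)` for a single site and a
Hill form with coefficient fixed at 2,
`dd = ddmax * c^2 / (KD^2 + c^2)`, for cooperative two-ion binding — the
published functional form of such fits is typically not printed, so the
Hill-2 surrogate is declared in every output. Free titrant is taken equal
to total (no depletion correction), valid for mM-scale titrant against
uM-scale RNA. Fits are Levenberg-Marquardt with KD bounded positive and
initialized at the concentration nearest half the maximal shift;
`compareModels()` reports both residual sums and their variance ratio
(the two models have equal parameter counts, so this is a descriptive
statistic, not a nested-model test) and deliberately renders no verdict.

# Synthetic data: what it emulates and what it does not

The generators produce every input the analyses consume, with declared
statistical structure, and each is a pure function of its spec and seed.

*Conformer ensembles* realize a per-frame Markov chain over a scheme's
states. Coordinates are toy geometry: two idealized planar pyrimidine
templates are rigidly posed so that each state's required bonds hold at
about 2.9 Angstrom with essentially linear N-H...acceptor geometry,
non-required donor/acceptor combinations are pushed beyond 4.2 Angstrom,
and bridging waters are placed to realize water-mediated states (unused
waters are parked far away so the atom table is constant). The generator
verifies at build time that each state's template classifies as its own
label and refuses unrealizable definitions. The default transition matrix
has equal rows (0.6, 0.4) over `2a`/`1a` — the rapid-exchange 60/40
two-state equilibrium used as the reference condition; equal rows make the
frames independent, so the binomial standard error applies exactly to
population recovery. Toy templates test the classification predicates,
not chemistry: real stacking, backbone context, and correlated motions
are absent, so passing tests validate the measurement chain, not force
fields.

*Ion tracks* alternate bound and unbound dwells with geometric
(discrete-time memoryless) lengths — the two-state counterpart of the
high-occupancy, fast-exchange site — with defaults of bound fraction 0.8,
mean residence 250 ps at dt 10 ps, bound positions Gaussian (sigma 0.15
Angstrom) around a 2.8-Angstrom contact, and unbound positions uniform
beyond the outer cutoff in a 20-Angstrom box. The bound-position sigma is
deliberately small enough that the geometric tail beyond the 3.4-Angstrom
cutoff is negligible, keeping measured occupancy equal to the generated
bound fraction. For occupancy recovery the correct standard error is the
binomial sigma inflated by the dwell autocorrelation factor
`sqrt((1+rho)/(1-rho))`; the tests use three of those standard errors.
A continuous-time exponential dwell variant is a possible extension; the
discrete geometric form matches the per-frame Markov framing used
throughout.

*Titrations* are exact isotherm curves plus Gaussian shift noise. The
default amplitude is 0.3 ppm — a typical saturating imino-proton shift
change for mM-scale cation binding — chosen so that the pre-registered
recovery tolerance (median relative KD error below 10% at 0.01 ppm noise
on 8 points) is attainable by any sensible design; amplitudes below about
0.25 ppm make that tolerance unreachable regardless of the concentration
grid. *Constant-time series* are `cos(pi J tau)` plus noise in the
protocol shape of seven delays measured twice.

*The NSR-style stand-in* (`genSyntheticNSR()`) is a synthetic 27-residue,
20-model ensemble whose generator conditions are the published NMR-row
features: both U/U pairs posed `2a`, A16(OP2) at 2.93 Angstrom along the
base-14 plane normal, U18(O4') at 3.01 Angstrom along the A16 plane
normal, the signature N3/OP2 bond at 2.86 Angstrom, and a K+ ion in
contact with U14(O4), under 0.05-Angstrom inter-model noise. It is
labelled synthetic everywhere: it exists because the analyses need a
deposition-shaped object to exercise the full chain (PDB round trip,
residue counting, table-style reporting), and results on it validate the
chain, not the deposition. Its residues are not chemically consistent
(base and backbone atoms of scaffold residues are placed independently),
which is irrelevant to, and documented for, every measurement made on it.

# Problem sizes and numerical choices

The test suite runs at sizes chosen to make stochastic assertions sharp
but cheap: 1e5 frames for population and ion-kinetics recovery (binomial
or chain-corrected 3-sigma bands), 1e4 frames for the superposition noise
oracle, 1e3 random ensembles for the NOE power-mean property, 100 seeded
replicates for KD recovery and model comparison. The full suite completes
in well under a minute on one CPU. Convergence tolerances: 1e-4 Angstrom
on the superposition average, 1e-12 on the 1-D coupling refinement,
`ftol`/`ptol` 1e-15 for isotherm least squares (needed for the 1e-6
noise-free inversion checks). Degenerate inputs fail loudly: collinear
rings, empty fit subsets, unresolvable atoms, non-stochastic transition
matrices, negative tolerances.

# Known limitations

Only the two built-in schemes plus user-defined states are classified —
this is not a general Leontis-Westhof annotator. The NOE module reproduces
the ensemble-validation arithmetic, not restraint-file dialects (the TSV
carrier is canonical; converters are out of scope). mmCIF and binary
trajectory formats are not read. Divalent-ion competition, force fields,
and any electronic-structure treatment of the pi contacts are out of
scope: the anion-pi and lone-pair-pi quantities here are geometry only.
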