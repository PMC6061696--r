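# uturn

Ensemble analysis of the RNA U-turn motif: hydrogen bonding, U/U base-pair
conformers, NOE validation, the cation atmosphere, and the associated NMR
observable fits.

## The problem

The neomycin-sensing riboswitch is a 27-nucleotide hairpin capped by a
U-turn — the backbone-reversal submotif with a 5′-UNR-3′ consensus whose
conserved uridine (U14 here) anchors the loop through a signature
N3–H3···OP2 hydrogen bond to a downstream phosphate. Characterizing such a
motif from a multi-model coordinate ensemble (an NMR model series or a
trajectory) means answering a recurring set of questions with tight,
reproducible conventions:

- which hydrogen bonds are formed, frame by frame, under the printed
  criteria (heavy-atom distance < 3.5 Å, D–H–A angle > 120°, both strict);
- which cis Watson–Crick U/U conformer each frame adopts — two direct
  bonds (`2a`/`2b`) or one direct plus one water-mediated bond
  (`1a`/`1b`) — and the resulting populations and transitions;
- how far phosphate / ether oxygens sit above the base planes (the
  anion-π and lone-pair-π contacts), as medians over the ensemble;
- whether the ensemble violates its NOE upper bounds under r⁻⁶
  ensemble averaging, `d = [⟨Σ r⁻⁶⟩]^(−1/6)`, with the "V of N" accounting
  of violations larger than 0.3 Å;
- how a monovalent cation behaves at its binding site: occupancy keyed to
  the primary coordinating atom, inner/outer-shell contacts, normalized
  radial distribution functions, density maxima, and residence-time
  episodes;
- and, from NMR titrations and constant-time intensity ratios, the
  dissociation constants `Δδ(c) = Δδ_max·c^h/(K_D^h + c^h)` (h = 1 or a
  fixed Hill coefficient of 2 for cooperative two-ion binding) and the
  trans-hydrogen-bond coupling `I_cross/I_ref = cos(π·J·τ_m)`.

The package implements all of these as tested functions over S4 containers
(`Ensemble`, `NOERestraint`, `IonSite`, `TitrationSeries`,
`CTIntensitySeries`), plus a synthetic-data layer that generates every
input with declared statistical structure — Markov-switching conformer
ensembles, two-state ion tracks, noisy titrations and cosine decays — so
every stage is testable end to end without external downloads. A
deposition-shaped synthetic stand-in ensemble (`genSyntheticNSR()`)
realizes the published NMR-row geometry of the motif for exercising the
full chain; it is toy geometry, clearly labelled synthetic.

## Worked example

```r
library(uturn)

e <- genSyntheticNSR(seed = 1)        # 27-residue, 20-model synthetic stand-in
e
#> Ensemble: 20 frame(s), 324 atoms, 30 residues
#>   provenance: synthetic NSR-style ensemble (seed 1, 20 models)

## anion-pi contact: A16 phosphate oxygen over the base-14 plane
planeAtomDistanceSeries(e, 14, "16:OP2")[c("median", "sd")]
#> $median
#> [1] 2.923023
#> $sd
#> [1] 0.05766056

## U13/U18 conformer populations
tracePopulations(e, builtinSchemes()$U13U18)
#> State trace (U13U18), 20 frames
#>   fractions over all frames:
#>         2a         1a unassigned
#>          1          0          0
#>   percent over assigned frames:
#>  2a  1a
#> 100   0

## cation site keyed to U14(O4)
siteOccupancy(e, ionSite("14:O4", aux = c("13:O4", "17:OP2", "18:O4")))
#> Site '14:O4' occupancy: 100.0% of 20 frames
#>   auxiliary shell fractions (over occupied frames):
#>        inner outer none
#> 13:O4      0     0    1
#> 17:OP2     0     1    0
#> 18:O4      0     0    1

## NMR models: coupling and dissociation constant from synthetic data
fitCTJCoupling(genCTSeries(J = 2.7, noise = 0.02, seed = 7), seed = 7)
#> Constant-time J fit: J = 2.672 Hz +/- 0.021 Hz (bootstrap); rss = 0.00829 on 14 points

fitBindingIsotherm(genTitration("single-site", KD = 3, noise = 0.01, seed = 7))
#> Isotherm fit (single-site): KD = 3.302 mM, ddMax = 0.3005 ppm, rss = 0.0008241 on 8 points
```

The median plane distance is the generator's declared anion-π condition
(2.93 Å) recovered through the least-squares plane fit; the 100% `2a`
population is the two-direct-bond cWW arrangement detected under the
strict criteria; the J and K_D fits recover their generating parameters
(2.7 Hz, 3 mM) from noisy synthetic observables.

Config-driven end-to-end runs (`runAnalysis("config.yaml")`) emit a
report bundle — JSON summary with all thresholds and seeds in the
metadata, per-section CSVs, and a log — and reproduce byte-identical JSON
for identical configs. A thin command-line wrapper lives at
`inst/scripts/uturn-run.R`.

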