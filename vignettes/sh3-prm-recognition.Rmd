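---
title: "Methods: modelling the high-affinity SH3/proline-rich-motif recognition mode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the high-affinity SH3/proline-rich-motif recognition mode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sh3ags)
```

## The scientific problem

SH3 domains bind proline-rich motifs (PRMs) built around a PxxP core.
Canonical class-II PRMs follow `xPxxPx+` — written in register notation
`x(-1) P(0) x(1) x(2) P(3) x(4) +(5)`, where the two prolines anchor the
hydrophobic groove and the positive residue at position 5 docks on an
acidic patch — and bind with typical dissociation constants of 20–200 µM.
A small group of SH3 domains from the ASAP, GRAF and SKAP families
("AGS"-type domains) replaces the groove-center aromatic of canonical
domains with a cysteine and carries an aspartate/glutamate three residues
downstream (the `Cxx(D/E)` RT-loop signature). The resulting acidic pocket
grips a lysine or arginine *inside* the PxxP core, at register position 2,
so that motifs of the form `xPx(K/R)Px(K/R)` ("Px+P" motifs) bind these
domains roughly an order of magnitude more tightly (≈0.3–10 µM).

This package implements that recognition mode as a testable pipeline:
position-registered motif scanning, alignment-based RT-loop
classification, a rule table reproducing the mutational evidence, a
proteome screen with a localization/PPII/conservation filter cascade plus
enrichment statistics, interface-geometry analysis of complex
coordinates, a one-site isothermal titration calorimetry (ITC) model, and
generators that produce every input with known ground truth.

## Motif scanning and the position register

The scanners report *every* 7-residue window matching their pattern
(overlapping and nested windows included) and attach the register map
(positions −2…5 to sequence indices; −2 is populated when a preceding
residue exists). Decisions worth recording:

* "+" means K or R only. Histidine is never counted as positive, matching
  the strict `(K/R)` of the screening pattern.
* The hydrophobic annotation set for position 2 is {A, V, L, I, M, F, W,
  P}. It is annotation only and never affects match/no-match.
* Windows containing `X` are voided individually; the rest of the scan
  proceeds.
* Class-I motifs (`+xxPxxP`, the mirror orientation) carry no published
  register subscripts, so the package anchors their register on the two
  prolines and reports the positive residue at a position named
  "minus_3". This is a package convention, not a literature claim.
* Biological numbering is handled by an explicit per-sequence offset
  (`biological = index + offset`), so a fragment numbered from residue
  828 places its position-2 lysine at 832 exactly.

The implementation is regex-based (zero-width lookahead so overlaps are
kept); the test suite re-derives every match set with an explicit
character-by-character window oracle on a thousand seeded random
sequences, which keeps the two routes independent.

## RT-loop classification

Diagnostic positions are located by end-gap-free global alignment
(BLOSUM62, gap open 11 / extend 1 — ordinary protein defaults) of the
query against an annotated reference. End-gap freedom makes the call
invariant to flanking tags and boundary choices, which the tests enforce.
A query is AGS only when the mapped groove-center residue is cysteine,
the mapped acidic residue is D or E (not H), and the two sites are
exactly three apart *on the query side* — an insertion inside the motif
disqualifies, because the signature is a fixed-spacing sequence.
Alignments scoring under 25% of the reference self-score are declared
unalignable and return UNKNOWN: diagnostic mapping must fail loudly on
non-SH3 input rather than classify noise.

The bundled reference is a constructed SH3-like model sequence (it is
synthetic; the database sequence of the ASAP1 domain is deliberately not
shipped), numbered 1087–1147 so the diagnostic sites fall at biological
residues 1096/1099, with four groove aromatic positions annotated. All
classifier tests derive their cases from this fixture by mutation, which
is exactly how the classification logic is exercised in practice.

## The affinity rule table

Affinity is categorical — HIGH (0.3–10 µM band), TYPICAL (20–200 µM),
NONE — because the underlying evidence is class-level: measured mutants
move between these regimes rather than along a continuum. The HIGH band's
upper bound of 10 µM covers the measured ≈0.3–8 µM range with margin and
is documented as a convention. Rules apply in a fixed order (charge
reversals first, then the pairing table, then anchor-proline downgrades),
and every prediction carries the rules it fired as human-readable
rationale. Two cells are genuinely untested by the evidence and are
labelled as such rather than silently defaulted: canonical SH3 ×
position-2-acidic motifs (kept TYPICAL) and class-I motifs (kept TYPICAL
with either domain type). A missing anchor proline downgrades one level
per missing anchor; the P3-substituted case lands in TYPICAL, matching
the ≈24 µM affinity reported for that motif variant.

## Interface geometry

Contacts are heavy-atom pairs across chains within 4.5 Å; salt bridges
are Lys NZ / Arg NE/NH1/NH2 nitrogens within 4.0 Å of Asp OD1/OD2 / Glu
OE1/OE2 oxygens (His excluded as a donor — protonation unknown). Both
cutoffs are common literature conventions and configurable. Backbone
φ/ψ follow the IUPAC sign convention (cross-checked in the tests against
an independent torsion implementation); a residue is PPII when (φ, ψ) is
within 30° angular distance of (−75°, +145°), the standard PPII region —
the source evidence names the conformation but gives no numeric
criterion, so the tolerance is explicit and configurable. The
structure-derived register ranks peptide prolines by their contact counts
to the annotated groove aromatics and cross-checks the sequence-derived
register; on disagreement the sequence register wins with a warning.
Alternate locations resolve to highest occupancy with first-seen
tie-breaks; hydrogens are ignored.

## Screen and enrichment

Candidates are proteins with at least one Px+P match. Three optional
filters follow: localization (labels intersecting {cytoplasm, cytosol} by
default), PPII (register positions −1…5 all PPII-true in the supplied
per-residue dihedrals — the package consumes precomputed dihedrals or
coordinates; running a structure predictor is out of scope), and
conservation (the 7-residue register window identical in ≥ 0.8 of the
protein's orthologs at aligned positions; the source states only "high
conservation", so both the metric and threshold are package choices).
Missing data fails the affected filter (fail-closed) with a configurable
fail-open switch, since the source is silent on the policy. Every
candidate retains per-stage flags, and the audit identity (eliminations
per stage + survivors = motif-positive proteins) is asserted in the
tests.

Enrichment uses the exact hypergeometric upper tail against the screened
universe (not an external annotation database — a documented divergence
from web-service internals), BH q-values reported alongside, and the
three published pass thresholds verbatim: p < 0.01, count ≥ 3, enrichment
factor > 1.5.

## ITC model

The forward model uses perfusion dilution: each injection of volume *v*
displaces *v* from the fixed-volume cell, so after injection *i* the
totals are `M_t = M0·f^i` and `X_t = X0·(1 − f^i)` with `f = 1 − v/V0`.
Bound complex comes from the closed-form one-site equilibrium (the
physical quadratic root, never exceeding `min(X_t, N·M_t)`); the heat of
injection *i* is `ΔH·V0·(B_i − f·B_{i−1})`, normalized per mole of
injectant, with a fitted constant offset absorbing dilution heats. A
consequence worth noting: material swept out of the cell before binding
evolves no heat, so the summed injection heats equal ΔH times the total
complex *formed*, which is a few percent less than `N·M0·V0·ΔH`; the
tight-binding test asserts the exact mole-bookkeeping identity rather
than the idealized one. Protocol defaults are 200 µL cell, 400 µM
syringe, 40 µM cell concentration, 19 × 3 µL injections (the cell volume
is not stated in the source and defaults to the instrument-typical
200 µL, configurable).

Fitting is Levenberg–Marquardt on the per-injection heats with Kd
positivity enforced by log-parameterization; standard errors come from
the Jacobian at the optimum (delta method for Kd). Initialization is
N = 1, ΔH = first-injection heat, Kd = M0/10, with an optional Kd-grid
multistart. When the fitted c-value `N·M0/Kd` drops below 1 the isotherm
is too shallow to identify the stoichiometry, so the fit is repeated with
N held at its nominal value and flagged `low_c`/`n_fixed` — the standard
low-c practice. With this in place, median recovered Kd over 20 seeded
replicates at 1% relative heat noise stays within 10% of truth across
0.3–100 µM, which the tests assert.

## Synthetic data and what passing tests mean

The generators plant every feature the pipeline can detect and record it:
motifs at known registers (proteins are redrawn until their scanned match
set equals the plantings, so truth tables are exact), nested screen
subsets (defaults 50 proteins / 12 motif / 8 cytoplasmic / 6 PPII / 5
conserved, so the full cascade's expected survivor count is 5), ortholog
sets whose motif windows are either untouched or forcibly mutated in
>20% of orthologs, ideal-geometry peptide backbones built by internal
coordinates (NeRF) at exact (φ, ψ) with pseudo-pocket marker atoms at
planted distances (3.5 Å aromatic markers by the anchor-proline CBs,
3.2 Å acidic oxygens by the position-2/5 basic tips), and titration
curves with attached generating parameters. A single global seed fans out
to named per-generator streams, so subsets regenerate independently.

Enrichment calibration runs at a 300-protein universe with a 60-protein
target set, base annotation rate 0.1 and planted odds 5 — a scale chosen
once so that the published thresholds have high power (the planted term
passes in ≥95% of replicates) while a null term's pass rate stays within
the nominal 2%; these rates are simulated in the acceptance tests, not
assumed.

What passing does *not* show: background sequences are i.i.d. (real
proteomes have compositional and repeat structure — a Swiss-Prot-like
composition option exists to stress false positives), the pseudo-pocket
is an atom cloud rather than a folded domain, ortholog evolution is
i.i.d. substitution without indels, and ITC noise is Gaussian and
uncorrelated. Validation against deposited complex structures is an
optional network-dependent exercise and deliberately outside the test
suite.

## Problem sizes

The shipped tests and scripts use desk-scale sizes chosen as the
package's own defaults: 1000 random 200-residue sequences for
scanner–oracle equivalence, a 50-protein planted screen, 100-replicate
enrichment calibration, 20 seeded geometry fixtures, and 20 ITC
replicates per affinity regime.
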