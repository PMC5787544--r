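---
title: "Selective detection of 3'-isomiRs by polyadenylation RT-qPCR: models and methods"
author: "isomiRsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective detection of 3'-isomiRs by polyadenylation RT-qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRsel)
```

## The problem

Most miRNA families exist as a ladder of 3'-end length variants
(3'-isomiRs) sharing one canonical 5' end. In polyadenylation RT-qPCR every
template receives an enzymatic poly(A) tail, is reverse transcribed with a
universal oligo-dT-anchored primer, and is then amplified with one
miRNA-specific forward primer plus a universal reverse primer. Because the
forward primer is the only isoform-specific reagent, which isoforms it
cross-amplifies decides what the assay actually measures. Two empirical
facts shape the design space:

* a forward primer matching a short isoform has a perfect binding site on
  every longer isoform of the family, so it reports the whole family;
* a forward primer matching a long isoform leaves its 3'-terminal bases
  unpaired on shorter isoforms, and a 5'→3' polymerase cannot extend an
  unpaired 3' terminus — two or more missing bases effectively abolish
  amplification.

Appending four adenosines to the 3' end of a short-isoform primer (the
"4A" modification) exploits the poly(A) step: on cDNA from isoforms of the
targeted length or shorter, the A-run pairs with the poly(A)-derived
region and amplification proceeds; on longer isoforms it collides with the
genuine 3' bases and amplification is suppressed. This package implements
the primer design rules, a sequence-level annealing model that predicts the
resulting cross-amplification pattern, the Cq arithmetic used to express
results, a read-level isomiR counter for sequencing-based validation, and a
simulator that ties all of it together.

## The annealing model

The model works on the *sense-extended template*: the template's sense DNA
followed by a modelled A-run (default 10 positions). Primer-vs-cDNA
hybridisation is mathematically identical to primer-vs-sense-extended-
template identity, which avoids antisense bookkeeping. The primer is
anchored with its 5' end at template position 1 — every assay primer starts
at the canonical 5' end, so no offset search is needed.

From the per-position match vector three summaries are taken:

* `terminal_mismatch_run` — consecutive mismatches ending at the primer's
  3' terminus;
* `window_mismatches` — mismatches among the last `w = 4` primer bases;
* `internal_fraction` — mismatches 5' of that window, divided by primer
  length.

The classification cascade is:

1. terminal run ≥ 2 → **blocked**;
2. window mismatches ≥ 3 → **blocked**;
3. terminal run = 1 or window mismatches = 2 → **reduced**;
4. internal fraction ≥ 0.09 → **reduced**;
5. otherwise **amplified**.

Rule 1's threshold of two missing bases is the observed cliff for
unmodified primers on shortened isoforms; a single terminal mismatch only
partially impairs extension. Rule 2 captures tailed primers facing ≥ 3
non-A bases. Rule 3 covers the intermediate +2 nt case and single terminal
mismatches. Rule 4's threshold 0.09 is a calibrated constant: two central
mismatches make a 22 nt primer discriminate (2/22 ≈ 0.091 ≥ 0.09) while the
same two mismatches in a 27 nt primer do not (2/27 ≈ 0.074) — short primers
are more mismatch-sensitive, consistent with their lower melting
temperature. Classes map to relative efficiencies 1.0 / 0.1 / 0.0005.
These efficiencies are a modelling choice, not measured constants: the
assay literature reports only qualitative classes and decrease ranges
(60–90%), so the package's own tests assert class identities and
orderings, never efficiency values. All thresholds and efficiencies are
arguments of `efficiency_rules()`.

Two emergent behaviours are worth noting because they are properties of the
cascade rather than extra rules. First, tailing a *long* primer weakens its
selectivity: on a shorter isoform the A-tail pairs with the template
poly(A), moving the mismatches inward where only rule 4 sees them, so a
blocked pair becomes merely reduced. This is why the design recommendation
restricts the 4A tail to short targets. Second, an A-rich template context
(e.g. an `AAACCAA` 3' end) lets part of the tail pair, dropping the window
mismatch count from 3-4 to 2 and weakening blocked to reduced — the model
reproduces the observed weaker suppression on such templates without
special-casing.

The modelled tail length is irrelevant beyond covering the primer overhang
(classifications are identical for any `tail_length ≥ a_tail + window`);
the default 10 leaves comfortable margin. Known limitation: empirically,
how strongly a long unmodified primer is blocked on a short isoform also
depends on *which* bases face the poly(A); the model treats all non-A
terminal bases identically.

## Primer design rules

`design_forward_primer()` is exact string assembly: DNA of the targeted
prefix plus an A-tail, named `F<stem>-<length>[-<k>A]`. The shipped tail
default is 4: observed selectivity is comparable for 2-5 appended
adenosines, and 4 was preferred on the expectation of better
discrimination against A-rich 3' contexts. `recommend_design()` encodes
the length rule — tail 4 for targets ≤ 21 nt, no tail from 23 nt up, and
22 nt treated as short with an `AMBIGUOUS_LENGTH_22` warning since tailed
22 nt primers behave like short-target primers but the published
recommendation covers only 19–21 and 23–25 nt.

`a_rich_context()` quantifies the A-rich caveat: the adenosine fraction of
the 4 reference bases immediately 3' of the target prefix (positions past
the reference end are poly(A) and count as A). The warning threshold 0.5
is calibrated so that the known problem case (downstream `CCAA`, fraction
0.5) warns while a pyrimidine-rich context (fraction 0) does not; the
source work gives no numeric definition of "A-rich", so both window and
threshold are explicit arguments. At the full reference length the window
is pure tail (fraction 1) but no warning is raised — there is no longer
isoform left to discriminate.

Melting temperatures use the Wallace rule `2(A+T) + 4(G+C)` by default —
adequate for ranking 20-29 nt primers — with a nearest-neighbour
alternative (unified dinucleotide enthalpies/entropies, 50 mM monovalent
salt correction) for users who want length-comparable estimates.

## Cq arithmetic

`relative_amplification()` implements `100 · 2^(Cq_ref − Cq)`;
`fold_change_ddcq()` implements `2^−ΔΔCq` against a reference gene and a
control condition. Technical replicates are averaged on the Cq (log)
scale, the standard practice; the convention is stated because source
material rarely specifies it. Undetermined wells (no threshold crossing)
are a first-class sentinel: they map to 0% relative amplification and are
flagged below the 0.1% annotation threshold rather than dropped, so matrix
shapes survive. The reference Cq is always an explicit argument — published
figures vary in what they normalise to, so nothing is inferred. Efficiency-
corrected (Pfaffl-type) models and Cq calling from fluorescence curves are
out of scope.

## The isomiR read counter

`classify_reads()` bins aligned small-RNA reads against mature-miRNA loci
by two strand-aware coordinates: the 5' offset of the read start from the
locus's canonical 5' end, and the read length measured from that canonical
5' end. Internal coordinates are 0-based half-open; GFF3 (1-based closed)
is converted on input, BED is native. Decisions the original in-house
tooling left unstated are made explicit and configurable here:

* a read must overlap a same-strand locus by ≥ 75% *of the read's length*
  (so long isomiRs protruding past the annotated locus still count);
* each read is assigned to exactly one locus — the one with the smallest
  absolute 5' offset, ties broken by locus order — so counts are conserved;
* 5'-variant reads are kept as separate offset classes;
  `length_proportions()` restricts to offset 0, matching the
  "length from the canonical 5' end" framing of per-length histograms;
* RPM uses all mapped reads as denominator by default (switchable), and
  `normalize_to_reference()` expresses counts per 100 reads of a reference
  small RNA for targeted sequencing;
* templated and non-templated 3' additions are not distinguished —
  classification is positional only.

## The simulator

`default_profiles()` encodes the stoichiometry that motivates the 4A
design: within a family, isoforms ≥ 23 nt are ten-fold more abundant than
the 20–22 nt ones (abundances 10 vs 1 over lengths `ref−4 … ref`), and the
interferon-stimulated condition scales long isoforms by 0.3 and short ones
by 1.5. The ten-fold gap is anchored to the reported order-of-magnitude
difference; the 0.3/1.5 factors are qualitative stand-ins for the observed
depletion/induction trends, not fits to any figure — per-isoform read
numbers are not published as numbers, only the order-of-magnitude statement
is.

`simulate_reads()` places a multinomial draw over isoform lengths at the
locus with offset 0 (or exact largest-remainder expected counts in `exact`
mode). `simulate_cq()` pushes abundances through the annealing model:
`signal(primer) = Σ_isoforms abundance × efficiency`, `Cq = 35 −
log2(signal) + N(0, sd)`. The intercept 35 cycles at unit abundance and
noise sd 0.15 cycles (typical technical-duplicate scatter; none is
published) are `sim_config()` defaults; Cq values beyond 45 cycles become
undetermined. With noise 0 the whole pipeline is closed-form, which is how
the masking effect is tested as a strict inequality: the unmodified
short-target primer's ΔΔCq fold change is dominated by the abundant long
isoforms (0.375, the long-isoform direction), while the 4A primer's (≈1.10)
sits closer in log2 distance to the generating short-isoform factor 1.5.
The residual gap is the reduced-class leakage of the +2 nt isoform — the
model reproduces the reported behaviour of tailed primers whose +2 nt
neighbours are abundant and strongly regulated.

What the simulator deliberately does not emulate: sequencing errors,
adapter remnants, non-templated tailing, RT or tailing efficiency biases,
and 5'-offset heterogeneity. Passing round-trip tests therefore shows the
counter inverts the generator's positional model, not that it is robust to
real library artefacts.

## Problem sizes and determinism

The shipped tests run the full fixture cross (39 primers × 15 templates)
exhaustively against an independently coded rule oracle, brute-force
prefix/deficit sweeps over three families, 200 randomised monotonicity
probes, and counter round trips at 10^5 reads over 20 seeds — a few
seconds in total. Every stochastic path requires an explicit seed and
refuses to run without one; reruns with the same seed are byte-identical,
which the command-line tests assert on the BED output.

## Known limitations

* The efficiency scale (1.0/0.1/0.0005) is ordinal, not quantitative;
  downstream numbers derived from it (e.g. simulated fold changes) carry
  that granularity.
* No thermodynamic duplex model: selectivity that depends on base identity
  beyond match/mismatch (GC content of the terminal window, dangling ends)
  is invisible.
* The counter assigns multi-mapping reads once, to their best locus; no
  fractional assignment.
* Primers with 5' offsets from the canonical end are out of scope, as are
  5'-isomiR linker strategies.
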