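---
title: "Quantifying factor IX gamma-carboxylation and host cell proteins from DIA data: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying factor IX gamma-carboxylation and host cell proteins from DIA data: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glaquant)
```

## The problem

Recombinant coagulation factor IX (rFIX) is active only when the GLA domain
at its N-terminus is γ-carboxylated: each of up to twelve glutamates gains a
second side-chain carboxyl (+43.98983 Da), enabling calcium binding.  In a
CHO fed-batch process the carboxylation machinery saturates, so the secreted
product is a mixture of *carboxyforms* — molecules with 0, 1, 2, … modified
glutamates — and the anion-exchange purification step enriches the most
carboxylated species.  Judging a bioreactor by its purified product is
therefore biased; the informative measurement is the carboxyform
distribution (and the other PTMs, and the host-cell-protein background) *in
the supernatant, day by day*.  DIA/SWATH mass spectrometry supports exactly
that: all precursors in stepped isolation windows are fragmented, and any
peptidoform in an ion library can be quantified afterwards by summing its
transitions at the right retention time.

`glaquant` implements this workflow end to end, and — because the raw study
data live in an external repository and require commercial search engines —
couples it to a synthetic fed-batch generator so that every stage can be
exercised and validated on data with known ground truth.

## Mass calculus

All masses are monoisotopic.  A peptidoform is a sequence plus a
modification string; its neutral mass is

$$ M = \sum_i m_{\text{res}(i)} + m_{H_2O} + \sum_j \Delta_j $$

with $m_{H_2O} = 18.010565$ and each $\Delta_j$ a registry delta (Gla
+43.98983 on E, methyl ester +14.01565, propionamide +71.03711 on C,
oxidation +15.99491 on D, deamidation +0.98402 on N/Q, sulfation +79.95682
on Y, phosphorylation +79.96633 on S/T/Y) or a glycan composition mass
(count-weighted sum over Hex 162.05282, HexNAc 203.07937, Fuc 146.05791,
NeuAc 291.09542, NeuGc 307.09033, Xyl 132.04226).  Precursor m/z is
$(M + z \cdot 1.007276)/z$.  Constants carry ≥5 decimals; observed
instrument values are matched at 0.002–0.01 m/z depending on charge, which
corresponds to the few-ppm accuracy of a QTOF.

Sulfation and phosphorylation of tyrosine differ by only 0.0095 Da and are
kept as distinct registry entries; at the resolution modelled here a
spectrum cannot adjudicate between them, so reports label the site
"sulfation/phosphorylation" where both are plausible.

Fragment ions use standard arithmetic: $b_i = \sum_{1..i} + z \cdot p$,
$y_i = \sum_{n-i+1..n} + m_{H_2O} + z \cdot p$ (with $p$ the proton mass),
with localized modification deltas included in the spanning fragments.
Neutral-loss ladders (−SO₃ for sulfopeptides, −CO₂ for γ-carboxyl) are
generated for fragments spanning the modified site; losing SO₃ restores the
unmodified ladder value, which is how sulfopeptide CID spectra actually
present.  Glycopeptide Y ions strip the glycans and add monosaccharides
back innermost-first — HexNAc, then Hex, then the distal residues — so for
a sialylated core-1 O-glycan Y1 = peptide+HexNAc and Y2 = Y1+Hex.  The
alternative (stripping the core first) is inconsistent with the observed
Y1/Y2 spacing of such glycopeptides and was not adopted.

Digestion is fully specific with a missed-cleavage cap; trypsin's classical
"no cleavage before proline" suppression is on by default and configurable,
since the cited GLA peptides are insensitive to the choice.  Methyl-ester
enumeration counts the free carboxyl inventory as
$\#D + \#E_{\text{free}} + 2\,\#\text{Gla} + [\text{free C-terminus}]$ — a
Gla residue carries *two* esterifiable carboxyls — and caps enumerated
forms at 6 methyls by default, the span a derivatized-GLA ion library
typically covers.

## Windows and conflicts

The default global acquisition scheme is 26 m/z windows with a 1 m/z
overlap starting at 399.5 (35 windows to 1250 m/z); the derivatized-GLA
scheme is non-overlapping 6.2 m/z windows across 400–917.  Exact window
boundaries of the original acquisition software are not recoverable; the
default geometry is the simplest one consistent with the two precursor
pairs known to co-isolate (603.3461²⁺ with 621.309³⁺, and 879.8644²⁺ with
887.8618²⁺), and it is fully configurable.

Two library entries conflict when they share a window and elute within
`rt_tolerance` (default 1.0 min — "similar RT" is not otherwise
quantified).  Conflict groups are formed greedily along the RT axis within
each window so that every group's RT span is at most the tolerance (hence
the pairwise constraint holds), and the result is independent of entry
order.  Conflicting entries are *pooled* and quantified as one merged class
with a combined label (e.g. "+947/+963"); per-member deconvolution is out
of scope.

## Quantification

Per sample and peptidoform class, the top `max_transitions` transitions
(default 6; "all" for the PTM profile) within ±`rt_window`/2 of the library
retention time are summed; a 75 ppm fragment m/z tolerance is applied when
the transition table carries measured fragment m/z.  Peptide values with
FDR > 0.01 are eliminated; protein intensity is the sum of passing peptide
intensities.  Shared peptides are excluded from the rollup by default —
this makes total passing intensity conserved and testable — with an
"assign-to-all" option available.  Protein abundances are normalized to the
trypsin autolysis peptide VATVSLPR (421.7584²⁺), which is present in every
digested sample at the same spiked amount; normalization therefore cancels
per-sample loading factors exactly.

Carboxyform stoichiometry marginalizes methyl and glycan states: intensities
of all variants with the same carboxyl count $k$ are summed and expressed
as a percentage of the family total.  A family with zero total intensity is
reported *undefined*, not 0% — fabricating a stoichiometry from absence
would be wrong.  Where a form does not ionize (fully carboxylated GLA
peptides are undetectable underivatized), percentages are conditional on
the detectable forms; this caveat is surfaced in the output rather than
hidden.

## Statistics

Per-variant comparisons use a one-tailed pooled-variance two-sample t test;
the direction must be declared per comparison.  When both groups are
constant and equal the test is uninformative and p = 0.5 is returned with a
flag.  Time-course screening across many units uses the two-stage linear
step-up procedure: stage 1 runs Benjamini–Hochberg at $q/(1+q)$ to estimate
the number of true nulls $m_0 = m - r_1$, stage 2 runs BH at $q\,m/m_0$.
Stage 2 always runs, so when stage 1 finds nothing the procedure reduces to
plain BH at $q$ — the discovery set always contains the plain BH
discoveries, a property the tests verify by brute force on random
p-vectors.

Protein-level differential abundance is a deliberately transparent
procedure: log2 feature intensities, Tukey median polish over the
feature × run matrix to get run-level summaries, equal-variance t across
runs, BH adjustment across proteins, significance at a configurable alpha
(default 10⁻⁵, following the convention for such screens).  It is *not* a
reimplementation of mixed-model summarization tools, and its validation is
property-based: on simulated panels with 10% of proteins at a 4-fold change
(multiplicative noise σ = 0.2, n = 3), ≥80% of changed proteins fall below
the scaled screening level 10⁻³ on the per-protein test p with ≤5% false
flags, and the raw-p false-positive rate on null panels (200 proteins, 50
seeds) stays within 1.5× nominal.  With n = 3 per group the pooled t has 4
degrees of freedom, so the *BH-adjusted* flag at 10⁻³ is conservative by
construction (the adjusted threshold lies beyond the df-4 tail for any
effect size); the adjusted flag is therefore checked for zero false
discoveries rather than for power.

## The synthetic fed-batch generator

The generator's defaults describe the study conditions being emulated: a
13-day fed batch in two conditions, where condition B secretes ~45% more
product but ends at 0.77 viability (vs 0.93 in A; both hold ~0.98 until
day 7), carboxylates the GLA domain less completely, and releases a larger
intracellular HCP load.  Specifically:

* **Product**: daily secretion follows a logistic ramp; condition A
  plateaus after day 8, B keeps secreting.  Supernatant abundance is the
  cumulative sum (fed-batch, no harvest).
* **HCPs** (panel of 40 by default): secreted HCPs accumulate with culture
  time; intracellular HCPs are released in proportion to the *integrated
  viability loss* (lysis coefficient 10).  The proportionality is an
  assumption — lysis-to-HCP stoichiometry is not otherwise constrained —
  and it is the simplest model with the right monotonicity: zero lysis
  means zero intracellular signal, and the lower-viability condition always
  ends with the larger intracellular load.  About 15% of HCPs are flagged
  calcium binders with elevated purification carry-over (0.30 vs 0.02),
  mirroring the tendency of calcium-binding contaminants to co-purify on
  resins that select for the calcium-binding GLA domain.
* **Carboxyforms**: each carboxylatable glutamate is modified independently
  with a per-day logistic probability (higher and flatter in A, lower and
  declining in B), giving binomial occupancy vectors that always sum to 1.
* **Purification**: carboxyform shares are reweighted by a retention
  probability logistic in $k$; the single-site TTEFWK family has flat
  retention (the terminal GLA-domain site does not drive binding), so its
  profile is unchanged — the behaviour the workflow should detect.
  Product recovery 0.6; HCP carry-over per panel flags.
* **Noise**: per-transition multiplicative log-normal (σ default 0.2), a
  per-sample log-normal loading factor (σ 0.1), censoring below an
  intensity floor, low uniform FDR scores for true entries and FDR > 0.01
  for injected decoys.  Retention times are copied from the library with
  small jitter; no drift model is simulated because quantification uses a
  generous RT window (2 or 6 min) that dwarfs realistic drift.

All randomness flows from one seed; a manifest (scenario hash, library
hash, seed, noise parameters) accompanies every rendered dataset, and the
same configuration is byte-identical on re-run.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: interference between co-eluting analytes beyond
the library (real DIA has chimeric signal), nonlinear detector response and
saturation, retention-time drift and misalignment, correlated noise across
transitions of one precursor, mechanistic CHO metabolism, and search-engine
identification errors other than the uniform decoy model.  The simulator
validates the *estimators* (recovery of known shares and abundances under
censoring, FDR filtering and normalization), not the chromatography.

## Numerical choices and degenerate inputs

Problem sizes used in the validation suite: the full default scenario
(13 days × 2 conditions × 3 replicates plus purified endpoints, 40 HCPs)
for parameter recovery; random sequences up to 60 residues against a
brute-force digestion oracle; 1000 random p-vectors for the two-stage FDR
dominance property; 200-protein null panels over 50 seeds for the type-I
bound.  Carboxyform recovery is asserted within 3 percentage points of
scenario truth at σ = 0.1 with triplicate renders, averaging over
replicates as the study design does.

Degenerate inputs are handled explicitly rather than silently: empty
sequences and unknown residue letters are rejected by name; a library row
with confidence outside [0, 1] is rejected with its line number while the
rest load; an entry whose transitions all fall outside the RT window is
reported at intensity 0 with a flag (distinct from absent); a sample
missing the normalization reference is excluded from normalized output
with a warning; a protein observed in only one group is reported with an
infinite fold change and excluded from testing.

## Limitations

Absolute occupancy would require labeled standards and is out of scope; all
abundances are relative.  Carboxyform identity is by count, not site
combination — site-resolved enumeration exists internally for mass
computation, but quantification cannot distinguish isobaric site variants.
The protein-level differential procedure is a screen, not a calibrated
mixed model.  The window-geometry default is one of several geometries
consistent with the known co-isolation constraints; users with the actual
acquisition method should configure it.
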