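---
title: "Annotating ginsenosides and ranking fermentation markers with ginsannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating ginsenosides and ranking fermentation markers with ginsannot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginsannot)
```

## The problem

Ginseng (*Panax ginseng*) owes most of its pharmacology to ginsenosides:
triterpene saponins built from one of three aglycone skeletons —
protopanaxadiol (PPD, C30H52O3), protopanaxatriol (PPT, C30H52O4) or
oleanolic acid (OLE, C30H48O3) — decorated with sugar residues. During
fermentation (for instance when ginseng is brewed into a rice wine rather
than merely soaked in one), microbial glycosidases strip those sugars,
converting abundant precursors such as Rb1 into rare, more bioavailable
ginsenosides such as compound K (CK), Rg3 or Rh2. Monitoring that
conversion from negative-mode high-resolution LC-MS/MS data requires
three things this package implements end to end:

1. **annotation** of tandem spectra by their glycosyl neutral-loss
   ladders and diagnostic aglycone ions;
2. **transformation-pathway graphs** that organise annotated compounds
   by single deglycosylation steps;
3. **marker statistics** — OPLS-DA with VIP scores, permutation
   validation and univariate testing — to rank which compounds separate
   two processing technologies, plus network utilities (hub centralities,
   hypergeometric enrichment) for downstream target analysis.

A seeded simulator generates spectra, feature tables and interaction
graphs with known ground truth, standing in for raw instrument data.

## Mass arithmetic

All m/z values derive from a vendored table of IUPAC monoisotopic atomic
masses (C = 12 exactly, H = 1.0078250319, O = 15.9949146221, N, S), so
results are bit-stable and independent of any runtime chemistry
dependency. Two negative-mode adducts are supported, with the electron
mass included in the deltas (anion convention):

* `[M-H]-`: −1.007276 Da,
* `[M+HCOO]-` (formate, from formic-acid mobile phases): +44.998203 Da.

The identification bound is the conventional |ppm| < 10 at MS1
(`ppm_deviation()`, `within_ppm()`); MS2 fragments are matched in
Daltons, 0.01 Da by default with a documented 0.05 Da loose mode (see
below). Isotope envelopes, positive-mode adducts and multiply charged
species are out of scope.

## The knowledgebase

`load_library()` ships 33 records: the 21 compounds of the curated
marker table — with retention time, measured precursor m/z, printed
MS/MS fragments and PPD/PPT classification — plus aglycones and
compounds named in profiling narratives (Ro, Re, Rg1, Rc, malonyl-Rb1,
…) whose compositions are derived from standard ginsenoside chemistry
and flagged `source = "text"`.

Every record must satisfy, element by element,

```
formula = aglycone + sum(residues) − dehydration × H2O
```

The residue alphabet is anhydrohexose (C6H10O5, 162.05282 Da),
deoxyhexose (rhamnose, C6H10O4, 146.05791), pentose (arabinose/xylose,
C5H8O4, 132.04226), hexuronic acid (C6H8O6, 176.03209), malonyl
(C3H2O3, 86.00039) and water (18.01056). Deoxyhexose and pentose are
required because Rg2, F4, Rb3, Rc and Ra1 carry them — a hexose-only
alphabet cannot balance their printed formulas. The dehydration count
may be negative (hydration): 20(S)-Rf2 (C42H74O14) is one water heavier
than its glycosylated skeleton. Sugar identity beyond the mass class is
deliberately not modelled — MS cannot distinguish glucose from
galactose — and 20(S)/20(R) stereoisomers are distinct names with
identical masses, separable only by retention time.

## Ladder annotation

`decompose_ladder()` runs a depth-first search over residue-mass
differences. The chain starts at the deprotonated precursor: a formate
precursor is first collapsed by loss of neutral formic acid
(46.00548 Da), and the direct `[M-H]-` reading is tried second. Each
step must land on an *observed* fragment within the MS2 tolerance of
(anchor − one residue mass); the search re-anchors on the observed
value so that instrument error does not accumulate. Residues are tried
hexose-first (then deoxyhexose, pentose, hexuronic acid, malonyl,
water), matching the glucose-dominated chemistry; among complete
solutions, ties break on fewer total residues and then smaller
cumulative mass error. A chain classifies when it ends on a fragment
within tolerance of an aglycone diagnostic ion — `[PPD-H]-` 459.38437,
`[PPT-H]-` 475.37928, `[OLE-H]-` 455.35307 — allowing up to two
dehydrations (or one hydration) of the aglycone so that anhydro
compounds such as Rg5 (Rg3 − H2O) terminate correctly. A ladder is
*complete* when every residue loss down to the aglycone ion was
observed; otherwise the longest partial chain is reported and the
spectrum stays unclassified at ladder level.

`classify()` combines this with precursor matching: candidates within
10 ppm are ranked by retention-time confirmation (±0.5 min window by
default — standards-based matching is how isomers like F2 /
Gypenoside LXXV / Rg3, all C42H72O13, are told apart), then ladder
corroboration, then |ppm|. Confidence is `standard_match` when a
record agrees in mass, RT and (when the ladder classified) class;
`ladder_complete` for de-novo composition calls; `mass_only` when only
the precursor matched. Contradictory precursor and ladder evidence is
flagged (`conflict = TRUE`) with both hypotheses retained. De-novo
annotation reports composition only and never invents a compound name.

**Why a loose MS2 mode exists.** Printed fragment lists in curated
tables of this kind carry transcription- and calibration-level error:
several rows in the packaged table deviate from any composition
consistent with their formula by up to ~0.1 Da, far beyond instrument
accuracy. Replaying such rows uses `tol_ms2 = 0.05`; where even that
fails, classification legitimately falls back on precursor mass plus
retention time. The 0.01 Da strict default is appropriate for real
profile data and for simulated spectra.

## Transformation pathways

`build_graph()` connects records by exact elemental bookkeeping: a
directed edge u → v exists iff v's formula equals u's minus exactly one
transformation unit (glycosyl loss, demalonylation or dehydration) and
both share an aglycone class. Edges are composition-level, not
position-specific — mass data cannot localise a loss to C-3 versus
C-20 — so isomeric children appear as parallel branches (Rb1 − hexose
gives both Rd and Gypenoside XVII), which is exactly how branched
deglycosylation cascades are drawn. Every transformation strictly
reduces mass, so the graph is a DAG; `find_paths()` enumerates simple
paths shortest-first. Kinetics, enzyme assignment and fermentation
conditions are out of scope.

## Chemometrics

`preprocess()` offers log2 transform, mean-centering, and
unit-variance / Pareto / centering-only scaling; unit variance is the
general default (the SIMCA convention). Zero-variance features are
dropped with a warning, and the preprocessing record travels with every
model so held-out data are transformed with training parameters only.

`fit_oplsda()` is a NIPALS orthogonal-signal-correction fit: each
orthogonal component removes the X variation orthogonal to the class
vector, then a single predictive component is extracted — the standard
geometry for a binary contrast, with one orthogonal component by
default. With `n_orthogonal = 0` the model reduces exactly to
one-component PLS-DA, which the test suite verifies against an
independent NIPALS oracle. R2X is the fraction of X sum of squares
captured by all components, R2Y the explained class variance, and Q2
the 7-fold cross-validated predicted class variance with seeded,
class-stratified folds (each training fold re-derives its own centering
and scaling). `permutation_test()` refits under random relabelings
(200 by default) and reports the empirical p-value
`(1 + #{Q2_perm ≥ Q2_obs})/(n + 1)` together with the intercepts of the
R2Y/Q2 versus label-correlation regressions. Hotelling's T² 95% ellipse
flags score outliers but never removes them.

VIP follows `VIP_j = sqrt(p · w_j² / Σ w²)` on the predictive
component, so `mean(VIP²) = 1` identically. Marker selection is the
strict rule VIP > 2 **and** p < 0.05 (Welch's t by default; one-way
ANOVA + Tukey HSD for multi-group designs).

**The marker-screening protocol and the VIP ceiling.** Because squared
VIPs average to one, *m* markers among *p* features can only all exceed
VIP 2 if they jointly carry at least 4m/p of the weight mass; the
equal-share ceiling on the smallest marker VIP is `sqrt(p/m)` — about
2.14 for 21 markers in 96 features. Two consequences shape the
recommended protocol:

* Under unit-variance scaling the weights are feature–class
  correlations, and with 12 samples the ~75 null features contribute an
  expected Σr² of 75/11 ≈ 6.8 to the VIP normaliser, capping marker VIP
  near 1.86 — below the threshold *regardless of effect size*. The
  marker screen therefore uses `log_transform = TRUE, scaling = "ctr"`:
  covariance weights preserve effect magnitude and let strong markers
  approach the ceiling.
* Even then the ceiling leaves little headroom: with 21/96 spiked at a
  4–8 within-group-SD effect, per-marker sampling jitter puts a
  substantial minority of true markers just below 2 (typical recall
  0.6–0.8 in simulation), while false positives are essentially absent.
  A fixed VIP > 2 cut on a wide marker panel is conservative by
  construction; rank-based reading of the VIP spectrum (all spiked
  markers occupy the top ranks) is the robust summary, and the test
  suite asserts exactly that.

`pca()` (SVD, with k-fold Q2), `hca()` (Ward/average/complete linkage
on euclidean or correlation distance) and `percent_change()`
(`100·(mean_case − mean_ref)/mean_ref`; an unbounded alternative
sometimes seen in the literature, with decreases beyond 100%, is not
reproduced) complete the workflow.

## Network ranking and enrichment

`hub_scores()` implements the six Cytohubba-style centralities used for
hub-gene screening: degree; harmonic closeness (sum of inverse
distances, finite on disconnected graphs); betweenness; inverse
eccentricity per connected component (isolated nodes score 0); MCC —
maximal clique centrality, Σ(|C|−1)! over maximal cliques of size ≥ 2
containing the node, so an edge outside any triangle contributes 1 and
tree-like nodes score their degree; and EPC — edge percolated
component, the seeded Monte-Carlo mean of the node's component size
when each edge is independently retained with probability 0.5 (1000
iterations by default; coefficient of variation across seeds < 5% on
PPI-sized graphs). `consensus_top_k()` intersects per-metric top-k
lists (k = 7 by convention), breaking ties by score then label; the
consensus may legitimately hold fewer than k nodes. On sparse random
graphs with a planted clique, MCC recovers the clique essentially
perfectly while eccentricity and betweenness need not — a peripheral
clique is not central by distance — so a full six-metric consensus is a
deliberately stringent hub definition.

`hypergeom_enrich()` is the one-sided hypergeometric tail with
Benjamini–Hochberg adjustment across terms; significance requires raw
p < 0.05 and q < 0.05, both strict. Database retrieval (target
prediction, STRING, expression archives) is out of scope: graphs, gene
sets (GMT) and backgrounds are consumed as user-supplied files, with a
weight threshold available for STRING-style confidence filtering.

## The simulators, and what passing tests do not show

`simulate_spectrum()` emits the full theoretical ladder of a record —
deprotonated ion, one fragment per residue in library order, terminal
(possibly dehydrated) aglycone ion — with ppm-scale precursor jitter
(2 ppm sd default), Da-scale fragment jitter (0.002 Da sd), and
optional fragment dropout that never removes the aglycone ion.
`make_feature_table()` draws per-feature log2 baselines N(14, 2),
within-group noise N(0, 0.25) on the log2 scale, and multiplies the
21 marker features by 2² in the case group — six replicates per group
and 96 features, mirroring a realistic two-technology comparison.
`make_graph()` plants a 5-clique in an Erdős–Rényi G(41, 71) graph.
All generators are pure functions of their seed.

These emulations omit real-data structure on purpose: no retention-time
drift, chromatographic peak shapes or isotope envelopes; feature noise
is independent across features (real LC-MS features co-vary through
batch and total-ion-current effects, which is precisely the variation
OPLS-DA's orthogonal component absorbs); fragment intensities are
uninformative. Tests passing on these simulations therefore validate
the *arithmetic and the algorithms* — mass bookkeeping, ladder logic,
model algebra, centrality math — not instrument-level performance on
real spectra.

## Numerical choices and problem sizes

Defaults: MS1 10 ppm; MS2 0.01 Da (0.05 loose); RT window ±0.5 min;
ladder depth 8; OPLS 1 orthogonal component, 7-fold CV; 200
permutations; VIP > 2, alpha 0.05 (strict); EPC 1000 iterations at
retain 0.5; consensus k = 7. The test suite exercises 50-seed marker
recovery runs, 20-seed graph recovery, 100 brute-force-checked random
graphs of ≤ 10 nodes, and whole-library (33 record) spectrum round
trips; everything runs in well under a minute per file on one CPU.
Known limitations: compositions, not structures, are annotated; the
VIP-threshold ceiling discussed above; consensus hub sets depend on the
metric family chosen.
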