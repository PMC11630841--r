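---
title: "Family-template rescue of low-confidence structure models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-template rescue: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldrescue)
```

## The procedure

`foldrescue` automates a family-level rescue loop for low-confidence
protein structure predictions. Its premise: within a protein family whose
per-domain mean plDDT distribution is bimodal, the confidently modelled
members can serve as structural templates for re-predicting the poorly
modelled ones. The pipeline has five stages — family profiling, family
ranking, cohort selection, template re-prediction, and statistical
reporting — each exposed as plain functions and orchestrated by
`run_rescue_pipeline()`.

The prediction step itself is deliberately a *contract*
(`predict_structure()` on a backend object): given a request (sequence,
mode, templates) it must return a model with per-residue plDDT. Three
modes exist: `no_template_msa` (the baseline), `template_msa`, and
`template_single` (MSA disabled, so only the query sequence and the
templates inform the model). The package ships a mock backend for testing
and a command adapter that exchanges FASTA and Cα-trace PDB files with an
external predictor. Running the actual neural network, MSA construction,
and downstream stereochemical validation are explicitly out of scope.

## Family profiling

Member domain plDDTs (the arithmetic mean of per-residue plDDT over the
1-based inclusive domain span) are binned into 100 equal-width bins on
[0, 100] and the counts divided by the maximum count, so the tallest bin
reads 1. Normalizing by the maximum — rather than to unit area — is what
makes a *fractional* peak-height threshold meaningful, and peak heights
are therefore relative quantities.

Peak detection scans for local maxima that are strictly greater than
their nearest unequal neighbour on each side. Numerical choices the
procedure needs but no convention fixes:

* **Plateaus** (runs of equal height with lower ground on both sides)
  yield one peak at the midpoint bin, the left bin when the run has even
  width. Plateaus touching either histogram edge have no lower neighbour
  there and are not peaks.
* **Height filter**: candidates below `min_height` (default 0.03 of the
  tallest bin) are discarded.
* **Distance filter**: candidates are visited in order of descending
  height (ties: lower bin first) and discarded when within `min_distance`
  bins (default 19, exclusive) of an already-accepted peak — the greedy
  highest-first rule used by the common peak finders. Both filters are
  tested against a brute-force enumerate-then-filter oracle.

Peaks are classified by their bin-centre plDDT: low < 50, medium 50–<70,
high ≥ 70. (Bin centres and edges differ by at most half a plDDT unit,
below any scientific resolution here.) A family is a rescue candidate
when it has at least `min_members` (default 100) members, one high peak,
and one medium or low peak.

**Ranking.** "Most balanced" families are preferred, and balance is not a
standardized quantity; this package defines the balance score as
`|n_below70 − n_at_or_above70| / n_total` over member domain plDDTs,
sorted ascending with ties broken by larger family then lexicographic id.
This definition is the package's own and is deliberately simple and
auditable.

## Cohort selection

From each selected family up to 30 proteins are drawn, 10 per stratum:
low (< 70), medium (70–<90), high (≥ 90). Two threshold systems coexist
on purpose: the 50/70 boundaries describe where a family's histogram
*peaks* sit, while the 70/90 boundaries stratify which *members* to
remodel — the low stratum is the rescue arm, the high stratum a positive
control whose templates can coincide with the protein being remodelled.
The boundary value 90 is assigned to the high stratum so the strata are
disjoint and exhaustive. Complete proteins are drawn before fragment
entries (database entries missing regions outside the domain of
interest); within a priority class the draw is uniform under an explicit
seed. A deficit in one stratum is never transferred to another — simpler,
and it keeps the per-stratum counts interpretable.

## Alignment and template identity

Percent identity to the closest template drives both the mock backend's
response and the reported correlations. Alignment is global
Needleman–Wunsch with affine (Gotoh) gap costs under BLOSUM62, end gaps
penalized, implemented on `Biostrings::pairwiseAlignment` and verified
against an exhaustive alignment-space oracle on short sequences. Choices
the field leaves open:

* **Gap costs** default to open −11 / extend −1 (the standard BLOSUM62
  pairing; the first gapped residue costs 11, each further one 1). They
  are configurable, and absolute identity values shift by a few percent
  under other choices.
* **Identity denominator** is the full alignment column count, gaps
  included — the most conservative of the common conventions, and
  monotone in the number of matches.
* **`X`** (nonstandard residues) scores 0 against everything, making it
  alignment-neutral rather than a penalty.
* Ties in the closest-template search break by higher alignment score,
  then lexicographic template id, making the selection deterministic.

## Rescue and best pick

The template bank of a family holds every baseline model with mean
plDDT ≥ 70 (boundary included), best first; at most 4 templates (a
common predictor limit, configurable) are passed per request. A
protein's own first-round model is *not* excluded from its template set
by default — that coincidence is exactly the design of the high-stratum
positive control — but `exclude_self = TRUE` is available.

Per protein, the best pick is the template-mode model with the higher
mean plDDT, ties resolved toward the MSA mode as the lower-variance
choice. "Rescued" means baseline mean plDDT < 70 and best pick ≥ 70; the
threshold comparison is inclusive, consistent with the ≥ 70 confidence
convention used for the bank. Proteins whose baseline is already ≥ 70
are tracked as controls and never counted as rescued. If the backend
fails in one mode, that field is recorded as missing, the best pick
falls back to the surviving mode, and the rescued flag is computed only
when determinable.

## The synthetic generator and mock backend

The generator exists so that every stage — including failure modes — is
exercisable without GPUs or downloads. A `family_spec` draws each
member's domain mean plDDT from a two-component truncated-Gaussian
mixture on [0, 100]; per-residue profiles add smooth noise recentred so
the domain mean equals the drawn value exactly (which is what makes
parameter-recovery tests sharp), with lower-confidence tapered termini
outside the domain; sequences are the family consensus mutated at a
per-member rate tied to the mixture component, so low-confidence members
are also the diverged ones; coordinates are an idealized helix —
geometry is a placeholder, and the pipeline treats confidence as fully
decoupled from coordinates.

Parameter choices and why:

* **Mixture means (40, 85), sds (2, 2)** by default. The sds were chosen
  by simulating the package's own parameter-recovery requirement: peak
  localization works on raw multinomial counts, and at 200 members per
  family the histogram argmax localizes a mode to ±2 bins reliably only
  when the mode is sharp (simulated per-trial recovery 0.995 at sd 2,
  dropping to ~0.4 by sd 8). Real AFDB family histograms, built from
  thousands of members, are smoother; sharp synthetic modes emulate that
  regime at desk scale rather than any claim about real plDDT spread.
* **The default pipeline batch** (`default_family_specs()`) instead uses
  means (55, 88) with sds (2, 3): the weak mode sits in the medium class
  near the confidence threshold so that rescue is actually reachable,
  and the confident mode straddles 90 so all three cohort strata are
  populated. Mixture weights spread over 0.35–0.65 so families differ in
  balance.
* **Mock response**: re-predicting with templates changes the mean plDDT
  by `gain × (identity − floor)/(100 − floor) + noise`, with
  `gain = 25`, `floor = 30`. In single-sequence mode the line applies
  everywhere — templates more diverged than 30% identity actively hurt.
  In MSA mode the MSA dominates and templates are partially ignored: the
  gain is attenuated (`msa_attenuation = 0.35`) and floored at zero below
  30% identity, with smaller noise (`sd_msa = 5` vs `sd_single = 8`).
  The attenuation-plus-noise ratios were set from the qualitative
  pattern the mock must emulate — single-sequence mode higher-gain,
  higher-risk, and more identity-driven than MSA mode — so that the
  identity–improvement correlation is genuinely stronger in
  single-sequence mode at the pipeline's sample sizes. The response
  model is a test harness, not a scientific claim about any predictor.
* Noise draws are keyed by (seed, protein, mode), so a run is a pure
  function of its configuration and seed; reports reproduce byte for
  byte.

What the generator does **not** emulate: realistic geometry, indel
evolution (sequences stay equal-length, so alignment identity closely
tracks the planted mutation fraction), MSA depth effects, and any
residue-level structure in the plDDT response. Passing tests therefore
demonstrate the pipeline's logic, determinism and statistics, not
predictor behaviour on real proteins.

## Statistics

Paired one-sided Wilcoxon signed-rank tests compare each template mode
and the best pick against baseline, and single-sequence against MSA
mode, over the low-baseline subset. Zero differences are dropped (the
common default of the reference routines) and ties receive midranks. The
null distribution is exact up to n = 25 — computed by dynamic programming
over doubled midranks, so exactness survives ties — and a normal
approximation with continuity and tie correction beyond; the two
branches agree within 0.005 at the crossover in testing. All paired
differences equal to zero is reported from `summarize_rescue()` as p = 1
with a `degenerate` flag (identical pairs are no evidence for a
one-sided increase), while calling `paired_wilcoxon_one_sided()`
directly on such data is an error. Pearson correlations (identity vs
plDDT change per mode) use the exact t-transform p-value; raw p-values
are reported without multiple-testing correction.

Plot-level deltas use whole-protein mean plDDT — the post-selection
metric — with domain-level values carried as extra columns.

## Problem sizes

The shipped configuration runs 10 families of 120 members (cohort ≈ 300,
~100 low-baseline proteins) in a few seconds on one core; the test suite
repeats the full pipeline across 20 seeds and checks the peak detector,
aligner and statistics against brute-force oracles (500 histograms, 200
short alignment pairs, exhaustive sign enumeration). These sizes were
chosen so the whole distribution is testable interactively while keeping
every stratum and statistic away from degenerate sample sizes.

## Known limitations

* Only single-chain, single-domain-annotation models; multi-chain input
  is an explicit error rather than a silent chain pick.
* The mmCIF writer/reader covers the minimal `atom_site` dialect the
  pipeline itself produces, not arbitrary PDBx files.
* The balance score, identity denominator and gap defaults are package
  definitions where the field has no single convention; all are
  configurable and documented above.
* Statistical reporting assumes records are paired by protein and
  complete; partially failed backends produce missing fields that are
  dropped pairwise.
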