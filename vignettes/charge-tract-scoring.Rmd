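---
title: "Scoring charged tracts in disordered regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring charged tracts in disordered regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abtscore)
```

## The problem and the model

Electrostatic attraction between contiguous tracts of oppositely charged
residues — acidic (D/E) and basic (K/R) blocks inside intrinsically
disordered regions (IDRs) — is one of the interaction modes that drive
protein phase separation into biomolecular condensates (complex
coacervation). The mere presence of charged residues is not sufficient:
scrambling the charges of a blocky IDR so that they alternate destroys the
interaction. This package quantifies that architecture per protein.

The pipeline has three stages.

**1. IDR segmentation.** A per-residue disorder propensity track (IUPRED
long-format output, or any per-residue score in [0, 1]) is smoothed with a
centered 7-residue rolling mean, and maximal runs with smoothed propensity
strictly greater than 0.45 are taken as candidate IDRs. Runs separated by
at most 7 residues are merged — the merged IDR keeps the intervening
low-disorder residues in its span and sequence — and IDRs shorter than 30
residues are discarded. Under these defaults a gap of 8 predicted-structured
residues is exactly what interrupts an IDR.

**2. Charged tracts within each IDR.** Within each retained IDR (and never
reading residues outside it), the net charge per residue (NCPR) is the mean
formal charge (+1 for K/R, −1 for D/E, 0 otherwise, histidine neutral) over
a centered 5-residue window. A charged tract is a maximal run of
sign-constant, nonzero NCPR values; its area is the number of residues
times the mean |NCPR|, i.e. |sum of NCPR| over the tract. Tract areas
strictly greater than 1 are summed; smaller tracts are considered too weak
to matter.

**3. Charge-segregation weighting.** The filtered area sum is multiplied by
$(0.6 + \kappa)^2$, where $\kappa \in [0, 1]$ is the Das–Pappu
charge-patterning parameter of the IDR sequence: for blob sizes $g = 5, 6$,
$\delta_g$ is the mean over all length-$g$ windows of
$(\sigma_{\text{win}} - \sigma_{\text{seq}})^2$ with
$\sigma = (f_+ - f_-)^2/(f_+ + f_-)$ (windows without charges contribute
$\sigma = 0$), and $\kappa = \tfrac12 \sum_g \delta_g / \delta_g^{\max}$.
Well-mixed charge patterns ("DKDKDK…") give $\kappa \approx 0$ and a
multiplier near 0.36; fully segregated diblocks give $\kappa = 1$ and
multiplier 2.56.

The per-protein **ABTscore** is the sum of the per-IDR scores, and the
**ABTdensity** divides the ABTscore by the total number of retained
disordered residues, so long and short proteins are comparable. The density
is bounded by 2.56, because each IDR's area sum cannot exceed its length.
Proteomes are ranked by ABTdensity and cut into four percentile groups
(top 5%, to 15%, to 30%, remainder, with floor arithmetic and stable
input-order tie-breaking).

## The delta-max normalization

$\delta_g^{\max}$ is the largest $\delta_g$ attainable by any permutation
of the sequence's composition. The common constructive recipe — try block
arrangements of the two charge species with the neutrals distributed around
them — does **not** always attain the maximum: for a composition of 2
positives, 4 negatives and no neutrals, the arrangement `+----+` beats
every contiguous-block arrangement, and compositions with neutrals show
analogous end-split optima. Exhaustive enumeration is only feasible for
short sequences.

We therefore compute $\delta_g^{\max}$ **exactly** with a dynamic program:
residues are placed left to right, a window's contribution is fixed once
its last residue is placed, and the DP state is the exact tuple of the last
$g-1$ placed residues (at most $3^{g-1}$ states) together with the number
of + and − residues used. The arrangement attaining the maximum is never
needed, only its value. The state space grows with the product of the
charge counts, so for compositions whose DP would exceed an operation
budget (`kappa_max_ops`, default 2e8 — roughly an IDR of several hundred
residues with dozens of charges per sign) the package falls back to the
maximum over a constructive family (all 3-gap block placements plus
one-species end-splits, and the observed sequence itself, which guarantees
$\kappa \le 1$). The regime switch is transparent and deterministic; on
sequences within the exact regime the test suite verifies the DP against
exhaustive permutation enumeration, and an independently written DP serves
as a cross-check on random 40-mers.

Blob terms are skipped when the IDR is shorter than the blob or when that
blob's $\delta^{\max}$ is 0 (no charged residues, or charges of one sign
only). If no term remains, $\kappa$ is undefined; an IDR with undefined
$\kappa$ but nonzero filtered area (e.g. a pure poly-D stretch) is scored
with the minimum multiplier 0.36 and a warning, never dropped.

## Numerical choices

* **Windows shrink at boundaries.** Both the 7-residue disorder smoothing
  and the 5-residue NCPR window are centered and shrink to the available
  residues at track/IDR ends, keeping output length equal to input length.
  NCPR windows never read outside the IDR, so a tract can touch the IDR
  edge.
* **Strict thresholds.** Disorder propensity exactly 0.45 does not qualify;
  an IDR of exactly 30 residues is retained; a tract area of exactly 1 does
  not contribute.
* **Area-threshold tolerance.** NCPR values are small rationals, so tract
  areas frequently land exactly on the threshold (a lone +0.2 × 5 window
  run has area exactly 1). The strict comparison uses a 1e-9 tolerance so
  that float summation order cannot flip an exact-boundary tract into the
  sum.
* **Deterministic accumulation.** All sums run in input order; rescoring
  identical input is bitwise reproducible, and all file writers emit
  byte-identical output on reruns.
* **Ties at group boundaries** are resolved by stable input order; group
  sizes use `floor(cut * N)` on the ranked count.

## Open design points and how they were resolved

* The minimum-length boundary was set to *retain* IDRs of exactly 30
  residues ("shorter than 30 are excluded" wins over a ">30" reading);
  users scoring against other implementations should check this boundary.
* ABTdensity normalizes by the **total** retained disordered residue count
  of the protein (one density per protein). The alternative per-region
  reading is exposed as `density_denominator = "per_region"` (mean of
  per-IDR score/length ratios); both stay within [0, 2.56].
* Percentile-group prose of the form "≤5% and >15%" is interpreted as the
  percentile-rank intervals (5%, 15%] and (15%, 30%] — the only reading
  consistent with "top 5%" and "the remainder".
* Kappa blob conventions (sizes 5 and 6, sliding windows fully contained,
  zero-charge windows contribute zero) follow the established reference
  implementation of the Das–Pappu parameter.

## What the synthetic generator emulates

`make_sequence()` builds archetypes with controlled charge architecture:
`diblock` (G₁₀D₁₅K₁₅G₁₀ by default — a maximally segregated 30-charge core
with neutral flanks), `alternating` (strict DK alternation, the classic
scramble control), `uncharged` (pure glycine), `scrambled` (a seeded
uniform permutation of the diblock's letters), and `npm1_multiblock`
(alternating acidic/basic blocks with neutral spacers, mimicking
multi-tract nucleolar IDRs). `make_disorder_track()` paints designed IDR
spans at 0.9 against a 0.1 background (optional seeded Gaussian noise, off
by default so fixture assertions can be exact), and
`make_synthetic_proteome()` writes a complete FASTA + track-directory +
manifest input set.

These fixtures establish the method's defining order: diblock architectures
outscore every scramble of the same composition, and alternating or
uncharged architectures score exactly zero. They do **not** emulate real
proteome statistics — realistic disorder tracks, composition biases, or
length distributions — so passing tests demonstrate the algorithm's
internal correctness and its qualitative charge-architecture ordering, not
agreement with any published proteome-wide ranking, which additionally
depends on the proteome snapshot and disorder predictor used.

## Problem sizes used by the test suite

The suite verifies: delta-max DP against exhaustive permutations for all
D/K/G compositions up to length 9; kappa against an independent DP oracle
on 50 random 40-mers; segmentation against a naive reimplementation on
1,000 random tracks up to length 200; the scramble property on 1,000
seeded permutations of the 50-residue diblock fixture; bounds and exact
additivity on 200 random proteins up to length 300; and end-to-end
byte-determinism of the synth → score → stratify command-line pipeline on a
60-protein proteome. The acceptance script scores a 100-protein synthetic
proteome and 500 scrambles.

## Known limitations

* Disorder prediction is an input, not part of the package; results depend
  on the predictor and its mode.
* Beyond the exact-DP regime the kappa normalizer is a lower bound from a
  constructive family, so kappa can be slightly overestimated for very
  long, charge-dense IDRs.
* The score flags charge-tract architecture only; pi-contact or
  SLiM-driven condensate proteins score low by design, and a high score is
  evidence of architecture, not proof of phase separation.
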