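---
title: "Quantifying invasion pattern and p-EMT state: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying invasion pattern and p-EMT state: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spoiq)
```

## The measurement problem

Organotypic 3D cultures of HNSCC keratinocytes grow an epithelial sheet
at an air–liquid interface and invade downward into a collagen/Matrigel
gel, either as a cohesive front or as detached tumor islands. Sections
are imaged by immunofluorescence (cytokeratin marking tumor cells, DAPI
marking nuclei, PDPN as a p-EMT marker), and three families of numbers
are read off each image:

* the **invasion index**, the product of total island area (µm²),
  island count, and invasion depth (µm) — a bulk measure of how much
  tumor has detached and how far it has gone;
* the **worst pattern of invasion (WPOI)**, an ordinal grade 1–5 of the
  histological pattern, from a broad pushing front to islands lying
  ≥ 1 mm from the tumor mass;
* the **single pattern of invasion (SPOI)**, the ratio of *singular*
  islands (fewer than 15 nuclei) to *clustered* islands (15 or more),
  defined as 0 when no singular island exists. SPOI isolates the
  single-cell-like component of invasion that WPOI saturates on in
  vitro, where gels rarely accommodate the 1 mm criterion.

In parallel, each keratinocyte population carries a **p-EMT score**
summarizing nine qPCR markers, and association analyses connect the
molecular state to the invasion phenotype.

## The p-EMT score, step by step

For each population and panel gene (default panel: PDPN, VIM, PAI1,
LAMC2, TGFBI, THBS1, MMP1, MMP10, ITGA5; reference GAPDH):

1. ΔCT = CT_gene − CT_GAPDH per replicate, then replicate-averaged per
   (population, gene). Averaging after the subtraction is standard ΔCT
   practice; with a common reference per block the order only matters
   when replicates are incomplete, which is an error here anyway.
2. EXP = 2^(−ΔCT) × 100.
3. Per gene, across the populations being scored, N_val =
   (100·EXP_min − EXP_max)/99 is subtracted from every EXP. This maps
   the gene's observed range onto an exact 100-fold span:
   (EXP_max − N_val) = 100·(EXP_min − N_val) whenever the extremes
   differ — the identity the test suite checks to 1e−9.
4. The nine normalized values are averaged per population, and the
   per-population means are mapped linearly onto [0.1, 10], so the
   cohort maximum scores exactly 10 and the minimum exactly 0.1.

Step 4 is the one genuinely open design point: "converted to the range
of 0.1–10" fixes only the endpoints. We adopt the linear min–max map on
the per-population averages, applied jointly across all samples passed
in one call (so control and treated conditions scored together share
one scale). The alternative — converting each gene to 0.1–10 before
averaging — was considered and rejected in favour of the explicit
average-then-convert chain; the difference matters only in one
invariance, discussed next.

**What is and is not invariant.** A Ct shift applied to *every* panel
gene across all populations rescales all per-population averages by the
same factor, and the min–max conversion cancels it exactly. A shift of
a *single* gene scales exactly that gene's normalized values by 2^(−c)
(N_val is equivariant under per-gene scaling) but perturbs the
per-population averages non-uniformly, so final scores can move by a
fraction of a percent. The property tests assert precisely these two
facts rather than a blanket invariance. Degenerate inputs follow the
formulas where they lead: a gene flat across populations has N_val =
EXP and contributes 0 to every average (warned); a cohort with
identical averages cannot be anchored at two endpoints and is set to
the midpoint 5.05 (warned).

## Image quantification

Segmentation is plain thresholding (Otsu by default, or a fixed
threshold), deliberately mirroring interactive ImageJ-style analysis;
the threshold used is always recorded in the provenance output because
the original workflow's thresholds were interactive and unrecorded.
Components use 8-connectivity throughout (a 1-px diagonal bridge joins
islands — a contract the tests pin down). The component touching the
top image border (the air side) with the largest area is the epithelial
sheet; the image orientation (sheet up, invasion downward) is an input
contract. Everything else of at least `min_island_area` = 25 px² is a
detached island; nuclei are counted by Otsu-thresholding the DAPI
channel *within* each island and counting 8-connected blobs of at
least `min_nucleus_area` = 9 px². These two size filters suppress
single-pixel noise and are config-exposed; watershed splitting of
touching nuclei is intentionally not attempted — the synthetic fixtures
render nuclei disjoint, and the counting operator is documented as
replaceable for real data.

The depth origin is the median over columns of the sheet's lowest
occupied row, which is robust to finger-like protrusions; per-island
depth is the island's deepest pixel below that base, clamped at 0, and
the image depth is the maximum over islands (0 without islands).
Finger-like fronts (WPOI 2) are operationalized as connected sheet
regions below the base row with bounding-box height/width ≥ 2 — the
visual "finger-like" criterion needs *some* computational reading, and
the aspect threshold is config-exposed. Cell elongation (LWR) is the
ratio of major to minor axis from the eigenvalues of the second central
moments of the mask pixel set, rotation-invariant by construction.

## Grading rules and their edge cases

WPOI precedence is 5 > 4 > 3 > 2 > 1 — the *worst* pattern wins. The
1 mm criterion uses the island's nearest Euclidean distance to the
sheet (island-to-sheet; the alternative island-to-island reading is
noted but not the default), and requires a pixel calibration. An island
with exactly 15 nuclei is *clustered*: the WPOI wording leaves 15
unassigned ("more than 15" vs "fewer than 15") but the SPOI definition
assigns ≥ 15 to clustered, and one convention is used everywhere. SPOI
with singular islands but no clustered island is undefined by the
definition; the singular count is returned with an explicit
`spoi_undefined` flag (preserving monotonicity in the singular count)
and is never silently mixed into aggregates. Experiments are imaged at
nine fields (triplicate images at the gel centre and one quarter in
from each edge, across three cultures) and averaged into a single
sample; `aggregate_experiment()` warns on any other field count.

## The synthetic-data generators

The generators exist so that every downstream stage has exactly known
truth. An `organ_image_spec()` renders: a full-width sheet in the top
rows; optional protrusion fingers (14 × 5 px, aspect 2.8); circular
islands below the sheet, each ≥ 2 px from the sheet and from each
other (violations are refused, never merged, because merged truth
would silently falsify counts); nuclei as disjoint 3-px-radius discs
with ≥ 2 px edge separation on an 8-px lattice, making counts
unambiguous at ground truth. Intensities are binary (foreground 1,
background 0; PDPN at 0.8 in islands vs 0.2 in sheet) plus optional
clipped Gaussian noise — the simplest model that still exercises
thresholding. Calibration defaults to 1 µm/px; WPOI-5 fixtures must
supply the calibration that makes 1 mm reachable, since 20× microscopy
pixel sizes vary by instrument. The Ct generator writes
CT = baseline − level × dynamic_range (default 30 − level × 5 cycles)
for each panel gene, GAPDH fixed at 20, so expression is strictly
monotone in the latent p-EMT level at zero noise. The default cohort
is six populations on an even p-EMT gradient with four TGF-β
responders (2–4-fold pSMAD3 stimulation) and two non-responders (fold
1), fifty cells per population for LWR, and a 40-TF matrix with one
planted invasion-tracking factor — the cohort structure of the study
design this pipeline serves.

What the generators do **not** emulate: nuclear texture and overlap,
uneven illumination, stain bleed-through, ragged island shapes, 3D
effects, or biological covariance between genes beyond the single
latent level. Passing the recovery tests therefore demonstrates that
the *rules* are implemented exactly and degrade gracefully under
additive noise — not that the segmentation would survive real
histology, where thresholds and the nuclei counter would need tuning.

## Statistics

Correlation plots use the sample Pearson r with the two-sided p from
t = r·sqrt((n−2)/(1−r²)) on n−2 df, and an OLS best-fit line (both via
`stats::cor.test()`/`lm()`, cross-checked against closed forms in the
tests). Paired t-tests are computed closed-form so the degenerate
conventions are explicit: all-zero differences give t = 0, p = 1;
constant nonzero differences give ±Inf with p = 0 and a flag. Outlier
flagging is iterative Grubbs at α = 0.05 — a documented, simpler
stand-in for proprietary interactive outlier tools (ROUT is a
non-goal); flags are returned, removal is the caller's decision, and
removal is applied only where requested (SPOI fold-change
comparisons). Because the family-wise false-flag rate of the Grubbs
step *equals* α under the null, the Monte-Carlo level check compares
the flagged count against the exact one-sided binomial bound at the 1%
level rather than the bare rate — a strict `rate ≤ α` on an unbiased
estimate would fail on a coin flip. The TGF-β responder cutoff
defaults to 1.5-fold (responders in practice sit at 2–4-fold,
non-responders near 1; the cutoff is config-exposed). The TF screen
ranks by |r| and appends BH q-values that never alter the ranking.

One power limit of the screen is worth stating because the test suite
computes it honestly: with a planted factor at generative correlation
0.95 among 39 null factors and only n = 6 populations, each null
factor out-|r|s a sample correlation of 0.95 with probability
2·pt(−0.95·√(4/(1−0.95²)), 4) ≈ 0.0037, so the planted factor ranks
first in at most (1−0.0037)³⁹ ≈ 87% of repeats — not 90%+. At this
cohort size the screen is a shortlist generator, not a significance
machine, which is also why the q-values are reported but not used to
rank.

## Problem sizes and runtime choices

The test and acceptance workloads are sized for a single CPU: 640 × 480
px images (50 noise-free + 10 noisy random geometries for parameter
recovery), 20-seed score-rank recovery, 1000-rep Grubbs null
simulations, and a 500-rep TF-screen power study at n = 6. These sizes
give Monte-Carlo standard errors well below the margins being tested
while keeping a full run in minutes.

## Known limitations

* The nine-gene panel is assembled from the figures of the source
  study design (with one apparent typo corrected); it is a default,
  not an assertion, and is fully configurable.
* Nuclei counting assumes separable nuclei; real DAPI staining of
  dense islands would undercount without a splitting step.
* WPOI 1 vs 2 rests on a geometric protrusion heuristic for an
  inherently visual criterion.
* The invasion index multiplies three quantities with different units;
  it is reported as the dimensionless composite it is, comparable only
  within a fixed calibration.
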