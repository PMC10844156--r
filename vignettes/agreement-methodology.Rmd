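---
title: "Measuring annotator agreement for bounding-box detections without a gold standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring annotator agreement for bounding-box detections without a gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotagree)
```

## The problem

When several readers mark lesions on medical images with bounding boxes —
the motivating case is caries annotation on bitewing radiographs — there is
usually no reliable reference standard. Destructive verification is
impossible at dataset scale, clinical follow-up is itself insensitive, and
every annotator, however experienced, has an individual style: different
detection thresholds, different box sizes, different numbers of marks per
image. The task is formulated as *detection*, not classification: absence of
a lesion is never labeled explicitly, so chance-corrected agreement
coefficients such as Cohen's kappa are not computable. This package instead
quantifies agreement directly on the box sets, three ways: pairwise between
annotators, against a majority consensus of an expert panel, and against a
single designated reference annotator.

## Box correspondence and greedy matching

Two boxes are taken to mark the same lesion when the centroid of either box
lies inside the other (boundary inclusive). This deliberately loose relation
separates the *detection* question ("did both annotators mark this site?")
from the *localization* question ("how well do the boxes overlap?"); plain
IoU thresholds conflate the two and punish honest size disagreements. The
relation is reflexive and symmetric but not transitive, so a matching step
is required before anything can be counted.

`greedy_match()` pairs two box sets one-to-one: boxes from the union of both
sides are visited in order of decreasing area; each seed is paired with the
corresponding box on the other side that maximizes the intersection area.
Unmatched boxes of both sides are *errors* — missed lesions and spurious
detections together; the pooled mean IoU over matched pairs measures
localization alone. Pooling is over all matched pairs of the whole dataset
(one division at the end), not a mean of per-image means, so images with
many lesions carry proportionally more weight.

Several details of the greedy procedure are underdetermined by the verbal
description, and the package fixes them deterministically:

* "largest box" means largest **area**; the longest-side reading was
  rejected because area is the standard magnitude for 2-D boxes. Ties are
  broken lexicographically on `(xmin, ymin, xmax, ymax)`, and a residual tie
  (coordinate-identical boxes on both sides) is processed side-a-first — a
  rule that provably cannot change the error count or the pooled IoU.
* candidate ties after maximal intersection are broken by the larger
  candidate, then lexicographically.
* a seed that finds no partner is set aside as unmatched but **stays
  available** as a partner for later seeds from the other side; boxes leave
  the pool only when matched. This makes the matching maximal: after
  termination no unmatched box on one side corresponds to an unmatched box
  on the other, so the error count reflects genuine disagreement only.

These choices make the result invariant under swapping the two annotators,
which the test suite verifies on random panels with deliberately engineered
area ties, alongside an exact comparison against an independent
brute-force enumeration of the rules.

```{r matching-example}
a <- boxes(c(100, 300), c(100, 300), c(160, 360), c(160, 360))
b <- boxes(110, 95, 180, 170)
m <- greedy_match(a, b)
m
count_errors(m)
```

## Consensus standards and tentative lesions

`build_consensus()` fuses a panel's annotations into a majority standard by
a greedy vote. Each round, the globally largest remaining box seeds a
lesion; every *other* panel member contributes at most one corresponding box
as a supporter. If seed plus supporters exceed half the panel — a strict
majority, which for a panel of two means unanimity — the lesion enters the
majority set S as the coordinate-wise mean of the supporting boxes;
otherwise the seed becomes a *tentative* lesion in the minority set S'.

Two readings of the vote were open and were resolved as follows. First, one
supporting box per panel member: the vote counts supporting *experts*, and
admitting two boxes from the same annotator would corrupt the majority rule.
Second, supporters removed together with a minority seed are discarded
rather than re-seeded: boxes are removed unconditionally with their seed,
and with the one-box-per-member rule a minority seed has at most
`floor(|panel|/2)` supporters, so no majority lesion can be lost this way at
panel sizes up to four; the supporter count of every tentative lesion is
nevertheless retained in the standard for audit.

An annotator evaluated against a standard
(`evaluate_against_consensus()`) is matched against S first and only the
leftovers against S'; boxes matching S' are discarded as neither true nor
false positives. Matching S first matters: a detection overlapping both a
confirmed and a tentative lesion must score as a true detection of the
confirmed one. For the same reason the reported IoU uses S-matches only —
tentative lesions influence no metric. The S-then-S' order, together with
matching maximality, guarantees that adding tentative lesions can only
remove errors, never add them (a property test asserts this).

To avoid self-confirmation, `leave_one_out_standards()` builds one standard
per evaluated expert, excluding that expert from the panel; a designated
annotator (for instance the one who annotated an automatic method's training
data, or an outlier expert) can additionally be excluded from every panel.
Experts are scored only on their own left-out standard; everyone else is
scored on all standards and the results averaged.

## Significance of pairwise differences

Whether annotator *a* agrees better with a reference than annotator *b* is
tested on the per-image paired differences
`sum_c [ e(B_ia, B_ic) - e(B_ib, B_ic) ]`, summed over the reference
annotators c (excluding a and b themselves), with the analogous series for
per-image pooled IoU. The test is the two-sided Wilcoxon signed-rank test,
summarized as the signed score `q = ±(1 - p)`: magnitude near 1 means
significant, the sign says which annotator is closer. `plot_significance()`
renders the grid in the conventional green/red form.

Numerical conventions, all switchable:

* **two-sided**, because the direction of a difference is never known in
  advance and the grid display needs both signs;
* **zeros discarded** before ranking (Wilcoxon's original treatment);
  the Pratt variant (`zeros = "pratt"`) ranks them and then drops them from
  the statistic;
* **ties get average ranks**; the exact null distribution of the rank-sum
  statistic is computed by dynamic programming over the (tie-adjusted,
  doubled) ranks for up to 25 nonzero differences — full enumeration at
  desk scale — and a normal approximation with continuity correction and
  tie-corrected variance is used beyond;
* per-image error differences are integers with many ties and zeros, which
  is exactly why the exact-with-ties path is the default rather than
  `stats::wilcox.test`'s switch to the approximation in the presence of
  ties. The test suite checks the DP distribution against full sign
  enumeration and against `wilcox.test` on tie-free data.

For the IoU series, an image where either of the two pairings being
differenced has no matched boxes is dropped (the per-image pooled IoU is
undefined there); the dropped count is reported. This is the
minimal-assumption choice — imputing 0 would conflate localization with
detection failures.

## The synthetic annotator panel

Because real multi-reader datasets are rarely shareable, the package ships a
seeded simulator used throughout the tests. `generate_layout()` draws
ground-truth lesion sites: Poisson lesion counts per image (default 3 per
image on 100 frames of 896×1024 px), log-normal side lengths truncated to
[8, 160] px and centered near 55 px — positively skewed box sizes in the
range of real caries annotations — and uniform in-frame placement with a
default guarantee that same-image sites are pairwise non-corresponding, so
every simulated annotation is attributable to a unique site.

`simulate_annotator()` degrades the truth through an `annotator_profile()`:
detection sensitivity, a Poisson false-positive rate per image (spurious
boxes placed away from true lesions by default, keeping the accounting
identifiable), Gaussian center jitter, and a multiplicative size bias with
log-normal noise (one multiplier per box, preserving aspect ratio).
`bitewing_panel_profiles()` bundles nine profiles that qualitatively mimic
an observed bitewing panel: per-annotator counts spanning roughly 240–430
boxes per 100 images, one over-calling expert, one expert drawing boxes
nearly twice as large as the rest, and three novices with noisier
localization. Per-annotator random streams are seeded by a stable hash of
the master seed and the annotator id, so adding an annotator never perturbs
the others.

What the simulator does *not* model: pixel content, tooth and surface
anatomy (so lesion positions are spatially uniform rather than clustered on
proximal surfaces), annotator fatigue or drift, and correlated errors
between annotators (all readers are conditionally independent given the
layout). Passing tests therefore demonstrate the correctness and
calibration of the *metrics* under known ground truth, not that any
particular real panel behaves like the preset.

```{r panel-example}
layout <- generate_layout(n_images = 20, lesion_rate = 3, seed = 11)
panel <- simulate_panel(layout, bitewing_panel_profiles()[c("E1", "E2", "E3", "E4", "M")],
                        seed = 11)
do.call(rbind, lapply(panel$annotations, annotation_stats))
ev <- evaluate_all_against_standards(panel, c("E1", "E2", "E3", "E4"))
ev$summary
```

## Degenerate inputs and numerical choices

* Coordinates are continuous; intervals are closed, and centroid
  containment includes the boundary. No discrete pixel convention is
  imposed.
* Zero-area boxes are rejected at ingest — the correspondence relation and
  IoU are ill-defined for them.
* An annotator with no boxes on an image is a negative finding, not missing
  data; absent image entries are treated as empty sets.
* A pair of annotators with no matches anywhere has an *undefined* pooled
  IoU, reported as `NA` and excluded (with a warning) from means — never
  silently coerced to 0.
* "Mean side length" statistics pool widths and heights into one sample of
  `2 * n` values, which yields a single mean/sd per annotator; the standard
  deviation uses the population (divide-by-n) convention by default, with
  the sample convention available, since either could underlie a published
  table.
* All-zero difference series give `p = 1`, `q = 0`, flagged degenerate; an
  IoU series that loses every image to the no-match drop rule is likewise
  reported degenerate rather than erroring inside a grid.

## Validation scale

The bundled checks run at desk scale, chosen to keep the full suite under a
few minutes while leaving the conclusions stable across seeds: exact
oracle-equivalence of the matcher on 10,000 random instances with up to 4
boxes per side; role-swap invariance on 1,000 panels; consensus voting
semantics over every support pattern at panel sizes 2–4; null calibration
of the signed-rank test over 500 replicate panels of 40 images (the
observed rejection rate at α = 0.05 must fall in the 99% binomial band);
and consensus recovery of ≥ 90% of true sites by a four-expert panel with
sensitivity 0.95 and 0.2 false positives per image over 10 seeds.

## Known limitations

* The greedy matching is not a maximum-cardinality assignment; it mirrors
  the field's procedure, and the brute-force comparator in the tests exists
  only as an oracle for the greedy rules themselves.
* The correspondence relation is not transitive, so consensus output can
  depend on processing order; the deterministic ordering makes results
  reproducible but is still a greedy resolution of an inherently ambiguous
  grouping.
* Error counts weight missed and spurious detections equally; applications
  with asymmetric costs need their own weighting downstream.
* The per-surface classification-error conversion assumes a fixed average
  number of scoreable surfaces per image (default 13) and is only as
  meaningful as that denominator.
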