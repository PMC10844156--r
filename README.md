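# annotagree

Inter-annotator agreement for bounding-box detection annotations when no
gold standard exists.

When several readers independently mark lesions on medical images — the
motivating application is caries annotation on bitewing radiographs, where
experienced dentists can disagree on hundreds of lesions across a hundred
images — there is no reliable reference against which to score anyone,
and because the task is detection (absence is never labeled), Cohen's kappa
cannot be computed. `annotagree` quantifies agreement directly on the box
sets:

* **Correspondence & matching.** Two boxes mark the same lesion iff the
  centroid of either lies inside the other. A deterministic greedy matcher
  pairs two annotators' boxes one-to-one per image, seeds ordered by
  decreasing area, partners chosen by maximal intersection.
* **Two complementary metrics.** The *number of errors*
  e(B, B′) = |B| + |B′| − 2|Ω| counts unmatched boxes of both sides —
  missed plus spurious detections, insensitive to box geometry; the
  *pooled matched IoU* (sum of matched-pair IoUs over the dataset divided
  by the number of matches) measures localization alone, ignoring
  detection failures.
* **Consensus standards.** A panel's annotations are fused by greedy
  majority voting: a lesion supported by a strict majority (> |E|/2; for a
  panel of two, unanimity) enters the standard S as the coordinate-wise
  mean of its supporting boxes; lesions without majority support are
  *tentative* (S′) and count as neither true nor false positives during
  evaluation. Leave-one-out standards avoid scoring any expert against a
  standard they helped build.
* **Reference comparison.** Precision / recall / F1 and an equivalent
  per-surface classification error against a designated reference
  annotator.
* **Significance.** Two-sided Wilcoxon signed-rank tests on per-image
  paired differences, exact under ties up to n = 25, reported as the signed
  score q = ±(1 − p) and rendered as the conventional green/red grid.
* **Simulation.** A seeded generator of ground-truth lesion layouts and
  annotator panels with controllable sensitivity, false-positive rate,
  center jitter and box-size bias, used to validate the whole pipeline
  under known truth.

Annotations are read from CVAT "for images 1.1" XML or COCO detection
JSON, plus a canonical JSON dump that round-trips bit-exactly.

## Worked example

Simulate a five-reader panel (four experts, one automatic method analogue)
on 20 images with ~3 true lesions each, then run the three evaluations:

```r
library(annotagree)

layout <- generate_layout(n_images = 20, lesion_rate = 3, seed = 11)
panel  <- simulate_panel(layout,
            bitewing_panel_profiles()[c("E1","E2","E3","E4","M")], seed = 11)

do.call(rbind, lapply(panel$annotations, annotation_stats))
#>    annotator_id n_boxes mean_side std_side
#> E1           E1      79  65.80453 26.60178
#> E2           E2      52  53.44695 22.45742
#> E3           E3      48  77.18715 31.13946
#> E4           E4      45 107.61133 47.26610
#> M             M      49  50.29219 21.27456
```

E1 over-calls (79 boxes), E4 draws boxes about twice as large as everyone
else — the kind of style differences the metrics must cope with. Pairwise
agreement, pooled IoU above the diagonal and error counts below, with
per-annotator means in the margins:

```r
print(agreement_table(pairwise_matrix(panel)), quote = FALSE)
#>     E1   E2   E3   E4   M    IoU_a
#> E1  .    0.60 0.62 0.43 0.56 0.56
#> E2  45   .    0.48 0.28 0.62 0.50
#> E3  39   24   .    0.53 0.45 0.52
#> E4  40   29   21   .    0.24 0.37
#> M   38   19   19   22   .    0.47
#> e_a 40.5 29.2 25.8 28.0 24.5 .
```

The M row: 24.5 mean errors over 20 images — best of the panel — while its
IoU suffers against the double-size boxes of E4 (0.24). Against
leave-one-out consensus standards (each expert scored only on the standard
excluding them, M averaged over all four):

```r
evaluate_all_against_standards(panel, c("E1","E2","E3","E4"))$summary
#>  annotator n_standards e_avg   iou_avg
#>         E1           1    30 0.6454593
#>         E2           1    15 0.4558084
#>         E3           1    11 0.7123224
#>         E4           1    14 0.4210717
#>          M           4     8 0.4854671
```

And against a single reference annotator, with the error count converted
to a per-surface classification error (13 proximal surfaces per bitewing):

```r
compare_to_reference(panel, "M", "E1")
#> <reference_comparison> M vs reference E1
#>   TP 45  FP 4  FN 34  (e = 38)
#>   precision 0.92  recall 0.57  F1 0.70  pooled IoU 0.563
#>   classification error 14.6% (13 surfaces/image)
```

Recall 0.57 against the over-calling E1 is expected: most of the 34 "false
negatives" are E1's unconfirmed extra marks. Significance of pairwise
differences in error counts, through the expert panel as reference
(positive q: row annotator closer to the experts; |q| > 0.95 significant
at α = 0.05):

```r
significance_matrix(panel, c("E2","E3","M"), mode = "experts",
                    metric = "errors", experts = c("E1","E2","E3","E4"))
#>       E2     E3      M
#> E2    NA -0.869 -0.883
#> E3 0.869     NA -0.373
#> M  0.883  0.373     NA
```

At 20 images no difference reaches significance — the panel is small, and
the grid honestly says so.

A thin command-line front end over the same functions ships in
`inst/cli/annotagree.R` (`stats`, `pairwise`, `consensus-build`,
`consensus-eval`, `compare`).

## Method details

See the methods vignette,
`vignettes/agreement-methodology.Rmd`, for the full model description,
the deterministic tie-breaking rules, the tentative-lesion semantics, the
exact-under-ties signed-rank implementation, and what the simulator does
and does not emulate.
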