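---
title: "Repair-junction analysis for two-cut GFP reporter assays"
author: "nhejscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repair-junction analysis for two-cut GFP reporter assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhejscan)
```

## The assay and its observables

A chromosomal reporter carries a GFP gene split by a large intron that is
interrupted by a "killer" exon flanked by two inverted I-SceI recognition
sites. Expressing I-SceI cuts both sites, excising the killer exon and
leaving two non-compatible DNA ends. Any non-homologous end joining (NHEJ)
event that rejoins the intron restores GFP, so repair *efficiency* is read
out by flow cytometry as the ratio of GFP-positive to DsRed-positive cells
(DsRed normalises transfection efficiency), and repair *fidelity* is read
out by PCR-rescuing, cloning and Sanger-sequencing individual junctions.

`nhejscan` implements the desk half of this assay:

1. **Construct model** — the annotated reporter, its post-cut flanks, and
   the primer-bounded *detection window*: the largest deletion on each side
   of the break that still leaves both rescue primers intact.
2. **Junction caller** — per-read inference of deletions, insertion and
   apparent microhomology, with MMEJ classification.
3. **Random-joining null** — the exhaustive distribution of apparent
   microhomology if ends were joined at random, the baseline for claiming
   microhomology *preference*.
4. **Cohort statistics** — deletion/insertion spectra, microhomology and
   MMEJ fractions, pooled-z and pooled-t comparisons, efficiency ratios and
   fold changes.
5. **Synthetic generator** — constructs, junction reads and FACS tables
   with full ground truth.

All coordinates are 1-based closed intervals on the top strand. A cut-site
`position` is the base immediately 5' of the top-strand scission.

## The junction model

A repair product is modelled as

```
read = left_flank[1..a] + insertion + right_flank[(R-b'+1)..R]
```

The caller computes `a` as the maximal exact prefix match of the read
against the left flank and `b` as the maximal exact suffix match against
the right flank ('N' matches nothing, conservatively). Three cases follow:

* `a + b > len(read)`: the matches overlap; the overlap `a + b - len(read)`
  is **apparent microhomology** — a tract over which the true breakpoint
  cannot be placed. The insertion is empty.
* `a + b == len(read)`: a blunt junction.
* `a + b < len(read)`: the interior `read[(a+1)..(len-b)]` is an
  **insertion**; microhomology is 0.

This equals exhaustive search over all decompositions minimising insertion
length with ties broken *left-greedy* (maximal `a`), which the test suite
verifies against an independently coded enumeration. Left-greedy means
microhomology bases are attributed to the left flank when splitting
`del_total` into `del_5prime`/`del_3prime`; the published junction tables
do not state which side they attributed such bases to, so the event record
carries an explicit `ambiguity` field (equal to `mh_len`) instead of
pretending the split is observable. The attribution never changes
`del_total` or `mh_len`.

`del_total` is defined as the total number of reference bases absent from
the read, `(L - a) + (R - b) + mh_len`, which is invariant under breakpoint
sliding. The round-trip contract `reconstruct_read(call_junction(r)) == r`
holds exactly for every called read and is enforced at scale in the tests.

Reads that begin with the forward rescue primer (amplicon-style input) are
anchored to the primer's known flank position rather than penalised: the
flank bases 5' of the primer are absent by PCR design, not by deletion.
Long insertions matching the excised segment are flagged `ad_retained`
(a single-cut event that kept killer-exon sequence) and excluded from
cohort statistics by default, since the cloning protocol depletes but does
not eliminate such products. Deduplication retains one junction signature
per PCR reaction, mirroring the protocol's uniqueness rule.

### Classification

Junctions with `mmej_min <= mh_len <= mmej_max` are classified MMEJ. The
defaults are `mmej_min = 5` (the classifier threshold used with the
reporter's junction tables: 5 bp and longer counts as MMEJ, 4 bp does not)
and `mmej_max = 25` (the upper end of the homology range MMEJ is described
to use); in practice the effective cap is the longest microhomology the
construct offers, 16 bp in the default synthetic construct. Deletions are
categorised small (1-500 bp) versus large (> 500 bp): a 500 bp deletion is
small, 501 bp is large.

## The random-joining null

For every breakpoint pair — `i` on the left flank within the 5' window,
`j` on the right flank within the 3' window — the enumeration scores the
apparent microhomology of the joint and tabulates the uniform-over-pairs
distribution. Decisions embedded here, and why:

* **Deletion junctions only.** The single zero-deletion (blunt) pair is
  excluded by default because apparent microhomology is undefined without
  a deleted span (`include_blunt = TRUE` reverses this). Junctions with a
  deletion on only one side *are* included: they are real deletion
  junctions. `n_pairs = (w5 + 1)(w3 + 1) - 1`.
* **Uniform weighting** over pairs, with no resection-length prior: that is
  what "joined at random" means. No annealing-energy weighting is applied.
* **Window-restricted by default** because only primer-rescuable junctions
  are observable; a full-intron mode exists for comparison. Whether the
  published 44% chance-microhomology figure was computed over the window
  or the whole intron is not stated; both modes are provided and neither
  is asserted as "the" published procedure.
* **Full-tract scoring** (`two_sided = TRUE`, default). A junction product
  is invariant under sliding breakpoints across its homology tract, and
  the caller necessarily reports the whole tract. Scoring each enumerated
  pair one-sidedly would undercount relative to what the caller measures
  (for iid uniform sequence it gives P(MH >= 1) = 1/4, whereas the
  observable-product probability is 1 - (3/4)^2 = 43.75% — the published
  ~44% expectation corresponds to the latter). The one-sided primitive
  `apparent_mh()` is still exported, and `two_sided = FALSE` reproduces
  its literal tabulation. With full-tract scoring the null and the caller
  measure *exactly* the same quantity, which the calibration test exploits
  (observed fraction at n = 10^4 within 3 binomial sd of the enumerated
  probability).

The observed-versus-null comparison is a one-sample z test on a percent:
`z = (p_obs - p0) / sqrt(p0 (1 - p0) / n)`.

```{r null-demo}
fa <- system.file("extdata", "demo_construct.fa", package = "nhejscan")
js <- system.file("extdata", "demo_construct.json", package = "nhejscan")
cons <- load_construct(fa, js)
cutref <- derive_cut_reference(cons)
window <- detection_window(cons, cutref)
random_joining_distribution(cutref, window)
```

## Cohort statistics

The percent metrics (large deletions, insertions, microhomology, MMEJ) are
compared between cohorts with the pooled two-proportion z statistic; the
"two-sample t-test between percents" of desktop statistics calculators is
exactly this pooled z, so the normal reference distribution is the default
(a df-based variant would differ only in the far tail at these n). Size
metrics use the classical pooled-variance unpaired t test. `mean_del` and
`mean_ins` average over feature-bearing junctions only — the published
panels plot "average deletion size" over clones that have deletions — and
a cohort with no such junctions reports `NA`, never 0; `include_zeros`
switches to all-junction averages since the published choice is not
stated. No multiple-testing correction is applied by default (per-metric
alpha = 0.05, matching the assay's reporting); Benjamini-Hochberg is
available via `p_adjust = "BH"`.

Efficiency is `n_gfp / n_dsred` per transfection, summarised as mean and
s.e.m. over replicates; the age effect is reported as
`mean(young) / mean(old)`.

## The synthetic world

The generator's defaults encode the study design the package is built
around, and they are fixed rather than tunable knobs:

* **Design**: 5 tissue analogs x 2 ages x 30 junctions = 300 junctions,
  60 per cell type; FACS tables of 20,000 cells per transfection.
* **Construct**: flanks of 920/780 bp giving the stated 886 x 750 bp
  rescue window with 25-nt primers; an excised segment carrying the two
  inverted 18-bp I-SceI recognition sequences; planted direct repeats of
  6, 9 and 16 bp, so the longest microhomology is 16 bp. Guard bases force
  each planted repeat's copies to differ at their boundaries, making the
  planted length exact.
* **Resection**: independent geometric laws per side (means 150/120 bp by
  default), truncated to the window so every read is rescuable. The law is
  a modelling choice — the assay reports only ranges (deletions of 1 up to
  ~990 bp), not a distribution — chosen for single-parameter simplicity.
* **Insertions**: present at half of c-NHEJ junctions by default (the
  observed insertion-bearing fractions span 33-67%), with 1 + geometric
  lengths (mean 12 bp, rare lengths reaching the ~138 bp scale).
* **MMEJ channel**: joins at a breakpoint pair with >= 5 bp apparent
  microhomology, drawn uniformly from the exhaustive enumeration, deleting
  the intervening sequence.
* **Chance microhomology at c-NHEJ junctions is not suppressed** — random
  flank sequence creating apparent homology is precisely what the
  random-joining null describes.
* **Errors**: substitution-only, default 0. Sanger clone consensus rarely
  carries indel errors, and indel errors would change the caller's
  contract itself.

Two deliberate canonicalisations make error-free ground truth *exactly*
recoverable, which the acceptance tests rely on: insertion first/last
bases are resampled so they cannot be absorbed into a flank match, and the
recorded truth microhomology of a chance junction is taken from the same
enumeration the caller's scoring provably reproduces. What a green test
therefore establishes is that inference inverts the generative model
exactly in the error-free regime and degrades measurably with sequencing
error — not that real Sanger chromatograms are error-free, and not that
real resection is geometric.

The aging contrast built into `simulate_study()` (old cohorts: more MMEJ,
longer resection, fewer/shorter insertions; efficiencies declining 1.8- to
3.8-fold, strongest in the skin analog) reproduces the *direction* of the
reported biology so that the comparison machinery has signal to find; the
numbers come from the stated study design where given and from plausible
mid-range choices where not.

## Numerical and degenerate-input choices

* Pooled proportion 0 or 1 gives statistic 0, p = 1, flagged `degenerate`.
* Zero pooled variance with equal means gives t = 0, p = 1; with unequal
  means the result is flagged degenerate (infinite statistic).
* `mh_excess_test` with `k_min` beyond the construct's longest
  microhomology has expected fraction 0 and is flagged degenerate rather
  than reporting an infinite statistic.
* An unalignable read (no >= 1 bp anchor on either flank) is a per-read
  reject, never a batch failure; deletions beyond the window flag the
  event rather than dropping it.
* The null enumeration normalises to 1 within 1e-12 and its exceedance
  curve is checked non-increasing on every construction.
* Whether overhang bases count as deleted is annotation-driven: the
  excised interval defines the flanks, and any retained overhang bases are
  simply flank sequence (clones are double-stranded, so strandedness of
  the intermediate is unobservable).

## Known limitations

* No translocation or multi-template junctions; insertions are reported
  verbatim, not traced to a templated origin.
* No base-quality-aware alignment; the mismatch-tolerant mode is a simple
  budgeted extension, not an aligner.
* No mixed-effects modelling across mice; per-mouse ids are carried as a
  grouping key only.
* The real reporter construct sequence is not deposited with the study, so
  the checks that would reproduce its published 44% chance-microhomology
  figure and 16 bp maximal microhomology run against a synthetic stand-in
  with the same stated geometry (and agree with both figures for the
  analytic reason given above), not against the real sequence.

## A worked run

```{r pipeline, eval = FALSE}
run <- run_pipeline(nhej_config(out_dir = "nhej_demo", seed = 1))
summary(run)
```

This writes `events.tsv`, `summary.tsv`, `comparisons.tsv`,
`mh_excess.tsv`, `null_probs.tsv`, `efficiency.tsv` and a `manifest.json`
that echoes the seed and every parameter, sufficient to reproduce any
output byte-for-byte.
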