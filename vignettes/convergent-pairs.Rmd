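---
title: "Methods: calling overlapping transcript pairs and testing interference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling overlapping transcript pairs and testing interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convpairs)
```

This vignette documents the model, the algorithms, the parameter choices
and their defaults, what the synthetic generator does and does not
emulate, and the package's known limitations.

## Coordinate conventions

All coordinates inside the package are **0-based, half-open** `[start,
end)`, in base pairs. Conversion to and from 1-based closed GFF3
coordinates happens only in `read_gff()` / `write_gff()`. BED and bedGraph
are already 0-based half-open and pass through unchanged. Lengths and
overlaps are therefore always simple differences, with no ±1 bookkeeping
anywhere in the arithmetic.

## UTR calling

The input is an ORF annotation (one interval and strand per gene) and
strand-specific per-base read coverage. A gene's transcript is assumed to
cover its ORF; the question is how far it extends beyond it.

For a plus-strand gene, `call_utr3()` walks rightward from the base
immediately after the ORF end along the **same strand's** coverage (the
antisense strand never contributes). The walk continues while coverage is
at least `min_cov`, tolerating runs of up to `max_gap` consecutive
below-threshold bases *inside* the extension; trailing sub-threshold bases
are trimmed, so the called UTR always ends on a covered base. The result
is capped at `max_utr_len` and at the chromosome end. `call_utr5()` is the
mirror-image walk upstream of the ORF start; minus-strand genes swap the
two directions. The implementation is a vectorized scan over covered
positions (`which`/`diff`), with a brute-force per-base walker kept in the
test suite as an oracle.

Parameters (`utr_call_params()`), all in bases or reads per base:

| parameter           | default | meaning                                               |
|---------------------|--------:|-------------------------------------------------------|
| `min_cov`           |       1 | minimum reads/base for a position to count as covered |
| `max_gap`           |       5 | longest tolerated internal sub-threshold run (bases)  |
| `max_utr_len`       |     600 | hard cap on either UTR length (bases)                 |
| `expr_min_mean_cov` |       1 | mean ORF reads/base below which a gene is "unexpressed" (used by validation) |

The caller is monotone: raising `min_cov` can only shorten a UTR; raising
`max_gap` can only lengthen it. Both properties are asserted in the tests
over random Poisson coverage.

## Pair classification

Genes are sorted by chromosome and start; every pair of **adjacent** genes
on the same chromosome is examined (classification refuses unsorted
input). With `up` the left gene and `down` the right gene:

* the **gap** is `down$orf_start − up$orf_end`, the distance between the
  facing ORF boundaries — negative when the ORFs themselves overlap;
* **convergent**: `up` on `+`, `down` on `−`, and the two 3′-UTR intervals
  intersect by at least 1 bp;
* **divergent**: `up` on `−`, `down` on `+`, and the two 5′-UTR intervals
  intersect by at least 1 bp;
* **consistent**: same strand and the transcript spans intersect by at
  least 1 bp (the reported `utr_overlap_bp` is then the overlap of the
  facing UTRs: the left gene's 3′-UTR against the right gene's 5′-UTR on
  `+`/`+`, mirrored on `−`/`−`).

Two overlap measures are reported deliberately. `utr_overlap_bp` is the
intersection of the two facing UTR intervals and is what the class
definitions test. `transcript_overlap_bp` is the intersection of the whole
transcript spans,

```
transcript_overlap = max(0, utr_up + utr_down − gap),
```

which can exceed `utr_overlap_bp` when one transcript reaches past the
partner's UTR into its ORF (e.g. 3′-UTRs of 53 and 9 bp with a 33 bp gap
overlap by 29 bp at the transcript level — more than the shorter UTR). The
closed form is proven equal to per-base interval intersection in the test
suite over 10,000 random geometries, including negative gaps.

If greedy adjacency ever assigns one gene to two convergent pairs (it
cannot for well-separated genomes, but can in principle),
`enforce_unique_convergent()` keeps the pair with the larger
`utr_overlap_bp`, breaking ties toward the leftmost pair.

## Expression statistics

`pair_correlation()` computes, for one condition, the Pearson correlation
between `log2` expression of upstream and downstream partners across all
pairs (at least 3 pairs required; constant vectors are an error naming the
offending side). Two p-values accompany it:

* `p_analytic`: the standard two-sided t-based p-value from
  `stats::cor.test`;
* `p_perm`: a one-sided permutation p-value **toward anti-correlation**.
  Downstream partners are shuffled `n_perm` times (default 10,000) and
  `p = (1 + #{r_perm ≤ r_obs}) / (n_perm + 1)` — add-one smoothing, so the
  p-value is never exactly 0 and is uniform under the null (verified by a
  Kolmogorov–Smirnov test in the suite).

Permutations are seeded: `correlate_all_conditions()` uses `seed + k` for
the *k*-th condition, so results are bit-identical across reruns. Each
condition (column) is tested independently; **no multiple-testing
correction** is applied, since the conditions are treated as replicate
views of the same hypothesis rather than a family of hypotheses.
Correlation point estimates and analytic p-values are symmetric in which
partner is called "up"; the permutation p-value is symmetric only in
distribution, since the shuffled side differs.

Other statistics:

* `utr_length_expression_correlation()` — Pearson correlation between a
  gene's 3′ (or 5′) UTR length and its expression in one sample;
* `single_cell_pair_correlation()` — Pearson correlation between two
  genes across cells (≥ 3 cells, exactly 2 genes);
* `relative_expression_ddct()` — fold change
  `2^−((Ct_target,test − Ct_ref,test) − (Ct_target,ctrl − Ct_ref,ctrl))`.

Expression files are TSV with `gene_id` first; linear-scale input is
transformed as `log2(x + pseudocount)` with pseudocount 1.

## Cross-dataset validation

`validate_pairs()` takes convergent pairs called in a reference dataset
and a second dataset (annotation + coverage). Genes missing from the
second annotation are an error listing the offending IDs. The expression
gate is applied first: if either partner's mean ORF coverage is below
`expr_min_mean_cov`, the pair is `partner_unexpressed` (this takes
precedence). Otherwise UTRs are re-called and pairs re-classified in the
second dataset; the pair is `confirmed` if it reappears as convergent (in
either gene order), else `not_confirmed`. `summarize_validation()` reports
counts and percentages (one decimal place).

## The synthetic generator

`simulate_genome()` plants a genome whose pair classes and UTR lengths are
known exactly, so recovery can be tested with zero tolerance. Design:

* Each planted unit is a **motif** — a convergent pair, divergent pair,
  consistent pair, or isolated gene — laid left to right and assigned
  round-robin across `n_chromosomes` (default 16) with `spacing` = 700 bp
  between motifs, which guarantees no *unplanned* adjacent-pair overlaps
  (UTRs are capped at 600 bp).
* ORF lengths are uniform on `orf_len_range` (default 300–1500 bp), UTRs
  uniform on `utr3_len_range` / `utr5_len_range` (default 9–211 bp).
* Convergent and divergent gaps are drawn from `[1, u_a + u_b − 1]`, which
  forces a facing-UTR overlap of at least 1 bp — every planted pair is a
  true pair.
* **Consistent motifs need care**: on a shared strand the two genes'
  coverage merges into one block, so interior UTR lengths are not
  independently identifiable from coverage. The generator therefore
  samples the ORF geometry and *derives* the interior UTR truths from the
  merged-block geometry (`u3_up = L2 − v + u3_down`,
  `u5_down = L1 − v + u5_up` for ORF lengths `L1`, `L2` and ORF overlap
  `v ∈ [50, 150]`), so that what the caller recovers from the merged
  coverage is exactly the planted truth. This is a modelling choice, not a
  caller bug: the identifiability limit is real for any coverage-based
  caller.

`simulate_coverage()` paints `depth` reads/base (default 10) over each
transcript span on its own strand; `noise = "poisson"` replaces constants
with Poisson draws (mean `depth`), `zero_genes` silences chosen genes.
`simulate_expression()` draws bivariate-normal log2 values with an exact
target correlation structure (`down = μ + σ(r·z₁ + √(1−r²)·z₂)`);
`simulate_single_cell()` adds optional dropout (zeros with probability
`dropout_p`). `simulate_validation_statuses()` /
`simulate_validation_coverage()` plant validation partitions by zeroing a
gene (→ `partner_unexpressed`) or shrinking both 3′-UTRs to
`⌊(gap−1)/2⌋` so they can no longer meet (→ `not_confirmed`).

What the generator does **not** emulate: read-level sampling (fragments,
mappability, library-size variation), overlapping motifs or interleaved
genes, nucleosome/terminator sequence signals, UTR length distributions
beyond uniform, or biological dropout structure beyond independent
Bernoulli zeros. It is a correctness instrument, not a data model.

All randomness goes through `withr::with_seed`; identical seeds give
byte-identical outputs, including exported GFF files (the GFF writer
strips the exporter's date pragma and writes `##sequence-region` lines so
reruns are file-identical).

## Problem sizes used in testing

The package's own test suite exercises genome-realistic scales: planted
genomes up to 645 convergent + 53 divergent + 65 consistent pairs
(~1,600 genes), expression matrices of 645 pairs × 7 conditions,
single-cell profiles of 1,000 cells, 10,000-case property checks of the
overlap arithmetic, and 500-replicate calibration of the permutation
p-value. The full suite runs in under a minute.

## Limitations and open choices

* UTR calling uses coverage only; it cannot separate two same-strand
  transcripts whose coverage merges (see the consistent-motif discussion
  above) and does not trim a called UTR at a downstream neighbour's ORF —
  a long 3′-UTR may legitimately extend over the neighbour, which is
  precisely the phenomenon of interest.
* `max_utr_len` = 600 bp is a hard cap appropriate for compact genomes;
  raise it for organisms with long UTRs.
* Only **adjacent** gene pairs are classified; triplet or nested
  arrangements reduce to their adjacent constituents.
* Pearson correlation on log2 values is the only association measure;
  heavy-tailed expression may warrant rank-based alternatives.
* The permutation test shuffles downstream partners across pairs within a
  condition; it does not model shared-condition covariance between pairs
  (pairs are treated as exchangeable).
* Per-condition results are reported without multiple-testing correction,
  as discussed above.
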