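#' Transcript-level overlap of a convergent pair from UTR lengths and gap
#'
#' For two convergent genes whose facing stop-codon boundaries are `gap_bp`
#' apart, the transcripts overlap over
#' `max(0, utr3_up + utr3_down - gap_bp)` bases: each 3'-UTR runs into the
#' intergenic gap from its own side, and whatever the two extensions cover
#' beyond the gap is shared. The value equals a per-base intersection of the
#' two transcript intervals (see [interval_overlap()]), and can exceed either
#' single UTR when one transcript crosses the partner's stop codon.
#'
#' @param utr3_up,utr3_down 3'-UTR lengths in bases (>= 0); vectorized.
#' @param gap_bp Distance in bases between the facing stop-codon boundaries;
#'   may be negative when the ORFs themselves overlap.
#' @return Overlap length(s) in bases, floored at 0.
#' @export
transcript_overlap <- function(utr3_up, utr3_down, gap_bp) {
  if (any(utr3_up < 0) || any(utr3_down < 0)) {
    abort("UTR lengths must be >= 0")
  }
  pmax(0, utr3_up + utr3_down - gap_bp)
}

#' Length of the intersection of two half-open intervals
#'
#' @param start1,end1,start2,end2 Interval bounds, 0-based half-open;
#'   vectorized.
#' @return `max(0, min(end1, end2) - max(start1, start2))`.
#' @export
interval_overlap <- function(start1, end1, start2, end2) {
  pmax(0, pmin(end1, end2) - pmax(start1, start2))
}

# The genomic interval covered by a gene's 3'-UTR (or 5'-UTR), strand-aware.
utr3_interval <- function(models) {
  plus <- models$strand == "+"
  tibble(
    start = ifelse(plus, models$orf_end, models$orf_start - models$utr3_len),
    end = ifelse(plus, models$orf_end + models$utr3_len, models$orf_start)
  )
}

utr5_interval <- function(models) {
  plus <- models$strand == "+"
  tibble(
    start = ifelse(plus, models$orf_start - models$utr5_len, models$orf_end),
    end = ifelse(plus, models$orf_start, models$orf_end + models$utr5_len)
  )
}

#' Classify adjacent gene pairs by orientation and overlap
#'
#' Genes adjacent in ORF start order on the same chromosome are examined
#' pairwise (`up` is the leftmost). A pair is emitted only when the
#' class-defining overlap is at least 1 base:
#'
#' * **convergent** — `up` on `+`, `down` on `-`, 3' ends facing, and the
#'   two 3'-UTR intervals intersect;
#' * **divergent** — `up` on `-`, `down` on `+`, 5' ends facing, and the
#'   two 5'-UTR intervals intersect;
#' * **consistent** — same strand and the transcript spans intersect.
#'
#' Each pair carries `gap_bp` (distance between the facing ORF boundaries;
#' negative when the ORFs overlap), `utr_overlap_bp` (intersection of the
#' facing UTR intervals) and `transcript_overlap_bp` (intersection of the
#' full transcript spans; always >= `utr_overlap_bp`). A gene may pair with
#' both neighbours, but joins at most one convergent pair: when both
#' neighbours qualify, the pair with the larger UTR overlap is kept, ties
#' going to the left neighbour.
#'
#' @param models A transcript-model tibble from [call_utrs()], sorted by
#'   chromosome and `orf_start` (unsorted input is an error).
#' @return A tibble with one row per emitted pair: `gene_up`, `gene_down`,
#'   `chrom`, `class`, `gap_bp`, `utr_overlap_bp`, `transcript_overlap_bp`.
#' @export
classify_pairs <- function(models) {
  empty <- tibble(gene_up = character(), gene_down = character(),
                  chrom = character(), class = character(),
                  gap_bp = numeric(), utr_overlap_bp = numeric(),
                  transcript_overlap_bp = numeric())
  if (nrow(models) < 2) return(empty)
  sorted <- unlist(lapply(split(models$orf_start, models$chrom),
                          function(x) !is.unsorted(x)))
  if (!all(sorted)) {
    abort(paste0("transcript models must be sorted by orf_start within ",
                 "chromosome; unsorted: ",
                 paste(names(sorted)[!sorted], collapse = ", ")))
  }

  i <- seq_len(nrow(models) - 1)
  same_chrom <- models$chrom[i] == models$chrom[i + 1]
  up <- models[i[same_chrom], ]
  down <- models[i[same_chrom] + 1, ]
  if (nrow(up) == 0) return(empty)

  u3_up <- utr3_interval(up); u3_down <- utr3_interval(down)
  u5_up <- utr5_interval(up); u5_down <- utr5_interval(down)
  tx_ov <- interval_overlap(up$tx_start, up$tx_end, down$tx_start, down$tx_end)
  gap <- down$orf_start - up$orf_end

  conv <- up$strand == "+" & down$strand == "-"
  dive <- up$strand == "-" & down$strand == "+"
  same <- up$strand == down$strand

  utr_ov <- numeric(nrow(up))
  utr_ov[conv] <- interval_overlap(u3_up$start[conv], u3_up$end[conv],
                                   u3_down$start[conv], u3_down$end[conv])
  utr_ov[dive] <- interval_overlap(u5_up$start[dive], u5_up$end[dive],
                                   u5_down$start[dive], u5_down$end[dive])
  # same-strand pairs: the facing UTRs are up's right-end UTR and down's
  # left-end UTR (3'/5' on +/+, 5'/3' on -/-)
  utr_ov[same] <- ifelse(up$strand[same] == "+",
                         interval_overlap(u3_up$start[same], u3_up$end[same],
                                          u5_down$start[same], u5_down$end[same]),
                         interval_overlap(u5_up$start[same], u5_up$end[same],
                                          u3_down$start[same], u3_down$end[same]))

  cls <- rep(NA_character_, nrow(up))
  cls[conv & utr_ov >= 1] <- "convergent"
  cls[dive & utr_ov >= 1] <- "divergent"
  cls[same & tx_ov >= 1] <- "consistent"

  keep <- !is.na(cls)
  pairs <- tibble(
    gene_up = up$gene_id[keep],
    gene_down = down$gene_id[keep],
    chrom = up$chrom[keep],
    class = cls[keep],
    gap_bp = gap[keep],
    utr_overlap_bp = utr_ov[keep],
    transcript_overlap_bp = tx_ov[keep]
  )
  enforce_unique_convergent(pairs)
}

# A gene has one 3' end, so it belongs to at most one convergent pair.
# Under anomalous annotations both neighbours can qualify; keep the pair
# with the larger UTR overlap, ties to the left (earlier) neighbour.
enforce_unique_convergent <- function(pairs) {
  conv_idx <- which(pairs$class == "convergent")
  if (length(conv_idx) < 2) return(pairs)
  ord <- conv_idx[order(-pairs$utr_overlap_bp[conv_idx], conv_idx)]
  used <- character(0)
  drop <- integer(0)
  for (k in ord) {
    g <- c(pairs$gene_up[k], pairs$gene_down[k])
    if (any(g %in% used)) drop <- c(drop, k) else used <- c(used, g)
  }
  if (length(drop) > 0) pairs <- pairs[-drop, ]
  pairs
}

#' Tally pair classes genome-wide
#'
#' @param pairs A pair tibble from [classify_pairs()].
#' @param annot The annotation (or transcript models) the pairs came from,
#'   or directly the total gene count.
#' @return One-row tibble: `n_convergent`, `n_divergent`, `n_consistent`,
#'   `n_genes_total`, and `convergent_gene_fraction` — the fraction of all
#'   genes that sit in a convergent pair, `2 * n_convergent / n_genes_total`.
#' @export
summarize_pairs <- function(pairs, annot) {
  n_genes <- if (is.data.frame(annot)) nrow(annot) else as.numeric(annot)
  if (n_genes <= 0) abort("total gene count must be positive")
  tibble(
    n_convergent = sum(pairs$class == "convergent"),
    n_divergent = sum(pairs$class == "divergent"),
    n_consistent = sum(pairs$class == "consistent"),
    n_genes_total = n_genes,
    convergent_gene_fraction = 2 * sum(pairs$class == "convergent") / n_genes
  )
}
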