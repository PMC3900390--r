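#' Confirm reference convergent pairs in a second dataset
#'
#' Re-runs the full UTR-calling and classification pipeline on the second
#' dataset's coverage, then assigns each reference pair one of three
#' mutually exclusive statuses:
#'
#' * `partner_unexpressed` — at least one of the two genes has mean ORF
#'   coverage below `expr_min_mean_cov` in the second dataset. This gate is
#'   checked first: a pair is only ever "not confirmed" when both genes are
#'   expressed.
#' * `confirmed` — both genes expressed and the pair is re-identified as
#'   convergent with overlapping 3'-UTRs (>= 1 base) in the second dataset.
#' * `not_confirmed` — both genes expressed but the re-called UTRs no longer
#'   overlap.
#'
#' @param ref_pairs Reference pair tibble (normally the convergent subset
#'   from [classify_pairs()]).
#' @param other_annot Annotation of the second dataset; every gene named in
#'   `ref_pairs` must be present (missing genes are an error).
#' @param other_cov Coverage track of the second dataset.
#' @param params [utr_call_params()]; `expr_min_mean_cov` is the expression
#'   gate.
#' @return Tibble with one row per reference pair: `gene_up`, `gene_down`,
#'   `status`.
#' @export
validate_pairs <- function(ref_pairs, other_annot, other_cov,
                           params = utr_call_params()) {
  needed <- unique(c(ref_pairs$gene_up, ref_pairs$gene_down))
  missing_ids <- setdiff(needed, other_annot$gene_id)
  if (length(missing_ids) > 0) {
    abort(paste0("gene(s) absent from second dataset's annotation: ",
                 paste(head(missing_ids, 10), collapse = ", ")))
  }
  genes <- as_tibble(other_annot)
  expressed <- setNames(mean_orf_coverage(genes, other_cov) >=
                          params$expr_min_mean_cov,
                        genes$gene_id)
  models <- call_utrs(other_annot, other_cov, params)
  other_pairs <- classify_pairs(models)
  conv <- other_pairs[other_pairs$class == "convergent", ]
  conv_key <- c(paste(conv$gene_up, conv$gene_down),
                paste(conv$gene_down, conv$gene_up))

  status <- dplyr::case_when(
    !expressed[ref_pairs$gene_up] | !expressed[ref_pairs$gene_down] ~
      "partner_unexpressed",
    paste(ref_pairs$gene_up, ref_pairs$gene_down) %in% conv_key ~ "confirmed",
    TRUE ~ "not_confirmed"
  )
  tibble(gene_up = ref_pairs$gene_up, gene_down = ref_pairs$gene_down,
         status = unname(status))
}

#' Summarize a validation run
#'
#' @param records Validation tibble from [validate_pairs()] (or any tibble
#'   with a `status` column over the three validation statuses).
#' @return One-row tibble: `n_total`, `n_confirmed`, `n_partner_unexpressed`,
#'   `n_not_confirmed`, plus `pct_confirmed` and `pct_partner_unexpressed`
#'   as percentages rounded to one decimal. Counts always sum to `n_total`.
#' @export
summarize_validation <- function(records) {
  if (nrow(records) == 0) abort("no validation records to summarize")
  bad <- setdiff(unique(records$status),
                 c("confirmed", "partner_unexpressed", "not_confirmed"))
  if (length(bad) > 0) {
    abort(paste0("unknown validation status: ", paste(bad, collapse = ", ")))
  }
  n <- nrow(records)
  n_conf <- sum(records$status == "confirmed")
  n_unexpr <- sum(records$status == "partner_unexpressed")
  tibble(
    n_total = n,
    n_confirmed = n_conf,
    n_partner_unexpressed = n_unexpr,
    n_not_confirmed = n - n_conf - n_unexpr,
    pct_confirmed = round(100 * n_conf / n, 1),
    pct_partner_unexpressed = round(100 * n_unexpr / n, 1)
  )
}
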