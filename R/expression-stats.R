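#' Read (or write) a gene expression matrix from TSV
#'
#' The on-disk contract is a TSV whose first column is `gene_id` and whose
#' remaining columns are samples (conditions or cells). Analysis is always
#' performed on the log2 scale: linear-scale input is transformed with
#' `log2(x + pseudocount)` on read.
#'
#' @param path Path to the TSV.
#' @param scale Scale of the stored values: `"log2"` (default, used as-is)
#'   or `"linear"` (log2-transformed with a pseudocount).
#' @param pseudocount Added before log2 of linear-scale data. Default 1.
#' @return A tibble: `gene_id` plus one numeric column per sample, on the
#'   log2 scale.
#' @export
read_expression <- function(path, scale = c("log2", "linear"), pseudocount = 1) {
  scale <- match.arg(scale)
  expr <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
  if (names(expr)[1] != "gene_id") {
    abort("expression TSV must have 'gene_id' as its first column")
  }
  vals <- as.matrix(expr[, -1])
  if (any(!is.finite(vals))) abort("expression values must be finite")
  if (anyDuplicated(expr$gene_id)) abort("duplicate gene_id in expression matrix")
  if (scale == "linear") {
    if (any(vals < 0)) abort("linear-scale expression must be >= 0")
    expr[, -1] <- log2(vals + pseudocount)
  }
  expr
}

#' @rdname read_expression
#' @param expr An expression tibble (`gene_id` + sample columns).
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

# Matched expression vectors for the two sides of each pair in one sample,
# dropping pairs with either gene absent.
pair_expression_xy <- function(pairs, expr, sample_id) {
  if (!sample_id %in% names(expr)) {
    abort(paste0("sample ", sample_id, " absent from expression matrix"))
  }
  v <- setNames(expr[[sample_id]], expr$gene_id)
  x <- v[pairs$gene_up]
  y <- v[pairs$gene_down]
  ok <- !is.na(x) & !is.na(y)
  list(x = unname(x[ok]), y = unname(y[ok]))
}

#' Anti-correlation of expression across convergent pairs in one condition
#'
#' For each pair, the point (log2 expression of the upstream gene, log2
#' expression of the downstream gene) is taken in the given sample; the
#' Pearson correlation over pairs measures transcriptional interference
#' (anti-regulation gives r < 0). Two p-values are reported: the analytic
#' two-sided p from the t transform of r, and a one-sided permutation p
#' toward anti-correlation, obtained by shuffling downstream partners across
#' pairs — which preserves each gene's marginal distribution — with add-one
#' smoothing: `p = (1 + #\{r_perm <= r_obs\}) / (n_perm + 1)`.
#'
#' @param pairs A pair tibble ([classify_pairs()]), normally the convergent
#'   subset. Pairs with either gene missing from `expr` are dropped.
#' @param expr An expression tibble from [read_expression()].
#' @param sample_id Column of `expr` to analyse.
#' @param n_perm Number of partner shuffles. Default 10000.
#' @param seed Integer seed for the shuffles; fixed seed gives bit-identical
#'   `p_perm`.
#' @return An object of class `pair_cor` (also a one-row tibble):
#'   `sample_id`, `n_pairs`, `r`, `p_analytic`, `p_perm`, `n_perm`.
#' @export
pair_correlation <- function(pairs, expr, sample_id, n_perm = 10000,
                             seed = NULL) {
  xy <- pair_expression_xy(pairs, expr, sample_id)
  x <- xy$x; y <- xy$y
  if (length(x) < 3) {
    abort(paste0("need >= 3 pairs with both genes measured; have ", length(x)))
  }
  if (stats::sd(x) == 0) abort("upstream expression is constant across pairs")
  if (stats::sd(y) == 0) abort("downstream expression is constant across pairs")
  r_obs <- cor(x, y)
  p_analytic <- cor.test(x, y)$p.value
  shuffle <- function() {
    r_perm <- vapply(seq_len(n_perm), function(b) cor(x, sample(y)), numeric(1))
    (1 + sum(r_perm <= r_obs)) / (n_perm + 1)
  }
  p_perm <- if (is.null(seed)) shuffle() else withr::with_seed(seed, shuffle())
  out <- tibble(sample_id = sample_id, n_pairs = length(x), r = r_obs,
                p_analytic = p_analytic, p_perm = p_perm, n_perm = n_perm)
  class(out) <- c("pair_cor", class(out))
  out
}

#' Pair anti-correlation across every condition of an expression matrix
#'
#' Runs [pair_correlation()] on each sample column independently (no
#' averaging of replicate columns, no multiple-testing correction across
#' conditions — per-condition p-values are reported raw).
#'
#' @inheritParams pair_correlation
#' @param seed Base seed; condition `k` uses `seed + k` so reruns are
#'   bit-identical while shuffles stay independent across conditions.
#' @return An object of class `conv_cor` wrapping the per-condition results;
#'   see [tidy.conv_cor()] and [glance.conv_cor()].
#' @export
correlate_all_conditions <- function(pairs, expr, n_perm = 10000, seed = NULL) {
  samples <- setdiff(names(expr), "gene_id")
  if (length(samples) == 0) abort("expression matrix has no sample columns")
  results <- purrr::map_dfr(seq_along(samples), function(k) {
    s <- if (is.null(seed)) NULL else seed + k
    pair_correlation(pairs, expr, samples[k], n_perm = n_perm, seed = s)
  })
  structure(list(results = as_tibble(results), n_perm = n_perm, seed = seed),
            class = "conv_cor")
}

#' @export
print.conv_cor <- function(x, ...) {
  cat("Convergent-pair expression correlation across",
      nrow(x$results), "condition(s)\n")
  cat(sprintf("  r range: [%.4f, %.4f]\n",
              min(x$results$r), max(x$results$r)))
  print(x$results)
  invisible(x)
}

#' Tidy the per-condition correlation results
#'
#' @param x A `conv_cor` object from [correlate_all_conditions()].
#' @param ... Unused.
#' @return Tibble with one row per condition: `sample_id`, `n_pairs`, `r`,
#'   `p_analytic`, `p_perm`, `n_perm`.
#' @method tidy conv_cor
#' @export
tidy.conv_cor <- function(x, ...) {
  as_tibble(x$results)
}

#' One-row summary of a cross-condition correlation analysis
#'
#' @inheritParams tidy.conv_cor
#' @return One-row tibble: `n_conditions`, `n_pairs` (minimum across
#'   conditions), `r_min`, `r_max`, `p_analytic_max`, `p_perm_max`.
#' @method glance conv_cor
#' @export
glance.conv_cor <- function(x, ...) {
  tibble(
    n_conditions = nrow(x$results),
    n_pairs = min(x$results$n_pairs),
    r_min = min(x$results$r),
    r_max = max(x$results$r),
    p_analytic_max = max(x$results$p_analytic),
    p_perm_max = max(x$results$p_perm)
  )
}

#' Correlation between called UTR length and expression level
#'
#' Pearson correlation between a gene's called UTR length (3' or 5') and its
#' log2 expression in one sample, over genes with a UTR of at least 1 base.
#' A genome-wide negative value for the 3' side indicates that long 3'-UTRs
#' — the substrate of convergent overlap — accompany lower expression.
#'
#' @param models Transcript models from [call_utrs()].
#' @param expr Expression tibble.
#' @param sample_id Column of `expr` to use.
#' @param utr_side `"3"` (default) or `"5"`.
#' @return One-row tibble: `n_genes`, `r`, `p_analytic`.
#' @export
utr_length_expression_correlation <- function(models, expr, sample_id,
                                              utr_side = c("3", "5")) {
  utr_side <- match.arg(utr_side)
  len <- if (utr_side == "3") models$utr3_len else models$utr5_len
  v <- setNames(expr[[sample_id]], expr$gene_id)
  e <- v[models$gene_id]
  ok <- len >= 1 & !is.na(e)
  len <- len[ok]; e <- unname(e[ok])
  if (length(len) < 3) abort("need >= 3 genes with a called UTR and expression")
  if (stats::sd(len) == 0) abort("degenerate input: all UTR lengths equal")
  if (stats::sd(e) == 0) abort("degenerate input: expression constant")
  ct <- cor.test(len, e)
  tibble(n_genes = length(len), r = unname(ct$estimate), p_analytic = ct$p.value)
}

#' Expression correlation of one gene pair across single cells
#'
#' Pearson correlation between the two genes' log2 expression profiles
#' across cells. Linear-scale input is transformed with `log2(x + 1)`.
#'
#' @param cell_expr Expression tibble restricted to exactly two genes
#'   (`gene_id` + one column per cell).
#' @param scale `"log2"` (default) or `"linear"`.
#' @return One-row tibble: `gene1`, `gene2`, `n_cells`, `r`, `p_analytic`.
#' @export
single_cell_pair_correlation <- function(cell_expr, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (nrow(cell_expr) != 2) {
    abort(paste0("expected exactly 2 genes, got ", nrow(cell_expr)))
  }
  m <- as.matrix(cell_expr[, -1])
  if (ncol(m) < 3) abort(paste0("need >= 3 cells; have ", ncol(m)))
  if (scale == "linear") m <- log2(m + 1)
  if (stats::sd(m[1, ]) == 0 || stats::sd(m[2, ]) == 0) {
    abort("constant expression profile; correlation undefined")
  }
  ct <- cor.test(m[1, ], m[2, ])
  tibble(gene1 = cell_expr$gene_id[1], gene2 = cell_expr$gene_id[2],
         n_cells = ncol(m), r = unname(ct$estimate), p_analytic = ct$p.value)
}

#' Relative expression by the delta-delta-Ct method
#'
#' qPCR relative quantification: with target and reference Ct values in a
#' test and a control (calibrator) sample, the fold ratio of normalized
#' target concentration is
#' `2^-((ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl))`.
#'
#' @param ct_target_test,ct_ref_test,ct_target_ctrl,ct_ref_ctrl PCR cycle
#'   threshold numbers; vectorized.
#' @return Fold ratio(s); 1 means no change, below 1 means lower relative
#'   target concentration in the test sample.
#' @export
relative_expression_ddct <- function(ct_target_test, ct_ref_test,
                                     ct_target_ctrl, ct_ref_ctrl) {
  ct <- cbind(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(ct))) abort("all Ct values must be finite")
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
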