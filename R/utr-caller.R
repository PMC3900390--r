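#' Parameters controlling UTR calling and the expression gate
#'
#' @param min_cov Minimum per-base read count (reads/base) for a base to
#'   count as covered during UTR extension. Default 1.
#' @param max_gap Longest run of sub-threshold bases tolerated inside a UTR
#'   before extension stops. Default 5 bases.
#' @param max_utr_len Hard cap on called UTR length. Default 600 bases,
#'   well above 3'-UTR lengths typical of compact genomes.
#' @param expr_min_mean_cov Mean ORF coverage (reads/base) below which a gene
#'   is treated as unexpressed when confirming pairs across datasets.
#'   Default 1.
#' @return A list of class `utr_call_params`.
#' @export
utr_call_params <- function(min_cov = 1, max_gap = 5, max_utr_len = 600,
                            expr_min_mean_cov = 1) {
  vals <- c(min_cov = min_cov, max_gap = max_gap, max_utr_len = max_utr_len,
            expr_min_mean_cov = expr_min_mean_cov)
  if (any(vals < 0)) abort("all UTR-calling parameters must be >= 0")
  structure(as.list(vals), class = "utr_call_params")
}

# Walk along `v` (coverage ordered in the direction of extension, element 1
# being the first base past the ORF boundary): extend while covered,
# tolerating sub-threshold runs no longer than max_gap, and trim trailing
# sub-threshold bases. Returns the number of bases extended.
scan_extension <- function(v, min_cov, max_gap) {
  idx <- which(v >= min_cov)
  if (length(idx) == 0) return(0)
  if (idx[1] - 1 > max_gap) return(0)
  gaps <- diff(idx) - 1
  brk <- which(gaps > max_gap)
  if (length(brk) == 0) idx[length(idx)] else idx[brk[1]]
}

# Extract coverage downstream/upstream of a boundary in walk order.
# `boundary` is the 0-based coordinate of the ORF edge; direction +1 walks
# right over bases boundary, boundary+1, ...; direction -1 walks left over
# bases boundary-1, boundary-2, ...
walk_vector <- function(covvec, boundary, direction, max_len) {
  n <- length(covvec)
  if (direction > 0) {
    from <- boundary + 1                    # R index of 0-based base `boundary`
    if (from > n) return(numeric(0))
    to <- min(n, boundary + max_len)
    covvec[from:to]
  } else {
    to <- boundary                          # R index of 0-based base boundary-1
    if (to < 1) return(numeric(0))
    from <- max(1, boundary - max_len + 1)
    rev(covvec[from:to])
  }
}

#' Call the 3'-UTR length of each gene from strand-specific coverage
#'
#' Starting just past the stop-codon boundary, extension proceeds in the 3'
#' direction (rightward on `+`, leftward on `-`) along the gene's own strand
#' only — antisense reads never contribute. Extension continues while
#' coverage is at least `min_cov`, tolerates interior sub-threshold runs up
#' to `max_gap` bases, trims trailing sub-threshold bases, and is capped at
#' `max_utr_len` and the chromosome end.
#'
#' @param genes A data frame of gene records (see [annotation()]).
#' @param cov A `conv_coverage` track covering every chromosome in `genes`.
#' @param params A [utr_call_params()] list.
#' @return Numeric vector of 3'-UTR lengths in bases (0 allowed), one per gene.
#' @export
call_utr3 <- function(genes, cov, params = utr_call_params()) {
  vapply(seq_len(nrow(genes)), function(i) {
    v <- coverage_vector(cov, genes$chrom[i], genes$strand[i])
    boundary <- if (genes$strand[i] == "+") genes$orf_end[i] else genes$orf_start[i]
    direction <- if (genes$strand[i] == "+") 1 else -1
    w <- walk_vector(v, boundary, direction, params$max_utr_len)
    scan_extension(w, params$min_cov, params$max_gap)
  }, numeric(1))
}

#' Call the 5'-UTR length of each gene (mirror of [call_utr3()])
#'
#' Extension runs upstream of the start-codon boundary in the 5' direction:
#' leftward on `+`, rightward on `-`, on the gene's own strand.
#'
#' @inheritParams call_utr3
#' @return Numeric vector of 5'-UTR lengths in bases.
#' @export
call_utr5 <- function(genes, cov, params = utr_call_params()) {
  vapply(seq_len(nrow(genes)), function(i) {
    v <- coverage_vector(cov, genes$chrom[i], genes$strand[i])
    boundary <- if (genes$strand[i] == "+") genes$orf_start[i] else genes$orf_end[i]
    direction <- if (genes$strand[i] == "+") -1 else 1
    w <- walk_vector(v, boundary, direction, params$max_utr_len)
    scan_extension(w, params$min_cov, params$max_gap)
  }, numeric(1))
}

#' Build transcript models for every gene in an annotation
#'
#' Calls both UTRs for each gene and derives the transcript span:
#' `tx_start = orf_start - utr5_len`, `tx_end = orf_end + utr3_len` on the
#' `+` strand, mirrored on `-`. Spans are already capped at the chromosome
#' ends via the UTR walk.
#'
#' @param annot An annotation tibble.
#' @param cov A `conv_coverage` track.
#' @param params A [utr_call_params()] list.
#' @return A tibble of transcript models: `gene_id`, `chrom`, `strand`,
#'   `orf_start`, `orf_end`, `utr5_len`, `utr3_len`, `tx_start`, `tx_end`,
#'   sorted like the annotation.
#' @seealso [utr_call_summary()] for genome-wide UTR tallies.
#' @export
call_utrs <- function(annot, cov, params = utr_call_params()) {
  models <- as_tibble(annot)[, c("gene_id", "chrom", "strand",
                                 "orf_start", "orf_end")]
  if (nrow(models) == 0) {
    models$utr5_len <- numeric(0)
    models$utr3_len <- numeric(0)
    models$tx_start <- numeric(0)
    models$tx_end <- numeric(0)
    return(models)
  }
  models$utr5_len <- call_utr5(models, cov, params)
  models$utr3_len <- call_utr3(models, cov, params)
  transcript_span(models)
}

# Derive tx_start/tx_end from ORF coordinates and UTR lengths, strandedly.
transcript_span <- function(models) {
  plus <- models$strand == "+"
  models$tx_start <- ifelse(plus,
                            models$orf_start - models$utr5_len,
                            models$orf_start - models$utr3_len)
  models$tx_end <- ifelse(plus,
                          models$orf_end + models$utr3_len,
                          models$orf_end + models$utr5_len)
  models
}

#' Genome-wide UTR tallies
#'
#' @param models A transcript-model tibble from [call_utrs()].
#' @return One-row tibble: `n_genes`, `n_utr5` (genes with a called 5'-UTR of
#'   at least 1 base), `n_utr3` (likewise for 3'-UTRs).
#' @export
utr_call_summary <- function(models) {
  tibble(
    n_genes = nrow(models),
    n_utr5 = sum(models$utr5_len >= 1),
    n_utr3 = sum(models$utr3_len >= 1)
  )
}

#' Mean per-base ORF coverage on the gene's own strand
#'
#' The expression gate used when confirming pairs in a second dataset: a
#' gene with mean ORF coverage below `expr_min_mean_cov` is "unexpressed".
#'
#' @param genes A data frame of gene records.
#' @param cov A `conv_coverage` track.
#' @return Numeric vector, mean reads/base over `[orf_start, orf_end)`.
#' @export
mean_orf_coverage <- function(genes, cov) {
  vapply(seq_len(nrow(genes)), function(i) {
    v <- coverage_vector(cov, genes$chrom[i], genes$strand[i])
    mean(v[(genes$orf_start[i] + 1):genes$orf_end[i]])
  }, numeric(1))
}

#' Write or read a transcript-model table (TSV)
#'
#' @param models A transcript-model tibble from [call_utrs()].
#' @param path Output (or input) path.
#' @return `write_models()` returns `path` invisibly; `read_models()` the tibble.
#' @export
write_models <- function(models, path) {
  cols <- c("gene_id", "chrom", "strand", "orf_start", "orf_end",
            "utr5_len", "utr3_len", "tx_start", "tx_end")
  readr::write_tsv(models[, cols], path)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      chrom = readr::col_character(),
      strand = readr::col_character(),
      .default = readr::col_double()
    )
  )
}
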