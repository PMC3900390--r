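#' Build a strand-specific per-base coverage track
#'
#' A coverage track stores, for each chromosome and strand, one non-negative
#' read count per base. It is the input from which UTRs are called and ORF
#' expression is gated.
#'
#' @param counts A named list, one element per chromosome, each a list with
#'   elements `"+"` and `"-"` holding numeric vectors of equal length
#'   (the chromosome length in bases).
#' @return The validated track, classed `conv_coverage`.
#' @export
coverage_track <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("coverage track chromosomes must be named")
  }
  for (chrom in names(counts)) {
    strands <- counts[[chrom]]
    if (!all(c("+", "-") %in% names(strands))) {
      abort(paste0("coverage for chromosome ", chrom,
                   " must carry both '+' and '-' strands"))
    }
    if (length(strands[["+"]]) != length(strands[["-"]])) {
      abort(paste0("strand vectors differ in length on chromosome ", chrom))
    }
    if (any(strands[["+"]] < 0) || any(strands[["-"]] < 0)) {
      abort(paste0("negative coverage on chromosome ", chrom))
    }
  }
  structure(counts, class = "conv_coverage")
}

# Fetch the per-base vector for one chromosome/strand, with a named error.
coverage_vector <- function(cov, chrom, strand) {
  if (is.null(cov[[chrom]])) {
    abort(paste0("chromosome ", chrom, " absent from coverage track"))
  }
  v <- cov[[chrom]][[strand]]
  if (is.null(v)) {
    abort(paste0("strand ", strand, " absent from coverage of ", chrom))
  }
  v
}

#' Read strand-specific coverage from a pair of bedGraph files
#'
#' bedGraph carries no strand, so strand-specific coverage arrives as one
#' file per strand. Intervals (0-based half-open) are expanded to per-base
#' arrays; uncovered bases are 0.
#'
#' @param plus_path,minus_path bedGraph files for the `+` and `-` strand.
#' @param chrom_lengths Named numeric vector of chromosome lengths. When
#'   `NULL`, lengths default to the largest interval end seen per chromosome.
#' @return A `conv_coverage` track.
#' @export
read_strand_coverage <- function(plus_path, minus_path, chrom_lengths = NULL) {
  for (p in c(plus_path, minus_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  plus <- rtracklayer::import(plus_path, format = "bedGraph")
  minus <- rtracklayer::import(minus_path, format = "bedGraph")
  chroms <- union(as.character(GenomicRanges::seqnames(plus)),
                  as.character(GenomicRanges::seqnames(minus)))
  if (!is.null(chrom_lengths)) chroms <- union(chroms, names(chrom_lengths))
  expand <- function(gr, chrom, len) {
    v <- numeric(len)
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    if (length(gr) > 0) {
      s <- BiocGenerics::start(gr)       # 1-based after import
      e <- BiocGenerics::end(gr)
      for (i in seq_along(gr)) v[s[i]:e[i]] <- gr$score[i]
    }
    v
  }
  counts <- lapply(chroms, function(chrom) {
    len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      chrom_lengths[[chrom]]
    } else {
      max(0,
          BiocGenerics::end(plus[as.character(GenomicRanges::seqnames(plus)) == chrom]),
          BiocGenerics::end(minus[as.character(GenomicRanges::seqnames(minus)) == chrom]))
    }
    list("+" = expand(plus, chrom, len), "-" = expand(minus, chrom, len))
  })
  names(counts) <- chroms
  coverage_track(counts)
}

#' Write strand-specific coverage to a pair of bedGraph files
#'
#' @param cov A `conv_coverage` track.
#' @param plus_path,minus_path Output bedGraph paths for the two strands.
#' @return Invisibly, `c(plus_path, minus_path)`.
#' @export
write_strand_coverage <- function(cov, plus_path, minus_path) {
  one_strand <- function(strand) {
    segs <- lapply(names(cov), function(chrom) {
      v <- cov[[chrom]][[strand]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- r$values != 0
      list(chrom = rep(chrom, sum(keep)), start = starts[keep],
           end = ends[keep], score = r$values[keep])
    })
    GenomicRanges::GRanges(
      seqnames = unlist(lapply(segs, `[[`, "chrom")),
      ranges = IRanges::IRanges(
        start = unlist(lapply(segs, `[[`, "start")),
        end = unlist(lapply(segs, `[[`, "end"))
      ),
      score = unlist(lapply(segs, `[[`, "score"))
    )
  }
  rtracklayer::export(one_strand("+"), plus_path, format = "bedGraph")
  rtracklayer::export(one_strand("-"), minus_path, format = "bedGraph")
  invisible(c(plus_path, minus_path))
}
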