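#' Build an annotation table of gene records
#'
#' An annotation is a tibble of ORF records in a single internal coordinate
#' convention: 0-based, half-open `[orf_start, orf_end)`. Only the I/O layer
#' converts to and from on-disk conventions (GFF3 is 1-based closed, BED is
#' already 0-based half-open). Records are kept sorted by `chrom` then
#' `orf_start`, and per-chromosome sequence lengths travel with the table as
#' an attribute.
#'
#' @param genes A data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"` or `"-"`), `orf_start`, `orf_end` and optionally `source_line`.
#' @param chrom_lengths Optional named numeric vector of chromosome lengths
#'   (bases). When supplied, every gene must lie within `[0, length)`.
#' @return A tibble of class `conv_annotation`, sorted by chromosome and
#'   `orf_start`, with `chrom_lengths` stored as an attribute.
#' @seealso [read_gff()], [read_bed()], [chrom_lengths()]
#' @export
annotation <- function(genes, chrom_lengths = NULL) {
  genes <- as_tibble(genes)
  required <- c("gene_id", "chrom", "strand", "orf_start", "orf_end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"source_line" %in% names(genes)) genes$source_line <- NA_integer_
  genes <- genes[, c(required, "source_line")]
  if (nrow(genes) > 0) {
    bad_strand <- !genes$strand %in% c("+", "-")
    if (any(bad_strand)) {
      abort(paste0("strand must be '+' or '-'; offending gene(s): ",
                   paste(head(genes$gene_id[bad_strand], 5), collapse = ", ")))
    }
    bad_span <- genes$orf_end <= genes$orf_start
    if (any(bad_span)) {
      abort(paste0("orf_start must be < orf_end; offending gene(s): ",
                   paste(head(genes$gene_id[bad_span], 5), collapse = ", ")))
    }
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    if (length(dup) > 0) {
      abort(paste0("duplicate gene ID(s): ", paste(head(dup, 5), collapse = ", ")))
    }
    if (!is.null(chrom_lengths)) {
      len <- chrom_lengths[genes$chrom]
      out_of_range <- is.na(len) | genes$orf_start < 0 | genes$orf_end > len
      if (any(out_of_range)) {
        abort(paste0("gene(s) outside [0, chrom_length): ",
                     paste(head(genes$gene_id[out_of_range], 5), collapse = ", ")))
      }
    }
    genes <- dplyr::arrange(genes, .data$chrom, .data$orf_start, .data$orf_end)
  }
  attr(genes, "chrom_lengths") <- chrom_lengths
  class(genes) <- c("conv_annotation", class(genes))
  genes
}

#' Chromosome lengths stored with an annotation
#'
#' @param annot An annotation from [annotation()], [read_gff()] or [read_bed()].
#' @return Named numeric vector of chromosome lengths, or `NULL` when the
#'   source carried none (e.g. a BED file).
#' @export
chrom_lengths <- function(annot) {
  attr(annot, "chrom_lengths")
}

#' Stop-codon-adjacent transcript boundary of each gene
#'
#' The genomic coordinate just past the stop codon, i.e. where the 3'-UTR
#' begins: `orf_end` on the `+` strand and `orf_start` on the `-` strand
#' (0-based). The definition is strand-symmetric: mirroring the genome and
#' swapping strands maps boundaries onto boundaries.
#'
#' @param genes A data frame with `strand`, `orf_start`, `orf_end`.
#' @return Numeric vector of boundary coordinates.
#' @export
stop_boundary <- function(genes) {
  ifelse(genes$strand == "+", genes$orf_end, genes$orf_start)
}

#' Start-codon-adjacent transcript boundary (where the 5'-UTR begins)
#'
#' @inheritParams stop_boundary
#' @return Numeric vector: `orf_start` on `+`, `orf_end` on `-`.
#' @export
start_boundary <- function(genes) {
  ifelse(genes$strand == "+", genes$orf_start, genes$orf_end)
}

empty_annotation <- function(chrom_lengths = NULL) {
  annotation(tibble(gene_id = character(), chrom = character(),
                    strand = character(), orf_start = numeric(),
                    orf_end = numeric(), source_line = integer()),
             chrom_lengths = chrom_lengths)
}

# Pre-scan of a GFF3 file: validates coordinates and IDs so errors can name
# the offending line (the downstream parser reports none), and reads
# ##sequence-region pragmas for chromosome lengths.
scan_gff_lines <- function(path, feature_type, id_attr = "ID") {
  lines <- readr::read_lines(path)
  seq_region <- grep("^##sequence-region", lines, value = TRUE)
  chrom_lengths <- NULL
  if (length(seq_region) > 0) {
    parts <- strsplit(trimws(seq_region), "\\s+")
    chrom_lengths <- setNames(
      vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
      vapply(parts, function(p) p[2], character(1))
    )
  }
  is_data <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(is_data)
  keep_line <- integer(0)
  ids <- character(0)
  for (i in rows) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      abort(paste0("malformed GFF record at line ", i, ": fewer than 8 fields"))
    }
    if (!f[3] %in% feature_type) next
    s <- suppressWarnings(as.numeric(f[4]))
    e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || e < s) {
      abort(paste0("malformed GFF record at line ", i,
                   ": end (", f[5], ") < start (", f[4], ")"))
    }
    m <- regmatches(f[9], regexec(paste0("(^|;)\\s*", id_attr, "=([^;]+)"), f[9]))[[1]]
    if (length(m) < 3) {
      abort(paste0("GFF record at line ", i, " lacks an ", id_attr, " attribute"))
    }
    id <- m[3]
    if (id %in% ids) {
      abort(paste0("duplicate gene ID '", id, "' at line ", i))
    }
    ids <- c(ids, id)
    keep_line <- c(keep_line, i)
  }
  list(chrom_lengths = chrom_lengths, source_line = keep_line, ids = ids)
}

#' Read a gene annotation from GFF3
#'
#' Feature rows of the requested type are converted from GFF3's 1-based
#' closed coordinates to the internal 0-based half-open convention
#' (`orf_start = start - 1`, `orf_end = end`). `##sequence-region` pragmas,
#' when present, supply chromosome lengths.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type(s) (column 3) to read; default `"gene"`.
#'   Use `"CDS"` for annotations that carry ORFs as CDS features.
#' @param id_attr Attribute key holding the gene identifier (default `"ID"`).
#' @return An annotation tibble (see [annotation()]).
#' @export
read_gff <- function(path, feature_type = "gene", id_attr = "ID") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  scan <- scan_gff_lines(path, feature_type, id_attr)
  if (length(scan$source_line) == 0) {
    return(empty_annotation(scan$chrom_lengths))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    abort("GFF gene records must carry strand '+' or '-'")
  }
  genes <- tibble(
    gene_id = as.character(S4Vectors::mcols(gr)[[id_attr]]),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    orf_start = BiocGenerics::start(gr) - 1,
    orf_end = as.numeric(BiocGenerics::end(gr)),
    source_line = scan$source_line
  )
  annotation(genes, chrom_lengths = scan$chrom_lengths)
}

#' Read a gene annotation from BED6
#'
#' BED is natively 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged. All six columns are required; a
#' record without an explicit strand is an error.
#'
#' @param path Path to a BED6 file.
#' @return An annotation tibble (see [annotation()]). An empty file yields an
#'   empty annotation.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) return(empty_annotation())
  nfields <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nfields < 6)) {
    abort(paste0("BED6 requires 6 columns; line ", which(nfields < 6)[1],
                 " has ", nfields[nfields < 6][1]))
  }
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    abort("BED records must carry strand '+' or '-' in column 6")
  }
  genes <- tibble(
    gene_id = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    orf_start = BiocGenerics::start(gr) - 1,  # GRanges re-adds 1 on import
    orf_end = as.numeric(BiocGenerics::end(gr)),
    source_line = seq_along(gr)
  )
  annotation(genes)
}

#' Write a gene annotation to GFF3
#'
#' Inverse of [read_gff()]: internal 0-based half-open coordinates are
#' converted back to GFF3's 1-based closed convention, and chromosome
#' lengths (when present) are written as `##sequence-region` pragmas.
#'
#' @param annot An annotation tibble.
#' @param path Output path.
#' @param feature_type Feature type to write (default `"gene"`).
#' @return `path`, invisibly.
#' @export
write_gff <- function(annot, path, feature_type = "gene") {
  gr <- GenomicRanges::GRanges(
    seqnames = annot$chrom,
    ranges = IRanges::IRanges(start = annot$orf_start + 1, end = annot$orf_end),
    strand = annot$strand
  )
  gr$type <- feature_type
  gr$ID <- annot$gene_id
  cl <- chrom_lengths(annot)
  if (!is.null(cl)) {
    GenomeInfoDb::seqlevels(gr) <- names(cl)
    GenomeInfoDb::seqlengths(gr) <- cl
  }
  rtracklayer::export(gr, path, format = "gff3")
  # normalize the header: drop run-dependent pragmas (a rerun must be
  # byte-identical) and record chromosome lengths as ##sequence-region
  lines <- readLines(path)
  lines <- lines[!grepl("^##(date|source-version)", lines)]
  if (!is.null(cl)) {
    region <- sprintf("##sequence-region %s 1 %d", names(cl), as.integer(cl))
    lines <- c(lines[1], region, lines[-1])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write or read a gene-pair table (TSV)
#'
#' The pair table is the classifier's output contract: columns `gene_up`,
#' `gene_down`, `chrom`, `class`, `gap_bp`, `utr_overlap_bp`,
#' `transcript_overlap_bp`. `read_pairs(write_pairs(x))` reproduces `x`.
#'
#' @param pairs A pair tibble from [classify_pairs()].
#' @param path Output (or input) path.
#' @return `write_pairs()` returns `path` invisibly; `read_pairs()` returns
#'   the pair tibble.
#' @export
write_pairs <- function(pairs, path) {
  cols <- c("gene_up", "gene_down", "chrom", "class",
            "gap_bp", "utr_overlap_bp", "transcript_overlap_bp")
  missing_cols <- setdiff(cols, names(pairs))
  if (length(missing_cols) > 0) {
    abort(paste0("pair table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  readr::write_tsv(pairs[, cols], path)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_up = readr::col_character(),
      gene_down = readr::col_character(),
      chrom = readr::col_character(),
      class = readr::col_character(),
      gap_bp = readr::col_double(),
      utr_overlap_bp = readr::col_double(),
      transcript_overlap_bp = readr::col_double()
    )
  )
}
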