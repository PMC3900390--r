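# Fixture builders shared across test files. Everything is generated in
# code; no fixture files on disk.

# Coverage track from a segment table: columns chrom, strand, start, end
# (0-based half-open), depth. Uncovered bases are 0.
make_coverage <- function(chrom_lengths, segments = NULL) {
  counts <- lapply(chrom_lengths, function(len) {
    list("+" = numeric(len), "-" = numeric(len))
  })
  names(counts) <- names(chrom_lengths)
  if (!is.null(segments)) {
    for (i in seq_len(nrow(segments))) {
      with(segments[i, ], {
        counts[[chrom]][[strand]][(start + 1):end] <<-
          counts[[chrom]][[strand]][(start + 1):end] + depth
      })
    }
  }
  coverage_track(counts)
}

# One gene record as a one-row tibble.
make_gene <- function(gene_id = "g1", chrom = "chrI", strand = "+",
                      orf_start = 1000, orf_end = 1500) {
  tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                 orf_start = orf_start, orf_end = orf_end)
}

# Mirror a genome: coordinate p (0-based) maps to len - 1 - p, so the
# interval [s, e) maps to [len - e, len - s), and strands swap. Coverage
# vectors reverse and swap strands. Used for strand-symmetry properties.
mirror_genes <- function(genes, chrom_lengths) {
  len <- chrom_lengths[genes$chrom]
  out <- genes
  out$orf_start <- len - genes$orf_end
  out$orf_end <- len - genes$orf_start
  out$strand <- ifelse(genes$strand == "+", "-", "+")
  out[order(out$chrom, out$orf_start), ]
}

mirror_coverage <- function(cov) {
  counts <- lapply(cov, function(strands) {
    list("+" = rev(strands[["-"]]), "-" = rev(strands[["+"]]))
  })
  coverage_track(counts)
}

# Write a small GFF3 file and return its path.
write_gff_lines <- function(lines, dir = tempdir()) {
  path <- tempfile("anno", tmpdir = dir, fileext = ".gff3")
  writeLines(lines, path)
  path
}

# A small planted genome shared by several tests: a few pairs of each class.
small_sim <- function(seed = 42, n_convergent = 8, n_divergent = 4,
                      n_consistent = 4, n_isolated = 6) {
  simulate_genome(genome_sim_config(
    n_convergent = n_convergent, n_divergent = n_divergent,
    n_consistent = n_consistent, n_isolated = n_isolated,
    n_chromosomes = 3, seed = seed
  ))
}

# Classifier output restricted and ordered for truth comparison.
pair_key <- function(pairs) {
  pairs <- pairs[order(pairs$gene_up, pairs$gene_down), ]
  pairs[, c("gene_up", "gene_down", "chrom", "class", "gap_bp",
            "utr_overlap_bp", "transcript_overlap_bp")]
}
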