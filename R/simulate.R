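#' Configuration for the synthetic genome generator
#'
#' The generator plants gene-pair motifs — convergent, divergent, consistent
#' — and isolated genes on a multi-chromosome toy genome, recording the full
#' ground truth (UTR lengths, pair classes, gaps, overlaps) so every
#' pipeline stage can be checked exactly.
#'
#' Defaults mirror the genome-wide study conditions: 645 convergent, 53
#' divergent and 65 consistent pairs, UTR lengths drawn uniformly over
#' 9–211 bases (the span observed among characterized convergent 3'-UTRs),
#' ORFs 300–1500 bases, 16 chromosomes. Convergent (divergent) gaps are
#' sampled so the facing UTR intervals intersect by at least 1 base.
#'
#' @param n_convergent,n_divergent,n_consistent Planted pair counts.
#' @param n_isolated Genes planted without a partner.
#' @param utr3_len_range,utr5_len_range Integer ranges (bases) for sampled
#'   UTR lengths.
#' @param orf_len_range Integer range (bases) for ORF lengths. Same-strand
#'   (consistent) motifs internally cap ORFs at 420 bases so the merged
#'   coverage block stays below the 600-base caller cap.
#' @param n_chromosomes Chromosomes to spread motifs over.
#' @param spacing Bases between motif bounding boxes; large enough
#'   (default 700) that no unplanned pair can form.
#' @param chrom_length Optional fixed chromosome length; an error is raised
#'   if the planted motifs do not fit. `NULL` (default) sizes chromosomes to
#'   their content.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `genome_sim_config`.
#' @export
genome_sim_config <- function(n_convergent = 645, n_divergent = 53,
                              n_consistent = 65, n_isolated = 100,
                              utr3_len_range = c(9, 211),
                              utr5_len_range = c(9, 211),
                              orf_len_range = c(300, 1500),
                              n_chromosomes = 16, spacing = 700,
                              chrom_length = NULL, seed = 1) {
  counts <- c(n_convergent, n_divergent, n_consistent, n_isolated)
  if (any(counts < 0)) abort("planted counts must be >= 0")
  for (r in list(utr3_len_range, utr5_len_range, orf_len_range)) {
    if (length(r) != 2 || r[1] < 1 || r[2] < r[1]) {
      abort("distribution ranges must be positive increasing pairs")
    }
  }
  structure(list(
    n_convergent = n_convergent, n_divergent = n_divergent,
    n_consistent = n_consistent, n_isolated = n_isolated,
    utr3_len_range = utr3_len_range, utr5_len_range = utr5_len_range,
    orf_len_range = orf_len_range, n_chromosomes = n_chromosomes,
    spacing = spacing, chrom_length = chrom_length, seed = seed
  ), class = "genome_sim_config")
}

rint <- function(lo, hi) if (lo >= hi) lo else lo + sample.int(hi - lo + 1, 1) - 1

# Motif builders: local coordinates with the bounding box starting at 0
# (every transcript extent inside [0, width)). Each returns gene rows
# (with true UTR lengths) and the planted pair row, if any.

motif_convergent <- function(id, cfg) {
  u5a <- rint(cfg$utr5_len_range[1], cfg$utr5_len_range[2])
  u5b <- rint(cfg$utr5_len_range[1], cfg$utr5_len_range[2])
  ua <- rint(cfg$utr3_len_range[1], cfg$utr3_len_range[2])
  ub <- rint(cfg$utr3_len_range[1], cfg$utr3_len_range[2])
  L1 <- rint(cfg$orf_len_range[1], cfg$orf_len_range[2])
  L2 <- rint(cfg$orf_len_range[1], cfg$orf_len_range[2])
  g <- rint(1, ua + ub - 1)            # forces the 3'-UTR intervals to meet
  a <- u5a
  sB <- a + L1 + g
  genes <- tibble(
    gene_id = paste0(id, c("U", "D")),
    strand = c("+", "-"),
    orf_start = c(a, sB), orf_end = c(a + L1, sB + L2),
    utr5_len = c(u5a, u5b), utr3_len = c(ua, ub)
  )
  list(genes = genes, pair_class = "convergent",
       width = u5a + L1 + g + L2 + u5b)
}

motif_divergent <- function(id, cfg) {
  u3a <- rint(cfg$utr3_len_range[1], cfg$utr3_len_range[2])
  u3b <- rint(cfg$utr3_len_range[1], cfg$utr3_len_range[2])
  ua5 <- rint(cfg$utr5_len_range[1], cfg$utr5_len_range[2])
  ub5 <- rint(cfg$utr5_len_range[1], cfg$utr5_len_range[2])
  L1 <- rint(cfg$orf_len_range[1], cfg$orf_len_range[2])
  L2 <- rint(cfg$orf_len_range[1], cfg$orf_len_range[2])
  g <- rint(1, ua5 + ub5 - 1)          # facing 5'-UTR intervals must meet
  a <- u3a
  sB <- a + L1 + g
  genes <- tibble(
    gene_id = paste0(id, c("U", "D")),
    strand = c("-", "+"),
    orf_start = c(a, sB), orf_end = c(a + L1, sB + L2),
    utr5_len = c(ua5, ub5), utr3_len = c(u3a, u3b)
  )
  list(genes = genes, pair_class = "divergent",
       width = u3a + L1 + g + L2 + u3b)
}

# Same-strand overlapping ORFs. The two transcripts merge into one covered
# block on their shared strand, so the interior extensions (up gene's
# 3'-UTR, down gene's 5'-UTR) are whatever the merged block implies; the
# generator plants exactly those lengths so truth matches what coverage can
# show. Exterior UTRs are sampled freely.
motif_consistent <- function(id, cfg) {
  orf_hi <- min(cfg$orf_len_range[2], 420)
  orf_lo <- min(cfg$orf_len_range[1], orf_hi)
  L1 <- rint(orf_lo, orf_hi)
  L2 <- rint(orf_lo, orf_hi)
  v <- rint(50, min(150, L1 - 1, L2 - 1))   # ORF overlap
  s <- if (rint(0, 1) == 1) "+" else "-"
  ext_left <- rint(cfg$utr3_len_range[1], cfg$utr3_len_range[2])
  ext_right <- rint(cfg$utr3_len_range[1], cfg$utr3_len_range[2])
  a <- ext_left
  cstart <- a + L1 - v
  d <- cstart + L2
  if (s == "+") {
    # free: up 5'-UTR (left), down 3'-UTR (right);
    # derived: up 3'-UTR and down 5'-UTR span the merged block
    utr5 <- c(ext_left, L1 - v + ext_left)
    utr3 <- c(L2 - v + ext_right, ext_right)
  } else {
    # free: up 3'-UTR (left), down 5'-UTR (right)
    utr3 <- c(ext_left, L1 - v + ext_left)
    utr5 <- c(L2 - v + ext_right, ext_right)
  }
  genes <- tibble(
    gene_id = paste0(id, c("U", "D")),
    strand = c(s, s),
    orf_start = c(a, cstart), orf_end = c(a + L1, d),
    utr5_len = utr5, utr3_len = utr3
  )
  list(genes = genes, pair_class = "consistent",
       width = ext_left + L1 - v + L2 + ext_right)
}

motif_isolated <- function(id, cfg) {
  u5 <- rint(cfg$utr5_len_range[1], cfg$utr5_len_range[2])
  u3 <- rint(cfg$utr3_len_range[1], cfg$utr3_len_range[2])
  L <- rint(cfg$orf_len_range[1], cfg$orf_len_range[2])
  s <- if (rint(0, 1) == 1) "+" else "-"
  left <- if (s == "+") u5 else u3
  genes <- tibble(gene_id = id, strand = s,
                  orf_start = left, orf_end = left + L,
                  utr5_len = u5, utr3_len = u3)
  list(genes = genes, pair_class = NA_character_, width = u5 + L + u3)
}

#' Generate a synthetic annotated genome with known ground truth
#'
#' Plants the configured pair motifs and isolated genes left-to-right across
#' chromosomes, each motif isolated by at least `spacing` bases so no
#' unplanned pair can form and planted truth is unambiguous. Deterministic
#' under a fixed seed.
#'
#' @param config A [genome_sim_config()].
#' @return A list with elements
#'   * `annotation` — the gene annotation (see [annotation()]);
#'   * `truth` — a list with `genes` (annotation columns plus true
#'     `utr5_len`, `utr3_len`, `tx_start`, `tx_end`) and `pairs` (the planted
#'     pair table in [classify_pairs()] format).
#' @export
simulate_genome <- function(config) {
  withr::with_seed(config$seed, {
    labels <- c(rep("convergent", config$n_convergent),
                rep("divergent", config$n_divergent),
                rep("consistent", config$n_consistent),
                rep("isolated", config$n_isolated))
    if (length(labels) == 0) {
      return(list(annotation = empty_annotation(),
                  truth = list(genes = tibble(), pairs = tibble())))
    }
    labels <- labels[sample.int(length(labels))]
    motifs <- lapply(seq_along(labels), function(j) {
      id <- sprintf("%s%04d", c(convergent = "CV", divergent = "DV",
                                consistent = "CS", isolated = "IS")[labels[j]], j)
      switch(labels[j],
             convergent = motif_convergent(id, config),
             divergent = motif_divergent(id, config),
             consistent = motif_consistent(id, config),
             isolated = motif_isolated(id, config))
    })

    chroms <- sprintf("chr%02d", seq_len(config$n_chromosomes))
    cursor <- setNames(rep(config$spacing, config$n_chromosomes), chroms)
    gene_tabs <- vector("list", length(motifs))
    pair_tabs <- list()
    for (j in seq_along(motifs)) {
      m <- motifs[[j]]
      chrom <- chroms[(j - 1) %% config$n_chromosomes + 1]
      g <- m$genes
      g$chrom <- chrom
      g$orf_start <- g$orf_start + cursor[chrom]
      g$orf_end <- g$orf_end + cursor[chrom]
      cursor[chrom] <- cursor[chrom] + m$width + config$spacing
      gene_tabs[[j]] <- g
      if (!is.na(m$pair_class)) pair_tabs[[length(pair_tabs) + 1]] <- g
    }
    if (!is.null(config$chrom_length)) {
      if (any(cursor > config$chrom_length)) {
        abort(paste0("chromosome too short (", config$chrom_length,
                     ") for the planted motifs; need up to ", max(cursor)))
      }
      cursor[] <- config$chrom_length
    }

    genes <- transcript_span(dplyr::bind_rows(gene_tabs))
    genes <- dplyr::arrange(genes, .data$chrom, .data$orf_start)
    pairs <- purrr::map_dfr(pair_tabs, function(g) {
      g <- transcript_span(g)
      up <- g[1, ]; down <- g[2, ]
      tibble(
        gene_up = up$gene_id, gene_down = down$gene_id, chrom = up$chrom,
        class = pair_class_of(up, down),
        gap_bp = down$orf_start - up$orf_end,
        utr_overlap_bp = facing_utr_overlap(up, down),
        transcript_overlap_bp = interval_overlap(up$tx_start, up$tx_end,
                                                 down$tx_start, down$tx_end)
      )
    })
    annot_cols <- genes[, c("gene_id", "chrom", "strand",
                            "orf_start", "orf_end")]
    list(
      annotation = annotation(annot_cols, chrom_lengths = cursor),
      truth = list(genes = genes, pairs = pairs)
    )
  })
}

pair_class_of <- function(up, down) {
  if (up$strand == down$strand) "consistent"
  else if (up$strand == "+") "convergent"
  else "divergent"
}

facing_utr_overlap <- function(up, down) {
  both <- dplyr::bind_rows(up, down)
  u3 <- utr3_interval(both); u5 <- utr5_interval(both)
  if (up$strand == "+" && down$strand == "-") {
    interval_overlap(u3$start[1], u3$end[1], u3$start[2], u3$end[2])
  } else if (up$strand == "-" && down$strand == "+") {
    interval_overlap(u5$start[1], u5$end[1], u5$start[2], u5$end[2])
  } else if (up$strand == "+") {
    interval_overlap(u3$start[1], u3$end[1], u5$start[2], u5$end[2])
  } else {
    interval_overlap(u5$start[1], u5$end[1], u3$start[2], u3$end[2])
  }
}

#' Generate strand-specific coverage consistent with planted transcripts
#'
#' Per-base counts equal `depth` over each true transcript span on the
#' gene's own strand (overlapping same-strand transcripts add), 0 elsewhere.
#' With `noise = "poisson"` each base is an independent Poisson draw with
#' that mean.
#'
#' @param annot Annotation from [simulate_genome()] (supplies chromosome
#'   lengths).
#' @param truth Truth list from [simulate_genome()].
#' @param depth Mean reads/base over transcripts. Default 10.
#' @param noise `"none"` (default, exact counts) or `"poisson"`.
#' @param seed Seed for the Poisson draws.
#' @param zero_genes Gene IDs whose transcripts get no coverage at all
#'   (planted "unexpressed" genes).
#' @return A `conv_coverage` track.
#' @export
simulate_coverage <- function(annot, truth, depth = 10,
                              noise = c("none", "poisson"), seed = 1,
                              zero_genes = character()) {
  noise <- match.arg(noise)
  cl <- chrom_lengths(annot)
  if (is.null(cl)) abort("annotation must carry chromosome lengths")
  genes <- truth$genes
  genes <- genes[!genes$gene_id %in% zero_genes, ]
  lambda <- lapply(names(cl), function(chrom) {
    list("+" = numeric(cl[[chrom]]), "-" = numeric(cl[[chrom]]))
  })
  names(lambda) <- names(cl)
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]; s <- genes$strand[i]
    from <- genes$tx_start[i] + 1; to <- genes$tx_end[i]
    lambda[[chrom]][[s]][from:to] <- lambda[[chrom]][[s]][from:to] + depth
  }
  if (noise == "poisson") {
    lambda <- withr::with_seed(seed, {
      lapply(lambda, function(strands) {
        lapply(strands, function(v) {
          out <- v
          nz <- v > 0
          out[nz] <- rpois(sum(nz), v[nz])
          out
        })
      })
    })
  }
  coverage_track(lambda)
}

#' Generate a log2 expression matrix with planted pair correlation
#'
#' For every pair and condition, the (upstream, downstream) log2 expression
#' values are one draw from a bivariate normal with correlation `r_target`;
#' unpaired genes are independent draws. Optional independent measurement
#' noise (`noise_sd`) is added afterwards; it attenuates the realized
#' correlation.
#'
#' @param pairs A pair tibble (only `gene_up`/`gene_down` are used).
#' @param r_target Planted Pearson correlation in `[-1, 1]`.
#' @param n_conditions Number of sample columns. Default 7.
#' @param mean_log2,sd_log2 Marginal mean and SD of log2 expression.
#'   Defaults 8 and 2, typical of log2 microarray intensities.
#' @param noise_sd Independent Gaussian noise added to every value.
#'   Default 0.
#' @param extra_genes IDs of unpaired genes to include as independent draws.
#' @param seed Integer seed.
#' @return Expression tibble: `gene_id` plus `cond_1` ... `cond_k`.
#' @export
simulate_expression <- function(pairs, r_target, n_conditions = 7,
                                mean_log2 = 8, sd_log2 = 2, noise_sd = 0,
                                extra_genes = character(), seed = 1) {
  if (abs(r_target) > 1) abort("r_target must lie in [-1, 1]")
  withr::with_seed(seed, {
    np <- nrow(pairs)
    cols <- lapply(seq_len(n_conditions), function(k) {
      z1 <- rnorm(np); z2 <- rnorm(np)
      up <- mean_log2 + sd_log2 * z1
      down <- mean_log2 + sd_log2 * (r_target * z1 + sqrt(1 - r_target^2) * z2)
      extra <- mean_log2 + sd_log2 * rnorm(length(extra_genes))
      vals <- c(up, down, extra)
      vals + rnorm(length(vals), sd = noise_sd)
    })
    expr <- tibble(gene_id = c(pairs$gene_up, pairs$gene_down, extra_genes))
    for (k in seq_len(n_conditions)) expr[[paste0("cond_", k)]] <- cols[[k]]
    expr
  })
}

#' Generate single-cell expression for one gene pair
#'
#' Draws per-cell log2 expression for two genes from a bivariate normal
#' with correlation `r_target` (a Gaussian copula with normal margins),
#' then applies independent dropout: each value is zeroed with probability
#' `dropout_p`, emulating single-cell capture loss.
#'
#' @param r_target Planted Pearson correlation.
#' @param n_cells Number of cells. Default 1000.
#' @param mean_log2,sd_log2 Marginal log2 mean and SD. Defaults 6 and 2.
#' @param dropout_p Per-value dropout probability. Default 0.
#' @param gene_ids Length-2 character vector of gene names.
#' @param seed Integer seed.
#' @return Expression tibble: 2 rows (`gene_id`) x `cell_1` ... `cell_n`.
#' @export
simulate_single_cell <- function(r_target, n_cells = 1000, mean_log2 = 6,
                                 sd_log2 = 2, dropout_p = 0,
                                 gene_ids = c("geneA", "geneB"), seed = 1) {
  if (abs(r_target) > 1) abort("r_target must lie in [-1, 1]")
  withr::with_seed(seed, {
    z1 <- rnorm(n_cells); z2 <- rnorm(n_cells)
    g1 <- mean_log2 + sd_log2 * z1
    g2 <- mean_log2 + sd_log2 * (r_target * z1 + sqrt(1 - r_target^2) * z2)
    if (dropout_p > 0) {
      g1[rbinom(n_cells, 1, dropout_p) == 1] <- 0
      g2[rbinom(n_cells, 1, dropout_p) == 1] <- 0
    }
    expr <- tibble(gene_id = gene_ids)
    m <- rbind(g1, g2)
    for (k in seq_len(n_cells)) expr[[paste0("cell_", k)]] <- m[, k]
    expr
  })
}

#' Plant a validation partition and the second dataset realizing it
#'
#' `simulate_validation_statuses()` assigns each reference convergent pair a
#' status (`confirmed`, `partner_unexpressed`, `not_confirmed`) with the
#' requested counts, in a seeded random order. `simulate_validation_coverage()`
#' builds a second dataset's coverage that realizes those statuses exactly:
#' confirmed pairs keep their planted transcripts; `partner_unexpressed`
#' pairs get the downstream gene's coverage zeroed; `not_confirmed` pairs
#' get both 3'-UTRs shortened to at most `floor((gap - 1) / 2)` bases so the
#' re-called UTR intervals can no longer meet while both genes stay
#' expressed.
#'
#' @param pairs Convergent pair tibble (from truth or [classify_pairs()]).
#' @param n_confirmed,n_partner_unexpressed Planted counts; the remainder of
#'   the pairs is `not_confirmed`.
#' @param seed Integer seed.
#' @return `simulate_validation_statuses()`: tibble `gene_up`, `gene_down`,
#'   `status`.
#' @export
simulate_validation_statuses <- function(pairs, n_confirmed,
                                         n_partner_unexpressed, seed = 1) {
  n <- nrow(pairs)
  if (n_confirmed + n_partner_unexpressed > n) {
    abort("planted status counts exceed the number of pairs")
  }
  status <- c(rep("confirmed", n_confirmed),
              rep("partner_unexpressed", n_partner_unexpressed),
              rep("not_confirmed", n - n_confirmed - n_partner_unexpressed))
  status <- withr::with_seed(seed, status[sample.int(n)])
  tibble(gene_up = pairs$gene_up, gene_down = pairs$gene_down, status = status)
}

#' @rdname simulate_validation_statuses
#' @param annot,truth Genome and truth from [simulate_genome()].
#' @param statuses Output of `simulate_validation_statuses()`.
#' @param depth Coverage depth for expressed transcripts.
#' @return `simulate_validation_coverage()`: a `conv_coverage` track for the
#'   second dataset.
#' @export
simulate_validation_coverage <- function(annot, truth, statuses, depth = 10) {
  genes <- truth$genes
  pairs <- truth$pairs
  zero <- statuses$gene_down[statuses$status == "partner_unexpressed"]
  shrink <- statuses[statuses$status == "not_confirmed", ]
  if (nrow(shrink) > 0) {
    gap <- pairs$gap_bp[match(paste(shrink$gene_up, shrink$gene_down),
                              paste(pairs$gene_up, pairs$gene_down))]
    if (any(is.na(gap))) abort("status table names pairs absent from truth")
    new_len <- pmax(0, floor((gap - 1) / 2))
    for (k in seq_len(nrow(shrink))) {
      for (g in c(shrink$gene_up[k], shrink$gene_down[k])) {
        genes$utr3_len[genes$gene_id == g] <- new_len[k]
      }
    }
    genes <- transcript_span(genes)
  }
  simulate_coverage(annot, list(genes = genes), depth = depth,
                    zero_genes = zero)
}

#' Transcript models of a single convergent pair laid out from its geometry
#'
#' Convenience constructor for worked examples: places an upstream `+`
#' strand gene and a downstream `-` strand gene on one chromosome with the
#' given 3'-UTR lengths and distance between facing stop-codon boundaries,
#' ready for [classify_pairs()].
#'
#' @param utr3_up,utr3_down 3'-UTR lengths in bases.
#' @param gap_bp Distance between the facing stop-codon boundaries.
#' @param chrom Chromosome name.
#' @param orf_len ORF length used for both genes. Default 500.
#' @param origin Left ORF start coordinate (0-based). Default 1000.
#' @param utr5 5'-UTR length used for both genes. Default 50.
#' @return A transcript-model tibble of the two genes.
#' @export
convergent_pair_models <- function(utr3_up, utr3_down, gap_bp, chrom = "chrI",
                                   orf_len = 500, origin = 1000, utr5 = 50) {
  models <- tibble(
    gene_id = c("up", "down"),
    chrom = chrom,
    strand = c("+", "-"),
    orf_start = c(origin, origin + orf_len + gap_bp),
    orf_end = c(origin + orf_len, origin + 2 * orf_len + gap_bp),
    utr5_len = c(utr5, utr5),
    utr3_len = c(utr3_up, utr3_down)
  )
  transcript_span(models)
}
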