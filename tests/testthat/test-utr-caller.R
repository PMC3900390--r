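params <- utr_call_params()

test_that("3'-UTR extension follows coverage past the stop codon", {
  g <- make_gene(strand = "+", orf_start = 1000, orf_end = 1500)
  # continuous coverage over ORF plus exactly 127 downstream bases
  cov <- make_coverage(c(chrI = 5000),
                       data.frame(chrom = "chrI", strand = "+",
                                  start = 1000, end = 1627, depth = 10))
  expect_equal(call_utr3(g, cov, params), 127)

  # nothing downstream: zero-length UTR is allowed
  cov0 <- make_coverage(c(chrI = 5000),
                        data.frame(chrom = "chrI", strand = "+",
                                   start = 1000, end = 1500, depth = 10))
  expect_equal(call_utr3(g, cov0, params), 0)
})

test_that("interior sub-threshold runs up to max_gap are tolerated, trailing ones trimmed", {
  g <- make_gene(strand = "+", orf_start = 1000, orf_end = 1500)
  # 50 covered, 3 zero, 20 covered
  seg <- data.frame(chrom = "chrI", strand = "+",
                    start = c(1500, 1553), end = c(1550, 1573), depth = 8)
  cov <- make_coverage(c(chrI = 5000), seg)
  expect_equal(call_utr3(g, cov, params), 73)
  # a stricter gap tolerance stops at the first run
  expect_equal(call_utr3(g, cov, utr_call_params(max_gap = 2)), 50)
  # brute-force oracle: walk base by base
  walk <- cov[["chrI"]][["+"]][1501:2100]
  brute <- function(v, min_cov, max_gap) {
    best <- 0; gap_run <- 0
    for (i in seq_along(v)) {
      if (v[i] >= min_cov) { best <- i; gap_run <- 0 }
      else { gap_run <- gap_run + 1; if (gap_run > max_gap) break }
    }
    best
  }
  expect_equal(call_utr3(g, cov, params), brute(walk, 1, 5))
})

test_that("minus-strand calls mirror plus-strand calls", {
  # same geometry reflected: gene on -, 3' direction is leftward
  g <- make_gene(strand = "-", orf_start = 1000, orf_end = 1500)
  cov <- make_coverage(c(chrI = 5000),
                       data.frame(chrom = "chrI", strand = "-",
                                  start = 873, end = 1500, depth = 10))
  expect_equal(call_utr3(g, cov, params), 127)
  # 5'-UTR of a minus-strand gene extends rightward
  cov5 <- make_coverage(c(chrI = 5000),
                        data.frame(chrom = "chrI", strand = "-",
                                   start = 1000, end = 1560, depth = 10))
  expect_equal(call_utr5(g, cov5, params), 60)
})

test_that("calls are capped at max_utr_len and at the chromosome end", {
  g <- make_gene(strand = "+", orf_start = 100, orf_end = 600)
  cov <- make_coverage(c(chrI = 2000),
                       data.frame(chrom = "chrI", strand = "+",
                                  start = 100, end = 2000, depth = 5))
  expect_equal(call_utr3(g, cov, params), 600)
  expect_equal(call_utr3(g, cov, utr_call_params(max_utr_len = 150)), 150)
  g_edge <- make_gene(strand = "+", orf_start = 1500, orf_end = 1900)
  expect_equal(call_utr3(g_edge, cov, params), 100)   # chromosome ends at 2000
})

test_that("antisense coverage never contributes to a gene's UTR", {
  g <- make_gene(strand = "+", orf_start = 1000, orf_end = 1500)
  cov <- make_coverage(c(chrI = 5000),
                       data.frame(chrom = "chrI", strand = "-",
                                  start = 1500, end = 1700, depth = 50))
  expect_equal(call_utr3(g, cov, params), 0)
})

test_that("unknown chromosome or strand in the coverage track is an error", {
  g <- make_gene(chrom = "chrX")
  cov <- make_coverage(c(chrI = 2000))
  expect_error(call_utr3(g, cov, params), "chrX")
})

test_that("mean ORF coverage is the strand-specific per-base mean", {
  g <- make_gene(strand = "+", orf_start = 1000, orf_end = 1400)
  cov4 <- make_coverage(c(chrI = 5000),
                        data.frame(chrom = "chrI", strand = "+",
                                   start = 1000, end = 1400, depth = 4))
  expect_equal(mean_orf_coverage(g, cov4), 4)
  expect_equal(mean_orf_coverage(g, make_coverage(c(chrI = 5000))), 0)
  half <- make_coverage(c(chrI = 5000),
                        data.frame(chrom = "chrI", strand = "+",
                                   start = 1000, end = 1200, depth = 10))
  expect_equal(mean_orf_coverage(g, half), 5)
})

test_that("call_utrs tallies genes with UTRs and handles empty annotations", {
  genes <- dplyr::bind_rows(
    make_gene("g1", orf_start = 1000, orf_end = 1400),
    make_gene("g2", orf_start = 3000, orf_end = 3400),
    make_gene("g3", orf_start = 6000, orf_end = 6400)
  )
  annot <- annotation(genes)
  seg <- data.frame(chrom = "chrI", strand = "+",
                    start = c(1000, 3000, 6000), end = c(1450, 3500, 6400),
                    depth = 10)
  models <- call_utrs(annot, make_coverage(c(chrI = 10000), seg))
  expect_equal(utr_call_summary(models)$n_utr3, 2)   # g3 has no downstream coverage
  expect_equal(models$tx_end, c(1450, 3500, 6400))

  empty <- call_utrs(annotation(genes[0, ]), make_coverage(c(chrI = 100)))
  expect_equal(nrow(empty), 0)
})

test_that("raising min_cov never lengthens and raising max_gap never shortens a UTR", {
  set.seed(7)
  g <- make_gene(strand = "+", orf_start = 100, orf_end = 200)
  for (rep in 1:25) {
    v <- rpois(700, lambda = runif(1, 0.3, 3))
    cov <- coverage_track(list(chrI = list("+" = c(numeric(200), v),
                                           "-" = numeric(900))))
    lens_min <- sapply(c(1, 2, 3, 5), function(mc)
      call_utr3(g, cov, utr_call_params(min_cov = mc)))
    expect_true(all(diff(lens_min) <= 0))
    lens_gap <- sapply(c(0, 1, 3, 5, 10), function(mg)
      call_utr3(g, cov, utr_call_params(max_gap = mg)))
    expect_true(all(diff(lens_gap) >= 0))
  }
})

test_that("mirroring the genome leaves all called UTR lengths unchanged", {
  sim <- small_sim(seed = 11)
  cov <- simulate_coverage(sim$annotation, sim$truth)
  models <- call_utrs(sim$annotation, cov)

  cl <- chrom_lengths(sim$annotation)
  m_genes <- mirror_genes(sim$annotation, cl)
  m_annot <- annotation(m_genes, chrom_lengths = cl)
  m_models <- call_utrs(m_annot, mirror_coverage(cov))

  ord <- match(models$gene_id, m_models$gene_id)
  expect_equal(m_models$utr3_len[ord], models$utr3_len)
  expect_equal(m_models$utr5_len[ord], models$utr5_len)
})
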