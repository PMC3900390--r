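test_that("transcript-level overlap arithmetic matches the worked examples", {
  expect_equal(transcript_overlap(98, 206, 98), 206)
  expect_equal(transcript_overlap(53, 9, 33), 29)
  expect_equal(transcript_overlap(100, 50, 150), 0)   # gap equals the UTR sum
})

test_that("the overlap formula equals per-base interval intersection", {
  # brute-force oracle on explicit transcript intervals (long ORFs so the
  # transcripts always reach across the gap region)
  set.seed(123)
  n <- 10000
  u_up <- sample(0:300, n, replace = TRUE)
  u_down <- sample(0:300, n, replace = TRUE)
  gap <- sample(-400:700, n, replace = TRUE)
  orf <- 1000
  brute <- vapply(seq_len(n), function(i) {
    up_tx <- seq(0, orf + u_up[i] - 1)                       # [0, orf + u_up)
    dn_start <- orf + gap[i] - u_down[i]
    dn_tx <- seq(dn_start, orf + gap[i] + orf - 1)           # down transcript
    length(intersect(up_tx, dn_tx))
  }, numeric(1))
  expect_equal(transcript_overlap(u_up, u_down, gap), brute)
})

test_that("a convergent pair is classified with both overlap measures", {
  models <- convergent_pair_models(127, 178, 141)
  pairs <- classify_pairs(models)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$class, "convergent")
  expect_equal(pairs$gap_bp, 141)
  expect_equal(pairs$transcript_overlap_bp, 164)
  # UTR-interval overlap lives inside the intergenic gap
  expect_equal(pairs$utr_overlap_bp, 127)
  expect_lte(pairs$utr_overlap_bp, pairs$transcript_overlap_bp)
})

test_that("the reported overlap is transcript-level and can exceed the shorter UTR", {
  pairs <- classify_pairs(convergent_pair_models(53, 9, 33))
  expect_equal(pairs$transcript_overlap_bp, 29)
  expect_gt(pairs$transcript_overlap_bp, 9)
  expect_equal(pairs$utr_overlap_bp, 9)     # min(53,33) - max(0, 33-9)
})

test_that("facing 3' ends without UTR overlap emit no pair", {
  models <- convergent_pair_models(100, 50, 150)
  expect_equal(nrow(classify_pairs(models)), 0)
  # and a wide gap likewise
  expect_equal(nrow(classify_pairs(convergent_pair_models(20, 30, 400))), 0)
})

test_that("same-strand genes with overlapping transcript spans are consistent", {
  models <- tibble::tibble(
    gene_id = c("a", "b"), chrom = "chrI", strand = "+",
    orf_start = c(100, 700), orf_end = c(600, 1200),
    utr5_len = c(10, 60), utr3_len = c(50, 40)
  )
  models <- convpairs:::transcript_span(models)
  # a tx ends 650, b tx starts 640: spans share 10 bases
  pairs <- classify_pairs(models)
  expect_equal(pairs$class, "consistent")
  expect_equal(pairs$transcript_overlap_bp, 10)
})

test_that("divergent pairs require facing 5'-UTR overlap", {
  models <- tibble::tibble(
    gene_id = c("a", "b"), chrom = "chrI", strand = c("-", "+"),
    orf_start = c(100, 680), orf_end = c(600, 1200),
    utr5_len = c(50, 40), utr3_len = c(10, 10)
  )
  models <- convpairs:::transcript_span(models)
  # a's 5'-UTR is [600, 650), b's is [640, 680): 10 shared bases
  pairs <- classify_pairs(models)
  expect_equal(pairs$class, "divergent")
  expect_equal(pairs$utr_overlap_bp, 10)
  expect_equal(pairs$gap_bp, 80)
})

test_that("unsorted models are rejected", {
  models <- convergent_pair_models(100, 100, 50)[2:1, ]
  expect_error(classify_pairs(models), "sorted")
})

test_that("classes partition: every emitted pair has exactly one class", {
  sim <- small_sim(seed = 3)
  cov <- simulate_coverage(sim$annotation, sim$truth)
  pairs <- classify_pairs(call_utrs(sim$annotation, cov))
  expect_true(all(pairs$class %in% c("convergent", "divergent", "consistent")))
  expect_false(any(duplicated(paste(pairs$gene_up, pairs$gene_down))))
  # at most one convergent pair per gene
  conv <- pairs[pairs$class == "convergent", ]
  expect_false(any(duplicated(c(conv$gene_up, conv$gene_down))))
})

test_that("a doubly-qualified convergent gene keeps the larger UTR overlap, ties to the left", {
  fake <- tibble::tibble(
    gene_up = c("a", "x", "b"), gene_down = c("x", "b", "y"),
    chrom = "chrI", class = "convergent",
    gap_bp = c(10, 10, 10), utr_overlap_bp = c(5, 9, 9),
    transcript_overlap_bp = c(20, 30, 30)
  )
  kept <- convpairs:::enforce_unique_convergent(fake)
  # (x,b) beats (a,x) on overlap; (b,y) then conflicts with (x,b) and drops
  expect_equal(paste(kept$gene_up, kept$gene_down), "x b")

  tie <- fake
  tie$utr_overlap_bp <- c(9, 9, 9)
  kept_tie <- convpairs:::enforce_unique_convergent(tie)
  # ties resolve to the leftmost pair; (b,y) no longer conflicts
  expect_equal(paste(kept_tie$gene_up, kept_tie$gene_down), c("a x", "b y"))
})

test_that("mirror-reversing the genome preserves classes and overlap lengths", {
  sim <- small_sim(seed = 19)
  cov <- simulate_coverage(sim$annotation, sim$truth)
  pairs <- classify_pairs(call_utrs(sim$annotation, cov))

  cl <- chrom_lengths(sim$annotation)
  m_annot <- annotation(mirror_genes(sim$annotation, cl), chrom_lengths = cl)
  m_pairs <- classify_pairs(call_utrs(m_annot, mirror_coverage(cov)))

  expect_equal(table(m_pairs$class), table(pairs$class))
  for (cls in unique(pairs$class)) {
    expect_equal(
      sort(m_pairs$transcript_overlap_bp[m_pairs$class == cls]),
      sort(pairs$transcript_overlap_bp[pairs$class == cls])
    )
    expect_equal(
      sort(m_pairs$utr_overlap_bp[m_pairs$class == cls]),
      sort(pairs$utr_overlap_bp[pairs$class == cls])
    )
  }
})

test_that("summaries tally classes and the convergent gene fraction", {
  pairs <- tibble::tibble(class = c(rep("convergent", 645),
                                    rep("divergent", 53),
                                    rep("consistent", 65)))
  s <- summarize_pairs(pairs, 6450)
  expect_equal(s$n_convergent, 645)
  expect_equal(s$n_divergent, 53)
  expect_equal(s$n_consistent, 65)
  expect_equal(s$convergent_gene_fraction, 0.2)

  s0 <- summarize_pairs(pairs[0, ], 10)
  expect_equal(unlist(s0[, 1:3]), c(n_convergent = 0, n_divergent = 0,
                                    n_consistent = 0))
})
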