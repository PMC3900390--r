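# A small pair table + expression matrix built directly.
make_pairs <- function(n) {
  tibble::tibble(gene_up = paste0("u", seq_len(n)),
                 gene_down = paste0("d", seq_len(n)),
                 chrom = "chrI", class = "convergent",
                 gap_bp = 10, utr_overlap_bp = 5, transcript_overlap_bp = 15)
}

expr_from <- function(pairs, up, down, sample_id = "cond_1") {
  out <- tibble::tibble(gene_id = c(pairs$gene_up, pairs$gene_down),
                        value = c(up, down))
  names(out)[2] <- sample_id
  out
}

test_that("Pearson r matches a direct covariance/variance oracle", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    pairs <- make_pairs(n)
    x <- rnorm(n); y <- rnorm(n)
    res <- pair_correlation(pairs, expr_from(pairs, x, y), "cond_1",
                            n_perm = 10, seed = 1)
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$r, oracle, tolerance = 1e-12)
  }
})

test_that("perfect anti-correlation gives r = -1", {
  pairs <- make_pairs(10)
  x <- rnorm(10)
  res <- pair_correlation(pairs, expr_from(pairs, x, -x), "cond_1",
                          n_perm = 50, seed = 1)
  expect_equal(res$r, -1)
})

test_that("degenerate inputs error informatively", {
  pairs <- make_pairs(2)
  expect_error(pair_correlation(pairs, expr_from(pairs, 1:2, 2:1), "cond_1"),
               ">= 3 pairs")
  pairs <- make_pairs(5)
  expect_error(
    pair_correlation(pairs, expr_from(pairs, rep(1, 5), rnorm(5)), "cond_1"),
    "upstream"
  )
  expect_error(
    pair_correlation(pairs, expr_from(pairs, rnorm(5), rep(2, 5)), "cond_1"),
    "downstream"
  )
})

test_that("planted anti-correlation of -0.14 is recovered at genome scale", {
  pairs <- make_pairs(645)
  expr <- simulate_expression(pairs, r_target = -0.14, n_conditions = 7,
                              seed = 202)
  res <- correlate_all_conditions(pairs, expr, n_perm = 200, seed = 1)
  d <- tidy(res)
  expect_equal(nrow(d), 7)
  # sampling SE of r at n = 645 is about 0.039; +/- 0.08 is ~2 SE
  expect_true(all(abs(d$r - (-0.14)) < 0.08))
  expect_true(all(d$p_perm < 0.05))
  g <- glance(res)
  expect_lt(g$r_max, 0)
})

test_that("permutation p is uniform under the null and bit-identical under a seed", {
  pairs <- make_pairs(100)
  set.seed(31)
  p_null <- replicate(200, {
    expr <- expr_from(pairs, rnorm(100), rnorm(100))
    pair_correlation(pairs, expr, "cond_1", n_perm = 99)$p_perm
  })
  expect_gt(mean(p_null), 0.45)
  expect_lt(mean(p_null), 0.55)

  expr <- expr_from(pairs, rnorm(100), rnorm(100))
  p1 <- pair_correlation(pairs, expr, "cond_1", n_perm = 200, seed = 7)$p_perm
  p2 <- pair_correlation(pairs, expr, "cond_1", n_perm = 200, seed = 7)$p_perm
  expect_identical(p1, p2)
})

test_that("r and the analytic p are invariant to swapping up/down labels", {
  pairs <- make_pairs(30)
  set.seed(9)
  expr <- expr_from(pairs, rnorm(30), rnorm(30))
  res <- pair_correlation(pairs, expr, "cond_1", n_perm = 10, seed = 1)
  swapped <- pairs
  swapped$gene_up <- pairs$gene_down
  swapped$gene_down <- pairs$gene_up
  res_sw <- pair_correlation(swapped, expr, "cond_1", n_perm = 10, seed = 1)
  expect_equal(res_sw$r, res$r)
  expect_equal(res_sw$p_analytic, res$p_analytic)
  expect_equal(res_sw$n_pairs, res$n_pairs)
})

test_that("pairs with genes missing from a sample are dropped, n_pairs reported", {
  pairs <- make_pairs(10)
  expr <- expr_from(pairs, rnorm(10), rnorm(10))
  expr <- expr[expr$gene_id != "d10", ]
  res <- pair_correlation(pairs, expr, "cond_1", n_perm = 10, seed = 1)
  expect_equal(res$n_pairs, 9)
})

test_that("UTR length vs expression correlation recovers a planted trend", {
  n <- 2000
  set.seed(77)
  e <- rnorm(n, 8, 2)
  len <- pmax(1, round(150 - 8 * e + rnorm(n, 0, 30)))
  models <- tibble::tibble(gene_id = paste0("g", 1:n), utr3_len = len,
                           utr5_len = 0)
  expr <- tibble::tibble(gene_id = models$gene_id, cond_1 = e)
  res <- utr_length_expression_correlation(models, expr, "cond_1", "3")
  expect_lt(res$r, 0)
  expect_lt(res$p_analytic, 0.05)

  # independent lengths: near-zero correlation on average
  r_null <- replicate(100, {
    m <- models
    m$utr3_len <- sample(9:211, n, replace = TRUE)
    utr_length_expression_correlation(m, expr, "cond_1", "3")$r
  })
  expect_lt(abs(mean(r_null)), 0.05)

  models$utr3_len <- rep(50, n)
  expect_error(utr_length_expression_correlation(models, expr, "cond_1", "3"),
               "degenerate")
})

test_that("single-cell pair correlation recovers the planted value", {
  # perfectly anti-correlated profiles
  cells <- simulate_single_cell(-1, n_cells = 50, seed = 4)
  expect_equal(single_cell_pair_correlation(cells)$r, -1)

  r_hat <- vapply(1:20, function(s) {
    sc <- simulate_single_cell(-0.38, n_cells = 1000, seed = s)
    single_cell_pair_correlation(sc)$r
  }, numeric(1))
  expect_lt(abs(mean(r_hat) - (-0.38)), 0.05)
})

test_that("single-cell correlation rejects tiny or constant inputs", {
  sc <- simulate_single_cell(-0.38, n_cells = 2, seed = 1)
  expect_error(single_cell_pair_correlation(sc), ">= 3 cells")
  # total dropout leaves constant all-zero profiles
  sc0 <- simulate_single_cell(-0.38, n_cells = 100, dropout_p = 1, seed = 1)
  expect_error(single_cell_pair_correlation(sc0), "constant")
})

test_that("delta-delta-Ct fold ratios follow 2^-ddCt", {
  expect_equal(relative_expression_ddct(20, 18, 22, 20), 1)   # ddCt = 0
  expect_equal(relative_expression_ddct(21, 18, 22, 20), 0.5) # ddCt = 1
  expect_equal(relative_expression_ddct(18, 18, 22, 20), 4)   # ddCt = -2
  expect_error(relative_expression_ddct(NA, 18, 22, 20), "finite")
})

test_that("expression matrices round-trip and linear input is log2-transformed", {
  expr <- tibble::tibble(gene_id = c("a", "b"), s1 = c(3, 7), s2 = c(0, 1))
  path <- tempfile(fileext = ".tsv")
  write_expression(expr, path)
  expect_equal(as.data.frame(read_expression(path)), as.data.frame(expr))
  lin <- read_expression(path, scale = "linear")
  expect_equal(lin$s1, log2(c(3, 7) + 1))
})
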