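# 4 time points x 3 replicates count fixture with given per-cell values
fixture_matrix <- function(counts, lib = 1e6) {
  n <- nrow(counts)
  rs <- region_set(data.frame(chrom = "c1",
                              start = seq(0, by = 1000, length.out = n),
                              end = seq(500, by = 1000, length.out = n)))
  tps <- sprintf("t%d", seq_len(ncol(counts) / 3))
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(ncol(counts))),
    time_point = rep(tps, each = 3),
    replicate = rep(1:3, length(tps)),
    library_size = lib, stringsAsFactors = FALSE)
  region_count_matrix(rs, samples, counts)
}

test_that("score matches the hand-computed two-group statistic", {
  # normalized values: t1 = {10,12,14}, rest = {5,6,7} x 3
  counts <- matrix(c(10, 12, 14, rep(c(5, 6, 7), 3)), nrow = 1)
  m <- fixture_matrix(counts)
  sc <- score_regions(m)
  s1 <- sc[sc$time_point == "t1", ]
  expect_equal(s1$mean_t, 12)
  expect_equal(s1$mean_rest, 6)
  expect_equal(s1$sd_t, 2)
  expect_equal(s1$sd_rest, sd(rep(c(5, 6, 7), 3)))
  expect_equal(s1$score, 6 / (2 + sd(rep(c(5, 6, 7), 3))))
  expect_equal(round(s1$score, 4), 2.0935)
  expect_equal(s1$direction, "up")
})

test_that("all-equal samples score zero; zero sd with unequal means is Inf", {
  m <- fixture_matrix(matrix(5, nrow = 2, ncol = 12))
  expect_true(all(score_regions(m)$score == 0))
  # constant within groups, different across: sd sum 0, means differ
  counts <- matrix(c(rep(10, 3), rep(2, 9)), nrow = 1)
  sc <- score_regions(fixture_matrix(counts))
  expect_true(is.infinite(sc$score[sc$time_point == "t1"]))
})

test_that("score is invariant to replicate order and global rescaling", {
  set.seed(3)
  counts <- matrix(rnbinom(20 * 12, mu = 50, size = 10), nrow = 20)
  m <- fixture_matrix(counts)
  base <- score_regions(m)
  # permute replicates within t2 (columns 4:6)
  m2 <- fixture_matrix(counts[, c(1:3, 6, 4, 5, 7:12)])
  expect_equal(score_regions(m2)$score, base$score)
  # scale all libraries by the same factor: normalized values scale by 1/c
  m3 <- fixture_matrix(counts, lib = 4e6)
  expect_equal(score_regions(m3)$score, base$score)
})

test_that("build_null is deterministic, calibrated and validates input", {
  set.seed(9)
  counts <- matrix(rnbinom(200 * 12, mu = 100, size = 25), nrow = 200)
  m <- fixture_matrix(counts)
  n1 <- build_null(m, n_permutations = 20, alpha = 0.05, seed = 5)
  n2 <- build_null(m, n_permutations = 20, alpha = 0.05, seed = 5)
  expect_identical(n1$threshold, n2$threshold)
  expect_identical(n1$permuted_scores, n2$permuted_scores)
  # monotone threshold as alpha -> 0
  n3 <- build_null(m, n_permutations = 20, alpha = 0.01, seed = 5)
  expect_gte(n3$threshold, n1$threshold)
  expect_error(build_null(m, 10, alpha = 1.2, seed = 1), "alpha")
  expect_error(build_null(m, 10, alpha = 0.05), "seed")
  # identical counts -> all permuted scores 0 -> threshold 0
  m0 <- fixture_matrix(matrix(7, nrow = 5, ncol = 12))
  n0 <- build_null(m0, n_permutations = 5, alpha = 0.05, seed = 2)
  expect_equal(n0$threshold, 0)
})

test_that("call_differential calls any nonzero score at threshold 0", {
  counts <- matrix(c(10, 12, 14, rep(c(5, 6, 7), 3),
                     rep(5, 12)), nrow = 2, byrow = TRUE)
  m <- fixture_matrix(counts)
  sc <- score_regions(m)
  m0 <- fixture_matrix(matrix(7, nrow = 2, ncol = 12))
  null0 <- build_null(m0, n_permutations = 5, alpha = 0.05, seed = 2)
  res <- call_differential(sc, null0, m$regions)
  expect_equal(res$report$called, c(TRUE, FALSE))
  expect_equal(res$report$time_point[1], "t1")
  expect_equal(length(res$regions), 1)
})

test_that("single-time-point designs are rejected", {
  rs <- region_set(data.frame(chrom = "c1", start = 0, end = 10))
  samples <- data.frame(sample_id = c("a", "b", "c"), time_point = "t1",
                        replicate = 1:3, library_size = 1e6)
  m <- region_count_matrix(rs, samples, matrix(1:3, nrow = 1))
  expect_error(score_regions(m), ">= 2 time points")
  samples2 <- data.frame(sample_id = c("a", "b"), time_point = c("t1", "t2"),
                         replicate = 1, library_size = 1e6)
  m2 <- region_count_matrix(rs, samples2, matrix(1:2, nrow = 1))
  expect_error(score_regions(m2), ">= 2 replicates")
})

test_that("null and observed score distributions agree on null data (KS)", {
  set.seed(21)
  counts <- matrix(rnbinom(2000 * 12, mu = 100, size = 25), nrow = 2000)
  m <- fixture_matrix(counts)
  null <- build_null(m, n_permutations = 4, alpha = 0.05, seed = 17)
  obs <- score_regions(m)$score
  ks <- suppressWarnings(stats::ks.test(obs, null$permuted_scores))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted shifts raise the expected max score monotonically", {
  # expectation over seeds: effect 2x vs 4x at one time point
  max_scores <- function(mult, seed) {
    set.seed(seed)
    base <- matrix(rnbinom(50 * 12, mu = 100, size = 25), nrow = 50)
    shifted <- base
    shifted[, 1:3] <- matrix(rnbinom(50 * 3, mu = 100 * mult, size = 25),
                             nrow = 50)
    sc <- score_regions(fixture_matrix(shifted))
    tapply(pmin(sc$score, 1e6), sc$region, max)
  }
  m2 <- mean(vapply(1:20, function(s) mean(max_scores(2, s)), numeric(1)))
  m4 <- mean(vapply(1:20, function(s) mean(max_scores(4, s)), numeric(1)))
  expect_gt(m4, m2)
})
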