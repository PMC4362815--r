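two_base_pwm <- function() {
  pwm(rbind(c(0.97, 0.01, 0.01, 0.01),
            c(0.01, 0.01, 0.01, 0.97)), motif_id = "at")
}

test_that("score_site matches hand computations and symmetry", {
  p <- two_base_pwm()
  expect_equal(score_site(p, "AT"), 2 * log2(0.97 / 0.25))
  expect_equal(round(score_site(p, "AT"), 4), 3.9121)
  # pwm equal to background scores 0 everywhere
  flat <- pwm(matrix(0.25, nrow = 3, ncol = 4))
  expect_equal(score_site(flat, c("ACG", "TTT", "GGG")), c(0, 0, 0))
  # ambiguous base -> NA
  expect_true(is.na(score_site(p, "AN")))
  expect_error(score_site(p, "A"), "length")
})

test_that("reverse-complement scanning reproduces forward scores", {
  set.seed(8)
  m <- matrix(runif(16, 0.05, 1), ncol = 4)
  m <- m / rowSums(m)
  p <- pwm(m, motif_id = "rnd")
  seqs <- c(s = paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                      collapse = ""))
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seqs[[1]], "")[[1]]),
                                     collapse = ""))
  h_fwd <- scan_sequences(p, seqs, p_threshold = 1)
  h_rc <- scan_sequences(p, c(s = rc), p_threshold = 1)
  # mirror coordinates and swap strands
  n <- nchar(seqs[[1]])
  key <- function(h, flip) {
    st <- if (flip) n - h$end else h$start
    sd <- if (flip) c("+" = "-", "-" = "+")[h$strand] else h$strand
    o <- order(st, sd)
    list(start = st[o], strand = unname(sd[o]), score = h$score[o])
  }
  expect_equal(key(h_rc, TRUE), key(h_fwd, FALSE))
})

test_that("score_pvalue is exact: closed forms and monotonicity", {
  p <- two_base_pwm()
  smax <- sum(apply(score_matrix(p), 1, max))
  # top path probability = product of background probs of the best bases
  expect_equal(score_pvalue(p, smax), 0.25^2)
  smin <- sum(apply(score_matrix(p), 1, min))
  expect_equal(score_pvalue(p, smin), 1)
  sweep_scores <- seq(smin, smax, length.out = 50)
  pv <- score_pvalue(p, sweep_scores)
  expect_true(all(diff(pv) <= 1e-15))
  expect_true(all(pv > 0 & pv <= 1))
})

test_that("DP p-values equal exhaustive enumeration for widths <= 8", {
  set.seed(12)
  for (W in c(2, 4, 6, 8)) {
    m <- matrix(runif(4 * W, 0.02, 1), ncol = 4)
    m <- m / rowSums(m)
    bg <- runif(4, 0.1, 0.4); bg <- bg / sum(bg)
    p <- pwm(m, background = bg, motif_id = paste0("w", W))
    smax <- sum(apply(score_matrix(p), 1, max))
    for (s in c(smax, smax * 0.6, 0, smax * -0.5)) {
      expect_equal(score_pvalue(p, s), enumeration_pvalue(p, s),
                   tolerance = 1e-12)
    }
  }
})

test_that("threshold inversion and scanning edge cases", {
  # width-10 motif: the score distribution is fine enough to attain 1e-3
  thr <- pwm_threshold_score(default_sim_pwm(), 1e-3)
  expect_lte(thr$p_value, 1e-3)
  # a 2-bp motif cannot attain p = 1e-3 (tails are multiples of 1/16)
  p <- two_base_pwm()
  expect_true(is.infinite(pwm_threshold_score(p, 1e-3)$score))
  # p_threshold = 1 -> every position on both strands is a hit
  seqs <- c(x = "ACGTACGT")
  h <- scan_sequences(p, seqs, p_threshold = 1)
  expect_equal(nrow(h), 2 * (8 - 2 + 1))
  # unknown chromosome rejected when a genome is supplied
  expect_error(scan_sequences(p, c(zz = "ACGT"),
                              genome = chrom_sizes(c(c1 = 10))),
               "absent")
})

test_that("a planted consensus is recovered at its exact position", {
  set.seed(19)
  p <- default_sim_pwm()
  bg <- sample(c("A", "C", "G", "T"), 10000, TRUE)
  consensus <- strsplit("TTCCCGGGAA", "")[[1]]
  bg[5001:5010] <- consensus
  h <- scan_sequences(p, c(chr = paste(bg, collapse = "")),
                      p_threshold = 1e-4)
  top <- h[h$strand == "+", ]
  expect_true(5000 %in% top$start)
  hit <- h[h$start == 5000 & h$strand == "+", ]
  expect_equal(hit$score, score_site(p, "TTCCCGGGAA"))
  expect_equal(hit$end, 5010)
})

test_that("occupancy_curve handles the trivial extremes and partitions hits", {
  hits <- data.frame(chrom = "c1", start = seq(0, 990, 10),
                     end = seq(8, 998, 10), strand = "+",
                     score = rep(c(2.5, 7.5), 50), p_value = 1e-5)
  open_r <- region_set(data.frame(chrom = "c1", start = 0, end = 500))
  none <- region_set(data.frame(chrom = "c2", start = 0, end = 10))
  all_peaks <- region_set(data.frame(chrom = "c1", start = 0, end = 1000))
  a1 <- annotate_hits(hits, none, open_r)
  oc1 <- occupancy_curve(a1)
  expect_true(all(oc1$frac_bound_in_open %in% c(0, NA)))
  a2 <- annotate_hits(hits, all_peaks, open_r)
  oc2 <- occupancy_curve(a2)
  populated <- oc2$n_in_open + oc2$n_outside > 0
  expect_true(all(oc2$frac_bound_in_open[oc2$n_in_open > 0] == 1))
  expect_equal(sum(oc2$n_in_open) + sum(oc2$n_outside), nrow(hits))
  # empty bins are NA, not 0
  expect_true(anyNA(oc2$frac_bound_in_open))
  expect_error(occupancy_curve(a2, bin_width = 0), "bin_width")
})

test_that("MEME minimal format and TSV round trips", {
  p <- default_sim_pwm()
  meme <- c("MEME version 4", "", "ALPHABET= ACGT", "",
            "Background letter frequencies",
            "A 0.25 C 0.25 G 0.25 T 0.25", "",
            sprintf("MOTIF %s", p$motif_id),
            sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                    p$width),
            apply(p$freq, 1, function(r) paste(sprintf("%.6f", r),
                                               collapse = " ")))
  f <- withr::local_tempfile(fileext = ".meme")
  writeLines(meme, f)
  got <- read_meme(f, pseudocount = 0)[[1]]
  expect_equal(got$freq, p$freq, tolerance = 1e-5)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(p$freq), f2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  got2 <- read_pwm_tsv(f2)
  expect_equal(got2$freq, p$freq)
})
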