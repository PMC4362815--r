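test_that("read_bed parses minimal BED3 and rejects malformed input", {
  g <- chrom_sizes(c(chr1 = 1000))
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", f)
  rs <- read_bed(f, g)
  expect_equal(rs$intervals$start, 100)
  expect_equal(rs$intervals$end, 200)

  writeLines("chr1\t200\t100", f)
  expect_error(read_bed(f, g), "start >= end")
  writeLines(c("chr1\t1\t2", "chr1\tx\t5"), f)
  expect_error(read_bed(f, g), "line 2")
  writeLines("chr9\t1\t2", f)
  expect_error(read_bed(f, g), "unknown chromosome")
  writeLines("chr1\t900\t2000", f)
  expect_error(read_bed(f, g), "exceeds chromosome length")
})

test_that("BED round trip preserves a random 500-interval set exactly", {
  set.seed(42)
  df <- random_intervals(500, chrom_len = 1e5, chroms = c("c1", "c2"))
  df$score <- round(runif(500) * 100, 3)
  df$strand <- sample(c("+", "-", "*"), 500, replace = TRUE)
  df$summit <- df$start + floor((df$end - df$start) / 2)
  g <- chrom_sizes(c(c1 = 1e5, c2 = 1e5))
  rs <- region_set(df, genome = g, name = "rt")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(rs, f)
  back <- read_bed(f, g, name = "rt")
  expect_equal(back$intervals, rs$intervals)
})

test_that("merge_regions merges overlaps but not book-ended intervals", {
  rs <- region_set(data.frame(chrom = "c1", start = c(100, 150),
                              end = c(200, 250)))
  expect_equal(merge_regions(rs)$intervals[, c("start", "end")],
               data.frame(start = 100, end = 250))
  rs2 <- region_set(data.frame(chrom = "c1", start = c(100, 300),
                               end = c(200, 400)))
  expect_equal(nrow(merge_regions(rs2)$intervals), 2)
  book <- region_set(data.frame(chrom = "c1", start = c(0, 10),
                                end = c(10, 20)))
  expect_equal(nrow(merge_regions(book)$intervals), 2)
})

test_that("merge_regions matches per-base coverage oracle and is idempotent", {
  set.seed(7)
  df <- random_intervals(1000, chrom_len = 1e5)
  rs <- region_set(df)
  m <- merge_regions(rs)
  # disjoint, sorted
  iv <- m$intervals
  expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
  covered <- coverage_oracle(df, 1e5)
  expect_equal(sum(iv$end - iv$start), sum(covered))
  # every merged interval is fully covered and flanked by uncovered bases
  for (i in seq_len(nrow(iv)))
    expect_true(all(covered[(iv$start[i] + 1):iv$end[i]]))
  expect_equal(merge_regions(m)$intervals, m$intervals)
})

test_that("region_overlaps has strict >= 1 bp half-open semantics", {
  a <- region_set(data.frame(chrom = "c1", start = 0, end = 10))
  b1 <- region_set(data.frame(chrom = "c1", start = 9, end = 20))
  b2 <- region_set(data.frame(chrom = "c1", start = 10, end = 20))
  expect_true(region_overlaps(a, b1)$flags)
  expect_false(region_overlaps(a, b2)$flags)
  g1 <- chrom_sizes(c(c1 = 100)); g2 <- chrom_sizes(c(c1 = 200))
  expect_error(
    region_overlaps(region_set(a$intervals, genome = g1),
                    region_set(b1$intervals, genome = g2)),
    "different genomes")
})

test_that("region_overlaps matches the all-pairs oracle on random sets", {
  set.seed(11)
  for (rep in 1:3) {
    a_df <- random_intervals(200, chrom_len = 5e4, chroms = c("c1", "c2"))
    b_df <- random_intervals(200, chrom_len = 5e4, chroms = c("c1", "c2"))
    a <- region_set(a_df); b <- region_set(b_df)
    got <- region_overlaps(a, b)$flags
    expect_equal(got, overlap_oracle(a$intervals, b$intervals))
    # symmetry of existence on identical multisets
    expect_equal(any(region_overlaps(a, b)$flags),
                 any(region_overlaps(b, a)$flags))
  }
})

test_that("count_reads counts 5' positions in [start, end)", {
  rs <- region_set(data.frame(chrom = "c1", start = 0, end = 100))
  tags <- list(s1 = data.frame(chrom = "c1", pos = c(5, 50, 150)))
  m <- count_reads(rs, tags)
  expect_equal(as.numeric(m$counts), 2)
  expect_equal(m$samples$library_size, 3)

  empty <- region_set(data.frame(chrom = character(0), start = numeric(0),
                                 end = numeric(0)))
  m0 <- count_reads(empty, tags)
  expect_equal(nrow(m0$counts), 0)

  expect_error(count_reads(rs, list(s1 = data.frame(chrom = character(0),
                                                    pos = numeric(0)))),
               "zero reads")
})

test_that("count_reads agrees with a per-read linear scan oracle", {
  set.seed(13)
  df <- random_intervals(150, chrom_len = 2e4)
  rs <- region_set(df)
  tags <- list(
    s1 = data.frame(chrom = "c1", pos = floor(runif(2000, 0, 2e4))),
    s2 = data.frame(chrom = "c1", pos = floor(runif(500, 0, 2e4))))
  m <- count_reads(rs, tags)
  iv <- rs$intervals
  for (s in names(tags)) {
    oracle <- vapply(seq_len(nrow(iv)), function(i)
      sum(tags[[s]]$pos >= iv$start[i] & tags[[s]]$pos < iv$end[i]),
      numeric(1))
    expect_equal(as.numeric(m$counts[, s]), oracle)
  }
  # on disjoint regions a read lands in at most one region
  md <- count_reads(merge_regions(rs), tags)
  expect_true(all(colSums(md$counts) <= md$samples$library_size))
})

test_that("region set invariants are enforced", {
  expect_error(region_set(data.frame(chrom = "c1", start = -1, end = 5)),
               "negative start")
  expect_error(region_set(data.frame(chrom = "c1", start = 5, end = 5)),
               "start >= end")
  expect_error(region_set(data.frame(chrom = "c1", start = 0, end = 10,
                                     summit = 10)), "summit")
  expect_error(chrom_sizes(c(c1 = 0)), "> 0")
})

test_that("gene set I/O round trips and validates", {
  genes <- toy_genes()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genes(genes, f)
  back <- read_genes(f)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$tss, genes$tss)
  expect_equal(back$exon_starts, genes$exon_starts)
  # minus-strand TSS is the transcript 3' coordinate
  expect_equal(genes$tss[genes$gene_id == "gB"], 320000)
  expect_error(gene_set(data.frame(gene_id = "g", chrom = "c", strand = "+",
                                   tx_start = 10, tx_end = 5)),
               "tx_start")
})
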