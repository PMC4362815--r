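test_that("nearest_tss signs distances by gene strand", {
  genes <- toy_genes() # gA: + TSS 100000; gB: - TSS 320000; gC on c2
  ann <- nearest_tss(data.frame(chrom = "c1", pos = c(100000, 320100, 99000)),
                     genes)
  expect_equal(ann$gene_id, c("gA", "gB", "gA"))
  # summit at a + TSS -> 0; 100 bp right of a - strand TSS -> upstream (-100)
  expect_equal(ann$distance, c(0, -100, -1000))
  # chromosome without genes
  ann2 <- nearest_tss(data.frame(chrom = "c9", pos = 5), genes)
  expect_true(is.na(ann2$gene_id))
})

test_that("nearest_tss matches the all-pairs oracle with lexical ties", {
  set.seed(23)
  genes <- gene_set(data.frame(
    gene_id = sprintf("g%02d", 1:50),
    chrom = sample(c("c1", "c2"), 50, TRUE),
    strand = sample(c("+", "-"), 50, TRUE),
    tx_start = ts <- floor(runif(50, 0, 9e5)),
    tx_end = ts + floor(runif(50, 1000, 5e4))))
  summits <- data.frame(chrom = sample(c("c1", "c2"), 1000, TRUE),
                        pos = floor(runif(1000, 0, 1e6)))
  got <- nearest_tss(summits, genes)
  for (i in seq_len(nrow(summits))) {
    gi <- which(genes$chrom == summits$chrom[i])
    d <- abs(summits$pos[i] - genes$tss[gi])
    cand <- gi[d == min(d)]
    best <- cand[order(genes$gene_id[cand])][1]
    expect_identical(got$gene_id[i], genes$gene_id[best])
    expect_equal(abs(got$distance[i]), min(d))
  }
})

test_that("classify_feature applies the documented precedence", {
  genes <- toy_genes()
  # gA + strand TSS 100000: 1000 bp upstream -> promoter window [-2500,+500)
  expect_equal(classify_feature(data.frame(chrom = "c1", pos = 99000), genes),
               "promoter")
  # inside gA transcript (single exon covering the transcript) -> exon
  expect_equal(classify_feature(data.frame(chrom = "c1", pos = 110000), genes),
               "exon")
  # 5 kb upstream of gA -> upstream; 5 kb past gA TTS -> downstream
  expect_equal(classify_feature(data.frame(chrom = "c1", pos = 95000), genes),
               "upstream")
  expect_equal(classify_feature(data.frame(chrom = "c1", pos = 125000), genes),
               "downstream")
  # far from everything -> distal intergenic
  expect_equal(classify_feature(data.frame(chrom = "c1", pos = 200000), genes),
               "distal_intergenic")
  # precedence: a summit in an exon that is also < 10 kb downstream of
  # another gene's TTS stays exonic
  g2 <- gene_set(data.frame(
    gene_id = c("left", "host"), chrom = "c1", strand = "+",
    tx_start = c(10000, 21000), tx_end = c(20000, 40000)))
  expect_equal(classify_feature(data.frame(chrom = "c1", pos = 25000), g2),
               "exon")
  # intron: host gene with two exons and a gap
  g3 <- gene_set(data.frame(gene_id = "g", chrom = "c1", strand = "+",
                            tx_start = 1000, tx_end = 9000,
                            exon_starts = I(list(c(1000, 8000))),
                            exon_ends = I(list(c(2000, 9000)))))
  expect_equal(classify_feature(data.frame(chrom = "c1", pos = 5000), g3),
               "intron")
})

test_that("feature classes partition random summits", {
  set.seed(29)
  genes <- toy_genes()
  summits <- data.frame(chrom = sample(c("c1", "c2"), 500, TRUE),
                        pos = floor(runif(500, 0, 4e5)))
  cls <- classify_feature(summits, genes)
  expect_equal(length(cls), 500)
  expect_true(all(cls %in% c("promoter", "exon", "intron", "upstream",
                             "downstream", "distal_intergenic")))
})

test_that("tss_density integrates to 1 and is flat for uniform distances", {
  d0 <- rep(0, 100)
  res <- tss_density(d0, bandwidth = 300)
  expect_equal(res$density$y[res$density$x == 0], max(res$density$y))
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(trap(res$density$x, res$density$y), 1, tolerance = 1e-6)
  set.seed(33)
  du <- runif(50000, -10000, 10000)
  resu <- tss_density(du)
  # interior histogram bins flat within 3 SE of the uniform expectation
  h <- resu$histogram
  n <- sum(h$count)
  p <- 500 / 20000
  se <- sqrt(n * p * (1 - p))
  expect_true(all(abs(h$count - n * p) < 3 * se + 1e-9))
  expect_warning(tss_density(numeric(0)), "no annotations")
})

test_that("feature_enrichment equals the closed-form binomial tail", {
  # independent oracle: exact summation
  oracle <- function(k, n, f) sum(vapply(k:n, function(j)
    choose(n, j) * f^j * (1 - f)^(n - j), numeric(1)))
  expect_equal(feature_enrichment(5, 10, 0.1), oracle(5, 10, 0.1),
               tolerance = 1e-12)
  expect_equal(feature_enrichment(0, 10, 0.1), 1)
  expect_equal(feature_enrichment(10, 10, 0.999), oracle(10, 10, 0.999))
  for (case in list(c(3, 20, 0.05), c(17, 40, 0.3), c(1, 5, 0.5)))
    expect_equal(feature_enrichment(case[1], case[2], case[3]),
                 oracle(case[1], case[2], case[3]))
  expect_error(feature_enrichment(11, 10, 0.1), "k <= n")
  expect_error(feature_enrichment(1, 10, 1), "genome_fraction")
})

test_that("regulatory domains reproduce the two-gene hand construction", {
  g <- chrom_sizes(c(c1 = 2e6))
  genes <- gene_set(data.frame(gene_id = c("A", "B"), chrom = "c1",
                               strand = "+",
                               tx_start = c(100000, 300000),
                               tx_end = c(110000, 310000)))
  dom <- regulatory_domains(genes, g)
  a <- dom[dom$gene_id == "A", ]; b <- dom[dom$gene_id == "B", ]
  expect_equal(c(a$basal_start, a$basal_end), c(95000, 101000))
  expect_equal(c(b$basal_start, b$basal_end), c(295000, 301000))
  expect_equal(a$domain_end, 295000) # stops at B's basal edge
  expect_equal(b$domain_start, 101000) # stops at A's basal edge
  expect_equal(a$domain_start, 0) # 1 Mb cap clipped at chromosome start
  expect_equal(b$domain_end, 1301000) # basal end + 1 Mb
  # lone gene: basal +/- 1 Mb, clipped
  lone <- regulatory_domains(
    gene_set(data.frame(gene_id = "L", chrom = "c1", strand = "-",
                        tx_start = 990000, tx_end = 1000000)), g)
  expect_equal(lone$basal_start, 999000) # - strand: 1 kb down, 5 kb up
  expect_equal(lone$basal_end, 1005000)
  expect_equal(lone$domain_start, 0)
  expect_equal(lone$domain_end, 2e6)
})

test_that("domains contain their basal even when basal domains overlap", {
  g <- chrom_sizes(c(c1 = 1e6))
  genes <- gene_set(data.frame(gene_id = c("A", "B"), chrom = "c1",
                               strand = "+",
                               tx_start = c(100000, 103000),
                               tx_end = c(102000, 113000)))
  dom <- regulatory_domains(genes, g)
  expect_true(all(dom$domain_start <= dom$basal_start))
  expect_true(all(dom$domain_end >= dom$basal_end))
})

test_that("associate_regions assigns summits to all containing domains", {
  g <- chrom_sizes(c(c1 = 2e6))
  genes <- gene_set(data.frame(gene_id = c("A", "B"), chrom = "c1",
                               strand = "+",
                               tx_start = c(100000, 300000),
                               tx_end = c(110000, 310000)))
  dom <- regulatory_domains(genes, g)
  rs <- region_set(data.frame(
    chrom = "c1", start = c(150000, 1900000), end = c(150200, 1900200),
    summit = c(150100, 1900100)))
  res <- associate_regions(rs, dom)
  # the summit sits between the genes, inside both extended domains
  # (A extends right to B's basal, B extends left to A's basal)
  expect_equal(sort(unique(res$associations$gene_id)), c("A", "B"))
  expect_true(all(res$associations$region == 1))
  expect_equal(res$unassociated, 2L)
  # a summit inside two overlapping domains gets two associations
  dom2 <- dom
  dom2$domain_start <- c(0, 0)
  dom2$domain_end <- c(4e5, 4e5)
  res2 <- associate_regions(rs[1], dom2)
  expect_equal(sort(res2$associations$gene_id), c("A", "B"))
})

test_that("regions_near_genes uses an inclusive radius on midpoints", {
  # single gene so the boundary case is unambiguous
  genes <- gene_set(data.frame(gene_id = "gA", chrom = "c1", strand = "+",
                               tx_start = 100000, tx_end = 120000))
  mk <- function(mid) region_set(data.frame(chrom = "c1", start = mid - 50,
                                            end = mid + 50))
  expect_equal(length(regions_near_genes(mk(100000), genes, radius = 5e5)), 1)
  expect_equal(length(regions_near_genes(mk(600000), genes, radius = 5e5)), 1)
  expect_equal(length(regions_near_genes(mk(600001), genes, radius = 5e5)), 0)
  expect_warning(
    out <- regions_near_genes(mk(100000), genes[integer(0), ], radius = 100),
    "empty gene group")
  expect_equal(length(out), 0)
})
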