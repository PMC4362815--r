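# Strand-aware peak-to-TSS annotation, feature classification, smoothed
# TSS-distance density, binomial feature enrichment, and GREAT-style
# regulatory-domain gene association.

.summits_of <- function(regions) {
  df <- regions$intervals
  s <- df$summit
  miss <- is.na(s)
  if (any(miss))
    s[miss] <- floor((df$start[miss] + df$end[miss]) / 2)
  data.frame(chrom = df$chrom, pos = s, stringsAsFactors = FALSE)
}

#' Map summits to the nearest TSS, incorporating strandedness
#'
#' Distance is signed on the gene's strand: negative = upstream of the TSS,
#' positive = downstream. The nearest gene minimizes |distance|; ties are
#' broken by lexical gene_id. Summits on chromosomes without genes get an
#' `NA` gene and distance.
#'
#' @param summits data.frame with `chrom`, `pos` (or a `RegionSet`, in which
#'   case summits — midpoints when absent — are used).
#' @param genes `GeneSet`
#' @return data.frame: chrom, pos, gene_id, distance.
#' @export
nearest_tss <- function(summits, genes) {
  if (inherits(summits, "RegionSet")) summits <- .summits_of(summits)
  n <- nrow(summits)
  gene_id <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  for (ch in unique(summits$chrom)) {
    gi <- which(genes$chrom == ch)
    si <- which(summits$chrom == ch)
    if (!length(gi)) next
    tss <- genes$tss[gi]
    pos <- summits$pos[si]
    for (k in seq_along(si)) {
      d_abs <- abs(pos[k] - tss)
      cand <- gi[d_abs == min(d_abs)]
      g <- cand[order(genes$gene_id[cand])][1]
      gene_id[si[k]] <- genes$gene_id[g]
      sign_ <- if (genes$strand[g] == "+") 1 else -1
      distance[si[k]] <- sign_ * (pos[k] - genes$tss[g])
    }
  }
  data.frame(chrom = summits$chrom, pos = summits$pos, gene_id = gene_id,
             distance = distance, stringsAsFactors = FALSE)
}

#' Classify summits into genomic feature classes
#'
#' Classes, in precedence order: `promoter` (window around a TSS), `exon`,
#' `intron` (inside a transcript but not exonic), `upstream` (<= 10 kb
#' upstream of a TSS), `downstream` (<= 10 kb downstream of a TTS) and
#' `distal_intergenic` (none of the above). Windows are strand-aware.
#'
#' @param summits data.frame (`chrom`, `pos`) or `RegionSet`.
#' @param genes `GeneSet`
#' @param promoter_window numeric `c(upstream, downstream)` in bp around the
#'   TSS; default `c(2500, 500)` = -2,500..+500. Use `c(2500, 0)` for the
#'   upstream-only preset.
#' @param flank_bp upstream/downstream flank width (default 10000).
#' @return character vector of classes, one per summit.
#' @export
classify_feature <- function(summits, genes,
                             promoter_window = c(2500, 500),
                             flank_bp = 10000) {
  if (inherits(summits, "RegionSet")) summits <- .summits_of(summits)
  n <- nrow(summits)
  out <- rep("distal_intergenic", n)
  for (i in seq_len(n)) {
    ch <- summits$chrom[i]
    p <- summits$pos[i]
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    in_prom <- in_exon <- in_intron <- in_up <- in_down <- FALSE
    for (g in gi) {
      tss <- genes$tss[g]; tts <- genes$tts[g]
      plus <- genes$strand[g] == "+"
      # signed position relative to TSS on the gene's strand
      rel <- if (plus) p - tss else tss - p
      if (rel >= -promoter_window[1] && rel < promoter_window[2])
        in_prom <- TRUE
      lo <- genes$tx_start[g]; hi <- genes$tx_end[g]
      if (p >= lo && p < hi) {
        ex <- any(p >= genes$exon_starts[[g]] & p < genes$exon_ends[[g]])
        if (ex) in_exon <- TRUE else in_intron <- TRUE
      }
      if (rel >= -flank_bp && rel < 0) in_up <- TRUE
      rel_tts <- if (plus) p - tts else tts - p
      if (rel_tts >= 0 && rel_tts < flank_bp) in_down <- TRUE
    }
    out[i] <- if (in_prom) "promoter" else if (in_exon) "exon" else
      if (in_intron) "intron" else if (in_up) "upstream" else
        if (in_down) "downstream" else "distal_intergenic"
  }
  out
}

#' Histogram and Gaussian-kernel density of summit-to-TSS distances
#'
#' Distances outside the window are dropped; the density is a Gaussian KDE
#' evaluated on the window grid and renormalized to integrate to 1 over the
#' window (trapezoid rule).
#'
#' @param distances numeric signed distances (bp), e.g. from [nearest_tss()].
#' @param bin histogram bin width, bp (default 500).
#' @param window half-width of the window about 0 (default 10000).
#' @param bandwidth Gaussian kernel standard deviation, bp (default = `bin`).
#' @param grid_n number of density evaluation points (default 401).
#' @return list with `histogram` (bin_lo, bin_mid, count) and `density`
#'   (x, y); empty (with a warning) when no distance falls in the window.
#' @export
tss_density <- function(distances, bin = 500, window = 10000,
                        bandwidth = bin, grid_n = 401) {
  if (bandwidth <= 0) stop("tss_density: bandwidth must be > 0")
  d <- distances[!is.na(distances) & abs(distances) <= window]
  if (!length(d)) {
    warning("tss_density: no annotations within the window")
    return(list(histogram = data.frame(bin_lo = numeric(0),
                                       bin_mid = numeric(0),
                                       count = numeric(0)),
                density = data.frame(x = numeric(0), y = numeric(0))))
  }
  breaks <- seq(-window, window, by = bin)
  cnt <- table(cut(d, breaks = breaks, right = FALSE, include.lowest = TRUE))
  hist_df <- data.frame(bin_lo = breaks[-length(breaks)],
                        bin_mid = breaks[-length(breaks)] + bin / 2,
                        count = as.numeric(cnt))
  x <- seq(-window, window, length.out = grid_n)
  y <- vapply(x, function(xx) mean(dnorm(xx, mean = d, sd = bandwidth)),
              numeric(1))
  area <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  y <- y / area
  list(histogram = hist_df, density = data.frame(x = x, y = y))
}

#' One-sided binomial enrichment test
#'
#' `p = P(X >= k)` with `X ~ Binomial(n, genome_fraction)`: the probability of
#' seeing at least the observed number of summits in a feature category whose
#' genomic footprint is `genome_fraction` of the genome.
#'
#' @param observed_k observed count in the category
#' @param n total number of summits
#' @param genome_fraction fraction of the genome in the category, in (0,1)
#' @return one-sided p-value.
#' @export
feature_enrichment <- function(observed_k, n, genome_fraction) {
  if (observed_k < 0 || observed_k > n)
    stop("feature_enrichment: need 0 <= k <= n")
  if (genome_fraction <= 0 || genome_fraction >= 1)
    stop("feature_enrichment: genome_fraction must be in (0,1)")
  pbinom(observed_k - 1, n, genome_fraction, lower.tail = FALSE)
}

#' Genome fraction occupied by each feature class
#'
#' Computes, from the supplied gene model and chromosome sizes, the fraction
#' of the genome covered by each class under the same precedence as
#' [classify_feature()] (approximated by classifying every `step`-th base).
#'
#' @param genes `GeneSet`
#' @param genome `ChromSizes`
#' @param step sampling stride in bp (default 1000)
#' @param ... passed to [classify_feature()]
#' @return named numeric vector of fractions summing to 1.
#' @export
feature_genome_fraction <- function(genes, genome, step = 1000, ...) {
  pts <- do.call(rbind, lapply(names(genome), function(ch)
    data.frame(chrom = ch, pos = seq(0, genome[[ch]] - 1, by = step),
               stringsAsFactors = FALSE)))
  cls <- classify_feature(pts, genes, ...)
  tab <- table(cls)
  structure(as.numeric(tab) / sum(tab), names = names(tab))
}

#' GREAT-style regulatory domains (basal plus extension)
#'
#' Each gene gets a basal domain from `upstream_bp` upstream to
#' `downstream_bp` downstream of its TSS (strand-aware). The domain is then
#' extended in both directions to the nearest other gene's basal-domain edge,
#' but by no more than `max_extension_bp` per direction, and clipped to the
#' chromosome. When another basal domain overlaps the gene's own basal
#' domain, the extension on that side is zero (the domain always contains its
#' basal).
#'
#' @param genes `GeneSet`
#' @param genome `ChromSizes`
#' @param upstream_bp basal upstream width (default 5000)
#' @param downstream_bp basal downstream width (default 1000)
#' @param max_extension_bp distal cap per direction (default 1e6)
#' @return data.frame: gene_id, chrom, strand, tss, basal_start, basal_end,
#'   domain_start, domain_end (0-based half-open).
#' @export
regulatory_domains <- function(genes, genome, upstream_bp = 5000,
                               downstream_bp = 1000, max_extension_bp = 1e6) {
  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, genes$tss - upstream_bp,
                        genes$tss - downstream_bp)
  basal_end <- ifelse(plus, genes$tss + downstream_bp,
                      genes$tss + upstream_bp)
  basal_start <- pmax(basal_start, 0)
  basal_end <- pmin(basal_end, as.numeric(genome[genes$chrom]))
  domain_start <- numeric(nrow(genes))
  domain_end <- numeric(nrow(genes))
  for (ch in unique(genes$chrom)) {
    idx <- which(genes$chrom == ch)
    bs <- basal_start[idx]; be <- basal_end[idx]
    for (k in seq_along(idx)) {
      others <- setdiff(seq_along(idx), k)
      # left: nearest other basal end at or left of our basal start
      left_edges <- be[others][be[others] <= bs[k]]
      left_lim <- max(c(left_edges, bs[k] - max_extension_bp, 0))
      # any other basal overlapping ours blocks extension on both sides
      overl <- others[bs[others] < be[k] & be[others] > bs[k]]
      if (any(be[overl] > bs[k] & bs[overl] < bs[k])) left_lim <- bs[k]
      right_edges <- bs[others][bs[others] >= be[k]]
      right_lim <- min(c(right_edges, be[k] + max_extension_bp,
                         genome[[ch]]))
      if (any(bs[overl] < be[k] & be[overl] > be[k])) right_lim <- be[k]
      domain_start[idx[k]] <- min(left_lim, bs[k])
      domain_end[idx[k]] <- max(right_lim, be[k])
    }
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             strand = genes$strand, tss = genes$tss,
             basal_start = basal_start, basal_end = basal_end,
             domain_start = domain_start, domain_end = domain_end,
             stringsAsFactors = FALSE)
}

#' Associate regions to genes via regulatory domains
#'
#' A region is assigned to every gene whose regulatory domain contains its
#' summit (midpoint when the summit is absent). Regions falling in no domain
#' are reported as unassociated.
#'
#' @param regions `RegionSet`
#' @param domains data.frame from [regulatory_domains()]
#' @return list with `associations` (gene_id, region index, chrom, summit)
#'   and `unassociated` (region indices).
#' @export
associate_regions <- function(regions, domains) {
  sm <- .summits_of(regions)
  res <- list()
  assoc_any <- logical(nrow(sm))
  for (ch in unique(sm$chrom)) {
    di <- which(domains$chrom == ch)
    si <- which(sm$chrom == ch)
    if (!length(di)) next
    for (d in di) {
      inside <- si[sm$pos[si] >= domains$domain_start[d] &
                     sm$pos[si] < domains$domain_end[d]]
      if (length(inside)) {
        assoc_any[inside] <- TRUE
        res[[length(res) + 1]] <- data.frame(
          gene_id = domains$gene_id[d], region = inside,
          chrom = ch, summit = sm$pos[inside], stringsAsFactors = FALSE)
      }
    }
  }
  associations <- if (length(res)) do.call(rbind, res) else
    data.frame(gene_id = character(0), region = integer(0),
               chrom = character(0), summit = numeric(0))
  associations <- associations[order(associations$gene_id,
                                     associations$region), , drop = FALSE]
  rownames(associations) <- NULL
  list(associations = associations, unassociated = which(!assoc_any))
}

#' Regions near a gene group
#'
#' Returns the regions whose midpoint lies within `radius` bp (inclusive) of
#' the TSS of any gene in the group.
#'
#' @param regions `RegionSet`
#' @param genes `GeneSet` (the group)
#' @param radius window half-width, bp (default 5e5)
#' @return `RegionSet` subset.
#' @export
regions_near_genes <- function(regions, genes, radius = 5e5) {
  if (radius <= 0) stop("regions_near_genes: radius must be > 0")
  if (nrow(genes) == 0) {
    warning("regions_near_genes: empty gene group")
    return(regions[integer(0)])
  }
  df <- regions$intervals
  mid <- floor((df$start + df$end) / 2)
  keep <- logical(nrow(df))
  for (ch in unique(df$chrom)) {
    tss <- genes$tss[genes$chrom == ch]
    if (!length(tss)) next
    ri <- which(df$chrom == ch)
    for (i in ri) keep[i] <- any(abs(mid[i] - tss) <= radius)
  }
  regions[which(keep)]
}
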