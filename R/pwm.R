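# Position weight matrices: log2-odds "motif quality" scoring in bits against
# a 0-order background, exact score p-values by dynamic programming over a
# discretized score grid (FIMO-style), genome scanning on both strands, and
# occupancy-vs-score curves stratified by open chromatin.

.BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param freq numeric W x 4 matrix of per-position base probabilities,
#'   columns A, C, G, T. Rows must sum to 1; a pseudocount can be applied at
#'   construction to remove zeros.
#' @param background length-4 base probabilities of the 0-order background
#'   (default uniform). Exact p-values are always computed under this 0-order
#'   model; a higher-order background, when used for discovery, is context
#'   only.
#' @param motif_id identifier string.
#' @param pseudocount added to every cell before row renormalization
#'   (default 0; use a small value such as 1e-3 if the matrix has zeros).
#' @return a `PWM` object.
#' @export
pwm <- function(freq, background = rep(0.25, 4), motif_id = "motif",
                pseudocount = 0) {
  freq <- as.matrix(freq)
  if (ncol(freq) != 4) stop("pwm: freq must have 4 columns (A,C,G,T)")
  if (pseudocount < 0) stop("pwm: pseudocount must be >= 0")
  if (pseudocount > 0) freq <- (freq + pseudocount) / rowSums(freq + pseudocount)
  if (any(abs(rowSums(freq) - 1) > 1e-9))
    stop("pwm: each row of freq must sum to 1 (use pseudocount to renormalize)")
  if (any(freq <= 0))
    stop("pwm: zero/negative probabilities; supply a pseudocount")
  background <- as.numeric(background)
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0))
    stop("pwm: background must be 4 positive probabilities summing to 1")
  colnames(freq) <- .BASES
  structure(list(motif_id = motif_id, width = nrow(freq), freq = freq,
                 background = background, pseudocount = pseudocount),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, max score %.3f bits\n",
              x$motif_id, x$width, sum(apply(score_matrix(x), 1, max))))
  invisible(x)
}

#' Log2-odds score matrix (bits) of a PWM
#' @param p `PWM`
#' @return W x 4 matrix `log2(freq / background)`.
#' @export
score_matrix <- function(p) {
  sweep(log2(p$freq), 2, log2(p$background), "-")
}

# reverse-complement score matrix: scanning forward with it gives the score
# of the minus-strand match at the same window
.rc_score_matrix <- function(L) {
  L[rev(seq_len(nrow(L))), c(4, 3, 2, 1), drop = FALSE]
}

#' Score one or more W-mers against a PWM
#'
#' Score = sum over positions of `log2(freq[i, base] / background[base])`,
#' in bits. Sequences containing non-ACGT characters score `NA`.
#'
#' @param p `PWM`
#' @param sequence character vector of sequences, each of length `p$width`.
#' @return numeric score(s) in bits.
#' @export
score_site <- function(p, sequence) {
  L <- score_matrix(p)
  vapply(toupper(sequence), function(s) {
    b <- match(strsplit(s, "")[[1]], .BASES)
    if (length(b) != p$width)
      stop("score_site: sequence length must equal motif width")
    if (anyNA(b)) return(NA_real_)
    sum(L[cbind(seq_len(p$width), b)])
  }, numeric(1), USE.NAMES = FALSE)
}

# Discretized score distribution under the 0-order background.
# Returns integer grid values (units of `precision` bits) and their
# probabilities, plus the rounded per-position integer score matrix.
pwm_score_distribution <- function(p, precision = 1e-3) {
  if (precision <= 0) stop("pwm_score_distribution: precision must be > 0")
  L <- score_matrix(p)
  I <- matrix(as.integer(round(L / precision)), nrow = nrow(L))
  lo <- sum(apply(I, 1, min))
  hi <- sum(apply(I, 1, max))
  # dist[k] = P(sum == lo + k - 1)
  dist <- numeric(hi - lo + 1)
  cur_lo <- 0L
  cur <- 1
  for (w in seq_len(nrow(I))) {
    row <- I[w, ]
    rlo <- min(row)
    new_lo <- cur_lo + rlo
    new <- numeric(length(cur) + (max(row) - rlo))
    for (b in 1:4) {
      off <- row[b] - rlo
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * p$background[b]
    }
    cur <- new
    cur_lo <- new_lo
  }
  stopifnot(cur_lo == lo, length(cur) == hi - lo + 1)
  list(values = seq.int(lo, hi), probs = cur, precision = precision, int = I,
       tail = rev(cumsum(rev(cur))))
}

#' Exact p-value of a PWM score
#'
#' Tail probability `P(score >= observed)` of the discretized score
#' distribution under the 0-order background, computed by convolving the
#' per-position score distributions over a grid of step `precision` bits.
#'
#' @param p `PWM`
#' @param score observed score(s), bits.
#' @param precision score-grid step in bits (default 1/1000).
#' @return p-value(s) in (0, 1].
#' @export
score_pvalue <- function(p, score, precision = 1e-3) {
  d <- pwm_score_distribution(p, precision)
  vapply(score, function(s) {
    k <- as.integer(round(s / precision))
    if (k <= d$values[1]) return(1)
    if (k > d$values[length(d$values)]) return(0)
    d$tail[k - d$values[1] + 1]
  }, numeric(1))
}

#' Score threshold attaining a p-value level
#'
#' Smallest grid score whose exact tail probability is <= `p_threshold`;
#' scanning at this score threshold reproduces hit calling at the p-value
#' threshold.
#'
#' @param p `PWM`
#' @param p_threshold p-value cutoff (default 1e-4).
#' @param precision grid step, bits.
#' @return list with `score` (bits) and `p_value` actually attained. When
#'   even the maximum score has p > p_threshold, `score = Inf`.
#' @export
pwm_threshold_score <- function(p, p_threshold = 1e-4, precision = 1e-3) {
  if (p_threshold >= 1)
    return(list(score = -Inf, p_value = 1))
  d <- pwm_score_distribution(p, precision)
  ok <- which(d$tail <= p_threshold)
  if (!length(ok)) return(list(score = Inf, p_value = NA_real_))
  k <- ok[1]
  list(score = d$values[k] * precision, p_value = d$tail[k])
}

#' Scan sequences with a PWM on both strands
#'
#' Every window of width W on either strand whose exact score p-value is
#' <= `p_threshold` is reported. Windows containing non-ACGT characters are
#' skipped. Overlapping hits are all kept; hits at the same coordinates on
#' opposite strands are distinct.
#'
#' @param p `PWM`
#' @param sequences named character vector (chromosome name -> sequence) or a
#'   `Biostrings::DNAStringSet`.
#' @param p_threshold hit p-value cutoff (default 1e-4).
#' @param precision score-grid step, bits.
#' @param genome optional `ChromSizes`; sequences absent from it are an error.
#' @return data.frame of hits: chrom, start, end (0-based half-open), strand,
#'   score (bits), p_value; sorted by (chrom, start, strand).
#' @export
scan_sequences <- function(p, sequences, p_threshold = 1e-4, precision = 1e-3,
                           genome = NULL) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- structure(as.character(sequences), names = names(sequences))
  if (is.null(names(sequences)))
    stop("scan_sequences: sequences must be named by chromosome")
  if (!is.null(genome)) {
    unknown <- setdiff(names(sequences), names(genome))
    if (length(unknown))
      stop("scan_sequences: chromosome(s) absent from genome: ",
           paste(unknown, collapse = ", "))
  }
  d <- pwm_score_distribution(p, precision)
  thr <- pwm_threshold_score(p, p_threshold, precision)
  L <- score_matrix(p)
  Lrc <- .rc_score_matrix(L)
  W <- p$width
  pval_of <- function(s) {
    k <- as.integer(round(s / precision))
    d$tail[pmin(pmax(k - d$values[1] + 1, 1), length(d$tail))]
  }
  res <- list()
  for (ch in names(sequences)) {
    b <- match(strsplit(toupper(sequences[[ch]]), "")[[1]], .BASES)
    n <- length(b)
    if (n < W) next
    np <- n - W + 1
    fwd <- numeric(np)
    rev_ <- numeric(np)
    ok <- !logical(np)
    for (w in seq_len(W)) {
      bw <- b[w:(w + np - 1)]
      miss <- is.na(bw)
      ok <- ok & !miss
      bw[miss] <- 1L
      fwd <- fwd + L[w, bw]
      rev_ <- rev_ + Lrc[w, bw]
    }
    thr_int <- if (is.finite(thr$score)) as.integer(round(thr$score / precision))
               else thr$score
    for (str in c("+", "-")) {
      sc <- if (str == "+") fwd else rev_
      hit <- ok & (round(sc / precision) >= thr_int)
      if (!any(hit)) next
      i <- which(hit)
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, start = i - 1, end = i - 1 + W, strand = str,
        score = sc[i], p_value = pval_of(sc[i]), stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$strand, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Annotate motif hits against binding peaks and open chromatin
#'
#' @param hits data.frame from [scan_sequences()] (or any table with chrom,
#'   start, end).
#' @param peaks `RegionSet` of TF binding sites; a hit is `bound` when it
#'   shares >= 1 bp with a peak.
#' @param open_regions `RegionSet` of open chromatin; sets `in_open_chromatin`.
#' @return `hits` with logical columns `bound` and `in_open_chromatin`.
#' @export
annotate_hits <- function(hits, peaks, open_regions) {
  # region_set sorts; keep original order via an index column
  hs2 <- region_set(cbind(hits[, c("chrom", "start", "end")],
                          name = as.character(seq_len(nrow(hits)))),
                    name = "hits")
  ord <- as.integer(hs2$intervals$name)
  bound <- logical(nrow(hits))
  inopen <- logical(nrow(hits))
  bound[ord] <- region_overlaps(hs2, peaks)$flags
  inopen[ord] <- region_overlaps(hs2, open_regions)$flags
  hits$bound <- bound
  hits$in_open_chromatin <- inopen
  hits
}

#' Occupancy as a function of motif quality score
#'
#' Bins annotated hits by score and reports, separately inside and outside
#' open chromatin, how many hits fall in each bin and what fraction of them
#' is bound. Bins with no hits in a stratum get `NA` (not 0) fractions.
#'
#' @param hits data.frame with `score`, `bound`, `in_open_chromatin` (see
#'   [annotate_hits()]).
#' @param bin_width score bin width in bits (default 1).
#' @return data.frame: bin_lo, bin_mid, n_in_open, n_bound_in_open,
#'   frac_bound_in_open, n_outside, n_bound_outside, frac_bound_outside.
#' @export
occupancy_curve <- function(hits, bin_width = 1) {
  if (bin_width <= 0) stop("occupancy_curve: bin_width must be > 0")
  if (!all(c("score", "bound", "in_open_chromatin") %in% names(hits)))
    stop("occupancy_curve: hits must be annotated (see annotate_hits)")
  bin <- floor(hits$score / bin_width)
  rng <- seq.int(min(bin), max(bin))
  agg <- function(sel) {
    n <- as.numeric(table(factor(bin[sel], levels = rng)))
    nb <- as.numeric(table(factor(bin[sel & hits$bound], levels = rng)))
    frac <- ifelse(n > 0, nb / n, NA_real_)
    list(n = n, nb = nb, frac = frac)
  }
  io <- agg(hits$in_open_chromatin)
  oo <- agg(!hits$in_open_chromatin)
  data.frame(bin_lo = rng * bin_width, bin_mid = (rng + 0.5) * bin_width,
             n_in_open = io$n, n_bound_in_open = io$nb,
             frac_bound_in_open = io$frac,
             n_outside = oo$n, n_bound_outside = oo$nb,
             frac_bound_outside = oo$frac)
}

#' Read PWMs from MEME minimal motif format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections and
#' the optional `Background letter frequencies` line.
#'
#' @param path file path
#' @param pseudocount applied at construction (default 1e-3 to clear zeros)
#' @return list of `PWM`s, named by motif id.
#' @export
read_meme <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    toks <- strsplit(trimws(lines[bgi[1] + 1]), "\\s+")[[1]]
    v <- as.numeric(toks[seq(2, 8, by = 2)])
    if (!anyNA(v)) bg <- v / sum(v)
  }
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop("read_meme: no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    mi <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[mi]))
    rows <- lines[(mi + 1):(mi + w)]
    m <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(x) as.numeric(x[1:4]), numeric(4)))
    out[[id]] <- pwm(m, background = bg, motif_id = id,
                     pseudocount = pseudocount)
  }
  out
}

#' Read a PWM from a plain W x 4 TSV (columns A, C, G, T)
#' @param path file path (header optional; detected by non-numeric first line)
#' @param background,motif_id,pseudocount passed to [pwm()]
#' @return `PWM`
#' @export
read_pwm_tsv <- function(path, background = rep(0.25, 4), motif_id = NULL,
                         pseudocount = 0) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  header <- anyNA(suppressWarnings(as.numeric(first)))
  m <- as.matrix(read.delim(path, header = header))
  if (is.null(motif_id)) motif_id <- sub("\\.[^.]*$", "", basename(path))
  pwm(m, background = background, motif_id = motif_id,
      pseudocount = pseudocount)
}

#' Write motif hits as BED6 plus score/p-value columns
#' @param hits data.frame from [scan_sequences()]
#' @param path output path
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(chrom = hits$chrom,
                    start = format(hits$start, scientific = FALSE, trim = TRUE),
                    end = format(hits$end, scientific = FALSE, trim = TRUE),
                    name = sprintf("hit_%d", seq_len(nrow(hits))),
                    score = format(hits$score, digits = 10, trim = TRUE),
                    strand = hits$strand,
                    p_value = format(hits$p_value, digits = 10, trim = TRUE),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
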