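# in-code fixture builders and independent oracles shared across tests
# (all coordinates here are 1-based closed, the GRanges convention)

make_gm <- function(genes, seqlengths, exons = NULL, utr5 = NULL,
                    utr3 = NULL) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = genes$strand)
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  feat <- function(df) {
    if (is.null(df)) {
      g <- GenomicRanges::GRanges()
      S4Vectors::mcols(g)$gene_id <- character(0)
      return(g)
    }
    i <- match(df$gene_id, genes$gene_id)
    g <- GenomicRanges::GRanges(genes$chrom[i],
                                IRanges::IRanges(df$start, df$end),
                                strand = genes$strand[i])
    S4Vectors::mcols(g)$gene_id <- df$gene_id
    g
  }
  ex <- if (is.null(exons))
    data.frame(gene_id = genes$gene_id, start = genes$start,
               end = genes$end)
  else exons
  structure(list(genes = gr, exons = feat(ex), utr5 = feat(utr5),
                 utr3 = feat(utr3), seqlengths = seqlengths),
            class = "gene_models")
}

make_track <- function(chrom, start, end, score) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         score = score)
}

make_peaks <- function(chrom, start, end, mark, tissue) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$mark <- mark
  S4Vectors::mcols(gr)$tissue <- tissue
  S4Vectors::mcols(gr)$score <- NA_real_
  gr
}

# dense per-base signal vector for brute-force oracles
dense_signal <- function(track, chrom, len) {
  v <- numeric(len)
  t <- track[as.character(GenomicRanges::seqnames(track)) == chrom]
  for (i in seq_along(t))
    v[GenomicRanges::start(t)[i]:GenomicRanges::end(t)[i]] <-
      S4Vectors::mcols(t)$score[i]
  v
}

# per-base region labels for the distribution oracle
dense_labels <- function(index, chrom, len) {
  lab <- rep(NA_character_, len)
  for (cl in names(index)) {
    g <- index[[cl]]
    g <- g[as.character(GenomicRanges::seqnames(g)) == chrom]
    for (i in seq_along(g))
      lab[GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]] <- cl
  }
  lab
}

# exhaustive-enumeration hypergeometric upper tail: draw all size-n
# subsets of 1..N, category = first K elements
enum_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# quadratic all-pairs overlap check for mark assignment
bf_assign <- function(windows, peaks) {
  out <- logical(length(windows))
  ws <- GenomicRanges::start(windows); we <- GenomicRanges::end(windows)
  wc <- as.character(GenomicRanges::seqnames(windows))
  ps <- GenomicRanges::start(peaks); pe <- GenomicRanges::end(peaks)
  pc <- as.character(GenomicRanges::seqnames(peaks))
  for (i in seq_along(windows)) {
    hit <- FALSE
    for (j in seq_along(peaks)) {
      if (wc[i] == pc[j] && ws[i] <= pe[j] && ps[j] <= we[i]) {
        hit <- TRUE; break
      }
    }
    out[i] <- hit
  }
  out
}

# per-base averaging oracle for one gene's metagene row
bf_metagene_row <- function(sig, gstart, gend, strand, flank_bp,
                            flank_bins, body_bins) {
  get <- function(pos) ifelse(pos >= 1 & pos <= length(sig), sig[pos], 0)
  W <- gend - gstart + 1
  fe <- round(seq(0, flank_bp, length.out = flank_bins + 1))
  be <- round(seq(0, W, length.out = body_bins + 1))
  vals <- numeric(0)
  for (b in seq_len(flank_bins)) {
    pos <- (gstart - flank_bp + fe[b]):(gstart - flank_bp + fe[b + 1] - 1)
    vals <- c(vals, mean(get(pos)))
  }
  for (b in seq_len(body_bins)) {
    pos <- (gstart + be[b]):(gstart + be[b + 1] - 1)
    vals <- c(vals, mean(get(pos)))
  }
  for (b in seq_len(flank_bins)) {
    pos <- (gend + fe[b] + 1):(gend + fe[b + 1])
    vals <- c(vals, mean(get(pos)))
  }
  if (strand == "-") vals <- rev(vals)
  vals
}

# small synthetic configuration for fast end-to-end tests
small_sim <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, chrom_lengths = c(Chr1 = 8e5, Chr2 = 8e5),
         n_genes = 120, n_deg = 20, n_pref = 30,
         n_panel_background = 400, n_tf = 60),
    list(...))
  do.call(sim_config, args)
}
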