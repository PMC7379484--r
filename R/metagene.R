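# shared bin-mean helper: mean per-base signal in nominal 1-based bins,
# counting bases outside the chromosome as zero signal
bin_means_rle <- function(cov_chr, starts, ends) {
  widths <- ends - starts + 1
  len <- length(cov_chr)
  cs <- pmax(starts, 1)
  ce <- pmin(ends, len)
  sums <- numeric(length(starts))
  ok <- cs <= ce
  if (any(ok))
    sums[ok] <- IRanges::viewSums(IRanges::Views(cov_chr, cs[ok], ce[ok]))
  sums / widths
}

track_coverage <- function(track, seqlengths) {
  GenomeInfoDb::seqlevels(track) <- names(seqlengths)
  GenomeInfoDb::seqlengths(track) <- seqlengths
  GenomicRanges::coverage(track, weight = "score")
}

#' Scaled meta-gene signal profile (flank / body / flank)
#'
#' Averages a signal track over genes after mapping each gene onto a common
#' coordinate system: fixed-width upstream flank bins, gene-body bins of
#' equal fractional width (the body is rescaled), and fixed-width
#' downstream flank bins. Bin values are mean per-base signal, so flank and
#' body bins are directly comparable. Minus-strand genes are reversed so
#' bin 1 is always the 5' end. Genes whose body is shorter than
#' `body_bins` bases are skipped (no interpolation is invented); the count
#' of skipped genes is reported.
#'
#' @param track Signal `GRanges` with `score`.
#' @param gm A `gene_models` object.
#' @param flank_bp Flank extent on each side, bp (default 1 kb).
#' @param flank_bins Bins per flank.
#' @param body_bins Bins across the rescaled gene body.
#' @return A `metagene_profile` list: `bin_labels`, `mean_signal`
#'   (length `2*flank_bins + body_bins`), `n_genes`, `n_skipped`, and
#'   `matrix` (per-gene rows, for downstream use).
#' @export
metagene_profile <- function(track, gm, flank_bp = 1000,
                             flank_bins = 20, body_bins = 60) {
  stopifnot(inherits(gm, "gene_models"))
  if (flank_bins < 1 || body_bins < 1)
    stop("flank_bins and body_bins must be >= 1")
  if (flank_bp < flank_bins)
    stop("flank_bp must be >= flank_bins")
  cov <- track_coverage(track, gm$seqlengths)
  g <- gm$genes
  keep <- width(g) >= body_bins
  n_skipped <- sum(!keep)
  g <- g[keep]
  nb <- 2L * flank_bins + body_bins
  rows <- matrix(NA_real_, nrow = length(g), ncol = nb)
  flank_edges <- round(seq(0, flank_bp, length.out = flank_bins + 1))
  chrs <- as.character(seqnames(g))
  for (i in seq_along(g)) {
    s <- start(g)[i]; e <- end(g)[i]; W <- e - s + 1
    body_edges <- s + round(seq(0, W, length.out = body_bins + 1)) - 1
    left_s <- s - flank_bp + flank_edges[-length(flank_edges)]
    left_e <- s - flank_bp + flank_edges[-1] - 1
    body_s <- body_edges[-length(body_edges)] + 1
    body_e <- body_edges[-1]
    right_s <- e + flank_edges[-length(flank_edges)] + 1
    right_e <- e + flank_edges[-1]
    v <- bin_means_rle(cov[[chrs[i]]],
                       c(left_s, body_s, right_s),
                       c(left_e, body_e, right_e))
    if (as.character(strand(g))[i] == "-") v <- rev(v)
    rows[i, ] <- v
  }
  labels <- c(paste0("up_", seq_len(flank_bins)),
              paste0("body_", seq_len(body_bins)),
              paste0("down_", seq_len(flank_bins)))
  colnames(rows) <- labels
  rownames(rows) <- mcols(g)$gene_id
  out <- list(bin_labels = labels,
              mean_signal = if (nrow(rows)) colMeans(rows)
                            else stats::setNames(numeric(nb), labels),
              n_genes = nrow(rows),
              n_skipped = n_skipped,
              matrix = rows)
  class(out) <- "metagene_profile"
  out
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile:", length(x$bin_labels), "bins over", x$n_genes,
      "genes (", x$n_skipped, "skipped)\n")
  invisible(x)
}

#' TSS-centred per-gene signal matrix
#'
#' Fixed-width bins across `[TSS - flank_bp, TSS + flank_bp)`,
#' strand-aware (upstream is always on the left). Windows running off a
#' chromosome edge contribute zero signal for the missing bases and the
#' affected rows are flagged.
#'
#' @param track Signal `GRanges` with `score`.
#' @param gm A `gene_models` object.
#' @param gene_ids Genes (rows), in the requested order; must all exist in
#'   the annotation.
#' @param flank_bp Half-window around the TSS, bp (default 3 kb).
#' @param bin_bp Bin width, bp; must divide `2 * flank_bp`.
#' @return A `heatmap_matrix`: numeric matrix (genes x bins, mean per-base
#'   signal) with attribute `clipped` (logical per row).
#' @export
tss_matrix <- function(track, gm, gene_ids, flank_bp = 3000,
                       bin_bp = 100) {
  stopifnot(inherits(gm, "gene_models"))
  if ((2 * flank_bp) %% bin_bp != 0)
    stop("bin_bp must divide 2 * flank_bp")
  missing <- setdiff(gene_ids, mcols(gm$genes)$gene_id)
  if (length(missing))
    stop("gene id(s) absent from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  g <- gm$genes[match(gene_ids, mcols(gm$genes)$gene_id)]
  cov <- track_coverage(track, gm$seqlengths)
  nb <- as.integer(2 * flank_bp / bin_bp)
  mat <- matrix(0, nrow = length(g), ncol = nb,
                dimnames = list(gene_ids,
                                paste0("bin_", seq_len(nb))))
  clipped <- logical(length(g))
  chrs <- as.character(seqnames(g))
  strands <- as.character(strand(g))
  tss <- ifelse(strands == "+", start(g), end(g))
  for (i in seq_along(g)) {
    ws <- tss[i] - flank_bp
    starts <- ws + bin_bp * (seq_len(nb) - 1L)
    ends <- starts + bin_bp - 1L
    v <- bin_means_rle(cov[[chrs[i]]], starts, ends)
    if (strands[i] == "-") v <- rev(v)
    mat[i, ] <- v
    clipped[i] <- ws < 1 || (tss[i] + flank_bp - 1) >
      gm$seqlengths[[chrs[i]]]
  }
  attr(mat, "clipped") <- clipped
  class(mat) <- c("heatmap_matrix", class(mat))
  mat
}

#' Export a meta-gene profile or TSS matrix as TSV
#'
#' @param x A `metagene_profile` or `heatmap_matrix`.
#' @param path Output file.
#' @export
write_profile <- function(x, path) {
  if (inherits(x, "metagene_profile")) {
    df <- data.frame(bin = x$bin_labels, mean_signal = x$mean_signal)
  } else {
    df <- data.frame(gene_id = rownames(x), unclass(x)[, , drop = FALSE],
                     check.names = FALSE)
  }
  write_stage_tsv(df, path)
}
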