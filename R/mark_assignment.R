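#' Strand-aware gene windows (gene body plus upstream extension)
#'
#' The unit of peak-to-gene assignment: the gene body extended by
#' `upstream_bp` bases upstream of the TSS on the gene's strand, clipped to
#' the chromosome.
#'
#' @param gm A `gene_models` object.
#' @param upstream_bp Upstream extension, bp (>= 0).
#' @return `GRanges` with a `gene_id` column, one window per gene.
#' @export
gene_windows <- function(gm, upstream_bp = 2000) {
  stopifnot(inherits(gm, "gene_models"), upstream_bp >= 0)
  g <- gm$genes
  strands <- as.character(strand(g))
  chr <- as.character(seqnames(g))
  sl <- gm$seqlengths
  s <- ifelse(strands == "+", pmax(start(g) - upstream_bp, 1), start(g))
  e <- ifelse(strands == "+", end(g), pmin(end(g) + upstream_bp, sl[chr]))
  win <- GenomicRanges::GRanges(chr, IRanges::IRanges(s, e),
                                strand = strands)
  mcols(win)$gene_id <- mcols(g)$gene_id
  win
}

# per-window mean signal from a run-length track (zeros where no run)
window_mean_signal <- function(track, windows, seqlengths) {
  GenomeInfoDb::seqlevels(track) <- names(seqlengths)
  GenomeInfoDb::seqlengths(track) <- seqlengths
  cov <- GenomicRanges::coverage(track, weight = "score")
  out <- numeric(length(windows))
  chr <- as.character(seqnames(windows))
  for (c in unique(chr)) {
    i <- which(chr == c)
    v <- IRanges::Views(cov[[c]], start(windows)[i], end(windows)[i])
    out[i] <- IRanges::viewSums(v) / width(windows)[i]
  }
  out
}

#' Assign histone marks and DHSs to genes
#'
#' A gene carries a mark in a tissue iff its window (gene body plus
#' `upstream_bp` upstream of the TSS) overlaps at least one peak of that
#' mark/tissue by >= 1 base — the literal reading of an "overlapping"
#' rule. When signal tracks are supplied, the mean per-base signal over the
#' window is recorded alongside the flag.
#'
#' @param peaks `GRanges` of peaks with `mark` and `tissue` columns
#'   (multiple marks/tissues may be mixed; one table row is produced per
#'   gene and observed (mark, tissue) slot).
#' @param gm A `gene_models` object.
#' @param upstream_bp Upstream window extension, bp.
#' @param tracks Optional named list of signal `GRanges`, names
#'   `"<mark>:<tissue>"`; missing slots get `NA` mean signal.
#' @return A `mark_table` data.frame: `gene_id`, `mark`, `tissue`,
#'   `present` (logical), `mean_signal`.
#' @export
assign_marks <- function(peaks, gm, upstream_bp = 2000, tracks = NULL) {
  stopifnot(inherits(gm, "gene_models"))
  win <- gene_windows(gm, upstream_bp)
  slots <- unique(data.frame(mark = mcols(peaks)$mark,
                             tissue = mcols(peaks)$tissue,
                             stringsAsFactors = FALSE))
  slots <- slots[order(slots$mark, slots$tissue), , drop = FALSE]
  res <- lapply(seq_len(nrow(slots)), function(i) {
    mk <- slots$mark[i]; ts <- slots$tissue[i]
    p <- peaks[mcols(peaks)$mark == mk & mcols(peaks)$tissue == ts]
    present <- IRanges::overlapsAny(win, p, ignore.strand = TRUE)
    key <- paste(mk, ts, sep = ":")
    ms <- if (!is.null(tracks) && !is.null(tracks[[key]]))
      window_mean_signal(tracks[[key]], win, gm$seqlengths)
    else rep(NA_real_, length(win))
    data.frame(gene_id = mcols(win)$gene_id, mark = mk, tissue = ts,
               present = present, mean_signal = ms,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("mark_table", "data.frame")
  out
}

# slice one (mark, tissue) slot out of a mark table, gene-indexed
mark_slot <- function(table, mark, tissue) {
  x <- table[table$mark == mark & table$tissue == tissue, , drop = FALSE]
  if (nrow(x) == 0L)
    stop("mark table has no rows for ", mark, " / ", tissue)
  x[order(x$gene_id), , drop = FALSE]
}

#' Call tissue-differential mark deposition
#'
#' A gene is A-preferential for a mark iff it carries the mark in tissue A
#' but not B, or carries it in both and the windowed mean-signal ratio
#' (A + pseudocount)/(B + pseudocount) is `>= min_fold`; symmetric for B.
#' The rule makes the tissue-differential gene sets fully auditable: fold
#' ratios are returned for every gene carrying the mark anywhere. The two
#' tracks must already be depth-normalized — totals differing by more than
#' 1% are an error (see [normalize_signal_pair()]).
#'
#' @param table A `mark_table` from [assign_marks()] covering both tissues
#'   of the contrast, with `mean_signal` filled for this mark.
#' @param mark Mark to test.
#' @param tissue_a,tissue_b The two tissues (A = first, e.g. callus).
#' @param signal_a,signal_b The normalized signal tracks backing the means
#'   (used only for the normalization check; pass `NULL` to skip, e.g.
#'   when means were computed from already-normalized tracks).
#' @param min_fold Minimum fold ratio for signal-based calls.
#' @param pseudocount Added to both means before the ratio.
#' @return A `differential_marks` list: `mark`, `a_genes`, `b_genes`
#'   (character vectors, disjoint), `fold` (named vector, A:B ratio for
#'   every gene carrying the mark in either tissue), `tissues`.
#' @export
differential_deposition <- function(table, mark,
                                    tissue_a = "callus",
                                    tissue_b = "seedling",
                                    signal_a = NULL, signal_b = NULL,
                                    min_fold = 2, pseudocount = 1) {
  a <- mark_slot(table, mark, tissue_a)
  b <- mark_slot(table, mark, tissue_b)
  if (!identical(a$gene_id, b$gene_id))
    stop("the two tissues cover different gene universes")
  if (!is.null(signal_a) && !is.null(signal_b)) {
    ta <- signal_total(signal_a); tb <- signal_total(signal_b)
    if (abs(ta - tb) > 0.01 * max(ta, tb))
      stop("signal tracks are not depth-normalized (totals differ by >1%);",
           " run normalize_signal_pair() first")
  }
  carry_any <- a$present | b$present
  ratio <- (a$mean_signal + pseudocount) / (b$mean_signal + pseudocount)
  a_only <- a$present & !b$present
  b_only <- b$present & !a$present
  both <- a$present & b$present
  a_genes <- a$gene_id[a_only | (both & !is.na(ratio) & ratio >= min_fold)]
  b_genes <- a$gene_id[b_only |
                         (both & !is.na(ratio) & ratio <= 1 / min_fold)]
  out <- list(mark = mark,
              a_genes = a_genes,
              b_genes = b_genes,
              fold = stats::setNames(ratio[carry_any],
                                     a$gene_id[carry_any]),
              tissues = c(tissue_a, tissue_b))
  class(out) <- "differential_marks"
  out
}

#' @export
print.differential_marks <- function(x, ...) {
  cat("differential_marks [", x$mark, "]: ",
      length(x$a_genes), " ", x$tissues[1], "-preferential, ",
      length(x$b_genes), " ", x$tissues[2], "-preferential\n", sep = "")
  invisible(x)
}
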