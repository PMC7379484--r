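#' Build the six-class genomic region index
#'
#' Partitions every base of the genome into exactly one of six classes —
#' promoter, 5' UTR, 3' UTR, coding exon, intron, intergenic — the
#' classification used for peak distribution summaries. The promoter is the
#' `promoter_bp` bases immediately upstream of the TSS on the gene's
#' strand, clipped at chromosome edges; coding exon is exon minus UTRs.
#' When labels collide across genes, precedence is
#' 5'UTR > 3'UTR > coding exon > promoter > intron > intergenic, applied
#' base-wise, so genic fine structure is never masked by a neighbour's
#' promoter.
#'
#' @param gm A `gene_models` object.
#' @param promoter_bp Promoter length upstream of the TSS, bp.
#' @return A `region_index`: named `list` of unstranded `GRanges` (one per
#'   class, disjoint, jointly covering the genome) with attribute
#'   `seqlengths`.
#' @export
build_region_index <- function(gm, promoter_bp = 2000) {
  stopifnot(inherits(gm, "gene_models"), promoter_bp > 0)
  g <- gm$genes
  strands <- as.character(strand(g))
  if (any(!strands %in% c("+", "-")))
    stop("unknown strand in gene models")
  sl <- gm$seqlengths
  chr <- as.character(seqnames(g))
  # promoter windows, strand-aware, clipped to chromosome
  prom_start <- ifelse(strands == "+", start(g) - promoter_bp, end(g) + 1)
  prom_end <- ifelse(strands == "+", start(g) - 1, end(g) + promoter_bp)
  prom_start <- pmax(prom_start, 1L)
  prom_end <- pmin(prom_end, sl[chr])
  ok <- prom_start <= prom_end
  promoters <- GenomicRanges::GRanges(chr[ok],
                                      IRanges::IRanges(prom_start[ok],
                                                       prom_end[ok]))
  unstrand <- function(x) {
    x <- granges(x)
    strand(x) <- "*"
    x
  }
  exons <- unstrand(gm$exons)
  utr5 <- unstrand(gm$utr5)
  utr3 <- unstrand(gm$utr3)
  bodies <- unstrand(g)
  utr_all <- GenomicRanges::union(utr5, utr3, ignore.strand = TRUE)
  raw <- list(
    five_prime_UTR = GenomicRanges::reduce(utr5, ignore.strand = TRUE),
    three_prime_UTR = GenomicRanges::reduce(utr3, ignore.strand = TRUE),
    coding_exon = GenomicRanges::setdiff(exons, utr_all,
                                         ignore.strand = TRUE),
    promoter = GenomicRanges::reduce(promoters, ignore.strand = TRUE),
    intron = GenomicRanges::setdiff(bodies, exons, ignore.strand = TRUE))
  genome <- GenomicRanges::GRanges(names(sl),
                                   IRanges::IRanges(1L, unname(sl)))
  taken <- GenomicRanges::GRanges()
  classes <- list()
  for (cl in names(raw)) {
    part <- GenomicRanges::setdiff(raw[[cl]], taken, ignore.strand = TRUE)
    classes[[cl]] <- GenomicRanges::sort(part, ignore.strand = TRUE)
    taken <- GenomicRanges::union(taken, part, ignore.strand = TRUE)
  }
  classes$intergenic <- GenomicRanges::sort(
    GenomicRanges::setdiff(genome, taken, ignore.strand = TRUE),
    ignore.strand = TRUE)
  classes <- classes[.region_classes]
  attr(classes, "seqlengths") <- sl
  class(classes) <- "region_index"
  classes
}

#' @export
print.region_index <- function(x, ...) {
  w <- vapply(x, function(g) sum(as.numeric(width(g))), 0)
  cat("region_index over", sum(as.numeric(attr(x, "seqlengths"))),
      "bp:\n")
  print(round(w / sum(w), 4))
  invisible(x)
}

#' Export a region index as BED
#'
#' One BED record per constant-class run with the class in the name column.
#'
#' @param index A `region_index`.
#' @param path Output BED file.
#' @export
write_region_index <- function(index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cl in names(index)) {
    g <- index[[cl]]
    if (length(g))
      writeLines(sprintf("%s\t%d\t%d\t%s",
                         as.character(seqnames(g)),
                         start(g) - 1L, end(g), cl), con)
  }
  invisible(path)
}

#' Genomic distribution of peaks over the six region classes
#'
#' Base-weighted fractions: every peak base contributes one count to the
#' class labelling that base, so the fractions sum to 1. A secondary
#' peak-count-weighted view assigns each whole peak to its majority class
#' (ties broken by class precedence).
#'
#' @param peaks `GRanges` of peaks.
#' @param index A `region_index` from [build_region_index()].
#' @return A list with `base_fraction` and `peak_fraction` (named numeric
#'   over the six classes), plus `total_bases` and `n_peaks`.
#' @export
peak_region_distribution <- function(peaks, index) {
  stopifnot(inherits(index, "region_index"))
  known <- names(attr(index, "seqlengths"))
  bad <- setdiff(unique(as.character(seqnames(peaks))), known)
  if (length(bad))
    stop("peak(s) on chromosome(s) absent from the region index: ",
         paste(bad, collapse = ", "))
  peaks <- granges(peaks)
  strand(peaks) <- "*"
  base_tally <- stats::setNames(numeric(length(index)), names(index))
  per_peak <- matrix(0, nrow = length(peaks), ncol = length(index),
                     dimnames = list(NULL, names(index)))
  for (cl in names(index)) {
    hits <- GenomicRanges::findOverlaps(peaks, index[[cl]],
                                        ignore.strand = TRUE)
    if (length(hits)) {
      ov <- width(IRanges::pintersect(peaks[queryHits(hits)],
                                      index[[cl]][subjectHits(hits)]))
      base_tally[cl] <- sum(as.numeric(ov))
      agg <- tapply(ov, queryHits(hits), sum)
      per_peak[as.integer(names(agg)), cl] <- agg
    }
  }
  total <- sum(as.numeric(width(peaks)))
  base_fraction <- if (total > 0) base_tally / total else base_tally
  if (length(peaks)) {
    maj <- apply(per_peak, 1L, function(r) names(index)[which.max(r)])
    peak_fraction <- stats::setNames(
      as.numeric(table(factor(maj, levels = names(index)))) /
        length(peaks),
      names(index))
  } else {
    peak_fraction <- stats::setNames(numeric(length(index)), names(index))
  }
  list(base_fraction = base_fraction,
       peak_fraction = peak_fraction,
       total_bases = total,
       n_peaks = length(peaks))
}
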