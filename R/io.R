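#' Read ChIP/DNase peaks from a BED3+ or narrowPeak file
#'
#' BED coordinates (0-based, half-open) are converted to the 1-based closed
#' convention of [GenomicRanges::GRanges] on read; [write_peaks()] restores
#' BED coordinates, so read/write round-trips are exact. Input order is
#' preserved. Comment (`#`), `track` and `browser` lines are skipped.
#'
#' @param path BED3+/narrowPeak file.
#' @param mark Mark label attached to every peak (e.g. `"H3K27me3"`).
#' @param tissue Tissue label attached to every peak (e.g. `"callus"`).
#' @return A `GRanges` with metadata columns `mark`, `tissue` and, when a
#'   numeric 5th column is present, `score`.
#' @export
read_peaks <- function(path, mark, tissue) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$mark <- character(0)
    mcols(gr)$tissue <- character(0)
    mcols(gr)$score <- numeric(0)
    return(gr)
  }
  fields <- strsplit(lines[idx], "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop("malformed BED record (fewer than 3 columns) at line ",
         idx[which(ncols < 3L)[1L]], " of ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0) |
    start0 != floor(start0) | end0 != floor(end0)
  if (any(bad))
    stop("malformed BED coordinate (non-integer) at line ",
         idx[which(bad)[1L]], " of ", path)
  bad <- start0 >= end0 | start0 < 0
  if (any(bad))
    stop("invalid BED interval (start >= end or negative) at line ",
         idx[which(bad)[1L]], " of ", path)
  score <- rep(NA_real_, length(idx))
  has5 <- ncols >= 5L
  if (any(has5)) {
    s <- suppressWarnings(as.numeric(
      vapply(fields[has5], `[[`, "", 5L)))
    score[has5] <- s
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0))
  mcols(gr)$mark <- mark
  mcols(gr)$tissue <- tissue
  mcols(gr)$score <- score
  gr
}

#' @rdname read_peaks
#' @param peaks A `GRanges` of peaks.
#' @export
write_peaks <- function(peaks, path) {
  score <- if (!is.null(mcols(peaks)$score)) mcols(peaks)$score
           else rep(NA_real_, length(peaks))
  score_txt <- ifelse(is.na(score), "0", num_txt(score))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s",
                   as.character(seqnames(peaks)),
                   start(peaks) - 1L, end(peaks),
                   ".", score_txt)
  writeLines(lines, path)
  invisible(path)
}

# full-precision, locale-independent number formatting for text emitters
num_txt <- function(x) {
  out <- sprintf("%.17g", x)
  simple <- sprintf("%g", x)
  roundtrip <- as.numeric(simple) == x
  out[roundtrip] <- simple[roundtrip]
  out
}

#' Read a signal track (bedGraph or wiggle)
#'
#' Accepts bedGraph and both `fixedStep`/`variableStep` wiggle dialects
#' (detected from the file content); wiggle's 1-based coordinates are
#' converted on read. Runs are sorted and adjacent equal-value runs merged
#' per chromosome. Overlapping runs with conflicting values are an error —
#' the reader never averages silently.
#'
#' @param path bedGraph or wiggle file.
#' @return A sorted `GRanges` with a numeric `score` column (one row per
#'   constant-value run).
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  head_lines <- readLines(path, n = 50L)
  if (any(grepl("^(fixedStep|variableStep)", head_lines))) {
    gr <- rtracklayer::import(path, format = "wig")
    gr <- GenomicRanges::GRanges(seqnames(gr),
                                 IRanges::IRanges(start(gr), end(gr)),
                                 score = as.numeric(mcols(gr)$score))
  } else {
    # bedGraph parsed directly so values round-trip to full precision
    lines <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) &
      nzchar(trimws(lines))
    idx <- which(keep)
    if (length(idx) == 0L)
      return(GenomicRanges::GRanges(score = numeric(0)))
    fields <- strsplit(lines[idx], "[ \t]+")
    if (any(lengths(fields) < 4L))
      stop("malformed bedGraph record at line ",
           idx[which(lengths(fields) < 4L)[1L]], " of ", path)
    start0 <- as.numeric(vapply(fields, `[[`, "", 2L))
    end0 <- as.numeric(vapply(fields, `[[`, "", 3L))
    score <- as.numeric(vapply(fields, `[[`, "", 4L))
    bad <- is.na(start0) | is.na(end0) | is.na(score) | start0 >= end0
    if (any(bad))
      stop("malformed bedGraph record at line ", idx[which(bad)[1L]],
           " of ", path)
    gr <- GenomicRanges::GRanges(vapply(fields, `[[`, "", 1L),
                                 IRanges::IRanges(start0 + 1, end0),
                                 score = score)
  }
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(hits)) {
    conflict <- mcols(gr)$score[queryHits(hits)] !=
      mcols(gr)$score[subjectHits(hits)]
    if (any(conflict))
      stop("overlapping signal runs with conflicting values in ", path,
           " (e.g. runs ", queryHits(hits)[conflict][1L], " and ",
           subjectHits(hits)[conflict][1L], " after sorting)")
  }
  merge_equal_runs(gr)
}

# merge overlapping/abutting runs that share a value (grouping stays on
# the numeric values: no character round-trip, no precision loss)
merge_equal_runs <- function(gr) {
  if (length(gr) == 0L) return(gr)
  vals <- mcols(gr)$score
  uniq <- unique(vals)
  merged <- lapply(uniq, function(v) {
    red <- GenomicRanges::reduce(gr[vals == v], ignore.strand = TRUE)
    mcols(red)$score <- rep(v, length(red))
    red
  })
  out <- do.call(c, merged)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' @rdname read_signal
#' @param track A `GRanges` with a `score` column.
#' @export
write_signal <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%s",
                   as.character(seqnames(track)),
                   start(track) - 1L, end(track),
                   num_txt(mcols(track)$score))
  writeLines(lines, path)
  invisible(path)
}

# total mass of a track: sum over bases of the run value
signal_total <- function(track) {
  sum(as.numeric(width(track)) * mcols(track)$score)
}

#' Scale two signal tracks to a common total
#'
#' Tracks from libraries of different depth are made comparable by scaling
#' each so its genome-wide sum (base pairs times value) matches the smaller
#' of the two totals.
#'
#' @param a,b `GRanges` signal tracks with `score`.
#' @return A list with elements `a` and `b`, rescaled.
#' @export
normalize_signal_pair <- function(a, b) {
  ta <- signal_total(a); tb <- signal_total(b)
  if (ta <= 0 || tb <= 0) stop("cannot normalize a track with zero total")
  target <- min(ta, tb)
  mcols(a)$score <- mcols(a)$score * target / ta
  mcols(b)$score <- mcols(b)$score * target / tb
  list(a = a, b = b)
}

#' Read gene models from GFF3
#'
#' Expects `gene`, `mRNA`, `exon`, `five_prime_UTR` and `three_prime_UTR`
#' features linked by `ID`/`Parent`. When a gene has several mRNAs the
#' longest transcript is kept (ties broken by ID), so downstream stages see
#' one representative model per gene. GFF3's 1-based closed coordinates map
#' directly onto `GRanges`.
#'
#' @param path GFF3 file with `##sequence-region` headers (or supply
#'   `seqlengths`).
#' @param seqlengths Optional named integer vector of chromosome lengths,
#'   overriding the header.
#' @return A `gene_models` object: list with `genes` (GRanges, `gene_id`
#'   mcol), `exons`, `utr5`, `utr3` (GRanges with `gene_id`), and
#'   `seqlengths`.
#' @export
read_gene_models <- function(path, seqlengths = NULL) {
  gff <- rtracklayer::import(path, format = "gff3")
  if (is.null(seqlengths)) {
    pragma <- grep("^##sequence-region", readLines(path), value = TRUE)
    if (length(pragma) == 0L)
      stop("GFF3 lacks ##sequence-region lengths; pass `seqlengths`")
    parts <- strsplit(trimws(pragma), "[ \t]+")
    seqlengths <- stats::setNames(
      as.integer(vapply(parts, `[[`, "", 4L)),
      vapply(parts, `[[`, "", 2L))
  }
  type <- as.character(mcols(gff)$type)
  genes <- gff[type == "gene"]
  gene_ids <- as.character(mcols(genes)$ID)
  strands <- as.character(strand(genes))
  if (any(!strands %in% c("+", "-")))
    stop("gene(s) with unknown strand: ",
         paste(gene_ids[!strands %in% c("+", "-")], collapse = ", "))
  first_parent <- function(x) vapply(as.list(mcols(x)$Parent),
                                     function(p) p[1L], "")
  mrna <- gff[type == "mRNA"]
  tx2gene <- stats::setNames(first_parent(mrna),
                             as.character(mcols(mrna)$ID))
  # representative transcript per gene: longest, ties by ID
  if (length(mrna)) {
    ord <- order(factor(tx2gene, levels = gene_ids),
                 -width(mrna), as.character(mcols(mrna)$ID))
    mrna_o <- mrna[ord]
    keep_tx <- as.character(mcols(mrna_o)$ID)[
      !duplicated(tx2gene[as.character(mcols(mrna_o)$ID)])]
  } else keep_tx <- character(0)
  sub_feat <- function(t) {
    f <- gff[type == t]
    if (length(f) == 0L) {
      out <- GenomicRanges::GRanges()
      mcols(out)$gene_id <- character(0)
      return(out)
    }
    par <- first_parent(f)
    f <- f[par %in% keep_tx]
    gid <- unname(tx2gene[first_parent(f)])
    out <- granges(f)
    mcols(out)$gene_id <- gid
    out
  }
  gm <- list(genes = {
    g <- granges(genes); mcols(g)$gene_id <- gene_ids; g
  },
  exons = sub_feat("exon"),
  utr5 = sub_feat("five_prime_UTR"),
  utr3 = sub_feat("three_prime_UTR"),
  seqlengths = seqlengths)
  class(gm) <- "gene_models"
  validate_gene_models(gm)
  gm
}

validate_gene_models <- function(gm) {
  g <- gm$genes
  if (any(end(g) > gm$seqlengths[as.character(seqnames(g))], na.rm = TRUE))
    stop("gene extends beyond chromosome end")
  if (length(gm$exons)) {
    ov <- match(mcols(gm$exons)$gene_id, mcols(g)$gene_id)
    if (any(is.na(ov))) stop("exon with unknown gene id")
    if (any(start(gm$exons) < start(g)[ov] | end(gm$exons) > end(g)[ov]))
      stop("exon outside its gene body")
  }
  invisible(gm)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "genes on",
      length(x$seqlengths), "chromosome(s)\n")
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Deterministic emitter (fixed column formatting, genes in input order)
#' used by the synthetic generator; output is readable by
#' [read_gene_models()] and any GFF3-aware tool.
#'
#' @param gm A `gene_models` object.
#' @param path Output file.
#' @export
write_gene_models <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (chr in names(gm$seqlengths))
    writeLines(sprintf("##sequence-region %s 1 %d", chr,
                       gm$seqlengths[[chr]]), con)
  gff_line <- function(chr, type, s, e, strand, attrs)
    sprintf("%s\tmarkstates\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chr, type, s, e, strand, attrs)
  g <- gm$genes
  for (i in seq_along(g)) {
    gid <- mcols(g)$gene_id[i]
    tid <- paste0(gid, ".t1")
    chr <- as.character(seqnames(g))[i]
    st <- as.character(strand(g))[i]
    writeLines(gff_line(chr, "gene", start(g)[i], end(g)[i], st,
                        paste0("ID=", gid)), con)
    writeLines(gff_line(chr, "mRNA", start(g)[i], end(g)[i], st,
                        paste0("ID=", tid, ";Parent=", gid)), con)
    for (slot in c("exons", "utr5", "utr3")) {
      f <- gm[[slot]][mcols(gm[[slot]])$gene_id == gid]
      type <- c(exons = "exon", utr5 = "five_prime_UTR",
                utr3 = "three_prime_UTR")[[slot]]
      for (j in seq_along(f))
        writeLines(gff_line(chr, type, start(f)[j], end(f)[j], st,
                            paste0("Parent=", tid)), con)
    }
  }
  invisible(path)
}

# deterministic TSV writers shared by all stages
write_stage_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], num_txt)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_stage_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
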