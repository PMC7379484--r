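#' Two-condition differential expression by fold change
#'
#' The simple fold-change filter used for two-condition FPKM tables: a
#' gene is A-higher iff `(expr_a + pseudocount) / (expr_b + pseudocount)`
#' strictly exceeds `fold`; symmetric for B. The pseudocount (default
#' 1 FPKM) makes the bare ratio rule well defined at zero expression.
#'
#' @param expr_a,expr_b Named nonnegative numeric vectors over the same
#'   genes (names = gene ids).
#' @param fold Fold-change cutoff (> 1), strict inequality.
#' @param pseudocount Added to both values before the ratio.
#' @return List: `a_higher`, `b_higher` (disjoint character vectors),
#'   `ratio` (named vector, A:B).
#' @export
call_deg <- function(expr_a, expr_b, fold = 2, pseudocount = 1) {
  stopifnot(fold > 1, pseudocount >= 0)
  if (is.null(names(expr_a)) || !identical(names(expr_a), names(expr_b)))
    stop("expr_a and expr_b must be named over the same genes")
  if (any(expr_a < 0) || any(expr_b < 0))
    stop("negative expression values")
  ratio <- (expr_a + pseudocount) / (expr_b + pseudocount)
  list(a_higher = names(expr_a)[ratio > fold],
       b_higher = names(expr_a)[ratio < 1 / fold],
       ratio = ratio)
}

#' Tissue-preferential expression from a multi-tissue panel
#'
#' Emulates the array-panel screen for callus-preferential genes: samples
#' are first normalized to the same level (each sample scaled so its mean
#' matches the grand mean; `"quantile"` distribution-matching via limma is
#' available but assumes few changed genes), then per gene
#' `Z = (mean(target samples) - mean(other samples)) / sd(other samples)`
#' (sample sd, n-1 denominator) and `p = P(N(0,1) > Z)`. A gene is called
#' preferential iff `p < p_cutoff` and `Z > 0`. Genes whose non-target
#' samples are constant (sd 0) are flagged preferential iff the target
#' mean exceeds that constant, with p reported as the smallest positive
#' double and a degenerate note, so extreme cases are not silently lost.
#'
#' @param matrix Numeric matrix, genes x samples, nonnegative.
#' @param sample_tissue Character vector (length = ncol) of tissue labels.
#' @param target Target tissue label (>= 1 sample; >= 3 non-target
#'   samples required).
#' @param p_cutoff Upper-tail p cutoff (default 0.05).
#' @param normalize `"scale"` (default; sample means equalized),
#'   `"quantile"`, or `"none"` (for testing invariances).
#' @param robust If `TRUE`, use median/MAD of the non-target samples
#'   instead of mean/sd.
#' @return data.frame: `gene_id`, `z`, `p`, `preferential`, `degenerate`.
#' @export
preferential_expression <- function(matrix, sample_tissue, target,
                                    p_cutoff = 0.05,
                                    normalize = c("scale", "quantile",
                                                  "none"),
                                    robust = FALSE) {
  normalize <- match.arg(normalize)
  if (length(sample_tissue) != ncol(matrix))
    stop("sample_tissue must label every column")
  if (any(matrix < 0)) stop("negative expression values")
  t_idx <- which(sample_tissue == target)
  o_idx <- which(sample_tissue != target)
  if (length(t_idx) < 1L) stop("target tissue has no samples")
  if (length(o_idx) < 3L)
    stop("need >= 3 non-target samples for a defined sd")
  m <- matrix
  if (normalize == "quantile") {
    m <- limma::normalizeQuantiles(matrix)
  } else if (normalize == "scale") {
    cm <- colMeans(matrix)
    if (any(cm == 0)) stop("cannot scale-normalize an all-zero sample")
    m <- sweep(matrix, 2L, mean(cm) / cm, "*")
  }
  mt <- rowMeans(m[, t_idx, drop = FALSE])
  if (robust) {
    mo <- apply(m[, o_idx, drop = FALSE], 1L, stats::median)
    so <- apply(m[, o_idx, drop = FALSE], 1L, stats::mad)
  } else {
    mo <- rowMeans(m[, o_idx, drop = FALSE])
    so <- apply(m[, o_idx, drop = FALSE], 1L, stats::sd)
  }
  degenerate <- so == 0
  z <- (mt - mo) / so
  p <- stats::pnorm(z, lower.tail = FALSE)
  pref <- !is.na(z) & z > 0 & p < p_cutoff
  if (any(degenerate)) {
    up <- mt[degenerate] > mo[degenerate]
    z[degenerate] <- ifelse(up, Inf, ifelse(mt[degenerate] ==
                                              mo[degenerate], 0, -Inf))
    p[degenerate] <- ifelse(up, .Machine$double.xmin, 1)
    pref[degenerate] <- up
  }
  data.frame(gene_id = rownames(matrix), z = z, p = p,
             preferential = pref, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' k-means clustering of genes on multi-mark signal matrices
#'
#' Concatenates one TSS-centred matrix per mark/tissue row-wise (all must
#' share the gene set and bin grid), standardizes each matrix to zero
#' mean / unit variance per bin (constant bins map to zero), and runs
#' k-means with `nstart` restarts under a fixed seed, so the assignment is
#' deterministic given the seed.
#'
#' @param matrices Named list of matrices (genes x bins), identical
#'   rownames in identical order.
#' @param k Number of clusters (1 <= k <= number of genes).
#' @param seed Integer seed.
#' @param nstart k-means restarts (best inertia kept).
#' @return A `cluster_assignment` list: `cluster` (named integer vector in
#'   1..k), `centers` (k x total-bins matrix), `k`, `seed`.
#' @export
cluster_by_marks <- function(matrices, k, seed, nstart = 10) {
  stopifnot(length(matrices) >= 1L)
  ids <- rownames(matrices[[1L]])
  for (m in matrices)
    if (!identical(rownames(m), ids))
      stop("all matrices must share the same genes in the same order")
  if (k < 1) stop("k must be >= 1")
  if (k > length(ids)) stop("k exceeds the number of genes")
  scaled <- lapply(matrices, function(m) {
    m <- unclass(m)
    mu <- colMeans(m)
    sdv <- apply(m, 2L, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    sweep(sweep(m, 2L, mu), 2L, sdv, "/")
  })
  features <- do.call(cbind, scaled)
  set.seed(as.integer(seed))
  if (k == 1L) {
    fit <- list(cluster = rep(1L, length(ids)),
                centers = matrix(colMeans(features), nrow = 1L))
  } else {
    fit <- stats::kmeans(features, centers = k, nstart = nstart,
                         iter.max = 100L)
  }
  out <- list(cluster = stats::setNames(as.integer(fit$cluster), ids),
              centers = fit$centers, k = as.integer(k),
              seed = as.integer(seed))
  class(out) <- "cluster_assignment"
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: k =", x$k, "over", length(x$cluster),
      "genes; sizes:", paste(table(x$cluster), collapse = ", "), "\n")
  invisible(x)
}

#' Cross-tabulate differential mark deposition against expression
#'
#' The Venn-style integration of a mark's tissue-preferential gene sets
#' with the differentially expressed gene sets: reports the four
#' intersection counts (mark-A x expr-A, mark-A x expr-B, mark-B x
#' expr-A, mark-B x expr-B) and the gene lists behind each cell. For a
#' repressive mark such as H3K27me3 the cross cells (mark high in one
#' tissue, expression high in the other) are the biologically loaded
#' ones.
#'
#' @param mark_result A `differential_marks` from
#'   [differential_deposition()].
#' @param deg_a,deg_b Character vectors: genes higher-expressed in tissue
#'   A / tissue B.
#' @return List: `counts` (2x2 integer matrix, rows = mark tissue, cols =
#'   expression tissue) and `genes` (list of the four cell gene vectors).
#' @export
integrate_marks_expression <- function(mark_result, deg_a, deg_b) {
  stopifnot(inherits(mark_result, "differential_marks"))
  cells <- list(
    markA_exprA = intersect(mark_result$a_genes, deg_a),
    markA_exprB = intersect(mark_result$a_genes, deg_b),
    markB_exprA = intersect(mark_result$b_genes, deg_a),
    markB_exprB = intersect(mark_result$b_genes, deg_b))
  counts <- matrix(lengths(cells), nrow = 2L, byrow = TRUE,
                   dimnames = list(mark = mark_result$tissues,
                                   expression = mark_result$tissues))
  list(counts = counts, genes = cells)
}

#' Read an expression matrix TSV with a sample-metadata sidecar
#'
#' @param path TSV: first column `gene_id`, remaining columns samples.
#' @param samples_path Optional TSV with columns `sample`, `tissue`
#'   (and optionally `stage`).
#' @return List: `matrix` (genes x samples), `samples` (data.frame or
#'   NULL).
#' @export
read_expression <- function(path, samples_path = NULL) {
  df <- read_stage_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  samples <- NULL
  if (!is.null(samples_path)) {
    samples <- read_stage_tsv(samples_path)
    if (!all(colnames(m) %in% samples$sample))
      stop("samples sidecar does not label every expression column")
    samples <- samples[match(colnames(m), samples$sample), , drop = FALSE]
  }
  list(matrix = m, samples = samples)
}
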