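#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` members of a size-`K` category in `n` draws without
#' replacement from a universe of size `N`. This is the over-representation
#' test used throughout the package (transition and TF-family enrichment).
#' Delegates to [stats::phyper()], which computes the tail stably in log
#' space and exactly for small N.
#'
#' @param N Universe size.
#' @param K Category size within the universe.
#' @param n Query (draw) size.
#' @param k Observed overlap.
#' @return The upper-tail probability, in (0, 1].
#' @export
hypergeometric_test <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || k > n || n > N || k > K || K > N)
    stop("hypergeometric bounds violated: need k <= n <= N and k <= K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment over a family catalog
#'
#' Tests each gene family for over-representation in a query set, drawing
#' from a configurable universe (by default the catalog itself, the right
#' universe when the query is a subset of a TF catalog). Families are
#' intersected with the universe before testing, and only families with at
#' least one member in the universe are tested. Benjamini-Hochberg
#' adjustment is applied over the tested families; results are sorted by p
#' then family label.
#'
#' @param query Character vector of gene ids; must be non-empty and a
#'   subset of the universe.
#' @param catalog data.frame with columns `gene_id` and `family` (the
#'   two-column catalog TSV read by [read_family_catalog()]).
#' @param universe Character vector of gene ids; default = all catalog
#'   genes.
#' @return data.frame: `family`, `N`, `K`, `n`, `k`, `p`, `q`,
#'   `fold_enrichment`.
#' @export
family_enrichment <- function(query, catalog, universe = NULL) {
  if (length(query) == 0L) stop("empty query gene set")
  if (is.null(universe)) universe <- unique(catalog$gene_id)
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query contains genes outside the universe")
  cat_u <- unique(catalog[catalog$gene_id %in% universe, , drop = FALSE])
  fams <- sort(unique(cat_u$family))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(fams, function(f) {
    members <- cat_u$gene_id[cat_u$family == f]
    K <- length(members)
    k <- length(intersect(query, members))
    data.frame(family = f, N = N, K = K, n = n, k = k,
               p = hypergeometric_test(N, K, n, k),
               fold_enrichment = (k / n) / (K / N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("family", "N", "K", "n", "k", "p", "q", "fold_enrichment")]
}

#' Read / write a TF family catalog (two-column TSV: gene, family)
#'
#' @param path TSV with header columns `gene_id` and `family`.
#' @return data.frame with `gene_id`, `family`.
#' @export
read_family_catalog <- function(path) {
  df <- read_stage_tsv(path)
  if (!all(c("gene_id", "family") %in% names(df)))
    stop("family catalog needs columns 'gene_id' and 'family'")
  if (anyDuplicated(df))
    df <- unique(df)
  df
}

#' @rdname read_family_catalog
#' @param catalog data.frame with `gene_id`, `family`.
#' @export
write_family_catalog <- function(catalog, path) {
  write_stage_tsv(catalog[, c("gene_id", "family")], path)
}
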