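#' Call the chromatin state of genes from two mark flags
#'
#' The state is a pure function of the H3K4me3 and H3K27me3 presence
#' flags: H3K4me3 only is "active", H3K27me3 only is "repressed", both is
#' "bivalent", and genes carrying neither mark get the fourth state
#' "none" (such genes are excluded from state transitions downstream).
#'
#' @param h3k4me3,h3k27me3 Logical vectors (recycled to common length).
#' @return Character vector of states in
#'   `c("active", "bivalent", "repressed", "none")`.
#' @export
call_state <- function(h3k4me3, h3k27me3) {
  n <- max(length(h3k4me3), length(h3k27me3))
  k4 <- rep_len(as.logical(h3k4me3), n)
  k27 <- rep_len(as.logical(h3k27me3), n)
  ifelse(k4 & k27, "bivalent",
         ifelse(k4, "active",
                ifelse(k27, "repressed", "none")))
}

#' Per-gene state calls for one tissue from a mark table
#'
#' @param table A `mark_table` from [assign_marks()].
#' @param tissue Tissue to call.
#' @return data.frame `gene_id`, `tissue`, `state`.
#' @export
call_states <- function(table, tissue) {
  k4 <- mark_slot(table, "H3K4me3", tissue)
  k27 <- mark_slot(table, "H3K27me3", tissue)
  if (!identical(k4$gene_id, k27$gene_id))
    stop("H3K4me3 and H3K27me3 cover different gene universes")
  data.frame(gene_id = k4$gene_id, tissue = tissue,
             state = call_state(k4$present, k27$present),
             stringsAsFactors = FALSE)
}

#' Classify the seven chromatin-state transitions between two tissues
#'
#' Over the 3 x 3 grid of {active, bivalent, repressed} state pairs,
#' exactly seven ordered pairs are named transitions: bivalent-active,
#' active-bivalent, repressed-bivalent, bivalent-repressed,
#' active-repressed, repressed-active, and bivalent-bivalent (e.g.
#' "active-bivalent" means active in the first tissue, bivalent in the
#' second). The two static cells (active-active, repressed-repressed) and
#' any pair involving "none" are "unclassified".
#'
#' @param states_a,states_b data.frames from [call_states()] for the first
#'   (e.g. callus) and second (e.g. seedling) tissue; must cover the same
#'   gene universe.
#' @return A `transition_table` data.frame: `gene_id`, `state_a`,
#'   `state_b`, `transition`.
#' @export
classify_transitions <- function(states_a, states_b) {
  a <- states_a[order(states_a$gene_id), , drop = FALSE]
  b <- states_b[order(states_b$gene_id), , drop = FALSE]
  if (!identical(a$gene_id, b$gene_id))
    stop("state calls cover different gene universes; gene(s) missing ",
         "from one tissue")
  lab <- paste(a$state, b$state, sep = "-")
  lab[!lab %in% .transition_labels] <- "unclassified"
  out <- data.frame(gene_id = a$gene_id,
                    state_a = a$state, state_b = b$state,
                    transition = lab, stringsAsFactors = FALSE)
  class(out) <- c("transition_table", "data.frame")
  out
}

#' The seven transition labels
#'
#' @return Character vector of the seven named state transitions.
#' @export
transition_labels <- function() .transition_labels

#' Counts per transition label
#'
#' @param transitions A `transition_table`.
#' @return Named integer vector over the seven labels plus "unclassified".
#' @export
transition_counts <- function(transitions) {
  tab <- table(factor(transitions$transition,
                      levels = c(.transition_labels, "unclassified")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Hypergeometric enrichment of a gene set across the seven transitions
#'
#' For each transition label, tests whether `gene_set` overlaps that
#' label's genes more than expected under random draws from the universe
#' (one-tailed, enrichment only), with significance stars at P < 0.01 (*)
#' and P < 0.001 (***). Raw p and Benjamini-Hochberg q over the seven
#' labels are reported side by side. The default universe is all genes
#' with a classified transition.
#'
#' @param gene_set Character vector of gene ids (subset of the universe).
#' @param table A `transition_table`.
#' @param universe Optional universe; default = genes with one of the
#'   seven labels.
#' @return data.frame: `transition`, `N`, `K`, `n`, `k`, `p`, `q`,
#'   `stars`.
#' @export
transition_enrichment <- function(gene_set, table, universe = NULL) {
  if (is.null(universe))
    universe <- table$gene_id[table$transition %in% .transition_labels]
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe))
    stop("gene_set contains genes outside the universe")
  t_u <- table[table$gene_id %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(gene_set)
  rows <- lapply(.transition_labels, function(lab) {
    members <- t_u$gene_id[t_u$transition == lab]
    K <- length(members)
    k <- length(intersect(gene_set, members))
    p <- hypergeometric_test(N, K, n, k)
    data.frame(transition = lab, N = N, K = K, n = n, k = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$stars <- ifelse(out$p < 0.001, "***",
                      ifelse(out$p < 0.01, "*", ""))
  out
}
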