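#' Score pipeline outputs against the planted truth
#'
#' One row per recoverable quantity, comparing a pipeline result computed
#' from the emitted files against the truth planted by
#' [simulate_study()]. Set-valued calls (mark flags, differential sets,
#' DEG sets, preferential calls) are scored by precision and recall;
#' multi-class calls (states, transitions) by exact-match accuracy;
#' clusterings by the adjusted Rand index against the planted archetypes
#' (label-permutation invariant).
#'
#' @param truth The `truth` data.frame of a `synthetic_study`.
#' @param mark_table Optional `mark_table` from [assign_marks()].
#' @param differential Optional named list of `differential_marks`
#'   (names = marks), tissue A = callus.
#' @param transitions Optional `transition_table` (callus then seedling).
#' @param deg Optional result of [call_deg()] (A = callus).
#' @param preferential Optional result of [preferential_expression()].
#' @param clusters Optional `cluster_assignment` over genes with a planted
#'   archetype.
#' @return data.frame: `quantity`, `precision`, `recall`, `accuracy`,
#'   `ari`, `n` (NA where a metric does not apply).
#' @export
truth_scorecard <- function(truth, mark_table = NULL, differential = NULL,
                            transitions = NULL, deg = NULL,
                            preferential = NULL, clusters = NULL) {
  rows <- list()
  add <- function(quantity, precision = NA_real_, recall = NA_real_,
                  accuracy = NA_real_, ari = NA_real_, n = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, precision = precision, recall = recall,
      accuracy = accuracy, ari = ari, n = n, stringsAsFactors = FALSE)
  }
  pr <- function(pred, pos) {
    tp <- length(intersect(pred, pos))
    c(precision = if (length(pred)) tp / length(pred) else 1,
      recall = if (length(pos)) tp / length(pos) else 1)
  }
  flag_name <- c(H3K4me3 = "k4", H3K27me3 = "k27", DHS = "dhs")
  if (!is.null(mark_table)) {
    if (!setequal(unique(mark_table$gene_id), truth$gene_id))
      stop("mark table and truth cover different gene universes")
    pred_pos <- character(0); true_pos <- character(0)
    for (mk in unique(mark_table$mark))
      for (ts in unique(mark_table$tissue)) {
        slot <- mark_slot(mark_table, mk, ts)
        key <- function(g) paste(mk, ts, g)
        pred_pos <- c(pred_pos, key(slot$gene_id[slot$present]))
        tcol <- truth[[paste(flag_name[mk], ts, sep = "_")]]
        true_pos <- c(true_pos, key(truth$gene_id[tcol]))
      }
    v <- pr(pred_pos, true_pos)
    add("mark_flags", v["precision"], v["recall"],
        n = nrow(mark_table))
  }
  if (!is.null(differential)) {
    diff_col <- c(H3K27me3 = "k27_diff", H3K4me3 = "k4_diff",
                  DHS = "dhs_diff")
    pred_pos <- character(0); true_pos <- character(0)
    for (mk in names(differential)) {
      d <- differential[[mk]]
      pred_pos <- c(pred_pos, paste(mk, "callus", d$a_genes),
                    paste(mk, "seedling", d$b_genes))
      tv <- truth[[diff_col[mk]]]
      true_pos <- c(true_pos,
                    paste(mk, "callus", truth$gene_id[tv == "callus"]),
                    paste(mk, "seedling",
                          truth$gene_id[tv == "seedling"]))
    }
    v <- pr(pred_pos, true_pos)
    add("differential_marks", v["precision"], v["recall"],
        n = length(true_pos))
  }
  if (!is.null(transitions)) {
    m <- match(truth$gene_id, transitions$gene_id)
    if (anyNA(m))
      stop("transition table and truth cover different gene universes")
    add("states_callus",
        accuracy = mean(transitions$state_a[m] == truth$state_callus),
        n = nrow(truth))
    add("states_seedling",
        accuracy = mean(transitions$state_b[m] == truth$state_seedling),
        n = nrow(truth))
    add("transitions",
        accuracy = mean(transitions$transition[m] == truth$transition),
        n = nrow(truth))
  }
  if (!is.null(deg)) {
    pred <- c(paste("callus", deg$a_higher),
              paste("seedling", deg$b_higher))
    pos <- c(paste("callus", truth$gene_id[truth$deg == "callus"]),
             paste("seedling", truth$gene_id[truth$deg == "seedling"]))
    v <- pr(pred, pos)
    add("deg_sets", v["precision"], v["recall"], n = length(pos))
  }
  if (!is.null(preferential)) {
    pred <- preferential$gene_id[preferential$preferential]
    pos <- truth$gene_id[truth$preferential]
    v <- pr(pred, pos)
    add("preferential_calls", v["precision"], v["recall"],
        n = length(pos))
  }
  if (!is.null(clusters)) {
    ids <- names(clusters$cluster)
    m <- match(ids, truth$gene_id)
    if (anyNA(m)) stop("clustered genes absent from truth")
    keep <- !is.na(truth$archetype[m])
    add("cluster_archetypes",
        ari = mclust::adjustedRandIndex(clusters$cluster[keep],
                                        truth$archetype[m][keep]),
        n = sum(keep))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
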