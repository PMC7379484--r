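#' Pipeline configuration
#'
#' Collects the tunable constants of the pipeline in one validated object.
#' Defaults follow the analysis design: a 2-kb upstream window for
#' peak-to-gene assignment, an expression fold-change cutoff of 2, a
#' preferential-expression p-value cutoff of 0.05, and 5 k-means clusters.
#'
#' @param upstream_bp Upstream extension of the gene window used for mark
#'   assignment and the promoter class, in bp.
#' @param fold_change_cutoff Fold-change cutoff for differential expression
#'   (strict `>`).
#' @param min_fold Minimum windowed-signal fold ratio for a differential
#'   deposition call on genes marked in both tissues.
#' @param preferential_p_cutoff Upper-tail p-value cutoff for
#'   preferential-expression calls.
#' @param kmeans_k Number of k-means clusters for multi-mark clustering.
#' @param pseudocount Pseudocount added to windowed signal means and to
#'   expression values before forming ratios.
#' @param seed Integer seed threaded to every stochastic step (k-means
#'   restarts, the synthetic generator).
#' @param profile_flank_bp,profile_flank_bins,profile_body_bins Meta-gene
#'   profile geometry: fixed flank extent and bin counts.
#' @param tss_flank_bp,tss_bin_bp TSS-centred matrix geometry.
#' @param marks,tissues Allowed mark and tissue labels.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(upstream_bp = 2000,
                            fold_change_cutoff = 2,
                            min_fold = 2,
                            preferential_p_cutoff = 0.05,
                            kmeans_k = 5,
                            pseudocount = 1,
                            seed = 1L,
                            profile_flank_bp = 1000,
                            profile_flank_bins = 20,
                            profile_body_bins = 60,
                            tss_flank_bp = 3000,
                            tss_bin_bp = 100,
                            marks = c("H3K27me3", "H3K4me3", "DHS"),
                            tissues = c("callus", "seedling")) {
  cfg <- list(upstream_bp = upstream_bp,
              fold_change_cutoff = fold_change_cutoff,
              min_fold = min_fold,
              preferential_p_cutoff = preferential_p_cutoff,
              kmeans_k = kmeans_k,
              pseudocount = pseudocount,
              seed = as.integer(seed),
              profile_flank_bp = profile_flank_bp,
              profile_flank_bins = profile_flank_bins,
              profile_body_bins = profile_body_bins,
              tss_flank_bp = tss_flank_bp,
              tss_bin_bp = tss_bin_bp,
              marks = marks,
              tissues = tissues)
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  positive <- c("upstream_bp", "fold_change_cutoff", "min_fold",
                "preferential_p_cutoff", "kmeans_k",
                "profile_flank_bp", "profile_flank_bins",
                "profile_body_bins", "tss_flank_bp", "tss_bin_bp")
  for (f in positive) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field '", f, "' must be a single positive number")
  }
  if (cfg$pseudocount < 0)
    stop("config field 'pseudocount' must be >= 0")
  if (is.na(cfg$seed))
    stop("config field 'seed' must be an integer")
  if (length(cfg$tissues) != 2L)
    stop("pipeline expects exactly two tissues")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stable digest of a config: md5 of its canonical YAML serialization.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
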