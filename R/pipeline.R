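#' Run the full analysis pipeline from a manifest
#'
#' Executes every stage on the inputs named by a manifest and writes one
#' TSV per stage plus a provenance file (config values, config hash, seed,
#' input digests). Re-running with identical inputs and seed reproduces
#' byte-identical outputs: all randomness is threaded from
#' `config$seed` and the writers format numbers deterministically.
#'
#' The manifest is a TSV with columns `kind`, `mark`, `tissue`, `path`
#' (paths relative to the manifest's directory). Required slots: one
#' `annotation` (GFF3), and `peaks` + `signal` for every (mark, tissue)
#' combination of `config$marks` x `config$tissues`. Optional:
#' `expression_pair`, `expression_panel` + `samples`, `tf_catalog`
#' (stages needing a missing optional input are skipped).
#'
#' @param config A `pipeline_config`.
#' @param manifest_path Path to the manifest TSV.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every in-memory stage result and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, manifest_path, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- read_stage_tsv(manifest_path)
  base <- dirname(manifest_path)
  manifest$path <- file.path(base, manifest$path)
  lookup <- function(kind, mark = "", tissue = "") {
    hit <- manifest$kind == kind &
      (mark == "" | manifest$mark == mark) &
      (tissue == "" | manifest$tissue == tissue)
    if (!any(hit)) return(NULL)
    manifest$path[which(hit)[1L]]
  }
  # validate completeness before any computation
  missing_slots <- character(0)
  if (is.null(lookup("annotation")))
    missing_slots <- c(missing_slots, "annotation")
  for (mk in config$marks)
    for (ts in config$tissues)
      for (kd in c("peaks", "signal"))
        if (is.null(lookup(kd, mk, ts)))
          missing_slots <- c(missing_slots,
                             paste(kd, mk, ts, sep = "/"))
  if (length(missing_slots))
    stop("manifest is missing required slot(s): ",
         paste(missing_slots, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(out_dir = out_dir)
  gm <- read_gene_models(lookup("annotation"))
  res$gene_models <- gm
  index <- build_region_index(gm, promoter_bp = config$upstream_bp)
  write_region_index(index, file.path(out_dir, "region_index.bed"))
  # per-slot peaks, signal, distribution, metagene profile
  peaks <- list(); tracks <- list()
  dist_rows <- list()
  for (mk in config$marks)
    for (ts in config$tissues) {
      key <- paste(mk, ts, sep = ":")
      peaks[[key]] <- read_peaks(lookup("peaks", mk, ts), mk, ts)
      tracks[[key]] <- read_signal(lookup("signal", mk, ts))
      d <- peak_region_distribution(peaks[[key]], index)
      dist_rows[[key]] <- data.frame(mark = mk, tissue = ts,
                                     region = names(d$base_fraction),
                                     base_fraction = d$base_fraction,
                                     peak_fraction = d$peak_fraction,
                                     stringsAsFactors = FALSE)
      prof <- metagene_profile(tracks[[key]], gm,
                               flank_bp = config$profile_flank_bp,
                               flank_bins = config$profile_flank_bins,
                               body_bins = config$profile_body_bins)
      write_profile(prof, file.path(
        out_dir, sprintf("metagene_%s_%s.tsv", mk, ts)))
    }
  write_stage_tsv(do.call(rbind, c(dist_rows, make.row.names = FALSE)),
                  file.path(out_dir, "region_distribution.tsv"))
  res$peaks <- peaks; res$tracks <- tracks
  # mark assignment and differential deposition
  all_peaks <- do.call(c, unname(peaks))
  table <- assign_marks(all_peaks, gm, config$upstream_bp, tracks)
  write_stage_tsv(table, file.path(out_dir, "mark_table.tsv"))
  res$mark_table <- table
  res$differential <- list()
  for (mk in intersect(config$marks, c("H3K27me3", "H3K4me3"))) {
    norm <- normalize_signal_pair(
      tracks[[paste(mk, config$tissues[1], sep = ":")]],
      tracks[[paste(mk, config$tissues[2], sep = ":")]])
    tr_n <- stats::setNames(list(norm$a, norm$b),
                            paste(mk, config$tissues, sep = ":"))
    tab_n <- assign_marks(all_peaks[mcols(all_peaks)$mark == mk], gm,
                          config$upstream_bp, tr_n)
    d <- differential_deposition(tab_n, mk,
                                 tissue_a = config$tissues[1],
                                 tissue_b = config$tissues[2],
                                 signal_a = norm$a, signal_b = norm$b,
                                 min_fold = config$min_fold,
                                 pseudocount = config$pseudocount)
    res$differential[[mk]] <- d
    genes <- sort(unique(c(d$a_genes, d$b_genes)))
    write_stage_tsv(data.frame(
      gene_id = genes,
      preferential_tissue = ifelse(genes %in% d$a_genes,
                                   config$tissues[1], config$tissues[2]),
      fold_a_over_b = unname(d$fold[genes]),
      stringsAsFactors = FALSE),
      file.path(out_dir, sprintf("differential_%s.tsv", mk)))
  }
  # chromatin states and transitions
  states <- lapply(config$tissues, function(ts) call_states(table, ts))
  write_stage_tsv(do.call(rbind, states),
                  file.path(out_dir, "states.tsv"))
  trans <- classify_transitions(states[[1]], states[[2]])
  write_stage_tsv(trans, file.path(out_dir, "transitions.tsv"))
  res$states <- states; res$transitions <- trans
  # expression stages (optional inputs)
  if (!is.null(lookup("expression_pair"))) {
    pair <- read_stage_tsv(lookup("expression_pair"))
    ea <- stats::setNames(pair[[config$tissues[1]]], pair$gene_id)
    eb <- stats::setNames(pair[[config$tissues[2]]], pair$gene_id)
    deg <- call_deg(ea, eb, fold = config$fold_change_cutoff,
                    pseudocount = config$pseudocount)
    res$deg <- deg
    deg_df <- data.frame(
      gene_id = c(deg$a_higher, deg$b_higher),
      higher_tissue = c(rep(config$tissues[1], length(deg$a_higher)),
                        rep(config$tissues[2], length(deg$b_higher))),
      stringsAsFactors = FALSE)
    write_stage_tsv(deg_df[order(deg_df$gene_id), , drop = FALSE],
                    file.path(out_dir, "deg.tsv"))
    if ("H3K27me3" %in% names(res$differential)) {
      venn <- integrate_marks_expression(res$differential$H3K27me3,
                                         deg$a_higher, deg$b_higher)
      res$venn <- venn
      write_stage_tsv(data.frame(
        mark_tissue = rep(config$tissues, each = 2L),
        expr_tissue = rep(config$tissues, 2L),
        n_genes = as.integer(t(venn$counts)),
        stringsAsFactors = FALSE),
        file.path(out_dir, "venn_H3K27me3.tsv"))
    }
  }
  if (!is.null(lookup("expression_panel")) &&
      !is.null(lookup("samples"))) {
    panel <- read_expression(lookup("expression_panel"),
                             lookup("samples"))
    pref <- preferential_expression(panel$matrix,
                                    panel$samples$tissue,
                                    target = config$tissues[1],
                                    p_cutoff =
                                      config$preferential_p_cutoff)
    res$preferential <- pref
    write_stage_tsv(pref, file.path(out_dir, "preferential.tsv"))
    # panel rows may include probes beyond the annotation; genic stages
    # downstream use only annotated preferential genes
    pref_genes <- intersect(pref$gene_id[pref$preferential],
                            mcols(gm$genes)$gene_id)
    te_universe <- trans$gene_id[trans$transition %in%
                                   transition_labels()]
    set_in_u <- intersect(pref_genes, te_universe)
    if (length(set_in_u)) {
      te <- transition_enrichment(set_in_u, trans)
      res$transition_enrichment <- te
      write_stage_tsv(te,
                      file.path(out_dir, "transition_enrichment.tsv"))
    }
    if (!is.null(lookup("tf_catalog"))) {
      catalog <- read_family_catalog(lookup("tf_catalog"))
      tf_query <- intersect(pref_genes, unique(catalog$gene_id))
      if (length(tf_query)) {
        fe <- family_enrichment(tf_query, catalog)
        res$tf_enrichment <- fe
        write_stage_tsv(fe, file.path(out_dir, "tf_enrichment.tsv"))
      }
    }
    if (length(pref_genes) >= config$kmeans_k) {
      mats <- lapply(config$marks, function(mk)
        tss_matrix(tracks[[paste(mk, config$tissues[1], sep = ":")]],
                   gm, sort(pref_genes),
                   flank_bp = config$tss_flank_bp,
                   bin_bp = config$tss_bin_bp))
      names(mats) <- config$marks
      cl <- cluster_by_marks(mats, k = config$kmeans_k,
                             seed = config$seed)
      res$clusters <- cl
      write_stage_tsv(data.frame(gene_id = names(cl$cluster),
                                 cluster = unname(cl$cluster),
                                 stringsAsFactors = FALSE),
                      file.path(out_dir, "clusters.tsv"))
    }
  }
  # provenance: config, hash, seed, input digests (no timestamps)
  prov <- list(config = unclass(config),
               config_md5 = config_hash(config),
               seed = config$seed,
               inputs = stats::setNames(
                 as.list(unname(tools::md5sum(manifest$path))),
                 basename(manifest$path)))
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  invisible(res)
}
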