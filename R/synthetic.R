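#' Configuration for the synthetic two-tissue study
#'
#' Defines the study conditions the generator emulates: a toy two-
#' chromosome genome with well-separated genes, H3K27me3/H3K4me3/DHS peak
#' sets per tissue whose placement provably respects the 2-kb-upstream
#' assignment rule, signal tracks honouring planted fold ratios,
#' a two-condition FPKM table with planted differential genes, and a
#' 45-sample / 13-tissue expression panel with planted callus-preferential
#' genes at a +4 sd effect. Genes are laid out in slots wide enough that
#' no gene's assignment window can touch a neighbour's, so the planted
#' mark flags are exactly recoverable.
#'
#' @param seed Integer seed (mandatory; drives every random draw).
#' @param chrom_lengths Named chromosome lengths (default 2 x 2 Mb).
#' @param n_genes Number of genes (default 500).
#' @param upstream_bp Assignment window upstream extension (2 kb).
#' @param gene_length_range Uniform range of gene body lengths, bp.
#' @param peak_meanlog,peak_sdlog Log-normal peak width parameters
#'   (median 1 kb); widths are truncated to fit the gene body with
#'   `peak_margin` clearance.
#' @param peak_margin Minimum clearance between a peak and the window
#'   boundary, bp; guards recovery tests from boundary flakiness.
#' @param boundary_stress If `TRUE`, peaks are instead placed with exactly
#'   1 bp of window overlap, to stress half-open boundary handling.
#' @param state_probs Per-tissue probabilities of the four states
#'   (active / repressed / bivalent / none); drawn independently per
#'   tissue so all transitions occur.
#' @param dhs_prob Probability of a DHS given the gene's state in that
#'   tissue.
#' @param diff_fraction Fraction of genes marked in both tissues that are
#'   planted as signal-differential (split evenly between tissues).
#' @param diff_fold Planted windowed-signal fold ratio.
#' @param base_amplitude Baseline peak signal amplitude.
#' @param signal_noise Relative sd of truncated-Gaussian amplitude noise
#'   (0 = noiseless).
#' @param n_deg Planted differentially expressed genes per direction.
#' @param deg_fold Planted expression fold.
#' @param expr_noise sdlog of multiplicative log-normal expression noise.
#' @param n_panel_tissues,n_panel_samples Panel design (13 tissues, 45
#'   samples; the target tissue gets 3 samples).
#' @param n_pref Planted callus-preferential genes.
#' @param n_panel_background Background probes added to the panel beyond
#'   the study genes, mimicking a whole-transcriptome array so planted
#'   genes stay a small fraction of each sample's distribution (as on a
#'   real chip) and cross-sample normalization behaves.
#' @param pref_effect_sd Planted preferential effect, in units of the
#'   total non-target sd.
#' @param panel_tissue_sd,panel_resid_sd Log2-scale sd of tissue effects
#'   and residual sample noise in the panel.
#' @param n_tf TF catalog size; families follow the rice TF family
#'   nomenclature.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       chrom_lengths = c(Chr1 = 2e6, Chr2 = 2e6),
                       n_genes = 500,
                       upstream_bp = 2000,
                       gene_length_range = c(1000, 3000),
                       peak_meanlog = log(1000),
                       peak_sdlog = 0.35,
                       peak_margin = 100,
                       boundary_stress = FALSE,
                       state_probs = c(active = 0.35, repressed = 0.25,
                                       bivalent = 0.20, none = 0.20),
                       dhs_prob = c(active = 0.7, bivalent = 0.5,
                                    repressed = 0.2, none = 0.2),
                       diff_fraction = 0.2,
                       diff_fold = 4,
                       base_amplitude = 50,
                       signal_noise = 0.1,
                       n_deg = 100,
                       deg_fold = 4,
                       expr_noise = 0.15,
                       n_panel_tissues = 13,
                       n_panel_samples = 45,
                       n_pref = 150,
                       n_panel_background = 2000,
                       pref_effect_sd = 4,
                       panel_tissue_sd = 0.15,
                       panel_resid_sd = 0.5,
                       n_tf = 200) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (any(state_probs < 0) || abs(sum(state_probs) - 1) > 1e-9)
    stop("state_probs must be a probability vector over the four states")
  if (any(dhs_prob < 0 | dhs_prob > 1))
    stop("dhs_prob entries must lie in [0, 1]")
  if (diff_fraction < 0 || diff_fraction > 1)
    stop("diff_fraction must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# slot layout: genes in disjoint slots so assignment windows cannot touch
plan_gene_slots <- function(cfg) {
  if (cfg$n_genes == 0L)
    return(data.frame(chrom = character(0), slot_start = numeric(0),
                      pitch = numeric(0)))
  tail_reserve <- 20000  # peak-free tail used for depth equalization
  lens <- cfg$chrom_lengths - tail_reserve
  if (any(lens <= 0)) stop("infeasible design: chromosomes too short")
  per_chr <- diff(round(cumsum(c(0, lens)) / sum(lens) * cfg$n_genes))
  need <- max(cfg$gene_length_range) + 2 * cfg$upstream_bp +
    2 * cfg$peak_margin
  rows <- list()
  for (i in seq_along(lens)) {
    n <- per_chr[i]
    if (n == 0L) next
    pitch <- unname(floor(lens[i] / n))
    if (pitch < need)
      stop("infeasible design: ", n, " genes on ",
           names(cfg$chrom_lengths)[i], " leave slots of ", pitch,
           " bp but windows need ", need, " bp")
    rows[[i]] <- data.frame(chrom = rep(names(cfg$chrom_lengths)[i], n),
                            slot_start = (seq_len(n) - 1) * pitch,
                            pitch = pitch,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic study with planted truth
#'
#' Runs the generator under `config$seed` and writes every input the
#' pipeline consumes (GFF3 annotation, BED peaks and bedGraph signal per
#' mark and tissue, two-condition FPKM table, multi-tissue panel with
#' sample sidecar, TF family catalog, manifest) plus a `truth.tsv` holding
#' the planted per-gene flags, states, transition labels, differential
#' memberships, DEG directions, preferential flags, and cluster
#' archetypes. Identical seeds give byte-identical files. Per-mark signal
#' tracks of the two tissues are depth-equalized by construction via a
#' compensating run in a reserved peak-free tail region, so planted fold
#' ratios survive normalization untouched.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return A `synthetic_study` list: `config`, `dir`, `paths`, `truth`
#'   (data.frame), `gene_models`, `peaks` (combined GRanges), `tracks`
#'   (named list `"<mark>:<tissue>"`), `expr_pair`, `panel`, `samples`,
#'   `catalog`.
#' @export
simulate_study <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  slots <- plan_gene_slots(cfg)
  n <- nrow(slots)
  gene_id <- sprintf("gene%04d", seq_len(n))
  # --- gene layout -------------------------------------------------------
  len <- if (n) round(runif(n, cfg$gene_length_range[1],
                            cfg$gene_length_range[2])) else numeric(0)
  margin <- cfg$upstream_bp + cfg$peak_margin
  jitter_max <- slots$pitch - len - 2 * margin
  offset <- floor(runif(n) * (jitter_max + 1))
  gstart <- slots$slot_start + margin + offset + 1
  gend <- gstart + len - 1
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gm <- build_synthetic_models(slots$chrom, gstart, gend, strand,
                               gene_id, cfg$chrom_lengths)
  # --- planted states, flags, transitions --------------------------------
  draw_state <- function()
    sample(names(cfg$state_probs), n, replace = TRUE,
           prob = cfg$state_probs)
  state_c <- draw_state()
  state_s <- draw_state()
  flags <- data.frame(
    k4_callus = state_c %in% c("active", "bivalent"),
    k27_callus = state_c %in% c("repressed", "bivalent"),
    dhs_callus = runif(n) < cfg$dhs_prob[state_c],
    k4_seedling = state_s %in% c("active", "bivalent"),
    k27_seedling = state_s %in% c("repressed", "bivalent"),
    dhs_seedling = runif(n) < cfg$dhs_prob[state_s])
  transition <- if (n) {
    lab <- paste(state_c, state_s, sep = "-")
    ifelse(lab %in% .transition_labels, lab, "unclassified")
  } else character(0)
  # --- planted signal-differential genes ---------------------------------
  flag_col <- function(mark, tissue)
    flags[[paste(c(H3K4me3 = "k4", H3K27me3 = "k27", DHS = "dhs")[mark],
                 tissue, sep = "_")]]
  diff_dir <- list()
  for (mark in c("H3K27me3", "H3K4me3", "DHS")) {
    dir_vec <- rep("none", n)
    in_c <- flag_col(mark, "callus")
    in_s <- flag_col(mark, "seedling")
    dir_vec[in_c & !in_s] <- "callus"      # presence/absence differential
    dir_vec[in_s & !in_c] <- "seedling"
    both <- which(in_c & in_s)
    if (mark != "DHS" && length(both) >= 2) {
      n_diff <- floor(cfg$diff_fraction * length(both) / 2) * 2
      picked <- sample(both, n_diff)
      dir_vec[picked[seq_len(n_diff / 2)]] <- "callus"
      dir_vec[picked[seq_len(n_diff / 2) + n_diff / 2]] <- "seedling"
    }
    diff_dir[[mark]] <- dir_vec
  }
  # --- peaks and signal tracks -------------------------------------------
  amp_noise <- function(amp)
    pmax(amp * (1 + rnorm(length(amp), 0, cfg$signal_noise)), 0.05 * amp)
  peaks <- list(); tracks <- list()
  win <- gene_windows(gm, cfg$upstream_bp)
  for (mark in c("H3K27me3", "H3K4me3", "DHS")) {
    w <- round(rlnorm(n, cfg$peak_meanlog, cfg$peak_sdlog))
    w <- pmin(pmax(w, 300), len - 2 * cfg$peak_margin)
    w <- pmax(w, 1)
    pos_max <- len - 2 * cfg$peak_margin - w
    ps <- gstart + cfg$peak_margin + floor(runif(n) * (pos_max + 1))
    pe <- ps + w - 1
    if (cfg$boundary_stress && n) {
      # 1-bp overlap with the window's leftmost base instead
      ps <- pmax(start(win) - 199L, 1L)
      pe <- start(win)
    }
    for (tissue in c("callus", "seedling")) {
      has <- flag_col(mark, tissue)
      high <- diff_dir[[mark]] == tissue &
        flag_col(mark, "callus") & flag_col(mark, "seedling")
      amp <- ifelse(high, cfg$base_amplitude * cfg$diff_fold,
                    cfg$base_amplitude)
      amp <- amp_noise(amp)
      idx <- which(has)
      gr <- GenomicRanges::GRanges(
        slots$chrom[idx], IRanges::IRanges(ps[idx], pe[idx]),
        score = amp[idx])
      mcols(gr)$mark <- rep(mark, length(gr))
      mcols(gr)$tissue <- rep(tissue, length(gr))
      peaks[[paste(mark, tissue, sep = ":")]] <- gr
    }
    # depth-equalize the two tissue tracks in the reserved tail region
    key_c <- paste(mark, "callus", sep = ":")
    key_s <- paste(mark, "seedling", sep = ":")
    tr <- lapply(list(peaks[[key_c]], peaks[[key_s]]), function(p) {
      g <- granges(p); mcols(g)$score <- mcols(p)$score; g
    })
    totals <- vapply(tr, signal_total, 0)
    deficit <- max(totals) - totals
    last_chr <- names(cfg$chrom_lengths)[length(cfg$chrom_lengths)]
    L <- cfg$chrom_lengths[[length(cfg$chrom_lengths)]]
    for (i in 1:2) {
      if (deficit[i] > 0) {
        eq <- GenomicRanges::GRanges(last_chr,
                                     IRanges::IRanges(L - 15000 + 1,
                                                      L - 5000),
                                     score = deficit[i] / 10000)
        tr[[i]] <- c(tr[[i]], eq)
      }
      tr[[i]] <- GenomicRanges::sort(tr[[i]], ignore.strand = TRUE)
    }
    tracks[[key_c]] <- tr[[1]]
    tracks[[key_s]] <- tr[[2]]
  }
  # --- two-condition expression ------------------------------------------
  base_fpkm <- if (n) rlnorm(n, meanlog = 2, sdlog = 1) else numeric(0)
  deg <- rep("none", n)
  if (2 * cfg$n_deg > n && n > 0)
    stop("infeasible design: more planted DEGs than genes")
  if (n && cfg$n_deg > 0) {
    picked <- sample(n, 2 * cfg$n_deg)
    deg[picked[seq_len(cfg$n_deg)]] <- "callus"
    deg[picked[seq_len(cfg$n_deg) + cfg$n_deg]] <- "seedling"
    base_fpkm[picked] <- pmax(base_fpkm[picked], 2)
  }
  noise_mult <- function()
    if (cfg$expr_noise > 0) rlnorm(n, 0, cfg$expr_noise) else rep(1, n)
  expr_pair <- data.frame(
    gene_id = gene_id,
    callus = base_fpkm * ifelse(deg == "callus", cfg$deg_fold, 1) *
      noise_mult(),
    seedling = base_fpkm * ifelse(deg == "seedling", cfg$deg_fold, 1) *
      noise_mult(),
    stringsAsFactors = FALSE)
  # --- multi-tissue panel -------------------------------------------------
  if (cfg$n_pref > n && n > 0)
    stop("infeasible design: more planted preferential genes than genes")
  other_n <- cfg$n_panel_samples - 3L
  other_tissues <- paste0("tissue", sprintf("%02d",
                                            seq_len(cfg$n_panel_tissues - 1L)))
  sizes <- rep(floor(other_n / length(other_tissues)),
               length(other_tissues))
  extra <- other_n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  tissue_of_sample <- c(rep("callus", 3L), rep(other_tissues, sizes))
  sample_id <- sprintf("S%02d", seq_along(tissue_of_sample))
  samples <- data.frame(sample = sample_id, tissue = tissue_of_sample,
                        stage = ((seq_along(sample_id) - 1L) %% 17L) + 1L,
                        stringsAsFactors = FALSE)
  preferential <- rep(FALSE, n)
  if (n && cfg$n_pref > 0)
    preferential[sample(n, cfg$n_pref)] <- TRUE
  n_bg <- if (n) cfg$n_panel_background else 0L
  probe_id <- c(gene_id,
                if (n_bg) sprintf("probe%04d", seq_len(n_bg)))
  np <- n + n_bg
  panel <- matrix(0, nrow = np, ncol = length(sample_id),
                  dimnames = list(probe_id, sample_id))
  if (np) {
    # log2-scale intensities, as normalized GeneChip panels are reported
    g_mean <- rnorm(np, 6, 1)
    pref_probe <- c(preferential, rep(FALSE, n_bg))
    all_tissues <- c("callus", other_tissues)
    t_eff <- matrix(rnorm(np * length(all_tissues), 0,
                          cfg$panel_tissue_sd),
                    nrow = np, dimnames = list(NULL, all_tissues))
    shift <- cfg$pref_effect_sd *
      sqrt(cfg$panel_tissue_sd^2 + cfg$panel_resid_sd^2)
    for (j in seq_along(sample_id)) {
      ts <- tissue_of_sample[j]
      panel[, j] <- pmax(g_mean + t_eff[, ts] +
                           rnorm(np, 0, cfg$panel_resid_sd) +
                           ifelse(pref_probe & ts == "callus",
                                  shift, 0), 0)
    }
  }
  # --- TF catalog ---------------------------------------------------------
  families <- c("AP2-EREBP", "NAC", "HB", "MADS", "LOB", "AUX-IAA",
                "WRKY", "bHLH", "GRAS", "C2C2-Dof")
  n_tf <- min(cfg$n_tf, n)
  catalog <- data.frame(
    gene_id = if (n_tf) sort(sample(gene_id, n_tf)) else character(0),
    stringsAsFactors = FALSE)
  catalog$family <- if (n_tf) sample(families, n_tf, replace = TRUE)
                    else character(0)
  # --- archetypes (for the k = 2 clustering check) ------------------------
  archetype <- rep(NA_integer_, n)
  archetype[state_c == "active"] <- 1L
  archetype[state_c == "repressed"] <- 2L
  truth <- data.frame(gene_id = gene_id, chrom = slots$chrom,
                      start = gstart, end = gend, strand = strand,
                      flags,
                      state_callus = state_c, state_seedling = state_s,
                      transition = transition,
                      k27_diff = diff_dir[["H3K27me3"]],
                      k4_diff = diff_dir[["H3K4me3"]],
                      dhs_diff = diff_dir[["DHS"]],
                      deg = deg, preferential = preferential,
                      archetype = archetype,
                      stringsAsFactors = FALSE)
  # --- write everything ---------------------------------------------------
  paths <- list(annotation = file.path(dir, "genes.gff3"),
                truth = file.path(dir, "truth.tsv"),
                expr_pair = file.path(dir, "expression_pair.tsv"),
                panel = file.path(dir, "expression_panel.tsv"),
                samples = file.path(dir, "samples.tsv"),
                catalog = file.path(dir, "tf_families.tsv"),
                manifest = file.path(dir, "manifest.tsv"))
  write_gene_models(gm, paths$annotation)
  write_stage_tsv(truth, paths$truth)
  write_stage_tsv(expr_pair, paths$expr_pair)
  panel_df <- data.frame(gene_id = rownames(panel), panel,
                         check.names = FALSE, stringsAsFactors = FALSE)
  write_stage_tsv(panel_df, paths$panel)
  write_stage_tsv(samples, paths$samples)
  write_family_catalog(catalog, paths$catalog)
  manifest <- data.frame(kind = "annotation", mark = "", tissue = "",
                         path = "genes.gff3", stringsAsFactors = FALSE)
  for (key in names(peaks)) {
    mk <- sub(":.*", "", key); ts <- sub(".*:", "", key)
    pb <- sprintf("peaks_%s_%s.bed", mk, ts)
    sb <- sprintf("signal_%s_%s.bedGraph", mk, ts)
    write_peaks(peaks[[key]], file.path(dir, pb))
    write_signal(tracks[[key]], file.path(dir, sb))
    manifest <- rbind(manifest,
                      data.frame(kind = c("peaks", "signal"),
                                 mark = mk, tissue = ts,
                                 path = c(pb, sb),
                                 stringsAsFactors = FALSE))
  }
  manifest <- rbind(manifest, data.frame(
    kind = c("expression_pair", "expression_panel", "samples",
             "tf_catalog", "truth"),
    mark = "", tissue = "",
    path = c("expression_pair.tsv", "expression_panel.tsv",
             "samples.tsv", "tf_families.tsv", "truth.tsv"),
    stringsAsFactors = FALSE))
  write_stage_tsv(manifest, paths$manifest)
  all_peaks <- if (length(peaks)) do.call(c, unname(peaks))
               else GenomicRanges::GRanges()
  out <- list(config = cfg, dir = dir, paths = paths, truth = truth,
              gene_models = gm, peaks = all_peaks, tracks = tracks,
              expr_pair = expr_pair, panel = panel, samples = samples,
              catalog = catalog)
  class(out) <- "synthetic_study"
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", nrow(x$truth), "genes, seed", x$config$seed,
      "->", x$dir, "\n")
  invisible(x)
}

# two-exon gene models with 100-bp terminal UTRs
build_synthetic_models <- function(chrom, gstart, gend, strand, gene_id,
                                   seqlengths) {
  n <- length(gene_id)
  genes <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(gstart, gend),
                                  strand = strand)
  mcols(genes)$gene_id <- gene_id
  empty <- function() {
    g <- GenomicRanges::GRanges(); mcols(g)$gene_id <- character(0); g
  }
  if (n == 0L) {
    gm <- list(genes = genes, exons = empty(), utr5 = empty(),
               utr3 = empty(), seqlengths = seqlengths)
    class(gm) <- "gene_models"
    return(gm)
  }
  len <- gend - gstart + 1
  e1_end <- gstart + pmax(round(0.4 * len), 150) - 1
  e2_start <- gend - pmax(round(0.4 * len), 150) + 1
  exons <- GenomicRanges::GRanges(
    rep(chrom, 2L),
    IRanges::IRanges(c(gstart, e2_start), c(e1_end, gend)),
    strand = rep(strand, 2L))
  mcols(exons)$gene_id <- rep(gene_id, 2L)
  left_utr <- GenomicRanges::GRanges(chrom,
                                     IRanges::IRanges(gstart,
                                                      gstart + 99),
                                     strand = strand)
  right_utr <- GenomicRanges::GRanges(chrom,
                                      IRanges::IRanges(gend - 99, gend),
                                      strand = strand)
  plus <- strand == "+"
  utr5 <- c(left_utr[plus], right_utr[!plus])
  mcols(utr5)$gene_id <- c(gene_id[plus], gene_id[!plus])
  utr3 <- c(right_utr[plus], left_utr[!plus])
  mcols(utr3)$gene_id <- c(gene_id[plus], gene_id[!plus])
  ord5 <- order(mcols(utr5)$gene_id)
  ord3 <- order(mcols(utr3)$gene_id)
  gm <- list(genes = genes, exons = exons, utr5 = utr5[ord5],
             utr3 = utr3[ord3], seqlengths = seqlengths)
  class(gm) <- "gene_models"
  gm
}
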