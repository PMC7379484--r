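test_that("the 2-kb-upstream-plus-body window rule assigns marks", {
  gm <- make_gm(data.frame(gene_id = "g1", chrom = "Chr1", start = 5001,
                           end = 8000, strand = "+"),
                c(Chr1 = 20000))
  # peak [3501,3600] overlaps the window [3001,8000]
  tab <- assign_marks(make_peaks("Chr1", 3501, 3600, "H3K27me3",
                                 "callus"), gm, 2000)
  expect_true(tab$present)
  # peak ending at 3000 does not touch the window starting at 3001
  tab2 <- assign_marks(make_peaks("Chr1", 2901, 3000, "H3K27me3",
                                  "callus"), gm, 2000)
  expect_false(tab2$present)
  # the flag table is boolean-complete over genes x observed slots
  expect_equal(nrow(tab), 1L)
  expect_false(anyNA(tab$present))
})

test_that("assignment matches a quadratic all-pairs overlap check", {
  set.seed(77)
  st <- simulate_study(small_sim(77), withr::local_tempdir())
  gm <- st$gene_models
  n_peaks <- 300
  chrom <- sample(names(gm$seqlengths), n_peaks, replace = TRUE)
  s <- sapply(gm$seqlengths[chrom] - 3000, function(m) sample(m, 1))
  peaks <- make_peaks(chrom, s, s + sample(100:2500, n_peaks,
                                           replace = TRUE),
                      "H3K4me3", "callus")
  tab <- assign_marks(peaks, gm, 2000)
  win <- gene_windows(gm, 2000)
  expected <- bf_assign(win, peaks)
  slot <- tab[order(match(tab$gene_id,
                          S4Vectors::mcols(win)$gene_id)), ]
  expect_identical(slot$present, expected)
})

test_that("enlarging the upstream window never removes a mark", {
  st <- simulate_study(small_sim(5), withr::local_tempdir())
  prev <- NULL
  for (up in c(0, 500, 2000, 5000)) {
    tab <- assign_marks(st$peaks, st$gene_models, up)
    cur <- tab$present
    if (!is.null(prev)) expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("differential deposition follows presence and fold rules", {
  st <- simulate_study(small_sim(9, signal_noise = 0),
                       withr::local_tempdir())
  tab <- assign_marks(st$peaks, st$gene_models, 2000, st$tracks)
  d <- differential_deposition(tab, "H3K27me3",
                               signal_a = st$tracks[["H3K27me3:callus"]],
                               signal_b = st$tracks[["H3K27me3:seedling"]])
  expect_length(intersect(d$a_genes, d$b_genes), 0L)
  # genes carrying the mark in exactly one tissue are always called
  a_slot <- tab[tab$mark == "H3K27me3" & tab$tissue == "callus", ]
  b_slot <- tab[tab$mark == "H3K27me3" & tab$tissue == "seedling", ]
  a_only <- a_slot$gene_id[a_slot$present &
                             !b_slot$present[match(a_slot$gene_id,
                                                   b_slot$gene_id)]]
  expect_true(all(a_only %in% d$a_genes))
  # every member carries the mark in at least one tissue
  carriers <- union(a_slot$gene_id[a_slot$present],
                    b_slot$gene_id[b_slot$present])
  expect_true(all(c(d$a_genes, d$b_genes) %in% carriers))

  # mirror: swapping tissues swaps the sets
  d_rev <- differential_deposition(tab, "H3K27me3",
                                   tissue_a = "seedling",
                                   tissue_b = "callus")
  expect_setequal(d_rev$a_genes, d$b_genes)
  expect_setequal(d_rev$b_genes, d$a_genes)

  # min_fold -> Inf reduces to the presence/absence set differences
  d_inf <- differential_deposition(tab, "H3K27me3", min_fold = Inf)
  b_only <- b_slot$gene_id[b_slot$present &
                             !a_slot$present[match(b_slot$gene_id,
                                                   a_slot$gene_id)]]
  expect_setequal(d_inf$a_genes, a_only)
  expect_setequal(d_inf$b_genes, b_only)
})

test_that("fold threshold is inclusive at min_fold and excludes below", {
  tab <- data.frame(gene_id = rep(c("g1", "g2"), each = 2),
                    mark = "H3K27me3",
                    tissue = rep(c("callus", "seedling"), 2),
                    present = TRUE,
                    mean_signal = c(3, 1, 2.999, 1))
  class(tab) <- c("mark_table", "data.frame")
  # pseudocount 1: g1 ratio = 4/2 = 2 (called); g2 = 3.999/2 < 2 (not)
  d <- differential_deposition(tab, "H3K27me3", min_fold = 2,
                               pseudocount = 1)
  expect_equal(d$a_genes, "g1")
  expect_length(d$b_genes, 0L)
})

test_that("unnormalized signal pairs are rejected, normalization fixes", {
  a <- make_track("Chr1", 1, 1000, 10)
  b <- make_track("Chr1", 1, 1000, 5)
  tab <- data.frame(gene_id = "g1", mark = "H3K4me3",
                    tissue = c("callus", "seedling"),
                    present = TRUE, mean_signal = c(10, 5))
  class(tab) <- c("mark_table", "data.frame")
  expect_error(differential_deposition(tab, "H3K4me3", signal_a = a,
                                       signal_b = b), "normalized")
  nrm <- normalize_signal_pair(a, b)
  expect_equal(sum(GenomicRanges::width(nrm$a) *
                     S4Vectors::mcols(nrm$a)$score),
               sum(GenomicRanges::width(nrm$b) *
                     S4Vectors::mcols(nrm$b)$score))
})

test_that("planted fold-4 differential genes are recovered exactly", {
  st <- simulate_study(small_sim(13, signal_noise = 0),
                       withr::local_tempdir())
  tab <- assign_marks(st$peaks, st$gene_models, 2000, st$tracks)
  for (mk in c("H3K27me3", "H3K4me3")) {
    d <- differential_deposition(tab, mk)
    col <- c(H3K27me3 = "k27_diff", H3K4me3 = "k4_diff")[[mk]]
    expect_setequal(d$a_genes,
                    st$truth$gene_id[st$truth[[col]] == "callus"])
    expect_setequal(d$b_genes,
                    st$truth$gene_id[st$truth[[col]] == "seedling"])
  }
})
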