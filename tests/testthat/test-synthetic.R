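test_that("identical seeds give byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(small_sim(101), d1)
  simulate_study(small_sim(101), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # different seed changes content
  d3 <- withr::local_tempdir()
  simulate_study(small_sim(102), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "truth.tsv"))),
    unname(tools::md5sum(file.path(d3, "truth.tsv")))))
})

test_that("planted truth is self-consistent", {
  st <- simulate_study(small_sim(103), withr::local_tempdir())
  tr <- st$truth
  expect_identical(call_state(tr$k4_callus, tr$k27_callus),
                   tr$state_callus)
  expect_identical(call_state(tr$k4_seedling, tr$k27_seedling),
                   tr$state_seedling)
  lab <- paste(tr$state_callus, tr$state_seedling, sep = "-")
  lab[!lab %in% transition_labels()] <- "unclassified"
  expect_identical(lab, tr$transition)
  # signal-differential genes carry the mark in both tissues or one
  both_dirs <- tr$k27_diff != "none"
  expect_true(all(tr$k27_callus[both_dirs] | tr$k27_seedling[both_dirs]))
})

test_that("flags recovered from the emitted files equal the truth", {
  st <- simulate_study(small_sim(104, signal_noise = 0),
                       withr::local_tempdir())
  # read everything back from disk, not from memory
  gm <- read_gene_models(st$paths$annotation)
  manifest <- utils::read.table(st$paths$manifest, sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  pk <- manifest[manifest$kind == "peaks", ]
  peaks <- do.call(c, lapply(seq_len(nrow(pk)), function(i)
    read_peaks(file.path(st$dir, pk$path[i]), pk$mark[i],
               pk$tissue[i])))
  tab <- assign_marks(peaks, gm, 2000)
  sc <- truth_scorecard(st$truth, mark_table = tab)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
})

test_that("boundary-stress placement still recovers flags exactly", {
  st <- simulate_study(small_sim(105, boundary_stress = TRUE),
                       withr::local_tempdir())
  tab <- assign_marks(st$peaks, st$gene_models, 2000)
  sc <- truth_scorecard(st$truth, mark_table = tab)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
})

test_that("infeasible designs error before writing anything", {
  d <- withr::local_tempdir()
  too_many <- sim_config(seed = 1, chrom_lengths = c(Chr1 = 1e5),
                         n_genes = 400)
  expect_error(simulate_study(too_many, file.path(d, "x")),
               "infeasible")
  expect_false(file.exists(file.path(d, "x", "truth.tsv")))
  expect_error(simulate_study(
    small_sim(1, n_deg = 100), withr::local_tempdir()), "infeasible")
  expect_error(sim_config(seed = 1, diff_fraction = 2), "diff_fraction")
  expect_error(sim_config(), "seed")
})

test_that("a zero-gene design produces valid empty outputs", {
  st <- simulate_study(sim_config(seed = 2, n_genes = 0, n_deg = 0,
                                  n_pref = 0, n_tf = 0),
                       withr::local_tempdir())
  expect_equal(nrow(st$truth), 0L)
  expect_length(st$peaks, 0L)
  expect_true(file.exists(st$paths$annotation))
  gm <- read_gene_models(st$paths$annotation)
  expect_length(gm$genes, 0L)
})

test_that("scorecard metrics are label-invariant and complete", {
  st <- simulate_study(small_sim(106, signal_noise = 0, expr_noise = 0),
                       withr::local_tempdir())
  tab <- assign_marks(st$peaks, st$gene_models, 2000, st$tracks)
  trans <- classify_transitions(call_states(tab, "callus"),
                                call_states(tab, "seedling"))
  sc <- truth_scorecard(st$truth, mark_table = tab, transitions = trans)
  expect_equal(sc$accuracy[sc$quantity == "transitions"], 1)
  # ARI is invariant under cluster label permutation
  ids <- st$truth$gene_id[!is.na(st$truth$archetype)]
  cl <- structure(list(cluster = stats::setNames(
    st$truth$archetype[match(ids, st$truth$gene_id)], ids),
    centers = NULL, k = 2L, seed = 1L),
    class = "cluster_assignment")
  cl_perm <- cl
  cl_perm$cluster <- stats::setNames(3L - cl$cluster, ids)
  s1 <- truth_scorecard(st$truth, clusters = cl)
  s2 <- truth_scorecard(st$truth, clusters = cl_perm)
  expect_equal(s1$ari, s2$ari)
  expect_equal(s1$ari, 1)
  # mismatched universes are an error
  bad <- tab[tab$gene_id != tab$gene_id[1], ]
  class(bad) <- c("mark_table", "data.frame")
  expect_error(truth_scorecard(st$truth, mark_table = bad), "universe")
})

test_that("recall rises with the planted effect size", {
  recalls <- vapply(c(1, 4), function(eff) {
    st <- simulate_study(small_sim(107, pref_effect_sd = eff),
                         withr::local_tempdir())
    res <- preferential_expression(st$panel, st$samples$tissue,
                                   "callus")
    truth_scorecard(st$truth, preferential = res)$recall
  }, 0)
  expect_true(diff(recalls) > 0)
  folds <- vapply(c(1.2, 4), function(fold) {
    st <- simulate_study(small_sim(108, diff_fold = fold,
                                   signal_noise = 0.2),
                         withr::local_tempdir())
    tab <- assign_marks(st$peaks, st$gene_models, 2000, st$tracks)
    d <- differential_deposition(tab, "H3K27me3")
    truth_scorecard(st$truth,
                    differential = list(H3K27me3 = d))$recall
  }, 0)
  expect_true(diff(folds) >= 0)
})
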