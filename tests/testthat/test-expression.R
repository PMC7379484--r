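test_that("fold-change DEG calling uses a strict ratio threshold", {
  ea <- c(g1 = 10, g2 = 8, g3 = 1)
  eb <- c(g1 = 4, g2 = 4, g3 = 9)
  d <- call_deg(ea, eb, fold = 2, pseudocount = 0)
  expect_equal(d$a_higher, "g1")     # ratio 2.5 > 2
  expect_equal(d$b_higher, "g3")     # ratio 1/9 < 1/2
  expect_false("g2" %in% c(d$a_higher, d$b_higher))  # exactly 2: strict
  # swap symmetry
  d2 <- call_deg(eb, ea, fold = 2, pseudocount = 0)
  expect_equal(d2$a_higher, d$b_higher)
  expect_equal(d2$b_higher, d$a_higher)
  expect_error(call_deg(c(g1 = -1), c(g1 = 1)), "negative")
  expect_error(call_deg(c(1, 2), c(1, 2)), "named")
})

test_that("planted DEG sets are recovered exactly without noise", {
  st <- simulate_study(small_sim(23, expr_noise = 0),
                       withr::local_tempdir())
  d <- call_deg(stats::setNames(st$expr_pair$callus,
                                st$expr_pair$gene_id),
                stats::setNames(st$expr_pair$seedling,
                                st$expr_pair$gene_id))
  expect_setequal(d$a_higher,
                  st$truth$gene_id[st$truth$deg == "callus"])
  expect_setequal(d$b_higher,
                  st$truth$gene_id[st$truth$deg == "seedling"])
})

test_that("preferential Z follows the mean/sd definition", {
  m <- rbind(gA = c(5, 1, 2, 3), gB = c(2, 1, 2, 3))
  colnames(m) <- paste0("s", 1:4)
  res <- preferential_expression(m, c("callus", "t1", "t2", "t3"),
                                 "callus", normalize = "none")
  # others {1,2,3}: mean 2, sd 1 -> target 5 gives Z = 3
  expect_equal(res$z[res$gene_id == "gA"], 3)
  expect_true(res$preferential[res$gene_id == "gA"])
  # target equal to the others' mean: Z = 0, not preferential
  expect_equal(res$z[res$gene_id == "gB"], 0)
  expect_false(res$preferential[res$gene_id == "gB"])
  expect_equal(res$p[res$gene_id == "gA"],
               stats::pnorm(3, lower.tail = FALSE))
})

test_that("degenerate sd-zero genes are kept, not dropped", {
  m <- rbind(up = c(9, 2, 2, 2), same = c(2, 2, 2, 2),
             down = c(1, 2, 2, 2))
  colnames(m) <- paste0("s", 1:4)
  res <- preferential_expression(m, c("callus", "t1", "t2", "t3"),
                                 "callus", normalize = "none")
  expect_true(res$degenerate[res$gene_id == "up"])
  expect_true(res$preferential[res$gene_id == "up"])
  expect_equal(res$p[res$gene_id == "up"], .Machine$double.xmin)
  expect_false(res$preferential[res$gene_id == "same"])
  expect_false(res$preferential[res$gene_id == "down"])
})

test_that("preferential calls are invariant to sample order", {
  set.seed(61)
  m <- matrix(rlnorm(50 * 8), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:8)))
  ts <- c("callus", "callus", "t1", "t1", "t2", "t2", "t3", "t3")
  r1 <- preferential_expression(m, ts, "callus")
  perm <- sample(8)
  r2 <- preferential_expression(m[, perm], ts[perm], "callus")
  expect_equal(r1, r2)
  expect_error(preferential_expression(m[, 1:4], ts[1:4], "callus"),
               "non-target")
})

test_that("planted preferential genes are recovered from the panel", {
  st <- simulate_study(small_sim(29), withr::local_tempdir())
  res <- preferential_expression(st$panel, st$samples$tissue, "callus")
  sc <- truth_scorecard(st$truth, preferential = res)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
})

test_that("k-means separates planted archetypes and is deterministic", {
  set.seed(71)
  n <- 60
  sharp <- cbind(matrix(rnorm(n / 2 * 10, 10), ncol = 10),
                 matrix(rnorm(n / 2 * 10, 0), ncol = 10))
  broad <- cbind(matrix(rnorm(n / 2 * 10, 0), ncol = 10),
                 matrix(rnorm(n / 2 * 10, 10), ncol = 10))
  m <- rbind(sharp, broad)
  rownames(m) <- sprintf("g%02d", seq_len(n))
  cl <- cluster_by_marks(list(mk = m), k = 2, seed = 5)
  truth <- rep(1:2, each = n / 2)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1)
  cl2 <- cluster_by_marks(list(mk = m), k = 2, seed = 5)
  expect_identical(cl$cluster, cl2$cluster)
  # k = 1: everything in one cluster
  expect_equal(unique(cluster_by_marks(list(mk = m), 1, 5)$cluster), 1L)
  expect_error(cluster_by_marks(list(mk = m), n + 1, 5), "exceeds")
})

test_that("duplicating every gene doubles cluster sizes", {
  set.seed(73)
  m <- rbind(matrix(rnorm(200, 5), ncol = 10),
             matrix(rnorm(200, -5), ncol = 10))
  rownames(m) <- sprintf("g%02d", 1:40)
  cl1 <- cluster_by_marks(list(a = m), k = 2, seed = 9)
  dup <- rbind(m, m)
  rownames(dup) <- sprintf("g%02d", 1:80)
  cl2 <- cluster_by_marks(list(a = dup), k = 2, seed = 9)
  expect_setequal(as.integer(table(cl2$cluster)),
                  2L * as.integer(table(cl1$cluster)))
})

test_that("mark x expression integration counts the four cells", {
  d <- structure(list(mark = "H3K27me3", a_genes = c("g1", "g2"),
                      b_genes = c("g3", "g4", "g5"),
                      fold = numeric(0),
                      tissues = c("callus", "seedling")),
                 class = "differential_marks")
  # disjoint expression sets: all cells zero
  v0 <- integrate_marks_expression(d, "x1", "x2")
  expect_equal(sum(v0$counts), 0)
  # containment: deg_a inside the B-preferential mark set
  v1 <- integrate_marks_expression(d, c("g3", "g4"), c("g1"))
  expect_equal(v1$counts["seedling", "callus"], 2,
               ignore_attr = TRUE)
  expect_equal(v1$counts["callus", "seedling"], 1,
               ignore_attr = TRUE)
  expect_setequal(v1$genes$markB_exprA, c("g3", "g4"))
  # no gene is lost or double-counted within a direction
  all_cells <- unlist(v1$genes)
  expect_equal(anyDuplicated(all_cells), 0L)
})

test_that("anti-correlated planted marks put mass in the cross cells", {
  # plant H3K27me3 loss in callus for exactly the genes expressed higher
  # in callus: the cross cells must dominate the same-direction cells
  d <- structure(list(mark = "H3K27me3",
                      a_genes = sprintf("g%02d", 1:10),
                      b_genes = sprintf("g%02d", 11:40),
                      fold = numeric(0),
                      tissues = c("callus", "seedling")),
                 class = "differential_marks")
  deg_a <- sprintf("g%02d", 11:35)   # callus-up where mark is seedling-high
  deg_b <- sprintf("g%02d", 1:8)     # seedling-up where mark is callus-high
  v <- integrate_marks_expression(d, deg_a, deg_b)
  expect_gt(v$counts["seedling", "callus"], v$counts["callus", "callus"])
  expect_gt(v$counts["callus", "seedling"],
            v$counts["seedling", "seedling"])
})
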