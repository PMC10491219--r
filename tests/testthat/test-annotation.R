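fake_partition <- function(cluster) {
  structure(list(cluster = as.integer(cluster),
                 n_clusters = length(unique(cluster)),
                 resolution = NA, quality = NA, seed = NA),
            class = "ClusterPartition")
}

test_that("metacluster merge maps many clusters onto one label", {
  part <- fake_partition(c(0, 0, 1, 1, 2, 2))
  mm <- metacluster_map(c("0" = "HSC", "1" = "HSC", "2" = "EMP1"),
                        c(HSC = "early", EMP1 = "erythroid"))
  X <- matrix(1:12 + 0.0, 6, 2, dimnames = list(NULL, c("a", "b")))
  res <- apply_metaclusters(part, mm, exprs = X)
  expect_equal(res$labels, c("HSC", "HSC", "HSC", "HSC", "EMP1", "EMP1"))
  expect_equal(unname(res$sizes[c("HSC", "EMP1")]), c(4, 2), ignore_attr = TRUE)
  expect_equal(nrow(res$medians), 2)  # one row per distinct label
  # unmapped cluster id is an error
  expect_error(apply_metaclusters(part, metacluster_map(c("0" = "HSC"))),
               "unmapped|cover")
  # label for an id with no cells is harmless
  mm2 <- metacluster_map(c("0" = "A", "1" = "A", "2" = "B", "3" = "C"))
  part2 <- fake_partition(c(0, 0, 1, 1, 2, 2))
  expect_error(apply_metaclusters(part2, mm2), NA)
})

test_that("majority_labels annotates clusters by their dominant truth label", {
  part <- fake_partition(c(0, 0, 0, 1, 1, 1))
  truth <- c("A", "A", "B", "B", "B", "A")
  expect_equal(majority_labels(part, truth), c("0" = "A", "1" = "B"))
})

test_that("constrained transfer votes only within the joint cluster", {
  # reference: two tight blobs with labels; query cells coincide with blob 1
  set.seed(12)
  ref1 <- matrix(rnorm(60, 0, 0.05), ncol = 2)
  ref2 <- matrix(rnorm(60, 5, 0.05), ncol = 2)
  q1 <- ref1[1:10, , drop = FALSE]          # coincident with blob 1
  novel <- matrix(rnorm(40, 20, 0.05), ncol = 2)  # no reference analog
  X <- rbind(ref1, ref2, q1, novel)
  colnames(X) <- c("x", "y")
  is_ref <- rep(c(TRUE, FALSE), c(60, 30))
  cluster <- c(rep(0, 30), rep(1, 30), rep(0, 10), rep(2, 20))
  res <- constrained_knn_transfer(fake_partition(cluster), X, is_ref,
                                  ref_labels = rep(c("alpha", "beta"), each = 30),
                                  k = 5, min_ref = 5)
  expect_equal(res$label[1:10], rep("alpha", 10))
  expect_true(all(res$margin[1:10] == 1))
  # query-only cluster -> unannotated
  expect_equal(res$label[11:30], rep("unannotated", 20))
  expect_equal(res$n_candidates[11:30], rep(0L, 20))
})

test_that("vote ties fall to the single nearest neighbor", {
  # 2-2 tie at k = 4; nearest reference carries label "near"
  refX <- matrix(c(0.1, 0, 0.2, 0, 0.3, 0, 0.4, 0), ncol = 2, byrow = TRUE)
  qX <- matrix(c(0, 0), ncol = 2)
  X <- rbind(refX, qX)
  colnames(X) <- c("x", "y")
  res <- constrained_knn_transfer(fake_partition(rep(0, 5)), X,
                                  is_ref = c(rep(TRUE, 4), FALSE),
                                  ref_labels = c("near", "near", "far", "far"),
                                  k = 4, min_ref = 2)
  expect_equal(res$label, "near")
  expect_equal(res$margin, 0.5)
})

test_that("self-transfer reproduces reference labels on synthetic data", {
  fx <- small_processed()
  truth <- fx$sim$truth
  bm <- which(truth$tissue == "BM" & !truth$is_anchor)
  X <- fx$events$exprs[bm, ]
  part <- trajectory_pipeline(X, resolution = 3, seed = 21)$partition
  res <- constrained_knn_transfer(part, X, is_ref = rep(TRUE, length(bm)),
                                  ref_labels = truth$population[bm],
                                  k = 15)
  # reference used as its own query: no query cells, empty result
  expect_equal(nrow(res), 0)
  # split the reference in half instead: same-distribution transfer
  half <- seq_along(bm) %% 2 == 0
  res2 <- constrained_knn_transfer(part, X, is_ref = !half,
                                   ref_labels = truth$population[bm][!half],
                                   k = 15)
  acc <- mean(res2$label == truth$population[bm][half] |
              res2$label == "unannotated")
  ann_acc <- mean(res2$label[res2$label != "unannotated"] ==
                  truth$population[bm][half][res2$label != "unannotated"])
  expect_gt(ann_acc, 0.7)  # boundary cells are intrinsically ambiguous
})

test_that("composition tables are proportion matrices with lineage rollup", {
  labels <- c(rep("A", 30), rep("B", 70), rep("A", 10), rep("C", 30))
  samples <- c(rep("s1", 100), rep("s2", 40))
  comp <- composition_table(labels, samples,
                            lineage_of = c(A = "early", B = "erythroid",
                                           C = "erythroid"))
  expect_equal(unname(comp$proportions["s1", c("A", "B", "C")]), c(0.3, 0.7, 0),
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(comp$proportions)), c(1, 1))
  expect_equal(unname(comp$lineage_proportions["s2", "erythroid"]), 0.75,
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(comp$lineage_proportions)), c(1, 1))
})
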