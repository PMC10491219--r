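test_that("knn graph on equidistant points is complete and self-loop free", {
  X <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), 3, 2, byrow = TRUE)
  colnames(X) <- c("x", "y")
  g <- build_knn_graph(X, k = 2)
  A <- as.matrix(g$adj)
  expect_true(isSymmetric(A))
  expect_equal(diag(A), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(A[upper.tri(A)] > 0))  # complete on 3 nodes
})

test_that("well-separated blobs produce no cross-blob edges", {
  set.seed(3)
  X <- rbind(matrix(rnorm(200, 0, 0.1), ncol = 2),
             matrix(rnorm(200, 50, 0.1), ncol = 2))
  colnames(X) <- c("x", "y")
  g <- build_knn_graph(X, k = 5)
  A <- g$adj
  expect_equal(sum(A[1:100, 101:200]), 0)
  # duplicates: distance 0 gets the maximal kernel weight, no self-loops
  Xd <- rbind(X[1:10, ], X[1:10, ])
  gd <- build_knn_graph(Xd, k = 3)
  expect_equal(sum(Matrix::diag(gd$adj)), 0)
  expect_equal(max(gd$adj), 1)
  expect_error(build_knn_graph(X, k = 200), "k")
  expect_error(build_knn_graph(matrix(1, 50, 2, dimnames = list(NULL, c("a", "b"))), k = 5),
               "zero-variance")
})

test_that("every node keeps at least its k out-edges after symmetrization", {
  set.seed(8)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  g <- build_knn_graph(X, k = 7)
  deg <- Matrix::rowSums(g$adj > 0)
  expect_true(all(deg >= 7))
})

test_that("diffusion map recovers a path graph ordering", {
  # chain adjacency: diffusion component 1 must be monotone along the chain
  n <- 20
  A <- Matrix::sparseMatrix(i = c(1:(n - 1), 2:n), j = c(2:n, 1:(n - 1)),
                            x = 1, dims = c(n, n))
  g <- structure(list(adj = A, k = 1, metric = "euclidean",
                      provenance = "expression-space", n = n),
                 class = "NeighborGraph")
  emb <- diffusion_map(g, m = 3)
  v <- emb$coordinates[, 1]
  expect_true(all(diff(v) > 0) || all(diff(v) < 0))
  # transition operator: leading eigenvalue 1, all retained below 1
  expect_true(all(emb$eigenvalues[["1"]] < 1))
  expect_error(diffusion_map(g, m = 25), "m")
})

test_that("disconnected graphs are embedded per component without NaN", {
  set.seed(5)
  X <- rbind(matrix(rnorm(300, 0, 0.5), ncol = 3),
             matrix(rnorm(300, 30, 0.5), ncol = 3))
  colnames(X) <- c("a", "b", "c")
  g <- build_knn_graph(X, k = 5)
  emb <- diffusion_map(g, m = 4)
  expect_equal(length(unique(emb$component)), 2)
  expect_true(all(is.finite(emb$coordinates)))
  # pseudotime: cells in the rootless component flagged unreachable
  labels <- rep(c("root", "other"), each = 100)
  pt <- compute_pseudotime(emb, g, "root", labels, seed = 2)
  expect_equal(pt$pseudotime[pt$root], 0)
  expect_true(all(is.na(pt$pseudotime[101:200])))
  expect_true(all(pt$unreachable[101:200]))
  expect_false(any(pt$unreachable[1:100]))
  expect_error(compute_pseudotime(emb, g, "absent", labels), "root")
})

test_that("Leiden separates disconnected cliques and is seed-deterministic", {
  # two disconnected 20-cliques: components can never merge
  n <- 40
  block <- matrix(1, 20, 20) - diag(20)
  A <- Matrix::bdiag(block, block)
  g <- structure(list(adj = methods::as(A, "CsparseMatrix"), k = 19,
                      metric = "euclidean", provenance = "expression-space",
                      n = n), class = "NeighborGraph")
  p1 <- leiden_partition(g, resolution = 1, seed = 42)
  expect_equal(p1$n_clusters, 2)
  expect_equal(length(unique(p1$cluster[1:20])), 1)
  p2 <- leiden_partition(g, resolution = 1, seed = 42)
  expect_identical(p1$cluster, p2$cluster)
})

test_that("cluster connectivity scores match the configuration-model null", {
  set.seed(7)
  # one homogeneous blob randomly split in two: score ~ 1
  X <- matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("x", "y")))
  g <- build_knn_graph(X, k = 10)
  split <- sample(rep(0:1, each = 1000))
  part <- structure(list(cluster = split, n_clusters = 2L, resolution = NA,
                         quality = NA, seed = NA), class = "ClusterPartition")
  cg <- cluster_connectivity(g, part, threshold = 0)
  expect_equal(cg$scores[1, 2], 1, tolerance = 0.2)
  # chain of three interpenetrating clusters A-B-C with no direct A-C edges
  set.seed(11)
  nA <- 60
  blocks <- function(p) matrix(runif(nA * nA) < p, nA, nA)
  Afull <- rbind(cbind(blocks(0.3), blocks(0.15), blocks(0) > 1),
                 cbind(blocks(0) > 1, blocks(0.3), blocks(0.15)),
                 cbind(blocks(0) > 1, blocks(0) > 1, blocks(0.3)))
  Afull <- Afull | t(Afull); diag(Afull) <- FALSE
  gy <- structure(list(adj = methods::as(Matrix::Matrix(Afull * 1, sparse = TRUE),
                                         "CsparseMatrix"),
                       k = 10, metric = "euclidean",
                       provenance = "expression-space", n = 3 * nA),
                  class = "NeighborGraph")
  py <- structure(list(cluster = rep(0:2, each = nA), n_clusters = 3L,
                       resolution = NA, quality = NA, seed = NA),
                  class = "ClusterPartition")
  cgy <- cluster_connectivity(gy, py, threshold = 0.3)
  expect_equal(cgy$scores[1, 3], 0)
  expect_true(cgy$scores[1, 2] > 0.3 && cgy$scores[2, 3] > 0.3)
  edges <- cgy$edges
  expect_false(any(edges$from == 0 & edges$to == 2))
})

test_that("pseudotime tracks latent time on a clean unbranched lineage", {
  # erythroid arm only, zero noise: ordering must be exact up to ties
  lin <- build_default_lineage()
  dyn <- default_marker_dynamics(noise_sd = 0, zero_p = 0)
  be <- identity_batch_effects("B1", dyn$markers)
  sheet <- data.frame(sample_id = "s", batch_id = "B1", tissue = "BM",
                      is_anchor = TRUE)
  sim <- simulate_dataset(lin, dyn, be, 2500, sheet, seed = 3)
  keep <- sim$truth$branch == "Ery"
  ev <- percentile_scale(arcsinh_transform(sim$events))
  pan <- default_panel()
  X <- ev$exprs[keep, pan$channel[pan$erythroid]]
  knn <- build_knn_graph(X, k = 15)
  emb <- diffusion_map(knn, m = 10)
  pt <- compute_pseudotime(emb, knn, "HSC", sim$truth$population[keep], seed = 4)
  rho <- cor(pt$pseudotime, sim$truth$latent_time[keep], method = "spearman")
  expect_gt(abs(rho), 0.98)
  expect_equal(pt$pseudotime[pt$root], 0)
})

test_that("subset re-analysis keeps only allowed, root-connected clusters", {
  fx <- small_processed()
  truth <- fx$sim$truth
  traj <- trajectory_pipeline(fx$events$exprs, resolution = 3,
                              root_population = "HSC",
                              labels = truth$population, seed = 11)
  ann <- majority_labels(traj$partition, truth$population)
  # allowed = everything, full panel: same cell set back
  all_labels <- unique(unname(ann))
  res <- subset_and_reanalyze(fx$events, traj$partition, traj$cluster_graph,
                              ann, allowed_labels = all_labels,
                              channel_subset = channels(fx$events),
                              root_label = "HSC", resolution = 3, seed = 1)
  expect_setequal(res$cells, seq_len(n_events(fx$events)))
  expect_error(subset_and_reanalyze(fx$events, traj$partition, traj$cluster_graph,
                                    ann, allowed_labels = "NotALabel",
                                    channel_subset = channels(fx$events)),
               "allowed")
})
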