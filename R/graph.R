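#' Build a symmetrized knn graph with Gaussian-kernel weights
#'
#' Finds each event's k nearest neighbors, converts distances to affinities
#' with a locally adaptive Gaussian kernel
#' `w_ij = exp(-d_ij^2 / (sigma_i * sigma_j))`, where `sigma_i` is event i's
#' distance to its k-th neighbor, and union-symmetrizes the result
#' (`w = max(w_ij, w_ji)`). Duplicate points (distance 0) get the maximal
#' kernel value 1; self-loops are never created.
#'
#' @param X numeric matrix, events x selected channels (scaled expression or
#'   diffusion coordinates).
#' @param k neighbors per event (default 15).
#' @param metric distance metric; only `"euclidean"` is implemented.
#' @param provenance provenance tag, `"expression-space"` or
#'   `"diffusion-space"`.
#' @return a `NeighborGraph`: sparse symmetric adjacency (`adj`), `k`,
#'   `metric`, `provenance`, `n`.
#' @export
build_knn_graph <- function(X, k = 15, metric = "euclidean",
                            provenance = "expression-space") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k >= n) stop("k (", k, ") must be smaller than the number of events (", n, ")")
  if (k < 1) stop("k must be >= 1")
  if (all(matrixStats::colVars(X) == 0)) stop("zero-variance input")
  if (metric != "euclidean") stop("only the euclidean metric is implemented")
  # tied neighbor distances are expected (duplicate events) and handled by
  # the kernel, so muffle BiocNeighbors' tie warning
  nn <- withCallingHandlers(
    BiocNeighbors::findKNN(X, k = k),
    warning = function(w) {
      if (grepl("tied distances", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  sigma <- nn$distance[, k]
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1)  # duplicate-heavy nodes
  ii <- rep(seq_len(n), k)
  jj <- as.vector(nn$index)
  dd <- as.vector(nn$distance)
  ww <- exp(-dd^2 / (sigma[ii] * sigma[jj]))
  # union symmetrization: the kernel weight is symmetric in (i, j), so when
  # both directions are present their values coincide and keeping either one
  # realizes the elementwise max without densifying
  keep <- ii != jj
  A <- Matrix::sparseMatrix(i = c(ii[keep], jj[keep]),
                            j = c(jj[keep], ii[keep]),
                            x = c(ww[keep], ww[keep]),
                            dims = c(n, n), use.last.ij = TRUE)
  A <- Matrix::drop0(A)
  structure(list(adj = A, k = k, metric = metric, provenance = provenance, n = n),
            class = "NeighborGraph")
}

#' @export
print.NeighborGraph <- function(x, ...) {
  cat(sprintf("NeighborGraph: %d nodes, %d edges (k=%d, %s, %s)\n",
              x$n, Matrix::nnzero(x$adj) / 2, x$k, x$metric, x$provenance))
  invisible(x)
}

graph_components <- function(graph) {
  g <- igraph::graph_from_adjacency_matrix(graph$adj, mode = "undirected",
                                           weighted = TRUE)
  igraph::components(g)$membership
}

#' Diffusion-map embedding of a neighbor graph
#'
#' Row-normalizes the affinity matrix into a Markov transition operator and
#' eigendecomposes its symmetric conjugate `D^-1/2 A D^-1/2`. The trivial
#' leading eigenpair (eigenvalue 1, constant right eigenvector) is dropped
#' and the top `m` nontrivial right eigenvectors, each scaled by its
#' eigenvalue, become the diffusion coordinates. Disconnected graphs are
#' embedded per connected component (each component has its own spectrum);
#' the component labels are returned so downstream stages can confine
#' pseudotime to the root's component.
#'
#' @param graph a `NeighborGraph`.
#' @param m number of diffusion components (default 15).
#' @return a `DiffusionEmbedding`: `coordinates` (n x m), `eigenvalues`
#'   (per component of the graph, a list), `m`, `component` (per-node
#'   component id), `degenerate` (logical: near-tied leading eigenvalues).
#' @export
diffusion_map <- function(graph, m = 15) {
  stopifnot(inherits(graph, "NeighborGraph"))
  n <- graph$n
  if (m >= n) stop("m (", m, ") must be smaller than the number of events (", n, ")")
  comp <- graph_components(graph)
  coords <- matrix(0, n, m)
  evals <- list()
  degenerate <- FALSE
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    nc <- length(idx)
    A <- graph$adj[idx, idx, drop = FALSE]
    if (nc < 3) { evals[[as.character(cid)]] <- numeric(0); next }
    d <- Matrix::rowSums(A)
    d[d == 0] <- 1
    Dhalf <- Matrix::Diagonal(x = 1 / sqrt(d))
    S <- Dhalf %*% A %*% Dhalf
    k_eig <- min(m + 1L, nc - 1L)
    if (nc <= 200) {
      e <- eigen(as.matrix(Matrix::forceSymmetric(S)), symmetric = TRUE)
      vals <- e$values[seq_len(k_eig)]
      vecs <- e$vectors[, seq_len(k_eig), drop = FALSE]
    } else {
      e <- RSpectra::eigs_sym(methods::as(Matrix::forceSymmetric(S), "generalMatrix"),
                              k = k_eig, which = "LA")
      ord <- order(e$values, decreasing = TRUE)
      vals <- e$values[ord]
      vecs <- e$vectors[, ord, drop = FALSE]
    }
    # right eigenvectors of the transition operator; drop the trivial one
    phi <- as.matrix(Dhalf %*% vecs)
    keep <- seq(2L, length(vals))
    lam <- vals[keep]
    phi <- phi[, keep, drop = FALSE]
    # unit-normalize then scale by eigenvalue
    phi <- sweep(phi, 2, sqrt(colSums(phi^2)), "/")
    take <- min(m, ncol(phi))
    if (length(lam) >= 2 && any(abs(diff(lam)) < 1e-12)) degenerate <- TRUE
    coords[idx, seq_len(take)] <- sweep(phi[, seq_len(take), drop = FALSE],
                                        2, lam[seq_len(take)], "*")
    evals[[as.character(cid)]] <- lam[seq_len(take)]
  }
  structure(list(coordinates = coords, eigenvalues = evals, m = m,
                 component = comp, degenerate = degenerate),
            class = "DiffusionEmbedding")
}

#' Leiden community detection on a neighbor graph
#'
#' Runs the Leiden algorithm (modularity objective) on the weighted graph.
#' The shipped default resolution deliberately over-clusters — many more
#' clusters than biological populations — so that fine clusters can later be
#' merged into annotated metaclusters without ever merging distinct
#' populations.
#'
#' @param graph a `NeighborGraph`.
#' @param resolution Leiden resolution (default 10; higher = more
#'   clusters).
#' @param seed RNG seed (Leiden refinement is stochastic).
#' @param n_iterations Leiden iterations (default 3).
#' @return a `ClusterPartition`: `cluster` (0-based contiguous ids),
#'   `n_clusters`, `resolution`, `quality`, `seed`.
#' @export
leiden_partition <- function(graph, resolution = 10, seed = 1, n_iterations = 3) {
  stopifnot(inherits(graph, "NeighborGraph"))
  g <- igraph::graph_from_adjacency_matrix(graph$adj, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               weights = igraph::E(g)$weight,
                               n_iterations = n_iterations)
  memb <- as.integer(igraph::membership(cl))
  memb <- match(memb, sort(unique(memb))) - 1L  # contiguous from 0
  structure(list(cluster = memb, n_clusters = length(unique(memb)),
                 resolution = resolution,
                 quality = igraph::modularity(g, memb + 1L,
                                              weights = igraph::E(g)$weight),
                 seed = seed),
            class = "ClusterPartition")
}

#' @export
print.ClusterPartition <- function(x, ...) {
  cat(sprintf("ClusterPartition: %d clusters over %d nodes (resolution %.2f, seed %d)\n",
              x$n_clusters, length(x$cluster), x$resolution, x$seed))
  invisible(x)
}

#' Cluster-connectivity (partition-graph) scores
#'
#' Coarse-grains the knn graph over a partition: for every cluster pair, the
#' connectivity score is the observed number of inter-cluster edges divided
#' by its expectation under random edge placement proportional to the
#' clusters' degree sums (a configuration-model null),
#' `score_ij = o_ij / (D_i * D_j / (2M))`. A score near 1 means the two
#' clusters are as connected as two random halves of one population; scores
#' below the threshold are dropped for downstream topology but retained in
#' the score matrix.
#'
#' @param graph a `NeighborGraph`.
#' @param partition a `ClusterPartition` over the same nodes.
#' @param threshold retained-edge threshold (default 0.3).
#' @return a `ClusterGraph`: `scores` (clusters x clusters symmetric
#'   matrix), `sizes`, `edges` (data.frame of retained edges), `threshold`.
#' @export
cluster_connectivity <- function(graph, partition, threshold = 0.3) {
  stopifnot(inherits(graph, "NeighborGraph"), inherits(partition, "ClusterPartition"))
  if (length(partition$cluster) != graph$n) stop("partition does not cover graph nodes")
  memb <- partition$cluster
  nc <- partition$n_clusters
  B <- Matrix::sparseMatrix(i = seq_len(graph$n), j = memb + 1L, x = 1,
                            dims = c(graph$n, nc))
  A01 <- graph$adj
  A01@x <- rep(1, length(A01@x))  # edge counts, not weights
  E_blocks <- as.matrix(Matrix::t(B) %*% A01 %*% B)  # 2x intra on diagonal
  deg_sum <- Matrix::rowSums(Matrix::t(B) %*% A01)   # per-cluster degree sum
  M <- sum(A01) / 2
  expected <- outer(deg_sum, deg_sum) / (2 * M)
  scores <- E_blocks / expected
  scores[expected == 0] <- 0
  diag(scores) <- 0
  dimnames(scores) <- list(seq_len(nc) - 1L, seq_len(nc) - 1L)
  ut <- which(upper.tri(scores) & scores >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = ut[, 1] - 1L, to = ut[, 2] - 1L,
                      score = scores[ut])
  structure(list(scores = scores, sizes = as.integer(table(factor(memb, levels = 0:(nc - 1)))),
                 edges = edges, threshold = threshold, n_clusters = nc),
            class = "ClusterGraph")
}

#' @export
print.ClusterGraph <- function(x, ...) {
  cat(sprintf("ClusterGraph: %d clusters, %d retained edges (threshold %.2f)\n",
              x$n_clusters, nrow(x$edges), x$threshold))
  invisible(x)
}

#' Root-anchored diffusion pseudotime
#'
#' Draws the root uniformly at random from the cells carrying the root
#' population label, then assigns each cell the diffusion distance from the
#' root: the Euclidean distance in diffusion coordinates rescaled per
#' component by `lambda / (1 - lambda)`, which weights slowly decaying
#' (large-scale) components most — the standard diffusion-pseudotime
#' construction. Cells in graph components not containing the root are
#' flagged unreachable (`NA` pseudotime), never silently assigned.
#'
#' @param embedding a `DiffusionEmbedding`.
#' @param graph the `NeighborGraph` the embedding came from (for component
#'   structure).
#' @param root_population root label (e.g. `"HSC"`).
#' @param labels per-cell labels the root is drawn from.
#' @param seed root-selection seed.
#' @return a `PseudotimeResult`: `pseudotime` (>= 0, `NA` when
#'   unreachable), `root` (cell index), `unreachable` (logical mask),
#'   `seed`.
#' @export
compute_pseudotime <- function(embedding, graph, root_population, labels, seed = 1) {
  stopifnot(inherits(embedding, "DiffusionEmbedding"))
  candidates <- which(labels == root_population)
  if (!length(candidates)) stop("no cell carries root population '", root_population, "'")
  set.seed(substream_seed(seed, "root"))
  root <- candidates[sample.int(length(candidates), 1L)]
  comp <- embedding$component
  root_comp <- comp[root]
  lam <- embedding$eigenvalues[[as.character(root_comp)]]
  take <- length(lam)
  # coordinates carry one factor of lambda; pseudotime wants lambda/(1-lambda)
  # on unit eigenvectors, i.e. a further 1/(1-lambda) rescale
  scale <- 1 / (1 - pmin(lam, 1 - 1e-12))
  idx <- which(comp == root_comp)
  phi <- sweep(embedding$coordinates[idx, seq_len(take), drop = FALSE], 2, scale, "*")
  root_row <- phi[match(root, idx), ]
  pt <- rep(NA_real_, length(comp))
  pt[idx] <- sqrt(rowSums(sweep(phi, 2, root_row, "-")^2))
  structure(list(pseudotime = pt, root = root, unreachable = comp != root_comp,
                 seed = seed),
            class = "PseudotimeResult")
}

#' @export
print.PseudotimeResult <- function(x, ...) {
  cat(sprintf("PseudotimeResult: root cell %d, %d/%d reachable, range [0, %.3g]\n",
              x$root, sum(!x$unreachable), length(x$pseudotime),
              max(x$pseudotime, na.rm = TRUE)))
  invisible(x)
}

#' Full graph-to-pseudotime pipeline on an expression matrix
#'
#' Convenience wrapper running knn graph, diffusion map, second knn graph in
#' diffusion space, Leiden partition, cluster connectivity, and (optionally)
#' pseudotime in one call.
#'
#' @param X scaled expression matrix (events x channels).
#' @param k neighbors for the diffusion-space knn graph (default 15).
#' @param k_expression neighbors for the expression-space knn graph feeding
#'   the diffusion operator (default 60): the operator needs a wider
#'   neighborhood than the clustering graph to average out channel noise.
#' @param m diffusion components (default 10).
#' @param resolution Leiden resolution (default 10).
#' @param threshold cluster-graph edge threshold (default 0.3).
#' @param root_population,labels when both given, pseudotime is computed.
#' @param seed seed for Leiden and root selection.
#' @return list with `knn`, `embedding`, `knn2`, `partition`,
#'   `cluster_graph`, and `pseudotime` (`NULL` unless a root was given).
#' @export
trajectory_pipeline <- function(X, k = 15, k_expression = 60, m = 10,
                                resolution = 10,
                                threshold = 0.3, root_population = NULL,
                                labels = NULL, seed = 1) {
  knn <- build_knn_graph(X, k = min(k_expression, nrow(X) - 1L))
  emb <- diffusion_map(knn, m = min(m, nrow(X) - 2L))
  knn2 <- build_knn_graph(emb$coordinates, k = min(k, nrow(X) - 1L),
                          provenance = "diffusion-space")
  part <- leiden_partition(knn2, resolution = resolution,
                           seed = substream_seed(seed, "leiden"))
  cg <- cluster_connectivity(knn2, part, threshold = threshold)
  pt <- NULL
  if (!is.null(root_population) && !is.null(labels)) {
    pt <- compute_pseudotime(emb, knn2, root_population, labels, seed = seed)
  }
  list(knn = knn, embedding = emb, knn2 = knn2, partition = part,
       cluster_graph = cg, pseudotime = pt)
}

#' Subset to annotated, graph-connected clusters and re-analyze
#'
#' Reproduces the arm-specific re-analysis: keep only the cells whose
#' cluster is (a) annotated with one of the allowed metacluster labels and
#' (b) in the thresholded cluster-graph connected component containing the
#' root-labeled clusters; then re-run the whole graph/clustering/pseudotime
#' pipeline on a restricted channel panel (only the proteins those cells
#' express).
#'
#' @param events a scaled `EventMatrix` aligned with `partition`.
#' @param partition the full-data `ClusterPartition`.
#' @param cluster_graph the full-data `ClusterGraph`.
#' @param metacluster_labels per-cluster labels (vector indexed by cluster
#'   id + 1, or named by cluster id).
#' @param allowed_labels metacluster labels to keep.
#' @param channel_subset channels for the re-analysis.
#' @param root_label label whose clusters anchor the connected component and
#'   whose cells provide the pseudotime root (default first of
#'   `allowed_labels`).
#' @param k,k_expression,m,resolution,threshold,seed pipeline parameters
#'   (see [trajectory_pipeline()]).
#' @return list: `cells` (kept row indices), `clusters` (kept cluster ids),
#'   and the re-run pipeline components (`knn`, `embedding`, `knn2`,
#'   `partition`, `cluster_graph`, `pseudotime`).
#' @export
subset_and_reanalyze <- function(events, partition, cluster_graph,
                                 metacluster_labels, allowed_labels,
                                 channel_subset, root_label = allowed_labels[1],
                                 k = 15, k_expression = 60, m = 10,
                                 resolution = 10,
                                 threshold = cluster_graph$threshold, seed = 1) {
  stopifnot(inherits(events, "EventMatrix"), inherits(partition, "ClusterPartition"),
            inherits(cluster_graph, "ClusterGraph"), length(allowed_labels) >= 1)
  nc <- partition$n_clusters
  lab <- cluster_label_vector(metacluster_labels, nc)
  allowed <- which(lab %in% allowed_labels) - 1L
  if (!length(allowed)) stop("no clusters carry an allowed label")
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(cluster_graph$edges$from),
               to = as.character(cluster_graph$edges$to)),
    directed = FALSE, vertices = data.frame(name = as.character(0:(nc - 1))))
  g <- igraph::induced_subgraph(g, as.character(allowed))
  comp <- igraph::components(g)$membership
  root_clusters <- as.character(which(lab == root_label) - 1L)
  root_clusters <- intersect(root_clusters, names(comp))
  if (!length(root_clusters)) stop("no allowed cluster carries root label '", root_label, "'")
  keep_comp <- unique(comp[root_clusters])
  keep_clusters <- as.integer(names(comp)[comp %in% keep_comp])
  cells <- which(partition$cluster %in% keep_clusters)
  if (!length(cells)) stop("no cells satisfy both criteria")
  sub <- subset_events(events, events = cells, keep_channels = channel_subset)
  cell_labels <- lab[partition$cluster[cells] + 1L]
  res <- trajectory_pipeline(sub$exprs, k = k, k_expression = k_expression,
                             m = m, resolution = resolution,
                             threshold = threshold, root_population = root_label,
                             labels = cell_labels, seed = seed)
  c(list(cells = cells, clusters = keep_clusters, events = sub,
         cell_labels = cell_labels), res)
}

# normalize a per-cluster label container (named by cluster id, or plain
# vector over 0..nc-1) to a plain vector indexed by cluster id + 1
cluster_label_vector <- function(metacluster_labels, nc) {
  if (!is.null(names(metacluster_labels))) {
    lab <- rep(NA_character_, nc)
    ids <- as.integer(names(metacluster_labels))
    if (any(is.na(ids)) || any(ids < 0)) stop("bad cluster ids in labels")
    keep <- ids < nc  # ids beyond the partition label empty clusters
    lab[ids[keep] + 1L] <- unname(metacluster_labels)[keep]
  } else {
    if (length(metacluster_labels) != nc) stop("label vector must cover all clusters")
    lab <- as.character(metacluster_labels)
  }
  if (anyNA(lab)) stop("unmapped cluster id(s): ",
                       paste(which(is.na(lab)) - 1L, collapse = ", "))
  lab
}
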