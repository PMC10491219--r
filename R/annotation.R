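#' Metacluster annotation map
#'
#' Maps fine-grained over-clustered ids to annotated metacluster labels,
#' and each label to one of the primary lineage groups.
#'
#' @param cluster_to_label named character vector: names are cluster ids
#'   (as characters, 0-based), values are metacluster labels (use
#'   `"unannotated"` for clusters left unassigned).
#' @param label_to_lineage named character vector mapping every label to a
#'   lineage group in `c("early", "lymphoid", "myeloid", "erythroid",
#'   "mature", "unassigned")`; labels missing from the map default to
#'   `"unassigned"`.
#' @return a `MetaclusterMap`.
#' @export
metacluster_map <- function(cluster_to_label, label_to_lineage = NULL) {
  stopifnot(!is.null(names(cluster_to_label)))
  groups <- c("early", "lymphoid", "myeloid", "erythroid", "mature", "unassigned")
  labels <- unique(unname(cluster_to_label))
  if (is.null(label_to_lineage)) {
    label_to_lineage <- stats::setNames(rep("unassigned", length(labels)), labels)
  } else {
    missing <- setdiff(labels, names(label_to_lineage))
    if (length(missing)) {
      label_to_lineage <- c(label_to_lineage,
                            stats::setNames(rep("unassigned", length(missing)), missing))
    }
    bad <- setdiff(unique(label_to_lineage), groups)
    if (length(bad)) stop("unknown lineage group(s): ", paste(bad, collapse = ", "))
  }
  structure(list(cluster_to_label = cluster_to_label,
                 label_to_lineage = label_to_lineage),
            class = "MetaclusterMap")
}

#' Apply a metacluster annotation to a partition
#'
#' Looks up each cell's metacluster label from its cluster id and summarizes
#' the metaclusters: sizes and per-metacluster median marker expression (the
#' input for an annotation heatmap).
#'
#' @param partition a `ClusterPartition`.
#' @param annotation a `MetaclusterMap` covering every cluster id in the
#'   partition.
#' @param exprs optional events x channels matrix for the median-expression
#'   summary.
#' @return list: `labels` (per-cell metacluster label), `sizes` (named
#'   counts), `medians` (labels x channels matrix, or `NULL`).
#' @export
apply_metaclusters <- function(partition, annotation, exprs = NULL) {
  stopifnot(inherits(partition, "ClusterPartition"), inherits(annotation, "MetaclusterMap"))
  lab_by_cluster <- cluster_label_vector(annotation$cluster_to_label,
                                         partition$n_clusters)
  labels <- lab_by_cluster[partition$cluster + 1L]
  sizes <- table(labels)
  medians <- NULL
  if (!is.null(exprs)) {
    exprs <- as.matrix(exprs)
    stopifnot(nrow(exprs) == length(labels))
    uls <- sort(unique(labels))
    medians <- t(vapply(uls, function(l) {
      matrixStats::colMedians(exprs[labels == l, , drop = FALSE])
    }, numeric(ncol(exprs))))
    colnames(medians) <- colnames(exprs)
  }
  list(labels = labels, sizes = sizes, medians = medians)
}

#' Majority-vote metacluster annotation from ground-truth labels
#'
#' On synthetic data (or any data with per-cell reference labels) each
#' cluster is annotated with the most frequent label among its cells —
#' the automated stand-in for manual annotation, used for evaluation.
#'
#' @param partition a `ClusterPartition`.
#' @param truth_labels per-cell labels.
#' @return a named character vector (cluster id -> majority label),
#'   suitable for [metacluster_map()] or [subset_and_reanalyze()].
#' @export
majority_labels <- function(partition, truth_labels) {
  stopifnot(inherits(partition, "ClusterPartition"),
            length(truth_labels) == length(partition$cluster))
  ids <- 0:(partition$n_clusters - 1L)
  out <- vapply(ids, function(cid) {
    tab <- table(truth_labels[partition$cluster == cid])
    if (!length(tab)) "unannotated" else names(tab)[which.max(tab)]
  }, character(1))
  stats::setNames(out, ids)
}

#' Cluster-constrained knn label transfer
#'
#' Transfers reference (e.g. bone-marrow) metacluster labels to query cells
#' from other tissues. Reference and query are first clustered jointly;
#' each query cell may then only vote among reference cells that share its
#' joint Leiden cluster. Query cells in clusters holding fewer than
#' `min_ref` reference cells are labeled `"unannotated"` — this is what
#' prevents spurious annotation of query phenotypes with no analog in the
#' reference. Otherwise the label is a majority vote over the k nearest
#' candidate reference cells (Euclidean distance in scaled expression
#' space); ties go to the label of the single nearest neighbor.
#'
#' @param joint_partition a `ClusterPartition` over reference + query cells.
#' @param X scaled expression matrix over the same cells (voting space).
#' @param is_ref logical: which rows are reference cells.
#' @param ref_labels labels for the reference cells (length `sum(is_ref)`),
#'   frozen from the reference-only analysis.
#' @param k neighbors to vote (default 15).
#' @param min_ref minimum reference cells a cluster needs before its query
#'   cells can be annotated (default `k`).
#' @param loo leave-one-out mode for self-transfer checks: when `TRUE`, the
#'   single nearest zero-distance candidate (the query cell's own reference
#'   copy) is excluded from each vote.
#' @return a `TransferResult` data.frame over query cells: `label`,
#'   `margin` (top-vote fraction, 0 when unannotated), `n_candidates`.
#' @export
constrained_knn_transfer <- function(joint_partition, X, is_ref, ref_labels,
                                     k = 15, min_ref = k, loo = FALSE) {
  stopifnot(inherits(joint_partition, "ClusterPartition"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1) stop("k must be >= 1")
  stopifnot(length(is_ref) == n, length(joint_partition$cluster) == n)
  if (length(ref_labels) != sum(is_ref)) stop("ref_labels must cover all reference cells")
  if (anyNA(ref_labels)) stop("missing reference labels")
  memb <- joint_partition$cluster
  ref_idx <- which(is_ref)
  query_idx <- which(!is_ref)
  nq <- length(query_idx)
  out <- data.frame(label = rep("unannotated", nq),
                    margin = numeric(nq), n_candidates = integer(nq),
                    stringsAsFactors = FALSE)
  for (cid in unique(memb[query_idx])) {
    q <- query_idx[memb[query_idx] == cid]
    cand <- ref_idx[memb[ref_idx] == cid]
    qpos <- match(q, query_idx)
    out$n_candidates[qpos] <- length(cand)
    if (length(cand) < min_ref) next
    kk <- min(k + loo, length(cand))
    nn <- BiocNeighbors::queryKNN(X[cand, , drop = FALSE],
                                  X[q, , drop = FALSE], k = kk)
    cand_labels <- ref_labels[match(cand, ref_idx)]
    for (r in seq_along(q)) {
      take <- seq_len(kk)
      if (loo && nn$distance[r, 1] == 0) take <- take[-1]
      take <- take[seq_len(min(k, length(take)))]
      votes <- cand_labels[nn$index[r, take]]
      kk_used <- length(votes)
      tab <- table(votes)
      top <- max(tab)
      winners <- names(tab)[tab == top]
      lab <- if (length(winners) == 1L) winners else votes[1L]  # nearest wins ties
      out$label[qpos[r]] <- lab
      out$margin[qpos[r]] <- top / kk_used
    }
  }
  class(out) <- c("TransferResult", class(out))
  out
}

#' Sample-by-label composition table
#'
#' @param labels per-cell labels (cluster ids or metacluster labels).
#' @param sample_ids per-cell sample ids.
#' @param lineage_of optional named vector mapping labels to lineage groups;
#'   when given, a lineage-grouped proportion table is also returned.
#' @return list: `proportions` (samples x labels, rows summing to 1),
#'   `counts`, and `lineage_proportions` when `lineage_of` was supplied.
#' @export
composition_table <- function(labels, sample_ids, lineage_of = NULL) {
  stopifnot(length(labels) == length(sample_ids))
  counts <- as.matrix(table(sample_ids, labels))
  proportions <- counts / rowSums(counts)
  out <- list(proportions = proportions, counts = counts)
  if (!is.null(lineage_of)) {
    grp <- unname(lineage_of[colnames(proportions)])
    grp[is.na(grp)] <- "unassigned"
    lp <- t(rowsum(t(proportions), grp))
    out$lineage_proportions <- lp
  }
  out
}

#' Population-level edge recovery of a cluster graph
#'
#' Collapses a thresholded cluster graph to population level using
#' per-cluster majority labels: two populations are connected when any
#' retained cluster-graph edge joins clusters with those (distinct)
#' majority labels. Used to check that the inferred coarse topology
#' recovers the ground-truth lineage tree.
#'
#' @param cluster_graph a `ClusterGraph`.
#' @param cluster_labels per-cluster labels (named by cluster id or plain
#'   vector).
#' @return list: `edges` (data.frame of distinct population pairs, sorted),
#'   and `population_graph` (igraph over the populations).
#' @export
population_graph <- function(cluster_graph, cluster_labels) {
  stopifnot(inherits(cluster_graph, "ClusterGraph"))
  lab <- cluster_label_vector(cluster_labels, cluster_graph$n_clusters)
  e <- cluster_graph$edges
  a <- lab[e$from + 1L]; b <- lab[e$to + 1L]
  keep <- a != b
  pairs <- unique(data.frame(from = pmin(a[keep], b[keep]),
                             to = pmax(a[keep], b[keep]),
                             stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                     vertices = data.frame(name = unique(lab)))
  list(edges = pairs, population_graph = g)
}

#' Compare a population graph against a lineage tree
#'
#' @param pop_edges data.frame of undirected population pairs (`from`,
#'   `to`), e.g. from [population_graph()].
#' @param lineage a `LineageSpec`.
#' @return list: `recovered` / `missing` (lineage edges present/absent in
#'   the population graph) and `spurious` (population-graph edges absent
#'   from the lineage).
#' @export
edge_recovery <- function(pop_edges, lineage) {
  stopifnot(inherits(lineage, "LineageSpec"))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
  truth <- key(lineage$edges$parent, lineage$edges$child)
  got <- if (nrow(pop_edges)) key(pop_edges$from, pop_edges$to) else character(0)
  list(recovered = intersect(truth, got),
       missing = setdiff(truth, got),
       spurious = setdiff(got, truth))
}
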