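#' Branching lineage specification for the synthetic-data generator
#'
#' A `LineageSpec` is a rooted tree of hematopoietic populations. Each
#' population occupies an interval of latent differentiation time in [0, 1]
#' (a child's interval starts at or after its parent's start), and each
#' tissue assigns non-negative sampling weights summing to 1 over the
#' populations, so that different tissues can be enriched for different
#' compartments.
#'
#' @param nodes character vector of population names; the first element that
#'   never appears as a child is the root.
#' @param edges two-column character matrix or data.frame of parent -> child
#'   pairs forming a tree.
#' @param intervals named list (by population) of numeric `c(t_start, t_end)`
#'   latent-time intervals within [0, 1].
#' @param tissue_weights named list (by tissue) of named numeric weight
#'   vectors over the populations; each must be non-negative and sum to 1.
#'
#' @return An object of class `LineageSpec` with elements `nodes`, `edges`
#'   (data.frame with `parent`, `child`), `intervals`, `tissue_weights`,
#'   `root`, and `branches` (named list mapping each root-to-leaf arm to its
#'   ordered population path).
#' @export
lineage_spec <- function(nodes, edges, intervals, tissue_weights) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges) <- c("parent", "child")
  if (!all(c(edges$parent, edges$child) %in% nodes)) {
    stop("edges reference unknown populations")
  }
  if (nrow(edges) != length(nodes) - 1L) {
    stop("edges do not form a tree: expected ", length(nodes) - 1L, " edges")
  }
  if (anyDuplicated(edges$child)) stop("a population has two parents")
  roots <- setdiff(nodes, edges$child)
  if (length(roots) != 1L) stop("tree must have exactly one root, found: ",
                                paste(roots, collapse = ", "))
  root <- roots
  # reachability check (no disconnected cycle components)
  reached <- root
  repeat {
    nxt <- edges$child[edges$parent %in% reached & !(edges$child %in% reached)]
    if (!length(nxt)) break
    reached <- c(reached, nxt)
  }
  if (length(reached) != length(nodes)) stop("edges contain a cycle or disconnected part")

  if (!setequal(names(intervals), nodes)) stop("intervals must cover every population")
  for (nd in nodes) {
    iv <- intervals[[nd]]
    if (length(iv) != 2L || iv[1] < 0 || iv[2] > 1 || iv[1] >= iv[2]) {
      stop("invalid latent-time interval for ", nd)
    }
  }
  for (i in seq_len(nrow(edges))) {
    if (intervals[[edges$child[i]]][1] < intervals[[edges$parent[i]]][1]) {
      stop("child '", edges$child[i], "' starts before its parent")
    }
  }
  for (ts in names(tissue_weights)) {
    w <- tissue_weights[[ts]]
    if (!setequal(names(w), nodes)) stop("tissue '", ts, "' weights must cover every population")
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      stop("tissue '", ts, "' weights must be non-negative and sum to 1")
    }
  }

  # enumerate root-to-leaf paths (the simulator's branches)
  leaves <- setdiff(nodes, edges$parent)
  path_to <- function(nd) {
    path <- nd
    while (nd != root) {
      nd <- edges$parent[edges$child == nd]
      path <- c(nd, path)
    }
    path
  }
  branches <- lapply(leaves, path_to)
  names(branches) <- leaves

  structure(list(nodes = nodes, edges = edges, intervals = intervals,
                 tissue_weights = tissue_weights, root = root,
                 branches = branches),
            class = "LineageSpec")
}

#' @export
print.LineageSpec <- function(x, ...) {
  cat(sprintf("LineageSpec: %d populations, %d edges, root '%s'\n",
              length(x$nodes), nrow(x$edges), x$root))
  for (b in names(x$branches)) {
    cat("  arm -> ", b, ": ", paste(x$branches[[b]], collapse = " > "), "\n", sep = "")
  }
  invisible(x)
}

#' Default two-arm hematopoietic lineage tree
#'
#' The default ground-truth topology: an unbranched erythroid arm
#' HSC > EMP1 > EMP2 > EMP3 > Ery, and a myeloid arm HSC > MPP > MP > MDP
#' that branches at MDP into a plasmacytoid-dendritic arm (pDCP > pDC) and a
#' monocyte/conventional-DC arm terminating in McDP — 11 populations, 10
#' edges. Latent-time intervals tile [0, 1] along each arm. Two tissues are
#' predefined: `BM` (bone marrow, the reference, spread across all
#' compartments) and `mPB` (mobilized peripheral blood, enriched for early
#' HSPCs), plus an `anchor` mixture used for the replicated anchor sample.
#'
#' @param tissues character vector naming which of the built-in tissue
#'   weight sets to keep (default all three).
#' @return a `LineageSpec`.
#' @export
build_default_lineage <- function(tissues = c("BM", "mPB", "anchor")) {
  nodes <- c("HSC", "EMP1", "EMP2", "EMP3", "Ery",
             "MPP", "MP", "MDP", "pDCP", "pDC", "McDP")
  edges <- data.frame(
    parent = c("HSC", "EMP1", "EMP2", "EMP3", "HSC", "MPP", "MP", "MDP", "pDCP", "MDP"),
    child  = c("EMP1", "EMP2", "EMP3", "Ery", "MPP", "MP", "MDP", "pDCP", "pDC", "McDP"),
    stringsAsFactors = FALSE
  )
  intervals <- list(
    HSC  = c(0.00, 0.20),
    EMP1 = c(0.20, 0.40), EMP2 = c(0.40, 0.60), EMP3 = c(0.60, 0.80),
    Ery  = c(0.80, 1.00),
    MPP  = c(0.20, 0.40), MP = c(0.40, 0.55), MDP = c(0.55, 0.70),
    pDCP = c(0.70, 0.85), pDC = c(0.85, 1.00),
    McDP = c(0.70, 1.00)
  )
  # BM spans all compartments; mPB is enriched for early HSPCs; the anchor
  # mixture is fixed so every batch's anchor sample has an identical
  # composition.
  w_bm <- c(HSC = 0.14, EMP1 = 0.10, EMP2 = 0.09, EMP3 = 0.09, Ery = 0.10,
            MPP = 0.12, MP = 0.09, MDP = 0.09, pDCP = 0.06, pDC = 0.06,
            McDP = 0.06)
  w_mpb <- c(HSC = 0.26, EMP1 = 0.08, EMP2 = 0.06, EMP3 = 0.05, Ery = 0.04,
             MPP = 0.22, MP = 0.09, MDP = 0.08, pDCP = 0.04, pDC = 0.04,
             McDP = 0.04)
  w_anchor <- w_bm
  all_w <- list(BM = w_bm, mPB = w_mpb, anchor = w_anchor)
  missing <- setdiff(tissues, names(all_w))
  if (length(missing)) stop("unknown tissue(s): ", paste(missing, collapse = ", "))
  lineage_spec(nodes, edges, intervals, all_w[tissues])
}

#' Population label implied by (branch, latent time)
#'
#' @param lineage a `LineageSpec`.
#' @param branch branch (leaf) name.
#' @param t latent times in [0, 1].
#' @return character vector of population labels along that arm.
#' @export
population_at <- function(lineage, branch, t) {
  path <- lineage$branches[[branch]]
  if (is.null(path)) stop("unknown branch: ", branch)
  out <- character(length(t))
  for (nd in path) {
    iv <- lineage$intervals[[nd]]
    inside <- t >= iv[1] & t <= iv[2] & !nzchar(out)
    out[inside] <- nd
  }
  if (any(!nzchar(out))) stop("latent time outside all intervals on branch ", branch)
  out
}
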