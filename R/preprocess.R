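#' Arcsinh transform raw ion intensities
#'
#' Applies `asinh(x / cofactor)` channel-wise. The hyperbolic arcsine is
#' near-linear around zero and logarithmic for large intensities; the CyTOF
#' convention is a cofactor of 5.
#'
#' @param events an `EventMatrix` with scale tag `"raw"`.
#' @param cofactor positive divisor applied before `asinh` (default 5).
#' @return the transformed `EventMatrix` (scale tag `"arcsinh"`).
#' @export
arcsinh_transform <- function(events, cofactor = 5) {
  stopifnot(inherits(events, "EventMatrix"))
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0) {
    stop("cofactor must be a single positive number")
  }
  if (events$scale != "raw") stop("arcsinh_transform expects raw-scale events, got '",
                                  events$scale, "'")
  out <- events
  out$exprs <- asinh(events$exprs / cofactor)
  out$scale <- "arcsinh"
  out$cofactor <- cofactor
  out
}

#' Scale each channel to a high percentile
#'
#' Divides every channel by its q-th percentile computed over the pooled
#' analysis set, putting markers on a comparable 0..~1 scale before graph
#' construction. Channels whose q-th percentile is zero (e.g. empty
#' channels) are left unchanged with a warning.
#'
#' @param events an `EventMatrix` with scale tag `"arcsinh"`.
#' @param q percentile in (0, 100); default 99.9.
#' @return the scaled `EventMatrix` (scale tag `"scaled"`); the divisors are
#'   attached as attribute-like element `scale_factors`.
#' @export
percentile_scale <- function(events, q = 99.9) {
  stopifnot(inherits(events, "EventMatrix"))
  if (q <= 0 || q >= 100) stop("q must lie in (0, 100)")
  if (events$scale != "arcsinh") {
    stop("percentile_scale expects arcsinh-scale events, got '", events$scale, "'")
  }
  qs <- matrixStats::colQuantiles(events$exprs, probs = q / 100)
  zero <- qs == 0
  if (any(zero)) {
    warning("channel(s) with zero ", q, "th percentile left unscaled: ",
            paste(colnames(events$exprs)[zero], collapse = ", "))
    qs[zero] <- 1
  }
  out <- events
  out$exprs <- sweep(events$exprs, 2, qs, "/")
  out$scale <- "scaled"
  out$scale_factors <- stats::setNames(qs, colnames(events$exprs))
  out
}

#' Define a gate node
#'
#' A gate is a conjunction of axis-aligned interval tests on named
#' (transformed-scale) channels; `polarity = "outside"` inverts the
#' conjunction. Gates are assembled into a rooted tree with
#' [gate_tree()] / [apply_gate_tree()]; membership is hierarchical, so an
#' event belongs to a node only if it also passes every ancestor.
#'
#' @param name gate name.
#' @param parent parent gate name, or `NA` for the root.
#' @param bounds named list of `c(lo, hi)` intervals per channel
#'   (use `-Inf`/`Inf` for one-sided thresholds). A 2-D rectangle is simply
#'   two entries.
#' @param polarity `"inside"` (default) or `"outside"`.
#' @return a `GateNode` list.
#' @export
gate_node <- function(name, parent = NA, bounds, polarity = c("inside", "outside")) {
  polarity <- match.arg(polarity)
  stopifnot(is.list(bounds), length(bounds) >= 1L, !is.null(names(bounds)))
  for (b in bounds) stopifnot(length(b) == 2L, b[1] <= b[2])
  structure(list(name = name, parent = parent, bounds = bounds,
                 polarity = polarity),
            class = "GateNode")
}

#' Assemble gate nodes into a tree
#'
#' @param ... `GateNode` objects (exactly one with `parent = NA`).
#' @return a `GateTree`: the nodes in topological order.
#' @export
gate_tree <- function(...) {
  nodes <- list(...)
  nms <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate gate names")
  names(nodes) <- nms
  parents <- vapply(nodes, function(n) as.character(n$parent), character(1))
  root <- nms[is.na(parents)]
  if (length(root) != 1L) stop("gate tree must have exactly one root")
  bad <- parents[!is.na(parents) & !(parents %in% nms)]
  if (length(bad)) stop("unknown parent gate(s): ", paste(bad, collapse = ", "))
  # topological order: parents before children
  ordered <- root
  while (length(ordered) < length(nms)) {
    nxt <- nms[!nms %in% ordered & parents %in% ordered]
    if (!length(nxt)) stop("gate tree contains a cycle")
    ordered <- c(ordered, nxt)
  }
  structure(nodes[ordered], class = "GateTree")
}

#' Evaluate a hierarchical gating tree
#'
#' @param events an `EventMatrix` on the scale the gate thresholds were
#'   written for (the package convention is arcsinh).
#' @param tree a `GateTree`.
#' @return list with `membership` (events x gates logical matrix, one column
#'   per node, hierarchical: membership in a node implies membership in all
#'   its ancestors) and `leaf_label` (per-event character: the deepest leaf
#'   gate containing the event, or `NA`).
#' @export
apply_gate_tree <- function(events, tree) {
  stopifnot(inherits(events, "EventMatrix"), inherits(tree, "GateTree"))
  X <- events$exprs
  n <- nrow(X)
  membership <- matrix(FALSE, n, length(tree),
                       dimnames = list(NULL, names(tree)))
  for (nm in names(tree)) {
    node <- tree[[nm]]
    miss <- setdiff(names(node$bounds), colnames(X))
    if (length(miss)) stop("gate '", nm, "' references unknown channel(s): ",
                           paste(miss, collapse = ", "))
    inside <- rep(TRUE, n)
    for (ch in names(node$bounds)) {
      b <- node$bounds[[ch]]
      inside <- inside & X[, ch] >= b[1] & X[, ch] <= b[2]
    }
    if (node$polarity == "outside") inside <- !inside
    if (!is.na(node$parent)) inside <- inside & membership[, node$parent]
    membership[, nm] <- inside
  }
  is_leaf <- !(names(tree) %in% vapply(tree, function(n) as.character(n$parent),
                                       character(1)))
  leaves <- names(tree)[is_leaf]
  leaf_label <- rep(NA_character_, n)
  for (lf in leaves) leaf_label[membership[, lf]] <- lf
  list(membership = membership, leaf_label = leaf_label)
}

#' Balanced downsampling across metadata groups
#'
#' Draws a fixed total number of events split as evenly as possible across
#' the groups defined by the given metadata columns (e.g. tissue x donor).
#' Groups smaller than their quota keep all their events and the deficit is
#' redistributed over the remaining groups by iterative water-filling in
#' deterministic (alphabetical group name) order. Sampling is without
#' replacement and reproducible under the seed.
#'
#' @param events an `EventMatrix`.
#' @param group_keys character vector of metadata column names.
#' @param total_n total events to keep.
#' @param seed RNG seed.
#' @return the downsampled `EventMatrix`; the selected row indices (relative
#'   to the input) are attached as element `selected`.
#' @export
downsample_balanced <- function(events, group_keys, total_n, seed = 1) {
  stopifnot(inherits(events, "EventMatrix"), total_n > 0)
  miss <- setdiff(group_keys, names(events$pheno))
  if (length(miss)) stop("unknown metadata column(s): ", paste(miss, collapse = ", "))
  grp <- do.call(paste, c(events$pheno[group_keys], sep = "\r"))
  sizes <- table(grp)
  sizes <- sizes[order(names(sizes))]  # deterministic order
  if (total_n > sum(sizes)) stop("total_n (", total_n, ") exceeds available events (",
                                 sum(sizes), ")")
  quotas <- balanced_quotas(as.integer(sizes), total_n)
  names(quotas) <- names(sizes)
  set.seed(substream_seed(seed, "downsample"))
  keep <- unlist(lapply(names(sizes), function(g) {
    idx <- which(grp == g)
    if (quotas[[g]] >= length(idx)) idx else sort(sample(idx, quotas[[g]]))
  }), use.names = FALSE)
  keep <- sort(keep)
  out <- subset_events(events, events = keep)
  out$selected <- keep
  out
}

# split total_n into per-group quotas: as equal as possible (+/-1), groups
# smaller than their quota capped with the deficit redistributed iteratively
balanced_quotas <- function(sizes, total_n) {
  k <- length(sizes)
  quotas <- integer(k)
  open <- rep(TRUE, k)
  remaining <- total_n
  repeat {
    n_open <- sum(open)
    base <- remaining %/% n_open
    extra <- remaining %% n_open
    # +1 for the first `extra` open groups (deterministic order)
    want <- integer(k)
    want[open] <- base + (seq_len(n_open) <= extra)
    capped <- open & sizes <= want
    if (!any(capped)) {
      quotas[open] <- want[open]
      break
    }
    quotas[capped] <- sizes[capped]
    remaining <- remaining - sum(sizes[capped])
    open <- open & !capped
    if (!any(open)) break
  }
  quotas
}
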