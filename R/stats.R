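#' Bin cells along pseudotime into equal-count bins
#'
#' Cells with finite pseudotime are rank-ordered and split into `B`
#' contiguous bins of equal size (a remainder of `r` cells is spread over
#' the first `r` bins, so bin sizes differ by at most one). Per bin the
#' cell count, mean pseudotime midpoint, and per-marker mean expression are
#' returned — the substrate for trajectory heatmaps and derivative
#' analysis.
#'
#' @param pseudotime a `PseudotimeResult` or a numeric vector.
#' @param X events x markers matrix aligned with the pseudotime.
#' @param B number of bins (default 200).
#' @return a `BinnedTrajectory`: `bin_means` (B x markers), `midpoints`,
#'   `counts`, `B`.
#' @export
bin_pseudotime <- function(pseudotime, X, B = 200) {
  pt <- if (inherits(pseudotime, "PseudotimeResult")) pseudotime$pseudotime else pseudotime
  X <- as.matrix(X)
  stopifnot(length(pt) == nrow(X))
  if (B < 2) stop("B must be >= 2")
  ok <- which(is.finite(pt))
  if (length(ok) < B) stop("fewer cells with finite pseudotime (", length(ok),
                           ") than bins (", B, ")")
  ord <- ok[order(pt[ok])]
  n <- length(ord)
  base <- n %/% B; r <- n %% B
  sizes <- rep(base, B) + (seq_len(B) <= r)
  bin <- rep(seq_len(B), times = sizes)
  midpoints <- as.vector(tapply(pt[ord], bin, mean))
  bin_means <- rowsum(X[ord, , drop = FALSE], bin) / sizes
  structure(list(bin_means = bin_means, midpoints = midpoints,
                 counts = sizes, B = B),
            class = "BinnedTrajectory")
}

#' Expression derivative and inflection points along pseudotime
#'
#' Smooths each marker's bin means with a centered moving average of odd
#' window `w`, takes finite differences against the bin pseudotime
#' midpoints, and smooths the resulting rates with the same window (finite
#' differences amplify bin noise, and the inflection readout needs the
#' smoothed derivative). Reported inflection structure per marker: the bins
#' where the smoothed derivative changes sign, and the bin of maximum
#' absolute derivative within each monotone run (the point of fastest up-
#' or downregulation).
#'
#' @param binned a `BinnedTrajectory`.
#' @param smoothing_window odd window size (default 9); 1 disables
#'   smoothing.
#' @return list: `derivative` ((B-1) x markers matrix of rates at bin
#'   boundaries, midpoint-spaced), `boundary_mid` (pseudotime of each
#'   boundary), `inflections` (named list per marker: `sign_changes`,
#'   `max_rate_bins`), `smoothing_window`.
#' @export
expression_derivative <- function(binned, smoothing_window = 9) {
  stopifnot(inherits(binned, "BinnedTrajectory"))
  B <- binned$B
  if (B < 3) stop("need at least 3 bins")
  w <- smoothing_window
  if (w %% 2 == 0) stop("smoothing window must be odd")
  if (w > B) stop("smoothing window larger than the number of bins")
  M <- as.matrix(binned$bin_means)
  if (w > 1) {
    M <- matrix(apply(M, 2, moving_average, w = w), nrow = B,
                dimnames = dimnames(M))
  }
  dt <- diff(binned$midpoints)
  dt[dt == 0] <- min(dt[dt > 0], 1)  # guard: tied midpoints
  D <- diff(M) / dt
  if (w > 1) {
    # smooth the rate estimate itself: finite differences of bin means are
    # far noisier than the means, and sign-change/extremum detection needs
    # the smoothed derivative
    D <- matrix(apply(D, 2, moving_average, w = w), nrow = B - 1L,
                dimnames = dimnames(D))
  }
  inflections <- lapply(seq_len(ncol(D)), function(j) {
    d <- D[, j]
    sgn <- sign(d)
    nz <- which(sgn != 0)
    sign_changes <- integer(0)
    if (length(nz) >= 2) {
      flips <- which(diff(sgn[nz]) != 0)
      sign_changes <- nz[flips] + 1L  # bin index after the flip
    }
    # bin of max |derivative| within each monotone run
    run_id <- cumsum(c(1L, diff(sgn) != 0))
    max_rate <- vapply(split(seq_along(d), run_id), function(ix) {
      ix[which.max(abs(d[ix]))]
    }, integer(1))
    max_rate <- unname(max_rate[vapply(split(seq_along(d), run_id),
                                       function(ix) any(d[ix] != 0), logical(1))])
    list(sign_changes = sign_changes, max_rate_bins = max_rate)
  })
  names(inflections) <- colnames(D)
  list(derivative = D,
       boundary_mid = (binned$midpoints[-1] + binned$midpoints[-B]) / 2,
       inflections = inflections, smoothing_window = w)
}

moving_average <- function(x, w) {
  half <- (w - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

#' Manhattan-distance sample dissimilarity with hierarchical clustering
#'
#' Computes the pairwise Manhattan (L1) distance between samples on their
#' cluster-proportion vectors, `D(a,b) = sum_c |p_ac - p_bc|`, and
#' hierarchically clusters the resulting distance matrix. Because the data
#' are over-clustered, this metric is sensitive both to shifts in overall
#' composition and to finer within-population expression shifts.
#'
#' @param composition a composition list from [composition_table()] or a
#'   samples x labels proportion matrix with rows summing to 1.
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return a `DistanceMatrix`: `D` (dense symmetric matrix), `dist` (the
#'   `stats::dist` object), `dendrogram` (an `hclust`), `metric`,
#'   `linkage`.
#' @export
sample_dissimilarity <- function(composition, linkage = "average") {
  P <- if (is.list(composition) && !is.null(composition$proportions)) {
    composition$proportions
  } else as.matrix(composition)
  if (nrow(P) < 2) stop("need at least 2 samples")
  if (any(abs(rowSums(P) - 1) > 1e-6)) stop("rows must be proportion vectors summing to 1")
  d <- stats::dist(P, method = "manhattan")
  hc <- stats::hclust(d, method = linkage)
  structure(list(D = as.matrix(d), dist = d, dendrogram = hc,
                 metric = "manhattan", linkage = linkage),
            class = "DistanceMatrix")
}

#' Wilcoxon rank-sum group comparisons with FDR control
#'
#' For each feature, compares the two groups with the Wilcoxon rank-sum
#' test: exact two-sided p-values when both groups have at most
#' `exact_max` samples and the data are tie-free, otherwise the normal
#' approximation with tie correction. The p-values are adjusted across the
#' feature family: a local-FDR estimate (empirical-null on the z-scale)
#' when at least 50 features are tested, Benjamini-Hochberg below that
#' (local FDR is unstable for small families). The method actually used is
#' recorded in the result.
#'
#' @param values samples x features numeric matrix (or data.frame).
#' @param groups length-`nrow(values)` factor/character with exactly two
#'   levels; each group needs >= 2 samples.
#' @param exact_max largest per-group n for the exact test (default 12).
#' @return a `GroupTestResult` data.frame: `feature`, `median_<g1>`,
#'   `median_<g2>`, `statistic` (rank-sum W), `p`, `q`, with attribute
#'   `fdr_method`.
#' @export
compare_groups <- function(values, groups, exact_max = 12) {
  values <- as.matrix(values)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  n1 <- sum(groups == levels(groups)[1]); n2 <- sum(groups == levels(groups)[2])
  if (min(n1, n2) < 2) stop("each group needs at least 2 samples")
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  res <- lapply(seq_len(ncol(values)), function(j) {
    x <- values[groups == g1, j]; y <- values[groups == g2, j]
    if (length(unique(c(x, y))) == 1L) {
      # fully tied: no rank separation at all
      return(c(stat = n1 * n2 / 2, p = 1,
               m1 = stats::median(x), m2 = stats::median(y)))
    }
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- max(n1, n2) <= exact_max && !ties
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    c(stat = unname(wt$statistic), p = wt$p.value,
      m1 = stats::median(x), m2 = stats::median(y))
  })
  res <- do.call(rbind, res)
  p <- pmin(res[, "p"], 1)
  if (length(p) >= 50) {
    q <- local_fdr(p)
    method <- "local-fdr"
  } else {
    q <- stats::p.adjust(p, method = "BH")
    method <- "BH"
  }
  out <- data.frame(feature = colnames(values) %||% seq_len(ncol(values)),
                    stringsAsFactors = FALSE)
  out[[paste0("median_", g1)]] <- res[, "m1"]
  out[[paste0("median_", g2)]] <- res[, "m2"]
  out$statistic <- res[, "stat"]
  out$p <- p
  out$q <- q
  attr(out, "fdr_method") <- method
  class(out) <- c("GroupTestResult", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Local FDR via empirical-null density estimation on the probit scale:
# z = qnorm(p); the mixture density f(z) is estimated by a Gaussian kernel,
# the null component is pi0 * N(0,1) with pi0 from the conservative share of
# p-values above 0.5; lfdr = min(1, pi0 * f0 / f), monotonized in p.
local_fdr <- function(p) {
  eps <- 1e-15
  z <- stats::qnorm(pmin(pmax(p, eps), 1 - eps))
  pi0 <- min(1, 2 * mean(p > 0.5))
  dens <- stats::density(z, n = 512)
  f <- stats::approx(dens$x, dens$y, xout = z, rule = 2)$y
  f <- pmax(f, 1e-12)
  lfdr <- pmin(1, pi0 * stats::dnorm(z) / f)
  # enforce monotone non-decreasing lfdr in p
  ord <- order(p)
  lfdr[ord] <- cummax(lfdr[ord])
  lfdr
}

#' Percent-positive summaries per sample
#'
#' For each sample and marker, the percentage of subset cells whose scaled
#' expression exceeds the marker's positivity threshold. Samples whose
#' subset is empty are reported as missing (`NA`), with a warning — never
#' as zero.
#'
#' @param X events x markers matrix (scaled expression).
#' @param sample_ids per-event sample ids.
#' @param subset logical mask of cells to consider (e.g. a gate), default
#'   all.
#' @param thresholds named per-marker thresholds; defaults to the 95th
#'   percentile of each marker's pooled distribution.
#' @return samples x markers matrix of percentages (0-100, `NA` for empty
#'   subsets).
#' @export
percent_positive <- function(X, sample_ids, subset = NULL, thresholds = NULL) {
  X <- as.matrix(X)
  stopifnot(length(sample_ids) == nrow(X))
  if (is.null(subset)) subset <- rep(TRUE, nrow(X))
  if (is.null(thresholds)) {
    thresholds <- matrixStats::colQuantiles(X[subset, , drop = FALSE], probs = 0.95)
    names(thresholds) <- colnames(X)
  }
  miss <- setdiff(colnames(X), names(thresholds))
  if (length(miss)) stop("missing threshold(s) for: ", paste(miss, collapse = ", "))
  samples <- sort(unique(sample_ids))
  out <- matrix(NA_real_, length(samples), ncol(X),
                dimnames = list(samples, colnames(X)))
  for (s in samples) {
    rows <- subset & sample_ids == s
    if (!any(rows)) {
      warning("sample '", s, "' has an empty subset; reported as missing")
      next
    }
    out[s, ] <- 100 * colMeans(sweep(X[rows, , drop = FALSE], 2,
                                     thresholds[colnames(X)], ">"))
  }
  out
}
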