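#' Fit the anchor-sample batch-correction transform
#'
#' One biological anchor (common) sample is acquired in every batch; because
#' the underlying cells are identical, any cross-batch difference in the
#' anchor's per-channel distributions is a batch effect. The transform fitted
#' here, per channel:
#' \enumerate{
#'   \item target median = minimum anchor median across batches; each
#'     batch's shift `delta = anchor median - target` is subtracted, moving
#'     distributions downward onto identical medians;
#'   \item values pushed below zero by the shift are later resampled from a
#'     half-normal noise floor with SD `sigma`, estimated per (batch,
#'     channel) as the SD of the anchor's sub-median values reflected about
#'     the median (a robust noise-floor proxy);
#'   \item target 99.8th percentile = minimum post-shift anchor 99.8th
#'     percentile across batches; each batch is multiplicatively rescaled
#'     down to it.
#' }
#' The anchor-derived transform is then applied to every sample of the batch
#' with [apply_anchor_transform()].
#'
#' @param anchors an `EventMatrix` (arcsinh scale) containing only anchor
#'   events, with `batch_id` metadata — exactly one anchor sample per batch.
#' @param percentile upper alignment percentile (default 99.8).
#' @return an `AnchorTransform`: per (batch, channel) matrices `delta`,
#'   `sigma`, `p_obs` (post-shift observed percentile), and per-channel
#'   vectors `target_median`, `p_target`.
#' @export
fit_anchor_transform <- function(anchors, percentile = 99.8) {
  stopifnot(inherits(anchors, "EventMatrix"))
  if (anchors$scale != "arcsinh") {
    stop("anchor correction is fitted on arcsinh-scale data, got '", anchors$scale, "'")
  }
  ph <- anchors$pheno
  if (!"batch_id" %in% names(ph)) stop("anchors need 'batch_id' metadata")
  per_batch <- table(unique(ph[c("sample_id", "batch_id")])$batch_id)
  if (any(per_batch != 1)) {
    stop("exactly one anchor sample per batch required; got: ",
         paste(names(per_batch), per_batch, sep = "=", collapse = ", "))
  }
  batches <- sort(unique(ph$batch_id))
  chs <- colnames(anchors$exprs)
  med <- sig <- p_obs <- matrix(NA_real_, length(batches), length(chs),
                                dimnames = list(batches, chs))
  for (b in batches) {
    X <- anchors$exprs[ph$batch_id == b, , drop = FALSE]
    med[b, ] <- matrixStats::colMedians(X)
    for (j in seq_along(chs)) {
      below <- X[, j][X[, j] < med[b, j]]
      # reflect sub-median spread about the median: SD of deviations
      sig[b, j] <- if (length(below) >= 2L) sqrt(mean((below - med[b, j])^2)) else 0
    }
  }
  target_median <- matrixStats::colMins(med)
  delta <- sweep(med, 2, target_median, "-")
  for (b in batches) {
    X <- sweep(anchors$exprs[ph$batch_id == b, , drop = FALSE], 2, delta[b, ], "-")
    p_obs[b, ] <- matrixStats::colQuantiles(X, probs = percentile / 100)
  }
  p_target <- matrixStats::colMins(p_obs)
  structure(list(delta = delta, sigma = sig, p_obs = p_obs,
                 target_median = target_median, p_target = p_target,
                 percentile = percentile, batches = batches, channels = chs),
            class = "AnchorTransform")
}

#' @export
print.AnchorTransform <- function(x, ...) {
  cat(sprintf("AnchorTransform: %d batches x %d channels (%.1fth percentile)\n",
              length(x$batches), length(x$channels), x$percentile))
  cat(sprintf("  median shift range: [%.3g, %.3g]\n", min(x$delta), max(x$delta)))
  invisible(x)
}

#' Apply an anchor-derived batch correction to all events
#'
#' Per channel and batch: (1) subtract the batch's median shift `delta`;
#' (2) replace every resulting negative value by the absolute value of a
#' draw from `N(0, sigma^2)` — aligning it with the channel's noise floor;
#' (3) rescale multiplicatively by `p_target / p_obs` so the batch's upper
#' percentile matches the cross-batch target. The resampling RNG stream is
#' keyed by (batch, channel), so applying the correction batch-by-batch or
#' to the pooled matrix gives identical results.
#'
#' @param events an `EventMatrix` (arcsinh scale) with `batch_id` metadata.
#' @param transform an `AnchorTransform` covering every batch present.
#' @param seed integer seed for the negative-resampling streams.
#' @return the corrected `EventMatrix` (scale unchanged: `"arcsinh"`); no
#'   negative values remain. The per-event resampling indicator count is
#'   attached as element `n_resampled` (per channel).
#' @export
apply_anchor_transform <- function(events, transform, seed = 1) {
  stopifnot(inherits(events, "EventMatrix"), inherits(transform, "AnchorTransform"))
  if (events$scale != "arcsinh") {
    stop("anchor correction applies to arcsinh-scale data, got '", events$scale, "'")
  }
  ph <- events$pheno
  bad <- setdiff(unique(ph$batch_id), transform$batches)
  if (length(bad)) stop("batch(es) not in transform: ", paste(bad, collapse = ", "))
  chs <- transform$channels
  if (!all(chs %in% colnames(events$exprs))) stop("channel mismatch with transform")
  X <- events$exprs[, chs, drop = FALSE]
  n_resampled <- stats::setNames(integer(length(chs)), chs)
  for (b in intersect(transform$batches, unique(ph$batch_id))) {
    rows <- which(ph$batch_id == b)
    for (j in seq_along(chs)) {
      v <- X[rows, j] - transform$delta[b, j]
      neg <- which(v < 0)
      if (length(neg)) {
        s <- transform$sigma[b, j]
        if (s == 0 && transform$delta[b, j] > 0) {
          # degenerate anchor (no sub-median spread): clamp to the floor
          v[neg] <- 0
        } else {
          set.seed(substream_seed(seed, paste0("resample:", b, ":", chs[j])))
          v[neg] <- abs(stats::rnorm(length(neg), 0, s))
        }
        n_resampled[j] <- n_resampled[j] + length(neg)
      }
      ratio <- transform$p_target[j] / transform$p_obs[b, j]
      if (!is.finite(ratio) || transform$p_obs[b, j] <= 0) ratio <- 1
      X[rows, j] <- v * ratio
    }
  }
  out <- events
  out$exprs[, chs] <- X
  out$n_resampled <- n_resampled
  out
}

#' Batch-correction QC report
#'
#' Summarizes, per (batch, channel), the anchor's median and upper
#' percentile before and after correction, plus the maximum cross-batch
#' anchor-median spread per channel before and after — the headline number
#' for how much batch effect the correction removed.
#'
#' @param before,after `EventMatrix` objects (arcsinh scale) with matched
#'   channels and `batch_id`/`is_anchor` metadata.
#' @param percentile upper percentile to report (default 99.8).
#' @return list with `per_batch` (data.frame: batch, channel, median/upper
#'   percentile before and after) and `spread` (data.frame per channel:
#'   max cross-batch anchor-median spread before/after and their ratio).
#' @export
correction_report <- function(before, after, percentile = 99.8) {
  stopifnot(inherits(before, "EventMatrix"), inherits(after, "EventMatrix"),
            identical(colnames(before$exprs), colnames(after$exprs)))
  chs <- colnames(before$exprs)
  summarize <- function(ev) {
    ph <- ev$pheno
    sel <- if ("is_anchor" %in% names(ph)) ph$is_anchor else rep(TRUE, nrow(ph))
    batches <- sort(unique(ph$batch_id[sel]))
    med <- up <- matrix(NA_real_, length(batches), length(chs),
                        dimnames = list(batches, chs))
    for (b in batches) {
      X <- ev$exprs[sel & ph$batch_id == b, , drop = FALSE]
      med[b, ] <- matrixStats::colMedians(X)
      up[b, ] <- matrixStats::colQuantiles(X, probs = percentile / 100)
    }
    list(med = med, up = up, batches = batches)
  }
  sb <- summarize(before); sa <- summarize(after)
  per_batch <- do.call(rbind, lapply(sb$batches, function(b) {
    data.frame(batch = b, channel = chs,
               median_before = sb$med[b, ], median_after = sa$med[b, ],
               upper_before = sb$up[b, ], upper_after = sa$up[b, ],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  spread_b <- matrixStats::colMaxs(sb$med) - matrixStats::colMins(sb$med)
  spread_a <- matrixStats::colMaxs(sa$med) - matrixStats::colMins(sa$med)
  spread <- data.frame(channel = chs, spread_before = spread_b,
                       spread_after = spread_a,
                       reduction = ifelse(spread_a > 0, spread_b / spread_a, Inf),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(per_batch = per_batch, spread = spread, percentile = percentile)
}
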