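#' Event matrix: the substrate of every pipeline stage
#'
#' An `EventMatrix` couples an events x channels expression matrix with
#' per-event metadata (sample, batch, tissue, anchor flag, optional
#' ground-truth columns) and a scale tag recording which transforms have been
#' applied (`"raw"`, `"arcsinh"`, or `"scaled"`). Every transform in the
#' package updates the tag, and stages check it so that, e.g., percentile
#' scaling cannot be applied to raw ion counts.
#'
#' @param exprs numeric matrix, events x channels, with unique non-empty
#'   column names and no `NA`/`Inf` values.
#' @param pheno data.frame of per-event metadata with one row per event.
#'   Must contain a `sample_id` column; `batch_id`, `tissue` and `is_anchor`
#'   are expected by the batch-correction and transfer stages.
#' @param scale scale tag, one of `"raw"`, `"arcsinh"`, `"scaled"`.
#'
#' @return An object of class `EventMatrix`: a list with elements `exprs`,
#'   `pheno` and `scale`.
#' @export
event_matrix <- function(exprs, pheno, scale = c("raw", "arcsinh", "scaled")) {
  scale <- match.arg(scale)
  exprs <- as.matrix(exprs)
  if (is.null(colnames(exprs)) || anyDuplicated(colnames(exprs)) ||
      any(!nzchar(colnames(exprs)))) {
    stop("'exprs' must have unique, non-empty channel (column) names")
  }
  if (!is.numeric(exprs)) stop("'exprs' must be numeric")
  if (any(!is.finite(exprs))) stop("'exprs' contains NA/NaN/Inf values")
  pheno <- as.data.frame(pheno, stringsAsFactors = FALSE)
  if (nrow(pheno) != nrow(exprs)) {
    stop("metadata row count (", nrow(pheno), ") != event count (", nrow(exprs), ")")
  }
  if (!"sample_id" %in% names(pheno)) stop("'pheno' must contain a 'sample_id' column")
  structure(list(exprs = exprs, pheno = pheno, scale = scale),
            class = "EventMatrix")
}

#' @export
print.EventMatrix <- function(x, ...) {
  cat(sprintf("EventMatrix: %d events x %d channels [scale: %s]\n",
              nrow(x$exprs), ncol(x$exprs), x$scale))
  cat(sprintf("  samples: %d  (%s%s)\n", length(unique(x$pheno$sample_id)),
              paste(utils::head(unique(x$pheno$sample_id), 4), collapse = ", "),
              if (length(unique(x$pheno$sample_id)) > 4) ", ..." else ""))
  if (!is.null(x$pheno$batch_id)) {
    cat(sprintf("  batches: %s\n", paste(unique(x$pheno$batch_id), collapse = ", ")))
  }
  cat(sprintf("  channels: %s%s\n",
              paste(utils::head(colnames(x$exprs), 6), collapse = ", "),
              if (ncol(x$exprs) > 6) ", ..." else ""))
  invisible(x)
}

#' Number of events in an EventMatrix
#' @param x an `EventMatrix`.
#' @return integer event count.
#' @export
n_events <- function(x) {
  stopifnot(inherits(x, "EventMatrix"))
  nrow(x$exprs)
}

#' Channel names of an EventMatrix
#' @param x an `EventMatrix`.
#' @return character vector of channel names.
#' @export
channels <- function(x) {
  stopifnot(inherits(x, "EventMatrix"))
  colnames(x$exprs)
}

#' Subset an EventMatrix by events and/or channels
#'
#' @param x an `EventMatrix`.
#' @param events integer or logical index over events (rows).
#' @param keep_channels character vector of channel names to retain.
#' @return the subsetted `EventMatrix` (scale tag preserved).
#' @export
subset_events <- function(x, events = NULL, keep_channels = NULL) {
  stopifnot(inherits(x, "EventMatrix"))
  ex <- x$exprs
  ph <- x$pheno
  if (!is.null(events)) {
    ex <- ex[events, , drop = FALSE]
    ph <- ph[events, , drop = FALSE]
    rownames(ph) <- NULL
  }
  if (!is.null(keep_channels)) {
    missing <- setdiff(keep_channels, colnames(ex))
    if (length(missing)) stop("unknown channel(s): ", paste(missing, collapse = ", "))
    ex <- ex[, keep_channels, drop = FALSE]
  }
  event_matrix(ex, ph, scale = x$scale)
}

# Deterministic substream seed derived from a master seed and a string key.
# Keeps seeds in [0, 2^31): a multiplicative string hash folded into the
# master seed, so parallel per-(batch, channel) streams are reproducible and
# independent of iteration order.
substream_seed <- function(seed, key) {
  h <- 0
  for (cp in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}
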