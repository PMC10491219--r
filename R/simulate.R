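#' Per-batch channel distortion specification
#'
#' Models the acquisition-level batch effects that anchor-sample correction
#' removes: on the raw (pre-arcsinh) scale each (batch, channel) pair has a
#' multiplicative gain `g > 0`, an additive shift `d`, and a Gaussian noise
#' floor with SD `floor_sd >= 0`. The first batch is the reference and must
#' be the identity (`g = 1`, `d = 0`).
#'
#' @param gains batches x channels numeric matrix of strictly positive
#'   gains; rownames are batch ids, colnames channel names.
#' @param shifts batches x channels numeric matrix of additive shifts.
#' @param floor_sd non-negative noise-floor SD, recycled to one value per
#'   batch.
#' @return an object of class `BatchEffectSpec`.
#' @export
batch_effect_spec <- function(gains, shifts, floor_sd = 0) {
  gains <- as.matrix(gains); shifts <- as.matrix(shifts)
  stopifnot(identical(dim(gains), dim(shifts)),
            identical(rownames(gains), rownames(shifts)),
            identical(colnames(gains), colnames(shifts)))
  if (is.null(rownames(gains)) || is.null(colnames(gains))) {
    stop("gains/shifts need batch rownames and channel colnames")
  }
  if (any(gains <= 0)) stop("gains must be strictly positive")
  if (any(gains[1, ] != 1) || any(shifts[1, ] != 0)) {
    stop("reference batch (first row) must have gain 1 and shift 0")
  }
  floor_sd <- rep_len(floor_sd, nrow(gains))
  if (any(floor_sd < 0)) stop("floor_sd must be >= 0")
  names(floor_sd) <- rownames(gains)
  structure(list(gains = gains, shifts = shifts, floor_sd = floor_sd,
                 batches = rownames(gains)),
            class = "BatchEffectSpec")
}

#' Identity batch-effect specification
#' @param batch_ids batch names.
#' @param channel_names channel names.
#' @return a `BatchEffectSpec` with all gains 1, shifts 0, noise floor 0.
#' @export
identity_batch_effects <- function(batch_ids, channel_names) {
  g <- matrix(1, length(batch_ids), length(channel_names),
              dimnames = list(batch_ids, channel_names))
  batch_effect_spec(g, g * 0, floor_sd = 0)
}

#' Per-channel reference median raw signal
#'
#' Median of the raw-scale (pre-arcsinh) mean signal over latent time and
#' lineage arms — the anchor for scaling channel-relative quantities such as
#' additive batch shifts.
#'
#' @param dynamics a `MarkerDynamics`.
#' @return named numeric vector, one value per marker.
#' @export
reference_channel_medians <- function(dynamics) {
  tt <- seq(0.005, 0.995, length.out = 100)
  branches <- unique(dynamics$curves$branch)
  vapply(dynamics$markers, function(mk) {
    mu <- unlist(lapply(branches, function(br) marker_mean(dynamics, mk, br, tt)))
    stats::median(5 * sinh(pmax(mu, 0)))
  }, numeric(1))
}

#' Random batch-effect specification
#'
#' Draws per-(batch, channel) gains uniformly from `gain_range` and additive
#' shifts uniformly from `[0, shift_frac * median raw signal]` of each
#' channel (so a dim channel is never swamped by a shift larger than its own
#' signal), leaving the first batch as the identity reference.
#'
#' @param batch_ids batch names; the first is the reference.
#' @param dynamics a `MarkerDynamics` (defines the channels and their
#'   reference medians).
#' @param seed RNG seed.
#' @param gain_range length-2 gain interval (default `c(0.7, 1.4)`).
#' @param shift_frac maximum additive shift as a fraction of the channel's
#'   median raw signal (default 0.1).
#' @param floor_sd per-batch raw-scale noise-floor SD (default 0.1).
#' @return a `BatchEffectSpec`.
#' @export
random_batch_effects <- function(batch_ids, dynamics, seed = 1,
                                 gain_range = c(0.7, 1.4), shift_frac = 0.1,
                                 floor_sd = 0.1) {
  stopifnot(inherits(dynamics, "MarkerDynamics"))
  channel_names <- dynamics$markers
  shift_max <- shift_frac * reference_channel_medians(dynamics)
  nb <- length(batch_ids); nc <- length(channel_names)
  set.seed(substream_seed(seed, "batch-effects"))
  g <- matrix(stats::runif(nb * nc, gain_range[1], gain_range[2]), nb, nc,
              dimnames = list(batch_ids, channel_names))
  d <- matrix(stats::runif(nb * nc) * rep(shift_max, each = nb), nb, nc,
              dimnames = list(batch_ids, channel_names))
  g[1, ] <- 1; d[1, ] <- 0
  batch_effect_spec(g, d, floor_sd = floor_sd)
}

#' Simulate a multi-batch, multi-tissue CyTOF-like dataset
#'
#' Generates raw-scale (pre-arcsinh) event intensities over a branching
#' lineage with known ground truth. For each event: a population is drawn
#' from its sample's tissue weights, a lineage arm containing that
#' population is chosen, latent time is drawn uniformly over the
#' population's interval, the arcsinh-scale logistic mean `mu(t)` is
#' perturbed by Gaussian noise and mapped to the raw scale through
#' `5 * sinh(.)` (log-normal-like, non-negative signal), zero-inflation is
#' applied, and finally the batch distortion
#' `max(0, g * (signal + floor noise) + d)` is imposed. Anchor samples use
#' the dedicated `"anchor"` tissue mixture when the lineage defines one, so
#' anchors in different batches share an identical composition and differ
#' only by batch effects and sampling noise.
#'
#' @param lineage a `LineageSpec`.
#' @param dynamics a `MarkerDynamics` whose branches match the lineage arms.
#' @param batches a `BatchEffectSpec` covering every batch in `samples`.
#' @param n_events_per_sample events per sample (positive integer).
#' @param samples data.frame with columns `sample_id`, `batch_id`, `tissue`,
#'   `is_anchor` (logical); exactly one anchor per batch.
#' @param seed integer master seed; each sample gets a deterministic
#'   substream, so per-sample generation is order-independent.
#'
#' @return list with `events` (an `EventMatrix`, scale `"raw"`, channels =
#'   dynamics markers) and `truth` (data.frame: `latent_time`, `branch`,
#'   `population`, plus the sample metadata, aligned row-for-row).
#' @export
simulate_dataset <- function(lineage, dynamics, batches, n_events_per_sample,
                             samples, seed = 1) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "batch_id", "tissue", "is_anchor") %in% names(samples)))
  if (n_events_per_sample <= 0) stop("n_events_per_sample must be positive")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  bad_tissue <- setdiff(samples$tissue[!samples$is_anchor],
                        names(lineage$tissue_weights))
  if (length(bad_tissue)) stop("unknown tissue(s): ", paste(bad_tissue, collapse = ", "))
  bad_batch <- setdiff(samples$batch_id, batches$batches)
  if (length(bad_batch)) stop("batch(es) missing from BatchEffectSpec: ",
                              paste(bad_batch, collapse = ", "))
  anchors_per_batch <- tapply(samples$is_anchor, samples$batch_id, sum)
  if (any(anchors_per_batch != 1)) {
    stop("each batch needs exactly one anchor sample; counts: ",
         paste(names(anchors_per_batch), anchors_per_batch, sep = "=", collapse = ", "))
  }
  if (!setequal(unique(dynamics$curves$branch), names(lineage$branches))) {
    stop("dynamics branches must match lineage arms")
  }

  markers <- dynamics$markers
  # arms containing each population, for branch assignment of trunk cells
  arms_of <- lapply(lineage$nodes, function(nd) {
    names(Filter(function(p) nd %in% p, lineage$branches))
  })
  names(arms_of) <- lineage$nodes
  anchor_tissue <- if ("anchor" %in% names(lineage$tissue_weights)) "anchor" else NULL

  per_sample <- lapply(seq_len(nrow(samples)), function(i) {
    sm <- samples[i, ]
    set.seed(substream_seed(seed, paste0("sample:", sm$sample_id)))
    n <- n_events_per_sample
    w_tissue <- if (isTRUE(sm$is_anchor) && !is.null(anchor_tissue)) anchor_tissue else sm$tissue
    w <- lineage$tissue_weights[[w_tissue]][lineage$nodes]
    pop <- sample(lineage$nodes, n, replace = TRUE, prob = w)
    branch <- vapply(pop, function(p) {
      a <- arms_of[[p]]
      if (length(a) == 1L) a else a[sample.int(length(a), 1L)]
    }, character(1), USE.NAMES = FALSE)
    lo <- vapply(pop, function(p) lineage$intervals[[p]][1], numeric(1), USE.NAMES = FALSE)
    hi <- vapply(pop, function(p) lineage$intervals[[p]][2], numeric(1), USE.NAMES = FALSE)
    t <- stats::runif(n, lo, hi)

    g <- batches$gains[sm$batch_id, markers]
    d <- batches$shifts[sm$batch_id, markers]
    fl <- batches$floor_sd[[sm$batch_id]]
    X <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
    truthX <- X  # clean pre-distortion raw signal, kept for evaluation
    for (j in seq_along(markers)) {
      mk <- markers[j]
      nz <- dynamics$noise[dynamics$noise$marker == mk, ]
      mu <- numeric(n)
      for (br in unique(branch)) {
        row <- dynamics$curves[dynamics$curves$marker == mk &
                               dynamics$curves$branch == br, ]
        sel <- branch == br
        mu[sel] <- logistic_mu(row$b, row$a, row$t0, row$s, t[sel])
      }
      v <- mu
      if (nz$noise_sd > 0) v <- v + stats::rnorm(n, 0, nz$noise_sd)
      sig <- 5 * sinh(v)
      if (nz$zero_p > 0) sig[stats::runif(n) < nz$zero_p] <- 0
      truthX[, j] <- pmax(0, sig)
      noise_fl <- if (fl > 0) stats::rnorm(n, 0, fl) else 0
      X[, j] <- pmax(0, g[j] * (sig + noise_fl) + d[j])
    }
    list(X = X, truthX = truthX,
         truth = data.frame(latent_time = t, branch = branch, population = pop,
                            sample_id = sm$sample_id, batch_id = sm$batch_id,
                            tissue = sm$tissue, is_anchor = sm$is_anchor,
                            stringsAsFactors = FALSE))
  })

  X <- do.call(rbind, lapply(per_sample, `[[`, "X"))
  truth <- do.call(rbind, lapply(per_sample, `[[`, "truth"))
  rownames(truth) <- NULL
  pheno <- truth[, c("sample_id", "batch_id", "tissue", "is_anchor",
                     "population", "branch", "latent_time")]
  ev <- event_matrix(X, pheno, scale = "raw")
  ev$truth_signal <- do.call(rbind, lapply(per_sample, `[[`, "truthX"))
  list(events = ev, truth = truth)
}

#' Standard sample-metadata sheet for simulations
#'
#' Convenience builder: `n_per` study samples of each tissue per batch plus
#' one anchor sample per batch.
#'
#' @param batch_ids batch names.
#' @param tissues tissue names for study samples.
#' @param n_per study samples per (batch, tissue).
#' @return data.frame with `sample_id`, `batch_id`, `tissue`, `is_anchor`.
#' @export
make_sample_sheet <- function(batch_ids, tissues = "BM", n_per = 1) {
  rows <- list()
  for (b in batch_ids) {
    for (ts in tissues) {
      for (k in seq_len(n_per)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_s%d", b, ts, k), batch_id = b,
          tissue = ts, is_anchor = FALSE, stringsAsFactors = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("%s_anchor", b), batch_id = b,
      tissue = tissues[1], is_anchor = TRUE, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
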