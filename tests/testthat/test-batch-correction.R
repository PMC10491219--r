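# anchors with prescribed per-batch medians, normal spread
anchor_fixture <- function(medians, n = 4000, sd = 0.4, channel = "CD34") {
  set.seed(31)
  X <- matrix(unlist(lapply(medians, function(m) rnorm(n, m, sd))), ncol = 1,
              dimnames = list(NULL, channel))
  ph <- data.frame(sample_id = paste0("anchor", seq_along(medians)),
                   batch_id = names(medians),
                   is_anchor = TRUE)[rep(seq_along(medians), each = n), ]
  event_matrix(pmax(X, 0), ph, scale = "arcsinh")
}

test_that("median shifts equal anchor median minus the cross-batch minimum", {
  anchors <- anchor_fixture(c(B1 = 1.5, B2 = 2.0, B3 = 1.8))
  tf <- fit_anchor_transform(anchors)
  med <- tapply(anchors$exprs[, 1], anchors$pheno$batch_id, median)
  expect_equal(unname(tf$delta[, 1]), as.numeric(med - min(med)))
  expect_equal(tf$delta[which.min(med), 1], 0)
  # rough magnitudes follow the construction
  expect_equal(unname(tf$delta["B2", 1]), 0.5, tolerance = 0.05)
  expect_equal(unname(tf$delta["B3", 1]), 0.3, tolerance = 0.05)
  # post-shift anchor medians identical across batches (exact)
  shifted <- anchors$exprs[, 1] - tf$delta[anchors$pheno$batch_id, 1]
  expect_equal(diff(range(tapply(shifted, anchors$pheno$batch_id, median))), 0)
})

test_that("a single batch or identical anchors yield the identity transform", {
  one <- anchor_fixture(c(B1 = 1.5))
  tf1 <- fit_anchor_transform(one)
  expect_equal(unname(tf1$delta[, 1]), 0)
  expect_equal(unname(tf1$p_obs[, 1]), unname(tf1$p_target))
  ident <- anchor_fixture(c(B1 = 1.7, B2 = 1.7, B3 = 1.7))
  # same generative median: deltas are the sampling noise of the median only
  tf2 <- fit_anchor_transform(ident)
  expect_lt(max(tf2$delta), 0.05)
})

test_that("applying the transform shifts, resamples negatives, and rescales", {
  anchors <- anchor_fixture(c(B1 = 1.0, B2 = 1.6))
  tf <- fit_anchor_transform(anchors)
  out <- apply_anchor_transform(anchors, tf, seed = 5)
  expect_true(all(out$exprs >= 0))
  # fraction resampled equals fraction of post-shift negatives
  shifted <- anchors$exprs[, 1] - tf$delta[anchors$pheno$batch_id, 1]
  expect_equal(unname(out$n_resampled[1]), sum(shifted < 0))
  # batch percentile aligned to the target within one order-statistic gap
  for (b in c("B1", "B2")) {
    v <- sort(out$exprs[out$pheno$batch_id == b, 1])
    p <- quantile(v, 0.998, names = FALSE)
    gap <- max(diff(v[max(1, floor(0.995 * length(v))):length(v)]))
    expect_lt(abs(p - tf$p_target[1]), gap + 1e-9)
  }
  # determinism
  out2 <- apply_anchor_transform(anchors, tf, seed = 5)
  expect_identical(out$exprs, out2$exprs)
  # no-op case: all values stay above the shift, percentiles already aligned
  tf0 <- fit_anchor_transform(anchor_fixture(c(B1 = 2)))
  ev0 <- anchor_fixture(c(B1 = 2))
  expect_equal(apply_anchor_transform(ev0, tf0, 1)$exprs, ev0$exprs)
})

test_that("half-normal resampling lands in the channel noise floor", {
  # value below the shift is replaced by |N(0, sigma^2)|: bounded w.h.p.
  anchors <- anchor_fixture(c(B1 = 0.2, B2 = 1.2), sd = 0.1)
  tf <- fit_anchor_transform(anchors)
  sigma <- tf$sigma["B2", 1]
  out <- apply_anchor_transform(anchors, tf, seed = 8)
  resampled <- out$exprs[anchors$pheno$batch_id == "B2" &
                         (anchors$exprs[, 1] - tf$delta["B2", 1]) < 0, 1]
  expect_true(length(resampled) > 0)
  expect_true(all(resampled >= 0))
  # undo the percentile rescale before comparing with the half-normal bound
  resampled_raw <- resampled / (tf$p_target[1] / tf$p_obs["B2", 1])
  expect_lt(mean(resampled_raw > 3.5 * sigma), 0.01)
})

test_that("a 2x channel gain is collapsed at least tenfold by correction", {
  lin <- build_default_lineage()
  dyn <- default_marker_dynamics(noise_sd = 0.2, zero_p = 0.05)
  g <- matrix(1, 2, length(dyn$markers),
              dimnames = list(c("B1", "B2"), dyn$markers))
  g["B2", "CD45"] <- 2.0  # uniformly expressed channel: a clean gain effect
  be <- batch_effect_spec(g, g * 0, floor_sd = 0)
  sheet <- make_sample_sheet(c("B1", "B2"), "BM", 1)
  sim <- simulate_dataset(lin, dyn, be, 3000, sheet, seed = 6)
  ev <- arcsinh_transform(sim$events)
  anchors <- subset_events(ev, which(ev$pheno$is_anchor))
  tf <- fit_anchor_transform(anchors)
  evc <- apply_anchor_transform(ev, tf, seed = 3)
  rep <- correction_report(ev, evc)
  expect_true(all(evc$exprs >= 0))
  row <- rep$spread[rep$spread$channel == "CD45", ]
  expect_gt(row$spread_before, 0.3)   # gain 2 is a visible arcsinh shift
  expect_gte(row$reduction, 10)
  # corrected anchor events track their pre-distortion truth signal on the
  # distorted channel (dim channels lose rank fidelity to the resampling
  # step; the acceptance suite quantifies that per channel)
  anchor_rows <- which(ev$pheno$is_anchor)
  truth_sig <- asinh(sim$events$truth_signal[anchor_rows, ] / 5)
  corr <- vapply(seq_len(ncol(truth_sig)), function(j) {
    cor(truth_sig[, j], evc$exprs[anchor_rows, j], method = "spearman")
  }, numeric(1))
  names(corr) <- colnames(truth_sig)
  expect_gte(corr[["CD45"]], 0.95)
  expect_gte(median(corr), 0.95)
})

test_that("transform fitting rejects multiple anchors per batch", {
  anchors <- anchor_fixture(c(B1 = 1, B2 = 2))
  anchors$pheno$batch_id <- "B1"  # two anchor samples, one batch
  expect_error(fit_anchor_transform(anchors), "exactly one anchor")
  raw <- anchors; raw$scale <- "raw"
  expect_error(fit_anchor_transform(raw), "arcsinh")
})
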