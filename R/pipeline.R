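#' Default pipeline configuration
#'
#' Returns the demo configuration: a three-batch, two-tissue simulated
#' dataset run end-to-end (simulate, arcsinh transform, anchor batch
#' correction, percentile scaling, graph/cluster/pseudotime, truth-based
#' metacluster annotation, composition statistics, binned trajectory).
#' Every parameter of every stage lives in this one nested list and can be
#' serialized to/from YAML.
#'
#' @param output_dir where [run_pipeline()] writes its artifacts.
#' @param seed global seed; per-stage streams are derived from it.
#' @return a named list (the `RunConfig`).
#' @export
default_config <- function(output_dir = tempfile("cytotraj_run_"), seed = 1) {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    simulate = list(
      enabled = TRUE,
      n_events_per_sample = 1500L,
      batches = c("B1", "B2", "B3"),
      tissues = c("BM", "mPB"),
      samples_per_tissue = 1L,
      gain_range = c(0.7, 1.4),
      shift_frac = 0.1,
      floor_sd = 0.1,
      noise_sd = 0.25,
      zero_p = 0.05
    ),
    input = list(fcs_dir = NULL, metadata = NULL),
    preprocess = list(cofactor = 5, scale_percentile = 99.9,
                      downsample_total = NULL),
    correct = list(enabled = TRUE, percentile = 99.8),
    cluster = list(k = 15L, k_expression = 60L, m = 10L, resolution = 10,
                   threshold = 0.3),
    stats = list(bins = 200L, smoothing_window = 9L)
  )
}

#' Validate a pipeline configuration
#'
#' Checks for unknown keys (warnings — forward compatible), out-of-range
#' values and missing input files (errors).
#'
#' @param config a config list or path to a YAML file.
#' @return list: `ok` (logical), `errors`, `warnings`; printed nicely.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errors <- character(0); warnings <- character(0)
  known <- names(default_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    warnings <- c(warnings, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  ref <- default_config()
  for (section in c("simulate", "preprocess", "correct", "cluster", "stats")) {
    unknown <- setdiff(names(config[[section]]), names(ref[[section]]))
    if (length(unknown)) {
      warnings <- c(warnings, paste0("unknown key(s) in ", section, ": ",
                                     paste(unknown, collapse = ", ")))
    }
  }
  need <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  need(is.numeric(config$seed) && config$seed == round(config$seed), "seed: must be an integer")
  cl <- config$cluster
  need(is.numeric(cl$k) && cl$k >= 1, "cluster$k: must be >= 1")
  need(is.numeric(cl$k_expression) && cl$k_expression >= 1,
       "cluster$k_expression: must be >= 1")
  need(is.numeric(cl$m) && cl$m >= 1, "cluster$m: must be >= 1")
  need(is.numeric(cl$resolution) && cl$resolution > 0, "cluster$resolution: must be > 0")
  need(is.numeric(cl$threshold) && cl$threshold >= 0, "cluster$threshold: must be >= 0")
  pp <- config$preprocess
  need(is.numeric(pp$cofactor) && pp$cofactor > 0, "preprocess$cofactor: must be > 0")
  need(is.numeric(pp$scale_percentile) && pp$scale_percentile > 0 &&
         pp$scale_percentile < 100, "preprocess$scale_percentile: must be in (0, 100)")
  need(is.numeric(config$correct$percentile) && config$correct$percentile > 0 &&
         config$correct$percentile < 100, "correct$percentile: must be in (0, 100)")
  st <- config$stats
  need(is.numeric(st$bins) && st$bins >= 2, "stats$bins: must be >= 2")
  need(is.numeric(st$smoothing_window) && st$smoothing_window %% 2 == 1,
       "stats$smoothing_window: must be odd")
  if (!isTRUE(config$simulate$enabled)) {
    for (f in c("fcs_dir", "metadata")) {
      path <- config$input[[f]]
      if (is.null(path)) {
        errors <- c(errors, paste0("input$", f, ": required when simulate is disabled"))
      } else if (!file.exists(path)) {
        errors <- c(errors, paste0("input$", f, ": file not found: ", path))
      }
    }
  } else {
    sim <- config$simulate
    need(is.numeric(sim$n_events_per_sample) && sim$n_events_per_sample > 0,
         "simulate$n_events_per_sample: must be > 0")
  }
  structure(list(ok = length(errors) == 0, errors = errors, warnings = warnings),
            class = "ConfigReport")
}

#' @export
print.ConfigReport <- function(x, ...) {
  cat(if (x$ok) "config OK" else "config INVALID", "\n")
  for (e in x$errors) cat("  error: ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Run the full pipeline from one configuration
#'
#' Executes simulate/read, arcsinh transform, anchor batch correction,
#' percentile scaling, optional balanced downsampling, the knn/diffusion/
#' Leiden/cluster-graph/pseudotime pipeline, metacluster annotation
#' (truth-majority when ground-truth labels are available), composition
#' and dissimilarity statistics, and the binned-trajectory summaries.
#' Every artifact is written as TSV into the run directory together with a
#' manifest (config, seeds, file checksums); rerunning with an identical
#' config reproduces identical artifacts.
#'
#' @param config a config list (see [default_config()]) or a YAML path.
#' @return invisibly, a list of in-memory stage results plus
#'   `output_dir`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  report <- validate_config(config)
  if (!report$ok) {
    stop("invalid config:\n  ", paste(report$errors, collapse = "\n  "))
  }
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  tsv <- function(x, name) {
    utils::write.table(as.data.frame(x), file.path(out_dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage: events in -------------------------------------------------
  truth <- NULL
  if (isTRUE(config$simulate$enabled)) {
    sim_cfg <- config$simulate
    lineage <- build_default_lineage()
    dynamics <- default_marker_dynamics(noise_sd = sim_cfg$noise_sd,
                                        zero_p = sim_cfg$zero_p)
    sheet <- make_sample_sheet(sim_cfg$batches, sim_cfg$tissues,
                               sim_cfg$samples_per_tissue)
    be <- random_batch_effects(sim_cfg$batches, dynamics,
                               seed = substream_seed(seed, "simulate"),
                               gain_range = sim_cfg$gain_range,
                               shift_frac = sim_cfg$shift_frac,
                               floor_sd = sim_cfg$floor_sd)
    sim <- simulate_dataset(lineage, dynamics, be, sim_cfg$n_events_per_sample,
                            sheet, seed = substream_seed(seed, "simulate"))
    events <- sim$events
    truth <- sim$truth
  } else {
    meta <- utils::read.delim(config$input$metadata, stringsAsFactors = FALSE)
    paths <- file.path(config$input$fcs_dir, meta$file)
    events <- read_fcs_set(paths, meta)
    lineage <- build_default_lineage()
  }

  # --- stage: transform + batch correction ------------------------------
  events <- arcsinh_transform(events, cofactor = config$preprocess$cofactor)
  if (isTRUE(config$correct$enabled) && length(unique(events$pheno$batch_id)) > 1 &&
      "is_anchor" %in% names(events$pheno)) {
    anchors <- subset_events(events, events = which(events$pheno$is_anchor))
    transform <- fit_anchor_transform(anchors, percentile = config$correct$percentile)
    before <- events
    events <- apply_anchor_transform(events, transform,
                                     seed = substream_seed(seed, "correct"))
    rep_qc <- correction_report(before, events,
                                percentile = config$correct$percentile)
    tsv(rep_qc$per_batch, "correction_per_batch.tsv")
    tsv(rep_qc$spread, "correction_spread.tsv")
  }
  events <- percentile_scale(events, q = config$preprocess$scale_percentile)
  if (!is.null(config$preprocess$downsample_total)) {
    events <- downsample_balanced(events, c("tissue", "sample_id"),
                                  config$preprocess$downsample_total,
                                  seed = substream_seed(seed, "downsample"))
    if (!is.null(truth)) truth <- truth[events$selected, , drop = FALSE]
  }

  # --- stage: graph / cluster / pseudotime ------------------------------
  cl <- config$cluster
  labels <- if (!is.null(truth)) truth$population else NULL
  traj <- trajectory_pipeline(events$exprs, k = cl$k,
                              k_expression = cl$k_expression, m = cl$m,
                              resolution = cl$resolution,
                              threshold = cl$threshold,
                              root_population = if (!is.null(labels)) lineage$root,
                              labels = labels,
                              seed = substream_seed(seed, "trajectory"))
  part_df <- data.frame(event = seq_len(n_events(events)),
                        cluster = traj$partition$cluster)
  if (!is.null(traj$pseudotime)) part_df$pseudotime <- traj$pseudotime$pseudotime
  tsv(part_df, "partition.tsv")
  tsv(traj$cluster_graph$edges, "cluster_graph_edges.tsv")

  # --- stage: annotation + composition ----------------------------------
  meta_labels <- NULL
  if (!is.null(labels)) {
    ann <- majority_labels(traj$partition, labels)
    mm <- metacluster_map(ann)
    meta <- apply_metaclusters(traj$partition, mm, exprs = events$exprs)
    meta_labels <- meta$labels
    tsv(data.frame(cluster = names(ann), label = unname(ann)), "metaclusters.tsv")
  }
  comp_labels <- meta_labels %||% as.character(traj$partition$cluster)
  comp <- composition_table(comp_labels, events$pheno$sample_id)
  tsv(data.frame(sample = rownames(comp$proportions), comp$proportions,
                 check.names = FALSE), "composition.tsv")
  if (nrow(comp$proportions) >= 2) {
    dis <- sample_dissimilarity(comp)
    tsv(data.frame(sample = rownames(dis$D), dis$D, check.names = FALSE),
        "dissimilarity.tsv")
  }

  # --- stage: binned trajectory -----------------------------------------
  binned <- deriv <- NULL
  if (!is.null(traj$pseudotime) &&
      sum(is.finite(traj$pseudotime$pseudotime)) >= config$stats$bins) {
    binned <- bin_pseudotime(traj$pseudotime, events$exprs, B = config$stats$bins)
    deriv <- expression_derivative(binned,
                                   smoothing_window = config$stats$smoothing_window)
    tsv(data.frame(bin = seq_len(binned$B), midpoint = binned$midpoints,
                   count = binned$counts, binned$bin_means, check.names = FALSE),
        "binned_trajectory.tsv")
    tsv(data.frame(boundary = seq_len(binned$B - 1),
                   midpoint = deriv$boundary_mid, deriv$derivative,
                   check.names = FALSE), "derivative.tsv")
  }

  # --- manifest ----------------------------------------------------------
  files <- setdiff(list.files(out_dir), "manifest.yaml")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(config = config, seed = seed,
                   checksums = as.list(stats::setNames(unname(sums), files)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(events = events, truth = truth, trajectory = traj,
                 metacluster_labels = meta_labels, composition = comp,
                 binned = binned, derivative = deriv, output_dir = out_dir,
                 manifest = manifest))
}
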