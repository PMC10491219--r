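# Shared synthetic fixtures, built once per test run and cached.
# Sizes are kept small for unit tests; the acceptance tests build their own
# larger datasets.

.fixtures <- new.env(parent = emptyenv())

# small 3-batch, 2-tissue dataset (~6.3k cells) with batch effects
small_sim <- function() {
  if (is.null(.fixtures$small)) {
    lin <- build_default_lineage()
    dyn <- default_marker_dynamics()
    sheet <- make_sample_sheet(c("B1", "B2", "B3"), c("BM", "mPB"), 1)
    be <- random_batch_effects(c("B1", "B2", "B3"), dyn, seed = 5)
    sim <- simulate_dataset(lin, dyn, be, 700, sheet, seed = 7)
    .fixtures$small <- list(lineage = lin, dynamics = dyn, batches = be,
                            sheet = sheet, sim = sim)
  }
  .fixtures$small
}

# the small dataset taken through arcsinh + anchor correction + scaling
small_processed <- function() {
  if (is.null(.fixtures$small_proc)) {
    fx <- small_sim()
    ev <- arcsinh_transform(fx$sim$events)
    anchors <- subset_events(ev, which(ev$pheno$is_anchor))
    tf <- fit_anchor_transform(anchors)
    ev <- apply_anchor_transform(ev, tf, seed = 3)
    .fixtures$small_proc <- c(fx, list(events = percentile_scale(ev), transform = tf))
  }
  .fixtures$small_proc
}

# noise-free single-batch dataset for exactness checks
clean_sim <- function(n = 400) {
  lin <- build_default_lineage()
  dyn <- default_marker_dynamics(noise_sd = 0, zero_p = 0)
  be <- identity_batch_effects("B1", dyn$markers)
  sheet <- data.frame(sample_id = "s1", batch_id = "B1", tissue = "BM",
                      is_anchor = TRUE, stringsAsFactors = FALSE)
  sim <- simulate_dataset(lin, dyn, be, n, sheet, seed = 11)
  list(lineage = lin, dynamics = dyn, sim = sim)
}

# brute-force Manhattan distance (independent oracle)
manhattan_brute <- function(P) {
  n <- nrow(P)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (c in seq_len(ncol(P))) s <- s + abs(P[i, c] - P[j, c])
    D[i, j] <- s
  }
  D
}

# exact two-sided Wilcoxon rank-sum p by full enumeration (independent oracle)
wilcox_enumerate <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # Mann-Whitney U
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2, function(ix) sum(r[ix])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# acceptance-scale dataset (~20.7k cells, 3 batches, BM + mPB) and its full
# trajectory analysis; built once and shared by the acceptance tests
acceptance_run <- function() {
  if (is.null(.fixtures$acc)) {
    lin <- build_default_lineage()
    dyn <- default_marker_dynamics()
    sheet <- make_sample_sheet(c("B1", "B2", "B3"), c("BM", "mPB"), 1)
    be <- random_batch_effects(c("B1", "B2", "B3"), dyn, seed = 41)
    sim <- simulate_dataset(lin, dyn, be, 2300, sheet, seed = 41)
    raw <- arcsinh_transform(sim$events)
    anchors <- subset_events(raw, which(raw$pheno$is_anchor))
    tf <- fit_anchor_transform(anchors)
    corrected <- apply_anchor_transform(raw, tf, seed = 41)
    events <- percentile_scale(corrected)
    traj <- trajectory_pipeline(events$exprs, root_population = "HSC",
                                labels = sim$truth$population, seed = 41)
    ann <- majority_labels(traj$partition, sim$truth$population)
    .fixtures$acc <- list(lineage = lin, dynamics = dyn, sheet = sheet,
                          batches = be, sim = sim, raw = raw, anchors = anchors,
                          transform = tf, corrected = corrected,
                          events = events, traj = traj, ann = ann)
  }
  .fixtures$acc
}

# is the population graph of a re-analysis an unbranched path over `pops`?
is_population_path <- function(pop_edges, pops) {
  g <- igraph::graph_from_data_frame(pop_edges, directed = FALSE,
                                     vertices = data.frame(name = pops))
  deg <- igraph::degree(g)
  igraph::is_connected(g) && all(deg <= 2) && sum(deg == 1) == 2
}
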