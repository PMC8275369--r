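# Shared fixtures, memoised so expensive objects (simulated genomes, small
# trained models) are built once per test run.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# small moderately noisy genome with 30 planted enhancers
fx_sim_small <- function() fx("sim_small", function() {
  simulate_dataset(sim_config(n_positive = 30L, noise_scale = 0.3, seed = 101L))
})

# small classifier trained on fx_sim_small (higher learning rate + few
# epochs: plenty for this near-separable toy problem)
fx_model_small <- function() fx("model_small", function() {
  sim <- fx_sim_small()
  m <- build_model(model_config(n_filters = 8L), sim$dataset$panel, seed = 5L)
  train_model(m, sim$dataset,
              train_config(learning_rate = 5e-4, epochs = 12L, patience = 6L,
                           seed = 5L))
})

# low-noise genome whose positive windows are exactly centered on the cores
fx_sim_centered <- function() fx("sim_centered", function() {
  simulate_dataset(sim_config(n_positive = 20L, noise_scale = 0.1,
                              offset_range = 0L,
                              enhancer_length = c(500L, 1500L), seed = 202L))
})

fx_model_centered <- function() fx("model_centered", function() {
  sim <- fx_sim_centered()
  m <- build_model(model_config(n_filters = 8L), sim$dataset$panel, seed = 6L)
  train_model(m, sim$dataset,
              train_config(learning_rate = 5e-4, epochs = 12L, patience = 6L,
                           seed = 6L))
})

# five constant-valued tracks (values 1..5 in panel order) over one 20 kb
# chromosome
fx_const_tracks <- function(chrom = "chr1", len = 20000L) {
  panel <- assay_panel()
  tracks <- lapply(seq_along(panel), function(i)
    signal_track(stats::setNames(list(rep(i, len)), chrom),
                 assay = unclass(panel)[i]))
  names(tracks) <- unclass(panel)
  tracks
}

expect_same_intervals <- function(a, b) {
  expect_equal(a$chrom, b$chrom)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
}

# naive per-base coverage oracle over [0, len) for one chromosome
naive_coverage <- function(x, len) {
  v <- logical(len)
  for (i in seq_len(nrow(x))) v[(x$start[i] + 1):x$end[i]] <- TRUE
  v
}
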