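# shared fixtures built in code; all randomness flows from explicit seeds

# two regions, single directed edge A -> B
tiny_conn <- function() {
  W <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  connectome(W)
}

# symmetric two-node graph with unit weights both ways
sym2_conn <- function() {
  W <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  connectome(W)
}

fixture_conn <- function(n = 20, density = 0.3, seed = 42, ...) {
  synth_connectome(n_regions = n, density = density, rng_seed = seed, ...)
}

# cheap deterministic fitting settings for permutation-heavy tests
quick_ctrl <- function(grid_n = 10, refine = FALSE) {
  fit_control(grid_n = grid_n, refine = refine)
}

# minimal hand-built spread_fit carrying only what the vulnerability
# operations consume
fake_fit <- function(residuals, timepoints, conn = NULL) {
  structure(list(residuals = residuals, timepoints = timepoints,
                 region_ids = rownames(residuals),
                 conn = conn, r = rep(NA_real_, length(timepoints))),
            class = "spread_fit")
}
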