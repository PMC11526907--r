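make_planted <- function(n = 30, seed = 31, retro_only = TRUE) {
  conn <- fixture_conn(n = n, density = 0.25, seed = seed)
  tps <- c(0.1, 0.2, 0.5, 1)
  coefs <- if (retro_only) synth_coefs(tps, b_a = 0, b_r = 1) else
    synth_coefs(tps)
  sp <- synth_pathology(conn, timepoints = tps, noise_sd = 0.1,
                        coefs = coefs, rng_seed = seed + 1)
  list(conn = conn, data = sp$data, seed_region = sp$truth$seed_region)
}

test_that("seed test recovers a planted seed with small p", {
  pl <- make_planted()
  sn <- alternate_seed_test(pl$data, pl$conn, pl$seed_region,
                            mode = "retrograde", n_alt = 25, rng_seed = 1)
  expect_true(sum(sn$p <= 0.05) >= 2)
  expect_true(all(sn$p > 0 & sn$p <= 1))
  expect_equal(nrow(sn$r_alt), 25)
})

test_that("add-one convention: one worse alternate gives p = 1/2", {
  pl <- make_planted()
  sn <- alternate_seed_test(pl$data, pl$conn, pl$seed_region,
                            mode = "retrograde", n_alt = 1, rng_seed = 2)
  worse <- which(sn$r_alt[1, ] < sn$r_actual)
  expect_gt(length(worse), 0)
  expect_true(all(sn$p[worse] == 0.5))
  expect_true(all(sn$p_raw[worse] == 0))
})

test_that("the actual seed is never drawn as an alternate", {
  pl <- make_planted()
  for (rs in 1:3) {
    sn <- alternate_seed_test(pl$data, pl$conn, pl$seed_region,
                              mode = "retrograde", n_alt = 10, rng_seed = rs)
    expect_false(pl$seed_region %in% sn$alt_seeds)
  }
})

test_that("seed test is bit-reproducible under a fixed rng seed", {
  pl <- make_planted(n = 20)
  a <- alternate_seed_test(pl$data, pl$conn, pl$seed_region,
                           mode = "retrograde", n_alt = 8, rng_seed = 7)
  b <- alternate_seed_test(pl$data, pl$conn, pl$seed_region,
                           mode = "retrograde", n_alt = 8, rng_seed = 7)
  expect_identical(a, b)
})

test_that("n_alt beyond the region count requires replacement", {
  pl <- make_planted(n = 20)
  expect_error(alternate_seed_test(pl$data, pl$conn, pl$seed_region,
                                   n_alt = 50, rng_seed = 1),
               "replace")
  sn <- alternate_seed_test(pl$data, pl$conn, pl$seed_region,
                            mode = "retrograde", n_alt = 25, rng_seed = 1,
                            replace = TRUE)
  expect_equal(length(sn$alt_seeds), 25)
  expect_error(alternate_seed_test(pl$data, pl$conn, pl$seed_region,
                                   n_alt = 0), "n_alt")
})

test_that("cross-validation ranks the planted direction above the wrong one", {
  pl <- make_planted(n = 30)
  cv <- crossval_compare(pl$data, pl$conn, pl$seed_region,
                         modes = c("anterograde", "retrograde"),
                         n_iter = 30, rng_seed = 3)
  med <- sapply(cv$r_test, median, na.rm = TRUE)
  expect_gt(med["retrograde"], med["anterograde"])
  late <- cv$comparisons[cv$comparisons$mpi >= 1, ]
  expect_true(any(late$p < 0.05))
})

test_that("cross-validation is bit-reproducible and order-invariant", {
  pl <- make_planted(n = 24)
  run <- function(data, conn) {
    crossval_compare(data, conn, pl$seed_region,
                     modes = c("anterograde", "retrograde"),
                     n_iter = 10, rng_seed = 5)
  }
  a <- run(pl$data, pl$conn)
  expect_identical(a, run(pl$data, pl$conn))

  # permute region order in both inputs: distributions must not change
  perm <- withr::with_seed(6, sample(length(pl$conn$region_ids)))
  conn2 <- connectome(pl$conn$W[perm, perm],
                      region_ids = pl$conn$region_ids[perm],
                      coords = pl$conn$coords[perm, ])
  data2 <- pl$data[withr::with_seed(7, sample(nrow(pl$data))), ]
  b <- run(data2, conn2)
  expect_identical(a$r_test, b$r_test)
})

test_that("self-comparison of identical mode specifications is null", {
  pl <- make_planted(n = 24)
  hits <- sapply(1:5, function(rs) {
    cv <- crossval_compare(pl$data, pl$conn, pl$seed_region,
                           modes = c("retrograde", "retrograde"),
                           n_iter = 12, rng_seed = rs)
    # identical specs on identical splits give identical distributions
    all(is.na(cv$comparisons$p) | cv$comparisons$p > 0.05)
  })
  expect_true(mean(hits) >= 0.9)
})

test_that("degenerate single-iteration comparisons are undefined", {
  pl <- make_planted(n = 24)
  cv <- crossval_compare(pl$data, pl$conn, pl$seed_region,
                         modes = c("anterograde", "retrograde"),
                         n_iter = 1, rng_seed = 9)
  expect_equal(nrow(cv$r_test[["retrograde"]]), 1)
  expect_true(all(is.na(cv$comparisons$p)))
})

test_that("modes that cannot fit most splits are flagged unstable", {
  conn <- fixture_conn(n = 20, density = 0.3, seed = 33)
  sp <- synth_pathology(conn, timepoints = c(1, 3), noise_sd = 0.1,
                        rng_seed = 33)
  dat <- sp$data
  # wipe out all but 4 regions so that half-splits cannot support the fit
  keep <- paste0("R00", 1:4)
  dat$pct_area[!dat$region_id %in% keep] <- 0
  cv <- suppressWarnings(
    crossval_compare(dat, conn, "R001", modes = "retrograde",
                     n_iter = 10, rng_seed = 11))
  expect_true("retrograde" %in% cv$unstable)
})
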