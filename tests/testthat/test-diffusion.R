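test_that("propagation at t = 0 is the identity", {
  conn <- fixture_conn(n = 12)
  L <- build_laplacians(conn)$retro
  x0 <- seed_vector(conn, conn$region_ids[3])
  expect_true(all(propagate(L, 1.3, 0, x0) == as.numeric(x0)))
})

test_that("two-node symmetric chain matches the closed form", {
  L <- build_laplacians(sym2_conn())$retro
  x0 <- seed_vector(sym2_conn(), "A")
  for (t in c(0.05, log(2) / 2, 1, 4)) {
    expect_equal(unname(propagate(L, 1, t, x0)),
                 c((1 + exp(-2 * t)) / 2, (1 - exp(-2 * t)) / 2),
                 tolerance = 1e-10)
  }
  expect_equal(unname(propagate(L, 1, log(2) / 2, x0)), c(0.75, 0.25),
               tolerance = 1e-10)
})

test_that("matrix exponential agrees with fixed-step RK4 integration", {
  skip_if_not_installed("deSolve")
  conn <- fixture_conn(n = 20, density = 0.3, seed = 5)
  x0 <- seed_vector(conn, conn$region_ids[1])
  cc <- 0.7; tt <- 3
  for (dir in c("antero", "retro")) {
    L <- build_laplacians(conn)[[dir]]
    ode <- deSolve::ode(y = as.numeric(x0), times = seq(0, tt, by = 1e-3),
                        func = function(t, y, p) list(-cc * (L %*% y)),
                        parms = NULL, method = "rk4")
    rk4 <- ode[nrow(ode), -1]
    expect_lt(max(abs(propagate(L, cc, tt, x0) - rk4)), 1e-6)
  }
})

test_that("propagator conserves mass, stays nonnegative, and is a semigroup", {
  conn <- fixture_conn(n = 15, density = 0.4, seed = 9)
  L <- build_laplacians(conn)$retro
  x0 <- seed_vector(conn, conn$region_ids[2])
  for (t in c(0.1, 1, 5)) {
    x <- propagate(L, 0.8, t, x0)
    expect_true(all(x >= 0))
    expect_equal(sum(x), 1, tolerance = 1e-10)
  }
  x12 <- propagate(L, 0.8, 1.7, x0)
  x1then2 <- propagate(L, 0.8, 1.2, propagate(L, 0.8, 0.5, x0))
  expect_equal(x12, x1then2, tolerance = 1e-10)
})

test_that("for small t pathology leaves the seed and reaches its targets", {
  conn <- fixture_conn(n = 10, density = 0.3, seed = 11)
  La <- build_laplacians(conn)$antero
  seed <- conn$region_ids[1]
  x0 <- seed_vector(conn, seed)
  targets <- conn$region_ids[conn$W[seed, ] > 0]
  x <- propagate(La, 1, 0.01, x0)
  expect_lt(x[seed], 1)
  expect_true(all(x[targets] > 0))
})

test_that("predict_log applies coefficients on the floor-masked scale", {
  res <- predict_log(c(1, 10, 100), NULL, b0 = 0, b_a = 1)
  expect_equal(res$yhat, c(0, 1, 2), ignore_attr = TRUE)
  expect_true(all(res$mask))

  res0 <- predict_log(c(0, 1), c(1, 1), b0 = 0, b_a = 1, b_r = 1)
  expect_equal(res0$mask, c(FALSE, TRUE), ignore_attr = TRUE)
  expect_true(is.na(res0$yhat[1]))

  resc <- predict_log(c(1, 2, 3), NULL, b0 = 2, b_a = 0)
  expect_equal(resc$yhat, rep(2, 3), ignore_attr = TRUE)

  expect_error(predict_log(1, 1, 0, 1, 1, floor = 0), "floor")
})

test_that("model fit statistic is Pearson r with an undefined flag", {
  y <- c(0.3, 1.1, 2.4, 3.0)
  expect_equal(model_fit_statistic(y, y), 1)
  expect_equal(model_fit_statistic(-y, y), -1)
  yh <- c(1, 2, 3, 5)
  num <- sum((yh - mean(yh)) * (y - mean(y)))
  den <- sqrt(sum((yh - mean(yh))^2) * sum((y - mean(y))^2))
  expect_equal(model_fit_statistic(yh, y), num / den)
  flat <- model_fit_statistic(rep(1, 4), y)
  expect_true(is.na(flat))
  expect_true(attr(flat, "undefined"))
  expect_true(is.na(model_fit_statistic(yh[1:2], y[1:2])))
})

test_that("noiseless self-generated data is fit exactly", {
  conn <- fixture_conn(n = 25, density = 0.3, seed = 13)
  sp <- synth_pathology(conn, noise_sd = 0, rng_seed = 13)
  f <- fit_model(sp$data, conn, sp$truth$seed_region)
  expect_true(all(abs(f$residuals[is.finite(f$residuals)]) < 1e-6))
  expect_true(all(f$r > 0.999))
})

test_that("rate constants are recovered from noiseless synthetic data", {
  errs <- sapply(1:3, function(i) {
    conn <- synth_connectome(40, 0.2, rng_seed = 100 + i)
    sp <- synth_pathology(conn, noise_sd = 0, rng_seed = 200 + i)
    f <- fit_model(sp$data, conn, sp$truth$seed_region)
    abs(f$rates - c(0.5, 2)) / c(0.5, 2)
  })
  expect_lt(median(errs), 0.10)
})

test_that("bidirectional fit objective is no worse than nested single modes", {
  # dense graph so that reachability masks agree across modes
  conn <- fixture_conn(n = 15, density = 0.9, seed = 17)
  sp <- synth_pathology(conn, noise_sd = 0.2, rng_seed = 17)
  ctrl <- quick_ctrl(grid_n = 8)
  f2 <- fit_model(sp$data, conn, "R001", mode = "bidirectional",
                  control = ctrl)
  fa <- fit_model(sp$data, conn, "R001", mode = "anterograde",
                  control = ctrl)
  fr <- fit_model(sp$data, conn, "R001", mode = "retrograde",
                  control = ctrl)
  expect_lte(f2$sse, fa$sse + 1e-9)
  expect_lte(f2$sse, fr$sse + 1e-9)
})

test_that("the matching direction fits planted single-direction data best", {
  conn <- fixture_conn(n = 30, density = 0.2, seed = 19)
  sp <- synth_pathology(conn, noise_sd = 0.1, rng_seed = 19,
                        coefs = synth_coefs(c(0.1, 0.5, 1, 3, 6),
                                            b_a = 0, b_r = 1),
                        timepoints = c(0.1, 0.5, 1, 3, 6))
  fr <- fit_model(sp$data, conn, "R001", mode = "retrograde")
  fa <- fit_model(sp$data, conn, "R001", mode = "anterograde")
  expect_gt(mean(fr$r, na.rm = TRUE), mean(fa$r, na.rm = TRUE))
})

test_that("alternate seed maps hold parameters fixed", {
  conn <- fixture_conn(n = 20, density = 0.3, seed = 23)
  sp <- synth_pathology(conn, noise_sd = 0.05, rng_seed = 23)
  f <- fit_model(sp$data, conn, "R001", control = quick_ctrl())

  same <- predict_alternate_seed_maps(f, seeds = "R001")[["R001"]]
  ok <- is.finite(f$predicted)
  expect_equal(same[ok], f$predicted[ok], tolerance = 1e-10)

  two <- predict_alternate_seed_maps(f, seeds = c("R005", "R011"))
  d <- abs(two[["R005"]] - two[["R011"]])
  expect_gt(max(d[is.finite(d)]), 0)

  expect_error(predict_alternate_seed_maps(f, seeds = "nope"), "nearest")
})

test_that("propagation respects disconnected components", {
  # two 3-node blocks with no edges between them
  W <- matrix(0, 6, 6, dimnames = list(paste0("r", 1:6), paste0("r", 1:6)))
  W[1, 2] <- W[2, 3] <- W[3, 1] <- 1
  W[4, 5] <- W[5, 6] <- W[6, 4] <- 1
  conn <- connectome(W)
  L <- build_laplacians(conn)$antero
  x <- propagate(L, 1, 2, seed_vector(conn, "r1"))
  expect_equal(unname(x[4:6]), rep(0, 3), tolerance = 1e-12)
  expect_equal(sum(x[1:3]), 1, tolerance = 1e-10)
})
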