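#' Propagate a seed along a network by linear diffusion
#'
#' Solves `dx/dt = -c * L * x` from initial condition `x0` with the matrix
#' exponential, giving `x(t) = expm(-c * L * t) %*% x0`. Because every column
#' of the Laplacian sums to zero, the total mass `sum(x)` is conserved; tiny
#' negative entries from floating-point roundoff are clipped to zero.
#'
#' @param L graph Laplacian (see [build_laplacians()]).
#' @param c nonnegative diffusion rate constant (per month).
#' @param t nonnegative time (months).
#' @param x0 initial condition, e.g. a [seed_vector()].
#' @return numeric vector `x(t)`, named like `x0`.
#' @export
propagate <- function(L, c, t, x0) {
  if (!is.numeric(c) || c < 0) stop("rate constant c must be >= 0")
  if (!is.numeric(t) || t < 0) stop("time t must be >= 0")
  E <- as.matrix(Matrix::expm(-c * t * Matrix::Matrix(L)))
  x <- drop(E %*% x0)
  if (any(!is.finite(x)))
    stop(sprintf("non-finite propagation result (c*t = %g is too large)",
                 c * t))
  x[x < 0] <- 0
  names(x) <- names(x0)
  x
}

# expm(-c L t) %*% x0 for each timepoint; returns N x T matrix
.propagate_tps <- function(L, c, timepoints, x0) {
  M <- Matrix::Matrix(L)
  out <- vapply(timepoints, function(t) {
    x <- drop(as.matrix(Matrix::expm(-c * t * M)) %*% x0)
    x[x < 0] <- 0
    x
  }, numeric(length(x0)))
  dimnames(out) <- list(names(x0), as.character(timepoints))
  out
}

# full propagator matrices expm(-c L t); list over timepoints of N x N
.propagator_mats <- function(L, c, timepoints) {
  M <- Matrix::Matrix(L)
  lapply(timepoints, function(t) {
    E <- as.matrix(Matrix::expm(-c * t * M))
    E[E < 0] <- 0
    E
  })
}

#' Predicted log pathology from propagated predictors
#'
#' Realizes the regression layer of the diffusion model. Regions where a
#' used predictor does not exceed `floor` are masked out (excluded) rather
#' than log-transformed, which is how unreachable regions are handled; on the
#' included regions
#' `yhat = b0 + b_a * log10(x_a) + b_r * log10(x_r)`.
#'
#' @param x_a anterograde propagated vector (or `NULL` if unused).
#' @param x_r retrograde propagated vector (or `NULL` if unused).
#' @param b0,b_a,b_r regression coefficients; the coefficient of a `NULL`
#'   predictor must be 0.
#' @param floor strictly positive reachability floor (default `1e-12`).
#' @return list with `yhat` (full-length, `NA` where masked) and logical
#'   `mask`.
#' @export
predict_log <- function(x_a, x_r, b0, b_a = 0, b_r = 0, floor = 1e-12) {
  if (!is.numeric(floor) || floor <= 0) stop("floor must be > 0")
  if (is.null(x_a) && is.null(x_r)) stop("at least one predictor is required")
  n <- length(if (is.null(x_a)) x_r else x_a)
  if (!is.null(x_a) && !is.null(x_r) && length(x_a) != length(x_r))
    stop("x_a and x_r must have the same length")
  mask <- rep(TRUE, n)
  if (!is.null(x_a)) mask <- mask & x_a > floor
  if (!is.null(x_r)) mask <- mask & x_r > floor
  yhat <- rep(NA_real_, n)
  yhat[mask] <- b0 +
    (if (is.null(x_a)) 0 else b_a * log10(x_a[mask])) +
    (if (is.null(x_r)) 0 else b_r * log10(x_r[mask]))
  nm <- names(if (is.null(x_a)) x_r else x_a)
  names(yhat) <- names(mask) <- nm
  list(yhat = yhat, mask = mask)
}

#' Pearson model-fit statistic
#'
#' Sample Pearson correlation between predicted and observed log pathology
#' over included regions. Returns `NA` (flagged undefined) when fewer than 3
#' regions are included or either vector has zero variance.
#'
#' @param yhat,y numeric vectors of equal length.
#' @param mask optional logical inclusion mask; `NA`s in either vector are
#'   always excluded.
#' @return Pearson r, or `NA_real_` with attribute `undefined = TRUE`.
#' @export
model_fit_statistic <- function(yhat, y, mask = NULL) {
  ok <- is.finite(yhat) & is.finite(y)
  if (!is.null(mask)) ok <- ok & mask
  undef <- structure(NA_real_, undefined = TRUE)
  if (sum(ok) < 3) return(undef)
  a <- yhat[ok]; b <- y[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(undef)
  stats::cor(a, b)
}

#' Fitting control parameters
#'
#' @param grid_n number of log-spaced grid points per rate constant.
#' @param c_range lower/upper bounds of the rate-constant search (per month).
#' @param refine run derivative-free local refinement from the best grid
#'   cell (Brent in 1-D, Nelder-Mead in 2-D on `log10(c)`).
#' @param refine_maxit iteration cap for the refinement.
#' @return list of control values.
#' @export
fit_control <- function(grid_n = 20, c_range = c(1e-3, 1e2), refine = TRUE,
                        refine_maxit = 500) {
  stopifnot(grid_n >= 2, length(c_range) == 2, c_range[1] > 0,
            c_range[2] > c_range[1])
  list(grid_n = grid_n, c_range = c_range, refine = refine,
       refine_maxit = refine_maxit)
}

# active predictor codes per mode
.mode_preds <- function(mode) {
  switch(mode,
         bidirectional = c("a", "r"),
         anterograde = "a",
         retrograde = "r",
         euclidean = "e",
         stop("unknown mode: ", mode))
}

# Laplacians needed for a mode
.mode_laplacians <- function(conn, mode) {
  preds <- .mode_preds(mode)
  out <- list()
  if (any(preds %in% c("a", "r"))) {
    lap <- build_laplacians(conn)
    if ("a" %in% preds) out$a <- lap$antero
    if ("r" %in% preds) out$r <- lap$retro
  }
  if ("e" %in% preds) {
    if (is.null(conn$coords))
      stop("euclidean mode requires region coordinates on the connectome")
    surr <- euclidean_surrogate(conn$coords, region_ids = conn$region_ids)
    out$e <- build_laplacians(surr)$retro
  }
  out
}

# Per-timepoint OLS of log10 observed on log10 predictors.
# xmats: named list of N x T propagated predictor matrices.
# fit_mask: optional logical length-N restriction (train regions).
# Returns pooled SSE (Inf if no timepoint is fittable), T x (1+k) coefs.
.fit_timepoints <- function(y_mat, xmats, floor, fit_mask = NULL) {
  n_t <- ncol(y_mat)
  k <- length(xmats)
  coefs <- matrix(NA_real_, n_t, k + 1)
  sse <- 0
  n_fit <- 0L
  for (ti in seq_len(n_t)) {
    obs <- y_mat[, ti]
    inc <- !is.na(obs) & obs > 0
    if (!is.null(fit_mask)) inc <- inc & fit_mask
    for (x in xmats) inc <- inc & x[, ti] > floor
    m <- sum(inc)
    if (m < k + 2) next
    y <- log10(obs[inc])
    X <- cbind(1, vapply(xmats, function(x) log10(x[inc, ti]), numeric(m)))
    f <- stats::.lm.fit(X, y)
    coefs[ti, ] <- f$coefficients
    sse <- sse + sum(f$residuals^2)
    n_fit <- n_fit + 1L
  }
  list(sse = if (n_fit == 0L) Inf else sse, coefs = coefs, n_fit = n_fit)
}

# Evaluate fitted coefficients: predictions, residuals and Pearson r per
# timepoint over eval_mask regions (default: all).
.predict_timepoints <- function(y_mat, xmats, coefs, floor, eval_mask = NULL) {
  n <- nrow(y_mat); n_t <- ncol(y_mat)
  yhat <- resid <- matrix(NA_real_, n, n_t, dimnames = dimnames(y_mat))
  mask <- matrix(FALSE, n, n_t, dimnames = dimnames(y_mat))
  r <- stats::setNames(rep(NA_real_, n_t), colnames(y_mat))
  n_used <- integer(n_t)
  for (ti in seq_len(n_t)) {
    if (anyNA(coefs[ti, ])) next
    obs <- y_mat[, ti]
    inc <- !is.na(obs) & obs > 0
    if (!is.null(eval_mask)) inc <- inc & eval_mask
    for (x in xmats) inc <- inc & x[, ti] > floor
    if (!any(inc)) next
    X <- cbind(1, vapply(xmats, function(x) log10(x[inc, ti]),
                         numeric(sum(inc))))
    pred <- drop(X %*% coefs[ti, ])
    yhat[inc, ti] <- pred
    resid[inc, ti] <- log10(obs[inc]) - pred
    mask[, ti] <- inc
    n_used[ti] <- sum(inc)
    r[ti] <- model_fit_statistic(pred, log10(obs[inc]))
  }
  list(yhat = yhat, resid = resid, mask = mask, r = r, n_used = n_used)
}

# Pooled-SSE objective over rate constants, recomputing propagators.
.rate_objective <- function(cvals, Ls, timepoints, x0, y_mat, floor,
                            fit_mask = NULL) {
  xmats <- mapply(function(L, cc) .propagate_tps(L, cc, timepoints, x0),
                  Ls, cvals, SIMPLIFY = FALSE)
  .fit_timepoints(y_mat, xmats, floor, fit_mask)$sse
}

#' Fit the bidirectional linear diffusion model
#'
#' Seeded pathology is propagated along the connectome with the anterograde
#' and retrograde Laplacian propagators `expm(-c * L * t) %*% x0`, and mean
#' observed log10 pathology at each timepoint is regressed on the log10
#' propagated predictors. The global rate constants are chosen to minimize
#' the pooled sum of squared residuals over all timepoints (equal weight per
#' region-timepoint), with per-timepoint intercept and predictor weights
#' profiled out by ordinary least squares. The search is a log-spaced grid
#' followed by optional derivative-free local refinement, so fits are
#' deterministic. Single-predictor modes (`anterograde`, `retrograde`,
#' `euclidean`) fix the unused weights at zero.
#'
#' @param pathology long pathology `data.frame` or a
#'   [summarize_pathology()] result.
#' @param conn a [connectome()].
#' @param seed_region label of the injected region.
#' @param mode spread model variant.
#' @param measure pathology measure to fit when `pathology` is long format.
#' @param floor reachability floor below which a propagated predictor masks
#'   its region out (strictly positive).
#' @param control a [fit_control()] list.
#' @return object of class `"spread_fit"` with elements `mode`, `params`
#'   (rate constants), `coefs` (per-timepoint regression weights and fit r),
#'   `observed`, `predicted`, `residuals`, `mask` (region x timepoint),
#'   `r`, `sse`, `timepoints`, `region_ids`, `seed_region` and the
#'   connectome used.
#' @export
fit_model <- function(pathology, conn,
                      seed_region,
                      mode = c("bidirectional", "anterograde", "retrograde",
                               "euclidean"),
                      measure = "total", floor = 1e-12,
                      control = fit_control()) {
  mode <- match.arg(mode)
  stopifnot(inherits(conn, "connectome"))
  if (!is.numeric(floor) || floor <= 0) stop("floor must be > 0")
  ps <- summarize_pathology(pathology, measure = measure)
  y_mat <- .align_summary(ps, conn)
  timepoints <- ps$timepoints

  n_pos <- colSums(!is.na(y_mat) & y_mat > 0)
  if (sum(n_pos >= 3) < 2)
    stop("need at least 2 timepoints with >= 3 regions of nonzero pathology")

  x0 <- seed_vector(conn, seed_region)
  Ls <- .mode_laplacians(conn, mode)
  preds <- names(Ls)
  k <- length(preds)

  cg <- 10^seq(log10(control$c_range[1]), log10(control$c_range[2]),
               length.out = control$grid_n)
  caches <- lapply(Ls, function(L)
    lapply(cg, function(cc) .propagate_tps(L, cc, timepoints, x0)))

  combos <- as.matrix(expand.grid(rep(list(seq_along(cg)), k)))
  sses <- apply(combos, 1, function(ix) {
    xmats <- mapply(function(cache, i) cache[[i]], caches, ix,
                    SIMPLIFY = FALSE)
    .fit_timepoints(y_mat, xmats, floor)$sse
  })
  if (all(!is.finite(sses)))
    stop("no rate-constant setting yields enough included regions to fit")
  best <- combos[which.min(sses), ]
  c_best <- cg[best]
  sse_best <- min(sses)

  if (isTRUE(control$refine)) {
    lo <- log10(control$c_range[1]); hi <- log10(control$c_range[2])
    obj <- function(u) {
      if (any(u < lo - 1e-9) || any(u > hi + 1e-9)) return(1e300)
      .rate_objective(10^u, Ls, timepoints, x0, y_mat, floor)
    }
    if (k == 1) {
      du <- (hi - lo) / (control$grid_n - 1)
      o <- stats::optimize(obj, lower = max(lo, log10(c_best) - du),
                           upper = min(hi, log10(c_best) + du),
                           tol = 1e-6)
      if (is.finite(o$objective) && o$objective < sse_best) {
        c_best <- 10^o$minimum; sse_best <- o$objective
      }
    } else {
      o <- stats::optim(log10(c_best), obj, method = "Nelder-Mead",
                        control = list(maxit = control$refine_maxit,
                                       reltol = 1e-10))
      if (o$convergence != 0)
        stop(sprintf(
          "rate-constant refinement did not converge (code %d, %d evals, sse %.6g)",
          o$convergence, o$counts[1], o$value))
      if (is.finite(o$value) && o$value < sse_best) {
        c_best <- 10^o$par; sse_best <- o$value
      }
    }
  }

  xmats <- mapply(function(L, cc) .propagate_tps(L, cc, timepoints, x0),
                  Ls, c_best, SIMPLIFY = FALSE)
  ft <- .fit_timepoints(y_mat, xmats, floor)
  pt <- .predict_timepoints(y_mat, xmats, ft$coefs, floor)

  params <- list(c_a = NA_real_, c_r = NA_real_, c_e = NA_real_)
  params[paste0("c_", preds)] <- as.list(c_best)
  cf <- matrix(0, length(timepoints), 3,
               dimnames = list(NULL, c("b0", "b_a", "b_r")))
  cf[, "b0"] <- ft$coefs[, 1]
  bcols <- c(a = "b_a", r = "b_r", e = "b_r")[preds]
  for (j in seq_along(preds)) cf[, bcols[j]] <- ft$coefs[, j + 1]
  cf[is.na(ft$coefs[, 1]), ] <- NA_real_
  coefs <- data.frame(mpi = timepoints, cf, n_regions = pt$n_used, r = pt$r,
                      row.names = NULL)

  structure(list(mode = mode, params = params,
                 rates = stats::setNames(c_best, paste0("c_", preds)),
                 coefs = coefs, timepoints = timepoints,
                 region_ids = conn$region_ids, seed_region = seed_region,
                 floor = floor, control = control, measure = ps$measure,
                 observed = y_mat, predicted = pt$yhat,
                 residuals = pt$resid, mask = pt$mask, r = pt$r,
                 sse = sse_best, conn = conn,
                 raw_coefs = ft$coefs),
            class = "spread_fit")
}

# align a pathology_summary to connectome region order; drops (with a
# warning) regions in the data that the connectome does not contain
.align_summary <- function(ps, conn) {
  extra <- setdiff(rownames(ps$mat), conn$region_ids)
  if (length(extra) > 0)
    warning("dropping ", length(extra),
            " pathology regions absent from the connectome: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "")
  out <- matrix(NA_real_, length(conn$region_ids), ncol(ps$mat),
                dimnames = list(conn$region_ids, colnames(ps$mat)))
  shared <- intersect(conn$region_ids, rownames(ps$mat))
  out[shared, ] <- ps$mat[shared, ]
  out
}

#' @export
print.spread_fit <- function(x, ...) {
  cat(sprintf("spread_fit: mode %s, %d regions, %d timepoints\n",
              x$mode, length(x$region_ids), length(x$timepoints)))
  cat("  rates:", paste(sprintf("%s = %.4g", names(x$rates), x$rates),
                        collapse = ", "), "\n")
  cat("  per-timepoint Pearson r:",
      paste(sprintf("%.3f", x$r), collapse = " "), "\n")
  invisible(x)
}

#' Predicted pathology maps for alternate seed regions
#'
#' Holds every fitted parameter fixed (rate constants and per-timepoint
#' regression weights) and recomputes the predicted log-pathology map after
#' moving the initial pathology mass to each requested seed region.
#'
#' @param fitted a [fit_model()] result.
#' @param conn connectome to propagate on; defaults to the one stored in the
#'   fit.
#' @param seeds character vector of seed region labels.
#' @return named list (one element per seed) of region x timepoint predicted
#'   log10 pathology matrices, `NA` where masked.
#' @export
predict_alternate_seed_maps <- function(fitted, conn = fitted$conn, seeds) {
  stopifnot(inherits(fitted, "spread_fit"))
  Ls <- .mode_laplacians(conn, fitted$mode)
  preds <- names(Ls)
  c_best <- fitted$rates
  out <- lapply(seeds, function(s) {
    x0 <- seed_vector(conn, s)
    xmats <- mapply(function(L, cc)
      .propagate_tps(L, cc, fitted$timepoints, x0), Ls, c_best,
      SIMPLIFY = FALSE)
    n <- length(x0); n_t <- length(fitted$timepoints)
    yhat <- matrix(NA_real_, n, n_t,
                   dimnames = list(conn$region_ids,
                                   as.character(fitted$timepoints)))
    for (ti in seq_len(n_t)) {
      if (anyNA(fitted$raw_coefs[ti, ])) next
      inc <- rep(TRUE, n)
      for (x in xmats) inc <- inc & x[, ti] > fitted$floor
      if (!any(inc)) next
      X <- cbind(1, vapply(xmats, function(x) log10(x[inc, ti]),
                           numeric(sum(inc))))
      yhat[inc, ti] <- drop(X %*% fitted$raw_coefs[ti, ])
    }
    yhat
  })
  names(out) <- seeds
  out
}
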