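# reorder a connectome's regions (used to canonicalize region order so that
# resampling results do not depend on input file ordering)
.reorder_conn <- function(conn, ord) {
  connectome(conn$W[ord, ord, drop = FALSE],
             region_ids = conn$region_ids[ord],
             hemisphere = conn$hemisphere[ord],
             coords = if (is.null(conn$coords)) NULL
                      else conn$coords[ord, , drop = FALSE],
             base_region = conn$base_region[ord])
}

# grid-search fit for one seed from cached predictor matrices.
# xs[[pred]][[ci]] is an N x T propagated-predictor matrix.
.grid_fit_cached <- function(xs, combos, y_mat, floor, fit_mask = NULL) {
  sse <- apply(combos, 1, function(ix) {
    xmats <- mapply(function(cache, i) cache[[i]], xs, ix, SIMPLIFY = FALSE)
    .fit_timepoints(y_mat, xmats, floor, fit_mask)$sse
  })
  if (all(!is.finite(sse))) return(NULL)
  best <- combos[which.min(sse), ]
  xmats <- mapply(function(cache, i) cache[[i]], xs, best, SIMPLIFY = FALSE)
  ft <- .fit_timepoints(y_mat, xmats, floor, fit_mask)
  list(best = best, sse = ft$sse, coefs = ft$coefs, xmats = xmats)
}

#' Seed-specificity permutation test
#'
#' Asks whether the model fits the observed pathology better when seeded at
#' the experimental injection site than at randomly chosen alternate
#' regions. For every alternate seed the initial condition is redefined and
#' the model is refit with the same procedure used for the actual seed
#' (grid search over rate constants with per-timepoint least squares, plus
#' local refinement if enabled in `control`). The per-timepoint
#' nonparametric p-value uses the add-one permutation convention
#' `p(t) = (1 + #\{r_alt(t) >= r_actual(t)\}) / (1 + n_alt)`, so it is never
#' zero; the raw proportion is also reported.
#'
#' @param pathology long pathology table or [summarize_pathology()] result.
#' @param conn a [connectome()].
#' @param actual_seed the experimental seed region label.
#' @param mode spread model variant.
#' @param measure pathology measure when `pathology` is long format.
#' @param n_alt number of alternate seed regions.
#' @param rng_seed integer seed controlling alternate-seed sampling; runs are
#'   bit-reproducible given the same seed.
#' @param replace sample alternate seeds with replacement (required when
#'   `n_alt` exceeds the number of non-seed regions).
#' @param floor reachability floor (see [fit_model()]).
#' @param control a [fit_control()]; the default disables local refinement so
#'   that large permutation runs stay cheap, with every seed (actual and
#'   alternate) fit under identical settings.
#' @return object of class `"seed_null"`: `r_actual`, matrix `r_alt`
#'   (`n_alt` x timepoints), `p`, `p_raw`, `alt_seeds`.
#' @export
alternate_seed_test <- function(pathology, conn, actual_seed,
                                mode = "bidirectional", measure = "total",
                                n_alt = 500, rng_seed = 1, replace = FALSE,
                                floor = 1e-12,
                                control = fit_control(refine = FALSE)) {
  if (n_alt < 1) stop("n_alt must be >= 1")
  stopifnot(inherits(conn, "connectome"))
  ord <- order(conn$region_ids)
  conn <- .reorder_conn(conn, ord)
  ps <- summarize_pathology(pathology, measure = measure)
  y_mat <- .align_summary(ps, conn)
  timepoints <- ps$timepoints

  candidates <- setdiff(conn$region_ids, actual_seed)
  if (!actual_seed %in% conn$region_ids)
    stop("unknown actual_seed '", actual_seed, "'")
  if (!replace && n_alt > length(candidates))
    stop("n_alt exceeds the number of non-seed regions; set replace = TRUE")
  alt_seeds <- withr::with_seed(rng_seed,
                                sample(candidates, n_alt, replace = replace))

  Ls <- .mode_laplacians(conn, mode)
  cg <- 10^seq(log10(control$c_range[1]), log10(control$c_range[2]),
               length.out = control$grid_n)
  combos <- as.matrix(expand.grid(rep(list(seq_along(cg)), length(Ls))))
  # full propagator matrices: column s is the propagated vector for seed s
  mats <- lapply(Ls, function(L)
    lapply(cg, function(cc) .propagator_mats(L, cc, timepoints)))

  fit_one <- function(seed_lab) {
    si <- match(seed_lab, conn$region_ids)
    xs <- lapply(mats, function(percs)
      lapply(percs, function(perts) {
        m <- vapply(perts, function(E) E[, si], numeric(nrow(y_mat)))
        dimnames(m) <- dimnames(y_mat)
        m
      }))
    g <- .grid_fit_cached(xs, combos, y_mat, floor)
    if (is.null(g))
      return(stats::setNames(rep(NA_real_, length(timepoints)),
                             colnames(y_mat)))
    coefs <- g$coefs
    xmats <- g$xmats
    if (isTRUE(control$refine)) {
      x0 <- seed_vector(conn, seed_lab)
      lo <- log10(control$c_range[1]); hi <- log10(control$c_range[2])
      obj <- function(u) {
        if (any(u < lo - 1e-9) || any(u > hi + 1e-9)) return(1e300)
        .rate_objective(10^u, Ls, timepoints, x0, y_mat, floor)
      }
      u0 <- log10(cg[g$best])
      o <- if (length(Ls) == 1) {
        du <- (hi - lo) / (control$grid_n - 1)
        op <- stats::optimize(obj, lower = max(lo, u0 - du),
                              upper = min(hi, u0 + du), tol = 1e-6)
        list(par = op$minimum, value = op$objective)
      } else {
        op <- stats::optim(u0, obj, method = "Nelder-Mead",
                           control = list(maxit = control$refine_maxit,
                                          reltol = 1e-10))
        list(par = op$par, value = op$value)
      }
      if (is.finite(o$value) && o$value < g$sse) {
        xmats <- mapply(function(L, cc)
          .propagate_tps(L, cc, timepoints, x0), Ls, 10^o$par,
          SIMPLIFY = FALSE)
        coefs <- .fit_timepoints(y_mat, xmats, floor)$coefs
      }
    }
    .predict_timepoints(y_mat, xmats, coefs, floor)$r
  }

  r_actual <- fit_one(actual_seed)
  r_alt <- t(vapply(alt_seeds, fit_one, numeric(length(timepoints))))
  rownames(r_alt) <- alt_seeds

  ge <- sweep(r_alt, 2, r_actual, ">=")
  n_ge <- colSums(ge, na.rm = TRUE)
  p <- (1 + n_ge) / (1 + n_alt)
  p_raw <- n_ge / n_alt
  structure(list(r_actual = r_actual, r_alt = r_alt, p = p, p_raw = p_raw,
                 alt_seeds = alt_seeds, actual_seed = actual_seed,
                 mode = mode, n_alt = n_alt, rng_seed = rng_seed,
                 timepoints = timepoints),
            class = "seed_null")
}

#' @export
print.seed_null <- function(x, ...) {
  cat(sprintf("seed_null: actual seed %s vs %d alternates (%s mode)\n",
              x$actual_seed, x$n_alt, x$mode))
  print(data.frame(mpi = x$timepoints, r_actual = x$r_actual, p = x$p,
                   row.names = NULL))
  invisible(x)
}

#' Cross-validated comparison of spread model variants
#'
#' Out-of-sample comparison of the Euclidean, anterograde-only,
#' retrograde-only and bidirectional spread models. In each iteration the
#' regions are randomly split into a training and a held-out set; rate
#' constants and regression weights are estimated on the training regions
#' with the same grid-search fitting process as [fit_model()], and
#' performance is the Pearson r between predicted and observed log pathology
#' on the held-out regions, per timepoint. The same region splits are used
#' for every model variant, and held-out r distributions are compared
#' pairwise per timepoint with a two-sided Wilcoxon rank-sum test.
#'
#' @inheritParams alternate_seed_test
#' @param seed_region the experimental seed region.
#' @param modes model variants to compare (euclidean requires coords).
#' @param n_iter number of random splits.
#' @param split_fraction fraction of regions assigned to the training set.
#' @return object of class `"crossval_result"`: `r_test` (named list of
#'   `n_iter` x timepoint matrices), `comparisons` (data.frame of pairwise
#'   Wilcoxon p-values and medians), `unstable` (modes failing to fit on
#'   more than half the iterations).
#' @export
crossval_compare <- function(pathology, conn, seed_region,
                             modes = c("euclidean", "anterograde",
                                       "retrograde", "bidirectional"),
                             measure = "total", n_iter = 500,
                             split_fraction = 0.5, rng_seed = 1,
                             floor = 1e-12,
                             control = fit_control(refine = FALSE)) {
  stopifnot(inherits(conn, "connectome"), n_iter >= 1,
            split_fraction > 0, split_fraction < 1)
  ord <- order(conn$region_ids)
  conn <- .reorder_conn(conn, ord)
  ps <- summarize_pathology(pathology, measure = measure)
  y_mat <- .align_summary(ps, conn)
  timepoints <- ps$timepoints
  n <- nrow(y_mat)
  n_train <- round(split_fraction * n)
  if (n_train < 4 || n - n_train < 3)
    stop("too few regions to support train/test splitting")

  splits <- withr::with_seed(rng_seed, lapply(seq_len(n_iter), function(i) {
    tr <- logical(n)
    tr[sample.int(n, n_train)] <- TRUE
    tr
  }))

  x0 <- seed_vector(conn, seed_region)
  cg <- 10^seq(log10(control$c_range[1]), log10(control$c_range[2]),
               length.out = control$grid_n)

  labels <- make.unique(modes)  # duplicated entries give self-comparison nulls
  r_test <- list()
  unstable <- character(0)
  for (mi in seq_along(modes)) {
    mode <- modes[mi]
    Ls <- .mode_laplacians(conn, mode)
    combos <- as.matrix(expand.grid(rep(list(seq_along(cg)), length(Ls))))
    xs <- lapply(Ls, function(L)
      lapply(cg, function(cc) .propagate_tps(L, cc, timepoints, x0)))
    rm <- matrix(NA_real_, n_iter, length(timepoints),
                 dimnames = list(NULL, colnames(y_mat)))
    n_fail <- 0L
    for (it in seq_len(n_iter)) {
      train <- splits[[it]]
      g <- .grid_fit_cached(xs, combos, y_mat, floor, fit_mask = train)
      if (is.null(g)) { n_fail <- n_fail + 1L; next }
      pt <- .predict_timepoints(y_mat, g$xmats, g$coefs, floor,
                                eval_mask = !train)
      rm[it, ] <- pt$r
    }
    if (n_fail > n_iter / 2) unstable <- c(unstable, labels[mi])
    r_test[[labels[mi]]] <- rm
  }

  pairs <- if (length(labels) >= 2) utils::combn(labels, 2) else
    matrix(character(0), 2, 0)
  comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    m1 <- pairs[1, j]; m2 <- pairs[2, j]
    do.call(rbind, lapply(seq_along(timepoints), function(ti) {
      a <- r_test[[m1]][, ti]; b <- r_test[[m2]][, ti]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      p <- if (n_iter < 2 || length(a) < 2 || length(b) < 2) NA_real_ else
        tryCatch(suppressWarnings(
          stats::wilcox.test(a, b, exact = FALSE)$p.value),
          error = function(e) NA_real_)
      data.frame(mode1 = m1, mode2 = m2, mpi = timepoints[ti],
                 median1 = stats::median(a), median2 = stats::median(b),
                 p = p)
    }))
  }))
  structure(list(r_test = r_test, comparisons = comparisons,
                 unstable = unstable, modes = labels,
                 timepoints = timepoints, n_iter = n_iter,
                 split_fraction = split_fraction, rng_seed = rng_seed),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("crossval_result: %d iterations, %d timepoints\n",
              x$n_iter, length(x$timepoints)))
  med <- vapply(x$r_test, function(m) stats::median(m, na.rm = TRUE),
                numeric(1))
  cat("  median held-out r by mode:\n")
  for (m in names(med)) cat(sprintf("    %-13s %.3f\n", m, med[m]))
  if (length(x$unstable) > 0)
    cat("  unstable modes:", paste(x$unstable, collapse = ", "), "\n")
  invisible(x)
}
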