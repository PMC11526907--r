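#' Composite regional vulnerability from model residuals
#'
#' The residual `epsilon(t)` of the diffusion model is the part of a
#' region's log pathology that connectivity does not explain: positive
#' residuals mean more pathology than predicted (vulnerable), negative mean
#' less (resilient). The composite score averages each region's residuals
#' over the included timepoints — by default the late ones, where the model
#' is strong and residual patterns are mutually consistent — and, when the
#' connectome carries hemisphere structure, over both hemisphere instances
#' of the same anatomical region. Regions masked out of the model at every
#' included timepoint carry no score.
#'
#' @param fitted a [fit_model()] result.
#' @param include_mpi timepoints (months) to average over; must intersect
#'   the fitted timepoints.
#' @param pool_hemispheres average ipsi/contra instances of the same
#'   anatomical region (requires `base_region` on the connectome; otherwise
#'   regions are kept as-is).
#' @return object of class `"vulnerability_map"`: a `data.frame` with
#'   columns `region_id`, `score` (mean residual, log10 pathology units) and
#'   `n_contributing` (number of timepoint-by-hemisphere residuals pooled).
#' @export
composite_vulnerability <- function(fitted, include_mpi = c(1, 3, 6, 9),
                                    pool_hemispheres = TRUE) {
  stopifnot(inherits(fitted, "spread_fit"))
  keep <- fitted$timepoints %in% include_mpi
  if (!any(keep))
    stop("include_mpi has no overlap with the fitted timepoints (",
         paste(fitted$timepoints, collapse = ", "), ")")
  res <- fitted$residuals[, keep, drop = FALSE]

  group <- fitted$region_ids
  if (pool_hemispheres && !is.null(fitted$conn$base_region))
    group <- fitted$conn$base_region
  groups <- unique(group)
  score <- n_contrib <- stats::setNames(numeric(length(groups)), groups)
  for (g in groups) {
    vals <- res[group == g, , drop = FALSE]
    vals <- vals[is.finite(vals)]
    n_contrib[g] <- length(vals)
    score[g] <- if (length(vals) > 0) mean(vals) else NA_real_
  }
  out <- data.frame(region_id = groups, score = unname(score),
                    n_contributing = unname(n_contrib),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("vulnerability_map", "data.frame")
  out
}

#' Extract a named vulnerability score vector
#'
#' @param vuln a [composite_vulnerability()] result (or data.frame with
#'   `region_id` and `score` columns).
#' @param drop_na drop regions without a defined score.
#' @return named numeric vector of scores.
#' @export
vulnerability_scores <- function(vuln, drop_na = TRUE) {
  v <- stats::setNames(vuln$score, vuln$region_id)
  if (drop_na) v <- v[is.finite(v)]
  v
}

#' Correlation matrix of residual patterns across timepoints
#'
#' Pairwise Pearson correlations between the per-region residual vectors of
#' all timepoint (and, when hemisphere structure is present, timepoint by
#' hemisphere) blocks, computed on each pair's shared included regions. High
#' off-diagonal correlation among late timepoints justifies pooling them
#' into one composite vulnerability measure.
#'
#' @param fitted a [fit_model()] result.
#' @param min_shared minimum shared regions for a pair; cells with fewer are
#'   `NA`.
#' @return symmetric correlation matrix with unit diagonal; block labels are
#'   `"<mpi>"` or `"<mpi>:<hemisphere>"`.
#' @export
residual_correlation_matrix <- function(fitted, min_shared = 3) {
  stopifnot(inherits(fitted, "spread_fit"))
  res <- fitted$residuals
  hemi <- fitted$conn$hemisphere
  base <- fitted$conn$base_region
  blocks <- list()
  if (!is.null(hemi) && !is.null(base) &&
      length(unique(hemi[hemi != "none"])) > 1) {
    for (h in unique(hemi)) {
      sel <- hemi == h
      for (ti in seq_along(fitted$timepoints)) {
        v <- stats::setNames(res[sel, ti], base[sel])
        blocks[[sprintf("%g:%s", fitted$timepoints[ti], h)]] <- v
      }
    }
  } else {
    for (ti in seq_along(fitted$timepoints))
      blocks[[sprintf("%g", fitted$timepoints[ti])]] <-
        stats::setNames(res[, ti], fitted$region_ids)
  }
  nb <- length(blocks)
  if (nb < 2) stop("need at least 2 residual vectors")
  M <- matrix(NA_real_, nb, nb, dimnames = list(names(blocks), names(blocks)))
  diag(M) <- 1
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    a <- blocks[[i]]; b <- blocks[[j]]
    shared <- intersect(names(a)[is.finite(a)], names(b)[is.finite(b)])
    if (length(shared) >= min_shared)
      M[i, j] <- M[j, i] <- stats::cor(a[shared], b[shared])
  }
  M
}

#' Timepoint of peak pathology per region
#'
#' For each region, the timepoint at which its mean pathology is maximal;
#' ties are broken toward the earliest timepoint. Regions whose series is
#' all zero (never affected) are flagged `"none"`.
#'
#' @param pathology long pathology table or [summarize_pathology()] result.
#' @param measure pathology measure when `pathology` is long format.
#' @return `data.frame` with `region_id`, `peak_mpi` (numeric, `NA` for
#'   all-zero series) and `status` (`"peak"` or `"none"`).
#' @export
peak_timepoint <- function(pathology, measure = "total") {
  ps <- summarize_pathology(pathology, measure = measure)
  if (length(ps$timepoints) < 2) stop("need at least 2 timepoints")
  mat <- ps$mat
  if (nrow(mat) == 0 || all(is.na(mat))) stop("empty pathology series")
  out <- data.frame(region_id = rownames(mat),
                    peak_mpi = NA_real_, status = "none",
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    v[is.na(v)] <- 0
    if (all(v == 0)) next
    out$peak_mpi[i] <- ps$timepoints[which.max(v)]
    out$status[i] <- "peak"
  }
  out
}
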