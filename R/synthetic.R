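#' Generate a synthetic directed weighted connectome
#'
#' Random sparse directed adjacency with log-normal projection strengths and
#' random 3-D centroids, emulating a mesoscale structural connectome. Weak
#' connectivity from a designated seed-candidate region is guaranteed by
#' adding repair edges from the seed to any disconnected component.
#' Optionally the graph has mirrored two-hemisphere block structure with
#' weak commissural edges (homotopic links at a tenth of the median
#' intrahemispheric weight plus sparse random cross edges).
#'
#' @param n_regions number of regions (even when `hemispheres = TRUE`).
#' @param density expected fraction of realized off-diagonal edges.
#' @param weight_meanlog,weight_sdlog log-normal weight parameters.
#' @param hemispheres mirror the network into two hemispheres.
#' @param rng_seed integer seed; identical seeds reproduce identical
#'   connectomes.
#' @return a [connectome()] with coords (and hemisphere tags plus
#'   `base_region` when mirrored).
#' @export
synth_connectome <- function(n_regions = 40, density = 0.2,
                             weight_meanlog = 0, weight_sdlog = 1,
                             hemispheres = FALSE, rng_seed = 1) {
  stopifnot(n_regions >= 4, density > 0, density <= 1)
  if (hemispheres && n_regions %% 2 != 0)
    stop("n_regions must be even for a two-hemisphere connectome")
  withr::with_seed(rng_seed, {
    if (!hemispheres) {
      ids <- sprintf("R%03d", seq_len(n_regions))
      W <- .rand_adjacency(n_regions, density, weight_meanlog, weight_sdlog)
      coords <- matrix(stats::runif(n_regions * 3, 0, 5000), ncol = 3)
      hemi <- base <- NULL
    } else {
      nh <- n_regions / 2
      base_ids <- sprintf("R%03d", seq_len(nh))
      ids <- c(paste0(base_ids, ".L"), paste0(base_ids, ".R"))
      Wh <- .rand_adjacency(nh, density, weight_meanlog, weight_sdlog)
      W <- matrix(0, n_regions, n_regions)
      W[seq_len(nh), seq_len(nh)] <- Wh
      W[nh + seq_len(nh), nh + seq_len(nh)] <- Wh
      wmed <- stats::median(Wh[Wh > 0])
      for (i in seq_len(nh)) {  # homotopic commissural links, both ways
        W[i, nh + i] <- W[nh + i, i] <- 0.1 * wmed
      }
      cross <- matrix(stats::runif(nh * nh) < density * 0.1, nh, nh)
      diag(cross) <- FALSE
      cw <- matrix(0.1 * stats::rlnorm(nh * nh, weight_meanlog,
                                       weight_sdlog), nh, nh)
      W[seq_len(nh), nh + seq_len(nh)] <-
        W[seq_len(nh), nh + seq_len(nh)] + cross * cw
      W[nh + seq_len(nh), seq_len(nh)] <-
        W[nh + seq_len(nh), seq_len(nh)] + t(cross * cw)
      ch <- matrix(stats::runif(nh * 3, 0, 5000), ncol = 3)
      mirrored <- ch %*% diag(c(-1, 1, 1))
      mirrored[, 1] <- mirrored[, 1] - 500   # keep hemispheres apart
      coords <- rbind(ch, mirrored)
      hemi <- rep(c("ipsi", "contra"), each = nh)
      base <- c(base_ids, base_ids)
    }
    W <- .ensure_weak_connectivity(W)
    connectome(W, region_ids = ids, hemisphere = hemi, coords = coords,
               base_region = base)
  })
}

.rand_adjacency <- function(n, density, meanlog, sdlog) {
  W <- matrix(stats::rlnorm(n * n, meanlog, sdlog), n, n) *
    matrix(stats::runif(n * n) < density, n, n)
  diag(W) <- 0
  W
}

# add seed -> component edges until the graph is weakly connected from
# region 1 (the designated seed candidate)
.ensure_weak_connectivity <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "directed")
  comp <- igraph::components(g, mode = "weak")
  if (comp$no > 1) {
    wmed <- stats::median(W[W > 0])
    seed_comp <- comp$membership[1]
    for (k in setdiff(unique(comp$membership), seed_comp)) {
      j <- which(comp$membership == k)[1]
      W[1, j] <- wmed
    }
  }
  W
}

#' Default per-timepoint regression weights for data generation
#'
#' @param timepoints numeric months.
#' @param b_a,b_r anterograde/retrograde weights (recycled per timepoint).
#' @param b0 intercepts; default drifts slowly upward with timepoint index,
#'   mimicking overall pathology accrual.
#' @return `data.frame` with columns `mpi`, `b0`, `b_a`, `b_r`.
#' @export
synth_coefs <- function(timepoints, b_a = 0.3, b_r = 0.7, b0 = NULL) {
  if (is.null(b0)) b0 <- 0.5 + 0.05 * seq_along(timepoints)
  data.frame(mpi = timepoints, b0 = rep_len(b0, length(timepoints)),
             b_a = rep_len(b_a, length(timepoints)),
             b_r = rep_len(b_r, length(timepoints)))
}

#' Generate pathology data from the diffusion model with known truth
#'
#' Evaluates the bidirectional diffusion equation at the supplied true rate
#' constants and per-timepoint weights, adds planted per-region
#' vulnerability offsets `delta` to the mean log10 pathology, then draws
#' per-mouse observations with i.i.d. normal noise in log10 space and
#' back-transforms to percent area occupied. Regions masked by the
#' reachability floor emit zero pathology.
#'
#' @param conn a [connectome()].
#' @param timepoints months post-injection.
#' @param n_mice mice per timepoint (the design is cross-sectional).
#' @param noise_sd per-mouse log10 noise standard deviation.
#' @param c_a,c_r true anterograde/retrograde rate constants (per month).
#' @param coefs `data.frame` as from [synth_coefs()]; a predictor whose
#'   weight is zero at every timepoint is treated as absent (no masking on
#'   it), enabling single-direction generation.
#' @param delta named per-region offsets in log10 units (default none).
#' @param delta_timepoints timepoints at which the offsets act (default
#'   all); restricting them to late timepoints emulates vulnerability that
#'   only manifests once pathology is established.
#' @param seed_region injected region; defaults to the first region.
#' @param floor reachability floor.
#' @param rng_seed integer seed.
#' @return list with `data` (long [pathology_dataset()]) and `truth` (list
#'   of every generating parameter).
#' @export
synth_pathology <- function(conn, timepoints = c(0.1, 0.2, 0.3, 0.5, 1, 3,
                                                 6, 9),
                            n_mice = 5, noise_sd = 0.1, c_a = 0.5, c_r = 2,
                            coefs = synth_coefs(timepoints), delta = NULL,
                            delta_timepoints = timepoints,
                            seed_region = conn$region_ids[1],
                            floor = 1e-12, rng_seed = 1) {
  stopifnot(inherits(conn, "connectome"), noise_sd >= 0)
  n <- length(conn$region_ids)
  if (is.null(delta)) delta <- stats::setNames(rep(0, n), conn$region_ids)
  delta <- delta[conn$region_ids]
  delta[is.na(delta)] <- 0
  x0 <- seed_vector(conn, seed_region)
  lap <- build_laplacians(conn)
  use_a <- any(coefs$b_a != 0)
  use_r <- any(coefs$b_r != 0)
  if (!use_a && !use_r) stop("at least one predictor weight must be nonzero")
  hemi <- if (is.null(conn$hemisphere)) rep("none", n) else conn$hemisphere

  rows <- withr::with_seed(rng_seed, {
    out <- vector("list", length(timepoints))
    for (ti in seq_along(timepoints)) {
      t <- timepoints[ti]
      xa <- if (use_a) propagate(lap$antero, c_a, t, x0) else NULL
      xr <- if (use_r) propagate(lap$retro, c_r, t, x0) else NULL
      pl <- predict_log(xa, xr, b0 = coefs$b0[ti], b_a = coefs$b_a[ti],
                        b_r = coefs$b_r[ti], floor = floor)
      mu <- pl$yhat + if (t %in% delta_timepoints) delta else 0
      eps <- matrix(stats::rnorm(n * n_mice, 0, noise_sd), n, n_mice)
      vals <- 10^(mu + eps)       # NA where masked
      vals[!pl$mask, ] <- 0
      out[[ti]] <- data.frame(
        mouse_id = rep(sprintf("m%02d_tp%g", seq_len(n_mice), t),
                       each = n),
        mpi = t,
        region_id = rep(conn$region_ids, n_mice),
        hemisphere = rep(hemi, n_mice),
        measure = "total",
        pct_area = as.vector(vals),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  truth <- list(c_a = if (use_a) c_a else NA_real_,
                c_r = if (use_r) c_r else NA_real_,
                coefs = coefs, delta = delta, seed_region = seed_region,
                timepoints = timepoints, n_mice = n_mice,
                noise_sd = noise_sd, floor = floor, rng_seed = rng_seed)
  list(data = pathology_dataset(rows, derive_neurite = FALSE), truth = truth)
}

#' Generate a synthetic expression atlas with planted vulnerability genes
#'
#' A chosen number of planted genes have regional profiles constructed as
#' `true_r * standardized(vuln) + sqrt(1 - true_r^2) * noise`, so their
#' expected sample correlation with the vulnerability map equals `true_r`;
#' the remaining genes are pure noise. Profiles are affine-mapped onto a
#' positive expression scale.
#'
#' @param regions character region ids.
#' @param vuln named numeric vulnerability scores covering `regions`.
#' @param n_genes total genes.
#' @param n_planted number of planted genes (`<= n_genes`).
#' @param true_r target correlation, `|true_r| < 1`.
#' @param base,gain affine map onto the expression scale
#'   (`base + gain * z`, floored at 0.01).
#' @param rng_seed integer seed.
#' @return list with `atlas` (gene x region matrix) and `truth` (planted
#'   gene ids and `true_r`).
#' @export
synth_expression <- function(regions, vuln, n_genes = 1000, n_planted = 50,
                             true_r = 0.6, base = 10, gain = 2,
                             rng_seed = 1) {
  stopifnot(abs(true_r) < 1, n_planted <= n_genes)
  v <- vuln[regions]
  if (anyNA(v)) stop("vuln must cover every region")
  vz <- (v - mean(v)) / stats::sd(v)
  nr <- length(regions)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  atlas <- withr::with_seed(rng_seed, {
    planted <- sort(sample.int(n_genes, n_planted))
    Z <- matrix(stats::rnorm(n_genes * nr), n_genes, nr)
    Z[planted, ] <- true_r * matrix(vz, n_planted, nr, byrow = TRUE) +
      sqrt(1 - true_r^2) * Z[planted, , drop = FALSE]
    A <- pmax(base + gain * Z, 0.01)
    dimnames(A) <- list(gene_ids, regions)
    attr(A, "planted") <- gene_ids[planted]
    A
  })
  planted <- attr(atlas, "planted")
  attr(atlas, "planted") <- NULL
  list(atlas = atlas,
       truth = list(planted = planted, true_r = true_r,
                    n_genes = n_genes, rng_seed = rng_seed))
}

#' The package's reference synthetic scenario
#'
#' One fixed configuration shared by the documentation and the end-to-end
#' tests: a 40-region connectome at density 0.2, the study-style timepoint
#' design {0.1, 0.2, 0.3, 0.5, 1, 3, 6, 9} months with 5 mice per
#' timepoint, log10 noise of 0.1, planted vulnerability offsets of SD 0.5,
#' and a 1,000-gene expression atlas with 50 genes planted at correlation
#' 0.6.
#'
#' @return named list of scenario parameters accepted by
#'   [simulate_scenario()].
#' @export
default_scenario <- function() {
  list(n_regions = 40, density = 0.2, hemispheres = FALSE,
       timepoints = c(0.1, 0.2, 0.3, 0.5, 1, 3, 6, 9), n_mice = 5,
       noise_sd = 0.1, c_a = 0.5, c_r = 2, delta_sd = 0.5,
       n_genes = 1000, n_planted = 50, true_r = 0.6)
}

#' Simulate a full synthetic dataset (connectome, pathology, expression)
#'
#' Generates every input of the pipeline from one scenario configuration
#' and one seed, optionally writing `connectome.tsv`, `pathology.csv`,
#' `expression.tsv` and `truth.json` to a directory. The planted expression
#' genes correlate with the *planted vulnerability offsets*, which is the
#' ground truth the downstream association stage should recover.
#'
#' @param scenario list as from [default_scenario()] (entries may be
#'   overridden).
#' @param rng_seed integer master seed; sub-seeds for each component are
#'   derived from it deterministically.
#' @param out_dir optional output directory.
#' @return list with `conn`, `pathology`, `atlas`, `truth`.
#' @export
simulate_scenario <- function(scenario = default_scenario(), rng_seed = 1,
                              out_dir = NULL) {
  sc <- utils::modifyList(default_scenario(), scenario)
  conn <- synth_connectome(sc$n_regions, sc$density,
                           hemispheres = sc$hemispheres,
                           rng_seed = rng_seed)
  delta <- withr::with_seed(rng_seed + 1000L, stats::setNames(
    stats::rnorm(length(conn$region_ids), 0, sc$delta_sd),
    conn$region_ids))
  sp <- synth_pathology(conn, timepoints = sc$timepoints,
                        n_mice = sc$n_mice, noise_sd = sc$noise_sd,
                        c_a = sc$c_a, c_r = sc$c_r, delta = delta,
                        rng_seed = rng_seed + 2000L)
  se <- synth_expression(conn$region_ids, delta, n_genes = sc$n_genes,
                         n_planted = sc$n_planted, true_r = sc$true_r,
                         rng_seed = rng_seed + 3000L)
  truth <- c(sp$truth, se$truth["planted"], se$truth["true_r"],
             list(scenario = sc, master_seed = rng_seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_connectome(conn, file.path(out_dir, "connectome.tsv"))
    sidecar <- data.frame(
      region_id = conn$region_ids,
      hemisphere = if (is.null(conn$hemisphere)) "none" else
        conn$hemisphere,
      x = conn$coords[, 1], y = conn$coords[, 2], z = conn$coords[, 3])
    utils::write.table(sidecar, file.path(out_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(sp$data, file.path(out_dir, "pathology.csv"),
                     row.names = FALSE, quote = FALSE)
    df <- data.frame(gene = rownames(se$atlas), se$atlas,
                     check.names = FALSE)
    utils::write.table(df, file.path(out_dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(conn = conn, pathology = sp$data, atlas = se$atlas, truth = truth)
}
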