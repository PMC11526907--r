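#' Construct a connectome object
#'
#' A connectome is a weighted directed adjacency matrix over labeled brain
#' regions. The orientation convention is fixed: `W[i, j]` is the projection
#' strength from region `i` to region `j` (soma in `i`, terminals in `j`).
#' Readers of external matrices must transpose on load if the file stores the
#' opposite orientation (see [read_connectome()]).
#'
#' @param W numeric N x N matrix of nonnegative projection strengths with a
#'   zero diagonal. Row/column names, if present, must agree with
#'   `region_ids`.
#' @param region_ids character vector of unique region labels; defaults to
#'   `rownames(W)`.
#' @param hemisphere optional character vector per region, each entry one of
#'   `"ipsi"`, `"contra"`, `"none"`.
#' @param coords optional N x 3 numeric matrix of region centroids
#'   (micrometres); all entries must be finite.
#' @param base_region optional character vector mapping each region to its
#'   anatomical (hemisphere-free) label; used when pooling hemispheres.
#'
#' @return An object of class `"connectome"`: a list with elements `W`,
#'   `region_ids`, `hemisphere`, `coords`, `base_region`.
#' @examples
#' W <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE,
#'             dimnames = list(c("A", "B"), c("A", "B")))
#' conn <- connectome(W)
#' @export
connectome <- function(W, region_ids = rownames(W), hemisphere = NULL,
                       coords = NULL, base_region = NULL) {
  W <- as.matrix(W)
  if (!is.numeric(W) || nrow(W) != ncol(W))
    stop("W must be a square numeric matrix")
  n <- nrow(W)
  if (n < 2) stop("a connectome needs at least 2 regions")
  if (is.null(region_ids))
    region_ids <- sprintf("R%0*d", nchar(as.character(n)), seq_len(n))
  region_ids <- as.character(region_ids)
  if (length(region_ids) != n) stop("region_ids length must equal nrow(W)")
  if (anyDuplicated(region_ids))
    stop("duplicate region_ids: ",
         paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "))
  if (anyNA(W) || any(!is.finite(W))) stop("W contains non-finite entries")
  neg <- which(W < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative weight at W[%s, %s] = %g",
                 region_ids[neg[1, 1]], region_ids[neg[1, 2]],
                 W[neg[1, , drop = FALSE]]))
  if (any(diag(W) != 0)) {
    bad <- which(diag(W) != 0)[1]
    stop(sprintf("nonzero diagonal at region %s (self-projections not allowed)",
                 region_ids[bad]))
  }
  dimnames(W) <- list(region_ids, region_ids)
  if (!is.null(hemisphere)) {
    hemisphere <- as.character(hemisphere)
    if (length(hemisphere) != n)
      stop("hemisphere must have one entry per region")
    if (!all(hemisphere %in% c("ipsi", "contra", "none")))
      stop("hemisphere entries must be 'ipsi', 'contra' or 'none'")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3)
      stop("coords must be an N x 3 matrix")
    if (any(!is.finite(coords))) stop("coords contain non-finite entries")
    rownames(coords) <- region_ids
  }
  if (!is.null(base_region)) {
    base_region <- as.character(base_region)
    if (length(base_region) != n)
      stop("base_region must have one entry per region")
  }
  structure(list(W = W, region_ids = region_ids, hemisphere = hemisphere,
                 coords = coords, base_region = base_region),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- length(x$region_ids)
  dens <- mean(x$W[upper.tri(x$W) | lower.tri(x$W)] > 0)
  cat(sprintf("connectome: %d regions, edge density %.3f\n", n, dens))
  cat(sprintf("  hemisphere tags: %s; coords: %s\n",
              if (is.null(x$hemisphere)) "none" else
                paste(names(table(x$hemisphere)), collapse = "/"),
              if (is.null(x$coords)) "absent" else "present"))
  invisible(x)
}

#' Directional graph Laplacians of a connectome
#'
#' Builds the unnormalized out-strength (anterograde) and in-strength
#' (retrograde) Laplacians. Under the linear diffusion model
#' `dx/dt = -c * L * x`, the anterograde Laplacian moves mass along the edge
#' direction (from soma to axon terminals) and the retrograde Laplacian moves
#' mass against it. With `D_out = diag(rowSums(W))` and
#' `D_in = diag(colSums(W))`:
#' \deqn{L_a = D_{out} - W^T, \qquad L_r = D_{in} - W.}
#' Every column of each Laplacian sums to zero, so total pathology mass is
#' conserved by the propagator, and `L_a(W)` equals `L_r(W^T)`.
#'
#' @param conn a [connectome()] object.
#' @return list with matrices `antero` and `retro`.
#' @examples
#' conn <- connectome(matrix(c(0, 1, 0, 0), 2, 2,
#'                    dimnames = list(c("A", "B"), c("A", "B"))))
#' build_laplacians(conn)
#' @export
build_laplacians <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  W <- conn$W
  list(antero = diag(rowSums(W), nrow(W)) - t(W),
       retro  = diag(colSums(W), nrow(W)) - W)
}

#' Euclidean distance surrogate connectome
#'
#' Null network used to test whether axonal connectivity explains pathology
#' spread beyond mere spatial proximity: regions are linked with symmetric
#' weight decreasing in their Euclidean distance.
#'
#' @param coords N x 3 matrix of region centroids with rownames as region ids
#'   (or supply `region_ids`).
#' @param region_ids character region labels; defaults to `rownames(coords)`.
#' @param kernel `"inverse"` for weight `1/d`, or `"exponential"` for
#'   `exp(-d/d0)`.
#' @param d0 length scale for the exponential kernel; defaults to the median
#'   pairwise distance.
#' @return a [connectome()] with symmetric weights and zero diagonal.
#' @export
euclidean_surrogate <- function(coords, region_ids = rownames(coords),
                                kernel = c("inverse", "exponential"),
                                d0 = NULL) {
  kernel <- match.arg(kernel)
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 regions")
  if (any(!is.finite(coords))) stop("coords contain non-finite entries")
  d <- as.matrix(stats::dist(coords))
  off <- d[upper.tri(d)]
  if (any(off == 0))
    stop("duplicate coordinates for distinct regions (zero distance, infinite weight)")
  W <- switch(kernel,
              inverse = 1 / d,
              exponential = {
                if (is.null(d0)) d0 <- stats::median(off)
                exp(-d / d0)
              })
  diag(W) <- 0
  connectome(W, region_ids = region_ids, coords = coords)
}

#' One-hot seed vector
#'
#' Unit vector that places all initial pathology mass in a single injected
#' region; the starting condition `x0` of the diffusion model.
#'
#' @param conn a [connectome()].
#' @param seed_region region label; must be one of `conn$region_ids`.
#' @return named numeric vector of length N summing to 1, with attribute
#'   `seed_region`.
#' @export
seed_vector <- function(conn, seed_region) {
  stopifnot(inherits(conn, "connectome"))
  ids <- conn$region_ids
  if (length(seed_region) != 1 || !seed_region %in% ids) {
    near <- ids[order(utils::adist(seed_region, ids))]
    stop(sprintf("unknown seed region '%s'; nearest labels: %s", seed_region,
                 paste(utils::head(near, 3), collapse = ", ")))
  }
  x0 <- stats::setNames(as.numeric(ids == seed_region), ids)
  attr(x0, "seed_region") <- seed_region
  x0
}

#' Read a connectome matrix from TSV/CSV
#'
#' Expects a square matrix with a header row and a first column of region
#' labels. The in-memory convention is `W[i, j]` = projection from `i` to `j`;
#' set `orientation = "col_to_row"` to transpose a file stored the other way.
#'
#' @param path path to the matrix file (tab- or comma-delimited, by
#'   extension).
#' @param orientation `"row_to_col"` (default, file rows are source regions)
#'   or `"col_to_row"`.
#' @param sidecar optional path to a TSV with columns `region_id`,
#'   `hemisphere`, `x`, `y`, `z` supplying tags and centroids.
#' @return a [connectome()].
#' @export
read_connectome <- function(path, orientation = c("row_to_col", "col_to_row"),
                            sidecar = NULL) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  W <- as.matrix(tab)
  if (!identical(rownames(W), colnames(W)))
    stop("matrix row and column labels disagree")
  if (orientation == "col_to_row") W <- t(W)
  hemisphere <- coords <- NULL
  if (!is.null(sidecar)) {
    sc <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("region_id", "hemisphere", "x", "y", "z")
    if (!all(need %in% names(sc)))
      stop("sidecar must have columns: ", paste(need, collapse = ", "))
    idx <- match(rownames(W), sc$region_id)
    if (anyNA(idx)) stop("sidecar is missing regions: ",
                         paste(rownames(W)[is.na(idx)], collapse = ", "))
    hemisphere <- sc$hemisphere[idx]
    coords <- as.matrix(sc[idx, c("x", "y", "z")])
  }
  connectome(W, hemisphere = hemisphere, coords = coords)
}

#' Write a connectome matrix to TSV
#'
#' Inverse of [read_connectome()] with the default orientation; round-trips
#' exactly.
#'
#' @param conn a [connectome()].
#' @param path output path.
#' @export
write_connectome <- function(conn, path) {
  stopifnot(inherits(conn, "connectome"))
  df <- data.frame(region_id = conn$region_ids, conn$W, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary checks for a connectome
#'
#' Reports size, density and the mass-conservation property of both
#' Laplacians (all column sums zero); used by the command-line `validate`
#' subcommand.
#'
#' @param conn a [connectome()].
#' @return list with `n_regions`, `density`, `max_colsum_antero`,
#'   `max_colsum_retro`, `conserves_mass`.
#' @export
connectome_checks <- function(conn) {
  L <- build_laplacians(conn)
  ca <- max(abs(colSums(L$antero)))
  cr <- max(abs(colSums(L$retro)))
  scale <- max(1, max(abs(conn$W)))
  list(n_regions = length(conn$region_ids),
       density = mean(conn$W[row(conn$W) != col(conn$W)] > 0),
       max_colsum_antero = ca, max_colsum_retro = cr,
       conserves_mass = (ca / scale < 1e-12) && (cr / scale < 1e-12))
}
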