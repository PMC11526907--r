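#' Read a regional pathology quantification table
#'
#' Long-format CSV as exported by slide-quantification pipelines: one row per
#' mouse, timepoint, region, hemisphere and measure, with percent area
#' occupied by pathology. When the `neurite` measure is absent for a
#' (mouse, mpi, region, hemisphere) group but `total` and `cell_body` are
#' present, neurite pathology is derived as `total - cell_body` (floored at
#' zero, since segmentation masks can overlap slightly).
#'
#' @param path CSV path with columns `mouse_id`, `mpi`, `region_id`,
#'   `hemisphere`, `measure`, `pct_area`.
#' @param derive_neurite derive the missing neurite measure (default TRUE).
#' @return a `data.frame` of class `"pathology_dataset"`.
#' @export
read_pathology <- function(path, derive_neurite = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pathology_dataset(df, derive_neurite = derive_neurite)
}

#' Validate an in-memory pathology table
#'
#' @param df data.frame with the columns documented in [read_pathology()].
#' @param derive_neurite derive neurite = total - cell_body where absent.
#' @return the validated `data.frame`, class `"pathology_dataset"`.
#' @export
pathology_dataset <- function(df, derive_neurite = TRUE) {
  need <- c("mouse_id", "mpi", "region_id", "hemisphere", "measure",
            "pct_area")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("pathology table is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$pct_area) | df$pct_area < 0)
  if (length(bad) > 0)
    stop("negative or non-finite pct_area at rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  known <- c("total", "cell_body", "neurite")
  badm <- which(!df$measure %in% known)
  if (length(badm) > 0)
    stop("unknown measure at rows: ", paste(utils::head(badm, 5), collapse = ", "),
         " (expected total, cell_body or neurite)")
  key <- paste(df$mouse_id, df$mpi, df$region_id, df$hemisphere, df$measure,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop("duplicate (mouse, mpi, region, hemisphere, measure) rows: ",
         paste(utils::head(dup, 5), collapse = ", "))
  if (derive_neurite) {
    gkey <- paste(df$mouse_id, df$mpi, df$region_id, df$hemisphere, sep = "\r")
    tot <- df[df$measure == "total", ]
    cb <- df[df$measure == "cell_body", ]
    has_neu <- unique(gkey[df$measure == "neurite"])
    tkey <- paste(tot$mouse_id, tot$mpi, tot$region_id, tot$hemisphere,
                  sep = "\r")
    ckey <- paste(cb$mouse_id, cb$mpi, cb$region_id, cb$hemisphere, sep = "\r")
    idx <- match(tkey, ckey)
    want <- !is.na(idx) & !(tkey %in% has_neu)
    if (any(want)) {
      neu <- tot[want, ]
      neu$measure <- "neurite"
      neu$pct_area <- pmax(tot$pct_area[want] - cb$pct_area[idx[want]], 0)
      df <- rbind(df, neu)
      rownames(df) <- NULL
    }
  }
  class(df) <- c("pathology_dataset", "data.frame")
  df
}

#' Summarize pathology to a region-by-timepoint matrix of means
#'
#' Averages percent area occupied across mice (and hemisphere rows carrying
#' the same region id) for one measure, producing the observation matrix the
#' diffusion model is fit to.
#'
#' @param x a long pathology `data.frame` (see [read_pathology()]).
#' @param measure one of `"total"`, `"cell_body"`, `"neurite"`.
#' @return object of class `"pathology_summary"`: list with `mat`
#'   (region x timepoint means), numeric `timepoints`, and `measure`.
#' @export
summarize_pathology <- function(x, measure = "total") {
  if (inherits(x, "pathology_summary")) return(x)
  stopifnot(is.data.frame(x))
  x <- x[x$measure == measure, , drop = FALSE]
  if (nrow(x) == 0) stop("no rows with measure '", measure, "'")
  # canonical row order makes the means bit-identical under input reordering
  x <- x[order(x$region_id, x$mpi, x$mouse_id, x$hemisphere), , drop = FALSE]
  tps <- sort(unique(x$mpi))
  regions <- sort(unique(x$region_id))
  agg <- stats::aggregate(pct_area ~ region_id + mpi, data = x, FUN = mean)
  mat <- matrix(NA_real_, length(regions), length(tps),
                dimnames = list(regions, as.character(tps)))
  mat[cbind(match(agg$region_id, regions), match(agg$mpi, tps))] <- agg$pct_area
  structure(list(mat = mat, timepoints = tps, measure = measure),
            class = "pathology_summary")
}
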