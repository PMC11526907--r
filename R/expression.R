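#' Segment-level sequencing quality control
#'
#' Filters profiled segments on the standard sequencing metrics: percent
#' trimmed reads, percent stitched reads, percent aligned reads, sequencing
#' saturation, and percent of genes detected above the limit of
#' quantification. A segment is removed if any metric falls strictly below
#' its threshold; the recorded reason is the first failing metric in the
#' order trimmed, stitched, aligned, saturation, loq.
#'
#' @param metrics `data.frame` with one row per segment and columns
#'   `trimmed_pct`, `stitched_pct`, `aligned_pct`, `saturation_pct`,
#'   `pct_genes_above_loq` (all on the 0-100 scale).
#' @param thresholds named numeric vector of minimum acceptable values;
#'   defaults `c(trimmed = 80, stitched = 80, aligned = 75, saturation = 50,
#'   loq = 3)`.
#' @return list with `kept` (passing rows) and `removed` (failing rows plus
#'   a `reason` column).
#' @export
qc_segments <- function(metrics,
                        thresholds = c(trimmed = 80, stitched = 80,
                                       aligned = 75, saturation = 50,
                                       loq = 3)) {
  cols <- c(trimmed = "trimmed_pct", stitched = "stitched_pct",
            aligned = "aligned_pct", saturation = "saturation_pct",
            loq = "pct_genes_above_loq")
  miss <- setdiff(unname(cols), names(metrics))
  if (length(miss) > 0)
    stop("metrics is missing columns: ", paste(miss, collapse = ", "))
  need <- setdiff(names(cols), names(thresholds))
  if (length(need) > 0)
    stop("thresholds is missing entries: ", paste(need, collapse = ", "))
  vals <- as.matrix(metrics[, cols])
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100))
    stop("all metrics must be finite percentages in [0, 100]")
  reason <- rep(NA_character_, nrow(metrics))
  for (rule in names(cols)) {
    fail <- vals[, cols[rule]] < thresholds[rule]
    reason[is.na(reason) & fail] <- rule
  }
  removed <- metrics[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(kept = metrics[is.na(reason), , drop = FALSE], removed = removed)
}

#' Two-sided single-outlier Grubbs test
#'
#' Tests whether the most extreme observation is an outlier:
#' `G = max |x_i - mean(x)| / sd(x)`, compared to the critical value
#' `G_crit = ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` where `t` is
#' the upper `alpha / (2n)` quantile of the t-distribution with `n - 2`
#' degrees of freedom.
#'
#' @param values numeric vector, `n >= 3`.
#' @param alpha significance level (default 0.01).
#' @return list with `outlier_index` (`NA` if none), `G`, `G_crit`,
#'   `is_outlier`, and `degenerate` (`TRUE` when the sample standard
#'   deviation is zero, in which case no outlier is reported).
#' @export
grubbs_test <- function(values, alpha = 0.01) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("Grubbs test needs at least 3 values")
  s <- stats::sd(values)
  if (s == 0)
    return(list(outlier_index = NA_integer_, G = NA_real_,
                G_crit = NA_real_, is_outlier = FALSE, degenerate = TRUE))
  dev <- abs(values - mean(values))
  i <- which.max(dev)
  G <- dev[i] / s
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  G_crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  out <- G > G_crit
  list(outlier_index = if (out) i else NA_integer_, G = G, G_crit = G_crit,
       is_outlier = out, degenerate = FALSE)
}

#' Gene-level quality control against negative-probe background
#'
#' Per-segment limit of quantification (LOQ) is the geometric mean of the
#' negative-control probes times the squared geometric standard deviation
#' (i.e. two geometric SDs above background, the platform convention; the
#' multiplier is configurable). A gene counts as detected in a segment when
#' its count exceeds that segment's LOQ. Genes are removed, in order, for
#' detection in fewer than `min_detect_frac` of segments, as global
#' outliers (Grubbs test on per-gene mean log2 counts across the dataset),
#' or as local outliers (Grubbs test across genes within a segment); the
#' ledger records the first rule that removed each gene. A keep-list
#' exempts a priori genes from removal.
#'
#' @param counts nonnegative gene x segment count matrix with rownames.
#' @param neg_probe_rows rownames (or indices) of negative-control probe
#'   rows; their counts must be positive.
#' @param alpha Grubbs significance level.
#' @param min_detect_frac minimum fraction of segments with detection.
#' @param geo_sd_mult number of geometric SDs defining the LOQ.
#' @param keep_list gene ids retained regardless of QC performance.
#' @return list with `kept` (gene ids), `removed` (`data.frame` of gene and
#'   first-failing rule among `"global_grubbs"`, `"local_grubbs"`, `"LOQ"`),
#'   and `loq` (per-segment LOQ values).
#' @export
qc_genes <- function(counts, neg_probe_rows, alpha = 0.01,
                     min_detect_frac = 0.01, geo_sd_mult = 2,
                     keep_list = character(0)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(rownames(counts))) stop("counts needs gene rownames")
  if (is.character(neg_probe_rows))
    neg_probe_rows <- match(neg_probe_rows, rownames(counts))
  if (length(neg_probe_rows) < 1 || anyNA(neg_probe_rows))
    stop("need at least one valid negative-probe row")
  neg <- counts[neg_probe_rows, , drop = FALSE]
  if (any(neg <= 0))
    stop("negative-probe counts must be positive to define the LOQ")
  loq <- apply(neg, 2, function(v) {
    gm <- exp(mean(log(v)))
    gsd <- if (length(v) > 1) exp(stats::sd(log(v))) else 1
    gm * gsd^geo_sd_mult
  })

  genes <- setdiff(rownames(counts), rownames(counts)[neg_probe_rows])
  gc <- counts[genes, , drop = FALSE]
  removed <- character(0); rule <- character(0)
  drop_gene <- function(g, why) {
    if (g %in% keep_list) return(invisible(NULL))
    removed <<- c(removed, g); rule <<- c(rule, why)
  }

  detected <- sweep(gc, 2, loq, ">")
  frac <- rowMeans(detected)
  for (g in genes[frac < min_detect_frac]) drop_gene(g, "LOQ")

  pooled <- rowMeans(log2(gc + 1))
  gt <- grubbs_test(pooled, alpha = alpha)
  if (gt$is_outlier) {
    g <- names(pooled)[gt$outlier_index]
    if (!g %in% removed) drop_gene(g, "global_grubbs")
  }

  for (j in seq_len(ncol(gc))) {
    lt <- grubbs_test(log2(gc[, j] + 1), alpha = alpha)
    if (lt$is_outlier) {
      g <- rownames(gc)[lt$outlier_index]
      if (!g %in% removed) drop_gene(g, "local_grubbs")
    }
  }

  list(kept = setdiff(genes, removed),
       removed = data.frame(gene = removed, rule = rule,
                            stringsAsFactors = FALSE, row.names = NULL),
       loq = loq)
}

#' Scaled sigmoidal normalization to [0, 1]
#'
#' Standardizes a vector, passes it through the logistic function, and
#' min-max rescales the result to span exactly [0, 1]. The transform is
#' strictly order-preserving, compresses extreme values, and puts every
#' gene's regional profile on a common scale.
#'
#' @param x finite numeric vector, `n >= 2`.
#' @param center,slope logistic parameters applied to the z-scores:
#'   `1 / (1 + exp(-slope * (z - center)))`.
#' @return numeric vector in [0, 1]; a constant input returns all 0.5 with
#'   attribute `degenerate = TRUE`.
#' @export
sigmoid_scale <- function(x, center = 0, slope = 1) {
  if (any(!is.finite(x))) stop("x must be finite")
  if (length(x) < 2) stop("need at least 2 values")
  s <- stats::sd(x)
  if (s == 0)
    return(structure(rep(0.5, length(x)), degenerate = TRUE,
                     names = names(x)))
  z <- (x - mean(x)) / s
  sig <- 1 / (1 + exp(-slope * (z - center)))
  out <- (sig - min(sig)) / (max(sig) - min(sig))
  names(out) <- names(x)
  out
}

#' Rank-based inverse normal transform
#'
#' Maps values through their ranks to normal quantiles using the Blom
#' offset: `z_i = qnorm((rank_i - 3/8) / (n + 1/4))`, with average ranks for
#' ties. The output is approximately standard normal for tie-free input.
#'
#' @param x numeric vector, `n >= 2`.
#' @return numeric vector of normal scores; an all-tied input returns all
#'   zeros with attribute `degenerate = TRUE`.
#' @export
rank_inverse_normal <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  if (any(!is.finite(x))) stop("x must be finite")
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  names(z) <- names(x)
  if (length(unique(x)) == 1) attr(z, "degenerate") <- TRUE
  z
}

#' Correlate regional gene expression with vulnerability
#'
#' For each gene, the regional expression profile is normalized with the
#' scaled sigmoid, then both the gene profile and the vulnerability scores
#' are rank-inverse-normal transformed, and their Pearson correlation with a
#' two-sided p-value is computed over the shared regions.
#' Benjamini-Hochberg q-values are assigned across all testable genes;
#' constant gene profiles are flagged and excluded from the correction.
#'
#' @param atlas gene x region matrix of nonnegative expression with gene
#'   rownames and region colnames (an expression atlas), or the result of
#'   [read_expression()].
#' @param vuln a [composite_vulnerability()] result or named score vector.
#' @param min_regions minimum shared regions required (default 4).
#' @return `data.frame` of class `"gene_association"` with columns `gene`,
#'   `r`, `p`, `q`, `n`, `flag`.
#' @export
gene_vulnerability_correlation <- function(atlas, vuln, min_regions = 4) {
  atlas <- as.matrix(atlas)
  v <- if (is.data.frame(vuln)) vulnerability_scores(vuln) else
    vuln[is.finite(vuln)]
  shared <- intersect(colnames(atlas), names(v))
  if (length(shared) < min_regions)
    stop("need at least ", min_regions, " regions shared between atlas and ",
         "vulnerability map (found ", length(shared), ")")
  vz <- rank_inverse_normal(v[shared])
  E <- atlas[, shared, drop = FALSE]

  genes <- rownames(E)
  r <- p <- rep(NA_real_, length(genes))
  flag <- rep("", length(genes))
  for (i in seq_along(genes)) {
    e <- E[i, ]
    if (stats::sd(e) == 0) { flag[i] <- "constant"; next }
    gz <- rank_inverse_normal(sigmoid_scale(e))
    ct <- stats::cor.test(gz, vz, method = "pearson",
                          alternative = "two.sided")
    r[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  q <- rep(NA_real_, length(genes))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- data.frame(gene = genes, r = r, p = p, q = q,
                    n = length(shared), flag = flag,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gene_association", "data.frame")
  out
}

#' Read a gene-by-region expression matrix
#'
#' @param path TSV with genes as rows (first column gene ids, header row of
#'   region ids).
#' @return numeric matrix with gene rownames and region colnames.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate region ids")
  if (any(!is.finite(m))) stop("expression matrix contains non-finite values")
  m
}

#' Read a one-symbol-per-line gene list
#'
#' @param path text file, one gene id per line; blank lines and `#` comments
#'   are ignored.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}
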