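# weighted Kolmogorov-Smirnov running-sum enrichment score for one set of
# hit positions within a score-sorted list; returns the signed extreme
# deviation and its position
.gsea_es <- function(sorted_scores, hit, weight = 1) {
  n <- length(sorted_scores)
  w <- abs(sorted_scores)^weight
  inc <- numeric(n)
  wh <- w[hit]
  if (sum(wh) == 0) wh <- rep(1, length(hit))  # all-zero scores in the set
  inc[hit] <- wh / sum(wh)
  miss <- rep(1 / (n - length(hit)), n)
  miss[hit] <- 0
  running <- cumsum(inc - miss)
  i <- which.max(abs(running))
  list(es = running[i], at = i, running = running)
}

#' Preranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov preranked enrichment: genes are
#' sorted by their score (here, correlation with regional vulnerability),
#' the running sum increments by the normalized weighted score at set
#' members and decrements uniformly between them, and the enrichment score
#' ES is the extreme deviation of that walk. The null distribution comes
#' from random gene-label sets of matching size; the normalized score NES
#' divides ES by the mean absolute null ES of matching sign, and p and FDR q
#' are computed per sign as in the standard preranked procedure. Results are
#' deterministic given `rng_seed`.
#'
#' @param scores named numeric vector of per-gene scores (e.g. the `r`
#'   column of [gene_vulnerability_correlation()] named by gene).
#' @param gene_sets named list of character vectors; each set is intersected
#'   with the ranked list first.
#' @param n_perm number of label permutations.
#' @param weight running-sum weighting exponent (1 = classic weighted).
#' @param min_size sets with fewer ranked genes than this are skipped.
#' @param rng_seed integer seed for the permutations.
#' @return `data.frame` of class `"gsea_result"` with columns `set`, `size`,
#'   `es`, `nes`, `p`, `q` and a `leading_edge` list-column of gene ids.
#' @export
preranked_gsea <- function(scores, gene_sets, n_perm = 1000, weight = 1,
                           min_size = 5, rng_seed = 1) {
  stopifnot(!is.null(names(scores)), n_perm >= 1)
  scores <- scores[is.finite(scores)]
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  genes <- names(s)
  n <- length(genes)

  sets <- lapply(gene_sets, function(g) intersect(g, genes))
  skip <- vapply(sets, length, integer(1)) < min_size
  if (any(skip))
    warning("skipping ", sum(skip), " gene set(s) with fewer than ",
            min_size, " ranked genes: ",
            paste(utils::head(names(sets)[skip], 5), collapse = ", "))
  sets <- sets[!skip]
  if (length(sets) == 0)
    return(structure(data.frame(set = character(0), size = integer(0),
                                es = numeric(0), nes = numeric(0),
                                p = numeric(0), q = numeric(0)),
                     leading_edge = list(), class = c("gsea_result",
                                                      "data.frame")))

  obs <- lapply(sets, function(g)
    .gsea_es(s, match(g, genes), weight = weight))
  es <- vapply(obs, `[[`, numeric(1), "es")
  sizes <- vapply(sets, length, integer(1))

  # null ES per set size, shared permutation stream per size
  null_by_size <- withr::with_seed(rng_seed, {
    out <- list()
    for (k in sort(unique(sizes))) {
      out[[as.character(k)]] <- vapply(seq_len(n_perm), function(i)
        .gsea_es(s, sample.int(n, k), weight = weight)$es, numeric(1))
    }
    out
  })

  nes <- p <- rep(NA_real_, length(sets))
  for (i in seq_along(sets)) {
    nul <- null_by_size[[as.character(sizes[i])]]
    same <- nul[sign(nul) == sign(es[i])]
    if (length(same) == 0) same <- abs(nul)
    nes[i] <- es[i] / mean(abs(same))
    p[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
  }

  # FDR per sign on NES, pooling null NES over sets
  null_nes <- unlist(lapply(seq_along(sets), function(i) {
    nul <- null_by_size[[as.character(sizes[i])]]
    pos <- nul[nul >= 0]; negv <- nul[nul < 0]
    c(if (length(pos) > 0) pos / mean(pos) else numeric(0),
      if (length(negv) > 0) negv / mean(abs(negv)) else numeric(0))
  }))
  q <- vapply(seq_along(sets), function(i) {
    if (!is.finite(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(null_nes[null_nes >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(null_nes[null_nes < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  leading <- lapply(seq_along(sets), function(i) {
    at <- obs[[i]]$at
    hit <- match(sets[[i]], genes)
    if (es[i] >= 0) genes[sort(hit[hit <= at])] else
      genes[sort(hit[hit >= at])]
  })
  out <- data.frame(set = names(sets), size = sizes, es = es, nes = nes,
                    p = p, q = q, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "leading_edge") <- stats::setNames(leading, names(sets))
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Filter vulnerability-associated kinases against a differential list
#'
#' Candidate prioritization: keep genes that (i) belong to the supplied
#' kinase class list, (ii) pass the FDR threshold with correlation of the
#' requested sign, and (iii) were independently identified as differentially
#' expressed (e.g. between inclusion-bearing neurons and their neighbors).
#' The result is ordered by correlation, strongest first.
#'
#' @param assoc a [gene_vulnerability_correlation()] table.
#' @param kinase_list character vector of kinase gene ids.
#' @param de_gene_list character vector of differentially expressed gene
#'   ids.
#' @param q_threshold FDR cutoff (genes with `q < q_threshold` pass).
#' @param direction `"positive"` or `"negative"` required sign of `r`.
#' @return character vector of retained genes, ordered by `|r|` descending.
#' @export
kinase_filter <- function(assoc, kinase_list, de_gene_list,
                          q_threshold = 0.05,
                          direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (length(kinase_list) == 0 || length(de_gene_list) == 0)
    stop("kinase_list and de_gene_list must be nonempty")
  sel <- assoc$gene %in% kinase_list &
    !is.na(assoc$q) & assoc$q < q_threshold &
    (if (direction == "positive") assoc$r > 0 else assoc$r < 0) &
    assoc$gene %in% de_gene_list
  hits <- assoc[sel, , drop = FALSE]
  hits$gene[order(abs(hits$r), decreasing = TRUE)]
}
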