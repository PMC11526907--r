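seg_metrics <- function(...) {
  m <- rbind(...)
  df <- as.data.frame(m)
  names(df) <- c("trimmed_pct", "stitched_pct", "aligned_pct",
                 "saturation_pct", "pct_genes_above_loq")
  df$segment <- paste0("s", seq_len(nrow(df)))
  df
}

test_that("segment QC keeps clean segments and names the first failure", {
  qc <- qc_segments(seg_metrics(c(85, 85, 80, 60, 5)))
  expect_equal(nrow(qc$kept), 1)
  expect_equal(nrow(qc$removed), 0)

  qc2 <- qc_segments(seg_metrics(c(79, 85, 80, 60, 5)))
  expect_equal(qc2$removed$reason, "trimmed")
})

test_that("one violation per rule yields five removals with matching reasons", {
  fix <- seg_metrics(c(79, 90, 90, 60, 5),   # trimmed
                     c(90, 79, 90, 60, 5),   # stitched
                     c(90, 90, 74, 60, 5),   # aligned
                     c(90, 90, 90, 49, 5),   # saturation
                     c(90, 90, 90, 60, 2))   # loq
  qc <- qc_segments(fix)
  expect_equal(nrow(qc$kept), 0)
  expect_equal(qc$removed$reason,
               c("trimmed", "stitched", "aligned", "saturation", "loq"))
})

test_that("segment removal count equals the union of per-rule failures", {
  vals <- withr::with_seed(8, matrix(runif(200, 40, 100), 40, 5))
  df <- seg_metrics(vals)
  qc <- qc_segments(df)
  thr <- c(80, 80, 75, 50, 3)
  union_fail <- rowSums(sweep(vals, 2, thr, "<") > 0) > 0
  expect_equal(nrow(qc$removed), sum(union_fail))
})

test_that("Grubbs statistic and critical value follow the t formula", {
  g <- grubbs_test(c(-1, 0, 1), alpha = 0.01)
  expect_equal(g$G, 1)
  n <- 3
  tq <- qt(1 - 0.01 / (2 * n), n - 2)
  expect_equal(g$G_crit, (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2)))
  expect_false(g$is_outlier)

  g2 <- grubbs_test(c(1, 1, 1, 1, 50), alpha = 0.01)
  expect_equal(g2$outlier_index, 5L)
  n <- 5
  x <- c(1, 1, 1, 1, 50)
  expect_equal(g2$G, max(abs(x - mean(x))) / sd(x))
  tq <- qt(1 - 0.01 / (2 * n), n - 2)
  expect_equal(g2$G_crit, (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2)))

  expect_true(grubbs_test(rep(3, 4))$degenerate)
  expect_error(grubbs_test(c(1, 2)), "at least 3")
})

gene_counts <- function(n_genes = 30, n_seg = 50, seed = 4) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n_genes * n_seg, 50), n_genes, n_seg,
                     dimnames = list(sprintf("g%02d", 1:n_genes),
                                     sprintf("s%02d", 1:n_seg)))
    neg <- matrix(rpois(3 * n_seg, 5) + 1, 3, n_seg,
                  dimnames = list(paste0("neg", 1:3), colnames(counts)))
    rbind(counts, neg)
  })
}

test_that("gene QC removes undetected genes at the LOQ boundary rule", {
  counts <- gene_counts()
  counts["g01", ] <- 0                       # never above LOQ
  qc <- qc_genes(counts, paste0("neg", 1:3))
  expect_true("g01" %in% qc$removed$gene)
  expect_equal(qc$removed$rule[qc$removed$gene == "g01"], "LOQ")

  # detected in exactly ceiling(1% of segments) -> kept by the LOQ rule
  counts2 <- gene_counts()
  k <- ceiling(0.01 * ncol(counts2))
  counts2["g02", ] <- 0
  counts2["g02", seq_len(k)] <- 1e4
  qc2 <- qc_genes(counts2, paste0("neg", 1:3))
  expect_false("g02" %in% qc2$removed$gene[qc2$removed$rule == "LOQ"])
})

test_that("a planted extreme gene is removed as a global outlier", {
  counts <- gene_counts()
  counts["g05", ] <- 1e6
  qc <- qc_genes(counts, paste0("neg", 1:3))
  expect_equal(qc$removed$rule[qc$removed$gene == "g05"], "global_grubbs")
  # a keep-listed gene survives regardless of QC performance
  qc2 <- qc_genes(counts, paste0("neg", 1:3), keep_list = "g05")
  expect_true("g05" %in% qc2$kept)
  expect_error(qc_genes(-counts, paste0("neg", 1:3)), "nonnegative")
})

test_that("sigmoid scaling spans [0,1], preserves order, centers symmetric input", {
  x <- c(3, -1, 7, 2, 5)
  s <- sigmoid_scale(x)
  expect_equal(range(s), c(0, 1))
  expect_equal(order(s), order(x))
  expect_equal(sigmoid_scale(c(0, 5, 10)), c(0, 0.5, 1))
  sc <- sigmoid_scale(rep(2, 4))
  expect_equal(as.numeric(sc), rep(0.5, 4))
  expect_true(attr(sc, "degenerate"))
})

test_that("rank inverse normal transform matches the Blom quantiles", {
  z <- rank_inverse_normal(c(10, 2, 30))
  expect_identical(z[1], 0)  # middle of three maps to the median exactly
  expect_equal(sort(z), qnorm(c(0.625 / 3.25, 0.5, 2.625 / 3.25)))
  expect_equal(abs(z[3]), 0.8694, tolerance = 1e-4)

  x <- withr::with_seed(10, rnorm(200))
  z2 <- rank_inverse_normal(x)
  expect_lt(abs(mean(z2)), 1e-8)
  expect_lt(abs(sd(z2) - 1), 0.05)
  expect_equal(order(z2), order(x))

  zt <- rank_inverse_normal(rep(1, 5))
  expect_equal(as.numeric(zt), rep(0, 5))
  expect_true(attr(zt, "degenerate"))
})

test_that("sigmoid before rank-INT changes nothing for tie-free input", {
  x <- withr::with_seed(12, rnorm(50))
  expect_equal(rank_inverse_normal(sigmoid_scale(x)),
               rank_inverse_normal(x), tolerance = 1e-12)
})

test_that("a gene identical to the vulnerability map correlates perfectly", {
  v <- withr::with_seed(14, setNames(rnorm(20), paste0("r", 1:20)))
  atlas <- rbind(match = v + 10, flat = rep(1, 20),
                 noise = withr::with_seed(15, rnorm(20)))
  colnames(atlas) <- names(v)
  assoc <- gene_vulnerability_correlation(atlas, v)
  expect_equal(assoc$r[assoc$gene == "match"], 1, tolerance = 1e-12)
  expect_lt(assoc$p[assoc$gene == "match"], 1e-12)
  expect_equal(assoc$flag[assoc$gene == "flat"], "constant")
  expect_true(is.na(assoc$q[assoc$gene == "flat"]))
})

test_that("BH q-values match the hand-computed toy case and are monotone", {
  v <- setNames(rnorm(10), paste0("r", 1:10))
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(p.adjust(p, "BH"), c(0.04, 0.04, 0.04, 0.5))

  atlas <- withr::with_seed(16, matrix(rnorm(200), 20, 10,
                                       dimnames = list(paste0("g", 1:20),
                                                       names(v))))
  assoc <- gene_vulnerability_correlation(atlas, v)
  o <- order(assoc$p)
  expect_true(all(diff(assoc$q[o]) >= -1e-12))
  expect_true(all(assoc$q >= 0 & assoc$q <= 1))
})

test_that("planted correlated genes are detected with controlled FDP", {
  res <- sapply(1:3, function(s) {
    v <- withr::with_seed(1000 + s, setNames(rnorm(100), paste0("r", 1:100)))
    se <- synth_expression(names(v), v, n_genes = 1050, n_planted = 50,
                           true_r = 0.6, rng_seed = 2000 + s)
    assoc <- gene_vulnerability_correlation(se$atlas, v)
    hit <- assoc$gene[!is.na(assoc$q) & assoc$q < 0.05]
    c(power = mean(se$truth$planted %in% hit),
      fdp = if (length(hit) == 0) 0 else
        mean(!hit %in% se$truth$planted))
  })
  expect_gte(median(res["power", ]), 0.9)
  expect_lte(median(res["fdp", ]), 0.10)
})

test_that("expression and gene-list files round-trip", {
  m <- withr::with_seed(18, matrix(abs(rnorm(12)), 3, 4,
                                   dimnames = list(paste0("g", 1:3),
                                                   paste0("r", 1:4))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression(path), m, tolerance = 1e-12)

  gl <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pak4", "", "# comment", "Pak6"), gl)
  expect_equal(read_gene_list(gl), c("Pak4", "Pak6"))

  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines("setA\tdesc\tg1\tg2\tg3", gmt)
  expect_equal(read_gmt(gmt), list(setA = c("g1", "g2", "g3")))
})
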