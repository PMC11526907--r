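#' Assemble and validate a pipeline configuration
#'
#' Collects file paths and analysis settings for [run_pipeline()]. Every
#' numeric field is validated against the preconditions of the operation it
#' feeds, and cross-field consistency (e.g. an association stage without an
#' expression matrix) is rejected before any computation starts.
#'
#' @param connectome path to the connectome matrix TSV/CSV.
#' @param pathology path to the long pathology CSV.
#' @param seed_region experimental seed region label.
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param expression optional path to the gene x region expression TSV.
#' @param gene_sets optional path to a GMT file (enables the enrichment
#'   stage; requires `expression`).
#' @param kinase_list,de_gene_list optional gene-list paths (enable the
#'   kinase filter stage; require `expression`).
#' @param sidecar optional connectome side-car TSV (hemisphere + coords).
#' @param mode,measure,floor,include_mpi,q_threshold analysis settings, see
#'   [fit_model()], [composite_vulnerability()] and [kinase_filter()].
#' @param n_alt alternate seeds for the seed-specificity test (0 disables).
#' @param n_iter cross-validation iterations (0 disables).
#' @param n_perm gene-set permutations.
#' @param rng_seed master seed for every stochastic stage.
#' @param grid_n,c_range,refine rate-constant search settings, see
#'   [fit_control()].
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(connectome, pathology, seed_region, out_dir,
                            expression = NULL, gene_sets = NULL,
                            kinase_list = NULL, de_gene_list = NULL,
                            sidecar = NULL,
                            mode = "bidirectional", measure = "total",
                            floor = 1e-12, include_mpi = c(1, 3, 6, 9),
                            n_alt = 0, n_iter = 0, n_perm = 1000,
                            rng_seed = 1, q_threshold = 0.05,
                            grid_n = 20, c_range = c(1e-3, 1e2),
                            refine = TRUE) {
  cfg <- list(connectome = connectome, pathology = pathology,
              seed_region = seed_region, out_dir = out_dir,
              expression = expression, gene_sets = gene_sets,
              kinase_list = kinase_list, de_gene_list = de_gene_list,
              sidecar = sidecar, mode = mode, measure = measure,
              floor = floor, include_mpi = include_mpi, n_alt = n_alt,
              n_iter = n_iter, n_perm = n_perm, rng_seed = rng_seed,
              q_threshold = q_threshold, grid_n = grid_n,
              c_range = c_range, refine = refine)
  for (f in c("connectome", "pathology", "expression", "gene_sets",
              "kinase_list", "de_gene_list", "sidecar")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("config: ", f, " file not found: ", p)
  }
  if (is.null(cfg$expression) &&
      (!is.null(cfg$gene_sets) || !is.null(cfg$kinase_list)))
    stop("config: enrichment/kinase stages require an expression matrix")
  if (!is.null(cfg$kinase_list) != !is.null(cfg$de_gene_list))
    stop("config: kinase_list and de_gene_list must be supplied together")
  stopifnot(cfg$mode %in% c("bidirectional", "anterograde", "retrograde",
                            "euclidean"),
            cfg$measure %in% c("total", "cell_body", "neurite"),
            cfg$floor > 0, cfg$n_alt >= 0, cfg$n_iter >= 0,
            cfg$n_perm >= 1, cfg$q_threshold > 0, cfg$q_threshold < 1,
            length(cfg$include_mpi) >= 1)
  fit_control(grid_n = cfg$grid_n, c_range = cfg$c_range)  # validates
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @param overrides named list of values taking precedence over the file.
#' @return a validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  dirn <- dirname(path)
  for (f in c("connectome", "pathology", "expression", "gene_sets",
              "kinase_list", "de_gene_list", "sidecar"))
    if (!is.null(raw[[f]]) && !file.exists(raw[[f]]))
      raw[[f]] <- file.path(dirn, raw[[f]])
  do.call(pipeline_config, raw)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes model fitting, optional seed-specificity and cross-validation
#' checks, vulnerability mapping, and (when expression inputs are
#' configured) gene association, preranked enrichment and kinase filtering,
#' writing every intermediate artifact plus a manifest with input hashes,
#' the configuration, package version and seeds. Reruns with an identical
#' configuration and seeds produce byte-identical outputs; a stage failure
#' aborts with the stage name while earlier outputs are retained.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stages <- character(0)
  outputs <- character(0)
  run_stage <- function(name, expr) {
    say("stage: ", name)
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages <<- c(stages, name)
    res
  }
  emit <- function(path) outputs <<- c(outputs, path)
  ctrl <- fit_control(grid_n = config$grid_n, c_range = config$c_range,
                      refine = config$refine)

  conn <- read_connectome(config$connectome, sidecar = config$sidecar)
  pathology <- read_pathology(config$pathology)

  fitted <- run_stage("fit", {
    f <- fit_model(pathology, conn, config$seed_region, mode = config$mode,
                   measure = config$measure, floor = config$floor,
                   control = ctrl)
    emit(.write_json(list(
      mode = f$mode, seed_region = f$seed_region, rates = as.list(f$rates),
      coefs = f$coefs, sse = f$sse,
      residuals = lapply(seq_along(f$timepoints), function(ti)
        as.list(stats::setNames(f$residuals[, ti], f$region_ids)))),
      file.path(config$out_dir, "fit.json")))
    f
  })

  if (config$n_alt > 0) {
    run_stage("seed_null", {
      sn <- alternate_seed_test(pathology, conn, config$seed_region,
                                mode = config$mode,
                                measure = config$measure,
                                n_alt = config$n_alt,
                                rng_seed = config$rng_seed,
                                floor = config$floor)
      emit(.write_json(list(r_actual = as.list(sn$r_actual),
                            p = as.list(sn$p), p_raw = as.list(sn$p_raw),
                            r_alt = apply(sn$r_alt, 2, as.list),
                            alt_seeds = sn$alt_seeds),
                       file.path(config$out_dir, "seednull.json")))
      sn
    })
  }

  if (config$n_iter > 0) {
    run_stage("crossval", {
      cv_modes <- c(if (!is.null(conn$coords)) "euclidean",
                    "anterograde", "retrograde", "bidirectional")
      cv <- crossval_compare(pathology, conn, config$seed_region,
                             modes = cv_modes,
                             measure = config$measure,
                             n_iter = config$n_iter,
                             rng_seed = config$rng_seed,
                             floor = config$floor)
      emit(.write_json(list(comparisons = cv$comparisons,
                            r_test = lapply(cv$r_test, function(m)
                              apply(m, 2, as.list))),
                       file.path(config$out_dir, "crossval.json")))
      cv
    })
  }

  vuln <- run_stage("vulnerability", {
    v <- composite_vulnerability(fitted, include_mpi = config$include_mpi)
    emit(.write_tsv(v, file.path(config$out_dir, "vulnerability.tsv")))
    pk <- peak_timepoint(pathology, measure = config$measure)
    pk$measure <- config$measure
    emit(.write_tsv(pk[, c("region_id", "measure", "peak_mpi", "status")],
                    file.path(config$out_dir, "peak_timepoints.tsv")))
    v
  })

  assoc <- NULL
  if (!is.null(config$expression)) {
    assoc <- run_stage("association", {
      atlas <- read_expression(config$expression)
      a <- gene_vulnerability_correlation(atlas, vuln)
      emit(.write_tsv(a, file.path(config$out_dir,
                                   "gene_association.tsv")))
      a
    })
  }

  if (!is.null(config$gene_sets)) {
    run_stage("enrichment", {
      sets <- read_gmt(config$gene_sets)
      scores <- stats::setNames(assoc$r, assoc$gene)
      g <- preranked_gsea(scores[!is.na(scores)], sets,
                          n_perm = config$n_perm,
                          rng_seed = config$rng_seed)
      emit(.write_tsv(as.data.frame(g),
                      file.path(config$out_dir, "gsea.tsv")))
      g
    })
  }

  if (!is.null(config$kinase_list)) {
    run_stage("kinase_filter", {
      hits <- kinase_filter(assoc, read_gene_list(config$kinase_list),
                            read_gene_list(config$de_gene_list),
                            q_threshold = config$q_threshold)
      pth <- file.path(config$out_dir, "kinases.txt")
      writeLines(hits, pth)
      emit(pth)
      hits
    })
  }

  inputs <- Filter(Negate(is.null),
                   config[c("connectome", "pathology", "expression",
                            "gene_sets", "kinase_list", "de_gene_list",
                            "sidecar")])
  manifest <- list(
    package = "netspread",
    version = as.character(utils::packageVersion("netspread")),
    config = unclass(config),
    rng_seed = config$rng_seed,
    stages = stages,
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    output_md5 = as.list(tools::md5sum(outputs)))
  .write_json(manifest, file.path(config$out_dir, "manifest.json"))
  say("pipeline complete: ", length(stages), " stages")
  invisible(manifest)
}
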