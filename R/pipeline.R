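#' Default pipeline configuration
#'
#' One nested list mirroring every stage's documented defaults, plus stage
#' on/off flags and a global seed from which each stage derives its own
#' stream by a fixed offset. Round-trips losslessly through JSON via
#' [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param out_dir run directory.
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "pipeline_run", seed = 1) {
  structure(list(
    out_dir = out_dir, seed = seed,
    stages = list(simulate = TRUE, preprocess = TRUE, cluster = TRUE,
                  spatialtime = TRUE, score = TRUE, trajectory = TRUE,
                  crossmap = TRUE, gsea = TRUE),
    simulate = list(n_rows = 32, n_cols = 40),
    preprocess = list(min_fraction = 0.003),
    cluster = list(n_pcs = 20, k_neighbors = 15, resolution = 1.0),
    spatialtime = list(df = 3, q_threshold = 0.05, n_classes = 4),
    score = list(n_bins = 24, n_ctrl = 100, curve_bins = 20),
    trajectory = list(hvg_n = 2000, root = "progenitor"),
    crossmap = list(n_perm = 200, min_shared = 50),
    gsea = list(n_perm = 500, weight = 1)),
    class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- pipeline_config()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]]))
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    else base[[nm]] <- cfg[[nm]]
  }
  base
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

log_stage <- function(msg, ..., quiet = FALSE) {
  if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                              sprintf(msg, ...)))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic
#' control/mutant pair: simulate, preprocess, cluster, SpatialTime trend
#' analysis, module scoring with genotype comparison, trajectory and
#' bimodality, cross-species mapping, and preranked enrichment. Every
#' output is written under `config$out_dir` and recorded in
#' `manifest.json` with its MD5 hash; a rerun with the same config
#' reproduces identical hashes.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  outputs <- character(0)
  emit <- function(stage, file) outputs[[length(outputs) + 1]] <<- file
  on_fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  st_run <- function(stage, fun) {
    if (!isTRUE(config$stages[[stage]])) {
      log_stage("stage %s disabled; skipping", stage, quiet = quiet)
      return(NULL)
    }
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) on_fail(stage, e))
    manifest$stages[[stage]] <<- list(
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    log_stage("stage %s done (%.1fs)", stage,
              manifest$stages[[stage]]$elapsed_s, quiet = quiet)
    out
  }
  env <- new.env()

  st_run("simulate", function() {
    scfg <- synthetic_config(n_rows = config$simulate$n_rows,
                             n_cols = config$simulate$n_cols,
                             seed = config$seed + 100L)
    env$pair <- generate_pair(scfg)
    env$scfg <- scfg
    for (g in c("control", "mutant")) {
      d <- file.path(config$out_dir, g)
      write_synthetic(env$pair[[g]], d)
    }
  })
  if (is.null(env$pair)) {
    log_stage("no simulated input; downstream stages skipped", quiet = quiet)
    return(invisible(manifest))
  }

  st_run("preprocess", function() {
    env$norm <- lapply(env$pair, function(s)
      normalize_log_cpm(filter_genes(s$section,
                                     config$preprocess$min_fraction)))
  })

  st_run("cluster", function() {
    nc <- env$norm$control
    emb <- run_pca(nc, n_components = config$cluster$n_pcs)
    env$clusters <- cluster_graph(emb, config$cluster$k_neighbors,
                                  config$cluster$resolution,
                                  seed = config$seed + 200L)
    env$emb <- emb
    mk <- find_markers(nc, env$clusters)
    env$markers <- mk
    utils::write.table(data.frame(barcode = names(env$clusters$cluster),
                                  cluster = env$clusters$cluster),
                       file.path(config$out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(mk, file.path(config$out_dir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  st_run("spatialtime", function() {
    env$st <- lapply(env$pair, function(s)
      assign_spatialtime(s$section, s$truth$plane))
    tr <- fit_gene_trends(env$norm$control, env$st$control,
                          df = config$spatialtime$df,
                          q_threshold = config$spatialtime$q_threshold)
    tr <- classify_trends(tr, k = config$spatialtime$n_classes)
    env$trends <- tr
    utils::write.table(tr$table, file.path(config$out_dir, "trends.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(env$st$control,
                       file.path(config$out_dir, "spatialtime.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  st_run("score", function() {
    if (is.null(env$st)) stop("requires the spatialtime stage")
    cat0 <- env$pair$control$truth$gene_catalog
    mods <- split(cat0$gene[cat0$role == "module"],
                  cat0$module[cat0$role == "module"])
    # joint scoring of the pair: one shared expression ranking, so the
    # genotype contrast is measured against a common baseline
    nm_all <- bind_normalized(env$norm$control, env$norm$mutant)
    n_c <- nrow(env$norm$control$values)
    rows <- list()
    for (m in names(mods)) {
      ms <- score_module(nm_all, intersect(mods[[m]], colnames(nm_all$values)),
                         n_bins = config$score$n_bins,
                         n_ctrl = config$score$n_ctrl,
                         seed = config$seed + 300L, name = m)
      cmp <- compare_genotypes(
        ms$score[seq_len(n_c)], env$st$control,
        ms$score[-seq_len(n_c)], env$st$mutant,
        n_bins = config$score$curve_bins,
        n_perm = 200, seed = config$seed + 301L)
      rows[[m]] <- data.frame(module = m, delta_auc = cmp$delta_auc,
                              peak_shift = cmp$peak_shift, p = cmp$p)
    }
    env$module_cmp <- do.call(rbind, rows)
    utils::write.table(env$module_cmp,
                       file.path(config$out_dir, "module_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  st_run("trajectory", function() {
    if (is.null(env$clusters)) stop("requires the cluster stage")
    # root at the cluster with most spots in the first (nearest-plane) domain
    dom <- env$pair$control$truth$domain_of_spot
    first_dom <- names(env$scfg$domain_spec)[1]
    tab <- table(env$clusters$cluster, dom[names(env$clusters$cluster)])
    root <- as.integer(rownames(tab)[which.max(tab[, first_dom])])
    tj <- infer_trajectory(env$norm$control, env$clusters, root,
                           hvg_n = min(config$trajectory$hvg_n,
                                       ncol(env$norm$control$values)))
    env$trajectory <- tj
    utils::write.table(data.frame(barcode = names(tj$pseudotime),
                                  pseudotime = tj$pseudotime,
                                  cluster = tj$cluster),
                       file.path(config$out_dir, "pseudotime.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  st_run("crossmap", function() {
    if (is.null(env$markers)) stop("requires the cluster stage")
    op <- generate_ortholog_pair(env$scfg, scramble = 0)
    na <- normalize_log_cpm(filter_genes(op$a$section))
    nb <- normalize_log_cpm(filter_genes(op$b$section))
    cla <- factor(op$a$truth$domain_of_spot)
    clb <- factor(op$b$truth$domain_of_spot)
    mka <- find_markers(na, as.integer(cla))
    mkb <- find_markers(nb, as.integer(clb))
    paired <- harmonize_orthologs(mka, mkb, ortholog_map(op$orthologs),
                                  min_shared = config$crossmap$min_shared)
    co <- cluster_correspondence(paired, n_perm = config$crossmap$n_perm,
                                 seed = config$seed + 400L)
    env$correspondence <- co
    utils::write.table(as.data.frame(co$similarity),
                       file.path(config$out_dir, "correspondence.tsv"),
                       sep = "\t", quote = FALSE)
    jsonlite::write_json(list(a_to_b = as.list(co$best_a_to_b),
                              b_to_a = as.list(co$best_b_to_a)),
                         file.path(config$out_dir, "best_matches.json"),
                         auto_unbox = TRUE)
  })

  st_run("gsea", function() {
    if (is.null(env$trends)) stop("requires the spatialtime stage")
    tb <- env$trends$table
    rl <- ranked_list(tb$gene, tb$stat)
    cat0 <- env$pair$control$truth$gene_catalog
    sets <- split(cat0$gene[cat0$role == "gradient"],
                  cat0$class[cat0$role == "gradient"])
    env$gsea <- preranked_significance(rl, sets,
                                       n_perm = config$gsea$n_perm,
                                       weight = config$gsea$weight,
                                       seed = config$seed + 500L)
    utils::write.table(env$gsea, file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  files <- list.files(config$out_dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  manifest$outputs <- lapply(stats::setNames(files, files), function(f)
    unname(tools::md5sum(file.path(config$out_dir, f))))
  manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
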