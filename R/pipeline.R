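# End-to-end orchestration: simulate -> microarray -> qPCR -> motif scan ->
# enrichment -> co-expression, with per-stage TSV outputs and a manifest
# that is sufficient to reproduce the run.

#' Pipeline configuration
#'
#' @param out_dir run directory (created if needed).
#' @param seed master seed, fed to the simulation config.
#' @param sim a [sim_config()] (defaults to `sim_config(seed = seed)`).
#' @param p_threshold motif-scan p-value threshold.
#' @param strands `"both"` or `"forward"`.
#' @param background `"uniform"` or `"estimate"` (0-order from the scanned
#'   promoters).
#' @param granularity score-grid step for scanning.
#' @param top_fraction fraction of ranked genes selected as differentially
#'   expressed (default 0.2, split into up/down by fold-change sign).
#' @param k cluster count or `"auto"` for the sqrt(n/2) rule.
#' @param restarts k-means restarts.
#' @param stages character vector of stages to run, in pipeline order.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(seed = seed),
                            p_threshold = 1e-4,
                            strands = c("both", "forward"),
                            background = c("uniform", "estimate"),
                            granularity = 0.01,
                            top_fraction = 0.2, k = "auto", restarts = 25L,
                            stages = c("simulate", "array", "qpcr", "scan",
                                       "enrich", "coexpr")) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            top_fraction > 0, top_fraction <= 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 p_threshold = p_threshold,
                 strands = match.arg(strands),
                 background = match.arg(background),
                 granularity = granularity, top_fraction = top_fraction,
                 k = k, restarts = restarts, stages = stages),
            class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  partial <- paste0(path, ".partial")
  utils::write.table(df, partial, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  file.rename(partial, path)
  path
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages on a synthetic study bundle, writes
#' per-stage TSV outputs plus a JSON manifest (seed, parameters, parameter
#' hash, output checksums) into the run directory, and returns the in-memory
#' results. Identical config and seed give identical manifest checksums.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the stage results (`study`, `de`, `sets`,
#'   `stability`, `clusters`, `scan`, `enrichment`, `coexpr`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  outputs <- character(0)
  msg <- function(...) message("[nacbs] ", ...)

  msg("simulate: generating study bundle (seed ", config$seed, ")")
  res$study <- .stage("simulate", gen_study(config$sim))

  if ("array" %in% config$stages) {
    msg("array: preprocessing and differential ranking")
    res <- .stage("array", {
      arr <- res$study$microarray
      corr <- background_correct_half(arr$raw, arr$background)
      norm <- quantile_normalize(log2(corr))
      filt <- filter_low_signal(2^norm, arr$background, groups = arr$groups)
      kept <- filt$kept
      rep_map <- dedup_probes(
        arr$probe_info[arr$probe_info$probe_id %in% kept, , drop = FALSE],
        norm[kept, , drop = FALSE])
      expr <- norm[rep_map$probe_id, , drop = FALSE]
      rownames(expr) <- rep_map$target_id
      de <- rank_differential(expr, arr$groups, c("NS", "SEN"))
      top <- select_top(de, max(1L, floor(config$top_fraction * nrow(de))))
      fc <- de$log2fc[match(top$genes, de$gene_id)]
      res$de <- de
      res$de_sets <- list(up = sort(top$genes[fc > 0]),
                          down = sort(top$genes[fc < 0]))
      outputs <- c(outputs,
                    .write_tsv(de, file.path(config$out_dir, "de_table.tsv")))
      writeLines(top$genes,
                 file.path(config$out_dir, "selected_genes.txt"))
      outputs <- c(outputs, file.path(config$out_dir, "selected_genes.txt"))
      res
    })
  }

  if ("qpcr" %in% config$stages) {
    msg("qpcr: Ct summarization, reference stability, clustering")
    res <- .stage("qpcr", {
      ctd <- res$study$ct
      summ <- summarize_ct_table(ctd$ct_table)
      refs <- ctd$ref_genes
      ref_q <- normalize_expression(summ$ct[refs, , drop = FALSE],
                                    max(summ$ct[refs, ], na.rm = TRUE))
      res$stability <- reference_stability(ref_q)
      best_ref <- res$stability$gene_id[res$stability$rank == 1L]
      target <- setdiff(rownames(summ$ct), refs)
      expr <- normalize_expression(
        summ$ct[target, , drop = FALSE],
        matrix(summ$ct[best_ref, ], nrow = length(target),
               ncol = ncol(summ$ct), byrow = TRUE))
      chl <- res$study$panel$chlorophyll
      panel <- expression_panel(expr, chl)
      k <- if (identical(config$k, "auto")) choose_k(nrow(expr)) else
        as.integer(config$k)
      res$clusters <- cluster_profiles(panel, k = k, seed = config$seed,
                                       restarts = config$restarts)
      res$k_used <- k
      outputs <- c(outputs,
        .write_tsv(res$stability,
                   file.path(config$out_dir, "reference_stability.tsv")),
        .write_tsv(data.frame(gene_id = names(res$clusters$assignment),
                              cluster = unname(res$clusters$assignment)),
                   file.path(config$out_dir, "clusters.tsv")),
        .write_tsv(data.frame(cluster = seq_len(res$clusters$k),
                              res$clusters$centroids, check.names = FALSE),
                   file.path(config$out_dir, "centroids.tsv")))
      res
    })
  }

  if ("scan" %in% config$stages) {
    msg("scan: FIMO-style scan of ", length(res$study$promoters),
        " promoters x 7 models")
    res <- .stage("scan", {
      bg <- if (config$background == "estimate")
        estimate_background(res$study$promoters) else background_freq()
      res$scan <- scan_promoter_sets(
        build_all_default(), res$study$promoters, sets = res$study$sets,
        bg = bg, p_threshold = config$p_threshold,
        strands = config$strands, granularity = config$granularity)
      res$scan_bg <- bg
      outputs <- c(outputs,
        .write_tsv(res$scan$counts,
                   file.path(config$out_dir, "hit_counts.tsv")))
      res
    })
  }

  if ("enrich" %in% config$stages) {
    msg("enrich: hypergeometric over-representation")
    res <- .stage("enrich", {
      res$enrichment <- enrichment_report(
        res$scan$hit_sets, names(res$study$promoters), res$study$sets)
      outputs <- c(outputs,
        .write_tsv(as.data.frame(res$enrichment),
                   file.path(config$out_dir, "enrichment.tsv")))
      res
    })
  }

  if ("coexpr" %in% config$stages) {
    msg("coexpr: rank-bias analysis")
    res <- .stage("coexpr", {
      cx <- res$study$coexpr
      lists <- build_coexpression_lists(cx$expr, cx$seed_gene)
      cl <- lists[[cx$seed_gene]]
      ra <- ranks_of_set(cl, cx$coregulated)
      rb <- ranks_of_set(cl, cx$independent)
      res$coexpr <- list(
        bias = rank_bias_test(ra, rb),
        hist_coregulated = rank_distribution(cl, cx$coregulated),
        hist_independent = rank_distribution(cl, cx$independent))
      outputs <- c(outputs, .write_tsv(
        data.frame(bin = seq_along(res$coexpr$hist_coregulated),
                   coregulated = as.integer(res$coexpr$hist_coregulated),
                   independent = as.integer(res$coexpr$hist_independent)),
        file.path(config$out_dir, "rank_histograms.tsv")))
      res
    })
  }

  params <- config[setdiff(names(config), c("out_dir", "sim"))]
  params$sim <- unclass(config$sim)
  params$sim$site_weights <- unclass(params$sim$site_weights)
  param_file <- file.path(config$out_dir, "parameters.json")
  jsonlite::write_json(params, param_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "nacbs",
    version = as.character(utils::packageVersion("nacbs")),
    seed = config$seed,
    k_used = res$k_used,
    parameter_hash = unname(tools::md5sum(param_file)),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  msg("done: ", config$out_dir)
  invisible(res)
}
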