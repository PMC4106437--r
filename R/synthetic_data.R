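# Synthetic-data generators: promoters with planted motifs, redundant-probe
# microarrays, archetype senescence panels, Ct tables and
# correlation-structured co-expression matrices, each paired with a ground
# truth so parameter recovery is measurable. Default scale is about one
# sixth of a genome-wide promoter study (2000 promoters instead of 12643),
# with the differentially-expressed set sizes scaled in proportion.

#' Simulation configuration
#'
#' Collects the sizes, rates and noise levels of the synthetic study. The
#' defaults describe the conditions the rest of the package is exercised
#' under: 2000 promoters of 1000 bp (a 12643-promoter study scaled by ~1/6),
#' up/down set sizes 175/210 (scaled from 1106/1329), a baseline planted
#' NACBS frequency of 10% of promoters with 30% in the up set, a
#' 7-archetype 10-sample expression panel with lognormal noise (sd 0.2 log2
#' units), Gaussian Ct noise of 0.15 cycles with 2% outlier wells, and four
#' candidate reference genes of graded stability.
#'
#' @param seed integer seed.
#' @param n_promoters,promoter_length promoter universe dimensions.
#' @param background 0-order background probabilities.
#' @param n_up,n_down sizes of the up-/down-regulated promoter sets.
#' @param plant_frac_universe,plant_frac_up,plant_frac_down planted-motif
#'   fractions for unassigned, up-set and down-set promoters.
#' @param genes_per_cluster genes per expression archetype (7 archetypes).
#' @param n_samples senescence panel size (>= 4).
#' @param panel_noise_sd lognormal noise sd, log2 units.
#' @param ct_noise_sd Gaussian Ct replicate noise, cycles.
#' @param ct_outlier_rate fraction of wells given an aberrant Ct shift.
#' @param ref_noise_sds per-candidate reference-gene noise sds, most stable
#'   first.
#' @param n_array_genes,n_de,de_log2fc,array_noise_sd,arrays_per_group,
#'   dead_probe_frac microarray generator parameters.
#' @param coexpr_n_genes,coexpr_n_samples,coexpr_set_size,coexpr_noise_sd
#'   co-expression generator parameters.
#' @param site_weights [weight_scheme()] used for *planted* sites in
#'   [gen_study()]. Near-deterministic by default: a genomic binding site is
#'   a concrete near-consensus word, while the soft default search weights
#'   describe the degeneracy the scanner must tolerate.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_promoters = 2000L, promoter_length = 1000L,
                       background = background_freq(),
                       n_up = 175L, n_down = 210L,
                       plant_frac_universe = 0.10,
                       plant_frac_up = 0.30,
                       plant_frac_down = 0.10,
                       genes_per_cluster = 13L, n_samples = 10L,
                       panel_noise_sd = 0.2,
                       ct_noise_sd = 0.15, ct_outlier_rate = 0.02,
                       ref_noise_sds = c(0.05, 0.6, 0.7, 0.8, 0.9,
                                         1.0, 1.1, 1.2),
                       n_array_genes = 300L, n_de = 50L, de_log2fc = 4,
                       array_noise_sd = 0.5,
                       arrays_per_group = c(3L, 3L),
                       dead_probe_frac = 0.05,
                       coexpr_n_genes = 150L, coexpr_n_samples = 20L,
                       coexpr_set_size = 40L, coexpr_noise_sd = 0.5,
                       site_weights = weight_scheme(0.997, 0.995,
                                                    floor = 5e-4)) {
  cfg <- as.list(environment())
  cfg$background <- background_freq(background)
  stopifnot(cfg$n_up + cfg$n_down <= cfg$n_promoters,
            all(c(plant_frac_universe, plant_frac_up, plant_frac_down) >= 0),
            all(c(plant_frac_universe, plant_frac_up, plant_frac_down) <= 1),
            n_samples >= 4L)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate background promoter sequences
#'
#' i.i.d. 0-order sequences; deterministic for a given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return named character vector of promoter sequences.
#' @export
gen_promoters <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_promoters
  len <- cfg$promoter_length
  chars <- sample(DNA_BASES, n * len, replace = TRUE, prob = cfg$background)
  seqs <- apply(matrix(chars, nrow = n), 1L, paste, collapse = "")
  names(seqs) <- sprintf("prom_%05d", seq_len(n))
  seqs
}

#' Plant motif instances into promoters
#'
#' Writes one word sampled from the model's letter probabilities at a
#' uniform random position, on a uniform random strand, into a fraction of
#' the promoters (or of `ids` if given).
#'
#' @param promoters named character vector of sequences.
#' @param model a `motif_model`.
#' @param fraction fraction of the target promoters to modify.
#' @param ids optional subset of promoter ids to plant into.
#' @param seed optional seed (`NULL` = use the current RNG stream).
#' @return list with `promoters` (modified sequences) and `truth`
#'   (data.frame `promoter_id`, `motif`, `position` 0-based, `strand`).
#' @export
plant_motif <- function(promoters, model, fraction, ids = NULL,
                        seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  validate_motif(model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ids)) ids <- names(promoters)
  stopifnot(all(ids %in% names(promoters)))
  L <- model$length
  if (any(nchar(promoters[ids]) < L)) {
    stop("motif longer than a target promoter", call. = FALSE)
  }
  n_plant <- round_half_up(fraction * length(ids))
  truth <- data.frame(promoter_id = character(0), motif = character(0),
                      position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (n_plant == 0L) return(list(promoters = promoters, truth = truth))
  chosen <- sample(ids, n_plant)
  pos <- integer(n_plant)
  strand <- character(n_plant)
  for (i in seq_len(n_plant)) {
    id <- chosen[i]
    word <- paste(apply(model$probs, 1L,
                        function(p) sample(DNA_BASES, 1L, prob = p)),
                  collapse = "")
    strand[i] <- sample(c("+", "-"), 1L)
    if (strand[i] == "-") word <- revcomp_chr(word)
    pos[i] <- sample.int(nchar(promoters[[id]]) - L + 1L, 1L) - 1L
    substr(promoters[[id]], pos[i] + 1L, pos[i] + L) <- word
  }
  list(promoters = promoters,
       truth = data.frame(promoter_id = chosen, motif = model$name,
                          position = pos, strand = strand,
                          stringsAsFactors = FALSE))
}

# The seven senescence expression archetypes over pseudotime s in [0, 1]
# (samples ordered by decreasing chlorophyll), log2 scale relative to the
# non-senescent baseline. Amplitudes: the moderate riser spans 2 log2 units
# and the early riser that levels off spans 4 (the two canonical mid
# clusters); the single extreme riser mimics an isocitrate-lyase-like gene
# (~11.6 log2 units), the late strong riser ~8.
archetype_profiles <- function(n_samples = 10L) {
  s <- seq(0, 1, length.out = n_samples)
  rbind(
    extreme_riser   = 11.6 * pmax(0, (s - 0.7) / 0.3)^3,
    late_strong     = 8 * s^3,
    late_peak       = 5 * exp(-((s - 0.78) / 0.16)^2),
    moderate_riser  = 2 * s,
    early_riser     = 4 * (1 - exp(-4 * s)) / (1 - exp(-4)),
    flat            = 0.8 * exp(-((s - 0.5) / 0.22)^2),
    late_down       = -3 * s^2)
}

#' Generate a senescence expression panel with known cluster structure
#'
#' Seven archetype profiles (see the package vignette), `genes_per_cluster`
#' genes each, multiplicative lognormal noise, over a strictly decreasing
#' synthetic chlorophyll series.
#'
#' @param cfg a [sim_config()].
#' @return list with `panel` (an [expression_panel()]) and `truth`
#'   (data.frame `gene_id`, `cluster`, `archetype`).
#' @export
gen_expression_panel <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  arch <- archetype_profiles(cfg$n_samples)
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  chlorophyll <- stats::setNames(
    round(48 * exp(-0.33 * (seq_len(cfg$n_samples) - 1L)), 3), samples)
  g <- cfg$genes_per_cluster
  expr <- matrix(NA_real_, 7L * g, cfg$n_samples,
                 dimnames = list(NULL, samples))
  gene_id <- character(7L * g)
  cluster <- integer(7L * g)
  for (a in 1:7) {
    for (j in seq_len(g)) {
      i <- (a - 1L) * g + j
      gene_id[i] <- sprintf("gene_c%d_%02d", a, j)
      cluster[i] <- a
      expr[i, ] <- 2^(arch[a, ] + stats::rnorm(cfg$n_samples, 0,
                                               cfg$panel_noise_sd))
    }
  }
  rownames(expr) <- gene_id
  list(panel = expression_panel(expr, chlorophyll),
       truth = data.frame(gene_id = gene_id, cluster = cluster,
                          archetype = rownames(arch)[cluster],
                          stringsAsFactors = FALSE))
}

#' Generate a redundant-probe microarray data set
#'
#' Genes carry 1-4 probes with distinct distances to the target 3' end and
#' mild distance attenuation; differentially expressed genes are shifted by
#' the true log2 fold change in the second group; a fraction of probes are
#' "dead" (signal at or below background). Background is an additive matrix
#' around 30 intensity units.
#'
#' @param cfg a [sim_config()].
#' @return list with `raw`, `background` (probe x array matrices), `groups`
#'   (array condition labels), `probe_info` (`probe_id`, `target_id`,
#'   `dist_to_3prime`, `dead`) and `truth` (`gene_id`, `de`, `log2fc`).
#' @export
gen_microarray <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 2L)
  ng <- cfg$n_array_genes
  stopifnot(cfg$n_de <= ng)
  genes <- sprintf("gene_%04d", seq_len(ng))
  de <- c(rep(TRUE, cfg$n_de), rep(FALSE, ng - cfg$n_de))
  log2fc <- ifelse(de, cfg$de_log2fc, 0)
  base <- stats::runif(ng, 8, 12)
  n_arr <- sum(cfg$arrays_per_group)
  groups <- rep(c("NS", "SEN"), times = cfg$arrays_per_group)
  arr_names <- paste0(groups,
                      stats::ave(seq_len(n_arr), groups, FUN = seq_along))

  n_probes <- sample(1:4, ng, replace = TRUE)
  probe_gene <- rep(seq_len(ng), n_probes)
  total_p <- length(probe_gene)
  probe_id <- sprintf("probe_%05d", seq_len(total_p))
  dist3 <- unlist(lapply(n_probes, function(np)
    sort(sample.int(900L, np) - 1L)), use.names = FALSE)
  dead <- stats::runif(total_p) < cfg$dead_probe_frac

  bg <- matrix(30 + stats::rnorm(total_p * n_arr, 0, 2), total_p, n_arr,
               dimnames = list(probe_id, arr_names))
  bg <- pmax(bg, 5)
  shift <- outer(log2fc[probe_gene], as.numeric(groups == "SEN"))
  lsig <- base[probe_gene] - dist3 / 1500 + shift +
    matrix(stats::rnorm(total_p * n_arr, 0, cfg$array_noise_sd),
           total_p, n_arr)
  raw <- 2^lsig + bg
  raw[dead, ] <- bg[dead, ] * matrix(stats::runif(sum(dead) * n_arr,
                                                  0.7, 1.0),
                                     sum(dead), n_arr)
  dimnames(raw) <- dimnames(bg)
  list(raw = raw, background = bg, groups = groups,
       probe_info = data.frame(probe_id = probe_id,
                               target_id = genes[probe_gene],
                               dist_to_3prime = dist3, dead = dead,
                               stringsAsFactors = FALSE),
       truth = data.frame(gene_id = genes, de = de, log2fc = log2fc,
                          stringsAsFactors = FALSE))
}

#' Generate a qPCR Ct table from an expression panel
#'
#' Each gene/sample well gets three replicate Ct values
#' `ref_base - log2(expression) + noise`; four candidate reference genes of
#' graded stability are appended (the most stable at base Ct equal to
#' `ref_base`, so zero-noise normalization against it inverts the panel
#' exactly); outlier wells receive a 3-8 cycle shift in one replicate.
#'
#' @param panel an [expression_panel()].
#' @param cfg a [sim_config()].
#' @param ref_base Ct of the most stable reference gene (default 15).
#' @return list with `ct_table` (long data.frame `gene_id`, `sample_id`,
#'   `replicate`, `ct`), `ref_genes` (ids, most stable first) and `truth`
#'   (`outliers` data.frame, `ref_noise_sds`).
#' @export
gen_ct_table <- function(panel, cfg = sim_config(), ref_base = 15) {
  set.seed(cfg$seed + 3L)
  samples <- colnames(panel$expr)
  genes <- rownames(panel$expr)
  refs <- sprintf("REF%d", seq_along(cfg$ref_noise_sds))
  ref_bases <- ref_base + 5 * (seq_along(refs) - 1L)

  grid <- expand.grid(gene_id = c(genes, refs), sample_id = samples,
                      replicate = 1:3, stringsAsFactors = FALSE)
  true_ct <- ifelse(
    grid$gene_id %in% refs,
    ref_bases[match(grid$gene_id, refs)],
    ref_base - log2(panel$expr[cbind(
      match(grid$gene_id, genes), match(grid$sample_id, samples))]))
  noise_sd <- ifelse(grid$gene_id %in% refs,
                     cfg$ref_noise_sds[match(grid$gene_id, refs)],
                     cfg$ct_noise_sd)
  ct <- true_ct + stats::rnorm(nrow(grid), 0, noise_sd)

  # aberrant wells: shift one replicate by 3-8 cycles
  well <- paste(grid$gene_id, grid$sample_id)
  outlier_wells <- unique(well)[stats::runif(length(unique(well))) <
                                  cfg$ct_outlier_rate]
  out_rows <- integer(0)
  for (w in outlier_wells) {
    rows <- which(well == w)
    r <- sample(rows, 1L)
    ct[r] <- ct[r] + sample(c(-1, 1), 1L) * stats::runif(1, 3, 8)
    out_rows <- c(out_rows, r)
  }
  list(ct_table = data.frame(grid, ct = ct, stringsAsFactors = FALSE),
       ref_genes = refs,
       truth = list(
         outliers = grid[out_rows, c("gene_id", "sample_id", "replicate")],
         ref_noise_sds = stats::setNames(cfg$ref_noise_sds, refs)))
}

#' Generate a correlation-structured co-expression data set
#'
#' A seed gene follows a latent profile; a co-regulated set shares that
#' latent profile plus independent noise; an equally sized independent set
#' and background genes are pure noise.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` (genes x samples), `seed_gene`, `coregulated`,
#'   `independent` (id vectors).
#' @export
gen_coexpression <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 4L)
  ng <- cfg$coexpr_n_genes
  ns <- cfg$coexpr_n_samples
  sz <- cfg$coexpr_set_size
  stopifnot(1L + 2L * sz <= ng)
  latent <- stats::rnorm(ns)
  genes <- sprintf("cx_%04d", seq_len(ng))
  expr <- matrix(stats::rnorm(ng * ns), ng, ns,
                 dimnames = list(genes, sprintf("S%02d", seq_len(ns))))
  seed_gene <- genes[1L]
  coreg <- genes[2:(sz + 1L)]
  indep <- genes[(sz + 2L):(2L * sz + 1L)]
  expr[seed_gene, ] <- latent + stats::rnorm(ns, 0, 0.1)
  for (g in coreg) {
    expr[g, ] <- latent + stats::rnorm(ns, 0, cfg$coexpr_noise_sd)
  }
  list(expr = expr, seed_gene = seed_gene, coregulated = coreg,
       independent = indep)
}

#' Generate a complete synthetic study bundle
#'
#' Runs every generator under one seed, assigns up/down promoter sets,
#' plants a motif at the configured per-set frequencies, and (optionally)
#' writes promoters FASTA, motifs MEME, gene-set files, expression / Ct
#' TSVs and a truth JSON into a directory.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (`NULL` = keep everything in memory).
#' @param model motif to plant. Defaults to NACBS-8 built with
#'   `cfg$site_weights`, so planted sites are near-consensus words while
#'   scanning still uses the soft search weights.
#' @param force overwrite a non-empty directory.
#' @return list with components `promoters`, `sets` (up/down ids),
#'   `plant_truth`, `panel`, `panel_truth`, `microarray`, `ct`, `coexpr`,
#'   `files` (paths when written).
#' @export
gen_study <- function(cfg = sim_config(), dir = NULL, model = NULL,
                      force = FALSE) {
  if (is.null(model)) model <- build_nacbs("NACBS-8", cfg$site_weights)
  promoters <- gen_promoters(cfg)
  ids <- names(promoters)
  picks <- sample(ids, cfg$n_up + cfg$n_down)
  up <- sort(picks[seq_len(cfg$n_up)])
  down <- sort(picks[cfg$n_up + seq_len(cfg$n_down)])
  rest <- setdiff(ids, c(up, down))
  p1 <- plant_motif(promoters, model, cfg$plant_frac_up, ids = up)
  p2 <- plant_motif(p1$promoters, model, cfg$plant_frac_down, ids = down)
  p3 <- plant_motif(p2$promoters, model, cfg$plant_frac_universe,
                    ids = rest)
  promoters <- p3$promoters
  plant_truth <- rbind(p1$truth, p2$truth, p3$truth)

  pan <- gen_expression_panel(cfg)
  arr <- gen_microarray(cfg)
  ctd <- gen_ct_table(pan$panel, cfg)
  cx <- gen_coexpression(cfg)

  files <- list()
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
      stop("directory '", dir, "' is not empty (use force = TRUE)",
           call. = FALSE)
    }
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files$promoters <- file.path(dir, "promoters.fasta")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(promoters),
                                files$promoters)
    files$motifs <- file.path(dir, "motifs.meme")
    write_meme(build_all_default(), files$motifs, bg = cfg$background)
    files$up <- file.path(dir, "set_up.txt")
    writeLines(up, files$up)
    files$down <- file.path(dir, "set_down.txt")
    writeLines(down, files$down)
    files$ct <- file.path(dir, "ct_table.tsv")
    utils::write.table(ctd$ct_table, files$ct, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files$chlorophyll <- file.path(dir, "chlorophyll.tsv")
    utils::write.table(
      data.frame(sample_id = names(pan$panel$chlorophyll),
                 chlorophyll = unname(pan$panel$chlorophyll)),
      files$chlorophyll, sep = "\t", quote = FALSE, row.names = FALSE)
    files$coexpr <- file.path(dir, "coexpression_expr.tsv")
    utils::write.table(
      data.frame(gene_id = rownames(cx$expr), cx$expr,
                 check.names = FALSE),
      files$coexpr, sep = "\t", quote = FALSE, row.names = FALSE)
    files$truth <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(seed = cfg$seed, planted = plant_truth, sets = list(up = up,
           down = down), panel_clusters = pan$truth,
           array_truth = arr$truth,
           ct_outliers = ctd$truth$outliers,
           ref_noise_sds = as.list(ctd$truth$ref_noise_sds),
           coexpr = list(seed_gene = cx$seed_gene,
                         coregulated = cx$coregulated,
                         independent = cx$independent)),
      files$truth, auto_unbox = TRUE, digits = NA)
  }
  list(promoters = promoters, sets = list(up = up, down = down),
       plant_truth = plant_truth, panel = pan$panel,
       panel_truth = pan$truth, microarray = arr, ct = ctd, coexpr = cx,
       files = files)
}
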