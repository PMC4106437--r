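test_that("promoter generation is deterministic with correct dimensions", {
  cfg <- sim_config(seed = 5, n_promoters = 50, promoter_length = 200,
                    n_up = 10, n_down = 10)
  p1 <- gen_promoters(cfg)
  p2 <- gen_promoters(cfg)
  expect_identical(p1, p2)
  expect_length(p1, 50L)
  expect_true(all(nchar(p1) == 200L))
  p3 <- gen_promoters(sim_config(seed = 6, n_promoters = 50,
                                 promoter_length = 200,
                                 n_up = 10, n_down = 10))
  expect_false(identical(p1, p3))
})

test_that("base composition matches the background within sampling bounds", {
  p <- gen_promoters(sim_config(seed = 7, n_promoters = 1000,
                                promoter_length = 1000))
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(p))[, c("A", "C", "G", "T")])
  n <- sum(counts)
  half <- 2.576 * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(counts / n - 0.25) <= half))
})

test_that("motif planting records a truth table within sequence bounds", {
  cfg <- sim_config(seed = 8, n_promoters = 60, promoter_length = 150,
                    n_up = 10, n_down = 10)
  pr <- gen_promoters(cfg)
  m <- build_nacbs("NACBS-8", cfg$site_weights)
  none <- plant_motif(pr, m, fraction = 0)
  expect_identical(none$promoters, pr)
  expect_identical(nrow(none$truth), 0L)
  pl <- plant_motif(pr, m, fraction = 0.5, seed = 1)
  expect_identical(nrow(pl$truth), 30L)
  expect_true(all(pl$truth$position >= 0))
  expect_true(all(pl$truth$position <= 150 - m$length))
  expect_true(all(pl$truth$strand %in% c("+", "-")))
  # only the chosen promoters changed
  changed <- names(pr)[pr != pl$promoters]
  expect_true(all(changed %in% pl$truth$promoter_id))
  expect_error(
    plant_motif(c(x = "ACGT"), m, fraction = 1), "longer than")
})

test_that("planted near-consensus sites are recovered by the scanner", {
  cfg <- sim_config(seed = 9, n_promoters = 400, promoter_length = 1000)
  pr <- gen_promoters(cfg)
  site <- build_nacbs("NACBS-8", cfg$site_weights)
  pl <- plant_motif(pr, site, fraction = 0.1, seed = 2)  # 40 of 400
  res <- count_promoters_with_hit(pl$promoters, build_nacbs("NACBS-8"))
  found_planted <- length(intersect(res$ids, pl$truth$promoter_id))
  expect_true(found_planted >= 0.9 * 40)
  # total count sits near planted + expected background promoters
  bg_rate <- 0.025  # generous bound on the per-promoter false-hit rate
  expect_true(res$count <= 40 + qbinom(0.999, 360, bg_rate))
  expect_true(res$count >= qbinom(0.001, 40, 0.9))
})

test_that("expression archetypes have the stated amplitudes and ordering", {
  arch <- nacbs:::archetype_profiles(10)
  expect_identical(nrow(arch), 7L)
  # the moderate riser spans 2 log2 units, the levelling early riser 4
  expect_equal(diff(range(arch["moderate_riser", ])), 2)
  expect_equal(diff(range(arch["early_riser", ])), 4)
  g <- gen_expression_panel(sim_config(seed = 10, panel_noise_sd = 0))
  expect_true(all(diff(g$panel$chlorophyll) < 0))
  expect_identical(dim(g$panel$expr), c(91L, 10L))
  # zero noise reproduces the archetypes exactly
  first <- g$panel$expr[g$truth$gene_id[g$truth$cluster == 2][1], ]
  expect_equal(unname(log2(first)), unname(arch["late_strong", ]),
               tolerance = 1e-12)
  expect_identical(sort(unique(g$truth$cluster)), 1:7)
})

test_that("synthetic microarrays have full probe coverage and null truth", {
  arr <- gen_microarray(sim_config(seed = 11))
  expect_setequal(arr$truth$gene_id, unique(arr$probe_info$target_id))
  expect_true(all(table(arr$probe_info$target_id) >= 1))
  expect_true(all(arr$truth$log2fc[!arr$truth$de] == 0))
  # per-gene probe distances are distinct
  dd <- tapply(arr$probe_info$dist_to_3prime, arr$probe_info$target_id,
               anyDuplicated)
  expect_true(all(dd == 0))
  expect_identical(dim(arr$raw), dim(arr$background))
})

test_that("noise-free Ct tables invert back to the expression panel", {
  cfg <- sim_config(seed = 12, genes_per_cluster = 2, ct_noise_sd = 0,
                    ct_outlier_rate = 0, ref_noise_sds = c(0, 0, 0))
  g <- gen_expression_panel(cfg)
  ctd <- gen_ct_table(g$panel, cfg)
  summ <- summarize_ct_table(ctd$ct_table)
  genes <- rownames(g$panel$expr)
  rec <- normalize_expression(
    summ$ct[genes, colnames(g$panel$expr)],
    matrix(summ$ct["REF1", colnames(g$panel$expr)], nrow = length(genes),
           ncol = 10, byrow = TRUE))
  expect_equal(rec, g$panel$expr, tolerance = 1e-9)
})

test_that("injected outlier wells are flagged by replicate screening", {
  cfg <- sim_config(seed = 13, genes_per_cluster = 5, ct_outlier_rate = 0.1)
  g <- gen_expression_panel(cfg)
  ctd <- gen_ct_table(g$panel, cfg)
  summ <- summarize_ct_table(ctd$ct_table)
  out <- ctd$truth$outliers
  expect_true(nrow(out) > 10)
  flagged <- mapply(function(g, s) summ$flags[g, s] != "clean",
                    out$gene_id, out$sample_id)
  expect_true(mean(flagged) >= 0.9)
})

test_that("study bundles are reproducible and written to disk on request", {
  cfg <- sim_config(seed = 14, n_promoters = 40, promoter_length = 120,
                    n_up = 8, n_down = 8, genes_per_cluster = 2)
  s1 <- gen_study(cfg)
  s2 <- gen_study(cfg)
  expect_identical(s1$promoters, s2$promoters)
  expect_identical(s1$plant_truth, s2$plant_truth)
  expect_identical(s1$sets, s2$sets)
  expect_length(intersect(s1$sets$up, s1$sets$down), 0L)

  dir <- withr::local_tempdir()
  out <- gen_study(cfg, dir = dir)
  files <- c("promoters.fasta", "motifs.meme", "set_up.txt", "set_down.txt",
             "ct_table.tsv", "chlorophyll.tsv", "coexpression_expr.tsv",
             "truth.json")
  expect_true(all(file.exists(file.path(dir, files))))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth$seed, 14L)
  expect_error(gen_study(cfg, dir = dir), "not empty")
  expect_silent(suppressMessages(gen_study(cfg, dir = dir, force = TRUE)))
})
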