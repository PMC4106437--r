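test_that("background correction 'half' subtracts and floors at 0.5", {
  raw <- matrix(c(100, 10, 40), 3, 2)
  bg <- matrix(c(30, 50, 0), 3, 2)
  out <- background_correct_half(raw, bg)
  expect_equal(out[1, 1], 70)
  expect_equal(out[2, 1], 0.5)   # below background
  expect_equal(out[3, 1], 40)    # zero background: identity where raw >= 0.5
  expect_true(all(out > 0))
  expect_error(background_correct_half(raw, bg[1:2, ]), "3 x 2")
  raw[2, 2] <- NA
  expect_error(background_correct_half(raw, bg), "probe 2, array 2")
})

test_that("quantile normalization maps columns onto common quantiles", {
  x <- cbind(a = c(1, 2, 3), b = c(6, 4, 2))
  out <- quantile_normalize(x)
  expect_equal(unname(out[, "a"]), c(1.5, 3, 4.5))
  expect_equal(unname(out[, "b"]), c(4.5, 3, 1.5))
  # column means are equalized; identical columns stay put
  set.seed(31)
  y <- matrix(rexp(500 * 4), 500)
  ny <- quantile_normalize(y)
  expect_equal(diff(range(colMeans(ny))), 0, tolerance = 1e-12)
  same <- cbind(y[, 1], y[, 1])
  expect_equal(quantile_normalize(same), same, ignore_attr = TRUE)
  # idempotent on tie-free input
  expect_equal(quantile_normalize(ny), ny, tolerance = 1e-12)
  expect_warning(quantile_normalize(y[, 1, drop = FALSE]), "single-column")
})

test_that("low-signal filtering removes exactly the planted dead probes", {
  sig <- rbind(live = c(100, 120, 110), dead = c(10, 11, 9))
  bg <- matrix(10, 2, 3, dimnames = list(rownames(sig), NULL))
  res <- filter_low_signal(sig, bg)
  expect_identical(res$kept, "live")
  arr <- gen_microarray(sim_config(seed = 3))
  res <- filter_low_signal(arr$raw, arr$background, groups = arr$groups)
  expect_setequal(res$kept,
                  arr$probe_info$probe_id[!arr$probe_info$dead])
})

test_that("the representative probe is the most 3' of the top-2 signals", {
  grp <- data.frame(probe_id = c("A", "B", "C"),
                    dist_to_3prime = c(50, 10, 0),
                    mean_signal = c(10, 8, 2))
  expect_identical(select_representative_probe(grp), "B")
  # distance tie goes to the higher signal, then to the smaller id
  tie <- data.frame(probe_id = c("A", "B"), dist_to_3prime = c(10, 10),
                    mean_signal = c(10, 8))
  expect_identical(select_representative_probe(tie), "A")
  tie2 <- data.frame(probe_id = c("B", "A"), dist_to_3prime = c(10, 10),
                     mean_signal = c(8, 8))
  expect_identical(select_representative_probe(tie2), "A")
  single <- grp[2, ]
  expect_identical(select_representative_probe(single), "B")
  expect_error(select_representative_probe(grp[0, ]), "empty")
  # pure function of the rows, invariant to input order
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_identical(select_representative_probe(grp[perm, ]), "B")
  }
})

test_that("deduplication returns one representative probe per gene", {
  arr <- gen_microarray(sim_config(seed = 4))
  rep_map <- dedup_probes(arr$probe_info, arr$raw)
  expect_identical(sort(rep_map$target_id), sort(unique(
    arr$probe_info$target_id)))
  expect_false(anyDuplicated(rep_map$probe_id) > 0)
  expect_true(all(rep_map$probe_id %in% arr$probe_info$probe_id))
})

test_that("probe-to-gene matching allows up to the mismatch budget", {
  set.seed(32)
  genes <- c(g2 = random_seq(300), g1 = random_seq(300))
  probe <- substr(genes["g1"], 101, 160)
  expect_identical(match_probe_to_gene(probe, genes), "g1")
  mut <- probe
  for (at in c(5, 20, 40)) substr(mut, at, at) <- "N"  # N always mismatches
  expect_identical(match_probe_to_gene(mut, genes), "g1")
  substr(mut, 55, 55) <- "N"
  expect_identical(match_probe_to_gene(mut, genes), NA_character_)
  expect_identical(match_probe_to_gene(mut, genes, max_mismatch = 4), "g1")
})

test_that("moderated ranking recovers planted differential genes", {
  for (seed in 1:3) {
    set.seed(seed)
    expr <- matrix(rnorm(300 * 6, sd = 0.5), 300,
                   dimnames = list(sprintf("g%03d", 1:300), NULL))
    expr[1:50, 4:6] <- expr[1:50, 4:6] + 4
    de <- rank_differential(expr, rep(c("NS", "SEN"), each = 3),
                            c("NS", "SEN"))
    expect_setequal(de$gene_id[1:50], sprintf("g%03d", 1:50))
    expect_true(all(de$p_adj >= de$p - 1e-15))
    expect_identical(de$rank, 1:300)
  }
})

test_that("a gene with identical group means gets zero fold change", {
  expr <- rbind(null = c(1, 2, 3, 1, 2, 3), up = c(0, 0, 0, 5, 5, 5))
  de <- rank_differential(expr, rep(c("a", "b"), each = 3), c("a", "b"))
  expect_equal(de$log2fc[de$gene_id == "null"], 0)
  expect_equal(de$stat[de$gene_id == "null"], 0)
  expect_equal(de$log2fc[de$gene_id == "up"], 5)
})

test_that("null data yields approximately uniform p-values", {
  set.seed(33)
  expr <- matrix(rnorm(400 * 6), 400,
                 dimnames = list(paste0("g", 1:400), NULL))
  de <- rank_differential(expr, rep(c("a", "b"), each = 3), c("a", "b"))
  hits <- sum(de$p <= 0.05)
  bounds <- qbinom(c(0.005, 0.995), 400, 0.05)
  expect_true(hits >= bounds[1] && hits <= bounds[2])
})

test_that("single-array groups fall back to fold-change ranking", {
  expr <- matrix(rnorm(20 * 4), 20, dimnames = list(paste0("g", 1:20), NULL))
  expect_warning(
    de <- rank_differential(expr, c("a", "b", "b", "b"), c("a", "b")),
    "single array")
  expect_true(all(is.na(de$p)))
  expect_identical(de$gene_id, de$gene_id[order(-abs(de$log2fc),
                                                de$gene_id)])
  expect_error(
    rank_differential(expr[, 1:2], c("a", "b"), c("a", "b")),
    ">= 2 arrays")
})

test_that("top selection reports counts and rounded percentages", {
  de <- data.frame(gene_id = paste0("g", 1:200), rank = 1:200)
  top <- select_top(de, 40)
  expect_identical(top$genes, paste0("g", 1:40))
  expect_identical(top$percentage, 20L)
  expect_identical(select_top(de, 200)$percentage, 100L)
  expect_identical(select_top(de, 1)$genes, "g1")
  expect_error(select_top(de, 0), "positive")
  expect_error(select_top(de, 201), "exceeds")
})

test_that("an array with globally depressed signal is flagged", {
  set.seed(34)
  base <- rnorm(500)
  expr <- sapply(1:5, function(i) base + rnorm(500, sd = 0.1))
  expr <- cbind(expr, rnorm(500))  # unrelated array
  colnames(expr) <- c(paste0("ok", 1:5), "weird")
  expect_identical(flag_outlier_arrays(expr), "weird")
})
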