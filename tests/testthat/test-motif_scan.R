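test_that("log-odds scores are log2 ratios against the background", {
  uni <- make_motif(matrix(0.25, 3, 4))
  expect_equal(unname(log_odds(uni)), matrix(0, 3, 4), ignore_attr = TRUE)
  probs <- matrix(c(0.5, 0.125, 0.25, 0.125), 1, 4)
  m <- make_motif(probs)
  sc <- log_odds(m)
  expect_equal(unname(sc[1, "A"]), 1)
  expect_equal(unname(sc[1, "C"]), -1)
})

test_that("a single-position score distribution is the letter distribution", {
  m <- make_motif(matrix(c(0.94, 0.02, 0.02, 0.02), 1, 4))
  sc <- matrix(c(2, 0, 0, 0), 1, 4,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  d <- score_pvalue_table(sc)
  expect_equal(tail_probability(d, 200L), 0.25)
  expect_equal(tail_probability(d, 0L), 1)
  expect_equal(tail_probability(d, 201L), 0)
})

test_that("DP tail probabilities equal brute-force enumeration", {
  set.seed(42)
  bg <- c(A = 0.3, C = 0.2, G = 0.3, T = 0.2)
  for (L in 2:6) {
    m <- random_motif(L)
    d <- score_pvalue_table(log_odds(m, bg), bg)
    probe <- unique(c(d$min_int, d$max_int,
                      sort(sample(d$min_int:d$max_int, 25))))
    expect_equal(tail_probability(d, probe), enum_tail(d$int_scores, bg,
                                                       probe),
                 tolerance = 1e-12)
  }
  # tail at the maximum achievable score = background mass of argmax words
  m <- random_motif(4)
  d <- score_pvalue_table(log_odds(m, bg), bg)
  argmax_mass <- prod(bg[apply(d$int_scores, 1L, which.max)])
  expect_equal(tail_probability(d, d$max_int), argmax_mass,
               tolerance = 1e-12)
  # pmf is a proper distribution, tail is monotone with tail(min) = 1
  expect_equal(sum(d$pmf), 1, tolerance = 1e-9)
  expect_true(all(diff(d$tail) <= 1e-15))
  expect_equal(d$tail[1], 1)
})

test_that("an oversized score grid is rejected with advice", {
  sc <- matrix(c(0, 10, 0, 0), 3, 4, byrow = TRUE,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_error(score_pvalue_table(sc, granularity = 1e-6),
               "coarser granularity")
})

test_that("a planted consensus word is found at its offset", {
  m8 <- build_nacbs("NACBS-8")
  set.seed(5)
  seq <- random_seq(200)
  word <- nacbs8_word()
  substr(seq, 101, 120) <- word
  hits <- scan_sequence(seq, m8)
  expect_true(any(hits$start == 100 & hits$strand == "+"))
  hit <- hits[hits$start == 100 & hits$strand == "+", ]
  expect_equal(hit$end, 120)
  expect_true(hit$p <= 1e-4)
  # the determined positions pin 8 letters: best-word p is about 4^-8
  expect_equal(hit$p, 4^-8, tolerance = 0.05)
})

test_that("sequences without the core never fire, N windows are skipped", {
  m8 <- build_nacbs("NACBS-8")
  expect_identical(nrow(scan_sequence(strrep("A", 500), m8)), 0L)
  set.seed(6)
  seq <- random_seq(200)
  substr(seq, 101, 120) <- nacbs8_word()
  substr(seq, 110, 110) <- "N"  # N inside the only strong window
  hits <- scan_sequence(seq, m8)
  expect_false(any(hits$start == 100))
  expect_warning(scan_sequence("ACGT", m8), "shorter than the motif")
})

test_that("hit lists are monotone in the p-value threshold", {
  m8 <- build_nacbs("NACBS-8")
  set.seed(7)
  seqs <- vapply(1:30, function(i) random_seq(500), character(1))
  names(seqs) <- paste0("p", 1:30)
  h1 <- scan_promoters(seqs, m8, p_threshold = 1e-4)
  h2 <- scan_promoters(seqs, m8, p_threshold = 2e-4)
  expect_true(nrow(h2) >= nrow(h1))
  key <- function(h) paste(h$promoter_id, h$start, h$strand)
  expect_true(all(key(h1) %in% key(h2)))
})

test_that("both-strand scanning is symmetric under reverse complement", {
  m <- build_nacbs("NACBS-6")
  set.seed(8)
  seqs <- vapply(1:40, function(i) random_seq(300), character(1))
  names(seqs) <- paste0("p", 1:40)
  fwd <- count_promoters_with_hit(seqs, m, p_threshold = 5e-4)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  rev <- count_promoters_with_hit(rc, m, p_threshold = 5e-4)
  expect_setequal(fwd$ids, rev$ids)
})

test_that("scan results do not depend on promoter input order", {
  m <- build_nacbs("NACBS-5")
  set.seed(9)
  seqs <- vapply(1:25, function(i) random_seq(400), character(1))
  names(seqs) <- paste0("p", 1:25)
  h1 <- scan_promoters(seqs, m, p_threshold = 5e-4)
  h2 <- scan_promoters(rev(seqs), m, p_threshold = 5e-4)
  o <- function(h) h[order(h$promoter_id, h$start, h$strand), ]
  expect_equal(o(h1), o(h2), ignore_attr = TRUE)
})

test_that("promoter-level counting collapses multiple matches", {
  m8 <- build_nacbs("NACBS-8")
  set.seed(10)
  seq <- random_seq(300)
  for (at in c(1, 101, 201)) substr(seq, at, at + 19) <- nacbs8_word()
  res <- count_promoters_with_hit(c(multi = seq), m8)
  expect_identical(res$count, 1L)
  expect_identical(res$ids, "multi")
  expect_identical(count_promoters_with_hit(character(0), m8)$count, 0L)
  expect_error(
    count_promoters_with_hit(c(a = "ACGTACGT", a = "ACGTACGT"), m8),
    "unique")
})

test_that("per-set tabulation reports a subadditive non-redundant union", {
  set.seed(11)
  site <- build_nacbs("NACBS-8", weight_scheme(0.997, 0.995, floor = 5e-4))
  seqs <- gen_promoters(sim_config(seed = 11, n_promoters = 120,
                                   promoter_length = 300,
                                   n_up = 20, n_down = 20))
  planted <- plant_motif(seqs, site, fraction = 0.4)
  models <- build_all_default()[c("NACBS-7", "NACBS-8", "NACBS-9")]
  sets <- list(odd = names(seqs)[c(TRUE, FALSE)])
  res <- scan_promoter_sets(models, planted$promoters, sets)
  per_motif <- res$counts$all[res$counts$model != "Total, non-redundant"]
  union_n <- res$counts$all[res$counts$model == "Total, non-redundant"]
  expect_true(union_n <= sum(per_motif))
  expect_identical(union_n, length(res$union_ids$all))
  # identical hit sets collapse to the common size
  hs <- list(a = c("p1", "p2"), b = c("p1", "p2"))
  er <- enrichment_report(hs, paste0("p", 1:10), list(s = paste0("p", 1:4)))
  expect_identical(er$k[er$motif == "Total, non-redundant"], 2L)
  expect_error(
    scan_promoter_sets(models, planted$promoters, list(bad = "nope")),
    "not contained")
})

test_that("empirical false-positive rate matches the threshold tail", {
  m1 <- build_nacbs("NACBS-1")
  bg <- background_freq()
  d <- score_pvalue_table(log_odds(m1, bg), bg)
  tmin <- nacbs:::.threshold_int(d, 1e-4)
  alpha <- tail_probability(d, tmin)
  set.seed(12)
  n <- 1.1e6
  codes <- sample.int(4L, n, replace = TRUE)
  w <- nacbs:::.window_scores(codes, d$int_scores)
  W <- length(w)
  hits <- sum(w >= tmin)
  bounds <- stats::qbinom(c(0.005, 0.995), W, alpha)
  expect_true(hits >= bounds[1] && hits <= bounds[2])
})
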