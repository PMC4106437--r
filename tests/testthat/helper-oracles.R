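# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; nothing is read from disk.

# a motif_model around an arbitrary probability matrix
make_motif <- function(probs, name = "test") {
  probs <- pmax(probs, 0.0015)
  probs <- probs / rowSums(probs)  # floor keeps cells above 0.001 after this
  colnames(probs) <- c("A", "C", "G", "T")
  structure(list(name = name, length = nrow(probs), probs = probs,
                 consensus = strrep("n", nrow(probs)), spacer = NA_integer_),
            class = "motif_model")
}

# random letter-probability matrix of width L (Dirichlet-ish rows)
random_motif <- function(L, concentration = 1) {
  g <- matrix(stats::rgamma(L * 4, concentration), L, 4)
  make_motif(g / rowSums(g), name = paste0("rand", L))
}

# Brute-force oracle: tail probability P(sum of rounded per-position scores
# >= t) by enumerating all 4^L words, independent of the package's DP.
enum_tail <- function(int_scores, bg, t) {
  L <- nrow(int_scores)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- numeric(nrow(words))
  lw <- numeric(nrow(words))
  for (j in seq_len(L)) {
    sc <- sc + int_scores[j, words[, j]]
    lw <- lw + log(bg[words[, j]])
  }
  vapply(t, function(tt) sum(exp(lw[sc >= tt])), numeric(1))
}

# uniform i.i.d. test sequence
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a word carrying the NACBS-8 determined positions (tt.CGT(8n)ACGnnn) with
# arbitrary bases at the free positions
nacbs8_word <- function() {
  paste0("TT", "A", "CGT", strrep("A", 8), "ACG", "AAA")
}

# independent hypergeometric upper tail (the stats distribution function)
phyper_upper <- function(N, K, n, k) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# printed promoter-occurrence counts of the seven palindromic models:
# columns: all-gene universe count, down-regulated count, up-regulated count
table4_counts <- function() {
  data.frame(
    motif = paste0("NACBS-", c(1, 5, 6, 7, 8, 9, 10)),
    all = c(817, 619, 511, 556, 747, 459, 529),
    down = c(84, 68, 68, 51, 74, 54, 73),
    up = c(108, 80, 56, 69, 93, 64, 62),
    star_down = c("NS", "NS", "*", "NS", "NS", "NS", "**"),
    star_up = c("**", "**", "*", "**", "**", "**", "**"),
    stringsAsFactors = FALSE)
}
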