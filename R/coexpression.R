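# Co-expression ranked lists and rank-bias analysis: are promoters carrying
# a binding site biased toward the top of a transcription factor's
# co-expression ranking?

#' Build co-expression ranked lists
#'
#' For each seed gene, ranks every other gene by Pearson correlation of
#' their expression profiles, descending (rank 1 = most co-expressed).
#' Zero-variance genes get correlation 0 with a warning; correlation ties
#' are broken by gene id.
#'
#' @param expr genes x samples matrix (>= 3 samples), gene-id rownames.
#' @param seeds seed gene ids (rows of `expr`).
#' @return named list of `coexpression_list` data.frames with columns
#'   `gene_id`, `correlation`, `rank` (the seed gene itself is excluded).
#' @export
build_coexpression_lists <- function(expr, seeds) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) >= 3L, !is.null(rownames(expr)),
            all(seeds %in% rownames(expr)))
  sdv <- apply(expr, 1L, stats::sd)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " zero-variance gene(s): correlation set to 0")
  }
  cc <- suppressWarnings(stats::cor(t(expr)))
  cc[!is.finite(cc)] <- 0
  out <- lapply(seeds, function(s) {
    r <- cc[s, setdiff(rownames(expr), s)]
    ord <- order(-r, names(r))
    df <- data.frame(gene_id = names(r)[ord], correlation = unname(r[ord]),
                     rank = seq_along(r), stringsAsFactors = FALSE)
    attr(df, "seed_gene") <- s
    class(df) <- c("coexpression_list", class(df))
    df
  })
  stats::setNames(out, seeds)
}

#' Ranks of a gene set within a co-expression list
#'
#' @param coexpr a `coexpression_list`.
#' @param genes gene ids.
#' @return integer ranks of the genes found in the list (genes absent from
#'   the list are skipped; their number is in attribute `n_skipped`).
#' @export
ranks_of_set <- function(coexpr, genes) {
  pos <- match(genes, coexpr$gene_id)
  out <- coexpr$rank[pos[!is.na(pos)]]
  attr(out, "n_skipped") <- sum(is.na(pos))
  out
}

#' Rank histogram of a gene set in a co-expression list
#'
#' Bins the co-expression ranks of the member genes into `n_bins`
#' equal-width bins over the full ranking.
#'
#' @param coexpr a `coexpression_list`.
#' @param genes gene ids (a subset of the ranked universe; absent genes are
#'   skipped and counted in attribute `n_skipped`).
#' @param n_bins number of bins (default 20).
#' @return integer vector of bin counts (bin 1 = most co-expressed).
#' @export
rank_distribution <- function(coexpr, genes, n_bins = 20L) {
  stopifnot(n_bins >= 1L)
  universe <- nrow(coexpr)
  r <- ranks_of_set(coexpr, genes)
  bins <- pmin(n_bins, ceiling(r / (universe / n_bins)))
  counts <- tabulate(bins, nbins = n_bins)
  attr(counts, "n_skipped") <- attr(r, "n_skipped")
  counts
}

# Mann-Whitney U counting pairs where an A rank beats (is smaller than) a
# B rank; ties count 1/2.
.u_statistic <- function(a, b) {
  sum(vapply(a, function(x) sum(x < b) + 0.5 * sum(x == b), numeric(1)))
}

#' One-sided rank-bias test (Mann-Whitney)
#'
#' Tests whether set A sits at smaller (better) co-expression ranks than
#' set B. `U` counts A-beats-B pairs, `auc = U / (|A||B|)` estimates
#' `P(rank_A < rank_B)`, and the one-sided p-value is exact by enumeration
#' of all splits when `|A| + |B| <= 12`, otherwise a normal approximation
#' with tie correction and continuity correction.
#'
#' @param ranks_a,ranks_b numeric rank vectors (non-empty).
#' @return list with `U`, `auc`, `p_one_sided`, `method`, and the input
#'   sizes `n_a`, `n_b`.
#' @export
rank_bias_test <- function(ranks_a, ranks_b) {
  stopifnot(length(ranks_a) > 0L, length(ranks_b) > 0L)
  m <- length(ranks_a); n <- length(ranks_b)
  U <- .u_statistic(ranks_a, ranks_b)
  if (m + n <= 12L) {
    comb <- c(ranks_a, ranks_b)
    splits <- utils::combn(m + n, m)
    us <- apply(splits, 2L, function(i) .u_statistic(comb[i], comb[-i]))
    p <- mean(us >= U - 1e-9)
    method <- "exact enumeration"
  } else {
    all_r <- c(ranks_a, ranks_b)
    ties <- table(all_r)
    Nt <- m + n
    mu <- m * n / 2
    sig2 <- m * n / 12 *
      ((Nt + 1) - sum(ties^3 - ties) / (Nt * (Nt - 1)))
    z <- (U - mu - 0.5) / sqrt(sig2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal approximation"
  }
  list(U = U, auc = U / (m * n), p_one_sided = p, method = method,
       n_a = m, n_b = n)
}

#' Deterministic random gene sample
#'
#' Uniform sample without replacement, reproducible for a given seed and
#' independent of the input order of the universe.
#'
#' @param universe gene ids.
#' @param size sample size (default 500).
#' @param seed integer seed.
#' @return character vector of sampled ids.
#' @export
random_gene_sample <- function(universe, size = 500L, seed = 1L) {
  if (size > length(universe)) {
    stop("size (", size, ") exceeds the universe (", length(universe), ")",
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  sample(sort(universe), size)
}

#' Read pre-ranked co-expression lists from TSV
#'
#' Accepts externally exported rankings with columns `seed_gene`,
#' `gene_id`, `rank` (and optionally `correlation`).
#'
#' @param path TSV file.
#' @return named list of `coexpression_list` data.frames.
#' @export
read_ranked_lists <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("seed_gene", "gene_id", "rank") %in% names(df)))
  if (is.null(df$correlation)) df$correlation <- NA_real_
  lapply(split(df, df$seed_gene), function(d) {
    seed <- d$seed_gene[1]
    d <- d[order(d$rank), c("gene_id", "correlation", "rank")]
    rownames(d) <- NULL
    attr(d, "seed_gene") <- seed
    class(d) <- c("coexpression_list", class(d))
    d
  })
}
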