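# qPCR Ct processing: technical-replicate summarization with outlier
# screening, geNorm-style reference-gene stability, delta-Ct normalization,
# chlorophyll-ordered senescence panels and k-means profile clustering.

#' Summarize technical Ct replicates
#'
#' Formalizes manual replicate inspection: when the replicate range exceeds
#' `max_range` cycles, values farther than `max_dev` from the median are
#' dropped and the result flagged `"outlier_removed"`; the retained values
#' are averaged. All-missing input gives `NA` with flag `"no_data"`; two
#' discordant replicates with nothing retained give `NA` with flag
#' `"discordant"`.
#'
#' @param ct up to 3 Ct values (NA allowed).
#' @param max_range replicate range (cycles) that triggers screening.
#' @param max_dev maximal absolute deviation from the median to retain.
#' @return list with `ct` (summary value) and `flag`.
#' @export
#' @examples
#' summarize_replicates(c(20.0, 20.1, 25.0)) # 20.05, outlier_removed
summarize_replicates <- function(ct, max_range = 1.0, max_dev = 0.5) {
  stopifnot(length(ct) <= 3L)
  x <- ct[!is.na(ct)]
  if (length(x) == 0L) return(list(ct = NA_real_, flag = "no_data"))
  if (length(x) > 1L && diff(range(x)) > max_range) {
    keep <- x[abs(x - stats::median(x)) <= max_dev]
    if (length(keep) == 0L) return(list(ct = NA_real_, flag = "discordant"))
    return(list(ct = mean(keep), flag = "outlier_removed"))
  }
  list(ct = mean(x), flag = "clean")
}

#' Summarize a long Ct table to a gene x sample matrix
#'
#' @param ct_table data.frame with columns `gene_id`, `sample_id`,
#'   `replicate`, `ct`.
#' @inheritParams summarize_replicates
#' @return list with `ct` (gene x sample matrix) and `flags` (same shape).
#' @export
summarize_ct_table <- function(ct_table, max_range = 1.0, max_dev = 0.5) {
  stopifnot(all(c("gene_id", "sample_id", "ct") %in% names(ct_table)))
  genes <- sort(unique(ct_table$gene_id))
  samples <- sort(unique(ct_table$sample_id))
  ct <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  flags <- matrix("no_data", length(genes), length(samples),
                  dimnames = list(genes, samples))
  idx <- split(seq_len(nrow(ct_table)),
               list(ct_table$gene_id, ct_table$sample_id), drop = TRUE)
  for (key in names(idx)) {
    rows <- idx[[key]]
    res <- summarize_replicates(ct_table$ct[rows], max_range, max_dev)
    g <- ct_table$gene_id[rows[1]]
    s <- ct_table$sample_id[rows[1]]
    ct[g, s] <- res$ct
    flags[g, s] <- res$flag
  }
  list(ct = ct, flags = flags)
}

#' geNorm-style reference-gene stability
#'
#' For every pair of candidate genes the standard deviation (n-1
#' denominator) of their per-sample log2 expression ratios is computed; a
#' gene's stability `M` is the mean of these pairwise SDs against all other
#' candidates. Lower `M` means more stable. This is the single-pass pairwise
#' variant (no iterative exclusion).
#'
#' @param quantities candidate-genes x samples matrix of strictly positive
#'   relative quantities.
#' @return data.frame with `gene_id`, `M` and `rank` (ascending by `M`,
#'   ties by gene id).
#' @export
reference_stability <- function(quantities) {
  q <- as.matrix(quantities)
  if (nrow(q) < 2L || ncol(q) < 2L) {
    stop("need >= 2 candidate genes and >= 2 samples", call. = FALSE)
  }
  bad <- which(!(is.finite(q) & q > 0), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-positive quantity at gene ", bad[1, 1], ", sample ",
         bad[1, 2], call. = FALSE)
  }
  ids <- rownames(q)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(q)))
  lg <- log2(q)
  M <- vapply(seq_len(nrow(q)), function(j) {
    v <- vapply(setdiff(seq_len(nrow(q)), j),
                function(k) stats::sd(lg[j, ] - lg[k, ]), numeric(1))
    mean(v)
  }, numeric(1))
  ord <- order(M, ids)
  out <- data.frame(gene_id = ids, M = M, stringsAsFactors = FALSE)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out
}

#' Reference-normalized relative expression
#'
#' Delta-Ct normalization assuming doubling per cycle:
#' `2^(ct_ref - ct_gene)`. Missing input propagates.
#'
#' @param ct_gene Ct value(s) of the gene of interest.
#' @param ct_ref Ct value(s) of the reference gene (recycled).
#' @return relative expression on the linear scale.
#' @export
normalize_expression <- function(ct_gene, ct_ref) {
  2^(ct_ref - ct_gene)
}

#' Senescence expression panel ordered by chlorophyll
#'
#' Orders samples by decreasing chlorophyll content (a proxy for senescence
#' progression; ties broken by sample id) and stores the expression matrix
#' in that order.
#'
#' @param expr genes x samples matrix of positive relative expression.
#' @param chlorophyll named per-sample chlorophyll contents covering the
#'   columns of `expr`.
#' @return object of class `expression_panel` with fields `expr`,
#'   `chlorophyll` (both in panel order) and `sample_order`.
#' @export
expression_panel <- function(expr, chlorophyll) {
  expr <- as.matrix(expr)
  stopifnot(!is.null(colnames(expr)), !is.null(names(chlorophyll)),
            all(colnames(expr) %in% names(chlorophyll)),
            all(chlorophyll >= 0))
  chl <- chlorophyll[colnames(expr)]
  ord <- order(-chl, names(chl))
  structure(list(expr = expr[, ord, drop = FALSE],
                 chlorophyll = chl[ord],
                 sample_order = colnames(expr)[ord]),
            class = "expression_panel")
}

#' Cluster-number rule of thumb
#'
#' `k = round(sqrt(n / 2))` with half-integers rounding up, minimum 1. For
#' the 91 genes of a 44 + 47 panel this gives 7.
#'
#' @param n_genes number of profiles to cluster.
#' @return integer k.
#' @export
choose_k <- function(n_genes) {
  stopifnot(all(n_genes >= 1))
  pmax(1L, as.integer(round_half_up(sqrt(n_genes / 2))))
}

# per-gene linear interpolation of missing values over the ordered samples
.impute_linear <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0L) stop("gene with no observed values", call. = FALSE)
  if (length(ok) == 1L) return(rep(x[ok], length(x)))
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

.zscore_rows <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' K-means clustering of expression patterns
#'
#' Profiles are imputed per gene (linear interpolation over the ordered
#' samples), standardized per gene (so patterns, not levels, are clustered;
#' constant genes map to all-zero profiles) and clustered with Lloyd's
#' k-means over `restarts` random initializations, keeping the best
#' inertia. Deterministic for a given seed.
#'
#' @param panel an [expression_panel()] (clustering uses log2 expression) or
#'   a plain genes x samples matrix taken as-is.
#' @param k number of clusters, or `"auto"` for [choose_k()].
#' @param seed integer seed for the restart stream.
#' @param restarts number of random initializations.
#' @param standardize per-gene z-scoring before clustering (default TRUE).
#' @return object of class `cluster_result` with fields `k`, `assignment`
#'   (named integer vector), `centroids` (k x samples, standardized scale)
#'   and `inertia`.
#' @export
cluster_profiles <- function(panel, k = "auto", seed = 1L, restarts = 100L,
                             standardize = TRUE) {
  x <- if (inherits(panel, "expression_panel")) log2(panel$expr) else
    as.matrix(panel)
  x <- t(apply(x, 1L, .impute_linear))
  if (identical(k, "auto")) k <- choose_k(nrow(x))
  k <- as.integer(k)
  if (k > nrow(x)) {
    stop("k (", k, ") exceeds the number of genes (", nrow(x), ")",
         call. = FALSE)
  }
  if (standardize) x <- .zscore_rows(x)
  ux <- unique(x)
  # canonical row order, so initialization (hence the fit) does not depend
  # on the order genes arrive in
  ux <- ux[do.call(order, as.data.frame(ux)), , drop = FALSE]
  if (nrow(ux) < k) {
    stop("only ", nrow(ux), " distinct profiles for k = ", k, call. = FALSE)
  }
  best <- NULL
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    centers <- ux[sample.int(nrow(ux), k), , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers,
                                     algorithm = "Lloyd", iter.max = 100L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed in every restart", call. = FALSE)
  structure(list(k = k,
                 assignment = stats::setNames(best$cluster, rownames(x)),
                 centroids = best$centers,
                 inertia = best$tot.withinss),
            class = "cluster_result")
}
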