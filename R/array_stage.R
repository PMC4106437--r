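# Single-channel microarray preprocessing: "half" background correction,
# quantile normalization, low-signal filtering, the 3'-biased representative
# probe rule, <=3-mismatch probe-to-gene matching, moderated differential
# ranking and top-fraction selection.

#' Background correction, method "half"
#'
#' Subtracts the per-feature background and floors the result at 0.5, so
#' every corrected intensity is strictly positive and log-transformable.
#'
#' @param raw probes x arrays raw intensity matrix.
#' @param background matrix of the same shape.
#' @return corrected matrix, entries `max(raw - background, 0.5)`.
#' @export
background_correct_half <- function(raw, background) {
  raw <- as.matrix(raw)
  background <- as.matrix(background)
  if (!identical(dim(raw), dim(background))) {
    stop("shape mismatch: raw is ", nrow(raw), " x ", ncol(raw),
         ", background is ", nrow(background), " x ", ncol(background),
         call. = FALSE)
  }
  bad <- which(!is.finite(raw) | !is.finite(background), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite intensity at probe ", bad[1, 1], ", array ", bad[1, 2],
         call. = FALSE)
  }
  pmax(raw - background, 0.5)
}

#' Quantile normalization across arrays
#'
#' Forces every array onto the common distribution given by the row means of
#' the sorted columns, preserving within-array rank order; ties receive the
#' mean of the values they would otherwise have taken. Delegates to
#' `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param x probes x arrays matrix without missing values.
#' @return normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values are not supported", call. = FALSE)
  if (ncol(x) < 2L) {
    warning("single-column matrix: quantile normalization is a no-op")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Filter probes with signals near or below background
#'
#' A probe is kept when its signal reaches `min_fold_over_bg` times its
#' background in at least `min_fraction_arrays` of the arrays — within at
#' least one condition group when `groups` is given (so a probe expressed in
#' only one condition survives), across all arrays otherwise.
#'
#' @param signal probes x arrays signal matrix with probe-id rownames.
#' @param background matrix of the same shape.
#' @param min_fold_over_bg required fold over background (default 1.1).
#' @param min_fraction_arrays required fraction of arrays in (0, 1]
#'   (default 1, i.e. all arrays of a group).
#' @param groups optional per-array condition labels.
#' @return list with `kept` (probe ids), `n_kept` and `n_total`.
#' @export
filter_low_signal <- function(signal, background, min_fold_over_bg = 1.1,
                              min_fraction_arrays = 1, groups = NULL) {
  signal <- as.matrix(signal)
  background <- as.matrix(background)
  if (!identical(dim(signal), dim(background))) {
    stop("shape mismatch between signal and background", call. = FALSE)
  }
  stopifnot(min_fold_over_bg > 0,
            min_fraction_arrays > 0, min_fraction_arrays <= 1)
  above <- signal >= min_fold_over_bg * background
  if (is.null(groups)) groups <- rep("all", ncol(signal))
  keep <- Reduce(`|`, lapply(unique(groups), function(g) {
    rowMeans(above[, groups == g, drop = FALSE]) >= min_fraction_arrays
  }))
  ids <- rownames(signal)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(signal)))
  list(kept = ids[keep], n_kept = sum(keep), n_total = nrow(signal))
}

#' Select the representative probe of a redundant group
#'
#' Among the probes targeting one sequence, restrict to the two with the
#' highest mean signal (all of them when the group has at most two members)
#' and return the one closest to the target 3' end; distance ties go to the
#' higher signal, remaining ties to the lexicographically smallest probe id.
#' The 3' bias reflects labelling that proceeds from the poly(A) tail.
#'
#' @param probes data.frame with columns `probe_id`, `dist_to_3prime` and
#'   `mean_signal` (or a `signals` matrix column from which means are taken).
#' @return the selected probe id.
#' @export
select_representative_probe <- function(probes) {
  if (is.null(probes) || nrow(probes) == 0L) {
    stop("empty probe group", call. = FALSE)
  }
  if (is.null(probes$mean_signal)) {
    if (is.null(probes$signals)) {
      stop("probes need a mean_signal column or a signals matrix",
           call. = FALSE)
    }
    probes$mean_signal <- rowMeans(as.matrix(probes$signals))
  }
  stopifnot(all(probes$dist_to_3prime >= 0))
  ord <- order(-probes$mean_signal, probes$dist_to_3prime, probes$probe_id)
  top <- if (nrow(probes) <= 2L) ord else ord[1:2]
  pick <- top[order(probes$dist_to_3prime[top], -probes$mean_signal[top],
                    probes$probe_id[top])][1L]
  probes$probe_id[pick]
}

#' Deduplicate probes per target sequence
#'
#' Applies [select_representative_probe()] within each `target_id` group.
#'
#' @param probe_info data.frame with columns `probe_id`, `target_id`,
#'   `dist_to_3prime`.
#' @param signals probes x arrays matrix, rownames matching `probe_id`.
#' @return data.frame mapping `target_id` to its representative `probe_id`.
#' @export
dedup_probes <- function(probe_info, signals) {
  stopifnot(all(probe_info$probe_id %in% rownames(signals)))
  probe_info$mean_signal <-
    rowMeans(as.matrix(signals))[probe_info$probe_id]
  groups <- split(probe_info, probe_info$target_id)
  data.frame(
    target_id = names(groups),
    probe_id = vapply(groups, select_representative_probe, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Match a probe sequence to a gene by near-exact substring search
#'
#' Finds genes whose sequence contains a window within `max_mismatch`
#' Hamming distance of the probe (forward orientation, no indels).
#' Ambiguous bases in the probe count as mismatches to every letter. With
#' several qualifying genes the smallest distance wins, then the
#' lexicographically smallest gene id.
#'
#' @param probe_seq probe sequence (typically 60 nt).
#' @param gene_seqs named character vector or `DNAStringSet` of gene
#'   sequences.
#' @param max_mismatch maximum Hamming distance (default 3).
#' @return the matching gene id, or `NA_character_` when none qualifies.
#' @export
match_probe_to_gene <- function(probe_seq, gene_seqs, max_mismatch = 3L) {
  stopifnot(nchar(probe_seq) >= 1L, max_mismatch >= 0L)
  subj <- if (inherits(gene_seqs, "DNAStringSet")) gene_seqs else
    Biostrings::DNAStringSet(gene_seqs)
  if (is.null(names(subj))) {
    stop("gene sequences must be named", call. = FALSE)
  }
  pat <- Biostrings::DNAString(probe_seq)
  for (mm in 0:max_mismatch) {
    cnt <- Biostrings::vcountPattern(pat, subj, max.mismatch = mm,
                                     with.indels = FALSE, fixed = TRUE)
    if (any(cnt > 0L)) {
      return(sort(names(subj)[cnt > 0L])[1L])
    }
  }
  NA_character_
}

#' Moderated differential-expression ranking
#'
#' Two-sample comparison on log2-scale expression with empirical-Bayes style
#' variance moderation: each gene's pooled variance is shrunk toward the
#' median gene variance with prior weight `d0`, the moderated t is referred
#' to a t distribution on `d0 + df` degrees of freedom, and p-values are
#' Benjamini-Hochberg adjusted. This is a deliberately simple moderated
#' statistic, not a re-implementation of any specific published pipeline.
#' When one group has a single array, genes are ranked by absolute fold
#' change and p-values are reported missing.
#'
#' @param expr genes x arrays matrix of log2 expression, gene-id rownames.
#' @param groups per-array condition labels.
#' @param contrast character pair `c(group1, group2)`; log2 fold change is
#'   `mean(group2) - mean(group1)`.
#' @param d0 prior degrees of freedom of the variance shrinkage (default 4).
#' @return data.frame with columns `gene_id`, `log2fc`, `stat`, `p`,
#'   `p_adj`, `rank`, sorted by ascending `p_adj` then `p` (ties broken by
#'   `|log2fc|` descending, then gene id).
#' @export
rank_differential <- function(expr, groups, contrast, d0 = 4) {
  expr <- as.matrix(expr)
  stopifnot(length(groups) == ncol(expr), length(contrast) == 2L,
            all(contrast %in% groups))
  g1 <- expr[, groups == contrast[1], drop = FALSE]
  g2 <- expr[, groups == contrast[2], drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  if (max(n1, n2) < 2L) {
    stop("at least one contrast group needs >= 2 arrays", call. = FALSE)
  }
  ids <- rownames(expr)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(expr)))
  fc <- rowMeans(g2) - rowMeans(g1)
  if (min(n1, n2) < 2L) {
    warning("a contrast group has a single array: ranking by fold change, ",
            "p-values set to missing")
    ord <- order(-abs(fc), ids)
    out <- data.frame(gene_id = ids, log2fc = fc, stat = NA_real_,
                      p = NA_real_, p_adj = NA_real_,
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
  } else {
    ss <- rowSums((g1 - rowMeans(g1))^2) + rowSums((g2 - rowMeans(g2))^2)
    df <- n1 + n2 - 2
    s2 <- ss / df
    s2_0 <- stats::median(s2)
    s2_mod <- (d0 * s2_0 + df * s2) / (d0 + df)
    tstat <- fc / sqrt(s2_mod * (1 / n1 + 1 / n2))
    tstat[fc == 0 & !is.finite(tstat)] <- 0
    p <- 2 * stats::pt(-abs(tstat), df = d0 + df)
    p_adj <- stats::p.adjust(p, method = "BH")
    ord <- order(p_adj, p, -abs(fc), ids)
    out <- data.frame(gene_id = ids, log2fc = fc, stat = tstat, p = p,
                      p_adj = p_adj,
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
  }
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the top-ranked genes
#'
#' @param de output of [rank_differential()].
#' @param count number of top genes to keep.
#' @return list with `genes` (ids in rank order), `count`, `total` and
#'   `percentage` (`100 count / total`, rounded half-up).
#' @export
select_top <- function(de, count) {
  if (length(count) != 1L || count <= 0) {
    stop("count must be a positive integer", call. = FALSE)
  }
  if (count > nrow(de)) {
    stop("count (", count, ") exceeds the list length (", nrow(de), ")",
         call. = FALSE)
  }
  list(genes = de$gene_id[seq_len(count)], count = as.integer(count),
       total = nrow(de),
       percentage = as.integer(round_half_up(100 * count / nrow(de))))
}

#' Flag outlier arrays by inter-array correlation
#'
#' An array is flagged when the median of its Spearman correlations with the
#' other arrays falls more than 3 MADs below the cohort median — the pattern
#' of a hybridization with globally depressed signal. Exclusion is left to
#' the caller.
#'
#' @param expr probes x arrays matrix.
#' @return character vector of flagged array names (possibly empty).
#' @export
flag_outlier_arrays <- function(expr) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) >= 3L)
  cc <- stats::cor(expr, method = "spearman")
  med <- vapply(seq_len(ncol(cc)),
                function(i) stats::median(cc[i, -i]), numeric(1))
  cut <- stats::median(med) - 3 * stats::mad(med)
  nm <- colnames(expr)
  if (is.null(nm)) nm <- as.character(seq_len(ncol(expr)))
  nm[med < cut]
}
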