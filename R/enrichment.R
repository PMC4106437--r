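# Hypergeometric over-representation of motif-containing promoters in gene
# sets, with the significance-star and per-1000-rate report layout used for
# promoter-occurrence tables.

#' Exact upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of at
#' least `k` annotated members in a size-`n` sample drawn without
#' replacement from a universe of `N` containing `K` annotated. Terms are
#' accumulated in log space.
#'
#' @param N universe size.
#' @param K annotated members of the universe.
#' @param n sample (gene-set) size.
#' @param k annotated members observed in the sample.
#' @return the upper-tail probability.
#' @export
#' @examples
#' hypergeom_upper(10, 5, 5, 5) # 1/choose(10,5)
hypergeom_upper <- function(N, K, n, k) {
  for (v in c("N", "K", "n", "k")) {
    x <- get(v)
    if (length(x) != 1L || !is.finite(x) || x < 0 || x != round(x)) {
      stop(v, " must be a single non-negative integer", call. = FALSE)
    }
  }
  if (K > N) stop("bound violated: K <= N (K=", K, ", N=", N, ")",
                  call. = FALSE)
  if (n > N) stop("bound violated: n <= N (n=", n, ", N=", N, ")",
                  call. = FALSE)
  if (k > n) stop("bound violated: k <= n (k=", k, ", n=", n, ")",
                  call. = FALSE)
  if (k > K) stop("bound violated: k <= K (k=", k, ", K=", K, ")",
                  call. = FALSE)
  kmin <- max(0, n + K - N)
  if (k <= kmin) return(1)
  lp <- stats::dhyper(k:min(K, n), K, N - K, n, log = TRUE)
  mx <- max(lp)
  min(1, exp(mx + log(sum(exp(lp - mx)))))
}

#' Significance stars
#'
#' `"**"` for p <= 0.01, `"*"` for p <= 0.05, else `"NS"`.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of annotations.
#' @export
stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "NS"))
}

#' Promoter-occurrence rate per 1000 genes
#'
#' `round(1000 k / n)`, half-up.
#'
#' @param k promoters with a hit in the set.
#' @param n set size.
#' @return integer rate(s).
#' @export
per_1000 <- function(k, n) {
  stopifnot(all(n >= 1))
  as.integer(round_half_up(1000 * k / n))
}

.enrichment_rows <- function(motif, set, N, K, n, k,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  p <- mapply(function(N, K, n, k) {
    up <- hypergeom_upper(N, K, n, k)
    if (alternative == "greater") return(up)
    lower <- 1 - up + exp(stats::dhyper(k, K, N - K, n, log = TRUE))
    min(1, 2 * min(up, lower))
  }, N, K, n, k)
  data.frame(motif = motif, set = set, N = N, K = K, n = n, k = k,
             p_upper = p, star = stars(p), per_1000 = per_1000(k, n),
             stringsAsFactors = FALSE)
}

#' Enrichment report for scanned promoter sets
#'
#' One hypergeometric over-representation row per motif per gene set, plus a
#' "Total, non-redundant" row per set testing the union of promoters hit by
#' any motif. The universe is the full set of promoters that were available
#' for scanning.
#'
#' @param hit_sets named list: motif name -> ids of universe promoters with
#'   at least one hit (e.g. `scan_promoter_sets()$hit_sets`).
#' @param universe character vector of all scanned promoter ids.
#' @param sets named list of promoter-id sets to test (subsets of the
#'   universe; must be non-empty).
#' @param alternative `"greater"` (over-representation, the default) or
#'   `"two.sided"`.
#' @return data.frame of class `enrichment_report` with columns `motif`,
#'   `set`, `N`, `K`, `n`, `k`, `p_upper`, `star`, `per_1000`.
#' @export
enrichment_report <- function(hit_sets, universe, sets,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(sets) == 0L || is.null(names(sets))) {
    stop("sets must be a non-empty named list", call. = FALSE)
  }
  for (sn in names(sets)) {
    if (length(sets[[sn]]) == 0L) {
      stop("set '", sn, "' is empty", call. = FALSE)
    }
    if (!all(sets[[sn]] %in% universe)) {
      stop("set '", sn, "' is not contained in the universe", call. = FALSE)
    }
  }
  if (length(sets) > 1L) {
    pairs <- utils::combn(names(sets), 2L, simplify = FALSE)
    for (pr in pairs) {
      ov <- length(intersect(sets[[pr[1]]], sets[[pr[2]]]))
      if (ov > 0L) {
        warning("sets '", pr[1], "' and '", pr[2], "' overlap in ", ov,
                " promoter(s)")
      }
    }
  }
  hit_sets <- lapply(hit_sets, intersect, x = universe)
  N <- length(universe)
  rows <- list()
  for (sn in names(sets)) {
    s <- sets[[sn]]
    rows[[sn]] <- .enrichment_rows(
      motif = names(hit_sets), set = sn, N = N,
      K = vapply(hit_sets, length, integer(1)),
      n = length(s),
      k = vapply(hit_sets, function(h) length(intersect(h, s)), integer(1)),
      alternative = alternative)
    u <- unique(unlist(hit_sets, use.names = FALSE))
    rows[[paste0(sn, "_total")]] <- .enrichment_rows(
      motif = "Total, non-redundant", set = sn, N = N, K = length(u),
      n = length(s), k = length(intersect(u, s)),
      alternative = alternative)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enrichment_report", class(out))
  out
}

#' Enrichment rows from pre-tabulated counts
#'
#' Computes the hypergeometric report directly from count quadruples, e.g.
#' when reproducing a published promoter-occurrence table without rerunning
#' the scan.
#'
#' @param motif,set labels (recycled).
#' @param N,K,n,k hypergeometric counts (vectorized).
#' @inheritParams enrichment_report
#' @return data.frame as in [enrichment_report()].
#' @export
enrichment_from_counts <- function(motif, set, N, K, n, k,
                                   alternative = c("greater", "two.sided")) {
  out <- .enrichment_rows(motif, set, N, K, n, k,
                          alternative = match.arg(alternative))
  class(out) <- c("enrichment_report", class(out))
  out
}
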