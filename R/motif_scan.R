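# FIMO-style motif scanning: log-odds scoring of promoter windows, exact
# p-values from a dynamic program over a discretized score grid, and
# promoter-level hit accounting.
#
# Scores are log2(motif probability / background probability), rounded to a
# grid of step `granularity`. Window scores are sums of the rounded
# per-position scores, so the DP null distribution of the sum over
# background-distributed letters gives *exact* p-values for the scores the
# scanner actually assigns (this is also how FIMO handles discretization).

#' 0-order background model
#'
#' @param p probabilities for A, C, G, T.
#' @return validated named probability vector.
#' @export
background_freq <- function(p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot_prob_vector(p, "background")
}

#' Estimate a 0-order background from sequences
#'
#' @param seqs character vector of sequences (N ignored).
#' @return background probability vector.
#' @export
estimate_background <- function(seqs) {
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs))[, DNA_BASES, drop = FALSE])
  background_freq(counts / sum(counts))
}

#' Log-odds score matrix of a motif against a background
#'
#' @param m a `motif_model`.
#' @param bg background probabilities.
#' @return L x 4 matrix of log2(prob/bg) scores.
#' @export
log_odds <- function(m, bg = background_freq()) {
  validate_motif(m)
  bg <- background_freq(bg)
  sweep(log2(m$probs), 2, log2(bg), "-")
}

#' Exact null distribution of the motif score
#'
#' Rounds the per-position scores to a grid of step `granularity` and
#' convolves the per-position, background-weighted score distributions into
#' the exact distribution of the L-position sum. The upper tail gives the
#' p-value of any achievable window score.
#'
#' @param scores L x 4 log-odds matrix from [log_odds()].
#' @param bg background probabilities.
#' @param granularity score-grid step (log2 units).
#' @return object of class `score_distribution` with fields `granularity`,
#'   `min_int`/`max_int` (integer grid span), `pmf`, `tail` and the rounded
#'   integer score matrix `int_scores`.
#' @export
score_pvalue_table <- function(scores, bg = background_freq(),
                               granularity = 0.01) {
  if (!is.numeric(granularity) || length(granularity) != 1L ||
      granularity <= 0) {
    stop("granularity must be a single positive number", call. = FALSE)
  }
  bg <- background_freq(bg)
  si <- matrix(as.integer(round_half_up(scores / granularity)),
               nrow = nrow(scores), dimnames = dimnames(scores))
  lo <- sum(apply(si, 1L, min))
  hi <- sum(apply(si, 1L, max))
  if (hi - lo + 1 > 1e7) {
    stop("score grid of ", hi - lo + 1,
         " cells exceeds 1e7; use a coarser granularity", call. = FALSE)
  }
  # convolution: pmf over integer offsets, carried with its own origin
  pmf <- 1
  origin <- 0L
  for (j in seq_len(nrow(si))) {
    smin <- min(si[j, ])
    smax <- max(si[j, ])
    new <- numeric(length(pmf) + (smax - smin))
    for (b in 1:4) {
      sh <- si[j, b] - smin
      idx <- seq_along(pmf) + sh
      new[idx] <- new[idx] + pmf * bg[b]
    }
    pmf <- new
    origin <- origin + smin
  }
  stopifnot(origin == lo, length(pmf) == hi - lo + 1)
  tail <- rev(cumsum(rev(pmf)))
  structure(list(granularity = granularity, min_int = lo, max_int = hi,
                 pmf = pmf, tail = tail, int_scores = si),
            class = "score_distribution")
}

#' Upper-tail p-value of an integer grid score
#'
#' `P(S >= s)` under the background for a score on the distribution's grid.
#'
#' @param dist a `score_distribution`.
#' @param int_score integer grid score(s) (i.e. score / granularity).
#' @return p-value(s) in `[0, 1]`.
#' @export
tail_probability <- function(dist, int_score) {
  i <- pmin(pmax(int_score - dist$min_int + 1L, 0L),
            length(dist$tail) + 1L)
  out <- numeric(length(int_score))
  out[i <= 0L] <- 1
  inside <- i >= 1L & i <= length(dist$tail)
  out[inside] <- dist$tail[i[inside]]
  out[i > length(dist$tail)] <- 0
  out
}

# Smallest integer grid score whose tail p-value is <= p_threshold
# (Inf when even the maximum score is above the threshold).
.threshold_int <- function(dist, p_threshold) {
  ok <- which(dist$tail <= p_threshold)
  if (length(ok) == 0L) Inf else dist$min_int + ok[1L] - 1L
}

# Vectorized window scores of an integer code vector against an integer
# score matrix; windows touching an NA code (N or separator) come out NA.
.window_scores <- function(codes, si) {
  L <- nrow(si)
  W <- length(codes) - L + 1L
  if (W < 1L) return(numeric(0))
  tot <- numeric(W)
  for (j in seq_len(L)) {
    tot <- tot + si[j, ][codes[j:(j + W - 1L)]]
  }
  tot
}

#' Scan one sequence for motif occurrences
#'
#' Scores every window of the sequence against the motif on the forward
#' strand and (by default) the reverse strand via the reverse-complement
#' model, and reports windows whose exact p-value is at or below the
#' threshold. Windows containing `N` are skipped.
#'
#' @param seq a sequence string over A,C,G,T,N.
#' @param m a `motif_model`.
#' @param bg background probabilities.
#' @param p_threshold per-window p-value threshold (default the scanning
#'   threshold 1e-4).
#' @param strands `"both"` or `"forward"`.
#' @param granularity score-grid step.
#' @return data.frame with columns `start` (0-based), `end` (half-open),
#'   `strand`, `score`, `p`, ordered by position then strand.
#' @export
scan_sequence <- function(seq, m, bg = background_freq(), p_threshold = 1e-4,
                          strands = c("both", "forward"),
                          granularity = 0.01) {
  strands <- match.arg(strands)
  hits <- scan_promoters(c(seq_1 = seq), m, bg = bg,
                         p_threshold = p_threshold, strands = strands,
                         granularity = granularity)
  hits$promoter_id <- NULL
  hits
}

#' Scan a set of promoters for motif occurrences
#'
#' @param promoters named character vector or `DNAStringSet` of promoter
#'   sequences (unique names required).
#' @param m a `motif_model`.
#' @inheritParams scan_sequence
#' @return data.frame with columns `promoter_id`, `start` (0-based), `end`,
#'   `strand`, `score`, `p`.
#' @export
scan_promoters <- function(promoters, m, bg = background_freq(),
                           p_threshold = 1e-4,
                           strands = c("both", "forward"),
                           granularity = 0.01) {
  strands <- match.arg(strands)
  if (inherits(promoters, "DNAStringSet")) {
    promoters <- stats::setNames(as.character(promoters), names(promoters))
  }
  bg <- background_freq(bg)
  validate_motif(m)
  empty <- data.frame(promoter_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(promoters) == 0L) return(empty)
  if (is.null(names(promoters)) || anyDuplicated(names(promoters))) {
    stop("promoters must have unique names", call. = FALSE)
  }
  L <- m$length
  lens <- nchar(promoters)
  if (any(lens < L)) {
    warning(sum(lens < L), " promoter(s) shorter than the motif (length ",
            L, ") yield no windows")
  }
  if (all(lens < L)) return(empty)

  models <- list("+" = m)
  if (strands == "both") models[["-"]] <- reverse_complement_model(m)

  # concatenate with L-long N spacers; spacer windows score NA and drop out
  glued <- paste(promoters, collapse = strrep("N", L))
  codes <- seq_codes(glued)
  starts_big <- cumsum(c(1L, lens[-length(lens)] + L))

  out <- list()
  for (st in names(models)) {
    sc <- log_odds(models[[st]], bg)
    dist <- score_pvalue_table(sc, bg, granularity)
    tmin <- .threshold_int(dist, p_threshold)
    if (!is.finite(tmin)) next
    w <- .window_scores(codes, dist$int_scores)
    hit <- which(!is.na(w) & w >= tmin)
    if (length(hit) == 0L) next
    pi <- findInterval(hit, starts_big)
    start0 <- hit - starts_big[pi]
    keep <- start0 <= lens[pi] - L  # paranoid: spacers already give NA
    hit <- hit[keep]; pi <- pi[keep]; start0 <- start0[keep]
    out[[st]] <- data.frame(
      promoter_id = names(promoters)[pi], start = start0, end = start0 + L,
      strand = st, score = w[hit] * granularity,
      p = tail_probability(dist, as.integer(w[hit])),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(match(res$promoter_id, names(promoters)), res$start,
                   res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count promoters containing at least one motif hit
#'
#' A promoter counts once regardless of how many matches it contains.
#'
#' @inheritParams scan_promoters
#' @return list with `count` and `ids` (the promoter id set).
#' @export
count_promoters_with_hit <- function(promoters, m, bg = background_freq(),
                                     p_threshold = 1e-4,
                                     strands = c("both", "forward"),
                                     granularity = 0.01) {
  hits <- scan_promoters(promoters, m, bg = bg, p_threshold = p_threshold,
                         strands = strands, granularity = granularity)
  ids <- unique(hits$promoter_id)
  list(count = length(ids), ids = ids)
}

#' Scan a promoter universe against several models and tabulate hits by set
#'
#' Scans every model once over the full universe and intersects the
#' promoter-level hit sets with the supplied gene sets; the per-set
#' "non-redundant" union counts promoters hit by at least one model.
#'
#' @param models named list of `motif_model` objects.
#' @param promoters named sequences forming the universe.
#' @param sets named list of promoter-id subsets of the universe (the
#'   universe itself is always reported as set `"all"`).
#' @inheritParams scan_promoters
#' @return list with `hit_sets` (model -> promoter ids with >= 1 hit),
#'   `counts` (data.frame model x set counts incl. the non-redundant union
#'   row), and `union_ids` per set.
#' @export
scan_promoter_sets <- function(models, promoters, sets = list(),
                               bg = background_freq(), p_threshold = 1e-4,
                               strands = c("both", "forward"),
                               granularity = 0.01) {
  strands <- match.arg(strands)
  univ <- names(promoters)
  bad <- vapply(sets, function(s) !all(s %in% univ), logical(1))
  if (any(bad)) {
    stop("sets not contained in the promoter universe: ",
         paste(names(sets)[bad], collapse = ", "), call. = FALSE)
  }
  hit_sets <- lapply(models, function(m) {
    count_promoters_with_hit(promoters, m, bg = bg,
                             p_threshold = p_threshold, strands = strands,
                             granularity = granularity)$ids
  })
  all_sets <- c(list(all = univ), sets)
  counts <- data.frame(model = names(models), stringsAsFactors = FALSE)
  for (sn in names(all_sets)) {
    counts[[sn]] <- vapply(hit_sets,
                           function(h) length(intersect(h, all_sets[[sn]])),
                           integer(1))
  }
  union_ids <- lapply(all_sets, function(s) {
    intersect(s, unique(unlist(hit_sets, use.names = FALSE)))
  })
  total <- c(list(model = "Total, non-redundant"),
             lapply(union_ids, length))
  counts <- rbind(counts, as.data.frame(total, stringsAsFactors = FALSE))
  rownames(counts) <- NULL
  list(hit_sets = hit_sets, counts = counts, union_ids = union_ids)
}
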