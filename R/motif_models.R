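# Construction of palindromic NAC binding site (NACBS) letter-probability
# models. The family shares a CGT core; the palindromic members pair the core
# with an inverted-repeat ACG block separated by a variable 5-10 nt spacer.

# Consensus strings of the seven default models. Upper case = core (fixed)
# positions, lower case = weakly conserved (minor weight) positions,
# n = unconstrained. NACBS-k for k in 5..10 is tt n CGT (n x k) ACG nnn;
# NACBS-1 has no inverted repeat but conserved T at -2/-3 of the core.
.nacbs_consensus <- function() {
  cons <- c("NACBS-1" = "nttnCGTgnnn")
  for (k in 5:10) {
    cons[paste0("NACBS-", k)] <-
      paste0("ttn", "CGT", strrep("n", k), "ACG", "nnn")
  }
  cons
}

#' Weighting scheme for consensus expansion
#'
#' Probabilities assigned when a consensus string is expanded into a
#' letter-probability matrix: `core_prob` for upper-case (core) bases,
#' `minor_prob` for lower-case (weakly conserved) bases, uniform 0.25 for
#' `n`. The remainder of each row is split equally over the other three
#' bases, every probability is floored at `floor` and the row renormalized.
#'
#' @param core_prob probability of the consensus base at a core position.
#' @param minor_prob probability of the consensus base at a minor position.
#' @param floor minimum probability retained in any cell (keeps log-odds
#'   scores finite).
#' @return an object of class `weight_scheme`.
#' @export
#' @examples
#' weight_scheme()
weight_scheme <- function(core_prob = 0.94, minor_prob = 0.70, floor = 0.001) {
  if (!(core_prob > minor_prob && minor_prob > 0.25)) {
    stop("weights must satisfy core_prob > minor_prob > 0.25", call. = FALSE)
  }
  off_core <- (1 - core_prob) / 3
  off_minor <- (1 - minor_prob) / 3
  if (!(0.25 >= off_core && 0.25 >= off_minor)) {
    stop("off-base probabilities must not exceed 0.25", call. = FALSE)
  }
  if (floor <= 0 || floor >= min(off_core, off_minor)) {
    stop("floor must be positive and below every off-base probability",
         call. = FALSE)
  }
  structure(list(core_prob = core_prob, minor_prob = minor_prob,
                 n_prob = 0.25, floor = floor),
            class = "weight_scheme")
}

.expand_position <- function(ch, weights) {
  row <- rep(0.25, 4)
  names(row) <- DNA_BASES
  up <- toupper(ch)
  if (ch == "n" || ch == "N") {
    # uniform
  } else if (up %in% DNA_BASES) {
    main <- if (ch == up) weights$core_prob else weights$minor_prob
    row[] <- (1 - main) / 3
    row[up] <- main
  } else {
    stop("consensus character '", ch, "' is not one of A,C,G,T,a,c,g,t,n",
         call. = FALSE)
  }
  row <- pmax(row, weights$floor)
  row / sum(row)
}

#' Build an NACBS letter-probability model
#'
#' Expands a consensus string position-wise into an L x 4 letter-probability
#' matrix using a [weight_scheme()]. The seven default models can be named
#' directly (`"NACBS-1"`, `"NACBS-5"` ... `"NACBS-10"`); alternatively a
#' custom consensus over `{A,C,G,T,a,c,g,t,n}` may be supplied.
#'
#' @param name model name; one of the defaults unless `consensus` is given.
#' @param weights a [weight_scheme()].
#' @param consensus optional custom consensus string.
#' @return an object of class `motif_model` with fields `name`, `length`,
#'   `probs` (L x 4 matrix, columns A,C,G,T), `consensus` and `spacer`
#'   (inverted-repeat span, `NA` when there is none).
#' @export
#' @examples
#' m <- build_nacbs("NACBS-8")
#' m$length # 20
build_nacbs <- function(name, weights = weight_scheme(), consensus = NULL) {
  stopifnot(inherits(weights, "weight_scheme"))
  defaults <- .nacbs_consensus()
  spacer <- NA_integer_
  if (is.null(consensus)) {
    if (!name %in% names(defaults)) {
      stop("unknown model name '", name,
           "' and no consensus string supplied; known names: ",
           paste(names(defaults), collapse = ", "), call. = FALSE)
    }
    consensus <- defaults[[name]]
    k <- as.integer(sub("NACBS-", "", name, fixed = TRUE))
    if (k >= 5L) spacer <- k
  }
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  probs <- t(vapply(chars, .expand_position, numeric(4), weights = weights))
  dimnames(probs) <- list(NULL, DNA_BASES)
  structure(list(name = name, length = length(chars), probs = probs,
                 consensus = consensus, spacer = spacer),
            class = "motif_model")
}

#' Build the seven default NACBS models
#'
#' @param weights a [weight_scheme()].
#' @return named list of seven `motif_model` objects (NACBS-1, NACBS-5 ...
#'   NACBS-10, lengths 11 and 17-22).
#' @export
build_all_default <- function(weights = weight_scheme()) {
  nm <- names(.nacbs_consensus())
  stats::setNames(lapply(nm, build_nacbs, weights = weights), nm)
}

#' Reverse-complement a motif model
#'
#' Reverses the positions and swaps A with T and C with G, giving the model
#' matched by the opposite strand. Applying it twice returns the original.
#'
#' @param m a `motif_model`.
#' @return a `motif_model` for the reverse strand.
#' @export
reverse_complement_model <- function(m) {
  stopifnot(inherits(m, "motif_model"))
  probs <- m$probs[rev(seq_len(m$length)), c("T", "G", "C", "A"), drop = FALSE]
  dimnames(probs) <- list(NULL, DNA_BASES)
  structure(list(name = m$name, length = m$length, probs = probs,
                 consensus = revcomp_chr(m$consensus), spacer = m$spacer),
            class = "motif_model")
}

validate_motif <- function(m) {
  stopifnot(inherits(m, "motif_model"))
  if (nrow(m$probs) != m$length || ncol(m$probs) != 4L) {
    stop("motif '", m$name, "': probability matrix must be length x 4",
         call. = FALSE)
  }
  if (any(abs(rowSums(m$probs) - 1) > 1e-9)) {
    stop("motif '", m$name, "': rows must sum to 1", call. = FALSE)
  }
  if (any(m$probs < 0.001 - 1e-12)) {
    stop("motif '", m$name, "': probabilities below the 0.001 floor",
         call. = FALSE)
  }
  invisible(m)
}

#' @export
print.motif_model <- function(x, ...) {
  sp <- if (is.na(x$spacer)) "none" else x$spacer
  cat(sprintf("<motif_model> %s  length %d  spacer %s\n  consensus %s\n",
              x$name, x$length, sp, x$consensus))
  invisible(x)
}

#' Per-position information content of a model
#'
#' Information content in bits relative to a background, `sum p * log2(p/bg)`
#' per position.
#'
#' @param m a `motif_model`.
#' @param bg background probabilities (default uniform).
#' @return numeric vector, one value per motif position.
#' @export
information_content <- function(m, bg = background_freq()) {
  rowSums(m$probs * log2(sweep(m$probs, 2, bg, "/")))
}
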