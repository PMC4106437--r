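# Shared small helpers.

DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Rounding used for reported integer rates and percentages (half-integers
#' round up), as opposed to base R's round-half-even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

# Reverse-complement a character DNA string, preserving case
# (a/c/g/t/n stay lower case). Used for consensus strings and planted words.
revcomp_chr <- function(s) {
  flipped <- chartr("ACGTacgtNn", "TGCAtgcaNn", s)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Map a sequence string to integer codes 1..4 (A,C,G,T); N and anything
# else becomes NA so windows containing it drop out of scoring.
seq_codes <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

stopifnot_prob_vector <- function(p, what) {
  if (length(p) != 4L || any(!is.finite(p)) || any(p <= 0) ||
      abs(sum(p) - 1) > 1e-6) {
    stop(what, " must be 4 positive probabilities over A,C,G,T summing to 1",
         call. = FALSE)
  }
  p <- as.numeric(p)
  names(p) <- DNA_BASES
  p
}
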