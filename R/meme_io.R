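# Reading and writing motif models in MEME minimal motif format. No
# installed R package parses this format, so the (small) parser lives here.

#' Write motif models in MEME minimal format
#'
#' @param models a `motif_model` or list of them.
#' @param path output file.
#' @param bg background letter frequencies written to the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(models, path, bg = background_freq()) {
  if (inherits(models, "motif_model")) models <- list(models)
  lapply(models, validate_motif)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, bg), collapse = " "), ""),
             con)
  for (m in models) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", m$length),
      con)
    writeLines(apply(m$probs, 1L,
                     function(r) paste(sprintf("%10.6f", r), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motif models from a MEME minimal file
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` headers. The
#' consensus string is reconstructed from the probabilities (>= 0.85 upper
#' case, >= 0.45 lower case, else `n`) and the spacer is recovered from
#' default model names where applicable.
#'
#' @param path MEME minimal file.
#' @return named list of `motif_model` objects (empty list for a file with
#'   no motif blocks).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  models <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[[i]])
    if (startsWith(line, "MOTIF")) {
      name <- strsplit(line, "[[:space:]]+")[[1]][2]
      if (is.na(name) || !nzchar(name)) {
        stop("line ", i, ": MOTIF line without a name", call. = FALSE)
      }
      # find the matrix header
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix", trimws(lines[[j]]))) {
        if (startsWith(trimws(lines[[j]]), "MOTIF")) {
          stop("line ", i, ": MOTIF block without letter-probability matrix",
               call. = FALSE)
        }
        j <- j + 1L
      }
      if (j > length(lines)) {
        stop("line ", i, ": MOTIF block without letter-probability matrix",
             call. = FALSE)
      }
      hdr <- trimws(lines[[j]])
      alength <- .meme_field(hdr, "alength")
      w <- .meme_field(hdr, "w")
      if (!is.na(alength) && alength != 4L) {
        stop("line ", j, ": alphabet length ", alength,
             " not supported (expected 4)", call. = FALSE)
      }
      rows <- list()
      j <- j + 1L
      while (j <= length(lines)) {
        vals <- suppressWarnings(
          as.numeric(strsplit(trimws(lines[[j]]), "[[:space:]]+")[[1]]))
        if (length(vals) == 0L || all(is.na(vals)) ||
            !nzchar(trimws(lines[[j]]))) break
        if (length(vals) != 4L || any(is.na(vals))) {
          stop("line ", j, ": expected 4 numeric probabilities, got '",
               trimws(lines[[j]]), "'", call. = FALSE)
        }
        if (abs(sum(vals) - 1) > 1e-3) {
          stop("line ", j, ": probability row sums to ",
               format(sum(vals)), ", not 1", call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- vals
        j <- j + 1L
      }
      if (length(rows) == 0L) {
        stop("line ", i, ": motif '", name, "' has an empty matrix",
             call. = FALSE)
      }
      if (!is.na(w) && w != length(rows)) {
        stop("line ", i, ": motif '", name, "' declares w= ", w,
             " but has ", length(rows), " rows", call. = FALSE)
      }
      probs <- do.call(rbind, rows)
      dimnames(probs) <- list(NULL, DNA_BASES)
      models[[name]] <- structure(
        list(name = name, length = nrow(probs), probs = probs,
             consensus = .consensus_from_probs(probs),
             spacer = .spacer_from_name(name)),
        class = "motif_model")
      i <- j
    } else {
      i <- i + 1L
    }
  }
  models
}

.meme_field <- function(hdr, field) {
  m <- regmatches(hdr, regexec(paste0(field, "=[[:space:]]*([0-9]+)"), hdr))[[1]]
  if (length(m) < 2L) NA_integer_ else as.integer(m[2])
}

.consensus_from_probs <- function(probs) {
  paste(apply(probs, 1L, function(r) {
    b <- DNA_BASES[which.max(r)]
    if (max(r) >= 0.85) b else if (max(r) >= 0.45) tolower(b) else "n"
  }), collapse = "")
}

.spacer_from_name <- function(name) {
  if (grepl("^NACBS-([5-9]|10)$", name)) {
    as.integer(sub("NACBS-", "", name, fixed = TRUE))
  } else {
    NA_integer_
  }
}
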