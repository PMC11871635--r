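# Position weight matrices: constructor, consensus, reverse complement, and
# MEME minimal-format I/O.

#' Construct a position weight matrix record
#'
#' @param motif_id Motif identifier.
#' @param tf_symbol Symbol of the transcription factor the motif belongs to.
#' @param probs Numeric `width x 4` matrix of per-position base
#'   probabilities, columns in A, C, G, T order; every row must sum to 1
#'   (within 1e-6).
#' @return A list of class `"pwm"`.
#' @export
pwm_record <- function(motif_id, tf_symbol, probs) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4, nrow(probs) >= 1,
            all(is.finite(probs)), all(probs >= 0))
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6)) {
    stop(sprintf("PWM '%s': row %d sums to %.8f, not 1",
                 motif_id, which(abs(rs - 1) > 1e-6)[1],
                 rs[which(abs(rs - 1) > 1e-6)[1]]), call. = FALSE)
  }
  dimnames(probs) <- list(NULL, DNA_BASES)
  structure(list(motif_id = as.character(motif_id),
                 tf_symbol = as.character(tf_symbol),
                 probs = probs),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (TF %s), width %d, consensus %s\n",
              x$motif_id, x$tf_symbol, pwm_width(x),
              pwm_consensus(x)))
  invisible(x)
}

#' Motif width of a PWM
#' @param pwm A `"pwm"` object.
#' @return Integer width.
#' @export
pwm_width <- function(pwm) nrow(pwm$probs)

#' Consensus sequence of a PWM (per-position argmax)
#' @param pwm A `"pwm"` object.
#' @return A character string.
#' @export
pwm_consensus <- function(pwm) {
  paste0(DNA_BASES[apply(pwm$probs, 1, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param pwm A `"pwm"` object.
#' @return A `"pwm"` with rows reversed and complementary columns swapped.
#' @export
pwm_revcomp <- function(pwm) {
  p <- pwm$probs[rev(seq_len(nrow(pwm$probs))), DNA_COMPLEMENT, drop = FALSE]
  dimnames(p) <- list(NULL, DNA_BASES)
  pwm_record(pwm$motif_id, pwm$tf_symbol, p)
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections.
#' The TF symbol is taken from the motif's alternate name when present,
#' otherwise from the motif id. Rows off unity by at most 1e-3 are
#' renormalised; larger deviations are an error, as is any alphabet other
#' than ACGT.
#'
#' @param path Path to a MEME minimal-format motif file.
#' @return A named list of `"pwm"` objects (names are motif ids).
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME minimal-format file (missing 'MEME version')",
         call. = FALSE)
  }
  alpha <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alpha) &&
      gsub("[[:space:]=]", "", alpha[1]) != "ALPHABETACGT") {
    stop("unsupported alphabet (need ACGT)", call. = FALSE)
  }
  starts <- grep("^MOTIF([[:space:]]|$)", lines)
  out <- list()
  for (s in starts) {
    tok <- strsplit(trimws(lines[s]), "[[:space:]]+")[[1]]
    if (length(tok) < 2) stop("MOTIF line without an id", call. = FALSE)
    motif_id <- tok[2]
    tf_symbol <- if (length(tok) >= 3) tok[3] else tok[2]
    mline <- s + which(grepl("^letter-probability matrix",
                             lines[(s + 1):length(lines)]))[1]
    if (is.na(mline)) {
      stop(sprintf("motif '%s': no letter-probability matrix", motif_id),
           call. = FALSE)
    }
    wm <- regmatches(lines[mline],
                     regexec("w=[[:space:]]*([0-9]+)", lines[mline]))[[1]]
    if (length(wm) < 2) {
      stop(sprintf("motif '%s': matrix line lacks w=", motif_id),
           call. = FALSE)
    }
    w <- as.integer(wm[2])
    rows <- matrix(NA_real_, nrow = w, ncol = 4)
    i <- mline
    for (r in seq_len(w)) {
      i <- i + 1
      while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1
      vals <- suppressWarnings(
        as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]))
      if (length(vals) != 4 || anyNA(vals)) {
        stop(sprintf("motif '%s': bad matrix row %d", motif_id, r),
             call. = FALSE)
      }
      rows[r, ] <- vals
    }
    rs <- rowSums(rows)
    if (any(abs(rs - 1) > 1e-3)) {
      stop(sprintf("motif '%s': row %d sums to %.6f (tolerance 1e-3)",
                   motif_id, which(abs(rs - 1) > 1e-3)[1],
                   rs[which(abs(rs - 1) > 1e-3)[1]]), call. = FALSE)
    }
    rows <- rows / rs
    out[[motif_id]] <- pwm_record(motif_id, tf_symbol, rows)
  }
  if (!length(out)) stop("no MOTIF blocks found", call. = FALSE)
  out
}

#' Write motifs in MEME minimal format
#' @param pwms A list of `"pwm"` objects.
#' @param path Output path.
#' @param background Background frequencies recorded in the header.
#' @export
write_meme_motifs <- function(pwms, path,
                              background = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, background),
                     collapse = " "), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s %s", p$motif_id, p$tf_symbol), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      pwm_width(p)), con)
    writeLines(apply(p$probs, 1, function(r) {
      paste(sprintf("%.6f", r), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}
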