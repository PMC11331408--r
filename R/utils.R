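#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr list_rbind
#' @importFrom stats rbinom rgeom runif sd setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequence
#'
#' Draws a sequence over {A,C,G,T} with a configurable GC content, using the
#' session RNG (seed it for reproducibility).
#'
#' @param n Sequence length in nt.
#' @param gc Target GC fraction in \[0,1\].
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

check_dna <- function(x, arg = "sequence") {
  if (length(x) != 1L || is.na(x) || !is.character(x)) {
    abort(sprintf("%s must be a single character string", arg))
  }
  if (nchar(x) > 0L && grepl("[^ACGT]", x)) {
    abort(sprintf("%s contains characters outside {A,C,G,T}", arg))
  }
  invisible(x)
}

substr0 <- function(x, start, stop) {
  # clamped substring; returns "" when the interval is empty
  if (stop < start) return("")
  substr(x, max(1L, start), min(nchar(x), stop))
}

#' Decode a PHRED+33 quality string
#'
#' @param qual Character vector of quality strings.
#' @return List of integer vectors of PHRED scores.
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Encode PHRED scores as a PHRED+33 quality string
#'
#' @param scores Integer vector of PHRED scores (0-60).
#' @return A single quality string.
#' @export
phred_encode <- function(scores) {
  stopifnot(all(scores >= 0), all(scores <= 93))
  rawToChar(as.raw(as.integer(scores) + 33L))
}

# longest common prefix length of two strings, capped at `cap`
common_prefix_len <- function(a, b, cap = Inf) {
  n <- min(nchar(a), nchar(b), cap)
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "")[[1L]]
  bv <- strsplit(substr(b, 1L, n), "")[[1L]]
  neq <- which(av != bv)
  if (length(neq) == 0L) as.integer(n) else neq[1L] - 1L
}

# longest common suffix length
common_suffix_len <- function(a, b, cap = Inf) {
  n <- min(nchar(a), nchar(b), cap)
  if (n == 0L) return(0L)
  av <- rev(strsplit(substr(a, nchar(a) - n + 1L, nchar(a)), "")[[1L]])
  bv <- rev(strsplit(substr(b, nchar(b) - n + 1L, nchar(b)), "")[[1L]])
  neq <- which(av != bv)
  if (length(neq) == 0L) as.integer(n) else neq[1L] - 1L
}
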