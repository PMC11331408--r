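#' Read filtering parameters
#'
#' The read-hygiene contract: exact duplicate pairs are removed, low-quality
#' ends are trimmed, and reads shorter than 36 bp or with PHRED quality
#' below 30 are discarded (together with their mates, since pairs without
#' both mates are unusable downstream).
#'
#' @param min_len Minimum retained read length (default 36 bp).
#' @param min_qual Mean-PHRED keep threshold (default 30): a read whose mean
#'   trimmed quality is below this is discarded.
#' @param trim_qual End-trimming threshold (default 3): leading/trailing
#'   bases below this are removed before filtering.
#' @param trim_mode `"leading_trailing"` trims bases below `trim_qual` from
#'   both ends; `"sliding_window"` additionally truncates the read at the
#'   first `window_len`-base window whose mean quality falls below
#'   `window_qual`.
#' @param window_len Window size for sliding-window mode (default 4).
#' @param window_qual Mean-quality threshold per window (default 15).
#' @param dedup Remove exact duplicate pairs first (default TRUE).
#' @return A list of class `read_filter_params`.
#' @export
read_filter_params <- function(min_len = 36L, min_qual = 30L, trim_qual = 3L,
                               trim_mode = c("leading_trailing", "sliding_window"),
                               window_len = 4L, window_qual = 15L,
                               dedup = TRUE) {
  trim_mode <- match.arg(trim_mode)
  stopifnot(min_len >= 1, min_qual >= 0, min_qual <= 60, trim_qual >= 0)
  structure(list(min_len = as.integer(min_len), min_qual = as.integer(min_qual),
                 trim_qual = as.integer(trim_qual), trim_mode = trim_mode,
                 window_len = as.integer(window_len),
                 window_qual = as.integer(window_qual),
                 dedup = isTRUE(dedup)),
            class = "read_filter_params")
}

#' Remove exact duplicate read pairs
#'
#' Pairs whose R1 and R2 sequences are both identical to an earlier pair are
#' collapsed to the first representative; survivor order is stable.
#'
#' @param pairs Read-pair tibble (`read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @return The deduplicated tibble.
#' @export
dedup_pairs <- function(pairs) {
  check_pairs(pairs)
  pairs[!duplicated(paste(pairs$seq1, pairs$seq2, sep = "\r")), , drop = FALSE]
}

check_pairs <- function(pairs) {
  need <- c("read_id", "seq1", "qual1", "seq2", "qual2")
  if (!all(need %in% names(pairs))) {
    abort(paste("read-pair table must have columns", paste(need, collapse = ", ")))
  }
  bad <- which(nchar(pairs$seq1) != nchar(pairs$qual1) |
                 nchar(pairs$seq2) != nchar(pairs$qual2))
  if (length(bad) > 0L) {
    abort(sprintf("malformed record at pair index %d: sequence/quality length mismatch", bad[1]))
  }
  invisible(pairs)
}

trim_read <- function(seq, qual, params) {
  q <- as.integer(charToRaw(qual)) - 33L
  n <- length(q)
  if (n == 0L) return(list(seq = "", qual = ""))
  keep_from <- 1L
  while (keep_from <= n && q[keep_from] < params$trim_qual) keep_from <- keep_from + 1L
  if (params$trim_mode == "leading_trailing") {
    keep_to <- n
    while (keep_to >= keep_from && q[keep_to] < params$trim_qual) keep_to <- keep_to - 1L
  } else {
    keep_to <- n
    w <- params$window_len
    if (keep_from <= n - w + 1L) {
      means <- vapply(keep_from:(n - w + 1L),
                      function(i) mean(q[i:(i + w - 1L)]), numeric(1))
      hit <- which(means < params$window_qual)
      if (length(hit) > 0L) keep_to <- keep_from + hit[1L] - 2L
    }
    while (keep_to >= keep_from && q[keep_to] < params$trim_qual) keep_to <- keep_to - 1L
  }
  if (keep_to < keep_from) return(list(seq = "", qual = ""))
  list(seq = substr(seq, keep_from, keep_to), qual = substr(qual, keep_from, keep_to))
}

#' Quality-trim reads and discard short or low-quality pairs
#'
#' Each read has low-quality ends trimmed per `params$trim_mode`; a read
#' whose trimmed length is below `min_len` or whose mean trimmed quality is
#' below `min_qual` is discarded together with its mate. The discard log
#' counts reasons (length takes precedence when both fail).
#'
#' @param pairs Read-pair tibble.
#' @param params A [read_filter_params()].
#' @return List with `pairs` (survivors, trimmed) and `log` (named list:
#'   `input_pairs`, `trimmed`, `discarded_len`, `discarded_qual`,
#'   `survivors`).
#' @export
trim_and_filter <- function(pairs, params = read_filter_params()) {
  check_pairs(pairs)
  n <- nrow(pairs)
  out <- pairs
  reason <- rep(NA_character_, n)
  trimmed_any <- logical(n)
  for (i in seq_len(n)) {
    fate <- NA_character_
    for (mate in 1:2) {
      sq <- out[[paste0("seq", mate)]][i]
      ql <- out[[paste0("qual", mate)]][i]
      tr <- trim_read(sq, ql, params)
      if (nchar(tr$seq) != nchar(sq)) trimmed_any[i] <- TRUE
      out[[paste0("seq", mate)]][i] <- tr$seq
      out[[paste0("qual", mate)]][i] <- tr$qual
      if (is.na(fate)) {
        if (nchar(tr$seq) < params$min_len) {
          fate <- "len"
        } else {
          q <- as.integer(charToRaw(tr$qual)) - 33L
          if (mean(q) < params$min_qual) fate <- "qual"
        }
      }
    }
    reason[i] <- fate
  }
  keep <- is.na(reason)
  list(
    pairs = out[keep, , drop = FALSE],
    log = list(
      input_pairs = n,
      trimmed = sum(trimmed_any),
      discarded_len = sum(reason == "len", na.rm = TRUE),
      discarded_qual = sum(reason == "qual", na.rm = TRUE),
      survivors = sum(keep)
    )
  )
}

#' Full read-hygiene step: deduplicate, trim, filter
#'
#' @param pairs Read-pair tibble.
#' @param params A [read_filter_params()].
#' @return List with `pairs` and a `log` including `dup_removed`.
#' @export
prep_reads <- function(pairs, params = read_filter_params()) {
  n0 <- nrow(pairs)
  if (params$dedup) pairs <- dedup_pairs(pairs)
  dup_removed <- n0 - nrow(pairs)
  res <- trim_and_filter(pairs, params)
  res$log <- c(list(input_pairs = n0, dup_removed = dup_removed),
               res$log[setdiff(names(res$log), "input_pairs")])
  res
}
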