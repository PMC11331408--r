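#' Alignment scoring parameters
#'
#' Match/mismatch scores with affine gap penalties: a gap of length L costs
#' `gap_open + L * gap_extend`. Defaults (1 / -4 / -6 / -1) follow the
#' magnitudes used by mainstream short-read mappers.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap opening penalty (>= 0, subtracted).
#' @param gap_extend Per-base gap extension penalty (>= 0, subtracted).
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -4, gap_open = 6, gap_extend = 1) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

scoring_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
}

# exact substring search on both strands; returns NULL or a segment row
exact_hit <- function(query, ref, scoring) {
  n <- nchar(query)
  pos <- regexpr(query, ref, fixed = TRUE)[1]
  if (pos > 0) {
    return(tibble(read_start = 1L, read_end = n, ref_start = as.integer(pos),
                  ref_end = as.integer(pos) + n - 1L, strand = "+",
                  score = scoring$match * n))
  }
  rc <- revcomp(query)
  pos <- regexpr(rc, ref, fixed = TRUE)[1]
  if (pos > 0) {
    return(tibble(read_start = 1L, read_end = n, ref_start = as.integer(pos),
                  ref_end = as.integer(pos) + n - 1L, strand = "-",
                  score = scoring$match * n))
  }
  NULL
}

#' Best local alignment of a query against a reference
#'
#' Affine-gap local (Smith-Waterman) alignment on both strands, with an
#' exact-substring fast path (an exact full-length match is always
#' score-optimal, and the leftmost occurrence is reported). Ties between
#' strands resolve to the plus strand. Strand `"-"` means the reverse
#' complement of the read interval matches the reference forward strand.
#'
#' @param query Query sequence (read or read fragment).
#' @param ref Reference sequence.
#' @param scoring An [align_scoring()].
#' @param both_strands Also try the reverse complement (default TRUE).
#' @return A one-row tibble: `read_start`, `read_end`, `ref_start`,
#'   `ref_end`, `strand`, `score`, `clipped_left`, `clipped_right` (unaligned
#'   read bases on each side).
#' @export
align_local <- function(query, ref, scoring = align_scoring(), both_strands = TRUE) {
  if (nchar(query) == 0L) abort("empty query")
  n <- nchar(query)
  seg <- exact_hit(query, ref, scoring)
  if (is.null(seg)) {
    mat <- scoring_matrix(scoring)
    fwd <- Biostrings::pairwiseAlignment(
      query, ref, type = "local", substitutionMatrix = mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    best <- fwd; strand <- "+"
    if (both_strands) {
      rev <- Biostrings::pairwiseAlignment(
        revcomp(query), ref, type = "local", substitutionMatrix = mat,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
      if (Biostrings::score(rev) > Biostrings::score(fwd)) {
        best <- rev; strand <- "-"
      }
    }
    p <- Biostrings::pattern(best)
    s <- Biostrings::subject(best)
    qs <- Biostrings::start(p); qe <- Biostrings::end(p)
    if (strand == "-") {
      tmp <- qs; qs <- n - qe + 1L; qe <- n - tmp + 1L
    }
    seg <- tibble(read_start = qs, read_end = qe,
                  ref_start = Biostrings::start(s), ref_end = Biostrings::end(s),
                  strand = strand, score = Biostrings::score(best))
  }
  seg$clipped_left <- seg$read_start - 1L
  seg$clipped_right <- n - seg$read_end
  seg
}

#' Split (supplementary) alignment of a read against one reference
#'
#' Repeatedly takes the best local alignment and recurses into the clipped
#' remainders, emulating a split-read mapper on a single reference. Segments
#' shorter than `min_seg_len` or scoring below `min_score` are left
#' unassigned (they become candidate nontemplated inserts downstream).
#'
#' @param query Read sequence.
#' @param ref Reference sequence.
#' @param scoring An [align_scoring()].
#' @param min_seg_len Minimum segment length (default 10).
#' @param min_score Minimum accepted segment score (default `min_seg_len`).
#' @return Tibble of segments (possibly 0 rows) in read order, columns as
#'   [align_local()] without the clip columns.
#' @export
align_split <- function(query, ref, scoring = align_scoring(),
                        min_seg_len = 10L, min_score = NULL) {
  min_score <- min_score %||% (min_seg_len * scoring$match)
  recurse <- function(a, b) {
    len <- b - a + 1L
    if (len < min_seg_len) return(NULL)
    seg <- align_local(substr(query, a, b), ref, scoring)
    if (seg$score < min_score || (seg$read_end - seg$read_start + 1L) < min_seg_len) {
      return(NULL)
    }
    seg$read_start <- seg$read_start + a - 1L
    seg$read_end <- seg$read_end + a - 1L
    bind_rows(
      recurse(a, seg$read_start - 1L),
      seg[, c("read_start", "read_end", "ref_start", "ref_end", "strand", "score")],
      recurse(seg$read_end + 1L, b)
    )
  }
  out <- recurse(1L, nchar(query))
  if (is.null(out)) {
    return(tibble(read_start = integer(), read_end = integer(),
                  ref_start = integer(), ref_end = integer(),
                  strand = character(), score = numeric()))
  }
  arrange(out, .data$read_start)
}

# Batched best local alignments: fragments (character vector) vs one ref.
# Returns a tibble with one row per fragment (read_start/read_end relative to
# the fragment). Uses exact fast paths, then vectorised pairwiseAlignment.
align_batch <- function(frags, ref, scoring) {
  n <- length(frags)
  if (n == 0L) {
    return(tibble(idx = integer(), read_start = integer(), read_end = integer(),
                  ref_start = integer(), ref_end = integer(),
                  strand = character(), score = numeric()))
  }
  lens <- nchar(frags)
  read_start <- integer(n); read_end <- integer(n)
  ref_start <- integer(n); ref_end <- integer(n)
  strand <- character(n); score <- numeric(n)
  todo <- logical(n)
  for (i in seq_len(n)) {
    pos <- regexpr(frags[i], ref, fixed = TRUE)[1]
    str <- "+"
    if (pos <= 0) {
      pos <- regexpr(revcomp(frags[i]), ref, fixed = TRUE)[1]
      str <- "-"
    }
    if (pos > 0) {
      read_start[i] <- 1L; read_end[i] <- lens[i]
      ref_start[i] <- pos; ref_end[i] <- pos + lens[i] - 1L
      strand[i] <- str; score[i] <- scoring$match * lens[i]
    } else {
      todo[i] <- TRUE
    }
  }
  if (any(todo)) {
    idx <- which(todo)
    mat <- scoring_matrix(scoring)
    pats <- Biostrings::DNAStringSet(frags[idx])
    fwd <- Biostrings::pairwiseAlignment(
      pats, ref, type = "local", substitutionMatrix = mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    rev <- Biostrings::pairwiseAlignment(
      Biostrings::reverseComplement(pats), ref, type = "local",
      substitutionMatrix = mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    fs <- Biostrings::score(fwd); rs <- Biostrings::score(rev)
    f_qs <- Biostrings::start(Biostrings::pattern(fwd))
    f_qe <- Biostrings::end(Biostrings::pattern(fwd))
    f_ss <- Biostrings::start(Biostrings::subject(fwd))
    f_se <- Biostrings::end(Biostrings::subject(fwd))
    r_qs <- Biostrings::start(Biostrings::pattern(rev))
    r_qe <- Biostrings::end(Biostrings::pattern(rev))
    r_ss <- Biostrings::start(Biostrings::subject(rev))
    r_se <- Biostrings::end(Biostrings::subject(rev))
    use_rev <- rs > fs
    l <- lens[idx]
    read_start[idx] <- ifelse(use_rev, l - r_qe + 1L, f_qs)
    read_end[idx] <- ifelse(use_rev, l - r_qs + 1L, f_qe)
    ref_start[idx] <- ifelse(use_rev, r_ss, f_ss)
    ref_end[idx] <- ifelse(use_rev, r_se, f_se)
    strand[idx] <- ifelse(use_rev, "-", "+")
    score[idx] <- ifelse(use_rev, rs, fs)
  }
  tibble(idx = seq_len(n), read_start = read_start, read_end = read_end,
         ref_start = ref_start, ref_end = ref_end, strand = strand,
         score = score)
}
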