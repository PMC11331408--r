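#' Cascade mapping parameters
#'
#' @param scoring An [align_scoring()].
#' @param min_seg_len Minimum reported segment length (default 10); shorter
#'   clipped portions are left unassigned and become candidate nontemplated
#'   inserts.
#' @param dp_min_score Minimum score for segments found by dynamic
#'   programming (default 18, high enough that chance local alignments of a
#'   150-nt read against desk-scale references are not reported); exact
#'   substring hits are accepted from `min_seg_len` up.
#' @param max_gap_len Largest indel (nt) a single segment may absorb
#'   (default 15); alignments bridging a longer insertion are split at the
#'   divergence point so the bridged sequence is re-mapped on its own.
#' @param fuzzy_max_edits Edit tolerance of the regex-style rescue against
#'   the insertion-site context (default 3).
#' @param context_len Length of rDNA context around the insertion site used
#'   for the rescue (default 60).
#' @param host_cover_frac Fraction of a read that a host alignment must
#'   explain before the read counts as host-dominant (default 0.9).
#' @return A list of class `cascade_params`.
#' @export
cascade_params <- function(scoring = align_scoring(), min_seg_len = 10L,
                           dp_min_score = 18, max_gap_len = 15L,
                           fuzzy_max_edits = 3L, context_len = 60L,
                           host_cover_frac = 0.9) {
  stopifnot(min_seg_len >= 10, fuzzy_max_edits >= 0, max_gap_len >= 0)
  structure(list(scoring = scoring, min_seg_len = as.integer(min_seg_len),
                 dp_min_score = dp_min_score,
                 max_gap_len = as.integer(max_gap_len),
                 fuzzy_max_edits = as.integer(fuzzy_max_edits),
                 context_len = as.integer(context_len),
                 host_cover_frac = host_cover_frac),
            class = "cascade_params")
}

# Trim noisy segment ends: a local alignment may extend a few bases past a
# true fusion point whenever a mismatch is followed by chance matches (any
# non-negative-scoring suffix is admissible). For gapless segments, edges
# containing a mismatch within `edge` bases are cut back to the exact core,
# so that on error-free data every reported segment matches its reference
# verbatim and breakpoint coordinates are stable.
refine_segments <- function(res, frags, ref, scoring, edge = 10L) {
  span_read <- res$read_end - res$read_start + 1L
  span_ref <- res$ref_end - res$ref_start + 1L
  check <- which(span_read == span_ref & span_read >= 2L)
  for (i in check) {
    piece <- substr(frags[i], res$read_start[i], res$read_end[i])
    if (res$strand[i] == "-") piece <- revcomp(piece)
    refpiece <- substr(ref, res$ref_start[i], res$ref_end[i])
    if (piece == refpiece) next
    pv <- strsplit(piece, "", fixed = TRUE)[[1L]]
    rv <- strsplit(refpiece, "", fixed = TRUE)[[1L]]
    m <- pv == rv
    n <- length(m)
    lead <- 0L
    bad <- which(!m[seq_len(min(edge, n))])
    if (length(bad) > 0L) lead <- max(bad)
    trail <- 0L
    bad <- which(!rev(m)[seq_len(min(edge, n - lead))])
    if (length(bad) > 0L) trail <- max(bad)
    if (lead == 0L && trail == 0L) next
    keep <- if (lead + trail >= n) logical(0) else m[(lead + 1L):(n - trail)]
    # trim in reference orientation; map back to read orientation by strand
    if (res$strand[i] == "+") {
      res$read_start[i] <- res$read_start[i] + lead
      res$read_end[i] <- res$read_end[i] - trail
    } else {
      res$read_start[i] <- res$read_start[i] + trail
      res$read_end[i] <- res$read_end[i] - lead
    }
    res$ref_start[i] <- res$ref_start[i] + lead
    res$ref_end[i] <- res$ref_end[i] - trail
    res$score[i] <- if (length(keep) == 0L) -Inf else
      sum(keep) * scoring$match + sum(!keep) * scoring$mismatch
  }
  res
}

# fuzzy rescue of a fragment against the insertion-site context
fuzzy_context_hit <- function(frag, context, max_edits, context_offset) {
  hit1 <- function(pattern, subject) {
    m <- Biostrings::matchPattern(pattern, subject,
                                  max.mismatch = max_edits, with.indels = TRUE)
    if (length(m) == 0L) NULL else m[1L]
  }
  n <- nchar(frag)
  if (n <= nchar(context)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") frag else revcomp(frag)
      m <- hit1(Biostrings::DNAString(pat), Biostrings::DNAString(context))
      if (!is.null(m)) {
        return(tibble(read_start = 1L, read_end = n,
                      ref_start = context_offset + Biostrings::start(m),
                      ref_end = context_offset + Biostrings::end(m),
                      strand = strand, score = n - max_edits))
      }
    }
  } else {
    for (strand in c("+", "-")) {
      sub <- if (strand == "+") frag else revcomp(frag)
      m <- hit1(Biostrings::DNAString(context), Biostrings::DNAString(sub))
      if (!is.null(m)) {
        rs <- Biostrings::start(m); re <- Biostrings::end(m)
        if (strand == "-") { tmp <- rs; rs <- n - re + 1L; re <- n - tmp + 1L }
        return(tibble(read_start = rs, read_end = re,
                      ref_start = context_offset + 1L,
                      ref_end = context_offset + nchar(context),
                      strand = strand, score = nchar(context) - max_edits))
      }
    }
  }
  NULL
}

#' Hierarchical alignment cascade over read pairs
#'
#' Maps reads stage by stage: (1) the composite `junction_ref` (transgene
#' with rDNA flanks), with split re-alignment of clipped portions on the
#' same reference; (2) unmapped mates and clipped portions against the rDNA
#' scaffold; (3) against the host reference; (4) approximate-match rescue of
#' remaining fragments against the context surrounding the insertion site.
#' A fragment explained at stage k is never re-assigned at a later stage.
#' Pairs are then discarded when a mate maps to a contaminant, when both
#' mates are better explained by the host genome than by the transgene
#' reference, or when not both mates are mapped.
#'
#' @param pairs Read-pair tibble (`read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`), typically from [prep_reads()].
#' @param refs A [mapping_references()].
#' @param params A [cascade_params()].
#' @return List with `segments` (tibble: `read_id`, `mate`, `read_start`,
#'   `read_end`, `ref_id`, `ref_start`, `ref_end`, `strand`, `score`,
#'   `stage`; kept pairs only), `pair_status` (tibble: `read_id`, `status`
#'   in kept/contaminant/host_better/unmapped_mate), and `log` (counts).
#' @export
run_cascade <- function(pairs, refs, params = cascade_params()) {
  if (!inherits(refs, "mapping_refs")) abort("refs must come from mapping_references()")
  check_pairs(pairs)
  if (nrow(pairs) > 0L &&
      refs$flank_len < max(nchar(pairs$seq1), nchar(pairs$seq2))) {
    warn("junction_ref flank is shorter than the longest read; junction-spanning reads may run off the reference")
  }
  scoring <- params$scoring
  reads <- bind_rows(
    tibble(read_id = pairs$read_id, mate = 1L, seq = pairs$seq1),
    tibble(read_id = pairs$read_id, mate = 2L, seq = pairs$seq2)
  )
  reads$ridx <- seq_len(nrow(reads))
  reads$len <- nchar(reads$seq)

  stage_refs <- list(
    list(id = "junction_ref", seq = refs$junction_ref),
    list(id = "rdna", seq = refs$rdna_ref),
    list(id = "host", seq = refs$host_ref)
  )
  segments <- list()
  # frontier of unassigned fragments: ridx, a, b (read coordinates)
  frontier <- tibble(ridx = reads$ridx, a = 1L, b = reads$len)

  for (st in seq_along(stage_refs)) {
    ref <- stage_refs[[st]]
    if (nchar(ref$seq) == 0L) next
    carry <- frontier[0, ]
    while (nrow(frontier) > 0L) {
      ok <- (frontier$b - frontier$a + 1L) >= params$min_seg_len
      carry <- bind_rows(carry, frontier[!ok, ])
      frontier <- frontier[ok, ]
      if (nrow(frontier) == 0L) break
      frags <- substr(reads$seq[frontier$ridx], frontier$a, frontier$b)
      res <- align_batch(frags, ref$seq, scoring)
      res <- bind_cols(frontier[res$idx, c("ridx", "a", "b")], res[, -match("idx", names(res))])
      res <- refine_segments(res, frags, ref$seq, scoring)
      seg_len <- res$read_end - res$read_start + 1L
      exact <- res$score == scoring$match * (res$b - res$a + 1L) &
        res$read_start == 1L & res$read_end == (res$b - res$a + 1L)
      accept <- seg_len >= params$min_seg_len &
        (exact | res$score >= params$dp_min_score)
      # alignments bridging a long indel are split at the divergence point
      gap_d <- seg_len - (res$ref_end - res$ref_start + 1L)
      resplit <- accept & abs(gap_d) > params$max_gap_len
      accept <- accept & !resplit
      split_children <- list()
      for (i in which(resplit)) {
        piece <- substr(frags[i], res$read_start[i], res$read_end[i])
        if (res$strand[i] == "-") piece <- revcomp(piece)
        refpiece <- substr(ref$seq, res$ref_start[i], res$ref_end[i])
        a1 <- common_prefix_len(piece, refpiece)
        span <- seg_len[i]
        if (a1 < 1L || a1 >= span) {
          carry <- bind_rows(carry, res[i, c("ridx", "a", "b")])
          next
        }
        cut <- if (res$strand[i] == "+") res$read_start[i] - 1L + a1
               else res$read_end[i] - a1
        split_children[[length(split_children) + 1L]] <- tibble(
          ridx = rep(res$ridx[i], 2L),
          a = c(res$a[i], res$a[i] + cut),
          b = c(res$a[i] + cut - 1L, res$b[i]))
      }
      carry <- bind_rows(carry, res[!accept & !resplit, c("ridx", "a", "b")])
      acc <- res[accept, , drop = FALSE]
      frontier <- if (length(split_children) > 0L) bind_rows(split_children) else
        tibble(ridx = integer(), a = integer(), b = integer())
      if (nrow(acc) > 0L) {
        segments[[length(segments) + 1L]] <- tibble(
          ridx = acc$ridx,
          read_start = acc$a + acc$read_start - 1L,
          read_end = acc$a + acc$read_end - 1L,
          ref_id = ref$id, ref_start = acc$ref_start, ref_end = acc$ref_end,
          strand = acc$strand, score = acc$score, stage = st
        )
        frontier <- bind_rows(
          frontier,
          tibble(ridx = acc$ridx, a = acc$a, b = acc$a + acc$read_start - 2L),
          tibble(ridx = acc$ridx, a = acc$a + acc$read_end, b = acc$b)
        )
      }
      frontier <- frontier[(frontier$b - frontier$a + 1L) >= params$min_seg_len, ,
                           drop = FALSE]
    }
    frontier <- carry
  }

  # stage 4: approximate-match rescue at the insertion-site context
  site <- refs$site
  half <- params$context_len %/% 2L
  ctx_from <- max(1L, site$nick_coord - half + 1L)
  ctx_to <- min(nchar(refs$rdna_ref), site$nick_coord + half)
  context <- substr(refs$rdna_ref, ctx_from, ctx_to)
  leftover <- frontier[(frontier$b - frontier$a + 1L) >= params$min_seg_len, ]
  if (nrow(leftover) > 0L) {
    for (i in seq_len(nrow(leftover))) {
      frag <- substr(reads$seq[leftover$ridx[i]], leftover$a[i], leftover$b[i])
      hit <- fuzzy_context_hit(frag, context, params$fuzzy_max_edits, ctx_from - 1L)
      if (!is.null(hit)) {
        segments[[length(segments) + 1L]] <- tibble(
          ridx = leftover$ridx[i],
          read_start = leftover$a[i] + hit$read_start - 1L,
          read_end = leftover$a[i] + hit$read_end - 1L,
          ref_id = "insertion_context", ref_start = hit$ref_start,
          ref_end = hit$ref_end, strand = hit$strand, score = hit$score,
          stage = 4L
        )
      }
    }
  }

  segs <- if (length(segments) > 0L) list_rbind(segments) else
    tibble(ridx = integer(), read_start = integer(), read_end = integer(),
           ref_id = character(), ref_start = integer(), ref_end = integer(),
           strand = character(), score = numeric(), stage = integer())

  # per-read score totals for the discard rules
  per_read <- segs |>
    group_by(ridx) |>
    summarise(
      junction_score = sum(score[ref_id %in% c("junction_ref", "insertion_context")]),
      rdna_score = sum(score[ref_id == "rdna"]),
      host_score = sum(score[ref_id == "host"]),
      host_cover = sum((read_end - read_start + 1L)[ref_id == "host"]),
      n_seg = n(), .groups = "drop"
    )
  reads <- left_join(reads, per_read, by = "ridx") |>
    mutate(across(c(junction_score, rdna_score, host_score, host_cover, n_seg),
                  ~ tidyr::replace_na(.x, 0)))

  # contaminant screen: poorly-explained reads checked against the panel
  reads$contam <- FALSE
  if (length(refs$contaminants) > 0L) {
    assigned <- segs |>
      group_by(ridx) |>
      summarise(cov = sum(read_end - read_start + 1L), .groups = "drop")
    reads <- left_join(reads, assigned, by = "ridx") |>
      mutate(cov = tidyr::replace_na(cov, 0))
    cand <- which(reads$cov < 0.5 * reads$len)
    for (i in cand) {
      for (cseq in refs$contaminants) {
        hit <- align_local(reads$seq[i], cseq, scoring)
        if (hit$score >= 0.8 * scoring$match * reads$len[i] &&
            hit$score > reads$junction_score[i]) {
          reads$contam[i] <- TRUE
          break
        }
      }
    }
  }
  reads$host_dominant <- reads$host_score > reads$junction_score &
    reads$host_cover >= params$host_cover_frac * reads$len
  reads$mapped <- reads$n_seg > 0L

  by_pair <- reads |>
    group_by(read_id) |>
    summarise(
      any_contam = any(contam),
      all_host = all(host_dominant),
      all_mapped = all(mapped), .groups = "drop"
    ) |>
    mutate(status = case_when(
      any_contam ~ "contaminant",
      all_host ~ "host_better",
      !all_mapped ~ "unmapped_mate",
      TRUE ~ "kept"
    ))
  kept_ids <- by_pair$read_id[by_pair$status == "kept"]
  segs_out <- segs |>
    left_join(reads[, c("ridx", "read_id", "mate")], by = "ridx") |>
    filter(read_id %in% kept_ids) |>
    select(read_id, mate, read_start, read_end, ref_id, ref_start, ref_end,
           strand, score, stage) |>
    arrange(read_id, mate, read_start)

  list(
    segments = segs_out,
    pair_status = by_pair[, c("read_id", "status")],
    log = list(
      input_pairs = nrow(pairs),
      kept = sum(by_pair$status == "kept"),
      contaminant = sum(by_pair$status == "contaminant"),
      host_better = sum(by_pair$status == "host_better"),
      unmapped_mate = sum(by_pair$status == "unmapped_mate")
    )
  )
}

#' Write a cascade segment table as TSV
#'
#' @param segments Segment tibble from [run_cascade()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
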