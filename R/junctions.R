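#' Classify a resolved 3' junction
#'
#' A transgene insertion is `on_target` when its 3' junction begins within
#' +/-3 bp of the 28S target site, `rdna_off_target` when it lies elsewhere
#' on the rDNA scaffold, and `genomic_off_target` when the 3' flank maps
#' elsewhere in the host genome.
#'
#' @param rdna_coord Signed junction coordinate(s) of the 3' junction
#'   (ignored for host context).
#' @param map_context `"rdna"` or `"host"` per junction.
#' @param window On-target half-width in bp (default 3).
#' @return Character vector of categories.
#' @export
classify_three_prime <- function(rdna_coord, map_context = "rdna", window = 3L) {
  n <- max(length(rdna_coord), length(map_context))
  rdna_coord <- rep_len(rdna_coord, n)
  map_context <- rep_len(map_context, n)
  ifelse(map_context == "host", "genomic_off_target",
         ifelse(abs(rdna_coord) <= window, "on_target", "rdna_off_target"))
}

# scalar 5' classification; the decision order is fixed:
# anneal -> snapback -> extra_template -> join -> other
classify5_one <- function(crosses_boundary, has_prev, prev_strand, prev_context,
                          prev_template_pos, entry_template_pos, insert, h) {
  if (crosses_boundary && !has_prev) {
    if (nchar(insert) == 0L && h > 0L) return("anneal")
    return("join")  # h = 0 seamless fusion, or an extracted nontemplated insert
  }
  if (has_prev) {
    if (!is.na(prev_strand) && prev_strand == "-" &&
        prev_context %in% c("template", "rdna_up", "rdna_down")) {
      return("snapback")
    }
    if (!is.na(prev_strand) && prev_strand == "+" && prev_context == "template" &&
        !is.na(prev_template_pos) && prev_template_pos > entry_template_pos) {
      return("extra_template")
    }
    if (!is.na(prev_strand) && prev_strand == "+" &&
        prev_context %in% c("rdna_up", "rdna_down")) {
      return("join")
    }
  }
  "other"
}

#' Classify 5' junction evidence into a mechanism category
#'
#' Applies the mechanistic taxonomy in a fixed decision order: seamless
#' boundary-crossing evidence with no preceding segment is `anneal` (for a
#' template with rRNA homology; with h = 0 the same evidence is a direct
#' `join` opposite the nick); a minus-strand template or rDNA segment
#' preceding the template entry is `snapback`; a plus-strand segment from
#' further 3' in the template is `extra_template`; a plus-strand rDNA
#' segment is `join`; anything else (host or ambiguous evidence) is
#' `other`.
#'
#' @param evidence Tibble with logical `crosses_boundary`, `has_prev`,
#'   character `insert`, and (when `has_prev`) `prev_strand`,
#'   `prev_context` (one of `"rdna_up"`, `"rdna_down"`, `"template"`,
#'   `"host"`), `prev_template_pos`, `entry_template_pos`.
#' @param h Template rRNA homology length (anneal requires h > 0).
#' @return Character vector of categories, one per row.
#' @export
classify_five_prime <- function(evidence, h = 0L) {
  vapply(seq_len(nrow(evidence)), function(i) {
    classify5_one(evidence$crosses_boundary[i], evidence$has_prev[i],
                  evidence$prev_strand[i], evidence$prev_context[i],
                  evidence$prev_template_pos[i], evidence$entry_template_pos[i],
                  evidence$insert[i] %||% "", h)
  }, character(1))
}

#' Full-length status of a 5' junction call
#'
#' An anneal junction is full-length when the full non-homology region is
#' detected (observed template offset at most h); for every other category
#' the total transgene cDNA length must be detected (offset 0).
#'
#' @param category Category vector.
#' @param template_coord Observed template offset (0-based) at the junction.
#' @param h Template rRNA homology length.
#' @return Tibble with `full_length` and `truncation_offset`.
#' @export
assess_full_length <- function(category, template_coord, h) {
  allowance <- ifelse(category == "anneal", h, 0L)
  trunc <- pmax(0L, as.integer(template_coord) - as.integer(allowance))
  tibble(full_length = trunc == 0L, truncation_offset = trunc)
}

# Locate an alignment-bridged difference (insert if d > 0, reference skip
# if d < 0) within a boundary-crossing segment. Candidate placements are
# derived from the maximal exact prefix and suffix; the one whose implied
# junction lies nearest the boundary wins (a substitution error on one side
# otherwise misplaces the bridge). Returns list(p, t0, insert) or NULL.
locate_bridge <- function(readseg, refseg, d, ref_start, refs, min_anchor,
                          max_insert_gap) {
  len <- nchar(readseg)
  flank <- refs$flank_len
  h <- refs$homology_len
  ins_len <- max(0L, d)
  a_left <- common_prefix_len(readseg, refseg)
  a_right <- len - common_suffix_len(readseg, refseg) - ins_len
  best <- NULL
  for (s in unique(c(a_left, a_right))) {
    if (s < min_anchor || len - s - ins_len < min_anchor) next
    jq <- ref_start + s - 1L              # last ref position before the bridge
    resume <- jq + 1L - min(0L, d)        # ref position after the bridge
    p_raw <- jq - flank
    if (p_raw < -(max_insert_gap + 10L) || p_raw > max_insert_gap) next
    if (resume <= flank || resume > refs$insert_end) next
    if (jq <= flank) {
      p <- p_raw
      cx <- junction_ref_context(refs, resume)
      t0 <- if (cx$context == "template") cx$coord - 1L else h + cx$coord
    } else if (d > 0L) {
      # prefix matched into the template (insert bases coincide with the
      # template start): clamp the junction back to the boundary
      p <- 0L
      t0 <- junction_ref_context(refs, flank + 1L)$coord - 1L
    } else {
      next  # a reference skip parsed past the boundary is not a junction
    }
    cand <- list(p = p, t0 = t0,
                 insert = substr(readseg, s + 1L, s + ins_len),
                 dist = abs(p_raw))
    if (is.null(best) || cand$dist < best$dist) best <- cand
  }
  if (is.null(best)) return(NULL)
  best[c("p", "t0", "insert")]
}

# growable row collector (amortised append of homogeneous rows)
new_collector <- function(template_row) {
  env <- new.env(parent = emptyenv())
  env$data <- lapply(template_row, function(v) rep(v, 64L))
  env$n <- 0L
  env$cap <- 64L
  env
}
collector_add <- function(env, row) {
  if (env$n == env$cap) {
    env$cap <- env$cap * 2L
    env$data <- lapply(env$data, function(v) { length(v) <- env$cap; v })
  }
  env$n <- env$n + 1L
  for (nm in names(row)) env$data[[nm]][env$n] <- row[[nm]]
  invisible(env)
}
collector_tibble <- function(env) {
  as_tibble(lapply(env$data, function(v) v[seq_len(env$n)]))
}

#' Call 3' and 5' junctions from cascade segments
#'
#' Reduces per-read segment patterns to junction calls: reads whose segments
#' switch reference context (rDNA to template, or across the insertion
#' boundaries within `junction_ref`) yield candidate junctions; when a read
#' supports several interpretations the taxonomy's decision order
#' (anneal, snapback, extra template, join, other) arbitrates. Candidates
#' sharing side, category, coordinates and inserted sequence are merged with
#' their supporting-read counts. A boundary-crossing alignment that absorbed
#' a short nontemplated insert as a gap is re-examined base by base and
#' called as a join with the extracted insert. Join junctions are
#' canonicalised to the maximal-rDNA breakpoint placement, with both extreme
#' placements reported (`rdna_coord_max_rdna`, `rdna_coord_max_transgene`;
#' these differ by exactly the microhomology). Within the homology region an
#' anneal breakpoint is inherently ambiguous, so anneal calls carry no point
#' coordinate.
#'
#' @param segments Segment tibble from [run_cascade()].
#' @param refs The [mapping_references()] used for the cascade.
#' @param pairs The read-pair tibble that was aligned (sequences are needed
#'   to extract nontemplated inserts).
#' @param min_anchor Minimum aligned bases required on each side of a
#'   boundary (default 10).
#' @param max_insert_gap Largest unaligned gap (nt) accepted between the two
#'   sides of a junction; the gap bases are reported as the nontemplated
#'   insert (default 15).
#' @param min_support Minimum supporting reads per reported call (default 1).
#' @param mh_window Microhomology counting window (default 20).
#' @return List with `calls` (tibble: `call_id`, `side`, `category`,
#'   `rdna_coord`, `rdna_coord_max_rdna`, `rdna_coord_max_transgene`,
#'   `template_coord`, `mh_max`, `mh_left`, `mh_right`, `inserted_seq`,
#'   `full_length`, `truncation_offset`, `ambiguous`, `supporting_reads`),
#'   `evidence` (tibble: `read_id`, `mate`, `side`, `call_id`) and
#'   `uncalled_reads`.
#' @export
call_junctions <- function(segments, refs, pairs, min_anchor = 10L,
                           max_insert_gap = 15L, min_support = 1L,
                           mh_window = 20L) {
  site <- refs$site
  template <- refs$template
  h <- refs$homology_len
  L <- refs$template_len
  flank <- refs$flank_len
  jref <- refs$junction_ref
  nick <- site$nick_coord
  seqs <- c(setNames(pairs$seq1, paste0(pairs$read_id, "/1")),
            setNames(pairs$seq2, paste0(pairs$read_id, "/2")))

  ev5 <- new_collector(list(rkey = "", crosses_boundary = FALSE, has_prev = FALSE,
                            prev_strand = NA_character_, prev_context = NA_character_,
                            prev_template_pos = NA_integer_,
                            entry_template_pos = NA_integer_,
                            join_pos = NA_integer_, insert = "",
                            category = "", rank = 0L))
  ev3 <- new_collector(list(rkey = "", context = "", coord = NA_integer_))
  cat_rank <- c(anneal = 1L, snapback = 2L, extra_template = 3L, join = 4L,
                other = 5L)
  n_reads_kept <- 0L

  if (nrow(segments) > 0L) {
    seg_rkey <- paste0(segments$read_id, "/", segments$mate)
    v_rs <- segments$read_start; v_re <- segments$read_end
    v_refid <- segments$ref_id; v_fs <- segments$ref_start
    v_fe <- segments$ref_end; v_str <- segments$strand
    by_read <- split(seq_len(nrow(segments)), seg_rkey)
    n_reads_kept <- length(by_read)
    for (rkey in names(by_read)) {
      ii <- by_read[[rkey]]
      rseq <- seqs[[rkey]]
      rlen <- nchar(rseq)
      segs <- list(read_start = v_rs[ii], read_end = v_re[ii],
                   ref_id = v_refid[ii], ref_start = v_fs[ii],
                   ref_end = v_fe[ii], strand = v_str[ii])
      minus_bases <- sum((segs$read_end - segs$read_start + 1L)[segs$strand == "-"])
      flipped <- minus_bases > sum(segs$read_end - segs$read_start + 1L) / 2
      if (flipped) {
        rs <- rlen - segs$read_end + 1L
        re <- rlen - segs$read_start + 1L
        segs$read_start <- rs; segs$read_end <- re
        segs$strand <- ifelse(segs$strand == "+", "-", "+")
        rseq <- revcomp(rseq)
      }
      o <- order(segs$read_start)
      segs <- lapply(segs, function(v) v[o])
      ns <- length(o)
      # read-orientation endpoint contexts
      l_ref <- ifelse(segs$strand == "+", segs$ref_start, segs$ref_end)
      r_ref <- ifelse(segs$strand == "+", segs$ref_end, segs$ref_start)
      ctx_at <- function(ref_id, pos) {
        if (ref_id == "junction_ref") {
          cx <- junction_ref_context(refs, pos)
          c(cx$context, cx$coord)
        } else if (ref_id %in% c("rdna", "insertion_context")) {
          cc <- pos - nick - 1L
          c(if (cc < 0L) "rdna_up" else "rdna_down", cc)
        } else c("host", NA_integer_)
      }
      l_ctx <- character(ns); l_coord <- integer(ns)
      r_ctx <- character(ns); r_coord <- integer(ns)
      for (i in seq_len(ns)) {
        a <- ctx_at(segs$ref_id[i], l_ref[i])
        b <- ctx_at(segs$ref_id[i], r_ref[i])
        l_ctx[i] <- a[1]; l_coord[i] <- as.integer(a[2])
        r_ctx[i] <- b[1]; r_coord[i] <- as.integer(b[2])
      }
      crosses5 <- segs$ref_id == "junction_ref" & segs$strand == "+" &
        segs$ref_start <= flank - min_anchor + 1L &
        segs$ref_end >= flank + min_anchor
      crosses3 <- segs$ref_id == "junction_ref" & segs$strand == "+" &
        segs$ref_start <= refs$insert_end - min_anchor + 1L &
        segs$ref_end >= refs$insert_end + min_anchor
      seg_len <- segs$read_end - segs$read_start + 1L

      # ---- 5' candidates
      cands <- list()
      for (i in seq_len(ns)) {
        entry_t <- NA_integer_
        if (segs$strand[i] == "+" && l_ctx[i] == "template") {
          entry_t <- l_coord[i]
        } else if (segs$strand[i] == "+" && segs$ref_id[i] == "junction_ref" &&
                   segs$ref_start[i] <= flank &&
                   segs$ref_end[i] >= flank + min_anchor) {
          # segment crosses into the template (possibly with only a few
          # chance-matching flank bases on its left)
          entry_t <- max(1L, h + segs$ref_start[i] - flank)
        }
        if (is.na(entry_t) || seg_len[i] < min_anchor) next
        prev <- NULL
        if (i > 1L) {
          gap <- segs$read_start[i] - segs$read_end[i - 1L] - 1L
          if (gap >= 0L && gap <= max_insert_gap && seg_len[i - 1L] >= min_anchor) {
            prev <- i - 1L
          }
        }
        if (is.null(prev)) {
          if (!crosses5[i] || segs$read_start[i] - 1L >= min_anchor) next
          # lone boundary-crossing segment: seamless, a gap-absorbed
          # nontemplated insert (read longer than reference span), or a
          # gap-absorbed truncation (reference span longer)
          d <- seg_len[i] - (segs$ref_end[i] - segs$ref_start[i] + 1L)
          readseg <- substr(rseq, segs$read_start[i], segs$read_end[i])
          refseg <- substr(jref, segs$ref_start[i], segs$ref_end[i])
          if (d == 0L) {
            cands[[length(cands) + 1L]] <- list(
              crosses_boundary = TRUE, has_prev = FALSE,
              prev_strand = NA_character_, prev_context = NA_character_,
              prev_template_pos = NA_integer_, entry_template_pos = entry_t,
              join_pos = if (h == 0L) 0L else NA_integer_,
              t0 = if (h == 0L) 0L else NA_integer_, insert = "")
          } else if ((d > 0L && d <= max_insert_gap) || d < 0L) {
            # the alignment bridged a nontemplated insert (d > 0) or a
            # reference skip from a truncation/upstream loss (d < 0);
            # locate the bridge from both ends so a substitution error on
            # one side does not misplace the junction
            br <- locate_bridge(readseg, refseg, d, segs$ref_start[i],
                                refs, min_anchor, max_insert_gap)
            if (!is.null(br)) {
              cands[[length(cands) + 1L]] <- list(
                crosses_boundary = TRUE, has_prev = FALSE,
                prev_strand = NA_character_, prev_context = NA_character_,
                prev_template_pos = NA_integer_,
                entry_template_pos = br$t0 + 1L,
                join_pos = br$p, t0 = br$t0, insert = br$insert)
            }
          }
          next
        }
        # a flank-anchored previous segment may chance-extend a few bases
        # into the template region; those overhang bases are alignment
        # artefacts of the junction ambiguity -- give them back to the gap
        # and treat the segment as rDNA evidence ending at the boundary
        prev_ctx <- r_ctx[prev]
        prev_coord <- r_coord[prev]
        prev_read_end <- segs$read_end[prev]
        if (prev_ctx == "template" && segs$strand[prev] == "+" &&
            segs$ref_id[prev] == "junction_ref" &&
            segs$ref_start[prev] <= flank) {
          overhang <- segs$ref_end[prev] - flank
          if (overhang >= 1L && overhang <= 5L &&
              segs$ref_end[prev] - segs$ref_start[prev] + 1L - overhang >= min_anchor) {
            prev_ctx <- "rdna_up"
            prev_coord <- -1L
            prev_read_end <- prev_read_end - overhang
          }
        }
        gapseq <- if (segs$read_start[i] - prev_read_end > 1L) {
          substr(rseq, prev_read_end + 1L, segs$read_start[i] - 1L)
        } else ""
        if (nchar(gapseq) > max_insert_gap) next
        jp <- if (prev_ctx %in% c("rdna_up", "rdna_down")) prev_coord + 1L
              else NA_integer_
        cands[[length(cands) + 1L]] <- list(
          crosses_boundary = crosses5[i], has_prev = TRUE,
          prev_strand = segs$strand[prev], prev_context = prev_ctx,
          prev_template_pos = if (prev_ctx == "template") prev_coord
                              else NA_integer_,
          entry_template_pos = entry_t, join_pos = jp, t0 = entry_t - 1L,
          insert = gapseq)
      }
      if (length(cands) > 0L) {
        cats <- vapply(cands, function(cd) {
          classify5_one(cd$crosses_boundary, cd$has_prev, cd$prev_strand,
                        cd$prev_context, cd$prev_template_pos,
                        cd$entry_template_pos, cd$insert, h)
        }, character(1))
        best <- which.min(cat_rank[cats])
        cd <- cands[[best]]
        collector_add(ev5, list(
          rkey = rkey, crosses_boundary = cd$crosses_boundary,
          has_prev = cd$has_prev, prev_strand = cd$prev_strand,
          prev_context = cd$prev_context,
          prev_template_pos = cd$prev_template_pos,
          entry_template_pos = if (cats[best] == "anneal") h + 0L
                               else (cd$t0 %||% (cd$entry_template_pos - 1L)) + 1L,
          join_pos = cd$join_pos %||% NA_integer_, insert = cd$insert,
          category = cats[best], rank = cat_rank[[cats[best]]]))
      }

      # ---- 3' evidence
      for (i in seq_len(ns)) {
        if (crosses3[i]) {
          collector_add(ev3, list(rkey = rkey, context = "rdna", coord = 0L))
          break
        }
        if (i > 1L) {
          gap <- segs$read_start[i] - segs$read_end[i - 1L] - 1L
          near_end <- r_ctx[i - 1L] == "template" && r_coord[i - 1L] >= L - 5L
          if (near_end && gap >= 0L && gap <= max_insert_gap &&
              segs$strand[i - 1L] == "+" &&
              l_ctx[i] %in% c("rdna_up", "rdna_down", "host")) {
            collector_add(ev3, list(
              rkey = rkey,
              context = if (l_ctx[i] == "host") "host" else "rdna",
              coord = if (l_ctx[i] == "host") NA_integer_ else l_coord[i]))
            break
          }
        }
      }
    }
  }

  # ---- reduce 5' evidence to calls
  empty_calls <- tibble(
    call_id = character(), side = character(), category = character(),
    rdna_coord = integer(), rdna_coord_max_rdna = integer(),
    rdna_coord_max_transgene = integer(), template_coord = integer(),
    mh_max = integer(), mh_left = integer(), mh_right = integer(),
    inserted_seq = character(), full_length = logical(),
    truncation_offset = integer(), ambiguous = logical(),
    supporting_reads = integer())
  evidence <- tibble(read_id = character(), mate = integer(),
                     side = character(), call_id = character())
  calls5 <- empty_calls; calls3 <- empty_calls

  e <- collector_tibble(ev5)
  if (nrow(e) > 0L) {
    e$t0 <- e$entry_template_pos - 1L
    e$mh_left <- 0L; e$mh_right <- 0L; e$mh_max <- NA_integer_
    e$p_can <- NA_integer_; e$t0_can <- e$t0
    mh_cache <- new.env(parent = emptyenv())
    for (k in which(e$category == "join")) {
      if (is.na(e$join_pos[k])) next
      if (nchar(e$insert[k]) == 0L) {
        key <- paste0(e$join_pos[k], "|", e$t0[k])
        mh <- mh_cache[[key]]
        if (is.null(mh)) {
          mh <- junction_microhomology(site, template, e$join_pos[k], e$t0[k],
                                       window = mh_window)
          mh_cache[[key]] <- mh
        }
        e$mh_left[k] <- mh$mh_left; e$mh_right[k] <- mh$mh_right
        e$mh_max[k] <- mh$mh_max
        e$p_can[k] <- e$join_pos[k] + mh$mh_right
        e$t0_can[k] <- e$t0[k] + mh$mh_right
      } else {
        e$mh_max[k] <- 0L
        e$p_can[k] <- e$join_pos[k]
      }
    }
    is_join <- e$category == "join"
    e$template_coord <- ifelse(e$category == "anneal", h,
                        ifelse(is_join, e$t0_can - e$mh_max, e$t0))
    e$rdna_coord <- ifelse(is_join, e$p_can,
                    ifelse(e$category %in% c("snapback", "extra_template"),
                           e$join_pos, NA_integer_))
    e$ambiguous <- e$category == "other" & !e$has_prev
    fl <- assess_full_length(e$category, e$template_coord, h)
    e$full_length <- fl$full_length
    e$truncation_offset <- fl$truncation_offset
    e$key <- paste(e$category, e$rdna_coord, e$template_coord, e$insert, sep = "|")
    grp <- e |>
      group_by(.data$key) |>
      summarise(
        category = first(category), rdna_coord = first(rdna_coord),
        template_coord = first(template_coord), mh_max = first(mh_max),
        mh_left = first(mh_left), mh_right = first(mh_right),
        inserted_seq = first(insert), full_length = first(full_length),
        truncation_offset = first(truncation_offset),
        ambiguous = any(ambiguous), supporting_reads = n(), .groups = "drop") |>
      filter(supporting_reads >= min_support)
    if (nrow(grp) > 0L) {
      grp$side <- "five_prime"
      grp$call_id <- paste0("J5_", seq_len(nrow(grp)))
      grp$rdna_coord_max_rdna <- ifelse(grp$category == "join",
                                        grp$rdna_coord, NA_integer_)
      grp$rdna_coord_max_transgene <- ifelse(grp$category == "join",
                                             grp$rdna_coord - grp$mh_max,
                                             NA_integer_)
      calls5 <- grp[, names(empty_calls)]
      key_to_id <- setNames(grp$call_id, grp$key)
      ek <- e[e$key %in% grp$key, , drop = FALSE]
      evidence <- bind_rows(evidence, tibble(
        read_id = sub("/[12]$", "", ek$rkey),
        mate = as.integer(sub("^.*/", "", ek$rkey)),
        side = "five_prime", call_id = unname(key_to_id[ek$key])))
    }
  }

  e3 <- collector_tibble(ev3)
  if (nrow(e3) > 0L) {
    e3$category <- classify_three_prime(e3$coord, e3$context)
    e3$key <- paste(e3$category, e3$coord, sep = "|")
    grp3 <- e3 |>
      group_by(.data$key) |>
      summarise(category = first(category), rdna_coord = first(coord),
                supporting_reads = n(), .groups = "drop") |>
      filter(supporting_reads >= min_support)
    if (nrow(grp3) > 0L) {
      grp3$side <- "three_prime"
      grp3$call_id <- paste0("J3_", seq_len(nrow(grp3)))
      grp3 <- grp3 |>
        mutate(rdna_coord_max_rdna = NA_integer_,
               rdna_coord_max_transgene = NA_integer_,
               template_coord = NA_integer_, mh_max = NA_integer_,
               mh_left = NA_integer_, mh_right = NA_integer_,
               inserted_seq = "", full_length = NA,
               truncation_offset = NA_integer_, ambiguous = FALSE)
      calls3 <- grp3[, names(empty_calls)]
      key_to_id3 <- setNames(grp3$call_id, grp3$key)
      ek3 <- e3[e3$key %in% grp3$key, , drop = FALSE]
      evidence <- bind_rows(evidence, tibble(
        read_id = sub("/[12]$", "", ek3$rkey),
        mate = as.integer(sub("^.*/", "", ek3$rkey)),
        side = "three_prime", call_id = unname(key_to_id3[ek3$key])))
    }
  }

  calls <- bind_rows(calls5, calls3)
  called_keys <- unique(paste0(evidence$read_id, "/", evidence$mate))
  list(calls = calls, evidence = evidence,
       uncalled_reads = n_reads_kept - length(called_keys))
}

#' Catalog of nontemplated insertions at join junctions
#'
#' @param calls Junction-call tibble.
#' @return Tibble `inserted_seq`, `length`, `n_junctions`,
#'   `supporting_reads`, sorted by supporting reads (descending).
#' @export
catalog_inserts <- function(calls) {
  joins <- calls[calls$side == "five_prime" & calls$category == "join", , drop = FALSE]
  if (nrow(joins) == 0L) {
    return(tibble(inserted_seq = character(), length = integer(),
                  n_junctions = integer(), supporting_reads = integer()))
  }
  joins |>
    group_by(.data$inserted_seq) |>
    summarise(length = nchar(first(inserted_seq)), n_junctions = n(),
              supporting_reads = sum(supporting_reads), .groups = "drop") |>
    arrange(desc(supporting_reads), inserted_seq)
}

#' Write junction calls as TSV and BED
#'
#' BED uses scaffold coordinates with the category in the name field and
#' supporting reads as the score.
#'
#' @param calls Junction-call tibble.
#' @param site The [target_site()] (for scaffold coordinates).
#' @param tsv_path,bed_path Output paths (NULL to skip either).
#' @return Invisibly, the written paths.
#' @export
write_calls <- function(calls, site, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(calls, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    has_pos <- !is.na(calls$rdna_coord)
    pos <- scaffold_pos(site, calls$rdna_coord[has_pos])
    bed <- data.frame(
      chrom = site$scaffold_id, start = pos - 1L, end = pos,
      name = paste0(calls$side[has_pos], ":", calls$category[has_pos]),
      score = calls$supporting_reads[has_pos], strand = "+")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(tsv_path, bed_path))
}
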