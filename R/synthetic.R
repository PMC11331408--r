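#' Construct a ground-truth insertion allele
#'
#' Builds the post-insertion locus sequence for one of the five 5'-junction
#' mechanisms:
#' \describe{
#'   \item{anneal}{cDNA 3'-end rRNA homology base-pairs with the upstream
#'     target site; seamless, one copy of the homology region. Requires a
#'     template with h >= 1.}
#'   \item{join}{direct end-joining of the (possibly 5'-truncated) cDNA to
#'     upstream rDNA at `join_pos`, with optional nontemplated insert and a
#'     realised microhomology recorded against the references.}
#'   \item{snapback}{a reverse-complement copy of template sequence adjacent
#'     to the cDNA 5' end precedes the template suffix (self-primed
#'     synthesis before joining).}
#'   \item{extra_template}{sequence copied from a second RNA template's 3'
#'     region precedes the template suffix.}
#'   \item{other}{the sequence upstream of the transgene derives from
#'     elsewhere in the host genome (simulated from a host decoy).}
#' }
#' The 3' junction is placed exactly at the first-strand nick
#' (`three_prime_exact`).
#'
#' For join alleles with a requested microhomology `m` and no insert, the
#' generator selects a `join_pos`/`template_start` pair whose naturally
#' realised microhomology (recomputed against the unmodified references)
#' equals `m`, preferring pairs close to the requested ones; references are
#' never mutated. The realised value is recorded in `microhomology_len`.
#'
#' @param site A [target_site()].
#' @param template A [transgene_template()].
#' @param mechanism One of `"anneal"`, `"join"`, `"snapback"`,
#'   `"extra_template"`, `"other"`.
#' @param template_start Requested 5' truncation offset (nt; 0 =
#'   full-length).
#' @param join_pos Requested junction coordinate of fusion (join; <= 0 is
#'   typical, default 0).
#' @param microhomology Requested microhomology (join, no insert; NULL =
#'   take whatever is realised at the requested coordinates).
#' @param insert Nontemplated insert (join only, default "").
#' @param snapback_len Reverse-complement arm length (snapback, default 40).
#' @param arm_len Upstream arm length for extra_template (default 40) and
#'   other (default 600).
#' @param host_seq Host decoy sequence (required for `mechanism = "other"`).
#' @param join_window Candidate `join_pos` range for microhomology
#'   realisation (default -10..0).
#' @param t0_max Largest candidate truncation offset considered (default
#'   150, clamped so at least 60 nt of template remain).
#' @param id Allele identifier.
#' @return An object of class `insertion_allele`: mechanism, coordinates,
#'   realised `microhomology_len`, `allele_seq`, and the internal junction
#'   bookkeeping (`upstream_len`, `arm_len`, `suffix_len`) used by the read
#'   simulator.
#' @export
make_allele <- function(site, template, mechanism,
                        template_start = 0L, join_pos = 0L,
                        microhomology = NULL, insert = "",
                        snapback_len = 40L, arm_len = NULL,
                        host_seq = NULL, join_window = c(-10L, 0L),
                        t0_max = 150L, id = NULL) {
  mechanism <- match.arg(mechanism,
                         c("anneal", "join", "snapback", "extra_template", "other"))
  scaf <- site$scaffold_seq
  nick <- site$nick_coord
  tpl <- template$full_seq
  L <- nchar(tpl)
  h <- template$homology_len
  t0 <- as.integer(template_start)
  p <- as.integer(join_pos)
  if (t0 < 0L || t0 >= L) abort("template_start outside template")
  arm <- ""
  realized_mh <- NA_integer_

  if (mechanism == "anneal") {
    if (h == 0L) abort("anneal requires a template with rRNA homology (h >= 1)")
    if (t0 >= h) abort("anneal truncation must leave homology (template_start < h)")
    upstream_len <- nick
    suffix <- substr(tpl, h + 1L, L)
    p <- NA_integer_
  } else if (mechanism == "join") {
    if (nchar(insert) > 0L) {
      check_dna(insert, "insert")
      realized_mh <- 0L
    } else if (!is.null(microhomology)) {
      sel <- select_join_coords(site, template, as.integer(microhomology),
                                p_pref = p, t0_pref = t0,
                                join_window = join_window, t0_max = t0_max)
      p <- sel$join_pos; t0 <- sel$template_start
      realized_mh <- sel$mh
    } else {
      realized_mh <- junction_microhomology(site, template, p, t0)$mh_max
    }
    upstream_len <- nick + p
    if (upstream_len < 1L) abort("join_pos removes the entire upstream scaffold")
    arm <- insert
    suffix <- substr(tpl, t0 + 1L, L)
  } else if (mechanism == "snapback") {
    snapback_len <- as.integer(snapback_len)
    if (t0 + snapback_len > L) abort("snapback arm exceeds template")
    upstream_len <- nick + p
    arm <- revcomp(substr(tpl, t0 + 1L, t0 + snapback_len))
    suffix <- substr(tpl, t0 + 1L, L)
  } else if (mechanism == "extra_template") {
    arm_len <- as.integer(arm_len %||% 40L)
    # arm copied from a second template's 3' module, just 5' of the tail
    tail_len <- nchar(template$tail_seq)
    arm_end <- L - tail_len
    if (arm_end - arm_len + 1L <= t0) abort("extra-template arm overlaps suffix start")
    upstream_len <- nick + p
    arm <- substr(tpl, arm_end - arm_len + 1L, arm_end)
    suffix <- substr(tpl, t0 + 1L, L)
  } else { # other
    arm_len <- as.integer(arm_len %||% 600L)
    if (is.null(host_seq) || nchar(host_seq) < arm_len) {
      abort("mechanism 'other' requires host_seq of at least arm_len")
    }
    start <- sample.int(nchar(host_seq) - arm_len + 1L, 1L)
    upstream_len <- 0L
    arm <- substr(host_seq, start, start + arm_len - 1L)
    suffix <- substr(tpl, t0 + 1L, L)
  }

  allele_seq <- paste0(
    substr(scaf, 1L, upstream_len), arm, suffix,
    substr(scaf, nick + 1L, nchar(scaf))
  )
  structure(
    list(
      id = id %||% paste0("allele_", mechanism),
      mechanism = mechanism,
      template_name = template$name,
      template_start = t0,
      join_pos = if (mechanism %in% c("join", "snapback", "extra_template")) p else NA_integer_,
      microhomology_len = realized_mh,
      nontemplated_insert = if (mechanism == "join") insert else "",
      snapback_len = if (mechanism == "snapback") snapback_len else NA_integer_,
      three_prime_exact = TRUE,
      allele_seq = allele_seq,
      upstream_len = upstream_len,
      arm_len = nchar(arm),
      suffix_len = nchar(suffix),
      homology_len = h
    ),
    class = "insertion_allele"
  )
}

#' @export
print.insertion_allele <- function(x, ...) {
  cat("<insertion_allele> ", x$id, " [", x$mechanism, "]\n", sep = "")
  cat("  template ", x$template_name, ", start offset ", x$template_start,
      "; join_pos ", x$join_pos, "; mh ", x$microhomology_len,
      "; insert '", x$nontemplated_insert, "'\n", sep = "")
  cat("  allele: ", nchar(x$allele_seq), " nt\n", sep = "")
  invisible(x)
}

# choose (join_pos, template_start) whose realised microhomology equals m,
# preferring coordinates near the requested ones; fall back to the closest
# achievable value >= m, then the largest available.
select_join_coords <- function(site, template, m, p_pref = 0L, t0_pref = 0L,
                               join_window = c(-10L, 0L), t0_max = 150L) {
  L <- nchar(template$full_seq)
  t0s <- 0:min(t0_max, L - 60L)
  ps <- join_window[1]:join_window[2]
  grid <- expand.grid(p = ps, t0 = t0s)
  S <- strsplit(site$scaffold_seq, "", fixed = TRUE)[[1L]]
  Tv <- strsplit(template$full_seq, "", fixed = TRUE)[[1L]]
  nS <- length(S); nick <- site$nick_coord; w <- 20L
  grid$mh <- vapply(seq_len(nrow(grid)), function(i) {
    bp <- nick + grid$p[i]; t0 <- grid$t0[i]
    r <- 0L
    while (r < w && bp + 1L + r <= nS && t0 + 1L + r <= L &&
           S[bp + 1L + r] == Tv[t0 + 1L + r]) r <- r + 1L
    l <- 0L
    while (l < w && bp - l >= 1L && t0 - l >= 1L &&
           S[bp - l] == Tv[t0 - l]) l <- l + 1L
    r + l
  }, integer(1))
  pick <- function(rows) {
    d <- abs(rows$p - p_pref) + abs(rows$t0 - t0_pref) / 10
    rows[order(d, rows$t0), ][1L, ]
  }
  hit <- grid[grid$mh == m, , drop = FALSE]
  if (nrow(hit) == 0L) {
    ge <- grid[grid$mh >= m, , drop = FALSE]
    hit <- if (nrow(ge) > 0L) ge[ge$mh == min(ge$mh), , drop = FALSE]
           else grid[grid$mh == max(grid$mh), , drop = FALSE]
  }
  best <- pick(hit)
  list(join_pos = best$p, template_start = best$t0, mh = best$mh)
}

#' Truth table row(s) for a set of alleles
#'
#' @param alleles List of [make_allele()] objects.
#' @return Tibble with one row per allele.
#' @export
allele_table <- function(alleles) {
  list_rbind(lapply(alleles, function(a) {
    tibble(
      allele_id = a$id, mechanism = a$mechanism, template = a$template_name,
      template_start = a$template_start, join_pos = a$join_pos,
      microhomology_len = a$microhomology_len,
      nontemplated_insert = a$nontemplated_insert,
      snapback_len = a$snapback_len, allele_len = nchar(a$allele_seq)
    )
  }))
}

#' Read-simulation configuration
#'
#' Emulates the sequencing setup used for junction characterisation: gDNA
#' sheared to 400-500 bp and sequenced as 150-bp paired-end reads.
#'
#' @param fragment_len_range Fragment length range in bp (default c(400,
#'   500)).
#' @param read_len Read length (default 150).
#' @param n_pairs Number of read pairs to draw (before duplicates).
#' @param substitution_error_rate Per-base substitution probability (default
#'   0.001).
#' @param quality Either a single PHRED score applied to every base
#'   (default 37) or a list `list(levels=, probs=)` for a mixed model.
#' @param duplicate_rate Expected fraction of pairs duplicated exactly
#'   (default 0.01).
#' @param contaminant_fraction Fraction of pairs drawn from contaminant
#'   sequences (default 0).
#' @param background_weight Weight of the uninserted wild-type locus class
#'   (default 0).
#' @param focus One of `"uniform"` (fragments uniform over the source) or
#'   `"junctions"` (fragment placement targets reads that span the 5' or 3'
#'   junction, emulating junction-enriched coverage at desk scale).
#' @param rng_seed Mandatory RNG seed.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(fragment_len_range = c(400L, 500L), read_len = 150L,
                            n_pairs = 1000L, substitution_error_rate = 0.001,
                            quality = 37L, duplicate_rate = 0.01,
                            contaminant_fraction = 0, background_weight = 0,
                            focus = c("uniform", "junctions"), rng_seed) {
  if (missing(rng_seed)) abort("rng_seed is mandatory")
  focus <- match.arg(focus)
  stopifnot(read_len <= fragment_len_range[1],
            substitution_error_rate >= 0, substitution_error_rate <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1)
  structure(list(
    fragment_len_range = as.integer(fragment_len_range),
    read_len = as.integer(read_len), n_pairs = as.integer(n_pairs),
    substitution_error_rate = substitution_error_rate, quality = quality,
    duplicate_rate = duplicate_rate, contaminant_fraction = contaminant_fraction,
    background_weight = background_weight, focus = focus,
    rng_seed = as.integer(rng_seed)
  ), class = "read_sim_config")
}

quality_string <- function(n, quality) {
  if (is.list(quality)) {
    phred_encode(sample(quality$levels, n, replace = TRUE, prob = quality$probs))
  } else {
    strrep(rawToChar(as.raw(as.integer(quality) + 33L)), n)
  }
}

apply_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  v <- strsplit(seq, "")[[1L]]
  for (i in pos) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1L)
  paste(v, collapse = "")
}

# interval on the allele that a 5'-junction-informative read must cover
allele_j5_interval <- function(a, anchor = 15L) {
  if (a$mechanism == "other") {
    c(max(1L, a$arm_len - 2L * anchor), a$arm_len + 2L * anchor)
  } else {
    c(a$upstream_len - anchor, a$upstream_len + a$arm_len + anchor)
  }
}

allele_j3_interval <- function(a, anchor = 15L) {
  j3 <- a$upstream_len + a$arm_len + a$suffix_len
  c(j3 - anchor, j3 + anchor)
}

#' Simulate paired-end reads from insertion alleles
#'
#' Draws fragments from a weighted mixture of insertion alleles (plus an
#' optional uninserted-locus background class and contaminant reads), emits
#' both mates with quality strings, applies substitution errors, and injects
#' exact duplicates. Fully reproducible from `config$rng_seed`.
#'
#' @param alleles List of [make_allele()] objects.
#' @param weights Numeric weights over alleles (normalised internally).
#' @param config A [read_sim_config()].
#' @param site The [target_site()] supplying the background (uninserted)
#'   locus when `background_weight > 0`.
#' @param contaminants Named character vector of contaminant sequences.
#' @return A list with `reads` (tibble: `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`) and `truth` (one row per pair: source, mechanism, coordinates,
#'   junction-spanning flags, duplicate flag).
#' @export
simulate_reads <- function(alleles, weights = NULL, config, site = NULL,
                           contaminants = character()) {
  stopifnot(inherits(config, "read_sim_config"))
  with_local_seed(config$rng_seed, {
    n <- config$n_pairs
    rl <- config$read_len
    empty_reads <- tibble(read_id = character(), seq1 = character(),
                          qual1 = character(), seq2 = character(), qual2 = character())
    empty_truth <- tibble(read_id = character(), class = character(),
                          allele_id = character(), mechanism = character(),
                          template_start = integer(), join_pos = integer(),
                          microhomology_len = integer(), nontemplated_insert = character(),
                          spans_5prime_junction = logical(),
                          spans_3prime_junction = logical(), is_duplicate = logical())
    if (n == 0L) return(list(reads = empty_reads, truth = empty_truth))
    weights <- weights %||% rep(1, length(alleles))
    if (length(alleles) > 0L) weights <- weights / sum(weights)
    if (config$contaminant_fraction > 0 && length(contaminants) == 0L) {
      abort("contaminant_fraction > 0 but no contaminants supplied")
    }
    if (config$background_weight > 0 && is.null(site)) {
      abort("background_weight > 0 requires site")
    }

    reads <- vector("list", n)
    truth <- vector("list", n)
    anchor <- 15L
    for (i in seq_len(n)) {
      frag_len <- sample(config$fragment_len_range[1]:config$fragment_len_range[2], 1L)
      u <- runif(1)
      if (u < config$contaminant_fraction) {
        cls <- "contaminant"
        src <- contaminants[[sample.int(length(contaminants), 1L)]]
        a <- NULL
      } else if (u < config$contaminant_fraction + config$background_weight) {
        cls <- "background"
        src <- site$scaffold_seq
        a <- NULL
      } else {
        cls <- "allele"
        k <- sample.int(length(alleles), 1L, prob = weights)
        a <- alleles[[k]]
        src <- a$allele_seq
      }
      slen <- nchar(src)
      frag_len <- min(frag_len, slen)
      smax <- slen - frag_len + 1L
      s <- NULL
      if (cls == "allele" && config$focus == "junctions") {
        # target a mate at the 5' (R1) or 3' (R2) junction
        if (runif(1) < 0.5) {
          iv <- allele_j5_interval(a, anchor)
          lo <- max(1L, iv[2] - rl + 1L); hi <- min(smax, iv[1])
        } else {
          iv <- allele_j3_interval(a, anchor)
          e_lo <- iv[2]; e_hi <- min(slen, iv[1] + rl - 1L)
          lo <- max(1L, e_lo - frag_len + 1L); hi <- min(smax, e_hi - frag_len + 1L)
        }
        if (hi >= lo) s <- sample(lo:hi, 1L)
      }
      if (is.null(s)) s <- sample.int(smax, 1L)
      frag <- substr(src, s, s + frag_len - 1L)
      r1 <- substr(frag, 1L, rl)
      r2 <- revcomp(substr(frag, frag_len - rl + 1L, frag_len))
      if (runif(1) < 0.5) { tmp <- r1; r1 <- r2; r2 <- tmp }  # random fragment strand
      r1 <- apply_substitutions(r1, config$substitution_error_rate)
      r2 <- apply_substitutions(r2, config$substitution_error_rate)
      id <- sprintf("read%06d", i)
      reads[[i]] <- tibble(read_id = id, seq1 = r1,
                           qual1 = quality_string(nchar(r1), config$quality),
                           seq2 = r2, qual2 = quality_string(nchar(r2), config$quality))
      cover <- function(iv) {
        # does either mate's fragment interval cover iv?
        (s <= iv[1] && s + rl - 1L >= iv[2]) ||
          (s + frag_len - rl <= iv[1] && s + frag_len - 1L >= iv[2])
      }
      if (cls == "allele") {
        truth[[i]] <- tibble(
          read_id = id, class = cls, allele_id = a$id, mechanism = a$mechanism,
          template_start = a$template_start, join_pos = a$join_pos,
          microhomology_len = a$microhomology_len,
          nontemplated_insert = a$nontemplated_insert,
          spans_5prime_junction = cover(allele_j5_interval(a, anchor)),
          spans_3prime_junction = cover(allele_j3_interval(a, anchor)),
          is_duplicate = FALSE)
      } else {
        truth[[i]] <- tibble(
          read_id = id, class = cls, allele_id = NA_character_,
          mechanism = NA_character_, template_start = NA_integer_,
          join_pos = NA_integer_, microhomology_len = NA_integer_,
          nontemplated_insert = NA_character_,
          spans_5prime_junction = FALSE, spans_3prime_junction = FALSE,
          is_duplicate = FALSE)
      }
    }
    reads <- list_rbind(reads)
    truth <- list_rbind(truth)
    n_dup <- rbinom(1L, n, config$duplicate_rate)
    if (n_dup > 0L) {
      idx <- sample.int(n, n_dup, replace = TRUE)
      dup_reads <- reads[idx, ]
      dup_truth <- truth[idx, ]
      dup_reads$read_id <- paste0(dup_reads$read_id, "_dup", seq_len(n_dup))
      dup_truth$read_id <- dup_reads$read_id
      dup_truth$is_duplicate <- TRUE
      reads <- bind_rows(reads, dup_reads)
      truth <- bind_rows(truth, dup_truth)
    }
    list(reads = reads, truth = truth)
  })
}

#' Write a read-pair tibble as paired FASTQ
#'
#' Standard 4-line records, PHRED+33.
#'
#' @param reads Tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param r1_path,r2_path Output paths.
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  rec <- function(id, seq, qual, mate) {
    as.vector(rbind(paste0("@", id, "/", mate), seq, "+", qual))
  }
  writeLines(rec(reads$read_id, reads$seq1, reads$qual1, 1L), r1_path)
  writeLines(rec(reads$read_id, reads$seq2, reads$qual2, 2L), r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param r1_path,r2_path Paths to the mate FASTQ files (uncompressed,
#'   4-line records).
#' @return Tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  parse1 <- function(path) {
    x <- readLines(path)
    if (length(x) %% 4L != 0L) abort(sprintf("malformed FASTQ: %s", path))
    id <- sub("^@", "", x[seq(1L, length(x), by = 4L)])
    id <- sub("/[12]$", "", id)
    list(id = id, seq = x[seq(2L, length(x), by = 4L)],
         qual = x[seq(4L, length(x), by = 4L)])
  }
  a <- parse1(r1_path); b <- parse1(r2_path)
  if (length(a$id) != length(b$id) || any(a$id != b$id)) {
    abort("unmatched mates between FASTQ files")
  }
  tibble(read_id = a$id, seq1 = a$seq, qual1 = a$qual,
         seq2 = b$seq, qual2 = b$qual)
}
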