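# Shared fixtures and independent oracles for the test suite.
# All fixtures are generated in code; nothing is read from disk.

fixture_site <- function(scaffold_len = 1200L, nick = 600L, seed = 101L) {
  withr::with_seed(seed, {
    target_site(random_dna(scaffold_len), nick_coord = nick)
  })
}

# templates sharing one 3' module: h = 28, h = 11 and h = 0 (gRz-like)
fixture_templates <- function(site, seed = 202L) {
  withr::with_seed(seed, {
    three_p <- random_dna(98)
    list(
      h28 = transgene_template(
        five_prime_module("Rz-28", random_dna(40), 28L, site),
        three_prime_seq = three_p, site = site),
      h11 = transgene_template(
        five_prime_module("Rz-11", random_dna(45), 11L, site),
        three_prime_seq = three_p, site = site),
      h0 = transgene_template(
        five_prime_module("gRz-like", random_dna(55), 0L),
        three_prime_seq = three_p, site = site)
    )
  })
}

fixture_host <- function(len = 20000L, seed = 303L) {
  withr::with_seed(seed, random_dna(len))
}

fixture_refs <- function(site, template, flank = 400L, host = fixture_host(),
                         contaminants = character()) {
  mapping_references(site, template, flank_len = flank, host_ref = host,
                     contaminants = contaminants)
}

# ---- exhaustive affine-gap local alignment oracle (pure R dynamic program)
# gap of length L costs open + L * extend; returns the best local score.
sw_oracle_score <- function(query, ref, scoring = align_scoring()) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)       # best ending in a match/mismatch
  Ix <- matrix(NEG, n + 1, m + 1)    # gap in ref (query base consumed)
  Iy <- matrix(NEG, n + 1, m + 1)    # gap in query (ref base consumed)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (q[i] == r[j]) scoring$match else scoring$mismatch
      M[i + 1, j + 1] <- max(0, M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - scoring$gap_open - scoring$gap_extend,
                              Ix[i, j + 1] - scoring$gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - scoring$gap_open - scoring$gap_extend,
                              Iy[i + 1, j] - scoring$gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# ---- exhaustive breakpoint-enumeration oracle for microhomology
# A junction built as up_ref[1..k] ++ down_ref[k2..] admits breakpoint
# shifts s where both sides stay consistent with their references; the
# maximal microhomology is the width of the contiguous admissible range.
mh_enum_oracle <- function(up_ref, down_ref, k, k2, window = 20L) {
  la <- nchar(up_ref); lb <- nchar(down_ref)
  admissible <- function(s) {
    if (s == 0L) return(TRUE)
    if (s > 0L) {
      if (k + s > la || k2 + s - 1L > lb) return(FALSE)
      substr(up_ref, k + 1L, k + s) == substr(down_ref, k2, k2 + s - 1L)
    } else {
      if (k + s < 0L || k2 + s < 1L) return(FALSE)
      substr(up_ref, k + s + 1L, k) == substr(down_ref, k2 + s, k2 - 1L)
    }
  }
  hi <- 0L
  while (hi < window && admissible(hi + 1L)) hi <- hi + 1L
  lo <- 0L
  while (lo > -window && admissible(lo - 1L)) lo <- lo - 1L
  hi - lo
}

# a 20-read-pair FASTQ fixture where every record's fate under the
# "length < 36 / PHRED < 30" rules is decidable by hand:
#  - pairs 1-10: 100 bp, all Q40                       -> kept (10)
#  - pairs 11-13: R1 with 80 trailing Q2 bases         -> trimmed to 20 -> len discard (3)
#  - pairs 14-16: R1 uniform Q29                       -> quality discard (3)
#  - pairs 17-18: exact duplicates of pair 1           -> dedup removes (2)
#  - pairs 19-20: 40 bp, all Q35                       -> kept (2)
# expected: dedup removes 2; survivors 12; len discards 3; qual discards 3
fixture_filter_pairs <- function() {
  q <- function(qv, n) strrep(rawToChar(as.raw(qv + 33L)), n)
  mk <- function(id, s1, q1, s2, q2) {
    tibble::tibble(read_id = id, seq1 = s1, qual1 = q1, seq2 = s2, qual2 = q2)
  }
  base1 <- withr::with_seed(7L, random_dna(100))
  base2 <- withr::with_seed(8L, random_dna(100))
  rows <- list()
  for (i in 1:10) {
    s1 <- withr::with_seed(100L + i, random_dna(100))
    s2 <- withr::with_seed(200L + i, random_dna(100))
    if (i == 1L) { s1 <- base1; s2 <- base2 }
    rows[[i]] <- mk(sprintf("p%02d", i), s1, q(40L, 100), s2, q(40L, 100))
  }
  for (i in 11:13) {
    s1 <- withr::with_seed(100L + i, random_dna(100))
    s2 <- withr::with_seed(200L + i, random_dna(100))
    q1 <- paste0(q(40L, 20), q(2L, 80))
    rows[[i]] <- mk(sprintf("p%02d", i), s1, q1, s2, q(40L, 100))
  }
  for (i in 14:16) {
    s1 <- withr::with_seed(100L + i, random_dna(100))
    s2 <- withr::with_seed(200L + i, random_dna(100))
    rows[[i]] <- mk(sprintf("p%02d", i), s1, q(29L, 100), s2, q(40L, 100))
  }
  for (i in 17:18) {
    rows[[i]] <- mk(sprintf("p%02d", i), base1, q(40L, 100), base2, q(40L, 100))
  }
  for (i in 19:20) {
    s1 <- withr::with_seed(100L + i, random_dna(40))
    s2 <- withr::with_seed(200L + i, random_dna(40))
    rows[[i]] <- mk(sprintf("p%02d", i), s1, q(35L, 40), s2, q(35L, 40))
  }
  dplyr::bind_rows(rows)
}

# simulate one mechanism population and run the pipeline; returns per-allele
# recovery info (modal 5' category among retained junction-spanning reads)
recover_labels <- function(site, template, alleles, refs, n_pairs_per_allele = 20L,
                           error_rate = 0, seed = 11L) {
  cfg <- read_sim_config(n_pairs = n_pairs_per_allele * length(alleles),
                         substitution_error_rate = error_rate,
                         duplicate_rate = 0, focus = "junctions",
                         rng_seed = seed)
  sim <- simulate_reads(alleles, config = cfg, site = site)
  res <- run_insertion_pipeline(sim$reads, refs)
  ev5 <- res$evidence[res$evidence$side == "five_prime", ]
  calls <- res$calls
  cat_of <- stats::setNames(calls$category, calls$call_id)
  truth <- sim$truth
  span5 <- truth[truth$spans_5prime_junction, c("read_id", "allele_id", "mechanism")]
  span3 <- truth[truth$spans_3prime_junction, c("read_id", "allele_id")]
  merged <- merge(span5, ev5, by = "read_id")
  merged$cat <- cat_of[merged$call_id]
  per_allele <- split(merged$cat, merged$allele_id)
  mech <- stats::setNames(vapply(alleles, function(a) a$mechanism, character(1)),
                          vapply(alleles, function(a) a$id, character(1)))
  rec5 <- vapply(names(per_allele), function(aid) {
    tab <- table(per_allele[[aid]])
    names(tab)[which.max(tab)] == mech[[aid]]
  }, logical(1))
  ev3 <- res$evidence[res$evidence$side == "three_prime", ]
  merged3 <- merge(span3, ev3, by = "read_id")
  merged3$cat <- cat_of[merged3$call_id]
  per_allele3 <- split(merged3$cat, merged3$allele_id)
  rec3 <- vapply(names(per_allele3), function(aid) {
    tab <- table(per_allele3[[aid]])
    names(tab)[which.max(tab)] == "on_target"
  }, logical(1))
  list(
    n_alleles = length(alleles),
    n5_evaluated = length(rec5), n5_correct = sum(rec5),
    n3_evaluated = length(rec3), n3_correct = sum(rec3),
    calls = calls, evidence = res$evidence, truth = truth
  )
}

# mixed-mechanism allele population used by the recovery tests. Anneal
# requires a template with rRNA homology; the end-joining mechanisms are
# generated on the homology-free template (mirroring the template designs
# whose junctions each mechanism dominates), so the two groups are analysed
# against their own mapping references.
build_allele_population <- function(site, templates, host,
                                    n_per_mech = 20L, seed = 5L) {
  withr::with_seed(seed, {
    anneal <- list()
    h0 <- list()
    idx <- 0L
    add <- function(a, grp) {
      idx <<- idx + 1L
      a$id <- paste0("A", idx)
      if (grp == "anneal") anneal[[length(anneal) + 1L]] <<- a
      else h0[[length(h0) + 1L]] <<- a
    }
    trunc_draw <- function() {
      if (runif(1) < 0.7) 0L else min(50L, rgeom(1L, 0.08))
    }
    for (i in seq_len(n_per_mech)) {
      add(make_allele(site, templates$h28, "anneal"), "anneal")
      if (i %% 2L == 0L) {
        add(make_allele(site, templates$h0, "join",
                        insert = random_dna(sample(2:6, 1L)),
                        template_start = trunc_draw(),
                        join_pos = 0L), "h0")
      } else {
        add(make_allele(site, templates$h0, "join",
                        microhomology = sample(0:3, 1L),
                        template_start = trunc_draw(),
                        join_pos = sample(-6:0, 1L)), "h0")
      }
      add(make_allele(site, templates$h0, "snapback",
                      template_start = trunc_draw()), "h0")
      add(make_allele(site, templates$h0, "extra_template",
                      template_start = sample(0:20, 1L)), "h0")
      add(make_allele(site, templates$h0, "other", host_seq = host,
                      template_start = trunc_draw()), "h0")
    }
    list(anneal = anneal, h0 = h0)
  })
}
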