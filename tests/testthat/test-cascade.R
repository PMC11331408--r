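# verifies a segment's bases against its reference (substring oracle)
segment_matches_ref <- function(seg, read_seq, refs) {
  ref <- switch(seg$ref_id,
                junction_ref = refs$junction_ref,
                rdna = , insertion_context = refs$rdna_ref,
                host = refs$host_ref)
  piece <- substr(read_seq, seg$read_start, seg$read_end)
  if (seg$strand == "-") piece <- revcomp(piece)
  piece == substr(ref, seg$ref_start, seg$ref_end)
}

test_that("error-free retained reads are tiled by mismatch-free segments", {
  site <- fixture_site()
  tpl <- fixture_templates(site)$h0
  refs <- fixture_refs(site, tpl)
  alleles <- list(
    make_allele(site, tpl, "join", join_pos = 0L, id = "j"),
    make_allele(site, tpl, "snapback", id = "s"),
    make_allele(site, tpl, "other", host_seq = refs$host_ref, id = "o"))
  cfg <- read_sim_config(n_pairs = 90, substitution_error_rate = 0,
                         duplicate_rate = 0, focus = "junctions", rng_seed = 41)
  sim <- simulate_reads(alleles, config = cfg, site = site)
  casc <- run_cascade(sim$reads, refs)
  seqs <- c(stats::setNames(sim$reads$seq1, paste0(sim$reads$read_id, "/1")),
            stats::setNames(sim$reads$seq2, paste0(sim$reads$read_id, "/2")))
  for (i in seq_len(nrow(casc$segments))) {
    seg <- casc$segments[i, ]
    ok <- segment_matches_ref(seg, seqs[[paste0(seg$read_id, "/", seg$mate)]], refs)
    expect_true(ok, info = sprintf("segment %d (%s stage %d)", i, seg$ref_id,
                                   seg$stage))
  }
  # segments of one read never overlap on the read
  by_read <- split(casc$segments, paste0(casc$segments$read_id, "/",
                                         casc$segments$mate))
  overlaps <- vapply(by_read, function(s) {
    s <- s[order(s$read_start), ]
    any(s$read_start[-1] <= s$read_end[-nrow(s)]) && nrow(s) > 1
  }, logical(1))
  expect_false(any(overlaps))
})

test_that("stage attribution is monotone: stage-1-explained reads stop there", {
  site <- fixture_site()
  tpl <- fixture_templates(site)$h28
  refs <- fixture_refs(site, tpl)
  a <- make_allele(site, tpl, "anneal")
  cfg <- read_sim_config(n_pairs = 40, substitution_error_rate = 0,
                         duplicate_rate = 0, focus = "junctions", rng_seed = 42)
  sim <- simulate_reads(list(a), config = cfg, site = site)
  casc <- run_cascade(sim$reads, refs)
  cover <- casc$segments |>
    dplyr::group_by(read_id, mate) |>
    dplyr::summarise(full = any(stage == 1 & read_end - read_start + 1L == 150L),
                     later = any(stage > 1), .groups = "drop")
  expect_false(any(cover$full & cover$later))
  # anneal junction reads: a single junction_ref segment without clips
  j5 <- refs$flank_len
  span <- casc$segments |>
    dplyr::filter(ref_id == "junction_ref", ref_start <= j5 - 15,
                  ref_end >= j5 + 15)
  expect_gt(nrow(span), 0)
  expect_true(all(span$read_start == 1L & span$read_end == 150L))
})

test_that("host-dominant pairs and contaminant pairs are discarded with reasons", {
  site <- fixture_site()
  tpl <- fixture_templates(site)$h0
  host <- fixture_host(30000)
  contam <- c(vector1 = fixture_host(4000, seed = 88))
  refs <- fixture_refs(site, tpl, host = host, contaminants = contam)
  a <- make_allele(site, tpl, "join", join_pos = 0L)
  withr::with_seed(43, {
    # pure host fragments
    sub_at <- function(x, s, len) {
      vapply(s, function(si) substr(x, si, si + len - 1L), character(1))
    }
    hstart <- sample(20000, 3)
    host_pairs <- tibble::tibble(
      read_id = paste0("h", 1:3),
      seq1 = sub_at(host, hstart, 150L),
      qual1 = strrep("I", 150),
      seq2 = revcomp(sub_at(host, hstart + 300L, 150L)),
      qual2 = strrep("I", 150))
    cstart <- sample(3000, 2)
    contam_pairs <- tibble::tibble(
      read_id = paste0("c", 1:2),
      seq1 = sub_at(contam, cstart, 150L),
      qual1 = strrep("I", 150),
      seq2 = revcomp(sub_at(contam, cstart + 200L, 150L)),
      qual2 = strrep("I", 150))
  })
  sim <- simulate_reads(list(a),
                        config = read_sim_config(n_pairs = 20,
                                                 substitution_error_rate = 0,
                                                 duplicate_rate = 0,
                                                 focus = "junctions",
                                                 rng_seed = 44),
                        site = site)
  casc <- run_cascade(dplyr::bind_rows(sim$reads, host_pairs, contam_pairs), refs)
  st <- stats::setNames(casc$pair_status$status, casc$pair_status$read_id)
  expect_true(all(st[paste0("h", 1:3)] == "host_better"))
  expect_true(all(st[paste0("c", 1:2)] == "contaminant"))
  expect_true(all(st[sim$reads$read_id] == "kept"))
  expect_equal(casc$log$host_better, 3L)
  expect_equal(casc$log$contaminant, 2L)
})

test_that("an empty contaminant panel makes the screen a no-op", {
  site <- fixture_site()
  tpl <- fixture_templates(site)$h0
  refs <- fixture_refs(site, tpl, contaminants = character())
  a <- make_allele(site, tpl, "join")
  sim <- simulate_reads(list(a),
                        config = read_sim_config(n_pairs = 10,
                                                 substitution_error_rate = 0,
                                                 duplicate_rate = 0,
                                                 rng_seed = 45),
                        site = site)
  casc <- run_cascade(sim$reads, refs)
  expect_equal(casc$log$contaminant, 0L)
})

test_that("the fuzzy rescue assigns error-laden fragments near the insertion site", {
  site <- fixture_site()
  tpl <- fixture_templates(site)$h0
  refs <- fixture_refs(site, tpl, host = "")
  # a fragment of the insertion-site context with 2 substitutions, too
  # divergent for exact matching but within the edit tolerance
  ctx <- substr(site$scaffold_seq, site$nick_coord - 19, site$nick_coord + 20)
  v <- strsplit(ctx, "")[[1]]
  v[5] <- setdiff(c("A", "C", "G", "T"), v[5])[1]
  v[25] <- setdiff(c("A", "C", "G", "T"), v[25])[1]
  frag <- paste(v, collapse = "")
  hit <- printmap:::fuzzy_context_hit(frag, ctx, max_edits = 3,
                                      context_offset = site$nick_coord - 20L)
  expect_false(is.null(hit))
  expect_equal(hit$read_start, 1L)
  none <- printmap:::fuzzy_context_hit(withr::with_seed(9, random_dna(40)),
                                       ctx, max_edits = 3, context_offset = 0L)
  expect_null(none)
})
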