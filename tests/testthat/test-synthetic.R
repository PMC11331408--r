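test_that("allele construction follows each mechanism's sequence invariant", {
  site <- fixture_site()
  tpls <- fixture_templates(site)
  up <- site$upstream_seq; down <- site$downstream_seq
  # anneal: seamless, one homology copy
  a <- make_allele(site, tpls$h28, "anneal")
  expect_equal(a$allele_seq,
               paste0(up, substr(tpls$h28$full_seq, 29, nchar(tpls$h28$full_seq)),
                      down))
  expect_error(make_allele(site, tpls$h0, "anneal"), "h >= 1")
  expect_error(make_allele(site, tpls$h28, "anneal", template_start = 28),
               "template_start < h")
  # join with a nontemplated insert between rDNA and template
  a <- make_allele(site, tpls$h0, "join", insert = "GG")
  expect_equal(a$allele_seq, paste0(up, "GG", tpls$h0$full_seq, down))
  expect_equal(a$microhomology_len, 0L)
  # join at position 0 with full-length template: direct fusion at the nick
  a <- make_allele(site, tpls$h0, "join", join_pos = 0L)
  expect_equal(a$allele_seq, paste0(up, tpls$h0$full_seq, down))
  # truncated join drops 5' template bases
  a <- make_allele(site, tpls$h0, "join", template_start = 25L, join_pos = -4L)
  expect_equal(a$allele_seq,
               paste0(substr(site$scaffold_seq, 1, site$nick_coord - 4),
                      substr(tpls$h0$full_seq, 26, nchar(tpls$h0$full_seq)),
                      down))
  expect_error(make_allele(site, tpls$h0, "join", template_start = 1000),
               "template")
  # snapback: reverse-complement arm precedes the template suffix
  a <- make_allele(site, tpls$h0, "snapback", snapback_len = 30L)
  expect_equal(substr(a$allele_seq, nchar(up) + 1, nchar(up) + 30),
               revcomp(substr(tpls$h0$full_seq, 1, 30)))
  # extra template: 3' module sequence precedes the suffix on the plus strand
  a <- make_allele(site, tpls$h0, "extra_template", arm_len = 30L)
  L <- nchar(tpls$h0$full_seq)
  expect_equal(substr(a$allele_seq, nchar(up) + 1, nchar(up) + 30),
               substr(tpls$h0$full_seq, L - 26 - 29, L - 26))
  # other: host-derived upstream arm
  host <- fixture_host(5000)
  withr::with_seed(1, a <- make_allele(site, tpls$h0, "other", host_seq = host))
  arm <- substr(a$allele_seq, 1, a$arm_len)
  expect_true(grepl(arm, host, fixed = TRUE))
})

test_that("requested join microhomology is realised against unmodified references", {
  site <- fixture_site()
  tpl <- fixture_templates(site)$h0
  withr::with_seed(55, {
    for (m in 0:3) {
      a <- make_allele(site, tpl, "join", microhomology = m)
      expect_equal(a$microhomology_len, m)
      # realised value verified against the reference-based recount
      rec <- junction_microhomology(site, tpl, a$join_pos, a$template_start)
      expect_equal(rec$mh_max, m)
    }
  })
})

test_that("read simulation is reproducible, well-formed and weight-consistent", {
  site <- fixture_site()
  tpl <- fixture_templates(site)$h0
  a1 <- make_allele(site, tpl, "join", join_pos = 0L, id = "al1")
  a2 <- make_allele(site, tpl, "snapback", id = "al2")
  cfg <- read_sim_config(n_pairs = 1200, substitution_error_rate = 0,
                         duplicate_rate = 0, rng_seed = 99)
  s1 <- simulate_reads(list(a1, a2), weights = c(0.3, 0.7), config = cfg,
                       site = site)
  s2 <- simulate_reads(list(a1, a2), weights = c(0.3, 0.7), config = cfg,
                       site = site)
  expect_identical(s1, s2)
  # byte-identical FASTQ from a fixed seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  g1 <- withr::local_tempfile(); g2 <- withr::local_tempfile()
  write_fastq_pair(s1$reads, f1, f2)
  write_fastq_pair(s2$reads, g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  # mixture frequencies within binomial 99% bounds
  n1 <- sum(s1$truth$allele_id == "al1")
  p_hat <- n1 / nrow(s1$truth)
  se <- sqrt(0.3 * 0.7 / nrow(s1$truth))
  expect_lt(abs(p_hat - 0.3), 2.58 * se + 1e-9)
  # constant quality model decodes exactly
  expect_true(all(phred_decode(s1$reads$qual1[1])[[1]] == 37L))
  # read lengths match the configuration
  expect_true(all(nchar(s1$reads$seq1) == 150L))
})

test_that("degenerate and erroneous configurations behave as specified", {
  site <- fixture_site()
  tpl <- fixture_templates(site)$h0
  a <- make_allele(site, tpl, "join")
  s <- simulate_reads(list(a), config = read_sim_config(n_pairs = 0, rng_seed = 1),
                      site = site)
  expect_equal(nrow(s$reads), 0L)
  expect_equal(nrow(s$truth), 0L)
  expect_error(read_sim_config(fragment_len_range = c(100, 120), read_len = 150,
                               rng_seed = 1))
  expect_error(read_sim_config(n_pairs = 10))  # seed is mandatory
  expect_error(simulate_reads(list(a),
                              config = read_sim_config(n_pairs = 5,
                                                       contaminant_fraction = 0.5,
                                                       rng_seed = 1),
                              site = site),
               "contaminant")
})

test_that("error-free junction-spanning reads match the junction reference exactly", {
  site <- fixture_site()
  tpl <- fixture_templates(site)$h28
  refs <- fixture_refs(site, tpl)
  a <- make_allele(site, tpl, "anneal")
  cfg <- read_sim_config(n_pairs = 60, substitution_error_rate = 0,
                         duplicate_rate = 0, focus = "junctions", rng_seed = 12)
  s <- simulate_reads(list(a), config = cfg, site = site)
  hits <- vapply(seq_len(nrow(s$reads)), function(i) {
    r1 <- s$reads$seq1[i]; r2 <- s$reads$seq2[i]
    (grepl(r1, refs$junction_ref, fixed = TRUE) ||
       grepl(revcomp(r1), refs$junction_ref, fixed = TRUE)) &&
      (grepl(r2, refs$junction_ref, fixed = TRUE) ||
         grepl(revcomp(r2), refs$junction_ref, fixed = TRUE))
  }, logical(1))
  expect_true(all(hits))
})

test_that("duplicates and contaminants are injected at the configured rates", {
  site <- fixture_site()
  tpl <- fixture_templates(site)$h0
  a <- make_allele(site, tpl, "join")
  contam <- c(mito = fixture_host(3000, seed = 77))
  cfg <- read_sim_config(n_pairs = 600, substitution_error_rate = 0,
                         duplicate_rate = 0.05, contaminant_fraction = 0.1,
                         rng_seed = 31)
  s <- simulate_reads(list(a), config = cfg, site = site, contaminants = contam)
  n_dup <- sum(s$truth$is_duplicate)
  expect_gt(n_dup, 600 * 0.05 - 3 * sqrt(600 * 0.05))
  expect_lt(n_dup, 600 * 0.05 + 3 * sqrt(600 * 0.05) + 1)
  frac_contam <- mean(s$truth$class[!s$truth$is_duplicate] == "contaminant")
  expect_lt(abs(frac_contam - 0.1), 3 * sqrt(0.1 * 0.9 / 600) + 1e-9)
  # duplicates are exact copies of their source pair
  dup <- s$truth$read_id[s$truth$is_duplicate][1]
  src <- sub("_dup.*$", "", dup)
  expect_equal(s$reads$seq1[s$reads$read_id == dup],
               s$reads$seq1[s$reads$read_id == src])
})
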