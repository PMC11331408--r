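test_that("3' classification applies the +/-3 bp on-target window", {
  expect_equal(classify_three_prime(0), "on_target")
  expect_equal(classify_three_prime(3), "on_target")
  expect_equal(classify_three_prime(-3), "on_target")
  expect_equal(classify_three_prime(4), "rdna_off_target")
  expect_equal(classify_three_prime(-400), "rdna_off_target")
  expect_equal(classify_three_prime(NA, "host"), "genomic_off_target")
  expect_equal(classify_three_prime(c(0, 5), c("rdna", "rdna")),
               c("on_target", "rdna_off_target"))
})

test_that("5' classification follows the decision order", {
  ev <- tibble::tibble(
    crosses_boundary = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    has_prev = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    prev_strand = c(NA, "-", "+", "+", "+", NA),
    prev_context = c(NA, "template", "template", "rdna_up", "host", NA),
    prev_template_pos = c(NA, 40L, 150L, NA, NA, NA),
    entry_template_pos = c(28L, 1L, 1L, 1L, 1L, 1L),
    insert = c("", "", "", "", "", "GG"))
  expect_equal(classify_five_prime(ev, h = 28L),
               c("anneal", "snapback", "extra_template", "join", "other",
                 "join"))
  # with no rRNA homology, seamless crossing evidence is a direct join
  expect_equal(classify_five_prime(ev[1, ], h = 0L), "join")
  # a minus-strand rDNA arm is also snap-back evidence
  ev2 <- ev[2, ]; ev2$prev_context <- "rdna_up"
  expect_equal(classify_five_prime(ev2, h = 28L), "snapback")
  # in-order template adjacency is not extra-template evidence
  ev3 <- ev[3, ]; ev3$prev_template_pos <- 1L; ev3$entry_template_pos <- 60L
  expect_equal(classify_five_prime(ev3, h = 28L), "other")
})

test_that("full-length assessment distinguishes anneal from other categories", {
  r <- assess_full_length("anneal", 28L, 28L)
  expect_true(r$full_length); expect_equal(r$truncation_offset, 0L)
  r <- assess_full_length("join", 0L, 28L)
  expect_true(r$full_length)
  r <- assess_full_length("join", 37L, 28L)
  expect_false(r$full_length); expect_equal(r$truncation_offset, 37L)
  r <- assess_full_length("anneal", 30L, 28L)
  expect_false(r$full_length); expect_equal(r$truncation_offset, 2L)
})

test_that("each mechanism is recovered from its own error-free simulation", {
  site <- fixture_site()
  tpls <- fixture_templates(site)
  host <- fixture_host()
  refs0 <- fixture_refs(site, tpls$h0, host = host)
  refs28 <- fixture_refs(site, tpls$h28, host = host)
  mk <- function(...) make_allele(site, ...)
  withr::with_seed(71, {
    alleles0 <- list(
      mk(tpls$h0, "join", microhomology = 0L, template_start = 0L, id = "j0"),
      mk(tpls$h0, "join", microhomology = 3L, id = "j3"),
      mk(tpls$h0, "join", insert = "GG", id = "jGG"),
      mk(tpls$h0, "snapback", id = "sb"),
      mk(tpls$h0, "extra_template", id = "et"),
      mk(tpls$h0, "other", host_seq = host, id = "ot"))
  })
  cfg <- read_sim_config(n_pairs = 300, substitution_error_rate = 0,
                         duplicate_rate = 0, focus = "junctions", rng_seed = 72)
  sim <- simulate_reads(alleles0, config = cfg, site = site)
  res <- run_insertion_pipeline(sim$reads, refs0)
  calls <- res$calls[res$calls$side == "five_prime", ]
  # every mechanism present among well-supported calls
  strong <- calls[calls$supporting_reads >= 5, ]
  expect_setequal(unique(strong$category),
                  c("join", "snapback", "extra_template", "other"))
  # the insert join is reported with its nontemplated bases at the nick
  jgg <- calls[calls$inserted_seq != "", ]
  expect_true(any(jgg$category == "join" & nchar(jgg$inserted_seq) == 2 &
                    jgg$rdna_coord == 0L))
  # the m=3 join: extreme placements differ by exactly the microhomology
  j3 <- calls[calls$category == "join" & !is.na(calls$mh_max) & calls$mh_max == 3L, ]
  expect_true(nrow(j3) >= 1)
  expect_equal(j3$rdna_coord_max_rdna - j3$rdna_coord_max_transgene,
               rep(3L, nrow(j3)))
  # anneal on the h=28 template
  a <- make_allele(site, tpls$h28, "anneal", id = "an")
  sim2 <- simulate_reads(list(a), config = read_sim_config(
    n_pairs = 40, substitution_error_rate = 0, duplicate_rate = 0,
    focus = "junctions", rng_seed = 73), site = site)
  res2 <- run_insertion_pipeline(sim2$reads, refs28)
  c5 <- res2$calls[res2$calls$side == "five_prime", ]
  expect_true(all(c5$category == "anneal"))
  expect_true(all(c5$inserted_seq == ""))
  expect_true(all(c5$full_length))
  # 3' junctions are on-target in both runs
  c3 <- dplyr::bind_rows(res$calls, res2$calls)
  c3 <- c3[c3$side == "three_prime", ]
  expect_true(all(c3$category == "on_target"))
  expect_true(all(c3$rdna_coord == 0L))
})

test_that("anneal calls never carry an inserted sequence", {
  site <- fixture_site()
  tpl <- fixture_templates(site)$h11
  refs <- fixture_refs(site, tpl)
  a <- make_allele(site, tpl, "anneal")
  sim <- simulate_reads(list(a), config = read_sim_config(
    n_pairs = 50, substitution_error_rate = 0.001, duplicate_rate = 0,
    focus = "junctions", rng_seed = 74), site = site)
  res <- run_insertion_pipeline(sim$reads, refs)
  ann <- res$calls[res$calls$category == "anneal", ]
  expect_gt(nrow(ann), 0)
  expect_true(all(ann$inserted_seq == ""))
})

test_that("each read supports at most one call per junction side", {
  site <- fixture_site()
  tpl <- fixture_templates(site)$h0
  refs <- fixture_refs(site, tpl)
  alleles <- list(make_allele(site, tpl, "join", join_pos = 0L, id = "x"),
                  make_allele(site, tpl, "snapback", id = "y"))
  sim <- simulate_reads(alleles, config = read_sim_config(
    n_pairs = 150, substitution_error_rate = 0, duplicate_rate = 0,
    focus = "junctions", rng_seed = 75), site = site)
  res <- run_insertion_pipeline(sim$reads, refs)
  dup <- res$evidence |>
    dplyr::count(read_id, mate, side) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(dup), 0L)
})

test_that("the insert catalog aggregates identical inserts", {
  calls <- tibble::tibble(
    side = "five_prime",
    category = c("join", "join", "join", "join", "anneal"),
    inserted_seq = c("", "G", "GG", "GG", ""),
    rdna_coord = 0L, supporting_reads = c(4L, 2L, 3L, 1L, 9L))
  tab <- catalog_inserts(calls)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$length, c(0L, 2L, 1L))
  expect_equal(tab$supporting_reads, c(4L, 4L, 2L))
  expect_equal(tab$n_junctions[tab$inserted_seq == "GG"], 2L)
  expect_equal(nrow(catalog_inserts(calls[calls$category == "anneal", ])), 0L)
})

test_that("calls export to TSV and BED with scaffold coordinates", {
  site <- fixture_site()
  calls <- tibble::tibble(
    call_id = c("J5_1", "J3_1"), side = c("five_prime", "three_prime"),
    category = c("join", "on_target"), rdna_coord = c(-2L, 0L),
    rdna_coord_max_rdna = c(-2L, NA), rdna_coord_max_transgene = c(-4L, NA),
    template_coord = c(0L, NA), mh_max = c(2L, NA), mh_left = c(2L, NA),
    mh_right = c(0L, NA), inserted_seq = "", full_length = c(TRUE, NA),
    truncation_offset = c(0L, NA), ambiguous = FALSE,
    supporting_reads = c(7L, 9L))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_calls(calls, site, tsv, bed)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), 2L)
  bedln <- utils::read.delim(bed, header = FALSE)
  expect_equal(bedln$V2, scaffold_pos(site, calls$rdna_coord) - 1L)
  expect_equal(bedln$V5, calls$supporting_reads)
})
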