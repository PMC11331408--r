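test_that("microhomology counting matches hand-built fixtures", {
  # references disagree at both junction-adjacent bases
  r <- count_microhomology("AAAA", "CCCC", up_ext = "GGGG", down_ext = "TTTT")
  expect_equal(r$mh_max, 0L)
  # 4 bases on each side are assignable to either reference
  r <- count_microhomology("AAATTAC", "GATTCCC",
                           up_ext = "GATTAGGC", down_ext = "CCGTTAC")
  expect_equal(r$mh_left, 4L)
  expect_equal(r$mh_right, 4L)
  expect_equal(r$mh_max, 8L)
  # counting is capped at the window
  r <- count_microhomology(strrep("A", 30), strrep("A", 30),
                           up_ext = strrep("A", 30), down_ext = strrep("A", 30),
                           window = 20)
  expect_equal(r$mh_max, 40L)
})

test_that("microhomology equals the breakpoint-enumeration oracle on random fixtures", {
  withr::with_seed(404, {
    for (i in 1:300) {
      up <- random_dna(sample(30:60, 1))
      down <- random_dna(sample(30:60, 1))
      k <- sample(10:(nchar(up) - 10), 1)
      k2 <- sample(10:(nchar(down) - 10), 1)
      w <- 8L
      got <- count_microhomology(
        read_left = substr(up, k - w + 1, k),
        read_right = substr(down, k2, nchar(down)),
        up_ext = substr(up, k + 1, k + w),
        down_ext = substr(down, k2 - w, k2 - 1),
        window = w)
      expect_equal(got$mh_max, mh_enum_oracle(up, down, k, k2, window = w),
                   info = sprintf("fixture %d", i))
    }
  })
})

test_that("generator-recorded join microhomology matches the enumeration oracle", {
  site <- fixture_site()
  tpl <- fixture_templates(site)$h0
  withr::with_seed(77, {
    for (i in 1:150) {
      m <- sample(0:4, 1)
      a <- make_allele(site, tpl, "join", microhomology = m,
                       template_start = sample(0:40, 1),
                       join_pos = sample(-8:0, 1))
      oracle <- mh_enum_oracle(site$scaffold_seq, tpl$full_seq,
                               k = site$nick_coord + a$join_pos,
                               k2 = a$template_start + 1L, window = 20L)
      expect_equal(a$microhomology_len, oracle,
                   info = sprintf("allele %d (requested m=%d)", i, m))
    }
  })
})

test_that("expected_by_chance implements the geometric chance model", {
  expect_equal(expected_by_chance(1, 0), 0.75)
  expect_equal(expected_by_chance(64, 1), 12)
  expect_equal(expected_by_chance(10, 0:3), 10 * 0.75 * 0.25^(0:3))
  # geometric normalisation: expectations sum to N
  expect_equal(sum(expected_by_chance(1, 0:60)), 1, tolerance = 1e-12)
  expect_error(expected_by_chance(-1, 0), "non-negative")
  expect_error(expected_by_chance(1, -2), "non-negative")
})

test_that("drawing geometric lengths equals the per-base Bernoulli construction", {
  withr::with_seed(505, {
    n <- 50000
    bern <- vapply(seq_len(n), function(i) {
      x <- 0L
      while (runif(1) < 0.25) x <- x + 1L
      x
    }, integer(1))
    for (x in 0:4) {
      expect_equal(mean(bern == x), 0.75 * 0.25^x, tolerance = 0.05)
    }
  })
})

test_that("resampling bands are reproducible and match the binomial SD", {
  r1 <- resample_ci(100, 4, n_reps = 2e4, rng_seed = 42)
  r2 <- resample_ci(100, 4, n_reps = 2e4, rng_seed = 42)
  expect_identical(r1, r2)
  # per-x count is Binomial(N, 0.75 * 0.25^x); SD known in closed form
  for (x in 0:2) {
    p <- 0.75 * 0.25^x
    expect_equal(r1$sd[r1$x == x], sqrt(100 * p * (1 - p)), tolerance = 0.05)
  }
  # bands are exactly expected +/- 2 SD
  expect_equal(r1$ci_low, r1$expected - 2 * r1$sd)
  expect_equal(r1$ci_high, r1$expected + 2 * r1$sd)
  expect_error(resample_ci(100, 3, n_reps = 1), "n_reps")
  expect_error(resample_ci(0, 3), "N must be")
})

test_that("observed distribution tabulates mh lengths with chance bands", {
  d <- microhomology_distribution(c(0, 0, 0, 1, 2, 0, 1), n_reps = 2000,
                                  rng_seed = 3)
  expect_s3_class(d, "mh_distribution")
  expect_equal(attr(d, "N"), 7L)
  expect_equal(d$observed, c(4L, 2L, 1L))
  expect_equal(d$expected, 7 * 0.75 * 0.25^(0:2))
  expect_equal(sum(d$observed), attr(d, "N"))
})

test_that("join-position tables split assignments and statuses correctly", {
  calls <- tibble::tibble(
    side = "five_prime", category = "join",
    rdna_coord = c(0L, 0L, -3L), rdna_coord_max_rdna = c(0L, 0L, -3L),
    rdna_coord_max_transgene = c(0L, -2L, -3L),
    template_coord = c(0L, 5L, 0L), mh_max = c(0L, 2L, 0L),
    mh_left = 0L, mh_right = 0L, inserted_seq = "",
    full_length = c(TRUE, FALSE, TRUE), truncation_offset = c(0L, 5L, 0L),
    ambiguous = FALSE, supporting_reads = c(5L, 2L, 1L))
  no_mh <- join_position_table(calls, "no_mh_only")
  expect_equal(no_mh$coord, c(-3L, 0L))
  expect_equal(no_mh$count_full, c(1L, 5L))
  max_r <- join_position_table(calls, "max_rdna")
  expect_equal(max_r$count_total[max_r$coord == 0], 7L)
  max_t <- join_position_table(calls, "max_transgene")
  # the m = 2 call moves by exactly its microhomology
  expect_equal(sort(max_t$coord), c(-3L, -2L, 0L))
  expect_equal(join_position_table(calls[0, ], "max_rdna")$coord, integer(0))
})
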