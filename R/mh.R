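#' Count maximum possible microhomology at a junction
#'
#' At an end-joining junction the breakpoint is ambiguous wherever bases
#' adjacent to it could derive from either flanking reference. The maximum
#' possible microhomology is counted in both directions: `mh_right` is the
#' longest run of junction bases immediately 3' of the breakpoint that also
#' matches the upstream reference's rightward continuation, and `mh_left` the
#' longest run immediately 5' of the breakpoint matching the downstream
#' reference's leftward extension. `mh_max = mh_left + mh_right` is the total
#' number of bases assignable to either side. Identity must be contiguous (no
#' mismatch tolerance) and counting is capped at `window` nt per side.
#'
#' @param read_left Junction sequence 5' of the breakpoint (only the last
#'   `window` bases are used).
#' @param read_right Junction sequence 3' of the breakpoint.
#' @param up_ext Upstream reference continuation 3' of the breakpoint
#'   (5'->3', first base abuts the breakpoint).
#' @param down_ext Downstream reference extension 5' of the breakpoint
#'   (5'->3', last base abuts the breakpoint).
#' @param window Maximum nt counted per side (default 20).
#' @return A one-row tibble: `mh_left`, `mh_right`, `mh_max`,
#'   `window_truncated` (TRUE when a run ran to the end of a reference
#'   extension shorter than `window`, so the count is a lower bound).
#' @examples
#' # junction ...TTAC | GATT... where the upstream reference continues GATT
#' # and the downstream reference is preceded by TTAC: 8 ambiguous bases
#' count_microhomology("AAATTAC", "GATTCCC", up_ext = "GATTAGGC", down_ext = "CCGTTAC")
#' @export
count_microhomology <- function(read_left, read_right, up_ext, down_ext,
                                window = 20L) {
  window <- as.integer(window)
  mh_right <- common_prefix_len(read_right, up_ext, cap = window)
  mh_left <- common_suffix_len(read_left, down_ext, cap = window)
  trunc <- (mh_right == min(nchar(read_right), nchar(up_ext)) && mh_right < window &&
              min(nchar(read_right), nchar(up_ext)) < window) ||
           (mh_left == min(nchar(read_left), nchar(down_ext)) && mh_left < window &&
              min(nchar(read_left), nchar(down_ext)) < window)
  tibble(
    mh_left = mh_left, mh_right = mh_right,
    mh_max = mh_left + mh_right,
    window_truncated = trunc
  )
}

#' Microhomology of a join junction defined by reference coordinates
#'
#' Convenience wrapper around [count_microhomology()] for a join between the
#' rDNA scaffold (retained through junction coordinate `join_pos`, exclusive)
#' and a template suffix starting at `template_start` (0 = full length). When
#' a nontemplated insert separates the two sides the insert belongs to
#' neither reference and the microhomology is 0 by definition.
#'
#' @param site A [target_site()].
#' @param template A [transgene_template()].
#' @param join_pos Junction coordinate of the fusion: scaffold retained is
#'   everything 5' of coordinate `join_pos` (so `join_pos = 0` retains the
#'   full upstream sequence).
#' @param template_start 5' truncation offset of the template (nt).
#' @param insert Nontemplated inserted sequence ("" for none).
#' @param window Maximum nt counted per side.
#' @return As [count_microhomology()], with `mh_left = mh_right = 0` when
#'   `insert` is non-empty.
#' @export
junction_microhomology <- function(site, template, join_pos, template_start,
                                   insert = "", window = 20L) {
  if (nchar(insert) > 0L) {
    return(tibble(mh_left = 0L, mh_right = 0L, mh_max = 0L, window_truncated = FALSE))
  }
  scaf <- site$scaffold_seq
  bp <- site$nick_coord + as.integer(join_pos)  # last retained scaffold position
  t0 <- as.integer(template_start)
  count_microhomology(
    read_left = substr0(scaf, bp - window + 1L, bp),
    read_right = substr0(template$full_seq, t0 + 1L, t0 + window),
    up_ext = substr0(scaf, bp + 1L, bp + window),
    down_ext = substr0(template$full_seq, t0 - window + 1L, t0),
    window = window
  )
}

#' Expected number of junctions with x bp of microhomology by chance
#'
#' Under a uniform 4-letter alphabet the chance that a junction shows exactly
#' x bp of microhomology follows a geometric law with per-base match
#' probability 1/4: the expected count among N junctions is
#' `N * (3/4) * (1/4)^x`.
#'
#' @param N Total number of join junctions analysed.
#' @param x Microhomology length(s) in bp (vectorised).
#' @param p_match Per-base chance match probability (default 0.25).
#' @return Numeric vector of expected counts.
#' @examples
#' expected_by_chance(1, 0)    # 0.75
#' expected_by_chance(64, 1)   # 12
#' @export
expected_by_chance <- function(N, x, p_match = 0.25) {
  if (any(N < 0) || any(x < 0)) abort("N and x must be non-negative")
  if (p_match <= 0 || p_match >= 1) abort("p_match must be in (0,1)")
  N * (1 - p_match) * p_match^x
}

#' Resampling confidence bands for the chance microhomology distribution
#'
#' Draws `n_reps` replicate datasets of N microhomology lengths from the
#' geometric chance model (per-base match probability `p_match`, stop
#' probability `1 - p_match`; drawing a geometric length per junction is
#' equivalent to the per-junction Bernoulli construction), tabulates counts
#' per length x, and reports the standard deviation across replicates. The
#' confidence band is `expected +/- ci_sd_mult * SD`.
#'
#' @param N Number of junctions per replicate (>= 1).
#' @param x_max Largest microhomology length tabulated.
#' @param n_reps Number of resampling repetitions (default 100000).
#' @param p_match Per-base chance match probability (default 0.25).
#' @param ci_sd_mult Band half-width in SD units (default 2).
#' @param rng_seed Optional seed making the bands reproducible.
#' @return A tibble with columns `x`, `expected`, `sd`, `ci_low`, `ci_high`.
#' @export
resample_ci <- function(N, x_max, n_reps = 1e5, p_match = 0.25,
                        ci_sd_mult = 2, rng_seed = NULL) {
  if (N < 1) abort("N must be >= 1")
  if (n_reps < 2) abort("n_reps must be >= 2 for a standard deviation")
  xs <- 0:x_max
  run <- function() {
    # chunk replicates to bound memory at ~2e7 draws at a time
    chunk <- max(1L, min(n_reps, floor(2e7 / N)))
    s1 <- numeric(length(xs)); s2 <- numeric(length(xs)); done <- 0L
    while (done < n_reps) {
      k <- min(chunk, n_reps - done)
      draws <- matrix(rgeom(k * N, prob = 1 - p_match), nrow = k)
      for (i in seq_along(xs)) {
        cnt <- rowSums(draws == xs[i])
        s1[i] <- s1[i] + sum(cnt)
        s2[i] <- s2[i] + sum(cnt^2)
      }
      done <- done + k
    }
    list(mean = s1 / n_reps, sd = sqrt(pmax(0, (s2 - s1^2 / n_reps) / (n_reps - 1))))
  }
  res <- if (is.null(rng_seed)) run() else with_local_seed(rng_seed, run())
  expected <- expected_by_chance(N, xs, p_match)
  tibble(
    x = xs, expected = expected, sd = res$sd,
    ci_low = expected - ci_sd_mult * res$sd,
    ci_high = expected + ci_sd_mult * res$sd
  )
}

#' Observed vs chance microhomology distribution
#'
#' Tabulates observed microhomology lengths at join junctions and attaches
#' the geometric chance expectation with resampling confidence bands.
#'
#' @param mh_values Integer vector of per-junction microhomology lengths, or
#'   a junction-call tibble with columns `category` and `mh_max` (join calls
#'   are used).
#' @param x_max Largest length tabulated (default: max observed).
#' @param n_reps,p_match,ci_sd_mult,rng_seed Passed to [resample_ci()].
#' @return A tibble of class `mh_distribution`: `x`, `observed`, `expected`,
#'   `sd`, `ci_low`, `ci_high`; attribute `N` = total junctions.
#' @export
microhomology_distribution <- function(mh_values, x_max = NULL, n_reps = 1e5,
                                       p_match = 0.25, ci_sd_mult = 2,
                                       rng_seed = NULL) {
  if (is.data.frame(mh_values)) {
    mh_values <- mh_values$mh_max[mh_values$category == "join"]
  }
  mh_values <- as.integer(mh_values)
  N <- length(mh_values)
  x_max <- as.integer(x_max %||% max(c(0L, mh_values)))
  observed <- vapply(0:x_max, function(x) sum(mh_values == x), integer(1))
  if (N >= 1) {
    bands <- resample_ci(N, x_max, n_reps = n_reps, p_match = p_match,
                         ci_sd_mult = ci_sd_mult, rng_seed = rng_seed)
  } else {
    bands <- tibble(x = 0:x_max, expected = 0, sd = 0, ci_low = 0, ci_high = 0)
  }
  out <- tibble(x = 0:x_max, observed = observed) |> left_join(bands, by = "x")
  class(out) <- c("mh_distribution", class(out))
  attr(out, "N") <- N
  out
}

#' Join-position frequency table
#'
#' Counts join-category 5' junction calls per rDNA position of fusion,
#' relative to the first-strand nick (coordinate 0), split into full-length
#' and truncated insertions. Junctions with microhomology have an ambiguous
#' position; `assignment` selects the convention: `"no_mh_only"` restricts to
#' junctions with no detected microhomology (unambiguous positions),
#' `"max_rdna"` assigns all potential microhomology to the rDNA, and
#' `"max_transgene"` assigns it to the transgene.
#'
#' @param calls Junction-call tibble (see [call_junctions()]).
#' @param assignment One of `"no_mh_only"`, `"max_rdna"`, `"max_transgene"`.
#' @return A tibble `coord`, `count_full`, `count_trunc`, `count_total`,
#'   sorted by coordinate.
#' @export
join_position_table <- function(calls,
                                assignment = c("no_mh_only", "max_rdna", "max_transgene")) {
  assignment <- match.arg(assignment)
  joins <- calls[calls$side == "five_prime" & calls$category == "join", , drop = FALSE]
  if (assignment == "no_mh_only") {
    joins <- joins[joins$mh_max == 0L, , drop = FALSE]
    joins$coord <- joins$rdna_coord_max_rdna
  } else if (assignment == "max_rdna") {
    joins$coord <- joins$rdna_coord_max_rdna
  } else {
    joins$coord <- joins$rdna_coord_max_transgene
  }
  if (nrow(joins) == 0L) {
    return(tibble(coord = integer(), count_full = integer(),
                  count_trunc = integer(), count_total = integer()))
  }
  joins |>
    group_by(coord) |>
    summarise(
      count_full = sum(supporting_reads[full_length]),
      count_trunc = sum(supporting_reads[!full_length]),
      .groups = "drop"
    ) |>
    mutate(count_total = count_full + count_trunc) |>
    arrange(coord)
}

# run code under a temporary RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
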