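#' Copy number from digital-PCR concentrations
#'
#' Converts a target amplicon concentration to copies per cell using a
#' reference gene of known copy number (default 3, the RPP30 copy number in
#' the assayed cell line).
#'
#' @param target_conc Target concentration (vectorised, >= 0).
#' @param reference_conc Reference-gene concentration (> 0).
#' @param reference_copy Reference copies per cell (default 3).
#' @return Numeric vector of copies per cell.
#' @examples
#' copy_number(2, 1, reference_copy = 3)  # 6
#' @export
copy_number <- function(target_conc, reference_conc, reference_copy = 3) {
  if (any(reference_conc <= 0)) abort("reference_conc must be > 0")
  if (any(target_conc < 0)) abort("target_conc must be >= 0")
  (target_conc / reference_conc) * reference_copy
}

#' ddPCR-style copy-number panel
#'
#' Holds the three concentrations needed for the productive-insertion
#' percentage: the transgene 5' promoter amplicon, the transgene 3' module
#' amplicon, and the reference gene. The promoter probe detects a fixed
#' background copy number in untransfected cells (default 1, subtracted
#' with a floor at 0).
#'
#' @param promoter_conc,module3_conc,reference_conc Non-negative
#'   concentrations (reference > 0).
#' @param reference_copy Reference-gene copies per cell (default 3).
#' @param promoter_background Background promoter copies subtracted
#'   (default 1).
#' @return A list of class `copy_number_panel` with derived
#'   `promoter_copies` (background-subtracted) and `module3_copies`.
#' @export
copy_number_panel <- function(promoter_conc, module3_conc, reference_conc,
                              reference_copy = 3, promoter_background = 1) {
  if (reference_conc <= 0) abort("reference_conc must be > 0")
  if (promoter_conc < 0 || module3_conc < 0) abort("concentrations must be >= 0")
  raw_prom <- copy_number(promoter_conc, reference_conc, reference_copy)
  structure(list(
    promoter_conc = promoter_conc, module3_conc = module3_conc,
    reference_conc = reference_conc, reference_copy = reference_copy,
    promoter_background = promoter_background,
    promoter_copies = max(0, raw_prom - promoter_background),
    module3_copies = copy_number(module3_conc, reference_conc, reference_copy)
  ), class = "copy_number_panel")
}

#' Productive-insertion percentage (PI%)
#'
#' The fraction of insertions carrying the transgene 5' end, measured as the
#' ratio of background-subtracted 5'-promoter copy number to 3'-module copy
#' number: `PI% = 100 * max(0, promoter_copies - background) /
#' module3_copies`.
#'
#' @param panel A [copy_number_panel()].
#' @return PI% as a number in \[0, 100+\].
#' @examples
#' pi_percent(copy_number_panel(2, 4, 3))  # promoter net 1 of module3 4 -> 25
#' @export
pi_percent <- function(panel) {
  if (!inherits(panel, "copy_number_panel")) abort("panel must be a copy_number_panel")
  if (panel$module3_copies == 0) abort("3' module copy number is 0; PI% undefined")
  100 * panel$promoter_copies / panel$module3_copies
}

#' Summarise junction calls into a report bundle
#'
#' Produces the standard summary tables: 5' category by full-length status,
#' truncation-offset histogram, microhomology distribution with chance
#' bands, join-position tables under the three microhomology assignments,
#' and the 3' on-target fraction.
#'
#' @param calls Junction-call tibble from [call_junctions()].
#' @param mh_n_reps Resampling repetitions for the chance bands.
#' @param rng_seed Seed for the resampling bands.
#' @return An object of class `junction_report`: a list of tibbles
#'   (`categories`, `truncations`, `mh`, `join_positions`, `inserts`,
#'   `three_prime`) plus totals.
#' @export
summarize_junctions <- function(calls, mh_n_reps = 1e4, rng_seed = 1L) {
  five <- calls[calls$side == "five_prime", , drop = FALSE]
  three <- calls[calls$side == "three_prime", , drop = FALSE]
  categories <- five |>
    group_by(category, full_length) |>
    summarise(n_calls = n(), supporting_reads = sum(supporting_reads),
              .groups = "drop")
  truncations <- five |>
    filter(!full_length) |>
    group_by(category, truncation_offset) |>
    summarise(n_calls = n(), supporting_reads = sum(supporting_reads),
              .groups = "drop")
  mh_values <- rep(five$mh_max[five$category == "join" & !is.na(five$mh_max)],
                   five$supporting_reads[five$category == "join" & !is.na(five$mh_max)])
  mh <- microhomology_distribution(mh_values, n_reps = mh_n_reps,
                                   rng_seed = rng_seed)
  join_positions <- list(
    no_mh_only = join_position_table(calls, "no_mh_only"),
    max_rdna = join_position_table(calls, "max_rdna"),
    max_transgene = join_position_table(calls, "max_transgene")
  )
  three_tab <- three |>
    group_by(category) |>
    summarise(n_calls = n(), supporting_reads = sum(supporting_reads),
              .groups = "drop")
  on_target_frac <- if (sum(three_tab$supporting_reads) > 0) {
    sum(three_tab$supporting_reads[three_tab$category == "on_target"]) /
      sum(three_tab$supporting_reads)
  } else NA_real_
  structure(list(
    categories = categories, truncations = truncations, mh = mh,
    join_positions = join_positions, inserts = catalog_inserts(calls),
    three_prime = three_tab,
    totals = list(
      five_prime_calls = nrow(five), three_prime_calls = nrow(three),
      five_prime_reads = sum(five$supporting_reads),
      three_prime_reads = sum(three$supporting_reads),
      on_target_fraction = on_target_frac
    )
  ), class = "junction_report")
}

#' @export
print.junction_report <- function(x, ...) {
  cat("<junction_report>\n")
  cat("  5' calls:", x$totals$five_prime_calls,
      "(", x$totals$five_prime_reads, "reads );",
      "3' calls:", x$totals$three_prime_calls,
      "(", x$totals$three_prime_reads, "reads )\n")
  if (!is.na(x$totals$on_target_fraction)) {
    cat(sprintf("  3' on-target fraction: %.3f\n", x$totals$on_target_fraction))
  }
  cat("  5' categories:\n")
  print(x$categories, n = 20)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a microhomology distribution
#'
#' @param x An `mh_distribution` (from [microhomology_distribution()]).
#' @param ... Unused.
#' @return A plain tibble of the distribution rows.
#' @export
tidy.mh_distribution <- function(x, ...) {
  out <- as_tibble(unclass(x)[names(x)])
  out
}

#' One-row summary of a junction report
#'
#' @param x A `junction_report`.
#' @param ... Unused.
#' @return A one-row tibble of totals and headline fractions.
#' @export
glance.junction_report <- function(x, ...) {
  five_reads <- sum(x$categories$supporting_reads)
  join_reads <- sum(x$categories$supporting_reads[x$categories$category == "join"])
  anneal_reads <- sum(x$categories$supporting_reads[x$categories$category == "anneal"])
  tibble(
    five_prime_calls = x$totals$five_prime_calls,
    three_prime_calls = x$totals$three_prime_calls,
    on_target_fraction = x$totals$on_target_fraction,
    anneal_read_fraction = if (five_reads > 0) anneal_reads / five_reads else NA_real_,
    join_read_fraction = if (five_reads > 0) join_reads / five_reads else NA_real_,
    mh_junctions = attr(x$mh, "N")
  )
}

#' Plot a microhomology distribution against the chance model
#'
#' Observed counts as bars; expected-by-chance with +/-2 SD resampling bands
#' as points and error bars.
#'
#' @param object An `mh_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mh_distribution <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.25) +
    ggplot2::labs(x = "Microhomology (bp)", y = "Junctions",
                  title = "Observed vs chance microhomology") +
    ggplot2::theme_minimal()
}

#' Plot join positions relative to the first-strand nick
#'
#' @param report A `junction_report`.
#' @param assignment Which assignment table to plot (default `no_mh_only`).
#' @return A ggplot object.
#' @export
plot_join_positions <- function(report, assignment = "no_mh_only") {
  df <- report$join_positions[[assignment]] |>
    tidyr::pivot_longer(c("count_full", "count_trunc"),
                        names_to = "status", values_to = "count") |>
    mutate(status = ifelse(.data$status == "count_full", "full-length", "truncated"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coord, y = .data$count,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("full-length" = "black",
                                          "truncated" = "grey60")) +
    ggplot2::labs(x = "Join position relative to first-strand nick (nt)",
                  y = "Supporting reads", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Write a junction report as JSON + TSV files
#'
#' @param report A `junction_report`.
#' @param dir Output directory (created if needed).
#' @param run_info Optional named list recorded verbatim in the JSON (seeds,
#'   parameters, versions).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, run_info = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(report$categories, "categories.tsv")
  w(report$truncations, "truncations.tsv")
  w(tidy(report$mh), "mh.tsv")
  w(report$join_positions$no_mh_only, "joinpos_no_mh.tsv")
  w(report$join_positions$max_rdna, "joinpos_max_rdna.tsv")
  w(report$join_positions$max_transgene, "joinpos_max_transgene.tsv")
  w(report$inserts, "inserts.tsv")
  js <- list(totals = report$totals, run_info = run_info)
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full junction-analysis pipeline
#'
#' Orchestrates read hygiene, the alignment cascade, junction calling and
#' summary statistics on a read-pair table. Deterministic given the inputs
#' and `rng_seed` (used only for the resampling bands).
#'
#' @param pairs Read-pair tibble (`read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @param refs A [mapping_references()].
#' @param filter_params A [read_filter_params()].
#' @param cascade_params A [cascade_params()].
#' @param min_anchor,max_insert_gap,min_support Passed to
#'   [call_junctions()].
#' @param mh_n_reps Resampling repetitions for chance bands.
#' @param rng_seed Seed for the resampling bands.
#' @return A list: `prep` (read hygiene log), `cascade` (pair status + log),
#'   `calls`, `evidence`, `report`.
#' @export
run_insertion_pipeline <- function(pairs, refs,
                                   filter_params = read_filter_params(),
                                   cascade_params = printmap::cascade_params(),
                                   min_anchor = 10L, max_insert_gap = 15L,
                                   min_support = 1L, mh_n_reps = 1e4,
                                   rng_seed = 1L) {
  prep <- prep_reads(pairs, filter_params)
  casc <- run_cascade(prep$pairs, refs, cascade_params)
  jc <- call_junctions(casc$segments, refs, prep$pairs,
                       min_anchor = min_anchor,
                       max_insert_gap = max_insert_gap,
                       min_support = min_support)
  report <- summarize_junctions(jc$calls, mh_n_reps = mh_n_reps,
                                rng_seed = rng_seed)
  list(prep = prep$log, cascade = list(pair_status = casc$pair_status,
                                       log = casc$log),
       calls = jc$calls, evidence = jc$evidence, report = report)
}
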