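#' Per-site percent methylation from a cytosine report
#'
#' `percent = 100 * methylated / (methylated + unmethylated)`; sites below
#' the coverage floor are excluded. Plus- and minus-strand calls are kept
#' as separate sites by default, matching the strand-resolved report;
#' `collapse_dyads = TRUE` sums the counts of each CpG dyad (plus-strand C
#' at p with minus-strand C at p+1) into a single plus-strand site.
#'
#' @param records Cytosine-record tibble from [read_cytosine_report()].
#' @param min_coverage Minimum total reads per site (default 1).
#' @param collapse_dyads Merge complementary CpG calls (default `FALSE`).
#' @return Tibble: `seq_id`, `position`, `strand`, `trinucleotide`,
#'   `context_class`, `count_methylated`, `count_unmethylated`,
#'   `coverage`, `percent`.
#' @export
site_methylation <- function(records, min_coverage = 1, collapse_dyads = FALSE) {
  rec <- records
  if (collapse_dyads && nrow(rec) > 0) {
    cpg <- filter(rec, .data$context_class == "CpG")
    other <- filter(rec, .data$context_class != "CpG")
    cpg <- cpg |>
      mutate(dyad_pos = ifelse(.data$strand == "-",
                               .data$position - 1L, .data$position)) |>
      group_by(.data$seq_id, .data$dyad_pos) |>
      summarise(
        position = min(.data$dyad_pos),
        strand = "+",
        count_methylated = sum(.data$count_methylated),
        count_unmethylated = sum(.data$count_unmethylated),
        context_class = "CpG",
        trinucleotide = .data$trinucleotide[.data$strand == "+"][1] %||%
          .data$trinucleotide[1],
        .groups = "drop"
      ) |>
      select(-all_of("dyad_pos"))
    rec <- bind_rows(cpg, other)
  }
  rec |>
    mutate(coverage = .data$count_methylated + .data$count_unmethylated) |>
    filter(.data$coverage >= min_coverage) |>
    mutate(percent = 100 * .data$count_methylated / .data$coverage) |>
    select(all_of(c("seq_id", "position", "strand", "trinucleotide",
                    "context_class", "count_methylated", "count_unmethylated",
                    "coverage", "percent"))) |>
    arrange(.data$seq_id, .data$position, .data$strand)
}

#' Trinucleotide-context methylation summaries
#'
#' Summarizes CpG-context sites by the trinucleotide starting at the
#' cytosine (CGA, CGC, CGG, CGT): per-context site-level percent
#' distributions and medians, plus the cross-context rank test
#' (Kruskal-Wallis with Dunn's post hoc via [group_compare()]) that asks
#' whether methylation shows a context preference. Contexts with fewer
#' than two qualifying sites are summarized but excluded from the test.
#'
#' @param records Cytosine-record tibble (CpG rows are selected
#'   internally).
#' @param contexts Contexts to summarize.
#' @param min_coverage Coverage floor per site.
#' @return A list of class `erv_context_meth`: `summary` (tibble with
#'   `context`, `n_sites`, `median_percent`, `mean_percent`), `sites`
#'   (per-site tibble) and `test` (`erv_group_test` or `NULL` when fewer
#'   than two contexts qualify).
#' @export
context_methylation <- function(records,
                                contexts = c("CGA", "CGC", "CGG", "CGT"),
                                min_coverage = 1) {
  sites <- site_methylation(records, min_coverage = min_coverage) |>
    filter(.data$context_class == "CpG", .data$trinucleotide %in% contexts)
  summary <- purrr::map_dfr(contexts, function(ctx) {
    v <- sites$percent[sites$trinucleotide == ctx]
    tibble(context = ctx, n_sites = length(v),
           median_percent = if (length(v)) median(v) else NA_real_,
           mean_percent = if (length(v)) mean(v) else NA_real_)
  })
  testable <- summary$context[summary$n_sites >= 2]
  test <- NULL
  if (length(testable) >= 2) {
    test <- group_compare(
      filter(sites, .data$trinucleotide %in% testable),
      value = "percent", group = "trinucleotide"
    )
  }
  structure(list(summary = summary, sites = sites, test = test),
            class = "erv_context_meth")
}

#' @export
print.erv_context_meth <- function(x, ...) {
  cat("<erv_context_meth>\n")
  print(x$summary)
  if (!is.null(x$test)) print(x$test)
  invisible(x)
}

#' @export
tidy.erv_context_meth <- function(x, ...) x$summary

#' Binned methylation track across a provirus
#'
#' Coverage-weighted mean percent methylation per bin tiling `[0, L)`,
#' plus the overall per-site median (the quantity plotted against CpG O/E
#' when asking whether heavily methylated proviruses are also
#' CpG-depleted). Bins without qualifying sites are flagged `no_data`.
#'
#' @param records Cytosine-record tibble for one sequence.
#' @param seq_length Sequence length in bp.
#' @param bin_size Bin width in bp (default 100).
#' @param min_coverage Coverage floor per site.
#' @param context Restrict to one context class (default `"CpG"`; `NULL`
#'   keeps all).
#' @return A list of class `erv_meth_track`: `track` tibble (`bin_start`,
#'   `bin_end`, `n_sites`, `coverage`, `mean_percent`, `no_data`) and
#'   `median_percent` over qualifying sites.
#' @export
provirus_track <- function(records, seq_length, bin_size = 100,
                           min_coverage = 1, context = "CpG") {
  if (bin_size <= 0) abort("bin_size must be positive")
  sites <- site_methylation(records, min_coverage = min_coverage)
  if (!is.null(context)) sites <- filter(sites, .data$context_class == context)
  starts <- seq(0L, max(0L, seq_length - 1L), by = bin_size)
  bins <- tibble(bin_start = starts,
                 bin_end = pmin(starts + bin_size, seq_length))
  sites$bin_start <- (sites$position - 1L) %/% bin_size * bin_size
  agg <- sites |>
    group_by(.data$bin_start) |>
    summarise(
      n_sites = dplyr::n(),
      coverage = sum(.data$coverage),
      mean_percent = 100 * sum(.data$count_methylated) / sum(.data$coverage),
      .groups = "drop"
    )
  track <- bins |>
    left_join(agg, by = "bin_start") |>
    mutate(
      n_sites = ifelse(is.na(.data$n_sites), 0L, .data$n_sites),
      coverage = ifelse(is.na(.data$coverage), 0L, .data$coverage),
      no_data = .data$n_sites == 0L
    )
  structure(
    list(track = track, median_percent = median(sites$percent),
         seq_id = if (nrow(sites)) sites$seq_id[1] else NA_character_,
         bin_size = bin_size),
    class = "erv_meth_track"
  )
}

#' @export
print.erv_meth_track <- function(x, ...) {
  cat(sprintf("<erv_meth_track> %s: %d bins of %d bp, overall median %.1f%%\n",
              x$seq_id, nrow(x$track), x$bin_size, x$median_percent))
  invisible(x)
}

#' @export
tidy.erv_meth_track <- function(x, ...) x$track

#' @export
glance.erv_meth_track <- function(x, ...) {
  tibble(seq_id = x$seq_id, n_bins = nrow(x$track),
         bin_size = x$bin_size, median_percent = x$median_percent)
}
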