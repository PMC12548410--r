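#' Write intervals as BED6
#'
#' Intervals are 0-based half-open, matching the package's internal
#' coordinate convention. The strand column is written as `"."`.
#'
#' @param intervals Tibble/data frame with columns `seq_id`, `start`, `end`,
#'   `name`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("seq_id", "start", "end", "name", "score")
  stopifnot(all(cols %in% names(intervals)))
  if (nrow(intervals) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (any(intervals$start >= intervals$end)) {
    abort("BED intervals must satisfy start < end (0-based half-open)")
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.",
                   intervals$seq_id, as.integer(intervals$start),
                   as.integer(intervals$end), intervals$name,
                   format(intervals$score, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}
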