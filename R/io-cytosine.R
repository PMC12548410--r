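#' Read a Bismark-style genome-wide cytosine report
#'
#' Parses the 7-column tab-separated cytosine report dialect:
#' `seq_id`, `position` (1-based), `strand` (+/-), `count_methylated`,
#' `count_unmethylated`, `context_class` (CpG/CHG/CHH), `trinucleotide`
#' (the 3-mer on the cytosine's own strand, starting at the cytosine).
#'
#' Rows violating the record invariants (trinucleotide not starting with C,
#' CpG context without a G in second position, negative counts, unknown
#' strand or context token) are rejected with their line numbers.
#'
#' @param path Path to the report.
#' @return A tibble with one row per cytosine; empty (with a warning) for an
#'   empty file.
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) abort(paste0("cytosine report not found: ", path))
  empty <- tibble(
    seq_id = character(), position = integer(), strand = character(),
    count_methylated = integer(), count_unmethylated = integer(),
    context_class = character(), trinucleotide = character()
  )
  lines <- readLines(path)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0) {
    warn(paste0("cytosine report is empty: ", path))
    return(empty)
  }

  fields <- strsplit(lines[lines_keep], "\t", fixed = TRUE)
  bad_shape <- lines_keep[lengths(fields) != 7L]
  if (length(bad_shape) > 0) {
    abort(paste0("malformed cytosine-report row (expected 7 tab-separated fields) at line(s): ",
                 paste(head(bad_shape, 5), collapse = ", ")))
  }
  m <- matrix(unlist(fields), ncol = 7, byrow = TRUE)
  rec <- tibble(
    seq_id = m[, 1],
    position = suppressWarnings(as.integer(m[, 2])),
    strand = m[, 3],
    count_methylated = suppressWarnings(as.integer(m[, 4])),
    count_unmethylated = suppressWarnings(as.integer(m[, 5])),
    context_class = m[, 6],
    trinucleotide = toupper(m[, 7])
  )

  check <- function(ok, what) {
    if (any(!ok)) {
      abort(paste0(what, " at line(s): ",
                   paste(head(lines_keep[!ok], 5), collapse = ", ")))
    }
  }
  check(!is.na(rec$position) & rec$position >= 1L, "invalid position")
  check(rec$strand %in% c("+", "-"), "invalid strand")
  check(!is.na(rec$count_methylated) & rec$count_methylated >= 0L,
        "invalid methylated count")
  check(!is.na(rec$count_unmethylated) & rec$count_unmethylated >= 0L,
        "invalid unmethylated count")
  check(rec$context_class %in% c("CpG", "CHG", "CHH"), "unknown context token")
  check(substr(rec$trinucleotide, 1, 1) == "C",
        "trinucleotide must start with C")
  check(rec$context_class != "CpG" | substr(rec$trinucleotide, 2, 2) == "G",
        "CpG context requires G at trinucleotide position 2")
  rec
}

#' Write a cytosine report
#'
#' Inverse of [read_cytosine_report()]; 1-based positions, 7 tab-separated
#' columns, no header.
#'
#' @param records Cytosine-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  cols <- c("seq_id", "position", "strand", "count_methylated",
            "count_unmethylated", "context_class", "trinucleotide")
  stopifnot(all(cols %in% names(records)))
  readr::write_tsv(records[, cols], path, col_names = FALSE)
  invisible(path)
}
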