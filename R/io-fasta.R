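#' Read proviral or genomic sequences from FASTA
#'
#' Reads a FASTA file into a tidy sequence table. Residues are uppercased,
#' `U` is mapped to `T`, and any other symbol outside `A/C/G/T` becomes `N`
#' (ambiguous bases are excluded from all downstream k-mer statistics).
#' Group labels are taken from an optional `key=value` convention on the
#' header line (`virus=...` and `class=...`), or from a tab-separated
#' manifest with columns `id`, `virus`, `class`.
#'
#' @param path Path to a FASTA file.
#' @param manifest Optional path to a TSV manifest (`id`, `virus`, `class`)
#'   overriding header-derived labels.
#' @return A tibble with columns `id`, `virus`, `variant_class`
#'   (`"endogenous"`, `"exogenous"` or `"unknown"`), `length` and `seq`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 virus=FeLV class=endogenous", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, manifest = NULL) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) abort(paste0("FASTA file is empty: ", path))

  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  if (any(ids == "")) abort("FASTA header with empty id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate sequence id(s) in FASTA: ", paste(dup, collapse = ", ")))
  }

  residues <- unname(normalize_residues(as.character(raw)))
  virus <- vapply(headers, header_field, character(1), field = "virus", USE.NAMES = FALSE)
  klass <- vapply(headers, header_field, character(1), field = "class", USE.NAMES = FALSE)

  out <- tibble(
    id = ids,
    virus = ifelse(is.na(virus), "unknown", virus),
    variant_class = normalize_class(klass),
    length = nchar(residues),
    seq = residues
  )

  if (!is.null(manifest)) {
    man <- readr::read_tsv(manifest, col_types = readr::cols(.default = "c"))
    need <- c("id", "virus", "class")
    if (!all(need %in% names(man))) {
      abort("manifest must have columns id, virus, class")
    }
    out <- out |>
      left_join(man, by = "id", suffix = c("", ".man")) |>
      mutate(
        virus = dplyr::coalesce(.data$virus.man, .data$virus),
        variant_class = ifelse(is.na(.data$class), .data$variant_class,
                               normalize_class(.data$class))
      ) |>
      select(all_of(c("id", "virus", "variant_class", "length", "seq")))
  }
  out
}

# Uppercase, U->T, anything outside ACGT -> N.
normalize_residues <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("[^ACGT]", "N", x)
}

normalize_class <- function(x) {
  x <- tolower(x)
  out <- ifelse(x %in% c("endogenous", "exogenous"), x, "unknown")
  out[is.na(x)] <- "unknown"
  out
}

header_field <- function(header, field) {
  m <- regmatches(header, regexpr(paste0("\\b", field, "=\\S+"), header))
  if (length(m) == 0) return(NA_character_)
  sub(paste0("^", field, "="), "", m)
}

#' Write a sequence table to FASTA
#'
#' Inverse of [read_fasta()]: group labels are written back as
#' `virus=`/`class=` header fields so a round trip preserves them.
#'
#' @param seqs Sequence tibble as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  virus <- if ("virus" %in% names(seqs)) seqs$virus else rep("unknown", nrow(seqs))
  klass <- if ("variant_class" %in% names(seqs)) seqs$variant_class else rep("unknown", nrow(seqs))
  lines <- unlist(purrr::pmap(
    list(seqs$id, virus, klass, seqs$seq),
    function(id, v, k, s) c(paste0(">", id, " virus=", v, " class=", k), s)
  ))
  writeLines(lines, path)
  invisible(path)
}
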