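#' Read motifs in MEME minimal format
#'
#' Parses the MEME minimal motif dialect: a `MEME version` line, optional
#' `ALPHABET` and `Background letter frequencies` sections, then one
#' `MOTIF <name>` block per motif, each with a
#' `letter-probability matrix:` header and `w` rows of 4 probabilities
#' (A, C, G, T order). A missing background defaults to uniform 0.25.
#'
#' A motif name of the form `H3K27ac_1` (or containing a recognizable
#' histone-mark token) sets the `source_mark` field used by
#' [cgi_overlap_filter()].
#'
#' @param path Path to a MEME minimal motif file.
#' @return A list of motif objects; each is a list with `name`, `width`,
#'   `probability_matrix` (width x 4, columns A/C/G/T), `background`
#'   (length 4) and `source_mark` (histone-mark label or `NA`).
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) abort(paste0("motif file not found: ", path))
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) {
    abort("not a MEME minimal motif file (missing 'MEME version' line)")
  }

  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) == 1 && bg_i < length(lines)) {
    toks <- strsplit(trimws(lines[bg_i + 1]), "\\s+")[[1]]
    if (length(toks) >= 8) {
      vals <- as.numeric(toks[seq(2, 8, by = 2)])
      names(vals) <- toks[seq(1, 7, by = 2)]
      background <- vals[DNA_LETTERS]
      if (abs(sum(background) - 1) > 1e-6) {
        abort("background frequencies do not sum to 1")
      }
    }
  }

  motif_i <- grep("^MOTIF\\b", lines)
  if (length(motif_i) == 0) abort("no MOTIF blocks found")
  purrr::map(motif_i, function(i) {
    name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    hdr_rel <- grep("^letter-probability matrix", lines[(i + 1):length(lines)])[1]
    if (is.na(hdr_rel)) abort(paste0("motif ", name, ": missing letter-probability matrix"))
    hdr <- i + hdr_rel
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[hdr]))
    if (is.na(w) || w < 2) abort(paste0("motif ", name, ": invalid or missing width (need w >= 2)"))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                    numeric(4), USE.NAMES = FALSE))
    colnames(mat) <- DNA_LETTERS
    bad <- which(abs(rowSums(mat) - 1) > 1e-3)
    if (length(bad) > 0) {
      abort(paste0("motif ", name, ": probability row(s) ",
                   paste(bad, collapse = ", "), " do not sum to 1"))
    }
    list(
      name = name,
      width = w,
      probability_matrix = mat,
      background = unname(background),
      source_mark = extract_mark(name)
    )
  })
}

# Pull a histone-mark token like H3K27ac / H3K4me3 out of a motif name.
extract_mark <- function(name) {
  m <- regmatches(name, regexpr("H[0-9]+K[0-9]+(me[0-9]+|ac)", name))
  if (length(m) == 0) NA_character_ else m
}

#' Write motifs in MEME minimal format
#'
#' @param motifs List of motif objects as returned by [read_meme_motifs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path) {
  bg <- motifs[[1]]$background
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", DNA_LETTERS, bg), collapse = " "), ""
  )
  for (m in motifs) {
    lines <- c(lines,
      paste0("MOTIF ", m$name),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", m$width),
      apply(m$probability_matrix, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build a motif object from a consensus string
#'
#' Convenience constructor for tests and simulations: each column puts
#' `weight` on the consensus base and splits the remainder evenly.
#'
#' @param name Motif name (a histone-mark token in the name sets
#'   `source_mark`).
#' @param consensus Consensus string over A/C/G/T.
#' @param weight Probability mass on the consensus base per column.
#' @param background Length-4 background distribution (A/C/G/T).
#' @return A motif object.
#' @export
consensus_motif <- function(name, consensus, weight = 0.97,
                            background = rep(0.25, 4)) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% DNA_LETTERS), length(bases) >= 2)
  mat <- matrix((1 - weight) / 3, nrow = length(bases), ncol = 4,
                dimnames = list(NULL, DNA_LETTERS))
  for (i in seq_along(bases)) mat[i, bases[i]] <- weight
  list(name = name, width = length(bases), probability_matrix = mat,
       background = background, source_mark = extract_mark(name))
}

#' Consensus string of a motif
#'
#' @param motif A motif object.
#' @return The per-column argmax base string.
#' @export
motif_consensus <- function(motif) {
  paste(DNA_LETTERS[apply(motif$probability_matrix, 1, which.max)], collapse = "")
}
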