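#' k-mer spectrum of a sequence
#'
#' Counts all length-k windows (k = 1, 2, 3) over the unambiguous alphabet.
#' Counting is linear (non-circular) and strand-specific: no
#' reverse-complement folding is ever applied, because the deamination
#' analysis relies on distinguishing TpG from CpA. Windows containing `N`
#' are skipped and do not enter the window denominators.
#'
#' @param seq A sequence string over `A/C/G/T/N`.
#' @param k Integer vector of k values to populate (subset of 1:3).
#' @return An object of class `kmer_spectrum`: per-k named count vectors and
#'   valid-window totals.
#' @export
kmer_spectrum <- function(seq, k = 1:3) {
  stopifnot(is.character(seq), length(seq) == 1)
  k <- as.integer(k)
  if (!all(k %in% 1:3)) abort("k must be within 1:3")
  L <- nchar(seq)
  if (any(k > L)) abort("k exceeds sequence length")
  dna <- Biostrings::DNAString(seq)
  counts <- lapply(setNames(k, k), function(kk) {
    Biostrings::oligonucleotideFrequency(dna, width = kk)
  })
  structure(
    list(counts = counts, valid = vapply(counts, sum, numeric(1))),
    class = "kmer_spectrum"
  )
}

#' Count k-mers in a sequence
#'
#' Tidy view of one k of [kmer_spectrum()]: observed k-mers with their
#' counts; the number of valid (N-free) windows rides along as the
#' `valid_windows` attribute and in every row.
#'
#' @param seq Sequence string.
#' @param k Window length (1, 2 or 3).
#' @param drop_zero Drop unobserved k-mers (default `TRUE`).
#' @return Tibble with columns `kmer`, `count`, `valid_windows`.
#' @examples
#' count_kmers("ACGNCG", 2) # N-containing windows are skipped
#' @export
count_kmers <- function(seq, k, drop_zero = TRUE) {
  sp <- kmer_spectrum(seq, k = k)
  cnt <- sp$counts[[as.character(k)]]
  out <- tibble(kmer = names(cnt), count = as.integer(cnt),
                valid_windows = as.integer(sp$valid[[as.character(k)]]))
  if (drop_zero) out <- filter(out, .data$count > 0)
  attr(out, "valid_windows") <- sp$valid[[as.character(k)]]
  out
}

# Observed frequency of a k-mer from a spectrum: count / valid windows of
# its own k (per-k denominators, exact on short sequences).
obs_freq <- function(spectrum, motif) {
  k <- as.character(nchar(motif))
  if (is.null(spectrum$counts[[k]])) abort(paste0("spectrum lacks k=", k))
  v <- spectrum$valid[[k]]
  if (v == 0) return(NA_real_)
  unname(spectrum$counts[[k]][motif] / v)
}

#' Expected k-mer frequency under the background model
#'
#' For a trinucleotide `XYZ` the expectation follows the first-order Markov
#' model of conditional probabilities,
#' `P_exp(XYZ) = P_obs(XY) * P_obs(YZ) / P_obs(Y)`.
#' For a dinucleotide `XY` the classical zeroth-order product
#' `P_obs(X) * P_obs(Y)` is used: under a first-order background a
#' dinucleotide O/E would be identically 1, so the product form — the
#' standard CpG O/E definition — is the informative choice.
#'
#' @param spectrum A `kmer_spectrum` covering the needed k values.
#' @param motif A 2- or 3-mer over `A/C/G/T`.
#' @return The expected frequency, or `NA` when undefined (zero
#'   middle-base frequency for a trinucleotide).
#' @export
expected_frequency <- function(spectrum, motif) {
  motif <- toupper(motif)
  w <- nchar(motif)
  if (!w %in% 2:3 || grepl("[^ACGT]", motif)) {
    abort("motif must be a 2- or 3-mer over A/C/G/T")
  }
  if (w == 2) {
    p1 <- obs_freq(spectrum, substr(motif, 1, 1))
    p2 <- obs_freq(spectrum, substr(motif, 2, 2))
    return(p1 * p2)
  }
  pxy <- obs_freq(spectrum, substr(motif, 1, 2))
  pyz <- obs_freq(spectrum, substr(motif, 2, 3))
  py <- obs_freq(spectrum, substr(motif, 2, 2))
  if (is.na(py) || py == 0) return(NA_real_)
  pxy * pyz / py
}

#' D-ratio (observed/expected) of a motif in one sequence
#'
#' The core statistic: `D = P_obs / P_exp`, with `P_obs` the motif's
#' frequency over valid windows and `P_exp` from [expected_frequency()].
#' A `D` below 1 indicates depletion (for CpG, the footprint of
#' methylation-driven deamination); above 1, enrichment.
#'
#' @param seq Sequence string (or a one-row sequence tibble).
#' @param motif A 2- or 3-mer.
#' @return One-row tibble: `motif`, `p_obs`, `p_exp`, `d_ratio`,
#'   `undefined`. When `p_exp` is 0 or undefined the `undefined` flag is
#'   set and `d_ratio` is `NA` rather than a silent 0 or Inf.
#' @examples
#' d_ratio("CGTCGT", "CGT")
#' @export
d_ratio <- function(seq, motif) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1)
    seq <- seq$seq
  }
  motif <- toupper(motif)
  sp <- kmer_spectrum(seq, k = unique(c(1:2, nchar(motif))))
  p_obs <- obs_freq(sp, motif)
  p_exp <- expected_frequency(sp, motif)
  undefined <- is.na(p_obs) || is.na(p_exp) || p_exp == 0
  tibble(
    motif = motif,
    p_obs = p_obs,
    p_exp = p_exp,
    d_ratio = if (undefined) NA_real_ else p_obs / p_exp,
    undefined = undefined
  )
}

#' D-ratio table over sequence sets and motifs
#'
#' One row per sequence x motif, carrying the group labels so medians by
#' virus and variant class are a `group_by()` away. Undefined entries are
#' carried with their flag, never dropped.
#'
#' @param seqs Sequence tibble from [read_fasta()] (columns `id`, `virus`,
#'   `variant_class`, `seq`).
#' @param motifs Character vector of 2-/3-mers, e.g.
#'   `c("CG", "TG", "CA", "CGA", "CGC", "CGG", "CGT")`.
#' @return Tibble: `seq_id`, `virus`, `variant_class`, `motif`, `p_obs`,
#'   `p_exp`, `d_ratio`, `undefined`.
#' @export
d_ratio_table <- function(seqs, motifs) {
  stopifnot(nrow(seqs) > 0, length(motifs) > 0)
  motifs <- toupper(motifs)
  purrr::pmap_dfr(
    list(seqs$id, seqs$virus, seqs$variant_class, seqs$seq),
    function(id, virus, klass, s) {
      sp <- kmer_spectrum(s, k = 1:3)
      purrr::map_dfr(motifs, function(m) {
        p_obs <- obs_freq(sp, m)
        p_exp <- expected_frequency(sp, m)
        undefined <- is.na(p_obs) || is.na(p_exp) || p_exp == 0
        tibble(seq_id = id, virus = virus, variant_class = klass, motif = m,
               p_obs = p_obs, p_exp = p_exp,
               d_ratio = if (undefined) NA_real_ else p_obs / p_exp,
               undefined = undefined)
      })
    }
  )
}

#' Group summaries of a D-ratio table
#'
#' Medians (the figure-level aggregation statistic) with means alongside
#' for comparison, per virus x variant class x motif.
#'
#' @param tbl Output of [d_ratio_table()].
#' @return Tibble: grouping columns, `n`, `median_d`, `mean_d`.
#' @export
d_ratio_medians <- function(tbl) {
  tbl |>
    group_by(.data$virus, .data$variant_class, .data$motif) |>
    summarise(
      n = dplyr::n(),
      median_d = median(.data$d_ratio, na.rm = TRUE),
      mean_d = mean(.data$d_ratio, na.rm = TRUE),
      .groups = "drop"
    )
}
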