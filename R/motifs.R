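#' Scan a sequence with a position weight matrix
#'
#' Scores every position on both strands with the log-odds (bits) of the
#' motif's probability matrix against its background. The calling
#' threshold is the smallest score whose exceedance probability under the
#' background (sequence letters i.i.d. from the background distribution)
#' is at most `threshold_quantile`; that null distribution is computed
#' exactly by dynamic programming over the discretized per-column score
#' distributions. Overlapping hits are allowed.
#'
#' @param seq Sequence string (or one-row sequence tibble).
#' @param motif Motif object (see [read_meme_motifs()]).
#' @param threshold_quantile Null exceedance probability of the calling
#'   threshold (default `1e-4`).
#' @param seq_id Id carried into the hit table.
#' @return Tibble of hits: `seq_id`, `motif_name`, `start` (0-based, plus
#'   strand coordinates), `strand`, `score` (bits). Empty (with a warning)
#'   when the motif is wider than the sequence.
#' @export
scan_motif <- function(seq, motif, threshold_quantile = 1e-4, seq_id = "seq") {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1)
    seq_id <- seq$id
    seq <- seq$seq
  }
  w <- motif$width
  L <- nchar(seq)
  empty <- tibble(seq_id = character(), motif_name = character(),
                  start = integer(), strand = character(), score = numeric())
  if (w > L) {
    warn(paste0("motif ", motif$name, " wider than sequence ", seq_id))
    return(empty)
  }

  sc <- score_matrix_int(motif)
  thr <- score_threshold_int(sc, motif$background, threshold_quantile)

  fwd <- scan_one_strand(seq, sc)
  rev <- scan_one_strand(revcomp_chr(seq), sc)

  hits <- bind_rows(
    tibble(start = which(fwd >= thr) - 1L, strand = "+",
           score = fwd[fwd >= thr] / 1000),
    tibble(start = L - (which(rev >= thr) - 1L) - w, strand = "-",
           score = rev[rev >= thr] / 1000)
  )
  if (nrow(hits) == 0) return(empty)
  hits |>
    mutate(seq_id = seq_id, motif_name = motif$name) |>
    select(all_of(c("seq_id", "motif_name", "start", "strand", "score"))) |>
    arrange(.data$start, .data$strand)
}

# Integer (millibit) log-odds score matrix with a small pseudocount so
# zero cells stay finite. N (or any ambiguous base) scores -Inf.
score_matrix_int <- function(motif, pseudocount = 1e-4) {
  p <- motif$probability_matrix
  bg <- motif$background
  p <- sweep(p + pseudocount, 1, rowSums(p + pseudocount), "/")
  s <- log2(sweep(p, 2, bg, "/"))
  round(s * 1000)
}

# Exact null score distribution by convolution over columns, on the
# integer grid; returns the smallest integer score t with
# P(score >= t) <= q.
score_threshold_int <- function(sc, bg, q) {
  offset <- apply(sc, 1, min)
  dist <- 1 # probability vector over score - sum(offset), index 1 == 0
  for (i in seq_len(nrow(sc))) {
    shifted <- sc[i, ] - offset[i]
    width_i <- max(shifted)
    new <- numeric(length(dist) + width_i)
    for (b in 1:4) {
      idx <- seq_along(dist) + shifted[b]
      new[idx] <- new[idx] + dist * bg[b]
    }
    dist <- new
  }
  tail_p <- rev(cumsum(rev(dist)))
  idx <- which(tail_p <= q)
  if (length(idx) == 0) {
    # even the best score is too probable; call only the maximum
    return(length(dist) - 1L + sum(offset) + 1L)
  }
  (min(idx) - 1L) + sum(offset)
}

# Total integer score at every start position of one strand; positions
# whose window contains an ambiguous base score -Inf.
scan_one_strand <- function(seq, sc) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  w <- nrow(sc)
  code <- match(ch, DNA_LETTERS) # NA for N etc.
  n_pos <- L - w + 1
  total <- numeric(n_pos)
  bad <- logical(n_pos)
  for (i in seq_len(w)) {
    ci <- code[i:(i + n_pos - 1)]
    bad <- bad | is.na(ci)
    v <- unname(sc[i, ][ci])
    v[is.na(v)] <- 0
    total <- total + v
  }
  total[bad] <- -Inf
  total
}

#' Set enrichment of motifs between two sequence sets
#'
#' For each motif, sequences are classified present/absent (at least one
#' [scan_motif()] hit) in the primary and control sets, and a one-sided
#' Fisher's exact test asks whether presence is enriched in the primary
#' set. The E-value is the Bonferroni-scaled p (`p * n_motifs_tested`).
#' The strict presence rule of [bespoke_filter()] is evaluated on every
#' row. This fixed-threshold presence/absence design is a deliberate
#' simplification of optimal-threshold enrichment machinery: the
#' biological conclusion rests on the presence pattern plus the strict
#' rule, which are preserved exactly.
#'
#' @param primary,control Sequence tibbles.
#' @param motifs List of motif objects.
#' @param n_motifs_tested Multiple-testing scale for the E-value (defaults
#'   to `length(motifs)`).
#' @param threshold_quantile Passed to [scan_motif()].
#' @param e_max E-value cutoff used by the strict filter (default 0.05).
#' @return Tibble: `motif_name`, `source_mark`, `n_primary_with_hit`,
#'   `n_primary`, `n_control_with_hit`, `n_control`, `p_value`, `e_value`,
#'   `passes_bespoke_filter`.
#' @export
sea_enrich <- function(primary, control, motifs,
                       n_motifs_tested = length(motifs),
                       threshold_quantile = 1e-4, e_max = 0.05) {
  stopifnot(nrow(primary) > 0, nrow(control) > 0)
  presence <- function(seqs, motif) {
    vapply(seq_len(nrow(seqs)), function(i) {
      nrow(scan_motif(seqs[i, ], motif,
                      threshold_quantile = threshold_quantile)) > 0
    }, logical(1))
  }
  out <- purrr::map_dfr(motifs, function(m) {
    hp <- sum(presence(primary, m))
    hc <- sum(presence(control, m))
    np <- nrow(primary); nc <- nrow(control)
    p <- fisher.test(matrix(c(hp, np - hp, hc, nc - hc), nrow = 2),
                     alternative = "greater")$p.value
    tibble(motif_name = m$name,
           source_mark = m$source_mark %||% NA_character_,
           n_primary_with_hit = hp, n_primary = np,
           n_control_with_hit = hc, n_control = nc,
           p_value = p, e_value = min(1, p * n_motifs_tested))
  })
  out$passes_bespoke_filter <- bespoke_filter(out, e_max = e_max)
  out
}

#' Strict presence-based significance rule
#'
#' A motif is called significant only when its E-value passes the cutoff
#' AND it is present in all primary sequences with at most one control
#' sequence, or present in all but one primary sequence with zero control
#' sequences. This all-or-almost-all rule is intentionally conservative:
#' it demands the presence pattern itself, not just a small p.
#'
#' @param result Tibble with the count and `e_value` columns of
#'   [sea_enrich()].
#' @param e_max E-value cutoff (default 0.05).
#' @return Logical vector, one element per row.
#' @export
bespoke_filter <- function(result, e_max = 0.05) {
  with(result, e_value <= e_max & (
    (n_primary_with_hit == n_primary & n_control_with_hit <= 1) |
    (n_primary_with_hit == n_primary - 1 & n_control_with_hit == 0)
  ))
}

#' Restrict promoter-mark motif hits to CpG islands
#'
#' Hits from motifs tagged with one of the restricted histone marks
#' (default H3K4me3, H3K27ac, H3K27me3 — the marks expected inside CpG
#' islands) are kept only when the hit interval intersects an island;
#' hits from any other mark pass through unfiltered.
#'
#' @param hits Hit tibble from [scan_motif()], with a `width` column or
#'   with motif widths supplied via `widths` (named by motif).
#' @param islands Island tibble from [call_islands()].
#' @param marks Character vector of restricted marks.
#' @param widths Optional named integer vector of motif widths.
#' @return The filtered hit tibble.
#' @export
cgi_overlap_filter <- function(hits, islands,
                               marks = c("H3K4me3", "H3K27ac", "H3K27me3"),
                               widths = NULL) {
  if (nrow(hits) == 0) return(hits)
  if (!"width" %in% names(hits)) {
    if (is.null(widths)) abort("supply a width column or the widths argument")
    hits$width <- unname(widths[hits$motif_name])
  }
  if (!"source_mark" %in% names(hits)) {
    hits$source_mark <- extract_mark(hits$motif_name)
  }
  restricted <- hits$source_mark %in% marks
  keep <- !restricted | overlap_any(hits, islands)
  hits[keep, ]
}

# Does [start, start+width) intersect any island on the same seq_id?
overlap_any <- function(hits, islands) {
  if (nrow(islands) == 0) return(rep(FALSE, nrow(hits)))
  vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    isl <- islands[islands$seq_id == h$seq_id, , drop = FALSE]
    any(h$start < isl$end & (h$start + h$width) > isl$start)
  }, logical(1))
}
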