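#' Sliding-window GC / CpG O/E profile
#'
#' For each window start `s` (0-based) the profile reports
#' `gc_percent = 100 * (#C + #G) / window` and the Gardiner-Garden
#' observed/expected CpG ratio `cpg_oe = #CG * window / (#C * #G)`
#' (0 when `#C * #G == 0`). This window O/E is deliberately distinct from
#' the Markov D-ratio of [d_ratio()] — the island caller uses the classical
#' window form. Windows containing `N` yield `NA` in both columns and can
#' never pass the island thresholds.
#'
#' @param seq Sequence string (or one-row sequence tibble).
#' @param window Window size in bp (default 100).
#' @param seq_id Sequence id carried into downstream island records.
#' @return Tibble of class `erv_window_profile`: `start`, `gc_percent`,
#'   `cpg_oe`; the sequence and window ride along as attributes.
#' @export
window_profile <- function(seq, window = 100, seq_id = "seq") {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1)
    seq_id <- seq$id
    seq <- seq$seq
  }
  L <- nchar(seq)
  if (L < window) abort("sequence shorter than window")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]

  # cumulative counts -> O(1) per window
  cum <- function(v) c(0, cumsum(v))
  cC <- cum(ch == "C"); cG <- cum(ch == "G"); cN <- cum(ch == "N")
  is_cg <- c(ch[-L] == "C" & ch[-1] == "G", FALSE)
  cCG <- cum(is_cg)

  starts <- 0:(L - window)               # 0-based
  i <- starts + 1                        # 1-based window begin
  j <- starts + window                   # 1-based window end (inclusive)
  nC <- cC[j + 1] - cC[i]
  nG <- cG[j + 1] - cG[i]
  nN <- cN[j + 1] - cN[i]
  nCG <- cCG[j] - cCG[i]                 # dinucleotide starts within window

  gc <- 100 * (nC + nG) / window
  oe <- ifelse(nC * nG == 0, 0, nCG * window / (nC * nG))
  gc[nN > 0] <- NA_real_
  oe[nN > 0] <- NA_real_

  out <- tibble(start = starts, gc_percent = gc, cpg_oe = oe)
  attr(out, "seq") <- seq
  attr(out, "seq_id") <- seq_id
  attr(out, "window") <- window
  class(out) <- c("erv_window_profile", class(out))
  out
}

#' Call CpG islands from a window profile
#'
#' A window passes when `cpg_oe >= oe_min` and `gc_percent >= gc_min`
#' (the classical island thresholds of 0.6 and 50). Overlapping or
#' adjacent passing windows are merged into maximal intervals (the union
#' of their spans) and intervals at least `min_length` bp long are
#' reported, with GC and O/E recomputed over the merged interval. This
#' union-of-passing-windows definition is deterministic and simpler than
#' smoothing-based callers; edge-case divergence from those is expected
#' and documented rather than hidden.
#'
#' @param profile An `erv_window_profile` from [window_profile()].
#' @param min_length Minimum island length in bp (200 by default; relax to
#'   100 for short proviruses whose islands would otherwise be missed).
#' @param oe_min,gc_min Window thresholds.
#' @return Tibble: `seq_id`, `start`, `end` (0-based half-open), `length`,
#'   `mean_gc`, `mean_oe`. Zero rows is a valid result.
#' @export
call_islands <- function(profile, min_length = 200, oe_min = 0.6, gc_min = 50) {
  w <- attr(profile, "window")
  seqc <- attr(profile, "seq")
  seq_id <- attr(profile, "seq_id")
  pass <- !is.na(profile$cpg_oe) & !is.na(profile$gc_percent) &
    profile$cpg_oe >= oe_min & profile$gc_percent >= gc_min
  empty <- tibble(seq_id = character(), start = integer(), end = integer(),
                  length = integer(), mean_gc = numeric(), mean_oe = numeric())
  if (!any(pass)) return(empty)

  spans <- IRanges::IRanges(start = profile$start[pass] + 1,
                            width = w) # 1-based closed for IRanges
  merged <- IRanges::reduce(spans)
  out <- tibble(
    seq_id = seq_id,
    start = IRanges::start(merged) - 1L,
    end = IRanges::end(merged),
    length = IRanges::width(merged)
  ) |>
    filter(.data$length >= min_length)
  if (nrow(out) == 0) return(empty)

  stats_ <- purrr::map2_dfr(out$start, out$end, function(s, e) {
    sub <- substr(seqc, s + 1, e)
    interval_gc_oe(sub)
  })
  dplyr::bind_cols(out, stats_) |> arrange(.data$start)
}

# GC% and Gardiner-Garden O/E measured over a whole interval.
interval_gc_oe <- function(sub) {
  ch <- strsplit(sub, "", fixed = TRUE)[[1]]
  L <- length(ch)
  nC <- sum(ch == "C"); nG <- sum(ch == "G")
  nCG <- sum(ch[-L] == "C" & ch[-1] == "G")
  tibble(
    mean_gc = 100 * (nC + nG) / L,
    mean_oe = if (nC * nG == 0) 0 else nCG * L / (nC * nG)
  )
}

#' Find CpG islands in one call
#'
#' Convenience wrapper: [window_profile()] then [call_islands()].
#'
#' @inheritParams window_profile
#' @inheritParams call_islands
#' @return See [call_islands()].
#' @export
find_cpg_islands <- function(seq, window = 100, min_length = 200,
                             oe_min = 0.6, gc_min = 50, seq_id = "seq") {
  call_islands(window_profile(seq, window = window, seq_id = seq_id),
               min_length = min_length, oe_min = oe_min, gc_min = gc_min)
}
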