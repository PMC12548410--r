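#' Stratify reference G positions by APOBEC3G context
#'
#' APOBEC3G deaminates the minus strand, which reads out as plus-strand
#' G-to-A changes in a characteristic downstream context. Following the
#' convention of the classical hypermutation detector, each reference `G`
#' whose next two reference bases are unambiguous is assigned to the
#' primary stratum when the downstream context matches `G R D`
#' (`R` in `{A,G}`, `D` in `{A,G,T}`), and to the control stratum
#' otherwise; a position counts as mutated when the query carries `A`
#' there. Positions with a gap (`-`) or `N` in either sequence are
#' skipped. Inputs must be pre-aligned (equal length).
#'
#' @param reference,query Aligned sequence strings of equal length
#'   (gaps as `-`).
#' @param primary_r,primary_d Downstream context sets defining the primary
#'   stratum (overridable for other APOBEC family members).
#' @return One-row tibble: `primary_mutated`, `primary_total`,
#'   `control_mutated`, `control_total`.
#' @export
classify_contexts <- function(reference, query,
                              primary_r = c("A", "G"),
                              primary_d = c("A", "G", "T")) {
  if (nchar(reference) != nchar(query)) {
    abort("reference and query must have equal (aligned) lengths")
  }
  r <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  q <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  L <- length(r)
  ok_base <- function(x) x %in% DNA_LETTERS

  i <- which(r == "G")
  i <- i[i + 2 <= L]
  if (length(i)) {
    keep <- ok_base(q[i]) & ok_base(r[i + 1]) & ok_base(r[i + 2])
    i <- i[keep]
  }
  if (length(i) == 0) {
    return(tibble(primary_mutated = 0L, primary_total = 0L,
                  control_mutated = 0L, control_total = 0L))
  }
  primary <- r[i + 1] %in% primary_r & r[i + 2] %in% primary_d
  mutated <- q[i] == "A"
  tibble(
    primary_mutated = sum(primary & mutated),
    primary_total = sum(primary),
    control_mutated = sum(!primary & mutated),
    control_total = sum(!primary)
  )
}

#' One-sided Fisher test for hypermutation
#'
#' Tests whether G-to-A mutation is enriched in the primary (APOBEC3G)
#' context stratum relative to the control stratum: one-sided Fisher's
#' exact test (hypergeometric tail) on the 2x2 table of
#' mutated/unmutated x primary/control.
#'
#' @param counts One-row tibble from [classify_contexts()].
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: the counts, `p_value`, `rate_ratio`
#'   (`Inf` when the control rate is zero but the primary rate is not) and
#'   `significant`.
#' @export
hypermut_test <- function(counts, alpha = 0.05) {
  pm <- counts$primary_mutated; pt <- counts$primary_total
  cm <- counts$control_mutated; ct <- counts$control_total
  if (pt == 0 || ct == 0) {
    abort("a context stratum has zero G positions; supply a longer alignment")
  }
  p <- fisher.test(matrix(c(pm, pt - pm, cm, ct - cm), nrow = 2),
                   alternative = "greater")$p.value
  rr <- if (cm == 0) {
    if (pm > 0) Inf else NA_real_
  } else {
    (pm / pt) / (cm / ct)
  }
  dplyr::bind_cols(counts,
                   tibble(p_value = p, rate_ratio = rr,
                          significant = p < alpha))
}

#' Majority-rule consensus of aligned sequences
#'
#' Column-wise majority over `A/C/G/T/-` with ties broken alphabetically
#' (gap sorts last), so the result is deterministic. `N` never wins a
#' column unless nothing else is present.
#'
#' @param seqs Character vector of aligned sequences (equal lengths), or a
#'   sequence tibble with a `seq` column.
#' @return The consensus string.
#' @export
consensus_sequence <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  stopifnot(length(seqs) >= 1)
  if (length(unique(nchar(seqs))) != 1) {
    abort("sequences must be aligned to equal lengths")
  }
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  order_pref <- c("A", "C", "G", "T", "-", "N")
  apply(m, 2, function(col) {
    tab <- table(factor(col, levels = order_pref))
    tab["N"] <- tab["N"] - 0.5 # N only wins when alone
    names(tab)[which.max(tab)]
  }) |> paste(collapse = "")
}

#' Per-sequence hypermutation scan of an aligned set
#'
#' Runs [classify_contexts()] + [hypermut_test()] for every query against
#' a reference. With no explicit reference, the column-wise majority
#' consensus of the whole set is used and recorded in the output metadata.
#'
#' @param seqs Sequence tibble of aligned sequences.
#' @param reference Optional reference string; default is the set
#'   consensus.
#' @param alpha Significance level.
#' @return Tibble with one row per sequence (id, counts, `p_value`,
#'   `rate_ratio`, `significant`); the reference mode is attached as the
#'   `reference_mode` attribute.
#' @export
hypermut_scan <- function(seqs, reference = NULL, alpha = 0.05) {
  mode <- if (is.null(reference)) "consensus" else "supplied"
  if (is.null(reference)) reference <- consensus_sequence(seqs)
  out <- purrr::map2_dfr(seqs$id, seqs$seq, function(id, s) {
    cnt <- classify_contexts(reference, s)
    dplyr::bind_cols(tibble(seq_id = id), hypermut_test(cnt, alpha = alpha))
  })
  attr(out, "reference_mode") <- mode
  out
}

#' Calibrate the hypermutation test by simulation
#'
#' Simulates queries from a reference by mutating G positions to A with
#' stratum-specific rates (the mutation process the test assumes), runs
#' [hypermut_test()] on each, and reports the rejection rate. With equal
#' rates this measures the type-I error (expected below nominal for an
#' exact test); with a primary-stratum excess it measures power.
#'
#' Because stratum membership depends only on the reference, each
#' simulated query reduces to binomial mutation counts over the fixed
#' stratum totals.
#'
#' @param reference Reference sequence string.
#' @param rate_primary,rate_control Per-position G-to-A rates.
#' @param n_sim Number of simulated queries.
#' @param seed Integer seed.
#' @param alpha Significance level.
#' @return One-row tibble: `rejection_rate`, `n_sim`, `primary_total`,
#'   `control_total`.
#' @export
hypermut_calibration <- function(reference, rate_primary, rate_control,
                                 n_sim, seed, alpha = 0.05) {
  base <- classify_contexts(reference, reference)
  np <- base$primary_total
  nc <- base$control_total
  if (np == 0 || nc == 0) abort("reference too short to populate both strata")
  with_seed(seed, {
    pm <- rbinom(n_sim, np, rate_primary)
    cm <- rbinom(n_sim, nc, rate_control)
  })
  rej <- vapply(seq_len(n_sim), function(i) {
    hypermut_test(tibble(primary_mutated = pm[i], primary_total = np,
                         control_mutated = cm[i], control_total = nc),
                  alpha = alpha)$significant
  }, logical(1))
  tibble(rejection_rate = mean(rej), n_sim = n_sim,
         primary_total = np, control_total = nc)
}
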