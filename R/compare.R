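#' Rank-based group comparison of D-ratios
#'
#' Two groups are compared by a two-sided Mann-Whitney U test (exact when
#' the combined n is at most 20 and there are no ties, normal approximation
#' with tie correction otherwise). Three or more groups get a
#' Kruskal-Wallis test followed by Dunn's pairwise z-tests with
#' Bonferroni-adjusted p-values (Holm available).
#'
#' @param data Tibble with a value column and a group column.
#' @param value,group Column names (character) holding the values and the
#'   group labels.
#' @param posthoc_adjust `"bonferroni"` (default) or `"holm"`.
#' @param exact_max Combined-n threshold below/at which the two-group test
#'   is exact.
#' @return An object of class `erv_group_test` with `tidy()`/`glance()`
#'   methods: method, statistic, p-value, per-group medians, post-hoc table
#'   (only for >= 3 groups) and the sign of the median difference for two
#'   groups.
#' @examples
#' d <- tibble::tibble(v = c(1:10, 11:20), g = rep(c("a", "b"), each = 10))
#' glance(group_compare(d, "v", "g"))
#' @export
group_compare <- function(data, value = "d_ratio", group = "variant_class",
                          posthoc_adjust = c("bonferroni", "holm"),
                          exact_max = 20) {
  posthoc_adjust <- match.arg(posthoc_adjust)
  x <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  tab <- table(g)
  if (length(tab) < 2) abort("need at least 2 groups")
  if (any(tab < 2)) {
    abort(paste0("group(s) with n < 2: ",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }

  groups <- tibble(
    group = names(tab),
    n = as.integer(tab),
    median = vapply(names(tab), function(gg) median(x[g == gg]), numeric(1))
  )

  if (length(unique(x)) == 1) {
    warn("all values identical across groups; p set to 1")
    res <- list(method = if (length(tab) == 2) "mann-whitney" else "kruskal-wallis",
                statistic = NA_real_, p_value = 1, groups = groups,
                posthoc = NULL, effect_direction = 0L)
    return(structure(res, class = "erv_group_test"))
  }

  if (length(tab) == 2) {
    g1 <- x[g == names(tab)[1]]
    g2 <- x[g == names(tab)[2]]
    exact <- (length(g1) + length(g2)) <= exact_max && !anyDuplicated(x)
    wt <- suppressWarnings(
      wilcox.test(g1, g2, alternative = "two.sided", exact = exact,
                  correct = !exact)
    )
    res <- list(
      method = "mann-whitney",
      statistic = unname(wt$statistic),
      p_value = min(1, wt$p.value),
      groups = groups,
      posthoc = NULL,
      effect_direction = sign(median(g1) - median(g2))
    )
    return(structure(res, class = "erv_group_test"))
  }

  kw <- kruskal.test(x, factor(g))
  res <- list(
    method = "kruskal-wallis",
    statistic = unname(kw$statistic),
    p_value = kw$p.value,
    groups = groups,
    posthoc = dunn_posthoc(x, g, adjust = posthoc_adjust),
    effect_direction = NA_integer_
  )
  structure(res, class = "erv_group_test")
}

# Dunn's z-tests on the joint ranks with the tie-corrected variance.
dunn_posthoc <- function(x, g, adjust = "bonferroni") {
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  levs <- sort(unique(g))
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p) {
    ri <- r[g == p[1]]; rj <- r[g == p[2]]
    z <- (mean(ri) - mean(rj)) /
      sqrt(s2 * (1 / length(ri) + 1 / length(rj)))
    tibble(group1 = p[1], group2 = p[2], z = z,
           p_unadjusted = 2 * pnorm(-abs(z)))
  })
  out$p_adjusted <- stats::p.adjust(out$p_unadjusted, method = adjust)
  out
}

#' @export
print.erv_group_test <- function(x, ...) {
  cat(sprintf("<erv_group_test> %s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  print(x$groups)
  if (!is.null(x$posthoc)) {
    cat("post-hoc (Dunn):\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' @export
tidy.erv_group_test <- function(x, ...) {
  if (!is.null(x$posthoc)) return(x$posthoc)
  x$groups
}

#' @export
glance.erv_group_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value,
         n_groups = nrow(x$groups), n_total = sum(x$groups$n),
         effect_direction = x$effect_direction)
}

new_cor_result <- function(method, est, p, n, undefined = FALSE, note = NULL) {
  structure(
    list(method = method, r = est, p_value = p, n = n,
         undefined = undefined, note = note),
    class = "erv_cor_test"
  )
}

#' @export
print.erv_cor_test <- function(x, ...) {
  if (x$undefined) {
    cat("<erv_cor_test> undefined (constant input), n =", x$n, "\n")
  } else {
    cat(sprintf("<erv_cor_test> %s: r = %.4f, p = %.4g, n = %d\n",
                x$method, x$r, x$p_value, x$n))
  }
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @export
tidy.erv_cor_test <- function(x, ...) {
  tibble(method = x$method, estimate = x$r, p_value = x$p_value,
         n = x$n, undefined = x$undefined)
}

#' @export
glance.erv_cor_test <- function(x, ...) tidy(x)

#' Deamination-signature correlation
#'
#' Methylated-cytosine deamination converts CpG to TpG on the plus strand
#' and, through the complementary strand, to CpA. Across sequences that
#' lost different amounts of CpG, the CpG D-ratio should therefore
#' anticorrelate with the TpG/CpA D-ratios. This computes Spearman's rank
#' correlation between the x-motif D-ratio and the per-sequence arithmetic
#' mean of the two y-motif D-ratios (or each separately with
#' `combine = "separate"`).
#'
#' @param tbl Output of [d_ratio_table()] containing the needed motifs.
#' @param x_motif Motif for the x axis (default `"CG"`; use `"CGC"` for the
#'   trinucleotide-context signature).
#' @param y_motifs Two product motifs (default `c("TG", "CA")`; use
#'   `c("TGC", "CAC")` with `x_motif = "CGC"`).
#' @param combine `"mean"` (default) or `"separate"`.
#' @return An `erv_cor_test` (or a tibble of two with
#'   `combine = "separate"`).
#' @export
deamination_correlation <- function(tbl, x_motif = "CG",
                                    y_motifs = c("TG", "CA"),
                                    combine = c("mean", "separate")) {
  combine <- match.arg(combine)
  stopifnot(length(y_motifs) == 2)
  wide <- tbl |>
    filter(.data$motif %in% c(x_motif, y_motifs)) |>
    select(all_of(c("seq_id", "motif", "d_ratio"))) |>
    tidyr::pivot_wider(names_from = "motif", values_from = "d_ratio") |>
    tidyr::drop_na()
  if (nrow(wide) < 4) abort("need >= 4 sequences with defined D-ratios")
  xv <- wide[[x_motif]]
  if (combine == "separate") {
    return(purrr::map_dfr(y_motifs, function(ym) {
      tidy(spearman_cor(xv, wide[[ym]])) |>
        mutate(x_motif = x_motif, y_motif = ym)
    }))
  }
  yv <- (wide[[y_motifs[1]]] + wide[[y_motifs[2]]]) / 2
  spearman_cor(xv, yv)
}

spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(new_cor_result("spearman", NA_real_, NA_real_, n, undefined = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  alternative = "two.sided"))
  new_cor_result("spearman", unname(ct$estimate), ct$p.value, n)
}

#' Methylation vs CpG O/E correlation across viruses
#'
#' Relates each endogenous virus's median CpG percent methylation to its
#' median CpG D-ratio. The Pearson coefficient is reported after a
#' Shapiro-Wilk normality check on both margins; if either margin fails at
#' alpha = 0.05 the result falls back to Spearman and says so. An optional
#' labelled point (a recent integrant that has not yet accumulated
#' deamination losses, such as KoRV-A in koalas) can be excluded and is
#' reported as an annotated outlier.
#'
#' @param points Tibble with columns `label`, `median_meth` (percent) and
#'   `median_oe`.
#' @param exclude Optional label to set aside before fitting.
#' @return An `erv_cor_test`; the excluded point (if any) is attached as
#'   the `excluded` attribute.
#' @export
meth_vs_oe_correlation <- function(points, exclude = NULL) {
  stopifnot(all(c("label", "median_meth", "median_oe") %in% names(points)))
  excluded <- NULL
  if (!is.null(exclude)) {
    excluded <- filter(points, .data$label %in% exclude)
    points <- filter(points, !.data$label %in% exclude)
  }
  if (nrow(points) < 3) abort("need >= 3 points after exclusion")
  x <- points$median_meth
  y <- points$median_oe
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    res <- new_cor_result("pearson", NA_real_, NA_real_, nrow(points),
                          undefined = TRUE)
    attr(res, "excluded") <- excluded
    return(res)
  }
  sw_ok <- tryCatch(
    shapiro.test(x)$p.value >= 0.05 && shapiro.test(y)$p.value >= 0.05,
    error = function(e) TRUE # constant-adjacent tiny samples: keep Pearson
  )
  if (sw_ok) {
    ct <- cor.test(x, y, method = "pearson")
    res <- new_cor_result("pearson", unname(ct$estimate), ct$p.value,
                          nrow(points))
  } else {
    res <- spearman_cor(x, y)
    res$note <- "normality check failed; Spearman reported instead of Pearson"
  }
  attr(res, "excluded") <- excluded
  res
}
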