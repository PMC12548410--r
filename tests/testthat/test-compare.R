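test_that("two-group comparison reproduces the exact Mann-Whitney p", {
  d <- tibble::tibble(v = c(1:10, 11:20), g = rep(c("a", "b"), each = 10))
  res <- group_compare(d, "v", "g")
  expect_equal(res$method, "mann-whitney")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 2 / choose(20, 10))      # completely separated
  expect_equal(res$p_value, 1.0825e-5, tolerance = 1e-3)
  expect_equal(res$effect_direction, -1)
  expect_null(res$posthoc)

  g <- glance(res)
  expect_equal(g$n_total, 20L)
  expect_equal(g$p_value, res$p_value)
})

test_that("identical groups give p = 1 and zero direction, with a warning", {
  d <- tibble::tibble(v = rep(c(3, 3, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_warning(res <- group_compare(d, "v", "g"), "identical")
  expect_equal(res$p_value, 1)
  expect_equal(res$effect_direction, 0L)

  expect_error(
    group_compare(tibble::tibble(v = c(1, 2, 3), g = c("a", "a", "b")),
                  "v", "g"),
    "n < 2"
  )
})

test_that("exact Mann-Whitney p matches full enumeration for small groups", {
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(rnorm(n1 + n2), 2)
    while (anyDuplicated(x)) x <- round(rnorm(n1 + n2), 2)
    d <- tibble::tibble(v = x, g = rep(c("a", "b"), c(n1, n2)))
    res <- group_compare(d, "v", "g")
    expect_equal(res$p_value, enum_mw_p(x[1:n1], x[-(1:n1)]),
                 tolerance = 1e-12)
  }
})

test_that("Dunn's post hoc flags only the shifted group's pairs", {
  set.seed(3)
  base <- rnorm(12)
  d <- tibble::tibble(
    v = c(base, base, base + 8),
    g = rep(c("a", "b", "c"), each = 12)
  )
  res <- group_compare(d, "v", "g")
  expect_equal(res$method, "kruskal-wallis")
  expect_lt(res$p_value, 0.001)
  ph <- tidy(res)
  sig <- ph$p_adjusted < 0.05
  involves_c <- ph$group1 == "c" | ph$group2 == "c"
  expect_true(all(sig[involves_c]))
  expect_false(any(sig[!involves_c]))
  # Bonferroni never smaller than unadjusted
  expect_true(all(ph$p_adjusted >= ph$p_unadjusted - 1e-15))
})

test_that("Kruskal-Wallis at k = 2 rejects identically to Mann-Whitney", {
  set.seed(19)
  agree <- replicate(1000, {
    n <- sample(4:10, 2, replace = TRUE)
    x <- rnorm(sum(n), mean = rep(c(0, sample(c(0, 1), 1)), n))
    g <- rep(c("a", "b"), n)
    kw <- kruskal.test(x, factor(g))$p.value
    mw <- suppressWarnings(wilcox.test(x[g == "a"], x[g == "b"],
                                       exact = FALSE)$p.value)
    (kw < 0.05) == (mw < 0.05)
  })
  expect_gt(mean(agree), 0.95)
})

test_that("Spearman deamination correlation handles monotone and degenerate input", {
  tbl <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(seq_id = paste0("s", i), virus = "v",
                   variant_class = "endogenous",
                   motif = c("CG", "TG", "CA"),
                   p_obs = 0.1, p_exp = 0.1,
                   d_ratio = c(5 - i, i, i), undefined = FALSE)
  }))
  res <- deamination_correlation(tbl)
  expect_equal(res$r, -1)
  expect_equal(res$n, 4)

  sep <- deamination_correlation(tbl, combine = "separate")
  expect_equal(nrow(sep), 2)
  expect_equal(sep$estimate, c(-1, -1))

  const <- tbl
  const$d_ratio[const$motif != "CG"] <- 1
  expect_true(deamination_correlation(const)$undefined)
})

test_that("methylation vs O/E correlation fits retained points and reports the outlier", {
  pts <- tibble::tibble(label = paste0("v", 1:6),
                        median_meth = c(10, 25, 40, 55, 70, 85),
                        median_oe = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  res <- meth_vs_oe_correlation(pts)
  expect_equal(res$method, "pearson")
  expect_equal(res$r, -1)

  # a recent integrant off the trend, excluded by label
  pts2 <- dplyr::bind_rows(pts, tibble::tibble(label = "recent",
                                               median_meth = 93,
                                               median_oe = 0.9))
  res2 <- meth_vs_oe_correlation(pts2, exclude = "recent")
  expect_equal(res2$r, -1)
  expect_equal(attr(res2, "excluded")$label, "recent")

  expect_error(meth_vs_oe_correlation(pts[1:2, ]), ">= 3")
  const <- pts
  const$median_meth <- 50
  expect_true(meth_vs_oe_correlation(const)$undefined)
})
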