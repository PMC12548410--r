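mk_rec <- function(pos, strand, meth, unmeth, ctx = "CpG", tri = "CGC",
                   id = "v1") {
  tibble::tibble(seq_id = id, position = as.integer(pos), strand = strand,
                 count_methylated = as.integer(meth),
                 count_unmethylated = as.integer(unmeth),
                 context_class = ctx, trinucleotide = tri)
}

test_that("site methylation is percent of reads with a coverage floor", {
  rec <- mk_rec(c(10, 20, 30, 40), "+",
                meth = c(8, 0, 10, 5), unmeth = c(2, 0, 0, 5))
  s <- site_methylation(rec, min_coverage = 1)
  expect_equal(nrow(s), 3)             # 0/0 site excluded
  expect_equal(s$percent, c(80, 100, 50))
  expect_equal(median(s$percent), 80)
  # no reads invented or lost among qualifying sites
  expect_equal(sum(s$coverage), 8 + 2 + 10 + 5 + 5)

  s20 <- site_methylation(rec, min_coverage = 20)
  expect_equal(nrow(s20), 0)
})

test_that("dyad collapsing sums complementary CpG counts into one site", {
  rec <- dplyr::bind_rows(
    mk_rec(10, "+", 8, 2, tri = "CGC"),
    mk_rec(11, "-", 6, 4, tri = "CGT")   # minus-strand C of the same dyad
  )
  s <- site_methylation(rec, collapse_dyads = TRUE)
  expect_equal(nrow(s), 1)
  expect_equal(s$position, 10L)
  expect_equal(s$coverage, 20L)
  expect_equal(s$percent, 70)
  # default keeps the two strand calls separate
  expect_equal(nrow(site_methylation(rec)), 2)
})

test_that("context summaries recover medians and the CGC preference", {
  rec <- dplyr::bind_rows(
    mk_rec(c(2, 12, 22), "+", c(90, 95, 100), c(10, 5, 0), tri = "CGC"),
    mk_rec(c(4, 14, 24), "+", c(10, 20, 30), c(90, 80, 70), tri = "CGA")
  )
  cm <- context_methylation(rec)
  expect_equal(cm$summary$median_percent[cm$summary$context == "CGC"], 95)
  expect_equal(cm$summary$median_percent[cm$summary$context == "CGA"], 20)
  expect_equal(cm$summary$n_sites[cm$summary$context == "CGG"], 0L)
  # n = 3 + 3, complete separation: the exact two-sided floor is 2/C(6,3)
  expect_equal(glance(cm$test)$p_value, 0.1)
  expect_equal(cm$test$effect_direction, -1)  # CGA below CGC
  med <- cm$summary
  expect_gt(med$median_percent[med$context == "CGC"],
            med$median_percent[med$context == "CGA"])

  # single qualifying context: summaries, no test
  one <- context_methylation(mk_rec(c(2, 12), "+", c(5, 6), c(5, 4),
                                    tri = "CGC"))
  expect_null(one$test)

  # identical distributions across contexts: no preference
  same <- dplyr::bind_rows(lapply(c("CGA", "CGC", "CGG", "CGT"), function(t)
    mk_rec(seq(2, 40, 4) + match(t, c("CGA", "CGC", "CGG", "CGT")), "+",
           rep(c(5, 5), 5), rep(c(5, 5), 5), tri = t)))
  expect_warning(cm2 <- context_methylation(same), "identical")
  expect_equal(glance(cm2$test)$p_value, 1)
})

test_that("provirus track bins coverage-weighted means and flags empty bins", {
  rec <- mk_rec(seq(10, 390, 20), "+", 8, 2)
  trk <- provirus_track(rec, seq_length = 800, bin_size = 100)
  t <- tidy(trk)
  expect_equal(nrow(t), 8)
  expect_true(all(t$mean_percent[1:4] == 80))
  expect_true(all(t$no_data[5:8]))     # sites only in the first half
  expect_equal(trk$median_percent, 80)
  expect_error(provirus_track(rec, 800, bin_size = 0), "positive")
})

test_that("sampled cytosine reports recover the generating probabilities", {
  # >= 500 CpG sites at p = 0.93, coverage 30: median site percent in [88,98]
  seq <- gen_markov_sequence(12000, 1.2, seed = 301)
  rep93 <- emit_cytosine_report(seq, cpg_prob = 0.93, coverage = 30,
                                seed = 302, seq_id = "v1")
  cpg <- dplyr::filter(rep93, context_class == "CpG")
  expect_gte(nrow(cpg), 500)
  s <- site_methylation(cpg, min_coverage = 1)
  expect_gte(median(s$percent), 88)
  expect_lte(median(s$percent), 98)

  # context-specific probabilities: CGC median strictly above every other
  probs <- c(CGC = 0.9, CGG = 0.5, CGA = 0.5, CGT = 0.5)
  st <- assign_methylation(seq, probs, seed = 303)
  # per-dyad read-level probability equal to the context probability
  rep_ctx <- emit_cytosine_report(
    seq, cpg_prob = tibble::tibble(position = st$position, prob = st$prob),
    coverage = 25, seed = 304
  )
  cm <- context_methylation(rep_ctx, min_coverage = 20)
  med <- cm$summary
  expect_true(all(med$n_sites >= 200))
  cgc <- med$median_percent[med$context == "CGC"]
  expect_true(all(cgc > med$median_percent[med$context != "CGC"]))
})
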