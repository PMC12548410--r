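test_that("PWM scanning finds an implanted consensus and respects strands", {
  motif <- consensus_motif("m1", "GGATCCTA")
  bg <- strrep("A", 200)
  s <- paste0(substr(bg, 1, 100), "GGATCCTA", strrep("A", 92))
  hits <- scan_motif(s, motif)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 100L)
  expect_equal(hits$strand, "+")

  # all-A sequence vs a GC-rich motif: nothing
  expect_equal(nrow(scan_motif(strrep("A", 300), consensus_motif("gc", "GCGCGC"))), 0)

  # strand symmetry: hits on the reverse complement mirror exactly
  set.seed(6)
  s2 <- paste0(random_seq(150), "GGATCCTA", random_seq(150))
  h_fwd <- scan_motif(s2, motif)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s2, "")[[1]]), collapse = ""))
  h_rev <- scan_motif(rc, motif)
  L <- nchar(s2); w <- motif$width
  reflect <- sort(L - h_rev$start - w)
  expect_equal(sort(h_fwd$start), reflect)
  expect_equal(nrow(h_fwd), nrow(h_rev))

  # wider motif than sequence: empty with warning
  expect_warning(h0 <- scan_motif("ACGT", motif), "wider")
  expect_equal(nrow(h0), 0)
})

test_that("hit count is non-increasing as the calling threshold tightens", {
  set.seed(8)
  s <- random_seq(2000)
  motif <- consensus_motif("m", "GGATC", weight = 0.7)
  qs <- c(1e-2, 1e-3, 1e-4, 1e-5)
  n <- vapply(qs, function(q) nrow(scan_motif(s, motif, threshold_quantile = q)),
              numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("set enrichment Fisher p matches hypergeometric enumeration", {
  set.seed(14)
  motif <- consensus_motif("m1", "GGATCCTAGG")
  decoy <- consensus_motif("m2", "TTTACGCATT")
  primary <- seq_tbl(replicate(8, random_seq(300)), klass = "exogenous")
  control <- seq_tbl(replicate(8, random_seq(300)), klass = "endogenous",
                     ids = paste0("c", 1:8))
  primary <- implant_motifs(primary, motif, seed = 99)
  res <- sea_enrich(primary, control, list(motif, decoy))

  m1 <- res[res$motif_name == "m1", ]
  expect_equal(m1$n_primary_with_hit, 8L)
  expect_equal(m1$n_control_with_hit, 0L)
  expect_equal(m1$p_value, 1 / choose(16, 8), tolerance = 1e-12)
  expect_equal(m1$p_value, enum_fisher_p(8, 8, 0, 8), tolerance = 1e-12)
  expect_equal(m1$e_value, m1$p_value * 2)
  expect_true(m1$passes_bespoke_filter)
  expect_false(res$passes_bespoke_filter[res$motif_name == "m2"])

  # identical presence rates: no signal
  both <- sea_enrich(primary, primary, list(motif))
  expect_gte(both$p_value, 0.5)
})

test_that("the strict presence rule implements the all-vs-at-most-one clauses", {
  mk <- function(hp, hc, e) {
    tibble::tibble(n_primary_with_hit = hp, n_primary = 8L,
                   n_control_with_hit = hc, n_control = 8L, e_value = e)
  }
  expect_true(bespoke_filter(mk(8L, 1L, 0.01)))    # all primary, one control
  expect_true(bespoke_filter(mk(7L, 0L, 0.01)))    # all but one, zero control
  expect_false(bespoke_filter(mk(8L, 2L, 0.001)))  # two controls: out
  expect_false(bespoke_filter(mk(7L, 1L, 0.001)))
  expect_false(bespoke_filter(mk(6L, 0L, 0.001)))
  expect_false(bespoke_filter(mk(8L, 0L, 0.2)))    # E-value gate still applies
})

test_that("island-overlap filtering restricts only the promoter-associated marks", {
  islands <- tibble::tibble(seq_id = "s1", start = 0L, end = 200L,
                            length = 200L, mean_gc = 60, mean_oe = 0.8)
  hits <- tibble::tibble(
    seq_id = "s1",
    motif_name = c("H3K4me3_1", "H3K4me3_1", "H3K9me3_1"),
    start = c(50L, 500L, 500L),
    strand = "+",
    score = 10,
    width = 10L,
    source_mark = c("H3K4me3", "H3K4me3", "H3K9me3")
  )
  out <- cgi_overlap_filter(hits, islands)
  expect_equal(nrow(out), 2)
  expect_true(all(out$start %in% c(50L, 500L)))
  expect_equal(out$source_mark[out$start == 500L], "H3K9me3")
})

test_that("implantation end-to-end: only the implanted motif passes the rule", {
  set.seed(31)
  for (trial in 1:5) {
    motif <- consensus_motif("target", paste(sample(c("G", "C", "A", "T"), 10,
                                                    replace = TRUE),
                                             collapse = ""))
    decoy <- consensus_motif("decoy", "TGCATACGGT")
    primary <- seq_tbl(replicate(6, random_seq(400)), klass = "exogenous",
                       ids = paste0("p", 1:6))
    control <- seq_tbl(replicate(6, random_seq(400)), klass = "endogenous",
                       ids = paste0("c", 1:6))
    primary <- implant_motifs(primary, motif, seed = 1000 + trial)
    res <- sea_enrich(primary, control, list(motif, decoy))
    expect_true(res$passes_bespoke_filter[res$motif_name == "target"])
    expect_false(res$passes_bespoke_filter[res$motif_name == "decoy"])
  }
})
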