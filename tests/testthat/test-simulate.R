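test_that("Markov generator is seed-deterministic and hits its target O/E", {
  s1 <- gen_markov_sequence(10000, 1.0, seed = 1)
  expect_identical(s1, gen_markov_sequence(10000, 1.0, seed = 1))
  expect_false(identical(s1, gen_markov_sequence(10000, 1.0, seed = 2)))
  expect_lt(abs(d_ratio(s1, "CG")$d_ratio - 1.0), 0.05)

  s5 <- gen_markov_sequence(10000, 0.5, seed = 1)
  expect_lt(abs(d_ratio(s5, "CG")$d_ratio - 0.5), 0.05)

  expect_error(gen_markov_sequence(1000, 10, seed = 1), "unreachable")
})

test_that("uniform sequences have mean D-ratio near 1 (law of large numbers)", {
  set.seed(77)
  d <- replicate(40, d_ratio(random_seq(10000), "CG")$d_ratio)
  expect_gt(mean(d), 0.97)
  expect_lt(mean(d), 1.03)
})

test_that("methylation assignment follows context probabilities", {
  seq <- gen_markov_sequence(40000, 1.2, seed = 41)
  st0 <- assign_methylation(seq, c(CGC = 0, CGG = 0, CGA = 0, CGT = 0),
                            seed = 42, default_prob = 0)
  expect_false(any(st0$methylated))
  st1 <- assign_methylation(seq, c(CGC = 1, CGG = 1, CGA = 1, CGT = 1),
                            seed = 42, default_prob = 1)
  expect_true(all(st1$methylated))

  st <- assign_methylation(seq, c(CGC = 0.9, CGA = 0.1), seed = 43)
  frac <- function(ctx) mean(st$methylated[st$context == ctx])
  expect_gt(sum(st$context == "CGC"), 500)
  expect_lt(abs(frac("CGC") - 0.9), 0.05)
  expect_lt(abs(frac("CGA") - 0.1), 0.05)
  expect_lt(abs(frac("CGG") - 0.5), 0.05)  # unlisted context -> default 0.5
})

test_that("deamination follows the closed-form survival and conserves events", {
  seq <- gen_markov_sequence(12000, 1.3, seed = 51)
  st <- assign_methylation(seq, c(CGC = 1, CGG = 1, CGA = 1, CGT = 1),
                           seed = 52, default_prob = 1)
  expect_gt(sum(st$methylated), 1000)

  # rate 0: untouched
  r0 <- evolve_deamination(seq, st, rate = 0, generations = 10, seed = 53)
  expect_identical(r0$descendant, r0$ancestor)

  # rate 1, one generation: no CpG survives at methylated sites
  r1 <- evolve_deamination(seq, st, rate = 1, generations = 1, seed = 54)
  ch <- strsplit(r1$descendant, "")[[1]]
  still_cg <- ch[st$position] == "C" & ch[st$position + 1] == "G"
  expect_false(any(still_cg))

  # rate 0.1 x 10 generations: survival ~ 0.9^10 = 0.349 +/- 0.05
  r <- evolve_deamination(seq, st, rate = 0.1, generations = 10, seed = 55)
  survived <- 1 - (r$n_cg_tg + r$n_cg_ca) / sum(st$methylated)
  expect_lt(abs(survived - 0.9^10), 0.05)

  # conservation: changes only at initially methylated CpGs, events add up
  anc <- strsplit(r$ancestor, "")[[1]]
  des <- strsplit(r$descendant, "")[[1]]
  diff_pos <- which(anc != des)
  allowed <- sort(c(st$position[st$methylated], st$position[st$methylated] + 1))
  expect_true(all(diff_pos %in% allowed))
  expect_equal(r$n_cg_tg + r$n_cg_ca, nrow(r$events))
  expect_equal(length(diff_pos), nrow(r$events))  # one base changed per event
  # event type matches the base actually changed
  expect_true(all(des[r$events$position[r$events$type == "CG>TG"]] == "T"))
  expect_true(all(des[r$events$position[r$events$type == "CG>CA"] + 1] == "A"))
})

test_that("lineage panels reproduce the deamination signature end to end", {
  cfg <- simulation_config(seed = 7)
  panel <- simulate_lineages(cfg)
  expect_equal(nrow(panel), 20)

  des <- seq_tbl(panel$descendant, klass = "endogenous",
                 ids = paste0("des_", panel$lineage))
  tbl <- d_ratio_table(des, c("CG", "TG", "CA"))
  res <- deamination_correlation(tbl)
  expect_lt(res$r, -0.5)
  expect_lt(res$p_value, 0.01)

  # context preference: with CGC methylation dominating, the CGC D-ratio
  # drops most and the deamination products TGC/CAC rise
  cfg2 <- simulation_config(
    context_meth_prob = c(CGC = 0.95, CGG = 0.3, CGA = 0.3, CGT = 0.3),
    generations_range = c(30L, 40L), seed = 19
  )
  p2 <- simulate_lineages(cfg2)
  anc <- seq_tbl(p2$ancestor, klass = "exogenous", ids = paste0("a", p2$lineage))
  des2 <- seq_tbl(p2$descendant, klass = "endogenous", ids = paste0("d", p2$lineage))
  ctx <- c("CGA", "CGC", "CGG", "CGT")
  med <- function(tbl) {
    dplyr::summarise(dplyr::group_by(tbl, motif),
                     m = median(d_ratio, na.rm = TRUE))
  }
  m_anc <- med(d_ratio_table(anc, ctx))
  m_des <- med(d_ratio_table(des2, ctx))
  drop <- m_anc$m - m_des$m[match(m_anc$motif, m_des$motif)]
  names(drop) <- m_anc$motif
  expect_true(all(drop["CGC"] > drop[setdiff(ctx, "CGC")]))

  m_anc2 <- med(d_ratio_table(anc, c("TGC", "CAC")))
  m_des2 <- med(d_ratio_table(des2, c("TGC", "CAC")))
  expect_true(all(m_des2$m > m_anc2$m))
})

test_that("motif implantation is reproducible and validates width", {
  seqs <- seq_tbl(replicate(3, random_seq(200)))
  motif <- consensus_motif("m", "GGATCC")
  a <- implant_motifs(seqs, motif, seed = 5)
  b <- implant_motifs(seqs, motif, seed = 5)
  expect_identical(a$seq, b$seq)
  expect_identical(a$implant_start, b$implant_start)
  for (i in 1:3) {
    expect_equal(substr(a$seq[i], a$implant_start[i] + 1,
                        a$implant_start[i] + 6), "GGATCC")
  }
  expect_error(
    implant_motifs(seq_tbl("ACG"), consensus_motif("m", "GGATCC"), seed = 1),
    "width"
  )
  expect_error(
    implant_motifs(seq_tbl(strrep("AT", 200)), motif, where = "in-CGI", seed = 1),
    "island"
  )
})
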