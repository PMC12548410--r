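#' Simulation configuration
#'
#' Bundles the study conditions the simulator emulates: a first-order
#' Markov proviral background with a target CpG O/E, context-dependent CpG
#' methylation (elevated at CGC/CGG, the methyltransferase preference the
#' analysis looks for), per-generation deamination of methylated CpGs
#' (CG to TG on the plus strand, CG to CA via the minus strand), and
#' binomially sampled bisulfite evidence at a mean coverage.
#'
#' @param length Sequence length in bp (default 8000, a full-length
#'   provirus).
#' @param target_cpg_oe Target dinucleotide CpG O/E of the background
#'   (default 1.0: an unconstrained, un-depleted starting genome).
#' @param context_meth_prob Named per-context methylation probabilities.
#' @param deamination_rate Per-methylated-CpG, per-generation deamination
#'   probability (default 0.05).
#' @param generations_range Range the per-lineage generation count is
#'   drawn from (default 1..40, giving lineages a wide spread of CpG
#'   loss).
#' @param n_lineages Number of independent lineages (default 20).
#' @param coverage Mean reads per cytosine for sampled reports
#'   (default 30).
#' @param seed Master seed; mandatory — all randomness flows from it
#'   through per-stream sub-seeds.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(length = 8000,
                              target_cpg_oe = 1.0,
                              context_meth_prob = c(CGC = 0.9, CGG = 0.8,
                                                    CGA = 0.5, CGT = 0.5),
                              deamination_rate = 0.05,
                              generations_range = c(1L, 40L),
                              n_lineages = 20,
                              coverage = 30,
                              seed) {
  if (missing(seed)) abort("seed is mandatory (no hidden entropy)")
  stopifnot(length >= 1000, target_cpg_oe > 0,
            all(context_meth_prob >= 0 & context_meth_prob <= 1),
            deamination_rate >= 0, deamination_rate <= 1,
            coverage > 0)
  structure(
    list(length = length, target_cpg_oe = target_cpg_oe,
         context_meth_prob = context_meth_prob,
         deamination_rate = deamination_rate,
         generations_range = as.integer(generations_range),
         n_lineages = n_lineages, coverage = coverage,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# First-order transition matrix: uniform rows except the C row, whose
# C->G probability g is solved so that the stationary CpG O/E
# (pi_C * g / (pi_C * pi_G) = g / pi_G) equals the target exactly.
markov_transition <- function(target_cpg_oe) {
  pi_g_of <- function(g) {
    pi_c <- 0.25 / (1.25 - (1 - g) / 3)
    0.25 + pi_c * (g - 0.25)
  }
  f <- function(g) g / pi_g_of(g) - target_cpg_oe
  g <- tryCatch(uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root,
                error = function(e) {
                  abort(paste0("target_cpg_oe ", target_cpg_oe,
                               " is unreachable with valid probabilities"))
                })
  P <- matrix(0.25, 4, 4, dimnames = list(DNA_LETTERS, DNA_LETTERS))
  P["C", ] <- (1 - g) / 3
  P["C", "G"] <- g
  # stationary distribution by power iteration
  pi <- rep(0.25, 4)
  for (i in 1:200) pi <- pi %*% P
  list(P = P, stationary = as.numeric(pi), cg_transition = g)
}

#' Generate a Markov-background proviral sequence
#'
#' Samples from a first-order Markov chain that is uniform except for the
#' C-to-G transition, calibrated exactly so the chain's stationary
#' dinucleotide CpG O/E equals `target_cpg_oe`. Deterministic given the
#' seed.
#'
#' @param length Sequence length in bp.
#' @param target_cpg_oe Target CpG O/E (> 0; errors if unreachable).
#' @param seed Integer seed.
#' @return The sequence string.
#' @export
gen_markov_sequence <- function(length, target_cpg_oe, seed) {
  mk <- markov_transition(target_cpg_oe)
  with_seed(seed, {
    out <- integer(length)
    out[1] <- sample.int(4, 1, prob = mk$stationary)
    # pre-draw uniforms; cumulative rows make the chain a lookup
    cumP <- t(apply(mk$P, 1, cumsum))
    u <- runif(length - 1)
    for (i in 2:length) {
      out[i] <- findInterval(u[i - 1], cumP[out[i - 1], ]) + 1L
    }
    paste(DNA_LETTERS[out], collapse = "")
  })
}

#' Assign context-dependent methylation states to CpG sites
#'
#' Each plus-strand CpG is methylated independently with the probability
#' of its trinucleotide context (the 3-mer starting at the C); unlisted
#' contexts default to `default_prob`. Dyad symmetry is assumed: the
#' minus-strand state mirrors the plus strand.
#'
#' @param seq Sequence string with at least one CpG.
#' @param context_meth_prob Named probabilities (e.g.
#'   `c(CGC = 0.9, CGG = 0.8, CGA = 0.5, CGT = 0.5)`).
#' @param seed Integer seed.
#' @param default_prob Probability for unlisted contexts (default 0.5).
#' @return Tibble: `position` (1-based plus-strand C position), `context`,
#'   `prob`, `methylated`.
#' @export
assign_methylation <- function(seq, context_meth_prob, seed,
                               default_prob = 0.5) {
  pos <- cpg_positions(seq)
  if (length(pos) == 0) abort("sequence contains no CpG")
  ctx <- substr_vec(seq, pos, pos + 2)
  prob <- unname(context_meth_prob[ctx])
  prob[is.na(prob)] <- default_prob
  meth <- with_seed(seed, runif(length(pos)) < prob)
  tibble(position = pos, context = ctx, prob = prob, methylated = meth)
}

cpg_positions <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  which(ch[-length(ch)] == "C" & ch[-1] == "G")
}

substr_vec <- function(seq, from, to) {
  substring(seq, from, pmin(to, nchar(seq)))
}

#' Evolve a methylated sequence by generational deamination
#'
#' Per generation, each surviving methylated CpG deaminates with
#' probability `rate`. On deamination the affected strand is chosen with
#' probability `1 - minus_strand_bias` for the plus strand (CG to TG)
#' and `minus_strand_bias` for the minus strand (read out as CG to CA on
#' the plus strand). A deaminated site is no longer a CpG and cannot fire
#' again; non-CpG positions never change — no back-mutation, selection or
#' indels.
#'
#' @param seq Ancestor sequence string.
#' @param states Methylation tibble from [assign_methylation()].
#' @param rate Per-generation deamination probability.
#' @param generations Number of generations.
#' @param seed Integer seed.
#' @param minus_strand_bias Probability the minus strand deaminates
#'   (default 0.5, strand-symmetric; raise it to emulate an
#'   APOBEC-like asymmetric pattern).
#' @return A `lineage_record` list: `ancestor`, `descendant`, `states`,
#'   `events` (tibble of position/generation/type), `n_cg_tg`, `n_cg_ca`.
#' @export
evolve_deamination <- function(seq, states, rate, generations, seed,
                               minus_strand_bias = 0.5) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  alive <- states$position[states$methylated]
  events <- list()
  with_seed(seed, {
    for (g in seq_len(generations)) {
      if (length(alive) == 0) break
      fire <- runif(length(alive)) < rate
      if (any(fire)) {
        hit <- alive[fire]
        minus <- runif(length(hit)) < minus_strand_bias
        ch[hit[!minus]] <- "T"       # plus strand: CG -> TG
        ch[hit[minus] + 1] <- "A"    # minus strand readout: CG -> CA
        events[[length(events) + 1]] <- tibble(
          position = hit, generation = g,
          type = ifelse(minus, "CG>CA", "CG>TG")
        )
        alive <- alive[!fire]
      }
    }
  })
  events <- if (length(events)) bind_rows(events) else
    tibble(position = integer(), generation = integer(), type = character())
  structure(
    list(ancestor = seq,
         descendant = paste(ch, collapse = ""),
         states = states,
         events = events,
         n_cg_tg = sum(events$type == "CG>TG"),
         n_cg_ca = sum(events$type == "CG>CA")),
    class = "lineage_record"
  )
}

#' @export
print.lineage_record <- function(x, ...) {
  cat(sprintf(
    "<lineage_record> %d bp, %d methylated CpG, events: %d CG>TG, %d CG>CA\n",
    nchar(x$ancestor), sum(x$states$methylated), x$n_cg_tg, x$n_cg_ca))
  invisible(x)
}

#' Sample a per-cytosine bisulfite report
#'
#' Emits a Bismark-style cytosine record for every cytosine on both
#' strands: coverage is Poisson with the given mean, the methylated count
#' binomial with the site's probability. CpG dyads share one probability
#' (dyad symmetry); non-CpG cytosines use `non_cpg_prob`. Trinucleotide
#' contexts are read off the sequence on the cytosine's own strand;
#' cytosines too close to the sequence end for a full 3-mer are skipped.
#'
#' @param seq Sequence string.
#' @param cpg_prob Either one probability for every CpG dyad, or a tibble
#'   (`position` of the plus-strand C, `prob`).
#' @param coverage Mean reads per site (> 0).
#' @param seed Integer seed.
#' @param seq_id Id written into the records.
#' @param non_cpg_prob Methylation probability at CHG/CHH cytosines
#'   (default 0.02, the near-zero non-CpG background of vertebrate
#'   genomes).
#' @return Cytosine-record tibble (see [read_cytosine_report()]).
#' @export
emit_cytosine_report <- function(seq, cpg_prob, coverage, seed,
                                 seq_id = "sim", non_cpg_prob = 0.02) {
  if (coverage <= 0) abort("coverage must be positive")
  L <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]

  # plus-strand cytosines with a full downstream 3-mer
  plus_pos <- which(ch == "C")
  plus_pos <- plus_pos[plus_pos + 2 <= L]
  plus_tri <- substr_vec(seq, plus_pos, plus_pos + 2)
  # minus-strand cytosines sit where the plus strand has G; their 3-mer is
  # the reverse complement of the plus-strand [pos-2, pos] window
  minus_pos <- which(ch == "G")
  minus_pos <- minus_pos[minus_pos - 2 >= 1]
  minus_tri <- revcomp_chr(substr_vec(seq, minus_pos - 2, minus_pos))

  sites <- bind_rows(
    tibble(position = plus_pos, strand = "+", trinucleotide = plus_tri),
    tibble(position = minus_pos, strand = "-", trinucleotide = minus_tri)
  ) |>
    filter(!grepl("N", .data$trinucleotide)) |>
    mutate(context_class = dplyr::case_when(
      substr(.data$trinucleotide, 2, 2) == "G" ~ "CpG",
      substr(.data$trinucleotide, 3, 3) == "G" ~ "CHG",
      TRUE ~ "CHH"
    ))

  # probability per site: CpG dyads share the plus-strand C's probability
  dyad_key <- ifelse(sites$strand == "+", sites$position, sites$position - 1L)
  if (is.data.frame(cpg_prob)) {
    stopifnot(all(c("position", "prob") %in% names(cpg_prob)))
    p <- cpg_prob$prob[match(dyad_key, cpg_prob$position)]
  } else {
    p <- rep(cpg_prob, nrow(sites))
  }
  p[sites$context_class != "CpG"] <- non_cpg_prob
  p[is.na(p)] <- non_cpg_prob

  with_seed(seed, {
    cov <- rpois(nrow(sites), coverage)
    meth <- rbinom(nrow(sites), cov, p)
  })
  sites |>
    mutate(seq_id = seq_id,
           count_methylated = meth,
           count_unmethylated = cov - meth) |>
    select(all_of(c("seq_id", "position", "strand", "count_methylated",
                    "count_unmethylated", "context_class",
                    "trinucleotide"))) |>
    arrange(.data$position, .data$strand)
}

#' Per-dyad methylation probabilities from binary states
#'
#' Maps the simulator's binary methylation states to bisulfite-readout
#' probabilities for [emit_cytosine_report()].
#'
#' @param states Tibble from [assign_methylation()].
#' @param p_methylated,p_unmethylated Readout probabilities for
#'   methylated / unmethylated dyads.
#' @return Tibble (`position`, `prob`).
#' @export
state_probs <- function(states, p_methylated = 0.95, p_unmethylated = 0.05) {
  tibble(position = states$position,
         prob = ifelse(states$methylated, p_methylated, p_unmethylated))
}

#' Implant a motif's consensus into sequences
#'
#' Overwrites each sequence with the motif consensus at a sampled (or
#' supplied) position; used to build positive controls for enrichment
#' testing.
#'
#' @param seqs Sequence tibble.
#' @param motif Motif object.
#' @param where `"random"`, a fixed 0-based start, or `"in-CGI"` (sample a
#'   start inside a called island; errors when a sequence has none).
#' @param seed Integer seed.
#' @return `seqs` with modified `seq` and a new `implant_start` column
#'   (0-based).
#' @export
implant_motifs <- function(seqs, motif, where = "random", seed) {
  w <- motif$width
  cons <- motif_consensus(motif)
  out <- seqs
  out$implant_start <- NA_integer_
  for (i in seq_len(nrow(seqs))) {
    L <- nchar(seqs$seq[i])
    if (w >= L) abort("motif width must be smaller than sequence length")
    si <- sub_seed(seed, i)
    if (identical(where, "random")) {
      start <- with_seed(si, sample.int(L - w + 1, 1)) - 1L
    } else if (identical(where, "in-CGI")) {
      isl <- find_cpg_islands(seqs$seq[i], seq_id = seqs$id[i])
      isl <- filter(isl, .data$length >= w)
      if (nrow(isl) == 0) abort(paste0("no CpG island to implant into for ",
                                       seqs$id[i]))
      row <- isl[1, ]
      start <- with_seed(si, sample(row$start:(row$end - w), 1))
    } else {
      start <- as.integer(where)
    }
    s <- seqs$seq[i]
    out$seq[i] <- paste0(substr(s, 1, start), cons,
                         substr(s, start + w + 1, L))
    out$implant_start[i] <- start
  }
  out$length <- nchar(out$seq)
  out
}

#' Simulate a panel of deaminating lineages
#'
#' The end-to-end study condition: `n_lineages` independent ancestors from
#' the calibrated Markov background, each given context-dependent
#' methylation and evolved for a generation count drawn uniformly from
#' `generations_range`. Older lineages lose more CpG and gain more
#' TpG/CpA, which is exactly the negative correlation the comparative
#' statistics are built to detect.
#'
#' @param config A [simulation_config()].
#' @return Tibble: `lineage`, `generations`, `n_meth`, `n_cg_tg`,
#'   `n_cg_ca`, `ancestor`, `descendant` (sequence strings), plus a
#'   `records` list-column of `lineage_record` objects.
#' @export
simulate_lineages <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gr <- config$generations_range
  gens <- with_seed(sub_seed(config$seed, 0),
                    sample(gr[1]:gr[2], config$n_lineages, replace = TRUE))
  purrr::map_dfr(seq_len(config$n_lineages), function(i) {
    anc <- gen_markov_sequence(config$length, config$target_cpg_oe,
                               seed = sub_seed(config$seed, i * 3 + 1))
    st <- assign_methylation(anc, config$context_meth_prob,
                             seed = sub_seed(config$seed, i * 3 + 2))
    rec <- evolve_deamination(anc, st, config$deamination_rate, gens[i],
                              seed = sub_seed(config$seed, i * 3 + 3))
    tibble(lineage = i, generations = gens[i],
           n_meth = sum(st$methylated),
           n_cg_tg = rec$n_cg_tg, n_cg_ca = rec$n_cg_ca,
           ancestor = anc, descendant = rec$descendant,
           records = list(rec))
  })
}

#' Write a complete synthetic input bundle
#'
#' Materializes one simulated study as files every other module can read:
#' a FASTA of ancestors (labelled exogenous) and descendants (labelled
#' endogenous) and a sampled cytosine report for the first descendant.
#' Generated data is indistinguishable from real inputs to the rest of
#' the pipeline.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param virus Virus label written into the FASTA headers.
#' @return Invisibly, a list with the written paths and the lineage
#'   table.
#' @export
simulate_bundle <- function(config, dir, virus = "simERV") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_lineages(config)
  seqs <- bind_rows(
    tibble(id = paste0("anc_", panel$lineage), virus = virus,
           variant_class = "exogenous", length = nchar(panel$ancestor),
           seq = panel$ancestor),
    tibble(id = paste0("des_", panel$lineage), virus = virus,
           variant_class = "endogenous", length = nchar(panel$descendant),
           seq = panel$descendant)
  )
  fasta <- file.path(dir, "sequences.fa")
  write_fasta(seqs, fasta)

  rec1 <- panel$records[[1]]
  report <- emit_cytosine_report(
    rec1$descendant,
    cpg_prob = state_probs(rec1$states),
    coverage = config$coverage,
    seed = sub_seed(config$seed, 999),
    seq_id = "des_1"
  )
  report_path <- file.path(dir, "cytosine_report.tsv")
  write_cytosine_report(report, report_path)
  invisible(list(fasta = fasta, cytosine_report = report_path,
                 panel = panel, seqs = seqs))
}
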