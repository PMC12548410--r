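#' Run the full endogenization-footprint analysis
#'
#' Orchestrates every stage over one YAML (or list) configuration:
#' D-ratio tables and group medians, endogenous-vs-exogenous rank tests,
#' deamination-signature correlations, CpG islands, methylation summaries,
#' hypermutation scan, and motif enrichment. Stages whose inputs are
#' absent from the config are skipped with a logged notice, not a crash;
#' a run manifest (parameters, seed, input checksums, package version) is
#' written alongside the outputs so a rerun is byte-reproducible.
#'
#' Config keys (all optional except `fasta`): `fasta` (path; headers or
#' `manifest` carry group labels), `motifs_kmer` (character vector,
#' default the CpG/TpG/CpA panel plus CGX/deamination trinucleotides),
#' `cytosine_report` (path), `seq_length` (for the methylation track),
#' `aligned_fasta` (pre-aligned set for the hypermutation scan),
#' `meme_motifs` (path), `control_fasta` (enrichment control set),
#' `cgi` (list: window, min_length, oe_min, gc_min), `out_dir`, `seed`.
#'
#' @param config Path to a YAML file or a named list.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$fasta)) abort("config must name a FASTA input ('fasta')")
  if (!file.exists(config$fasta)) {
    abort(paste0("fasta input does not exist: ", config$fasta))
  }
  out_dir <- config$out_dir %||% "ervfootprint_results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  motifs_kmer <- config$motifs_kmer %||%
    c("CG", "TG", "CA", "CGA", "CGC", "CGG", "CGT", "TGC", "CAC")
  say <- function(...) message("[ervfootprint] ", ...)
  written <- character()
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(x, p)
    written <<- c(written, p)
    p
  }

  seqs <- read_fasta(config$fasta, manifest = config$manifest)
  say("loaded ", nrow(seqs), " sequences")

  # --- D-ratios and group statistics -------------------------------------
  dr <- d_ratio_table(seqs, motifs_kmer)
  emit(dr, "dratio_table.tsv")
  emit(d_ratio_medians(dr), "dratio_medians.tsv")

  classes <- unique(dr$variant_class)
  if (length(classes) >= 2) {
    tests <- purrr::map_dfr(motifs_kmer, function(m) {
      sub <- filter(dr, .data$motif == m, !.data$undefined)
      tab <- table(sub$variant_class)
      if (length(tab) < 2 || any(tab < 2)) return(tibble())
      glance(group_compare(sub, "d_ratio", "variant_class")) |>
        mutate(motif = m, .before = 1)
    })
    emit(tests, "group_tests.tsv")
  } else {
    say("single variant class; group tests skipped")
  }

  corr <- purrr::map_dfr(
    list(c("CG", "TG", "CA"), c("CGC", "TGC", "CAC")),
    function(trip) {
      res <- tryCatch(
        deamination_correlation(dr, trip[1], trip[2:3]),
        error = function(e) NULL
      )
      if (is.null(res)) return(tibble())
      tidy(res) |> mutate(x_motif = trip[1],
                          y_motifs = paste(trip[2:3], collapse = "/"))
    }
  )
  emit(corr, "deamination_correlations.tsv")

  # --- CpG islands -------------------------------------------------------
  cgi_par <- config$cgi %||% list()
  window <- cgi_par$window %||% 100
  islands <- purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    if (seqs$length[i] < window) return(tibble())
    find_cpg_islands(seqs$seq[i], window = window,
                     min_length = cgi_par$min_length %||% 200,
                     oe_min = cgi_par$oe_min %||% 0.6,
                     gc_min = cgi_par$gc_min %||% 50,
                     seq_id = seqs$id[i])
  })
  emit(islands, "cpg_islands.tsv")
  if (nrow(islands) > 0) {
    bed <- islands |>
      mutate(name = paste0("CGI_", dplyr::row_number()),
             score = round(.data$mean_oe, 3))
    write_bed(bed, file.path(out_dir, "cpg_islands.bed"))
    written <- c(written, file.path(out_dir, "cpg_islands.bed"))
  }

  # --- Methylation summaries (needs a cytosine report) -------------------
  meth_median <- NA_real_
  if (!is.null(config$cytosine_report) && file.exists(config$cytosine_report)) {
    rec <- read_cytosine_report(config$cytosine_report)
    ctx <- context_methylation(rec)
    emit(ctx$summary, "context_methylation.tsv")
    sl <- config$seq_length %||%
      (seqs$length[match(rec$seq_id[1], seqs$id)] %||% max(rec$position))
    if (is.na(sl)) sl <- max(rec$position)
    trk <- provirus_track(rec, seq_length = sl)
    emit(tidy(trk), "methylation_track.tsv")
    meth_median <- trk$median_percent
  } else {
    say("no cytosine report configured; methylation stage skipped")
  }

  # --- Hypermutation (needs an aligned set) ------------------------------
  if (!is.null(config$aligned_fasta) && file.exists(config$aligned_fasta)) {
    aligned <- read_fasta(config$aligned_fasta)
    emit(hypermut_scan(aligned), "hypermut.tsv")
  } else {
    say("no aligned set configured; hypermutation stage skipped")
  }

  # --- Motif enrichment (needs motifs + control set) ---------------------
  if (!is.null(config$meme_motifs) && file.exists(config$meme_motifs) &&
      !is.null(config$control_fasta) && file.exists(config$control_fasta)) {
    motifs <- read_meme_motifs(config$meme_motifs)
    control <- read_fasta(config$control_fasta)
    emit(sea_enrich(seqs, control, motifs), "motif_enrichment.tsv")
  } else {
    say("motif enrichment inputs not configured; stage skipped")
  }

  manifest <- list(
    package = "ervfootprint",
    version = as.character(utils::packageVersion("ervfootprint")),
    seed = seed,
    parameters = config[setdiff(names(config), "out_dir")],
    inputs = lapply(
      Filter(function(p) is.character(p) && length(p) == 1 && file.exists(p),
             config[c("fasta", "cytosine_report", "aligned_fasta",
                      "meme_motifs", "control_fasta")]),
      function(p) unname(tools::md5sum(p))
    ),
    outputs = basename(written),
    overall_methylation_median = meth_median
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", length(written), " output tables in ", out_dir)
  invisible(manifest)
}
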