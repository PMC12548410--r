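# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain string scans and direct formula transcription.

# All length-k windows of a sequence as a character vector.
windows_of <- function(seq, k) {
  L <- nchar(seq)
  if (k > L) return(character(0))
  substring(seq, 1:(L - k + 1), k:L)
}

# Frequency of a k-mer over N-free windows of its own length.
naive_freq <- function(seq, kmer) {
  w <- windows_of(seq, nchar(kmer))
  w <- w[!grepl("N", w, fixed = TRUE)]
  if (length(w) == 0) return(NA_real_)
  sum(w == kmer) / length(w)
}

# Direct D-ratio: product form for 2-mers, first-order Markov for 3-mers.
naive_dratio <- function(seq, motif) {
  p_obs <- naive_freq(seq, motif)
  if (nchar(motif) == 2) {
    p_exp <- naive_freq(seq, substr(motif, 1, 1)) *
      naive_freq(seq, substr(motif, 2, 2))
  } else {
    py <- naive_freq(seq, substr(motif, 2, 2))
    if (is.na(py) || py == 0) return(list(p_obs = p_obs, p_exp = NA_real_,
                                          d = NA_real_))
    p_exp <- naive_freq(seq, substr(motif, 1, 2)) *
      naive_freq(seq, substr(motif, 2, 3)) / py
  }
  d <- if (is.na(p_exp) || p_exp == 0) NA_real_ else p_obs / p_exp
  list(p_obs = p_obs, p_exp = p_exp, d = d)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
enum_mw_p <- function(g1, g2) {
  x <- c(g1, g2)
  n1 <- length(g1)
  r <- rank(x)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- combn(length(x), n1, u_of)
  mu <- n1 * length(g2) / 2
  if (u_obs > mu) {
    min(1, 2 * mean(us >= u_obs))
  } else {
    min(1, 2 * mean(us <= u_obs))
  }
}

# One-sided Fisher p by direct hypergeometric summation.
enum_fisher_p <- function(pm, pt, cm, ct) {
  M <- pm + cm
  ks <- max(pm, M - ct):min(pt, M)
  ks <- ks[ks >= pm]
  sum(choose(pt, ks) * choose(ct, M - ks)) / choose(pt + ct, M)
}

# Random test sequence with optional N contamination.
random_seq <- function(L, n_frac = 0) {
  letters <- c("A", "C", "G", "T")
  s <- sample(letters, L, replace = TRUE)
  if (n_frac > 0) {
    idx <- sample(L, max(1, round(L * n_frac)))
    s[idx] <- "N"
  }
  paste(s, collapse = "")
}

# Minimal sequence tibble for functions that want the FASTA layout.
seq_tbl <- function(seqs, virus = "v", klass = "unknown",
                    ids = paste0("s", seq_along(seqs))) {
  tibble::tibble(id = ids, virus = virus, variant_class = klass,
                 length = nchar(seqs), seq = seqs)
}

# A MEME minimal file written from scratch (independent of the package's
# writer) for parser tests.
write_meme_fixture <- function(path, with_background = TRUE,
                               break_row = FALSE) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "")
  if (with_background) {
    lines <- c(lines, "Background letter frequencies",
               "A 0.3 C 0.2 G 0.2 T 0.3", "")
  }
  row3 <- if (break_row) "0.7 0.7 0 0" else "0 0 1 0"
  lines <- c(lines,
             "MOTIF m1",
             "letter-probability matrix: alength= 4 w= 4 nsites= 10 E= 0",
             "1 0 0 0", "0 1 0 0", row3, "0 0 0 1", "")
  writeLines(lines, path)
  path
}
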