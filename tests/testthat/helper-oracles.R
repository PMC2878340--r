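# Independent oracles used to cross-check the package's scanning and
# column-comparison code. Deliberately written with different primitives
# (per-character loops on substring()) than the implementation.

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# All-offsets brute-force in-silico PCR: every forward offset x every
# reverse offset, counting mismatches character by character.
brute_force_pcr <- function(fwd, rev, template, constraints) {
  n <- nchar(template)
  site_scan <- function(primer, window_at_start) {
    m <- nchar(primer)
    k <- constraints$three_prime_k
    hits <- integer(0)
    if (n < m) return(hits)
    for (s in seq_len(n - m + 1L)) {
      mm_win <- 0L
      mm_out <- 0L
      for (i in seq_len(m)) {
        if (substring(primer, i, i) != substring(template, s + i - 1L, s + i - 1L)) {
          in_win <- if (window_at_start) i <= k else i > m - k
          if (in_win) mm_win <- mm_win + 1L else mm_out <- mm_out + 1L
        }
      }
      if (mm_win == 0L && mm_out <= constraints$max_internal_mismatches) {
        hits <- c(hits, s)
      }
    }
    hits
  }
  f_sites <- site_scan(fwd, window_at_start = FALSE)
  r_sites <- site_scan(oracle_revcomp(rev), window_at_start = TRUE)
  out <- data.frame(start = integer(), end = integer(), size = integer())
  for (fs in f_sites) {
    for (rs in r_sites) {
      re <- rs + nchar(rev) - 1L
      size <- re - fs + 1L
      if (rs >= fs && size >= constraints$product_window[1L] &&
          size <= constraints$product_window[2L]) {
        out <- rbind(out, data.frame(start = fs, end = re, size = size))
      }
    }
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force discriminating-column scan over an equal-length family.
brute_force_disc <- function(db, target) {
  rec <- db$records[[target]]
  others <- setdiff(names(db$records), target)
  coords <- integer(0)
  for (i in seq_len(nchar(rec$cdna))) {
    b <- substring(rec$cdna, i, i)
    if (b == "-") next
    all_diff <- TRUE
    for (a in others) {
      ob <- substring(db$records[[a]]$cdna, i, i)
      if (ob == "-" || ob == b) { all_diff <- FALSE; break }
    }
    if (all_diff) coords <- c(coords, index_to_coord(rec, i))
  }
  sort(coords)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Two-locus toy FASTA used by the parser tests.
toy_fasta <- function() {
  paste(
    ">HLA:A0201 A*02:01 24 bp atg=5",
    "ACGCAATGGCTCTAGGCTTACGTA",
    ">HLA:A0301 A*03:01 24 bp atg=5",
    "ACGCAATGGCTCTAGCCTTACGTA",
    sep = "\n")
}
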