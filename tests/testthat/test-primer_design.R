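test_that("amplicon length follows the label-subtraction convention", {
  expect_equal(amplicon_length_from_labels(272, 383), 111L)
  expect_equal(amplicon_length_from_labels(522, 621), 99L)
  # ATG-straddling labels: plain subtraction still applies
  expect_equal(amplicon_length_from_labels(-2, 1063), 1065L)
  expect_error(amplicon_length_from_labels(0, 100), "no-zero")
  expect_error(amplicon_length_from_labels(100, 50), "exceed")
})

test_that("designed pair labels reproduce the amplicon length", {
  fam <- gen_allele_family(seed = 3, n_loci = 2, n_alleles = 4, length = 600)
  res <- design_allele_specific(fam$db, "A*01:01")
  expect_equal(res$status, "ok")
  for (pp in res$pairs) {
    expect_equal(pp$label_len, pp$amplicon_len)
  }
})

test_that("in-silico PCR honours perfect-match ends and the 3' block rule", {
  set.seed(11)
  template <- random_dna(60)
  fwd <- substr(template, 1, 8)
  rev <- oracle_revcomp(substr(template, 53, 60))
  cons <- design_constraints()
  prod <- in_silico_pcr(fwd, rev, template, cons)
  expect_equal(prod, brute_force_pcr(fwd, rev, template, cons))
  expect_true(any(prod$size == 60))

  # mutating the base under the forward primer's 3' terminus kills the site
  ch <- strsplit(template, "")[[1]]
  ch[8] <- setdiff(c("A", "C", "G", "T"), ch[8])[1]
  mut <- paste(ch, collapse = "")
  expect_equal(nrow(in_silico_pcr(fwd, rev, mut, cons)), 0L)
})

test_that("in-silico PCR equals the brute-force all-offsets oracle", {
  set.seed(99)
  cons <- design_constraints(product_window = c(30L, 2000L))
  for (i in 1:10) {
    template <- random_dna(500)
    # primers lifted from the template with up to 2 mutations planted
    fs <- sample(1:430, 1)
    fl <- sample(15:22, 1)
    fwd <- substr(template, fs, fs + fl - 1L)
    rs <- sample((fs + 30):470, 1)
    rl <- sample(15:22, 1)
    rev <- oracle_revcomp(substr(template, rs, rs + rl - 1L))
    mutate <- function(p) {
      ch <- strsplit(p, "")[[1]]
      for (j in sample(seq_along(ch), sample(0:2, 1))) {
        ch[j] <- sample(c("A", "C", "G", "T"), 1)
      }
      paste(ch, collapse = "")
    }
    fwd <- mutate(fwd); rev <- mutate(rev)
    expect_equal(in_silico_pcr(fwd, rev, template, cons),
                 brute_force_pcr(fwd, rev, template, cons),
                 info = sprintf("case %d", i))
  }
})

test_that("cross-reactivity finds conserved-region pairs and spares AS pairs", {
  fam <- gen_allele_family(seed = 5, n_loci = 2, n_alleles = 4, length = 600)
  db <- fam$db
  # primers lifted from the locus-private 5'UTR of A*01:01 bind every A
  # allele (UTRs are identical within a locus) but no B allele
  tmpl <- db$records[["A*01:01"]]$cdna
  pp <- primer_pair(substr(tmpl, 1, 20),
                    oracle_revcomp(substr(tmpl, 35, 54)),
                    target = "A*01:01")
  xr <- cross_reactivity(pp, db, design_constraints(product_window = c(50L, 500L)))
  expect_setequal(xr, c("A*02:01", "A*03:01", "A*04:01"))

  # a single-allele database has no comparison set
  db1 <- allele_database(db$records["A*01:01"])
  expect_length(cross_reactivity(pp, db1), 0L)
})

test_that("designed assays anchor the 3' terminus on the engineered SNP", {
  fam <- gen_allele_family(seed = 3, n_loci = 2, n_alleles = 4, length = 600)
  tg <- "A*01:01"
  res <- design_allele_specific(fam$db, tg)
  expect_equal(res$status, "ok")
  snp_idx <- fam$truth$engineered$index[fam$truth$engineered$allele == tg]
  tmpl <- fam$db$records[[tg]]$cdna
  top <- res$pairs[[1L]]
  fwd_at <- as.integer(regexpr(top$forward$sequence, tmpl, fixed = TRUE))
  rev_at <- as.integer(regexpr(oracle_revcomp(top$reverse$sequence), tmpl,
                               fixed = TRUE))
  fwd_3p <- fwd_at + nchar(top$forward$sequence) - 1L
  expect_true(fwd_3p == snp_idx || rev_at == snp_idx)
})

test_that("a target identical to another allele is undesignable", {
  seqs <- paste0(strrep("C", 40), "ATG", random_dna(300))
  db <- allele_database(list(
    allele_record("A*01:01", seqs, 41L),
    allele_record("A*01:02", seqs, 41L)))
  res <- design_allele_specific(db, "A*01:01")
  expect_equal(res$status, "undesignable")
  expect_length(res$pairs, 0L)
})

test_that("an isolated discriminating site with no partner window fails on the amplicon bound", {
  # discriminating base 30 nt from the 3' end: no 70-120 bp partner window
  # fits on the template downstream, and none upstream either
  set.seed(13)
  base <- paste0(strrep("C", 40), "ATG", random_dna(40, gc = 0.6))
  db <- allele_database(list(
    allele_record("A*01:01", paste0(base, "A", strrep("G", 9)), 41L),
    allele_record("A*02:01", paste0(base, "C", strrep("G", 9)), 41L)))
  res <- design_allele_specific(db, "A*01:01",
                                design_constraints(tm_tol = 40))
  expect_equal(res$status, "no_pair")
  expect_gt(res$failure_counts[["amplicon"]], 0L)
})

test_that("design results tabulate and export as TSV", {
  fam <- gen_allele_family(seed = 3, n_loci = 2, n_alleles = 4, length = 600)
  res <- design_allele_specific(fam$db, "A*01:01")
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- design_table(res, path)
  expect_equal(nrow(tab), length(res$pairs))
  expect_equal(tab$rev_label - tab$fwd_label, tab$amplicon_bp)
  re <- read.delim(path)
  expect_equal(re$fwd_seq, tab$fwd_seq)
})

test_that("the designer is deterministic", {
  fam <- gen_allele_family(seed = 8, n_loci = 2, n_alleles = 4, length = 600)
  r1 <- design_allele_specific(fam$db, "B*02:01")
  r2 <- design_allele_specific(fam$db, "B*02:01")
  expect_identical(r1, r2)
})

test_that("the independent validator passes designed pairs and rejects published out-of-bound ones", {
  fam <- gen_allele_family(seed = 3, n_loci = 2, n_alleles = 4, length = 600)
  res <- design_allele_specific(fam$db, "A*01:01")
  rep <- validate_pair(res$pairs[[1L]], fam$db)
  expect_true(all(rep$pass[!is.na(rep$pass)]))

  # the published A*03:01 assay: labels 508/636 give a 128 bp fragment,
  # outside the stated 70-120 bp bound
  pub <- primer_pair(
    primer("AAGTGGGAGGCGGCCCATGA", "forward", label_coord = 508L),
    primer("ATGTGTCTTGGGGGGGTCCGT", "reverse", label_coord = 636L),
    target = "A*03:01")
  rep <- validate_pair(pub)
  amp_row <- rep[rep$constraint == "amplicon", ]
  expect_false(amp_row$pass)
  expect_equal(amp_row$observed, "128")

  short <- primer_pair(primer("ACGTACGTACGTACGT", "forward"),
                       primer("TGCATGCATGCATGCATGCA", "reverse"))
  rep <- validate_pair(short)
  expect_false(rep$pass[rep$constraint == "forward_length"])
})

test_that("locus-specific long-range design covers every junction", {
  fam <- gen_allele_family(seed = 1)
  ld <- design_locus_specific(fam$db, "A")
  expect_equal(ld$status, "ok")
  expect_equal(nrow(ld$splice$junctions_covered), 7L)  # 8 exons
  expect_equal(ld$splice$full_length_size, ld$pair$amplicon_len)
  expect_true(all(ld$splice$skip_variant_sizes < ld$splice$full_length_size))

  # primers are conserved within the locus and absent from the others
  a_alleles <- fam$db$locus_index$A
  for (a in a_alleles) {
    tmpl <- fam$db$records[[a]]$cdna
    expect_true(grepl(ld$pair$forward$sequence, tmpl, fixed = TRUE))
    expect_true(grepl(oracle_revcomp(ld$pair$reverse$sequence), tmpl,
                      fixed = TRUE))
  }
  for (b in setdiff(names(fam$db$records), a_alleles)) {
    expect_equal(nrow(in_silico_pcr(ld$pair$forward, ld$pair$reverse,
                                    fam$db$records[[b]]$cdna,
                                    long_range_constraints())), 0L)
  }
})

test_that("splice-variant size prediction is exon arithmetic", {
  rec <- allele_record(
    "A*01:01", paste0(strrep("T", 40), "ATG", strrep("A", 837)), 41L,
    exons = cbind(start = c(41L, 141L, 411L), end = c(140L, 410L, 880L)))
  sc <- splice_check(rec, amp_start = 30L, amp_end = 880L)
  expect_equal(nrow(sc$junctions_covered), 2L)
  expect_equal(sc$full_length_size, 851L)
  # skipping the 270 bp middle exon
  expect_equal(unname(sc$skip_variant_sizes["exon2"]), 851L - 270L)
})
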