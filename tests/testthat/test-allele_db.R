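test_that("multi-FASTA parsing builds a locus-indexed database", {
  db <- parse_allele_fasta(toy_fasta())
  expect_s3_class(db, "allele_db")
  expect_length(db, 2L)
  expect_named(db$locus_index, "A")
  expect_setequal(db$locus_index$A, c("A*02:01", "A*03:01"))
  rec <- db$records[["A*02:01"]]
  expect_equal(rec$atg_pos, 6L)  # header atg= is 0-based
  expect_equal(substr(rec$cdna, rec$atg_pos, rec$atg_pos + 2L), "ATG")
})

test_that("parser applies the alphabet policy and rejects bad records", {
  # lower case and U are folded into uppercase DNA; ATG found by scan
  db <- parse_allele_fasta(">x A*01:01 9 bp\nacguaUGTA")
  expect_equal(db$records[["A*01:01"]]$cdna, "ACGTATGTA")
  expect_equal(db$records[["A*01:01"]]$atg_pos, 5L)

  expect_error(parse_allele_fasta(">x A*01:01 6 bp\nCCCCCC"), "no ATG")
  expect_error(parse_allele_fasta(">x A*01:01 6 bp\nATGXCC"), "A\\*01:01")
  expect_error(
    parse_allele_fasta(">x A*01:01 6 bp\nATGCCC\n>y A*01:01 6 bp\nATGCCC"),
    "duplicate")
  expect_error(parse_allele_fasta(">x no-name-here\nATGCCC"), "allele name")
})

test_that("FASTA round trip preserves every field", {
  fam <- gen_allele_family(seed = 11, n_loci = 2, n_alleles = 3, length = 400)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_allele_fasta(fam$db, path)
  db2 <- parse_allele_fasta(path)
  expect_identical(names(db2$records), names(fam$db$records))
  for (a in names(fam$db$records)) {
    expect_identical(db2$records[[a]]$cdna, fam$db$records[[a]]$cdna)
    expect_identical(db2$records[[a]]$atg_pos, fam$db$records[[a]]$atg_pos)
    expect_identical(db2$records[[a]]$exons, fam$db$records[[a]]$exons)
  }
  # write -> parse -> write is byte-stable
  path2 <- withr::local_tempfile(fileext = ".fasta")
  write_allele_fasta(db2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("ATG-anchored coordinates convert and round-trip", {
  rec <- allele_record("A*01:01", paste0(strrep("C", 30), "ATG", strrep("G", 500)),
                       atg_pos = 31L)
  expect_equal(coord_to_index(rec, 1L), 31L)
  expect_equal(coord_to_index(rec, -1L), 30L)
  # a primer starting at +272 on a record whose ATG is the 31st base
  expect_equal(coord_to_index(rec, 272L), 302L)
  expect_error(coord_to_index(rec, 0L), "0")
  expect_error(coord_to_index(rec, 10000L), "outside")

  idx <- seq_len(nchar(rec$cdna))
  expect_equal(coord_to_index(rec, index_to_coord(rec, idx)), idx)
  coords <- setdiff(-30:50, 0L)
  expect_equal(index_to_coord(rec, coord_to_index(rec, coords)), coords)
})

test_that("discriminating positions match a single mismatch column", {
  db <- allele_database(list(
    allele_record("A*01:01", "ATGCA", 1L),
    allele_record("A*02:01", "ATGTA", 1L)))
  expect_equal(discriminating_positions(db, "A*01:01"), 4L)
  expect_equal(discriminating_positions(db, "A*02:01"), 4L)

  # identical sequences admit no discriminating site
  db2 <- allele_database(list(
    allele_record("A*01:01", "ATGCA", 1L),
    allele_record("A*02:01", "ATGCA", 1L)))
  expect_length(discriminating_positions(db2, "A*01:01"), 0L)

  db3 <- allele_database(list(allele_record("A*01:01", "ATGCA", 1L)))
  expect_warning(res <- discriminating_positions(db3, "A*01:01"),
                 "no comparison")
  expect_length(res, 0L)
  expect_error(discriminating_positions(db, "B*99:99"), "not found")
})

test_that("discriminating positions equal the brute-force column scan", {
  n_alleles <- c(2L, 3L, 4L, 5L, 3L, 2L)
  for (seed in 1:6) {
    fam <- gen_allele_family(seed = seed, n_loci = 2,
                             n_alleles = n_alleles[seed],
                             length = 450, snp_rate = 0.01)
    for (a in names(fam$db$records)) {
      expect_identical(discriminating_positions(fam$db, a),
                       brute_force_disc(fam$db, a),
                       info = sprintf("seed %d allele %s", seed, a))
    }
  }
})

test_that("gap columns map to no position", {
  db <- allele_database(list(
    allele_record("A*01:01", "ATG-CAA", 1L),
    allele_record("A*02:01", "ATGACAT", 1L)))
  # position 4 is gapped in the target, position 7 discriminates
  expect_equal(discriminating_positions(db, "A*01:01"), 7L)
})

test_that("discrimination table reports target and other bases", {
  db <- allele_database(list(
    allele_record("A*01:01", "ATGCA", 1L),
    allele_record("A*02:01", "ATGTA", 1L),
    allele_record("B*01:01", "ATGGA", 1L)))
  tab <- discrimination_table(db)
  expect_setequal(tab$allele, c("A*01:01", "A*02:01", "B*01:01"))
  row <- tab[tab$allele == "A*01:01", ]
  expect_equal(row$coord, 4L)
  expect_equal(row$target_base, "C")
  expect_equal(row$other_bases, "G/T")
})
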