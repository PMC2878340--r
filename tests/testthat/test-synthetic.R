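test_that("the default family has the documented structure", {
  fam <- gen_allele_family(seed = 1)
  expect_length(fam$db, 12L)
  expect_named(fam$db$locus_index, c("A", "B", "C"))
  expect_equal(nrow(fam$truth$engineered), 12L)
  expect_equal(fam$truth$atg_pos, 61L)
  expect_equal(nrow(fam$truth$exons), 8L)
  lens <- vapply(fam$db$records, function(r) nchar(r$cdna), 0L)
  expect_true(all(lens == 1200L))
  # exons partition the coding portion
  ex <- fam$truth$exons
  expect_equal(unname(ex[1, "start"]), fam$truth$atg_pos)
  expect_equal(unname(ex[nrow(ex), "end"]), 1200L - 60L)
})

test_that("engineered sites are exactly the discriminating positions", {
  fam <- gen_allele_family(seed = 2)
  for (a in names(fam$db$records)[c(1, 5, 9, 12)]) {
    truth_coord <- sort(fam$truth$engineered$coord[fam$truth$engineered$allele == a])
    expect_identical(discriminating_positions(fam$db, a), truth_coord,
                     info = a)
  }
})

test_that("zero SNP rate and no engineered sites give identical alleles per locus", {
  fam <- gen_allele_family(seed = 3, snp_rate = 0, engineered_sites = 0)
  for (loc in names(fam$db$locus_index)) {
    seqs <- vapply(fam$db$records[fam$db$locus_index[[loc]]],
                   `[[`, "", "cdna")
    expect_length(unique(seqs), 1L)
  }
  # cross-locus divergence remains
  firsts <- vapply(fam$db$locus_index, function(a) fam$db$records[[a[1]]]$cdna, "")
  expect_length(unique(firsts), 3L)
})

test_that("generation is deterministic and streams are independent", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fasta"); f2 <- file.path(d, "b.fasta")
  write_allele_fasta(gen_allele_family(seed = 5)$db, f1)
  write_allele_fasta(gen_allele_family(seed = 5)$db, f2)
  expect_identical(readLines(f1), readLines(f2))

  # interleaving another generator does not perturb a stream's draws
  q1 <- gen_qpcr_run(seed = 9)
  invisible(gen_bead_panel(seed = 9))
  invisible(gen_cdc_counts(seed = 9))
  q2 <- gen_qpcr_run(seed = 9)
  expect_identical(q1, q2)
})

test_that("infeasible family specs are rejected", {
  expect_error(gen_allele_family(seed = 1, n_loci = 10, n_alleles = 40,
                                 length = 300, utr5 = 40, utr3 = 40),
               "engineered")
  expect_error(gen_allele_family(seed = 1, length = 200), "length")
})

test_that("forward models invert exactly without noise", {
  qp <- gen_qpcr_run(seed = 6, noise_sd_ct = 0)
  run <- analyze_qpcr_run(qp$wells, plasmid_bp = 4031)
  expect_equal(run$curves[["FBXL12"]]$slope,
               unname(qp$truth$slope["FBXL12"]), tolerance = 1e-9)

  bp <- gen_bead_panel(seed = 6, cv = 0)
  cal <- fit_bead_calibration(bp$beads$abc, bp$beads$mfi)
  expect_equal(cal$slope, bp$truth$slope, tolerance = 1e-9)
  expect_equal(cal$intercept, bp$truth$intercept, tolerance = 1e-9)
})

test_that("binomial CDC wells reproduce the published negative call", {
  cd <- gen_cdc_counts(seed = 7, p_kill = c(anti_B = 0.28), n_cells = 200,
                       wells = 6)
  r <- aggregate_and_call(cd$wells$red, cd$wells$green, threshold = 50)
  expect_equal(r$call, "negative")
})

test_that("the default scenario writes a complete fixture set", {
  d <- withr::local_tempdir()
  sc <- simulate_scenario(seed = 1, outdir = d)
  expect_setequal(list.files(d),
                  c("alleles.fasta", "wells.tsv", "beads.tsv", "samples.tsv",
                    "cdc.tsv", "truth.json"))
  expect_length(sc$db, 12L)
  expect_equal(length(unique(sc$wells$target)), 7L)  # 6 alleles + reference
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$seed, 1L)
})
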