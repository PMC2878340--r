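# Seeded synthetic-data generators. Every generator is a pure function of
# (spec, seed) with its own named sub-stream of the master seed, so adding
# one generator never perturbs another's draws, and each returns the data
# together with the ground truth needed for recovery tests.

.STREAM_OFFSETS <- c(alleles = 101L, qpcr = 211L, beads = 307L,
                     cells = 401L, cdc = 503L)

# Documented stream-splitting rule: sub-seed = (seed * 7919 + offset) mod
# (2^31 - 1), one fixed offset per assay stream.
.stream_seed <- function(seed, stream) {
  offset <- .STREAM_OFFSETS[[stream]]
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic polymorphic allele family
#'
#' Builds an equal-length, ungapped cDNA family over several loci that has
#' the structural properties an allele-specific designer needs: a shared
#' ancestral coding sequence, per-locus divergence (cross-locus divergence
#' exceeding within-locus divergence), locus-private UTRs (so
#' locus-specific long-range primers can anchor there), a fixed ATG with at
#' least 40 nt of 5'UTR (so negative ATG-anchored coordinates are
#' exercised), an exon model, and exactly `engineered_sites` positions per
#' allele at which that allele differs from every other allele in the
#' family -- the ground-truth discriminating positions.
#'
#' Within-locus random polymorphisms (rate `snp_rate`) are shared by two
#' alleles of the locus, mimicking lineage-shared polymorphism, so they
#' never create additional discriminating positions; they require at least
#' 4 alleles per locus and are omitted otherwise.
#'
#' @param seed master seed; the generator draws from its own sub-stream.
#' @param n_loci,n_alleles loci and alleles per locus.
#' @param length sequence length, nt (>= 300).
#' @param snp_rate per-position probability of a shared within-locus SNP.
#' @param engineered_sites unique discriminating SNPs per allele (0
#'   disables them).
#' @param exon_count exons in the coding-region model.
#' @param utr5,utr3 UTR lengths, nt (`utr5 >= 40`).
#' @param locus_divergence per-position substitution rate between loci.
#' @param gc GC content of generated sequence (HLA class I cDNA is GC-rich,
#'   hence the 0.62 default, which also makes a 66 degree Tm target
#'   reachable at 17-25 nt).
#' @return list with `db` (an [allele_database()]) and `truth` (seed,
#'   parameters, `atg_pos`, `exons`, and the `engineered` table of
#'   allele/index/coord/base).
#' @export
gen_allele_family <- function(seed = 1, n_loci = 3, n_alleles = 4,
                              length = 1200, snp_rate = 0.002,
                              engineered_sites = 1, exon_count = 8,
                              utr5 = 60, utr3 = 60,
                              locus_divergence = 0.04, gc = 0.62) {
  stopifnot(length >= 300, utr5 >= 40, utr3 >= 0, n_loci >= 1,
            n_alleles >= 1, engineered_sites >= 0, exon_count >= 1)
  coding_len <- length - utr5 - utr3
  if (coding_len < exon_count * 10L) {
    stop("sequence too short for the requested exon model", call. = FALSE)
  }
  .with_seed(.stream_seed(seed, "alleles"), {
    ancestor <- .sample_bases(coding_len, gc)
    ancestor[1:3] <- c("A", "T", "G")

    margin <- 30L
    eligible <- setdiff(seq(margin + 1L, coding_len - margin), 1:3)
    n_eng <- n_loci * n_alleles * engineered_sites
    if (n_eng > length(eligible)) {
      stop("more engineered sites requested than eligible positions",
           call. = FALSE)
    }
    eng_pos <- sample(eligible, n_eng)

    loci <- LETTERS[seq_len(n_loci)]
    mutable <- setdiff(seq(4L, coding_len), eng_pos)
    alt_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

    locus_coding <- list()
    locus_utr5 <- list()
    locus_utr3 <- list()
    for (loc in loci) {
      cs <- ancestor
      mut <- mutable[runif(length(mutable)) < locus_divergence]
      for (p in mut) cs[p] <- alt_base(cs[p])
      locus_coding[[loc]] <- cs
      locus_utr5[[loc]] <- .sample_bases(utr5, gc)
      locus_utr3[[loc]] <- .sample_bases(utr3, gc)
    }

    allele_names <- as.vector(t(outer(loci, seq_len(n_alleles),
                                      function(l, j) sprintf("%s*%02d:01", l, j))))
    allele_seqs <- list()
    eng_rows <- list()
    snp_rows <- list()
    i_eng <- 0L
    for (loc in loci) {
      shared <- NULL
      if (n_alleles >= 4L) {
        pos <- mutable[runif(length(mutable)) < snp_rate]
        shared <- lapply(pos, function(p) {
          list(pos = p, base = alt_base(locus_coding[[loc]][p]),
               carriers = sample(seq_len(n_alleles), 2L))
        })
        for (sp in shared) {
          snp_rows[[length(snp_rows) + 1L]] <- data.frame(
            locus = loc, index = utr5 + sp$pos, base = sp$base,
            carriers = paste(sp$carriers, collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
      for (j in seq_len(n_alleles)) {
        cs <- locus_coding[[loc]]
        for (sp in shared) {
          if (j %in% sp$carriers) cs[sp$pos] <- sp$base
        }
        for (s in seq_len(engineered_sites)) {
          i_eng <- i_eng + 1L
          p <- eng_pos[i_eng]
          b <- alt_base(ancestor[p])  # all non-target alleles keep the ancestor base
          cs[p] <- b
          eng_rows[[i_eng]] <- data.frame(
            allele = sprintf("%s*%02d:01", loc, j),
            index = utr5 + p, coord = p, base = b,
            ancestral = ancestor[p], stringsAsFactors = FALSE)
        }
        allele_seqs[[sprintf("%s*%02d:01", loc, j)]] <- paste(
          c(locus_utr5[[loc]], cs, locus_utr3[[loc]]), collapse = "")
      }
    }

    atg_pos <- utr5 + 1L
    w <- rep(coding_len %/% exon_count, exon_count)
    rem <- coding_len %% exon_count
    if (rem > 0L) w[seq_len(rem)] <- w[seq_len(rem)] + 1L
    ends <- atg_pos - 1L + cumsum(w)
    exons <- cbind(start = c(atg_pos, ends[-exon_count] + 1L), end = ends)

    records <- lapply(allele_names, function(a) {
      allele_record(a, allele_seqs[[a]], atg_pos, exons = exons)
    })
    db <- allele_database(records)
    eng <- do.call(rbind, eng_rows)
    truth <- list(
      seed = seed,
      params = list(n_loci = n_loci, n_alleles = n_alleles, length = length,
                    snp_rate = snp_rate, engineered_sites = engineered_sites,
                    exon_count = exon_count, utr5 = utr5, utr3 = utr3,
                    locus_divergence = locus_divergence, gc = gc),
      atg_pos = atg_pos,
      exons = exons,
      engineered = eng,
      shared_snps = if (length(snp_rows) > 0L)
        unique(do.call(rbind, snp_rows)) else NULL)
    list(db = db, truth = truth)
  })
}

#' Generate a synthetic qPCR run with known truth
#'
#' Forward-simulates exactly the model [analyze_qpcr_run()] fits: per
#' target, CT = intercept + slope * log10(copies) + N(0, noise_sd_ct), with
#' the slope implied by a per-target Pfaffl efficiency. Standards are a
#' serial 10-fold plasmid dilution series; unknown wells follow a
#' fold-induction trajectory fold(t) = fold_72h^(t/72) from a constitutive
#' target/reference ratio. Inter-experiment variation scales target and
#' reference copies together, so the truth ratios are exact.
#'
#' @param seed master seed (own sub-stream).
#' @param targets target gene names (excluding the reference).
#' @param base_ratio constitutive target/reference copy ratio per target.
#' @param fold_72h fold induction at 72 h per target.
#' @param timepoints sampled timepoints, hours.
#' @param n_experiments independent experiments (samples).
#' @param n_replicates technical replicates per well group.
#' @param efficiency per-target Pfaffl efficiencies; drawn uniformly in
#'   \[1.96, 2\] when `NULL`.
#' @param intercept per-target curve intercepts; drawn in \[37, 40\] when
#'   `NULL`.
#' @param ref_copies reference-gene copies per reaction at baseline.
#' @param noise_sd_ct CT noise standard deviation, cycles.
#' @param dilution_conc standard-series concentrations, ng/uL.
#' @param volume_ul,plasmid_bp standard-well template volume and plasmid
#'   size for [conc_to_copies()].
#' @param reference reference gene name.
#' @return list with `wells` (data.frame in the layout
#'   [analyze_qpcr_run()] reads) and `truth`.
#' @export
gen_qpcr_run <- function(seed = 1,
                         targets = c("A*01:01", "A*02:01", "B*01:01",
                                     "B*02:01", "C*01:01", "C*02:01"),
                         base_ratio = c(1.8, 1.7, 0.9, 2.0, 1.6, 7.4),
                         fold_72h = c(8.9, 10.7, 30.1, 41.8, 18.6, 5.4),
                         timepoints = c(0, 24, 48, 72),
                         n_experiments = 3, n_replicates = 2,
                         efficiency = NULL, intercept = NULL,
                         ref_copies = 1e5, noise_sd_ct = 0.1,
                         dilution_conc = 2 * 10^-(2:7),
                         volume_ul = 5, plasmid_bp = 4031,
                         reference = "FBXL12") {
  stopifnot(length(base_ratio) == length(targets),
            length(fold_72h) == length(targets),
            noise_sd_ct >= 0, all(base_ratio > 0), all(fold_72h > 0))
  all_targets <- c(targets, reference)
  .with_seed(.stream_seed(seed, "qpcr"), {
    if (is.null(efficiency)) efficiency <- runif(length(all_targets), 1.96, 2)
    if (is.null(intercept)) intercept <- runif(length(all_targets), 37, 40)
    efficiency <- rep_len(efficiency, length(all_targets))
    intercept <- rep_len(intercept, length(all_targets))
    names(efficiency) <- names(intercept) <- all_targets
    slope <- -1 / log10(efficiency)

    rows <- list()
    emit <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
      ..., stringsAsFactors = FALSE)
    ct_of <- function(tg, copies) {
      intercept[[tg]] + slope[[tg]] * log10(copies) +
        rnorm(length(copies), 0, noise_sd_ct)
    }
    for (tg in all_targets) {
      for (conc in dilution_conc) {
        copies <- conc_to_copies(conc, volume_ul, plasmid_bp)
        for (rep_i in seq_len(n_replicates)) {
          emit(run_id = "run1", target = tg, sample = "standard",
               timepoint_h = NA_real_, ct = ct_of(tg, copies),
               replicate = rep_i, role = "standard", conc_ng_ul = conc)
        }
      }
    }
    exp_effect <- rlnorm(n_experiments, 0, 0.15)
    fold_at <- function(i, t) fold_72h[i]^(t / 72)
    for (e in seq_len(n_experiments)) {
      for (t in timepoints) {
        refc <- ref_copies * exp_effect[e]
        for (rep_i in seq_len(n_replicates)) {
          emit(run_id = "run1", target = reference, sample = sprintf("exp%d", e),
               timepoint_h = t, ct = ct_of(reference, refc),
               replicate = rep_i, role = "unknown", conc_ng_ul = NA_real_)
        }
        for (i in seq_along(targets)) {
          copies <- refc * base_ratio[i] * fold_at(i, t)
          for (rep_i in seq_len(n_replicates)) {
            emit(run_id = "run1", target = targets[i],
                 sample = sprintf("exp%d", e), timepoint_h = t,
                 ct = ct_of(targets[i], copies), replicate = rep_i,
                 role = "unknown", conc_ng_ul = NA_real_)
          }
        }
      }
    }
    wells <- do.call(rbind, rows)
    truth <- list(seed = seed, targets = targets, reference = reference,
                  efficiency = efficiency, slope = slope,
                  intercept = intercept,
                  base_ratio = setNames(base_ratio, targets),
                  fold_72h = setNames(fold_72h, targets),
                  timepoints = timepoints, ref_copies = ref_copies,
                  noise_sd_ct = noise_sd_ct)
    list(wells = wells, truth = truth)
  })
}

#' Generate a synthetic bead calibration panel
#'
#' Beads with known IgG loads; MFIs follow the inverse of the log-log
#' calibration log10(abc) = intercept + slope * log10(mfi), with
#' multiplicative lognormal noise of coefficient of variation `cv`.
#'
#' @param seed master seed (own sub-stream).
#' @param abc known IgG molecules per bead level.
#' @param slope,intercept true calibration coefficients.
#' @param cv lognormal coefficient of variation of the MFIs.
#' @return list with `beads` (data.frame `bead_id`, `abc`, `mfi`) and
#'   `truth`.
#' @export
gen_bead_panel <- function(seed = 1,
                           abc = c(4500, 40000, 120000, 290000, 580000),
                           slope = 1, intercept = 1.3, cv = 0.05) {
  stopifnot(all(abc > 0), slope > 0, cv >= 0)
  .with_seed(.stream_seed(seed, "beads"), {
    mfi_true <- 10^((log10(abc) - intercept) / slope)
    sdlog <- sqrt(log(1 + cv^2))
    mfi <- mfi_true * rlnorm(length(abc), -sdlog^2 / 2, sdlog)
    list(beads = data.frame(bead_id = sprintf("bead%d", seq_along(abc)),
                            abc = abc, mfi = mfi),
         truth = list(seed = seed, slope = slope, intercept = intercept,
                      cv = cv))
  })
}

#' Generate synthetic per-sample MFIs with known ABC truth
#'
#' Specific-antibody MFIs follow the same calibration as
#' [gen_bead_panel()]; isotype-control MFIs are constant. Lognormal noise
#' of coefficient of variation `cv` is applied to the specific MFIs.
#'
#' @param seed master seed (own sub-stream).
#' @param abc named vector of true antibody binding capacities per sample.
#' @param slope,intercept true calibration coefficients (must match the
#'   bead panel they will be analyzed against).
#' @param isotype_mfi isotype-control MFI.
#' @param cv lognormal coefficient of variation.
#' @param timepoint_h timepoint annotation.
#' @return list with `samples` (data.frame `sample`, `stain`, `mfi`,
#'   `timepoint_h`) and `truth`.
#' @export
gen_cell_mfi <- function(seed = 1,
                         abc = c(A2 = 204370, B7 = 12076, B27 = 5174),
                         slope = 1, intercept = 1.3, isotype_mfi = 30,
                         cv = 0.05, timepoint_h = 0) {
  stopifnot(all(abc > 0), slope > 0, isotype_mfi > 0, cv >= 0)
  .with_seed(.stream_seed(seed, "cells"), {
    mfi_true <- 10^((log10(abc) - intercept) / slope)
    sdlog <- sqrt(log(1 + cv^2))
    mfi <- mfi_true * rlnorm(length(abc), -sdlog^2 / 2, sdlog)
    samples <- rbind(
      data.frame(sample = names(abc), stain = "specific", mfi = mfi,
                 timepoint_h = timepoint_h, stringsAsFactors = FALSE),
      data.frame(sample = names(abc), stain = "isotype", mfi = isotype_mfi,
                 timepoint_h = timepoint_h, stringsAsFactors = FALSE))
    list(samples = samples,
         truth = list(seed = seed, abc = abc, slope = slope,
                      intercept = intercept, isotype_mfi = isotype_mfi,
                      cv = cv))
  })
}

#' Generate synthetic CDC well counts
#'
#' Dead-cell counts are binomial draws red ~ Binomial(n_cells, p_kill) per
#' well; green = n_cells - red.
#'
#' @param seed master seed (own sub-stream).
#' @param p_kill named vector of true kill fractions per serum.
#' @param n_cells cells counted per well.
#' @param wells wells per serum (duplicates x experiments).
#' @param sample sample identifier.
#' @return list with `wells` (data.frame `sample`, `serum_id`, `replicate`,
#'   `red`, `green`) and `truth`.
#' @export
gen_cdc_counts <- function(seed = 1,
                           p_kill = c(anti_A = 0.96, anti_B = 0.28,
                                      anti_Cw = 0.09, AB_serum = 0.09),
                           n_cells = 200, wells = 6, sample = "MSC") {
  stopifnot(all(p_kill >= 0), all(p_kill <= 1), n_cells > 0, wells >= 1)
  .with_seed(.stream_seed(seed, "cdc"), {
    rows <- do.call(rbind, lapply(names(p_kill), function(sid) {
      red <- rbinom(wells, n_cells, p_kill[[sid]])
      data.frame(sample = sample, serum_id = sid, replicate = seq_len(wells),
                 red = red, green = n_cells - red, stringsAsFactors = FALSE)
    }))
    list(wells = rows,
         truth = list(seed = seed, p_kill = p_kill, n_cells = n_cells,
                      wells = wells))
  })
}

#' Simulate the default study-shaped scenario
#'
#' One call that emulates the full study design: a 3-locus x 4-allele
#' family of 1200-nt cDNAs, six target alleles (two per locus) plus a
#' reference gene measured by qPCR over a 0/24/48/72 h induction time
#' course in three experiments with duplicate wells, a five-level bead
#' panel with cell MFIs for three surface antigens, and CDC plates for an
#' unstimulated and a stimulated sample. Constitutive ratios, fold
#' inductions, ABC values and kill fractions default to the published
#' values of the HLA class I study design this scenario mirrors.
#'
#' @param seed master seed; every assay draws from its own sub-stream.
#' @param outdir optional directory; when given, writes `alleles.fasta`,
#'   `wells.tsv`, `beads.tsv`, `samples.tsv`, `cdc.tsv` and `truth.json`.
#' @return list with `db`, `wells`, `beads`, `samples`, `cdc` and `truth`
#'   (per-assay truth records under `family`, `qpcr`, `beads`, `cells`,
#'   `cdc`).
#' @export
simulate_scenario <- function(seed = 1, outdir = NULL) {
  fam <- gen_allele_family(seed = seed)
  targets <- as.vector(t(outer(c("A", "B", "C"), 1:2,
                               function(l, j) sprintf("%s*%02d:01", l, j))))
  qp <- gen_qpcr_run(seed = seed, targets = targets)
  bp <- gen_bead_panel(seed = seed)
  cm <- gen_cell_mfi(seed = seed)
  cdc0 <- gen_cdc_counts(seed = seed, sample = "MSC_0h")
  cdc48 <- gen_cdc_counts(seed = seed + 1,
                          p_kill = c(anti_A = 0.96, anti_B = 0.81,
                                     anti_Cw = 0.26, AB_serum = 0.09),
                          sample = "MSC_48h")
  cdc <- rbind(cdc0$wells, cdc48$wells)
  truth <- list(seed = seed, family = fam$truth, qpcr = qp$truth,
                beads = bp$truth, cells = cm$truth,
                cdc = list(MSC_0h = cdc0$truth, MSC_48h = cdc48$truth))
  out <- list(db = fam$db, wells = qp$wells, beads = bp$beads,
              samples = cm$samples, cdc = cdc, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_allele_fasta(fam$db, file.path(outdir, "alleles.fasta"))
    wt <- function(d, f) write.table(d, file.path(outdir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(qp$wells, "wells.tsv")
    wt(bp$beads, "beads.tsv")
    wt(cm$samples, "samples.tsv")
    wt(cdc, "cdc.tsv")
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
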