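# Pipeline orchestration: validated run configuration, staged execution
# with JSON reports, and the published-fixture self-check.

.CONFIG_KEYS <- c("alleles", "wells", "beads", "samples", "cdc", "outdir",
                  "seed", "plasmid_bp", "volume_ul", "reference",
                  "design_targets", "design_constraints")

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file holding one) with any of
#' the keys `alleles`, `wells`, `beads`, `samples`, `cdc` (input file
#' paths), `outdir` (required), `seed`, `plasmid_bp`, `volume_ul`,
#' `reference`, `design_targets` (allele names to design assays for) and
#' `design_constraints` (arguments for [design_constraints()]). Unknown
#' keys are rejected and all referenced input files must exist before any
#' stage runs.
#'
#' @param config named list or path to a YAML file.
#' @return the validated configuration with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or YAML path",
                             call. = FALSE)
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(config$outdir)) stop("config requires 'outdir'", call. = FALSE)
  for (key in c("alleles", "wells", "beads", "samples", "cdc")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop(sprintf("config input '%s' does not exist: %s", key, config[[key]]),
           call. = FALSE)
    }
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$plasmid_bp)) config$plasmid_bp <- 4031
  if (is.null(config$volume_ul)) config$volume_ul <- 5
  if (is.null(config$reference)) config$reference <- "FBXL12"
  config
}

.write_report <- function(x, outdir, name) {
  path <- file.path(outdir, name)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order -- allele database
#' parsing, optional allele-specific assay design, qPCR quantification,
#' flow quantification, CDC scoring -- writing one JSON report per stage
#' and a top-level summary that cross-links them. A failed stage is
#' recorded and its dependents skipped; the summary's `ok` field is FALSE
#' if any stage failed. Rerunning with the same configuration and seed
#' reproduces the summary byte for byte.
#'
#' @param config see [validate_config()].
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  stages <- list()
  reports <- list()
  run_stage <- function(name, deps, fn) {
    failed_dep <- deps[vapply(deps, function(d) {
      is.null(stages[[d]]) || stages[[d]]$status != "ok"
    }, logical(1L))]
    if (length(failed_dep) > 0L) {
      stages[[name]] <<- list(status = "skipped",
                              reason = paste("dependency failed:",
                                             paste(failed_dep, collapse = ",")))
      return(invisible(NULL))
    }
    res <- tryCatch(list(status = "ok", value = fn()),
                    error = function(e) list(status = "error",
                                             reason = conditionMessage(e)))
    stages[[name]] <<- res[setdiff(names(res), "value")]
    invisible(res$value)
  }

  db <- NULL
  if (!is.null(config$alleles)) {
    db <- run_stage("alleles", character(0), function() {
      parse_allele_fasta(config$alleles)
    })
    if (!is.null(db)) stages$alleles$n_alleles <- length(db$records)
    if (!is.null(db) && !is.null(config$design_targets)) {
      run_stage("design", "alleles", function() {
        cons <- do.call(design_constraints,
                        as.list(config$design_constraints %||% list()))
        designs <- lapply(config$design_targets, function(tg) {
          res <- design_allele_specific(db, tg, cons)
          top <- if (length(res$pairs) > 0L) res$pairs[[1L]] else NULL
          list(target = tg, status = res$status,
               n_pairs = length(res$pairs),
               top_pair = if (is.null(top)) NULL else list(
                 fwd_seq = top$forward$sequence,
                 fwd_label = top$forward$label_coord,
                 rev_seq = top$reverse$sequence,
                 rev_label = top$reverse$label_coord,
                 amplicon_bp = top$amplicon_len,
                 fwd_tm = top$forward$tm, rev_tm = top$reverse$tm))
        })
        reports$design <<- .write_report(designs, config$outdir, "design.json")
        designs
      })
    }
  }

  if (!is.null(config$wells)) {
    qrun <- run_stage("qpcr", character(0), function() {
      run <- analyze_qpcr_run(config$wells, plasmid_bp = config$plasmid_bp,
                              volume_ul = config$volume_ul,
                              reference = config$reference)
      rep <- list(
        targets = names(run$curves),
        curves = lapply(run$curves, function(cv) {
          list(slope = cv$slope, intercept = cv$intercept, r2 = cv$r2,
               efficiency = cv$efficiency, qc = cv$qc)
        }),
        summary = run$summary, folds = run$folds)
      reports$qpcr <<- .write_report(rep, config$outdir, "qpcr_report.json")
      run
    })
    if (!is.null(qrun)) stages$qpcr$n_targets <- length(qrun$curves)
  }
  if (!is.null(config$beads) && !is.null(config$samples)) {
    run_stage("flow", character(0), function() {
      run <- analyze_flow_run(config$beads, config$samples)
      rep <- list(calibration = list(slope = run$calibration$slope,
                                     intercept = run$calibration$intercept,
                                     r2 = run$calibration$r2),
                  results = run$results)
      reports$flow <<- .write_report(rep, config$outdir, "flow_report.json")
      run
    })
  }
  if (!is.null(config$cdc)) {
    run_stage("cdc", character(0), function() {
      res <- analyze_cdc(config$cdc)
      reports$cdc <<- .write_report(res, config$outdir, "cdc_report.json")
      res
    })
  }

  # the hash covers the analysis-relevant configuration, not the output path
  cfg <- config[setdiff(names(config), "outdir")]
  cfg_json <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE)
  cfg_file <- tempfile()
  writeLines(as.character(cfg_json), cfg_file)
  summary <- list(
    config = config,
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    stages = stages,
    reports = lapply(reports, basename),
    ok = all(vapply(stages, function(s) s$status == "ok", logical(1L)))
  )
  unlink(cfg_file)
  .write_report(summary, config$outdir, "summary.json")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check the package against the published assay table
#'
#' Recomputes, from the assay table shipped with the package (primer
#' coordinate labels, fragment lengths, mRNA fold inductions and antibody
#' binding capacities of a published allele-specific HLA class I assay
#' panel), every desk-checkable quantity: fragment lengths from the
#' label-subtraction convention, protein-level fold differences from the
#' ABC column, the rounded B*27 mRNA fold induction, the Pfaffl identity,
#' and the semi-quantitative scale boundaries. The HLA-B long-range row is
#' internally inconsistent in the source table (labels -40/1091 imply 1131
#' bp, printed 1143 bp); it is reported as a failure rather than silently
#' corrected.
#'
#' @return data.frame with columns `check`, `observed`, `expected`, `pass`.
#' @export
fixture_check <- function() {
  tab <- published_assays()
  rows <- list()
  add <- function(check, observed, expected) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, observed = as.character(observed),
      expected = as.character(expected),
      pass = !is.na(observed) && !is.na(expected) && observed == expected,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    if (is.na(tab$rev_label[i])) {
      add(sprintf("fragment length: %s", tab$assay[i]), NA, tab$printed_len[i])
    } else {
      add(sprintf("fragment length: %s", tab$assay[i]),
          amplicon_length_from_labels(tab$fwd_label[i], tab$rev_label[i]),
          tab$printed_len[i])
    }
  }
  abc <- setNames(tab$abc, tab$assay)
  add("ABC fold A*02:01:01 / B*07:02",
      fold_expression(abc[["A*02:01:01"]], abc[["B*07:02"]]), 17)
  add("ABC fold A*02:01:01 / B*27:02",
      fold_expression(abc[["A*02:01:01"]], abc[["B*27:02"]]), 40)
  add("ABC fold B*07:02 / B*27:02",
      fold_expression(abc[["B*07:02"]], abc[["B*27:02"]]), 2.3)
  add("B*27:02 mRNA fold induction (rounded)",
      round_fold(tab$mrna_fold[tab$assay == "B*27:02"]), 42)
  add("Pfaffl identity: slope -1/log10(2) gives E",
      efficiency_pfaffl(-1 / log10(2)), 2)
  lab <- as.character(semiquant_label(c(3, 10, 30, 50, 100)))
  add("semiquant scale at boundary ratios 3,10,30,50,100",
      paste(lab, collapse = " "), "- 1+ 2+ 3+ 4+")
  do.call(rbind, rows)
}

#' Published assay table shipped with the package
#'
#' Primer coordinate labels, sequences, printed fragment lengths, mRNA fold
#' inductions and antibody binding capacities of the published
#' allele-specific HLA class I assay panel used by [fixture_check()] and
#' the worked examples.
#'
#' @return data.frame, one row per assay.
#' @export
published_assays <- function() {
  read.delim(system.file("extdata", "published_assays.tsv",
                         package = "allelequant"),
             stringsAsFactors = FALSE, check.names = FALSE)
}
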