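# Absolute qPCR quantification: plasmid standard curves, Pfaffl
# amplification efficiency, copy-number estimation and reference-gene
# normalization.

#' Convert a plasmid concentration to copy number
#'
#' Copies = conc * volume * 1e-9 * N_A / (plasmid_size * 650), using
#' Avogadro's number and an average molar mass of 650 g/mol per base pair
#' of double-stranded DNA.
#'
#' @param conc_ng_ul plasmid concentration, ng/uL.
#' @param volume_ul template volume added to the reaction, uL.
#' @param plasmid_bp plasmid size including insert, bp.
#' @return copy number (numeric, not rounded).
#' @export
conc_to_copies <- function(conc_ng_ul, volume_ul, plasmid_bp) {
  if (any(conc_ng_ul <= 0) || any(volume_ul <= 0) || any(plasmid_bp <= 0)) {
    stop("concentration, volume and plasmid size must all be positive",
         call. = FALSE)
  }
  conc_ng_ul * volume_ul * 1e-9 * 6.022e23 / (plasmid_bp * 650)
}

#' Pfaffl amplification efficiency from a standard-curve slope
#'
#' E = 10^(-1/slope), the per-cycle amplification factor implied by the
#' slope of CT against log10(copies). A slope of -1/log10(2) = -3.321928
#' corresponds to perfect doubling, E = 2.
#'
#' @param slope standard-curve slope, cycles per log10(copies); must be
#'   negative.
#' @return efficiency E (fold per cycle).
#' @export
efficiency_pfaffl <- function(slope) {
  if (any(slope >= 0)) stop("standard-curve slope must be negative",
                            call. = FALSE)
  10^(-1 / slope)
}

#' Efficiency quality control
#'
#' Assays are accepted when E exceeds the warning threshold; values in the
#' band between the hard floor and the warning threshold are usable but
#' flagged; below the hard floor the assay fails QC. Defaults encode an
#' acceptance rule of "exceeding 1.96 per cycle" with an observed working
#' range reaching down to 1.92.
#'
#' @param efficiency Pfaffl efficiency E.
#' @param hard_floor below this E the assay fails.
#' @param warn_below E in `[hard_floor, warn_below)` passes with a warning
#'   flag.
#' @param ceiling E above this is physically implausible and fails.
#' @return character: `"pass"`, `"warn"` or `"fail"`.
#' @export
qc_efficiency <- function(efficiency, hard_floor = 1.92, warn_below = 1.96,
                          ceiling = 2.1) {
  ifelse(efficiency < hard_floor | efficiency > ceiling, "fail",
         ifelse(efficiency < warn_below, "warn", "pass"))
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of CT on log10(copies) over a plasmid dilution
#' series (serial 10-fold dilutions in the reference protocol). The Pfaffl
#' efficiency E = 10^(-1/slope) is attached along with its QC flag.
#'
#' @param ct CT values, cycles.
#' @param copies starting copy numbers of the corresponding wells.
#' @param min_levels minimum number of distinct copy levels (default 4).
#' @return an object of class `"standard_curve"` with elements `slope`,
#'   `intercept`, `r2`, `efficiency`, `qc`, `n_levels`, `n_wells` and the
#'   underlying `fit`.
#' @export
fit_standard_curve <- function(ct, copies, min_levels = 4L) {
  if (length(ct) != length(copies)) stop("ct and copies differ in length",
                                         call. = FALSE)
  if (any(ct <= 0) || any(copies <= 0)) {
    stop("CT values and copy numbers must be positive", call. = FALSE)
  }
  lc <- log10(copies)
  n_levels <- length(unique(signif(lc, 10)))
  if (n_levels < min_levels) {
    stop(sprintf("standard curve needs >= %d distinct dilution levels, got %d",
                 min_levels, n_levels), call. = FALSE)
  }
  if (stats::var(lc) == 0) stop("zero variance in log10(copies)", call. = FALSE)
  fit <- lm(ct ~ lc)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0) stop("fitted slope is non-negative; not a qPCR dilution series",
                       call. = FALSE)
  eff <- efficiency_pfaffl(slope)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn in summary.lm
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1L]),
         r2 = r2, efficiency = eff,
         qc = qc_efficiency(eff), n_levels = n_levels,
         n_wells = length(ct), fit = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.4f, intercept %.3f, r2 %.5f, E %.4f [%s]\n",
    x$slope, x$intercept, x$r2, x$efficiency, x$qc))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Copy number from an observed CT
#'
#' Inverts the standard-curve model: copies = 10^((ct - intercept)/slope).
#'
#' @param ct observed CT, cycles.
#' @param curve a [fit_standard_curve()] result.
#' @return estimated starting copy number.
#' @export
copies_from_ct <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' @export
predict.standard_curve <- function(object, ct, ...) copies_from_ct(ct, object)

#' Normalized expression ratio, geometric mean, and fold change
#'
#' `normalized_ratio()` divides the target copy number by the reference
#' gene copy number measured in the same sample. `gmean()` is the geometric
#' mean exp(mean(log x)) used to summarize ratios over independent
#' experiments. `fold_change()` is the ratio of normalized ratios between a
#' timepoint and baseline.
#'
#' @param target_copies,reference_copies positive copy numbers.
#' @return numeric.
#' @export
normalized_ratio <- function(target_copies, reference_copies) {
  if (any(target_copies <= 0) || any(reference_copies <= 0)) {
    stop("copy numbers must be positive", call. = FALSE)
  }
  target_copies / reference_copies
}

#' @rdname normalized_ratio
#' @param x positive values to average.
#' @export
gmean <- function(x) {
  if (length(x) < 1L || any(x <= 0)) {
    stop("geometric mean needs >= 1 positive value", call. = FALSE)
  }
  exp(mean(log(x)))
}

#' @rdname normalized_ratio
#' @param ratio_t,ratio_0 normalized ratios at a timepoint and at baseline.
#' @export
fold_change <- function(ratio_t, ratio_0) {
  if (any(ratio_t <= 0) || any(ratio_0 <= 0)) {
    stop("ratios must be positive", call. = FALSE)
  }
  ratio_t / ratio_0
}

#' Analyze a qPCR run from a wells table
#'
#' Full absolute-quantification pipeline for one run: fits one standard
#' curve per target from the `standard` wells (copy numbers derived from
#' `conc_ng_ul` via [conc_to_copies()]), averages technical replicates of
#' `unknown` wells on the CT scale, converts CT to copies, normalizes each
#' sample's targets by the reference gene, summarizes ratios across
#' samples (independent experiments) by geometric mean per timepoint, and
#' derives fold changes against the earliest timepoint.
#'
#' @param wells data.frame with columns `run_id`, `target`, `sample`,
#'   `timepoint_h`, `ct`, `replicate`, `role` (`"standard"`/`"unknown"`),
#'   `conc_ng_ul` (standards only), or a path to such a TSV.
#' @param plasmid_bp plasmid size used for the dilution series, bp.
#' @param volume_ul template volume per standard well, uL.
#' @param reference name of the reference gene target.
#' @return an object of class `"qpcr_run"` with elements `curves` (named
#'   list of standard curves), `quant` (per sample/target copies),
#'   `ratios`, `summary` (geometric-mean ratio per target/timepoint) and
#'   `folds` (fold change vs the earliest timepoint).
#' @export
analyze_qpcr_run <- function(wells, plasmid_bp, volume_ul = 5,
                             reference = "FBXL12") {
  if (is.character(wells)) {
    wells <- read.delim(wells, stringsAsFactors = FALSE)
  }
  need <- c("target", "sample", "timepoint_h", "ct", "replicate", "role")
  miss <- setdiff(need, names(wells))
  if (length(miss) > 0L) {
    stop(sprintf("wells table lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  std <- wells[wells$role == "standard", , drop = FALSE]
  unk <- wells[wells$role == "unknown", , drop = FALSE]
  if (nrow(std) == 0L) stop("no standard wells in run", call. = FALSE)
  if (!reference %in% unique(wells$target)) {
    stop(sprintf("reference gene '%s' absent from run", reference),
         call. = FALSE)
  }
  curves <- lapply(split(std, std$target), function(d) {
    fit_standard_curve(d$ct, conc_to_copies(d$conc_ng_ul, volume_ul, plasmid_bp))
  })

  # technical replicates averaged on the CT scale before quantification
  key <- interaction(unk$target, unk$sample, unk$timepoint_h, drop = TRUE)
  agg <- do.call(rbind, lapply(split(unk, key), function(d) {
    data.frame(target = d$target[1L], sample = d$sample[1L],
               timepoint_h = d$timepoint_h[1L], ct = mean(d$ct),
               n_wells = nrow(d), stringsAsFactors = FALSE)
  }))
  agg$copies <- vapply(seq_len(nrow(agg)), function(i) {
    cv <- curves[[agg$target[i]]]
    if (is.null(cv)) stop(sprintf("no standard curve for target '%s'",
                                  agg$target[i]), call. = FALSE)
    copies_from_ct(agg$ct[i], cv)
  }, 0)

  ref <- agg[agg$target == reference, c("sample", "timepoint_h", "copies")]
  names(ref)[3L] <- "reference_copies"
  tgt <- agg[agg$target != reference, , drop = FALSE]
  ratios <- merge(tgt, ref, by = c("sample", "timepoint_h"))
  ratios$ratio <- normalized_ratio(ratios$copies, ratios$reference_copies)
  ratios <- ratios[order(ratios$target, ratios$timepoint_h, ratios$sample), ]
  rownames(ratios) <- NULL

  skey <- interaction(ratios$target, ratios$timepoint_h, drop = TRUE)
  summ <- do.call(rbind, lapply(split(ratios, skey), function(d) {
    data.frame(target = d$target[1L], timepoint_h = d$timepoint_h[1L],
               gmean_ratio = gmean(d$ratio), n_experiments = nrow(d),
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$target, summ$timepoint_h), ]
  rownames(summ) <- NULL

  t0 <- min(summ$timepoint_h)
  base <- summ[summ$timepoint_h == t0, c("target", "gmean_ratio")]
  names(base)[2L] <- "baseline_ratio"
  folds <- merge(summ, base, by = "target")
  folds$fold <- fold_change(folds$gmean_ratio, folds$baseline_ratio)
  folds <- folds[order(folds$target, folds$timepoint_h),
                 c("target", "timepoint_h", "gmean_ratio", "fold")]
  rownames(folds) <- NULL

  structure(list(curves = curves, quant = agg, ratios = ratios,
                 summary = summ, folds = folds, reference = reference),
            class = "qpcr_run")
}

#' @export
print.qpcr_run <- function(x, ...) {
  cat(sprintf("<qpcr_run> %d target curves (reference %s)\n",
              length(x$curves), x$reference))
  for (nm in names(x$curves)) {
    cv <- x$curves[[nm]]
    cat(sprintf("  %s: slope %.3f, E %.3f [%s]\n", nm, cv$slope,
                cv$efficiency, cv$qc))
  }
  cat(sprintf("  %d normalized ratios over %d timepoints\n",
              nrow(x$ratios), length(unique(x$summary$timepoint_h))))
  invisible(x)
}
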