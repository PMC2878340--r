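# Quantitative flow cytometry: bead calibration (MFI -> antibody binding
# capacity), the semi-quantitative MFI-ratio scale, and fold summaries.

#' Fit a bead calibration curve
#'
#' Least squares of log10(ABC) on log10(MFI) over a panel of beads carrying
#' known numbers of IgG molecules stained with the same secondary antibody
#' as the cells (QifiKit-style calibration). The log-log linear model is
#' the standard for such kits; `scale = "linear"` fits ABC on MFI directly.
#'
#' @param abc known IgG molecules per bead.
#' @param mfi measured mean/median fluorescence intensities.
#' @param min_levels minimum number of distinct bead levels (default 4).
#' @param scale `"log"` (default) or `"linear"`.
#' @return an object of class `"flow_calibration"` with `slope`,
#'   `intercept`, `r2`, `scale`.
#' @export
fit_bead_calibration <- function(abc, mfi, min_levels = 4L,
                                 scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (length(abc) != length(mfi)) stop("abc and mfi differ in length",
                                       call. = FALSE)
  if (any(abc <= 0) || any(mfi <= 0)) {
    stop("bead ABC and MFI values must be positive", call. = FALSE)
  }
  if (length(unique(abc)) < min_levels) {
    stop(sprintf("bead calibration needs >= %d distinct ABC levels, got %d",
                 min_levels, length(unique(abc))), call. = FALSE)
  }
  fit <- if (scale == "log") lm(log10(abc) ~ log10(mfi)) else lm(abc ~ mfi)
  slope <- unname(coef(fit)[2L])
  if (slope <= 0) {
    stop("calibration slope is non-positive; more antibody must mean more signal",
         call. = FALSE)
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn in summary.lm
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1L]),
         r2 = r2, scale = scale, fit = fit),
    class = "flow_calibration"
  )
}

#' @export
print.flow_calibration <- function(x, ...) {
  cat(sprintf("<flow_calibration> %s scale: slope %.4f, intercept %.4f, r2 %.5f\n",
              x$scale, x$slope, x$intercept, x$r2))
  invisible(x)
}

#' @export
coef.flow_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Antibody binding capacity from a measured MFI
#'
#' On the log scale: ABC = 10^(intercept + slope * log10(MFI)); monotone
#' increasing in MFI.
#'
#' @param mfi positive fluorescence intensity value(s).
#' @param calibration a [fit_bead_calibration()] result.
#' @return estimated antibodies bound per cell.
#' @export
abc_from_mfi <- function(mfi, calibration) {
  stopifnot(inherits(calibration, "flow_calibration"))
  if (any(mfi <= 0)) stop("MFI must be positive", call. = FALSE)
  if (calibration$scale == "log") {
    10^(calibration$intercept + calibration$slope * log10(mfi))
  } else {
    calibration$intercept + calibration$slope * mfi
  }
}

#' @export
predict.flow_calibration <- function(object, mfi, ...) abc_from_mfi(mfi, object)

.SEMIQUANT_LEVELS <- c("-", "+/-", "1+", "2+", "3+", "4+")

#' Semi-quantitative expression score from an MFI ratio
#'
#' The ordinal scale used for reporting surface expression: with
#' ratio = specific MFI / isotype-control MFI, a ratio of at most 3 scores
#' `"-"`, below 10 `"+/-"`, at least 10 `"1+"`, at least 30 `"2+"`, at
#' least 50 `"3+"` and at least 100 `"4+"`. The bins are half-open and the
#' score is non-decreasing in the ratio.
#'
#' @param specific_mfi MFI with the allele-specific antibody.
#' @param isotype_mfi MFI with the matched isotype control (> 0).
#' @return an ordered factor with levels `-, +/-, 1+, 2+, 3+, 4+` and the
#'   ratios attached as attribute `"ratio"`.
#' @export
semiquant_score <- function(specific_mfi, isotype_mfi) {
  if (any(isotype_mfi <= 0)) stop("isotype MFI must be positive", call. = FALSE)
  ratio <- specific_mfi / isotype_mfi
  lab <- semiquant_label(ratio)
  attr(lab, "ratio") <- ratio
  lab
}

#' @rdname semiquant_score
#' @param ratio specific/isotype MFI ratio(s).
#' @export
semiquant_label <- function(ratio) {
  # mixed bin openness per the reporting scale: "-" is ratio <= 3, but the
  # graded bins are >= 10, >= 30, >= 50, >= 100
  idx <- 1L + (ratio > 3) + (ratio >= 10) + (ratio >= 30) +
    (ratio >= 50) + (ratio >= 100)
  factor(.SEMIQUANT_LEVELS[idx], levels = .SEMIQUANT_LEVELS, ordered = TRUE)
}

#' Fold difference in expression between two ABC values
#'
#' Ratio `abc_a / abc_b` with the presentation rounding used when quoting
#' fold differences: nearest integer for folds of at least 10, one decimal
#' below 10. `round_fold()` applies the same policy to an existing fold.
#'
#' @param abc_a,abc_b positive antibody-binding capacities.
#' @param rounding `"presentation"` (default) or `"none"`.
#' @return numeric fold.
#' @export
fold_expression <- function(abc_a, abc_b,
                            rounding = c("presentation", "none")) {
  rounding <- match.arg(rounding)
  if (any(abc_a <= 0) || any(abc_b <= 0)) {
    stop("ABC values must be positive", call. = FALSE)
  }
  fold <- abc_a / abc_b
  if (rounding == "presentation") round_fold(fold) else fold
}

#' @rdname fold_expression
#' @param fold positive fold value(s).
#' @export
round_fold <- function(fold) {
  ifelse(fold >= 10, round(fold), round(fold, 1L))
}

#' Analyze a flow cytometry run
#'
#' Fits the bead calibration, then for each sample/timepoint converts the
#' specific-antibody MFI to an antibody binding capacity and scores the
#' semi-quantitative level from the specific/isotype MFI ratio.
#'
#' @param beads data.frame with columns `abc`, `mfi` (optionally `bead_id`),
#'   or a path to such a TSV.
#' @param samples data.frame with columns `sample`, `stain`
#'   (`"specific"`/`"isotype"`), `mfi` and optionally `timepoint_h`, or a
#'   path to such a TSV.
#' @param scale calibration scale, see [fit_bead_calibration()].
#' @return an object of class `"flow_run"` with `calibration` and `results`
#'   (per sample/timepoint: specific and isotype MFI, ABC, ratio, label).
#' @export
analyze_flow_run <- function(beads, samples, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (is.character(beads)) beads <- read.delim(beads, stringsAsFactors = FALSE)
  if (is.character(samples)) samples <- read.delim(samples, stringsAsFactors = FALSE)
  cal <- fit_bead_calibration(beads$abc, beads$mfi, scale = scale)
  if (!"timepoint_h" %in% names(samples)) samples$timepoint_h <- 0
  key <- interaction(samples$sample, samples$timepoint_h, drop = TRUE)
  results <- do.call(rbind, lapply(split(samples, key), function(d) {
    spec <- d$mfi[d$stain == "specific"]
    iso <- d$mfi[d$stain == "isotype"]
    if (length(spec) != 1L || length(iso) != 1L) {
      stop(sprintf("sample '%s' t=%s needs exactly one specific and one isotype MFI",
                   d$sample[1L], d$timepoint_h[1L]), call. = FALSE)
    }
    data.frame(sample = d$sample[1L], timepoint_h = d$timepoint_h[1L],
               specific_mfi = spec, isotype_mfi = iso,
               abc = abc_from_mfi(spec, cal),
               ratio = spec / iso,
               label = as.character(semiquant_label(spec / iso)),
               stringsAsFactors = FALSE)
  }))
  results <- results[order(results$sample, results$timepoint_h), ]
  rownames(results) <- NULL
  structure(list(calibration = cal, results = results), class = "flow_run")
}

#' @export
print.flow_run <- function(x, ...) {
  print(x$calibration)
  print(x$results, digits = 4)
  invisible(x)
}
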