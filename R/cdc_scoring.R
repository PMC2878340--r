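# Complement-dependent microcytotoxicity (CDC) scoring: red (dead) / green
# (live) counts per well, aggregation over duplicate wells and experiments,
# and the serological typing call.

#' Percentage of dead cells in a CDC well
#'
#' 100 * red / (red + green), where dead cells stain red (ethidium bromide
#' enters lysed cells) and live cells green (acridine orange).
#'
#' @param red dead-cell count(s).
#' @param green live-cell count(s).
#' @return percent dead, 0-100.
#' @export
percent_dead <- function(red, green) {
  if (any(red < 0) || any(green < 0)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  if (any(red + green == 0)) stop("empty well: red + green must be > 0",
                                  call. = FALSE)
  100 * red / (red + green)
}

#' Aggregate CDC wells and make a typing call
#'
#' Averages the per-well kill percentages (unweighted) over duplicate wells
#' and experiments and types the serum positive when the mean strictly
#' exceeds the threshold (default 50 percent killing, the standard
#' serological criterion). Wells with fewer than `min_cells` counted cells
#' are flagged but not excluded. The negative-control background is
#' reported alongside and, by default, not subtracted before calling;
#' `subtract_background = TRUE` subtracts it first.
#'
#' @param red,green per-well dead and live counts (equal length, >= 1 well).
#' @param threshold typing threshold, percent killing.
#' @param min_cells minimum cells per well before the low-count flag is set.
#' @param background negative-control (AB serum) kill percentage.
#' @param subtract_background subtract `background` before calling?
#' @return an object of class `"cdc_result"`: `percent_dead` (mean over
#'   wells, after any background subtraction), `raw_percent_dead`,
#'   `background`, `n_cells` (total counted), `n_wells`, `call`
#'   (`"positive"`/`"negative"`) and `flag_low_count`.
#' @export
aggregate_and_call <- function(red, green, threshold = 50, min_cells = 200L,
                               background = 0, subtract_background = FALSE) {
  pw <- percent_dead(red, green)
  raw <- mean(pw)
  adj <- if (subtract_background) max(raw - background, 0) else raw
  structure(
    list(percent_dead = adj, raw_percent_dead = raw, background = background,
         n_cells = sum(red) + sum(green), n_wells = length(pw),
         call = if (adj > threshold) "positive" else "negative",
         flag_low_count = any(red + green < min_cells),
         threshold = threshold),
    class = "cdc_result"
  )
}

#' @export
print.cdc_result <- function(x, ...) {
  cat(sprintf("<cdc_result> %.1f%% killing over %d well(s): %s (>%g%% rule)%s\n",
              x$percent_dead, x$n_wells, x$call, x$threshold,
              if (x$flag_low_count) " [low cell count]" else ""))
  invisible(x)
}

#' Score a CDC plate table serum by serum
#'
#' @param wells data.frame with columns `sample`, `serum_id`, `replicate`,
#'   `red`, `green`, or a path to such a TSV.
#' @param ... passed to [aggregate_and_call()].
#' @return data.frame with one row per sample/serum: `percent_dead`,
#'   `n_wells`, `n_cells`, `call`, `flag_low_count`.
#' @export
analyze_cdc <- function(wells, ...) {
  if (is.character(wells)) wells <- read.delim(wells, stringsAsFactors = FALSE)
  need <- c("sample", "serum_id", "red", "green")
  miss <- setdiff(need, names(wells))
  if (length(miss) > 0L) {
    stop(sprintf("CDC table lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  key <- interaction(wells$sample, wells$serum_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(wells, key), function(d) {
    r <- aggregate_and_call(d$red, d$green, ...)
    data.frame(sample = d$sample[1L], serum_id = d$serum_id[1L],
               percent_dead = r$percent_dead, n_wells = r$n_wells,
               n_cells = r$n_cells, call = r$call,
               flag_low_count = r$flag_low_count, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample, out$serum_id), ]
  rownames(out) <- NULL
  out
}
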