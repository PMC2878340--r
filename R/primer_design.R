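#' Design constraint set for allele-specific primers
#'
#' Bundles the constraints an allele-specific qPCR assay must satisfy:
#' primer length, nearest-neighbor Tm window, amplicon size bounds, the
#' 3'-terminal perfect-match (ARMS) rule used by the in-silico PCR binding
#' model, and the off-target product size window. Defaults follow the
#' design rules of the assay family this package implements: 21-mer target
#' length (17-25 allowed), Tm 66 +/- 2 degrees C, 70-120 bp amplicons, one
#' 3'-terminal discriminating base.
#'
#' @param primer_len target primer length, nt.
#' @param len_range length-2 vector, allowed primer length span.
#' @param tm_target target melting temperature, degrees C.
#' @param tm_tol allowed deviation from `tm_target`, degrees C.
#' @param amp_min,amp_max amplicon size bounds, bp.
#' @param three_prime_k number of 3'-terminal bases that must match
#'   perfectly for predicted extension (>= 1).
#' @param max_internal_mismatches mismatches tolerated outside the 3'
#'   window for predicted binding.
#' @param product_window length-2 vector, plausible off-target product size
#'   span in bp for [in_silico_pcr()].
#' @return an object of class `"design_constraints"`.
#' @export
design_constraints <- function(primer_len = 21L,
                               len_range = c(17L, 25L),
                               tm_target = 66,
                               tm_tol = 2,
                               amp_min = 70L,
                               amp_max = 120L,
                               three_prime_k = 1L,
                               max_internal_mismatches = 2L,
                               product_window = c(50L, 2000L)) {
  stopifnot(amp_min < amp_max,
            len_range[1L] <= primer_len, primer_len <= len_range[2L],
            three_prime_k >= 1L,
            max_internal_mismatches >= 0L,
            product_window[1L] <= product_window[2L],
            tm_tol > 0)
  structure(
    list(primer_len = as.integer(primer_len),
         len_range = as.integer(len_range),
         tm_target = tm_target, tm_tol = tm_tol,
         amp_min = as.integer(amp_min), amp_max = as.integer(amp_max),
         three_prime_k = as.integer(three_prime_k),
         max_internal_mismatches = as.integer(max_internal_mismatches),
         product_window = as.integer(product_window)),
    class = "design_constraints"
  )
}

#' Default constraint set for locus-specific long-range assays
#'
#' Long-range locus-specific amplicons must span every exon-exon junction,
#' so the size bounds move to 1000-1200 bp and the Tm window widens to
#' +/- 5 degrees C (long-range primers anchor in locus-private UTRs whose
#' composition is not under the designer's control; published long-range
#' primers range 20-24 nt).
#'
#' @inheritParams design_constraints
#' @param ... passed through to [design_constraints()].
#' @return an object of class `"design_constraints"`.
#' @export
long_range_constraints <- function(amp_min = 1000L, amp_max = 1200L,
                                   len_range = c(18L, 25L), tm_tol = 5, ...) {
  design_constraints(amp_min = amp_min, amp_max = amp_max,
                     len_range = len_range, tm_tol = tm_tol,
                     product_window = c(200L, 5000L), ...)
}

#' @export
print.design_constraints <- function(x, ...) {
  cat(sprintf(
    paste0("<design_constraints> len %d (%d-%d), Tm %.1f+/-%.1f C, ",
           "amplicon %d-%d bp, 3' window %d nt (0 mm), <=%d internal mm, ",
           "product window %d-%d bp\n"),
    x$primer_len, x$len_range[1L], x$len_range[2L], x$tm_target, x$tm_tol,
    x$amp_min, x$amp_max, x$three_prime_k, x$max_internal_mismatches,
    x$product_window[1L], x$product_window[2L]))
  invisible(x)
}

#' Construct a primer
#'
#' @param sequence 5'->3' nucleotide string.
#' @param orientation `"forward"` or `"reverse"`.
#' @param label_coord ATG-anchored coordinate used in the primer's name
#'   (the start of the primer relative to +1 ATG for forward primers; for
#'   reverse primers the module's half-open label convention, chosen so
#'   that reverse label minus forward label equals the fragment length).
#' @param na_m,primer_nm Tm model conditions, see [tm_nearest_neighbor()].
#'   The Tm is always computed by the module's model, never user-supplied.
#' @return an object of class `"primer"`.
#' @export
primer <- function(sequence, orientation = c("forward", "reverse"),
                   label_coord = NA_integer_, na_m = 0.05, primer_nm = 500) {
  orientation <- match.arg(orientation)
  sequence <- toupper(sequence)
  .check_acgt(sequence, what = "primer", allow_gap = FALSE)
  structure(
    list(sequence = sequence, orientation = orientation,
         label_coord = as.integer(label_coord),
         tm = tm_nearest_neighbor(sequence, na_m = na_m, primer_nm = primer_nm)),
    class = "primer"
  )
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer %s> %s (%d nt, Tm %.1f C%s)\n", x$orientation,
              x$sequence, nchar(x$sequence), x$tm,
              if (is.na(x$label_coord)) "" else
                sprintf(", label %+d", x$label_coord)))
  invisible(x)
}

#' Construct a primer pair
#'
#' @param forward,reverse [primer()] objects (or sequences, coerced).
#' @param target allele or locus name the pair was designed against.
#' @param amplicon_len amplicon length on the target sequence, bp.
#' @return an object of class `"primer_pair"` with `label_len` derived from
#'   the coordinate labels by plain subtraction when both are present.
#' @export
primer_pair <- function(forward, reverse, target = NA_character_,
                        amplicon_len = NA_integer_) {
  if (is.character(forward)) forward <- primer(forward, "forward")
  if (is.character(reverse)) reverse <- primer(reverse, "reverse")
  stopifnot(inherits(forward, "primer"), inherits(reverse, "primer"))
  label_len <- if (!is.na(forward$label_coord) && !is.na(reverse$label_coord)) {
    amplicon_length_from_labels(forward$label_coord, reverse$label_coord)
  } else NA_integer_
  structure(
    list(forward = forward, reverse = reverse, target = target,
         amplicon_len = as.integer(amplicon_len), label_len = label_len),
    class = "primer_pair"
  )
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> target %s, amplicon %s bp\n", x$target,
              ifelse(is.na(x$amplicon_len), x$label_len, x$amplicon_len)))
  print(x$forward)
  print(x$reverse)
  invisible(x)
}

#' Amplicon length from primer-name coordinate labels
#'
#' Primer names of the assay family carry the start of the primer relative
#' to +1 ATG (no-zero coordinates: -1 immediately precedes +1). The
#' fragment length printed for an assay equals the reverse label minus the
#' forward label by plain subtraction, for positive as well as
#' ATG-straddling coordinates (e.g. labels -2 and 1063 give 1065 bp).
#'
#' @param f_label,r_label integer ATG-anchored labels, `r_label > f_label`.
#' @return integer amplicon length(s) in bp.
#' @export
amplicon_length_from_labels <- function(f_label, r_label) {
  f_label <- as.integer(f_label)
  r_label <- as.integer(r_label)
  if (any(f_label == 0L | r_label == 0L, na.rm = TRUE)) {
    stop("coordinate labels use a no-zero convention; 0 is invalid",
         call. = FALSE)
  }
  if (any(r_label <= f_label, na.rm = TRUE)) {
    stop("reverse label must exceed forward label", call. = FALSE)
  }
  r_label - f_label
}

# --- in-silico PCR ---------------------------------------------------------

# All binding sites of a primer on the plus strand of `tmpl` (character
# vector of bases). A site requires zero mismatches in the k-base 3' window
# and at most max_mm mismatches elsewhere. For sense = "reverse" the primer
# binds the minus strand: its reverse complement is scanned against the
# plus strand and the 3' window maps to the *first* k bases of the matched
# region.
.binding_sites <- function(primer_seq, tmpl, k, max_mm,
                           sense = c("forward", "reverse")) {
  sense <- match.arg(sense)
  p <- .seq_chars(if (sense == "reverse") .revcomp(primer_seq) else primer_seq)
  m <- length(p)
  n <- length(tmpl)
  if (n < m) return(integer(0))
  n_off <- n - m + 1L
  win <- if (sense == "forward") (m - k + 1L):m else 1L:k
  # the 3' window must match perfectly, so filter on it first; internal
  # mismatches are only counted at offsets that survive
  ok <- rep(TRUE, n_off)
  for (i in win) ok <- ok & tmpl[i:(n_off + i - 1L)] == p[i]
  cand <- which(ok)
  if (length(cand) == 0L) return(integer(0))
  mm <- integer(length(cand))
  for (i in setdiff(seq_len(m), win)) {
    mm <- mm + (tmpl[cand + i - 1L] != p[i])
    if (all(mm > max_mm)) return(integer(0))
  }
  cand[mm <= max_mm]
}

# Product prediction on a pre-split template; shared fast path for
# in_silico_pcr() and the designer's cross-reactivity screen.
.pcr_products <- function(fseq, rseq, tmpl, constraints) {
  k <- constraints$three_prime_k
  max_mm <- constraints$max_internal_mismatches
  f_start <- .binding_sites(fseq, tmpl, k, max_mm, "forward")
  if (length(f_start) == 0L) {
    return(data.frame(start = integer(), end = integer(), size = integer()))
  }
  r_start <- .binding_sites(rseq, tmpl, k, max_mm, "reverse")
  if (length(r_start) == 0L) {
    return(data.frame(start = integer(), end = integer(), size = integer()))
  }
  r_end <- r_start + nchar(rseq) - 1L
  combos <- expand.grid(fs = f_start, ri = seq_along(r_start))
  rs <- r_start[combos$ri]
  re <- r_end[combos$ri]
  size <- re - combos$fs + 1L
  keep <- rs >= combos$fs &
    size >= constraints$product_window[1L] &
    size <= constraints$product_window[2L]
  out <- data.frame(start = combos$fs[keep], end = re[keep],
                    size = size[keep])
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict PCR products of a primer pair on a template
#'
#' Binding model: a primer binds where it matches the template with at most
#' `max_internal_mismatches` mismatches outside its 3'-terminal
#' `three_prime_k`-base window and zero mismatches inside it (the ARMS
#' extension-blocking rule). A product is emitted for every
#' forward/reverse binding-site pair in convergent orientation whose size
#' falls inside `product_window`. Alignment gaps in the template are
#' removed before scanning.
#'
#' @param forward,reverse [primer()] objects or sequences (5'->3').
#' @param template template sequence (A/C/G/T, `-` allowed and ignored).
#' @param constraints a [design_constraints()] object.
#' @return data.frame with columns `start`, `end`, `size` (1-based template
#'   positions), sorted by `start`; zero rows when no product is predicted.
#' @export
in_silico_pcr <- function(forward, reverse, template,
                          constraints = design_constraints()) {
  fseq <- if (inherits(forward, "primer")) forward$sequence else toupper(forward)
  rseq <- if (inherits(reverse, "primer")) reverse$sequence else toupper(reverse)
  template <- gsub("-", "", toupper(template), fixed = TRUE)
  .check_acgt(template, what = "template", allow_gap = FALSE)
  .pcr_products(fseq, rseq, .seq_chars(template), constraints)
}

#' Screen a primer pair for cross-reactivity against a database
#'
#' Runs [in_silico_pcr()] against every allele except the pair's target.
#' An empty result means the pair is predicted to be allele-specific.
#'
#' @param pair a [primer_pair()].
#' @param db an [allele_database()] containing the pair's target.
#' @param constraints a [design_constraints()] object.
#' @return character vector of non-target allele names with at least one
#'   predicted product.
#' @export
cross_reactivity <- function(pair, db, constraints = design_constraints()) {
  .get_record(db, pair$target)
  others <- setdiff(names(db$records), pair$target)
  chars <- .db_chars(db, others)
  .xr_hits(pair$forward$sequence, pair$reverse$sequence, chars, constraints)
}

# Pre-split (degapped) template characters for a set of alleles.
.db_chars <- function(db, alleles) {
  lapply(setNames(alleles, alleles), function(a) {
    .seq_chars(gsub("-", "", db$records[[a]]$cdna, fixed = TRUE))
  })
}

.xr_hits <- function(fseq, rseq, chars, constraints) {
  hits <- vapply(chars, function(tmpl) {
    nrow(.pcr_products(fseq, rseq, tmpl, constraints)) > 0L
  }, logical(1L))
  names(chars)[hits]
}

# Reverse-primer label convention: labels are presentation only, chosen so
# that plain subtraction r_label - f_label reproduces the fragment length
# (also for amplicons straddling the ATG, where coordinate arithmetic with
# no-zero labels would be off by one).
.rev_label <- function(f_label, amplicon_len) {
  r <- f_label + amplicon_len
  if (r == 0L) stop("degenerate label: amplicon ends exactly at the missing 0",
                    call. = FALSE)
  as.integer(r)
}

# --- allele-specific designer ---------------------------------------------

#' Design allele-specific primer pairs
#'
#' Enumerates primer pairs in which at least one primer places its
#' 3'-terminal base on a position that discriminates the target allele from
#' every other allele in the database (the ARMS rule), and that satisfy all
#' constraints: primer length within `len_range`, both Tm within
#' `tm_tol` of `tm_target`, amplicon within `[amp_min, amp_max]`, and no
#' predicted product on any other allele ([cross_reactivity()] empty).
#'
#' Ranking is deterministic: ascending sum of |Tm - target| over both
#' primers, then distance of the amplicon from the midpoint of the size
#' bounds, then lexicographic primer sequence.
#'
#' @param db an [allele_database()] of aligned/equal-length cDNAs.
#' @param target allele name to design against.
#' @param constraints a [design_constraints()] object.
#' @return an object of class `"design_result"`: `status` is
#'   `"ok"` (with `pairs`, a ranked list of [primer_pair()] objects),
#'   `"undesignable"` (no discriminating position exists), or
#'   `"no_pair"` (candidates existed but none satisfied every constraint;
#'   `failure_counts` tallies which constraint removed them).
#' @export
design_allele_specific <- function(db, target,
                                   constraints = design_constraints()) {
  rec <- .get_record(db, target)
  coords <- suppressWarnings(discriminating_positions(db, target))
  fail <- c(tm_allele_specific = 0L, tm_partner = 0L, amplicon = 0L,
            cross_reactivity = 0L)
  if (length(coords) == 0L) {
    return(structure(list(status = "undesignable", target = target,
                          pairs = list(), failure_counts = fail),
                     class = "design_result"))
  }
  template <- rec$cdna
  n <- nchar(template)
  disc_idx <- coord_to_index(rec, coords)
  gap_cum <- c(0L, cumsum(.seq_chars(template) == "-"))
  has_gap <- function(s, e) gap_cum[e + 1L] > gap_cum[s]
  ungapped_len <- function(s, e) (e - s + 1L) - (gap_cum[e + 1L] - gap_cum[s])
  # gap columns are masked from candidate windows below; the placeholder
  # base only ever enters Tm sums for windows that are then discarded
  twf <- .tm_window_fun(gsub("-", "A", template, fixed = TRUE))
  lens <- constraints$len_range[1L]:constraints$len_range[2L]
  tmt <- constraints$tm_target; tol <- constraints$tm_tol
  cand <- list()

  partner_windows <- function(lo, hi) {
    lo <- max(lo, 1L); hi <- min(hi, n)
    if (lo > hi) return(integer(0))
    lo:hi
  }

  for (d in disc_idx) {
    # AS primer forward: 3' terminus on the discriminating base at d
    for (L in lens) {
      s <- d - L + 1L
      if (s < 1L || has_gap(s, d)) next
      tmF <- twf(s, d)
      if (abs(tmF - tmt) > tol) { fail["tm_allele_specific"] <- fail["tm_allele_specific"] + 1L; next }
      res <- partner_windows(s + constraints$amp_min - 1L,
                             s + constraints$amp_max - 1L)
      res <- res[res > d + min(lens) - 1L]  # partner must sit 3' of the AS base
      if (length(res) == 0L) { fail["amplicon"] <- fail["amplicon"] + 1L; next }
      for (L2 in lens) {
        rs <- res - L2 + 1L
        ok <- rs > d & !vapply(seq_along(res),
                               function(i) has_gap(rs[i], res[i]), logical(1L))
        if (!any(ok)) next
        tmR <- twf(rs[ok], res[ok])
        pass <- abs(tmR - tmt) <= tol
        fail["tm_partner"] <- fail["tm_partner"] + sum(!pass)
        for (i in which(pass)) {
          re <- res[ok][i]
          cand[[length(cand) + 1L]] <- list(
            fs = s, fe = d, rs = rs[ok][i], re = re,
            tmF = tmF, tmR = tmR[i], as_side = "forward")
        }
      }
    }
    # AS primer reverse: binds the minus strand, 3' base pairing position d
    for (L in lens) {
      e <- d + L - 1L
      if (e > n || has_gap(d, e)) next
      tmR <- twf(d, e)
      if (abs(tmR - tmt) > tol) { fail["tm_allele_specific"] <- fail["tm_allele_specific"] + 1L; next }
      fss <- partner_windows(e - constraints$amp_max + 1L,
                             e - constraints$amp_min + 1L)
      fss <- fss[fss + min(lens) - 1L < d]
      if (length(fss) == 0L) { fail["amplicon"] <- fail["amplicon"] + 1L; next }
      for (L2 in lens) {
        fes <- fss + L2 - 1L
        ok <- fes < d & !vapply(seq_along(fss),
                                function(i) has_gap(fss[i], fes[i]), logical(1L))
        if (!any(ok)) next
        tmF <- twf(fss[ok], fes[ok])
        pass <- abs(tmF - tmt) <= tol
        fail["tm_partner"] <- fail["tm_partner"] + sum(!pass)
        for (i in which(pass)) {
          cand[[length(cand) + 1L]] <- list(
            fs = fss[ok][i], fe = fes[ok][i], rs = d, re = e,
            tmF = tmF[i], tmR = tmR, as_side = "reverse")
        }
      }
    }
  }

  if (length(cand) == 0L) {
    return(structure(list(status = "no_pair", target = target,
                          pairs = list(), failure_counts = fail),
                     class = "design_result"))
  }
  key <- vapply(cand, function(cc) sprintf("%d:%d:%d:%d", cc$fs, cc$fe,
                                           cc$rs, cc$re), "")
  cand <- cand[!duplicated(key)]

  mid <- (constraints$amp_min + constraints$amp_max) / 2
  fwd_seq <- vapply(cand, function(cc) substr(template, cc$fs, cc$fe), "")
  rev_seq <- vapply(cand, function(cc) .revcomp(substr(template, cc$rs, cc$re)), "")
  amp <- vapply(cand, function(cc) ungapped_len(cc$fs, cc$re), 0L)
  s1 <- vapply(cand, function(cc) abs(cc$tmF - tmt) + abs(cc$tmR - tmt), 0)
  ord <- order(s1, abs(amp - mid), fwd_seq, rev_seq)

  other_chars <- .db_chars(db, setdiff(names(db$records), target))
  pairs <- list()
  for (i in ord) {
    cc <- cand[[i]]
    xr <- .xr_hits(fwd_seq[i], rev_seq[i], other_chars, constraints)
    if (length(xr) > 0L) {
      fail["cross_reactivity"] <- fail["cross_reactivity"] + 1L
      next
    }
    f_label <- index_to_coord(rec, cc$fs)
    fwd <- primer(fwd_seq[i], "forward", label_coord = f_label)
    rev <- primer(rev_seq[i], "reverse",
                  label_coord = .rev_label(f_label, amp[i]))
    pairs[[length(pairs) + 1L]] <- primer_pair(fwd, rev, target = target,
                                               amplicon_len = amp[i])
  }
  status <- if (length(pairs) > 0L) "ok" else "no_pair"
  structure(list(status = status, target = target, pairs = pairs,
                 failure_counts = fail),
            class = "design_result")
}

#' Tabulate a design result (optionally to TSV)
#'
#' @param result a [design_allele_specific()] result.
#' @param path optional path; when given the table is written as TSV.
#' @return data.frame with one row per ranked pair: `target`, `fwd_seq`,
#'   `fwd_label`, `rev_seq`, `rev_label`, `amplicon_bp`, `fwd_tm`,
#'   `rev_tm`, `n_cross_reactive` (always 0 for emitted pairs).
#' @export
design_table <- function(result, path = NULL) {
  stopifnot(inherits(result, "design_result"))
  out <- do.call(rbind, lapply(result$pairs, function(pp) {
    data.frame(target = result$target,
               fwd_seq = pp$forward$sequence,
               fwd_label = pp$forward$label_coord,
               rev_seq = pp$reverse$sequence,
               rev_label = pp$reverse$label_coord,
               amplicon_bp = pp$amplicon_len,
               fwd_tm = pp$forward$tm, rev_tm = pp$reverse$tm,
               n_cross_reactive = 0L, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(target = character(), fwd_seq = character(),
                      fwd_label = integer(), rev_seq = character(),
                      rev_label = integer(), amplicon_bp = integer(),
                      fwd_tm = numeric(), rev_tm = numeric(),
                      n_cross_reactive = integer(), stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result> target %s: %s, %d pair(s)\n",
              x$target, x$status, length(x$pairs)))
  if (length(x$pairs) > 0L) print(x$pairs[[1L]])
  if (any(x$failure_counts > 0L)) {
    cat("  candidates rejected by constraint:\n")
    fc <- x$failure_counts[x$failure_counts > 0L]
    for (nm in names(fc)) cat(sprintf("    %s: %d\n", nm, fc[[nm]]))
  }
  invisible(x)
}

# --- locus-specific long-range designer ------------------------------------

#' Check which exon-exon junctions an amplicon covers
#'
#' @param record an [allele_record()] with an exon model.
#' @param amp_start,amp_end 1-based template indices of the amplicon.
#' @return an object of class `"splice_check"`: `junctions_covered`
#'   (data.frame of junction index and the template index of the last base
#'   of the upstream exon), `full_length_size` (bp), and
#'   `skip_variant_sizes` (named vector: amplicon size if each fully
#'   contained exon were skipped).
#' @export
splice_check <- function(record, amp_start, amp_end) {
  if (is.null(record$exons)) stop("record has no exon model", call. = FALSE)
  ex <- record$exons
  k <- nrow(ex)
  full <- amp_end - amp_start + 1L
  covered <- integer(0)
  if (k > 1L) {
    jpos <- ex[-k, "end"]
    covered <- which(amp_start <= jpos & amp_end >= jpos + 1L)
  }
  inside <- which(ex[, "start"] >= amp_start & ex[, "end"] <= amp_end)
  skip <- setNames(full - (ex[inside, "end"] - ex[inside, "start"] + 1L),
                   paste0("exon", inside))
  structure(
    list(junctions_covered = data.frame(
           junction = covered,
           boundary_index = if (k > 1L) ex[covered, "end"] else integer(0)),
         full_length_size = full,
         skip_variant_sizes = skip),
    class = "splice_check"
  )
}

#' @export
print.splice_check <- function(x, ...) {
  cat(sprintf("<splice_check> %d junction(s) covered, full length %d bp\n",
              nrow(x$junctions_covered), x$full_length_size))
  invisible(x)
}

#' Design a locus-specific long-range primer pair
#'
#' Finds a primer pair anchored in regions identical across all alleles of
#' a locus and absent (per [in_silico_pcr()]) from all other loci, whose
#' amplicon covers every exon-exon junction of the locus's exon model --
#' the design used to rule out predominant splice variants by a single
#' long-range RT-PCR per locus.
#'
#' @param db an [allele_database()].
#' @param locus locus name; at least one allele must carry an exon model.
#' @param constraints a [design_constraints()] object; see
#'   [long_range_constraints()] for the long-range defaults.
#' @return an object of class `"locus_design"`: `status` (`"ok"`,
#'   `"no_conserved_window"` or `"no_pair"`), `pair` (a [primer_pair()]
#'   or `NULL`) and `splice` (a [splice_check()] or `NULL`).
#' @export
design_locus_specific <- function(db, locus,
                                  constraints = long_range_constraints()) {
  alleles <- db$locus_index[[locus]]
  if (is.null(alleles)) stop(sprintf("locus '%s' not in database", locus),
                             call. = FALSE)
  with_ex <- alleles[!vapply(db$records[alleles],
                             function(r) is.null(r$exons), logical(1L))]
  if (length(with_ex) == 0L) {
    stop(sprintf("no allele of locus '%s' carries an exon model", locus),
         call. = FALSE)
  }
  rec <- db$records[[with_ex[1L]]]
  template <- rec$cdna
  n <- nchar(template)
  mat <- vapply(db$records[alleles], function(r) .seq_chars(r$cdna),
                character(n))
  mat <- matrix(mat, nrow = n)
  conserved <- apply(mat, 1L, function(col) length(unique(col)) == 1L) &
    .seq_chars(template) != "-"
  cons_cum <- c(0L, cumsum(!conserved))
  all_conserved <- function(s, e) cons_cum[e + 1L] == cons_cum[s]

  ex <- rec$exons
  k <- nrow(ex)
  first_j <- if (k > 1L) ex[1L, "end"] else rec$atg_pos
  last_j <- if (k > 1L) ex[k - 1L, "end"] else rec$atg_pos
  twf <- .tm_window_fun(template)
  lens <- constraints$len_range[1L]:constraints$len_range[2L]
  tmt <- constraints$tm_target; tol <- constraints$tm_tol

  window_cands <- function(starts, ends) {
    ok <- starts >= 1L & ends <= n
    starts <- starts[ok]; ends <- ends[ok]
    ok <- vapply(seq_along(starts),
                 function(i) all_conserved(starts[i], ends[i]), logical(1L))
    starts <- starts[ok]; ends <- ends[ok]
    if (length(starts) == 0L) return(NULL)
    tm <- twf(starts, ends)
    ok <- abs(tm - tmt) <= tol
    if (!any(ok)) return(NULL)
    data.frame(s = starts[ok], e = ends[ok], tm = tm[ok])
  }
  fwd <- do.call(rbind, lapply(lens, function(L) {
    s <- 1L:first_j
    window_cands(s, s + L - 1L)
  }))
  rev <- do.call(rbind, lapply(lens, function(L) {
    e <- (last_j + 1L):n
    window_cands(e - L + 1L, e)
  }))
  if (is.null(fwd) || is.null(rev)) {
    return(structure(list(status = "no_conserved_window", locus = locus,
                          pair = NULL, splice = NULL),
                     class = "locus_design"))
  }
  combos <- expand.grid(fi = seq_len(nrow(fwd)), ri = seq_len(nrow(rev)))
  size <- rev$e[combos$ri] - fwd$s[combos$fi] + 1L
  keep <- size >= constraints$amp_min & size <= constraints$amp_max &
    fwd$s[combos$fi] <= first_j & rev$e[combos$ri] >= last_j + 1L &
    rev$s[combos$ri] > fwd$e[combos$fi]
  combos <- combos[keep, , drop = FALSE]
  size <- size[keep]
  if (nrow(combos) == 0L) {
    return(structure(list(status = "no_pair", locus = locus,
                          pair = NULL, splice = NULL),
                     class = "locus_design"))
  }
  mid <- (constraints$amp_min + constraints$amp_max) / 2
  s1 <- abs(fwd$tm[combos$fi] - tmt) + abs(rev$tm[combos$ri] - tmt)
  fseqs <- substr(rep(template, nrow(combos)), fwd$s[combos$fi],
                  fwd$e[combos$fi])
  rseqs <- vapply(seq_len(nrow(combos)), function(i) {
    .revcomp(substr(template, rev$s[combos$ri[i]], rev$e[combos$ri[i]]))
  }, "")
  ord <- order(s1, abs(size - mid), fseqs, rseqs)

  other_chars <- .db_chars(db, setdiff(names(db$records), alleles))
  for (i in ord) {
    fi <- combos$fi[i]; ri <- combos$ri[i]
    if (length(.xr_hits(fseqs[i], rseqs[i], other_chars, constraints)) == 0L) {
      f_label <- index_to_coord(rec, fwd$s[fi])
      pp <- primer_pair(
        primer(fseqs[i], "forward", label_coord = f_label),
        primer(rseqs[i], "reverse",
               label_coord = .rev_label(f_label, size[i])),
        target = locus, amplicon_len = size[i])
      sc <- splice_check(rec, fwd$s[fi], rev$e[ri])
      return(structure(list(status = "ok", locus = locus, pair = pp,
                            splice = sc),
                       class = "locus_design"))
    }
  }
  structure(list(status = "no_pair", locus = locus, pair = NULL,
                 splice = NULL),
            class = "locus_design")
}

#' @export
print.locus_design <- function(x, ...) {
  cat(sprintf("<locus_design> locus %s: %s\n", x$locus, x$status))
  if (!is.null(x$pair)) print(x$pair)
  if (!is.null(x$splice)) print(x$splice)
  invisible(x)
}

# --- independent validator --------------------------------------------------

#' Re-validate a primer pair against every design constraint
#'
#' An independent checker: every constraint is re-evaluated from scratch
#' (per-primer Tm via [tm_nearest_neighbor()], primer location by exact
#' string match, discrimination via [discriminating_positions()],
#' cross-reactivity via [cross_reactivity()]); it shares no code with the
#' designer's enumeration or pruning. When the pair cannot be located on a
#' database sequence (e.g. published primers without their reference
#' sequence), the amplicon check falls back on the pair's stored amplicon
#' length or its coordinate-label difference, and sequence-dependent checks
#' are reported as `NA`.
#'
#' @param pair a [primer_pair()].
#' @param db optional [allele_database()] holding the pair's target.
#' @param constraints a [design_constraints()] object.
#' @return data.frame with columns `constraint`, `pass`, `observed`.
#' @export
validate_pair <- function(pair, db = NULL,
                          constraints = design_constraints()) {
  ck <- function(constraint, pass, observed) {
    data.frame(constraint = constraint, pass = pass,
               observed = as.character(observed), stringsAsFactors = FALSE)
  }
  out <- list()
  for (side in c("forward", "reverse")) {
    p <- pair[[side]]
    L <- nchar(p$sequence)
    out[[length(out) + 1L]] <- ck(
      paste0(side, "_length"),
      L >= constraints$len_range[1L] && L <= constraints$len_range[2L], L)
    tm <- tm_nearest_neighbor(p$sequence)
    out[[length(out) + 1L]] <- ck(
      paste0(side, "_tm"),
      abs(tm - constraints$tm_target) <= constraints$tm_tol,
      sprintf("%.2f", tm))
  }

  fs <- fe <- rs <- re <- NA_integer_
  located <- FALSE
  if (!is.null(db) && !is.na(pair$target) && pair$target %in% names(db$records)) {
    template <- gsub("-", "", db$records[[pair$target]]$cdna, fixed = TRUE)
    fhit <- gregexpr(pair$forward$sequence, template, fixed = TRUE)[[1L]]
    rhit <- gregexpr(.revcomp(pair$reverse$sequence), template, fixed = TRUE)[[1L]]
    if (fhit[1L] > 0L && rhit[1L] > 0L) {
      located <- TRUE
      fs <- as.integer(fhit[1L]); fe <- fs + nchar(pair$forward$sequence) - 1L
      rs <- as.integer(rhit[length(rhit)])
      re <- rs + nchar(pair$reverse$sequence) - 1L
    }
  }
  amp <- if (located) re - fs + 1L else
    if (!is.na(pair$amplicon_len)) pair$amplicon_len else pair$label_len
  out[[length(out) + 1L]] <- ck(
    "amplicon",
    !is.na(amp) && amp >= constraints$amp_min && amp <= constraints$amp_max,
    amp)

  if (!is.null(db) && !is.na(pair$target) &&
      pair$target %in% names(db$records)) {
    coords <- suppressWarnings(discriminating_positions(db, pair$target))
    if (located && length(coords) > 0L) {
      rec <- db$records[[pair$target]]
      disc_idx <- coord_to_index(rec, coords)
      hit <- fe %in% disc_idx || rs %in% disc_idx
      out[[length(out) + 1L]] <- ck("three_prime_discrimination", hit,
                                    if (hit) "anchored" else "not anchored")
    } else {
      out[[length(out) + 1L]] <- ck("three_prime_discrimination", NA,
                                    "primers not located on target")
    }
    xr <- cross_reactivity(pair, db, constraints)
    out[[length(out) + 1L]] <- ck("cross_reactivity", length(xr) == 0L,
                                  if (length(xr) == 0L) "none" else
                                    paste(xr, collapse = ","))
  }
  do.call(rbind, out)
}
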