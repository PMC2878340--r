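#' @importFrom stats coef lm median predict rbinom rlnorm rnorm runif setNames var
#' @importFrom utils read.delim write.table
#' @importFrom tools md5sum
NULL

# Internal sequence helpers. Sequences are stored as plain uppercase character
# strings; "-" marks an alignment gap and is excluded from scanning.

.seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.revcomp <- function(s) {
  paste(rev(.seq_chars(chartr("ACGTacgt-", "TGCAtgca-", s))), collapse = "")
}

.check_acgt <- function(s, what = "sequence", allow_gap = TRUE) {
  alphabet <- if (allow_gap) "ACGT-" else "ACGT"
  bad <- setdiff(unique(.seq_chars(s)), .seq_chars(alphabet))
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-ACGT symbol(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a single allele record
#'
#' An allele record holds the cDNA sequence of one allele of a polymorphic
#' gene family, the position of the translation start, and (optionally) an
#' exon model. Coordinates used throughout the package are "ATG-anchored":
#' +1 is the A of the start codon, -1 the base immediately 5' of it, and
#' there is no coordinate 0 (the convention used in primer names such as
#' `HLA-A020101-272F`).
#'
#' @param name allele identifier of the form `LOCUS*ff:ff...`, e.g.
#'   `"A*02:01:01"`. The text before `*` is the locus; the colon-separated
#'   fields must be numeric.
#' @param cdna nucleotide string over A/C/G/T (case-insensitive; `U` is
#'   mapped to `T`; `-` marks an alignment gap).
#' @param atg_pos 1-based position of the A of the start codon within `cdna`.
#' @param exons optional integer matrix with columns `start`, `end` (1-based,
#'   inclusive) giving an ordered, contiguous partition of the coding
#'   portion of the cDNA.
#' @return an object of class `"allele_record"`.
#' @export
allele_record <- function(name, cdna, atg_pos, exons = NULL) {
  if (!grepl("^[^*]+\\*[0-9]+(:[0-9]+)*$", name)) {
    stop(sprintf("allele name '%s' does not parse as LOCUS*ff[:ff...]", name),
         call. = FALSE)
  }
  cdna <- chartr("uU", "tT", cdna)
  cdna <- toupper(cdna)
  .check_acgt(cdna, what = sprintf("allele '%s'", name))
  atg_pos <- as.integer(atg_pos)
  if (is.na(atg_pos) || atg_pos < 1L || atg_pos + 2L > nchar(cdna) ||
      substr(cdna, atg_pos, atg_pos + 2L) != "ATG") {
    stop(sprintf("allele '%s': no ATG at position %s", name, atg_pos),
         call. = FALSE)
  }
  if (!is.null(exons)) {
    exons <- matrix(as.integer(exons), ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))
    if (nrow(exons) < 1L || any(exons[, "end"] < exons[, "start"])) {
      stop("exon intervals must be non-empty with end >= start", call. = FALSE)
    }
    if (nrow(exons) > 1L &&
        any(exons[-1L, "start"] != exons[-nrow(exons), "end"] + 1L)) {
      stop("exon intervals must be ordered and contiguous", call. = FALSE)
    }
    if (exons[1L, "start"] != atg_pos) {
      stop("first exon must start at the ATG", call. = FALSE)
    }
  }
  structure(
    list(name = name,
         locus = sub("\\*.*$", "", name),
         cdna = cdna,
         atg_pos = atg_pos,
         exons = exons),
    class = "allele_record"
  )
}

#' @export
print.allele_record <- function(x, ...) {
  cat(sprintf("<allele_record> %s  (%d nt, ATG at %d%s)\n",
              x$name, nchar(x$cdna), x$atg_pos,
              if (is.null(x$exons)) "" else
                sprintf(", %d exons", nrow(x$exons))))
  invisible(x)
}

#' Construct an allele database
#'
#' @param records list of [allele_record()] objects with unique names.
#' @return an object of class `"allele_db"` with elements `records` (named
#'   list) and `locus_index` (named list mapping locus to allele names).
#' @export
allele_database <- function(records) {
  nms <- vapply(records, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate allele name(s): %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")),
         call. = FALSE)
  }
  names(records) <- nms
  loci <- vapply(records, `[[`, "", "locus")
  structure(
    list(records = records,
         locus_index = split(nms, loci)),
    class = "allele_db"
  )
}

#' @export
print.allele_db <- function(x, ...) {
  cat(sprintf("<allele_db> %d alleles over %d loci\n",
              length(x$records), length(x$locus_index)))
  for (loc in names(x$locus_index)) {
    cat(sprintf("  %s: %s\n", loc, paste(x$locus_index[[loc]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
length.allele_db <- function(x) length(x$records)

.get_record <- function(db, name) {
  rec <- db$records[[name]]
  if (is.null(rec)) {
    stop(sprintf("allele '%s' not found in database", name), call. = FALSE)
  }
  rec
}

# Parse one FASTA header of the dialect
#   >HLA:<id> <allele name> <length> bp [atg=<0-based>] [exons=s1-e1,...]
# Exon annotations are 0-based half-open on the wire and converted to the
# package's 1-based inclusive representation.
.parse_header <- function(header) {
  toks <- strsplit(trimws(header), "[[:space:]]+")[[1]]
  name <- toks[grepl("^[^*=]+\\*[0-9]+(:[0-9]+)*$", toks)]
  if (length(name) == 0L) {
    stop(sprintf("no allele name token (LOCUS*ff:ff...) in header '%s'", header),
         call. = FALSE)
  }
  atg_tok <- toks[grepl("^atg=", toks)]
  exon_tok <- toks[grepl("^exons=", toks)]
  atg_pos <- if (length(atg_tok) > 0L) {
    as.integer(sub("^atg=", "", atg_tok[1L])) + 1L
  } else NA_integer_
  exons <- NULL
  if (length(exon_tok) > 0L) {
    pieces <- strsplit(sub("^exons=", "", exon_tok[1L]), ",", fixed = TRUE)[[1]]
    se <- do.call(rbind, lapply(strsplit(pieces, "-", fixed = TRUE), as.integer))
    exons <- cbind(start = se[, 1L] + 1L, end = se[, 2L])
  }
  list(name = name[1L], atg_pos = atg_pos, exons = exons)
}

#' Parse an allele multi-FASTA into a database
#'
#' Reads an IMGT/HLA-style multi-record FASTA. Each header must contain an
#' allele name token `LOCUS*ff[:ff...]`; optional `atg=<0-based index>` and
#' `exons=<s1-e1,...>` (0-based half-open) tokens carry the start codon and
#' exon model. Without an `atg=` annotation the first ATG in the sequence is
#' used. Sequences are case-folded to upper case and `U` is mapped to `T`.
#'
#' @param x path to a FASTA file, or the FASTA text itself (detected by the
#'   presence of a `>` record start).
#' @return an [allele_database()].
#' @export
parse_allele_fasta <- function(x) {
  if (length(x) == 1L && grepl("^[[:space:]]*>", x)) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(x, path)
  } else {
    path <- x
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records found", call. = FALSE)
  records <- lapply(seq_along(set), function(i) {
    hdr <- .parse_header(names(set)[i])
    seq <- toupper(chartr("uU", "tT", as.character(set[[i]])))
    if (nchar(seq) == 0L) {
      stop(sprintf("record '%s' has an empty sequence", hdr$name), call. = FALSE)
    }
    atg_pos <- hdr$atg_pos
    if (is.na(atg_pos)) {
      atg_pos <- as.integer(regexpr("ATG", seq, fixed = TRUE))
      if (atg_pos < 1L) {
        stop(sprintf("record '%s': sequence contains no ATG", hdr$name),
             call. = FALSE)
      }
    }
    allele_record(hdr$name, seq, atg_pos, exons = hdr$exons)
  })
  allele_database(records)
}

#' Write an allele database to FASTA
#'
#' Emits the same header dialect that [parse_allele_fasta()] reads, so a
#' parse -> write -> parse round trip preserves every field.
#'
#' @param db an [allele_database()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(db, path) {
  stopifnot(inherits(db, "allele_db"))
  headers <- vapply(db$records, function(rec) {
    h <- sprintf("HLA:%s %s %d bp atg=%d", gsub("[*:]", "", rec$name),
                 rec$name, nchar(rec$cdna), rec$atg_pos - 1L)
    if (!is.null(rec$exons)) {
      h <- paste0(h, " exons=",
                  paste(sprintf("%d-%d", rec$exons[, "start"] - 1L,
                                rec$exons[, "end"]), collapse = ","))
    }
    h
  }, "")
  set <- Biostrings::BStringSet(vapply(db$records, `[[`, "", "cdna"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Convert between ATG-anchored coordinates and sequence indices
#'
#' ATG-anchored coordinates have no zero: +1 is the A of the start codon and
#' -1 immediately precedes it. `coord_to_index()` maps a coordinate to the
#' 1-based index within the cDNA; `index_to_coord()` is its inverse.
#'
#' @param record an [allele_record()].
#' @param coord integer vector of nonzero ATG-anchored coordinates.
#' @param index integer vector of 1-based sequence indices.
#' @return integer vector of indices (resp. coordinates).
#' @export
coord_to_index <- function(record, coord) {
  coord <- as.integer(coord)
  if (any(coord == 0L, na.rm = TRUE)) {
    stop("ATG-anchored coordinate 0 does not exist (-1 precedes +1)",
         call. = FALSE)
  }
  idx <- ifelse(coord >= 1L, record$atg_pos + coord - 1L, record$atg_pos + coord)
  if (any(idx < 1L | idx > nchar(record$cdna), na.rm = TRUE)) {
    stop("coordinate maps outside the sequence", call. = FALSE)
  }
  as.integer(idx)
}

#' @rdname coord_to_index
#' @export
index_to_coord <- function(record, index) {
  index <- as.integer(index)
  if (any(index < 1L | index > nchar(record$cdna), na.rm = TRUE)) {
    stop("index outside the sequence", call. = FALSE)
  }
  delta <- index - record$atg_pos
  as.integer(ifelse(delta >= 0L, delta + 1L, delta))
}

#' Positions discriminating one allele from all others
#'
#' Scans the (pre-aligned or equal-length, ungapped) database for positions
#' at which the target's base differs from the base of *every* other allele
#' in the comparison set. These are the positions where an allele-specific
#' primer can anchor its 3' terminus (the ARMS principle). By default the
#' comparison set is every other allele in the database regardless of locus,
#' since cross-locus similarity is what causes cross-reactive priming in
#' families like HLA-A/B/C; `within_locus = TRUE` restricts it.
#'
#' Alignment gap columns (`-` in the target or any comparator) map to no
#' position and are skipped.
#'
#' @param db an [allele_database()] of equal-length sequences.
#' @param target allele name present in `db`.
#' @param within_locus restrict the comparison set to the target's locus?
#' @return integer vector of ATG-anchored coordinates, ascending. A database
#'   with no comparator yields `integer(0)` with a warning.
#' @export
discriminating_positions <- function(db, target, within_locus = FALSE) {
  rec <- .get_record(db, target)
  others <- if (within_locus) {
    setdiff(db$locus_index[[rec$locus]], target)
  } else {
    setdiff(names(db$records), target)
  }
  if (length(others) == 0L) {
    warning("no comparison alleles in database; no discriminating positions",
            call. = FALSE)
    return(integer(0))
  }
  n <- nchar(rec$cdna)
  lens <- vapply(db$records[others], function(r) nchar(r$cdna), 0L)
  if (any(lens != n)) {
    stop("sequences must be pre-aligned or equal-length for column comparison",
         call. = FALSE)
  }
  tgt <- .seq_chars(rec$cdna)
  mat <- matrix(vapply(db$records[others], function(r) .seq_chars(r$cdna),
                       character(n)), nrow = n)
  gap <- tgt == "-" | rowSums(mat == "-") > 0L
  disc <- !gap & rowSums(mat != tgt) == length(others)
  sort(index_to_coord(rec, which(disc)))
}

#' Table of discriminating positions for every allele
#'
#' Runs [discriminating_positions()] for each allele and tabulates the
#' target base and the bases carried by the other alleles at each site, in
#' the layout used for TSV export.
#'
#' @inheritParams discriminating_positions
#' @param path optional path; when given the table is written as TSV.
#' @return data.frame with columns `allele`, `coord`, `target_base`,
#'   `other_bases`.
#' @export
discrimination_table <- function(db, within_locus = FALSE, path = NULL) {
  rows <- lapply(names(db$records), function(a) {
    coords <- suppressWarnings(
      discriminating_positions(db, a, within_locus = within_locus))
    if (length(coords) == 0L) return(NULL)
    rec <- db$records[[a]]
    idx <- coord_to_index(rec, coords)
    others <- setdiff(names(db$records), a)
    other_bases <- vapply(idx, function(i) {
      paste(sort(unique(vapply(db$records[others],
                               function(r) substr(r$cdna, i, i), ""))),
            collapse = "/")
    }, "")
    data.frame(allele = a, coord = coords,
               target_base = vapply(idx, function(i) substr(rec$cdna, i, i), ""),
               other_bases = other_bases, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(allele = character(), coord = integer(),
                      target_base = character(), other_bases = character(),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
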