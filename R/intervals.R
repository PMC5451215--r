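# Genomic intervals are plain data frames with 0-based half-open coordinates
# (the BED convention), columns: chrom, start, end, and optionally name,
# score, strand plus extra columns. Conversion to 1-based closed coordinates
# happens only at the GRanges boundary.

.empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

.validate_intervals <- function(x, assembly = NULL, what = "interval") {
  .assert(all(c("chrom", "start", "end") %in% names(x)),
          "%s table needs chrom/start/end columns", what)
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!(x$start >= 0 & x$end > x$start))
  .assert(length(bad) == 0, "%s %s violates 0 <= start < end", what,
          paste(bad, collapse = ","))
  if (!is.null(assembly)) {
    unk <- setdiff(unique(x$chrom), chrom_names(assembly))
    .assert(length(unk) == 0, "unknown chromosome(s): %s",
            paste(unk, collapse = ", "))
    over <- which(x$end > assembly$lengths[x$chrom])
    .assert(length(over) == 0, "%s %s extends beyond chromosome end", what,
            paste(over, collapse = ","))
  }
  invisible(x)
}

# data.frame -> GRanges (1-based closed) for overlap machinery.
.as_granges <- function(x, assembly = NULL) {
  sl <- if (!is.null(assembly)) assembly$lengths else NULL
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*",
    seqlengths = sl)
}

# For each row of x, does it overlap (>= 1 bp) any row of y?
.overlaps_any <- function(x, y) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  GenomicRanges::countOverlaps(.as_granges(x), .as_granges(y),
                               ignore.strand = TRUE) > 0
}

#' Read genomic intervals from BED or TSV
#'
#' BED coordinates are 0-based half-open and are taken directly as the
#' internal convention; the strand column is honored when present and record
#' order is preserved. A TSV file must have a header with at least
#' chrom/start/end columns.
#'
#' @param path Path to the file.
#' @param format `"bed"` or `"tsv"`.
#' @return A data frame with columns chrom, start, end and, when present,
#'   name, score, strand plus any extra columns.
#' @export
read_intervals <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  .assert(file.exists(path), "file not found: %s", path)
  if (format == "tsv") {
    x <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
    .validate_intervals(x, what = "TSV row")
    return(x)
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(.empty_intervals()[0, 1:3])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  .assert(all(nf >= 3), "malformed BED line %s: fewer than 3 columns",
          paste(lineno[nf < 3], collapse = ","))
  ncol_use <- min(nf, 6L)
  x <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L))),
    end = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L))),
    stringsAsFactors = FALSE)
  badnum <- which(is.na(x$start) | is.na(x$end))
  .assert(length(badnum) == 0, "malformed BED line %s: non-numeric coordinate",
          paste(lineno[badnum], collapse = ","))
  if (ncol_use >= 4) x$name <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else ".", "")
  if (ncol_use >= 5) x$score <- suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5) f[[5]] else "0", "")))
  if (ncol_use >= 6) {
    x$strand <- vapply(fields, function(f) if (length(f) >= 6) f[[6]] else "*", "")
    x$strand[!x$strand %in% c("+", "-")] <- "*"
  }
  badc <- which(x$end <= x$start)
  .assert(length(badc) == 0, "BED line %s: end <= start",
          paste(lineno[badc], collapse = ","))
  x
}

#' Write genomic intervals as BED
#'
#' Writes BED3 when only coordinates are present, otherwise BED6. Extra
#' columns named in `extra` are appended after the strand column.
#'
#' @param x Interval data frame (0-based half-open).
#' @param path Output path.
#' @param extra Character vector of extra column names to append.
#' @export
write_intervals <- function(x, path, extra = character()) {
  .validate_intervals(x)
  out <- data.frame(chrom = x$chrom,
                    start = format(x$start, scientific = FALSE, trim = TRUE),
                    end = format(x$end, scientific = FALSE, trim = TRUE),
                    stringsAsFactors = FALSE)
  has6 <- any(c("name", "score", "strand") %in% names(x)) || length(extra)
  if (has6) {
    out$name <- if ("name" %in% names(x)) x$name else "."
    out$score <- if ("score" %in% names(x)) x$score else 0
    out$strand <- if ("strand" %in% names(x)) x$strand else "*"
    for (cc in extra) out[[cc]] <- x[[cc]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Median distance between neighboring site summits
#'
#' @param positions Numeric vector of summit positions on one chromosome.
#' @return Median of the sorted neighbor distances (NA with < 2 positions).
#' @export
median_intersite_distance <- function(positions) {
  if (length(positions) < 2) return(NA_real_)
  stats::median(diff(sort(positions)))
}
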