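# Coverage tracks: dense per-base numeric vectors, one per chromosome,
# indexed internally with 0-based offsets (value at base offset p is
# values[[chrom]][p + 1]). Dense vectors are the canonical form; the package
# targets desk-scale genomes where simplicity of window statistics wins.

#' Construct a coverage track
#'
#' @param values Named list of per-chromosome numeric vectors at 1-bp
#'   resolution.
#' @param assembly Optional `genome_assembly`; when given, vector lengths are
#'   checked against the declared chromosome lengths.
#' @param label Free-text label (protein, strain, replicate).
#' @param kind One of `"raw"`, `"normalized"`, `"enrichment"`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, assembly = NULL, label = "",
                           kind = c("raw", "normalized", "enrichment")) {
  kind <- match.arg(kind)
  .assert(is.list(values) && !is.null(names(values)),
          "values must be a named list of numeric vectors")
  for (nm in names(values)) {
    .assert(is.numeric(values[[nm]]), "track values for %s not numeric", nm)
    .assert(all(is.finite(values[[nm]])), "non-finite values on %s", nm)
  }
  if (!is.null(assembly)) {
    unk <- setdiff(names(values), chrom_names(assembly))
    .assert(length(unk) == 0, "unknown chromosome(s): %s",
            paste(unk, collapse = ", "))
    for (nm in names(values)) {
      .assert(length(values[[nm]]) == chrom_length(assembly, nm),
              "track length %d on %s differs from assembly length %d",
              length(values[[nm]]), nm, chrom_length(assembly, nm))
    }
  }
  structure(list(values = values, label = label, kind = kind),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track [%s] '%s': %d chromosome(s), %.3g bp\n",
              x$kind, x$label, length(x$values),
              sum(vapply(x$values, length, 0L))))
  invisible(x)
}

track_chroms <- function(track) names(track$values)

.same_chroms <- function(tracks) {
  nms <- lapply(tracks, track_chroms)
  all(vapply(nms, function(n) identical(sort(n), sort(nms[[1]])), TRUE)) &&
    all(vapply(tracks[-1], function(t) {
      all(vapply(nms[[1]], function(ch)
        length(t$values[[ch]]) == length(tracks[[1]]$values[[ch]]), TRUE))
    }, TRUE))
}

#' Read a coverage track from wiggle or bedGraph
#'
#' Wiggle fixedStep/variableStep 1-based positions are converted to the
#' internal 0-based offsets; bedGraph half-open intervals are expanded to
#' per-base values. Bases not covered by the file default to 0.
#'
#' @param path Path to the file.
#' @param format `"bedgraph"` or `"wig"`.
#' @param assembly A `genome_assembly`; declared chromosomes must exist and
#'   positions must lie within their lengths.
#' @inheritParams coverage_track
#' @return A `coverage_track` covering every assembly chromosome.
#' @export
read_track <- function(path, format = c("bedgraph", "wig"), assembly,
                       label = "", kind = c("raw", "normalized", "enrichment")) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  .assert(file.exists(path), "file not found: %s", path)
  gr <- rtracklayer::import(path,
                            format = if (format == "wig") "wig" else "bedGraph")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  unk <- setdiff(unique(chroms), chrom_names(assembly))
  .assert(length(unk) == 0, "track declares unknown chromosome(s): %s",
          paste(unk, collapse = ", "))
  ends <- GenomicRanges::end(gr)
  over <- ends > assembly$lengths[chroms]
  .assert(!any(over), "position beyond chromosome length on %s",
          paste(unique(chroms[over]), collapse = ", "))
  values <- lapply(chrom_names(assembly),
                   function(ch) numeric(chrom_length(assembly, ch)))
  names(values) <- chrom_names(assembly)
  starts <- GenomicRanges::start(gr)  # 1-based
  scores <- GenomicRanges::score(gr)
  widths <- GenomicRanges::width(gr)
  for (ch in unique(chroms)) {
    sel <- chroms == ch
    idx <- sequence(widths[sel], from = starts[sel])
    values[[ch]][idx] <- rep(scores[sel], widths[sel])
  }
  coverage_track(values, assembly = assembly, label = label, kind = kind)
}

#' Write a coverage track as bedGraph
#'
#' Consecutive equal values are run-length collapsed; zero runs are omitted
#' (absent bases read back as 0, so write/read round-trips per-base values).
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @param assembly Optional assembly supplying seqlengths.
#' @export
write_track <- function(track, path, assembly = NULL) {
  chroms <- starts <- ends <- scores <- list()
  for (ch in track_chroms(track)) {
    r <- rle(track$values[[ch]])
    e <- cumsum(r$lengths)
    s <- e - r$lengths  # 0-based starts
    keep <- r$values != 0
    chroms[[ch]] <- rep(ch, sum(keep))
    starts[[ch]] <- s[keep]
    ends[[ch]] <- e[keep]
    scores[[ch]] <- r$values[keep]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = unlist(chroms, use.names = FALSE) %||% character(),
    ranges = IRanges::IRanges(
      start = unlist(starts, use.names = FALSE) + 1,
      end = unlist(ends, use.names = FALSE)),
    score = unlist(scores, use.names = FALSE))
  if (!is.null(assembly)) {
    GenomeInfoDb::seqlengths(gr) <-
      assembly$lengths[GenomeInfoDb::seqlevels(gr)]
  }
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# Mean track value over 0-based half-open windows on one chromosome.
track_window_means <- function(track, chrom, starts, ends) {
  v <- track$values[[chrom]]
  .assert(!is.null(v), "track has no chromosome '%s'", chrom)
  s <- pmax(as.integer(round(starts)), 0L)
  e <- pmin(as.integer(round(ends)), length(v))
  .assert(all(e > s), "empty window after clipping")
  .window_means(v, s, e)
}
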