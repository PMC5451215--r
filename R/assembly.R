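#' Construct a genome assembly
#'
#' A genome assembly names the chromosomes, records their lengths, optionally
#' carries their sequence, and flags the chromosome treated as "X" in
#' X-versus-autosome analyses plus an optional mitochondrial chromosome that
#' genome-wide statistics exclude.
#'
#' @param lengths Named numeric vector of chromosome lengths in base pairs.
#' @param sequence Optional named character vector of chromosome sequences
#'   over A/C/G/T/N; names and lengths must match `lengths`.
#' @param x_name Name of the chromosome treated as X (optional).
#' @param mito_name Name of the mitochondrial chromosome (optional); it is
#'   excluded from genome-wide normalization and motif statistics.
#' @return An object of class `genome_assembly`.
#' @export
genome_assembly <- function(lengths, sequence = NULL, x_name = NULL,
                            mito_name = NULL) {
  .assert(length(lengths) > 0 && !is.null(names(lengths)) &&
            all(nzchar(names(lengths))), "chromosome lengths must be named")
  .assert(!anyDuplicated(names(lengths)), "duplicate chromosome names")
  .assert(all(is.finite(lengths)) && all(lengths > 0),
          "every chromosome must have a positive length")
  if (!is.null(sequence)) {
    .assert(all(names(sequence) %in% names(lengths)),
            "sequence names must match chromosome names")
    sequence <- toupper(sequence)
    bad <- names(sequence)[nchar(sequence) != lengths[names(sequence)]]
    .assert(length(bad) == 0,
            "sequence length disagrees with declared length for: %s",
            paste(bad, collapse = ", "))
  }
  for (nm in c(x_name, mito_name)) {
    .assert(nm %in% names(lengths), "chromosome '%s' not in assembly", nm)
  }
  structure(list(lengths = lengths, sequence = sequence,
                 x_name = x_name, mito_name = mito_name),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly: %d chromosomes, %.3g bp total%s\n",
              length(x$lengths), sum(x$lengths),
              if (is.null(x$sequence)) "" else " (with sequence)"))
  if (!is.null(x$x_name)) cat("  X:", x$x_name, "\n")
  if (!is.null(x$mito_name)) cat("  mito:", x$mito_name, "\n")
  invisible(x)
}

chrom_names <- function(assembly) names(assembly$lengths)

chrom_length <- function(assembly, chrom) {
  .assert(chrom %in% chrom_names(assembly),
          "unknown chromosome '%s'", chrom)
  unname(assembly$lengths[chrom])
}

# Chromosomes entering genome-wide statistics (mito excluded).
.non_mito <- function(assembly) {
  setdiff(chrom_names(assembly), assembly$mito_name)
}

.autosomes <- function(assembly) {
  setdiff(.non_mito(assembly), assembly$x_name)
}

#' Read a genome assembly from a FASTA file
#'
#' Sequences are uppercased; record order is preserved. Duplicate record
#' names and empty records are errors.
#'
#' @param path Path to a FASTA file.
#' @inheritParams genome_assembly
#' @return A `genome_assembly` with sequence.
#' @export
read_fasta <- function(path, x_name = NULL, mito_name = NULL) {
  .assert(file.exists(path), "file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  nms <- sub("\\s.*$", "", names(ss))
  .assert(!anyDuplicated(nms), "duplicate FASTA record names: %s",
          paste(unique(nms[duplicated(nms)]), collapse = ", "))
  .assert(all(Biostrings::width(ss) > 0), "empty FASTA record: %s",
          paste(nms[Biostrings::width(ss) == 0], collapse = ", "))
  seqs <- toupper(as.character(ss))
  names(seqs) <- nms
  lens <- nchar(seqs)
  names(lens) <- nms
  genome_assembly(lens, sequence = seqs, x_name = x_name,
                  mito_name = mito_name)
}

#' Write a genome assembly to FASTA
#'
#' @param assembly A `genome_assembly` carrying sequence.
#' @param path Output path.
#' @export
write_fasta <- function(assembly, path) {
  .assert(!is.null(assembly$sequence), "assembly has no sequence")
  ss <- Biostrings::DNAStringSet(assembly$sequence)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
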