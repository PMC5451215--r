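# Shared builders and independent oracles used across the test files.

# Constant-valued track over a set of chromosome lengths.
const_track <- function(lengths, value = 1, kind = "raw", label = "") {
  coverage_track(lapply(as.list(lengths), function(L) rep(value, L)),
                 label = label, kind = kind)
}

tiny_assembly <- function(lengths = c(chrA = 1000, chrX = 2000,
                                      chrM = 100),
                          sequence = NULL) {
  genome_assembly(
    lengths, sequence = sequence,
    x_name = if ("chrX" %in% names(lengths)) "chrX",
    mito_name = if ("chrM" %in% names(lengths)) "chrM")
}

# Peak row helper (0-based half-open, summit at the interval midpoint
# unless given).
mk_peaks <- function(chrom, start, end, summit = NULL, height = 1) {
  data.frame(chrom = chrom, start = start, end = end,
             summit = summit %||% floor((start + end) / 2),
             summit_height = height, score = height,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force motif scoring oracle: per start position, score the 12-mer and
# its reverse complement directly through score_sequences() and keep the
# better strand. Returns NA where the window contains a non-ACGT base.
brute_scan <- function(seq, model, w = 12L) {
  n <- nchar(seq) - w + 1L
  vapply(seq_len(n), function(p) {
    s <- substr(seq, p, p + w - 1L)
    if (grepl("[^ACGT]", s)) return(NA_real_)
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    max(score_sequences(model, s), score_sequences(model, rc))
  }, 0)
}

# Exhaustive hypergeometric tail oracle for the one-sided Fisher window
# test: probability of k or more "up" genes in a window of n genes, given K
# up among N total, summed table by table with binomial coefficients.
hyper_tail <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(vapply(js, function(j)
    choose(K, j) * choose(N - K, n - j), 0)) / choose(N, n)
}

# Direct evaluation of the majority rule for consensus peaks.
majority_oracle <- function(combined, replicate_sets) {
  votes <- vapply(seq_len(nrow(combined)), function(i) {
    sum(vapply(replicate_sets, function(r) {
      any(r$chrom == combined$chrom[i] &
            r$start < combined$end[i] & r$end > combined$start[i])
    }, TRUE))
  }, 0)
  out <- combined[votes > length(replicate_sets) / 2, , drop = FALSE]
  rownames(out) <- NULL
  out
}
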