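# Domain-scale quantification of DCC binding loss after a recruitment-site
# deletion: variable-step sliding windows over binding peaks, percent
# deviation from wild type normalized at an anchor locus, depleted-region
# extraction, TAD-boundary proximity permutation test, and windowed Fisher
# tests of the expression response.

#' Sliding-window deviation of deletion-strain binding from wild type
#'
#' For every binding peak, the log2 ratio of mean deletion-strain enrichment
#' to mean wild-type enrichment over the peak is computed (means floored at
#' `eps`). A window of width `window` is stepped across each peak center;
#' member peaks are those whose centers lie within half a window of the
#' center. The window mean log2 ratio m is normalized by subtracting the
#' log2 ratio at the anchor locus (a designated positive-control site), and
#' the percent deviation from wild type is 100 * (2^(m - r_anchor) - 1).
#' Significance per window is a one-tailed two-sample Welch t-test of the
#' member log2 ratios against the log2 ratios of all peaks on the
#' chromosome (alternative: window lower); window members are included in
#' the chromosome-wide reference unless `exclude_window_from_reference`.
#'
#' @param wt,del Enrichment `coverage_track`s for wild type and the deletion
#'   strain.
#' @param peaks Peak data frame on a single chromosome (nonempty).
#' @param anchor Anchor interval (1-row data frame chrom/start/end); it must
#'   overlap at least one peak.
#' @param window Window size in bp (default 2 Mb).
#' @param alpha Significance level for the per-window flag.
#' @param eps Floor for per-peak means before log2.
#' @param exclude_window_from_reference Drop window members from the
#'   chromosome-wide reference distribution (default FALSE).
#' @return An object of class `deletion_effect_profile`: data frame with
#'   center, n_members, m (window mean log2 ratio), m_norm, percent
#'   deviation, p, significant; attributes `anchor_log2`, `window`, `alpha`,
#'   `peak_log2` (per-peak ratios).
#' @export
sliding_window_deviation <- function(wt, del, peaks, anchor,
                                     window = 2e6, alpha = 0.05, eps = 1e-3,
                                     exclude_window_from_reference = FALSE) {
  .assert(nrow(peaks) > 0, "peak set is empty")
  .assert(length(unique(peaks$chrom)) == 1,
          "sliding-window analysis expects peaks on a single chromosome")
  .assert(eps > 0, "eps must be > 0")
  ch <- peaks$chrom[1]
  mw <- pmax(track_window_means(wt, ch, peaks$start, peaks$end), eps)
  md <- pmax(track_window_means(del, ch, peaks$start, peaks$end), eps)
  lr <- log2(md / mw)
  centers <- (peaks$start + peaks$end) / 2
  on_anchor <- .overlaps_any(peaks, anchor)
  .assert(any(on_anchor), "anchor interval overlaps no peak")
  r_anchor <- mean(lr[on_anchor])
  half <- window / 2
  ord <- order(centers)
  m <- p <- rep(NA_real_, length(centers))
  nmem <- integer(length(centers))
  for (i in seq_along(centers)) {
    memb <- abs(centers - centers[i]) <= half
    nmem[i] <- sum(memb)
    m[i] <- mean(lr[memb])
    if (nmem[i] >= 2) {
      ref <- if (exclude_window_from_reference) lr[!memb] else lr
      if (length(ref) >= 2) {
        p[i] <- .welch_one_tailed(lr[memb], ref, "less")$p.value
      }
    }
  }
  m_norm <- m - r_anchor
  prof <- data.frame(chrom = ch, center = centers, n_members = nmem,
                     m = m, m_norm = m_norm,
                     percent_deviation = 100 * (2^m_norm - 1),
                     p = p, significant = !is.na(p) & p < alpha,
                     stringsAsFactors = FALSE)
  prof <- prof[ord, , drop = FALSE]
  rownames(prof) <- NULL
  structure(prof, class = c("deletion_effect_profile", "data.frame"),
            anchor_log2 = r_anchor, window = window, alpha = alpha,
            peak_log2 = lr[ord], eps = eps)
}

#' Extract depleted regions from a deletion-effect profile
#'
#' Maximal runs of consecutive significant windows (in window-center order)
#' become regions; region edges are the outermost significant window
#' centers.
#'
#' @param profile A [sliding_window_deviation()] profile.
#' @param alpha Significance level (default: the profile's).
#' @return Data frame: chrom, start, end (edge window centers), n_windows.
#' @export
call_depleted_regions <- function(profile, alpha = NULL) {
  alpha <- alpha %||% attr(profile, "alpha")
  sig <- !is.na(profile$p) & profile$p < alpha
  runs <- .true_runs(sig)
  data.frame(chrom = rep(profile$chrom[1], nrow(runs)),
             start = profile$center[runs$start],
             end = profile$center[runs$end],
             n_windows = runs$end - runs$start + 1L,
             stringsAsFactors = FALSE)
}

#' TAD-boundary proximity permutation test for depleted regions
#'
#' The observed statistic is the summed distance from every depleted-region
#' edge to the nearest TAD boundary. Under the null, each region is
#' independently relocated uniformly at random on the chromosome preserving
#' its length and the statistic recomputed; the empirical p-value is
#' (1 + #\{null <= observed\}) / (1 + permutations).
#'
#' @param regions Depleted-region data frame (possibly pooled over several
#'   deletion experiments) with `start` and `end`.
#' @param boundaries Numeric vector of TAD-boundary positions.
#' @param chrom_length Chromosome length in bp.
#' @param permutations Number of permutations (default 10000).
#' @param seed Random seed.
#' @return List: observed summed distance, p, null_mean, null_sd, and
#'   null_log10 (the permuted statistic on a log10 scale).
#' @export
tad_proximity_test <- function(regions, boundaries, chrom_length,
                               permutations = 10000L, seed = 1L) {
  .assert(nrow(regions) >= 1, "need at least one region")
  .assert(length(boundaries) >= 1, "need at least one boundary")
  lens <- regions$end - regions$start
  .assert(all(lens <= chrom_length), "region longer than chromosome")
  b <- sort(boundaries)
  observed <- sum(.nearest_dist(c(regions$start, regions$end), b))
  set.seed(seed)
  R <- nrow(regions)
  starts <- matrix(stats::runif(R * permutations), R) * (chrom_length - lens)
  edges <- rbind(starts, starts + lens)
  d <- matrix(.nearest_dist(as.vector(edges), b), nrow = 2 * R)
  null <- colSums(d)
  list(observed = observed,
       p = (1 + sum(null <= observed)) / (1 + permutations),
       null_mean = mean(null), null_sd = stats::sd(null),
       null_log10 = log10(pmax(null, 1)))
}

#' Windowed Fisher test of expression response
#'
#' The chromosome is tiled contiguously into windows of `window` bp. A gene
#' is "up" when its log2 expression ratio (deletion over wild type) exceeds
#' zero. Per window, a one-sided Fisher exact test asks whether up genes are
#' enriched in the window relative to the rest of the chromosome.
#'
#' @param expression Data frame with `pos` (gene position) and `log2_ratio`.
#' @param chrom_length Chromosome length in bp.
#' @param window Window size in bp (default 500 kb).
#' @return Data frame: start, end, n_genes, n_up, p (NA for gene-less
#'   windows).
#' @export
expression_window_test <- function(expression, chrom_length, window = 5e5) {
  .assert(nrow(expression) >= 1, "no genes supplied")
  up <- expression$log2_ratio > 0
  N <- nrow(expression)
  K <- sum(up)
  starts <- seq(0, chrom_length - 1, by = window)
  ends <- pmin(starts + window, chrom_length)
  rows <- lapply(seq_along(starts), function(i) {
    inw <- expression$pos >= starts[i] & expression$pos < ends[i]
    n <- sum(inw)
    k <- sum(up & inw)
    p <- if (n == 0) NA_real_ else
      stats::fisher.test(matrix(c(k, n - k, K - k, (N - n) - (K - k)), 2),
                         alternative = "greater")$p.value
    data.frame(start = starts[i], end = ends[i], n_genes = n, n_up = k,
               p = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
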