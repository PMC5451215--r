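# ChIP enrichment processing: per-base median normalization with input
# subtraction, replicate averaging, threshold peak calling on synthetic
# tracks, majority-rule consensus peaks, and summit-aware peak splitting.

.genome_median <- function(track, assembly, chroms) {
  stats::median(unlist(track$values[chroms], use.names = FALSE))
}

# Divide a track by its genome-wide median (mito excluded); when
# separate_x is set the X and the pooled autosomes get their own medians
# (for strains with an altered X:autosome ratio).
.median_normalize <- function(track, assembly, exclude_mito = TRUE,
                              separate_x = FALSE) {
  chroms <- if (exclude_mito) .non_mito(assembly) else chrom_names(assembly)
  out <- track$values
  if (separate_x) {
    .assert(!is.null(assembly$x_name), "separate X normalization needs x_name")
    xch <- assembly$x_name
    ach <- setdiff(chroms, xch)
    med_x <- .genome_median(track, assembly, xch)
    med_a <- .genome_median(track, assembly, ach)
    .assert(med_x > 0 && med_a > 0,
            "zero median coverage (X: %g, autosomes: %g); check background level",
            med_x, med_a)
    for (ch in names(out)) {
      out[[ch]] <- out[[ch]] / if (identical(ch, xch)) med_x else med_a
    }
  } else {
    med <- .genome_median(track, assembly, chroms)
    .assert(med > 0, "zero genome-wide median coverage; check background level")
    for (ch in names(out)) out[[ch]] <- out[[ch]] / med
  }
  coverage_track(out, label = track$label, kind = "normalized")
}

#' Per-base ChIP enrichment: median normalization and input subtraction
#'
#' ChIP and input coverage are each divided by their own genome-wide median
#' (computed over all bases, excluding the mitochondrial chromosome), and the
#' enrichment score per base is the normalized ChIP minus the normalized
#' input; values may be negative. For strains with an altered X:autosome
#' ratio, `separate_x = TRUE` computes medians separately for the X and the
#' pooled autosomes before recombining.
#'
#' @param chip,input `coverage_track`s on the same assembly.
#' @param assembly The shared `genome_assembly`.
#' @param exclude_mito Exclude the mitochondrial chromosome from the median
#'   (default TRUE).
#' @param separate_x Normalize the X and the autosomes separately.
#' @return An enrichment `coverage_track`.
#' @export
normalize_and_subtract <- function(chip, input, assembly,
                                   exclude_mito = TRUE, separate_x = FALSE) {
  .assert(.same_chroms(list(chip, input)), "chip and input tracks disagree")
  cn <- .median_normalize(chip, assembly, exclude_mito, separate_x)
  iN <- .median_normalize(input, assembly, exclude_mito, separate_x)
  vals <- Map(`-`, cn$values, iN$values[names(cn$values)])
  coverage_track(vals, assembly = assembly, label = chip$label,
                 kind = "enrichment")
}

#' Average replicate tracks position-wise
#'
#' @param tracks Non-empty list of `coverage_track`s on the same assembly.
#' @return A `coverage_track` holding the arithmetic mean at every base.
#' @export
merge_replicates <- function(tracks) {
  .assert(length(tracks) >= 1, "empty track list")
  .assert(.same_chroms(tracks), "tracks are on mismatched assemblies")
  out <- tracks[[1]]$values
  if (length(tracks) > 1) {
    for (t in tracks[-1]) {
      for (ch in names(out)) out[[ch]] <- out[[ch]] + t$values[[ch]]
    }
  }
  for (ch in names(out)) out[[ch]] <- out[[ch]] / length(tracks)
  coverage_track(out, label = tracks[[1]]$label, kind = tracks[[1]]$kind)
}

#' Call peaks on a track by smoothed thresholding
#'
#' Intended for synthetic enrichment tracks (raw-read peak calling with a
#' background model is out of scope): maximal runs where the running-mean
#' smoothed signal exceeds `threshold` for at least `min_width` bases become
#' peaks. The summit is the leftmost maximal base of the unsmoothed signal
#' within the peak; the score is the mean signal over the peak.
#'
#' @param track A `coverage_track`.
#' @param threshold Signal threshold.
#' @param min_width Minimum peak width in bp.
#' @param smooth Width of the centered running mean (odd integer; 1 = none).
#' @param chroms Chromosomes to scan (default: all on the track).
#' @return Peak data frame: chrom, start, end, summit, summit_height, score.
#' @export
call_peaks <- function(track, threshold, min_width = 100L, smooth = 51L,
                       chroms = NULL) {
  chroms <- chroms %||% track_chroms(track)
  res <- list()
  for (ch in chroms) {
    v <- track$values[[ch]]
    sm <- .smooth_vec(v, smooth)
    runs <- .true_runs(sm > threshold)
    if (nrow(runs) == 0) next
    runs <- runs[runs$end - runs$start + 1L >= min_width, , drop = FALSE]
    if (nrow(runs) == 0) next
    summit <- integer(nrow(runs))
    height <- score <- numeric(nrow(runs))
    for (i in seq_len(nrow(runs))) {
      seg <- v[runs$start[i]:runs$end[i]]
      summit[i] <- runs$start[i] - 1L + .which_max_left(seg) - 1L  # 0-based
      height[i] <- max(seg)
      score[i] <- mean(seg)
    }
    res[[ch]] <- data.frame(chrom = ch, start = runs$start - 1L,
                            end = runs$end, summit = summit,
                            summit_height = height, score = score,
                            stringsAsFactors = FALSE)
  }
  if (length(res) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      summit = numeric(), summit_height = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Majority-rule consensus peaks
#'
#' A peak from the combined (pooled-replicate) set is retained if and only if
#' it overlaps (>= 1 bp) a peak in strictly more than half of the individual
#' replicate peak sets. When the replicate-averaged enrichment track is
#' supplied, summits are recomputed on it as the leftmost position of maximum
#' enrichment within each retained peak.
#'
#' @param combined Peak data frame from pooled replicates.
#' @param replicate_sets List of per-replicate peak data frames.
#' @param track Optional replicate-averaged enrichment `coverage_track`.
#' @return The retained peaks.
#' @export
consensus_peaks <- function(combined, replicate_sets, track = NULL) {
  .assert(length(replicate_sets) >= 1, "need at least one replicate peak set")
  if (nrow(combined) == 0) return(combined)
  votes <- rowSums(matrix(vapply(replicate_sets,
                                 function(r) .overlaps_any(combined, r),
                                 logical(nrow(combined))),
                          nrow = nrow(combined)))
  keep <- combined[votes > length(replicate_sets) / 2, , drop = FALSE]
  if (!is.null(track) && nrow(keep) > 0) {
    for (i in seq_len(nrow(keep))) {
      v <- track$values[[keep$chrom[i]]]
      seg <- v[(keep$start[i] + 1L):keep$end[i]]
      keep$summit[i] <- keep$start[i] + .which_max_left(seg) - 1L
      keep$summit_height[i] <- max(seg)
    }
  }
  rownames(keep) <- NULL
  keep
}

# Split one peak; returns a data frame of sub-peaks partitioning [start,end).
.split_one_peak <- function(chrom, start, end, v_chrom, separation,
                            min_height) {
  seg <- v_chrom[(start + 1L):end]
  # Plateau-aware local maxima: a run of equal values higher than both
  # neighboring runs (chromosome of the peak edges counts as lower).
  r <- rle(seg)
  k <- length(r$values)
  rs <- cumsum(r$lengths) - r$lengths + 1L
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1], -Inf)
  is_max <- r$values > left & r$values > right
  cand <- rs[is_max & r$values >= min_height]  # leftmost base of each plateau
  if (length(cand) <= 1) {
    return(data.frame(chrom = chrom, start = start, end = end,
                      summit = start + .which_max_left(seg) - 1L,
                      summit_height = max(seg), score = mean(seg),
                      stringsAsFactors = FALSE))
  }
  # Walk candidates left to right. A qualifying valley (below separation
  # times the smaller summit) cuts the peak; otherwise the pair merges into
  # its taller member, so minor shoulders collapse and true valleys are
  # eventually judged between true summits.
  cuts <- integer(0)
  cur <- cand[1]
  for (i in 2:length(cand)) {
    nxt <- cand[i]
    valley_rel <- cur - 1L + .which_min_left(seg[cur:nxt])
    valley_val <- seg[valley_rel]
    pair_min <- min(seg[cur], seg[nxt])
    if (valley_val < separation * pair_min) {
      cuts <- c(cuts, valley_rel)
      cur <- nxt
    } else if (seg[nxt] > seg[cur]) {
      cur <- nxt
    }
  }
  bounds <- c(1L, cuts, length(seg) + 1L)
  parts <- lapply(seq_len(length(bounds) - 1L), function(j) {
    a <- bounds[j]; b <- bounds[j + 1L] - 1L
    sub <- seg[a:b]
    data.frame(chrom = chrom, start = start + a - 1L, end = start + b,
               summit = start + a - 1L + .which_max_left(sub) - 1L,
               summit_height = max(sub), score = mean(sub),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Split long multi-summit peaks
#'
#' Local maxima with height at least `min_height` are candidate sub-summits.
#' Between each adjacent candidate pair the peak is split at the lowest
#' intervening valley (leftmost on ties) if and only if the valley height is
#' below `separation` times the smaller of the two summit heights. Sub-peaks
#' partition the parent interval and carry their own summits.
#'
#' @param peaks Peak data frame.
#' @param track Enrichment `coverage_track` the peaks were called on.
#' @param separation Separation float in (0, 1]; default 0.85.
#' @param min_height Minimum candidate summit height, or `"auto"` for the
#'   median of the summit heights of all peaks in `peaks`.
#' @param smooth Width of a centered running mean applied before locating
#'   candidate summits and valleys (1 = none); on noisy per-base tracks
#'   this keeps base-level jitter from nominating spurious sub-summits.
#' @return Peak data frame of (possibly split) peaks.
#' @export
split_peaks <- function(peaks, track, separation = 0.85,
                        min_height = "auto", smooth = 1L) {
  .assert(separation > 0 && separation <= 1,
          "separation must be in (0, 1]")
  if (nrow(peaks) == 0) return(peaks)
  if (identical(min_height, "auto")) {
    min_height <- stats::median(peaks$summit_height)
  }
  values <- track$values
  if (smooth > 1) values <- lapply(values, .smooth_vec, width = smooth)
  parts <- lapply(seq_len(nrow(peaks)), function(i) {
    .split_one_peak(peaks$chrom[i], peaks$start[i], peaks$end[i],
                    values[[peaks$chrom[i]]], separation, min_height)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
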