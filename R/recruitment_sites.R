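# Recruitment-site definition and classification: 400-bp windows centered on
# SDC-2 summits, retained only when the window overlaps SDC-3, DPY-30, and
# DPY-27 peaks and no H3K4me3 peak; strength classes by k-means (k = 3) on
# mean enrichment of the four DCC proteins over a 3-kb centered window.

#' Define recruitment sites from per-protein peak sets
#'
#' SDC-2 peaks are first selected: either the mixture-model foci (posterior
#' of the high component above 0.5, see [fit_foci_mixture()]) or the `n_top`
#' strongest summits. Each selected summit nominates a 400-bp window
#' centered on it (clipped at chromosome edges); the window becomes a
#' recruitment site if and only if it overlaps (>= 1 bp) at least one peak
#' in each of the SDC-3, DPY-30 and DPY-27 sets and overlaps no H3K4me3
#' peak. "No significant H3K4me3 enrichment" is operationalized as zero
#' overlap with the H3K4me3 peak set; alternatively a mean-enrichment
#' threshold over the window can be supplied via `h3k4me3_track` and
#' `h3k4me3_max`. The first failing filter (in order SDC-3, DPY-30, DPY-27,
#' H3K4me3) is recorded for every excluded candidate.
#'
#' @param sdc2_peaks,sdc3_peaks,dpy30_peaks,dpy27_peaks,h3k4me3_peaks Peak
#'   data frames (chrom, start, end, summit, summit_height).
#' @param assembly The shared `genome_assembly`.
#' @param mode Candidate selection: `"top_n"` (the `n_top` strongest SDC-2
#'   summits) or `"mixture"` (two-component mixture foci).
#' @param n_top Number of strongest peaks kept in `"top_n"` mode.
#' @param window Site window width in bp (default 400).
#' @param h3k4me3_track,h3k4me3_max Optional mean-enrichment alternative to
#'   the overlap-based H3K4me3 exclusion.
#' @return List with `sites` (chrom, start, end, summit, summit_height,
#'   clipped flag) and `excluded` (candidates with the filter that removed
#'   them).
#' @export
define_recruitment_sites <- function(sdc2_peaks, sdc3_peaks, dpy30_peaks,
                                     dpy27_peaks, h3k4me3_peaks, assembly,
                                     mode = c("top_n", "mixture"),
                                     n_top = 100L, window = 400L,
                                     h3k4me3_track = NULL,
                                     h3k4me3_max = NULL) {
  mode <- match.arg(mode)
  cand <- sdc2_peaks
  if (nrow(cand) > 0) {
    if (mode == "mixture") {
      fm <- fit_foci_mixture(cand$summit_height)
      cand <- cand[fm$foci, , drop = FALSE]
    } else {
      ord <- order(-cand$summit_height)
      cand <- cand[ord[seq_len(min(n_top, nrow(cand)))], , drop = FALSE]
    }
  }
  half <- window / 2
  sites <- data.frame(chrom = cand$chrom,
                      start = pmax(cand$summit - half, 0),
                      end = pmin(cand$summit + half, assembly$lengths[cand$chrom]),
                      summit = cand$summit,
                      summit_height = cand$summit_height,
                      stringsAsFactors = FALSE)
  sites$clipped <- (sites$end - sites$start) < window
  reason <- rep(NA_character_, nrow(sites))
  filters <- list(`SDC-3` = sdc3_peaks, `DPY-30` = dpy30_peaks,
                  `DPY-27` = dpy27_peaks)
  for (nm in names(filters)) {
    fail <- !.overlaps_any(sites, filters[[nm]]) & is.na(reason)
    reason[fail] <- nm
  }
  if (!is.null(h3k4me3_track) && !is.null(h3k4me3_max)) {
    means <- vapply(seq_len(nrow(sites)), function(i)
      track_window_means(h3k4me3_track, sites$chrom[i], sites$start[i],
                         sites$end[i]), 0)
    fail <- means > h3k4me3_max & is.na(reason)
  } else {
    fail <- .overlaps_any(sites, h3k4me3_peaks) & is.na(reason)
  }
  reason[fail] <- "H3K4me3"
  keep <- is.na(reason)
  excluded <- sites[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  sites <- sites[keep, , drop = FALSE]
  # Deterministic output order, invariant to input peak order.
  ord <- order(sites$chrom, sites$start)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- rownames(excluded) <- NULL
  list(sites = sites, excluded = excluded)
}

#' Per-site enrichment features over a centered window
#'
#' @param sites Site data frame with `chrom` and `summit`.
#' @param tracks Named list of enrichment `coverage_track`s.
#' @param window Feature window width in bp (default 3000).
#' @return Matrix of mean enrichments, one column per track.
#' @export
site_features <- function(sites, tracks, window = 3000L) {
  half <- window / 2
  feats <- vapply(tracks, function(tr) {
    out <- numeric(nrow(sites))
    for (ch in unique(sites$chrom)) {
      sel <- sites$chrom == ch
      out[sel] <- track_window_means(tr, ch,
                                     pmax(sites$summit[sel] - half, 0),
                                     sites$summit[sel] + half)
    }
    out
  }, numeric(nrow(sites)))
  feats <- matrix(feats, nrow = nrow(sites),
                  dimnames = list(NULL, names(tracks)))
  feats
}

#' Rank recruitment sites and classify their strength
#'
#' The feature vector of a site is the mean enrichment of each of SDC-2,
#' SDC-3, DPY-30 and DPY-27 over a 3-kb window centered on the summit.
#' Sites are clustered with k-means (k = 3, fixed seed); clusters are
#' labeled strong/intermediate/weak by descending cluster-mean SDC-2
#' feature. The rank orders sites by the descending sum of the four
#' features (rank 1 = strongest).
#'
#' @param sites Site data frame (>= 3 rows).
#' @param tracks Named list of the four DCC enrichment tracks; the first
#'   entry (conventionally SDC-2) drives the class labeling.
#' @param seed Random seed for the k-means initialization.
#' @param window Feature window width in bp.
#' @return `sites` with added feature columns, `rank`, and `class`.
#' @export
classify_sites <- function(sites, tracks, seed = 1L, window = 3000L) {
  .assert(nrow(sites) >= 3, "need at least 3 sites to classify, got %d",
          nrow(sites))
  feats <- site_features(sites, tracks, window = window)
  .assert(nrow(unique(feats)) >= 3,
          "degenerate features: fewer than 3 distinct feature vectors, k-means with k = 3 is undefined")
  set.seed(seed)
  km <- stats::kmeans(feats, centers = 3L, nstart = 10L)
  lead <- km$centers[, 1]
  labels <- c("strong", "intermediate", "weak")[rank(-lead, ties.method = "first")]
  out <- cbind(sites, as.data.frame(feats))
  out$class <- labels[km$cluster]
  out$rank <- rank(-rowSums(feats), ties.method = "first")
  attr(out, "kmeans_seed") <- seed
  attr(out, "feature_window") <- window
  out
}

#' Windowed log2 comparison of two tracks
#'
#' Compares mean signal of two tracks either over tiling windows (width 200,
#' step 100 by default) across a chromosome, or over a 40-bp window centered
#' on each site summit. Window means are floored at `eps` before the log2
#' ratio. Windows clipped at chromosome edges retain their true extent and
#' are flagged.
#'
#' @param track_a,track_b `coverage_track`s on the same assembly (B is
#'   compared against A, ratio = log2(B/A)).
#' @param mode `"tiling"` or `"summit"`.
#' @param chrom Chromosome for tiling mode.
#' @param sites Site data frame for summit mode.
#' @param width,step Tiling window width and step in bp.
#' @param summit_width Summit-centered window width in bp.
#' @param eps Pseudo-level floor for window means before log2.
#' @return List with `windows` (chrom, start, end, mean_a, mean_b,
#'   log2_ratio, clipped) and `median_log2`, the median ratio over windows.
#' @export
windowed_log2_comparison <- function(track_a, track_b,
                                     mode = c("tiling", "summit"),
                                     chrom = NULL, sites = NULL,
                                     width = 200L, step = 100L,
                                     summit_width = 40L, eps = 1e-3) {
  mode <- match.arg(mode)
  .assert(.same_chroms(list(track_a, track_b)), "tracks disagree")
  .assert(eps > 0, "eps must be > 0")
  if (mode == "tiling") {
    .assert(!is.null(chrom), "tiling mode needs a chromosome")
    L <- length(track_a$values[[chrom]])
    starts <- seq(0L, max(L - 1L, 0L), by = step)
    ends <- pmin(starts + width, L)
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    wdf <- data.frame(chrom = chrom, start = starts, end = ends,
                      stringsAsFactors = FALSE)
  } else {
    .assert(!is.null(sites) && nrow(sites) > 0, "summit mode needs sites")
    half <- summit_width / 2
    wdf <- data.frame(chrom = sites$chrom,
                      start = pmax(sites$summit - half, 0),
                      end = pmin(sites$summit + half,
                                 vapply(seq_len(nrow(sites)), function(i)
                                   length(track_a$values[[sites$chrom[i]]]), 0)),
                      stringsAsFactors = FALSE)
  }
  wdf$clipped <- (wdf$end - wdf$start) <
    if (mode == "tiling") width else summit_width
  ma <- mb <- numeric(nrow(wdf))
  for (ch in unique(wdf$chrom)) {
    sel <- wdf$chrom == ch
    ma[sel] <- track_window_means(track_a, ch, wdf$start[sel], wdf$end[sel])
    mb[sel] <- track_window_means(track_b, ch, wdf$start[sel], wdf$end[sel])
  }
  wdf$mean_a <- ma
  wdf$mean_b <- mb
  wdf$log2_ratio <- log2(pmax(mb, eps) / pmax(ma, eps))
  list(windows = wdf, median_log2 = stats::median(wdf$log2_ratio))
}
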