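# Genome-wide affinity scanning, homotypic cluster detection, per-chromosome
# enrichment curves, and occupancy comparisons.

.COMP <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G on the 1..4 base code

# Per-start mismatch energies (unscaled by lambda) for a code vector under a
# log-prob matrix: sum over positions of max(column) - column[base]. Summing
# per-position differences keeps the consensus at exactly zero energy.
# Positions containing N (NA codes) propagate to NA.
.scan_codes <- function(codes, logp) {
  w <- ncol(logp)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  delta <- sweep(-logp, 2, apply(logp, 2, max), `+`)
  acc <- numeric(n)
  for (i in seq_len(w)) {
    col <- delta[, i]
    acc <- acc + col[codes[i:(i + n - 1L)]]
  }
  acc
}

#' Scan a genome for motif hits with standardized affinity scores
#'
#' Every width-w window on both strands is scored under the affinity model;
#' per start position the better strand is reported (ties go to the plus
#' strand) and windows containing N are skipped. With analytic
#' standardization the consensus scores exactly 10 and the anti-consensus
#' exactly 0; with empirical standardization the min-max bounds are taken
#' over the occupancies observed in this scan.
#'
#' @param assembly A `genome_assembly` carrying sequence.
#' @param model An [affinity_model()] (or a `pwm`, wrapped with defaults).
#' @param threshold Minimum standardized score to report, in [0, 10].
#' @param chroms Chromosomes to scan (default: all).
#' @return Data frame of hits sorted by position: chrom, start (0-based),
#'   strand, score (standardized), occupancy; the model (with any empirical
#'   bounds) is attached as attribute `model`.
#' @export
scan_genome <- function(assembly, model, threshold = 0, chroms = NULL) {
  if (inherits(model, "pwm")) model <- affinity_model(model)
  .assert(!is.null(assembly$sequence), "assembly carries no sequence")
  .assert(threshold >= 0 && threshold <= 10, "threshold must be in [0, 10]")
  chroms <- chroms %||% names(assembly$sequence)
  w <- pwm_width(model$pwm)
  logp <- model$logp
  rc_logp <- logp[.COMP, rev(seq_len(w)), drop = FALSE]
  res <- list()
  code_map <- stats::setNames(c(1L, 2L, 3L, 4L), .BASES)
  for (ch in chroms) {
    s <- assembly$sequence[[ch]]
    if (nchar(s) < w) next
    raw <- utf8ToInt(s)
    codes <- rep(NA_integer_, length(raw))
    codes[raw == 65L] <- 1L  # A
    codes[raw == 67L] <- 2L  # C
    codes[raw == 71L] <- 3L  # G
    codes[raw == 84L] <- 4L  # T
    e_f <- .scan_codes(codes, logp) / model$lambda
    e_r <- .scan_codes(codes, rc_logp) / model$lambda
    a_f <- .occupancy(model, e_f)
    a_r <- .occupancy(model, e_r)
    plus <- !is.na(a_f) & (is.na(a_r) | a_f >= a_r)
    a <- ifelse(plus, a_f, a_r)
    ok <- !is.na(a)
    res[[ch]] <- data.frame(chrom = ch, start = which(ok) - 1L,
                            strand = ifelse(plus[ok], "+", "-"),
                            occupancy = a[ok], stringsAsFactors = FALSE)
  }
  hits <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), start = integer(), strand = character(),
               occupancy = numeric(), stringsAsFactors = FALSE)
  a_min <- model$a_min
  a_max <- model$a_max
  if (model$standardize == "empirical" && nrow(hits) > 0) {
    a_min <- min(hits$occupancy)
    a_max <- max(hits$occupancy)
    model$a_min_empirical <- a_min
    model$a_max_empirical <- a_max
  }
  hits$score <- .standardize_score(model, hits$occupancy, a_min, a_max)
  hits <- hits[hits$score >= threshold, , drop = FALSE]
  hits <- hits[order(hits$chrom, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits <- hits[, c("chrom", "start", "strand", "score", "occupancy")]
  attr(hits, "model") <- model
  attr(hits, "width") <- w
  hits
}

#' Detect homotypic motif clusters
#'
#' A cluster is seeded by an anchor hit with standardized score at or above
#' `anchor_threshold` whose neighborhood (start-to-start distance at most
#' `window` bp) contains at least one other hit scoring at or above
#' `member_threshold`. Clusters sharing any member are merged and each is
#' reported once; detection is invariant to input order.
#'
#' @param hits Hit data frame from [scan_genome()].
#' @param anchor_threshold Anchor score threshold (default 7).
#' @param member_threshold Member score threshold (default 5).
#' @param window Start-to-start flanking distance in bp (default 200).
#' @param width Motif width used for cluster spans (default from `hits`).
#' @return List with `clusters` (cluster id, chrom, start, end, n_members,
#'   anchor_start, anchor_score, max_score) and `members` mapping cluster id
#'   to hit rows.
#' @export
detect_clusters <- function(hits, anchor_threshold = 7, member_threshold = 5,
                            window = 200L, width = NULL) {
  width <- width %||% attr(hits, "width") %||% 12L
  hits <- hits[order(hits$chrom, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  n <- nrow(hits)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  in_cluster <- rep(FALSE, n)
  for (ch in unique(hits$chrom)) {
    idx <- which(hits$chrom == ch)
    pos <- hits$start[idx]
    memb <- hits$score[idx] >= member_threshold
    anch <- hits$score[idx] >= anchor_threshold
    for (k in which(anch)) {
      near <- which(memb & abs(pos - pos[k]) <= window)
      near <- setdiff(near, k)
      if (length(near) == 0) next
      in_cluster[idx[c(k, near)]] <- TRUE
      for (m in near) union_(idx[k], idx[m])
    }
  }
  ids <- which(in_cluster)
  if (length(ids) == 0) {
    return(list(clusters = data.frame(cluster = integer(), chrom = character(),
                                      start = numeric(), end = numeric(),
                                      n_members = integer(),
                                      anchor_start = numeric(),
                                      anchor_score = numeric(),
                                      max_score = numeric(),
                                      stringsAsFactors = FALSE),
                members = cbind(hits[0, ], cluster = integer())))
  }
  roots <- vapply(ids, find, 0L)
  cl_id <- as.integer(factor(roots, levels = unique(roots)))
  members <- hits[ids, , drop = FALSE]
  members$cluster <- cl_id
  clusters <- do.call(rbind, lapply(split(members, members$cluster),
    function(m) {
      best <- .which_max_left(m$score)
      data.frame(cluster = m$cluster[1], chrom = m$chrom[1],
                 start = min(m$start), end = max(m$start) + width,
                 n_members = nrow(m), anchor_start = m$start[best],
                 anchor_score = m$score[best], max_score = max(m$score),
                 stringsAsFactors = FALSE)
    }))
  clusters <- clusters[order(clusters$chrom, clusters$start), , drop = FALSE]
  clusters$cluster <- seq_len(nrow(clusters))
  # Re-map member cluster ids to the sorted cluster numbering.
  key <- stats::setNames(clusters$cluster,
                         paste(clusters$chrom, clusters$start))
  spans <- split(seq_len(nrow(members)), cl_id)
  members$cluster <- NA_integer_
  for (grp in spans) {
    ch <- members$chrom[grp[1]]
    st <- min(members$start[grp])
    members$cluster[grp] <- key[[paste(ch, st)]]
  }
  rownames(clusters) <- rownames(members) <- NULL
  list(clusters = clusters, members = members)
}

#' Per-cutoff X-versus-autosome motif enrichment
#'
#' For each score cutoff, counts hits at or above the cutoff on the X and on
#' the autosomes (mitochondrial chromosome excluded) and reports the fold
#' enrichment of the X fraction over the length expectation:
#' (X hits / total hits) / (X length / total length).
#'
#' @param hits Hit data frame from [scan_genome()].
#' @param assembly Assembly declaring which chromosome is X.
#' @param cutoffs Numeric vector of score cutoffs.
#' @return Data frame: cutoff, x_count, autosome_count, x_fraction,
#'   fold_enrichment (NA when no hits survive a cutoff).
#' @export
enrichment_curve <- function(hits, assembly, cutoffs = c(5, 6, 7, 8, 9, 10)) {
  .assert(!is.null(assembly$x_name), "assembly does not declare an X chromosome")
  xch <- assembly$x_name
  auto <- .autosomes(assembly)
  x_len <- assembly$lengths[xch]
  tot_len <- x_len + sum(assembly$lengths[auto])
  hits <- hits[hits$chrom %in% c(xch, auto), , drop = FALSE]
  rows <- lapply(cutoffs, function(co) {
    h <- hits[hits$score >= co, , drop = FALSE]
    nx <- sum(h$chrom == xch)
    na_ <- nrow(h) - nx
    tot <- nx + na_
    frac <- if (tot > 0) nx / tot else NA_real_
    data.frame(cutoff = co, x_count = nx, autosome_count = na_,
               x_fraction = frac,
               fold_enrichment = if (tot > 0) frac / (x_len / tot_len)
                                 else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare mean occupancy across position groups
#'
#' For each element (chromosome, center) the mean of the occupancy track
#' over a 150-bp centered window is computed (clipped and flagged at
#' chromosome ends); groups are summarized by the median of those means and
#' compared pairwise with one-tailed two-sample t-tests ("row group
#' greater").
#'
#' @param track Occupancy `coverage_track` with values in [0, 1].
#' @param groups Named list (>= 2) of data frames with `chrom` and `center`.
#' @param window Window width in bp (default 150).
#' @return List with `values` (per-element window means by group), `medians`,
#'   and `p_greater`, the matrix of one-tailed p-values.
#' @export
occupancy_compare <- function(track, groups, window = 150L) {
  .assert(length(groups) >= 2 && !is.null(names(groups)),
          "need >= 2 named groups")
  half <- window / 2
  vals <- lapply(groups, function(g) {
    .assert(nrow(g) > 0, "empty group")
    vapply(seq_len(nrow(g)), function(i) {
      L <- length(track$values[[g$chrom[i]]])
      track_window_means(track, g$chrom[i],
                         max(g$center[i] - half, 0),
                         min(g$center[i] + half, L))
    }, 0)
  })
  medians <- vapply(vals, stats::median, 0)
  k <- length(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    p[i, j] <- .welch_one_tailed(vals[[i]], vals[[j]], "greater")$p.value
  }
  list(values = vals, medians = medians, p_greater = p)
}
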