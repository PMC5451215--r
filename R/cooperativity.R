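# Ectopic-recruitment qPCR quantification, region-overlap permutation tests,
# and contact-matrix interaction counting.

#' Delta-delta-Ct and percent-endogenous quantification of ChIP-qPCR
#'
#' For each biological replicate and each target (ectopic, endogenous),
#' ddCt = (Ct_experimental - Ct_control)_ChIP -
#' (Ct_experimental - Ct_control)_input, enrichment over background is
#' 2^(-ddCt), and percent endogenous recruitment is 100 times the ratio of
#' ectopic to endogenous enrichment. Because background enrichment varies
#' between replicates, everything is computed per replicate and then
#' summarized as mean and standard deviation.
#'
#' @param table Data frame with columns `replicate`, `locus`
#'   ("experimental"/"control"), `fraction` ("ChIP"/"input"), `target`
#'   ("ectopic"/"endogenous"), `ct`.
#' @return List with `per_replicate` (replicate, target, ddct, enrichment;
#'   plus percent_endogenous per replicate) and `summary` (mean and sd of
#'   ddct per target and of percent endogenous).
#' @export
ddct_percent_endogenous <- function(table) {
  need <- c("replicate", "locus", "fraction", "target", "ct")
  .assert(all(need %in% names(table)), "qPCR table needs columns: %s",
          paste(need, collapse = ", "))
  reps <- unique(table$replicate)
  targets <- unique(table$target)
  cell <- function(r, tg, loc, fr) {
    v <- table$ct[table$replicate == r & table$target == tg &
                    table$locus == loc & table$fraction == fr]
    .assert(length(v) == 1,
            "missing or duplicated Ct for (replicate=%s, target=%s, locus=%s, fraction=%s)",
            r, tg, loc, fr)
    v
  }
  per <- do.call(rbind, lapply(reps, function(r) {
    do.call(rbind, lapply(targets, function(tg) {
      ddct <- (cell(r, tg, "experimental", "ChIP") -
                 cell(r, tg, "control", "ChIP")) -
        (cell(r, tg, "experimental", "input") -
           cell(r, tg, "control", "input"))
      data.frame(replicate = r, target = tg, ddct = ddct,
                 enrichment = 2^(-ddct), stringsAsFactors = FALSE)
    }))
  }))
  rownames(per) <- NULL
  pct <- NULL
  if (all(c("ectopic", "endogenous") %in% targets)) {
    pct <- vapply(reps, function(r) {
      e <- per$enrichment[per$replicate == r & per$target == "ectopic"]
      n <- per$enrichment[per$replicate == r & per$target == "endogenous"]
      100 * e / n
    }, 0)
    names(pct) <- as.character(reps)
  }
  summ <- do.call(rbind, lapply(targets, function(tg) {
    d <- per$ddct[per$target == tg]
    data.frame(quantity = paste0("ddct_", tg), mean = mean(d),
               sd = stats::sd(d), stringsAsFactors = FALSE)
  }))
  if (!is.null(pct)) {
    summ <- rbind(summ, data.frame(quantity = "percent_endogenous",
                                   mean = mean(pct), sd = stats::sd(pct)))
  }
  rownames(summ) <- NULL
  list(per_replicate = per, percent_endogenous = pct, summary = summ)
}

#' One-tailed Welch t-test between two groups of replicate measurements
#'
#' @param group1,group2 Numeric vectors with at least 2 replicates each.
#' @param alternative Direction of the alternative for group1 relative to
#'   group2 (`"greater"` or `"less"`).
#' @return List with `p`, `statistic`, and `degenerate` (TRUE when both
#'   groups have zero variance, in which case equal means give p = 0.5 by
#'   convention).
#' @export
compare_conditions <- function(group1, group2,
                               alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  .assert(length(group1) >= 2 && length(group2) >= 2,
          "need at least 2 replicates per group")
  ht <- .welch_one_tailed(group1, group2, alternative)
  list(p = ht$p.value, statistic = ht$statistic,
       degenerate = isTRUE(ht$degenerate))
}

# Number of annotation intervals overlapping at least one query interval;
# plain-arithmetic fast path used inside permutation loops.
.count_annot_overlaps <- function(annot, q_chrom, q_start, q_end) {
  total <- 0L
  for (ch in unique(annot$chrom)) {
    a <- annot[annot$chrom == ch, , drop = FALSE]
    sel <- q_chrom == ch
    if (!any(sel)) next
    qs <- q_start[sel]; qe <- q_end[sel]
    hit <- vapply(seq_len(nrow(a)), function(i)
      any(qs < a$end[i] & qe > a$start[i]), TRUE)
    total <- total + sum(hit)
  }
  total
}

#' Region-overlap permutation test
#'
#' The observed statistic is the number of annotation elements overlapping
#' at least one query region. Under the null, the query regions are
#' relocated uniformly at random within their own chromosomes preserving
#' their lengths (overlap among relocated queries is not prevented);
#' empirical p = (1 + #\{null as or more extreme\}) / (1 + permutations),
#' with extremeness toward enrichment (null >= observed) or depletion
#' (null <= observed).
#'
#' @param query Query interval data frame (e.g., recruitment sites).
#' @param annotation Annotation interval data frame.
#' @param assembly The shared `genome_assembly`.
#' @param permutations Number of permutations (default 100).
#' @param seed Random seed.
#' @param mode `"enrichment"` or `"depletion"`.
#' @return List: observed, null_mean, null_sd, z, p, flagged (TRUE when the
#'   annotation is empty, in which case observed = 0 and p = 1).
#' @export
overlap_permutation_test <- function(query, annotation, assembly,
                                     permutations = 100L, seed = 1L,
                                     mode = c("enrichment", "depletion")) {
  mode <- match.arg(mode)
  .validate_intervals(query, assembly, "query")
  if (nrow(annotation) == 0) {
    return(list(observed = 0L, null_mean = NA_real_, null_sd = NA_real_,
                z = NA_real_, p = 1, flagged = TRUE))
  }
  .validate_intervals(annotation, assembly, "annotation")
  observed <- .count_annot_overlaps(annotation, query$chrom, query$start,
                                    query$end)
  lens <- query$end - query$start
  chrom_len <- assembly$lengths[query$chrom]
  set.seed(seed)
  null <- vapply(seq_len(permutations), function(k) {
    s <- floor(stats::runif(nrow(query)) * (chrom_len - lens + 1))
    .count_annot_overlaps(annotation, query$chrom, s, s + lens)
  }, 0L)
  extreme <- if (mode == "enrichment") sum(null >= observed)
             else sum(null <= observed)
  sd0 <- stats::sd(null)
  list(observed = observed, null_mean = mean(null), null_sd = sd0,
       z = if (sd0 > 0) (observed - mean(null)) / sd0 else NA_real_,
       p = (1 + extreme) / (1 + permutations), flagged = FALSE)
}

#' Construct a binned contact matrix
#'
#' @param mat Square symmetric numeric matrix of interaction scores.
#' @param bin_size Bin size in bp.
#' @param chrom Chromosome name.
#' @param tol Symmetry tolerance.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(mat, bin_size, chrom = "chrX", tol = 1e-8) {
  .assert(is.matrix(mat) && nrow(mat) == ncol(mat),
          "contact matrix must be square")
  .assert(max(abs(mat - t(mat))) <= tol * max(1, max(abs(mat))),
          "contact matrix is not symmetric")
  structure(list(mat = mat, bin_size = bin_size, chrom = chrom),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins of %g bp\n", x$chrom,
              nrow(x$mat), x$bin_size))
  invisible(x)
}

#' Write / read a contact matrix as tab-delimited text
#'
#' A square matrix with a bin-start coordinate header row and column.
#'
#' @param cm A `contact_matrix`.
#' @param path File path.
#' @export
write_contact_matrix <- function(cm, path) {
  coords <- (seq_len(nrow(cm$mat)) - 1) * cm$bin_size
  m <- cm$mat
  dimnames(m) <- list(coords, coords)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @param chrom Chromosome name to record on the matrix read back.
#' @export
read_contact_matrix <- function(path, chrom = "chrX") {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  coords <- as.numeric(rownames(m))
  bin <- if (length(coords) > 1) coords[2] - coords[1] else 1
  dimnames(m) <- NULL
  contact_matrix(m, bin_size = bin, chrom = chrom)
}

#' Sites interacting through high-scoring contacts
#'
#' The interaction threshold is the given quantile of the upper-triangle
#' off-diagonal entries (zeros included). Two distinct sites interact when
#' any bin pair between them scores strictly above the threshold. Returns
#' the sites having at least one partner and the pair list.
#'
#' @param cm A `contact_matrix`.
#' @param sites Interval data frame on the matrix chromosome.
#' @param quantile Quantile defining the threshold (default 0.99).
#' @param nonzero_only Compute the quantile over nonzero entries only.
#' @return List: count (sites with >= 1 partner), interacting (logical per
#'   site), pairs (data frame of site index pairs), threshold.
#' @export
hic_interacting_sites <- function(cm, sites, quantile = 0.99,
                                  nonzero_only = FALSE) {
  n_bins <- nrow(cm$mat)
  extent <- n_bins * cm$bin_size
  .assert(all(sites$end <= extent) && all(sites$start >= 0),
          "site outside contact-matrix extent")
  vals <- cm$mat[upper.tri(cm$mat)]
  if (nonzero_only) vals <- vals[vals != 0]
  thr <- stats::quantile(vals, quantile, names = FALSE)
  bins <- lapply(seq_len(nrow(sites)), function(i) {
    (floor(sites$start[i] / cm$bin_size) + 1L):
      (floor((sites$end[i] - 1) / cm$bin_size) + 1L)
  })
  n <- nrow(sites)
  interacting <- rep(FALSE, n)
  pairs <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (any(cm$mat[bins[[i]], bins[[j]], drop = FALSE] > thr)) {
        interacting[c(i, j)] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  pairs <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    data.frame(site_a = m[, 1], site_b = m[, 2])
  } else data.frame(site_a = integer(), site_b = integer())
  list(count = sum(interacting), interacting = interacting, pairs = pairs,
       threshold = thr)
}

#' Read / write a ChIP-qPCR Ct table as CSV
#'
#' Columns: replicate, locus, fraction, target, ct.
#'
#' @param path File path.
#' @export
read_qpcr <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_qpcr
#' @param table qPCR data frame.
#' @export
write_qpcr <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
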