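# Position weight matrix construction and the biophysical affinity model.
#
# The affinity of a width-w site s is the occupancy of a mismatch-energy
# model: E(s) = (1/lambda) * sum_i ln(p_i(consensus_i) / p_i(s_i)), so that
# E(consensus) = 0, and a(s) = R0 * exp(-E) / (1 + R0 * exp(-E)). Scores are
# standardized to the 0-10 scale by min-max over the analytic extremes
# (consensus scores exactly 10, anti-consensus exactly 0).

.BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from aligned motif occurrences
#'
#' Column probabilities are (count + pseudocount) / (n + 4 * pseudocount).
#' The consensus is the per-column argmax base (ties broken alphabetically).
#'
#' @param occurrences Character vector (>= 2) of equal-length A/C/G/T
#'   sequences.
#' @param pseudocount Pseudocount added per base (default 0.01).
#' @param background Background base distribution over A/C/G/T.
#' @return An object of class `pwm`: 4 x width probability matrix with
#'   attributes `pseudocount`, `background`, `consensus`.
#' @export
build_pwm <- function(occurrences, pseudocount = 0.01,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  .assert(length(occurrences) >= 2, "need at least 2 aligned occurrences")
  occurrences <- toupper(occurrences)
  w <- unique(nchar(occurrences))
  .assert(length(w) == 1, "occurrences have unequal lengths: %s",
          paste(sort(w), collapse = ", "))
  chars <- do.call(rbind, strsplit(occurrences, "", fixed = TRUE))
  bad <- which(!chars %in% .BASES)
  if (length(bad)) {
    pos <- ((bad[1] - 1) %/% length(occurrences)) + 1
    .stopf("non-ACGT character '%s' at motif position %d",
           chars[bad[1]], pos)
  }
  counts <- vapply(seq_len(w), function(j)
    table(factor(chars[, j], levels = .BASES)), numeric(4))
  probs <- (counts + pseudocount) / (length(occurrences) + 4 * pseudocount)
  rownames(probs) <- .BASES
  structure(probs, class = "pwm", pseudocount = pseudocount,
            background = background,
            consensus = paste(.BASES[apply(probs, 2, which.max)],
                              collapse = ""))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: width %d, consensus %s\n", ncol(x),
              attr(x, "consensus")))
  print(round(unclass(x), 3))
  invisible(x)
}

pwm_width <- function(pwm) ncol(pwm)

pwm_consensus <- function(pwm) attr(pwm, "consensus")

#' Biophysical affinity model over a PWM
#'
#' @param pwm A [build_pwm()] object.
#' @param lambda Energy-scaling constant (default 0.7).
#' @param R0 Concentration-like prefactor; default `exp(0.584 * width - 5.66)`.
#' @param standardize `"analytic"` (min-max over the consensus and
#'   anti-consensus extremes; default) or `"empirical"` (min-max over the
#'   scores observed in a genome scan).
#' @return An object of class `affinity_model` with the PWM, `lambda`, `R0`,
#'   per-position log-probabilities, and the analytic occupancy bounds
#'   `a_min`, `a_max`.
#' @export
affinity_model <- function(pwm, lambda = 0.7, R0 = NULL,
                           standardize = c("analytic", "empirical")) {
  standardize <- match.arg(standardize)
  .assert(lambda > 0, "lambda must be positive")
  w <- pwm_width(pwm)
  R0 <- R0 %||% exp(0.584 * w - 5.66)
  logp <- log(unclass(pwm))
  cons_lp <- apply(logp, 2, max)
  anti_lp <- apply(logp, 2, min)
  e_max <- sum(cons_lp - anti_lp) / lambda
  a_of_e <- function(e) {
    x <- R0 * exp(-e)
    x / (1 + x)
  }
  structure(list(pwm = pwm, lambda = lambda, R0 = R0, logp = logp,
                 cons_logp_sum = sum(cons_lp),
                 a_max = a_of_e(0), a_min = a_of_e(e_max),
                 e_max = e_max, standardize = standardize),
            class = "affinity_model")
}

# Occupancy for a vector of energies.
.occupancy <- function(model, e) {
  x <- model$R0 * exp(-e)
  x / (1 + x)
}

.standardize_score <- function(model, a, a_min = model$a_min,
                               a_max = model$a_max) {
  10 * (a - a_min) / (a_max - a_min)
}

#' Score individual sequences under an affinity model
#'
#' @param model An [affinity_model()].
#' @param seqs Character vector of width-matched A/C/G/T sequences.
#' @return Numeric vector of standardized scores in [0, 10] (analytic
#'   standardization).
#' @export
score_sequences <- function(model, seqs) {
  w <- pwm_width(model$pwm)
  .assert(all(nchar(seqs) == w), "sequences must have the PWM width %d", w)
  vapply(toupper(seqs), function(s) {
    idx <- match(strsplit(s, "")[[1]], .BASES)
    .assert(!anyNA(idx), "non-ACGT character in '%s'", s)
    lp <- sum(model$logp[cbind(idx, seq_len(w))])
    e <- (model$cons_logp_sum - lp) / model$lambda
    .standardize_score(model, .occupancy(model, e))
  }, 0, USE.NAMES = FALSE)
}

# Design a width-w sequence whose standardized score is as close as possible
# to `target`, by dynamic programming over per-position base substitutions on
# an energy grid. Used by the synthetic-genome generator to plant motif
# instances with planned scores.
design_scored_sequence <- function(model, target, grid = 0.005) {
  .assert(target >= 0 && target <= 10, "target score must be in [0, 10]")
  a_t <- model$a_min + target / 10 * (model$a_max - model$a_min)
  a_t <- .clip(a_t, 1e-12, 1 - 1e-12)
  e_target <- log(model$R0) - log(a_t / (1 - a_t))
  e_target <- max(e_target, 0)
  w <- pwm_width(model$pwm)
  cons_lp <- apply(model$logp, 2, max)
  # Per position, energy increments of the four bases (consensus = 0).
  delta <- sweep(-model$logp, 2, cons_lp, `+`) / model$lambda
  e_cap <- min(model$e_max, e_target + 10) + grid
  nbin <- as.integer(ceiling(e_cap / grid)) + 1L
  reach <- rep(NA_real_, nbin)   # achieved energy per bin
  choice <- matrix(NA_integer_, nbin, w)
  reach[1] <- 0
  choice[1, ] <- apply(model$logp, 2, which.max)
  for (j in seq_len(w)) {
    ord <- order(reach)  # visit filled bins; NA sorts last
    filled <- ord[!is.na(reach[ord])]
    new_reach <- reach
    new_choice <- choice
    for (b in seq_len(4)) {
      d <- delta[b, j]
      if (d == 0) next
      cand_e <- reach[filled] + d
      ok <- cand_e <= e_cap
      if (!any(ok)) next
      bins <- pmin(as.integer(round(cand_e[ok] / grid)) + 1L, nbin)
      for (k in seq_along(bins)) {
        bi <- bins[k]
        if (is.na(new_reach[bi]) ||
            abs(new_reach[bi] - e_target) > abs(cand_e[ok][k] - e_target)) {
          src <- filled[which(ok)[k]]
          new_reach[bi] <- cand_e[ok][k]
          new_choice[bi, ] <- choice[src, ]
          new_choice[bi, j] <- b
        }
      }
    }
    reach <- new_reach
    choice <- new_choice
  }
  best <- which.min(abs(reach - e_target))
  seq <- paste(.BASES[choice[best, ]], collapse = "")
  achieved <- .standardize_score(model, .occupancy(model, reach[best]))
  list(sequence = seq, score = achieved, energy = reach[best])
}

#' Aligned occurrences defining the default 12-bp recruitment motif
#'
#' Twenty artificial aligned occurrences whose column counts give a
#' conserved 8-bp GCGCAGGG core (17 of 20) with graded flanking
#' specificities (counts 7/6/4/3), consensus ATCGCGCAGGGA. They stand in for
#' motif-discovery output, which is out of scope; a user-supplied alignment
#' can be swapped in via [build_pwm()].
#'
#' @return Character vector of 20 aligned 12-mers.
#' @export
example_occurrences <- function() {
  consensus <- strsplit("ATCGCGCAGGGA", "")[[1]]
  flank_pos <- c(1L, 2L, 3L, 12L)
  core_counts <- c(17L, 1L, 1L, 1L)
  flank_counts <- c(7L, 6L, 4L, 3L)
  cols <- lapply(seq_len(12), function(j) {
    counts <- if (j %in% flank_pos) flank_counts else core_counts
    # consensus base receives the top count; remaining bases in alphabetical
    # order receive the rest.
    others <- setdiff(.BASES, consensus[j])
    rep(c(consensus[j], others), counts)
  })
  vapply(seq_len(20), function(i)
    paste(vapply(cols, `[[`, "", i), collapse = ""), "")
}

#' Default recruitment-motif PWM
#'
#' @param pseudocount Pseudocount for [build_pwm()].
#' @return A `pwm` built from [example_occurrences()].
#' @export
default_pwm <- function(pseudocount = 0.01) {
  build_pwm(example_occurrences(), pseudocount = pseudocount)
}

#' Export / import a PWM as a tab-delimited matrix
#'
#' Four columns (A, C, G, T) with a header, one row per motif position.
#'
#' @param pwm A `pwm`.
#' @param path File path.
#' @export
write_pwm <- function(pwm, path) {
  utils::write.table(t(unclass(pwm)), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = .BASES)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  .assert(ncol(m) == 4, "PWM table must have 4 columns (A, C, G, T)")
  probs <- t(m)
  rownames(probs) <- .BASES
  probs <- sweep(probs, 2, colSums(probs), `/`)
  structure(probs, class = "pwm", pseudocount = NA_real_,
            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
            consensus = paste(.BASES[apply(probs, 2, which.max)],
                              collapse = ""))
}
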