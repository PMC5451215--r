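# Synthetic-data generation: genomes with planted motif clusters, ChIP
# experiments with recruitment peaks and domain-confined spreading, deletion
# strains, and ancillary qPCR / contact / occupancy / expression data. The
# generator's defaults define the study conditions every downstream test
# runs under; they are documented in the methods vignette and are not tuned
# per test.

.SIM_DEFAULTS <- function() list(
  chrom_lengths = c(chrI = 5e5, chrII = 5e5, chrIII = 5e5, chrIV = 5e5,
                    chrV = 5e5, chrX = 2e6, chrM = 1.5e4),
  x_name = "chrX",
  mito_name = "chrM",
  n_strong = 4L, n_intermediate = 4L, n_weak = 8L,
  tier_amplitude = c(strong = 10, intermediate = 5, weak = 2),
  protein_multiplier = c(SDC2 = 1, SDC3 = 0.8, DPY30 = 0.7, DPY27 = 1.2),
  domain_boundaries = c(0, 5e5, 1e6, 1.5e6, 2e6),
  peak_sd = 75,
  spread_decay = 5e4,
  spread_fraction = 0.5,
  background = 1,
  noise_sd = 0.2,
  replicates = 3L,
  h3_level = 2,
  h3_dip = 0.7,
  h3_dip_sd = 150,
  h3k4me3_amplitude = 8,
  n_h3k4me3 = 6L,
  n_decoy = 2L,
  n_autosomal_sdc = 3L,
  decoy_amplitude = 5,
  motif_plan = list(
    strong = list(scores = c(10, 8, 6), offsets = c(-80, 10, 90)),
    intermediate = list(scores = c(8, 6), offsets = c(-60, 60)),
    weak = list(scores = c(7.5), offsets = c(0))),
  deletion = list(site = 1L, d_max = 0.2, shape = "linear"),
  qpcr = list(base_ct = 30, enrich_endogenous = 16, enrich_ectopic = 4,
              sd = 0.1, replicates = 3L),
  contact = list(bin_size = 1e4, alpha = 1, bonus = 5, noise_sd = 0.02),
  occupancy = list(baseline = 0.45, site_gain = 0.3, sd = 100,
                   noise_sd = 0.02),
  expression = list(genes_per_window = 40L, window = 5e5, base_mean = 100,
                    dispersion = 0.1, lfc = 0.4),
  seed = 1L)

#' Simulation configuration
#'
#' Builds a simulation configuration from defaults; any default can be
#' overridden by name and unknown keys are rejected. The defaults describe a
#' desk-scale genome (five 0.5-Mb autosomes, one 2-Mb X, one 15-kb
#' mitochondrial chromosome), 16 recruitment sites on the X in three tiers
#' with strictly ordered amplitudes (strong 10, intermediate 5, weak 2),
#' Gaussian peak kernels (sd 75 bp) with exponential spreading (decay 50 kb)
#' truncated at domain boundaries, multiplicative log-normal replicate noise
#' (sd 0.2), and a deletion strain with 20% maximal depletion.
#'
#' @param ... Named overrides of the default fields.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- .SIM_DEFAULTS()
  over <- list(...)
  if (length(over)) {
    .assert(!is.null(names(over)) && all(nzchar(names(over))),
            "overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    .assert(length(unknown) == 0, "unknown configuration key(s): %s",
            paste(unknown, collapse = ", "))
    for (nm in names(over)) {
      if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
        sub_unknown <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
        .assert(length(sub_unknown) == 0,
                "unknown configuration key(s) in %s: %s", nm,
                paste(sub_unknown, collapse = ", "))
        cfg[[nm]][names(over[[nm]])] <- over[[nm]]
      } else {
        cfg[[nm]] <- over[[nm]]
      }
    }
  }
  .assert(all(cfg$chrom_lengths > 0), "chromosome lengths must be positive")
  .assert(cfg$peak_sd > 0 && cfg$spread_decay > 0,
          "widths and decay lengths must be positive")
  d <- cfg$deletion$d_max
  .assert(d >= 0 && d <= 1, "d_max must be in [0, 1]")
  amps <- cfg$tier_amplitude
  .assert(amps["strong"] > amps["intermediate"] &&
            amps["intermediate"] > amps["weak"],
          "tier amplitudes must be strictly ordered strong > intermediate > weak")
  .assert(cfg$noise_sd >= 0 && cfg$background > 0,
          "noise sd must be >= 0 and background > 0")
  structure(cfg, class = "sim_config")
}

sim_assembly <- function(config, sequence = NULL) {
  genome_assembly(config$chrom_lengths, sequence = sequence,
                  x_name = config$x_name, mito_name = config$mito_name)
}

# Deterministic placement of planted sites and non-site loci on the genome.
sim_site_plan <- function(config) {
  n <- config$n_strong + config$n_intermediate + config$n_weak
  Lx <- config$chrom_lengths[[config$x_name]]
  pos <- round(seq(0.06 * Lx, 0.94 * Lx, length.out = n))
  pattern <- rep(c("strong", "weak", "intermediate", "weak"), length.out = n)
  # Rebalance if requested tier counts differ from the repeating pattern:
  # positions keep the interleaved order, tiers are reassigned by rank.
  tiers <- c(rep("strong", config$n_strong),
             rep("intermediate", config$n_intermediate),
             rep("weak", config$n_weak))
  key <- c(strong = 1L, intermediate = 2L, weak = 3L)
  ord <- order(key[pattern])
  tier <- character(n)
  tier[ord] <- tiers[order(key[tiers])]
  sites <- data.frame(chrom = config$x_name, position = pos, tier = tier,
                      amplitude = config$tier_amplitude[tier],
                      stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  sites
}

# Non-site loci: H3K4me3 peaks on X (the first n_decoy of which also carry
# full DCC-like binding, exercising the H3K4me3 exclusion), and autosomal
# loci bound by the recruiter proteins but not by condensin DC.
sim_extra_loci <- function(config, sites) {
  Lx <- config$chrom_lengths[[config$x_name]]
  gap_mid <- round((sites$position[-1] + sites$position[-nrow(sites)]) / 2)
  h3k4 <- gap_mid[round(seq(1, length(gap_mid),
                            length.out = config$n_h3k4me3))]
  autos <- setdiff(names(config$chrom_lengths),
                   c(config$x_name, config$mito_name))
  asdc <- data.frame(
    chrom = autos[seq_len(config$n_autosomal_sdc)],
    position = round(config$chrom_lengths[
      autos[seq_len(config$n_autosomal_sdc)]] / 2))
  list(h3k4me3 = data.frame(chrom = config$x_name, position = h3k4),
       decoy = data.frame(chrom = config$x_name,
                          position = h3k4[seq_len(config$n_decoy)]),
       autosomal_sdc = asdc)
}

#' Generate a synthetic genome with planted motif instances
#'
#' Random background sequence is drawn for every chromosome and motif
#' instances are embedded at offsets around each planted recruitment site
#' according to the site's tier plan (by default: strong sites carry a
#' cluster of three motifs with target scores 10/8/6 within 200 bp,
#' intermediate sites a cluster of two at 8/6, weak sites a single motif at
#' 7.5). Instances are designed by [design_scored_sequence()] so their
#' achieved standardized scores track the plan. The same seed reproduces
#' the sequence and ground truth exactly.
#'
#' @param config A [sim_config()].
#' @param pwm A `pwm` (default [default_pwm()]).
#' @return List: `assembly` (with sequence), `sites` (planted site table),
#'   `hits` (planted instances with target and achieved scores).
#' @export
generate_genome <- function(config, pwm = default_pwm()) {
  set.seed(config$seed)
  .assert(pwm_width(pwm) <= min(config$chrom_lengths),
          "motif wider than the shortest chromosome")
  model <- affinity_model(pwm)
  w <- pwm_width(pwm)
  seqs <- vapply(names(config$chrom_lengths), function(ch)
    paste(sample(.BASES, config$chrom_lengths[[ch]], replace = TRUE),
          collapse = ""), "")
  sites <- sim_site_plan(config)
  hits <- list()
  for (i in seq_len(nrow(sites))) {
    plan <- config$motif_plan[[sites$tier[i]]]
    for (k in seq_along(plan$scores)) {
      start <- sites$position[i] + plan$offsets[k]  # 0-based
      des <- design_scored_sequence(model, plan$scores[k])
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = sites$chrom[i], start = start, strand = "+",
        site = i, tier = sites$tier[i],
        target_score = plan$scores[k], planted_score = des$score,
        sequence = des$sequence, stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hits)
  ord <- order(hits$chrom, hits$start)
  hits <- hits[ord, , drop = FALSE]
  overlap <- unlist(lapply(split(hits$start, hits$chrom), function(s)
    diff(sort(s)) < w))
  .assert(!any(overlap), "planted motif instances overlap; adjust offsets")
  for (i in seq_len(nrow(hits))) {
    ch <- hits$chrom[i]
    substr(seqs[[ch]], hits$start[i] + 1L, hits$start[i] + w) <-
      hits$sequence[i]
  }
  rownames(hits) <- NULL
  list(assembly = sim_assembly(config, sequence = seqs), sites = sites,
       hits = hits)
}

# Add a Gaussian kernel of amplitude amp (sd in bp) to a per-base vector.
.add_kernel <- function(v, pos, amp, sd) {
  lo <- max(floor(pos - 6 * sd), 0)
  hi <- min(ceiling(pos + 6 * sd), length(v) - 1)
  if (hi < lo) return(v)
  x <- lo:hi
  v[x + 1] <- v[x + 1] + amp * exp(-(x - pos)^2 / (2 * sd^2))
  v
}

# Add exponential spreading truncated at the enclosing domain boundaries.
.add_spread <- function(v, pos, amp, decay, dom_lo, dom_hi) {
  lo <- max(floor(dom_lo), 0)
  hi <- min(ceiling(dom_hi), length(v)) - 1
  if (hi < lo) return(v)
  x <- lo:hi
  v[x + 1] <- v[x + 1] + amp * exp(-abs(x - pos) / decay)
  v
}

.enclosing_domain <- function(config, pos) {
  b <- sort(config$domain_boundaries)
  i <- findInterval(pos, b, rightmost.closed = TRUE)
  .assert(i >= 1 && i < length(b), "position %g outside the domain partition",
          pos)
  c(b[i], b[i + 1])
}

# Noiseless signal of one protein across the genome (list of vectors).
.protein_signal <- function(config, sites, assembly, protein,
                            drop_site = NULL) {
  extras <- sim_extra_loci(config, sites)
  vals <- lapply(assembly$lengths, function(L) rep(config$background, L))
  dcc <- c("SDC2", "SDC3", "DPY30", "DPY27")
  recruiters <- c("SDC2", "SDC3", "DPY30")
  xch <- config$x_name
  if (protein %in% dcc) {
    mult <- config$protein_multiplier[[protein]]
    for (i in seq_len(nrow(sites))) {
      if (!is.null(drop_site) && i == drop_site) next
      amp <- sites$amplitude[i] * mult
      vals[[xch]] <- .add_kernel(vals[[xch]], sites$position[i], amp,
                                 config$peak_sd)
      dom <- .enclosing_domain(config, sites$position[i])
      vals[[xch]] <- .add_spread(vals[[xch]], sites$position[i],
                                 config$spread_fraction * amp,
                                 config$spread_decay, dom[1], dom[2])
    }
    for (i in seq_len(nrow(extras$decoy))) {
      vals[[xch]] <- .add_kernel(vals[[xch]], extras$decoy$position[i],
                                 config$decoy_amplitude * mult,
                                 config$peak_sd)
    }
    if (protein %in% recruiters) {
      for (i in seq_len(nrow(extras$autosomal_sdc))) {
        ch <- extras$autosomal_sdc$chrom[i]
        vals[[ch]] <- .add_kernel(vals[[ch]],
                                  extras$autosomal_sdc$position[i],
                                  config$decoy_amplitude * mult,
                                  config$peak_sd)
      }
    }
  } else if (protein == "H3") {
    vals <- lapply(vals, function(v) v * config$h3_level)
    for (i in seq_len(nrow(sites))) {
      vals[[xch]] <- .add_kernel(vals[[xch]], sites$position[i],
                                 -config$h3_dip * config$h3_level *
                                   config$background, config$h3_dip_sd)
    }
    vals <- lapply(vals, function(v) pmax(v, 0.05 * config$background))
  } else if (protein == "H3K4me3") {
    for (i in seq_len(nrow(extras$h3k4me3))) {
      vals[[xch]] <- .add_kernel(vals[[xch]], extras$h3k4me3$position[i],
                                 config$h3k4me3_amplitude, config$h3_dip_sd)
    }
  } else {
    .stopf("unknown protein '%s'", protein)
  }
  vals
}

# Mean-one multiplicative log-normal noise; deterministic per stream id.
.lognoise <- function(config, stream, n) {
  if (config$noise_sd == 0) return(rep(1, n))
  set.seed((config$seed * 131L + stream) %% .Machine$integer.max)
  exp(stats::rnorm(n, 0, config$noise_sd) - config$noise_sd^2 / 2)
}

.apply_noise <- function(vals, config, stream) {
  out <- vals
  for (k in seq_along(out)) {
    out[[k]] <- out[[k]] * .lognoise(config, stream * 1000L + k,
                                     length(out[[k]]))
  }
  out
}

.input_track <- function(config, assembly, rep_id) {
  vals <- lapply(assembly$lengths, function(L) rep(config$background, L))
  vals <- .apply_noise(vals, config, stream = 900L + rep_id)
  coverage_track(vals, label = sprintf("input_rep%d", rep_id), kind = "raw")
}

.PROTEIN_STREAM <- c(SDC2 = 1L, SDC3 = 2L, DPY30 = 3L, DPY27 = 4L,
                     H3 = 5L, H3K4me3 = 6L)

#' Simulate a ChIP experiment
#'
#' ChIP coverage is background plus Gaussian peak kernels at the planted
#' sites (amplitude = tier amplitude times the protein multiplier) plus an
#' exponential spreading term from each site truncated at the enclosing
#' domain boundaries (DCC proteins only), all multiplied by mean-one
#' log-normal noise drawn independently per replicate; matching input is
#' background noise only and is shared across proteins within a replicate.
#' The H3 track is high genome-wide with dips at sites; H3K4me3 peaks sit at
#' designated non-site loci. Noise streams are keyed by (protein,
#' replicate), so simulating a subset of proteins reproduces exactly the
#' tracks of a full run.
#'
#' @param config A [sim_config()].
#' @param sites Planted site table from [generate_genome()] (or
#'   [sim_site_plan()]).
#' @param assembly The simulation assembly.
#' @param proteins Proteins to simulate.
#' @param replicates Number of replicates (default from config).
#' @return Nested list: `tracks[[protein]][[replicate]]` with elements
#'   `chip` and `input` (`coverage_track`s), plus `extras`, the non-site
#'   locus table.
#' @export
simulate_chip_experiment <- function(config, sites, assembly,
                                     proteins = names(.PROTEIN_STREAM),
                                     replicates = config$replicates) {
  .assert(all(sites$position < assembly$lengths[sites$chrom]),
          "sites lie outside the assembly")
  inputs <- lapply(seq_len(replicates), function(r)
    .input_track(config, assembly, r))
  tracks <- list()
  for (pr in proteins) {
    signal <- .protein_signal(config, sites, assembly, pr)
    tracks[[pr]] <- lapply(seq_len(replicates), function(r) {
      vals <- .apply_noise(signal, config,
                           stream = .PROTEIN_STREAM[[pr]] * 10L + r)
      list(chip = coverage_track(vals,
                                 label = sprintf("%s_rep%d", pr, r),
                                 kind = "raw"),
           input = inputs[[r]])
    })
  }
  list(tracks = tracks, extras = sim_extra_loci(config, sites))
}

# Depletion fraction profile within a domain: linear tent peaking at the
# deleted site (d_max at the site, 0 at the domain edges) or uniform d_max.
.depletion_profile <- function(config, site_pos, dom, n_x) {
  d <- rep(0, n_x)
  lo <- max(floor(dom[1]), 0)
  hi <- min(ceiling(dom[2]), n_x)
  if (hi <= lo) return(d)
  x <- lo:(hi - 1)
  if (identical(config$deletion$shape, "uniform")) {
    d[x + 1] <- config$deletion$d_max
  } else {
    left <- pmax((x - dom[1]) / max(site_pos - dom[1], 1), 0)
    right <- pmax((dom[2] - x) / max(dom[2] - site_pos, 1), 0)
    d[x + 1] <- config$deletion$d_max * pmin(left, right, 1)
  }
  d
}

#' Simulate a recruitment-site deletion strain
#'
#' DCC-protein signal within the deleted site's domain is multiplied by
#' (1 - d(x)), where d(x) falls linearly from `d_max` at the site to 0 at
#' the domain edges (or is uniformly `d_max` with shape `"uniform"`), and
#' the deleted site's own peak and spreading contribution are removed.
#' Signal outside the domain is untouched. When wild-type tracks are
#' supplied they are transformed directly (noise is then shared with wild
#' type); otherwise fresh tracks with independent noise are generated.
#'
#' @param config A [sim_config()]; `config$deletion` names the site.
#' @param sites Planted site table.
#' @param assembly The simulation assembly.
#' @param tracks Optional wild-type `tracks` structure from
#'   [simulate_chip_experiment()] to transform in place.
#' @param proteins DCC proteins to simulate.
#' @param replicates Number of replicates.
#' @return Same structure as [simulate_chip_experiment()].
#' @export
simulate_deletion_strain <- function(config, sites, assembly, tracks = NULL,
                                     proteins = c("SDC2", "SDC3", "DPY30",
                                                  "DPY27"),
                                     replicates = config$replicates) {
  del <- config$deletion$site
  .assert(del >= 1 && del <= nrow(sites), "deletion names no existing site")
  .assert(identical(sites$chrom[del], config$x_name),
          "deleted site is not on the X chromosome")
  xch <- config$x_name
  pos <- sites$position[del]
  dom <- .enclosing_domain(config, pos)
  n_x <- assembly$lengths[[xch]]
  dprof <- .depletion_profile(config, pos, dom, n_x)
  out <- list()
  if (!is.null(tracks)) {
    for (pr in intersect(proteins, names(tracks$tracks))) {
      mult <- config$protein_multiplier[[pr]]
      contrib <- numeric(n_x)
      contrib <- .add_kernel(contrib, pos, sites$amplitude[del] * mult,
                             config$peak_sd)
      contrib <- .add_spread(contrib, pos,
                             config$spread_fraction *
                               sites$amplitude[del] * mult,
                             config$spread_decay, dom[1], dom[2])
      out[[pr]] <- lapply(tracks$tracks[[pr]], function(rep_tr) {
        vals <- rep_tr$chip$values
        vals[[xch]] <- pmax(vals[[xch]] - contrib, 0) * (1 - dprof)
        list(chip = coverage_track(vals,
                                   label = paste0("del_", rep_tr$chip$label),
                                   kind = rep_tr$chip$kind),
             input = rep_tr$input)
      })
    }
    return(list(tracks = out, extras = sim_extra_loci(config, sites),
                domain = dom, deleted_site = del))
  }
  inputs <- lapply(seq_len(replicates), function(r) {
    vals <- lapply(assembly$lengths, function(L) rep(config$background, L))
    vals <- .apply_noise(vals, config, stream = 950L + r)
    coverage_track(vals, label = sprintf("del_input_rep%d", r), kind = "raw")
  })
  for (pr in proteins) {
    signal <- .protein_signal(config, sites, assembly, pr, drop_site = del)
    signal[[xch]] <- signal[[xch]] * (1 - dprof)
    out[[pr]] <- lapply(seq_len(replicates), function(r) {
      vals <- .apply_noise(signal, config,
                           stream = 500L + .PROTEIN_STREAM[[pr]] * 10L + r)
      list(chip = coverage_track(vals,
                                 label = sprintf("del_%s_rep%d", pr, r),
                                 kind = "raw"),
           input = inputs[[r]])
    })
  }
  list(tracks = out, extras = sim_extra_loci(config, sites), domain = dom,
       deleted_site = del)
}

#' Simulate ancillary data: qPCR, contact matrix, occupancy, expression
#'
#' qPCR Ct values follow Ct = base - log2(template) + Normal(0, sd) for each
#' (locus, fraction, target, replicate) combination, with ChIP template at
#' the experimental locus elevated by the configured enrichment (default 16x
#' endogenous, 4x ectopic, a planted 25% percent-endogenous). The contact
#' matrix is symmetric with entries proportional to (|i - j| + 1)^(-alpha)
#' plus a bonus on every site-site bin pair plus symmetric noise. The
#' occupancy track lies in [0, 1] with elevated values at site centers. The
#' expression table draws negative-binomial counts with the planted log2
#' fold-change applied inside the deleted site's domain.
#'
#' @param config A [sim_config()].
#' @param sites Planted site table.
#' @param assembly The simulation assembly.
#' @return List: `qpcr` (Ct table), `contacts` (`contact_matrix`),
#'   `occupancy` (`coverage_track` on the X), `expression` (gene table with
#'   log2 ratios).
#' @export
simulate_ancillary <- function(config, sites, assembly) {
  set.seed(config$seed + 7L)
  qc <- config$qpcr
  enr <- c(endogenous = qc$enrich_endogenous, ectopic = qc$enrich_ectopic)
  rows <- list()
  for (r in seq_len(qc$replicates)) {
    for (tg in names(enr)) {
      for (loc in c("experimental", "control")) {
        for (fr in c("ChIP", "input")) {
          template <- if (fr == "ChIP" && loc == "experimental") enr[[tg]]
                      else 1
          ct <- qc$base_ct - log2(template) + stats::rnorm(1, 0, qc$sd)
          rows[[length(rows) + 1L]] <- data.frame(
            replicate = r, locus = loc, fraction = fr, target = tg, ct = ct,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  qpcr <- do.call(rbind, rows)

  cc <- config$contact
  n_x <- assembly$lengths[[config$x_name]]
  nb <- ceiling(n_x / cc$bin_size)
  ij <- abs(outer(seq_len(nb), seq_len(nb), `-`))
  mat <- (ij + 1)^(-cc$alpha)
  site_bins <- unique(floor(sites$position / cc$bin_size) + 1)
  for (a in site_bins) for (b in site_bins) {
    if (a < b) mat[a, b] <- mat[a, b] + cc$bonus
  }
  if (cc$noise_sd > 0) {
    noise <- matrix(stats::rnorm(nb * nb, 0, cc$noise_sd), nb)
    mat <- mat + (noise + t(noise)) / 2
  }
  mat[lower.tri(mat)] <- t(mat)[lower.tri(mat)]
  contacts <- contact_matrix(mat, bin_size = cc$bin_size,
                             chrom = config$x_name)

  oc <- config$occupancy
  occ <- rep(oc$baseline, n_x)
  for (i in seq_len(nrow(sites))) {
    occ <- .add_kernel(occ, sites$position[i], oc$site_gain, oc$sd)
  }
  if (oc$noise_sd > 0) occ <- occ + stats::rnorm(n_x, 0, oc$noise_sd)
  occ <- .clip(occ, 0, 1)
  occupancy <- coverage_track(stats::setNames(list(occ), config$x_name),
                              label = "intrinsic_occupancy", kind = "raw")

  ex <- config$expression
  dom <- .enclosing_domain(config, sites$position[config$deletion$site])
  n_win <- ceiling(n_x / ex$window)
  pos <- unlist(lapply(seq_len(n_win), function(wdx) {
    lo <- (wdx - 1) * ex$window
    hi <- min(wdx * ex$window, n_x)
    sort(floor(stats::runif(ex$genes_per_window, lo, hi)))
  }))
  size <- 1 / ex$dispersion
  mu_wt <- rep(ex$base_mean, length(pos))
  in_dom <- pos >= dom[1] & pos < dom[2]
  mu_del <- mu_wt * ifelse(in_dom, 2^ex$lfc, 1)
  count_wt <- stats::rnbinom(length(pos), mu = mu_wt, size = size)
  count_del <- stats::rnbinom(length(pos), mu = mu_del, size = size)
  expression <- data.frame(
    gene = sprintf("gene%04d", seq_along(pos)), chrom = config$x_name,
    pos = pos, count_wt = count_wt, count_del = count_del,
    log2_ratio = log2((count_del + 0.5) / (count_wt + 0.5)),
    in_depleted_domain = in_dom, stringsAsFactors = FALSE)

  list(qpcr = qpcr, contacts = contacts, occupancy = occupancy,
       expression = expression)
}
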