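# The synthetic-data generator: determinism, planted structure, and
# recoverability of the ground truth by the downstream stages.

small_sim <- function(...) {
  sim_config(
    chrom_lengths = c(chrI = 5e4, chrII = 5e4, chrX = 2e5, chrM = 5e3),
    domain_boundaries = c(0, 1e5, 2e5),
    n_strong = 2, n_intermediate = 1, n_weak = 2,
    n_h3k4me3 = 2, n_decoy = 1, n_autosomal_sdc = 1,
    contact = list(bin_size = 2e3),
    ...)
}

test_that("configuration validation enforces the documented invariants", {
  expect_error(sim_config(nonsense = 1), "unknown configuration")
  expect_error(sim_config(deletion = list(d_max = 1.5)), "d_max")
  expect_error(sim_config(tier_amplitude = c(strong = 2, intermediate = 5,
                                             weak = 2)), "ordered")
  expect_error(sim_config(chrom_lengths = c(chrX = -1)), "positive")
  expect_error(sim_config(contact = list(binsize = 1)), "unknown")
})

test_that("the same seed reproduces genome and tracks exactly", {
  cfg <- small_sim(seed = 21)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$assembly$sequence, g2$assembly$sequence)
  expect_identical(g1$hits, g2$hits)
  e1 <- simulate_chip_experiment(cfg, g1$sites, g1$assembly,
                                 proteins = "SDC2", replicates = 2)
  e2 <- simulate_chip_experiment(cfg, g2$sites, g2$assembly,
                                 proteins = "SDC2", replicates = 2)
  expect_identical(e1$tracks$SDC2[[1]]$chip$values,
                   e2$tracks$SDC2[[1]]$chip$values)
  # simulating a protein subset reproduces the full run's tracks
  efull <- simulate_chip_experiment(cfg, g1$sites, g1$assembly,
                                    proteins = c("SDC2", "DPY27"),
                                    replicates = 2)
  expect_identical(efull$tracks$SDC2[[2]]$chip$values,
                   e1$tracks$SDC2[[2]]$chip$values)
})

test_that("strong sites carry motif clusters within 200 bp", {
  g <- generate_genome(small_sim(seed = 22))
  for (i in which(g$sites$tier == "strong")) {
    h <- g$hits[g$hits$site == i, ]
    expect_gte(nrow(h), 2)
    expect_lte(max(h$start) - min(h$start), 200)
  }
})

test_that("scanning recovers planted instances at their planned scores", {
  g <- generate_genome(small_sim(seed = 23))
  hits <- scan_genome(g$assembly, affinity_model(default_pwm()),
                      threshold = 4)
  m <- merge(g$hits, hits, by = c("chrom", "start"))
  expect_gte(nrow(m) / nrow(g$hits), 0.95)
  expect_true(all(abs(m$target_score - m$score) <= 0.5))
  expect_true(all(abs(m$planted_score - m$score) < 1e-9))
})

test_that("noiseless ChIP signal peaks exactly at the planted sites", {
  cfg <- small_sim(noise_sd = 0, seed = 24)
  g <- generate_genome(cfg)
  ex <- simulate_chip_experiment(cfg, g$sites, g$assembly,
                                 proteins = "SDC2", replicates = 1)
  enr <- normalize_and_subtract(ex$tracks$SDC2[[1]]$chip,
                                ex$tracks$SDC2[[1]]$input, g$assembly)
  v <- enr$values$chrX
  strong_pos <- g$sites$position[g$sites$tier == "strong"]
  expect_true((which.max(v) - 1) %in% strong_pos)
  # summit heights separate the planted tiers in the planted order
  heights <- v[g$sites$position + 1]
  tier <- g$sites$tier
  expect_gt(min(heights[tier == "strong"]),
            max(heights[tier == "intermediate"]))
  expect_gt(min(heights[tier == "intermediate"]),
            max(heights[tier == "weak"]))
})

test_that("replicate averages concentrate around the noiseless signal", {
  cfg <- small_sim(seed = 25)
  g <- generate_genome(cfg)
  noiseless <- simulate_chip_experiment(small_sim(noise_sd = 0, seed = 25),
                                        g$sites, g$assembly,
                                        proteins = "SDC2", replicates = 1)
  ref <- noiseless$tracks$SDC2[[1]]$chip$values$chrX
  ex <- simulate_chip_experiment(cfg, g$sites, g$assembly,
                                 proteins = "SDC2", replicates = 10)
  center <- g$sites$position[which.max(g$sites$amplitude)] + 1
  reps <- vapply(ex$tracks$SDC2, function(r) r$chip$values$chrX[center], 0)
  expect_lt(abs(mean(reps) - ref[center]) / ref[center], 0.1)
})

test_that("deletion strains deplete only inside the domain", {
  cfg <- small_sim(noise_sd = 0, spread_fraction = 0, seed = 26,
                   deletion = list(site = 1, d_max = 0.2, shape = "linear"))
  g <- generate_genome(cfg)
  wt <- simulate_chip_experiment(cfg, g$sites, g$assembly,
                                 proteins = "DPY27", replicates = 1)
  del <- simulate_deletion_strain(cfg, g$sites, g$assembly, tracks = wt,
                                  proteins = "DPY27", replicates = 1)
  vw <- wt$tracks$DPY27[[1]]$chip$values$chrX
  vd <- del$tracks$DPY27[[1]]$chip$values$chrX
  dom <- del$domain
  pos <- g$sites$position[1]
  # away from the removed peak, the in-domain ratio is 1 - d(x) with the
  # linear profile; beyond the boundary the signal is untouched
  x_in <- pos + 2e3
  d_expect <- 0.2 * min((x_in - dom[1]) / (pos - dom[1]),
                        (dom[2] - x_in) / (dom[2] - pos))
  expect_equal(vd[x_in + 1] / vw[x_in + 1], 1 - d_expect, tolerance = 1e-9)
  x_out <- dom[2] + 5e3
  expect_equal(vd[x_out + 1] / vw[x_out + 1], 1)
  # the deleted site's own peak is removed
  expect_lt(vd[pos + 1], 0.5 * vw[pos + 1])
  expect_error(simulate_deletion_strain(
    sim_config(deletion = list(site = 99)), g$sites, g$assembly),
    "no existing site")
})

test_that("downstream windows flag depletion only inside the domain", {
  cfg <- small_sim(noise_sd = 0, seed = 27)
  g <- generate_genome(cfg)
  wt <- simulate_chip_experiment(cfg, g$sites, g$assembly,
                                 proteins = "DPY27", replicates = 1)
  del <- simulate_deletion_strain(cfg, g$sites, g$assembly, tracks = wt,
                                  proteins = "DPY27", replicates = 1)
  asm <- g$assembly
  wt_enr <- normalize_and_subtract(wt$tracks$DPY27[[1]]$chip,
                                   wt$tracks$DPY27[[1]]$input, asm)
  del_enr <- normalize_and_subtract(del$tracks$DPY27[[1]]$chip,
                                    del$tracks$DPY27[[1]]$input, asm)
  centers <- seq(5e3, 195e3, by = 5e3)
  peaks <- data.frame(chrom = "chrX", start = centers - 100,
                      end = centers + 100)
  anchor_pos <- g$sites$position[g$sites$position >= del$domain[2]][1]
  anchor <- peaks[which.min(abs(centers - anchor_pos)), ]
  prof <- sliding_window_deviation(wt_enr, del_enr, peaks, anchor,
                                   window = 2e4)
  sig_centers <- prof$center[prof$significant]
  expect_gt(length(sig_centers), 0)
  expect_true(all(sig_centers >= del$domain[1] &
                    sig_centers <= del$domain[2]))
})

test_that("ancillary data have the planted quantitative structure", {
  cfg <- small_sim(seed = 28, qpcr = list(sd = 0))
  g <- generate_genome(cfg)
  anc <- simulate_ancillary(cfg, g$sites, g$assembly)
  # zero qPCR noise: a 16-fold ChIP template gives a Ct difference of -4
  ct <- anc$qpcr
  endo <- ct[ct$target == "endogenous" & ct$replicate == 1, ]
  d <- endo$ct[endo$locus == "experimental" & endo$fraction == "ChIP"] -
    endo$ct[endo$locus == "control" & endo$fraction == "ChIP"]
  expect_equal(d, -4)
  out <- ddct_percent_endogenous(ct)
  expect_equal(unname(out$percent_endogenous), rep(25, 3))
  # contact matrix symmetric; all site pairs carry bonuses
  expect_equal(anc$contacts$mat, t(anc$contacts$mat))
  x_sites <- data.frame(chrom = "chrX", start = g$sites$position - 200,
                        end = g$sites$position + 200)
  hic <- hic_interacting_sites(anc$contacts, x_sites)
  expect_equal(hic$count, nrow(x_sites))
  # occupancy in [0, 1], elevated at site centers
  occ <- anc$occupancy$values$chrX
  expect_true(all(occ >= 0 & occ <= 1))
  expect_gt(mean(occ[g$sites$position + 1]), mean(occ))
  # expression: up-regulation planted inside the deleted domain
  ex <- anc$expression
  expect_gt(mean(ex$log2_ratio[ex$in_depleted_domain]),
            mean(ex$log2_ratio[!ex$in_depleted_domain]))
})
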