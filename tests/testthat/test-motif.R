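# PWM construction, biophysical affinity scoring standardized to 0-10,
# genome scanning, homotypic clusters, enrichment curves, and occupancy
# comparisons.

test_that("PWM columns follow pseudocount-adjusted frequencies", {
  p <- build_pwm(rep("ATCGCGCAGGGA", 10), pseudocount = 0.01)
  expect_equal(attr(p, "consensus"), "ATCGCGCAGGGA")
  expect_equal(unname(unclass(p)["A", 1]), 10.01 / 10.04,
               tolerance = 1e-12)
  expect_equal(colSums(unclass(p)), rep(1, 12), ignore_attr = TRUE)
  p2 <- build_pwm(c("AAAA", "AAAT"))
  expect_equal(unname(unclass(p2)["A", 4]), unname(unclass(p2)["T", 4]))
  expect_error(build_pwm(c("AAA", "AAAA")), "unequal")
  expect_error(build_pwm(c("AAAA", "AAXA")), "position 3")
})

test_that("consensus scores exactly 10 and anti-consensus exactly 0", {
  m <- affinity_model(default_pwm())
  cons <- attr(m$pwm, "consensus")
  anti <- paste(c("A", "C", "G", "T")[apply(m$logp, 2, which.min)],
                collapse = "")
  expect_identical(score_sequences(m, cons), 10)
  expect_equal(score_sequences(m, anti), 0, tolerance = 1e-12)
})

test_that("substituting in a lower-probability base never raises the score", {
  m <- affinity_model(default_pwm())
  probs <- unclass(m$pwm)
  set.seed(4)
  for (rep_i in 1:25) {
    s <- strsplit("ATCGCGCAGGGA", "")[[1]]
    j <- sample(12, 1)
    cur_p <- probs[s[j], j]
    worse <- rownames(probs)[probs[, j] < cur_p]
    if (length(worse) == 0) next
    s2 <- s
    s2[j] <- sample(worse, 1)
    expect_lte(score_sequences(m, paste(s2, collapse = "")),
               score_sequences(m, paste(s, collapse = "")))
  }
})

test_that("genome scanning matches brute-force per-12-mer scoring", {
  m <- affinity_model(default_pwm())
  set.seed(5)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  substr(seq1, 2001, 2012) <- "ATCGCGCAGGGA"
  asm <- genome_assembly(c(chr1 = 5000), sequence = c(chr1 = seq1))
  hits <- scan_genome(asm, m, threshold = 0)
  oracle <- brute_scan(seq1, m)
  expect_equal(hits$score, unname(oracle), tolerance = 1e-9)
  expect_equal(max(hits$score), 10)
  expect_equal(hits$start[which.max(hits$score)], 2000)
})

test_that("windows containing N are skipped", {
  m <- affinity_model(default_pwm())
  s <- paste0(strrep("ACGT", 10), "N", strrep("ACGT", 10))
  asm <- genome_assembly(c(chr1 = nchar(s)), sequence = c(chr1 = s))
  hits <- scan_genome(asm, m, threshold = 0)
  # every window touching offset 40 (the N) is absent
  expect_false(any(hits$start %in% 29:40))
  expect_true(all(is.finite(hits$score)))
})

test_that("reverse-complementing the genome mirrors hits and flips strands", {
  m <- affinity_model(default_pwm())
  set.seed(6)
  s <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  substr(s, 501, 512) <- "ATCGCGCAGGGA"
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  h1 <- scan_genome(genome_assembly(c(c1 = 3000), sequence = c(c1 = s)), m)
  h2 <- scan_genome(genome_assembly(c(c1 = 3000), sequence = c(c1 = rc)), m)
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-9)
  # the planted plus-strand hit at 500 appears at the mirrored start
  mirrored <- 3000 - 12 - 500
  expect_equal(h2$score[h2$start == mirrored], 10)
  expect_equal(h2$strand[h2$start == mirrored], "-")
})

test_that("empirical standardization rescales to the observed extremes", {
  m <- affinity_model(default_pwm(), standardize = "empirical")
  set.seed(8)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  hits <- scan_genome(genome_assembly(c(c1 = 2000), sequence = c(c1 = s)), m)
  expect_equal(min(hits$score), 0, tolerance = 1e-9)
  expect_equal(max(hits$score), 10, tolerance = 1e-9)
})

mk_hits <- function(start, score, chrom = "chrX", strand = "+") {
  structure(data.frame(chrom = chrom, start = start, strand = strand,
                       score = score, occupancy = NA_real_,
                       stringsAsFactors = FALSE), width = 12L)
}

test_that("cluster detection applies both thresholds and the 200-bp window", {
  # strongest pair of a real autosomal cluster: scores 9.5 and 6.25, 68 bp
  cl <- detect_clusters(mk_hits(c(1000, 1068), c(9.5, 6.25)))
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n_members, 2)
  # anchor without a qualifying member: no cluster
  cl2 <- detect_clusters(mk_hits(c(1000, 1100), c(7.5, 4.9)))
  expect_equal(nrow(cl2$clusters), 0)
  # member beyond 200 bp start-to-start: no cluster
  cl3 <- detect_clusters(mk_hits(c(1000, 1201), c(7.5, 6)))
  expect_equal(nrow(cl3$clusters), 0)
})

test_that("clusters sharing a member merge and order does not matter", {
  h <- mk_hits(c(0, 150, 290), c(7.2, 6.0, 7.1))
  cl <- detect_clusters(h)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n_members, 3)
  h_shuf <- h[c(3, 1, 2), ]
  cl2 <- detect_clusters(h_shuf)
  expect_equal(cl2$clusters, cl$clusters)
  # merging is idempotent: re-detecting on the member hits changes nothing
  cl3 <- detect_clusters(cl$members[, names(h)])
  expect_equal(cl3$clusters$n_members, cl$clusters$n_members)
})

test_that("enrichment curve counts and length-normalizes per cutoff", {
  asm <- genome_assembly(c(chrI = 3e4, chrX = 1e4), x_name = "chrX")
  # X is 25% of the genome and holds 9 of 12 strong hits -> fold 3 at 7
  h <- rbind(mk_hits(seq(100, by = 50, length.out = 9), rep(8, 9), "chrX"),
             mk_hits(seq(100, by = 50, length.out = 3), rep(8, 3), "chrI"),
             mk_hits(2000, 4, "chrI"))
  ec <- enrichment_curve(h, asm, cutoffs = c(4, 7, 9.5))
  expect_equal(ec$fold_enrichment[ec$cutoff == 7], 3.0)
  expect_equal(ec$x_count[ec$cutoff == 7], 9)
  expect_true(is.na(ec$fold_enrichment[ec$cutoff == 9.5]))
  expect_equal(ec$x_count[ec$cutoff == 9.5], 0)
  solo <- enrichment_curve(mk_hits(c(1, 50), c(8, 8)),
                           genome_assembly(c(chrX = 1e4), x_name = "chrX"),
                           cutoffs = 7)
  expect_equal(solo$fold_enrichment, 1.0)
})

test_that("occupancy comparisons report medians and one-tailed p-values", {
  v <- rep(0.4, 10000); v[1:5000] <- 0.8
  tr <- coverage_track(list(chrX = v))
  gA <- data.frame(chrom = "chrX", center = seq(1000, 4000, by = 500))
  gB <- data.frame(chrom = "chrX", center = seq(6000, 9000, by = 500))
  out <- occupancy_compare(tr, list(A = gA, B = gB))
  expect_equal(unname(out$medians), c(0.8, 0.4))
  expect_lt(out$p_greater["A", "B"], 1e-6)
  expect_equal(out$p_greater["B", "A"], 1)
  # same constant track in both groups: p = 0.5 by convention
  same <- occupancy_compare(tr, list(A = gB, B = gB))
  expect_equal(unname(same$p_greater["A", "B"]), 0.5)
})

test_that("occupancy group differences are detected at simulated effect sizes", {
  set.seed(9)
  L <- 6e4
  # 100 plateaus of 300 bp; the first 50 (group A) drawn around 0.6, the
  # next 50 (group B) around 0.5
  centers <- seq(200, L - 200, length.out = 100)
  levels <- pmin(pmax(c(rnorm(50, 0.6, 0.05), rnorm(50, 0.5, 0.05)), 0), 1)
  v <- rep(0, L)
  for (i in seq_along(centers)) {
    v[(centers[i] - 150):(centers[i] + 150) + 1] <- levels[i]
  }
  tr <- coverage_track(list(chrX = v))
  groups <- list(A = data.frame(chrom = "chrX", center = centers[1:50]),
                 B = data.frame(chrom = "chrX", center = centers[51:100]))
  out <- occupancy_compare(tr, groups)
  expect_equal(unname(out$medians["A"]), 0.6, tolerance = 0.02)
  expect_equal(unname(out$medians["B"]), 0.5, tolerance = 0.02)
  expect_lt(out$p_greater["A", "B"], 0.01)
})
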