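# Median normalization with input subtraction, replicate averaging,
# majority-rule consensus peaks, and summit-aware peak splitting.

test_that("normalization divides by genome-wide medians before subtracting", {
  asm <- tiny_assembly(c(chrA = 5, chrM = 5))
  chip <- const_track(asm$lengths, 6)
  input <- const_track(asm$lengths, 2)
  enr <- normalize_and_subtract(chip, input, asm)
  expect_true(all(abs(enr$values$chrA) < 1e-12))

  chip2 <- coverage_track(list(chrA = c(2, 4, 6, 8, 10), chrM = rep(6, 5)))
  enr2 <- normalize_and_subtract(chip2, input, asm)
  expect_equal(enr2$values$chrA,
               c(2, 4, 6, 8, 10) / 6 - 1)  # chip median 6 (mito excluded)
})

test_that("mitochondrial bases do not influence normalization", {
  asm1 <- tiny_assembly(c(chrA = 100, chrM = 50))
  asm2 <- genome_assembly(c(chrA = 100))
  set.seed(3)
  v <- rlnorm(100)
  chip1 <- coverage_track(list(chrA = v, chrM = rep(1000, 50)))
  chip2 <- coverage_track(list(chrA = v))
  input1 <- const_track(asm1$lengths, 2)
  input2 <- const_track(asm2$lengths, 2)
  e1 <- normalize_and_subtract(chip1, input1, asm1)
  e2 <- normalize_and_subtract(chip2, input2, asm2)
  expect_equal(e1$values$chrA, e2$values$chrA)
})

test_that("separate X/autosome normalization uses per-group medians", {
  asm <- tiny_assembly(c(chrA = 10, chrX = 10, chrM = 5))
  chip <- coverage_track(list(chrA = rep(4, 10), chrX = rep(8, 10),
                              chrM = rep(1, 5)))
  input <- const_track(asm$lengths, 1)
  enr <- normalize_and_subtract(chip, input, asm, separate_x = TRUE)
  # each group normalizes to 1, so enrichment is 0 on both X and autosomes
  expect_true(all(abs(enr$values$chrA) < 1e-12))
  expect_true(all(abs(enr$values$chrX) < 1e-12))
})

test_that("zero median coverage is rejected with guidance", {
  asm <- tiny_assembly(c(chrA = 10, chrM = 5))
  chip <- const_track(asm$lengths, 0)
  input <- const_track(asm$lengths, 1)
  expect_error(normalize_and_subtract(chip, input, asm), "background")
})

test_that("a track already at median one is unchanged by normalization", {
  asm <- tiny_assembly(c(chrA = 101, chrM = 5))
  v <- seq(0.5, 1.5, length.out = 101)  # median exactly 1
  chip <- coverage_track(list(chrA = v, chrM = rep(1, 5)))
  input <- const_track(asm$lengths, 7)
  enr <- normalize_and_subtract(chip, input, asm)
  expect_equal(enr$values$chrA, v - 1)
})

test_that("replicate merging is the positionwise arithmetic mean", {
  asm <- tiny_assembly(c(chrA = 4))
  t1 <- coverage_track(list(chrA = c(2, 2, 2, 2)))
  t2 <- coverage_track(list(chrA = c(4, 4, 4, 4)))
  expect_equal(merge_replicates(list(t1))$values, t1$values)
  expect_equal(merge_replicates(list(t1, t2))$values$chrA, rep(3, 4))
  consts <- c(1, 4, 7, 10)
  tracks <- lapply(consts, function(cst) const_track(c(chrA = 4), cst))
  expect_equal(merge_replicates(tracks)$values$chrA,
               rep(mean(consts), 4))
  expect_error(merge_replicates(list()), "empty")
  expect_error(merge_replicates(list(t1, const_track(c(chrB = 4), 1))),
               "mismatch")
})

test_that("consensus peaks obey the strict majority rule", {
  combined <- mk_peaks("chrA", c(100, 300), c(200, 400))
  r1 <- mk_peaks("chrA", 150, 180)
  r2 <- mk_peaks("chrA", 120, 160)
  r3 <- mk_peaks("chrA", 600, 700)
  # overlapped in 2 of 3 replicates -> retained; 1 of 3 -> dropped
  got <- consensus_peaks(combined, list(r1, r2, r3))
  expect_equal(got$start, 100)
  got1 <- consensus_peaks(combined, list(r1, r3, r3))
  expect_equal(nrow(got1), 0)
  # majority of 2 is 2: 1 of 2 -> dropped
  got2 <- consensus_peaks(combined, list(r1, r3))
  expect_equal(nrow(got2), 0)
  expect_equal(consensus_peaks(combined, list(r1, r2)),
               majority_oracle(combined, list(r1, r2)))
})

test_that("consensus summits are recomputed on the merged track", {
  v <- rep(0, 1000); v[501] <- 9; v[151] <- 5  # maxima at offsets 500, 150
  tr <- coverage_track(list(chrA = v), kind = "enrichment")
  combined <- mk_peaks("chrA", 100, 600, summit = 110, height = 1)
  got <- consensus_peaks(combined, list(mk_peaks("chrA", 450, 550)),
                         track = tr)
  expect_equal(got$summit, 500)
  expect_equal(got$summit_height, 9)
})

test_that("adding a replicate covering every peak never removes one", {
  set.seed(7)
  combined <- mk_peaks("chrA", seq(0, 900, 100), seq(50, 950, 100))
  reps <- lapply(1:3, function(i) {
    keep <- runif(nrow(combined)) < 0.6
    combined[keep, , drop = FALSE]
  })
  base <- consensus_peaks(combined, reps)
  more <- consensus_peaks(combined, c(reps, list(combined)))
  expect_true(all(base$start %in% more$start))
})

test_that("peaks split at qualifying valleys and partition the parent", {
  # piecewise-linear profile: summits 10 @100 and 8 @300, valley 3 @200
  v <- approx(x = c(0, 100, 200, 300, 499), y = c(0.5, 10, 3, 8, 0.5),
              xout = 0:499)$y
  tr <- coverage_track(list(chrA = v), kind = "enrichment")
  pk <- mk_peaks("chrA", 0, 500, summit = 100, height = 10)
  out <- split_peaks(pk, tr, separation = 0.85, min_height = 4)
  # valley 3 < 0.85 * min(10, 8) = 6.8 -> split at offset 200
  expect_equal(nrow(out), 2)
  expect_equal(out$end[1], out$start[2])
  expect_equal(out$start[1], 0)
  expect_equal(out$end[2], 500)
  expect_equal(out$summit, c(100, 300))
  # partition property and summit locality
  for (i in 1:2) {
    seg <- v[(out$start[i] + 1):out$end[i]]
    expect_equal(out$summit_height[i], max(seg))
  }
})

test_that("monotone peaks and sub-threshold maxima do not split", {
  v <- c(seq(0, 10, length.out = 250), seq(10, 0, length.out = 250))
  tr <- coverage_track(list(chrA = v), kind = "enrichment")
  pk <- mk_peaks("chrA", 0, 500, summit = 249, height = 10)
  out <- split_peaks(pk, tr, min_height = 4)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 0)
  expect_equal(out$end, 500)
  # second maximum below the minimum height is not a candidate
  v2 <- approx(x = c(0, 100, 200, 300, 499), y = c(0.5, 10, 1, 3, 0.5),
               xout = 0:499)$y
  tr2 <- coverage_track(list(chrA = v2), kind = "enrichment")
  out2 <- split_peaks(mk_peaks("chrA", 0, 500, summit = 100, height = 10),
                      tr2, min_height = 4)
  expect_equal(nrow(out2), 1)
})

test_that("automatic minimum height is the median summit height", {
  v <- approx(x = c(0, 100, 200, 300, 499), y = c(0.5, 10, 3, 8, 0.5),
              xout = 0:499)$y
  tr <- coverage_track(list(chrA = v), kind = "enrichment")
  pks <- rbind(mk_peaks("chrA", 0, 500, summit = 100, height = 10))
  # median summit height = 10: the 8-high maximum is not a candidate
  out <- split_peaks(pks, tr, min_height = "auto")
  expect_equal(nrow(out), 1)
})

test_that("threshold peak calling finds runs and leftmost summits", {
  v <- rep(0, 1000)
  v[201:400] <- 2
  v[301:305] <- 5  # plateau: summit is its leftmost base (offset 300)
  tr <- coverage_track(list(chrA = v), kind = "enrichment")
  pk <- call_peaks(tr, threshold = 1, min_width = 50, smooth = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 200)
  expect_equal(pk$end, 400)
  expect_equal(pk$summit, 300)
  expect_equal(pk$summit_height, 5)
})
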