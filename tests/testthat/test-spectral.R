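# Featurization pipeline: segmentation, band power, grid mapping.

test_that("segmentation tiles the recording into 4-s windows, partial tail dropped", {
  rec <- raw_recording(matrix(rnorm(62 * 12000), 62), fs = 200, label = 2L)
  segs <- segment_recording(rec)                      # 60 s -> 15 segments
  expect_length(segs, 15)
  expect_true(all(vapply(segs, function(s) ncol(s$samples), numeric(1)) == 800))
  expect_true(all(vapply(segs, function(s) s$label, integer(1)) == 2L))
  # segments tile the prefix contiguously
  expect_identical(do.call(cbind, lapply(segs, function(s) s$samples)),
                   rec$samples[, 1:12000])

  short <- raw_recording(matrix(rnorm(62 * 780), 62), fs = 200)  # 3.9 s
  expect_length(segment_recording(short), 0)

  exact <- raw_recording(matrix(rnorm(62 * 800), 62), fs = 200)
  one <- segment_recording(exact)
  expect_length(one, 1)
  expect_identical(one[[1]]$samples, exact$samples)

  # arbitrary T, fs: count is floor(T / (4 fs))
  for (n in c(799, 800, 801, 3205, 4800)) {
    r <- raw_recording(matrix(0, 2, n), c("A", "B"), fs = 200)
    expect_length(segment_recording(r), n %/% 800)
  }
  bad <- raw_recording(matrix(0, 1, 900), "A", fs = 200)
  bad$samples[1, 5] <- NaN
  expect_error(segment_recording(bad), "non-finite")
})

test_that("band power localises a pure sinusoid and scales quadratically", {
  alpha <- list(name = "alpha", lo = 8, hi = 14)
  seg <- sine_recording(10)
  # zero signal
  zero <- raw_recording(matrix(0, 3, 800), paste0("C", 1:3), fs = 200)
  expect_equal(unname(band_power(zero, alpha)), rep(0, 3))
  expect_equal(unname(band_power(zero, alpha, "mean_square")), rep(0, 3))
  # mean square of a unit sinusoid in its own band ~ 1/2
  expect_equal(unname(band_power(seg, alpha, "mean_square")), 0.5,
               tolerance = 0.05)
  # welch: >= 90% of five-band power in alpha; independent periodogram oracle
  bp <- band_power_table(seg)
  expect_gte(bp[, "alpha"] / sum(bp), 0.9)
  x <- seg$samples[1, ]
  pg <- Mod(stats::fft(x))^2 / length(x)
  f <- (seq_along(x) - 1) * 200 / length(x)
  oracle_frac <- sum(pg[f >= 8 & f < 14]) / sum(pg[f >= 1 & f < 50])
  expect_gte(oracle_frac, 0.9)   # the oracle agrees the band captures it
  # off-band leakage: power(beta) / power(alpha) <= 0.1
  expect_lte(bp[, "beta"] / bp[, "alpha"], 0.1)
  # quadratic amplitude scaling, both estimators
  for (m in c("welch", "mean_square")) {
    p1 <- band_power(sine_recording(10, amp = 1), alpha, m)
    p3 <- band_power(sine_recording(10, amp = 3), alpha, m)
    expect_equal(unname(p3 / p1), 9, tolerance = 1e-9)
  }
  # errors: Nyquist violation and resolution failure
  expect_error(band_power(seg, list(name = "x", lo = 90, hi = 110)), "Nyquist")
  expect_error(band_power(sine_recording(10, dur = 4),
                          list(name = "x", lo = 8.3, hi = 8.7)),
               "resolution")
})

test_that("electrode layout is injective and the scatter map round-trips", {
  lay <- electrode_layout()
  expect_equal(nrow(lay$table), 62)
  expect_false(any(duplicated(lay$table[, c("row", "col")])))
  expect_true(all(lay$table$row >= 1 & lay$table$row <= 32))
  expect_true(all(lay$table$col >= 1 & lay$table$col <= 32))

  bp <- matrix(runif(62 * 5), 62, 5,
               dimnames = list(eeg_channels_62(), eeg_bands()$name))
  m <- build_spatial_spectral(bp, lay)
  expect_equal(dim(m), c(32, 32, 5))
  # exactly 62 nonzero cells per band slice (all-ones input)
  ones <- build_spatial_spectral(bp * 0 + 1, lay)
  expect_equal(apply(ones, 3, function(s) sum(s == 1)), rep(62, 5))
  expect_equal(apply(ones, 3, function(s) sum(s != 0)), rep(62, 5))
  # round trip recovers the table exactly
  back <- read_map_cells(m, lay)
  expect_equal(rownames(back), rownames(bp))
  expect_equal(unname(back), unname(bp))
  # missing electrode is named in the error
  bad <- bp; rownames(bad)[1] <- "NOPE"
  expect_error(build_spatial_spectral(bad, lay), "NOPE")
  # interpolation fills every cell
  mi <- build_spatial_spectral(bp, lay, mode = "interpolate")
  expect_true(all(mi > 0))
  # a smaller grid still resolves collisions injectively
  lay8 <- electrode_layout(8, 8)
  expect_false(any(duplicated(lay8$table[, c("row", "col")])))
})

test_that("featurize_dataset yields floor(T/4fs) maps per recording and standardizes", {
  set.seed(9)
  recs <- lapply(0:1, function(cl)
    raw_recording(matrix(rnorm(62 * 4000), 62), fs = 200, label = cl))
  maps <- featurize_dataset(recs)                     # 2 x 20 s -> 10 maps
  expect_length(maps, 10)
  expect_equal(map_labels(maps), rep(0:1, each = 5))
  expect_length(featurize_dataset(list()), 0)

  zmaps <- featurize_dataset(recs, standardize = TRUE)
  flat <- vapply(zmaps, as.numeric, numeric(length(zmaps[[1]])))
  mapped <- which(apply(flat, 1, function(r) any(r != 0)))
  expect_lt(max(abs(rowMeans(flat[mapped, ]))), 1e-10)
  expect_equal(apply(flat[mapped, ], 1, sd), rep(1, length(mapped)),
               tolerance = 1e-8)
  # reusing training statistics on new data keeps the transform fixed
  st <- attr(zmaps, "standardization")
  z2 <- featurize_dataset(recs[1], standardize = TRUE, stats = st)
  expect_equal(as.numeric(z2[[1]]), as.numeric(zmaps[[1]]))

  het <- c(recs[1], list(raw_recording(matrix(0, 2, 900), c("A", "B"), fs = 200)))
  expect_error(featurize_dataset(het), "heterogeneous")
})
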