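test_that("pair counting matches the closed form", {
  expect_equal(pair_count(2400), 2878800)
  expect_equal(pair_count(80), 3160)
  expect_equal(pair_count(1), 0)
})

test_that("parcel averaging is the signed per-sample mean", {
  # identical waveforms in one parcel reproduce the waveform
  x <- matrix(rep(sin(1:50), 3), 3, 50, byrow = TRUE)
  pm <- data.frame(patch_id = 1:3, parcel = "A_L", hemisphere = "left")
  expect_equal(as.numeric(average_by_parcel(x, pm)), sin(1:50))
  # antiphase pair cancels (documented hazard of signed averaging)
  y <- rbind(sin(1:50), -sin(1:50))
  pm2 <- data.frame(patch_id = 1:2, parcel = "B_L", hemisphere = "left")
  expect_lt(max(abs(average_by_parcel(y, pm2))), 1e-14)
  # brute-force oracle on a random 10-patch / 3-parcel map
  set.seed(31)
  J <- array(rnorm(10 * 20 * 4), dim = c(10, 20, 4))
  parc <- sample(c("P1_L", "P2_R", "P3_L"), 10, replace = TRUE)
  pm3 <- data.frame(patch_id = 1:10, parcel = parc,
                    hemisphere = ifelse(grepl("_R$", parc), "right", "left"))
  got <- average_by_parcel(J, pm3)
  for (p in sort(unique(parc))) {
    rows <- which(parc == p)
    for (e in 1:4) {
      man <- colMeans(J[rows, , e, drop = FALSE][, , 1, drop = TRUE],
                      na.rm = FALSE)
      if (length(rows) == 1) man <- J[rows, , e]
      expect_equal(as.numeric(got[p, , e]), as.numeric(man),
                   tolerance = 1e-12, info = p)
    }
  }
  expect_error(average_by_parcel(J, pm2), "covers")
})

test_that("1-s epochs give exactly 1 Hz bin spacing and clean sine peaks", {
  fs <- 250
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- matrix(sin(2 * pi * 10 * t))
  cs <- cross_spectra(x, x, fs)
  expect_equal(cs$freq, 1:70)
  expect_equal(unique(diff(cs$freq)), 1)
  # Fourier orthogonality on the integer-Hz grid: all power in the 10 Hz bin
  expect_gt(cs$Sxx[cs$freq == 10] / sum(cs$Sxx), 0.999)
  # S_XY for x = y is the real, non-negative autospectrum
  expect_equal(Im(cs$Sxy), rep(0, 70), tolerance = 1e-12)
  expect_equal(Re(cs$Sxy), cs$Sxx, tolerance = 1e-12)
  expect_error(cross_spectra(x, x, fs = 100, fmax = 70), "Nyquist")
  expect_error(cross_spectra(x, x[-1, , drop = FALSE], fs), "identical")
})

test_that("coherence identities hold", {
  fs <- 200
  set.seed(32)
  x <- matrix(rnorm(fs * 8), fs, 8)
  cs <- cross_spectra(x, x, fs)
  coh <- coherence(cs)
  expect_equal(coh, rep(1, 70), tolerance = 1e-12)       # self-coherence
  y <- matrix(rnorm(fs * 8), fs, 8)
  cxy <- coherence(cross_spectra(x, y, fs))
  expect_true(all(cxy >= 0 & cxy <= 1))
  # scale invariance
  c2 <- coherence(cross_spectra(511.3 * x, 1e-3 * y, fs))
  expect_equal(c2, cxy, tolerance = 1e-12)
  # single epoch: identically 1, with a warning
  expect_warning(c1 <- coherence(cross_spectra(x[, 1], y[, 1], fs)),
                 "single epoch")
  expect_equal(c1, rep(1, 70), tolerance = 1e-10)
  expect_error(coherence(-cs$Sxx, cs$Syy, cs$Sxy), "non-negative")
})

test_that("coherence of a shared sinusoid matches the long-run oracle", {
  fs <- 250
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  s_amp <- 1
  gen <- function(M) {
    shared <- outer(sin(2 * pi * 10 * t), rep(s_amp, M))
    list(x = shared + matrix(rnorm(fs * M), fs, M),
         y = shared + matrix(rnorm(fs * M), fs, M))
  }
  set.seed(33)
  # long-run oracle at large M
  big <- gen(20000)
  oracle <- coherence(cross_spectra(big$x, big$y, fs))[10]
  # theory: s2 / (s2 + sigma_bin2) at the 10 Hz bin
  sig2 <- (s_amp * fs / 2)^2
  noise2 <- fs
  expect_equal(oracle, sig2 / (sig2 + noise2), tolerance = 0.02)
  small <- gen(100)
  est <- coherence(cross_spectra(small$x, small$y, fs))[10]
  expect_lt(abs(est - oracle), 0.1)
})

test_that("band averaging follows the documented bin mapping", {
  bt <- band_table()
  expect_equal(bt$band, c("delta", "theta", "alpha", "beta", "gamma"))
  freq <- 1:70
  # constant coherence: every band equals the constant
  expect_equal(unname(band_average(rep(0.4, 70), freq)), rep(0.4, 5))
  # unit coherence at 10 Hz only: alpha = 1/5 (bins 8..12), others 0
  coh <- as.numeric(freq == 10)
  ba <- band_average(coh, freq)
  expect_equal(unname(ba), c(0, 0, 1 / 5, 0, 0))
  # linear ramp: band means equal the enumerated bin means
  ramp <- freq / 70
  ba2 <- band_average(ramp, freq)
  for (i in seq_len(nrow(bt))) {
    bins <- bt$fmin[i]:bt$fmax[i]
    expect_equal(unname(ba2[bt$band[i]]), mean(bins / 70))
  }
  # band with zero defined bins is NA
  expect_true(is.na(band_average(rep(NA_real_, 3), 1:3)["delta"]))
})

test_that("coherence matrices are symmetric, bounded and block-ordered", {
  fs <- 200
  set.seed(34)
  M <- 8
  mk <- function() matrix(rnorm(fs * M), fs, M)
  shared <- mk()
  arr <- array(0, dim = c(5, fs, M),
               dimnames = list(c("B2_R", "A1_R", "C3_R", "A1_L", "B2_L"),
                               NULL, NULL))
  for (p in 1:5) arr[p, , ] <- mk() + if (p <= 2) shared else 0
  res <- coherence_matrix(list(pre = arr, spike = arr, post = arr), fs)
  # right-hemisphere parcels first (sorted), so intra-right is upper-left
  expect_equal(res$parcels, c("A1_R", "B2_R", "C3_R", "A1_L", "B2_L"))
  for (iv in res$intervals) {
    expect_true(all(iv$coh >= 0 & iv$coh <= 1, na.rm = TRUE))
    for (f in c(1, 35, 70)) {
      expect_equal(iv$coh[, , f], t(iv$coh[, , f]), tolerance = 1e-12)
      expect_equal(unname(diag(iv$coh[, , f])), rep(1, 5))
    }
  }
  expect_output(print(res), "5 parcels")
  expect_s3_class(summary(res), "data.frame")
})

test_that("independent parcels show only the small-sample coherence bias", {
  fs <- 160
  set.seed(35)
  M <- 200
  arr <- array(rnorm(6 * fs * M), dim = c(6, fs, M),
               dimnames = list(sprintf("P%d_L", 1:6), NULL, NULL))
  res <- coherence_matrix(arr, fs)
  band <- res$intervals[[1]]$band
  off <- band[upper.tri(band[, , 1])]
  for (b in 1:5) expect_lt(mean(band[, , b][upper.tri(band[, , b])]), 0.25)
})

test_that("null coherence decays as the epoch count doubles", {
  fs <- 160
  set.seed(36)
  mean_off <- sapply(c(2, 4, 8, 16, 32, 64, 128, 256), function(M) {
    arr <- array(rnorm(8 * fs * M), dim = c(8, fs, M),
                 dimnames = list(sprintf("P%d_L", 1:8), NULL, NULL))
    cm <- suppressWarnings(coherence_matrix(arr, fs))$intervals[[1]]$coh
    mean(apply(cm, 3, function(m) mean(m[upper.tri(m)])))
  })
  expect_true(all(diff(mean_off) < 0))
})

test_that("top-k edge extraction ranks and ties deterministically", {
  fs <- 200
  set.seed(37)
  M <- 30
  shared <- matrix(rnorm(fs * M), fs, M)
  arr <- array(rnorm(6 * fs * M), dim = c(6, fs, M),
               dimnames = list(sprintf("P%d_%s", 1:6,
                                       rep(c("R", "L"), each = 3)),
                               NULL, NULL))
  arr[2, , ] <- arr[2, , ] + 2 * shared
  arr[5, , ] <- arr[5, , ] + 2 * shared
  res <- coherence_matrix(arr, fs)
  ed <- top_k_edges(res, k = 3)
  expect_named(ed, c("interval", "band", "parcel_a", "parcel_b", "coherence"))
  expect_equal(nrow(ed), 15)  # 3 per band
  # the planted broadband pair tops every band
  for (b in band_table()$band) {
    top <- ed[ed$band == b, ][1, ]
    expect_setequal(c(top$parcel_a, top$parcel_b), c("P2_R", "P5_L"))
  }
  # k larger than the number of pairs returns all pairs
  ed_all <- top_k_edges(res, k = 1e6, per_band = FALSE)
  expect_equal(nrow(ed_all), pair_count(6) * 5)
  expect_true(all(diff(ed_all$coherence) <= 0))
  expect_error(top_k_edges(res, k = 5, interval = "nope"), "unknown")
})

test_that("a planted band-limited pair is recovered in the band top-10", {
  fs <- 200
  t_idx <- seq_len(fs)
  hits <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    set.seed(4000 + r)
    M <- 20
    P <- 12
    arr <- array(rnorm(P * fs * M), dim = c(P, fs, M),
                 dimnames = list(sprintf("P%02d_%s", 1:P,
                                         rep(c("R", "L"), each = 6)),
                                 NULL, NULL))
    for (e in seq_len(M)) {
      sb <- epicoh:::band_noise(fs, fs, 8, 12)
      ua <- epicoh:::band_noise(fs, fs, 8, 12)
      ub <- epicoh:::band_noise(fs, fs, 8, 12)
      arr[3, , e] <- arr[3, , e] + 2 * (sqrt(0.9) * sb + sqrt(0.1) * ua)
      arr[9, , e] <- arr[9, , e] + 2 * (sqrt(0.9) * sb + sqrt(0.1) * ub)
    }
    res <- coherence_matrix(arr, fs)
    ed <- top_k_edges(res, k = 10)
    alpha <- ed[ed$band == "alpha", ]
    if (any((alpha$parcel_a == "P03_R" & alpha$parcel_b == "P09_L") |
              (alpha$parcel_a == "P09_L" & alpha$parcel_b == "P03_R"))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 95L)
})

test_that("coherence outputs are written as readable TSV bundles", {
  fs <- 160
  set.seed(38)
  arr <- array(rnorm(4 * fs * 5), dim = c(4, fs, 5),
               dimnames = list(c("P1_R", "P2_R", "P1_L", "P2_L"), NULL, NULL))
  res <- coherence_matrix(list(pre = arr, spike = arr, post = arr), fs)
  d <- withr::local_tempdir()
  files <- write_coherence(res, file.path(d, "coh"), k = 5)
  expect_true(all(file.exists(files)))
  m <- read.delim(files[1])
  expect_equal(m$parcel, res$parcels)
})
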