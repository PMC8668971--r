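test_that("default frequency grid is arithmetic up to the Nyquist limit", {
  g <- defaultFrequencyGrid(101, oversample = 1)
  expect_equal(g, seq(0.01, 0.5, by = 0.01), tolerance = 1e-12)
  g4 <- defaultFrequencyGrid(101, oversample = 4)
  expect_equal(length(g4), 4 * length(g))
  expect_equal(g4[1], 0.0025, tolerance = 1e-12)
  expect_lte(max(g4), 0.5)
  expect_lte(max(defaultFrequencyGrid(37, oversample = 2.7)), 0.5)
  expect_error(defaultFrequencyGrid(3), "at least 4")
})

test_that("constant curves carry no spectral power", {
  sp <- lombScarglePSD(rep(3.2, 50))
  expect_lte(max(spectralPower(sp)), 1e-10)
  spRaw <- lombScarglePSD(rep(3.2, 50), normalization = "psd")
  expect_lte(max(spectralPower(spRaw)), 1e-10)
})

test_that("a pure cosine is recovered at its frequency", {
  x <- cos(2 * pi * 0.1 * (1:100))
  g <- defaultFrequencyGrid(100, oversample = 4)
  sp <- lombScarglePSD(x, g)
  fhat <- frequencies(sp)[which.max(spectralPower(sp))]
  expect_lte(abs(fhat - 0.1), diff(g)[1])
})

test_that("raw power equals the least-squares sinusoid-fit oracle", {
  set.seed(31)
  for (rep in 1:3) {
    x <- rnorm(40)
    fs <- runif(10, 0.03, 0.47)
    sp <- lombScarglePSD(x, sort(fs), normalization = "psd")
    for (k in seq_along(fs)) {
      expected <- oracleLombPower(x, sort(fs)[k])
      expect_equal(spectralPower(sp)[k], expected,
                   tolerance = 1e-8)
    }
  }
})

test_that("standard normalization divides raw power by the curve variance", {
  set.seed(32)
  x <- rnorm(60)
  g <- defaultFrequencyGrid(60)
  raw <- spectralPower(lombScarglePSD(x, g, normalization = "psd"))
  std <- spectralPower(lombScarglePSD(x, g, normalization = "standard"))
  expect_equal(std, raw / var(x), tolerance = 1e-12)
})

test_that("uniform sampling reduces to the classical DFT periodogram", {
  set.seed(33)
  n <- 64
  x <- rnorm(n); xc <- x - mean(x)
  k <- 1:31
  sp <- lombScarglePSD(x, k / n, normalization = "psd")
  dft <- Mod(fft(xc))^2 / n
  expect_equal(spectralPower(sp), dft[k + 1], tolerance = 1e-6)
})

test_that("power scales as the square of the curve for raw normalization", {
  set.seed(34)
  x <- rnorm(50); g <- defaultFrequencyGrid(50)
  p1 <- spectralPower(lombScarglePSD(x, g, normalization = "psd"))
  pk <- spectralPower(lombScarglePSD(3 * x, g, normalization = "psd"))
  expect_equal(pk, 9 * p1, tolerance = 1e-10)      # homogeneity degree 2
  s1 <- spectralPower(lombScarglePSD(x, g))
  sk <- spectralPower(lombScarglePSD(3 * x, g))
  expect_equal(sk, s1, tolerance = 1e-10)          # scale-free (degree 0)
})

test_that("inner-product spectrum is the elementwise power product", {
  f <- (1:6) / 12
  P12 <- new("PowerSpectrum", frequencies = f, power = c(1, 4, 2, 0, 5, 3))
  ones <- new("PowerSpectrum", frequencies = f, power = rep(1, 6))
  zero <- new("PowerSpectrum", frequencies = f, power = rep(0, 6))
  expect_equal(spectralPower(innerProductSpectrum(P12, ones)),
               spectralPower(P12))
  expect_equal(spectralPower(innerProductSpectrum(P12, zero)), rep(0, 6))
  set.seed(35)
  P23 <- new("PowerSpectrum", frequencies = f, power = runif(6))
  expect_equal(spectralPower(innerProductSpectrum(P12, P23)),
               spectralPower(P12) * spectralPower(P23))
  other <- new("PowerSpectrum", frequencies = f + 0.01, power = rep(1, 6))
  expect_error(innerProductSpectrum(P12, other), "grids differ")
})

test_that("first-peak exclusion removes through the first following minimum", {
  mk <- function(p) new("PowerSpectrum",
                        frequencies = seq_along(p) / (2 * length(p)),
                        power = p)
  out <- excludeFirstPeak(mk(c(9, 4, 1, 6, 3)))
  expect_equal(spectralPower(out), c(6, 3))

  expect_error(excludeFirstPeak(mk(c(9, 7, 5, 3, 1))), "spectrum exhausted")

  # two-peak spectrum: retained argmax is the second (higher-frequency) peak
  f <- defaultFrequencyGrid(100, oversample = 1)
  p <- 10 * exp(-(f / 0.03)^2) + 3 * exp(-((f - 0.2) / 0.02)^2)
  out <- excludeFirstPeak(new("PowerSpectrum", frequencies = f, power = p))
  expect_lte(abs(frequencies(out)[which.max(spectralPower(out))] - 0.2),
             diff(f)[1])

  # rule is idempotent when the remaining leading run rises into a peak
  again <- excludeFirstPeak(out)
  expect_lt(length(spectralPower(again)), length(spectralPower(out)))
})

test_that("cutoff frequency is the earliest persistently-small frequency", {
  mk <- function(f, p) new("PowerSpectrum", frequencies = f, power = p)
  expect_equal(cutoffFrequency(mk(c(0.1, 0.2, 0.3), c(8, 4, 0)),
                               epsilon = 0.01), 0.3)
  expect_equal(cutoffFrequency(mk(c(0.1, 0.2, 0.3), c(8, 4, 2)),
                               epsilon = 0.01), 0.3)  # fallback: last grid f
  expect_error(cutoffFrequency(mk(c(0.1, 0.2), c(0, 0))), "all-zero")

  # brute-force suffix-scan oracle on random decaying spectra
  set.seed(36)
  for (rep in 1:10) {
    f <- defaultFrequencyGrid(60, oversample = 1)
    p <- exp(-5 * f) * (1 + 0.3 * runif(length(f)))
    sp <- mk(f, p)
    eps <- runif(1, 0.01, 0.3)
    thr <- eps * max(p)
    ok <- which(vapply(seq_along(p),
                       function(k) all(p[k:length(p)] < thr), logical(1)))
    expected <- if (length(ok)) f[ok[1]] else max(f)
    expect_equal(cutoffFrequency(sp, eps), expected)
  }

  # monotone non-increasing in epsilon
  f <- defaultFrequencyGrid(60, oversample = 1)
  p <- exp(-6 * f)
  sp <- mk(f, p)
  cuts <- vapply(c(0.01, 0.05, 0.1, 0.3), function(e)
    cutoffFrequency(sp, e), numeric(1))
  expect_true(all(diff(cuts) <= 1e-12))
})

test_that("spectral features follow their defining arithmetic", {
  f <- (1:2) / 10
  P12 <- new("PowerSpectrum", frequencies = f, power = c(1, 2))
  P23 <- new("PowerSpectrum", frequencies = f, power = c(1, 2))
  feats <- extractSpectralFeatures(P12, P23, excludeFirst = FALSE)
  expect_equal(feats$difference_energy, 0)
  expect_equal(feats$total_volumetric_energy, 5)
  expect_equal(feats$cutoff_frequency, 0.2)

  P23b <- new("PowerSpectrum", frequencies = f, power = c(4, 0.5))
  featsB <- extractSpectralFeatures(P12, P23b, excludeFirst = FALSE)
  expect_equal(featsB$difference_energy, abs(3 - 4.5))
  expect_equal(featsB$total_volumetric_energy, 4 + 1)
})

test_that("consistent stacks give lower difference energy than independent ones", {
  set.seed(37)
  cfg <- phantomConfig(12, 12, roiSize = c(32, 32), contrasts = c(T1C = 2),
                       seed = 41)
  stacks <- phantomStacks(cfg)
  feats <- voccFeatures(stacks)
  de <- split(feats$difference_energy, feats$label)
  expect_lt(wilcox.test(de[["co-deleted"]], de[["non-deleted"]],
                        alternative = "less")$p.value, 0.05)
  tve <- split(feats$total_volumetric_energy, feats$label)
  expect_gt(mean(tve[["co-deleted"]]), mean(tve[["non-deleted"]]))
})
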