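test_that("single-b ADC inverts the mono-exponential decay", {
  s0 <- matrix(1000, 4, 4)
  st <- DWIStack(list(s0, s0), c(0, 800))
  expect_equal(adcValues(computeADC(st, 800)),
               matrix(0, 4, 4))  # no decay -> ADC 0

  st2 <- DWIStack(list(s0, dwiSignal(s0, 800, 1e-3)), c(0, 800))
  expect_equal(adcValues(computeADC(st2, 800))[1, 1], 1e-3,
               tolerance = 1e-12)

  # scale invariance
  st3 <- DWIStack(list(2 * s0, 2 * dwiSignal(s0, 800, 1e-3)), c(0, 800))
  expect_equal(adcValues(computeADC(st3, 800)),
               adcValues(computeADC(st2, 800)))

  expect_error(computeADC(st2, 600), "not present")
  # non-positive signal pixels are masked, not infinite
  sb <- dwiSignal(s0, 800, 1e-3); sb[1, 1] <- -5
  st4 <- DWIStack(list(s0, sb), c(0, 800))
  m <- computeADC(st4, 800)
  expect_false(validMask(m)[1, 1])
  expect_true(all(is.finite(adcValues(m)[validMask(m)])))
})

test_that("multi-b least squares recovers exact and noisy ADC", {
  s0 <- matrix(1000, 20, 25)
  adc <- 1.1e-3
  b <- c(0, 600, 800, 1000)
  st <- DWIStack(lapply(b, function(x) dwiSignal(s0, x, adc)), b)
  fit <- fitADCMultiB(st)
  expect_lt(max(abs(adcValues(fit) - adc)) / adc, 1e-12)

  # two-point stack: identical to the single-b formula
  st2 <- DWIStack(list(s0, dwiSignal(s0, 800, adc)), c(0, 800))
  expect_equal(adcValues(fitADCMultiB(st2)), adcValues(computeADC(st2, 800)),
               tolerance = 1e-12)

  # 500-pixel Monte-Carlo: mean fitted ADC within 2% of truth
  set.seed(17)
  noisy <- lapply(b, function(x)
    dwiSignal(s0, x, adc) + matrix(rnorm(500, 0, 20), 20, 25))
  mfit <- fitADCMultiB(DWIStack(noisy, b))
  expect_lt(abs(mean(adcValues(mfit)[validMask(mfit)]) - adc) / adc, 0.02)
})

test_that("DWIStack validity catches malformed stacks", {
  s0 <- matrix(1, 4, 4)
  expect_error(DWIStack(list(s0, s0), c(600, 800)), "must be 0")
  expect_error(DWIStack(list(s0, s0), c(0, 0)), "increasing")
  expect_s4_class(signalAt(DWIStack(list(s0, s0 / 2), c(0, 800)), 800),
                  "GrayImage")
})

test_that("cohort simulation round-trips ADC exactly at zero noise", {
  coh <- simulateResponseCohort(5, 5, noiseFractions = c(0, 0, 0, 0),
                                seed = 3)
  for (col in c("adc_600", "adc_800", "adc_1000", "adc_fit"))
    expect_lt(max(abs(coh[[col]] - coh$adcTrue)), 1e-10)
})

test_that("cohort simulation is deterministic per seed and class-faithful", {
  a <- simulateResponseCohort(8, 8, seed = 42)
  b <- simulateResponseCohort(8, 8, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a$responder), 8)
  expect_error(simulateResponseCohort(0, 5), ">= 1")
  expect_error(simulateResponseCohort(5, 5, adcSd = 0), "positive")
})
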