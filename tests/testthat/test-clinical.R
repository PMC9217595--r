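test_that("percentages follow the printed half-up, two-decimal convention", {
  expect_equal(proportionPercent(27, 59), 45.76)
  expect_equal(proportionPercent(0, 59), 0)
  expect_equal(proportionPercent(57, 59), 96.61)
  expect_equal(proportionPercent(1, 8), 12.5)
  # half-up, not banker's: 0.125 -> 12.50 would tie at 4 decimals; check an
  # explicit .xx5 case
  expect_equal(proportionPercent(1, 16), 6.25)
  expect_equal(proportionPercent(49, 80), 61.25)
  expect_error(proportionPercent(3, 0), "total")
  expect_error(proportionPercent(5, 4), "count")
})

test_that("chi-square matches hand arithmetic and permutation invariance", {
  tab <- rbind(c(10, 20), c(20, 10))
  res <- chiSquareTest(tab)
  # expected counts are all 15; statistic = 4 * 25/15
  expect_equal(res$statistic, 4 * 25 / 15, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$pValue, pchisq(4 * 25 / 15, 1, lower.tail = FALSE))

  same <- rbind(c(5, 7, 9), c(5, 7, 9))
  res2 <- chiSquareTest(same)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$pValue, 1)

  vom <- loadClinicalFixture("vomiting")
  a <- chiSquareTest(vom)
  b <- chiSquareTest(vom[2:1, rev(seq_len(ncol(vom)))])
  expect_equal(a$statistic, b$statistic)

  expect_error(chiSquareTest(rbind(c(0, 0), c(1, 2))), "zero")
})

test_that("summary t test agrees with a raw-data reconstruction oracle", {
  # equal means: t exactly 0, p exactly 1
  flat <- tTestFromSummary(10, 2, 30, 10, 3, 30)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$pValue, 1)

  cases <- list(c(23.52, 2.04, 59, 16.49, 1.2, 59),
                c(5.1, 1.3, 12, 4.2, 2.1, 17),
                c(-3, 0.5, 25, -2.8, 0.7, 40))
  for (cs in cases) {
    got <- tTestFromSummary(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    x <- samplesWithMoments(cs[1], cs[2], cs[3], seed = 1)
    y <- samplesWithMoments(cs[4], cs[5], cs[6], seed = 2)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$pValue, ref$p.value, tolerance = 1e-9)

    gotW <- tTestFromSummary(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6],
                             pooled = FALSE)
    refW <- t.test(x, y)
    expect_equal(gotW$statistic, unname(refW$statistic), tolerance = 1e-9)
    expect_equal(gotW$df, unname(refW$parameter), tolerance = 1e-9)
  }
  expect_error(tTestFromSummary(1, 0, 10, 2, 1, 10), "deviations")
})

test_that("fixtures carry the published counts with row sums of 59", {
  vom <- loadClinicalFixture("vomiting")
  expect_equal(dim(vom), c(2L, 5L))
  expect_equal(unname(rowSums(vom)), c(59, 59))
  expect_equal(unname(vom["experiment", ]), c(27, 24, 7, 1, 0))
  expect_equal(unname(vom["control", ]), c(7, 12, 20, 11, 9))

  sat <- loadClinicalFixture("satisfaction")
  expect_equal(unname(sat$experiment),
               c(47, 10, 2))
  expect_equal(sum(sat$experiment), 59)
  expect_equal(sat$controlOverallPercent, 81.36)

  dem <- loadClinicalFixture("demographics")
  expect_equal(dem["gender:male", "control"], 37)
  expect_equal(unname(colSums(dem[1:2, ])), c(59, 59))
  expect_equal(unname(colSums(dem[3:5, ])), c(59, 59))
  expect_equal(unname(colSums(dem[6:7, ])), c(59, 59))

  sm <- loadClinicalFixture("summaries")
  expect_true(all(sm$sd > 0))
  expect_true(all(sm$n == 59))
  hamd <- sm[sm$endpoint == "HAMD" & sm$phase == "after", ]
  expect_equal(sort(hamd$mean), c(16.49, 23.52))
})

test_that("percentages round-trip back to fixture counts", {
  vom <- loadClinicalFixture("vomiting")
  for (g in rownames(vom)) for (j in seq_len(ncol(vom))) {
    pct <- proportionPercent(vom[g, j], 59)
    expect_equal(round(59 * pct / 100), vom[g, j])
  }
})
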