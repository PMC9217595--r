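#' Percentage of a count, printed-table convention
#'
#' \code{100 * count / total}, rounded half-up to two decimals — the rounding
#' used throughout the bundled outcome tables.
#'
#' @param count non-negative integer, \code{count <= total}.
#' @param total positive integer.
#' @return Percentage rounded to 2 decimals.
#' @examples
#' proportionPercent(27, 59)  # 45.76
#' @export
proportionPercent <- function(count, total) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(count < 0) || any(count > total))
    stop("count must lie in [0, total]")
  roundHalfUp(100 * count / total, 2L)
}

#' Pearson chi-square test on a contingency table
#'
#' Classical \code{sum((O - E)^2 / E)} with \code{(r-1)(c-1)} degrees of
#' freedom; no continuity correction by default (\code{correct = TRUE}
#' applies Yates for 2 x 2 tables).  Implemented through
#' \code{\link[stats]{chisq.test}}.
#'
#' @param counts matrix of non-negative counts, at least 2 x 2.
#' @param correct apply the Yates continuity correction (2 x 2 only).
#' @return A list with \code{statistic}, \code{df}, \code{pValue} and
#'   \code{method}.
#' @examples
#' chiSquareTest(rbind(c(10, 20), c(20, 10)))
#' @export
chiSquareTest <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("table must be at least 2 x 2")
  if (any(counts < 0)) stop("counts must be non-negative")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    bad <- which(expected == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("expected count is zero in cell (%d, %d)",
                 bad[1], bad[2]))
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       pValue = unname(res$p.value),
       method = if (correct) "Pearson chi-square (Yates)"
                else "Pearson chi-square")
}

#' Two-sample t test from summary statistics
#'
#' Independent-samples Student t test computed from group means, standard
#' deviations and sizes; pooled variance by default, Welch via
#' \code{pooled = FALSE}.  Two-sided p value.
#'
#' @param meanX,sdX,nX first group summary (sd > 0, n >= 2).
#' @param meanY,sdY,nY second group summary.
#' @param pooled use the pooled-variance Student statistic (default) or
#'   Welch's unequal-variance form.
#' @return A list with \code{statistic}, \code{df}, \code{pValue} and
#'   \code{method}.
#' @examples
#' tTestFromSummary(23.52, 2.04, 59, 16.49, 1.2, 59)
#' @export
tTestFromSummary <- function(meanX, sdX, nX, meanY, sdY, nY, pooled = TRUE) {
  if (sdX <= 0 || sdY <= 0) stop("standard deviations must be > 0")
  if (nX < 2 || nY < 2) stop("group sizes must be >= 2")
  if (pooled) {
    sp2 <- ((nX - 1) * sdX^2 + (nY - 1) * sdY^2) / (nX + nY - 2)
    se <- sqrt(sp2 * (1 / nX + 1 / nY))
    df <- nX + nY - 2
    method <- "Two-sample t test (pooled variance)"
  } else {
    vX <- sdX^2 / nX; vY <- sdY^2 / nY
    se <- sqrt(vX + vY)
    df <- (vX + vY)^2 / (vX^2 / (nX - 1) + vY^2 / (nY - 1))
    method <- "Welch two-sample t test"
  }
  tStat <- (meanX - meanY) / se
  list(statistic = tStat, df = df,
       pValue = 2 * stats::pt(-abs(tStat), df), method = method)
}

#' Bundled clinical outcome fixtures
#'
#' Transcriptions of the outcome tables of the emulated two-arm comfort-care
#' trial (59 patients per arm).  Available fixtures:
#' \describe{
#'   \item{vomiting}{2 x 5 contingency matrix of post-chemotherapy vomiting
#'     grades 0-IV by arm.  The source table prints the control degree-IV
#'     share as 15.69\% although 9/59 = 15.25\%; the count (9) is stored and
#'     the printed percentage kept in the raw CSV for reference.}
#'   \item{satisfaction}{experiment-arm satisfaction counts
#'     (very / basically / dissatisfied) plus the control arm's overall
#'     satisfaction, which the source reports only as a percentage.}
#'   \item{demographics}{baseline categorical counts (gender, education,
#'     smoking history) as a category x arm matrix.}
#'   \item{summaries}{data.frame of mean / sd / n summary endpoints (HAMD,
#'     HAMA, quality-of-life subscales, serum tumour markers, age).}
#' }
#'
#' @param name one of "vomiting", "satisfaction", "demographics",
#'   "summaries".
#' @return A matrix, list or data.frame depending on the fixture.
#' @examples
#' loadClinicalFixture("vomiting")
#' @export
loadClinicalFixture <- function(name = c("vomiting", "satisfaction",
                                         "demographics", "summaries")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "DWIdenoise",
                                  mustWork = TRUE)
  switch(name,
    vomiting = {
      d <- utils::read.csv(path("clinical_vomiting.csv"))
      tab <- stats::xtabs(count ~ group + degree, data = d)
      m <- matrix(as.integer(tab), nrow = nrow(tab),
                  dimnames = dimnames(tab))
      m[c("experiment", "control"), ]
    },
    satisfaction = {
      d <- utils::read.csv(path("clinical_satisfaction.csv"))
      exp <- d[d$group == "experiment", ]
      counts <- stats::setNames(as.integer(exp$count), exp$category)
      ctrl <- d[d$group == "control", ]
      list(experiment = counts,
           controlOverallPercent = ctrl$printed_percent[1])
    },
    demographics = {
      d <- utils::read.csv(path("clinical_demographics.csv"))
      m <- cbind(control = d$control, experiment = d$experiment)
      rownames(m) <- paste(d$item, d$category, sep = ":")
      m
    },
    summaries = utils::read.csv(path("clinical_summaries.csv")))
}
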