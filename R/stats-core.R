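#' @title Statistical primitives shared across pipeline stages
#' @description Thin, contract-checked wrappers around the classical tests
#'   used throughout the package (Welch t, Mann-Whitney U, chi-square,
#'   exact binomial, Spearman rank correlation, two-way ANOVA) plus
#'   Benjamini-Hochberg adjustment. Every wrapper returns a uniform
#'   \code{TestResult} list so downstream code never touches \code{htest}
#'   internals, and degenerate inputs (zero-variance samples, constant
#'   vectors) follow documented contracts instead of erroring deep inside
#'   \code{stats}.
#' @name stats-core
NULL

.match_alternative <- function(alternative) {
  alternative <- match.arg(alternative, c("two_sided", "greater", "less"))
  c(two_sided = "two.sided", greater = "greater", less = "less")[[alternative]]
}

#' Construct a TestResult
#'
#' Uniform container for a hypothesis-test outcome.
#'
#' @param statistic test statistic (finite for non-degenerate input).
#' @param p_value p-value in \[0, 1\].
#' @param df degrees of freedom, or \code{NA} where undefined.
#' @param alternative one of \code{"two_sided"}, \code{"greater"}, \code{"less"}.
#' @param method label of the underlying test.
#' @param estimate optional point estimate (e.g. Spearman's rho).
#' @param degenerate flag set when a documented degenerate contract fired.
#' @return A list of class \code{"TestResult"}.
#' @export
TestResult <- function(statistic, p_value, df = NA_real_,
                       alternative = "two_sided", method = "",
                       estimate = NULL, degenerate = FALSE) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         df = unname(df), alternative = alternative, method = method,
         estimate = estimate, degenerate = degenerate),
    class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.4g (%s)%s\n",
              x$method, x$statistic,
              ifelse(is.na(x$df), "NA", format(x$df, digits = 4)),
              x$p_value, x$alternative,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom.
#' When both samples have zero variance the test is degenerate: equal means
#' give statistic 0 and p = 1; unequal means give an infinite statistic and
#' p = 0 (the data carry unbounded evidence under the normal model).
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param alternative \code{"two_sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return A \code{\link{TestResult}}.
#' @examples
#' welchTTest(c(1, 2, 3), c(4, 5, 6))
#' @export
welchTTest <- function(x, y, alternative = "two_sided") {
  if (length(x) < 2L || length(y) < 2L)
    stop("welchTTest: each sample needs at least 2 values")
  if (anyNA(x) || anyNA(y)) stop("welchTTest: NA values not allowed")
  alt <- .match_alternative(alternative)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    d <- mean(x) - mean(y)
    if (d == 0)
      return(TestResult(0, 1, NA_real_, alternative, "welch_t",
                        degenerate = TRUE))
    p <- switch(alt, two.sided = 0,
                greater = if (d > 0) 0 else 1,
                less = if (d < 0) 0 else 1)
    return(TestResult(sign(d) * Inf, p, NA_real_, alternative, "welch_t",
                      degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, alternative = alt, var.equal = FALSE)
  TestResult(ht$statistic, ht$p.value, ht$parameter, alternative, "welch_t")
}

#' Row-wise Welch t-tests for two sample matrices
#'
#' Vectorised Welch test across the rows of two matrices sharing row order
#' (genes or lipids by samples). Degenerate rows (zero variance in both
#' groups) follow the \code{\link{welchTTest}} contract.
#'
#' @param mx,my numeric matrices with identical row counts; columns are the
#'   samples of each group (>= 2 per group).
#' @return A data.frame with columns \code{statistic}, \code{df},
#'   \code{p_value}, \code{mean_diff} (row mean of \code{mx} minus
#'   \code{my}) and \code{degenerate}. p-values are two-sided.
#' @export
rowWelchTest <- function(mx, my) {
  mx <- as.matrix(mx); my <- as.matrix(my)
  if (nrow(mx) != nrow(my)) stop("rowWelchTest: row counts differ")
  nx <- ncol(mx); ny <- ncol(my)
  if (nx < 2L || ny < 2L) stop("rowWelchTest: need >= 2 columns per group")
  m1 <- rowMeans(mx); m2 <- rowMeans(my)
  v1 <- rowSums((mx - m1)^2) / (nx - 1)
  v2 <- rowSums((my - m2)^2) / (ny - 1)
  se2 <- v1 / nx + v2 / ny
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / nx)^2 / (nx - 1) + (v2 / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  degen <- se2 == 0
  if (any(degen)) {
    d <- (m1 - m2)[degen]
    stat[degen] <- ifelse(d == 0, 0, sign(d) * Inf)
    p[degen] <- ifelse(d == 0, 1, 0)
    df[degen] <- NA_real_
  }
  data.frame(statistic = stat, df = df, p_value = p,
             mean_diff = m1 - m2, degenerate = degen)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1, input order
#' preserved.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return A list with \code{raw}, \code{adjusted} and
#'   \code{method = "benjamini_hochberg"}.
#' @export
bhAdjust <- function(p) {
  if (length(p) && (anyNA(p) || any(p < 0 | p > 1)))
    stop("bhAdjust: p-values must lie in [0, 1]")
  list(raw = p, adjusted = stats::p.adjust(p, method = "BH"),
       method = "benjamini_hochberg")
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The p-value uses the exact
#' permutation distribution for n < 10 without ties and the t-approximation
#' otherwise. A constant input vector yields a flagged degenerate result
#' (rho undefined) rather than an error.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param alternative alternative hypothesis.
#' @return A \code{\link{TestResult}} whose \code{estimate} is rho.
#' @export
spearmanCor <- function(x, y, alternative = "two_sided") {
  if (length(x) != length(y)) stop("spearmanCor: lengths differ")
  n <- length(x)
  if (n < 3L) stop("spearmanCor: need at least 3 pairs")
  alt <- .match_alternative(alternative)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(TestResult(NA_real_, NA_real_, NA_real_, alternative,
                      "spearman", estimate = NA_real_, degenerate = TRUE))
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = alt,
                    exact = n < 10L && !has_ties))
  TestResult(ht$statistic, ht$p.value, NA_real_, alternative, "spearman",
             estimate = unname(ht$estimate))
}

#' Exact binomial test
#'
#' Exact tail probability by summation of the binomial mass function.
#' Boundary null rates (0 or 1) are rejected; callers that derive rates
#' empirically must floor them first (see \code{\link{teFamilyEnrichment}}).
#'
#' @param k observed successes, \code{0 <= k <= n}.
#' @param n number of trials.
#' @param p0 null success probability, strictly inside (0, 1).
#' @param alternative alternative hypothesis.
#' @return A \code{\link{TestResult}} (statistic is \code{k}).
#' @export
binomialTest <- function(k, n, p0, alternative = "two_sided") {
  if (k < 0 || k > n) stop("binomialTest: need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1)
    stop("binomialTest: p0 must lie strictly inside (0, 1)")
  alt <- .match_alternative(alternative)
  ht <- stats::binom.test(k, n, p = p0, alternative = alt)
  TestResult(k, ht$p.value, NA_real_, alternative, "binomial_exact",
             estimate = k / n)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson statistic (no Yates continuity correction) with one
#' degree of freedom. Tables with a zero margin are rejected.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return A \code{\link{TestResult}}.
#' @export
chiSquare2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("chiSquare2x2: table must be 2x2")
  if (any(tab < 0)) stop("chiSquare2x2: negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chiSquare2x2: zero margin")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  TestResult(ht$statistic, ht$p.value, ht$parameter, "two_sided",
             "chi_square_pearson")
}

#' Mann-Whitney U test
#'
#' Rank-sum test: exact when the combined sample size does not exceed
#' \code{exact_threshold} and no ties are present, otherwise the normal
#' approximation with tie correction.
#'
#' @param x,y non-empty numeric samples.
#' @param alternative alternative hypothesis.
#' @param exact_threshold combined-n switch point for the exact computation.
#' @return A \code{\link{TestResult}} (statistic is U for \code{x}).
#' @export
mannWhitneyU <- function(x, y, alternative = "two_sided",
                         exact_threshold = 20L) {
  if (!length(x) || !length(y)) stop("mannWhitneyU: empty sample")
  alt <- .match_alternative(alternative)
  use_exact <- (length(x) + length(y)) <= exact_threshold
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = use_exact))
  if (is.na(ht$p.value))  # complete ties: no evidence either way
    return(TestResult(ht$statistic, 1, NA_real_, alternative,
                      "mann_whitney_u", degenerate = TRUE))
  TestResult(ht$statistic, ht$p.value, NA_real_, alternative,
             "mann_whitney_u")
}

#' Two-way ANOVA with type-II sums of squares
#'
#' Crossed two-factor analysis of variance on a (near-)balanced design.
#' Type-II sums of squares are used (via \code{car::Anova}) so main effects
#' are tested after the other main effect regardless of mild imbalance.
#' The interaction requires at least one cell with >= 2 observations; with
#' an empty cell the interaction is flagged undefined and an additive model
#' is fitted for the main effects. A response with zero variance returns
#' F = 0, p = 1 for every term (degenerate contract).
#'
#' @param value numeric response.
#' @param factor_a,factor_b factor labels, >= 2 levels each.
#' @return A list with \code{TestResult}s \code{factor_a}, \code{factor_b},
#'   \code{interaction} (the latter \code{NULL}-statistic and flagged when
#'   undefined).
#' @export
twoWayAnova <- function(value, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("twoWayAnova: each factor needs >= 2 levels")
  if (length(value) != length(a) || length(value) != length(b))
    stop("twoWayAnova: lengths differ")
  if (stats::var(value) == 0) {
    r <- TestResult(0, 1, NA_real_, "two_sided", "two_way_anova_typeII",
                    degenerate = TRUE)
    return(list(factor_a = r, factor_b = r, interaction = r))
  }
  cells <- table(a, b)
  interaction_ok <- all(cells > 0) && any(cells >= 2)
  d <- data.frame(value = value, a = a, b = b)
  fit <- if (interaction_ok) stats::lm(value ~ a * b, data = d)
         else stats::lm(value ~ a + b, data = d)
  an <- car::Anova(fit, type = 2)
  row_of <- function(term) {
    i <- match(term, rownames(an))
    if (is.na(i) || is.na(an[i, "F value"]))
      return(TestResult(NA_real_, NA_real_, NA_real_, "two_sided",
                        "two_way_anova_typeII", degenerate = TRUE))
    TestResult(an[i, "F value"], an[i, "Pr(>F)"], an[i, "Df"],
               "two_sided", "two_way_anova_typeII")
  }
  list(factor_a = row_of("a"), factor_b = row_of("b"),
       interaction = if (interaction_ok) row_of("a:b")
                     else TestResult(NA_real_, NA_real_, NA_real_,
                                     "two_sided", "two_way_anova_typeII",
                                     degenerate = TRUE))
}
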