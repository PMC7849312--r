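#' Fisher's exact test for a 2x2 table with sample odds ratio
#'
#' Two-sided exact test on a 2x2 contingency table
#' \code{rbind(c(a, b), c(c, d))} with fixed margins. The two-sided p-value is
#' the sum of hypergeometric probabilities of all tables (with the observed
#' margins) that are no more probable than the observed one — the
#' probability-ordering convention. The reported odds ratio is the sample
#' (cross-product) estimate \eqn{ad/bc}, the quantity conventionally colour-coded
#' in gene-set overlap heat maps, not the conditional MLE.
#'
#' @param a,b,c,d Non-negative integer cell counts: \code{a} = in both
#'   classifications, \code{b}, \code{c} = in one only, \code{d} = in neither.
#' @param alternative \code{"two.sided"} (probability ordering, default) or
#'   \code{"doubled"} (twice the smaller one-sided tail, capped at 1).
#' @return List with \code{p} and \code{odds_ratio} (\code{Inf} when
#'   \code{b*c == 0} and \code{a*d > 0}; \code{NA} when both products are 0).
#' @examples
#' fisher_exact(2, 0, 0, 2)$p          # 1/3
#' fisher_exact(4, 2, 2, 4)$odds_ratio # 4
#' @export
fisher_exact <- function(a, b, c, d, alternative = c("two.sided", "doubled")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("table cells must be non-negative integers")
  }
  n <- sum(cells)
  if (n == 0) stop("all-zero 2x2 table")
  m1 <- a + b   # row 1 margin
  k  <- a + c   # column 1 margin
  lo <- max(0L, k - (n - m1))
  hi <- min(k, m1)
  support <- lo:hi
  probs <- dhyper(support, m1, n - m1, k)
  p_obs <- dhyper(a, m1, n - m1, k)
  if (alternative == "two.sided") {
    # relative tolerance guards against ties broken by floating-point noise
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(probs[support <= a])
    upper <- sum(probs[support >= a])
    p <- min(1, 2 * min(lower, upper))
  }
  ad <- as.numeric(a) * d
  bc <- as.numeric(b) * c
  or <- if (bc > 0) ad / bc else if (ad > 0) Inf else NA_real_
  list(p = min(1, p), odds_ratio = or)
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over [stats::p.adjust()] exposing the three procedures used
#' throughout the pipeline: Benjamini-Hochberg step-up (gene-set overlaps,
#' differential testing), Holm step-down (granule ratio comparisons) and
#' Bonferroni (metagene bin tests). Input order is preserved and adjusted
#' values are capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed, passed through).
#' @param method One of \code{"BH"}, \code{"Holm"}, \code{"Bonferroni"}.
#' @param m Number of comparisons; defaults to \code{length(p)}. Useful for
#'   Bonferroni with a fixed factor (e.g. 10 gene-length bins).
#' @return Numeric vector of adjusted p-values, same order as input.
#' @export
adjust_pvalues <- function(p, method = c("BH", "Holm", "Bonferroni"),
                           m = length(p)) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = c(BH = "BH", Holm = "holm", Bonferroni = "bonferroni")[method],
           n = max(m, sum(ok)))
}

#' Two-sample t-test (unpaired)
#'
#' Classical unpaired two-sample t-test, equal-variance by default (the
#' convention behind "unpaired t-test (two-tailed)" in figure legends), with a
#' Welch option.
#'
#' @param x,y Numeric vectors, length >= 2 each.
#' @param var_equal Pool variances (default TRUE); FALSE gives Welch.
#' @param two_tailed Two-sided p (default); FALSE gives the upper-tail p for
#'   \code{mean(x) > mean(y)}.
#' @return List with \code{t}, \code{df} and \code{p} (\code{NA} when both
#'   samples are constant).
#' @export
t_test2 <- function(x, y, var_equal = TRUE, two_tailed = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per group")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  }
  ht <- t.test(x, y, var.equal = var_equal,
               alternative = if (two_tailed) "two.sided" else "greater")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided unpaired Mann-Whitney/Wilcoxon rank-sum test. The U statistic
#' uses midranks for ties. The p-value is exact by enumeration when
#' \code{length(x) + length(y) <= exact_max} and there are no ties, and a
#' tie-corrected normal approximation otherwise.
#'
#' @param x,y Numeric vectors, non-empty.
#' @param exact_max Largest combined sample size for exact enumeration.
#' @return List with \code{U} (for sample \code{x}), \code{p} and
#'   \code{exact} flag.
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && (length(x) + length(y)) <= exact_max
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = FALSE,
                alternative = "two.sided")
  )
  list(U = U, p = unname(ht$p.value), exact = use_exact)
}

#' Two-proportion z-test (pooled)
#'
#' Tests equality of two binomial proportions with the pooled-variance normal
#' statistic
#' \deqn{z = (p_1 - p_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)},}
#' where \eqn{\hat p = (x_1+x_2)/(n_1+n_2)}; two-sided p from the standard
#' normal.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with \code{z} and \code{p} (both \code{NA} when the pooled
#'   proportion is 0 or 1, where the statistic is undefined).
#' @examples
#' two_prop_z(8, 10, 2, 10)$z  # ~2.683
#' @export
two_prop_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  phat <- (x1 + x2) / (n1 + n2)
  if (phat <= 0 || phat >= 1) {
    return(list(z = NA_real_, p = NA_real_))
  }
  se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  z <- (x1 / n1 - x2 / n2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Transposon reversion frequency (zero-class estimator)
#'
#' Estimates the per-animal excision frequency from plate counts by the
#' Poisson zero-class method: with \code{T} plates scored, \code{R} of them
#' showing at least one revertant and \code{N} animals per plate,
#' \deqn{f = -\ln[(T - R)/T] / N.}
#' \code{R = 0} gives \code{f = 0}; \code{R = T} leaves the zero class empty
#' and the frequency is not estimable (error).
#'
#' @param T_plates Total number of plates scored.
#' @param R_revertant Number of plates with revertants.
#' @param N_worms Number of worms per plate (default 10000, the population of
#'   a starved plate).
#' @return Estimated frequency per worm (numeric scalar).
#' @examples
#' reversion_frequency(2, 1, 10000) # log(2)/10000
#' @export
reversion_frequency <- function(T_plates, R_revertant, N_worms = 10000) {
  stopifnot(T_plates > 0, N_worms > 0, R_revertant >= 0)
  if (R_revertant > T_plates) stop("R cannot exceed T")
  if (R_revertant == T_plates) {
    stop("all plates reverted: zero class empty, frequency not estimable")
  }
  -log((T_plates - R_revertant) / T_plates) / N_worms
}

#' Reversion frequencies from a plate-count table
#'
#' Applies [reversion_frequency()] row-wise to a table of plate counts.
#' Rows with \code{R == T} get \code{NA} with a flag rather than an error so
#' a mixed table can still be summarized.
#'
#' @param tbl Data frame with columns \code{genotype}, \code{T}, \code{R},
#'   \code{N} (extra columns preserved).
#' @return The input with columns \code{f} and \code{estimable} appended.
#' @export
reversion_table <- function(tbl) {
  stopifnot(all(c("genotype", "T", "R", "N") %in% names(tbl)))
  tbl$estimable <- tbl$R < tbl$T
  tbl$f <- ifelse(
    tbl$estimable,
    mapply(function(T, R, N) reversion_frequency(T, R, N), tbl$T,
           pmin(tbl$R, tbl$T - 1L), tbl$N),
    NA_real_
  )
  tbl$f[tbl$R == 0] <- 0
  tbl
}
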