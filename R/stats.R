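#' Exact two-sided binomial test p-value
#'
#' Tests whether `k` successes out of `n` trials are compatible with success
#' probability `p0` (default 0.5, the homoeolog 1:1 null).  The two-sided
#' p-value is computed by the minimum-likelihood rule: the sum of binomial
#' probabilities over all outcomes no more probable than the observed one
#' (with a small relative tolerance so ties are included despite floating
#' point).  At `p0 = 0.5` this coincides with doubling the smaller tail.
#'
#' All three arguments are recycled, so vectors of counts can be tested in
#' one call.
#'
#' @param k integer vector, number of successes (0 <= k <= n).
#' @param n integer vector, number of trials (>= 1).
#' @param p0 null success probability in (0, 1).
#' @return numeric vector of p-values in \[0, 1\].
#' @examples
#' binom_exact_two_sided(8, 10)            # 0.109375
#' binom_exact_two_sided(c(10, 0), 20)
#' @export
binom_exact_two_sided <- function(k, n, p0 = 0.5) {
  m <- max(length(k), length(n), length(p0))
  k <- rep_len(as.numeric(k), m)
  n <- rep_len(as.numeric(n), m)
  p0 <- rep_len(as.numeric(p0), m)
  if (any(n < 1, na.rm = TRUE)) stop("binomial test undefined for n = 0")
  if (any(k < 0 | k > n, na.rm = TRUE)) stop("k must satisfy 0 <= k <= n")
  vapply(seq_len(m), function(i) {
    d <- stats::dbinom(0:n[i], n[i], p0[i])
    p <- sum(d[d <= d[k[i] + 1] * (1 + 1e-07)])
    min(p, 1)
  }, numeric(1))
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Computes the chi-square statistic with continuity correction for the 2x2
#' table \code{rbind(c(a, b), c(c, d))}:
#' `N * (|ad - bc| - N/2)^2 / (r1 * r2 * c1 * c2)`, with the continuity
#' term floored at zero, and its p-value from the chi-square distribution
#' with one degree of freedom.  This is the ratio-change test used to
#' compare allele proportions between two samples (it is algebraically the
#' Yates-corrected two-proportion test).
#'
#' Tables with a zero row or column margin are untestable and yield
#' `NA` statistic and p-value.
#'
#' @param a,b,c,d non-negative counts; vectors are recycled, so many tables
#'   can be tested at once.  Rows are (a, b) and (c, d).
#' @return data.frame with columns `statistic` and `p`.
#' @examples
#' yates_chi2_2x2(30, 10, 10, 30)   # statistic 18.05
#' yates_chi2_2x2(1, 0, 0, 1)       # correction floors the statistic at 0
#' @export
yates_chi2_2x2 <- function(a, b, c, d) {
  m <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), m); b <- rep_len(as.numeric(b), m)
  c <- rep_len(as.numeric(c), m); d <- rep_len(as.numeric(d), m)
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) stop("counts must be >= 0")
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  testable <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  stat <- rep(NA_real_, m)
  delta <- pmax(abs(a * d - b * c) - N / 2, 0)
  stat[testable] <- (N * delta^2 / (r1 * r2 * c1 * c2))[testable]
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  data.frame(statistic = stat, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of a vector of raw p-values to q-values, in the
#' original input order.  `NA` p-values stay `NA` and are excluded from the
#' family size.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic Kolmogorov distribution (no exact small-sample
#' correction), which is appropriate at gene-scale sample sizes.
#'
#' @param x,y non-empty numeric vectors of finite values.
#' @return list with elements `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' Hypergeometric term enrichment
#'
#' For each term in `term_map`, tests whether the study set is enriched for
#' the term's genes relative to the population, with the upper-tail
#' hypergeometric probability of observing at least the realised overlap.
#' q-values come from [bh_adjust()] across all terms with at least one
#' population gene.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population character vector of population gene ids.
#' @param term_map named list: term id -> character vector of gene ids.
#' @return data.frame with one row per term kept: `term`, `k` (study hits),
#'   `K` (population genes in term), `n` (study size), `N` (population
#'   size), `p`, `q`.
#' @export
hypergeom_enrichment <- function(study, population, term_map) {
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  if (!all(study %in% population))
    stop("study genes must be a subset of the population")
  N <- length(population)
  n <- length(study)
  rows <- lapply(names(term_map), function(term) {
    genes <- intersect(unique(as.character(term_map[[term]])), population)
    K <- length(genes)
    if (K == 0L) return(NULL)
    k <- length(intersect(study, genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0)))
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Log2 allelic ratio
#'
#' `log2((n_count + pseudocount) / (i_count + pseudocount))`.  The
#' pseudocount (default 0.5) keeps genes with a zero count finite; it is
#' used only for ratio displays, never inside the tests, which operate on
#' raw counts.  Returns `NA` when both counts and the pseudocount are zero.
#'
#' @param n_count,i_count non-negative counts (vectors recycled).
#' @param pseudocount non-negative offset added to both counts.
#' @return numeric vector of log2 ratios.
#' @export
log2_allelic_ratio <- function(n_count, i_count, pseudocount = 0.5) {
  if (any(n_count < 0 | i_count < 0, na.rm = TRUE)) stop("counts must be >= 0")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  num <- n_count + pseudocount
  den <- i_count + pseudocount
  out <- log2(num / den)
  out[num == 0 & den == 0] <- NA_real_
  out
}

#' Percentage of a count relative to a total
#'
#' The summary-report arithmetic used for every count-plus-percentage pair
#' the pipeline prints: `round(100 * count / total, digits)`.
#'
#' @param count numeric vector of counts.
#' @param total denominator (single number or vector recycled).
#' @param digits decimal places (default 2).
#' @return numeric vector of percentages.
#' @export
count_percentage <- function(count, total, digits = 2) {
  if (any(total <= 0)) stop("total must be positive")
  round(100 * count / total, digits)
}
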