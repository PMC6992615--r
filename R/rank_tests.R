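#' Wilcoxon signed-rank test with exact small-sample p-value
#'
#' Paired two-sided test. Absolute differences receive mid-ranks (ties
#' averaged); zero differences are dropped by default (Wilcoxon's original
#' rule) or kept and ranked (Pratt's rule). For \code{m <= exact_max}
#' non-zero pairs the exact null distribution of the positive-rank sum is
#' obtained by full enumeration of all \eqn{2^m} sign assignments (computed
#' as a subset-sum convolution, which enumerates the same distribution); the
#' two-sided p doubles the smaller tail, capped at 1. A normal approximation
#' with tie correction is always reported alongside.
#'
#' @param x,y Paired observations (\code{y = NULL}: \code{x} holds
#'   differences).
#' @param zero_method \code{"wilcox"} (drop zeros) or \code{"pratt"}.
#' @param exact_max Largest m for which the exact enumeration is used.
#' @param correct Continuity correction for the normal approximation.
#' @return Object of class \code{"rank_test"}: statistic (positive-rank sum
#'   W+), \code{p_exact} (NA when not enumerated), \code{p_approx},
#'   \code{p_value} (exact when available), \code{n} (pairs used),
#'   \code{exact} flag.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 zero_method = c("wilcox", "pratt"),
                                 exact_max = 20, correct = TRUE) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[is.finite(d)]
  if (sum(d != 0) < 2) stop("need at least 2 non-zero paired differences")
  if (zero_method == "wilcox") d <- d[d != 0]
  r <- rank(abs(d))
  if (zero_method == "pratt") {
    w_plus <- sum(r[d > 0])
    r <- r[d != 0]
    d <- d[d != 0]
  } else {
    w_plus <- sum(r[d > 0])
  }
  m <- length(d)

  # exact: distribution of W+ over all 2^m sign vectors, via subset-sum
  # convolution on doubled (integer) mid-ranks
  p_exact <- NA_real_
  exact <- m <= exact_max
  if (exact) {
    r2 <- round(2 * r)
    counts <- c(1, numeric(sum(r2)))
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    tot <- 2^m
    w2 <- round(2 * w_plus)
    p_lo <- sum(counts[seq_len(w2 + 1)]) / tot
    p_hi <- sum(counts[(w2 + 1):length(counts)]) / tot
    p_exact <- min(1, 2 * min(p_lo, p_hi))
  }

  mu <- m * (m + 1) / 4
  ties <- table(r)
  sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  z <- w_plus - mu
  if (correct) z <- z - sign(z) * 0.5
  z <- if (sig2 > 0) z / sqrt(sig2) else 0
  p_approx <- min(1, 2 * stats::pnorm(-abs(z)))

  structure(list(method = "Wilcoxon signed-rank test",
                 statistic = c(W_plus = w_plus),
                 p_exact = p_exact, p_approx = p_approx,
                 p_value = if (exact) p_exact else p_approx,
                 n = m, exact = exact),
            class = "rank_test")
}

#' Mann-Whitney U test with exact small-sample p-value
#'
#' Unpaired two-sided test on mid-ranks. For total \code{n <= exact_max_total}
#' the exact permutation distribution of U is obtained by enumerating all
#' \code{choose(n, n_a)} group labelings; the two-sided p doubles the smaller
#' tail, capped at 1. A tie-corrected normal approximation is always
#' reported alongside.
#'
#' @param a,b Numeric samples.
#' @param exact_max_total Largest total n for which enumeration is used.
#' @param correct Continuity correction for the normal approximation.
#' @return Object of class \code{"rank_test"} (statistic U of group
#'   \code{a}).
#' @export
mann_whitney_u <- function(a, b, exact_max_total = 20, correct = TRUE) {
  a <- as.numeric(a[is.finite(a)]); b <- as.numeric(b[is.finite(b)])
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2

  p_exact <- NA_real_
  exact <- n <= exact_max_total
  if (exact) {
    combos <- utils::combn(n, na)
    rs <- colSums(matrix(r[combos], nrow = na))
    us <- rs - na * (na + 1) / 2
    eps <- 1e-9
    p_lo <- mean(us <= u + eps)
    p_hi <- mean(us >= u - eps)
    p_exact <- min(1, 2 * min(p_lo, p_hi))
  }

  mu <- na * nb / 2
  ties <- table(r)
  sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- u - mu
  if (correct) z <- z - sign(z) * 0.5
  z <- if (sig2 > 0) z / sqrt(sig2) else 0
  p_approx <- min(1, 2 * stats::pnorm(-abs(z)))

  structure(list(method = "Mann-Whitney U test",
                 statistic = c(U = u),
                 p_exact = p_exact, p_approx = p_approx,
                 p_value = if (exact) p_exact else p_approx,
                 n = c(n_a = na, n_b = nb), exact = exact),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s\n  %s = %g, n = %s\n  p = %.4g (%s)",
              x$method, names(x$statistic), x$statistic,
              paste(x$n, collapse = "+"),
              x$p_value, if (x$exact) "exact enumeration" else "normal approx."))
  if (x$exact) cat(sprintf("; normal approx. p = %.4g", x$p_approx))
  cat("\n")
  invisible(x)
}

#' Mean and standard error summary of a cohort table
#'
#' Column means and standard errors (sample SD / sqrt(n), n = non-missing
#' count), as printed in per-case clinical tables.
#'
#' @param df Data frame of per-case rows.
#' @param columns Columns to summarize; default: all numeric columns except
#'   \code{"case"}.
#' @param digits Rounding for the formatted \code{mean_se} string.
#' @return Data frame: column, n, mean, se, and formatted \code{mean_se}.
#' @export
cohort_summary <- function(df, columns = NULL, digits = 1) {
  if (is.null(columns))
    columns <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "case")
  rows <- lapply(columns, function(cc) {
    v <- df[[cc]]
    if (is.null(v)) stop("no such column: ", cc)
    if (!is.numeric(v)) stop("non-numeric column '", cc, "'")
    bad <- which(!is.finite(v) & !is.na(v))
    if (length(bad)) stop("non-numeric cell in column '", cc, "', row ", bad[1])
    v <- v[!is.na(v)]
    if (length(v) < 2) stop("column '", cc, "' has fewer than 2 values")
    m <- mean(v)
    se <- stats::sd(v) / sqrt(length(v))
    data.frame(column = cc, n = length(v), mean = m, se = se,
               mean_se = sprintf("%.*f ± %.*f", digits, m, digits, se),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
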