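# Shared statistical tests and the LUMIER hit filter.

#' Filter LUMIER screen hits
#'
#' Selects preys whose luminescence intensity ratio reaches the threshold in
#' *both* replicate screens (inclusive: a LIR of exactly 3 in both passes
#' the default filter). Row order is preserved; rows with missing LIRs are
#' rejected with a warning.
#'
#' @param table Tibble with columns `prey`, `lir_rep1`, `lir_rep2`.
#' @param threshold Hit threshold (default 3).
#' @return Character vector of hit prey names.
#' @export
filter_lumier_hits <- function(table, threshold = 3) {
  assert_cols(table, c("prey", "lir_rep1", "lir_rep2"), "LUMIER table")
  threshold <- assert_number(threshold, "threshold")
  bad <- !is.finite(table$lir_rep1) | !is.finite(table$lir_rep2)
  if (any(bad)) {
    warn(sprintf("%d row(s) with missing LIR values rejected", sum(bad)))
    table <- table[!bad, ]
  }
  assert_that(all(table$lir_rep1 >= 0) && all(table$lir_rep2 >= 0),
    "LIR values must be non-negative")
  table$prey[table$lir_rep1 >= threshold & table$lir_rep2 >= threshold]
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with Welch–Satterthwaite degrees of
#' freedom, the comparison used for ciliation percentages, flow statistics
#' and similar group means. Both groups need at least two observations;
#' otherwise missing values are returned with a warning.
#'
#' @param a,b Numeric vectors.
#' @return A list with `t`, `df`, `p_value`.
#' @examples
#' welch_t_test(c(10, 12, 11), c(20, 22, 21))
#' @export
welch_t_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    warn("Welch t-test needs at least 2 observations per group; returning NA")
    return(list(t = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: both groups constant
    eq <- mean(a) == mean(b)
    return(list(t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
      df = length(a) + length(b) - 2, p_value = if (eq) 1 else 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = unname(ht$p.value))
}

#' Mann–Whitney U test
#'
#' Rank-sum comparison of two samples. For tie-free data with
#' `min(n_a, n_b) <= 8` the two-sided p-value is exact, from full
#' enumeration of all rank assignments; otherwise the normal approximation
#' with tie and continuity corrections is used. `U` counts pairs where a
#' value of `a` exceeds one of `b` (ties count 1/2).
#'
#' @param a,b Non-empty numeric vectors.
#' @return A list with `U`, `p_value`, and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  assert_that(length(a) >= 1 && length(b) >= 1, "both samples must be non-empty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  has_ties <- any(duplicated(pooled))

  if (!has_ties && min(na, nb) <= 8) {
    # exact: enumerate all C(na+nb, na) rank assignments of sample a
    combos <- utils::combn(na + nb, na)
    u_all <- colSums(combos) - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
    return(list(U = u, p_value = p, method = "exact"))
  }
  n <- na + nb
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
  if (sigma == 0) {
    return(list(U = u, p_value = 1, method = "normal_approx"))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sigma # continuity correction
  if (u == mu) z <- 0
  list(U = u, p_value = min(1, 2 * pnorm(-abs(z))), method = "normal_approx")
}
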