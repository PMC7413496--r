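# Statistical tests used by the comparison stages: Welch's t-test with
# Bonferroni correction across refractive-index conditions, and the
# Friedman test with Dwass-Steel-Critchlow-Fligner (DSCF) all-pairs
# post-hoc comparisons across imaging conditions blocked by plane.

new_pairwise_result <- function(statistic, df, p_value, method,
                                adjusted_p = NULL) {
  structure(list(statistic = statistic, degrees_of_freedom = df,
                 p_value = p_value, adjusted_p = adjusted_p,
                 method = method),
            class = "pairwise_test")
}

#' @export
print.pairwise_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g%s\n", x$method, x$statistic,
              if (!is.null(x$degrees_of_freedom) &&
                  is.finite(x$degrees_of_freedom))
                sprintf(", df = %.4g", x$degrees_of_freedom) else "",
              x$p_value,
              if (!is.null(x$adjusted_p))
                sprintf(" (adjusted %.4g)", x$adjusted_p) else ""))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom and
#' a two-sided p-value.
#'
#' @param x,y Numeric samples, each of size at least 2, with nonzero
#'   variance in at least one.
#' @return A `pairwise_test` with `statistic` (t), `degrees_of_freedom`
#'   and `p_value`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("degenerate samples: both variances are zero", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = FALSE)
  new_pairwise_result(unname(ht$statistic), unname(ht$parameter),
                      ht$p.value, "Welch's t-test")
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of comparisons and caps at 1.
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @param m Number of comparisons (defaults to `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, p_values * m)
}

#' Friedman rank test for a randomised block design
#'
#' Within-block average ranks with the tie-corrected chi-square statistic
#' \deqn{Q = (k - 1) \sum_j (R_j - n(k+1)/2)^2 / (\sum_{ij} r_{ij}^2 - n k (k+1)^2 / 4)}
#' referred to a chi-square distribution with k - 1 degrees of freedom.
#' A design in which every block is entirely tied yields statistic 0 and
#' p = 1 (not an error).
#'
#' @param design Numeric matrix, rows = blocks (e.g. the 21 planes of a
#'   stack), columns = treatments (conditions); at least 2 of each, no
#'   missing cells.
#' @return A `pairwise_test` with the chi-square statistic, df = k - 1 and
#'   the asymptotic p-value.
#' @export
friedman_test <- function(design) {
  if (!is.matrix(design) || nrow(design) < 2 || ncol(design) < 2 ||
      any(!is.finite(design)))
    stop("design must be a complete numeric matrix with >= 2 blocks and >= 2 treatments",
         call. = FALSE)
  n <- nrow(design); k <- ncol(design)
  r <- t(apply(design, 1, rank))
  Rj <- colSums(r)
  denom <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (denom <= 0)
    return(new_pairwise_result(0, k - 1, 1, "Friedman test"))
  stat <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / denom
  new_pairwise_result(stat, k - 1,
                      stats::pchisq(stat, k - 1, lower.tail = FALSE),
                      "Friedman test")
}

#' Dwass-Steel-Critchlow-Fligner all-pairs comparison test
#'
#' For each pair of groups, the Wilcoxon rank-sum statistic is computed on
#' that pair alone (average ranks for ties, tie-corrected variance),
#' standardised, and referred to the studentized-range distribution with
#' `k` groups and infinite degrees of freedom:
#' `p = P(Q >= sqrt(2) |W*|)`.
#'
#' @param groups List of k >= 2 numeric samples, each of size >= 2.
#' @return An object of class `dscf_test` with symmetric matrices
#'   `statistic` (standardised W*) and `p_value`, and a tidy `pairs`
#'   data.frame.
#' @export
dscf_all_pairs <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) < 2))
    stop("every group needs at least 2 observations", call. = FALSE)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  W <- matrix(0, k, k, dimnames = list(labels, labels))
  P <- matrix(1, k, k, dimnames = list(labels, labels))
  pairs <- NULL
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    xi <- groups[[i]]; xj <- groups[[j]]
    ni <- length(xi); nj <- length(xj); N <- ni + nj
    r <- rank(c(xi, xj))
    Wij <- sum(r[(ni + 1):N])  # rank sum of group j
    ties <- table(c(xi, xj))
    tie_term <- sum(ties^3 - ties) / ((N) * (N - 1))
    v <- ni * nj / 12 * ((N + 1) - tie_term)
    stat <- if (v > 0) (Wij - nj * (N + 1) / 2) / sqrt(v) else 0
    p <- stats::ptukey(sqrt(2) * abs(stat), nmeans = k, df = Inf,
                       lower.tail = FALSE)
    W[i, j] <- W[j, i] <- stat
    P[i, j] <- P[j, i] <- p
    pairs <- rbind(pairs, data.frame(group_a = labels[i],
                                     group_b = labels[j],
                                     statistic = stat, p_value = p))
  }
  structure(list(statistic = W, p_value = P, pairs = pairs,
                 k = k, method = "Dwass-Steel-Critchlow-Fligner all-pairs"),
            class = "dscf_test")
}

#' @export
print.dscf_test <- function(x, ...) {
  cat(x$method, "\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
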