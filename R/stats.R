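#' Build a contingency table
#'
#' Thin validated wrapper around an integer matrix for the association
#' statistics. Row/column labels default to the dimnames.
#'
#' @param counts Matrix (or coercible) of nonnegative counts, at least 2x2.
#' @return An integer matrix of class `contingency_table`.
#' @export
contingency_table <- function(counts) {
  m <- as.matrix(counts)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(m) == 0) stop("contingency table is empty", call. = FALSE)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  class(m) <- c("contingency_table", class(m))
  m
}

#' Pearson chi-square test of independence with Cramer's V
#'
#' Computes chi-square = sum (O - E)^2 / E with expected counts from the
#' row/column marginals, df = (r-1)(c-1), the upper-tail P value, and
#' Cramer's V = sqrt(chi-square / (n * min(r-1, c-1))). No continuity
#' correction is applied (matching plain calculator conventions).
#'
#' @param t Matrix of counts or a [contingency_table()].
#' @return List with `statistic`, `df`, `p_value`, `effect_size`
#'   (Cramer's V), `n`.
#' @examples
#' chi_square_independence(matrix(c(10, 20, 20, 10), 2))
#' @export
chi_square_independence <- function(t) {
  m <- contingency_table(t)
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0)) {
    stop("row '", rownames(m)[which(rs == 0)[1]], "' has zero marginal",
         call. = FALSE)
  }
  if (any(cs == 0)) {
    stop("column '", colnames(m)[which(cs == 0)[1]], "' has zero marginal",
         call. = FALSE)
  }
  e <- outer(rs, cs) / n
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  v <- sqrt(stat / (n * min(nrow(m) - 1L, ncol(m) - 1L)))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       effect_size = v, n = n)
}

#' Cohen's kappa for a square agreement table
#'
#' Unweighted chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e)
#' with observed agreement p_o = diagonal sum / n and chance agreement
#' p_e = sum of row_i * col_i / n^2. Rows and columns must represent the
#' same categories in the same order.
#'
#' @param t Square matrix of counts or a [contingency_table()].
#' @return List with `statistic` (kappa), `p_o`, `p_e`, `n`.
#' @export
cohens_kappa <- function(t) {
  m <- contingency_table(t)
  if (nrow(m) != ncol(m)) {
    stop("kappa requires a square table with matched label order",
         call. = FALSE)
  }
  n <- sum(m)
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (p_e >= 1) {
    stop("both ratings are constant; agreement beyond chance is undefined",
         call. = FALSE)
  }
  list(statistic = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e, n = n)
}

#' Pooled two-proportion z-test
#'
#' z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2)) with the pooled
#' proportion p = (x1 + x2) / (n1 + n2); two-sided P from the standard
#' normal. No continuity correction. The sign follows p1 - p2, so
#' x1/n1 < x2/n2 gives z < 0.
#'
#' @param x1,n1 Successes and trials of the first proportion.
#' @param x2,n2 Successes and trials of the second proportion.
#' @return List with `statistic` (z), `p_value`, `p1`, `p2`, `p_pooled`.
#' @examples
#' two_proportion_z(151, 803, 248, 803)
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  if (p <= 0 || p >= 1) {
    stop("pooled proportion is degenerate (", p,
         "); z is undefined", call. = FALSE)
  }
  z <- (p1 - p2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
       p1 = p1, p2 = p2, p_pooled = p)
}

#' Significance of the gain in positive descriptions
#'
#' Pooled two-proportion z-test comparing the fraction of positively
#' described samples before and after a change to the prediction
#' procedure (e.g. step 1 only vs. both steps).
#'
#' @param x1,n1 Positives and cohort size before.
#' @param x2,n2 Positives and cohort size after.
#' @return As [two_proportion_z()].
#' @export
positive_description_gain <- function(x1, n1, x2, n2) {
  two_proportion_z(x1, n1, x2, n2)
}
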