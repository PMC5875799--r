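#' Fisher's exact test with the sample odds ratio
#'
#' Exact hypergeometric tail probabilities for a 2x2 contingency table
#' `[[a, b], [c, d]]`, conditioning on both margins.  The two-sided
#' p-value sums the probabilities of all tables (with the observed
#' margins) whose point probability does not exceed that of the observed
#' table.  The odds ratio reported is the sample cross-product ratio
#' `(a*d)/(b*c)` (infinite when `b*c = 0` with `a*d > 0`), the quantity
#' conventionally printed alongside this test; a Wald 95% confidence
#' interval on it is included with the usual caveat that other interval
#' constructions exist.
#'
#' @param table 2x2 matrix (or coercible) of non-negative integer counts.
#' @param tail `"two_sided"`, `"right"` (P(X >= a)) or `"left"`
#'   (P(X <= a)); selects which p-value is placed in `p_value`.  All three
#'   are always returned.
#' @return A `contingency_result`: list with `table`, `odds_ratio`,
#'   `ci_wald_95`, `p_right`, `p_left`, `p_two_sided`, `p_value`, `tail`,
#'   `n`, `df`.
#' @export
fisher_exact <- function(table, tail = c("two_sided", "right", "left")) {
  tail <- match.arg(tail)
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2, 2))) stop("table must be 2x2")
  if (any(tb < 0) || any(abs(tb - round(tb)) > 1e-8))
    stop("table entries must be non-negative integers")
  tb <- round(tb)
  a <- tb[1, 1]; b <- tb[1, 2]; c_ <- tb[2, 1]; d <- tb[2, 2]
  if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0)
    stop("both margins must be positive")
  m <- a + b          # row-1 total ("white balls")
  n2 <- c_ + d        # row-2 total
  k <- a + c_         # column-1 total (draws)
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p_right <- sum(probs[support >= a])
  p_left <- sum(probs[support <= a])
  p_two <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  ci <- if (all(tb > 0)) {
    se <- sqrt(sum(1 / tb))
    exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  } else c(NA_real_, NA_real_)
  p_value <- switch(tail, two_sided = p_two, right = p_right, left = p_left)
  structure(list(table = tb, odds_ratio = or, ci_wald_95 = ci,
                 p_right = p_right, p_left = p_left, p_two_sided = p_two,
                 p_value = p_value, tail = tail, n = sum(tb), df = 1L),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> n = %d, df = %d\n", x$n, x$df))
  cat(sprintf("  odds ratio %.4g (Wald 95%% CI %.3g-%.3g)\n",
              x$odds_ratio, x$ci_wald_95[1], x$ci_wald_95[2]))
  cat(sprintf("  p right %.4g | left %.4g | two-sided %.4g\n",
              x$p_right, x$p_left, x$p_two_sided))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples.  `U` is the statistic
#' of the first sample (`rank sum - n1(n1+1)/2`, midranks for ties).  For
#' small samples the two-sided p-value is computed from the full
#' permutation null (every assignment of the pooled values to the two
#' groups); larger samples use the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param method `"auto"` (exact when `n1 + n2 <= 20`), `"exact"` or
#'   `"normal"`.
#' @return A `group_comparison`: list with `U`, `p_value`, `medians`,
#'   `n`, `method`.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (method == "auto") method <- if (N <= 20) "exact" else "normal"
  if (method == "exact") {
    combs <- utils::combn(N, n1)
    U_null <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(U_null - mu) >= abs(U - mu) - 1e-9)
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  structure(list(U = U, p_value = p,
                 medians = c(x = stats::median(x), y = stats::median(y)),
                 n = c(n1 = n1, n2 = n2), method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> U = %.4g, p = %.4g (%s)\n",
              x$U, x$p_value, x$method))
  cat(sprintf("  medians: %.4g vs %.4g (n = %d, %d)\n",
              x$medians[1], x$medians[2], x$n[1], x$n[2]))
  invisible(x)
}

#' Pearson correlation between two kymographs
#'
#' The image correlation over all cells where both fields are supported,
#' optionally restricted to the apical growth zone.
#'
#' @param field_a,field_b [kinematic_field]s on the same grids.
#' @param gz_length if non-`NULL`, restrict the correlation to
#'   `s <= gz_length` (mm).
#' @return A `correlation_result`: list with `r` and `n_cells`.
#' @export
kymograph_correlation <- function(field_a, field_b, gz_length = NULL) {
  stopifnot_same_grid(field_a, field_b)
  joint <- field_a$mask & field_b$mask &
    !is.na(field_a$values) & !is.na(field_b$values)
  if (!is.null(gz_length))
    joint <- joint & matrix(field_a$s <= gz_length, nrow(joint),
                            ncol(joint), byrow = TRUE)
  n_cells <- sum(joint)
  if (n_cells < 10) stop("need at least 10 jointly supported cells")
  va <- field_a$values[joint]; vb <- field_b$values[joint]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("correlation undefined: a field has zero variance on the joint support")
  structure(list(r = stats::cor(va, vb), n_cells = n_cells),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.4g over %d cells\n",
              x$r, x$n_cells))
  invisible(x)
}

#' Straight-vs-tilted comparisons over a cohort summary table
#'
#' Runs Mann-Whitney U tests between the two treatment groups for each
#' per-plant summary quantity (oscillation periods and pulse velocities of
#' the REGR and curvature-variation kymographs, early/late temporal
#' averages, and the growth-curvature coupling correlation `r`).
#'
#' @param summaries data.frame with a `group` column
#'   (`"straight"`/`"tilted"`) and numeric summary columns.
#' @param quantities columns to compare; defaults to every numeric column.
#' @return data.frame with one row per quantity: group medians, sample
#'   sizes, `U` and `p`.  Plants with a missing value for a quantity are
#'   dropped from that comparison with a warning.
#' @export
cohort_compare <- function(summaries, quantities = NULL) {
  if (!"group" %in% names(summaries)) stop("summaries need a 'group' column")
  g <- summaries$group
  if (length(unique(g)) != 2)
    stop("need exactly two treatment groups")
  if (min(table(g)) < 2)
    stop("need at least 2 plants per group")
  if (is.null(quantities))
    quantities <- names(summaries)[vapply(summaries, is.numeric, logical(1))]
  rows <- lapply(quantities, function(q) {
    v <- summaries[[q]]
    ok <- !is.na(v)
    if (any(!ok))
      warning(sum(!ok), " plants missing '", q, "' skipped")
    xs <- v[ok & g == "straight"]; xt <- v[ok & g == "tilted"]
    if (length(xs) < 2 || length(xt) < 2)
      return(data.frame(quantity = q, median_straight = NA, median_tilted = NA,
                        n_straight = length(xs), n_tilted = length(xt),
                        U = NA, p = NA))
    mw <- mann_whitney_u(xs, xt)
    data.frame(quantity = q,
               median_straight = stats::median(xs),
               median_tilted = stats::median(xt),
               n_straight = length(xs), n_tilted = length(xt),
               U = mw$U, p = mw$p_value)
  })
  do.call(rbind, rows)
}
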