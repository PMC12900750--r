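#' Yates continuity-corrected chi-square test for a 2x2 table
#'
#' `chi2 = sum((max(|O - E| - 0.5, 0))^2 / E)` with the correction clamped so
#' the corrected deviation never goes negative; p-value from the chi-square
#' distribution with 1 degree of freedom. For a near-balanced sex table such
#' as 8/7 vs 7/8 the corrected statistic is exactly 0 (p = 1).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List of class `mddpanel_test` with `statistic_name`, `statistic`,
#'   `p_value`, `method_chosen`.
#' @export
yates_chi_square <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers")
  }
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column margin")
  e <- outer(rs, cs) / sum(table)
  stat <- sum(pmax(abs(table - e) - 0.5, 0)^2 / e)
  structure(list(statistic_name = "chi2_yates", statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method_chosen = "chi-square with Yates continuity correction"),
            class = "mddpanel_test")
}

#' Normality-gated two-group comparison
#'
#' Assesses normality in each group with the Shapiro-Wilk test; if both
#' groups look normal (p >= `alpha_normality`) a Welch two-sample t-test is
#' used, otherwise a two-sided Mann-Whitney U test (normal approximation
#' with continuity and tie correction by default; exact enumeration
#' optional). A group in which Shapiro-Wilk is undefined (constant values)
#' is treated as non-normal.
#'
#' @param values Numeric vector of measurements.
#' @param groups Two-level labels, one per value; at least 3 per group.
#' @param alpha_normality Shapiro-Wilk gate, default 0.05.
#' @param exact Use the exact Mann-Whitney distribution (default FALSE).
#' @return `mddpanel_test` list; `method_chosen` is `"welch_t"`,
#'   `"mann_whitney"`, or `"degenerate"` (both groups constant and equal,
#'   p = 1 with a warning).
#' @export
group_compare <- function(values, groups, alpha_normality = 0.05,
                          exact = FALSE) {
  grp <- match_two_groups(groups)
  x <- values[grp$is_case]; y <- values[!grp$is_case]
  if (length(x) < 3 || length(y) < 3) stop("need at least 3 values per group")
  if (stats::sd(values) == 0) {
    warning("all values identical; comparison is degenerate")
    return(structure(list(statistic_name = "none", statistic = NA_real_,
                          p_value = 1, method_chosen = "degenerate"),
                     class = "mddpanel_test"))
  }
  sw_p <- function(v) {
    if (stats::sd(v) == 0) return(0)  # constant: treat as non-normal
    stats::shapiro.test(v)$p.value
  }
  normal <- sw_p(x) >= alpha_normality && sw_p(y) >= alpha_normality
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    structure(list(statistic_name = "t", statistic = unname(tt$statistic),
                   p_value = tt$p.value, method_chosen = "welch_t"),
              class = "mddpanel_test")
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    structure(list(statistic_name = "U", statistic = unname(wt$statistic),
                   p_value = wt$p.value, method_chosen = "mann_whitney"),
              class = "mddpanel_test")
  }
}

#' @export
print.mddpanel_test <- function(x, ...) {
  cat(sprintf("%s: %s = %s, p = %.4g\n", x$method_chosen, x$statistic_name,
              format(x$statistic, digits = 4), x$p_value))
  invisible(x)
}

#' Relative quantification by the 2^-ddCt method
#'
#' `dCt = ct_target - ct_ref`; `ddCt = dCt - mean_dct_control`; the relative
#' fold change is `2^-ddCt` (always positive). Vectorized over samples.
#'
#' @param ct_target Target-gene Ct value(s).
#' @param ct_ref Reference-gene Ct value(s), same length or scalar.
#' @param mean_dct_control Mean dCt of the control group for this gene.
#' @return Fold change(s) relative to the control mean.
#' @export
ddct_fold_change <- function(ct_target, ct_ref, mean_dct_control) {
  if (!all(is.finite(ct_target), is.finite(ct_ref),
           is.finite(mean_dct_control))) {
    stop("Ct inputs must be finite")
  }
  2^(-((ct_target - ct_ref) - mean_dct_control))
}

#' Per-gene 2^-ddCt fold changes for a Ct matrix
#'
#' Convenience wrapper over [ddct_fold_change()]: computes each sample's
#' fold change relative to the control-group mean dCt, per gene.
#'
#' @param ct Gene-by-sample Ct matrix.
#' @param ct_ref Per-sample reference-gene Ct vector.
#' @param groups Two-level labels per sample.
#' @param control_level Label of the control group (default `"HC"` when
#'   present, otherwise the non-case level).
#' @return Gene-by-sample matrix of fold changes.
#' @export
ddct_analysis <- function(ct, ct_ref, groups, control_level = NULL) {
  ct <- as.matrix(ct)
  grp <- match_two_groups(groups)
  ctrl <- if (is.null(control_level)) !grp$is_case else
    as.character(groups) == control_level
  if (!any(ctrl)) stop("no control samples found")
  out <- ct
  for (g in seq_len(nrow(ct))) {
    dct <- ct[g, ] - ct_ref
    out[g, ] <- ddct_fold_change(ct[g, ], ct_ref, mean(dct[ctrl]))
  }
  out
}

#' Partial Spearman rank correlation
#'
#' All variables (x, y, and every covariate) are rank-transformed with
#' average ranks for ties; the partial correlation is the Pearson
#' correlation of the rank vectors after residualizing both on the
#' rank-transformed covariates. The p-value uses the t approximation with
#' `n - 2 - k` degrees of freedom (k = number of covariates). With no
#' covariates this is exactly Spearman's rho.
#'
#' @param x,y Numeric vectors, no missing values.
#' @param covariates Optional numeric matrix/data.frame of covariates
#'   (columns); factors must be numerically encoded by the caller.
#' @return List of class `partial_cor`: `adj_r`, `adj_p`, `n`, `covariates`
#'   (names), `df`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  k <- 0L
  z <- NULL
  if (!is.null(covariates)) {
    z <- as.matrix(covariates)
    if (nrow(z) != n) stop("covariates must have one row per observation")
    if (anyNA(z)) stop("missing values are not supported")
    k <- ncol(z)
  }
  if (n <= k + 2) stop("need n > number of covariates + 2")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("x or y is constant after rank transformation; correlation undefined")
  }
  if (k > 0) {
    rz <- apply(z, 2, rank, ties.method = "average")
    qr_z <- qr(cbind(1, rz))
    rx <- qr.resid(qr_z, rx)
    ry <- qr.resid(qr_z, ry)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
      stop("x or y is fully explained by the covariates; correlation undefined")
    }
  }
  r <- stats::cor(rx, ry)
  r <- max(-1, min(1, r))
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(adj_r = r, adj_p = min(1, p), n = n,
                 covariates = colnames(z) %||% character(0), df = df),
            class = "partial_cor")
}

#' @export
print.partial_cor <- function(x, ...) {
  cov_txt <- if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "none"
  cat(sprintf("partial Spearman: adj.r = %.3f, adj.p = %.4g (n = %d, covariates: %s)\n",
              x$adj_r, x$adj_p, x$n, cov_txt))
  invisible(x)
}
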