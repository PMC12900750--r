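#' Counts per million
#'
#' Library-size normalization: `count / library_size * 1e6`.
#'
#' @param counts Non-negative gene-by-sample count matrix.
#' @param lib_sizes Per-sample library sizes; defaults to column sums.
#' @return Real matrix of the same shape.
#' @export
cpm_counts <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(lib_sizes <= 0)) {
    bad <- colnames(counts)[lib_sizes <= 0] %||% which(lib_sizes <= 0)
    stop("zero or negative library size for sample(s): ",
         paste(bad, collapse = ", "))
  }
  sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' Fragments per kilobase per million mapped reads
#'
#' `count / (length/1000) / (library_size/1e6)`.
#'
#' @param counts Gene-by-sample count matrix.
#' @param gene_lengths Positive gene lengths in bp, one per row.
#' @param lib_sizes Per-sample mapped-fragment totals; default column sums.
#' @return Real matrix of FPKM values.
#' @export
fpkm_counts <- function(counts, gene_lengths, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (missing(gene_lengths) || is.null(gene_lengths)) {
    stop("gene lengths are required for FPKM")
  }
  if (length(gene_lengths) != nrow(counts)) {
    stop("need one gene length per row")
  }
  miss <- !is.finite(gene_lengths) | gene_lengths <= 0
  if (any(miss)) {
    bad <- rownames(counts)[miss] %||% which(miss)
    stop("missing or non-positive length for gene(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts / (gene_lengths / 1e3), 2, lib_sizes / 1e6, "/")
}

# Scale columns to the geometric-mean library size so groups are comparable
# under the conditional exact test. With equal library sizes this is the
# identity.
scale_to_common_lib <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  common <- exp(mean(log(lib_sizes)))
  sweep(as.matrix(counts), 2, common / lib_sizes, "*")
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-gene pooled estimate `phi = max(0, (s^2 - m) / m^2)` where `m` is the
#' mean of the two group means and `s^2` the pooled within-group variance,
#' computed on counts scaled to a common (geometric-mean) library size.
#'
#' @param counts Gene-by-sample count matrix.
#' @param groups Two-level group labels, one per column.
#' @param lib_sizes Per-sample library sizes; default column sums.
#' @return Named per-gene numeric vector of dispersions (never negative).
#' @export
estimate_dispersion <- function(counts, groups, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  grp <- match_two_groups(groups)
  n1 <- sum(grp$is_case); n2 <- sum(!grp$is_case)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  x <- scale_to_common_lib(counts, lib_sizes)
  x1 <- x[, grp$is_case, drop = FALSE]
  x2 <- x[, !grp$is_case, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  m <- (m1 + m2) / 2
  phi <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), 0)
  stats::setNames(phi, rownames(counts))
}

# Two-sided exact p-value for the split of an integer total `t` between two
# groups, conditioning on the total. Group sums are NB(n_g*mu, size n_g/phi);
# phi = 0 degenerates to the binomial split. p = sum of probabilities of all
# splits no more probable than the observed one.
exact_split_pvalue <- function(y1, t, n1, n2, phi) {
  if (t <= 0) return(1)
  ys <- 0:t
  if (phi <= 0) {
    logf <- stats::dbinom(ys, t, n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- t / (n1 + n2)
    logf <- stats::dnbinom(ys, mu = n1 * mu, size = n1 / phi, log = TRUE) +
      stats::dnbinom(t - ys, mu = n2 * mu, size = n2 / phi, log = TRUE)
  }
  logf <- logf - max(logf)
  f <- exp(logf)
  p <- sum(f[f <= f[y1 + 1L] * (1 + 1e-12)]) / sum(f)
  min(1, max(p, .Machine$double.xmin))
}

#' Negative-binomial exact test for a two-group comparison
#'
#' For each gene, conditions on the gene's total count across all samples
#' (after scaling to a common library size) and computes the exact two-sided
#' probability of a group split as or less probable than the observed one,
#' with group sums distributed negative-binomially under the null of equal
#' means. Dispersion zero degenerates to the binomial (Poisson-split) exact
#' test.
#'
#' @param counts Gene-by-sample count matrix (no NAs).
#' @param groups Two-level labels, one per column.
#' @param dispersions Per-gene non-negative dispersions (recycled if scalar).
#' @param lib_sizes Per-sample library sizes; default column sums.
#' @param case_level Which group plays the "case" role (affects nothing about
#'   the p-value; retained for interface symmetry). Default `"MDD"` when
#'   present.
#' @return Named per-gene vector of p-values in (0, 1].
#' @export
nb_exact_test <- function(counts, groups, dispersions,
                          lib_sizes = colSums(counts), case_level = NULL) {
  counts <- as.matrix(counts)
  if (anyNA(counts)) stop("counts contain NA")
  grp <- match_two_groups(groups, case_level)
  n1 <- sum(grp$is_case); n2 <- sum(!grp$is_case)
  if (length(dispersions) == 1L) dispersions <- rep(dispersions, nrow(counts))
  if (length(dispersions) != nrow(counts)) {
    stop("need one dispersion per gene")
  }
  if (any(dispersions < 0)) stop("dispersions must be >= 0")
  x <- scale_to_common_lib(counts, lib_sizes)
  s1 <- round(rowSums(x[, grp$is_case, drop = FALSE]))
  s2 <- round(rowSums(x[, !grp$is_case, drop = FALSE]))
  p <- vapply(seq_len(nrow(counts)), function(i) {
    exact_split_pvalue(s1[i], s1[i] + s2[i], n1, n2, dispersions[i])
  }, numeric(1))
  stats::setNames(p, rownames(counts))
}

#' Log2 fold change of group mean CPM with a prior count
#'
#' `log2((mean CPM case + prior) / (mean CPM control + prior))`;
#' antisymmetric under swapping the group roles.
#'
#' @inheritParams nb_exact_test
#' @param prior Prior count added to both means (default 0.5) to avoid
#'   division by zero.
#' @return Named per-gene log2 fold changes.
#' @export
log2_fold_change <- function(counts, groups, prior = 0.5,
                             lib_sizes = colSums(counts), case_level = NULL) {
  if (prior < 0) stop("prior must be >= 0")
  grp <- match_two_groups(groups, case_level)
  cp <- cpm_counts(counts, lib_sizes)
  m1 <- rowMeans(cp[, grp$is_case, drop = FALSE])
  m2 <- rowMeans(cp[, !grp$is_case, drop = FALSE])
  stats::setNames(log2((m1 + prior) / (m2 + prior)), rownames(counts))
}

#' Two-group differential-expression screen
#'
#' Runs the full per-gene screen: CPM group means, log2 fold change with
#' prior count, method-of-moments dispersion, negative-binomial exact test,
#' and the joint nominal-p / fold-change DEG flag. Nominal p-values are used
#' by design (high-magnitude regulators would be penalized by FDR correction
#' under strong inter-individual heterogeneity); Benjamini-Hochberg adjusted
#' values can be added alongside.
#'
#' @inheritParams nb_exact_test
#' @param p_thresh Nominal p-value threshold (strict `<`), default 0.05.
#' @param fc_thresh |log2FC| threshold (strict `>`), default 1.
#' @param prior Prior count for the fold change, default 0.5.
#' @param adjust `"none"` (default) or `"BH"` to append a `p_adj` column
#'   (the DEG flag still uses the nominal p-value).
#' @return A `de_table` data.frame: `gene`, `mean_cpm_case`,
#'   `mean_cpm_control`, `log2fc`, `dispersion`, `p_value`, (`p_adj`,)
#'   `is_deg`, `direction`.
#' @export
de_analysis <- function(counts, groups, p_thresh = 0.05, fc_thresh = 1,
                        prior = 0.5, adjust = c("none", "BH"),
                        lib_sizes = colSums(counts), case_level = NULL) {
  adjust <- match.arg(adjust)
  counts <- as.matrix(counts)
  grp <- match_two_groups(groups, case_level)
  cp <- cpm_counts(counts, lib_sizes)
  phi <- estimate_dispersion(counts, groups, lib_sizes)
  pv <- nb_exact_test(counts, groups, phi, lib_sizes, case_level)
  lfc <- log2_fold_change(counts, groups, prior, lib_sizes, case_level)
  de <- data.frame(
    gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    mean_cpm_case = rowMeans(cp[, grp$is_case, drop = FALSE]),
    mean_cpm_control = rowMeans(cp[, !grp$is_case, drop = FALSE]),
    log2fc = unname(lfc),
    dispersion = unname(phi),
    p_value = unname(pv),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (adjust == "BH") de$p_adj <- stats::p.adjust(de$p_value, "BH")
  de$is_deg <- de$p_value < p_thresh & abs(de$log2fc) > fc_thresh
  de$direction <- ifelse(!de$is_deg, "none",
                         ifelse(de$log2fc > 0, "up", "down"))
  attr(de, "thresholds") <- c(p = p_thresh, fc = fc_thresh)
  class(de) <- c("de_table", "data.frame")
  de
}

#' Filter a differential-expression table to its DEG set
#'
#' Re-applies the joint screen with strict inequalities (`p < p_thresh` and
#' `|log2fc| > fc_thresh`) and partitions the survivors by sign.
#'
#' @param de A `de_table` (or any data.frame with `gene`, `log2fc`,
#'   `p_value`).
#' @param p_thresh,fc_thresh Thresholds, strict.
#' @return Data frame of DEGs with `direction` in `up`/`down`.
#' @export
filter_degs <- function(de, p_thresh = 0.05, fc_thresh = 1) {
  if (p_thresh < 0 || p_thresh > 1) stop("p_thresh must be in [0, 1]")
  if (fc_thresh < 0) stop("fc_thresh must be >= 0")
  keep <- de$p_value < p_thresh & abs(de$log2fc) > fc_thresh
  out <- de[keep, , drop = FALSE]
  out$is_deg <- TRUE
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' @export
print.de_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  n_up <- sum(x$direction == "up"); n_dn <- sum(x$direction == "down")
  cat(sprintf("DE screen: %d genes, %d DEGs (%d up, %d down) at p < %g, |log2FC| > %g\n",
              nrow(x), n_up + n_dn, n_up, n_dn, th[["p"]], th[["fc"]]))
  NextMethod()
}
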