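# Shared fixture builders (all generated in code at test time).

# Feature matrix with `n_signal` planted discriminative features among
# `p` candidates: features are N(0,1), planted ones shifted by `effect`
# (standardized units) in the case class.
make_feature_matrix <- function(n1 = 15, n0 = 15, p = 8, n_signal = 0,
                                effect = 2, seed = 1) {
  set.seed(seed)
  y <- c(rep(1L, n1), rep(0L, n0))
  x <- matrix(rnorm((n1 + n0) * p), n1 + n0, p,
              dimnames = list(NULL, sprintf("GENE%02d", seq_len(p))))
  if (n_signal > 0) {
    x[y == 1, seq_len(n_signal)] <- x[y == 1, seq_len(n_signal)] + effect
  }
  list(x = x, y = y, signal = colnames(x)[seq_len(n_signal)])
}

# Small count matrix with equal library sizes (a filler gene absorbs the
# difference) so the conditional exact test is exact, not approximate.
make_equal_lib_counts <- function(counts_by_gene, target = NULL) {
  m <- do.call(rbind, counts_by_gene)
  rownames(m) <- names(counts_by_gene) %||%
    sprintf("g%02d", seq_along(counts_by_gene))
  cs <- colSums(m)
  target <- target %||% (max(cs) + 10)
  rbind(m, FILLER = target - cs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

null_cohort_params <- function(n_genes = 300, seed = 1, dispersion = 0.1,
                               n_case = 15, n_control = 15) {
  cohort_params(
    n_case = n_case, n_control = n_control, n_genes = n_genes,
    hub_spec = data.frame(gene = character(0), direction = character(0),
                          log2fc = numeric(0), stringsAsFactors = FALSE),
    nb_dispersion = dispersion, gene_hamd_rho = numeric(0),
    protein_sign = numeric(0), seed = seed)
}
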