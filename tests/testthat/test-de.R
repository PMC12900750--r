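test_that("cpm applies the counts-per-million formula", {
  m <- matrix(c(5, 7, 0, 123), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  out <- cpm_counts(m, lib_sizes = c(10, 4567890))
  expect_equal(out["a", "s1"], 5 / 10 * 1e6)
  expect_equal(out["b", "s2"], 123 / 4567890 * 1e6, tolerance = 1e-12)
  zero <- matrix(0, 1, 3, dimnames = list("z", NULL))
  expect_equal(unname(cpm_counts(zero, lib_sizes = c(1, 2, 3))[1, ]),
               c(0, 0, 0))
  expect_error(cpm_counts(m, lib_sizes = c(0, 10)), "s1")
})

test_that("fpkm applies the per-kilobase per-million formula", {
  m <- matrix(c(100, 0, 30, 250), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  out <- fpkm_counts(m, gene_lengths = c(2000, 1500),
                     lib_sizes = c(1e7, 2e6))
  expect_equal(out["a", "s1"], 100 / 2 / 10)     # = 5.0
  expect_equal(out["b", "s1"], 0)
  expect_equal(out["b", "s2"], 250 / 1.5 / 2, tolerance = 1e-12)
  expect_error(fpkm_counts(m, gene_lengths = c(2000, NA)), "b")
  expect_error(fpkm_counts(m), "required")
})

test_that("method-of-moments dispersion matches hand-computed values", {
  groups <- c("MDD", "MDD", "HC", "HC")
  lib <- rep(1e6, 4)
  flat <- matrix(10, 1, 4, dimnames = list("g", NULL))
  expect_equal(unname(estimate_dispersion(flat, groups, lib)), 0)
  # mean 100, within-group variance 300 in both groups -> (300-100)/100^2
  a <- sqrt(150)
  m <- matrix(c(100 - a, 100 + a, 100 - a, 100 + a), 1, 4,
              dimnames = list("g", NULL))
  expect_equal(unname(estimate_dispersion(m, groups, lib)), 0.02,
               tolerance = 1e-12)
  # Poisson-like variance (= mean) gives zero dispersion
  b <- sqrt(50)
  pois <- matrix(c(100 - b, 100 + b, 100 - b, 100 + b), 1, 4)
  expect_equal(unname(estimate_dispersion(pois, groups, lib)), 0,
               tolerance = 1e-12)
  expect_error(estimate_dispersion(flat, c("MDD", "HC", "HC", "HC"), lib),
               "2 samples")
})

test_that("exact split test returns 1 at the mode and for empty totals", {
  groups <- rep(c("MDD", "HC"), each = 3)
  lib <- rep(1e6, 6)
  m <- make_equal_lib_counts(list(
    even = c(4, 3, 3, 3, 3, 4),    # equal group sums -> observed at the mode
    empty = c(0, 0, 0, 0, 0, 0)))
  p <- nb_exact_test(m, c(groups), dispersions = 0, lib_sizes = rep(100, 6))
  expect_equal(unname(p["even"]), 1)
  expect_equal(unname(p["empty"]), 1)
})

test_that("zero-dispersion exact test matches binomial enumeration", {
  set.seed(42)
  for (rep in 1:60) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    t_total <- sample(0:50, 1)
    y1 <- sample(0:t_total, 1)
    got <- mddpanel:::exact_split_pvalue(y1, t_total, n1, n2, phi = 0)
    want <- oracle_binom_split_p(y1, t_total, n1, n2)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # extreme split, equal group sizes: p = 2 * symmetric binomial tail at 0
  expect_equal(mddpanel:::exact_split_pvalue(0, 20, 3, 3, 0),
               2 * 0.5^20, tolerance = 1e-12)
})

test_that("positive-dispersion exact test agrees with an independent NB screen", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  n <- 5
  counts <- matrix(rnbinom(40 * 2 * n, mu = 60, size = 10), 40, 2 * n,
                   dimnames = list(sprintf("g%02d", 1:40), NULL))
  # equalize library sizes so both conditional tests are exact
  counts <- rbind(counts, FILLER = max(colSums(counts)) + 50 - colSums(counts))
  groups <- rep(c("MDD", "HC"), each = n)
  phi <- 0.1
  p_mine <- nb_exact_test(counts, groups, dispersions = phi)
  dge <- edgeR::DGEList(counts = counts,
                        group = factor(groups, levels = c("HC", "MDD")))
  dge$samples$norm.factors <- 1
  et <- edgeR::exactTest(dge, dispersion = phi, rejection.region = "smallp")
  # same conditional construction; the nuisance mean is estimated differently
  # (pooled sample mean here, conditional MLE there), so agreement is close
  # but not exact
  expect_equal(unname(p_mine), et$table$PValue, tolerance = 1e-3)
})

test_that("swapping group labels negates log2FC and preserves p-values", {
  set.seed(3)
  counts <- matrix(rnbinom(30 * 10, mu = 50, size = 5), 30, 10,
                   dimnames = list(sprintf("g%02d", 1:30), NULL))
  g1 <- rep(c("MDD", "HC"), each = 5)
  g2 <- rep(c("HC", "MDD"), each = 5)
  expect_equal(log2_fold_change(counts, g1), -log2_fold_change(counts, g2))
  phi <- estimate_dispersion(counts, g1)
  expect_equal(estimate_dispersion(counts, g2), phi)
  expect_equal(nb_exact_test(counts, g1, phi), nb_exact_test(counts, g2, phi))
})

test_that("log2 fold change follows the prior-count formula", {
  lib <- rep(1e6, 4)
  groups <- c("MDD", "MDD", "HC", "HC")
  m <- matrix(c(40, 40, 10, 10), 1, 4, dimnames = list("g", NULL))
  expect_equal(unname(log2_fold_change(m, groups, prior = 0, lib_sizes = lib)),
               2)
  same <- matrix(c(10, 20, 20, 10), 1, 4, dimnames = list("g", NULL))
  expect_equal(unname(log2_fold_change(same, groups, prior = 0.5,
                                       lib_sizes = lib)), 0)
  zero <- matrix(0, 1, 4, dimnames = list("g", NULL))
  expect_equal(unname(log2_fold_change(zero, groups, prior = 0.5,
                                       lib_sizes = lib)), 0)
})

test_that("DEG filtering applies strict joint thresholds", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2fc = c(1.5, 0.5, 3, -2),
                   p_value = c(0.01, 0.01, 0.2, 0.05))
  out <- filter_degs(de, 0.05, 1)
  expect_equal(out$gene, "a")          # b fails fc, c fails p, d at p boundary
  expect_equal(out$direction, "up")
  all_in <- filter_degs(de, 1, 0)
  expect_equal(nrow(all_in), 4)        # every p < 1, every |fc| > 0
  expect_error(filter_degs(de, -0.1, 1), "p_thresh")
})

test_that("planted high-magnitude genes are recovered as DEGs", {
  hub <- data.frame(gene = c("UP1", "DN1"), direction = c("up", "down"),
                    log2fc = c(2, -2))
  hit <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_params(
      n_genes = 30L, hub_spec = hub, nb_dispersion = 0.1,
      mean_log_expression = c(log(80), 0.5),
      gene_hamd_rho = numeric(0), protein_sign = numeric(0), seed = s))
    de <- de_analysis(co$counts, co$samples$group)
    degs <- filter_degs(de)
    all(c("UP1", "DN1") %in% degs$gene) &&
      degs$direction[degs$gene == "UP1"] == "up" &&
      degs$direction[degs$gene == "DN1"] == "down"
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("the DE table is internally consistent", {
  co <- generate_cohort(cohort_params(n_genes = 60L, seed = 21L))
  de <- de_analysis(co$counts, co$samples$group, adjust = "BH")
  expect_s3_class(de, "de_table")
  expect_true(all(de$p_value > 0 & de$p_value <= 1))
  expect_true(all(de$dispersion >= 0))
  expect_identical(de$is_deg, de$p_value < 0.05 & abs(de$log2fc) > 1)
  expect_true(all(de$direction[de$is_deg & de$log2fc > 0] == "up"))
  expect_true(all(de$direction[!de$is_deg] == "none"))
  expect_true(all(de$p_adj >= de$p_value - 1e-15))
})
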