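#' Parameters for a synthetic case-control PBMC cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults emulate the statistical structure of a 15-vs-15 adolescent
#' case-control RNA-seq study: negative-binomial counts over a log-normal
#' baseline, eight designated hub genes with a dichotomous effect (four
#' erythroid/inflammatory genes up, four neurotrophic/remodeling genes down),
#' HAMD-17 severity scores drawn on the groups' observed ranges (19-33 for
#' cases, 0-6 for controls), ages 12-17, and a near-balanced sex split.
#'
#' @param n_case,n_control Number of case (MDD) and control (HC) samples;
#'   both must be at least 2.
#' @param n_genes Size of the gene universe (hub genes included).
#' @param hub_spec Data frame with columns `gene`, `direction` (`"up"` or
#'   `"down"`) and `log2fc` (planted log2 fold change, case over control;
#'   sign must agree with `direction`). Defaults to the eight-gene
#'   dichotomous pattern with |log2FC| = 3.
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   mu + phi * mu^2), shared across genes; a named per-gene numeric vector
#'   overrides individual genes.
#' @param mean_log_expression Length-2 numeric `(location, scale)` of the
#'   log-normal baseline mean expression.
#' @param hamd_case_range,hamd_control_range Integer HAMD-17 ranges per group.
#' @param age_range Integer age range (years).
#' @param gene_hamd_rho Named numeric vector mapping gene symbols to target
#'   latent (Gaussian-copula) rank correlations with HAMD, in [-1, 1].
#' @param protein_sign Named numeric vector of +1/-1 per gene; -1 plants a
#'   transcript-protein discordance (protein tracks the negative of the
#'   latent mRNA signal). Genes not named default to +1.
#' @param seed Integer seed; the generator is deterministic given the seed.
#'
#' @return An object of class `cohort_params` (a validated list).
#' @export
cohort_params <- function(n_case = 15L,
                          n_control = 15L,
                          n_genes = 500L,
                          hub_spec = default_hub_spec(),
                          nb_dispersion = 0.1,
                          mean_log_expression = c(log(50), 1),
                          hamd_case_range = c(19L, 33L),
                          hamd_control_range = c(0L, 6L),
                          age_range = c(12L, 17L),
                          gene_hamd_rho = c(IL6 = 0.7, MMP9 = -0.52),
                          protein_sign = c(IL6 = -1),
                          seed = 1L) {
  stopifnot(length(n_case) == 1L, length(n_control) == 1L)
  if (n_case != round(n_case) || n_control != round(n_control)) {
    stop("n_case and n_control must be integers")
  }
  if (n_case < 2 || n_control < 2) stop("need at least 2 samples per group")
  if (n_genes < 0 || n_genes != round(n_genes)) stop("n_genes must be a non-negative integer")
  hub_spec <- as.data.frame(hub_spec, stringsAsFactors = FALSE)
  if (nrow(hub_spec)) {
    stopifnot(all(c("gene", "direction", "log2fc") %in% names(hub_spec)))
    if (!all(hub_spec$direction %in% c("up", "down"))) {
      stop("hub_spec$direction must be 'up' or 'down'")
    }
    if (!all(is.finite(hub_spec$log2fc))) stop("planted log2fc must be finite")
    bad <- (hub_spec$direction == "up" & hub_spec$log2fc < 0) |
      (hub_spec$direction == "down" & hub_spec$log2fc > 0)
    if (any(bad)) stop("hub_spec log2fc sign disagrees with direction for: ",
                       paste(hub_spec$gene[bad], collapse = ", "))
  }
  if (any(nb_dispersion < 0)) stop("nb_dispersion must be >= 0")
  if (length(mean_log_expression) != 2L) {
    stop("mean_log_expression must be (location, scale)")
  }
  if (length(gene_hamd_rho) && any(abs(gene_hamd_rho) > 1)) {
    stop("|gene_hamd_rho| must be <= 1")
  }
  p <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
            n_genes = as.integer(n_genes), hub_spec = hub_spec,
            nb_dispersion = nb_dispersion,
            mean_log_expression = as.numeric(mean_log_expression),
            hamd_case_range = as.integer(hamd_case_range),
            hamd_control_range = as.integer(hamd_control_range),
            age_range = as.integer(age_range),
            gene_hamd_rho = gene_hamd_rho,
            protein_sign = protein_sign,
            seed = as.integer(seed))
  class(p) <- "cohort_params"
  p
}

#' Default eight-gene dichotomous hub specification
#'
#' Four erythroid/inflammatory genes planted up (SLC4A1, HBB, GYPA, IL6) and
#' four neurotrophic/remodeling genes planted down (IGF1, CSF2, MMP9, CXCR1),
#' each with |log2FC| = 3, a high-magnitude effect well above the usual
#' differential-expression screen thresholds.
#'
#' @return Data frame with columns `gene`, `direction`, `log2fc`.
#' @export
default_hub_spec <- function() {
  data.frame(
    gene = c("SLC4A1", "HBB", "GYPA", "IL6", "IGF1", "CSF2", "MMP9", "CXCR1"),
    direction = c(rep("up", 4), rep("down", 4)),
    log2fc = c(rep(3, 4), rep(-3, 4)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic case-control cohort
#'
#' Draws a complete multi-layer cohort: an integer RNA-seq count matrix
#' (negative binomial, gene-wise log-normal baseline means, group means of
#' planted hub genes multiplied by `2^log2fc` in cases), a sample table
#' (group, age, sex, HAMD-17), an ELISA-analogue protein matrix, a
#' qPCR-analogue Ct matrix with a reference-gene row, and a `truth` record of
#' every planted parameter.
#'
#' Gene-HAMD rank associations are induced through a Gaussian copula: each
#' sample carries a latent standard-normal severity score that determines its
#' (integer, uniformly ranged) HAMD value, and each gene named in
#' `gene_hamd_rho` couples its latent count quantile to that severity latent
#' at the requested correlation.
#'
#' @param params A [cohort_params()] object.
#' @return An object of class `synthetic_cohort`: list with elements
#'   `counts`, `samples`, `protein_levels`, `ct_values`, `ct_reference`,
#'   `truth`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  p <- params
  with_seed(p$seed, {
    n <- p$n_case + p$n_control
    sample_id <- sprintf("S%02d", seq_len(n))
    group <- c(rep("MDD", p$n_case), rep("HC", p$n_control))
    # Table-1-style sex balance: ceiling(n/2) males in cases, floor in controls
    sex <- c(sample(rep(c("M", "F"), c(ceiling(p$n_case / 2), floor(p$n_case / 2)))),
             sample(rep(c("M", "F"), c(floor(p$n_control / 2), ceiling(p$n_control / 2)))))
    age <- sample(seq(p$age_range[1], p$age_range[2]), n, replace = TRUE)

    # latent severity drives HAMD within each group's stated range
    z_h <- stats::rnorm(n)
    hamd <- integer(n)
    rng <- function(is_case) if (is_case) p$hamd_case_range else p$hamd_control_range
    for (i in seq_len(n)) {
      r <- rng(group[i] == "MDD")
      hamd[i] <- as.integer(round(r[1] + stats::pnorm(z_h[i]) * (r[2] - r[1])))
    }

    genes <- p$hub_spec$gene
    n_extra <- p$n_genes - length(genes)
    if (n_extra < 0) stop("n_genes smaller than the number of hub genes")
    if (n_extra > 0) genes <- c(genes, sprintf("G%04d", seq_len(n_extra)))
    if (anyDuplicated(genes)) stop("duplicate gene symbols in universe")
    bad_rho <- setdiff(names(p$gene_hamd_rho), genes)
    if (length(bad_rho)) stop("gene_hamd_rho names not in gene universe: ",
                              paste(bad_rho, collapse = ", "))

    base_mean <- stats::rlnorm(length(genes), p$mean_log_expression[1],
                               p$mean_log_expression[2])
    names(base_mean) <- genes
    phi <- if (length(p$nb_dispersion) == 1L && is.null(names(p$nb_dispersion))) {
      stats::setNames(rep(p$nb_dispersion, length(genes)), genes)
    } else {
      out <- stats::setNames(rep(p$nb_dispersion[[1]], length(genes)), genes)
      out[names(p$nb_dispersion)] <- p$nb_dispersion
      out
    }

    fc <- stats::setNames(rep(0, length(genes)), genes)
    fc[p$hub_spec$gene] <- p$hub_spec$log2fc
    is_case <- group == "MDD"

    mu <- matrix(base_mean, nrow = length(genes), ncol = n,
                 dimnames = list(genes, sample_id))
    if (any(fc != 0)) mu[, is_case] <- mu[, is_case] * 2^fc

    counts <- matrix(0L, length(genes), n, dimnames = list(genes, sample_id))
    for (g in genes) {
      size_g <- if (phi[g] > 0) 1 / phi[g] else Inf
      rho <- if (g %in% names(p$gene_hamd_rho)) p$gene_hamd_rho[[g]] else 0
      if (rho != 0) {
        z_g <- rho * z_h + sqrt(1 - rho^2) * stats::rnorm(n)
        u <- stats::pnorm(z_g)
        counts[g, ] <- if (is.finite(size_g)) {
          stats::qnbinom(u, mu = mu[g, ], size = size_g)
        } else {
          stats::qpois(u, lambda = mu[g, ])
        }
      } else {
        counts[g, ] <- if (is.finite(size_g)) {
          stats::rnbinom(n, mu = mu[g, ], size = size_g)
        } else {
          stats::rpois(n, lambda = mu[g, ])
        }
      }
    }
    storage.mode(counts) <- "integer"

    samples <- data.frame(sample_id = sample_id, group = group, age = age,
                          sex = sex, hamd = hamd, stringsAsFactors = FALSE)

    hub_genes <- p$hub_spec$gene
    sign_vec <- stats::setNames(rep(1, length(hub_genes)), hub_genes)
    common <- intersect(names(p$protein_sign), hub_genes)
    sign_vec[common] <- p$protein_sign[common]

    # protein = affine transform of the latent log2 mRNA signal + noise;
    # a -1 sign plants a transcript-protein discordance
    protein <- matrix(NA_real_, length(hub_genes), n,
                      dimnames = list(hub_genes, sample_id))
    ct <- matrix(NA_real_, length(hub_genes), n,
                 dimnames = list(hub_genes, sample_id))
    for (g in hub_genes) {
      latent <- log2(counts[g, ] + 0.5)
      latent_z <- if (stats::sd(latent) > 0) (latent - mean(latent)) / stats::sd(latent) else latent * 0
      protein[g, ] <- 10 + 2 * sign_vec[g] * latent_z + stats::rnorm(n, sd = 0.3)
      # Ct declines one cycle per doubling of expression, so planted fold
      # changes are recoverable via 2^-ddCt
      ct[g, ] <- 32 - log2(mu[g, ]) + stats::rnorm(n, sd = 0.15)
    }
    ct_ref <- stats::setNames(stats::rnorm(n, mean = 20, sd = 0.1), sample_id)

    truth <- list(
      hub_spec = p$hub_spec,
      gene_hamd_rho = as.list(p$gene_hamd_rho),
      protein_sign = as.list(sign_vec),
      nb_dispersion = unname(p$nb_dispersion[1]),
      mean_log_expression = p$mean_log_expression,
      hamd_case_range = p$hamd_case_range,
      hamd_control_range = p$hamd_control_range,
      n_case = p$n_case, n_control = p$n_control, n_genes = p$n_genes,
      seed = p$seed
    )

    structure(list(counts = counts, samples = samples,
                   protein_levels = protein, ct_values = ct,
                   ct_reference = ct_ref, truth = truth),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  tab <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  planted hub genes:", paste(x$truth$hub_spec$gene, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a gene interaction network with a planted hub clique
#'
#' Builds an undirected simple graph over a gene universe in which the
#' designated hub genes form a dense (near-complete) cluster, a moderate
#' halo of edges connects hubs to other genes, and sparse Erdos-Renyi noise
#' edges connect the rest. This stands in for a pre-built protein-protein
#' interaction subnetwork over a differential-expression gene set when no
#' external edge list is supplied; it is synthetic plumbing, not a database
#' snapshot.
#'
#' @param genes Character vector of node names.
#' @param hub_genes Subset of `genes` to plant as the dense cluster.
#' @param p_hub Edge probability within the hub cluster (default 0.95).
#' @param halo_per_hub Expected number of hub-to-background edges per hub.
#' @param p_noise Edge probability between background genes.
#' @param seed Integer seed.
#' @return An [igraph::graph] object.
#' @export
simulate_gene_network <- function(genes, hub_genes, p_hub = 0.95,
                                  halo_per_hub = 3, p_noise = 0.01,
                                  seed = 1L) {
  stopifnot(all(hub_genes %in% genes))
  with_seed(seed, {
    edges <- character(0)
    add_edge <- function(a, b) {
      if (a != b) edges <<- c(edges, paste(sort(c(a, b)), collapse = "\t"))
    }
    hg <- sort(hub_genes)
    if (length(hg) >= 2) {
      pairs <- utils::combn(hg, 2)
      keep <- stats::runif(ncol(pairs)) < p_hub
      for (j in which(keep)) add_edge(pairs[1, j], pairs[2, j])
    }
    bg <- setdiff(genes, hub_genes)
    for (h in hg) {
      k <- stats::rpois(1, halo_per_hub)
      if (k > 0 && length(bg)) {
        for (b in sample(bg, min(k, length(bg)))) add_edge(h, b)
      }
    }
    if (length(bg) >= 2) {
      n_bg <- length(bg)
      n_pairs <- n_bg * (n_bg - 1) / 2
      n_noise <- stats::rbinom(1, n_pairs, p_noise)
      if (n_noise > 0) {
        for (i in seq_len(n_noise)) {
          pick <- sample(bg, 2)
          add_edge(pick[1], pick[2])
        }
      }
    }
    edges <- unique(edges)
    el <- if (length(edges)) do.call(rbind, strsplit(edges, "\t", fixed = TRUE)) else
      matrix(character(0), 0, 2)
    g <- igraph::graph_from_data_frame(as.data.frame(el, stringsAsFactors = FALSE),
                                       directed = FALSE,
                                       vertices = data.frame(name = sort(genes)))
    igraph::simplify(g)
  })
}

#' Write a synthetic cohort to a directory of TSV/JSON files
#'
#' Emits `counts.tsv`, `samples.tsv`, `proteins.tsv`, `ct.tsv` (with the
#' reference-gene Ct as a final `REF` row) and `truth.json`. Numeric values
#' are written at full double precision so matrices round-trip losslessly
#' through [read_cohort()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory '", directory, "'")
  }
  write_tsv_full(as.data.frame(cohort$counts, check.names = FALSE),
                 file.path(directory, "counts.tsv"), row_label = "gene")
  write_tsv_full(cohort$samples, file.path(directory, "samples.tsv"))
  write_tsv_full(as.data.frame(cohort$protein_levels, check.names = FALSE),
                 file.path(directory, "proteins.tsv"), row_label = "gene")
  ct_all <- rbind(cohort$ct_values, REF = cohort$ct_reference)
  write_tsv_full(as.data.frame(ct_all, check.names = FALSE),
                 file.path(directory, "ct.tsv"), row_label = "gene")
  jsonlite::write_json(cohort$truth, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(directory)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param directory Directory containing `counts.tsv`, `samples.tsv` and
#'   optionally `proteins.tsv`, `ct.tsv`, `truth.json`.
#' @return A `synthetic_cohort` (with `truth = NULL` if `truth.json` absent).
#' @export
read_cohort <- function(directory) {
  counts <- read_tsv_matrix(file.path(directory, "counts.tsv"), "gene")
  storage.mode(counts) <- "integer"
  samples <- utils::read.delim(file.path(directory, "samples.tsv"),
                               stringsAsFactors = FALSE,
                               colClasses = c(sample_id = "character"))
  protein <- NULL
  ct <- NULL
  ct_ref <- NULL
  pp <- file.path(directory, "proteins.tsv")
  if (file.exists(pp)) protein <- read_tsv_matrix(pp, "gene")
  cp <- file.path(directory, "ct.tsv")
  if (file.exists(cp)) {
    ct_all <- read_tsv_matrix(cp, "gene")
    if ("REF" %in% rownames(ct_all)) {
      ct_ref <- ct_all["REF", ]
      ct <- ct_all[setdiff(rownames(ct_all), "REF"), , drop = FALSE]
    } else {
      ct <- ct_all
    }
  }
  truth <- NULL
  tp <- file.path(directory, "truth.json")
  if (file.exists(tp)) truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
  structure(list(counts = counts, samples = samples, protein_levels = protein,
                 ct_values = ct, ct_reference = ct_ref, truth = truth),
            class = "synthetic_cohort")
}
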