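#' Default pipeline configuration
#'
#' Returns the fully populated configuration list used when a config file
#' omits fields. The defaults mirror the study design the synthetic cohort
#' emulates: 15 vs 15 samples, nominal p < 0.05 with |log2FC| > 1 for the
#' DEG screen, top-25 subgraph-centrality nodes intersected with MCODE
#' modules for hubs, and the tri-algorithm consensus (100 stratified
#' bootstraps at threshold 0.6, ntree 2000, 1000 label permutations).
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    input_dir = NULL,          # cohort directory (write_cohort layout); NULL = simulate
    network_file = NULL,       # pre-built edge list; NULL = simulate from DEGs
    network_dialect = "tsv2col",
    n_case = 15L, n_control = 15L, n_genes = 500L,
    nb_dispersion = 0.1,
    p_thresh = 0.05, fc_thresh = 1.0, prior = 0.5,
    top_k = 25L, mcode_vwp = 0.2, mcode_haircut = TRUE, mcode_fluff = FALSE,
    candidate_genes = NULL,    # NULL = the detected consensus hubs
    B_stability = 100L, stability_threshold = 0.6,
    ntree = 2000L, B_permutation = 1000L, svm_cost = 1,
    master_seed = 1L,
    out_dir = NULL
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a list; fills in every default and reports
#' all violations at once (field paths included).
#'
#' @param config Path to a YAML file, a list, or NULL (pure defaults).
#' @return Normalized configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: '", config, "'")
    config <- yaml::read_yaml(config) %||% list()
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  cfg <- def
  cfg[names(config)] <- config
  errs <- character(0)
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$p_thresh) && cfg$p_thresh > 0 && cfg$p_thresh <= 1,
      "p_thresh: must be in (0, 1]")
  chk(is.numeric(cfg$fc_thresh) && cfg$fc_thresh >= 0,
      "fc_thresh: must be >= 0")
  chk(is.numeric(cfg$prior) && cfg$prior >= 0, "prior: must be >= 0")
  chk(is.numeric(cfg$top_k) && cfg$top_k >= 1, "top_k: must be >= 1")
  chk(is.numeric(cfg$mcode_vwp) && cfg$mcode_vwp >= 0 && cfg$mcode_vwp < 1,
      "mcode_vwp: must be in [0, 1)")
  chk(is.numeric(cfg$B_stability) && cfg$B_stability >= 1,
      "B_stability: must be >= 1")
  chk(is.numeric(cfg$stability_threshold) && cfg$stability_threshold >= 0 &&
        cfg$stability_threshold <= 1,
      "stability_threshold: must be in [0, 1]")
  chk(is.numeric(cfg$ntree) && cfg$ntree >= 1, "ntree: must be >= 1")
  chk(is.numeric(cfg$B_permutation) && cfg$B_permutation >= 1,
      "B_permutation: must be >= 1")
  chk(is.numeric(cfg$svm_cost) && cfg$svm_cost > 0, "svm_cost: must be > 0")
  chk(is.numeric(cfg$n_case) && cfg$n_case >= 2, "n_case: must be >= 2")
  chk(is.numeric(cfg$n_control) && cfg$n_control >= 2,
      "n_control: must be >= 2")
  chk(is.numeric(cfg$nb_dispersion) && all(cfg$nb_dispersion >= 0),
      "nb_dispersion: must be >= 0")
  chk(is.numeric(cfg$master_seed), "master_seed: must be an integer")
  if (!is.null(cfg$input_dir)) {
    chk(dir.exists(cfg$input_dir),
        paste0("input_dir: directory not found: '", cfg$input_dir, "'"))
  }
  if (!is.null(cfg$network_file)) {
    chk(file.exists(cfg$network_file),
        paste0("network_file: file not found: '", cfg$network_file, "'"))
  }
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  }
  int_fields <- c("n_case", "n_control", "n_genes", "top_k", "B_stability",
                  "ntree", "B_permutation", "master_seed")
  cfg[int_fields] <- lapply(cfg[int_fields], as.integer)
  cfg
}

#' Run the end-to-end biomarker pipeline
#'
#' Executes cohort acquisition (simulation or load), the
#' differential-expression screen, network hub identification, clinical
#' statistics, and the machine-learning consensus, writing every stage's
#' table plus a self-contained `report.json` to the output directory. A
#' rerun with the same configuration and master seed reproduces
#' `report.json` byte-identically; per-stage seeds are derived from the
#' master seed and logged in the report.
#'
#' @param config A config list or YAML path (see [validate_config()]).
#' @param out_dir Output directory (overrides `config$out_dir`); NULL keeps
#'   results in memory only.
#' @param seed Optional master-seed override.
#' @return Object of class `mdd_report` (the report list), invisibly
#'   returning all stage objects in `attr(, "stages")`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$master_seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  emit <- function(df, name, row_label = NULL) {
    if (!is.null(out)) write_tsv_full(df, file.path(out, name), row_label)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- cohort ---------------------------------------------------------------
  cohort <- stage("cohort", {
    if (!is.null(cfg$input_dir)) {
      read_cohort(cfg$input_dir)
    } else {
      generate_cohort(cohort_params(
        n_case = cfg$n_case, n_control = cfg$n_control,
        n_genes = cfg$n_genes, nb_dispersion = cfg$nb_dispersion,
        seed = derive_seed(cfg$master_seed, 1L)))
    }
  })
  samples <- cohort$samples
  groups <- samples$group

  # --- differential expression ---------------------------------------------
  de <- stage("de", de_analysis(cohort$counts, groups,
                                p_thresh = cfg$p_thresh,
                                fc_thresh = cfg$fc_thresh,
                                prior = cfg$prior))
  degs <- filter_degs(de, cfg$p_thresh, cfg$fc_thresh)
  emit(de, "de_table.tsv")

  # --- network hubs ---------------------------------------------------------
  net <- stage("network", {
    if (!is.null(cfg$network_file)) {
      read_edge_list(cfg$network_file, cfg$network_dialect)
    } else {
      planted <- if (!is.null(cohort$truth)) {
        as.data.frame(cohort$truth$hub_spec)$gene
      } else character(0)
      node_set <- union(degs$gene, planted)
      if (length(node_set) < 2) node_set <- rownames(cohort$counts)
      simulate_gene_network(node_set, intersect(planted, node_set),
                            seed = derive_seed(cfg$master_seed, 2L))
    }
  })
  ranking <- stage("network", subgraph_centrality(net))
  topk <- top_k_nodes(ranking, min(cfg$top_k, nrow(ranking)))
  modules <- stage("network", mcode_find_modules(net, vwp = cfg$mcode_vwp,
                                                 haircut = cfg$mcode_haircut,
                                                 fluff = cfg$mcode_fluff))
  hubs <- consensus_hubs(topk, modules)
  hubs <- hubs[hubs %in% rownames(cohort$counts)]
  emit(ranking, "centrality.tsv")
  if (length(modules)) {
    emit(data.frame(
      module_id = seq_along(modules),
      score = vapply(modules, `[[`, numeric(1), "score"),
      members = vapply(modules, function(m) paste(m$members, collapse = ","),
                       character(1)), stringsAsFactors = FALSE),
      "modules.tsv")
  }
  if (!is.null(out)) writeLines(hubs, file.path(out, "hubs.txt"))

  # --- clinical statistics --------------------------------------------------
  candidates <- cfg$candidate_genes %||% hubs
  candidates <- intersect(candidates, rownames(cohort$counts))
  clin <- stage("stats", {
    cpm <- cpm_counts(cohort$counts)
    cov <- cbind(age = samples$age, sex = as.integer(samples$sex == "M"))
    layers <- list(mRNA = log2(cpm + 0.5))
    if (!is.null(cohort$protein_levels)) {
      layers$protein <- cohort$protein_levels
    }
    cors <- do.call(rbind, lapply(names(layers), function(ly) {
      mat <- layers[[ly]]
      genes <- intersect(candidates, rownames(mat))
      if (!length(genes)) return(NULL)
      do.call(rbind, lapply(genes, function(g) {
        pc <- partial_spearman(mat[g, samples$sample_id], samples$hamd, cov)
        data.frame(marker = g, layer = ly, adj_r = pc$adj_r, adj_p = pc$adj_p,
                   n = pc$n, stringsAsFactors = FALSE)
      }))
    }))
    tests <- do.call(rbind, lapply(names(layers), function(ly) {
      mat <- layers[[ly]]
      genes <- intersect(candidates, rownames(mat))
      if (!length(genes)) return(NULL)
      do.call(rbind, lapply(genes, function(g) {
        gt <- group_compare(mat[g, samples$sample_id], groups)
        data.frame(marker = g, layer = ly, statistic = gt$statistic,
                   statistic_name = gt$statistic_name, p_value = gt$p_value,
                   method = gt$method_chosen, stringsAsFactors = FALSE)
      }))
    }))
    fold <- NULL
    if (!is.null(cohort$ct_values) && !is.null(cohort$ct_reference)) {
      genes <- intersect(candidates, rownames(cohort$ct_values))
      if (length(genes)) {
        fc_mat <- ddct_analysis(cohort$ct_values[genes, , drop = FALSE],
                                cohort$ct_reference, groups)
        is_case <- groups == match_two_groups(groups)$case
        fold <- data.frame(marker = genes,
                           mean_fold_change_case = rowMeans(fc_mat[, is_case, drop = FALSE]),
                           mean_fold_change_control = rowMeans(fc_mat[, !is_case, drop = FALSE]),
                           stringsAsFactors = FALSE)
      }
    }
    list(correlations = cors, group_tests = tests, qpcr_fold_changes = fold)
  })
  if (!is.null(clin$correlations)) emit(clin$correlations, "correlations.tsv")
  if (!is.null(clin$group_tests)) emit(clin$group_tests, "group_tests.tsv")
  if (!is.null(clin$qpcr_fold_changes)) emit(clin$qpcr_fold_changes, "qpcr_fold_changes.tsv")

  # --- machine-learning consensus ------------------------------------------
  ml <- NULL
  if (length(candidates) >= 2) {
    ml <- stage("select", {
      feat <- t(log2(cpm_counts(cohort$counts)[candidates, , drop = FALSE] + 0.5))
      y <- as.integer(groups == match_two_groups(groups)$case)
      ml_consensus(feat, y, B_stability = cfg$B_stability,
                   stability_threshold = cfg$stability_threshold,
                   ntree = cfg$ntree, B_permutation = cfg$B_permutation,
                   svm_cost = cfg$svm_cost,
                   seed = derive_seed(cfg$master_seed, 3L))
    })
    if (!is.null(out)) {
      emit(data.frame(feature = names(ml$lasso$selection_probability),
                      selection_probability = unname(ml$lasso$selection_probability),
                      stable = names(ml$lasso$selection_probability) %in%
                        ml$lasso$stable_set, stringsAsFactors = FALSE),
           "stability.tsv")
      emit(data.frame(size = as.integer(names(ml$svm$accuracy_curve)),
                      loocv_accuracy = unname(ml$svm$accuracy_curve)),
           "rfe_curve.tsv")
      emit(data.frame(feature = names(ml$rf$importance),
                      mean_decrease_gini = unname(ml$rf$importance),
                      rank = unname(ml$rf$rank[names(ml$rf$importance)]),
                      stringsAsFactors = FALSE), "importance.tsv")
      writeLines(ml$panel, file.path(out, "panel.txt"))
      if (!is.null(ml$model)) emit(ml$model$roc, "roc_points.tsv")
    }
  }

  # --- report ---------------------------------------------------------------
  report <- list(
    parameters = cfg[setdiff(names(cfg), c("input_dir", "network_file",
                                           "out_dir"))],
    seeds = list(master = cfg$master_seed,
                 cohort = derive_seed(cfg$master_seed, 1L),
                 network = derive_seed(cfg$master_seed, 2L),
                 ml = derive_seed(cfg$master_seed, 3L)),
    n_samples = nrow(samples),
    n_genes = nrow(cohort$counts),
    n_deg = nrow(degs),
    n_deg_up = sum(degs$direction == "up"),
    n_deg_down = sum(degs$direction == "down"),
    hub_genes = as.list(hubs),
    candidate_genes = as.list(candidates),
    panel = as.list(ml$panel %||% character(0)),
    auc = if (!is.null(ml) && !is.na(ml$auc)) ml$auc else NULL,
    permutation_p = if (!is.null(ml) && !is.null(ml$permutation))
      ml$permutation$p_value else NULL
  )
  class(report) <- "mdd_report"
  if (!is.null(out)) {
    jsonlite::write_json(unclass(report), file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  attr(report, "stages") <- list(cohort = cohort, de = de, degs = degs,
                                 network = net, ranking = ranking,
                                 modules = modules, hubs = hubs,
                                 clinical = clin, ml = ml)
  invisible(report)
}

#' @export
print.mdd_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  samples: %d, genes: %d\n", x$n_samples, x$n_genes))
  cat(sprintf("  DEGs: %d (%d up, %d down)\n", x$n_deg, x$n_deg_up,
              x$n_deg_down))
  cat("  hub genes:", paste(unlist(x$hub_genes), collapse = ", "), "\n")
  cat("  consensus panel:",
      if (length(x$panel)) paste(unlist(x$panel), collapse = ", ") else "(empty)",
      "\n")
  if (!is.null(x$auc)) {
    cat(sprintf("  panel AUC %.3f, permutation p %.4g\n", x$auc,
                x$permutation_p))
  }
  invisible(x)
}
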