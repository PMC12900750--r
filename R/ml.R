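#' Mann-Whitney AUC
#'
#' Area under the ROC curve via the rank-sum identity:
#' `(concordant pairs + 0.5 * tied pairs) / (n1 * n0)` — the probability that
#' a random case outscores a random control.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels (1/TRUE = case, 0/FALSE = control).
#' @return AUC in [0, 1].
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_feature_matrix <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  if (anyNA(x)) stop("feature matrix contains missing values")
  y <- as.integer(as.logical(y))
  if (length(y) != nrow(x)) stop("need one label per sample (row)")
  if (length(unique(y)) != 2L) stop("labels must contain both classes")
  list(x = x, y = y)
}

#' LASSO stability selection with stratified bootstrap
#'
#' Features are z-scored internally. The L1 penalty `lambda` is chosen once
#' on the full data by leave-one-out cross-validation over a log-spaced path
#' and then held fixed. In each of `B` iterations a stratified bootstrap
#' resamples, with replacement, within each class to that class's size; an
#' L1-penalized logistic regression is fitted (convergence tolerance 1e-7)
#' and the features with nonzero coefficients recorded. The selection
#' probability of a feature is its selection count divided by `B`; the
#' stable set contains features whose probability strictly exceeds
#' `threshold`.
#'
#' @param x Sample-by-feature numeric matrix.
#' @param y Binary labels (1 = case).
#' @param B Number of bootstrap iterations, default 100.
#' @param threshold Stability threshold (strict `>`), default 0.6.
#' @param lambda Optional fixed penalty; if `NULL` (default) chosen by LOOCV.
#' @param lambda_rule `"1se"` (default) picks the largest lambda within one
#'   standard error of the LOOCV minimum — the parsimonious rule, which keeps
#'   the stable set empty under label-permuted null data; `"min"` picks the
#'   deviance-minimizing lambda.
#' @param retune_per_iteration Re-tune lambda by LOOCV inside every bootstrap
#'   iteration instead of fixing it (default FALSE).
#' @param seed Integer seed.
#' @return Object of class `stability_result`: `selection_probability`
#'   (named), `stable_set`, `B`, `threshold`, `lambda_used`.
#' @export
lasso_stability_selection <- function(x, y, B = 100L, threshold = 0.6,
                                      lambda = NULL,
                                      lambda_rule = c("1se", "min"),
                                      retune_per_iteration = FALSE,
                                      seed = NULL) {
  if (B < 1) stop("B must be >= 1")
  lambda_rule <- match.arg(lambda_rule)
  d <- check_feature_matrix(x, y)
  x <- scale(d$x)
  x[, attr(x, "scaled:scale") == 0] <- 0  # constant features carry no signal
  y <- d$y
  n <- nrow(x)
  idx_case <- which(y == 1L); idx_ctrl <- which(y == 0L)
  loocv_lambda <- function(xx, yy) {
    cv <- glmnet::cv.glmnet(xx, yy, family = "binomial", nfolds = length(yy),
                            foldid = seq_along(yy), grouped = FALSE,
                            standardize = FALSE, thresh = 1e-7)
    if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
  }
  with_seed(seed, {
    lam <- lambda %||% loocv_lambda(x, y)
    counts <- stats::setNames(numeric(ncol(x)), colnames(x))
    for (b in seq_len(B)) {
      idx <- c(sample(idx_case, length(idx_case), replace = TRUE),
               sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
      lam_b <- if (retune_per_iteration) loocv_lambda(x[idx, , drop = FALSE], y[idx]) else lam
      fit <- glmnet::glmnet(x[idx, , drop = FALSE], y[idx],
                            family = "binomial", lambda = lam_b,
                            standardize = FALSE, thresh = 1e-7)
      beta <- as.numeric(fit$beta)
      counts[beta != 0] <- counts[beta != 0] + 1
    }
    prob <- counts / B
    structure(list(selection_probability = prob,
                   stable_set = names(prob)[prob > threshold],
                   B = as.integer(B), threshold = threshold,
                   lambda_used = lam),
              class = "stability_result")
  })
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("LASSO stability selection: B = %d, lambda = %.4g, threshold > %g\n",
              x$B, x$lambda_used, x$threshold))
  p <- sort(x$selection_probability, decreasing = TRUE)
  for (f in names(p)) {
    cat(sprintf("  %-10s %.2f%s\n", f, p[[f]],
                if (f %in% x$stable_set) "  *stable*" else ""))
  }
  invisible(x)
}

#' @export
plot.stability_result <- function(x, ...) {
  p <- sort(x$selection_probability)
  graphics::barplot(p, horiz = TRUE, las = 1, xlim = c(0, 1),
                    xlab = "selection probability",
                    main = "LASSO stability selection", ...)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}

# Linear-SVM feature weights; ties in |w| broken by eliminating the
# lexicographically larger feature name first.
svm_weights <- function(x, y, cost) {
  fit <- e1071::svm(x, factor(y), kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  stats::setNames(w, colnames(x))
}

svm_rfe_rank <- function(x, y, cost) {
  remaining <- colnames(x)
  eliminated <- character(0)
  while (length(remaining) > 1) {
    w <- svm_weights(x[, remaining, drop = FALSE], y, cost)
    sq <- w^2
    cand <- names(sq)[sq <= min(sq) * (1 + 1e-12)]
    drop_f <- sort(cand, decreasing = TRUE)[1]
    remaining <- setdiff(remaining, drop_f)
    eliminated <- c(eliminated, drop_f)
  }
  # ranking best -> worst: survivor first, then reverse elimination order
  c(remaining, rev(eliminated))
}

scale_train_test <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(xtr, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(xte, 2, mu, check.margin = FALSE), 2, sdv, "/"))
}

#' SVM-RFE with leave-one-out cross-validation
#'
#' Recursive feature elimination with a linear soft-margin SVM (fixed cost):
#' at each step the feature with the smallest squared weight is eliminated.
#' Classification accuracy at every subset size is estimated by LOOCV; by
#' default the elimination ranking is recomputed within each fold's training
#' split, so the held-out sample never informs the ranking it is scored
#' against. The optimal size maximizes LOOCV accuracy, ties going to the
#' smaller subset; the optimal set is the top of the full-data ranking at
#' that size.
#'
#' @param x Sample-by-feature matrix (>= 2 features).
#' @param y Binary labels.
#' @param cost SVM cost parameter, default 1.
#' @param nested Recompute the ranking within each LOOCV training fold
#'   (default TRUE); `FALSE` reuses the full-data ranking (optimistic).
#' @return Object of class `rfe_result`: `ranking` (best first),
#'   `elimination_order`, `accuracy_curve` (size -> LOOCV accuracy),
#'   `optimal_size`, `optimal_set`.
#' @export
svm_rfe_loocv <- function(x, y, cost = 1, nested = TRUE) {
  d <- check_feature_matrix(x, y)
  x <- d$x; y <- d$y
  if (ncol(x) < 2) stop("need at least 2 features")
  n <- nrow(x); p <- ncol(x)
  full_scaled <- scale_train_test(x, x)$train
  full_rank <- svm_rfe_rank(full_scaled, y, cost)
  correct <- matrix(0, n, p)
  for (i in seq_len(n)) {
    sc <- scale_train_test(x[-i, , drop = FALSE], x[i, , drop = FALSE])
    rk <- if (nested) svm_rfe_rank(sc$train, y[-i], cost) else full_rank
    for (s in seq_len(p)) {
      feats <- rk[seq_len(s)]
      fit <- e1071::svm(sc$train[, feats, drop = FALSE], factor(y[-i]),
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- stats::predict(fit, sc$test[, feats, drop = FALSE])
      correct[i, s] <- as.integer(as.character(pred) == as.character(y[i]))
    }
  }
  acc <- colMeans(correct)
  names(acc) <- as.character(seq_len(p))
  opt <- which(acc == max(acc))[1]  # ties -> smallest size
  structure(list(ranking = full_rank,
                 elimination_order = rev(full_rank),
                 accuracy_curve = acc,
                 optimal_size = as.integer(opt),
                 optimal_set = full_rank[seq_len(opt)]),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("SVM-RFE (LOOCV): optimal %d feature(s), accuracy %.3f\n",
              x$optimal_size, max(x$accuracy_curve)))
  cat("  optimal set:", paste(x$optimal_set, collapse = ", "), "\n")
  cat("  accuracy by size:",
      paste(sprintf("%s:%.2f", names(x$accuracy_curve), x$accuracy_curve),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.rfe_result <- function(x, ...) {
  sizes <- as.integer(names(x$accuracy_curve))
  graphics::plot(sizes, x$accuracy_curve, type = "b",
                 xlab = "number of features", ylab = "LOOCV accuracy",
                 main = "SVM-RFE feature selection", ...)
  graphics::points(x$optimal_size, x$accuracy_curve[x$optimal_size],
                   col = "red", pch = 19)
  invisible(x)
}

#' Random-forest Gini importance ranking
#'
#' Classification random forest (bootstrap CART trees, sqrt(p) candidate
#' features per split) with the Mean Decrease Gini importance accumulated
#' per feature. The default selection rule keeps every feature with
#' positive importance; `top_k` keeps only the k most important.
#'
#' @param x Sample-by-feature matrix.
#' @param y Binary labels.
#' @param ntree Number of trees, default 2000.
#' @param top_k Optional integer; keep only the top-k features.
#' @param seed Integer seed (forest growth is stochastic).
#' @return Object of class `importance_ranking`: `importance` (named,
#'   descending), `rank`, `selected_set`.
#' @export
rf_importance <- function(x, y, ntree = 2000L, top_k = NULL, seed = NULL) {
  if (ntree < 1) stop("ntree must be >= 1")
  d <- check_feature_matrix(x, y)
  with_seed(seed, {
    fit <- randomForest::randomForest(d$x, factor(d$y), ntree = ntree)
    imp <- fit$importance[, "MeanDecreaseGini"]
    ord <- order(-imp, names(imp))
    imp <- imp[ord]
    selected <- if (is.null(top_k)) names(imp)[imp > 0] else
      names(imp)[seq_len(min(top_k, length(imp)))]
    structure(list(importance = imp,
                   rank = stats::setNames(seq_along(imp), names(imp)),
                   selected_set = selected, ntree = as.integer(ntree)),
              class = "importance_ranking")
  })
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("Random-forest importance (ntree = %d):\n", x$ntree))
  for (f in names(x$importance)) {
    cat(sprintf("  %2d. %-10s MeanDecreaseGini %.3f\n", x$rank[[f]], f,
                x$importance[[f]]))
  }
  invisible(x)
}

#' Three-algorithm consensus feature set
#'
#' Exact intersection of the LASSO-stable, SVM-RFE-optimal and
#' random-forest-selected feature sets, ordered by the first set's order
#' (deterministic). An empty intersection is returned with a warning.
#'
#' @param lasso_set,svm_set,rf_set Character vectors over one universe.
#' @return Character vector (possibly empty).
#' @export
consensus_features <- function(lasso_set, svm_set, rf_set) {
  out <- lasso_set[lasso_set %in% svm_set & lasso_set %in% rf_set]
  if (!length(out)) warning("consensus intersection is empty")
  out
}

# L2-stabilized logistic regression by iteratively reweighted least squares.
# The small ridge penalty (not applied to the intercept) keeps the fit
# finite under complete separation, which is routine at n = 30.
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  xd <- cbind(`(Intercept)` = 1, x)
  p <- ncol(xd)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(xd, y - mu) - pen %*% beta
    hess <- crossprod(xd, xd * w) + pen
    step <- solve(hess, grad)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  stats::setNames(as.vector(beta), colnames(xd))
}

#' Logistic diagnostic model with ROC analysis
#'
#' Fits a logistic regression on the panel features with a small L2
#' stabilizer (default 1e-4) so the fit converges even under complete
#' separation, scores the training samples, and summarizes discrimination
#' by the Mann-Whitney AUC and the full ROC step curve.
#'
#' @param x Sample-by-feature matrix restricted to the panel.
#' @param y Binary labels.
#' @param lambda_l2 Ridge stabilizer, default 1e-4.
#' @return Object of class `panel_model`: `coefficients`, `scores`
#'   (linear predictor), `auc`, `roc` (data.frame `fpr`, `tpr`,
#'   `threshold`), plus the training data for `predict()`.
#' @export
fit_logistic_roc <- function(x, y, lambda_l2 = 1e-4) {
  d <- check_feature_matrix(x, y)
  if (ncol(d$x) < 1) stop("panel must be non-empty")
  beta <- ridge_logistic(d$x, d$y, lambda = lambda_l2)
  scores <- as.vector(cbind(1, d$x) %*% beta)
  structure(list(coefficients = beta, scores = scores,
                 auc = auc_mann_whitney(scores, d$y),
                 roc = roc_points(scores, d$y),
                 features = colnames(d$x), labels = d$y,
                 lambda_l2 = lambda_l2),
            class = "panel_model")
}

# ROC step points over all score thresholds, (0,0) to (1,1).
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, numeric(1))
  data.frame(fpr = fpr, tpr = tpr, threshold = thr)
}

#' @export
coef.panel_model <- function(object, ...) object$coefficients

#' @export
predict.panel_model <- function(object, newdata = NULL,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$scores
  } else {
    nd <- as.matrix(newdata)[, object$features, drop = FALSE]
    eta <- as.vector(cbind(1, nd) %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
print.panel_model <- function(x, ...) {
  cat("Logistic panel model (L2 stabilizer", format(x$lambda_l2), ")\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat("  in-sample AUC:", format(round(x$auc, 4)), "\n")
  invisible(x)
}

#' @export
plot.panel_model <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "false positive rate",
                 ylab = "true positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Permutation test for the in-sample AUC
#'
#' Permutes the class labels `B` times, refits the stabilized logistic model
#' on the fixed panel each time, and recomputes the in-sample AUC. The
#' permutation p-value is `(1 + #(AUC_perm >= AUC_obs)) / (1 + B)`, with
#' attainable minimum `1 / (B + 1)`.
#'
#' @param x Sample-by-feature matrix restricted to the panel.
#' @param y Binary labels.
#' @param B Number of permutations, default 1000.
#' @param lambda_l2 Ridge stabilizer for each refit.
#' @param seed Integer seed.
#' @return List: `observed_auc`, `p_value`, `B`, `null_aucs`.
#' @export
permutation_test_auc <- function(x, y, B = 1000L, lambda_l2 = 1e-4,
                                 seed = NULL) {
  if (B < 1) stop("B must be >= 1")
  d <- check_feature_matrix(x, y)
  obs <- fit_logistic_roc(d$x, d$y, lambda_l2)$auc
  with_seed(seed, {
    null_aucs <- vapply(seq_len(B), function(b) {
      yp <- sample(d$y)
      beta <- ridge_logistic(d$x, yp, lambda = lambda_l2)
      auc_mann_whitney(as.vector(cbind(1, d$x) %*% beta), yp)
    }, numeric(1))
    p <- (1 + sum(null_aucs >= obs - 1e-12)) / (1 + B)
    list(observed_auc = obs, p_value = p, B = as.integer(B),
         null_aucs = null_aucs)
  })
}

#' Run the full tri-algorithm biomarker consensus
#'
#' Applies LASSO stability selection, SVM-RFE with LOOCV, and random-forest
#' Gini importance to the candidate feature matrix, intersects the three
#' selected sets, fits the stabilized logistic model on the consensus panel,
#' and validates its AUC by label permutation.
#'
#' @param x Sample-by-feature matrix (candidate genes as columns).
#' @param y Binary labels (1 = case).
#' @param B_stability Bootstrap iterations for stability selection.
#' @param stability_threshold Stability cutoff (strict `>`).
#' @param ntree Random-forest trees.
#' @param B_permutation Label permutations for the AUC test.
#' @param svm_cost Linear-SVM cost.
#' @param seed Master seed; per-algorithm seeds are derived from it.
#' @return Object of class `consensus_panel`: the three selection results,
#'   `panel`, `model` (`panel_model` or NULL if the panel is empty),
#'   `auc`, `permutation`.
#' @export
ml_consensus <- function(x, y, B_stability = 100L, stability_threshold = 0.6,
                         ntree = 2000L, B_permutation = 1000L, svm_cost = 1,
                         seed = 1L) {
  d <- check_feature_matrix(x, y)
  stab <- lasso_stability_selection(d$x, d$y, B = B_stability,
                                    threshold = stability_threshold,
                                    seed = derive_seed(seed, 1L))
  rfe <- svm_rfe_loocv(d$x, d$y, cost = svm_cost)
  rf <- rf_importance(d$x, d$y, ntree = ntree, seed = derive_seed(seed, 2L))
  panel <- consensus_features(stab$stable_set, rfe$optimal_set,
                              rf$selected_set)
  model <- NULL
  perm <- NULL
  auc <- NA_real_
  if (length(panel)) {
    xp <- d$x[, panel, drop = FALSE]
    model <- fit_logistic_roc(xp, d$y)
    auc <- model$auc
    perm <- permutation_test_auc(xp, d$y, B = B_permutation,
                                 seed = derive_seed(seed, 3L))
  }
  structure(list(lasso = stab, svm = rfe, rf = rf, panel = panel,
                 model = model, auc = auc, permutation = perm,
                 seed = as.integer(seed)),
            class = "consensus_panel")
}

#' @export
print.consensus_panel <- function(x, ...) {
  cat("Tri-algorithm consensus\n")
  cat("  LASSO stable set:   ", paste(x$lasso$stable_set, collapse = ", "), "\n")
  cat("  SVM-RFE optimal set:", paste(x$svm$optimal_set, collapse = ", "), "\n")
  cat("  RF selected set:    ", paste(x$rf$selected_set, collapse = ", "), "\n")
  cat("  consensus panel:    ",
      if (length(x$panel)) paste(x$panel, collapse = ", ") else "(empty)", "\n")
  if (!is.null(x$model)) {
    cat(sprintf("  in-sample AUC %.3f, permutation p %.4g (B = %d)\n",
                x$auc, x$permutation$p_value, x$permutation$B))
  }
  invisible(x)
}

#' @export
summary.consensus_panel <- function(object, ...) {
  print(object)
  cat("\nSelection probabilities:\n")
  print(round(sort(object$lasso$selection_probability, decreasing = TRUE), 3))
  cat("\nLOOCV accuracy by subset size:\n")
  print(round(object$svm$accuracy_curve, 3))
  invisible(object)
}

#' @export
coef.consensus_panel <- function(object, ...) {
  if (is.null(object$model)) stop("empty panel: no model was fitted")
  object$model$coefficients
}

#' @export
predict.consensus_panel <- function(object, newdata = NULL, ...) {
  if (is.null(object$model)) stop("empty panel: no model was fitted")
  predict(object$model, newdata = newdata, ...)
}
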