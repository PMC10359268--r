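# Slide-level prediction from morphometric moments: each slide is summarized
# by the mean and unbiased variance of every feature over its cells (per cell
# type), optionally joined with blood counts, and the four diagnostic tasks
# are classified with cross-validated elastic-net logistic regression.

#' Morphometric moments of a slide bag
#'
#' @param bag A [slide_bag()].
#' @return One-row tibble: `slide_id`, condition, cell counts, blood counts,
#'   task labels, and `wbc_mean_*`, `wbc_var_*`, `rbc_mean_*`, `rbc_var_*`
#'   moment columns (variance uses the n-1 denominator; moments are NA when
#'   the cell type has fewer than 2 cells).
#' @export
compute_moments <- function(bag) {
  stopifnot(inherits(bag, "slide_bag"))
  if (nrow(bag$wbc_features) + nrow(bag$rbc_features) == 0) {
    stop("empty bag: no cells in slide ", bag$slide_id, call. = FALSE)
  }
  one_type <- function(X, prefix) {
    d <- ncol(X)
    nms <- colnames(X) %||% sprintf("f%02d", seq_len(d))
    if (nrow(X) >= 2) {
      m <- colMeans(X)
      v <- apply(X, 2, stats::var)
    } else if (nrow(X) == 1) {
      m <- X[1, ]
      v <- rep(NA_real_, d)
    } else {
      m <- rep(NA_real_, d)
      v <- rep(NA_real_, d)
    }
    stats::setNames(c(m, v),
                    c(paste0(prefix, "_mean_", nms), paste0(prefix, "_var_", nms)))
  }
  moments <- c(one_type(bag$wbc_features, "wbc"),
               one_type(bag$rbc_features, "rbc"))
  tibble::tibble(
    slide_id = bag$slide_id,
    condition = bag$condition %||% NA_character_,
    n_wbc = nrow(bag$wbc_features), n_rbc = nrow(bag$rbc_features),
    wbcc = bag$blood_counts[["wbcc"]], hb = bag$blood_counts[["hb"]],
    plt = bag$blood_counts[["plt"]],
    !!!as.list(bag$labels), !!!as.list(moments))
}

#' @rdname compute_moments
#' @param bags List of slide bags.
#' @return Tibble with one row per slide.
#' @export
moments_table <- function(bags) dplyr::bind_rows(purrr::map(bags, compute_moments))

moment_columns <- function(summaries, use_blood_counts) {
  cols <- grep("^(wbc|rbc)_(mean|var)_", names(summaries), value = TRUE)
  if (use_blood_counts) cols <- c(cols, intersect(c("wbcc", "hb", "plt"),
                                                  names(summaries)))
  cols
}

stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Fit a cross-validated elastic-net model on slide summaries
#'
#' Features are z-scored with training-fold statistics only; folds are
#' stratified on the task label; the regularization path is selected per fold
#' by inner cross-validated deviance on the training fold. Missing values
#' (blood counts, under-populated moments) are imputed with the training-fold
#' median.
#'
#' @param summaries Tibble from [moments_table()].
#' @param task One of [cyto_tasks] (a label column in `summaries`).
#' @param folds Number of cross-validation folds.
#' @param use_blood_counts Append WBCC/Hb/Plt to the moments?
#' @param alpha Elastic-net mixing parameter (0 ridge .. 1 lasso).
#' @param lambda Optional fixed penalty; skips the inner selection (use 0 for
#'   the unpenalized limit).
#' @param seed Integer seed.
#' @return Object of class `moments_fit`: per-fold models, pooled
#'   cross-validated predictions and AUC, per-fold AUC, best fold, and a
#'   final model refitted on all eligible slides.
#' @export
fit_elastic_net_cv <- function(summaries, task = cyto_tasks[1], folds = 5,
                               use_blood_counts = FALSE, alpha = 0.5,
                               lambda = NULL, seed = 1L) {
  task <- match.arg(task, cyto_tasks)
  cols <- moment_columns(summaries, use_blood_counts)
  elig <- summaries[!is.na(summaries[[task]]), , drop = FALSE]
  y <- elig[[task]]
  if (min(table(y)) < folds) {
    stop("need at least `folds` eligible slides per class for task ", task,
         call. = FALSE)
  }
  X <- as.matrix(elig[, cols, drop = FALSE])
  fold_id <- stratified_folds(y, folds, seed)
  fit_one <- function(train_idx, fold_seed) {
    Xtr <- X[train_idx, , drop = FALSE]
    med <- apply(Xtr, 2, stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    for (j in seq_len(ncol(Xtr))) Xtr[is.na(Xtr[, j]), j] <- med[j]
    mu <- colMeans(Xtr)
    sdev <- pmax(apply(Xtr, 2, stats::sd), 1e-8)
    Xs <- sweep(sweep(Xtr, 2, mu), 2, sdev, "/")
    ytr <- y[train_idx]
    if (is.null(lambda)) {
      nf <- min(5L, min(table(ytr)))
      cvfit <- with_seed(fold_seed, suppressWarnings(glmnet::cv.glmnet(
        Xs, ytr, family = "binomial", alpha = alpha, nfolds = max(nf, 3L),
        standardize = FALSE)))
      lam <- cvfit$lambda.min
      fit <- cvfit$glmnet.fit
    } else {
      lam <- lambda
      fit <- suppressWarnings(
        glmnet::glmnet(Xs, ytr, family = "binomial", alpha = alpha,
                       lambda = lambda, standardize = FALSE,
                       thresh = 1e-12, maxit = 1e6))
    }
    list(fit = fit, lambda = lam, center = mu, scale = sdev, impute = med)
  }
  predict_fold <- function(fm, idx) {
    Xv <- X[idx, , drop = FALSE]
    for (j in seq_len(ncol(Xv))) Xv[is.na(Xv[, j]), j] <- fm$impute[j]
    Xs <- sweep(sweep(Xv, 2, fm$center), 2, fm$scale, "/")
    as.numeric(stats::predict(fm$fit, Xs, s = fm$lambda, type = "response"))
  }
  fold_models <- list()
  preds <- numeric(nrow(X))
  fold_auc <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- which(fold_id != k); va <- which(fold_id == k)
    if (length(unique(y[va])) < 2 || length(unique(y[tr])) < 2) {
      stop("stratification failure: a fold lacks a class", call. = FALSE)
    }
    fm <- fit_one(tr, seed + k)
    fold_models[[k]] <- fm
    preds[va] <- predict_fold(fm, va)
    fold_auc[k] <- auc_rank(preds[va], y[va])
  }
  final <- fit_one(seq_len(nrow(X)), seed)
  structure(list(
    task = task, columns = cols, use_blood_counts = use_blood_counts,
    alpha = alpha, folds = folds, fold_id = fold_id,
    fold_models = fold_models, final = final,
    predictions = tibble::tibble(slide_id = elig$slide_id, label = y,
                                 cv_prob = preds, fold = fold_id),
    cv_auc = auc_rank(preds, y), fold_auc = fold_auc,
    best_fold = which.max(fold_auc)),
    class = "moments_fit")
}

#' @export
print.moments_fit <- function(x, ...) {
  cat(sprintf("<moments_fit task=%s folds=%d cv AUC=%.3f>\n",
              x$task, x$folds, x$cv_auc))
  invisible(x)
}

#' Predict a slide's probability from a fitted moments model
#'
#' @param model A `moments_fit`.
#' @param summary One-row (or multi-row) tibble of slide summaries.
#' @param use Which model to apply: `"final"` (refit on all data) or
#'   `"best_fold"`.
#' @return Numeric vector of probabilities.
#' @export
predict_slide <- function(model, summary, use = c("final", "best_fold")) {
  use <- match.arg(use)
  fm <- if (use == "final") model$final else model$fold_models[[model$best_fold]]
  missing <- setdiff(model$columns, names(summary))
  if (length(missing)) {
    stop("summary missing model column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  Xv <- as.matrix(summary[, model$columns, drop = FALSE])
  for (j in seq_len(ncol(Xv))) Xv[is.na(Xv[, j]), j] <- fm$impute[j]
  Xs <- sweep(sweep(Xv, 2, fm$center), 2, fm$scale, "/")
  as.numeric(stats::predict(fm$fit, Xs, s = fm$lambda, type = "response"))
}

default_feature_groups <- function(columns) {
  dplyr::case_when(
    grepl("^rbc_mean_", columns) ~ "rbc_mean",
    grepl("^rbc_var_", columns) ~ "rbc_variance",
    grepl("^wbc_mean_", columns) ~ "wbc_mean",
    grepl("^wbc_var_", columns) ~ "wbc_variance",
    TRUE ~ "blood_counts"
  )
}

#' Share of prediction variance attributable to feature groups
#'
#' Decomposes the variance of the linear predictor into per-group terms;
#' covariance cross-terms are split equally between the two groups involved
#' (equivalently, each group's share is `Cov(eta_g, eta) / Var(eta)`).
#' Shares sum to 1 and are invariant to feature reordering.
#'
#' @param model A `moments_fit`.
#' @param summaries The slide summaries to evaluate on (defaults semantics:
#'   pass the training summaries).
#' @param groups Optional character vector assigning each model column to a
#'   group; defaults to RBC/WBC x mean/variance plus blood counts.
#' @return Tibble with `group` and `share`.
#' @export
feature_group_contribution <- function(model, summaries, groups = NULL) {
  fm <- model$final
  beta <- as.numeric(stats::coef(fm$fit, s = fm$lambda))[-1]
  if (all(beta == 0)) {
    stop("all coefficients are zero: contribution undefined", call. = FALSE)
  }
  elig <- summaries[!is.na(summaries[[model$task]]), , drop = FALSE]
  Xv <- as.matrix(elig[, model$columns, drop = FALSE])
  for (j in seq_len(ncol(Xv))) Xv[is.na(Xv[, j]), j] <- fm$impute[j]
  Xs <- sweep(sweep(Xv, 2, fm$center), 2, fm$scale, "/")
  groups <- groups %||% default_feature_groups(model$columns)
  stopifnot(length(groups) == length(model$columns))
  etas <- sapply(unique(groups), function(g) {
    sel <- groups == g
    Xs[, sel, drop = FALSE] %*% beta[sel]
  })
  eta <- rowSums(etas)
  v <- stats::var(eta)
  if (v < 1e-14) stop("linear predictor has zero variance", call. = FALSE)
  share <- apply(etas, 2, function(e) stats::cov(e, eta)) / v
  tibble::tibble(group = colnames(etas), share = as.numeric(share))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.moments_fit <- function(x, ...) {
  fm <- x$final
  co <- as.matrix(stats::coef(fm$fit, s = fm$lambda))
  tibble::tibble(term = rownames(co), estimate = co[, 1])
}

#' @export
glance.moments_fit <- function(x, ...) {
  tibble::tibble(task = x$task, folds = x$folds, n = nrow(x$predictions),
                 cv_auc = x$cv_auc, best_fold = x$best_fold,
                 best_fold_auc = max(x$fold_auc))
}

#' ROC curve of the pooled cross-validated predictions
#'
#' @param object A `moments_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.moments_fit <- function(object, ...) {
  p <- object$predictions
  th <- sort(unique(c(-Inf, p$cv_prob, Inf)), decreasing = TRUE)
  roc <- purrr::map_dfr(th, function(t) {
    tibble::tibble(tpr = mean(p$cv_prob[p$label == 1] >= t),
                   fpr = mean(p$cv_prob[p$label == 0] >= t))
  })
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = 2, color = "grey70") +
    ggplot2::geom_path(color = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%s: cross-validated AUC %.3f",
                                  object$task, object$cv_auc)) +
    ggplot2::theme_minimal()
}
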