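# Morphotype analysis: soft cell prototypes ("computational morphotypes")
# learned jointly with slide-level linear classifiers over per-slide
# morphotype proportions, trained end-to-end by gradient descent (Adam) on a
# masked multi-task cross-entropy, with stratified cross-validation and
# cross-fold stability selection of prototypes.
#
# Model: per cell type, cells x_i (standardized) are softly assigned to K
# prototypes m_k via a_ik = softmax_k(-tau * ||x_i - m_k||^2); the slide's
# morphotype proportions are the mean assignment row over its cells; each
# task head is a linear model over the concatenated WBC and RBC proportions
# (plus optionally standardized blood counts).

#' Initialize a morphotype model
#'
#' Prototypes are initialized by k-means on a subsample of the (standardized)
#' training cells; task heads start at zero and the assignment temperature at
#' 1. Deterministic given `seed`.
#'
#' @param bags Training list of [slide_bag()] objects.
#' @param K Named vector `c(wbc = , rbc = )` of prototype counts (typical
#'   choices 10, 25, 50).
#' @param tasks Character vector of tasks to model (subset of [cyto_tasks]).
#' @param use_blood_counts Concatenate standardized blood counts to the
#'   proportions?
#' @param seed Integer seed.
#' @param max_init_cells Subsample size for the k-means initialization.
#' @return Object of class `morphotype_model`.
#' @export
init_model <- function(bags, K = c(wbc = 10, rbc = 10), tasks = cyto_tasks,
                       use_blood_counts = FALSE, seed = 1L,
                       max_init_cells = 20000L) {
  stopifnot(all(K >= 2), all(tasks %in% cyto_tasks))
  # scalers come from slides eligible for at least one selected task, so
  # adding fully ineligible slides cannot perturb training
  elig <- purrr::map_lgl(bags, function(b) any(!is.na(b$labels[tasks])))
  ebags <- bags[elig]
  if (!length(ebags)) stop("no slides eligible for the selected tasks",
                           call. = FALSE)
  proto <- list(); scaler <- list()
  for (ct in c("wbc", "rbc")) {
    X <- do.call(rbind, purrr::map(ebags, ~ .x[[paste0(ct, "_features")]]))
    if (K[[ct]] > nrow(X)) {
      stop("K exceeds the number of training cells for ", ct, call. = FALSE)
    }
    mu <- colMeans(X)
    sdev <- pmax(apply(X, 2, stats::sd), 1e-8)
    Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
    sub <- with_seed(seed + match(ct, c("wbc", "rbc")), {
      idx <- if (nrow(Xs) > max_init_cells)
        sample.int(nrow(Xs), max_init_cells) else seq_len(nrow(Xs))
      km <- stats::kmeans(Xs[idx, , drop = FALSE], centers = K[[ct]],
                          nstart = 20, iter.max = 100)
      km$centers
    })
    proto[[ct]] <- unname(sub)
    scaler[[ct]] <- list(center = mu, scale = sdev)
  }
  bc_mat <- do.call(rbind, purrr::map(ebags, ~ .x$blood_counts))
  bc_scaler <- list(
    center = apply(bc_mat, 2, stats::median, na.rm = TRUE),
    scale = pmax(apply(bc_mat, 2, stats::sd, na.rm = TRUE), 1e-8))
  bc_scaler$center[!is.finite(bc_scaler$center)] <- 0
  bc_scaler$scale[!is.finite(bc_scaler$scale)] <- 1
  n_in <- sum(K) + if (use_blood_counts) 3L else 0L
  heads <- purrr::map(stats::setNames(tasks, tasks),
                      ~ list(w = numeric(n_in), b = 0))
  structure(list(K = K, prototypes = proto, tau = c(wbc = 1, rbc = 1),
                 heads = heads, tasks = tasks, scaler = scaler,
                 bc_scaler = bc_scaler, use_blood_counts = use_blood_counts),
            class = "morphotype_model")
}

#' @export
print.morphotype_model <- function(x, ...) {
  cat(sprintf("<morphotype_model K_wbc=%d K_rbc=%d tasks=%s%s>\n",
              x$K[["wbc"]], x$K[["rbc"]], paste(x$tasks, collapse = ","),
              if (x$use_blood_counts) " +blood_counts" else ""))
  invisible(x)
}

standardize_cells <- function(model, X, cell_type) {
  s <- model$scaler[[cell_type]]
  sweep(sweep(X, 2, s$center), 2, s$scale, "/")
}

#' Soft assignment of cells to morphotypes
#'
#' `a_ik = softmax_k(-tau * ||x_i - m_k||^2)`; every row lies on the simplex.
#'
#' @param model A `morphotype_model`.
#' @param X Cell feature matrix, already standardized with the model's
#'   statistics (see `standardize = TRUE` to apply them here).
#' @param cell_type `"wbc"` or `"rbc"`.
#' @param standardize Apply the model's feature scaling first?
#' @return n x K assignment matrix with rows summing to 1.
#' @export
soft_assign <- function(model, X, cell_type = c("wbc", "rbc"),
                        standardize = FALSE) {
  cell_type <- match.arg(cell_type)
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite features", call. = FALSE)
  if (standardize) X <- standardize_cells(model, X, cell_type)
  M <- model$prototypes[[cell_type]]
  if (ncol(X) != ncol(M)) {
    stop("feature dimension mismatch with prototypes", call. = FALSE)
  }
  D <- outer(rowSums(X^2), rep(1, nrow(M))) +
    outer(rep(1, nrow(X)), rowSums(M^2)) - 2 * X %*% t(M)
  Z <- -model$tau[[cell_type]] * pmax(D, 0)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Per-slide morphotype proportions
#'
#' @param assignments n x K soft-assignment matrix.
#' @param slide_ids Slide id per row.
#' @return Matrix (slides x K) of proportion vectors, each summing to 1; row
#'   names are the slide ids.
#' @export
slide_proportions <- function(assignments, slide_ids) {
  if (!nrow(assignments)) stop("no cells: empty slide", call. = FALSE)
  counts <- table(slide_ids)
  P <- rowsum(assignments, slide_ids)
  sweep(P, 1, as.numeric(counts[rownames(P)]), "/")
}

# standardized blood-count vector (median-imputed) for one bag
bag_bc <- function(model, bag) {
  b <- bag$blood_counts[c("wbcc", "hb", "plt")]
  b[is.na(b)] <- model$bc_scaler$center[is.na(b)]
  as.numeric((b - model$bc_scaler$center) / model$bc_scaler$scale)
}

# proportions + input vector for one bag (a missing cell type contributes a
# zero block)
bag_input <- function(model, bag) {
  blocks <- list()
  for (ct in c("wbc", "rbc")) {
    X <- bag[[paste0(ct, "_features")]]
    if (nrow(X) == 0) {
      blocks[[ct]] <- rep(0, model$K[[ct]])
    } else {
      A <- soft_assign(model, X, ct, standardize = TRUE)
      blocks[[ct]] <- colMeans(A)
    }
  }
  inp <- c(blocks$wbc, blocks$rbc)
  if (model$use_blood_counts) inp <- c(inp, bag_bc(model, bag))
  inp
}

#' Per-task logits for one slide bag
#'
#' @param model A `morphotype_model`.
#' @param bag A [slide_bag()].
#' @return Named numeric vector of logits (one per configured task).
#' @export
mil_forward <- function(model, bag) {
  inp <- bag_input(model, bag)
  vapply(model$heads, function(h) sum(h$w * inp) + h$b, numeric(1))
}

# pack/unpack model parameters to a flat vector for the optimizer
pack_params <- function(model) {
  c(as.vector(model$prototypes$wbc), as.vector(model$prototypes$rbc),
    log(model$tau[["wbc"]]), log(model$tau[["rbc"]]),
    unlist(purrr::map(model$heads, ~ c(.x$w, .x$b)), use.names = FALSE))
}

unpack_params <- function(model, theta) {
  Kw <- model$K[["wbc"]]; Kr <- model$K[["rbc"]]
  dw <- ncol(model$prototypes$wbc); dr <- ncol(model$prototypes$rbc)
  i <- 0
  model$prototypes$wbc <- matrix(theta[i + seq_len(Kw * dw)], Kw); i <- i + Kw * dw
  model$prototypes$rbc <- matrix(theta[i + seq_len(Kr * dr)], Kr); i <- i + Kr * dr
  model$tau <- c(wbc = exp(theta[i + 1]), rbc = exp(theta[i + 2])); i <- i + 2
  n_in <- length(model$heads[[1]]$w)
  for (t in names(model$heads)) {
    model$heads[[t]]$w <- theta[i + seq_len(n_in)]
    model$heads[[t]]$b <- theta[i + n_in + 1]
    i <- i + n_in + 1
  }
  model
}

# loss and analytic gradient over all bags; cells are pre-standardized and
# concatenated per cell type for vectorized distance computations
mil_loss_grad <- function(model, data) {
  S <- data$n_slides
  Kw <- model$K[["wbc"]]; Kr <- model$K[["rbc"]]
  tasks <- model$tasks
  # forward
  fw <- list()
  P_all <- matrix(0, S, Kw + Kr)
  for (ct in c("wbc", "rbc")) {
    X <- data[[ct]]$X
    M <- model$prototypes[[ct]]
    tau <- model$tau[[ct]]
    D <- outer(rowSums(X^2), rep(1, nrow(M))) +
      outer(rep(1, nrow(X)), rowSums(M^2)) - 2 * X %*% t(M)
    D <- pmax(D, 0)
    Z <- -tau * D
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    A <- E / rowSums(E)
    P <- rowsum(A, data[[ct]]$slide) / data[[ct]]$counts_by_slide
    fw[[ct]] <- list(A = A, D = D, P = P)
    cols <- if (ct == "wbc") seq_len(Kw) else Kw + seq_len(Kr)
    P_all[data[[ct]]$slide_rows, cols] <- P
  }
  inputs <- if (model$use_blood_counts) cbind(P_all, data$bc) else P_all
  W <- do.call(cbind, purrr::map(model$heads, "w"))
  bvec <- vapply(model$heads, "[[", numeric(1), "b")
  logits <- sweep(inputs %*% W, 2, bvec, "+")
  probs <- sigmoid(logits)
  # masked multi-task BCE
  L <- 0
  G_logit <- matrix(0, S, length(tasks))
  for (ti in seq_along(tasks)) {
    y <- data$labels[, tasks[ti]]
    ok <- !is.na(y)
    if (!any(ok)) next
    p <- pmin(pmax(probs[ok, ti], 1e-12), 1 - 1e-12)
    L <- L + mean(-y[ok] * log(p) - (1 - y[ok]) * log(1 - p))
    G_logit[ok, ti] <- (p - y[ok]) / sum(ok)
  }
  # backward
  gW <- crossprod(inputs, G_logit)
  gb <- colSums(G_logit)
  G_inp <- G_logit %*% t(W)
  g_proto <- list(); g_logtau <- c(wbc = 0, rbc = 0)
  for (ct in c("wbc", "rbc")) {
    cols <- if (ct == "wbc") seq_len(Kw) else Kw + seq_len(Kr)
    GP <- G_inp[data[[ct]]$slide_rows, cols, drop = FALSE]
    A <- fw[[ct]]$A; D <- fw[[ct]]$D
    GA <- GP[data[[ct]]$slide_of_cell_row, , drop = FALSE] /
      data[[ct]]$counts_by_slide[data[[ct]]$slide_of_cell_row]
    GZ <- A * (GA - rowSums(GA * A))
    tau <- model$tau[[ct]]
    GD <- -tau * GZ
    X <- data[[ct]]$X
    M <- model$prototypes[[ct]]
    g_proto[[ct]] <- 2 * (colSums(GD) * M - crossprod(GD, X))
    g_logtau[[ct]] <- tau * sum(GZ * (-D))
  }
  grad <- c(as.vector(g_proto$wbc), as.vector(g_proto$rbc),
            g_logtau[["wbc"]], g_logtau[["rbc"]],
            unlist(purrr::map(seq_along(tasks), ~ c(gW[, .x], gb[.x])),
                   use.names = FALSE))
  list(loss = L, grad = grad)
}

# precompute standardized, concatenated training tensors for a bag list
mil_prepare <- function(model, bags) {
  S <- length(bags)
  data <- list(n_slides = S)
  for (ct in c("wbc", "rbc")) {
    Xs <- list(); slide <- integer(0)
    for (s in seq_len(S)) {
      X <- bags[[s]][[paste0(ct, "_features")]]
      if (nrow(X)) {
        Xs[[length(Xs) + 1]] <- standardize_cells(model, X, ct)
        slide <- c(slide, rep(s, nrow(X)))
      }
    }
    X <- do.call(rbind, Xs)
    slide_rows <- sort(unique(slide))
    counts <- as.numeric(table(factor(slide, levels = slide_rows)))
    data[[ct]] <- list(
      X = X, slide = slide, slide_rows = slide_rows,
      counts_by_slide = counts,
      slide_of_cell_row = match(slide, slide_rows))
  }
  data$bc <- do.call(rbind, purrr::map(bags, ~ bag_bc(model, .x)))
  data$labels <- do.call(rbind, purrr::map(bags, "labels"))
  data
}

#' Train a morphotype model by gradient descent
#'
#' Full-batch Adam on the masked multi-objective binary cross-entropy: each
#' task's term averages over its eligible slides only, and the total loss is
#' the sum over selected tasks. Two parameter groups use different learning
#' rates: the task heads (fast) and the prototypes/temperature (slow), so
#' that morphotypes stay anchored to the density structure found at
#' initialization while they fine-tune toward the tasks. A small ridge
#' penalty on the head weights bounds their growth so the loss reaches a
#' genuine plateau and early stopping engages. Deterministic given `seed`.
#'
#' @param model A `morphotype_model` (typically from [init_model()]).
#' @param bags Training bags.
#' @param lr_heads Adam learning rate for the task heads.
#' @param lr_prototypes Adam learning rate for prototypes and temperature.
#' @param weight_decay Ridge penalty on head weights (not intercepts).
#' @param epochs Maximum epochs.
#' @param patience Early-stop patience (epochs without smoothed improvement);
#'   `Inf` disables early stopping.
#' @param min_delta Minimum decrease of the running-mean smoothed loss that
#'   counts as an improvement.
#' @param seed Integer seed.
#' @return The trained model, with attribute `loss` (per-epoch trajectory).
#' @export
mil_train <- function(model, bags, lr_heads = 5e-2, lr_prototypes = 5e-4,
                      weight_decay = 1e-3, epochs = 500, patience = 50,
                      min_delta = 1e-4, seed = 1L) {
  stopifnot(inherits(model, "morphotype_model"))
  labels <- do.call(rbind, purrr::map(bags, "labels"))
  for (t in model$tasks) {
    y <- labels[, t]
    if (length(unique(stats::na.omit(y))) == 1) {
      stop("task ", t, " has a single class among eligible slides",
           call. = FALSE)
    }
  }
  data <- mil_prepare(model, bags)
  theta <- pack_params(model)
  n_proto <- length(model$prototypes$wbc) + length(model$prototypes$rbc) + 2L
  n_in <- length(model$heads[[1]]$w)
  lr_vec <- c(rep(lr_prototypes, n_proto),
              rep(lr_heads, length(theta) - n_proto))
  # ridge on head weights only (intercepts excluded)
  wd_mask <- c(rep(0, n_proto),
               rep(c(rep(1, n_in), 0), length(model$heads)))
  opt <- adam_init(length(theta), lr = 1)
  traj <- numeric(0)
  best <- Inf; stall <- 0
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      model <- unpack_params(model, theta)
      lg <- mil_loss_grad(model, data)
      traj <- c(traj, lg$loss)
      sm <- mean(utils::tail(traj, 25))
      if (sm < best - min_delta) { best <- sm; stall <- 0 } else stall <- stall + 1
      if (stall > patience) break
      opt <- adam_step(opt, lg$grad + weight_decay * wd_mask * theta)
      theta <- theta - lr_vec * opt$delta
    }
  })
  model <- unpack_params(model, theta)
  attr(model, "loss") <- traj
  model
}

#' Cross-validated morphotype analysis
#'
#' Slides are split into stratified folds on the primary (first) objective;
#' each fold's model is initialized and trained on the remaining slides and
#' evaluated on the held-out fold. The best fold is the one with the highest
#' mean held-out AUC over the objectives.
#'
#' @param bags List of [slide_bag()] objects.
#' @param K Prototype counts, named `wbc`/`rbc`.
#' @param objectives Tasks to train on (first = primary, used for
#'   stratification).
#' @param folds Number of folds.
#' @param use_blood_counts Include blood counts in the heads?
#' @param lr_heads,lr_prototypes,weight_decay,epochs,patience,min_delta
#'   Passed to [mil_train()].
#' @param seed Integer seed.
#' @return Object of class `morphotype_cv`: fold models, per-task pooled
#'   cross-validated AUC, per-fold AUC matrix, best fold id, and held-out
#'   predictions.
#' @export
crossvalidate <- function(bags, K = c(wbc = 10, rbc = 10),
                          objectives = cyto_tasks, folds = 5,
                          use_blood_counts = FALSE, lr_heads = 5e-2,
                          lr_prototypes = 5e-4, weight_decay = 1e-3,
                          epochs = 500, patience = 50, min_delta = 1e-4,
                          seed = 1L) {
  labels <- do.call(rbind, purrr::map(bags, "labels"))
  primary <- objectives[1]
  y <- labels[, primary]
  any_elig <- apply(labels[, objectives, drop = FALSE], 1,
                    function(r) any(!is.na(r)))
  idx <- which(any_elig)
  strat <- ifelse(is.na(y[idx]), 2L + seq_along(idx) %% folds, y[idx])
  fold_of <- integer(length(bags))
  fold_of[idx] <- stratified_folds(strat, folds, seed)
  fold_models <- list()
  preds <- list()
  fold_auc <- matrix(NA_real_, folds, length(objectives),
                     dimnames = list(NULL, objectives))
  for (k in seq_len(folds)) {
    tr_bags <- bags[fold_of != k & any_elig]
    va_bags <- bags[fold_of == k]
    ytr <- do.call(rbind, purrr::map(tr_bags, "labels"))[, primary]
    if (length(unique(stats::na.omit(ytr))) < 2) {
      stop("stratification failure on the primary task", call. = FALSE)
    }
    m0 <- init_model(tr_bags, K = K, tasks = objectives,
                     use_blood_counts = use_blood_counts, seed = seed + k)
    mk <- mil_train(m0, tr_bags, lr_heads = lr_heads,
                    lr_prototypes = lr_prototypes,
                    weight_decay = weight_decay, epochs = epochs,
                    patience = patience, min_delta = min_delta,
                    seed = seed + k)
    fold_models[[k]] <- mk
    pv <- do.call(rbind, purrr::map(va_bags, ~ sigmoid(mil_forward(mk, .x))))
    yl <- do.call(rbind, purrr::map(va_bags, "labels"))
    preds[[k]] <- tibble::tibble(
      slide_id = rep(purrr::map_chr(va_bags, "slide_id"),
                     times = length(objectives)),
      fold = k,
      task = rep(objectives, each = nrow(pv)),
      prob = as.numeric(pv[, objectives]),
      label = as.numeric(yl[, objectives]))
    for (t in objectives) {
      yy <- yl[, t]; ok <- !is.na(yy)
      if (sum(ok) >= 2 && length(unique(yy[ok])) == 2) {
        fold_auc[k, t] <- auc_rank(pv[ok, t], yy[ok])
      }
    }
  }
  pred_tbl <- dplyr::bind_rows(preds)
  cv_auc <- purrr::map_dbl(stats::setNames(objectives, objectives),
                           function(t) {
    pp <- dplyr::filter(pred_tbl, .data$task == t, !is.na(.data$label))
    if (length(unique(pp$label)) < 2) return(NA_real_)
    auc_rank(pp$prob, pp$label)
  })
  mean_auc <- rowMeans(fold_auc, na.rm = TRUE)
  structure(list(fold_models = fold_models, fold_of = fold_of,
                 objectives = objectives, K = K, folds = folds,
                 predictions = pred_tbl, cv_auc = cv_auc,
                 fold_auc = fold_auc, best_fold = which.max(mean_auc)),
            class = "morphotype_cv")
}

#' @export
print.morphotype_cv <- function(x, ...) {
  cat(sprintf("<morphotype_cv folds=%d best=%d>\n", x$folds, x$best_fold))
  print(round(x$cv_auc, 3))
  invisible(x)
}

cosine_matrix <- function(A, B) {
  An <- A / sqrt(rowSums(A^2))
  Bn <- B / sqrt(rowSums(B^2))
  An %*% t(Bn)
}

#' Cross-fold stability selection of morphotypes
#'
#' Prototypes of the reference fold are matched one-to-one against every
#' other fold's prototypes by solving the assignment problem that maximizes
#' total cosine similarity (in standardized feature space). A reference
#' morphotype is stable iff its matched similarity reaches `theta` in every
#' fold.
#'
#' @param cv A `morphotype_cv` (or a plain list of fold models).
#' @param theta Cosine-similarity stability threshold.
#' @param reference Reference fold id; defaults to the best-performing fold.
#' @return Object of class `stability_report`: per-cell-type match table and
#'   stable morphotype sets.
#' @export
stability_select <- function(cv, theta = 0.8, reference = NULL) {
  models <- if (inherits(cv, "morphotype_cv")) cv$fold_models else cv
  if (length(models) < 2) stop("need at least 2 fold models", call. = FALSE)
  reference <- reference %||%
    (if (inherits(cv, "morphotype_cv")) cv$best_fold else 1L)
  ref <- models[[reference]]
  others <- setdiff(seq_along(models), reference)
  matches <- list(); stable <- list()
  for (ct in c("wbc", "rbc")) {
    Mref <- ref$prototypes[[ct]]
    K <- nrow(Mref)
    rows <- list()
    for (f in others) {
      Mf <- models[[f]]$prototypes[[ct]]
      if (ncol(Mf) != ncol(Mref) || nrow(Mf) != K) {
        stop("fold models differ in K or feature dimension", call. = FALSE)
      }
      S <- cosine_matrix(Mref, Mf)
      asg <- solve_assignment(-S)
      rows[[length(rows) + 1]] <- tibble::tibble(
        cell_type = ct, morphotype = seq_len(K), fold = f,
        matched = asg, similarity = S[cbind(seq_len(K), asg)])
    }
    tab <- dplyr::bind_rows(rows)
    min_sim <- dplyr::summarise(dplyr::group_by(tab, .data$morphotype),
                                min_sim = min(.data$similarity))
    stable[[ct]] <- min_sim$morphotype[min_sim$min_sim >= theta]
    matches[[ct]] <- tab
  }
  structure(list(reference = reference, theta = theta,
                 matches = dplyr::bind_rows(matches),
                 stable = stable),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report ref=%d theta=%.2f stable: %d WCM, %d RCM>\n",
              x$reference, x$theta, length(x$stable$wbc),
              length(x$stable$rbc)))
  invisible(x)
}

#' @export
tidy.stability_report <- function(x, ...) x$matches

#' Predict with stable morphotypes only
#'
#' Proportions are restricted to the stable morphotypes of each cell type and
#' renormalized to sum to 1; head weights are restricted correspondingly.
#'
#' @param model A trained `morphotype_model`.
#' @param stable List with integer vectors `wbc` and `rbc` (e.g.
#'   `stability_report$stable`).
#' @param bag A [slide_bag()].
#' @return Named vector of per-task probabilities.
#' @export
predict_stable <- function(model, stable, bag) {
  kw <- stable$wbc; kr <- stable$rbc
  if (!length(kw) && !length(kr)) {
    stop("empty stable set", call. = FALSE)
  }
  Kw <- model$K[["wbc"]]
  inp <- bag_input(model, bag)
  pw <- inp[seq_len(Kw)][kw]
  pr <- inp[Kw + seq_len(model$K[["rbc"]])][kr]
  if (sum(pw) > 0) pw <- pw / sum(pw)
  if (sum(pr) > 0) pr <- pr / sum(pr)
  rest <- if (model$use_blood_counts) utils::tail(inp, 3) else numeric(0)
  newinp <- c(pw, pr, rest)
  sel <- c(kw, Kw + kr,
           if (model$use_blood_counts) sum(model$K) + 1:3 else integer(0))
  vapply(model$heads, function(h) {
    as.numeric(sigmoid(sum(h$w[sel] * newinp) + h$b))
  }, numeric(1))
}

#' @export
tidy.morphotype_model <- function(x, ...) {
  Kw <- x$K[["wbc"]]; Kr <- x$K[["rbc"]]
  input <- c(sprintf("wbc_cm%02d", seq_len(Kw)),
             sprintf("rbc_cm%02d", seq_len(Kr)),
             if (x$use_blood_counts) c("wbcc", "hb", "plt"))
  purrr::map_dfr(names(x$heads), function(t) {
    tibble::tibble(task = t, term = c(input, "(intercept)"),
                   estimate = c(x$heads[[t]]$w, x$heads[[t]]$b))
  })
}

#' @export
glance.morphotype_cv <- function(x, ...) {
  tibble::tibble(task = names(x$cv_auc), cv_auc = as.numeric(x$cv_auc),
                 folds = x$folds, best_fold = x$best_fold)
}

#' Heatmap of cross-fold prototype match similarities
#'
#' @param object A `stability_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.stability_report <- function(object, ...) {
  ggplot2::ggplot(object$matches,
                  ggplot2::aes(x = factor(.data$fold),
                               y = factor(.data$morphotype),
                               fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~ .data$cell_type, scales = "free_y") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = object$theta,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "fold", y = "reference morphotype",
                  fill = "cosine") +
    ggplot2::theme_minimal()
}
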