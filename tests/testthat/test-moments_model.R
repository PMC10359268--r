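make_summaries <- function(seed = 1, strong = TRUE) {
  des <- bag_design(conditions = c(control = 15, IDA = 8, MA = 7,
                                   MDS_SF3B1 = 8, MDS_other = 7),
                    cells_per_slide = c(60, 120), seed = seed)
  moments_table(simulate_bags(des)$bags)
}

test_that("moments are exact means and unbiased variances", {
  b <- slide_bag("s1", matrix(c(1, 2, 3), 3, 1,
                              dimnames = list(NULL, "f01")),
                 matrix(5, 3, 1, dimnames = list(NULL, "f01")),
                 condition = "control")
  m <- compute_moments(b)
  expect_equal(m$wbc_mean_f01, 2)
  expect_equal(m$wbc_var_f01, 1)
  expect_equal(m$rbc_var_f01, 0)

  # two-pass oracle on 1000 random cells
  set.seed(8)
  X <- matrix(rnorm(1000 * 5), 1000, 5,
              dimnames = list(NULL, sprintf("f%02d", 1:5)))
  b2 <- slide_bag("s2", X, X[1:10, ], condition = "control")
  m2 <- compute_moments(b2)
  for (j in 1:5) {
    mu <- sum(X[, j]) / 1000
    v <- sum((X[, j] - mu)^2) / 999
    expect_equal(m2[[paste0("wbc_mean_f0", j)]], mu, tolerance = 1e-10)
    expect_equal(m2[[paste0("wbc_var_f0", j)]], v, tolerance = 1e-10)
  }

  expect_error(compute_moments(slide_bag("e", matrix(0, 0, 3),
                                         matrix(0, 0, 3))), "empty")

  # single-cell slides flag variances as missing
  b3 <- slide_bag("s3", X[1, , drop = FALSE], X[1:2, ], condition = "control")
  m3 <- compute_moments(b3)
  expect_true(is.na(m3$wbc_var_f01))
  expect_false(is.na(m3$rbc_var_f01))
})

test_that("planted condition signal yields high cross-validated AUC", {
  summaries <- make_summaries(seed = 5)
  fit <- fit_elastic_net_cv(summaries, "disease_detection", folds = 5,
                            seed = 17)
  expect_gte(fit$cv_auc, 0.95)
  expect_equal(sort(unique(fit$fold_id)), 1:5)
  g <- glance(fit)
  expect_equal(g$cv_auc, fit$cv_auc)
})

test_that("label permutation drives the cross-validated AUC to 0.5", {
  summaries <- make_summaries(seed = 6)
  aucs <- sapply(1:20, function(i) {
    perm <- summaries
    set.seed(100 + i)
    perm$disease_detection <- sample(perm$disease_detection)
    fit_elastic_net_cv(perm, "disease_detection", folds = 5,
                       seed = 200 + i)$cv_auc
  })
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("the penalty-free limit matches the logistic regression oracle", {
  set.seed(3)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3)
  colnames(X) <- c("wbc_mean_a", "wbc_var_a", "rbc_mean_a")
  y <- rbinom(n, 1, plogis(0.8 * X[, 1] - 0.5 * X[, 3]))
  summaries <- tibble::tibble(slide_id = sprintf("s%02d", 1:n),
                              disease_detection = y,
                              tibble::as_tibble(X))
  fit <- fit_elastic_net_cv(summaries, "disease_detection", folds = 4,
                            lambda = 0, seed = 2)
  beta <- tidy(fit)
  Xs <- scale(X)
  oracle <- glm(y ~ Xs, family = binomial())
  expect_equal(unname(beta$estimate[match(colnames(X), beta$term)]),
               unname(coef(oracle)[-1]), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(unname(beta$estimate[beta$term == "(Intercept)"]),
               unname(coef(oracle)[1]), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("standardization never leaks validation-fold statistics", {
  summaries <- make_summaries(seed = 9)
  # sentinel: one slide carries an extreme value in one moment column
  col <- "wbc_mean_f01"
  outlier <- 3
  summaries[[col]] <- 0
  summaries[[col]][outlier] <- 1000
  fit <- fit_elastic_net_cv(summaries, "disease_detection", folds = 5,
                            seed = 4)
  k_out <- fit$fold_id[!is.na(summaries$disease_detection)][outlier]
  j <- match(col, fit$columns)
  for (k in seq_len(5)) {
    if (k == k_out) {
      # outlier is held out: its fold's training scaler must not see it
      expect_equal(unname(fit$fold_models[[k]]$center[j]), 0)
    } else {
      expect_gt(fit$fold_models[[k]]$center[j], 1)
    }
  }
})

test_that("prediction equals the logistic oracle on the stored scaler", {
  summaries <- make_summaries(seed = 12)
  fit <- fit_elastic_net_cv(summaries, "disease_classification", folds = 3,
                            seed = 3)
  fm <- fit$final
  idx <- sample(nrow(summaries), 10)
  probs <- predict_slide(fit, summaries[idx, ])
  co <- as.matrix(coef(fm$fit, s = fm$lambda))
  X <- as.matrix(summaries[idx, fit$columns])
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- fm$impute[j]
  eta <- co[1] + scale(X, fm$center, fm$scale) %*% co[-1]
  expect_equal(probs, as.numeric(plogis(eta)), tolerance = 1e-10)

  expect_error(predict_slide(fit, summaries[idx, 1:4]), "missing")
})

test_that("group contributions decompose the linear predictor variance", {
  # two independent groups with equal variance share 50/50
  set.seed(14)
  n <- 400
  tb <- tibble::tibble(slide_id = as.character(1:n),
                       disease_detection = rep(c(0, 1), n / 2),
                       wbc_mean_a = rnorm(n), rbc_mean_a = rnorm(n))
  fit <- fit_elastic_net_cv(tb, "disease_detection", folds = 3, lambda = 0,
                            seed = 5)
  fit$final$fit$beta[] <- c(1, 1)  # force equal unit coefficients
  contrib <- feature_group_contribution(fit, tb)
  expect_equal(sum(contrib$share), 1, tolerance = 1e-9)
  expect_equal(contrib$share[contrib$group == "wbc_mean"], 0.5,
               tolerance = 0.1)

  # single nonzero group takes share 1
  fit$final$fit$beta[] <- c(1, 0)
  contrib <- feature_group_contribution(fit, tb)
  expect_equal(contrib$share[contrib$group == "wbc_mean"], 1,
               tolerance = 1e-9)

  # correlated two-variable case against the closed form on a 2x2 covariance
  rho <- 0.6
  set.seed(15)
  z <- matrix(rnorm(n * 2), n) %*% chol(matrix(c(1, rho, rho, 1), 2))
  tb2 <- tibble::tibble(slide_id = as.character(1:n),
                        disease_detection = rep(c(0, 1), n / 2),
                        wbc_mean_a = z[, 1], rbc_mean_a = z[, 2])
  fit2 <- fit_elastic_net_cv(tb2, "disease_detection", folds = 3, lambda = 0,
                             seed = 6)
  b <- c(2, 1)
  fit2$final$fit$beta[] <- b
  contrib <- feature_group_contribution(fit2, tb2)
  X <- scale(z)
  S <- stats::cov(X)
  expected_w <- (b[1]^2 * S[1, 1] + b[1] * b[2] * S[1, 2]) /
    as.numeric(t(b) %*% S %*% b)
  got <- contrib$share[contrib$group == "wbc_mean"]
  expect_equal(got, expected_w, tolerance = 1e-9)

  # invariant to feature reordering
  tb3 <- tb2[, c("slide_id", "disease_detection", "rbc_mean_a", "wbc_mean_a")]
  fit3 <- fit_elastic_net_cv(tb3, "disease_detection", folds = 3, lambda = 0,
                             seed = 6)
  fit3$final$fit$beta[] <- rev(b)
  contrib3 <- feature_group_contribution(fit3, tb3)
  expect_equal(contrib3$share[contrib3$group == "wbc_mean"], got,
               tolerance = 1e-9)

  fit3$final$fit$beta[] <- c(0, 0)
  expect_error(feature_group_contribution(fit3, tb3), "zero")
})
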