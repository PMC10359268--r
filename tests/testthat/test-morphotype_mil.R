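# Small planted designs keep these unit tests fast; the full-scale parameter
# recovery study lives in the acceptance suite.

small_bags <- function(seed = 3, n = 10, cells = c(30, 60)) {
  des <- bag_design(conditions = c(control = n, MDS_other = n),
                    cells_per_slide = cells,
                    K_true = c(wbc = 4, rbc = 4), separation = 6,
                    mixing = list(
                      wbc = list(control = c(.4, .4, .1, .1),
                                 MDS_other = c(.1, .1, .4, .4)),
                      rbc = list(control = c(.4, .4, .1, .1),
                                 MDS_other = c(.1, .1, .4, .4))),
                    seed = seed)
  simulate_bags(des)$bags
}

# a hand-buildable model: identity scalers, chosen prototypes
toy_model <- function(prototypes_wbc, prototypes_rbc = prototypes_wbc,
                      tau = 1, tasks = "disease_detection") {
  bags <- small_bags(n = 2, cells = c(10, 10))
  m <- init_model(bags, K = c(wbc = nrow(prototypes_wbc),
                              rbc = nrow(prototypes_rbc)),
                  tasks = tasks, seed = 1)
  d_w <- ncol(prototypes_wbc); d_r <- ncol(prototypes_rbc)
  m$prototypes$wbc <- prototypes_wbc
  m$prototypes$rbc <- prototypes_rbc
  m$tau <- c(wbc = tau, rbc = tau)
  m$scaler$wbc <- list(center = rep(0, d_w), scale = rep(1, d_w))
  m$scaler$rbc <- list(center = rep(0, d_r), scale = rep(1, d_r))
  m$heads <- purrr::map(m$heads, function(h) {
    list(w = numeric(sum(m$K)), b = 0)
  })
  m
}

test_that("initialization is deterministic and validates K against cells", {
  bags <- small_bags()
  m1 <- init_model(bags, K = c(wbc = 5, rbc = 5), seed = 7)
  m2 <- init_model(bags, K = c(wbc = 5, rbc = 5), seed = 7)
  expect_identical(m1$prototypes, m2$prototypes)
  expect_equal(m1$tau, c(wbc = 1, rbc = 1))
  expect_true(all(vapply(m1$heads, function(h) all(h$w == 0), logical(1))))

  expect_error(init_model(bags, K = c(wbc = 1e6, rbc = 5)), "exceeds")
})

test_that("soft assignments follow the softmax over negative squared distance", {
  # 1-d, prototypes {0, 2}, tau = 1, x = 0.5: a1 = sigmoid(d2^2 - d1^2)
  m <- toy_model(matrix(c(0, 2), 2, 1), matrix(c(0, 2), 2, 1))
  a <- soft_assign(m, matrix(0.5, 1, 1), "wbc")
  expect_equal(a[1, 1], plogis(2.0), tolerance = 1e-12)
  expect_equal(a[1, 1], 0.8808, tolerance = 1e-4)

  # at a prototype with high temperature: one-hot
  m_hot <- toy_model(matrix(c(0, 10), 2, 1), tau = 50)
  a <- soft_assign(m_hot, matrix(0, 1, 1), "wbc")
  expect_gte(a[1, 1], 0.99)

  # equidistant from all prototypes: uniform
  protos <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  m_eq <- toy_model(protos, protos)
  a <- soft_assign(m_eq, matrix(0, 1, 2), "wbc")
  expect_equal(as.numeric(a), rep(0.25, 4))

  expect_error(soft_assign(m, matrix(NA_real_, 1, 1), "wbc"), "finite")
  expect_error(soft_assign(m, matrix(0, 1, 3), "wbc"), "dimension")
})

test_that("assignment rows and slide proportions live on the simplex", {
  bags <- small_bags(seed = 9, n = 4)
  m <- init_model(bags, K = c(wbc = 6, rbc = 6), seed = 2)
  X <- standardize_cells <- cytomorph:::standardize_cells(
    m, bags[[1]]$wbc_features, "wbc")
  A <- soft_assign(m, X, "wbc")
  expect_true(all(A >= 0))
  expect_true(all(abs(rowSums(A) - 1) < 1e-9))

  ids <- rep(c("a", "b", "c"), length.out = nrow(A))
  P <- slide_proportions(A, ids)
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))

  # brute-force oracle: per-slide column means
  for (s in c("a", "b", "c")) {
    expect_equal(P[s, ], colMeans(A[ids == s, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  expect_equal(slide_proportions(A[1, , drop = FALSE], "solo")[1, ], A[1, ])
  expect_error(slide_proportions(A[0, , drop = FALSE], character(0)),
               "empty")
})

test_that("forward logits are the linear head over concatenated proportions", {
  bags <- small_bags(seed = 5, n = 3)
  m <- init_model(bags, K = c(wbc = 4, rbc = 4), seed = 3)

  # zero heads: all logits zero, probabilities one half
  lg <- mil_forward(m, bags[[1]])
  expect_equal(unname(lg), rep(0, 4))

  # unit weight on one morphotype reproduces its proportion as the logit
  A <- soft_assign(m, bags[[1]]$wbc_features, "wbc", standardize = TRUE)
  p3 <- mean(A[, 3])
  m1 <- m
  m1$heads$disease_detection$w[3] <- 1
  expect_equal(unname(mil_forward(m1, bags[[1]])["disease_detection"]), p3)

  # independent recomputation on 5 random bags with random heads
  set.seed(77)
  for (t in names(m$heads)) {
    m$heads[[t]]$w <- rnorm(8)
    m$heads[[t]]$b <- rnorm(1)
  }
  for (b in bags[sample(length(bags), 5, replace = TRUE)]) {
    pa <- colMeans(soft_assign(m, b$wbc_features, "wbc", standardize = TRUE))
    pb <- colMeans(soft_assign(m, b$rbc_features, "rbc", standardize = TRUE))
    inp <- c(pa, pb)
    manual <- vapply(m$heads, function(h) sum(h$w * inp) + h$b, numeric(1))
    expect_equal(mil_forward(m, b), manual, tolerance = 1e-12)
  }
})

test_that("training is deterministic, reduces the loss, and can be frozen", {
  bags <- small_bags(seed = 6, n = 8)
  m0 <- init_model(bags, K = c(wbc = 4, rbc = 4),
                   tasks = "disease_detection", seed = 4)

  frozen <- mil_train(m0, bags, lr_heads = 0, lr_prototypes = 0, epochs = 5)
  expect_equal(frozen$prototypes, m0$prototypes)
  expect_equal(frozen$heads, m0$heads)

  # multi-objective loss at zero-head initialization is n_tasks * ln 2
  m_all <- init_model(bags, K = c(wbc = 4, rbc = 4), tasks = cyto_tasks,
                      seed = 4)
  expect_error(mil_train(m_all, bags, epochs = 1), "single class")
  mixed <- simulate_bags(bag_design(
    conditions = c(control = 4, IDA = 4, MDS_other = 4),
    cells_per_slide = c(20, 30), seed = 14))$bags
  m_two <- init_model(mixed, K = c(wbc = 4, rbc = 4),
                      tasks = c("disease_detection", "disease_classification"),
                      seed = 4)
  tr <- attr(mil_train(m_two, mixed, epochs = 1), "loss")
  expect_equal(tr[1], 2 * log(2), tolerance = 1e-12)

  t1 <- mil_train(m0, bags, epochs = 120, seed = 5)
  t2 <- mil_train(m0, bags, epochs = 120, seed = 5)
  expect_identical(t1$prototypes, t2$prototypes)
  traj <- attr(t1, "loss")
  expect_lt(traj[length(traj)], traj[1])

  # separable planted bags: training AUC >= 0.95
  probs <- vapply(bags, function(b) plogis(mil_forward(t1, b))[1], numeric(1))
  y <- vapply(bags, function(b) b$labels[["disease_detection"]], numeric(1))
  expect_gte(auc_rank(probs, y), 0.95)
})

test_that("slides ineligible for every selected task change nothing", {
  bags <- small_bags(seed = 8, n = 6)
  # mds_subtyping is defined for neither control nor MDS_other... use
  # disease_classification (defined only for MDS/anemia): controls are inert
  des <- bag_design(conditions = c(IDA = 5, MDS_other = 5, control = 4),
                    cells_per_slide = c(20, 30), seed = 12)
  all_bags <- simulate_bags(des)$bags
  is_ctrl <- vapply(all_bags, function(b) b$condition == "control", logical(1))
  elig <- all_bags[!is_ctrl]

  m <- init_model(all_bags, K = c(wbc = 3, rbc = 3),
                  tasks = "disease_classification", seed = 2)
  d_all <- cytomorph:::mil_prepare(m, all_bags)
  d_elig <- cytomorph:::mil_prepare(m, elig)
  g_all <- cytomorph:::mil_loss_grad(m, d_all)
  g_elig <- cytomorph:::mil_loss_grad(m, d_elig)
  expect_equal(g_all$loss, g_elig$loss, tolerance = 1e-12)
  expect_equal(g_all$grad, g_elig$grad, tolerance = 1e-12)
})

test_that("cross-validation folds partition the eligible slides", {
  bags <- small_bags(seed = 13, n = 10, cells = c(20, 30))
  cv <- crossvalidate(bags, K = c(wbc = 4, rbc = 4),
                      objectives = "disease_detection", folds = 4,
                      epochs = 60, seed = 21)
  expect_equal(sort(unique(cv$fold_of)), 1:4)
  expect_length(cv$fold_of, length(bags))
  expect_equal(sum(table(cv$fold_of)), length(bags))
  expect_true(cv$best_fold %in% 1:4)
  expect_true(all(cv$predictions$prob >= 0 & cv$predictions$prob <= 1))
})

test_that("multi-objective cross-validation evaluates every task", {
  mixed <- simulate_bags(bag_design(
    conditions = c(control = 6, IDA = 6, MDS_other = 6),
    cells_per_slide = c(20, 30), seed = 17))$bags
  objectives <- c("disease_detection", "disease_classification")
  cv <- crossvalidate(mixed, K = c(wbc = 3, rbc = 3),
                      objectives = objectives, folds = 3, epochs = 40,
                      seed = 6)
  expect_setequal(unique(cv$predictions$task), objectives)
  expect_equal(nrow(cv$predictions),
               length(objectives) * sum(cv$fold_of > 0))
  expect_equal(colnames(cv$fold_auc), objectives)
  # eligibility masks survive into the predictions: controls have no
  # disease_classification label
  ctrl <- grepl("^control", cv$predictions$slide_id)
  dc <- cv$predictions$task == "disease_classification"
  expect_true(all(is.na(cv$predictions$label[ctrl & dc])))
})

test_that("stability matching finds repeated prototypes exactly", {
  protos <- list(
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)))  # same set, permuted

  mk <- function(M) {
    m <- toy_model(M, M)
    m
  }
  models <- list(mk(protos[[1]]), mk(protos[[2]]), mk(protos[[1]]))
  rep_all <- stability_select(models, theta = 0.8, reference = 1)
  expect_equal(rep_all$stable$wbc, 1:3)
  expect_true(all(rep_all$matches$similarity > 0.999))

  # exactly 2 of 3 prototypes repeat in the other fold
  other <- rbind(c(1, 0, 0), c(0, 1, 0), c(0.6, -0.6, 0.5))
  models2 <- list(mk(protos[[1]]), mk(other))
  rep2 <- stability_select(models2, theta = 0.8, reference = 1)
  expect_equal(rep2$stable$wbc, 1:2)

  expect_error(stability_select(models[1]), "at least 2")
})

test_that("independent random prototypes are essentially never stable", {
  set.seed(42)
  stable_counts <- replicate(20, {
    models <- lapply(1:3, function(i) {
      toy_model(matrix(rnorm(25 * 42), 25), matrix(rnorm(25 * 42), 25))
    })
    length(stability_select(models, theta = 0.8, reference = 1)$stable$wbc)
  })
  expect_lte(mean(stable_counts), 0.5)
})

test_that("prototype matching solves the assignment problem optimally", {
  set.seed(33)
  brute_best <- function(S) {
    n <- nrow(S)
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) for (r in perms(v[-i]))
        out[[length(out) + 1]] <- c(v[i], r)
      out
    }
    max(vapply(perms(seq_len(n)),
               function(p) sum(S[cbind(seq_len(n), p)]), numeric(1)))
  }
  for (i in 1:10) {
    A <- matrix(rnorm(5 * 7), 5)
    B <- matrix(rnorm(5 * 7), 5)
    S <- cytomorph:::cosine_matrix(A, B)
    asg <- cytomorph:::solve_assignment(-S)
    expect_equal(sum(S[cbind(1:5, asg)]), brute_best(S), tolerance = 1e-12)
  }
})

test_that("stable-only prediction renormalizes restricted proportions", {
  bags <- small_bags(seed = 19, n = 4)
  m <- init_model(bags, K = c(wbc = 4, rbc = 4),
                  tasks = "disease_detection", seed = 6)
  set.seed(3)
  m$heads$disease_detection$w <- rnorm(8)
  m$heads$disease_detection$b <- 0.3

  # full stable set reproduces mil_forward exactly
  all_stable <- list(wbc = 1:4, rbc = 1:4)
  expect_equal(predict_stable(m, all_stable, bags[[1]]),
               plogis(mil_forward(m, bags[[1]])), tolerance = 1e-12)

  # restricted: matches a brute-force recomputation
  st <- list(wbc = c(1, 3), rbc = c(2, 4))
  for (b in bags) {
    got <- predict_stable(m, st, b)
    pw <- colMeans(soft_assign(m, b$wbc_features, "wbc", standardize = TRUE))
    pr <- colMeans(soft_assign(m, b$rbc_features, "rbc", standardize = TRUE))
    pw <- pw[st$wbc] / sum(pw[st$wbc])
    pr <- pr[st$rbc] / sum(pr[st$rbc])
    expect_equal(sum(pw), 1, tolerance = 1e-12)
    w <- m$heads$disease_detection$w
    manual <- plogis(sum(w[st$wbc] * pw) + sum(w[4 + st$rbc] * pr) + 0.3)
    expect_equal(unname(got["disease_detection"]), manual, tolerance = 1e-12)
  }
  expect_error(predict_stable(m, list(wbc = integer(0), rbc = integer(0)),
                              bags[[1]]), "empty")
})
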