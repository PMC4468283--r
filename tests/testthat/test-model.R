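test_that("CFS merit reduces to |r_cf| for one feature and ignores sign", {
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(50, 0, 0.2)
  ccf <- abs(cor(X, y))[, 1]
  cff <- abs(cor(X))
  expect_equal(cfs_merit(ccf, cff, 1), ccf[["a"]])
  # sign flip of a feature leaves the merit unchanged
  X2 <- X; X2[, 2] <- -X2[, 2]
  ccf2 <- abs(cor(X2, y))[, 1]; cff2 <- abs(cor(X2))
  expect_equal(cfs_merit(ccf2, cff2, c(1, 2)), cfs_merit(ccf, cff, c(1, 2)),
               tolerance = 1e-12)
})

test_that("a planted signal feature is selected in every fold", {
  s <- synth_feature_table(60, c(sig = 1, n1 = 0, n2 = 0, n3 = 0, n4 = 0,
                                 n5 = 0, n6 = 0, n7 = 0, n8 = 0, n9 = 0),
                           noise_sd = 0.05, seed = 3)
  sel <- cfs_select(s$table, s$target, folds = 10, seed = 1)
  expect_equal(sel$ranking$feature[1], "sig")
  expect_equal(sel$ranking$frequency[1], 1.0)
})

test_that("best-first search equals exhaustive subset search on 8 features", {
  for (seed in c(9, 23, 41)) {
    s <- synth_feature_table(40, c(a = 1, b = 0.5, c = 0.3, d = 0, e = 0,
                                   f = 0, g = 0, h = 0),
                             noise_sd = 0.3, seed = seed)
    X <- as.matrix(s$table[-1])
    ccf <- abs(cor(X, s$target))[, 1]
    cff <- abs(cor(X))
    best_m <- -Inf; best_s <- NULL
    for (k in 1:255) {
      sub <- which(bitwAnd(k, 2^(0:7)) > 0)
      m <- cfs_merit(ccf, cff, sub)
      if (m > best_m) { best_m <- m; best_s <- sub }
    }
    bf <- voqual:::cfs_best_first(ccf, cff)
    expect_equal(bf$subset, best_s)
    expect_equal(bf$merit, best_m, tolerance = 1e-12)
  }
})

test_that("selection is deterministic given the seed", {
  s <- synth_feature_table(40, c(a = 1, b = -0.5, c = 0, d = 0, e = 0),
                           noise_sd = 0.3, seed = 4)
  s1 <- cfs_select(s$table, s$target, folds = 5, seed = 11)
  s2 <- cfs_select(s$table, s$target, folds = 5, seed = 11)
  expect_identical(s1$ranking, s2$ranking)
  expect_identical(s1$fold_subsets, s2$fold_subsets)
})

test_that("SVR recovers a noiseless linear model in original units", {
  set.seed(1)
  tbl <- data.frame(x1 = rnorm(50))
  y <- 2 * tbl$x1 + 1
  fit <- train_svr(tbl, y, "x1", C = 100, epsilon = 0.01)
  co <- coef(fit)
  expect_equal(unname(co["x1"]), 2, tolerance = 0.01)
  expect_equal(unname(co["(Intercept)"]), 1, tolerance = 0.02)
  expect_lt(max(abs(predict(fit, tbl) - y)), 0.02)
})

test_that("a constant target gives zero weights and the constant intercept", {
  set.seed(2)
  tbl <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  fit <- train_svr(tbl, rep(1.7, 30), c("x1", "x2"))
  expect_equal(unname(fit$weights), c(0, 0))
  expect_equal(fit$intercept, 1.7)
})

test_that("SMO reaches the quadratic-programming optimum", {
  skip_if_not_installed("kernlab")
  qp_objective <- function(Z, y, C, eps) {
    n <- length(y); K <- Z %*% t(Z)
    H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * n)
    sv <- kernlab::ipop(c = c(eps - y, eps + y), H = H,
                        A = matrix(c(rep(1, n), rep(-1, n)), 1), b = 0,
                        l = rep(0, 2 * n), u = rep(C, 2 * n), r = 0)
    th <- kernlab::primal(sv)
    beta <- th[1:n] - th[(n + 1):(2 * n)]
    0.5 * sum(beta * (K %*% beta)) + eps * sum(abs(beta)) - sum(y * beta)
  }
  for (rep in 1:6) {
    set.seed(rep)
    n <- sample(10:30, 1); p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    tbl <- as.data.frame(X); names(tbl) <- paste0("f", 1:p)
    fit <- train_svr(tbl, y, names(tbl), C = 1, epsilon = 0.1, tol = 1e-6)
    expect_lt(abs(fit$objective - qp_objective(scale(X), y, 1, 0.1)), 1e-4)
  }
})

test_that("doubling C leaves an interpolation-feasible fit unchanged", {
  set.seed(3)
  tbl <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  y <- 0.8 * tbl$x1 - 0.3 * tbl$x2 + 0.5
  f1 <- train_svr(tbl, y, c("x1", "x2"), C = 50, epsilon = 0.05, tol = 1e-8)
  f2 <- train_svr(tbl, y, c("x1", "x2"), C = 100, epsilon = 0.05, tol = 1e-8)
  expect_lt(max(abs(predict(f1, tbl) - predict(f2, tbl))), 1e-6)
})

test_that("prediction is the intercept at the standardized origin", {
  set.seed(4)
  tbl <- data.frame(a = rnorm(20), b = rnorm(20))
  fit <- train_svr(tbl, rnorm(20), c("a", "b"))
  origin <- data.frame(a = fit$center["a"], b = fit$center["b"])
  expect_equal(predict(fit, origin), fit$intercept, tolerance = 1e-9)
  expect_error(predict(fit, data.frame(a = 1)),
               class = "voq_validation_error")
})

test_that("preset registry matches the published weights", {
  reg <- preset_registry()
  expect_length(reg, 12)
  rb <- preset_model("R_best_I")
  # six prosodic predictors plus CFx
  expect_length(rb$weights, 7)
  expect_equal(sum(names(rb$weights) != "CFx"), 6)
  expect_equal(unname(rb$weights["CFx"]), 0.210, tolerance = 5e-4)
  expect_equal(unname(rb$weights["F0MinW"]), -0.446, tolerance = 5e-4)
  hb <- preset_model("H_best_I")
  expect_equal(unname(hb$weights["CQx"]), 0.643, tolerance = 5e-4)
  # every preset references only canonical feature names
  for (p in reg)
    expect_true(all(names(p$weights) %in% feature_names()))
  # unit standardized CFx under R_best_I scores exactly its weight
  z <- setNames(numeric(7), names(rb$weights))
  z["CFx"] <- 1
  expect_equal(preset_score(rb, z), 0.210)
})

test_that("evaluation returns perfect and inverted correlations", {
  ref <- c(0.2, 0.8, 1.5, 2.1, 2.9)
  ev <- evaluate_predictions(ref, ref)
  expect_equal(ev$r, 1); expect_equal(ev$rho, 1)
  ev2 <- evaluate_predictions(-ref, ref)
  expect_equal(ev2$r, -1)
})

test_that("attenuation by noise matches the closed form", {
  set.seed(5)
  n <- 400
  signal <- rnorm(n, sd = 1)
  noise_sd <- 0.8
  ref <- signal + rnorm(n, sd = noise_sd)
  ev <- evaluate_predictions(signal, ref)
  expect_equal(ev$r, sqrt(1 / (1 + noise_sd^2)), tolerance = 0.05)
})

test_that("SVR on the published roughness weights recovers every weight", {
  rb <- preset_model("R_best_I")
  s <- synth_feature_table(200, rb$weights, noise_sd = 0, seed = 12)
  fit <- train_svr(s$table, s$target, names(rb$weights), C = 10,
                   epsilon = 0.001, tol = 1e-6)
  # features are ~standard normal, so standardized weights match the truth
  expect_lt(max(abs(fit$weights - rb$weights)), 0.02)
})
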