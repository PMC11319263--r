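test_that("marker coding and panel size are enforced at the contract", {
  X <- random_markers(30, 20, seed = 1)
  y <- stats::rnorm(30)
  Xbad <- X; Xbad[1, 1] <- 2
  expect_error(gp_fit(gp_engine("lasso"), Xbad, y), "coded")
  Xna <- X; Xna[2, 3] <- NA
  expect_error(gp_fit(gp_engine("lasso"), Xna, y), "missing")
  m <- gp_fit(gp_engine("lasso", seed = 1), X, y)
  expect_error(predict(m, X[, 1:10]), "panel mismatch")
  expect_error(gp_engine("lasso", nonsense = 1), "unknown setting")
})

test_that("all engines share the fit/predict contract shapes", {
  X <- random_markers(40, 400, seed = 2)
  y <- drop(X[, 1:5] %*% rep(1, 5)) + stats::rnorm(40, 0, 0.5)
  engines <- list(
    gp_engine("lasso", seed = 1),
    gp_engine("bayesc", n_iter = 300, burn_in = 50, thin = 2, seed = 1),
    gp_engine("cnn", epochs = 2, val_fraction = 0, seed = 1))
  for (eng in engines) {
    m <- gp_fit(eng, X, y)
    p <- predict(m, X[1:7, ])
    expect_equal(dim(p), c(7, 1), label = eng$name)
    expect_true(all(is.finite(p)), label = eng$name)
  }
})

test_that("lasso matches the soft-threshold closed form on orthonormal designs", {
  n <- 40; p <- 8
  X <- orthonormal_design(n, p, seed = 1)
  set.seed(2)
  y <- drop(X %*% c(2, -1.5, rep(0, p - 2))) + stats::rnorm(n)
  lam <- 0.5
  st <- cgmgp:::lasso_fit_impl(X, y, lasso_settings(lambda = lam,
                                                    standardize = FALSE,
                                                    thresh = 1e-12))
  beta <- as.matrix(stats::coef(st$fit, s = lam))[-1, 1]
  ols <- drop(crossprod(X, y) / n)
  soft <- sign(ols) * pmax(abs(ols) - lam, 0)
  expect_lt(max(abs(beta - soft)), 1e-6)
})

test_that("lasso shrinks to the null model at lambda_max and to OLS at zero", {
  n <- 40; p <- 8
  X <- orthonormal_design(n, p, seed = 3)
  set.seed(4)
  y <- drop(X %*% c(1, rep(0, p - 1))) + stats::rnorm(n)
  lmax <- lasso_lambda_max(X, y, standardize = FALSE)
  st <- cgmgp:::lasso_fit_impl(X, y, lasso_settings(
    lambda = c(2 * lmax, lmax * 1.0001), standardize = FALSE, thresh = 1e-12))
  beta <- as.matrix(stats::coef(st$fit, s = lmax * 1.0001))
  expect_equal(max(abs(beta[-1, 1])), 0)
  expect_equal(beta[1, 1], mean(y))
  st0 <- cgmgp:::lasso_fit_impl(X, y, lasso_settings(lambda = 0,
                                                     standardize = FALSE,
                                                     thresh = 1e-14))
  b0 <- drop(as.matrix(stats::coef(st0$fit, s = 0)))
  expect_lt(max(abs(b0 - stats::coef(stats::lm(y ~ X)))), 1e-6)
})

test_that("every fitted lasso model satisfies the KKT conditions", {
  for (s in 1:3) {
    X <- random_markers(60, 50, seed = s)
    set.seed(s + 10)
    y <- drop(X[, 1] * 1.5 - X[, 2]) + stats::rnorm(60, 0, 0.5)
    m <- gp_fit(gp_engine("lasso", thresh = 1e-12, seed = s), X, y)
    expect_lt(lasso_kkt_violation(m, X, y), 1e-6)
  }
})

test_that("a constant target yields an intercept-only lasso with a warning", {
  X <- random_markers(20, 10, seed = 5)
  expect_warning(m <- gp_fit(gp_engine("lasso"), X, rep(3, 20)), "constant")
  expect_equal(drop(predict(m, X)), rep(3, 20))
})

test_that("bayesc validates pi and returns the train mean exactly at pi = 1", {
  X <- random_markers(25, 15, seed = 6)
  set.seed(7)
  y <- stats::rnorm(25, 10)
  expect_error(gp_fit(gp_engine("bayesc", pi = 1.2), X, y), "pi")
  expect_error(gp_fit(gp_engine("bayesc", n_iter = 100, burn_in = 200), X, y),
               "burn-in")
  m <- gp_fit(gp_engine("bayesc", pi = 1), X, y)
  expect_equal(drop(predict(m, X)), rep(mean(y), 25))
})

test_that("bayesc with pi = 0 and fixed variances matches the ridge solution", {
  set.seed(5)
  n <- 20; p <- 10
  X <- scale(matrix(stats::rnorm(n * p), n), center = TRUE, scale = FALSE)
  y <- drop(X %*% stats::rnorm(p)) + stats::rnorm(n)
  s2a <- 0.5; s2e <- 1
  st <- cgmgp:::bayesc_fit_impl(X, y, bayesc_settings(
    pi = 0, fix_var = TRUE, s2a = s2a, s2e = s2e,
    n_iter = 30000, burn_in = 2000, thin = 2, seed = 7))
  lam <- s2e / s2a
  ridge <- drop(solve(crossprod(X) + diag(lam, p), crossprod(X, y - mean(y))))
  # tolerance: 3 posterior SDs deflated by a conservative effective sample
  # size (autocorrelation inflation factor 10)
  post_sd <- sqrt(s2e / (colSums(X^2) + lam))
  tol <- 3 * post_sd / sqrt(st$n_kept / 10)
  expect_true(all(abs(st$effects - ridge) < tol))
})

test_that("bayesc chains are seed-reproducible and prediction is row-wise", {
  X <- random_markers(30, 40, seed = 8)
  set.seed(9)
  y <- drop(X[, 1:3] %*% c(1, -1, 0.5)) + stats::rnorm(30, 0, 0.3)
  s <- gp_engine("bayesc", n_iter = 500, burn_in = 100, thin = 2, seed = 4)
  m1 <- gp_fit(s, X, y); m2 <- gp_fit(s, X, y)
  expect_identical(bayesc_posterior(m1)$effects,
                   bayesc_posterior(m2)$effects)
  p_all <- predict(m1, X)
  p_split <- rbind(predict(m1, X[1:10, ]), predict(m1, X[11:30, ]))
  expect_equal(p_all, p_split)
})

test_that("bayesc recovers the residual variance on a pure-noise trait", {
  X <- random_markers(120, 80, seed = 10)
  set.seed(11)
  y <- stats::rnorm(120, 0, 2)
  st <- cgmgp:::bayesc_fit_impl(X, y, bayesc_settings(
    n_iter = 3000, burn_in = 500, thin = 2, keep_samples = TRUE, seed = 12))
  expect_lt(abs(st$s2e - stats::var(y)), 2 * max(st$s2e_sd, 0.1))
})

test_that("linear engines agree on a purely additive trait", {
  pas <- vapply(1:5, function(s) {
    X <- random_markers(300, 1000, seed = s)
    set.seed(s + 20)
    b <- rep(0, 1000); qtl <- sample(1000, 20); b[qtl] <- stats::rnorm(20)
    g <- drop(X %*% b)
    y <- g + stats::rnorm(300, 0, sqrt(stats::var(g) * 0.25))  # h2 = 0.8
    tr <- 1:240; te <- 241:300
    ml <- gp_fit(gp_engine("lasso", seed = s), X[tr, ], y[tr])
    mb <- gp_fit(gp_engine("bayesc", n_iter = 1000, burn_in = 200, thin = 2,
                           seed = s), X[tr, ], y[tr])
    c(stats::cor(y[te], drop(predict(ml, X[te, ]))),
      stats::cor(y[te], drop(predict(mb, X[te, ]))))
  }, numeric(2))
  expect_lt(stats::median(abs(pas[1, ] - pas[2, ])), 0.1)
})

test_that("the convolution stack keeps the quoted shape chain", {
  expect_equal(conv_out_lengths(2000), c(2000, 667, 134, 27, 6))
  expect_equal(conv_out_lengths(3000), c(3000, 1000, 200, 40, 8))
  # head size 8 in parameter mode
  X <- random_markers(30, 500, seed = 13)
  Y <- matrix(stats::runif(30 * 8, 1, 2), 30)
  m <- gp_fit(gp_engine("cnn", epochs = 1, val_fraction = 0, seed = 1), X, Y)
  expect_equal(dim(predict(m, X[1:4, ])), c(4, 8))
  expect_warning(gp_fit(gp_engine("cnn", epochs = 1, val_fraction = 0,
                                  seed = 1), X, Y[, 1:3]), "head")
})

test_that("CNN backpropagation matches numerical gradients", {
  set.seed(3)
  s <- cnn_settings(kernels = c(3, 3), strides = c(2, 3), channels = c(2, 3),
                    dense_units = 4, val_fraction = 0, seed = 9)
  p <- 13; B <- 3; m <- 2
  X <- matrix(sample(c(-1, 0, 1), B * p, TRUE), B)
  Ys <- matrix(stats::runif(B * m, 0.2, 0.8), B)
  net <- cgmgp:::cnn_init(p, m, s)
  # jitter all parameters away from exact ReLU kinks (zero-initialized
  # biases with discrete inputs put some pre-activations exactly at zero,
  # where the subgradient and a central difference legitimately differ)
  for (nm in names(net$params))
    net$params[[nm]] <- net$params[[nm]] +
      stats::rnorm(length(net$params[[nm]]), 0, 0.05)
  fw <- cgmgp:::cnn_forward(X, net, s, keep_cache = TRUE)
  bk <- cgmgp:::cnn_backward(X, Ys, fw, net, s)
  worst <- 0
  for (nm in names(net$params)) {
    for (i in sample(length(net$params[[nm]]),
                     min(4, length(net$params[[nm]])))) {
      eps <- 1e-6
      n1 <- net; n1$params[[nm]][i] <- n1$params[[nm]][i] + eps
      n2 <- net; n2$params[[nm]][i] <- n2$params[[nm]][i] - eps
      f1 <- cgmgp:::cnn_forward(X, n1, s)
      f2 <- cgmgp:::cnn_forward(X, n2, s)
      ng <- (cgmgp:::cnn_loss(Ys, f1$Yhat, s$rel_floor) -
               cgmgp:::cnn_loss(Ys, f2$Yhat, s$rel_floor)) / (2 * eps)
      ag <- bk$grads[[nm]][i]
      worst <- max(worst, abs(ng - ag) / max(abs(ng) + abs(ag), 1e-8))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("CNN predictions stay inside the target scaler range", {
  X <- random_markers(40, 500, seed = 14)
  set.seed(15)
  y <- stats::runif(40, 10, 30)
  m <- gp_fit(gp_engine("cnn", epochs = 3, val_fraction = 0, seed = 2), X, y)
  pr <- drop(predict(m, X))
  expect_true(all(pr >= min(y) - 1e-9))
  expect_true(all(pr <= max(y) + 1e-9))
  # fixed bounds are honoured too
  m2 <- gp_fit(gp_engine("cnn", epochs = 2, val_fraction = 0, seed = 2,
                         target_bounds = list(lower = 0, upper = 100)),
               X, y)
  pr2 <- drop(predict(m2, X))
  expect_true(all(pr2 >= 0 & pr2 <= 100))
})

test_that("the target scaler inverts itself and absorbs constant targets", {
  sc <- target_scaler(c(0, 10), c(1, 20))
  Y <- cbind(stats::runif(20), stats::runif(20, 10, 20))
  expect_lt(max(abs(sc$inverse(sc$forward(Y)) - Y)), 1e-12)
  scc <- scaler_from_data(matrix(5, 10, 1))
  expect_true(all(scc$forward(matrix(5, 10, 1)) == 0.5))
  expect_true(all(scc$inverse(matrix(stats::runif(10), 10, 1)) == 5))
})
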