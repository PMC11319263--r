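#' LASSO engine settings
#'
#' The LASSO engine minimizes `(1/2n) RSS + lambda * sum(|beta_j|)` with an
#' unpenalized intercept and internally standardized markers, along a
#' log-spaced path from `lambda_max = max_j |x_j' (y - ybar)| / n` down
#' four decades; `lambda` is chosen by inner k-fold cross-validation under
#' the minimum-MSE rule unless supplied explicitly.
#'
#' @param inner_k Inner cross-validation folds for the lambda choice.
#' @param nlambda Path length.
#' @param lambda.min.ratio Ratio of the smallest to the largest lambda.
#' @param lambda Optional fixed lambda (scalar, skips the inner CV) or
#'   explicit path.
#' @param standardize Standardize markers internally (coefficients are
#'   reported on the original scale either way).
#' @param thresh Coordinate-descent convergence threshold.
#' @param seed Seed for the inner CV fold draw.
#' @return Settings list.
#' @export
lasso_settings <- function(inner_k = 5, nlambda = 100,
                           lambda.min.ratio = 1e-4, lambda = NULL,
                           standardize = TRUE, thresh = 1e-7, seed = 1) {
  list(inner_k = inner_k, nlambda = nlambda,
       lambda.min.ratio = lambda.min.ratio, lambda = lambda,
       standardize = standardize, thresh = thresh, seed = seed)
}

lasso_fit_impl <- function(X, y, s) {
  if (stats::sd(y) == 0) {
    warning("constant target: intercept-only model")
    return(list(intercept_only = TRUE, mu = y[1]))
  }
  if (!is.null(s$lambda)) {
    fit <- glmnet::glmnet(X, y, alpha = 1, lambda = sort(s$lambda,
                                                         decreasing = TRUE),
                          standardize = s$standardize, thresh = s$thresh)
    lam <- min(s$lambda)
  } else {
    set.seed(s$seed)
    cv <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = s$inner_k,
                            nlambda = s$nlambda,
                            lambda.min.ratio = s$lambda.min.ratio,
                            standardize = s$standardize, thresh = s$thresh)
    fit <- cv$glmnet.fit
    lam <- cv$lambda.min
  }
  list(intercept_only = FALSE, fit = fit, lambda = lam)
}

lasso_predict_impl <- function(state, X) {
  if (state$intercept_only)
    return(matrix(state$mu, nrow(X), 1))
  as.matrix(stats::predict(state$fit, newx = X, s = state$lambda,
                           exact = FALSE))
}

#' Coefficients of a fitted LASSO model
#'
#' @param model A `gp_model` fitted with the lasso engine.
#' @return List with `intercept`, `beta` (original-scale coefficients) and
#'   `lambda`.
#' @export
lasso_coefficients <- function(model) {
  stopifnot(inherits(model, "gp_model"), model$engine$name == "lasso")
  st <- model$state
  if (st$intercept_only)
    return(list(intercept = st$mu, beta = rep(0, model$p), lambda = Inf))
  cf <- as.matrix(stats::coef(st$fit, s = st$lambda))
  list(intercept = cf[1, 1], beta = cf[-1, 1], lambda = st$lambda)
}

#' Karush-Kuhn-Tucker residual of a LASSO fit
#'
#' On the standardized scale the solution must satisfy
#' `|x_j' r| / n <= lambda` for every excluded marker and
#' `x_j' r / n = lambda * sign(beta_j)` for included ones. Returns the
#' largest violation, which should be numerically zero for a converged fit.
#'
#' @param model A lasso `gp_model`.
#' @param X,y The training data.
#' @return Non-negative scalar (maximum KKT violation).
#' @export
lasso_kkt_violation <- function(model, X, y) {
  cf <- lasso_coefficients(model)
  if (!is.finite(cf$lambda)) return(0)
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- nrow(X)
  st <- model$engine$settings$standardize
  ctr <- colMeans(X)
  sdn <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  sdn[sdn == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, if (st) sdn else rep(1, ncol(X)), "/")
  beta_s <- cf$beta * (if (st) sdn else rep(1, ncol(X)))
  r <- y - (cf$intercept + drop(X %*% cf$beta))  # 1'r = 0 at the optimum
  grad <- drop(crossprod(Xs, r)) / n
  lam <- cf$lambda
  viol <- ifelse(beta_s == 0, pmax(abs(grad) - lam, 0),
                 abs(grad - lam * sign(beta_s)))
  max(viol)
}

#' Largest lambda with an all-zero LASSO solution
#'
#' @param X Marker matrix.
#' @param y Target vector.
#' @param standardize Match the fit's standardization.
#' @return `max_j |x_j'(y - ybar)| / n` on the (standardized) scale.
#' @export
lasso_lambda_max <- function(X, y, standardize = TRUE) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (standardize) {
    sdn <- sqrt(colMeans(Xc^2)); sdn[sdn == 0] <- 1
    Xc <- sweep(Xc, 2, sdn, "/")
  }
  max(abs(drop(crossprod(Xc, y - mean(y))))) / n
}
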