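#' Construct a genomic prediction engine
#'
#' Engines share one fit/predict contract over `{-1, 0, 1}` marker
#' matrices: [gp_fit()] returns a fitted `gp_model`, and `predict()` maps a
#' new marker matrix (same marker panel) to predictions on the original
#' target scale. Built-in engines are `"lasso"` (penalized linear
#' regression, single target), `"bayesc"` (spike-and-slab Gibbs sampler,
#' single target) and `"cnn"` (1D convolutional network, single or
#' multi-target). A `"custom"` engine takes `fit` and `predict` functions,
#' which is convenient for oracle engines in tests.
#'
#' @param name One of `"lasso"`, `"bayesc"`, `"cnn"`, `"custom"`.
#' @param ... Engine settings; see [lasso_settings()], [bayesc_settings()],
#'   [cnn_settings()]. For `"custom"`: `fit(X, Y)` returning any state and
#'   `predict(state, X)` returning predictions.
#' @return List of class `gp_engine`.
#' @export
gp_engine <- function(name = c("lasso", "bayesc", "cnn", "custom"), ...) {
  name <- match.arg(name)
  settings <- list(...)
  defaults <- switch(name,
                     lasso = lasso_settings(), bayesc = bayesc_settings(),
                     cnn = cnn_settings(), custom = list())
  unknown <- setdiff(names(settings), c(names(defaults), "fit", "predict"))
  if (length(unknown))
    stop("unknown setting(s) for engine '", name, "': ",
         paste(unknown, collapse = ", "))
  eng <- list(name = name, settings = utils::modifyList(defaults, settings))
  class(eng) <- "gp_engine"
  eng
}

gp_multi_output <- function(engine) engine$name == "cnn"

check_marker_matrix <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("marker matrix contains missing entries")
  if (!all(X %in% c(-1, 0, 1)))
    stop("marker matrix entries must be coded {-1, 0, 1}")
  storage.mode(X) <- "double"
  X
}

#' Fit a genomic prediction engine
#'
#' @param engine A [gp_engine()].
#' @param X Marker matrix (n x p, coded `{-1, 0, 1}`).
#' @param Y Target vector, or single/multi-column matrix.
#' @return Object of class `gp_model` with a `predict()` method.
#' @export
gp_fit <- function(engine, X, Y) {
  stopifnot(inherits(engine, "gp_engine"))
  X <- check_marker_matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(X))
  state <- switch(engine$name,
    lasso = {
      stopifnot(ncol(Y) == 1)
      lasso_fit_impl(X, drop(Y), engine$settings)
    },
    bayesc = {
      stopifnot(ncol(Y) == 1)
      bayesc_fit_impl(X, drop(Y), engine$settings)
    },
    cnn = cnn_fit_impl(X, Y, engine$settings),
    custom = engine$settings$fit(X, Y))
  model <- list(engine = engine, state = state, p = ncol(X),
                m = ncol(Y), target_names = colnames(Y))
  class(model) <- "gp_model"
  model
}

#' Predict from a fitted genomic prediction model
#'
#' @param object A `gp_model` from [gp_fit()].
#' @param newdata Marker matrix with the training marker panel.
#' @param ... Unused.
#' @return Numeric matrix `n_new x m` on the original target scale.
#' @export
predict.gp_model <- function(object, newdata, ...) {
  X <- check_marker_matrix(newdata)
  if (ncol(X) != object$p)
    stop("marker panel mismatch: model trained on ", object$p,
         " markers, got ", ncol(X))
  out <- switch(object$engine$name,
    lasso = lasso_predict_impl(object$state, X),
    bayesc = bayesc_predict_impl(object$state, X),
    cnn = cnn_predict_impl(object$state, X),
    custom = object$engine$settings$predict(object$state, X))
  out <- as.matrix(out)
  colnames(out) <- object$target_names
  out
}

#' Affine target scaler
#'
#' Maps a target onto `[0, 1]` by min-max and back; the bounded scale is
#' what a sigmoid output layer requires. For genotypic parameters the
#' calibration bounds provide a genotype-independent map; for a trait the
#' training values set the range. A degenerate (constant) target maps to
#' 0.5 and inverts to the constant.
#'
#' @param lower,upper Per-target range (recycled to the target count).
#' @return List of class `target_scaler` with `forward` and `inverse`
#'   matrix functions.
#' @export
target_scaler <- function(lower, upper) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  rng <- upper - lower
  degenerate <- rng == 0
  forward <- function(Y) {
    Y <- as.matrix(Y)
    out <- sweep(sweep(Y, 2, lower), 2, ifelse(degenerate, 1, rng), "/")
    out[, degenerate] <- 0.5
    out
  }
  inverse <- function(S) {
    S <- as.matrix(S)
    out <- sweep(sweep(S, 2, rng, "*"), 2, lower, "+")
    out[, degenerate] <- rep(lower[degenerate], each = nrow(out))
    out
  }
  structure(list(forward = forward, inverse = inverse, lower = lower,
                 upper = upper), class = "target_scaler")
}

#' Scaler from observed target values
#' @param Y Target matrix (columns are targets).
#' @return A [target_scaler()] with per-column min/max range.
#' @export
scaler_from_data <- function(Y) {
  Y <- as.matrix(Y)
  target_scaler(apply(Y, 2, min), apply(Y, 2, max))
}
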