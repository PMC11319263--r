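#' Bayes C engine settings
#'
#' Spike-and-slab whole-genome regression: each SNP effect is zero with
#' probability `pi` and otherwise drawn from a normal slab with one common
#' variance across SNPs. Variances carry scaled-inverse-chi-squared priors
#' whose scales are solved from `var(y)` split by `r2_prior`; the overall
#' mean has a flat prior. Prediction is the posterior-mean genomic value.
#'
#' @param pi Prior exclusion probability of a SNP effect, in `[0, 1]`.
#' @param n_iter Chain length (must exceed `burn_in`).
#' @param burn_in Discarded initial iterations.
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @param nu Prior degrees of freedom for both variances.
#' @param r2_prior Prior share of `var(y)` attributed to markers.
#' @param fix_var Hold both variances at their starting values (degenerate
#'   priors); with `pi = 0` the posterior-mean effects then solve a ridge
#'   system, which is used as an oracle in tests.
#' @param s2a,s2e Optional starting/fixed variance values.
#' @param keep_samples Keep the residual-variance samples.
#' @param seed Integer seed (R RNG drives the chain).
#' @return Settings list.
#' @export
bayesc_settings <- function(pi = 0.99, n_iter = 12000, burn_in = 2000,
                            thin = 10, nu = 4, r2_prior = 0.5,
                            fix_var = FALSE, s2a = NULL, s2e = NULL,
                            keep_samples = FALSE, seed = 1) {
  list(pi = pi, n_iter = n_iter, burn_in = burn_in, thin = thin, nu = nu,
       r2_prior = r2_prior, fix_var = fix_var, s2a = s2a, s2e = s2e,
       keep_samples = keep_samples, seed = seed)
}

bayesc_fit_impl <- function(X, y, s) {
  if (s$pi < 0 || s$pi > 1) stop("pi must lie in [0, 1]")
  if (s$n_iter <= s$burn_in) stop("chain length must exceed burn-in")
  if (s$pi == 1) {
    # all effects excluded with probability one: the empty model, handled
    # analytically so the train mean is returned exactly
    return(list(empty = TRUE, mu = mean(y),
                effects = rep(0, ncol(X)), inclusion = rep(0, ncol(X))))
  }
  vy <- stats::var(y)
  msx <- sum(colMeans(X^2) - colMeans(X)^2)
  if (msx == 0) msx <- 1
  exp_in <- max(1 - s$pi, 1 / ncol(X))
  s2a0 <- if (!is.null(s$s2a)) s$s2a else
    max(s$r2_prior * vy / (exp_in * msx), 1e-8)
  s2e0 <- if (!is.null(s$s2e)) s$s2e else max((1 - s$r2_prior) * vy, 1e-8)
  S_a <- s2a0 * (s$nu - 2) / s$nu  # prior mean of scaled-inv-chi^2 = nu S/(nu-2)
  S_e <- s2e0 * (s$nu - 2) / s$nu
  set.seed(s$seed)
  res <- .bayesc_gibbs(X, y, s$pi, as.integer(s$n_iter),
                       as.integer(s$burn_in), as.integer(s$thin),
                       s$nu, S_a, s$nu, S_e, s2a0, s2e0,
                       isTRUE(s$fix_var), isTRUE(s$keep_samples))
  res$empty <- FALSE
  res
}

bayesc_predict_impl <- function(state, X) {
  matrix(state$mu + drop(X %*% state$effects), ncol = 1)
}

#' Posterior summaries of a fitted Bayes C model
#'
#' @param model A `gp_model` fitted with the bayesc engine.
#' @return List with `mu`, `effects` (posterior-mean effect per SNP,
#'   inclusion-weighted), `inclusion` probabilities, and the variance
#'   summaries `s2a`, `s2e`, `s2e_sd`.
#' @export
bayesc_posterior <- function(model) {
  stopifnot(inherits(model, "gp_model"), model$engine$name == "bayesc")
  model$state
}
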