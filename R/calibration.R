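#' Normalized root mean square error
#'
#' `sqrt(mean(((y - yhat) / y)^2))`: each residual is scaled by its
#' observation before averaging, so traits of different magnitudes are
#' comparable in one objective.
#'
#' @param observed,predicted Equal-length numeric vectors; `observed` must
#'   not contain zeros (the caller may drop such points).
#' @return Non-negative scalar.
#' @export
#' @examples
#' nrmse(c(2, 4), c(1, 4))  # sqrt(0.25 / 2)
nrmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  if (any(observed == 0)) stop("zero observation in relative error")
  sqrt(mean(((observed - predicted) / observed)^2))
}

#' Define a single-genotype calibration problem
#'
#' Bundles the observed phenotype table of one genotype, the weather, the
#' parameter bounds and the Differential Evolution settings.
#'
#' @param phenotypes Tidy table (`replicate`, `day`, `trait`, `value`) for
#'   one genotype, or the full trial table plus `genotype_id`.
#' @param weather Weather data frame.
#' @param genotype_id Optional genotype to extract from `phenotypes`.
#' @param traits Traits entering the objective (default the seven
#'   calibration traits; traits absent from the table are skipped with a
#'   warning).
#' @param bounds Parameter bounds matrix.
#' @param constants [model_constants()] list.
#' @param de_settings List overriding [de_settings()] entries.
#' @return List of class `calibration_problem`.
#' @export
calibration_problem <- function(phenotypes, weather, genotype_id = NULL,
                                traits = calibration_traits(),
                                bounds = parameter_bounds(),
                                constants = model_constants(),
                                de_settings = list()) {
  if (!is.null(genotype_id))
    phenotypes <- phenotypes[phenotypes$genotype_id == genotype_id, ]
  stopifnot(nrow(phenotypes) > 0,
            all(c("replicate", "day", "trait", "value") %in% names(phenotypes)))
  weather <- validate_weather(weather)
  missing_tr <- setdiff(traits, unique(phenotypes$trait))
  if (length(missing_tr)) {
    warning("traits absent from the observations, skipped: ",
            paste(missing_tr, collapse = ", "))
    traits <- setdiff(traits, missing_tr)
  }
  if (!length(traits)) stop("no calibration traits available")
  settings <- utils::modifyList(de_settings_default(), de_settings)
  pr <- list(phenotypes = phenotypes, weather = weather, traits = traits,
             bounds = bounds, constants = constants, settings = settings)
  class(pr) <- "calibration_problem"
  pr
}

de_settings_default <- function() {
  list(np = 80, f = 0.8, cr = 0.9, iterations = 250, seed = 1)
}

#' Differential Evolution settings
#'
#' @param np Population size (>= 4); default 10 x dimension for the 8
#'   growth-model parameters.
#' @param f Differential weight in `(0, 2]`.
#' @param cr Crossover rate in `[0, 1]`.
#' @param iterations Number of generations (0 returns the best of the
#'   initial population).
#' @param seed Integer seed.
#' @return Settings list.
#' @export
de_settings <- function(np = 80, f = 0.8, cr = 0.9, iterations = 250,
                        seed = 1) {
  stopifnot(np >= 4, f > 0, cr >= 0, cr <= 1, iterations >= 0)
  list(np = np, f = f, cr = cr, iterations = iterations, seed = seed)
}

#' Multi-trait calibration objective
#'
#' Simulates once with the candidate parameters, then returns the mean over
#' traits of the replicate-mean NRMSE between observed and simulated values
#' at the observed time points. Zero-valued observations (e.g. early tiller
#' counts) are dropped from the relative-error sums. A failing simulation
#' yields `Inf` so population-based optimizers can discard the candidate.
#'
#' @param params Numeric vector of the 8 genotypic parameters.
#' @param problem A [calibration_problem()].
#' @return Non-negative scalar (or `Inf`).
#' @export
calibration_objective <- function(params, problem) {
  sim <- tryCatch(
    simulate_growth(as_genotype_parameters(params), problem$weather,
                    problem$constants),
    error = function(e) NULL)
  if (is.null(sim)) return(Inf)
  per_trait <- vapply(problem$traits, function(tr) {
    obs_tr <- problem$phenotypes[problem$phenotypes$trait == tr, ]
    if (!nrow(obs_tr)) return(NA_real_)
    reps <- unique(obs_tr$replicate)
    vals <- vapply(reps, function(r) {
      o <- obs_tr[obs_tr$replicate == r, ]
      keep <- o$value != 0
      if (!any(keep)) return(NA_real_)
      o <- o[keep, ]
      pred <- simulated_trait(sim, tr, o$day)
      nrmse(o$value, pred)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  val <- mean(per_trait, na.rm = TRUE)
  if (!is.finite(val)) Inf else val
}

#' Differential Evolution (rand/1/bin)
#'
#' Classic DE: mutation `v = a + F (b - c)` over three distinct population
#' members, binomial crossover at rate `CR` with a forced index, reflection
#' of out-of-bounds coordinates back into the box, and greedy selection.
#' Deterministic given the seed.
#'
#' @param fn Objective function of a numeric vector, returning a scalar
#'   (may be `Inf`).
#' @param bounds 2 x d matrix with rows `lower`, `upper` (finite).
#' @param settings [de_settings()] list.
#' @return List with `par` (best vector, named by the bounds columns),
#'   `value`, and `trace` (best objective after the initial population and
#'   each generation; non-increasing).
#' @export
differential_evolution <- function(fn, bounds, settings = de_settings()) {
  stopifnot(is.matrix(bounds), nrow(bounds) == 2, all(is.finite(bounds)))
  lo <- bounds[1, ]; hi <- bounds[2, ]; d <- length(lo)
  np <- settings$np
  stopifnot(np >= 4)
  set.seed(settings$seed)
  pop <- matrix(stats::runif(np * d, rep(lo, each = np), rep(hi, each = np)),
                np, d)
  cost <- apply(pop, 1, fn)
  trace <- numeric(settings$iterations + 1)
  trace[1] <- min(cost)
  if (settings$iterations > 0) for (g in seq_len(settings$iterations)) {
    for (i in seq_len(np)) {
      abc <- sample(seq_len(np)[-i], 3)
      v <- pop[abc[1], ] + settings$f * (pop[abc[2], ] - pop[abc[3], ])
      # reflect into the box, clamp as a last resort
      for (rep_ in 1:2) {
        v <- ifelse(v < lo, 2 * lo - v, v)
        v <- ifelse(v > hi, 2 * hi - v, v)
      }
      v <- pmin(pmax(v, lo), hi)
      jr <- sample.int(d, 1)
      cross <- stats::runif(d) < settings$cr
      cross[jr] <- TRUE
      trial <- ifelse(cross, v, pop[i, ])
      tc <- fn(trial)
      if (tc <= cost[i]) { pop[i, ] <- trial; cost[i] <- tc }
    }
    trace[g + 1] <- min(cost)
  }
  best <- which.min(cost)
  par <- pop[best, ]
  names(par) <- colnames(bounds)
  list(par = par, value = cost[best], trace = trace)
}

#' Normalized mean absolute error of a fitted simulation, per trait
#'
#' Replicate-mean NMAE between observed values and the simulation at the
#' fitted parameters, reported per calibration trait.
#' @noRd
fit_nmae <- function(params, problem) {
  sim <- simulate_growth(as_genotype_parameters(params), problem$weather,
                         problem$constants)
  vapply(problem$traits, function(tr) {
    obs_tr <- problem$phenotypes[problem$phenotypes$trait == tr, ]
    reps <- unique(obs_tr$replicate)
    vals <- vapply(reps, function(r) {
      o <- obs_tr[obs_tr$replicate == r, ]
      o <- o[o$value != 0, ]
      if (!nrow(o)) return(NA_real_)
      nmae(o$value, simulated_trait(sim, tr, o$day))
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
}

#' Estimate the genotypic parameters of one genotype
#'
#' Runs Differential Evolution on the multi-trait NRMSE objective and
#' reports the best parameter set (the genotype's "observed" parameter
#' values), the achieved objective, and a per-trait NMAE fit report.
#'
#' @param problem A [calibration_problem()].
#' @return List of class `calibration_fit`: `params`
#'   (genotype_parameters), `objective`, `per_trait_nmae` (named vector,
#'   one entry per calibration trait), `trace`.
#' @export
estimate_genotype_parameters <- function(problem) {
  stopifnot(inherits(problem, "calibration_problem"))
  res <- differential_evolution(
    function(x) calibration_objective(x, problem),
    problem$bounds, problem$settings)
  fit <- list(params = as_genotype_parameters(res$par),
              objective = res$value,
              per_trait_nmae = fit_nmae(res$par, problem),
              trace = res$trace)
  class(fit) <- "calibration_fit"
  fit
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> objective (mean NRMSE):", signif(x$objective, 4), "\n")
  print(round(unclass(x$params), 4))
  cat("per-trait NMAE:\n")
  print(round(x$per_trait_nmae, 4))
  invisible(x)
}
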