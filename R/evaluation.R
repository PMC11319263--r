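#' Normalized mean absolute error
#'
#' `mean(abs((y - yhat) / y))`.
#'
#' @param observed,predicted Equal-length numeric vectors; `observed` must
#'   not contain zeros.
#' @return Non-negative scalar.
#' @export
#' @examples
#' nmae(c(2, 4), c(1, 5))  # 0.375
nmae <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  if (any(observed == 0)) stop("zero observation in relative error")
  mean(abs((observed - predicted) / observed))
}

#' Predictive ability
#'
#' Pearson correlation between observed and predicted values,
#' `Cov(y, yhat) / (sd(y) sd(yhat))`.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2, both
#'   non-constant).
#' @return Scalar in `[-1, 1]`.
#' @export
predictive_ability <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("undefined PA: constant input")
  stats::cor(observed, predicted)
}

#' Random k-fold assignment shared across prediction methods
#'
#' Partitions the genotypes into `k` folds whose sizes differ by at most
#' one, by random permutation. The same assignment object is meant to be
#' consumed by every engine and both scenarios; a checksum of the
#' assignment is carried along so reports can assert fold identity.
#'
#' @param genotype_ids Character vector of genotype identifiers.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of class `fold_assignment` with `ids`, `fold` (integer in
#'   `0:(k-1)` per genotype), `k`, `seed`, `checksum`.
#' @export
kfold_split <- function(genotype_ids, k = 5, seed = 1) {
  n <- length(genotype_ids)
  if (n < k) stop("fewer genotypes than folds")
  set.seed(seed)
  fold <- integer(n)
  fold[sample.int(n)] <- rep(seq_len(k) - 1L, length.out = n)
  fa <- list(ids = genotype_ids, fold = fold, k = as.integer(k),
             seed = seed,
             checksum = sum((fold + 1) * seq_len(n)) %% 2147483647)
  class(fa) <- "fold_assignment"
  fa
}

oof_predict <- function(engine, X, Y, folds, postprocess = identity) {
  Y <- as.matrix(Y)
  pred <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (f in seq_len(folds$k) - 1L) {
    tr <- folds$fold != f; te <- !tr
    model <- gp_fit(engine, X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
    pred[te, ] <- postprocess(predict(model, X[te, , drop = FALSE]))
  }
  pred
}

#' Direct genomic prediction scenario
#'
#' For each engine, fits marker -> trait models on the training folds and
#' predicts each held-out genotype exactly once; NMAE and predictive
#' ability are computed on the pooled out-of-fold predictions.
#'
#' @param X Marker matrix (genotypes x markers).
#' @param trait Named numeric vector of the observed integrative trait,
#'   aligned with the rows of `X`.
#' @param folds A [kfold_split()] assignment.
#' @param engines Named list of [gp_engine()] objects.
#' @return List of class `scenario_report` (scenario `"direct"`): per
#'   engine, `nmae`, `pa`, `per_fold` (data frame) and `predictions`.
#' @export
run_direct_scenario <- function(X, trait, folds, engines) {
  stopifnot(length(trait) == nrow(X), inherits(folds, "fold_assignment"))
  res <- lapply(engines, function(eng) {
    Y <- matrix(trait, ncol = 1,
                dimnames = list(rownames(X), "trait"))
    pred <- drop(oof_predict(eng, X, Y, folds))
    per_fold <- do.call(rbind, lapply(seq_len(folds$k) - 1L, function(f) {
      te <- folds$fold == f
      data.frame(fold = f, nmae = nmae(trait[te], pred[te]),
                 pa = tryCatch(predictive_ability(trait[te], pred[te]),
                               error = function(e) NA_real_))
    }))
    pa <- tryCatch(predictive_ability(trait, pred),
                   error = function(e) NA_real_)
    list(nmae = nmae(trait, pred), pa = pa, per_fold = per_fold,
         predictions = pred,
         # an engine that predicts a constant within any fold has no
         # defined within-fold ability; flag it for the caller
         constant_prediction = is.na(pa) || anyNA(per_fold$pa))
  })
  structure(list(scenario = "direct", engines = res,
                 fold_checksum = folds$checksum, n = nrow(X)),
            class = "scenario_report")
}

#' Crop-model-mediated genomic prediction scenario
#'
#' For each engine: fit marker -> parameter models on the training folds
#' (jointly for multi-output engines, one model per parameter otherwise),
#' predict the held-out genotypes' parameters, clamp them into the
#' calibration bounds, simulate each held-out genotype under the shared
#' weather, and compare the simulated final aboveground fresh weight with
#' the observed trait. Also reports the per-parameter NMAE of the pooled
#' out-of-fold parameter predictions and simulated secondary traits.
#'
#' @param X Marker matrix.
#' @param params Matrix of "observed" genotypic parameters (n x 8), from
#'   calibration or the synthetic truth.
#' @param trait Observed integrative trait aligned with `X` rows.
#' @param weather Weather data frame.
#' @param folds A [kfold_split()] assignment (the same object as the direct
#'   scenario).
#' @param engines Named list of [gp_engine()] objects.
#' @param constants [model_constants()] list.
#' @param bounds Parameter bounds matrix used for clamping.
#' @return List of class `scenario_report` (scenario `"cgm-gp"`): per
#'   engine, `nmae`, `pa`, `per_fold`, `parameter_nmae` (named length-8
#'   vector), `predictions` and `secondary` (data frame of simulated
#'   Mainstemfw, PHT, Arealfel per genotype).
#' @export
run_cgmgp_scenario <- function(X, params, trait, weather, folds, engines,
                               constants = model_constants(),
                               bounds = parameter_bounds()) {
  stopifnot(nrow(params) == nrow(X), length(trait) == nrow(X),
            inherits(folds, "fold_assignment"))
  weather <- validate_weather(weather)
  res <- lapply(engines, function(eng) {
    pred_par <- if (gp_multi_output(eng)) {
      oof_predict(eng, X, params, folds)
    } else {
      out <- params; out[] <- NA_real_
      for (j in seq_len(ncol(params)))
        out[, j] <- drop(oof_predict(eng, X, params[, j, drop = FALSE], folds))
      out
    }
    pred_par <- clamp_parameters(pred_par, bounds)
    sim_trait <- rep(NA_real_, nrow(X))
    secondary <- data.frame(genotype = rownames(X),
                            Mainstemfw = NA_real_, PHT = NA_real_,
                            Arealfel = NA_real_)
    failed <- character(0)
    for (i in seq_len(nrow(X))) {
      sim <- tryCatch(
        simulate_growth(pred_par[i, ], weather, constants),
        error = function(e) NULL)
      if (is.null(sim)) { failed <- c(failed, rownames(X)[i]); next }
      nd <- nrow(sim$daily)
      sim_trait[i] <- sim$daily$Biomaerofw[nd]
      secondary$Mainstemfw[i] <- sim$harvest$Mainstemfw
      secondary$PHT[i] <- sim$daily$PHT[nd]
      secondary$Arealfel[i] <- sim$harvest$Arealfel
    }
    if (length(failed))
      warning("simulation failed for ", length(failed),
              " genotype(s); excluded from metrics")
    ok <- !is.na(sim_trait)
    per_fold <- do.call(rbind, lapply(seq_len(folds$k) - 1L, function(f) {
      te <- folds$fold == f & ok
      data.frame(fold = f, nmae = nmae(trait[te], sim_trait[te]),
                 pa = tryCatch(predictive_ability(trait[te], sim_trait[te]),
                               error = function(e) NA_real_))
    }))
    # zero-valued observed parameters (e.g. a population minimum mapped onto
    # a bound at zero) are dropped from the relative error, as in the
    # calibration objective
    param_nmae <- vapply(colnames(params), function(k) {
      keep <- params[, k] != 0
      nmae(params[keep, k], pred_par[keep, k])
    }, numeric(1))
    pa <- tryCatch(predictive_ability(trait[ok], sim_trait[ok]),
                   error = function(e) NA_real_)
    list(nmae = nmae(trait[ok], sim_trait[ok]), pa = pa,
         per_fold = per_fold, parameter_nmae = param_nmae,
         predictions = sim_trait, predicted_params = pred_par,
         secondary = secondary, failed = failed,
         constant_prediction = is.na(pa))
  })
  structure(list(scenario = "cgm-gp", engines = res,
                 fold_checksum = folds$checksum, n = nrow(X)),
            class = "scenario_report")
}

#' Merge the two scenario reports and compute deltas
#'
#' @param direct Report from [run_direct_scenario()].
#' @param cgmgp Report from [run_cgmgp_scenario()] on the same folds.
#' @return List of class `comparison_report`: `summary` data frame (engine,
#'   scenario, nmae, pa), `delta` data frame (CGM-GP minus direct, per
#'   engine and metric), `parameter_nmae` matrix (8 parameters x engines),
#'   and the two inputs.
#' @export
compare_scenarios <- function(direct, cgmgp) {
  stopifnot(direct$scenario == "direct", cgmgp$scenario == "cgm-gp")
  if (direct$fold_checksum != cgmgp$fold_checksum)
    stop("scenario reports built on different fold assignments")
  eng <- names(direct$engines)
  stopifnot(identical(sort(eng), sort(names(cgmgp$engines))))
  summary <- do.call(rbind, lapply(eng, function(e) rbind(
    data.frame(engine = e, scenario = "direct",
               nmae = direct$engines[[e]]$nmae, pa = direct$engines[[e]]$pa),
    data.frame(engine = e, scenario = "cgm-gp",
               nmae = cgmgp$engines[[e]]$nmae, pa = cgmgp$engines[[e]]$pa))))
  delta <- do.call(rbind, lapply(eng, function(e) data.frame(
    engine = e,
    delta_nmae = cgmgp$engines[[e]]$nmae - direct$engines[[e]]$nmae,
    delta_pa = cgmgp$engines[[e]]$pa - direct$engines[[e]]$pa)))
  pnm <- vapply(eng, function(e) cgmgp$engines[[e]]$parameter_nmae,
                numeric(length(parameter_names())))
  structure(list(summary = summary, delta = delta, parameter_nmae = pnm,
                 fold_checksum = direct$fold_checksum,
                 direct = direct, cgmgp = cgmgp),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> folds checksum", x$fold_checksum, "\n")
  print(transform(x$summary, nmae = round(nmae, 3), pa = round(pa, 3)),
        row.names = FALSE)
  cat("deltas (cgm-gp minus direct):\n")
  print(transform(x$delta, delta_nmae = round(delta_nmae, 3),
                  delta_pa = round(delta_pa, 3)), row.names = FALSE)
  invisible(x)
}
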