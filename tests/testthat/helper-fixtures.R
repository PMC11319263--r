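# shared fixtures, all generated in code

constant_weather <- function(days = 45, tmean = 26.5, rad = 8) {
  data.frame(day = seq_len(days), tmean_C = tmean, rad_MJ_m2 = rad)
}

# a small noise-free single-genotype trial from known parameters
noise_free_problem <- function(truth, weather = simulate_weather(45, seed = 3),
                               de = list(np = 40, iterations = 150, seed = 5)) {
  des <- trial_design(n_genotypes = 2, n_markers = 10, replicates = 1,
                      noise_cv = 0)
  tp <- matrix(unclass(truth), nrow = 1,
               dimnames = list("G001", parameter_names()))
  tr <- simulate_trial(tp, weather, des, seed = 1)
  calibration_problem(tr$phenotypes, weather, genotype_id = "G001",
                      de_settings = de)
}

# orthonormal design (columns orthogonal to the intercept, X'X = n I)
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  M <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n * p), n))))[, -1, drop = FALSE]
  M * sqrt(n)
}

random_markers <- function(n, p, seed = 1,
                           prob = c(0.25, 0.5, 0.25)) {
  set.seed(seed)
  matrix(sample(c(-1, 0, 1), n * p, replace = TRUE, prob = prob), n, p,
         dimnames = list(sprintf("G%03d", seq_len(n)),
                         sprintf("m%d", seq_len(p))))
}

# engines with the reduced training budgets used in the end-to-end tests
headline_engines <- function(seed, epochs = 6, param_bounds = NULL) {
  cnn_extra <- if (is.null(param_bounds)) list() else
    list(target_bounds = list(lower = param_bounds["lower", ],
                              upper = param_bounds["upper", ]))
  list(
    lasso = gp_engine("lasso", nlambda = 40, lambda.min.ratio = 1e-3,
                      seed = seed),
    bayesc = gp_engine("bayesc", n_iter = 800, burn_in = 200, thin = 3,
                       seed = seed),
    cnn = do.call(gp_engine,
                  c(list("cnn", epochs = epochs, batch_size = 16, lr = 3e-3,
                         val_fraction = 0, seed = seed), cnn_extra)))
}

# one full synthetic world: markers, parameters, weather, trial, trait
synthetic_world <- function(seed, des = trial_design(), n_qtl = 30,
                            n_pairs = 0, h2_range = c(0.5, 0.9)) {
  X <- simulate_genotypes(des, seed = seed)
  arch <- random_architecture(des$n_markers, n_qtl = n_qtl,
                              n_pairs = n_pairs, h2_range = h2_range,
                              seed = seed + 1000)
  P <- simulate_parameters(X, arch, seed = seed + 2000)
  w <- simulate_weather(des$duration_days, seed = seed + 3000)
  tr <- simulate_trial(P, w, des, seed = seed + 4000)
  list(X = X, params = P, weather = w, trial = tr,
       trait = observed_biomass(tr$phenotypes), arch = arch, design = des)
}
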