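test_that("evaluation metrics match hand calculations", {
  expect_equal(nmae(c(2, 4), c(2, 4)), 0)
  expect_equal(nmae(c(2, 4), c(1, 5)), 0.375)
  expect_equal(nmae(1, 0), 1)
  expect_error(nmae(c(0, 1), c(1, 1)), "zero observation")
  expect_equal(predictive_ability(1:5, 1:5), 1)
  y <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(predictive_ability(y, 2 + 3 * y), 1)
  expect_equal(predictive_ability(y, 2 - 3 * y), -1)
  expect_equal(predictive_ability(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(predictive_ability(c(1, 1), c(1, 2)), "undefined PA")
})

test_that("k-fold splits are balanced, deterministic and shared", {
  f <- kfold_split(sprintf("G%03d", 1:136), k = 5, seed = 1)
  expect_equal(sort(as.vector(table(f$fold)), decreasing = TRUE),
               c(28, 27, 27, 27, 27))
  f2 <- kfold_split(sprintf("G%03d", 1:10), k = 5, seed = 2)
  expect_true(all(table(f2$fold) == 2))
  expect_identical(kfold_split(letters[1:10], 5, seed = 3)$fold,
                   kfold_split(letters[1:10], 5, seed = 3)$fold)
  expect_error(kfold_split(letters[1:3], k = 5), "fewer genotypes")
})

oracle_engine <- function(lookup) {
  # predicts the stored truth for whatever rows are requested
  gp_engine("custom",
            fit = function(X, Y) colnames(Y),
            predict = function(state, X)
              as.matrix(lookup[rownames(X), state, drop = FALSE]))
}

test_that("a perfect oracle engine attains NMAE 0 and PA 1", {
  X <- random_markers(30, 40, seed = 1)
  set.seed(2)
  y <- stats::runif(30, 50, 150)
  lookup <- matrix(y, dimnames = list(rownames(X), "trait"))
  folds <- kfold_split(rownames(X), k = 5, seed = 3)
  rep <- run_direct_scenario(X, y, folds, list(oracle = oracle_engine(lookup)))
  expect_equal(rep$engines$oracle$nmae, 0)
  expect_equal(rep$engines$oracle$pa, 1)
  expect_true(all(is.finite(rep$engines$oracle$predictions)))
})

test_that("a constant mean predictor is flagged as having undefined PA", {
  X <- random_markers(20, 30, seed = 4)
  set.seed(5)
  y <- stats::runif(20, 1, 2)
  mean_eng <- gp_engine("custom",
                        fit = function(X, Y) mean(Y),
                        predict = function(state, X)
                          matrix(state, nrow(X), 1))
  folds <- kfold_split(rownames(X), k = 5, seed = 6)
  rep <- run_direct_scenario(X, y, folds, list(mean = mean_eng))
  expect_true(rep$engines$mean$constant_prediction)
  expect_true(all(is.na(rep$engines$mean$per_fold$pa)))
})

test_that("pooled out-of-fold predictions cover every genotype exactly once", {
  X <- random_markers(33, 25, seed = 7)
  set.seed(8)
  y <- stats::runif(33, 1, 2)
  folds <- kfold_split(rownames(X), k = 5, seed = 9)
  seen <- new.env(); seen$rows <- character(0)
  counting <- gp_engine("custom",
                        fit = function(X, Y) mean(Y),
                        predict = function(state, X) {
                          seen$rows <- c(seen$rows, rownames(X))
                          matrix(state + stats::runif(nrow(X)), nrow(X), 1)
                        })
  rep <- run_direct_scenario(X, y, folds, list(count = counting))
  expect_identical(sort(seen$rows), sort(rownames(X)))
  expect_false(anyNA(rep$engines$count$predictions))
})

test_that("the crop-model scenario reproduces the trait from true parameters", {
  des <- trial_design(n_genotypes = 15, n_markers = 40, replicates = 2,
                      noise_cv = 0)
  world <- synthetic_world(1, des, n_qtl = 5)
  folds <- kfold_split(rownames(world$X), k = 5, seed = 2)
  oracle <- oracle_engine(world$params)
  cgm <- run_cgmgp_scenario(world$X, world$params, world$trait, world$weather,
                            folds, list(oracle = oracle))
  # noise-free observations + true parameters: the pipeline is an identity
  expect_lt(cgm$engines$oracle$nmae, 1e-9)
  expect_gt(cgm$engines$oracle$pa, 1 - 1e-9)
  expect_true(all(cgm$engines$oracle$parameter_nmae < 1e-12))
  # parameter NMAE table has one row per genotypic parameter
  expect_named(cgm$engines$oracle$parameter_nmae, parameter_names())
  # secondary simulated traits are reported
  expect_true(all(c("Mainstemfw", "PHT", "Arealfel") %in%
                    names(cgm$engines$oracle$secondary)))
})

test_that("out-of-bounds parameter predictions are clamped before simulation", {
  des <- trial_design(n_genotypes = 10, n_markers = 30, replicates = 1,
                      noise_cv = 0)
  world <- synthetic_world(3, des, n_qtl = 5)
  folds <- kfold_split(rownames(world$X), k = 5, seed = 4)
  wild <- gp_engine("custom",
                    fit = function(X, Y) NULL,
                    predict = function(state, X)
                      matrix(1e3, nrow(X), 1))  # far outside every interval
  cgm <- run_cgmgp_scenario(world$X, world$params, world$trait, world$weather,
                            folds, list(wild = wild))
  b <- parameter_bounds()
  pp <- cgm$engines$wild$predicted_params
  for (k in colnames(pp)) expect_true(all(pp[, k] == b["upper", k]))
})

test_that("scenario comparison requires shared folds and reports all cells", {
  des <- trial_design(n_genotypes = 15, n_markers = 40, replicates = 2,
                      noise_cv = 0)
  world <- synthetic_world(5, des, n_qtl = 5)
  folds <- kfold_split(rownames(world$X), k = 5, seed = 6)
  lookup <- matrix(world$trait,
                   dimnames = list(rownames(world$X), "trait"))
  oracle_t <- oracle_engine(lookup)
  oracle_p <- oracle_engine(world$params)
  direct <- run_direct_scenario(world$X, world$trait, folds,
                                list(oracle = oracle_t))
  cgm <- run_cgmgp_scenario(world$X, world$params, world$trait, world$weather,
                            folds, list(oracle = oracle_p))
  cmp <- compare_scenarios(direct, cgm)
  expect_equal(nrow(cmp$summary), 2)  # engines x scenarios
  expect_setequal(cmp$summary$scenario, c("direct", "cgm-gp"))
  expect_lt(max(abs(cmp$delta$delta_nmae)), 1e-9)
  expect_lt(max(abs(cmp$delta$delta_pa)), 1e-9)
  expect_equal(dim(cmp$parameter_nmae), c(8L, 1L))
  other <- run_direct_scenario(world$X, world$trait,
                               kfold_split(rownames(world$X), 5, seed = 99),
                               list(oracle = oracle_t))
  expect_error(compare_scenarios(other, cgm), "different fold")
})
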