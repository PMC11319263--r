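test_that("thermal time accumulates above the base temperature only", {
  expect_equal(thermal_time_increment(30, 11), 19)
  expect_equal(thermal_time_increment(11, 11), 0)
  expect_equal(thermal_time_increment(5, 11), 0)
  expect_equal(thermal_time_increment(c(30, 5), 11), c(19, 0))
})

test_that("carbon supply follows Beer-Lambert interception", {
  cst <- model_constants()
  expect_equal(daily_supply(5, 0, 1e5, cst), 0)
  expect_equal(daily_supply(5, 10, 0, cst), 0)
  # full interception limit
  expect_equal(daily_supply(3, 10, 1e12, cst), 3 * 10 * cst$ground_area,
               tolerance = 1e-9)
  # leaf area giving exactly 50% interception
  pla_half <- -log(0.5) / cst$k_light * cst$ground_area * 1e6
  expect_equal(daily_supply(3, 10, pla_half, cst), 1.2, tolerance = 1e-12)
})

test_that("competition index is the windowed supply/demand ratio", {
  expect_equal(competition_index(2, 2), 1.0)
  expect_equal(competition_index(0, 0, ic_max = 5), 5.0)
  expect_equal(competition_index(c(1, 1), c(4, 4)), 0.25)
  expect_equal(competition_index(100, 1, ic_max = 5), 5)
})

test_that("blade pre-dimensioning is additive in rank with SLA decay", {
  cst <- model_constants(first_leaf_length = 100)
  b1 <- potential_blade(1, mgr = 12, slap = 0.05, ic_at_predim = 1, cst)
  expect_equal(b1$length, 100)
  b5 <- potential_blade(5, mgr = 10, slap = 0, ic_at_predim = 1, cst)
  expect_equal(b5$length, 140)
  # slap = 0 keeps SLA constant: dry mass proportional to area
  b2 <- potential_blade(2, mgr = 10, slap = 0, ic_at_predim = 1, cst)
  expect_equal(b2$dry / b2$area, b5$dry / b5$area)
  # limiting carbon shrinks the increment, not the base length
  b5lim <- potential_blade(5, mgr = 10, slap = 0, ic_at_predim = 0.5, cst)
  expect_equal(b5lim$length, 120)
  # beyond the maximum rank no organ is made
  expect_null(potential_blade(cst$max_rank + 1, 10, 0, 1, cst))
  # strictly increasing in rank under non-limiting light
  lens <- vapply(1:10, function(r)
    potential_blade(r, 10, 0.05, 1, cst)$length, numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("internode sizing is a blade-length ratio with cylinder mass", {
  cst <- model_constants(internode_diameter = 10, internode_density = 1e-4)
  i1 <- potential_internode(100, 0.1, cst)
  expect_equal(i1$length, 10)
  expect_equal(i1$dry, pi * 25 * 10 * 1e-4)
  # at the calibration bounds the internode stays within 20% of the blade
  b <- parameter_bounds()
  expect_lte(potential_internode(100, b["upper", "ll_to_il"], cst)$length, 20)
})

test_that("simulation is deterministic and spans the weather series", {
  w <- constant_weather(45)
  p <- genotype_parameters()
  s1 <- simulate_growth(p, w)
  s2 <- simulate_growth(p, w)
  expect_identical(s1$daily, s2$daily)
  expect_identical(s1$harvest, s2$harvest)
  expect_equal(nrow(s1$daily), 45)
  expect_error(simulate_growth(p, w[0, ]), "empty|shorter")
  wbad <- w; wbad$tmean_C[3] <- NA
  expect_error(simulate_growth(p, wbad), "missing")
})

test_that("leaves appear at the phyllochron cadence under constant heat", {
  # 19 degree-days per day, phyllochron 38: one new leaf every 2 days
  p <- genotype_parameters(phyllo_init = 38, plasto_init = 38)
  s <- simulate_growth(p, constant_weather(45, tmean = 30))
  app <- s$daily$App
  expect_equal(app[seq(2, 44, by = 2)], 1:22)
  expect_true(all(diff(app) %in% c(0L, 1L)))
})

test_that("tillering requires the competition index to exceed ict", {
  w <- constant_weather(45)
  # IC clamped below the threshold: no tiller can ever be emitted
  cst <- model_constants(ic_max = 2.0)
  s <- simulate_growth(genotype_parameters(ict = 2.5), w, cst)
  expect_true(all(s$daily$Tillernb == 0))
  # final tiller count is non-increasing in ict
  tn <- vapply(c(0.5, 1, 1.5, 2, 2.5), function(ic)
    max(simulate_growth(genotype_parameters(ict = ic), w)$daily$Tillernb),
    numeric(1))
  expect_true(all(diff(tn) <= 0))
})

test_that("without light the plant stays at its seed-derived weight", {
  cst <- model_constants()
  s <- simulate_growth(genotype_parameters(),
                       constant_weather(45, rad = 0), cst)
  fin <- s$daily$Biomaerofw[45]
  expect_gte(fin, cst$seed_biomass / cst$dmc * 0.999)
  expect_lte(fin, 2 * cst$seed_biomass / cst$dmc)
})

test_that("carbon is conserved and trajectories are monotone", {
  cst <- model_constants()
  for (p in list(genotype_parameters(),
                 genotype_parameters(epsib = 8, ict = 0.5, mgr_init = 14),
                 genotype_parameters(epsib = 3, plasto_init = 25,
                                     phyllo_init = 45, slap = 0.1))) {
    s <- simulate_growth(p, simulate_weather(45, seed = 11))
    d <- s$daily
    growth <- diff(c(0, d$Biomaerofw * cst$dmc - cst$seed_biomass))
    expect_true(all(cumsum(growth) <= cumsum(d$supply) + 1e-9))
    for (tr in c("Biomaerofw", "PLA", "PHT", "App", "Lig", "Tillernb"))
      expect_true(all(diff(d[[tr]]) >= -1e-9), label = paste(tr, "monotone"))
    # biomass additivity across axes, every day
    expect_equal(d$Biomaerofw, d$mainstem_fw + d$tiller_fw, tolerance = 1e-12)
  }
})

test_that("final biomass increases with the light conversion coefficient", {
  w <- simulate_weather(45, seed = 2)
  fin <- vapply(c(3, 5, 8), function(e)
    utils::tail(simulate_growth(genotype_parameters(epsib = e), w)$daily$Biomaerofw, 1),
    numeric(1))
  expect_true(all(diff(fin) >= 0))
})

test_that("out-of-bounds parameters warn and clamping repairs them", {
  expect_warning(genotype_parameters(epsib = 9), "outside")
  pm <- rbind(c(epsib = 10, plasto_init = 30, phyllo_init = 30,
                ligulo_init = 30, ict = 0.1, mgr_init = 10, ll_to_il = 0.15,
                slap = 0.05))
  cl <- clamp_parameters(pm)
  b <- parameter_bounds()
  expect_true(all(cl >= b["lower", colnames(cl)]))
  expect_true(all(cl <= b["upper", colnames(cl)]))
  expect_equal(unname(cl[1, "epsib"]), 8)
  expect_equal(unname(cl[1, "ict"]), 0.5)
})
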