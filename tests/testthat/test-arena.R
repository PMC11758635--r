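# A slow-turnover three-group system keeps the integrator cheap in tests.
arena_toy <- function(catch = c(0, 0, 0)) {
  g <- data.frame(
    name = c("producer", "grazer", "detritus"),
    role = c("producer", "consumer", "detritus"),
    B = c(20, 2, 10), PB = c(20, 4, NA), QB = c(NA, 16, NA),
    Ui = c(NA, 0.25, NA), catch = catch
  )
  d <- matrix(0, 3, 3, dimnames = list(g$name, g$name))
  d["producer", "grazer"] <- 1
  model_definition(g, d, name = "arena_toy")
}

test_that("vulnerability follows the empirical trophic-level relation", {
  vp <- vulnerability_params(2.02)
  expect_equal(vp$v, 0.1515 * 2.02 + 0.0485, tolerance = 1e-12)
  expect_equal(vp$v, 0.35453, tolerance = 1e-9)
  # the log in the multiplier map is natural: v = 0.3 gives about 2
  vp3 <- vulnerability_params((0.3 - 0.0485) / 0.1515)
  expect_equal(vp3$v_new, exp(2.301958 * 0.3 + 0.001051), tolerance = 1e-12)
  expect_equal(vp3$v_new, 1.997, tolerance = 1e-3)
  # v = 0 maps to the lower bound of the multiplier scale (about 1)
  expect_equal(exp(0.001051), 1.001, tolerance = 1e-3)
})

test_that("arena calibration reproduces every baseline flow", {
  for (seed in c(2, 9)) {
    b <- solve_mass_balance(generate_model(synthesis_config(n_groups = 7,
                                                            seed = seed)))
    ar <- calibrate_arena(b)
    q <- ranchena:::arena_flows(ar, ar$B0)
    expect_lt(max(abs(q - ar$links$flow0) / ar$links$flow0), 1e-9)
  }
})

test_that("consumption saturates below the vulnerability ceiling", {
  b <- solve_mass_balance(arena_toy())
  ar <- calibrate_arena(b)
  # doubling predator biomass yields less than double the flow
  B2 <- ar$B0
  B2["grazer"] <- 2 * B2["grazer"]
  q2 <- ranchena:::arena_flows(ar, B2)
  expect_lt(q2, 2 * ar$links$flow0)
  expect_gt(q2, ar$links$flow0)
  # predation mortality approaches v_new times baseline as predators explode
  B_inf <- ar$B0
  B_inf["grazer"] <- 1e9
  mort_inf <- ranchena:::arena_flows(ar, B_inf) / ar$B0["producer"]
  mort0 <- ar$links$flow0 / ar$B0["producer"]
  vnew <- ar$v$v_new[["grazer"]]
  expect_equal(unname(mort_inf / mort0), vnew, tolerance = 1e-6)
})

test_that("infinite vulnerability recovers mass-action scaling", {
  b <- solve_mass_balance(arena_toy())
  v <- vulnerability_params(b$TL)
  v$v_new[] <- 1e9
  ar <- calibrate_arena(b, v)
  B2 <- ar$B0
  B2["grazer"] <- 2 * B2["grazer"]
  q2 <- ranchena:::arena_flows(ar, B2)
  expect_equal(unname(q2 / ar$links$flow0), 2, tolerance = 1e-6)
})

test_that("the unperturbed system is stationary over 14 years", {
  b <- solve_mass_balance(arena_toy())
  ar <- calibrate_arena(b)
  tr <- simulate_scenario(ar, scenario_spec(years = 14))
  final <- tr$biomass[nrow(tr$biomass), ]
  expect_lt(max(abs(final / tr$biomass[1, ] - 1)), 0.01)
  expect_true(tr$evaluable)
  expect_false(any(tr$collapsed))
})

test_that("forcing a group to its baseline reproduces the unforced run", {
  b <- solve_mass_balance(arena_toy())
  ar <- calibrate_arena(b)
  tr0 <- simulate_scenario(ar, scenario_spec(years = 5))
  tr1 <- simulate_scenario(
    ar, scenario_spec(enhanced = c(grazer = 2), years = 5))
  expect_equal(tr1$biomass, tr0$biomass, tolerance = 1e-9)
})

test_that("the vectorised integrator matches an independent scalar coding", {
  b <- solve_mass_balance(arena_toy())
  ar <- calibrate_arena(b)
  tr <- simulate_scenario(ar, scenario_spec(years = 3), substeps = 4)
  oracle <- scalar_arena_oracle(ar, years = 3, steps_per_year = 48)
  expect_equal(unname(tr$biomass[nrow(tr$biomass), ]), oracle,
               tolerance = 1e-6)
})

test_that("halving the time step barely moves 14-year endpoints", {
  b <- solve_mass_balance(arena_toy())
  ar <- calibrate_arena(b)
  sc <- scenario_spec(enhanced = c(grazer = 3.5), years = 14)
  end1 <- simulate_scenario(ar, sc, substeps = 4)$biomass[169, ]
  end2 <- simulate_scenario(ar, sc, substeps = 8)$biomass[169, ]
  expect_lt(max(abs(end2 / end1 - 1)), 1e-3)
})

test_that("mediation multipliers are normalised and monotone", {
  ms <- mediation_spec("shellfish", cbind("preyA", "predB"),
                       floor = 0.5, ceiling = 2, steepness = -2)
  expect_equal(ranchena:::mediation_multiplier(ms, 1), 1)
  x <- seq(0.2, 3, by = 0.2)
  mult <- ranchena:::mediation_multiplier(ms, x)
  expect_true(all(diff(mult) < 0)) # sheltering: more mediator, less predation
  ms_fac <- mediation_spec("m", cbind("a", "b"), steepness = 2)
  expect_true(all(diff(ranchena:::mediation_multiplier(ms_fac, x)) > 0))
  # a mediated stationary run stays stationary (multiplier 1 at baseline)
  b <- solve_mass_balance(arena_toy())
  ar <- calibrate_arena(b)
  med <- mediation_spec("detritus", cbind("producer", "grazer"))
  tr <- simulate_scenario(ar, scenario_spec(years = 3), mediation = list(med))
  expect_lt(max(abs(tr$biomass[37, ] / tr$biomass[1, ] - 1)), 1e-9)
})

test_that("snapshots of a stationary run reproduce the baseline indices", {
  m <- generate_model(synthesis_config(n_groups = 7, seed = 4))
  b <- solve_mass_balance(m)
  ar <- calibrate_arena(b)
  tr <- simulate_scenario(ar, scenario_spec(years = 12))
  snap <- snapshot_and_evaluate(tr, year = 10)
  expect_true(snap$feasible)
  expect_lt(max(abs(unlist(snap$indices) - unlist(compute_index_set(b)))),
            1e-6)
})

test_that("forcing a detritus feeder upward raises detritivory in the snapshot", {
  g <- data.frame(
    name = c("producer", "grazer", "detfeeder", "detritus"),
    role = c("producer", "consumer", "consumer", "detritus"),
    B = c(20, 2, 1, 10), PB = c(20, 4, 4, NA), QB = c(NA, 16, 16, NA),
    Ui = c(NA, 0.25, 0.25, NA)
  )
  d <- matrix(0, 4, 4, dimnames = list(g$name, g$name))
  d["producer", "grazer"] <- 1
  d["producer", "detfeeder"] <- 0.3
  d["detritus", "detfeeder"] <- 0.7
  m <- model_definition(g, d)
  b <- solve_mass_balance(m)
  ar <- calibrate_arena(b)
  tr0 <- simulate_scenario(ar, scenario_spec(years = 12))
  tr1 <- simulate_scenario(ar, scenario_spec(enhanced = c(detfeeder = 2),
                                             years = 12))
  s0 <- snapshot_and_evaluate(tr0, 10)
  s1 <- snapshot_and_evaluate(tr1, 10)
  sp0 <- lindeman_spine(s0$balanced)
  sp1 <- lindeman_spine(s1$balanced)
  expect_gt(sp1$detritivory, sp0$detritivory)
})

test_that("collapses are flagged and block evaluation", {
  # an overwhelming forced predator crashes its prey
  g <- data.frame(
    name = c("producer", "prey", "pred", "detritus"),
    role = c("producer", "consumer", "consumer", "detritus"),
    B = c(30, 1, 0.05, 10), PB = c(20, 5, 2, NA), QB = c(NA, 20, 10, NA),
    Ui = c(NA, 0.25, 0.25, NA)
  )
  d <- matrix(0, 4, 4, dimnames = list(g$name, g$name))
  d["producer", "prey"] <- 1
  d["prey", "pred"] <- 1
  m <- model_definition(g, d)
  b <- solve_mass_balance(m)
  v <- vulnerability_params(b$TL)
  v$v_new[] <- 30 # strongly top-down links let the forced predator bite
  ar <- calibrate_arena(b, v)
  tr <- simulate_scenario(ar, scenario_spec(enhanced = c(pred = 500),
                                            years = 12))
  expect_true(any(tr$collapsed))
  expect_false(tr$evaluable)
  out <- snapshot_and_evaluate(tr, 10)
  expect_s3_class(out, "not_evaluable")
})

test_that("the scenario suite enumerates the full design", {
  b <- solve_mass_balance(arena_toy(catch = c(0, 0.4, 0)))
  ar <- calibrate_arena(b)
  sc <- load_fixture("grade_scale")
  w <- load_fixture("weights")
  suite <- run_scenario_suite(ar, c(grazer = 3), sc, w, years = 11,
                              snapshot_year = 10)
  # one enhancement group: 2 forced scenarios + fishing only
  expect_equal(nrow(suite$table), 3)
  expect_equal(suite$table$scenario[3], "fishing only")
  expect_true(suite$table$fishing[3])
  # the fishing-only scenario applies F and no forcing
  expect_length(suite$results[[3]]$scenario$enhanced, 0)
  # evaluable rows carry a complete indicator record and a grade
  idx_cols <- c("DH", "TE_mean", "AC", "CI", "SOI", "FCI", "FML", "TPP_TR",
                "TPP_TB", "TB_TST")
  expect_true(all(idx_cols %in% names(suite$table)))
  ok <- suite$table$evaluable
  expect_true(all(is.finite(as.matrix(suite$table[ok, idx_cols]))))
  expect_true(all(!is.na(suite$table$grade[ok])))
  # three enhancement labels give the published 15-scenario design
  combos <- sum(vapply(1:3, function(k) choose(3, k), numeric(1))) * 2 + 1
  expect_equal(combos, 15)
})
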