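test_that("carrying capacity matches the closed-form toy", {
  # herbivore consuming the whole producer production: B * 50 = 10 * 100
  m <- toy_chain(herb_B = 1, herb_QB = 50)
  cc <- carrying_capacity(m, "herbivore")
  expect_equal(cc$carrying_capacity, 20, tolerance = 1e-4)
  expect_equal(cc$enhancement_potential, 19, tolerance = 1e-3)
  expect_equal(cc$limiting_group, "producer")
  expect_false(cc$unbounded)

  # a prey already at EE = 1 pins the capacity at the baseline
  m2 <- toy_chain(herb_B = 20, herb_QB = 50)
  expect_equal(solve_mass_balance(m2)$EE[["producer"]], 1)
  cc2 <- carrying_capacity(m2, "herbivore")
  expect_equal(cc2$carrying_capacity, 20, tolerance = 1e-3)
  expect_equal(cc2$enhancement_potential, 0, tolerance = 0.05)
})

test_that("capacity brackets the feasibility boundary", {
  m <- toy_chain()
  cc <- carrying_capacity(m, "herbivore")
  eps <- 1e-3 * cc$carrying_capacity
  below <- m; below$groups$B[2] <- cc$carrying_capacity - eps
  above <- m; above$groups$B[2] <- cc$carrying_capacity + eps
  expect_true(is_feasible(solve_mass_balance(below)))
  expect_false(is_feasible(solve_mass_balance(above)))
})

test_that("bisection agrees with a fine grid scan on generated webs", {
  for (seed in 1:20) {
    m <- generate_model(synthesis_config(n_groups = 6, seed = seed))
    cons <- m$groups$name[m$groups$role == "consumer"]
    target <- cons[length(cons)]
    cc <- carrying_capacity(m, target)
    if (cc$unbounded) next
    scan <- capacity_grid_scan(m, target, upper = cc$carrying_capacity * 1.1)
    expect_equal(cc$carrying_capacity, scan,
                 tolerance = 2e-3)
  }
})

test_that("raising prey production never lowers a predator's capacity", {
  m <- toy_web(det_frac = 0.2)
  cc1 <- carrying_capacity(m, "carn")
  m2 <- m
  m2$groups$PB[m2$groups$name == "herb"] <- 1.5 *
    m2$groups$PB[m2$groups$name == "herb"]
  cc2 <- carrying_capacity(m2, "carn")
  expect_gte(cc2$carrying_capacity, cc1$carrying_capacity - 1e-6)
})

test_that("infeasible baselines and detritus targets are rejected", {
  m <- toy_chain(herb_B = 25) # producer EE = 1.25
  expect_error(carrying_capacity(m, "herbivore"), "infeasible")
  expect_error(carrying_capacity(toy_chain(), "detritus"), "carrying capacity")
  expect_error(carrying_capacity(toy_chain(), "nope"), "unknown group")
})

test_that("trophic-level bins use half-open intervals", {
  expect_equal(tl_bin(c(2.0, 2.49, 2.5, 2.89, 3.0, 3.08, 3.49)),
               c("TL 2.0-2.5", "TL 2.0-2.5", "TL 2.5-3.0", "TL 2.5-3.0",
                 "TL 3.0-3.5", "TL 3.0-3.5", "TL 3.0-3.5"))
  expect_true(is.na(tl_bin(1.9)))
  expect_true(is.na(tl_bin(3.5)))
})

test_that("enhancement potentials rank descending within bins", {
  df <- data.frame(
    group = c("a", "b", "c", "d"),
    carrying_capacity = c(10, 8, 3, 2.5),
    baseline_biomass = c(1, 5, 0.5, 2),
    TL = c(2.1, 2.2, 3.1, 3.2)
  )
  tab <- enhancement_potential_table(df)
  expect_equal(tab$potential, c(9, 3, 2.5, 0.5))
  expect_equal(tab$group, c("a", "b", "c", "d"))
  expect_equal(tab$bin, c("TL 2.0-2.5", "TL 2.0-2.5", "TL 3.0-3.5",
                          "TL 3.0-3.5"))
})

test_that("merging groups conserves biomass, production and every intake", {
  m <- generate_model(synthesis_config(n_groups = 8, seed = 5))
  b <- solve_mass_balance(m)
  members <- m$groups$name[m$groups$role == "consumer"][1:2]
  mm <- merge_groups(m, members, "merged")
  bm <- solve_mass_balance(mm)

  expect_equal(n_groups(mm), n_groups(m) - 1)
  expect_equal(sum(mm$groups$B), sum(m$groups$B))
  live_p <- function(bal) sum(bal$P[bal$definition$groups$role != "detritus"])
  expect_equal(live_p(bm), live_p(b), tolerance = 1e-9)
  expect_equal(sum(bm$Q), sum(b$Q), tolerance = 1e-9)
  # every surviving predator keeps its total intake
  common <- intersect(group_names(m), group_names(mm))
  expect_equal(bm$Q[common], b$Q[common], tolerance = 1e-9)
  # merged diet columns still sum to 1
  cons <- mm$groups$role == "consumer"
  expect_equal(unname(colSums(mm$diet)[cons]), rep(1, sum(cons)),
               tolerance = 1e-9)

  expect_error(merge_groups(m, character(0), "x"), "empty")
  expect_error(merge_groups(m, rep(members[1], 2), "x"), "twice")
})

test_that("merging shellfish-like groups sums their biomass", {
  g <- data.frame(
    name = c("phyto", "mussels", "oysters", "barnacles", "pred", "det"),
    role = c("producer", "consumer", "consumer", "consumer", "consumer",
             "detritus"),
    B = c(60, 80.40, 21.76, 30.00, 0.3, 30),
    PB = c(113.82, 5.06, 4.61, 6.15, 5, NA),
    QB = c(NA, 19.34, 20.93, 27.19, 25, NA),
    Ui = c(NA, 0.4, 0.4, 0.2, 0.2, NA)
  )
  d <- matrix(0, 6, 6, dimnames = list(g$name, g$name))
  d["phyto", c("mussels", "oysters", "barnacles")] <- 0.6
  d["det", c("mussels", "oysters", "barnacles")] <- 0.4
  d[c("mussels", "oysters", "barnacles"), "pred"] <- c(0.5, 0.3, 0.2)
  m <- model_definition(g, d)
  mm <- merge_groups(m, c("mussels", "oysters", "barnacles"), "MOB")
  expect_equal(mm$groups$B[mm$groups$name == "MOB"], 132.16)
  expect_equal(unname(mm$diet["MOB", "pred"]), 1)
  expect_equal(unname(colSums(mm$diet)["MOB"]), 1, tolerance = 1e-12)
})
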