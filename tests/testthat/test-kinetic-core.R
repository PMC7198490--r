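test_that("adenylate partition satisfies conservation and equilibrium", {
  # symmetric equilibrium at r = 1 splits the pool in thirds
  ps <- partition_adenines(3, r = 1, K_AK = 1)
  expect_equal(unlist(ps), c(AMP = 1, ADP = 1, ATP = 1))

  # r -> infinity pushes everything into ATP
  pl <- partition_adenines(3, r = 1e12, K_AK = 1)
  expect_lt(pl$AMP + pl$ADP, 1e-10)
  expect_equal(pl$ATP, 3, tolerance = 1e-10)

  # generic case: substitute back into the two defining equations
  pg <- partition_adenines(2.5, r = 4, K_AK = 1)
  expect_lt(abs(pg$AMP + pg$ADP + pg$ATP - 2.5), 1e-10 * 2.5)
  expect_lt(abs(pg$ADP^2 - pg$ATP * pg$AMP), 1e-10 * pg$ADP^2)

  # property: random (A_tot, r, K_AK) all satisfy both identities
  set.seed(7)
  for (i in 1:50) {
    A <- runif(1, 0.01, 10); r <- exp(runif(1, -4, 4)); K <- exp(runif(1, -2, 2))
    pp <- partition_adenines(A, r, K)
    expect_lt(abs(pp$AMP + pp$ADP + pp$ATP - A) / A, 1e-12)
    expect_lt(abs(pp$ADP^2 - K * pp$ATP * pp$AMP) / pp$ADP^2, 1e-10)
    expect_equal(pp$ATP / pp$ADP, r, tolerance = 1e-12)
  }

  expect_error(partition_adenines(-1, 1), class = "formateswitch_domain_error")
  expect_error(partition_adenines(1, 0), class = "formateswitch_domain_error")
})

test_that("energy balance ratio solves supply = demand", {
  # symmetric supply/demand capacities with equal half-saturations give r = 1
  p_sym <- kinetic_params(V_gly = 2, V_ox = 3, V_use = 5,
                          K_gly = 0.5, K_ox = 0.5, K_use = 0.5)
  expect_equal(energy_balance_ratio(1, p_sym), 1, tolerance = 1e-10)

  # overwhelming consumption capacity drives the cell ATP-poor
  p_poor <- kinetic_params(V_use = 500, K_use = 0.5,
                           V_gly = 1, V_ox = 1, K_gly = 0.5, K_ox = 0.5)
  expect_lt(energy_balance_ratio(1, p_poor), 0.05)

  # defaults: plug the root back into the balance equation
  p <- default_params
  r <- energy_balance_ratio(1, p)
  pools <- partition_adenines(1, r, p$K_AK)
  supply <- p$V_gly * pools$ADP / (p$K_gly + pools$ADP) +
    p$V_ox * pools$ADP / (p$K_ox + pools$ADP)
  demand <- p$V_use * pools$ATP / (p$K_use + pools$ATP)
  expect_lt(abs(supply - demand) / demand, 1e-10)

  expect_error(energy_balance_ratio(0, p), class = "formateswitch_domain_error")
})

test_that("steady state solves all four balances on a production grid", {
  p <- default_params
  sw <- sweep_production(p, seq(0, 0.6, length.out = 50))
  res <- sweep_residuals(sw, p)
  expect_lt(max(res$ak), 1e-8)
  for (nm in c("formate", "one_carbon", "energy", "purine")) {
    expect_lt(max(res[[nm]]), 1e-6)
  }
})

test_that("degenerate zero-source input returns the zero fixed point", {
  p <- kinetic_params(q_cyto = 0)
  st <- steady_state(p, v_ser = 0, F_ext = 0)
  expect_equal(st$F, 0)
  expect_equal(st$C, 0)
  expect_equal(st$A_tot, 0)
  expect_equal(st$v_pur, 0)
  expect_false(st$saturated)
})

test_that("exogenous formate alone is taken up and drives purine synthesis", {
  st <- steady_state(default_params, v_ser = 0, F_ext = 1)
  expect_lt(st$v_tr, 0) # net uptake
  expect_gt(st$v_pur, 0)
  # uptake must equal net fixation when there is no endogenous production
  expect_equal(-st$v_tr, st$v_fix, tolerance = 1e-9)
})

test_that("dynamic relaxation reproduces the root-finding steady state", {
  skip_if_not_installed("deSolve")
  p <- default_params
  for (v in c(0.1, 0.35)) {
    st <- steady_state(p, v, 0.02)
    rx <- relax_steady_state(p, v, 0.02, t_end = 20000)
    expect_equal(rx$F, st$F, tolerance = 1e-6)
    expect_equal(rx$C, st$C, tolerance = 1e-6)
    expect_equal(rx$A_tot, st$A_tot, tolerance = 1e-6)
  }
})

test_that("closed system with excess one-carbon supply is flagged saturated", {
  p <- kinetic_params(k_tr = 0)
  st <- steady_state(p, v_ser = 2 * p$n_1C * p$V_pur, F_ext = 0)
  expect_true(st$saturated)
  expect_identical(st$F, Inf)
  # with transport a finite state always exists
  st2 <- steady_state(default_params, v_ser = 2, F_ext = 0)
  expect_false(st2$saturated)
  expect_true(is.finite(st2$F))
})

test_that("predicted quantities increase monotonically with formate production", {
  for (mode in c("ATP_MM", "ADP_MM", "CONSTANT")) {
    p <- kinetic_params(prolif_mode = mode)
    sw <- sweep_production(p, coarse_grid)
    for (q in c("F", "C", "A_tot", "ATP", "ADP", "AMP", "v_pur", "v_gly", "mu")) {
      expect_gte(min(diff(sw[[q]])), -1e-9)
    }
  }
})

test_that("sweep validates its grid and propagates the scenario settings", {
  p <- default_params
  expect_error(sweep_production(p, c(0.2, 0.1)),
               class = "formateswitch_domain_error")
  expect_error(sweep_production(p, c(-0.1, 0.2)),
               class = "formateswitch_domain_error")
  # a single-point grid equals the plain steady-state call
  one <- sweep_production(p, 0.3, "formate_1mM")
  st <- steady_state(p, 0.3, F_ext = 1)
  expect_equal(one[names(st)], st)
  # the cytosolic scenario injects half the fixation capacity
  cy <- sweep_production(p, 0.1, "cytosolic")
  expect_equal(cy$q_cyto, 0.5 * p$V_fts)
})

test_that("exogenous formate and cytosolic production shift predictions left", {
  p <- default_params
  base <- sweep_production(p, coarse_grid, "baseline_0.02mM")
  red <- sweep_production(p, coarse_grid, "formate_1mM")
  cyan <- sweep_production(p, coarse_grid, "cytosolic")
  for (q in c("F", "ATP", "ADP", "AMP", "v_pur", "v_gly", "mu")) {
    expect_gte(min(red[[q]] - base[[q]]), -1e-9)
    expect_gte(min(cyan[[q]] - base[[q]]), -1e-9)
  }
})

test_that("parameter objects validate and round-trip through JSON", {
  expect_error(kinetic_params(V_fts = -1), class = "formateswitch_domain_error")
  expect_error(kinetic_params(n_1C = 0), class = "formateswitch_domain_error")
  expect_error(kinetic_params(prolif_mode = "bogus"))
  path <- withr::local_tempfile(fileext = ".json")
  p <- kinetic_params(V_fts = 0.77, prolif_mode = "ADP_MM")
  write_kinetic_params(p, path)
  expect_equal(read_kinetic_params(path), p)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(V_fts = 1, nonsense = 2), bad, auto_unbox = TRUE)
  expect_error(read_kinetic_params(bad), class = "formateswitch_domain_error")
})
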