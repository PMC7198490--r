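test_that("production rate follows the Hill law in ATP", {
  p <- threshold_params(Vp = 2, Kp = 1, h = 1)
  expect_equal(production_rate(0, p), 0)
  expect_equal(production_rate(1, p), 1)        # half-saturation: Vp/2
  expect_equal(production_rate(1e9, p), 2, tolerance = 1e-8)
  p2 <- threshold_params(Vp = 3, Kp = 0.8, h = 2)
  expect_equal(production_rate(0.8, p2), 1.5)
  expect_error(production_rate(-1, p), class = "formateswitch_domain_error")
  expect_error(threshold_params(h = 0.5), class = "formateswitch_domain_error")
})

test_that("steady-state level matches an independent root-finder", {
  p <- threshold_params(Vp = 2, Kp = 6, Vt = 1, Kt = 1.7)
  atp <- seq(0.2, 0.9 * critical_atp(p), length.out = 25)
  closed <- orotate_steady_state(atp, p)
  for (i in seq_along(atp)) {
    v <- production_rate(atp[i], p)
    # oracle: solve the turnover balance numerically, independent of the
    # closed form
    root <- uniroot(function(o) p$Vt * o / (p$Kt + o) - v,
                    c(0, 1e9), tol = 1e-14)$root
    expect_lt(abs(closed[i] - root) / root, 1e-10)
  }
})

test_that("turnover half-saturation point gives level equal to Kt", {
  p <- threshold_params(Vp = 2, Kp = 1, Vt = 1, Kt = 3)
  # production equals Vt/2 exactly at ATP = Kp/(2 Vp/Vt - 1)^(1/h) = Kp/3
  atp_half <- p$Kp / 3
  expect_equal(orotate_steady_state(atp_half, p), 3, tolerance = 1e-12)
})

test_that("levels stay finite when turnover capacity exceeds production", {
  p <- threshold_params(Vp = 0.8, Kp = 1, Vt = 1, Kt = 1)
  expect_true(is.na(critical_atp(p)))
  expect_true(all(is.finite(orotate_steady_state(c(0.1, 1, 100, 1e6), p))))
})

test_that("divergence is one-sided at the critical ATP", {
  p <- threshold_params(Vp = 2, Vt = 1, Kp = 1, h = 1)
  crit <- critical_atp(p)
  expect_equal(crit, 1)
  expect_equal(production_rate(crit, p), p$Vt, tolerance = 1e-12)
  # finite below, unbounded at and above
  expect_true(all(is.finite(orotate_steady_state(crit * (1 - 10^(-(1:6))), p))))
  expect_identical(orotate_steady_state(crit, p), Inf)
  expect_identical(orotate_steady_state(crit * 1.5, p), Inf)
  # the level exceeds any bound as ATP approaches the critical value
  expect_gt(orotate_steady_state(crit * (1 - 1e-9), p), 1e6)
  # h = 2 compresses the critical point in log-ATP
  p2 <- threshold_params(Vp = 2, Vt = 1, Kp = 1, h = 2)
  expect_equal(critical_atp(p2), sqrt(1))
  expect_equal(production_rate(critical_atp(p2), p2), 1, tolerance = 1e-12)
})

test_that("level is strictly increasing in ATP wherever finite and 0 at 0", {
  p <- threshold_params(Vp = 2, Kp = 6, Vt = 1, Kt = 1)
  atp <- seq(0, 0.99 * critical_atp(p), length.out = 200)
  lev <- orotate_steady_state(atp, p)
  expect_equal(lev[1], 0)
  expect_true(all(diff(lev) > 0))
})

test_that("Hill-2 cooperativity steepens the normalized response at Kp", {
  # d/dATP of v/Vp at ATP = Kp is h/(4 Kp): the argininosuccinate curve
  # (h = 2) is steeper there than the orotate curve (h = 1)
  slope_at_kp <- function(h) {
    p <- threshold_params(Vp = 1, Kp = 1, h = h)
    dx <- 1e-6
    (production_rate(1 + dx, p) - production_rate(1 - dx, p)) / (2 * dx)
  }
  expect_gt(slope_at_kp(2), slope_at_kp(1))
  expect_equal(slope_at_kp(2) / slope_at_kp(1), 2, tolerance = 1e-4)
})

test_that("threshold-model fit recovers generating parameters", {
  truth <- threshold_params(Vp = 2, Kp = 6, Vt = 1, Kt = 1)
  sc <- gen_orotate_scatter(truth, noise_frac = 0, seed = 5)
  f <- fit_threshold_model(sc, h = 1)
  expect_lt(abs(f$params$Vp / truth$Vp - 1), 1e-4)
  expect_lt(abs(f$params$Kp - truth$Kp) / truth$Kp, 1e-4)
  # the Hill-2 analogue round-trips as well
  truth2 <- threshold_params(Vp = 3, Kp = 2, h = 2, Vt = 1, Kt = 1)
  sc2 <- gen_orotate_scatter(truth2, noise_frac = 0, seed = 6)
  f2 <- fit_threshold_model(sc2, h = 2)
  expect_lt(abs(f2$params$Vp / truth2$Vp - 1), 1e-4)
  expect_lt(abs(f2$params$Kp - truth2$Kp) / truth2$Kp, 1e-4)
})

test_that("capacity ratio is recovered within 15% under 10% noise", {
  truth <- threshold_params(Vp = 2, Kp = 6, Vt = 1, Kt = 1)
  errs <- vapply(1:100, function(i) {
    sc <- gen_orotate_scatter(truth, n = 30, noise_frac = 0.1, seed = 500 + i)
    abs(fit_threshold_model(sc, h = 1)$params$Vp / truth$Vp - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("flat scatter yields the no-threshold regime", {
  set.seed(11)
  flat <- tibble::tibble(ATP = seq(0.5, 5, length.out = 40),
                         level = 2 * (1 + rnorm(40, 0, 0.05)))
  f <- fit_threshold_model(flat, h = 1)
  expect_lt(f$params$Vp, 1) # production never exceeds turnover: no divergence
  expect_lt(f$R2, 0.3)
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
  expect_equal(tidy(f)$term, c("Vp_over_Vt", "Kp", "Kt"))
})

test_that("orotate scatter generator enforces the sub-critical grid", {
  truth <- threshold_params(Vp = 2, Kp = 6, Vt = 1, Kt = 1)
  sc <- gen_orotate_scatter(truth, noise_frac = 0.1, seed = 1)
  expect_true(all(sc$ATP < critical_atp(truth)))
  expect_identical(sc, gen_orotate_scatter(truth, noise_frac = 0.1, seed = 1))
  expect_error(
    gen_orotate_scatter(truth, atp_grid = c(1, critical_atp(truth) + 1)),
    class = "formateswitch_domain_error"
  )
})
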