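test_that("chain rates vanish without acceptor or redox partner", {
  expect_equal(glycolysis_rate(0, 2, 0.5, 0.1), 0)
  expect_equal(glycolysis_rate(0.5, 2, 0, 0.1), 0)   # oxidation blocked
  expect_equal(glycolysis_rate(0.5, 2, 0.5, 0), 0)   # terminal step blocked
  expect_equal(oxphos_rate(0, 2, 0.5, 0.1), 0)
  expect_equal(oxphos_rate(0.5, 2, 0.5, 0), 0)
  expect_error(glycolysis_rate(-1, 1, 1, 1), class = "formateswitch_domain_error")
})

test_that("detailed rates are deterministic and monotone in ADP", {
  cf <- sample_cofactors(100, seed = 3)
  g1 <- glycolysis_rate(cf$ADP, cf$ATP, cf$NAD_ox, cf$NAD_red)
  g2 <- glycolysis_rate(cf$ADP, cf$ATP, cf$NAD_ox, cf$NAD_red)
  expect_identical(g1, g2)
  adp <- seq(0.001, 5, length.out = 100)
  expect_gte(min(diff(glycolysis_rate(adp, 2, 0.5, 0.1))), 0)
  expect_gte(min(diff(oxphos_rate(adp, 2, 0.5, 0.1))), 0)
})

test_that("cofactor sampling is reproducible and respects its ranges", {
  a <- sample_cofactors(500, seed = 1)
  b <- sample_cofactors(500, seed = 1)
  expect_identical(a, b)
  expect_true(all(a$ADP >= 0.01 & a$ADP <= 5))
  expect_true(all(a$NAD_ox >= 0.01 & a$NAD_ox <= 1))
  d <- sample_cofactors(500, seed = 2)
  expect_false(identical(a, d))
  expect_error(sample_cofactors(0), class = "formateswitch_domain_error")
  expect_error(sample_cofactors(5, ranges = list(ADP = c(2, 1))),
               class = "formateswitch_domain_error")
})

test_that("an effective Michaelis-Menten law emerges from the sampled cloud", {
  cf <- sample_cofactors(500, seed = 1)
  fg <- fit_michaelis_menten(
    tibble::tibble(substrate = cf$ADP,
                   rate = glycolysis_rate(cf$ADP, cf$ATP, cf$NAD_ox, cf$NAD_red))
  )
  fo <- fit_michaelis_menten(
    tibble::tibble(substrate = cf$ADP,
                   rate = oxphos_rate(cf$ADP, cf$ATP, cf$NAD_ox, cf$NAD_red))
  )
  expect_gte(fg$R2, 0.9)
  expect_gte(fo$R2, 0.9)
})

test_that("the fitter recovers exact Michaelis-Menten curves", {
  pts <- gen_mm_points(Vmax = 2, Km = 0.5, n = 60, noise_frac = 0, seed = 1)
  f <- fit_michaelis_menten(pts)
  expect_equal(f$Vmax, 2, tolerance = 1e-8)
  expect_equal(f$Km, 0.5, tolerance = 1e-8)
  expect_equal(f$R2, 1, tolerance = 1e-12)

  # two distinct substrate levels determine the two parameters exactly
  two <- tibble::tibble(substrate = c(0.2, 2, 0.2, 2),
                        rate = 3 * c(0.2, 2, 0.2, 2) / (0.7 + c(0.2, 2, 0.2, 2)))
  f2 <- fit_michaelis_menten(two)
  expect_equal(f2$Vmax, 3, tolerance = 1e-7)
  expect_equal(f2$Km, 0.7, tolerance = 1e-7)
})

test_that("Km is recovered within 10% under 5% multiplicative noise", {
  errs <- vapply(1:100, function(i) {
    pts <- gen_mm_points(Vmax = 2, Km = 0.5, n = 200, noise_frac = 0.05,
                         seed = 100 + i)
    abs(fit_michaelis_menten(pts)$Km - 0.5) / 0.5
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("the fit is exactly scale-equivariant in the rates", {
  pts <- gen_mm_points(Vmax = 2, Km = 0.5, n = 80, noise_frac = 0.1, seed = 9)
  f1 <- fit_michaelis_menten(pts)
  c_scale <- 137.5
  f2 <- fit_michaelis_menten(dplyr::mutate(pts, rate = rate * c_scale))
  expect_lt(abs(f2$Vmax - c_scale * f1$Vmax) / (c_scale * f1$Vmax), 1e-10)
  expect_lt(abs(f2$Km - f1$Km) / f1$Km, 1e-10)
})

test_that("degenerate fitting designs are rejected", {
  expect_error(
    fit_michaelis_menten(tibble::tibble(substrate = c(1, 1, 1),
                                        rate = c(0.5, 0.6, 0.4))),
    class = "formateswitch_fit_error"
  )
  expect_error(
    fit_michaelis_menten(tibble::tibble(substrate = c(1, 2), rate = c(1, 2))),
    class = "formateswitch_fit_error"
  )
})

test_that("fit objects expose tidy, glance and autoplot", {
  f <- fit_michaelis_menten(gen_mm_points(n = 30, noise_frac = 0, seed = 2))
  td <- tidy(f)
  expect_equal(td$term, c("Vmax", "Km"))
  gl <- glance(f)
  expect_equal(gl$nobs, 30)
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
})
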