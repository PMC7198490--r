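test_that("index slope behaves as the OLS trend per index step", {
  expect_equal(index_slope(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(index_slope(c(5, 5, 5), c(0, 1, 2)), 0)
  expect_equal(index_slope(c(2, 1, 0), c(0, 1, 2)), -1)
  # tied indices of the six-condition design
  x <- c(0, 1, 1, 2, 2, 2)
  y <- 3 + 0.5 * x
  expect_equal(index_slope(y, x), 0.5)
  expect_error(index_slope(c(1, 2), c(1, 1)), class = "formateswitch_domain_error")
})

test_that("condition index lookup follows the design", {
  d <- gen_condition_design()
  expect_identical(assign_oc_index("MFT-SHMT1", d), 0L)
  expect_identical(assign_oc_index(c("MFT", "SHMT2"), d), c(1L, 1L))
  expect_identical(
    assign_oc_index(c("MFT + 1 mM Formate", "SHMT2 + 1 mM Formate", "WT"), d),
    c(2L, 2L, 2L)
  )
  expect_error(assign_oc_index("HeLa", d), class = "formateswitch_domain_error")
})

test_that("spearman statistic equals the explicit average-rank formula", {
  expect_equal(spearman_index(c(1, 5, 9), c(0, 1, 2)), 1)
  expect_equal(spearman_index(c(9, 5, 1), c(0, 1, 2)), -1)
  # tie structure of the standard design, against a direct rank computation
  x <- c(0, 1, 1, 2, 2, 2)
  y <- c(0.3, 1.1, 0.9, 2.5, 2.2, 2.8)
  rx <- rank(x); ry <- rank(y)
  manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_index(y, x), manual, tolerance = 1e-12)
})

test_that("spearman is invariant to strictly monotone transforms", {
  set.seed(21)
  for (i in 1:20) {
    x <- c(0, 1, 1, 2, 2, 2)
    y <- rnorm(6)
    s0 <- spearman_index(y, x)
    expect_equal(spearman_index(exp(y), x), s0, tolerance = 1e-12)
    expect_equal(spearman_index(2 * y^3 + y, x), s0, tolerance = 1e-12)
  }
})

test_that("exhaustive permutation p matches direct enumeration", {
  # (1,2,3) against indices (0,1,2): only the identity reaches slope 1
  res <- permutation_p(c(1, 2, 3), c(0, 1, 2), alternative = "greater")
  expect_true(res$exhaustive)
  expect_equal(res$n_used, 6)
  expect_equal(res$p_value, 1 / 6)
  # two-sided: the reversed ordering ties in absolute value
  res2 <- permutation_p(c(1, 2, 3), c(0, 1, 2), alternative = "two_sided")
  expect_equal(res2$p_value, 2 / 6)
  # all values equal: every permutation ties
  res3 <- permutation_p(rep(1, 4), c(0, 1, 1, 2))
  expect_equal(res3$p_value, 1)
})

test_that("Monte-Carlo p agrees with the exhaustive oracle within its CI", {
  y <- c(0.2, 1.4, 0.9, 2.7, 2.0, 2.4)
  x <- c(0, 1, 1, 2, 2, 2)
  exact <- permutation_p(y, x, n_perm = 720)
  expect_true(exact$exhaustive)
  mc <- permutation_p(y, x, n_perm = 1e4, seed = 42, exhaustive = "never")
  expect_false(mc$exhaustive)
  # 99% binomial interval around the exact p (the +1 correction is
  # negligible at this budget)
  half <- 2.576 * sqrt(exact$p_value * (1 - exact$p_value) / 1e4)
  expect_lt(abs(mc$p_value - exact$p_value), half + 2e-4)
})

test_that("the Monte-Carlo p-value floor is 1/(n_perm + 1)", {
  # eight units (8! = 40320 assignments) so a 199-draw sample essentially
  # never revisits the identity, the only ordering reaching the observed
  # statistic
  y <- c(0, 10, 20, 30, 40, 50, 60, 5000)
  x <- 0:7
  res <- permutation_p(y, x, n_perm = 199, seed = 1, alternative = "greater")
  expect_false(res$exhaustive)
  expect_equal(res$p_value, 1 / 200)
  expect_identical(res,
                   permutation_p(y, x, n_perm = 199, seed = 1,
                                 alternative = "greater"))
})

test_that("table-level associations recover the planted log2 trend", {
  design <- gen_condition_design()
  sim <- gen_proteomics(n_features = 40, frac_responsive = 0.5,
                        true_slope = 1, noise_sd = 0, seed = 3)
  assoc <- oc_associations(sim$table, design, n_perm = 720, seed = 1)
  expect_true(all(assoc$exhaustive))
  resp <- sim$truth$responsive
  # with no replicate noise the slope is exactly the planted trend
  expect_equal(assoc$estimate[resp], rep(1, sum(resp)), tolerance = 1e-9)
  expect_equal(assoc$estimate[!resp], rep(0, sum(!resp)), tolerance = 1e-9)
  # replicate-level block permutation gives the same estimates
  assoc_r <- oc_associations(sim$table, design, n_perm = 720, seed = 1,
                             permute = "replicate")
  expect_equal(assoc_r$estimate, assoc$estimate, tolerance = 1e-9)
  # BH adjustment is opt-in only
  expect_false("p_adjusted" %in% names(assoc))
  expect_true("p_adjusted" %in%
                names(oc_associations(sim$table, design, n_perm = 10,
                                      seed = 1, adjust = TRUE)))
})

test_that("zeros are masked rather than carried into the log2 transform", {
  design <- gen_condition_design()
  sim <- gen_proteomics(n_features = 5, frac_responsive = 0, noise_sd = 0,
                        seed = 4)
  tab <- sim$table
  tab[["MFT_R1"]][1] <- 0 # one missing measurement for feature 1
  assoc <- oc_associations(tab, design, n_perm = 720, seed = 1)
  expect_true(all(is.finite(assoc$estimate)))
  expect_equal(assoc$estimate[1], 0, tolerance = 1e-9)
})

test_that("welch test matches the explicit Satterthwaite formula", {
  a <- c(1, 2, 3); b <- c(4, 5, 7)
  res <- welch_t(a, b)
  # independent arithmetic: t = -sqrt(10), df = 100/29
  se2 <- var(a) / 3 + var(b) / 3
  t_manual <- (mean(a) - mean(b)) / sqrt(se2)
  df_manual <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$t, -sqrt(10), tolerance = 1e-10)
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$df, df_manual, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(t_manual, df_manual), tolerance = 1e-10)
  # symmetry and the identical-group edge
  swapped <- welch_t(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_value, res$p_value)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t(1, c(1, 2)), class = "formateswitch_domain_error")
})

test_that("pathway mass is additive and matches a hand summed toy", {
  tab <- tibble::tibble(
    feature = c("a", "b", "c"),
    X_R1 = c(1, 10, 100), X_R2 = c(3, 10, 100),
    Y_R1 = c(5, 20, 200), Y_R2 = c(5, 20, 200)
  )
  attr(tab, "value_scale") <- "raw"
  m <- pathway_mass(tab, list(ab = c("a", "b")))
  # replicates averaged first: X -> 2 + 10, Y -> 5 + 20
  expect_equal(m$mass[m$condition == "X"], 12)
  expect_equal(m$mass[m$condition == "Y"], 25)
  # disjoint sets sum to the all-features total
  parts <- pathway_mass(tab, list(s1 = c("a", "b"), s2 = "c"))
  total <- pathway_mass(tab, list(all = c("a", "b", "c")))
  sums <- tapply(parts$mass, parts$condition, sum)
  expect_equal(as.numeric(sums[total$condition]), total$mass)
  # invariant to feature order
  shuffled <- tab[c(3, 1, 2), ]
  attr(shuffled, "value_scale") <- "raw"
  m2 <- pathway_mass(shuffled, list(ab = c("b", "a")))
  expect_equal(m2$mass, m$mass)
})
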