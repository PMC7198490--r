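#' Partition total adenine nucleotides by the adenylate kinase equilibrium
#'
#' The adenylate kinase reaction ATP + AMP <-> 2 ADP is fast relative to the
#' net fluxes of the model, so at any accepted state the three free pools
#' satisfy `ADP^2 = K_AK * ATP * AMP` together with conservation
#' `AMP + ADP + ATP = A_tot`. Given the ATP/ADP ratio `r` this has the
#' closed-form split `ADP = A_tot / (1 + r + 1/(K_AK * r))`, `ATP = r * ADP`,
#' `AMP = ADP / (K_AK * r)`.
#'
#' @param A_tot Total free adenine nucleotide pool AMP + ADP + ATP (mM).
#' @param r ATP/ADP ratio (dimensionless, > 0).
#' @param K_AK Adenylate kinase equilibrium constant (dimensionless).
#' @return A tibble with columns `AMP`, `ADP`, `ATP` (mM), one row per input
#'   element (inputs are recycled as in arithmetic).
#' @export
#' @examples
#' partition_adenines(3, r = 1, K_AK = 1) # symmetric split: 1 mM each
partition_adenines <- function(A_tot, r, K_AK = 1) {
  if (any(!is.finite(A_tot)) || any(A_tot <= 0)) {
    abort("partition_adenines: `A_tot` must be positive and finite.",
          class = "formateswitch_domain_error")
  }
  if (any(!is.finite(r)) || any(r <= 0) || any(K_AK <= 0)) {
    abort("partition_adenines: `r` and `K_AK` must be positive.",
          class = "formateswitch_domain_error")
  }
  adp <- A_tot / (1 + r + 1 / (K_AK * r))
  tibble::tibble(AMP = adp / (K_AK * r), ADP = adp, ATP = r * adp)
}

# bare-arithmetic version used inside solvers (no validation, list out)
.partition <- function(A_tot, r, K_AK) {
  adp <- A_tot / (1 + r + 1 / (K_AK * r))
  list(AMP = adp / (K_AK * r), ADP = adp, ATP = r * adp)
}

.supply_rate <- function(ADP, p) {
  p$V_gly * ADP / (p$K_gly + ADP) + p$V_ox * ADP / (p$K_ox + ADP)
}

.demand_rate <- function(ATP, p) {
  p$V_use * ATP / (p$K_use + ATP)
}

# ATP/ADP ratio in the limit A_tot -> 0, from the linearized balance
.r_zero_limit <- function(p) {
  p$K_use * (p$V_gly / p$K_gly + p$V_ox / p$K_ox) / p$V_use
}

#' ATP/ADP ratio balancing ADP phosphorylation against ATP consumption
#'
#' Solves, for a fixed total adenine pool, the energy balance
#' `V_gly*ADP/(K_gly+ADP) + V_ox*ADP/(K_ox+ADP) = V_use*ATP/(K_use+ATP)`
#' where the pools follow [partition_adenines()] at the returned ratio. The
#' root is bracketed in log(r) and refined to a relative tolerance of 1e-12.
#'
#' @param A_tot Total adenine nucleotide pool (mM, > 0).
#' @param p A [kinetic_params()] object.
#' @return The ATP/ADP ratio `r` (> 0).
#' @export
#' @examples
#' p <- kinetic_params()
#' r <- energy_balance_ratio(1, p)
#' partition_adenines(1, r, p$K_AK)
energy_balance_ratio <- function(A_tot, p) {
  p <- validate_kinetic_params(p)
  if (!is.finite(A_tot) || A_tot <= 0) {
    abort("energy_balance_ratio: `A_tot` must be positive.",
          class = "formateswitch_domain_error")
  }
  g <- function(logr) {
    pools <- .partition(A_tot, exp(logr), p$K_AK)
    .supply_rate(pools$ADP, p) - .demand_rate(pools$ATP, p)
  }
  lo <- -27.6; hi <- 27.6 # r in ~[1e-12, 1e12]
  glo <- g(lo); ghi <- g(hi)
  if (glo <= 0 && ghi <= 0) {
    abort(paste0("energy_balance_ratio: no balance on the search bracket; ",
                 "ADP phosphorylation capacity (V_gly + V_ox) is limiting."),
          class = "formateswitch_balance_error")
  }
  if (glo >= 0 && ghi >= 0) {
    abort(paste0("energy_balance_ratio: no balance on the search bracket; ",
                 "ATP consumption capacity (V_use) is limiting."),
          class = "formateswitch_balance_error")
  }
  exp(uniroot(g, c(lo, hi), tol = 1e-13)$root)
}

# steady 1C pool for a given total 1C supply s = gross fixation + q_cyto.
# Solves s = k_rev*C + n_1C*V_pur*C/(K_C + C); closed form (quadratic).
.c_pool <- function(s, p) {
  if (s <= 0) return(0)
  nVp <- p$n_1C * p$V_pur
  if (p$k_rev == 0) {
    if (s >= nVp) return(Inf)
    return(p$K_C * s / (nVp - s))
  }
  b <- p$k_rev * p$K_C + nVp - s
  (-b + sqrt(b * b + 4 * p$k_rev * s * p$K_C)) / (2 * p$k_rev)
}

# A_tot solving v_pur = mu(A_tot) * A_tot for the MM proliferation couplings
.a_tot_from_vpur <- function(v_pur, p) {
  if (v_pur <= 0) return(0)
  if (p$prolif_mode == "CONSTANT") return(v_pur / p$mu_max)
  mu_of <- function(A) {
    r <- energy_balance_ratio(A, p)
    pools <- .partition(A, r, p$K_AK)
    x <- if (p$prolif_mode == "ATP_MM") pools$ATP else pools$ADP
    p$mu_max * x / (p$K_mu + x)
  }
  psi <- function(A) mu_of(A) * A - v_pur
  lo <- 1e-12
  hi <- max(v_pur / p$mu_max, 1e-6)
  it <- 0L
  while (psi(hi) < 0 && it < 200L) { hi <- hi * 2; it <- it + 1L }
  if (psi(hi) < 0) {
    abort("steady_state: purine-pool balance did not bracket a root.",
          class = "formateswitch_solver_error")
  }
  uniroot(psi, c(lo, hi), tol = hi * 1e-13)$root
}

#' Steady state of the formate--purine--energy model
#'
#' Solves the coupled steady-state system for a given mitochondrial
#' serine-to-formate production rate and extracellular formate
#' concentration: the formate balance (production, passive transport, net
#' fixation), the one-carbon pool balance, the purine-pool growth balance
#' `v_pur = mu * A_tot`, and the energy balance (see
#' [energy_balance_ratio()]). The solution is obtained by nested
#' deterministic scalar root finding (intracellular formate first, then the
#' total adenine pool), not by ODE integration; [relax_steady_state()]
#' provides an independent dynamic cross-check.
#'
#' If `k_tr = 0` and the one-carbon supply exceeds what purine synthesis and
#' the reverse flux can consume, no finite steady state exists and a row
#' flagged `saturated = TRUE` with `F = Inf` is returned. With `k_tr > 0` a
#' finite state always exists (excess formate is exported).
#'
#' @param p A [kinetic_params()] object.
#' @param v_ser Mitochondrial serine catabolism to formate rate (mM/h, >= 0).
#' @param F_ext Extracellular formate concentration (mM, >= 0).
#' @return A one-row tibble with the cell state (`F`, `C`, `A_tot`, `AMP`,
#'   `ADP`, `ATP`, `r`) and flux vector (`v_ser`, `v_tr`, `v_fix`, `v_pur`,
#'   `v_gly`, `v_ox`, `v_use`, `mu`) plus `F_ext`, `q_cyto` and a
#'   `saturated` flag. `v_tr = k_tr*(F - F_ext)`; positive values are net
#'   formate release, negative net uptake.
#' @export
#' @examples
#' p <- kinetic_params()
#' steady_state(p, v_ser = 0.2, F_ext = 0.02)
#' # exogenous formate alone drives purine synthesis (net uptake, v_tr < 0):
#' steady_state(p, v_ser = 0, F_ext = 1)
steady_state <- function(p, v_ser, F_ext = 0.02) {
  p <- validate_kinetic_params(p)
  if (!is.finite(v_ser) || v_ser < 0 || !is.finite(F_ext) || F_ext < 0) {
    abort("steady_state: `v_ser` and `F_ext` must be non-negative.",
          class = "formateswitch_domain_error")
  }

  vfg <- function(F) p$V_fts * F / (p$K_F + F) # gross fixation

  if (p$k_tr == 0) {
    # closed system: v_ser + q_cyto must be fully consumed by purines
    tot <- v_ser + p$q_cyto
    if (tot >= p$n_1C * p$V_pur) {
      return(.saturated_state(p, v_ser, F_ext))
    }
    v_pur <- tot / p$n_1C
    C <- p$K_C * v_pur / (p$V_pur - v_pur)
    g <- v_ser + p$k_rev * C # gross fixation carries production + recycling
    if (g >= p$V_fts) {
      return(.saturated_state(p, v_ser, F_ext))
    }
    F <- if (g <= 0) 0 else p$K_F * g / (p$V_fts - g)
  } else {
    # h(F) is strictly decreasing with h(0) >= 0: unique root
    h <- function(F) {
      C <- .c_pool(vfg(F) + p$q_cyto, p)
      v_fix_net <- vfg(F) - p$k_rev * C
      v_ser + p$k_tr * (F_ext - F) - v_fix_net
    }
    if (h(0) <= 0) {
      F <- 0
    } else {
      hi <- max(F_ext, p$K_F, 1e-3)
      it <- 0L
      while (h(hi) > 0 && it < 200L) { hi <- hi * 2; it <- it + 1L }
      if (h(hi) > 0) {
        abort("steady_state: formate balance did not bracket a root.",
              class = "formateswitch_solver_error")
      }
      F <- uniroot(h, c(0, hi), tol = max(hi, 1) * 1e-14)$root
    }
  }

  # report fluxes through the conservation identities so that the formate
  # and one-carbon balances hold exactly; the root tolerance on F only
  # affects the (tight) rate-law consistency
  if (p$k_tr == 0) {
    v_fix <- v_ser
  } else {
    v_fix <- v_ser + p$k_tr * (F_ext - F)
  }
  v_pur <- (v_fix + p$q_cyto) / p$n_1C
  C <- if (v_pur <= 0) 0 else if (v_pur < p$V_pur) {
    p$K_C * v_pur / (p$V_pur - v_pur)
  } else {
    Inf
  }
  v_tr <- p$k_tr * (F - F_ext)
  A_tot <- .a_tot_from_vpur(v_pur, p)

  if (A_tot <= 0) {
    r <- .r_zero_limit(p)
    pools <- list(AMP = 0, ADP = 0, ATP = 0)
  } else {
    r <- energy_balance_ratio(A_tot, p)
    pools <- .partition(A_tot, r, p$K_AK)
  }
  mu <- switch(p$prolif_mode,
    ATP_MM = p$mu_max * pools$ATP / (p$K_mu + pools$ATP),
    ADP_MM = p$mu_max * pools$ADP / (p$K_mu + pools$ADP),
    CONSTANT = p$mu_max
  )

  tibble::tibble(
    v_ser = v_ser, F_ext = F_ext, q_cyto = p$q_cyto,
    F = F, C = C, A_tot = A_tot,
    AMP = pools$AMP, ADP = pools$ADP, ATP = pools$ATP, r = r,
    v_tr = v_tr, v_fix = v_fix, v_pur = v_pur,
    v_gly = p$V_gly * pools$ADP / (p$K_gly + pools$ADP),
    v_ox = p$V_ox * pools$ADP / (p$K_ox + pools$ADP),
    v_use = p$V_use * pools$ATP / (p$K_use + pools$ATP),
    mu = mu, saturated = FALSE
  )
}

.saturated_state <- function(p, v_ser, F_ext) {
  tibble::tibble(
    v_ser = v_ser, F_ext = F_ext, q_cyto = p$q_cyto,
    F = Inf, C = Inf, A_tot = NA_real_,
    AMP = NA_real_, ADP = NA_real_, ATP = NA_real_, r = NA_real_,
    v_tr = 0, v_fix = NA_real_, v_pur = p$V_pur,
    v_gly = NA_real_, v_ox = NA_real_, v_use = NA_real_,
    mu = NA_real_, saturated = TRUE
  )
}

#' Sweep the formate production rate under the standard scenarios
#'
#' Computes steady states along a grid of serine-to-formate production
#' rates under one of the three standard conditions: `baseline_0.02mM`
#' (0.02 mM extracellular formate, no cytosolic one-carbon production),
#' `formate_1mM` (1 mM extracellular formate) or `cytosolic` (0.02 mM
#' extracellular formate plus a cytosolic 10-formyl-THF production flux set
#' to 50% of the maximal 10-formyl-THF synthetase activity). Exogenous
#' formate and the cytosolic flux both shift the predicted transition to
#' lower production rates (the "left shift").
#'
#' @param p A [kinetic_params()] object. The scenario overrides `F_ext` and
#'   `q_cyto`.
#' @param v_ser_grid Strictly increasing non-negative grid of production
#'   rates (mM/h).
#' @param scenario One of `"baseline_0.02mM"`, `"formate_1mM"`,
#'   `"cytosolic"`.
#' @return A tibble with one [steady_state()] row per grid point and a
#'   `scenario` column.
#' @seealso [overflow_threshold()], [plot_sweep()]
#' @export
#' @examples
#' sw <- sweep_production(kinetic_params(), seq(0, 0.6, length.out = 11))
#' sw[, c("v_ser", "ATP", "v_tr")]
sweep_production <- function(p, v_ser_grid,
                             scenario = c("baseline_0.02mM", "formate_1mM",
                                          "cytosolic")) {
  scenario <- match.arg(scenario)
  p <- validate_kinetic_params(p)
  if (length(v_ser_grid) < 1L || any(v_ser_grid < 0) ||
      (length(v_ser_grid) > 1L && any(diff(v_ser_grid) <= 0))) {
    abort("sweep_production: `v_ser_grid` must be non-negative and strictly increasing.",
          class = "formateswitch_domain_error")
  }
  sc <- switch(scenario,
    baseline_0.02mM = list(F_ext = 0.02, q_cyto = 0),
    formate_1mM = list(F_ext = 1, q_cyto = 0),
    cytosolic = list(F_ext = 0.02, q_cyto = 0.5 * p$V_fts)
  )
  p$q_cyto <- sc$q_cyto
  out <- purrr::map(v_ser_grid, function(v) {
    tryCatch(steady_state(p, v, sc$F_ext),
             error = function(e) {
               abort(sprintf("sweep_production: failure at grid point v_ser = %g: %s",
                             v, conditionMessage(e)),
                     class = "formateswitch_solver_error")
             })
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(scenario = scenario, .before = 1)
}

#' Formate overflow threshold
#'
#' Locates the smallest production rate `v_ser` at which the net formate
#' release reaches a fraction `eps` of production (`v_tr >= eps * v_ser`),
#' i.e. the onset of formate overflow. Because transport is passive, some
#' release occurs whenever intracellular formate exceeds the extracellular
#' level, so the operational `eps`-crossing is reported alongside the
#' analytic demand bound `n_1C * V_pur - q_cyto` (the production rate at
#' which purine demand saturates).
#'
#' @param p A [kinetic_params()] object.
#' @param F_ext Extracellular formate (mM).
#' @param eps Release fraction defining the operational threshold, in (0,1).
#' @param v_max Upper end of the searched production range (mM/h); defaults
#'   to 20x the analytic demand bound.
#' @return A one-row tibble with columns `v_ser_star` (NA when the crossing
#'   is not found on the searched range), `analytic_bound`, `eps`, `found`.
#' @export
#' @examples
#' overflow_threshold(kinetic_params(), F_ext = 0.02)
overflow_threshold <- function(p, F_ext = 0.02, eps = 0.05, v_max = NULL) {
  p <- validate_kinetic_params(p)
  if (!is.finite(eps) || eps <= 0 || eps >= 1) {
    abort("overflow_threshold: `eps` must lie in (0, 1).",
          class = "formateswitch_domain_error")
  }
  bound <- p$n_1C * p$V_pur - p$q_cyto
  v_max <- v_max %||% (20 * max(bound, p$V_fts))
  g <- function(v) {
    st <- steady_state(p, v, F_ext)
    st$v_tr - eps * v
  }
  # coarse bisection on a sweep, then root refinement
  grid <- seq(0, v_max, length.out = 64L)
  vals <- vapply(grid, g, numeric(1))
  idx <- which(vals[-1L] > 0 & vals[-length(vals)] <= 0)
  if (!length(idx)) {
    if (vals[1L] > 0) {
      return(tibble::tibble(v_ser_star = 0, analytic_bound = bound,
                            eps = eps, found = TRUE))
    }
    return(tibble::tibble(v_ser_star = NA_real_, analytic_bound = bound,
                          eps = eps, found = FALSE))
  }
  i <- idx[1L]
  root <- uniroot(g, c(grid[i], grid[i + 1L]), tol = 1e-7 * max(grid[i + 1L], 1e-6))$root
  tibble::tibble(v_ser_star = root, analytic_bound = bound, eps = eps,
                 found = TRUE)
}

#' Relax the model dynamically to its steady state (cross-check)
#'
#' Integrates the dynamic counterpart of the model (ODEs for intracellular
#' formate, the one-carbon pool and the total adenine pool, with the
#' adenylate kinase split and the energy balance treated as fast) until
#' `t_end` and returns the final state. This is an independent check on the
#' root-finding solver in [steady_state()]; it requires the `deSolve`
#' package.
#'
#' @inheritParams steady_state
#' @param t_end Integration horizon (h).
#' @return A one-row tibble with `F`, `C`, `A_tot` at `t_end`.
#' @export
relax_steady_state <- function(p, v_ser, F_ext = 0.02, t_end = 5000) {
  if (!requireNamespace("deSolve", quietly = TRUE)) {
    abort("relax_steady_state requires the deSolve package.")
  }
  p <- validate_kinetic_params(p)
  deriv <- function(t, y, parms) {
    F <- max(y[1L], 0); C <- max(y[2L], 0); A <- max(y[3L], 0)
    vfg <- p$V_fts * F / (p$K_F + F)
    v_pur <- p$V_pur * C / (p$K_C + C)
    if (A > 0) {
      r <- energy_balance_ratio(A, p)
      pools <- .partition(A, r, p$K_AK)
    } else {
      pools <- list(ATP = 0, ADP = 0)
    }
    mu <- switch(p$prolif_mode,
      ATP_MM = p$mu_max * pools$ATP / (p$K_mu + pools$ATP),
      ADP_MM = p$mu_max * pools$ADP / (p$K_mu + pools$ADP),
      CONSTANT = p$mu_max
    )
    list(c(
      v_ser + p$k_tr * (F_ext - F) - vfg + p$k_rev * C,
      vfg + p$q_cyto - p$k_rev * C - p$n_1C * v_pur,
      v_pur - mu * A
    ))
  }
  y0 <- c(F = 0, C = 0, A = 1e-6)
  sol <- deSolve::ode(y0, times = c(0, t_end), func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  fin <- sol[nrow(sol), ]
  tibble::tibble(F = unname(fin["F"]), C = unname(fin["C"]),
                 A_tot = unname(fin["A"]))
}
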