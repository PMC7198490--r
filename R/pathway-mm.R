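#' Detailed multi-step rate models of glycolysis and oxidative phosphorylation
#'
#' Reduced kinetic chain models used to demonstrate that the ADP
#' phosphorylation rate of a multi-reaction pathway collapses onto an
#' effective Michaelis--Menten dependence on ADP when the remaining
#' cofactors (ATP, NAD+, NADH) vary over physiological ranges.
#'
#' The glycolytic chain has five saturable steps: an ATP-consuming upper
#' step (hexokinase/phosphofructokinase lump, Michaelis--Menten in ATP), an
#' NAD+-dependent oxidation step (GAPDH lump), two ADP-phosphorylating
#' steps (phosphoglycerate kinase and pyruvate kinase lumps,
#' Michaelis--Menten in ADP) and an NADH-consuming terminal step (lactate
#' dehydrogenase lump). At steady state the chain carries one common flux;
#' it is composed as the series ("harmonic") limit of the sequential
#' saturable steps, so the slowest step dominates. The net ADP
#' phosphorylation rate is twice the chain flux (four ATP produced minus
#' two consumed per glucose).
#'
#' The oxidative phosphorylation model is a two-stage lump: respiration
#' (Michaelis--Menten in NADH) in series with the ATP synthase step
#' (Michaelis--Menten in ADP, inhibited by the ATP/ADP ratio through the
#' factor `K_i / (K_i + ATP/ADP)`).
#'
#' @param ADP,ATP,NAD_ox,NAD_red Cofactor concentrations (mM, >= 0).
#'   Vectorised.
#' @param pars Named list of step capacities and half-saturations; see
#'   [glycolysis_pathway_params()] / [oxphos_pathway_params()] for the
#'   defaults and names.
#' @return Net ADP phosphorylation rate (mM/h), same length as the inputs.
#' @seealso [sample_cofactors()], [fit_michaelis_menten()]
#' @export
#' @examples
#' glycolysis_rate(ADP = 0.5, ATP = 2, NAD_ox = 0.5, NAD_red = 0.1)
#' oxphos_rate(ADP = 0.5, ATP = 2, NAD_ox = 0.5, NAD_red = 0.1)
glycolysis_rate <- function(ADP, ATP, NAD_ox, NAD_red,
                            pars = glycolysis_pathway_params()) {
  .check_cofactors(ADP, ATP, NAD_ox, NAD_red)
  v1 <- pars$V_upper * ATP / (pars$K_atp + ATP)
  v2 <- pars$V_oxid * NAD_ox / (pars$K_nadox + NAD_ox)
  v3 <- pars$V_pgk * ADP / (pars$K_pgk + ADP)
  v4 <- pars$V_pk * ADP / (pars$K_pk + ADP)
  v5 <- pars$V_term * NAD_red / (pars$K_nadred + NAD_red)
  J <- .series_flux(cbind(v1, v2, v3, v4, v5))
  pmax(2 * J, 0)
}

#' @rdname glycolysis_rate
#' @export
oxphos_rate <- function(ADP, ATP, NAD_ox, NAD_red,
                        pars = oxphos_pathway_params()) {
  .check_cofactors(ADP, ATP, NAD_ox, NAD_red)
  v_resp <- pars$V_resp * NAD_red / (pars$K_nadred + NAD_red)
  ratio <- ifelse(ADP > 0, ATP / ADP, Inf)
  v_syn <- pars$V_syn * ADP / (pars$K_adp + ADP) *
    pars$K_i / (pars$K_i + ratio)
  J <- .series_flux(cbind(v_resp, v_syn))
  pmax(J, 0)
}

# series (harmonic) composition of sequential saturable steps: the common
# steady flux is dominated by the slowest step; zero anywhere blocks the chain
.series_flux <- function(v) {
  J <- 1 / rowSums(1 / v)
  J[apply(v <= 0, 1L, any)] <- 0
  J
}

.check_cofactors <- function(ADP, ATP, NAD_ox, NAD_red) {
  if (any(c(ADP, ATP, NAD_ox, NAD_red) < 0) ||
      any(!is.finite(c(ADP, ATP, NAD_ox, NAD_red)))) {
    abort("cofactor concentrations must be finite and non-negative.",
          class = "formateswitch_domain_error")
  }
}

#' @rdname glycolysis_rate
#' @export
glycolysis_pathway_params <- function() {
  list(V_upper = 14, K_atp = 0.02,
       V_oxid = 10, K_nadox = 0.008,
       V_pgk = 12, K_pgk = 0.3,
       V_pk = 10, K_pk = 0.25,
       V_term = 10, K_nadred = 0.008)
}

#' @rdname glycolysis_rate
#' @export
oxphos_pathway_params <- function() {
  list(V_resp = 10, K_nadred = 0.008,
       V_syn = 12, K_adp = 0.25, K_i = 50)
}

#' Sample random cofactor sets
#'
#' Draws cofactor concentrations log-uniformly within the given ranges, one
#' independent draw per cofactor, emulating the spread of cellular states
#' over which the effective Michaelis--Menten behaviour of the pathway
#' models is probed. Concentrations span decades, hence the log-uniform
#' choice.
#'
#' @param n Number of cofactor sets (>= 1).
#' @param ranges Named list of `c(min, max)` ranges (mM) for `ADP`, `ATP`,
#'   `NAD_ox`, `NAD_red`; defaults are 0.01--5 mM for the adenines and
#'   0.01--1 mM for the NAD pools.
#' @param seed Integer seed; the draw is a pure function of `n`, `ranges`
#'   and `seed`.
#' @return A tibble with columns `ADP`, `ATP`, `NAD_ox`, `NAD_red`.
#' @export
#' @examples
#' sample_cofactors(5, seed = 1)
sample_cofactors <- function(n, ranges = NULL, seed = 1L) {
  if (!is.numeric(n) || n < 1) {
    abort("sample_cofactors: `n` must be >= 1.",
          class = "formateswitch_domain_error")
  }
  defaults <- list(ADP = c(0.01, 5), ATP = c(0.01, 5),
                   NAD_ox = c(0.01, 1), NAD_red = c(0.01, 1))
  ranges <- modifyList(defaults, ranges %||% list())
  for (nm in names(defaults)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2L || any(rg <= 0) || rg[2L] <= rg[1L]) {
      abort(sprintf("sample_cofactors: invalid range for `%s`.", nm),
            class = "formateswitch_domain_error")
    }
  }
  out <- with_seed_local(seed, {
    purrr::map(ranges[names(defaults)], function(rg) {
      exp(runif(n, log(rg[1L]), log(rg[2L])))
    })
  })
  tibble::as_tibble(out)
}

#' Fit the Michaelis--Menten equation to (substrate, rate) points
#'
#' Least squares fit of `v = Vmax * s / (Km + s)` on the rate scale
#' (unweighted, not on linearised coordinates). The fit profiles out
#' `Vmax`, which enters linearly for fixed `Km`, and minimises the
#' one-dimensional profile objective over `log(Km)`; a Hanes linearisation
#' (`s/v` vs `s`) brackets the search window. This makes the fit
#' deterministic, free of starting values and exactly equivariant under
#' rescaling of the rates.
#'
#' @param data A data frame with the substrate and rate columns.
#' @param substrate,rate Column names (strings) in `data`.
#' @return An object of class `mm_fit` with elements `Vmax`, `Km`, `R2`,
#'   `residuals`, `fitted`, `n_points` and the input `data`; supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' pts <- gen_mm_points(Vmax = 2, Km = 0.5, n = 50, noise_frac = 0, seed = 1)
#' fit <- fit_michaelis_menten(pts)
#' glance(fit)
fit_michaelis_menten <- function(data, substrate = "substrate", rate = "rate") {
  s <- data[[substrate]]
  v <- data[[rate]]
  if (is.null(s) || is.null(v)) {
    abort("fit_michaelis_menten: substrate/rate columns not found.",
          class = "formateswitch_domain_error")
  }
  keep <- is.finite(s) & is.finite(v)
  s <- s[keep]; v <- v[keep]
  if (length(s) < 3L) {
    abort("fit_michaelis_menten: need at least 3 points.",
          class = "formateswitch_fit_error")
  }
  if (length(unique(s)) < 2L) {
    abort("fit_michaelis_menten: all substrate values are equal (degenerate design).",
          class = "formateswitch_fit_error")
  }
  if (any(v < 0) || any(s <= 0)) {
    abort("fit_michaelis_menten: substrate must be positive and rates non-negative.",
          class = "formateswitch_domain_error")
  }

  # Hanes linearisation s/v = s/Vmax + Km/Vmax gives the search window centre
  pos <- v > 0
  km_hanes <- NA_real_
  if (sum(pos) >= 2L) {
    h <- stats::lm.fit(cbind(1, s[pos]), s[pos] / v[pos])$coefficients
    if (is.finite(h[1L]) && is.finite(h[2L]) && h[1L] > 0 && h[2L] > 0) {
      km_hanes <- h[1L] / h[2L]
    }
  }
  lo <- log(min(s) * 1e-4)
  hi <- log(max(s) * 1e4)
  if (is.finite(km_hanes)) {
    lo <- min(lo, log(km_hanes) - 2)
    hi <- max(hi, log(km_hanes) + 2)
  }

  sse <- function(logkm) {
    w <- s / (exp(logkm) + s)
    vmax <- sum(w * v) / sum(w * w)
    sum((v - vmax * w)^2)
  }
  opt <- optimize(sse, c(lo, hi), tol = 1e-12)
  # profile gradient (envelope theorem: the Vmax term drops out); positive
  # where SSE increases with Km
  grad <- function(logkm) {
    km <- exp(logkm)
    w <- s / (km + s)
    vmax <- sum(w * v) / sum(w * w)
    2 * vmax * km * sum((v - vmax * w) * s / (km + s)^2)
  }
  # optimize() cannot resolve the minimum below ~sqrt(eps); a sign-based
  # bisection on the profile gradient is deterministic to machine precision
  # and exactly scale-equivariant (the gradient's sign is scale-free)
  km_log <- opt$minimum
  blo <- km_log - 1e-5; bhi <- km_log + 1e-5
  it <- 0L
  while (grad(blo) > 0 && blo > lo && it < 30L) { blo <- blo - 0.1; it <- it + 1L }
  it <- 0L
  while (grad(bhi) < 0 && bhi < hi && it < 30L) { bhi <- bhi + 0.1; it <- it + 1L }
  if (grad(blo) <= 0 && grad(bhi) >= 0) {
    for (i in 1:80) {
      mid <- (blo + bhi) / 2
      if (grad(mid) <= 0) blo <- mid else bhi <- mid
    }
    km_log <- (blo + bhi) / 2
  }
  km <- exp(km_log)
  w <- s / (km + s)
  vmax <- sum(w * v) / sum(w * w)
  fitted <- vmax * w
  resid <- v - fitted
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_

  if (!is.finite(vmax) || vmax <= 0 || !is.finite(km) || km <= 0) {
    abort(sprintf(paste0("fit_michaelis_menten: fit did not converge to a ",
                         "positive (Vmax, Km); Hanes initialization gave ",
                         "Km = %g."), km_hanes),
          class = "formateswitch_fit_error")
  }

  structure(
    list(Vmax = vmax, Km = km, R2 = r2, residuals = resid, fitted = fitted,
         n_points = length(s),
         data = tibble::tibble(substrate = s, rate = v)),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit>  Vmax = %.6g, Km = %.6g mM, R^2 = %.4f (n = %d)\n",
              x$Vmax, x$Km, x$R2, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(term = c("Vmax", "Km"), estimate = c(x$Vmax, x$Km))
}

#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(Vmax = x$Vmax, Km = x$Km, r.squared = x$R2,
                 nobs = x$n_points)
}

#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble::tibble(
    substrate = seq(0, max(object$data$substrate), length.out = 200)
  )
  grid$rate <- object$Vmax * grid$substrate / (object$Km + grid$substrate)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$substrate, .data$rate)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "#b2182b") +
    ggplot2::labs(x = "substrate (mM)", y = "rate",
                  subtitle = sprintf("Vmax = %.3g, Km = %.3g mM, R² = %.3f",
                                     object$Vmax, object$Km, object$R2)) +
    ggplot2::theme_minimal()
}
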