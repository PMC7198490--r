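#' ATP-threshold flux-balance model of orotate and argininosuccinate
#'
#' A minimal flux balance for a metabolite whose production is catalysed by
#' an ATP-dependent synthetase and whose turnover is saturable. Production
#' follows a (possibly cooperative) Hill law in ATP,
#' `v = Vp * ATP^h / (Kp^h + ATP^h)`; carbamoyl-phosphate synthetase (CAD,
#' upstream of orotate) has a half-saturation on the mM ATP range with
#' `h = 1`, while argininosuccinate synthetase shows sigmoidal ATP kinetics
#' with a Hill coefficient of 2. Turnover is Michaelis--Menten in the
#' metabolite, `Vt * O / (Kt + O)`. When the maximal production rate
#' exceeds the turnover capacity (`Vp > Vt`), the steady-state level
#' diverges as ATP approaches the critical value where production equals
#' `Vt` -- the model's explanation for the steep, threshold-like rise of
#' orotate with ATP.
#'
#' @param Vp Maximal production rate (a.u./h).
#' @param Kp ATP half-saturation of the synthetase (mM).
#' @param h Hill coefficient (>= 1); 1 for orotate/CAD, 2 for
#'   argininosuccinate.
#' @param Vt Maximal turnover rate (a.u./h).
#' @param Kt Turnover half-saturation (a.u., same scale as the level).
#' @return A `threshold_params` object (validated named list).
#' @seealso [orotate_steady_state()], [critical_atp()],
#'   [fit_threshold_model()]
#' @export
#' @examples
#' threshold_params(Vp = 2, Kp = 1, Vt = 1, Kt = 1)
threshold_params <- function(Vp = 2, Kp = 6, h = 1, Vt = 1, Kt = 1) {
  p <- list(Vp = Vp, Kp = Kp, h = h, Vt = Vt, Kt = Kt)
  for (f in names(p)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("threshold_params: `%s` must be a single positive number.", f),
            class = "formateswitch_domain_error")
    }
  }
  if (p$h < 1) {
    abort("threshold_params: Hill coefficient `h` must be >= 1.",
          class = "formateswitch_domain_error")
  }
  structure(p, class = "threshold_params")
}

#' Production rate of the ATP-dependent synthetase
#'
#' @param ATP ATP concentration (mM, >= 0). Vectorised.
#' @param p A [threshold_params()] object.
#' @return Production rate `Vp * ATP^h / (Kp^h + ATP^h)` (a.u./h).
#' @export
#' @examples
#' p <- threshold_params(Vp = 2, Kp = 1)
#' production_rate(c(0, 1, 100), p) # 0, Vp/2, ~Vp
production_rate <- function(ATP, p) {
  stopifnot(inherits(p, "threshold_params"))
  if (any(ATP < 0) || any(!is.finite(ATP))) {
    abort("production_rate: `ATP` must be finite and non-negative.",
          class = "formateswitch_domain_error")
  }
  p$Vp * ATP^p$h / (p$Kp^p$h + ATP^p$h)
}

#' Steady-state metabolite level of the threshold model
#'
#' Balances production against saturable turnover:
#' `Vt * O / (Kt + O) = production_rate(ATP)`. The closed-form solution is
#' `O = Kt * v / (Vt - v)` for `v < Vt`; when production reaches or exceeds
#' the turnover capacity no finite steady state exists and `Inf` is
#' returned (the unbounded-accumulation sentinel).
#'
#' @inheritParams production_rate
#' @return Steady-state level (a.u.), `Inf` where unbounded. Vectorised.
#' @export
#' @examples
#' p <- threshold_params(Vp = 2, Kp = 1, Vt = 1, Kt = 3)
#' orotate_steady_state(c(0.5, 0.9), p)
#' orotate_steady_state(2, p) # beyond the critical ATP: Inf
orotate_steady_state <- function(ATP, p) {
  v <- production_rate(ATP, p)
  ifelse(v < p$Vt, p$Kt * v / (p$Vt - v), Inf)
}

#' Critical ATP concentration of the threshold model
#'
#' When `Vp > Vt` the production rate reaches the turnover capacity at
#' `ATP* = Kp * (Vt / (Vp - Vt))^(1/h)`; steady-state levels are finite
#' below `ATP*` and unbounded at or above it. When `Vp <= Vt` production
#' never exceeds turnover and there is no critical point (`NA`).
#'
#' @param p A [threshold_params()] object.
#' @return The critical ATP (mM), or `NA_real_` when none exists.
#' @export
#' @examples
#' critical_atp(threshold_params(Vp = 2, Vt = 1, Kp = 1, h = 1)) # 1
critical_atp <- function(p) {
  stopifnot(inherits(p, "threshold_params"))
  if (p$Vp <= p$Vt) return(NA_real_)
  p$Kp * (p$Vt / (p$Vp - p$Vt))^(1 / p$h)
}

#' Fit the threshold model to a (ATP, level) scatter
#'
#' Least-squares fit of the steady-state level curve to a metabolite vs ATP
#' scatter (the orotate-versus-ATP plot), on the level scale (not on
#' linearised coordinates). The curve `O = Kt * v / (Vt - v)` determines
#' only two parameter combinations -- an amplitude `Kt*Vp/Kp^h` and the
#' critical point `(Vp - Vt)/Kp^h` -- so two of the four constants must be
#' fixed by convention: `Vt = 1` (making `Vp` the production/turnover
#' capacity ratio `Vp/Vt`) and the turnover half-saturation `Kt`
#' (defaulting to 1, the level-scale unit; peak areas carry an arbitrary
#' scale anyway). The Hill coefficient is fixed (not fitted), per the
#' mechanistic assignment of the synthetase.
#'
#' Starting values come from inverting the turnover law: `O/(O + Kt)` is
#' the production rate, which is Michaelis--Menten in `ATP^h` and is fitted
#' with [fit_michaelis_menten()]; Nelder--Mead on the log-parameters then
#' minimises the level-scale least squares, with a fallback grid of starts
#' and restarts from the incumbent. Predicted levels in the unbounded
#' region are capped at `ceiling_mult` times the largest observed level to
#' keep the objective finite.
#'
#' @param data Data frame holding the scatter.
#' @param atp,level Column names (strings) in `data`.
#' @param h Fixed Hill coefficient.
#' @param Kt Fixed turnover half-saturation (level units).
#' @param ceiling_mult Cap for predicted levels near the divergence,
#'   as a multiple of `max(level)`.
#' @return A `threshold_fit` object: the fitted [threshold_params()]
#'   (with `Vt = 1`, `Kt` as fixed), `R2`, `fitted`, `residuals`,
#'   `n_points`, `data`; supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' truth <- threshold_params(Vp = 2, Kp = 6, Vt = 1, Kt = 1)
#' sc <- gen_orotate_scatter(truth, noise_frac = 0, seed = 1)
#' fit <- fit_threshold_model(sc, h = 1)
#' glance(fit)
fit_threshold_model <- function(data, atp = "ATP", level = "level", h = 1,
                                Kt = 1, ceiling_mult = 20) {
  x <- data[[atp]]
  y <- data[[level]]
  if (is.null(x) || is.null(y)) {
    abort("fit_threshold_model: ATP/level columns not found.",
          class = "formateswitch_domain_error")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) {
    abort("fit_threshold_model: need at least 4 points.",
          class = "formateswitch_fit_error")
  }
  if (any(y < 0) || any(x < 0)) {
    abort("fit_threshold_model: ATP and levels must be non-negative.",
          class = "formateswitch_domain_error")
  }
  stopifnot(Kt > 0)
  cap <- ceiling_mult * max(y)

  predict_level <- function(vp, kp) {
    v <- vp * x^h / (kp^h + x^h)
    out <- ifelse(v < 1, Kt * v / (1 - v), Inf)
    pmin(out, cap)
  }
  obj <- function(par) {
    pred <- predict_level(exp(par[1L]), exp(par[2L]))
    sum((y - pred)^2)
  }

  # invert the turnover law: O/(O+Kt) = production, Michaelis-Menten in x^h
  med_x <- stats::median(x[x > 0]) %||% 1
  starts <- expand.grid(vp = c(0.5, 1.2, 2, 5, 20),
                        kp = med_x * c(0.5, 1, 2, 5))
  init <- tryCatch({
    mf <- fit_michaelis_menten(
      tibble::tibble(substrate = x^h, rate = y / (y + Kt))
    )
    data.frame(vp = mf$Vmax, kp = mf$Km^(1 / h))
  }, error = function(e) NULL)
  if (!is.null(init) && all(is.finite(unlist(init)))) {
    starts <- rbind(init, starts)
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- log(as.numeric(starts[i, ]))
    fit <- tryCatch(
      stats::optim(par0, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    abort("fit_threshold_model: optimisation failed from every start.",
          class = "formateswitch_fit_error")
  }
  # polish: restart Nelder-Mead from the incumbent until converged
  for (k in 1:3) {
    ref <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-15))
    if (ref$value < best$value) best <- ref else break
  }

  est <- exp(best$par)
  pred <- predict_level(est[1L], est[2L])
  if (all(!is.finite(pred)) || all(pred >= cap)) {
    abort("fit_threshold_model: fitted model is unbounded over the whole data range.",
          class = "formateswitch_fit_error")
  }
  resid <- y - pred
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_

  structure(
    list(params = threshold_params(Vp = est[1L], Kp = est[2L], h = h,
                                   Vt = 1, Kt = Kt),
         R2 = r2, fitted = pred, residuals = resid, n_points = length(x),
         cap = cap, data = tibble::tibble(ATP = x, level = y)),
    class = "threshold_fit"
  )
}

#' @export
print.threshold_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<threshold_fit>  Vp/Vt = %.4g, Kp = %.4g mM, ",
                     "Kt = %.4g, h = %g, R^2 = %.4f (n = %d)\n"),
              p$Vp, p$Kp, p$Kt, p$h, x$R2, x$n_points))
  if (p$Vp > 1) cat(sprintf("  critical ATP* = %.4g mM\n", critical_atp(p)))
  invisible(x)
}

#' @method tidy threshold_fit
#' @export
tidy.threshold_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(term = c("Vp_over_Vt", "Kp", "Kt"),
                 estimate = c(p$Vp, p$Kp, p$Kt))
}

#' @method glance threshold_fit
#' @export
glance.threshold_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(Vp_over_Vt = p$Vp, Kp = p$Kp, Kt = p$Kt, h = p$h,
                 critical_atp = critical_atp(p), r.squared = x$R2,
                 nobs = x$n_points)
}

#' @method autoplot threshold_fit
#' @export
autoplot.threshold_fit <- function(object, ...) {
  p <- object$params
  xmax <- max(object$data$ATP)
  grid <- tibble::tibble(ATP = seq(0, xmax, length.out = 400))
  grid$level <- pmin(orotate_steady_state(grid$ATP, p), object$cap)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$ATP, .data$level)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#b2182b") +
    ggplot2::labs(x = "ATP (mM)", y = "level (a.u.)",
                  subtitle = sprintf("Vp/Vt = %.3g, Kp = %.3g mM, h = %g",
                                     p$Vp, p$Kp, p$h)) +
    ggplot2::theme_minimal()
}
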