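#' The standard six-condition HAP1 design
#'
#' The genetic/supplementation panel behind the one-carbon availability
#' index: the MFT-SHMT1 double knockout (index 0, no formate source), the
#' MFT and SHMT2 single knockouts (index 1), and the 1 mM
#' formate-supplemented knockouts plus the parental WT line (index 2).
#'
#' @param replicates Replicates per condition (default 3).
#' @return A tibble with columns `condition`, `oc_index`, `formate_mM`,
#'   `replicates`.
#' @export
#' @examples
#' gen_condition_design()
gen_condition_design <- function(replicates = 3L) {
  tibble::tibble(
    condition = c("MFT-SHMT1", "MFT", "SHMT2",
                  "MFT + 1 mM Formate", "SHMT2 + 1 mM Formate", "WT"),
    oc_index = c(0L, 1L, 1L, 2L, 2L, 2L),
    formate_mM = c(0, 0, 0, 1, 1, 0),
    replicates = as.integer(replicates)
  )
}

# multiplicative log-normal noise factors with unit mean and the given CV
.lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sigma^2 / 2, sigma))
}

#' Generate a synthetic label-free proteomics table
#'
#' Emulates the statistical structure of an LFQ protein intensity table
#' over the six-condition design: per-feature log2 baselines drawn from a
#' normal distribution, a responsive subset carrying a linear log2 trend
#' versus the one-carbon availability index, and independent normal
#' replicate noise on the log2 scale. The table is exported on the raw
#' intensity scale (`2^x`).
#'
#' @param n_features Number of features (proteins).
#' @param frac_responsive Fraction of features given the true trend.
#' @param true_slope Trend, log2 units per index step.
#' @param noise_sd Replicate noise SD on the log2 scale.
#' @param design Condition design (see [gen_condition_design()]).
#' @param baseline_mean,baseline_sd Log2 baseline distribution.
#' @param seed Integer seed; output is a pure function of arguments + seed.
#' @return A list with `table` (wide raw-scale tibble, `value_scale`
#'   attribute `"raw"`) and `truth` (per-feature `responsive` flag and
#'   `true_slope`, plus the generator arguments as attributes).
#' @export
#' @examples
#' sim <- gen_proteomics(n_features = 10, frac_responsive = 0.5, seed = 1)
#' sim$table
gen_proteomics <- function(n_features = 1000, frac_responsive = 0.1,
                           true_slope = 1, noise_sd = 0.2,
                           design = gen_condition_design(),
                           baseline_mean = 25, baseline_sd = 2,
                           seed = 1L) {
  if (frac_responsive < 0 || frac_responsive > 1) {
    abort("gen_proteomics: `frac_responsive` must be in [0, 1].",
          class = "formateswitch_domain_error")
  }
  if (noise_sd < 0) {
    abort("gen_proteomics: `noise_sd` must be >= 0.",
          class = "formateswitch_domain_error")
  }
  feats <- sprintf("P%04d", seq_len(n_features))
  n_resp <- round(frac_responsive * n_features)

  out <- with_seed_local(seed, {
    responsive <- rep(FALSE, n_features)
    responsive[sample.int(n_features, n_resp)] <- TRUE
    baseline <- rnorm(n_features, baseline_mean, baseline_sd)
    cols <- list(feature = feats)
    for (i in seq_len(nrow(design))) {
      for (k in seq_len(design$replicates[i])) {
        x <- baseline +
          true_slope * design$oc_index[i] * responsive +
          rnorm(n_features, 0, noise_sd)
        cols[[paste0(design$condition[i], "_R", k)]] <- 2^x
      }
    }
    list(table = tibble::as_tibble(cols), responsive = responsive)
  })

  table <- out$table
  attr(table, "value_scale") <- "raw"
  truth <- tibble::tibble(feature = feats, responsive = out$responsive,
                          true_slope = ifelse(out$responsive, true_slope, 0))
  attr(truth, "seed") <- as.integer(seed)
  attr(truth, "noise_sd") <- noise_sd
  list(table = table, truth = truth)
}

#' Generate a synthetic formate-titration metabolomics table
#'
#' Emulates the formate supplementation titration of the MFT-SHMT1
#' deficient line (no endogenous formate production, `v_ser = 0`): for
#' each supplemented formate concentration of a twofold dilution series
#' (default 1 mM down to 0.00390625 mM, nine levels) the kinetic model is
#' solved at steady state and per-replicate metabolite "peak areas" are
#' emitted with multiplicative log-normal noise:
#' \itemize{
#'   \item `AMP`, `ADP`, `ATP`: the model's adenine nucleotide pools (mM);
#'   \item `orotate`: the ATP-threshold satellite model driven by the
#'     state's ATP;
#'   \item `AICAR`: a phenomenological purine-intermediate proxy
#'     `scale * v_pur * K_I/(K_I + ATP)` that rises with purine synthesis
#'     flux at low ATP and is suppressed at high ATP, reproducing the
#'     rise-then-fall of AICAR across the titration (the core model does
#'     not carry intermediate purine pools mechanistically);
#'   \item `lactate`: proportional to the glycolytic rate `v_gly`.
#' }
#'
#' @param p [kinetic_params()] for the cell model.
#' @param dilution_levels Supplemented formate concentrations (mM),
#'   descending; default the nine twofold dilutions from 1 mM.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal replicate noise (0 = deterministic model output).
#' @param replicates Replicates per level.
#' @param orotate_params [threshold_params()] for the orotate readout.
#' @param aicar_scale,aicar_K AICAR proxy scale (a.u.) and ATP
#'   suppression constant (mM).
#' @param seed Integer seed.
#' @return A list with `table` (wide raw-scale tibble; conditions labelled
#'   `F<mM>`) and `truth` (per-level deterministic model outputs and
#'   steady states).
#' @export
#' @examples
#' sim <- gen_titration_metabolomics(noise_cv = 0, seed = 1)
#' sim$truth[, c("F_ext", "ATP", "AICAR")]
gen_titration_metabolomics <- function(p = kinetic_params(),
                                       dilution_levels = 1 * 2^-(0:8),
                                       noise_cv = 0.1, replicates = 3L,
                                       orotate_params = threshold_params(),
                                       aicar_scale = 50, aicar_K = 0.2,
                                       seed = 1L) {
  if (any(dilution_levels <= 0)) {
    abort("gen_titration_metabolomics: dilution levels must be positive.",
          class = "formateswitch_domain_error")
  }
  p <- validate_kinetic_params(p)
  states <- dplyr::bind_rows(
    purrr::map(dilution_levels, function(fe) steady_state(p, 0, fe))
  )
  det <- tibble::tibble(
    F_ext = dilution_levels,
    AMP = states$AMP, ADP = states$ADP, ATP = states$ATP,
    AICAR = aicar_scale * states$v_pur * aicar_K / (aicar_K + states$ATP),
    orotate = orotate_steady_state(states$ATP, orotate_params),
    lactate = states$v_gly
  )
  metabs <- c("AMP", "ADP", "ATP", "AICAR", "orotate", "lactate")

  cols <- with_seed_local(seed, {
    out <- list(feature = metabs)
    for (i in seq_along(dilution_levels)) {
      cond <- sprintf("F%g", dilution_levels[i])
      base <- as.numeric(det[i, metabs])
      for (k in seq_len(replicates)) {
        out[[paste0(cond, "_R", k)]] <-
          base * .lognormal_noise(length(metabs), noise_cv)
      }
    }
    out
  })
  table <- tibble::as_tibble(cols)
  attr(table, "value_scale") <- "raw"
  truth <- dplyr::bind_cols(det, states[setdiff(names(states), names(det))])
  attr(truth, "seed") <- as.integer(seed)
  attr(truth, "noise_cv") <- noise_cv
  list(table = table, truth = truth)
}

#' Generate (substrate, rate) points from a Michaelis--Menten law
#'
#' Fixture generator for [fit_michaelis_menten()]: log-uniform substrate
#' levels with multiplicative normal noise on the rates.
#'
#' @param Vmax,Km True curve parameters.
#' @param n Number of points.
#' @param noise_frac SD of the multiplicative noise (0 = exact values).
#' @param range Substrate range `c(min, max)` (mM), sampled log-uniformly.
#' @param seed Integer seed.
#' @return A tibble with columns `substrate`, `rate` and the truth in
#'   attributes `Vmax`/`Km`.
#' @export
gen_mm_points <- function(Vmax = 2, Km = 0.5, n = 100, noise_frac = 0.05,
                          range = c(0.01, 5), seed = 1L) {
  stopifnot(n >= 1, range[1L] > 0, range[2L] > range[1L])
  out <- with_seed_local(seed, {
    s <- exp(runif(n, log(range[1L]), log(range[2L])))
    v <- Vmax * s / (Km + s)
    if (noise_frac > 0) v <- pmax(v * (1 + rnorm(n, 0, noise_frac)), 0)
    tibble::tibble(substrate = s, rate = v)
  })
  attr(out, "Vmax") <- Vmax
  attr(out, "Km") <- Km
  out
}

#' Generate a synthetic orotate-versus-ATP scatter
#'
#' Draws levels from the closed-form steady state of the threshold model
#' with multiplicative noise, over an ATP grid restricted below the
#' critical ATP (where the level diverges).
#'
#' @param params [threshold_params()] truth.
#' @param n Number of points (when `atp_grid` is NULL).
#' @param atp_grid Optional explicit ATP grid (must lie below the
#'   critical ATP).
#' @param atp_frac Upper end of the default grid as a fraction of the
#'   critical ATP (or of `3 * Kp` when no critical point exists).
#' @param noise_frac SD of the multiplicative noise.
#' @param seed Integer seed.
#' @return A tibble with columns `ATP`, `level`; truth in attributes.
#' @export
gen_orotate_scatter <- function(params = threshold_params(), n = 40,
                                atp_grid = NULL, atp_frac = 0.9,
                                noise_frac = 0.1, seed = 1L) {
  stopifnot(inherits(params, "threshold_params"))
  crit <- critical_atp(params)
  top <- if (is.na(crit)) 3 * params$Kp else atp_frac * crit
  if (is.null(atp_grid)) {
    atp_grid <- seq(top / n, top, length.out = n)
  }
  if (!is.na(crit) && any(atp_grid >= crit)) {
    abort("gen_orotate_scatter: ATP grid must lie below the critical ATP.",
          class = "formateswitch_domain_error")
  }
  lev <- orotate_steady_state(atp_grid, params)
  out <- with_seed_local(seed, {
    if (noise_frac > 0) {
      lev <- pmax(lev * (1 + rnorm(length(lev), 0, noise_frac)), 0)
    }
    tibble::tibble(ATP = atp_grid, level = lev)
  })
  attr(out, "params") <- params
  out
}
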