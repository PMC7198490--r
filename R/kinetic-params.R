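#' Parameters of the formate--purine--energy kinetic model
#'
#' Bundles every rate constant and capacity of the steady-state model linking
#' mitochondrial formate production, the usable one-carbon (10-formyl-THF
#' equivalent) pool, de novo purine synthesis and the adenine-nucleotide
#' energy system. Units are mM for concentrations and mM/h for rates
#' throughout; proliferation rates are 1/h.
#'
#' The model couples four balances at steady state:
#' \itemize{
#'   \item formate: `v_ser + k_tr*(F_ext - F) = v_fix`, with net fixation
#'     `v_fix = V_fts*F/(K_F + F) - k_rev*C` (10-formyl-THF synthetase is
#'     reversible; the reverse term is the relief valve that returns excess
#'     one-carbon units to formate once purine demand saturates, which is
#'     what makes the overflow threshold a property of the purine synthesis
#'     rate rather than of the fixation capacity),
#'   \item one-carbon pool: `v_fix + q_cyto = n_1C * v_pur`, with
#'     `v_pur = V_pur*C/(K_C + C)`,
#'   \item purine pool growth: `v_pur = mu * A_tot`, with `mu` set by
#'     `prolif_mode`,
#'   \item energy: glycolytic plus oxidative ADP phosphorylation balancing
#'     ATP consumption, with the AMP/ADP/ATP split fixed by the adenylate
#'     kinase equilibrium constant `K_AK`.
#' }
#'
#' @param V_fts Maximal formate fixation rate of 10-formyl-THF synthetase
#'   (mM/h).
#' @param K_F Formate half-saturation of fixation (mM).
#' @param q_cyto Constant cytosolic 10-formyl-THF production rate (mM/h).
#'   The cytosolic scenario of [sweep_production()] sets this to
#'   `0.5 * V_fts`.
#' @param V_pur Maximal purine synthesis rate (mM/h).
#' @param K_C One-carbon pool half-saturation of purine synthesis (mM).
#' @param n_1C One-carbon units consumed per purine (integer, two formyl
#'   transfers: GAR- and AICAR-transformylase).
#' @param k_tr Passive formate membrane transport coefficient (1/h).
#' @param k_rev First-order rate of the reverse (1C pool to formate) flux
#'   (1/h).
#' @param K_AK Adenylate kinase equilibrium constant
#'   `[ADP]^2 / ([ATP][AMP])` (dimensionless).
#' @param V_gly,K_gly Glycolytic ADP phosphorylation capacity (mM/h) and ADP
#'   half-saturation (mM).
#' @param V_ox,K_ox Oxidative phosphorylation capacity (mM/h) and ADP
#'   half-saturation (mM).
#' @param V_use,K_use ATP consumption capacity (mM/h) and ATP
#'   half-saturation (mM).
#' @param mu_max Maximal proliferation rate (1/h).
#' @param K_mu Half-saturation of the proliferation coupling (mM ATP or ADP,
#'   depending on `prolif_mode`).
#' @param prolif_mode Coupling of proliferation to the energy state:
#'   `"ATP_MM"` (Michaelis--Menten in ATP, default), `"ADP_MM"`
#'   (Michaelis--Menten in ADP) or `"CONSTANT"` (`mu = mu_max`).
#'
#' @return An object of class `kinetic_params` (a validated named list).
#' @seealso [steady_state()], [sweep_production()], [overflow_threshold()],
#'   [read_kinetic_params()]
#' @export
#' @examples
#' p <- kinetic_params()
#' p$V_fts
#' kinetic_params(prolif_mode = "CONSTANT")
kinetic_params <- function(V_fts = 0.5, K_F = 0.02, q_cyto = 0,
                           V_pur = 0.15, K_C = 0.05, n_1C = 2L,
                           k_tr = 1, k_rev = 1, K_AK = 1,
                           V_gly = 2, K_gly = 0.25,
                           V_ox = 4, K_ox = 0.25,
                           V_use = 5, K_use = 0.4,
                           mu_max = 0.05, K_mu = 0.002,
                           prolif_mode = c("ATP_MM", "ADP_MM", "CONSTANT")) {
  prolif_mode <- match.arg(prolif_mode)
  p <- list(
    V_fts = V_fts, K_F = K_F, q_cyto = q_cyto,
    V_pur = V_pur, K_C = K_C, n_1C = as.integer(n_1C),
    k_tr = k_tr, k_rev = k_rev, K_AK = K_AK,
    V_gly = V_gly, K_gly = K_gly, V_ox = V_ox, K_ox = K_ox,
    V_use = V_use, K_use = K_use,
    mu_max = mu_max, K_mu = K_mu,
    prolif_mode = prolif_mode
  )
  validate_kinetic_params(structure(p, class = "kinetic_params"))
}

validate_kinetic_params <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  pos <- c("V_fts", "K_F", "V_pur", "K_C", "K_AK",
           "V_gly", "K_gly", "V_ox", "K_ox", "V_use", "K_use",
           "mu_max", "K_mu")
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("kinetic_params: `%s` must be a single positive number.", f),
            class = "formateswitch_domain_error")
    }
  }
  for (f in c("q_cyto", "k_tr", "k_rev")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(sprintf("kinetic_params: `%s` must be a single non-negative number.", f),
            class = "formateswitch_domain_error")
    }
  }
  if (p$n_1C < 1L) {
    abort("kinetic_params: `n_1C` must be an integer >= 1.",
          class = "formateswitch_domain_error")
  }
  if (!p$prolif_mode %in% c("ATP_MM", "ADP_MM", "CONSTANT")) {
    abort("kinetic_params: invalid `prolif_mode`.",
          class = "formateswitch_domain_error")
  }
  p
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>  (mM, mM/h, 1/h)\n")
  num <- x[setdiff(names(x), "prolif_mode")]
  cat(paste0("  ", format(names(num), width = 7), " = ",
             vapply(num, format, character(1))), sep = "\n")
  cat("  prolif_mode =", x$prolif_mode, "\n")
  invisible(x)
}

#' Read or write kinetic model parameters as JSON
#'
#' Parameter files are flat JSON objects whose keys are exactly the
#' [kinetic_params()] field names; missing keys fall back to the defaults so
#' a file may specify only the constants it overrides.
#'
#' @param path File path.
#' @param p A `kinetic_params` object.
#' @return `read_kinetic_params()` returns a `kinetic_params` object;
#'   `write_kinetic_params()` returns `path` invisibly.
#' @export
read_kinetic_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(kinetic_params))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("Unknown kinetic parameter key(s): ",
                 paste(extra, collapse = ", ")),
          class = "formateswitch_domain_error")
  }
  do.call(kinetic_params, raw)
}

#' @rdname read_kinetic_params
#' @export
write_kinetic_params <- function(p, path) {
  p <- validate_kinetic_params(p)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
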