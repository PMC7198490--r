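#' Configuration for the end-to-end pipeline
#'
#' Bundles every knob of [run_pipeline()]: the kinetic parameters (inline
#' or from a JSON file), the production-rate grid and scenarios, sizes of
#' the synthetic datasets, permutation budget, noise levels, tolerances of
#' the invariant checks, and the master seed. All stochastic stages derive
#' their seeds from `seed`, so a configuration determines the run
#' bit-for-bit.
#'
#' @param seed Master seed.
#' @param params A [kinetic_params()] object (ignored when `params_file`
#'   is given).
#' @param params_file,design_file,gmt_file Optional input file paths
#'   (JSON parameters, TSV design, GMT gene sets); must exist at run
#'   start.
#' @param grid Production-rate grid for the sweeps (mM/h).
#' @param scenarios Sweep scenarios to run.
#' @param n_cofactors Cofactor sample size for the effective-MM stage.
#' @param n_features,frac_responsive,true_slope,noise_sd Proteomics
#'   generator settings.
#' @param n_perm Permutation budget for associations and enrichment.
#' @param titration_cv Noise CV of the titration stage.
#' @param orotate_noise Noise of the orotate scatter stage.
#' @param tol_ak,tol_balance,tol_mono Invariant-check tolerances
#'   (adenylate kinase residual, mass balances, monotonicity slack).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(seed = 1L,
                            params = kinetic_params(),
                            params_file = NULL, design_file = NULL,
                            gmt_file = NULL,
                            grid = seq(0, 0.6, length.out = 50),
                            scenarios = c("baseline_0.02mM", "formate_1mM",
                                          "cytosolic"),
                            n_cofactors = 500,
                            n_features = 300, frac_responsive = 0.1,
                            true_slope = 1, noise_sd = 0.2,
                            n_perm = 1000,
                            titration_cv = 0.1, orotate_noise = 0.1,
                            tol_ak = 1e-8, tol_balance = 1e-6,
                            tol_mono = 1e-9) {
  cfg <- list(seed = as.integer(seed), params = params,
              params_file = params_file, design_file = design_file,
              gmt_file = gmt_file, grid = grid, scenarios = scenarios,
              n_cofactors = n_cofactors, n_features = n_features,
              frac_responsive = frac_responsive, true_slope = true_slope,
              noise_sd = noise_sd, n_perm = n_perm,
              titration_cv = titration_cv, orotate_noise = orotate_noise,
              tol_ak = tol_ak, tol_balance = tol_balance,
              tol_mono = tol_mono)
  structure(cfg, class = "pipeline_config")
}

.check_sweep_invariants <- function(sw, p, cfg) {
  ak <- with(sw, abs(ADP^2 - p$K_AK * ATP * AMP) / pmax(ADP^2, 1e-300))
  bal <- c(
    with(sw, abs(v_ser - v_tr - v_fix) / pmax(v_ser, 1e-12)),
    with(sw, abs(v_fix + q_cyto - p$n_1C * v_pur) / pmax(abs(v_fix), 1e-12)),
    with(sw, abs(v_gly + v_ox - v_use) / pmax(v_use, 1e-12)),
    with(sw, abs(v_pur - mu * A_tot) / pmax(v_pur, 1e-12))
  )
  mono <- vapply(c("F", "C", "A_tot", "ATP", "ADP", "AMP", "v_pur",
                   "v_gly", "mu"),
                 function(q) min(diff(sw[[q]])), numeric(1))
  list(ak_max = max(ak, na.rm = TRUE), balance_max = max(bal, na.rm = TRUE),
       mono_min = min(mono))
}

#' Run the end-to-end desk-scale analysis
#'
#' Executes, in order: the production-rate sweeps under the standard
#' scenarios; cofactor sampling and effective Michaelis--Menten fits for
#' the glycolysis and oxidative phosphorylation chain models; the
#' formate-titration synthetic experiment with re-detection of the
#' metabolic switch (ATP fold change and the lactate-proxy jump); orotate
#' scatter generation and threshold-model fit recovery; synthetic
#' proteomics generation, index association and gene-set enrichment. Every
#' stage writes TSV/JSON outputs into `out_dir`, and a machine-readable
#' manifest of all invariant checks (plus the configuration hash and seed)
#' is written to `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly (a list; `checks` is a named list of
#'   logicals, `measures` the underlying numbers).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("params_file", "design_file", "gmt_file")) {
    pf <- config[[f]]
    if (!is.null(pf) && !file.exists(pf)) {
      abort(sprintf("run_pipeline: configured %s does not exist: %s", f, pf),
            class = "formateswitch_config_error")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- if (!is.null(config$params_file)) {
    read_kinetic_params(config$params_file)
  } else {
    validate_kinetic_params(config$params)
  }
  design <- if (!is.null(config$design_file)) {
    read_condition_design(config$design_file)
  } else {
    gen_condition_design()
  }
  seed <- config$seed
  write_kinetic_params(p, file.path(out_dir, "kinetic_params.json"))
  measures <- list()
  checks <- list()

  # -- stage 1: sweeps ------------------------------------------------------
  sweeps <- lapply(config$scenarios, function(sc) {
    sw <- sweep_production(p, config$grid, sc)
    write_sweep_tsv(sw, file.path(out_dir, paste0("sweep_", sc, ".tsv")))
    sw
  })
  names(sweeps) <- config$scenarios
  inv <- lapply(sweeps, .check_sweep_invariants, p = p, cfg = config)
  measures$ak_residual_max <- max(vapply(inv, `[[`, numeric(1), "ak_max"))
  measures$balance_residual_max <-
    max(vapply(inv, `[[`, numeric(1), "balance_max"))
  measures$monotonicity_min_step <-
    min(vapply(inv, `[[`, numeric(1), "mono_min"))
  checks$adenylate_kinase_equilibrium <-
    measures$ak_residual_max <= config$tol_ak
  checks$mass_balances <- measures$balance_residual_max <= config$tol_balance
  checks$monotone_in_production <-
    measures$monotonicity_min_step >= -config$tol_mono

  if (all(c("baseline_0.02mM", "formate_1mM") %in% config$scenarios)) {
    b <- sweeps$baseline_0.02mM; fm <- sweeps$formate_1mM
    measures$left_shift_min_gap <- min(fm$ATP - b$ATP, fm$ADP - b$ADP,
                                       fm$AMP - b$AMP, fm$v_gly - b$v_gly)
    checks$exogenous_formate_left_shift <-
      measures$left_shift_min_gap >= -config$tol_mono
  }

  # -- stage 2: overflow threshold -----------------------------------------
  th <- overflow_threshold(p, F_ext = 0.02, eps = 0.05)
  measures$threshold_v_ser <- th$v_ser_star
  measures$threshold_analytic_bound <- th$analytic_bound
  checks$threshold_found <- isTRUE(th$found)
  checks$threshold_below_demand_bound <-
    isTRUE(th$found) && th$v_ser_star <= th$analytic_bound
  pq <- p; pq$q_cyto <- 0.5 * p$V_fts
  thq <- overflow_threshold(pq, F_ext = 0.02, eps = 0.05)
  checks$cytosolic_flux_lowers_threshold <-
    isTRUE(thq$found) && thq$v_ser_star < th$v_ser_star

  # -- stage 3: effective Michaelis-Menten ---------------------------------
  cf <- sample_cofactors(config$n_cofactors, seed = seed + 1L)
  for (pw in c("glycolysis", "oxphos")) {
    rate <- if (pw == "glycolysis") {
      glycolysis_rate(cf$ADP, cf$ATP, cf$NAD_ox, cf$NAD_red)
    } else {
      oxphos_rate(cf$ADP, cf$ATP, cf$NAD_ox, cf$NAD_red)
    }
    pts <- tibble::tibble(substrate = cf$ADP, rate = rate)
    readr::write_tsv(pts, file.path(out_dir, paste0("mm_points_", pw, ".tsv")),
                     progress = FALSE)
    fit <- fit_michaelis_menten(pts)
    jsonlite::write_json(glance(fit),
                         file.path(out_dir, paste0("mm_fit_", pw, ".json")),
                         auto_unbox = TRUE, digits = NA)
    measures[[paste0("mm_r2_", pw)]] <- fit$R2
    checks[[paste0("effective_mm_", pw)]] <- fit$R2 >= 0.9
  }
  exact <- gen_mm_points(Vmax = 2, Km = 0.5, n = 60, noise_frac = 0,
                         seed = seed + 2L)
  fe <- fit_michaelis_menten(exact)
  measures$mm_recovery_rel_err <- max(abs(fe$Vmax - 2) / 2,
                                      abs(fe$Km - 0.5) / 0.5)
  checks$mm_noiseless_recovery <- measures$mm_recovery_rel_err <= 1e-8

  # -- stage 4: titration ---------------------------------------------------
  tit <- gen_titration_metabolomics(p, noise_cv = config$titration_cv,
                                    seed = seed + 3L)
  write_omics_table(tit$table, file.path(out_dir, "titration.tsv"))
  det <- gen_titration_metabolomics(p, noise_cv = 0, seed = seed + 3L)$truth
  det <- det[order(det$F_ext), ]
  measures$titration_atp_fold_change <- max(det$ATP) / min(det$ATP)
  checks$titration_atp_switch <- measures$titration_atp_fold_change >= 2
  pk <- which.max(det$AICAR)
  checks$titration_aicar_nonmonotone <- pk > 1 && pk < nrow(det)
  measures$titration_lactate_fold_change <- max(det$lactate) / min(det$lactate)
  checks$titration_lactate_rises <- measures$titration_lactate_fold_change > 1.2

  # -- stage 5: orotate threshold model ------------------------------------
  truth_op <- threshold_params()
  sc_noisy <- gen_orotate_scatter(truth_op, noise_frac = config$orotate_noise,
                                  seed = seed + 4L)
  readr::write_tsv(sc_noisy, file.path(out_dir, "orotate_scatter.tsv"),
                   progress = FALSE)
  sc_exact <- gen_orotate_scatter(truth_op, noise_frac = 0, seed = seed + 4L)
  f0 <- fit_threshold_model(sc_exact, h = truth_op$h)
  fn <- fit_threshold_model(sc_noisy, h = truth_op$h)
  jsonlite::write_json(glance(fn), file.path(out_dir, "orotate_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  measures$orotate_recovery_rel_err <- max(
    abs(f0$params$Vp / truth_op$Vp * truth_op$Vt - 1),
    abs(f0$params$Kp - truth_op$Kp) / truth_op$Kp
  )
  checks$orotate_noiseless_recovery <- measures$orotate_recovery_rel_err <= 1e-4

  # -- stage 6: proteomics association + enrichment ------------------------
  sim <- gen_proteomics(n_features = config$n_features,
                        frac_responsive = config$frac_responsive,
                        true_slope = config$true_slope,
                        noise_sd = config$noise_sd,
                        design = design, seed = seed + 5L)
  write_omics_table(sim$table, file.path(out_dir, "proteomics.tsv"))
  readr::write_tsv(sim$truth, file.path(out_dir, "proteomics_truth.tsv"),
                   progress = FALSE)
  assoc <- oc_associations(sim$table, design, stat = "slope",
                           n_perm = config$n_perm, seed = seed + 6L)
  readr::write_tsv(assoc, file.path(out_dir, "associations.tsv"),
                   progress = FALSE)
  resp <- sim$truth$responsive
  if (any(resp)) {
    measures$association_power <- mean(assoc$p_value[resp] < 0.05)
    checks$responsive_features_detected <- measures$association_power >= 0.8
  }
  if (any(!resp)) {
    measures$association_null_fpr <- mean(assoc$p_value[!resp] < 0.05)
    checks$null_features_controlled <- measures$association_null_fpr <= 0.15
  }

  sets <- if (!is.null(config$gmt_file)) {
    read_gmt(config$gmt_file)
  } else {
    list(responsive = sim$truth$feature[resp],
         random = with_seed_local(seed + 7L, {
           sample(sim$truth$feature, min(20L, config$n_features))
         }))
  }
  enr <- gene_set_enrichment(assoc, sets, n_perm = config$n_perm,
                             seed = seed + 8L)
  readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"),
                   progress = FALSE)
  if ("responsive" %in% enr$set && any(resp)) {
    row <- enr[enr$set == "responsive", ]
    checks$responsive_set_enriched <- row$es > 0 && row$p_value <= 0.05
  }

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = seed,
    checks = checks,
    measures = measures,
    all_checks_pass = all(unlist(checks))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
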