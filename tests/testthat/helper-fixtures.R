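# shared fixtures: the default model, a coarse production grid, and the
# sweep residual checker used by several files
default_params <- kinetic_params()
coarse_grid <- seq(0, 0.6, length.out = 20)

sweep_residuals <- function(sw, p) {
  list(
    ak = with(sw, abs(ADP^2 - p$K_AK * ATP * AMP) / pmax(ADP^2, 1e-300)),
    formate = with(sw, abs(v_ser - v_tr - v_fix) / pmax(v_ser, 1e-12)),
    one_carbon = with(sw, abs(v_fix + q_cyto - p$n_1C * v_pur) /
                        pmax(abs(v_fix), 1e-12)),
    energy = with(sw, abs(v_gly + v_ox - v_use) / pmax(v_use, 1e-12)),
    purine = with(sw, abs(v_pur - mu * A_tot) / pmax(v_pur, 1e-12))
  )
}
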