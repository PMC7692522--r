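# Calibrated synthetic ensemble shared by the slower evaluation tests:
# 50 single-peak institutions (17/17/16 across the volume groups), T = 25
# weeks, Poisson-noised counts, swept over five filling rates with all
# three deployable strategies. Built once per test run and cached.

acceptance_f_grid <- c(0.4, 0.55, 0.7, 0.85, 1.0)

calibrated_config <- function() {
  synthetic_config(n_institutions = 50, T = 25,
                   group_mix = c(A = 17, B = 17, C = 16),
                   noise = "poisson", seed = 101L)
}

calibrated_sweep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ens <- generate_ensemble(calibrated_config())
      cache <<- sweep_filling_rates(ens, strategies = c("M", "S1", "S2"),
                                    f_grid = acceptance_f_grid)
    }
    cache
  }
})
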