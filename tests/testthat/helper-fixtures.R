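# shared fixtures: computed once per test run

# canonical phase functions
pf_iso <- pf_tthg(alpha = 1, g_f = 0, g_b = 0)
pf_hg8 <- pf_tthg(alpha = 1, g_f = 0.8, g_b = 0)

# small filtered grid, reused by several files (moments + p_sb for ~600
# candidates take about a second)
cached_grid <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- pf_grid()
    g
  }
})

# a moderate SFR transport run shared between the SIA and diffusion tests
cached_sfr_run <- local({
  res <- NULL
  function() {
    if (is.null(res)) {
      cfg <- mc_config(pf_tthg(0.9, 0.85, -0.1),
                       sfr_geometry("SFR", 0.22, 1.0),
                       mu_s_prime = 5, batch_size = 2e5,
                       min_detected = 8000, seed = 424,
                       max_path_mm = 150, max_depth_mm = 30)
      res <<- mc_simulate(cfg)
    }
    res
  }
})
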