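skin <- tissue_model("skin")
geom05 <- sfr_geometry("iSFR", 0.05, 0.5)
wl26 <- seq(400, 900, by = 20)

test_that("retrieval objective is the relative least-squares sum", {
  spec <- synthesize_spectrum(skin, geom05, engine = "model",
                              wavelengths = wl26)
  th <- c(skin$a, skin$b, skin$v_f_blood, skin$sO2, skin$p1, skin$p2,
          skin$p3)
  expect_equal(retrieval_objective(th, spec, geom05), 0,
               tolerance = 1e-18)
  # uniform 10% offset: n * (0.1 / 1.1)^2
  off <- spec
  off$R <- 1.1 * off$R
  expect_equal(retrieval_objective(th, off, geom05),
               length(wl26) * (0.1 / 1.1)^2, tolerance = 1e-10)
  # invariant under joint rescaling of model and observation is implied by
  # the relative residual; a negative observation is rejected
  bad <- spec
  bad$R[3] <- -1
  expect_error(retrieval_objective(th, bad, geom05), "positive")
})

test_that("inverse crime recovers every parameter to solver precision", {
  spec <- synthesize_spectrum(skin, geom05, engine = "model",
                              wavelengths = wl26)
  ret <- retrieve_properties(spec, geom05, n_starts = 25, seed = 5)
  m <- retrieval_metrics(ret, skin, wl26)
  for (p in c("a", "b", "v_f_blood", "sO2"))
    expect_lt(m[[p]], 1e-4)
  expect_lt(m$psb_rmse, 1e-3)
  expect_lt(ret$objective, 1e-12)
})

test_that("best-of-n objective is nonincreasing in the number of starts", {
  spec <- synthesize_spectrum(skin, geom05, engine = "model",
                              wavelengths = wl26)
  noisy <- add_noise(spec, 0.02, seed = 8)
  noisy$R <- pmax(noisy$R, 1e-12)
  objs <- vapply(c(4, 12), function(ns)
    retrieve_properties(noisy, geom05, n_starts = ns,
                        seed = 5)$objective, numeric(1))
  expect_lte(objs[2], objs[1] + 1e-12)
})

test_that("retrieval metrics report relative errors and the p_sb curve
           summary", {
  est <- tissue_model(a = 5.06, b = 1.26, v_f_blood = 0.011, sO2 = 0.63,
                      p1 = skin$p1, p2 = skin$p2, p3 = skin$p3)
  m <- retrieval_metrics(est, skin)
  expect_equal(m$a, abs(5.06 - 4.6) / 4.6, tolerance = 1e-12)
  expect_equal(m$b, 0.1, tolerance = 1e-9)
  expect_equal(m$sO2, 0.1, tolerance = 1e-9)
  expect_equal(m$psb_rmse, 0, tolerance = 1e-12)
  m0 <- retrieval_metrics(skin, skin)
  expect_true(all(unlist(m0[c("a", "b", "v_f_blood", "sO2",
                              "psb_rmse")]) == 0))
})

test_that("replicated retrieval aggregates medians and quartiles per
           noise level", {
  spec <- synthesize_spectrum(skin, geom05, engine = "model",
                              wavelengths = wl26)
  tab <- replicate_retrieval(spec, skin, geom05,
                             noise_rms = c(0.005, 0.03),
                             n_replicates = 4, n_starts = 6, seed = 3)
  expect_identical(nrow(tab), 10L)  # 2 levels x 5 summaries
  expect_setequal(unique(tab$param),
                  c("a", "b", "v_f_blood", "sO2", "psb_rmse"))
  expect_true(all(tab$q25 <= tab$median_rel_error + 1e-12))
  expect_true(all(tab$q75 >= tab$median_rel_error - 1e-12))
  # errors widen with noise for the model-consistent spectra (noise is the
  # only perturbation here, so the ordering is clean in aggregate)
  lo <- tab[tab$noise_rms == 0.005, "median_rel_error"]
  hi <- tab[tab$noise_rms == 0.03, "median_rel_error"]
  expect_gt(sum(hi), sum(lo))
})

test_that("retrieval bounds and seeds are enforced", {
  spec <- synthesize_spectrum(skin, geom05, engine = "model",
                              wavelengths = wl26)
  expect_error(retrieve_properties(spec, geom05, n_starts = 2), "seed")
  b <- retrieval_bounds()
  expect_setequal(b$param, c("a", "b", "v_f_blood", "sO2", "p1", "p2",
                             "p3"))
  ret <- retrieve_properties(spec, geom05, n_starts = 4, seed = 2,
                             bounds = b)
  expect_true(all(ret$theta >= b$lower - 1e-9 &
                  ret$theta <= b$upper + 1e-9))
})
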