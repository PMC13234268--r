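test_that("chromophore table covers the working range with the expected
           spectral landmarks", {
  tab <- chromophore_table()
  expect_true(all(c("wavelength_nm", "mu_a_HbO2_mm", "mu_a_Hb_mm") %in%
                  names(tab)))
  expect_lte(min(tab$wavelength_nm), 400)
  expect_gte(max(tab$wavelength_nm), 900)
  expect_true(all(tab$mu_a_HbO2_mm > 0 & tab$mu_a_Hb_mm > 0))
  at <- function(l, col) tab[[col]][tab$wavelength_nm == l]
  # oxygenated blood absorbs less than deoxygenated in the red
  expect_lt(at(650, "mu_a_HbO2_mm"), at(650, "mu_a_Hb_mm") / 5)
  # and more in the near infrared beyond the isosbestic crossover
  expect_gt(at(900, "mu_a_HbO2_mm"), at(900, "mu_a_Hb_mm"))
  # Soret band dominates everything else
  expect_gt(max(tab$mu_a_HbO2_mm), 100)
})

test_that("tissue parameterizations evaluate their closed forms", {
  skin <- tissue_model("skin")
  expect_equal(mus_prime_at(650, skin), 4.6)
  expect_equal(mus_prime_at(900, skin), 4.6 * (900 / 650)^-1.4,
               tolerance = 1e-12)
  expect_equal(mus_prime_at(900, skin), 2.92, tolerance = 1e-2)
  lam <- seq(400, 900, 50)
  expect_true(all(diff(mus_prime_at(lam, skin)) < 0))
  # absorption mixing: zero blood, pure oxy limit, linear in volume
  none <- tissue_model(a = 1, b = 1, v_f_blood = 0, sO2 = 0.5)
  expect_equal(mua_at(lam, none), rep(0, length(lam)))
  oxy <- tissue_model(a = 1, b = 1, v_f_blood = 0.02, sO2 = 1)
  tab <- chromophore_table()
  expect_equal(mua_at(tab$wavelength_nm, oxy), 0.02 * tab$mu_a_HbO2_mm,
               tolerance = 1e-12)
  half <- tissue_model(a = 1, b = 1, v_f_blood = 0.01, sO2 = 1)
  expect_equal(mua_at(lam, oxy), 2 * mua_at(lam, half), tolerance = 1e-12)
  expect_error(mua_at(300, skin), "coverage")
  # p_sb cubic
  simple <- tissue_model(a = 1, b = 1, v_f_blood = 0, sO2 = 0.5,
                         p1 = 1, p2 = 0, p3 = 0)
  expect_equal(psb_at(1300, simple), 2e-5)
  expect_equal(psb_at(650, skin),
               1e-5 * (skin$p1 + skin$p2 + skin$p3), tolerance = 1e-12)
  expect_warning(psb_at(650, tissue_model(a = 1, b = 1, v_f_blood = 0,
                                          sO2 = 0.5, p1 = -1, p2 = 0,
                                          p3 = 0)),
                 "non-positive")
})

test_that("preset p_sb coefficients track the reference phase function", {
  skin <- tissue_model("skin")
  lam <- seq(400, 900, 50)
  target <- vapply(reference_phase_function(lam), pf_psb, numeric(1))
  expect_equal(psb_at(lam, skin), target, tolerance = 0.03)
  # reference realization: anisotropy decreases linearly with wavelength
  g400 <- pf_moments(reference_phase_function(400))$g1
  g900 <- pf_moments(reference_phase_function(900))$g1
  expect_equal(g400, 0.8 * 0.8 + 0.2 * (-0.05), tolerance = 1e-8)
  expect_equal(g900, 0.8 * 0.7 + 0.2 * (-0.05), tolerance = 1e-8)
})

test_that("spectrum synthesis produces the default grid and is
           reproducible", {
  skin <- tissue_model("skin")
  geom <- sfr_geometry("iSFR", 0.05, 0.5)
  spec <- synthesize_spectrum(skin, geom, engine = "model")
  expect_identical(nrow(spec), 101L)
  expect_identical(spec$wavelength_nm, seq(400, 900, by = 5))
  expect_true(all(spec$R > 0))
  # mc engine at a few wavelengths: deterministic under a fixed seed
  wl <- c(500, 650, 800)
  ctrl <- list(estimator = "peeloff", batch_size = 2e4, max_batches = 6L,
               target_rel_se = 0.05, stop_d_f = 0.5, max_path_mm = 50,
               max_depth_mm = 20, rho_max = 0.5)
  s1 <- synthesize_spectrum(skin, geom, engine = "mc", wavelengths = wl,
                            seed = 12, mc_control = ctrl)
  s2 <- synthesize_spectrum(skin, geom, engine = "mc", wavelengths = wl,
                            seed = 12, mc_control = ctrl)
  expect_identical(s1$R, s2$R)
  expect_error(synthesize_spectrum(skin, geom, engine = "mc",
                                   wavelengths = wl),
               "seed")
})

test_that("noise injection is scaled to the spectrum RMS and seeded", {
  skin <- tissue_model("skin")
  geom <- sfr_geometry("iSFR", 0.05, 0.5)
  spec <- synthesize_spectrum(skin, geom, engine = "model")
  expect_identical(add_noise(spec, 0), spec)
  n1 <- add_noise(spec, 0.02, seed = 4)
  n2 <- add_noise(spec, 0.02, seed = 4)
  expect_identical(n1$R, n2$R)
  # realized noise standard deviation matches the requested fraction
  rms <- sqrt(mean(spec$R^2))
  draws <- vapply(1:400, function(i)
    sd(add_noise(spec, 0.01, seed = i)$R - spec$R), numeric(1))
  expect_equal(mean(draws) / rms, 0.01, tolerance = 0.02)
  # scale equivariance: scaling R scales the injected noise
  spec2 <- spec
  spec2$R <- spec2$R * 7
  n3 <- add_noise(spec2, 0.02, seed = 4)
  expect_equal(n3$R - spec2$R, 7 * (n1$R - spec$R), tolerance = 1e-12)
  expect_error(add_noise(spec, 0.01), "seed")
})
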