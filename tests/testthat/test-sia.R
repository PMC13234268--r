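test_that("absorption weights follow the Beer-Lambert law", {
  expect_equal(absorption_weights(c(1, 5, 10), 0), rep(1, 3))
  expect_equal(absorption_weights(10, 0.1), exp(-1), tolerance = 1e-12)
  w1 <- absorption_weights(c(0.5, 2, 7), 0.05)
  w2 <- absorption_weights(c(0.5, 2, 7), 0.5)
  expect_true(all(w1 >= w2))
  expect_error(absorption_weights(1, -0.1), "mu_a")
})

test_that("disk-overlap weight matches the distance density identity", {
  d <- 1.3
  rho <- seq(0, d, length.out = 50)
  w <- overlap_weight(rho, d)
  expect_equal(w[1], 1)
  expect_equal(w[length(w)], 0)
  expect_true(all(diff(w) < 0))
  # w = (pi d^2 / 4) p(rho, d) / (2 pi rho)
  mid <- rho[2:49]
  expect_equal(w[2:49],
               pi * d^2 / 4 * disk_distance_pdf(mid, d) / (2 * pi * mid),
               tolerance = 1e-12)
  # rho -> 0 limit of the identity: p/(2 pi rho) -> 4/(pi d^2)
  expect_equal(disk_distance_pdf(1e-9, d) / (2 * pi * 1e-9) ,
               4 / (pi * d^2), tolerance = 1e-6)
})

test_that("single-integral reflectance agrees with the direct-geometry
           oracle and is monotone in absorption", {
  pf <- pf_tthg(0.9, 0.85, -0.1)
  geom <- sfr_geometry("SFR", 0.22, 1.0)
  point <- cached_sfr_run()
  direct <- mc_simulate(mc_config(pf, geom, mu_s_prime = 5,
                                  batch_size = 2e5, min_detected = 8000,
                                  seed = 13, max_path_mm = 150,
                                  max_depth_mm = 30, source_diam = 1.0))
  for (mua in c(0.01, 1)) {
    sia <- geometry_reflectance(point, 1.0, mua)
    wd <- absorption_weights(direct$records$path_mm, mua)
    rd <- sum(wd) / direct$n_launched
    sed <- sqrt(sum(wd^2) / direct$n_launched - rd^2) /
      sqrt(direct$n_launched)
    expect_lt(abs(sia$R_tot - rd),
              3 * sqrt((sia$R_tot * sia$rel_se)^2 + sed^2))
  }
  r <- vapply(c(0, 0.1, 1, 5), function(m)
    geometry_reflectance(point, 1.0, m)$R_tot, numeric(1))
  expect_true(all(diff(r) < 0))
  # per-photon weights are bounded: reflectance below the record fraction
  expect_lt(geometry_reflectance(point, 1.0, 0)$R_tot,
            nrow(point$records) / point$n_launched)
  expect_error(geometry_reflectance(point, 2.0, 0.1), "rho_max")
})

test_that("peel-off estimator matches the analog estimator", {
  pf <- pf_tthg(0.8, 0.75, -0.05)
  geom <- sfr_geometry("iSFR", 0.1, 0.5)
  analog <- mc_simulate(mc_config(pf, geom, mu_s_prime = 4.6,
                                  rho_max = 0.5, batch_size = 5e5,
                                  min_detected = 6000, seed = 31,
                                  max_path_mm = 100, max_depth_mm = 30))
  peel <- mc_simulate(mc_config(pf, geom, mu_s_prime = 4.6,
                                rho_max = 0.5, batch_size = 5e4,
                                target_rel_se = 0.01, stop_d_f = 0.5,
                                stop_mu_a = 0.1, seed = 77,
                                max_path_mm = 100, max_depth_mm = 30,
                                estimator = "peeloff",
                                max_batches = 50L))
  for (mua in c(0.01, 0.5, 2)) {
    a <- geometry_reflectance(analog, 0.5, mua)
    p <- geometry_reflectance(peel, 0.5, mua)
    expect_lt(abs(a$R_tot - p$R_tot),
              3.5 * sqrt((a$R_tot * a$rel_se)^2 + (p$R_tot * p$rel_se)^2))
  }
})

test_that("doubling the photon budget halves the squared standard error", {
  pf <- pf_hg8
  geom <- sfr_geometry("SFR", 0.22, 1.0)
  res1 <- mc_simulate(mc_config(pf, geom, mu_s_prime = 2.5,
                                batch_size = 5e4, max_batches = 1L,
                                min_detected = 1, seed = 61,
                                max_path_mm = 100, max_depth_mm = 30))
  res2 <- mc_simulate(mc_config(pf, geom, mu_s_prime = 2.5,
                                batch_size = 1e5, max_batches = 1L,
                                min_detected = 1, seed = 61,
                                max_path_mm = 100, max_depth_mm = 30))
  se1 <- geometry_reflectance(res1, 1.0, 0.1)$rel_se
  se2 <- geometry_reflectance(res2, 1.0, 0.1)$rel_se
  expect_equal(se1^2 / se2^2, 2, tolerance = 0.5)
})

test_that("dataset sweep expands the Cartesian grid with provenance", {
  res <- cached_sfr_run()
  ds <- dataset_sweep(list(res), d_f = c(0.5, 1.0), mu_a = c(0, 0.1, 1))
  expect_identical(nrow(ds), 6L)
  expect_setequal(names(ds),
                  c("modality", "na", "d_f_mm", "mu_a_mm",
                    "mu_s_prime_mm", "pf_id", "p_sb", "g1", "g2",
                    "R_MC", "rel_se"))
  expect_true(all(ds$R_MC > 0))
  # rows ordered by the (d_f, mu_a) grid with constant provenance
  expect_identical(unique(ds$pf_id), res$config$pf$id)
  expect_equal(unique(ds$mu_s_prime_mm), 5)
})

test_that("study sweep cardinalities match the published totals", {
  gi <- study_grids("iSFR")
  gs <- study_grids("SFR")
  ni <- sweep_cardinality(length(gi$na), length(gi$d_f_mm),
                          length(gi$mu_s_prime_mm), length(gi$mu_a_mm),
                          gi$n_pf)
  ns <- sweep_cardinality(length(gs$na), length(gs$d_f_mm),
                          length(gs$mu_s_prime_mm), length(gs$mu_a_mm),
                          gs$n_pf)
  expect_identical(ni, 5 * 11 * 8 * 13 * 207)
  expect_identical(ns, 4 * 10 * 8 * 13 * 207)
  expect_equal(ni / 1.1e6, 1, tolerance = 0.1)
  expect_equal(ns / 0.9e6, 1, tolerance = 0.1)
})
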