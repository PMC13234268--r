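test_that("Fresnel transmission matches closed forms", {
  # normal incidence tissue -> air
  expect_equal(fresnel_transmission(1, 1.35, 1.00),
               1 - ((1.35 - 1) / (1.35 + 1))^2, tolerance = 1e-12)
  expect_equal(fresnel_transmission(1, 1.35, 1.00), 0.97782,
               tolerance = 1e-4)
  # matched media transmit at every angle
  expect_equal(fresnel_transmission(c(0.01, 0.3, 1), 1.35, 1.35),
               rep(1, 3))
  # total internal reflection beyond the critical angle
  mu_crit <- sqrt(1 - (1 / 1.35)^2)
  expect_equal(fresnel_transmission(mu_crit * 0.99, 1.35, 1.00), 0)
  expect_gt(fresnel_transmission(mu_crit * 1.01, 1.35, 1.00), 0)
  expect_error(fresnel_transmission(1.2, 1.35, 1), "cos_i")
})

test_that("transport conserves photons and honors the seed contract", {
  pf <- pf_hg8
  geom <- sfr_geometry("iSFR", 0.22, 1.0)
  cfg <- mc_config(pf, geom, mu_s_prime = 1, rho_max = 2.5,
                   batch_size = 2e4, max_batches = 2L, min_detected = 1,
                   seed = 99, max_path_mm = 3e5, max_depth_mm = 500)
  res <- mc_simulate(cfg)
  # every photon either escaped the surface or was terminated by a cap
  n_exit <- nrow(res$records) + res$n_exit_rejected
  expect_identical(n_exit + res$n_killed_path + res$n_killed_depth,
                   res$n_launched)
  # with the caps essentially lifted, photons in a non-absorbing
  # half-space all but surely escape through the surface
  expect_gt(n_exit / res$n_launched, 0.99)
  # byte-identical rerun with the same config and seed
  res2 <- mc_simulate(cfg)
  expect_identical(res$records, res2$records)
  # a different seed gives different records
  cfg3 <- mc_config(pf, geom, mu_s_prime = 2, rho_max = 2.5,
                    batch_size = 3e4, max_batches = 2L, min_detected = 1,
                    seed = 100, max_path_mm = 500, max_depth_mm = 50)
  expect_false(identical(mc_simulate(cfg3)$records, res$records))
})

test_that("widening the acceptance cone only adds detections", {
  pf <- pf_hg8
  counts <- vapply(c(0.05, 0.22, 0.5), function(na) {
    cfg <- mc_config(pf, sfr_geometry("iSFR", na, 1.0),
                     mu_s_prime = 2, rho_max = 2.5, batch_size = 3e4,
                     max_batches = 1L, min_detected = 1, seed = 5,
                     max_path_mm = 300, max_depth_mm = 50)
    nrow(mc_simulate(cfg)$records)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("reflectance agrees with an independent classical random walk", {
  # total reflectance of a semi-infinite isotropically scattering medium
  # with albedo 0.9 under near-normal incidence: classical absorbing-walk
  # oracle in plain R vs the white-MC engine with retrospective weights
  set.seed(301)
  n <- 4e4; mua <- 1; mus <- 9; mut <- 10
  Rsum <- 0; R2 <- 0
  for (i in seq_len(n)) {
    z <- 0; uz <- 1; w <- 1
    repeat {
      z2 <- z + uz * stats::rexp(1, mut)
      if (z2 < 0) { Rsum <- Rsum + w; R2 <- R2 + w^2; break }
      z <- z2
      w <- w * (mus / mut)
      uz <- stats::runif(1, -1, 1)
      if (w < 1e-7) break
    }
  }
  oracle <- Rsum / n
  oracle_se <- sqrt(R2 / n - oracle^2) / sqrt(n)
  # engine run: normal-incidence pencil, full angular acceptance, matched
  # boundary (white-box call so launch and acceptance cones can differ)
  tab <- pf_cdf_table(pf_iso)
  out <- isfr:::.mc_batch_cpp(2e5, mus, tab$cos_theta, 1e-6, 0.999999,
                              1e9, 1.35, 1.35, 1e4, 1e3, 0, FALSE, 17,
                              FALSE, numeric(0))
  w <- exp(-mua * out$records[, "path_mm"])
  R <- sum(w) / out$n_launched
  se <- sqrt(sum(w^2) / out$n_launched - R^2) / sqrt(out$n_launched)
  expect_lt(abs(R - oracle), 4 * sqrt(se^2 + oracle_se^2))
})

test_that("radial exit profile approaches the diffusion kernel far from
           the source", {
  # air-tissue boundary, wide acceptance, mu_s' = 1: binned R(rho) vs the
  # extrapolated-boundary dipole with retrospective absorption
  geom <- sfr_geometry("iSFR", 1.3499, 1.0)
  cfg <- mc_config(pf_hg8, geom, mu_s_prime = 1, rho_max = 7,
                   batch_size = 2e5, max_batches = 3L,
                   min_detected = 3e5, seed = 7, max_path_mm = 1500,
                   max_depth_mm = 80)
  res <- mc_simulate(cfg)
  mua <- 0.05
  w <- absorption_weights(res$records$path_mm, mua)
  br <- seq(2, 6, by = 0.5)
  idx <- findInterval(res$records$rho, br)
  ok <- idx >= 1 & idx < length(br)
  num <- tapply(w[ok], factor(idx[ok], levels = seq_len(length(br) - 1)),
                sum)
  num[is.na(num)] <- 0
  area <- pi * (br[-1]^2 - br[-length(br)]^2)
  r_mc <- as.numeric(num) / res$n_launched / area
  mid <- (br[-1] + br[-length(br)]) / 2
  r_th <- diffuse_radial(mid, mua, 1, geom$A)
  expect_true(all(abs(r_mc / r_th - 1) < 0.35))
  expect_lt(median(abs(r_mc / r_th - 1)), 0.30)
})

test_that("launch cone limits the initial directions (uniform-theta
           sensitivity option runs)", {
  cfg <- mc_config(pf_iso, sfr_geometry("iSFR", 0.22, 1.0),
                   mu_s_prime = 1, batch_size = 1e4, max_batches = 1L,
                   min_detected = 1, seed = 3, launch = "uniform_theta",
                   max_path_mm = 200, max_depth_mm = 50)
  expect_s3_class(mc_simulate(cfg), "mc_result")
  expect_error(mc_config(pf_iso, sfr_geometry("iSFR", 0.22, 1.0),
                         mu_s_prime = 1),
               "seed")
  expect_error(mc_config(pf_iso, sfr_geometry("iSFR", 0.22, 1.0),
                         seed = 1),
               "mu_s")
})
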