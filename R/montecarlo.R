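#' Unpolarized Fresnel transmittance
#'
#' Transmittance of an unpolarized ray crossing a planar interface from
#' refractive index `n1` into `n2` at incidence cosine `cos_i`. Returns 0
#' beyond the critical angle when `n1 > n2` (total internal reflection) and
#' 1 for matched media.
#'
#' @param cos_i cosine(s) of the incidence angle, in \[0, 1\].
#' @param n1,n2 refractive indices of the incident and transmitting media.
#' @return Transmittance in \[0, 1\], vectorized over `cos_i`.
#' @export
fresnel_transmission <- function(cos_i, n1, n2) {
  if (any(cos_i < 0 | cos_i > 1))
    stop("'cos_i' must lie in [0, 1]", call. = FALSE)
  if (n1 <= 0 || n2 <= 0) stop("refractive indices must be > 0", call. = FALSE)
  .fresnel_transmission_cpp(as.numeric(cos_i), n1, n2)
}

#' Monte Carlo simulation configuration
#'
#' Assembles the configuration for one absorption-free transport run. The
#' scattering coefficient may be given directly (`mu_s`) or derived from a
#' reduced scattering coefficient as `mu_s = mu_s_prime / (1 - g1)`.
#'
#' Photons are launched in batches of `batch_size` until a stopping rule is
#' met (or `max_batches` is hit); the per-batch seed is `seed + batch`, so
#' runs are reproducible and batches independent. Two stopping rules are
#' available: at least `min_detected` recorded photons (default), or --
#' when `target_rel_se` together with `stop_d_f` is given -- a relative
#' standard error of the reflectance at spot diameter `stop_d_f` and
#' absorption `stop_mu_a` (the worst-case quantity of interest) at or below
#' `target_rel_se`. Photons are terminated when their total path exceeds
#' `max_path_mm` or their depth exceeds `max_depth_mm`, emulating a large
#' lossy computational domain; termination losses are counted in the
#' result.
#'
#' Estimators: `"analog"` records photons that physically exit within the
#' acceptance cone and `rho_max` (unit weight). `"peeloff"` uses next-event
#' estimation: at every collision near the surface the probability of
#' scattering directly into the acceptance cone and escaping is integrated
#' over the cone and stored as a weighted record; analog exits are then not
#' recorded. Peel-off is unbiased and far more efficient for narrow
#' acceptance cones (it is used by the spectrum synthesizer at NA 0.05).
#'
#' @param pf a [pf_spec][pf_mhg] phase function.
#' @param geometry an [sfr_geometry()] object (supplies NA and indices).
#' @param mu_s scattering coefficient, mm^-1 (exclusive with `mu_s_prime`).
#' @param mu_s_prime reduced scattering coefficient, mm^-1.
#' @param rho_max maximum recorded radial exit distance, mm; defaults to
#'   1.0 (SFR) or 2.5 (iSFR).
#' @param batch_size photons per batch.
#' @param max_batches cap on the number of batches.
#' @param min_detected stop once this many photons are recorded.
#' @param target_rel_se optional relative-standard-error stopping target.
#' @param stop_d_f,stop_mu_a quantity of interest for the rel-SE rule.
#' @param seed integer seed (mandatory).
#' @param max_path_mm,max_depth_mm termination caps, mm.
#' @param launch `"solid_angle"` (uniform over solid angle within the
#'   in-tissue NA cone; default) or `"uniform_theta"` (uniform in polar
#'   angle, for sensitivity checks).
#' @param estimator `"analog"` or `"peeloff"`, see Details.
#' @param source_diam source-disk diameter, mm; 0 (default) launches from a
#'   point and records exit radii for the single-integral approximation,
#'   a positive value switches to the direct finite-disk geometry in which
#'   the source disk is also the detector (analog estimator only).
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(pf, geometry, mu_s = NULL, mu_s_prime = NULL,
                      rho_max = NULL, batch_size = 1e5, max_batches = 400L,
                      min_detected = 1e4, target_rel_se = NULL,
                      stop_d_f = NULL, stop_mu_a = 0, seed,
                      max_path_mm = 1e4, max_depth_mm = 100,
                      launch = c("solid_angle", "uniform_theta"),
                      estimator = c("analog", "peeloff"),
                      source_diam = 0) {
  stopifnot(inherits(pf, "pf_spec"), inherits(geometry, "sfr_geometry"))
  launch <- match.arg(launch)
  estimator <- match.arg(estimator)
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("'seed' is mandatory for reproducible simulations", call. = FALSE)
  if (is.null(mu_s)) {
    if (is.null(mu_s_prime))
      stop("supply either 'mu_s' or 'mu_s_prime'", call. = FALSE)
    g1 <- pf_moments(pf)$g1
    mu_s <- mu_s_prime / (1 - g1)
  } else if (!is.null(mu_s_prime)) {
    stop("supply only one of 'mu_s' and 'mu_s_prime'", call. = FALSE)
  } else {
    g1 <- pf_moments(pf)$g1
    mu_s_prime <- mu_s * (1 - g1)
  }
  if (mu_s <= 0) stop("'mu_s' must be > 0", call. = FALSE)
  if (estimator == "peeloff" && source_diam > 0)
    stop("peel-off estimation requires a point source", call. = FALSE)
  if (!is.null(target_rel_se) && is.null(stop_d_f))
    stop("'stop_d_f' is required for the rel-SE stopping rule",
         call. = FALSE)
  if (is.null(rho_max))
    rho_max <- if (geometry$modality == "SFR") 1.0 else 2.5
  structure(list(pf = pf, geometry = geometry, mu_s = mu_s,
                 mu_s_prime = mu_s_prime, g1 = g1, rho_max = rho_max,
                 batch_size = as.integer(batch_size),
                 max_batches = as.integer(max_batches),
                 min_detected = min_detected,
                 target_rel_se = target_rel_se, stop_d_f = stop_d_f,
                 stop_mu_a = stop_mu_a, seed = as.integer(seed),
                 max_path_mm = max_path_mm, max_depth_mm = max_depth_mm,
                 launch = launch, estimator = estimator,
                 source_diam = source_diam),
            class = "mc_config")
}

#' Run an absorption-free Monte Carlo transport simulation
#'
#' Launches photons from the boundary within the in-tissue NA cone
#' (`sin(theta_max) = NA / n_tissue`), propagates them with exponential free
#' paths of rate `mu_s` and deflection angles drawn from the phase
#' function's tabulated inverse CDF, applies stochastic unpolarized Fresnel
#' transmission (with total internal reflection) at every boundary
#' crossing, and records detected photons (see [mc_config()] for the two
#' estimators). No absorption is simulated; path lengths are stored so
#' absorption can be applied retrospectively ([geometry_reflectance()]).
#'
#' @param config an [mc_config()] object.
#' @param verbose print per-batch progress?
#' @return An object of class `mc_result`: list with `records` (data frame
#'   with columns `rho`, `path_mm`, `cos_exit`, `weight`, `photon`,
#'   `batch`), `n_launched`, termination counters and the `config`.
#' @export
mc_simulate <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "mc_config"))
  g <- config$geometry
  sin_cone <- g$na / g$n_tissue
  tab <- pf_cdf_table(config$pf)
  peel <- config$estimator == "peeloff"
  pdf_tab <- if (peel) {
    cg <- seq(-1, 1, length.out = 2^15)
    pf_pdf(config$pf, acos(pmin(1, pmax(-1, cg))))
  } else numeric(0)
  recs <- vector("list", config$max_batches)
  n_launched <- 0; n_detected <- 0
  killed_path <- 0; killed_depth <- 0; exit_rejected <- 0
  b <- 0L
  plan_b <- 1L  # next batch at which the rel-SE stopping rule is checked
  repeat {
    b <- b + 1L
    out <- .mc_batch_cpp(config$batch_size, config$mu_s, tab$cos_theta,
                         sin_cone, sin_cone, config$rho_max,
                         g$n_tissue, g$n_external,
                         config$max_path_mm, config$max_depth_mm,
                         config$source_diam,
                         config$launch == "uniform_theta",
                         as.numeric(config$seed) + b,
                         peel, pdf_tab)
    m <- out$records
    recs[[b]] <- data.frame(rho = m[, 1], path_mm = m[, 2],
                            cos_exit = m[, 3], weight = m[, 4],
                            photon = m[, 5], batch = b)
    n_launched <- n_launched + out$n_launched
    n_detected <- n_detected + nrow(m)
    killed_path <- killed_path + out$n_killed_path
    killed_depth <- killed_depth + out$n_killed_depth
    exit_rejected <- exit_rejected + out$n_exit_rejected
    if (verbose)
      message(sprintf("batch %d: %d records / %.0f launched", b,
                      n_detected, n_launched))
    if (b >= config$max_batches) break
    if (is.null(config$target_rel_se)) {
      if (n_detected >= config$min_detected) break
    } else if (n_detected > 0 && b >= plan_b) {
      # project the number of batches needed from the current SE
      # (SE ~ 1/sqrt(batches)) instead of rescanning every batch
      part <- structure(list(records = do.call(rbind, recs[seq_len(b)]),
                             n_launched = n_launched, config = config),
                        class = "mc_result")
      gr <- geometry_reflectance(part, config$stop_d_f, config$stop_mu_a)
      if (is.finite(gr$rel_se) && gr$rel_se <= config$target_rel_se) break
      ratio <- if (is.finite(gr$rel_se))
        (gr$rel_se / config$target_rel_se)^2 else 2
      plan_b <- min(config$max_batches,
                    max(b + 1L, ceiling(b * ratio * 1.02)))
    }
  }
  if (n_detected == 0)
    stop("no photons detected after ", b, " batches (",
         format(n_launched, big.mark = ","), " launched); increase ",
         "'batch_size'/'max_batches' or widen the geometry", call. = FALSE)
  structure(list(records = do.call(rbind, recs[seq_len(b)]),
                 n_launched = n_launched, n_batches = b,
                 n_killed_path = killed_path, n_killed_depth = killed_depth,
                 n_exit_rejected = exit_rejected, config = config),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> %s NA=%g (%s): %d records / %.3g launched (%d batches)\n",
    x$config$geometry$modality, x$config$geometry$na, x$config$estimator,
    nrow(x$records), x$n_launched, x$n_batches))
  cat(sprintf("  mu_s = %.3g mm^-1 (mu_s' = %.3g, g1 = %.3f), pf = %s\n",
              x$config$mu_s, x$config$mu_s_prime, x$config$g1,
              x$config$pf$id))
  cat(sprintf("  terminated: %.0f path cap, %.0f depth cap; %.0f exits rejected\n",
              x$n_killed_path, x$n_killed_depth, x$n_exit_rejected))
  invisible(x)
}
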