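#' Retrospective Beer-Lambert absorption weights
#'
#' In white (absorption-free) Monte Carlo, absorption is applied after the
#' fact: each detected photon with in-medium path length `l` carries the
#' weight `exp(-mu_a * l)`, so one simulation serves every absorption
#' coefficient.
#'
#' @param path_mm photon path length(s), mm; or an `mc_result` whose record
#'   paths are used.
#' @param mu_a absorption coefficient, mm^-1 (>= 0).
#' @return Numeric vector of per-photon weights in (0, 1\].
#' @export
absorption_weights <- function(path_mm, mu_a) {
  if (mu_a < 0) stop("'mu_a' must be >= 0", call. = FALSE)
  if (inherits(path_mm, "mc_result")) path_mm <- path_mm$records$path_mm
  exp(-mu_a * path_mm)
}

#' Disk-overlap weight of the single-integral approximation
#'
#' Probability that a point displaced by `rho` from a uniformly random
#' point of a disk of diameter `d_f` (with uniformly random azimuth) still
#' falls inside the disk:
#' `w(rho) = (2/pi) * (acos(t) - t * sqrt(1 - t^2))`, `t = rho / d_f`.
#' Equivalently `w = (pi d_f^2 / 4) * p(rho, d_f) / (2 pi rho)` with the
#' point-pair density of [disk_distance_pdf()]. Monotone decreasing from
#' `w(0) = 1` to `w(d_f) = 0`.
#'
#' @param rho radial displacement(s), mm.
#' @param d_f disk diameter, mm.
#' @return Weights in \[0, 1\].
#' @export
overlap_weight <- function(rho, d_f) {
  if (d_f <= 0) stop("'d_f' must be > 0", call. = FALSE)
  t <- pmin(1, pmax(0, rho / d_f))
  2 / pi * (acos(t) - t * sqrt(1 - t^2))
}

#' Reflectance for a finite spot from point-source photon records
#'
#' Converts the point-source exit records of an absorption-free simulation
#' into the total reflectance of an overlapping source-detector disk of
#' diameter `d_f` at absorption `mu_a`, using per-photon single-integral
#' weights (no radial binning):
#' `R_tot = (1 / n_launched) * sum(exp(-mu_a l_i) * w(rho_i, d_f))`.
#' The relative standard error treats photons as i.i.d. Bernoulli-weighted
#' contributions.
#'
#' @param result an [mc_simulate()] result from a point-source run.
#' @param d_f spot diameter, mm; must not exceed the simulation's `rho_max`.
#' @param mu_a absorption coefficient, mm^-1.
#' @return A list with `R_tot`, `rel_se`, `n_effective`, `d_f`, `mu_a`.
#' @export
geometry_reflectance <- function(result, d_f, mu_a) {
  stopifnot(inherits(result, "mc_result"))
  if (result$config$source_diam > 0)
    stop("records come from a finite-source run; the single-integral ",
         "conversion applies to point-source records only", call. = FALSE)
  if (d_f > result$config$rho_max + 1e-12)
    stop("d_f = ", d_f, " mm exceeds the simulated rho_max = ",
         result$config$rho_max, " mm: photons beyond rho_max were ",
         "discarded at simulation time", call. = FALSE)
  if (nrow(result$records) == 0) stop("no photon records", call. = FALSE)
  rec <- result$records
  w <- rec$weight * absorption_weights(rec$path_mm, mu_a) *
    overlap_weight(rec$rho, d_f)
  n <- result$n_launched
  r <- sum(w) / n
  # standard error treats photons (not records) as the i.i.d. unit: the
  # peel-off estimator emits several correlated records per photon
  key <- rec$batch * (result$config$batch_size + 1) + rec$photon
  wp <- rowsum(w, key)
  v <- sum(wp^2)
  se <- sqrt(max(0, v / n - r^2) / n)
  list(R_tot = r, rel_se = if (r > 0) se / r else Inf,
       n_effective = if (v > 0) sum(w)^2 / v else 0,
       d_f = d_f, mu_a = mu_a)
}

#' Reflectance dataset from a set of simulations
#'
#' Expands a list of point-source simulations (one per phase function /
#' scattering / geometry combination) into the full Cartesian reflectance
#' table over spot diameters and absorption coefficients, evaluated in
#' post-processing via [geometry_reflectance()].
#'
#' @param results list of [mc_simulate()] results.
#' @param d_f numeric vector of spot diameters, mm.
#' @param mu_a numeric vector of absorption coefficients, mm^-1.
#' @return A data frame with one row per (simulation, d_f, mu_a): columns
#'   `modality`, `na`, `d_f_mm`, `mu_a_mm`, `mu_s_prime_mm`, `pf_id`,
#'   `p_sb`, `g1`, `g2`, `R_MC`, `rel_se`.
#' @export
dataset_sweep <- function(results, d_f, mu_a) {
  stopifnot(length(results) > 0)
  rows <- lapply(results, function(res) {
    stopifnot(inherits(res, "mc_result"))
    cfg <- res$config
    m <- pf_moments(cfg$pf)
    grid <- expand.grid(d_f = d_f, mu_a = mu_a)
    vals <- mapply(function(d, a) {
      gr <- geometry_reflectance(res, d, a)
      c(gr$R_tot, gr$rel_se)
    }, grid$d_f, grid$mu_a)
    data.frame(modality = cfg$geometry$modality, na = cfg$geometry$na,
               d_f_mm = grid$d_f, mu_a_mm = grid$mu_a,
               mu_s_prime_mm = cfg$mu_s_prime, pf_id = cfg$pf$id,
               p_sb = pf_psb(cfg$pf), g1 = m$g1, g2 = m$g2,
               R_MC = vals[1, ], rel_se = vals[2, ],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Size of a full reflectance parameter sweep
#'
#' Number of rows a Cartesian reflectance dataset would contain, i.e. the
#' product of the grid sizes for numerical aperture, spot diameter, reduced
#' scattering, absorption and phase function.
#'
#' @param n_na,n_d_f,n_mu_s_prime,n_mu_a,n_pf grid sizes.
#' @return Integer-valued count (as double to avoid overflow).
#' @export
sweep_cardinality <- function(n_na, n_d_f, n_mu_s_prime, n_mu_a, n_pf) {
  as.numeric(n_na) * n_d_f * n_mu_s_prime * n_mu_a * n_pf
}

#' Study parameter grids for the two modalities
#'
#' The geometric and optical grids over which the reflectance model was
#' derived: numerical apertures and spot diameters per modality, reduced
#' scattering and absorption coefficients shared by both.
#'
#' @param modality `"SFR"` or `"iSFR"`.
#' @return A list with elements `na`, `d_f_mm`, `mu_s_prime_mm`,
#'   `mu_a_mm`, `n_pf` (phase-function count after filtering).
#' @export
study_grids <- function(modality = c("SFR", "iSFR")) {
  modality <- match.arg(modality)
  list(
    na = if (modality == "SFR") c(0.10, 0.22, 0.39, 0.50)
    else c(0.01, 0.025, 0.05, 0.10, 0.22),
    d_f_mm = if (modality == "SFR") seq(0.1, 1.0, by = 0.1)
    else c(seq(0.2, 2.0, by = 0.2), 2.5),
    mu_s_prime_mm = c(0.5, 1, 2.5, 5, 7.5, 10, 15, 20),
    mu_a_mm = c(0.01, 0.025, 0.05, 0.075, 0.1, 0.25, 0.5, 0.75, 1,
                2.5, 5, 7.5, 10),
    n_pf = 207)
}
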