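#' Bundled whole-blood chromophore absorption table
#'
#' Loads the packaged table of whole-blood absorption coefficients (mm^-1)
#' for fully oxygenated and fully deoxygenated blood at 150 g/L hemoglobin,
#' tabulated from 400 to 900 nm in 5 nm steps. The table is a synthetic
#' compilation that reproduces the canonical spectral features of
#' hemoglobin (see the provenance header of the bundled CSV); absolute
#' absorption scales with the assumed hemoglobin concentration.
#'
#' @return Data frame with columns `wavelength_nm`, `mu_a_HbO2_mm`,
#'   `mu_a_Hb_mm`.
#' @export
chromophore_table <- function() {
  if (is.null(.isfr_env$chromophores)) {
    path <- system.file("extdata", "hemoglobin_whole_blood_synthetic.csv",
                        package = "isfr", mustWork = TRUE)
    .isfr_env$chromophores <- utils::read.csv(path, comment.char = "#")
  }
  .isfr_env$chromophores
}

.isfr_env <- new.env(parent = emptyenv())

#' Wavelength-parameterized tissue optical model
#'
#' A tissue is described by wavelength parameterizations about the
#' reference wavelength `lambda* = 650` nm:
#' * reduced scattering: power law `mu_s'(lambda) = a (lambda/lambda*)^-b`;
#' * absorption: whole-blood mixing `mu_a(lambda) = v_f_blood * (sO2 *
#'   mu_a_HbO2(lambda) + (1 - sO2) * mu_a_Hb(lambda))`;
#' * phase-function descriptor: cubic `p_sb(lambda) = 1e-5 * (p1 x + p2 x^2
#'   + p3 x^3)` with `x = lambda/lambda*`.
#'
#' Two named presets are shipped: `"skin"` (`a = 4.6` mm^-1, `b = 1.4`,
#' `v_f_blood = 0.01`, `sO2 = 0.7`) and `"soft_tissue"` (`a = 1.9` mm^-1,
#' `b = 1.3`, `v_f_blood = 0.05`, `sO2 = 0.7`). Their `p1..p3` coefficients
#' are derived once by fitting the cubic to the descriptor of the reference
#' scattering realization (see [reference_phase_function()]), so the
#' presets' `p_sb(lambda)` tracks the phase functions actually used for
#' simulated ground truth.
#'
#' @param preset `"skin"` or `"soft_tissue"`; or `NULL` with explicit
#'   parameters.
#' @param a scattering amplitude at `lambda*`, mm^-1.
#' @param b scattering power.
#' @param v_f_blood blood volume fraction in \[0, 1\].
#' @param sO2 hemoglobin oxygen saturation in \[0, 1\].
#' @param p1,p2,p3 `p_sb` cubic coefficients.
#' @param lambda_star reference wavelength, nm.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(preset = NULL, a, b, v_f_blood, sO2,
                         p1 = NULL, p2 = NULL, p3 = NULL,
                         lambda_star = 650) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("skin", "soft_tissue"))
    vals <- switch(preset,
      skin = list(a = 4.6, b = 1.4, v_f_blood = 0.01, sO2 = 0.7),
      soft_tissue = list(a = 1.9, b = 1.3, v_f_blood = 0.05, sO2 = 0.7))
    a <- vals$a; b <- vals$b; v_f_blood <- vals$v_f_blood; sO2 <- vals$sO2
  }
  stopifnot(a > 0, v_f_blood >= 0, v_f_blood <= 1, sO2 >= 0, sO2 <= 1)
  if (is.null(p1)) {
    p <- reference_psb_coefficients(lambda_star)
    p1 <- p[1]; p2 <- p[2]; p3 <- p[3]
  }
  structure(list(a = a, b = b, v_f_blood = v_f_blood, sO2 = sO2,
                 p1 = p1, p2 = p2, p3 = p3, lambda_star = lambda_star,
                 preset = preset),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf(
    "<tissue_model%s> a=%.3g mm^-1, b=%.3g, v_f_blood=%.3g, sO2=%.3g\n",
    if (!is.null(x$preset)) paste0(" ", x$preset) else "",
    x$a, x$b, x$v_f_blood, x$sO2))
  cat(sprintf("  p_sb(%g nm) = %.3g (p = %.4g, %.4g, %.4g)\n",
              x$lambda_star, psb_at(x$lambda_star, x), x$p1, x$p2, x$p3))
  invisible(x)
}

#' Reference scattering phase function for spectrum synthesis
#'
#' The complete phase-function realization used when synthesizing spectra
#' with the Monte Carlo engine (a scalar `p_sb` is not enough to transport
#' photons): a TTHG with `alpha = 0.8`, `g_b = -0.05` and a forward
#' anisotropy decreasing linearly with wavelength from `g_f = 0.8` at
#' 400 nm to `g_f = 0.7` at 900 nm.
#'
#' @param lambda wavelength(s), nm.
#' @return For scalar `lambda`, a [pf_spec][pf_mhg]; for vector input, a
#'   list of them.
#' @export
reference_phase_function <- function(lambda) {
  g_f <- 0.8 + (0.7 - 0.8) * (lambda - 400) / (900 - 400)
  specs <- lapply(g_f, function(g) pf_tthg(alpha = 0.8, g_f = g,
                                           g_b = -0.05))
  if (length(lambda) == 1L) specs[[1]] else specs
}

# cubic p_sb coefficients matching the reference phase function, cached
reference_psb_coefficients <- function(lambda_star = 650) {
  key <- as.character(lambda_star)
  if (is.null(.isfr_env$psb_coef[[key]])) {
    lam <- seq(400, 900, by = 25)
    psb <- vapply(reference_phase_function(lam), pf_psb, numeric(1))
    x <- lam / lambda_star
    fit <- stats::lm.fit(cbind(x, x^2, x^3), psb / 1e-5)
    if (is.null(.isfr_env$psb_coef)) .isfr_env$psb_coef <- list()
    .isfr_env$psb_coef[[key]] <- unname(fit$coefficients)
  }
  .isfr_env$psb_coef[[key]]
}

#' Tissue optical properties at given wavelengths
#'
#' `mus_prime_at()`, `mua_at()` and `psb_at()` evaluate the three
#' wavelength parameterizations of a [tissue_model()].
#'
#' @param lambda wavelength(s), nm.
#' @param model a [tissue_model()].
#' @param table chromophore table (defaults to the bundled one); `mua_at`
#'   interpolates it linearly and errors outside its coverage.
#' @return Numeric vector: mm^-1 for `mus_prime_at` and `mua_at`,
#'   dimensionless for `psb_at`.
#' @export
mus_prime_at <- function(lambda, model) {
  stopifnot(inherits(model, "tissue_model"), all(lambda > 0))
  model$a * (lambda / model$lambda_star)^(-model$b)
}

#' @rdname mus_prime_at
#' @export
mua_at <- function(lambda, model, table = chromophore_table()) {
  stopifnot(inherits(model, "tissue_model"))
  rng <- range(table$wavelength_nm)
  if (any(lambda < rng[1] | lambda > rng[2]))
    stop("wavelength outside chromophore table coverage [",
         rng[1], ", ", rng[2], "] nm", call. = FALSE)
  hbo2 <- stats::approx(table$wavelength_nm, table$mu_a_HbO2_mm,
                        xout = lambda)$y
  hb <- stats::approx(table$wavelength_nm, table$mu_a_Hb_mm,
                      xout = lambda)$y
  model$v_f_blood * (model$sO2 * hbo2 + (1 - model$sO2) * hb)
}

#' @rdname mus_prime_at
#' @export
psb_at <- function(lambda, model) {
  stopifnot(inherits(model, "tissue_model"))
  x <- lambda / model$lambda_star
  out <- 1e-5 * (model$p1 * x + model$p2 * x^2 + model$p3 * x^3)
  if (any(out <= 0))
    warning("p_sb(lambda) is non-positive at some wavelengths: ",
            "physically invalid descriptor", call. = FALSE)
  out
}

#' Synthesize a reflectance spectrum
#'
#' Computes the reflectance spectrum of a tissue model for a given
#' acquisition geometry, either through the semi-empirical forward model
#' (`engine = "model"`, fast) or through the Monte Carlo + single-integral
#' pipeline (`engine = "mc"`, the simulation ground truth; one transport
#' run per wavelength using the [reference_phase_function()]).
#'
#' @param model a [tissue_model()].
#' @param geometry an [sfr_geometry()].
#' @param engine `"model"` or `"mc"`.
#' @param wavelengths wavelength grid, nm (default 400-900 nm in 5 nm
#'   steps, 101 points).
#' @param seed integer seed (required for `engine = "mc"`).
#' @param params forward-model parameters (default: shipped values for the
#'   geometry).
#' @param mc_control list of overrides passed to [mc_config()] for the mc
#'   engine (e.g. `min_detected`, `batch_size`, `max_path_mm`).
#' @return An object of class `sfr_spectrum`: data frame with columns
#'   `wavelength_nm`, `R`, `rel_se`, and attributes `tissue`, `geometry`,
#'   `engine`, `seed`, `noise_rms_frac`.
#' @export
synthesize_spectrum <- function(model, geometry,
                                engine = c("model", "mc"),
                                wavelengths = seq(400, 900, by = 5),
                                seed = NULL, params = NULL,
                                mc_control = list()) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "tissue_model"),
            inherits(geometry, "sfr_geometry"))
  mua <- mua_at(wavelengths, model)
  mus <- mus_prime_at(wavelengths, model)
  if (engine == "model") {
    psb <- psb_at(wavelengths, model)
    pred <- predict_reflectance(mua, mus, psb, geometry, params)
    out <- data.frame(wavelength_nm = wavelengths, R = pred$R_total,
                      rel_se = 0)
  } else {
    if (is.null(seed))
      stop("'seed' is required for the mc engine", call. = FALSE)
    pfs <- reference_phase_function(wavelengths)
    R <- rel_se <- numeric(length(wavelengths))
    for (i in seq_along(wavelengths)) {
      args <- c(list(pf = pfs[[i]], geometry = geometry,
                     mu_s_prime = mus[i],
                     seed = seed + 1000L * i), mc_control)
      # rel-SE stopping, when requested, targets this wavelength's own
      # absorption (the quantity actually entering the spectrum)
      if (!is.null(args$target_rel_se) && is.null(args$stop_mu_a))
        args$stop_mu_a <- mua[i]
      res <- mc_simulate(do.call(mc_config, args))
      gr <- geometry_reflectance(res, geometry$d_f, mua[i])
      R[i] <- gr$R_tot
      rel_se[i] <- gr$rel_se
    }
    out <- data.frame(wavelength_nm = wavelengths, R = R, rel_se = rel_se)
  }
  structure(out, class = c("sfr_spectrum", "data.frame"),
            tissue = model, geometry = geometry, engine = engine,
            seed = seed, noise_rms_frac = 0)
}

#' Add measurement noise to a spectrum
#'
#' Adds i.i.d. zero-mean Gaussian noise to every spectral point with a
#' standard deviation equal to `rms_frac` times the root-mean-square of the
#' reflectance over the full wavelength range (so the injected noise is
#' scale-equivariant in the reflectance).
#'
#' @param spectrum an [sfr_spectrum][synthesize_spectrum].
#' @param rms_frac noise level as a fraction of the spectrum RMS (>= 0).
#' @param seed integer seed (required for `rms_frac > 0`).
#' @return The noisy spectrum, with `noise_rms_frac` recorded.
#' @export
add_noise <- function(spectrum, rms_frac, seed = NULL) {
  stopifnot(inherits(spectrum, "sfr_spectrum"), rms_frac >= 0)
  if (rms_frac == 0) return(spectrum)
  if (is.null(seed))
    stop("'seed' is required to inject noise reproducibly", call. = FALSE)
  sdev <- rms_frac * sqrt(mean(spectrum$R^2))
  noise <- stats::qnorm(withr_seed_runif(nrow(spectrum), seed),
                        sd = sdev)
  out <- spectrum
  out$R <- out$R + noise
  attr(out, "noise_rms_frac") <- rms_frac
  attr(out, "noise_seed") <- seed
  out
}
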