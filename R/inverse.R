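#' Default parameter bounds for inverse retrieval
#'
#' Bounded box for the seven fitted tissue parameters. The `p_sb(lambda)`
#' cubic is additionally constrained to the validity range of the
#' semi-empirical model (1e-6 to 1e-4) through a smooth penalty inside the
#' objective rather than through box bounds on the coefficients.
#'
#' @return Data frame with columns `param`, `lower`, `upper`.
#' @export
retrieval_bounds <- function() {
  data.frame(
    param = c("a", "b", "v_f_blood", "sO2", "p1", "p2", "p3"),
    lower = c(0.1, 0.1, 0, 0, -30, -30, -30),
    upper = c(30, 4, 0.3, 1, 30, 30, 30),
    stringsAsFactors = FALSE)
}

# forward model spectrum for a parameter vector theta (a,b,vf,sO2,p1,p2,p3)
retrieval_forward <- function(theta, lambda, geometry, params, chrom) {
  mus <- theta[1] * (lambda / 650)^(-theta[2])
  mua <- theta[3] * (theta[4] * chrom$hbo2 + (1 - theta[4]) * chrom$hb)
  x <- lambda / 650
  psb <- 1e-5 * (theta[5] * x + theta[6] * x^2 + theta[7] * x^3)
  list(mus = mus, mua = mua, psb = psb)
}

# residual vector of the relative least-squares objective, with a penalty
# pushing p_sb(lambda) into [1e-6, 1e-4]
retrieval_residuals <- function(theta, lambda, R_obs, geometry, params,
                                chrom) {
  q <- retrieval_forward(theta, lambda, geometry, params, chrom)
  pen <- numeric(length(lambda))
  bad_lo <- q$psb < 1e-6
  bad_hi <- q$psb > 1e-4
  pen[bad_lo] <- (1e-6 - q$psb[bad_lo]) / 1e-6
  pen[bad_hi] <- (q$psb[bad_hi] - 1e-4) / 1e-4
  psb_eval <- pmin(1e-4, pmax(1e-6, q$psb))
  eta_c <- collection_efficiency(geometry$na, geometry$n_external)
  r_diff <- sfr_diffuse(q$mua, q$mus, geometry$d_f, geometry$A)
  xr <- params$a2 * (psb_eval / (q$mus * geometry$d_f)^2)^params$a3 *
    exp(params$b1 * (q$mua / q$mus)^params$b2)
  r_model <- (1 + xr) * eta_c * params$a1 * r_diff
  c((r_model - R_obs) / R_obs, 10 * pen)
}

#' Relative least-squares retrieval objective
#'
#' The objective minimized during inverse retrieval:
#' `sum_lambda ((R_model(lambda; theta) - R_obs(lambda)) / R_obs(lambda))^2`
#' (excluding the internal `p_sb` validity penalty).
#'
#' @param theta named or positional numeric vector
#'   `(a, b, v_f_blood, sO2, p1, p2, p3)`.
#' @param spectrum observed [sfr_spectrum][synthesize_spectrum].
#' @param geometry an [sfr_geometry()].
#' @param params forward-model parameters (default: shipped values for the
#'   geometry).
#' @return Scalar objective value.
#' @export
retrieval_objective <- function(theta, spectrum, geometry, params = NULL) {
  stopifnot(inherits(spectrum, "sfr_spectrum"))
  if (any(spectrum$R <= 0))
    stop("observed reflectance must be positive at every wavelength",
         call. = FALSE)
  if (is.null(params)) params <- model_params(geometry$modality, geometry$na)
  chrom <- retrieval_chrom(spectrum$wavelength_nm)
  res <- retrieval_residuals(as.numeric(theta), spectrum$wavelength_nm,
                             spectrum$R, geometry, params, chrom)
  sum(res[seq_along(spectrum$wavelength_nm)]^2)
}

# silence the expected lmdif maxiter chatter from exploration starts
quiet_lm_warnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("lmdif|lmder", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

retrieval_chrom <- function(lambda) {
  tab <- chromophore_table()
  list(hbo2 = stats::approx(tab$wavelength_nm, tab$mu_a_HbO2_mm,
                            xout = lambda)$y,
       hb = stats::approx(tab$wavelength_nm, tab$mu_a_Hb_mm,
                          xout = lambda)$y)
}

#' Multistart inverse retrieval of tissue optical properties
#'
#' Estimates the seven tissue parameters (scattering amplitude `a` and
#' power `b`, blood volume fraction, oxygen saturation, and the three
#' `p_sb` cubic coefficients) from an observed reflectance spectrum by
#' bounded Levenberg-Marquardt least squares on the relative residuals,
#' restarted from `n_starts` initial points drawn uniformly in the bound
#' box. The best final objective wins (ties by first found).
#'
#' @inheritParams retrieval_objective
#' @param n_starts number of randomized initializations.
#' @param bounds bound box as from [retrieval_bounds()].
#' @param seed integer seed controlling the initial points (mandatory).
#' @return An object of class `sfr_retrieval`: list with `theta_hat`
#'   (a [tissue_model()]), `theta` (named vector), `objective`, `n_starts`,
#'   `converged`, `start_objectives`.
#' @export
retrieve_properties <- function(spectrum, geometry, params = NULL,
                                n_starts = 50, bounds = retrieval_bounds(),
                                seed) {
  stopifnot(inherits(spectrum, "sfr_spectrum"),
            inherits(geometry, "sfr_geometry"))
  if (missing(seed) || is.null(seed))
    stop("'seed' is mandatory for reproducible retrieval", call. = FALSE)
  if (any(spectrum$R <= 0))
    stop("observed reflectance must be positive at every wavelength",
         call. = FALSE)
  if (is.null(params)) params <- model_params(geometry$modality, geometry$na)
  lambda <- spectrum$wavelength_nm
  chrom <- retrieval_chrom(lambda)
  npar <- nrow(bounds)
  # prefix-stable schedule: start i depends on (seed, i) only, so adding
  # starts never changes the earlier ones and best-of-n is monotone
  starts <- t(vapply(seq_len(n_starts), function(i)
    bounds$lower + withr_seed_runif(npar, seed + 104729L * i) *
      (bounds$upper - bounds$lower), numeric(npar)))
  # exploration phase: cheap bounded LM from every start; the best two
  # endpoints are then polished to tight tolerances
  fits <- vector("list", n_starts)
  objs <- rep(NA_real_, n_starts)
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      quiet_lm_warnings(minpack.lm::nls.lm(
        par = starts[i, ], lower = bounds$lower, upper = bounds$upper,
        fn = retrieval_residuals, lambda = lambda, R_obs = spectrum$R,
        geometry = geometry, params = params, chrom = chrom,
        control = minpack.lm::nls.lm.control(maxiter = 25, ftol = 1e-8,
                                             ptol = 1e-6))),
      error = function(e) NULL)
    if (is.null(fit)) next
    fits[[i]] <- fit
    objs[i] <- fit$deviance
  }
  if (all(is.na(objs)))
    stop("all ", n_starts, " retrieval starts failed", call. = FALSE)
  best <- NULL
  for (i in order(objs)[seq_len(min(2L, sum(!is.na(objs))))]) {
    polish <- tryCatch(
      quiet_lm_warnings(minpack.lm::nls.lm(
        par = fits[[i]]$par, lower = bounds$lower, upper = bounds$upper,
        fn = retrieval_residuals, lambda = lambda, R_obs = spectrum$R,
        geometry = geometry, params = params, chrom = chrom,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-10))),
      error = function(e) NULL)
    cand <- if (!is.null(polish) &&
                polish$deviance <= fits[[i]]$deviance) polish
    else fits[[i]]
    if (is.null(best) || cand$deviance < best$deviance) best <- cand
  }
  theta <- best$par
  names(theta) <- bounds$param
  model <- tissue_model(a = theta[["a"]], b = theta[["b"]],
                        v_f_blood = theta[["v_f_blood"]],
                        sO2 = theta[["sO2"]], p1 = theta[["p1"]],
                        p2 = theta[["p2"]], p3 = theta[["p3"]])
  structure(list(theta_hat = model, theta = theta,
                 objective = best$deviance, n_starts = n_starts,
                 converged = best$info %in% 1:4,
                 start_objectives = objs),
            class = "sfr_retrieval")
}

#' @export
print.sfr_retrieval <- function(x, ...) {
  cat(sprintf("<sfr_retrieval> objective = %.4g over %d starts (%s)\n",
              x$objective, x$n_starts,
              if (x$converged) "converged" else "not converged"))
  print(round(x$theta, 5))
  invisible(x)
}

#' Retrieval error metrics against a known truth
#'
#' Relative errors `|x_hat - x| / |x|` of the four scalar parameters and
#' the relative root-mean-square error of the retrieved `p_sb(lambda)`
#' curve over a wavelength range (the cubic coefficients themselves are
#' not individually meaningful).
#'
#' @param result an [sfr_retrieval][retrieve_properties] (or a
#'   [tissue_model()] estimate).
#' @param truth the true [tissue_model()].
#' @param wavelengths wavelengths over which to evaluate the `p_sb` RMSE.
#' @return Named list: `a`, `b`, `v_f_blood`, `sO2` (relative errors),
#'   `psb_rmse` (relative RMSE of `p_sb(lambda)`), `psb_at_ref` (retrieved
#'   descriptor at `lambda*`).
#' @export
retrieval_metrics <- function(result, truth,
                              wavelengths = seq(400, 900, by = 5)) {
  est <- if (inherits(result, "sfr_retrieval")) result$theta_hat else result
  stopifnot(inherits(est, "tissue_model"), inherits(truth, "tissue_model"))
  rel <- function(xh, x) abs(xh - x) / abs(x)
  psb_e <- psb_curve(wavelengths, est)
  psb_t <- psb_curve(wavelengths, truth)
  list(a = rel(est$a, truth$a), b = rel(est$b, truth$b),
       v_f_blood = rel(est$v_f_blood, truth$v_f_blood),
       sO2 = rel(est$sO2, truth$sO2),
       psb_rmse = sqrt(mean(((psb_e - psb_t) / psb_t)^2)),
       psb_at_ref = psb_curve(est$lambda_star, est))
}

# p_sb cubic without the positivity warning (internal)
psb_curve <- function(lambda, model) {
  x <- lambda / model$lambda_star
  1e-5 * (model$p1 * x + model$p2 * x^2 + model$p3 * x^3)
}

#' Replicated retrieval under noise
#'
#' Generates `n_replicates` noisy copies of a ground-truth spectrum at each
#' noise level, retrieves the tissue parameters from each, and aggregates
#' the per-parameter relative errors (median and interquartile range).
#'
#' @param spectrum noise-free ground-truth [sfr_spectrum][synthesize_spectrum].
#' @param truth the generating [tissue_model()].
#' @param geometry an [sfr_geometry()].
#' @param noise_rms numeric vector of noise levels (fraction of spectrum
#'   RMS).
#' @param n_replicates noisy replicates per level.
#' @param n_starts multistart count per retrieval.
#' @param seed integer seed.
#' @param params forward-model parameters.
#' @return Data frame with one row per (noise level, parameter):
#'   `noise_rms`, `param`, `median_rel_error`, `q25`, `q75`.
#' @export
replicate_retrieval <- function(spectrum, truth, geometry, noise_rms = 0.01,
                                n_replicates = 25, n_starts = 50, seed,
                                params = NULL) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  rows <- list()
  for (nz in noise_rms) {
    errs <- matrix(NA_real_, n_replicates, 5,
                   dimnames = list(NULL, c("a", "b", "v_f_blood", "sO2",
                                           "psb_rmse")))
    for (r in seq_len(n_replicates)) {
      sseed <- seed + 7919L * r + round(1e5 * nz)
      noisy <- add_noise(spectrum, nz, seed = sseed)
      if (any(noisy$R <= 0)) noisy$R <- pmax(noisy$R, 1e-12)
      ret <- retrieve_properties(noisy, geometry, params = params,
                                 n_starts = n_starts, seed = sseed + 1L)
      m <- retrieval_metrics(ret, truth,
                             wavelengths = spectrum$wavelength_nm)
      errs[r, ] <- c(m$a, m$b, m$v_f_blood, m$sO2, m$psb_rmse)
    }
    for (p in colnames(errs)) {
      q <- stats::quantile(errs[, p], c(0.25, 0.5, 0.75), na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        noise_rms = nz, param = p, median_rel_error = q[[2]],
        q25 = q[[1]], q75 = q[[3]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
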