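#' Two-step fit of the semi-empirical reflectance model
#'
#' Fits the model constants to a reflectance dataset (as produced by
#' [dataset_sweep()] or simulated with the forward model) by relative
#' least squares: the residual for row `i` is
#' `(R_model_i - R_MC_i) / R_MC_i`, which weights the many orders of
#' magnitude of reflectance equally. The fit is sequential:
#' [fit_scattering_params()] estimates `(a1, a2, a3)` on the
#' absorption-free subset (`mu_a = 0`, where the absorption exponential is
#' identically 1), then [fit_absorption_params()] estimates `(b1, b2)` on
#' the full dataset with the scattering constants frozen. All parameters
#' are constrained positive. `fit_model()` runs both steps and attaches
#' approximate 95% confidence intervals (local linearization of the
#' residual Jacobian) and the error metrics of [error_metrics()].
#'
#' The dataset must contain a single (modality, NA) combination and the
#' columns `na`, `d_f_mm`, `mu_a_mm`, `mu_s_prime_mm`, `p_sb`, `R_MC`.
#'
#' @param dataset reflectance dataset (see Details).
#' @param geometry_modality modality of the dataset rows.
#' @param n_starts number of multistart initializations for the scattering
#'   step (log-spaced in `a2`).
#' @return `fit_model()`: an object of class `sfr_model_fit` with elements
#'   `params` ([sfr_model_params][model_params]), `ci95`, `objective`,
#'   `residuals`, `median_abs_rel_error`, `frac_within_10pct`.
#' @name model_fitting
NULL

fit_dataset_check <- function(dataset) {
  need <- c("na", "d_f_mm", "mu_a_mm", "mu_s_prime_mm", "p_sb", "R_MC")
  miss <- setdiff(need, names(dataset))
  if (length(miss))
    stop("dataset lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(dataset) == 0) stop("empty dataset", call. = FALSE)
  if (length(unique(dataset$na)) != 1L)
    stop("dataset must contain a single NA per fit", call. = FALSE)
  if (any(dataset$R_MC <= 0))
    stop("R_MC must be positive", call. = FALSE)
  invisible(dataset)
}

# model reflectance for parameter vectors, with precomputed diffuse part
model_R <- function(dataset, eta_c, r_diff, a1, a2, a3, b1 = 0, b2 = 1) {
  x <- a2 * (dataset$p_sb / (dataset$mu_s_prime_mm * dataset$d_f_mm)^2)^a3 *
    exp(b1 * (dataset$mu_a_mm / dataset$mu_s_prime_mm)^b2)
  (1 + x) * eta_c * a1 * r_diff
}

fit_precompute <- function(dataset, modality) {
  g0 <- sfr_geometry(modality, na = dataset$na[1], d_f = 1)
  eta_c <- collection_efficiency(dataset$na[1], g0$n_external)
  r_diff <- numeric(nrow(dataset))
  for (d in unique(dataset$d_f_mm)) {
    i <- dataset$d_f_mm == d
    r_diff[i] <- sfr_diffuse(dataset$mu_a_mm[i], dataset$mu_s_prime_mm[i],
                             d, g0$A)
  }
  list(eta_c = eta_c, r_diff = r_diff)
}

#' @rdname model_fitting
#' @export
fit_scattering_params <- function(dataset,
                                  geometry_modality = c("SFR", "iSFR"),
                                  n_starts = 8) {
  geometry_modality <- match.arg(geometry_modality)
  fit_dataset_check(dataset)
  dataset <- dataset[dataset$mu_a_mm == 0, , drop = FALSE]
  if (nrow(dataset) < 30)
    stop("the scattering step needs the absorption-free subset ",
         "(mu_a = 0) with at least 10 rows per parameter", call. = FALSE)
  pre <- fit_precompute(dataset, geometry_modality)
  resid_fn <- function(lp) {
    p <- exp(lp)
    model_R(dataset, pre$eta_c, pre$r_diff, p[1], p[2], p[3]) /
      dataset$R_MC - 1
  }
  a2_starts <- 10^seq(1, 5, length.out = n_starts)
  best <- NULL
  for (a2s in a2_starts) {
    fit <- minpack.lm::nls.lm(par = log(c(a1 = 1, a2 = a2s, a3 = 0.8)),
                              fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500, ftol = 1e-12, ptol = 1e-12))
    if (is.null(best) || fit$deviance < best$deviance -
        1e-12 * best$deviance ||
        (abs(fit$deviance - best$deviance) <= 1e-12 * best$deviance &&
         sum(fit$par^2) < sum(best$par^2)))
      best <- fit
  }
  if (is.null(best) || !is.finite(best$deviance))
    stop("scattering-parameter fit failed to converge", call. = FALSE)
  out <- exp(best$par)
  names(out) <- c("a1", "a2", "a3")
  attr(out, "objective") <- best$deviance
  attr(out, "fit") <- best
  out
}

#' @rdname model_fitting
#' @param a_params named vector `(a1, a2, a3)` from the scattering step.
#' @export
fit_absorption_params <- function(dataset, a_params,
                                  geometry_modality = c("SFR", "iSFR")) {
  geometry_modality <- match.arg(geometry_modality)
  fit_dataset_check(dataset)
  if (all(dataset$mu_a_mm == 0))
    stop("absorption step is ill-posed on a mu_a = 0 dataset: the ",
         "absorption exponential is identically 1", call. = FALSE)
  pre <- fit_precompute(dataset, geometry_modality)
  resid_fn <- function(lp) {
    p <- exp(lp)
    model_R(dataset, pre$eta_c, pre$r_diff, a_params[["a1"]],
            a_params[["a2"]], a_params[["a3"]], p[1], p[2]) /
      dataset$R_MC - 1
  }
  fit <- minpack.lm::nls.lm(par = log(c(b1 = 1.2, b2 = 0.6)), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (!is.finite(fit$deviance))
    stop("absorption-parameter fit failed to converge", call. = FALSE)
  out <- exp(fit$par)
  names(out) <- c("b1", "b2")
  attr(out, "objective") <- fit$deviance
  attr(out, "fit") <- fit
  out
}

# 95% CI half-widths from the log-parameter Jacobian, delta method
fit_ci95 <- function(fit, par_exp) {
  hess <- fit$hessian
  dof <- max(1, length(fit$fvec) - length(fit$par))
  s2 <- fit$deviance / dof
  cov_lp <- tryCatch(solve(hess) * s2, error = function(e) NULL)
  if (is.null(cov_lp)) return(rep(NA_real_, length(par_exp)))
  se_lp <- sqrt(pmax(0, diag(cov_lp)))
  # d(exp(lp)) = exp(lp) d(lp)
  stats::qt(0.975, dof) * se_lp * par_exp
}

#' @rdname model_fitting
#' @export
fit_model <- function(dataset, geometry_modality = c("SFR", "iSFR"),
                      n_starts = 8) {
  geometry_modality <- match.arg(geometry_modality)
  fit_dataset_check(dataset)
  a <- fit_scattering_params(dataset, geometry_modality, n_starts)
  b <- fit_absorption_params(dataset, a, geometry_modality)
  params <- structure(list(a1 = a[["a1"]], a2 = a[["a2"]], a3 = a[["a3"]],
                           b1 = b[["b1"]], b2 = b[["b2"]],
                           modality = geometry_modality,
                           na = dataset$na[1], source = "fitted",
                           interpolated = FALSE),
                      class = "sfr_model_params")
  ci_a <- fit_ci95(attr(a, "fit"), unname(a))
  ci_b <- fit_ci95(attr(b, "fit"), unname(b))
  met <- error_metrics(dataset, params)
  structure(list(params = params,
                 ci95 = c(a1 = ci_a[1], a2 = ci_a[2], a3 = ci_a[3],
                          b1 = ci_b[1], b2 = ci_b[2]),
                 objective = attr(b, "objective"),
                 residuals = met$residuals,
                 median_abs_rel_error = met$median_abs_rel_error,
                 frac_within_10pct = met$frac_within_10pct),
            class = "sfr_model_fit")
}

#' @export
print.sfr_model_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<sfr_model_fit %s NA=%g>\n", p$modality, p$na))
  for (f in c("a1", "a2", "a3", "b1", "b2"))
    cat(sprintf("  %s = %.4g (+/- %.2g)\n", f, p[[f]], x$ci95[[f]]))
  cat(sprintf("  median |rel err| = %.2f%%, within 10%%: %.1f%%\n",
              100 * x$median_abs_rel_error, 100 * x$frac_within_10pct))
  invisible(x)
}

#' Relative error metrics of model predictions against a dataset
#'
#' Computes, per dataset row, the relative residual
#' `(R_model - R_MC) / R_MC`, and summarizes it by the median absolute
#' relative error and the fraction of rows with absolute relative error
#' below 10%.
#'
#' @param dataset reflectance dataset (see [model_fitting]).
#' @param params an [sfr_model_params][model_params] object.
#' @return List with `median_abs_rel_error`, `frac_within_10pct` and the
#'   per-row `residuals` data frame.
#' @export
error_metrics <- function(dataset, params) {
  fit_dataset_check(dataset)
  stopifnot(inherits(params, "sfr_model_params"))
  pre <- fit_precompute(dataset, params$modality)
  r_model <- model_R(dataset, pre$eta_c, pre$r_diff, params$a1, params$a2,
                     params$a3, params$b1, params$b2)
  rel <- r_model / dataset$R_MC - 1
  res <- cbind(dataset, R_model = r_model, rel_error = rel)
  list(median_abs_rel_error = stats::median(abs(rel)),
       frac_within_10pct = mean(abs(rel) < 0.10),
       residuals = res)
}
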