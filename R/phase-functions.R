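#' Scattering phase-function specifications
#'
#' Constructors for the three analytic phase-function families used to model
#' single-scattering in soft tissue: the modified Henyey-Greenstein (MHG),
#' the two-term Henyey-Greenstein (TTHG) and the Reynolds-McCormick (RMC,
#' Gegenbauer-kernel) functions. A specification stores the family, its
#' parameters and a stable id; the density itself is evaluated with
#' [pf_pdf()].
#'
#' Parameter domains:
#' * MHG: `g_hg` in \[0, 1), `alpha` in \[0, 1\]. `p(theta) =
#'   alpha * HG(g_hg) + (1 - alpha) * 3 cos^2(theta) / (4 pi)`.
#' * TTHG: `alpha` in \[0, 1\], forward `g_f` in \[0, 1), backward `g_b` in
#'   (-1, 0\]. `p(theta) = alpha * HG(g_f) + (1 - alpha) * HG(g_b)`.
#' * RMC: `alpha > 0`, `g_r` in (0, 1). `p(theta) = K (1 + g_r^2 -
#'   2 g_r cos(theta))^-(alpha + 1)` with the closed-form normalization
#'   `K = alpha g_r / pi * (1 - g_r^2)^(2 alpha) / ((1 + g_r)^(2 alpha) -
#'   (1 - g_r)^(2 alpha))`.
#'
#' All densities are per steradian and normalized so that
#' `2 pi * integral(p(theta) sin(theta), 0, pi) = 1`.
#'
#' @param g_hg,alpha,g_f,g_b,g_r family parameters, see Details.
#' @param id optional stable label; a default is derived from the parameters.
#' @return An object of class `pf_spec`: a list with elements `family`,
#'   `params` (named numeric vector) and `id`.
#' @examples
#' pf <- pf_tthg(alpha = 0.9, g_f = 0.9, g_b = -0.1)
#' pf_moments(pf)
#' @seealso [pf_pdf()], [pf_moments()], [pf_psb()], [pf_grid()]
#' @export
pf_mhg <- function(g_hg, alpha, id = NULL) {
  stopifnot(is.numeric(g_hg), is.numeric(alpha))
  if (g_hg < 0 || g_hg >= 1)
    stop("MHG parameter 'g_hg' must lie in [0, 1)", call. = FALSE)
  if (alpha < 0 || alpha > 1)
    stop("MHG parameter 'alpha' must lie in [0, 1]", call. = FALSE)
  new_pf_spec("MHG", c(g_hg = g_hg, alpha = alpha), id)
}

#' @rdname pf_mhg
#' @export
pf_tthg <- function(alpha, g_f, g_b, id = NULL) {
  stopifnot(is.numeric(alpha), is.numeric(g_f), is.numeric(g_b))
  if (alpha < 0 || alpha > 1)
    stop("TTHG parameter 'alpha' must lie in [0, 1]", call. = FALSE)
  if (g_f < 0 || g_f >= 1)
    stop("TTHG parameter 'g_f' must lie in [0, 1)", call. = FALSE)
  if (g_b > 0 || g_b <= -1)
    stop("TTHG parameter 'g_b' must lie in (-1, 0]", call. = FALSE)
  new_pf_spec("TTHG", c(alpha = alpha, g_f = g_f, g_b = g_b), id)
}

#' @rdname pf_mhg
#' @export
pf_rmc <- function(alpha, g_r, id = NULL) {
  stopifnot(is.numeric(alpha), is.numeric(g_r))
  if (alpha <= 0)
    stop("RMC parameter 'alpha' must be positive", call. = FALSE)
  if (g_r <= 0 || g_r >= 1)
    stop("RMC parameter 'g_r' must lie in (0, 1)", call. = FALSE)
  new_pf_spec("RMC", c(alpha = alpha, g_r = g_r), id)
}

new_pf_spec <- function(family, params, id = NULL) {
  if (is.null(id))
    id <- paste0(family, "_", paste(formatC(params, format = "g", digits = 6),
                                    collapse = "_"))
  structure(list(family = family, params = params, id = id),
            class = "pf_spec")
}

#' @export
print.pf_spec <- function(x, ...) {
  m <- pf_moments(x)
  cat(sprintf("<pf_spec %s> %s\n", x$family,
              paste(names(x$params), signif(x$params, 4),
                    sep = " = ", collapse = ", ")))
  cat(sprintf("  g1 = %.4f, g2 = %.4f, p_sb = %.3g\n", m$g1, m$g2,
              pf_psb(x)))
  invisible(x)
}

# single-term Henyey-Greenstein density [sr^-1], vectorized over theta
hg_pdf <- function(theta, g) {
  (1 - g^2) / (4 * pi * (1 + g^2 - 2 * g * cos(theta))^1.5)
}

#' Evaluate a phase-function density
#'
#' Returns the scattering probability density per steradian at polar
#' deflection angle `theta`.
#'
#' @param spec a [pf_spec][pf_mhg] object.
#' @param theta deflection angle(s) in radians, in \[0, pi\].
#' @return Numeric vector of densities (per steradian).
#' @export
pf_pdf <- function(spec, theta) {
  stopifnot(inherits(spec, "pf_spec"))
  if (any(theta < 0 | theta > pi))
    stop("'theta' must lie in [0, pi]", call. = FALSE)
  p <- spec$params
  switch(spec$family,
    MHG = p[["alpha"]] * hg_pdf(theta, p[["g_hg"]]) +
      (1 - p[["alpha"]]) * 3 * cos(theta)^2 / (4 * pi),
    TTHG = p[["alpha"]] * hg_pdf(theta, p[["g_f"]]) +
      (1 - p[["alpha"]]) * hg_pdf(theta, p[["g_b"]]),
    RMC = {
      a <- p[["alpha"]]; g <- p[["g_r"]]
      K <- a * g / pi * (1 - g^2)^(2 * a) /
        ((1 + g)^(2 * a) - (1 - g)^(2 * a))
      K * (1 + g^2 - 2 * g * cos(theta))^(-(a + 1))
    },
    stop("unknown phase-function family: ", spec$family, call. = FALSE))
}

# adaptive quadrature of 2*pi*f(theta)*p(theta)*sin(theta) over [0, pi].
# Forward-peaked densities are split at 5 degrees to protect accuracy.
pf_quad <- function(spec, f = function(theta) 1, rel.tol = 1e-10) {
  integrand <- function(theta) {
    2 * pi * f(theta) * pf_pdf(spec, theta) * sin(theta)
  }
  split <- 5 * pi / 180
  i1 <- stats::integrate(integrand, 0, split, rel.tol = rel.tol,
                         subdivisions = 200L)
  i2 <- stats::integrate(integrand, split, pi, rel.tol = rel.tol,
                         subdivisions = 200L)
  i1$value + i2$value
}

#' Angular moments of a phase function
#'
#' Computes the first and second Legendre moments by adaptive quadrature:
#' `g1 = <P1(cos theta)> = <cos theta>` (the anisotropy factor `g`) and
#' `g2 = <P2(cos theta)>` with `P2(x) = (3 x^2 - 1) / 2`.
#'
#' @param spec a [pf_spec][pf_mhg] object.
#' @return A list with elements `g1`, `g2` and `norm` (the numerically
#'   evaluated normalization integral, equal to 1 for a valid density).
#' @export
pf_moments <- function(spec) {
  stopifnot(inherits(spec, "pf_spec"))
  norm <- pf_quad(spec)
  if (abs(norm - 1) > 1e-6)
    warning(sprintf(
      "phase function '%s' normalization off by %.2g; moments renormalized",
      spec$id, norm - 1))
  g1 <- pf_quad(spec, function(th) cos(th)) / norm
  g2 <- pf_quad(spec, function(th) (3 * cos(th)^2 - 1) / 2) / norm
  list(g1 = g1, g2 = g2, norm = norm)
}

#' Semi-ballistic phase-function descriptor p_sb
#'
#' The semi-ballistic descriptor is the probability of a single backward
#' scattering within `theta_back` of 180 degrees, divided by the probability
#' of not scattering within `theta_fwd` of the forward direction:
#' `p_sb = p_b(theta_back) / (1 - p_f(theta_fwd))` with
#' `p_b = 2 pi * integral(p sin, 180 - theta_back, 180)` and
#' `p_f = 2 pi * integral(p sin, 0, theta_fwd)`. The defaults (1 and 23
#' degrees) are the angular limits that minimize the spread of reflectance
#' for a given descriptor value in subdiffuse fiber geometries.
#'
#' @param spec a [pf_spec][pf_mhg] object.
#' @param theta_back,theta_fwd angular integration limits in degrees.
#' @return `p_sb` (dimensionless), or the full components when
#'   `components = TRUE`.
#' @param components return `p_b` and `p_f` alongside `p_sb`?
#' @export
pf_psb <- function(spec, theta_back = 1, theta_fwd = 23, components = FALSE) {
  stopifnot(inherits(spec, "pf_spec"))
  if (theta_back <= 0 || theta_back >= 90 || theta_fwd <= 0 || theta_fwd >= 90)
    stop("integration limits must lie in (0, 90) degrees", call. = FALSE)
  norm <- pf_quad(spec)
  if (abs(norm - 1) > 1e-6)
    warning(sprintf(
      "phase function '%s' normalization off by %.2g; p_sb renormalized",
      spec$id, norm - 1))
  tb <- theta_back * pi / 180
  tf <- theta_fwd * pi / 180
  integrand <- function(th) 2 * pi * pf_pdf(spec, th) * sin(th)
  p_b <- stats::integrate(integrand, pi - tb, pi, rel.tol = 1e-10)$value / norm
  p_f <- stats::integrate(integrand, 0, tf, rel.tol = 1e-10)$value / norm
  if (p_f >= 1 - 1e-12)
    stop("degenerate phase function: forward probability p_f >= 1",
         call. = FALSE)
  p_sb <- p_b / (1 - p_f)
  if (components) list(p_sb = p_sb, p_b = p_b, p_f = p_f) else p_sb
}

#' Enumerate and filter the phase-function grid
#'
#' Builds the full grid of candidate phase functions over the three families
#' and retains those with a biologically plausible anisotropy. Grid ranges
#' ("N steps" are N evenly spaced values including both endpoints):
#' * MHG: `g_hg` 10 steps over \[0.01, 0.95\]; `alpha` 10 steps over
#'   \[0.01, 0.99\].
#' * TTHG: `alpha` 3 steps over \[0.5, 0.9\] plus 5 steps over
#'   \[0.91, 0.99\]; `g_f` 10 steps over \[0.05, 0.95\]; `g_b` 5 steps over
#'   \[-0.95, -0.05\].
#' * RMC: `alpha` 10 steps over \[0.01, 2.5\]; `g_r` 10 steps over
#'   \[0.01, 0.95 - 0.2 alpha\] for each `alpha`.
#'
#' Two filtering rules are available. The default `"g1_band"` keeps
#' combinations with `0.5 <= g1 <= 0.95`, the anisotropy band typical of
#' soft tissue; it reproduces the published survivor counts for the MHG (15)
#' and RMC (46) families exactly. The alternative `"g1_g2"` excludes
#' combinations with `g1 > 0.95` or `g2 < 0.5`.
#'
#' @param filter filtering rule, `"g1_band"` (default) or `"g1_g2"`.
#' @param keep_all if `TRUE`, return the full grid with a logical `kept`
#'   column instead of dropping excluded rows.
#' @return A data frame with columns `family`, `id`, the family parameters
#'   (`alpha`, `g_hg`, `g_f`, `g_b`, `g_r`; unused ones `NA`), `g1`, `g2`,
#'   `p_sb` and (when `keep_all`) `kept`.
#' @export
pf_grid <- function(filter = c("g1_band", "g1_g2"), keep_all = FALSE) {
  filter <- match.arg(filter)
  specs <- c(pf_grid_specs_mhg(), pf_grid_specs_tthg(), pf_grid_specs_rmc())
  rows <- lapply(specs, function(s) {
    m <- pf_moments(s)
    data.frame(family = s$family, id = s$id,
               alpha = pf_param(s, "alpha"), g_hg = pf_param(s, "g_hg"),
               g_f = pf_param(s, "g_f"), g_b = pf_param(s, "g_b"),
               g_r = pf_param(s, "g_r"),
               g1 = m$g1, g2 = m$g2, p_sb = pf_psb(s),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  grid$kept <- switch(filter,
    g1_band = grid$g1 >= 0.5 & grid$g1 <= 0.95,
    g1_g2 = !(grid$g1 > 0.95 | grid$g2 < 0.5))
  if (!keep_all) {
    grid <- grid[grid$kept, , drop = FALSE]
    grid$kept <- NULL
    rownames(grid) <- NULL
  }
  grid
}

pf_param <- function(spec, name) {
  if (name %in% names(spec$params)) unname(spec$params[[name]]) else NA_real_
}

pf_grid_specs_mhg <- function() {
  g <- expand.grid(g_hg = seq(0.01, 0.95, length.out = 10),
                   alpha = seq(0.01, 0.99, length.out = 10))
  mapply(function(gh, a) pf_mhg(gh, a), g$g_hg, g$alpha, SIMPLIFY = FALSE)
}

pf_grid_specs_tthg <- function() {
  alphas <- c(seq(0.5, 0.9, length.out = 3), seq(0.91, 0.99, length.out = 5))
  g <- expand.grid(alpha = alphas,
                   g_f = seq(0.05, 0.95, length.out = 10),
                   g_b = seq(-0.95, -0.05, length.out = 5))
  mapply(function(a, f, b) pf_tthg(a, f, b), g$alpha, g$g_f, g$g_b,
         SIMPLIFY = FALSE)
}

pf_grid_specs_rmc <- function() {
  alphas <- seq(0.01, 2.5, length.out = 10)
  specs <- list()
  for (a in alphas) {
    for (g in seq(0.01, 0.95 - 0.2 * a, length.out = 10))
      specs[[length(specs) + 1L]] <- pf_rmc(a, g)
  }
  specs
}

#' Reconstruct phase-function specs from a grid table
#'
#' Inverse of the tabular representation written by [pf_grid()]: turns rows
#' back into a list of [pf_spec][pf_mhg] objects.
#'
#' @param grid a data frame as returned by [pf_grid()].
#' @return List of `pf_spec` objects.
#' @export
pf_from_grid <- function(grid) {
  lapply(seq_len(nrow(grid)), function(i) {
    r <- grid[i, ]
    switch(as.character(r$family),
      MHG = pf_mhg(r$g_hg, r$alpha, id = r$id),
      TTHG = pf_tthg(r$alpha, r$g_f, r$g_b, id = r$id),
      RMC = pf_rmc(r$alpha, r$g_r, id = r$id),
      stop("unknown family in grid: ", r$family, call. = FALSE))
  })
}

#' Tabulated inverse-CDF sampler for scattering angles
#'
#' Builds a monotone inverse-CDF lookup table for the deflection-angle
#' density `p(theta) sin(theta)` and draws reproducible samples from it.
#' The table holds `cos(theta)` at `n_nodes` equally spaced quantiles and is
#' interpolated linearly; it is also the sampling table consumed by the
#' Monte Carlo transport engine.
#'
#' @param spec a [pf_spec][pf_mhg] object.
#' @param n_nodes number of quantile nodes (default `2^15`).
#' @return `pf_cdf_table()`: a list with `u` (quantiles) and `cos_theta`;
#'   `pf_sample_theta()`: numeric vector of angles in radians.
#' @export
pf_cdf_table <- function(spec, n_nodes = 2^15) {
  stopifnot(inherits(spec, "pf_spec"))
  # fine theta grid, denser near 0 to resolve forward peaks
  theta <- sort(unique(c(0, pi * (seq_len(4L * n_nodes) / (4L * n_nodes))^2,
                         pi)))
  dens <- 2 * pi * pf_pdf(spec, theta) * sin(theta)
  cdf <- cumsum(c(0, diff(theta) * (dens[-1] + dens[-length(dens)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  u <- seq(0, 1, length.out = n_nodes)
  # invert by monotone interpolation (cdf is nondecreasing in theta)
  keep <- c(TRUE, diff(cdf) > 0)
  th_u <- stats::approx(cdf[keep], theta[keep], xout = u, rule = 2)$y
  list(u = u, cos_theta = cos(th_u))
}

#' @rdname pf_cdf_table
#' @param n number of samples.
#' @param seed integer seed; mandatory for reproducibility.
#' @param table optional precomputed [pf_cdf_table()].
#' @export
pf_sample_theta <- function(spec, n, seed, table = NULL) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is required: unseeded sampling is not reproducible",
         call. = FALSE)
  if (is.null(table)) table <- pf_cdf_table(spec)
  u <- withr_seed_runif(n, seed)
  ct <- stats::approx(table$u, table$cos_theta, xout = u, rule = 2)$y
  acos(pmin(1, pmax(-1, ct)))
}

# draw n uniforms under a local, restored RNG state
withr_seed_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n)
}
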