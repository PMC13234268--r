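#' Extrapolated-boundary coefficient
#'
#' The boundary coefficient `A` entering the extrapolated-boundary distance
#' `z_b = 2 A / (3 mu_s')` of the diffusion dipole. Values are tabulated for
#' the two interfaces relevant to fiber reflectance: a glass-tissue contact
#' interface (n = 1.45 / 1.35, conventional SFR) and an air-tissue interface
#' (n = 1.00 / 1.35, imaging SFR). No general formula in the refractive
#' indices is provided.
#'
#' @param interface `"glass_tissue"` or `"air_tissue"`.
#' @return The dimensionless boundary coefficient.
#' @export
boundary_coefficient <- function(interface) {
  if (length(interface) != 1L || !interface %in% c("glass_tissue", "air_tissue"))
    stop("unsupported interface '", paste(interface, collapse = ","),
         "': only 'glass_tissue' (n = 1.45/1.35) and 'air_tissue' ",
         "(n = 1.00/1.35) are tabulated", call. = FALSE)
  c(glass_tissue = 1.027, air_tissue = 2.6355)[[interface]]
}

#' Radial diffuse reflectance of a pencil beam
#'
#' Steady-state diffuse reflectance at radial distance `rho` from a
#' pencil-beam source on a semi-infinite medium, using the dipole solution
#' with extrapolated boundary condition:
#' source depth `z0 = 1 / mu_s'`, image distance `z0 + 2 z_b` with
#' `z_b = 2 A / (3 mu_s')`, transport albedo `a' = mu_s' / (mu_s' + mu_a)`
#' and effective attenuation `mu_eff = sqrt(3 mu_a mu_s')`.
#'
#' @param rho radial distance(s) from the source, mm.
#' @param mu_a absorption coefficient, mm^-1 (>= 0).
#' @param mu_s_prime reduced scattering coefficient, mm^-1 (> 0).
#' @param A boundary coefficient, see [boundary_coefficient()].
#' @return Reflectance per mm^2, same length as `rho`.
#' @export
diffuse_radial <- function(rho, mu_a, mu_s_prime, A) {
  if (any(mu_s_prime <= 0)) stop("'mu_s_prime' must be > 0", call. = FALSE)
  if (any(mu_a < 0)) stop("'mu_a' must be >= 0", call. = FALSE)
  if (any(rho < 0)) stop("'rho' must be >= 0", call. = FALSE)
  ap <- mu_s_prime / (mu_s_prime + mu_a)
  z0 <- 1 / mu_s_prime
  zb <- 2 * A / (3 * mu_s_prime)
  mu_eff <- sqrt(3 * mu_a * mu_s_prime)
  r1 <- sqrt(z0^2 + rho^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
  ap / (4 * pi) * (
    z0 * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / r1^2 +
      (z0 + 2 * zb) * (mu_eff + 1 / r2) * exp(-mu_eff * r2) / r2^2)
}

#' Distance density between two uniform points on a disk
#'
#' Probability density of the distance `rho` between two independent points
#' drawn uniformly on a disk of diameter `d_f`:
#' `p(rho) = 16 rho / (pi d_f^2) * acos(rho / d_f)
#'   - 16 / (pi d_f) * (rho / d_f)^2 * sqrt(1 - (rho / d_f)^2)`.
#' Zero outside \[0, d_f\].
#'
#' @param rho distance(s), mm.
#' @param d_f disk diameter, mm (> 0).
#' @return Density per mm.
#' @export
disk_distance_pdf <- function(rho, d_f) {
  if (d_f <= 0) stop("'d_f' must be > 0", call. = FALSE)
  t <- rho / d_f
  out <- numeric(length(rho))
  ok <- t >= 0 & t <= 1
  tt <- t[ok]
  out[ok] <- 16 * rho[ok] / (pi * d_f^2) * acos(tt) -
    16 / (pi * d_f) * tt^2 * sqrt(pmax(0, 1 - tt^2))
  out
}

# composite Gauss-Legendre nodes/weights on [0, 1] (memoized per n)
gl_nodes_01 <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      # Golub-Welsch from the Jacobi matrix of Legendre polynomials
      i <- seq_len(n - 1)
      b <- i / sqrt(4 * i^2 - 1)
      J <- diag(0, n)
      J[cbind(i, i + 1)] <- b
      J[cbind(i + 1, i)] <- b
      e <- eigen(J, symmetric = TRUE)
      x <- e$values
      w <- 2 * e$vectors[1, ]^2
      cache[[key]] <<- list(x = (x + 1) / 2, w = w / 2)
    }
    cache[[key]]
  }
})

#' Diffuse reflectance collected by an overlapping source-detector disk
#'
#' The diffuse component of the (i)SFR signal: the radial diffuse
#' reflectance integrated against the disk point-pair distance density,
#' `R = (pi / 4) d_f^2 * integral(R_diffuse(rho) p(rho, d_f), 0, d_f)`.
#' Geometrically this is the probability that a photon re-emitted at radial
#' displacement `rho` from a uniformly distributed entry point lands inside
#' the illumination/collection disk of diameter `d_f`.
#'
#' The quadrature is composite Gauss-Legendre with panels concentrated near
#' `rho = 0`, where the dipole kernel is peaked on the scale `z0 = 1/mu_s'`;
#' `method = "adaptive"` uses `stats::integrate` instead and serves as an
#' accuracy reference.
#'
#' @inheritParams diffuse_radial
#' @param d_f spot (fiber) diameter, mm.
#' @param method `"gauss"` (fast, vectorized over `mu_a`/`mu_s_prime`) or
#'   `"adaptive"`.
#' @return Dimensionless reflectance; vectorized over `mu_a`/`mu_s_prime`
#'   (recycled to a common length) for `method = "gauss"`.
#' @export
sfr_diffuse <- function(mu_a, mu_s_prime, d_f, A, method = c("gauss", "adaptive")) {
  method <- match.arg(method)
  if (d_f <= 0) stop("'d_f' must be > 0", call. = FALSE)
  if (method == "adaptive") {
    stopifnot(length(mu_a) == 1L, length(mu_s_prime) == 1L)
    val <- stats::integrate(function(rho)
      diffuse_radial(rho, mu_a, mu_s_prime, A) * disk_distance_pdf(rho, d_f),
      0, d_f, rel.tol = 1e-10, subdivisions = 500L)$value
    return(pi / 4 * d_f^2 * val)
  }
  n <- max(length(mu_a), length(mu_s_prime))
  mu_a <- rep_len(mu_a, n)
  mu_s_prime <- rep_len(mu_s_prime, n)
  gl <- gl_nodes_01(24)
  # panel breaks per column: [0, c1], [c1, c2], [c2, d_f] with c1 ~ 5 z0
  z0 <- 1 / mu_s_prime
  c1 <- pmin(5 * z0, d_f / 3)
  c2 <- pmin(25 * z0, 2 * d_f / 3)
  acc <- numeric(n)
  lo <- rep(0, n)
  for (brk in list(c1, c2, rep(d_f, n))) {
    len <- brk - lo
    # nodes: n_nodes x n matrix
    rho <- outer(gl$x, len) + rep(lo, each = length(gl$x))
    kern <- diffuse_radial(as.vector(rho),
                           rep(mu_a, each = length(gl$x)),
                           rep(mu_s_prime, each = length(gl$x)), A) *
      disk_distance_pdf(as.vector(rho), d_f)
    acc <- acc + as.vector(crossprod(matrix(kern, nrow = length(gl$x)),
                                     gl$w)) * len
    lo <- brk
  }
  pi / 4 * d_f^2 * acc
}
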