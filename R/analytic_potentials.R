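# Packaged analytic test potentials with quadrature-computed free-energy
# references. These are the ground-truth targets for validating the
# metadynamics engine and the WHAM estimator.

#' Construct an analytic test potential
#'
#' Available kinds:
#' * `double_well_1d`: U(x) = a (x^2 - 1)^2
#' * `asymmetric_double_well_1d`: U(x) = a (x^2 - 1)^2 + b x
#' * `two_basin_2d`: U(x, y) = a (x^2 - 1)^2 + ky y^2 / 2 + c x y
#'
#' At construction the basin free-energy difference (left basin x < x*
#' vs right basin, x* the barrier top), the barrier height and -- for
#' the 2D kind -- both one-dimensional marginal free-energy profiles
#' are computed by quadrature at the stated kT and stored as
#' references.
#'
#' @param kind potential kind.
#' @param params named list overriding the default parameters
#'   (`a`, `b`, `ky`, `c`).
#' @param kT thermal energy (kJ/mol) at which references are computed.
#' @return object of class `AnalyticPotential` with elements `U`
#'   (vectorised energy), `grad`, `dim`, `domain` and `reference`.
#' @export
make_analytic_potential <- function(kind = c("double_well_1d",
                                             "asymmetric_double_well_1d",
                                             "two_basin_2d"),
                                    params = list(), kT = 2.744) {
  kind <- match.arg(kind)
  p <- utils::modifyList(switch(kind,
    double_well_1d = list(a = 5, b = 0),
    asymmetric_double_well_1d = list(a = 5, b = 1),
    two_basin_2d = list(a = 4, b = 0, ky = 2, c = 1)), params)
  if (!is.numeric(kT) || kT <= 0) stop("invalid kT")

  if (kind %in% c("double_well_1d", "asymmetric_double_well_1d")) {
    U <- function(x) p$a * (x^2 - 1)^2 + p$b * x
    grad <- function(x) 4 * p$a * x * (x^2 - 1) + p$b
    domain <- list(c(-2.2, 2.2))
    # barrier top between the two minima
    xstar <- stats::optimize(function(x) -U(x), c(-0.9, 0.9))$minimum
    za <- stats::integrate(function(x) exp(-U(x) / kT), domain[[1]][1], xstar,
                           rel.tol = 1e-12, abs.tol = 1e-13)$value
    zb <- stats::integrate(function(x) exp(-U(x) / kT), xstar, domain[[1]][2],
                           rel.tol = 1e-12, abs.tol = 1e-13)$value
    xa <- stats::optimize(U, c(domain[[1]][1], xstar))$minimum
    xb <- stats::optimize(U, c(xstar, domain[[1]][2]))$minimum
    ref <- list(kT = kT, basin_split = xstar,
                dF = -kT * log(zb / za),            # F(right) - F(left)
                barrier = U(xstar) - min(U(xa), U(xb)),
                minima = c(xa, xb))
    obj <- list(kind = kind, params = p, dim = 1L, U = U, grad = grad,
                domain = domain, reference = ref)
  } else {
    U <- function(x, y) p$a * (x^2 - 1)^2 + 0.5 * p$ky * y^2 + p$c * x * y
    Uxy <- function(xy) U(xy[1L], xy[2L])
    grad <- function(xy) c(4 * p$a * xy[1L] * (xy[1L]^2 - 1) + p$c * xy[2L],
                           p$ky * xy[2L] + p$c * xy[1L])
    domain <- list(c(-2.2, 2.2), c(-3.5, 3.5))
    # marginal free energies on fine grids by Simpson quadrature; the y
    # integration range extends past the sampling domain so truncation
    # does not bias the x-marginal
    nx <- 801L; ny <- 2401L
    xs <- seq(domain[[1]][1], domain[[1]][2], length.out = nx)
    ys <- seq(-6, 6, length.out = ny)
    wy <- simpson_weights(ny) * (ys[2L] - ys[1L])
    wx <- simpson_weights(nx) * (xs[2L] - xs[1L])
    bz <- exp(-outer(xs, ys, U) / kT)       # nx x ny Boltzmann weights
    px <- as.vector(bz %*% wy)
    py <- as.vector(wx %*% bz)
    fx <- -kT * log(px); fx <- fx - min(fx)
    fy <- -kT * log(py); fy <- fy - min(fy)
    ref <- list(kT = kT,
                marginal_x = list(x = xs, F = fx),
                marginal_y = list(x = ys, F = fy))
    obj <- list(kind = kind, params = p, dim = 2L, U = Uxy, grad = grad,
                domain = domain, reference = ref)
  }
  class(obj) <- "AnalyticPotential"
  obj
}

simpson_weights <- function(n) {
  stopifnot(n %% 2L == 1L)
  w <- rep(c(2, 4), length.out = n)
  w[1L] <- 1; w[n] <- 1
  w / 3
}

#' Basin free-energy difference of a 1D profile by Boltzmann integration
#'
#' Integrates exp(-F/kT) on each side of the split point and returns
#' -kT log(Z_right / Z_left), the same functional the analytic
#' references use.
#'
#' @param x grid, `F` free energy on the grid (kJ/mol).
#' @param split basin boundary.
#' @param kT thermal energy (kJ/mol).
#' @export
profile_basin_dF <- function(x, F, split, kT) {
  ok <- is.finite(F)
  x <- x[ok]; F <- F[ok]
  n <- length(x)  # trapezoidal weights on a possibly irregular grid
  w <- numeric(n)
  w[1L] <- (x[2L] - x[1L]) / 2
  w[n] <- (x[n] - x[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  za <- sum(w[x < split] * exp(-F[x < split] / kT))
  zb <- sum(w[x >= split] * exp(-F[x >= split] / kT))
  -kT * log(zb / za)
}

#' Barrier height of a 1D free-energy profile
#'
#' Maximum of the profile between the two flanking minima, relative to
#' the deeper minimum, evaluated in a window around the split point.
#'
#' @inheritParams profile_basin_dF
#' @export
profile_barrier <- function(x, F, split, kT) {
  ok <- is.finite(F)
  x <- x[ok]; F <- F[ok]
  fa <- min(F[x < split]); fb <- min(F[x >= split])
  # barrier: max in the inter-minimum region
  ia <- which.min(F + ifelse(x < split, 0, Inf))
  ib <- which.min(F + ifelse(x >= split, 0, Inf))
  sel <- seq(min(ia, ib), max(ia, ib))
  max(F[sel]) - min(fa, fb)
}
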