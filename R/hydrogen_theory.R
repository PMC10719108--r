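#' Hydrogen 1s electron density
#'
#' \eqn{\rho(r) = \frac{1}{\pi a_0^3} e^{-2r/a_0}} with \eqn{a_0} the Bohr
#' radius; integrates to one electron.
#'
#' @param r radius from the density centre in A (non-negative).
#' @param a0 Bohr radius in A.
#' @return density in e/A^3.
#' @export
density_1s <- function(r, a0 = .mx_bohr) {
  if (any(r < 0)) stop("r must be non-negative")
  exp(-2 * r / a0) / (pi * a0^3)
}

#' Coulomb potential of the unsmeared 1s cloud
#'
#' Closed form of \eqn{\int \rho(r')/|r - r'| d^3r'} for the 1s density:
#' \eqn{\frac{1}{r}\left(1 - e^{-2r/a_0}(1 + r/a_0)\right)}, with limit
#' \eqn{1/a_0} at r = 0.  Units e/(4 pi eps0 A).
#'
#' @inheritParams density_1s
#' @export
potential_1s <- function(r, a0 = .mx_bohr) {
  if (any(r < 0)) stop("r must be non-negative")
  out <- numeric(length(r))
  small <- r < 1e-10
  out[small] <- 1 / a0
  rr <- r[!small]
  out[!small] <- (1 - exp(-2 * rr / a0) * (1 + rr / a0)) / rr
  out
}

# Radial convolution of a spherically symmetric function f(r) with an
# isotropic Gaussian of per-axis variance u2:
#   (f * G)(r) = 1/(r sqrt(2 pi u2)) Int_0^inf r' f(r')
#                [exp(-(r-r')^2 / 2u2) - exp(-(r+r')^2 / 2u2)] dr'
# with the analytic r -> 0 limit.  `upper` bounds the quadrature range.
smear_radial <- function(f, r, u2, upper = NULL, rel.tol = 1e-10) {
  if (u2 < 0) stop("variance must be non-negative")
  if (u2 == 0) return(f(r))
  s <- sqrt(u2)
  if (is.null(upper)) upper <- max(r) + 12 * s + 5
  one <- function(ri) {
    if (ri < 1e-8) {
      g <- function(rp) rp^2 * f(rp) * exp(-rp^2 / (2 * u2))
      return(stats::integrate(g, 0, upper, rel.tol = rel.tol,
                              subdivisions = 400L)$value *
               sqrt(2 / pi) / s^3)
    }
    g <- function(rp) rp * f(rp) *
      (exp(-(ri - rp)^2 / (2 * u2)) - exp(-(ri + rp)^2 / (2 * u2)))
    stats::integrate(g, 0, upper, rel.tol = rel.tol,
                     subdivisions = 400L)$value / (ri * sqrt(2 * pi) * s)
  }
  vapply(r, one, numeric(1))
}

#' Thermally smeared 1s density and potentials
#'
#' Convolution of the 1s model with an isotropic Gaussian of per-axis
#' variance \eqn{\langle u^2\rangle = B / 8\pi^2} (the Fourier transform of
#' the Debye-Waller factor).  The smeared point-charge potential has the
#' closed form \eqn{\mathrm{erf}(r/\sqrt{2\langle u^2\rangle})/r}; the
#' smeared cloud terms use adaptive radial quadrature of the convolution
#' integral.
#'
#' @param r radius in A.
#' @param u2 per-axis mean-square displacement in A^2.
#' @param a0 Bohr radius in A.
#' @name smeared-hydrogen
NULL

#' @rdname smeared-hydrogen
#' @export
density_1s_smeared <- function(r, u2, a0 = .mx_bohr) {
  smear_radial(function(x) density_1s(x, a0), r, u2)
}

#' @rdname smeared-hydrogen
#' @export
potential_1s_smeared <- function(r, u2, a0 = .mx_bohr) {
  smear_radial(function(x) potential_1s(x, a0), r, u2)
}

#' @rdname smeared-hydrogen
#' @export
potential_point_smeared <- function(r, u2) {
  if (u2 < 0) stop("variance must be non-negative")
  if (u2 == 0) {
    if (any(r == 0)) stop("unsmeared point-nucleus potential diverges at r = 0")
    return(1 / r)
  }
  out <- numeric(length(r))
  small <- r < 1e-10
  out[small] <- sqrt(2 / (pi * u2))
  rr <- r[!small]
  out[!small] <- .mx_erf(rr / sqrt(2 * u2)) / rr
  out
}

.mx_erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Hydrogen bond model
#'
#' Geometry and thermal parameters of the hydrogen model along an X-H bond:
#' the nucleus sits at `nucleus` A from the parent atom, the 1s electron
#' cloud is centred at `cloud` A (the X-ray peak position), and both are
#' smeared with isotropic displacement `B` (A^2).
#'
#' @param nucleus nuclear distance from the parent atom along the bond, A.
#' @param cloud electron-cloud centre distance, A.
#' @param B isotropic displacement parameter, A^2.
#' @param a0 Bohr radius, A.
#' @param z_nuclear nuclear charge (1 for hydrogen).
#' @return object of class `hydrogen_bond_model`.
#' @export
hydrogen_bond_model <- function(nucleus = 1.083, cloud = 0.930, B = 6,
                                a0 = .mx_bohr, z_nuclear = 1) {
  stopifnot(nucleus >= 0, cloud >= 0, B >= 0, a0 > 0)
  structure(list(nucleus = nucleus, cloud = cloud, B = B, a0 = a0,
                 z_nuclear = z_nuclear, u2 = u2_from_b(B)),
            class = "hydrogen_bond_model")
}

#' @export
print.hydrogen_bond_model <- function(x, ...) {
  cat(sprintf(
    "<hydrogen_bond_model> nucleus %.3f A, cloud %.3f A, B %.2f A^2\n",
    x$nucleus, x$cloud, x$B))
  invisible(x)
}

#' 1-D bond profile container
#'
#' @param offsets strictly increasing offsets along the bond axis (A, from
#'   the parent atom).
#' @param values profile values at the offsets.
#' @param units units tag.
#' @return object of class `bond_profile` with the interpolated peak
#'   (`peak_offset`, `peak_value`, `peak_interior`) attached.
#' @export
bond_profile <- function(offsets, values, units = "potential") {
  stopifnot(length(offsets) == length(values), all(diff(offsets) > 0))
  p <- structure(list(offsets = offsets, values = values, units = units),
                 class = "bond_profile")
  pk <- tryCatch(find_peak(p), error = function(e) NULL)
  p$peak_offset <- if (is.null(pk)) NA_real_ else pk$offset
  p$peak_value <- if (is.null(pk)) NA_real_ else pk$value
  p$peak_interior <- if (is.null(pk)) FALSE else pk$interior
  p
}

#' @export
print.bond_profile <- function(x, ...) {
  cat(sprintf("<bond_profile> %d samples [%.3f, %.3f] A (%s), peak %.4f A\n",
              length(x$offsets), min(x$offsets), max(x$offsets), x$units,
              x$peak_offset))
  invisible(x)
}

#' Coulomb-potential profile along the bond
#'
#' Exact line section of the 3-D superposition
#' \eqn{\phi(x) = Z_{nuc}\,g_{pt}(|x - x_{nuc}|) - g_{1s}(|x - x_{cloud}|)}
#' where each term is the (optionally thermally smeared) spherically
#' symmetric potential about its own centre.
#'
#' @param model a [hydrogen_bond_model()].
#' @param offsets sample offsets along the bond from the parent atom (A).
#' @param smeared apply thermal smearing (default TRUE; with `B = 0` or
#'   `smeared = FALSE` the unsmeared closed forms are used).
#' @return a [bond_profile()] in potential units.
#' @export
coulomb_potential_profile <- function(model, offsets, smeared = TRUE) {
  stopifnot(inherits(model, "hydrogen_bond_model"))
  u2 <- if (smeared) model$u2 else 0
  rn <- abs(offsets - model$nucleus)
  rc <- abs(offsets - model$cloud)
  phi <- model$z_nuclear * potential_point_smeared(rn, u2) -
    (if (u2 > 0) potential_1s_smeared(rc, u2, model$a0)
     else potential_1s(rc, model$a0))
  bond_profile(offsets, phi, "potential")
}

#' Electron-density profile along the bond
#'
#' Line section of the (optionally smeared) 1s density centred at the
#' electron-cloud position.
#'
#' @inheritParams coulomb_potential_profile
#' @return a [bond_profile()] in e/A^3.
#' @export
electron_density_profile <- function(model, offsets, smeared = TRUE) {
  stopifnot(inherits(model, "hydrogen_bond_model"))
  u2 <- if (smeared) model$u2 else 0
  rc <- abs(offsets - model$cloud)
  rho <- if (u2 > 0) density_1s_smeared(rc, u2, model$a0)
         else density_1s(rc, model$a0)
  bond_profile(offsets, rho, "e/A^3")
}

#' Locate the profile peak by parabolic sub-grid interpolation
#'
#' Finds the discrete argmax inside the window and refines it by fitting a
#' parabola through the three bracketing samples.  A maximum sitting on the
#' window edge is flagged as non-interior (no refinement possible).
#'
#' @param profile a [bond_profile()].
#' @param window numeric length-2 window of offsets to search (default:
#'   whole range).
#' @return list with `offset`, `value`, `interior`.
#' @export
find_peak <- function(profile, window = NULL) {
  x <- profile$offsets; y <- profile$values
  if (!is.null(window)) {
    sel <- x >= window[1] & x <= window[2]
    if (sum(sel) < 3) stop("fewer than 3 samples in the peak window")
    x <- x[sel]; y <- y[sel]
  }
  i <- which.max(y)
  if (i == 1L || i == length(y))
    return(list(offset = x[i], value = y[i], interior = FALSE))
  # parabola through (x[i-1], x[i], x[i+1]); exact for symmetric sampling
  x0 <- x[i]; dl <- x[i] - x[i - 1]; dr <- x[i + 1] - x[i]
  yl <- y[i - 1]; y0 <- y[i]; yr <- y[i + 1]
  denom <- dl * dr * (dl + dr)
  a <- (dl * (yr - y0) + dr * (yl - y0)) / denom
  b <- (dl^2 * (yr - y0) - dr^2 * (yl - y0)) / denom
  if (a >= 0)  # degenerate curvature; keep discrete maximum
    return(list(offset = x0, value = y0, interior = TRUE))
  dx <- -b / (2 * a)
  list(offset = x0 + dx, value = y0 + b * dx + a * dx^2, interior = TRUE)
}
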