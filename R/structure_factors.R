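# species-resolved scattering factor for one site column, vectorized over s
.mx_site_factor <- function(element, q, s, radiation) {
  if (q == 0) {
    if (radiation == "xray") xray_form_factor(element, s)
    else electron_form_factor(element, s)
  } else {
    partial_charge_form_factor(element, q, s, radiation)
  }
}

#' Direct-summation structure factors
#'
#' \deqn{F(h) = \sum_{ops} \sum_{sites} occ \; f(s; element, q, radiation)
#'   \; e^{-B s^2} \; e^{2\pi i \, h \cdot (R x + t)}}
#'
#' For electron radiation a model with net charge has no finite F(000);
#' if (0,0,0) is present in `hkl` it is flagged by an error.
#'
#' @param structure a [crystal_structure()].
#' @param hkl a [reflection_list()] or data.frame with `h`, `k`, `l` (and
#'   optionally `d`).
#' @param radiation `"xray"` or `"electron"`.
#' @param omit character vector of site labels to leave out of the sum.
#' @return complex vector of structure factors, one per reflection.
#' @export
calc_structure_factors <- function(structure, hkl,
                                   radiation = c("xray", "electron"),
                                   omit = NULL) {
  radiation <- match.arg(radiation)
  cell <- structure$cell; sg <- structure$sg
  sites <- structure$sites
  if (!is.null(omit)) {
    bad <- setdiff(omit, sites$label)
    if (length(bad)) stop("omit label(s) not in structure: ",
                          paste(bad, collapse = ", "))
    sites <- sites[!(sites$label %in% omit), , drop = FALSE]
  }
  H <- as.matrix(as.data.frame(hkl)[c("h", "k", "l")])
  d <- if (!is.null(hkl$d)) hkl$d else cell_dspacing(cell, H)
  zero <- rowSums(abs(H)) == 0
  s <- ifelse(zero, 0, 1 / (2 * d))
  if (radiation == "electron" && any(zero) &&
      abs(sum(sites$occ * sites$q)) > 1e-12)
    stop("F(000) undefined for electron radiation with a net-charged model")
  if (nrow(sites) == 0) return(complex(real = rep(0, nrow(H))))

  # per-species factor columns (n_refl x n_sites), with Debye-Waller
  keys <- paste(sites$element, sites$q)
  fcols <- matrix(0, nrow(H), nrow(sites))
  for (k in unique(keys)) {
    j <- which(keys == k)
    fcols[, j] <- .mx_site_factor(sites$element[j[1]], sites$q[j[1]],
                                  s, radiation)
  }
  fcols <- fcols * exp(-outer(s^2, sites$b)) *
    matrix(sites$occ, nrow(H), nrow(sites), byrow = TRUE)

  X <- t(as.matrix(sites[c("x", "y", "z")]))  # 3 x n_sites
  Fh <- complex(real = rep(0, nrow(H)))
  for (o in sg$ops) {
    XS <- o$R %*% X + o$t               # 3 x n_sites
    phase <- 2 * pi * (H %*% XS)        # n_refl x n_sites
    Fh <- Fh + rowSums(fcols * exp(1i * phase))
  }
  unname(Fh)
}

# geometric symmetry sums per site (n_refl x n_sites complex); the structure
# factor is rowSums(occ * f * DW * this).  Used by the refinement engine.
.mx_geometry_matrix <- function(structure, hkl) {
  H <- as.matrix(as.data.frame(hkl)[c("h", "k", "l")])
  X <- t(as.matrix(structure$sites[c("x", "y", "z")]))
  G <- matrix(0 + 0i, nrow(H), ncol(X))
  for (o in structure$sg$ops) {
    XS <- o$R %*% X + o$t
    G <- G + exp(2i * pi * (H %*% XS))
  }
  G
}

#' Real-space map grid
#'
#' Container for density/potential samples on a fractional grid over the
#' unit cell.
#'
#' @param values 3-D numeric array of grid values, index `[i, j, k]`
#'   corresponding to fractional coordinates `((i-1)/n1, (j-1)/n2, (k-1)/n3)`.
#' @param cell a [unit_cell()].
#' @param units units tag, e.g. `"e/A^3"`, `"potential"`, `"sigma"`.
#' @return object of class `map_grid`.
#' @export
map_grid <- function(values, cell, units = "e/A^3") {
  stopifnot(is.array(values), length(dim(values)) == 3)
  structure(list(values = values, dim = dim(values), cell = cell,
                 units = units), class = "map_grid")
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf("<map_grid> %d x %d x %d (%s), range [%.3g, %.3g]\n",
              x$dim[1], x$dim[2], x$dim[3], x$units,
              min(x$values), max(x$values)))
  invisible(x)
}

# default FFT grid: >= 4 samples per d_min along each axis and enough to
# hold the band limit, rounded up to highly composite sizes
.mx_nice_grid <- function(n) {
  nice <- sort(unique(as.integer(outer(c(1, 3, 9, 15), 2^(0:9)))))
  vapply(n, function(ni) {
    ok <- nice[nice >= ni]
    if (length(ok)) ok[1] else as.integer(ni)
  }, integer(1))
}

default_grid_dim <- function(cell, d_min) {
  .mx_nice_grid(ceiling(4 * c(cell$a, cell$b, cell$c) / d_min))
}

# expand unique reflections to the full sphere using the space-group phase
# relation F(h R) = F(h) exp(-2 pi i h.t) plus Friedel conjugates
.mx_expand_reflections <- function(hkl, F, sg) {
  H <- as.matrix(as.data.frame(hkl)[c("h", "k", "l")])
  allH <- NULL; allF <- NULL
  for (o in sg$ops) {
    Hp <- H %*% o$R
    Fp <- F * exp(-2i * pi * as.numeric(H %*% o$t))
    allH <- rbind(allH, Hp, -Hp)
    allF <- c(allF, Fp, Conj(Fp))
  }
  key <- paste(allH[, 1], allH[, 2], allH[, 3])
  first <- !duplicated(key)
  list(H = allH[first, , drop = FALSE], F = allF[first])
}

#' Fourier synthesis of a real-space map
#'
#' \deqn{\rho(x) = \frac{1}{V} \sum_h F(h) e^{-2\pi i h \cdot x}}
#'
#' Unique reflections are expanded to the full sphere by the space-group
#' symmetry and Friedel mates before the FFT.  F(000) contributes only if
#' explicitly present in `hkl`.
#'
#' @param hkl a [reflection_list()] (carries cell and space group).
#' @param F complex structure factors matching `hkl` rows.
#' @param grid_dim integer grid dimensions; default from the band limit
#'   with 2x oversampling.
#' @param units units tag for the output map.
#' @return a [map_grid()].
#' @export
synthesize_map <- function(hkl, F, grid_dim = NULL, units = "e/A^3") {
  cell <- attr(hkl, "cell"); sg <- attr(hkl, "sg")
  ex <- .mx_expand_reflections(hkl, F, sg)
  maxh <- apply(abs(ex$H), 2, max)
  if (is.null(grid_dim)) {
    dmin <- if (!is.null(hkl$d)) min(hkl$d) else NA
    over <- if (is.finite(dmin) && dmin > 0)
      ceiling(4 * c(cell$a, cell$b, cell$c) / dmin) else 2
    grid_dim <- .mx_nice_grid(pmax(2 * maxh + 1, over, 2))
  }
  if (any(grid_dim < 2 * maxh + 1))
    stop("grid dimensions ", paste(grid_dim, collapse = "x"),
         " alias the included reflections (need >= ",
         paste(2 * maxh + 1, collapse = "x"), ")")
  A <- array(0 + 0i, grid_dim)
  idx <- sweep(ex$H, 2, grid_dim, `%%`) + 1
  A[cbind(idx[, 1], idx[, 2], idx[, 3])] <- ex$F
  rho <- Re(stats::fft(A)) / cell_volume(cell)
  map_grid(rho, cell, units)
}

#' Difference (omit) map
#'
#' Fourier synthesis with coefficients
#' \eqn{(k F_o - |F_{c,omit}|) e^{i\varphi_{c,omit}}} where the scale
#' \eqn{k = \sum |F_c||F_o| / \sum |F_o|^2} is computed against the full
#' (non-omitted) model.  Omitting all hydrogens yields the hydrogen-omit
#' map used for hydrogen-density analysis.  F(000) is never included.
#'
#' @param Fo observed amplitudes (numeric, >= 0), matching `hkl` rows.
#' @param hkl a [reflection_list()].
#' @param structure the model [crystal_structure()].
#' @param omit labels of sites excluded from the phasing model.
#' @param radiation `"xray"` or `"electron"`.
#' @param grid_dim optional grid dimensions.
#' @return a [map_grid()].
#' @export
difference_map <- function(Fo, hkl, structure, omit = character(),
                           radiation = "xray", grid_dim = NULL) {
  keep <- !(hkl$h == 0 & hkl$k == 0 & hkl$l == 0)
  hkl <- hkl[keep, ]; Fo <- Fo[keep]
  Fc_full <- calc_structure_factors(structure, hkl, radiation)
  Fc_omit <- calc_structure_factors(structure, hkl, radiation, omit = omit)
  k <- sum(Mod(Fc_full) * Fo) / sum(Fo^2)
  coeff <- (k * Fo - Mod(Fc_omit)) * exp(1i * Arg(Fc_omit))
  synthesize_map(hkl, coeff, grid_dim = grid_dim, units = "difference")
}

#' Normalize a map to sigma units
#'
#' Subtracts the mean and divides by the r.m.s. deviation, so the result
#' has mean 0 and standard deviation 1 ("sigma-scaled" map; contour levels
#' quoted in sigma refer to such maps).
#'
#' @param map a [map_grid()].
#' @return a [map_grid()] with `units = "sigma"`.
#' @export
sigma_normalize <- function(map) {
  v <- map$values
  mu <- mean(v)
  sd <- sqrt(mean((v - mu)^2))
  if (sd == 0) stop("cannot sigma-normalize a constant map")
  map_grid((v - mu) / sd, map$cell, "sigma")
}

# trilinear interpolation of a map at fractional coordinates (n x 3)
map_interpolate <- function(map, frac) {
  frac <- matrix(frac, ncol = 3)
  n <- map$dim
  out <- numeric(nrow(frac))
  g <- sweep(frac %% 1, 2, n, `*`)   # grid coordinates in [0, n)
  i0 <- floor(g); f <- g - i0
  for (r in seq_len(nrow(frac))) {
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f[r, ], 1 - f[r, ]))
      ii <- (i0[r, ] + c(dx, dy, dz)) %% n + 1
      acc <- acc + w * map$values[ii[1], ii[2], ii[3]]
    }
    out[r] <- acc
  }
  out
}

#' Crystallographic R1 factor
#'
#' \eqn{R1 = \sum ||F_o| - k |F_c|| / \sum |F_o|} with the least-squares
#' scale \eqn{k = \sum |F_o||F_c| / \sum |F_c|^2}, reported for the strong
#' subset (\eqn{F_o > threshold \cdot \sigma(F_o)}) and for all reflections.
#'
#' @param Fo observed amplitudes.
#' @param Fc calculated amplitudes (numeric or complex).
#' @param sig_Fo amplitude uncertainties; if NULL the strong set equals the
#'   full set.
#' @param threshold sigma threshold defining the strong subset (default 4).
#' @return list with `R1_strong`, `R1_all`, `k`, `n_strong`, `n_all`.
#' @export
r_factor <- function(Fo, Fc, sig_Fo = NULL, threshold = 4) {
  Fc <- Mod(Fc)
  if (length(Fo) == 0) stop("empty reflection set")
  k <- sum(Fo * Fc) / sum(Fc^2)
  r1 <- function(sel) {
    if (!any(sel)) stop("empty qualifying subset for R1")
    sum(abs(Fo[sel] - k * Fc[sel])) / sum(Fo[sel])
  }
  strong <- if (is.null(sig_Fo)) rep(TRUE, length(Fo))
            else Fo > threshold * sig_Fo
  list(R1_strong = r1(strong), R1_all = r1(rep(TRUE, length(Fo))),
       k = k, n_strong = sum(strong), n_all = length(Fo))
}
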