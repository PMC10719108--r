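# --- geometric helpers for idealized molecule building (Cartesian, A) ---

# rotate a vector in the xy-plane by `deg` degrees
.mx_rot_xy <- function(v, deg) {
  th <- deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2], v[3])
}

# unit vector
.mx_unit <- function(v) v / sqrt(sum(v^2))

# three tetrahedral H positions around atom at `c0`, bonded from `from`
.mx_tripod <- function(c0, from, blen = 1.08) {
  axis <- .mx_unit(c0 - from)
  p1 <- if (abs(axis[3]) < 0.9) .mx_unit(c(-axis[2], axis[1], 0))
        else c(1, 0, 0)
  p1 <- .mx_unit(p1 - sum(p1 * axis) * axis)
  p2 <- c(axis[2] * p1[3] - axis[3] * p1[2],
          axis[3] * p1[1] - axis[1] * p1[3],
          axis[1] * p1[2] - axis[2] * p1[1])
  ct <- cos(70.5 * pi / 180); st <- sin(70.5 * pi / 180)
  # azimuthal phase 90 deg: one H out of the p1 plane, two straddling it,
  # which keeps methyl hydrogens clear of in-plane ring substituents
  lapply(c(90, 210, 330) * pi / 180, function(th)
    c0 + blen * (ct * axis + st * (cos(th) * p1 + sin(th) * p2)))
}

# two methylene H positions: perpendicular to the C's two heavy bonds
.mx_ch2 <- function(c0, nb1, nb2, blen = 1.08) {
  bis <- -.mx_unit(.mx_unit(nb1 - c0) + .mx_unit(nb2 - c0))
  perp <- .mx_unit(cross <- c(
    (nb1 - c0)[2] * (nb2 - c0)[3] - (nb1 - c0)[3] * (nb2 - c0)[2],
    (nb1 - c0)[3] * (nb2 - c0)[1] - (nb1 - c0)[1] * (nb2 - c0)[3],
    (nb1 - c0)[1] * (nb2 - c0)[2] - (nb1 - c0)[2] * (nb2 - c0)[1]))
  half <- 54.25 * pi / 180  # half the H-C-H angle
  list(c0 + blen * (cos(half) * bis + sin(half) * perp),
       c0 + blen * (cos(half) * bis - sin(half) * perp))
}

# Cartesian coordinates of the idealized rhodamine-6G-like molecule, read
# from the packaged synthetic-geometry fixture (ETKDG-embedded,
# MMFF94-minimized; labels match the connectivity graph).  The chloride is
# placed on a bent hydrogen bond off N15-H15 at 3.35 A from N15, and the
# half-occupied water oxygen beside it.
.mx_rhodamine_coords <- function() {
  tab <- .mx_resource("rhodamine6g_synthetic.xyz", function(p)
    utils::read.table(p, header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE))
  xyz <- lapply(seq_len(nrow(tab)), function(i)
    c(tab$x[i], tab$y[i], tab$z[i]))
  names(xyz) <- tab$label
  dH <- .mx_unit(xyz$H15 - xyz$N15)
  perp <- .mx_unit(pracma_null <- {
    v <- c(-dH[2], dH[1], 0)
    if (sqrt(sum(v^2)) < 1e-6) c(1, 0, 0) else v
  })
  xyz$CL1 <- xyz$N15 + 3.35 * .mx_unit(dH + 0.55 * perp)
  xyz$O2W <- xyz$CL1 + 3.0 * .mx_unit(perp + c(0, 0, 1))
  xyz
}

#' Build a deterministic toy crystal structure
#'
#' Three synthetic test structures with idealized geometry:
#' `two_atom` (a C and an O in P1), `planar_ring` (a benzene-like aromatic
#' ring with hydrogens, P1 or placed in a Pbca cell) and `rhodamine_like`
#' (an idealized rhodamine-6G-like molecule - 28 C, 2 N, 3 O, 31 H, a
#' chloride and a half-occupied water oxygen - matching the packaged
#' connectivity graph; composition C28 H31 N2 O3.5 Cl).  These are
#' synthetic idealized geometries, not refined experimental coordinates.
#'
#' @param kind `"two_atom"`, `"planar_ring"` or `"rhodamine_like"`.
#' @param sg_name space-group name (`"P1"`, `"P-1"` or `"Pbca"`).
#' @param cell optional [unit_cell()]; a kind-appropriate default otherwise.
#' @param b_heavy,b_h default isotropic B for heavy atoms / hydrogens (A^2).
#' @return a [crystal_structure()] with an attached connectivity graph
#'   (where the kind has hydrogens).
#' @export
build_toy_structure <- function(kind = c("two_atom", "planar_ring",
                                         "rhodamine_like"),
                                sg_name = "P1", cell = NULL,
                                b_heavy = 3, b_h = 4.5) {
  kind <- match.arg(kind)
  sg <- space_group(sg_name)
  if (kind == "two_atom") {
    if (is.null(cell)) cell <- unit_cell(6, 7, 8)
    sites <- data.frame(label = c("C1", "O1"), element = c("C", "O"),
                        x = c(0.15, 0.40), y = c(0.20, 0.45),
                        z = c(0.30, 0.55), b = b_heavy)
    return(crystal_structure(cell, sg, sites))
  }
  if (kind == "planar_ring") {
    if (is.null(cell))
      cell <- if (sg_name == "Pbca") unit_cell(10, 12, 14)
              else unit_cell(9, 9, 7)
    ang <- seq(0, 300, by = 60) * pi / 180
    cxy <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
    hxy <- cbind(2.47 * cos(ang), 2.47 * sin(ang), 0)
    lab_c <- paste0("C", 1:6); lab_h <- paste0("H", 1:6)
    cart <- rbind(cxy, hxy)
    # place the ring at a general position of the cell
    M <- cell_orth_matrix(cell)
    origin <- as.numeric(M %*% c(0.31, 0.27, 0.23))
    frac <- t(solve(M, t(sweep(cart, 2, -origin))))
    sites <- data.frame(label = c(lab_c, lab_h),
                        element = rep(c("C", "H"), each = 6),
                        x = frac[, 1], y = frac[, 2], z = frac[, 3],
                        b = rep(c(b_heavy, b_h), each = 6))
    atoms <- data.frame(label = c(lab_c, lab_h),
                        element = rep(c("C", "H"), each = 6),
                        aromatic = rep(c(TRUE, FALSE), each = 6))
    bonds <- data.frame(
      from = c(lab_c, lab_h),
      to = c(lab_c[c(2:6, 1)], lab_c),
      aromatic = c(rep(TRUE, 6), rep(FALSE, 6)))
    g <- molecular_graph(atoms, bonds)
    return(crystal_structure(cell, sg, sites, graph = g))
  }
  # rhodamine_like
  xyz <- .mx_rhodamine_coords()
  g <- rhodamine6g_graph()
  # append the water oxygen to the graph atoms (unbonded solvent)
  g$atoms <- rbind(g$atoms, data.frame(label = "O2W", element = "O",
                                       aromatic = FALSE))
  cart <- do.call(rbind, xyz)
  if (is.null(cell)) {
    if (sg_name == "Pbca") {
      cell <- unit_cell(14.88, 15.11, 23.31)
    } else {
      span <- apply(cart, 2, function(v) diff(range(v)))
      cell <- unit_cell(span[1] + 6, span[2] + 6, span[3] + 6)
    }
  }
  M <- cell_orth_matrix(cell)
  shift <- -apply(cart, 2, min) + 3
  frac <- t(solve(M, t(sweep(cart, 2, shift, `+`))))
  if (sg_name == "Pbca") frac <- frac / 2  # keep within the asymmetric unit
  labs <- rownames(cart)
  el <- vapply(labs, function(l) {
    if (l == "O2W") "O"
    else g$atoms$element[match(l, g$atoms$label)]
  }, "")
  sites <- data.frame(label = labs, element = el,
                      x = frac[, 1], y = frac[, 2], z = frac[, 3],
                      occ = ifelse(labs == "O2W", 0.5, 1),
                      b = ifelse(el == "H", b_h, b_heavy))
  crystal_structure(cell, sg, sites, graph = g)
}

#' Simulate rotation-style integrated reflection intensities
#'
#' Generates the symmetry-unique reflection list, computes noise-free
#' intensities \eqn{I = |F|^2} for the chosen radiation, and applies
#' multiplicative Gaussian counting noise with
#' \eqn{\sigma(I) = noise \cdot I_{true}}.  A fixed seed makes the output
#' fully reproducible.
#'
#' @param structure a [crystal_structure()].
#' @param d_min,d_max resolution range in A.
#' @param radiation `"xray"` or `"electron"`.
#' @param noise fractional Gaussian noise level (0 = noise-free).
#' @param seed integer RNG seed (mandatory when noise > 0).
#' @return a [reflection_list()] with columns `I`, `sigma`, `Fo`
#'   (amplitude, negative intensities clamped to 0 and flagged in
#'   `clamped`) and `F_true` (complex noise-free structure factor).
#' @export
simulate_reflections <- function(structure, d_min, d_max = Inf,
                                 radiation = c("xray", "electron"),
                                 noise = 0, seed = NULL) {
  radiation <- match.arg(radiation)
  if (noise > 0 && is.null(seed)) stop("a seed is mandatory for noisy simulation")
  hkl <- generate_unique_hkl(structure$cell, structure$sg, d_min, d_max)
  Ftrue <- calc_structure_factors(structure, hkl, radiation)
  I_true <- Mod(Ftrue)^2
  sigma <- noise * I_true
  I_obs <- .mx_with_seed(seed, I_true + stats::rnorm(length(I_true), 0, sigma))
  hkl$I <- I_obs
  hkl$sigma <- sigma
  hkl$clamped <- I_obs < 0
  hkl$Fo <- sqrt(pmax(I_obs, 0))
  hkl$F_true <- Ftrue
  hkl
}

#' Simulation configuration for still-frame serial data
#'
#' Defaults mirror a serial still-diffraction run on randomly oriented
#' microcrystals: about half the frames are blank (no crystal hit), the
#' reflecting condition is a Gaussian partiality slab around the Ewald
#' sphere, and per-frame scales fluctuate lognormally.
#'
#' @param n_frames number of frames.
#' @param seed integer RNG seed (mandatory).
#' @param d_min resolution limit in A.
#' @param wavelength beam wavelength in A (default: 15 keV photons).
#' @param blank_fraction fraction of blank (missed or beam-down) frames.
#' @param partiality_width Gaussian width of the excitation slab in
#'   reciprocal A (default 0.004).
#' @param scale_sdlog lognormal sigma of per-frame scales (default 0.3).
#' @param noise fractional Gaussian counting noise on partial intensities.
#' @param beam_scale overall detector-counts scaling (default 25).
#' @param min_partiality detection threshold: a reflection is recorded as a
#'   spot only when its partiality exceeds this fraction (default 0.1;
#'   weaker partials are below the measurable limit).
#' @param radiation `"xray"` or `"electron"`.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_frames, seed, d_min = 1.2,
                              wavelength = photon_wavelength(15),
                              blank_fraction = 0.5,
                              partiality_width = 0.004,
                              scale_sdlog = 0.3, noise = 0,
                              beam_scale = 25, min_partiality = 0.1,
                              radiation = "xray") {
  stopifnot(n_frames >= 1, partiality_width >= 0, scale_sdlog >= 0,
            noise >= 0, min_partiality > 0, min_partiality < 1)
  if (missing(seed)) stop("a seed is mandatory")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate still diffraction frames from randomly oriented crystals
#'
#' Each non-blank frame gets a uniformly random orientation (quaternion
#' method).  A reflection is recorded when its rotated reciprocal-lattice
#' point lies within the Gaussian partiality slab of the Ewald sphere for
#' the configured wavelength; its partial intensity is
#' \eqn{|F|^2 \cdot partiality \cdot scale_{frame} \cdot beam + noise}.
#' Negative noisy intensities are kept.  Blank frames (no crystal, or beam
#' down) are injected at the configured fraction.
#'
#' @param structure a [crystal_structure()].
#' @param config a [simulation_config()].
#' @return a [frame_set()].
#' @export
simulate_still_frames <- function(structure, config) {
  stopifnot(inherits(config, "simulation_config"))
  cell <- structure$cell; sg <- structure$sg
  lambda <- config$wavelength
  if (2 * config$d_min < lambda)
    stop("wavelength too long: no reflection inside d_min can diffract")
  hkl <- generate_unique_hkl(cell, sg, config$d_min)
  Fu <- calc_structure_factors(structure, hkl, config$radiation)
  ex <- .mx_expand_reflections(hkl, Fu, sg)
  I_full <- Mod(ex$F)^2 * config$beam_scale
  Minv_t <- t(solve(cell_orth_matrix(cell)))
  Q <- ex$H %*% t(Minv_t)             # reciprocal vectors, n x 3 (1/A)
  kin <- c(0, 0, 1 / lambda)
  w <- config$partiality_width
  e_cut <- w * sqrt(-2 * log(config$min_partiality))

  .mx_with_seed(config$seed, {
    frames <- vector("list", config$n_frames)
    for (i in seq_len(config$n_frames)) {
      blank <- stats::runif(1) < config$blank_fraction
      if (blank) {
        frames[[i]] <- list(
          id = i, orientation = c(1, 0, 0, 0),
          spots = data.frame(h = integer(), k = integer(), l = integer(),
                             I = numeric(), sigma = numeric()),
          max_pixel = 0, beam_on = FALSE)
        next
      }
      q4 <- stats::rnorm(4); q4 <- q4 / sqrt(sum(q4^2))
      R <- .mx_quat_matrix(q4)
      Qr <- Q %*% t(R)
      e <- sqrt((Qr[, 1] + kin[1])^2 + (Qr[, 2] + kin[2])^2 +
                (Qr[, 3] + kin[3])^2) - 1 / lambda
      sel <- which(abs(e) < e_cut)
      part <- exp(-e[sel]^2 / (2 * w^2))
      scale <- stats::rlnorm(1, 0, config$scale_sdlog)
      I <- I_full[sel] * part * scale
      sigma <- config$noise * abs(I)
      if (config$noise > 0) I <- I + stats::rnorm(length(I), 0, sigma)
      frames[[i]] <- list(
        id = i, orientation = q4,
        spots = data.frame(h = ex$H[sel, 1], k = ex$H[sel, 2],
                           l = ex$H[sel, 3], I = I, sigma = sigma),
        max_pixel = if (length(I)) max(I) else 0, beam_on = TRUE)
    }
    frame_set(frames, cell, sg, lambda)
  })
}

.mx_quat_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Paired hydrogen-omit maps with known ground truth
#'
#' Builds two sigma-normalized hydrogen-omit difference maps from the same
#' structure: a reference map with hydrogens at their input (electron-cloud
#' style) positions, and an alternate map with each hydrogen displaced
#' outward along its bond by a per-class amount, emulating the outward
#' shift of Coulomb-potential hydrogen peaks relative to electron-density
#' peaks.  Default displacements follow the magnitudes typical of
#' methyl/methylene/aromatic/amide bonds.
#'
#' @param structure a [crystal_structure()] with hydrogens and a graph.
#' @param d_min band limit of the synthetic amplitudes in A (default 0.8).
#' @param displacements named per-class outward displacement in A.
#' @param oversample map-grid samples per `d_min` along each axis (default
#'   8; peak-position interpolation needs a finer grid than the synthesis
#'   minimum).
#' @return list with `map_ref`, `map_alt` (sigma maps), `structure_ref`,
#'   `structure_alt` and `hkl`.
#' @export
make_paired_maps <- function(structure, d_min = 0.8,
                             displacements = c(methyl = 0.095,
                                               methylene = 0.077,
                                               aromatic = 0.139,
                                               amide = 0.24),
                             oversample = 8) {
  if (is.null(structure$graph)) stop("structure needs a connectivity graph")
  cls <- classify_hydrogens(structure$graph)
  hlab <- intersect(names(cls), structure$sites$label)
  if (!length(hlab)) stop("structure has no hydrogen sites")
  st_alt <- structure
  M <- cell_orth_matrix(structure$cell)
  for (h in hlab) {
    dcl <- displacements[[cls[[h]]]]
    if (is.null(dcl) || is.na(dcl)) next
    i <- match(h, st_alt$sites$label)
    p <- match(h_parent_label(st_alt, h), st_alt$sites$label)
    dfr <- unlist(st_alt$sites[i, c("x", "y", "z")]) -
      unlist(st_alt$sites[p, c("x", "y", "z")])
    dfr <- dfr - round(dfr)
    v <- as.numeric(M %*% dfr)
    vnew <- v * (1 + dcl / sqrt(sum(v^2)))
    st_alt$sites[i, c("x", "y", "z")] <-
      (unlist(st_alt$sites[p, c("x", "y", "z")]) +
         as.numeric(solve(M, vnew))) %% 1
  }
  hkl <- generate_unique_hkl(structure$cell, structure$sg, d_min)
  cl <- structure$cell
  gd <- .mx_nice_grid(
    ceiling(oversample * c(cl$a, cl$b, cl$c) / d_min))
  omap <- function(st) {
    Fo <- Mod(calc_structure_factors(st, hkl, "xray"))
    sigma_normalize(difference_map(Fo, hkl, st, omit = hlab,
                                   radiation = "xray", grid_dim = gd))
  }
  list(map_ref = omap(structure), map_alt = omap(st_alt),
       structure_ref = structure, structure_alt = st_alt, hkl = hkl)
}
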