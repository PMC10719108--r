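# Cached per-site model pieces for repeated Fc evaluation: the geometric
# symmetry sums G (n_refl x n_sites) and the per-site scattering factor
# columns f(s) (recomputed only for sites whose charge changes).
.mx_fc_engine <- function(structure, hkl, radiation) {
  G <- .mx_geometry_matrix(structure, hkl)
  s <- hkl$s
  sites <- structure$sites
  fcols <- matrix(0, length(s), nrow(sites))
  for (j in seq_len(nrow(sites)))
    fcols[, j] <- .mx_site_factor(sites$element[j], sites$q[j], s, radiation)
  H <- as.matrix(as.data.frame(hkl)[c("h", "k", "l")])
  list(G = G, s = s, sites = sites, fcols = fcols, radiation = radiation,
       H = H, ops = structure$sg$ops)
}

.mx_fc_eval <- function(eng, b = NULL, xyz = NULL, q_update = NULL) {
  fcols <- eng$fcols
  if (!is.null(q_update))
    for (lab in names(q_update)) {
      j <- match(lab, eng$sites$label)
      fcols[, j] <- .mx_site_factor(eng$sites$element[j], q_update[[lab]],
                                    eng$s, eng$radiation)
    }
  if (is.null(b)) b <- eng$sites$b
  G <- if (is.null(xyz)) eng$G else {
    Gn <- matrix(0 + 0i, nrow(eng$H), ncol = nrow(eng$sites))
    for (o in eng$ops)
      Gn <- Gn + exp(2i * pi * (eng$H %*% (o$R %*% t(xyz) + o$t)))
    Gn
  }
  contrib <- fcols * exp(-outer(eng$s^2, b)) *
    matrix(eng$sites$occ, length(eng$s), nrow(eng$sites), byrow = TRUE) *
    G
  list(F = rowSums(contrib), contrib = contrib)
}

#' Simplified least-squares re-refinement against amplitudes
#'
#' Minimizes \eqn{\sum (|F_o| - k |F_c|)^2} over an overall scale and,
#' optionally, the per-atom isotropic B factors (quasi-Newton with analytic
#' gradients).  This is a deliberately reduced refinement - no restraints,
#' no coordinate shifts by default - sufficient for synthetic parameter
#' recovery; it is not a full crystallographic refinement engine.
#'
#' @param structure starting [crystal_structure()] (within the convergence
#'   basin; intended for synthetic data).
#' @param Fo observed amplitudes matching `hkl` rows.
#' @param hkl a [reflection_list()].
#' @param radiation `"xray"` or `"electron"`.
#' @param scope `"scale"` (overall scale only), `"scale_b"` (scale plus
#'   per-atom B) or `"scale_b_xyz"` (scale, per-atom B and a coordinate
#'   polish).
#' @param max_iter iteration cap for the optimizer.
#' @return list with `scale`, `b` (refined per-atom B), `structure`
#'   (B updated), `rss`, `converged`, plus the engine internals reused by
#'   [shell_r()].
#' @export
refine_simple <- function(structure, Fo, hkl,
                          radiation = c("xray", "electron"),
                          scope = c("scale_b", "scale", "scale_b_xyz"),
                          max_iter = 60L) {
  radiation <- match.arg(radiation)
  scope <- match.arg(scope)
  keep <- !(hkl$h == 0 & hkl$k == 0 & hkl$l == 0)
  hkl <- hkl[keep, ]; Fo <- Fo[keep]
  eng <- .mx_fc_engine(structure, hkl, radiation)

  best_scale <- function(Fc_mod) sum(Fo * Fc_mod) / sum(Fc_mod^2)

  if (scope == "scale") {
    ev <- .mx_fc_eval(eng)
    k <- best_scale(Mod(ev$F))
    rss <- sum((Fo - k * Mod(ev$F))^2)
    return(list(scale = k, b = structure$sites$b, structure = structure,
                rss = rss, converged = TRUE, eng = eng, hkl = hkl, Fo = Fo))
  }

  n_sites <- nrow(structure$sites)
  xyz0 <- as.matrix(structure$sites[c("x", "y", "z")])
  with_xyz <- scope == "scale_b_xyz"
  # hydrogen positions are not refined (riding convention: they are too
  # weakly determined at these resolutions and would drift freely)
  movable <- structure$sites$element != "H"
  n_mov <- sum(movable)
  HRs <- lapply(structure$sg$ops, function(o) eng$H %*% o$R)
  unpack <- function(par) {
    xyz <- NULL
    if (with_xyz) {
      xyz <- xyz0
      xyz[movable, ] <- matrix(par[-seq_len(n_sites)], n_mov, 3)
    }
    list(b = par[seq_len(n_sites)], xyz = xyz)
  }
  # value and analytic gradient in one pass, memoized on the parameter
  # vector (optim calls fn and gr separately)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    p <- unpack(par)
    xyz <- if (with_xyz) p$xyz else xyz0
    W <- eng$fcols * exp(-outer(eng$s^2, p$b)) *
      matrix(eng$sites$occ, length(eng$s), n_sites, byrow = TRUE)
    Pops <- lapply(eng$ops, function(o)
      exp(2i * pi * (eng$H %*% (o$R %*% t(xyz) + o$t))))
    G <- Reduce(`+`, Pops)
    contrib <- W * G
    Fh <- rowSums(contrib)
    Fc <- Mod(Fh); Fcs <- pmax(Fc, 1e-12)
    k <- best_scale(Fc)
    resid <- Fo - k * Fc
    val <- sum(resid^2)
    # d|F|/dB_j; the scale k is at its optimum, so its derivative term
    # vanishes (envelope theorem)
    dB <- as.numeric(-2 * k * crossprod(
      resid, -eng$s^2 * Re(Conj(Fh) * contrib) / Fcs))
    grad <- dB
    if (with_xyz) {
      dxyz <- matrix(0, n_sites, 3)
      for (io in seq_along(Pops)) {
        WP <- W * Pops[[io]]
        for (a in 1:3) {
          dF <- 2i * pi * HRs[[io]][, a] * WP
          dmod <- Re(Conj(Fh) * dF) / Fcs
          dxyz[, a] <- dxyz[, a] - 2 * k * as.numeric(crossprod(resid, dmod))
        }
      }
      grad <- c(dB, as.numeric(dxyz[movable, , drop = FALSE]))
    }
    cache$par <- par
    cache$res <- list(value = val, gradient = grad, k = k, b = p$b,
                      xyz = xyz)
    cache$res
  }
  xyz0m <- xyz0[movable, , drop = FALSE]
  par0 <- c(structure$sites$b, if (with_xyz) as.numeric(xyz0m))
  lower <- c(rep(0, n_sites), if (with_xyz) as.numeric(xyz0m) - 0.05)
  upper <- c(rep(60, n_sites), if (with_xyz) as.numeric(xyz0m) + 0.05)
  opt <- stats::optim(par0, function(p) evaluate(p)$value,
                      function(p) evaluate(p)$gradient,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = max_iter))
  fin <- evaluate(opt$par)
  st <- structure
  st$sites$b <- fin$b
  if (with_xyz) {
    st$sites[c("x", "y", "z")] <- fin$xyz %% 1
    eng <- .mx_fc_engine(st, hkl, radiation)  # refresh geometry for callers
  }
  list(scale = fin$k, b = fin$b, structure = st, rss = opt$value,
       converged = opt$convergence == 0, eng = eng, hkl = hkl, Fo = Fo)
}

#' Shell-resolved R factors after re-refinement
#'
#' Refines the model against all supplied reflections (see
#' [refine_simple()]) and reports R1 in the low-resolution shell
#' (\eqn{s < s_{cut}}), the remaining shells (\eqn{s \ge s_{cut}}) and over
#' all reflections, with the single refined overall scale.  Low-resolution
#' data carry most of the charge signal, which is why the low shell is the
#' grid-search objective.
#'
#' @inheritParams refine_simple
#' @param s_cut shell boundary in 1/A (default 0.2).
#' @return list with `R_low`, `R_high`, `R_all`, `s_cut`, `scale`, `b`,
#'   `n_low`, `n_high`, `converged`.
#' @export
shell_r <- function(structure, Fo, hkl, radiation = c("xray", "electron"),
                    s_cut = 0.2, scope = "scale_b", max_iter = 60L) {
  radiation <- match.arg(radiation)
  ref <- refine_simple(structure, Fo, hkl, radiation, scope, max_iter)
  Fc <- Mod(.mx_fc_eval(ref$eng, b = ref$b)$F)
  k <- ref$scale
  lo <- ref$hkl$s < s_cut
  if (!any(lo)) stop("low-resolution shell (s < ", s_cut, ") is empty")
  if (!any(!lo)) stop("high-resolution shell (s >= ", s_cut, ") is empty")
  r1 <- function(sel) sum(abs(ref$Fo[sel] - k * Fc[sel])) / sum(ref$Fo[sel])
  list(R_low = r1(lo), R_high = r1(!lo), R_all = r1(rep(TRUE, length(lo))),
       s_cut = s_cut, scale = k, b = ref$b,
       n_low = sum(lo), n_high = sum(!lo), converged = ref$converged)
}

#' Grid search over partial charges
#'
#' Exhaustive search over all combinations of partial charges on the
#' requested sites (hydrogen-type sites positive in \[0, +1\], halide sites
#' negative in \[-1, 0\], step 0.1 by default), re-refining scale and B for
#' every combination and selecting the assignment with the lowest R in the
#' low-resolution shell.  Ties are broken by R over all shells, then by the
#' smallest total absolute charge.
#'
#' @param structure a [crystal_structure()].
#' @param Fo observed amplitudes matching `hkl`.
#' @param hkl a [reflection_list()].
#' @param sites character vector of searched site labels.
#' @param radiation `"xray"` or `"electron"`.
#' @param step charge grid step (default 0.1; grids are multiples of it).
#' @param scope refinement scope per combination (see [refine_simple()]).
#' @param s_cut low-shell boundary in 1/A.
#' @param max_iter optimizer cap per combination.
#' @return list with `best` (named charge vector), `best_r` (its shell-R
#'   report), `surface` (data.frame of the full R surface), `degenerate`
#'   (TRUE when all R_low are equal and the neutral assignment is returned).
#' @export
charge_grid_search <- function(structure, Fo, hkl, sites,
                               radiation = c("xray", "electron"),
                               step = 0.1, scope = "scale", s_cut = 0.2,
                               max_iter = 40L) {
  radiation <- match.arg(radiation)
  idx <- match(sites, structure$sites$label)
  if (anyNA(idx)) stop("searched site(s) not in structure: ",
                       paste(sites[is.na(idx)], collapse = ", "))
  grids <- lapply(idx, function(i) {
    el <- structure$sites$element[i]
    if (el %in% c("Cl", "Br", "I", "F")) -rev(seq(0, 1, by = step))
    else seq(0, 1, by = step)
  })
  names(grids) <- sites
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)

  keep <- !(hkl$h == 0 & hkl$k == 0 & hkl$l == 0)
  hkl <- hkl[keep, ]; Fo <- Fo[keep]

  lo <- hkl$s < s_cut
  if (!any(lo) || all(lo)) stop("resolution shells must both be non-empty")
  rows <- vector("list", nrow(combos))
  if (scope == "scale") {
    # fast path: one shared engine, only the searched-site factor columns
    # change between combinations
    eng <- .mx_fc_engine(structure, hkl, radiation)
    for (r in seq_len(nrow(combos))) {
      qup <- as.list(stats::setNames(as.numeric(combos[r, ]), sites))
      Fc <- Mod(.mx_fc_eval(eng, q_update = qup)$F)
      k <- sum(Fo * Fc) / sum(Fc^2)
      r1 <- function(sel) sum(abs(Fo[sel] - k * Fc[sel])) / sum(Fo[sel])
      rows[[r]] <- data.frame(combos[r, , drop = FALSE],
                              R_low = r1(lo), R_high = r1(!lo),
                              R_all = r1(rep(TRUE, length(lo))),
                              converged = TRUE)
    }
  } else {
    for (r in seq_len(nrow(combos))) {
      st <- structure
      st$sites$q[idx] <- as.numeric(combos[r, ])
      rep_r <- shell_r(st, Fo, hkl, radiation, s_cut = s_cut,
                       scope = scope, max_iter = max_iter)
      rows[[r]] <- data.frame(combos[r, , drop = FALSE],
                              R_low = rep_r$R_low, R_high = rep_r$R_high,
                              R_all = rep_r$R_all,
                              converged = rep_r$converged)
    }
  }
  surface <- do.call(rbind, rows)
  rownames(surface) <- NULL

  degenerate <- diff(range(surface$R_low)) < 1e-12
  if (degenerate) {
    best_q <- stats::setNames(rep(0, length(sites)), sites)
  } else {
    ord <- order(surface$R_low, surface$R_all,
                 rowSums(abs(surface[seq_along(sites)])))
    best_q <- stats::setNames(as.numeric(surface[ord[1], seq_along(sites)]),
                              sites)
  }
  st <- structure
  st$sites$q[idx] <- best_q
  best_r <- shell_r(st, Fo, hkl, radiation, s_cut = s_cut,
                    scope = scope, max_iter = max_iter)
  list(best = best_q, best_r = best_r, surface = surface,
       degenerate = degenerate)
}
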