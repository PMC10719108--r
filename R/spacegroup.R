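#' Space-group operators
#'
#' Hard-coded symmetry operators for the three groups needed for this
#' package: P1, P-1 and Pbca (no. 61).  Each operator is a pair of a 3x3
#' integer rotation matrix `R` and a translation vector `t`; a site at
#' fractional `x` maps to `R x + t`.  Operator-set closure is exercised by
#' the test suite.
#'
#' @param name one of `"P1"`, `"P-1"`, `"Pbca"`.
#' @return object of class `space_group` with elements `name`, `number`,
#'   `ops` (list of `list(R, t)`), `centrosymmetric`.
#' @export
space_group <- function(name = c("P1", "P-1", "Pbca")) {
  name <- match.arg(name)
  I3 <- diag(3)
  op <- function(R, t) list(R = R, t = t)
  ops <- switch(
    name,
    "P1" = list(op(I3, c(0, 0, 0))),
    "P-1" = list(op(I3, c(0, 0, 0)), op(-I3, c(0, 0, 0))),
    "Pbca" = {
      # 2_1 screw axes along c, b, a plus the inversion-related glides
      R2z <- diag(c(-1, -1, 1)); R2y <- diag(c(-1, 1, -1))
      R2x <- diag(c(1, -1, -1))
      base <- list(
        op(I3,  c(0, 0, 0)),
        op(R2z, c(0.5, 0, 0.5)),
        op(R2y, c(0, 0.5, 0.5)),
        op(R2x, c(0.5, 0.5, 0)))
      c(base, lapply(base, function(o) op(-o$R, -o$t %% 1)))
    })
  number <- switch(name, "P1" = 1L, "P-1" = 2L, "Pbca" = 61L)
  structure(list(name = name, number = number, ops = ops,
                 centrosymmetric = name != "P1"),
            class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat("<space_group> ", x$name, " (no. ", x$number, "), ",
      length(x$ops), " operators\n", sep = "")
  invisible(x)
}

# Laue-group rotation matrices used for merging intensities: the distinct
# rotation parts of the space group closed under inversion (Friedel).
laue_rotations <- function(sg) {
  rots <- lapply(sg$ops, `[[`, "R")
  rots <- c(rots, lapply(rots, function(R) -R))
  keys <- vapply(rots, function(R) paste(R, collapse = ","), "")
  rots[!duplicated(keys)]
}

# Map an integer hkl matrix (n x 3) to canonical Laue-group representatives:
# the lexicographically largest equivalent (h, then k, then l).
canonical_hkl <- function(hkl, sg) {
  hkl <- matrix(as.integer(round(hkl)), ncol = 3)
  rots <- laue_rotations(sg)
  best <- NULL
  for (R in rots) {
    cand <- hkl %*% R
    if (is.null(best)) { best <- cand; next }
    repl <- cand[, 1] > best[, 1] |
      (cand[, 1] == best[, 1] & cand[, 2] > best[, 2]) |
      (cand[, 1] == best[, 1] & cand[, 2] == best[, 2] & cand[, 3] > best[, 3])
    best[repl, ] <- cand[repl, ]
  }
  best
}

# Systematic-absence test from the operators themselves: h is absent iff
# some operator fixes h (h R = h) while h . t is not an integer.
hkl_absent <- function(hkl, sg) {
  hkl <- matrix(as.integer(round(hkl)), ncol = 3)
  absent <- rep(FALSE, nrow(hkl))
  for (o in sg$ops) {
    fixed <- rowSums(abs(hkl %*% o$R - hkl)) == 0
    phase <- hkl %*% o$t
    absent <- absent | (fixed & abs(phase - round(phase)) > 1e-9)
  }
  absent
}

#' Reflection list constructor
#'
#' A data.frame of reflections with the generating cell and space group kept
#' as attributes.  Columns always include `h`, `k`, `l`, `d` (A) and
#' `s` (= 1/(2d), 1/A); amplitude/intensity/sigma columns are added by the
#' simulators and mergers.
#'
#' @param df data.frame with at least `h`, `k`, `l`.
#' @param cell a [unit_cell()].
#' @param sg a [space_group()].
#' @return object of classes `reflection_list` and `data.frame`.
#' @export
reflection_list <- function(df, cell, sg) {
  df <- as.data.frame(df)
  stopifnot(all(c("h", "k", "l") %in% names(df)))
  if (is.null(df$d)) df$d <- cell_dspacing(cell, as.matrix(df[c("h", "k", "l")]))
  df$s <- 1 / (2 * df$d)
  structure(df, class = c("reflection_list", "data.frame"),
            cell = cell, sg = sg)
}

#' @export
print.reflection_list <- function(x, ...) {
  cat("<reflection_list> ", nrow(x), " reflections, d ",
      sprintf("%.2f-%.2f A", max(x$d), min(x$d)),
      " (", attr(x, "sg")$name, ")\n", sep = "")
  utils::str(as.data.frame(utils::head(x, 3)))
  invisible(x)
}

#' Generate symmetry-unique reflections in a resolution range
#'
#' Enumerates all integer hkl with \eqn{d_{min} \le d \le d_{max}}, removes
#' systematic absences and (0,0,0), and merges Laue-group equivalents and
#' Friedel mates to one canonical representative each.  The stored
#' `multiplicity` is the orbit size (number of distinct equivalents,
#' Friedel mates included).
#'
#' @param cell a [unit_cell()].
#' @param sg a [space_group()].
#' @param d_min,d_max resolution bounds in A, `d_min < d_max`.
#' @return a [reflection_list()].
#' @export
generate_unique_hkl <- function(cell, sg, d_min, d_max = Inf) {
  if (!(d_min > 0) || !(d_min < d_max)) stop("need 0 < d_min < d_max")
  hmax <- ceiling(c(cell$a, cell$b, cell$c) / d_min)
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                                k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  d <- cell_dspacing(cell, grid)
  keep <- d >= d_min & d <= d_max
  grid <- grid[keep, , drop = FALSE]; d <- d[keep]
  keep <- !hkl_absent(grid, sg)
  grid <- grid[keep, , drop = FALSE]; d <- d[keep]
  canon <- canonical_hkl(grid, sg)
  key <- paste(canon[, 1], canon[, 2], canon[, 3])
  mult <- table(key)
  first <- !duplicated(key)
  df <- data.frame(h = canon[first, 1], k = canon[first, 2],
                   l = canon[first, 3], d = d[first])
  df$multiplicity <- as.integer(mult[key[first]])
  df <- df[order(-df$d, df$h, df$k, df$l), ]
  rownames(df) <- NULL
  reflection_list(df, cell, sg)
}

#' Atom-site table and crystal structure
#'
#' `crystal_structure()` bundles a unit cell, a space group and a table of
#' atom sites in the asymmetric unit.  Site coordinates are stored reduced
#' mod 1; occupancies must lie in (0, 1] and partial charges in \[-1, 1\].
#'
#' @param cell a [unit_cell()].
#' @param sg a [space_group()].
#' @param sites data.frame with columns `label`, `element`, `x`, `y`, `z`
#'   and optionally `occ` (default 1), `b` (isotropic B in A^2, default 3)
#'   and `q` (partial charge, default 0).
#' @param graph optional [molecular_graph()] giving the connectivity of the
#'   sites (labels must match); used for hydrogen-parent lookup.
#' @return object of class `crystal_structure`.
#' @export
crystal_structure <- function(cell, sg, sites, graph = NULL) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "element", "x", "y", "z") %in% names(sites)))
  if (is.null(sites$occ)) sites$occ <- 1
  if (is.null(sites$b)) sites$b <- 3
  if (is.null(sites$q)) sites$q <- 0
  if (any(sites$occ <= 0 | sites$occ > 1)) stop("occupancy must be in (0, 1]")
  if (any(abs(sites$q) > 1)) stop("partial charge must be in [-1, 1]")
  if (any(sites$b < 0)) stop("B must be non-negative")
  sites[c("x", "y", "z")] <- lapply(sites[c("x", "y", "z")], function(v) v %% 1)
  if (anyDuplicated(sites$label)) stop("duplicate site labels")
  # no two listed sites may be symmetry equivalents of each other
  X <- as.matrix(sites[c("x", "y", "z")])
  if (nrow(X) > 1) {
    for (o in sg$ops[-1]) {
      Xi <- (X %*% t(o$R) + matrix(o$t, nrow(X), 3, byrow = TRUE)) %% 1
      for (i in seq_len(nrow(X) - 1)) {
        dd <- abs(sweep(X[-seq_len(i), , drop = FALSE], 2, Xi[i, ]))
        dd <- pmin(dd, 1 - dd)
        if (any(rowSums(dd) < 1e-3 * 3 & apply(dd, 1, max) < 1e-3))
          stop("sites contain symmetry-equivalent duplicates (op in ",
               sg$name, ")")
      }
    }
  }
  structure(list(cell = cell, sg = sg, sites = sites, graph = graph),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat("<crystal_structure> ", nrow(x$sites), " sites in ", x$sg$name,
      ", cell ", sprintf("%.3g/%.3g/%.3g A", x$cell$a, x$cell$b, x$cell$c),
      "\n", sep = "")
  invisible(x)
}

# parent heavy atom of a hydrogen site, via the attached graph
h_parent_label <- function(structure, h_label) {
  g <- structure$graph
  if (is.null(g)) stop("structure carries no connectivity graph")
  nb <- graph_neighbors(g, h_label)
  if (length(nb) != 1L)
    stop("hydrogen ", h_label, " has ambiguous parent")
  nb
}

#' Reposition riding hydrogens at target bond lengths
#'
#' Moves each hydrogen along the (unchanged) parent-to-hydrogen direction so
#' that the bond length equals the target for its class, as in riding-model
#' refinement with elongated X-H distances.
#'
#' @param structure a [crystal_structure()] with an attached graph.
#' @param lengths named numeric vector of target bond lengths in A by
#'   hydrogen class (`methyl`, `methylene`, `aromatic`, `amide`); classes
#'   absent from the map are left untouched.
#' @return the modified [crystal_structure()].
#' @export
set_riding_hydrogens <- function(structure, lengths) {
  g <- structure$graph
  if (is.null(g)) stop("structure carries no connectivity graph")
  cls <- classify_hydrogens(g)
  M <- cell_orth_matrix(structure$cell)
  s <- structure$sites
  for (h in names(cls)) {
    if (!(cls[h] %in% names(lengths))) next
    i <- match(h, s$label)
    if (is.na(i)) next
    p <- match(h_parent_label(structure, h), s$label)
    if (is.na(p)) stop("parent of hydrogen ", h, " absent from sites")
    # minimum-image fractional difference, then Cartesian
    dfr <- unlist(s[i, c("x", "y", "z")]) - unlist(s[p, c("x", "y", "z")])
    dfr <- dfr - round(dfr)
    v <- as.numeric(M %*% dfr)
    len <- sqrt(sum(v^2))
    if (len < 1e-6) stop("degenerate H-parent geometry for ", h)
    vnew <- v * (lengths[[cls[h]]] / len)
    newfr <- unlist(s[p, c("x", "y", "z")]) + as.numeric(solve(M, vnew))
    s[i, c("x", "y", "z")] <- newfr %% 1
  }
  structure$sites <- s
  structure
}
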