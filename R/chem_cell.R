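#' Molecular connectivity graph
#'
#' A light container for molecular connectivity: atoms carry a label, an
#' element symbol and an aromaticity flag; bonds are unordered atom pairs.
#' Aromaticity is an input flag, not perceived algorithmically.
#'
#' @param atoms data.frame with columns `label`, `element` and optionally
#'   logical `aromatic` (default FALSE).
#' @param bonds data.frame with columns `from`, `to` (atom labels) and
#'   optionally logical `aromatic`.
#' @return an object of class `molecular_graph`.
#' @export
molecular_graph <- function(atoms, bonds) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "element") %in% names(atoms)),
            all(c("from", "to") %in% names(bonds)))
  if (is.null(atoms$aromatic)) atoms$aromatic <- rep(FALSE, nrow(atoms))
  if (is.null(bonds$aromatic)) bonds$aromatic <- rep(FALSE, nrow(bonds))
  if (anyDuplicated(atoms$label))
    stop("duplicate atom labels in graph")
  bad <- setdiff(c(bonds$from, bonds$to), atoms$label)
  if (length(bad))
    stop("bond references unknown atom(s): ", paste(bad, collapse = ", "))
  g <- structure(list(atoms = atoms, bonds = bonds),
                 class = "molecular_graph")
  deg <- graph_degree(g)
  hyd <- atoms$element == "H"
  if (any(deg[hyd] != 1))
    stop("every hydrogen must have exactly one bond; offending: ",
         paste(atoms$label[hyd][deg[hyd] != 1], collapse = ", "))
  if (any(deg[atoms$element == "C"] > 4))
    stop("carbon degree exceeds 4")
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  tab <- table(x$atoms$element)
  cat("  composition:", paste(names(tab), tab, sep = "", collapse = " "), "\n")
  invisible(x)
}

graph_degree <- function(graph) {
  deg <- stats::setNames(rep(0L, nrow(graph$atoms)), graph$atoms$label)
  for (v in c(graph$bonds$from, graph$bonds$to))
    deg[v] <- deg[v] + 1L
  deg
}

# labels of atoms bonded to `label`
graph_neighbors <- function(graph, label) {
  c(graph$bonds$to[graph$bonds$from == label],
    graph$bonds$from[graph$bonds$to == label])
}

#' Read a molecular graph from a whitespace-delimited text file
#'
#' Format: one record per line; `atom <label> <element> [ar]` declares an
#' atom (with optional aromatic flag `ar`), `bond <label1> <label2> [ar]`
#' declares a bond.  Blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a [molecular_graph()].
#' @export
read_graph <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  at <- list(); bd <- list()
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (tk[1] == "atom" && length(tk) >= 3) {
      at[[length(at) + 1L]] <- data.frame(
        label = tk[2], element = tk[3],
        aromatic = length(tk) > 3 && tk[4] == "ar")
    } else if (tk[1] == "bond" && length(tk) >= 3) {
      bd[[length(bd) + 1L]] <- data.frame(
        from = tk[2], to = tk[3],
        aromatic = length(tk) > 3 && tk[4] == "ar")
    } else {
      stop("malformed graph record at line ", i, ": ", lines[i])
    }
  }
  molecular_graph(do.call(rbind, at), do.call(rbind, bd))
}

#' The packaged rhodamine-6G connectivity graph
#'
#' Connectivity of the rhodamine-6G cation
#' (9-\[2-(ethoxycarbonyl)phenyl\]-3,6-bis(ethylamino)-2,7-dimethylxanthylium)
#' plus its chloride counter-ion: 28 C, 2 N, 3 O, 31 H and one Cl.  The two
#' outer xanthene rings and the pendant phenyl ring are flagged aromatic.
#'
#' @return a [molecular_graph()].
#' @export
rhodamine6g_graph <- function() {
  .mx_resource("rhodamine6g.graph", read_graph)
}

#' Classify bonded hydrogens by bond type
#'
#' Assigns each bonded hydrogen one of the four classes used for
#' hydrogen-density statistics: `methyl` (H on a carbon carrying three
#' hydrogens), `methylene` (carbon carrying two), `aromatic` (H on an
#' aromatic-flagged carbon) and `amide` (H on nitrogen).
#'
#' @param graph a [molecular_graph()].
#' @return named character vector, hydrogen label -> class.
#' @examples
#' table(classify_hydrogens(rhodamine6g_graph()))  # 15 methyl, 6 methylene, 8 aromatic, 2 amide
#' @export
classify_hydrogens <- function(graph) {
  atoms <- graph$atoms
  hlab <- atoms$label[atoms$element == "H"]
  out <- character(0)
  for (h in hlab) {
    parent <- graph_neighbors(graph, h)
    if (length(parent) != 1L)
      stop("hydrogen ", h, " must have exactly one bond")
    pel <- atoms$element[atoms$label == parent]
    if (pel == "N") {
      out[h] <- "amide"
    } else if (pel == "C") {
      if (isTRUE(atoms$aromatic[atoms$label == parent])) {
        out[h] <- "aromatic"
      } else {
        sib <- graph_neighbors(graph, parent)
        nh <- sum(atoms$element[match(sib, atoms$label)] == "H")
        out[h] <- switch(as.character(nh),
                         "3" = "methyl", "2" = "methylene",
                         stop("hydrogen ", h, " on non-aromatic carbon ",
                              parent, " with ", nh,
                              " hydrogen(s) is not classifiable"))
      }
    } else {
      stop("hydrogen ", h, " bonded to unsupported parent element ",
           pel, " (", parent, ")")
    }
  }
  out
}

#' Unit cell
#'
#' @param a,b,c cell lengths in Angstrom (positive).
#' @param alpha,beta,gamma cell angles in degrees, in (0, 180).
#' @return an object of class `unit_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c); ang <- c(alpha, beta, gamma)
  if (any(!is.finite(len)) || any(len <= 0)) stop("cell lengths must be positive")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  ca <- cos(ang[1] * pi / 180); cb <- cos(ang[2] * pi / 180)
  cg <- cos(ang[3] * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("cell angles give a non-positive-definite metric")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> %.4g/%.4g/%.4g A  %.4g/%.4g/%.4g deg  V = %.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Unit-cell volume
#'
#' Triclinic volume
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
#'   +2\cos\alpha\cos\beta\cos\gamma}}; reduces to \eqn{abc} for
#' orthorhombic cells.
#'
#' @param cell a [unit_cell()].
#' @return volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  cell$a * cell$b * cell$c *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

# fractional -> Cartesian orthogonalization matrix (a along x, b in xy plane)
cell_orth_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  cx <- cell$c * cb
  cy <- cell$c * (ca - cb * cg) / sg
  cz <- sqrt(cell$c^2 - cx^2 - cy^2)
  matrix(c(cell$a, cell$b * cg, cx,
           0,      cell$b * sg, cy,
           0,      0,           cz), nrow = 3, byrow = TRUE)
}

# real-space metric tensor G (G_ij = a_i . a_j)
cell_metric <- function(cell) {
  M <- cell_orth_matrix(cell)
  t(M) %*% M
}

# d-spacings (A) for an integer hkl matrix (n x 3)
cell_dspacing <- function(cell, hkl) {
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  Gstar <- solve(cell_metric(cell))
  inv_d2 <- rowSums((hkl %*% Gstar) * hkl)
  1 / sqrt(inv_d2)
}

#' Formula unit
#'
#' @param counts named numeric vector, element -> count per formula unit
#'   (fractional counts allowed, e.g. partial-occupancy solvent).
#' @param Z formula units per unit cell (positive integer).
#' @return an object of class `formula_unit`.
#' @export
formula_unit <- function(counts, Z = 1L) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector of element counts")
  if (any(counts < 0)) stop("element counts must be non-negative")
  if (length(Z) != 1L || Z < 1 || Z != round(Z))
    stop("Z must be a positive integer")
  structure(list(counts = counts, Z = as.integer(Z)),
            class = "formula_unit")
}

#' Calculated crystallographic density
#'
#' \eqn{D = Z M / (N_A V)} with the formula mass \eqn{M} from the packaged
#' standard atomic weights and the cell volume \eqn{V} in \eqn{cm^3}.
#'
#' @param cell a [unit_cell()].
#' @param fu a [formula_unit()].
#' @return density in g/cm^3.
#' @examples
#' sx <- unit_cell(14.88, 15.11, 23.31)
#' fu <- formula_unit(c(C = 28, H = 31, N = 2, O = 3.5, Cl = 1), Z = 8)
#' calc_density(sx, fu)  # ~1.235
#' @export
calc_density <- function(cell, fu) {
  stopifnot(inherits(fu, "formula_unit"))
  M <- sum(fu$counts * .mx_weight(names(fu$counts)))
  V_cm3 <- cell_volume(cell) * 1e-24
  fu$Z * M / .mx_avogadro / V_cm3
}
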