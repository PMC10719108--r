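# Physical constants (CODATA 2018), in the units used throughout:
# lengths in Angstrom, energies in keV, voltages in kV, B factors in A^2.
.mx_planck    <- 6.62607015e-34    # J s
.mx_clight    <- 299792458         # m/s
.mx_echarge   <- 1.602176634e-19   # C
.mx_emass     <- 9.1093837015e-31  # kg
.mx_bohr      <- 0.529177210903    # Angstrom
.mx_amu_g     <- 1.66053906660e-24 # g
.mx_avogadro  <- 6.02214076e23

# package-level cache for lazily loaded data tables
.mx_env <- new.env(parent = emptyenv())

#' Photon wavelength from energy
#'
#' \eqn{\lambda = hc/E}, the X-ray wavelength for a given photon energy.
#'
#' @param energy_keV photon energy in keV (positive).
#' @return wavelength in Angstrom.
#' @examples
#' photon_wavelength(15.0)  # 0.827 A
#' @export
photon_wavelength <- function(energy_keV) {
  if (any(!is.finite(energy_keV)) || any(energy_keV <= 0))
    stop("photon energy must be positive and finite")
  (.mx_planck * .mx_clight) / (energy_keV * 1e3 * .mx_echarge) * 1e10
}

#' Electron wavelength from accelerating voltage
#'
#' Relativistic de Broglie wavelength
#' \eqn{\lambda = h / \sqrt{2 m_0 e V (1 + eV / 2 m_0 c^2)}}.
#' The relativistic correction matters: at 300 kV it changes the
#' wavelength by more than 5 percent.
#'
#' @param voltage_kV accelerating voltage in kV (positive).
#' @param relativistic apply the relativistic correction (default TRUE).
#' @return wavelength in Angstrom.
#' @examples
#' electron_wavelength(300)  # 0.0197 A
#' @export
electron_wavelength <- function(voltage_kV, relativistic = TRUE) {
  if (any(!is.finite(voltage_kV)) || any(voltage_kV <= 0))
    stop("accelerating voltage must be positive and finite")
  V <- voltage_kV * 1e3
  p2 <- 2 * .mx_emass * .mx_echarge * V
  if (relativistic)
    p2 <- p2 * (1 + .mx_echarge * V / (2 * .mx_emass * .mx_clight^2))
  .mx_planck / sqrt(p2) * 1e10
}

# read a packaged extdata resource, cached
.mx_resource <- function(name, loader) {
  if (!is.null(.mx_env[[name]])) return(.mx_env[[name]])
  path <- system.file("extdata", name, package = "microxtal")
  if (!nzchar(path)) stop("packaged resource not found: ", name)
  .mx_env[[name]] <- loader(path)
  .mx_env[[name]]
}

#' Standard atomic weights
#'
#' IUPAC 2021 conventional atomic weights for the elements supported by the
#' package, shipped as a plain-text resource.
#'
#' @return data.frame with columns `element` and `weight` (g/mol).
#' @export
atomic_weights <- function() {
  .mx_resource("atomic_weights.txt", function(p)
    utils::read.table(p, header = TRUE, stringsAsFactors = FALSE))
}

.mx_weight <- function(element) {
  tab <- atomic_weights()
  i <- match(element, tab$element)
  if (anyNA(i))
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(i)]), collapse = ", "))
  tab$weight[i]
}

# evaluate-once seeded RNG scope: preserves the caller's RNG state
.mx_with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
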