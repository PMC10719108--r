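#' Read reflections from a SHELX HKLF-4 file
#'
#' Fixed-width dialect 3I4 (h, k, l) + 2F8.2 (intensity, sigma).  Reading
#' stops at the all-zero terminator record; data after it are ignored with
#' a warning.  Negative intensities are kept as stored; the amplitude
#' column `Fo` clamps them to zero and flags them in `clamped`.
#'
#' @param path input file.
#' @param cell,sg optional [unit_cell()] / [space_group()] to attach (gives
#'   d-spacings); plain data.frame otherwise.
#' @return a [reflection_list()] (or data.frame) with `h,k,l,I,sigma`.
#' @export
read_hkl <- function(path, cell = NULL, sg = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parse_int <- function(x, ln) {
    v <- suppressWarnings(as.integer(x))
    if (any(is.na(v))) stop("malformed HKLF-4 line ", ln, ": '", x, "'")
    v
  }
  n <- length(lines)
  h <- k <- l <- I <- sig <- numeric(n)
  stopped <- NA_integer_
  for (i in seq_len(n)) {
    ln <- lines[i]
    if (nchar(ln) < 12) stop("malformed HKLF-4 line ", i, " (too short)")
    h[i] <- parse_int(substr(ln, 1, 4), i)
    k[i] <- parse_int(substr(ln, 5, 8), i)
    l[i] <- parse_int(substr(ln, 9, 12), i)
    if (h[i] == 0 && k[i] == 0 && l[i] == 0) { stopped <- i; break }
    if (nchar(ln) < 28) stop("malformed HKLF-4 line ", i, " (too short)")
    I[i] <- suppressWarnings(as.numeric(substr(ln, 13, 20)))
    sig[i] <- suppressWarnings(as.numeric(substr(ln, 21, 28)))
    if (is.na(I[i]) || is.na(sig[i]))
      stop("malformed HKLF-4 line ", i, ": '", ln, "'")
  }
  if (!is.na(stopped)) {
    if (stopped < n)
      warning(n - stopped, " record(s) after the 0 0 0 terminator ignored")
    keep <- seq_len(stopped - 1)
  } else keep <- seq_len(n)
  df <- data.frame(h = as.integer(h[keep]), k = as.integer(k[keep]),
                   l = as.integer(l[keep]), I = I[keep], sigma = sig[keep])
  df$clamped <- df$I < 0
  df$Fo <- sqrt(pmax(df$I, 0))
  if (!is.null(cell) && !is.null(sg)) reflection_list(df, cell, sg) else df
}

#' Write reflections to a SHELX HKLF-4 file
#'
#' @param refl data.frame with `h`, `k`, `l` and `I`, `sigma` (or `Fo`,
#'   whose square is written with sigma 0).
#' @param path output file.
#' @param rescale scale intensities and sigmas by a common power of ten to
#'   fit the F8.2 field when needed (default FALSE: out-of-range values
#'   are an error).
#' @return invisibly, the path.
#' @export
write_hkl <- function(refl, path, rescale = FALSE) {
  I <- if (!is.null(refl$I)) refl$I else refl$Fo^2
  sig <- if (!is.null(refl$sigma)) refl$sigma else rep(0, nrow(refl))
  sig[is.na(sig)] <- 0
  if (rescale && length(I)) {
    mx <- max(abs(c(I, sig)))
    if (mx > 99999) {
      fac <- 10^ceiling(log10(mx / 99999))
      I <- I / fac; sig <- sig / fac
    }
  }
  hkl <- round(cbind(refl$h, refl$k, refl$l))
  if (any(abs(hkl) > 999) || any(hkl <= -1000))
    stop("index out of range for I4 field width")
  num <- function(x) {
    s <- formatC(x, format = "f", digits = 2, width = 8)
    if (any(nchar(s) > 8))
      stop("intensity/sigma out of range for F8.2 field width")
    s
  }
  recs <- paste0(formatC(hkl[, 1], width = 4), formatC(hkl[, 2], width = 4),
                 formatC(hkl[, 3], width = 4), num(I), num(sig))
  term <- paste0(paste0(formatC(c(0, 0, 0), width = 4), collapse = ""),
                 formatC(0, format = "f", digits = 2, width = 8),
                 formatC(0, format = "f", digits = 2, width = 8))
  writeLines(c(recs, term), path)
  invisible(path)
}

#' Write a minimal small-molecule CIF
#'
#' Emits cell parameters, the Hermann-Mauguin symbol and number of the
#' space group, and a site loop with label, type symbol, fractional
#' coordinates, occupancy and B_iso.
#'
#' @param structure a [crystal_structure()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_cif <- function(structure, path) {
  cell <- structure$cell; sg <- structure$sg
  hm <- c("P1" = "P 1", "P-1" = "P -1", "Pbca" = "P b c a")[sg$name]
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("data_microxtal")
  w("_cell_length_a %.6f", cell$a)
  w("_cell_length_b %.6f", cell$b)
  w("_cell_length_c %.6f", cell$c)
  w("_cell_angle_alpha %.6f", cell$alpha)
  w("_cell_angle_beta %.6f", cell$beta)
  w("_cell_angle_gamma %.6f", cell$gamma)
  w("_space_group_name_H-M_alt '%s'", hm)
  w("_space_group_IT_number %d", sg$number)
  w("loop_")
  w("_atom_site_label")
  w("_atom_site_type_symbol")
  w("_atom_site_fract_x")
  w("_atom_site_fract_y")
  w("_atom_site_fract_z")
  w("_atom_site_occupancy")
  w("_atom_site_B_iso_or_equiv")
  s <- structure$sites
  for (i in seq_len(nrow(s)))
    w("%s %s %.6f %.6f %.6f %.4f %.4f", s$label[i], s$element[i],
      s$x[i], s$y[i], s$z[i], s$occ[i], s$b[i])
  invisible(path)
}

#' Read back a CIF written by [write_cif()]
#'
#' Minimal reader for the package's own CIF dialect (cell, space group,
#' site loop); not a general CIF parser.
#'
#' @param path input file.
#' @return a [crystal_structure()] (without connectivity graph).
#' @export
read_cif <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  val <- function(tag) {
    ln <- grep(paste0("^", tag, " "), lines, value = TRUE)[1]
    sub(paste0("^", tag, " +"), "", ln)
  }
  cell <- unit_cell(as.numeric(val("_cell_length_a")),
                    as.numeric(val("_cell_length_b")),
                    as.numeric(val("_cell_length_c")),
                    as.numeric(val("_cell_angle_alpha")),
                    as.numeric(val("_cell_angle_beta")),
                    as.numeric(val("_cell_angle_gamma")))
  hm <- gsub("'", "", val("_space_group_name_H-M_alt"))
  name <- c("P 1" = "P1", "P -1" = "P-1", "P b c a" = "Pbca")[hm]
  if (is.na(name)) stop("unsupported space group in CIF: ", hm)
  iloop <- which(lines == "loop_")[1]
  tags <- grep("^_atom_site", lines, value = TRUE)
  body <- lines[(iloop + length(tags) + 1):length(lines)]
  body <- body[nzchar(body)]
  toks <- strsplit(body, "[[:space:]]+")
  sites <- do.call(rbind, lapply(toks, function(tk)
    data.frame(label = tk[1], element = tk[2],
               x = as.numeric(tk[3]), y = as.numeric(tk[4]),
               z = as.numeric(tk[5]), occ = as.numeric(tk[6]),
               b = as.numeric(tk[7]))))
  crystal_structure(cell, space_group(name), sites)
}
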