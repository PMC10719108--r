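#' Measure a hydrogen peak in a sigma-scaled omit map
#'
#' Samples the map along the parent-to-hydrogen bond direction by trilinear
#' interpolation (step <= 0.02 A), locates the peak inside the search
#' window by parabolic sub-grid interpolation, and measures the peak height
#' above the estimated base level.  The default base level is the profile
#' minimum between the parent atom and the peak; alternatively the value at
#' a fixed 0.5 A from the parent can be used.
#'
#' @param map a sigma-normalized [map_grid()].
#' @param structure a [crystal_structure()] with an attached graph.
#' @param h_label hydrogen site label.
#' @param window search window along the bond, A from the parent
#'   (default c(0.5, 1.6), excluding the parent's own peak).
#' @param step profile sampling step in A (default 0.02).
#' @param threshold observation threshold in sigma (default 1.5).
#' @param base base-level estimator, `"min_profile"` or `"fixed"`.
#' @return one-row data.frame (class `h_peak_record`): `label`, `class`,
#'   `parent`, `offset` (A), `height` (sigma), `observed`, `model_offset`.
#' @export
measure_h_peak <- function(map, structure, h_label,
                           window = c(0.5, 1.6), step = 0.02,
                           threshold = 1.5,
                           base = c("min_profile", "fixed")) {
  base <- match.arg(base)
  if (!identical(map$units, "sigma"))
    stop("map must be sigma-normalized (see sigma_normalize())")
  s <- structure$sites
  i <- match(h_label, s$label)
  if (is.na(i)) stop("hydrogen ", h_label, " not in structure")
  parent <- h_parent_label(structure, h_label)
  p <- match(parent, s$label)
  if (is.na(p)) stop("parent ", parent, " not in structure")
  cls <- classify_hydrogens(structure$graph)[[h_label]]

  M <- cell_orth_matrix(structure$cell)
  xp <- unlist(s[p, c("x", "y", "z")])
  dfr <- unlist(s[i, c("x", "y", "z")]) - xp
  dfr <- dfr - round(dfr)
  v <- as.numeric(M %*% dfr)
  blen <- sqrt(sum(v^2))
  u_frac <- dfr / blen               # fractional step per A along the bond

  offs <- seq(0, window[2] + 2 * step, by = step)
  frac <- sweep(outer(offs, u_frac), 2, xp, `+`)
  prof <- map_interpolate(map, frac)
  pk <- find_peak(bond_profile(offs, prof, "sigma"), window = window)

  if (!pk$interior) {
    rec <- data.frame(label = h_label, class = cls, parent = parent,
                      offset = NA_real_, height = NA_real_,
                      observed = FALSE, model_offset = blen)
  } else {
    base_level <- if (base == "min_profile")
      min(prof[offs >= 0 & offs <= pk$offset])
    else prof[which.min(abs(offs - 0.5))]
    height <- pk$value - base_level
    rec <- data.frame(label = h_label, class = cls, parent = parent,
                      offset = pk$offset, height = height,
                      observed = height > threshold, model_offset = blen)
  }
  class(rec) <- c("h_peak_record", "data.frame")
  rec
}

#' Measure all hydrogens of a structure in an omit map
#'
#' @inheritParams measure_h_peak
#' @param labels hydrogen labels to measure (default: all H sites).
#' @return data.frame of [measure_h_peak()] records.
#' @export
measure_all_h_peaks <- function(map, structure, labels = NULL, ...) {
  s <- structure$sites
  if (is.null(labels)) labels <- s$label[s$element == "H"]
  do.call(rbind, lapply(labels, function(h)
    measure_h_peak(map, structure, h, ...)))
}

#' Per-class summary of hydrogen peak records
#'
#' For each hydrogen class reports N_all, N_obs (height above threshold),
#' and the mean and standard deviation of the observed peak offsets, as in
#' hydrogen-density summary tables.
#'
#' @param records data.frame of peak records ([measure_all_h_peaks()]).
#' @param threshold observation threshold in sigma units (default 1.5).
#' @return data.frame with one row per class: `class`, `n_all`, `n_obs`,
#'   `mean_offset`, `sd_offset`.
#' @export
summarize_h_peaks <- function(records, threshold = 1.5) {
  obs <- !is.na(records$height) & records$height > threshold
  out <- lapply(split(seq_len(nrow(records)), records$class), function(idx) {
    o <- idx[obs[idx]]
    data.frame(class = records$class[idx[1]],
               n_all = length(idx), n_obs = length(o),
               mean_offset = if (length(o)) mean(records$offset[o]) else NA_real_,
               sd_offset = if (length(o) >= 2) stats::sd(records$offset[o])
                           else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-class peak-offset differences between two paired maps
#'
#' Pairs records by hydrogen label, keeps hydrogens observed in both, and
#' averages the per-hydrogen difference `alt - ref` within each class (the
#' "observed in both" convention).  With `ref` the electron-density (X-ray)
#' records and `alt` the Coulomb-potential (electron) records a positive
#' delta means the potential peak sits further from the parent.
#'
#' @param ref,alt data.frames of peak records.
#' @param threshold observation threshold in sigma.
#' @return data.frame with `class`, `n_both`, `delta` (A, mean alt - ref).
#' @export
delta_peaks <- function(ref, alt, threshold = 1.5) {
  keyed <- merge(ref, alt, by = "label", suffixes = c("_ref", "_alt"))
  both <- !is.na(keyed$height_ref) & keyed$height_ref > threshold &
          !is.na(keyed$height_alt) & keyed$height_alt > threshold
  keyed <- keyed[both, , drop = FALSE]
  d <- keyed$offset_alt - keyed$offset_ref
  out <- lapply(split(seq_len(nrow(keyed)), keyed$class_ref), function(idx)
    data.frame(class = keyed$class_ref[idx[1]], n_both = length(idx),
               delta = mean(d[idx])))
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(class = character(), n_both = integer(),
                                      delta = numeric())
  rownames(out) <- NULL
  out
}
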