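#' Still-frame container
#'
#' A `frame_set` is a list of frames, each a list with `id`, `orientation`
#' (unit quaternion, w-x-y-z), `spots` (data.frame `h`, `k`, `l`, `I`,
#' `sigma`), `max_pixel` (detector max-pixel proxy) and `beam_on`.
#'
#' @param frames list of frame lists.
#' @param cell the [unit_cell()] shared by all frames.
#' @param sg the [space_group()].
#' @param wavelength beam wavelength in A.
#' @return object of class `frame_set`.
#' @export
frame_set <- function(frames, cell, sg, wavelength) {
  structure(list(frames = frames, cell = cell, sg = sg,
                 wavelength = wavelength), class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  ns <- vapply(x$frames, function(f) nrow(f$spots), integer(1))
  cat("<frame_set> ", length(x$frames), " frames, ",
      sum(ns), " spots (", min(ns), "-", max(ns), " per frame), lambda ",
      signif(x$wavelength, 3), " A\n", sep = "")
  invisible(x)
}

#' Hit filtering of still frames
#'
#' Keeps frames whose detector max-pixel proxy exceeds `min_max_pixel`
#' (frames with no strong pixel are discarded) and whose spot count lies in
#' `[min_spots, max_spots]` (too few or too many spots defeat indexing);
#' frames recorded with the beam down are always dropped.
#'
#' @param frames a [frame_set()].
#' @param min_spots,max_spots inclusive spot-count bounds (defaults 30, 300).
#' @param min_max_pixel max-pixel threshold (default 1000, exclusive).
#' @return the filtered [frame_set()].
#' @export
hit_filter <- function(frames, min_spots = 30, max_spots = 300,
                       min_max_pixel = 1000) {
  keep <- vapply(frames$frames, function(f) {
    isTRUE(f$beam_on) && f$max_pixel > min_max_pixel &&
      nrow(f$spots) >= min_spots && nrow(f$spots) <= max_spots
  }, logical(1))
  frames$frames <- frames$frames[keep]
  frames
}

#' Highest resolution recorded on a frame
#'
#' \eqn{s_{max} = \sin\theta_{max}/\lambda}, the largest scattering-vector
#' magnitude among the frame's spots.
#'
#' @param frame one frame (element of a [frame_set()]`$frames`).
#' @param cell the [unit_cell()].
#' @return s_max in 1/A, or NA for an empty frame.
#' @export
frame_smax <- function(frame, cell) {
  if (nrow(frame$spots) == 0) return(NA_real_)
  d <- cell_dspacing(cell, as.matrix(frame$spots[c("h", "k", "l")]))
  max(1 / (2 * d))
}

# flat observation table (frame_id, h, k, l canonicalized, I, sigma)
.mx_observations <- function(frames) {
  sg <- frames$sg
  obs <- do.call(rbind, lapply(frames$frames, function(f) {
    if (nrow(f$spots) == 0) return(NULL)
    cbind(frame = f$id, f$spots)
  }))
  if (is.null(obs) || nrow(obs) == 0) stop("no observations to merge")
  canon <- canonical_hkl(as.matrix(obs[c("h", "k", "l")]), sg)
  obs$h <- canon[, 1]; obs$k <- canon[, 2]; obs$l <- canon[, 3]
  obs$key <- paste(obs$h, obs$k, obs$l)
  obs
}

.mx_merge_obs <- function(obs) {
  sp <- split(seq_len(nrow(obs)), obs$key)
  df <- do.call(rbind, lapply(sp, function(idx) {
    I <- obs$I[idx]
    n <- length(I)
    data.frame(h = obs$h[idx[1]], k = obs$k[idx[1]], l = obs$l[idx[1]],
               I = mean(I),
               sigma = if (n >= 2) stats::sd(I) / sqrt(n) else NA_real_,
               multiplicity = n)
  }))
  rownames(df) <- NULL
  df
}

#' Monte-Carlo merging of still-frame partial intensities
#'
#' Merges all observations of each symmetry-unique reflection (Laue group
#' of the frame set's space group, Friedel mates included) by the
#' unweighted mean, the Monte-Carlo estimate whose partiality and scale
#' fluctuations average out over many frames.  The uncertainty is the
#' standard error of the mean.  Odd- and even-indexed frames are also
#' merged separately into two half-sets for precision statistics.
#'
#' @param frames a [frame_set()].
#' @return object of class `merged_data`: list with `merged` (data.frame
#'   `h, k, l, I, sigma, multiplicity`), `half1`, `half2` (same shape),
#'   `cell`, `sg`.
#' @export
monte_carlo_merge <- function(frames) {
  obs <- .mx_observations(frames)
  fr_ids <- vapply(frames$frames, `[[`, numeric(1), "id")
  parity <- stats::setNames(seq_along(fr_ids) %% 2, fr_ids)
  p <- parity[as.character(obs$frame)]
  out <- list(merged = .mx_merge_obs(obs),
              half1 = .mx_merge_obs(obs[p == 1, , drop = FALSE]),
              half2 = .mx_merge_obs(obs[p == 0, , drop = FALSE]),
              cell = frames$cell, sg = frames$sg)
  class(out) <- "merged_data"
  out
}

#' @export
print.merged_data <- function(x, ...) {
  cat("<merged_data> ", nrow(x$merged), " unique reflections, mean multiplicity ",
      round(mean(x$merged$multiplicity), 1), "\n", sep = "")
  invisible(x)
}

# pair two half-set tables on their common reflections
.mx_pair_halves <- function(half1, half2) {
  m <- merge(half1, half2, by = c("h", "k", "l"), suffixes = c("1", "2"))
  if (nrow(m) == 0) stop("half-sets share no reflections")
  m
}

#' R_split between two half datasets
#'
#' \deqn{R_{split} = 2^{-1/2} \frac{\sum |I_1 - I_2|}
#'   {\tfrac12 \sum (I_1 + I_2)} \times 100}
#'
#' the standard still-merging precision metric (the \eqn{2^{-1/2}} factor
#' corrects for each half having half the multiplicity).
#'
#' @param half1,half2 half-set data.frames with `h`, `k`, `l`, `I`.
#' @return R_split in percent.
#' @export
rsplit <- function(half1, half2) {
  m <- .mx_pair_halves(half1, half2)
  100 * (1 / sqrt(2)) * sum(abs(m$I1 - m$I2)) / (0.5 * sum(m$I1 + m$I2))
}

#' CC_1/2 between two half datasets
#'
#' Pearson correlation coefficient of the half-set mean intensities over
#' their common reflections.
#'
#' @inheritParams rsplit
#' @return correlation in \[-1, 1\].
#' @export
cc_half <- function(half1, half2) {
  m <- .mx_pair_halves(half1, half2)
  if (nrow(m) < 3) stop("need at least 3 common reflections for CC_1/2")
  stats::cor(m$I1, m$I2)
}

#' R_merge over multiply observed reflections
#'
#' \deqn{R_{merge} = \frac{\sum_{hkl}\sum_i |I_i - \langle I \rangle|}
#'   {\sum_{hkl}\sum_i I_i} \times 100}
#'
#' @param frames a [frame_set()] (all observations before merging).
#' @return R_merge in percent.
#' @export
rmerge <- function(frames) {
  obs <- .mx_observations(frames)
  sp <- split(obs$I, obs$key)
  if (!any(lengths(sp) >= 2)) stop("no reflection has multiplicity >= 2")
  num <- sum(vapply(sp, function(I) sum(abs(I - mean(I))), numeric(1)))
  den <- sum(obs$I)
  100 * num / den
}

#' Completeness, multiplicity and I/sigma of a merged dataset
#'
#' Completeness is the fraction of possible symmetry-unique reflections
#' (from [generate_unique_hkl()]) actually observed; reported overall and
#' in the outermost of `n_bins` equal-volume resolution shells, together
#' with mean multiplicity and mean I/sigma.
#'
#' @param merged a `merged_data` object ([monte_carlo_merge()]).
#' @param d_min,d_max resolution range matching the generation.
#' @param n_bins number of equal-volume resolution shells (default 10).
#' @return list with `completeness`, `completeness_outer` (percent),
#'   `multiplicity`, `multiplicity_outer`, `i_over_sigma`, `n_possible`,
#'   `n_observed`.
#' @export
completeness_multiplicity <- function(merged, d_min, d_max = Inf, n_bins = 10) {
  poss <- generate_unique_hkl(merged$cell, merged$sg, d_min, d_max)
  pk <- paste(poss$h, poss$k, poss$l)
  mk <- paste(merged$merged$h, merged$merged$k, merged$merged$l)
  inrange <- mk %in% pk
  mtab <- merged$merged[inrange, , drop = FALSE]
  mk <- mk[inrange]
  # equal reciprocal-volume shells in 1/d^3
  v <- 1 / poss$d^3
  vmax <- max(v); vmin <- min(v)
  outer_sel <- v >= vmin + (vmax - vmin) * (n_bins - 1) / n_bins
  ok_outer <- pk[outer_sel] %in% mk
  isig <- mtab$I / mtab$sigma
  list(completeness = 100 * length(unique(mk)) / nrow(poss),
       completeness_outer = 100 * mean(ok_outer),
       multiplicity = mean(mtab$multiplicity),
       multiplicity_outer = mean(mtab$multiplicity[mk %in% pk[outer_sel]]),
       i_over_sigma = mean(isig[is.finite(isig)]),
       n_possible = nrow(poss), n_observed = length(unique(mk)))
}
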