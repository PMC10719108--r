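#' Write / read a frame set as JSON lines
#'
#' One JSON object per line: a header record with cell, space group and
#' wavelength, then one record per frame (id, orientation quaternion,
#' max-pixel proxy, beam flag, spot table).  A plain-text, diff-friendly
#' interchange format for simulated still frames.
#'
#' @param frames a [frame_set()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_frames <- function(frames, path) {
  con <- file(path, "w"); on.exit(close(con))
  hdr <- list(type = "header",
              cell = unclass(frames$cell)[c("a", "b", "c", "alpha", "beta",
                                            "gamma")],
              sg = frames$sg$name, wavelength = frames$wavelength)
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA), con)
  for (f in frames$frames) {
    rec <- list(type = "frame", id = f$id, orientation = f$orientation,
                max_pixel = f$max_pixel, beam_on = f$beam_on,
                spots = f$spots)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns"), con)
  }
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- jsonlite::fromJSON(lines[1])
  if (!identical(hdr$type, "header")) stop("missing frame-file header")
  cell <- unit_cell(hdr$cell$a, hdr$cell$b, hdr$cell$c,
                    hdr$cell$alpha, hdr$cell$beta, hdr$cell$gamma)
  sg <- space_group(hdr$sg)
  frames <- lapply(lines[-1], function(ln) {
    r <- jsonlite::fromJSON(ln)
    spots <- as.data.frame(r$spots)
    if (nrow(spots) == 0)
      spots <- data.frame(h = integer(), k = integer(), l = integer(),
                          I = numeric(), sigma = numeric())
    list(id = r$id, orientation = as.numeric(r$orientation),
         spots = spots, max_pixel = r$max_pixel, beam_on = r$beam_on)
  })
  frame_set(frames, cell, sg, hdr$wavelength)
}
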