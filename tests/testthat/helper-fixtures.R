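# shared in-code fixtures for the test suite

benzene_graph <- function() {
  cl <- paste0("C", 1:6); hl <- paste0("H", 1:6)
  molecular_graph(
    atoms = data.frame(label = c(cl, hl),
                       element = rep(c("C", "H"), each = 6),
                       aromatic = rep(c(TRUE, FALSE), each = 6)),
    bonds = data.frame(from = c(cl, hl), to = c(cl[c(2:6, 1)], cl),
                       aromatic = c(rep(TRUE, 6), rep(FALSE, 6))))
}

ethane_graph <- function() {
  molecular_graph(
    atoms = data.frame(label = c("C1", "C2", paste0("H", 1:6)),
                       element = c("C", "C", rep("H", 6))),
    bonds = data.frame(from = c("C1", paste0("H", 1:3), paste0("H", 4:6)),
                       to = c("C2", rep("C1", 3), rep("C2", 3))))
}

random_valid_cell <- function() {
  repeat {
    ang <- stats::runif(3, 60, 120)
    ok <- tryCatch({
      cl <- unit_cell(stats::runif(1, 5, 30), stats::runif(1, 5, 30),
                      stats::runif(1, 5, 30), ang[1], ang[2], ang[3])
      return(cl)
    }, error = function(e) NULL)
  }
}

random_structure <- function(n_atoms, cell, sg,
                             elements = c("C", "N", "O")) {
  crystal_structure(cell, sg, data.frame(
    label = paste0("A", seq_len(n_atoms)),
    element = sample(elements, n_atoms, replace = TRUE),
    x = stats::runif(n_atoms), y = stats::runif(n_atoms),
    z = stats::runif(n_atoms), b = stats::runif(n_atoms, 1, 6)))
}

# independent brute-force structure factor: explicit double loop over
# operators and sites, no shared code with calc_structure_factors
brute_force_sf <- function(structure, hkl, radiation = "xray") {
  out <- complex(real = numeric(nrow(hkl)))
  for (i in seq_len(nrow(hkl))) {
    h <- c(hkl$h[i], hkl$k[i], hkl$l[i])
    s <- hkl$s[i]
    acc <- 0 + 0i
    for (o in structure$sg$ops) {
      for (j in seq_len(nrow(structure$sites))) {
        sj <- structure$sites[j, ]
        f <- if (radiation == "xray") xray_form_factor(sj$element, s)
             else electron_form_factor(sj$element, s)
        xj <- o$R %*% c(sj$x, sj$y, sj$z) + o$t
        acc <- acc + sj$occ * f * exp(-sj$b * s^2) *
          exp(2i * pi * sum(h * xj))
      }
    }
    out[i] <- acc
  }
  out
}

# frame set with every reflection observed in every frame under fractional
# Gaussian noise: the partiality-width -> infinity limit of a still
# simulation, used for controlled merging-statistics tests
noisy_obs_frames <- function(n_frames, noise, seed, n_refl = 60) {
  cell <- unit_cell(8, 9, 10)
  sg <- space_group("P1")
  hkl <- generate_unique_hkl(cell, sg, 1.5)[seq_len(n_refl), ]
  Itrue <- seq(100, 2000, length.out = n_refl)
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(i) {
    I <- Itrue * (1 + rnorm(n_refl, 0, noise))
    list(id = i, orientation = c(1, 0, 0, 0),
         spots = data.frame(h = hkl$h, k = hkl$k, l = hkl$l, I = I,
                            sigma = noise * Itrue),
         max_pixel = max(I), beam_on = TRUE)
  })
  frame_set(frames, cell, sg, 0.827)
}

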