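test_that("space-group operator sets are closed groups of the right order", {
  for (nm in c("P1", "P-1", "Pbca")) {
    sg <- space_group(nm)
    n <- c(P1 = 1, `P-1` = 2, Pbca = 8)[[nm]]
    expect_length(sg$ops, n)
    key <- function(R, t) paste(c(R, round(t %% 1, 9)), collapse = ",")
    keys <- vapply(sg$ops, function(o) key(o$R, o$t), "")
    expect_true(key(diag(3), c(0, 0, 0)) %in% keys)
    for (a in sg$ops) for (b in sg$ops) {
      R <- a$R %*% b$R; t <- (a$R %*% b$t + a$t) %% 1
      expect_true(key(R, t) %in% keys)
    }
  }
})

test_that("unique reflection generation respects resolution and symmetry", {
  cl <- unit_cell(10, 10, 10)
  u <- generate_unique_hkl(cl, space_group("P1"), 5, 100)
  expect_true(any(u$h == 2 & u$k == 0 & u$l == 0 & abs(u$d - 5) < 1e-9) ||
              any(abs(u$d - 5) < 1e-9))
  expect_true(all(u$d >= 5))
  expect_false(any(u$h == 0 & u$k == 0 & u$l == 0))
  expect_equal(u$s, 1 / (2 * u$d))
  expect_error(generate_unique_hkl(cl, space_group("P1"), 5, 2), "d_min")
})

test_that("Pbca systematic absences follow the glide extinction rules", {
  sg <- space_group("Pbca")
  # 0kl: k odd; h0l: l odd; hk0: h odd
  expect_true(microxtal:::hkl_absent(rbind(c(0, 1, 1)), sg))
  expect_true(microxtal:::hkl_absent(rbind(c(1, 0, 1)), sg))
  expect_true(microxtal:::hkl_absent(rbind(c(1, 1, 0)), sg))
  expect_false(microxtal:::hkl_absent(rbind(c(0, 2, 1)), sg))
  expect_false(microxtal:::hkl_absent(rbind(c(1, 2, 3)), sg))
  # absent classes have numerically zero structure factor
  set.seed(7)
  cl <- unit_cell(9, 11, 13)
  absent <- data.frame(h = c(0, 0, 3, 5, 1, 7),
                       k = c(1, 3, 0, 0, 1, 3),
                       l = c(1, 5, 1, 3, 0, 0))
  absent$d <- microxtal:::cell_dspacing(cl, as.matrix(absent))
  for (i in 1:50) {
    st <- random_structure(4, cl, sg)
    Fa <- calc_structure_factors(st, absent, "xray")
    hkl <- generate_unique_hkl(cl, sg, 1.5)
    Fmax <- max(Mod(calc_structure_factors(st, hkl, "xray")))
    expect_lt(max(Mod(Fa)), 1e-8 * Fmax)
  }
})

test_that("unique-reflection count is close to the published rt-ED count", {
  u <- generate_unique_hkl(unit_cell(14.74, 15.05, 22.88),
                           space_group("Pbca"), 0.90, 11.44)
  expect_lt(abs(nrow(u) - 3651) / 3651, 0.02)
})

test_that("direct summation matches an independent brute-force oracle", {
  set.seed(11)
  for (sgn in c("P1", "P-1", "Pbca")) {
    sg <- space_group(sgn)
    cl <- unit_cell(8, 9, 10)
    st <- random_structure(if (sgn == "P1") 10 else 4, cl, sg)
    hkl <- generate_unique_hkl(cl, sg, 1.8)
    hkl <- hkl[seq_len(min(40, nrow(hkl))), ]
    F1 <- calc_structure_factors(st, hkl, "xray")
    F2 <- brute_force_sf(st, hkl, "xray")
    expect_lt(max(Mod(F1 - F2)) / max(Mod(F2)), 1e-8)
  }
})

test_that("single neutral atom at the origin gives phase-zero factors", {
  st <- crystal_structure(unit_cell(8, 8, 8), space_group("P1"),
                          data.frame(label = "C1", element = "C",
                                     x = 0, y = 0, z = 0, b = 0))
  hkl <- generate_unique_hkl(st$cell, st$sg, 1.2)
  Fh <- calc_structure_factors(st, hkl, "xray")
  expect_lt(max(abs(Arg(Fh))), 1e-10)
  expect_equal(Mod(Fh), xray_form_factor("C", hkl$s), tolerance = 1e-10)
})

test_that("centrosymmetric structures give real structure factors", {
  set.seed(3)
  st <- random_structure(5, unit_cell(9, 10, 11), space_group("P-1"))
  hkl <- generate_unique_hkl(st$cell, st$sg, 1.5)
  Fh <- calc_structure_factors(st, hkl, "xray")
  expect_lt(max(abs(Im(Fh))) / max(Mod(Fh)), 1e-10)
})

test_that("Friedel mates are conjugate", {
  set.seed(4)
  st <- random_structure(6, unit_cell(8, 9, 10), space_group("P1"))
  hkl <- data.frame(h = c(1, 2, 3), k = c(2, -1, 0), l = c(3, 1, -2))
  hkl$d <- microxtal:::cell_dspacing(st$cell, as.matrix(hkl))
  minus <- hkl; minus[c("h", "k", "l")] <- -minus[c("h", "k", "l")]
  expect_equal(calc_structure_factors(st, minus, "xray"),
               Conj(calc_structure_factors(st, hkl, "xray")),
               tolerance = 1e-10)
})

test_that("map synthesis satisfies the Fourier identities", {
  st <- crystal_structure(unit_cell(8, 8, 8), space_group("P1"),
                          data.frame(label = "C1", element = "C",
                                     x = 0.25, y = 0.25, z = 0.25, b = 2))
  hkl <- generate_unique_hkl(st$cell, st$sg, 0.8)
  Fh <- calc_structure_factors(st, hkl, "xray")
  m <- synthesize_map(hkl, Fh)
  # global maximum within one grid step of the atom
  pk <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
  expect_true(all(abs((pk - 1) / m$dim - 0.25) <= 1 / min(m$dim)))
  # Parseval over the expanded sphere
  ex <- microxtal:::.mx_expand_reflections(hkl, Fh, st$sg)
  V <- cell_volume(st$cell)
  expect_equal(mean(m$values^2), sum(Mod(ex$F)^2) / V^2, tolerance = 1e-8)
  # F(000) alone gives a constant map
  h0 <- data.frame(h = 0, k = 0, l = 0, d = Inf)
  m0 <- synthesize_map(reflection_list(h0, st$cell, st$sg),
                       complex(real = V), grid_dim = c(4, 4, 4))
  expect_equal(range(m0$values), c(1, 1), tolerance = 1e-12)
  # aliasing grids are rejected
  expect_error(synthesize_map(hkl, Fh, grid_dim = c(8, 8, 8)), "alias")
})

test_that("difference maps vanish for a complete model and locate omitted
           atoms", {
  set.seed(9)
  st <- random_structure(6, unit_cell(9, 9, 9), space_group("P1"))
  hkl <- generate_unique_hkl(st$cell, st$sg, 1.0)
  Fo <- Mod(calc_structure_factors(st, hkl, "xray"))
  m0 <- difference_map(Fo, hkl, st)
  expect_lt(max(abs(m0$values)), 1e-10)
  # omitting one atom puts the strongest peak at that atom
  m1 <- difference_map(Fo, hkl, st, omit = "A3")
  pk <- which(m1$values == max(m1$values), arr.ind = TRUE)[1, ]
  frac <- (pk - 1) / m1$dim
  target <- unlist(st$sites[st$sites$label == "A3", c("x", "y", "z")])
  dd <- abs(frac - target); dd <- pmin(dd, 1 - dd)
  expect_true(all(dd <= 1.5 / min(m1$dim)))
  expect_error(difference_map(Fo, hkl, st, omit = "nope"), "omit")
})

test_that("sigma normalization gives mean 0, rms 1 and scale invariance", {
  set.seed(21)
  v <- array(rnorm(40^3), c(40, 40, 40))
  m <- map_grid(v, unit_cell(10, 10, 10))
  sm <- sigma_normalize(m)
  expect_lt(abs(mean(sm$values)), 1e-12)
  expect_equal(sqrt(mean(sm$values^2)), 1, tolerance = 1e-12)
  sm7 <- sigma_normalize(map_grid(7 * v, m$cell))
  expect_equal(sm$values, sm7$values, tolerance = 1e-12)
  # normal upper tail above 3 sigma ~ 0.135%
  expect_lt(abs(mean(sm$values > 3) - stats::pnorm(3, lower.tail = FALSE)),
            5e-4)
  expect_error(sigma_normalize(map_grid(array(1, c(4, 4, 4)), m$cell)),
               "constant")
})

test_that("R1 behaves under scaling and multiplicative noise", {
  set.seed(31)
  Fc <- runif(1000, 1, 50)
  expect_equal(r_factor(Fc, Fc)$R1_all, 0)
  expect_equal(r_factor(2 * Fc, Fc)$R1_all, 0, tolerance = 1e-12)
  # 10% uniform multiplicative noise: R1 ~ E|1-u| = 0.05
  u <- runif(1000, 0.9, 1.1)
  r <- r_factor(Fc * u, Fc)$R1_all
  expect_gt(r, 0.04); expect_lt(r, 0.065)
  # strong subset selection with mixed-precision sigmas
  sig <- runif(1000, 0.1, 0.4) * Fc
  rr <- r_factor(Fc * u, Fc, sig_Fo = sig, threshold = 4)
  expect_lt(rr$n_strong, rr$n_all)
  expect_gt(rr$n_strong, 0)
  expect_error(r_factor(Fc, Fc, sig_Fo = Fc, threshold = 4), "empty")
})

test_that("riding hydrogens are repositioned along unchanged directions", {
  st <- build_toy_structure("planar_ring")
  long <- set_riding_hydrogens(st, c(aromatic = 1.083))
  M <- microxtal:::cell_orth_matrix(st$cell)
  for (i in 1:6) {
    h <- paste0("H", i); cc <- paste0("C", i)
    v0 <- M %*% (unlist(st$sites[st$sites$label == h, c("x", "y", "z")]) -
                 unlist(st$sites[st$sites$label == cc, c("x", "y", "z")]))
    v1 <- M %*% (unlist(long$sites[long$sites$label == h, c("x", "y", "z")]) -
                 unlist(long$sites[long$sites$label == cc, c("x", "y", "z")]))
    expect_equal(sqrt(sum(v1^2)), 1.083, tolerance = 1e-9)
    expect_equal(as.numeric(v1 / sqrt(sum(v1^2))),
                 as.numeric(v0 / sqrt(sum(v0^2))), tolerance = 1e-9)
  }
  # identity map leaves the structure unchanged
  same <- set_riding_hydrogens(st, c(aromatic = 1.08))
  expect_equal(same$sites$x, st$sites$x, tolerance = 1e-12)
})

test_that("elongated riding model fits long-H truth better", {
  st <- build_toy_structure("planar_ring")          # C-H 1.08
  long_truth <- set_riding_hydrogens(st, c(aromatic = 1.183))
  short_model <- set_riding_hydrogens(st, c(aromatic = 0.983))
  hkl <- generate_unique_hkl(st$cell, st$sg, 0.9)
  Fo <- Mod(calc_structure_factors(long_truth, hkl, "electron"))
  r_long <- r_factor(Fo, calc_structure_factors(long_truth, hkl, "electron"))
  r_short <- r_factor(Fo, calc_structure_factors(short_model, hkl, "electron"))
  expect_lt(r_long$R1_all, r_short$R1_all)
})
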