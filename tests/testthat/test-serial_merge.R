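
test_that("hit filtering applies the spot-count and pixel rules", {
  cell <- unit_cell(8, 9, 10); sg <- space_group("P1")
  mk <- function(id, nspots, maxpix = 5000, beam = TRUE) {
    list(id = id, orientation = c(1, 0, 0, 0),
         spots = data.frame(h = rep(1, nspots), k = 2, l = 3,
                            I = 10, sigma = 1),
         max_pixel = maxpix, beam_on = beam)
  }
  fr <- frame_set(list(mk(1, 29), mk(2, 30), mk(3, 300), mk(4, 301),
                       mk(5, 100, maxpix = 0), mk(6, 100, beam = FALSE),
                       mk(7, 100)),
                  cell, sg, 0.827)
  kept <- hit_filter(fr)
  expect_equal(vapply(kept$frames, `[[`, numeric(1), "id"), c(2, 3, 7))
})

test_that("frame s_max is the highest recorded scattering vector", {
  cell <- unit_cell(10, 10, 10)
  f <- list(id = 1, orientation = c(1, 0, 0, 0),
            spots = data.frame(h = 10, k = 0, l = 0, I = 1, sigma = 1),
            max_pixel = 2000, beam_on = TRUE)
  expect_equal(frame_smax(f, cell), 0.5)  # d = 1 A -> s = 0.5
  f0 <- f; f0$spots <- f0$spots[0, ]
  expect_true(is.na(frame_smax(f0, cell)))
})

test_that("merging exact observations returns the truth with half-set
           identity", {
  fr <- noisy_obs_frames(8, noise = 0, seed = 1)
  mg <- monte_carlo_merge(fr)
  expect_equal(sort(mg$merged$I), sort(seq(100, 2000, length.out = 60)))
  expect_equal(mg$merged$multiplicity, rep(8, 60))
  expect_equal(rsplit(mg$half1, mg$half2), 0)
  expect_equal(cc_half(mg$half1, mg$half2), 1)
})

test_that("merged results are invariant to frame order and Laue
           re-indexing", {
  fr <- noisy_obs_frames(10, noise = 0.2, seed = 2)
  mg1 <- monte_carlo_merge(fr)
  fr2 <- fr; fr2$frames <- rev(fr2$frames)
  mg2 <- monte_carlo_merge(fr2)
  o1 <- mg1$merged[order(mg1$merged$h, mg1$merged$k, mg1$merged$l), ]
  o2 <- mg2$merged[order(mg2$merged$h, mg2$merged$k, mg2$merged$l), ]
  expect_equal(o1$I, o2$I, tolerance = 1e-12)
  # flipping every observation to its Friedel mate merges identically
  fr3 <- fr
  fr3$frames <- lapply(fr3$frames, function(f) {
    f$spots[c("h", "k", "l")] <- -f$spots[c("h", "k", "l")]
    f
  })
  mg3 <- monte_carlo_merge(fr3)
  o3 <- mg3$merged[order(mg3$merged$h, mg3$merged$k, mg3$merged$l), ]
  expect_equal(o1$I, o3$I, tolerance = 1e-12)
})

test_that("R_split is zero on identical halves, symmetric, and permutation
           invariant", {
  fr <- noisy_obs_frames(12, noise = 0.3, seed = 3)
  mg <- monte_carlo_merge(fr)
  expect_equal(rsplit(mg$half1, mg$half1), 0)
  expect_equal(rsplit(mg$half1, mg$half2), rsplit(mg$half2, mg$half1))
  perm <- mg$half2[sample(nrow(mg$half2)), ]
  expect_equal(rsplit(mg$half1, perm), rsplit(mg$half1, mg$half2))
})

test_that("R_split scales as 1/sqrt(multiplicity)", {
  rs <- vapply(c(8, 32, 128), function(n) {
    vals <- vapply(1:6, function(rep)
      rsplit_of <- {
        mg <- monte_carlo_merge(noisy_obs_frames(2 * n, 0.25,
                                                 seed = 1000 * n + rep))
        rsplit(mg$half1, mg$half2)
      }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_equal(rs[1] / rs[2], 2, tolerance = 0.2 * 2)
  expect_equal(rs[2] / rs[3], 2, tolerance = 0.2 * 2)
})

test_that("CC_1/2 rises to one and R_split falls to zero as noise
           vanishes", {
  noise <- c(0.5, 0.2, 0.05, 0.01, 0)
  cc <- numeric(length(noise)); rs <- numeric(length(noise))
  for (i in seq_along(noise)) {
    mg <- monte_carlo_merge(noisy_obs_frames(16, noise[i], seed = 42))
    cc[i] <- cc_half(mg$half1, mg$half2)
    rs[i] <- rsplit(mg$half1, mg$half2)
  }
  expect_true(all(diff(cc) >= -1e-12))
  expect_true(all(diff(rs) <= 1e-12))
  expect_equal(cc[length(cc)], 1)
  expect_equal(rs[length(rs)], 0)
  # independent pure-noise halves decorrelate
  set.seed(9)
  h1 <- data.frame(h = 1:50, k = 0, l = 0, I = rnorm(50))
  h2 <- data.frame(h = 1:50, k = 0, l = 0, I = rnorm(50))
  expect_lt(abs(cc_half(h1, h2)), 0.35)
})

test_that("R_merge follows its definition and grows with scale spread", {
  fr0 <- noisy_obs_frames(6, 0, seed = 4)
  expect_equal(rmerge(fr0), 0)
  # two observations I(1 +/- eps) give R_merge = eps (in percent)
  cell <- unit_cell(8, 9, 10); sg <- space_group("P1")
  eps <- 0.07
  fr2 <- frame_set(list(
    list(id = 1, orientation = c(1, 0, 0, 0),
         spots = data.frame(h = 1, k = 0, l = 0, I = 100 * (1 + eps),
                            sigma = 1),
         max_pixel = 5000, beam_on = TRUE),
    list(id = 2, orientation = c(1, 0, 0, 0),
         spots = data.frame(h = 1, k = 0, l = 0, I = 100 * (1 - eps),
                            sigma = 1),
         max_pixel = 5000, beam_on = TRUE)), cell, sg, 0.827)
  expect_equal(rmerge(fr2), 100 * eps, tolerance = 1e-10)
  # lognormal per-frame scale spread: R_merge monotone in the spread
  rm <- vapply(c(0.05, 0.15, 0.3, 0.6), function(sdlog) {
    set.seed(11)
    fr <- noisy_obs_frames(10, 0, seed = 11)
    fr$frames <- lapply(fr$frames, function(f) {
      f$spots$I <- f$spots$I * rlnorm(1, 0, sdlog); f
    })
    rmerge(fr)
  }, numeric(1))
  expect_true(all(diff(rm) > 0))
})

test_that("completeness accounting matches removed fractions", {
  st <- build_toy_structure("planar_ring", sg_name = "Pbca")
  cfg <- simulation_config(n_frames = 600, seed = 5, d_min = 1.4)
  mg <- monte_carlo_merge(hit_filter(simulate_still_frames(st, cfg)))
  cm <- completeness_multiplicity(mg, d_min = 1.4)
  expect_equal(cm$completeness, 100)
  # drop half the unique reflections -> 50%
  half <- mg
  half$merged <- half$merged[seq_len(floor(nrow(half$merged) / 2)), ]
  cm2 <- completeness_multiplicity(half, d_min = 1.4)
  expect_equal(cm2$n_observed / cm2$n_possible, 0.5, tolerance = 0.01)
})
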