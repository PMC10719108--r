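test_that("resolution shells split at s = sin(theta)/lambda = 0.2", {
  # d = 6 A -> s ~ 0.083 (low shell); d = 2 A -> s = 0.25 (high shell)
  expect_lt(1 / (2 * 6), 0.2)
  demo <- charged_demo_structure()
  refl <- simulate_reflections(demo$truth, d_min = 1.2,
                               radiation = "electron")
  sr <- shell_r(demo$truth, refl$Fo, refl, "electron", scope = "scale")
  expect_gt(sr$n_low, 0); expect_gt(sr$n_high, 0)
  expect_equal(sr$n_low + sr$n_high, sum(refl$s > 0))
})

test_that("a model scored against its own data gives zero R everywhere", {
  demo <- charged_demo_structure(q_h = 0.3, q_cl = -0.6)
  refl <- simulate_reflections(demo$truth, d_min = 1.0,
                               radiation = "electron")
  sr <- shell_r(demo$truth, refl$Fo, refl, "electron", scope = "scale")
  expect_equal(c(sr$R_low, sr$R_high, sr$R_all), c(0, 0, 0),
               tolerance = 1e-12)
})

test_that("charge misfit concentrates in the low-resolution shell for
           electrons", {
  demo <- charged_demo_structure(q_h = 0.5, q_cl = -0.8)
  refl <- simulate_reflections(demo$truth, d_min = 1.0,
                               radiation = "electron")
  sr <- shell_r(demo$neutral, refl$Fo, refl, "electron", scope = "scale")
  expect_gt(sr$R_low, sr$R_high)
})

test_that("simplified refinement recovers perturbed parameters", {
  demo <- charged_demo_structure(q_h = 0, q_cl = 0)
  refl <- simulate_reflections(demo$truth, d_min = 1.0,
                               radiation = "xray")
  # self-refinement leaves parameters unchanged
  ref0 <- refine_simple(demo$truth, refl$Fo, refl, "xray", "scale_b")
  expect_equal(ref0$b, demo$truth$sites$b, tolerance = 1e-6)
  expect_equal(ref0$scale, 1, tolerance = 1e-8)
  # pure scale perturbation is absorbed exactly
  ref1 <- refine_simple(demo$truth, 3.7 * refl$Fo, refl, "xray", "scale")
  expect_equal(ref1$scale, 3.7, tolerance = 1e-10)
  # +2 A^2 on one atom is recovered from noise-free data
  pert <- demo$truth
  pert$sites$b[2] <- pert$sites$b[2] + 2
  ref2 <- refine_simple(pert, refl$Fo, refl, "xray", "scale_b",
                        max_iter = 200)
  expect_lt(max(abs(ref2$b - demo$truth$sites$b)), 0.05)
})

test_that("the charge grid search recovers injected charges exactly", {
  demo <- charged_demo_structure(q_h = 0.4, q_cl = -0.9)
  refl <- simulate_reflections(demo$truth, d_min = 1.0,
                               radiation = "electron")
  res <- charge_grid_search(demo$neutral, refl$Fo, refl, demo$sites,
                            radiation = "electron", step = 0.1)
  expect_equal(unname(res$best), c(0.4, -0.9))
  expect_equal(res$best_r$R_low, 0, tolerance = 1e-10)
  expect_false(res$degenerate)
  # exhaustive surface
  expect_equal(nrow(res$surface), 11 * 11)
  expect_true(all(is.finite(res$surface$R_low)))
})

test_that("neutral truth selects the neutral assignment", {
  demo <- charged_demo_structure(q_h = 0, q_cl = 0)
  refl <- simulate_reflections(demo$truth, d_min = 1.0,
                               radiation = "electron")
  res <- charge_grid_search(demo$neutral, refl$Fo, refl, demo$sites,
                            radiation = "electron", step = 0.5)
  expect_equal(unname(res$best), c(0, 0))
})

test_that("R_low degrades monotonically moving away from the truth", {
  demo <- charged_demo_structure(q_h = 0.4, q_cl = -0.9)
  refl <- simulate_reflections(demo$truth, d_min = 1.0,
                               radiation = "electron")
  res <- charge_grid_search(demo$neutral, refl$Fo, refl, demo$sites,
                            radiation = "electron", step = 0.1)
  surf <- res$surface
  # along the hydrogen axis at the true chloride charge
  line <- surf[abs(surf$CL1 + 0.9) < 1e-9, ]
  line <- line[order(line$H1q), ]
  below <- line$R_low[line$H1q <= 0.4]
  above <- line$R_low[line$H1q >= 0.4]
  expect_true(all(diff(below) < 0))
  expect_true(all(diff(above) > 0))
  # along the chloride axis at the true hydrogen charge
  line2 <- surf[abs(surf$H1q - 0.4) < 1e-9, ]
  line2 <- line2[order(line2$CL1), ]
  below2 <- line2$R_low[line2$CL1 <= -0.9]
  above2 <- line2$R_low[line2$CL1 >= -0.9]
  expect_true(all(diff(below2) < 0))
  expect_true(all(diff(above2) > 0))
})

test_that("refining with and without charges barely moves the structure", {
  st <- build_toy_structure("rhodamine_like")
  truth <- st
  truth$sites$q[truth$sites$label == "H15"] <- 0.4
  truth$sites$q[truth$sites$label == "H16"] <- 0.2
  truth$sites$q[truth$sites$label == "CL1"] <- -0.9
  refl <- simulate_reflections(truth, d_min = 1.5, radiation = "xray")
  ref_n <- refine_simple(st, refl$Fo, refl, "xray", "scale_b_xyz",
                         max_iter = 400)
  ref_t <- refine_simple(truth, refl$Fo, refl, "xray", "scale_b_xyz",
                         max_iter = 400)
  M <- microxtal:::cell_orth_matrix(st$cell)
  dxyz <- as.matrix(ref_n$structure$sites[c("x", "y", "z")]) -
    as.matrix(ref_t$structure$sites[c("x", "y", "z")])
  dxyz <- dxyz - round(dxyz)
  shifts <- sqrt(rowSums((dxyz %*% t(M))^2))
  heavy <- st$sites$element != "H"
  expect_lt(max(shifts[heavy]), 0.02)
  expect_lt(max(abs(ref_n$b - ref_t$b)[heavy]), 0.2)
})

test_that("charges trialled on nitrogen sites do not beat the neutral model
           when the truth is neutral there", {
  demo <- charged_demo_structure(q_h = 0.4, q_cl = -0.9)
  refl <- simulate_reflections(demo$truth, d_min = 1.0,
                               radiation = "electron")
  model <- demo$neutral
  model$sites$q[model$sites$label == "H1q"] <- 0.4
  model$sites$q[model$sites$label == "CL1"] <- -0.9
  res <- charge_grid_search(model, refl$Fo, refl, sites = "N1",
                            radiation = "electron", step = 0.5)
  expect_equal(unname(res$best), 0)
})
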