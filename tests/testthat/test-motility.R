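# Density-speed response, chemotaxis models, and the contact-guidance
# composition

test_that("density_speed_factor is the documented tent", {
  expect_equal(density_speed_factor(0.5), 1)   # ideal density
  expect_equal(density_speed_factor(1), 0)     # cells cannot pass
  expect_equal(density_speed_factor(0), 0)     # nothing to attach to
  expect_equal(density_speed_factor(0.75), 0.5)
  expect_equal(density_speed_factor(0.25), 0.5)
  expect_equal(density_speed_factor(c(0.1, 0.5, 0.9), 0, 0.5, 1),
               c(0.2, 1, 0.2))
  # custom nodes
  expect_equal(density_speed_factor(0.9, 0, 0.5, 0.9), 0)
  expect_equal(density_speed_factor(0.7, 0, 0.5, 0.9), 0.5)
  expect_error(density_speed_factor(0.5, 0.6, 0.5, 1), "rho_l <= rho_ideal")
  # compiled tent used by the engine agrees everywhere
  for (r in seq(0, 1, by = 0.05))
    expect_equal(cpp_density_speed_factor(r, 0.1, 0.4, 0.8),
                 density_speed_factor(r, 0.1, 0.4, 0.8))
})

test_that("chemotaxis models set direction and effective bias", {
  r <- chemotaxis_direction("I", gradient = c(2, 0, 0), bias = 1)
  expect_equal(r$direction, c(1, 0, 0))
  expect_equal(r$beta, 1)
  # Model II in virgin ECM: zero bias regardless of gradient
  r <- chemotaxis_direction("II", gradient = c(0, 5, 0), anisotropy = 0)
  expect_equal(r$beta, 0)
  r <- chemotaxis_direction("II", gradient = c(0, 3, 0), anisotropy = 0.6)
  expect_equal(r$direction, c(0, 1, 0))
  expect_equal(r$beta, 0.6)
  # ECM-blind cells cannot use anisotropy as a cue
  r <- chemotaxis_direction("II", gradient = c(0, 3, 0), anisotropy = 0.6,
                            sensitivity = 0)
  expect_equal(r$beta, 0)
  expect_equal(chemotaxis_direction("none", gradient = c(1, 1, 0))$beta, 0)
  expect_equal(chemotaxis_direction("I", gradient = c(0, 0, 0))$beta, 0)
})

test_that("guidance limits: s*a = 0 gives the pure cue, s*a = 1 gives +-f", {
  # s*a = 0 with deterministic chemotaxis: direction is exactly the gradient
  s <- one_cell_motility(c(0, 1, 0), a = 0.9, rho = 0.5,
                         par_override = list(bias = 1, ecm_sensitivity = 0,
                                             chemotaxis_model = "I",
                                             chemoattractant = "s",
                                             tau_p = 0.1))
  set.seed(1)
  up <- update_motility_vector(s$cells, s$grid, s$subs, dt = 0.1)
  expect_equal(up$motdir[1, ], c(1, 0, 0), tolerance = 1e-12)
  expect_equal(up$motvec[1, ], c(1, 0, 0), tolerance = 1e-12) # S_max * tent(0.5)
  # s = a = 1, beta = 1: direction is the fiber, sign-matched to the gradient
  f45 <- c(1, 1, 0) / sqrt(2)
  s <- one_cell_motility(f45, a = 1, rho = 0.5,
                         par_override = list(bias = 1, ecm_sensitivity = 1,
                                             chemotaxis_model = "I",
                                             chemoattractant = "s",
                                             tau_p = 0.1))
  set.seed(1)
  up <- update_motility_vector(s$cells, s$grid, s$subs, dt = 0.1)
  expect_equal(abs(sum(up$motdir[1, ] * f45)), 1, tolerance = 1e-12)
  expect_gt(sum(up$motdir[1, ] * c(1, 0, 0)), 0) # sign toward the gradient
})

test_that("with beta = 0 and s*a = 1 motion is a sign-random 1-D walk on f", {
  f <- c(0, 1, 0)
  s <- one_cell_motility(f, a = 1, rho = 0.5, grad_x = FALSE,
                         par_override = list(ecm_sensitivity = 1, tau_p = 0.1))
  set.seed(99)
  signs <- replicate(200, {
    up <- update_motility_vector(s$cells, s$grid, s$subs, dt = 0.1)
    expect_equal(abs(up$motdir[1, 2]), 1, tolerance = 1e-12)
    sign(up$motdir[1, 2])
  })
  expect_true(all(signs %in% c(-1, 1)))
  expect_gt(mean(signs == 1), 0.3) # both signs occur
  expect_lt(mean(signs == 1), 0.7)
})

test_that("guidance is invariant under flipping the fiber sign", {
  s1 <- one_cell_motility(c(0.6, 0.8, 0), a = 0.7, rho = 0.5,
                          par_override = list(bias = 0.4, ecm_sensitivity = 0.8,
                                              chemotaxis_model = "I",
                                              chemoattractant = "s",
                                              tau_p = 0.1))
  s2 <- one_cell_motility(-c(0.6, 0.8, 0), a = 0.7, rho = 0.5,
                          par_override = list(bias = 0.4, ecm_sensitivity = 0.8,
                                              chemotaxis_model = "I",
                                              chemoattractant = "s",
                                              tau_p = 0.1))
  for (seed in 1:20) {
    set.seed(seed)
    u1 <- update_motility_vector(s1$cells, s1$grid, s1$subs, dt = 0.1)
    set.seed(seed)
    u2 <- update_motility_vector(s2$cells, s2$grid, s2$subs, dt = 0.1)
    expect_equal(u1$motdir, u2$motdir, tolerance = 1e-12)
  }
})

test_that("speed never exceeds S_max and attains it only at ideal density", {
  for (rho in c(0.1, 0.3, 0.5, 0.8, 0.95)) {
    s <- one_cell_motility(c(1, 0, 0), a = 0.5, rho = rho,
                           par_override = list(S_max = 1.25, bias = 1,
                                               ecm_sensitivity = 0.5,
                                               chemotaxis_model = "I",
                                               chemoattractant = "s",
                                               tau_p = 0.1))
    set.seed(5)
    up <- update_motility_vector(s$cells, s$grid, s$subs, dt = 0.1)
    sp <- sqrt(sum(up$motvec[1, ]^2))
    expect_lte(sp, 1.25 + 1e-12)
    if (rho == 0.5) expect_equal(sp, 1.25, tolerance = 1e-12)
    else expect_lt(sp, 1.25)
  }
})

test_that("mean direction blends monotonically between gradient and fiber", {
  f45 <- c(1, 1, 0) / sqrt(2)
  angles <- sapply(seq(0.1, 0.9, by = 0.2), function(sa) {
    s <- one_cell_motility(f45, a = sa, rho = 0.5,
                           par_override = list(bias = 1, ecm_sensitivity = 1,
                                               chemotaxis_model = "I",
                                               chemoattractant = "s",
                                               tau_p = 0.1))
    set.seed(2)
    up <- update_motility_vector(s$cells, s$grid, s$subs, dt = 0.1)
    acos(pmin(1, sum(up$motdir[1, ] * c(1, 0, 0))))
  })
  # deterministic blend (beta = 1): angle from the gradient grows with s*a,
  # strictly between 0 and 45 degrees
  expect_true(all(diff(angles) > 0))
  expect_true(all(angles > 0 & angles < pi / 4))
})

test_that("cells track +-45 degree stripes under an +x gradient", {
  scn <- build_scenario("poc_stripes", seed = 1)
  p0 <- scn$state$cells$pos
  res <- run_simulation(scn, keep_snapshots = FALSE)
  p1 <- res$state$cells$pos
  disp <- p1 - p0
  ang <- atan2(disp[, 2], disp[, 1]) * 180 / pi
  top <- p0[, 2] > 100
  expect_true(all(abs(ang[top] - 45) < 5))
  expect_true(all(abs(ang[!top] + 45) < 5))
})
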