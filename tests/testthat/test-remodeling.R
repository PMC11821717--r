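# Fiber reorientation, anisotropy growth, density relaxation

test_that("remodel_instant snaps orientation and saturates anisotropy", {
  e <- ecm_element(c(1, 0, 0), anisotropy = 0.2, density = 0.4)
  out <- remodel_instant(e, c(2, 0, 0))
  expect_equal(out$orientation, c(1, 0, 0))
  expect_equal(out$anisotropy, 1)
  expect_equal(out$density, 0.4) # density untouched
  out <- remodel_instant(ecm_element(c(1, 0, 0), 0, 0.5), c(0, -3, 0))
  expect_equal(out$orientation, c(0, -1, 0))
  expect_equal(out$anisotropy, 1) # virgin element jumps to full alignment
  expect_equal(remodel_instant(e, c(0, 0, 0)), e) # stationary cell: no-op
})

test_that("remodel_orientation blends monotonically toward the travel axis", {
  e <- ecm_element(c(1, 0, 0))
  # fixed point: fiber already parallel
  expect_equal(remodel_orientation(e, c(2, 0, 0), 0.1, 4)$orientation,
               c(1, 0, 0))
  # frozen derived value: blend weight exactly 0.5
  out <- remodel_orientation(e, c(0, 1, 0), dt = 0.1, r_f0 = 5)
  expect_equal(out$orientation, c(sqrt(2) / 2, sqrt(2) / 2, 0),
               tolerance = 1e-12)
  # k = 1 reproduces the instantaneous limit in one step
  out <- remodel_orientation(e, c(0, 1, 0), dt = 1, r_f0 = 100)
  expect_equal(out$orientation, c(0, 1, 0))
  # the angle to the travel axis strictly decreases across repeated updates
  f <- ecm_element(c(1, 0.05, 0))
  v <- c(0, 1, 0)
  ang <- acos(abs(f$orientation[2]))
  for (i in 1:50) {
    f <- remodel_orientation(f, v, 0.1, 1)
    a2 <- acos(abs(f$orientation[2]))
    expect_lt(a2, ang + 1e-12)
    ang <- a2
  }
  expect_lt(ang, 0.01)
})

test_that("anisotropy growth follows its exponential closed form", {
  e <- ecm_element(c(1, 0, 0), anisotropy = 0.9)
  # speed * r_a0 = 0.001/min over 1000 min
  out <- remodel_anisotropy(e, speed = 1, dt = 1000, r_a0 = 0.001)
  expect_equal(out$anisotropy, 1 - 0.1 * exp(-1), tolerance = 1e-9)
  expect_equal(out$anisotropy, 0.9632, tolerance = 1e-4)
  # saturation and zero-speed fixed points
  expect_equal(remodel_anisotropy(ecm_element(c(1, 0, 0), 1), 5, 10, 1)$anisotropy, 1)
  expect_equal(remodel_anisotropy(e, 0, 10, 1)$anisotropy, 0.9)
})

test_that("density relaxes exponentially toward the target from both sides", {
  e <- ecm_element(c(1, 0, 0), density = 0.5)
  out <- remodel_density(e, dt = 100, r_rho = 0.01, rho_target = 1)
  expect_equal(out$density, 1 - 0.5 * exp(-1), tolerance = 1e-9)
  expect_equal(out$density, 0.8161, tolerance = 1e-4)
  # fixed point
  expect_equal(remodel_density(ecm_element(c(1, 0, 0), 0, 0.5), 10, 0.1,
                               0.5)$density, 0.5)
  # basement-membrane degradation: strictly decreasing toward 0.5
  bm <- ecm_element(c(1, 0, 0), density = 1)
  prev <- 1
  for (i in 1:20) {
    bm <- remodel_density(bm, 10, 0.05, 0.5)
    expect_lt(bm$density, prev)
    expect_gte(bm$density, 0.5)
    prev <- bm$density
  }
})

test_that("randomized remodeling preserves unit norm, bounds and monotone a", {
  set.seed(8)
  e <- ecm_element(c(1, 2, 0), anisotropy = 0.1, density = 0.3)
  for (i in 1:500) {
    v <- rnorm(3) * c(1, 1, 0)
    a_before <- e$anisotropy
    e <- remodel_orientation(e, v, 0.1, runif(1, 0, 10))
    e <- remodel_anisotropy(e, sqrt(sum(v^2)), 0.1, runif(1, 0, 1))
    e <- remodel_density(e, 0.1, runif(1, 0, 0.2), runif(1))
    expect_equal(sqrt(sum(e$orientation^2)), 1, tolerance = 1e-9)
    expect_gte(e$anisotropy, a_before)
    expect_true(e$anisotropy >= 0 && e$anisotropy <= 1)
    expect_true(e$density >= 0 && e$density <= 1)
  }
})

test_that("continuous remodeling converges to the instant limit as r grows", {
  v <- c(0.6, 0.8, 0)
  e0 <- ecm_element(c(1, 0, 0), anisotropy = 0.4, density = 0.5)
  inst <- remodel_instant(e0, v)
  cont <- remodel_anisotropy(remodel_orientation(e0, v, 1, 1e6), 1, 1, 1e6)
  expect_equal(abs(sum(cont$orientation * inst$orientation)), 1,
               tolerance = 1e-9)
  expect_equal(cont$anisotropy, 1, tolerance = 1e-9)
})

test_that("the engine's remodeling matches the scalar update functions", {
  # one cell gliding at a known velocity across a known element
  s <- one_cell_motility(c(0, 1, 0), a = 0.3, rho = 0.4,
                         par_override = list(S_max = 1, bias = 1,
                                             ecm_sensitivity = 0,
                                             chemotaxis_model = "I",
                                             chemoattractant = "s",
                                             tau_p = 0.1, r_f0 = 2,
                                             r_a0 = 0.5, r_rho = 0.1,
                                             rho_target = 0.9,
                                             C_cca = 0, C_ccr = 0))
  cells <- s$cells
  set.seed(4)
  res <- cpp_engine_advance(cells$pos, cells$motdir, cells$radius,
                            cells$volume, cells$dead, cells$par,
                            cells$sec_rate, cells$sec_target, cells$upt_rate,
                            s$grid$f, s$grid$a, s$grid$rho,
                            list(list(conc = s$subs[[1]]$conc, D = 0,
                                      lambda = 0, dirichlet = rep(NA_real_, 6),
                                      static = TRUE)),
                            s$grid$dims, s$grid$origin, s$grid$h,
                            c(0, 0, -10), c(60, 60, 10),
                            1, 0.1, 1, 0.1, TRUE, FALSE, 1.25, 0.005)
  # speed = S_max * tent(0.4) = 0.8 along +x
  idx <- element_index(s$grid, res$pos[1, ])
  lin <- 1 + idx[1] + s$grid$dims[1] * idx[2]
  e <- ecm_element(c(0, 1, 0), 0.3, 0.4)
  v <- c(0.8, 0, 0)
  e <- remodel_orientation(e, v, 0.1, 2)
  e <- remodel_anisotropy(e, 0.8, 0.1, 0.5)
  e <- remodel_density(e, 0.1, 0.1, 0.9)
  expect_equal(res$ecm_f[lin, ], e$orientation, tolerance = 1e-12)
  expect_equal(res$ecm_a[lin], e$anisotropy, tolerance = 1e-12)
  expect_equal(res$ecm_rho[lin], e$density, tolerance = 1e-12)
})
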