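# Center-based pairwise mechanics and overdamped position updates

radius_default <- radius_from_volume(2494)

test_that("pair_velocity reproduces the polynomial potentials", {
  # out of adhesive range: zero
  expect_equal(pair_velocity(c(0, 0, 0), c(50, 0, 0), 8.4, 8.4), c(0, 0, 0))
  # frozen derived value: pure repulsion at d = 10 with R = 16.8
  v <- pair_velocity(c(0, 0, 0), c(10, 0, 0), 8.4, 8.4, cca_i = 0, ccr_i = 25)
  expect_equal(v, c(-25 * (1 - 10 / 16.8)^2, 0, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(v^2)), 4.05, tolerance = 0.02)
  expect_lt(v[1], 0) # repulsive: pushes i away from j
  # pair antisymmetry for arbitrary asymmetric parameters
  vij <- pair_velocity(c(1, 2, 0), c(9, 7, 0), 8, 9, cca_i = 2, cca_j = 8,
                       ccr_i = 25, ccr_j = 4)
  vji <- pair_velocity(c(9, 7, 0), c(1, 2, 0), 9, 8, cca_i = 8, cca_j = 2,
                       ccr_i = 4, ccr_j = 25)
  expect_equal(vij, -vji, tolerance = 1e-12)
})

test_that("neighbor-list mechanics matches the brute-force O(N^2) oracle", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 200
    pos <- cbind(runif(n, 0, 300), runif(n, 0, 300), 0)
    radius <- runif(n, 6, 10)
    cca <- runif(n, 0, 5)
    ccr <- runif(n, 5, 30)
    fast <- cpp_pair_velocities(pos, radius, cca, ccr, 1.25,
                                c(0, 0, -10), c(300, 300, 10))
    slow <- brute_force_pair_velocities(pos, radius, cca, ccr)
    expect_equal(fast, slow, tolerance = 1e-10)
  }
})

test_that("an isolated pair is momentum-free and relaxes to equilibrium", {
  d_eq <- equilibrium_spacing(0.4, 10)
  expect_equal(d_eq, 16.024, tolerance = 1e-3)
  relax <- function(d0, steps = 20000) {
    pos <- rbind(c(0, 0, 0), c(d0, 0, 0))
    radius <- rep(radius_default, 2)
    dists <- numeric(steps)
    drift <- 0
    for (i in seq_len(steps)) {
      pv <- cpp_pair_velocities(pos, radius, rep(0.4, 2), rep(10, 2), 1.25,
                                c(-100, -100, -10), c(100, 100, 10))
      com0 <- colMeans(pos)
      pos <- pos + 0.1 * pv
      drift <- max(drift, max(abs(colMeans(pos) - com0)))
      dists[i] <- abs(pos[2, 1] - pos[1, 1])
    }
    expect_lt(drift, 1e-10) # momentum-free: no per-step center-of-mass drift
    dists
  }
  from_below <- relax(13)
  from_above <- relax(20)
  expect_true(all(diff(from_below) >= -1e-12)) # monotone approach
  expect_true(all(diff(from_above) <= 1e-12))
  expect_equal(tail(from_below, 1), d_eq, tolerance = 1e-3)
  expect_equal(tail(from_above, 1), d_eq, tolerance = 1e-3)
})

test_that("internal forces cancel for co-moving adhered cells", {
  ty <- cell_type("t", C_cca = 10, C_ccr = 25)
  cells <- make_cells(list(ty), list(list(type = "t",
    positions = rbind(c(0, 0, 0), c(14, 0, 0)))))
  dom <- list(lo = c(-100, -100, -10), hi = c(100, 100, 10))
  # identical motility vectors: pair terms cancel pairwise, both cells move
  # at exactly the motility speed
  cells$motvec <- rbind(c(0.5, 0.2, 0), c(0.5, 0.2, 0))
  v <- total_velocity(cells, dom)
  expect_equal(colSums(v), c(1, 0.4, 0), tolerance = 1e-12)
  # opposite motility of equal magnitude: center of mass stays put
  cells$motvec <- rbind(c(0.5, 0, 0), c(-0.5, 0, 0))
  v <- total_velocity(cells, dom)
  expect_equal(colSums(v), c(0, 0, 0), tolerance = 1e-12)
  # isolated cell: velocity equals the motility vector
  solo <- make_cells(list(ty), list(list(type = "t",
    positions = rbind(c(0, 0, 0)))))
  solo$motvec <- rbind(c(1.25, 0, 0))
  expect_equal(total_velocity(solo, dom), rbind(c(1.25, 0, 0)))
})

test_that("advance_positions integrates Euler steps and reflects at walls", {
  ty <- cell_type("t")
  cells <- make_cells(list(ty), list(list(type = "t",
    positions = rbind(c(10, 10, 0)))))
  dom <- list(lo = c(0, 0, -10), hi = c(100, 100, 10))
  cells$vel <- rbind(c(0, 0, 0))
  expect_equal(advance_positions(cells, 0.1, dom)$pos, rbind(c(10, 10, 0)))
  cells$vel <- rbind(c(1, 0, 0))
  p <- cells
  for (i in 1:10) p <- advance_positions(p, 0.1, dom)
  expect_equal(p$pos, rbind(c(11, 10, 0)), tolerance = 1e-12)
  # reflection at the lower wall
  cells$pos <- rbind(c(0.2, 50, 0))
  cells$vel <- rbind(c(-30, 0, 0))
  refl <- advance_positions(cells, 0.1, dom)
  expect_equal(refl$pos[1, 1], 2.8, tolerance = 1e-12)
  expect_error(advance_positions(cells, -1, dom))
})

test_that("dead cells shrink exponentially and are removed below threshold", {
  ty_live <- cell_type("live")
  ty_dead <- cell_type("gone", dead = TRUE)
  cells <- make_cells(list(ty_live, ty_dead),
                      list(list(type = "live", positions = rbind(c(0, 0, 0))),
                           list(type = "gone", positions = rbind(c(50, 0, 0)))))
  v0 <- cells$volume[2]
  out <- remove_and_shrink_dead(cells, dt = 100, shrink_rate = 0.005)
  expect_equal(out$volume[1], cells$volume[1]) # live cell untouched
  expect_equal(out$volume[2], v0 * exp(-0.5), tolerance = 1e-12)
  expect_equal(out$radius[2], radius_from_volume(v0 * exp(-0.5)))
  # shrink past 3% of default volume: removed
  out2 <- remove_and_shrink_dead(out, dt = 710, shrink_rate = 0.005)
  expect_equal(length(out2$id), 1L)
  expect_equal(out2$type, "live")
})

test_that("engine dead-cell shrinkage matches the closed form", {
  ty <- cell_type("d", dead = TRUE, C_cca = 0, C_ccr = 0)
  s <- one_cell_motility(c(1, 0, 0), 0, 0.5, grad_x = FALSE)
  cells <- make_cells(list(ty), list(list(type = "d",
    positions = rbind(c(30, 30, 0)))))
  res <- cpp_engine_advance(cells$pos, cells$motdir, cells$radius,
                            cells$volume, cells$dead, cells$par,
                            cells$sec_rate, cells$sec_target, cells$upt_rate,
                            s$grid$f, s$grid$a, s$grid$rho, list(),
                            s$grid$dims, s$grid$origin, s$grid$h,
                            c(0, 0, -10), c(60, 60, 10),
                            200, 0.1, 1, 0.1, TRUE, FALSE, 1.25, 0.005)
  expect_equal(res$volume, cells$volume * exp(-0.005 * 20), tolerance = 1e-9)
  expect_equal(res$pos, cells$pos) # dead cells do not move on their own
})
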