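# Hill responses and the declarative signal -> behavior couplings

test_that("hill_response hits base, midpoint and saturation", {
  r_up <- rule("m", "contact:dead", "phagocytosis_rate", "increase",
               base_value = 0.1, saturation_value = 0.9, half_max = 2,
               hill_power = 4)
  expect_equal(hill_response(0, r_up), 0.1)
  expect_equal(hill_response(2, r_up), 0.5) # midpoint at the half-max
  expect_equal(hill_response(1e6, r_up), 0.9, tolerance = 1e-9)
  r_dn <- rule("c", "contact:fibroblast", "C_cca", "decrease",
               base_value = 10, saturation_value = 0.4, half_max = 0.5)
  expect_equal(hill_response(0, r_dn), 10)
  expect_equal(hill_response(0.5, r_dn), 5.2)
  expect_equal(hill_response(1e6, r_dn), 0.4, tolerance = 1e-6)
  # outputs bounded by [min(base, sat), max(base, sat)] for any signal
  x <- c(0, 10^runif(200, -3, 3))
  expect_true(all(hill_response(x, r_up) >= 0.1 & hill_response(x, r_up) <= 0.9))
  expect_true(all(hill_response(x, r_dn) >= 0.4 & hill_response(x, r_dn) <= 10))
})

test_that("rule construction validates its fields", {
  expect_error(rule("m", "contact:dead", "S_max", "increase", 0, 1, half_max = 0),
               "half_max")
  expect_error(rule("m", "bogus:dead", "S_max", "increase", 0, 1, 1),
               "unknown signal")
  expect_error(rule("m", "contact:dead", "bogus", "increase", 0, 1, 1),
               "unknown behavior")
  expect_error(rule("m", "contact:dead", "S_max", "increase", 2, 1, 1),
               "saturation_value >= base_value")
  expect_error(
    rulebook(rule("m", "contact:dead", "S_max", "increase", 0, 1, 1),
             rule("m", "ecm_density", "S_max", "decrease", 1, 0, 1)),
    "same behavior")
})

make_trio <- function() {
  # a macrophage in contact with two dead cells, and one isolated fibroblast
  dead <- cell_type("dead_cell", dead = TRUE)
  mac <- cell_type("macrophage")
  fib <- cell_type("fibroblast", rho_target = 1)
  make_cells(list(dead, mac, fib),
             list(list(type = "dead_cell",
                       positions = rbind(c(0, 0, 0), c(12, 0, 0))),
                  list(type = "macrophage", positions = rbind(c(0, 10, 0))),
                  list(type = "fibroblast", positions = rbind(c(200, 200, 0)))),
             substrates = "inflam")
}

test_that("signals count contacts and read local fields", {
  g <- ecm_grid(c(-20, 280), c(-20, 280))
  cells <- make_trio()
  subs <- list(substrate_field(g, "inflam", D = 100, lambda = 0.1, initial = 0.25))
  sig <- compute_signals(cells, subs, g)
  expect_equal(sig$contact_dead, c(1, 1, 2, 0)) # macrophage touches both dead
  expect_equal(unname(sig$contact[, "macrophage"]), c(1, 1, 0, 0))
  expect_equal(unname(sig$substrate[, "inflam"]), rep(0.25, 4))
  expect_equal(sig$ecm_density, rep(0.5, 4))
})

test_that("evaluate_rules overwrites targeted behaviors and keeps the rest", {
  g <- ecm_grid(c(-20, 280), c(-20, 280))
  cells <- make_trio()
  subs <- list(substrate_field(g, "inflam", D = 100, lambda = 0.1))
  rules <- rulebook(
    rule("macrophage", "contact:dead", "secretion_rate:inflam", "increase",
         base_value = 0, saturation_value = 1, half_max = 0.5),
    rule("macrophage", "contact:dead", "phagocytosis_rate", "increase",
         base_value = 0, saturation_value = 0.05, half_max = 1),
    rule("fibroblast", "contact:macrophage", "ecm_density_target_rate",
         "increase", base_value = 0, saturation_value = 0.05, half_max = 0.5))
  sig <- compute_signals(cells, subs, g)
  out <- evaluate_rules(cells, sig, rules)
  mac <- which(out$type == "macrophage")
  fib <- which(out$type == "fibroblast")
  # two dead contacts with Hill power 4: H = 2^4/(2^4 + h^4)
  expect_equal(unname(out$sec_rate[mac, "inflam"]), 16 / (16 + 0.5^4),
               tolerance = 1e-12)
  expect_equal(unname(out$phago_rate[mac]), 0.05 * 16 / 17, tolerance = 1e-12)
  # deposition is gated on macrophage contact: isolated fibroblast inert
  expect_equal(unname(out$par[fib, "rrho"]), 0)
  # untouched behaviors keep their configured constants
  expect_equal(unname(out$par[mac, "S_max"]), 1)
  # with no macrophages around, fibroblasts never deposit (loop closure)
  cells2 <- cells_subset(cells, cells$type != "macrophage")
  sig2 <- compute_signals(cells2, subs, g)
  out2 <- evaluate_rules(cells2, sig2, rules)
  expect_true(all(out2$par[out2$type == "fibroblast", "rrho"] == 0))
})

test_that("macrophages with no dead contacts secrete at base rate", {
  g <- ecm_grid(c(-20, 280), c(-20, 280))
  mac <- cell_type("macrophage")
  cells <- make_cells(list(mac),
                      list(list(type = "macrophage",
                                positions = rbind(c(100, 100, 0)))),
                      substrates = "inflam")
  subs <- list(substrate_field(g, "inflam", D = 100, lambda = 0.1))
  rules <- rulebook(rule("macrophage", "contact:dead", "secretion_rate:inflam",
                         "increase", base_value = 0, saturation_value = 1,
                         half_max = 0.5))
  out <- evaluate_rules(cells, compute_signals(cells, subs, g), rules)
  expect_equal(unname(out$sec_rate[1, "inflam"]), 0)
})

test_that("phagocytosis removes contacting dead cells at the expected rate", {
  dead <- cell_type("dead_cell", dead = TRUE)
  mac <- cell_type("macrophage")
  set.seed(10)
  # 300 dead cells piled within contact range of one macrophage
  pts <- cbind(runif(300, -4, 4), runif(300, -4, 4), 0)
  cells <- make_cells(list(dead, mac),
                      list(list(type = "dead_cell", positions = pts),
                           list(type = "macrophage",
                                positions = rbind(c(0, 0, 0)))))
  n_mac <- which(cells$type == "macrophage")
  # rate * dt = ln 2 -> each contacting dead cell removed with p = 1/2
  cells$phago_rate[n_mac] <- log(2)
  out <- phagocytose(cells, dt = 1)
  removed <- 301 - length(out$id)
  expect_gt(removed, 300 * 0.5 - 4 * sqrt(300 * 0.25))
  expect_lt(removed, 300 * 0.5 + 4 * sqrt(300 * 0.25))
  # zero rate or no contacts: nothing happens
  cells$phago_rate[n_mac] <- 0
  expect_equal(length(phagocytose(cells, 1)$id), 301)
  cells$phago_rate[n_mac] <- 10
  cells$pos[n_mac, ] <- c(500, 500, 0)
  expect_equal(length(phagocytose(cells, 1)$id), 301)
})

test_that("an empty rulebook leaves all type constants in force", {
  g <- ecm_grid(c(-20, 280), c(-20, 280))
  cells <- make_trio()
  subs <- list(substrate_field(g, "inflam", D = 100, lambda = 0.1))
  out <- evaluate_rules(cells, compute_signals(cells, subs, g), rulebook())
  expect_equal(out$par, cells$par)
  expect_equal(out$sec_rate, cells$sec_rate)
})
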