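# Independent oracles used across tests: brute-force pair mechanics and a
# scalar breadth-first reachability search, both deliberately written without
# reusing package internals.

# O(N^2) pairwise velocity sum straight from the potential definitions
brute_force_pair_velocities <- function(pos, radius, cca, ccr, factor = 1.25) {
  n <- nrow(pos)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dvec <- pos[j, ] - pos[i, ]
    d <- sqrt(sum(dvec^2))
    R <- radius[i] + radius[j]
    Ra <- factor * R
    if (d >= Ra || d == 0) next
    u <- dvec / d
    mag <- 0
    if (d < R) mag <- mag - sqrt(ccr[i] * ccr[j]) * (1 - d / R)^2
    mag <- mag + sqrt(cca[i] * cca[j]) * (1 - d / Ra)^2
    out[i, ] <- out[i, ] + mag * u
  }
  out
}

# scalar-queue flood fill from the boundary; TRUE where reachable
brute_force_reachable <- function(blocked) {
  nx <- nrow(blocked); ny <- ncol(blocked)
  reached <- matrix(FALSE, nx, ny)
  stack <- list()
  for (i in seq_len(nx)) stack <- c(stack, list(c(i, 1)), list(c(i, ny)))
  for (j in seq_len(ny)) stack <- c(stack, list(c(1, j)), list(c(nx, j)))
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- p[1]; j <- p[2]
    if (i < 1 || i > nx || j < 1 || j > ny) next
    if (blocked[i, j] || reached[i, j]) next
    reached[i, j] <- TRUE
    stack <- c(stack, list(c(i + 1, j)), list(c(i - 1, j)),
               list(c(i, j + 1)), list(c(i, j - 1)))
  }
  reached
}

# single-cell motility scenario helper: one cell in a small grid with a
# prescribed ECM element under it
one_cell_motility <- function(f, a, rho, par_override = list(), dt = 0.1,
                              grad_x = TRUE) {
  g <- ecm_grid(c(0, 60), c(0, 60))
  g$f <- matrix(rep(f / sqrt(sum(f^2)), each = nrow(g$f)), ncol = 3)
  g$a <- rep(a, length(g$a))
  g$rho <- rep(rho, length(g$rho))
  ty <- do.call(cell_type, c(list(name = "c"), par_override))
  cells <- make_cells(list(ty),
                      list(list(type = "c", positions = rbind(c(30, 30, 0)))),
                      substrates = if (grad_x) "s" else character())
  subs <- if (grad_x) {
    ctr <- element_centers(g)
    list(substrate_field(g, "s", D = 0, lambda = 0, initial = ctr[, 1] / 60,
                         static = TRUE))
  } else list()
  list(grid = g, cells = cells, subs = subs, dt = dt)
}
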