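# Declarative signal -> behavior couplings: each rule maps a local signal
# (substrate concentration, contact counts, or local ECM density) through a
# Hill response onto one behavior parameter of one cell type. Rules are
# re-evaluated on the rules time step and overwrite the type's constant for
# that step only; removing every rule leaves inert types with constant
# parameters.

.rule_signals <- c("substrate", "contact", "ecm_density")
.rule_behaviors <- c("secretion_rate", "uptake_rate", "S_max", "C_cca",
                     "ecm_density_target_rate", "phagocytosis_rate",
                     "chemotactic_bias", "transform_to")

#' Define a signal-response rule
#'
#' @param cell_type name of the responding type.
#' @param signal one of `"substrate:<name>"`, `"contact:<type>"` (use
#'   `"contact:dead"` for contacts with dead cells of any type), or
#'   `"ecm_density"`. Contact means center distance below `R_i + R_j`.
#' @param behavior one of `"secretion_rate:<substrate>"`,
#'   `"uptake_rate:<substrate>"`, `"S_max"`, `"C_cca"`,
#'   `"ecm_density_target_rate"` (the density remodeling rate `r_rho`),
#'   `"phagocytosis_rate"`, `"chemotactic_bias"`, `"transform_to:<type>"`
#'   (output read as a transition rate, 1/min).
#' @param direction `"increase"` or `"decrease"`.
#' @param base_value response at zero signal.
#' @param saturation_value response at saturating signal.
#' @param half_max signal value giving the half-maximal response (> 0).
#' @param hill_power Hill coefficient (>= 1, default 4: sharp but smooth).
#' @return list of class `ecm_rule`.
#' @export
rule <- function(cell_type, signal, behavior,
                 direction = c("increase", "decrease"),
                 base_value, saturation_value, half_max, hill_power = 4) {
  direction <- match.arg(direction)
  if (!(half_max > 0)) stop("half_max must be > 0")
  if (hill_power < 1) stop("hill_power must be >= 1")
  if (!is.finite(base_value) || !is.finite(saturation_value) ||
      base_value < 0 || saturation_value < 0)
    stop("base and saturation values must be finite and non-negative")
  if (!strsplit(signal, ":")[[1]][1] %in% .rule_signals)
    stop("unknown signal: ", signal)
  if (!strsplit(behavior, ":")[[1]][1] %in% .rule_behaviors)
    stop("unknown behavior: ", behavior)
  if (direction == "increase" && saturation_value < base_value)
    stop("increasing rule needs saturation_value >= base_value")
  if (direction == "decrease" && saturation_value > base_value)
    stop("decreasing rule needs saturation_value <= base_value")
  structure(list(cell_type = cell_type, signal = signal, behavior = behavior,
                 direction = direction, base_value = base_value,
                 saturation_value = saturation_value, half_max = half_max,
                 hill_power = hill_power), class = "ecm_rule")
}

#' Assemble a rulebook
#'
#' Validates that no two rules target the same behavior of the same type
#' (evaluation order is then irrelevant).
#' @param ... [rule()]s.
#' @return list of class `ecm_rulebook`.
#' @export
rulebook <- function(...) {
  rules <- list(...)
  if (length(rules) == 1 && is.list(rules[[1]]) &&
      !inherits(rules[[1]], "ecm_rule"))
    rules <- rules[[1]]
  keys <- vapply(rules, function(r) paste(r$cell_type, r$behavior, sep = "|"), "")
  if (anyDuplicated(keys))
    stop("two rules target the same behavior of one cell type: ",
         keys[duplicated(keys)][1])
  structure(rules, class = "ecm_rulebook")
}

#' Hill response of a rule
#'
#' `H = x^n / (x^n + h^n)`; increasing rules return
#' `base + (sat - base) * H`, decreasing rules `base - (base - sat) * H`.
#' The output always stays within `[min(base, sat), max(base, sat)]`.
#'
#' @param x signal value(s), >= 0.
#' @param rule an [rule()].
#' @return behavior value(s).
#' @export
hill_response <- function(x, rule) {
  H <- x^rule$hill_power / (x^rule$hill_power + rule$half_max^rule$hill_power)
  H[x == 0] <- 0 # guard 0^0
  if (rule$direction == "increase")
    rule$base_value + (rule$saturation_value - rule$base_value) * H
  else
    rule$base_value - (rule$base_value - rule$saturation_value) * H
}

#' Read the local signals of every cell
#'
#' @param cells a `cell_population`.
#' @param substrates list of [substrate_field()]s.
#' @param grid the [ecm_grid()].
#' @return list with per-cell substrate concentrations (matrix), live contact
#'   counts by type, dead-contact counts, and local ECM density.
#' @export
compute_signals <- function(cells, substrates, grid) {
  n <- length(cells$id)
  tnames <- names(cells$types)
  cnt <- cpp_contact_counts(cells$pos, cells$radius, cells$dead,
                            match(cells$type, tnames), length(tnames))
  conc <- matrix(0, n, length(substrates),
                 dimnames = list(NULL, vapply(substrates, `[[`, "", "name")))
  if (n > 0) {
    d <- grid$dims
    idx <- floor(sweep(cells$pos, 2, grid$origin) / grid$h)
    idx <- pmin(pmax(idx, 0), matrix(d - 1, n, 3, byrow = TRUE))
    lin <- 1 + idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3])
    for (s in seq_along(substrates)) conc[, s] <- substrates[[s]]$conc[lin]
    rho <- grid$rho[lin]
  } else rho <- numeric(0)
  list(substrate = conc,
       contact = cnt[, seq_along(tnames), drop = FALSE] |>
         `colnames<-`(tnames),
       contact_dead = cnt[, length(tnames) + 1],
       ecm_density = rho)
}

# fetch the signal vector named by a rule
signal_values <- function(rule, signals) {
  parts <- strsplit(rule$signal, ":")[[1]]
  switch(parts[1],
    substrate = signals$substrate[, parts[2]],
    contact = if (parts[2] == "dead") signals$contact_dead
              else signals$contact[, parts[2]],
    ecm_density = signals$ecm_density)
}

#' Evaluate a rulebook over a population
#'
#' Resets all behavior parameters to their type constants, then lets every
#' matched rule overwrite its target behavior for this step. Targets are
#' disjoint by construction, so evaluation order is irrelevant. Cells whose
#' `transform_to` rule fires (probability `1 - exp(-rate * dt)`) switch type.
#'
#' @param cells a `cell_population`.
#' @param signals output of [compute_signals()].
#' @param rules an [rulebook()].
#' @param dt rules time step, min (used by `transform_to`).
#' @return the updated population.
#' @export
evaluate_rules <- function(cells, signals, rules, dt = 6) {
  cells <- reset_behaviors(cells)
  transformed <- FALSE
  for (r in rules) {
    sel <- which(cells$type == r$cell_type & cells$dead == 0L)
    if (!length(sel)) next
    x <- signal_values(r, signals)[sel]
    val <- hill_response(x, r)
    parts <- strsplit(r$behavior, ":")[[1]]
    switch(parts[1],
      S_max = { cells$par[sel, "S_max"] <- val },
      C_cca = { cells$par[sel, "cca"] <- val },
      chemotactic_bias = { cells$par[sel, "bias"] <- val },
      ecm_density_target_rate = { cells$par[sel, "rrho"] <- val },
      phagocytosis_rate = { cells$phago_rate[sel] <- val },
      secretion_rate = { cells$sec_rate[sel, parts[2]] <- val },
      uptake_rate = { cells$upt_rate[sel, parts[2]] <- val },
      transform_to = {
        p <- 1 - exp(-val * dt)
        flip <- sel[runif(length(sel)) < p]
        if (length(flip)) { cells$type[flip] <- parts[2]; transformed <- TRUE }
      })
  }
  if (transformed) cells <- reset_behaviors(cells)
  cells
}

#' Phagocytosis of dead cells
#'
#' Each (eater, contacting dead cell) pair removes the dead cell with
#' probability `1 - exp(-rate * dt)` (exponential waiting time at the eater's
#' current phagocytosis rate). The eater is unchanged (no volume transfer).
#' Pairs are visited in storage order so runs are reproducible per seed.
#'
#' @param cells a `cell_population` (uses `cells$phago_rate`).
#' @param dt elapsed time, min.
#' @return the updated population.
#' @export
phagocytose <- function(cells, dt) {
  eaters <- which(cells$phago_rate > 0 & cells$dead == 0L)
  if (!length(eaters)) return(cells)
  dead_idx <- which(cells$dead == 1L)
  if (!length(dead_idx)) return(cells)
  removed <- rep(FALSE, length(cells$id))
  for (e in eaters) {
    p <- 1 - exp(-cells$phago_rate[e] * dt)
    for (d in dead_idx) {
      if (removed[d]) next
      R <- cells$radius[e] + cells$radius[d]
      if (sum((cells$pos[e, ] - cells$pos[d, ])^2) < R^2 && runif(1) < p)
        removed[d] <- TRUE
    }
  }
  if (any(removed)) cells <- cells_subset(cells, !removed)
  cells
}
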