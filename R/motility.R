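# The ECM-aware motility update. Each refresh of the biased persistent random
# walk composes, in order: (1) the chemotactic/random base cue
# d_cue = normalize(beta * ghat + (1 - beta) * xi); (2) the sign-matched local
# fiber f* = f * sign(f . d_cue); (3) contact guidance
# d = normalize((1 - s a) d_cue + s a f*); (4) the density-dependent speed.
# Orientation is nondirectional: every consumer is sign-invariant in f.

#' Density-dependent speed factor
#'
#' Piecewise-linear tent in local ECM density: 0 at/below `rho_l` (nothing to
#' attach to), rising to 1 at `rho_ideal`, falling to 0 at/above `rho_h`
#' (too dense to pass). Defaults `(0, 0.5, 1)`.
#'
#' @param rho ECM density (vectorized).
#' @param rho_l,rho_ideal,rho_h tent nodes, `0 <= rho_l <= rho_ideal <=
#'   rho_h <= 1`.
#' @return speed multiplier in `[0, 1]`.
#' @export
density_speed_factor <- function(rho, rho_l = 0, rho_ideal = 0.5, rho_h = 1) {
  if (!(0 <= rho_l && rho_l <= rho_ideal && rho_ideal <= rho_h && rho_h <= 1))
    stop("density response must satisfy 0 <= rho_l <= rho_ideal <= rho_h <= 1")
  up <- if (rho_ideal > rho_l) (rho - rho_l) / (rho_ideal - rho_l) else 1
  down <- if (rho_h > rho_ideal) (rho_h - rho) / (rho_h - rho_ideal) else 1
  out <- ifelse(rho < rho_ideal, up, down)
  out[rho == rho_ideal] <- 1
  pmin(pmax(out, 0), 1)
}

#' Chemotaxis direction and effective bias
#'
#' Model I uses the fixed per-cell bias `b`; Model II sets the bias to the
#' local ECM anisotropy `a` read through the cell's ECM sensitivity `s`
#' (`beta = s * a`), so cells in unaligned ECM - and ECM-blind cells with
#' `s = 0` - move randomly. With no model or a zero gradient the bias is 0
#' and the direction undefined (pure random walk).
#'
#' @param model `"none"`, `"I"` or `"II"`.
#' @param gradient local substrate gradient (length 3).
#' @param bias fixed bias for Model I.
#' @param anisotropy local ECM anisotropy for Model II.
#' @param sensitivity ECM sensitivity `s` gating Model II (default 1).
#' @return list with unit `direction` (NA if undefined) and effective bias
#'   `beta`.
#' @export
chemotaxis_direction <- function(model = c("none", "I", "II"), gradient = c(0, 0, 0),
                                 bias = 1, anisotropy = 0, sensitivity = 1) {
  model <- match.arg(model)
  gn <- sqrt(sum(gradient^2))
  if (model == "none" || gn == 0)
    return(list(direction = c(NA_real_, NA_real_, NA_real_), beta = 0))
  list(direction = gradient / gn,
       beta = if (model == "I") bias else sensitivity * anisotropy)
}

#' Update motility vectors for a population
#'
#' With probability `dt / tau_p` per call each cell's direction is refreshed
#' (otherwise retained) via the cue-then-guidance composition described
#' above; the motility vector is always recomputed as
#' `S_max * density_speed_factor(rho_local) * direction`, so the output speed
#' never exceeds `S_max` and attains it only at ideal density. Draws come
#' from R's RNG stream.
#'
#' @param cells a `cell_population`.
#' @param grid the [ecm_grid()] supplying orientation/anisotropy/density at
#'   each cell's element.
#' @param substrates list of [substrate_field()]s (chemoattractant lookup by
#'   position in `cells$substrates`).
#' @param dt mechanics time step, min.
#' @return the population with `motdir` and `motvec` updated.
#' @export
update_motility_vector <- function(cells, grid, substrates = list(), dt = 0.1) {
  res <- cpp_update_motility(cells$pos, cells$motdir, cells$par, cells$dead,
                             lapply(substrates, `[[`, "conc"),
                             grid$f, grid$a, grid$rho, grid$dims, grid$origin,
                             grid$h, dt, grid$two_d)
  cells$motdir <- res$motdir
  cells$motvec <- res$motvec
  cells
}
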