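# Cell agents: center-based, off-lattice, overdamped. Pairwise mechanics are
# polynomial adhesion/repulsion potentials acting on center distance; motility
# is supplied by the motility module and simply added (no renormalization, so
# adhesion pulling against motility lowers the realized speed of a cluster).

#' Define a cell type
#'
#' A parameter block for one phenotype. Defaults follow the conventions of
#' center-based tissue simulators: cell volume 2494 um^3 (radius ~8.41 um),
#' base migration speed 1 um/min, adhesion strength 0.4 um/min and repulsion
#' strength 10 um/min, persistence time 10 min.
#'
#' @param name type name.
#' @param S_max base (maximum) migration speed, um/min.
#' @param bias chemotactic bias b in `[0,1]` (Chemotaxis Model I).
#' @param ecm_sensitivity contact-guidance sensitivity s in `[0,1]`.
#' @param tau_p persistence time, min (mean interval between direction
#'   refreshes of the biased random walk).
#' @param C_cca cell-cell adhesion strength, um/min. Heterotypic pairs use
#'   the geometric mean of the two cells' values.
#' @param C_ccr cell-cell repulsion strength, um/min (geometric mean across
#'   pairs as well).
#' @param r_f0 fiber reorientation rate, 1/min (scaled by cell speed).
#' @param r_a0 fiber realignment (anisotropy growth) rate, 1/min (scaled by
#'   cell speed).
#' @param r_rho ECM density remodeling rate, 1/min.
#' @param rho_target ECM density target in `[0,1]` for density remodeling.
#' @param instant if `TRUE`, fiber remodeling is instantaneous (orientation
#'   snaps to the travel direction and anisotropy to 1) whenever `r_f0` or
#'   `r_a0` is positive.
#' @param rho_l,rho_ideal,rho_h density-speed tent: speed factor 0 at/below
#'   `rho_l`, 1 at `rho_ideal`, 0 at/above `rho_h`.
#' @param chemotaxis_model `"none"`, `"I"` (fixed bias `b`) or `"II"` (bias
#'   equals the local ECM anisotropy).
#' @param chemoattractant substrate name the cell chemotaxes along.
#' @param secretion named list `substrate = c(rate, target)` or
#'   `substrate = rate` (target defaults to 1).
#' @param uptake named list `substrate = rate` (1/min).
#' @param volume cell volume, um^3.
#' @param dead if `TRUE`, cells of this type start dead (no motility, no
#'   remodeling, shrinking volume; they still exert mechanics and secrete).
#' @param phagocytosis_rate baseline rate (1/min) at which this type removes
#'   contacting dead cells.
#' @return a list of class `cell_type`.
#' @export
cell_type <- function(name, S_max = 1, bias = 0, ecm_sensitivity = 0,
                      tau_p = 10, C_cca = 0.4, C_ccr = 10,
                      r_f0 = 0, r_a0 = 0, r_rho = 0, rho_target = 0.5,
                      instant = FALSE, rho_l = 0, rho_ideal = 0.5, rho_h = 1,
                      chemotaxis_model = c("none", "I", "II"),
                      chemoattractant = NA_character_,
                      secretion = list(), uptake = list(),
                      volume = 2494, dead = FALSE, phagocytosis_rate = 0) {
  chemotaxis_model <- match.arg(chemotaxis_model)
  stopifnot(S_max >= 0, tau_p > 0, C_cca >= 0, C_ccr >= 0,
            r_f0 >= 0, r_a0 >= 0, r_rho >= 0,
            bias >= 0, bias <= 1, ecm_sensitivity >= 0, ecm_sensitivity <= 1)
  if (!(0 <= rho_l && rho_l <= rho_ideal && rho_ideal <= rho_h && rho_h <= 1))
    stop("density response must satisfy 0 <= rho_l <= rho_ideal <= rho_h <= 1")
  structure(as.list(environment()), class = "cell_type")
}

#' Default cell radius from a volume
#' @param volume cell volume in um^3.
#' @return radius in um.
#' @export
radius_from_volume <- function(volume) (3 * volume / (4 * pi))^(1 / 3)

# numeric chemotaxis model code used by the engine
.chemo_code <- c(none = 0, I = 1, II = 2)

#' Build a cell population
#'
#' Assembles the per-cell state arrays from type definitions and placements.
#'
#' @param types list of [cell_type()] definitions.
#' @param placements list of `list(type = <name>, positions = <n x 3 matrix>)`.
#' @param substrates character vector of substrate names present in the
#'   simulation (defines the secretion/uptake columns).
#' @return object of class `cell_population`.
#' @export
make_cells <- function(types, placements, substrates = character()) {
  names(types) <- vapply(types, `[[`, "", "name")
  pos <- NULL; tname <- character()
  for (p in placements) {
    if (!p$type %in% names(types)) stop("unknown cell type: ", p$type)
    m <- rbind(p$positions)
    pos <- rbind(pos, m)
    tname <- c(tname, rep(p$type, nrow(m)))
  }
  n <- length(tname)
  cells <- list(
    id = seq_len(n),
    type = tname,
    types = types,
    substrates = substrates,
    pos = if (n) pos else matrix(numeric(), 0, 3),
    motdir = matrix(rep(c(1, 0, 0), each = n), ncol = 3),
    vel = matrix(0, n, 3),
    radius = numeric(n),
    volume = numeric(n),
    volume0 = numeric(n),
    dead = integer(n),
    phago_rate = numeric(n),
    par = matrix(0, n, length(.par_cols), dimnames = list(NULL, .par_cols)),
    sec_rate = matrix(0, n, length(substrates),
                      dimnames = list(NULL, substrates)),
    sec_target = matrix(1, n, length(substrates),
                        dimnames = list(NULL, substrates)),
    upt_rate = matrix(0, n, length(substrates),
                      dimnames = list(NULL, substrates)),
    next_id = n + 1L
  )
  class(cells) <- "cell_population"
  reset_behaviors(cells, seq_len(n))
}

# (re)apply type-level constant parameters to the given cells; rules overwrite
# on top of this baseline each rules step
reset_behaviors <- function(cells, idx = seq_along(cells$id)) {
  for (tn in unique(cells$type[idx])) {
    ty <- cells$types[[tn]]
    sel <- idx[cells$type[idx] == tn]
    cells$par[sel, ] <- matrix(rep(c(
      ty$S_max, ty$bias, ty$ecm_sensitivity, ty$tau_p, ty$C_cca, ty$C_ccr,
      ty$r_f0, ty$r_a0, ty$r_rho, ty$rho_target, as.numeric(ty$instant),
      ty$rho_l, ty$rho_ideal, ty$rho_h, .chemo_code[[ty$chemotaxis_model]],
      if (is.na(ty$chemoattractant)) 0 else
        match(ty$chemoattractant, cells$substrates, nomatch = 0)
    ), each = length(sel)), nrow = length(sel))
    cells$phago_rate[sel] <- ty$phagocytosis_rate
    newly <- sel[cells$volume[sel] == 0]
    cells$volume[newly] <- ty$volume
    cells$volume0[sel] <- ty$volume
    cells$radius[sel] <- radius_from_volume(cells$volume[sel])
    cells$dead[sel] <- pmax(cells$dead[sel], as.integer(ty$dead))
    cells$sec_rate[sel, ] <- 0
    cells$sec_target[sel, ] <- 1
    cells$upt_rate[sel, ] <- 0
    for (sn in names(ty$secretion)) {
      v <- ty$secretion[[sn]]
      cells$sec_rate[sel, sn] <- v[1]
      cells$sec_target[sel, sn] <- if (length(v) > 1) v[2] else 1
    }
    for (sn in names(ty$uptake)) cells$upt_rate[sel, sn] <- ty$uptake[[sn]]
  }
  cells
}

#' Number of cells
#' @param x a `cell_population`.
#' @param ... unused.
#' @export
length.cell_population <- function(x) length(x$id)

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("cell population: %d cells (%d dead)\n", length(x$id),
              sum(x$dead)))
  print(table(x$type))
  invisible(x)
}

# keep a logical/integer subset of cells, preserving storage (id) order
cells_subset <- function(cells, keep) {
  for (f in c("id", "type", "radius", "volume", "volume0", "dead",
              "phago_rate"))
    cells[[f]] <- cells[[f]][keep]
  for (f in c("pos", "motdir", "vel", "par", "sec_rate", "sec_target",
              "upt_rate"))
    cells[[f]] <- cells[[f]][keep, , drop = FALSE]
  cells
}

# append freshly placed cells of one type
cells_append <- function(cells, type, positions) {
  positions <- rbind(positions)
  n0 <- length(cells$id)
  n <- nrow(positions)
  if (n == 0) return(cells)
  cells$id <- c(cells$id, cells$next_id - 1L + seq_len(n))
  cells$next_id <- cells$next_id + n
  cells$type <- c(cells$type, rep(type, n))
  cells$pos <- rbind(cells$pos, positions)
  cells$motdir <- rbind(cells$motdir, matrix(rep(c(1, 0, 0), each = n), ncol = 3))
  cells$vel <- rbind(cells$vel, matrix(0, n, 3))
  for (f in c("radius", "volume", "volume0", "phago_rate"))
    cells[[f]] <- c(cells[[f]], numeric(n))
  cells$dead <- c(cells$dead, integer(n))
  cells$par <- rbind(cells$par, matrix(0, n, ncol(cells$par)))
  for (f in c("sec_rate", "sec_target", "upt_rate"))
    cells[[f]] <- rbind(cells[[f]], matrix(0, n, ncol(cells[[f]])))
  reset_behaviors(cells, n0 + seq_len(n))
}

#' Pairwise adhesion-repulsion velocity between two cells
#'
#' With `d` the center distance, `R = R_i + R_j` and the maximum adhesive
#' reach `R_A = adhesion_distance_factor * R`, the contribution to cell i is
#' `[-sqrt(C_ccr,i C_ccr,j) (1 - d/R)^2 1(d<R) + sqrt(C_cca,i C_cca,j)
#' (1 - d/R_A)^2 1(d<R_A)] u`, with `u` the unit vector from i toward j.
#' The contribution to j is the negation. Heterotypic coefficients combine by
#' geometric mean (identical cells recover their common value).
#'
#' @param pos_i,pos_j cell centers (length 3, um).
#' @param radius_i,radius_j radii (um).
#' @param cca_i,cca_j adhesion strengths (um/min).
#' @param ccr_i,ccr_j repulsion strengths (um/min).
#' @param adhesion_distance_factor maximum adhesive reach as a multiple of
#'   `R_i + R_j` (default 1.25).
#' @return length-3 velocity contribution to cell i, um/min.
#' @export
pair_velocity <- function(pos_i, pos_j, radius_i, radius_j,
                          cca_i = 0.4, cca_j = cca_i,
                          ccr_i = 10, ccr_j = ccr_i,
                          adhesion_distance_factor = 1.25) {
  dvec <- pos_j - pos_i
  d <- sqrt(sum(dvec^2))
  R <- radius_i + radius_j
  Ra <- adhesion_distance_factor * R
  if (d >= Ra) return(c(0, 0, 0))
  if (d < 1e-12) {
    warning("coincident cell centers; applying seeded random jitter")
    th <- runif(1, 0, 2 * pi)
    u <- c(cos(th), sin(th), 0)
    d <- 1e-6
  } else u <- dvec / d
  mag <- 0
  if (d < R) mag <- mag - sqrt(ccr_i * ccr_j) * (1 - d / R)^2
  mag <- mag + sqrt(cca_i * cca_j) * (1 - d / Ra)^2
  mag * u
}

#' Total velocity of one cell
#'
#' Sum of all pairwise mechanics contributions plus the motility vector; no
#' renormalization is applied, so adhesion pulling against motility reduces
#' the realized speed (the closer the velocities of a cluster's members, the
#' closer its average speed gets to `S_max`).
#'
#' @param cells a `cell_population`.
#' @param domain list with `lo`, `hi` (length-3 bounds, um).
#' @param adhesion_distance_factor see [pair_velocity()].
#' @return n x 3 matrix of velocities, um/min (pair terms + motility vectors
#'   stored in `cells$motvec` if present, else the zero motility).
#' @export
total_velocity <- function(cells, domain, adhesion_distance_factor = 1.25) {
  pv <- cpp_pair_velocities(cells$pos, cells$radius, cells$par[, "cca"],
                            cells$par[, "ccr"], adhesion_distance_factor,
                            domain$lo, domain$hi)
  mv <- if (!is.null(cells$motvec)) cells$motvec else matrix(0, length(cells$id), 3)
  pv + mv
}

#' Advance cell positions (explicit Euler, overdamped)
#'
#' `position <- position + dt * velocity`; positions leaving the domain are
#' reflected back (no-flux boundaries for cells). Single-layer (2-D) domains
#' pin z to the layer center.
#'
#' @param cells a `cell_population` with `vel` set.
#' @param dt mechanics time step, min (default 0.1).
#' @param domain list with `lo`, `hi`.
#' @param two_d pin z?
#' @return the population with updated positions.
#' @export
advance_positions <- function(cells, dt, domain, two_d = TRUE) {
  stopifnot(dt > 0)
  p <- cells$pos + dt * cells$vel
  for (ax in 1:3) {
    lo <- domain$lo[ax]; hi <- domain$hi[ax]
    p[, ax] <- ifelse(p[, ax] < lo, pmin(2 * lo - p[, ax], hi), p[, ax])
    p[, ax] <- ifelse(p[, ax] > hi, pmax(2 * hi - p[, ax], lo), p[, ax])
  }
  if (two_d) p[, 3] <- (domain$lo[3] + domain$hi[3]) / 2
  cells$pos <- p
  cells
}

#' Shrink and remove dead cells
#'
#' Dead cells' volumes decay exponentially (default rate 0.005/min) with
#' radius tracking `(3V/4pi)^(1/3)`; a dead cell is removed once its volume
#' falls below `min_volume_fraction` of its type's default volume (removal by
#' phagocytosis is handled by the rules module).
#'
#' @param cells a `cell_population`.
#' @param dt elapsed time, min.
#' @param shrink_rate exponential volume decay rate for dead cells, 1/min.
#' @param min_volume_fraction removal threshold as a fraction of the default
#'   volume (default 0.03).
#' @return the updated population (possibly with fewer cells).
#' @export
remove_and_shrink_dead <- function(cells, dt, shrink_rate = 0.005,
                                   min_volume_fraction = 0.03) {
  dead <- cells$dead == 1L
  if (any(dead)) {
    cells$volume[dead] <- cells$volume[dead] * exp(-shrink_rate * dt)
    cells$radius[dead] <- radius_from_volume(cells$volume[dead])
  }
  drop <- dead & cells$volume < min_volume_fraction * cells$volume0
  if (any(drop)) cells <- cells_subset(cells, !drop)
  cells
}

#' Cell snapshot as a data frame
#'
#' Columns `id,type,x,y,z,radius,vx,vy,vz,dead`.
#' @param cells a `cell_population`.
#' @return data.frame, one row per cell.
#' @export
cells_df <- function(cells) {
  data.frame(id = cells$id, type = cells$type,
             x = cells$pos[, 1], y = cells$pos[, 2], z = cells$pos[, 3],
             radius = cells$radius,
             vx = cells$vel[, 1], vy = cells$vel[, 2], vz = cells$vel[, 3],
             dead = cells$dead)
}

#' Write a cell snapshot to CSV
#' @param cells a `cell_population`.
#' @param file output path.
#' @export
write_cells_csv <- function(cells, file) {
  write.csv(cells_df(cells), file, row.names = FALSE)
  invisible(file)
}
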