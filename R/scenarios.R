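# Scenario builders and the time-stepping engine. Every experiment in the
# package is produced from configuration alone: a domain, an initial ECM
# field, substrate definitions, cell-type blocks, a rulebook, and seeds.
# Placement uses its own fixed seed so that initial cell positions are held
# consistent across stochastic replicates; the dynamics seed varies per
# replicate.

#' Mechanical equilibrium spacing of a cell pair
#'
#' Distance at which the repulsion and adhesion polynomials balance:
#' `sqrt(C_ccr) (1 - d/R) = sqrt(C_cca) (1 - d/R_A)` with `R = 2 r` and
#' `R_A = adhesion_distance_factor * R`. With zero adhesion this is the
#' contact distance `2 r`. Used as the default hexagonal packing spacing.
#'
#' @param C_cca,C_ccr adhesion/repulsion strengths, um/min.
#' @param radius cell radius, um.
#' @param adhesion_distance_factor maximum adhesive reach factor.
#' @return spacing in um.
#' @export
equilibrium_spacing <- function(C_cca, C_ccr, radius = radius_from_volume(2494),
                                adhesion_distance_factor = 1.25) {
  R <- 2 * radius
  if (C_cca <= 0) return(R)
  if (C_ccr <= C_cca) stop("no stable spacing: repulsion must exceed adhesion")
  (sqrt(C_ccr) - sqrt(C_cca)) /
    (sqrt(C_ccr) / R - sqrt(C_cca) / (adhesion_distance_factor * R))
}

#' Hexagonally packed disc of cell positions
#'
#' Triangular lattice (row pitch `spacing * sqrt(3)/2`, alternate rows offset
#' by `spacing / 2`) centered on `center`, keeping points within distance `R`
#' of the center. Deterministic. The half-disc variant keeps `y >= center_y`
#' (cells initialized at approximate equilibrium spacing with six neighbors).
#'
#' @param center disc center (length 3, um).
#' @param R disc radius, um.
#' @param spacing lattice spacing, um (e.g. [equilibrium_spacing()]).
#' @param half keep only the upper half (`y >= center[2]`)?
#' @return n x 3 matrix of positions.
#' @export
hex_pack_disc <- function(center = c(0, 0, 0), R = 175, spacing, half = FALSE) {
  stopifnot(spacing > 0)
  pitch <- spacing * sqrt(3) / 2
  jmax <- ceiling(R / pitch) + 1L
  imax <- ceiling(R / spacing) + 1L
  js <- if (half) 0:jmax else (-jmax):jmax
  out <- NULL
  for (j in js) {
    y <- j * pitch
    off <- if (j %% 2 == 0) 0 else spacing / 2
    xs <- ((-imax):imax) * spacing + off
    keep <- xs^2 + y^2 <= R^2
    if (any(keep)) out <- rbind(out, cbind(xs[keep], y, 0))
  }
  if (is.null(out)) out <- matrix(c(0, 0, 0), 1)
  sweep(out, 2, center, `+`)
}

#' Add an influx of cells along a domain edge
#'
#' Places `n_cells` of the given type at uniformly random positions along the
#' specified edge, inset by one cell radius plus a sub-micrometer random
#' jitter (an exactly collinear row is mechanically degenerate: pairwise
#' forces would never acquire a component away from the edge). Positions are
#' drawn from the current (dynamics) RNG stream. Placement collisions are
#' allowed; the mechanics resolves overlap.
#'
#' @param state a `simulation_state`.
#' @param n_cells number of cells per event.
#' @param type cell type name.
#' @param edge one of `"ymin"`, `"ymax"`, `"xmin"`, `"xmax"`.
#' @return the updated state.
#' @export
boundary_influx <- function(state, n_cells, type, edge = "ymin") {
  dom <- state$domain
  r <- radius_from_volume(state$cells$types[[type]]$volume)
  zc <- (dom$lo[3] + dom$hi[3]) / 2
  inset <- r + runif(n_cells, 0, 1)
  pos <- switch(edge,
    ymin = cbind(runif(n_cells, dom$lo[1] + r, dom$hi[1] - r), dom$lo[2] + inset, zc),
    ymax = cbind(runif(n_cells, dom$lo[1] + r, dom$hi[1] - r), dom$hi[2] - inset, zc),
    xmin = cbind(dom$lo[1] + inset, runif(n_cells, dom$lo[2] + r, dom$hi[2] - r), zc),
    xmax = cbind(dom$hi[1] - inset, runif(n_cells, dom$lo[2] + r, dom$hi[2] - r), zc),
    stop("unknown edge: ", edge))
  state$cells <- cells_append(state$cells, type, pos)
  state
}

# rejection-sample n points uniformly in the domain interior outside the
# exclusion predicate
place_random_outside <- function(n, dom, margin = 20, exclude = NULL) {
  zc <- (dom$lo[3] + dom$hi[3]) / 2
  out <- matrix(0, 0, 3)
  while (nrow(out) < n) {
    m <- 2 * (n - nrow(out)) + 10
    x <- runif(m, dom$lo[1] + margin, dom$hi[1] - margin)
    y <- runif(m, dom$lo[2] + margin, dom$hi[2] - margin)
    keep <- if (is.null(exclude)) rep(TRUE, m) else !exclude(x, y)
    out <- rbind(out, cbind(x[keep], y[keep], zc))
  }
  out[seq_len(n), , drop = FALSE]
}

new_config <- function(name, domain, duration, seed,
                       dt_diffusion = 0.01, dt_mech = 0.1, dt_rules = 6,
                       output_interval = 360, placement_seed = 1912L,
                       influx = NULL, rules = rulebook(),
                       wrap_x = FALSE, adhesion_distance_factor = 1.25,
                       shrink_rate = 0.005, min_volume_fraction = 0.03,
                       precondition = 10) {
  if (!(dt_diffusion <= dt_mech && dt_mech <= dt_rules))
    stop("need dt_diffusion <= dt_mech <= dt_rules")
  if (abs(dt_rules / dt_mech - round(dt_rules / dt_mech)) > 1e-9)
    stop("dt_rules must be a multiple of dt_mech")
  if (abs(duration %% dt_rules) > 1e-9)
    stop("duration must be a multiple of dt_rules")
  if (abs(output_interval %% dt_rules) > 1e-9)
    stop("output_interval must be a multiple of dt_rules")
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

new_state <- function(cells, grid, substrates, domain) {
  structure(list(t = 0, cells = cells, grid = grid, substrates = substrates,
                 domain = domain), class = "simulation_state")
}

#' Read a scenario configuration file
#'
#' JSON file with a `scenario` name plus any override arguments of the
#' corresponding builder (see [build_scenario()]).
#' @param path file path.
#' @return list with `scenario` and `overrides`.
#' @export
read_scenario_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$scenario)) stop("config file must name a scenario")
  list(scenario = cfg$scenario,
       overrides = cfg[setdiff(names(cfg), "scenario")])
}

#' Build a scenario
#'
#' Returns a fully initialized `(config, state)` pair for one of the built-in
#' experiments:
#' `poc_combing`, `poc_stripes`, `poc_circles_random`,
#' `poc_circles_chemotaxis`, `invasive_front`, `fibrosis`,
#' `basement_membrane`, `leader_follower`.
#' Initial ECM fields and cell placements are generated under the fixed
#' `placement_seed` so replicates share initial conditions; `seed` drives the
#' dynamics only.
#'
#' @param name scenario name.
#' @param seed dynamics seed for this replicate.
#' @param overrides named list of builder arguments to override (e.g.
#'   `list(variant = "parallel")` for the invasive front, `list(mode =
#'   "writing_only", remodeling = "continuous")` for leader-follower, or any
#'   geometric/kinetic parameter exposed by the builder).
#' @return list with `config` and `state`.
#' @export
build_scenario <- function(name, seed = 1, overrides = list()) {
  builder <- switch(name,
    poc_combing = scenario_combing,
    poc_stripes = scenario_stripes,
    poc_circles_random = function(seed, ...) scenario_circles(seed, chemotaxis = FALSE, ...),
    poc_circles_chemotaxis = function(seed, ...) scenario_circles(seed, chemotaxis = TRUE, ...),
    invasive_front = scenario_invasive_front,
    fibrosis = scenario_fibrosis,
    basement_membrane = scenario_basement_membrane,
    leader_follower = scenario_leader_follower,
    stop("unknown scenario: ", name))
  do.call(builder, c(list(seed = seed), overrides))
}

# --- proof-of-concept builders ----------------------------------------------

# a static substrate whose gradient points along +x (used as the external
# chemotactic cue of the proof-of-concept experiments)
static_ramp <- function(grid, name = "guide") {
  ctr <- element_centers(grid)
  substrate_field(grid, name, D = 0, lambda = 0,
                  initial = (ctr[, 1] - grid$lo[1]) / (grid$hi[1] - grid$lo[1]),
                  static = TRUE)
}

scenario_combing <- function(seed, width = 400, height = 200, S_max = 1.25,
                             r_f0 = 4, r_a0 = 0.004, anisotropy = 0.9,
                             density = 0.5, passes = 4,
                             placement_seed = 1912L, output_interval = NULL) {
  set.seed(placement_seed)
  grid <- ecm_grid(c(0, width), c(0, height))
  grid <- make_field(grid, field_uniform_random(), anisotropy, density)
  guide <- static_ramp(grid)
  comber <- cell_type("comber", S_max = S_max, bias = 1, ecm_sensitivity = 0,
                      tau_p = 0.1, C_cca = 0, C_ccr = 0, r_f0 = r_f0,
                      r_a0 = r_a0, chemotaxis_model = "I",
                      chemoattractant = "guide")
  ys <- seq(grid$h / 2, height - grid$h / 2, by = grid$h)
  cells <- make_cells(list(comber),
                      list(list(type = "comber",
                                positions = cbind(grid$h / 2, ys, 0))),
                      substrates = "guide")
  duration <- passes * width / S_max
  dt_rules <- 4
  duration <- round(duration / dt_rules) * dt_rules
  cfg <- new_config("poc_combing", domain = list(lo = grid$lo, hi = grid$hi),
                    duration = duration, seed = seed, dt_rules = dt_rules,
                    output_interval = if (is.null(output_interval)) duration
                                      else output_interval,
                    placement_seed = placement_seed, wrap_x = TRUE,
                    precondition = 0)
  list(config = cfg,
       state = new_state(cells, grid, list(guide),
                         list(lo = grid$lo, hi = grid$hi)))
}

scenario_stripes <- function(seed, width = 400, height = 200,
                             theta_top = pi / 4, theta_bottom = -pi / 4,
                             S_max = 1, duration = 48,
                             placement_seed = 1912L) {
  set.seed(placement_seed)
  grid <- ecm_grid(c(0, width), c(0, height))
  grid <- make_field(grid, field_stripes(theta_top, theta_bottom),
                     anisotropy = 1, density = 0.5)
  guide <- static_ramp(grid)
  walker <- cell_type("walker", S_max = S_max, bias = 1, ecm_sensitivity = 1,
                      tau_p = 0.1, C_cca = 0, C_ccr = 0,
                      chemotaxis_model = "I", chemoattractant = "guide")
  ys <- seq(50, height - 50, by = 20)
  cells <- make_cells(list(walker),
                      list(list(type = "walker", positions = cbind(20, ys, 0))),
                      substrates = "guide")
  cfg <- new_config("poc_stripes", domain = list(lo = grid$lo, hi = grid$hi),
                    duration = duration, seed = seed, output_interval = duration,
                    placement_seed = placement_seed, precondition = 0)
  list(config = cfg,
       state = new_state(cells, grid, list(guide),
                         list(lo = grid$lo, hi = grid$hi)))
}

scenario_circles <- function(seed, chemotaxis = FALSE, half_width = 400,
                             duration = if (chemotaxis) 1500 else 900,
                             exclusion_radius = 80, placement_seed = 1912L,
                             output_interval = NULL) {
  set.seed(placement_seed)
  grid <- ecm_grid(c(-half_width, half_width), c(-half_width, half_width))
  grid <- make_field(grid, field_concentric(c(0, 0, 0), exclusion_radius),
                     anisotropy = 1, density = 0.5)
  subs <- list()
  walker <- cell_type("walker", S_max = 1,
                      bias = if (chemotaxis) 1 else 0, ecm_sensitivity = 1,
                      tau_p = if (chemotaxis) 0.1 else 10,
                      C_cca = 0, C_ccr = 0,
                      chemotaxis_model = if (chemotaxis) "I" else "none",
                      chemoattractant = if (chemotaxis) "guide" else NA)
  if (chemotaxis) subs <- list(static_ramp(grid))
  pos <- if (chemotaxis) {
    th <- seq(0, 2 * pi, length.out = 13)[-13]
    cbind(260 * cos(th), 260 * sin(th), 0)
  } else {
    x <- c(seq(-360, -120, by = 40), seq(120, 360, by = 40))
    cbind(x, 0, 0)
  }
  cells <- make_cells(list(walker), list(list(type = "walker", positions = pos)),
                      substrates = if (chemotaxis) "guide" else character())
  cfg <- new_config(if (chemotaxis) "poc_circles_chemotaxis" else
                      "poc_circles_random",
                    domain = list(lo = grid$lo, hi = grid$hi),
                    duration = duration, seed = seed,
                    output_interval = if (is.null(output_interval)) duration
                                      else output_interval,
                    placement_seed = placement_seed, precondition = 0)
  list(config = cfg,
       state = new_state(cells, grid, subs, list(lo = grid$lo, hi = grid$hi)))
}

# --- application builders ----------------------------------------------------

scenario_invasive_front <- function(seed, variant = "random", width = 600,
                                    height = 1000, duration = 7200,
                                    influx_n = 30, influx_period = 180,
                                    influx_end = 5400, S_max = 1.25,
                                    C_cca = 0.4, C_ccr = 25, tau_p = 10,
                                    placement_seed = 1912L,
                                    output_interval = NULL) {
  set.seed(placement_seed)
  grid <- ecm_grid(c(0, width), c(0, height))
  grid <- make_field(grid, field_front(variant), anisotropy = 1, density = 0.5)
  invader <- cell_type("invader", S_max = S_max, ecm_sensitivity = 1,
                       tau_p = tau_p, C_cca = C_cca, C_ccr = C_ccr)
  cells <- make_cells(list(invader), list(), substrates = character())
  cfg <- new_config("invasive_front", domain = list(lo = grid$lo, hi = grid$hi),
                    duration = duration, seed = seed,
                    output_interval = if (is.null(output_interval)) duration
                                      else output_interval,
                    placement_seed = placement_seed,
                    influx = list(n = influx_n, period = influx_period,
                                  end = influx_end, type = "invader",
                                  edge = "ymin"),
                    precondition = 0)
  list(config = cfg,
       state = new_state(cells, grid, list(), list(lo = grid$lo, hi = grid$hi)))
}

scenario_fibrosis <- function(seed, domain_size = 1000, wound_radius = 175,
                              wound_spacing = 18.5,
                              n_macrophage = 40, n_fibroblast = 59,
                              duration = 21600, dt_diffusion = 0.01,
                              deposition_rate = 0.01, phago_rate = 0.002,
                              inflam_secretion = 1, inflam_half_max = 0.05,
                              deposition_half_max = 0.02, debris_uptake = 0,
                              chemo_bias = 0.9,
                              rho_h = 0.9, shrink_rate = 0.001,
                              exclusion_half = 100, placement_seed = 1912L,
                              output_interval = 1440) {
  set.seed(placement_seed)
  hw <- domain_size / 2
  grid <- ecm_grid(c(-hw, hw), c(-hw, hw))
  grid <- make_field(grid, field_uniform_random(), anisotropy = 0, density = 0.5)
  debris <- substrate_field(grid, "debris", D = 1, lambda = 0)
  inflam <- substrate_field(grid, "inflam", D = 1000, length_scale = 32)
  dead_cell <- cell_type("dead_cell", C_cca = 0, dead = TRUE,
                         secretion = list(debris = c(1, 1)))
  macrophage <- cell_type("macrophage", S_max = 1, bias = chemo_bias,
                          chemotaxis_model = "I", chemoattractant = "debris",
                          rho_h = rho_h, uptake = list(debris = debris_uptake))
  # fibroblasts keep the full density tent (hard stop only at rho = 1): they
  # creep slowly through elements already densified past the macrophage hard
  # stop, which lets a single fibroblast paint a contiguous patch instead of
  # walling itself into one element
  fibroblast <- cell_type("fibroblast", S_max = 1, bias = chemo_bias,
                          chemotaxis_model = "I", chemoattractant = "inflam",
                          rho_h = 1, rho_target = 1)
  rules <- rulebook(
    rule("macrophage", "contact:dead", "phagocytosis_rate", "increase",
         base_value = 0, saturation_value = phago_rate, half_max = 1),
    rule("macrophage", "substrate:debris", "secretion_rate:inflam", "increase",
         base_value = 0, saturation_value = inflam_secretion,
         half_max = inflam_half_max, hill_power = 2),
    rule("fibroblast", "substrate:inflam", "ecm_density_target_rate",
         "increase", base_value = 0, saturation_value = deposition_rate,
         half_max = deposition_half_max, hill_power = 2))
  wound <- hex_pack_disc(c(0, 0, 0), wound_radius, spacing = wound_spacing)
  dom <- list(lo = grid$lo, hi = grid$hi)
  outside_square <- function(x, y) abs(x) <= exclusion_half & abs(y) <= exclusion_half
  recruits <- place_random_outside(n_macrophage + n_fibroblast, dom,
                                   exclude = outside_square)
  cells <- make_cells(list(dead_cell, macrophage, fibroblast),
                      list(list(type = "dead_cell", positions = wound),
                           list(type = "macrophage",
                                positions = recruits[seq_len(n_macrophage), ,
                                                     drop = FALSE]),
                           list(type = "fibroblast",
                                positions = recruits[n_macrophage +
                                                       seq_len(n_fibroblast), ,
                                                     drop = FALSE])),
                      substrates = c("debris", "inflam"))
  cfg <- new_config("fibrosis", domain = dom, duration = duration, seed = seed,
                    dt_diffusion = dt_diffusion,
                    output_interval = output_interval,
                    placement_seed = placement_seed, rules = rules,
                    shrink_rate = shrink_rate)
  cfg$wound_radius <- wound_radius
  cfg$rho_h <- rho_h
  list(config = cfg,
       state = new_state(cells, grid, list(debris, inflam), dom))
}

scenario_basement_membrane <- function(seed, domain_size = 1000,
                                       duct_radius = 175,
                                       n_fibroblast = NULL, band_width = 40,
                                       duration = 14400, dt_diffusion = 0.01,
                                       degradation_rate = 0.05,
                                       cancer_S_max = 1, chemo_bias = 0.9,
                                       r_f0 = 4, r_a0 = 0.004,
                                       oxygen_uptake = 30,
                                       placement_seed = 1912L,
                                       output_interval = 1440) {
  set.seed(placement_seed)
  hw <- domain_size / 2
  grid <- ecm_grid(c(-hw, hw), c(-hw, hw))
  grid <- make_field(grid, field_layered_duct(membrane_top = 0,
                                              membrane_bottom = -band_width),
                     anisotropy = 0)
  inflam <- substrate_field(grid, "inflam", D = 1000, length_scale = 100)
  oxygen <- substrate_field(grid, "oxygen", D = 1e5, length_scale = 1000,
                            initial = 1, dirichlet = c(ymin = 1))
  cancer <- cell_type("cancer", S_max = cancer_S_max, bias = chemo_bias,
                      ecm_sensitivity = 1, C_cca = 10, C_ccr = 25,
                      chemotaxis_model = "I", chemoattractant = "oxygen",
                      secretion = list(inflam = c(1, 1)),
                      uptake = list(oxygen = oxygen_uptake))
  fibroblast <- cell_type("fibroblast", S_max = 1, bias = chemo_bias,
                          chemotaxis_model = "I", chemoattractant = "inflam",
                          r_rho = degradation_rate, rho_target = 0.5,
                          r_f0 = r_f0, r_a0 = r_a0,
                          uptake = list(oxygen = oxygen_uptake))
  rules <- rulebook(
    rule("cancer", "contact:fibroblast", "C_cca", "decrease",
         base_value = 10, saturation_value = 0.4, half_max = 0.5),
    rule("fibroblast", "contact:cancer", "S_max", "decrease",
         base_value = 1, saturation_value = 0.1, half_max = 0.5))
  # half-disc resting on the membrane: diameter row half an element below the
  # lumen-membrane interface so the bottom cell row sits in the top membrane
  # elements
  tumor <- hex_pack_disc(c(0, -grid$h / 2, 0), duct_radius,
                         spacing = equilibrium_spacing(10, 25), half = TRUE)
  n_cancer <- nrow(tumor)
  if (is.null(n_fibroblast)) n_fibroblast <- 517 - n_cancer
  dom <- list(lo = grid$lo, hi = grid$hi)
  in_stroma <- function(x, y) y > -band_width - 40
  fibro_pos <- place_random_outside(n_fibroblast, dom, exclude = in_stroma)
  cells <- make_cells(list(cancer, fibroblast),
                      list(list(type = "cancer", positions = tumor),
                           list(type = "fibroblast", positions = fibro_pos)),
                      substrates = c("inflam", "oxygen"))
  cfg <- new_config("basement_membrane", domain = dom, duration = duration,
                    seed = seed, dt_diffusion = dt_diffusion,
                    output_interval = output_interval,
                    placement_seed = placement_seed, rules = rules)
  cfg$band_midline <- -band_width / 2
  list(config = cfg,
       state = new_state(cells, grid, list(inflam, oxygen), dom))
}

scenario_leader_follower <- function(seed, mode = "both",
                                     remodeling = "instant", adhesion = 10,
                                     S_max = 0.5, domain_size = 1000,
                                     disc_radius = 175,
                                     leader_fraction = 0.05,
                                     r_f0 = 4, r_a0 = 0.004,
                                     duration = 14400, dt_diffusion = 0.01,
                                     oxygen_uptake = 30,
                                     placement_seed = 1912L,
                                     output_interval = 1440) {
  mode <- match.arg(mode, c("both", "writing_only", "reading_only"))
  remodeling <- match.arg(remodeling, c("instant", "continuous"))
  set.seed(placement_seed)
  hw <- domain_size / 2
  grid <- ecm_grid(c(-hw, hw), c(-hw, hw))
  grid <- make_field(grid, field_uniform_random(), anisotropy = 0, density = 0.5)
  oxygen <- substrate_field(grid, "oxygen", D = 1e5, length_scale = 1000,
                            initial = 1,
                            dirichlet = c(xmin = 1, xmax = 1, ymin = 1, ymax = 1))
  writes <- mode != "reading_only"
  reads <- mode != "writing_only"
  leader <- cell_type("leader", S_max = S_max, bias = 1, ecm_sensitivity = 0,
                      C_cca = adhesion, C_ccr = 25,
                      chemotaxis_model = "I", chemoattractant = "oxygen",
                      instant = remodeling == "instant" && writes,
                      r_f0 = if (writes) r_f0 else 0,
                      r_a0 = if (writes) r_a0 else 0,
                      uptake = list(oxygen = oxygen_uptake))
  follower <- cell_type("follower", S_max = S_max,
                        ecm_sensitivity = if (reads) 1 else 0,
                        C_cca = adhesion, C_ccr = 25,
                        chemotaxis_model = "II", chemoattractant = "oxygen",
                        uptake = list(oxygen = oxygen_uptake))
  disc <- hex_pack_disc(c(0, 0, 0), disc_radius,
                        spacing = equilibrium_spacing(10, 25))
  n <- nrow(disc)
  lead_idx <- sample(n, round(leader_fraction * n))
  dom <- list(lo = grid$lo, hi = grid$hi)
  cells <- make_cells(list(leader, follower),
                      list(list(type = "leader",
                                positions = disc[lead_idx, , drop = FALSE]),
                           list(type = "follower",
                                positions = disc[-lead_idx, , drop = FALSE])),
                      substrates = "oxygen")
  cfg <- new_config("leader_follower", domain = dom, duration = duration,
                    seed = seed, dt_diffusion = dt_diffusion,
                    output_interval = output_interval,
                    placement_seed = placement_seed)
  cfg$mode <- mode
  cfg$remodeling <- remodeling
  list(config = cfg, state = new_state(cells, grid, list(oxygen), dom))
}

# --- engine loop --------------------------------------------------------------

state_snapshot <- function(state, out_dir, frame) {
  if (!is.null(out_dir)) {
    tag <- formatC(frame, width = 4, flag = "0")
    write_cells_csv(state$cells, file.path(out_dir, paste0("cells_", tag, ".csv")))
    write_ecm_csv(state$grid, file.path(out_dir, paste0("ecm_", tag, ".csv")))
  }
  list(time = state$t, cells = cells_df(state$cells))
}

#' Run a scenario
#'
#' Advances the state from t = 0 to the configured duration. Loop order per
#' rules step: signal readings and rule evaluation, phagocytosis, removal of
#' fully shrunk dead cells, boundary influx, then the mechanics sub-loop
#' (diffusion substeps, motility update, pairwise mechanics, position
#' advance, ECM remodeling, dead-cell shrinkage) carried out by compiled
#' code. The dynamics RNG is seeded from `config$seed` at entry, so two runs
#' with the same seed are bit-identical. Non-finite state aborts with a
#' diagnostic.
#'
#' @param scenario list with `config` and `state` from [build_scenario()].
#' @param out_dir optional directory for CSV snapshots (`cells_####.csv`,
#'   `ecm_####.csv` per output time).
#' @param keep_snapshots keep in-memory cell snapshots at every output
#'   interval?
#' @return list with the final `state`, the `config`, and `snapshots` (list
#'   of `time` + cell data frames).
#' @export
run_simulation <- function(scenario, out_dir = NULL, keep_snapshots = TRUE) {
  cfg <- scenario$config
  state <- scenario$state
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  set.seed(cfg$seed)
  # pre-condition the diffusive microenvironment before t = 0
  if (cfg$precondition > 0 && length(state$substrates)) {
    nst <- round(cfg$precondition / cfg$dt_mech)
    nsub <- round(cfg$dt_mech / cfg$dt_diffusion)
    for (s in seq_along(state$substrates)) {
      if (state$substrates[[s]]$static) next
      for (i in seq_len(nst * nsub))
        state$substrates[[s]] <- diffusion_step(state$substrates[[s]],
                                                cfg$dt_diffusion)
    }
  }
  frame <- 0L
  snapshots <- list()
  snap <- state_snapshot(state, out_dir, frame)
  if (keep_snapshots) snapshots[[1]] <- snap
  k_mech <- round(cfg$dt_rules / cfg$dt_mech)
  n_diff <- round(cfg$dt_mech / cfg$dt_diffusion)
  n_int <- round(cfg$duration / cfg$dt_rules)
  for (interval in seq_len(n_int)) {
    cells <- state$cells
    # rules, phagocytosis, death bookkeeping, influx at the interval start
    if (length(cfg$rules) && length(cells$id)) {
      sig <- compute_signals(cells, state$substrates, state$grid)
      cells <- evaluate_rules(cells, sig, cfg$rules, cfg$dt_rules)
    }
    if (any(cells$phago_rate > 0) && any(cells$dead == 1L))
      cells <- phagocytose(cells, cfg$dt_rules)
    drop <- cells$dead == 1L & cells$volume < cfg$min_volume_fraction * cells$volume0
    if (any(drop)) cells <- cells_subset(cells, !drop)
    state$cells <- cells
    if (!is.null(cfg$influx) && state$t < cfg$influx$end &&
        abs(state$t %% cfg$influx$period) < 1e-9)
      state <- boundary_influx(state, cfg$influx$n, cfg$influx$type,
                               cfg$influx$edge)
    cells <- state$cells
    res <- cpp_engine_advance(
      cells$pos, cells$motdir, cells$radius, cells$volume, cells$dead,
      cells$par, cells$sec_rate, cells$sec_target, cells$upt_rate,
      state$grid$f, state$grid$a, state$grid$rho,
      lapply(state$substrates, function(s)
        list(conc = s$conc, D = s$D, lambda = s$lambda,
             dirichlet = s$dirichlet, static = s$static)),
      state$grid$dims, state$grid$origin, state$grid$h,
      state$domain$lo, state$domain$hi,
      k_mech, cfg$dt_mech, n_diff, cfg$dt_diffusion,
      state$grid$two_d, cfg$wrap_x, cfg$adhesion_distance_factor,
      cfg$shrink_rate)
    cells$pos <- res$pos; cells$motdir <- res$motdir; cells$vel <- res$vel
    cells$radius <- res$radius; cells$volume <- res$volume
    state$grid$f <- res$ecm_f; state$grid$a <- res$ecm_a
    state$grid$rho <- res$ecm_rho
    for (s in seq_along(state$substrates)) {
      state$substrates[[s]]$conc <- res$subs_conc[[s]]
      if (any(!is.finite(res$subs_conc[[s]])))
        stop("non-finite concentration in substrate ",
             state$substrates[[s]]$name, " (microenvironment)")
    }
    state$cells <- cells
    state$t <- state$t + cfg$dt_rules
    if (abs(state$t %% cfg$output_interval) < 1e-9) {
      frame <- frame + 1L
      snap <- state_snapshot(state, out_dir, frame)
      if (keep_snapshots) snapshots[[frame + 1L]] <- snap
    }
  }
  list(state = state, config = cfg, snapshots = snapshots)
}
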