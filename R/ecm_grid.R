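# The ECM data structure: a Cartesian mesh of ECM elements, each carrying a
# nondirectional unit fiber orientation, an anisotropy in [0,1] (fiber-fiber
# alignment correlation) and a density in [0,1] (fiber volume fraction).
# The element mesh is coincident with the diffusion mesh: same origin, same
# spacing.

#' Create an ECM grid over a rectangular domain
#'
#' Builds a Cartesian mesh of ECM elements covering the domain exactly.
#' Element `(i,j,k)` (zero-based) spans the half-open box
#' `[origin + i*h, origin + (i+1)*h)` along each axis. Two-dimensional
#' simulations use a single layer of 3-D elements (`zlim` spanning one
#' element) with all orientation z-components forced to zero.
#'
#' @param xlim,ylim,zlim numeric length-2 domain bounds in micrometers. The
#'   default `zlim` gives one 20 um layer centered on z = 0.
#' @param element_size element side length in micrometers (default 20, on the
#'   order of one cell diameter).
#' @param anisotropy,density initial uniform values in `[0, 1]`.
#' @return An object of class `ecm_grid`: a list with `origin`, `h`, `dims`,
#'   the orientation matrix `f` (elements x 3), vectors `a` and `rho`, and an
#'   `exclude` flag used by summary statistics.
#' @export
ecm_grid <- function(xlim, ylim, zlim = c(-10, 10), element_size = 20,
                     anisotropy = 0, density = 0.5) {
  h <- element_size
  ext <- c(diff(xlim), diff(ylim), diff(zlim))
  dims <- round(ext / h)
  if (any(abs(dims * h - ext) > 1e-6))
    stop("domain extent must be an integer multiple of element_size on every axis")
  dims <- as.integer(pmax(dims, 1L))
  m <- prod(dims)
  g <- list(
    origin = c(xlim[1], ylim[1], zlim[1]),
    h = h,
    dims = dims,
    lo = c(xlim[1], ylim[1], zlim[1]),
    hi = c(xlim[2], ylim[2], zlim[2]),
    two_d = dims[3] == 1L,
    f = matrix(rep(c(1, 0, 0), each = m), ncol = 3),
    a = rep(as.numeric(anisotropy), m),
    rho = rep(as.numeric(density), m),
    exclude = rep(FALSE, m)
  )
  class(g) <- "ecm_grid"
  g
}

#' @export
print.ecm_grid <- function(x, ...) {
  cat(sprintf("ECM grid: %d x %d x %d elements of %g um (origin %s)\n",
              x$dims[1], x$dims[2], x$dims[3], x$h,
              paste(x$origin, collapse = ", ")))
  cat(sprintf("  anisotropy [%.3f, %.3f], density [%.3f, %.3f]\n",
              min(x$a), max(x$a), min(x$rho), max(x$rho)))
  invisible(x)
}

#' Map a position to its ECM element index
#'
#' Half-open convention: a point exactly on an interior face belongs to the
#' higher-index element, so the map from positions to elements is total and
#' unambiguous. Indices are zero-based triples matching
#' `floor((position - origin) / element_size)`.
#'
#' @param grid an [ecm_grid()].
#' @param position numeric length-3 position in micrometers.
#' @return integer triple (zero-based).
#' @export
element_index <- function(grid, position) {
  ax <- c("x", "y", "z")
  out_lo <- position < grid$lo - 1e-12
  out_hi <- position >= grid$hi + 1e-12
  # the upper domain face itself still maps to the last element
  at_hi <- position >= grid$hi - 1e-12 & !out_hi
  if (any(out_lo | out_hi))
    stop(sprintf("position outside domain on axis %s",
                 paste(ax[out_lo | out_hi], collapse = ", ")))
  idx <- as.integer(floor((position - grid$origin) / grid$h))
  idx[at_hi] <- grid$dims[at_hi] - 1L
  pmin(pmax(idx, 0L), grid$dims - 1L)
}

# zero-based triple -> 1-based linear index into the element arrays
element_linear <- function(grid, ijk) {
  1L + ijk[1] + grid$dims[1] * (ijk[2] + grid$dims[2] * ijk[3])
}

#' Element center coordinates
#'
#' @param grid an [ecm_grid()].
#' @return matrix (elements x 3) of element centers, in storage order
#'   (x index fastest).
#' @export
element_centers <- function(grid) {
  d <- grid$dims
  i <- (seq_len(d[1]) - 1)
  j <- (seq_len(d[2]) - 1)
  k <- (seq_len(d[3]) - 1)
  cbind(
    grid$origin[1] + grid$h * (rep(i, times = d[2] * d[3]) + 0.5),
    grid$origin[2] + grid$h * (rep(rep(j, each = d[1]), times = d[3]) + 0.5),
    grid$origin[3] + grid$h * (rep(k, each = d[1] * d[2]) + 0.5)
  )
}

# --- field pattern descriptors ------------------------------------------------

#' ECM field patterns
#'
#' Descriptors for the initial ECM fields used by the scenario builders,
#' consumed by [make_field()]:
#' * `field_uniform_random()`: independent random orientation per element
#'   (in-plane for single-layer grids).
#' * `field_constant(direction)`: one fixed orientation everywhere.
#' * `field_stripes(theta_top, theta_bottom)`: two horizontal half-domains at
#'   the given angles (radians from the x-axis).
#' * `field_front(variant)`: invasive-front configurations with the front
#'   entering from y = 0: `"random"`, `"parallel"` (orientation along x,
#'   parallel to the advancing front), `"perpendicular"` (along y) or
#'   `"mixed"` (outer thirds parallel, central third perpendicular).
#' * `field_concentric(center, exclusion_radius)`: orientation tangent to the
#'   circle through each element center; inside the exclusion radius
#'   (default 80 um, where the piecewise-linear representation of circles
#'   becomes inaccurate) the orientation is random and the element is flagged
#'   as excluded from summary statistics.
#' * `field_layered_duct(...)`: three horizontal density zones - fluid lumen
#'   on top, a dense basement-membrane band, stroma below.
#' @param direction length-3 orientation vector (normalized internally).
#' @param theta_top,theta_bottom stripe angles in radians.
#' @param variant front configuration name.
#' @param center circle center (length 3).
#' @param exclusion_radius radius of the central excluded disc in um.
#' @param lumen_density,membrane_density,stroma_density densities of the three
#'   zones.
#' @param membrane_top,membrane_bottom y-bounds (um) of the membrane band.
#' @return a pattern descriptor for [make_field()].
#' @name field_patterns
NULL

#' @rdname field_patterns
#' @export
field_uniform_random <- function() {
  structure(list(type = "uniform_random"), class = "ecm_field_pattern")
}

#' @rdname field_patterns
#' @export
field_constant <- function(direction) {
  structure(list(type = "constant", direction = direction),
            class = "ecm_field_pattern")
}

#' @rdname field_patterns
#' @export
field_stripes <- function(theta_top, theta_bottom) {
  structure(list(type = "stripes", theta_top = theta_top,
                 theta_bottom = theta_bottom), class = "ecm_field_pattern")
}

#' @rdname field_patterns
#' @export
field_front <- function(variant = c("random", "parallel", "perpendicular",
                                    "mixed")) {
  variant <- match.arg(variant)
  structure(list(type = "front", variant = variant),
            class = "ecm_field_pattern")
}

#' @rdname field_patterns
#' @export
field_concentric <- function(center = c(0, 0, 0), exclusion_radius = 80) {
  structure(list(type = "concentric", center = center,
                 exclusion_radius = exclusion_radius),
            class = "ecm_field_pattern")
}

#' @rdname field_patterns
#' @export
field_layered_duct <- function(lumen_density = 0, membrane_density = 1,
                               stroma_density = 0.5, membrane_top = 0,
                               membrane_bottom = -40) {
  structure(list(type = "layered_duct", lumen_density = lumen_density,
                 membrane_density = membrane_density,
                 stroma_density = stroma_density, membrane_top = membrane_top,
                 membrane_bottom = membrane_bottom),
            class = "ecm_field_pattern")
}

# random in-plane (or 3-D) unit orientations drawn from the current RNG stream
random_orientations <- function(n, two_d) {
  if (two_d) {
    th <- runif(n, 0, 2 * pi)
    cbind(cos(th), sin(th), 0)
  } else {
    u <- runif(n, -1, 1)
    th <- runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - u^2))
    cbind(r * cos(th), r * sin(th), u)
  }
}

#' Initialize an ECM grid from a field pattern
#'
#' Every element receives an orientation from the pattern plus the uniform
#' `anisotropy` and `density` values (the layered duct pattern overrides
#' density zone by zone). Random patterns consume the current RNG stream, so
#' the result is deterministic given the pattern, the grid and the seed.
#'
#' @param grid an [ecm_grid()].
#' @param pattern one of the [field_patterns].
#' @param anisotropy,density uniform initial values in `[0, 1]`.
#' @return the initialized `ecm_grid`.
#' @export
make_field <- function(grid, pattern, anisotropy = grid$a[1],
                       density = grid$rho[1]) {
  if (!inherits(pattern, "ecm_field_pattern"))
    stop("unknown field pattern (use one of the field_* constructors)")
  m <- nrow(grid$f)
  ctr <- element_centers(grid)
  grid$a <- rep(as.numeric(anisotropy), m)
  grid$rho <- rep(as.numeric(density), m)
  grid$exclude <- rep(FALSE, m)
  f <- switch(pattern$type,
    uniform_random = random_orientations(m, grid$two_d),
    constant = {
      d <- pattern$direction / sqrt(sum(pattern$direction^2))
      matrix(rep(d, each = m), ncol = 3)
    },
    stripes = {
      ymid <- (grid$lo[2] + grid$hi[2]) / 2
      th <- ifelse(ctr[, 2] >= ymid, pattern$theta_top, pattern$theta_bottom)
      cbind(cos(th), sin(th), 0)
    },
    front = switch(pattern$variant,
      random = random_orientations(m, grid$two_d),
      parallel = matrix(rep(c(1, 0, 0), each = m), ncol = 3),
      perpendicular = matrix(rep(c(0, 1, 0), each = m), ncol = 3),
      mixed = {
        w <- grid$hi[1] - grid$lo[1]
        central <- ctr[, 1] >= grid$lo[1] + w / 3 &
          ctr[, 1] < grid$lo[1] + 2 * w / 3
        out <- matrix(rep(c(1, 0, 0), each = m), ncol = 3)
        out[central, ] <- matrix(rep(c(0, 1, 0), each = sum(central)), ncol = 3)
        out
      }
    ),
    concentric = {
      dx <- ctr[, 1] - pattern$center[1]
      dy <- ctr[, 2] - pattern$center[2]
      r <- sqrt(dx^2 + dy^2)
      inner <- r < pattern$exclusion_radius
      tang <- cbind(-dy, dx, 0) / pmax(r, 1e-12)
      tang[inner, ] <- random_orientations(sum(inner), grid$two_d)
      grid$exclude <- inner
      tang
    },
    layered_duct = {
      y <- ctr[, 2]
      rho <- ifelse(y >= pattern$membrane_top, pattern$lumen_density,
                    ifelse(y >= pattern$membrane_bottom,
                           pattern$membrane_density, pattern$stroma_density))
      grid$rho <- rho
      random_orientations(m, grid$two_d)
    },
    stop(sprintf("unknown field pattern '%s'", pattern$type))
  )
  if (grid$two_d) f[, 3] <- 0
  dimnames(f) <- NULL
  grid$f <- f / pmax(sqrt(rowSums(f^2)), 1e-12)
  grid
}

#' Summarize an ECM region
#'
#' Arithmetic means over the elements whose centers lie in `region`
#' (optionally restricted further by the grid's exclusion flags). The
#' alignment statistic is `mean(|f . u|)` with the absolute value taken
#' because fiber orientation is nondirectional.
#'
#' @param grid an [ecm_grid()].
#' @param region optional list with `lo` and `hi` length-3 bounds (um);
#'   `NULL` means the whole grid.
#' @param axis reference unit vector for the alignment statistic.
#' @param include_excluded include elements flagged as excluded (e.g. the
#'   center of a concentric-circle field)?
#' @return list with `mean_anisotropy`, `mean_density`, `mean_alignment`,
#'   and the element count `n`.
#' @export
field_summary <- function(grid, region = NULL, axis = c(1, 0, 0),
                          include_excluded = FALSE) {
  ctr <- element_centers(grid)
  keep <- rep(TRUE, nrow(ctr))
  if (!is.null(region)) {
    keep <- ctr[, 1] >= region$lo[1] & ctr[, 1] <= region$hi[1] &
      ctr[, 2] >= region$lo[2] & ctr[, 2] <= region$hi[2] &
      ctr[, 3] >= region$lo[3] & ctr[, 3] <= region$hi[3]
  }
  if (!include_excluded) keep <- keep & !grid$exclude
  if (!any(keep)) stop("empty region: no element centers inside")
  u <- axis / sqrt(sum(axis^2))
  list(
    mean_anisotropy = mean(grid$a[keep]),
    mean_density = mean(grid$rho[keep]),
    mean_alignment = mean(abs(grid$f[keep, , drop = FALSE] %*% u)),
    n = sum(keep)
  )
}

#' Write an ECM snapshot to CSV
#'
#' One row per element center with columns
#' `x,y,z,fx,fy,fz,anisotropy,density`.
#'
#' @param grid an [ecm_grid()].
#' @param file output path.
#' @export
write_ecm_csv <- function(grid, file) {
  ctr <- element_centers(grid)
  df <- data.frame(x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                   fx = grid$f[, 1], fy = grid$f[, 2], fz = grid$f[, 3],
                   anisotropy = grid$a, density = grid$rho)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
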