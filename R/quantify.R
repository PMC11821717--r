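# Measurement procedures: the front-advance histogram metric, the
# wound-enclosure classifier (reachability through sub-blocking ECM), and
# replicate summary tables.

#' Invasive front position
#'
#' Histograms cell y-positions into fixed-width bins and reports the bin
#' containing the 95th percentile of the cell count, using the nearest-rank
#' (ceiling) convention: the value at rank `ceiling(p * N)` of the ascending
#' sort.
#'
#' @param y numeric vector of cell y-positions (um), or a cell snapshot data
#'   frame with a `y` column.
#' @param bin_width histogram bin width, um (default 25).
#' @param percentile front percentile (default 0.95).
#' @return list with `y` (the percentile position), zero-based `bin`, and the
#'   `bin_center` in um.
#' @export
front_position <- function(y, bin_width = 25, percentile = 0.95) {
  if (is.data.frame(y)) y <- y$y
  if (!length(y)) stop("front_position needs at least one cell")
  ys <- sort(y)
  v <- ys[ceiling(percentile * length(ys))]
  bin <- floor(v / bin_width)
  list(y = v, bin = as.integer(bin), bin_center = (bin + 0.5) * bin_width)
}

#' Classify wound enclosure
#'
#' An element is blocked when its density stops migration outright
#' (`density >= rho_h`, the hard-stop node of the density-speed tent). A
#' flood fill with 4-connectivity runs from every boundary element through
#' unblocked elements; if it cannot reach the element containing the wound
#' center the wound is `fully_enclosed`. Otherwise the blocked fraction of
#' the element ring at radius `wound_radius + 2` elements decides between
#' `partially_enclosed` (fraction at or above the threshold) and `open`.
#'
#' @param grid an [ecm_grid()] (single-layer).
#' @param wound_center length-3 wound center (um).
#' @param wound_radius wound radius (um).
#' @param rho_h blocking density (defaults to 0.9, the hard-stop used by the
#'   fibrosis cell types).
#' @param threshold blocked-perimeter fraction separating partial enclosure
#'   from open (default 0.5).
#' @return list of class `enclosure_result` with `label` and
#'   `blocked_fraction`.
#' @export
classify_enclosure <- function(grid, wound_center = c(0, 0, 0),
                               wound_radius = 175, rho_h = 0.9,
                               threshold = 0.5) {
  nx <- grid$dims[1]; ny <- grid$dims[2]
  blocked <- matrix(grid$rho[seq_len(nx * ny)] >= rho_h, nx, ny)
  reached <- flood_fill_from_boundary(blocked)
  cidx <- element_index(grid, wound_center)
  center_reached <- reached[cidx[1] + 1L, cidx[2] + 1L] &&
    !blocked[cidx[1] + 1L, cidx[2] + 1L]
  ctr <- element_centers(grid)[seq_len(nx * ny), , drop = FALSE]
  r <- sqrt((ctr[, 1] - wound_center[1])^2 + (ctr[, 2] - wound_center[2])^2)
  ring_r <- wound_radius + 2 * grid$h
  ring <- which(abs(r - ring_r) <= grid$h / 2)
  frac <- if (length(ring)) mean(blocked[ring]) else 0
  label <- if (!center_reached) "fully_enclosed"
           else if (frac >= threshold) "partially_enclosed"
           else "open"
  structure(list(label = label,
                 blocked_fraction = if (label == "fully_enclosed") 1 else frac),
            class = "enclosure_result")
}

# BFS reachability from all boundary elements through unblocked elements,
# 4-connectivity
flood_fill_from_boundary <- function(blocked) {
  nx <- nrow(blocked); ny <- ncol(blocked)
  reached <- matrix(FALSE, nx, ny)
  queue <- integer(0)
  push <- function(i, j) (j - 1L) * nx + i
  for (i in seq_len(nx)) queue <- c(queue, push(i, 1L), push(i, ny))
  for (j in seq_len(ny)) queue <- c(queue, push(1L, j), push(nx, j))
  queue <- unique(queue[!blocked[queue]])
  reached[queue] <- TRUE
  while (length(queue)) {
    cur <- queue
    queue <- integer(0)
    i <- ((cur - 1L) %% nx) + 1L
    j <- ((cur - 1L) %/% nx) + 1L
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      ii <- i + d[1]; jj <- j + d[2]
      ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
      idx <- (jj[ok] - 1L) * nx + ii[ok]
      idx <- idx[!blocked[idx] & !reached[idx]]
      reached[idx] <- TRUE
      queue <- c(queue, idx)
    }
    queue <- unique(queue)
  }
  reached
}

#' Summarize a metric across replicates
#'
#' @param values numeric metric values, one per replicate.
#' @param metric metric name.
#' @param scenario scenario name (must be a single value; mixing scenarios in
#'   one table is an error).
#' @param file optional CSV output path.
#' @return list with `table` (one row per replicate) and `summary` (mean,
#'   sample standard deviation, min, max).
#' @export
replicate_table <- function(values, metric, scenario, file = NULL) {
  if (length(unique(scenario)) > 1)
    stop("cannot mix scenarios in one replicate table")
  tab <- data.frame(scenario = scenario[1], replicate = seq_along(values),
                    metric = metric, value = values)
  summ <- data.frame(scenario = scenario[1], metric = metric,
                     n = length(values), mean = mean(values),
                     sd = if (length(values) > 1) sd(values) else 0,
                     min = min(values), max = max(values))
  if (!is.null(file)) write.csv(tab, file, row.names = FALSE)
  list(table = tab, summary = summ)
}
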