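#' Define a toroidal landscape
#'
#' The simulation arena is a 1- or 2-dimensional box with periodic (toroidal)
#' boundaries, which removes edge effects and matches the homogeneous SLFV
#' theory. All coordinates handled by the package live in `[0, extent)` on
#' each axis.
#'
#' @param extent Numeric vector of axis lengths (length 1 or 2), all > 0.
#'   Units are arbitrary distance units; every radius, coordinate and
#'   dispersal quantity in the package is expressed in the same units.
#' @return An object of class `slfv_landscape` with fields `dimension`,
#'   `extent` and `area` (length in 1D).
#' @examples
#' landscape(c(1, 1))   # unit 2D torus
#' landscape(10)        # 1D ring of circumference 10
#' @export
landscape <- function(extent) {
  extent <- as.numeric(extent)
  if (!length(extent) %in% 1:2 || anyNA(extent) || any(extent <= 0)) {
    stop("`extent` must be 1 or 2 positive axis lengths", call. = FALSE)
  }
  structure(
    list(dimension = length(extent), extent = extent, area = prod(extent)),
    class = "slfv_landscape"
  )
}

#' @export
print.slfv_landscape <- function(x, ...) {
  cat(sprintf(
    "<slfv_landscape> %dD torus, extent %s\n",
    x$dimension, paste(format(x$extent), collapse = " x ")
  ))
  invisible(x)
}

#' @export
print.slfv_kernel <- function(x, ...) {
  cat(sprintf(
    "<slfv_kernel> %s: radius %g, impact %g, rate density %g%s\n",
    x$family, x$radius, x$impact, x$rate_density,
    if (is.null(x$heterogeneity)) "" else ", heterogeneous raster"
  ))
  invisible(x)
}

as_coord_matrix <- function(x, landscape) {
  m <- if (is.matrix(x)) x else matrix(x, ncol = landscape$dimension, byrow = TRUE)
  if (ncol(m) != landscape$dimension) {
    stop("coordinates must have ", landscape$dimension, " columns", call. = FALSE)
  }
  m
}

check_in_landscape <- function(x, landscape, what = "coordinate") {
  m <- as_coord_matrix(x, landscape)
  ok <- sweep(m, 2, landscape$extent, function(a, b) a >= 0 & a < b)
  if (!all(ok)) {
    stop(what, " outside the landscape [0, extent)", call. = FALSE)
  }
  invisible(m)
}

#' Minimal-image displacement and distance on the torus
#'
#' `torus_displacement()` returns the shortest periodic displacement vector(s)
#' from `a` to `b`; `torus_distance()` returns its Euclidean norm. On a torus
#' the distance between two points is at most half the box diagonal.
#'
#' @param a,b Coordinates: numeric vectors, or matrices with one row per point
#'   and one column per axis. When both are matrices they are paired row-wise
#'   (with recycling of a single row).
#' @param landscape An [landscape()] object.
#' @return `torus_displacement()`: a matrix of displacement vectors;
#'   `torus_distance()`: a numeric vector of distances.
#' @examples
#' L <- landscape(1)
#' torus_distance(0.1, 0.9, L)   # 0.2, across the periodic boundary
#' @export
torus_displacement <- function(a, b, landscape) {
  a <- check_in_landscape(a, landscape)
  b <- check_in_landscape(b, landscape)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  d <- b - a
  for (j in seq_len(ncol(d))) {
    L <- landscape$extent[j]
    d[, j] <- d[, j] - L * round(d[, j] / L)
  }
  d
}

#' @rdname torus_displacement
#' @export
torus_distance <- function(a, b, landscape) {
  d <- torus_displacement(a, b, landscape)
  sqrt(rowSums(d^2))
}

wrap_coords <- function(x, landscape) {
  for (j in seq_len(ncol(x))) {
    x[, j] <- x[, j] %% landscape$extent[j]
  }
  x
}

#' Spatial event kernels
#'
#' An event kernel describes the localized reproduction/extinction events that
#' drive the SLFV process: events fall as a Poisson process in space-time with
#' rate `rate_density` per unit time per unit area (optionally modulated by a
#' raster weight map), and an event centered at `e` affects a lineage at `x`
#' with probability given by the kernel shape:
#'
#' * `"disc"`: probability `impact` if the torus distance to the center is at
#'   most `radius`, else 0 (uniform d-sphere events);
#' * `"gaussian"`: `impact * exp(-dist^2 / (2 * radius^2))`, an untruncated
#'   smooth kernel where `radius` plays the role of the Gaussian scale.
#'
#' The affected lineages coalesce into an ancestor whose location is drawn
#' from the event's replacement distribution (uniform on the disc, or Gaussian
#' around the center, matching the kernel family).
#'
#' @param family `"disc"` or `"gaussian"`.
#' @param radius Disc radius or Gaussian scale, > 0, in landscape units.
#' @param impact Per-lineage selection probability at full kernel weight,
#'   in (0, 1]. Small impacts give near-binary (Kingman-like) mergers; large
#'   impacts give frequent multiple mergers.
#' @param rate_density Events per unit time per unit area, > 0.
#' @param heterogeneity Optional non-negative matrix of raster weights
#'   multiplying the local event intensity (rows = y tiles top-to-bottom not
#'   assumed; the raster is laid out with rows along the x axis and columns
#'   along the y axis, covering the landscape in equal tiles). A 1D landscape
#'   takes a vector. Default `NULL` means a homogeneous landscape.
#' @param landscape Optionally pass the target [landscape()] so the
#'   self-overlap constraint `radius < min(extent)/2` can be checked at
#'   construction time.
#' @param allow_large_radius Set `TRUE` to permit radii at or beyond half the
#'   smallest extent. Such kernels self-overlap on the torus, which is exactly
#'   what a panmictic (whole-torus) event regime needs; the simulator then
#'   uses global event sampling, which remains exact.
#' @return An object of class `slfv_kernel`.
#' @examples
#' event_kernel("disc", radius = 0.1, impact = 0.5, rate_density = 10)
#' @export
event_kernel <- function(family = c("disc", "gaussian"), radius, impact,
                         rate_density,
                         heterogeneity = NULL,
                         landscape = NULL,
                         allow_large_radius = FALSE) {
  family <- match.arg(family)
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0)
  if (!is.numeric(impact) || length(impact) != 1L || impact <= 0 || impact > 1) {
    stop("`impact` must be in (0, 1]", call. = FALSE)
  }
  stopifnot(is.numeric(rate_density), length(rate_density) == 1L, rate_density > 0)
  if (!is.null(heterogeneity)) {
    if (!is.matrix(heterogeneity)) heterogeneity <- matrix(heterogeneity, ncol = 1L)
    if (anyNA(heterogeneity) || any(heterogeneity < 0)) {
      stop("heterogeneity weights must be non-negative and finite", call. = FALSE)
    }
    if (sum(heterogeneity) <= 0) {
      stop("heterogeneity map is zero everywhere", call. = FALSE)
    }
  }
  if (!is.null(landscape) && !allow_large_radius &&
      radius >= min(landscape$extent) / 2) {
    stop(
      "radius must be < min(extent)/2 so the kernel does not self-overlap ",
      "on the torus (use allow_large_radius = TRUE for panmictic kernels)",
      call. = FALSE
    )
  }
  structure(
    list(
      family = family, radius = radius, impact = impact,
      rate_density = rate_density, heterogeneity = heterogeneity
    ),
    class = "slfv_kernel"
  )
}

# Tile layout for a raster heterogeneity map: tile (i, j) covers
# [(i-1)*dx, i*dx) x [(j-1)*dy, j*dy). 1D rasters are n x 1 matrices.
raster_tiles <- function(kernel, landscape) {
  h <- kernel$heterogeneity
  if (is.null(h)) h <- matrix(1, 1L, 1L)
  nx <- nrow(h)
  ny <- if (landscape$dimension == 2L) ncol(h) else 1L
  if (landscape$dimension == 1L && ncol(h) != 1L) {
    stop("1D landscapes take a vector (single-column) heterogeneity map", call. = FALSE)
  }
  dx <- landscape$extent[1] / nx
  dy <- if (landscape$dimension == 2L) landscape$extent[2] / ny else 1
  list(
    weights = as.numeric(h), nx = nx, ny = ny, dx = dx, dy = dy,
    tile_area = dx * if (landscape$dimension == 2L) dy else 1
  )
}

# Total weighted event rate over the landscape (events per unit time).
total_event_rate <- function(kernel, landscape) {
  t <- raster_tiles(kernel, landscape)
  kernel$rate_density * sum(t$weights) * t$tile_area
}

#' Probability that an event affects a lineage
#'
#' The per-lineage selection probability of an event with the given kernel
#' centered at `center`, evaluated for a lineage at `x`. Distances are
#' minimal-image torus distances, so the probability is invariant under any
#' joint torus translation of center and lineage.
#'
#' @inheritParams torus_displacement
#' @param kernel An [event_kernel()].
#' @param center Event center coordinate.
#' @param x Lineage coordinate(s); a matrix evaluates several lineages at once.
#' @return Numeric vector of probabilities in `[0, impact]`.
#' @examples
#' L <- landscape(c(1, 1))
#' k <- event_kernel("disc", 0.1, 0.8, 1)
#' selection_probability(k, c(0.5, 0.5), c(0.52, 0.5), L)  # inside: 0.8
#' @export
selection_probability <- function(kernel, center, x, landscape) {
  d <- torus_distance(center, x, landscape)
  switch(kernel$family,
    disc = ifelse(d <= kernel$radius, kernel$impact, 0),
    gaussian = kernel$impact * exp(-d^2 / (2 * kernel$radius^2))
  )
}

#' Draw the next event
#'
#' Events form a Poisson process in time with rate
#' `rate_density * weighted area`; the waiting time from `current_time` is
#' exponential and the event center falls with density proportional to the
#' heterogeneity raster (uniform on a homogeneous landscape). Tile selection
#' uses inverse-CDF sampling on the raster weights followed by a uniform draw
#' within the tile.
#'
#' @inheritParams selection_probability
#' @param current_time Backward time of the previous event (>= 0).
#' @return A list of class `slfv_event` with `time` (absolute backward time),
#'   `center`, and the `kernel`.
#' @export
sample_event <- function(landscape, kernel, current_time = 0) {
  t <- raster_tiles(kernel, landscape)
  rate <- kernel$rate_density * sum(t$weights) * t$tile_area
  wait <- stats::rexp(1L, rate)
  tile <- sample.int(length(t$weights), 1L, prob = t$weights)
  # raster is column-major over (x tiles, y tiles)
  ix <- (tile - 1L) %% t$nx
  iy <- (tile - 1L) %/% t$nx
  center <- (ix + stats::runif(1L)) * t$dx
  if (landscape$dimension == 2L) {
    center <- c(center, (iy + stats::runif(1L)) * t$dy)
  }
  structure(
    list(time = current_time + wait, center = center, kernel = kernel),
    class = "slfv_event"
  )
}

#' Read and write landscape/kernel configurations
#'
#' Plain-text YAML configuration with keys `dimension`, `extent`, `family`,
#' `radius`, `impact`, `rate_density`, optional `raster` (path to a
#' whitespace-delimited grid of weights, relative to the config file) and
#' optional `seed`.
#'
#' @param path Config file path.
#' @return `read_kernel_config()`: a list with elements `landscape`, `kernel`
#'   and `seed` (NULL if absent).
#' @export
read_kernel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  L <- landscape(as.numeric(cfg$extent))
  raster <- NULL
  if (!is.null(cfg$raster)) {
    rp <- file.path(dirname(path), cfg$raster)
    raster <- as.matrix(utils::read.table(rp))
    dimnames(raster) <- NULL
  }
  k <- event_kernel(
    family = cfg$family, radius = cfg$radius, impact = cfg$impact,
    rate_density = cfg$rate_density, heterogeneity = raster,
    landscape = L, allow_large_radius = isTRUE(cfg$allow_large_radius)
  )
  list(landscape = L, kernel = k, seed = cfg$seed)
}

#' @rdname read_kernel_config
#' @param landscape,kernel Objects to serialize.
#' @param seed Optional integer seed recorded in the config.
#' @export
write_kernel_config <- function(landscape, kernel, path, seed = NULL) {
  cfg <- list(
    dimension = landscape$dimension,
    extent = landscape$extent,
    family = kernel$family,
    radius = kernel$radius,
    impact = kernel$impact,
    rate_density = kernel$rate_density
  )
  if (!is.null(kernel$heterogeneity)) {
    rp <- paste0(tools::file_path_sans_ext(basename(path)), ".raster.txt")
    utils::write.table(kernel$heterogeneity, file.path(dirname(path), rp),
      row.names = FALSE, col.names = FALSE
    )
    cfg$raster <- rp
  }
  if (min(landscape$extent) / 2 <= kernel$radius) cfg$allow_large_radius <- TRUE
  if (!is.null(seed)) cfg$seed <- seed
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' Read and write georeferenced sample sheets
#'
#' Tab-separated sheet with columns `id`, `x` and (for 2D landscapes) `y`;
#' coordinates in landscape units.
#'
#' @param path File path.
#' @param landscape Optional [landscape()] used to validate coordinates.
#' @return A tibble with columns `id`, `x` and optionally `y`.
#' @export
read_sample_sheet <- function(path, landscape = NULL) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()
  ))
  validate_sample_sheet(sheet, landscape)
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(sheet, path)
  invisible(path)
}

validate_sample_sheet <- function(sheet, landscape = NULL) {
  sheet <- tibble::as_tibble(sheet)
  need <- c("id", "x")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet needs columns id, x (and y in 2D)", call. = FALSE)
  }
  if (anyDuplicated(sheet$id)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  if (!is.null(landscape)) {
    if (landscape$dimension == 2L && !"y" %in% names(sheet)) {
      stop("2D landscape needs a y column", call. = FALSE)
    }
    check_in_landscape(sample_locations(sheet, landscape), landscape, "sample location")
  }
  sheet
}

sample_locations <- function(sheet, landscape) {
  cols <- if (landscape$dimension == 2L) c("x", "y") else "x"
  as.matrix(sheet[, cols])
}
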