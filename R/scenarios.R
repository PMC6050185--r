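# run code under a temporary RNG state so scenario construction is
# reproducible without clobbering the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

new_scenario <- function(name, landscape, kernel, sheet, mutation,
                         priors = NULL, seed = 1L, max_events = 5e6) {
  structure(
    list(name = name, landscape = landscape, kernel = kernel, sheet = sheet,
         mutation = mutation, priors = priors, seed = as.integer(seed),
         max_events = max_events),
    class = "slfv_scenario"
  )
}

#' @export
print.slfv_scenario <- function(x, ...) {
  cat(sprintf("<slfv_scenario> '%s': n = %d on %dD torus, %s kernel\n",
              x$name, nrow(x$sheet), x$landscape$dimension, x$kernel$family))
  invisible(x)
}

#' Place sampled individuals on a landscape
#'
#' Uniform-random locations (the default for scenario construction) or a
#' regular grid for deterministic-geometry tests.
#'
#' @param n Number of individuals.
#' @param landscape An [landscape()].
#' @param layout `"uniform"` or `"grid"`.
#' @return A sample-sheet tibble (`id`, `x`, `y` in 2D).
#' @export
place_samples <- function(n, landscape, layout = c("uniform", "grid")) {
  layout <- match.arg(layout)
  d <- landscape$dimension
  if (layout == "uniform") {
    loc <- matrix(stats::runif(n * d), n, d)
    loc <- sweep(loc, 2, landscape$extent, "*")
  } else {
    if (d == 1L) {
      loc <- matrix(landscape$extent[1] * (seq_len(n) - 1) / n, n, 1)
    } else {
      side <- ceiling(sqrt(n))
      g <- expand.grid(ix = seq_len(side) - 1, iy = seq_len(side) - 1)[seq_len(n), ]
      loc <- cbind((g$ix + 0.5) / side * landscape$extent[1],
                   (g$iy + 0.5) / side * landscape$extent[2])
    }
  }
  out <- tibble::tibble(id = sprintf("ind%02d", seq_len(n)), x = loc[, 1])
  if (d == 2L) out$y <- loc[, 2]
  out
}

#' The multilocus validation scenario
#'
#' The package's reference configuration for validating neighborhood-size
#' estimation: 8 individuals sampled at 10 unlinked loci of 1,000 bp each on
#' a homogeneous unit 2D torus with disc events. The free parameters default
#' to the center of the inference priors (neighborhood size log-uniform over
#' a 1.5-decade range, dispersal radius uniform); a concrete kernel at the
#' requested parameter values is attached for direct simulation.
#'
#' @param seed Seed governing the sample locations (and recorded on the
#'   scenario for reproducible runs).
#' @param neighborhood_size,dispersal_radius Generating parameter values;
#'   defaults are the prior medians.
#' @param n,n_loci,seq_length Sampling design; defaults 8, 10, 1000.
#' @param mu Mutation rate per site per unit model time; the default gives
#'   typical nuclear-locus diversity (pi of order 1e-3 to 1e-2) across the
#'   prior range.
#' @param layout Sample placement (see [place_samples()]).
#' @return An `slfv_scenario`.
#' @export
make_validation_scenario <- function(seed = 1L,
                                     neighborhood_size = NULL,
                                     dispersal_radius = NULL,
                                     n = 8L, n_loci = 10L, seq_length = 1000L,
                                     mu = slfv_defaults$mu,
                                     layout = "uniform") {
  L <- landscape(c(1, 1))
  priors <- slfv_priors(slfv_defaults$ns_bounds, slfv_defaults$r_bounds)
  if (is.null(neighborhood_size)) {
    neighborhood_size <- exp(mean(log(slfv_defaults$ns_bounds)))
  }
  if (is.null(dispersal_radius)) {
    dispersal_radius <- mean(slfv_defaults$r_bounds)
  }
  kern <- kernel_for_parameters(neighborhood_size, dispersal_radius, L)
  sheet <- with_local_seed(seed, place_samples(n, L, layout))
  cfg <- mutation_config("k2p", mu = mu, kappa = slfv_defaults$kappa,
                         seq_length = seq_length, n_loci = n_loci)
  new_scenario("validation", L, kern, sheet, cfg, priors, seed)
}

#' Population-structure corner scenarios
#'
#' Three configurations spanning the classical spatial-structure extremes
#' that the SLFV bridges:
#' * `ibd`: homogeneous landscape, dispersal radius much smaller than the
#'   torus — genetic distance grows with geographic distance;
#' * `two_patch`: a raster heterogeneity map with two high-intensity habitat
#'   patches separated by low-intensity gaps — discrete-population-like
#'   structure emerges without imposing it;
#' * `panmixia`: event radius covering the whole torus — location becomes
#'   irrelevant and the isolation-by-distance slope collapses to zero.
#'
#' @param seed Seed for sample placement.
#' @param n Individuals per scenario.
#' @return Named list of three `slfv_scenario` objects.
#' @export
make_triangle_corner_scenarios <- function(seed = 1L, n = 8L) {
  L <- landscape(c(1, 1))
  cfg <- mutation_config("k2p", mu = slfv_defaults$mu,
                         kappa = slfv_defaults$kappa,
                         seq_length = 1000L, n_loci = 10L)
  ibd_kern <- kernel_for_parameters(20, 0.05, L)
  pan_kern <- event_kernel("disc", radius = 0.75, impact = 0.05,
                           rate_density = 2, landscape = L,
                           allow_large_radius = TRUE)
  # two habitat patches along x (tiles 1 and 3), near-empty gaps between
  raster <- matrix(c(1, 0.02, 1, 0.02), nrow = 4, ncol = 1)
  patch_kern <- event_kernel("disc", radius = 0.08, impact = 0.3,
                             rate_density = 120, heterogeneity = raster,
                             landscape = L)
  sheets <- with_local_seed(seed, {
    s_ibd <- place_samples(n, L)
    s_pan <- place_samples(n, L)
    # patch samples: half in each patch interior
    px <- c(stats::runif(ceiling(n / 2), 0.02, 0.23),
            stats::runif(floor(n / 2), 0.52, 0.73))
    s_patch <- tibble::tibble(id = sprintf("ind%02d", seq_len(n)),
                              x = px, y = stats::runif(n))
    list(ibd = s_ibd, pan = s_pan, patch = s_patch)
  })
  list(
    ibd = new_scenario("ibd", L, ibd_kern, sheets$ibd, cfg, seed = seed),
    two_patch = new_scenario("two_patch", L, patch_kern, sheets$patch, cfg,
                             seed = seed),
    panmixia = new_scenario("panmixia", L, pan_kern, sheets$pan, cfg,
                            seed = seed)
  )
}

#' Edge-case fixture scenarios
#'
#' Degenerate configurations exercising the simulator's contracts: a single
#' sampled individual (trivial genealogy), a zero mutation rate (monomorphic
#' data), full impact with a torus-covering radius (every event coalesces
#' everything), and a sparse low-rate case with a small work bound that
#' surfaces the explicit non-coalescence status.
#'
#' @param seed Seed for sample placement.
#' @return Named list of `slfv_scenario` objects.
#' @export
make_edge_fixtures <- function(seed = 1L) {
  L <- landscape(c(1, 1))
  cfg <- function(mu) mutation_config("k2p", mu = mu, seq_length = 200L,
                                      n_loci = 2L)
  kern <- kernel_for_parameters(20, 0.1, L)
  global <- event_kernel("disc", radius = 0.75, impact = 1, rate_density = 1,
                         landscape = L, allow_large_radius = TRUE)
  sparse <- event_kernel("disc", radius = 0.02, impact = 0.02,
                         rate_density = 1, landscape = L)
  sheets <- with_local_seed(seed, list(
    one = place_samples(1L, L), few = place_samples(4L, L),
    sparse = place_samples(6L, L)
  ))
  list(
    single = new_scenario("single", L, kern, sheets$one, cfg(0.01), seed = seed),
    monomorphic = new_scenario("monomorphic", L, kern, sheets$few, cfg(0),
                               seed = seed),
    instant = new_scenario("instant", L, global, sheets$few, cfg(0.01),
                           seed = seed),
    sparse = new_scenario("sparse", L, sparse, sheets$sparse, cfg(0.01),
                          seed = seed, max_events = 2000)
  )
}

#' Run a scenario end-to-end
#'
#' Seeds the RNG with the scenario seed (unless overridden) and simulates the
#' full multilocus dataset, so reruns are byte-identical.
#'
#' @param sc An `slfv_scenario`.
#' @param seed Override the scenario seed.
#' @param keep_genealogies Passed to [simulate_dataset()].
#' @return An `slfv_dataset`.
#' @export
run_scenario <- function(sc, seed = sc$seed, keep_genealogies = FALSE) {
  set.seed(seed)
  simulate_dataset(sc$sheet, sc$landscape, sc$kernel, sc$mutation,
                   max_events = sc$max_events,
                   keep_genealogies = keep_genealogies)
}

#' Serialize a scenario to plain-text configuration files
#'
#' Writes `scenario.yaml` (landscape, kernel, mutation, priors, seed, work
#' bound; raster weights to a side file) and `sample.tsv` into `dir`.
#' `read_scenario()` restores the scenario from such a directory.
#'
#' @param sc An `slfv_scenario`.
#' @param dir Output directory (created if needed).
#' @return The directory (write) or an `slfv_scenario` (read).
#' @export
write_scenario <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(
    name = sc$name, seed = sc$seed, max_events = sc$max_events,
    dimension = sc$landscape$dimension, extent = sc$landscape$extent,
    family = sc$kernel$family, radius = sc$kernel$radius,
    impact = sc$kernel$impact, rate_density = sc$kernel$rate_density,
    mutation = list(model = sc$mutation$model, mu = sc$mutation$mu,
                    kappa = sc$mutation$kappa,
                    seq_length = sc$mutation$seq_length,
                    n_loci = sc$mutation$n_loci)
  )
  if (min(sc$landscape$extent) / 2 <= sc$kernel$radius) {
    cfg$allow_large_radius <- TRUE
  }
  if (!is.null(sc$kernel$heterogeneity)) {
    utils::write.table(sc$kernel$heterogeneity,
                       file.path(dir, "raster.txt"),
                       row.names = FALSE, col.names = FALSE)
    cfg$raster <- "raster.txt"
  }
  if (!is.null(sc$priors)) {
    cfg$priors <- list(
      ns_dist = sc$priors$neighborhood_size$dist,
      ns_bounds = sc$priors$neighborhood_size$bounds,
      r_dist = sc$priors$dispersal_radius$dist,
      r_bounds = sc$priors$dispersal_radius$bounds
    )
  }
  yaml::write_yaml(cfg, file.path(dir, "scenario.yaml"), precision = 12)
  write_sample_sheet(sc$sheet, file.path(dir, "sample.tsv"))
  invisible(dir)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "scenario.yaml"))
  L <- landscape(as.numeric(cfg$extent))
  raster <- NULL
  if (!is.null(cfg$raster)) {
    raster <- as.matrix(utils::read.table(file.path(dir, cfg$raster)))
    dimnames(raster) <- NULL
  }
  kern <- event_kernel(cfg$family, cfg$radius, cfg$impact, cfg$rate_density,
                       heterogeneity = raster, landscape = L,
                       allow_large_radius = isTRUE(cfg$allow_large_radius))
  mut <- mutation_config(cfg$mutation$model, mu = cfg$mutation$mu,
                         kappa = cfg$mutation$kappa %||% 3,
                         seq_length = cfg$mutation$seq_length,
                         n_loci = cfg$mutation$n_loci)
  priors <- NULL
  if (!is.null(cfg$priors)) {
    priors <- slfv_priors(as.numeric(cfg$priors$ns_bounds),
                          as.numeric(cfg$priors$r_bounds),
                          cfg$priors$ns_dist, cfg$priors$r_dist)
  }
  sheet <- read_sample_sheet(file.path(dir, "sample.tsv"), L)
  new_scenario(cfg$name, L, kern, sheet, mut, priors, cfg$seed,
               cfg$max_events %||% 5e6)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
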