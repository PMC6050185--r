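#' Classical island-model differentiation
#'
#' Expected equilibrium F_ST under the n-island model as a function of the
#' effective number of migrants per generation: `1 / (4 Ne m + 1)`. Included
#' as the classical point of contrast for the spatially explicit model: it
#' presumes discrete populations connected by migration, whereas the SLFV
#' lets spatial structure emerge from density and dispersal.
#'
#' @param Ne_m Effective migrants per generation (>= 0), vectorized.
#' @return Expected F_ST in (0, 1].
#' @examples
#' island_model_fst(1)     # 0.2
#' island_model_fst(0.25)  # 0.5
#' @export
island_model_fst <- function(Ne_m) {
  if (!is.numeric(Ne_m) || anyNA(Ne_m) || any(Ne_m < 0)) {
    stop("`Ne_m` must be non-negative", call. = FALSE)
  }
  1 / (4 * Ne_m + 1)
}

#' Neighborhood sizes
#'
#' Two standard notions of neighborhood size tie the SLFV parameters to
#' classical continuous-space theory:
#'
#' * `wright_neighborhood_size()`: Wright's convention from local density
#'   `d` and per-axis parent-offspring dispersal variance `sigma2` —
#'   `4 * pi * sigma2 * d` in 2D, `2 * d * sqrt(2 * pi * sigma2)` in 1D.
#' * `event_neighborhood_size()`: the event-based definition — the expected
#'   number of individuals within the area swept by one reproduction event
#'   of radius `r`: `d * pi * r^2` in 2D, `d * 2 * r` in 1D.
#'
#' @param sigma2 Per-axis dispersal variance (squared landscape units per
#'   generation/time unit), > 0.
#' @param density Effective population density `d` (individuals per unit
#'   area, or per unit length in 1D), > 0.
#' @param radius Event radius, > 0.
#' @param dimension 1 or 2.
#' @return Neighborhood size (dimensionless count).
#' @examples
#' wright_neighborhood_size(1, 1)            # 4*pi
#' event_neighborhood_size(100, 0.1)         # pi
#' @export
wright_neighborhood_size <- function(sigma2, density, dimension = 2L) {
  check_positive(sigma2, "sigma2"); check_positive(density, "density")
  if (dimension == 2L) 4 * pi * density * sigma2
  else 2 * density * sqrt(2 * pi * sigma2)
}

#' @rdname wright_neighborhood_size
#' @export
event_neighborhood_size <- function(density, radius, dimension = 2L) {
  check_positive(density, "density"); check_positive(radius, "radius")
  density * event_area(radius, dimension)
}

event_area <- function(radius, dimension = 2L) {
  if (dimension == 2L) pi * radius^2 else 2 * radius
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop("`", name, "` must be strictly positive", call. = FALSE)
  }
  invisible(x)
}

#' Map between (neighborhood size, radius) and SLFV kernel parameters
#'
#' The homogeneous disc SLFV has an effective population density fixed by
#' its event parameters. Matching the Wright-Malecot identity-by-descent
#' theory (per-axis dispersal variance accumulated by lineage jumps,
#' `sigma_t^2 = lambda u A_r r^2 / (2 dim)` with `A_r` the event area,
#' against the total pairwise coalescence mass `Gamma = lambda u^2 A_r^2`)
#' gives `d_eff = 1 / Gamma` and the classical disc-model neighborhood size
#' `2/u`.
#'
#' `kernel_for_parameters()` uses the Wright-consistent convention: the
#' impact realizes the neighborhood size directly, `u = 2 / N_s`, and the
#' event rate density is set to `lambda = N_s / (4 A_r)` so that the
#' effective density matches `d_eff = N_s / A_r`. Under this
#' convention the event-based definition (`d_eff * A_r`) and Wright's
#' (`4 pi sigma^2 d` in 2D) coincide at `N_s` exactly, every lineage jumps
#' at rate 1/2 per unit model time regardless of parameters, the per-axis
#' dispersal variance per unit time is `r^2/4` (2D), and two coincident
#' lineages coalesce at rate `1/N_s` — model time is calibrated to
#' movement, and coalescence depth scales with neighborhood size alone.
#'
#' `slfv_parameters()` reads the implied density, neighborhood sizes and
#' dispersal intensity back off any disc kernel (also ones not built by
#' this convention).
#'
#' @param neighborhood_size Target neighborhood size `N_s` (>= 2, so that
#'   `u = 2/N_s` is a probability).
#' @param radius Disc radius (the maximum dispersal distance per event).
#' @param landscape The target [landscape()].
#' @return `kernel_for_parameters()`: an [event_kernel()].
#'   `slfv_parameters()`: a one-row tibble with `density`,
#'   `neighborhood_size` (event-based), `wright_ns`, `sigma2` (per-axis
#'   dispersal variance per unit time), `dispersal_radius`, `impact`.
#' @export
kernel_for_parameters <- function(neighborhood_size, radius, landscape) {
  check_positive(neighborhood_size, "neighborhood_size")
  check_positive(radius, "radius")
  if (neighborhood_size < 2) {
    stop("neighborhood size below 2 needs impact u = 2/N_s > 1; ",
         "the disc model cannot realize it", call. = FALSE)
  }
  A <- event_area(radius, landscape$dimension)
  u <- 2 / neighborhood_size
  lambda <- neighborhood_size / (4 * A)
  event_kernel("disc", radius = radius, impact = u,
               rate_density = lambda, landscape = landscape)
}

#' @rdname kernel_for_parameters
#' @param kernel A disc [event_kernel()].
#' @export
slfv_parameters <- function(kernel, landscape) {
  dim <- landscape$dimension
  r <- kernel$radius; u <- kernel$impact; lam <- kernel$rate_density
  A <- event_area(r, dim)
  d_eff <- 1 / (lam * u^2 * A^2)
  sigma2 <- if (dim == 2L) lam * u * pi * r^4 / 2 else 4 * lam * u * r^3 / 3
  tibble::tibble(
    density = d_eff,
    neighborhood_size = d_eff * A,
    wright_ns = wright_neighborhood_size(sigma2, d_eff, dim),
    sigma2 = sigma2,
    dispersal_radius = r,
    impact = u
  )
}

pairwise_index <- function(n) {
  p <- utils::combn(n, 2)
  tibble::tibble(i = p[1, ], j = p[2, ])
}

# mean per-site difference for every pair of rows of an alignment
pairwise_genetic_distance <- function(aln, pairs) {
  L <- ncol(aln)
  vapply(seq_len(nrow(pairs)),
         function(k) sum(aln[pairs$i[k], ] != aln[pairs$j[k], ]) / L,
         numeric(1))
}

#' Per-locus diversity summaries
#'
#' Mean pairwise nucleotide diversity (pi, per site) and Watterson's
#' estimator `S / (a_n * L)` for each locus of a dataset.
#'
#' @param alignments List of `slfv_alignment` objects (or an `slfv_dataset`).
#' @return Tibble with columns `locus`, `pi`, `theta_w`, `n_segregating`.
#' @export
locus_summaries <- function(alignments) {
  if (inherits(alignments, "slfv_dataset")) alignments <- alignments$alignments
  n <- nrow(alignments[[1]])
  pairs <- pairwise_index(n)
  a_n <- sum(1 / seq_len(n - 1))
  purrr::map_dfr(seq_along(alignments), function(l) {
    aln <- alignments[[l]]
    S <- n_segregating(aln)
    tibble::tibble(
      locus = l,
      pi = mean(pairwise_genetic_distance(aln, pairs)),
      theta_w = S / (a_n * ncol(aln)),
      n_segregating = S
    )
  })
}

#' Spatial-genetic summary vector
#'
#' Condenses a georeferenced multilocus dataset into the summary vector used
#' for ABC: across-locus mean and SD of per-locus pairwise diversity pi and
#' of Watterson's estimator; the total segregating-site count, mean number
#' of distinct haplotypes per locus and fraction of polymorphic loci (these
#' discriminate weakly polymorphic datasets that per-site rates blur
#' together); the least-squares slope and intercept of pairwise genetic
#' distance (mean per-site differences across loci) regressed on
#' minimal-image torus distance (the isolation-by-distance signal); and a
#' distance-class variogram of mean pairwise genetic distance over fixed
#' distance bins. Deterministic given its inputs and invariant to the order
#' of sequences within loci and of loci.
#'
#' @param alignments List of `slfv_alignment` (or an `slfv_dataset`, in which
#'   case `sheet` defaults to the dataset's sheet).
#' @param sheet Sample sheet with `id`, `x` (and `y` in 2D) matching the
#'   alignment row ids.
#' @param landscape The [landscape()] the coordinates live on.
#' @param bin_edges Right edges of the variogram distance classes; default
#'   10 equal bins covering (0, max torus distance]. Empty classes yield NA
#'   (dropped later by the ABC distance, which logs them).
#' @return A one-row tibble: `n`, `n_loci`, `mean_pi`, `sd_pi`,
#'   `mean_theta_w`, `sd_theta_w`, `ibd_slope`, `ibd_intercept`,
#'   `vario_1` ... `vario_K`. The non-metadata column names are recorded in
#'   attribute `summary_cols`.
#' @export
compute_summaries <- function(alignments, sheet = NULL, landscape,
                              bin_edges = NULL) {
  if (inherits(alignments, "slfv_dataset")) {
    if (is.null(sheet)) sheet <- alignments$sheet
    alignments <- alignments$alignments
  }
  sheet <- validate_sample_sheet(sheet, landscape)
  n <- nrow(sheet)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  ids <- rownames(alignments[[1]])
  for (l in seq_along(alignments)) {
    a <- alignments[[l]]
    if (ncol(a) != ncol(alignments[[1]])) {
      stop("locus ", l, ": sequence length differs from locus 1", call. = FALSE)
    }
    missing <- setdiff(sheet$id, rownames(a))
    if (length(missing)) {
      stop("locus ", l, ": ids missing from alignment: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  # align all loci to sample-sheet id order so results are order-invariant
  alignments <- lapply(alignments, function(a) a[match(sheet$id, rownames(a)), ,
                                                 drop = FALSE])

  per_locus <- locus_summaries(alignments)
  pairs <- pairwise_index(n)
  gd <- rowMeans(matrix(
    vapply(alignments, pairwise_genetic_distance, numeric(nrow(pairs)),
           pairs = pairs),
    nrow = nrow(pairs)
  ))
  loc <- sample_locations(sheet, landscape)
  td <- torus_distance(loc[pairs$i, , drop = FALSE],
                       loc[pairs$j, , drop = FALSE], landscape)

  if (length(td) > 1 && stats::var(td) > 0) {
    fit <- stats::lm.fit(cbind(1, td), gd)
    intercept <- fit$coefficients[1]
    slope <- fit$coefficients[2]
  } else {
    intercept <- mean(gd)
    slope <- 0
  }

  max_d <- sqrt(sum((landscape$extent / 2)^2))
  if (is.null(bin_edges)) bin_edges <- seq(0, max_d, length.out = 11)[-1]
  lower <- c(0, utils::head(bin_edges, -1))
  vario <- vapply(seq_along(bin_edges), function(b) {
    inb <- td > lower[b] & td <= bin_edges[b]
    if (any(inb)) mean(gd[inb]) else NA_real_
  }, numeric(1))

  n_haps <- vapply(alignments, function(a) nrow(unique(unclass(a))),
                   numeric(1))
  out <- tibble::tibble(
    n = n, n_loci = length(alignments),
    mean_pi = mean(per_locus$pi),
    sd_pi = if (length(alignments) > 1) stats::sd(per_locus$pi) else 0,
    mean_theta_w = mean(per_locus$theta_w),
    sd_theta_w = if (length(alignments) > 1) stats::sd(per_locus$theta_w) else 0,
    total_seg = sum(per_locus$n_segregating),
    mean_haplotypes = mean(n_haps),
    prop_polymorphic = mean(per_locus$n_segregating > 0),
    ibd_slope = as.numeric(slope),
    ibd_intercept = as.numeric(intercept)
  )
  for (b in seq_along(vario)) out[[paste0("vario_", b)]] <- vario[b]
  attr(out, "summary_cols") <- setdiff(names(out), c("n", "n_loci"))
  attr(out, "bin_edges") <- bin_edges
  attr(out, "per_locus") <- per_locus
  out
}

summary_cols_of <- function(x) {
  sc <- attr(x, "summary_cols")
  if (is.null(sc)) sc <- setdiff(
    names(x),
    c("n", "n_loci", "neighborhood_size", "dispersal_radius", "impact",
      "density", "sim", "coalesced")
  )
  sc
}
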