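#' Prior specification for SLFV inference
#'
#' Independent priors on the two estimable parameters: the (event-based)
#' neighborhood size and the dispersal radius. Each is uniform or
#' log-uniform over finite positive bounds. The default shapes follow common
#' practice for a scale parameter spanning decades (log-uniform neighborhood
#' size) and a bounded length (uniform radius).
#'
#' @param ns_bounds Length-2 positive bounds for neighborhood size.
#' @param r_bounds Length-2 positive bounds for the dispersal radius.
#' @param ns_dist,r_dist `"log-uniform"` or `"uniform"`.
#' @return An object of class `slfv_priors`.
#' @examples
#' slfv_priors(c(5, 158), c(0.05, 0.15))
#' @export
slfv_priors <- function(ns_bounds, r_bounds,
                        ns_dist = c("log-uniform", "uniform"),
                        r_dist = c("uniform", "log-uniform")) {
  check_bounds <- function(b, name) {
    if (!is.numeric(b) || length(b) != 2L || anyNA(b) || !all(is.finite(b)) ||
        b[1] <= 0 || b[1] > b[2]) {
      stop("`", name, "` must be finite positive bounds with lower <= upper",
           call. = FALSE)
    }
  }
  check_bounds(ns_bounds, "ns_bounds")
  check_bounds(r_bounds, "r_bounds")
  structure(
    list(
      neighborhood_size = list(dist = match.arg(ns_dist), bounds = ns_bounds),
      dispersal_radius = list(dist = match.arg(r_dist), bounds = r_bounds)
    ),
    class = "slfv_priors"
  )
}

#' @export
print.slfv_priors <- function(x, ...) {
  for (p in names(x)) {
    cat(sprintf("%s ~ %s(%g, %g)\n", p, x[[p]]$dist,
                x[[p]]$bounds[1], x[[p]]$bounds[2]))
  }
  invisible(x)
}

#' Draw parameters from the priors
#'
#' @param priors An [slfv_priors()].
#' @param n Number of draws.
#' @return Tibble with columns `neighborhood_size` and `dispersal_radius`.
#' @export
draw_priors <- function(priors, n) {
  draw1 <- function(p) {
    if (p$dist == "uniform") {
      stats::runif(n, p$bounds[1], p$bounds[2])
    } else {
      exp(stats::runif(n, log(p$bounds[1]), log(p$bounds[2])))
    }
  }
  tibble::tibble(
    neighborhood_size = draw1(priors$neighborhood_size),
    dispersal_radius = draw1(priors$dispersal_radius)
  )
}

#' Build an ABC reference table
#'
#' For each of `n_sims` rows: draw (neighborhood size, dispersal radius) from
#' the priors, convert them to a disc event kernel via
#' [kernel_for_parameters()], simulate a full multilocus dataset for the
#' given sample, and condense it with [compute_summaries()]. Rows whose
#' simulation fails to coalesce within `max_events` are redrawn from the
#' priors; the redraw count is recorded in attribute `n_redraws` (and
#' messaged unless `quiet`).
#'
#' @param priors An [slfv_priors()].
#' @param n_sims Number of retained simulations (rows).
#' @param sheet Sample sheet of the individuals every simulated dataset
#'   mimics (ids, coordinates).
#' @param landscape The [landscape()].
#' @param config A [mutation_config()] (loci, sequence length, rates).
#' @param max_events Per-genealogy work bound before a draw is abandoned and
#'   redrawn.
#' @param bin_edges Variogram bin edges passed to [compute_summaries()].
#' @param quiet Suppress progress messages.
#' @return An `slfv_reference_table`: a tibble with one row per simulation —
#'   the drawn `neighborhood_size` and `dispersal_radius`, the implied
#'   `impact` and `density`, and the summary columns — carrying attributes
#'   `summary_cols`, `priors`, `n_redraws`.
#' @export
build_reference_table <- function(priors, n_sims, sheet, landscape, config,
                                  max_events = 5e6,
                                  bin_edges = NULL, quiet = TRUE) {
  stopifnot(n_sims >= 1)
  sheet <- validate_sample_sheet(sheet, landscape)
  rows <- vector("list", n_sims)
  n_redraws <- 0L
  for (i in seq_len(n_sims)) {
    repeat {
      par <- draw_priors(priors, 1L)
      kern <- kernel_for_parameters(par$neighborhood_size,
                                    par$dispersal_radius, landscape)
      ds <- tryCatch(
        simulate_dataset(sheet, landscape, kern, config, max_events),
        slfv_not_coalesced = function(e) NULL
      )
      if (!is.null(ds)) break
      n_redraws <- n_redraws + 1L
    }
    sm <- compute_summaries(ds, sheet, landscape, bin_edges)
    rows[[i]] <- dplyr::bind_cols(
      par,
      tibble::tibble(impact = kern$impact,
                     density = par$neighborhood_size /
                       event_area(par$dispersal_radius, landscape$dimension)),
      sm
    )
    if (!quiet && i %% 100L == 0L) {
      message("reference table: ", i, "/", n_sims, " simulations")
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "summary_cols") <- attr(rows[[1]], "summary_cols")
  attr(out, "priors") <- priors
  attr(out, "n_redraws") <- n_redraws
  if (!quiet && n_redraws > 0) {
    message(n_redraws, " non-coalesced draw(s) redrawn")
  }
  class(out) <- c("slfv_reference_table", class(out))
  out
}

#' Read/write a reference table
#'
#' Tab-separated with a header row; the summary column names are recoverable
#' from the stored schema (all columns after the parameter block).
#'
#' @param table An `slfv_reference_table` (or posterior tibble).
#' @param path File path.
#' @export
write_reference_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double()
  ))
  attr(out, "summary_cols") <- setdiff(
    names(out),
    c("neighborhood_size", "dispersal_radius", "impact", "density",
      "n", "n_loci")
  )
  class(out) <- c("slfv_reference_table", class(out))
  out
}

# distance matrix machinery shared by rejection_abc and loo_cv_r2:
# per-column scaling by the table's median absolute deviation, Euclidean
# distance, zero-spread or non-finite columns dropped.
abc_distances <- function(observed, table, cols) {
  obs <- unlist(observed[1, cols])
  tab <- as.matrix(table[, cols])
  mads <- apply(tab, 2, stats::mad)
  keep <- is.finite(mads) & mads > 0 & is.finite(obs) &
    apply(is.finite(tab), 2, all)
  dropped <- cols[!keep]
  tab <- tab[, keep, drop = FALSE]
  obs <- obs[keep]
  mads <- mads[keep]
  if (!length(obs)) {
    stop("no usable summary columns (all zero-spread or non-finite)",
         call. = FALSE)
  }
  z <- sweep(sweep(tab, 2, obs), 2, mads, "/")
  list(distance = sqrt(rowSums(z^2)), dropped = dropped, used = cols[keep])
}

#' Rejection ABC
#'
#' Accepts the reference-table rows whose summary vectors are nearest the
#' observed summaries: distances are Euclidean after scaling every summary
#' column by its median absolute deviation in the table (columns with zero
#' spread or non-finite entries are dropped and recorded), and the nearest
#' `ceiling(tolerance * n_sims)` rows are accepted. Ties at the cutoff are
#' broken by row order.
#'
#' @param observed A one-row summary tibble from [compute_summaries()] (or a
#'   named list/vector covering the table's summary columns).
#' @param table An `slfv_reference_table`.
#' @param tolerance Accepted fraction of the table, in (0, 1].
#' @return An `slfv_posterior`: the accepted rows (parameters + summaries +
#'   `distance`), with attributes `tolerance`, `dropped_cols`, `used_cols`,
#'   `observed`.
#' @export
rejection_abc <- function(observed, table, tolerance) {
  if (!is.numeric(tolerance) || tolerance <= 0 || tolerance > 1) {
    stop("`tolerance` must be in (0, 1]", call. = FALSE)
  }
  if (!nrow(table)) stop("empty reference table", call. = FALSE)
  if (!is.data.frame(observed)) observed <- tibble::as_tibble(as.list(observed))
  cols <- summary_cols_of(table)
  missing <- setdiff(cols, names(observed))
  if (length(missing)) {
    stop("observed summaries lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- abc_distances(observed, table, cols)
  n_accept <- ceiling(tolerance * nrow(table))
  take <- order(d$distance)[seq_len(n_accept)]  # stable: ties by row order
  out <- tibble::as_tibble(table)[take, ]
  out$distance <- d$distance[take]
  structure(out,
    class = c("slfv_posterior", class(tibble::tibble())),
    tolerance = tolerance, dropped_cols = d$dropped, used_cols = d$used,
    observed = observed
  )
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted sample values — the interval style commonly reported for skewed
#' ABC posteriors.
#'
#' @param samples Numeric parameter draws (>= 2 values).
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' hpdi(rnorm(1e4))
#' @export
hpdi <- function(samples, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop("`mass` must be in (0, 1)", call. = FALSE)
  }
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 2L) stop("need at least 2 finite samples", call. = FALSE)
  w <- ceiling(mass * n)
  if (w < 2L) w <- 2L
  if (w >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[w:n] - x[1:(n - w + 1)]  # windows of w consecutive points
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + w - 1L])
}

#' Posterior point estimates and intervals
#'
#' @param x An `slfv_posterior`.
#' @param mass HPDI mass.
#' @param ... Unused.
#' @return `glance()`: one row per parameter with the posterior `median`,
#'   `mean`, and HPDI bounds. `tidy()`: accepted draws in long form.
#' @method glance slfv_posterior
#' @export
glance.slfv_posterior <- function(x, mass = 0.95, ...) {
  purrr::map_dfr(c("neighborhood_size", "dispersal_radius"), function(p) {
    v <- x[[p]]
    h <- hpdi(v, mass)
    tibble::tibble(parameter = p, median = stats::median(v), mean = mean(v),
                   hpdi_lower = unname(h["lower"]),
                   hpdi_upper = unname(h["upper"]),
                   mass = mass, n_accepted = length(v))
  })
}

#' @rdname glance.slfv_posterior
#' @method tidy slfv_posterior
#' @export
tidy.slfv_posterior <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("neighborhood_size", "dispersal_radius")],
    dplyr::everything(),
    names_to = "parameter", values_to = "value"
  )
}

# coefficient of determination of the simple regression of estimate on
# truth; for univariate least squares with intercept this is cor^2
r_squared <- function(truth, estimate) {
  if (stats::var(estimate) == 0 || stats::var(truth) == 0) return(0)
  stats::cor(truth, estimate)^2
}

#' Leave-one-out cross-validation of the ABC estimator
#'
#' Replicates the standard ABC validation: hold one reference-table row out,
#' treat its summaries as the observed data, run [rejection_abc()] against
#' the remaining rows, and take the posterior median as the estimate. Over
#' `n_heldout` replicates, reports the least-squares R-squared of estimates
#' regressed on true parameter values, per parameter, optionally with a
#' bootstrap confidence interval and a permuted-truth baseline (the R-squared
#' after shuffling the truth column, which destroys any real association and
#' so should be near zero when the parameter is identifiable).
#'
#' @param table An `slfv_reference_table`.
#' @param tolerance Rejection-ABC tolerance; `tolerance * (nrow - 1)` must be
#'   at least 1.
#' @param n_heldout Number of held-out replicates (<= `nrow(table)`).
#' @param params Parameter columns to evaluate.
#' @param n_boot Bootstrap resamples for the R-squared CI (0 = none).
#' @param permuted_baseline Also report the permuted-truth R-squared.
#' @return An `slfv_cv` object: list with `estimates` (tibble: `replicate`,
#'   `parameter`, `truth`, `estimate`) and `r2` (tibble: `parameter`,
#'   `r_squared`, optional `ci_lower`/`ci_upper`/`r_squared_permuted`).
#' @export
loo_cv_r2 <- function(table, tolerance, n_heldout,
                      params = c("neighborhood_size", "dispersal_radius"),
                      n_boot = 0L, permuted_baseline = FALSE) {
  n <- nrow(table)
  if (n_heldout > n) stop("`n_heldout` exceeds the table size", call. = FALSE)
  if (tolerance * (n - 1) < 1) {
    stop("tolerance too small: no rows would be accepted", call. = FALSE)
  }
  held <- sample.int(n, n_heldout)
  cols <- summary_cols_of(table)
  est <- purrr::map_dfr(seq_along(held), function(k) {
    i <- held[k]
    post <- rejection_abc(tibble::as_tibble(table)[i, ],
                          table[-i, , drop = FALSE], tolerance)
    tibble::tibble(
      replicate = k, parameter = params,
      truth = unlist(tibble::as_tibble(table)[i, params]),
      estimate = vapply(params, function(p) stats::median(post[[p]]),
                        numeric(1))
    )
  })
  r2 <- purrr::map_dfr(params, function(p) {
    e <- est[est$parameter == p, ]
    row <- tibble::tibble(parameter = p,
                          r_squared = r_squared(e$truth, e$estimate))
    if (n_boot > 0) {
      bs <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(e), replace = TRUE)
        r_squared(e$truth[idx], e$estimate[idx])
      }, numeric(1))
      row$ci_lower <- stats::quantile(bs, 0.025, names = FALSE)
      row$ci_upper <- stats::quantile(bs, 0.975, names = FALSE)
    }
    if (permuted_baseline) {
      row$r_squared_permuted <- r_squared(sample(e$truth), e$estimate)
    }
    row
  })
  structure(
    list(estimates = est, r2 = r2, tolerance = tolerance,
         n_heldout = n_heldout),
    class = "slfv_cv"
  )
}

#' @export
print.slfv_cv <- function(x, ...) {
  cat(sprintf("<slfv_cv> %d held-out replicates at tolerance %g\n",
              x$n_heldout, x$tolerance))
  print(x$r2)
  invisible(x)
}

#' @rdname loo_cv_r2
#' @param x An `slfv_cv`.
#' @param ... Unused.
#' @method tidy slfv_cv
#' @export
tidy.slfv_cv <- function(x, ...) x$estimates

#' @rdname loo_cv_r2
#' @method glance slfv_cv
#' @export
glance.slfv_cv <- function(x, ...) {
  dplyr::bind_cols(x$r2,
                   tibble::tibble(tolerance = x$tolerance,
                                  n_heldout = x$n_heldout))
}
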