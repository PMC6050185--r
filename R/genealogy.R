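#' Lineage sets
#'
#' The simulator's working state: the set `C(t)` of ancestral lineages extant
#' at backward time `t`, each with a current location and the id of the
#' genealogy node it currently represents.
#'
#' @param sheet Sample sheet (`id`, `x`, optionally `y`).
#' @param landscape An [landscape()].
#' @return A tibble of class `slfv_lineages` with columns `node` (integer),
#'   `x`, `y` (2D only) and attribute `clock` (current backward time).
#' @export
lineage_set <- function(sheet, landscape) {
  sheet <- validate_sample_sheet(sheet, landscape)
  out <- tibble::tibble(node = seq_len(nrow(sheet)), x = sheet$x)
  if (landscape$dimension == 2L) out$y <- sheet$y
  attr(out, "clock") <- 0
  class(out) <- c("slfv_lineages", class(out))
  out
}

lineage_coords <- function(C, landscape) {
  cols <- if (landscape$dimension == 2L) c("x", "y") else "x"
  as.matrix(C[, cols])
}

#' Select the lineages affected by an event
#'
#' Each lineage in `C` is included independently with probability
#' [selection_probability()] of the event's kernel at the lineage's location.
#' The returned subset may be empty (the event then has no effect).
#'
#' @param C An `slfv_lineages` tibble.
#' @param event An event from [sample_event()].
#' @param landscape The [landscape()].
#' @return The affected subset of `C` (same columns, possibly zero rows).
#' @export
select_affected <- function(C, event, landscape) {
  p <- selection_probability(
    event$kernel, event$center, lineage_coords(C, landscape), landscape
  )
  C[stats::runif(nrow(C)) < p, , drop = FALSE]
}

# Draw one ancestor/movement location from the replacement distribution
# R(x | C') of an event: uniform on the disc for disc kernels, Gaussian
# around the event center for Gaussian kernels, wrapped onto the torus.
replacement_location <- function(event, landscape) {
  k <- event$kernel
  d <- landscape$dimension
  if (k$family == "disc") {
    if (d == 1L) {
      off <- stats::runif(1, -k$radius, k$radius)
    } else {
      rad <- k$radius * sqrt(stats::runif(1))
      ang <- stats::runif(1, 0, 2 * pi)
      off <- c(rad * cos(ang), rad * sin(ang))
    }
  } else {
    off <- stats::rnorm(d, 0, k$radius)
  }
  wrap_coords(matrix(event$center + off, nrow = 1L), landscape)
}

empty_genealogy_builder <- function(C, landscape) {
  loc <- lineage_coords(C, landscape)
  list(
    node_time = rep(0, nrow(C)),
    node_x = loc[, 1],
    node_y = if (landscape$dimension == 2L) loc[, 2] else rep(0, nrow(C)),
    edge_child = integer(), edge_parent = integer(),
    merger_sizes = integer()
  )
}

#' Apply one SLFV event to a lineage set
#'
#' Implements the event outcomes of the backward SLFV loop: an empty affected
#' set leaves everything unchanged; a singleton is pure movement (the lineage
#' is relocated by the replacement distribution, no genealogy node is
#' created); two or more affected lineages coalesce into a single new
#' ancestor placed by the replacement distribution, reducing the lineage
#' count by `nrow(C_prime) - 1`.
#'
#' @inheritParams select_affected
#' @param C_prime The affected subset, from [select_affected()].
#' @param builder Genealogy accumulator, created internally by
#'   [simulate_genealogy()]; `NULL` starts a fresh one from `C`.
#' @return List with the updated `lineages` (clock advanced to the event
#'   time) and `builder`.
#' @export
apply_event <- function(C, C_prime, event, landscape, builder = NULL) {
  if (is.null(builder)) builder <- empty_genealogy_builder(C, landscape)
  if (!all(C_prime$node %in% C$node)) {
    stop("C_prime is not a subset of C", call. = FALSE)
  }
  m <- nrow(C_prime)
  if (m >= 1L) {
    loc <- replacement_location(event, landscape)
    rows <- match(C_prime$node, C$node)
    if (m == 1L) {
      C$x[rows] <- loc[1, 1]
      if (landscape$dimension == 2L) C$y[rows] <- loc[1, 2]
    } else {
      parent <- length(builder$node_time) + 1L
      builder$node_time <- c(builder$node_time, event$time)
      builder$node_x <- c(builder$node_x, loc[1, 1])
      builder$node_y <- c(builder$node_y,
                          if (landscape$dimension == 2L) loc[1, 2] else 0)
      builder$edge_child <- c(builder$edge_child, C_prime$node)
      builder$edge_parent <- c(builder$edge_parent, rep(parent, m))
      builder$merger_sizes <- c(builder$merger_sizes, m)
      keep <- rows[1]
      C$node[keep] <- parent
      C$x[keep] <- loc[1, 1]
      if (landscape$dimension == 2L) C$y[keep] <- loc[1, 2]
      C <- C[-rows[-1], , drop = FALSE]
    }
  }
  attr(C, "clock") <- event$time
  list(lineages = C, builder = builder)
}

#' Simulate an SLFV genealogy
#'
#' Runs the backward-in-time SLFV event loop from the sampled individuals to
#' their most recent common ancestor: events are drawn in space-time, each
#' event probabilistically selects nearby lineages, selected sets of size
#' two or more coalesce into a relocated ancestor, singletons move, and the
#' loop ends when one lineage remains (or `max_events` is exhausted, which is
#' reported explicitly rather than silently truncated).
#'
#' Engines (all sample from the identical process law):
#' * `"thinned"` (default where valid): compiled loop restricting candidate
#'   event centers to the union of lineage-centered kernel supports, with the
#'   event rate corrected accordingly. Requires a homogeneous disc kernel
#'   with `radius < min(extent)/2`.
#' * `"naive"`: compiled loop sampling events over the whole landscape;
#'   handles Gaussian kernels, raster heterogeneity and panmictic radii.
#' * `"reference"`: pure-R loop composing [sample_event()],
#'   [select_affected()] and [apply_event()]; slow, used for cross-checks.
#'
#' @param sheet Sample sheet (`id`, `x`, optionally `y`) of the `n` sampled
#'   individuals at backward time 0.
#' @param landscape An [landscape()].
#' @param kernel An [event_kernel()].
#' @param max_events Work bound on the event loop (candidate events for the
#'   thinned engine); default `1e7`.
#' @param engine `"auto"`, `"thinned"`, `"naive"` or `"reference"`.
#' @return An object of class `slfv_genealogy`: a list with
#'   * `tree`: an [ape::phylo] (branch lengths in model time;
#'     multifurcations allowed), `NULL` when `n = 1` or not coalesced;
#'   * `nodes`: tibble `node`, `label`, `time`, `x`, `y`, `parent` (NA at
#'     roots); node locations are birth locations, leaves are nodes `1..n`;
#'   * `coalesced`: logical; `FALSE` means `max_events` was reached and the
#'     genealogy is a multi-root forest;
#'   * `tmrca`: root time (NA if not coalesced);
#'   * `merger_sizes`: integer vector of coalescence sizes (>= 2);
#'   * event counters `n_iter`, `n_events`, `n_nonempty`.
#' @examples
#' L <- landscape(c(1, 1))
#' k <- event_kernel("disc", 0.2, 0.8, 20)
#' sheet <- tibble::tibble(id = paste0("s", 1:4),
#'                         x = runif(4), y = runif(4))
#' g <- simulate_genealogy(sheet, L, k)
#' glance(g)
#' @export
simulate_genealogy <- function(sheet, landscape, kernel, max_events = 1e7,
                               engine = c("auto", "thinned", "naive",
                                          "reference")) {
  engine <- match.arg(engine)
  sheet <- validate_sample_sheet(sheet, landscape)
  n <- nrow(sheet)
  loc <- sample_locations(sheet, landscape)
  check_in_landscape(loc, landscape, "sample location")

  thin_ok <- kernel$family == "disc" && is.null(kernel$heterogeneity) &&
    kernel$radius < min(landscape$extent) / 2
  if (engine == "auto") engine <- if (thin_ok) "thinned" else "naive"
  if (engine == "thinned" && !thin_ok) {
    stop("thinned engine needs a homogeneous disc kernel with ",
         "radius < min(extent)/2", call. = FALSE)
  }

  if (n == 1L) {
    raw <- c(empty_genealogy_builder(lineage_set(sheet, landscape), landscape),
             list(coalesced = TRUE, n_iter = 0, n_events = 0, n_nonempty = 0,
                  roots = 0L))
    return(new_genealogy(raw, sheet, landscape, kernel, zero_based = FALSE))
  }

  if (engine == "reference") {
    raw <- simulate_genealogy_reference(sheet, landscape, kernel, max_events)
    return(new_genealogy(raw, sheet, landscape, kernel, zero_based = FALSE))
  }

  raw <- .slfv_simulate_cpp(
    loc, landscape$extent, kernel$family, kernel$radius, kernel$impact,
    kernel$rate_density, kernel$heterogeneity, max_events,
    engine == "thinned"
  )
  new_genealogy(raw, sheet, landscape, kernel, zero_based = TRUE)
}

# pure-R naive event loop over the exported operations (oracle engine)
simulate_genealogy_reference <- function(sheet, landscape, kernel,
                                         max_events) {
  C <- lineage_set(sheet, landscape)
  builder <- empty_genealogy_builder(C, landscape)
  t_now <- 0
  n_iter <- 0
  n_nonempty <- 0
  while (nrow(C) > 1L && n_iter < max_events) {
    n_iter <- n_iter + 1
    ev <- sample_event(landscape, kernel, t_now)
    t_now <- ev$time
    Cp <- select_affected(C, ev, landscape)
    if (nrow(Cp) > 0L) n_nonempty <- n_nonempty + 1
    res <- apply_event(C, Cp, ev, landscape, builder)
    C <- res$lineages
    builder <- res$builder
  }
  c(builder, list(
    coalesced = nrow(C) == 1L, n_iter = n_iter, n_events = n_iter,
    n_nonempty = n_nonempty, roots = C$node
  ))
}

# Assemble the user-facing genealogy object from an engine's raw record.
# zero_based: C++ node ids start at 0.
new_genealogy <- function(raw, sheet, landscape, kernel, zero_based) {
  off <- if (zero_based) 1L else 0L
  n <- nrow(sheet)
  n_nodes <- length(raw$node_time)
  parent <- rep(NA_integer_, n_nodes)
  if (length(raw$edge_child)) {
    parent[raw$edge_child + off] <- raw$edge_parent + off
  }
  nodes <- tibble::tibble(
    node = seq_len(n_nodes),
    label = c(as.character(sheet$id), sprintf("a%d", seq_len(n_nodes - n))),
    parent = parent,
    time = as.numeric(raw$node_time),
    x = as.numeric(raw$node_x)
  )
  if (landscape$dimension == 2L) nodes$y <- as.numeric(raw$node_y)
  coalesced <- isTRUE(raw$coalesced)
  roots <- raw$roots + off
  out <- structure(
    list(
      tree = NULL,
      nodes = nodes,
      n_leaves = n,
      coalesced = coalesced,
      tmrca = if (coalesced && n > 1L) raw$node_time[[n_nodes]] else
        if (n == 1L) 0 else NA_real_,
      merger_sizes = as.integer(raw$merger_sizes),
      roots = as.integer(roots),
      n_iter = as.numeric(raw$n_iter),
      n_events = as.numeric(raw$n_events),
      n_nonempty = as.numeric(raw$n_nonempty),
      landscape = landscape,
      kernel = kernel
    ),
    class = "slfv_genealogy"
  )
  if (coalesced && n >= 2L) out$tree <- genealogy_to_phylo(out)
  out
}

# Newick text from the node table (handles multifurcations); internal nodes
# labelled a1, a2, ... so the companion node table can be re-linked on read.
genealogy_newick <- function(g) {
  nodes <- g$nodes
  kids <- split(nodes$node, factor(nodes$parent, levels = nodes$node))
  build <- function(v) {
    ch <- kids[[v]]
    lab <- nodes$label[v]
    if (!length(ch)) return(lab)
    parts <- vapply(ch, function(c) {
      paste0(build(c), ":", format(nodes$time[v] - nodes$time[c], digits = 12))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  paste0(build(g$roots[1]), ";")
}

genealogy_to_phylo <- function(g) {
  ape::read.tree(text = genealogy_newick(g))
}

#' @export
print.slfv_genealogy <- function(x, ...) {
  cat(sprintf(
    "<slfv_genealogy> %d leaves, %s, %d merger(s)%s\n",
    x$n_leaves,
    if (x$coalesced) sprintf("coalesced (TMRCA %.4g)", x$tmrca)
    else sprintf("NOT coalesced (%d roots after %g events)",
                 length(x$roots), x$n_iter),
    length(x$merger_sizes),
    if (length(x$merger_sizes))
      sprintf(", sizes %s", paste(sort(unique(x$merger_sizes)), collapse = "/"))
    else ""
  ))
  invisible(x)
}

#' Tidy an SLFV genealogy into its node table
#'
#' @param x An `slfv_genealogy`.
#' @param ... Unused.
#' @return Tibble with one row per genealogy node: `node`, `label`, `parent`
#'   (NA at roots), `time` (backward model time; leaves at 0), and birth
#'   location `x` (and `y` in 2D).
#' @method tidy slfv_genealogy
#' @export
tidy.slfv_genealogy <- function(x, ...) {
  x$nodes
}

#' One-row summary of an SLFV genealogy
#'
#' @param x An `slfv_genealogy`.
#' @param ... Unused.
#' @return Tibble with `n_leaves`, `coalesced`, `tmrca`, `n_mergers`,
#'   `max_merger`, `total_branch_length` and the event counters.
#' @method glance slfv_genealogy
#' @export
glance.slfv_genealogy <- function(x, ...) {
  tbl <- if (!is.null(x$tree)) sum(x$tree$edge.length) else NA_real_
  tibble::tibble(
    n_leaves = x$n_leaves,
    coalesced = x$coalesced,
    tmrca = x$tmrca,
    n_mergers = length(x$merger_sizes),
    max_merger = if (length(x$merger_sizes)) max(x$merger_sizes) else NA_integer_,
    total_branch_length = tbl,
    n_iter = x$n_iter,
    n_events = x$n_events,
    n_nonempty = x$n_nonempty
  )
}

#' Write / read a genealogy as Newick plus a node table
#'
#' `write_genealogy()` emits `<prefix>.nwk` (Newick with branch lengths,
#' multifurcations allowed, internal nodes labelled) and
#' `<prefix>.nodes.tsv` (tab-separated `node`, `label`, `parent`, `time`,
#' `x`, `y`). `read_genealogy()` reads the pair back; the returned object
#' carries the tree and node table (engine counters are not persisted).
#'
#' @param g An `slfv_genealogy` (must be coalesced, with >= 2 leaves).
#' @param prefix Output path prefix.
#' @return `write_genealogy()`: the prefix, invisibly. `read_genealogy()`:
#'   an `slfv_genealogy`.
#' @export
write_genealogy <- function(g, prefix) {
  if (!g$coalesced) stop("refusing to write a non-coalesced forest", call. = FALSE)
  writeLines(genealogy_newick(g), paste0(prefix, ".nwk"))
  readr::write_tsv(g$nodes, paste0(prefix, ".nodes.tsv"))
  invisible(prefix)
}

#' @rdname write_genealogy
#' @export
read_genealogy <- function(prefix) {
  nodes <- readr::read_tsv(paste0(prefix, ".nodes.tsv"), col_types = readr::cols(
    node = readr::col_integer(), label = readr::col_character(),
    parent = readr::col_integer(), .default = readr::col_double()
  ))
  kids_per_parent <- table(nodes$parent)
  structure(
    list(
      tree = ape::read.tree(paste0(prefix, ".nwk")),
      nodes = nodes,
      n_leaves = sum(is_leaf(nodes)),
      coalesced = TRUE,
      tmrca = max(nodes$time),
      merger_sizes = as.integer(kids_per_parent[kids_per_parent >= 2]),
      roots = nodes$node[is.na(nodes$parent)],
      n_iter = NA_real_, n_events = NA_real_, n_nonempty = NA_real_,
      landscape = NULL, kernel = NULL
    ),
    class = "slfv_genealogy"
  )
}

is_leaf <- function(nodes) {
  !nodes$node %in% nodes$parent
}
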