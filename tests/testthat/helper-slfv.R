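# Shared fixtures and independent oracles for the test suite.

unit_torus <- landscape(c(1, 1))
ring <- landscape(1)

quick_sheet <- function(n, landscape = unit_torus, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  place_samples(n, landscape)
}

# A hand-built coalesced genealogy with known topology and branch lengths:
# ((a:1,b:1):2,(c:2,d:2):1); leaf times 0, internal times 1, 2, 3.
toy_genealogy <- function() {
  nodes <- tibble::tibble(
    node = 1:7,
    label = c("a", "b", "c", "d", "a1", "a2", "a3"),
    parent = c(5L, 5L, 6L, 6L, 7L, 7L, NA),
    time = c(0, 0, 0, 0, 1, 2, 3),
    x = rep(0.5, 7), y = rep(0.5, 7)
  )
  structure(
    list(tree = ape::read.tree(text = "((a:1,b:1):2,(c:2,d:2):1);"),
         nodes = nodes, n_leaves = 4L, coalesced = TRUE, tmrca = 3,
         merger_sizes = c(2L, 2L, 2L), roots = 7L,
         n_iter = NA_real_, n_events = NA_real_, n_nonempty = NA_real_,
         landscape = unit_torus, kernel = NULL),
    class = "slfv_genealogy"
  )
}

toy_total_branch_length <- function() 1 + 1 + 2 + 2 + 2 + 1  # = 9

# Independent forward-in-time Moran-style dual oracle for the pairwise
# coalescence time: run reproduction/extinction events forward on the torus
# and trace the ancestry of two marked individuals. Written from scratch
# (plain arithmetic, no package internals) so it can serve as an oracle for
# the backward engines.
forward_dual_pair_time <- function(x1, x2, extent, r, u, lambda,
                                   max_events = 1e6) {
  area <- prod(extent)
  rate <- lambda * area
  tdist <- function(a, b) {
    d <- abs(a - b)
    d <- pmin(d, extent - d)
    sqrt(sum(d^2))
  }
  t <- 0
  for (i in seq_len(max_events)) {
    t <- t + stats::rexp(1, rate)
    center <- stats::runif(2) * extent
    in1 <- tdist(center, x1) <= r
    in2 <- tdist(center, x2) <= r
    hit1 <- in1 && stats::runif(1) < u
    hit2 <- in2 && stats::runif(1) < u
    if (!hit1 && !hit2) next
    # parent (ancestor) born uniformly inside the event disc
    repeat {
      p <- center + (stats::runif(2) * 2 - 1) * r
      if (sum((p - center)^2) <= r^2) break
    }
    p <- p %% extent
    if (hit1 && hit2) return(t)
    if (hit1) x1 <- p else x2 <- p
  }
  NA_real_
}

# Jukes-Cantor probability that two sequences separated by total path time
# T differ at a site, for total substitution rate mu per unit time.
jc_p_diff <- function(mu, T) 0.75 * (1 - exp(-4 / 3 * mu * T))

# brute-force HPDI: scan every contiguous window of the sorted sample
brute_force_hpdi <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  w <- max(2L, ceiling(mass * n))
  if (w >= n) return(c(x[1], x[n]))
  best <- c(Inf, NA, NA)
  for (i in seq_len(n - w + 1)) {
    width <- x[i + w - 1] - x[i]
    if (width < best[1]) best <- c(width, x[i], x[i + w - 1])
  }
  best[2:3]
}

# cheap mutation settings for tests that only need data to exist
tiny_mutation <- function(model = "k2p", mu = 2.5e-6, n_loci = 2,
                          seq_length = 200) {
  mutation_config(model, mu = mu, kappa = 3, seq_length = seq_length,
                  n_loci = n_loci)
}

# synthetic reference table whose summaries are a known invertible function
# of the parameters plus optional noise; exercises the ABC machinery without
# the simulator
synthetic_table <- function(n, noise = 0, seed = 1) {
  set.seed(seed)
  ns <- exp(runif(n, log(10), log(1000)))
  r <- runif(n, 0.02, 0.2)
  out <- tibble::tibble(
    neighborhood_size = ns,
    dispersal_radius = r,
    s_ns = log(ns) + rnorm(n, 0, noise),
    s_r = r + rnorm(n, 0, noise * 0.01),
    s_mix = log(ns) * r + rnorm(n, 0, noise)
  )
  attr(out, "summary_cols") <- c("s_ns", "s_r", "s_mix")
  class(out) <- c("slfv_reference_table", class(out))
  out
}
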