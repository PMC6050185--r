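test_that("select_affected follows the kernel's Bernoulli law", {
  set.seed(21)
  k <- event_kernel("disc", 0.1, 1, 10)
  sheet <- quick_sheet(6)
  C <- lineage_set(sheet, unit_torus)

  # every lineage far from the center: nothing selected
  far <- list(time = 0.1, center = c(0.5, 0.5), kernel = k)
  C_far <- C
  C_far$x <- runif(6, 0.8, 0.9)
  C_far$y <- runif(6, 0.8, 0.9)
  expect_equal(nrow(select_affected(C_far, far, unit_torus)), 0L)

  # full impact with everyone at the center: all selected
  C_at <- C
  C_at$x <- rep(0.5, 6)
  C_at$y <- rep(0.5, 6)
  expect_equal(nrow(select_affected(C_at, far, unit_torus)), 6L)

  # u = 0.5 with 1000 lineages inside the disc: binomial 99.9% bounds
  k5 <- event_kernel("disc", 0.1, 0.5, 10)
  big <- tibble::tibble(node = 1:1000,
                        x = 0.5 + runif(1000, -0.05, 0.05),
                        y = 0.5 + runif(1000, -0.05, 0.05))
  ev <- list(time = 0.1, center = c(0.5, 0.5), kernel = k5)
  got <- nrow(select_affected(big, ev, unit_torus))
  bounds <- qbinom(c(0.0005, 0.9995), 1000, 0.5)
  expect_gte(got, bounds[1])
  expect_lte(got, bounds[2])
})

test_that("apply_event handles empty, movement and merger outcomes", {
  set.seed(22)
  k <- event_kernel("disc", 0.1, 0.8, 10)
  C <- lineage_set(quick_sheet(5), unit_torus)
  ev <- list(time = 0.3, center = c(0.4, 0.4), kernel = k)

  # empty: nothing changes, no node added
  res <- apply_event(C, C[0, ], ev, unit_torus)
  expect_equal(res$lineages$node, C$node)
  expect_equal(res$lineages$x, C$x)
  expect_length(res$builder$merger_sizes, 0)

  # singleton: pure movement within the event disc, count unchanged
  res <- apply_event(C, C[2, ], ev, unit_torus)
  expect_equal(nrow(res$lineages), 5L)
  expect_equal(res$lineages$node, C$node)
  moved <- c(res$lineages$x[2], res$lineages$y[2])
  expect_lte(torus_distance(ev$center, moved, unit_torus), k$radius)
  expect_length(res$builder$merger_sizes, 0)

  # three-way merger: one ancestor, count drops by 2, children recorded
  res <- apply_event(C, C[c(1, 3, 5), ], ev, unit_torus)
  expect_equal(nrow(res$lineages), 3L)
  expect_equal(res$builder$merger_sizes, 3L)
  expect_setequal(res$builder$edge_child, c(1L, 3L, 5L))
  expect_equal(unique(res$builder$edge_parent), 6L)
  anc <- c(res$builder$node_x[6], res$builder$node_y[6])
  expect_lte(torus_distance(ev$center, anc, unit_torus), k$radius)

  # non-subset rejected
  alien <- tibble::tibble(node = 99L, x = 0.1, y = 0.1)
  expect_error(apply_event(C, alien, ev, unit_torus), "subset")
})

test_that("a single sampled individual yields a trivial genealogy", {
  k <- event_kernel("disc", 0.1, 0.5, 10)
  g <- simulate_genealogy(quick_sheet(1, seed = 3), unit_torus, k)
  expect_true(g$coalesced)
  expect_equal(g$n_leaves, 1L)
  expect_equal(g$tmrca, 0)
  expect_length(g$merger_sizes, 0)
})

test_that("panmictic full-impact events coalesce everyone at the first event", {
  set.seed(23)
  pan <- event_kernel("disc", 0.75, 1, rate_density = 5,
                      landscape = unit_torus, allow_large_radius = TRUE)
  tm <- replicate(2000, {
    g <- simulate_genealogy(quick_sheet(4), unit_torus, pan)
    expect_true(g$coalesced)
    g$tmrca
  })
  # every event covers the torus and selects everyone: TMRCA ~ Exp(lambda*A)
  ks <- suppressWarnings(ks.test(tm, "pexp", 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("all engines draw from the same coalescence-time law", {
  set.seed(24)
  k <- event_kernel("disc", 0.2, 0.6, rate_density = 10)
  sheet <- tibble::tibble(id = c("a", "b"), x = c(0.3, 0.5), y = c(0.5, 0.5))
  t_thin <- replicate(2000,
    simulate_genealogy(sheet, unit_torus, k, engine = "thinned")$tmrca)
  t_naive <- replicate(2000,
    simulate_genealogy(sheet, unit_torus, k, engine = "naive")$tmrca)
  ks <- suppressWarnings(ks.test(t_thin, t_naive))
  expect_gt(ks$p.value, 0.01)

  # the pure-R reference engine agrees too (smaller n: it is slow)
  t_ref <- replicate(300,
    simulate_genealogy(sheet, unit_torus, k, engine = "reference")$tmrca)
  ks2 <- suppressWarnings(ks.test(t_ref, t_thin))
  expect_gt(ks2$p.value, 0.01)
})

test_that("lineage count bookkeeping matches the merger sizes", {
  set.seed(25)
  k <- event_kernel("disc", 0.15, 0.9, 30)
  for (n in c(2, 5, 9)) {
    g <- simulate_genealogy(quick_sheet(n), unit_torus, k)
    expect_true(g$coalesced)
    # n - 1 net losses, each merger of size m removes m - 1
    expect_equal(sum(g$merger_sizes - 1L), n - 1L)
    expect_true(all(g$merger_sizes >= 2L))
    # parent times nondecreasing along every edge
    nd <- g$nodes
    has_p <- !is.na(nd$parent)
    expect_true(all(nd$time[nd$parent[has_p]] >= nd$time[has_p]))
    # one root
    expect_equal(sum(!has_p), 1L)
    # phylo view agrees with leaf count and TMRCA
    expect_equal(length(g$tree$tip.label), n)
    depths <- ape::node.depth.edgelength(g$tree)
    expect_equal(max(depths[seq_len(n)]), g$tmrca, tolerance = 1e-8)
  }
})

test_that("exhausting the event budget reports non-coalescence explicitly", {
  set.seed(26)
  sparse <- event_kernel("disc", 0.02, 0.05, rate_density = 1)
  g <- simulate_genealogy(quick_sheet(6), unit_torus, sparse, max_events = 500)
  expect_false(g$coalesced)
  expect_gt(length(g$roots), 1L)
  expect_true(is.na(g$tmrca))
  expect_error(write_genealogy(g, tempfile()), "non-coalesced")
  expect_error(overlay_mutations(g, tiny_mutation()),
               class = "slfv_not_coalesced")
})

test_that("first-merger membership is exchangeable for co-located samples", {
  set.seed(27)
  # all four samples at one point; with a global kernel every pair is an
  # equally likely first merger
  sheet <- tibble::tibble(id = paste0("s", 1:4), x = rep(0.5, 4),
                          y = rep(0.5, 4))
  pan <- event_kernel("disc", 0.75, 0.25, rate_density = 5,
                      landscape = unit_torus, allow_large_radius = TRUE)
  pair_of <- replicate(5000, {
    g <- simulate_genealogy(sheet, unit_torus, pan)
    kids <- sort(g$nodes$node[g$nodes$parent == 5L & !is.na(g$nodes$parent)])
    if (length(kids) == 2) paste(kids, collapse = "-") else NA
  })
  counts <- table(pair_of[!is.na(pair_of)])
  expect_equal(length(counts), 6L)
  expect_gt(chisq.test(as.numeric(counts))$p.value, 0.001)
})

test_that("genealogies round-trip through Newick plus node table", {
  set.seed(28)
  k <- event_kernel("disc", 0.15, 0.8, 30)
  g <- simulate_genealogy(quick_sheet(6), unit_torus, k)
  prefix <- file.path(withr::local_tempdir(), "g1")
  write_genealogy(g, prefix)
  back <- read_genealogy(prefix)
  expect_equal(as.data.frame(back$nodes), as.data.frame(g$nodes),
               tolerance = 1e-9)
  expect_equal(back$tmrca, g$tmrca, tolerance = 1e-9)
  # topologies identical
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back$tree),
                                         ape::unroot(g$tree))), 0)
  expect_equal(sum(back$tree$edge.length), sum(g$tree$edge.length),
               tolerance = 1e-6)
})

test_that("tidy and glance expose the node table and run summary", {
  set.seed(29)
  k <- event_kernel("disc", 0.15, 0.8, 30)
  g <- simulate_genealogy(quick_sheet(5), unit_torus, k)
  td <- tidy(g)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("node", "label", "parent", "time", "x", "y") %in% names(td)))
  gl <- glance(g)
  expect_equal(gl$n_leaves, 5L)
  expect_true(gl$coalesced)
  expect_equal(gl$tmrca, g$tmrca)
})
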