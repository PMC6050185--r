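test_that("K2P matrices have the required structure and limits", {
  Q <- k2p_rate_matrix(1, 3)
  expect_equal(rowSums(Q), rep(0, 4), ignore_attr = TRUE)
  # total substitution rate mu: alpha + 2 beta
  expect_equal(unname(Q["A", "G"] + Q["A", "C"] + Q["A", "T"]), 1)
  expect_equal(unname(Q["A", "G"] / Q["A", "C"]), 3)  # kappa

  expect_equal(k2p_transition_matrix(0, 1, 3),
               diag(4), ignore_attr = TRUE)
  P_inf <- k2p_transition_matrix(1e3, 1, 3)
  expect_true(all(abs(P_inf - 0.25) < 1e-6))
  expect_error(k2p_transition_matrix(-1, 1, 3), "non-negative")

  # purine/pyrimidine relabeling symmetry: A<->G entry equals C<->T entry
  P <- k2p_transition_matrix(0.3, 0.7, 2.5)
  expect_equal(P["A", "G"], P["C", "T"])
  expect_equal(P["A", "C"], P["G", "T"])
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)
})

test_that("closed-form K2P probabilities match the matrix exponential", {
  skip_if_not_installed("Matrix")
  set.seed(31)
  for (i in 1:5) {
    t <- runif(1, 0, 3)
    mu <- runif(1, 0.1, 2)
    kappa <- runif(1, 0.3, 6)
    P_closed <- k2p_transition_matrix(t, mu, kappa)
    P_expm <- as.matrix(Matrix::expm(k2p_rate_matrix(mu, kappa) * t))
    expect_lt(max(abs(P_closed - P_expm)), 1e-9)
  }
})

test_that("zero mutation rate gives monomorphic data under both models", {
  set.seed(32)
  g <- toy_genealogy()
  for (model in c("k2p", "infinite_sites")) {
    aln <- overlay_mutations(g, mutation_config(model, mu = 0,
                                                seq_length = 100))
    expect_equal(nrow(unique(unclass(aln))), 1L)
  }
})

test_that("infinite-sites segregating sites match the Poisson expectation", {
  set.seed(33)
  g <- toy_genealogy()
  mu <- 0.002
  L <- 500
  cfg <- mutation_config("infinite_sites", mu = mu, seq_length = L)
  S <- replicate(500, slfv:::n_segregating(overlay_mutations(g, cfg)))
  expected <- mu * L * toy_total_branch_length()
  se <- sqrt(expected / 500)  # Poisson variance
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("infinite-sites alignments pass the four-gamete test", {
  set.seed(34)
  k <- event_kernel("disc", 0.15, 0.8, 30)
  cfg <- mutation_config("infinite_sites", mu = 1e-4, seq_length = 300)
  for (rep in 1:5) {
    g <- simulate_genealogy(quick_sheet(6), unit_torus, k)
    aln <- unclass(overlay_mutations(g, cfg))
    seg <- which(colSums(aln) > 0 & colSums(aln) < nrow(aln))
    if (length(seg) < 2) next
    for (a in seg[1:min(5, length(seg))]) for (b in seg) {
      if (b <= a) next
      gam <- unique(paste(aln[, a], aln[, b]))
      expect_lte(length(gam), 3L)
    }
  }
})

test_that("K2P at kappa = 1 reduces to the Jukes-Cantor law", {
  set.seed(35)
  # two leaves separated by total path length 2 * 0.5; one long locus
  nodes <- tibble::tibble(
    node = 1:3, label = c("a", "b", "r"), parent = c(3L, 3L, NA),
    time = c(0, 0, 0.5), x = 0.5, y = 0.5
  )
  g <- structure(
    list(tree = NULL, nodes = nodes, n_leaves = 2L, coalesced = TRUE,
         tmrca = 0.5, merger_sizes = 2L, roots = 3L,
         n_iter = NA_real_, n_events = NA_real_, n_nonempty = NA_real_,
         landscape = unit_torus, kernel = NULL),
    class = "slfv_genealogy"
  )
  mu <- 0.8
  aln <- overlay_mutations(g, mutation_config("k2p", mu = mu, kappa = 1,
                                              seq_length = 20000))
  p_diff <- jc_p_diff(mu, 2 * 0.5)
  n_diff <- sum(aln[1, ] != aln[2, ])
  # binomial check at the JC expectation
  bounds <- qbinom(c(0.0005, 0.9995), 20000, p_diff)
  expect_gte(n_diff, bounds[1])
  expect_lte(n_diff, bounds[2])
  # transitions and transversions equally probable per remaining class:
  # under JC each of the three substitution types is equally represented
  diffs <- which(aln[1, ] != aln[2, ])
  type <- paste0(pmin(aln[1, diffs], aln[2, diffs]),
                 pmax(aln[1, diffs], aln[2, diffs]))
  is_ts <- factor(type %in% c("AG", "CT"), levels = c(FALSE, TRUE))
  expect_gt(chisq.test(table(is_ts), p = c(2 / 3, 1 / 3))$p.value, 0.001)
})

test_that("base composition tends to uniform on deep trees", {
  set.seed(36)
  g <- toy_genealogy()
  g$nodes$time <- g$nodes$time * 1e3  # very long branches: stationarity
  aln <- overlay_mutations(g, mutation_config("k2p", mu = 1, seq_length = 4000))
  tab <- table(factor(unclass(aln), levels = c("A", "C", "G", "T")))
  expect_gt(chisq.test(as.numeric(tab))$p.value, 0.001)
})

test_that("segregating sites are invariant to leaf relabeling", {
  set.seed(37)
  g <- toy_genealogy()
  cfg <- mutation_config("infinite_sites", mu = 0.01, seq_length = 400)
  aln <- overlay_mutations(g, cfg)
  shuffled <- unclass(aln)[sample(nrow(aln)), ]
  expect_equal(slfv:::n_segregating(aln),
               sum(colSums(shuffled) > 0 & colSums(shuffled) < nrow(shuffled)))
})

test_that("multilocus datasets honor the sampling design and determinism", {
  k <- event_kernel("disc", 0.15, 0.8, 30)
  cfg <- tiny_mutation(n_loci = 3, seq_length = 150)
  sheet <- quick_sheet(4, seed = 5)
  set.seed(40)
  ds1 <- simulate_dataset(sheet, unit_torus, k, cfg)
  set.seed(40)
  ds2 <- simulate_dataset(sheet, unit_torus, k, cfg)
  expect_length(ds1$alignments, 3L)
  for (l in 1:3) {
    expect_equal(dim(ds1$alignments[[l]]), c(4L, 150L))
    expect_identical(unclass(ds1$alignments[[l]]), unclass(ds2$alignments[[l]]))
  }
})

test_that("alignments round-trip through FASTA and site-matrix files", {
  set.seed(41)
  dir <- withr::local_tempdir()
  g <- toy_genealogy()

  nt <- overlay_mutations(g, mutation_config("k2p", mu = 0.1, seq_length = 170))
  fp <- file.path(dir, "locus.fa")
  write_locus_fasta(nt, fp)
  lines <- readLines(fp)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 80))
  back <- read_locus_fasta(fp)
  expect_equal(unclass(back), unclass(nt), ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(nt))

  bin <- overlay_mutations(g, mutation_config("infinite_sites", mu = 0.01,
                                              seq_length = 60))
  sp <- file.path(dir, "locus.tsv")
  write_site_matrix(bin, sp)
  back2 <- read_site_matrix(sp)
  expect_equal(unclass(back2), unclass(bin), ignore_attr = TRUE)
  expect_equal(rownames(back2), rownames(bin))
})
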