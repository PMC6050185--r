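test_that("prior draws respect their distributions and bounds", {
  expect_error(slfv_priors(c(-1, 10), c(0.1, 0.2)), "positive")
  expect_error(slfv_priors(c(10, 1), c(0.1, 0.2)), "lower")
  expect_error(slfv_priors(c(1, Inf), c(0.1, 0.2)), "finite")

  set.seed(61)
  pri <- slfv_priors(c(10, 1000), c(0.02, 0.2))
  d <- draw_priors(pri, 5000)
  expect_true(all(d$neighborhood_size >= 10 & d$neighborhood_size <= 1000))
  expect_true(all(d$dispersal_radius >= 0.02 & d$dispersal_radius <= 0.2))
  # log-uniform: log N_s uniform by KS
  ks1 <- suppressWarnings(
    ks.test(log(d$neighborhood_size), "punif", log(10), log(1000))
  )
  expect_gt(ks1$p.value, 0.01)
  ks2 <- suppressWarnings(ks.test(d$dispersal_radius, "punif", 0.02, 0.2))
  expect_gt(ks2$p.value, 0.01)
})

test_that("reference tables are reproducible and honor degenerate priors", {
  sheet <- quick_sheet(4, seed = 3)
  cfg <- tiny_mutation(n_loci = 2, seq_length = 150)
  pri <- slfv_priors(c(10, 40), c(0.08, 0.14))
  set.seed(62)
  t1 <- build_reference_table(pri, 10, sheet, unit_torus, cfg)
  set.seed(62)
  t2 <- build_reference_table(pri, 10, sheet, unit_torus, cfg)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  expect_equal(nrow(t1), 10L)

  # point-mass priors: constant parameter columns
  pt <- slfv_priors(c(25, 25), c(0.1, 0.1))
  set.seed(63)
  t3 <- build_reference_table(pt, 5, sheet, unit_torus, cfg)
  expect_equal(unique(t3$neighborhood_size), 25)
  expect_equal(unique(t3$dispersal_radius), 0.1)

  # tables round-trip through TSV
  path <- file.path(withr::local_tempdir(), "table.tsv")
  write_reference_table(t1, path)
  back <- read_reference_table(path)
  expect_equal(as.data.frame(back), as.data.frame(t1), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_setequal(slfv:::summary_cols_of(back), slfv:::summary_cols_of(t1))
})

test_that("non-coalescing draws are redrawn and counted", {
  # a kernel regime that cannot finish within the work bound
  sheet <- quick_sheet(6, seed = 4)
  cfg <- tiny_mutation(n_loci = 1, seq_length = 50)
  pri <- slfv_priors(c(20, 30), c(0.1, 0.12))
  set.seed(64)
  # max_events too small for anything: every draw flagged; cap redraws by
  # letting a generous budget through after verifying the error path
  g <- simulate_genealogy(sheet, unit_torus,
                          kernel_for_parameters(25, 0.11, unit_torus),
                          max_events = 10)
  expect_false(g$coalesced)
  tab <- build_reference_table(pri, 3, sheet, unit_torus, cfg,
                               max_events = 2e5)
  expect_equal(nrow(tab), 3L)
  expect_true(attr(tab, "n_redraws") >= 0)
})

test_that("rejection ABC accepts the nearest quantile with stable ties", {
  tab <- synthetic_table(200, noise = 0.05)
  obs <- tibble::as_tibble(tab)[17, ]

  # tolerance 1: the posterior is the prior sample
  post <- rejection_abc(obs, tab, 1)
  expect_equal(nrow(post), 200L)
  expect_setequal(post$neighborhood_size, tab$neighborhood_size)

  # exact match at minimal tolerance: that row comes back
  post1 <- rejection_abc(obs, tab, 1 / 200)
  expect_equal(nrow(post1), 1L)
  expect_equal(post1$neighborhood_size, tab$neighborhood_size[17])
  expect_equal(post1$distance, 0)

  # acceptance count is the ceiling of the quantile
  expect_equal(nrow(rejection_abc(obs, tab, 0.123)), ceiling(0.123 * 200))

  # row shuffling leaves the accepted parameter set unchanged
  set.seed(65)
  perm <- sample(200)
  tabp <- tab[perm, ]
  attr(tabp, "summary_cols") <- attr(tab, "summary_cols")
  class(tabp) <- class(tab)
  p1 <- rejection_abc(obs, tab, 0.1)
  p2 <- rejection_abc(obs, tabp, 0.1)
  expect_setequal(round(p1$neighborhood_size, 10),
                  round(p2$neighborhood_size, 10))

  expect_error(rejection_abc(obs, tab, 0), "tolerance")
  expect_error(rejection_abc(obs, tab[0, ], 0.1), "empty")
  # all-constant summaries are an explicit failure
  tabc <- tab
  tabc$s_ns <- 1; tabc$s_r <- 2; tabc$s_mix <- 3
  expect_error(rejection_abc(obs, tabc, 0.1), "zero-spread|usable")
})

test_that("posterior point estimates tighten as tolerance shrinks", {
  tab <- synthetic_table(4000, noise = 0.02, seed = 66)
  truth <- list(neighborhood_size = 100, dispersal_radius = 0.1)
  obs <- tibble::tibble(s_ns = log(100), s_r = 0.1, s_mix = log(100) * 0.1)
  err <- vapply(c(0.5, 0.1, 0.02), function(tol) {
    post <- rejection_abc(obs, tab, tol)
    abs(mean(post$neighborhood_size) - truth$neighborhood_size)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("HPDI is the shortest window and matches brute force", {
  expect_equal(unname(hpdi(rep(3.3, 50))), c(3.3, 3.3))
  expect_error(hpdi(1), "at least 2")
  expect_error(hpdi(1:10, mass = 1.2), "mass")

  set.seed(67)
  u <- runif(1e5)
  h <- hpdi(u, 0.95)
  expect_lt(abs(diff(h) - 0.95), 0.01)

  # bimodal: interval hugs the heavier mode and beats the equal-tailed one
  x <- c(rnorm(1400, 0, 0.1), rnorm(600, 5, 0.1))
  h50 <- hpdi(x, 0.5)
  expect_lt(h50["upper"], 1)  # sits on the mode near zero
  eq_tail <- diff(quantile(x, c(0.25, 0.75), names = FALSE))
  expect_lt(diff(h50), eq_tail)

  # exact agreement with an exhaustive window scan
  for (mass in c(0.5, 0.8, 0.95)) {
    y <- rexp(97)
    expect_equal(unname(hpdi(y, mass)), brute_force_hpdi(y, mass))
  }
})

test_that("R-squared of the cross-validation obeys its definition", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(slfv:::r_squared(x, x), 1)
  expect_equal(slfv:::r_squared(x, rep(mean(x), 5)), 0)
  expect_equal(slfv:::r_squared(x, 2 * x + 3), 1)  # affine maps score 1
})

test_that("cross-validation recovers parameters from informative summaries", {
  tab <- synthetic_table(800, noise = 0)
  set.seed(68)
  cv <- loo_cv_r2(tab, tolerance = 0.02, n_heldout = 60,
                  permuted_baseline = TRUE)
  r2 <- glance(cv)
  expect_gt(r2$r_squared[r2$parameter == "neighborhood_size"], 0.95)
  expect_gt(r2$r_squared[r2$parameter == "dispersal_radius"], 0.95)
  # permuting truths destroys the association
  expect_true(all(r2$r_squared > r2$r_squared_permuted))

  # uninformative summaries give near-zero R-squared
  noise_tab <- synthetic_table(400, noise = 0)
  set.seed(69)
  noise_tab$s_ns <- rnorm(400)
  noise_tab$s_r <- rnorm(400)
  noise_tab$s_mix <- rnorm(400)
  cv0 <- loo_cv_r2(noise_tab, tolerance = 0.05, n_heldout = 50)
  expect_lt(max(glance(cv0)$r_squared), 0.15)

  expect_error(loo_cv_r2(tab, tolerance = 1e-6, n_heldout = 10), "tolerance")
  expect_error(loo_cv_r2(tab, tolerance = 0.1, n_heldout = 1e4), "exceeds")
})

test_that("posterior tidiers report medians and intervals", {
  tab <- synthetic_table(500, noise = 0.05)
  obs <- tibble::as_tibble(tab)[100, ]
  post <- rejection_abc(obs, tab, 0.2)
  gl <- glance(post)
  expect_equal(gl$parameter, c("neighborhood_size", "dispersal_radius"))
  expect_true(all(gl$hpdi_lower <= gl$median & gl$median <= gl$hpdi_upper))
  expect_equal(unique(gl$n_accepted), nrow(post))
  td <- tidy(post)
  expect_equal(nrow(td), 2 * nrow(post))
})

test_that("HPDIs are calibrated by construction at loose tolerance", {
  # with tolerance 1 the posterior equals the prior sample, and truths are
  # prior draws, so the 95% HPDI covers the truth ~95% of the time
  tab <- synthetic_table(400, noise = 0.05, seed = 70)
  set.seed(71)
  covered <- vapply(sample.int(400, 200), function(i) {
    post <- rejection_abc(tibble::as_tibble(tab)[i, ], tab[-i, ], 1)
    h <- hpdi(post$neighborhood_size, 0.95)
    tab$neighborhood_size[i] >= h["lower"] && tab$neighborhood_size[i] <= h["upper"]
  }, logical(1))
  bounds <- qbinom(c(0.005, 0.995), 200, 0.95)
  expect_gte(sum(covered), bounds[1])
  expect_lte(sum(covered), bounds[2])
})
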