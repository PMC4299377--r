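test_that("hypergeometric tails match exhaustive enumeration", {
  # worked example: all 4 query genes inside a 5-member category of 10
  expect_equal(hypergeom_tail(10, 5, 4, 4, "enriched"), 5 / 210)
  expect_equal(enum_hyper_tail(10, 5, 4, 4, "enriched"), 5 / 210)
  # a certain event: no category members, lower tail at k = 0
  expect_equal(hypergeom_tail(10, 0, 4, 0, "depleted"), 1)
  # random spot checks against the enumeration oracle
  set.seed(12)
  for (i in 1:25) {
    N <- sample(2:12, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    dir <- sample(c("enriched", "depleted"), 1)
    expect_equal(hypergeom_tail(N, K, n, k, dir),
                 enum_hyper_tail(N, K, n, k, dir), tolerance = 1e-12)
  }
})

test_that("complement identity P(X>=k) + P(X<=k-1) = 1 holds", {
  set.seed(3)
  for (i in 1:20) {
    N <- sample(5:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(1:min(K, n), 1)
    expect_equal(hypergeom_tail(N, K, n, k, "enriched") +
                   hypergeom_tail(N, K, n, k - 1, "depleted"), 1,
                 tolerance = 1e-12)
  }
})

test_that("invalid overlap tables are rejected", {
  expect_error(hypergeom_tail(10, 11, 4, 2), "argument error")
  expect_error(hypergeom_tail(10, 5, 4, 5), "argument error")
  expect_error(hypergeom_tail(10, 5, -1, 0), "argument error")
})

test_that("BH adjustment reproduces the step-up rule and is permutation-equivariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(2:30, 1))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "argument error")
})

test_that("log odds ratio uses the half-corrected 2x2 table", {
  expect_equal(log_odds_ratio(100, 10, 10, 5), log2((5.5 / 5.5) / (5.5 / 85.5)))
  expect_equal(log_odds_ratio(100, 10, 10, 5), 3.9585, tolerance = 1e-4)
  # proportional table at large counts: no association
  expect_equal(log_odds_ratio(10000, 1000, 500, 50), 0, tolerance = 0.02)
  # query entirely inside the category: positive association
  expect_gt(log_odds_ratio(20, 8, 4, 4), 0)
  # always finite, even for degenerate cells
  expect_true(is.finite(log_odds_ratio(10, 0, 5, 0)))
  expect_true(is.finite(log_odds_ratio(10, 10, 10, 10)))
})

test_that("a strongly over-represented set dominates the enrichment ranking", {
  set.seed(15)
  universe <- sprintf("g%04d", 1:1000)
  planted <- sample(universe, 50)
  # query takes planted members at ~10x the rate of the rest
  query <- union(sample(planted, 40), sample(setdiff(universe, planted), 76))
  sets <- gene_set_collection(c(
    list(planted = planted),
    lapply(stats::setNames(1:10, sprintf("rand%02d", 1:10)),
           function(i) sample(universe, 50))), "GO")
  res <- enrich_sets(query, universe, sets, q_cutoff = 0.01)
  expect_equal(res$set[1], "planted")
  expect_true(res$significant[1])
  expect_equal(res$direction[1], "enriched")
  expect_gt(res$LR[1], 0)
})

test_that("degenerate enrichment inputs behave predictably", {
  universe <- sprintf("g%02d", 1:40)
  sets <- gene_set_collection(list(inside = universe[1:10],
                                   outside = c("x1", "x2")))
  expect_message(res <- enrich_sets(universe[1:5], universe, sets),
                 "skipping set 'outside'")
  expect_equal(nrow(res), 1)
  # query = universe: overlap is forced, nothing can be significant
  res2 <- suppressMessages(enrich_sets(universe, universe, sets))
  expect_false(any(res2$significant))
  expect_error(enrich_sets("g01", character(0), sets), "argument error")
  expect_error(enrich_sets("zz", universe, sets), "argument error")
})

test_that("label-shuffled enrichment stays at the nominal false-positive level", {
  set.seed(22)
  universe <- sprintf("g%04d", 1:400)
  sets <- gene_set_collection(
    lapply(stats::setNames(1:5, sprintf("s%d", 1:5)),
           function(i) sample(universe, 40)))
  hits <- 0
  for (i in 1:200) {
    query <- sample(universe, 60)  # null: no association with any set
    res <- enrich_sets(query, universe, sets, q_cutoff = 0.05)
    if (any(res$significant)) hits <- hits + 1
  }
  # BH at q < 0.05 over a null family: at most ~5% of shuffles may fire
  expect_lte(hits / 200, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("list overlap test reduces to the right hypergeometric tail", {
  u <- c("g1", "g2", "g3", "g4")
  res <- overlap_test(c("g1", "g2"), c("g2", "g3"), u)
  expect_equal(res$k, 1)
  expect_equal(res$p, 5 / 6)
  expect_equal(enum_hyper_tail(4, 2, 2, 1, "enriched"), 5 / 6)
  expect_equal(overlap_test(c("g1", "g2"), c("g3", "g4"), u)$p, 1)
  res_sub <- overlap_test(c("g1", "g2", "g3"), c("g1", "g2"), u)
  expect_equal(res_sub$k, 2)
  expect_equal(res_sub$p, hypergeom_tail(4, 3, 2, 2, "enriched"))
})

test_that("kernel density curves are normalized and match the normal closed form", {
  set.seed(4)
  x <- rnorm(1000)
  kd <- kde_curve(x)
  at0 <- kd$density[which.min(abs(kd$x))]
  expect_equal(at0, stats::dnorm(0), tolerance = 0.05)
  # trapezoid integral ~ 1
  integral <- sum(diff(kd$x) * (head(kd$density, -1) + tail(kd$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-2)
  # symmetric input, symmetric curve
  xs <- c(-3, -1, 0, 1, 3)
  grid <- seq(-6, 6, length.out = 201)
  kds <- kde_curve(xs, grid = grid, bandwidth = 0.7)
  expect_equal(kds$density, rev(kds$density), tolerance = 1e-12)
  expect_true(all(kd$density >= 0))
  expect_error(kde_curve(rep(2, 5)), "zero-variance")
  expect_error(kde_curve(1), "at least 2")
})
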