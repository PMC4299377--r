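test_that("config validation catches impossible settings", {
  expect_error(sim_config(library_size = 0), "config error")
  expect_error(sim_config(fraction_enriched = 0.6, fraction_depleted = 0.5),
               "config error")
  expect_error(sim_config(fp_rate = 1.2), "config error")
  expect_error(sim_config(pool_size = 0), "config error")
  expect_error(sim_config(hub_share = 1.5), "config error")
  expect_error(sim_config(sigma = -0.1), "config error")
})

test_that("YAML config reader accepts known keys only", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_genes: 100", "seed: 9"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_genes, 100)
  expect_equal(cfg$seed, 9)
  writeLines("n_gene: 100", path)
  expect_error(read_sim_config(path), "unknown setting")
})

test_that("all generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 7, n_genes = 100, n_tfs = 16, n_fragments = 4,
                    n_true_pdis = 6, n_pairs = 5)
  a <- simulate_translatome(cfg)
  b <- simulate_translatome(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_y1h(cfg)$table, simulate_y1h(cfg)$table)
  expect_identical(simulate_promoters(cfg)$promoters,
                   simulate_promoters(cfg)$promoters)
  rt <- simulate_regulatory_truth(cfg)
  expect_identical(simulate_genotype_expression(rt, cfg),
                   simulate_genotype_expression(rt, cfg))
})

test_that("planted fold changes are recovered in the low-noise limit", {
  cfg <- sim_config(seed = 3, n_genes = 200, dispersion = 0,
                    library_size = 5e7, fraction_enriched = 0.2,
                    fraction_depleted = 0.1, effect_log2fc = 2)
  sim <- simulate_translatome(cfg)
  d <- sim$counts$design
  cnt <- sim$counts$counts
  lfc <- log2(rowMeans(cnt[, d$sample[d$domain == "boundary"]]) /
                rowMeans(cnt[, d$sample[d$domain == "leaf"]]))
  expect_equal(unname(stats::median(lfc[sim$truth$enriched])), 2,
               tolerance = 0.1)
  expect_equal(unname(stats::median(lfc[sim$truth$depleted])), -2,
               tolerance = 0.1)
})

test_that("zero planted fractions yield empty truth sets", {
  sim <- simulate_translatome(sim_config(seed = 1, n_genes = 50,
                                         fraction_enriched = 0,
                                         fraction_depleted = 0))
  expect_length(sim$truth$enriched, 0)
  expect_length(sim$truth$depleted, 0)
})

test_that("unplanted promoters carry only background-chance motif hits", {
  cfg <- sim_config(seed = 21, motif_rate_query = 0, motif_rate_background = 0,
                    n_promoters_query = 40, n_promoters_background = 1)
  motifs <- data.frame(name = "G-box", iupac = "CACGTG")
  sim <- simulate_promoters(cfg, motifs)
  obs <- sum(vapply(sim$promoters$query, scan_motif, integer(1),
                    pattern = "CACGTG"))
  # CACGTG is its own reverse complement, so the per-position hit chance
  # is just the forward-match probability under the base composition
  p <- unname(prod(cfg$base_probs[c("C", "A", "C", "G", "T", "G")]))
  n_pos <- 40 * (cfg$promoter_length - 6 + 1)
  expect_lt(abs(obs - n_pos * p), 3 * sqrt(n_pos * p * (1 - p)) + 1)
  expect_equal(nrow(sim$truth$placements), 0)
})

test_that("planted occurrences are exactly recoverable when the background cannot produce them", {
  # motif is its own reverse complement and contains A; background has no A
  cfg <- sim_config(seed = 8, motif_rate_query = 1, motif_rate_background = 0,
                    n_promoters_query = 25, n_promoters_background = 1,
                    base_probs = c(A = 0, C = 0.4, G = 0.3, T = 0.3))
  motifs <- data.frame(name = "pal", iupac = "ATCGAT")
  sim <- simulate_promoters(cfg, motifs)
  obs <- sum(vapply(sim$promoters$query, scan_motif, integer(1),
                    pattern = "ATCGAT"))
  planted <- sum(sim$truth$placements$group == "query")
  expect_equal(obs, planted)
  expect_error(
    simulate_promoters(sim_config(promoter_length = 4), motifs),
    "config error")
})

test_that("error-free pools grow exactly when they contain a true binder", {
  cfg <- sim_config(seed = 13, n_tfs = 8, n_fragments = 3, pool_size = 4,
                    n_true_pdis = 3, fp_rate = 0, fn_rate = 0,
                    control_fail_rate = 0, n_autoactive = 0)
  sim <- simulate_y1h(cfg)
  pools <- call_pools(sim$table)
  expect_equal(nrow(pools), 3 * 8 / 4)  # two pools per fragment
  truth_key <- paste(sim$truth$pdis$tf, sim$truth$pdis$fragment)
  has_binder <- vapply(seq_len(nrow(pools)), function(i) {
    any(paste(pools$members[[i]], pools$fragment[i]) %in% truth_key)
  }, logical(1))
  expect_equal(pools$status == "positive", has_binder)
})

test_that("every TF appears in exactly one pool per fragment", {
  sim <- simulate_y1h(sim_config(seed = 2, n_tfs = 10, n_fragments = 2,
                                 pool_size = 4, n_true_pdis = 3,
                                 n_autoactive = 0, control_fail_rate = 0))
  pools <- call_pools(sim$table)
  for (f in unique(pools$fragment)) {
    members <- unlist(pools$members[pools$fragment == f])
    expect_setequal(members, sprintf("TF%04d", 1:10))
    expect_equal(anyDuplicated(members), 0)
  }
})

test_that("spurious pool growth tracks the configured false-positive rate", {
  # no true interactions: every positive pool is a false positive
  cfg <- sim_config(seed = 17, n_tfs = 336, n_fragments = 12,
                    n_true_pdis = 0, hub_share = 0, fp_rate = 0.1,
                    fn_rate = 0, control_fail_rate = 0, n_autoactive = 0)
  pools <- call_pools(simulate_y1h(cfg)$table)
  n <- nrow(pools)
  expect_gte(n, 1000)
  frac <- mean(pools$status == "positive")
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("noiseless genotype series lie exactly on the planted line", {
  cfg <- sim_config(seed = 4, sigma = 0, n_pairs = 2)
  truth <- data.frame(tf = c("t1", "t2"), target = c("y1", "y2"),
                      a = c(1, 9), b = c(2, -2))
  gx <- simulate_genotype_expression(truth, cfg)
  for (i in 1:2) {
    pts <- gx[gx$tf == truth$tf[i], ]
    expect_equal(pts$y, truth$a[i] + truth$b[i] * pts$x, tolerance = 1e-12)
    fit <- wls_fit(pts)
    expect_equal(fit$b, truth$b[i], tolerance = 1e-9)
  }
})

test_that("a zero slope leaves genotype target means level", {
  cfg <- sim_config(seed = 4, sigma = 0)
  gx <- simulate_genotype_expression(
    data.frame(tf = "t", target = "y", a = 1.5, b = 0), cfg)
  means <- tapply(gx$y, gx$genotype, mean)
  expect_equal(unname(diff(range(means))), 0, tolerance = 1e-12)
})

test_that("simulate_study emits a directory readable by the io module", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 6, n_genes = 60, n_tfs = 12, n_fragments = 3,
                    n_true_pdis = 4, n_pairs = 4, n_autoactive = 0,
                    n_promoters_query = 3, n_promoters_background = 5)
  simulate_study(cfg, dir)
  cm <- read_count_table(file.path(dir, "counts.tsv"),
                         file.path(dir, "design.tsv"))
  expect_s3_class(cm, "count_matrix")
  expect_length(read_promoters(file.path(dir, "promoters_query.fasta")), 3)
  expect_gt(nrow(read_y1h_table(file.path(dir, "y1h.tsv"))), 0)
  expect_gt(nrow(read_genotype_table(file.path(dir, "genotypes.tsv"))), 0)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_named(truth, c("translatome", "promoters", "y1h", "regulation"))
})
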