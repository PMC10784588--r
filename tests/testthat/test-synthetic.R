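# Synthetic-study generator: seeded determinism, marginal distributions,
# discretization, and recoverable ground truth.

test_that("every generator is reproducible under a fixed seed", {
  cfg <- simulation_config(n_lines = 20, n_markers = 15,
                           causal_marker_index = 3, effect_dr = 2, seed = 11)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  l1 <- simulate_lifespans(g1, cfg)
  l2 <- simulate_lifespans(g2, cfg)
  expect_identical(l1, l2)
  o1 <- simulate_omics(n_features = 30, n_pairs = 4, n_de = 5, seed = 7)
  o2 <- simulate_omics(n_features = 30, n_pairs = 4, n_de = 5, seed = 7)
  expect_identical(o1, o2)
  s1 <- simulate_gene_lists(100, 20, 30, 10, seed = 3)
  s2 <- simulate_gene_lists(100, 20, 30, 10, seed = 3)
  expect_identical(s1, s2)
  expect_false(identical(simulate_genotypes(simulation_config(
    n_lines = 20, n_markers = 15, seed = 12)), g1))
})

test_that("alternate-line frequency follows the configured binomial draw", {
  cfg <- simulation_config(n_lines = 10000, n_markers = 1,
                           maf_range = c(0.5, 0.5), missing_rate = 0,
                           seed = 5)
  g <- simulate_genotypes(cfg)
  f_alt <- mean(g$calls[, 1] == 2L)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(f_alt - 0.5), 3 * se)
})

test_that("degenerate sizes and invalid configurations are handled", {
  cfg <- simulation_config(n_lines = 8, n_markers = 0, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g), c(8L, 0L))
  expect_length(g$line_ids, 8)
  expect_error(simulation_config(n_lines = 0), "n_lines")
  expect_error(simulation_config(maf_range = c(0.6, 0.7)), "maf_range")
  expect_error(simulation_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(simulation_config(n_markers = 10, causal_marker_index = 11),
               "causal_marker_index")
})

test_that("recorded deaths land on positive multiples of the check interval", {
  cfg <- simulation_config(n_lines = 10, n_markers = 2, flies_per_line = 20,
                           check_interval_days = 3, seed = 2)
  g <- simulate_genotypes(cfg)
  life <- simulate_lifespans(g, cfg)
  expect_true(all(life$deaths$death_day > 0))
  expect_true(all(life$deaths$death_day %% 3 == 0))
  # huge baseline hazard: every fly is found dead at the first check
  cfg2 <- simulation_config(n_lines = 3, n_markers = 1, flies_per_line = 1,
                            gompertz_baseline_a = 1e6, seed = 2)
  life2 <- simulate_lifespans(simulate_genotypes(cfg2), cfg2)
  expect_true(all(life2$deaths$death_day == cfg2$check_interval_days))
})

test_that("raw Gompertz draws match the closed-form survival law", {
  a <- 8e-4; b <- 0.1
  x <- rgompertz(1e5, a = a, b = b, seed = 9)
  cdf <- function(q) 1 - exp(-(a / b) * (exp(b * q) - 1))
  ks <- suppressWarnings(stats::ks.test(x, cdf))
  expect_gt(ks$p.value, 0.01)
  expect_equal(gompertz_survival(c(10, 40), a, b),
               1 - cdf(c(10, 40)))
})

test_that("with no allele effect, alt and ref line medians are exchangeable", {
  # null calibration: two-sample t-test of alt vs ref DR medians should
  # reject at roughly the nominal 5% rate across seeded replicates
  n_rep <- 200
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(n_lines = 40, n_markers = 1,
                             maf_range = c(0.5, 0.5), missing_rate = 0,
                             causal_marker_index = 1, effect_dr = 1,
                             flies_per_line = 30, seed = 1000 + r)
    g <- simulate_genotypes(cfg)
    life <- simulate_lifespans(g, cfg)
    dr <- life$phenotypes[life$phenotypes$diet == "DR", ]
    carrier <- life$truth$carrier[dr$line_id]
    if (sum(carrier) < 2 || sum(!carrier) < 2) next
    rej[r] <- stats::t.test(dr$median_lifespan[carrier],
                            dr$median_lifespan[!carrier])$p.value < 0.05
  }
  rate <- mean(rej)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(rate, 0.05 + 3 * se)
  expect_gt(rate, 0.05 - 3 * se)
})

test_that("a DR-specific hazard effect shortens DR but not AL lifespans", {
  cfg <- simulation_config(n_lines = 60, n_markers = 5,
                           causal_marker_index = 2, effect_dr = 3,
                           effect_al = 1, flies_per_line = 60, seed = 21)
  g <- simulate_genotypes(cfg)
  life <- simulate_lifespans(g, cfg)
  carrier <- life$truth$carrier
  dr <- life$phenotypes[life$phenotypes$diet == "DR", ]
  al <- life$phenotypes[life$phenotypes$diet == "AL", ]
  expect_lt(mean(dr$median_lifespan[carrier[dr$line_id]]),
            mean(dr$median_lifespan[!carrier[dr$line_id]]))
  expect_gt(stats::t.test(al$median_lifespan[carrier[al$line_id]],
                          al$median_lifespan[!carrier[al$line_id]])$p.value,
            0.05)
  # DR extends lifespan panel-wide relative to AL
  expect_gt(mean(dr$median_lifespan[!carrier[dr$line_id]]),
            mean(al$median_lifespan[!carrier[al$line_id]]))
})

test_that("omics generator plants recoverable fold-changes and peptide counts", {
  om <- simulate_omics(n_features = 50, n_pairs = 5, n_de = 0, seed = 1)
  expect_length(om$truth$de_feature_ids, 0)
  om2 <- simulate_omics(n_features = 50, n_pairs = 5, n_de = 10,
                        log2fc_de = 1, sigma = 0.1,
                        frac_single_peptide = 0.2, seed = 2)
  expect_true(all(om2$truth$de_feature_ids %in% om2$expr$feature_ids))
  # planted features always carry enough peptide evidence to be selectable
  planted <- match(om2$truth$de_feature_ids, om2$expr$feature_ids)
  expect_true(all(om2$expr$unique_peptides[planted] >= 2))
  expect_true(any(om2$expr$unique_peptides == 1))
  expect_error(simulate_omics(n_features = 5, n_de = 6), "n_de")
})

test_that("gene-list generator hits the requested overlap exactly", {
  gl <- simulate_gene_lists(100, 20, 30, 0, seed = 4)
  expect_length(intersect(gl$set_a, gl$set_b), 0)
  gl2 <- simulate_gene_lists(10, 5, 5, 5, seed = 4)
  expect_length(intersect(gl2$set_a, gl2$set_b), 5)
  expect_setequal(gl2$set_a, gl2$set_b)
  gl3 <- simulate_gene_lists(500, 40, 60, 12, seed = 8)
  expect_length(intersect(gl3$set_a, gl3$set_b), 12)
  expect_true(all(c(gl3$set_a, gl3$set_b) %in% gl3$universe))
  expect_error(simulate_gene_lists(10, 5, 5, 6), "overlap")
  expect_error(simulate_gene_lists(10, 8, 8, 2), "cannot fit")
})
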