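# Paired/Welch t tests, Storey q-values, the DE filter, the Spearman screen
# and the hypergeometric overlap test.

test_that("paired t-test reproduces hand arithmetic and the stats oracle", {
  d <- c(0.9, 1.1, 1.0, 0.8, 1.2)
  r <- paired_t_test(d)
  expect_equal(r$t, 1.0 / (stats::sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$t, 14.1421356, tolerance = 1e-6)
  tt <- stats::t.test(d)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  expect_false(r$degenerate)
  r0 <- suppressWarnings(paired_t_test(c(0, 0, 0)))
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  expect_warning(r1 <- paired_t_test(c(1, 1, 1, 1)), "zero variance")
  expect_true(r1$degenerate)
  expect_equal(r1$p, 0)
  expect_error(paired_t_test(1), ">= 2")
})

test_that("Welch test matches t.test and handles degeneracy symmetrically", {
  set.seed(1)
  for (i in 1:20) {
    x <- stats::rnorm(sample(3:10, 1)); y <- stats::rnorm(sample(3:10, 1), 1)
    r <- two_sample_t_test(x, y)
    tt <- stats::t.test(x, y)
    expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p, tt$p.value, tolerance = 1e-12)
    expect_equal(r$df, unname(tt$parameter), tolerance = 1e-12)
    # two-sidedness: swapping the samples preserves p
    expect_equal(two_sample_t_test(y, x)$p, r$p, tolerance = 1e-12)
  }
  same <- suppressWarnings(two_sample_t_test(c(2, 2), c(2, 2)))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
})

test_that("q-values reduce to BH with pi0 = 1 and preserve p-value order", {
  expect_equal(as.numeric(storey_qvalues(0.04, pi0 = 1)), 0.04)
  set.seed(2)
  for (i in 1:20) {
    p <- stats::runif(sample(5:300, 1))^sample(1:3, 1)
    q <- storey_qvalues(p, pi0 = 1)
    expect_equal(as.numeric(q), stats::p.adjust(p, "BH"), tolerance = 0)
    # monotone in p
    o <- order(p)
    expect_true(all(diff(q[o]) >= 0))
  }
  expect_error(storey_qvalues(c(0.5, 1.2)), "0, 1")
  expect_length(storey_qvalues(numeric(0)), 0)
})

test_that("the smoothed pi0 estimate is calibrated on uniform nulls", {
  set.seed(3)
  pi0s <- replicate(10, {
    q <- storey_qvalues(stats::runif(2000))
    attr(q, "pi0")
  })
  expect_true(all(pi0s >= 0.85 & pi0s <= 1))
})

test_that("de_analysis pairs arms correctly and plants are recovered", {
  om <- simulate_omics(n_features = 60, n_pairs = 5, n_de = 8, log2fc_de = 1,
                       sigma = 0.1, seed = 4)
  de <- de_analysis(om$expr)
  expect_equal(de$feature_id, om$expr$feature_ids)
  planted <- de$feature_id %in% om$truth$de_feature_ids
  expect_equal(mean(de$log2fc[planted]), 1, tolerance = 0.15)
  expect_equal(mean(de$log2fc[!planted]), 0, tolerance = 0.1)
  sel <- select_de(de)
  expect_setequal(sel$feature_id, om$truth$de_feature_ids)
})

test_that("planted effects are recovered by the filter in nearly all seeds", {
  n_seed <- 100
  all_recovered <- 0L
  for (s in seq_len(n_seed)) {
    om <- simulate_omics(n_features = 80, n_pairs = 5, n_de = 8,
                         log2fc_de = 1, sigma = 0.1, seed = 4000 + s)
    sel <- select_de(de_analysis(om$expr))
    all_recovered <- all_recovered +
      all(om$truth$de_feature_ids %in% sel$feature_id)
  }
  expect_gte(all_recovered, 0.95 * n_seed)
})

test_that("the realized false-discovery proportion respects the q cutoff", {
  fp <- 0L; n_sel <- 0L
  for (s in 1:40) {
    om <- simulate_omics(n_features = 150, n_pairs = 5, n_de = 15,
                         log2fc_de = 1, sigma = 0.2, seed = 7000 + s)
    sel <- select_de(de_analysis(om$expr))
    fp <- fp + sum(!sel$feature_id %in% om$truth$de_feature_ids)
    n_sel <- n_sel + nrow(sel)
  }
  expect_gt(n_sel, 0)
  expect_lte(fp / n_sel, 2 * 0.05)
})

test_that("DE selection applies every threshold strictly", {
  res <- data.frame(
    feature_id = sprintf("f%02d", 1:10),
    n_pairs = 5L,
    log2fc = c(1.0, 0.58, -0.60, 0.50, 2.0, -1.2, 0.59, 1.0, 0.7, -0.59),
    t = 5, p = 0.001,
    q = c(0.01, 0.01, 0.01, 0.01, 0.05, 0.049, 0.04, 0.01, 0.06, 0.0499),
    unique_peptides = c(3L, 4L, 2L, 5L, 6L, 2L, 1L, 1L, 3L, 2L),
    degenerate = FALSE, stringsAsFactors = FALSE)
  sel <- select_de(res)
  # f01: passes all; f02: |lfc| = 0.58 exactly -> out; f03: -0.60, q ok -> in
  # f04: |lfc| 0.5 -> out; f05: q = 0.05 exactly -> out; f06: in
  # f07/f08: single peptide -> out; f09: q 0.06 -> out; f10: in
  expect_setequal(sel$feature_id, c("f01", "f03", "f06", "f10"))
})

test_that("the Spearman screen is a strict, rank-invariant positive filter", {
  set.seed(5)
  n <- 10
  target <- stats::rnorm(n)
  ab <- rbind(target = target,
              same = target,
              cubed = target^3,            # strictly monotone transform
              flipped = -target,
              noise = stats::rnorm(n))
  colnames(ab) <- sprintf("s%02d", 1:n)
  out <- spearman_screen(ab, "target", rho_min = 0.30)
  expect_true(all(c("same", "cubed") %in% out$feature_id))
  expect_equal(out$rho[out$feature_id == "same"], 1)
  expect_equal(out$rho[out$feature_id == "cubed"], 1)
  expect_false("flipped" %in% out$feature_id)
  # strictly monotone transform of every abundance leaves the screen fixed
  out2 <- spearman_screen(exp(ab), "target", rho_min = 0.30)
  expect_identical(out$feature_id, out2$feature_id)
  expect_equal(out$rho, out2$rho)
  # features sharing too few samples are skipped, with a count
  ab2 <- rbind(ab, sparse = c(1, 2, rep(NA, n - 2)))
  expect_message(out3 <- spearman_screen(ab2, "target"), "skipped 1")
  expect_false("sparse" %in% out3$feature_id)
  expect_error(spearman_screen(ab, "absent"), "not found")
})

test_that("overlap test matches the closed-form hypergeometric tail", {
  u <- sprintf("g%02d", 1:10)
  r <- overlap_test(u[1:5], u[6:10], u)
  expect_equal(r$overlap, 0)
  expect_equal(r$p, 1)
  full <- overlap_test(u[1:5], u[1:5], u)
  expect_equal(full$overlap, 5)
  expect_equal(full$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(full$fold_enrichment, 5 / (5 * 5 / 10))
  expect_error(overlap_test(c(u[1], "stranger"), u[1:3], u), "stranger")
})

test_that("overlap p agrees with subset enumeration on small universes", {
  for (n in c(6, 9, 12)) {
    u <- sprintf("g%02d", seq_len(n))
    for (na in c(2, n %/% 2)) for (nb in c(3, n %/% 2)) {
      gl <- simulate_gene_lists(n, na, nb, min(2, na, nb), seed = n)
      r <- overlap_test(gl$set_a, gl$set_b, gl$universe)
      expect_equal(r$p, oracle_overlap_p(n, na, nb, r$overlap),
                   tolerance = 1e-12)
    }
  }
})
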