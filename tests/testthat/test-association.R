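# Dichotomization, contingency tables, and the two-sided Fisher scan.

test_that("top-k assignment takes the k longest-lived lines, ties by line id", {
  ph <- toy_phenotypes(c(30, 50, 45, 48, 44, 41, 60, 33, 39, 42,
                         55, 47, 46, 43, 40, 38, 37, 36, 35, 34,
                         31, 32, 49, 51, 52, 53, 54, 56, 57, 58))
  ca <- assign_cases(ph, top_k = 25)
  expect_equal(sum(ca$assignment$label == "IN_CASE"), 25)
  expect_equal(sum(ca$assignment$label == "NON_CASE"), 5)
  # the 5 shortest-lived lines are the non-cases
  worst <- ph$line_id[order(ph$median_lifespan)][1:5]
  expect_setequal(ca$assignment$line_id[ca$assignment$label == "NON_CASE"],
                  worst)
  # all lines in-case when k equals the panel size
  expect_true(all(assign_cases(ph, top_k = 30)$assignment$label == "IN_CASE"))
  expect_error(assign_cases(ph, top_k = 31), "only 30 lines")
  # ties at the k-th lifespan resolved by ascending line id
  tie <- toy_phenotypes(c(50, 40, 40, 40, 30),
                        line_ids = c("La", "Lc", "Lb", "Ld", "Le"))
  ca2 <- assign_cases(tie, top_k = 3)
  expect_setequal(ca2$assignment$line_id[ca2$assignment$label == "IN_CASE"],
                  c("La", "Lb", "Lc"))
})

test_that("threshold assignment is strictly greater-than", {
  ph <- toy_phenotypes(c(40, 41, 42), line_ids = c("L1", "L2", "L3"))
  ca <- assign_cases(ph, mode = "threshold", lifespan_threshold = 41)
  expect_equal(ca$assignment$label[ca$assignment$line_id == "L3"], "IN_CASE")
  expect_equal(sum(ca$assignment$label == "IN_CASE"), 1)
  expect_warning(assign_cases(ph, mode = "threshold",
                              lifespan_threshold = 100),
                 "empty")
})

test_that("top-k assignment is invariant to a constant lifespan shift", {
  for (seed in 1:5) {
    set.seed(seed)
    ph <- toy_phenotypes(round(stats::runif(40, 20, 60), 1))
    shifted <- ph
    shifted$median_lifespan <- shifted$median_lifespan + 17.3
    a1 <- assign_cases(ph, top_k = 10)$assignment
    a2 <- assign_cases(shifted, top_k = 10)$assignment
    expect_identical(a1$label, a2$label)
  }
})

test_that("contingency tables count calls per group and drop missing lines", {
  g <- toy_genotypes(rbind(L1 = c(0L), L2 = c(2L), L3 = c(0L), L4 = c(2L)),
                     line_ids = c("L1", "L2", "L3", "L4"))
  ph <- toy_phenotypes(c(50, 49, 20, 21), line_ids = paste0("L", 1:4))
  ca <- assign_cases(ph, top_k = 2)
  tab <- build_table(g, "M01", ca)
  expect_equal(unname(tab), matrix(c(1L, 1L, 1L, 1L), 2, byrow = TRUE))
  # a missing call in an in-case line lands in no cell
  g2 <- toy_genotypes(rbind(L1 = NA_integer_, L2 = 2L, L3 = 0L, L4 = 2L),
                      line_ids = c("L1", "L2", "L3", "L4"))
  tab2 <- build_table(g2, "M01", ca)
  expect_equal(sum(tab2), 3)
  expect_equal(unname(tab2["IN_CASE", ]), c(0L, 1L))
  expect_error(build_table(g, "nope", ca), "not present")
})

test_that("table counts conserve the labeled, non-missing lines", {
  for (seed in 1:5) {
    cfg <- simulation_config(n_lines = 30, n_markers = 10,
                             missing_rate = 0.2, seed = seed)
    g <- simulate_genotypes(cfg)
    set.seed(seed)
    ph <- toy_phenotypes(stats::runif(30, 20, 60), line_ids = g$line_ids)
    ca <- assign_cases(ph, top_k = 10)
    for (m in g$marker_ids[c(1, 5, 10)]) {
      tab <- build_table(g, m, ca)
      expect_equal(sum(tab), sum(!is.na(g$calls[, m])))
    }
  }
})

test_that("two-sided Fisher p matches hand-enumerated tables", {
  expect_equal(fisher_exact_two_sided(c(5, 5, 5, 5)), 1.0)
  # [[10,0],[0,10]]: only the two perfectly separated tables qualify
  expect_equal(fisher_exact_two_sided(matrix(c(10, 0, 0, 10), 2,
                                             byrow = TRUE)),
               2 / choose(20, 10), tolerance = 1e-12)
  # [[2,1],[1,2]]: probabilities (1,9,9,1)/20, observed 9/20 -> all qualify
  expect_equal(fisher_exact_two_sided(c(2, 1, 1, 2)), 1.0)
  expect_warning(p0 <- fisher_exact_two_sided(c(0, 0, 0, 0)), "all-zero")
  expect_equal(p0, 1)
  expect_error(fisher_exact_two_sided(c(-1, 1, 1, 1)), "non-negative")
})

test_that("Fisher p agrees with the enumeration oracle and fisher.test", {
  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(rpois(4, lambda = sample(1:8, 1)), 2)
    p <- suppressWarnings(fisher_exact_two_sided(tab))
    expect_equal(p, oracle_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1],
                                    tab[2, 2]), tolerance = 1e-12)
    if (sum(tab) > 0)
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher p is invariant under simultaneous row and column swap", {
  set.seed(7)
  for (i in 1:50) {
    v <- rpois(4, 5)
    swapped <- c(v[4], v[3], v[2], v[1])
    expect_equal(fisher_exact_two_sided(v), fisher_exact_two_sided(swapped),
                 tolerance = 1e-12)
  }
})

test_that("the marker scan preserves order, is deterministic, and flags a planted separator", {
  cfg <- simulation_config(n_lines = 24, n_markers = 12, missing_rate = 0.05,
                           seed = 3)
  g <- simulate_genotypes(cfg)
  set.seed(3)
  life <- stats::runif(24, 20, 60)
  # plant marker 4 as a perfect separator of the top-12 lines
  top <- rank(-life) <= 12
  g$calls[, 4] <- ifelse(top, 0L, 2L)
  ph <- toy_phenotypes(life, line_ids = g$line_ids)
  ca <- assign_cases(ph, top_k = 12)
  res <- run_association(g, ca)
  expect_equal(res$marker_id, g$marker_ids)
  expect_equal(which.min(res$p_nominal), 4L)
  expect_identical(res, run_association(g, ca))
  # empty marker set gives an empty result
  g0 <- simulate_genotypes(simulation_config(n_lines = 24, n_markers = 0,
                                             seed = 1))
  expect_equal(nrow(run_association(g0, ca)), 0)
  # lines missing from either input are excluded with a message
  g_small <- toy_genotypes(g$calls[1:20, , drop = FALSE],
                           line_ids = g$line_ids[1:20],
                           marker_ids = g$marker_ids)
  expect_message(run_association(g_small, ca), "excluding")
})

test_that("under a null panel the p <= 0.05 fraction stays near or below nominal", {
  cfg <- simulation_config(n_lines = 100, n_markers = 500,
                           missing_rate = 0.02, seed = 17)
  g <- simulate_genotypes(cfg)
  set.seed(17)
  ph <- toy_phenotypes(stats::runif(100, 30, 60), line_ids = g$line_ids)
  ca <- assign_cases(ph, top_k = 25)
  res <- run_association(g, ca)
  frac <- mean(res$p_nominal <= 0.05)
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lte(frac, 0.05 + 3 * se)
})

test_that("marker annotation uses 1-based inclusive gene intervals", {
  iv <- data.frame(gene_id = "gA", contig = "2L", start = 50L, end = 150L,
                   stringsAsFactors = FALSE)
  res <- data.frame(marker_id = c("m1", "m2", "m3", "m4"),
                    contig = "2L", position = c(100L, 150L, 151L, 50L),
                    p_nominal = 1, stringsAsFactors = FALSE)
  ann <- annotate_markers(res, iv)
  expect_equal(ann$gene_ids, c("gA", "gA", "", "gA"))
  res2 <- data.frame(marker_id = "m1", p_nominal = 1)
  expect_warning(ann2 <- annotate_markers(res2, iv), "no coordinates")
  expect_true(is.na(ann2$gene_ids))
})
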