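# Downstream omics statistics: paired/Welch t tests, Storey q-values, the
# differential-abundance filter, a Spearman co-abundance screen, and the
# hypergeometric gene-set overlap test.

#' Paired expression matrix container
#'
#' Log2-scale feature x sample abundance matrix with condition labels and
#' pair identifiers (e.g. five replicate pools of knockdown heads paired with
#' five control pools), plus a unique-peptide count per feature used as an
#' identification-evidence filter. Pairs must be complete: every pair id must
#' appear exactly once in each condition.
#'
#' @param abundances numeric matrix, features x samples, log2 scale; `NA`
#'   marks a missing quantification.
#' @param condition character vector per sample with exactly two levels; the
#'   first level in sort order of `condition_order` is the "condition" arm.
#' @param pair_id character vector per sample pairing the two arms.
#' @param unique_peptides integer vector per feature (>= 0).
#' @param condition_order optional length-2 character giving (condition,
#'   control); defaults to `c("condition", "control")` when present,
#'   otherwise the two levels in first-appearance order.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(abundances, condition, pair_id, unique_peptides,
                              condition_order = NULL) {
  abundances <- as.matrix(abundances)
  if (is.null(rownames(abundances)) || is.null(colnames(abundances)))
    stop_fmt("abundance matrix needs feature rownames and sample colnames")
  ns <- ncol(abundances)
  if (length(condition) != ns || length(pair_id) != ns)
    stop_fmt("condition/pair_id length (%d/%d) must match %d samples",
             length(condition), length(pair_id), ns)
  condition <- as.character(condition); pair_id <- as.character(pair_id)
  levs <- unique(condition)
  if (length(levs) != 2L)
    stop_fmt("exactly two condition labels required (got: %s)",
             paste(levs, collapse = ", "))
  if (is.null(condition_order))
    condition_order <- if (all(c("condition", "control") %in% levs))
      c("condition", "control") else levs
  if (!setequal(condition_order, levs) || length(condition_order) != 2L)
    stop_fmt("condition_order must name the two condition labels")
  for (lv in levs) {
    pid <- pair_id[condition == lv]
    if (anyDuplicated(pid))
      stop_fmt("pair '%s' appears twice in condition '%s'",
               pid[duplicated(pid)][1L], lv)
  }
  if (!setequal(pair_id[condition == levs[1L]], pair_id[condition == levs[2L]]))
    stop_fmt("pairs are incomplete: every pair id needs both conditions")
  if (length(unique_peptides) != nrow(abundances))
    stop_fmt("unique_peptides length must match the %d features",
             nrow(abundances))
  unique_peptides <- vapply(unique_peptides, check_count, integer(1),
                            name = "unique_peptides")
  structure(list(abundances = abundances,
                 feature_ids = rownames(abundances),
                 sample_ids = colnames(abundances),
                 condition = condition, pair_id = pair_id,
                 condition_order = condition_order,
                 unique_peptides = unique_peptides),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (%d pairs; %s vs %s)\n",
              nrow(x$abundances), ncol(x$abundances),
              length(unique(x$pair_id)), x$condition_order[1L],
              x$condition_order[2L]))
  invisible(x)
}

#' Write / read the paired expression TSV
#'
#' Tab-separated layout with a two-row header: row 1 holds `feature_id`, the
#' per-sample condition labels, and `unique_peptides`; row 2 holds `pair_id`
#' and the per-sample pair identifiers. Round-trips exactly through
#' [read_expression_tsv()].
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  h1 <- paste(c("feature_id", expr$condition, "unique_peptides"),
              collapse = "\t")
  h2 <- paste(c("pair_id", expr$pair_id, ""), collapse = "\t")
  h3 <- paste(c("sample_id", expr$sample_ids, ""), collapse = "\t")
  body <- vapply(seq_along(expr$feature_ids), function(i) {
    paste(c(expr$feature_ids[i],
            formatC(expr$abundances[i, ], format = "g", digits = 17),
            expr$unique_peptides[i]), collapse = "\t")
  }, character(1))
  writeLines(c(h1, h2, h3, body), path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @return [read_expression_tsv()] returns the [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_fmt("expression file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 4L)
    stop_fmt("%s: expected 3 header rows and at least one feature", path)
  split_row <- function(i) strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
  h1 <- split_row(1L); h2 <- split_row(2L); h3 <- split_row(3L)
  if (h1[1L] != "feature_id" || h1[length(h1)] != "unique_peptides" ||
      h2[1L] != "pair_id" || h3[1L] != "sample_id")
    stop_fmt("%s: malformed expression header", path)
  ns <- length(h1) - 2L
  condition <- h1[1L + seq_len(ns)]
  pair_id <- h2[1L + seq_len(ns)]
  sample_ids <- h3[1L + seq_len(ns)]
  nf <- length(lines) - 3L
  ab <- matrix(NA_real_, nrow = nf, ncol = ns)
  pept <- integer(nf); fid <- character(nf)
  for (i in seq_len(nf)) {
    row <- split_row(i + 3L)
    if (length(row) != ns + 2L)
      stop_fmt("%s: row %d has %d fields, expected %d", path, i + 3L,
               length(row), ns + 2L)
    fid[i] <- row[1L]
    ab[i, ] <- suppressWarnings(as.numeric(row[1L + seq_len(ns)]))
    pept[i] <- suppressWarnings(as.integer(row[ns + 2L]))
  }
  if (anyNA(pept)) stop_fmt("%s: non-integer unique_peptides value", path)
  dimnames(ab) <- list(fid, sample_ids)
  expression_matrix(ab, condition = condition, pair_id = pair_id,
                    unique_peptides = pept)
}

#' Paired t-test on per-pair differences
#'
#' Classical one-sample t-test of the paired differences:
#' t = mean(d) / (sd(d) / sqrt(n)), two-sided p from Student's t with n - 1
#' degrees of freedom. Zero-variance differences are degenerate: p = 1 when
#' the common difference is 0, p = 0 otherwise, flagged and logged.
#'
#' @param diffs numeric vector of per-pair differences (condition minus
#'   control), length >= 2, no NA.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
paired_t_test <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2L || anyNA(diffs))
    stop_fmt("need >= 2 complete paired differences")
  n <- length(diffs); m <- mean(diffs); s <- stats::sd(diffs)
  if (s == 0) {
    warn_fmt("paired t-test: zero variance across pairs (degenerate)")
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                p = if (m == 0) 1 else 0, df = n - 1L, degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1L), df = n - 1L,
       degenerate = FALSE)
}

#' Welch two-sample t-test
#'
#' Two-sided t-test with the Welch unequal-variance form and
#' Welch-Satterthwaite degrees of freedom. Degenerate when both samples have
#' zero variance (p = 1 if the means agree, else 0, with a warning).
#'
#' @param x,y numeric vectors, each with >= 2 values.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
two_sample_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L || anyNA(x) || anyNA(y))
    stop_fmt("each sample needs >= 2 complete values")
  vx <- stats::var(x); vy <- stats::var(y)
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  dm <- mean(x) - mean(y)
  if (se2 == 0) {
    warn_fmt("two-sample t-test: both samples have zero variance (degenerate)")
    return(list(t = if (dm == 0) 0 else sign(dm) * Inf,
                p = if (dm == 0) 1 else 0, df = NA_real_, degenerate = TRUE))
  }
  t <- dm / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df = df), df = df,
       degenerate = FALSE)
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the Storey estimate of the null
#' proportion pi0: on the grid lambda = 0, 0.05, ..., 0.90, the raw
#' estimates #\{p > lambda\} / (m (1 - lambda)) are smoothed with a cubic
#' smoothing spline (3 df) and extrapolated to lambda -> 1, then clamped to
#' (0, 1]. Q-values are the step-up transform
#' q_(i) = min_\{j >= i\} pi0 m p_(j) / j, so they preserve the order of the
#' p-values; with `pi0 = 1` the result equals Benjamini-Hochberg adjusted
#' p-values exactly.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param lambda tuning grid for the pi0 estimate.
#' @param pi0 optional fixed null proportion overriding the estimate.
#' @return numeric vector of q-values in input order, with the estimate
#'   attached as attribute `pi0`.
#' @export
storey_qvalues <- function(p, lambda = seq(0, 0.90, by = 0.05), pi0 = NULL) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop_fmt("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  if (is.null(pi0)) {
    lambda <- sort(unique(check_threshold_grid_pi0(lambda)))
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- if (length(lambda) >= 4L) {
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(fit, x = 1)$y
    } else pi0_l[length(lambda)]
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  } else {
    pi0 <- check_number(pi0, "pi0", min = 0, max = 1, strict_min = TRUE)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * (m / (m:1)) * p[o]))[ro]
  attr(q, "pi0") <- pi0
  q
}

check_threshold_grid_pi0 <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) == 0L || anyNA(lambda) ||
      any(lambda < 0) || any(lambda >= 1))
    stop_fmt("lambda grid must lie in [0, 1)")
  lambda
}

#' Differential-abundance analysis of a paired expression matrix
#'
#' Per feature: paired differences (condition minus control, matched by pair
#' id over pairs where both arms are quantified), log2 fold-change as the
#' mean difference, paired t-test, and Storey q-values over all tested
#' features. Features with fewer than 2 complete pairs are reported with NA
#' statistics and excluded from the q-value computation.
#'
#' @param expr an [expression_matrix()].
#' @param pi0 optional fixed pi0 forwarded to [storey_qvalues()].
#' @return data.frame of class `de_result`: `feature_id`, `n_pairs`,
#'   `log2fc`, `t`, `p`, `q`, `unique_peptides`, `degenerate`.
#' @export
de_analysis <- function(expr, pi0 = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  cond <- expr$condition_order[1L]; ctrl <- expr$condition_order[2L]
  ci <- which(expr$condition == cond)
  ki <- which(expr$condition == ctrl)
  ki <- ki[match(expr$pair_id[ci], expr$pair_id[ki])]
  d <- expr$abundances[, ci, drop = FALSE] -
    expr$abundances[, ki, drop = FALSE]
  nf <- nrow(d)
  res <- data.frame(feature_id = expr$feature_ids,
                    n_pairs = as.integer(rowSums(!is.na(d))),
                    log2fc = NA_real_, t = NA_real_, p = NA_real_,
                    q = NA_real_,
                    unique_peptides = expr$unique_peptides,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nf)) {
    di <- d[i, ][!is.na(d[i, ])]
    if (length(di) < 2L) next
    res$log2fc[i] <- mean(di)
    tt <- withCallingHandlers(paired_t_test(di),
                              warning = function(w) invokeRestart("muffleWarning"))
    res$t[i] <- tt$t; res$p[i] <- tt$p; res$degenerate[i] <- tt$degenerate
  }
  tested <- !is.na(res$p)
  if (sum(res$degenerate) > 0)
    message(sprintf("de_analysis: %d feature(s) with zero-variance differences flagged degenerate",
                    sum(res$degenerate)))
  if (any(tested)) {
    q <- storey_qvalues(res$p[tested], pi0 = pi0)
    res$q[tested] <- q
    attr(res, "pi0") <- attr(q, "pi0")
  }
  class(res) <- c("de_result", "data.frame")
  res
}

#' Select significantly changed features
#'
#' Applies the differential-abundance filter: identification evidence of at
#' least `min_peptides` unique peptides, q strictly below `q_max`, and
#' absolute log2 fold-change strictly above `min_abs_log2fc`. The defaults
#' (2 peptides, q < 0.05, |log2FC| > 0.58, i.e. fold-change ~1.5x) follow
#' standard DIA proteomics practice; all three comparisons are strict exactly
#' as stated, so q = 0.05 or |log2FC| = 0.58 is excluded.
#'
#' @param results a `de_result` from [de_analysis()].
#' @param min_peptides minimum unique-peptide count (inclusive).
#' @param q_max strict upper bound on q.
#' @param min_abs_log2fc strict lower bound on |log2fc|.
#' @return the selected rows of `results`.
#' @export
select_de <- function(results, min_peptides = 2L, q_max = 0.05,
                      min_abs_log2fc = 0.58) {
  stopifnot(is.data.frame(results),
            all(c("q", "log2fc", "unique_peptides") %in% names(results)))
  keep <- !is.na(results$q) & !is.na(results$log2fc) &
    results$unique_peptides >= min_peptides &
    results$q < q_max &
    abs(results$log2fc) > min_abs_log2fc
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman co-abundance screen against a target feature
#'
#' Ranks every other feature by Spearman correlation with the target feature
#' across samples (average ranks for ties, pairwise-complete observations)
#' and returns those with rho strictly above `rho_min` — a one-sided positive
#' screen for co-regulated proteins. Features sharing fewer than `min_n`
#' complete samples with the target are skipped (count reported in a
#' message). Being rank-based, the screen is invariant under any strictly
#' increasing transform of the abundances.
#'
#' @param expr an [expression_matrix()] or a plain numeric matrix
#'   (features x samples).
#' @param target_feature feature id of the screen target.
#' @param rho_min strict lower bound on rho (default 0.30).
#' @param min_n minimum number of shared non-missing samples (default 3).
#' @return data.frame `feature_id`, `rho`, `n_used` for passing features,
#'   sorted by decreasing rho; the number of skipped features is attached as
#'   attribute `n_skipped`.
#' @export
spearman_screen <- function(expr, target_feature, rho_min = 0.30,
                            min_n = 3L) {
  ab <- if (inherits(expr, "expression_matrix")) expr$abundances else
    as.matrix(expr)
  if (is.null(rownames(ab))) stop_fmt("abundance matrix needs feature rownames")
  ti <- match(target_feature, rownames(ab))
  if (is.na(ti)) stop_fmt("target feature '%s' not found", target_feature)
  rho_min <- check_number(rho_min, "rho_min", min = -1, max = 1)
  min_n <- check_count(min_n, "min_n", min = 2L)
  target <- ab[ti, ]
  others <- setdiff(seq_len(nrow(ab)), ti)
  rho <- rep(NA_real_, length(others))
  n_used <- integer(length(others))
  for (k in seq_along(others)) {
    x <- ab[others[k], ]
    ok <- !is.na(x) & !is.na(target)
    n_used[k] <- sum(ok)
    if (n_used[k] >= min_n)
      rho[k] <- stats::cor(x[ok], target[ok], method = "spearman")
  }
  n_skipped <- sum(is.na(rho) & n_used < min_n)
  if (n_skipped > 0)
    message(sprintf("spearman_screen: skipped %d feature(s) with < %d shared samples",
                    n_skipped, min_n))
  keep <- !is.na(rho) & rho > rho_min
  out <- data.frame(feature_id = rownames(ab)[others][keep],
                    rho = rho[keep], n_used = n_used[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rho, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Hypergeometric gene-set overlap test
#'
#' Tests whether two gene sets drawn from a common universe share more
#' members than chance: with N the universe size, the overlap count k is
#' referred to the hypergeometric upper tail P(X >= k), equivalent to a
#' one-sided Fisher's exact test on the 2x2 membership table. Fold enrichment
#' is k divided by its chance expectation |A||B|/N. The universe must be
#' supplied explicitly — the p-value is meaningless without it.
#'
#' @param set_a,set_b character vectors of gene ids (de-duplicated
#'   internally); both must be subsets of `universe`.
#' @param universe character vector of all testable gene ids.
#' @return object of class `overlap_result`: list with `n_a`, `n_b`,
#'   `n_universe`, `overlap`, `overlap_ids`, `p`, `fold_enrichment`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  stray_a <- setdiff(set_a, universe)
  stray_b <- setdiff(set_b, universe)
  if (length(stray_a) || length(stray_b))
    stop_fmt("ids outside the universe: %s",
             paste(utils::head(c(stray_a, stray_b), 5L), collapse = ", "))
  N <- length(universe); na <- length(set_a); nb <- length(set_b)
  shared <- intersect(set_a, set_b)
  k <- length(shared)
  p <- if (na == 0L || nb == 0L) 1 else
    stats::phyper(k - 1, na, N - na, nb, lower.tail = FALSE)
  fold <- if (na == 0L || nb == 0L) NA_real_ else k / (na * nb / N)
  structure(list(n_a = na, n_b = nb, n_universe = N, overlap = k,
                 overlap_ids = sort(shared), p = min(1, p),
                 fold_enrichment = fold),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d of |A|=%d, |B|=%d in universe %d; fold = %.3g, p = %.4g\n",
              x$overlap, x$n_a, x$n_b, x$n_universe, x$fold_enrichment, x$p))
  invisible(x)
}
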