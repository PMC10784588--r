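# Empirical FDR for the association scan by phenotype permutation.
#
# For permutation i, median lifespans are shuffled across lines (within the
# analyzed diet), cases are re-assigned on the shuffled phenotypes, and the
# full Fisher scan is re-run. With n^i(t) the number of markers at p <= t in
# permutation i, FDR(t) = mean_i n^i(t) / n_real(t), capped at 1 and left
# undefined where the real scan calls nothing (0/0 is not evidence of
# control).

#' Default p-value threshold grid for FDR tabulation
#'
#' Strictly increasing thresholds spanning the decades a marker scan is read
#' at: 1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05.
#'
#' @return numeric vector of thresholds in (0, 1).
#' @export
default_threshold_grid <- function() c(1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05)

check_threshold_grid <- function(thresholds) {
  if (!is.numeric(thresholds) || length(thresholds) == 0L ||
      anyNA(thresholds) || any(thresholds <= 0) || any(thresholds >= 1) ||
      any(diff(thresholds) <= 0))
    stop_fmt("thresholds must be strictly increasing and inside (0, 1)")
  as.numeric(thresholds)
}

#' Permute phenotype values across lines
#'
#' Uniformly shuffles the median lifespans of one diet across its line ids,
#' preserving the multiset of values; rows of the other diet are untouched.
#'
#' @param phenotypes data.frame with `line_id`, `diet`, `median_lifespan`.
#' @param diet diet whose values are permuted.
#' @param seed integer seed (NULL uses the current RNG stream).
#' @return the phenotype table with permuted lifespans.
#' @export
permute_phenotypes <- function(phenotypes, diet = "DR", seed = NULL) {
  rows <- which(phenotypes$diet == diet)
  if (length(rows) < 2L) stop_fmt("need >= 2 lines on diet '%s' to permute",
                                  diet)
  perm <- with_seed(seed, sample.int(length(rows)))
  phenotypes$median_lifespan[rows] <- phenotypes$median_lifespan[rows][perm]
  phenotypes
}

#' Permutation-based empirical FDR for the marker scan
#'
#' Runs the real association scan, then `n_perm` phenotype permutations; each
#' permutation re-assigns in-case/non-case labels on the shuffled phenotypes
#' before re-testing every marker, so the null preserves the extreme-group
#' construction. Per-permutation seeds are derived from `seed` by counter,
#' making the whole estimate deterministic and each permutation independently
#' reproducible.
#'
#' @param genotypes a (pre-filtered) [genotype_matrix].
#' @param phenotypes phenotype data.frame (`line_id`, `diet`,
#'   `median_lifespan`).
#' @param diet diet analyzed (default `"DR"`).
#' @param mode,top_k,lifespan_threshold dichotomization parameters passed to
#'   [assign_cases()].
#' @param thresholds threshold grid (default [default_threshold_grid()]).
#' @param n_perm number of permutations (default 10).
#' @param seed master integer seed.
#' @param perm_fun permutation function with the signature of
#'   [permute_phenotypes()]; replaceable for audit (e.g. an identity
#'   permutation makes every defined FDR exactly 1).
#' @return object of class `fdr_curve`: `curve` data.frame (`t`, `n_real`,
#'   `mean_null`, `fdr`, `defined`), `null_counts` matrix (n_perm x
#'   thresholds), the real `results`, and the parameters.
#' @export
estimate_fdr <- function(genotypes, phenotypes, diet = "DR",
                         mode = c("top_k", "threshold"), top_k = 25L,
                         lifespan_threshold = 41,
                         thresholds = default_threshold_grid(),
                         n_perm = 10L, seed = 1L,
                         perm_fun = permute_phenotypes) {
  mode <- match.arg(mode)
  thresholds <- check_threshold_grid(thresholds)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  cache <- new.env(parent = emptyenv())
  cases <- assign_cases(phenotypes, diet = diet, mode = mode, top_k = top_k,
                        lifespan_threshold = lifespan_threshold)
  real <- run_association(genotypes, cases, cache = cache)
  n_real <- vapply(thresholds, function(t) sum(real$p_nominal <= t),
                   numeric(1))
  null_counts <- matrix(NA_real_, nrow = n_perm, ncol = length(thresholds),
                        dimnames = list(paste0("perm_", seq_len(n_perm)),
                                        format(thresholds)))
  for (i in seq_len(n_perm)) {
    ph_i <- perm_fun(phenotypes, diet = diet, seed = derive_seed(seed, i))
    cases_i <- assign_cases(ph_i, diet = diet, mode = mode, top_k = top_k,
                            lifespan_threshold = lifespan_threshold)
    res_i <- run_association(genotypes, cases_i, cache = cache)
    null_counts[i, ] <- vapply(thresholds,
                               function(t) sum(res_i$p_nominal <= t),
                               numeric(1))
  }
  mean_null <- colMeans(null_counts)
  fdr <- ifelse(n_real > 0, pmin(1, mean_null / n_real), NA_real_)
  if (all(n_real == 0))
    warn_fmt("no marker called at any threshold in the real data; FDR undefined everywhere")
  curve <- data.frame(t = thresholds, n_real = as.integer(n_real),
                      mean_null = mean_null, fdr = fdr,
                      defined = n_real > 0)
  structure(list(curve = curve, null_counts = null_counts, results = real,
                 diet = diet, mode = mode, n_perm = n_perm, seed = seed),
            class = "fdr_curve")
}

#' @export
print.fdr_curve <- function(x, ...) {
  cat(sprintf("fdr_curve: %d markers, %d permutations (%s, %s)\n",
              nrow(x$results), x$n_perm, x$diet, x$mode))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Call markers at an FDR bound
#'
#' Picks the largest threshold t* whose estimated FDR is defined and at most
#' `fdr_max`, and returns the markers with nominal p <= t*. Because mean null
#' counts and real counts are both non-decreasing in t, enlarging `fdr_max`
#' can only grow the called set.
#'
#' @param results the real `association_result` the curve was computed on.
#' @param curve an `fdr_curve`.
#' @param fdr_max maximum acceptable FDR.
#' @return character vector of called marker ids (empty when no threshold
#'   qualifies), with attributes `t_star` and `fdr_at_t_star`.
#' @export
call_significant <- function(results, curve, fdr_max = 0.2) {
  stopifnot(inherits(curve, "fdr_curve"))
  fdr_max <- check_number(fdr_max, "fdr_max", min = 0, max = 1)
  if (!identical(results$marker_id, curve$results$marker_id))
    stop_fmt("FDR curve was computed on a different marker set")
  ok <- which(curve$curve$defined & curve$curve$fdr <= fdr_max)
  if (length(ok) == 0L)
    return(structure(character(0), t_star = NA_real_,
                     fdr_at_t_star = NA_real_))
  t_star <- curve$curve$t[max(ok)]
  called <- results$marker_id[results$p_nominal <= t_star]
  structure(called, t_star = t_star,
            fdr_at_t_star = curve$curve$fdr[max(ok)])
}
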