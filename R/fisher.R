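#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test of independence for a 2x2 contingency table with
#' the two-sided p-value defined by the minimum-likelihood rule: conditioning
#' on both margins, p is the sum of hypergeometric point probabilities over
#' all tables whose probability does not exceed that of the observed table.
#' This is the convention of the mainstream scientific stacks (and of
#' [stats::fisher.test()]); near-ties in point probability are admitted with
#' a relative tolerance of 1e-7. The association scan arranges each marker's
#' counts as `[[case_ref, case_alt], [noncase_ref, noncase_alt]]`.
#'
#' @param tab 2x2 numeric matrix of non-negative counts, or a length-4 vector
#'   in row-major order `c(case_ref, case_alt, noncase_ref, noncase_alt)`.
#' @return the two-sided p-value in (0, 1]. An all-zero table returns 1 by
#'   convention (with a warning): no data, no evidence.
#' @examples
#' fisher_exact_two_sided(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(tab) {
  if (is.matrix(tab)) {
    if (!all(dim(tab) == c(2L, 2L))) stop_fmt("table must be 2x2")
    v <- c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  } else {
    if (length(tab) != 4L) stop_fmt("table must have 4 counts")
    v <- as.numeric(tab)
  }
  if (anyNA(v) || any(v < 0) || any(v != floor(v)))
    stop_fmt("table counts must be non-negative integers")
  if (sum(v) == 0) {
    warn_fmt("all-zero contingency table; returning p = 1 by convention")
    return(1)
  }
  .fisher_p(v[1], v[2], v[3], v[4])
}

# Core p-value on counts (a, b, c, d) = (case_ref, case_alt, noncase_ref,
# noncase_alt). Conditional on margins, case_ref ~ Hypergeometric(m1, m2, k)
# with m1 = total ref lines, m2 = total alt lines, k = case-group size.
.fisher_p <- function(a, b, c, d, rel_tol = 1e-7) {
  m1 <- a + c; m2 <- b + d; k <- a + b
  x <- max(0, k - m2):min(k, m1)
  dens <- stats::dhyper(x, m1, m2, k)
  pobs <- dens[x == a]
  min(1, sum(dens[dens <= pobs * (1 + rel_tol)]))
}

# Vectorized scan over many tables with memoization: association scans and
# permutation nulls revisit the same table repeatedly (margins are pinned by
# the case-group size), so p-values are computed once per distinct table.
# `cache` is an environment shared across calls within one analysis.
.fisher_p_many <- function(a, b, c, d, cache = NULL) {
  key <- paste(a, b, c, d, sep = ":")
  p <- rep(NA_real_, length(key))
  if (!is.null(cache) && length(key)) {
    hits <- mget(key, envir = cache, ifnotfound = list(NULL))
    found <- !vapply(hits, is.null, logical(1))
    p[found] <- unlist(hits[found], use.names = FALSE)
  }
  for (i in which(is.na(p))) {
    if (!is.na(p[i])) next  # filled as a duplicate of an earlier key
    pi <- if (a[i] + b[i] + c[i] + d[i] == 0) 1 else
      .fisher_p(a[i], b[i], c[i], d[i])
    p[key == key[i]] <- pi
    if (!is.null(cache)) assign(key[i], pi, envir = cache)
  }
  p
}
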