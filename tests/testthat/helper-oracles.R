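`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles used to check the package implementations.
# These deliberately take the slow, direct route: factorial enumeration for
# the Fisher p-value, explicit per-event-time summation for the log-rank
# statistic, bitmask enumeration for set overlaps.

# Two-sided Fisher p by enumerating every table with the observed margins and
# computing each table's probability from factorials (no dhyper).
oracle_fisher_p <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  if (n == 0) return(1)
  tab_prob <- function(x) {
    # P(table) = r1! r2! c1! c2! / (n! x! (r1-x)! (c1-x)! (r2-c1+x)!)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
          lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
          lfactorial(c1 - x) - lfactorial(r2 - c1 + x))
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, tab_prob, numeric(1))
  pobs <- probs[xs == a]
  min(1, sum(probs[probs <= pobs * (1 + rel_tol)]))
}

# Mantel-Cox log-rank by direct summation over distinct pooled event times.
# Each argument is a data.frame with death_day and censored columns (or a
# bare numeric vector of uncensored death days).
oracle_logrank <- function(a, b) {
  norm <- function(x) if (is.data.frame(x))
    data.frame(t = x$death_day, e = !x$censored) else
      data.frame(t = x, e = TRUE)
  A <- norm(a); B <- norm(b)
  times <- sort(unique(c(A$t[A$e], B$t[B$e])))
  U <- 0; V <- 0
  for (tj in times) {
    nA <- sum(A$t >= tj); nB <- sum(B$t >= tj)
    n <- nA + nB
    dA <- sum(A$t == tj & A$e); dB <- sum(B$t == tj & B$e)
    d <- dA + dB
    U <- U + dA - d * nA / n
    if (n > 1)
      V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  list(U = U, V = V, statistic = if (V > 0) U^2 / V else NA_real_)
}

# Random small censored dataset for log-rank oracle sweeps.
random_death_df <- function(n, max_day = 12L, p_censor = 0.2) {
  data.frame(death_day = sample.int(max_day, n, replace = TRUE),
             censored = stats::runif(n) < p_censor)
}

# Hypergeometric upper-tail by bitmask enumeration of every draw of size nb
# from a universe of size n, with the A-set fixed to the first na elements.
# Returns the enumeration p for overlap >= k.
oracle_overlap_p <- function(n, na, nb, k) {
  stopifnot(n <= 15)
  masks <- 0:(2^n - 1)
  popcount <- function(x) {
    cnt <- integer(length(x))
    while (any(x > 0)) {
      cnt <- cnt + x %% 2L
      x <- x %/% 2L
    }
    cnt
  }
  size <- popcount(masks)
  amask <- if (na > 0) sum(2^(0:(na - 1))) else 0
  ov <- popcount(bitwAnd(masks, amask))
  sel <- size == nb
  if (!any(sel)) return(NA_real_)
  mean(ov[sel] >= k)
}

# A tiny valid VCF written as text; returns the path.
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=2L,length=23000000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("2L", "100", "m1", "A", "T", ".", "PASS", ".", "GT",
            "0/0", "1/1", "0/1"), collapse = "\t"),
    paste(c("2L", "200", "m2", "C", "G", ".", "PASS", ".", "GT",
            "./.", "1|1", "0/0"), collapse = "\t"),
    paste(c("2L", "300", "m3", "G", "A,T", ".", "PASS", ".", "GT",
            "0/0", "1/1", "2/2"), collapse = "\t"))
  writeLines(lines, path)
  path
}

# Small genotype/phenotype fixtures built in code.
toy_genotypes <- function(calls, line_ids = NULL, marker_ids = NULL) {
  calls <- as.matrix(calls)
  if (is.null(line_ids))
    line_ids <- rownames(calls) %||% sprintf("L%02d", seq_len(nrow(calls)))
  if (is.null(marker_ids))
    marker_ids <- colnames(calls) %||% sprintf("M%02d", seq_len(ncol(calls)))
  genotype_matrix(calls, line_ids = line_ids, marker_ids = marker_ids)
}

toy_phenotypes <- function(lifespans, diet = "DR",
                           line_ids = sprintf("L%02d", seq_along(lifespans))) {
  data.frame(line_id = line_ids, diet = diet, median_lifespan = lifespans,
             stringsAsFactors = FALSE)
}
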