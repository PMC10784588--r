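#' Genotype matrix of homozygous inbred lines
#'
#' Container for biallelic, homozygous-only genotype calls across a panel of
#' inbred lines. Calls are coded `0` (homozygous reference), `2` (homozygous
#' alternate) and `NA` (missing). Heterozygous calls are never stored: inbred
#' reference panels are fully homozygous by construction, and readers map any
#' residual heterozygous call to missing.
#'
#' @param calls integer matrix, lines x markers, values in \{0, 2, NA\}.
#' @param line_ids unique line identifiers (rows); defaults to rownames.
#' @param marker_ids unique marker identifiers (columns); defaults to colnames.
#' @param coords optional data.frame with columns `marker_id`, `contig`,
#'   `position` (1-based), one row per marker.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, line_ids = rownames(calls),
                            marker_ids = colnames(calls), coords = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(line_ids) || is.null(marker_ids))
    stop_fmt("line and marker identifiers are required")
  line_ids <- as.character(line_ids)
  marker_ids <- as.character(marker_ids)
  if (nrow(calls) != length(line_ids) || ncol(calls) != length(marker_ids))
    stop_fmt("call matrix is %d x %d but %d line ids and %d marker ids given",
             nrow(calls), ncol(calls), length(line_ids), length(marker_ids))
  if (anyDuplicated(line_ids))
    stop_fmt("duplicate line id: '%s'", line_ids[duplicated(line_ids)][1L])
  if (anyDuplicated(marker_ids))
    stop_fmt("duplicate marker id: '%s'", marker_ids[duplicated(marker_ids)][1L])
  bad <- !(calls %in% c(0L, 2L) | is.na(calls))
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop_fmt("invalid genotype call '%s' at line '%s', marker '%s' (allowed: 0, 2, NA)",
             calls[idx], line_ids[(idx - 1L) %% nrow(calls) + 1L],
             marker_ids[(idx - 1L) %/% nrow(calls) + 1L])
  }
  dimnames(calls) <- list(line_ids, marker_ids)
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    need <- c("marker_id", "contig", "position")
    if (!all(need %in% names(coords)))
      stop_fmt("coords must have columns: %s", paste(need, collapse = ", "))
    coords <- coords[match(marker_ids, coords$marker_id), need]
    if (anyNA(coords$marker_id))
      stop_fmt("coords missing for marker '%s'",
               marker_ids[which(is.na(coords$marker_id))[1L]])
    rownames(coords) <- NULL
  }
  structure(list(calls = calls, line_ids = line_ids, marker_ids = marker_ids,
                 coords = coords),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers (%.1f%% missing)%s\n",
              length(x$line_ids), length(x$marker_ids),
              100 * mean(is.na(x$calls)),
              if (is.null(x$coords)) "" else ", with coordinates"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Per-marker allele frequency and call-rate statistics
#'
#' Computes, for every marker, the minor-allele frequency among lines with a
#' non-missing call and the call rate. Because lines are homozygous, allele
#' frequency equals the frequency of alternate-carrying lines; the MAF is
#' folded as `min(f_alt, 1 - f_alt)` and so never exceeds 0.5. A marker with
#' no non-missing calls gets `call_rate = 0` and `maf = NA`.
#'
#' @param geno a [genotype_matrix].
#' @return data.frame with columns `marker_id`, `n_called`, `maf`, `call_rate`.
#' @export
compute_marker_stats <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n_lines <- length(geno$line_ids)
  n_called <- colSums(!is.na(geno$calls))
  n_alt <- colSums(geno$calls == 2L, na.rm = TRUE)
  f_alt <- ifelse(n_called > 0L, n_alt / n_called, NA_real_)
  data.frame(marker_id = geno$marker_ids,
             n_called = as.integer(n_called),
             maf = pmin(f_alt, 1 - f_alt),
             call_rate = if (n_lines > 0L) n_called / n_lines else numeric(0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter markers on minor-allele frequency and call rate
#'
#' Retains markers with `maf >= maf_min` (inclusive: a marker at exactly the
#' threshold is kept) and `call_rate >= min_call_rate`, preserving marker
#' order. The default MAF cutoff of 0.25 keeps only markers whose minor allele
#' is carried by a substantial fraction of lines, so that both alleles are
#' well represented in the 2x2 association tables. Markers with undefined MAF
#' (all calls missing) are always removed.
#'
#' @inheritParams compute_marker_stats
#' @param stats marker statistics from [compute_marker_stats()]; recomputed
#'   when omitted.
#' @param maf_min minimum minor-allele frequency (default 0.25).
#' @param min_call_rate minimum fraction of lines with a call (default 0).
#' @return the filtered [genotype_matrix].
#' @export
filter_markers <- function(geno, stats = NULL, maf_min = 0.25,
                           min_call_rate = 0) {
  stopifnot(inherits(geno, "genotype_matrix"))
  maf_min <- check_number(maf_min, "maf_min", min = 0, max = 0.5)
  min_call_rate <- check_number(min_call_rate, "min_call_rate", min = 0, max = 1)
  if (is.null(stats)) stats <- compute_marker_stats(geno)
  if (!identical(as.character(stats$marker_id), geno$marker_ids))
    stop_fmt("marker stats are not aligned to the genotype matrix")
  keep <- !is.na(stats$maf) & stats$maf >= maf_min &
    stats$call_rate >= min_call_rate
  genotype_matrix(geno$calls[, keep, drop = FALSE],
                  line_ids = geno$line_ids,
                  marker_ids = geno$marker_ids[keep],
                  coords = if (is.null(geno$coords)) NULL else
                    geno$coords[keep, , drop = FALSE])
}
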