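# Extreme-phenotype dichotomization and the per-marker Fisher scan.

#' Dichotomize lines into in-case and non-case groups
#'
#' Splits the phenotyped lines on one diet into an extreme-longevity in-case
#' group and a non-case group, either as the `top_k` longest-lived lines
#' (default, k = 25) or as all lines whose median lifespan strictly exceeds
#' `lifespan_threshold` days (default 41, the DR longevity cut used for
#' sensitivity analysis). In `top_k` mode, ties at the k-th lifespan are
#' broken by ascending line id so the assignment is deterministic; adding a
#' constant to every lifespan never changes it.
#'
#' @param phenotypes data.frame with `line_id`, `diet`, `median_lifespan`.
#' @param diet diet to analyze, `"DR"` (default) or `"AL"`.
#' @param mode `"top_k"` or `"threshold"`.
#' @param top_k in-case group size for `top_k` mode (default 25).
#' @param lifespan_threshold strict lower bound in days for `threshold` mode
#'   (default 41).
#' @return object of class `case_assignment`: data.frame `assignment`
#'   (`line_id`, `median_lifespan`, `label` in \{IN_CASE, NON_CASE\}) plus the
#'   parameters used.
#' @export
assign_cases <- function(phenotypes, diet = "DR",
                         mode = c("top_k", "threshold"),
                         top_k = 25L, lifespan_threshold = 41) {
  mode <- match.arg(mode)
  stopifnot(all(c("line_id", "diet", "median_lifespan") %in% names(phenotypes)))
  if (!diet %in% c("AL", "DR")) stop_fmt("diet must be 'AL' or 'DR'")
  ph <- phenotypes[phenotypes$diet == diet, , drop = FALSE]
  if (nrow(ph) == 0L) stop_fmt("no lines phenotyped on diet '%s'", diet)
  if (anyDuplicated(ph$line_id))
    stop_fmt("duplicate phenotype rows for line '%s' on diet '%s'",
             ph$line_id[duplicated(ph$line_id)][1L], diet)
  if (mode == "top_k") {
    top_k <- check_count(top_k, "top_k", min = 1L)
    if (nrow(ph) < top_k)
      stop_fmt("top_k = %d but only %d lines phenotyped on '%s'", top_k,
               nrow(ph), diet)
    ord <- order(-ph$median_lifespan, ph$line_id)
    label <- rep("NON_CASE", nrow(ph))
    label[ord[seq_len(top_k)]] <- "IN_CASE"
  } else {
    lifespan_threshold <- check_number(lifespan_threshold,
                                       "lifespan_threshold")
    label <- ifelse(ph$median_lifespan > lifespan_threshold,
                    "IN_CASE", "NON_CASE")
    if (!any(label == "IN_CASE"))
      warn_fmt("no line exceeds the %s-day threshold: in-case group is empty",
               format(lifespan_threshold))
  }
  out <- data.frame(line_id = ph$line_id,
                    median_lifespan = ph$median_lifespan,
                    label = label, stringsAsFactors = FALSE)
  out <- out[order(out$line_id), ]
  rownames(out) <- NULL
  structure(list(assignment = out, diet = diet, mode = mode,
                 top_k = if (mode == "top_k") top_k else NA_integer_,
                 lifespan_threshold = if (mode == "threshold")
                   lifespan_threshold else NA_real_),
            class = "case_assignment")
}

#' @export
print.case_assignment <- function(x, ...) {
  cat(sprintf("case_assignment (%s, %s): %d IN_CASE / %d NON_CASE lines\n",
              x$diet, x$mode, sum(x$assignment$label == "IN_CASE"),
              sum(x$assignment$label == "NON_CASE")))
  invisible(x)
}

#' Build the 2x2 genotype-by-group table for one marker
#'
#' Counts reference and alternate calls in the in-case and non-case groups,
#' arranged `[[case_ref, case_alt], [noncase_ref, noncase_alt]]`. Lines with
#' a missing call at the marker contribute to no cell, and lines genotyped
#' but not phenotyped (or vice versa) are excluded; exclusion is per marker,
#' which keeps every other line's information.
#'
#' @param genotypes a [genotype_matrix].
#' @param marker_id marker to tabulate.
#' @param cases a `case_assignment` from [assign_cases()].
#' @return 2x2 integer matrix with dimnames group x allele.
#' @export
build_table <- function(genotypes, marker_id, cases) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(cases, "case_assignment"))
  j <- match(marker_id, genotypes$marker_ids)
  if (is.na(j)) stop_fmt("marker '%s' not present in the genotype matrix",
                         marker_id)
  idx <- match(cases$assignment$line_id, genotypes$line_ids)
  keep <- !is.na(idx)
  g <- genotypes$calls[idx[keep], j]
  lab <- cases$assignment$label[keep]
  tab <- matrix(c(sum(g == 0L & lab == "IN_CASE", na.rm = TRUE),
                  sum(g == 2L & lab == "IN_CASE", na.rm = TRUE),
                  sum(g == 0L & lab == "NON_CASE", na.rm = TRUE),
                  sum(g == 2L & lab == "NON_CASE", na.rm = TRUE)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("IN_CASE", "NON_CASE"), c("REF", "ALT")))
  tab
}

#' Fisher-scan every marker against a case assignment
#'
#' Runs the two-sided Fisher's exact test on the 2x2 genotype-by-group table
#' of every marker, in input order. Lines present in only one of the two
#' inputs are dropped (with a message reporting how many); missing calls are
#' excluded per marker. The computation is deterministic.
#'
#' @inheritParams build_table
#' @param cache optional environment memoizing p-values across repeated scans
#'   (used by the permutation-FDR machinery).
#' @return data.frame of class `association_result`: `marker_id`, optional
#'   `contig`/`position`, the four cell counts, and `p_nominal`.
#' @export
run_association <- function(genotypes, cases, cache = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(cases, "case_assignment"))
  idx <- match(cases$assignment$line_id, genotypes$line_ids)
  n_unphen <- sum(!genotypes$line_ids %in% cases$assignment$line_id)
  n_ungeno <- sum(is.na(idx))
  if (n_unphen + n_ungeno > 0)
    message(sprintf(
      "run_association: excluding %d ungenotyped and %d unphenotyped line(s)",
      n_ungeno, n_unphen))
  keep <- !is.na(idx)
  calls <- genotypes$calls[idx[keep], , drop = FALSE]
  in_case <- cases$assignment$label[keep] == "IN_CASE"
  case_ref <- colSums(calls[in_case, , drop = FALSE] == 0L, na.rm = TRUE)
  case_alt <- colSums(calls[in_case, , drop = FALSE] == 2L, na.rm = TRUE)
  noncase_ref <- colSums(calls[!in_case, , drop = FALSE] == 0L, na.rm = TRUE)
  noncase_alt <- colSums(calls[!in_case, , drop = FALSE] == 2L, na.rm = TRUE)
  p <- .fisher_p_many(case_ref, case_alt, noncase_ref, noncase_alt,
                      cache = cache)
  res <- data.frame(marker_id = genotypes$marker_ids,
                    case_ref = as.integer(case_ref),
                    case_alt = as.integer(case_alt),
                    noncase_ref = as.integer(noncase_ref),
                    noncase_alt = as.integer(noncase_alt),
                    p_nominal = p, stringsAsFactors = FALSE)
  if (!is.null(genotypes$coords)) {
    res$contig <- genotypes$coords$contig
    res$position <- genotypes$coords$position
    res <- res[, c("marker_id", "contig", "position", "case_ref", "case_alt",
                   "noncase_ref", "noncase_alt", "p_nominal")]
  }
  class(res) <- c("association_result", "data.frame")
  res
}

#' Annotate scanned markers with overlapping genes
#'
#' Labels each marker with every gene whose 1-based inclusive interval
#' contains the marker position (both endpoints inclusive, the GFF/FlyBase
#' convention); markers inside no gene are labeled intergenic (empty string).
#' Markers without coordinates are left unannotated with a warning.
#'
#' @param results an `association_result` carrying `contig` and `position`.
#' @param intervals gene intervals from [read_gene_intervals()].
#' @return `results` with an added `gene_ids` column (comma-joined).
#' @export
annotate_markers <- function(results, intervals) {
  stopifnot(is.data.frame(results),
            all(c("gene_id", "contig", "start", "end") %in% names(intervals)))
  if (!all(c("contig", "position") %in% names(results))) {
    warn_fmt("markers carry no coordinates; skipping gene annotation")
    results$gene_ids <- NA_character_
    return(results)
  }
  results$gene_ids <- vapply(seq_len(nrow(results)), function(i) {
    hit <- intervals$contig == results$contig[i] &
      intervals$start <= results$position[i] &
      intervals$end >= results$position[i]
    paste(intervals$gene_id[hit], collapse = ",")
  }, character(1))
  results
}
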