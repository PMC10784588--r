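# End-to-end drivers: generate a complete synthetic study on disk, run the
# association + permutation-FDR scan, the survival comparison, the DE filter
# and the overlap test, and record a reproducibility manifest. These
# functions are the package's command surface; each is a thin orchestration
# over the module functions and is fully determined by one master seed.

#' Write a key/value manifest
#'
#' Structured text, one `key<TAB>value` per line, used for the ground-truth
#' and run manifests so a study directory is self-describing.
#'
#' @param x named list of scalars (vectors are comma-joined).
#' @param path output path.
#' @export
write_manifest <- function(x, path) {
  stopifnot(length(names(x)) == length(x))
  lines <- vapply(names(x), function(k)
    paste0(k, "\t", paste(format(x[[k]], digits = 17, trim = TRUE,
                                 scientific = FALSE),
                          collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @return [read_manifest()] returns the named list (values as character).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_fmt("manifest not found: %s", path)
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop_fmt("%s: malformed manifest line %d", path,
                         which(bad)[1L])
  vals <- lapply(parts, function(p) strsplit(p[[2L]], ",", fixed = TRUE)[[1L]])
  stats::setNames(vals, vapply(parts, `[[`, character(1), 1L))
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$causal_marker_index <- out$causal_marker_index %||% NA_integer_
  out
}

run_manifest <- function(command, config, out_dir, files) {
  digest <- tools::md5sum(file.path(out_dir, files))
  c(list(command = command,
         tool = paste0("epscan ", as.character(utils::packageVersion("epscan"))),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         master_seed = config$seed),
    stats::setNames(config_as_list(config),
                    paste0("config.", names(config_as_list(config)))),
    stats::setNames(as.list(unname(digest)), paste0("md5.", files)))
}

#' Generate a complete synthetic study on disk
#'
#' Simulates genotypes, per-fly lifespans, per-line median phenotypes, a
#' paired omics matrix and a pair of gene lists, and writes them in the
#' pipeline's file formats together with a ground-truth manifest and a run
#' manifest. All randomness flows from `config$seed` (omics and gene-list
#' substreams are derived from it), so the same configuration reproduces the
#' directory byte-for-byte.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param omics_args named list of overrides for [simulate_omics()].
#' @param gene_list_args named list of overrides for
#'   [simulate_gene_lists()]; defaults give two 120-gene sets sharing 40 of
#'   a 2000-gene universe.
#' @return (invisibly) list with the simulated objects and `paths`.
#' @export
write_study <- function(config, out_dir, omics_args = list(),
                        gene_list_args = list()) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geno <- simulate_genotypes(config)
  life <- simulate_lifespans(geno, config)
  om_args <- utils::modifyList(list(seed = derive_seed(config$seed, 101L)),
                               omics_args)
  om <- do.call(simulate_omics, om_args)
  gl_args <- utils::modifyList(
    list(universe_size = 2000L, size_a = 120L, size_b = 120L, overlap = 40L,
         seed = derive_seed(config$seed, 102L)),
    gene_list_args)
  gl <- do.call(simulate_gene_lists, gl_args)
  paths <- c(genotypes = "genotypes.tsv", phenotypes = "phenotypes.csv",
             deaths = "deaths.csv", expression = "expression.tsv",
             gene_list_a = "genes_a.txt", gene_list_b = "genes_b.txt",
             gene_universe = "gene_universe.txt",
             ground_truth = "ground_truth.txt")
  write_genotypes_tsv(geno, file.path(out_dir, paths["genotypes"]))
  write_phenotypes_csv(life$phenotypes, file.path(out_dir, paths["phenotypes"]))
  write_deaths_csv(life$deaths, file.path(out_dir, paths["deaths"]))
  write_expression_tsv(om$expr, file.path(out_dir, paths["expression"]))
  write_gene_list(gl$set_a, file.path(out_dir, paths["gene_list_a"]))
  write_gene_list(gl$set_b, file.path(out_dir, paths["gene_list_b"]))
  write_gene_list(gl$universe, file.path(out_dir, paths["gene_universe"]))
  write_manifest(list(
    causal_marker_id = life$truth$causal_marker_id,
    causal_carrier_lines = names(life$truth$carrier)[life$truth$carrier],
    de_feature_ids = om$truth$de_feature_ids,
    planted_overlap = length(intersect(gl$set_a, gl$set_b))),
    file.path(out_dir, paths["ground_truth"]))
  write_manifest(run_manifest("simulate", config, out_dir, unname(paths)),
                 file.path(out_dir, "run_manifest.txt"))
  invisible(list(genotypes = geno, lifespans = life, omics = om,
                 gene_lists = gl, paths = paths, out_dir = out_dir))
}

#' Run the full synthetic study end to end
#'
#' Generates a study with [write_study()], then runs every analysis stage:
#' MAF filtering, extreme-phenotype case assignment, the Fisher scan with
#' permutation FDR on the analyzed diet, an association scan on the control
#' diet for the causal marker, a survival comparison of alt-carrier vs
#' reference lines on each diet, the paired DE analysis with the
#' peptide/q/fold-change filter, and the gene-list overlap test. The returned
#' evaluation compares every stage against the planted ground truth.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory for data files and result TSVs.
#' @param diet diet analyzed for association (default `"DR"`).
#' @param maf_min MAF filter threshold (default 0.25).
#' @param mode,top_k,lifespan_threshold dichotomization parameters.
#' @param n_perm permutations for the FDR estimate (default 10).
#' @param fdr_max FDR bound for calling markers (default 0.2).
#' @param omics_args,gene_list_args forwarded to [write_study()].
#' @return list with `study`, `filtered`, `fdr` (the `fdr_curve`), `called`,
#'   `survival` (per-diet carrier-vs-reference log-rank), `de`, `de_selected`,
#'   `overlap`, and `evaluation` (causal marker called?; control-diet p;
#'   DE precision/recall; overlap recovered).
#' @export
run_end_to_end <- function(config, out_dir, diet = "DR", maf_min = 0.25,
                           mode = "top_k", top_k = 25L,
                           lifespan_threshold = 41, n_perm = 10L,
                           fdr_max = 0.2, omics_args = list(),
                           gene_list_args = list()) {
  study <- write_study(config, out_dir, omics_args = omics_args,
                       gene_list_args = gene_list_args)
  other_diet <- setdiff(c("AL", "DR"), diet)
  filtered <- filter_markers(study$genotypes, maf_min = maf_min)
  fdr <- estimate_fdr(filtered, study$lifespans$phenotypes, diet = diet,
                      mode = mode, top_k = top_k,
                      lifespan_threshold = lifespan_threshold,
                      n_perm = n_perm, seed = derive_seed(config$seed, 201L))
  called <- call_significant(fdr$results, fdr, fdr_max = fdr_max)
  write_results_tsv(fdr$results, file.path(out_dir, "association.tsv"))
  write_results_tsv(fdr$curve, file.path(out_dir, "fdr_curve.tsv"))
  write_results_tsv(as.data.frame(fdr$null_counts),
                    file.path(out_dir, "fdr_null_counts.tsv"))

  truth <- study$lifespans$truth
  causal_id <- truth$causal_marker_id
  ctrl_cases <- assign_cases(study$lifespans$phenotypes, diet = other_diet,
                             mode = mode, top_k = top_k,
                             lifespan_threshold = lifespan_threshold)
  ctrl_scan <- run_association(filtered, ctrl_cases)
  causal_p_ctrl <- if (!is.na(causal_id) && causal_id %in% ctrl_scan$marker_id)
    ctrl_scan$p_nominal[ctrl_scan$marker_id == causal_id] else NA_real_

  surv <- list()
  if (!is.na(causal_id) && any(truth$carrier) && !all(truth$carrier)) {
    for (d in c(diet, other_diet)) {
      dd <- study$lifespans$deaths
      dd <- dd[dd$diet == d, , drop = FALSE]
      carrier_rows <- truth$carrier[dd$group_id]
      surv[[d]] <- logrank_test(dd[carrier_rows, , drop = FALSE],
                                dd[!carrier_rows, , drop = FALSE])
    }
  }

  de <- de_analysis(study$omics$expr)
  de_sel <- select_de(de)
  write_results_tsv(de, file.path(out_dir, "de_results.tsv"))
  ov <- overlap_test(study$gene_lists$set_a, study$gene_lists$set_b,
                     study$gene_lists$universe)
  write_results_tsv(data.frame(n_a = ov$n_a, n_b = ov$n_b,
                               n_universe = ov$n_universe,
                               overlap = ov$overlap, p = ov$p,
                               fold_enrichment = ov$fold_enrichment),
                    file.path(out_dir, "overlap.tsv"))

  planted <- study$omics$truth$de_feature_ids
  tp <- sum(de_sel$feature_id %in% planted)
  evaluation <- list(
    causal_marker_id = causal_id,
    causal_called = !is.na(causal_id) && causal_id %in% called,
    n_called = length(called),
    t_star = attr(called, "t_star"),
    causal_p_analyzed_diet = if (!is.na(causal_id) &&
                                 causal_id %in% fdr$results$marker_id)
      fdr$results$p_nominal[fdr$results$marker_id == causal_id] else NA_real_,
    causal_p_control_diet = causal_p_ctrl,
    de_precision = if (nrow(de_sel) > 0) tp / nrow(de_sel) else NA_real_,
    de_recall = if (length(planted) > 0) tp / length(planted) else NA_real_,
    overlap_recovered = ov$overlap)
  write_manifest(evaluation[!vapply(evaluation, is.null, logical(1))],
                 file.path(out_dir, "evaluation.txt"))
  invisible(list(study = study, filtered = filtered, fdr = fdr,
                 called = called, survival = surv, de = de,
                 de_selected = de_sel, overlap = ov,
                 evaluation = evaluation))
}
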