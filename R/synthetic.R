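#' Configuration for a synthetic inbred-panel lifespan study
#'
#' Bundles and validates every parameter of the synthetic-study generator:
#' panel dimensions, allele-frequency range, a single optional causal marker
#' with diet-specific hazard effects, the Gompertz mortality law, cohort size
#' and the death-check schedule. The defaults emulate a dietary-restriction
#' (DR) lifespan screen across ~100 homozygous fly lines scored against an
#' ad libitum (AL) control diet, with deaths recorded every other day when
#' flies are transferred to fresh vials.
#'
#' The causal allele acts multiplicatively on the Gompertz baseline hazard:
#' `effect_dr > 1` with `effect_al = 1` produces an allele that shortens
#' lifespan under DR while leaving AL lifespan untouched — the diet-specific
#' pattern this pipeline is designed to detect. `al_hazard_factor` scales the
#' baseline hazard on the AL diet so that DR extends lifespan panel-wide.
#'
#' @param n_lines number of inbred lines.
#' @param n_markers number of biallelic markers.
#' @param maf_range length-2 numeric, low/high alternate-line frequency; each
#'   marker's frequency is drawn uniformly from this interval, in (0, 0.5].
#' @param missing_rate per-call probability of a missing genotype.
#' @param causal_marker_index column index of the causal marker, or `NULL`
#'   for a fully null panel.
#' @param effect_dr multiplicative hazard factor for alt-carrying lines under
#'   DR (>= 0; 1 = no effect; > 1 shortens lifespan).
#' @param effect_al same under AL (default 1).
#' @param gompertz_baseline_a initial hazard per day on the DR diet.
#' @param gompertz_b exponential hazard growth rate per day.
#' @param al_hazard_factor baseline hazard multiplier on AL relative to DR
#'   (default 2.5, giving the usual DR lifespan extension).
#' @param flies_per_line cohort size per line per diet (default 100).
#' @param check_interval_days death-check interval; recorded death days are
#'   multiples of this (default 2).
#' @param seed master integer seed for the whole study.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_lines = 100L,
                              n_markers = 500L,
                              maf_range = c(0.25, 0.5),
                              missing_rate = 0.02,
                              causal_marker_index = NULL,
                              effect_dr = 1,
                              effect_al = 1,
                              gompertz_baseline_a = 8e-4,
                              gompertz_b = 0.1,
                              al_hazard_factor = 2.5,
                              flies_per_line = 100L,
                              check_interval_days = 2L,
                              seed = 1L) {
  cfg <- list(
    n_lines = check_count(n_lines, "n_lines", min = 1L),
    n_markers = check_count(n_markers, "n_markers", min = 0L),
    maf_range = maf_range,
    missing_rate = check_number(missing_rate, "missing_rate", min = 0, max = 1,
                                strict_max = TRUE),
    causal_marker_index = causal_marker_index,
    effect_dr = check_number(effect_dr, "effect_dr", min = 0),
    effect_al = check_number(effect_al, "effect_al", min = 0),
    gompertz_baseline_a = check_number(gompertz_baseline_a,
                                       "gompertz_baseline_a", min = 0,
                                       strict_min = TRUE),
    gompertz_b = check_number(gompertz_b, "gompertz_b", min = 0),
    al_hazard_factor = check_number(al_hazard_factor, "al_hazard_factor",
                                    min = 0, strict_min = TRUE),
    flies_per_line = check_count(flies_per_line, "flies_per_line", min = 1L),
    check_interval_days = check_count(check_interval_days,
                                      "check_interval_days", min = 1L),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (length(maf_range) != 2L || !is.numeric(maf_range) || anyNA(maf_range) ||
      maf_range[1] <= 0 || maf_range[1] > maf_range[2] || maf_range[2] > 0.5)
    stop_fmt("maf_range must satisfy 0 < low <= high <= 0.5")
  cfg$maf_range <- as.numeric(maf_range)
  if (!is.null(causal_marker_index)) {
    cfg$causal_marker_index <- check_count(causal_marker_index,
                                           "causal_marker_index", min = 1L)
    if (cfg$causal_marker_index > cfg$n_markers)
      stop_fmt("causal_marker_index %d exceeds n_markers = %d",
               cfg$causal_marker_index, cfg$n_markers)
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate homozygous biallelic genotypes
#'
#' Generates an `n_lines x n_markers` panel of homozygous calls. Each marker's
#' alternate-line frequency is drawn uniformly from `maf_range`; each line
#' then carries the alternate allele independently with that frequency, and
#' each call is independently set missing at `missing_rate`. Identical
#' configuration and seed give an identical matrix.
#'
#' @param config a [simulation_config()].
#' @return a [genotype_matrix] with synthetic coordinates (one contig,
#'   markers 1 kb apart).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$n_lines; M <- config$n_markers
  line_ids <- sprintf("line_%03d", seq_len(L))
  marker_ids <- sprintf("m%05d", seq_len(M))
  calls <- with_seed(derive_seed(config$seed, 1L), {
    freq <- stats::runif(M, config$maf_range[1], config$maf_range[2])
    g <- matrix(2L * stats::rbinom(L * M, 1L,
                                   rep(freq, each = L)), nrow = L, ncol = M)
    if (config$missing_rate > 0)
      g[stats::runif(L * M) < config$missing_rate] <- NA_integer_
    g
  })
  coords <- if (M > 0)
    data.frame(marker_id = marker_ids, contig = "chrS",
               position = 1000L * seq_len(M), stringsAsFactors = FALSE)
  else NULL
  genotype_matrix(calls, line_ids = line_ids, marker_ids = marker_ids,
                  coords = coords)
}

#' Simulate per-fly lifespans and per-line median phenotypes
#'
#' For every line and diet, draws `flies_per_line` death times from a Gompertz
#' law with hazard \eqn{a m e^{bt}}, where the multiplier `m` combines the
#' diet baseline (`al_hazard_factor` on AL, 1 on DR) and the causal-allele
#' effect (`effect_dr` or `effect_al`) for lines carrying the alternate call
#' at the causal marker. Death times are rounded UP to the next multiple of
#' `check_interval_days`, emulating flies found dead at the next scheduled
#' vial transfer. A line whose call at the causal marker is missing is treated
#' as reference (no effect).
#'
#' @param genotypes a [genotype_matrix] from [simulate_genotypes()].
#' @param config the same [simulation_config()].
#' @return list with `deaths` (data.frame: `group_id`, `diet`, `death_day`,
#'   `censored`; one row per fly), `phenotypes` (data.frame: `line_id`,
#'   `diet`, `median_lifespan`) and `truth` (causal marker id, alt-carrier
#'   flags, true continuous medians per diet).
#' @export
simulate_lifespans <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "simulation_config"))
  ci <- config$causal_marker_index
  if (!is.null(ci) && ci > length(genotypes$marker_ids))
    stop_fmt("causal_marker_index %d out of range (%d markers)", ci,
             length(genotypes$marker_ids))
  L <- length(genotypes$line_ids)
  carrier <- if (is.null(ci)) rep(FALSE, L) else
    !is.na(genotypes$calls[, ci]) & genotypes$calls[, ci] == 2L
  a <- config$gompertz_baseline_a; b <- config$gompertz_b
  n <- config$flies_per_line; step <- config$check_interval_days
  diets <- c("AL", "DR")
  death_list <- vector("list", 2L * L)
  pheno <- expand.grid(line_id = genotypes$line_ids, diet = diets,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pheno$median_lifespan <- NA_real_
  truth_median <- pheno
  names(truth_median)[3] <- "true_median"
  with_seed(derive_seed(config$seed, 2L), {
    k <- 0L
    for (d in diets) {
      diet_mult <- if (d == "AL") config$al_hazard_factor else 1
      eff <- if (d == "AL") config$effect_al else config$effect_dr
      for (i in seq_len(L)) {
        k <- k + 1L
        mult <- diet_mult * if (carrier[i]) eff else 1
        t_raw <- rgompertz(n, a = a * mult, b = b)
        day <- step * ceiling(t_raw / step)
        day[day < step] <- step  # a death in (0, step] is found at the first check
        death_list[[k]] <- data.frame(group_id = genotypes$line_ids[i],
                                      diet = d, death_day = day,
                                      censored = FALSE,
                                      stringsAsFactors = FALSE)
        row <- pheno$line_id == genotypes$line_ids[i] & pheno$diet == d
        pheno$median_lifespan[row] <- stats::median(day)
        # closed-form continuous median of the scaled Gompertz law
        am <- a * mult
        truth_median$true_median[row] <- if (b == 0) log(2) / am else
          log1p(b * log(2) / am) / b
      }
    }
  })
  deaths <- do.call(rbind, death_list)
  rownames(deaths) <- NULL
  truth <- list(causal_marker_id = if (is.null(ci)) NA_character_ else
                  genotypes$marker_ids[ci],
                causal_marker_index = ci,
                carrier = stats::setNames(carrier, genotypes$line_ids),
                true_medians = truth_median)
  list(deaths = deaths, phenotypes = pheno, truth = truth)
}

#' Simulate a paired log2 abundance matrix with planted fold-changes
#'
#' Builds a feature x sample matrix of log2 abundances for `n_pairs` paired
#' condition/control samples (e.g. replicate pools of knockdown vs control
#' fly heads). The first `n_de` features are shifted by `log2fc_de` in the
#' condition samples; i.i.d. Gaussian noise with standard deviation `sigma`
#' is added throughout. Each feature carries a unique-peptide count; a
#' configurable fraction of non-planted features get a single peptide so the
#' downstream >= 2-peptide evidence filter is exercised (planted features
#' always have >= 2 peptides, so ground truth stays recoverable).
#'
#' @param n_features number of features (protein groups).
#' @param n_pairs number of condition/control pairs.
#' @param n_de number of planted differentially abundant features.
#' @param log2fc_de planted log2 fold-change (condition minus control).
#' @param sigma Gaussian noise SD on the log2 scale.
#' @param frac_single_peptide fraction of non-planted features assigned a
#'   single unique peptide (default 0.1).
#' @param seed integer seed.
#' @return list with `expr` (an `expression_matrix`) and `truth`
#'   (planted feature ids and their true log2 fold-change).
#' @export
simulate_omics <- function(n_features = 200L, n_pairs = 5L, n_de = 20L,
                           log2fc_de = 1, sigma = 0.2,
                           frac_single_peptide = 0.1, seed = 1L) {
  n_features <- check_count(n_features, "n_features", min = 1L)
  n_pairs <- check_count(n_pairs, "n_pairs", min = 2L)
  n_de <- check_count(n_de, "n_de", min = 0L)
  if (n_de > n_features)
    stop_fmt("n_de = %d exceeds n_features = %d", n_de, n_features)
  sigma <- check_number(sigma, "sigma", min = 0)
  frac_single_peptide <- check_number(frac_single_peptide,
                                      "frac_single_peptide", min = 0, max = 1)
  feature_ids <- sprintf("prot_%04d", seq_len(n_features))
  sample_ids <- c(sprintf("cond_p%02d", seq_len(n_pairs)),
                  sprintf("ctrl_p%02d", seq_len(n_pairs)))
  condition <- rep(c("condition", "control"), each = n_pairs)
  pair_id <- rep(sprintf("p%02d", seq_len(n_pairs)), times = 2L)
  out <- with_seed(seed, {
    base <- stats::rnorm(n_features, mean = 20, sd = 2)
    ab <- matrix(rep(base, times = 2L * n_pairs), nrow = n_features)
    if (n_de > 0)
      ab[seq_len(n_de), seq_len(n_pairs)] <-
        ab[seq_len(n_de), seq_len(n_pairs)] + log2fc_de
    ab <- ab + matrix(stats::rnorm(length(ab), sd = sigma), nrow = n_features)
    pept <- 1L + stats::rbinom(n_features, 9L, 0.4)  # 2..10 peptides
    pept <- pmax(pept, 2L)
    nonde <- setdiff(seq_len(n_features), seq_len(n_de))
    n_single <- round(frac_single_peptide * length(nonde))
    if (n_single > 0)
      pept[nonde[sample.int(length(nonde), n_single)]] <- 1L
    list(ab = ab, pept = pept)
  })
  dimnames(out$ab) <- list(feature_ids, sample_ids)
  expr <- expression_matrix(out$ab, condition = condition, pair_id = pair_id,
                            unique_peptides = out$pept)
  truth <- list(de_feature_ids = feature_ids[seq_len(n_de)],
                true_log2fc = rep(log2fc_de, n_de))
  list(expr = expr, truth = truth)
}

#' Simulate two gene lists with a controlled overlap
#'
#' Draws a universe of `universe_size` gene identifiers and two subsets of the
#' requested sizes sharing exactly `overlap` identifiers, for exercising the
#' hypergeometric overlap test with known ground truth.
#'
#' @param universe_size number of genes in the universe.
#' @param size_a,size_b sizes of the two sets.
#' @param overlap exact number of shared identifiers.
#' @param seed integer seed.
#' @return list with character vectors `set_a`, `set_b`, `universe`.
#' @export
simulate_gene_lists <- function(universe_size, size_a, size_b, overlap,
                                seed = 1L) {
  universe_size <- check_count(universe_size, "universe_size", min = 0L)
  size_a <- check_count(size_a, "size_a", min = 0L)
  size_b <- check_count(size_b, "size_b", min = 0L)
  overlap <- check_count(overlap, "overlap", min = 0L)
  if (size_a > universe_size || size_b > universe_size)
    stop_fmt("set sizes (%d, %d) exceed universe size %d", size_a, size_b,
             universe_size)
  if (overlap > min(size_a, size_b))
    stop_fmt("overlap %d exceeds the smaller set size %d", overlap,
             min(size_a, size_b))
  if (size_a + size_b - overlap > universe_size)
    stop_fmt("sets of sizes %d and %d with overlap %d cannot fit in a universe of %d",
             size_a, size_b, overlap, universe_size)
  universe <- sprintf("gene_%05d", seq_len(universe_size))
  with_seed(seed, {
    pool <- sample(universe)
    shared <- pool[seq_len(overlap)]
    rest <- if (overlap > 0) pool[-seq_len(overlap)] else pool
    a_only <- rest[seq_len(size_a - overlap)]
    b_only <- rest[size_a - overlap + seq_len(size_b - overlap)]
    list(set_a = sort(c(shared, a_only)),
         set_b = sort(c(shared, b_only)),
         universe = universe)
  })
}
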