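# Readers and writers for the pipeline's tabular formats. Every reader
# validates structure and reports malformed input with the offending row or
# column; every writer/read pair is an identity on valid data.

#' Read a genotype TSV
#'
#' Tab-separated genotype table: header row `line_id` followed by marker ids;
#' one row per line; cells `0` (hom. reference), `2` (hom. alternate) or `NA`
#' (missing).
#'
#' @param path file path.
#' @return a [genotype_matrix].
#' @export
read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop_fmt("genotype file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop_fmt("%s: empty genotype file", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (length(header) < 1L || header[1L] != "line_id")
    stop_fmt("%s: first header field must be 'line_id'", path)
  marker_ids <- header[-1L]
  ncol_exp <- length(header)
  body <- cells[-1L]
  n <- length(body)
  calls <- matrix(NA_integer_, nrow = n, ncol = length(marker_ids))
  line_ids <- character(n)
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != ncol_exp)
      stop_fmt("%s: row %d has %d fields, expected %d", path, i + 1L,
               length(row), ncol_exp)
    line_ids[i] <- row[1L]
    vals <- row[-1L]
    bad <- !(vals %in% c("0", "2", "NA"))
    if (any(bad))
      stop_fmt("%s: row %d ('%s'), column '%s': invalid genotype token '%s'",
               path, i + 1L, row[1L], marker_ids[which(bad)[1L]],
               vals[which(bad)[1L]])
    calls[i, ] <- suppressWarnings(as.integer(vals))
  }
  if (anyDuplicated(line_ids))
    stop_fmt("%s: duplicate line id '%s'", path,
             line_ids[duplicated(line_ids)][1L])
  genotype_matrix(calls, line_ids = line_ids, marker_ids = marker_ids)
}

#' Write a genotype TSV
#'
#' Inverse of [read_genotypes_tsv()]; round-trips exactly. Coordinates, if
#' present, are not stored in this format.
#'
#' @param geno a [genotype_matrix].
#' @param path output path.
#' @export
write_genotypes_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  header <- paste(c("line_id", geno$marker_ids), collapse = "\t")
  body <- vapply(seq_along(geno$line_ids), function(i) {
    paste(c(geno$line_ids[i],
            ifelse(is.na(geno$calls[i, ]), "NA",
                   as.character(geno$calls[i, ]))), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read homozygous genotypes from a VCF
#'
#' Parses the GT field of a VCF into a [genotype_matrix] under the
#' homozygous-only rule: `0/0` maps to reference, `1/1` (or phased `1|1`) to
#' alternate, and missing (`./.`) or heterozygous (`0/1`, `1/0`) calls to
#' missing — inbred panels are homozygous, so a residual heterozygous call
#' carries no usable information here. Multi-allelic records are skipped with
#' a warning. Positions are stored 1-based as in the VCF.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return a [genotype_matrix] with coordinates.
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop_fmt("VCF not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop_fmt("%s: VCF contains no records", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warn_fmt("%s: skipping %d multi-allelic record(s) (e.g. %s:%s)", path,
             sum(multi), fix$CHROM[multi][1L], fix$POS[multi][1L])
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  marker_ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                       paste0(fix$CHROM, "_", fix$POS), fix$ID)
  core <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  calls[t(core == "0/0")] <- 0L
  calls[t(core == "1/1")] <- 2L
  genotype_matrix(calls, line_ids = colnames(gt), marker_ids = marker_ids,
                  coords = data.frame(marker_id = marker_ids,
                                      contig = fix$CHROM,
                                      position = as.integer(fix$POS),
                                      stringsAsFactors = FALSE))
}

#' Read per-line median lifespan phenotypes
#'
#' CSV with header `line_id,diet,median_lifespan`; diet in \{AL, DR\};
#' lifespans positive; one row per (line, diet).
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_phenotypes_csv <- function(path) {
  df <- read_named_csv(path, c("line_id", "diet", "median_lifespan"))
  df$median_lifespan <- parse_numeric_col(df$median_lifespan,
                                          "median_lifespan", path)
  check_diet_col(df$diet, path)
  if (any(df$median_lifespan <= 0))
    stop_fmt("%s: non-positive median_lifespan in row %d", path,
             which(df$median_lifespan <= 0)[1L] + 1L)
  key <- paste(df$line_id, df$diet)
  if (anyDuplicated(key))
    stop_fmt("%s: duplicate (line_id, diet) pair '%s'", path,
             key[duplicated(key)][1L])
  df
}

#' Read per-fly death records
#'
#' CSV with header `group_id,diet,death_day,censored`; `death_day` positive;
#' `censored` 0/1 or TRUE/FALSE (a censored record carries the last observed
#' day).
#'
#' @param path file path.
#' @return data.frame with those columns (`censored` logical).
#' @export
read_deaths_csv <- function(path) {
  df <- read_named_csv(path, c("group_id", "diet", "death_day", "censored"))
  df$death_day <- parse_numeric_col(df$death_day, "death_day", path)
  check_diet_col(df$diet, path)
  if (any(df$death_day <= 0))
    stop_fmt("%s: non-positive death_day in row %d", path,
             which(df$death_day <= 0)[1L] + 1L)
  cen <- df$censored
  ok <- cen %in% c("0", "1", "TRUE", "FALSE", "true", "false")
  if (any(!ok))
    stop_fmt("%s: invalid censored flag '%s' in row %d", path,
             cen[!ok][1L], which(!ok)[1L] + 1L)
  df$censored <- cen %in% c("1", "TRUE", "true")
  df
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines ignored; duplicates removed
#' (first occurrence kept, order preserved).
#'
#' @param path file path.
#' @return character vector of unique identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_fmt("gene list not found: %s", path)
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids)]
  unique(ids)
}

#' Write a plain-text gene list
#' @param ids character vector of identifiers.
#' @param path output path.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Read gene intervals from BED or GFF3
#'
#' Accepts BED (0-based half-open) or GFF3 (1-based inclusive), dispatching on
#' the file extension, and normalizes to the internal 1-based inclusive
#' convention used for marker annotation. Gene identifiers come from the BED
#' name column or the GFF `ID`/`Name` attribute.
#'
#' @param path `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @return data.frame with columns `gene_id`, `contig`, `start`, `end`
#'   (1-based inclusive, `start <= end`).
#' @export
read_gene_intervals <- function(path) {
  if (!file.exists(path)) stop_fmt("interval file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("bed", "gff", "gff3", "gtf"))
    stop_fmt("%s: unsupported interval format '.%s' (use BED or GFF3)",
             path, ext)
  gr <- rtracklayer::import(path)  # rtracklayer yields 1-based inclusive ranges
  meta <- S4Vectors::mcols(gr)
  gene_id <- if ("name" %in% names(meta)) as.character(meta$name)
    else if ("ID" %in% names(meta) && !all(is.na(meta$ID))) as.character(meta$ID)
    else if ("Name" %in% names(meta)) as.character(meta$Name)
    else if ("gene_id" %in% names(meta)) as.character(meta$gene_id)
    else stop_fmt("%s: no gene identifier column found", path)
  out <- data.frame(gene_id = gene_id,
                    contig = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$gene_id) | !nzchar(out$gene_id)))
    stop_fmt("%s: record %d has no gene identifier", path,
             which(is.na(out$gene_id) | !nzchar(out$gene_id))[1L])
  if (any(out$start > out$end))
    stop_fmt("%s: record %d has start > end", path,
             which(out$start > out$end)[1L])
  out
}

#' Write gene intervals as BED
#'
#' Converts the internal 1-based inclusive intervals back to BED's 0-based
#' half-open convention; [read_gene_intervals()] of the result is an identity.
#'
#' @param intervals data.frame as returned by [read_gene_intervals()].
#' @param path output `.bed` path.
#' @export
write_gene_intervals_bed <- function(intervals, path) {
  stopifnot(all(c("gene_id", "contig", "start", "end") %in% names(intervals)))
  df <- data.frame(intervals$contig, intervals$start - 1L, intervals$end,
                   intervals$gene_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Generic tab-separated writer used for association, FDR, survival, DE and
#' overlap outputs; `NA` is written as the literal `NA`.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_results_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a phenotype CSV (inverse of [read_phenotypes_csv()])
#' @param phenotypes data.frame with `line_id`, `diet`, `median_lifespan`.
#' @param path output path.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  utils::write.csv(phenotypes[, c("line_id", "diet", "median_lifespan")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a death-record CSV (inverse of [read_deaths_csv()])
#' @param deaths data.frame with `group_id`, `diet`, `death_day`, `censored`.
#' @param path output path.
#' @export
write_deaths_csv <- function(deaths, path) {
  df <- deaths[, c("group_id", "diet", "death_day", "censored")]
  df$censored <- as.integer(df$censored)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- internal CSV helpers -----------------------------------------------------

read_named_csv <- function(path, required) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_fmt("%s: missing required column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  df[, required, drop = FALSE]
}

parse_numeric_col <- function(x, name, path) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out))
    stop_fmt("%s: non-numeric '%s' value '%s' in row %d", path, name,
             x[which(is.na(out))[1L]], which(is.na(out))[1L] + 1L)
  out
}

check_diet_col <- function(diet, path) {
  bad <- !diet %in% c("AL", "DR")
  if (any(bad))
    stop_fmt("%s: invalid diet '%s' in row %d (allowed: AL, DR)", path,
             diet[bad][1L], which(bad)[1L] + 1L)
  invisible(TRUE)
}
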