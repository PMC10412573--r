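# Cohort container, TSV readers/writers, probe filtering, BED output.

#' Construct a methylation cohort
#'
#' Bundles the aligned per-sample tables of one cohort: methylation
#' beta-values, categorical covariates, drug response AUCs and (optionally)
#' normalized gene expression. All tables are sample-by-variable tibbles
#' whose first column is `sample_id`; on construction samples are
#' intersected across the supplied tables and reordered identically.
#'
#' @param beta tibble of methylation beta-values in `[0, 1]` (`sample_id`
#'   plus one column per probe; `NA` allowed).
#' @param covariates tibble with columns `sample_id`, `cancer_type`,
#'   `medium` (screening medium), `growth` (growth properties) and `msi`
#'   (microsatellite instability status).
#' @param auc tibble of drug response AUC values in `(0, 1]` (`sample_id`
#'   plus one column per drug), or `NULL` for cohorts without drug data.
#' @param expression tibble of normalized expression (`sample_id` plus one
#'   column per gene), or `NULL`.
#' @param manifest probe manifest tibble as returned by
#'   [read_probe_manifest()]; probes in `beta` absent from the manifest are
#'   dropped with a message.
#' @param genes optional gene annotation tibble (`gene`, `chromosome`,
#'   `tss`, `strand`).
#' @param cohort_tag short label (e.g. `"cell_lines"`, `"tumours"`).
#' @returns A `pharmaco_cohort` object (a named list of aligned tibbles).
#' @export
pharmaco_cohort <- function(beta, covariates, auc = NULL, expression = NULL,
                            manifest = NULL, genes = NULL,
                            cohort_tag = "cell_lines") {
  stopifnot(is.data.frame(beta), is.data.frame(covariates))
  bm <- as.matrix(beta[setdiff(names(beta), "sample_id")])
  bad <- which(!is.na(bm) & (bm < 0 | bm > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "beta value %.4g outside [0, 1] for probe '%s', sample '%s'",
      bm[bad[1, , drop = FALSE]],
      colnames(bm)[bad[1, 2]], beta$sample_id[bad[1, 1]]))
  }
  if (!is.null(manifest)) {
    probes <- setdiff(names(beta), "sample_id")
    known <- probes %in% manifest$probe_id
    if (any(!known)) {
      inform(sprintf("dropping %d beta probe(s) absent from the manifest",
                     sum(!known)))
      beta <- beta[c("sample_id", probes[known])]
    }
  }
  ids <- list(beta$sample_id, covariates$sample_id)
  if (!is.null(auc)) ids <- c(ids, list(auc$sample_id))
  if (!is.null(expression)) ids <- c(ids, list(expression$sample_id))
  common <- Reduce(intersect, ids)
  if (length(common) == 0) abort("no samples shared across cohort tables")
  align <- function(tbl) tbl[match(common, tbl$sample_id), , drop = FALSE]
  structure(
    list(beta = as_tibble(align(beta)),
         covariates = as_tibble(align(covariates)),
         auc = if (is.null(auc)) NULL else as_tibble(align(auc)),
         expression = if (is.null(expression)) NULL
                      else as_tibble(align(expression)),
         manifest = manifest,
         genes = genes,
         cohort_tag = cohort_tag),
    class = "pharmaco_cohort")
}

#' @export
print.pharmaco_cohort <- function(x, ...) {
  cat(sprintf("<pharmaco_cohort '%s'>\n", x$cohort_tag))
  cat(sprintf("  samples:    %d\n", nrow(x$beta)))
  cat(sprintf("  probes:     %d\n", ncol(x$beta) - 1L))
  cat(sprintf("  drugs:      %s\n",
              if (is.null(x$auc)) "none" else ncol(x$auc) - 1L))
  cat(sprintf("  expression: %s\n",
              if (is.null(x$expression)) "none"
              else sprintf("%d genes", ncol(x$expression) - 1L)))
  invisible(x)
}

#' Sample identifiers of a cohort
#' @param cohort a `pharmaco_cohort`.
#' @returns Character vector of aligned sample ids.
#' @export
cohort_samples <- function(cohort) cohort$beta$sample_id

#' Read a probe manifest
#'
#' Reads the tab-separated probe annotation (one row per array probe) and
#' derives 0-based half-open single-base intervals from the 1-based
#' `position` column, so that a probe at position P occupies `[P-1, P)`.
#'
#' Expected columns: `probe_id`, `chromosome`, `position` (1-based),
#' `gene` (may be empty), `feature` (one of TSS200, TSS1500, UTR5,
#' FirstExon, Body, UTR3, Intergenic), and logical flags `cgi`, `dhs`,
#' `enhancer`, `cross_reactive`.
#'
#' @param path path to the manifest TSV.
#' @returns A tibble sorted by chromosome and position with added `start`
#'   and `end` columns (0-based half-open).
#' @export
read_probe_manifest <- function(path) {
  man <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("probe_id", "chromosome", "position", "gene", "feature",
                "cgi", "dhs", "enhancer", "cross_reactive")
  missing <- setdiff(required, names(man))
  if (length(missing) > 0) {
    abort(paste0("manifest lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(man$probe_id)) abort("duplicate probe_id in manifest")
  if (any(man$position < 1)) abort("manifest positions must be >= 1")
  man$gene <- ifelse(is.na(man$gene), "", man$gene)
  for (cl in c("cgi", "dhs", "enhancer", "cross_reactive")) {
    man[[cl]] <- as.logical(man[[cl]])
  }
  man$start <- man$position - 1L
  man$end <- man$position
  dplyr::arrange(as_tibble(man), .data$chromosome, .data$position)
}

read_sample_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# beta TSVs keep probes as rows (probe_id + one column per sample),
# matching the array-export convention; transpose to sample-major.
read_beta_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(raw[-1])
  rownames(m) <- raw[[1]]
  matrix_to_tbl(t(m))
}

write_beta_tsv <- function(beta, path) {
  m <- t(tbl_to_matrix(beta))
  out <- dplyr::bind_cols(tibble(probe_id = rownames(m)), as_tibble(m))
  readr::write_tsv(out, path, progress = FALSE)
}

#' Load a cohort from TSV files
#'
#' Reads the beta matrix (probes as rows), probe manifest, AUC table,
#' covariates and optional expression matrix, intersects samples across
#' tables and aligns their order.
#'
#' @param beta_path probes-by-samples beta TSV (`probe_id` first column).
#' @param manifest_path probe manifest TSV (see [read_probe_manifest()]).
#' @param auc_path samples-by-drugs AUC TSV (`sample_id` first column).
#' @param covariate_path covariate TSV (`sample_id`, `cancer_type`,
#'   `medium`, `growth`, `msi`).
#' @param expression_path optional samples-by-genes expression TSV.
#' @param genes_path optional gene annotation TSV (`gene`, `chromosome`,
#'   `tss`, `strand`).
#' @param cohort_tag cohort label.
#' @returns A [pharmaco_cohort()] with the manifest attached.
#' @export
load_cohort <- function(beta_path, manifest_path, auc_path, covariate_path,
                        expression_path = NULL, genes_path = NULL,
                        cohort_tag = "cell_lines") {
  manifest <- read_probe_manifest(manifest_path)
  beta <- read_beta_tsv(beta_path)
  auc <- read_sample_table(auc_path)
  covariates <- read_sample_table(covariate_path)
  expression <- if (is.null(expression_path)) NULL
                else read_sample_table(expression_path)
  genes <- if (is.null(genes_path)) NULL else read_sample_table(genes_path)
  pharmaco_cohort(beta, covariates, auc = auc, expression = expression,
                  manifest = manifest, genes = genes, cohort_tag = cohort_tag)
}

#' Remove unreliable probes from a cohort
#'
#' Drops probes on the sex chromosomes, caller-supplied blacklisted probes
#' and probes flagged cross-reactive in the manifest. A probe matching
#' several reasons is counted once, under the first matching reason in the
#' order: `cross_reactive`, `blacklist`, `sex_chromosome`.
#'
#' @param cohort a `pharmaco_cohort` with a manifest attached.
#' @param drop_sex drop probes on chromosomes X and Y (default `TRUE`).
#' @param blacklist character vector of probe ids to drop.
#' @returns The reduced cohort; removal counts by reason are attached as
#'   attribute `"removed"` and reported with a message.
#' @export
filter_probes <- function(cohort, drop_sex = TRUE, blacklist = character()) {
  man <- cohort$manifest
  if (is.null(man)) abort("cohort has no manifest; load one first")
  probes <- setdiff(names(cohort$beta), "sample_id")
  man <- man[match(probes, man$probe_id), , drop = FALSE]
  cross <- !is.na(man$cross_reactive) & man$cross_reactive
  black <- probes %in% blacklist & !cross
  sex <- drop_sex & man$chromosome %in% c("chrX", "chrY", "X", "Y") &
    !cross & !black
  drop <- cross | black | sex
  if (all(drop)) abort("probe filtering removed every probe")
  removed <- c(cross_reactive = sum(cross), blacklist = sum(black),
               sex_chromosome = sum(sex))
  if (any(drop)) {
    inform(sprintf(
      "filter_probes: removed %d probe(s) (cross_reactive %d, blacklist %d, sex_chromosome %d)",
      sum(drop), removed[["cross_reactive"]], removed[["blacklist"]],
      removed[["sex_chromosome"]]))
  }
  cohort$beta <- cohort$beta[c("sample_id", probes[!drop])]
  cohort$manifest <- cohort$manifest[
    cohort$manifest$probe_id %in% probes[!drop] |
      !(cohort$manifest$probe_id %in% probes), , drop = FALSE]
  attr(cohort, "removed") <- removed
  cohort
}

#' Write a cohort to a directory of TSV files
#'
#' Inverse of [load_cohort()]: writes `beta.tsv` (probes as rows),
#' `manifest.tsv`, `auc.tsv`, `covariates.tsv` and, when present,
#' `expression.tsv` and `genes.tsv`. Output is deterministic: identical
#' cohorts produce byte-identical files.
#'
#' @param cohort a `pharmaco_cohort`.
#' @param dir output directory (created if needed).
#' @returns Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_tsv(cohort$beta, file.path(dir, "beta.tsv"))
  man <- cohort$manifest
  if (!is.null(man)) {
    readr::write_tsv(man[setdiff(names(man), c("start", "end"))],
                     file.path(dir, "manifest.tsv"), progress = FALSE)
  }
  readr::write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"),
                   progress = FALSE)
  if (!is.null(cohort$auc)) {
    readr::write_tsv(cohort$auc, file.path(dir, "auc.tsv"), progress = FALSE)
  }
  if (!is.null(cohort$expression)) {
    readr::write_tsv(cohort$expression, file.path(dir, "expression.tsv"),
                     progress = FALSE)
  }
  if (!is.null(cohort$genes)) {
    readr::write_tsv(cohort$genes, file.path(dir, "genes.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Write called regions as BED6 and TSV
#'
#' The BED file is 0-based half-open with `name = drug:cancer_type`,
#' `score = min(1000, round(-10 * log10(sidak_p)))` and strand `"."`.
#' The TSV carries every dDMR field (probe id lists comma-joined).
#'
#' @param ddmrs dDMR tibble (as in [call_ddmrs()] output).
#' @param bed_path output BED path.
#' @param tsv_path output TSV path.
#' @returns Invisibly, a list with both paths.
#' @export
write_ddmr_outputs <- function(ddmrs, bed_path, tsv_path) {
  flat <- ddmrs
  if (nrow(flat) > 0) {
    flat$probe_ids <- vapply(flat$probe_ids, paste, character(1),
                             collapse = ",")
    score <- pmin(1000, round(-10 * log10(pmax(flat$sidak_p, 1e-300))))
    bed <- tibble(chrom = flat$chrom, start = flat$start, end = flat$end,
                  name = paste0(flat$drug, ":", flat$cancer_type),
                  score = as.integer(score), strand = ".")
  } else {
    flat$probe_ids <- character(0)
    bed <- tibble(chrom = character(0), start = integer(0), end = integer(0),
                  name = character(0), score = integer(0),
                  strand = character(0))
  }
  readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  readr::write_tsv(flat, tsv_path, progress = FALSE)
  invisible(list(bed = bed_path, tsv = tsv_path))
}
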