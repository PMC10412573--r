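# Genetic-alteration association scans and enrichment statistics
# (one-sided hypergeometric / Fisher, binomial signature test, BH).

#' Binarise mutation and copy-number calls into an alteration matrix
#'
#' Builds one binary column per gene mutation and per gene
#' amplification/deletion, dropping features altered in fewer than
#' `min_altered` samples (i.e. keeping only alterations seen in more than
#' three cell lines at the default).
#'
#' @param mutation_calls long tibble (`sample_id`, `gene`) of coding
#'   mutations.
#' @param cna_calls long tibble (`sample_id`, `gene`, `type`) with `type`
#'   in `"amp"` / `"del"`, or `NULL`.
#' @param samples character vector fixing the sample universe and order.
#' @param min_altered minimum altered samples per retained feature.
#' @returns Samples-by-features tibble (`sample_id` first column) with a
#'   `"features"` attribute tibble (`feature`, `gene`, `type`).
#' @export
binarize_alterations <- function(mutation_calls, cna_calls = NULL, samples,
                                 min_altered = 4) {
  feats <- list()
  meta <- list()
  add_feature <- function(name, gene, type, altered) {
    v <- as.integer(samples %in% altered)
    if (sum(v) < min_altered) return(invisible())
    feats[[name]] <<- v
    meta[[name]] <<- tibble(feature = name, gene = gene, type = type)
    invisible()
  }
  if (!is.null(mutation_calls) && nrow(mutation_calls) > 0) {
    for (g in sort(unique(mutation_calls$gene))) {
      add_feature(paste0(g, "_mut"), g, "mutation",
                  mutation_calls$sample_id[mutation_calls$gene == g])
    }
  }
  if (!is.null(cna_calls) && nrow(cna_calls) > 0) {
    for (ty in c("amp", "del")) {
      sub <- cna_calls[cna_calls$type == ty, , drop = FALSE]
      for (g in sort(unique(sub$gene))) {
        add_feature(paste0(g, "_", ty), g, ty,
                    sub$sample_id[sub$gene == g])
      }
    }
  }
  out <- dplyr::bind_cols(tibble(sample_id = samples), as_tibble(feats))
  attr(out, "features") <- if (length(meta) > 0) dplyr::bind_rows(meta)
                           else tibble(feature = character(0),
                                       gene = character(0),
                                       type = character(0))
  out
}

#' Region-by-feature univariate association scan
#'
#' Fits, for every (feature, region) pair, the univariate OLS of
#' region-mean methylation on the feature (binary alteration status or a
#' continuous gene effect), with a two-sided t-test on the slope and
#' Benjamini-Hochberg adjustment across all tests in the scan.
#' Zero-variance features are skipped with a message.
#'
#' @param region_beta samples-by-regions tibble (`sample_id` first) of
#'   region-mean beta values.
#' @param features samples-by-features tibble (`sample_id` first).
#' @returns Tibble with `feature`, `region`, `slope`, `t_stat`, `p`,
#'   `bh_adjusted_p`.
#' @export
feature_association_scan <- function(region_beta, features) {
  rb <- tbl_to_matrix(region_beta)
  fm <- tbl_to_matrix(features)
  stopifnot(nrow(rb) == nrow(fm))
  keep <- apply(fm, 2, function(x) var(x, na.rm = TRUE) > 0)
  if (any(!keep)) {
    inform(sprintf("feature_association_scan: skipping %d zero-variance feature(s)",
                   sum(!keep)))
    fm <- fm[, keep, drop = FALSE]
  }
  rows <- list()
  for (f in colnames(fm)) {
    x <- fm[, f]
    for (rg in colnames(rb)) {
      y <- rb[, rg]
      use <- !is.na(x) & !is.na(y)
      n <- sum(use)
      if (n < 3 || var(x[use]) == 0) next
      fit <- ols_fit(cbind(`(Intercept)` = 1, feature = x[use]), y[use])
      if (!fit$ok) next
      rows[[length(rows) + 1]] <- tibble(
        feature = f, region = rg, slope = unname(fit$coef["feature"]),
        t_stat = unname(fit$t["feature"]), p = unname(fit$p["feature"]),
        n_used = n)
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble(feature = character(0), region = character(0),
           slope = numeric(0), t_stat = numeric(0), p = numeric(0),
           n_used = integer(0))
  out$bh_adjusted_p <- p.adjust(out$p, method = "BH")
  out
}

#' One-sided Fisher / hypergeometric enrichment test
#'
#' Tests over-representation ("greater") of an annotation within a set
#' against its background via the exact hypergeometric tail, reporting
#' the sample odds ratio of the 2x2 table.
#'
#' @param in_set_and_annotated annotated members of the set.
#' @param in_set_total size of the set.
#' @param background_annotated annotated members of the background (which
#'   contains the set).
#' @param background_total size of the background.
#' @returns One-row tibble with `odds_ratio` and `p` (degenerate margins
#'   give `p = 1` and `NA` odds ratio).
#' @export
fisher_enrichment <- function(in_set_and_annotated, in_set_total,
                              background_annotated, background_total) {
  a <- in_set_and_annotated
  b <- in_set_total - a
  c_ <- background_annotated - a
  d <- (background_total - background_annotated) - b
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  if (in_set_total == 0 || background_annotated == 0 ||
      background_annotated == background_total) {
    return(tibble(odds_ratio = NA_real_, p = 1))
  }
  p <- phyper(a - 1, background_annotated,
              background_total - background_annotated, in_set_total,
              lower.tail = FALSE)
  or <- if (b > 0 && c_ > 0) (a * d) / (b * c_) else Inf
  tibble(odds_ratio = or, p = p)
}

#' Drug-class enrichment per cancer type
#'
#' For each (cancer type, drug class) pair, a one-sided hypergeometric
#' test of whether drugs with at least one called dDMR in that cancer
#' type over-represent the class, with the universe restricted to the
#' drugs screened in that cancer type and BH adjustment across all pairs.
#'
#' @param hits tibble (`cancer_type`, `drug`) of drugs with >= 1 dDMR.
#' @param universe tibble (`cancer_type`, `drug`) of all screened drugs.
#' @param class_membership tibble (`class`, `drug`).
#' @returns Tibble with `cancer_type`, `class`, counts, `odds_ratio`,
#'   `p`, `fdr`.
#' @export
drug_class_enrichment <- function(hits, universe, class_membership) {
  rows <- list()
  for (ct in sort(unique(universe$cancer_type))) {
    uni <- unique(universe$drug[universe$cancer_type == ct])
    hit <- intersect(unique(hits$drug[hits$cancer_type == ct]), uni)
    for (cl in sort(unique(class_membership$class))) {
      members <- intersect(
        unique(class_membership$drug[class_membership$class == cl]), uni)
      if (length(members) == 0) next
      k <- length(intersect(hit, members))
      ft <- fisher_enrichment(k, length(hit), length(members), length(uni))
      rows[[length(rows) + 1]] <- tibble(
        cancer_type = ct, class = cl, n_hits = length(hit),
        n_class_in_universe = length(members), n_universe = length(uni),
        n_class_hits = k, odds_ratio = ft$odds_ratio, p = ft$p)
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble(cancer_type = character(0), class = character(0),
           n_hits = integer(0), n_class_in_universe = integer(0),
           n_universe = integer(0), n_class_hits = integer(0),
           odds_ratio = numeric(0), p = numeric(0))
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}

#' Binomial enrichment of genes in signature hits
#'
#' For each gene, a one-sided binomial tail test of its signature hit
#' count against the background hit rate estimated from all genes, with
#' BH adjustment across genes.
#'
#' @param signature_hits tibble (`gene`, `n_hits`) of per-gene counts of
#'   signatures containing the gene.
#' @param n_signatures total number of signatures (> 0).
#' @param background_rate optional fixed background success probability;
#'   by default estimated as `sum(n_hits) / (n_genes * n_signatures)`.
#' @returns Tibble with `gene`, `n_hits`, `p`, `fdr`.
#' @export
signature_enrichment <- function(signature_hits, n_signatures,
                                 background_rate = NULL) {
  if (n_signatures <= 0) abort("n_signatures must be positive")
  p0 <- background_rate %||%
    (sum(signature_hits$n_hits) / (nrow(signature_hits) * n_signatures))
  p <- pbinom(signature_hits$n_hits - 1, n_signatures, p0,
              lower.tail = FALSE)
  tibble(gene = signature_hits$gene, n_hits = signature_hits$n_hits,
         p = p, fdr = p.adjust(p, method = "BH"))
}
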