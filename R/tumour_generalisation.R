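# Tumour-cohort replication of methylation-expression links (tgdDMRs) and
# cross-cohort effect-size concordance.

#' Replicate methylation-expression links in a tumour cohort
#'
#' Reruns the M/U grouping, Mann-Whitney link test and permutation
#' empirical adjustment on an independent cohort (typically primary
#' tumours, which carry no drug response data). A candidate link becomes a
#' tumour-generalisable dDMR (tgdDMR) when it is significant in both
#' cohorts with the same direction of the methylation-expression
#' association. Cohorts with fewer than `min_cohort` samples are skipped
#' with a warning (mirroring the exclusion of small tumour cohorts).
#'
#' @param candidate_links `link_result` (or its `links` tibble) from the
#'   discovery cohort; only its significant links are re-tested.
#' @param tumour_cohort a [pharmaco_cohort()] with beta and expression.
#' @param n_permutations,emp_adj_cut,seed see [empirical_adjust()].
#' @param min_cohort minimum tumour sample count (default 8).
#' @param fraction,min_group see [define_mu_groups()].
#' @returns Object of class `tgddmr_result` with a `links` tibble: the
#'   candidate links plus tumour-side `mwu_p_tumour`,
#'   `direction_tumour`, `emp_adj_p_tumour`, `pearson_r_tumour` and the
#'   logical `tgddmr`.
#' @export
replicate_links <- function(candidate_links, tumour_cohort,
                            n_permutations = 50000, emp_adj_cut = 0.001,
                            min_cohort = 8, seed = 1, fraction = 0.2,
                            min_group = 4) {
  if (inherits(candidate_links, "link_result")) {
    candidate_links <- candidate_links$links
  }
  cand <- candidate_links[candidate_links$significant, , drop = FALSE]
  empty <- dplyr::bind_cols(
    cand[0, ], tibble(mwu_p_tumour = numeric(0),
                      direction_tumour = integer(0),
                      emp_p_tumour = numeric(0),
                      emp_adj_p_tumour = numeric(0),
                      pearson_r_tumour = numeric(0), tgddmr = logical(0)))
  n_tum <- nrow(tumour_cohort$beta)
  if (n_tum < min_cohort) {
    warn(sprintf("tumour cohort has %d samples (< %d); skipped",
                 n_tum, min_cohort))
    return(structure(list(links = empty), class = "tgddmr_result"))
  }
  if (nrow(cand) == 0) {
    return(structure(list(links = empty), class = "tgddmr_result"))
  }
  bm <- tbl_to_matrix(tumour_cohort$beta)
  em <- tbl_to_matrix(tumour_cohort$expression)

  rows <- list()
  for (i in seq_len(nrow(cand))) {
    probes <- intersect(cand$probe_ids[[i]] %||% character(0), colnames(bm))
    if (length(probes) == 0 || !(cand$gene[i] %in% colnames(em))) {
      inform(sprintf(
        "replicate_links: link %s-%s skipped (missing probes or gene in tumour cohort)",
        cand$region_id[i], cand$gene[i]))
      next
    }
    rm_beta <- rowMeans(bm[, probes, drop = FALSE], na.rm = TRUE)
    groups <- define_mu_groups(rm_beta, fraction = fraction,
                               min_group = min_group)
    if (!groups$testable) next
    tst <- mwu_link_test(em[, cand$gene[i]], groups$m_samples,
                         groups$u_samples)
    row <- cand[i, , drop = FALSE]
    row$mwu_p_tumour <- tst$mwu_p
    row$direction_tumour <- tst$direction
    row$pearson_r_tumour <- suppressWarnings(cor(rm_beta, em[, cand$gene[i]]))
    row$tumour_m_samples <- list(groups$m_samples)
    row$tumour_u_samples <- list(groups$u_samples)
    rows[[length(rows) + 1]] <- row
  }
  if (length(rows) == 0) {
    return(structure(list(links = empty), class = "tgddmr_result"))
  }
  out <- dplyr::bind_rows(rows)
  perm_in <- tibble(gene = out$gene, mwu_p = out$mwu_p_tumour,
                    m_samples = out$tumour_m_samples,
                    u_samples = out$tumour_u_samples)
  perm <- empirical_adjust(perm_in, tumour_cohort$expression,
                           n_permutations = n_permutations,
                           raw_cut = 0.05, emp_adj_cut = emp_adj_cut,
                           seed = seed)
  out$emp_p_tumour <- perm$emp_p
  out$emp_adj_p_tumour <- perm$emp_adj_p
  out$tgddmr <- perm$significant &
    !is.na(out$direction_tumour) &
    out$direction_tumour == out$direction
  out$tumour_m_samples <- NULL
  out$tumour_u_samples <- NULL
  structure(list(links = out), class = "tgddmr_result")
}

#' @export
print.tgddmr_result <- function(x, ...) {
  cat(sprintf("<tgddmr_result> %d replicated link(s), %d tgdDMR(s)\n",
              nrow(x$links), sum(x$links$tgddmr)))
  invisible(x)
}

#' Cross-cohort effect-size concordance
#'
#' Given paired effect sizes from two screens (matched by region/drug),
#' counts sign-consistent pairs (zeros excluded) and reports the Pearson
#' correlation with its two-sided test.
#'
#' @param effects tibble with columns `effect_a` and `effect_b` (pairs
#'   with a missing side are dropped), or a numeric vector (then
#'   `effects_b` must be supplied).
#' @param effects_b optional numeric vector paired with `effects`.
#' @returns One-row tibble: `n_overlapping`, `n_consistent_sign`,
#'   `consistent_fraction`, `pearson_r`, `p` (`pearson_r`/`p` are `NA`
#'   with fewer than 3 pairs).
#' @export
effect_concordance <- function(effects, effects_b = NULL) {
  if (is.numeric(effects)) {
    effects <- tibble(effect_a = effects, effect_b = effects_b)
  }
  ok <- complete.cases(effects[c("effect_a", "effect_b")])
  a <- effects$effect_a[ok]
  b <- effects$effect_b[ok]
  nz <- a != 0 & b != 0
  n_consistent <- sum(sign(a[nz]) == sign(b[nz]))
  if (length(a) >= 3 && sd(a) > 0 && sd(b) > 0) {
    ct <- cor.test(a, b)
    r <- unname(ct$estimate)
    p <- ct$p.value
  } else {
    r <- NA_real_
    p <- NA_real_
  }
  tibble(n_overlapping = length(a), n_consistent_sign = n_consistent,
         consistent_fraction = if (sum(nz) > 0) n_consistent / sum(nz)
                               else NA_real_,
         pearson_r = r, p = p)
}
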