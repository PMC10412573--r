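# dDMR -> proximal gene expression linking: candidate genes, M/U quantile
# groups, Mann-Whitney tests with a permutation empirical null, mechanism
# case labels, and the independent expression-drug model.

#' Candidate proximal genes for a region
#'
#' In `promoter` mode, returns genes whose strand-aware promoter window
#' (default 2000 bp upstream to 200 bp downstream of the TSS) overlaps the
#' region. In `distal` mode, returns the `n_nearest` genes on the region's
#' chromosome ranked by TSS distance from the region midpoint, taking up
#' to half from each side when available.
#'
#' @param ddmr one-row dDMR tibble (needs `chrom`, `start`, `end`).
#' @param gene_annotation tibble with `gene`, `chromosome`, `tss`
#'   (1-based), `strand`.
#' @param mode `"promoter"` or `"distal"`.
#' @param n_nearest number of genes in distal mode.
#' @param promoter_up,promoter_down promoter window extents in bp.
#' @returns Tibble with `gene`, `mode` and `distance` (bp from region
#'   midpoint to TSS).
#' @export
candidate_gene_pairs <- function(ddmr, gene_annotation,
                                 mode = c("promoter", "distal"),
                                 n_nearest = 20, promoter_up = 2000,
                                 promoter_down = 200) {
  mode <- match.arg(mode)
  g <- gene_annotation[gene_annotation$chromosome == ddmr$chrom, ,
                       drop = FALSE]
  empty <- tibble(gene = character(0), mode = character(0),
                  distance = numeric(0))
  if (nrow(g) == 0) return(empty)
  mid <- (ddmr$start + ddmr$end) / 2
  dist <- abs(g$tss - mid)
  if (mode == "promoter") {
    win_start <- ifelse(g$strand == "+", g$tss - promoter_up,
                        g$tss - promoter_down)
    win_end <- ifelse(g$strand == "+", g$tss + promoter_down,
                      g$tss + promoter_up)
    # overlap of [win_start, win_end] (1-based inclusive) with the 0-based
    # half-open region [start, end): compare on 1-based inclusive terms
    hit <- pmax(win_start, ddmr$start + 1) <= pmin(win_end, ddmr$end)
    res <- tibble(gene = g$gene[hit], mode = "promoter",
                  distance = dist[hit])
  } else {
    side <- ifelse(g$tss < mid, "left", "right")
    half <- floor(n_nearest / 2)
    take <- function(s, k) {
      sel <- which(side == s)
      sel[order(dist[sel])][seq_len(min(k, length(sel)))]
    }
    left <- take("left", half)
    right <- take("right", half)
    chosen <- c(left, right)
    # top up from whichever side has genes left
    remaining <- setdiff(order(dist), chosen)
    if (length(chosen) < n_nearest) {
      chosen <- c(chosen, remaining[seq_len(min(n_nearest - length(chosen),
                                                length(remaining)))])
    }
    res <- tibble(gene = g$gene[chosen], mode = "distal",
                  distance = dist[chosen])
  }
  dplyr::arrange(res, .data$distance, .data$gene)
}

#' Define methylated / unmethylated sample groups
#'
#' Takes the `g = max(min_group, floor(fraction * n))` samples with the
#' lowest region-mean beta as the U (unmethylated) group and the `g`
#' highest as the M (methylated) group, ties broken by stable input
#' order. The pair is untestable when the groups would overlap
#' (`2g > n`) or the beta values are constant.
#'
#' @param region_mean_beta named numeric vector of per-sample region-mean
#'   beta values.
#' @param fraction tail fraction per group.
#' @param min_group minimum group size.
#' @returns List with `m_samples`, `u_samples`, `g`, and `testable`.
#' @export
define_mu_groups <- function(region_mean_beta, fraction = 0.2,
                             min_group = 4) {
  n <- length(region_mean_beta)
  g <- max(min_group, floor(fraction * n))
  if (2 * g > n || isTRUE(var(region_mean_beta) == 0) ||
      anyNA(region_mean_beta)) {
    return(list(m_samples = character(0), u_samples = character(0),
                g = g, testable = FALSE))
  }
  ord <- order(region_mean_beta)         # stable for ties
  ids <- names(region_mean_beta) %||% as.character(seq_len(n))
  list(m_samples = ids[ord[(n - g + 1):n]],
       u_samples = ids[ord[1:g]],
       g = g, testable = TRUE)
}

# exact two-sided MWU by exhaustive enumeration of group assignments
# (handles ties); returns both one-sided tails for the observed M group
mwu_enumerate <- function(pooled, nm) {
  N <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nm)]) - nm * (nm + 1) / 2
  combs <- combn(N, nm)
  u_null <- apply(combs, 2, function(ix) sum(r[ix])) - nm * (nm + 1) / 2
  list(p_less = mean(u_null <= u_obs), p_greater = mean(u_null >= u_obs))
}

# scalar MWU tails for expression values of the M and U groups
mwu_tails <- function(x_m, x_u) {
  nm <- length(x_m)
  nu <- length(x_u)
  pooled <- c(x_m, x_u)
  r <- rank(pooled)
  u <- sum(r[seq_len(nm)]) - nm * (nm + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (nm <= 8 && nu <= 8) {
    if (!ties) {
      return(list(p_less = pwilcox(u, nm, nu),
                  p_greater = 1 - pwilcox(u - 1, nm, nu)))
    }
    return(mwu_enumerate(pooled, nm))
  }
  # tie-corrected normal approximation with continuity correction
  N <- nm + nu
  mu <- nm * nu / 2
  tie_tab <- table(pooled)
  sigma2 <- nm * nu / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  sigma <- sqrt(max(sigma2, 0))
  if (sigma == 0) return(list(p_less = 1, p_greater = 1))
  list(p_less = pnorm((u - mu + 0.5) / sigma),
       p_greater = pnorm(-(u - mu - 0.5) / sigma))
}

#' Mann-Whitney test of expression between M and U groups
#'
#' Runs both one-sided rank-sum tests (M below U and M above U) on the
#' expression values of the two groups; the reported p-value is twice the
#' smaller tail, capped at 1, and the direction is the sign of that tail
#' (negative when the methylated group expresses less). Exact enumeration
#' is used when both groups have at most 8 samples (via the exact
#' rank-sum distribution without ties, exhaustive assignment enumeration
#' with ties), a tie-corrected normal approximation otherwise.
#'
#' @param expression named numeric expression vector covering both groups.
#' @param m_samples,u_samples disjoint sample id vectors.
#' @returns Tibble with `mwu_p` and `direction` (-1, 0 or 1).
#' @export
mwu_link_test <- function(expression, m_samples, u_samples) {
  if (length(intersect(m_samples, u_samples)) > 0) {
    abort("M and U groups overlap")
  }
  tails <- mwu_tails(expression[m_samples], expression[u_samples])
  p <- min(1, 2 * min(tails$p_less, tails$p_greater))
  dir <- if (tails$p_less < tails$p_greater) -1L
         else if (tails$p_greater < tails$p_less) 1L else 0L
  tibble(mwu_p = p, direction = dir)
}

# two-sided MWU p for every column of a (samples x genes) matrix whose
# rows are ordered c(M, U); used for the permutation null
mwu_p_columns <- function(mat, nm) {
  apply(mat, 2, function(col) {
    tails <- mwu_tails(col[seq_len(nm)], col[-seq_len(nm)])
    min(1, 2 * min(tails$p_less, tails$p_greater))
  })
}

#' Permutation-based empirical adjustment of link p-values
#'
#' Links whose raw Mann-Whitney p is below `raw_cut` enter the permutation
#' stage; for each, the same M/U groups are applied to `n_permutations`
#' genes drawn uniformly with replacement from all genes except the linked
#' one, giving `emp_p = (1 + #[null <= observed]) / (n_permutations + 1)`.
#' Empirical p-values are then Benjamini-Hochberg adjusted across all
#' tested links; a link is significant when `emp_adj_p < emp_adj_cut`.
#'
#' @param links tibble with at least `gene`, `mwu_p` and list-columns
#'   `m_samples`, `u_samples`.
#' @param expression samples-by-genes expression tibble (`sample_id`
#'   first).
#' @param n_permutations permutation count (published default 50000).
#' @param raw_cut raw p-value gate.
#' @param emp_adj_cut significance threshold on the adjusted empirical p.
#' @param seed integer seed for the permutation draws.
#' @returns `links` with added `emp_p`, `emp_adj_p` and `significant`;
#'   untested links carry `NA` empirical values and are non-significant.
#' @export
empirical_adjust <- function(links, expression, n_permutations = 50000,
                             raw_cut = 0.05, emp_adj_cut = 0.001,
                             seed = 1) {
  E <- tbl_to_matrix(expression)
  links$emp_p <- NA_real_
  links$emp_adj_p <- NA_real_
  links$significant <- FALSE
  tested <- which(!is.na(links$mwu_p) & links$mwu_p < raw_cut)
  if (length(tested) == 0) return(links)
  set.seed(seed)
  for (i in tested) {
    pool <- setdiff(colnames(E), links$gene[i])
    if (length(pool) < 10) {
      abort("empirical_adjust needs at least 10 candidate null genes")
    }
    draw <- sample(pool, n_permutations, replace = TRUE)
    idx <- c(links$m_samples[[i]], links$u_samples[[i]])
    null_p <- mwu_p_columns(E[idx, draw, drop = FALSE],
                            length(links$m_samples[[i]]))
    links$emp_p[i] <- (1 + sum(null_p <= links$mwu_p[i])) /
      (n_permutations + 1)
  }
  links$emp_adj_p[tested] <- p.adjust(links$emp_p[tested], method = "BH")
  links$significant <- !is.na(links$emp_adj_p) &
    links$emp_adj_p < emp_adj_cut
  links
}

#' Mechanism case label from effect-size and correlation signs
#'
#' Case 1: hypermethylation-sensitive (negative dDMR effect size) with
#' negative methylation-expression correlation; Case 2: negative effect,
#' positive correlation; Case 3: positive effect, negative correlation
#' (the SLFN11 pattern); Case 4: positive effect, positive correlation.
#' A zero argument leaves the label unset (`NA`).
#'
#' @param ddmr_effect_size signed dDMR effect size(s).
#' @param pearson_r methylation-expression correlation(s).
#' @returns Integer vector of case labels in `1:4` (or `NA`).
#' @export
classify_case <- function(ddmr_effect_size, pearson_r) {
  dplyr::case_when(
    ddmr_effect_size < 0 & pearson_r < 0 ~ 1L,
    ddmr_effect_size < 0 & pearson_r > 0 ~ 2L,
    ddmr_effect_size > 0 & pearson_r < 0 ~ 3L,
    ddmr_effect_size > 0 & pearson_r > 0 ~ 4L,
    TRUE ~ NA_integer_)
}

#' Expression-drug response model
#'
#' Tests whether a gene's expression associates with drug response
#' independently of its dDMR: OLS of AUC on expression with the
#' categorical covariates and the first two expression principal
#' components, two-sided t-test on the expression slope.
#'
#' @param expression_gene numeric expression vector (aligned samples).
#' @param auc_for_drug numeric AUC vector.
#' @param covariates covariate tibble.
#' @param expression_pcs tibble of expression PCs (or `NULL`).
#' @returns One-row tibble with `slope`, `se`, `t_stat`, `p`, `n_used`;
#'   zero rows if the design is rank deficient.
#' @export
expression_drug_model <- function(expression_gene, auc_for_drug, covariates,
                                  expression_pcs = NULL) {
  use <- !is.na(expression_gene) & !is.na(auc_for_drug)
  covd <- covariate_design(covariates[use, , drop = FALSE])
  pcm <- if (is.null(expression_pcs)) NULL
         else as.matrix(expression_pcs[grep("^pc", names(expression_pcs))])[use, , drop = FALSE]
  X <- cbind(expr = expression_gene[use],
             `(Intercept)` = rep(1, sum(use)), covd, pcm)
  X <- drop_constant_cols(X)
  fit <- ols_fit(X, auc_for_drug[use])
  if (!fit$ok || !"expr" %in% colnames(X)) {
    inform("expression_drug_model: rank-deficient design; skipped")
    return(tibble(slope = numeric(0), se = numeric(0), t_stat = numeric(0),
                  p = numeric(0), n_used = integer(0)))
  }
  tibble(slope = unname(fit$coef["expr"]), se = unname(fit$se["expr"]),
         t_stat = unname(fit$t["expr"]), p = unname(fit$p["expr"]),
         n_used = sum(use))
}

#' Link dDMRs to proximal gene expression
#'
#' For every called region: find candidate proximal genes, split samples
#' into M/U groups on region-mean methylation, test each gene with the
#' Mann-Whitney link test, apply the permutation empirical adjustment
#' across all links, and label significant links with their mechanism
#' case from the dDMR effect size and the all-sample Pearson correlation
#' of region-mean beta with expression.
#'
#' @param ddmrs dDMR tibble (from [call_ddmrs()] or [tidy()] thereof).
#' @param cohort a [pharmaco_cohort()] with expression.
#' @param gene_annotation gene annotation tibble (defaults to
#'   `cohort$genes`).
#' @param mode `"promoter"` or `"distal"` candidate definition.
#' @param n_permutations,raw_cut,emp_adj_cut,seed see
#'   [empirical_adjust()].
#' @param fraction,min_group see [define_mu_groups()].
#' @returns Object of class `link_result` with a `links` tibble
#'   (`region_id`, `gene`, `mode`, `mwu_p`, `direction`, `emp_p`,
#'   `emp_adj_p`, `pearson_r`, `case`, `significant`, `cohort_tag`).
#' @export
link_dmr_expression <- function(ddmrs, cohort, gene_annotation = NULL,
                                mode = "promoter", n_permutations = 50000,
                                raw_cut = 0.05, emp_adj_cut = 0.001,
                                seed = 1, fraction = 0.2, min_group = 4) {
  if (inherits(ddmrs, "ddmr_result")) ddmrs <- ddmrs$ddmrs
  gene_annotation <- gene_annotation %||% cohort$genes
  if (is.null(gene_annotation)) abort("no gene annotation available")
  if (is.null(cohort$expression)) abort("cohort has no expression matrix")
  bm <- tbl_to_matrix(cohort$beta)
  em <- tbl_to_matrix(cohort$expression)

  rows <- list()
  for (i in seq_len(nrow(ddmrs))) {
    cand <- candidate_gene_pairs(ddmrs[i, ], gene_annotation, mode = mode)
    cand <- cand[cand$gene %in% colnames(em), , drop = FALSE]
    if (nrow(cand) == 0) next
    rm_beta <- rowMeans(bm[, ddmrs$probe_ids[[i]], drop = FALSE],
                        na.rm = TRUE)
    groups <- define_mu_groups(rm_beta, fraction = fraction,
                               min_group = min_group)
    for (gn in cand$gene) {
      if (!groups$testable) {
        rows[[length(rows) + 1]] <- tibble(
          region_id = ddmrs$region_id[i], gene = gn, mode = mode,
          drug = ddmrs$drug[i] %||% NA_character_,
          effect_size = ddmrs$effect_size[i],
          mwu_p = NA_real_, direction = NA_integer_,
          pearson_r = NA_real_, probe_ids = list(ddmrs$probe_ids[[i]]),
          m_samples = list(character(0)), u_samples = list(character(0)))
        next
      }
      tst <- mwu_link_test(em[, gn], groups$m_samples, groups$u_samples)
      rows[[length(rows) + 1]] <- tibble(
        region_id = ddmrs$region_id[i], gene = gn, mode = mode,
        drug = ddmrs$drug[i] %||% NA_character_,
        effect_size = ddmrs$effect_size[i],
        mwu_p = tst$mwu_p, direction = tst$direction,
        pearson_r = suppressWarnings(cor(rm_beta, em[, gn])),
        probe_ids = list(ddmrs$probe_ids[[i]]),
        m_samples = list(groups$m_samples),
        u_samples = list(groups$u_samples))
    }
  }
  links <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble(region_id = character(0), gene = character(0),
           mode = character(0), drug = character(0),
           effect_size = numeric(0), mwu_p = numeric(0),
           direction = integer(0), pearson_r = numeric(0),
           probe_ids = list(), m_samples = list(), u_samples = list())
  links <- empirical_adjust(links, cohort$expression,
                            n_permutations = n_permutations,
                            raw_cut = raw_cut, emp_adj_cut = emp_adj_cut,
                            seed = seed)
  links$case <- ifelse(links$significant,
                       classify_case(links$effect_size, links$pearson_r),
                       NA_integer_)
  links$cohort_tag <- cohort$cohort_tag
  structure(list(links = links,
                 params = list(mode = mode, n_permutations = n_permutations,
                               raw_cut = raw_cut,
                               emp_adj_cut = emp_adj_cut, seed = seed)),
            class = "link_result")
}

#' @export
print.link_result <- function(x, ...) {
  cat(sprintf("<link_result> %d link(s), %d significant\n",
              nrow(x$links), sum(x$links$significant)))
  invisible(x)
}
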