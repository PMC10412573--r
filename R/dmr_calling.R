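# Per-CpG drug-response models and spatially-aware region extraction:
# ACF estimation, Stouffer-Liptak-Kechris combination, Sidak adjustment,
# post-filters, and the per-scan / whole-cohort orchestrators.

#' dDMR calling configuration
#'
#' All thresholds of the region-calling dialect in one place. Defaults:
#' drugs need >= 3 responders at AUC <= 0.7; cancer types need > 15 cell
#' lines; per-probe models require >= 8 complete observations; the ACF is
#' estimated in 250 bp bins up to 1000 bp; seeds and extensions use
#' SLK-corrected p < 0.05 with 1000 bp peak merging; reported regions need
#' Sidak-adjusted p < 1e-6, every constituent probe at raw p < 0.01, and at
#' least 4 cell lines in each aberrant methylation state (region-mean beta
#' < 0.3 and > 0.7).
#'
#' @param auc_thresh,min_responders drug eligibility: at least
#'   `min_responders` samples with AUC `<= auc_thresh`.
#' @param min_lines cancer-type eligibility: at least this many cell lines.
#' @param n_pcs number of methylation principal components as covariates.
#' @param min_n minimum complete (beta, AUC) pairs per probe model.
#' @param max_lag,bin_width,min_pairs ACF estimation parameters (bp, bp,
#'   minimum pairs per bin).
#' @param window SLK neighbourhood half-width in bp.
#' @param seed_p,extend_p,merge_dist region extraction: seed and extension
#'   thresholds on corrected p, and the peak-merging distance in bp.
#' @param sidak_cut,raw_p_cut,min_aberrant reporting filters.
#' @returns A `ddmr_config` list.
#' @export
ddmr_config <- function(auc_thresh = 0.7, min_responders = 3, min_lines = 16,
                        n_pcs = 2, min_n = 8, max_lag = 1000, bin_width = 250,
                        min_pairs = 10, window = 1000, seed_p = 0.05,
                        extend_p = 0.05, merge_dist = 1000, sidak_cut = 1e-6,
                        raw_p_cut = 0.01, min_aberrant = 4) {
  structure(as.list(environment()), class = "ddmr_config")
}

#' Drugs eligible for dDMR scanning
#'
#' A drug qualifies when at least `min_responders` samples show partial
#' response, i.e. AUC at or below `auc_thresh` (bound inclusive).
#'
#' @param auc samples-by-drugs AUC tibble (`sample_id` first column).
#' @param auc_thresh AUC cutoff defining a responder.
#' @param min_responders minimum responder count.
#' @returns Tibble with columns `drug` and `n_responders`.
#' @export
eligible_drugs <- function(auc, auc_thresh = 0.7, min_responders = 3) {
  drugs <- setdiff(names(auc), "sample_id")
  n_resp <- vapply(drugs, function(d) {
    sum(!is.na(auc[[d]]) & auc[[d]] <= auc_thresh)
  }, integer(1))
  tibble(drug = drugs, n_responders = unname(n_resp)) |>
    dplyr::filter(.data$n_responders >= min_responders)
}

#' Cancer types eligible for dDMR scanning
#'
#' Keeps cancer types with at least `min_lines` (default 16, i.e. more
#' than 15) cell lines.
#'
#' @param covariates covariate tibble with a `cancer_type` column.
#' @param min_lines minimum cell-line count per cancer type.
#' @returns Tibble with columns `cancer_type` and `n`.
#' @export
eligible_cancer_types <- function(covariates, min_lines = 16) {
  dplyr::count(covariates, .data$cancer_type, name = "n") |>
    dplyr::filter(.data$n >= min_lines)
}

#' Methylation principal-component scores
#'
#' Projects samples onto the top right singular directions of the
#' column-centered sample-by-probe beta matrix (global methylation
#' pattern correction). Sign convention: within each component, the
#' largest-magnitude probe loading is positive.
#'
#' @param beta samples-by-probes tibble or numeric matrix.
#' @param n_components number of components (default 2).
#' @returns Tibble with `sample_id` and `pc1`, `pc2`, ...
#' @export
methylation_pcs <- function(beta, n_components = 2) {
  m <- if (is.data.frame(beta)) tbl_to_matrix(beta) else beta
  if (nrow(m) < 3) abort("principal components need at least 3 samples")
  m[is.na(m)] <- mean(m, na.rm = TRUE)
  cm <- scale(m, center = TRUE, scale = FALSE)
  k <- min(n_components, nrow(m) - 1, ncol(m))
  sv <- svd(cm, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("pc", seq_len(k))
  dplyr::bind_cols(tibble(sample_id = rownames(m)), as_tibble(scores))
}

#' Per-CpG linear models of drug response
#'
#' For one drug within one cancer type, fits per probe the ordinary least
#' squares model `AUC ~ beta + medium + growth + msi + pc1 + pc2`
#' (categorical covariates one-hot encoded against the lexicographically
#' first level; constant columns dropped) and reports the slope on the
#' methylation beta-value with its two-sided t-test at residual degrees of
#' freedom. Samples with missing beta or AUC are dropped per probe; probes
#' with fewer than `min_n` complete pairs, or rank-deficient designs, are
#' skipped.
#'
#' @param beta samples-by-probes tibble or matrix.
#' @param auc_for_drug numeric AUC vector aligned with the beta rows.
#' @param covariates covariate tibble aligned with the beta rows.
#' @param pcs tibble from [methylation_pcs()] (or `NULL` to omit).
#' @param min_n minimum complete observations per probe.
#' @returns Tibble with `probe_id`, `beta1`, `se`, `t_stat`, `p_raw`,
#'   `n_used`, `intercept` and a `coefs` list-column holding the full
#'   coefficient vector.
#' @export
fit_cpg_models <- function(beta, auc_for_drug, covariates, pcs = NULL,
                           min_n = 8) {
  m <- if (is.data.frame(beta)) tbl_to_matrix(beta) else beta
  n <- nrow(m)
  stopifnot(length(auc_for_drug) == n, nrow(covariates) == n)
  covd <- covariate_design(covariates)
  pcm <- if (is.null(pcs)) NULL else as.matrix(pcs[grep("^pc", names(pcs))])
  base <- cbind(`(Intercept)` = rep(1, n), covd, pcm)
  base <- drop_constant_cols(base)

  probes <- colnames(m)
  np <- length(probes)
  keep <- logical(np)
  beta1 <- se <- t_stat <- p_raw <- intercept <- rep(NA_real_, np)
  n_used <- rep(NA_integer_, np)
  coefs <- vector("list", np)
  y_all <- auc_for_drug
  for (j in seq_len(np)) {
    mv <- m[, j]
    use <- !is.na(mv) & !is.na(y_all)
    if (sum(use) < min_n) next
    X <- cbind(beta_cpg = mv[use], base[use, , drop = FALSE])
    X <- drop_constant_cols(X)
    if (!"beta_cpg" %in% colnames(X)) next   # constant methylation
    fit <- ols_fit(X, y_all[use])
    if (!fit$ok) {
      inform(sprintf("fit_cpg_models: skipping probe '%s' (rank-deficient design)",
                     probes[j]))
      next
    }
    keep[j] <- TRUE
    beta1[j] <- fit$coef[["beta_cpg"]]
    se[j] <- fit$se[["beta_cpg"]]
    t_stat[j] <- fit$t[["beta_cpg"]]
    p_raw[j] <- fit$p[["beta_cpg"]]
    n_used[j] <- sum(use)
    intercept[j] <- fit$coef[["(Intercept)"]]
    coefs[[j]] <- fit$coef
  }
  tibble(probe_id = probes, beta1 = beta1, se = se, t_stat = t_stat,
         p_raw = p_raw, n_used = n_used, intercept = intercept,
         coefs = coefs)[keep, , drop = FALSE]
}

#' Distance-binned autocorrelation of association z-scores
#'
#' Converts per-probe p-values to signed z-scores
#' (`qnorm(1 - p/2) * sign(t)`) and estimates, per base-pair distance bin,
#' the Pearson correlation over all probe pairs whose genomic distance
#' falls in the bin, pooled across chromosomes. Bins with fewer than
#' `min_pairs` pairs inherit the previous bin's value (the first bin falls
#' back to 0). Estimates are clipped to `[0, 0.99]`.
#'
#' @param associations tibble from [fit_cpg_models()] (`probe_id`,
#'   `p_raw`, `t_stat`).
#' @param manifest probe manifest with `probe_id`, `chromosome`,
#'   `position`.
#' @param max_lag largest distance considered (bp).
#' @param bin_width bin width (bp).
#' @param min_pairs minimum pairs for a bin to be estimated directly.
#' @returns Tibble of class `acf_estimate` with `lag_min`, `lag_max`,
#'   `correlation`, `n_pairs`.
#' @export
estimate_acf <- function(associations, manifest, max_lag = 1000,
                         bin_width = 250, min_pairs = 10) {
  breaks <- seq(0, max_lag, by = bin_width)
  n_bins <- length(breaks) - 1
  ann <- dplyr::inner_join(
    associations,
    manifest[c("probe_id", "chromosome", "position")], by = "probe_id")
  z <- qnorm(clip_p(ann$p_raw) / 2, lower.tail = FALSE) * sign(ann$t_stat)

  pair_x <- vector("list", 0)
  pair_bin <- vector("list", 0)
  for (chr in unique(ann$chromosome)) {
    sel <- which(ann$chromosome == chr)
    ord <- sel[order(ann$position[sel])]
    pos <- ann$position[ord]
    zc <- z[ord]
    np <- length(pos)
    if (np < 2) next
    for (i in seq_len(np - 1)) {
      j <- i + 1
      while (j <= np && pos[j] - pos[i] <= max_lag) j <- j + 1
      if (j - 1 > i) {
        jj <- (i + 1):(j - 1)
        d <- pos[jj] - pos[i]
        keep <- d > 0
        if (any(keep)) {
          pair_x[[length(pair_x) + 1]] <-
            cbind(zc[i], zc[jj[keep]])
          pair_bin[[length(pair_bin) + 1]] <-
            pmin(n_bins, ceiling(d[keep] / bin_width))
        }
      }
    }
  }
  corrs <- rep(NA_real_, n_bins)
  counts <- integer(n_bins)
  warned_zero_var <- FALSE
  if (length(pair_x) > 0) {
    px <- do.call(rbind, pair_x)
    pb <- unlist(pair_bin)
    for (b in seq_len(n_bins)) {
      sel <- pb == b
      counts[b] <- sum(sel)
      if (counts[b] >= min_pairs) {
        x <- px[sel, 1]
        y <- px[sel, 2]
        if (isTRUE(sd(x) > 0 && sd(y) > 0)) {
          corrs[b] <- cor(x, y)
        } else {
          if (!warned_zero_var) {
            warn("estimate_acf: zero variance among z-scores; using 0")
            warned_zero_var <- TRUE
          }
          corrs[b] <- 0
        }
      }
    }
  } else {
    warn("estimate_acf: no probe pairs within max_lag; returning all-zero ACF")
  }
  for (b in seq_len(n_bins)) {
    if (is.na(corrs[b])) corrs[b] <- if (b == 1) 0 else corrs[b - 1]
  }
  structure(
    tibble(lag_min = breaks[-length(breaks)], lag_max = breaks[-1],
           correlation = pmin(pmax(corrs, 0), 0.99), n_pairs = counts),
    class = c("acf_estimate", "tbl_df", "tbl", "data.frame"))
}

# correlation for a vector of pairwise distances under an ACF estimate
acf_lookup <- function(acf, distance) {
  n_bins <- nrow(acf)
  bin <- ceiling(distance / (acf$lag_max[1] - acf$lag_min[1]))
  out <- numeric(length(distance))
  inside <- bin >= 1 & bin <= n_bins
  out[inside] <- acf$correlation[bin[inside]]
  out[distance <= 0] <- acf$correlation[1]
  out
}

#' Stouffer-Liptak combination of correlated p-values
#'
#' Transforms p-values to one-sided z-scores (`qnorm(1 - p)`) and combines
#' them as `sum(z) / sqrt(sum(C))` where `C` is the correlation matrix;
#' the combined p is the upper normal tail. The denominator is floored at
#' the number of tests, which guards against non-positive-definite
#' correlation inputs. A single p-value is returned unchanged.
#'
#' @param p_values numeric vector of p-values (clipped internally to
#'   `[1e-300, 1 - 1e-16]`).
#' @param correlation_matrix symmetric matrix with unit diagonal (or a
#'   scalar pairwise correlation for exchangeable inputs).
#' @returns Combined probability.
#' @export
stouffer_liptak <- function(p_values, correlation_matrix = NULL) {
  k <- length(p_values)
  if (k == 0) abort("stouffer_liptak needs at least one p-value")
  p <- clip_p(p_values)
  if (k == 1) return(p)
  if (is.null(correlation_matrix)) correlation_matrix <- diag(k)
  if (length(correlation_matrix) == 1) {
    correlation_matrix <-
      matrix(correlation_matrix, k, k) + diag(1 - correlation_matrix, k)
  }
  z <- qnorm(p, lower.tail = FALSE)
  denom <- max(sum(correlation_matrix), k)
  clip_p(1 - pnorm(sum(z) / sqrt(denom)))
}

#' Spatially-corrected per-site p-values (SLK)
#'
#' For each probe, combines its raw p-value with those of all probes
#' within `window` bp on the same chromosome via [stouffer_liptak()],
#' using pairwise correlations looked up from the distance-binned ACF.
#' Isolated probes keep their raw p-value.
#'
#' @param associations tibble from [fit_cpg_models()].
#' @param acf an `acf_estimate` from [estimate_acf()].
#' @param manifest probe manifest (`probe_id`, `chromosome`, `position`).
#' @param window neighbourhood half-width in bp.
#' @returns The association tibble with an added `p_slk` column, sorted by
#'   chromosome and position.
#' @export
slk_correct_sites <- function(associations, acf, manifest, window = 1000) {
  ann <- dplyr::inner_join(
    associations, manifest[c("probe_id", "chromosome", "position")],
    by = "probe_id") |>
    dplyr::arrange(.data$chromosome, .data$position)
  p_slk <- numeric(nrow(ann))
  for (chr in unique(ann$chromosome)) {
    sel <- which(ann$chromosome == chr)
    pos <- ann$position[sel]
    p <- ann$p_raw[sel]
    for (ii in seq_along(sel)) {
      nb <- which(abs(pos - pos[ii]) <= window)
      if (length(nb) == 1) {
        p_slk[sel[ii]] <- p[ii]
      } else {
        d <- abs(outer(pos[nb], pos[nb], "-"))
        C <- matrix(acf_lookup(acf, as.vector(d)), length(nb), length(nb))
        diag(C) <- 1
        p_slk[sel[ii]] <- stouffer_liptak(p[nb], C)
      }
    }
  }
  ann$p_slk <- p_slk
  ann
}

#' Extract candidate regions from corrected p-values
#'
#' Seeds are probes with corrected p below `seed_p`; a region extends over
#' probes with corrected p below `extend_p` whose gaps do not exceed
#' `merge_dist` bp, and regions closer than `merge_dist` are merged.
#' Region intervals are 0-based half-open over the constituent probe
#' positions.
#'
#' @param corrected tibble from [slk_correct_sites()] (needs `probe_id`,
#'   `chromosome`, `position`, `p_slk`).
#' @param seed_p,extend_p,merge_dist extraction thresholds.
#' @returns Tibble with `region_id`, `chrom`, `start`, `end`, `probe_ids`
#'   (list-column) and `n_probes`.
#' @export
extract_regions <- function(corrected, seed_p = 0.05, extend_p = 0.05,
                            merge_dist = 1000) {
  out <- list()
  for (chr in unique(corrected$chromosome)) {
    cc <- corrected[corrected$chromosome == chr, , drop = FALSE]
    cc <- cc[order(cc$position), , drop = FALSE]
    ext <- which(cc$p_slk < extend_p)
    if (length(ext) == 0) next
    pos <- cc$position[ext]
    new_group <- c(TRUE, diff(pos) > merge_dist)
    grp <- cumsum(new_group)
    for (g in unique(grp)) {
      idx <- ext[grp == g]
      if (!any(cc$p_slk[idx] < seed_p)) next
      out[[length(out) + 1]] <- tibble(
        chrom = chr,
        start = as.integer(min(cc$position[idx]) - 1L),
        end = as.integer(max(cc$position[idx])),
        probe_ids = list(cc$probe_id[idx]),
        n_probes = length(idx))
    }
  }
  if (length(out) == 0) {
    return(tibble(region_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), probe_ids = list(),
                  n_probes = integer(0)))
  }
  res <- dplyr::bind_rows(out) |>
    dplyr::arrange(.data$chrom, .data$start)
  dplyr::bind_cols(
    tibble(region_id = sprintf("region_%03d", seq_len(nrow(res)))), res)
}

#' Sidak family-wise adjustment over effective test count
#'
#' Effective number of tests is `max(1, floor(n_total_probes /
#' n_region_probes))`; the adjusted value is `1 - (1 - p)^n_eff`.
#'
#' @param region_p region-level combined p-value(s).
#' @param n_region_probes probes in the region.
#' @param n_total_probes probes in the scan.
#' @returns Adjusted probability, same length as `region_p`.
#' @export
sidak_adjust <- function(region_p, n_region_probes, n_total_probes) {
  n_eff <- pmax(1, floor(n_total_probes / n_region_probes))
  # log-scale for numerical stability at tiny p
  -expm1(n_eff * log1p(-clip_p(region_p)))
}

#' Filter and score candidate regions into dDMRs
#'
#' The region-level p combines the constituent probes' raw p-values via
#' [stouffer_liptak()] with ACF-derived correlations, then receives the
#' Sidak adjustment. Reported dDMRs must pass `sidak_p < sidak_cut`, have
#' every constituent probe at `p_raw < raw_p_cut`, and show at least
#' `min_aberrant` samples in each aberrant methylation state (region-mean
#' beta below 0.3 and above 0.7). The effect size is the mean per-probe
#' slope of AUC on beta across the region.
#'
#' @param regions tibble from [extract_regions()].
#' @param associations tibble from [fit_cpg_models()].
#' @param beta samples-by-probes tibble or matrix.
#' @param acf `acf_estimate` used for the region correlation matrix.
#' @param manifest probe manifest.
#' @param sidak_cut,raw_p_cut,min_aberrant reporting thresholds.
#' @param n_total_probes total probes tested in the scan (defaults to
#'   `nrow(associations)`).
#' @returns dDMR tibble: `region_id`, `chrom`, `start`, `end`,
#'   `probe_ids`, `n_probes`, `region_p`, `sidak_p`, `effect_size`,
#'   `n_hypo`, `n_hyper`.
#' @export
filter_and_score_regions <- function(regions, associations, beta, acf,
                                     manifest, sidak_cut = 1e-6,
                                     raw_p_cut = 0.01, min_aberrant = 4,
                                     n_total_probes = nrow(associations)) {
  m <- if (is.data.frame(beta)) tbl_to_matrix(beta) else beta
  if (nrow(regions) == 0) {
    return(dplyr::bind_cols(regions,
                            tibble(region_p = numeric(0), sidak_p = numeric(0),
                                   effect_size = numeric(0),
                                   n_hypo = integer(0), n_hyper = integer(0))))
  }
  assoc_ix <- match(associations$probe_id, associations$probe_id)
  rows <- purrr::map(seq_len(nrow(regions)), function(i) {
    probes <- regions$probe_ids[[i]]
    a <- associations[match(probes, associations$probe_id), , drop = FALSE]
    pos <- manifest$position[match(probes, manifest$probe_id)]
    d <- abs(outer(pos, pos, "-"))
    C <- matrix(acf_lookup(acf, as.vector(d)), length(pos), length(pos))
    diag(C) <- 1
    region_p <- stouffer_liptak(a$p_raw, C)
    sidak_p <- sidak_adjust(region_p, length(probes), n_total_probes)
    rm_beta <- rowMeans(m[, probes, drop = FALSE], na.rm = TRUE)
    tibble(region_id = regions$region_id[i], chrom = regions$chrom[i],
           start = regions$start[i], end = regions$end[i],
           probe_ids = list(probes), n_probes = length(probes),
           region_p = region_p, sidak_p = sidak_p,
           effect_size = mean(a$beta1),
           n_hypo = sum(rm_beta < 0.3, na.rm = TRUE),
           n_hyper = sum(rm_beta > 0.7, na.rm = TRUE),
           max_p_raw = max(a$p_raw))
  })
  res <- dplyr::bind_rows(rows)
  res |>
    dplyr::filter(.data$sidak_p < sidak_cut,
                  .data$max_p_raw < raw_p_cut,
                  pmin(.data$n_hypo, .data$n_hyper) >= min_aberrant) |>
    dplyr::select(-"max_p_raw")
}

#' Run one (drug, cancer type) dDMR scan
#'
#' The per-scan pipeline: per-CpG models, ACF estimation, SLK correction,
#' region extraction, Sidak adjustment and reporting filters. Exposed for
#' calibration studies; [call_ddmrs()] drives it across all eligible
#' scans.
#'
#' @param beta,auc_for_drug,covariates,pcs as in [fit_cpg_models()].
#' @param manifest probe manifest for the scanned probes.
#' @param config a [ddmr_config()].
#' @returns dDMR tibble (possibly empty) as in
#'   [filter_and_score_regions()].
#' @export
ddmr_scan <- function(beta, auc_for_drug, covariates, manifest,
                      pcs = NULL, config = ddmr_config()) {
  assoc <- fit_cpg_models(beta, auc_for_drug, covariates, pcs,
                          min_n = config$min_n)
  if (nrow(assoc) == 0) return(filter_and_score_regions(
    extract_regions(tibble(probe_id = character(0), chromosome = character(0),
                           position = integer(0), p_slk = numeric(0))),
    assoc, beta, NULL, manifest))
  acf <- estimate_acf(assoc, manifest, max_lag = config$max_lag,
                      bin_width = config$bin_width,
                      min_pairs = config$min_pairs)
  corrected <- slk_correct_sites(assoc, acf, manifest,
                                 window = config$window)
  regions <- extract_regions(corrected, seed_p = config$seed_p,
                             extend_p = config$extend_p,
                             merge_dist = config$merge_dist)
  filter_and_score_regions(regions, assoc, beta, acf, manifest,
                           sidak_cut = config$sidak_cut,
                           raw_p_cut = config$raw_p_cut,
                           min_aberrant = config$min_aberrant,
                           n_total_probes = nrow(assoc))
}

#' Call dDMRs across all eligible (drug, cancer type) scans
#'
#' Orchestrates cancer-type and drug eligibility, per-cancer-type
#' methylation principal components, and [ddmr_scan()] per eligible pair.
#' A failing scan is logged and skipped. Deterministic given its inputs.
#'
#' @param cohort a [pharmaco_cohort()] with manifest and AUC table.
#' @param config a [ddmr_config()].
#' @returns Object of class `ddmr_result`: list with `ddmrs` (tibble of
#'   called regions tagged by `drug` and `cancer_type`), `scans` (per-scan
#'   log) and `config`. Use [tidy()] / [glance()] / [autoplot()].
#' @export
call_ddmrs <- function(cohort, config = ddmr_config()) {
  stopifnot(inherits(cohort, "pharmaco_cohort"))
  if (is.null(cohort$auc)) abort("cohort has no AUC table")
  types <- eligible_cancer_types(cohort$covariates,
                                 min_lines = config$min_lines)
  all_ddmrs <- list()
  scan_log <- list()
  for (ct in types$cancer_type) {
    in_ct <- cohort$covariates$cancer_type == ct
    beta_ct <- cohort$beta[in_ct, , drop = FALSE]
    auc_ct <- cohort$auc[in_ct, , drop = FALSE]
    cov_ct <- cohort$covariates[in_ct, , drop = FALSE]
    pcs <- methylation_pcs(beta_ct, n_components = config$n_pcs)
    drugs <- eligible_drugs(auc_ct, auc_thresh = config$auc_thresh,
                            min_responders = config$min_responders)
    for (d in drugs$drug) {
      res <- tryCatch(
        ddmr_scan(beta_ct, auc_ct[[d]], cov_ct, cohort$manifest,
                  pcs = pcs, config = config),
        error = function(e) {
          inform(sprintf("scan %s / %s failed: %s", ct, d,
                         conditionMessage(e)))
          NULL
        })
      scan_log[[length(scan_log) + 1]] <- tibble(
        cancer_type = ct, drug = d,
        status = if (is.null(res)) "failed" else "ok",
        n_ddmrs = if (is.null(res)) NA_integer_ else nrow(res))
      if (!is.null(res) && nrow(res) > 0) {
        res$drug <- d
        res$cancer_type <- ct
        all_ddmrs[[length(all_ddmrs) + 1]] <- res
      }
    }
  }
  ddmrs <- if (length(all_ddmrs) > 0) dplyr::bind_rows(all_ddmrs) else
    tibble(region_id = character(0), chrom = character(0),
           start = integer(0), end = integer(0), probe_ids = list(),
           n_probes = integer(0), region_p = numeric(0),
           sidak_p = numeric(0), effect_size = numeric(0),
           n_hypo = integer(0), n_hyper = integer(0),
           drug = character(0), cancer_type = character(0))
  structure(list(ddmrs = ddmrs,
                 scans = dplyr::bind_rows(scan_log),
                 config = config),
            class = "ddmr_result")
}

#' @export
print.ddmr_result <- function(x, ...) {
  cat(sprintf("<ddmr_result> %d dDMR(s) from %d scan(s)\n",
              nrow(x$ddmrs), nrow(x$scans)))
  invisible(x)
}
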