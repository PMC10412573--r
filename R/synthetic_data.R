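# Synthetic pharmacoepigenomic cohorts: bimodal beta-values with AR(1)
# spatial correlation on the logit scale, planted drug-responsive regions,
# proximal-gene expression mediation (four sign cases), and toy networks.

#' Describe a planted drug-responsive region
#'
#' @param n_probes number of consecutive CpG probes in the region.
#' @param fraction_shifted fraction of samples whose region methylation is
#'   moved to the opposite beta mode.
#' @param auc_effect signed slope of AUC on region-mean beta (AUC units per
#'   beta unit); negative = hypermethylation confers sensitivity.
#' @param case mechanism class 1-4: sign of `auc_effect` crossed with the
#'   sign of the methylation-expression slope (1: -/-, 2: -/+, 3: +/-,
#'   4: +/+).
#' @param linked_gene name of the proximal gene whose expression the region
#'   mediates.
#' @param drug name of the drug carrying the planted AUC effect.
#' @returns A one-row tibble describing the region.
#' @export
planted_region <- function(n_probes = 8, fraction_shifted = 0.25,
                           auc_effect = -0.15, case = 1,
                           linked_gene = "GENE_PL1", drug = "drug_1") {
  stopifnot(case %in% 1:4)
  expected_sign <- if (case %in% c(1, 2)) -1 else 1
  if (sign(auc_effect) != 0 && sign(auc_effect) != expected_sign) {
    abort(sprintf("case %d requires auc_effect sign %+d", case, expected_sign))
  }
  tibble(n_probes = as.integer(n_probes),
         fraction_shifted = fraction_shifted,
         auc_effect = auc_effect, case = as.integer(case),
         linked_gene = linked_gene, drug = drug)
}

#' Simulation configuration
#'
#' Defaults describe a single-cancer-type screen of 40 cell lines and 500
#' array probes, with bimodal beta-values (modes near 0.1 and 0.9) and
#' AR(1) spatial correlation 0.7 on the logit scale. Probes are placed in
#' dense clusters (CpG-island-like: ~8 probes at 30-80 bp spacing)
#' separated by multi-kilobase gaps, mirroring the clustered seeding of
#' methylation arrays; planted regions occupy whole clusters. The AUC
#' baseline is 0.8 with residual noise SD 0.03 plus small categorical
#' covariate offsets.
#'
#' @param n_samples number of cell lines.
#' @param n_probes number of CpG probes.
#' @param span_bp genomic span over which probe clusters are spread.
#' @param cluster_size mean number of probes per cluster.
#' @param intra_spacing range (bp) of consecutive probe spacing within a
#'   cluster.
#' @param n_drugs number of screened drugs.
#' @param n_genes number of genes in the expression matrix.
#' @param planted_regions tibble of [planted_region()] rows (possibly
#'   zero-row for a null cohort).
#' @param noise_sd_auc SD of the Gaussian AUC noise.
#' @param spatial_rho AR(1) correlation of logit-scale spatial noise,
#'   in `[0, 1)`.
#' @param spatial_sd SD of the spatial noise component (logit scale).
#' @param sample_sd SD of the independent per-(sample, probe) noise
#'   (logit scale).
#' @param global_factor_sd SDs of two global latent methylation factors
#'   (logit scale) that load on every probe, emulating the cohort-wide
#'   methylation patterns which dominate the top principal components of
#'   real array cohorts (and which the per-CpG model's PC covariates are
#'   meant to absorb).
#' @param auc_baseline intercept of the AUC model.
#' @param covariate_effects named offsets added to AUC for the second level
#'   of each covariate.
#' @param expr_intercept,expr_slope,expr_sd linked-gene expression model:
#'   `a + b * region_mean_beta + noise`, `|b| = expr_slope` with the sign
#'   set by the region's case.
#' @param seed integer seed; all draws are reproducible from it.
#' @returns A `sim_config` list.
#' @export
sim_config <- function(n_samples = 40, n_probes = 500,
                       span_bp = 400 * n_probes, cluster_size = 8,
                       intra_spacing = c(30, 80), n_drugs = 3, n_genes = 200,
                       planted_regions = planted_region(),
                       noise_sd_auc = 0.03, spatial_rho = 0.7,
                       spatial_sd = 0.5, sample_sd = 0.3,
                       global_factor_sd = c(1.5, 1.5), auc_baseline = 0.8,
                       covariate_effects = c(medium = 0.02, growth = -0.02,
                                             msi = 0.01),
                       expr_intercept = 8, expr_slope = 2, expr_sd = 0.5,
                       seed = 1) {
  stopifnot(spatial_rho >= 0, spatial_rho < 1)
  if (is.null(planted_regions)) {
    planted_regions <- planted_region()[0, ]
  }
  if (nrow(planted_regions) > 0) {
    if (sum(planted_regions$n_probes) > n_probes) {
      abort("planted regions exceed the probe count")
    }
    detectable <- planted_regions$auc_effect != 0
    if (any(detectable &
            planted_regions$fraction_shifted * n_samples < 4)) {
      abort("a detectable planted region needs fraction_shifted * n_samples >= 4")
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

# AR(1) noise along probe index, one row per sample (stationary start)
ar1_noise <- function(n_samples, n_probes, rho, sd) {
  e <- matrix(rnorm(n_samples * n_probes, sd = sd), n_samples, n_probes)
  if (rho > 0 && n_probes > 1) {
    scale <- sqrt(1 - rho^2)
    for (j in 2:n_probes) {
      e[, j] <- rho * e[, j - 1] + scale * e[, j]
    }
  }
  e
}

#' Simulate a pharmacoepigenomic cell-line cohort
#'
#' Generates probe positions sorted uniform over the span, bimodal baseline
#' probe means, logit-scale AR(1) spatial noise plus independent sample
#' noise, planted regions whose shifted samples move to the opposite beta
#' mode, AUC tables with the planted slopes and covariate offsets, and a
#' gene expression matrix in which each region's linked gene is mediated by
#' region-mean methylation with the sign of its mechanism case.
#'
#' @param config a [sim_config()].
#' @returns A list of class `pharmaco_sim` with elements `cohort`
#'   (a [pharmaco_cohort()] carrying manifest and gene annotation) and
#'   `truth` (planted intervals, shifted samples, true slopes, generator
#'   state for tumour regeneration).
#' @export
simulate_pharmaco_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_probes
  regions <- config$planted_regions

  probe_ids <- sprintf("cg%06d", seq_len(p))
  samples <- sprintf("CL%03d", seq_len(n))

  # clustered probe placement (dense CpG-island-like clusters separated by
  # multi-kb gaps); each planted region claims one dedicated cluster
  n_r <- nrow(regions)
  n_left <- p - sum(if (n_r > 0) regions$n_probes else 0L)
  if (n_left < 0) abort("planted regions exceed the probe count")
  n_free <- if (n_left > 0) max(1, round(n_left / config$cluster_size)) else 0
  free_sizes <- if (n_free > 0) {
    s <- rep(n_left %/% n_free, n_free)
    if (n_left %% n_free > 0) s[seq_len(n_left %% n_free)] <- s[1] + 1
    s
  } else integer(0)
  n_c <- n_free + n_r
  # spread planted clusters among the free ones
  planted_slot <- if (n_r > 0) unique(pmax(1, pmin(n_c,
    round(seq_len(n_r) * n_c / (n_r + 1))))) else integer(0)
  while (length(planted_slot) < n_r) {
    planted_slot <- sort(unique(c(planted_slot,
                                  setdiff(seq_len(n_c), planted_slot)[1])))
  }
  sizes <- integer(n_c)
  sizes[planted_slot] <- regions$n_probes
  sizes[setdiff(seq_len(n_c), planted_slot)] <- free_sizes
  cluster_starts <- round(seq(1, config$span_bp - 2000, length.out = n_c)) +
    sample.int(500, n_c, replace = TRUE)
  positions <- integer(0)
  cluster_of <- integer(0)
  for (cix in seq_len(n_c)) {
    gaps <- sample(seq(config$intra_spacing[1], config$intra_spacing[2]),
                   max(sizes[cix] - 1, 0), replace = TRUE)
    positions <- c(positions, as.integer(cluster_starts[cix] + cumsum(c(0, gaps))))
    cluster_of <- c(cluster_of, rep(cix, sizes[cix]))
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("span_bp too small for the requested cluster layout")
  }

  # bimodal baseline: low mode ~0.1, high mode ~0.9 (logit scale jitter);
  # probes within a cluster share a mode, as in islands vs open sea
  cluster_high <- runif(n_c) < 0.5
  mode_high <- cluster_high[cluster_of]
  mu <- ifelse(mode_high, qlogis(0.9), qlogis(0.1)) + rnorm(p, sd = 0.3)

  region_idx <- list()
  if (n_r > 0) {
    for (r in seq_len(n_r)) {
      region_idx[[r]] <- which(cluster_of == planted_slot[r])
      # region baseline sits in one mode; shifted samples take the other
      base_mode <- if (regions$auc_effect[r] <= 0) qlogis(0.1) else qlogis(0.9)
      mu[region_idx[[r]]] <- base_mode + rnorm(length(region_idx[[r]]),
                                               sd = 0.15)
    }
  }

  # global latent methylation factors: per-probe loadings, per-sample
  # scores; these dominate the top PCs as in real array cohorts
  loadings <- cbind(rnorm(p, mean = 0.8, sd = 0.3),
                    rnorm(p, mean = 0, sd = 0.8))
  scores <- cbind(rnorm(n, sd = config$global_factor_sd[1]),
                  rnorm(n, sd = config$global_factor_sd[2]))
  eta <- matrix(mu, n, p, byrow = TRUE) +
    scores %*% t(loadings) +
    ar1_noise(n, p, config$spatial_rho, config$spatial_sd) +
    matrix(rnorm(n * p, sd = config$sample_sd), n, p)

  shifted <- vector("list", nrow(regions))
  if (nrow(regions) > 0) {
    for (r in seq_len(nrow(regions))) {
      k <- round(regions$fraction_shifted[r] * n)
      shifted[[r]] <- sort(sample.int(n, k))
      opposite <- if (regions$auc_effect[r] <= 0) qlogis(0.9) else qlogis(0.1)
      idx <- region_idx[[r]]
      eta[shifted[[r]], idx] <-
        opposite + matrix(rnorm(k * length(idx), sd = 0.3), k, length(idx))
    }
  }
  beta <- plogis(eta)
  dimnames(beta) <- list(samples, probe_ids)

  covariates <- tibble(
    sample_id = samples,
    cancer_type = "CT1",
    medium = sample(c("D/F12", "RPMI"), n, replace = TRUE),
    growth = sample(c("Adherent", "Suspension"), n, replace = TRUE),
    msi = sample(c("MSI-H", "MSS"), n, replace = TRUE, prob = c(0.2, 0.8)))
  offsets <- rep(0, n)
  ce <- config$covariate_effects
  offsets <- offsets +
    (covariates$medium == "RPMI") * (ce[["medium"]] %||% 0) +
    (covariates$growth == "Suspension") * (ce[["growth"]] %||% 0) +
    (covariates$msi == "MSS") * (ce[["msi"]] %||% 0)

  drugs <- sprintf("drug_%d", seq_len(config$n_drugs))
  auc <- matrix(config$auc_baseline + offsets, n, config$n_drugs) +
    matrix(rnorm(n * config$n_drugs, sd = config$noise_sd_auc),
           n, config$n_drugs)
  dimnames(auc) <- list(samples, drugs)
  region_mean <- vector("list", nrow(regions))
  if (nrow(regions) > 0) {
    for (r in seq_len(nrow(regions))) {
      region_mean[[r]] <- rowMeans(beta[, region_idx[[r]], drop = FALSE])
      d <- regions$drug[r]
      if (!d %in% drugs) abort(sprintf("planted drug '%s' not simulated", d))
      auc[, d] <- auc[, d] + regions$auc_effect[r] * region_mean[[r]]
    }
  }
  auc <- pmin(pmax(auc, 1e-6), 1)

  # gene annotation: linked genes get a TSS at their region start (plus
  # strand), remaining genes are scattered over the span
  gene_names <- sprintf("GENE_%04d", seq_len(config$n_genes))
  if (nrow(regions) > 0) {
    gene_names[seq_len(nrow(regions))] <- regions$linked_gene
  }
  gene_tss <- sample.int(config$span_bp, config$n_genes, replace = TRUE)
  gene_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  expr <- matrix(rnorm(n * config$n_genes, mean = config$expr_intercept),
                 n, config$n_genes, dimnames = list(samples, gene_names))
  expr_slopes <- numeric(nrow(regions))
  if (nrow(regions) > 0) {
    for (r in seq_len(nrow(regions))) {
      b <- config$expr_slope * (if (regions$case[r] %in% c(1, 3)) -1 else 1)
      expr_slopes[r] <- b
      expr[, regions$linked_gene[r]] <-
        config$expr_intercept - b * 0.5 + b * region_mean[[r]] +
        rnorm(n, sd = config$expr_sd)
      gene_tss[r] <- positions[region_idx[[r]][1]]
      gene_strand[r] <- "+"
    }
  }
  genes <- tibble(gene = gene_names, chromosome = "chr1",
                  tss = as.integer(gene_tss), strand = gene_strand)

  features <- c("TSS200", "TSS1500", "UTR5", "FirstExon", "Body", "UTR3",
                "Intergenic")
  manifest <- tibble(
    probe_id = probe_ids, chromosome = "chr1", position = as.integer(positions),
    gene = "", feature = sample(features, p, replace = TRUE,
                                prob = c(1, 1, 1, 1, 3, 1, 2)),
    cgi = runif(p) < 0.3, dhs = runif(p) < 0.2, enhancer = runif(p) < 0.1,
    cross_reactive = FALSE,
    start = as.integer(positions) - 1L, end = as.integer(positions))
  if (nrow(regions) > 0) {
    for (r in seq_len(nrow(regions))) {
      manifest$gene[region_idx[[r]]] <- regions$linked_gene[r]
      manifest$feature[region_idx[[r]]] <- "TSS200"
      manifest$cgi[region_idx[[r]]] <- TRUE
    }
  }

  cohort <- pharmaco_cohort(
    beta = matrix_to_tbl(beta), covariates = covariates,
    auc = matrix_to_tbl(auc), expression = matrix_to_tbl(expr),
    manifest = manifest, genes = genes, cohort_tag = "cell_lines")

  truth_regions <- if (nrow(regions) == 0) {
    tibble(region_id = character(0), drug = character(0),
           case = integer(0), linked_gene = character(0),
           chrom = character(0), start = integer(0), end = integer(0),
           probe_ids = list(), shifted_samples = list(),
           auc_effect = numeric(0), expr_slope = numeric(0))
  } else {
    tibble(
      region_id = sprintf("planted_%d", seq_len(nrow(regions))),
      drug = regions$drug, case = regions$case,
      linked_gene = regions$linked_gene, chrom = "chr1",
      start = vapply(region_idx, function(i) positions[i[1]] - 1L, integer(1)),
      end = vapply(region_idx, function(i) positions[i[length(i)]], integer(1)),
      probe_ids = lapply(region_idx, function(i) probe_ids[i]),
      shifted_samples = lapply(shifted, function(i) samples[i]),
      auc_effect = regions$auc_effect, expr_slope = expr_slopes)
  }
  truth <- list(regions = truth_regions, config = config,
                generator = list(mu = mu, positions = positions,
                                 probe_ids = probe_ids,
                                 region_idx = region_idx,
                                 mode_high = mode_high,
                                 loadings = loadings))
  structure(list(cohort = cohort, truth = truth), class = "pharmaco_sim")
}

#' Simulate a null cohort (no planted effects)
#'
#' Identical generative model to [simulate_pharmaco_cohort()] with no
#' planted regions, so AUC is independent of every beta-value.
#'
#' @param config a [sim_config()]; its `planted_regions` are ignored.
#' @returns A [pharmaco_cohort()].
#' @export
simulate_null_scan <- function(config = sim_config()) {
  config$planted_regions <- planted_region()[0, ]
  simulate_pharmaco_cohort(config)$cohort
}

#' Simulate an independent tumour cohort sharing planted regulation
#'
#' Draws new samples from the cell-line generator state and re-plants the
#' region methylation shifts, regenerating each linked gene's expression
#' with the same methylation-expression slope sign when `concordant`, or
#' the flipped sign otherwise. Tumour cohorts carry no drug response table.
#'
#' @param truth truth record from [simulate_pharmaco_cohort()].
#' @param n_tumours number of tumour samples; below 8 a warning is issued
#'   (cohorts that small are excluded downstream).
#' @param concordant keep (`TRUE`) or flip (`FALSE`) the sign of the
#'   methylation-expression slope.
#' @param seed integer seed.
#' @returns A [pharmaco_cohort()] tagged `"tumours"`.
#' @export
simulate_tumour_cohort <- function(truth, n_tumours = 60, concordant = TRUE,
                                   seed = 1) {
  if (n_tumours < 8) {
    warn(sprintf(
      "tumour cohort has %d samples; cohorts below the minimum of 8 are excluded downstream",
      n_tumours))
  }
  config <- truth$config
  gen <- truth$generator
  set.seed(seed)
  n <- n_tumours
  p <- length(gen$mu)
  samples <- sprintf("TU%03d", seq_len(n))
  scores <- cbind(rnorm(n, sd = config$global_factor_sd[1]),
                  rnorm(n, sd = config$global_factor_sd[2]))
  eta <- matrix(gen$mu, n, p, byrow = TRUE) +
    scores %*% t(gen$loadings) +
    ar1_noise(n, p, config$spatial_rho, config$spatial_sd) +
    matrix(rnorm(n * p, sd = config$sample_sd), n, p)
  regions <- truth$regions
  shifted <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    frac <- config$planted_regions$fraction_shifted[r]
    k <- max(1, round(frac * n))
    shifted[[r]] <- sort(sample.int(n, k))
    idx <- gen$region_idx[[r]]
    opposite <- if (regions$auc_effect[r] <= 0) qlogis(0.9) else qlogis(0.1)
    eta[shifted[[r]], idx] <-
      opposite + matrix(rnorm(k * length(idx), sd = 0.3), k, length(idx))
  }
  beta <- plogis(eta)
  dimnames(beta) <- list(samples, gen$probe_ids)

  gene_names <- sprintf("GENE_%04d", seq_len(config$n_genes))
  if (nrow(regions) > 0) gene_names[seq_len(nrow(regions))] <- regions$linked_gene
  expr <- matrix(rnorm(n * config$n_genes, mean = config$expr_intercept),
                 n, config$n_genes, dimnames = list(samples, gene_names))
  for (r in seq_len(nrow(regions))) {
    b <- truth$regions$expr_slope[r] * (if (concordant) 1 else -1)
    rm_beta <- rowMeans(beta[, gen$region_idx[[r]], drop = FALSE])
    expr[, regions$linked_gene[r]] <-
      config$expr_intercept - b * 0.5 + b * rm_beta + rnorm(n, sd = config$expr_sd)
  }
  covariates <- tibble(sample_id = samples, cancer_type = "CT1",
                       medium = "tissue", growth = "tissue", msi = "unknown")
  manifest <- tibble(probe_id = gen$probe_ids, chromosome = "chr1",
                     position = as.integer(gen$positions), gene = "",
                     feature = "Body", cgi = FALSE, dhs = FALSE,
                     enhancer = FALSE, cross_reactive = FALSE,
                     start = as.integer(gen$positions) - 1L,
                     end = as.integer(gen$positions))
  pharmaco_cohort(beta = matrix_to_tbl(beta), covariates = covariates,
                  auc = NULL, expression = matrix_to_tbl(expr),
                  manifest = manifest, cohort_tag = "tumours")
}

#' Build a toy directed signalling network
#'
#' Creates exactly one forward path of `path_length` hops from the
#' biomarker gene to each drug target, plus decoy nodes and edges that are
#' unreachable from the biomarker and therefore cannot create shorter
#' paths.
#'
#' @param biomarker_gene source node name.
#' @param drug_targets character vector of target node names.
#' @param path_length hop count of each planted path (>= 1).
#' @param decoys number of decoy nodes.
#' @returns A tibble edge list (`from`, `to`, `weight`) of class
#'   `signaling_network`.
#' @export
make_toy_network <- function(biomarker_gene, drug_targets, path_length = 5,
                             decoys = 0) {
  stopifnot(path_length >= 1, length(drug_targets) >= 1)
  edges <- list()
  for (tg in drug_targets) {
    if (path_length == 1) {
      chain <- c(biomarker_gene, tg)
    } else {
      mids <- sprintf("STEP_%s_%d", tg, seq_len(path_length - 1))
      chain <- c(biomarker_gene, mids, tg)
    }
    edges[[tg]] <- tibble(from = chain[-length(chain)], to = chain[-1])
  }
  edges <- dplyr::bind_rows(edges)
  if (decoys > 0) {
    dn <- sprintf("DECOY_%02d", seq_len(decoys))
    decoy_edges <- tibble(from = dn[-length(dn)] %||% character(0),
                          to = dn[-1] %||% character(0))
    if (decoys >= 1) {
      # decoys feed into targets but are unreachable from the biomarker
      decoy_edges <- dplyr::bind_rows(
        decoy_edges,
        tibble(from = dn[length(dn)], to = drug_targets[1]))
    }
    edges <- dplyr::bind_rows(edges, decoy_edges)
  }
  as_signaling_network(dplyr::distinct(edges))
}
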