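# Per-CpG models, ACF, Stouffer-Liptak, region extraction, Sidak, filters.

test_that("drug eligibility uses an inclusive AUC bound and responder count", {
  auc <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    good = c(0.6, 0.65, 0.69, 0.9, 0.95, 0.99),
    boundary = c(0.7, 0.7, 0.7, 0.9, 0.9, 0.9),
    two_resp = c(0.5, 0.6, 0.75, 0.9, 0.9, 0.9),
    resistant = c(0.8, 0.9, 0.85, 0.95, 0.71, 0.99))
  el <- eligible_drugs(auc)
  expect_setequal(el$drug, c("good", "boundary"))
  expect_equal(el$n_responders[el$drug == "boundary"], 3L)
})

test_that("cancer types need more than 15 cell lines", {
  cov <- tibble::tibble(
    sample_id = sprintf("s%d", 1:31),
    cancer_type = c(rep("BIG", 16), rep("SMALL", 15)))
  el <- eligible_cancer_types(cov)
  expect_equal(el$cancer_type, "BIG")
  expect_equal(nrow(eligible_cancer_types(cov[0, ])), 0)
})

test_that("methylation PCs match an eigendecomposition oracle up to sign", {
  set.seed(41)
  m <- matrix(runif(30 * 20), 30, 20,
              dimnames = list(sprintf("s%02d", 1:30), NULL))
  pcs <- methylation_pcs(m)
  cm <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(cm %*% t(cm), symmetric = TRUE)
  for (j in 1:2) {
    ref <- ev$vectors[, j] * sqrt(ev$values[j])
    got <- pcs[[paste0("pc", j)]]
    expect_lt(min(max(abs(got - ref)), max(abs(got + ref))), 1e-8)
  }
})

test_that("rank-1 beta matrices put no variance on the second PC", {
  u <- rnorm(20); v <- runif(15)
  m <- outer(u, v)
  rownames(m) <- sprintf("s%02d", 1:20)
  pcs <- methylation_pcs(m)
  expect_lt(var(pcs$pc2) / var(pcs$pc1), 1e-10)
})

test_that("permuting samples permutes PC scores identically", {
  set.seed(7)
  m <- matrix(runif(15 * 12), 15, 12,
              dimnames = list(sprintf("s%02d", 1:15), NULL))
  perm <- sample(15)
  a <- methylation_pcs(m)
  b <- methylation_pcs(m[perm, ])
  expect_equal(b$pc1, a$pc1[perm], tolerance = 1e-10)
  expect_equal(b$pc2, a$pc2[perm], tolerance = 1e-10)
})

test_that("a noiseless linear response is fit exactly", {
  set.seed(1)
  m <- matrix(runif(10), 10, 1, dimnames = list(sprintf("s%d", 1:10), "cg1"))
  cov <- tibble::tibble(sample_id = rownames(m), cancer_type = "CT1",
                        medium = "m", growth = "g", msi = "MSS")
  fit <- fit_cpg_models(m, 2 * m[, 1], cov, NULL)
  expect_equal(fit$beta1, 2, tolerance = 1e-10)
  expect_lt(fit$p_raw, 1e-100)
})

test_that("per-CpG coefficients match the normal-equations oracle", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(12:40, 1)
    m <- matrix(runif(n * 4), n, 4,
                dimnames = list(sprintf("s%02d", 1:n), sprintf("cg%d", 1:4)))
    cov <- tibble::tibble(
      sample_id = rownames(m), cancer_type = "CT1",
      medium = sample(c("a", "b"), n, replace = TRUE),
      growth = sample(c("x", "y"), n, replace = TRUE),
      msi = sample(c("MSI-H", "MSS"), n, replace = TRUE))
    pcs <- methylation_pcs(m)
    y <- rnorm(n)
    fit <- fit_cpg_models(m, y, cov, pcs)
    covd <- cbind(medium = as.numeric(cov$medium == "b"),
                  growth = as.numeric(cov$growth == "y"),
                  msi = as.numeric(cov$msi == "MSS"))
    covd <- covd[, apply(covd, 2, var) > 0, drop = FALSE]
    for (j in seq_len(4)) {
      X <- cbind(1, m[, j], covd, pcs$pc1, pcs$pc2)
      orc <- oracle_ols(X, y)
      row <- fit[fit$probe_id == colnames(m)[j], ]
      expect_equal(row$beta1, unname(orc$coef[2]), tolerance = 1e-8)
      expect_equal(row$t_stat, unname(orc$t[2]), tolerance = 1e-8)
      expect_equal(row$p_raw, unname(orc$p[2]), tolerance = 1e-8)
    }
  }
})

test_that("probes with too few complete observations are skipped", {
  m <- matrix(runif(20), 10, 2,
              dimnames = list(sprintf("s%d", 1:10), c("cg1", "cg2")))
  m[1:4, 2] <- NA
  cov <- tibble::tibble(sample_id = rownames(m), cancer_type = "CT1",
                        medium = "m", growth = "g", msi = "MSS")
  fit <- fit_cpg_models(m, rnorm(10), cov, NULL, min_n = 8)
  expect_equal(fit$probe_id, "cg1")
})

test_that("ACF is zero with a warning when z-scores carry no variance", {
  assoc <- tibble::tibble(probe_id = sprintf("p%03d", 1:20),
                          p_raw = 0.5, t_stat = 1)
  man <- make_manifest(seq(100, by = 100, length.out = 20))
  expect_warning(acf <- estimate_acf(assoc, man), "zero variance")
  expect_true(all(acf$correlation == 0))
})

test_that("i.i.d. p-values give a near-zero, non-negative ACF", {
  set.seed(12)
  p <- runif(500)
  assoc <- tibble::tibble(probe_id = sprintf("p%03d", 1:500), p_raw = p,
                          t_stat = sample(c(-1, 1), 500, replace = TRUE))
  man <- make_manifest(seq(100, by = 100, length.out = 500))
  acf <- estimate_acf(assoc, man)
  expect_true(all(acf$correlation >= 0 & acf$correlation < 0.15))
})

test_that("the lag-1 ACF bin recovers an AR(1) correlation of 0.7", {
  set.seed(13)
  n <- 800
  z <- numeric(n); z[1] <- rnorm(1)
  for (i in 2:n) z[i] <- 0.7 * z[i - 1] + sqrt(1 - 0.49) * rnorm(1)
  p <- 2 * pnorm(-abs(z))
  assoc <- tibble::tibble(probe_id = sprintf("p%04d", 1:n), p_raw = p,
                          t_stat = z)
  man <- make_manifest(seq(250, by = 250, length.out = n),
                       probe_ids = assoc$probe_id)
  acf <- estimate_acf(assoc, man)
  expect_gt(acf$correlation[1], 0.4)
  expect_lt(acf$correlation[1], 0.9)
})

test_that("Stouffer-Liptak reproduces its closed forms", {
  expect_equal(stouffer_liptak(0.37), 0.37)
  # independent evidence: z = 2 * 1.6449 / sqrt(2)
  expect_equal(stouffer_liptak(c(0.05, 0.05), 0),
               1 - pnorm(2 * qnorm(0.95) / sqrt(2)), tolerance = 1e-12)
  expect_equal(round(stouffer_liptak(c(0.05, 0.05), 0), 4), 0.0100)
  # fully redundant evidence collapses to the single-test p
  expect_equal(stouffer_liptak(c(0.05, 0.05), 1), 0.05, tolerance = 1e-12)
})

test_that("Stouffer-Liptak is monotone and matches classic Stouffer at rho 0", {
  set.seed(14)
  for (i in 1:250) {
    k <- sample(2:6, 1)
    p <- runif(k)
    rho <- runif(1, 0, 0.9)
    base <- stouffer_liptak(p, rho)
    j <- sample(k, 1)
    p2 <- p; p2[j] <- p[j] * runif(1)
    expect_lte(stouffer_liptak(p2, rho), base + 1e-12)
    classic <- 1 - pnorm(sum(qnorm(1 - p)) / sqrt(k))
    expect_equal(stouffer_liptak(p, 0), classic, tolerance = 1e-9)
  }
})

test_that("SLK correction leaves isolated sites untouched", {
  assoc <- tibble::tibble(probe_id = c("a", "b"), p_raw = c(0.03, 0.4),
                          t_stat = c(2, 1))
  man <- make_manifest(c(100, 5000), probe_ids = c("a", "b"))
  out <- slk_correct_sites(assoc, make_acf(c(0.5, 0.4, 0.3, 0.2)), man)
  expect_equal(out$p_slk, out$p_raw)
})

test_that("SLK sharpens equally significant neighbours and dilutes against p = 1", {
  man <- make_manifest(c(100, 200, 300))
  equal_sig <- tibble::tibble(probe_id = man$probe_id, p_raw = 0.01,
                              t_stat = 3)
  out <- slk_correct_sites(equal_sig, make_acf(rep(0, 4)), man)
  expect_true(all(out$p_slk < 0.01))
  diluted <- tibble::tibble(probe_id = man$probe_id,
                            p_raw = c(1, 0.01, 1), t_stat = c(0.1, 3, 0.1))
  out2 <- slk_correct_sites(diluted, make_acf(rep(0, 4)), man)
  expect_gte(out2$p_slk[2], 0.01)
})

test_that("region extraction follows the seed/extend/merge rule", {
  corrected <- tibble::tibble(
    probe_id = sprintf("p%d", 1:5), chromosome = "chr1",
    position = c(10L, 110L, 210L, 310L, 1510L),
    p_slk = c(0.5, 1e-8, 1e-8, 1e-8, 0.5))
  reg <- extract_regions(corrected)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$probe_ids[[1]], c("p2", "p3", "p4"))
  expect_equal(reg$start, 109L)
  expect_equal(reg$end, 310L)
})

test_that("seed clusters within 1000 bases merge into one region", {
  corrected <- tibble::tibble(
    probe_id = sprintf("p%d", 1:4), chromosome = "chr1",
    position = c(100L, 150L, 1050L, 1100L),
    p_slk = rep(1e-8, 4))
  reg <- extract_regions(corrected)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$n_probes, 4L)
})

test_that("no seeds means no regions", {
  corrected <- tibble::tibble(probe_id = c("a", "b"), chromosome = "chr1",
                              position = c(100L, 200L), p_slk = c(0.2, 0.6))
  expect_equal(nrow(extract_regions(corrected)), 0)
})

test_that("Sidak adjustment matches its closed form and is monotone", {
  expect_equal(sidak_adjust(0.5, 10, 10), 0.5)
  expect_equal(sidak_adjust(0.01, 7, 70), 1 - 0.99^10, tolerance = 1e-12)
  expect_equal(round(sidak_adjust(0.01, 7, 70), 5), 0.09562)
  p_grid <- c(1e-10, 1e-4, 0.01, 0.3, 0.9)
  for (ntot in c(10, 100, 5000)) {
    expect_equal(sidak_adjust(p_grid, 5, ntot),
                 1 - (1 - p_grid)^max(1, floor(ntot / 5)),
                 tolerance = 1e-9)
  }
  expect_true(all(diff(vapply(c(10, 50, 200, 1000), function(ntot)
    sidak_adjust(0.01, 5, ntot), numeric(1))) >= 0))
})

test_that("region filters enforce aberrant counts and per-probe raw p", {
  man <- make_manifest(c(100, 150, 200), probe_ids = c("a", "b", "c"))
  regions <- tibble::tibble(region_id = "r1", chrom = "chr1", start = 99L,
                            end = 200L, probe_ids = list(c("a", "b", "c")),
                            n_probes = 3L)
  assoc <- tibble::tibble(probe_id = c("a", "b", "c"),
                          beta1 = c(-0.1, -0.2, -0.3),
                          t_stat = c(-9, -9, -9),
                          p_raw = c(1e-9, 1e-9, 1e-9))
  # 30 hypo- and 10 hyper-methylated samples
  beta <- matrix(c(rep(0.1, 30), rep(0.9, 10)), 40, 3,
                 dimnames = list(sprintf("s%02d", 1:40), c("a", "b", "c")))
  acf <- make_acf(rep(0.3, 4))
  kept <- filter_and_score_regions(regions, assoc, beta, acf, man,
                                   n_total_probes = 300)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$effect_size, -0.2)
  expect_equal(kept$n_hypo, 30L)
  expect_equal(kept$n_hyper, 10L)

  # only 3 hypermethylated lines: "more than three" fails
  beta3 <- matrix(c(rep(0.1, 37), rep(0.9, 3)), 40, 3,
                  dimnames = dimnames(beta))
  expect_equal(nrow(filter_and_score_regions(regions, assoc, beta3, acf, man,
                                             n_total_probes = 300)), 0)

  # one constituent probe above raw p 0.01 rejects the region
  assoc2 <- assoc; assoc2$p_raw[2] <- 0.02
  expect_equal(nrow(filter_and_score_regions(regions, assoc2, beta, acf, man,
                                             n_total_probes = 300)), 0)
})

test_that("calling dDMRs twice on the same cohort is deterministic", {
  sim <- simulate_pharmaco_cohort(sim_config(seed = 4))
  a <- suppressMessages(call_ddmrs(sim$cohort))
  b <- suppressMessages(call_ddmrs(sim$cohort))
  expect_identical(tidy(a), tidy(b))
  expect_gt(nrow(tidy(a)), 0)
})
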