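# Candidate genes, M/U groups, Mann-Whitney link tests, empirical null,
# mechanism cases and the expression-drug model.

test_that("promoter mode respects strand-aware windows", {
  region <- tibble::tibble(chrom = "chr1", start = 10000L, end = 10500L)
  genes <- tibble::tibble(
    gene = c("plus_hit", "minus_hit", "plus_miss", "other_chr"),
    chromosome = c("chr1", "chr1", "chr1", "chr2"),
    # + strand: window [tss-2000, tss+200]; - strand: [tss-200, tss+2000]
    tss = c(11500L, 9000L, 14000L, 10100L),
    strand = c("+", "-", "+", "+"))
  hit <- candidate_gene_pairs(region, genes, mode = "promoter")
  expect_setequal(hit$gene, c("plus_hit", "minus_hit"))
})

test_that("distal mode returns the 20 nearest genes, 10 per side when possible", {
  region <- tibble::tibble(chrom = "chr1", start = 50000L, end = 50100L)
  genes <- tibble::tibble(gene = sprintf("g%02d", 1:30), chromosome = "chr1",
                          tss = as.integer(seq(20000, 80000, length.out = 30)),
                          strand = "+")
  got <- candidate_gene_pairs(region, genes, mode = "distal")
  expect_equal(nrow(got), 20)
  mid <- 50050
  expect_equal(sum(genes$tss[match(got$gene, genes$gene)] < mid), 10)
  # chromosome without genes
  empty <- candidate_gene_pairs(tibble::tibble(chrom = "chrZ", start = 1L,
                                               end = 2L), genes, "distal")
  expect_equal(nrow(empty), 0)
})

test_that("M/U group sizes follow the tail-fraction rule", {
  g50 <- define_mu_groups(setNames(runif(50), sprintf("s%d", 1:50)))
  expect_equal(g50$g, 10)
  expect_length(g50$m_samples, 10)
  g20 <- define_mu_groups(setNames(runif(20), sprintf("s%d", 1:20)))
  expect_equal(g20$g, 4)
  constant <- define_mu_groups(setNames(rep(0.5, 30), sprintf("s%d", 1:30)))
  expect_false(constant$testable)
  tiny <- define_mu_groups(setNames(runif(6), sprintf("s%d", 1:6)))
  expect_false(tiny$testable)  # 2 * 4 > 6
})

test_that("M/U groups pick the extreme tails with stable tie order", {
  x <- setNames(c(0.9, 0.1, 0.5, 0.5, 0.95, 0.05, 0.92, 0.08, 0.91, 0.07),
                sprintf("s%d", 1:10))
  gr <- define_mu_groups(x, min_group = 4)
  expect_setequal(gr$u_samples, c("s6", "s8", "s10", "s2"))
  expect_setequal(gr$m_samples, c("s5", "s7", "s9", "s1"))
})

test_that("the Mann-Whitney link test matches hand enumeration", {
  ex <- setNames(c(1, 2, 3, 4, 5, 6), sprintf("s%d", 1:6))
  res <- mwu_link_test(ex, m_samples = c("s1", "s2", "s3"),
                       u_samples = c("s4", "s5", "s6"))
  expect_equal(res$mwu_p, 2 * 1 / 20)     # one-sided 1/20, doubled
  expect_equal(res$direction, -1L)
  tied <- mwu_link_test(setNames(rep(2, 8), sprintf("s%d", 1:8)),
                        sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  expect_equal(tied$mwu_p, 1)
  expect_error(mwu_link_test(ex, c("s1", "s2"), c("s2", "s3")), "overlap")
})

test_that("exact MWU p-values match the enumeration oracle, ties included", {
  set.seed(55)
  for (i in 1:50) {
    nm <- sample(3:7, 1)
    nu <- sample(3:7, 1)
    vals <- if (i %% 2 == 0) sample(1:5, nm + nu, replace = TRUE)
            else rnorm(nm + nu)
    ex <- setNames(vals, sprintf("s%d", seq_len(nm + nu)))
    res <- mwu_link_test(ex, names(ex)[seq_len(nm)], names(ex)[-seq_len(nm)])
    expect_equal(res$mwu_p,
                 oracle_mwu_two_sided(ex[seq_len(nm)], ex[-seq_len(nm)]),
                 tolerance = 1e-12)
  }
})

test_that("an observed p below every permuted p hits the empirical floor", {
  set.seed(8)
  n <- 20
  samples <- sprintf("s%02d", 1:n)
  expr <- tibble::tibble(sample_id = samples)
  expr$linked <- c(rep(0, 10), rep(1, 10)) + rnorm(n, sd = 0.01)
  for (g in sprintf("null%02d", 1:15)) expr[[g]] <- rep(1, n)  # all ties: p = 1
  links <- tibble::tibble(gene = "linked",
                          mwu_p = mwu_link_test(
                            setNames(expr$linked, samples),
                            samples[16:20], samples[1:5])$mwu_p,
                          m_samples = list(samples[16:20]),
                          u_samples = list(samples[1:5]))
  out <- empirical_adjust(links, expr, n_permutations = 400, seed = 2)
  expect_equal(out$emp_p, 1 / 401)
  expect_true(out$significant %in% c(TRUE, FALSE))
})

test_that("empirical p is uniform when the observed gene is itself null", {
  set.seed(9)
  n <- 30
  samples <- sprintf("s%02d", 1:n)
  expr <- tibble::tibble(sample_id = samples)
  for (g in sprintf("g%03d", 1:40)) expr[[g]] <- rnorm(n)
  m_set <- samples[1:6]; u_set <- samples[7:12]
  emp <- vapply(1:200, function(i) {
    gene <- sprintf("g%03d", (i %% 40) + 1)
    obs <- mwu_link_test(setNames(expr[[gene]], samples), m_set, u_set)
    links <- tibble::tibble(gene = gene, mwu_p = obs$mwu_p,
                            m_samples = list(m_set), u_samples = list(u_set))
    out <- empirical_adjust(links, expr, n_permutations = 150,
                            raw_cut = 1.01, seed = i)
    out$emp_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(emp, "punif"))$p.value, 0.01)
})

test_that("the BH stage equals the step-up oracle across tested links", {
  set.seed(10)
  n <- 24
  samples <- sprintf("s%02d", 1:n)
  expr <- tibble::tibble(sample_id = samples)
  for (g in sprintf("g%03d", 1:30)) expr[[g]] <- rnorm(n)
  m_set <- samples[1:5]; u_set <- samples[6:10]
  links <- dplyr::bind_rows(lapply(sprintf("g%03d", 1:12), function(gene) {
    obs <- mwu_link_test(setNames(expr[[gene]], samples), m_set, u_set)
    tibble::tibble(gene = gene, mwu_p = obs$mwu_p,
                   m_samples = list(m_set), u_samples = list(u_set))
  }))
  out <- empirical_adjust(links, expr, n_permutations = 200,
                          raw_cut = 1.01, seed = 3)
  expect_equal(out$emp_adj_p, oracle_bh(out$emp_p), tolerance = 1e-12)
})

test_that("too small a null gene pool is fatal", {
  samples <- sprintf("s%02d", 1:20)
  expr <- tibble::tibble(sample_id = samples, a = rnorm(20), b = rnorm(20))
  links <- tibble::tibble(gene = "a", mwu_p = 0.01,
                          m_samples = list(samples[1:4]),
                          u_samples = list(samples[5:8]))
  expect_error(empirical_adjust(links, expr, n_permutations = 50, seed = 1),
               "at least 10")
})

test_that("mechanism cases map sign combinations and unset on zero", {
  expect_equal(classify_case(-0.1, -0.5), 1L)
  expect_equal(classify_case(-0.1, 0.5), 2L)
  expect_equal(classify_case(0.1, -0.5), 3L)   # the SLFN11 pattern
  expect_equal(classify_case(0.1, 0.5), 4L)
  expect_true(is.na(classify_case(0, 0.4)))
  expect_true(is.na(classify_case(-0.2, 0)))
  # labels partition every nonzero sign combination
  grid <- expand.grid(e = c(-1, 1), r = c(-1, 1))
  expect_setequal(classify_case(grid$e, grid$r), 1:4)
})

test_that("the expression-drug model is exact and matches the OLS oracle", {
  set.seed(11)
  n <- 25
  cov <- tibble::tibble(sample_id = sprintf("s%d", 1:n), cancer_type = "CT1",
                        medium = sample(c("a", "b"), n, TRUE),
                        growth = "g", msi = sample(c("h", "l"), n, TRUE))
  ex <- rnorm(n)
  exact <- expression_drug_model(ex, 0.5 * ex, cov)
  expect_equal(exact$slope, 0.5, tolerance = 1e-10)
  expect_lt(exact$p, 1e-200)
  for (i in 1:25) {
    y <- rnorm(n)
    pcs <- tibble::tibble(pc1 = rnorm(n), pc2 = rnorm(n))
    got <- expression_drug_model(ex, y, cov, pcs)
    X <- cbind(ex, 1, medium = as.numeric(cov$medium == "b"),
               msi = as.numeric(cov$msi == "l"), pcs$pc1, pcs$pc2)
    orc <- oracle_ols(X, y)
    expect_equal(got$slope, unname(orc$coef[1]), tolerance = 1e-8)
    expect_equal(got$p, unname(orc$p[1]), tolerance = 1e-8)
  }
})

test_that("a planted Case-1 cohort yields a significant Case-1 link", {
  sim <- simulate_pharmaco_cohort(sim_config(seed = 3))
  res <- suppressMessages(call_ddmrs(sim$cohort))
  links <- suppressMessages(link_dmr_expression(
    res, sim$cohort, n_permutations = 2000, seed = 3))
  l <- links$links
  planted <- l[l$gene == sim$truth$regions$linked_gene, ]
  expect_gt(nrow(planted), 0)
  expect_true(any(planted$significant))
  expect_true(all(planted$case[planted$significant] == 1L))
  expect_true(all(planted$direction[planted$significant] == -1L))
})
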