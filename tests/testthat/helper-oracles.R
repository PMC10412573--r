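# Independent oracles used across tests. Each re-derives the quantity a
# package function computes, through a different route (normal equations,
# exhaustive enumeration, closed forms), so agreement is informative.

# OLS by explicit normal equations: (X'X)^-1 X'y with textbook t-tests
oracle_ols <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  coef <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% coef)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(xtx_inv) * sigma2)
  t <- coef / se
  list(coef = coef, se = se, t = t, p = 2 * pt(-abs(t), df), df = df)
}

# exhaustive two-sided Mann-Whitney p over all assignments of the pooled
# values to the first group, via the U statistic computed from scratch
oracle_mwu_two_sided <- function(x_m, x_u) {
  pooled <- c(x_m, x_u)
  nm <- length(x_m)
  u_stat <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(seq_len(nm))
  eps <- 1e-9
  u_all <- apply(combn(length(pooled), nm), 2, u_stat)
  p_less <- mean(u_all <= u_obs + eps)
  p_greater <- mean(u_all >= u_obs - eps)
  min(1, 2 * min(p_less, p_greater))
}

# Benjamini-Hochberg step-up from its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# hypergeometric upper tail by direct summation of the density
oracle_hyper_tail <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# all simple directed paths from an edge tibble, sorted by (weight, lex)
oracle_all_paths_sorted <- function(edges, source, target) {
  adj <- split(edges$to, edges$from)
  wt <- setNames(edges$weight, paste0(edges$from, "->", edges$to))
  paths <- list()
  walk <- function(node, path, w) {
    if (node == target) {
      paths[[length(paths) + 1]] <<- list(nodes = path, weight = w)
      return(invisible())
    }
    for (nxt in adj[[node]] %||% character(0)) {
      if (nxt %in% path) next
      walk(nxt, c(path, nxt), w + wt[[paste0(node, "->", nxt)]])
    }
  }
  if (source == target) return(list(list(nodes = source, weight = 0)))
  walk(source, source, 0)
  if (length(paths) == 0) return(list())
  key <- vapply(paths, function(p)
    paste(sprintf("%012.4f", p$weight),
          paste(p$nodes, collapse = "\001")), character(1))
  paths[order(key, method = "radix")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# distance-binned ACF table of the class estimate_acf returns
make_acf <- function(correlations, bin_width = 250) {
  n <- length(correlations)
  structure(
    tibble::tibble(lag_min = (seq_len(n) - 1) * bin_width,
                   lag_max = seq_len(n) * bin_width,
                   correlation = correlations,
                   n_pairs = rep(1000L, n)),
    class = c("acf_estimate", "tbl_df", "tbl", "data.frame"))
}

# minimal manifest for hand-built probe layouts
make_manifest <- function(positions, chrom = "chr1",
                          probe_ids = sprintf("p%03d", seq_along(positions))) {
  tibble::tibble(probe_id = probe_ids, chromosome = chrom,
                 position = as.integer(positions), gene = "",
                 feature = "Body", cgi = FALSE, dhs = FALSE,
                 enhancer = FALSE, cross_reactive = FALSE,
                 start = as.integer(positions) - 1L,
                 end = as.integer(positions))
}

# (region, gene) null link table over the probe clusters of a cohort,
# used by the empirical-FDR simulations
build_cluster_links <- function(cohort, genes_per_cluster = 8, seed = 1) {
  bm <- as.matrix(cohort$beta[-1])
  rownames(bm) <- cohort$beta$sample_id
  cl <- cumsum(c(TRUE, diff(cohort$manifest$position) > 1000))
  em_genes <- colnames(cohort$expression)[-1]
  set.seed(seed)
  rows <- list()
  for (g in unique(cl)) {
    rmb <- rowMeans(bm[, cl == g, drop = FALSE])
    gr <- define_mu_groups(rmb)
    if (!gr$testable) next
    for (gn in sample(em_genes, genes_per_cluster)) {
      tst <- mwu_link_test(setNames(cohort$expression[[gn]],
                                    cohort$expression$sample_id),
                           gr$m_samples, gr$u_samples)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = gn, mwu_p = tst$mwu_p,
        m_samples = list(gr$m_samples), u_samples = list(gr$u_samples))
    }
  }
  dplyr::bind_rows(rows)
}
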