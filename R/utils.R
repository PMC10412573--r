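# Shared numeric helpers: OLS with t-statistics, design assembly, p clipping.

# p-value clipping bounds used before any z-transform
.P_LO <- 1e-300
.P_HI <- 1 - 1e-16

clip_p <- function(p) pmin(pmax(p, .P_LO), .P_HI)

#' Ordinary least squares with per-coefficient t-tests
#'
#' Minimal OLS fit used by the per-CpG and expression-drug models. Returns
#' the full coefficient vector together with standard errors, t statistics
#' and two-sided p-values at the residual degrees of freedom.
#'
#' @param X numeric design matrix (including the intercept column).
#' @param y numeric response vector.
#' @returns A list with `coef`, `se`, `t`, `p` (named per column of `X`),
#'   `df` residual degrees of freedom, and `ok = FALSE` when the design is
#'   rank deficient or leaves no residual degrees of freedom.
#' @keywords internal
ols_fit <- function(X, y) {
  n <- nrow(X)
  qx <- qr(X)
  k <- ncol(X)
  if (qx$rank < k || n - k < 1) {
    return(list(ok = FALSE, coef = NULL, se = NULL, t = NULL, p = NULL,
                df = n - qx$rank))
  }
  coef <- qr.coef(qx, y)
  res <- y - qr.fitted(qx, y)
  df <- n - k
  sigma2 <- sum(res^2) / df
  # unscaled covariance from the (pivoted) R factor
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  pivot <- qx$pivot
  se <- numeric(k)
  se[pivot] <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  names(se) <- colnames(X)
  tval <- ifelse(se > 0, coef / se, sign(coef) * Inf)
  pval <- clip_p(2 * pt(-abs(tval), df))
  list(ok = TRUE, coef = coef, se = se, t = tval, p = pval, df = df)
}

# One-hot design columns for the categorical covariates (screening medium,
# growth properties, MSI status), reference level = lexicographically first.
# Covariates with a single observed level contribute no columns.
covariate_design <- function(covariates,
                             cols = c("medium", "growth", "msi")) {
  cols <- intersect(cols, names(covariates))
  mats <- lapply(cols, function(cl) {
    x <- as.character(covariates[[cl]])
    lev <- sort(unique(x))
    if (length(lev) < 2) return(NULL)
    m <- vapply(lev[-1], function(l) as.numeric(x == l),
                numeric(length(x)))
    colnames(m) <- paste0(cl, lev[-1])
    m
  })
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (length(mats) == 0) {
    matrix(numeric(0), nrow = nrow(covariates), ncol = 0)
  } else {
    do.call(cbind, mats)
  }
}

# Drop constant (zero-variance) columns, never the intercept.
drop_constant_cols <- function(X) {
  keep <- apply(X, 2, function(col) length(unique(col)) > 1)
  if ("(Intercept)" %in% colnames(X)) keep[colnames(X) == "(Intercept)"] <- TRUE
  X[, keep, drop = FALSE]
}

# samples-by-features tibble (first column = sample id) -> numeric matrix
tbl_to_matrix <- function(tbl, id_col = "sample_id") {
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- tbl[[id_col]]
  storage.mode(m) <- "double"
  m
}

matrix_to_tbl <- function(m, id_col = "sample_id") {
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}
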