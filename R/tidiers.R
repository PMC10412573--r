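# broom-style tidy()/glance() and ggplot2 autoplot() methods for the
# result objects.

#' @exportS3Method generics::tidy
tidy.ddmr_result <- function(x, ...) {
  out <- x$ddmrs
  out$probe_ids <- NULL
  as_tibble(out)
}

#' @exportS3Method generics::glance
glance.ddmr_result <- function(x, ...) {
  tibble(n_scans = nrow(x$scans),
         n_failed_scans = sum(x$scans$status == "failed"),
         n_ddmrs = nrow(x$ddmrs),
         n_drugs = length(unique(x$ddmrs$drug)),
         n_cancer_types = length(unique(x$ddmrs$cancer_type)),
         median_probes = if (nrow(x$ddmrs) > 0)
           stats::median(x$ddmrs$n_probes) else NA_real_)
}

#' Effect-size overview of called dDMRs
#'
#' Plots each dDMR's effect size (mean slope of AUC on beta) against its
#' Sidak-adjusted p-value, sized by probe count; negative effects mark
#' regions whose hypermethylation confers sensitivity.
#'
#' @param object a `ddmr_result`.
#' @param ... unused.
#' @returns A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ddmr_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effect_size,
                                  y = -log10(.data$sidak_p),
                                  size = .data$n_probes,
                                  colour = .data$drug)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "dDMR effect size (AUC per beta unit)",
                  y = expression(-log[10] ~ "adj. p"),
                  size = "CpG sites", colour = "drug") +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.link_result <- function(x, ...) {
  out <- x$links
  out$probe_ids <- NULL
  out$m_samples <- NULL
  out$u_samples <- NULL
  as_tibble(out)
}

#' @exportS3Method generics::glance
glance.link_result <- function(x, ...) {
  l <- x$links
  tibble(n_links = nrow(l),
         n_tested = sum(!is.na(l$emp_p)),
         n_significant = sum(l$significant),
         n_case1 = sum(l$case == 1, na.rm = TRUE),
         n_case2 = sum(l$case == 2, na.rm = TRUE),
         n_case3 = sum(l$case == 3, na.rm = TRUE),
         n_case4 = sum(l$case == 4, na.rm = TRUE))
}

#' Mechanism-case map of methylation-expression links
#'
#' Scatter of dDMR effect size against the methylation-expression
#' correlation; the four quadrants correspond to the four mechanism
#' cases.
#'
#' @param object a `link_result`.
#' @param ... unused.
#' @returns A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.link_result <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$pearson_r), , drop = FALSE]
  d$label <- ifelse(is.na(d$case), "not significant",
                    paste("Case", d$case))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effect_size,
                                  y = .data$pearson_r,
                                  colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "dDMR effect size (AUC per beta unit)",
                  y = "methylation-expression Pearson r",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.tgddmr_result <- function(x, ...) {
  out <- x$links
  out$probe_ids <- NULL
  out$m_samples <- NULL
  out$u_samples <- NULL
  as_tibble(out)
}

#' @exportS3Method generics::glance
glance.tgddmr_result <- function(x, ...) {
  tibble(n_candidates = nrow(x$links),
         n_tgddmr = sum(x$links$tgddmr))
}

#' Write expression links to TSV
#'
#' Flattens list-columns (comma-joined probe ids, group sizes) and writes
#' a deterministic TSV.
#'
#' @param links a `link_result`, `tgddmr_result`, or links tibble.
#' @param path output path.
#' @returns Invisibly, the path.
#' @export
write_links_tsv <- function(links, path) {
  if (inherits(links, "link_result") || inherits(links, "tgddmr_result")) {
    links <- links$links
  }
  flat <- links
  for (cl in intersect(c("probe_ids"), names(flat))) {
    flat[[cl]] <- vapply(flat[[cl]], paste, character(1), collapse = ",")
  }
  for (cl in intersect(c("m_samples", "u_samples"), names(flat))) {
    flat[[paste0("n_", sub("_samples", "", cl))]] <-
      vapply(flat[[cl]], length, integer(1))
    flat[[cl]] <- NULL
  }
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
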