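#' Nonparametric group comparison
#'
#' Kruskal-Wallis omnibus test followed by Dunn's multiple-comparison post
#' hoc (pairwise rank-based z statistics with tie correction,
#' Bonferroni-adjusted over the number of pairs), the procedure used for
#' comparing per-condition Raman indices. Summaries are reported as
#' mean +/- SE.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values` (or a named list of
#'   numeric vectors in place of `values`, with `groups` missing).
#' @return A list of class `group_comparison` with elements `summary`
#'   (data.frame: group, n, mean, se), `kruskal_p` (omnibus p-value),
#'   `kruskal_statistic`, and `posthoc` (data.frame: group1, group2, z,
#'   p_raw, p_adj).
#' @export
group_compare <- function(values, groups) {
  if (missing(groups)) {
    if (!is.list(values) || is.null(names(values))) {
      stop_ramanredox("provide (values, groups) or a named list of vectors",
                      "ramanredox_validation_error")
    }
    if (any(lengths(values) < 1)) {
      stop_ramanredox("every group needs at least one observation",
                      "ramanredox_validation_error")
    }
    groups <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  values <- as.numeric(values)
  groups <- as.character(groups)
  if (length(values) != length(groups)) {
    stop_ramanredox("values and groups must have equal length",
                    "ramanredox_validation_error")
  }
  labs <- unique(groups)
  if (length(labs) < 2) {
    stop_ramanredox("need at least two groups", "ramanredox_validation_error")
  }
  n_per <- table(factor(groups, levels = labs))
  if (any(n_per < 1) || anyNA(values)) {
    stop_ramanredox("every group needs at least one finite observation",
                    "ramanredox_validation_error")
  }

  summary_df <- data.frame(
    group = labs,
    n = as.integer(n_per[labs]),
    mean = vapply(labs, function(g) mean(values[groups == g]), numeric(1)),
    se = vapply(labs, function(g) {
      v <- values[groups == g]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    }, numeric(1)),
    row.names = NULL
  )

  all_tied <- length(unique(values)) == 1
  if (all_tied) {
    ## degenerate case: identical observations everywhere -> no evidence
    pairs <- utils::combn(labs, 2)
    posthoc <- data.frame(
      group1 = pairs[1, ], group2 = pairs[2, ],
      z = 0, p_raw = 1, p_adj = 1, row.names = NULL
    )
    out <- list(summary = summary_df, kruskal_statistic = 0, kruskal_p = 1,
                posthoc = posthoc)
    class(out) <- "group_comparison"
    return(out)
  }

  kw <- stats::kruskal.test(values, factor(groups, levels = labs))
  posthoc <- dunn_posthoc(values, groups, labs)
  out <- list(summary = summary_df,
              kruskal_statistic = unname(kw$statistic),
              kruskal_p = kw$p.value,
              posthoc = posthoc)
  class(out) <- "group_comparison"
  out
}

## Dunn's pairwise z tests on the joint ranks, with tie correction
## z_ij = (Rbar_i - Rbar_j) / sqrt( (N(N+1)/12 - T) * (1/n_i + 1/n_j) ),
## T = sum(t^3 - t) / (12 (N - 1)); p_adj = Bonferroni over the pairs.
dunn_posthoc <- function(values, groups, labs) {
  N <- length(values)
  rk <- rank(values)
  rbar <- vapply(labs, function(g) mean(rk[groups == g]), numeric(1))
  nn <- vapply(labs, function(g) sum(groups == g), numeric(1))
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(labs, 2)
  m <- ncol(pairs)
  z <- p_raw <- numeric(m)
  for (k in seq_len(m)) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    sd_ij <- sqrt((N * (N + 1) / 12 - tie_corr) *
                    (1 / nn[[g1]] + 1 / nn[[g2]]))
    z[k] <- (rbar[[g1]] - rbar[[g2]]) / sd_ij
    p_raw[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = z, p_raw = p_raw, p_adj = pmin(1, p_raw * m),
             row.names = NULL)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  cat(sprintf("  Kruskal-Wallis: H = %.3f, p = %.4g\n",
              x$kruskal_statistic, x$kruskal_p))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %s: %.4g +/- %.2g (n = %d)\n", x$summary$group[i],
                x$summary$mean[i], x$summary$se[i], x$summary$n[i]))
  }
  cat("  Dunn post hoc (adjusted):\n")
  for (i in seq_len(nrow(x$posthoc))) {
    cat(sprintf("    %s vs %s: z = %.3f, p = %.4g\n", x$posthoc$group1[i],
                x$posthoc$group2[i], x$posthoc$z[i], x$posthoc$p_adj[i]))
  }
  invisible(x)
}
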