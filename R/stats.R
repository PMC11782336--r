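# Cohort statistics: Spearman correlation, Bland-Altman method comparison,
# Wilcoxon tests with a pinned exact/approximate switch, the VDP
# correlation table with family-specific Bonferroni levels, and
# median/IQR cohort summaries. The pipeline always takes the nonparametric
# branch; quartiles use the linear-interpolation convention throughout.

# Exact Wilcoxon p-values are used up to this sample size (per group),
# falling back to the normal approximation (with tie/continuity
# correction) above it or whenever ties make the exact distribution
# unavailable.
EXACT_N_MAX <- 25

#' Spearman rank correlation with midranks
#'
#' @param x,y Paired numeric vectors of equal length >= 3.
#' @return List with `r` (rho in `[-1, 1]`) and `p` (two-sided).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_lungvent("need paired vectors of equal length >= 3",
                  class = "lungvent_value_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_lungvent("correlation undefined for a constant vector",
                  class = "lungvent_value_error")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Bland-Altman method comparison
#'
#' Differences `d = x - y` are summarised by their mean bias and 95%
#' limits of agreement `bias +- 1.96 * SD(d)` (sample SD), with a paired
#' Wilcoxon signed-rank p-value for a systematic difference (exact for
#' n <= 25 without ties, normal approximation otherwise).
#'
#' @param x,y Paired numeric vectors.
#' @return An object of class `bland_altman_result`: `mean_bias`,
#'   `loa_low`, `loa_high`, `p_paired`, `n`, and `note` for degenerate
#'   data.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_lungvent("need paired vectors of equal length >= 2",
                  class = "lungvent_value_error")
  }
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  note <- NULL
  if (all(d == 0)) {
    p <- 1
    note <- "all paired differences are zero"
  } else {
    exact <- length(d) <= EXACT_N_MAX && !any(duplicated(abs(d[d != 0]))) &&
      all(d != 0)
    p <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = exact)$p.value)
  }
  structure(list(mean_bias = bias,
                 loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s,
                 p_paired = p,
                 n = length(d),
                 note = note),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean bias %.2f (LoA %.2f to %.2f), paired p = %.4g, n = %d\n",
              x$mean_bias, x$loa_low, x$loa_high, x$p_paired, x$n))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact for small samples without ties (both groups at most 25), normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param a,b Numeric samples.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop_lungvent("both samples must be non-empty",
                  class = "lungvent_value_error")
  }
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) <= EXACT_N_MAX && length(b) <= EXACT_N_MAX
  suppressWarnings(stats::wilcox.test(a, b, exact = exact)$p.value)
}

#' VDP correlation table
#'
#' Spearman correlations of each proton-derived VDP (RVent, FVL-CM,
#' Combined) with the gas VDP, and of all four VDP measures with the
#' spirometry columns, with family-specific Bonferroni-adjusted
#' significance levels: `xe_alpha` (default 0.0167, three VDP-vs-VDP
#' comparisons) and `spiro_alpha` (default 0.0125, four markers per
#' spirometry outcome).
#'
#' @param records Data frame with columns `vdp_rvent`, `vdp_fvlcm`,
#'   `vdp_combined`, `vdp_xe` and optionally `fev1_pct`, `fvc_pct`,
#'   `fev1_fvc_pct`.
#' @param xe_alpha Significance level for VDP-vs-VDP cells.
#' @param spiro_alpha Significance level for VDP-vs-spirometry cells.
#' @return Data frame with one row per (marker, outcome) pair: `r`, `p`,
#'   `alpha`, `significant`, `n`. Cells with fewer than 3 complete pairs
#'   are returned with NA statistics.
#' @export
vdp_correlation_table <- function(records, xe_alpha = 0.0167,
                                  spiro_alpha = 0.0125) {
  markers <- c("vdp_rvent", "vdp_fvlcm", "vdp_combined")
  spiro <- intersect(c("fev1_pct", "fvc_pct", "fev1_fvc_pct"),
                     names(records))
  rows <- list()
  add_row <- function(marker, outcome, alpha) {
    x <- records[[marker]]; y <- records[[outcome]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      rows[[length(rows) + 1]] <<- data.frame(
        marker = marker, outcome = outcome, r = NA_real_, p = NA_real_,
        alpha = alpha, significant = NA, n = sum(ok))
      return(invisible())
    }
    sc <- spearman_cor(x[ok], y[ok])
    rows[[length(rows) + 1]] <<- data.frame(
      marker = marker, outcome = outcome, r = sc$r, p = sc$p, alpha = alpha,
      significant = sc$p < alpha, n = sum(ok))
  }
  for (m in markers) add_row(m, "vdp_xe", xe_alpha)
  for (s in spiro) {
    for (m in c(markers, "vdp_xe")) add_row(m, s, spiro_alpha)
  }
  do.call(rbind, rows)
}

#' Cohort summary table
#'
#' Per-group median and interquartile range (linear-interpolation quartile
#' convention) for every numeric column, with a between-group Wilcoxon
#' rank-sum p-value when two groups are present.
#'
#' @param records Data frame with a `group` column and numeric columns.
#' @param group_col Name of the grouping column.
#' @return Data frame with one row per (column, group): `median`, `q1`,
#'   `q3`, `n`, plus a `p_between` column (NA when fewer than two groups).
#' @export
cohort_summary <- function(records, group_col = "group") {
  if (!group_col %in% names(records)) {
    stop_lungvent("records must carry a '", group_col, "' column",
                  class = "lungvent_value_error")
  }
  groups <- sort(unique(as.character(records[[group_col]])))
  num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  rows <- list()
  for (col in num_cols) {
    p <- NA_real_
    if (length(groups) == 2) {
      a <- records[[col]][records[[group_col]] == groups[1]]
      b <- records[[col]][records[[group_col]] == groups[2]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) > 0 && length(b) > 0) p <- wilcoxon_rank_sum(a, b)
    }
    for (g in groups) {
      v <- records[[col]][records[[group_col]] == g]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1]] <- data.frame(
        column = col, group = g,
        median = if (length(v)) stats::median(v) else NA_real_,
        q1 = if (length(v)) percentile_linear(v, 0.25) else NA_real_,
        q3 = if (length(v)) percentile_linear(v, 0.75) else NA_real_,
        n = length(v), p_between = p)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a rank-correlated pair of cohort measures
#'
#' Draws `n` pairs from a Gaussian copula whose linear correlation is
#' chosen so the population Spearman correlation equals `rho_s`
#' (`rho = 2 sin(pi * rho_s / 6)`), then maps the margins to positive
#' VDP-like scales. Used to validate rank-correlation recovery.
#'
#' @param n Number of subjects.
#' @param rho_s Target Spearman correlation.
#' @param seed Integer seed.
#' @return Data frame with columns `x` and `y`.
#' @export
simulate_rank_correlated <- function(n, rho_s, seed = 1L) {
  rho <- 2 * sin(pi * rho_s / 6)
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    # monotone margin transforms: Spearman correlation is unaffected
    data.frame(x = 50 * stats::pnorm(z1), y = 40 * stats::pnorm(z2)^1.5)
  })
}
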