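#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction, referred to a chi-square
#' distribution with k - 1 degrees of freedom (the convention of standard
#' statistical software, and the one used for the tissue comparisons here).
#' When all observations are identical, H = 0 and p = 1.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List with `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(!vapply(groups, length, 1L)))
    stop("need >= 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, p_value = 1, df = length(groups) - 1L))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Mann-Whitney U test
#'
#' Two-sided. The U statistic follows the x-based convention (number of
#' pairs with x > y, counting ties as 1/2), so `U = 0` when every x is below
#' every y and swapping the samples maps U to `n_x * n_y - U`. The p-value is
#' exact by enumeration when the combined sample size is <= 12 and there are
#' no ties; otherwise the normal approximation with tie and continuity
#' correction is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `U`, `p_value`, `exact`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = min(wt$p.value, 1), exact = exact)
}

#' Pearson product-moment correlation
#'
#' Two-sided p-value from the t distribution with n - 2 degrees of freedom.
#' Zero variance in either argument leaves the coefficient undefined; this is
#' reported via the `undefined` flag rather than as 0.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r`, `p_value`, `n`, `undefined`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length samples with n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                undefined = TRUE))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       undefined = FALSE)
}

#' Collagen-content correlations with the phase metrics
#'
#' Computes the two headline correlations across all sutures pooled over
#' tissues — collagen/protein content versus the percent loss in the rapid
#' cutting phase, and versus the plateau-to-peak percentage — plus the same
#' pair computed on tissue means (a secondary, n = number-of-tissues record).
#'
#' @param metrics Tibble from [analyze_traces()].
#' @param collagen Tibble with `suture_id`, `tissue`, `collagen_ug_per_mg`.
#' @return Tibble with columns `variable`, `scope`, `r`, `p_value`, `n`,
#'   `undefined`.
#' @export
collagen_correlations <- function(metrics, collagen) {
  orphans <- c(setdiff(metrics$suture_id, collagen$suture_id),
               setdiff(collagen$suture_id, metrics$suture_id))
  if (length(orphans))
    stop("validation error: unmatched suture_ids: ",
         paste(orphans, collapse = ", "))
  m <- merge(as.data.frame(metrics),
             as.data.frame(collagen)[c("suture_id", "collagen_ug_per_mg")],
             by = "suture_id")
  vars <- c(rcp_loss_pct = "rcp_loss_pct",
            plateau_ratio_pct = "plateau_ratio_pct")
  pooled <- lapply(names(vars), function(v) {
    ct <- pearson_correlation(m$collagen_ug_per_mg, m[[vars[[v]]]])
    tibble::tibble(variable = paste0("collagen_vs_", v), scope = "pooled",
                   r = ct$r, p_value = ct$p_value, n = ct$n,
                   undefined = ct$undefined)
  })
  agg <- aggregate(m[c("collagen_ug_per_mg", unname(vars))],
                   by = list(tissue = m$tissue), FUN = mean, na.rm = TRUE)
  by_tissue <- lapply(names(vars), function(v) {
    ct <- if (nrow(agg) >= 3)
      pearson_correlation(agg$collagen_ug_per_mg, agg[[vars[[v]]]])
    else list(r = NA_real_, p_value = NA_real_, n = nrow(agg), undefined = TRUE)
    tibble::tibble(variable = paste0("collagen_vs_", v), scope = "tissue_mean",
                   r = ct$r, p_value = ct$p_value, n = ct$n,
                   undefined = ct$undefined)
  })
  do.call(rbind, c(pooled, by_tissue))
}

#' @importFrom stats aggregate
summarize_metric <- function(values, tissues, censored = NULL) {
  rows <- lapply(split(seq_along(values), tissues), function(idx) {
    v <- values[idx]
    cen <- if (is.null(censored)) rep(FALSE, length(v)) else censored[idx]
    n_cen <- sum(cen)
    v_use <- v[!cen & !is.na(v)]
    tibble::tibble(
      n = length(idx), n_censored = n_cen,
      mean = if (length(v_use)) mean(v_use) else NA_real_,
      sd = if (length(v_use) >= 2L) sd(v_use) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$tissue <- names(rows)
  out[c("tissue", "n", "n_censored", "mean", "sd")]
}

#' Tissue-level summary of a suture cohort
#'
#' Aggregates per-suture phase metrics, fit results, and collagen content to
#' tissue level (mean and sample SD, n - 1 denominator), runs the
#' Kruskal-Wallis omnibus test per metric across tissues, follows up with
#' pairwise Mann-Whitney tests only where the omnibus is significant at 0.05
#' (no multiple-testing correction is applied — mirroring the original
#' analysis; interpret pairwise p-values accordingly), and computes the
#' collagen correlations. Censored half-tension times are excluded from the
#' mean and reported via a censored count (the "> record length" convention);
#' a tissue with a single suture gets a missing SD, not zero.
#'
#' @param metrics Tibble from [analyze_traces()].
#' @param fits Optional tibble from [fit_traces()] (adds the per-minute
#'   decline row).
#' @param collagen Optional collagen tibble (adds the collagen row and the
#'   correlations).
#' @param alpha Significance threshold gating the pairwise tests.
#' @return An object of class `cohort_summary`: list with `tissue_summary`
#'   (long tibble: tissue, metric, n, n_censored, mean, sd), `omnibus`,
#'   `pairwise`, `correlations`.
#' @export
summarize_by_tissue <- function(metrics, fits = NULL, collagen = NULL,
                                alpha = 0.05) {
  stopifnot(is.data.frame(metrics))
  m <- as.data.frame(metrics)
  if (!is.null(fits))
    m <- merge(m, as.data.frame(fits)[c("suture_id", "decline_pct_per_min")],
               by = "suture_id", all.x = TRUE)
  if (!is.null(collagen))
    m <- merge(m, as.data.frame(collagen)[c("suture_id", "collagen_ug_per_mg")],
               by = "suture_id", all.x = TRUE)
  metric_cols <- intersect(
    c("p0", "p1", "pplat", "rcp_loss_pct", "decline_pct_per_min",
      "plateau_ratio_pct", "half_time_min", "collagen_ug_per_mg"),
    names(m))
  summ <- lapply(metric_cols, function(col) {
    cen <- if (col == "half_time_min") m$half_time_censored else NULL
    s <- summarize_metric(m[[col]], m$tissue, cen)
    s$metric <- col
    s
  })
  tissue_summary <- do.call(rbind, summ)
  tissue_summary <- tibble::as_tibble(
    tissue_summary[c("metric", "tissue", "n", "n_censored", "mean", "sd")])

  omnibus <- list(); pairwise <- list()
  for (col in metric_cols) {
    keep <- !is.na(m[[col]])
    if (col == "half_time_min") keep <- keep & !m$half_time_censored
    groups <- split(m[[col]][keep], m$tissue[keep])
    groups <- groups[lengths(groups) > 0L]
    if (length(groups) < 2L || sum(lengths(groups) >= 2) < 2L) next
    kw <- kruskal_wallis(groups)
    omnibus[[col]] <- tibble::tibble(metric = col, H = kw$H,
                                     p_value = kw$p_value, df = kw$df)
    if (is.finite(kw$p_value) && kw$p_value < alpha) {
      prs <- utils::combn(names(groups), 2L, simplify = FALSE)
      for (pr in prs) {
        mw <- mann_whitney(groups[[pr[1L]]], groups[[pr[2L]]])
        pairwise[[paste(col, pr[1L], pr[2L])]] <- tibble::tibble(
          metric = col, tissue_a = pr[1L], tissue_b = pr[2L],
          U = mw$U, p_value = mw$p_value, exact = mw$exact)
      }
    }
  }
  correlations <- if (!is.null(collagen))
    collagen_correlations(metrics, collagen) else NULL
  structure(list(tissue_summary = tissue_summary,
                 omnibus = if (length(omnibus)) do.call(rbind, omnibus) else NULL,
                 pairwise = if (length(pairwise)) do.call(rbind, pairwise) else NULL,
                 correlations = correlations,
                 n = nrow(m)),
            class = "cohort_summary")
}

#' Render a cohort summary as a tissue-characteristics table
#'
#' One row per metric, one column per tissue, cells as `mean +/- sd`;
#' all-censored half-time cells are rendered as `> <record length>`, matching
#' the lower-bound convention.
#'
#' @param summary A [summarize_by_tissue()] result.
#' @param digits Significant digits for the cells.
#' @return Character vector of markdown table lines.
#' @export
format_summary_table <- function(summary, digits = 2) {
  stopifnot(inherits(summary, "cohort_summary"))
  ts <- summary$tissue_summary
  labels <- c(p0 = "P0 in N", p1 = "P1 in N", pplat = "Pplat in N",
              rcp_loss_pct = "Decrease of tension in the RCP in %",
              decline_pct_per_min = "Decrease of tension in the CDP per minute in %",
              plateau_ratio_pct = "Relation of Pplat to P0 in %",
              half_time_min = "Time after half of the tension is reached in min",
              collagen_ug_per_mg = "Collagen/Protein content in ug/mg")
  tissues <- unique(ts$tissue)
  lines <- c(paste0("| Metric | ", paste(tissues, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(tissues) + 1L),
                               collapse = "|"), "|"))
  for (metric in intersect(names(labels), unique(ts$metric))) {
    cells <- vapply(tissues, function(tt) {
      row <- ts[ts$metric == metric & ts$tissue == tt, ]
      if (!nrow(row) || (is.na(row$mean) && row$n_censored == 0))
        return("-")
      if (metric == "half_time_min" && row$n_censored == row$n)
        return("> 60")
      cell <- signif(row$mean, digits)
      if (!is.na(row$sd)) cell <- paste0(cell, " ± ", signif(row$sd, digits))
      if (metric == "half_time_min" && row$n_censored > 0)
        cell <- paste0(cell, " (", row$n_censored, " censored)")
      as.character(cell)
    }, character(1L))
    lines <- c(lines, paste0("| ", labels[[metric]], " | ",
                             paste(cells, collapse = " | "), " |"))
  }
  lines
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", x$n, " sutures\n\n", sep = "")
  cat(format_summary_table(x), sep = "\n")
  if (!is.null(x$omnibus)) {
    cat("\nKruskal-Wallis omnibus:\n")
    print(as.data.frame(x$omnibus), row.names = FALSE, digits = 3)
  }
  if (!is.null(x$pairwise)) {
    cat("\nPairwise Mann-Whitney (uncorrected):\n")
    print(as.data.frame(x$pairwise), row.names = FALSE, digits = 3)
  }
  if (!is.null(x$correlations)) {
    cat("\nCollagen correlations:\n")
    print(as.data.frame(x$correlations), row.names = FALSE, digits = 3)
  }
  invisible(x)
}
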