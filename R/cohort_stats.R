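#' Summarize one sample's classified cells
#'
#' Produces the per-sample summary row used in cohort tables: cell counts,
#' the number of distinct chain identity keys observed in the sample, the
#' percentage of cells able to assemble a functional TCR, the split of
#' functional cells into single vs multiple TCR, the percentage of abnormal
#' cells, and the 23-pattern and chain-count-group frequency vectors.
#' Percentages are stored at full precision; [format_pct()] renders them to
#' the conventional three decimals.
#'
#' @param profiles list of `cell_profile` objects for one sample.
#' @param sample_id sample identifier.
#' @return a `sample_summary` (list); see Details for fields.
#' @details Fields: `sample_id`, `n_cells`, `n_unique_sequences`,
#'   `n_functional`, `pct_functional`, `pct_single`, `pct_multiple` (of
#'   functional cells; `NA` when no cell is functional), `pct_abnormal`,
#'   `pattern_freqs` (named 23-vector summing to 1), `group_freqs`
#'   (one/two/three_plus, summing to 1).
#' @export
summarize_sample <- function(profiles, sample_id) {
  stopifnot(length(profiles) >= 1)
  cls <- classify_cells(profiles)
  n <- nrow(cls)
  keys <- unlist(lapply(profiles, function(p) chain_identity_key(p$chains)),
                 use.names = FALSE)
  n_fun <- sum(cls$functional)
  n_single <- sum(cls$status == "single")
  n_multi <- sum(cls$status == "multiple")
  pat <- pattern_labels()
  pf <- stats::setNames(tabulate(cls$pattern_code, nbins = 23) / n,
                        pat$name)
  gf <- vapply(c("one", "two", "three_plus"),
               function(g) mean(cls$chain_group == g), numeric(1))
  s <- list(sample_id = sample_id,
            n_cells = n,
            n_unique_sequences = length(unique(keys)),
            n_functional = n_fun,
            pct_functional = 100 * n_fun / n,
            pct_single = if (n_fun > 0) 100 * n_single / n_fun else NA_real_,
            pct_multiple = if (n_fun > 0) 100 * n_multi / n_fun else NA_real_,
            pct_abnormal = 100 * (n - n_fun) / n,
            pattern_freqs = pf,
            group_freqs = gf)
  class(s) <- "sample_summary"
  s
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf(
    "<sample_summary> %s: %d cells, %d unique chains, %s%% functional (single/multiple %s/%s)\n",
    x$sample_id, x$n_cells, x$n_unique_sequences,
    format_pct(x$pct_functional), format_pct(x$pct_single),
    format_pct(x$pct_multiple)))
  invisible(x)
}

#' @export
as.data.frame.sample_summary <- function(x, ...) {
  data.frame(sample_id = x$sample_id, n_cells = x$n_cells,
             n_unique_sequences = x$n_unique_sequences,
             n_functional = x$n_functional,
             pct_functional = x$pct_functional,
             pct_single = x$pct_single, pct_multiple = x$pct_multiple,
             pct_abnormal = x$pct_abnormal, stringsAsFactors = FALSE)
}

#' Bind sample summaries into a cohort table
#'
#' @param summaries list of `sample_summary` objects.
#' @return data frame, one row per sample.
#' @export
summary_table <- function(summaries) {
  out <- do.call(rbind, lapply(summaries, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Aggregate per-sample percentages into group averages
#'
#' Group means are unweighted arithmetic means of the member samples'
#' percentages — each sample counts once, regardless of its cell count —
#' matching how cohort "Average" rows are conventionally reported.
#'
#' @param summaries either a list of `sample_summary` objects or a data
#'   frame with columns `sample_id`, `pct_functional`, `pct_single`,
#'   `pct_multiple`.
#' @param group_id group identifier.
#' @return a `group_summary`: `group_id`, `sample_ids`,
#'   `mean_pct_functional`, `mean_pct_single`, `mean_pct_multiple`.
#' @export
aggregate_group <- function(summaries, group_id) {
  df <- if (is.data.frame(summaries)) summaries else summary_table(summaries)
  if (nrow(df) == 0) stop("cannot aggregate an empty group")
  g <- list(group_id = group_id,
            sample_ids = df$sample_id,
            n_samples = nrow(df),
            mean_pct_functional = mean(df$pct_functional),
            mean_pct_single = mean(df$pct_single),
            mean_pct_multiple = mean(df$pct_multiple))
  class(g) <- "group_summary"
  g
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s (%d samples): functional %s%%, single/multiple %s/%s\n",
              x$group_id, x$n_samples, format_pct(x$mean_pct_functional),
              format_pct(x$mean_pct_single), format_pct(x$mean_pct_multiple)))
  invisible(x)
}

#' Compare a quantity across sample groups
#'
#' Dispatches the standard test battery: for two groups that both pass a
#' Shapiro-Wilk normality screen, a two-tailed t test (Student when Levene's
#' test accepts equal variances, Welch otherwise); for three or more normal,
#' homoscedastic groups, one-way ANOVA; otherwise the non-parametric
#' Mann-Whitney (two groups) or Kruskal-Wallis (three or more) test. Groups
#' too small for the normality screen (n < 3) are dispatched to the
#' non-parametric branch.
#'
#' @param values_by_group named list mapping group id to a numeric vector of
#'   per-sample values (each of length >= 2).
#' @param alpha_normality significance level for the Shapiro-Wilk and Levene
#'   screens (default 0.05).
#' @return a `test_result`: `test_name` (one of `t_test_two_tailed`,
#'   `anova_one_way`, `mann_whitney`, `kruskal_wallis`), `statistic`,
#'   `p_value`, `significance_label` (`ns`, `*` for p < 0.05, `**` for
#'   p < 0.01), and the screen p-values.
#' @export
compare_groups <- function(values_by_group, alpha_normality = 0.05) {
  k <- length(values_by_group)
  if (k < 2) stop("need at least two groups")
  sizes <- vapply(values_by_group, length, integer(1))
  if (any(sizes < 2)) stop("every group needs at least two values")
  x <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group), sizes))

  shapiro_p <- vapply(values_by_group, function(v) {
    if (length(v) < 3 || stats::var(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  # identical-value groups are degenerate but trivially symmetric; treat as
  # passing so the parametric identity case (t = 0, p = 1) is reachable
  normal_ok <- all(is.na(shapiro_p) | shapiro_p >= alpha_normality) &&
    all(sizes >= 3 | vapply(values_by_group, function(v)
      stats::var(v) == 0, logical(1)))
  levene_p <- if (normal_ok && stats::var(x) > 0) {
    lt <- car::leveneTest(x ~ g, center = mean)
    lt[["Pr(>F)"]][1]
  } else NA_real_
  var_ok <- is.na(levene_p) || levene_p >= alpha_normality

  if (k == 2) {
    if (normal_ok) {
      tt <- stats::t.test(values_by_group[[1]], values_by_group[[2]],
                          var.equal = var_ok, alternative = "two.sided")
      res <- list(test_name = "t_test_two_tailed",
                  statistic = unname(tt$statistic), p_value = tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(values_by_group[[1]],
                                                values_by_group[[2]]))
      res <- list(test_name = "mann_whitney",
                  statistic = unname(wt$statistic), p_value = wt$p.value)
    }
  } else {
    if (normal_ok && var_ok) {
      av <- stats::oneway.test(x ~ g, var.equal = TRUE)
      res <- list(test_name = "anova_one_way",
                  statistic = unname(av$statistic), p_value = av$p.value)
    } else {
      kw <- stats::kruskal.test(x ~ g)
      res <- list(test_name = "kruskal_wallis",
                  statistic = unname(kw$statistic), p_value = kw$p.value)
    }
  }
  res$significance_label <- significance_label(res$p_value)
  res$shapiro_p <- shapiro_p
  res$levene_p <- levene_p
  class(res) <- "test_result"
  res
}

#' Significance label for a p-value
#'
#' @param p p-value.
#' @return `"**"` if p < 0.01, `"*"` if p < 0.05, else `"ns"`.
#' @export
significance_label <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g [%s]\n",
              x$test_name, x$statistic, x$p_value, x$significance_label))
  invisible(x)
}

#' Write a cohort table with formatted percentages
#'
#' @param df data frame from [summary_table()] (optionally with group rows
#'   appended).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(df, path) {
  for (col in grep("^pct_|^mean_pct_", names(df), value = TRUE))
    df[[col]] <- format_pct(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
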