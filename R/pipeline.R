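#' Run the full chain-pattern analysis pipeline
#'
#' Chains the pipeline stages over one or more samples: read contigs,
#' apply QC, build per-cell chain profiles, classify patterns and TCR
#' status, summarize each sample, aggregate groups, run between-group
#' tests on the per-sample percentages, and trace multi-rearrangement
#' cells. All outputs are written as plain-text TSV/JSON under `out_dir`,
#' together with a run manifest.
#'
#' A summaries-only mode is supported: when `config$summaries` is given (a
#' data frame with `sample_id`, `group`, `pct_functional`, `pct_single`,
#' `pct_multiple`), the cell-level stages are skipped and only group
#' aggregation and tests are run, so cohort "Average" arithmetic can be
#' reproduced from published per-sample percentages.
#'
#' @param config list with either `samples` (data frame: `sample_id`,
#'   `path`, `dialect`, `group`) plus `species`, or `summaries` (see
#'   above); and `out_dir`. Optional: `seed` (recorded in the manifest).
#' @return (invisibly) list with `summaries` (data frame), `groups` (list
#'   of `group_summary`), `tests` (list of `test_result`), `qc` (list of
#'   `qc_report`), `mechanisms` (data frame or NULL), `manifest`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("tcrtrace")),
                   seed = config$seed %||% NA,
                   species = config$species %||% NA,
                   stages = character(0), warnings = character(0))

  if (!is.null(config$summaries)) {
    df <- config$summaries
    need <- c("sample_id", "group", "pct_functional", "pct_single",
              "pct_multiple")
    if (!all(need %in% names(df)))
      stop("stage summaries-input: missing column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
    summaries <- df
    qc <- NULL; mechanisms <- NULL
    manifest$stages <- "summaries_input"
  } else {
    samples <- config$samples
    species <- config$species %||% "human"
    qc <- list(); per_sample <- list(); mech_rows <- list()
    for (i in seq_len(nrow(samples))) {
      sid <- samples$sample_id[i]
      res <- tryCatch({
        rec <- read_contig_table(samples$path[i], samples$dialect[i])
        flt <- apply_qc_filters(rec)
        profiles <- withCallingHandlers(
          build_cell_profiles(flt$kept, species),
          warning = function(w) {
            manifest$warnings <<- c(manifest$warnings,
                                    paste0(sid, ": ", conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
        if (!length(profiles))
          stop("no classifiable cells after QC")
        cls <- classify_cells(profiles)
        utils::write.table(cls, file.path(out_dir,
                                          paste0(sid, "_cells.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        write_qc_report(flt$report, file.path(out_dir,
                                              paste0(sid, "_qc.json")))
        tr <- trace_sample(profiles, species)
        if (!is.null(tr)) tr <- cbind(sample_id = sid, tr)
        list(qc = flt$report, summary = summarize_sample(profiles, sid),
             trace = tr)
      }, error = function(e)
        stop("stage sample-processing, sample ", sid, ": ",
             conditionMessage(e), call. = FALSE))
      qc[[sid]] <- res$qc
      per_sample[[sid]] <- res$summary
      if (!is.null(res$trace)) mech_rows[[sid]] <- res$trace
    }
    summaries <- summary_table(per_sample)
    summaries$group <- samples$group[match(summaries$sample_id,
                                           samples$sample_id)]
    mechanisms <- if (length(mech_rows)) do.call(rbind, mech_rows) else NULL
    if (!is.null(mechanisms)) {
      rownames(mechanisms) <- NULL
      utils::write.table(mechanisms, file.path(out_dir, "mechanisms.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages <- c("qc", "classify", "summarize", "trace")
  }

  groups <- lapply(split(summaries, summaries$group), function(df)
    aggregate_group(df, df$group[1]))
  group_df <- do.call(rbind, lapply(groups, function(g)
    data.frame(group_id = g$group_id, n_samples = g$n_samples,
               mean_pct_functional = g$mean_pct_functional,
               mean_pct_single = g$mean_pct_single,
               mean_pct_multiple = g$mean_pct_multiple,
               stringsAsFactors = FALSE)))
  rownames(group_df) <- NULL
  write_summary_tsv(summaries, file.path(out_dir, "sample_summaries.tsv"))
  write_summary_tsv(group_df, file.path(out_dir, "group_summaries.tsv"))

  tests <- list()
  by_group <- split(summaries, summaries$group)
  if (length(by_group) >= 2 &&
      all(vapply(by_group, nrow, integer(1)) >= 2)) {
    for (metric in c("pct_functional", "pct_single", "pct_multiple")) {
      vals <- lapply(by_group, `[[`, metric)
      if (any(vapply(vals, function(v) any(is.na(v)), logical(1)))) next
      tests[[metric]] <- compare_groups(vals)
    }
    jsonlite::write_json(
      lapply(tests, function(t)
        list(test_name = t$test_name, statistic = t$statistic,
             p_value = t$p_value,
             significance_label = t$significance_label)),
      file.path(out_dir, "group_tests.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages <- c(manifest$stages, "compare")
  }

  manifest$config_hash <- config_hash(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(summaries = summaries, groups = groups, tests = tests,
                 qc = qc, mechanisms = mechanisms, manifest = manifest))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  # out_dir does not affect results; exclude it from the hash
  config$out_dir <- NULL
  saveRDS(config, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
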